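#' Feature selection frequencies across holdout iterations
#'
#' The stability profile of the ensemble: for each feature, the fraction of
#' holdout iterations in which its coefficient was nonzero.
#'
#' @param result A `model_result` from [repeated_holdout()].
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
selection_frequencies <- function(result) {
  stopifnot(inherits(result, "model_result"))
  if (is.null(result$selection) || nrow(result$selection) < 1L)
    id_stop("model result has no iterations", "immunodyn_config_error")
  colMeans(result$selection)
}

#' Two-segment piecewise-regression breakpoint
#'
#' Given a descending sequence (selection frequencies sorted high to low),
#' finds the split index `k` minimizing the total SSE of two independent
#' least-squares lines fit to positions `1..k` and `k+1..n`. This locates the
#' "abrupt shift" separating stably selected features from the rest. The two
#' segments are free (discontinuous); a continuity-constrained broken-line
#' variant is available via `continuous = TRUE`. Ties resolve to the smallest
#' `k`. If no split improves on a single line by more than a relative 1e-12,
#' the result is flagged `no_shift`.
#'
#' @param sorted_frequencies Numeric vector, sorted non-increasing, length >= 4.
#' @param continuous Constrain the two segments to meet at the breakpoint.
#' @return List: `k` (breakpoint index, last position of the first segment),
#'   `sse`, `sse_single` (one-line fit), `no_shift` flag.
#' @export
piecewise_breakpoint <- function(sorted_frequencies, continuous = FALSE) {
  f <- as.numeric(sorted_frequencies)
  n <- length(f)
  if (n < 4L)
    id_stop("need at least 4 points for a two-segment fit", "immunodyn_config_error")
  if (any(diff(f) > 1e-12))  # tolerate fp jitter
    id_stop("frequencies must be sorted in descending order", "immunodyn_config_error")
  x <- seq_len(n)
  seg_sse <- function(idx) {
    if (length(idx) < 2L) return(0)
    fit <- stats::lm.fit(cbind(1, x[idx]), f[idx])
    sum(fit$residuals^2)
  }
  sse_single <- seg_sse(x)
  ks <- 2:(n - 2L)
  sse <- vapply(ks, function(k) {
    if (!continuous) return(seg_sse(1:k) + seg_sse((k + 1L):n))
    # continuous broken line: basis {1, x, (x - k)_+}
    B <- cbind(1, x, pmax(x - k, 0))
    sum(stats::lm.fit(B, f)$residuals^2)
  }, numeric(1))
  best <- which.min(sse)  # first minimum: exact ties resolve to smallest k
  k <- ks[best]
  total_ss <- sum((f - mean(f))^2)
  no_shift <- (sse_single - sse[best]) < 1e-12 * max(total_ss, .Machine$double.eps)
  list(k = k, sse = sse[best], sse_single = sse_single, no_shift = no_shift)
}

#' Reduce the ensemble model to its stable informative core
#'
#' Ranks features by selection frequency (ties broken by mean absolute
#' standardized coefficient across iterations, then by feature id), locates
#' the piecewise-regression breakpoint on the descending frequency curve, and
#' returns the features above the breakpoint, each annotated with its
#' univariate rate-of-change AUC for the group contrast.
#'
#' @param result A `model_result`.
#' @param continuous Passed to [piecewise_breakpoint()].
#' @return A `selection_profile`: `table` (feature, frequency, rank, mean
#'   absolute coefficient, univariate AUC, `in_top_set`), `breakpoint`,
#'   `top_features`, `no_shift`.
#' @export
reduce_model <- function(result, continuous = FALSE) {
  freq <- selection_frequencies(result)
  if (all(freq == 0))
    id_stop("null model; nothing to reduce", "immunodyn_null_model_error")
  tie <- result$mean_abs_coef
  ord <- order(-freq, -tie, names(freq), method = "radix")
  freq_sorted <- freq[ord]
  bp <- piecewise_breakpoint(as.numeric(freq_sorted), continuous = continuous)
  top <- names(freq_sorted)[seq_len(bp$k)]
  uni_auc <- vapply(names(freq_sorted), function(fid) {
    v <- result$rates[, fid]
    ok <- !is.na(v)
    if (length(unique(result$labels[ok])) < 2L) return(NA_real_)
    auc_mann_whitney(v[ok], result$labels[ok])
  }, numeric(1))
  tab <- data.frame(feature = names(freq_sorted),
                    frequency = as.numeric(freq_sorted),
                    rank = seq_along(freq_sorted),
                    mean_abs_coef = as.numeric(tie[ord]),
                    univariate_auc = as.numeric(uni_auc),
                    in_top_set = seq_along(freq_sorted) <= bp$k,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, breakpoint = bp$k, top_features = top,
                 no_shift = bp$no_shift, sse = bp$sse,
                 sse_single = bp$sse_single),
            class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf("selection_profile: breakpoint at %d feature(s)%s\n",
              x$breakpoint, if (x$no_shift) " [no abrupt shift detected]" else ""))
  print(utils::head(x$table, x$breakpoint))
  invisible(x)
}
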