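# Independent oracles used to cross-check package implementations.
# These deliberately use different algorithms/code paths than the package.

# penalized logistic objective, direct R formula
oracle_objective <- function(X, y, b0, beta, lambda) {
  eta <- b0 + drop(X %*% beta)
  -sum(y * eta - log(1 + exp(eta))) + lambda * sum(abs(beta))
}

# brute-force optimum: Nelder-Mead restarts from several starts, including a
# perturbed copy of `start` when given
oracle_lasso_optimum <- function(X, y, lambda, start = NULL, n_restarts = 8,
                                 seed = 1) {
  set.seed(seed)
  p <- ncol(X)
  f <- function(par) oracle_objective(X, y, par[1], par[-1], lambda)
  starts <- list(rep(0, p + 1))
  if (!is.null(start)) {
    starts <- c(starts, list(start),
                lapply(seq_len(3), function(i) start + rnorm(p + 1, 0, 0.05)))
  }
  starts <- c(starts, lapply(seq_len(n_restarts), function(i) rnorm(p + 1, 0, 0.5)))
  best <- Inf
  for (s in starts) {
    o <- optim(s, f, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
    o <- optim(o$par, f, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# exhaustive concordant-pair AUC with ties counted 0.5
oracle_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# exhaustive two-segment OLS breakpoint (independent lm-based implementation)
oracle_breakpoint <- function(f) {
  n <- length(f)
  x <- seq_len(n)
  sse2 <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(resid(lm(f[idx] ~ x[idx]))^2)
  }
  ks <- 2:(n - 2)
  sse <- sapply(ks, function(k) sse2(1:k) + sse2((k + 1):n))
  ks[which.min(sse)]
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# exhaustive best-bipartition modularity for a small undirected graph
oracle_best_bipartition <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 12)
  best_q <- -Inf
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {  # fix node 1 in group 0: halves the search
    memb <- c(0, as.integer(intToBits(mask))[seq_len(n - 1)])
    q <- igraph::modularity(g, memb + 1)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  list(membership = best, modularity = best_q)
}

# build an edge data.frame in the package's expected shape
make_edges <- function(from, to, weight = 1, features = NULL) {
  weight <- rep(weight, length.out = length(from))
  ed <- data.frame(from = from, to = to, rho = rep(1, length(from)),
                   p = 10^(-weight), weight = weight,
                   stringsAsFactors = FALSE)
  attr(ed, "features") <- if (is.null(features)) sort(unique(c(from, to)))
  else features
  ed
}

# planted-partition random graph; returns edges + truth labels
make_planted_partition <- function(n_blocks, block_size, p_in, p_out, seed) {
  set.seed(seed)
  n <- n_blocks * block_size
  labels <- rep(seq_len(n_blocks), each = block_size)
  nodes <- sprintf("v%02d", seq_len(n))
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pr <- if (labels[i] == labels[j]) p_in else p_out
    if (runif(1) < pr) { from <- c(from, nodes[i]); to <- c(to, nodes[j]) }
  }
  list(edges = make_edges(from, to, weight = 1, features = nodes),
       truth = setNames(labels, nodes))
}

# minimal stand-in for a model_result (for reduction unit tests)
make_fake_result <- function(selection, rates = NULL, labels = NULL,
                             mean_abs_coef = NULL) {
  p <- ncol(selection)
  feats <- colnames(selection)
  if (is.null(feats)) feats <- sprintf("f%02d", seq_len(p))
  colnames(selection) <- feats
  if (is.null(rates)) {
    rates <- matrix(rnorm(10 * p), 10, p, dimnames = list(NULL, feats))
  }
  if (is.null(labels)) labels <- rep(c(0L, 1L), length.out = nrow(rates))
  if (is.null(mean_abs_coef)) mean_abs_coef <- setNames(rep(0, p), feats)
  structure(list(selection = selection, rates = rates, labels = labels,
                 mean_abs_coef = mean_abs_coef,
                 n_iterations = nrow(selection)),
            class = "model_result")
}

# tiny event table with exact transformed values
tiny_event_table <- function(df, patient = "P1", timepoint = "T1",
                             condition = "unstim", transformed = TRUE) {
  event_table(df, patient, timepoint, condition, transformed = transformed)
}
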