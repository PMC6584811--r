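#' Significant Spearman edges between immune features
#'
#' Computes the Spearman correlation for every unordered feature pair over the
#' supplied observations (by default the stacked T1 + T2 samples, so each
#' (patient, timepoint) is one observation), with the two-sided p-value from
#' the t approximation `t = rho * sqrt((n-2) / (1-rho^2))`. Pairs with
#' `p < threshold` become edges; perfectly monotone pairs (`|rho| = 1`) are
#' retained with `-log10(p)` clamped at 300. Constant features are skipped.
#' Observations are pairwise-complete.
#'
#' @param fm Numeric matrix of observations x features (e.g.
#'   `rbind(t1, t2)`), or a single `feature_matrix`.
#' @param threshold Two-sided p-value threshold (default `1e-12`).
#' @param min_obs Minimum paired observations per pair.
#' @return `data.frame` of edges: `from`, `to`, `rho`, `p`, `weight`
#'   (`-log10 p`, clamped), plus a `features` attribute listing all non-constant
#'   nodes.
#' @export
spearman_edges <- function(fm, threshold = 1e-12, min_obs = 10L) {
  X <- as.matrix(fm)
  feats <- colnames(X)
  keep <- apply(X, 2L, function(v) length(unique(v[!is.na(v)])) > 1L)
  if (any(!keep))
    id_log("skipping %d constant feature(s)", sum(!keep))
  X <- X[, keep, drop = FALSE]
  feats <- feats[keep]
  p <- ncol(X)
  if (!anyNA(X) && nrow(X) >= min_obs && p >= 2L) {
    # complete data: Spearman = Pearson on midranks, computed in one shot
    n <- nrow(X)
    R <- apply(X, 2L, rank)
    C <- suppressWarnings(cor(R))
    iu <- which(upper.tri(C), arr.ind = TRUE)
    rho <- C[iu]
    pv <- ifelse(abs(rho) >= 1 - 1e-15, 0,
                 2 * pt(-abs(rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))),
                        df = n - 2))
    sel <- !is.na(rho) & pv < threshold
    edges <- data.frame(from = feats[iu[sel, 1L]], to = feats[iu[sel, 2L]],
                        rho = rho[sel], p = pv[sel],
                        weight = pmin(-log10(pmax(pv[sel], 1e-300)), 300),
                        stringsAsFactors = FALSE)
    attr(edges, "features") <- feats
    return(edges)
  }
  out <- vector("list", 256L); n_out <- 0L
  for (i in seq_len(max(p - 1L, 0L))) {
    xi <- X[, i]
    for (j in (i + 1L):p) {
      ok <- !is.na(xi) & !is.na(X[, j])
      n <- sum(ok)
      if (n < min_obs) next
      rho <- suppressWarnings(cor(xi[ok], X[ok, j], method = "spearman"))
      if (is.na(rho)) next
      if (abs(rho) >= 1 - 1e-15) {
        pv <- 0
      } else {
        tt <- rho * sqrt((n - 2) / (1 - rho^2))
        pv <- 2 * pt(-abs(tt), df = n - 2)
      }
      if (pv < threshold) {
        n_out <- n_out + 1L
        if (n_out > length(out)) out <- c(out, vector("list", length(out)))
        out[[n_out]] <- list(from = feats[i], to = feats[j], rho = rho, p = pv)
      }
    }
  }
  edges <- if (n_out) {
    d <- do.call(rbind.data.frame, c(out[seq_len(n_out)],
                                     list(stringsAsFactors = FALSE)))
    d$weight <- pmin(-log10(pmax(d$p, 1e-300)), 300)
    d
  } else {
    data.frame(from = character(), to = character(), rho = numeric(),
               p = numeric(), weight = numeric(), stringsAsFactors = FALSE)
  }
  attr(edges, "features") <- feats
  edges
}

#' Build a correlation network object
#'
#' Wraps the edge list into an igraph graph over all (non-constant) features
#' and runs community detection and the 2-D layout.
#'
#' @param edges Output of [spearman_edges()].
#' @param seed Seed for community detection restarts and the layout.
#' @param detect,layout Toggles for the two computations.
#' @return A `correlation_network`: `graph` (igraph), `edges`, `communities`
#'   (named membership vector), `modularity`, `layout` (n x 2 matrix).
#' @export
build_correlation_network <- function(edges, seed = 1L, detect = TRUE,
                                      layout = TRUE) {
  feats <- attr(edges, "features")
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight", "rho", "p")],
    directed = FALSE,
    vertices = data.frame(name = feats, stringsAsFactors = FALSE))
  net <- structure(list(graph = g, edges = edges,
                        communities = NULL, modularity = NA_real_,
                        layout = NULL, seed = seed),
                   class = "correlation_network")
  if (detect) net <- detect_communities(net, seed = seed)
  if (layout) net$layout <- layout_network(net, seed = seed)
  net
}

#' Louvain community detection on the correlation network
#'
#' Multi-level modularity optimization (igraph's Louvain implementation) with
#' edge weights `-log10(p)`. The algorithm is run `n_restarts` times from the
#' seeded RNG state and the partition with the highest modularity is kept, so
#' the result is deterministic given `seed`. With no edges every node becomes
#' its own community (with a warning).
#'
#' @param net A `correlation_network` (or list with `graph`).
#' @param seed Integer seed.
#' @param n_restarts Louvain restarts; best modularity wins.
#' @return `net` with `communities` (named integer membership) and
#'   `modularity` filled in.
#' @export
detect_communities <- function(net, seed = 1L, n_restarts = 10L) {
  g <- net$graph
  if (igraph::ecount(g) == 0L) {
    warning("empty edge set: every node is its own community")
    memb <- seq_len(igraph::vcount(g))
    names(memb) <- igraph::V(g)$name
    net$communities <- memb
    net$modularity <- NA_real_
    return(net)
  }
  set.seed(seed)
  best <- NULL; best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
    if (q > best_q) { best_q <- q; best <- cl }
  }
  memb <- as.integer(igraph::membership(best))
  names(memb) <- igraph::V(g)$name
  net$communities <- memb
  net$modularity <- best_q
  net
}

#' 2-D layout of the correlation network (t-SNE)
#'
#' Embeds the feature nodes with t-SNE on the node dissimilarity matrix:
#' `1 / (1 + weight)` for connected pairs (`weight = -log10 p`) and the
#' maximum dissimilarity otherwise. Cosmetic only — no analysis depends on
#' coordinates. Deterministic given `seed`. Fewer than 3 nodes get a trivial
#' layout.
#'
#' @param net A `correlation_network`.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; capped at `(n-1)/3`.
#' @return Numeric n x 2 matrix of coordinates (rownames = features).
#' @export
layout_network <- function(net, seed = 1L, perplexity = 10) {
  g <- net$graph
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (n < 3L) {
    xy <- cbind(x = seq_len(n), y = rep(0, n))
    rownames(xy) <- nm
    return(xy)
  }
  W <- matrix(0, n, n, dimnames = list(nm, nm))
  ed <- net$edges
  if (nrow(ed)) {
    W[cbind(ed$from, ed$to)] <- ed$weight
    W[cbind(ed$to, ed$from)] <- ed$weight
  }
  D <- 1 / (1 + W)
  diag(D) <- 0
  perp <- min(perplexity, floor((n - 1) / 3))
  perp <- max(perp, 1)
  set.seed(seed)
  fit <- Rtsne::Rtsne(stats::as.dist(D), is_distance = TRUE, dims = 2L,
                      perplexity = perp, theta = 0, max_iter = 500L,
                      verbose = FALSE)
  xy <- fit$Y
  dimnames(xy) <- list(nm, c("x", "y"))
  xy
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d nodes, %d edges",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  if (!is.null(x$communities))
    cat(sprintf(", %d communities (modularity %.3f)",
                length(unique(x$communities)), x$modularity))
  cat("\n")
  invisible(x)
}

#' Export the network
#'
#' Writes the graph as GraphML plus a plain edge-list CSV and a community
#' table CSV.
#'
#' @param net A `correlation_network`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- net$graph
  if (!is.null(net$communities))
    g <- igraph::set_vertex_attr(g, "community",
                                 value = net$communities[igraph::V(g)$name])
  paths <- c(graphml = file.path(dir, "network.graphml"),
             edges = file.path(dir, "edges.csv"),
             communities = file.path(dir, "communities.csv"))
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  write.csv(net$edges, paths[["edges"]], row.names = FALSE)
  if (!is.null(net$communities))
    write.csv(data.frame(feature = names(net$communities),
                         community = as.integer(net$communities)),
              paths[["communities"]], row.names = FALSE)
  invisible(paths)
}
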