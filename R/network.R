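#' Fisher r-to-Z meta-combination of correlations
#'
#' Fixed-effect combination: per-cohort correlations are transformed with
#' `atanh`, averaged with weights `n_k - 3`, and back-transformed; the
#' combined p-value comes from `z_bar * sqrt(sum(n_k - 3))` against the
#' standard normal. With a single cohort the input is returned unchanged.
#'
#' @param r_list List of correlation matrices (or scalars), one per cohort.
#' @param n Vector of per-cohort sample sizes (each > 3).
#' @return List with `r` (combined correlation), `z` (weighted mean
#'   transform), and `p` (two-sided). Matrix inputs give matrix outputs with
#'   unit diagonal and `NA` diagonal p.
#' @export
meta_correlation <- function(r_list, n) {
  if (length(r_list) != length(n)) stop("one sample size per cohort")
  if (any(n <= 3)) stop("every cohort needs n > 3")
  is_mat <- is.matrix(r_list[[1]])
  for (r in r_list) {
    off <- if (is.matrix(r)) r[row(r) != col(r)] else r
    if (any(abs(off) >= 1))
      stop("|r| = 1 cannot be combined (infinite z)")
  }
  w <- n - 3
  zs <- lapply(seq_along(r_list), function(k) {
    z <- suppressWarnings(atanh(r_list[[k]]))
    if (is.matrix(z)) diag(z) <- 0
    z * w[k]
  })
  zbar <- Reduce(`+`, zs) / sum(w)
  rbar <- tanh(zbar)
  zstat <- zbar * sqrt(sum(w))
  p <- 2 * pnorm(-abs(zstat))
  if (is_mat) { diag(rbar) <- 1; diag(p) <- NA }
  list(r = rbar, z = zbar, p = p, n = n)
}

#' Build a co-occurrence network from combined correlations
#'
#' Keeps the pairs with combined `p < p_cut` as undirected edges weighted by
#' `|r|` (the sign is stored as an edge attribute); every species is a node,
#' optionally annotated with an enrichment direction.
#'
#' @param r Combined correlation matrix.
#' @param p Combined p-value matrix.
#' @param labels Optional per-species annotation (e.g. enriched/depleted),
#'   named or in row order.
#' @param p_cut Edge inclusion cutoff.
#' @return Object of class `meta_network` wrapping an igraph graph plus the
#'   underlying `r`, `p` and cutoff.
#' @export
build_network <- function(r, p, labels = NULL, p_cut = 0.05) {
  if (is.null(rownames(r)))
    rownames(r) <- colnames(r) <- sprintf("sp%04d", seq_len(nrow(r)))
  dimnames(p) <- dimnames(r)
  ut <- which(upper.tri(r) & !is.na(p) & p < p_cut, arr.ind = TRUE)
  edges <- data.frame(from = rownames(r)[ut[, 1]], to = rownames(r)[ut[, 2]],
                      weight = abs(r[ut]), sign = sign(r[ut]), r = r[ut],
                      p = p[ut], stringsAsFactors = FALSE)
  nodes <- data.frame(name = rownames(r), stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    nodes$enrichment <- if (!is.null(names(labels)))
      as.character(labels[nodes$name]) else as.character(labels)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, r = r, p = p, p_cut = p_cut),
            class = "meta_network")
}

#' @export
print.meta_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (p < %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$p_cut))
  invisible(x)
}

.as_graph <- function(net) {
  if (inherits(net, "meta_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected a meta_network or igraph object")
}

#' Connectivity metrics of a weighted network
#'
#' Weighted degree centrality (sum of incident edge weights per node),
#' global efficiency
#' `E_global = 2 / (n (n - 1)) * sum over pairs of 1 / d(i, j)` with `d` the
#' shortest-path hop count (`1 / d = 0` for disconnected pairs; a complete
#' graph scores 1), and weighted connectance
#' `sum over ordered pairs of w(i, j) / n^2`.
#'
#' @param net A `meta_network` or igraph graph with edge `weight`s.
#' @param distance `"hops"` (default) for unweighted shortest paths or
#'   `"inverse-weight"` for `1/w`-weighted paths.
#' @return List with `centrality` (named vector), `global_efficiency`,
#'   `connectance` and `n`.
#' @export
network_metrics <- function(net, distance = c("hops", "inverse-weight")) {
  distance <- match.arg(distance)
  g <- .as_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 nodes")
  wts <- if (distance == "hops") NA else 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = wts)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  eg <- sum(inv) / (n * (n - 1))
  w <- if (igraph::ecount(g) > 0) sum(igraph::E(g)$weight) else 0
  list(centrality = igraph::strength(g),
       global_efficiency = eg,
       connectance = 2 * w / n^2,
       n = n)
}

#' Node-removal robustness of network connectivity
#'
#' Removes nodes one at a time — targeted by descending weighted degree
#' centrality, and as a random baseline averaged over `n_random` orders —
#' recording global efficiency and connectance after each removal.
#'
#' @param net A `meta_network` or igraph graph.
#' @param n_random Random removal orders for the baseline.
#' @param seed Optional integer seed.
#' @return Data frame with columns `order_type`, `removed`, `efficiency`,
#'   `connectance` and (random baseline) `efficiency_se`.
#' @export
robustness_analysis <- function(net, n_random = 20, seed = NULL) {
  .seed_in(seed)
  g <- .as_graph(net)
  n <- igraph::vcount(g)
  if (n < 3) stop("need at least 3 nodes")
  trace_order <- function(ord) {
    keep <- igraph::V(g)$name
    steps <- lapply(0:(n - 2), function(k) {
      if (k > 0) keep <<- setdiff(keep, ord[k])
      mt <- network_metrics(igraph::induced_subgraph(g, keep))
      c(efficiency = mt$global_efficiency, connectance = mt$connectance)
    })
    do.call(rbind, steps)
  }
  targeted <- trace_order(names(sort(igraph::strength(g),
                                     decreasing = TRUE)))
  rand <- lapply(seq_len(n_random), function(b)
    trace_order(sample(igraph::V(g)$name)))
  rmean <- Reduce(`+`, rand) / n_random
  rse <- sqrt(Reduce(`+`, lapply(rand, function(m) (m - rmean)^2)) /
                (n_random * max(n_random - 1, 1)))
  rbind(
    data.frame(order_type = "targeted", removed = 0:(n - 2),
               efficiency = targeted[, 1], connectance = targeted[, 2],
               efficiency_se = 0),
    data.frame(order_type = "random", removed = 0:(n - 2),
               efficiency = rmean[, 1], connectance = rmean[, 2],
               efficiency_se = rse[, 1]))
}

#' Compare two networks over a shared pair universe
#'
#' Tests the difference in the proportion of significant correlations
#' (two-proportion test over all node pairs) and in correlation strength
#' (two-sided Mann-Whitney on `|r|` over the pair universe), plus a
#' histogram-midpoint summary of the `|r|` distributions.
#'
#' @param net_a,net_b `meta_network` objects over the same node universe.
#' @param breaks Histogram breaks for the strength summary.
#' @return List with `proportion_test`, `strength_test`, per-network
#'   significant-pair counts and the strength histogram midpoints.
#' @export
compare_networks <- function(net_a, net_b, breaks = seq(0, 1, 0.1)) {
  if (!identical(rownames(net_a$r), rownames(net_b$r)))
    stop("networks must share the same node universe")
  ut <- upper.tri(net_a$r)
  n_pairs <- sum(ut)
  ka <- sum(net_a$p[ut] < net_a$p_cut, na.rm = TRUE)
  kb <- sum(net_b$p[ut] < net_b$p_cut, na.rm = TRUE)
  pt <- prop.test(c(ka, kb), c(n_pairs, n_pairs))
  sa <- abs(net_a$r[ut]); sb <- abs(net_b$r[ut])
  st <- suppressWarnings(wilcox.test(sa, sb))
  mids <- breaks[-length(breaks)] + diff(breaks) / 2
  hist_a <- hist(sa, breaks = breaks, plot = FALSE)$counts
  hist_b <- hist(sb, breaks = breaks, plot = FALSE)$counts
  list(proportion_test = list(p_value = pt$p.value,
                              proportions = c(a = ka / n_pairs,
                                              b = kb / n_pairs)),
       strength_test = list(p_value = st$p.value,
                            median_abs_r = c(a = median(sa), b = median(sb))),
       n_significant = c(a = ka, b = kb), n_pairs = n_pairs,
       strength_histogram = data.frame(midpoint = mids, a = hist_a,
                                       b = hist_b))
}

#' Export a network to GraphML and an edge-list TSV
#'
#' Writes a Cytoscape-ingestible GraphML file (node enrichment and
#' centrality attributes; edge weight, sign and p attributes) and a plain
#' edge-list TSV.
#'
#' @param net A `meta_network` (>= 1 node).
#' @param graphml Output GraphML path (`NULL` to skip).
#' @param edges Output edge TSV path (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, graphml = NULL, edges = NULL) {
  g <- .as_graph(net)
  if (igraph::vcount(g) < 1) stop("network has no nodes")
  igraph::V(g)$centrality <- igraph::strength(g)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edges)) {
    ed <- igraph::as_data_frame(g, what = "edges")
    write.table(ed, edges, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(graphml = graphml, edges = edges))
}
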