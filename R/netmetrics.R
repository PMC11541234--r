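# Graph construction and metrics: density thresholding of the asymmetric
# connectivity matrix, global metrics normalized to Erdos-Renyi random
# digraphs of the same size (small-world gamma, lambda, sigma), nodal
# metrics, the sigma(density) curve over the 2-20% grid, and turning-point
# density selection.

GLOBAL_METRIC_NAMES <- c(
  "C_raw", "L_raw", "gamma", "lambda", "sigma",
  "largest_component", "n_components", "global_efficiency", "diameter",
  "assortativity", "transitivity", "modularity",
  "mean_strength", "mean_betweenness")

NODE_METRIC_NAMES <- c(
  "in_degree", "out_degree", "degree",
  "in_strength", "out_strength", "strength",
  "clustering", "nodal_path_length",
  "hub_score", "authority_score",
  "betweenness", "closeness", "eigenvector", "local_efficiency")

#' Threshold a connectivity matrix to a target edge density
#'
#' Keeps the `k = round(d * R * (R - 1))` algebraically largest off-diagonal
#' entries (signed ranking: strong negative correlations are dropped first),
#' with deterministic tie-breaking by row-then-column index.  Produces a
#' binary adjacency for topology metrics and a weighted twin (retained
#' correlations) for strengths.
#'
#' @param cm a `connectivity_matrix` or plain R x R matrix.
#' @param d target density in (0, 1], the fraction of the R(R-1) possible
#'   directed edges.
#' @param rank_by `"signed"` (default) or `"abs"`.
#' @return list of class `brain_graph`: `adj` (binary), `w` (weighted),
#'   `d`, `R`.
#' @export
threshold_to_density <- function(cm, d, rank_by = c("signed", "abs")) {
  rank_by <- match.arg(rank_by)
  M <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  R <- nrow(M)
  if (R < 2L) stop("need at least 2 regions")
  if (d <= 0 || d > 1) stop("density must lie in (0, 1]")
  k <- round(d * R * (R - 1))
  if (k == 0L) stop(sprintf("density %g too low for R = %d (no edges)", d, R))
  off <- which(row(M) != col(M))
  key <- M[off]
  if (rank_by == "abs") key <- abs(key)
  ord <- off[order(-key, row(M)[off], col(M)[off])]
  keep <- ord[seq_len(min(k, length(ord)))]
  adj <- matrix(0L, R, R)
  adj[keep] <- 1L
  w <- matrix(0, R, R)
  w[keep] <- M[keep]
  dimnames(adj) <- dimnames(w) <- dimnames(M)
  structure(list(adj = adj, w = w, d = d, R = R), class = "brain_graph")
}

.as_igraph <- function(graph, weighted = FALSE) {
  m <- if (weighted) graph$w else graph$adj
  igraph::graph_from_adjacency_matrix(
    m, mode = "directed", weighted = if (weighted) TRUE else NULL,
    diag = FALSE)
}

# raw clustering / path length on a directed binary graph: clustering on
# the underlying undirected graph, L over ordered reachable pairs only
.c_and_l <- function(g) {
  gu <- igraph::as_undirected(g, mode = "collapse")
  cl <- igraph::transitivity(gu, type = "localaverage", isolates = "zero")
  D <- igraph::distances(g, mode = "out")
  finite <- is.finite(D) & row(D) != col(D)
  L <- if (any(finite)) mean(D[finite]) else NA_real_
  list(C = cl, L = L)
}

#' Global graph metrics with random-network normalization
#'
#' Computes the 14-metric global schema on the binary directed graph:
#' mean local clustering `C_raw` and characteristic path length `L_raw`
#' (mean over ordered reachable pairs), their ratios `gamma` and `lambda`
#' to the mean over `n_random` Erdos-Renyi digraphs with identical node and
#' edge counts, the small-world index `sigma = gamma / lambda`, component
#' structure, efficiency, diameter, degree assortativity, global
#' transitivity, modularity of the undirected collapse, and mean strength /
#' betweenness.
#'
#' @param graph a `brain_graph`.
#' @param n_random number of random reference digraphs (default 100).
#' @param seed RNG seed for the reference ensemble.
#' @param null_model `"erdos_renyi"` (matched node/edge counts, default) or
#'   `"rewire"` (degree-preserving rewiring) for sensitivity analysis.
#' @return named numeric vector over the fixed 14-metric schema.
#' @export
global_metrics <- function(graph, n_random = 100L, seed = 1L,
                           null_model = c("erdos_renyi", "rewire")) {
  null_model <- match.arg(null_model)
  stopifnot(inherits(graph, "brain_graph"))
  g <- .as_igraph(graph)
  gw <- .as_igraph(graph, weighted = TRUE)
  m <- igraph::ecount(g)
  if (m == 0L) stop("graph has no edges")
  obs <- .c_and_l(g)
  if (is.na(obs$L))
    warning("no reachable pairs: L undefined, lambda and sigma missing")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  Cr <- Lr <- numeric(n_random)
  for (b in seq_len(n_random)) {
    gr <- if (null_model == "erdos_renyi")
      igraph::sample_gnm(graph$R, m, directed = TRUE)
    else
      igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
    rb <- .c_and_l(gr)
    Cr[b] <- rb$C; Lr[b] <- rb$L
  }
  gamma <- obs$C / mean(Cr)
  lambda <- obs$L / mean(Lr, na.rm = TRUE)
  comp <- igraph::components(g, mode = "weak")
  strengths <- rowSums(abs(graph$w)) + colSums(abs(graph$w))
  out <- c(
    C_raw = obs$C, L_raw = obs$L, gamma = gamma, lambda = lambda,
    sigma = gamma / lambda,
    largest_component = max(comp$csize), n_components = comp$no,
    global_efficiency = igraph::global_efficiency(g, directed = TRUE),
    diameter = igraph::diameter(g),
    assortativity = igraph::assortativity_degree(g, directed = TRUE),
    transitivity = igraph::transitivity(
      igraph::as_undirected(g, mode = "collapse"), type = "global"),
    modularity = igraph::modularity(igraph::cluster_louvain(
      igraph::as_undirected(g, mode = "collapse"))),
    mean_strength = mean(strengths),
    mean_betweenness = mean(igraph::betweenness(g, directed = TRUE)))
  out[GLOBAL_METRIC_NAMES]
}

#' Nodal graph metrics
#'
#' The 14-metric nodal schema per region: in/out/total degree on the binary
#' graph, in/out/total strength on the weighted twin (absolute weights),
#' local clustering (undirected collapse, isolates 0), nodal path length
#' (mean shortest path to reachable targets; `NA` when none), HITS hub and
#' authority scores, betweenness, out-closeness (`NA` for isolated nodes),
#' eigenvector centrality of the undirected collapse, and local efficiency.
#'
#' @param graph a `brain_graph`.
#' @return data.frame, one row per region, 14 metric columns.
#' @export
node_metrics <- function(graph) {
  stopifnot(inherits(graph, "brain_graph"))
  g <- .as_igraph(graph)
  if (igraph::ecount(g) == 0L) stop("graph has no edges")
  gu <- igraph::as_undirected(g, mode = "collapse")
  W <- abs(graph$w)
  D <- igraph::distances(g, mode = "out")
  diag(D) <- NA
  npl <- apply(D, 1L, function(x) {
    f <- is.finite(x)
    if (any(f)) mean(x[f]) else NA_real_
  })
  hits <- .hits_scores(g)
  deg_all <- igraph::degree(g, mode = "all")
  clo <- suppressWarnings(igraph::closeness(g, mode = "out"))
  clo[deg_all == 0L] <- NA_real_
  out <- data.frame(
    region = rownames(graph$adj) %||% as.character(seq_len(graph$R)),
    in_degree = igraph::degree(g, mode = "in"),
    out_degree = igraph::degree(g, mode = "out"),
    degree = deg_all,
    in_strength = colSums(W),
    out_strength = rowSums(W),
    strength = colSums(W) + rowSums(W),
    clustering = igraph::transitivity(gu, type = "local", isolates = "zero"),
    nodal_path_length = npl,
    hub_score = hits$hub,
    authority_score = hits$authority,
    betweenness = igraph::betweenness(g, directed = TRUE),
    closeness = clo,
    eigenvector = igraph::eigen_centrality(gu)$vector,
    local_efficiency = igraph::local_efficiency(g, directed = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

.hits_scores <- function(g) {
  if ("hits_scores" %in% getNamespaceExports("igraph")) {
    h <- igraph::hits_scores(g)
    list(hub = h$hub, authority = h$authority)
  } else {
    list(hub = igraph::hub_score(g)$vector,
         authority = igraph::authority_score(g)$vector)
  }
}

#' Global metrics over the density grid
#'
#' Thresholds the matrix at each density of the grid (default 2% to 20% in
#' 1% steps, 19 points) and computes [global_metrics()] at each, yielding
#' the sigma(density) curve used for turning-point selection.
#'
#' @param cm a `connectivity_matrix` or matrix.
#' @param densities density grid.
#' @param n_random,seed passed to [global_metrics()].
#' @return data.frame of class `sigma_curve`: one row per density with the
#'   14 global metrics.
#' @export
sigma_curve <- function(cm, densities = seq(0.02, 0.20, by = 0.01),
                        n_random = 100L, seed = 1L) {
  rows <- lapply(seq_along(densities), function(k) {
    gm <- global_metrics(threshold_to_density(cm, densities[k]),
                         n_random = n_random, seed = seed + k)
    as.data.frame(as.list(gm))
  })
  out <- cbind(density = densities, do.call(rbind, rows))
  # soft check only: sigma(d) is expected to decay, but noisy matrices
  # violate it locally
  sig <- out$sigma[is.finite(out$sigma)]
  if (length(sig) > 2L && any(diff(sig) > 0.5))
    message("sigma(d) rises markedly along the density grid")
  class(out) <- c("sigma_curve", "data.frame")
  out
}

#' Turning-point density of a sigma(density) curve
#'
#' Returns the grid density of maximum absolute discrete curvature (second
#' difference) of sigma(d).  When the curvature is flat (all |second
#' differences| below `tol`) or fewer than 5 finite points are available,
#' falls back to `default` with a message/warning.
#'
#' @param curve a [sigma_curve()] result (or data.frame with `density` and
#'   `sigma`).
#' @param default fallback density (default 0.07, the conventional
#'   turning point of the hyperbolic small-world curve).
#' @param tol flatness tolerance on the second difference.
#' @return a single density value.
#' @export
turning_point <- function(curve, default = 0.07, tol = 1e-8) {
  ok <- is.finite(curve$sigma)
  if (sum(ok) < 5L) {
    warning("fewer than 5 finite sigma values; returning default density")
    return(default)
  }
  d <- curve$density[ok]; s <- curve$sigma[ok]
  d2 <- diff(s, differences = 2L)
  if (max(abs(d2)) < tol) {
    message("flat sigma curve; returning default density ", default)
    return(default)
  }
  d[which.max(abs(d2)) + 1L]
}

#' Write a brain graph as a directed edge list
#' @param graph a `brain_graph`.
#' @param file output path (tab-separated source, target, weight).
#' @export
write_edgelist <- function(graph, file) {
  idx <- which(graph$adj == 1L, arr.ind = TRUE)
  el <- data.frame(source = idx[, 1L], target = idx[, 2L],
                   weight = graph$w[idx])
  utils::write.table(el[order(el$source, el$target), ], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("Brain graph: %d nodes, %d directed edges (density %.3f)\n",
              x$R, sum(x$adj), x$d))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
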