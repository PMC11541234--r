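# Network-based statistics (NBS).  Edge-wise tests on (Fisher-z
# transformed) connectivity entries, supra-threshold component extraction,
# permutation family-wise error control for the two-sample homoscedastic
# design, and the control-adjusted paired variant in which a matched
# control contrast tightens the edge-wise alpha before the experimental
# contrast is read out.

# --- internal edge bookkeeping -------------------------------------------

# stack a list of R x R matrices into an n x E matrix over off-diagonal
# (directed) edges, optionally Fisher-z transformed
.stack_edges <- function(mats, fisher_z = TRUE) {
  mats <- lapply(mats, function(m)
    if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m))
  R <- nrow(mats[[1L]])
  if (any(vapply(mats, nrow, 1L) != R)) stop("matrices must share R")
  off <- which(row(diag(R)) != col(diag(R)))
  Z <- t(vapply(mats, function(m) m[off], numeric(length(off))))
  if (fisher_z) Z <- atanh(pmin(pmax(Z, -1 + 1e-7), 1 - 1e-7))
  list(Z = Z, R = R, off = off,
       ri = row(diag(R))[off], ci = col(diag(R))[off])
}

# vectorized pooled-variance two-sample t over edge columns
.pooled_t <- function(S1A, S2A, nA, S1B, S2B, nB) {
  mA <- S1A / nA; mB <- S1B / nB
  ssA <- S2A - S1A^2 / nA
  ssB <- S2B - S1B^2 / nB
  df <- nA + nB - 2
  vp <- (ssA + ssB) / df
  se <- sqrt(vp * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[!is.finite(t)] <- 0  # zero pooled variance
  t
}

# largest weakly connected supra-threshold component, by union-find over
# edge endpoints; returns the edge count (fast path for permutation nulls)
.max_component_edges <- function(ri, ci) {
  if (length(ri) == 0L) return(0L)
  nodes <- unique(c(ri, ci))
  parent <- seq_along(nodes)
  id <- match(c(ri, ci), nodes)
  a <- id[seq_along(ri)]
  b <- id[length(ri) + seq_along(ci)]
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(a, find, 1L)
  max(tabulate(roots))
}

# --- edge-wise statistics -------------------------------------------------

#' Edge-wise homoscedastic two-sample t statistics
#'
#' Pooled-variance t per off-diagonal edge on (by default) Fisher-z
#' transformed connectivity entries; `df = nA + nB - 2`.  Edges with zero
#' pooled variance get `t = 0` with a warning.
#'
#' @param groupA,groupB lists of `connectivity_matrix` objects (or plain
#'   R x R matrices), one per subject.
#' @param fisher_z variance-stabilize with `atanh` before testing.
#' @return list of class `edge_stat`: `t` (R x R, zero diagonal), `df`,
#'   `contrast`.
#' @export
edgewise_t_homoscedastic <- function(groupA, groupB, fisher_z = TRUE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need at least 2 subjects per group")
  st <- .stack_edges(c(groupA, groupB), fisher_z = fisher_z)
  nA <- length(groupA); nB <- length(groupB)
  ZA <- st$Z[seq_len(nA), , drop = FALSE]
  ZB <- st$Z[nA + seq_len(nB), , drop = FALSE]
  tv <- .pooled_t(colSums(ZA), colSums(ZA^2), nA,
                  colSums(ZB), colSums(ZB^2), nB)
  ssA <- colSums(ZA^2) - colSums(ZA)^2 / nA
  ssB <- colSums(ZB^2) - colSums(ZB)^2 / nB
  if (any(ssA + ssB <= 0))
    warning(sprintf("%d edge(s) with zero pooled variance recorded as t = 0",
                    sum(ssA + ssB <= 0)))
  tm <- matrix(0, st$R, st$R)
  tm[st$off] <- tv
  structure(list(t = tm, df = nA + nB - 2,
                 contrast = sprintf("two-sample (n=%d vs %d)", nA, nB)),
            class = "edge_stat")
}

#' Edge-wise paired t statistics
#'
#' One-sample t on per-subject edge differences (condition 1 minus
#' condition 2); `df = n - 1`.  Zero difference variance yields `t = 0`
#' when the mean difference is also zero, and an infinite-separation flag
#' (`t = Inf` with matching sign) otherwise.
#'
#' @param cond1,cond2 lists of connectivity matrices for the same subjects
#'   in the same order.
#' @param fisher_z variance-stabilize before differencing.
#' @return an `edge_stat` with `df = n - 1`.
#' @export
paired_edgewise_t <- function(cond1, cond2, fisher_z = TRUE) {
  n <- length(cond1)
  if (n < 2L || length(cond2) != n)
    stop("paired design needs the same subjects (n >= 2) in both conditions")
  st <- .stack_edges(c(cond1, cond2), fisher_z = fisher_z)
  D <- st$Z[seq_len(n), , drop = FALSE] - st$Z[n + seq_len(n), , drop = FALSE]
  m <- colMeans(D)
  v <- colSums((D - rep(m, each = n))^2) / (n - 1)
  tv <- m / sqrt(v / n)
  # relative tolerance: catches analytically-constant differences whose
  # variance is only floating-point dust
  degen <- v <= 1e-20 * pmax(m^2, 1)
  if (any(degen)) {
    warning(sprintf("%d edge(s) with zero difference variance", sum(degen)))
    tv[degen] <- ifelse(m[degen] == 0, 0, sign(m[degen]) * Inf)
  }
  tm <- matrix(0, st$R, st$R)
  tm[st$off] <- tv
  structure(list(t = tm, df = n - 1,
                 contrast = sprintf("paired (n=%d)", n)),
            class = "edge_stat")
}

# --- components -----------------------------------------------------------

#' Supra-threshold components of an edge-statistic matrix
#'
#' Thresholds at the two-sided critical value for `alpha` on the statistic's
#' degrees of freedom; supra-threshold edges (|t| > t_crit, sign retained)
#' form a graph whose weakly connected components are returned sorted by
#' edge count, ties broken by the smallest member node id.
#'
#' @param stat an `edge_stat`.
#' @param alpha edge-wise significance level.
#' @return list of components, each `list(edges, n_edges, nodes)` where
#'   `edges` is a 3-column matrix (i, j, t); empty list when no edge
#'   survives.
#' @export
suprathreshold_components <- function(stat, alpha = 0.05) {
  stopifnot(inherits(stat, "edge_stat"))
  t_crit <- stats::qt(1 - alpha / 2, df = stat$df)
  idx <- which(abs(stat$t) > t_crit & row(stat$t) != col(stat$t),
               arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership[idx[, 1L]]
  comps <- lapply(sort(unique(memb)), function(cid) {
    e <- idx[memb == cid, , drop = FALSE]
    list(edges = cbind(i = e[, 1L], j = e[, 2L],
                       t = stat$t[e]),
         n_edges = nrow(e),
         nodes = sort(unique(as.vector(e))))
  })
  ord <- order(-vapply(comps, function(x) as.integer(x$n_edges), 1L),
               vapply(comps, function(x) as.integer(min(x$nodes)), 1L))
  comps[ord]
}

# --- NBS ------------------------------------------------------------------

.nbs_result <- function(alpha_used, comps, p_fwe, n_perm, null_sizes,
                        status, contrast) {
  largest <- if (length(comps)) comps[[1L]] else
    list(edges = cbind(i = integer(0), j = integer(0), t = numeric(0)),
         n_edges = 0L, nodes = integer(0))
  structure(list(alpha_used = alpha_used,
                 component_edges = largest$edges,
                 component_size = largest$n_edges,
                 component_nodes = largest$nodes,
                 components = comps,
                 p_fwe = p_fwe, n_perm = n_perm, null_sizes = null_sizes,
                 status = status, contrast = contrast),
            class = "nbs_result")
}

#' Homoscedastic NBS with permutation FWE control
#'
#' Tests whether the largest supra-threshold component of group-difference
#' edges is larger than expected under random relabeling of subjects.
#' `p_fwe = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param groupA,groupB lists of connectivity matrices.
#' @param alpha edge-wise level (default 0.05).
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed for the permutation stream.
#' @param fisher_z variance-stabilize edges before testing.
#' @return an `nbs_result`.
#' @export
nbs_homoscedastic <- function(groupA, groupB, alpha = 0.05, n_perm = 10000L,
                              seed = 1L, fisher_z = TRUE) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group")
  if (n_perm < 100L) warning("n_perm < 100 gives an unstable p-value")
  if (min(nA, nB) == 2L)
    warning("group of size 2: few distinct relabelings, p is coarse")
  st <- .stack_edges(c(groupA, groupB), fisher_z = fisher_z)
  n <- nA + nB
  Z <- st$Z; Z2 <- Z^2
  tot1 <- colSums(Z); tot2 <- colSums(Z2)
  df <- n - 2
  t_crit <- stats::qt(1 - alpha / 2, df = df)
  comp_size <- function(idxA) {
    S1A <- colSums(Z[idxA, , drop = FALSE])
    S2A <- colSums(Z2[idxA, , drop = FALSE])
    tv <- .pooled_t(S1A, S2A, nA, tot1 - S1A, tot2 - S2A, nB)
    supra <- abs(tv) > t_crit
    .max_component_edges(st$ri[supra], st$ci[supra])
  }
  obs_size <- comp_size(seq_len(nA))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  null_sizes <- vapply(seq_len(n_perm),
                       function(b) comp_size(sample.int(n, nA)), 1L)
  p_fwe <- (1 + sum(null_sizes >= obs_size)) / (1 + n_perm)
  stat <- edgewise_t_homoscedastic(groupA, groupB, fisher_z = fisher_z)
  comps <- suprathreshold_components(stat, alpha)
  status <- if (obs_size > 0L && p_fwe < 0.05) "significant" else
    "not_significant"
  .nbs_result(alpha, comps, p_fwe, n_perm, null_sizes, status,
              stat$contrast)
}

#' Control-adjusted edge-wise alpha
#'
#' Scans a descending alpha grid and returns the largest alpha at which the
#' control contrast's largest supra-threshold component has at most
#' `max_control_component` edges — i.e. the loosest edge-wise threshold at
#' which the control experiment is clean.  Returns `NA` when no grid value
#' qualifies (the experimental contrast is then not testable).
#'
#' @param control_stat an `edge_stat` for the control contrast (or a list
#'   `list(cond1, cond2)` of matrices, from which a paired statistic is
#'   computed).
#' @param alpha_grid descending grid within (0, 0.05].
#' @param max_control_component tolerated control component size in edges
#'   (default 0: the control must be entirely clean).
#' @return a single alpha, or `NA_real_`.
#' @export
control_adjusted_alpha <- function(control_stat,
                                   alpha_grid = c(0.05, 0.04, 0.03, 0.02,
                                                  0.01, 0.005, 0.001),
                                   max_control_component = 0L) {
  if (length(alpha_grid) == 0L) stop("empty alpha grid")
  if (is.unsorted(rev(alpha_grid))) stop("alpha_grid must be descending")
  if (any(alpha_grid <= 0 | alpha_grid > 0.05))
    stop("alpha_grid values must lie in (0, 0.05]")
  if (!inherits(control_stat, "edge_stat"))
    control_stat <- paired_edgewise_t(control_stat$cond1, control_stat$cond2)
  for (a in alpha_grid) {
    comps <- suprathreshold_components(control_stat, a)
    size <- if (length(comps)) comps[[1L]]$n_edges else 0L
    if (size <= max_control_component) return(a)
  }
  NA_real_
}

#' Control-adjusted paired NBS
#'
#' The paired variant for designs where group permutation is unavailable:
#' a matched control contrast (same subjects, no experimental stimulation)
#' fixes the edge-wise alpha via [control_adjusted_alpha()], and the
#' experimental contrast's largest supra-threshold component at that alpha
#' is reported.  Any surviving component is therefore specific to the
#' experimental manipulation.  Status is `not_testable` when no grid alpha
#' leaves the control clean.
#'
#' @param experimental_pair,control_pair lists `list(cond1, cond2)` of
#'   connectivity matrices for the same subjects.
#' @param alpha_grid descending grid (see [control_adjusted_alpha()]).
#' @param max_control_component tolerated control component size.
#' @param fisher_z variance-stabilize before testing.
#' @return an `nbs_result` with `p_fwe = NA` (no permutation null in this
#'   design).
#' @export
nbs_paired_controlled <- function(experimental_pair, control_pair,
                                  alpha_grid = c(0.05, 0.04, 0.03, 0.02,
                                                 0.01, 0.005, 0.001),
                                  max_control_component = 0L,
                                  fisher_z = TRUE) {
  ctrl_stat <- paired_edgewise_t(control_pair$cond1, control_pair$cond2,
                                 fisher_z = fisher_z)
  alpha_star <- control_adjusted_alpha(ctrl_stat, alpha_grid,
                                       max_control_component)
  if (is.na(alpha_star))
    return(.nbs_result(NA_real_, list(), NA_real_, 0L, integer(0),
                       "not_testable", "paired, control-adjusted"))
  exp_stat <- paired_edgewise_t(experimental_pair$cond1,
                                experimental_pair$cond2,
                                fisher_z = fisher_z)
  comps <- suprathreshold_components(exp_stat, alpha_star)
  status <- if (length(comps) && comps[[1L]]$n_edges > 0L) "significant"
  else "not_significant"
  .nbs_result(alpha_star, comps, NA_real_, 0L, integer(0), status,
              "paired, control-adjusted")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("Network-based statistics:", x$contrast, "\n")
  cat(sprintf("  status: %s  alpha: %s  largest component: %d edge(s)\n",
              x$status,
              if (is.na(x$alpha_used)) "none" else format(x$alpha_used),
              x$component_size))
  if (!is.na(x$p_fwe))
    cat(sprintf("  p_FWE = %.4g (%d permutations)\n", x$p_fwe, x$n_perm))
  invisible(x)
}

#' Write an NBS result as JSON plus an edge-list
#' @param x an `nbs_result`.
#' @param file base path; writes `<file>.json` and `<file>_edges.tsv`.
#' @export
write_nbs <- function(x, file) {
  rec <- list(contrast = x$contrast, status = x$status,
              alpha_used = x$alpha_used, component_size = x$component_size,
              p_fwe = x$p_fwe, n_perm = x$n_perm)
  jsonlite::write_json(rec, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  e <- as.data.frame(x$component_edges)
  if (nrow(e)) e$direction <- ifelse(e$t > 0, "increased", "decreased")
  utils::write.table(e, paste0(file, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
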