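# Shared fixture builders and independent oracles.

# small cohort spec for fast tests
tiny_spec <- function(..., R = 10L, T = 100L, n_communities = 2L,
                      n_per_group = c(adult_HC = 2L, adult_AN = 2L,
                                      young_HC = 2L, young_AN = 2L)) {
  cohort_spec(n_per_group = n_per_group, R = R, T = T,
              n_communities = n_communities, ...)
}

make_bold <- function(values, TR = 3) {
  structure(list(values = values, TR = TR, ids = seq_len(nrow(values)),
                 nuisance = NULL, meta = list()),
            class = "bold_series")
}

# simulate n subject-level correlation matrices (R x R, unit diagonal)
# from a population correlation S, each from a T-volume Gaussian scan
sim_corr_group <- function(n, S, T = 150L, seed = 1L) {
  set.seed(seed)
  L <- chol(S)
  lapply(seq_len(n), function(i) {
    X <- matrix(rnorm(T * nrow(S)), T) %*% L
    stats::cor(X)
  })
}

# population correlation with a planted edge set at correlation r
planted_sigma <- function(R, edges, r) {
  S <- diag(R)
  for (k in seq_len(nrow(edges))) {
    S[edges[k, 1L], edges[k, 2L]] <- r
    S[edges[k, 2L], edges[k, 1L]] <- r
  }
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  stopifnot(ev > 1e-6)
  S
}

# a 10-edge chain component over nodes 1..11
chain_edges <- function(n_edges = 10L) {
  cbind(i = seq_len(n_edges), j = seq_len(n_edges) + 1L)
}

# undirected unique pairs from a component's directed edge matrix
undirected_pairs <- function(edges) {
  if (NROW(edges) == 0L) return(character(0))
  unique(paste(pmin(edges[, 1L], edges[, 2L]),
               pmax(edges[, 1L], edges[, 2L])))
}

jaccard_pairs <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# fabricate a metric store with the real schema shapes for n subjects:
# the global block is a genuine sigma-curve layout (19 x 14), the nodal
# block a node-metrics layout (R x 14)
fake_store <- function(subjects, R = 3L, rs_list = c("RS2", "RS3"),
                       seed = 1) {
  set.seed(seed)
  grid <- seq(0.02, 0.20, by = 0.01)
  store <- lapply(subjects, function(s) {
    per_rs <- lapply(rs_list, function(rs) {
      g <- as.data.frame(matrix(rnorm(19 * 14), 19, 14))
      names(g) <- msranet:::GLOBAL_METRIC_NAMES
      g <- cbind(density = grid, g)
      n <- as.data.frame(matrix(rnorm(R * 14), R, 14))
      names(n) <- msranet:::NODE_METRIC_NAMES
      n <- cbind(region = sprintf("R%03d", seq_len(R)), n)
      list(global = g, node = n)
    })
    names(per_rs) <- rs_list
    per_rs
  })
  names(store) <- subjects
  store
}

# --- independent oracles --------------------------------------------------

# Benjamini-Hochberg by brute-force scan over candidate thresholds
bh_oracle <- function(p, q) {
  m <- length(p)
  thresholds <- sort(p)
  best <- 0
  for (k in seq_len(m))
    if (thresholds[k] <= k * q / m) best <- thresholds[k]
  p <= best & best > 0
}

# largest connected component (edge count) by flood fill over an edge list
max_component_oracle <- function(edges) {
  if (NROW(edges) == 0L) return(0L)
  nodes <- unique(as.vector(edges[, 1:2]))
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[as.character(start)])) next
    cid <- cid + 1L
    frontier <- start
    while (length(frontier)) {
      comp[as.character(frontier)] <- cid
      nb <- unique(c(edges[edges[, 1L] %in% frontier, 2L],
                     edges[edges[, 2L] %in% frontier, 1L]))
      frontier <- nb[is.na(comp[as.character(nb)])]
    }
  }
  edge_comp <- comp[as.character(edges[, 1L])]
  max(tabulate(edge_comp))
}

# directed betweenness by explicit shortest-path counting (Floyd-Warshall
# distances plus path-count dynamic program), endpoints excluded
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    alt <- D[i, k] + D[k, j]
    if (alt < D[i, j]) D[i, j] <- alt
  }
  # shortest-path counts by exhaustive depth-first enumeration
  count_paths <- function(s, t) {
    if (!is.finite(D[s, t]) || s == t) return(0)
    target_len <- D[s, t]
    total <- 0
    stack <- list(list(node = s, len = 0))
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (cur$node == t && cur$len == target_len) {
        total <- total + 1
        next
      }
      if (cur$len >= target_len) next
      for (nb in which(adj[cur$node, ] == 1))
        if (cur$len + 1 + D[nb, t] == target_len || nb == t)
          if (cur$len + 1 + (if (nb == t) 0 else D[nb, t]) == target_len)
            stack[[length(stack) + 1L]] <- list(node = nb, len = cur$len + 1)
    }
    total
  }
  N <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n))
    if (s != t) N[s, t] <- count_paths(s, t)
  btw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (length(unique(c(s, t, v))) < 3L) next
    if (!is.finite(D[s, t]) || N[s, t] == 0) next
    if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
      btw[v] <- btw[v] + N[s, v] * N[v, t] / N[s, t]
  }
  btw
}
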