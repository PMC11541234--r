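# Network-based statistics: edge-wise t statistics against closed-form
# oracles, component extraction against a flood-fill oracle, permutation
# FWE against exhaustive enumeration, and the control-adjusted paired
# variant.

test_that("homoscedastic edge t matches the pooled-variance formula", {
  set.seed(1)
  R <- 5
  gA <- replicate(3, {m <- matrix(rnorm(R * R, 0, 0.3), R, R); diag(m) <- 1; m},
                  simplify = FALSE)
  gB <- replicate(3, {m <- matrix(rnorm(R * R, 0, 0.3), R, R); diag(m) <- 1; m},
                  simplify = FALSE)
  st <- edgewise_t_homoscedastic(gA, gB, fisher_z = TRUE)
  expect_equal(st$df, 4)
  # hand-computed pooled t at edge (2, 3)
  a <- atanh(sapply(gA, function(m) m[2, 3]))
  b <- atanh(sapply(gB, function(m) m[2, 3]))
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(st$t[2, 3], t_hand, tolerance = 1e-12)
  # identical groups: all t = 0
  st0 <- suppressWarnings(edgewise_t_homoscedastic(gA, gA))
  expect_true(all(st0$t == 0))
  # a single strongly separated edge dominates (small within-group jitter
  # keeps the pooled variance positive)
  gA2 <- lapply(gA, function(m) {m[1, 4] <- 0.9 + 0.01 * m[1, 4]; m})
  gB2 <- lapply(gB, function(m) {m[1, 4] <- -0.9 + 0.01 * m[1, 4]; m})
  st2 <- edgewise_t_homoscedastic(gA2, gB2)
  expect_equal(which.max(abs(st2$t)), which(row(st2$t) == 1 & col(st2$t) == 4))
})

test_that("paired edge t matches the closed-form paired oracle", {
  set.seed(2)
  R <- 4; n <- 5
  c1 <- replicate(n, matrix(runif(R * R, -0.5, 0.5), R, R), simplify = FALSE)
  c2 <- replicate(n, matrix(runif(R * R, -0.5, 0.5), R, R), simplify = FALSE)
  st <- paired_edgewise_t(c1, c2, fisher_z = FALSE)
  expect_equal(st$df, n - 1)
  d <- sapply(seq_len(n), function(k) c1[[k]][3, 2] - c2[[k]][3, 2])
  expect_equal(st$t[3, 2], mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-12)
  # identical conditions: all zero
  st0 <- suppressWarnings(paired_edgewise_t(c1, c1))
  expect_true(all(st0$t == 0))
  # constant nonzero difference: infinite-separation flag
  c3 <- lapply(c1, function(m) {m[1, 2] <- m[1, 2] + 0.3; m})
  expect_warning(sti <- paired_edgewise_t(c3, c1, fisher_z = FALSE),
                 "zero difference variance")
  expect_true(is.infinite(sti$t[1, 2]) && sti$t[1, 2] > 0)
})

test_that("components match the flood-fill oracle and ordering rules", {
  mk_stat <- function(tm, df = 20) structure(list(t = tm, df = df,
                                                  contrast = "test"),
                                             class = "edge_stat")
  tm <- matrix(0, 10, 10)
  expect_length(suprathreshold_components(mk_stat(tm), 0.05), 0L)
  # planted supra edges {(1,2), (2,3), (7,8)}
  tm[1, 2] <- tm[2, 3] <- tm[7, 8] <- 10
  comps <- suprathreshold_components(mk_stat(tm), 0.05)
  expect_length(comps, 2L)
  expect_equal(comps[[1]]$n_edges, 2L)
  expect_setequal(comps[[1]]$nodes, 1:3)
  expect_equal(comps[[2]]$n_edges, 1L)
  # alpha -> 1: every nonzero-t edge joins one supra graph
  set.seed(3)
  tm <- matrix(rnorm(100), 10, 10); diag(tm) <- 0
  comps <- suprathreshold_components(mk_stat(tm), 0.9999)
  expect_equal(sum(sapply(comps, `[[`, "n_edges")), 90L)
  # random sparse patterns vs the oracle
  for (i in 1:20) {
    tm <- matrix(0, 12, 12)
    k <- sample(3:12, 1)
    idx <- cbind(sample(12, k, TRUE), sample(12, k, TRUE))
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    tm[idx] <- 10
    comps <- suprathreshold_components(mk_stat(tm), 0.05)
    largest <- if (length(comps)) comps[[1]]$n_edges else 0L
    supra <- which(tm != 0, arr.ind = TRUE)
    expect_equal(largest, max_component_oracle(supra))
    # internal union-find fast path agrees as well
    expect_equal(msranet:::.max_component_edges(supra[, 1], supra[, 2]),
                 max_component_oracle(supra))
  }
})

test_that("4v4 permutation p matches exhaustive 70-relabeling enumeration", {
  set.seed(4)
  R <- 8
  mats <- sim_corr_group(8, planted_sigma(R, chain_edges(3), 0.5),
                         T = 60, seed = 9)
  gA <- mats[1:4]; gB <- mats[5:8]
  n_perm <- 4000
  res <- suppressWarnings(
    nbs_homoscedastic(gA, gB, n_perm = n_perm, seed = 10))
  # exhaustive null over all C(8,4) = 70 relabelings
  all_mats <- c(gA, gB)
  combos <- combn(8, 4)
  t_crit <- qt(1 - 0.05 / 2, df = 6)
  sizes <- apply(combos, 2, function(idxA) {
    st <- suppressWarnings(
      edgewise_t_homoscedastic(all_mats[idxA], all_mats[-idxA]))
    supra <- which(abs(st$t) > t_crit & row(st$t) != col(st$t), arr.ind = TRUE)
    max_component_oracle(supra)
  })
  obs <- sizes[ncol(combos)]  # not used; observed recomputed below
  st_obs <- suppressWarnings(edgewise_t_homoscedastic(gA, gB))
  supra <- which(abs(st_obs$t) > t_crit & row(st_obs$t) != col(st_obs$t),
                 arr.ind = TRUE)
  obs_size <- max_component_oracle(supra)
  p_exact <- mean(sizes >= obs_size)
  mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p_fwe - p_exact), 4 * mc_se + 2 / n_perm)
  expect_equal(res$component_size, obs_size)
})

test_that("p_fwe respects its defining identity and label-swap symmetry", {
  set.seed(5)
  R <- 10
  mats <- sim_corr_group(12, diag(R), T = 50, seed = 21)
  gA <- mats[1:6]; gB <- mats[7:12]
  r1 <- suppressWarnings(nbs_homoscedastic(gA, gB, n_perm = 300, seed = 7))
  expect_equal(r1$p_fwe,
               (1 + sum(r1$null_sizes >= r1$component_size)) / (1 + 300))
  # |t| is label-swap invariant, so p agrees up to Monte-Carlo error of the
  # permutation stream
  r2 <- suppressWarnings(nbs_homoscedastic(gB, gA, n_perm = 300, seed = 7))
  mc_se <- sqrt(r1$p_fwe * (1 - r1$p_fwe) / 300)
  expect_equal(r2$component_size, r1$component_size)
  expect_lt(abs(r1$p_fwe - r2$p_fwe), 4 * mc_se + 2 / 300)
  r3 <- suppressWarnings(nbs_homoscedastic(gA, gB, n_perm = 300, seed = 7))
  expect_identical(r1$null_sizes, r3$null_sizes)  # fixed seed
})

test_that("component recovery grows with planted effect size", {
  set.seed(6)
  R <- 12
  edges <- chain_edges(5)
  planted <- undirected_pairs(edges)
  jac <- sapply(c(0.05, 0.25, 0.45), function(r_eff) {
    mean(sapply(1:8, function(rep) {
      gA <- sim_corr_group(12, planted_sigma(R, edges, r_eff), T = 60,
                           seed = 1000 * r_eff + rep)
      gB <- sim_corr_group(12, diag(R), T = 60, seed = 999 + rep)
      st <- suppressWarnings(edgewise_t_homoscedastic(gA, gB))
      comps <- suprathreshold_components(st, 0.05)
      if (!length(comps)) return(0)
      jaccard_pairs(undirected_pairs(comps[[1]]$edges), planted)
    }))
  })
  expect_true(all(diff(jac) >= -0.1))  # monotone up to simulation noise
  expect_gt(jac[3], jac[1])
})

test_that("control-adjusted alpha scans the grid as specified", {
  mk_stat <- function(tm, df = 14) structure(list(t = tm, df = df,
                                                  contrast = "ctl"),
                                             class = "edge_stat")
  tm0 <- matrix(0, 8, 8)
  expect_equal(control_adjusted_alpha(mk_stat(tm0)), 0.05)  # clean control
  tm_huge <- matrix(50, 8, 8); diag(tm_huge) <- 0
  expect_true(is.na(control_adjusted_alpha(mk_stat(tm_huge))))  # none
  # one moderate edge: alpha* from a direct scan of the grid
  tm1 <- matrix(0, 8, 8); tm1[2, 5] <- 2.6
  grid <- c(0.05, 0.04, 0.03, 0.02, 0.01, 0.005, 0.001)
  expected <- NA_real_
  for (a in grid) {
    if (abs(2.6) <= qt(1 - a / 2, 14)) { expected <- a; break }
  }
  expect_equal(control_adjusted_alpha(mk_stat(tm1)), expected)
  expect_error(control_adjusted_alpha(mk_stat(tm1), numeric(0)), "empty")
  expect_error(control_adjusted_alpha(mk_stat(tm1), c(0.01, 0.05)),
               "descending")
})

test_that("paired controlled NBS recovers planted effects, else not_testable", {
  set.seed(7)
  R <- 10; n <- 12
  edges <- chain_edges(4)
  base <- sim_corr_group(n, diag(R), T = 120, seed = 31)
  post <- sim_corr_group(n, planted_sigma(R, edges, 0.55), T = 120, seed = 32)
  # control with no modulation at all (identical conditions)
  ctl <- list(cond1 = base, cond2 = base)
  res <- suppressWarnings(
    nbs_paired_controlled(list(cond1 = post, cond2 = base), ctl))
  expect_equal(res$alpha_used, 0.05)
  expect_equal(res$status, "significant")
  rec <- undirected_pairs(res$component_edges)
  expect_gt(jaccard_pairs(rec, undirected_pairs(edges)), 0.3)
  # effect-laden control: no alpha qualifies
  ctl_bad <- list(cond1 = post, cond2 = base)
  res2 <- suppressWarnings(
    nbs_paired_controlled(list(cond1 = post, cond2 = base), ctl_bad))
  expect_equal(res2$status, "not_testable")
  expect_true(is.na(res2$alpha_used))
})

test_that("degenerate inputs are rejected or warned about", {
  m <- replicate(2, diag(3), simplify = FALSE)
  expect_error(edgewise_t_homoscedastic(m[1], m), "2 subjects")
  w <- capture_warnings(nbs_homoscedastic(m, m, n_perm = 50, seed = 1))
  expect_match(w, "n_perm", all = FALSE)
  expect_match(w, "size 2", all = FALSE)
})
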