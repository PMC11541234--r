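# Feature table schema, stratified splits, the two feature selectors,
# classification metrics and the stability-selection loop.

toy_table <- function(n = 32, p = 40, informative = 3, delta = 3,
                      seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- sprintf("RS2_NP_R%03d_strength", seq_len(p))
  y <- factor(rep(c("HC", "AN"), each = n / 2), levels = c("HC", "AN"))
  if (informative > 0)
    x[y == "AN", seq_len(informative)] <-
      x[y == "AN", seq_len(informative)] + delta
  structure(list(x = x, y = y), class = "feature_table")
}

test_that("feature table width follows 2 (19*14 + 14 R) for any R", {
  subjects <- sprintf("S%02d", 1:4)
  labels <- setNames(rep(c("AN", "HC"), 2), subjects)
  for (R in c(1L, 3L, 7L)) {
    ft <- build_feature_table(fake_store(subjects, R = R), labels)
    expect_equal(ncol(ft$x), 2 * (19 * 14 + 14 * R))
  }
  # single resting state, R = 1: 266 + 14 columns, GraphInfo then NodeParams
  ft1 <- build_feature_table(fake_store(subjects, R = 1L), labels,
                             rs_list = "RS2")
  expect_equal(ncol(ft1$x), 280L)
  expect_equal(sum(ft1$provenance$family == "GraphInfo"), 266L)
  expect_equal(sum(ft1$provenance$family == "NodeParams"), 14L)
  # deterministic column order: GraphInfo by density then metric, RS2 first
  expect_equal(ft1$provenance$column[1], "RS2_GI_d0.02_C_raw")
  expect_equal(ft1$provenance$column[267], "RS2_NP_R001_in_degree")
})

test_that("missing subject metrics are reported by name", {
  subjects <- sprintf("S%02d", 1:3)
  labels <- setNames(c("AN", "HC", "AN"), subjects)
  store <- fake_store(subjects)
  store[["S02"]][["RS3"]] <- NULL
  expect_error(build_feature_table(store, labels), "S02")
})

test_that("stratified splits preserve class proportions and determinism", {
  y <- factor(rep(c("AN", "HC"), each = 16))
  sp <- split_stratified(y, seed = 3)
  expect_length(sp$train, 24L)
  expect_length(sp$test, 8L)
  expect_equal(as.integer(table(y[sp$train])), c(12L, 12L))
  expect_equal(as.integer(table(y[sp$test])), c(4L, 4L))
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_identical(split_stratified(y, seed = 3), split_stratified(y, seed = 3))
  # over 100 seeds each subject lands in test about a quarter of the time
  counts <- integer(32)
  for (s in 1:100) {
    sp <- split_stratified(y, seed = s)
    counts[sp$test] <- counts[sp$test] + 1L
  }
  expect_true(all(counts > 25 - 4 * sqrt(100 * 0.25 * 0.75)))
  expect_true(all(counts < 25 + 4 * sqrt(100 * 0.25 * 0.75)))
  expect_error(split_stratified(factor(rep("AN", 4))), "class")
})

test_that("Boruta-style selection finds planted features, not noise", {
  tb <- toy_table(n = 32, p = 30, informative = 3, delta = 4, seed = 5)
  fs <- boruta_select(tb$x, tb$y, seed = 2)
  expect_true(all(sprintf("RS2_NP_R%03d_strength", 1:3) %in% fs$selected))
  # a feature duplicated from the label is always confirmed
  x2 <- cbind(tb$x, label_copy = as.integer(tb$y == "AN"))
  fs2 <- boruta_select(x2, tb$y, seed = 3)
  expect_true("label_copy" %in% fs2$selected)
  # pure noise: near-zero false confirmation rate
  rates <- sapply(1:10, function(s) {
    tbn <- toy_table(n = 24, p = 30, informative = 0, seed = 100 + s)
    boruta_select(tbn$x, tbn$y, seed = s)$n_selected / 30
  })
  expect_lte(mean(rates), 0.05)
  expect_error(boruta_select(tb$x[, 1, drop = FALSE], tb$y), "2 features")
  expect_error(boruta_select(tb$x, factor(rep("AN", 32))), "degenerate")
})

test_that("sPLS-DA keeps n_keep features, led by the separating one", {
  tb <- toy_table(n = 24, p = 50, informative = 1, delta = 6, seed = 6)
  fs <- splsda_select(tb$x, tb$y, n_keep = 20)
  expect_equal(fs$n_selected, 20L)
  expect_equal(fs$selected[1], colnames(tb$x)[1])
  expect_error(splsda_select(tb$x, tb$y, n_keep = 100), "n_keep")
})

test_that("sPLS-DA loadings agree with a power-iteration oracle", {
  set.seed(7)
  n <- 20
  x <- matrix(rnorm(n * 5), n, 5)
  colnames(x) <- paste0("f", 1:5)
  y <- factor(rep(c("HC", "AN"), each = 10), levels = c("HC", "AN"))
  x[y == "AN", 2] <- x[y == "AN", 2] + 2
  x[y == "AN", 4] <- x[y == "AN", 4] - 1
  # oracle: first singular vector of scaled-X' x dummy-Y via power iteration
  Xs <- scale(x)
  Yd <- scale(model.matrix(~ y - 1))
  M <- t(Xs) %*% Yd
  v <- c(1, -1)  # not orthogonal to the rank-1 dummy contrast
  for (i in 1:200) {
    u <- M %*% v; u <- u / sqrt(sum(u^2))
    v <- t(M) %*% u; v <- v / sqrt(sum(v^2))
  }
  ranked_oracle <- order(abs(u), decreasing = TRUE)
  fs <- splsda_select(x, y, n_keep = 2)
  expect_setequal(fs$selected, colnames(x)[ranked_oracle[1:2]])
})

test_that("classification metrics define balanced accuracy correctly", {
  expect_equal(balanced_accuracy(72.25, 57.75), 65)
  expect_equal(balanced_accuracy(33.83, 29.25), 31.54)
  expect_equal(balanced_accuracy(100, 100), 100)
  tb <- toy_table(n = 24, p = 10, informative = 2, delta = 6, seed = 8)
  sp <- split_stratified(tb$y, seed = 1)
  res <- classify(tb$x, tb$y, sp$train, sp$test, colnames(tb$x)[1:2])
  expect_equal(res[["balanced_accuracy"]],
               (res[["sensitivity"]] + res[["specificity"]]) / 2,
               tolerance = 1e-12)
  expect_gte(res[["balanced_accuracy"]], 80)
  expect_error(classify(tb$x, tb$y, sp$train, sp$test, character(0)),
               "empty")
})

test_that("stability loop reports frequencies and excludes failed runs", {
  tb <- toy_table(n = 32, p = 25, informative = 3, delta = 4, seed = 9)
  rep_b <- repeat_pipeline(tb, "splsda", n_iter = 15, seed = 2,
                           fs_args = list(n_keep = 5),
                           clf_args = list(nrounds = 50))
  expect_gte(rep_b$balanced_accuracy, 85)
  expect_true(all(sprintf("RS2_NP_R%03d_strength", 1:3) %in%
                    rep_b$most_relevant))
  expect_true(all(rep_b$selection_frequency >= 0 &
                    rep_b$selection_frequency <= 100))
  ident <- repeat_pipeline(tb, "splsda", n_iter = 5, seed = 2,
                           fs_args = list(n_keep = 5),
                           clf_args = list(nrounds = 50))
  expect_equal(ident$per_iteration[1:5, ], rep_b$per_iteration[1:5, ])
  ft <- frequency_table(rep_b)
  expect_true(all(c("rs", "family", "unit", "measure", "frequency") %in%
                    names(ft)))
  expect_equal(ft$family[ft$feature == "RS2_NP_R001_strength"], "NodeParams")
})

test_that("selection frequency is invariant to column order", {
  tb <- toy_table(n = 28, p = 12, informative = 2, delta = 5, seed = 10)
  r1 <- repeat_pipeline(tb, "splsda", n_iter = 8, seed = 4,
                        fs_args = list(n_keep = 4),
                        clf_args = list(nrounds = 30))
  perm <- sample(ncol(tb$x))
  tb2 <- tb
  tb2$x <- tb$x[, perm]
  r2 <- repeat_pipeline(tb2, "splsda", n_iter = 8, seed = 4,
                        fs_args = list(n_keep = 4),
                        clf_args = list(nrounds = 30))
  expect_equal(r2$selection_frequency[colnames(tb$x)],
               r1$selection_frequency[colnames(tb$x)])
})

test_that("a leakage canary (test labels, constant on train) is never selected", {
  tb <- toy_table(n = 32, p = 20, informative = 2, delta = 4, seed = 11)
  sp <- split_stratified(tb$y, seed = 5)
  canary <- numeric(32)
  canary[sp$test] <- as.integer(tb$y[sp$test] == "AN")  # constant 0 on train
  x2 <- cbind(tb$x, canary = canary)
  fs_b <- boruta_select(x2[sp$train, ], tb$y[sp$train], seed = 6)
  fs_s <- splsda_select(x2[sp$train, ], tb$y[sp$train], n_keep = 5)
  expect_false("canary" %in% fs_b$selected)
  expect_false("canary" %in% fs_s$selected)
})
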