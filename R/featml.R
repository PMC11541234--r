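# Stability-selection classification of groups from graph features.
# The feature table concatenates, per resting state, the "GraphInfo" family
# (global metrics across the 19-density grid, 19 x 14 = 266 columns) and
# the "NodeParams" family (14 nodal metrics per region at the selected
# density, 14 R columns); with R = 205 and two resting states the table is
# 2 x (266 + 2870) = 6272 columns wide.  Feature selection (Boruta-style
# shadow features or sparse PLS-DA) runs on the training rows of each of
# 100 stratified 75/25 splits, a gradient-boosted classifier is scored on
# the held-out rows, and per-feature selection frequencies over the
# iterations give the stable biosignature.

#' Assemble the GraphInfo + NodeParams feature table
#'
#' @param metric_store nested list: `metric_store[[subject]][[rs]]` holds
#'   `global` (a [sigma_curve()] data.frame over the density grid) and
#'   `node` (a [node_metrics()] data.frame at the selected density).
#' @param labels named character vector (`AN`/`HC`) over subjects.
#' @param rs_list resting states to include, in column order
#'   (default `c("RS2", "RS3")`).
#' @return list of class `feature_table`: `x` (subjects x features matrix),
#'   `y` (factor with levels HC, AN), `provenance` (per-column family/RS).
#' @export
build_feature_table <- function(metric_store, labels,
                                rs_list = c("RS2", "RS3")) {
  subjects <- names(metric_store)
  if (is.null(subjects) || !length(subjects)) stop("empty metric store")
  missing <- subjects[!vapply(subjects, function(s)
    all(rs_list %in% names(metric_store[[s]])), logical(1))]
  if (length(missing))
    stop("missing metrics for subjects: ", paste(missing, collapse = ", "))
  if (!all(subjects %in% names(labels)))
    stop("labels missing for some subjects")
  rows <- lapply(subjects, function(s) {
    unlist(lapply(rs_list, function(rs) {
      st <- metric_store[[s]][[rs]]
      gi <- st$global
      dens <- gi$density
      gim <- as.matrix(gi[, GLOBAL_METRIC_NAMES, drop = FALSE])
      gvals <- as.vector(t(gim))  # density-major, then metric
      names(gvals) <- as.vector(t(outer(
        sprintf("%s_GI_d%.2f", rs, dens), GLOBAL_METRIC_NAMES,
        paste, sep = "_")))
      nd <- st$node
      ndm <- as.matrix(nd[, NODE_METRIC_NAMES, drop = FALSE])
      nvals <- as.vector(t(ndm))  # region-major, then metric
      names(nvals) <- as.vector(t(outer(
        sprintf("%s_NP_%s", rs, nd$region), NODE_METRIC_NAMES,
        paste, sep = "_")))
      c(gvals, nvals)
    }))
  })
  x <- do.call(rbind, rows)
  rownames(x) <- subjects
  y <- factor(labels[subjects], levels = c("HC", "AN"))
  prov <- data.frame(
    column = colnames(x),
    rs = sub("_.*", "", colnames(x)),
    family = ifelse(grepl("_GI_", colnames(x)), "GraphInfo", "NodeParams"),
    stringsAsFactors = FALSE)
  structure(list(x = x, y = y, provenance = prov), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d subjects x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", names(table(x$provenance$family)),
                            table(x$provenance$family)), collapse = ", ")))
  print(table(x$y))
  invisible(x)
}

#' Stratified train/test split
#'
#' Samples `round(train_frac * n_class)` training rows per class; the
#' remainder is the test set.  Splits are disjoint and exhaustive.
#'
#' @param y class factor (or a `feature_table`).
#' @param train_frac training fraction (default 0.75).
#' @param seed RNG seed.
#' @return list with integer row indices `train` and `test`.
#' @export
split_stratified <- function(y, train_frac = 0.75, seed = 1L) {
  if (inherits(y, "feature_table")) y <- y$y
  classes <- levels(factor(y))
  if (length(classes) < 2L) stop("both classes must be present")
  if (any(table(y) < 2L)) stop("each class needs at least 2 members")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  train <- unlist(lapply(classes, function(cl) {
    idx <- which(y == cl)
    sample(idx, round(train_frac * length(idx)))
  }))
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# drop zero-variance columns (computed on the given rows only)
.informative_cols <- function(x) {
  v <- apply(x, 2L, stats::var)
  which(is.finite(v) & v > 0)
}

#' Boruta-style shadow-feature selection
#'
#' All-relevant feature selection: each round appends a shuffled "shadow"
#' copy of every candidate feature, fits a random-forest importance model
#' (permutation importance via ranger; optionally gradient-boosted gain),
#' and counts a hit for each feature whose importance exceeds the maximum
#' shadow importance.  After each round a two-sided binomial test on the
#' hit count confirms features that beat the shadows significantly more
#' often than chance and rejects those that do so significantly less
#' often; rejected features leave the model.  Iterates until all features
#' are decided or `max_rounds` is reached; undecided features are not
#' selected.
#'
#' @param x training feature matrix; @param y training class factor.
#' @param max_rounds maximum shadow rounds (default 10).
#' @param seed RNG seed.
#' @param p_threshold decision level of the binomial test (default 0.05).
#' @param importance `"ranger"` (permutation, default) or `"xgboost"`
#'   (gain).
#' @param num_trees forest size per round.
#' @return list of class `fs_result`: `algorithm`, `selected`,
#'   `n_selected`.
#' @export
boruta_select <- function(x, y, max_rounds = 10L, seed = 1L,
                          p_threshold = 0.05,
                          importance = c("ranger", "xgboost"),
                          num_trees = 200L) {
  importance <- match.arg(importance)
  if (ncol(x) < 2L) stop("need at least 2 features")
  if (length(unique(y)) < 2L) stop("degenerate labels")
  keep <- .informative_cols(x)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  active <- colnames(x)[keep]
  hits <- stats::setNames(integer(length(active)), active)
  status <- stats::setNames(rep("tentative", length(active)), active)
  rounds <- 0L
  while (rounds < max_rounds && any(status == "tentative")) {
    rounds <- rounds + 1L
    cand <- names(status)[status != "rejected"]
    Xc <- x[, cand, drop = FALSE]
    shadow <- apply(Xc, 2L, sample)
    colnames(shadow) <- paste0(".shadow.", seq_len(ncol(shadow)))
    imp <- .importance(cbind(Xc, shadow), y, importance, num_trees)
    max_shadow <- max(imp[colnames(shadow)], 0)
    beat <- imp[cand] > max_shadow
    hits[cand[beat]] <- hits[cand[beat]] + 1L
    if (rounds >= 3L) {
      for (f in names(status)[status == "tentative"]) {
        pv <- stats::binom.test(hits[[f]], rounds, 0.5)$p.value
        if (pv < p_threshold)
          status[f] <- if (hits[[f]] > rounds / 2) "confirmed" else "rejected"
      }
    }
  }
  selected <- names(status)[status == "confirmed"]
  structure(list(algorithm = "boruta", selected = selected,
                 n_selected = length(selected), rounds = rounds,
                 status = status),
            class = "fs_result")
}

.importance <- function(X, y, engine, num_trees) {
  if (engine == "ranger") {
    fit <- ranger::ranger(x = as.data.frame(X), y = factor(y),
                          num.trees = num_trees,
                          importance = "permutation",
                          num.threads = 1L,
                          seed = sample.int(1e6, 1))
    fit$variable.importance
  } else {
    d <- xgboost::xgb.DMatrix(as.matrix(X),
                              label = as.integer(factor(y)) - 1L)
    fit <- xgboost::xgb.train(list(objective = "binary:logistic",
                                   max_depth = 3, eta = 0.3, nthread = 1),
                              d, nrounds = 30L, verbose = 0)
    it <- xgboost::xgb.importance(model = fit)
    imp <- stats::setNames(rep(0, ncol(X)), colnames(X))
    imp[it$Feature] <- it$Gain
    imp
  }
}

#' Sparse PLS-DA feature selection
#'
#' Selects the `n_keep` features with non-zero (largest absolute) loadings
#' on the first sparse partial-least-squares discriminant component.
#'
#' @param x training feature matrix; @param y training class factor.
#' @param n_keep number of features to keep (default 20).
#' @param seed RNG seed (sPLS-DA is deterministic given the data; kept for
#'   interface symmetry).
#' @return an `fs_result`.
#' @export
splsda_select <- function(x, y, n_keep = 20L, seed = 1L) {
  keep <- .informative_cols(x)
  if (n_keep > length(keep))
    stop("n_keep exceeds the number of informative features")
  if (length(unique(y)) < 2L) stop("degenerate labels")
  fit <- mixOmics::splsda(x[, keep, drop = FALSE], factor(y),
                          ncomp = 1, keepX = n_keep)
  sel <- mixOmics::selectVar(fit, comp = 1)$name
  structure(list(algorithm = "splsda", selected = sel,
                 n_selected = length(sel)),
            class = "fs_result")
}

#' Gradient-boosted classification of a selected feature set
#'
#' Fits an XGBoost binary classifier on the training rows restricted to the
#' selected features and scores the test rows.  AN is the positive class:
#' sensitivity = TP/(TP+FN) over AN test subjects, specificity = TN/(TN+FP)
#' over HC, balanced accuracy their mean, all in percent.
#'
#' @param x feature matrix; @param y factor with levels HC, AN.
#' @param train,test row indices.
#' @param selected feature names to use.
#' @param params override list: `nrounds`, `max_depth`, `eta`.
#' @param seed RNG seed for the boosting subsampling stream.
#' @return named numeric vector: `sensitivity`, `specificity`,
#'   `balanced_accuracy` (percent).
#' @export
classify <- function(x, y, train, test, selected,
                     params = list(nrounds = 300L, max_depth = 3, eta = 0.1),
                     seed = 1L) {
  if (!length(selected)) stop("empty feature selection")
  if (!length(test)) stop("empty test set")
  lab <- as.integer(y == "AN")
  dtrain <- xgboost::xgb.DMatrix(x[train, selected, drop = FALSE],
                                 label = lab[train])
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth %||% 3,
                  eta = params$eta %||% 0.1,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = params$nrounds %||% 300L, verbose = 0)
  pred <- as.integer(stats::predict(
    fit, xgboost::xgb.DMatrix(x[test, selected, drop = FALSE])) > 0.5)
  truth <- lab[test]
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = balanced_accuracy(sens, spec))
}

#' Balanced accuracy from sensitivity and specificity
#'
#' The mean of sensitivity and specificity (both in percent); chance level
#' is 50 for two classes.
#'
#' @param sensitivity,specificity percentages.
#' @return balanced accuracy in percent.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Repeated stratified split, feature selection and classification
#'
#' The stability-selection loop: for each of `n_iter` iterations a fresh
#' 75/25 stratified split is drawn, feature selection runs on the training
#' rows only, and the classifier is scored on the held-out rows.  Reports
#' mean sensitivity/specificity/balanced accuracy and the per-feature
#' selection frequency (percent of iterations); features selected in more
#' than half the iterations form the stable signature.
#'
#' @param table a `feature_table` (or list with `x` and `y`).
#' @param algorithm `"boruta"` or `"splsda"`.
#' @param n_iter iterations (default 100).
#' @param seed root seed; iteration b uses `seed + b`.
#' @param train_frac training fraction (default 0.75).
#' @param fs_args extra arguments for the selector.
#' @param clf_args `params` override for [classify()].
#' @return list of class `classification_report`.
#' @export
repeat_pipeline <- function(table, algorithm = c("boruta", "splsda"),
                            n_iter = 100L, seed = 1L, train_frac = 0.75,
                            fs_args = list(), clf_args = NULL) {
  algorithm <- match.arg(algorithm)
  x <- table$x; y <- table$y
  sel_count <- stats::setNames(numeric(ncol(x)), colnames(x))
  per_iter <- matrix(NA_real_, n_iter, 3,
                     dimnames = list(NULL, c("sensitivity", "specificity",
                                             "balanced_accuracy")))
  n_failed <- 0L
  for (b in seq_len(n_iter)) {
    sp <- split_stratified(y, train_frac, seed = seed + b)
    fs <- tryCatch({
      args <- c(list(x = x[sp$train, , drop = FALSE], y = y[sp$train],
                     seed = seed + b), fs_args)
      do.call(if (algorithm == "boruta") boruta_select else splsda_select,
              args)
    }, error = function(e) NULL)
    if (is.null(fs) || fs$n_selected == 0L) {
      n_failed <- n_failed + 1L
      next
    }
    sel_count[fs$selected] <- sel_count[fs$selected] + 1
    res <- classify(x, y, sp$train, sp$test, fs$selected,
                    params = clf_args %||%
                      list(nrounds = 300L, max_depth = 3, eta = 0.1),
                    seed = seed + b)
    per_iter[b, ] <- res
  }
  if (n_failed == n_iter) stop("all iterations failed (empty selections)")
  if (n_failed > 0L)
    message(n_failed, " iteration(s) with empty selection excluded")
  freq <- 100 * sel_count / n_iter
  agg <- colMeans(per_iter, na.rm = TRUE)
  structure(list(
    algorithm = algorithm, n_iter = n_iter, n_failed = n_failed,
    per_iteration = as.data.frame(per_iter),
    sensitivity = agg[["sensitivity"]],
    specificity = agg[["specificity"]],
    balanced_accuracy = agg[["balanced_accuracy"]],
    selection_frequency = freq,
    most_relevant = names(freq)[freq > 50]),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Stability-selection classification (%s, %d iterations)\n",
              x$algorithm, x$n_iter))
  cat(sprintf("  balanced accuracy: %.2f%%  sensitivity: %.2f%%  specificity: %.2f%%\n",
              x$balanced_accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  stable features (>50%% of iterations): %d\n",
              length(x$most_relevant)))
  if (length(x$most_relevant))
    print(utils::head(sort(x$selection_frequency[x$most_relevant],
                           decreasing = TRUE), 10))
  invisible(x)
}

#' Tidy feature-selection frequency table
#'
#' One row per feature with frequency > 0, parsed into family (GraphInfo /
#' NodeParams), resting state, structure/density and metric — the layout
#' used for stable-signature reporting and chord-plot input.
#'
#' @param report a `classification_report`.
#' @param min_freq report features at or above this frequency (percent).
#' @return data.frame sorted by decreasing frequency.
#' @export
frequency_table <- function(report, min_freq = 1) {
  f <- report$selection_frequency
  f <- f[f >= min_freq]
  if (!length(f))
    return(data.frame(feature = character(0), rs = character(0),
                      family = character(0), unit = character(0),
                      measure = character(0), frequency = numeric(0)))
  parts <- strsplit(names(f), "_")
  df <- data.frame(
    feature = names(f),
    rs = vapply(parts, `[`, "", 1L),
    family = ifelse(vapply(parts, `[`, "", 2L) == "GI",
                    "GraphInfo", "NodeParams"),
    unit = vapply(parts, `[`, "", 3L),
    measure = vapply(parts, function(p) paste(p[-(1:3)], collapse = "_"), ""),
    frequency = unname(f),
    stringsAsFactors = FALSE)
  df[order(-df$frequency, df$feature), ]
}
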