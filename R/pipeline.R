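# Configuration-driven orchestration of the full analysis on a synthetic
# (or user-supplied) cohort: simulate -> preprocess -> MSRA -> graph
# metrics -> NBS contrasts -> stability-selection ML -> cohort statistics.
# All randomness flows from one root seed through named, deterministic
# substreams; every artifact records the configuration hash and seed.

#' Study configuration
#'
#' Defaults give a desk-scale run; pass a paper-scale `spec` (R = 205,
#' group sizes 15/13/16/17) for the full schema.
#'
#' @param spec a [cohort_spec()]; the generator's settings.
#' @param q MSRA FDR level.
#' @param densities density grid for global metrics.
#' @param node_density density for nodal metrics; `"turning_point"`
#'   selects it from the sigma curve of the first scan.
#' @param n_random random reference networks per density.
#' @param nbs_alpha,nbs_n_perm homoscedastic NBS settings.
#' @param ml_algorithms,ml_n_iter stability-selection settings.
#' @param seed root seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(spec = cohort_spec(
                           n_per_group = c(adult_HC = 8L, adult_AN = 8L,
                                           young_HC = 8L, young_AN = 8L),
                           R = 40L, n_communities = 4L),
                         q = 0.05,
                         densities = seq(0.02, 0.20, by = 0.01),
                         node_density = 0.07,
                         n_random = 20L,
                         nbs_alpha = 0.05, nbs_n_perm = 1000L,
                         ml_algorithms = "splsda", ml_n_iter = 20L,
                         seed = 1L) {
  structure(list(spec = spec, q = q, densities = densities,
                 node_density = node_density, n_random = n_random,
                 nbs_alpha = nbs_alpha, nbs_n_perm = nbs_n_perm,
                 ml_algorithms = ml_algorithms, ml_n_iter = ml_n_iter,
                 seed = as.integer(seed)),
            class = "study_config")
}

# djb2-style rolling hash over the deparsed configuration: stable
# identifier for outputs
.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full study pipeline
#'
#' Executes every stage on a synthetic cohort generated from
#' `config$spec`: preprocessing (nuisance regression + band-pass), MSRA
#' connectivity per scan, sigma curves and nodal metrics, the NBS
#' contrasts (baseline AN vs HC per age class on session-1 RS1;
#' young vs adult per diagnosis; paired chips-vs-zucchini RS3 with the
#' zucchini session as control), the stability-selection classification
#' per age class on RS2 + RS3 features, and demographics statistics.
#'
#' @param config a [study_config()].
#' @param out optional output directory; when given, artifacts and a run
#'   manifest (seed, parameters, config hash) are written there.
#' @param verbose log stage progress to stderr.
#' @return list of class `study_result` with elements `connectivity`,
#'   `metrics`, `node_density`, `nbs`, `ml`, `cohort_stats`, `manifest`,
#'   `config_hash`.
#' @export
run_study <- function(config = study_config(), out = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  log_ <- function(...) if (verbose) message("[msranet] ", sprintf(...))
  hash <- .config_hash(config)
  spec <- config$spec
  spec$seed <- config$seed
  log_("simulating cohort (R=%d, %d subjects)", spec$R, sum(spec$n_per_group))
  cohort <- simulate_cohort(spec)
  manifest <- cohort$manifest

  log_("preprocessing and MSRA on %d scans", nrow(manifest))
  pc <- prep_config()
  conn <- lapply(manifest$key, function(k) {
    sc <- prep_pipeline(cohort$scans[[k]], pc)
    msra_matrix(sc, cohort$atlas, q = config$q)
  })
  names(conn) <- manifest$key

  log_("global metric curves and nodal metrics")
  node_density <- config$node_density
  if (identical(node_density, "turning_point")) {
    curve <- sigma_curve(conn[[1L]], config$densities,
                         n_random = config$n_random, seed = config$seed)
    node_density <- turning_point(curve)
    log_("turning-point density: %.2f", node_density)
  }
  metrics <- lapply(seq_along(conn), function(k) {
    cmk <- conn[[k]]
    list(global = sigma_curve(cmk, config$densities,
                              n_random = config$n_random,
                              seed = config$seed + k),
         node = node_metrics(threshold_to_density(cmk, node_density)))
  })
  names(metrics) <- manifest$key

  log_("NBS contrasts")
  ses1 <- manifest[manifest$session == 1L & manifest$scan == "RS1", ]
  pick <- function(rows) conn[rows$key]
  nbs <- list()
  for (ac in c("young", "adult")) {
    rows <- ses1[ses1$age_class == ac, ]
    nbs[[paste0("baseline_AN_vs_HC_", ac)]] <- nbs_homoscedastic(
      pick(rows[rows$diagnosis == "AN", ]),
      pick(rows[rows$diagnosis == "HC", ]),
      alpha = config$nbs_alpha, n_perm = config$nbs_n_perm,
      seed = config$seed + 11L)
  }
  for (dg in c("AN", "HC")) {
    rows <- ses1[ses1$diagnosis == dg, ]
    nbs[[paste0("young_vs_adult_", dg)]] <- nbs_homoscedastic(
      pick(rows[rows$age_class == "young", ]),
      pick(rows[rows$age_class == "adult", ]),
      alpha = config$nbs_alpha, n_perm = config$nbs_n_perm,
      seed = config$seed + 12L)
  }
  # paired food-consumption contrast: RS3 vs RS2 in the chips session,
  # controlled by the same contrast in the zucchini session
  paired <- function(cond) {
    rows <- manifest[manifest$food_condition == cond, ]
    subj <- sort(unique(rows$subject_id))
    list(cond1 = conn[rows$key[match(paste0(subj, "RS3"),
                                     paste0(rows$subject_id, rows$scan))]],
         cond2 = conn[rows$key[match(paste0(subj, "RS2"),
                                     paste0(rows$subject_id, rows$scan))]])
  }
  nbs[["consumption_chips_vs_zucchini_control"]] <-
    nbs_paired_controlled(paired("chips"), paired("zucchini"))

  log_("stability-selection classification")
  labels <- manifest$diagnosis[!duplicated(manifest$subject_id)]
  names(labels) <- manifest$subject_id[!duplicated(manifest$subject_id)]
  ml <- list()
  for (ac in c("young", "adult")) {
    subj <- unique(manifest$subject_id[manifest$age_class == ac])
    store <- lapply(subj, function(s) {
      rows <- manifest[manifest$subject_id == s & manifest$session == 1L, ]
      list(RS2 = metrics[[rows$key[rows$scan == "RS2"]]],
           RS3 = metrics[[rows$key[rows$scan == "RS3"]]])
    })
    names(store) <- subj
    ft <- build_feature_table(store, labels[subj])
    for (alg in config$ml_algorithms)
      ml[[paste(ac, alg, sep = "_")]] <- repeat_pipeline(
        ft, alg, n_iter = config$ml_n_iter, seed = config$seed + 31L)
  }

  log_("cohort statistics")
  demo <- simulate_ratings_demographics(spec$n_per_group,
                                        seed = config$seed + 41L)
  cs <- cohort_stats(demo)

  result <- structure(list(
    connectivity = conn, metrics = metrics, node_density = node_density,
    nbs = nbs, ml = ml, cohort_stats = cs, manifest = manifest,
    config = config, config_hash = hash), class = "study_result")

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    tag <- sprintf("%s_seed%d", hash, config$seed)
    utils::write.csv(manifest,
                     file.path(out, sprintf("manifest_%s.csv", tag)),
                     row.names = FALSE)
    for (nm in names(nbs))
      write_nbs(nbs[[nm]], file.path(out, sprintf("nbs_%s_%s", nm, tag)))
    utils::write.csv(cs, file.path(out, sprintf("cohort_stats_%s.csv", tag)),
                     row.names = FALSE)
    run <- list(package_version = as.character(utils::packageVersion("msranet")),
                r_version = R.version.string,
                seed = config$seed, config_hash = hash,
                node_density = node_density,
                parameters = list(q = config$q,
                                  densities = config$densities,
                                  n_random = config$n_random,
                                  nbs_alpha = config$nbs_alpha,
                                  nbs_n_perm = config$nbs_n_perm,
                                  ml_n_iter = config$ml_n_iter))
    jsonlite::write_json(run, file.path(out, sprintf("run_%s.json", tag)),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study pipeline result (config ", x$config_hash, ")\n", sep = "")
  cat(sprintf("  scans analysed: %d  node density: %.2f\n",
              length(x$connectivity), x$node_density))
  cat("  NBS contrasts:\n")
  for (nm in names(x$nbs))
    cat(sprintf("    %-45s %s (size %d%s)\n", nm, x$nbs[[nm]]$status,
                x$nbs[[nm]]$component_size,
                if (!is.na(x$nbs[[nm]]$p_fwe))
                  sprintf(", p_FWE=%.3f", x$nbs[[nm]]$p_fwe) else ""))
  for (nm in names(x$ml))
    cat(sprintf("  ML %-20s balanced accuracy %.1f%%\n", nm,
                x$ml[[nm]]$balanced_accuracy))
  invisible(x)
}
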