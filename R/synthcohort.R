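# Synthetic resting-state cohort generator.
#
# Emulates a two-session symptom-provocation study: four cohorts
# (young/adult x AN/HC), two sessions per subject (food condition
# counterbalanced), three resting-state scans per session.  Region-wise BOLD
# series are drawn from a multivariate normal whose correlation carries a
# block community structure plus planted, contrast-specific edge effects,
# temporally colored by a common AR(1) process, with additive shared
# slow-drift nuisance components and white measurement noise.

#' Build a synthetic atlas definition
#'
#' Assigns `R` regions to `n_communities` planted resting-state-network
#' communities of balanced size (sizes differ by at most one).  Region voxel
#' centers are drawn uniformly in a nominal grid; they only matter in voxel
#' mode.
#'
#' @param R number of regions (default 205).
#' @param n_communities number of planted communities (default 7).
#' @param seed RNG seed for the voxel-center draw.
#' @param n_voxels voxels per region (voxel mode bookkeeping).
#' @return A data.frame of class `atlas_definition` with columns
#'   `region_id`, `region_name`, `community_id`, `n_voxels` and center
#'   coordinates `cx`, `cy`, `cz`.
#' @export
make_atlas <- function(R = 205L, n_communities = 7L, seed = 1L, n_voxels = 27L) {
  R <- as.integer(R); n_communities <- as.integer(n_communities)
  if (R < 1L || n_communities < 1L)
    stop("R and n_communities must be positive")
  if (R < n_communities)
    stop("R must be >= n_communities")
  sizes <- rep(R %/% n_communities, n_communities)
  extra <- R %% n_communities
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  community <- rep.int(seq_len(n_communities), sizes)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  centers <- matrix(stats::runif(3L * R, 1, 50), ncol = 3L)
  atlas <- data.frame(
    region_id = seq_len(R),
    region_name = sprintf("R%03d", seq_len(R)),
    community_id = community,
    n_voxels = as.integer(n_voxels),
    cx = centers[, 1L], cy = centers[, 2L], cz = centers[, 3L],
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("atlas_definition", "data.frame")
  atlas
}

#' Specify a synthetic cohort
#'
#' Collects every knob of the generator.  Defaults reproduce the study
#' conditions: group sizes 15 adult HC / 13 adult AN / 16 young HC /
#' 17 young AN, 200 volumes per scan at TR 3 s, two sessions with three
#' resting-state scans each, and the food condition (chips vs zucchini)
#' counterbalanced across sessions.
#'
#' `effect_edges` plants group-, age-, scan- or condition-specific
#' connectivity shifts: a data.frame with columns `i`, `j`, `delta` and the
#' selector columns `diagnosis`, `age_class`, `scan`, `food_condition`
#' (each either a level or `"any"`).  A correlation matrix is symmetric, so
#' a planted edge (i, j) shifts both (i, j) and (j, i); asymmetry in the
#' final connectivity matrix arises downstream from per-seed FDR
#' thresholding, not from the generator.
#'
#' @param n_per_group named integer vector over
#'   `adult_HC`, `adult_AN`, `young_HC`, `young_AN`.
#' @param R regions; `T` volumes per scan; `TR` repetition time in seconds.
#' @param base_within_community_r baseline correlation between regions of
#'   the same community.
#' @param effect_edges planted effects (see Details); `NULL` for none.
#' @param ar1_phi lag-one autocorrelation of the temporal coloring.
#' @param noise_sd white measurement-noise SD (signal has unit SD).
#' @param n_nuisance number of shared slow-drift confound regressors.
#' @param nuisance_sd amplitude of the drift loadings.
#' @param seed root seed; all scans derive deterministic seeds from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(adult_HC = 15L, adult_AN = 13L,
                                        young_HC = 16L, young_AN = 17L),
                        R = 205L, T = 200L, TR = 3.0,
                        base_within_community_r = 0.3,
                        n_communities = 7L,
                        effect_edges = NULL,
                        ar1_phi = 0.3, noise_sd = 0.2,
                        n_nuisance = 2L, nuisance_sd = 0.5,
                        seed = 1L) {
  stopifnot(all(c("adult_HC", "adult_AN", "young_HC", "young_AN") %in%
                  names(n_per_group)))
  if (T < 8L) stop("T must be >= 8")
  if (TR <= 0) stop("TR must be positive")
  if (base_within_community_r < 0 || base_within_community_r >= 1)
    stop("base_within_community_r must lie in [0, 1)")
  if (ar1_phi < 0 || ar1_phi >= 1) stop("ar1_phi must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(effect_edges)) effect_edges <- .validate_effects(effect_edges, R)
  spec <- list(
    n_per_group = vapply(n_per_group, as.integer, integer(1)),
    R = as.integer(R), T = as.integer(T), TR = TR,
    base_within_community_r = base_within_community_r,
    n_communities = as.integer(n_communities),
    effect_edges = effect_edges,
    ar1_phi = ar1_phi, noise_sd = noise_sd,
    n_nuisance = as.integer(n_nuisance), nuisance_sd = nuisance_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

.validate_effects <- function(effect_edges, R) {
  effect_edges <- as.data.frame(effect_edges)
  needed <- c("i", "j", "delta")
  if (!all(needed %in% names(effect_edges)))
    stop("effect_edges needs columns i, j, delta")
  for (col in c("diagnosis", "age_class", "scan", "food_condition"))
    if (is.null(effect_edges[[col]])) effect_edges[[col]] <- "any"
  if (any(effect_edges$i < 1 | effect_edges$i > R |
            effect_edges$j < 1 | effect_edges$j > R))
    stop("effect edge indices outside 1..R")
  if (any(effect_edges$i == effect_edges$j))
    stop("effect edges must be off-diagonal")
  effect_edges
}

# Population correlation for one subject-scan: community blocks plus the
# planted deltas whose selectors match.  PD violations below 1e-8 are
# repaired by eigenvalue clipping; larger violations abort naming the
# offending edges, because silently repairing them would corrupt the
# planted ground truth.
.population_correlation <- function(spec, atlas, diagnosis, age_class,
                                    scan_index, food_condition) {
  R <- spec$R
  comm <- atlas$community_id
  S <- outer(comm, comm, "==") * spec$base_within_community_r
  diag(S) <- 1
  ee <- spec$effect_edges
  if (!is.null(ee) && nrow(ee)) {
    sel <- (ee$diagnosis == "any" | ee$diagnosis == diagnosis) &
      (ee$age_class == "any" | ee$age_class == age_class) &
      (ee$scan == "any" | ee$scan == scan_index) &
      (ee$food_condition == "any" | ee$food_condition == food_condition)
    for (k in which(sel)) {
      i <- ee$i[k]; j <- ee$j[k]
      S[i, j] <- S[i, j] + ee$delta[k]
      S[j, i] <- S[i, j]
    }
    if (any(abs(S[upper.tri(S)]) >= 1))
      stop("planted deltas push a correlation outside (-1, 1)")
  }
  ev <- eigen(S, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) <= -1e-8) {
    bad <- if (!is.null(ee) && nrow(ee))
      paste(sprintf("(%d,%d: %+0.2f)", ee$i, ee$j, ee$delta), collapse = " ")
    else "none"
    stop(sprintf(
      "implied correlation matrix not positive definite (min eigenvalue %.3g); planted deltas: %s",
      min(lam), bad))
  }
  if (min(lam) < 1e-12) {  # near-PSD: clip and renormalize to unit diagonal
    lam <- pmax(lam, 1e-10)
    S <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
  }
  S
}

#' Simulate one resting-state scan
#'
#' Draws an `R x T` region-by-time BOLD series: a stationary AR(1) process
#' whose zero-lag cross-correlation equals the population correlation for
#' this subject's contrast cell, plus shared slow-drift nuisance signals
#' (standing in for white-matter/ventricle confounds) and white noise.  The
#' injected nuisance regressors are attached so preprocessing can remove
#' exactly what was added.
#'
#' @param spec a [cohort_spec()].
#' @param atlas an [make_atlas()] result with `spec$R` regions.
#' @param diagnosis `"AN"` or `"HC"`; @param age_class `"young"` or
#'   `"adult"`; @param scan_index `"RS1"`, `"RS2"` or `"RS3"`.
#' @param food_condition `"chips"` or `"zucchini"`.
#' @param seed scan-level seed.
#' @param meta optional list stored on the result.
#' @return list of class `bold_series`: `values` (R x T), `TR`, `ids`,
#'   `nuisance` (T x K regressor matrix), `meta`.
#' @export
simulate_scan <- function(spec, atlas, diagnosis, age_class, scan_index,
                          food_condition, seed, meta = list()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!scan_index %in% c("RS1", "RS2", "RS3"))
    stop("scan_index must be RS1, RS2 or RS3")
  R <- spec$R; Tn <- spec$T
  S <- .population_correlation(spec, atlas, diagnosis, age_class,
                               scan_index, food_condition)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  L <- chol(S)
  phi <- spec$ar1_phi
  # stationary AR(1) with innovation covariance (1 - phi^2) * S keeps the
  # zero-lag cross-covariance at S for every t
  E <- matrix(stats::rnorm(Tn * R), Tn, R) %*% L
  X <- matrix(0, Tn, R)
  X[1L, ] <- E[1L, ]
  if (Tn > 1L) {
    sc <- sqrt(1 - phi^2)
    for (t in 2:Tn) X[t, ] <- phi * X[t - 1L, ] + sc * E[t, ]
  }
  K <- spec$n_nuisance
  nuis <- matrix(0, Tn, max(K, 0L))
  if (K > 0L) {
    tt <- seq_len(Tn) / Tn
    for (k in seq_len(K)) {
      # very slow random-phase drifts, below the analysis pass-band
      ph <- stats::runif(1, 0, 2 * pi)
      nuis[, k] <- cos(2 * pi * (k / 2) * tt + ph)
    }
    loadings <- matrix(stats::rnorm(R * K, sd = spec$nuisance_sd), R, K)
    X <- X + nuis %*% t(loadings)
  }
  if (spec$noise_sd > 0)
    X <- X + matrix(stats::rnorm(Tn * R, sd = spec$noise_sd), Tn, R)
  out <- list(values = t(X), TR = spec$TR, ids = atlas$region_id,
              nuisance = nuis, meta = c(meta, list(
                diagnosis = diagnosis, age_class = age_class,
                scan = scan_index, food_condition = food_condition)))
  class(out) <- "bold_series"
  out
}

#' Simulate the full cohort
#'
#' One scan per subject x session x scan index (RS1-RS3).  The food
#' condition alternates deterministically with subject index (odd subjects
#' eat chips in session 1, even subjects in session 2), giving the
#' counterbalanced two-session design.
#'
#' @param spec a [cohort_spec()].
#' @param atlas optional atlas; built from the cohort settings when `NULL`.
#' @return list of class `synthetic_cohort` with elements `scans` (named
#'   list of `bold_series`), `manifest` (one row per scan), `atlas`, and
#'   `ground_truth` (planted effect table and the informative regions).
#' @export
simulate_cohort <- function(spec, atlas = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(atlas))
    atlas <- make_atlas(spec$R, spec$n_communities, seed = spec$seed)
  groups <- names(spec$n_per_group)
  rows <- list(); scans <- list()
  sub_idx <- 0L
  for (g in groups) {
    age_class <- sub("_.*", "", g)
    diagnosis <- sub(".*_", "", g)
    for (s in seq_len(spec$n_per_group[[g]])) {
      sub_idx <- sub_idx + 1L
      subject_id <- sprintf("S%03d", sub_idx)
      chips_session <- if (sub_idx %% 2L == 1L) 1L else 2L
      for (session in 1:2) {
        cond <- if (session == chips_session) "chips" else "zucchini"
        for (scan in c("RS1", "RS2", "RS3")) {
          scan_seed <- (spec$seed + 7919L * sub_idx + 613L * session +
                          101L * match(scan, c("RS1", "RS2", "RS3"))) %% 2147483647L
          key <- sprintf("%s_ses%d_%s", subject_id, session, scan)
          scans[[key]] <- simulate_scan(
            spec, atlas, diagnosis, age_class, scan, cond, seed = scan_seed,
            meta = list(subject_id = subject_id, session = session, key = key))
          rows[[key]] <- data.frame(
            subject_id = subject_id, diagnosis = diagnosis,
            age_class = age_class, session = session, scan = scan,
            food_condition = cond, key = key, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  gt <- list(effect_edges = spec$effect_edges,
             informative_regions =
               if (is.null(spec$effect_edges)) integer(0)
               else sort(unique(c(spec$effect_edges$i, spec$effect_edges$j))))
  out <- list(scans = scans, manifest = manifest, atlas = atlas,
              ground_truth = gt, spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic resting-state cohort\n")
  cat(sprintf("  subjects: %d  scans: %d  regions: %d  T: %d  TR: %gs\n",
              length(unique(x$manifest$subject_id)), nrow(x$manifest),
              x$spec$R, x$spec$T, x$spec$TR))
  n_eff <- if (is.null(x$spec$effect_edges)) 0L else nrow(x$spec$effect_edges)
  cat(sprintf("  planted effect edges: %d\n", n_eff))
  invisible(x)
}

#' Simulate demographics and desire ratings
#'
#' Per-subject normal draws with group-specific means and SDs, mirroring a
#' demographics/ratings table.  `params` is a data.frame with columns
#' `variable`, `group` (e.g. `adult_HC`), `mean`, `sd`.
#'
#' @param n_per_group named counts as in [cohort_spec()].
#' @param params parameter table; defaults to [ratings_demographics_defaults()].
#' @param seed RNG seed.
#' @return data.frame of class `cohort_table`: one row per subject, one
#'   column per variable.
#' @export
simulate_ratings_demographics <- function(n_per_group = c(adult_HC = 15L,
                                                          adult_AN = 13L,
                                                          young_HC = 16L,
                                                          young_AN = 17L),
                                          params = ratings_demographics_defaults(),
                                          seed = 1L) {
  params <- as.data.frame(params)
  stopifnot(all(c("variable", "group", "mean", "sd") %in% names(params)))
  if (any(params$sd < 0)) stop("sd must be non-negative")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  out <- list()
  sub_idx <- 0L
  for (g in names(n_per_group)) {
    pg <- params[params$group == g, , drop = FALSE]
    for (s in seq_len(n_per_group[[g]])) {
      sub_idx <- sub_idx + 1L
      row <- list(subject_id = sprintf("S%03d", sub_idx),
                  age_class = sub("_.*", "", g),
                  diagnosis = sub(".*_", "", g))
      for (k in seq_len(nrow(pg)))
        row[[pg$variable[k]]] <- stats::rnorm(1, pg$mean[k], pg$sd[k])
      out[[sub_idx]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("cohort_table", "data.frame")
  res
}

#' Default demographics/ratings parameters
#'
#' Group means and SDs for depression score (BDI), state anxiety before the
#' scan (STAI-S pre), body-mass index and food-craving questionnaire,
#' configured to the adult and young cohort summaries of the emulated
#' study.
#' @return data.frame with columns `variable`, `group`, `mean`, `sd`.
#' @export
ratings_demographics_defaults <- function() {
  data.frame(
    variable = rep(c("BDI", "STAI_S_pre", "BMI", "FCQ_T"), each = 4),
    group = rep(c("adult_HC", "adult_AN", "young_HC", "young_AN"), 4),
    mean = c(4.9, 24.2, 5.9, 28.4,
             43.0, 37.9, 42.8, 38.5,
             23.5, 17.1, 21.5, 16.5,
             27.0, 44.1, 25.4, 46.1),
    sd = c(5.8, 9.3, 5.1, 12.1,
           3.3, 4.3, 3.1, 4.0,
           3.5, 1.8, 3.0, 1.5,
           10.6, 15.9, 10.3, 19.7),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort to delimited text files
#'
#' One tab-separated regions-by-time matrix per scan (header row of region
#' ids), a `manifest.csv`, and `ground_truth.json`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest with a `file` column.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort$manifest
  manifest$file <- file.path(dir, paste0(manifest$key, ".tsv"))
  for (k in seq_len(nrow(manifest))) {
    sc <- cohort$scans[[manifest$key[k]]]
    m <- t(sc$values)  # write as time x region with region-id header
    colnames(m) <- sc$ids
    utils::write.table(m, manifest$file[k], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nf <- file.path(dir, paste0(manifest$key[k], "_nuisance.tsv"))
    utils::write.table(sc$nuisance, nf, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  if (is.null(gt$effect_edges)) gt$effect_edges <- data.frame()
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a scan written by [write_cohort()]
#' @param file path to a `.tsv` scan file.
#' @param TR repetition time in seconds.
#' @return a `bold_series`.
#' @export
read_bold_tsv <- function(file, TR = 3.0) {
  m <- as.matrix(utils::read.table(file, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  nf <- sub("\\.tsv$", "_nuisance.tsv", file)
  nuis <- if (file.exists(nf))
    as.matrix(utils::read.table(nf, sep = "\t")) else NULL
  out <- list(values = t(m), TR = TR,
              ids = as.integer(colnames(m)), nuisance = nuis,
              meta = list(file = file))
  class(out) <- "bold_series"
  out
}

# preserve caller RNG state around seeded draws
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
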