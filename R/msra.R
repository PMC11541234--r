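# Multi-seed region analysis (MSRA): every atlas region serves in turn as a
# seed; the seed's mean time course is correlated with every target signal,
# the resulting correlation map is thresholded by Benjamini-Hochberg FDR
# per seed, and surviving correlations are averaged per target region.
# Because the FDR family is per-seed, entry (i, j) generally differs from
# (j, i): the matrix is asymmetric.

#' Extract a seed time course
#'
#' Mean across the seed's member signals (the rows of `series` listed in
#' `members`).
#'
#' @param series a `bold_series` or R x T matrix.
#' @param members integer row indices of the seed's member signals.
#' @return numeric vector of length T.
#' @export
extract_seed <- function(series, members) {
  v <- .series_values(series)
  if (length(members) == 0L) stop("empty seed region")
  if (any(members < 1L | members > nrow(v))) stop("seed member out of range")
  if (length(members) == 1L) v[members, ] else colMeans(v[members, , drop = FALSE])
}

#' Correlate a seed time course with every target signal
#'
#' Pearson correlation per target row, with the exact two-sided p-value
#' from the t transform `t = r * sqrt((T-2) / (1-r^2))` on `T - 2` degrees
#' of freedom.  Zero-variance targets get `r = NA` and `p = 1` (recorded as
#' non-significant) with a warning.
#'
#' @param seed_tc numeric vector of length T.
#' @param series a `bold_series` or matrix of target signals (rows).
#' @return list with `r` and `p`, one entry per target.
#' @export
correlation_map <- function(seed_tc, series) {
  v <- .series_values(series)
  Tn <- length(seed_tc)
  if (ncol(v) != Tn) stop("seed and targets must share T")
  if (Tn < 4L) stop("T >= 4 required")
  sdt <- apply(v, 1L, stats::sd)
  bad <- sdt == 0 | is.na(sdt)
  r <- rep(NA_real_, nrow(v))
  if (stats::sd(seed_tc) == 0) {
    warning("zero-variance seed: all correlations undefined")
    return(list(r = r, p = rep(1, nrow(v))))
  }
  if (any(!bad))
    r[!bad] <- drop(stats::cor(seed_tc, t(v[!bad, , drop = FALSE])))
  if (any(bad))
    warning(sprintf("%d zero-variance target(s) recorded as non-significant",
                    sum(bad)))
  p <- rep(1, nrow(v))
  ok <- !is.na(r)
  rr <- pmin(pmax(r[ok], -1 + 1e-15), 1 - 1e-15)
  tstat <- rr * sqrt((Tn - 2) / (1 - rr^2))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = Tn - 2)
  p[ok][abs(r[ok]) >= 1 - 1e-15] <- 0
  list(r = r, p = p)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure at level `q`: rejects all p-values at or below the
#' largest `p_(k)` with `p_(k) <= k q / m`.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical rejection mask of the same length.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) return(logical(0))
  stats::p.adjust(pvals, method = "BH") <= q
}

#' MSRA connectivity matrix
#'
#' Region mode: one signal per atlas region; each region seeds in turn, the
#' BH-FDR family being that seed's full correlation map over all R targets
#' (the self-correlation is part of the family, stored on the diagonal, and
#' excluded from graph construction downstream).  Entry (i, j) is the
#' seed-i correlation with region j when it survives FDR, else 0.
#'
#' Voxel mode (`voxel_map` supplied): signals are voxels; each seed is the
#' six voxels nearest the region's center of mass, targets are all voxels,
#' and surviving correlations are averaged per target region.
#'
#' @param scan a preprocessed `bold_series`.
#' @param atlas an `atlas_definition`.
#' @param q FDR level (default 0.05).
#' @param voxel_map optional data.frame (voxel mode) with one row per
#'   signal row: columns `region_id`, `x`, `y`, `z`.
#' @param signed keep the sign of surviving correlations (default TRUE).
#' @return list of class `connectivity_matrix`: `values` (R x R), `n_sig`
#'   (surviving-target counts), `q`, `meta`.
#' @export
msra_matrix <- function(scan, atlas, q = 0.05, voxel_map = NULL,
                        signed = TRUE) {
  v <- .series_values(scan)
  R <- nrow(atlas)
  if (is.null(voxel_map)) {
    if (nrow(v) != R) stop("scan must cover all atlas regions")
    vals <- matrix(0, R, R)
    nsig <- matrix(0L, R, R)
    C <- stats::cor(t(v))
    Tn <- ncol(v)
    rr <- pmin(pmax(C, -1 + 1e-15), 1 - 1e-15)
    P <- 2 * stats::pt(-abs(rr * sqrt((Tn - 2) / (1 - rr^2))), df = Tn - 2)
    P[abs(C) >= 1 - 1e-15] <- 0
    for (i in seq_len(R)) {
      keep <- fdr_bh(P[i, ], q)
      vals[i, keep] <- C[i, keep]
      nsig[i, keep] <- 1L
    }
  } else {
    if (nrow(voxel_map) != nrow(v))
      stop("voxel_map must have one row per signal")
    vals <- matrix(0, R, R)
    nsig <- matrix(0L, R, R)
    for (i in seq_len(R)) {
      seed_vox <- .seed_voxels(atlas[i, ], voxel_map)
      tc <- extract_seed(v, seed_vox)
      cm <- correlation_map(tc, v)
      keep <- fdr_bh(cm$p, q)
      for (j in seq_len(R)) {
        tj <- which(voxel_map$region_id == atlas$region_id[j] & keep)
        nsig[i, j] <- length(tj)
        if (length(tj)) vals[i, j] <- mean(cm$r[tj])
      }
    }
  }
  if (!signed) vals[vals < 0] <- 0
  dimnames(vals) <- list(atlas$region_name, atlas$region_name)
  out <- list(values = vals, n_sig = nsig, q = q,
              meta = if (inherits(scan, "bold_series")) scan$meta else list())
  class(out) <- "connectivity_matrix"
  out
}

# six voxels nearest the region's center of mass, restricted to the region
.seed_voxels <- function(region, voxel_map) {
  idx <- which(voxel_map$region_id == region$region_id)
  if (!length(idx)) stop("region has no voxels")
  coords <- as.matrix(voxel_map[idx, c("x", "y", "z")])
  com <- colMeans(coords)
  d2 <- rowSums((coords - rep(com, each = nrow(coords)))^2)
  idx[order(d2)][seq_len(min(6L, length(idx)))]
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  R <- nrow(x$values)
  off <- x$values[row(x$values) != col(x$values)]
  cat(sprintf("MSRA connectivity matrix: %d x %d (q = %g)\n", R, R, x$q))
  cat(sprintf("  nonzero off-diagonal entries: %d / %d (%.1f%%)\n",
              sum(off != 0), length(off), 100 * mean(off != 0)))
  invisible(x)
}

#' Write a connectivity matrix as delimited text
#' @param cm a `connectivity_matrix`.
#' @param file output path; a sidecar `<file>.meta.json` records `q` and
#'   the scan identity.
#' @export
write_connectivity <- function(cm, file) {
  utils::write.table(cm$values, file, sep = "\t", quote = FALSE,
                     col.names = NA)
  meta <- c(cm$meta, list(q = cm$q, n_sig_total = sum(cm$n_sig)))
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE)
  invisible(file)
}
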