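## 2 kb segment grid anchored at the region start: segments slide at the
## window step and must lie fully inside the region; a trailing partial
## segment is dropped. Returns 0-based segment starts.
segment_grid <- function(start, end, segment_bp = 2000L, step_bp = 50L) {
  start <- as.integer(ceiling(start / step_bp) * step_bp)  # snap to grid
  span <- end - start
  if (span < segment_bp) return(integer(0))
  start + step_bp * (0:(floor((span - segment_bp) / step_bp)))
}

segment_profile_impl <- function(group, region, T, segment_bp = 2000L) {
  stopifnot(inherits(group, "replicate_group"))
  chrom <- region$chrom[1]
  tr1 <- group$tracks[[1]]
  step <- tr1$step_bp; window <- tr1$window_bp
  seg_starts <- segment_grid(region$start[1], region$end[1], segment_bp, step)
  if (length(seg_starts) == 0L)
    stop("region shorter than one segment (", segment_bp, " bp)")
  nw <- (segment_bp - window) %/% step + 1L   # windows per segment
  i0 <- seg_starts %/% step + 1L
  i1 <- i0 + nw - 1L
  vs <- log_vectors(group, chrom, T)
  lce <- meance_ranges(vs, i0, i1)
  mean_cov <- Reduce(`+`, lapply(group$tracks,
                                 function(tr) tr$values[[chrom]])) /
    group$n_replicates
  cs <- c(0, cumsum(mean_cov))
  lcs <- cs[i1 + 1L] - cs[i0]
  rid <- if (!is.null(region$region_id)) region$region_id[1] else
    sprintf("%s:%d-%d", chrom, region$start[1], region$end[1])
  data.frame(region_id = rid, chrom = chrom,
             segment_start = seg_starts,
             segment_end = seg_starts + segment_bp,
             lce = lce, lcs = lcs,
             condition = group$condition,
             stringsAsFactors = FALSE)
}

#' Local correlation estimate (LCE) profile of a region
#'
#' Applies the meanCE construction (natural-log window sums gated at the
#' coverage minimum T, mean off-diagonal replicate-pairwise Pearson
#' correlation) to every tiled segment of fixed length (`segment_bp`,
#' default 2 kb) sliding at the window step inside the region. High LCE means
#' the replicates agree on the nucleosome-scale shape of the enrichment
#' profile; values near zero indicate locally variegated topology.
#'
#' @param group A [replicate_group].
#' @param region One-row data.frame (or list) with `chrom`, `start`, `end`
#'   and optionally `region_id`.
#' @param T Integer coverage-minimum threshold.
#' @param segment_bp Segment length in bp (default 2000).
#' @return data.frame with `region_id`, `chrom`, `segment_start`,
#'   `segment_end`, `lce`, `condition`.
#' @export
lce_profile <- function(group, region, T, segment_bp = 2000L) {
  p <- segment_profile_impl(group, region, T, segment_bp)
  p[, c("region_id", "chrom", "segment_start", "segment_end", "lce",
        "condition")]
}

#' Local coverage sum (LCS) profile of a region
#'
#' Per tiled segment, the sum over the segment's windows of the
#' replicate-mean window sums: the conventional intensity measure,
#' insensitive to local profile shape.
#'
#' @inheritParams lce_profile
#' @return data.frame with `region_id`, `chrom`, `segment_start`,
#'   `segment_end`, `lcs`, `condition`.
#' @export
lcs_profile <- function(group, region, segment_bp = 2000L) {
  p <- segment_profile_impl(group, region, T = 0L, segment_bp)
  p[, c("region_id", "chrom", "segment_start", "segment_end", "lcs",
        "condition")]
}

#' Joint LCE + LCS segment profile
#'
#' @inheritParams lce_profile
#' @return data.frame with both `lce` and `lcs` columns.
#' @export
segment_profiles <- function(group, region, T, segment_bp = 2000L) {
  segment_profile_impl(group, region, T, segment_bp)
}

#' Region-level cross-condition profile correlation
#'
#' Correlates two conditions' per-segment LCE (and/or LCS) vectors over a
#' shared region and segment grid. This is the region-scale comparison that
#' contrasts topology conservation (LCE corr) with the conventional coverage
#' envelope (LCS corr).
#'
#' @param profile_a,profile_b Segment profiles from [segment_profiles] (or
#'   [lce_profile]/[lcs_profile]) for the same region in two conditions.
#' @param method Correlation type (default `"pearson"`; rank correlation via
#'   `"spearman"`).
#' @return One-row data.frame: `region_id`, `pair` (condition labels),
#'   `lce_corr`, `lcs_corr` (NA when the metric is absent from either profile
#'   or a vector has zero variance), `n_segments`.
#' @export
region_correlation <- function(profile_a, profile_b, method = "pearson") {
  if (!identical(profile_a$region_id[1], profile_b$region_id[1]))
    stop("profiles are for different regions")
  m <- merge(profile_a, profile_b, by = "segment_start",
             suffixes = c("_a", "_b"))
  if (nrow(m) < 3L) stop("need at least 3 shared segments")
  corr_or_na <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok], method = method)
  }
  lce_corr <- if (all(c("lce_a", "lce_b") %in% names(m)))
    corr_or_na(m$lce_a, m$lce_b) else NA_real_
  lcs_corr <- if (all(c("lcs_a", "lcs_b") %in% names(m)))
    corr_or_na(m$lcs_a, m$lcs_b) else NA_real_
  data.frame(region_id = profile_a$region_id[1],
             pair = paste(profile_a$condition[1], profile_b$condition[1],
                          sep = "-"),
             lce_corr = lce_corr, lcs_corr = lcs_corr,
             n_segments = nrow(m), stringsAsFactors = FALSE)
}

#' Eigenvalue-based correlation estimate (eigenCE)
#'
#' Alternative replicate-agreement summary: the largest eigenvalue of the
#' replicate correlation matrix divided by its trace. For a compound-
#' symmetric k x k matrix with off-diagonal r this equals
#' (1 + (k-1) r) / k, so for three replicates eigenCE = (1 + 2 meanCE) / 3.
#'
#' @param m Symmetric correlation matrix (unit diagonal).
#' @return eigenCE value in `(0, 1]`.
#' @export
eigen_ce <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("m must be a square matrix")
  if (!isSymmetric(m, tol = 1e-8))
    stop("m must be symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  max(ev) / sum(diag(m))
}

#' Mean region LCE
#'
#' Arithmetic mean of a region's per-segment LCE values; the region-level
#' topology-conservation summary related to expression in the quantile
#' curves.
#'
#' @param profile A profile containing an `lce` column.
#' @return Mean LCE.
#' @export
region_mean_lce <- function(profile) {
  stopifnot("lce" %in% names(profile), nrow(profile) >= 1L)
  mean(profile$lce)
}
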