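#' Pipeline configuration
#'
#' Collects the thresholds and geometry shared across the pipeline stages.
#' The defaults mirror the published operating point of the method: a
#' composite fraction of 2/3 replicates, a density rule of 40 consecutive
#' enriched bins within a 4 kb span, fixed 2 kb topology segments, 50%/75%
#' span-overlap rules for matching/conservation, 10,000 resampling draws and
#' BH FDR at 0.05. `coverage_min` (the Poisson-calibrated coverage minimum T)
#' is data-dependent and has no default; for deep genome-wide libraries the
#' study operated in the band 47-50.
#'
#' @param coverage_min Integer coverage-minimum threshold T.
#' @param composite_fraction Fraction of replicates that must meet T
#'   (default 2/3).
#' @param density_bins Consecutive enriched bins required (default 40).
#' @param density_span_bp Maximum span of those bin positions (default 4000).
#' @param segment_bp Topology segment length (default 2000).
#' @param overlap_min_match Reciprocal span overlap for cross-condition
#'   matching (default 0.5).
#' @param overlap_min_conserved Reciprocal span overlap for the conserved
#'   subset (default 0.75).
#' @param n_resample Resampling depth (default 10000).
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param window_bp,step_bp Window geometry (default 100/50).
#' @param seed Integer RNG seed for the stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(coverage_min, composite_fraction = 2 / 3,
                            density_bins = 40L, density_span_bp = 4000L,
                            segment_bp = 2000L,
                            overlap_min_match = 0.5,
                            overlap_min_conserved = 0.75,
                            n_resample = 10000L, fdr_alpha = 0.05,
                            window_bp = 100L, step_bp = 50L, seed = 1L) {
  stopifnot(coverage_min >= 0,
            composite_fraction > 0, composite_fraction <= 1,
            density_bins > 0, segment_bp > 0, n_resample > 0,
            fdr_alpha > 0, fdr_alpha < 1)
  if (!(density_bins * step_bp <= density_span_bp &&
        density_span_bp <= 2 * density_bins * step_bp))
    stop("density_span_bp must lie in [density_bins*step_bp, 2*density_bins*step_bp]")
  structure(list(coverage_min = as.integer(coverage_min),
                 composite_fraction = composite_fraction,
                 density_bins = as.integer(density_bins),
                 density_span_bp = as.integer(density_span_bp),
                 segment_bp = as.integer(segment_bp),
                 overlap_min_match = overlap_min_match,
                 overlap_min_conserved = overlap_min_conserved,
                 n_resample = as.integer(n_resample),
                 fdr_alpha = fdr_alpha,
                 window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Composite replicate-enrichment mask
#'
#' Marks a window as enriched when the coverage minimum T is met or exceeded
#' in at least a fraction `f` of the replicates (the study used 2 of 3).
#'
#' @param group A [replicate_group].
#' @param T Integer coverage-minimum threshold.
#' @param f Required fraction of replicates (default 2/3).
#' @return Object of class `enrichment_mask`: named list of logical vectors
#'   per chromosome plus provenance.
#' @export
composite_mask <- function(group, T, f = 2 / 3) {
  stopifnot(inherits(group, "replicate_group"), T >= 0, f > 0, f <= 1)
  chroms <- names(group$tracks[[1]]$values)
  n <- group$n_replicates
  mask <- lapply(chroms, function(chrom) {
    counts <- Reduce(`+`, lapply(group$tracks,
                                 function(tr) tr$values[[chrom]] >= T))
    counts >= n * f - 1e-9
  })
  names(mask) <- chroms
  structure(list(mask = mask, T = as.integer(T), f = f,
                 n_replicates = n, condition = group$condition,
                 window_bp = group$tracks[[1]]$window_bp,
                 step_bp = group$tracks[[1]]$step_bp),
            class = "enrichment_mask")
}

#' @export
print.enrichment_mask <- function(x, ...) {
  cat(sprintf("<enrichment_mask> T = %d, f = %.3f; %d / %d windows enriched\n",
              x$T, x$f, sum(unlist(lapply(x$mask, sum))),
              sum(lengths(x$mask))))
  invisible(x)
}

#' Density scan for core enrichment domain (CED) candidates
#'
#' Slides over the ordered list of enriched windows on each chromosome and,
#' for every run of `density_bins` consecutive *enriched* windows (small
#' internal gaps of unenriched windows are allowed), accepts the run when the
#' span of its window positions (last start minus first start) does not
#' exceed `density_span_bp`. At the default geometry this enforces that at
#' least 50% of the 50 bp window positions across the span are enriched.
#' Each accepted run yields a candidate CED covering first window start to
#' last window end; overlapping candidates are retained for the merge stage.
#'
#' @param mask An [composite_mask()] result.
#' @param density_bins Run length in enriched bins (default 40).
#' @param density_span_bp Maximum position span in bp (default 4000).
#' @return data.frame with columns `chrom`, `start`, `end`, `first_idx`,
#'   `last_idx` (1-based window indices), possibly empty.
#' @export
density_scan <- function(mask, density_bins = 40L, density_span_bp = 4000L) {
  stopifnot(inherits(mask, "enrichment_mask"))
  step <- mask$step_bp
  window <- mask$window_bp
  out <- lapply(names(mask$mask), function(chrom) {
    idx <- which(mask$mask[[chrom]])
    if (length(idx) < density_bins) return(NULL)
    i <- seq_len(length(idx) - density_bins + 1L)
    first <- idx[i]
    last <- idx[i + density_bins - 1L]
    ok <- (last - first) * step <= density_span_bp
    if (!any(ok)) return(NULL)
    data.frame(chrom = chrom,
               start = (first[ok] - 1L) * step,
               end = (last[ok] - 1L) * step + window,
               first_idx = first[ok], last_idx = last[ok],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), first_idx = integer(0),
                      last_idx = integer(0))
  out
}

## threshold-gated log vectors: ln(sum) when >= T, else 0
log_vectors <- function(group, chrom, T) {
  lapply(group$tracks, function(tr) {
    x <- tr$values[[chrom]]
    v <- numeric(length(x))
    above <- x >= T
    v[above] <- log(x[above])
    v
  })
}

## Mean off-diagonal Pearson correlation for many window ranges at once,
## via cumulative-sum moments. vs: list of replicate vectors (already
## log/zero gated); i0, i1: 1-based inclusive index ranges. Pairs where
## either vector has (numerically) zero variance contribute 0.
meance_ranges <- function(vs, i0, i1, tol = 1e-7) {
  k <- length(vs)
  n <- i1 - i0 + 1
  cums <- lapply(vs, function(v) c(0, cumsum(v)))
  cumsq <- lapply(vs, function(v) c(0, cumsum(v * v)))
  S <- lapply(seq_len(k), function(j) cums[[j]][i1 + 1L] - cums[[j]][i0])
  V <- lapply(seq_len(k), function(j)
    n * (cumsq[[j]][i1 + 1L] - cumsq[[j]][i0]) - S[[j]]^2)
  pairs <- utils::combn(k, 2L)
  total <- numeric(length(i0))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    cp <- c(0, cumsum(vs[[a]] * vs[[b]]))
    covab <- n * (cp[i1 + 1L] - cp[i0]) - S[[a]] * S[[b]]
    r <- ifelse(V[[a]] <= tol | V[[b]] <= tol, 0,
                covab / sqrt(pmax(V[[a]], tol) * pmax(V[[b]], tol)))
    total <- total + pmin(pmax(r, -1), 1)
  }
  total / ncol(pairs)
}

#' Mean correlation estimate (meanCE) over a candidate CED
#'
#' For each replicate, window sums across the CED are converted to natural
#' log values (or zero when below the coverage minimum T); the meanCE is the
#' mean of the off-main-diagonal entries of the replicate-pairwise Pearson
#' correlation matrix of these vectors. Pairs in which either vector has zero
#' variance contribute 0.
#'
#' @param group A [replicate_group].
#' @param chrom Chromosome name.
#' @param start,end CED interval, 0-based half-open; must cover >= 3 windows.
#' @param T Integer coverage-minimum threshold.
#' @return meanCE in `[-1, 1]`.
#' @export
ced_mean_ce <- function(group, chrom, start, end, T) {
  tr <- group$tracks[[1]]
  ws <- window_starts(tr$chrom_sizes[[chrom]], tr$window_bp, tr$step_bp)
  idx <- which(ws >= start & ws + tr$window_bp <= end)
  if (length(idx) < 3L) stop("CED must cover at least 3 windows")
  vs <- log_vectors(group, chrom, T)
  meance_ranges(vs, min(idx), max(idx))
}

#' Merge retained CEDs into PcG regions
#'
#' Overlapping CEDs (>= 1 bp, half-open coordinates) are merged transitively;
#' region bounds are the min start / max end of the constituent CEDs. Only
#' CEDs with positive meanCE may enter (those with estimates of zero or less
#' are discarded upstream).
#'
#' @param ceds data.frame with columns `chrom`, `start`, `end`, `mean_ce`
#'   (all `mean_ce > 0`).
#' @return data.frame of disjoint regions, sorted by chromosome and start:
#'   `region_id`, `chrom`, `start`, `end`, `span_bp`, `n_ceds`, `mean_ce`
#'   (mean of constituent CED estimates).
#' @export
merge_ceds <- function(ceds) {
  empty <- data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      span_bp = integer(0), n_ceds = integer(0),
                      mean_ce = numeric(0))
  if (is.null(ceds) || nrow(ceds) == 0L) return(empty)
  if (any(ceds$mean_ce <= 0))
    stop("merge_ceds expects only CEDs with meanCE > 0")
  gr <- gr_from_df(ceds)
  ## min.gapwidth = 0: touching half-open intervals share no base, stay apart
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  grp <- S4Vectors::subjectHits(hits)
  stopifnot(length(grp) == nrow(ceds))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    n_ceds = as.integer(tabulate(grp, nbins = length(merged))),
    mean_ce = as.numeric(tapply(ceds$mean_ce, factor(grp, levels = seq_along(merged)), mean)),
    stringsAsFactors = FALSE)
  out$span_bp <- out$end - out$start
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$region_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out[, c("region_id", "chrom", "start", "end", "span_bp", "n_ceds", "mean_ce")]
}

#' Call PcG regions from a replicate group
#'
#' Full caller: composite replicate mask at the coverage minimum, density
#' scan for candidate CEDs, correlation filtering (meanCE > 0), and merging
#' of overlapping retained CEDs into disjoint regions. Deterministic given
#' its inputs (no RNG).
#'
#' @param group A [replicate_group].
#' @param config A [pipeline_config] supplying `coverage_min`,
#'   `composite_fraction` and the density rule.
#' @return data.frame of regions as in [merge_ceds], plus per-replicate mean
#'   window coverage columns `cov_rep1..n` and their mean `mean_cov`.
#' @export
call_regions <- function(group, config) {
  stopifnot(inherits(group, "replicate_group"),
            inherits(config, "pipeline_config"))
  T <- config$coverage_min
  mask <- composite_mask(group, T, config$composite_fraction)
  cands <- density_scan(mask, config$density_bins, config$density_span_bp)
  ## deduplicate candidates sharing a span before correlation
  cands <- cands[!duplicated(cands[, c("chrom", "start", "end")]), , drop = FALSE]
  if (nrow(cands)) {
    mce <- numeric(nrow(cands))
    for (chrom in unique(cands$chrom)) {
      sel <- cands$chrom == chrom
      vs <- log_vectors(group, chrom, T)
      mce[sel] <- meance_ranges(vs, cands$first_idx[sel], cands$last_idx[sel])
    }
    cands$mean_ce <- mce
    cands <- cands[cands$mean_ce > 0, , drop = FALSE]
  }
  regions <- merge_ceds(cands)
  ## per-replicate mean coverage over region windows
  n_rep <- group$n_replicates
  covm <- matrix(NA_real_, nrow(regions), n_rep)
  if (nrow(regions)) {
    tr1 <- group$tracks[[1]]
    for (i in seq_len(nrow(regions))) {
      chrom <- regions$chrom[i]
      ws <- window_starts(tr1$chrom_sizes[[chrom]], tr1$window_bp, tr1$step_bp)
      idx <- which(ws >= regions$start[i] & ws + tr1$window_bp <= regions$end[i])
      for (r in seq_len(n_rep))
        covm[i, r] <- mean(group$tracks[[r]]$values[[chrom]][idx])
    }
  }
  colnames(covm) <- paste0("cov_rep", seq_len(n_rep))
  regions <- cbind(regions, as.data.frame(covm))
  regions$mean_cov <- if (nrow(regions)) rowMeans(covm) else numeric(0)
  regions
}
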