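#' Pile up read intervals into a binned coverage track
#'
#' Converts 0-based half-open read placements into per-window coverage sums:
#' each window's value is the number of read *bases* falling inside the
#' window. Windows are `window_bp` wide, anchored at position 0, and stepped
#' by `step_bp`, so every interior base is counted by exactly two overlapping
#' windows.
#'
#' @param reads data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param window_bp,step_bp Window geometry in bp.
#' @param read_length Read length metadata recorded on the track (default the
#'   modal read length, or 36 for an empty input).
#' @return A [binned_track].
#' @export
pileup_reads <- function(reads, chrom_sizes, window_bp = 100L, step_bp = 50L,
                         read_length = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(reads)))
  unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("reads on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (is.null(read_length)) {
    read_length <- if (nrow(reads)) {
      w <- reads$end - reads$start
      as.integer(names(sort(table(w), decreasing = TRUE))[1])
    } else 36L
  }
  values <- vector("list", length(chrom_sizes))
  names(values) <- names(chrom_sizes)
  n_clipped <- 0L
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    n <- n_windows(len, window_bp, step_bp)
    r <- reads[reads$chrom == chrom, , drop = FALSE]
    if (nrow(r) == 0L || n == 0L) {
      values[[chrom]] <- numeric(n)
      next
    }
    s <- pmax(r$start, 0)
    e <- pmin(r$end, len)
    n_clipped <- n_clipped + sum(s != r$start | e != r$end)
    keep <- e > s
    cov <- IRanges::coverage(IRanges::IRanges(start = s[keep] + 1L,
                                              end = e[keep]),
                             width = len)
    ws <- window_starts(len, window_bp, step_bp)
    v <- IRanges::Views(cov, start = ws + 1L, width = window_bp)
    values[[chrom]] <- as.numeric(IRanges::viewSums(v))
  }
  if (n_clipped > 0L)
    message(n_clipped, " read(s) clipped to chromosome bounds")
  binned_track(values, chrom_sizes, window_bp, step_bp, read_length)
}

#' Observed vs Poisson-expected coverage exceedance curve
#'
#' For every integer threshold t, counts windows genome-wide whose coverage
#' sum exceeds t, together with the count predicted for a Poisson
#' distribution at the genome-wide mean window sum. Broad enrichment shows up
#' as an excess of observed over expected counts in the upper tail.
#'
#' @param track A [binned_track].
#' @return Object of class `enrichment_curve`: a list with `curve`
#'   (data.frame `threshold`, `observed`, `expected`), `lambda` (mean window
#'   sum) and `n_windows`.
#' @export
enrichment_curve <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  x <- unlist(track$values, use.names = FALSE)
  if (length(x) == 0L) stop("empty track")
  if (all(x == 0)) stop("no coverage")
  n <- length(x)
  lambda <- mean(x)
  xmax <- max(x)
  thresholds <- 0:xmax
  ## observed_count(t) = # windows with sum > t, via cumulative counts
  counts <- tabulate(pmin(floor(x), xmax) + 1L, nbins = xmax + 1L)
  observed <- n - cumsum(counts)
  expected <- n * stats::ppois(thresholds, lambda, lower.tail = FALSE)
  structure(list(curve = data.frame(threshold = thresholds,
                                    observed = observed,
                                    expected = expected),
                 lambda = lambda, n_windows = n),
            class = "enrichment_curve")
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("<enrichment_curve> %d windows, mean window sum %.2f, thresholds 0..%d\n",
              x$n_windows, x$lambda, max(x$curve$threshold)))
  invisible(x)
}

#' Coverage-minimum threshold from an enrichment curve
#'
#' Selects the smallest threshold t at which the observed exceedance count is
#' at least `excess_ratio` times the Poisson prediction, then clamps it into
#' `[floor, cap]`. A minimum observed-window count guards the rule against
#' spurious crossings driven by the handful of windows in the extreme sample
#' tail, where the Poisson prediction is essentially zero.
#'
#' @param curve An [enrichment_curve].
#' @param excess_ratio Required observed/expected excess (default 2).
#' @param floor,cap Clamp band for the returned threshold. `cap = NULL` uses
#'   the largest tabulated threshold.
#' @param min_windows Minimum observed windows above t for a valid crossing
#'   (default 30).
#' @return List of class `poisson_threshold`: `threshold` (clamped),
#'   `pre_clamp`, `crossed` (logical; `FALSE` means no crossing was found
#'   below `cap` and the cap was returned with a warning), plus the rule
#'   parameters.
#' @export
poisson_threshold <- function(curve, excess_ratio = 2, floor = 0L, cap = NULL,
                              min_windows = 30L) {
  stopifnot(inherits(curve, "enrichment_curve"), excess_ratio > 0)
  cv <- curve$curve
  if (is.null(cap)) cap <- max(cv$threshold)
  ok <- cv$observed >= excess_ratio * cv$expected &
    cv$observed >= min_windows & cv$threshold <= cap
  crossed <- any(ok)
  if (crossed) {
    pre_clamp <- cv$threshold[which(ok)[1]]
  } else {
    pre_clamp <- as.integer(cap)
    warning("no threshold below cap satisfies the excess rule; returning cap")
  }
  structure(list(threshold = as.integer(min(max(pre_clamp, floor), cap)),
                 pre_clamp = as.integer(pre_clamp),
                 crossed = crossed,
                 excess_ratio = excess_ratio,
                 floor = as.integer(floor), cap = as.integer(cap),
                 min_windows = as.integer(min_windows)),
            class = "poisson_threshold")
}

#' @export
print.poisson_threshold <- function(x, ...) {
  cat(sprintf("<poisson_threshold> T = %d (pre-clamp %d, %s), excess ratio %.2f, band [%d, %d]\n",
              x$threshold, x$pre_clamp,
              if (x$crossed) "crossing found" else "NO crossing (cap)",
              x$excess_ratio, x$floor, x$cap))
  invisible(x)
}
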