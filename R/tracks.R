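#' Number of coverage windows on a chromosome
#'
#' Windows of `window_bp` bases are anchored at position 0 and tiled at
#' `step_bp` steps; a trailing partial window is dropped.
#'
#' @param chrom_len Chromosome length in bp.
#' @param window_bp Window size in bp (default 100).
#' @param step_bp Step between window starts in bp (default 50).
#' @return Integer number of windows.
#' @export
n_windows <- function(chrom_len, window_bp = 100L, step_bp = 50L) {
  if (chrom_len < window_bp) return(0L)
  as.integer(floor((chrom_len - window_bp) / step_bp) + 1L)
}

#' Window start positions (0-based) for a chromosome
#'
#' @inheritParams n_windows
#' @return Integer vector of 0-based window start positions.
#' @export
window_starts <- function(chrom_len, window_bp = 100L, step_bp = 50L) {
  n <- n_windows(chrom_len, window_bp, step_bp)
  if (n == 0L) return(integer(0))
  step_bp * (seq_len(n) - 1L)
}

#' Binned coverage track
#'
#' The universal substrate of the pipeline: per-chromosome coverage sums over
#' `window_bp` windows stepped by `step_bp` (defaults 100 bp / 50 bp, so
#' adjacent windows overlap by half and each base contributes to exactly two
#' windows away from chromosome ends). Coordinates are 0-based half-open
#' throughout.
#'
#' @param values Named list (one entry per chromosome) of non-negative
#'   numeric vectors of window sums.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param window_bp,step_bp Window geometry in bp.
#' @param read_length Read length metadata in bp (default 36).
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, chrom_sizes, window_bp = 100L, step_bp = 50L,
                         read_length = 36L) {
  stopifnot(is.list(values), !is.null(names(values)),
            !is.null(names(chrom_sizes)), all(chrom_sizes > 0))
  if (!all(names(values) %in% names(chrom_sizes)))
    stop("track has chromosomes absent from chrom_sizes: ",
         paste(setdiff(names(values), names(chrom_sizes)), collapse = ", "))
  for (chrom in names(values)) {
    v <- values[[chrom]]
    n_exp <- n_windows(chrom_sizes[[chrom]], window_bp, step_bp)
    if (length(v) != n_exp)
      stop(sprintf("chromosome %s: %d window values, expected %d",
                   chrom, length(v), n_exp))
    if (any(v < 0)) stop("negative window sums on ", chrom)
  }
  structure(list(values = values,
                 chrom_sizes = chrom_sizes[names(values)],
                 window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 read_length = as.integer(read_length)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %d chromosome(s), %d windows (%d bp / %d bp step)\n",
              length(x$values), sum(lengths(x$values)), x$window_bp, x$step_bp))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$window_bp, b$window_bp) && identical(a$step_bp, b$step_bp) &&
    identical(names(a$values), names(b$values)) &&
    identical(lengths(a$values), lengths(b$values))
}

#' Replicate group of binned tracks
#'
#' A condition label (cell type x age) together with the replicate tracks for
#' that condition, all sharing one window grid. The composite-enrichment and
#' correlation machinery operates on these groups.
#'
#' @param tracks List of [binned_track] objects (>= 2, typically 3).
#' @param condition Condition label, e.g. `"Mo_Cb"`.
#' @return An object of class `replicate_group`.
#' @export
replicate_group <- function(tracks, condition = "cond") {
  stopifnot(is.list(tracks), length(tracks) >= 2L)
  if (!all(vapply(tracks, inherits, logical(1), "binned_track")))
    stop("all elements must be binned_track objects")
  for (i in seq_along(tracks)[-1])
    if (!same_grid(tracks[[1]], tracks[[i]]))
      stop("replicate ", i, " is not on the same window grid as replicate 1")
  structure(list(tracks = tracks, condition = condition,
                 n_replicates = length(tracks)),
            class = "replicate_group")
}

#' @export
print.replicate_group <- function(x, ...) {
  cat(sprintf("<replicate_group> condition %s, %d replicates\n",
              x$condition, x$n_replicates))
  invisible(x)
}

## GRanges conversion for 0-based half-open interval tables
gr_from_df <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}
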