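#' Reciprocal span overlap of two intervals
#'
#' Defined as intersection length / union length by default (the symmetric
#' convention used by the matching and conservation rules);
#' `denom = "shorter"` switches to intersection / shorter-span.
#'
#' @param start_a,end_a,start_b,end_b Interval bounds (0-based half-open);
#'   vectorised.
#' @param denom `"union"` (default) or `"shorter"`.
#' @return Overlap fraction(s) in `[0, 1]`.
#' @export
span_overlap <- function(start_a, end_a, start_b, end_b, denom = "union") {
  denom <- match.arg(denom, c("union", "shorter"))
  int <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  d <- if (denom == "union")
    (end_a - start_a) + (end_b - start_b) - int
  else pmin(end_a - start_a, end_b - start_b)
  ifelse(d > 0, int / d, 0)
}

largest_region <- function(df) df[which.max(df$end - df$start), , drop = FALSE]

#' Match regions across condition-replicates through shared genes
#'
#' Builds matched groups around genes: for each gene, the regions overlapping
#' it in every condition-replicate set are collected; the group is retained
#' when, in at least one condition, every replicate contributes a member and
#' the replicate representatives (largest members) show pairwise reciprocal
#' span overlap of at least `min_overlap`. The outer comparison boundary is
#' the maximal extension of the members that overlap their condition's mean
#' boundary interval (per-condition mean of representative starts/ends across
#' replicates). Genes yielding identical member sets are merged into one
#' group ("genes in common").
#'
#' @param region_sets Named list: condition label -> list of replicate region
#'   data.frames (`chrom`, `start`, `end`).
#' @param genes data.frame with `chrom`, `start`, `end`, `gene_id`.
#' @param min_overlap Reciprocal span overlap threshold (default 0.5).
#' @param overlap_denom Overlap convention, see [span_overlap].
#' @return List of matched groups; each a list with `gene_ids`, `members`
#'   (data.frame `condition`, `replicate`, `chrom`, `start`, `end`,
#'   `span_bp`), `outer` (`chrom`, `start`, `end`) and `spans` (condition x
#'   replicate matrix of representative spans within the outer boundary).
#' @export
match_regions <- function(region_sets, genes, min_overlap = 0.5,
                          overlap_denom = "union") {
  if (is.null(genes) || nrow(genes) == 0L) stop("empty gene annotation")
  stopifnot(is.list(region_sets), length(region_sets) >= 1L)
  conditions <- names(region_sets)
  gg <- gr_from_df(genes)
  ## per condition-replicate overlap hits
  hits <- list()
  for (cond in conditions) {
    for (r in seq_along(region_sets[[cond]])) {
      df <- region_sets[[cond]][[r]]
      key <- paste(cond, r, sep = "|")
      if (is.null(df) || nrow(df) == 0L) {
        hits[[key]] <- NULL
        next
      }
      ov <- GenomicRanges::findOverlaps(gr_from_df(df), gg)
      hits[[key]] <- data.frame(
        region = S4Vectors::queryHits(ov), gene = S4Vectors::subjectHits(ov))
    }
  }
  groups <- list()
  for (g in seq_len(nrow(genes))) {
    members <- NULL
    for (cond in conditions) {
      for (r in seq_along(region_sets[[cond]])) {
        key <- paste(cond, r, sep = "|")
        h <- hits[[key]]
        if (is.null(h)) next
        ri <- h$region[h$gene == g]
        if (!length(ri)) next
        df <- region_sets[[cond]][[r]][ri, , drop = FALSE]
        members <- rbind(members, data.frame(
          condition = cond, replicate = r, chrom = df$chrom,
          start = df$start, end = df$end, span_bp = df$end - df$start,
          stringsAsFactors = FALSE))
      }
    }
    if (is.null(members)) next
    ## consistency: at least one condition fully represented with
    ## reciprocal overlap >= min_overlap among replicate representatives
    reps_of <- function(cond) {
      m <- members[members$condition == cond, , drop = FALSE]
      do.call(rbind, lapply(split(m, m$replicate), largest_region))
    }
    consistent_cond <- character(0)
    for (cond in conditions) {
      n_rep <- length(region_sets[[cond]])
      rep_m <- reps_of(cond)
      if (is.null(rep_m) || nrow(rep_m) < n_rep) next
      ok <- TRUE
      for (i in seq_len(nrow(rep_m) - 1L)) for (j in (i + 1L):nrow(rep_m))
        if (span_overlap(rep_m$start[i], rep_m$end[i],
                         rep_m$start[j], rep_m$end[j],
                         overlap_denom) < min_overlap) ok <- FALSE
      if (ok) consistent_cond <- c(consistent_cond, cond)
    }
    if (!length(consistent_cond)) next
    ## outer boundary: members overlapping their condition's mean interval
    contrib <- rep(FALSE, nrow(members))
    for (cond in conditions) {
      rep_m <- reps_of(cond)
      n_rep <- length(region_sets[[cond]])
      if (is.null(rep_m) || nrow(rep_m) < n_rep) next
      ms <- mean(rep_m$start); me <- mean(rep_m$end)
      sel <- members$condition == cond
      contrib[sel] <- members$start[sel] < me & members$end[sel] > ms
    }
    if (!any(contrib)) contrib <- rep(TRUE, nrow(members))
    outer <- list(chrom = members$chrom[1],
                  start = min(members$start[contrib]),
                  end = max(members$end[contrib]))
    ## representative spans per condition-replicate within the outer field
    max_rep <- max(vapply(region_sets, length, integer(1)))
    spans <- matrix(NA_real_, length(conditions), max_rep,
                    dimnames = list(conditions, NULL))
    for (cond in conditions) for (r in seq_along(region_sets[[cond]])) {
      m <- members[members$condition == cond & members$replicate == r &
                     members$start < outer$end & members$end > outer$start, ,
                   drop = FALSE]
      if (nrow(m)) spans[cond, r] <- max(m$span_bp)
    }
    sig <- paste(sort(sprintf("%s|%d|%s:%d-%d", members$condition,
                              members$replicate, members$chrom,
                              members$start, members$end)), collapse = ";")
    if (!is.null(groups[[sig]])) {
      groups[[sig]]$gene_ids <- union(groups[[sig]]$gene_ids, genes$gene_id[g])
    } else {
      groups[[sig]] <- list(gene_ids = genes$gene_id[g], members = members,
                            outer = outer, spans = spans,
                            consistent_conditions = consistent_cond)
    }
  }
  unname(groups)
}

#' Boundary-conserved region subset across three replicates
#'
#' Keeps regions of the first replicate set whose best-matching regions in
#' the other two sets show pairwise reciprocal span overlap of at least
#' `min_overlap` (default 0.75) for all three replicate pairs.
#'
#' @param region_sets List of exactly 3 replicate region data.frames.
#' @param min_overlap Pairwise reciprocal overlap threshold (default 0.75).
#' @param overlap_denom Overlap convention, see [span_overlap].
#' @return Subset of the first set's rows (possibly empty).
#' @export
conserved_subset <- function(region_sets, min_overlap = 0.75,
                             overlap_denom = "union") {
  stopifnot(is.list(region_sets), length(region_sets) == 3L)
  a <- region_sets[[1]]
  if (is.null(a) || nrow(a) == 0L) return(a[0, , drop = FALSE])
  best_match <- function(row, df) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    cand <- df[df$chrom == row$chrom, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    ov <- span_overlap(row$start, row$end, cand$start, cand$end, overlap_denom)
    if (max(ov) <= 0) return(NULL)
    cand[which.max(ov), , drop = FALSE]
  }
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    ra <- a[i, , drop = FALSE]
    rb <- best_match(ra, region_sets[[2]])
    rc <- best_match(ra, region_sets[[3]])
    if (is.null(rb) || is.null(rc)) next
    keep[i] <-
      span_overlap(ra$start, ra$end, rb$start, rb$end, overlap_denom) >= min_overlap &&
      span_overlap(ra$start, ra$end, rc$start, rc$end, overlap_denom) >= min_overlap &&
      span_overlap(rb$start, rb$end, rc$start, rc$end, overlap_denom) >= min_overlap
  }
  a[keep, , drop = FALSE]
}

#' Consistency-filtered span-change call from replicate span estimates
#'
#' Forms all pairwise region-length (RL) ratios between the two sides' span
#' estimates (nine ratios for 3 x 3 replicates, oriented first/second). The
#' group is classed `increase` only when every ratio exceeds
#' `ratio_threshold` and their mean exceeds `mean_threshold`; `decrease` is
#' the symmetric rule applied to the reciprocal ratios; anything else is
#' `none`. Zero-span denominators give infinite ratios (logged).
#'
#' @param spans_a,spans_b Numeric span estimates per replicate for the first
#'   and second condition.
#' @param ratio_threshold All-comparisons filter threshold (default 1).
#' @param mean_threshold Mean-ratio threshold (default 1.5).
#' @param group_id Optional identifier carried through.
#' @return List of class `span_change_call`: `ratios`, `mean_ratio`, `class`,
#'   `group_id` and the thresholds.
#' @export
span_change_call <- function(spans_a, spans_b, ratio_threshold = 1,
                             mean_threshold = 1.5, group_id = NULL) {
  spans_a <- spans_a[!is.na(spans_a)]
  spans_b <- spans_b[!is.na(spans_b)]
  stopifnot(length(spans_a) >= 1L, length(spans_b) >= 1L,
            ratio_threshold >= 1, mean_threshold >= 1)
  if (any(spans_b == 0) || any(spans_a == 0))
    message("zero span estimate: ratio treated as infinite")
  ratios <- as.vector(outer(spans_a, spans_b, "/"))
  recip <- 1 / ratios
  cls <- if (all(ratios > ratio_threshold) && mean(ratios) > mean_threshold)
    "increase"
  else if (all(recip > ratio_threshold) && mean(recip) > mean_threshold)
    "decrease"
  else "none"
  structure(list(group_id = group_id, ratios = ratios,
                 mean_ratio = mean(ratios), class = cls,
                 ratio_threshold = ratio_threshold,
                 mean_threshold = mean_threshold),
            class = "span_change_call")
}

#' @export
print.span_change_call <- function(x, ...) {
  cat(sprintf("<span_change_call> class %s; mean of %d RL ratios = %.3f\n",
              x$class, length(x$ratios), x$mean_ratio))
  invisible(x)
}

#' Span-change call for a matched group
#'
#' Convenience wrapper applying [span_change_call] to the representative
#' spans of two conditions of a [match_regions] group, and attaching the
#' fold-change assignment of [fold_change_assign] computed from the member
#' spans within the outer boundary.
#'
#' @param group A matched group from [match_regions].
#' @param cond_a,cond_b Condition labels (ratio orientation `cond_a/cond_b`).
#' @inheritParams span_change_call
#' @return A `span_change_call` with an additional `fold_change` element.
#' @export
group_span_change <- function(group, cond_a, cond_b, ratio_threshold = 1,
                              mean_threshold = 1.5) {
  call <- span_change_call(group$spans[cond_a, ], group$spans[cond_b, ],
                           ratio_threshold, mean_threshold,
                           group_id = paste(group$gene_ids, collapse = ","))
  in_outer <- function(cond) {
    m <- group$members
    m <- m[m$condition == cond & m$start < group$outer$end &
             m$end > group$outer$start, , drop = FALSE]
    m$span_bp
  }
  call$fold_change <- fold_change_assign(in_outer(cond_a), in_outer(cond_b))
  call
}

#' Fold-change assignment from member spans
#'
#' Computes (a) the ratio of summed member spans per side and (b) the ratio
#' of the largest single member spans within the outer boundary field. A
#' fold change is assigned only when both ratios agree in direction; its
#' magnitude is the largest-region ratio. Disagreement yields no assignment
#' (flagged).
#'
#' @param spans_a,spans_b Member span vectors (bp) for the two sides.
#' @return List: `fold_change` (largest-region ratio, NA when not assigned),
#'   `sum_ratio`, `largest_ratio`, `assigned` (logical).
#' @export
fold_change_assign <- function(spans_a, spans_b) {
  stopifnot(length(spans_a) >= 1L, length(spans_b) >= 1L)
  sum_ratio <- sum(spans_a) / sum(spans_b)
  largest_ratio <- max(spans_a) / max(spans_b)
  agree <- (sum_ratio - 1) * (largest_ratio - 1) >= 0
  list(fold_change = if (agree) largest_ratio else NA_real_,
       sum_ratio = sum_ratio, largest_ratio = largest_ratio,
       assigned = agree)
}
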