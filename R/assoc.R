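#' Link regions to overlapping genes
#'
#' A gene and a region are linked when their intervals intersect by at least
#' one base (0-based half-open; touching intervals do not overlap).
#'
#' @param regions data.frame with `region_id`, `chrom`, `start`, `end`.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return data.frame of links (`region_id`, `gene_id`), one row per
#'   overlapping pair; regions without genes simply contribute no rows (see
#'   [genes_by_region] for an explicit empty-list view).
#' @export
overlap_genes <- function(regions, genes) {
  if (nrow(regions) == 0L || nrow(genes) == 0L)
    return(data.frame(region_id = character(0), gene_id = character(0)))
  ov <- GenomicRanges::findOverlaps(gr_from_df(regions), gr_from_df(genes))
  data.frame(region_id = regions$region_id[S4Vectors::queryHits(ov)],
             gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' Genes linked to each region, including empty sets
#'
#' @param links Links from [overlap_genes].
#' @param regions The region table used to build the links.
#' @return Named list mapping every `region_id` to a (possibly empty)
#'   character vector of gene ids.
#' @export
genes_by_region <- function(links, regions) {
  out <- stats::setNames(vector("list", nrow(regions)), regions$region_id)
  for (id in regions$region_id)
    out[[id]] <- links$gene_id[links$region_id == id]
  out
}

#' Majority expression direction per region
#'
#' Among each region's linked genes that changed significantly
#' (FDR < `fdr_alpha`), counts up- and down-regulated genes and assigns the
#' majority direction: `up`, `down`, `tie` (equal non-zero counts) or `none`
#' (no significant genes).
#'
#' @param links Links from [overlap_genes].
#' @param expression data.frame with `gene_id`, `logfc`, `fdr`.
#' @param fdr_alpha Significance level (default 0.05).
#' @return data.frame `region_id`, `n_up`, `n_down`, `direction`.
#' @export
region_directions <- function(links, expression, fdr_alpha = 0.05) {
  m <- merge(links, expression[, c("gene_id", "logfc", "fdr")], by = "gene_id")
  m$sig_up <- m$fdr < fdr_alpha & m$logfc > 0
  m$sig_down <- m$fdr < fdr_alpha & m$logfc < 0
  ids <- unique(links$region_id)
  up <- tapply(m$sig_up, factor(m$region_id, levels = ids), sum,
               default = 0L)
  down <- tapply(m$sig_down, factor(m$region_id, levels = ids), sum,
                 default = 0L)
  direction <- ifelse(up + down == 0L, "none",
                      ifelse(up > down, "up",
                             ifelse(down > up, "down", "tie")))
  data.frame(region_id = ids, n_up = as.integer(up),
             n_down = as.integer(down), direction = direction,
             stringsAsFactors = FALSE)
}

#' Up:down direction ratio over regions
#'
#' Ratio of the number of regions whose linked significant genes are mostly
#' up-regulated to the number mostly down-regulated; ties and regions with
#' no significant genes are excluded from both counts.
#'
#' @inheritParams region_directions
#' @param region_ids Optional restriction to a subset of regions.
#' @return List: `ratio` (NA with a message when the denominator is zero),
#'   `n_up`, `n_down`.
#' @export
direction_ratio <- function(links, expression, region_ids = NULL,
                            fdr_alpha = 0.05) {
  if (!is.null(region_ids))
    links <- links[links$region_id %in% region_ids, , drop = FALSE]
  d <- region_directions(links, expression, fdr_alpha)
  n_up <- sum(d$direction == "up")
  n_down <- sum(d$direction == "down")
  if (n_down == 0L) {
    message("direction_ratio undefined: no majority-down regions")
    return(list(ratio = NA_real_, n_up = n_up, n_down = n_down))
  }
  list(ratio = n_up / n_down, n_up = n_up, n_down = n_down)
}

#' Expression as a function of overlapping-region span quantiles
#'
#' Genes are assigned the largest span among their overlapping regions and
#' partitioned into overlapping span-quantile windows (0-0.25, 0-0.5,
#' 0.25-0.75, 0.5-1, 0.75-1), with a separate `none` bucket for genes with
#' no region overlap. For each bucket the median assigned span and median
#' logCPM are reported; with span-dependent repression the bucket medians
#' trace the reciprocal span-expression relationship.
#'
#' @param links Links from [overlap_genes].
#' @param regions Region table with `region_id` and `span_bp`.
#' @param expression data.frame with `gene_id` and the `logcpm_col` column.
#' @param logcpm_col Name of the expression column (default `"logcpm"`).
#' @param quantile_windows List of `c(lo, hi)` probability pairs.
#' @return data.frame `bucket`, `median_span`, `median_logcpm`, `n`.
#' @export
span_quantile_curve <- function(links, regions, expression,
                                logcpm_col = "logcpm",
                                quantile_windows = list(
                                  c(0, .25), c(0, .5), c(.25, .75),
                                  c(.5, 1), c(.75, 1))) {
  stopifnot(logcpm_col %in% names(expression))
  m <- merge(links, regions[, c("region_id", "span_bp")], by = "region_id")
  span_by_gene <- tapply(m$span_bp, m$gene_id, max)
  linked <- names(span_by_gene)
  expr_of <- function(ids)
    expression[[logcpm_col]][match(ids, expression$gene_id)]
  rows <- list()
  none_genes <- setdiff(expression$gene_id, linked)
  rows[["none"]] <- data.frame(
    bucket = "none", median_span = NA_real_,
    median_logcpm = stats::median(expr_of(none_genes), na.rm = TRUE),
    n = length(none_genes))
  spans <- as.numeric(span_by_gene)
  for (w in quantile_windows) {
    qs <- stats::quantile(spans, w, na.rm = TRUE)
    sel <- spans >= qs[1] & spans <= qs[2]
    name <- sprintf("q%g-%g", w[1], w[2])
    rows[[name]] <- data.frame(
      bucket = name,
      median_span = stats::median(spans[sel]),
      median_logcpm = stats::median(expr_of(linked[sel]), na.rm = TRUE),
      n = sum(sel))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resampling p-value for a median shift
#'
#' Draws `n_resample` samples of the subset's size with replacement from the
#' population and compares sampled medians to the observed subset median.
#' Both one-sided p-values are reported with the add-one correction, so the
#' attainable floor is 1 / (n_resample + 1) (1e-4 at the default depth).
#'
#' @param subset_values Numeric subset (e.g. logFC of a gene subset).
#' @param population_values Numeric population to resample from.
#' @param n_resample Number of resampling draws (default 10000).
#' @param seed Optional integer seed.
#' @return List: `p_low` (sampled median <= observed), `p_high`,
#'   `observed_median`, `n_resample`.
#' @export
median_shift_pvalue <- function(subset_values, population_values,
                                n_resample = 10000L, seed = NULL) {
  if (length(population_values) == 0L) stop("empty population")
  stopifnot(length(subset_values) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  obs <- stats::median(subset_values)
  m <- length(subset_values)
  meds <- vapply(seq_len(n_resample), function(i)
    stats::median(sample(population_values, m, replace = TRUE)), numeric(1))
  list(p_low = (1 + sum(meds <= obs)) / (n_resample + 1),
       p_high = (1 + sum(meds >= obs)) / (n_resample + 1),
       observed_median = obs, n_resample = n_resample)
}

## place |spans| span-matched intervals uniformly on the genome
place_virtual <- function(chrom_sizes, spans) {
  chroms <- names(chrom_sizes)
  avail <- pmax(as.numeric(chrom_sizes) - 1, 1)
  ci <- sample.int(length(chroms), length(spans), replace = TRUE,
                   prob = avail)
  len <- as.numeric(chrom_sizes)[ci]
  span <- pmin(spans, len)
  start <- floor(stats::runif(length(spans)) * (len - span + 1))
  data.frame(region_id = sprintf("v%d", seq_along(spans)),
             chrom = chroms[ci], start = start, end = start + span,
             stringsAsFactors = FALSE)
}

#' Virtual-region null distribution for the direction ratio
#'
#' Builds the null distribution of the up:down direction ratio from sets of
#' "virtual" genome regions span-matched to the real region set. Each
#' accepted placement must match the real set's gene-clustering level (mean
#' linked genes per gene-overlapping region) within a relative tolerance; in
#' `exclude_pcg` mode virtual regions may not overlap any gene linked to the
#' real set. Significance of the real ratio is assessed by Fisher's exact
#' test on the real vs pooled-null region direction counts.
#'
#' @param chrom_sizes Named chromosome lengths.
#' @param regions Real region table (`region_id`, `chrom`, `start`, `end`).
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param expression Expression table (`gene_id`, `logfc`, `fdr`).
#' @param mode `"unrestricted"` or `"exclude_pcg"`.
#' @param clustering_tol Relative tolerance on the clustering statistic
#'   (default 0.2).
#' @param n_resample Number of accepted virtual placements (default 1000).
#' @param seed Optional integer seed.
#' @param max_tries Maximum rejection attempts per placement (default 100).
#' @param fdr_alpha Significance level for gene direction (default 0.05).
#' @return List of class `virtual_region_null`: `ratios` (length
#'   `n_resample`, NA where a placement had no majority-down region),
#'   `real_ratio`, real and pooled null direction counts, `fisher_p`,
#'   `clustering_target`, `mode`, `n_pcg_overlaps` (accepted virtual-region
#'   links to real-set genes; 0 in exclusion mode) and `last_placement`
#'   (the final accepted placement, for inspection).
#' @export
virtual_region_null <- function(chrom_sizes, regions, genes, expression,
                                mode = c("unrestricted", "exclude_pcg"),
                                clustering_tol = 0.2, n_resample = 1000L,
                                seed = NULL, max_tries = 100L,
                                fdr_alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(nrow(regions) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  links <- overlap_genes(regions, genes)
  real <- direction_ratio(links, expression, fdr_alpha = fdr_alpha)
  cl_stat <- function(lk) {
    if (nrow(lk) == 0L) return(0)
    mean(table(lk$region_id))
  }
  clustering_target <- cl_stat(links)
  pcg_genes <- unique(links$gene_id)
  spans <- regions$end - regions$start
  ratios <- rep(NA_real_, n_resample)
  null_up <- 0L; null_down <- 0L
  n_pcg_overlaps <- 0L
  last_placement <- NULL
  for (it in seq_len(n_resample)) {
    accepted <- FALSE
    for (try in seq_len(max_tries)) {
      vr <- place_virtual(chrom_sizes, spans)
      lk <- overlap_genes(vr, genes)
      if (mode == "exclude_pcg" && length(pcg_genes)) {
        bad <- unique(lk$region_id[lk$gene_id %in% pcg_genes])
        sub_try <- 0L
        while (length(bad) && sub_try < max_tries) {
          redo <- place_virtual(chrom_sizes,
                                spans[match(bad, vr$region_id)])
          redo$region_id <- bad
          vr[match(bad, vr$region_id), ] <- redo
          lk <- overlap_genes(vr, genes)
          bad <- unique(lk$region_id[lk$gene_id %in% pcg_genes])
          sub_try <- sub_try + 1L
        }
        if (length(bad)) next
      }
      cl <- cl_stat(lk)
      if (clustering_target > 0 &&
          abs(cl - clustering_target) > clustering_tol * clustering_target)
        next
      accepted <- TRUE
      break
    }
    if (!accepted)
      stop(sprintf(paste0("could not satisfy clustering target %.2f ",
                          "(tol %.0f%%) within %d tries at iteration %d"),
                   clustering_target, 100 * clustering_tol, max_tries, it))
    n_pcg_overlaps <- n_pcg_overlaps + sum(lk$gene_id %in% pcg_genes)
    last_placement <- vr
    d <- region_directions(lk, expression, fdr_alpha)
    up <- sum(d$direction == "up"); down <- sum(d$direction == "down")
    null_up <- null_up + up; null_down <- null_down + down
    if (down > 0L) ratios[it] <- up / down
  }
  fisher_p <- if (real$n_up + real$n_down > 0L && null_up + null_down > 0L)
    stats::fisher.test(matrix(c(real$n_up, real$n_down,
                                null_up, null_down), 2))$p.value
  else NA_real_
  structure(list(ratios = ratios, real_ratio = real$ratio,
                 real_up = real$n_up, real_down = real$n_down,
                 null_up = null_up, null_down = null_down,
                 fisher_p = fisher_p,
                 clustering_target = clustering_target,
                 clustering_tol = clustering_tol, mode = mode,
                 n_resample = n_resample,
                 n_pcg_overlaps = n_pcg_overlaps,
                 last_placement = last_placement),
            class = "virtual_region_null")
}

#' @export
print.virtual_region_null <- function(x, ...) {
  cat(sprintf("<virtual_region_null> mode %s: real ratio %.3f (%d up / %d down), Fisher p = %.3g\n",
              x$mode, x$real_ratio, x$real_up, x$real_down, x$fisher_p))
  invisible(x)
}

#' Postnatal shift in differentiation-induced activation
#'
#' Restricts to genes activated by differentiation in both newborn and adult
#' cells (`cblogfc > 0` and `adlogfc > 0`) and compares the per-gene
#' postnatal change in activation magnitude (`adlogfc - cblogfc`) between
#' region-linked genes and all genes, by Wilcoxon rank-sum test.
#'
#' @param expression data.frame with `gene_id` and the two contrast columns.
#' @param links Links from [overlap_genes] defining the region-linked subset.
#' @param cb_col,ad_col Column names for the newborn and adult
#'   differentiation logFC (defaults `"cblogfc"`, `"adlogfc"`).
#' @return List: `delta_pcg`, `delta_all` (activation-change vectors),
#'   their medians, `p_value` and subset sizes.
#' @export
activation_shift <- function(expression, links, cb_col = "cblogfc",
                             ad_col = "adlogfc") {
  stopifnot(all(c(cb_col, ad_col) %in% names(expression)))
  e <- expression[expression[[cb_col]] > 0 & expression[[ad_col]] > 0, ,
                  drop = FALSE]
  if (nrow(e) == 0L) stop("no genes with positive logFC in both contrasts")
  delta <- e[[ad_col]] - e[[cb_col]]
  is_pcg <- e$gene_id %in% unique(links$gene_id)
  if (!any(is_pcg)) stop("no region-linked genes in the activated subset")
  p <- stats::wilcox.test(delta[is_pcg], delta)$p.value
  list(delta_pcg = delta[is_pcg], delta_all = delta,
       median_pcg = stats::median(delta[is_pcg]),
       median_all = stats::median(delta),
       p_value = p, n_pcg = sum(is_pcg), n_all = length(delta))
}

#' Quantile- and direction-restricted subset ratio
#'
#' Filters regions by a quantile cutoff on one structural parameter (span,
#' coverage, LCS correlation or LCE correlation), optionally combined with
#' cross-condition inequality constraints, and recomputes the up:down
#' direction ratio over the retained regions. Gene-level significant up/down
#' counts (each gene counted once) feed Fisher's exact test against the
#' all-region gene counts.
#'
#' @param region_values data.frame with `region_id` and numeric parameter
#'   columns.
#' @param links,expression As in [direction_ratio].
#' @param param Name of the parameter column the quantile applies to.
#' @param q Quantile cutoff in (0, 1].
#' @param range `"low"` keeps values below the cutoff; `"high"` above.
#' @param constraint Optional `function(region_values) -> logical` for the
#'   cross-condition inequalities.
#' @param fdr_alpha Significance level (default 0.05).
#' @return List: retained `region_ids`, region-level `ratio`/counts,
#'   gene-level `gene_up`/`gene_down`, `fisher_vs_all_p`, `cutoff`. An empty
#'   subset is reported (`n_regions = 0`) without tests.
#' @export
quantile_subset_ratio <- function(region_values, links, expression, param,
                                  q = 1, range = c("low", "high"),
                                  constraint = NULL, fdr_alpha = 0.05) {
  range <- match.arg(range)
  stopifnot(param %in% names(region_values), q > 0, q <= 1)
  x <- region_values[[param]]
  cutoff <- stats::quantile(x, q, na.rm = TRUE, names = FALSE)
  sel <- if (range == "low") !is.na(x) & x <= cutoff else !is.na(x) & x > cutoff
  if (!is.null(constraint)) sel <- sel & constraint(region_values)
  ids <- region_values$region_id[sel]
  gene_counts <- function(region_ids) {
    lk <- links[links$region_id %in% region_ids, , drop = FALSE]
    e <- expression[match(unique(lk$gene_id), expression$gene_id), ,
                    drop = FALSE]
    sig <- e$fdr < fdr_alpha
    c(up = sum(sig & e$logfc > 0), down = sum(sig & e$logfc < 0))
  }
  if (!length(ids)) {
    message("empty region subset; no test performed")
    return(list(region_ids = character(0), ratio = NA_real_,
                n_up_regions = 0L, n_down_regions = 0L,
                gene_up = 0L, gene_down = 0L,
                fisher_vs_all_p = NA_real_, cutoff = cutoff, n_regions = 0L))
  }
  rr <- direction_ratio(links, expression, region_ids = ids,
                        fdr_alpha = fdr_alpha)
  gsub_ <- gene_counts(ids)
  gall <- gene_counts(unique(links$region_id))
  fisher_p <- if (sum(gsub_) > 0L && sum(gall) > 0L)
    stats::fisher.test(matrix(c(gsub_, gall), 2))$p.value else NA_real_
  list(region_ids = ids, ratio = rr$ratio, n_up_regions = rr$n_up,
       n_down_regions = rr$n_down,
       gene_up = unname(gsub_["up"]), gene_down = unname(gsub_["down"]),
       fisher_vs_all_p = fisher_p, cutoff = cutoff,
       n_regions = length(ids))
}

#' Fisher comparison of two subset ratios
#'
#' Left-vs-right comparison of two [quantile_subset_ratio] results on their
#' gene-level significant up/down counts.
#'
#' @param left,right Results from [quantile_subset_ratio].
#' @return Fisher's exact p-value (NA when either subset is empty).
#' @export
compare_subset_ratios <- function(left, right) {
  if (left$n_regions == 0L || right$n_regions == 0L) return(NA_real_)
  stats::fisher.test(matrix(c(left$gene_up, left$gene_down,
                              right$gene_up, right$gene_down), 2))$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (monotone, capped at 1).
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @return Adjusted values aligned with the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Quantile-binned expression curve with sampling band
#'
#' Bins genes by quantiles of a structural parameter (default quintiles) and
#' reports the median logCPM per bin, together with a null band built from
#' medians of random same-size gene samples (0.05 and 0.005 two-sided
#' envelopes). Bin medians escaping the band indicate a parameter-expression
#' relationship beyond sampling noise.
#'
#' @param param_values Numeric parameter per gene.
#' @param logcpm Expression per gene (same length).
#' @param n_bins Number of quantile bins (default 5).
#' @param n_resample Random samples for the band (default 1000).
#' @param seed Optional integer seed.
#' @param population_logcpm Pool to sample the band from (default `logcpm`).
#' @return List: `curve` (data.frame `bin`, `n`, `param_median`,
#'   `logcpm_median`, `band_lo05`, `band_hi05`, `band_lo005`, `band_hi005`).
#' @export
param_expression_curve <- function(param_values, logcpm, n_bins = 5L,
                                   n_resample = 1000L, seed = NULL,
                                   population_logcpm = logcpm) {
  stopifnot(length(param_values) == length(logcpm),
            length(param_values) >= n_bins, n_bins >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ok <- stats::complete.cases(param_values, logcpm)
  param_values <- param_values[ok]; logcpm <- logcpm[ok]
  br <- stats::quantile(param_values, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(param_values, breaks = unique(br), include.lowest = TRUE,
             labels = FALSE)
  rows <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    m <- sum(sel)
    meds <- vapply(seq_len(n_resample), function(i)
      stats::median(sample(population_logcpm, m, replace = TRUE)),
      numeric(1))
    qs <- stats::quantile(meds, c(.025, .975, .0025, .9975), names = FALSE)
    data.frame(bin = b, n = m,
               param_median = stats::median(param_values[sel]),
               logcpm_median = stats::median(logcpm[sel]),
               band_lo05 = qs[1], band_hi05 = qs[2],
               band_lo005 = qs[3], band_hi005 = qs[4])
  })
  list(curve = do.call(rbind, rows), n_bins = n_bins,
       n_resample = n_resample)
}
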