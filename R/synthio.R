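#' Planted enriched domain specification
#'
#' Describes one broad enriched domain planted on the synthetic genome:
#' its base interval, enrichment over background, and an optional remodeling
#' mode applied in a set of target conditions. Remodeling modes are
#' `span_change` (the interval is rescaled by `factor` about its midpoint),
#' `coverage_change` (enrichment multiplied by `factor`) and
#' `topology_shuffle` (the nucleosome-scale relative-modulation blocks of
#' the expected local rate profile are permuted across the domain,
#' independently per condition, leaving the smooth coverage envelope and
#' hence 2 kb window-sum totals unchanged in expectation).
#'
#' @param chrom Chromosome name.
#' @param start,end Base interval (0-based half-open), at least 2000 bp.
#' @param enrichment Multiplier over background (> 1).
#' @param remodeling One of `"none"`, `"span_change"`, `"coverage_change"`,
#'   `"topology_shuffle"`.
#' @param factor Remodeling factor (span or coverage modes).
#' @param block_bp Shuffle block size in bp (default 200, nucleosome scale).
#' @param conditions Condition labels carrying the remodeling.
#' @return List of class `planted_domain`.
#' @export
planted_domain <- function(chrom, start, end, enrichment = 6,
                           remodeling = c("none", "span_change",
                                          "coverage_change",
                                          "topology_shuffle"),
                           factor = NA_real_, block_bp = 200L,
                           conditions = character(0)) {
  remodeling <- match.arg(remodeling)
  if (end - start < 2000) stop("planted domain must span at least 2000 bp")
  if (enrichment <= 1) stop("enrichment_factor must exceed 1")
  if (block_bp < 100) stop("block_bp must be at least 100")
  if (remodeling %in% c("span_change", "coverage_change") &&
      (is.na(factor) || factor <= 0))
    stop("remodeling mode ", remodeling, " requires a positive factor")
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), enrichment = enrichment,
                 remodeling = remodeling, factor = factor,
                 block_bp = as.integer(block_bp),
                 conditions = as.character(conditions)),
            class = "planted_domain")
}

#' Simulation configuration
#'
#' Generative assumptions of the synthetic data: Poisson background coverage
#' per 100 bp window, independent replicate draws around a shared
#' per-condition rate profile, planted enriched domains with optional
#' remodeling, and a uniform gene annotation. Defaults reflect the study
#' design the generator emulates: 3 replicates in each of six conditions
#' (monocyte/DC x newborn/young/old).
#'
#' @param chrom_sizes Named chromosome lengths (bp, > 0).
#' @param conditions Condition labels.
#' @param n_replicates Replicates per condition (>= 2, default 3).
#' @param background_rate Mean background window sum (Poisson, default 30).
#' @param domains List of [planted_domain] objects; may not overlap on a
#'   chromosome and must lie inside it.
#' @param read_length Read length in bp (default 36).
#' @param n_genes,gene_bp Gene annotation size (default 400 genes of 2 kb).
#' @param topo_sigma_min,topo_sigma Range of the log-sd of the
#'   nucleosome-scale block modulation of the enriched rate profile; each
#'   2 kb tile draws its own contrast level from this range (defaults
#'   0.02-0.6, weighted toward the flat end), so local topology ranges from
#'   nearly flat to strongly structured, as in real enrichment profiles.
#' @param envelope_sigma Log-amplitude of the smooth coverage envelope
#'   shared across conditions (default 0.5); this is the multi-kb intensity
#'   structure that LCS tracks.
#' @param envelope_period_bp Envelope period in bp (default 20000).
#' @param window_bp,step_bp Window geometry (default 100/50).
#' @param keep_rates Store expected rate profiles in the truth (default
#'   FALSE; needed for rate-level conservation checks).
#' @param seed Integer RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes,
                       conditions = c("Mo_Cb", "Mo_Yo", "Mo_Ol",
                                      "DC_Cb", "DC_Yo", "DC_Ol"),
                       n_replicates = 3L, background_rate = 30,
                       domains = list(), read_length = 36L,
                       n_genes = 400L, gene_bp = 2000L,
                       topo_sigma_min = 0.02, topo_sigma = 0.6,
                       envelope_sigma = 0.5, envelope_period_bp = 20000L,
                       window_bp = 100L, step_bp = 50L,
                       keep_rates = FALSE, seed = 1L) {
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes > 0),
            n_replicates >= 2L, background_rate > 0,
            length(conditions) >= 1L)
  by_chrom <- split(domains, vapply(domains, `[[`, character(1), "chrom"))
  for (chrom in names(by_chrom)) {
    if (!chrom %in% names(chrom_sizes))
      stop("domain on unknown chromosome ", chrom)
    dd <- by_chrom[[chrom]]
    s <- vapply(dd, `[[`, numeric(1), "start")
    e <- vapply(dd, `[[`, numeric(1), "end")
    if (any(s < 0) || any(e > chrom_sizes[[chrom]]))
      stop("domain outside chromosome ", chrom)
    o <- order(s)
    if (length(dd) > 1L && any(s[o][-1] < e[o][-length(e)]))
      stop("overlapping planted domains on ", chrom)
  }
  for (d in domains)
    if (length(d$conditions) && !all(d$conditions %in% conditions))
      stop("domain targets unknown condition(s): ",
           paste(setdiff(d$conditions, conditions), collapse = ", "))
  structure(list(chrom_sizes = chrom_sizes, conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 background_rate = background_rate, domains = domains,
                 read_length = as.integer(read_length),
                 n_genes = as.integer(n_genes),
                 gene_bp = as.integer(gene_bp),
                 topo_sigma_min = topo_sigma_min, topo_sigma = topo_sigma,
                 envelope_sigma = envelope_sigma,
                 envelope_period_bp = as.integer(envelope_period_bp),
                 window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 keep_rates = keep_rates, seed = as.integer(seed)),
            class = "sim_config")
}

## condition-specific domain interval (span_change rescales about midpoint)
domain_interval <- function(d, cond, chrom_len) {
  if (d$remodeling == "span_change" && cond %in% d$conditions) {
    mid <- (d$start + d$end) / 2
    half <- (d$end - d$start) / 2 * d$factor
    c(start = max(0, round(mid - half)), end = min(chrom_len, round(mid + half)))
  } else c(start = d$start, end = d$end)
}

## Expected per-window rate profiles per condition, plus ground truth.
## Consumes the RNG stream from config$seed deterministically.
sim_rates <- function(config) {
  set.seed(config$seed)
  wb <- config$window_bp; sb <- config$step_bp
  rates <- lapply(config$conditions, function(cond)
    lapply(config$chrom_sizes, function(L)
      rep(config$background_rate, n_windows(L, wb, sb))))
  names(rates) <- config$conditions
  intervals <- list()
  for (di in seq_along(config$domains)) {
    d <- config$domains[[di]]
    L <- config$chrom_sizes[[d$chrom]]
    ## modulation blocks over the maximal extent, shared across conditions
    exts <- vapply(config$conditions, function(cond)
      domain_interval(d, cond, L), numeric(2))
    ext_start <- min(exts["start", ]); ext_end <- max(exts["end", ])
    nb <- ceiling((ext_end - ext_start) / d$block_bp)
    tile_nb <- max(1L, 2000L %/% d$block_bp)   # blocks per 2 kb tile
    ## per-tile contrast level: local topology ranges from nearly flat
    ## (below the Poisson noise floor) to strongly structured
    n_tiles_tot <- ceiling(nb / tile_nb)
    sig_tile <- config$topo_sigma_min +
      (config$topo_sigma - config$topo_sigma_min) *
      stats::runif(n_tiles_tot)^2
    ## smooth multi-kb coverage envelope, shared across conditions and
    ## untouched by the shuffle: a random-phase sinusoid whose period is
    ## much longer than a segment, so every domain has guaranteed
    ## between-segment intensity structure while the envelope gradient
    ## within any single 2 kb segment stays small
    tile_of <- (seq_len(nb) - 1L) %/% tile_nb + 1L
    phase <- stats::runif(1, 0, 2 * pi)
    blk_mid <- (seq_len(nb) - 0.5) * d$block_bp
    lev_blk <- exp(config$envelope_sigma *
                     sin(2 * pi * blk_mid / config$envelope_period_bp +
                           phase))
    ## relative modulation: mean-1 blocks carrying the fine-scale topology
    m_rel <- stats::rlnorm(nb, meanlog = -sig_tile[tile_of]^2 / 2,
                           sdlog = sig_tile[tile_of])
    for (cond in config$conditions) {
      iv <- domain_interval(d, cond, L)
      m_cond <- lev_blk * m_rel
      if (d$remodeling == "topology_shuffle" && cond %in% d$conditions) {
        ## permute the relative (mean-1) modulation blocks across the
        ## condition interval, independently per condition; the position-
        ## fixed coverage envelope is untouched, so window-sum totals over
        ## any 2 kb span are conserved in expectation while the fine-scale
        ## block arrangement decorrelates between conditions
        blk_s <- ext_start + d$block_bp * (seq_len(nb) - 1L)
        inside <- which(blk_s >= iv["start"] & blk_s + d$block_bp <= iv["end"])
        if (length(inside) >= 2L) {
          m_cond[inside] <- lev_blk[inside] *
            m_rel[inside][sample.int(length(inside))]
        }
      }
      E <- d$enrichment
      if (d$remodeling == "coverage_change" && cond %in% d$conditions)
        E <- E * d$factor
      ws <- window_starts(L, wb, sb)
      idx <- which(ws + wb > iv["start"] & ws < iv["end"])
      if (length(idx)) {
        ov <- (pmin(ws[idx] + wb, iv["end"]) -
                 pmax(ws[idx], iv["start"])) / wb
        bi <- pmin(pmax(floor((ws[idx] + wb / 2 - ext_start) /
                                d$block_bp) + 1, 1), nb)
        rates[[cond]][[d$chrom]][idx] <-
          rates[[cond]][[d$chrom]][idx] * (1 + (E - 1) * ov * m_cond[bi])
      }
      intervals[[length(intervals) + 1L]] <- data.frame(
        domain_id = sprintf("d%03d", di), condition = cond,
        chrom = d$chrom, start = unname(iv["start"]),
        end = unname(iv["end"]), stringsAsFactors = FALSE)
    }
  }
  domains_df <- if (length(config$domains)) do.call(rbind, lapply(
    seq_along(config$domains), function(di) {
      d <- config$domains[[di]]
      data.frame(domain_id = sprintf("d%03d", di), chrom = d$chrom,
                 start = d$start, end = d$end, enrichment = d$enrichment,
                 remodeling = d$remodeling, factor = d$factor,
                 block_bp = d$block_bp,
                 target_conditions = paste(d$conditions, collapse = ","),
                 stringsAsFactors = FALSE)
    })) else data.frame()
  list(rates = rates,
       domains = domains_df,
       domain_intervals = if (length(intervals)) do.call(rbind, intervals)
       else data.frame())
}

#' Simulate replicate coverage tracks with planted domains
#'
#' Draws each replicate's window sums as independent Poisson variates around
#' a shared per-condition expected rate profile: uniform background,
#' multiplied inside planted domains by the enrichment factor and a
#' nucleosome-scale block modulation (shared across conditions unless
#' shuffled). Deterministic given the config seed.
#'
#' @param config A [sim_config].
#' @return List with `groups` (named list condition -> [replicate_group]),
#'   `truth` (planted domain table, per-condition intervals, gene table,
#'   seed; expected rate profiles when `keep_rates`).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sr <- sim_rates(config)
  groups <- list()
  for (cond in config$conditions) {
    tracks <- lapply(seq_len(config$n_replicates), function(r) {
      values <- lapply(sr$rates[[cond]], function(lam)
        as.numeric(stats::rpois(length(lam), lam)))
      binned_track(values, config$chrom_sizes, config$window_bp,
                   config$step_bp, config$read_length)
    })
    groups[[cond]] <- replicate_group(tracks, cond)
  }
  genes <- simulate_genes(config)
  truth <- list(domains = sr$domains,
                domain_intervals = sr$domain_intervals,
                genes = genes, seed = config$seed)
  if (isTRUE(config$keep_rates)) truth$rates <- sr$rates
  list(groups = groups, truth = truth)
}

## uniform gene placement (continues the RNG stream of simulate_tracks)
simulate_genes <- function(config) {
  n <- config$n_genes
  if (n == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  chroms <- names(config$chrom_sizes)
  L <- as.numeric(config$chrom_sizes)
  ci <- sample.int(length(chroms), n, replace = TRUE, prob = L)
  start <- floor(stats::runif(n) * pmax(L[ci] - config$gene_bp, 1))
  data.frame(gene_id = sprintf("g%04d", seq_len(n)), chrom = chroms[ci],
             start = start, end = start + config$gene_bp,
             stringsAsFactors = FALSE)
}

#' Expression effect model for the synthetic generator
#'
#' Mean logFC by planted remodeling class, noise level, span-dependent
#' repression of baseline logCPM, and the domain-linked shift in
#' differentiation-induced activation. `noise_sd` doubles as the standard
#' error used to turn logFC into p-values, so the null z-scores are standard
#' normal.
#'
#' @param logfc_span_increase,logfc_span_decrease,logfc_coverage_increase,logfc_shuffle
#'   Mean logFC for genes overlapping domains of each remodeling class.
#' @param noise_sd Per-gene logFC noise sd (default 0.3).
#' @param baseline_logcpm,baseline_sd Baseline expression (default 4, sd 2).
#' @param span_repression_per_kb logCPM lost per kb of overlapping domain
#'   span (default 0.37, reproducing >50-fold repression near 15 kb spans).
#' @param activation_shift Extra postnatal activation for domain-linked
#'   genes (default 1).
#' @param fdr_alpha Significance level for the FDR flag (default 0.05).
#' @return List of class `expression_effects`.
#' @export
expression_effects <- function(logfc_span_increase = -2,
                               logfc_span_decrease = 2,
                               logfc_coverage_increase = -1,
                               logfc_shuffle = -1,
                               noise_sd = 0.3,
                               baseline_logcpm = 4, baseline_sd = 2,
                               span_repression_per_kb = 0.37,
                               activation_shift = 1, fdr_alpha = 0.05) {
  structure(list(logfc_span_increase = logfc_span_increase,
                 logfc_span_decrease = logfc_span_decrease,
                 logfc_coverage_increase = logfc_coverage_increase,
                 logfc_shuffle = logfc_shuffle, noise_sd = noise_sd,
                 baseline_logcpm = baseline_logcpm, baseline_sd = baseline_sd,
                 span_repression_per_kb = span_repression_per_kb,
                 activation_shift = activation_shift,
                 fdr_alpha = fdr_alpha),
            class = "expression_effects")
}

#' Simulate a paired expression table with known ground truth
#'
#' Genes overlapping span-increase domains receive negative postnatal logFC
#' on average (and symmetrically for the other remodeling classes); baseline
#' logCPM decreases with the span of the overlapping domain; p-values come
#' from standard-normal z-scores of the noisy logFC and are FDR-adjusted via
#' [bh_fdr]. Deterministic given `seed`.
#'
#' @param truth Truth list from [simulate_tracks] (needs `domains`, `genes`).
#' @param effect An [expression_effects] model.
#' @param seed Integer seed (default: the truth's seed + 1).
#' @return data.frame with `gene_id`, `logcpm`, `logfc`, `pvalue`, `fdr`,
#'   `significant`, `cblogfc`, `adlogfc`, plus ground-truth columns
#'   `true_class` (up/down/null) and `true_logfc`.
#' @export
simulate_expression <- function(truth, effect = expression_effects(),
                                seed = NULL) {
  genes <- truth$genes
  if (is.null(genes) || nrow(genes) == 0L) stop("empty gene table")
  if (is.null(seed)) seed <- truth$seed + 1L
  set.seed(seed)
  dm <- truth$domains
  true_logfc <- numeric(nrow(genes))
  span_kb <- numeric(nrow(genes))
  if (!is.null(dm) && nrow(dm)) {
    dm$region_id <- dm$domain_id
    lk <- overlap_genes(dm, genes)
    for (i in seq_len(nrow(genes))) {
      dids <- lk$region_id[lk$gene_id == genes$gene_id[i]]
      if (!length(dids)) next
      dsub <- dm[dm$domain_id %in% dids, , drop = FALSE]
      span_kb[i] <- max(dsub$end - dsub$start) / 1000
      eff <- 0
      for (j in seq_len(nrow(dsub))) {
        eff <- eff + switch(
          dsub$remodeling[j],
          span_change = if (!is.na(dsub$factor[j]) && dsub$factor[j] > 1)
            effect$logfc_span_increase else effect$logfc_span_decrease,
          coverage_change = effect$logfc_coverage_increase,
          topology_shuffle = effect$logfc_shuffle,
          0)
      }
      true_logfc[i] <- eff
    }
  }
  n <- nrow(genes)
  logfc <- true_logfc + stats::rnorm(n, 0, effect$noise_sd)
  z <- logfc / effect$noise_sd
  pvalue <- 2 * stats::pnorm(-abs(z))
  fdr <- bh_fdr(pvalue)
  logcpm <- stats::rnorm(n, effect$baseline_logcpm, effect$baseline_sd) -
    effect$span_repression_per_kb * span_kb
  is_linked <- span_kb > 0
  cblogfc <- stats::rnorm(n, 0.5, 1)
  adlogfc <- cblogfc + stats::rnorm(n, 0, 0.3) +
    effect$activation_shift * is_linked
  data.frame(gene_id = genes$gene_id, logcpm = logcpm, logfc = logfc,
             pvalue = pvalue, fdr = fdr,
             significant = fdr < effect$fdr_alpha,
             cblogfc = cblogfc, adlogfc = adlogfc,
             true_class = ifelse(true_logfc > 0, "up",
                                 ifelse(true_logfc < 0, "down", "null")),
             true_logfc = true_logfc, stringsAsFactors = FALSE)
}

#' Simulate read placements whose pileup reproduces the rate profiles
#'
#' Optional reads mode: emits fixed-length read intervals with per-cell
#' Poisson counts calibrated so that [pileup_reads] recovers the expected
#' window-sum rates (a window sum of lambda corresponds to a read-start
#' density of lambda / (read_length x window_bp) per bp).
#'
#' @param config A [sim_config].
#' @param condition,replicate Which track to emit reads for.
#' @return data.frame of reads (`chrom`, `start`, `end`), 0-based half-open.
#' @export
simulate_reads <- function(config, condition = config$conditions[1],
                           replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  sr <- sim_rates(config)
  ## advance the stream deterministically per condition/replicate
  set.seed(config$seed + 7919L * match(condition, config$conditions) +
             104729L * as.integer(replicate))
  rl <- config$read_length; wb <- config$window_bp
  out <- list()
  for (chrom in names(config$chrom_sizes)) {
    L <- config$chrom_sizes[[chrom]]
    lam <- sr$rates[[condition]][[chrom]]
    ## non-overlapping 100 bp cells from even window indices
    cell_idx <- seq(1L, length(lam), by = wb %/% config$step_bp)
    cell_start <- (cell_idx - 1L) * config$step_bp
    n_reads <- stats::rpois(length(cell_idx), lam[cell_idx] * wb / (rl * wb))
    if (sum(n_reads) == 0L) next
    starts <- unlist(lapply(seq_along(cell_idx), function(i) {
      if (n_reads[i] == 0L) return(numeric(0))
      cell_start[i] + floor(stats::runif(n_reads[i]) * wb)
    }))
    starts <- pmin(starts, L - rl)
    out[[chrom]] <- data.frame(chrom = chrom, start = starts,
                               end = starts + rl, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  rownames(res) <- NULL
  res
}

#' Random non-overlapping planted domains
#'
#' Draws domain spans from a log-normal distribution (median span 10 kb by
#' default, capped at 178 kb as in large Polycomb domains) and places them
#' without overlap by distributing the free sequence between consecutive
#' domains uniformly.
#'
#' @param chrom_sizes Named chromosome lengths.
#' @param n Number of domains.
#' @param median_span,span_sigma Log-normal span distribution (default
#'   median 10000, sigma 0.6).
#' @param min_span,max_span Span bounds (default 2000 / 178000).
#' @param enrichment,remodeling,factor,block_bp,conditions Passed to
#'   [planted_domain].
#' @return List of [planted_domain] objects (uses the current RNG stream).
#' @export
random_domains <- function(chrom_sizes, n, median_span = 10000,
                           span_sigma = 0.6, min_span = 2000,
                           max_span = 178000, enrichment = 6,
                           remodeling = "none", factor = NA_real_,
                           block_bp = 200L, conditions = character(0)) {
  spans <- pmin(pmax(round(stats::rlnorm(n, log(median_span), span_sigma)),
                     min_span), max_span)
  chroms <- names(chrom_sizes)
  ci <- sample.int(length(chroms), n, replace = TRUE,
                   prob = as.numeric(chrom_sizes))
  out <- list()
  for (k in seq_along(chroms)) {
    sp <- spans[ci == k]
    if (!length(sp)) next
    L <- chrom_sizes[[k]]
    free <- L - sum(sp)
    if (free <= length(sp)) stop("domains do not fit on ", chroms[k])
    gaps <- diff(c(0, sort(stats::runif(length(sp))))) * free
    pos <- cumsum(gaps) + cumsum(c(0, sp[-length(sp)]))
    for (i in seq_along(sp))
      out[[length(out) + 1L]] <- planted_domain(
        chroms[k], floor(pos[i]), floor(pos[i]) + sp[i],
        enrichment = enrichment, remodeling = remodeling, factor = factor,
        block_bp = block_bp, conditions = conditions)
  }
  out
}
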