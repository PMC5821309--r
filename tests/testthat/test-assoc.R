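expr_table <- function(gene_id, logfc, fdr, logcpm = 0) {
  data.frame(gene_id = gene_id, logfc = logfc, fdr = fdr, logcpm = logcpm,
             significant = fdr < 0.05, stringsAsFactors = FALSE)
}

test_that("gene-region overlap follows the half-open convention", {
  regions <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                        start = c(7000, 50000), end = c(30000, 60000))
  genes <- data.frame(gene_id = c("in", "touch", "far"), chrom = "chr1",
                      start = c(5000, 5000, 90000),
                      end = c(8000, 7000, 92000))
  lk <- overlap_genes(regions, genes)
  expect_equal(lk$gene_id[lk$region_id == "r1"], "in")
  expect_false("touch" %in% lk$gene_id)    # [5k,7k) vs [7k,30k): empty
  gbr <- genes_by_region(lk, regions)
  expect_equal(gbr$r2, character(0))       # region with no genes
})

test_that("direction ratio counts majority regions, excluding ties", {
  links <- data.frame(region_id = rep(sprintf("r%d", 1:11), each = 1),
                      gene_id = sprintf("g%d", 1:11))
  e <- expr_table(sprintf("g%d", 1:11),
                  logfc = c(rep(1, 2), rep(-1, 8), 1),
                  fdr = c(rep(0.01, 10), 0.5))
  dr <- direction_ratio(links, e)
  expect_equal(dr$ratio, 2 / 8)
  expect_equal(dr$n_up, 2L)

  # all ties -> undefined
  links2 <- data.frame(region_id = rep("r1", 2), gene_id = c("a", "b"))
  e2 <- expr_table(c("a", "b"), c(1, -1), c(0.01, 0.01))
  expect_message(dr2 <- direction_ratio(links2, e2), "undefined")
  expect_true(is.na(dr2$ratio))
})

test_that("direction ratio agrees with brute-force recounts on fuzz tables", {
  set.seed(51)
  for (rep in 1:25) {
    n_reg <- sample(5:20, 1); n_gene <- sample(10:60, 1)
    links <- data.frame(
      region_id = sprintf("r%d", sample(n_reg, n_gene, replace = TRUE)),
      gene_id = sprintf("g%d", seq_len(n_gene)))
    e <- expr_table(sprintf("g%d", seq_len(n_gene)),
                    logfc = rnorm(n_gene),
                    fdr = runif(n_gene, 0, 0.2))
    got <- direction_ratio(links, e)
    # independent recount with plain loops
    up <- 0L; down <- 0L
    for (r in unique(links$region_id)) {
      gs <- links$gene_id[links$region_id == r]
      ee <- e[e$gene_id %in% gs & e$fdr < 0.05, ]
      nu <- sum(ee$logfc > 0); nd <- sum(ee$logfc < 0)
      if (nu + nd == 0) next
      if (nu > nd) up <- up + 1L else if (nd > nu) down <- down + 1L
    }
    expect_equal(got$n_up, up)
    expect_equal(got$n_down, down)
  }
})

test_that("span quantile curve recovers monotone span-dependent repression", {
  set.seed(52)
  n <- 200
  spans <- sort(rlnorm(n, log(10000), 0.8))
  regions <- data.frame(region_id = sprintf("r%d", 1:n), chrom = "chr1",
                        start = cumsum(spans + 5000) - spans,
                        end = cumsum(spans + 5000))
  regions$span_bp <- regions$end - regions$start
  genes <- data.frame(gene_id = sprintf("g%d", 1:(n + 50)), chrom = "chr1",
                      start = c(regions$start + 100, 1e9 + (1:50) * 1e4),
                      end = c(regions$start + 1100, 1e9 + (1:50) * 1e4 + 2000))
  expr <- data.frame(gene_id = genes$gene_id,
                     logcpm = c(8 - regions$span_bp / 2000, rep(8, 50)) +
                       rnorm(n + 50, 0, 0.1))
  lk <- overlap_genes(regions, genes)
  curve <- span_quantile_curve(lk, regions, expr)
  expect_equal(curve$bucket[1], "none")
  expect_equal(curve$n[1], 50L)
  med <- curve$median_logcpm[-1]
  sp <- curve$median_span[-1]
  expect_true(all(diff(med[order(sp)]) < 0))  # repression grows with span
  # order statistics: q0-0.5 median span between q0-0.25 and q0.25-0.75
  expect_gte(curve$median_span[curve$bucket == "q0-0.5"],
             curve$median_span[curve$bucket == "q0-0.25"])
  expect_lte(curve$median_span[curve$bucket == "q0-0.5"],
             curve$median_span[curve$bucket == "q0.25-0.75"])
})

test_that("median shift p-values are calibrated, floored and monotone", {
  set.seed(53)
  pop <- rnorm(2000)
  res <- median_shift_pvalue(pop, pop, n_resample = 2000, seed = 1)
  expect_gt(res$p_low, 0.45); expect_lt(res$p_low, 0.55)
  expect_gt(res$p_high, 0.45); expect_lt(res$p_high, 0.55)

  # extreme subset hits the resampling floor 1/(n+1)
  extreme <- median_shift_pvalue(max(pop) + 1:5, pop,
                                 n_resample = 10000, seed = 2)
  expect_equal(extreme$p_high, 1 / 10001)

  # p_high non-increasing as the subset median moves tail-ward
  ps <- vapply(c(0, 0.5, 1, 2), function(shift)
    median_shift_pvalue(rnorm(50, shift), pop, n_resample = 1000,
                        seed = 3)$p_high, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(median_shift_pvalue(1, numeric(0)), "empty population")
})

test_that("activation shift recovers a planted domain-linked gain", {
  set.seed(54)
  n <- 600
  e <- data.frame(gene_id = sprintf("g%d", 1:n),
                  cblogfc = rnorm(n, 1, 0.5))
  is_pcg <- seq_len(n) <= 150
  e$adlogfc <- e$cblogfc + rnorm(n, 0, 0.2) + ifelse(is_pcg, 1, 0)
  links <- data.frame(region_id = "r1", gene_id = e$gene_id[is_pcg])
  res <- activation_shift(e, links)
  expect_equal(res$median_pcg - res$median_all, 1, tolerance = 0.2)
  expect_lt(res$p_value, 1e-6)
  # the both-positive filter excludes genes with cblogfc <= 0
  e2 <- e; e2$cblogfc[1] <- -1
  res2 <- activation_shift(e2, links)
  expect_equal(res2$n_all, sum(e2$cblogfc > 0 & e2$adlogfc > 0))
})

test_that("activation shift p-values are roughly uniform under the null", {
  set.seed(55)
  ps <- vapply(1:20, function(i) {
    n <- 400
    e <- data.frame(gene_id = sprintf("g%d", 1:n),
                    cblogfc = rnorm(n, 1, 0.5))
    e$adlogfc <- e$cblogfc + rnorm(n, 0, 0.2)
    links <- data.frame(region_id = "r1",
                        gene_id = sample(e$gene_id, 100))
    activation_shift(e, links)$p_value
  }, numeric(1))
  # loose Kolmogorov-style check: no pile-up of small p-values
  expect_lte(mean(ps < 0.05), 0.2)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("quantile subset with degenerate filter reproduces the global ratio", {
  set.seed(56)
  n_reg <- 40
  rv <- data.frame(region_id = sprintf("r%d", 1:n_reg),
                   span = rlnorm(n_reg, log(10000), 0.5))
  links <- data.frame(region_id = rep(rv$region_id, each = 2),
                      gene_id = sprintf("g%d", 1:(2 * n_reg)))
  e <- expr_table(sprintf("g%d", 1:(2 * n_reg)),
                  logfc = rnorm(2 * n_reg),
                  fdr = runif(2 * n_reg, 0, 0.1))
  all_ratio <- direction_ratio(links, e)
  qs <- quantile_subset_ratio(rv, links, e, param = "span", q = 1,
                              range = "low")
  expect_equal(qs$ratio, all_ratio$ratio)
  expect_equal(qs$n_regions, n_reg)
})

test_that("quantile subset filtering matches brute-force row filters", {
  set.seed(57)
  for (rep in 1:20) {
    n_reg <- sample(20:60, 1)
    rv <- data.frame(region_id = sprintf("r%d", 1:n_reg),
                     span_cb = rlnorm(n_reg, log(10000), 0.5),
                     span_yo = rlnorm(n_reg, log(10000), 0.5))
    links <- data.frame(region_id = sample(rv$region_id, 2 * n_reg,
                                           replace = TRUE),
                        gene_id = sprintf("g%d", 1:(2 * n_reg)))
    e <- expr_table(sprintf("g%d", 1:(2 * n_reg)),
                    logfc = rnorm(2 * n_reg), fdr = runif(2 * n_reg, 0, 0.1))
    q <- runif(1, 0.3, 0.9)
    con <- function(df) df$span_cb < df$span_yo
    got <- quantile_subset_ratio(rv, links, e, param = "span_cb", q = q,
                                 range = "low", constraint = con)
    cutoff <- quantile(rv$span_cb, q, names = FALSE)
    manual <- rv$region_id[rv$span_cb <= cutoff & rv$span_cb < rv$span_yo]
    expect_setequal(got$region_ids, manual)
  }
})

test_that("planted low-parameter down-bias separates left and right subsets", {
  set.seed(58)
  n_reg <- 240
  rv <- data.frame(region_id = sprintf("r%d", 1:n_reg),
                   lce_corr = runif(n_reg))
  links <- data.frame(region_id = rv$region_id,
                      gene_id = sprintf("g%d", 1:n_reg))
  p_down <- ifelse(rv$lce_corr < 0.5, 0.85, 0.5)
  e <- expr_table(sprintf("g%d", 1:n_reg),
                  logfc = ifelse(runif(n_reg) < p_down, -1, 1),
                  fdr = 0.01)
  left <- quantile_subset_ratio(rv, links, e, "lce_corr", q = 0.5, "low")
  right <- quantile_subset_ratio(rv, links, e, "lce_corr", q = 0.5, "high")
  expect_lt(left$ratio, right$ratio)
  expect_lt(compare_subset_ratios(left, right), 0.05)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # step-up arithmetic: m*p/i with cumulative minimum from the largest p
  expect_equal(bh_fdr(c(0.001, 0.01, 0.9, 0.04)),
               c(0.001 * 4 / 1, 0.01 * 4 / 2, 0.9, 0.04 * 4 / 3))
  # order invariance after realignment
  p <- c(0.3, 0.001, 0.2, 0.02, 0.6)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH rejections form a prefix of the sorted p-values", {
  set.seed(59)
  for (rep in 1:20) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    fdr <- bh_fdr(p)
    o <- order(p)
    expect_true(all(diff(fdr[o]) >= -1e-12))
    rejected <- fdr[o] < 0.05
    if (any(rejected))
      expect_true(all(rejected[seq_len(max(which(rejected)))]))
  }
})

test_that("parameter-expression curve finds construction and respects bins", {
  set.seed(60)
  n <- 300
  logcpm <- rnorm(n, 4, 2)
  par_neg <- -logcpm + rnorm(n, 0, 0.01)
  res <- param_expression_curve(par_neg, logcpm, n_bins = 5,
                                n_resample = 300, seed = 1)
  expect_true(all(diff(res$curve$logcpm_median) < 0))
  # single bin collapses to the overall median
  one <- param_expression_curve(par_neg, logcpm, n_bins = 1,
                                n_resample = 50, seed = 1)
  expect_equal(one$curve$logcpm_median, median(logcpm))
  expect_equal(one$curve$n, n)
})

test_that("independent parameters stay inside the sampling band", {
  set.seed(61)
  inside <- vapply(1:10, function(i) {
    n <- 250
    logcpm <- rnorm(n, 4, 2)
    par_ind <- rnorm(n)
    res <- param_expression_curve(par_ind, logcpm, n_bins = 5,
                                  n_resample = 400, seed = i)
    with(res$curve, all(logcpm_median >= band_lo05 &
                          logcpm_median <= band_hi05))
  }, logical(1))
  expect_gte(mean(inside), 0.6)
})
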