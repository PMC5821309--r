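small_config <- function(seed = 7, ...) {
  cs <- c(chr1 = 3e5, chr2 = 2e5)
  doms <- list(planted_domain("chr1", 50000, 70000),
               planted_domain("chr2", 20000, 32000,
                              remodeling = "topology_shuffle",
                              conditions = "Yo"))
  sim_config(cs, conditions = c("Cb", "Yo"), domains = doms,
             n_genes = 30, seed = seed, ...)
}

test_that("identical seeds give byte-identical bundles", {
  b1 <- simulate_tracks(small_config())
  b2 <- simulate_tracks(small_config())
  expect_identical(b1, b2)
  e1 <- simulate_expression(b1$truth)
  e2 <- simulate_expression(b2$truth)
  expect_identical(e1, e2)
  # a different seed changes the draws
  b3 <- simulate_tracks(small_config(seed = 8))
  expect_false(identical(b1$groups, b3$groups))
})

test_that("background-only tracks follow the Poisson exceedance prediction", {
  cfg <- sim_config(c(chr1 = 5.1e6), conditions = "Cb", n_genes = 5,
                    seed = 13)
  b <- simulate_tracks(cfg)
  cv <- enrichment_curve(b$groups$Cb$tracks[[1]])
  expect_equal(cv$lambda, 30, tolerance = 0.01)
  sub <- cv$curve[cv$curve$threshold <= 30 + 4 * sqrt(30), ]
  dev <- abs(sub$observed - sub$expected)
  ok <- dev / pmax(sub$expected, 1) < 0.10 | dev < 4 * sqrt(sub$expected)
  expect_true(all(ok))
  # and no crossing is found: threshold falls back to the cap
  expect_warning(th <- poisson_threshold(cv, floor = 47, cap = 50), "cap")
  expect_false(th$crossed)
})

test_that("invalid domain layouts are rejected", {
  cs <- c(chr1 = 1e5)
  overlapping <- list(planted_domain("chr1", 1000, 11000),
                      planted_domain("chr1", 9000, 20000))
  expect_error(sim_config(cs, domains = overlapping), "overlapping")
  outside <- list(planted_domain("chr1", 90000, 120000))
  expect_error(sim_config(cs, domains = outside), "outside")
  expect_error(planted_domain("chr1", 0, 1500), "2000")
  expect_error(planted_domain("chr1", 0, 5000, enrichment = 1), "exceed 1")
  expect_error(planted_domain("chr1", 0, 5000, block_bp = 50), "100")
  expect_error(planted_domain("chr1", 0, 5000, remodeling = "span_change"),
               "factor")
})

test_that("shuffle conserves expected domain coverage across conditions", {
  cfg <- small_config(keep_rates = TRUE)
  b <- simulate_tracks(cfg)
  r <- b$truth$rates
  d <- cfg$domains[[2]]  # the shuffled domain on chr2
  ws <- window_starts(2e5)
  idx <- which(ws >= d$start & ws + 100 <= d$end)
  tot_cb <- sum(r$Cb$chr2[idx])
  tot_yo <- sum(r$Yo$chr2[idx])
  # totals agree in expectation; per-domain deviation is block-sampling
  # noise, small relative to the domain total
  expect_lt(abs(tot_yo - tot_cb) / tot_cb, 0.15)
  # the fine-scale profiles themselves differ between conditions
  expect_gt(max(abs(r$Yo$chr2[idx] - r$Cb$chr2[idx])), 1)
  # outside domains the conditions share the flat background exactly
  out_idx <- which(ws + 100 <= d$start)
  expect_identical(r$Cb$chr2[out_idx], r$Yo$chr2[out_idx])
})

test_that("expected shuffle conservation is unbiased across many domains", {
  set.seed(71)
  cs <- c(chr1 = 6e6)
  doms <- random_domains(cs, 40, median_span = 10000, span_sigma = 0.3,
                         remodeling = "topology_shuffle",
                         conditions = "Yo")
  cfg <- sim_config(cs, conditions = c("Cb", "Yo"), domains = doms,
                    n_genes = 5, keep_rates = TRUE, seed = 72)
  b <- simulate_tracks(cfg)
  ws <- window_starts(6e6)
  rel <- vapply(doms, function(d) {
    idx <- which(ws >= d$start & ws + 100 <= d$end)
    (sum(b$truth$rates$Yo$chr1[idx]) - sum(b$truth$rates$Cb$chr1[idx])) /
      sum(b$truth$rates$Cb$chr1[idx])
  }, numeric(1))
  expect_lt(abs(mean(rel)), 0.05)
  expect_lt(max(abs(rel)), 0.3)
})

test_that("null effect model keeps the FDR-positive fraction near zero", {
  null_eff <- expression_effects(logfc_span_increase = 0,
                                 logfc_span_decrease = 0,
                                 logfc_coverage_increase = 0,
                                 logfc_shuffle = 0)
  fracs <- vapply(1:10, function(i) {
    b <- simulate_tracks(small_config(seed = 100 + i))
    e <- simulate_expression(b$truth, null_eff)
    mean(e$significant)
  }, numeric(1))
  expect_lt(mean(fracs), 0.01)
})

test_that("a planted -2 logFC effect is recovered by the affected genes", {
  cs <- c(chr1 = 1e6)
  doms <- list(planted_domain("chr1", 100000, 600000,
                              remodeling = "span_change", factor = 2,
                              conditions = "Yo"))
  cfg <- sim_config(cs, conditions = c("Cb", "Yo"), domains = doms,
                    n_genes = 450, seed = 77)
  b <- simulate_tracks(cfg)
  e <- simulate_expression(b$truth)
  down <- e[e$true_class == "down", ]
  expect_gte(nrow(down), 200)
  expect_equal(median(down$logfc), -2, tolerance = 0.3)
  expect_error(simulate_expression(list(genes = NULL, seed = 1)),
               "empty gene table")
})

test_that("span change rescales the target-condition interval only", {
  cs <- c(chr1 = 1e6)
  doms <- list(planted_domain("chr1", 400000, 420000,
                              remodeling = "span_change", factor = 0.5,
                              conditions = "Yo"))
  cfg <- sim_config(cs, conditions = c("Cb", "Yo"), domains = doms,
                    n_genes = 5, seed = 78)
  b <- simulate_tracks(cfg)
  iv <- b$truth$domain_intervals
  cb <- iv[iv$condition == "Cb", ]
  yo <- iv[iv$condition == "Yo", ]
  expect_equal(cb$end - cb$start, 20000)
  expect_equal(yo$end - yo$start, 10000)
  expect_equal((cb$start + cb$end) / 2, (yo$start + yo$end) / 2)
})

test_that("simulated reads pile up to the configured background rate", {
  cfg <- sim_config(c(chr1 = 5.1e6), conditions = "Cb", n_genes = 5,
                    seed = 14)
  reads <- simulate_reads(cfg)
  tr <- pileup_reads(reads, cfg$chrom_sizes)
  # total window-sum mass per bp = 2 * read_length * reads-per-bp,
  # where reads-per-bp = background_rate / (read_length * window_bp)
  rho <- 30 / (36 * 100)
  got <- sum(unlist(tr$values)) / 5.1e6
  expect_equal(got, 2 * 36 * rho, tolerance = 0.01)
})

test_that("fixtures round-trip losslessly through the text readers", {
  b <- simulate_tracks(small_config())
  b$expression <- simulate_expression(b$truth)
  dir <- file.path(tempdir(), "fixture-rt")
  write_fixture(b, dir, config = small_config())
  back <- read_fixture(dir)
  for (cond in names(b$groups))
    for (r in 1:3)
      expect_equal(back$groups[[cond]]$tracks[[r]]$values,
                   b$groups[[cond]]$tracks[[r]]$values)
  expect_equal(back$truth$genes$gene_id, b$truth$genes$gene_id)
  expect_equal(back$truth$genes$start, b$truth$genes$start)
  expect_equal(back$truth$domains$start, b$truth$domains$start)
  expect_equal(back$expression$logfc, b$expression$logfc, tolerance = 1e-9)
  expect_equal(back$expression$significant, b$expression$significant)
  # truth JSON carries the required fields
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_true(all(c("domains", "domain_intervals", "seed") %in% names(tj)))
  unlink(dir, recursive = TRUE)
})
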