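regset <- function(...) {
  # data.frame of regions from start,end pairs
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(chrom = "chr1", start = m[, 1], end = m[, 2])
}

test_that("identical region sets self-match with the region as outer boundary", {
  rs <- regset(1000, 21000, 50000, 60000)
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(5000, 52000), end = c(7000, 54000))
  sets <- list(Mo = list(rs, rs, rs), DC = list(rs, rs, rs))
  groups <- match_regions(sets, genes)
  expect_length(groups, 2L)
  g1 <- groups[[which(vapply(groups, function(g) "gA" %in% g$gene_ids,
                             logical(1)))]]
  expect_equal(g1$outer$start, 1000)
  expect_equal(g1$outer$end, 21000)
  expect_true(all(g1$spans == 20000))
})

test_that("regions with 40% reciprocal overlap are not grouped at 0.5", {
  a <- regset(0, 10000)
  b <- regset(7500, 17500)   # intersection 2500 / union 17500 = 0.14
  c_ <- regset(4000, 14000)  # vs a: 6000/14000 = 0.43 < 0.5
  genes <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = 8000, end = 9000)
  expect_length(match_regions(list(Mo = list(a, c_)), genes), 0L)
  expect_length(match_regions(list(Mo = list(a, b)), genes), 0L)
  # and grouped when overlap is sufficient
  d <- regset(1000, 11000)   # vs a: 9000/11000 = 0.82
  expect_length(match_regions(list(Mo = list(a, d)), genes), 1L)
})

test_that("nested span change yields one group with the 20 kb outer extent", {
  big <- regset(10000, 30000)
  small <- regset(15000, 25000)
  genes <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = 18000, end = 20000)
  sets <- list(Mo = list(big, big, big), DC = list(small, small, small))
  groups <- match_regions(sets, genes)
  expect_length(groups, 1L)
  expect_equal(groups[[1]]$outer$start, 10000)
  expect_equal(groups[[1]]$outer$end, 30000)
  expect_equal(unname(groups[[1]]$spans["Mo", ]), rep(20000, 3))
  expect_equal(unname(groups[[1]]$spans["DC", ]), rep(10000, 3))
})

test_that("conserved subset keeps only well-aligned triplicate regions", {
  a <- regset(0, 10000)
  expect_equal(nrow(conserved_subset(list(a, a, a))), 1L)
  # one replicate shifted by 30% of the span: overlap below 0.75
  shifted <- regset(3000, 13000)
  expect_equal(nrow(conserved_subset(list(a, shifted, a))), 0L)
  empty <- a[0, ]
  expect_equal(nrow(conserved_subset(list(empty, a, a))), 0L)
})

test_that("span change calls require all-nine consistency plus mean threshold", {
  inc <- span_change_call(c(10, 10, 10), c(5, 5, 5),
                          ratio_threshold = 1, mean_threshold = 1.5)
  expect_equal(inc$class, "increase")
  expect_equal(inc$mean_ratio, 2)
  expect_length(inc$ratios, 9L)

  # one discordant ratio breaks consistency
  mix <- span_change_call(c(10, 10, 4.5), c(5, 5, 5),
                          ratio_threshold = 1, mean_threshold = 1.5)
  expect_equal(mix$class, "none")

  # all ratios 1.1: consistency passes, mean threshold fails
  weak <- span_change_call(c(11, 11, 11), c(10, 10, 10),
                           ratio_threshold = 1, mean_threshold = 1.5)
  expect_equal(weak$class, "none")

  dec <- span_change_call(c(5, 5, 5), c(10, 10, 10),
                          ratio_threshold = 1, mean_threshold = 1.5)
  expect_equal(dec$class, "decrease")
})

test_that("span change calls are antisymmetric under side swap", {
  set.seed(41)
  for (i in 1:50) {
    a <- rlnorm(3, log(10000), 0.4)
    b <- rlnorm(3, log(10000), 0.4)
    f <- span_change_call(a, b)
    r <- span_change_call(b, a)
    expect_equal(f$class,
                 c(increase = "decrease", decrease = "increase",
                   none = "none")[[r$class]])
    expect_equal(sort(f$ratios), sort(1 / r$ratios), tolerance = 1e-12)
  }
})

test_that("replicate-permuted same-condition spans are almost never called", {
  set.seed(42)
  n_called <- 0L
  for (i in 1:200) {
    s <- rlnorm(1, log(10000), 0.5)
    reps <- s * rlnorm(6, 0, 0.05)     # six same-condition estimates
    call <- span_change_call(reps[1:3], reps[4:6])
    if (call$class != "none") n_called <- n_called + 1L
  }
  expect_lte(n_called / 200, 0.05)
})

test_that("planted two-fold span changes are called in the correct direction", {
  set.seed(43)
  correct <- 0L
  for (i in 1:100) {
    s <- rlnorm(1, log(10000), 0.5)
    a <- 2 * s * rlnorm(3, 0, 0.08)
    b <- s * rlnorm(3, 0, 0.08)
    if (span_change_call(a, b)$class == "increase") correct <- correct + 1L
  }
  expect_gte(correct / 100, 0.90)
})

test_that("fold change is assigned only when sum and largest ratios agree", {
  one <- fold_change_assign(20000, 10000)
  expect_true(one$assigned)
  expect_equal(one$fold_change, 2)

  agree <- fold_change_assign(c(12000, 2000), 10000)
  expect_equal(agree$sum_ratio, 1.4)
  expect_equal(agree$largest_ratio, 1.2)
  expect_equal(agree$fold_change, 1.2)

  conflict <- fold_change_assign(c(12000, 2000), 13000)
  expect_false(conflict$assigned)
  expect_true(is.na(conflict$fold_change))
  expect_gt(conflict$sum_ratio, 1)
  expect_lt(conflict$largest_ratio, 1)
})

test_that("span overlap supports both denominator conventions", {
  expect_equal(span_overlap(0, 1000, 300, 1300), 700 / 1300)
  expect_equal(span_overlap(0, 1000, 300, 1300, denom = "shorter"), 0.7)
  expect_equal(span_overlap(0, 1000, 1000, 2000), 0)
})
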