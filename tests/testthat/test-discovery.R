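## Differential-CpG calling and region assembly.

test_that("compute_beta applies the coverage floor", {
  expect_equal(compute_beta(3L, 7L, 1L), 0.3)
  expect_true(is.na(compute_beta(0L, 0L, 1L)))
  expect_true(is.na(compute_beta(4L, 0L, 5L)))
  expect_error(compute_beta(-1L, 3L), "non-negative")
})

test_that("missingness_filter drops rows missing in more than half of a group", {
  beta <- matrix(0.5, nrow = 3, ncol = 10)
  groups <- rep(c("tumor_tissue", "normal_tissue"), each = 5)
  beta[1, 1:3] <- NA   # 3/5 tumor missing -> removed
  beta[2, c(1, 2, 6)] <- NA  # exactly half nowhere: 2/5 and 1/5 -> kept
  bm <- toy_beta_matrix(beta, groups)
  out <- missingness_filter(bm)
  expect_equal(nrow(out$beta), 2L)
  expect_equal(out$sites$pos, c(2000L, 3000L))

  ## missing in exactly half (strict "more than") keeps the row
  beta4 <- matrix(0.5, nrow = 1, ncol = 4)
  beta4[1, 1] <- NA   # 1 of 2 tumor samples
  bm4 <- toy_beta_matrix(beta4, rep(c("tumor_tissue", "normal_tissue"),
                                    each = 2))
  expect_equal(nrow(missingness_filter(bm4)$beta), 1L)

  ## fully observed matrix unchanged
  full <- toy_beta_matrix(matrix(0.2, 4, 10), groups)
  expect_equal(missingness_filter(full)$beta, full$beta)
})

test_that("rank_sum_test exact branch reproduces full enumeration", {
  x <- c(0.9, 0.91, 0.92, 0.93, 0.94)
  y <- c(0.1, 0.11, 0.12, 0.13, 0.14)
  expect_equal(rank_sum_test(x, y), 2 / choose(10, 5))
  expect_equal(rank_sum_test(x, y), oracle_ranksum_exact(x, y))

  ## identical multisets give p = 1
  z <- c(1, 2, 3)
  expect_equal(rank_sum_test(z, z), 1)

  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")

  set.seed(11)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq_len(100), n1)  # distinct -> no ties
    y <- sample(setdiff(seq_len(200), x), n2)
    expect_equal(rank_sum_test(x, y), oracle_ranksum_exact(x, y),
                 info = sprintf("case %d", i))
  }
})

test_that("rank_sum_test approximation matches the tie-corrected normal test", {
  set.seed(12)
  for (i in 1:20) {
    x <- round(rnorm(20), 1)  # rounding induces ties
    y <- round(rnorm(20, 0.3), 1)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_equal(rank_sum_test(x, y), ref, tolerance = 1e-10)
  }
  ## Monte-Carlo sanity: approximation within 10% of the exact-oracle
  ## branch near the boundary of the exact regime
  set.seed(13)
  x <- sample(seq_len(1000), 6)
  y <- sample(setdiff(seq_len(1000), x), 6)
  approx_p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
  exact_p <- rank_sum_test(x, y)
  expect_lt(abs(approx_p - exact_p) / exact_p, 0.35)
})

test_that("bh_fdr applies the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_differential_cpgs applies all three filters with BH first", {
  ## planted toy: one differential CpG among 50 null CpGs, 5 vs 5 samples
  make_toy <- function(plasma_beta) {
    set.seed(21)
    n <- 51L
    beta <- matrix(stats::runif(n * 15, 0.08, 0.12), n, 15)
    beta[1, 1:5] <- c(0.90, 0.91, 0.92, 0.93, 0.94)     # tumor high
    beta[1, 11:15] <- plasma_beta
    toy_beta_matrix(beta, rep(c("tumor_tissue", "normal_tissue",
                                "healthy_plasma"), each = 5))
  }
  bm <- make_toy(0.01)

  ## independent brute-force oracle over all three filters + BH
  oracle_calls <- function(bm, fdr_max, plasma_thresh = 0.05) {
    p <- sapply(seq_len(nrow(bm$beta)), function(i)
      oracle_ranksum_exact(bm$beta[i, 1:5], bm$beta[i, 6:10]))
    q <- stats::p.adjust(p, "BH")
    delta <- rowMeans(bm$beta[, 1:5]) - rowMeans(bm$beta[, 6:10])
    mp <- rowMeans(bm$beta[, 11:15])
    which(q < fdr_max & delta > 0.3 & mp < plasma_thresh)
  }

  ## with 5 vs 5 the rank-sum p floor is 2/252, so BH over 51 CpGs can
  ## never reach q < 0.05 — both implementation and oracle return empty
  expect_equal(nrow(call_differential_cpgs(bm, "hyper")), 0L)
  expect_equal(length(oracle_calls(bm, 0.05)), 0L)

  ## at an attainable FDR the planted CpG (and only it) is returned
  got <- call_differential_cpgs(bm, "hyper", fdr_max = 0.45)
  expect_equal(got$pos, bm$sites$pos[oracle_calls(bm, 0.45)])
  expect_equal(got$pos, 1000L)

  ## plasma mean 0.06 breaks the plasma filter
  expect_equal(nrow(call_differential_cpgs(make_toy(0.06), "hyper",
                                           fdr_max = 0.45)), 0L)

  ## tumor identical to normal -> no calls at any FDR
  null_beta <- matrix(0.1, 20, 15)
  null_bm <- toy_beta_matrix(null_beta, rep(c("tumor_tissue",
                                              "normal_tissue",
                                              "healthy_plasma"), each = 5))
  expect_equal(nrow(call_differential_cpgs(null_bm, "hyper",
                                           fdr_max = 0.99)), 0L)

  ## missing required group errors
  bad <- toy_beta_matrix(matrix(0.1, 3, 4),
                         rep(c("tumor_tissue", "normal_tissue"), each = 2))
  expect_error(call_differential_cpgs(bad, "hyper"), "healthy_plasma")
})

test_that("per-sample plasma mode requires every sample below threshold", {
  beta <- matrix(0.01, 2, 15)
  beta[, 1:5] <- 0.95
  beta[2, 11] <- 0.07   # one plasma sample above 0.05
  bm <- toy_beta_matrix(beta, rep(c("tumor_tissue", "normal_tissue",
                                    "healthy_plasma"), each = 5))
  mean_mode <- call_differential_cpgs(bm, "hyper", fdr_max = 0.45)
  all_mode <- call_differential_cpgs(bm, "hyper", fdr_max = 0.45,
                                     plasma_mode = "all")
  expect_equal(mean_mode$pos, c(1000L, 2000L))  # mean still < 0.05
  expect_equal(all_mode$pos, 1000L)
})

test_that("merge_to_fragments chains CpGs within 2*flank, inclusively", {
  expect_equal(merge_to_fragments(c(100L, 200L, 360L), 75L),
               list(c(100L, 200L), 360L))
  expect_equal(merge_to_fragments(500L, 75L), list(500L))
  ## gap of exactly 150 = 2*flank merges (touching intervals chain)
  expect_equal(merge_to_fragments(c(100L, 250L), 75L),
               list(c(100L, 250L)))
  expect_error(merge_to_fragments(c(5L, 2L), 75L), "increasing")
  expect_equal(merge_to_fragments(integer(), 75L), list())
})

test_that("merge_to_fragments equals the interval-union oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(1:60, 1)
    pos <- sort(sample.int(5000L, n))
    flank <- sample(c(10L, 75L, 120L), 1)
    expect_equal(merge_to_fragments(pos, flank),
                 oracle_interval_union(pos, flank),
                 info = sprintf("case %d", i))
  }
})

test_that("filter_fragments keeps fragments with at least min_cpgs", {
  frags <- list(1:9 * 10L, 1:10 * 10L, 1:12 * 10L)
  out <- filter_fragments(frags, 10L)
  expect_equal(lengths(out), c(10L, 12L))
  expect_equal(filter_fragments(list(), 10L), list())
})

test_that("finalize_regions spans first to last member CpG", {
  members <- as.integer(c(1000, 1010, 1015, 1020, 1025, 1030, 1035,
                          1040, 1045, 1051))
  r <- finalize_regions(list(members), chrom = "chr2")
  expect_equal(r$start, 1000L)
  expect_equal(r$end, 1051L)
  expect_equal(r$length, 52L)
  expect_equal(r$n_cpgs, 10L)

  big <- finalize_regions(list(as.integer(seq(391824, 393789, by = 131))),
                          chrom = "chr6")
  expect_equal(big$length, 1966L)

  set.seed(32)
  pos <- sort(sample.int(1e5, 200))
  frags <- merge_to_fragments(pos, 75L)
  regs <- finalize_regions(frags)
  expect_false(is.unsorted(regs$start, strictly = TRUE))
  expect_true(all(regs$start[-1L] > regs$end[-nrow(regs)]))
})

test_that("discover_regions recovers planted regions and nothing else", {
  cfg <- synth_config(seed = 3, n_regions = 10L, chrom_length = 2e5)
  g <- make_genome(cfg)
  tis <- make_tissue_counts(g, 5)
  res <- suppressMessages(
    discover_regions(tis$tumor, tis$normal, tis$plasma,
                     direction = "hyper"))
  reg <- res$hyper
  expect_gte(nrow(reg), 9L)
  ## every discovered region matches a planted region reciprocally
  truth <- g$regions
  for (i in seq_len(nrow(reg))) {
    hit <- truth[chrom == reg$chrom[i] & start <= reg$end[i] &
                   end >= reg$start[i]]
    expect_equal(nrow(hit), 1L)
    inter <- min(hit$end, reg$end[i]) - max(hit$start, reg$start[i]) + 1L
    expect_gte(inter, 0.5 * (hit$end - hit$start + 1L))
    expect_gte(inter, 0.5 * (reg$end[i] - reg$start[i] + 1L))
  }
})

test_that("discovery is invariant to input row order", {
  cfg <- synth_config(seed = 4, n_regions = 6L, chrom_length = 1e5)
  g <- make_genome(cfg)
  tis <- make_tissue_counts(g, 5)
  res1 <- suppressMessages(discover_regions(tis$tumor, tis$normal,
                                            tis$plasma,
                                            direction = "hyper"))$hyper
  shuffled <- lapply(tis, function(grp) lapply(grp, function(tab) {
    tab[sample(nrow(tab))]
  }))
  set.seed(5)
  res2 <- suppressMessages(discover_regions(shuffled$tumor,
                                            shuffled$normal,
                                            shuffled$plasma,
                                            direction = "hyper"))$hyper
  expect_equal(res2[, .(chrom, start, end, n_cpgs)],
               res1[, .(chrom, start, end, n_cpgs)])
})

test_that("hyper discovery mirrors hypo discovery on mirrored inputs", {
  cfg <- synth_config(seed = 6, n_regions = 6L, chrom_length = 1e5)
  g <- make_genome(cfg)
  tis <- make_tissue_counts(g, 5)
  hyper <- suppressMessages(discover_regions(tis$tumor, tis$normal,
                                             tis$plasma,
                                             direction = "hyper"))$hyper
  mirror <- function(tab) {
    out <- data.table::copy(tab)
    data.table::setnames(out, c("meth", "unmeth"), c("unmeth", "meth"))
    out
  }
  hypo <- suppressMessages(discover_regions(
    tis$normal, tis$tumor, lapply(tis$plasma, mirror),
    direction = "hypo"))$hypo
  expect_equal(hypo[, .(chrom, start, end, n_cpgs)],
               hyper[, .(chrom, start, end, n_cpgs)])
})

test_that("null cohorts yield no regions", {
  cfg <- synth_config(seed = 8, n_regions = 4L, chrom_length = 1e5)
  g <- make_genome(cfg)
  tis <- null_tissue_counts(g, 5)
  res <- suppressMessages(discover_regions(tis$tumor, tis$normal,
                                           tis$plasma))
  expect_equal(nrow(res$hyper), 0L)
  expect_equal(nrow(res$hypo), 0L)
})
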