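## The synthetic-data generator: construction contracts, determinism and
## the statistical structure downstream stages rely on.

test_that("make_genome honours the construction contract", {
  cfg <- synth_config(seed = 1, n_regions = 12L, chrom_length = 2e5)
  g <- make_genome(cfg)
  expect_equal(nrow(g$regions), 12L)
  expect_true(all(g$regions$n_cpgs >= 10L))
  expect_true(all(g$regions$end - g$regions$start + 1L <= 500L))
  ## pairwise gaps of at least region_min_gap within each chromosome
  for (ch in unique(g$regions$chrom)) {
    r <- g$regions[chrom == ch][order(start)]
    if (nrow(r) > 1)
      expect_true(all(r$start[-1L] - r$end[-nrow(r)] >= cfg$region_min_gap))
  }
  ## CpG positions strictly increasing per chromosome, >= 2 bp apart
  for (ch in unique(g$cpgs$chrom)) {
    p <- g$cpgs[chrom == ch, pos]
    expect_true(all(diff(p) >= 2L))
  }
  ## determinism
  expect_identical(make_genome(cfg)$cpgs, g$cpgs)

  ## pure background genome
  g0 <- make_genome(synth_config(seed = 2, n_regions = 0L,
                                 chrom_length = 1e5))
  expect_equal(nrow(g0$regions), 0L)
  expect_true(all(g0$cpgs$region_id == 0L))

  ## infeasible packing errors
  expect_error(make_genome(synth_config(seed = 3, n_regions = 60L,
                                        chrom_length = 5e4)),
               "infeasible")
})

test_that("make_profiles separates planted strata by group", {
  cfg <- synth_config(seed = 5, n_regions = 8L, chrom_length = 2e5)
  g <- make_genome(cfg)
  prof <- make_profiles(g, c("tumor_tissue", "normal_tissue",
                             "healthy_plasma"), seed = 6)
  planted <- g$cpgs$region_id > 0L
  ## planted delta exceeds the discovery threshold by construction
  expect_gt(mean(prof[planted, 1]) - mean(prof[planted, 2]), 0.3)
  expect_lt(mean(prof[planted, 3]), 0.05)
  ## background is shared across groups
  expect_lt(abs(mean(prof[!planted, 1]) - mean(prof[!planted, 2])), 0.02)
  ## deterministic; distinct samples get distinct draws
  expect_identical(make_profiles(g, c("tumor_tissue", "normal_tissue",
                                      "healthy_plasma"), seed = 6), prof)
  two <- make_profiles(g, c("tumor_tissue", "tumor_tissue"), seed = 7)
  expect_false(identical(two[, 1], two[, 2]))
})

test_that("hypo-direction profiles mirror the hyper architecture", {
  cfg <- synth_config(seed = 8, n_regions = 6L, chrom_length = 1e5,
                      direction = "hypo")
  g <- make_genome(cfg)
  prof <- make_profiles(g, c("tumor_tissue", "normal_tissue",
                             "healthy_plasma"), seed = 9)
  planted <- g$cpgs$region_id > 0L
  expect_gt(mean(prof[planted, 2]) - mean(prof[planted, 1]), 0.3)
  expect_gt(mean(prof[planted, 3]), 0.95)
})

test_that("emit_counts produces beta-binomial counts at the right level", {
  cfg <- synth_config(seed = 10, n_regions = 6L, chrom_length = 1e5,
                      coverage = 100)
  g <- make_genome(cfg)

  ## epsilon = 0 and full methylation -> every read methylated
  cfg0 <- synth_config(seed = 11, n_regions = 6L, chrom_length = 1e5,
                       epsilon = 0)
  g0 <- make_genome(cfg0)
  ones <- matrix(1, nrow(g0$cpgs), 1)
  tab0 <- emit_counts(ones, g0, seed = 12)[[1L]]
  expect_equal(sum(tab0$unmeth), 0L)

  ## depth concentrates near the Poisson coverage target
  prof <- make_profiles(g, "tumor_tissue", seed = 13)
  tab <- emit_counts(prof, g, seed = 14)[[1L]]
  per_site <- collapse_strands(tab)[, meth + unmeth]
  expect_lt(abs(mean(per_site) - 100), 5 * sqrt(100 / length(per_site)))

  ## empirical beta at planted tumor sites matches the effective
  ## methylation probability m_eff = m (1 - 2 eps) + eps within 3 sigma
  planted <- g$cpgs$region_id > 0L
  coll <- collapse_strands(tab)
  betas <- coll[planted, meth / (meth + unmeth)]
  m_eff <- prof[planted, 1] * (1 - 2 * cfg$epsilon) + cfg$epsilon
  expect_lt(abs(mean(betas) - mean(m_eff)),
            3 * sd(betas) / sqrt(length(betas)))
})

test_that("emit_reads is deterministic and carries Bernoulli calls", {
  cfg <- synth_config(seed = 15, n_regions = 4L, chrom_length = 1e5)
  g <- make_genome(cfg)
  prof <- make_profiles(g, "tumor_tissue", seed = 16)
  r1 <- emit_reads(prof[, 1], g, seed = 17)
  r2 <- emit_reads(prof[, 1], g, seed = 17)
  expect_identical(as.data.table(r1), as.data.table(r2))
  expect_equal(nrow(r1),
               round(cfg$coverage * 2 * cfg$chrom_length / cfg$read_length))
  expect_equal(attr(r1, "total_mapped_reads"), nrow(r1))
  expect_true(all(r1$end - r1$start + 1L == cfg$read_length))
  expect_true(all(r1$n_meth <= r1$n_calls))

  ## window mode materialises fewer reads but keeps the notional total
  windows <- g$regions[, .(chrom, start = start - cfg$read_length + 1L,
                           end = end)]
  rw <- emit_reads(prof[, 1], g, seed = 18, windows = windows)
  expect_lt(nrow(rw), nrow(r1) / 10)
  expect_equal(attr(rw, "total_mapped_reads"), nrow(r1))

  ## detail mode records per-call positions consistent with the tallies
  rd <- emit_reads(prof[, 1], g, seed = 19, windows = windows,
                   detail = TRUE)
  expect_equal(vapply(rd$call_m, sum, 0L), rd$n_meth)
  expect_equal(lengths(rd$call_pos), rd$n_calls)
})

test_that("make_cohort records truth and matches the requested shape", {
  cfg <- synth_config(seed = 20, n_regions = 6L, chrom_length = 1e5)
  coh <- make_cohort(cfg, n_cases = 6L, n_controls = 8L)
  expect_equal(length(coh$reads), 14L)
  expect_equal(as.integer(table(coh$labels)[c("case", "control")]),
               c(6L, 8L))
  expect_true(all(coh$truth[label == "case", tumor_fraction] >= 0.005))
  expect_true(all(coh$truth[label == "case", tumor_fraction] <= 0.05))
  expect_true(all(coh$truth[label == "control", tumor_fraction] == 0))
  ## truth round-trips through plain-text serialization
  f <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(coh$truth, f, sep = "\t")
  expect_equal(data.table::fread(f, colClasses = list(
    character = "sample_id")), coh$truth)
  ## determinism of the whole cohort
  coh2 <- make_cohort(cfg, n_cases = 6L, n_controls = 8L)
  expect_identical(as.data.table(coh2$reads[[1L]]),
                   as.data.table(coh$reads[[1L]]))
  expect_equal(coh2$truth, coh$truth)
})

test_that("background sites essentially never pass the delta filter", {
  ## expected number of background CpGs with a 5v5 empirical delta-beta
  ## above 0.3 is far below 1 per genome
  total_bad <- 0L
  for (s in 1:10) {
    cfg <- synth_config(seed = 200 + s, n_regions = 2L,
                        chrom_length = 2e5)
    g <- make_genome(cfg)
    tis <- make_tissue_counts(g, 5)
    bm <- build_beta_matrix(
      c(tis$tumor, tis$normal),
      rep(c("tumor_tissue", "normal_tissue"), each = 5))
    bg <- g$cpgs$region_id[match(paste(bm$sites$chrom, bm$sites$pos),
                                 paste(g$cpgs$chrom, g$cpgs$pos))] == 0L
    delta <- rowMeans(bm$beta[, 1:5], na.rm = TRUE) -
      rowMeans(bm$beta[, 6:10], na.rm = TRUE)
    total_bad <- total_bad + sum(bg & delta > 0.3, na.rm = TRUE)
  }
  expect_lt(total_bad / 10, 1)
})
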