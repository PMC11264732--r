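## Deterministic synthetic-data generator. Emulates the data structure
## the method assumes: a toy genome with planted marker regions whose CpGs
## are hypermethylated in tumor tissue and essentially unmethylated in
## normal tissue and healthy plasma; beta-binomial count tables; and
## read sets with per-CpG Bernoulli calls subject to a small symmetric
## conversion-error rate. Case plasma is built by mixing tumor-profile
## reads into healthy-plasma-profile reads at a known fraction.

#' Generator configuration
#'
#' Defaults state the simulated world: a 2 x 1 Mb genome; 50 planted
#' regions of 18 CpGs across ~420 bp (matching the reported ~400 bp mean
#' marker-region length), pairwise >= 2 kb apart; background CpGs at
#' 1 per kb — a marker-panel-like miniature chosen so that, with the
#' 5-vs-5 tissue design, planted CpGs form a large enough fraction of all
#' tested sites for BH-FDR < 0.05 to be attainable at the 5-vs-5 rank-sum
#' p-value floor of 2/C(10,5) (see the methods vignette); planted-site
#' methylation Beta(mean 0.90, conc 50) in tumor and Beta(0.02, 50) in
#' normal tissue and healthy plasma; background Beta(0.05, 20) in all
#' groups; conversion error 0.005; 150 bp single-end reads at 30x
#' coverage. `direction = "hypo"` mirrors the planted means
#' (tumor 0.02, normal 0.90, plasma 0.98) and the background (0.95).
#'
#' @param seed Master seed; every derived stream comes from it.
#' @param n_chrom,chrom_length Genome shape.
#' @param background_cpg_rate Background CpG density per bp.
#' @param n_regions Number of planted regions (split across chromosomes).
#' @param region_n_cpgs CpGs per planted region (>= 10).
#' @param region_span Planted-region span in bp (<= 500).
#' @param region_min_gap Minimum distance between planted regions.
#' @param planted_means Named vector `c(tumor=, normal=, plasma=)` of
#'   planted-site methylation means; `NULL` picks the per-direction
#'   default.
#' @param planted_conc,background_mean,background_conc Beta-law
#'   hyperparameters (`conc` = concentration; shape1 = mean * conc).
#' @param epsilon Symmetric conversion-error rate.
#' @param read_length,coverage Read emission parameters.
#' @param direction `"hyper"` or `"hypo"` planted architecture.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 1e6,
                         background_cpg_rate = 0.001, n_regions = 50L,
                         region_n_cpgs = 18L, region_span = 420L,
                         region_min_gap = 2000L, planted_means = NULL,
                         planted_conc = 50, background_mean = NULL,
                         background_conc = 20, epsilon = 0.005,
                         read_length = 150L, coverage = 30,
                         direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  planted_means <- planted_means %||% (if (direction == "hyper")
    c(tumor = 0.90, normal = 0.02, plasma = 0.02)
  else c(tumor = 0.02, normal = 0.90, plasma = 0.98))
  background_mean <- background_mean %||%
    (if (direction == "hyper") 0.05 else 0.95)
  cfg <- list(
    seed = .assert_whole(seed, "seed", min = 0L),
    n_chrom = .assert_whole(n_chrom, "n_chrom", min = 1L),
    chrom_length = .assert_whole(chrom_length, "chrom_length", min = 1000L),
    background_cpg_rate = .assert_scalar_number(background_cpg_rate,
                                                "background_cpg_rate", 0, 1),
    n_regions = .assert_whole(n_regions, "n_regions", min = 0L),
    region_n_cpgs = .assert_whole(region_n_cpgs, "region_n_cpgs", min = 10L),
    region_span = .assert_whole(region_span, "region_span", min = 20L),
    region_min_gap = .assert_whole(region_min_gap, "region_min_gap",
                                   min = 0L),
    planted_means = planted_means, planted_conc = planted_conc,
    background_mean = background_mean, background_conc = background_conc,
    epsilon = .assert_scalar_number(epsilon, "epsilon", 0, 1),
    read_length = .assert_whole(read_length, "read_length", min = 1L),
    coverage = .assert_scalar_number(coverage, "coverage", 0, Inf),
    direction = direction)
  if (cfg$region_span > 500L) .err("region_span must be <= 500 bp")
  if (!all(c("tumor", "normal", "plasma") %in% names(cfg$planted_means)))
    .err("planted_means needs tumor/normal/plasma entries")
  if (any(cfg$planted_means < 0 | cfg$planted_means > 1))
    .err("planted_means must lie in [0, 1]")
  structure(cfg, class = "synth_config")
}

#' Build the toy genome
#'
#' Places `n_regions` planted regions (near-regularly spaced CpGs inside a
#' compact span) in evenly sized slots so regions are pairwise at least
#' `region_min_gap` apart, then scatters background CpGs at
#' `background_cpg_rate` outside the planted neighbourhoods (planted
#' regions emulate CpG islands, so no background CpG falls within a read
#' length of a region). Deterministic given the config seed.
#'
#' @param config A [synth_config()].
#' @return A `synth_genome`: list with `cpgs` (`chrom`, `pos`,
#'   `region_id`; 0 = background), `regions` (truth table: `region_id`,
#'   `chrom`, `start`, `end`, `n_cpgs`) and `config`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    per_chrom <- diff(round(seq(0, config$n_regions,
                                length.out = config$n_chrom + 1L)))
    cpg_list <- vector("list", config$n_chrom)
    reg_list <- vector("list", config$n_chrom)
    rid <- 0L
    for (ci in seq_len(config$n_chrom)) {
      L <- config$chrom_length
      K <- per_chrom[ci]
      regs <- NULL
      if (K > 0L) {
        slot <- L / K
        margin <- config$region_min_gap / 2
        if (slot < config$region_span + 2 * margin + 10)
          .err("planted regions infeasible: %d regions of %d bp + %d bp gaps exceed chromosome length %d",
               K, config$region_span, config$region_min_gap, L)
        starts <- vapply(seq_len(K), function(k) {
          lo <- (k - 1) * slot + margin
          hi <- k * slot - margin - config$region_span
          floor(runif(1, lo, hi))
        }, 0)
        members <- lapply(starts, function(s) {
          offs <- round(seq(0, config$region_span,
                            length.out = config$region_n_cpgs)) +
            sample(-5:5, config$region_n_cpgs, replace = TRUE)
          p <- as.integer(s + offs)
          for (i in seq_along(p)[-1L])      # keep CpGs >= 2 bp apart
            if (p[i] < p[i - 1L] + 2L) p[i] <- p[i - 1L] + 2L
          p
        })
        regs <- data.table(
          region_id = rid + seq_len(K), chrom = chroms[ci],
          start = vapply(members, min, 0L),
          end = vapply(members, max, 0L),
          n_cpgs = lengths(members))
        planted <- data.table(
          chrom = chroms[ci], pos = unlist(members),
          region_id = rep(regs$region_id, lengths(members)))
        rid <- rid + K
      } else {
        planted <- data.table(chrom = character(), pos = integer(),
                              region_id = integer())
      }
      bg_pos <- which(runif(L - config$read_length) <
                        config$background_cpg_rate)
      bg_pos <- bg_pos[c(TRUE, diff(bg_pos) >= 2L)]
      if (!is.null(regs) && nrow(regs) && length(bg_pos)) {
        pad <- config$read_length
        hits <- IRanges::findOverlaps(
          IRanges::IRanges(bg_pos, width = 1L),
          IRanges::IRanges(regs$start - pad, regs$end + pad))
        if (length(hits))
          bg_pos <- bg_pos[-unique(S4Vectors::queryHits(hits))]
      }
      cpg_list[[ci]] <- rbind(
        planted,
        data.table(chrom = chroms[ci], pos = as.integer(bg_pos),
                   region_id = 0L))
      reg_list[[ci]] <- regs
    }
    cpgs <- rbindlist(cpg_list)
    setorder(cpgs, chrom, pos)
    regions <- rbindlist(reg_list[!vapply(reg_list, is.null, TRUE)])
    structure(list(cpgs = cpgs, regions = regions, config = config),
              class = "synth_genome")
  })
}

.effective_m <- function(m, epsilon) m * (1 - epsilon) + (1 - m) * epsilon

.group_key <- function(group) {
  switch(group,
         tumor_tissue = "tumor", normal_tissue = "normal",
         healthy_plasma = "plasma", case_plasma = "plasma",
         .err("unknown group '%s'", group))
}

#' Draw per-sample per-site methylation levels
#'
#' Each sample's true methylation level at each CpG is an independent
#' Beta draw whose mean depends on the stratum (planted region vs
#' background) and, for planted sites, on the sample group.
#'
#' @param genome A `synth_genome`.
#' @param groups Character vector of group labels, one per sample, among
#'   `tumor_tissue`, `normal_tissue`, `healthy_plasma`, `case_plasma`.
#' @param seed Seed for this draw (defaults to the config seed + 1).
#' @return Numeric matrix, CpG sites x samples, of true methylation
#'   levels in `[0, 1]`.
#' @export
make_profiles <- function(genome, groups, seed = NULL) {
  stopifnot(inherits(genome, "synth_genome"))
  cfg <- genome$config
  seed <- seed %||% (cfg$seed + 1L)
  planted <- genome$cpgs$region_id > 0L
  n_site <- nrow(genome$cpgs)
  withr::with_seed(seed, {
    m <- matrix(NA_real_, n_site, length(groups))
    for (s in seq_along(groups)) {
      mu_p <- cfg$planted_means[[.group_key(groups[s])]]
      m[planted, s] <- rbeta(sum(planted), mu_p * cfg$planted_conc,
                             (1 - mu_p) * cfg$planted_conc)
      m[!planted, s] <- rbeta(sum(!planted),
                              cfg$background_mean * cfg$background_conc,
                              (1 - cfg$background_mean) * cfg$background_conc)
    }
    colnames(m) <- paste0(groups, "_", seq_along(groups))
    m
  })
}

#' Emit cytosine-report count tables
#'
#' Per site and sample, total depth is Poisson(coverage), split
#' binomially between the two strands; methylated counts are Binomial
#' with the effective methylation probability
#' `m * (1 - epsilon) + (1 - m) * epsilon`. Two strand rows are emitted
#' per CpG (the minus-strand cytosine at pos + 1) so the tables exercise
#' [collapse_strands()].
#'
#' @param profiles Site x sample matrix from [make_profiles()].
#' @param genome A `synth_genome`.
#' @param seed Seed (defaults to config seed + 2).
#' @return Named list of cytosine-report-style `data.table`s (`chrom`,
#'   `pos`, `strand`, `meth`, `unmeth`).
#' @export
emit_counts <- function(profiles, genome, seed = NULL) {
  stopifnot(inherits(genome, "synth_genome"))
  cfg <- genome$config
  seed <- seed %||% (cfg$seed + 2L)
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  stopifnot(n == nrow(genome$cpgs))
  withr::with_seed(seed, {
    out <- lapply(seq_len(ncol(profiles)), function(s) {
      m_eff <- .effective_m(profiles[, s], cfg$epsilon)
      depth <- rpois(n, cfg$coverage)
      d_plus <- rbinom(n, depth, 0.5)
      d_minus <- depth - d_plus
      meth_plus <- rbinom(n, d_plus, m_eff)
      meth_minus <- rbinom(n, d_minus, m_eff)
      rbind(
        data.table(chrom = genome$cpgs$chrom, pos = genome$cpgs$pos,
                   strand = "+", meth = meth_plus,
                   unmeth = d_plus - meth_plus),
        data.table(chrom = genome$cpgs$chrom, pos = genome$cpgs$pos + 1L,
                   strand = "-", meth = meth_minus,
                   unmeth = d_minus - meth_minus))[order(chrom, pos)]
    })
    names(out) <- colnames(profiles) %||% paste0("s", seq_along(out))
    out
  })
}

#' Emit a read set for one sample
#'
#' Read starts are uniform over the genome (or over supplied windows,
#' with the out-of-window read count carried only in the
#' `total_mapped_reads` attribute — reads outside the windows can never
#' be scored, so per-region counts are unaffected). Each read carries a
#' Bernoulli methylation call at every CpG it spans, with success
#' probability equal to the site's effective methylation level.
#'
#' @param profile Per-site methylation vector for this sample.
#' @param genome A `synth_genome`.
#' @param seed Integer seed.
#' @param n_reads Total mapped reads; default
#'   `round(coverage * genome_length / read_length)`.
#' @param windows Optional region table (`chrom`, `start`, `end`); when
#'   given, only reads overlapping a window are materialised.
#' @param detail Keep per-call list columns (`call_pos`, `call_m`)?
#'   Default `FALSE` (the scoring path only needs the per-read tallies).
#' @return A `meth_reads` table with attribute `total_mapped_reads`.
#' @export
emit_reads <- function(profile, genome, seed, n_reads = NULL,
                       windows = NULL, detail = FALSE) {
  stopifnot(inherits(genome, "synth_genome"))
  cfg <- genome$config
  rl <- cfg$read_length
  genome_len <- cfg$n_chrom * cfg$chrom_length
  n_total <- n_reads %||% round(cfg$coverage * genome_len / rl)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  withr::with_seed(seed, {
    if (is.null(windows)) {
      n_emit <- n_total
      chrom_of <- sample(chroms, n_emit, replace = TRUE)
      start <- floor(runif(n_emit, 1, cfg$chrom_length - rl + 2))
    } else {
      w <- copy(as.data.table(windows))
      w[, `:=`(start = pmax(1L, as.integer(start)),
               end = pmin(as.integer(end), cfg$chrom_length - rl + 1L))]
      w <- w[end >= start]
      wlen <- w[, end - start + 1L]
      n_emit <- rbinom(1L, n_total, sum(wlen) / (genome_len - cfg$n_chrom * (rl - 1)))
      wi <- sample.int(nrow(w), n_emit, replace = TRUE,
                       prob = wlen / sum(wlen))
      chrom_of <- w$chrom[wi]
      start <- w$start[wi] + floor(runif(n_emit) * wlen[wi])
    }
    reads <- data.table(chrom = chrom_of, start = as.integer(start))
    reads[, end := start + rl - 1L]
    reads[, read_id := .I]
    m_eff <- .effective_m(profile, cfg$epsilon)
    calls <- vector("list", 0L)
    tal <- NULL
    for (ch in chroms) {
      qi <- which(reads$chrom == ch)
      si <- which(genome$cpgs$chrom == ch)
      if (!length(qi) || !length(si)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(genome$cpgs$pos[si], width = 1L),
        IRanges::IRanges(reads$start[qi], reads$end[qi]))
      if (!length(hits)) next
      site <- si[S4Vectors::queryHits(hits)]
      rd <- qi[S4Vectors::subjectHits(hits)]
      call <- runif(length(site)) < m_eff[site]
      calls[[ch]] <- data.table(read_id = rd,
                                pos = genome$cpgs$pos[site],
                                m = call)
    }
    allc <- if (length(calls)) rbindlist(calls) else
      data.table(read_id = integer(), pos = integer(), m = logical())
    tal <- allc[, .(n_calls = .N, n_meth = sum(m)), by = read_id]
    reads[, `:=`(n_calls = 0L, n_meth = 0L)]
    if (nrow(tal)) {
      reads[tal$read_id, `:=`(n_calls = tal$n_calls, n_meth = tal$n_meth)]
    }
    if (detail) {
      setorder(allc, read_id, pos)
      det <- allc[, .(call_pos = list(pos), call_m = list(m)), by = read_id]
      reads[, `:=`(call_pos = list(integer()), call_m = list(logical()))]
      if (nrow(det)) {
        reads[det$read_id, `:=`(call_pos = det$call_pos,
                                call_m = det$call_m)]
      }
    }
    reads[, read_id := NULL]
    out <- as_meth_reads(reads)
    setattr(out, "total_mapped_reads", as.integer(n_total))
    out
  })
}

#' Generate a synthetic plasma cohort
#'
#' Controls are healthy-plasma-profile read sets; cases mix
#' tumor-profile reads into a healthy-plasma-profile read set via
#' [mix_reads()] at a per-patient tumor fraction drawn uniformly from
#' `fraction_range`. By default only reads overlapping a planted-region
#' window (padded by one read length) are materialised; the notional
#' genome-wide total is recorded per sample as the CPM denominator, which
#' leaves per-region counts and CPM distributionally unchanged while
#' keeping cohort generation desk-sized.
#'
#' @param config A [synth_config()].
#' @param n_cases,n_controls Cohort sizes (defaults 49 and 60).
#' @param fraction_range Range of the uniform tumor-fraction law for
#'   cases (default `c(0.005, 0.05)`).
#' @param genome Optional pre-built `synth_genome` (so the cohort shares
#'   the genome used for discovery).
#' @param window_mode Materialise region-overlapping reads only
#'   (default `TRUE`).
#' @return A `synth_cohort`: list with `reads` (named list of
#'   `meth_reads`), `labels` (named `"case"`/`"control"`), `truth`
#'   (`sample_id`, `label`, `tumor_fraction`), `genome`.
#' @export
make_cohort <- function(config, n_cases = 49L, n_controls = 60L,
                        fraction_range = c(0.005, 0.05), genome = NULL,
                        window_mode = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  genome <- genome %||% make_genome(config)
  n_cases <- .assert_whole(n_cases, "n_cases", min = 0L)
  n_controls <- .assert_whole(n_controls, "n_controls", min = 0L)
  windows <- NULL
  if (window_mode && nrow(genome$regions)) {
    windows <- genome$regions[, .(
      chrom, start = start - config$read_length + 1L, end = end)]
  }
  ids <- c(sprintf("case%02d", seq_len(n_cases)),
           sprintf("control%02d", seq_len(n_controls)))
  labels <- stats::setNames(rep(c("case", "control"),
                                c(n_cases, n_controls)), ids)
  master <- .derive_seeds(config$seed + 3L, 2L + 3L * n_cases + n_controls)
  fractions <- withr::with_seed(master[1L], runif(n_cases,
                                                  fraction_range[1L],
                                                  fraction_range[2L]))
  reads <- vector("list", length(ids))
  names(reads) <- ids
  si <- 2L
  for (i in seq_len(n_cases)) {
    m_pl <- make_profiles(genome, "case_plasma", seed = master[si + 1L])
    m_tu <- make_profiles(genome, "tumor_tissue", seed = master[si + 1L] + 1L)
    pl <- emit_reads(m_pl[, 1L], genome, seed = master[si + 2L],
                     windows = windows)
    tu <- emit_reads(m_tu[, 1L], genome, seed = master[si + 2L] + 1L,
                     windows = windows)
    mixed <- mix_reads(pl, tu, fractions[i], seed = master[si + 3L])
    setattr(mixed, "total_mapped_reads", attr(pl, "total_mapped_reads"))
    reads[[ids[i]]] <- mixed
    si <- si + 3L
  }
  for (i in seq_len(n_controls)) {
    m_pl <- make_profiles(genome, "healthy_plasma", seed = master[si + 1L])
    reads[[ids[n_cases + i]]] <-
      emit_reads(m_pl[, 1L], genome, seed = master[si + 1L] + 1L,
                 windows = windows)
    si <- si + 1L
  }
  truth <- data.table(sample_id = ids, label = unname(labels),
                      tumor_fraction = c(fractions, rep(0, n_controls)))
  structure(list(reads = reads, labels = labels, truth = truth,
                 genome = genome),
            class = "synth_cohort")
}

#' Convenience: synthetic tissue-cohort count tables
#'
#' Generates the discovery input (tumor tissue, normal tissue, healthy
#' plasma cytosine-report tables) for a genome.
#'
#' @param genome A `synth_genome`.
#' @param n_per_group Samples per group (default 5).
#' @param seed Seed (defaults to config seed + 17).
#' @return List of three named lists of count tables: `tumor`, `normal`,
#'   `plasma`.
#' @export
make_tissue_counts <- function(genome, n_per_group = 5L, seed = NULL) {
  stopifnot(inherits(genome, "synth_genome"))
  seed <- seed %||% (genome$config$seed + 17L)
  groups <- rep(c("tumor_tissue", "normal_tissue", "healthy_plasma"),
                each = n_per_group)
  seeds <- .derive_seeds(seed, 2L)
  prof <- make_profiles(genome, groups, seed = seeds[1L])
  counts <- emit_counts(prof, genome, seed = seeds[2L])
  split_idx <- split(seq_along(groups), groups)
  list(tumor = counts[split_idx$tumor_tissue],
       normal = counts[split_idx$normal_tissue],
       plasma = counts[split_idx$healthy_plasma])
}
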