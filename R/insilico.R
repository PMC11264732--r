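## In-silico dilution validation: mix tumor-tissue reads into healthy
## plasma reads at known fractions and test the ctCandi dose-response.

#' Downsample a read set
#'
#' Uniform sampling without replacement, deterministic given `seed`.
#'
#' @param reads A `meth_reads` table.
#' @param target_count Number of reads to keep; must not exceed the input
#'   size.
#' @param seed Integer seed.
#' @return The sampled reads (original order preserved).
#' @export
downsample_reads <- function(reads, target_count, seed) {
  n <- nrow(reads)
  target_count <- .assert_whole(target_count, "target_count", min = 0L)
  if (target_count > n)
    .err("target_count (%d) exceeds available reads (%d)", target_count, n)
  idx <- withr::with_seed(seed, sort(sample.int(n, target_count)))
  out <- as.data.table(reads)[idx]
  setattr(out, "class", class(reads))
  out
}

#' Mix tumor reads into plasma reads at a fixed fraction
#'
#' `round(fraction * N)` uniformly chosen tumor reads replace the same
#' number of uniformly chosen plasma reads, where `N` is the plasma read
#' count, so the output always has exactly `N` reads. Replacement (rather
#' than addition) keeps the total read count — the CPM denominator —
#' constant across a dilution series, so ctCandi differences reflect
#' composition only. Deterministic given `seed`.
#'
#' @param plasma_reads,tumor_reads `meth_reads` tables.
#' @param fraction Tumor fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `meth_reads` table of `nrow(plasma_reads)` rows with an
#'   `origin` column (`"plasma"`/`"tumor"`) and attributes
#'   `n_tumor_reads` and `tumor_fraction`.
#' @export
mix_reads <- function(plasma_reads, tumor_reads, fraction, seed) {
  .assert_scalar_number(fraction, "fraction", 0, 1)
  pl <- as.data.table(plasma_reads)
  tu <- as.data.table(tumor_reads)
  common <- intersect(names(pl), names(tu))
  n <- nrow(pl)
  k <- round(fraction * n)
  if (k > nrow(tu))
    .err("need %d tumor reads, only %d available", k, nrow(tu))
  sel <- withr::with_seed(seed, list(tumor = sample.int(nrow(tu), k),
                                     replaced = sample.int(n, k)))
  keep <- pl[!seq_len(n) %in% sel$replaced, common, with = FALSE]
  take <- tu[sel$tumor, common, with = FALSE]
  out <- rbind(keep[, origin := "plasma"], take[, origin := "tumor"])
  out <- as_meth_reads(out)
  setattr(out, "n_tumor_reads", as.integer(k))
  setattr(out, "tumor_fraction", fraction)
  out
}

#' Run an in-silico dilution series
#'
#' For each (fraction, replicate) pair a mixture is built with
#' [mix_reads()] using seed `base_seed + running_index` (logged in the
#' output so any point can be regenerated in isolation) and scored with
#' [score_sample()]. The default grid spans the 0.1%-5% mixing range with
#' six replicates per ratio.
#'
#' @param plasma_reads,tumor_reads `meth_reads` tables.
#' @param regions Region table for scoring.
#' @param fractions Tumor fractions (default
#'   `c(0.001, 0.005, 0.01, 0.02, 0.03, 0.05)`).
#' @param n_reps Replicates per fraction (default 6).
#' @param base_seed Base seed for the per-point seed schedule.
#' @param direction,hyper_min,hypo_max,min_calls Passed to
#'   [score_sample()].
#' @param total_mapped_reads CPM denominator; defaults to
#'   `nrow(plasma_reads)` (constant across the series).
#' @return A `data.table` with one row per dilution point: `fraction`,
#'   `replicate`, `seed`, `ctcandi`, `n_total_reads`, `n_tumor_reads`;
#'   the Spearman correlation of ctCandi against fraction is attached as
#'   attribute `spearman` (list `rho`, `p_value`).
#' @export
dilution_series <- function(plasma_reads, tumor_reads, regions,
                            fractions = c(0.001, 0.005, 0.01, 0.02,
                                          0.03, 0.05),
                            n_reps = 6L, base_seed = 1L,
                            direction = "hyper", hyper_min = 0.6,
                            hypo_max = 0.3, min_calls = 1L,
                            total_mapped_reads = NULL) {
  n_reps <- .assert_whole(n_reps, "n_reps", min = 1L)
  total <- total_mapped_reads %||%
    attr(plasma_reads, "total_mapped_reads") %||% nrow(plasma_reads)
  grid <- CJ(fraction = fractions, replicate = seq_len(n_reps),
             sorted = FALSE)
  setorder(grid, fraction, replicate)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- grid$fraction[i]
    pt_seed <- base_seed + i
    mixed <- mix_reads(plasma_reads, tumor_reads, f, seed = pt_seed)
    sc <- score_sample(mixed, regions, total_mapped_reads = total,
                       direction = direction, hyper_min = hyper_min,
                       hypo_max = hypo_max, min_calls = min_calls)
    rows[[i]] <- data.table(
      fraction = f, replicate = grid$replicate[i], seed = pt_seed,
      ctcandi = sc$ctcandi, n_total_reads = nrow(mixed),
      n_tumor_reads = attr(mixed, "n_tumor_reads"))
  }
  out <- rbindlist(rows)
  if (nrow(out) >= 3L && length(unique(out$fraction)) > 1L &&
      length(unique(out$ctcandi)) > 1L) {
    sp <- spearman_cor(out$fraction, out$ctcandi)
    setattr(out, "spearman", sp)
  }
  out[]
}

#' Spearman rank correlation
#'
#' Average-rank (tie-aware) Spearman rho. The p-value is computed by
#' exact permutation enumeration for `n <= 8` and by the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return List with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) .err("x and y must have the same length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) .err("need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) .err("constant input: rho undefined")
  rho <- cor(rx, ry)
  if (n <= 8L) {
    perms <- .all_perms(n)
    cx <- rx - mean(rx)
    m <- matrix(ry[perms], nrow = nrow(perms))
    num <- (m - mean(ry)) %*% cx
    rho_perm <- num / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

## All permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small.
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}
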