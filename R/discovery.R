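## Discovery of cancer-specific hyper-/hypomethylated (CaSH) regions from
## tissue and healthy-plasma methylation count tables.
##
## Pipeline: per-CpG beta values -> missingness filter -> per-CpG Wilcoxon
## rank-sum test (tumor vs normal) with BH adjustment -> three filters
## (delta-beta, healthy-plasma level, FDR) -> merge surviving CpGs within
## 75 bp up/downstream into fragments -> drop fragments with < 10 CpGs ->
## region = span from first to last member CpG.

#' Per-CpG methylation ratio (beta value)
#'
#' beta = meth / (meth + unmeth) when total coverage reaches
#' `min_coverage`, otherwise `NA` (the site is treated as missing in that
#' sample). Low-coverage ratios are too noisy to support a delta-beta
#' threshold of 0.3.
#'
#' @param meth,unmeth Non-negative integer count vectors.
#' @param min_coverage Minimum total reads for a beta call (default 5).
#' @return Numeric vector of beta values in `[0, 1]` with `NA` for
#'   under-covered sites.
#' @export
compute_beta <- function(meth, unmeth, min_coverage = 5L) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    .err("counts must be non-negative")
  tot <- meth + unmeth
  ifelse(tot >= min_coverage & tot > 0, meth / tot, NA_real_)
}

#' Assemble a beta matrix from per-sample count tables
#'
#' @param samples Named list of strand-collapsed site tables (columns
#'   `chrom`, `pos`, `meth`, `unmeth`); names become sample ids. Tables
#'   with a `strand` column are collapsed with [collapse_strands()] first.
#' @param groups Character vector (same length/order as `samples`) with
#'   values among `tumor_tissue`, `normal_tissue`, `healthy_plasma`,
#'   `case_plasma`.
#' @param min_coverage Passed to [compute_beta()].
#' @return A `beta_matrix`: list with `sites` (data.table `chrom`, `pos`),
#'   `beta` (sites x samples numeric matrix, `NA` = missing) and `groups`
#'   (named character vector).
#' @export
build_beta_matrix <- function(samples, groups, min_coverage = 5L) {
  if (length(samples) == 0L) .err("no samples")
  if (length(groups) != length(samples))
    .err("'groups' must match 'samples' in length")
  ok <- c("tumor_tissue", "normal_tissue", "healthy_plasma", "case_plasma")
  if (!all(groups %in% ok))
    .err("unknown group label(s): %s",
         paste(setdiff(groups, ok), collapse = ", "))
  ids <- names(samples) %||% paste0("s", seq_along(samples))
  if (is.null(names(samples))) names(samples) <- ids
  long <- rbindlist(lapply(ids, function(id) {
    x <- as.data.table(samples[[id]])
    if ("strand" %in% names(x)) x <- collapse_strands(x)
    data.table(sample_id = id, chrom = x$chrom, pos = x$pos,
               beta = compute_beta(x$meth, x$unmeth, min_coverage))
  }))
  wide <- dcast(long, chrom + pos ~ sample_id, value.var = "beta")
  setorder(wide, chrom, pos)
  beta <- as.matrix(wide[, ids, with = FALSE])
  structure(list(sites = wide[, .(chrom, pos)], beta = beta,
                 groups = stats::setNames(groups, ids)),
            class = "beta_matrix")
}

#' Drop CpGs with too many missing beta values
#'
#' A CpG row is removed when the fraction of missing beta values exceeds
#' `max_missing_frac` (strictly) in any discovery group. The default 0.5
#' reproduces the "unavailable in more than half of the samples" rule;
#' missing in exactly half keeps the site.
#'
#' @param bm A `beta_matrix`.
#' @param max_missing_frac Maximum tolerated missing fraction per group.
#' @return The filtered `beta_matrix`.
#' @export
missingness_filter <- function(bm, max_missing_frac = 0.5) {
  stopifnot(inherits(bm, "beta_matrix"))
  keep <- rep(TRUE, nrow(bm$beta))
  for (g in unique(bm$groups)) {
    cols <- which(bm$groups == g)
    if (length(cols) == 0L) .err("empty group '%s'", g)
    frac <- rowMeans(is.na(bm$beta[, cols, drop = FALSE]))
    keep <- keep & frac <= max_missing_frac
  }
  bm$sites <- bm$sites[keep]
  bm$beta <- bm$beta[keep, , drop = FALSE]
  bm
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value by full enumeration of the rank-sum null distribution
#' when `length(x) + length(y) <= 12` and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y Non-empty numeric vectors (NAs dropped).
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) .err("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (n1 + n2 <= 12L && !ties) {
    p <- 2 * min(pwilcox(U, n1, n2),
                 pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  tab <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- max(abs(U - mu) - 0.5, 0) / sqrt(sigma2)
  min(1, 2 * pnorm(-z))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed and
#'   preserved).
#' @return Step-up adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .err("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially methylated CpGs
#'
#' For `direction = "hyper"` a CpG is retained when (i) mean tumor beta
#' minus mean normal beta exceeds `delta_min` (strict), (ii) the healthy
#' plasma level is below `plasma_thresh` (strict), and (iii) the BH
#' q-value of the per-CpG two-sided Wilcoxon rank-sum test (tumor vs
#' normal betas) is below `fdr_max`. For `"hypo"` the delta is normal
#' minus tumor and the plasma condition is `> plasma_thresh`. BH is
#' applied once over all CpGs in `bm` (assumed missingness-filtered),
#' before the beta-threshold filters, so q-values do not depend on the
#' plasma filter.
#'
#' @param bm A missingness-filtered `beta_matrix` containing the
#'   `tumor_tissue`, `normal_tissue` and `healthy_plasma` groups.
#' @param direction `"hyper"` or `"hypo"`.
#' @param delta_min Minimum group-mean beta difference (default 0.3).
#' @param plasma_thresh Healthy-plasma threshold; defaults to 0.05 for
#'   hyper and 0.95 for hypo.
#' @param fdr_max FDR ceiling (default 0.05).
#' @param plasma_mode `"mean"` applies the plasma threshold to the group
#'   mean beta; `"all"` requires every healthy-plasma sample to satisfy it.
#' @return `data.table` of retained CpGs: `chrom`, `pos`, `delta_beta`,
#'   `p_value`, `q_value`, `direction`, ordered by position.
#' @export
call_differential_cpgs <- function(bm, direction = c("hyper", "hypo"),
                                   delta_min = 0.3, plasma_thresh = NULL,
                                   fdr_max = 0.05,
                                   plasma_mode = c("mean", "all")) {
  stopifnot(inherits(bm, "beta_matrix"))
  direction <- match.arg(direction)
  plasma_mode <- match.arg(plasma_mode)
  plasma_thresh <- plasma_thresh %||%
    (if (direction == "hyper") 0.05 else 0.95)
  for (g in c("tumor_tissue", "normal_tissue", "healthy_plasma"))
    if (!any(bm$groups == g)) .err("required group '%s' missing", g)
  tu <- bm$beta[, bm$groups == "tumor_tissue", drop = FALSE]
  no <- bm$beta[, bm$groups == "normal_tissue", drop = FALSE]
  pl <- bm$beta[, bm$groups == "healthy_plasma", drop = FALSE]
  n <- nrow(bm$beta)
  p <- vapply(seq_len(n), function(i) {
    xi <- tu[i, ]; yi <- no[i, ]
    if (all(is.na(xi)) || all(is.na(yi))) return(NA_real_)
    rank_sum_test(xi, yi)
  }, 0)
  q <- bh_fdr(p)
  mt <- rowMeans(tu, na.rm = TRUE)
  mn <- rowMeans(no, na.rm = TRUE)
  delta <- if (direction == "hyper") mt - mn else mn - mt
  plasma_ok <- if (plasma_mode == "mean") {
    mp <- rowMeans(pl, na.rm = TRUE)
    if (direction == "hyper") mp < plasma_thresh else mp > plasma_thresh
  } else {
    if (direction == "hyper")
      rowSums(pl >= plasma_thresh, na.rm = TRUE) == 0L & rowSums(!is.na(pl)) > 0L
    else
      rowSums(pl <= plasma_thresh, na.rm = TRUE) == 0L & rowSums(!is.na(pl)) > 0L
  }
  keep <- !is.na(q) & q < fdr_max & delta > delta_min & plasma_ok
  keep[is.na(keep)] <- FALSE
  out <- cbind(bm$sites[keep],
               data.table(delta_beta = delta[keep], p_value = p[keep],
                          q_value = q[keep], direction = direction))
  setorder(out, chrom, pos)
  out[]
}

#' Merge differential CpGs into fragments
#'
#' Each CpG position is extended `flank` bp up- and downstream; CpGs whose
#' extensions overlap or touch chain into one fragment. Equivalently,
#' consecutive CpGs join when their position gap is at most `2 * flank`
#' (a gap of exactly `2 * flank` merges: touching closed intervals chain).
#'
#' @param positions Sorted (strictly increasing) integer CpG positions on
#'   one chromosome.
#' @param flank Extension in bp (default 75).
#' @return List of integer vectors, one per fragment, in genomic order.
#' @export
merge_to_fragments <- function(positions, flank = 75L) {
  if (length(positions) == 0L) return(list())
  if (is.unsorted(positions, strictly = TRUE))
    .err("positions must be strictly increasing within a chromosome")
  brk <- c(0L, cumsum(diff(positions) > 2L * flank))
  unname(split(as.integer(positions), brk))
}

#' Drop fragments with too few CpGs
#'
#' @param fragments List of member-position vectors (see
#'   [merge_to_fragments()]).
#' @param min_cpgs Minimum member count to survive (default 10: fragments
#'   with fewer than ten CpGs are excluded).
#' @return Filtered list.
#' @export
filter_fragments <- function(fragments, min_cpgs = 10L) {
  fragments[lengths(fragments) >= min_cpgs]
}

#' Finalize fragments into regions
#'
#' A region spans from the first to the last member CpG (C positions,
#' 1-based inclusive), so its length is `end - start + 1`.
#'
#' @param fragments Either a list of member-position vectors (single
#'   chromosome; supply `chrom`) or a `data.table` with columns `chrom`
#'   and `members` (list).
#' @param direction `"hyper"` or `"hypo"`, recorded per region.
#' @param chrom Chromosome name when `fragments` is a plain list.
#' @return A `cash_regions` `data.table`: `chrom`, `start`, `end`,
#'   `length`, `n_cpgs`, `direction`, `members` (list column), sorted and
#'   non-overlapping.
#' @export
finalize_regions <- function(fragments, direction = "hyper",
                             chrom = "chr1") {
  if (is.list(fragments) && !is.data.frame(fragments)) {
    fragments <- data.table(chrom = rep(chrom, length(fragments)),
                            members = fragments)
  }
  x <- as.data.table(fragments)
  if (nrow(x) == 0L)
    return(structure(
      data.table(chrom = character(), start = integer(), end = integer(),
                 length = integer(), n_cpgs = integer(),
                 direction = character(), members = list()),
      class = c("cash_regions", "data.table", "data.frame")))
  out <- data.table(
    chrom = x$chrom,
    start = vapply(x$members, function(m) as.integer(min(m)), 0L),
    end = vapply(x$members, function(m) as.integer(max(m)), 0L),
    n_cpgs = lengths(x$members),
    direction = direction,
    members = x$members)
  out[, length := end - start + 1L]
  setcolorder(out, c("chrom", "start", "end", "length", "n_cpgs",
                     "direction", "members"))
  setorder(out, chrom, start)
  setattr(out, "class", c("cash_regions", "data.table", "data.frame"))
  out[]
}

#' Discover CaSH regions from tissue and plasma count tables
#'
#' Composes the full discovery pipeline: beta matrix assembly,
#' missingness filter, per-CpG differential calling, fragment merging,
#' CpG-count filter and region finalization. Stage counts (CpGs tested,
#' differential CpGs, fragments, filtered fragments, regions) are logged
#' with `message()`.
#'
#' @param tumor,normal,plasma Named lists of site tables (cytosine-report
#'   style, strand-collapsed or not) for tumor tissue, normal tissue and
#'   healthy plasma.
#' @param direction Directions to run (default both).
#' @param delta_min,plasma_thresh,fdr_max,plasma_mode See
#'   [call_differential_cpgs()]. `plasma_thresh` may be `NULL` for the
#'   per-direction default.
#' @param flank,min_cpgs See [merge_to_fragments()], [filter_fragments()].
#' @param min_coverage,max_missing_frac See [build_beta_matrix()],
#'   [missingness_filter()].
#' @return Named list of `cash_regions` tables, one per direction.
#' @export
discover_regions <- function(tumor, normal, plasma,
                             direction = c("hyper", "hypo"),
                             delta_min = 0.3, plasma_thresh = NULL,
                             fdr_max = 0.05, flank = 75L, min_cpgs = 10L,
                             min_coverage = 5L, max_missing_frac = 0.5,
                             plasma_mode = "mean") {
  direction <- match.arg(direction, several.ok = TRUE)
  if (!length(tumor) || !length(normal) || !length(plasma))
    .err("tumor, normal and plasma groups must each have at least one sample")
  samples <- c(tumor, normal, plasma)
  names(samples) <- make.unique(c(
    names(tumor) %||% paste0("tumor", seq_along(tumor)),
    names(normal) %||% paste0("normal", seq_along(normal)),
    names(plasma) %||% paste0("plasma", seq_along(plasma))))
  groups <- rep(c("tumor_tissue", "normal_tissue", "healthy_plasma"),
                c(length(tumor), length(normal), length(plasma)))
  bm <- build_beta_matrix(samples, groups, min_coverage = min_coverage)
  n0 <- nrow(bm$beta)
  bm <- missingness_filter(bm, max_missing_frac = max_missing_frac)
  message(sprintf("discovery: %d CpGs, %d after missingness filter",
                  n0, nrow(bm$beta)))
  out <- list()
  for (dir in direction) {
    cpgs <- call_differential_cpgs(bm, direction = dir,
                                   delta_min = delta_min,
                                   plasma_thresh = plasma_thresh,
                                   fdr_max = fdr_max,
                                   plasma_mode = plasma_mode)
    frags <- cpgs[, .(members = merge_to_fragments(pos, flank = flank)),
                  by = chrom]
    kept <- frags[lengths(members) >= min_cpgs]
    regions <- finalize_regions(kept[, .(chrom, members)], direction = dir)
    message(sprintf(
      "discovery [%s]: %d differential CpGs -> %d fragments -> %d with >= %d CpGs -> %d regions",
      dir, nrow(cpgs), nrow(frags), nrow(kept), min_cpgs, nrow(regions)))
    out[[dir]] <- regions
  }
  out
}
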