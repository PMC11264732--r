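## Scoring plasma read sets against CaSH regions: candidate ctDNA reads
## are fully contained in a region and carry an extreme read methylation
## density; per-region counts are CPM-normalised and averaged into the
## scalar ctCandi index.

#' Read methylation density (RMD)
#'
#' Fraction of methylated CpG calls on a read. Reads with fewer than
#' `min_calls` CpG calls are ineligible and get `NA`.
#'
#' @param reads A `meth_reads` table.
#' @param min_calls Minimum CpG calls for eligibility (default 1).
#' @return Numeric vector of densities in `[0, 1]`, `NA` for ineligible
#'   reads.
#' @export
rmd <- function(reads, min_calls = 1L) {
  x <- as.data.table(reads)
  ifelse(x$n_calls >= min_calls, x$n_meth / x$n_calls, NA_real_)
}

#' Candidate ctDNA read test
#'
#' A read is a candidate for a region when it is completely contained in
#' the region (`region.start <= read.start` and `read.end <= region.end`)
#' and its RMD is strictly above `hyper_min` (hyper direction) or strictly
#' below `hypo_max` (hypo direction). A read with RMD exactly at the
#' threshold is not a candidate.
#'
#' @param reads A `meth_reads` table.
#' @param region A single region (list/one-row table with `chrom`,
#'   `start`, `end`).
#' @param direction `"hyper"` or `"hypo"`.
#' @param hyper_min,hypo_max RMD thresholds (defaults 0.6 and 0.3).
#' @param min_calls Minimum CpG calls for RMD eligibility.
#' @return Logical vector along `reads`.
#' @export
is_candidate <- function(reads, region, direction = c("hyper", "hypo"),
                         hyper_min = 0.6, hypo_max = 0.3, min_calls = 1L) {
  direction <- match.arg(direction)
  x <- as.data.table(reads)
  d <- rmd(reads, min_calls = min_calls)
  contained <- x$chrom == region$chrom & x$start >= region$start &
    x$end <= region$end
  dens_ok <- if (direction == "hyper") d > hyper_min else d < hypo_max
  contained & !is.na(dens_ok) & dens_ok
}

#' Count candidate reads per region
#'
#' Interval search (not all-pairs): eligible reads are matched to the
#' regions that fully contain them via [IRanges::findOverlaps()] with
#' `type = "within"`. A read contributes at most one count to a region.
#'
#' @inheritParams is_candidate
#' @param regions A region table (`chrom`, `start`, `end`), sorted and
#'   non-overlapping; overlapping regions are an error.
#' @return The region table with an added `raw_count` column, input order
#'   preserved.
#' @export
count_candidates <- function(reads, regions, direction = c("hyper", "hypo"),
                             hyper_min = 0.6, hypo_max = 0.3,
                             min_calls = 1L) {
  direction <- match.arg(direction)
  reg <- as.data.table(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(reg)))
  if (.regions_overlap(reg)) .err("regions must be non-overlapping")
  x <- as.data.table(reads)
  d <- rmd(reads, min_calls = min_calls)
  keep <- if (direction == "hyper") !is.na(d) & d > hyper_min
          else !is.na(d) & d < hypo_max
  x <- x[keep]
  counts <- integer(nrow(reg))
  if (nrow(x)) {
    for (ch in unique(reg$chrom)) {
      ri <- which(reg$chrom == ch)
      qi <- which(x$chrom == ch)
      if (!length(qi)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(x$start[qi], x$end[qi]),
        IRanges::IRanges(reg$start[ri], reg$end[ri]),
        type = "within")
      tab <- tabulate(S4Vectors::subjectHits(hits), nbins = length(ri))
      counts[ri] <- counts[ri] + tab
    }
  }
  out <- copy(reg)
  out[, raw_count := counts]
  out[]
}

#' Counts-per-million normalisation
#'
#' @param raw_count Non-negative raw counts.
#' @param total_mapped_reads Positive total mapped (deduplicated) read
#'   count of the sample.
#' @return `raw_count * 1e6 / total_mapped_reads`.
#' @export
cpm_normalize <- function(raw_count, total_mapped_reads) {
  if (length(total_mapped_reads) != 1L || is.na(total_mapped_reads) ||
      total_mapped_reads <= 0)
    .err("total_mapped_reads must be a single positive number")
  raw_count * 1e6 / total_mapped_reads
}

#' ctDNA candidate count index (ctCandi) for one sample
#'
#' Counts candidate reads per region, CPM-normalises each count by the
#' sample's total mapped reads, and averages the per-region CPM values
#' over all regions (zero-count regions included), yielding the scalar
#' ctCandi.
#'
#' @inheritParams count_candidates
#' @param total_mapped_reads CPM denominator. When `NULL`, the number of
#'   reads supplied is used (or the `total_mapped_reads` attribute of
#'   `reads`, if set by the generator) and a message notes the choice.
#' @return A `ctcandi_score`: list with `per_region` (`chrom`, `start`,
#'   `end`, `raw_count`, `cpm`), `total_mapped_reads`, `n_regions` and
#'   `ctcandi`.
#' @export
score_sample <- function(reads, regions, total_mapped_reads = NULL,
                         direction = c("hyper", "hypo"), hyper_min = 0.6,
                         hypo_max = 0.3, min_calls = 1L) {
  direction <- match.arg(direction)
  reg <- as.data.table(regions)
  if (nrow(reg) == 0L) .err("empty region list")
  if (is.null(total_mapped_reads)) {
    total_mapped_reads <- attr(reads, "total_mapped_reads") %||% nrow(reads)
    message(sprintf("score_sample: using total_mapped_reads = %d",
                    as.integer(total_mapped_reads)))
  }
  rdt <- as.data.table(reads)
  if (nrow(rdt) &&
      max(reg$end - reg$start + 1L) < min(rdt$end - rdt$start + 1L))
    message("score_sample: every region is shorter than every read; ",
            "containment is impossible and all counts will be 0")
  counted <- count_candidates(reads, reg, direction = direction,
                              hyper_min = hyper_min, hypo_max = hypo_max,
                              min_calls = min_calls)
  counted[, cpm := cpm_normalize(raw_count, total_mapped_reads)]
  structure(list(
    per_region = counted[, .(chrom, start, end, raw_count, cpm)],
    total_mapped_reads = total_mapped_reads,
    n_regions = nrow(counted),
    ctcandi = mean(counted$cpm)),
    class = "ctcandi_score")
}

#' @export
print.ctcandi_score <- function(x, ...) {
  cat(sprintf("ctCandi score: %.6g over %d regions (%d candidate reads, %s mapped reads)\n",
              x$ctcandi, x$n_regions, sum(x$per_region$raw_count),
              format(x$total_mapped_reads, big.mark = ",")))
  invisible(x)
}
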