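## I/O for the three formats the pipeline touches: cytosine-report count
## tables, read-level methylation calls, and BED region files.
##
## Internal coordinate convention (everywhere in this package): 1-based,
## inclusive on both ends. A region chr6:391824-393789 has length
## 393789 - 391824 + 1 = 1966 bp. On-disk BED is 0-based half-open and is
## converted at the boundary.

#' Read a Bismark-style cytosine report
#'
#' Parses a tab-separated cytosine report with columns chrom, position
#' (1-based), strand (`+`/`-`), methylated count, unmethylated count and
#' trinucleotide context. Only CpG-context rows (`CpG` or `CG`) are
#' retained; other contexts are skipped.
#'
#' @param file Path to a (possibly headerless) TSV cytosine report.
#' @param sample_id Optional sample identifier stored in a `sample_id`
#'   column of the result.
#' @return A `data.table` with columns `chrom`, `pos`, `strand`, `meth`,
#'   `unmeth` (and `sample_id` when given), one row per CpG-context input
#'   row, positions preserved verbatim.
#' @export
read_cytosine_report <- function(file, sample_id = NULL) {
  empty <- data.table(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      unmeth = integer())
  if (!is.null(sample_id)) empty[, sample_id := character()]
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty[])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    .err("cytosine report %s: line %d has %d fields, expected 6",
         file, which(nf != 6L)[1L], nf[nf != 6L][1L])
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  int_ok <- function(v) grepl("^[0-9]+$", v)
  for (j in c(2L, 4L, 5L)) {
    bad <- which(!int_ok(m[, j]))
    if (length(bad))
      .err("cytosine report %s: line %d: non-negative integer expected in column %d, got '%s'",
           file, bad[1L], j, m[bad[1L], j])
  }
  bad <- which(!m[, 3L] %in% c("+", "-"))
  if (length(bad))
    .err("cytosine report %s: line %d: strand must be '+' or '-', got '%s'",
         file, bad[1L], m[bad[1L], 3L])
  x <- data.table(chrom = m[, 1L], pos = as.integer(m[, 2L]),
                  strand = m[, 3L], meth = as.integer(m[, 4L]),
                  unmeth = as.integer(m[, 5L]), context = m[, 6L])
  bad <- x[, which(pos < 1L)]
  if (length(bad))
    .err("cytosine report %s: line %d: position must be >= 1", file, bad[1L])
  x <- x[context %in% c("CpG", "CG")]
  x[, context := NULL]
  if (!is.null(sample_id)) set(x, j = "sample_id", value = sample_id)
  x[]
}

#' Collapse CpG counts onto the plus-strand cytosine
#'
#' The two strands of one CpG dinucleotide report the same methylation
#' state at adjacent positions: the minus-strand cytosine sits one base
#' downstream of the plus-strand cytosine. Counts from a minus-strand row
#' at position p are added to the plus-strand row at p - 1, yielding at
#' most one row per (chrom, pos). Total methylated and unmethylated counts
#' are conserved.
#'
#' @param sites A site table as returned by [read_cytosine_report()]; a
#'   `strand` column is required. A `sample_id` column, if present, is part
#'   of the collapsing key.
#' @return A `data.table` keyed by (`chrom`, `pos`) (plus `sample_id` if
#'   present) with summed `meth`/`unmeth` counts; the `strand` column is
#'   dropped.
#' @export
collapse_strands <- function(sites) {
  x <- as.data.table(sites)
  if (!"strand" %in% names(x)) .err("'sites' must have a strand column")
  x <- copy(x)
  x[strand == "-", pos := pos - 1L]
  by_cols <- intersect(c("sample_id", "chrom", "pos"), names(x))
  out <- x[, .(meth = sum(meth), unmeth = sum(unmeth)), by = by_cols]
  setorderv(out, by_cols)
  out[]
}

#' Read and write BED region files
#'
#' On disk BED intervals are 0-based half-open; internally regions are
#' 1-based inclusive, so BED `(start, end)` maps to internal
#' `(start + 1, end)` and the round trip is the identity.
#'
#' @param file Path to a BED file (at least three tab-separated columns,
#'   no header).
#' @return `read_bed_regions()`: a `data.table` with columns `chrom`,
#'   `start`, `end` (1-based inclusive) and, when a fourth BED column is
#'   present, `name`.
#' @export
read_bed_regions <- function(file) {
  nf <- utils::count.fields(file, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  if (any(nf < 3L))
    .err("BED %s: line %d has fewer than 3 fields", file, which(nf < 3L)[1L])
  x <- fread(file, header = FALSE, sep = "\t", fill = TRUE)
  out <- data.table(chrom = as.character(x[[1L]]),
                    start = as.integer(x[[2L]]) + 1L,
                    end = as.integer(x[[3L]]))
  if (ncol(x) >= 4L) out[, name := as.character(x[[4L]])]
  bad <- out[, which(start > end)]
  if (length(bad))
    .err("BED %s: line %d: start must be < end (0-based half-open)",
         file, bad[1L])
  out[]
}

#' @param regions A region table with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`.
#' @rdname read_bed_regions
#' @export
write_bed_regions <- function(regions, file) {
  x <- as.data.table(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$start > x$end)) .err("regions must have start <= end")
  out <- data.table(chrom = x$chrom, start = x$start - 1L, end = x$end)
  if ("name" %in% names(x)) out[, name := x$name]
  fwrite(out, file, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(file)
}

## ---- read-level methylation calls ------------------------------------

#' Construct/validate a meth_reads table
#'
#' A `meth_reads` object is a `data.table` with one row per aligned read
#' (each mate of a pair is an independent read): `chrom`, `start`, `end`
#' (1-based inclusive aligned span), `n_calls`, `n_meth`, and optionally
#' list columns `call_pos` (ordered reference positions of CpG calls) and
#' `call_m` (logical, methylated). Invariants: `start <= end`, call
#' positions strictly increasing and inside the aligned span,
#' `n_meth <= n_calls`.
#'
#' @param x A data.frame/data.table with at least `chrom`, `start`, `end`
#'   and either (`n_calls`, `n_meth`) or (`call_pos`, `call_m`).
#' @return The validated table with class `meth_reads`.
#' @export
as_meth_reads <- function(x) {
  x <- as.data.table(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$start > x$end)) .err("read with start > end")
  if (nrow(x) && any(x$start < 1L)) .err("read with start < 1")
  has_detail <- all(c("call_pos", "call_m") %in% names(x))
  if (has_detail) {
    nc <- lengths(x$call_pos)
    if (any(nc != lengths(x$call_m)))
      .err("call_pos and call_m lengths differ")
    x[, n_calls := nc]
    x[, n_meth := vapply(call_m, function(m) sum(as.logical(m)), 0L)]
    for (i in which(nc > 0L)) {
      p <- x$call_pos[[i]]
      if (is.unsorted(p, strictly = TRUE))
        .err("read %d: call positions must be strictly increasing", i)
      if (p[1L] < x$start[i] || p[length(p)] > x$end[i])
        .err("read %d: call position outside aligned span", i)
    }
  } else if (!all(c("n_calls", "n_meth") %in% names(x))) {
    .err("need n_calls/n_meth or call_pos/call_m columns")
  }
  if (nrow(x) && any(x$n_meth > x$n_calls)) .err("n_meth > n_calls")
  setattr(x, "class", unique(c("meth_reads", class(x))))
  x[]
}

#' Read per-read CpG methylation calls
#'
#' Two dialects are supported. `"tsv"` is the package's plain-text read
#' dialect: five tab-separated columns `chrom`, `start`, `end` (1-based
#' inclusive), a call string of `M` (methylated) / `u` (unmethylated), and
#' comma-separated 0-based CpG offsets from `start` (call string and
#' offsets both `.` for a read without CpG calls). `"sam"` accepts SAM/BAM
#' alignments carrying Bismark-style `XM` tags (`Z` = methylated CpG,
#' `z` = unmethylated CpG, all other symbols ignored); it requires the
#' Rsamtools, GenomicAlignments and Biostrings packages.
#'
#' @param file Path to the read file.
#' @param dialect `"tsv"` or `"sam"`.
#' @param sample_id Optional sample identifier (stored as an attribute).
#' @return A [as_meth_reads()] table with call detail columns.
#' @export
read_meth_reads <- function(file, dialect = c("tsv", "sam"),
                            sample_id = NULL) {
  dialect <- match.arg(dialect)
  out <- if (dialect == "tsv") .read_reads_tsv(file) else .read_reads_sam(file)
  if (!is.null(sample_id)) setattr(out, "sample_id", sample_id)
  out
}

.read_reads_tsv <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(as_meth_reads(data.table(
      chrom = character(), start = integer(), end = integer(),
      call_pos = list(), call_m = list())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L))
    .err("read TSV %s: line %d has %d fields, expected 5",
         file, which(nf != 5L)[1L], nf[nf != 5L][1L])
  m <- matrix(unlist(fields), ncol = 5L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end))
    .err("read TSV %s: non-integer start/end", file)
  call_pos <- vector("list", nrow(m))
  call_m <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    calls <- m[i, 4L]
    offs <- m[i, 5L]
    if (calls == "." || calls == "") {
      call_pos[[i]] <- integer()
      call_m[[i]] <- logical()
      next
    }
    ch <- strsplit(calls, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% c("M", "u")))
      .err("read TSV %s: line %d: call string may contain only 'M'/'u'",
           file, i)
    off <- suppressWarnings(as.integer(strsplit(offs, ",", fixed = TRUE)[[1L]]))
    if (anyNA(off) || length(off) != length(ch))
      .err("read TSV %s: line %d: offsets must be %d comma-separated integers",
           file, i, length(ch))
    p <- start[i] + off
    if (is.unsorted(p, strictly = TRUE))
      .err("read TSV %s: line %d: call positions must be strictly increasing",
           file, i)
    if (p[1L] < start[i] || p[length(p)] > end[i])
      .err("read TSV %s: line %d: call position outside aligned span",
           file, i)
    call_pos[[i]] <- p
    call_m[[i]] <- ch == "M"
  }
  as_meth_reads(data.table(chrom = m[, 1L], start = start, end = end,
                           call_pos = call_pos, call_m = call_m))
}

.read_reads_sam <- function(file) {
  for (pkg in c("Rsamtools", "GenomicAlignments", "Biostrings"))
    if (!requireNamespace(pkg, quietly = TRUE))
      .err("SAM/BAM support needs the %s package", pkg)
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE))
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(tag = "XM"))
  xm <- S4Vectors::mcols(ga)$XM
  if (length(ga) && all(is.na(xm))) .err("no XM tags found in %s", file)
  ## project the per-query call string onto reference coordinates so
  ## insertions are dropped and deletions padded
  ref <- as.character(GenomicAlignments::sequenceLayer(
    Biostrings::BStringSet(ifelse(is.na(xm), "", xm)),
    GenomicAlignments::cigar(ga), from = "query", to = "reference"))
  starts <- GenomicAlignments::start(ga)
  call_pos <- vector("list", length(ga))
  call_m <- vector("list", length(ga))
  for (i in seq_along(ga)) {
    ch <- strsplit(ref[i], "", fixed = TRUE)[[1L]]
    k <- which(ch %in% c("Z", "z"))
    call_pos[[i]] <- starts[i] + k - 1L
    call_m[[i]] <- ch[k] == "Z"
  }
  as_meth_reads(data.table(
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = starts, end = GenomicAlignments::end(ga),
    call_pos = call_pos, call_m = call_m))
}

#' @param reads A `meth_reads` table with call detail columns.
#' @rdname read_meth_reads
#' @export
write_meth_reads <- function(reads, file) {
  x <- as.data.table(reads)
  if (!all(c("call_pos", "call_m") %in% names(x)))
    .err("writing the TSV read dialect requires call detail columns")
  calls <- vapply(x$call_m, function(m) {
    if (!length(m)) "." else paste(ifelse(m, "M", "u"), collapse = "")
  }, "")
  offs <- mapply(function(p, s) {
    if (!length(p)) "." else paste(p - s, collapse = ",")
  }, x$call_pos, x$start)
  writeLines(paste(x$chrom, x$start, x$end, calls, offs, sep = "\t"), file)
  invisible(file)
}
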