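`%||%` <- function(x, y) if (is.null(x)) y else x

## Stop with a sprintf-formatted message, no call in the condition.
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    .err("'%s' must be a single number in [%s, %s]", name,
         format(min), format(max))
  invisible(x)
}

.assert_whole <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) ||
      x < min)
    .err("'%s' must be a single integer >= %s", name, format(min))
  invisible(as.integer(x))
}

## n seeds derived from one master seed; each < 2^31 so they are valid
## R integer seeds whatever the caller passed.
.derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Closed-interval overlap check used by several validators.
.regions_overlap <- function(regions) {
  if (nrow(regions) < 2L) return(FALSE)
  x <- data.table::as.data.table(regions)[order(chrom, start)]
  any(x[, c(FALSE, end[-.N] >= start[-1L] & chrom[-.N] == chrom[-1L])])
}
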