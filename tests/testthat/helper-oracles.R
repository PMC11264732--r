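## Brute-force oracles and small fixture builders shared across tests.
## Oracles are deliberately naive and independent of the implementation
## paths they check.

## Closed-interval union: expand each position by `flank` on both sides
## and group positions whose expansions overlap or touch, by exhaustive
## pairwise chaining.
oracle_interval_union <- function(positions, flank) {
  n <- length(positions)
  if (n == 0L) return(list())
  lo <- positions - flank
  hi <- positions + flank
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] && lo[i] <= hi[j] && lo[j] <= hi[i]) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(grp[order(positions)]), function(g)
    sort(positions[grp == g]))
  out[order(vapply(out, min, 0))]
}

## Exact two-sided rank-sum p by enumerating all C(n1+n2, n1) rank
## assignments (no ties assumed).
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  u_all <- apply(combs, 2L, function(ix) sum(ranks[ix])) -
    n1 * (n1 + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

## AUC by averaging over all case-control pairs, ties counted half.
oracle_auc <- function(scores, labels) {
  cs <- scores[labels]; ct <- scores[!labels]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

## Candidate counting by testing every read against every region.
oracle_count_candidates <- function(reads, regions, direction = "hyper",
                                    hyper_min = 0.6, hypo_max = 0.3,
                                    min_calls = 1L) {
  vapply(seq_len(nrow(regions)), function(j) {
    sum(is_candidate(reads, as.list(regions[j, ]), direction = direction,
                     hyper_min = hyper_min, hypo_max = hypo_max,
                     min_calls = min_calls))
  }, 0)
}

## Build a meth_reads table from a compact description: a data.frame with
## chrom/start/end plus a `calls` character column like "M@110,u@150".
toy_reads <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  call_pos <- vector("list", nrow(df))
  call_m <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    spec <- df$calls[i]
    if (is.na(spec) || spec == "") {
      call_pos[[i]] <- integer(); call_m[[i]] <- logical()
    } else {
      parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1L]], "@",
                        fixed = TRUE)
      call_pos[[i]] <- as.integer(vapply(parts, `[`, "", 2L))
      call_m[[i]] <- vapply(parts, `[`, "", 1L) == "M"
    }
  }
  as_meth_reads(data.table::data.table(
    chrom = df$chrom, start = as.integer(df$start),
    end = as.integer(df$end), call_pos = call_pos, call_m = call_m))
}

## Random detail-free meth_reads for counting/mixing property tests.
random_reads <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000L,
                         len_range = c(50L, 200L)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  n_calls <- sample(0:8, n, replace = TRUE)
  as_meth_reads(data.table::data.table(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len - 1L,
    n_calls = n_calls,
    n_meth = vapply(n_calls, function(k) sample(0:k, 1L), 0L)))
}

## Directly assemble a beta_matrix object from a numeric matrix.
toy_beta_matrix <- function(beta, groups, chrom = "chr1",
                            pos = NULL) {
  beta <- as.matrix(beta)
  pos <- pos %||% (seq_len(nrow(beta)) * 1000L)
  ids <- paste0("s", seq_len(ncol(beta)))
  colnames(beta) <- ids
  structure(list(
    sites = data.table::data.table(chrom = chrom, pos = as.integer(pos)),
    beta = beta, groups = stats::setNames(groups, ids)),
    class = "beta_matrix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Tissue count tables for a fully null genome: every group drawn from
## the same (healthy-plasma) profile law.
null_tissue_counts <- function(genome, n_per_group = 5L, seed = 99L) {
  groups <- rep("healthy_plasma", 3L * n_per_group)
  prof <- make_profiles(genome, groups, seed = seed)
  counts <- emit_counts(prof, genome, seed = seed + 1L)
  idx <- split(seq_along(groups), rep(c("tumor", "normal", "plasma"),
                                      each = n_per_group))
  list(tumor = counts[idx$tumor], normal = counts[idx$normal],
       plasma = counts[idx$plasma])
}
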