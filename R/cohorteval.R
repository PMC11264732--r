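## Cohort-level evaluation: cross-validated logistic classification of
## case vs control plasma from per-region candidate counts, and
## longitudinal monitoring analytics.

#' ROC AUC via the Mann-Whitney identity
#'
#' AUC equals the probability that a random case outscores a random
#' control, ties counted one half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Logical, or factor/character/0-1 coercible; `TRUE`/`"case"`/1
#'   marks cases. Both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  lab <- .as_case_logical(labels)
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L) .err("both classes must be present")
  r <- rank(scores)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels <- as.character(labels)
  u <- sort(unique(labels))
  if (all(u %in% c("case", "control"))) return(labels == "case")
  if (length(u) > 2L) .err("labels must have two classes")
  labels == u[2L]
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return `data.table` with `threshold` (predict case when
#'   `score >= threshold`), `tpr` (sensitivity) and `fpr`
#'   (1 - specificity), from the all-negative to the all-positive end.
#' @export
roc_curve <- function(scores, labels) {
  lab <- .as_case_logical(labels)
  if (!any(lab) || all(lab)) .err("both classes must be present")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  out <- data.table(threshold = th)
  out[, `:=`(
    tpr = vapply(th, function(t) mean(scores[lab] >= t), 0),
    fpr = vapply(th, function(t) mean(scores[!lab] >= t), 0))]
  out[]
}

#' Youden operating point
#'
#' Scans all thresholds of the ROC (predict case when
#' `score >= threshold`) and returns the one maximising Youden's
#' J = sensitivity + specificity - 1, breaking ties toward higher
#' specificity (i.e. the more conservative, higher threshold).
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_operating_point <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  roc[, j := tpr - fpr]
  spec <- 1 - roc$fpr
  best <- which(roc$j == max(roc$j))
  best <- best[which.max(spec[best])]
  list(threshold = roc$threshold[best], sensitivity = roc$tpr[best],
       specificity = spec[best], j = roc$j[best])
}

#' Cross-validated unpenalized logistic regression
#'
#' Stratified k-fold cross-validation of an unpenalized (maximum
#' likelihood) logistic regression on per-region CPM features. The
#' negative log-likelihood is minimised with L-BFGS from a zero start
#' with a capped iteration count: under complete separation the MLE does
#' not exist, and an early-stopped quasi-Newton fit retains a
#' well-behaved separating direction (Newton/IRLS picks an essentially
#' arbitrary one, which ranks held-out samples poorly). Each fold
#' reports its out-of-fold ROC, AUC and the Youden operating point.
#'
#' @param features Samples x regions numeric matrix (or data.frame), or a
#'   single numeric vector for the scalar model.
#' @param labels Case/control labels (see [roc_auc()]).
#' @param k Number of folds (default 3).
#' @param seed Integer seed for the stratified fold assignment.
#' @param feature_mode `"vector"` uses the full per-region matrix,
#'   `"scalar"` collapses it to its row mean (the scalar ctCandi).
#' @param maxit Iteration cap for the ML fit.
#' @return A `cv_result`: list with `folds` (per-fold list: `fold`,
#'   `auc`, `threshold`, `sensitivity`, `specificity`, `roc`), `oof`
#'   (out-of-fold table: `sample`, `fold`, `score`, `label`), `mean_auc`,
#'   `auc_range`, `mean_sensitivity`, `mean_specificity`.
#' @export
fit_logistic_cv <- function(features, labels, k = 3L, seed = 1L,
                            feature_mode = c("vector", "scalar"),
                            maxit = 100L) {
  feature_mode <- match.arg(feature_mode)
  X <- as.matrix(features)
  if (feature_mode == "scalar" && ncol(X) > 1L)
    X <- matrix(rowMeans(X), ncol = 1L)
  lab <- .as_case_logical(labels)
  if (nrow(X) != length(lab)) .err("features and labels disagree in length")
  k <- .assert_whole(k, "k", min = 2L)
  if (min(sum(lab), sum(!lab)) < k)
    .err("each class needs at least k samples for stratified folds")
  fold <- integer(length(lab))
  withr::with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(lab == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  oof <- data.table(sample = seq_along(lab), fold = fold,
                    score = NA_real_, label = lab)
  folds <- vector("list", k)
  any_nonconv <- FALSE
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (length(unique(lab[tr])) < 2L || length(unique(lab[te])) < 2L)
      .err("fold %d has a single class; re-stratify", f)
    fit <- .logistic_ml(X[tr, , drop = FALSE], lab[tr], maxit = maxit)
    if (!fit$converged) any_nonconv <- TRUE
    sc <- as.vector(plogis(cbind(1, X[te, , drop = FALSE]) %*% fit$coef))
    oof[te, score := sc]
    yp <- youden_operating_point(sc, lab[te])
    folds[[f]] <- list(fold = f, auc = roc_auc(sc, lab[te]),
                       threshold = yp$threshold,
                       sensitivity = yp$sensitivity,
                       specificity = yp$specificity,
                       roc = roc_curve(sc, lab[te]))
  }
  if (any_nonconv)
    message("fit_logistic_cv: L-BFGS hit the iteration cap in at least ",
            "one fold (likely separation); the early-stopped direction ",
            "is retained")
  aucs <- vapply(folds, `[[`, 0, "auc")
  structure(list(
    folds = folds, oof = oof,
    mean_auc = mean(aucs), auc_range = range(aucs),
    mean_sensitivity = mean(vapply(folds, `[[`, 0, "sensitivity")),
    mean_specificity = mean(vapply(folds, `[[`, 0, "specificity"))),
    class = "cv_result")
}

## Unpenalized logistic ML fit: L-BFGS on the negative log-likelihood,
## zero start, capped iterations. Stable log1p-based likelihood.
.logistic_ml <- function(X, y, maxit = 100L) {
  X1 <- cbind(1, X)
  y <- as.numeric(y)
  nll <- function(b) {
    eta <- as.vector(X1 %*% b)
    sum(log1p(exp(-abs(eta)))) + sum(pmax(eta, 0)) - sum(eta * y)
  }
  grd <- function(b) {
    p <- plogis(as.vector(X1 %*% b))
    as.vector(crossprod(X1, p - y))
  }
  o <- stats::optim(rep(0, ncol(X1)), nll, grd, method = "L-BFGS-B",
                    control = list(maxit = maxit))
  list(coef = o$par, converged = o$convergence == 0L)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV: mean AUC %.3f (%.3f-%.3f), mean sensitivity %.1f%%, mean specificity %.1f%%\n",
    length(x$folds), x$mean_auc, x$auc_range[1], x$auc_range[2],
    100 * x$mean_sensitivity, 100 * x$mean_specificity))
  invisible(x)
}

#' Two-group score comparison
#'
#' Two-sided Wilcoxon rank-sum test between two sets of ctCandi scores
#' (e.g. cases vs controls); delegates to [rank_sum_test()].
#'
#' @param scores_a,scores_b Numeric score vectors.
#' @return Two-sided p-value.
#' @export
group_compare <- function(scores_a, scores_b) rank_sum_test(scores_a, scores_b)

#' Longitudinal post-operative deltas
#'
#' For each patient with a pre-operative baseline, computes the change in
#' ctCandi at each later timepoint and flags strict decreases. Patients
#' without a baseline row are skipped with a warning.
#'
#' @param series `data.table`/data.frame with columns `patient_id`,
#'   `timepoint` and `ctcandi`.
#' @param baseline The `timepoint` value that marks the pre-operative
#'   sample (default `"pre"`).
#' @return `data.table` (`patient_id`, `timepoint`, `ctcandi`, `delta`,
#'   `decreased`) for non-baseline timepoints; attribute `summary` holds
#'   per-timepoint decreased fractions.
#' @export
longitudinal_deltas <- function(series, baseline = "pre") {
  x <- as.data.table(series)
  stopifnot(all(c("patient_id", "timepoint", "ctcandi") %in% names(x)))
  has_pre <- x[, .(ok = any(timepoint == baseline)), by = patient_id]
  missing_pre <- has_pre[ok == FALSE, patient_id]
  if (length(missing_pre))
    warning(sprintf("skipping %d patient(s) without a '%s' baseline: %s",
                    length(missing_pre), baseline,
                    paste(missing_pre, collapse = ", ")), call. = FALSE)
  x <- x[!patient_id %in% missing_pre]
  pre <- x[timepoint == baseline, .(pre_value = ctcandi[1L]),
           by = patient_id]
  out <- merge(x[timepoint != baseline], pre, by = "patient_id")
  out[, `:=`(delta = ctcandi - pre_value, decreased = ctcandi < pre_value)]
  out[, pre_value := NULL]
  setorder(out, patient_id, timepoint)
  smry <- out[, .(n = .N, n_decreased = sum(decreased),
                  frac_decreased = mean(decreased)), by = timepoint]
  setattr(out, "summary", smry[])
  out[]
}

#' Per-region contribution to a paired pre/post decrease
#'
#' For each region, a two-sided paired Wilcoxon signed-rank test of
#' pre-operative vs post-operative per-region CPM counts across matched
#' patients, with BH adjustment. The signed-rank p-value is computed by
#' exact enumeration of all sign assignments when at most 12 non-zero
#' differences remain (valid under tied magnitudes), and by the normal
#' approximation with tie and continuity corrections otherwise. Regions
#' are ranked by q-value, ties broken by the median paired decrease.
#' Regions with fewer than two complete pairs are skipped; a region whose
#' pairs are all exactly equal gets p = 1.
#'
#' @param pre,post Patients x regions numeric matrices with matching
#'   dimensions (and dimnames, when present).
#' @return `data.table` (`region`, `n_pairs`, `p_value`, `q_value`,
#'   `median_delta`), ordered by q then decreasing median delta.
#' @export
region_contribution <- function(pre, post) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!all(dim(pre) == dim(post)))
    .err("pre and post must have identical dimensions")
  regions <- colnames(pre) %||% paste0("region", seq_len(ncol(pre)))
  rows <- lapply(seq_len(ncol(pre)), function(j) {
    a <- pre[, j]; b <- post[, j]
    ok <- !(is.na(a) | is.na(b))
    if (sum(ok) < 2L) return(NULL)
    d <- a[ok] - b[ok]
    data.table(region = regions[j], n_pairs = sum(ok),
               p_value = .signed_rank_test(d), median_delta = median(d))
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L)
    return(data.table(region = character(), n_pairs = integer(),
                      p_value = numeric(), q_value = numeric(),
                      median_delta = numeric()))
  out[, q_value := bh_fdr(p_value)]
  setorder(out, q_value, -median_delta)
  setcolorder(out, c("region", "n_pairs", "p_value", "q_value",
                     "median_delta"))
  out[]
}

## Two-sided Wilcoxon signed-rank p-value on paired differences. Zero
## differences are dropped (all-zero -> p = 1). Exact enumeration of the
## 2^n sign assignments when n <= 12 (also valid under tied magnitudes);
## otherwise normal approximation with tie and continuity corrections.
.signed_rank_test <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- 2 * min(mean(w_all <= W), mean(w_all >= W))
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  if (sigma2 <= 0) return(1)
  z <- max(abs(W - mu) - 0.5, 0) / sqrt(sigma2)
  min(1, 2 * pnorm(-z))
}

#' Spearman correlation of ctCandi with a covariate
#'
#' Delegates to [spearman_cor()] (e.g. ctCandi vs tumor size).
#'
#' @param ctcandi_scores,covariate Numeric vectors of equal length.
#' @return List with `rho` and `p_value`.
#' @export
covariate_correlation <- function(ctcandi_scores, covariate) {
  spearman_cor(ctcandi_scores, covariate)
}
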