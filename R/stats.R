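#' ROC analysis of a continuous RWA parameter
#'
#' The AUC is the normalized Mann-Whitney statistic (probability that a
#' random positive scores above a random negative, ties counted one half),
#' computed from ranks and therefore exactly equal to pairwise counting. The
#' standard error and 95% confidence interval use DeLong's method. The cut
#' point maximizes Youden's J (sensitivity + specificity - 1), ties broken
#' toward higher specificity; the maximum sensitivity attainable at
#' specificity 1 is reported alongside, matching how visual RWA cut-offs are
#' usually quoted.
#'
#' @param scores Numeric scores (higher = more RBD-like).
#' @param labels Binary labels: logical, 0/1, or a two-level factor whose
#'   second level is the positive class.
#' @return An object of class `rwa_roc`: `auc`, `se`, `ci95` (length 2),
#'   `cut_point`, `sensitivity`, `specificity`, `cut_point_spec1`,
#'   `sensitivity_spec1`, `n_pos`, `n_neg`, `curve` (tibble of all operating
#'   points).
#' @examples
#' r <- roc(c(1, 2, 3, 0, 1.5), c(TRUE, TRUE, TRUE, FALSE, FALSE))
#' r$auc # 5/6
#' @export
roc <- function(scores, labels) {
  lab <- .as_binary(labels)
  if (anyNA(scores) || anyNA(lab)) stop("missing scores or labels")
  if (length(scores) != length(lab)) stop("scores and labels differ in length")
  n_pos <- sum(lab)
  n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")

  # Mann-Whitney AUC via midranks: ties count 1/2 exactly
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  se <- sqrt(.delong_var(scores[lab], scores[!lab]))
  ci <- pmin(1, pmax(0, auc + stats::qnorm(c(0.025, 0.975)) * se))

  curve <- .roc_curve(scores, lab)
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.max(curve$specificity[best])]
  spec1 <- curve[curve$specificity == 1, , drop = FALSE]
  i1 <- which.max(spec1$sensitivity)

  structure(
    list(
      auc = auc, se = se, ci95 = ci,
      cut_point = curve$threshold[best],
      sensitivity = curve$sensitivity[best],
      specificity = curve$specificity[best],
      cut_point_spec1 = spec1$threshold[i1],
      sensitivity_spec1 = spec1$sensitivity[i1],
      n_pos = n_pos, n_neg = n_neg,
      curve = curve
    ),
    class = "rwa_roc"
  )
}

#' @export
print.rwa_roc <- function(x, ...) {
  cat(sprintf(
    "<rwa_roc> AUC = %.3f (95%% CI %.3f-%.3f, SE %.4f), n = %d/%d\n",
    x$auc, x$ci95[1], x$ci95[2], x$se, x$n_pos, x$n_neg
  ))
  cat(sprintf(
    "  Youden cut point %.4g: sensitivity %.2f, specificity %.2f\n",
    x$cut_point, x$sensitivity, x$specificity
  ))
  cat(sprintf(
    "  at specificity 1.00: cut point %.4g, sensitivity %.2f\n",
    x$cut_point_spec1, x$sensitivity_spec1
  ))
  invisible(x)
}

.as_binary <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("factor labels must have two levels")
    return(labels == levels(labels)[2])
  }
  if (is.logical(labels)) return(labels)
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
  labels == 1
}

# all operating points: classify positive when score > threshold
.roc_curve <- function(scores, lab) {
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(scores[lab] > t), 1)
  spec <- vapply(thr, function(t) mean(scores[!lab] <= t), 1)
  tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec)
}

# DeLong variance of a single AUC (components V10, V01)
.delong_var <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), 1)
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), 1)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  s10 / m + s01 / n
}

#' Compare two correlated ROC curves (paired DeLong test)
#'
#' Tests whether two scoring parameters measured on the *same* subjects
#' differ in AUC, using DeLong's method for correlated ROC curves (via pROC).
#' Bit-identical score vectors are a degenerate case with zero variance of
#' the AUC difference; the comparison then returns `z = 0, p = 1`.
#'
#' @param scores_a,scores_b Two score vectors on the same subjects.
#' @param labels Binary labels (see [roc()]).
#' @return A list with `z` (statistic), `p` (two-sided), `auc_a`, `auc_b`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired comparison requires equal-length score vectors")
  }
  lab <- .as_binary(labels)
  ra <- roc(scores_a, lab)
  rb <- roc(scores_b, lab)
  if (isTRUE(all(scores_a == scores_b))) {
    return(list(z = 0, p = 1, auc_a = ra$auc, auc_b = rb$auc))
  }
  pa <- pROC::roc(response = lab, predictor = scores_a,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  pb <- pROC::roc(response = lab, predictor = scores_b,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  tst <- pROC::roc.test(pa, pb, method = "delong", paired = TRUE)
  list(
    z = unname(tst$statistic), p = unname(tst$p.value),
    auc_a = ra$auc, auc_b = rb$auc
  )
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return A list with `r` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way ANOVA with Bonferroni post-hoc t-tests
#'
#' Classic one-way ANOVA across groups, followed by all pairwise two-sample
#' t-tests (equal-variance) whose p-values are multiplied by the number of
#' pairs (capped at 1).
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @return A list with `F`, `p`, `df`, and `pairwise`, a tibble of
#'   `group1`, `group2`, `p_raw`, `p_adj`.
#' @export
anova_bonferroni <- function(values, groups) {
  groups <- factor(groups)
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  sizes <- table(groups)
  if (nlevels(groups) < 2L || any(sizes < 2L)) {
    stop("need >= 2 groups with >= 2 observations each")
  }
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  pairs <- utils::combn(levels(groups), 2)
  n_pairs <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    tt <- stats::t.test(values[groups == g1], values[groups == g2],
                        var.equal = TRUE)
    tibble::tibble(group1 = g1, group2 = g2, p_raw = tt$p.value,
                   p_adj = min(1, tt$p.value * n_pairs))
  })
  list(
    F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
    df = c(s[["Df"]][1], s[["Df"]][2]),
    pairwise = pw
  )
}

#' Fisher's exact test on a 2 x k contingency table
#'
#' Exact conditional test with all margins fixed (hypergeometric enumeration
#' for 2 x 2, network algorithm for larger tables).
#'
#' @param table A 2 x k matrix of non-negative integer counts.
#' @return The exact two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("empty row or column margin")
  }
  stats::fisher.test(table)$p.value
}

#' Simple linear regression with R-squared and overall F
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, intercept,
#' coefficient of determination, and the overall F statistic with its p-value
#' (for one predictor, F = t² of the slope).
#'
#' @param x Predictor (non-constant, length >= 3).
#' @param y Response.
#' @return A list with `slope`, `intercept`, `r2`, `F`, `p`, `n`.
#' @export
linreg <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  fstat <- s$fstatistic
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = s$r.squared,
    F = unname(fstat[1]),
    p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = length(x)
  )
}

#' Bonferroni-corrected correlation matrix
#'
#' Pearson correlations of one set of columns against another, with p-values
#' Bonferroni-corrected over the whole family of tests computed in this one
#' call.
#'
#' @param data A data frame.
#' @param xvars,yvars Column names to correlate (every x against every y).
#' @return A tibble with `x`, `y`, `r`, `p_raw`, `p_adj`, `n`.
#' @export
correlation_table <- function(data, xvars, yvars) {
  grid <- expand.grid(x = xvars, y = yvars, stringsAsFactors = FALSE)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    xv <- grid$x[i]; yv <- grid$y[i]
    res <- tryCatch(pearson(data[[xv]], data[[yv]]), error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(x = xv, y = yv, r = NA_real_, p_raw = NA_real_,
                            n = NA_integer_))
    }
    tibble::tibble(x = xv, y = yv, r = res$r, p_raw = res$p, n = res$n)
  })
  m <- sum(!is.na(out$p_raw))
  out$p_adj <- pmin(1, out$p_raw * m)
  out
}
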