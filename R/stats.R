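# Evaluation statistics: AUC with DeLong variance, the paired DeLong test
# for correlated ROC curves, the exact McNemar test, Fisher's exact test,
# the Dice similarity coefficient, and sensitivity/specificity at an
# operating point.

# Placement values (DeLong structural components). labels: 0/1, 1 = positive.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  assert_that(length(x) > 0 && length(y) > 0, "both classes must be present")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), auc = mean(psi))
}

#' ROC AUC with DeLong variance and Wald 95% CI
#'
#' AUC by the Mann–Whitney statistic with half credit for ties; variance
#' from DeLong's structural components; Wald 95% interval clipped to
#' `[0, 1]`.
#'
#' @param scores numeric scores (higher = more malignant).
#' @param labels 0/1 vector, 1 = malignant; both classes required.
#' @return object of class `auc_estimate`: `auc`, `var`, `ci` (length 2),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  pl <- delong_placements(scores, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  v <- (if (m > 1) var(pl$v10) / m else 0) + (if (n > 1) var(pl$v01) / n else 0)
  ci <- clip01(pl$auc + c(-1, 1) * 1.959964 * sqrt(v))
  structure(list(auc = pl$auc, var = v, ci = ci, n_pos = m, n_neg = n),
            class = "auc_estimate")
}

#' DeLong test for two correlated AUCs
#'
#' Both score vectors must be paired on the identical case roster. The
#' covariance of the two AUCs comes from the shared placement values;
#' `z = (auc1 - auc2) / sqrt(var1 + var2 - 2 cov)` with a two-sided normal
#' p-value. Identical score vectors (zero-variance difference) give p = 1 by
#' convention.
#'
#' @param scores1,scores2 paired scores from the two arms.
#' @param labels shared 0/1 labels.
#' @return list: `auc1`, `auc2`, `var1`, `var2`, `cov`, `z`, `p`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  assert_that(length(scores1) == length(scores2) &&
                length(scores1) == length(labels),
              "arms must be paired on the same cases")
  labels <- as.integer(labels)
  p1 <- delong_placements(scores1, labels)
  p2 <- delong_placements(scores2, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  v1 <- s10[1, 1] / m + s01[1, 1] / n
  v2 <- s10[2, 2] / m + s01[2, 2] / n
  cv <- s10[1, 2] / m + s01[1, 2] / n
  vd <- v1 + v2 - 2 * cv
  if (identical(scores1, scores2) || vd <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- (p1$auc - p2$auc) / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc1 = p1$auc, auc2 = p2$auc, var1 = v1, var2 = v2, cov = cv,
       z = z, p = p)
}

#' Exact McNemar test on discordant pairs
#'
#' Exact binomial test on the `n = b + c` discordant pairs with success
#' probability 1/2: `p = min(1, 2 * P(Binom(n, 1/2) <= min(b, c)))`; with no
#' discordant pairs p = 1.
#'
#' @param b cases where arm 1 is correct and arm 2 wrong.
#' @param c cases where arm 1 is wrong and arm 2 correct.
#' @return two-sided p-value.
#' @export
mcnemar_exact <- function(b, c) {
  assert_that(b >= 0 && c >= 0 && b == round(b) && c == round(c),
              "discordant counts must be non-negative integers")
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * pbinom(min(b, c), n, 0.5))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided conditional exact test: the sum of hypergeometric probabilities
#' of all tables with the same margins whose point probability does not
#' exceed the observed one (computed by [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integer counts (e.g. the
#'   [localization_table()] layout: benign/malignant by correct/incorrect).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  assert_that(all(dim(table) == 2), "table must be 2x2")
  assert_that(all(table >= 0) && all(table == round(table)),
              "cells must be non-negative integers")
  assert_that(sum(table) > 0, "all-zero table")
  fisher.test(table)$p.value
}

#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2 |A ∩ B| / (|A| + |B|)` by exact pixel counts; symmetric;
#' undefined (error) when both masks are empty.
#'
#' @param m_s,m_g binary masks of identical shape.
#' @return DSC in `[0, 1]`.
#' @export
dice_coefficient <- function(m_s, m_g) {
  assert_that(all(dim(m_s) == dim(m_g)), "mask shapes differ")
  a <- sum(m_s != 0); b <- sum(m_g != 0)
  assert_that(a + b > 0, "DSC undefined for two empty masks")
  2 * sum((m_s != 0) & (m_g != 0)) / (a + b)
}

#' Sensitivity and specificity at an operating threshold
#'
#' Malignant-positive convention: a case is called positive when its score
#' (POM) is `>= threshold`.
#'
#' @param scores numeric POMs.
#' @param labels 0/1 vector, 1 = malignant.
#' @param threshold operating point (default 0.5).
#' @return list: `sensitivity`, `specificity`, counts `tp`, `fn`, `tn`,
#'   `fp`, and display strings `sens_str`/`spec_str` in
#'   `"x% (num/den)"` form.
#' @export
sens_spec <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  assert_that(length(unique(labels)) == 2, "both classes must be present")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec, tp = tp, fn = fn, tn = tn,
       fp = fp,
       sens_str = sprintf("%.0f%% (%d/%d)", 100 * sens, tp, tp + fn),
       spec_str = sprintf("%.0f%% (%d/%d)", 100 * spec, tn, tn + fp))
}
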