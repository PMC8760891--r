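# Diagnostic-accuracy and agreement statistics: Pearson correlation,
# Bland-Altman, Mann-Whitney group comparison, ROC with DeLong variance,
# Youden-index threshold selection, McNemar paired proportions, and a
# cohort-level evaluation table.

#' Pearson product-moment correlation
#'
#' @param x,y paired finite numeric vectors, n >= 3.
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    pq_error("pq_bad_params", "need paired vectors of length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    pq_error("pq_bad_params", "non-finite inputs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    pq_error("pq_degenerate_input", "zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = auto - manual`; bias = mean(d); limits of agreement =
#' bias +/- 1.96 sd(d); `bias_p` is the two-sided one-sample t-test p-value
#' for mean difference != 0 (0 or 1 by convention when sd(d) = 0).
#'
#' @param auto,manual paired measurements, length >= 3.
#' @return list of class `AgreementResult`: `pearson_r`, `bias`, `loa`,
#'   `bias_p`.
#' @export
bland_altman <- function(auto, manual) {
  if (length(auto) != length(manual) || length(auto) < 3)
    pq_error("pq_bad_params", "need paired vectors of length >= 3")
  d <- auto - manual
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  bias_p <- if (s == 0) {
    if (bias == 0) 1 else 0
  } else stats::t.test(d)$p.value
  r <- if (stats::sd(auto) > 0 && stats::sd(manual) > 0)
    stats::cor(auto, manual) else NA_real_
  structure(list(pearson_r = r, bias = bias, loa = loa, bias_p = bias_p,
                 sd_diff = s, n = length(d)),
            class = "AgreementResult")
}

#' Mann-Whitney rank-sum test
#'
#' Exact two-sided p for `min(n1, n2) <= 8` with no ties, normal
#' approximation (with tie correction and continuity correction) otherwise.
#'
#' @param a,b nonempty numeric samples.
#' @return `list(U =, p =)`; `U` is the count of (a, b) pairs with a > b
#'   (ties counted 1/2).
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b))
    pq_error("pq_bad_params", "both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

# DeLong structural components: for positives x (n_pos) and negatives y,
# V10[i] = mean_j psi(x_i, y_j), V01[j] = mean_i psi(x_i, y_j),
# psi = 1 / 0.5 / 0 for x > y / x == y / x < y. AUC = mean(V10) = mean(V01).
delong_components <- function(pos, neg) {
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' ROC analysis with DeLong standard error
#'
#' AUC equals the Mann-Whitney concordance probability (ties count 1/2).
#' `direction = "lower"` means lower marker values indicate the positive
#' (diseased) class, the convention for perfusion metrics; values are negated
#' internally. The 95% CI is `auc +/- 1.96 SE`, truncated to `[0, 1]`.
#'
#' @param values numeric marker values.
#' @param labels logical/0-1 disease labels (TRUE/1 = positive).
#' @param direction `"lower"` (lower-is-positive) or `"higher"`.
#' @return list of class `RocResult`: `thresholds`, `sensitivities`,
#'   `specificities`, `auc`, `auc_se`, `ci95`, `direction`, `n_pos`, `n_neg`.
#' @export
roc <- function(values, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(values) != length(labels) || anyNA(values) || anyNA(labels))
    pq_error("pq_bad_params", "values/labels must be complete and paired")
  if (!any(labels) || all(labels))
    pq_error("pq_degenerate_input", "both classes must be present")
  score <- if (direction == "lower") -values else values
  pos <- score[labels]; neg <- score[!labels]
  comp <- delong_components(pos, neg)
  m <- length(pos); n <- length(neg)
  s10 <- if (m > 1) stats::var(comp$v10) else 0
  s01 <- if (n > 1) stats::var(comp$v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  # operating points at midpoints between adjacent sorted unique scores,
  # plus the two extremes; positive call: score > threshold
  u <- sort(unique(score))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  sens <- vapply(thr, function(th) mean(pos > th), 0)
  spec <- vapply(thr, function(th) mean(neg <= th), 0)
  # report thresholds on the original value scale
  thr_orig <- if (direction == "lower") -thr else thr
  structure(list(thresholds = thr_orig, sensitivities = sens,
                 specificities = spec, auc = comp$auc, auc_se = se,
                 ci95 = c(max(0, comp$auc - 1.96 * se),
                          min(1, comp$auc + 1.96 * se)),
                 direction = direction,
                 v10 = comp$v10, v01 = comp$v01, n_pos = m, n_neg = n),
            class = "RocResult")
}

#' DeLong test for two correlated AUCs
#'
#' Both markers must be measured on the same subjects with the same labels.
#' `z = (auc1 - auc2) / SE(diff)` with the covariance of the paired
#' structural components; two-sided p.
#'
#' @param values1,values2 paired marker values.
#' @param labels shared disease labels.
#' @param direction1,direction2 per-marker direction, as in [roc()].
#' @return `list(auc1, auc2, z, p, se)` with `se` the standard error of the
#'   AUC difference.
#' @export
delong_test <- function(values1, values2, labels,
                        direction1 = "lower", direction2 = direction1) {
  labels <- as.logical(labels)
  s1 <- if (direction1 == "lower") -values1 else values1
  s2 <- if (direction2 == "lower") -values2 else values2
  c1 <- delong_components(s1[labels], s1[!labels])
  c2 <- delong_components(s2[labels], s2[!labels])
  m <- sum(labels); n <- sum(!labels)
  var_diff <- stats::var(c1$v10 - c2$v10) / m +
    stats::var(c1$v01 - c2$v01) / n
  if (!is.finite(var_diff) || var_diff <= 0) {
    if (isTRUE(all.equal(c1$auc, c2$auc)))
      return(list(auc1 = c1$auc, auc2 = c2$auc, z = 0, p = 1, se = 0))
    pq_error("pq_degenerate_input", "zero variance of AUC difference")
  }
  z <- (c1$auc - c2$auc) / sqrt(var_diff)
  list(auc1 = c1$auc, auc2 = c2$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), se = sqrt(var_diff))
}

#' Youden-index optimal threshold
#'
#' Maximizes `J = sensitivity + specificity - 1` over thresholds at midpoints
#' between adjacent sorted unique values; ties are broken toward the smaller
#' `|sensitivity - specificity|` (the balance criterion), then toward higher
#' specificity. Rates are reported in percent; `youden_j` on the proportion
#' scale.
#'
#' @param roc_result a [roc()] result.
#' @param values,labels the data the ROC was computed from.
#' @return list of class `ThresholdResult`: `threshold`, `sensitivity`,
#'   `specificity`, `accuracy` (all %), `youden_j`.
#' @export
youden_threshold <- function(roc_result, values, labels) {
  labels <- as.logical(labels)
  score <- if (roc_result$direction == "lower") -values else values
  pos <- score[labels]; neg <- score[!labels]
  u <- sort(unique(score))
  thr <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  sens <- vapply(thr, function(th) mean(pos > th), 0)
  spec <- vapply(thr, function(th) mean(neg <= th), 0)
  J <- sens + spec - 1
  best <- which(J == max(J))
  if (length(best) > 1) {
    bal <- abs(sens[best] - spec[best])
    best <- best[bal == min(bal)]
    if (length(best) > 1) best <- best[which.max(spec[best])]
  }
  i <- best[1]
  tp <- sum(pos > thr[i]); fn <- sum(pos <= thr[i])
  tn <- sum(neg <= thr[i]); fp <- sum(neg > thr[i])
  structure(list(
    threshold = if (roc_result$direction == "lower") -thr[i] else thr[i],
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    youden_j = J[i],
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn)
  ), class = "ThresholdResult")
}

#' McNemar test from discordant-pair counts
#'
#' Exact binomial test of `b` against `Binomial(b + c, 1/2)` for
#' `b + c < 25`, continuity-corrected chi-square otherwise; `p = 1` by
#' convention when `b + c = 0`.
#'
#' @param b,c discordant counts (nonnegative integers).
#' @return two-sided p-value.
#' @export
mcnemar <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    pq_error("pq_bad_params", "b and c must be nonnegative integers")
  n <- b + c
  if (n == 0) return(1)
  if (n < 25) {
    min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
  } else {
    x2 <- (abs(b - c) - 1)^2 / n
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }
}

#' Cohort-level diagnostic accuracy evaluation
#'
#' For each metric and analysis level, computes the ROC (lower-is-positive),
#' the Youden-optimal operating point, pairwise DeLong comparisons of AUCs,
#' and pairwise McNemar tests on sensitivity and specificity at the chosen
#' thresholds.
#'
#' @param summaries data.frame with columns `unit_id`, `level` (`"patient"` /
#'   `"vessel"`), `metric` (`"mbf"`, `"mpr"`, `"rmbf"`, `"rmpr"`), `value`.
#' @param truth data.frame with columns `unit_id`, `level`, `label` (0/1).
#' @param metrics metrics to evaluate.
#' @return list of class `CohortReport`: `table` (one row per metric x level:
#'   AUC, CI, threshold, sensitivity, specificity, accuracy), `delong`
#'   (pairwise AUC p-values), `mcnemar` (pairwise sens/spec p-values),
#'   `rocs`.
#' @export
evaluate_cohort <- function(summaries, truth,
                            metrics = c("mbf", "mpr", "rmbf", "rmpr")) {
  out <- list(); rocs <- list()
  delong_rows <- list(); mcnemar_rows <- list()
  for (lev in intersect(c("patient", "vessel"), unique(truth$level))) {
    tr <- truth[truth$level == lev, ]
    vals <- list(); labs <- NULL; preds <- list()
    for (met in metrics) {
      s <- summaries[summaries$level == lev & summaries$metric == met, ]
      s <- s[match(tr$unit_id, s$unit_id), ]
      if (anyNA(s$value))
        pq_error("pq_bad_params", sprintf(
          "missing %s/%s summary for some units", lev, met))
      vals[[met]] <- s$value
      r <- roc(s$value, tr$label, direction = "lower")
      th <- youden_threshold(r, s$value, tr$label)
      rocs[[paste(lev, met, sep = "_")]] <- r
      preds[[met]] <- s$value < th$threshold
      out[[length(out) + 1]] <- data.frame(
        level = lev, metric = met, auc = r$auc,
        ci_lo = r$ci95[1], ci_hi = r$ci95[2], threshold = th$threshold,
        sensitivity = th$sensitivity, specificity = th$specificity,
        accuracy = th$accuracy)
    }
    labs <- as.logical(tr$label)
    for (i in seq_along(metrics)) for (j in seq_along(metrics)) {
      if (j <= i) next
      dl <- delong_test(vals[[metrics[i]]], vals[[metrics[j]]], labs)
      delong_rows[[length(delong_rows) + 1]] <- data.frame(
        level = lev, metric1 = metrics[i], metric2 = metrics[j], p = dl$p)
      for (side in c("sensitivity", "specificity")) {
        sel <- if (side == "sensitivity") labs else !labs
        pi <- preds[[metrics[i]]][sel] == (side == "sensitivity")
        pj <- preds[[metrics[j]]][sel] == (side == "sensitivity")
        mcnemar_rows[[length(mcnemar_rows) + 1]] <- data.frame(
          level = lev, metric1 = metrics[i], metric2 = metrics[j],
          side = side, p = mcnemar(sum(pi & !pj), sum(!pi & pj)))
      }
    }
  }
  structure(list(table = do.call(rbind, out),
                 delong = do.call(rbind, delong_rows),
                 mcnemar = do.call(rbind, mcnemar_rows),
                 rocs = rocs),
            class = "CohortReport")
}
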