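# Agreement, group comparison, and ROC-based diagnostic accuracy.

# brute-force concordance oracle: P(score_pos > score_neg) + 0.5 P(==)
auc_oracle <- function(values, labels, direction = "lower") {
  s <- if (direction == "lower") -values else values
  pos <- s[as.logical(labels)]; neg <- s[!as.logical(labels)]
  mean(outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y)))
}

test_that("pearson_r matches closed-form cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "pq_degenerate_input")
  expect_error(pearson_r(1:2, 2:3), class = "pq_bad_params")
})

test_that("bland_altman reports bias, limits of agreement and a t-test p", {
  a <- c(1, 2, 3, 4)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa, c(0, 0))
  expect_equal(ba0$bias_p, 1)

  ba <- bland_altman(a - 0.25, a)
  expect_equal(ba$bias, -0.25)
  expect_equal(ba$loa, c(-0.25, -0.25))
  expect_equal(ba$bias_p, 0)               # constant nonzero difference

  ba3 <- bland_altman(c(0, 2, 4), c(1, 2, 3))   # d = {-1, 0, 1}
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$loa, c(-1.96, 1.96))

  # antisymmetry
  set.seed(4)
  u <- rnorm(10); v <- rnorm(10)
  expect_equal(bland_altman(u, v)$bias, -bland_altman(v, u)$bias)
  expect_error(bland_altman(1:2, 1:2), class = "pq_bad_params")
})

test_that("mann_whitney is exact for small untied samples", {
  r <- mann_whitney(c(1, 2, 3), c(10, 20, 30))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)                  # 2 * (1/C(6,3)=1/20 ... ) = 0.1
  expect_gt(mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))$p, 0.9)
  # invariance under strictly monotone transforms
  set.seed(9)
  a <- rnorm(7); b <- rnorm(9, 0.5)
  p1 <- mann_whitney(a, b)$p
  p2 <- mann_whitney(exp(a), exp(b))$p
  expect_equal(p1, p2)
  expect_error(mann_whitney(numeric(0), 1:3), class = "pq_bad_params")
})

test_that("mann_whitney exact p for n1 = n2 = 3 equals full enumeration", {
  a <- c(1.2, 3.4, 2.2); b <- c(2.9, 5.1, 4.4)
  pooled <- c(a, b)
  # oracle: all C(6,3) label assignments of ranks
  ranks <- rank(pooled)
  obs_u <- sum(outer(a, b, ">"))
  combos <- combn(6, 3)
  us <- apply(combos, 2, function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">"))
  })
  # two-sided: doubled smaller tail of the permutation distribution of U
  p_oracle <- 2 * min(mean(us <= obs_u), mean(us >= obs_u))
  p_oracle <- min(1, p_oracle)
  expect_equal(mann_whitney(a, b)$p, p_oracle)
})

test_that("roc matches the enumerated 8-point example and edge cases", {
  vals <- c(1, 2, 3, 4, 3, 4, 5, 6)
  labs <- c(1, 1, 1, 1, 0, 0, 0, 0)
  # explicit enumeration of the 16 pairs (lower value = positive):
  # strictly concordant 13 (1<3,4,5,6; 2<3,4,5,6; 3<4,5,6; 4<5,6),
  # exact ties (3,3) and (4,4) at half credit -> (13 + 2*0.5)/16 = 0.875
  expect_equal(auc_oracle(vals, labs, "lower"), (13 + 2 * 0.5) / 16)
  r <- roc(vals, labs, "lower")
  expect_equal(r$auc, 0.875)
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
  # curve endpoints in (1 - spec, sens) space
  expect_equal(min(r$sensitivities), 0); expect_equal(max(r$sensitivities), 1)
  expect_equal(min(r$specificities), 0); expect_equal(max(r$specificities), 1)

  expect_equal(roc(c(1, 2, 9, 10), c(1, 1, 0, 0), "lower")$auc, 1.0)
  expect_equal(roc(rep(3, 6), c(1, 0, 1, 0, 1, 0), "lower")$auc, 0.5)
  expect_error(roc(1:4, c(1, 1, 1, 1), "lower"),
               class = "pq_degenerate_input")
})

test_that("roc AUC equals brute-force concordance on random cohorts", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    labs <- c(rep(1, 2), rep(0, 2), rbinom(n - 4, 1, 0.4))
    vals <- round(rnorm(n, mean = ifelse(labs == 1, -0.5, 0.5)), 1)  # ties
    dir <- sample(c("lower", "higher"), 1)
    expect_equal(roc(vals, labs, dir)$auc, auc_oracle(vals, labs, dir))
  }
})

test_that("delong_test is symmetric, null on self, near a jackknife oracle", {
  labs <- c(1, 1, 1, 0, 0, 0)
  x <- c(0.5, 1.2, 0.8, 2.3, 1.9, 2.8)
  y <- c(0.7, 1.9, 1.4, 2.0, 1.1, 2.2)
  expect_equal(delong_test(x, x, labs)$p, 1)
  d12 <- delong_test(x, y, labs)
  d21 <- delong_test(y, x, labs)
  expect_equal(d12$z, -d21$z)
  expect_equal(d12$p, d21$p)
  expect_true(d12$auc1 != d12$auc2)

  # jackknife oracle for SE of the AUC difference
  theta <- function(keep) auc_oracle(x[keep], labs[keep]) -
    auc_oracle(y[keep], labs[keep])
  n <- length(labs)
  loo <- vapply(1:n, function(i) theta(setdiff(1:n, i)), 0)
  se_jack <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  expect_lt(abs(d12$se - se_jack) / se_jack, 0.2)
})

test_that("DeLong SE shrinks as the cohort doubles", {
  ses <- sapply(c(40, 80, 160), function(n) {
    set.seed(100 + n)
    labs <- rep(c(1, 0), n / 2)
    vals <- rnorm(n, ifelse(labs == 1, -1, 0))
    roc(vals, labs, "lower")$auc_se
  })
  expect_true(all(diff(ses) < 0))
})

test_that("youden_threshold equals the brute-force scan and its own counts", {
  vals <- c(1, 2, 3, 4, 3, 4, 5, 6)
  labs <- c(1, 1, 1, 1, 0, 0, 0, 0)
  r <- roc(vals, labs, "lower")
  th <- youden_threshold(r, vals, labs)
  # oracle: exhaustive scan over all midpoints (lower-is-positive)
  u <- sort(unique(vals))
  cand <- (u[-1] + u[-length(u)]) / 2
  Js <- sapply(cand, function(ct) {
    sens <- mean(vals[labs == 1] < ct); spec <- mean(vals[labs == 0] >= ct)
    sens + spec - 1
  })
  expect_equal(th$youden_j, max(Js))
  expect_true(th$threshold %in% cand[Js == max(Js)])
  # confusion counts recomputed independently
  pred <- vals < th$threshold
  expect_equal(unname(th$counts["tp"]), sum(pred & labs == 1))
  expect_equal(th$sensitivity, 100 * sum(pred & labs == 1) / sum(labs == 1))
  expect_equal(th$accuracy, 100 * mean(pred == (labs == 1)))

  sep <- youden_threshold(roc(c(1, 2, 8, 9), c(1, 1, 0, 0), "lower"),
                          c(1, 2, 8, 9), c(1, 1, 0, 0))
  expect_equal(sep$youden_j, 1)
  expect_equal(sep$accuracy, 100)
  expect_true(sep$threshold > 2 && sep$threshold < 8)

  unif <- youden_threshold(roc(rep(4, 6), c(1, 0, 1, 0, 1, 0), "lower"),
                           rep(4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(unif$youden_j, 0)
})

test_that("mcnemar handles exact, asymptotic and degenerate regimes", {
  expect_equal(mcnemar(5, 5), 1.0)
  expect_equal(mcnemar(10, 0), 2 * 0.5^10)
  expect_equal(mcnemar(0, 0), 1)
  # asymptotic regime agrees with the continuity-corrected chi-square
  expect_equal(mcnemar(20, 10),
               pchisq((abs(20 - 10) - 1)^2 / 30, 1, lower.tail = FALSE))
  expect_error(mcnemar(-1, 2), class = "pq_bad_params")
})

test_that("evaluate_cohort produces the Table-3-shaped report", {
  set.seed(77)
  n <- 60
  labs <- rep(c(1, 0), n / 2)
  mk <- function(sep) {
    # lower values in diseased units
    data.frame(value = rnorm(n, mean = ifelse(labs == 1, 1 - sep, 1), sd = 0.2))
  }
  summaries <- do.call(rbind, lapply(c("mbf", "mpr", "rmbf", "rmpr"),
    function(m) data.frame(unit_id = 1:n, level = "patient", metric = m,
                           value = mk(4)$value)))
  truth <- data.frame(unit_id = 1:n, level = "patient", label = labs)
  rep1 <- evaluate_cohort(summaries, truth)
  expect_equal(nrow(rep1$table), 4)
  expect_true(all(rep1$table$auc == 1))
  expect_true(all(rep1$table$accuracy == 100))
  expect_equal(nrow(rep1$delong), choose(4, 2))
  expect_equal(nrow(rep1$mcnemar), 2 * choose(4, 2))

  # uninformative markers: AUC near 1/2 at n = 200
  set.seed(78)
  n <- 200; labs <- rbinom(n, 1, 0.5)
  summaries <- do.call(rbind, lapply(c("mbf", "mpr"), function(m)
    data.frame(unit_id = 1:n, level = "vessel", metric = m,
               value = rnorm(n))))
  truth <- data.frame(unit_id = 1:n, level = "vessel", label = labs)
  rep2 <- evaluate_cohort(summaries, truth, metrics = c("mbf", "mpr"))
  # Monte-Carlo tolerance: 4 null standard errors of the AUC
  se0 <- sqrt((1 / sum(labs == 1) + 1 / sum(labs == 0)) / 12)
  expect_true(all(abs(rep2$table$auc - 0.5) < 4 * se0))

  # two levels x four metrics -> 8 report rows
  t3 <- rbind(truth, transform(truth, level = "patient"))
  rep3 <- evaluate_cohort(rbind(
    do.call(rbind, lapply(c("mbf", "mpr", "rmbf", "rmpr"), function(m)
      data.frame(unit_id = 1:n, level = "patient", metric = m,
                 value = rnorm(n)))),
    do.call(rbind, lapply(c("mbf", "mpr", "rmbf", "rmpr"), function(m)
      data.frame(unit_id = 1:n, level = "vessel", metric = m,
                 value = rnorm(n))))), t3)
  expect_equal(nrow(rep3$table), 8)
})
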