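test_that("trapezoidal AUC matches hand calculations and is linear", {
  expect_equal(auc_trapezoid(c(0, 72), c(5, 5)), 360)       # constant c
  expect_equal(auc_trapezoid(c(0, 24, 48), c(0, 10, 0)), 240)
  t <- c(0, 4, 24, 48, 72)
  v <- c(1, 3, 8, 4, 2)
  expect_equal(auc_trapezoid(t, 2 * v), 2 * auc_trapezoid(t, v))
  # missing values are dropped, unordered input is sorted
  expect_equal(auc_trapezoid(c(48, 0, 24), c(0, 0, 10)), 240)
  expect_equal(auc_trapezoid(c(0, 24, 48), c(0, NA, 4)), 96)
  expect_error(auc_trapezoid(c(0), c(1)), "2 non-missing")
})

test_that("group peak is the timepoint of highest group mean, ties earliest", {
  tab <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 3),
    group = "g", cohort = "Prime",
    time_hr = rep(c(4, 24, 48), 2),
    value = c(1, 5, 3, 1, 5, 3))
  pk <- group_max(tab)
  expect_true(all(pk$peak_time_hr == 24))
  expect_equal(pk$value, c(5, 5))
  # tie in group means resolves to the earliest timepoint, with a message
  tab2 <- tab
  tab2$value <- c(5, 5, 3, 5, 5, 3)
  expect_message(pk2 <- group_max(tab2), "earliest")
  expect_true(all(pk2$peak_time_hr == 4))
  # single subject: its own max timepoint
  one <- tab[tab$subject_id == "s1", ]
  expect_equal(unique(group_max(one)$peak_time_hr), 24)
})

test_that("AUC and group max commute with unit rescaling", {
  ser <- make_endpoint_series(noise_cv = 0.3, seed = 61)
  ser2 <- ser
  ser2$value <- ser$value * 1000
  expect_equal(endpoint_auc(ser2)$auc, endpoint_auc(ser)$auc * 1000)
  a <- group_max(ser); b <- group_max(ser2)
  expect_equal(b$peak_time_hr, a$peak_time_hr)
  expect_equal(b$value, a$value * 1000)
})

test_that("group-peak timepoint recovers the simulated peak under zero noise", {
  ser <- make_endpoint_series(peak_time = 24, noise_cv = 0, seed = 62)
  expect_true(all(group_max(ser)$peak_time_hr == 24))
})

test_that("log-ANOVA contracts: positivity, identical groups, two-factor models", {
  expect_error(anova_log_tukey(c(1, 2, 0), c("a", "a", "b")), "positive")
  expect_error(anova_log_tukey(c(1, 2), c("a", "a")), "2 groups")
  # identical group values: no evidence of a difference
  # (suppresses R's benign perfect-fit warning from summary.lm)
  res <- suppressWarnings(anova_log_tukey(rep(3, 8), rep(c("a", "b"), 4)))
  expect_equal(res$p_value, 1)
  expect_equal(res$estimate, 0)
  # two-factor model with interaction returns all crossed contrasts
  set.seed(63)
  v <- rlnorm(16)
  g <- rep(c("a", "b"), 8)
  co <- rep(c("Prime", "Boost"), each = 8)
  res2 <- anova_log_tukey(v, g, cohort = co, interaction = TRUE)
  expect_equal(nrow(res2), choose(4, 2))
  expect_true(all(res2$adjustment == "tukey"))
})

test_that("log-ANOVA type-I error is calibrated near 5%", {
  set.seed(64)
  n_sim <- 300
  hits <- 0L
  for (i in seq_len(n_sim)) {
    v <- rlnorm(8, sdlog = 0.2)
    g <- rep(c("a", "b"), each = 4)
    if (anova_log_tukey(v, g)$p_value[1] < 0.05) hits <- hits + 1L
  }
  rate <- hits / n_sim
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("beta regression recovers a logit-scale effect and honours the pseudo count", {
  set.seed(65)
  n <- 30
  phi <- 20
  mu <- c(a = plogis(0), b = plogis(1))
  y <- c(rbeta(n, mu["a"] * phi, (1 - mu["a"]) * phi),
         rbeta(n, mu["b"] * phi, (1 - mu["b"]) * phi))
  g <- rep(c("a", "b"), each = n)
  fit <- beta_regression(y, g)
  est <- -fit$contrasts$estimate[1]  # contrast is a - b
  expect_lt(abs(est - 1), 3 * fit$contrasts$se[1])
  # zeros map to exactly the pseudo count, ones to its complement
  fit2 <- beta_regression(c(0, 0.5, 1, 0.2, 0.3, 0.4),
                          rep(c("a", "b"), each = 3))
  expect_identical(fit2$adjusted_ratios[1], 1e-5)
  expect_identical(fit2$adjusted_ratios[3], 1 - 1e-5)
  expect_error(beta_regression(c(-0.1, 0.5), c("a", "b")), "\\[0, 1\\]")
})

test_that("beta regression precision shrinks estimator variance as phi grows", {
  set.seed(66)
  sds <- vapply(c(5, 20, 100), function(phi) {
    ests <- vapply(1:30, function(i) {
      y <- c(rbeta(20, 0.3 * phi, 0.7 * phi),
             rbeta(20, 0.5 * phi, 0.5 * phi))
      fit <- beta_regression(y, rep(c("a", "b"), each = 20))
      fit$contrasts$estimate[1]
    }, numeric(1))
    sd(ests)
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("transformed linear models respect domains and recover shifts", {
  expect_error(transformed_lm(c(-1, 2, 3, 4), rep(c("a", "b"), 2), "sqrt"),
               "non-negative")
  expect_error(transformed_lm(c(0, 2, 3, 4), rep(c("a", "b"), 2), "log"),
               "positive")
  expect_error(transformed_lm(c(1, 2), c("a", "b"), "sqrt"), "residual")
  res <- suppressWarnings(transformed_lm(rep(4, 8), rep(c("a", "b"), 4),
                                         "sqrt"))
  expect_equal(res$estimate, 0)
  # known shift on the sqrt scale recovered within 3 SE
  set.seed(67)
  y_a <- (rnorm(40, 3, 0.3))^2
  y_b <- (rnorm(40, 5, 0.3))^2
  res2 <- transformed_lm(c(y_a, y_b), rep(c("a", "b"), each = 40), "sqrt")
  expect_lt(abs(res2$estimate[1] - (3 - 5)), 3 * res2$se[1])
  expect_equal(res2$adjustment[1], "none")
})

test_that("Pearson matrix handles identity, orthogonality and edge cases", {
  set.seed(68)
  x <- rnorm(20)
  y <- rnorm(20)
  y_orth <- residuals(lm(y ~ x))
  X <- cbind(a = x, b = y_orth, flat = rep(1, 20))
  out <- pearson_matrix(X)
  expect_equal(out$r["a", "a"], 1, tolerance = 1e-12)
  expect_lt(abs(out$r["a", "b"]), 1e-12)
  expect_true(is.na(out$r["flat", "a"]))  # undefined, not 0
  # minimal n = 3 returns a finite p
  m3 <- pearson_matrix(cbind(p = c(1, 2, 4)), cbind(q = c(1, 3, 4)))
  expect_true(is.finite(m3$p[1, 1]))
  # pairwise-complete handling of missing values
  Xm <- cbind(u = c(x[1:18], NA, NA))
  out2 <- pearson_matrix(Xm, cbind(v = y))
  expect_equal(out2$n[1, 1], 18)
  expect_error(pearson_matrix(X[1:5, ], X[1:4, ]), "same rows")
})
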