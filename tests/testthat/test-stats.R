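# The statistical battery against hand oracles, exhaustive enumeration and
# null simulations.

test_that("paired comparison handles degenerate, normal and constructed cases", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  r0 <- paired_compare(x, x)
  expect_equal(r0$cohens_d, 0)
  expect_equal(r0$p_value, 1)

  # constructed effect: +0.01 shift with tiny normal noise
  set.seed(21)
  g <- rnorm(30, 0.08, 0.02)
  s <- g + 0.01 + rnorm(30, 0, 0.001)
  r1 <- paired_compare(s, g)
  expect_lt(r1$p_value, 0.05)
  expect_gt(r1$cohens_d, 2)
  # Cohen's d is the paired variant: mean(diff) / sd(diff)
  expect_equal(r1$cohens_d, mean(s - g) / sd(s - g))
  expect_error(paired_compare(1:2, 1:2), "at least 3")
  expect_error(paired_compare(1:4, 1:3), "paired")
})

test_that("Wilcoxon branch matches exhaustive signed-rank enumeration (n = 8)", {
  # heavily skewed differences so the Shapiro gate rejects normality
  g <- c(1, 2, 3, 4, 5, 6, 7, 8) / 10
  d <- c(0.011, 0.012, 0.013, 0.014, 0.015, 0.016, -0.017, 0.9)
  s <- g + d
  expect_lt(shapiro.test(d)$p.value, 0.05)
  r <- paired_compare(s, g)
  expect_equal(r$test, "wilcoxon")
  # V statistic: sum of ranks of |d| over positive differences
  rk <- rank(abs(d))
  expect_equal(r$statistic, sum(rk[d > 0]))
  # exact two-sided p by enumerating all 2^8 sign assignments
  V_all <- vapply(0:255, function(m) {
    signs <- as.integer(intToBits(m))[1:8]
    sum(rk[signs == 1])
  }, numeric(1))
  V_obs <- sum(rk[d > 0])
  p_exact <- min(1, 2 * min(mean(V_all >= V_obs), mean(V_all <= V_obs)))
  expect_equal(r$p_value, p_exact)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # textbook 3 x 5 layout, hand oracle via SSB / SSW
  y <- c(6, 8, 4, 5, 3, 8, 12, 9, 11, 6, 13, 9, 11, 8, 7)
  gr <- rep(c("a", "b", "c"), each = 5)
  grand <- mean(y)
  ssb <- sum(tapply(y, gr, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, gr, function(v) sum((v - mean(v))^2)))
  F_hand <- (ssb / 2) / (ssw / 12)
  res <- one_way_anova(y, gr)
  expect_equal(res$F, F_hand)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_residual, 12)
  expect_equal(res$p_value, pf(F_hand, 2, 12, lower.tail = FALSE))
  # Tukey-adjusted p never below the unadjusted pairwise p
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p_unadj - 1e-12))
  # identical values across groups: F defined as 0
  expect_equal(one_way_anova(rep(5, 9), rep(1:3, 3))$F, 0)
  expect_error(one_way_anova(1:5, c(1, 1, 1, 1, 2)), "n >= 2")
})

test_that("ANOVA and paired test hold their type-I error under the null", {
  set.seed(22)
  reps <- 200
  rej <- replicate(reps, {
    y <- rnorm(148)
    g <- rep(1:3, c(49, 69, 30))
    a <- one_way_anova(y, g)$p_value < 0.05
    s <- rnorm(148, 0.1, 0.03); gy <- rnorm(148, 0.1, 0.03)
    p <- paired_compare(s, gy)$p_value < 0.05
    c(a, p)
  })
  se3 <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej[1, ]) - 0.05), se3)
  expect_lt(abs(mean(rej[2, ]) - 0.05), se3)
})

test_that("repeated-measures ANOVA detects a constructed within-subject effect", {
  set.seed(230)
  n <- 36
  base <- rlnorm(n, log(0.1), 0.3)
  d <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:n), 2),
    profile = rep(rep(1:3, each = n / 3), 2),
    region = rep(c("gyral", "sulcal"), each = n),
    value = c(base, base * 1.4 + rnorm(n, 0, 0.005)))
  r <- rm_anova(d)
  eff <- r$effects
  expect_lt(eff$p_value[eff$term == "region"], 0.001)
  expect_gt(eff$p_value[eff$term == "profile"], 0.05)
  # all-identical response: F = 0 throughout
  d0 <- d; d0$value <- 1
  expect_true(all(rm_anova(d0)$effects$F == 0))
  # incomplete within-subject data
  expect_error(rm_anova(d[-1, ]), "incomplete")
})

test_that("repeated-measures sums of squares partition the total", {
  set.seed(24)
  n <- 12
  d <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:n), 2),
    profile = rep(rep(1:3, each = n / 3), 2),
    region = rep(c("gyral", "sulcal"), each = n),
    value = rlnorm(2 * n, log(0.1), 0.4))
  r <- rm_anova(d, transform = "none")
  total_ss <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(r$strata$ss), total_ss)
  expect_equal(sum(r$strata$df), 2 * n - 1)
})

test_that("correlations match the covariance-formula oracle and Fisher CIs", {
  # exact linear relation
  d <- tibble::tibble(sulcal_mean_strain = 2 * (1:10),
                      sulcal_mean_strain_rate = 20 * (1:10) + 3,
                      peak_lin_vel = 1:10 + c(0.1, -0.2, 0.3, 0, 0.2,
                                              -0.1, 0.4, -0.3, 0.2, 0),
                      peak_lin_acc = c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10),
                      peak_rot_vel = as.numeric(1:10),
                      peak_rot_acc = c(2, 4, 1, 6, 3, 9, 5, 10, 7, 8))
  res <- kinematics_correlations(d)
  r_self <- res[res$response == "sulcal_mean_strain" &
                res$predictor == "peak_rot_vel", ]
  expect_equal(r_self$r2, 1, tolerance = 1e-12)
  # hand-computed 5-point covariance-formula oracle
  x <- c(1, 2, 4, 7, 9); y <- c(2.2, 2.8, 4.5, 6.1, 9.0)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  d5 <- tibble::tibble(sulcal_mean_strain = y, sulcal_mean_strain_rate = y + 1,
                       peak_lin_vel = x, peak_lin_acc = rev(x) + x / 2,
                       peak_rot_vel = x^2, peak_rot_acc = sqrt(x))
  res5 <- kinematics_correlations(d5)
  expect_equal(res5$r[res5$response == "sulcal_mean_strain" &
                      res5$predictor == "peak_lin_vel"], r_hand)
  # independent noise: r^2 near zero
  set.seed(25)
  dn <- tibble::tibble(sulcal_mean_strain = rnorm(1000),
                       sulcal_mean_strain_rate = rnorm(1000),
                       peak_lin_vel = rnorm(1000), peak_lin_acc = rnorm(1000),
                       peak_rot_vel = rnorm(1000), peak_rot_acc = rnorm(1000))
  expect_lt(max(kinematics_correlations(dn)$r2), 0.02)
  # degenerate input
  dd <- dn; dd$peak_lin_vel <- 1
  expect_error(kinematics_correlations(dd), "zero-variance")
})

test_that("Fisher interval covers the true r^2 at nominal rate", {
  set.seed(26)
  reps <- 500; n <- 148; r_true <- 0.8
  cover <- replicate(reps, {
    x <- rnorm(n)
    y <- r_true * x + sqrt(1 - r_true^2) * rnorm(n)
    ci <- sulcalstrain:::.fisher_r2_ci(cor(x, y), n)
    ci[1] <= r_true^2 && r_true^2 <= ci[2]
  })
  expect_lt(abs(mean(cover) - 0.95), 0.03)
})

test_that("regression recovers constructed coefficients and flags degeneracy", {
  set.seed(27)
  n <- 148
  d <- tibble::tibble(peak_lin_vel = rnorm(n, 3.5, 1),
                      peak_lin_acc = rnorm(n, 400, 100),
                      peak_rot_vel = rnorm(n, 22, 5),
                      peak_rot_acc = rnorm(n, 2500, 600))
  d$sulcal_mean_strain <- 3 * d$peak_rot_vel + rnorm(n, 0, 2)
  r <- kinematics_regression(d)
  co <- r$coefficients
  rv <- co[co$term == "peak_rot_vel", ]
  expect_equal(rv$beta, 3, tolerance = 0.05)
  expect_true(rv$conf_lo <= 3 && 3 <= rv$conf_hi)
  expect_lt(rv$p_value, 1e-6)
  # the inert predictors' intervals cover zero
  for (tm in c("peak_lin_vel", "peak_lin_acc", "peak_rot_acc")) {
    ci <- co[co$term == tm, ]
    expect_true(ci$conf_lo <= 0 && 0 <= ci$conf_hi)
  }
  # exact linear response with zero noise: R^2 = 1, degenerate-narrow CIs
  d$sulcal_mean_strain <- 2 * d$peak_lin_vel + 0.5 * d$peak_rot_vel
  rx <- suppressWarnings(kinematics_regression(d))
  expect_equal(rx$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(rx$coefficients$conf_hi - rx$coefficients$conf_lo), 1e-6)
  # constant response: betas ~ 0 and R^2 = 0
  d$sulcal_mean_strain <- 0.25
  rc <- suppressWarnings(kinematics_regression(d))
  expect_equal(max(abs(rc$coefficients$beta)), 0, tolerance = 1e-12)
  expect_equal(rc$r_squared, 0)
  expect_error(kinematics_regression(d[1:5, ]), "n >")
})

test_that("tidiers return well-formed tibbles", {
  set.seed(28)
  r <- paired_compare(rnorm(20, 0.1, 0.02), rnorm(20, 0.09, 0.02))
  expect_s3_class(tidy(r), "tbl_df")
  a <- one_way_anova(rnorm(30), rep(1:3, 10))
  expect_named(glance(a), c("F", "df_between", "df_residual", "p_value"))
  expect_true(all(c("comparison", "p_adj") %in% names(tidy(a))))
})
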