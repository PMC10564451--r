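test_that("ICC(2,1) equals 1 for perfect agreement and errors on degenerate
           input", {
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  fit <- icc_2_1(m)
  expect_equal(fit$icc, 1)
  expect_error(icc_2_1(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc_2_1(matrix(1:2, 1, 2)), "at least 2 subjects")
  expect_error(icc_2_1(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("ICC(2,1) matches the aov-based variance-components oracle on the
           worked 2x2 example and random matrices", {
  m <- rbind(c(1, 2), c(2, 1))
  expect_equal(icc_2_1(m)$icc, oracle_icc_2_1(m), tolerance = 1e-10)
  set.seed(20)
  for (rep in 1:200) {
    n <- sample(3:8, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * k, sd = sample(c(0.5, 1, 3), 1)) +
                  rep(rnorm(n, sd = 2), k), n, k)
    expect_equal(icc_2_1(x)$icc, oracle_icc_2_1(x), tolerance = 1e-10)
  }
})

test_that("ICC is shift-invariant and scale-invariant; CI brackets the
           estimate", {
  set.seed(4)
  x <- matrix(rnorm(20) + rep(rnorm(10, sd = 2), 2), 10, 2)
  f0 <- icc_2_1(x)
  expect_equal(icc_2_1(x + 100)$icc, f0$icc, tolerance = 1e-12)
  expect_equal(icc_2_1(x * 3.7)$icc, f0$icc, tolerance = 1e-12)
  expect_true(f0$ci_low <= f0$icc && f0$icc <= f0$ci_high)
  td <- tidy(f0)
  expect_identical(td$estimate, f0$icc)
  gl <- glance(f0)
  expect_identical(gl$n, 10L)
})

test_that("ICC recovers the theoretical variance ratio on simulated rater
           data", {
  # subject variance 9, error variance 1 -> ICC = 9/10
  set.seed(123)
  true_vals <- rnorm(500, mean = 10, sd = 3)
  long <- simulate_rater_study(true_vals, sigma_error = 1,
                               k_measurements = 2, seed = 123)
  fit <- icc_2_1(as.data.frame(long))
  expect_equal(fit$icc, 0.9, tolerance = 0.03)
})

test_that("long-format data-frame input matches the matrix route", {
  set.seed(8)
  m <- matrix(rnorm(12) + rep(rnorm(6, sd = 2), 2), 6, 2,
              dimnames = list(NULL, c("a", "b")))
  long <- tibble::tibble(subject = rep(1:6, 2),
                         rater = rep(c("a", "b"), each = 6),
                         value = c(m[, 1], m[, 2]))
  expect_equal(icc_2_1(as.data.frame(long))$icc, icc_2_1(m)$icc,
               tolerance = 1e-12)
})

test_that("Dahlberg error follows the closed form and its basic properties", {
  expect_equal(dahlberg_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dahlberg_error(c(2, 3), c(1, 2)), sqrt(2 / 4))  # diffs (1,1)
  expect_equal(dahlberg_error(3.2, 1.2), 2 / sqrt(2))          # n = 1: |d|/sqrt(2)
  expect_error(dahlberg_error(1:3, 1:2), "same length")
  set.seed(14)
  for (rep in 1:20) {
    a <- rnorm(7); b <- rnorm(7)
    d <- dahlberg_error(a, b)
    expect_gte(d, 0)
    expect_lte(d, max(abs(a - b)))
    expect_equal(dahlberg_error(b, a), d)
  }
})

test_that("Bland-Altman bias and limits of agreement are exact on closed-form
           cases", {
  ba <- bland_altman(c(2, 3, 4), c(1, 2, 3))  # diffs (1,1,1)
  expect_equal(ba$bias, 1)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(1, 1))
  ba0 <- bland_altman(c(1, 5, 9), c(1, 5, 9))
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  ba2 <- bland_altman(c(1, 3), c(1, 1))  # diffs (0, 2)
  expect_equal(ba2$bias, 1)
  expect_equal(ba2$sd_diff, sqrt(2))
  expect_equal(ba2$loa_low, 1 - 1.96 * sqrt(2))
  expect_equal(ba2$loa_high, 1 + 1.96 * sqrt(2))
  expect_error(bland_altman(1, 2), "at least 2")
  expect_identical(nrow(tidy(ba2)), 2L)
  expect_equal(glance(ba2)$bias, 1)
})

test_that("Bland-Altman limits contain about 95% of large normal samples", {
  set.seed(2024)
  n <- 10000
  a <- rnorm(n, 5, 1); b <- a + rnorm(n, 0.2, 0.5)
  ba <- bland_altman(a, b)
  inside <- mean(ba$data$diff >= ba$loa_low & ba$data$diff <= ba$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("paired t-test matches hand computation and flags zero variance", {
  r <- paired_t_test(c(1, 3), c(0, 0))  # diffs (1, 3): t = 2, df = 1
  expect_equal(r$t, 2)
  expect_equal(r$df, 1)
  r2 <- paired_t_test(c(-1, 1), c(0, 0))  # diffs symmetric about 0
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)
  r3 <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(r3$zero_variance)
  expect_equal(r3$p, 1)
  # against the textbook formula on noisy data
  set.seed(31)
  a <- rnorm(12); b <- a + rnorm(12, 0.3, 0.4)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  r4 <- paired_t_test(a, b)
  expect_equal(r4$t, t_manual, tolerance = 1e-12)
  expect_equal(r4$p, 2 * pt(-abs(t_manual), length(d) - 1),
               tolerance = 1e-12)
})

test_that("ICC bands and systematic-error gates reproduce the published
           criteria", {
  expect_identical(classify_icc(0.95), "excellent")
  expect_identical(classify_icc(0.39), "poor")
  expect_identical(classify_icc(0.60), "good")
  expect_identical(classify_icc(0.9), "excellent")
  expect_identical(classify_icc(0.4), "reasonable")
  expect_identical(classify_icc(1), "excellent")
  expect_identical(classify_icc(-0.2), "poor")
  expect_error(classify_icc(1.2), "must be in")

  expect_true(systematic_error_gate(0.3, "linear"))
  expect_true(systematic_error_gate(1.0, "linear"))     # inclusive bound
  expect_false(systematic_error_gate(1.001, "linear"))
  expect_true(systematic_error_gate(1.5, "angular"))
  expect_false(systematic_error_gate(1.6, "angular"))
  expect_error(systematic_error_gate(-0.1, "linear"), "non-negative")
})

test_that("build_reliability_table produces one full row per tooth-movement
           block", {
  set.seed(55)
  teeth <- c("LR1", "LR2", "LL1")
  movements <- c("buccolingual_translation", "rotation")
  rows <- list()
  for (tt in teeth) for (mm in movements) {
    true_vals <- rnorm(26, mean = if (mm == "rotation") 7 else 0.35,
                       sd = if (mm == "rotation") 5 else 0.3)
    noise_sd <- if (mm == "rotation") 0.3 else 0.02
    rows[[paste(tt, mm)]] <- tibble::tibble(
      subject_id = rep(1:26, 2),
      tooth_id = tt, movement = mm,
      measurement_label = rep(c("measure_1", "measure_2"), each = 26),
      value = rep(true_vals, 2) + rnorm(52, 0, noise_sd),
      units = if (mm == "rotation") "degrees" else "mm")
  }
  tbl <- build_reliability_table(dplyr::bind_rows(rows))
  expect_identical(nrow(tbl), length(teeth) * length(movements))
  # high subject variance, small error: every block rates excellent
  expect_true(all(tbl$icc_category == "excellent"))
  expect_true(all(tbl$error_gate_pass))
  expect_true(all(tbl$ci_low <= tbl$icc & tbl$icc <= tbl$ci_high))
  expect_true(all(tbl$ba_loa_low <= tbl$ba_bias &
                    tbl$ba_bias <= tbl$ba_loa_high))
  # single-subject block is rejected
  one <- tibble::tibble(subject_id = c(1, 1), tooth_id = "LR1",
                        movement = "vertical",
                        measurement_label = c("m1", "m2"),
                        value = c(0.1, 0.2), units = "mm")
  expect_error(build_reliability_table(one), "fewer than 2 subjects")
  # mixed units within one movement are rejected
  mixed <- dplyr::bind_rows(rows)
  mixed$units[1] <- "degrees"
  expect_error(build_reliability_table(mixed), "mixed units")
})
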