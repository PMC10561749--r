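# Agreement statistics: normality, paired t, correlation gating,
# Bland-Altman arithmetic and the cohort-level report.

test_that("normality test is calibrated and has power", {
  p_norm <- vapply(1:100, function(s) {
    set.seed(s); normality_test(rnorm(50))$p
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.9)

  p_exp <- vapply(1:100, function(s) {
    set.seed(s); normality_test(rexp(50))$p
  }, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.9)

  expect_error(normality_test(c(1, 2)), "3 to 5000")
})

test_that("paired t-test matches hand computation and handles degeneracy", {
  tt <- paired_t(c(1, 2, 3, 4), c(2, 2, 2, 2))
  # differences (-1, 0, 1, 2): mean 0.5, sd 1.291, t = 0.5 / (1.291 / 2)
  expect_equal(tt$t, 0.7746, tolerance = 1e-4)
  expect_equal(tt$p, 0.495, tolerance = 1e-3)

  same <- paired_t(1:5, 1:5)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  off <- paired_t(1:10 + 1, 1:10)
  expect_true(off$exact_offset)
  expect_lt(off$p, 1e-6)
})

test_that("correlation method is gated on normality and rank-invariant", {
  a <- seq(-2, 2, length.out = 20)
  expect_equal(correlate(a, 2 * a + 1, normal = TRUE)$r, 1)
  cub <- correlate(a, a^3, normal = FALSE)
  expect_identical(cub$method, "spearman")
  expect_equal(cub$r, 1)
  expect_equal(correlate(a, rev(a), normal = TRUE)$r, -1)

  # affine rescaling does not change the method choice
  set.seed(4)
  x <- rnorm(40); y <- x + rnorm(40, sd = 0.3)
  m1 <- correlate(x, y)$method
  m2 <- correlate(100 * x + 3, 0.01 * y - 7)$method
  expect_identical(m1, m2)
})

test_that("Bland-Altman arithmetic follows the LoA definition", {
  ba <- bland_altman(c(-1, 1), c(0, 0))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2), tolerance = 1e-9)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-9)
  expect_equal(ba$loa_high, 2.7719, tolerance = 1e-4)
  expect_equal(ba$n_outside_loa, 0)

  same <- bland_altman(1:5, 1:5)
  expect_equal(c(same$mean_diff, same$sd_diff, same$loa_low,
                 same$loa_high, same$n_outside_loa), rep(0, 5))

  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman is mirror-symmetric and has exact LoA width", {
  set.seed(8)
  a <- rnorm(30, 1.2, 0.1); b <- a + rnorm(30, 0, 0.05)
  ab <- bland_altman(a, b); ba <- bland_altman(b, a)
  expect_equal(ab$mean_diff, -ba$mean_diff)
  expect_equal(ab$loa_low, -ba$loa_high)
  expect_equal(ab$loa_high, -ba$loa_low)
  expect_identical(ab$n_outside_loa, ba$n_outside_loa)
  expect_equal(ab$loa_high - ab$loa_low, 2 * 1.96 * ab$sd_diff)
})

test_that("an identical second method yields null differences and r = 1", {
  set.seed(12)
  base <- data.frame(
    participant = rep(sprintf("P%02d", 1:20), each = 2),
    source = rep(c("KINEMATIC", "IMU"), 20),
    stride_length_m = rep(rnorm(20, 1.2, 0.1), each = 2),
    stride_time_s = rep(rnorm(20, 1.1, 0.05), each = 2)
  )
  rep_ <- full_report(base)
  expect_equal(rep_$report$mean_diff, c(0, 0))
  expect_equal(rep_$report$cor_r, c(1, 1), tolerance = 1e-12)
})

test_that("cohort bias and difference dispersion are recovered", {
  sm <- simulate_cohort_summaries(n = 54, bias = -0.005, sd_diff = 0.03,
                                  seed = 42)
  rep_ <- full_report(sm)
  row <- rep_$report[rep_$report$parameter == "stride_length_m", ]
  expect_lt(abs(row$mean_diff - (-0.005)), 2 * 0.03 / sqrt(54))
  expect_lt(abs(row$sd_diff - 0.03), 0.2 * 0.03)
  expect_identical(row$cor_method, "pearson")
})

test_that("a single participant cannot be analysed", {
  sm <- simulate_cohort_summaries(n = 1, seed = 1)
  expect_error(full_report(sm), "at least 2 participants")
})

test_that("participants missing one modality are dropped with a message", {
  sm <- simulate_cohort_summaries(n = 10, seed = 3)
  sm$stride_length_m[sm$participant == "P01" & sm$source == "IMU"] <- NA
  expect_message(rep_ <- full_report(sm), "dropped incomplete")
  expect_equal(rep_$report$n, 9)
})
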