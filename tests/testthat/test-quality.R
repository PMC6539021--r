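test_that("operational availability is the delivered/expected ratio, capped", {
  expect_equal(round_half_up(100 * availability(237, 244)), 97.13)
  expect_equal(availability(244, 244), 1)
  expect_equal(availability(0, 244), 0)
  expect_equal(availability(250, 244), 1)   # over-delivery caps at 1
  expect_error(availability(10, 0), "positive")
  expect_error(availability(-1, 244), ">= 0")
})

test_that("ICC(2,1) matches an independent ANOVA oracle on random matrices", {
  set.seed(4021)
  for (i in 1:50) {
    n <- sample(4:9, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, mean = 100, sd = sample(1:15, 1)), n, k)
    expect_equal(icc_2_1(m), icc_aov_oracle(m), tolerance = 1e-10)
    expect_lte(icc_2_1(m), 1)
  }
})

test_that("ICC is 1 for perfect agreement and ~0 for pure noise", {
  base <- c(72, 80, 95, 64, 88, 77)
  perfect <- matrix(rep(base, 4), 6, 4)
  expect_equal(icc_2_1(perfect), 1)
  expect_warning(icc_2_1(matrix(5, 4, 4)), "degenerate")

  set.seed(11)
  noise <- matrix(rnorm(1000 * 4), 1000, 4)   # no subject effect at all
  expect_lt(abs(icc_2_1(noise)), 0.05)
})

test_that("ICC recovers the analytic value of a two-way random-effects model", {
  set.seed(2024)
  n <- 200; k <- 4
  var_r <- 9; var_c <- 1; var_e <- 4
  analytic <- var_r / (var_r + var_c + var_e)
  # Monte Carlo over replicates: a single n = 200 draw carries sampling
  # error of the same order as the tolerance, the estimator mean must not
  est <- replicate(20, {
    m <- 100 + matrix(rnorm(n, 0, sqrt(var_r)), n, k) +
      matrix(rnorm(k, 0, sqrt(var_c)), n, k, byrow = TRUE) +
      matrix(rnorm(n * k, 0, sqrt(var_e)), n, k)
    icc_2_1(m)
  })
  expect_lt(abs(mean(est) - analytic), 0.05)
})

test_that("ICC is invariant under subject reordering and drops gappy rows", {
  set.seed(3)
  m <- matrix(rnorm(24, 90, 12), 6, 4)
  expect_equal(icc_2_1(m), icc_2_1(m[sample(6), ]))
  gappy <- rbind(m, c(NA, 1, 2, 3))
  expect_equal(icc_2_1(gappy), icc_2_1(m))
  expect_error(icc_2_1(matrix(1:4, 1, 4)), ">= 2")
})

test_that("overall quality reproduces the reference report values exactly", {
  expect_equal(round_half_up(overall_quality(97.54, 7.14, 91.00)), 90.58)
  expect_equal(round_half_up(overall_quality(97.13, 5.44, 90.00)), 91.18)
  expect_equal(round_half_up(overall_quality(99.59, 8.20, 95.00)), 92.47)
  expect_equal(round_half_up(overall_quality(97.95, 9.05, 96.00)), 91.03)
  expect_equal(overall_quality(100, 0, 100), 100)
  expect_error(overall_quality(50, 0, 50, w_avail = 0.5, w_icc = 0.4),
               "sum to 1")
})

test_that("overall quality is monotone in each channel", {
  base <- overall_quality(95, 5, 90)
  expect_gt(overall_quality(96, 5, 90), base)
  expect_gt(overall_quality(95, 5, 91), base)
  expect_lt(overall_quality(95, 6, 90), base)
})

test_that("the 90% gate is strict", {
  expect_equal(quality_gate(92.47), "keep")
  expect_equal(quality_gate(90.00), "discard")
  expect_equal(quality_gate(89.99), "discard")
  expect_equal(quality_gate(90.01), "keep")
})

test_that("quality_report combines cleaning, availability and reliability", {
  cl <- clean_dataset(make_table_fixture("Withings BPM"))
  qr <- quality_report(cl$report, expected = 244, icc_pct = 95)
  expect_equal(qr$availability_pct, 99.59)
  expect_equal(qr$faulty_data_pct, 8.20)
  expect_equal(qr$overall_quality_pct, 92.47)
  expect_equal(qr$decision, "keep")
  # raw-count availability convention uses delivered records instead
  cl2 <- clean_dataset(make_table_fixture("iHealth Track"))
  qr_auto <- quality_report(cl2$report, expected = 244, icc_pct = 90)
  qr_raw <- quality_report(cl2$report, expected = 244, icc_pct = 90,
                           use_raw = TRUE)
  expect_equal(qr_auto$availability_pct, 97.13)   # 237 cleaned records
  expect_equal(qr_raw$availability_pct, 97.95)    # 239 delivered records
  # ICC computed natively from the cleaned stream when not supplied
  qr_native <- quality_report(cl$report, expected = 244, cleaned = cl$dataset)
  expect_true(qr_native$icc_pct >= -100 && qr_native$icc_pct <= 100)
})
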