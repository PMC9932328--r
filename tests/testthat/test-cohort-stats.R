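test_that("median/IQR summaries match a brute-force quantile oracle", {
  s <- qct_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3); expect_equal(s$q1, 2); expect_equal(s$q3, 4)
  one <- qct_summary(42)
  expect_equal(one$median, 42)
  expect_equal(one$q1, 42)
  expect_equal(one$q3, 42)
  # linear-interpolation order-statistic oracle: q = x_(h) interpolated
  set.seed(8)
  x <- rnorm(23)
  xs <- sort(x)
  oracle_q <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(x))] - xs[lo])
  }
  s2 <- qct_summary(x)
  expect_equal(s2$q1, oracle_q(0.25))
  expect_equal(s2$median, oracle_q(0.5))
  expect_equal(s2$q3, oracle_q(0.75))
  expect_error(qct_summary(numeric(0)), "empty")

  b <- summarize_binary(c(TRUE, TRUE, FALSE, NA))
  expect_equal(b$count, 2); expect_equal(b$pct, 200 / 3); expect_equal(b$n, 3)
})

test_that("Friedman test: identical columns give statistic 0 and P 1", {
  m <- matrix(rep(c(5, 5, 5), each = 6), nrow = 6)
  ft <- friedman_qct(m)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)
  expect_error(friedman_qct(matrix(1:4, 2, 2)), "3 complete")
  expect_error(friedman_qct(matrix(1:6, 6, 1)), "2 timepoints")
})

test_that("Friedman P agrees with the exact full-enumeration oracle", {
  set.seed(3)
  for (rep in 1:3) {
    m <- matrix(rnorm(5 * 3), nrow = 5)  # (3!)^5 = 7776 orderings
    got <- friedman_qct(m)
    expect_identical(got$method, "exact permutation")
    exact <- friedman_exact_p_oracle(m)
    expect_lt(abs(got$p_value - exact), 1e-9)
  }
  # a design with ties still matches the oracle (average ranks)
  m_t <- matrix(c(1, 1, 2, 3, 2, 2, 1, 4, 5, 3, 3, 1), nrow = 4)
  expect_lt(abs(friedman_qct(m_t)$p_value - friedman_exact_p_oracle(m_t)), 1e-9)
  # large designs fall back to the chi-square reference
  m_big <- matrix(rnorm(30 * 4), nrow = 30)
  expect_identical(friedman_qct(m_big)$method, "chi-square")
  # under perfect within-subject ordering the statistic attains its maximum
  m_perf <- matrix(rep(1:4, each = 6), nrow = 6) + matrix(rnorm(24, 0, 1e-3), 6)
  got <- friedman_qct(m_perf)
  expect_equal(got$statistic, 6 * (4 - 1))  # n (k - 1)
})

test_that("subjects with missing visits are dropped and counted", {
  m <- matrix(rnorm(15), 5, 3)
  m[2, 3] <- NA
  ft <- friedman_qct(m)
  expect_equal(ft$n_subjects_used, 4)
  expect_equal(ft$n_subjects_dropped, 1)
})

test_that("McNemar test matches its continuity-corrected closed form", {
  # 5 discordant pairs each way: ((|5-5|-1)^2)/10 vs chi-square(1)
  before <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 4))
  after <- c(rep(FALSE, 5), rep(TRUE, 5), rep(TRUE, 4))
  mt <- mcnemar_qct(before, after)
  expect_equal(mt$statistic, (abs(5 - 5) - 1)^2 / 10)
  expect_equal(mt$p_value, 1 - stats::pchisq(0.1, df = 1))
  expect_gt(mt$p_value, 0.7)
  # fully concordant pairs: statistic 0, P 1
  conc <- mcnemar_qct(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(conc$p_value, 1)
  # away from the b = c corner the closed form agrees with stats::mcnemar.test
  b2 <- c(rep(TRUE, 8), rep(FALSE, 3), rep(TRUE, 5))
  a2 <- c(rep(FALSE, 8), rep(TRUE, 3), rep(TRUE, 5))
  ref <- stats::mcnemar.test(table(b2, a2), correct = TRUE)
  got <- mcnemar_qct(b2, a2)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
})

test_that("WMW exact P equals enumeration over group assignments", {
  set.seed(5)
  for (rep in 1:3) {
    a <- sample(seq(1, 100), 4)
    b <- sample(seq(101, 200), 4) / 1.7  # distinct values, overlapping range
    got <- wmw_test(a, b)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, wmw_exact_p_oracle(a, b), tolerance = 1e-10)
  }
  same <- wmw_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  big <- wmw_test(rnorm(30), rnorm(30))
  expect_match(big$method, "normal")
})

test_that("BH adjustment equals the step-up definition and its fixed points", {
  set.seed(10)
  p <- runif(20)
  expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
  # all raw P equal alpha -> all adjusted equal alpha
  expect_equal(stats::p.adjust(rep(0.03, 7), "BH"), rep(0.03, 7))
  # monotone: adjustment preserves the P ordering
  adj <- bh_oracle(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # an all-equal adjusted set is a fixed point of re-adjustment
  expect_equal(bh_oracle(rep(0.03, 7)), rep(0.03, 7))
})

test_that("correlation map reports r, Fisher CI, BH adjustment and ratings", {
  set.seed(2)
  n <- 60
  x <- rnorm(n)
  df <- tibble::tibble(
    x = x, y = 2 * x + 1, z = rnorm(n), w = 0.5 * x + rnorm(n)
  )
  cm <- correlation_map(df)
  xy <- cm[cm$var1 == "x" & cm$var2 == "y", ]
  expect_equal(xy$r, 1)
  expect_equal(xy$ci_lo, 1)
  expect_equal(xy$ci_hi, 1)
  expect_identical(xy$rating, "very strong")
  # BH over all off-diagonal cells matches the oracle
  expect_equal(cm$p_adj, bh_oracle(cm$p_value))
  expect_identical(rate_correlation(0.19), "very weak")
  expect_identical(rate_correlation(0.28), "weak")
  expect_identical(rate_correlation(-0.42), "moderate")
  expect_identical(rate_correlation(0.54), "moderate")
})

test_that("degenerate correlation cells are flagged, not guessed", {
  df <- tibble::tibble(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  cm <- correlation_map(df, c("a", "b"))
  expect_true(cm$degenerate)
  expect_true(is.na(cm$r))
  expect_error(correlation_map(tibble::tibble(a = 1:2, b = 2:1)), "3 complete")
})
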