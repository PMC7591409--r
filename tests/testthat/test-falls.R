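test_that("falls counts map deterministically onto categories", {
  got <- classify_falls(c(0L, 1L, 2L, 7L, NA))
  expect_identical(as.character(got),
                   c("no_falls", "one_fall", "recurrent", "recurrent", NA))
  expect_identical(levels(got), c("no_falls", "one_fall", "recurrent"))
  expect_error(classify_falls(-1L), "non-negative")
  expect_error(classify_falls(1.5), "non-negative")
})

test_that("fall-frailty groups combine faller and frailty status", {
  st <- classify_falls(c(2L, 0L, 1L, 0L))
  frail <- c(TRUE, TRUE, FALSE, FALSE)
  expect_identical(as.character(fall_frailty_group(st, frail)),
                   c("faller_frail", "nonfaller_frail", "faller_nonfrail",
                     "nonfaller_nonfrail"))
  expect_true(is.na(fall_frailty_group(classify_falls(NA), TRUE)))
})

test_that("cross-tabulation counts and row percentages are exact", {
  d <- data.frame(
    status = c("frail", "frail", "non_frail", "non_frail", "non_frail", NA),
    falls = c("recurrent", "no_falls", "no_falls", "one_fall", "no_falls",
              "no_falls")
  )
  tab <- cross_tabulate(d, "status", "falls")
  expect_identical(tab$counts["frail", "recurrent"], 1L)
  expect_identical(tab$counts["non_frail", "no_falls"], 2L)
  expect_equal(tab$row_pct["frail", ], c(no_falls = 50, one_fall = 0,
                                         recurrent = 50))
  expect_identical(tab$n, 5L)
  expect_identical(tab$n_excluded, 1L)
  expect_equal(rowSums(tab$row_pct), c(frail = 100, non_frail = 100))
  # single-category column
  one_col <- cross_tabulate(data.frame(a = c("x", "y"), b = "z"), "a", "b")
  expect_identical(ncol(one_col$counts), 1L)
  expect_true(all(one_col$row_pct == 100))
  expect_error(cross_tabulate(data.frame(a = NA, b = NA), "a", "b"),
               "no complete records")
})

test_that("chi-square equals the brute-force sum over expecteds", {
  prop <- contingency_table(matrix(c(10, 20, 20, 40), 2))
  res <- chi_square(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res2 <- chi_square(contingency_table(matrix(c(10, 20, 20, 10), 2)))
  expect_equal(res2$statistic, 20 / 3, tolerance = 1e-12)
  expect_identical(res2$df, 1L)

  expect_identical(chi_square(contingency_table(
    matrix(rpois(20, 10) + 1, 5, 4)))$df, 12L)

  expect_error(chi_square(contingency_table(matrix(c(0, 0, 3, 4), 2))),
               "merge")
})

test_that("chi-square matches brute force on random small tables", {
  set.seed(61)
  for (r in 1:200) {
    nr <- sample(2:5, 1); nc <- sample(2:4, 1)
    counts <- matrix(rpois(nr * nc, lambda = sample(3:20, 1)) + 1, nr, nc)
    got <- chi_square(contingency_table(counts))
    want <- bruteforce_chisq(counts)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_identical(got$df, as.integer(want$df))
    expect_equal(got$p_value,
                 pchisq(want$statistic, want$df, lower.tail = FALSE))
  }
})

test_that("2x2 odds ratios follow the cross-product and Woolf interval", {
  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$odds_ratio, 1)

  # recurrent falls at baseline, frail vs non-frail
  est <- odds_ratio_2x2(72, 149, 62, 631)
  expect_equal(est$odds_ratio, (72 * 631) / (149 * 62), tolerance = 1e-12)
  expect_equal(round(est$odds_ratio, 3), 4.918)
  se <- sqrt(1 / 72 + 1 / 149 + 1 / 62 + 1 / 631)
  expect_equal(est$ci_low, est$odds_ratio * exp(-qnorm(0.975) * se))
  expect_equal(est$ci_high, est$odds_ratio * exp(qnorm(0.975) * se))
  expect_true(est$ci_low <= est$odds_ratio & est$odds_ratio <= est$ci_high)

  # zero cell triggers the Haldane-Anscombe correction and a flag
  cor <- odds_ratio_2x2(0, 10, 5, 5)
  expect_true(cor$corrected)
  expect_equal(cor$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))

  expect_error(odds_ratio_2x2(0, 0, 5, 5), "margin")
})

test_that("2x2 odds ratios obey the symmetry invariants", {
  set.seed(62)
  for (r in 1:25) {
    cells <- rpois(4, 20) + 1
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    or1 <- odds_ratio_2x2(a, b, c, d)$odds_ratio
    # swapping rows and columns simultaneously leaves the OR unchanged
    expect_equal(odds_ratio_2x2(d, c, b, a)$odds_ratio, or1)
    # exchanging exposure labels inverts it
    expect_equal(odds_ratio_2x2(c, d, a, b)$odds_ratio, 1 / or1,
                 tolerance = 1e-12)
  }
})

test_that("unadjusted logistic OR equals the 2x2 cross-product OR", {
  set.seed(63)
  for (r in 1:50) {
    cells <- rpois(4, 15) + 1
    d <- data.frame(
      y = rep(c(1, 0, 1, 0), cells),
      x = rep(c(1, 1, 0, 0), cells)
    )
    fit <- logistic_or(d, "y", "x")[["x"]]
    tab <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(fit$odds_ratio, tab$odds_ratio, tolerance = 1e-6)
  }
})

test_that("logistic models recover a known effect with Wald coverage", {
  set.seed(64)
  covered <- 0
  n_rep <- 200
  for (r in 1:n_rep) {
    x <- rbinom(2000, 1, 0.4)
    y <- rbinom(2000, 1, plogis(-1 + 1 * x))  # true log-OR 1.0
    est <- logistic_or(data.frame(x = x, y = y), "y", "x")[["x"]]
    covered <- covered +
      (est$ci_low <= exp(1) && exp(1) <= est$ci_high)
  }
  expect_gte(covered / n_rep, 0.93)
})

test_that("logistic degeneracies raise informative errors", {
  d <- data.frame(y = rep(0, 50), x = rnorm(50))
  expect_error(logistic_or(d, "y", "x"), "degenerate outcome")
  d2 <- data.frame(y = rbinom(50, 1, 0.5), x = 1)
  expect_error(logistic_or(d2, "y", "x"), "zero variance")
  # perfect separation is detected and names the culprit
  d3 <- data.frame(y = rep(c(0, 1), each = 25), x = rep(c(0, 1), each = 25))
  expect_error(suppressWarnings(logistic_or(d3, "y", "x")), "separation")
})

test_that("complete-case exclusions are counted", {
  d <- data.frame(y = rbinom(100, 1, 0.5), x = rnorm(100),
                  z = c(NA, rnorm(99)))
  ests <- logistic_or(d, "y", "x", "z")
  expect_identical(attr(ests, "n_used"), 99L)
  expect_identical(attr(ests, "n_excluded"), 1L)
})

test_that("the per-0.01 increment OR is the exponentiated scaled slope", {
  set.seed(65)
  fi <- rbeta(1500, 2.2, 10.4)
  y <- rbinom(1500, 1, plogis(-2.7 + log(1.05) * 100 * fi))
  est <- frailty_increment_or(data.frame(fi = fi, y = y), "y", "fi")
  ref <- glm(y ~ I(fi * 100), family = binomial())
  expect_equal(est$odds_ratio, exp(coef(ref)[2]), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(frailty_increment_or(data.frame(fi = rep(0.2, 60),
                                               y = rbinom(60, 1, 0.5)),
                                    "y", "fi"),
               "zero variance")
})
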