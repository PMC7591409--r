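steps <- deficit_spec("steps_30m", "continuous", "higher_is_worse",
                      v_min = 21, v_max = 160)

test_that("continuous rescaling matches the min-max formula and clamps", {
  # (54 - 21) / 139
  expect_equal(rescale_continuous(54, steps), 33 / 139)
  expect_equal(rescale_continuous(21, steps), 0)
  expect_equal(rescale_continuous(160, steps), 1)
  expect_equal(rescale_continuous(200, steps), 1)   # above V_max
  expect_equal(rescale_continuous(5, steps), 0)     # below V_min
  grip <- deficit_spec("grip", "continuous", "lower_is_worse",
                       v_min = 4, v_max = 40)
  # weaker grip -> higher deficit score; score near 0 is the healthier state
  expect_equal(rescale_continuous(40, grip), 0)
  expect_equal(rescale_continuous(4, grip), 1)
  expect_equal(rescale_continuous(22, grip), 1 - 18 / 36)
  degen <- deficit_spec("d", "continuous", v_min = NA, v_max = NA)
  expect_error(rescale_continuous(1, degen), "no rescaling range")
})

test_that("rescaling is invariant to affine increasing transforms", {
  set.seed(11)
  for (i in 1:20) {
    v <- runif(1, 21, 160)
    a <- runif(1, 0.5, 3); b <- runif(1, -10, 10)
    tr <- deficit_spec("t", "continuous", "higher_is_worse",
                       v_min = a * 21 + b, v_max = a * 160 + b)
    expect_equal(rescale_continuous(a * v + b, tr),
                 rescale_continuous(v, steps), tolerance = 1e-10)
  }
})

test_that("binary scoring dichotomises at the cut-point per direction", {
  steps_bin <- deficit_spec("steps_30m", "binary", "higher_is_worse",
                            cutpoint = 54)
  expect_identical(score_binary(53, steps_bin), 0)  # < 54 steps = 0
  expect_identical(score_binary(54, steps_bin), 1)  # >= 54 steps = 1
  disease <- deficit_spec("diabetes", "binary", "higher_is_worse",
                          cutpoint = 0.5)
  expect_identical(score_binary(TRUE, disease), 1)
  expect_identical(score_binary(FALSE, disease), 0)
  grip_bin <- deficit_spec("grip", "binary", "lower_is_worse", cutpoint = 20)
  expect_identical(score_binary(19, grip_bin), 1)
  expect_identical(score_binary(21, grip_bin), 0)
})

test_that("determine_range drops extreme outliers but keeps the true range", {
  # no exclusion at the trivial rule
  expect_equal(determine_range(1:100, c(0, 1)),
               c(v_min = 1, v_max = 100))
  # a single gross outlier is excluded; the genuine extremes survive
  vals <- c(21:160, 10000)
  expect_equal(determine_range(vals), c(v_min = 21, v_max = 160))
  expect_error(determine_range(rep(5, 30)), "degenerate range")
  expect_error(determine_range(1:10), "at least 20")
})

test_that("the index is the mean over non-missing items", {
  specs <- synthetic_deficit_specs()
  healthiest <- stats::setNames(as.list(numeric(13)), names(specs))
  for (nm in names(specs)) {
    s <- specs[[nm]]
    healthiest[[nm]] <- if (s$kind == "binary") 0
      else if (s$direction == "higher_is_worse") s$v_min else s$v_max
  }
  visit0 <- c(list(participant_id = "A", visit_age = 75), healthiest)
  r0 <- compute_frailty_index(visit0, specs)
  expect_equal(r0$index, 0)
  expect_identical(r0$n_items_scored, 13L)
  expect_false(r0$frail)

  worst <- healthiest
  for (nm in names(specs)) {
    s <- specs[[nm]]
    worst[[nm]] <- if (s$kind == "binary") 1
      else if (s$direction == "higher_is_worse") s$v_max else s$v_min
  }
  r1 <- compute_frailty_index(c(list(participant_id = "A", visit_age = 75),
                                worst), specs)
  expect_equal(r1$index, 1)
  expect_true(r1$frail)

  # 12 items scored (one missing), scores summing to 3.0 -> index 0.25
  twelve <- healthiest
  twelve$diabetes <- NA
  twelve$cancer <- 1
  twelve$balance_disease <- 1
  twelve$self_rated_fall_risk <- 1
  r12 <- compute_frailty_index(c(list(participant_id = "A", visit_age = 75),
                                 twelve), specs)
  expect_identical(r12$n_items_scored, 12L)
  expect_equal(r12$index, 3 / 12)
  expect_true(r12$frail)  # 0.25 is frail under the default >= boundary

  # below the completeness threshold the index is undefined and flagged
  sparse <- healthiest
  for (nm in names(specs)[1:4]) sparse[[nm]] <- NA
  rs <- compute_frailty_index(c(list(participant_id = "A", visit_age = 75),
                                sparse), specs)
  expect_false(rs$complete)
  expect_true(is.na(rs$index))
})

test_that("frailty classification respects the cutoff and boundary", {
  expect_identical(classify_frailty(0.32), "frail")      # frail-range median
  expect_identical(classify_frailty(0.14), "non_frail")  # non-frail median
  expect_identical(classify_frailty(0.25), "frail")      # boundary, default >=
  gt <- index_config(frail_boundary = "gt")
  expect_identical(classify_frailty(0.25, gt), "non_frail")
  expect_identical(classify_frailty(c(0.1, 0.3)), c("non_frail", "frail"))
})

test_that("index is monotone in any single deficit score", {
  specs <- synthetic_deficit_specs()
  set.seed(21)
  base <- lapply(specs, function(s) {
    if (s$kind == "binary") rbinom(1, 1, 0.3)
    else runif(1, s$v_min, s$v_max)
  })
  v0 <- c(list(participant_id = "A", visit_age = 75), base)
  i0 <- compute_frailty_index(v0, specs)$index
  for (nm in names(specs)) {
    s <- specs[[nm]]
    worse <- base
    worse[[nm]] <- if (s$kind == "binary") 1
      else if (s$direction == "higher_is_worse") s$v_max else s$v_min
    i1 <- compute_frailty_index(c(list(participant_id = "A", visit_age = 75),
                                  worse), specs)$index
    expect_gte(i1 + 1e-12, i0)
  }
})

test_that("quintile sizes differ by at most one and labels are ordered", {
  q100 <- assign_quintiles(seq(0.01, 1, by = 0.01))
  expect_identical(as.vector(table(q100)), rep(20L, 5))
  # boundaries at the order statistics of the sorted sample
  expect_identical(q100[order(seq(0.01, 1, 0.01))], rep(1:5, each = 20))

  q101 <- assign_quintiles(runif(101))
  expect_identical(as.vector(table(q101)), c(21L, 20L, 20L, 20L, 20L))

  set.seed(31)
  for (n in c(5, 7, 23, 100, 457)) {
    q <- assign_quintiles(runif(n))
    expect_lte(diff(range(table(q))), 1)
    expect_identical(length(q), as.integer(n))
  }
  expect_error(assign_quintiles(runif(4)), "at least 5")
})

test_that("quintile labels are permutation invariant for distinct values", {
  set.seed(32)
  v <- sample(seq(0.01, 1, by = 0.01), 100)
  perm <- sample.int(100)
  expect_identical(assign_quintiles(v)[perm], assign_quintiles(v[perm]))
})

test_that("tied values spanning a boundary can be forced to the lower quintile", {
  v <- c(rep(0.2, 30), seq(0.3, 0.9, length.out = 70))
  stable <- assign_quintiles(v)
  expect_lte(diff(range(table(stable))), 1)
  lower <- assign_quintiles(v, ties = "lower")
  expect_true(all(lower[v == 0.2] == 1L))
})

test_that("index comparison matches a brute-force correlation", {
  set.seed(41)
  a <- runif(10, 0, 0.6)
  b <- 0.5 * a + rnorm(10, 0, 0.05)
  cmp <- compare_indices(a, b)
  r_brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cmp$r, r_brute, tolerance = 1e-12)
  expect_equal(cmp$median_a, median(a))
  expect_equal(compare_indices(a, a)$r, 1)
  expect_equal(compare_indices(a, 1 - a)$r, -1)
  expect_error(compare_indices(a, rep(0.5, 10)), "zero variance")
  expect_error(compare_indices(a[1:2], b[1:2]), "at least 3")
})

test_that("built indices are bounded and reproduce single-visit results", {
  sim <- generate_cohort(small_config(seed = 5))
  fi <- build_frailty_index(sim$cohort)
  expect_true(all(is.na(fi$index) | (fi$index >= 0 & fi$index <= 1)))
  # vectorised builder agrees with the per-visit computation
  v <- sim$cohort$visits[sim$cohort$visits$attended, ][c(3, 57, 101), ]
  for (k in seq_len(nrow(v))) {
    single <- compute_frailty_index(v[k, ], sim$cohort$deficit_specs)
    row <- fi[fi$participant_id == single$participant_id &
                fi$visit_age == single$visit_age, ]
    expect_equal(row$index, single$index)
    expect_identical(row$n_items_scored, single$n_items_scored)
  }
})
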