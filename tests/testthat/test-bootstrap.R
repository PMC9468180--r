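test_that("degenerate cohorts give zero bootstrap SE and exact determinism", {
  rows <- lapply(1:6, function(i) {
    ind_rows(sprintf("i%02d", i), c(egg = 1, female = 3),
             eggs = c(0, 0, 4, 4), prey = c(0, 2, 2, 2))
  })
  ch <- do.call(toy_cohort, rows)
  bt <- bootstrap_lifetable(ch, B = 200, seed = 3)
  expect_equal(unname(bt$se[is.finite(bt$se)]),
               rep(0, sum(is.finite(bt$se))))

  bt2 <- bootstrap_lifetable(ch, B = 200, seed = 3)
  expect_identical(bt$replicates, bt2$replicates)
})

test_that("bootstrap_se is the sample sd of defined replicates", {
  expect_equal(bootstrap_se(c(1, 2, 3)), 1)
  expect_equal(bootstrap_se(rep(4, 10)), 0)
  expect_true(is.na(bootstrap_se(c(2, NA, NaN))))
  x <- c(rnorm(50), NA)
  expect_equal(bootstrap_se(x), sd(x, na.rm = TRUE))
})

test_that("SE(R0) matches the binomial female-count delta approximation", {
  # all females identical, all males identical: R0 = E0 * N_f / n with
  # N_f binomial under resampling, so SE(R0) ~ E0 * sqrt(p(1-p)/n)
  E0 <- 30L
  n_f <- 20L; n_m <- 30L
  rows <- c(
    lapply(seq_len(n_f), function(i) {
      ind_rows(sprintf("f%02d", i), c(egg = 1, female = 3),
               eggs = c(0, 0, E0, 0))
    }),
    lapply(seq_len(n_m), function(i) {
      ind_rows(sprintf("m%02d", i), c(egg = 1, male = 3))
    }))
  ch <- do.call(toy_cohort, rows)
  bt <- bootstrap_lifetable(ch, B = 4000, seed = 5, parameters = "R0")
  p <- n_f / (n_f + n_m)
  analytic <- E0 * sqrt(p * (1 - p) / (n_f + n_m))
  expect_lt(abs(bt$se[["R0"]] - analytic) / analytic, 0.10)
})

test_that("bootstrap mean of R0 converges to the point estimate", {
  sc <- quick_scenario(seed = 26L)
  ch <- generate_cohort(sc)
  bt <- bootstrap_lifetable(ch, B = 3000, seed = 7, parameters = "R0")
  expect_lt(abs(mean(bt$replicates[, "R0"]) - bt$estimates[["R0"]]),
            3 * bt$se[["R0"]] / sqrt(3000))
})

test_that("replicates without reproduction are counted and excluded", {
  # one ovipositing female among many preadult deaths: zero-egg replicates
  rows <- c(list(ind_rows("f", c(egg = 1, female = 2), eggs = c(0, 6, 0))),
            lapply(1:9, function(i) {
              ind_rows(sprintf("d%02d", i), c(egg = 2))
            }))
  ch <- do.call(toy_cohort, rows)
  bt <- bootstrap_lifetable(ch, B = 500, seed = 9,
                            parameters = c("R0", "r", "lambda", "T"))
  expect_gt(bt$n_undefined, 0)
  zero <- bt$replicates[, "R0"] == 0
  expect_true(all(is.na(bt$replicates[zero, "r"])))
  expect_true(all(is.finite(bt$replicates[!zero, "r"])))
  expect_equal(bt$n_undefined + sum(!zero), 500)
})

test_that("paired bootstrap test: identity, antisymmetry and separation", {
  sc <- quick_scenario(seed = 28L)
  ch <- generate_cohort(sc)
  self <- paired_bootstrap_test(ch, ch, "F", B = 300, seed = 1)
  expect_false(self$significant)
  expect_equal(self$estimate, 0)

  sc2 <- quick_scenario(seed = 29L, F = 500)
  ch2 <- generate_cohort(sc2)
  ab <- paired_bootstrap_test(ch, ch2, "F", B = 600, seed = 1)
  ba <- paired_bootstrap_test(ch2, ch, "F", B = 600, seed = 1)
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$ci, -rev(ba$ci))
  expect_identical(ab$significant, ba$significant)
  # F 120 vs 500 eggs/female must separate
  expect_true(ab$significant)
})

test_that("percentile cohorts use ceiling-rank order statistics of lambda", {
  sc <- quick_scenario(seed = 30L)
  ch <- generate_cohort(sc)
  pc <- percentile_cohorts(ch, B = 40, seed = 2)
  expect_identical(pc$ranks, c(1L, 39L))
  expect_lte(pc$lambda[["lower"]], pc$lambda[["upper"]])

  fit <- lifetable(ch)
  pc2 <- percentile_cohorts(ch, B = 400, seed = 2)
  expect_lte(pc2$lambda[["lower"]], fit$params[["lambda"]])
  expect_gte(pc2$lambda[["upper"]], fit$params[["lambda"]])
  # the returned cohorts reproduce their order-statistic lambdas
  # two independent Euler-Lotka solvers (scalar vs vectorised bisection)
  expect_equal(lifetable(pc2$lower)$params[["lambda"]],
               unname(pc2$lambda["lower"]), tolerance = 1e-8)
  expect_equal(lifetable(pc2$upper)$params[["lambda"]],
               unname(pc2$lambda["upper"]), tolerance = 1e-8)

  expect_error(percentile_cohorts(ch, B = 39, seed = 1), "at least 40")
})

test_that("bootstrap SEs are stable across seeds", {
  sc <- quick_scenario(seed = 32L)
  ch <- generate_cohort(sc)
  se1 <- bootstrap_lifetable(ch, B = 4000, seed = 1,
                             parameters = "F")$se[["F"]]
  se2 <- bootstrap_lifetable(ch, B = 4000, seed = 99,
                             parameters = "F")$se[["F"]]
  expect_lt(abs(se1 - se2) / se1, 0.05)
})
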