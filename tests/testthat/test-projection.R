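test_that("schedules from deterministic cohorts are 0/1 and conserve mass", {
  ch <- toy_cohort(ind_rows("a", c(egg = 2, L1 = 3)),
                   ind_rows("b", c(egg = 2, L1 = 3)))
  sched <- build_schedule(ch)
  expect_true(all(sched$trans %in% c(0, 1)))
  out_mass <- apply(sched$trans, c(1, 2), sum)
  expect_true(all(out_mass <= 1 + 1e-12))
  # everyone moves egg->egg at age 0, egg->L1 at age 1
  expect_equal(unname(sched$trans["0", "egg", "egg"]), 1)
  expect_equal(unname(sched$trans["1", "egg", "L1"]), 1)
  # the final age transitions nowhere (death)
  expect_equal(sum(sched$trans["4", , ]), 0)
})

test_that("reprojecting the cohort's own start reproduces n_xj exactly", {
  sc <- quick_scenario(seed = 34L)
  gch <- generate_cohort(sc)
  fit <- lifetable(gch)
  sched <- build_schedule(fit)
  init <- matrix(0, 1, 8, dimnames = list(0, stage_order()))
  init[1, "egg"] <- gch$n_01
  counts <- fit$counts
  # original mass sits at age t on day t; offspring are all younger
  for (t in c(1L, 5L, 15L, sched$max_age)) {
    st <- project_population(sched, init, horizon = t)$final_state
    expect_equal(unname(st[t + 1L, ]),
                 unname(as.numeric(counts[t + 1L, ])),
                 tolerance = 1e-9, label = paste("day", t))
  }
})

test_that("mass conservation per step: survivors plus newborns", {
  sc <- quick_scenario(seed = 36L)
  gch <- generate_cohort(sc)
  fit <- lifetable(gch)
  sched <- build_schedule(fit)
  pr <- project_population(sched, initial_pairs(fit), horizon = 40)
  # recompute one step by hand from the day-10 state
  pr10 <- project_population(sched, initial_pairs(fit), horizon = 10)
  st <- pr10$final_state
  births <- sum(sched$f_xj * st)
  survivors <- 0
  for (y in 1:8) {
    survivors <- survivors +
      sum(st[-nrow(st), ] * sched$trans[-nrow(st), , y])
  }
  expect_equal(pr$N_t[12], births + survivors, tolerance = 1e-9)
})

test_that("non-reproducing survivable window keeps N constant; zero start stays zero", {
  ch <- toy_cohort(ind_rows("a", c(egg = 10)), ind_rows("b", c(egg = 10)))
  sched <- build_schedule(ch)
  init <- matrix(0, 1, 8, dimnames = list(0, stage_order()))
  init[1, "egg"] <- 7
  pr <- project_population(sched, init, horizon = 5)
  expect_equal(pr$N_t, rep(7, 6))
  expect_equal(project_population(sched, init * 0, horizon = 5)$N_t,
               rep(0, 6))
  expect_error(project_population(sched,
                                  matrix(0, 50, 8,
                                         dimnames = list(0:49,
                                                         stage_order())),
                                  horizon = 2),
               "beyond max_age")
})

test_that("asymptotic growth matches lambda and P/N converges to psi", {
  sc <- quick_scenario(seed = 38L)
  gch <- generate_cohort(sc)
  fit <- lifetable(gch)
  pred <- predation_rates(fit)
  sched <- build_schedule(fit)
  init <- matrix(0, 1, 8, dimnames = list(0, stage_order()))
  init[1, "egg"] <- 1
  horizon <- 3L * sched$max_age + 30L
  pr <- project_population(sched, init, horizon)
  n <- length(pr$N_t)
  growth <- pr$N_t[n] / pr$N_t[n - 1L]
  expect_lt(abs(growth - fit$params[["lambda"]]) / fit$params[["lambda"]],
            1e-3)
  expect_lt(abs(pr$P_t[n] / pr$N_t[n] - pred$params[["psi"]]) /
              pred$params[["psi"]], 1e-3)
})

test_that("percentile bands usually bracket the point projection", {
  # bracketing is a stochastic property; require 8 of 10 seeded runs
  hits <- 0L
  for (s in 1:10) {
    gch <- generate_cohort(quick_scenario(seed = 200L + s))
    pb <- project_with_bands(gch, horizon = 90, B = 200, seed = s)
    n <- 91L
    hits <- hits + (pb$lower$N_t[n] <= pb$point$N_t[n] &&
                      pb$upper$N_t[n] >= pb$point$N_t[n])
  }
  expect_gte(hits, 8L)
  gch <- generate_cohort(quick_scenario(seed = 40L))
  expect_error(project_with_bands(gch, B = 30, seed = 1), "at least 40")
})

test_that("resampling identical individuals projects identically", {
  rows <- lapply(1:8, function(i) {
    ind_rows(sprintf("i%02d", i), c(egg = 1, female = 4),
             eggs = c(0, 0, 3, 3, 0), prey = c(0, 1, 1, 1, 1))
  })
  ch <- do.call(toy_cohort, rows)
  init <- matrix(0, 1, 8, dimnames = list(0, stage_order()))
  init[1, "egg"] <- 20
  pb <- project_with_bands(ch, initial = init, horizon = 20, B = 50,
                           seed = 6)
  expect_equal(pb$lower$N_t, pb$point$N_t, tolerance = 1e-12)
  expect_equal(pb$upper$N_t, pb$point$N_t, tolerance = 1e-12)
})
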