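test_that("c_xj is the per-cell mean with structural zeros for egg and pupa", {
  ch <- toy_cohort(
    ind_rows("a", c(egg = 1, L1 = 2), prey = c(0, 7, 7)),
    ind_rows("b", c(egg = 1, L1 = 2), prey = c(0, 7, 7)))
  cxj <- compute_cxj(ch)
  expect_equal(unname(cxj["1", "L1"]), 7)
  expect_equal(unname(cxj[, "egg"]), rep(0, nrow(cxj)))

  sc <- quick_scenario(seed = 12L)
  gch <- generate_cohort(sc)
  cxj <- compute_cxj(gch)
  d <- gch$data
  # brute-force per-cell oracle
  for (x in c(4L, 9L, 20L)) {
    for (j in c("L2", "L4", "female")) {
      rows <- d$age == x & d$stage == j & d$alive == 1L
      want <- if (any(rows)) mean(d$prey_consumed[rows]) else 0
      expect_equal(unname(cxj[as.character(x), j]), want,
                   label = paste(x, j))
    }
  }
  expect_equal(unname(cxj[, "pupa"]), rep(0, nrow(cxj)))
})

test_that("k_x and q_x identities", {
  sc <- quick_scenario(seed = 14L)
  gch <- generate_cohort(sc)
  fit <- lifetable(gch)
  cxj <- compute_cxj(gch)
  k <- compute_kx(fit$s_xj, cxj)
  q <- compute_qx(fit$l_x, k)
  # both Eq-12 forms agree at every age
  expect_equal(q, rowSums(fit$s_xj * cxj), tolerance = 1e-12)
  expect_true(all(q <= k + 1e-12))
  # ages where everyone is still an egg have zero predation
  egg_only <- rowSums(fit$s_xj[, -1, drop = FALSE]) == 0 & fit$l_x > 0
  expect_equal(unname(k[egg_only]), rep(0, sum(egg_only)))

  # single-stage occupancy: k equals that stage's c
  one <- toy_cohort(ind_rows("a", c(egg = 1, L1 = 1), prey = c(0, 9)))
  f1 <- lifetable(one)
  c1 <- compute_cxj(one)
  expect_equal(unname(compute_kx(f1$s_xj, c1)["1"]), 9)
})

test_that("C0 is conserved mass: total prey over n_01", {
  sc <- quick_scenario(seed = 16L)
  gch <- generate_cohort(sc)
  pred <- predation_rates(lifetable(gch))
  expect_equal(unname(pred$params["C0"]),
               sum(gch$data$prey_consumed) / gch$n_01, tolerance = 1e-12)
  expect_equal(sum(pred$q_x), unname(pred$params["C0"]), tolerance = 1e-12)

  nofeed <- toy_cohort(ind_rows("a", c(egg = 2, pupa = 1)))
  p0 <- predation_rates(lifetable(nofeed))
  expect_equal(unname(p0$params["C0"]), 0)
  expect_equal(unname(p0$params["Qp"]), 0)
})

test_that("the transformation rate divides predation by reproduction", {
  expect_equal(compute_Qp(7935.54, 198.02), 7935.54 / 198.02)
  expect_equal(compute_Qp(0, 0), 0)
  expect_error(compute_Qp(10, 0), "R0 = 0")
})

test_that("stable age-stage distribution: normalisation and limiting case", {
  # lambda = 1 and one stage occupied over three ages: uniform thirds
  s <- matrix(0, 3, 8, dimnames = list(0:2, stage_order()))
  s[, "L1"] <- 1
  a <- compute_sasd(s, lambda = 1)
  expect_equal(unname(a[, "L1"]), rep(1 / 3, 3))
  expect_equal(sum(a), 1)

  sc <- quick_scenario(seed = 18L)
  fit <- lifetable(generate_cohort(sc))
  a <- compute_sasd(fit$s_xj, fit$params[["lambda"]])
  expect_equal(sum(a), 1, tolerance = 1e-12)
})

test_that("sasd closed form agrees with long-run projection composition", {
  sc <- quick_scenario(seed = 20L)
  gch <- generate_cohort(sc)
  fit <- lifetable(gch)
  a <- compute_sasd(fit$s_xj, fit$params[["lambda"]])
  sched <- build_schedule(fit)
  init <- matrix(0, 1, 8, dimnames = list(0, stage_order()))
  init[1, "egg"] <- 100
  horizon <- 3L * sched$max_age + 30L
  pr <- project_population(sched, init, horizon)
  comp <- pr$final_state / sum(pr$final_state)
  expect_lt(sum(abs(comp - a)) / 2, 1e-3)  # total-variation distance
})

test_that("psi and omega satisfy the finite-predation identity", {
  sc <- quick_scenario(seed = 22L)
  fit <- lifetable(generate_cohort(sc))
  pred <- predation_rates(fit)
  lam <- fit$params[["lambda"]]
  expect_equal(unname(pred$params["omega"]),
               lam * unname(pred$params["psi"]), tolerance = 1e-15)
  po <- compute_psi_omega(pred$a_xj, pred$c_xj, lam)
  expect_equal(po$psi, unname(pred$params["psi"]), tolerance = 1e-12)

  nofeed <- toy_cohort(
    ind_rows("f", c(egg = 1, female = 2), eggs = c(0, 2, 1)))
  pn <- predation_rates(lifetable(nofeed))
  expect_equal(unname(pn$params[c("psi", "omega")]), c(0, 0))
})

test_that("stage daily predation divides prey by stage days", {
  ch <- toy_cohort(ind_rows("a", c(egg = 1, L1 = 3),
                            prey = c(0, 10, 10, 10)))
  dj <- stage_daily_predation(ch)
  expect_equal(unname(dj["L1"]), 10)
  expect_equal(unname(dj["preadult"]), 30 / 4)  # egg day in the denominator

  sc <- quick_scenario(seed = 24L)
  gch <- generate_cohort(sc)
  dj <- stage_daily_predation(gch)
  d <- gch$data[gch$data$alive == 1L, ]
  for (j in c("L2", "female")) {
    rows <- d$stage == j
    expect_equal(unname(dj[j]),
                 sum(d$prey_consumed[rows]) / sum(rows), label = j)
  }
})
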