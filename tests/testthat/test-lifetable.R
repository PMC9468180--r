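test_that("survival grids and l_x match direct counting", {
  ch <- toy_cohort(ind_rows("a", c(egg = 3)), ind_rows("b", c(egg = 3)),
                   ind_rows("c", c(egg = 3)))
  s <- compute_sxj(agestage_counts(ch))
  expect_equal(unname(s["1", "egg"]), 1)
  expect_error(compute_sxj(agestage_counts(ch), n_01 = 0), "positive")

  sc <- quick_scenario(seed = 2L)
  gch <- generate_cohort(sc)
  s <- compute_sxj(agestage_counts(gch), gch$n_01)
  l <- compute_lx(s)
  expect_equal(unname(l[1]), 1)
  # oracle: direct alive count per age / n_01
  d <- gch$data
  for (x in c(0L, 3L, 10L, 25L)) {
    expect_equal(unname(l[as.character(x)]),
                 sum(d$age == x & d$alive == 1L) / gch$n_01)
  }
  expect_equal(rowSums(s), l)  # sum over stages is l_x, exactly
  expect_true(all(diff(l) <= 1e-12))
})

test_that("m_x averages eggs over the two-sex survivor pool", {
  # one female laying 10 and one male alive at the same age: m = 5
  ch <- toy_cohort(
    ind_rows("f", c(egg = 1, female = 2), eggs = c(0, 0, 10)),
    ind_rows("m", c(egg = 1, male = 2)))
  fit <- lifetable(ch)
  expect_equal(unname(fit$m_x[as.character(2)]), 5)
  expect_equal(unname(fit$m_x[fit$l_x == 0]),
               rep(0, sum(fit$l_x == 0)))

  # conservation: sum l_x m_x = total eggs / n_01 on any cohort
  sc <- quick_scenario(seed = 4L)
  gch <- generate_cohort(sc)
  gfit <- lifetable(gch)
  expect_equal(sum(gfit$l_x * gfit$m_x),
               sum(gch$data$eggs_laid) / gch$n_01, tolerance = 1e-12)
  # Chi's identity R0 = F * N_female / n_01, exactly
  expect_equal(gfit$params[["R0"]],
               gfit$params[["F"]] * gfit$reproduction$n_female / gch$n_01,
               tolerance = 1e-12)
})

test_that("the Euler-Lotka solver matches closed forms and a grid oracle", {
  # net maternity concentrated at one age: r = ln(R0)/(x+1)
  lxmx <- c(0, 0, 0, 8, 0)
  r <- solve_r(lxmx, rep(1, 5))
  expect_equal(r, log(8) / 4, tolerance = 1e-10)

  # R0 = 1 spread across ages: r = 0
  expect_equal(solve_r(c(0.2, 0.5, 0.3), rep(1, 3)), 0, tolerance = 1e-10)

  # two-age schedule vs brute-force 1e-6 grid search
  lm <- c(0, 2, 2)
  r <- solve_r(lm, rep(1, 3))
  grid <- seq(0.5, 1.5, by = 1e-6)
  resid <- abs(sapply(grid, function(rr) sum(exp(-rr * (1:3)) * lm) - 1))
  expect_lt(abs(r - grid[which.min(resid)]), 2e-6)
  # residual at the solution
  expect_lt(abs(sum(exp(-r * (1:3)) * lm) - 1), 1e-10)

  expect_error(solve_r(c(0, 0), c(1, 1)), "R0 = 0")
})

test_that("lambda and T identities hold to machine precision", {
  expect_equal(compute_lambda(0), 1)
  expect_equal(compute_T(exp(1), 1), 1)
  sc <- quick_scenario(seed = 6L)
  fit <- lifetable(generate_cohort(sc))
  p <- coef(fit)
  expect_equal(p[["lambda"]], exp(p[["r"]]), tolerance = 1e-15)
  expect_equal(p[["T"]], log(p[["R0"]]) / p[["r"]], tolerance = 1e-15)
  expect_true(is.na(compute_T(5, 0)))
})

test_that("life expectancy equals conditional mean remaining lifespan", {
  # deterministic cohort: e declines by exactly one day along the course
  ch <- toy_cohort(ind_rows("a", c(egg = 2, L1 = 3)),
                   ind_rows("b", c(egg = 2, L1 = 3)))
  e <- compute_exj(ch)
  expect_equal(unname(e["0", "egg"]), 5)
  expect_equal(unname(e["1", "egg"]), 4)
  expect_equal(unname(e["4", "L1"]), 1)
  expect_true(is.na(e["0", "L1"]))

  # e_01 is the cohort mean lifespan, preadult deaths included
  sc <- quick_scenario(seed = 8L)
  gch <- generate_cohort(sc)
  e <- compute_exj(gch)
  s <- agestage:::individual_stats(gch)
  expect_equal(unname(e["0", "egg"]), mean(s$lifespan), tolerance = 1e-12)
})

test_that("reproductive value reduces to lambda at birth and to hand sums", {
  sc <- quick_scenario(seed = 10L)
  gch <- generate_cohort(sc)
  fit <- lifetable(gch)
  expect_equal(unname(fit$v_xj["0", "egg"]), fit$params[["lambda"]],
               tolerance = 1e-9)
  # ages past the last egg have zero reproductive value
  last_rep <- max(gch$data$age[gch$data$eggs_laid > 0])
  late <- fit$v_xj[as.numeric(rownames(fit$v_xj)) > last_rep, ]
  expect_equal(unname(late[!is.na(late)]),
               rep(0, sum(!is.na(late))))

  # three-day toy, spreadsheet oracle: single female, eggs on days 1 and 2
  ch <- toy_cohort(ind_rows("f", c(egg = 1, female = 2),
                            eggs = c(0, 3, 2)))
  fit <- lifetable(ch)
  r <- fit$params[["r"]]
  v1 <- exp(r * 2) * (exp(-r * 2) * 3 + exp(-r * 3) * 2)
  expect_equal(unname(fit$v_xj["1", "female"]), v1, tolerance = 1e-12)
  expect_equal(unname(fit$v_xj["0", "egg"]), exp(r), tolerance = 1e-9)
})

test_that("reproduction and stage summaries match hand computation", {
  # female emerges at age 20, first egg at 28: APOP 8, TPOP 28
  ch <- toy_cohort(
    ind_rows("f", c(egg = 5, L1 = 5, L2 = 3, L3 = 3, L4 = 2, pupa = 2,
                    female = 12),
             eggs = c(rep(0, 28), 4, 3, 0, 2)),
    ind_rows("m", c(egg = 5, L1 = 5, L2 = 3, L3 = 3, L4 = 2, pupa = 2,
                    male = 5)))
  rs <- reproduction_summaries(ch)
  expect_equal(rs$APOP, 8)
  expect_equal(rs$TPOP, 28)
  expect_equal(rs$F, 9)
  expect_equal(rs$Od, 3)

  ss <- stage_summaries(ch)
  expect_equal(unname(ss$duration_mean),
               c(5, 5, 3, 3, 2, 2))
  expect_equal(ss$preadult_mean, 20)
  expect_equal(unname(ss$adult_longevity), c(12, 5))
  expect_equal(unname(ss$total_longevity), c(32, 25))
  expect_equal(ss$preadult_survival, 1)

  # preadult deaths lower s_a and never contribute reproduction fields
  ch2 <- toy_cohort(ind_rows("d", c(egg = 2)),
                    ind_rows("f", c(egg = 2, female = 3),
                             eggs = c(0, 0, 0, 5, 0)))
  rs2 <- reproduction_summaries(ch2)
  expect_equal(rs2$n_female, 1L)
  expect_equal(stage_summaries(ch2)$preadult_survival, 0.5)
  fit2 <- lifetable(ch2)
  expect_equal(fit2$params[["R0"]], 5 * 1 / 2)  # F * N_f / n_01
})

test_that("a cohort with no reproduction leaves the rate parameters undefined", {
  ch <- toy_cohort(ind_rows("a", c(egg = 2, male = 2)),
                   ind_rows("b", c(egg = 3)))
  fit <- lifetable(ch)
  expect_equal(fit$params[["R0"]], 0)
  expect_true(all(is.na(fit$params[c("r", "lambda", "T")])))
})
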