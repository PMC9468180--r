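# Hand-built cohort fixtures: one individual's rows from a named vector of
# days per stage (in developmental order). eggs/prey align with alive days.
ind_rows <- function(id, stage_days, eggs = NULL, prey = NULL) {
  stages <- rep(names(stage_days), stage_days)
  k <- length(stages)
  if (is.null(eggs)) eggs <- integer(k)
  if (is.null(prey)) prey <- integer(k)
  data.frame(individual_id = id, age = 0:k,
             stage = c(stages, stages[k]),
             alive = c(rep(1L, k), 0L),
             eggs_laid = c(as.integer(eggs), 0L),
             prey_consumed = c(as.integer(prey), 0L),
             stringsAsFactors = FALSE)
}

toy_cohort <- function(..., label = NULL) {
  cohort(do.call(rbind, list(...)), label = label)
}

# deterministic scenario: everything survives, no duration spread
det_scenario <- function(F = 60, Od = 5, apop = 2,
                         lon_f = 20, lon_m = 15, sex_ratio = 0.5,
                         pred = c(L1 = 2, L2 = 4, L3 = 6, L4 = 8,
                                  female = 10, male = 9),
                         seed = 11L) {
  pre <- preadult_stages()
  scenario(label = "det", n_01 = 50L,
           duration_mean = stats::setNames(c(2, 2, 2, 2, 3, 3), pre),
           duration_sd = stats::setNames(rep(0, 6), pre),
           survival = stats::setNames(rep(1, 6), pre),
           sex_ratio_female = sex_ratio,
           adult_longevity_mean = c(female = lon_f, male = lon_m),
           adult_longevity_sd = c(female = 0, male = 0),
           fecundity_total_mean = F, oviposition_days_mean = Od,
           apop_mean = apop,
           predation_daily_mean = pred, rng_seed = seed)
}

# a small fast stochastic scenario (short lifespans keep row counts down)
quick_scenario <- function(seed = 5L, n_01 = 50L, F = 120) {
  sc <- default_scenarios(seed = seed)[["30C"]]
  sc$n_01 <- as.integer(n_01)
  sc$fecundity_total_mean <- F
  sc$rng_seed <- as.integer(seed)
  sc
}
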