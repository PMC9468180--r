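#' Define a synthetic-cohort scenario
#'
#' A scenario bundles the statistical targets used by
#' \code{\link{generate_cohort}}: per-stage development-time means and
#' individual-level standard deviations (days), per-stage completion
#' probabilities, the female fraction at emergence, adult longevity by sex,
#' the fecundity targets (lifetime eggs per female \code{F},
#' oviposition days \code{Od}, adult pre-oviposition period \code{APOP})
#' and per-stage mean daily predation.
#'
#' @param label scenario name, e.g. \code{"25C"}.
#' @param n_01 cohort size at oviposition.
#' @param duration_mean,duration_sd named numeric vectors over the six
#'   preadult stages (egg, L1--L4, pupa), in days.
#' @param survival named numeric vector over the preadult stages:
#'   probability of completing each stage given entry.
#' @param sex_ratio_female probability an emerging adult is female.
#' @param adult_longevity_mean,adult_longevity_sd named vectors
#'   (\code{female}, \code{male}), adult days.
#' @param fecundity_total_mean expected lifetime eggs per female (F target).
#' @param oviposition_days_mean expected number of egg-laying days (Od).
#' @param apop_mean mean adult pre-oviposition period, days.
#' @param predation_daily_mean named vector of mean prey consumed per day
#'   for L1, L2, L3, L4, female and male (egg and pupa do not feed).
#' @param rng_seed integer seed making \code{\link{generate_cohort}}
#'   reproducible.
#' @return An object of class \code{"scenario"}.
#' @export
scenario <- function(label, n_01,
                     duration_mean, duration_sd, survival,
                     sex_ratio_female,
                     adult_longevity_mean, adult_longevity_sd,
                     fecundity_total_mean, oviposition_days_mean, apop_mean,
                     predation_daily_mean, rng_seed = 1L) {
  pre <- preadult_stages()
  feed <- c("L1", "L2", "L3", "L4", "female", "male")
  stopifnot(setequal(names(duration_mean), pre),
            setequal(names(duration_sd), pre),
            setequal(names(survival), pre),
            setequal(names(adult_longevity_mean), c("female", "male")),
            setequal(names(adult_longevity_sd), c("female", "male")),
            setequal(names(predation_daily_mean), feed))
  if (any(duration_mean < 1)) {
    stop("scenario config error: duration_mean must be >= 1 day",
         call. = FALSE)
  }
  stopifnot(all(duration_sd >= 0), all(survival >= 0 & survival <= 1),
            sex_ratio_female >= 0, sex_ratio_female <= 1,
            all(adult_longevity_mean >= 1),
            fecundity_total_mean > 0, oviposition_days_mean > 0,
            apop_mean >= 0, all(predation_daily_mean >= 0), n_01 >= 1)
  structure(list(label = label, n_01 = as.integer(n_01),
                 duration_mean = duration_mean[pre],
                 duration_sd = duration_sd[pre],
                 survival = survival[pre],
                 sex_ratio_female = sex_ratio_female,
                 adult_longevity_mean = adult_longevity_mean[c("female", "male")],
                 adult_longevity_sd = adult_longevity_sd[c("female", "male")],
                 fecundity_total_mean = fecundity_total_mean,
                 oviposition_days_mean = oviposition_days_mean,
                 apop_mean = apop_mean,
                 predation_daily_mean = predation_daily_mean[feed],
                 rng_seed = as.integer(rng_seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario '", x$label, "': n_01 = ", x$n_01,
      ", preadult survival = ",
      round(prod(x$survival), 3),
      ", F target = ", x$fecundity_total_mean, " eggs/female\n", sep = "")
  invisible(x)
}

#' The four default temperature scenarios
#'
#' Scenario parameterisations emulating the published four-temperature
#' (15/20/25/30 degrees C) cohort study of \emph{Harmonia axyridis} reared
#' on \emph{Spodoptera litura} eggs: cohorts of 50 eggs; stage-duration
#' means with individual spread sd = SE * sqrt(n); per-stage completion
#' probabilities derived from the published stage-by-stage sample-size
#' chain (their product reproduces the published preadult survival 0.92,
#' 0.92, 0.82 and 0.76); observed female fractions at emergence (18/46,
#' 24/46, 19/41, 20/38); fecundity, oviposition-day and pre-oviposition
#' targets; and stage mean daily predation.
#'
#' @param seed base RNG seed; scenario i uses \code{seed + i - 1}.
#' @return Named list of four \code{\link{scenario}} objects
#'   (\code{"15C"}, \code{"20C"}, \code{"25C"}, \code{"30C"}).
#' @export
default_scenarios <- function(seed = 1L) {
  pre <- preadult_stages()
  mk <- function(i, label, dur, se, n_chain, sexes, lon, lon_se, lon_n,
                 Fm, Od, apop, pred) {
    names(dur) <- names(se) <- pre
    # completion probability of stage j = completers_j / enterers_j
    enter <- c(50, n_chain[-6L])
    surv <- n_chain / enter
    names(surv) <- pre
    scenario(label = label, n_01 = 50L,
             duration_mean = dur, duration_sd = se * sqrt(n_chain),
             survival = surv,
             sex_ratio_female = sexes[1L] / sum(sexes),
             adult_longevity_mean = c(female = lon[1L], male = lon[2L]),
             adult_longevity_sd = c(female = lon_se[1L] * sqrt(lon_n[1L]),
                                    male = lon_se[2L] * sqrt(lon_n[2L])),
             fecundity_total_mean = Fm, oviposition_days_mean = Od,
             apop_mean = apop,
             predation_daily_mean = c(L1 = pred[1L], L2 = pred[2L],
                                      L3 = pred[3L], L4 = pred[4L],
                                      female = pred[5L], male = pred[6L]),
             rng_seed = seed + i - 1L)
  }
  list(
    "15C" = mk(1L, "15C",
               dur = c(6.02, 7.08, 5.33, 5.19, 8.85, 11.80),
               se = c(0.11, 0.12, 0.10, 0.09, 0.20, 0.24),
               n_chain = c(50, 49, 49, 48, 47, 46),
               sexes = c(18, 28),
               lon = c(105.94, 88.32), lon_se = c(3.85, 2.76),
               lon_n = c(18, 28),
               Fm = 550.06, Od = 26.94, apop = 11.50,
               pred = c(8.02, 17.56, 32.65, 77.08, 86.30, 74.40)),
    "20C" = mk(2L, "20C",
               dur = c(4.72, 4.50, 4.00, 4.67, 7.02, 8.02),
               se = c(0.09, 0.09, 0.07, 0.09, 0.14, 0.12),
               n_chain = c(50, 48, 48, 48, 46, 46),
               sexes = c(24, 22),
               lon = c(81.25, 71.68), lon_se = c(1.86, 2.28),
               lon_n = c(24, 22),
               Fm = 495.75, Od = 22.83, apop = 12.88,
               pred = c(13.62, 20.58, 40.44, 140.95, 146.79, 110.36)),
    "25C" = mk(3L, "25C",
               dur = c(3.00, 3.23, 2.62, 2.98, 3.90, 4.88),
               se = c(0.07, 0.06, 0.07, 0.06, 0.09, 0.08),
               n_chain = c(50, 49, 44, 44, 42, 41),
               sexes = c(19, 22),
               lon = c(70.58, 61.82), lon_se = c(2.68, 1.99),
               lon_n = c(19, 22),
               Fm = 484.74, Od = 19.32, apop = 10.00,
               pred = c(17.43, 30.43, 56.20, 166.04, 193.91, 150.43)),
    "30C" = mk(4L, "30C",
               dur = c(2.47, 2.24, 1.64, 2.11, 3.21, 3.74),
               se = c(0.07, 0.06, 0.07, 0.08, 0.06, 0.07),
               n_chain = c(49, 46, 44, 44, 43, 38),
               sexes = c(20, 18),
               lon = c(46.65, 37.61), lon_se = c(1.63, 0.99),
               lon_n = c(20, 18),
               Fm = 334.80, Od = 16.65, apop = 8.85,
               pred = c(22.94, 36.61, 70.29, 175.83, 223.41, 164.58))
  )
}

#' Published population and predation parameter estimates
#'
#' The published point estimates (bootstrap means) of the population and
#' predation parameters for \emph{Harmonia axyridis} fed \emph{Spodoptera
#' litura} eggs at the four rearing temperatures, together with the adult
#' sex counts and initial cohort size. These serve as calibration targets
#' for \code{\link{default_scenarios}} and as inputs to the
#' internal-consistency identities linking them
#' (\code{T = ln(R0)/r}, \code{lambda = exp(r)},
#' \code{R0 = F * N_f / n_01}, \code{Qp = C0/R0}, \code{omega = lambda *
#' psi}).
#'
#' @return data.frame with one row per parameter and one column per
#'   temperature (\code{t15}, \code{t20}, \code{t25}, \code{t30}).
#' @export
reference_estimates <- function() {
  p <- c("R0", "r", "lambda", "T", "F", "Od", "APOP", "TPOP",
         "C0", "Qp", "omega", "psi", "preadult_survival",
         "n_female", "n_male", "n_01")
  data.frame(
    parameter = p,
    t15 = c(198.02, 0.0662, 1.0685, 79.84, 550.06, 26.94, 11.50, 56.17,
            7935.54, 40.0744, 19.1684, 17.9399, 0.92, 18, 28, 50),
    t20 = c(237.96, 0.0843, 1.0880, 64.90, 495.75, 22.83, 12.88, 45.46,
            10466.28, 43.9834, 34.3995, 31.6179, 0.92, 24, 22, 50),
    t25 = c(184.20, 0.1067, 1.1126, 48.89, 484.74, 19.32, 10.00, 30.63,
            10139.38, 55.0455, 50.2287, 45.1458, 0.82, 19, 22, 50),
    t30 = c(133.92, 0.1378, 1.1477, 35.55, 334.80, 16.65, 8.85, 24.25,
            7126.36, 53.2136, 61.9303, 53.9603, 0.76, 20, 18, 50),
    row.names = p)
}

#' Write / read a scenario as a flat key=value config file
#'
#' Serialises a \code{\link{scenario}} as one \code{key = value} pair per
#' line (vectors comma-separated in stage order), with units noted in
#' comments, and reads it back.
#'
#' @param x a \code{\link{scenario}}.
#' @param path file path.
#' @return \code{write_scenario}: \code{path} invisibly;
#'   \code{read_scenario}: a \code{\link{scenario}}.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "scenario"))
  num <- function(v) paste(sprintf("%.17g", unname(v)), collapse = ",")
  lines <- c(
    "# synthetic cohort scenario; durations/longevities in days,",
    "# predation in prey/day, fecundity in eggs/female",
    paste0("label = ", x$label),
    paste0("n_01 = ", x$n_01),
    paste0("duration_mean = ", num(x$duration_mean)),
    paste0("duration_sd = ", num(x$duration_sd)),
    paste0("survival = ", num(x$survival)),
    paste0("sex_ratio_female = ", num(x$sex_ratio_female)),
    paste0("adult_longevity_mean = ", num(x$adult_longevity_mean)),
    paste0("adult_longevity_sd = ", num(x$adult_longevity_sd)),
    paste0("fecundity_total_mean = ", num(x$fecundity_total_mean)),
    paste0("oviposition_days_mean = ", num(x$oviposition_days_mean)),
    paste0("apop_mean = ", num(x$apop_mean)),
    paste0("predation_daily_mean = ", num(x$predation_daily_mean)),
    paste0("rng_seed = ", x$rng_seed))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(p) p[2L]),
                          vapply(kv, function(p) trimws(p[1L]), ""))
  num <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1L]])
  pre <- preadult_stages()
  scenario(label = trimws(vals[["label"]]),
           n_01 = num("n_01"),
           duration_mean = stats::setNames(num("duration_mean"), pre),
           duration_sd = stats::setNames(num("duration_sd"), pre),
           survival = stats::setNames(num("survival"), pre),
           sex_ratio_female = num("sex_ratio_female"),
           adult_longevity_mean = stats::setNames(
             num("adult_longevity_mean"), c("female", "male")),
           adult_longevity_sd = stats::setNames(
             num("adult_longevity_sd"), c("female", "male")),
           fecundity_total_mean = num("fecundity_total_mean"),
           oviposition_days_mean = num("oviposition_days_mean"),
           apop_mean = num("apop_mean"),
           predation_daily_mean = stats::setNames(
             num("predation_daily_mean"),
             c("L1", "L2", "L3", "L4", "female", "male")),
           rng_seed = num("rng_seed"))
}
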