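# gamma(shape, scale) matched to mean/sd, rounded to integer days, floor 1;
# sd = 0 degenerates to round(mean)
discretized_gamma <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(1L, as.integer(round(mean))), n))
  shape <- (mean / sd)^2
  draws <- stats::rgamma(n, shape = shape, scale = sd^2 / mean)
  pmax(1L, as.integer(round(draws)))
}

#' Sample per-stage development times for one individual
#'
#' Durations are drawn from a gamma distribution matched to the scenario's
#' per-stage mean and sd, rounded to the nearest whole day with a floor of
#' one day. A right-skewed positive family is the natural choice for
#' development times; with \code{sd = 0} the draw is deterministic.
#'
#' @param config a \code{\link{scenario}}.
#' @return Named integer vector of days over the six preadult stages.
#' @export
sample_stage_durations <- function(config) {
  stopifnot(inherits(config, "scenario"))
  d <- mapply(function(m, s) discretized_gamma(1L, m, s),
              config$duration_mean, config$duration_sd)
  stats::setNames(as.integer(d), preadult_stages())
}

# triangular daily-mean weights over an oviposition span: linear rise to a
# peak at ~1/3 of the reproductive life, then linear decline; sums to 1
triangular_weights <- function(span) {
  if (span == 1L) return(1)
  peak <- max(1L, round(span / 3))
  d <- seq_len(span)
  w <- ifelse(d <= peak, d / peak, (span + 1L - d) / (span + 1L - peak))
  w / sum(w)
}

#' Sample a daily fecundity schedule for one female
#'
#' Zero eggs through an adult pre-oviposition period drawn from a geometric
#' distribution with mean \code{apop_mean}; afterwards, daily counts follow
#' a zero-inflated Poisson whose daily means trace a triangular profile
#' (peak at one third of the reproductive life) scaled so the expected
#' lifetime total equals the scenario's \code{F} target and the expected
#' number of positive days equals the \code{Od} target. A female whose
#' pre-oviposition draw reaches or exceeds her adult lifespan lays nothing.
#'
#' @param config a \code{\link{scenario}}.
#' @param adult_lifespan adult days lived (>= 1).
#' @return Integer vector of length \code{adult_lifespan}: eggs laid on
#'   each adult day.
#' @export
sample_fecundity_schedule <- function(config, adult_lifespan) {
  stopifnot(inherits(config, "scenario"), adult_lifespan >= 1)
  eggs <- integer(adult_lifespan)
  apop <- stats::rgeom(1L, prob = 1 / (1 + config$apop_mean))
  span <- adult_lifespan - apop
  if (span < 1L) return(eggs)
  w <- triangular_weights(span)
  mu <- config$fecundity_total_mean * w
  p_pos <- min(1, config$oviposition_days_mean / span)
  lay <- stats::rbinom(span, 1L, p_pos) *
    stats::rpois(span, mu / p_pos)
  eggs[(apop + 1L):adult_lifespan] <- lay
  eggs
}

#' Sample a daily predation schedule along a stage sequence
#'
#' Daily prey counts are Poisson around the scenario's per-stage daily
#' mean; egg and pupa days never feed and always return zero.
#'
#' @param config a \code{\link{scenario}}.
#' @param stage_sequence character vector, the stage occupied on each alive
#'   day.
#' @return Integer vector of prey consumed per day.
#' @export
sample_predation_schedule <- function(config, stage_sequence) {
  stopifnot(inherits(config, "scenario"),
            all(stage_sequence %in% stage_order()))
  out <- integer(length(stage_sequence))
  feeding <- !(stage_sequence %in% nonfeeding_stages())
  if (any(feeding)) {
    mu <- config$predation_daily_mean[stage_sequence[feeding]]
    out[feeding] <- stats::rpois(sum(feeding), mu)
  }
  out
}

#' Generate a synthetic cohort from a scenario
#'
#' For each of the \code{n_01} individuals: per-stage gamma development
#' times; a single completion Bernoulli at each stage entry (an individual
#' failing it lives a uniform 1..duration days in that stage, then dies);
#' sex drawn at emergence; a gamma adult lifespan by sex; a fecundity
#' schedule for females and a Poisson predation schedule over all feeding
#' days. The terminal record of every individual is its death day
#' (\code{alive = 0}, zero counts). Reproducible given the scenario's
#' \code{rng_seed}.
#'
#' @param config a \code{\link{scenario}}.
#' @param n_01 optional override of the scenario's cohort size.
#' @param seed optional override of the scenario's \code{rng_seed}.
#' @return A validated \code{\link{cohort}}.
#' @export
generate_cohort <- function(config, n_01 = NULL, seed = NULL) {
  stopifnot(inherits(config, "scenario"))
  n <- if (is.null(n_01)) config$n_01 else as.integer(n_01)
  set.seed(if (is.null(seed)) config$rng_seed else as.integer(seed),
           kind = "Mersenne-Twister")
  pre <- preadult_stages()

  id_l <- vector("list", n); age_l <- id_l; st_l <- id_l
  alive_l <- id_l; eggs_l <- id_l; prey_l <- id_l

  for (i in seq_len(n)) {
    dur <- sample_stage_durations(config)
    # stage-entry survival; first failure -> death within that stage
    surv <- stats::rbinom(6L, 1L, config$survival) == 1L
    fatal <- which(!surv)[1L]
    if (!is.na(fatal)) {
      days_in <- if (fatal > 1L) dur[seq_len(fatal - 1L)] else integer()
      u <- sample.int(dur[fatal], 1L)
      stage_seq <- rep(pre[seq_len(fatal)], c(days_in, u))
      death_stage <- pre[fatal]
      eggs <- integer(length(stage_seq))
    } else {
      sex <- if (stats::runif(1L) < config$sex_ratio_female) "female"
             else "male"
      L <- discretized_gamma(1L, config$adult_longevity_mean[sex],
                             config$adult_longevity_sd[sex])
      stage_seq <- rep(c(pre, sex), c(dur, L))
      death_stage <- sex
      eggs <- integer(length(stage_seq))
      if (sex == "female") {
        eggs[(sum(dur) + 1L):length(stage_seq)] <-
          sample_fecundity_schedule(config, L)
      }
    }
    prey <- sample_predation_schedule(config, stage_seq)
    k <- length(stage_seq)
    id_l[[i]] <- rep.int(sprintf("i%04d", i), k + 1L)
    age_l[[i]] <- 0:k
    st_l[[i]] <- c(stage_seq, death_stage)
    alive_l[[i]] <- c(rep.int(1L, k), 0L)
    eggs_l[[i]] <- c(eggs, 0L)
    prey_l[[i]] <- c(prey, 0L)
  }

  cohort(data.frame(individual_id = unlist(id_l),
                    age = unlist(age_l),
                    stage = unlist(st_l),
                    alive = unlist(alive_l),
                    eggs_laid = unlist(eggs_l),
                    prey_consumed = unlist(prey_l),
                    stringsAsFactors = FALSE),
         label = config$label)
}

#' Expected daily fecundity profile of the generator
#'
#' Closed-form expectation of the fecundity model in
#' \code{\link{sample_fecundity_schedule}} for a fixed adult lifespan:
#' a geometric mixture over pre-oviposition periods of triangular daily-mean
#' profiles (zero inflation does not change the expectation). Used to
#' derive the analytic growth rate of deterministic-schedule scenarios.
#'
#' @param config a \code{\link{scenario}}.
#' @param adult_lifespan fixed adult lifespan in days.
#' @return Numeric vector of expected eggs laid on each adult day.
#' @export
expected_fecundity_profile <- function(config, adult_lifespan) {
  stopifnot(inherits(config, "scenario"), adult_lifespan >= 1)
  p <- 1 / (1 + config$apop_mean)
  profile <- numeric(adult_lifespan)
  for (apop in 0:(adult_lifespan - 1L)) {
    span <- adult_lifespan - apop
    mu <- config$fecundity_total_mean * triangular_weights(span)
    idx <- (apop + 1L):adult_lifespan
    profile[idx] <- profile[idx] + stats::dgeom(apop, p) * mu
  }
  profile
}
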