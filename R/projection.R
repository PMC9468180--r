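#' Build a daily projection schedule from a cohort
#'
#' Estimates, for every occupied (age, stage) cell, the empirical
#' frequencies of the observed one-day moves: stay in stage, develop to
#' the next stage, or die (the remaining mass). Together with the
#' fecundity grid \code{f_xj} (eggs per female-cell occupant per day) and
#' predation grid \code{c_xj} this drives the deterministic projection.
#'
#' @param x a \code{\link{cohort}} or fitted \code{\link{lifetable}}.
#' @return Object of class \code{"projection_schedule"}: \code{trans}
#'   (age x stage x stage array of transition probabilities),
#'   \code{f_xj}, \code{c_xj}, \code{max_age}.
#' @export
build_schedule <- function(x) {
  lt <- if (inherits(x, "lifetable")) x else lifetable(x)
  ch <- lt$cohort
  d <- ch$data
  alive <- d$alive == 1L
  counts <- lt$counts
  nage <- nrow(counts)
  # consecutive rows of the same individual describe the (x)->(x+1) move;
  # next-day stage counts only if the next-day row is alive
  id <- d$individual_id
  same <- id[-1L] == id[-length(id)]
  from_ok <- alive[-length(alive)] & same
  to_alive <- alive[-1L]
  fx <- d$age[-length(alive)][from_ok]
  fs <- d$stage[-length(alive)][from_ok]
  ts <- d$stage[-1L][from_ok]
  surv <- to_alive[from_ok]
  trans <- array(0, dim = c(nage, 8L, 8L),
                 dimnames = list(rownames(counts), stage_order(),
                                 stage_order()))
  if (any(surv)) {
    tab <- table(factor(fx[surv], levels = rownames(counts)),
                 stage_factor(fs[surv]), stage_factor(ts[surv]))
    denom <- counts
    denom[denom == 0L] <- 1L
    trans[] <- as.numeric(tab) / rep(as.numeric(denom), times = 8L)
  }
  c_xj <- compute_cxj(ch)
  structure(list(trans = trans, f_xj = lt$f_xj, c_xj = c_xj,
                 max_age = nage - 1L, label = lt$label,
                 lifetable = lt),
            class = "projection_schedule")
}

#' Deterministic population and predation projection
#'
#' Day-by-day expected-value projection from an initial age-stage vector:
#' each cell's mass survives and develops according to the schedule's
#' empirical transition frequencies, newborn eggs enter at (age 0, egg)
#' the next day at \code{sum_{x,j} f_xj n_xj(t)}, and predation potential
#' accumulates as \code{P(t) = sum_{x,j} c_xj n_xj(t)}. Masses are
#' real-valued; growth is unsuppressed (no density dependence or prey
#' depletion).
#'
#' @param schedule a \code{\link{build_schedule}} result.
#' @param initial age-by-stage matrix of starting counts (ages up to the
#'   schedule's \code{max_age}), e.g. from \code{\link{initial_pairs}}.
#' @param horizon days to project (>= 1).
#' @return Object of class \code{"projection"}: \code{N_t} and \code{P_t}
#'   (length \code{horizon + 1}, day 0 first), \code{stage_totals}
#'   ((horizon+1) x stage matrix) and the final age-stage state.
#' @export
project_population <- function(schedule, initial, horizon = 90L) {
  stopifnot(inherits(schedule, "projection_schedule"), horizon >= 1)
  nage <- schedule$max_age + 1L
  if (is.null(dim(initial))) {
    stop("initial must be an age x stage matrix", call. = FALSE)
  }
  if (nrow(initial) > nage) {
    stop("initial vector references ages beyond max_age", call. = FALSE)
  }
  state <- matrix(0, nage, 8L,
                  dimnames = list(0:(nage - 1L), stage_order()))
  state[seq_len(nrow(initial)), ] <- initial
  tr <- schedule$trans
  f <- schedule$f_xj
  cc <- schedule$c_xj
  N_t <- numeric(horizon + 1L)
  P_t <- numeric(horizon + 1L)
  stage_totals <- matrix(0, horizon + 1L, 8L,
                         dimnames = list(0:horizon, stage_order()))
  for (t in 0:horizon) {
    N_t[t + 1L] <- sum(state)
    P_t[t + 1L] <- sum(cc * state)
    stage_totals[t + 1L, ] <- colSums(state)
    if (t == horizon) break
    births <- sum(f * state)
    nxt <- matrix(0, nage, 8L)
    for (y in 1:8) {
      # mass arriving in stage y at age x+1 from every stage j at age x
      nxt[-1L, y] <- rowSums(state[-nage, , drop = FALSE] *
                               tr[-nage, , y])
    }
    nxt[1L, 1L] <- births
    state <- nxt
  }
  structure(list(N_t = N_t, P_t = P_t, stage_totals = stage_totals,
                 final_state = state, horizon = horizon,
                 label = schedule$label),
            class = "projection")
}

#' Initial age-stage vector for a projection
#'
#' Builds the starting matrix for \code{\link{project_population}}. The
#' conventional "n pairs" start places \code{pairs} females and
#' \code{pairs} males at their sex's first observed adult age
#' (\code{at = "first_adult"}); \code{at = "egg"} instead starts from
#' \code{2 * pairs} newly laid eggs at age 0.
#'
#' @param x a \code{\link{cohort}} or \code{\link{lifetable}}.
#' @param pairs number of adult pairs (default 10).
#' @param at \code{"first_adult"} or \code{"egg"}.
#' @return Age-by-stage matrix of starting counts.
#' @export
initial_pairs <- function(x, pairs = 10, at = c("first_adult", "egg")) {
  at <- match.arg(at)
  lt <- if (inherits(x, "lifetable")) x else lifetable(x)
  init <- matrix(0, nrow(lt$counts), 8L, dimnames = dimnames(lt$counts))
  if (at == "egg") {
    init["0", "egg"] <- 2 * pairs
    return(init)
  }
  stats <- individual_stats(lt$cohort)
  for (sx in c("female", "male")) {
    em <- stats$emergence_age[stats$sex == sx]
    if (length(em) == 0L) {
      stop("no ", sx, " adults observed; cannot place pairs", call. = FALSE)
    }
    init[as.character(min(em)), sx] <- pairs
  }
  init
}

#' Projection with bootstrap percentile confidence bands
#'
#' The point projection plus projections built from the two
#' \code{\link{percentile_cohorts}} whose bootstrap \code{lambda} values
#' attain the 2.5th and 97.5th percentiles.
#'
#' @param x a \code{\link{cohort}}.
#' @param initial starting matrix, or \code{NULL} for
#'   \code{\link{initial_pairs}} with 10 pairs.
#' @param horizon days to project.
#' @param B bootstrap replicates (>= 40).
#' @param seed integer seed.
#' @return List of three \code{"projection"} objects: \code{point},
#'   \code{lower}, \code{upper}, plus the percentile \code{lambda}s.
#' @export
project_with_bands <- function(x, initial = NULL, horizon = 90L,
                               B = 2000L, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  pc <- percentile_cohorts(x, B = B, seed = seed)
  sched <- build_schedule(x)
  auto <- is.null(initial)
  if (auto) initial <- initial_pairs(x)
  run <- function(ch) {
    s <- build_schedule(ch)
    # the pairs start must refer to this resample's own adult ages --
    # a shared matrix could place mass in cells the resample never visits
    if (auto) return(project_population(s, initial_pairs(ch), horizon))
    init <- matrix(0, s$max_age + 1L, 8L,
                   dimnames = list(0:s$max_age, stage_order()))
    k <- min(nrow(initial), nrow(init))
    init[seq_len(k), ] <- initial[seq_len(k), ]
    project_population(s, init, horizon)
  }
  list(point = project_population(sched, initial, horizon),
       lower = run(pc$lower),
       upper = run(pc$upper),
       lambda = pc$lambda)
}

#' @export
print.projection <- function(x, ...) {
  cat("Population/predation projection",
      if (!is.null(x$label)) paste0("(", x$label, ")"),
      "\n  horizon:", x$horizon, "d",
      "\n  N(0) =", format(x$N_t[1], digits = 4),
      " N(horizon) =", format(x$N_t[length(x$N_t)], digits = 4),
      "\n  P(horizon) =", format(x$P_t[length(x$P_t)], digits = 4), "\n")
  invisible(x)
}

#' Plot a projection on the log10 scale
#'
#' Total population size N(t) and predation potential P(t), log base 10.
#'
#' @param x a \code{"projection"}.
#' @param ... passed to \code{plot}.
#' @export
plot.projection <- function(x, ...) {
  t <- 0:x$horizon
  graphics::plot(t, log10(pmax(x$N_t, 1e-12)), type = "l",
                 xlab = "day", ylab = "log10 count",
                 main = paste("Projection", x$label), ...)
  graphics::lines(t, log10(pmax(x$P_t, 1e-12)), lty = 2)
  graphics::legend("topleft", legend = c("N(t)", "P(t)"), lty = 1:2)
  invisible(x)
}
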