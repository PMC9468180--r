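#' Age-stage survival rate grid s_xj
#'
#' \code{s_xj = n_xj / n_01}: the probability that a newborn is alive and
#' in stage \code{j} at age \code{x}.
#'
#' @param counts age-stage count grid from \code{\link{agestage_counts}}.
#' @param n_01 initial cohort size (defaults to the grid's attribute).
#' @return Numeric matrix of the same shape as \code{counts}.
#' @export
compute_sxj <- function(counts, n_01 = attr(counts, "n_01")) {
  if (is.null(n_01) || n_01 < 1) {
    stop("n_01 must be a positive count", call. = FALSE)
  }
  m <- counts / n_01
  attr(m, "n_01") <- NULL
  m
}

#' Age-specific survival rate l_x
#'
#' \code{l_x = sum_j s_xj}, the probability of being alive at age \code{x}
#' irrespective of stage.
#'
#' @param s_xj survival-rate grid from \code{\link{compute_sxj}}.
#' @return Numeric vector indexed by age.
#' @export
compute_lx <- function(s_xj) rowSums(s_xj)

#' Age-specific fecundity m_x
#'
#' \code{m_x = sum_j s_xj f_xj / sum_j s_xj}: mean eggs per individual
#' alive at age \code{x}, with the two-sex denominator (males and
#' undetermined-sex survivors dilute it). Defined as 0 at ages where no
#' individual survives, so the net maternity \code{l_x m_x} is always well
#' formed.
#'
#' @param s_xj survival-rate grid.
#' @param f_xj grid of mean eggs laid per (age, stage) occupant; nonzero
#'   only in the female column.
#' @return Numeric vector indexed by age.
#' @export
compute_mx <- function(s_xj, f_xj) {
  stopifnot(all(dim(s_xj) == dim(f_xj)))
  l <- rowSums(s_xj)
  m <- rowSums(s_xj * f_xj)
  out <- numeric(length(l))
  pos <- l > 0
  out[pos] <- m[pos] / l[pos]
  names(out) <- rownames(s_xj)
  out
}

#' Net reproductive rate R0
#'
#' \code{R0 = sum_x l_x m_x}: lifetime offspring per newborn, preadult
#' mortality included.
#'
#' @param l_x,m_x conformable age vectors.
#' @return Scalar R0.
#' @export
compute_R0 <- function(l_x, m_x) {
  stopifnot(length(l_x) == length(m_x))
  sum(l_x * m_x)
}

#' Solve the Euler--Lotka equation for the intrinsic rate of increase
#'
#' Finds r with \code{sum_x exp(-r (x+1)) l_x m_x = 1} (age indexed from
#' 0) by bracketing bisection on the strictly decreasing left-hand side.
#' The initial bracket [-1, 5] is expanded geometrically if needed.
#'
#' @param l_x,m_x age vectors (ages \code{0..length-1}).
#' @param tol residual tolerance (default 1e-12).
#' @return r, the per-day intrinsic rate of increase.
#' @export
solve_r <- function(l_x, m_x, tol = 1e-12) {
  lxmx <- l_x * m_x
  if (sum(lxmx) <= 0) {
    stop("intrinsic rate undefined: no reproduction (R0 = 0)",
         call. = FALSE)
  }
  xp1 <- seq_along(lxmx)  # x + 1 for x = 0,1,...
  g <- function(r) sum(exp(-r * xp1) * lxmx) - 1
  lo <- -1; hi <- 5
  while (g(lo) < 0) lo <- lo * 2
  while (g(hi) > 0) hi <- hi * 2
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(gm) < tol || (hi - lo) < .Machine$double.eps * max(1, abs(mid))) {
      return(mid)
    }
    if (gm > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Finite rate of increase
#'
#' \code{lambda = exp(r)}, the per-day multiplicative growth factor.
#'
#' @param r intrinsic rate of increase (per day).
#' @return lambda.
#' @export
compute_lambda <- function(r) exp(r)

#' Mean generation time
#'
#' \code{T = ln(R0) / r}: the time a population at stable growth needs to
#' increase R0-fold.
#'
#' @param R0 net reproductive rate (> 0).
#' @param r intrinsic rate of increase.
#' @return T in days; \code{NA} if \code{r = 0}.
#' @export
compute_T <- function(R0, r) {
  if (R0 <= 0) stop("T undefined for R0 <= 0", call. = FALSE)
  if (r == 0) return(NA_real_)
  log(R0) / r
}

# f_xj grid: mean eggs laid per occupant of each (age, stage) cell
compute_fxj <- function(x, counts) {
  d <- x$data[x$data$alive == 1L, ]
  f <- matrix(0, nrow(counts), 8L, dimnames = dimnames(counts))
  keep <- d$eggs_laid > 0L
  if (any(keep)) {
    tot <- rowsum(as.numeric(d$eggs_laid[keep]),
                  interaction(d$age[keep], d$stage[keep], drop = TRUE))
    parts <- strsplit(rownames(tot), ".", fixed = TRUE)
    ix <- cbind(match(vapply(parts, `[`, "", 1L), rownames(counts)),
                match(vapply(parts, `[`, "", 2L), colnames(counts)))
    f[ix] <- tot[, 1L] / counts[ix]
  }
  f
}

#' Age-stage life expectancy grid e_xj
#'
#' \code{e_xj} is the expected remaining lifespan (in days, counting the
#' current day) of an individual alive in stage \code{j} at age \code{x},
#' estimated from the forward survival schedule of the sub-cohort that
#' reached that cell with its current survival set to 1. Empirically this
#' is the mean of (alive days from \code{x} to death) over individuals
#' observed alive in \code{(x, j)}. Cells never reached are \code{NA}.
#'
#' @param x a \code{\link{cohort}}.
#' @return Numeric age-by-stage matrix.
#' @export
compute_exj <- function(x) {
  stopifnot(inherits(x, "cohort"))
  counts <- agestage_counts(x)
  stats <- individual_stats(x)
  d <- x$data[x$data$alive == 1L, ]
  idf <- factor(d$individual_id, levels = stats$id)
  remaining <- stats$lifespan[as.integer(idf)] - d$age
  cell_mean(remaining, d$age, d$stage, counts)
}

# mean of `value` within each (age, stage) cell; NA where the cell is empty
cell_mean <- function(value, age, stage, counts) {
  out <- matrix(NA_real_, nrow(counts), 8L, dimnames = dimnames(counts))
  tot <- rowsum(as.numeric(value), interaction(age, stage, drop = TRUE))
  parts <- strsplit(rownames(tot), ".", fixed = TRUE)
  ix <- cbind(match(vapply(parts, `[`, "", 1L), rownames(counts)),
              match(vapply(parts, `[`, "", 2L), colnames(counts)))
  out[ix] <- tot[, 1L] / counts[ix]
  # occupied cells that produced no rowsum group (all-zero values) keep NA
  # only if truly unoccupied:
  occupied <- counts > 0 & is.na(out)
  out[occupied] <- 0
  out
}

#' Age-stage reproductive value grid v_xj
#'
#' \code{v_xj} is the expected contribution of an individual alive in
#' \code{(x, j)} to the future population: its expected future reproduction
#' discounted at the intrinsic rate,
#' \code{v_xj = exp(r (x+1)) * E[ sum_{i >= x} exp(-r (i+1)) eggs_i ]},
#' the expectation taken over the sub-cohort observed alive in the cell.
#' For a newborn this reduces to the finite rate of increase:
#' \code{v_01 = lambda}. Cells never reached are \code{NA}.
#'
#' @param x a \code{\link{cohort}}.
#' @param r intrinsic rate of increase (from \code{\link{solve_r}}).
#' @return Numeric age-by-stage matrix.
#' @export
compute_vxj <- function(x, r) {
  stopifnot(inherits(x, "cohort"), is.finite(r))
  counts <- agestage_counts(x)
  d <- x$data[x$data$alive == 1L, ]
  # rows are sorted by individual then age: reverse-cumulative discounted
  # future eggs within each individual
  disc <- exp(-r * (d$age + 1)) * d$eggs_laid
  idf <- factor(d$individual_id, levels = unique(d$individual_id))
  future <- unlist(lapply(split(disc, idf),
                          function(v) rev(cumsum(rev(v)))),
                   use.names = FALSE)
  v <- cell_mean(future, d$age, d$stage, counts)
  v * exp(r * (as.numeric(rownames(counts)) + 1))
}

#' Reproduction summaries F, Od, APOP, TPOP
#'
#' \code{F}: mean lifetime fecundity over all females; \code{Od}: mean
#' number of days with at least one egg, over all females; \code{APOP}:
#' mean adult pre-oviposition period (first-egg age minus emergence age)
#' over ovipositing females; \code{TPOP}: mean first-egg age over
#' ovipositing females. APOP and TPOP are \code{NA} when no female
#' oviposits.
#'
#' @param x a \code{\link{cohort}}.
#' @return Named list with F, Od, APOP, TPOP, n_female, n_ovipositing.
#' @export
reproduction_summaries <- function(x) {
  s <- individual_stats(x)
  fem <- s$sex == "female"
  ovi <- fem & s$eggs_total > 0L
  list(F = if (any(fem)) mean(s$eggs_total[fem]) else NA_real_,
       Od = if (any(fem)) mean(s$ovi_days[fem]) else NA_real_,
       APOP = if (any(ovi)) {
         mean(s$first_egg_age[ovi] - s$emergence_age[ovi])
       } else NA_real_,
       TPOP = if (any(ovi)) mean(s$first_egg_age[ovi]) else NA_real_,
       n_female = sum(fem), n_ovipositing = sum(ovi))
}

#' Stage duration and longevity summaries
#'
#' Mean days spent in each preadult stage over the individuals that
#' completed it; adult longevity and total longevity by sex; and the
#' preadult survival rate (fraction of the cohort reaching adulthood).
#'
#' @param x a \code{\link{cohort}}.
#' @return Named list: \code{duration_mean} (per preadult stage, with the
#'   number of completers as \code{duration_n}), \code{preadult_mean}
#'   (total preadult days of adults), \code{adult_longevity} and
#'   \code{total_longevity} (female, male), \code{preadult_survival}.
#' @export
stage_summaries <- function(x) {
  s <- individual_stats(x)
  pre <- preadult_stages()
  dur <- vapply(pre, function(j) {
    ok <- s$completed[, j]
    if (any(ok)) mean(s$stage_days[ok, j]) else NA_real_
  }, 0)
  dn <- vapply(pre, function(j) sum(s$completed[, j]), 0L)
  fem <- s$sex == "female"; mal <- s$sex == "male"
  adult_days <- s$stage_days[, "female"] + s$stage_days[, "male"]
  pre_days <- rowSums(s$stage_days[, pre, drop = FALSE])
  list(duration_mean = dur, duration_n = dn,
       preadult_mean = if (any(s$reached_adult)) {
         mean(pre_days[s$reached_adult])
       } else NA_real_,
       adult_longevity = c(
         female = if (any(fem)) mean(adult_days[fem]) else NA_real_,
         male = if (any(mal)) mean(adult_days[mal]) else NA_real_),
       total_longevity = c(
         female = if (any(fem)) mean(s$lifespan[fem]) else NA_real_,
         male = if (any(mal)) mean(s$lifespan[mal]) else NA_real_),
       preadult_survival = mean(s$reached_adult))
}

#' Fit the age-stage, two-sex life table of a cohort
#'
#' The central model fit: from daily individual records it computes the
#' age-stage survival grid \code{s_xj}, the age-specific survival
#' \code{l_x} and fecundity \code{m_x}, the net maternity \code{l_x m_x},
#' the population parameters (net reproductive rate \code{R0}, intrinsic
#' rate of increase \code{r} from the Euler--Lotka equation, finite rate
#' \code{lambda = exp(r)}, mean generation time \code{T = ln(R0)/r}), the
#' age-stage life expectancy \code{e_xj} and reproductive value
#' \code{v_xj} grids, and the reproduction and stage-duration summaries.
#'
#' When the cohort produced no eggs, \code{R0 = 0} and \code{r},
#' \code{lambda}, \code{T} and \code{v_xj} are \code{NA}.
#'
#' @param x a \code{\link{cohort}} (or a data.frame conforming to the
#'   cohort schema).
#' @param label optional label override.
#' @return An object of class \code{"lifetable"} with components
#'   \code{counts}, \code{s_xj}, \code{f_xj}, \code{l_x}, \code{m_x},
#'   \code{e_xj}, \code{v_xj}, \code{params} (named numeric vector),
#'   \code{stage_summary}, \code{n_01}, \code{label} and the fitted
#'   \code{cohort}.
#' @seealso \code{\link{predation_rates}}, \code{\link{bootstrap_lifetable}},
#'   \code{\link{project_population}}
#' @examples
#' sc <- default_scenarios(seed = 7)[["25C"]]
#' ch <- generate_cohort(sc)
#' fit <- lifetable(ch)
#' coef(fit)
#' @export
lifetable <- function(x, label = NULL) {
  if (!inherits(x, "cohort")) x <- cohort(x, label = label)
  counts <- agestage_counts(x)
  s_xj <- compute_sxj(counts, x$n_01)
  l_x <- compute_lx(s_xj)
  f_xj <- compute_fxj(x, counts)
  m_x <- compute_mx(s_xj, f_xj)
  R0 <- compute_R0(l_x, m_x)
  if (R0 > 0) {
    r <- solve_r(l_x, m_x)
    lam <- compute_lambda(r)
    Tg <- compute_T(R0, r)
    v_xj <- compute_vxj(x, r)
  } else {
    r <- lam <- Tg <- NA_real_
    v_xj <- matrix(NA_real_, nrow(counts), 8L, dimnames = dimnames(counts))
  }
  e_xj <- compute_exj(x)
  rep_sum <- reproduction_summaries(x)
  st_sum <- stage_summaries(x)
  params <- c(R0 = R0, r = r, lambda = lam, T = Tg,
              F = rep_sum$F, Od = rep_sum$Od,
              APOP = rep_sum$APOP, TPOP = rep_sum$TPOP,
              preadult_survival = st_sum$preadult_survival)
  structure(list(counts = counts, s_xj = s_xj, f_xj = f_xj,
                 l_x = l_x, m_x = m_x, e_xj = e_xj, v_xj = v_xj,
                 params = params,
                 reproduction = rep_sum, stage_summary = st_sum,
                 n_01 = x$n_01,
                 label = if (is.null(label)) x$label else label,
                 cohort = x),
            class = "lifetable")
}

#' @export
coef.lifetable <- function(object, ...) object$params

#' @export
print.lifetable <- function(x, digits = 4, ...) {
  cat("Age-stage two-sex life table",
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  n_01 =", x$n_01, " max age =", nrow(x$counts) - 1L, "d\n")
  p <- x$params
  cat(sprintf("  R0 = %.2f offspring/individual, r = %.4f /d, lambda = %.4f /d, T = %.2f d\n",
              p["R0"], p["r"], p["lambda"], p["T"]))
  cat(sprintf("  F = %.2f eggs/female, Od = %.2f d, APOP = %.2f d, TPOP = %.2f d, s_a = %.2f\n",
              p["F"], p["Od"], p["APOP"], p["TPOP"],
              p["preadult_survival"]))
  invisible(x)
}

#' @export
summary.lifetable <- function(object, ...) {
  st <- object$stage_summary
  structure(list(label = object$label, n_01 = object$n_01,
                 params = object$params,
                 duration_mean = st$duration_mean,
                 duration_n = st$duration_n,
                 preadult_mean = st$preadult_mean,
                 adult_longevity = st$adult_longevity,
                 total_longevity = st$total_longevity,
                 n_female = object$reproduction$n_female),
            class = "summary.lifetable")
}

#' @export
print.summary.lifetable <- function(x, ...) {
  cat("Age-stage two-sex life table",
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n\n")
  cat("Population parameters:\n")
  print(round(x$params, 4))
  cat("\nStage durations (days, completers only):\n")
  print(round(rbind(mean = x$duration_mean, n = x$duration_n), 2))
  cat(sprintf("\nTotal preadult: %.2f d; adult longevity F/M: %.2f/%.2f d; females: %d\n",
              x$preadult_mean, x$adult_longevity["female"],
              x$adult_longevity["male"], x$n_female))
  invisible(x)
}

#' Plot survival and fecundity schedules of a fitted life table
#'
#' Two panels: age-stage survival curves \code{s_xj} with the pooled
#' \code{l_x}, and the fecundity schedule (\code{m_x} and net maternity
#' \code{l_x m_x}).
#'
#' @param x a \code{\link{lifetable}}.
#' @param ... passed to \code{matplot}.
#' @export
plot.lifetable <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ages <- as.numeric(rownames(x$s_xj))
  graphics::matplot(ages, x$s_xj, type = "l", lty = 1,
                    xlab = "age (d)", ylab = "s_xj",
                    main = paste("Age-stage survival", x$label), ...)
  graphics::lines(ages, x$l_x, lwd = 2)
  graphics::legend("topright", legend = c(colnames(x$s_xj), "l_x"),
                   col = c(seq_len(8), "black"),
                   lty = 1, lwd = c(rep(1, 8), 2), cex = 0.6)
  graphics::plot(ages, x$m_x, type = "l", xlab = "age (d)",
                 ylab = "eggs/day", main = "Fecundity")
  graphics::lines(ages, x$l_x * x$m_x, lty = 2)
  graphics::legend("topright", legend = c("m_x", "l_x m_x"), lty = 1:2,
                   cex = 0.7)
  invisible(x)
}
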