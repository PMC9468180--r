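#' Age-stage predation rate grid c_xj
#'
#' \code{c_xj}: mean prey consumed per day by the individuals alive in
#' stage \code{j} at age \code{x}; 0 where the cell is unoccupied. Egg and
#' pupa cells are structurally 0 (non-feeding stages), producing the two
#' characteristic gaps in the predation curves.
#'
#' @param x a \code{\link{cohort}}.
#' @return Numeric age-by-stage matrix.
#' @export
compute_cxj <- function(x) {
  stopifnot(inherits(x, "cohort"))
  counts <- agestage_counts(x)
  d <- x$data[x$data$alive == 1L, ]
  cxj <- cell_mean(d$prey_consumed, d$age, d$stage, counts)
  cxj[is.na(cxj)] <- 0
  cxj
}

#' Age-specific predation rate k_x
#'
#' \code{k_x = sum_j s_xj c_xj / sum_j s_xj}: mean prey consumed per
#' surviving individual at age \code{x}; 0 at ages with no survivors.
#'
#' @param s_xj survival-rate grid.
#' @param c_xj predation-rate grid from \code{\link{compute_cxj}}.
#' @return Numeric vector indexed by age.
#' @export
compute_kx <- function(s_xj, c_xj) {
  stopifnot(all(dim(s_xj) == dim(c_xj)))
  l <- rowSums(s_xj)
  num <- rowSums(s_xj * c_xj)
  out <- numeric(length(l))
  pos <- l > 0
  out[pos] <- num[pos] / l[pos]
  names(out) <- rownames(s_xj)
  out
}

#' Age-specific net predation rate q_x
#'
#' \code{q_x = l_x k_x = sum_j s_xj c_xj}: predation weighted by
#' survivorship, so that its sum over ages is the net predation rate.
#'
#' @param l_x age-specific survival vector.
#' @param k_x age-specific predation vector.
#' @return Numeric vector indexed by age.
#' @export
compute_qx <- function(l_x, k_x) {
  stopifnot(length(l_x) == length(k_x))
  l_x * k_x
}

#' Net predation rate C0
#'
#' \code{C0 = sum_x q_x}: prey consumed by an average cohort member over
#' its lifetime, individuals dying as preadults included. Identically
#' equal to total prey consumed by the cohort divided by \code{n_01}.
#'
#' @param q_x net predation vector.
#' @return Scalar C0 (prey per individual).
#' @export
compute_C0 <- function(q_x) sum(q_x)

#' Transformation rate Qp
#'
#' \code{Qp = C0 / R0}: the number of prey a predator needs to consume to
#' produce one offspring.
#'
#' @param C0 net predation rate.
#' @param R0 net reproductive rate.
#' @return Scalar Qp; errors if \code{R0 = 0} while \code{C0 > 0}.
#' @export
compute_Qp <- function(C0, R0) {
  if (C0 == 0) return(0)
  if (R0 <= 0) {
    stop("transformation rate undefined: R0 = 0", call. = FALSE)
  }
  C0 / R0
}

#' Stable age-stage distribution a_xj
#'
#' The limiting proportion of individuals in each (age, stage) cell of a
#' population growing at rate \code{lambda}:
#' \code{a_xj = s_xj lambda^{-x} / sum_{x,j} s_xj lambda^{-x}},
#' truncated at the cohort's maximum observed age (beyond which
#' \code{s_xj = 0}) and normalised to sum to 1.
#'
#' @param s_xj survival-rate grid.
#' @param lambda finite rate of increase (> 0).
#' @return Numeric age-by-stage matrix summing to 1.
#' @export
compute_sasd <- function(s_xj, lambda) {
  stopifnot(lambda > 0)
  x <- as.numeric(rownames(s_xj))
  if (is.null(rownames(s_xj))) x <- seq_len(nrow(s_xj)) - 1
  w <- s_xj * lambda^(-x)
  w / sum(w)
}

#' Stable and finite predation rates
#'
#' \code{psi = sum_{x,j} a_xj c_xj}: prey consumed per individual per day
#' by a population at its stable age-stage distribution;
#' \code{omega = lambda * psi}: the finite predation rate, combining
#' population growth with stable predation.
#'
#' @param a_xj stable age-stage distribution from \code{\link{compute_sasd}}.
#' @param c_xj predation-rate grid.
#' @param lambda finite rate of increase.
#' @return Named list with \code{psi} and \code{omega}.
#' @export
compute_psi_omega <- function(a_xj, c_xj, lambda) {
  stopifnot(all(dim(a_xj) == dim(c_xj)))
  psi <- sum(a_xj * c_xj)
  list(psi = psi, omega = lambda * psi)
}

#' Stage daily predation D_j
#'
#' \code{D_j} = total prey consumed during stage \code{j} divided by total
#' individual-days spent in stage \code{j}, reported per instar plus the
#' preadult aggregate (egg and pupa days included in the denominator),
#' female, male, and the adult aggregate.
#'
#' @param x a \code{\link{cohort}}.
#' @return Named numeric vector (\code{L1..L4}, \code{preadult},
#'   \code{female}, \code{male}, \code{adult}); \code{NA} where the stage
#'   was never occupied.
#' @export
stage_daily_predation <- function(x) {
  s <- individual_stats(x)
  pre <- preadult_stages()
  agg <- function(prey, days) if (days > 0) prey / days else NA_real_
  out <- c(
    vapply(c("L1", "L2", "L3", "L4"), function(j) {
      agg(sum(s$stage_prey[, j]), sum(s$stage_days[, j]))
    }, 0),
    preadult = agg(sum(s$stage_prey[, pre]), sum(s$stage_days[, pre])),
    female = agg(sum(s$stage_prey[, "female"]),
                 sum(s$stage_days[, "female"])),
    male = agg(sum(s$stage_prey[, "male"]), sum(s$stage_days[, "male"])),
    adult = agg(sum(s$stage_prey[, c("female", "male")]),
                sum(s$stage_days[, c("female", "male")])))
  out
}

#' Predation-rate analysis of a cohort
#'
#' Computes the full predator-demography summary: the age-stage predation
#' grid \code{c_xj}, age-specific (\code{k_x}) and net (\code{q_x})
#' predation rates, net predation rate \code{C0}, transformation rate
#' \code{Qp = C0/R0}, the stable age-stage distribution \code{a_xj}, the
#' stable (\code{psi}) and finite (\code{omega = lambda psi}) predation
#' rates, and per-stage daily predation \code{D_j}.
#'
#' \code{psi}, \code{omega} and \code{a_xj} require a positive growth rate
#' and are \code{NA} when the life table has \code{R0 = 0}.
#'
#' @param x a \code{\link{cohort}} or a fitted \code{\link{lifetable}}.
#' @return An object of class \code{"predation_table"}: grids
#'   \code{c_xj}, \code{a_xj}, vectors \code{k_x}, \code{q_x}, \code{D_j},
#'   and \code{params} (named vector C0, Qp, psi, omega), plus the
#'   underlying \code{lifetable}.
#' @examples
#' sc <- default_scenarios(seed = 7)[["25C"]]
#' fit <- lifetable(generate_cohort(sc))
#' pred <- predation_rates(fit)
#' coef(pred)
#' @export
predation_rates <- function(x) {
  lt <- if (inherits(x, "lifetable")) x else lifetable(x)
  ch <- lt$cohort
  c_xj <- compute_cxj(ch)
  k_x <- compute_kx(lt$s_xj, c_xj)
  q_x <- compute_qx(lt$l_x, k_x)
  C0 <- compute_C0(q_x)
  R0 <- lt$params[["R0"]]
  Qp <- if (C0 == 0) 0 else if (R0 > 0) compute_Qp(C0, R0) else NA_real_
  lam <- lt$params[["lambda"]]
  if (is.finite(lam) && lam > 0) {
    a_xj <- compute_sasd(lt$s_xj, lam)
    po <- compute_psi_omega(a_xj, c_xj, lam)
    psi <- po$psi; omega <- po$omega
  } else {
    a_xj <- matrix(NA_real_, nrow(c_xj), 8L, dimnames = dimnames(c_xj))
    psi <- omega <- NA_real_
  }
  structure(list(c_xj = c_xj, k_x = k_x, q_x = q_x, a_xj = a_xj,
                 D_j = stage_daily_predation(ch),
                 params = c(C0 = C0, Qp = Qp, psi = psi, omega = omega),
                 lifetable = lt, label = lt$label),
            class = "predation_table")
}

#' @export
coef.predation_table <- function(object, ...) object$params

#' @export
print.predation_table <- function(x, ...) {
  cat("Predation-rate analysis",
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  p <- x$params
  cat(sprintf("  C0 = %.2f prey/individual, Qp = %.4f prey/offspring\n",
              p["C0"], p["Qp"]))
  cat(sprintf("  psi = %.4f, omega = %.4f prey/d\n", p["psi"], p["omega"]))
  cat("  Stage daily predation D_j:\n")
  print(round(x$D_j, 2))
  invisible(x)
}

#' Plot predation schedules
#'
#' Age-specific predation \code{k_x} and net predation \code{q_x} curves;
#' the gaps at all-egg and all-pupa ages are structural (non-feeding
#' stages).
#'
#' @param x a \code{\link{predation_rates}} result.
#' @param ... passed to \code{plot}.
#' @export
plot.predation_table <- function(x, ...) {
  ages <- as.numeric(rownames(x$c_xj))
  graphics::plot(ages, x$k_x, type = "l", xlab = "age (d)",
                 ylab = "prey/day",
                 main = paste("Predation rates", x$label), ...)
  graphics::lines(ages, x$q_x, lty = 2)
  graphics::legend("topright", legend = c("k_x", "q_x"), lty = 1:2)
  invisible(x)
}
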