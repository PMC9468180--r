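# content-derived offset so replicate streams are a deterministic function
# of (seed, cohort) and invariant to argument order in paired tests
cohort_checksum <- function(x) {
  d <- x$data
  v <- sum(d$age) + 7L * sum(d$eggs_laid %% 65536L) +
    13L * sum(d$prey_consumed %% 65536L) +
    31L * nrow(d) + 3L * sum(stage_rank(d$stage))
  as.integer(abs(v) %% 1048576L)
}

# precompute the per-individual structures every replicate reuses
boot_prep <- function(x, need_cells = TRUE) {
  s <- individual_stats(x)
  E <- eggs_by_age(x)
  prep <- list(stats = s, E = E, n = s$n, n_01 = x$n_01,
               nage = ncol(E))
  if (need_cells) {
    d <- x$data[x$data$alive == 1L, ]
    idf <- factor(d$individual_id, levels = s$id)
    ncell <- prep$nage * 8L
    cellcol <- d$age * 8L + as.integer(stage_factor(d$stage))
    A <- matrix(0, s$n, ncell)
    A[cbind(as.integer(idf), cellcol)] <- 1
    P <- matrix(0, s$n, ncell)
    P[cbind(as.integer(idf), cellcol)] <- d$prey_consumed
    prep$cell_alive <- A
    prep$cell_prey <- P
    prep$cell_age <- rep(0:(prep$nage - 1L), each = 8L)
  }
  prep
}

# Euler-Lotka solved row-wise by bracketing bisection (vectorised)
solve_r_rows <- function(LM, tol = 1e-10) {
  ok <- rowSums(LM) > 0
  r <- rep(NA_real_, nrow(LM))
  if (!any(ok)) return(r)
  M <- LM[ok, , drop = FALSE]
  xp1 <- seq_len(ncol(M))
  g <- function(rv) rowSums(M * exp(-outer(rv, xp1))) - 1
  lo <- rep(-1, nrow(M)); hi <- rep(5, nrow(M))
  for (k in 1:30) {
    bad <- g(lo) < 0
    if (!any(bad)) break
    lo[bad] <- lo[bad] * 2
  }
  for (k in 1:30) {
    bad <- g(hi) > 0
    if (!any(bad)) break
    hi[bad] <- hi[bad] * 2
  }
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    up <- g(mid) > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(hi - lo) < tol) break
  }
  r[ok] <- (lo + hi) / 2
  r
}

# parameters for one block of replicates; W is a B x n count matrix
boot_block <- function(W, prep, parameters) {
  s <- prep$stats
  n01 <- prep$n
  res <- list()
  tot <- function(v) as.vector(W %*% v)
  eggs <- tot(s$eggs_total)
  fem <- tot(as.numeric(s$sex == "female"))
  res$R0 <- eggs / n01
  if (any(c("F", "Od") %in% parameters)) {
    res$F <- ifelse(fem > 0, eggs / fem, NA_real_)
    res$Od <- ifelse(fem > 0,
                     tot(as.numeric(s$sex == "female") * s$ovi_days) / fem,
                     NA_real_)
  }
  if (any(c("APOP", "TPOP") %in% parameters)) {
    ovi <- as.numeric(s$sex == "female" & s$eggs_total > 0L)
    novi <- tot(ovi)
    apop_i <- ifelse(ovi > 0, s$first_egg_age - s$emergence_age, 0)
    tpop_i <- ifelse(ovi > 0, s$first_egg_age, 0)
    res$APOP <- ifelse(novi > 0, tot(ovi * apop_i) / novi, NA_real_)
    res$TPOP <- ifelse(novi > 0, tot(ovi * tpop_i) / novi, NA_real_)
  }
  if ("preadult_survival" %in% parameters) {
    res$preadult_survival <- tot(as.numeric(s$reached_adult)) / n01
  }
  need_r <- any(c("r", "lambda", "T", "psi", "omega") %in% parameters)
  if (need_r) {
    LM <- (W %*% prep$E) / n01
    r <- solve_r_rows(LM)
    res$r <- r
    res$lambda <- exp(r)
    res$T <- ifelse(is.finite(r) & r != 0 & res$R0 > 0,
                    log(res$R0) / r, NA_real_)
  }
  if (any(c("C0", "Qp", "psi", "omega") %in% parameters)) {
    res$C0 <- tot(s$prey_total) / n01
    res$Qp <- ifelse(res$C0 == 0, 0,
                     ifelse(res$R0 > 0, res$C0 / res$R0, NA_real_))
  }
  if (any(c("psi", "omega") %in% parameters)) {
    cnt <- W %*% prep$cell_alive
    prey <- W %*% prep$cell_prey
    lam <- res$lambda
    disc <- exp(outer(-log(lam), prep$cell_age))  # lambda^{-x} per cell
    wgt <- cnt * disc
    psi <- rowSums(prey * disc) / rowSums(wgt)
    psi[!is.finite(lam)] <- NA_real_
    res$psi <- psi
    res$omega <- lam * psi
  }
  pre <- preadult_stages()
  dur_pars <- paste0("dur_", pre)
  if (any(dur_pars %in% parameters)) {
    for (j in seq_along(pre)) {
      comp <- as.numeric(s$completed[, pre[j]])
      nc <- tot(comp)
      res[[dur_pars[j]]] <- ifelse(nc > 0,
                                   tot(comp * s$stage_days[, pre[j]]) / nc,
                                   NA_real_)
    }
  }
  dj_pars <- paste0("D_", c("L1", "L2", "L3", "L4", "preadult",
                            "female", "male", "adult"))
  if (any(dj_pars %in% parameters)) {
    grp <- list(L1 = "L1", L2 = "L2", L3 = "L3", L4 = "L4",
                preadult = pre, female = "female", male = "male",
                adult = c("female", "male"))
    for (g in names(grp)) {
      days <- tot(rowSums(s$stage_days[, grp[[g]], drop = FALSE]))
      prey <- tot(rowSums(s$stage_prey[, grp[[g]], drop = FALSE]))
      res[[paste0("D_", g)]] <- ifelse(days > 0, prey / days, NA_real_)
    }
  }
  do.call(cbind, res[intersect(c(names(res)), parameters)])
}

boot_parameter_set <- function() {
  c("R0", "r", "lambda", "T", "F", "Od", "APOP", "TPOP",
    "preadult_survival", "C0", "Qp", "psi", "omega",
    paste0("dur_", preadult_stages()),
    paste0("D_", c("L1", "L2", "L3", "L4", "preadult",
                   "female", "male", "adult")))
}

#' Bootstrap a cohort's demography and predation parameters
#'
#' Resamples \code{n_01} individuals with replacement (the individual,
#' with its entire daily life history, is the resampling unit, preserving
#' within-individual correlation) and recomputes every requested parameter
#' per replicate. Replicates with no eggs contribute \code{R0 = 0} but are
#' undefined (and counted) for \code{r}, \code{lambda}, \code{T},
#' \code{Qp}, \code{psi} and \code{omega}.
#'
#' The published convention is 100,000 replicates; \code{B} is fully
#' configurable and examples use far fewer.
#'
#' @param x a \code{\link{cohort}}.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed; replicate streams are derived from it plus a
#'   content checksum of the cohort, so they are reproducible and
#'   independent of argument order in paired tests.
#' @param parameters character vector of parameter names (default: all of
#'   R0, r, lambda, T, F, Od, APOP, TPOP, preadult_survival, C0, Qp, psi,
#'   omega, per-stage durations \code{dur_*} and daily predation
#'   \code{D_*}).
#' @param keep_indices keep the B x n matrix of resampled indices (needed
#'   by \code{\link{percentile_cohorts}}).
#' @param block replicates per computation block (memory/speed trade-off).
#' @return Object of class \code{"lifetable_boot"}: \code{replicates}
#'   (B x parameters matrix), point \code{estimates}, bootstrap \code{se},
#'   \code{n_undefined} (replicates without reproduction), \code{B},
#'   \code{seed}.
#' @export
bootstrap_lifetable <- function(x, B = 100000L, seed = 1L,
                                parameters = boot_parameter_set(),
                                keep_indices = FALSE, block = 5000L) {
  stopifnot(inherits(x, "cohort"), B >= 2)
  parameters <- match.arg(parameters, boot_parameter_set(),
                          several.ok = TRUE)
  parameters <- union(parameters, "R0")  # defines the undefined-replicate count
  need_cells <- any(c("psi", "omega") %in% parameters)
  prep <- boot_prep(x, need_cells = need_cells)
  n <- prep$n
  set.seed(as.integer(seed) + cohort_checksum(x),
           kind = "Mersenne-Twister")
  blocks <- split(seq_len(B), ceiling(seq_len(B) / block))
  reps <- vector("list", length(blocks))
  idx_all <- if (keep_indices) matrix(0L, B, n) else NULL
  for (bi in seq_along(blocks)) {
    nb <- length(blocks[[bi]])
    idx <- matrix(sample.int(n, nb * n, replace = TRUE), nb, n)
    if (keep_indices) idx_all[blocks[[bi]], ] <- idx
    W <- t(vapply(seq_len(nb),
                  function(b) tabulate(idx[b, ], nbins = n),
                  integer(n)))
    reps[[bi]] <- boot_block(W, prep, parameters)
  }
  reps <- do.call(rbind, reps)
  lt <- lifetable(x)
  pt <- c(coef(lt),
          if (need_cells || any(grepl("^(C0|Qp|D_)", parameters))) {
            coef(predation_rates(lt))
          },
          stats::setNames(lt$stage_summary$duration_mean,
                          paste0("dur_", preadult_stages())))
  dj <- stage_daily_predation(x)
  pt <- c(pt, stats::setNames(dj, paste0("D_", names(dj))))
  structure(list(replicates = reps,
                 estimates = pt[colnames(reps)],
                 se = apply(reps, 2L, bootstrap_se),
                 n_undefined = sum(reps[, "R0"] == 0),
                 B = B, seed = as.integer(seed),
                 indices = idx_all, label = x$label),
            class = "lifetable_boot")
}

#' Bootstrap standard error
#'
#' The sample standard deviation of the defined (finite) replicate
#' estimates; \code{NA} when fewer than two replicates are defined.
#'
#' @param distribution numeric vector of replicate estimates.
#' @return Scalar SE.
#' @export
bootstrap_se <- function(distribution) {
  v <- distribution[is.finite(distribution)]
  if (length(v) < 2L) return(NA_real_)
  stats::sd(v)
}

#' @export
print.lifetable_boot <- function(x, ...) {
  cat("Bootstrap (B = ", x$B, ") ",
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n", sep = "")
  out <- cbind(estimate = x$estimates, SE = x$se)
  print(round(out, 4))
  if (x$n_undefined > 0) {
    cat("replicates without reproduction (excluded from r/lambda/T):",
        x$n_undefined, "\n")
  }
  invisible(x)
}

#' Paired bootstrap test between two cohorts
#'
#' Draws B independent replicate pairs (one from each cohort's stream),
#' forms the per-pair parameter difference, and takes its 2.5th and 97.5th
#' percentiles; the difference is significant at the 5% level iff the
#' interval excludes 0. Streams are seeded from \code{seed} plus each
#' cohort's content checksum, so swapping the arguments exactly negates
#' the difference.
#'
#' @param a,b two \code{\link{cohort}}s.
#' @param parameter single parameter name (see
#'   \code{\link{bootstrap_lifetable}}).
#' @param B replicates per cohort.
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return Object of class \code{"paired_boot_test"}: the point-estimate
#'   difference, percentile CI, significance flag, and the share of
#'   defined replicate pairs (the test is flagged inconclusive when more
#'   than half are undefined).
#' @export
paired_bootstrap_test <- function(a, b, parameter, B = 2000L, seed = 1L,
                                  conf = 0.95) {
  stopifnot(inherits(a, "cohort"), inherits(b, "cohort"),
            length(parameter) == 1L)
  ba <- bootstrap_lifetable(a, B = B, seed = seed, parameters = parameter)
  bb <- bootstrap_lifetable(b, B = B, seed = seed, parameters = parameter)
  diff <- ba$replicates[, parameter] - bb$replicates[, parameter]
  defined <- is.finite(diff)
  inconclusive <- mean(defined) < 0.5
  alpha <- 1 - conf
  ci <- unname(stats::quantile(diff[defined],
                               probs = c(alpha / 2, 1 - alpha / 2),
                               names = FALSE))
  est <- unname(ba$estimates[parameter] - bb$estimates[parameter])
  structure(list(parameter = parameter, estimate = est,
                 ci = ci, conf = conf,
                 significant = !inconclusive && (ci[1] > 0 || ci[2] < 0),
                 inconclusive = inconclusive,
                 prop_defined = mean(defined),
                 B = B, seed = as.integer(seed),
                 labels = c(a$label, b$label)),
            class = "paired_boot_test")
}

#' @export
print.paired_boot_test <- function(x, ...) {
  cat(sprintf(
    "Paired bootstrap test, %s (%s vs %s):\n  diff = %.4f, %.0f%% CI [%.4f, %.4f] -> %s\n",
    x$parameter,
    if (is.null(x$labels[1])) "A" else x$labels[1],
    if (is.null(x$labels[2])) "B" else x$labels[2],
    x$estimate, 100 * x$conf, x$ci[1], x$ci[2],
    if (x$inconclusive) "inconclusive"
    else if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Percentile cohorts of the finite rate of increase
#'
#' Bootstraps \code{lambda}, sorts the defined replicate values, and
#' returns the resampled cohorts attaining the \code{ceiling(p * m)}-th
#' order statistics (m = defined replicates) for the requested
#' probabilities -- the inputs for projection confidence bands.
#'
#' @param x a \code{\link{cohort}}.
#' @param B replicates (>= 40).
#' @param seed integer seed.
#' @param probs two probabilities (default \code{c(0.025, 0.975)}).
#' @return List with the \code{lower} and \code{upper} resampled
#'   \code{\link{cohort}}s, their \code{lambda} values, the order-statistic
#'   \code{ranks} used, and the count of excluded undefined replicates.
#' @export
percentile_cohorts <- function(x, B = 100000L, seed = 1L,
                               probs = c(0.025, 0.975)) {
  stopifnot(inherits(x, "cohort"), length(probs) == 2L)
  if (B < 40) stop("B must be at least 40 for percentile cohorts",
                   call. = FALSE)
  bt <- bootstrap_lifetable(x, B = B, seed = seed, parameters = "lambda",
                            keep_indices = TRUE)
  lam <- bt$replicates[, "lambda"]
  def <- which(is.finite(lam))
  m <- length(def)
  if (m < 40) stop("fewer than 40 defined lambda replicates",
                   call. = FALSE)
  ord <- def[order(lam[def])]
  ranks <- as.integer(pmin(pmax(ceiling(probs * m), 1L), m))
  pick <- ord[ranks]
  list(lower = resample_cohort(x, bt$indices[pick[1L], ]),
       upper = resample_cohort(x, bt$indices[pick[2L], ]),
       lambda = c(lower = lam[pick[1L]], upper = lam[pick[2L]]),
       ranks = ranks, n_excluded = B - m)
}
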