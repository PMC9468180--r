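#' Format a "mean +/- SE letter" table cell
#'
#' @param mean point estimate.
#' @param se standard error (\code{NA} renders as an em-dash with a
#'   footnote marker).
#' @param letter significance letter(s) from \code{\link{compact_letters}}.
#' @param digits decimals (the reporting convention is 4 for rates, 2 for
#'   days and counts).
#' @return Character scalar such as \code{"79.84 ± 1.87 a"}.
#' @export
render_cell <- function(mean, se, letter = "", digits = 2) {
  m <- formatC(mean, format = "f", digits = digits)
  s <- if (is.na(se)) "— †"
       else formatC(se, format = "f", digits = digits)
  trimws(paste(m, "±", s, letter))
}

#' Compact letter display from a pairwise significance matrix
#'
#' Greedy insert-and-absorb: starting from one group holding every level,
#' each significantly different pair splits the groups containing both;
#' duplicate or nested groups are absorbed and letters are assigned in
#' level order.
#'
#' @param significant logical matrix, \code{significant[i, j]} TRUE when
#'   levels i and j differ.
#' @return Character vector of letters per level (e.g. \code{"a"},
#'   \code{"ab"}).
#' @export
compact_letters <- function(significant) {
  k <- nrow(significant)
  groups <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!isTRUE(significant[i, j])) next
      nxt <- list()
      for (g in groups) {
        if (i %in% g && j %in% g) {
          nxt <- c(nxt, list(setdiff(g, i)), list(setdiff(g, j)))
        } else {
          nxt <- c(nxt, list(g))
        }
      }
      # absorb groups contained in another
      keep <- rep(TRUE, length(nxt))
      for (a in seq_along(nxt)) {
        for (b in seq_along(nxt)) {
          if (a != b && keep[a] &&
              all(nxt[[a]] %in% nxt[[b]]) &&
              (length(nxt[[a]]) < length(nxt[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      groups <- nxt[keep]
    }
  }
  # order groups by their smallest member for stable letters
  groups <- groups[order(vapply(groups, min, 1L))]
  out <- character(k)
  for (gi in seq_along(groups)) {
    for (m in groups[[gi]]) {
      out[m] <- paste0(out[m], letters[gi])
    }
  }
  out
}

#' Render a parameter comparison table
#'
#' One row per parameter, one column per scenario, cells formatted as
#' \code{"mean +/- SE letter"}.
#'
#' @param estimates,ses,letters parameter x scenario matrices.
#' @param digits named vector of decimals per parameter (default 2; rates
#'   r and lambda use 4).
#' @param style \code{"text"} or \code{"csv"} (identical numbers, CSV has
#'   no padding).
#' @return Character matrix (text) or data.frame (csv).
#' @export
render_table <- function(estimates, ses, letters = NULL,
                         digits = NULL, style = c("text", "csv")) {
  style <- match.arg(style)
  if (is.null(letters)) {
    letters <- matrix("", nrow(estimates), ncol(estimates))
  }
  if (is.null(digits)) {
    digits <- ifelse(rownames(estimates) %in%
                       c("r", "lambda", "Qp", "psi", "omega"), 4, 2)
    names(digits) <- rownames(estimates)
  }
  out <- matrix("", nrow(estimates), ncol(estimates),
                dimnames = dimnames(estimates))
  for (i in seq_len(nrow(estimates))) {
    for (j in seq_len(ncol(estimates))) {
      out[i, j] <- render_cell(estimates[i, j], ses[i, j],
                               letters[i, j], digits[i])
    }
  }
  if (style == "csv") as.data.frame(out) else out
}

#' Run the full analysis pipeline over scenarios
#'
#' Generates (or accepts) one cohort per scenario and runs life table,
#' predation, bootstrap and projection, writing per-scenario parameter
#' CSVs and a cross-scenario comparison table whose significance letters
#' come from pairwise bootstrap tests of the replicate distributions. All
#' outputs carry a provenance metadata header (seed, B, package version,
#' input checksum). Any stage error aborts the run and removes partial
#' outputs.
#'
#' @param scenarios list of \code{\link{scenario}}s, or a list of
#'   \code{\link{cohort}}s.
#' @param outdir output directory (created if needed).
#' @param B bootstrap replicates.
#' @param seed integer seed for generation and resampling.
#' @param horizon projection horizon in days.
#' @param parameters parameters to bootstrap and compare.
#' @param project logical: run projections.
#' @return Invisible list with per-scenario fits, bootstraps, projections,
#'   the comparison matrices and the output file paths.
#' @export
run_pipeline <- function(scenarios = default_scenarios(),
                         outdir = tempfile("agestage_run_"),
                         B = 500L, seed = 1L, horizon = 90L,
                         parameters = c("R0", "r", "lambda", "T", "F",
                                        "Od", "APOP", "TPOP",
                                        "preadult_survival",
                                        "C0", "Qp", "psi", "omega"),
                         project = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage_do <- function(stage, expr) {
    tryCatch(expr, error = function(e) on_fail(stage, e))
  }
  cohorts <- stage_do("generate", {
    lapply(seq_along(scenarios), function(i) {
      sc <- scenarios[[i]]
      if (inherits(sc, "cohort")) sc
      else generate_cohort(sc, seed = seed + i - 1L)
    })
  })
  labels <- vapply(cohorts, function(ch) {
    if (is.null(ch$label)) "scenario" else ch$label
  }, "")
  names(cohorts) <- labels
  fits <- stage_do("lifetable", lapply(cohorts, lifetable))
  preds <- stage_do("predation", lapply(fits, predation_rates))
  boots <- stage_do("bootstrap", lapply(cohorts, bootstrap_lifetable,
                                        B = B, seed = seed,
                                        parameters = parameters))
  projections <- if (project) {
    stage_do("project", lapply(fits, function(f) {
      project_population(build_schedule(f), initial_pairs(f), horizon)
    }))
  } else NULL

  meta <- function(ch) {
    c(seed = as.character(seed), B = as.character(B),
      version = as.character(utils::packageVersion("agestage")),
      input_checksum = as.character(cohort_checksum(ch)))
  }
  write_with_meta <- function(df, path, ch) {
    con <- file(path, "wt", encoding = "UTF-8")
    on.exit(close(con))
    m <- meta(ch)
    writeLines(paste0("# ", names(m), "=", unname(m)), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
    path
  }
  paths <- stage_do("report", {
    per_scenario <- vapply(labels, function(lb) {
      est <- c(coef(fits[[lb]]), coef(preds[[lb]]))
      se <- boots[[lb]]$se[intersect(names(est),
                                     names(boots[[lb]]$se))]
      df <- data.frame(parameter = names(est),
                       estimate = unname(est),
                       SE = unname(se[names(est)]))
      write_with_meta(df, file.path(outdir,
                                    paste0("params_", lb, ".csv")),
                      cohorts[[lb]])
    }, "")
    # cross-scenario comparison with compact letters
    k <- length(labels)
    est <- vapply(labels, function(lb) {
      boots[[lb]]$estimates[parameters]
    }, numeric(length(parameters)))
    ses <- vapply(labels, function(lb) {
      boots[[lb]]$se[parameters]
    }, numeric(length(parameters)))
    rownames(est) <- rownames(ses) <- parameters
    letters_m <- matrix("", length(parameters), k,
                        dimnames = list(parameters, labels))
    for (p in parameters) {
      sig <- matrix(FALSE, k, k)
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          di <- boots[[i]]$replicates[, p] - boots[[j]]$replicates[, p]
          di <- di[is.finite(di)]
          if (length(di) < 2L) next
          ci <- stats::quantile(di, c(0.025, 0.975), names = FALSE)
          sig[i, j] <- sig[j, i] <- ci[1] > 0 || ci[2] < 0
        }
      }
      letters_m[p, ] <- compact_letters(sig)
    }
    cmp <- render_table(est, ses, letters_m, style = "csv")
    cmp <- cbind(parameter = parameters, cmp)
    cmp_path <- file.path(outdir, "comparison.csv")
    write_with_meta(cmp, cmp_path, cohorts[[1L]])
    c(per_scenario, comparison = cmp_path)
  })
  invisible(list(cohorts = cohorts, fits = fits, predation = preds,
                 bootstraps = boots, projections = projections,
                 paths = paths, outdir = outdir,
                 comparison = list()))
}
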