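#' Construct a cohort of daily individual life-history records
#'
#' A cohort holds one row per individual per day of a life-table trial that
#' followed every individual from oviposition (age 0) to death. Required
#' columns: \code{individual_id}, \code{age} (integer days from 0),
#' \code{stage} (one of \code{\link{stage_order}}), \code{alive} (0/1),
#' \code{eggs_laid} and \code{prey_consumed} (non-negative integer counts).
#'
#' Validation enforces the record invariants:
#' \itemize{
#'   \item ages are consecutive integers starting at 0 for every individual;
#'   \item the stage sequence never regresses and visits at most one adult
#'     stage (sex is fixed at emergence);
#'   \item exactly one terminal row per individual is flagged dead
#'     (\code{alive = 0}); records without a death day are rejected
#'     (censoring is not supported);
#'   \item \code{eggs_laid > 0} only on alive female days;
#'     \code{prey_consumed > 0} only on alive feeding (non-egg, non-pupa)
#'     days; the death-day row carries zero counts.
#' }
#'
#' The census convention is that an individual alive at the start of day
#' \code{x} contributes to age \code{x}; the death day itself is the first
#' day not counted, so \code{l_0 = 1} and stage durations equal counts of
#' days spent in the stage.
#'
#' @param data data.frame with the columns listed above.
#' @param label optional scenario label (e.g. a temperature such as
#'   \code{"25C"}), carried into outputs.
#' @return An object of class \code{"cohort"}: the validated, sorted data
#'   plus \code{label} and the initial count \code{n_01}.
#' @export
cohort <- function(data, label = NULL) {
  required <- c("individual_id", "age", "stage", "alive",
                "eggs_laid", "prey_consumed")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[required]
  data$individual_id <- as.character(data$individual_id)
  for (col in c("age", "alive", "eggs_laid", "prey_consumed")) {
    v <- data[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != floor(v))) {
      stop("cohort value error: column '", col,
           "' must be non-missing integers", call. = FALSE)
    }
    data[[col]] <- as.integer(v)
  }
  if (any(data$eggs_laid < 0L) || any(data$prey_consumed < 0L)) {
    stop("cohort value error: negative counts", call. = FALSE)
  }
  if (!all(data$alive %in% c(0L, 1L))) {
    stop("cohort value error: alive must be 0 or 1", call. = FALSE)
  }
  bad_stage <- setdiff(unique(data$stage), stage_order())
  if (length(bad_stage) > 0L) {
    stop("cohort schema error: unknown stage(s) ",
         paste(bad_stage, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) stop("cohort value error: no rows", call. = FALSE)

  ord <- order(data$individual_id, data$age)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  id <- data$individual_id
  new_ind <- c(TRUE, id[-1L] != id[-length(id)])
  last_ind <- c(new_ind[-1L], TRUE)

  if (any(data$age[new_ind] != 0L)) {
    bad <- id[new_ind][data$age[new_ind] != 0L][1L]
    stop("cohort validation error: individual ", bad,
         " does not start at age 0", call. = FALSE)
  }
  dage <- diff(data$age)
  bad_step <- !new_ind[-1L] & dage != 1L
  if (any(bad_step)) {
    k <- which(bad_step)[1L] + 1L
    stop("cohort validation error: individual ", id[k],
         " has non-consecutive ages near age ", data$age[k], call. = FALSE)
  }
  # exactly one death row per individual, and it is the terminal row
  if (any(data$alive[last_ind] != 0L)) {
    bad <- id[last_ind][data$alive[last_ind] != 0L][1L]
    stop("cohort validation error: individual ", bad,
         " has no terminal death day (censoring is not supported)",
         call. = FALSE)
  }
  if (any(data$alive[!last_ind] != 1L)) {
    k <- which(!last_ind & data$alive == 0L)[1L]
    stop("cohort validation error: individual ", id[k],
         " is flagged dead before its final day", call. = FALSE)
  }
  rk <- stage_rank(data$stage)
  regress <- !new_ind[-1L] & diff(rk) < 0
  if (any(regress)) {
    k <- which(regress)[1L] + 1L
    stop("cohort validation error: individual ", id[k], " regresses from ",
         data$stage[k - 1L], " to ", data$stage[k], " at age ",
         data$age[k], call. = FALSE)
  }
  idf <- factor(id, levels = unique(id))
  sex_mix <- tapply(data$stage, idf, function(s) {
    all(c("female", "male") %in% s)
  })
  if (any(sex_mix)) {
    stop("cohort validation error: individual ",
         names(sex_mix)[sex_mix][1L], " occupies both adult stages",
         call. = FALSE)
  }
  bad_eggs <- data$eggs_laid > 0L & (data$stage != "female" | data$alive == 0L)
  if (any(bad_eggs)) {
    k <- which(bad_eggs)[1L]
    stop("cohort validation error: individual ", id[k],
         " has eggs_laid > 0 outside an alive female day (age ",
         data$age[k], ")", call. = FALSE)
  }
  bad_prey <- data$prey_consumed > 0L &
    (data$stage %in% nonfeeding_stages() | data$alive == 0L)
  if (any(bad_prey)) {
    k <- which(bad_prey)[1L]
    stop("cohort validation error: individual ", id[k],
         " has prey_consumed > 0 on a non-feeding or death day (age ",
         data$age[k], ")", call. = FALSE)
  }

  structure(list(data = data,
                 label = label,
                 n_01 = length(unique(id))),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort", if (!is.null(x$label)) paste0("'", x$label, "'") else "",
      "\n  individuals (n_01):", x$n_01,
      "\n  individual-days:   ", sum(x$data$alive),
      "\n  max age:           ", max(x$data$age[x$data$alive == 1L]), "d\n")
  invisible(x)
}

#' Read a cohort from its CSV representation
#'
#' Reads the canonical cohort CSV (UTF-8, header required, one row per
#' individual-day). Lines starting with \code{#} are metadata of the form
#' \code{# key=value}; a \code{label} key becomes the cohort label unless
#' overridden. Row order in the file is irrelevant.
#'
#' @param path path to a CSV file conforming to the schema in
#'   \code{\link{cohort}}.
#' @param label optional scenario label overriding any \code{# label=} line.
#' @return A validated \code{\link{cohort}}.
#' @export
read_cohort <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  if (is.null(label) && length(meta_lines) > 0L) {
    kv <- sub("^#\\s*", "", meta_lines)
    hit <- grep("^label=", kv, value = TRUE)
    if (length(hit) > 0L) label <- sub("^label=", "", hit[1L])
  }
  data <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  cohort(data, label = label)
}

#' Write a cohort to CSV
#'
#' Writes the canonical column order with a \code{# key=value} metadata
#' header (label, n_01, plus any extra metadata supplied).
#'
#' @param x a \code{\link{cohort}}.
#' @param path output file path.
#' @param metadata optional named character vector of extra metadata lines.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(x, path, metadata = NULL) {
  stopifnot(inherits(x, "cohort"))
  meta <- c(if (!is.null(x$label)) c(label = x$label),
            n_01 = as.character(x$n_01), metadata)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  utils::write.csv(x$data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Age-stage count grid n_xj
#'
#' Counts, for every age \code{x} and stage \code{j}, the individuals alive
#' and in stage \code{j} at the start of day \code{x}. The grid extends to
#' the maximum observed (alive) age; division by \code{n_01} gives the
#' age-stage survival rate grid s_xj (see \code{\link{compute_sxj}}).
#'
#' @param x a \code{\link{cohort}}.
#' @return Integer matrix with one row per age (rownames \code{0..X_max})
#'   and one column per stage, with attribute \code{n_01}.
#' @export
agestage_counts <- function(x) {
  stopifnot(inherits(x, "cohort"))
  d <- x$data[x$data$alive == 1L, ]
  ages <- 0:max(d$age)
  tab <- table(factor(d$age, levels = ages), stage_factor(d$stage))
  m <- matrix(as.integer(tab), nrow = length(ages),
              dimnames = list(ages, stage_order()))
  attr(m, "n_01") <- x$n_01
  m
}

# Per-individual life-history summaries used by the life table, the
# predation statistics and the bootstrap. One row per individual.
individual_stats <- function(x) {
  stopifnot(inherits(x, "cohort"))
  d <- x$data
  alive <- d$alive == 1L
  idf <- factor(d$individual_id, levels = unique(d$individual_id))
  ids <- levels(idf)
  n <- length(ids)

  lifespan <- as.integer(rowsum(as.numeric(alive), idf, reorder = FALSE))
  is_f <- as.integer(rowsum(as.numeric(alive & d$stage == "female"), idf,
                            reorder = FALSE) > 0)
  is_m <- as.integer(rowsum(as.numeric(alive & d$stage == "male"), idf,
                            reorder = FALSE) > 0)
  sex <- ifelse(is_f == 1L, "female", ifelse(is_m == 1L, "male",
                                             "undetermined"))
  eggs_total <- as.integer(rowsum(as.numeric(d$eggs_laid), idf,
                                  reorder = FALSE))
  prey_total <- as.integer(rowsum(as.numeric(d$prey_consumed), idf,
                                  reorder = FALSE))
  ovi_days <- as.integer(rowsum(as.numeric(d$eggs_laid > 0L), idf,
                                reorder = FALSE))

  big <- max(d$age) + 1L
  adult_day <- alive & d$stage %in% adult_stages()
  emergence <- suppressWarnings(
    tapply(ifelse(adult_day, d$age, big), idf, min))
  emergence <- ifelse(emergence >= big, NA_integer_, as.integer(emergence))
  egg_day <- d$eggs_laid > 0L
  first_egg <- suppressWarnings(
    tapply(ifelse(egg_day, d$age, big), idf, min))
  first_egg <- ifelse(first_egg >= big, NA_integer_, as.integer(first_egg))

  # per-stage alive-day and prey totals (n x 8 matrices)
  sf <- stage_factor(d$stage)
  key <- (as.integer(idf) - 1L) * 8L + as.integer(sf)
  days_flat <- rowsum(as.numeric(alive), key)
  prey_flat <- rowsum(as.numeric(d$prey_consumed), key)
  stage_days <- matrix(0, n, 8L, dimnames = list(ids, stage_order()))
  stage_prey <- matrix(0, n, 8L, dimnames = list(ids, stage_order()))
  pos <- as.integer(rownames(days_flat))
  stage_days[cbind((pos - 1L) %/% 8L + 1L, (pos - 1L) %% 8L + 1L)] <-
    days_flat[, 1L]
  pos <- as.integer(rownames(prey_flat))
  stage_prey[cbind((pos - 1L) %/% 8L + 1L, (pos - 1L) %% 8L + 1L)] <-
    prey_flat[, 1L]

  # a preadult stage is "completed" if a later-ranked stage was reached alive
  max_rank <- tapply(ifelse(alive, stage_rank(d$stage), 0L), idf, max)
  completed <- outer(as.integer(max_rank), 1:6, ">")  # stages egg..pupa
  colnames(completed) <- preadult_stages()

  list(id = ids, n = n,
       lifespan = lifespan, sex = sex,
       reached_adult = as.integer(max_rank) >= 7L,
       emergence_age = emergence, first_egg_age = first_egg,
       eggs_total = eggs_total, prey_total = prey_total,
       ovi_days = ovi_days,
       stage_days = stage_days, stage_prey = stage_prey,
       completed = completed)
}

# n x (max age + 1) matrix of eggs laid per individual per age
eggs_by_age <- function(x) {
  d <- x$data
  idf <- factor(d$individual_id, levels = unique(d$individual_id))
  ages <- 0:max(d$age)
  E <- matrix(0, nlevels(idf), length(ages),
              dimnames = list(levels(idf), ages))
  keep <- d$eggs_laid > 0L
  if (any(keep)) {
    # one row per individual-day, so direct assignment is exact
    E[cbind(as.integer(idf)[keep], d$age[keep] + 1L)] <- d$eggs_laid[keep]
  }
  E
}

# build a new cohort by resampling individuals (with replacement) by index
resample_cohort <- function(x, idx, label = NULL) {
  stopifnot(inherits(x, "cohort"))
  d <- x$data
  idf <- factor(d$individual_id, levels = unique(d$individual_id))
  rows <- split(seq_len(nrow(d)), idf)
  picked <- unlist(rows[idx], use.names = FALSE)
  reps <- vapply(rows[idx], length, 1L)
  new <- d[picked, , drop = FALSE]
  new$individual_id <- paste0("b", rep(seq_along(idx), reps), "_",
                              new$individual_id)
  cohort(new, label = if (is.null(label)) x$label else label)
}
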