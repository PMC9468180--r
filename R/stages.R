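#' Stage vocabulary of the age-stage life table
#'
#' The life course is egg, four larval instars (L1--L4), pupa, then one of
#' the two terminal adult stages (female or male). Female and male are
#' alternative successors of the pupal stage; the number of stages beta = 8.
#'
#' @return Character vector of the eight stage labels in developmental order.
#' @export
stage_order <- function() {
  c("egg", "L1", "L2", "L3", "L4", "pupa", "female", "male")
}

# developmental rank; female and male share rank 7 (terminal alternatives)
stage_rank <- function(stage) {
  r <- c(egg = 1, L1 = 2, L2 = 3, L3 = 4, L4 = 5, pupa = 6,
         female = 7, male = 7)
  unname(r[stage])
}

preadult_stages <- function() stage_order()[1:6]
adult_stages <- function() c("female", "male")
# egg and pupa do not feed: predation is structurally zero there
nonfeeding_stages <- function() c("egg", "pupa")

stage_factor <- function(stage) factor(stage, levels = stage_order())
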