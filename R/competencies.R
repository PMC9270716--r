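#' The 11 core motivational-communication competencies
#'
#' Motivational communication (MC) is a behaviour-change communication style
#' for health care providers, defined by 11 core competencies: 8 desirable
#' ("positive") behaviours and 3 undesirable ("negative") behaviours that a
#' provider should avoid. Every response option in a case bank is tagged with
#' the subset of competencies it demonstrates.
#'
#' @return A tibble with one row per competency and columns
#'   \describe{
#'     \item{competency}{machine identifier (snake case), used in tags}
#'     \item{label}{human-readable name}
#'     \item{polarity}{`"positive"` or `"negative"`}
#'   }
#' @examples
#' mc_competencies()
#' @export
mc_competencies <- function() {
  tibble::tibble(
    competency = c(
      "reflective_listening",
      "expressing_empathy",
      "evocation",
      "responding_to_resistance",
      "goal_setting",
      "acceptance_tolerance_respect",
      "being_collaborative",
      "expressing_hostility",
      "negatively_judging",
      "being_argumentative",
      "providing_information_neutrally"
    ),
    label = c(
      "Reflective listening",
      "Expressing empathy",
      "Eliciting change-talk or evocation",
      "Responding to resistance",
      "Goal setting",
      "Demonstrating acceptance, tolerance, and respect",
      "Being collaborative",
      "(Not) expressing hostility or impatience",
      "(Not) negatively judging or blaming",
      "(Not) being argumentative or confrontational",
      "Providing information neutrally"
    ),
    polarity = c(
      "positive", "positive", "positive", "positive", "positive",
      "positive", "positive", "negative", "negative", "negative",
      "positive"
    )
  )
}

positive_competencies <- function() {
  comp <- mc_competencies()
  comp$competency[comp$polarity == "positive"]
}

negative_competencies <- function() {
  comp <- mc_competencies()
  comp$competency[comp$polarity == "negative"]
}

#' Canonical per-case competency-opportunity distribution
#'
#' The canonical 16-case bank is built from 4 base-case families (A–D), one
#' per behavioural target. Each family offers a fixed number of opportunities
#' to demonstrate each competency; this function returns that design
#' distribution, which [generate_fixture_bank()] reproduces exactly and
#' [opportunity_census()] recovers from any canonical bank. Totals per family
#' are 29/33/33/31 opportunities (grand total 126) spread over 6/6/7/6
#' exchanges.
#'
#' @return A tibble with columns `competency`, `family` (`"A"`–`"D"`) and
#'   `n` (opportunity count for that competency in that family).
#' @seealso [canonical_exchange_counts()], [generate_fixture_bank()]
#' @examples
#' canonical_opportunities() |> dplyr::count(family, wt = n)
#' @export
canonical_opportunities <- function() {
  counts <- matrix(
    c(
      3, 4, 5, 4, # reflective_listening
      2, 3, 3, 2, # expressing_empathy
      2, 2, 3, 2, # evocation
      2, 2, 0, 2, # responding_to_resistance
      2, 1, 2, 2, # goal_setting
      4, 2, 4, 3, # acceptance_tolerance_respect
      2, 2, 1, 3, # being_collaborative
      1, 4, 5, 1, # expressing_hostility
      5, 6, 4, 5, # negatively_judging
      6, 6, 6, 6, # being_argumentative
      0, 1, 0, 1  # providing_information_neutrally
    ),
    ncol = 4, byrow = TRUE
  )
  tibble::tibble(
    competency = rep(mc_competencies()$competency, each = 4),
    family = rep(c("A", "B", "C", "D"), times = 11),
    n = as.integer(t(counts))
  )
}

#' Exchanges per base-case family in the canonical bank
#'
#' @return A named integer vector: number of conversational exchanges in each
#'   family's cases (every variant of a family has the same exchange count).
#' @examples
#' sum(canonical_exchange_counts()) # 25 exchanges per assembled form
#' @export
canonical_exchange_counts <- function() {
  c(A = 6L, B = 6L, C = 7L, D = 6L)
}

#' Behavioural targets of the canonical base-case families
#' @noRd
canonical_behavior_targets <- function() {
  c(
    A = "physical inactivity",
    B = "smoking",
    C = "unhealthy diet",
    D = "medication nonadherence"
  )
}

#' MC-consistency points for a response rank
#'
#' Response options within an exchange are ranked 1 (most consistent with
#' motivational communication) to 5 (least consistent) and carry points on a
#' +2 to -2 scale: 2 = very MC-consistent, 1 = somewhat consistent,
#' 0 = neither, -1 = inconsistent, -2 = very inconsistent. The negative side
#' of the scale reflects that MC-inconsistent replies are actively
#' counterproductive, not merely neutral.
#'
#' @param rank integer vector of ranks in 1..5.
#' @return Integer vector of points in \{2, 1, 0, -1, -2\}.
#' @examples
#' points_for_rank(1:5)
#' @export
points_for_rank <- function(rank) {
  if (!is.numeric(rank) || anyNA(rank) || any(rank != as.integer(rank))) {
    stop("`rank` must be integers in 1..5", call. = FALSE)
  }
  rank <- as.integer(rank)
  if (any(rank < 1L | rank > 5L)) {
    stop("`rank` must be integers in 1..5", call. = FALSE)
  }
  c(2L, 1L, 0L, -1L, -2L)[rank]
}
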