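#' Generate the canonical synthetic fixture bank
#'
#' Builds a 16-case bank (4 variants of each family A–D) whose per-case,
#' per-competency opportunity counts reproduce the canonical design
#' distribution of [canonical_opportunities()] exactly: 29/33/33/31
#' opportunities per family over 6/6/7/6 exchanges, 126 in total. Because a
#' family's four variants are structurally identical by construction, every
#' assembled four-case form carries that full distribution.
#'
#' All dialog text is synthetic placeholder prose (the real clinical content
#' is not distributable); patient charts are synthetic demographics varied
#' across variants. Tag placement is deterministic given `seed`:
#' each exchange's rank-1 option carries all positive tags allotted to that
#' exchange, and negative tags are placed on rank-4/5 options, so rank
#' order and tag polarity agree by construction and a respondent always
#' choosing rank 1 earns the maximum global competency score of 100.
#'
#' @param seed integer seed controlling tag placement and chart synthesis.
#'   The same seed always yields a byte-identical bank (see [write_bank()]).
#' @param language language tag recorded on each case.
#' @return A validated `mccat_bank` with 16 cases.
#' @examples
#' bank <- generate_fixture_bank(seed = 1)
#' census_totals(opportunity_census(bank))$grand # 126 per variant set x 4
#' @export
generate_fixture_bank <- function(seed = 1L, language = "en") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  targets <- canonical_opportunities()
  n_ex <- canonical_exchange_counts()
  behaviors <- canonical_behavior_targets()
  comp <- mc_competencies()
  pos <- comp$competency[comp$polarity == "positive"]
  neg <- comp$competency[comp$polarity == "negative"]

  withr::with_seed(as.integer(seed), {
    fam_structures <- lapply(names(n_ex), function(fam) {
      k <- n_ex[[fam]]
      fam_targets <- targets[targets$family == fam & targets$n > 0, ]
      # tags[[e]][[rank]] : character vector of tags on that option
      tags <- replicate(k, replicate(5, character(0), simplify = FALSE),
                        simplify = FALSE)
      for (i in seq_len(nrow(fam_targets))) {
        cpt <- fam_targets$competency[i]
        cnt <- fam_targets$n[i]
        if (cnt > k) {
          stop("placement infeasible: competency ", cpt, " needs ", cnt,
               " exchanges but family ", fam, " has ", k, call. = FALSE)
        }
        exch <- sample.int(k, cnt)
        for (e in exch) {
          r <- if (cpt %in% pos) 1L else sample(4:5, 1)
          tags[[e]][[r]] <- c(tags[[e]][[r]], cpt)
        }
      }
      lapply(tags, function(ex) lapply(ex, function(tg) sort(tg)))
    })
    names(fam_structures) <- names(n_ex)

    charts <- synthetic_charts()

    cases <- list(); exchanges <- list(); options <- list()
    for (fam in names(n_ex)) {
      for (variant in 1:4) {
        case_id <- paste0(fam, variant)
        chart <- charts[[case_id]]
        cases[[case_id]] <- tibble::tibble(
          case_id = case_id, family = fam, variant = as.integer(variant),
          behavior_target = behaviors[[fam]], language = language,
          chart = list(chart)
        )
        k <- n_ex[[fam]]
        exchanges[[case_id]] <- tibble::tibble(
          case_id = case_id,
          exchange_index = seq_len(k),
          patient_statement = paste0(
            "Synthetic patient statement ", seq_len(k), " for case ",
            case_id, " (", behaviors[[fam]], ").")
        )
        struct <- fam_structures[[fam]]
        opt_rows <- tidyr::expand_grid(
          exchange_index = seq_len(k), rank = 1:5)
        opt_rows$case_id <- case_id
        opt_rows$option_id <- paste0(
          case_id, "-e", opt_rows$exchange_index, "-r", opt_rows$rank)
        opt_rows$text <- paste0(
          "Synthetic clinician reply (rank ", opt_rows$rank,
          ") for ", case_id, " exchange ", opt_rows$exchange_index, ".")
        opt_rows$mc_points <- points_for_rank(opt_rows$rank)
        opt_rows$tags <- purrr::map2(
          opt_rows$exchange_index, opt_rows$rank,
          function(e, r) struct[[e]][[r]])
        options[[case_id]] <- dplyr::select(
          opt_rows, "case_id", "exchange_index", "option_id",
          "text", "rank", "mc_points", "tags")
      }
    }

    mccat_bank(
      dplyr::bind_rows(cases),
      dplyr::bind_rows(exchanges),
      dplyr::bind_rows(options),
      name = "canonical synthetic fixture bank",
      version = "1",
      languages = language,
      check = "strict"
    )
  })
}

# deterministic-but-varied synthetic patient charts; draws come from the
# caller's seeded RNG stream
synthetic_charts <- function() {
  conditions <- list(
    A = c("obesity", "hypertension", "type 2 diabetes", "osteoarthritis"),
    B = c("COPD", "asthma", "coronary artery disease", "chronic bronchitis"),
    C = c("type 2 diabetes", "dyslipidemia", "obesity", "hypertension"),
    D = c("hypertension", "heart failure", "type 2 diabetes", "asthma")
  )
  statuses <- c(
    A = "sedentary, less than 30 minutes of activity per week",
    B = "smokes about a pack a day, has tried quitting twice",
    C = "diet high in processed food, irregular meals",
    D = "takes prescribed medication fewer than half of days"
  )
  meds <- c(
    A = "metformin; atorvastatin",
    B = "salbutamol inhaler; tiotropium",
    C = "metformin; ramipril",
    D = "ramipril; bisoprolol; furosemide"
  )
  out <- list()
  for (fam in c("A", "B", "C", "D")) {
    for (variant in 1:4) {
      case_id <- paste0(fam, variant)
      out[[case_id]] <- list(
        age = sample(35:75, 1),
        sex = sample(c("female", "male"), 1),
        picture_ref = NULL,
        condition = conditions[[fam]][variant],
        behavior_status = statuses[[fam]],
        medications = meds[[fam]]
      )
    }
  }
  out
}
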