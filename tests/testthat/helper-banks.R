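# Builders for small experimental banks and logs used across tests.
# Toy banks deliberately use fewer exchanges than a deployable case would
# carry, so they are constructed with check = "none" (per-exchange structure
# is still kept valid).

# one exchange: 5 options ranked 1..5; `tags` is a list mapping rank -> tags
toy_exchange <- function(case_id, exchange_index, tags = list()) {
  rank <- 1:5
  tibble::tibble(
    case_id = case_id,
    exchange_index = exchange_index,
    option_id = paste0(case_id, "-e", exchange_index, "-r", rank),
    text = paste0("reply r", rank),
    rank = rank,
    mc_points = points_for_rank(rank),
    tags = lapply(rank, function(r) {
      tg <- tags[[as.character(r)]]
      if (is.null(tg)) character(0) else tg
    })
  )
}

# a single-case bank; exchange_tags is a list (one element per exchange) of
# rank -> tags maps
toy_bank <- function(exchange_tags, case_id = "A1") {
  k <- length(exchange_tags)
  cases <- tibble::tibble(
    case_id = case_id, family = substr(case_id, 1, 1), variant = 1L,
    behavior_target = "smoking", language = "en",
    chart = list(list(age = 50, sex = "female", condition = "test",
                      behavior_status = "test", medications = "none")))
  exchanges <- tibble::tibble(
    case_id = case_id, exchange_index = seq_len(k),
    patient_statement = paste0("statement ", seq_len(k)))
  options <- dplyr::bind_rows(lapply(seq_len(k), function(e) {
    toy_exchange(case_id, e, exchange_tags[[e]])
  }))
  mccat_bank(cases, exchanges, options, name = "toy", check = "none")
}

# random toy bank with n_ex exchanges: every positive competency tags the
# rank 1-3 option of a random subset of exchanges, negatives rank 3-5, at
# most one option per competency per exchange
random_toy_bank <- function(n_ex, seed) {
  comp <- mc_competencies()
  withr::with_seed(seed, {
    exchange_tags <- lapply(seq_len(n_ex), function(e) list())
    for (i in seq_len(nrow(comp))) {
      cpt <- comp$competency[i]
      ranks_ok <- if (comp$polarity[i] == "positive") 1:3 else 3:5
      in_ex <- which(stats::runif(n_ex) < 0.5)
      for (e in in_ex) {
        r <- as.character(sample(ranks_ok, 1))
        exchange_tags[[e]][[r]] <- c(exchange_tags[[e]][[r]], cpt)
      }
    }
    toy_bank(exchange_tags)
  })
}

# the 2-exchange bank used for the worked global-score example:
# empathy offered in both exchanges, listening in one, judging in one
worked_example_bank <- function() {
  toy_bank(list(
    list("1" = c("expressing_empathy"),
         "2" = c("reflective_listening")),
    list("1" = c("expressing_empathy"),
         "4" = c("negatively_judging"))
  ))
}

# a log selecting, for each exchange of the given cases, the option with
# the stated rank (scalar or vector recycled over exchanges, in case then
# exchange order)
log_with_ranks <- function(bank, case_ids, ranks,
                           respondent_id = "r1", form_id = "f1") {
  opts <- bank$options[bank$options$case_id %in% case_ids, ]
  opts <- opts[order(opts$case_id, opts$exchange_index), ]
  ex <- dplyr::distinct(opts, case_id, exchange_index)
  ex$rank <- rep_len(ranks, nrow(ex))
  sel <- dplyr::inner_join(ex, opts,
                           by = c("case_id", "exchange_index", "rank"))
  tibble::tibble(
    respondent_id = respondent_id, form_id = form_id,
    case_id = sel$case_id, exchange_index = sel$exchange_index,
    option_id = sel$option_id, occasion = 1L)
}

# cached canonical fixture bank shared across test files
fixture_bank_cached <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- generate_fixture_bank(seed = 1)
    bank
  }
})
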