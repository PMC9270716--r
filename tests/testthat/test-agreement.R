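test_that("rank-agreement classification matches the published rule", {
  expect_identical(classify_rank_agreement(5, 4), "acceptable")
  expect_identical(classify_rank_agreement(1, 3), "poor")
  expect_identical(classify_rank_agreement(2, 2), "good")
  expect_error(classify_rank_agreement(0, 3), "1..5")
  expect_error(classify_rank_agreement(2, 6), "1..5")
})

test_that("classification is sign-symmetric and partitions all rank pairs", {
  pairs <- expand.grid(expert = 1:5, reference = 1:5)
  cls <- classify_rank_agreement(pairs$expert, pairs$reference)
  expect_true(all(cls %in% c("good", "acceptable", "poor")))
  expect_identical(sum(cls == "good"), 5L)
  expect_identical(sum(cls == "acceptable"), 8L)
  expect_identical(sum(cls == "poor"), 12L)
  flipped <- classify_rank_agreement(pairs$reference, pairs$expert)
  expect_identical(cls, flipped)
})

# a panel where each expert's assigned rank deviates from the reference by
# a fixed offset (clamped into 1..5 exactly when stated)
panel_with_deviations <- function(bank, case_id, deviations) {
  opts <- bank$options[bank$options$case_id == case_id, ]
  dplyr::bind_rows(lapply(seq_along(deviations), function(i) {
    tibble::tibble(
      expert_id = paste0("e", i),
      case_id = opts$case_id,
      exchange_index = opts$exchange_index,
      option_id = opts$option_id,
      assigned_rank = pmin(pmax(opts$rank + deviations[i], 1L), 5L),
      identified_tags = opts$tags)
  }))
}

test_that("a fully agreeing panel reports 100% good everywhere", {
  bank <- fixture_bank_cached()
  ratings <- panel_with_deviations(bank, "A1", rep(0, 10))
  rep <- aggregate_agreement(ratings, bank)
  expect_true(all(rep$per_exchange$good == 100))
  expect_true(all(rep$per_option$good == 100))
  ov <- glance(rep)
  expect_equal(ov$good_mean, 100)
  expect_equal(ov$good_sd, 0)
})

test_that("per-option percentages count deviations directly", {
  bank <- fixture_bank_cached()
  # 4 experts rating one option (reference rank 2) with deviations
  # 0, +1, -1, +3 -> good 25%, acceptable 50%, poor 25%
  opt <- bank$options[bank$options$case_id == "A1" &
                        bank$options$exchange_index == 1 &
                        bank$options$rank == 2, ]
  ratings <- tibble::tibble(
    expert_id = paste0("e", 1:4),
    case_id = opt$case_id,
    exchange_index = opt$exchange_index,
    option_id = opt$option_id,
    assigned_rank = opt$rank + c(0L, 1L, -1L, 3L),
    identified_tags = rep(opt$tags, 4))
  rep <- aggregate_agreement(ratings, bank)
  row <- rep$per_option
  expect_equal(c(row$good, row$acceptable, row$poor), c(25, 50, 25))
})

test_that("good + acceptable + poor is exactly 100 per row", {
  bank <- fixture_bank_cached()
  withr::with_seed(4, {
    ratings <- panel_with_deviations(bank, "B1",
                                     sample(-2:2, 7, replace = TRUE))
  })
  rep <- aggregate_agreement(ratings, bank)
  expect_equal(rep$per_exchange$good + rep$per_exchange$acceptable +
                 rep$per_exchange$poor,
               rep(100, nrow(rep$per_exchange)))
})

test_that("dangling expert ratings are rejected", {
  bank <- fixture_bank_cached()
  ratings <- panel_with_deviations(bank, "A1", 0)
  ratings$option_id[1] <- "nope"
  expect_error(aggregate_agreement(ratings, bank), "not present")
})

test_that("re-summarizing the per-exchange rows reproduces the summary", {
  bank <- fixture_bank_cached()
  withr::with_seed(9, {
    ratings <- dplyr::bind_rows(
      lapply(c("A1", "B1", "C1", "D1"), function(id) {
        panel_with_deviations(bank, id, sample(-1:1, 8, replace = TRUE))
      }))
  })
  rep <- aggregate_agreement(ratings, bank)
  rows <- dplyr::mutate(rep$per_exchange, case = substr(case_id, 1, 1))
  expect_equal(summarize_agreement_table(rows), rep$summary)
})

test_that("summary arithmetic reproduces the bundled development-round table", {
  rows <- expert_agreement_rows()
  initial <- summarize_agreement_table(
    dplyr::transmute(rows, case,
                     good = good_initial,
                     acceptable = acceptable_initial,
                     poor = poor_initial))
  expect_identical(initial$n_rows, c(6L, 6L, 7L, 6L, 25L))
  caseA <- initial[initial$case == "A", ]
  expect_equal(caseA$good_mean, 54.8, tolerance = 0.002)
  expect_equal(caseA$good_sd, 11.6, tolerance = 0.005)
  overall <- initial[initial$case == "Overall", ]
  expect_equal(overall$good_mean, 61.2, tolerance = 0.002)
  expect_equal(overall$good_sd, 13.8, tolerance = 0.005)

  # identical rows give SD 0
  same <- summarize_agreement_table(
    tibble::tibble(case = "A", good = rep(60, 6),
                   acceptable = rep(30, 6), poor = rep(10, 6)))
  expect_equal(same$good_sd, c(0, 0))
})

test_that("competency identification agreement is recall of reference tags", {
  bank <- worked_example_bank()
  ref <- bank$options[bank$options$option_id == "A1-e1-r1", ]

  make_rating <- function(expert, tags) {
    tibble::tibble(expert_id = expert, case_id = ref$case_id,
                   exchange_index = ref$exchange_index,
                   option_id = ref$option_id,
                   assigned_rank = ref$rank,
                   identified_tags = list(tags))
  }
  # exact identification -> 100
  exact <- competency_identification_agreement(
    make_rating("e1", ref$tags[[1]]), bank)
  expect_equal(exact$overall$agreement, 100)
  # no tags -> 0
  none <- competency_identification_agreement(make_rating("e1", character(0)),
                                              bank)
  expect_equal(none$overall$agreement, 0)
  # half of a two-tag reference -> 50, false positives counted separately
  two_tag_bank <- toy_bank(list(
    list("1" = c("expressing_empathy", "reflective_listening"))))
  r <- competency_identification_agreement(
    tibble::tibble(expert_id = "e1", case_id = "A1", exchange_index = 1L,
                   option_id = "A1-e1-r1", assigned_rank = 1L,
                   identified_tags = list(c("expressing_empathy",
                                            "goal_setting"))),
    two_tag_bank)
  expect_equal(r$overall$agreement, 50)
  expect_equal(r$per_option$false_positives, 1)
})

test_that("modification decisions follow the published criteria table", {
  d <- modification_decision(72, 20, 8, 80)
  expect_identical(d$rank_decision, "NO_MODIFICATION")
  expect_identical(d$competency_decision, "KEEP_OR_ADD")

  d <- modification_decision(50, 41, 9, 55)
  expect_identical(d$rank_decision, "NO_MODIFICATION") # 91% good+acceptable
  expect_identical(d$competency_decision, "TEAM_DISCRETION")

  d <- modification_decision(60, 20, 20, 25)
  expect_identical(d$rank_decision, "MODIFY")
  expect_identical(d$competency_decision, "DELETE")
  expect_match(d$post_modification_requirement, "70% perfect agreement")

  # the 31-39% identification gap is treated as DELETE but flagged
  d <- modification_decision(80, 15, 5, 35)
  expect_identical(d$competency_decision, "DELETE")
  expect_true(d$gap_region)
  expect_false(modification_decision(80, 15, 5, 30)$gap_region)

  expect_error(modification_decision(120, 0, 0, 50), "0, 100")
})
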