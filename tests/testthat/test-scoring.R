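test_that("rank-to-points mapping follows the +2..-2 consistency scale", {
  expect_identical(points_for_rank(1:5), c(2L, 1L, 0L, -1L, -2L))
  expect_error(points_for_rank(0), "1..5")
  expect_error(points_for_rank(6), "1..5")
  expect_error(points_for_rank(2.5), "1..5")
  expect_error(points_for_rank(NA), "1..5")
})

test_that("ranking score matches the brute-force point sum on a full form", {
  bank <- fixture_bank_cached()
  form <- assemble_form(bank, seed = 3)

  all1 <- log_with_ranks(bank, form$cases$case_id, ranks = 1)
  # independent oracle: sum the points by hand over the 25 selections
  expect_equal(score_ranking(all1, bank, form), (25 * 2) / 50 * 100)
  expect_equal(score_ranking(all1, bank, form), 100)

  all3 <- log_with_ranks(bank, form$cases$case_id, ranks = 3)
  expect_equal(score_ranking(all3, bank, form), 0)

  counts <- c(10, 5, 5, 3, 2)
  ranks <- rep(1:5, times = counts)
  mixed <- log_with_ranks(bank, form$cases$case_id, ranks = ranks)
  oracle <- sum(counts * c(2, 1, 0, -1, -2)) / (2 * 25) * 100
  expect_equal(score_ranking(mixed, bank, form), oracle)
  expect_equal(score_ranking(mixed, bank, form), 36)
})

test_that("the worked two-exchange example scores 8.33", {
  bank <- worked_example_bank()
  # exchange 1: the empathy-tagged rank-1 reply; exchange 2: the
  # judging-tagged rank-4 reply
  log <- log_with_ranks(bank, "A1", ranks = c(1, 4))
  scores <- score_competencies(log, bank)
  # empathy 1 of 2 occasions, weight 100*2/3; listening 0; judging block
  # 1/1 times the negative share 100*1/4
  expect_equal(scores$global_competency, (1 / 2) * (100 * 2 / 3) - 25)
  expect_equal(round(scores$global_competency, 2), 8.33)
  tab <- tidy(scores)
  expect_equal(tab$contribution[tab$competency == "expressing_empathy"],
               (1 / 2) * (100 * 2 / 3))
  expect_equal(scores$negative_block, 25)
})

test_that("a perfect respondent scores exactly 100; untagged-only scores 0", {
  bank <- fixture_bank_cached()
  form <- assemble_form(bank, seed = 17)
  perfect <- perfect_log(bank, form)
  scores <- score_competencies(perfect, bank, form)
  expect_equal(scores$global_competency, 100)
  pos <- scores$per_competency[scores$per_competency$polarity == "positive", ]
  expect_true(all(pos$S[pos$assessed] == pos$O[pos$assessed]))

  # rank-2/3 options are untagged in the canonical bank
  neutral <- log_with_ranks(bank, form$cases$case_id, ranks = c(2, 3))
  expect_equal(score_competencies(neutral, bank, form)$global_competency, 0)
})

test_that("competencies never offered are flagged and weights renormalize", {
  # rank-1 options carry every positive tag of their exchange, so the best
  # possible respondent exists; most competencies are never offered
  bank <- toy_bank(list(
    list("1" = c("expressing_empathy", "reflective_listening")),
    list("1" = c("expressing_empathy"),
         "5" = c("negatively_judging"))))
  log <- log_with_ranks(bank, "A1", ranks = c(1, 1))
  scores <- score_competencies(log, bank)
  tab <- tidy(scores)
  offered <- c("expressing_empathy", "reflective_listening")
  expect_true(all(tab$assessed[tab$competency %in% offered]))
  not_offered <- tab$polarity == "positive" & !tab$competency %in% offered
  expect_true(all(!tab$assessed[not_offered]))
  expect_true(all(tab$contribution[not_offered] == 0))
  # perfect selection still reaches the 100 ceiling
  expect_equal(scores$global_competency, 100)
})

test_that("score reports satisfy internal conservation and bounds", {
  bank <- fixture_bank_cached()
  form <- assemble_form(bank, seed = 23)
  rng <- theoretical_range(bank, form = form)
  withr::with_seed(99, {
    for (i in 1:25) {
      log <- log_with_ranks(bank, form$cases$case_id,
                            ranks = sample(1:5, 25, replace = TRUE))
      scores <- score_competencies(log, bank, form)
      tab <- tidy(scores)
      pos <- tab[tab$polarity == "positive", ]
      expect_equal(sum(pos$contribution) - scores$negative_block,
                   scores$global_competency, tolerance = 1e-12)
      expect_true(all(tab$S <= tab$O))
      expect_identical(sum(scores$rank_histogram), 25L)
      expect_lte(scores$global_competency, 100)
      expect_gte(scores$global_competency, rng$min - 1e-9)
      expect_gte(scores$ranking, -100)
      expect_lte(scores$ranking, 100)
    }
  })
})

test_that("incomplete or inconsistent logs are rejected", {
  bank <- fixture_bank_cached()
  form <- assemble_form(bank, seed = 29)
  log <- perfect_log(bank, form)
  expect_error(score_ranking(log[-1, ], bank, form), "incomplete")
  dup <- rbind(log, log[1, ])
  expect_error(score_ranking(dup, bank, form), "more than one selection")
  foreign <- log
  foreign$option_id[1] <- "A1-e1-r9"
  expect_error(score_ranking(foreign, bank, form), "does not belong")
  other_case <- log
  other_case$case_id[1] <- setdiff(bank$cases$case_id,
                                   form$cases$case_id)[1]
  expect_error(score_ranking(other_case, bank, form), ".")
})

test_that("batch cohort scoring equals single-log scoring", {
  bank <- fixture_bank_cached()
  cohort <- simulate_cohort(bank, n = 6, beta = 1, occasions = 2, seed = 8)
  batch <- score_cohort(cohort$logs, bank, by_family = TRUE)
  for (i in seq_len(nrow(batch$overall))) {
    row <- batch$overall[i, ]
    lg <- dplyr::filter(cohort$logs,
                        .data$respondent_id == row$respondent_id,
                        .data$occasion == row$occasion)
    single <- score_competencies(lg, bank)
    expect_equal(row$global_competency, single$global_competency,
                 tolerance = 1e-12)
    expect_equal(row$ranking, single$ranking, tolerance = 1e-12)
  }
  fam_row <- batch$by_family[3, ]
  lg <- dplyr::filter(cohort$logs,
                      .data$respondent_id == fam_row$respondent_id,
                      .data$occasion == fam_row$occasion,
                      .data$case_id == fam_row$case_id)
  expect_equal(fam_row$global_competency,
               score_competencies(lg, bank)$global_competency,
               tolerance = 1e-12)
})

test_that("theoretical range brackets the canonical bank at (min < 0, 100]", {
  bank <- fixture_bank_cached()
  rng <- theoretical_range(bank)
  expect_lt(rng$min, 0)
  expect_equal(rng$max, 100)
  # identical across forms, by variant structural equivalence
  rng2 <- theoretical_range(bank, form = assemble_form(bank, seed = 41))
  expect_equal(rng, rng2)
})

test_that("subscale_report exposes S, O, weight and contribution", {
  bank <- fixture_bank_cached()
  form <- assemble_form(bank, seed = 43)
  rep <- subscale_report(perfect_log(bank, form), bank, form)
  expect_named(rep, c("competency", "label", "polarity", "S", "O",
                      "assessed", "weight", "contribution"))
  expect_identical(nrow(rep), 11L)
  pos <- rep[rep$polarity == "positive" & rep$assessed, ]
  expect_equal(sum(pos$weight), 100)
})
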