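test_that("due dates follow interval arithmetic and transition rules", {
  cfg <- programme_config("breast")
  h <- tibble::tibble(birth_month = ym(1960, 1),
                      last_screen_month = ym(2020, 1))
  expect_equal(due_date(h, cfg, ym(2020, 1)), ym(2022, 1))

  cx <- programme_config("cervix")
  h2 <- tibble::tibble(
    birth_month = ym(1980, 1), last_screen_month = NA_integer_,
    hpv_transitioned = c(FALSE, TRUE),
    first_hpv_month = c(NA_integer_, ym(2017, 12)),
    last_cytology_month = c(ym(2019, 1), NA_integer_)
  )
  due <- due_date(h2, cx, ym(2020, 1))
  expect_equal(due[1], ym(2021, 1))        # 2 years after last cytology
  expect_gte(due[2], ym(2022, 12))         # not before December 2022
  h3 <- tibble::tibble(birth_month = ym(2005, 1),
                       last_screen_month = NA_integer_)
  expect_error(due_date(h3, cfg, ym(2020, 1)), "eligible")
})

test_that("screen outcomes follow the configured test characteristics", {
  cfg <- programme_config("breast", fp_rate = 0)
  res <- perform_screen(rep("healthy", 5000), cfg, ym(2020, 1))
  expect_true(all(res$outcome == "negative"))   # perfect specificity

  cfg2 <- programme_config("bowel",
                           sensitivity = list(adenoma = 1, crc = 1))
  res2 <- perform_screen(c("adenoma", "crc_12", "crc_34"), cfg2, 0)
  expect_equal(res2$outcome, c("detected-precursor", "detected-cancer",
                               "detected-cancer"))
  # size-dependent mammographic sensitivity
  cfg3 <- programme_config("breast",
                           sensitivity = list(small = 0.3, large = 0.9))
  u <- withr::with_seed(1, stats::runif(20000))
  small <- perform_screen(rep("small", 20000), cfg3, 0, u_test = u)
  large <- perform_screen(rep("large", 20000), cfg3, 0, u_test = u)
  expect_lt(abs(mean(small$outcome == "detected-cancer") - 0.3), 0.01)
  expect_lt(abs(mean(large$outcome == "detected-cancer") - 0.9), 0.01)
})

test_that("follow-up completion and pathways match the bowel rules", {
  cfg <- programme_config("bowel")
  expect_error(resolve_followup("negative", cfg, 0), "positive")
  fu <- withr::with_seed(2, resolve_followup(rep("positive", 100000), cfg, 0))
  expect_lt(abs(sum(fu$completes) - 70000), 3 * sqrt(100000 * 0.7 * 0.3))
  expect_true(all(fu$pathway == "return-to-iFOBT-4y"))
  fu2 <- resolve_followup("detected-precursor", cfg, 10)
  expect_equal(fu2$pathway, "surveillance")
  expect_equal(fu2$followup_month, 10 + cfg$colonoscopy_delay)
})

test_that("a clear follow-up colonoscopy returns to iFOBT after 4 years", {
  # all-positive kits, certain follow-up, no disease: kit -> colonoscopy
  # (+2 mo) -> clear -> next kit due 48 months after the colonoscopy
  ch <- cohort_spec("bowel", size = 300, scale = 1e-5) |>
    generate_cohort(seed = 21) |>
    assign_screening_behaviour(1, adherence_profile = list(
      on_schedule = c(1, 1), mean_delay_months = 1), seed = 21)
  cfg <- programme_config("bowel", fp_rate = 1, followup_completion = 1,
                          surveillance_init = 0, return_init = 0)
  p <- nh_params("bowel", adenoma_onset_rate = 0)
  run <- simulate_programme(ch, disruption_scenario("bowel", 0),
                            config = cfg, params = p, seed = 21,
                            horizon = c(ym(2018, 1), ym(2025, 1)))
  ev <- run$events
  per <- ev |>
    dplyr::filter(type %in% c("screen", "colonoscopy")) |>
    dplyr::arrange(id, month) |>
    dplyr::group_by(id) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(
      col_after_kit = month[2] - month[1],
      kit_after_col = month[3] - month[2],
      types = paste(type[1:3], collapse = ",")
    )
  expect_gt(nrow(per), 50)
  expect_true(all(per$types == "screen,colonoscopy,screen"))
  expect_true(all(per$col_after_kit == cfg$colonoscopy_delay))
  expect_true(all(per$kit_after_col == cfg$return_interval))
})

test_that("recalls partition into cancers and benign outcomes", {
  pr <- cached_paired("breast", 0)
  ev <- pr$status_quo$events
  recalls <- sum(ev$type == "assessment")
  benign <- sum(ev$type == "assessment" & ev$outcome == "benign")
  expect_gte(recalls, benign)
  expect_equal(recalls - benign,
               sum(ev$type == "assessment" & ev$outcome == "cancer"))
})

test_that("recorded stage equals the natural-history stage at detection", {
  pr <- cached_paired("bowel", 0)
  run <- pr$status_quo
  tr <- draw_trajectories(
    cohort_spec("bowel", scale = 0.002) |> generate_cohort(seed = 42) |>
      assign_screening_behaviour(0.435, seed = 42),
    run$params, seed = 42, run$horizon[1], run$horizon[2])
  dx <- dplyr::filter(run$events, type == "diagnosis")
  expect_gt(nrow(dx), 20)
  # diagnosis months are floored to whole months, so a symptomatic
  # presentation can be dated fractionally before the continuous
  # cancer-entry time; query the stage at or after entry
  at <- pmax(dx$month + 1e-9, tr$t_crc[dx$id] + 1e-9)
  expect_equal(dx$stage, stage_at_event(tr[dx$id, ], at))
})

test_that("with perfect test sensitivity no detectable cancer is missed", {
  # every interval cancer's onset must postdate its last negative screen:
  # a prevalent preclinical cancer cannot survive a perfect test
  ch <- cohort_spec("breast", scale = 0.002) |>
    generate_cohort(seed = 31) |>
    assign_screening_behaviour(0.55, seed = 31)
  cfg <- programme_config("breast", sensitivity = list(small = 1, large = 1),
                          presim_detect = list(small = 1, large = 1))
  run <- simulate_programme(ch, disruption_scenario("breast", 0),
                            config = cfg, seed = 31)
  tr <- draw_trajectories(ch, run$params, seed = 31,
                          run$horizon[1], run$horizon[2])
  cls <- classify_detection_mode(run$events)
  iv <- dplyr::filter(cls, interval_27)
  if (nrow(iv) > 0) {
    neg <- dplyr::filter(run$events, type == "screen", outcome == "negative")
    last_neg <- vapply(seq_len(nrow(iv)), function(i) {
      max(neg$month[neg$id == iv$id[i] & neg$month < iv$month[i]])
    }, numeric(1))
    expect_true(all(tr$t_onset[iv$id] > last_neg))
  } else {
    succeed()
  }
})
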