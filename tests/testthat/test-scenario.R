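test_that("capacity schedules encode pause, ramp, and identity", {
  hz <- c(ym(2018, 1), ym(2023, 1))
  null_sched <- build_capacity_schedule(disruption_scenario("breast", 0), hz)
  expect_true(all(null_sched$multiplier == 1))

  sc6 <- disruption_scenario("bowel", 6)   # instant resumption, no ramp
  s <- build_capacity_schedule(sc6, hz)
  get <- function(tab, m) tab$multiplier[match(m, tab$month)]
  expect_equal(get(s, ym(2020, 3)), 1)
  expect_equal(get(s, ym(2020, 4)), 0)
  expect_equal(get(s, ym(2020, 9)), 0)
  expect_equal(get(s, ym(2020, 10)), 1)

  sc12 <- disruption_scenario("breast", 12)   # ramp to 150% by month 7
  s12 <- build_capacity_schedule(sc12, hz)
  expect_true(all(s12$multiplier[s12$month >= ym(2020, 4) &
                                   s12$month < ym(2021, 4)] == 0))
  k <- 0:5
  s0 <- sc12$ramp_start_frac
  expect_equal(get(s12, ym(2021, 4) + k),
               s0 + (1.5 - s0) * k / 6)         # linear interpolation
  expect_equal(get(s12, ym(2021, 10)), 1.5)     # seventh month: target
  expect_equal(get(s12, ym(2022, 6)), 1.5)
  # shorter pauses creep back to the status quo target from a low start
  s6 <- disruption_scenario("breast", 6)
  expect_equal(s6$ramp_start_frac, 0.3)
  expect_equal(s6$recovery_target, 1.0)
  sch6 <- build_capacity_schedule(s6, hz)
  expect_equal(get(sch6, ym(2021, 4)), 1.0)     # seventh month after Oct
  expect_error(build_capacity_schedule(sc12, c(ym(2020, 1), ym(2020, 6))),
               "horizon")
})

test_that("attendance modifiers reduce routine cervical screening only", {
  sc <- disruption_scenario("cervix", 6)    # 50% reduction Apr-Sep 2020
  expect_equal(attendance_modifier(sc, ym(2020, 5), "routine"), 0.5)
  expect_equal(attendance_modifier(sc, ym(2020, 5), "surveillance"), 1)
  expect_equal(attendance_modifier(sc, ym(2021, 5), "routine"), 1)
  sc12 <- disruption_scenario("cervix", 12) # 95% reduction over 2020
  expect_equal(attendance_modifier(sc12, ym(2020, 2), "routine"), 0.05)
  # breast pause blocks throughput, not attendance; opportunistic halved
  b <- disruption_scenario("breast", 12)
  expect_equal(attendance_modifier(b, ym(2020, 6), "routine"), 1)
  expect_equal(opportunistic_modifier(b, ym(2020, 6)), 0.5)
  expect_equal(opportunistic_modifier(b, ym(2021, 6)), 1)
})

test_that("missed screens reschedule per programme policy", {
  bw <- disruption_scenario("bowel", 6)
  expect_equal(reschedule_missed(bw, ym(2020, 5)), ym(2022, 5))
  cx12 <- disruption_scenario("cervix", 12)
  m <- reschedule_missed(cx12, rep(ym(2020, 6), 10000))
  expect_true(all(m >= ym(2021, 1) & m <= ym(2022, 12)))
  cx9 <- disruption_scenario("cervix", 9)
  m9 <- reschedule_missed(cx9, rep(ym(2020, 6), 10000))
  expect_true(all(m9 >= ym(2021, 1) & m9 <= ym(2021, 12)))
  bad <- disruption_scenario("bowel", 6)
  bad$reschedule_policy <- "nonsense"
  expect_error(reschedule_missed(bad, ym(2020, 5)), "unknown")
})

test_that("programme-aware scenario defaults match the evaluated grid", {
  expect_equal(disruption_scenario("cervix", 9)$degree, 0.75)
  expect_equal(disruption_scenario("cervix", 12)$degree, 0.95)
  expect_equal(disruption_scenario("cervix", 12)$pause_start, ym(2020, 1))
  expect_equal(disruption_scenario("bowel", 12)$pause_start, ym(2020, 1))
  expect_equal(disruption_scenario("bowel", 6)$pause_start, ym(2020, 4))
  expect_equal(disruption_scenario("breast", 12)$recovery_target, 1.5)
  expect_equal(disruption_scenario("breast", 6)$recovery_target, 1.0)
  expect_error(disruption_scenario("breast", 6, degree = 2), "degree")
})

test_that("the null scenario reproduces the status quo bit for bit", {
  pr <- cached_paired("bowel", 0)
  expect_identical(pr$status_quo$events, pr$scenario$events)
  # and repeated runs are byte-identical
  pr2 <- run_paired(
    cohort_spec("bowel", scale = 0.002) |> generate_cohort(seed = 42) |>
      assign_screening_behaviour(0.435, seed = 42),
    disruption_scenario("bowel", 0), seed = 42)
  expect_identical(pr$status_quo$events, pr2$status_quo$events)
})

test_that("provided plus missed screens reconcile with the status quo", {
  pr <- cached_paired("bowel", 6)
  w <- c(ym(2020, 4), ym(2021, 4))
  in_w <- function(run) {
    dplyr::filter(run$events, type == "screen", month >= w[1], month < w[2])
  }
  sq <- in_w(pr$status_quo); sc <- in_w(pr$scenario)
  # per-person conservation: every kit provided under the scenario pairs
  # with a status quo kit; the remainder are the missed screens
  extra <- setdiff(sc$id, sq$id)
  expect_length(extra, 0)
  expect_equal(nrow(sc) + (nrow(sq) - nrow(sc)), nrow(sq))
  expect_lt(nrow(sc), nrow(sq))
})
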