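# independent pairwise comparator: returns TRUE if request a precedes b
# under the four-factor ordering (target age, pause period, existing
# client, most overdue, id tie-break)
oracle_precedes <- function(a, b, now) {
  key <- function(r) {
    c(ifelse(r$age >= 50 & r$age <= 74, 0, 1),
      ifelse(r$period == "pause", 0, 1),
      ifelse(r$newly_invited, 1, 0),
      -(now - r$scheduled_month),
      r$id)
  }
  ka <- key(a); kb <- key(b)
  i <- which(ka != kb)[1]
  ka[i] < kb[i]
}

random_requests <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    id = sample(100, n),
    age = sample(c(45, 55, 60, 74, 78), n, replace = TRUE),
    newly_invited = sample(c(TRUE, FALSE), n, replace = TRUE),
    period = sample(c("pause", "recovery"), n, replace = TRUE),
    scheduled_month = ym(2020, 4) + sample(0:11, n, replace = TRUE)
  ))
}

test_that("target-age women precede others; ties break by id", {
  now <- ym(2021, 6)
  req <- tibble::tibble(
    id = c(1L, 2L), age = c(60, 45), newly_invited = FALSE,
    period = "pause", scheduled_month = ym(2020, 6)
  )
  keyed <- priority_key(req, now)
  expect_lt(keyed$priority[keyed$age == 60], keyed$priority[keyed$age == 45])
  same <- tibble::tibble(id = c(9L, 4L), age = 60, newly_invited = FALSE,
                         period = "pause", scheduled_month = ym(2020, 6))
  keyed2 <- priority_key(same, now)
  expect_equal(keyed2$id[order(keyed2$priority)], c(4L, 9L))
})

test_that("sorted order equals the exhaustive pairwise-comparison oracle", {
  now <- ym(2021, 8)
  for (case in 1:25) {
    req <- random_requests(sample(2:8, 1), seed = case)
    keyed <- priority_key(req, now)
    got <- keyed$id[order(keyed$priority)]
    # brute-force total order: selection sort via the pairwise oracle
    rows <- split(req, seq_len(nrow(req)))
    expected <- integer(0)
    while (length(rows)) {
      best <- 1
      for (j in seq_along(rows)) {
        if (j != best && oracle_precedes(rows[[j]], rows[[best]], now)) {
          best <- j
        }
      }
      expected <- c(expected, rows[[best]]$id)
      rows <- rows[-best]
    }
    expect_equal(got, expected)
  }
})

test_that("allocation respects capacity, priority, and determinism", {
  now <- ym(2021, 6)
  req <- random_requests(30, seed = 99)
  all_in <- allocate(req, multiplier = 1, now, base_capacity = 50)
  expect_equal(nrow(all_in$booked), 30)
  expect_equal(nrow(all_in$carried), 0)
  none <- allocate(req, multiplier = 0, now, base_capacity = 50)
  expect_equal(nrow(none$booked), 0)
  expect_equal(nrow(none$carried), 30)
  some <- allocate(req, multiplier = 0.5, now, base_capacity = 20)
  expect_equal(nrow(some$booked), 10)    # floor(20 * 0.5)
  # no carried request outranks a booked one
  expect_lt(max(some$booked$priority), min(some$carried$priority))
  again <- allocate(req, multiplier = 0.5, now, base_capacity = 20)
  expect_identical(some$booked$id, again$booked$id)
  expect_error(allocate(req, 1, now, base_capacity = -1), "capacity")
})

test_that("median screening intervals follow the definition", {
  # perfect biennial attendance: 24 months is ~104.3 weeks
  ev <- tibble::tibble(id = rep(1:5, each = 3), type = "screen",
                       month = rep(c(0, 24, 48), 5))
  expect_equal(median_screening_interval(ev), 104.36, tolerance = 1e-3)
  ev2 <- tibble::tibble(id = c(1, 1, 2, 2, 3, 3), type = "screen",
                        month = c(0, 23, 0, 25, 0, 30))
  expect_equal(median_screening_interval(ev2),
               months_to_weeks(25), tolerance = 1e-6)
  expect_warning(out <- median_screening_interval(ev[0, ]), "no completed")
  expect_true(is.na(out))
  # window restriction keeps intervals ending inside the window
  expect_equal(median_screening_interval(ev, window = c(40, 60)),
               104.36, tolerance = 1e-3)
})

test_that("capacity is never exceeded and no priority inversion occurs", {
  pr <- cached_paired("breast", 12)
  run <- pr$scenario
  scr <- dplyr::filter(run$events, type == "screen",
                       month >= ym(2021, 4))
  sched <- build_capacity_schedule(run$scenario, run$horizon)
  monthly <- dplyr::count(scr, month)
  caps <- sched$multiplier[match(monthly$month, sched$month)]
  expect_true(all(monthly$n <= floor(run$base_capacity * caps) + 1e-9))
})

test_that("median intervals are non-decreasing in pause duration", {
  meds <- vapply(c(3, 6, 12), function(d) {
    run <- cached_paired("breast", d)$scenario
    median_screening_interval(run$events,
                              window = c(ym(2020, 4), ym(2023, 1)))
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})
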