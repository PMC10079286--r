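test_that("zero hazards produce no disease events over any horizon", {
  ch <- tiny_cohort("breast", 500)
  p <- nh_params("breast", onset_rate = 0)
  tr <- draw_trajectories(ch, p, seed = 1, ym(2018, 1), ym(2023, 1))
  expect_true(all(!is.finite(tr$t_onset)))
  expect_equal(nrow(advance_state(tr, ym(2018, 1), ym(2023, 1))), 0)
  expect_error(nh_params("breast", onset_rate = -1), "non-negative")
  expect_error(advance_state(tr, 10, 10), "to_month")
})

test_that("symptomatic presentation matches the exponential closed form", {
  # single preclinical compartment with presentation hazard h: the
  # fraction presenting within 12 months of onset is 1 - exp(-12 h)
  h <- 0.05
  n <- 100000
  ch <- cohort_spec("breast", size = n) |> generate_cohort(seed = 2) |>
    assign_screening_behaviour(0, seed = 2)
  p <- nh_params("breast", onset_rate = 5e-4, mean_small = 1e9,
                 present_small_rate = h, grade3_speed = 1)
  tr <- draw_trajectories(ch, p, seed = 2, ym(2018, 1), ym(2030, 1))
  d <- (tr$t_clin - tr$t_onset)[is.finite(tr$t_onset)]
  frac <- mean(d <= 12)
  expected <- 1 - exp(-12 * h)
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / length(d)))
})

test_that("vaccination scales HPV acquisition by the configured multiplier", {
  p <- nh_params("cervix", vaccine_multiplier = 0.1)
  expect_equal(apply_vaccination_effect(p, c(TRUE, FALSE)),
               p$hpv_onset_rate * c(0.1, 1))
  expect_error(apply_vaccination_effect(nh_params("breast"), TRUE), "cervical")
  expect_error(nh_params("cervix", vaccine_multiplier = 1.5), "multiplier")

  # population-level acquisition under 80% coverage matches the mixture
  n <- 100000
  ch <- cohort_spec("cervix", size = n) |> generate_cohort(seed = 3) |>
    assign_screening_behaviour(0, seed = 3)
  ch$vaccinated <- seq_len(n) <= 0.8 * n
  p <- nh_params("cervix", vaccine_multiplier = 0.1, lookback = 1)
  tr <- draw_trajectories(ch, p, seed = 3, ym(2018, 1), ym(2028, 1))
  p_on <- function(r) 1 - exp(-r * (120 + 1))
  expected <- 0.8 * p_on(p$hpv_onset_rate * 0.1) + 0.2 * p_on(p$hpv_onset_rate)
  frac <- mean(is.finite(tr$t_hpv))
  expect_lt(abs(frac - expected), 3 * sqrt(expected / n))
  # multiplier 0: vaccinated women never acquire HPV
  tr0 <- draw_trajectories(ch, nh_params("cervix", vaccine_multiplier = 0),
                           seed = 3, ym(2018, 1), ym(2028, 1))
  expect_true(all(!is.finite(tr0$t_hpv[ch$vaccinated])))
})

test_that("stages never reverse along a trajectory", {
  for (s in 1:5) {
    ch <- tiny_cohort("cervix", 2000, seed = s)
    tr <- draw_trajectories(ch, nh_params("cervix"), seed = s,
                            ym(2018, 1), ym(2025, 1))
    ok <- is.finite(tr$t_loc)
    expect_true(all(tr$t_loc[ok] <= tr$t_reg[ok]))
    expect_true(all(tr$t_reg[ok] <= tr$t_dist[ok]))
    expect_true(all(tr$t_clin[ok] >= tr$t_loc[ok]))
    trb <- draw_trajectories(ch, nh_params("bowel"), seed = s,
                             ym(2018, 1), ym(2025, 1))
    okb <- is.finite(trb$t_crc)
    expect_true(all(trb$t_adenoma[okb] <= trb$t_crc[okb]))
    expect_true(all(trb$t_crc[okb] <= trb$t_34[okb]))
  }
})

test_that("later detection stochastically increases detected stage", {
  ch <- tiny_cohort("breast", 50000, seed = 4)
  tr <- draw_trajectories(ch, nh_params("breast"), seed = 4,
                          ym(2018, 1), ym(2026, 1))
  # among tumours preclinical at m1, the share already >15 mm grows with
  # the inspection month
  m1 <- ym(2020, 1); m2 <- ym(2021, 1)
  pre1 <- tr$t_onset <= m1 & m1 < tr$t_clin
  pre2 <- tr$t_onset <= m1 & m2 < tr$t_clin
  expect_gt(mean(m2 >= tr$t_large[pre2]), mean(m1 >= tr$t_large[pre1]))
})

test_that("compartment occupancy matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  # 3-state chain: healthy -> preclinical -> clinical, rates h1, h2
  h1 <- 0.02; h2 <- 0.06; Tm <- 18
  n <- 100000
  ch <- cohort_spec("breast", size = n) |> generate_cohort(seed = 6) |>
    assign_screening_behaviour(0, seed = 6)
  p <- nh_params("breast", onset_rate = h1, mean_small = 1e9,
                 present_small_rate = h2, grade3_speed = 1,
                 lookback = 1e-9)
  start <- ym(2018, 1)
  tr <- draw_trajectories(ch, p, seed = 6, start, start + 600)
  occ <- c(
    healthy = mean(tr$t_onset > start + Tm),
    preclinical = mean(tr$t_onset <= start + Tm & tr$t_clin > start + Tm),
    clinical = mean(tr$t_clin <= start + Tm)
  )
  Q <- matrix(c(-h1, h1, 0, 0, -h2, h2, 0, 0, 0), 3, byrow = TRUE)
  expected <- as.numeric(c(1, 0, 0) %*% Matrix::expm(Q * Tm))
  expect_lt(max(abs(occ - expected)), 0.005)
})

test_that("stage lookup is deterministic and rejects non-cancer states", {
  ch <- tiny_cohort("bowel", 3000, seed = 8)
  tr <- draw_trajectories(ch, nh_params("bowel"), seed = 8,
                          ym(2018, 1), ym(2026, 1))
  i <- which(is.finite(tr$t_34))[1]
  skip_if(is.na(i), "no progressing case drawn")
  expect_equal(stage_at_event(tr[i, ], tr$t_34[i] - 0.5), "1-2")
  expect_equal(stage_at_event(tr[i, ], tr$t_34[i] + 0.5), "3-4")
  expect_error(stage_at_event(tr[i, ], tr$t_crc[i] - 1), "compartment")
  chc <- tiny_cohort("cervix", 3000, seed = 8)
  trc <- draw_trajectories(chc, nh_params("cervix"), seed = 8,
                           ym(2018, 1), ym(2026, 1))
  j <- which(is.finite(trc$t_loc) & is.finite(trc$t_reg))[1]
  skip_if(is.na(j), "no invasive case drawn")
  expect_equal(stage_at_event(trc[j, ], trc$t_reg[j] - 0.5), "localised")
})
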