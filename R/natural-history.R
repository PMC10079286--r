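# Simplified stochastic natural histories for breast, colorectal and
# cervical cancer. Each disease is a continuous-time multistate process
# with exponential (memoryless) dwell times. Because dwell times are
# exponential, a person's complete no-intervention trajectory can be drawn
# up front as a set of event times (competing exponential clocks); monthly
# stepping of competing hazards converges to exactly this law, and the
# pre-drawn form gives perfect common-random-number pairing across
# scenarios: screening changes which part of a trajectory is *observed*
# (detection truncates it), never the trajectory itself.
#
# Onsets follow a stationary Poisson process: the first onset is drawn on a
# lookback window long relative to the sojourn times, so disease prevalent
# at the start of the simulation has the stationary distribution.

#' Natural-history parameters for one cancer type
#'
#' All rates are per person-month; all means are months. Defaults are the
#' packaged calibrated values (see [default_nh_params()]). Free parameters
#' are set by [calibrate()] against status quo programme outcomes; the
#' absolute levels are not observable directly and are meaningful only
#' through that calibration.
#'
#' @param cancer One of "breast", "bowel", "cervix".
#' @param ... Named parameter overrides (see [default_nh_params()] for the
#'   full set per cancer).
#' @return A named list of class `nh_params`.
#' @export
nh_params <- function(cancer = c("breast", "bowel", "cervix"), ...) {
  cancer <- match.arg(cancer)
  p <- utils::modifyList(default_nh_params(cancer), list(...))
  p$cancer <- cancer
  rates <- p[grepl("_rate$", names(p))]
  if (any(unlist(rates) < 0)) {
    stop("natural-history hazards must be non-negative", call. = FALSE)
  }
  means <- p[grepl("^mean_", names(p))]
  if (any(unlist(means) <= 0)) {
    stop("mean dwell times must be positive", call. = FALSE)
  }
  if (!is.null(p$vaccine_multiplier) &&
      (p$vaccine_multiplier < 0 || p$vaccine_multiplier > 1)) {
    stop("vaccine multiplier must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "nh_params")
}

#' Packaged default (calibrated) natural-history parameters
#'
#' Breast: healthy -> preclinical tumour <=15 mm -> preclinical >15 mm ->
#' clinical (symptomatic) cancer, with grade fixed at onset (grade-3
#' tumours run all clocks faster) and nodal involvement accruing mainly in
#' the >15 mm phase. Bowel: healthy -> adenoma (may regress) -> preclinical
#' CRC stage 1-2 -> preclinical stage 3-4 -> clinical, with symptomatic
#' presentation competing in both cancer stages. Cervix: healthy -> HPV
#' infection (may clear) -> CIN (may regress) -> localised -> regional ->
#' distant invasive cancer; vaccination multiplies the HPV acquisition
#' hazard.
#'
#' @param cancer One of "breast", "bowel", "cervix".
#' @return Named list of parameters.
#' @export
default_nh_params <- function(cancer = c("breast", "bowel", "cervix")) {
  cancer <- match.arg(cancer)
  switch(cancer,
    breast = list(
      onset_rate = 1.24e-4,      # preclinical tumour onsets per woman-month
      mean_small = 62,           # mean months <=15 mm before progression
      mean_large = 12,           # mean months >15 mm before presentation
      present_small_rate = 0.004, # symptomatic presentation while <=15 mm
      nodal_small_rate = 0.004,
      nodal_large_rate = 0.045,
      grade3_prob = 0.48,        # grade 3 (vs 1-2) assigned at onset
      grade3_speed = 3.2,        # clock multiplier for grade-3 tumours
      lookback = 300
    ),
    bowel = list(
      adenoma_onset_rate = 8.0e-4,
      adenoma_regress_rate = 3.6e-3,
      adenoma_progress_rate = 1.25e-3, # adenoma -> preclinical CRC 1-2
      present_12_rate = 0.027,        # symptomatic while stage 1-2
      progress_12_rate = 0.019,       # stage 1-2 -> 3-4
      present_34_rate = 0.090,
      lookback = 480
    ),
    cervix = list(
      hpv_onset_rate = 2.4e-3,   # acquisition among unvaccinated women
      hpv_clear_rate = 0.075,
      cin_onset_rate = 0.004,    # persistent infection -> CIN
      cin_regress_rate = 0.010,
      cin_progress_rate = 1.6e-3, # CIN -> localised invasive cancer
      present_loc_rate = 0.012,
      progress_loc_rate = 0.020, # localised -> regional
      present_reg_rate = 0.040,
      progress_reg_rate = 0.030, # regional -> distant
      present_dist_rate = 0.120,
      vaccine_multiplier = 0.1,
      lookback = 480
    )
  )
}

#' Vaccination-adjusted HPV acquisition hazard
#'
#' Vaccinated women acquire HPV at the baseline hazard times the configured
#' multiplier (0 = complete protection, 1 = no effect).
#'
#' @param params Cervical [nh_params()].
#' @param vaccinated Logical vector.
#' @return Numeric vector of per-month acquisition hazards.
#' @export
apply_vaccination_effect <- function(params, vaccinated) {
  if (params$cancer != "cervix") {
    stop("vaccination applies to the cervical model only", call. = FALSE)
  }
  m <- params$vaccine_multiplier
  if (m < 0 || m > 1) stop("vaccine multiplier must lie in [0, 1]", call. = FALSE)
  params$hpv_onset_rate * ifelse(vaccinated, m, 1)
}

# first arrival of a stationary Poisson(rate) process on
# [start - lookback, end]; Inf if none (or rate 0)
draw_onset <- function(n, rate, start, end, lookback) {
  t0 <- start - lookback
  t <- if (length(rate) == 1 && rate == 0) rep(Inf, n) else t0 + stats::rexp(n, rate)
  t[t >= end] <- Inf
  t
}

# competing exponential clocks: returns list(time, which) where `which` is
# the index of the winning clock (1..k); rates is a list of vectors
compete <- function(...) {
  rates <- list(...)
  n <- length(rates[[1]])
  draws <- vapply(rates, function(r) {
    d <- rep(Inf, n)
    pos <- r > 0
    if (any(pos)) d[pos] <- stats::rexp(sum(pos), r[pos])
    d
  }, numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1)
  which <- max.col(-draws, ties.method = "first")
  time <- draws[cbind(seq_len(n), which)]
  list(time = time, which = which)
}

#' Draw complete no-intervention disease trajectories for a cohort
#'
#' Returns one row per person with the calendar times (fractional month
#' indices, `Inf` = never) of every potential disease event. Screening
#' logic later decides which events are observed or pre-empted.
#'
#' @param cohort Cohort tibble (needs `id`; `vaccinated` for cervix).
#' @param params [nh_params()] for the matching cancer type.
#' @param seed Master integer seed.
#' @param start,end Simulation window as month indices.
#' @return A tibble of trajectory times, class `nh_trajectories`, with the
#'   cancer type in attribute `"cancer"`.
#' @export
draw_trajectories <- function(cohort, params, seed, start, end) {
  fn <- switch(params$cancer,
    breast = draw_breast_trajectories,
    bowel = draw_bowel_trajectories,
    cervix = draw_cervix_trajectories
  )
  out <- with_substream(seed, paste0("nh_", params$cancer),
                        fn(cohort, params, start, end))
  out$id <- cohort$id
  attr(out, "cancer") <- params$cancer
  class(out) <- c("nh_trajectories", class(out))
  out
}

draw_breast_trajectories <- function(cohort, p, start, end) {
  n <- nrow(cohort)
  t_onset <- draw_onset(n, p$onset_rate, start, end, p$lookback)
  grade3 <- stats::runif(n) < p$grade3_prob
  f <- ifelse(grade3, p$grade3_speed, 1)
  small <- compete(f / p$mean_small, f * p$present_small_rate)
  presents_small <- small$which == 2
  t_large <- ifelse(presents_small, Inf, t_onset + small$time)
  d_large <- stats::rexp(n, f / p$mean_large)
  t_clin <- ifelse(presents_small, t_onset + small$time, t_large + d_large)
  # nodal involvement: piecewise-constant hazard, low while small
  e <- stats::rexp(n)
  d_small <- ifelse(presents_small, small$time, t_large - t_onset)
  h_small <- f * p$nodal_small_rate
  h_large <- f * p$nodal_large_rate
  cum_small <- h_small * d_small
  t_nodal <- ifelse(
    e < cum_small,
    t_onset + e / pmax(h_small, 1e-12),
    t_large + (e - cum_small) / pmax(h_large, 1e-12)
  )
  tibble::tibble(t_onset = t_onset, t_large = t_large, t_clin = t_clin,
                 t_nodal = t_nodal, grade3 = grade3)
}

draw_bowel_trajectories <- function(cohort, p, start, end) {
  n <- nrow(cohort)
  t_adenoma <- draw_onset(n, p$adenoma_onset_rate, start, end, p$lookback)
  aden <- compete(rep(p$adenoma_regress_rate, n),
                  rep(p$adenoma_progress_rate, n))
  progresses <- aden$which == 2
  t_adenoma_end <- t_adenoma + aden$time      # adenoma absent after this
  t_crc <- ifelse(progresses, t_adenoma + aden$time, Inf)
  s12 <- compete(rep(p$present_12_rate, n), rep(p$progress_12_rate, n))
  presents_12 <- s12$which == 1
  t_34 <- ifelse(presents_12, Inf, t_crc + s12$time)
  d_34 <- stats::rexp(n, p$present_34_rate)
  t_clin <- ifelse(presents_12, t_crc + s12$time, t_34 + d_34)
  tibble::tibble(t_adenoma = t_adenoma, t_adenoma_end = t_adenoma_end,
                 t_crc = t_crc, t_34 = t_34, t_clin = t_clin)
}

draw_cervix_trajectories <- function(cohort, p, start, end) {
  n <- nrow(cohort)
  vacc <- if (!is.null(cohort$vaccinated)) cohort$vaccinated else rep(FALSE, n)
  rate <- apply_vaccination_effect(p, vacc)
  t_hpv <- draw_onset(n, pmax(rate, 1e-12), start, end, p$lookback)
  t_hpv[rate == 0] <- Inf
  hpv <- compete(rep(p$hpv_clear_rate, n), rep(p$cin_onset_rate, n))
  to_cin <- hpv$which == 2
  t_hpv_end <- t_hpv + hpv$time
  t_cin <- ifelse(to_cin, t_hpv + hpv$time, Inf)
  cin <- compete(rep(p$cin_regress_rate, n), rep(p$cin_progress_rate, n))
  to_cancer <- cin$which == 2
  t_cin_end <- t_cin + cin$time
  t_loc <- ifelse(to_cancer, t_cin + cin$time, Inf)
  loc <- compete(rep(p$present_loc_rate, n), rep(p$progress_loc_rate, n))
  presents_loc <- loc$which == 1
  t_reg <- ifelse(presents_loc, Inf, t_loc + loc$time)
  reg <- compete(rep(p$present_reg_rate, n), rep(p$progress_reg_rate, n))
  presents_reg <- reg$which == 1
  t_dist <- ifelse(presents_reg, Inf, t_reg + reg$time)
  d_dist <- stats::rexp(n, p$present_dist_rate)
  t_clin <- ifelse(presents_loc, t_loc + loc$time,
                   ifelse(presents_reg, t_reg + reg$time, t_dist + d_dist))
  tibble::tibble(t_hpv = t_hpv, t_hpv_end = t_hpv_end, t_cin = t_cin,
                 t_cin_end = t_cin_end, t_loc = t_loc, t_reg = t_reg,
                 t_dist = t_dist, t_clin = t_clin)
}

#' Disease events occurring in a time window
#'
#' The operational surface over pre-drawn trajectories: lists every onset,
#' progression and symptomatic-presentation event with `from_month < time
#' <= to_month`, in chronological order per person. Cancer stages never
#' reverse; precursor regression (adenoma, CIN) appears as an `*_end`
#' event.
#'
#' @param traj An `nh_trajectories` tibble.
#' @param from_month,to_month Window bounds (months, `to_month` >
#'   `from_month`).
#' @return Tibble with columns `id`, `month`, `event`.
#' @export
advance_state <- function(traj, from_month, to_month) {
  stopifnot(to_month > from_month)
  cancer <- attr(traj, "cancer")
  cols <- setdiff(names(traj)[startsWith(names(traj), "t_")], "t_nodal")
  ev <- lapply(cols, function(cl) {
    t <- traj[[cl]]
    keep <- is.finite(t) & t > from_month & t <= to_month
    tibble::tibble(id = traj$id[keep], month = t[keep],
                   event = sub("^t_", "", cl))
  })
  out <- dplyr::bind_rows(ev)
  dplyr::arrange(out, .data$id, .data$month)
}

#' Stage label occupied at a given month
#'
#' Deterministic lookup against the trajectory history. Errors if the
#' person is not in a cancer compartment at `month`.
#'
#' @param traj An `nh_trajectories` tibble (or subset of rows).
#' @param month Month (scalar or vector matching rows).
#' @return Character stage labels: breast `"small"`/`"large"` (tumour <=15
#'   mm vs >15 mm); bowel `"1-2"`/`"3-4"`; cervix
#'   `"localised"`/`"regional"`/`"distant"`.
#' @export
stage_at_event <- function(traj, month) {
  cancer <- attr(traj, "cancer")
  if (is.null(cancer)) stop("not a trajectory object", call. = FALSE)
  switch(cancer,
    breast = {
      if (any(month < traj$t_onset)) {
        stop("stage requested outside a cancer compartment", call. = FALSE)
      }
      ifelse(month < traj$t_large, "small", "large")
    },
    bowel = {
      if (any(month < traj$t_crc)) {
        stop("stage requested outside a cancer compartment", call. = FALSE)
      }
      ifelse(month < traj$t_34, "1-2", "3-4")
    },
    cervix = {
      if (any(month < traj$t_loc)) {
        stop("stage requested outside a cancer compartment", call. = FALSE)
      }
      ifelse(month < traj$t_reg, "localised",
             ifelse(month < traj$t_dist, "regional", "distant"))
    }
  )
}
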