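# Programme simulation engines. Each engine walks calendar months over a
# cohort with pre-drawn disease trajectories, applying screening logic,
# the scenario's capacity / attendance / rescheduling rules, and follow-up
# pathways, and accumulates a dated event log.
#
# Common-random-number pairing: the cohort, trajectories and all
# per-person-per-round uniforms are drawn from seed-derived substreams
# before the monthly loop, so a scenario run and its status quo
# counterfactual share every draw. A null scenario follows exactly the
# same code path and reproduces the status quo bit for bit.

default_horizon <- function(programme) {
  switch(programme,
    breast = c(ym(2018, 1), ym(2023, 1)),
    bowel = c(ym(2018, 1), ym(2022, 1)),
    cervix = c(ym(2018, 1), ym(2023, 1))
  )
}

new_run <- function(programme, cohort, events, scenario, config, params,
                    seed, horizon, base_capacity = NA) {
  spec <- attr(cohort, "spec")
  structure(
    list(programme = programme, events = events, scenario = scenario,
         config = config, params = params, seed = seed, horizon = horizon,
         n = nrow(cohort), scale = if (!is.null(spec)) spec$scale else NA,
         base_capacity = base_capacity),
    class = "disruption_run"
  )
}

#' @export
print.disruption_run <- function(x, ...) {
  cat("<disruption_run> ", x$programme,
      if (is_null_scenario(x$scenario)) " (status quo)" else
        sprintf(" (%d-mo %s)", x$scenario$duration, x$scenario$mode),
      ": ", x$n, " persons, ",
      sum(x$events$type == "screen"), " screens, ",
      sum(x$events$type == "diagnosis"), " diagnoses\n", sep = "")
  invisible(x)
}

empty_events <- function() {
  tibble::tibble(
    id = integer(), month = integer(), type = character(),
    modality = character(), outcome = character(), stage = character(),
    mode = character(), routine = logical(), scheduled_month = integer(),
    nodal = logical(), grade3 = logical()
  )
}

ev <- function(id, month, type, modality = NA_character_,
               outcome = NA_character_, stage = NA_character_,
               mode = NA_character_, routine = NA, scheduled_month = NA,
               nodal = NA, grade3 = NA) {
  tibble::tibble(
    id = as.integer(id), month = as.integer(month), type = type,
    modality = modality, outcome = outcome, stage = stage, mode = mode,
    routine = as.logical(routine),
    scheduled_month = as.integer(scheduled_month),
    nodal = as.logical(nodal), grade3 = as.logical(grade3)
  )
}

#' Simulate one programme under one scenario
#'
#' Runs the full microsimulation for a cohort: natural-history
#' trajectories, routine screening with attendance delays, disruption
#' (pause / attendance reduction), capacity-constrained recovery with the
#' prioritisation queue (breast), rescheduling of missed screens,
#' follow-up pathways, and symptomatic presentation. Deterministic given
#' `seed`.
#'
#' @param cohort A behaviour-assigned cohort tibble (see
#'   [generate_cohort()], [assign_screening_behaviour()]; cervical
#'   cohorts additionally need [assign_hpv_history()]).
#' @param scenario A [disruption_scenario()] for the same programme.
#' @param config A [programme_config()]; defaults to the programme's
#'   packaged configuration.
#' @param params [nh_params()]; defaults to the packaged calibrated set.
#' @param seed Master integer seed.
#' @param horizon `c(start, end)` month indices (end exclusive).
#' @return A `disruption_run` object; `$events` holds the dated event log.
#' @export
simulate_programme <- function(cohort, scenario,
                               config = programme_config(scenario$programme),
                               params = nh_params(scenario$programme),
                               seed = attr(cohort, "seed"),
                               horizon = default_horizon(scenario$programme)) {
  engine <- switch(scenario$programme,
    breast = simulate_breast_engine,
    bowel = simulate_bowel_engine,
    cervix = simulate_cervix_engine
  )
  engine(cohort, scenario, config, params, seed, horizon)
}

#' Run a scenario and its status quo counterfactual with shared draws
#'
#' The scenario run and the paired status quo run share the cohort,
#' trajectories and screening draws (common random numbers), so
#' scenario-minus-status-quo differences are free of cohort-level noise.
#'
#' @inheritParams simulate_programme
#' @return List of class `paired_runs` with elements `status_quo` and
#'   `scenario`.
#' @export
run_paired <- function(cohort, scenario,
                       config = programme_config(scenario$programme),
                       params = nh_params(scenario$programme),
                       seed = attr(cohort, "seed"),
                       horizon = default_horizon(scenario$programme)) {
  null_sc <- disruption_scenario(scenario$programme, 0)
  structure(
    list(
      status_quo = simulate_programme(cohort, null_sc, config, params,
                                      seed, horizon),
      scenario = simulate_programme(cohort, scenario, config, params,
                                    seed, horizon)
    ),
    class = "paired_runs"
  )
}

# the next routine due month is anchored to the last attended screen
# (re-invitation follows the attended date, matching due_date())
next_anchor <- function(scheduled, actual, interval) {
  as.integer(actual + interval)
}

# Pre-simulation screening history: participants' prevalent disease at the
# simulation start has already been exposed to their earlier screening
# rounds, so thin it accordingly; otherwise the first simulated years ride
# an unscreened-stationary prevalence wave and early detection rates are
# far above the programme's steady state. Walks the pre-start rounds
# implied by each participant's schedule stagger back to the programme
# era, detecting with the configured per-state probabilities. Returns the
# state in which each person's disease was found pre-sim (NA = never).
presim_screening <- function(cohort, config, seed, start, first_due,
                             state_fn, cutoff = start) {
  n <- nrow(cohort)
  part <- cohort$participant & !is.na(cohort$participant)
  det <- unlist(config$presim_detect)
  iv <- config$presim_interval
  era <- config$era_start
  invite <- cohort$birth_month + config$invitation_age * 12L
  J <- max(1L, as.integer(ceiling((max(cutoff) - era) / iv)))
  u <- with_substream(seed, paste0("presim_", config$programme),
                      matrix(stats::runif(n * J), n))
  state_found <- rep(NA_character_, n)
  done <- rep(FALSE, n)
  for (j in J:1) {                       # oldest round first
    mj <- first_due - j * iv
    ok <- part & !done & mj >= era & mj >= invite & mj < cutoff
    if (!any(ok)) next
    idx <- which(ok)
    st <- state_fn(idx, mj[idx])
    p <- det[st]
    p[is.na(p)] <- 0
    hit <- idx[u[cbind(idx, j)] < p]
    if (length(hit)) {
      done[hit] <- TRUE
      state_found[hit] <- st[match(hit, idx)]
    }
  }
  state_found
}

# signed attendance-delay draws: on-schedule rounds attend in the due
# month; off-schedule rounds run late (1 + geometric, capped at 12
# months) or, for a fraction of rounds, up to three months early
delay_matrix <- function(n, K, mean_delay, early_frac) {
  if (is.null(early_frac)) early_frac <- 0.35
  late <- pmin(1L + stats::rgeom(n * K, 1 / mean_delay), 12L)
  dir <- stats::runif(n * K)
  early <- -pmin(1L + stats::rgeom(n * K, 0.5), 3L)
  matrix(as.integer(ifelse(dir < early_frac, early, late)), n)
}

# ---------------------------------------------------------------- breast

simulate_breast_engine <- function(cohort, scenario, config, params, seed,
                                   horizon) {
  start <- horizon[1]; end <- horizon[2]
  n <- nrow(cohort)
  traj <- draw_trajectories(cohort, params, seed, start, end)
  sched <- build_capacity_schedule(scenario, horizon)
  mult <- sched$multiplier
  interval <- config$interval
  K <- as.integer(ceiling((end - start) / interval) + 4L)

  dr <- with_substream(seed, "breast_screening", {
    list(
      u_on = matrix(stats::runif(n * K), n),
      d_extra = delay_matrix(n, K, cohort$mean_delay, cohort$early_frac),
      u_test = matrix(stats::runif(n * K), n),
      u_fp = matrix(stats::runif(n * K), n),
      stagger = as.integer(floor(stats::runif(n) * interval)),
      e_opp = stats::rexp(n)
    )
  })

  part <- cohort$participant & !is.na(cohort$participant)
  birth <- cohort$birth_month
  invite_month <- birth + config$invitation_age * 12L
  first_due <- pmax(start + dr$stagger, invite_month)
  newly_invited0 <- invite_month > start       # first-ever round in-sim
  # synthetic pre-sim screen for existing clients anchors interval stats
  last_screen <- ifelse(part & !newly_invited0,
                        first_due - interval, NA_integer_)

  round_i <- rep(1L, n)
  delay1 <- ifelse(dr$u_on[cbind(1:n, 1L)] < cohort$on_schedule, 0L,
                   dr$d_extra[cbind(1:n, 1L)])
  due <- ifelse(part, first_due, NA_integer_)
  attend <- pmax(due + delay1, start)
  sched_month <- due                            # originally scheduled month
  diagnosed <- rep(FALSE, n)

  # anyone whose cancer presented clinically before the simulation start
  # is a prevalent survivor, not a new case
  diagnosed[traj$t_clin < start] <- TRUE
  due[diagnosed] <- NA_integer_; attend[diagnosed] <- NA_integer_

  breast_state <- function(idx, m) {
    ifelse(traj$t_onset[idx] <= m,
           ifelse(m < traj$t_large[idx], "small", "large"), "healthy")
  }
  sf <- presim_screening(cohort, config, seed, start, first_due,
                         breast_state)
  pre_dx <- !is.na(sf)
  diagnosed[pre_dx] <- TRUE
  due[pre_dx] <- NA_integer_; attend[pre_dx] <- NA_integer_
  # non-participants: account for pre-start opportunistic exposure of
  # prevalent preclinical disease (memoryless clock, so thinning is exact)
  opp_cum <- rep(0, n)
  prev_np <- which(!part & traj$t_onset < start & start < traj$t_clin)
  if (length(prev_np)) {
    sz <- ifelse(start < traj$t_large[prev_np], config$sensitivity$small,
                 config$sensitivity$large)
    opp_cum[prev_np] <- config$opportunistic_rate * sz *
      (start - pmax(traj$t_onset[prev_np], start - 240))
    gone <- prev_np[opp_cum[prev_np] >= dr$e_opp[prev_np]]
    diagnosed[gone] <- TRUE
  }

  m_clin <- floor(traj$t_clin)   # Inf for never-presenting
  pause_on <- !is_null_scenario(scenario) && scenario$mode == "pause"
  ps <- scenario$pause_start
  pe <- ps + scenario$duration
  ramp_end <- pe + scenario$ramp_months
  # status quo demand, measured from this run's own pre-pause throughput
  # (the twelve months before the pause are scenario-free by construction)
  base_capacity <- NA_integer_
  monthly_screens <- integer(end - start)
  queue <- tibble::tibble(id = integer(), age = numeric(),
                          newly_invited = logical(), period = character(),
                          scheduled_month = integer())
  queue_retired <- !pause_on
  events <- vector("list", 4L * (end - start))
  ei <- 0L
  add <- function(x) {
    ei <<- ei + 1L
    if (ei > length(events)) length(events) <<- 2L * length(events)
    events[[ei]] <<- x
  }

  dx_breast <- function(ids, month, tmonth, mode) {
    size <- ifelse(tmonth < traj$t_large[ids], "small", "large")
    add(ev(cohort$id[ids], month, "diagnosis", stage = size, mode = mode,
           nodal = traj$t_nodal[ids] <= tmonth, grade3 = traj$grade3[ids]))
  }

  do_screens <- function(idx, m, scheduled) {
    # idx: row indices screened this month; scheduled: their booked months
    state <- ifelse(traj$t_onset[idx] <= m,
                    ifelse(m < traj$t_large[idx], "small", "large"),
                    "healthy")
    k <- cbind(idx, pmin(round_i[idx], K))
    res <- perform_screen(state, config, m, dr$u_test[k], dr$u_fp[k])
    add(ev(cohort$id[idx], m, "screen", modality = "mammogram",
           outcome = res$outcome, routine = TRUE,
           scheduled_month = scheduled))
    recalled <- res$outcome != "negative"
    if (any(recalled)) {
      cancer <- res$outcome == "detected-cancer"
      add(ev(cohort$id[idx[recalled]], m, "assessment",
             outcome = ifelse(cancer[recalled], "cancer", "benign")))
      if (any(cancer)) {
        ci <- idx[cancer]
        dx_breast(ci, m, m, "screen")
        diagnosed[ci] <<- TRUE
      }
    }
    monthly_screens[m - start + 1L] <<- monthly_screens[m - start + 1L] +
      length(idx)
    last_screen[idx] <<- m
    round_i[idx] <<- round_i[idx] + 1L
    nxt <- next_anchor(scheduled, m, interval)
    keep <- !diagnosed[idx] & (nxt - birth[idx]) / 12 <= config$age_range[2] + 1 &
      nxt < end
    due[idx] <<- ifelse(keep, nxt, NA_integer_)
    k2 <- cbind(idx, pmin(round_i[idx], K))
    d2 <- ifelse(dr$u_on[k2] < cohort$on_schedule[idx], 0L, dr$d_extra[k2])
    attend[idx] <<- due[idx] + d2
    sched_month[idx] <<- due[idx]
  }

  for (m in seq.int(start, end - 1L)) {
    mi <- m - start + 1L
    # symptomatic presentation first: a symptomatic woman is diagnosed
    # clinically, not screened
    pres <- which(!diagnosed & m_clin == m)
    if (length(pres)) {
      dx_breast(pres, m, traj$t_clin[pres], "symptomatic")
      diagnosed[pres] <- TRUE
    }
    # opportunistic (off-programme) detection among non-participants
    opp <- which(!part & !diagnosed & traj$t_onset <= m & m < traj$t_clin)
    if (length(opp)) {
      sz_small <- m < traj$t_large[opp]
      h <- config$opportunistic_rate * opportunistic_modifier(scenario, m) *
        ifelse(sz_small, config$sensitivity$small, config$sensitivity$large)
      opp_cum[opp] <- opp_cum[opp] + h
      hit <- opp[opp_cum[opp] >= dr$e_opp[opp]]
      if (length(hit)) {
        dx_breast(hit, m, m, "opportunistic")
        diagnosed[hit] <- TRUE
      }
    }
    due_now <- which(!diagnosed & !is.na(attend) & attend == m)
    if (!queue_retired && m >= ps && is.na(base_capacity)) {
      lookback <- seq.int(max(1L, ps - start - 11L), ps - start)
      base_capacity <- round(mean(monthly_screens[lookback]))
    }
    if (!queue_retired && m >= ps) {
      # booking requests accumulate; capacity-constrained allocation
      if (length(due_now)) {
        queue <- dplyr::bind_rows(queue, tibble::tibble(
          id = due_now,                        # row index; ids match here
          age = (m - birth[due_now]) / 12,
          newly_invited = is.na(last_screen[due_now]),
          period = if (m < pe) "pause" else "recovery",
          scheduled_month = sched_month[due_now]
        ))
      }
      queue <- queue[!diagnosed[queue$id], , drop = FALSE]
      alloc <- allocate(queue, mult[mi], m, base_capacity)
      queue <- alloc$carried[, c("id", "age", "newly_invited", "period",
                                 "scheduled_month")]
      if (nrow(alloc$booked)) {
        do_screens(alloc$booked$id, m, alloc$booked$scheduled_month)
      }
      if (m >= ramp_end && nrow(queue) == 0) queue_retired <- TRUE
    } else if (length(due_now)) {
      do_screens(due_now, m, sched_month[due_now])
    }
  }
  new_run("breast", cohort, dplyr::bind_rows(events[seq_len(ei)]) |>
            dplyr::arrange(.data$id, .data$month),
          scenario, config, params, seed, horizon, base_capacity)
}

# ----------------------------------------------------------------- bowel

simulate_bowel_engine <- function(cohort, scenario, config, params, seed,
                                  horizon) {
  start <- horizon[1]; end <- horizon[2]
  n <- nrow(cohort)
  traj <- draw_trajectories(cohort, params, seed, start, end)
  interval <- config$interval
  K <- as.integer(ceiling((end - start) / interval) + 6L)

  dr <- with_substream(seed, "bowel_screening", {
    list(
      u_on = matrix(stats::runif(n * K), n),
      d_extra = delay_matrix(n, K, cohort$mean_delay, cohort$early_frac),
      u_test = matrix(stats::runif(n * K), n),
      u_fp = matrix(stats::runif(n * K), n),
      u_col = matrix(stats::runif(n * K), n),
      stagger = as.integer(floor(stats::runif(n) * interval)),
      u_surv = stats::runif(n),
      u_drop = stats::runif(n),
      surv_stagger = as.integer(floor(stats::runif(n) *
                                        config$surveillance_interval)),
      ret_stagger = as.integer(floor(stats::runif(n) *
                                       config$return_interval)),
      death = if (!is.null(params$background_mortality_rate) &&
                  params$background_mortality_rate > 0) {
        start + stats::rexp(n, params$background_mortality_rate)
      } else rep(Inf, n)
    )
  })

  part <- cohort$participant & !is.na(cohort$participant)
  birth <- cohort$birth_month
  invite_month <- birth + config$invitation_age * 12L
  first_due <- pmax(start + dr$stagger, invite_month)

  # effective (intervention-modifiable) trajectory times
  t_crc <- traj$t_crc; t_34 <- traj$t_34; t_clin <- traj$t_clin
  aden_present0 <- traj$t_adenoma
  aden_removed <- rep(FALSE, n)

  in_surv <- part & dr$u_surv < config$surveillance_init
  pend_col <- ifelse(in_surv, start + dr$surv_stagger, NA_integer_)
  col_kind <- ifelse(in_surv, "surveillance", NA_character_)
  # participants whose pre-sim positive kit led to a clear colonoscopy
  # re-enter routine screening on the 4-year return schedule
  in_ret <- part & !in_surv &
    dr$u_surv < config$surveillance_init + config$return_init
  first_due[in_ret] <- start + dr$ret_stagger[in_ret]

  round_i <- rep(1L, n)
  due <- ifelse(part & !in_surv, first_due, NA_integer_)
  d1 <- ifelse(dr$u_on[cbind(1:n, 1L)] < cohort$on_schedule, 0L,
               dr$d_extra[cbind(1:n, 1L)])
  attend <- pmax(due + d1, start)
  sched_month <- due
  diagnosed <- rep(FALSE, n)
  dead <- rep(FALSE, n)
  # clinical presentation before the simulation start: prevalent survivor
  pre_clin <- is.finite(traj$t_clin) & traj$t_clin < start
  diagnosed[pre_clin] <- TRUE
  due[pre_clin] <- NA_integer_; attend[pre_clin] <- NA_integer_
  pend_col[pre_clin] <- NA_integer_

  pause_on <- !is_null_scenario(scenario) && scenario$mode == "pause" &&
    scenario$duration > 0
  ps <- scenario$pause_start; pe <- ps + scenario$duration
  events <- vector("list", 5L * (end - start)); ei <- 0L
  add <- function(x) {
    ei <<- ei + 1L
    if (ei > length(events)) length(events) <<- 2L * length(events)
    events[[ei]] <<- x
  }

  crc_state <- function(idx, m) {
    ifelse(t_crc[idx] <= m & !aden_removed[idx],
           ifelse(m < t_34[idx], "crc_12", "crc_34"),
           ifelse(traj$t_adenoma[idx] <= m & m < traj$t_adenoma_end[idx] &
                    !aden_removed[idx], "adenoma", "healthy"))
  }
  schedule_next <- function(idx, from, months) {
    nxt <- as.integer(from + months)
    keep <- !diagnosed[idx] & !dead[idx] &
      (nxt - birth[idx]) / 12 <= config$age_range[2] + 1 & nxt < end
    due[idx] <<- ifelse(keep, nxt, NA_integer_)
    k <- cbind(idx, pmin(round_i[idx], K))
    d <- ifelse(dr$u_on[k] < cohort$on_schedule[idx], 0L, dr$d_extra[k])
    attend[idx] <<- due[idx] + d
    sched_month[idx] <<- due[idx]
  }

  sf <- presim_screening(cohort, config, seed, start, first_due, crc_state)
  pre_aden <- !is.na(sf) & sf == "adenoma"
  aden_removed[pre_aden] <- TRUE
  pre_dx <- !is.na(sf) & sf %in% c("crc_12", "crc_34")
  diagnosed[pre_dx] <- TRUE
  due[pre_dx] <- NA_integer_; attend[pre_dx] <- NA_integer_
  pend_col[pre_dx] <- NA_integer_

  for (m in seq.int(start, end - 1L)) {
    in_pause <- pause_on && m >= ps && m < pe
    newly_dead <- which(!dead & dr$death <= m)
    if (length(newly_dead)) {
      dead[newly_dead] <- TRUE
      due[newly_dead] <- NA_integer_; attend[newly_dead] <- NA_integer_
      pend_col[newly_dead] <- NA_integer_
    }
    pres <- which(!diagnosed & !dead & !aden_removed &
                    floor(t_clin) == m)
    # adenoma removal cancels cancers that had not yet begun
    if (length(pres)) {
      stage <- ifelse(m < t_34[pres], "1-2", "3-4")
      add(ev(cohort$id[pres], m, "diagnosis", stage = stage,
             mode = "symptomatic"))
      diagnosed[pres] <- TRUE
    }
    # colonoscopies (follow-up and surveillance); halted during the pause
    if (!in_pause) {
      ci <- which(!diagnosed & !dead & !is.na(pend_col) & pend_col <= m)
      if (length(ci)) {
        st <- crc_state(ci, m)
        add(ev(cohort$id[ci], m, "colonoscopy",
               outcome = dplyr::case_match(st, "adenoma" ~ "adenoma",
                                           "crc_12" ~ "cancer",
                                           "crc_34" ~ "cancer",
                                           .default = "clear"),
               mode = col_kind[ci]))
        canc <- ci[st %in% c("crc_12", "crc_34")]
        if (length(canc)) {
          add(ev(cohort$id[canc], m, "diagnosis",
                 stage = ifelse(m < t_34[canc], "1-2", "3-4"),
                 mode = "screen"))
          diagnosed[canc] <- TRUE
        }
        aden <- ci[st == "adenoma"]
        if (length(aden)) {
          aden_removed[aden] <- TRUE
          pend_col[aden] <- m + config$surveillance_interval
          col_kind[aden] <- "surveillance"
          due[aden] <- NA_integer_; attend[aden] <- NA_integer_
        }
        clear <- ci[st == "healthy"]
        if (length(clear)) {
          pend_col[clear] <- NA_integer_
          round_i[clear] <- round_i[clear] + 1L
          schedule_next(clear, m, config$return_interval)
        }
      }
    }
    # iFOBT kits returned; none sent or processed during the pause
    due_now <- which(!diagnosed & !dead & !is.na(attend) & attend == m)
    if (length(due_now)) {
      if (in_pause) {
        attend[due_now] <- reschedule_missed(scenario, rep(m, length(due_now)))
        sched_month[due_now] <- attend[due_now]
        # lasting behavioural effect: some people whose round was
        # cancelled by the pause do not return to screening
        p_drop <- scenario$missed_round_dropout
        if (!is.null(p_drop) && p_drop > 0) {
          drop <- due_now[dr$u_drop[due_now] < p_drop]
          if (length(drop)) {
            due[drop] <- NA_integer_
            attend[drop] <- NA_integer_
          }
        }
      } else {
        st <- crc_state(due_now, m)
        k <- cbind(due_now, pmin(round_i[due_now], K))
        res <- perform_screen(st, config, m, dr$u_test[k], dr$u_fp[k])
        add(ev(cohort$id[due_now], m, "screen", modality = "iFOBT",
               outcome = res$outcome, routine = TRUE,
               scheduled_month = sched_month[due_now]))
        pos <- res$outcome != "negative"
        round_i[due_now] <- round_i[due_now] + 1L
        if (any(pos)) {
          pi <- due_now[pos]
          fu <- resolve_followup(res$outcome[pos], config, m,
                                 u = dr$u_col[cbind(pi, pmin(round_i[pi], K))])
          comp <- fu$completes
          if (any(comp)) {
            pend_col[pi[comp]] <- fu$followup_month[comp]
            col_kind[pi[comp]] <- "followup"
            due[pi[comp]] <- NA_integer_; attend[pi[comp]] <- NA_integer_
          }
          if (any(!comp)) {
            schedule_next(pi[!comp], sched_month[pi[!comp]], interval)
          }
        }
        neg <- due_now[!pos]
        if (length(neg)) schedule_next(neg, sched_month[neg], interval)
      }
    }
  }
  new_run("bowel", cohort, dplyr::bind_rows(events[seq_len(ei)]) |>
            dplyr::arrange(.data$id, .data$month),
          scenario, config, params, seed, horizon)
}

# ---------------------------------------------------------------- cervix

simulate_cervix_engine <- function(cohort, scenario, config, params, seed,
                                   horizon) {
  start <- horizon[1]; end <- horizon[2]
  n <- nrow(cohort)
  traj <- draw_trajectories(cohort, params, seed, start, end)
  K <- 10L
  dr <- with_substream(seed, "cervix_screening", {
    list(
      u_on = matrix(stats::runif(n * K), n),
      d_extra = delay_matrix(n, K, cohort$mean_delay, cohort$early_frac),
      u_test = matrix(stats::runif(n * K), n),
      u_fp = matrix(stats::runif(n * K), n),
      u_attend = matrix(stats::runif(n * K), n),
      u_resched = stats::runif(n),
      u_surv = stats::runif(n),
      surv_stagger = as.integer(floor(stats::runif(n) *
                                        config$surveillance_interval))
    )
  })
  part <- cohort$participant & !is.na(cohort$participant)
  birth <- cohort$birth_month
  trans <- part & cohort$hpv_transitioned
  t_loc <- traj$t_loc; t_clin <- traj$t_clin
  treated <- rep(FALSE, n)

  in_surv <- part & dr$u_surv < config$surveillance_init
  # routine due month under the renewal transition rules
  hist0 <- tibble::tibble(
    birth_month = birth,
    last_screen_month = NA_integer_,
    hpv_transitioned = cohort$hpv_transitioned,
    first_hpv_month = cohort$first_hpv_month,
    last_cytology_month = cohort$last_cytology_month
  )
  due0 <- rep(NA_integer_, n)
  ref <- attr(cohort, "spec")$reference_month
  if (is.null(ref)) ref <- ym(2020, 1)
  age_ref <- (ref - birth) / 12
  of_age <- part & age_ref >= config$age_range[1] &
    age_ref <= config$age_range[2] + 1
  due0[of_age] <- due_date(hist0[of_age, ], config, ref)
  # women still below the invitation age are invited at 25; women already
  # beyond the eligible ages have no further routine screens
  young <- part & age_ref < config$age_range[1]
  due0[young] <- birth[young] + config$invitation_age * 12L
  # transitioned women whose first HPV test falls inside the horizon
  # attend it in-sim; before that they have no routine visit
  due0[trans & cohort$first_hpv_month >= start] <-
    cohort$first_hpv_month[trans & cohort$first_hpv_month >= start]
  due0[in_surv] <- NA_integer_

  round_i <- rep(1L, n)
  due <- due0
  d1 <- ifelse(dr$u_on[cbind(1:n, 1L)] < cohort$on_schedule, 0L,
               dr$d_extra[cbind(1:n, 1L)])
  attend <- pmax(due + d1, start)
  sched_month <- due
  surv_next <- ifelse(in_surv, start + dr$surv_stagger, NA_integer_)
  diagnosed <- rep(FALSE, n)
  events <- vector("list", 5L * (end - start)); ei <- 0L
  add <- function(x) {
    ei <<- ei + 1L
    if (ei > length(events)) length(events) <<- 2L * length(events)
    events[[ei]] <<- x
  }

  cx_state <- function(idx, m) {
    ifelse(treated[idx], "healthy",
    ifelse(t_loc[idx] <= m,
           ifelse(m < traj$t_reg[idx], "localised",
                  ifelse(m < traj$t_dist[idx], "regional", "distant")),
    ifelse(traj$t_cin[idx] <= m & m < traj$t_cin_end[idx], "cin",
    ifelse(traj$t_hpv[idx] <= m & m < traj$t_hpv_end[idx], "hpv",
           "healthy"))))
  }
  schedule_routine <- function(idx, from) {
    nxt <- as.integer(from + config$interval)
    keep <- !diagnosed[idx] & (nxt - birth[idx]) / 12 <= config$age_range[2] + 1 &
      nxt < end
    due[idx] <<- ifelse(keep, nxt, NA_integer_)
    k <- cbind(idx, pmin(round_i[idx], K))
    d <- ifelse(dr$u_on[k] < cohort$on_schedule[idx], 0L, dr$d_extra[k])
    attend[idx] <<- due[idx] + d
    sched_month[idx] <<- due[idx]
  }

  pre_clin <- is.finite(traj$t_clin) & traj$t_clin < start
  diagnosed[pre_clin] <- TRUE
  due[pre_clin] <- NA_integer_; attend[pre_clin] <- NA_integer_
  surv_next[pre_clin] <- NA_integer_

  cyt_anchor <- as.integer(ifelse(trans, cohort$first_hpv_month,
                                  cohort$last_cytology_month + 24L))
  cyt_anchor[is.na(cyt_anchor)] <- start
  sf <- presim_screening(cohort, config, seed, start, cyt_anchor, cx_state,
                         cutoff = ifelse(trans, cohort$first_hpv_month,
                                         ym(2020, 1)))
  pre_treat <- !is.na(sf) & sf %in% c("hpv", "cin")
  treated[pre_treat] <- TRUE
  pre_dx <- !is.na(sf) & sf %in% c("localised", "regional", "distant")
  diagnosed[pre_dx] <- TRUE
  due[pre_dx] <- NA_integer_; attend[pre_dx] <- NA_integer_
  surv_next[pre_dx] <- NA_integer_

  do_tests <- function(idx, m, routine) {
    st <- cx_state(idx, m)
    k <- cbind(idx, pmin(round_i[idx], K))
    res <- perform_screen(st, config, m, dr$u_test[k], dr$u_fp[k])
    add(ev(cohort$id[idx], m, "screen", modality = "HPV test",
           outcome = res$outcome, routine = routine,
           scheduled_month = sched_month[idx]))
    round_i[idx] <<- round_i[idx] + 1L
    pos <- res$outcome != "negative"
    if (any(pos)) {
      pi <- idx[pos]; stp <- st[pos]
      add(ev(cohort$id[pi], m, "colposcopy",
             outcome = dplyr::case_match(stp, "cin" ~ "cin",
                                         "localised" ~ "cancer",
                                         "regional" ~ "cancer",
                                         "distant" ~ "cancer",
                                         .default = "clear")))
      canc <- pi[stp %in% c("localised", "regional", "distant")]
      if (length(canc)) {
        add(ev(cohort$id[canc], m, "diagnosis",
               stage = stage_at_event(traj[canc, ], m), mode = "screen"))
        diagnosed[canc] <<- TRUE
      }
      cin <- pi[stp == "cin"]
      if (length(cin)) treated[cin] <<- TRUE    # excision prevents progression
      fup <- setdiff(pi, canc)
      if (length(fup)) {
        surv_next[fup] <<- m + config$surveillance_interval
        due[fup] <<- NA_integer_; attend[fup] <<- NA_integer_
      }
    }
    neg <- idx[!pos]
    if (length(neg)) {
      surv_next[neg] <<- NA_integer_
      schedule_routine(neg, m)
    }
  }

  for (m in seq.int(start, end - 1L)) {
    pres <- which(!diagnosed & !treated & floor(t_clin) == m)
    if (length(pres)) {
      add(ev(cohort$id[pres], m, "diagnosis",
             stage = stage_at_event(traj[pres, ], t_clin[pres]),
             mode = "symptomatic"))
      diagnosed[pres] <- TRUE
    }
    # surveillance / follow-up testing: unaffected by the disruption
    sv <- which(!diagnosed & !is.na(surv_next) & surv_next == m)
    if (length(sv)) do_tests(sv, m, routine = FALSE)
    # routine primary screening, subject to the attendance reduction
    due_now <- which(!diagnosed & !is.na(attend) & attend == m)
    if (length(due_now)) {
      mod <- attendance_modifier(scenario, m, "routine")
      k <- cbind(due_now, pmin(round_i[due_now], K))
      attends <- dr$u_attend[k] < mod
      miss <- due_now[!attends]
      if (length(miss)) {
        attend[miss] <- reschedule_missed(scenario, rep(m, length(miss)),
                                          u = dr$u_resched[miss])
        sched_month[miss] <- attend[miss]
      }
      go <- due_now[attends]
      if (length(go)) do_tests(go, m, routine = TRUE)
    }
  }
  new_run("cervix", cohort, dplyr::bind_rows(events[seq_len(ei)]) |>
            dplyr::arrange(.data$id, .data$month),
          scenario, config, params, seed, horizon)
}
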