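# Reported metrics: detection-mode classification, interval cancers and
# programme sensitivity, stage-shift (upstaging) attribution, outcome
# tables against the paired status quo, and diagnostic service demand.

#' Classify each diagnosis by detection mode
#'
#' Screen-detected diagnoses result from a screening/assessment chain.
#' Non-screen-detected diagnoses are interval cancers when they occur
#' within 12 (or 27) months of a negative screening episode, and "other"
#' otherwise (e.g. never-screened individuals).
#'
#' @param events Event-log tibble from a run.
#' @return Tibble with one row per diagnosis: `id`, `month`, `stage`,
#'   `mode` ("screen-detected", "interval", "other"),
#'   `months_since_negative` and window flags `interval_12`,
#'   `interval_27` (an interval-12 cancer is always also interval-27).
#' @export
classify_detection_mode <- function(events) {
  dx <- dplyr::filter(events, .data$type == "diagnosis")
  if (nrow(dx) == 0) {
    return(tibble::tibble(id = integer(), month = integer(),
                          stage = character(), mode = character(),
                          months_since_negative = numeric(),
                          interval_12 = logical(), interval_27 = logical()))
  }
  negs <- events |>
    dplyr::filter(.data$type == "screen", .data$outcome == "negative") |>
    dplyr::select(id, neg_month = "month")
  last_neg <- dx |>
    dplyr::select("id", dx_month = "month") |>
    dplyr::inner_join(negs, by = "id", relationship = "many-to-many") |>
    dplyr::filter(.data$neg_month < .data$dx_month) |>
    dplyr::group_by(.data$id, .data$dx_month) |>
    dplyr::summarise(neg_month = max(.data$neg_month), .groups = "drop")
  out <- dx |>
    dplyr::left_join(last_neg, by = c("id", month = "dx_month")) |>
    dplyr::mutate(
      months_since_negative = .data$month - .data$neg_month,
      screen_detected = .data$mode == "screen",
      interval_12 = !.data$screen_detected &
        !is.na(.data$months_since_negative) &
        .data$months_since_negative <= 12,
      interval_27 = !.data$screen_detected &
        !is.na(.data$months_since_negative) &
        .data$months_since_negative <= 27,
      mode = dplyr::case_when(
        screen_detected ~ "screen-detected",
        interval_27 ~ "interval",
        .default = "other"
      )
    ) |>
    dplyr::select("id", "month", "stage", "mode", "months_since_negative",
                  "interval_12", "interval_27")
  out
}

#' Programme sensitivity
#'
#' Screen-detected cancers as a percentage of screen-detected plus
#' interval (27-month) cancers.
#'
#' @param screen_detected,interval_27 Non-negative counts.
#' @return Percentage; `NA` with a warning if both counts are zero.
#' @export
programme_sensitivity <- function(screen_detected, interval_27) {
  stopifnot(screen_detected >= 0, interval_27 >= 0)
  if (screen_detected + interval_27 == 0) {
    warning("programme sensitivity undefined: no screen-detected or interval cancers")
    return(NA_real_)
  }
  100 * screen_detected / (screen_detected + interval_27)
}

#' Attribute stage shift between a scenario and its status quo
#'
#' Excess-flow bookkeeping over per-stage diagnosis counts summed across
#' the reporting window: (1) the excess in total cancers is attributed to
#' additional cancers diagnosed at the earliest stage; (2) any increase
#' in the latest stage is attributed to upstaging from the stage below;
#' (3) residual changes in the lower stages are attributed to upstaging
#' one step up. Supports the invasive cervical stage ladder
#' (localised/regional/distant) and the grouped CRC ladder ("1-2"/"3-4").
#'
#' @param status_quo,scenario Tibbles with columns `stage` and `count`
#'   (an optional `year` column is summed over).
#' @param window Character label stored on the record (e.g.
#'   "2020-2022").
#' @return One-row tibble: the shift counts, the additional-cancer
#'   excess, `affected` (additional + upstaged), and `pct_upstaged`
#'   (upstaged as % of status quo cases).
#' @export
upstaging_attribution <- function(status_quo, scenario, window = NA_character_) {
  agg <- function(x) {
    x |>
      dplyr::group_by(.data$stage) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  sq <- agg(status_quo); sc <- agg(scenario)
  if (!setequal(sq$stage, sc$stage)) {
    stop("stage sets differ between the two tables", call. = FALSE)
  }
  ladders <- list(c("localised", "regional", "distant"), c("1-2", "3-4"))
  ladder <- ladders[[which(vapply(ladders, setequal, TRUE, y = sq$stage))]]
  d <- vapply(ladder, function(s) {
    sc$count[sc$stage == s] - sq$count[sq$stage == s]
  }, numeric(1))
  excess <- sum(d)
  if (length(ladder) == 3) {
    reg_to_dist <- max(d[[3]], 0)
    loc_to_reg <- max(d[[2]] + reg_to_dist, 0)
  } else {
    reg_to_dist <- 0
    loc_to_reg <- max(d[[2]], 0)   # 1-2 -> 3-4 advance
  }
  upstaged <- loc_to_reg + reg_to_dist
  tibble::tibble(
    window = window,
    loc_to_reg = loc_to_reg,
    reg_to_dist = reg_to_dist,
    additional = excess,
    affected = excess + upstaged,
    pct_upstaged = 100 * upstaged / sum(sq$count)
  )
}

window_count <- function(events, type, window, ...) {
  dots <- rlang::enquos(...)
  x <- dplyr::filter(events, .data$type == !!type,
                     .data$month >= window[1], .data$month < window[2])
  if (length(dots)) x <- dplyr::filter(x, !!!dots)
  nrow(x)
}

#' Per-stage diagnosis counts by calendar year
#' @param run A `disruption_run`.
#' @param years Calendar years to include.
#' @return Tibble with `year`, `stage`, `count` (all combinations,
#'   zero-filled).
#' @export
stage_year_table <- function(run, years) {
  dx <- dplyr::filter(run$events, .data$type == "diagnosis")
  stages <- switch(run$programme,
    cervix = c("localised", "regional", "distant"),
    bowel = c("1-2", "3-4"),
    breast = c("small", "large")
  )
  dx |>
    dplyr::mutate(year = ym_year(.data$month)) |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::count(.data$year, .data$stage, name = "count") |>
    tidyr::complete(year = years, stage = stages,
                    fill = list(count = 0L)) |>
    dplyr::filter(.data$stage %in% stages)
}

run_metrics <- function(run) {
  ev <- run$events
  n <- run$n
  per100k <- function(x) 1e5 * x / n
  screens_w <- c(ym(2020, 4), ym(2021, 4))   # 1 Apr 2020 - 31 Mar 2021
  if (run$programme == "breast") {
    w <- c(ym(2020, 1), ym(2022, 1))
    cls <- classify_detection_mode(ev)
    dxw <- dplyr::filter(cls, .data$month >= w[1], .data$month < w[2])
    dx_rows <- dplyr::filter(ev, .data$type == "diagnosis",
                             .data$month >= w[1], .data$month < w[2])
    sd_n <- sum(dxw$mode == "screen-detected")
    ic27 <- sum(dxw$interval_27)
    ic12 <- sum(dxw$interval_12 & ym_year(dxw$month) == 2020)
    scr20 <- window_count(ev, "screen", w)
    recalls <- window_count(ev, "assessment", w)
    benign <- window_count(ev, "assessment", w, .data$outcome == "benign")
    c(screens_provided = window_count(ev, "screen", screens_w),
      dx_per_100k = per100k(nrow(dxw)),
      screen_detected_per_100k = per100k(sd_n),
      interval_12_per_100k = per100k(ic12),
      interval_27_per_100k = per100k(ic27),
      programme_sensitivity = if (sd_n + ic27 > 0)
        programme_sensitivity(sd_n, ic27) else NA_real_,
      pct_small = 100 * mean(dx_rows$stage == "small"),
      pct_nodal = 100 * mean(dx_rows$nodal),
      pct_grade3 = 100 * mean(dx_rows$grade3),
      recall_rate = 100 * recalls / max(scr20, 1),
      fp_recall_rate = 100 * benign / max(scr20, 1))
  } else if (run$programme == "bowel") {
    w <- c(ym(2020, 1), ym(2022, 1))
    dx <- dplyr::filter(ev, .data$type == "diagnosis",
                        .data$month >= w[1], .data$month < w[2])
    c(screens_provided = window_count(ev, "screen", screens_w),
      crc_diagnoses = nrow(dx),
      crc_per_100k = per100k(nrow(dx)),
      pct_stage_34 = 100 * mean(dx$stage == "3-4"),
      colonoscopies = window_count(ev, "colonoscopy", w),
      colonoscopies_followup = window_count(ev, "colonoscopy", w,
                                            .data$mode == "followup"),
      colonoscopies_surveillance = window_count(ev, "colonoscopy", w,
                                                .data$mode == "surveillance"))
  } else {
    w <- c(ym(2020, 1), ym(2023, 1))
    dx <- dplyr::filter(ev, .data$type == "diagnosis",
                        .data$month >= w[1], .data$month < w[2])
    c(screens_provided = window_count(ev, "screen", screens_w),
      cancer_diagnoses = nrow(dx),
      colposcopies = window_count(ev, "colposcopy", c(ym(2020, 1), ym(2022, 1))),
      colposcopies_2020 = window_count(ev, "colposcopy",
                                       c(ym(2020, 1), ym(2021, 1))))
  }
}

#' Tabulate scenario outcomes against the paired status quo
#'
#' Computes the reporting metrics for both runs of a seed-paired pair and
#' returns them side by side with absolute and percentage changes. Count
#' metrics are also rescaled to national scale using the cohort scale
#' factor. Screens-provided rows cover 1 April 2020 - 31 March 2021;
#' diagnosis windows are programme-specific (breast and bowel 2020-2021,
#' cervix 2020-2022). For the cervical and bowel pairs the stage-shift
#' attribution of [upstaging_attribution()] is appended.
#'
#' @param paired A `paired_runs` object from [run_paired()].
#' @return A tibble: `programme`, `metric`, `status_quo`, `scenario`,
#'   `change`, `pct_change`, `status_quo_rescaled`, `scenario_rescaled`.
#' @export
tabulate_outcomes <- function(paired) {
  sq <- paired$status_quo; sc <- paired$scenario
  if (sq$programme != sc$programme || !identical(sq$seed, sc$seed)) {
    stop("runs are not a seed-paired pair", call. = FALSE)
  }
  m_sq <- run_metrics(sq); m_sc <- run_metrics(sc)
  rescale <- function(metric, value) {
    ifelse(grepl("per_100k|pct_|rate|sensitivity", metric), value,
           value / sq$scale)
  }
  out <- tibble::tibble(
    programme = sq$programme,
    metric = names(m_sq),
    status_quo = unname(m_sq),
    scenario = unname(m_sc)
  ) |>
    dplyr::mutate(
      change = .data$scenario - .data$status_quo,
      pct_change = 100 * .data$change / .data$status_quo,
      status_quo_rescaled = rescale(.data$metric, .data$status_quo),
      scenario_rescaled = rescale(.data$metric, .data$scenario)
    )
  if (sq$programme %in% c("cervix", "bowel")) {
    years <- if (sq$programme == "cervix") 2020:2022 else 2020:2021
    up <- upstaging_attribution(stage_year_table(sq, years),
                                stage_year_table(sc, years),
                                paste(range(years), collapse = "-"))
    out <- dplyr::bind_rows(out, tibble::tibble(
      programme = sq$programme,
      metric = c("upstaged_low_to_high", "upstaged_mid_to_distant",
                 "pct_upstaged"),
      status_quo = c(0, 0, 0),
      scenario = c(up$loc_to_reg, up$reg_to_dist, up$pct_upstaged),
      change = .data$scenario, pct_change = NA_real_,
      status_quo_rescaled = 0,
      scenario_rescaled = ifelse(.data$metric == "pct_upstaged",
                                 .data$scenario, .data$scenario / sq$scale)
    ))
  }
  out
}

#' Diagnostic service volumes in a period
#'
#' Counts follow-up colonoscopies, surveillance colonoscopies, their sum
#' (programme-related colonoscopies), colposcopies, and breast
#' assessments.
#'
#' @param events Event-log tibble.
#' @param window `c(start, end)` month indices (end exclusive).
#' @return One-row tibble of service counts.
#' @export
demand_summary <- function(events, window) {
  fu <- window_count(events, "colonoscopy", window, .data$mode == "followup")
  sv <- window_count(events, "colonoscopy", window,
                     .data$mode == "surveillance")
  tibble::tibble(
    colonoscopies_followup = fu,
    colonoscopies_surveillance = sv,
    colonoscopies_programme = fu + sv,
    colposcopies = window_count(events, "colposcopy", window),
    breast_assessments = window_count(events, "assessment", window)
  )
}

# ------------------------------------------------------- broom + ggplot2

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation run into its event log
#' @param x A `disruption_run`.
#' @param ... Unused.
#' @return The event-log tibble.
#' @export
tidy.disruption_run <- function(x, ...) x$events

#' One-row summary of a simulation run
#' @param x A `disruption_run`.
#' @param ... Unused.
#' @return A one-row tibble of headline counts.
#' @export
glance.disruption_run <- function(x, ...) {
  cls <- classify_detection_mode(x$events)
  tibble::tibble(
    programme = x$programme,
    n = x$n,
    scenario_duration = x$scenario$duration,
    screens = sum(x$events$type == "screen"),
    diagnoses = nrow(cls),
    screen_detected = sum(cls$mode == "screen-detected"),
    interval_27 = sum(cls$interval_27)
  )
}

#' Tidy a paired scenario/status quo comparison
#' @param x A `paired_runs` object.
#' @param ... Unused.
#' @return The [tabulate_outcomes()] tibble.
#' @export
tidy.paired_runs <- function(x, ...) tabulate_outcomes(x)

#' One-row summary of a paired comparison
#' @param x A `paired_runs` object.
#' @param ... Unused.
#' @return One-row tibble with headline changes.
#' @export
glance.paired_runs <- function(x, ...) {
  tab <- tabulate_outcomes(x)
  dx_metric <- c(breast = "dx_per_100k", bowel = "crc_diagnoses",
                 cervix = "cancer_diagnoses")[[x$status_quo$programme]]
  tibble::tibble(
    programme = x$status_quo$programme,
    scenario_duration = x$scenario$scenario$duration,
    screens_pct_of_status_quo =
      100 * tab$scenario[tab$metric == "screens_provided"] /
      tab$status_quo[tab$metric == "screens_provided"],
    dx_pct_change = tab$pct_change[tab$metric == dx_metric]
  )
}

#' Plot monthly screening and diagnosis volumes for a run
#' @param object A `disruption_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.disruption_run <- function(object, ...) {
  dat <- object$events |>
    dplyr::filter(.data$type %in% c("screen", "diagnosis")) |>
    dplyr::count(.data$type, .data$month) |>
    dplyr::mutate(date = .data$month / 12)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$date, y = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$type), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "calendar year", y = "events per month",
                  title = paste(object$programme, "programme volumes")) +
    ggplot2::theme_minimal()
}

#' Plot scenario-versus-status quo monthly screening volumes
#' @param object A `paired_runs` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.paired_runs <- function(object, ...) {
  dat <- dplyr::bind_rows(
    status_quo = dplyr::count(
      dplyr::filter(object$status_quo$events, .data$type == "screen"),
      .data$month),
    scenario = dplyr::count(
      dplyr::filter(object$scenario$events, .data$type == "screen"),
      .data$month),
    .id = "run"
  ) |>
    dplyr::mutate(date = .data$month / 12)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$date, y = .data$n,
                                    colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "calendar year", y = "screens per month",
                  colour = NULL,
                  title = paste(object$status_quo$programme,
                                "screening throughput")) +
    ggplot2::theme_minimal()
}
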