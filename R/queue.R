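# Capacity-constrained allocation of breast-screening appointments during
# recovery. Four prioritisation factors: target age range, whether the
# appointment fell during the pause or during recovery, existing versus
# newly invited clients, and time overdue. The factor ordering is
# configurable; the default puts women 50-74 first and, within the
# leading factors, the most overdue clients first.

#' Priority keys for booking requests
#'
#' Builds the deterministic sort key for each request. Lower keys are
#' served first. The default factor order is target age (50-74 first),
#' then period class (appointments that fell during the pause before
#' those falling during recovery), then client class (existing before
#' newly invited), then weeks overdue (descending), with ties broken by
#' id so allocation is reproducible.
#'
#' @param requests Tibble with columns `id`, `age` (years at request),
#'   `newly_invited` (logical), `period` ("pause" or "recovery"),
#'   `scheduled_month`.
#' @param now_month Month at which priorities are evaluated.
#' @param factors Character permutation of
#'   `c("target_age", "period", "client", "overdue")`.
#' @param target_age Inclusive target age range (default 50-74).
#' @return `requests` with key columns and a `priority` rank added
#'   (1 = first served).
#' @export
priority_key <- function(requests, now_month,
                         factors = c("target_age", "period", "client",
                                     "overdue"),
                         target_age = c(50, 74)) {
  stopifnot(setequal(factors, c("target_age", "period", "client", "overdue")))
  weeks_overdue <- months_to_weeks(pmax(now_month - requests$scheduled_month, 0))
  keys <- list(
    target_age = ifelse(requests$age >= target_age[1] &
                          requests$age <= target_age[2], 0L, 1L),
    period = ifelse(requests$period == "pause", 0L, 1L),
    client = ifelse(requests$newly_invited, 1L, 0L),
    overdue = -weeks_overdue
  )
  ord <- do.call(order, c(unname(keys[factors]), list(requests$id)))
  requests$weeks_overdue <- weeks_overdue
  for (f in factors) requests[[paste0("key_", f)]] <- keys[[f]]
  requests$priority <- integer(nrow(requests))
  requests$priority[ord] <- seq_len(nrow(requests))
  requests
}

#' Allocate queued booking requests to available appointments
#'
#' Books the top `floor(base_capacity * multiplier)` requests by priority;
#' the remainder are carried over (their overdue time keeps growing).
#' Allocation is deterministic given the queue and the capacity.
#'
#' @param queue Request tibble (see [priority_key()]).
#' @param multiplier Capacity multiplier for this month (from the
#'   capacity schedule).
#' @param now_month Current month.
#' @param base_capacity Status quo screens per month (>= 0).
#' @param factors Priority factor order, passed to [priority_key()].
#' @return List with `booked` and `carried` request tibbles.
#' @export
allocate <- function(queue, multiplier, now_month, base_capacity,
                     factors = c("target_age", "period", "client",
                                 "overdue")) {
  if (base_capacity < 0) stop("capacity must be non-negative", call. = FALSE)
  slots <- floor(base_capacity * multiplier)
  if (nrow(queue) == 0 || slots <= 0) {
    return(list(booked = queue[0, ], carried = queue))
  }
  keyed <- priority_key(queue, now_month, factors = factors)
  booked <- keyed[keyed$priority <= slots, , drop = FALSE]
  carried <- keyed[keyed$priority > slots, , drop = FALSE]
  list(booked = booked, carried = carried)
}

#' Median screen-to-screen interval in weeks
#'
#' Computes intervals between consecutive attended screens from an event
#' log and returns the median in weeks. Intervals are attributed to the
#' month of the later screen; `window` restricts to intervals ending in
#' the reporting window, and `ids` restricts to a subgroup of
#' individuals.
#'
#' @param events Event-log tibble containing `type == "screen"` rows with
#'   `id` and `month`.
#' @param ids Optional vector of individual ids to keep.
#' @param window Optional `c(start, end)` month indices (end exclusive)
#'   for the interval-ending month.
#' @return Median interval in weeks, or `NA` with a warning if the
#'   subgroup has no completed interval.
#' @export
median_screening_interval <- function(events, ids = NULL, window = NULL) {
  scr <- dplyr::filter(events, .data$type == "screen")
  if (!is.null(ids)) scr <- dplyr::filter(scr, .data$id %in% ids)
  iv <- scr |>
    dplyr::arrange(.data$id, .data$month) |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(gap = .data$month - dplyr::lag(.data$month)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$gap))
  if (!is.null(window)) {
    iv <- dplyr::filter(iv, .data$month >= window[1], .data$month < window[2])
  }
  if (nrow(iv) == 0) {
    warning("no completed screening intervals in subgroup")
    return(NA_real_)
  }
  stats::median(months_to_weeks(iv$gap))
}
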