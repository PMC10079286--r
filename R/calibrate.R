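# Calibration of the simplified natural-history and test-characteristic
# parameters against status quo programme outcomes. Scenario outputs are
# never fitted: the model is calibrated to the no-disruption world and
# scenarios are predictions.

#' Weighted discrepancy between simulated metrics and calibration targets
#'
#' Weighted sum of squared relative errors; zero iff every target is hit
#' exactly.
#'
#' @param simulated Named numeric vector of simulated metrics.
#' @param targets Tibble with columns `metric`, `target` and optionally
#'   `weight` (default 1).
#' @return Scalar discrepancy.
#' @export
discrepancy <- function(simulated, targets) {
  if (!"weight" %in% names(targets)) targets$weight <- 1
  missing <- setdiff(targets$metric, names(simulated))
  if (length(missing)) {
    stop("simulated metrics missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sim <- simulated[targets$metric]
  sum(targets$weight * ((sim - targets$target) / targets$target)^2)
}

#' Fit free parameters to calibration targets by coordinate search
#'
#' Derivative-free coordinate search on log-scaled parameters with a
#' shrinking step, against a deterministic objective (the simulator is
#' run under a fixed seed, so repeated evaluations at the same point
#' agree: common random numbers). Returns parameters whose discrepancy is
#' never worse than the initial point; `budget = 0` returns the initial
#' parameters unchanged.
#'
#' @param initial Named list/vector of starting parameter values.
#' @param targets Target tibble (see [discrepancy()]).
#' @param simulate_fn Function `(params, seed)` returning a named metric
#'   vector.
#' @param budget Maximum number of objective evaluations.
#' @param seed Seed passed to every `simulate_fn` call.
#' @param free Names of the parameters to vary (default: all in
#'   `initial`).
#' @param lower,upper Named bounds for free parameters (optional).
#' @param step Initial multiplicative step (default 0.25, i.e. +/-25%).
#' @param polish Run a Nelder-Mead simplex polish on log-scaled
#'   parameters with whatever budget the coordinate phase leaves
#'   (default TRUE; coordinate moves alone can stall on ridges where
#'   parameters trade off against each other).
#' @return List with `params`, `discrepancy`, `evaluations`, `trace`.
#' @export
calibrate <- function(initial, targets, simulate_fn, budget = 50, seed = 1,
                      free = names(initial), lower = NULL, upper = NULL,
                      step = 0.25, polish = TRUE) {
  stopifnot(budget >= 0)
  params <- initial
  evals <- 0L
  objective <- function(p) {
    m <- simulate_fn(p, seed)
    val <- discrepancy(m, targets)
    if (!is.finite(val)) {
      stop("non-finite calibration objective at parameters: ",
           paste(names(p), signif(unlist(p), 4), sep = "=", collapse = ", "),
           call. = FALSE)
    }
    evals <<- evals + 1L
    val
  }
  if (budget == 0) {
    return(list(params = params, discrepancy = NA_real_, evaluations = 0L,
                trace = tibble::tibble()))
  }
  clamp <- function(name, value) {
    if (!is.null(lower[[name]])) value <- max(value, lower[[name]])
    if (!is.null(upper[[name]])) value <- min(value, upper[[name]])
    value
  }
  best <- objective(params)
  trace <- list(tibble::tibble(evaluation = evals, discrepancy = best))
  s <- step
  while (evals < budget && s > 0.01) {
    improved <- FALSE
    for (nm in free) {
      if (evals >= budget) break
      for (dir in c(1 + s, 1 / (1 + s))) {
        if (evals >= budget) break
        cand <- params
        cand[[nm]] <- clamp(nm, params[[nm]] * dir)
        if (identical(cand[[nm]], params[[nm]])) next
        val <- objective(cand)
        trace[[length(trace) + 1L]] <-
          tibble::tibble(evaluation = evals, discrepancy = val)
        if (val < best) {
          best <- val
          params <- cand
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) s <- s / 2
  }
  if (polish && evals < budget && length(free) > 1 && best > 0) {
    fn <- function(lp) {
      cand <- params
      for (i in seq_along(free)) {
        cand[[free[i]]] <- clamp(free[i], exp(lp[i]))
      }
      val <- objective(cand)
      trace[[length(trace) + 1L]] <<-
        tibble::tibble(evaluation = evals, discrepancy = val)
      if (val < best) {
        best <<- val
        params <<- cand
      }
      val
    }
    opt <- stats::optim(log(unlist(params[free])), fn,
                        method = "Nelder-Mead",
                        control = list(maxit = budget - evals,
                                       reltol = 1e-4))
  }
  list(params = params, discrepancy = best, evaluations = evals,
       trace = dplyr::bind_rows(trace))
}

#' Status quo calibration targets for the breast programme
#'
#' The status quo reporting column the breast model is calibrated to:
#' 2020-2021 rates per 100,000 women 50-74 (including non-participants),
#' the tumour-characteristic distribution, and per-episode recall rates.
#'
#' @return Target tibble for [calibrate()].
#' @export
breast_calibration_targets <- function() {
  tibble::tribble(
    ~metric,                    ~target, ~weight,
    "dx_per_100k",              298,     3,
    "screen_detected_per_100k", 127,     3,
    "interval_27_per_100k",     38,      1,
    "interval_12_per_100k",     15,      1,
    "pct_small",                59.7,    1,
    "pct_nodal",                24.9,    1,
    "pct_grade3",               46.6,    1
  )
}

#' Simulate status quo breast metrics for a parameter vector
#'
#' Objective wrapper used by breast calibration: builds the standard
#' breast cohort at the requested scale, runs a status quo simulation
#' with the supplied natural-history overrides, and returns the
#' calibration metric vector.
#'
#' @param overrides Named list of [nh_params()] overrides (e.g.
#'   `onset_rate`, `mean_small`).
#' @param seed Master seed.
#' @param scale Cohort scale factor (default 1:100).
#' @param config Programme configuration.
#' @return Named numeric metric vector.
#' @export
breast_status_quo_metrics <- function(overrides, seed, scale = 0.01,
                                      config = programme_config("breast")) {
  overrides <- as.list(overrides)
  # mammographic sensitivities live in the programme config; route the
  # pseudo-parameters sens_small / sens_large there (pre-sim detection
  # probabilities follow the in-sim sensitivities)
  if (!is.null(overrides$sens_small)) {
    config$sensitivity$small <- min(overrides$sens_small, 0.999)
    overrides$sens_small <- NULL
  }
  if (!is.null(overrides$sens_large)) {
    config$sensitivity$large <- min(overrides$sens_large, 0.999)
    overrides$sens_large <- NULL
  }
  config$presim_detect <- config$sensitivity
  cohort <- cohort_spec("breast", scale = scale) |>
    generate_cohort(seed = seed) |>
    assign_screening_behaviour(config$participation, seed = seed)
  params <- do.call(nh_params, c(list(cancer = "breast"), overrides))
  run <- simulate_programme(cohort, disruption_scenario("breast", 0),
                            config, params, seed)
  run_metrics(run)
}

#' Calibrate the breast model to its status quo targets
#'
#' Runs [calibrate()] over the free breast natural-history parameters,
#' starting from the packaged defaults.
#'
#' @param seed Master seed (fixed inside the objective).
#' @param budget Objective-evaluation budget.
#' @param scale Cohort scale for calibration runs.
#' @param free Parameters to vary.
#' @return The [calibrate()] result; `$params` slots into [nh_params()].
#' @export
calibrate_breast <- function(seed = 1, budget = 40, scale = 0.01,
                             free = c("onset_rate", "mean_small",
                                      "mean_large", "present_small_rate",
                                      "grade3_prob", "sens_small",
                                      "sens_large"), step = 0.25) {
  defaults <- default_nh_params("breast")
  cfg <- programme_config("breast")
  defaults$sens_small <- cfg$sensitivity$small
  defaults$sens_large <- cfg$sensitivity$large
  calibrate(
    initial = defaults[free],
    targets = breast_calibration_targets(),
    simulate_fn = function(p, seed) {
      breast_status_quo_metrics(as.list(p), seed, scale)
    },
    budget = budget, seed = seed, free = free, step = step,
    lower = list(onset_rate = 1e-5, mean_small = 4, mean_large = 3,
                 present_small_rate = 1e-4, grade3_prob = 0.05,
                 sens_small = 0.3, sens_large = 0.5),
    upper = list(onset_rate = 1e-3, mean_small = 120, mean_large = 90,
                 present_small_rate = 0.2, grade3_prob = 0.95,
                 sens_small = 0.999, sens_large = 0.999)
  )
}
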