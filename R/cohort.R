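# Synthetic screening cohorts. A cohort is a tibble, one row per simulated
# person, created from a CohortSpec and enriched by behaviour / HPV-history
# assignment steps, so the pieces chain with the pipe:
#
#   cohort_spec("bowel", size = 71000) |>
#     generate_cohort(seed = 1) |>
#     assign_screening_behaviour(participation = 0.435, seed = 1)

#' Specification of a synthetic screening cohort
#'
#' National default sizes reflect the populations the three Australian
#' programmes target: 7.1 million persons aged 50-74 for bowel screening
#' (3.5 M men, 3.6 M women), 3.54 million women aged 50-74 for breast
#' screening, and 8.2 million women aged 25-74 for cervical screening.
#' `scale` shrinks the national size for desk-scale runs (default 1:100);
#' all rate outputs are scale-invariant and count outputs are rescaled on
#' report.
#'
#' @param programme One of "breast", "bowel", "cervix".
#' @param size Cohort size in persons. Defaults to the national size times
#'   `scale`.
#' @param scale Scale factor relative to the national population (default
#'   0.01, i.e. 1:100).
#' @param age_range Inclusive eligible age range in years at the reference
#'   date.
#' @param sex_split Fraction male (0 for the female-only programmes).
#' @param reference_month Calendar month at which ages are evaluated
#'   (default January 2020).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(programme = c("breast", "bowel", "cervix"),
                        size = NULL,
                        scale = 0.01,
                        age_range = NULL,
                        sex_split = NULL,
                        reference_month = ym(2020, 1)) {
  programme <- match.arg(programme)
  national <- c(breast = 3538000, bowel = 7100000, cervix = 8200000)
  if (is.null(age_range)) {
    # cohorts cover everyone age-eligible at some point over the 2020-2021
    # reporting window (for breast/bowel: born ~1945-1971, i.e. 48-75 at
    # the reference date), so invitation inflow balances ageing-out and
    # status quo throughput is stationary across the window
    age_range <- if (programme == "cervix") c(24L, 75L) else c(48L, 75L)
  }
  if (is.null(sex_split)) {
    sex_split <- if (programme == "bowel") 3.5 / 7.1 else 0
  }
  if (is.null(size)) size <- round(national[[programme]] * scale)
  spec <- structure(
    list(programme = programme, size = as.integer(size), scale = scale,
         age_range = as.integer(age_range), sex_split = sex_split,
         reference_month = as.integer(reference_month)),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (!is.finite(spec$size) || spec$size <= 0) {
    stop("invalid cohort spec: size must be a positive integer", call. = FALSE)
  }
  if (spec$sex_split < 0 || spec$sex_split > 1) {
    stop("invalid cohort spec: sex_split must lie in [0, 1]", call. = FALSE)
  }
  if (spec$age_range[1] < 18 || spec$age_range[2] > 85 ||
      spec$age_range[1] > spec$age_range[2]) {
    stop("invalid cohort spec: age range must lie within [18, 85]", call. = FALSE)
  }
  if (spec$scale <= 0) stop("invalid cohort spec: scale must be > 0", call. = FALSE)
  invisible(spec)
}

#' Generate a synthetic cohort from a specification
#'
#' Ages are uniform within the eligible range at the reference date unless
#' an age pyramid is supplied as a two-column data frame (`age`, `weight`);
#' sexes are assigned by the cohort specification's sex split.
#' Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master integer seed.
#' @param age_pyramid Optional data frame with columns `age` (years) and
#'   `weight` giving a within-range age distribution.
#' @return A tibble with columns `id`, `sex`, `birth_month`, carrying the
#'   spec as attribute `"spec"` and the seed as `"seed"`.
#' @export
generate_cohort <- function(spec, seed, age_pyramid = NULL) {
  validate_cohort_spec(spec)
  n <- spec$size
  with_substream(seed, "cohort", {
    sex <- ifelse(stats::runif(n) < spec$sex_split, "male", "female")
    if (is.null(age_pyramid)) {
      age_months <- stats::runif(
        n, spec$age_range[1] * 12, (spec$age_range[2] + 1) * 12
      )
    } else {
      stopifnot(all(c("age", "weight") %in% names(age_pyramid)))
      yrs <- sample(age_pyramid$age, n, replace = TRUE,
                    prob = age_pyramid$weight)
      age_months <- yrs * 12 + stats::runif(n, 0, 12)
    }
    out <- tibble::tibble(
      id = seq_len(n),
      sex = sex,
      birth_month = as.integer(spec$reference_month - floor(age_months))
    )
    attr(out, "spec") <- spec
    attr(out, "seed") <- seed
    out
  })
}

#' Age in whole years at a given month
#' @param cohort A cohort tibble.
#' @param month Month index.
#' @return Integer years.
#' @export
age_at <- function(cohort, month) {
  as.integer((month - cohort$birth_month) %/% 12L)
}

#' Assign ever-screener status and attendance-delay profiles
#'
#' Each person becomes an ever-screener with probability `participation`
#' (binomial). Screeners receive an attendance-delay profile: a personal
#' on-schedule probability drawn uniformly from `adherence_profile$on_schedule`
#' (a range within [0.60, 0.84] by default, reflecting the observed spread
#' of round-specific on-schedule attendance) and a mean lateness for delayed
#' rounds.
#'
#' @param cohort A cohort tibble.
#' @param participation Fraction in [0, 1] who ever screen.
#' @param adherence_profile List with `on_schedule` (length-2 probability
#'   range), `mean_delay_months` (mean lateness when off schedule and
#'   late), and `early_fraction` (share of off-schedule rounds attended
#'   early, up to three months ahead of schedule).
#' @param seed Master integer seed.
#' @return The cohort with columns `participant`, `on_schedule`,
#'   `mean_delay`, `early_frac` added.
#' @export
assign_screening_behaviour <- function(cohort, participation,
                                       adherence_profile = list(
                                         on_schedule = c(0.60, 0.84),
                                         mean_delay_months = 6,
                                         early_fraction = 0.35
                                       ),
                                       seed = attr(cohort, "seed")) {
  if (!is.finite(participation) || participation < 0 || participation > 1) {
    stop("participation must lie in [0, 1]", call. = FALSE)
  }
  rng_on <- range(adherence_profile$on_schedule)
  with_substream(seed, "behaviour", {
    n <- nrow(cohort)
    cohort$participant <- stats::runif(n) < participation
    cohort$on_schedule <- stats::runif(n, rng_on[1], rng_on[2])
    cohort$mean_delay <- rep(adherence_profile$mean_delay_months, n)
    ef <- adherence_profile$early_fraction
    cohort$early_frac <- rep(if (is.null(ef)) 0.35 else ef, n)
    cohort
  })
}

#' Assign HPV screening-transition and vaccination history
#'
#' Marks the configured fraction of women as having already attended their
#' first primary HPV screen (these women are not due for routine screening
#' again until at least December 2022, i.e. five years after the earliest
#' transition date); the remainder carry a last-cytology date and are due
#' for their first HPV test two years later. Vaccination flags are set by
#' birth cohort: women born in or after `vaccination_birth_year` are
#' vaccinated with probability `vaccination_coverage`.
#'
#' @param cohort A cervical cohort tibble (all female).
#' @param transitioned_fraction Fraction already transitioned to HPV
#'   screening (default 0.536).
#' @param vaccination_coverage Three-dose coverage in eligible birth
#'   cohorts (default 0.80).
#' @param seed Master integer seed.
#' @param vaccination_birth_year First vaccinated birth year (default 1993).
#' @return Cohort with columns `hpv_transitioned`, `first_hpv_month`,
#'   `last_cytology_month`, `vaccinated` added.
#' @export
assign_hpv_history <- function(cohort, transitioned_fraction = 0.536,
                               vaccination_coverage = 0.80,
                               seed = attr(cohort, "seed"),
                               vaccination_birth_year = 1993) {
  spec <- attr(cohort, "spec")
  if (!is.null(spec) && spec$programme != "cervix") {
    stop("HPV history applies only to cervical cohorts", call. = FALSE)
  }
  if (any(cohort$sex != "female")) {
    stop("HPV history applies only to female cohorts", call. = FALSE)
  }
  stopifnot(transitioned_fraction >= 0, transitioned_fraction <= 1,
            vaccination_coverage >= 0, vaccination_coverage <= 1)
  with_substream(seed, "hpv_history", {
    n <- nrow(cohort)
    trans <- stats::runif(n) < transitioned_fraction
    cohort$hpv_transitioned <- trans
    # first HPV tests accrued from the Dec 2017 programme renewal up to the
    # March 2020 snapshot; routine rescreen is five-yearly thereafter
    first_hpv <- as.integer(floor(
      stats::runif(n, ym(2017, 12), ym(2020, 3) + 1)
    ))
    cohort$first_hpv_month <- ifelse(trans, first_hpv, NA_integer_)
    last_cyt <- as.integer(floor(
      stats::runif(n, ym(2018, 1), ym(2019, 12) + 1)
    ))
    cohort$last_cytology_month <- ifelse(trans, NA_integer_, last_cyt)
    eligible <- ym_year(cohort$birth_month) >= vaccination_birth_year
    cohort$vaccinated <- eligible & stats::runif(n) < vaccination_coverage
    cohort
  })
}

#' Write a cohort to a tab-separated file for inspection
#' @param cohort Cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
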