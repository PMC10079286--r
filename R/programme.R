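# Status quo screening logic for the three programmes: routine intervals,
# invitation ages, test characteristics, and follow-up pathways.

#' Programme configuration
#'
#' Encodes one programme's routine screening rules and test
#' characteristics. Defaults follow the Australian national programmes:
#' biennial mammography for women 50-74 (invited at 50, 55% participation);
#' biennial iFOBT for persons 50-74 (invited at 50, 43.5% participation,
#' ~70% of positives completing follow-up colonoscopy, return to iFOBT
#' after a clear colonoscopy at 4 years, surveillance colonoscopy
#' pathways at 1-5 years); five-yearly primary HPV screening for women
#' 25-74 (invited at 25, 46% participation, first HPV test due 2 years
#' after the last cytology test for women yet to transition).
#'
#' Test sensitivities and the false-positive rate are calibration
#' parameters (set so that status quo recall and detection metrics match
#' the reference evaluation), not literature constants.
#'
#' @param programme One of "breast", "bowel", "cervix".
#' @param ... Named overrides of the defaults.
#' @return Named list of class `programme_config`.
#' @export
programme_config <- function(programme = c("breast", "bowel", "cervix"), ...) {
  programme <- match.arg(programme)
  defaults <- switch(programme,
    breast = list(
      sex = "female", age_range = c(50L, 74L), interval = 24L,
      invitation_age = 50L, participation = 0.55,
      sensitivity = list(small = 0.94, large = 0.99),
      fp_rate = 0.046,                # benign recall per screening episode
      followup_completion = 1,        # assessment is within-programme
      opportunistic_rate = 0.009,     # monthly off-programme screen uptake
      era_start = ym(1991, 1),        # programme inception
      presim_interval = 24L,
      presim_detect = list(small = 0.94, large = 0.99)
    ),
    bowel = list(
      sex = "any", age_range = c(50L, 74L), interval = 24L,
      invitation_age = 50L, participation = 0.435,
      sensitivity = list(adenoma = 0.28, crc = 0.85),
      fp_rate = 0.060,                # iFOBT positive with no neoplasia
      followup_completion = 0.70,     # positive iFOBT -> colonoscopy
      colonoscopy_delay = 2L,         # months from positive kit
      surveillance_interval = 36L,    # within the 12-60 month menu
      return_interval = 48L,          # clear colonoscopy -> next iFOBT
      surveillance_init = 0.023,      # fraction under surveillance at start
      return_init = 0.075,            # fraction awaiting 4-y return at start
      era_start = ym(2006, 1),        # programme inception
      presim_interval = 24L,
      presim_detect = list(adenoma = 0.28 * 0.70, crc_12 = 0.85 * 0.70,
                           crc_34 = 0.85 * 0.70)
    ),
    cervix = list(
      sex = "female", age_range = c(25L, 74L), interval = 60L,
      invitation_age = 25L, participation = 0.46,
      sensitivity = list(hpv = 0.92, cin = 0.92, cancer = 0.96),
      fp_rate = 0.055,                # HPV-positive, no progressing lesion
      followup_completion = 1,        # positive -> colposcopy (collapsed)
      surveillance_interval = 12L,    # repeat HPV test after a positive
      surveillance_init = 0.045,
      era_start = ym(1991, 1),        # cytology-era inception
      presim_interval = 24L,
      # pre-renewal rounds were 2-yearly cytology
      presim_detect = list(hpv = 0, cin = 0.60, localised = 0.80,
                           regional = 0.85, distant = 0.85)
    )
  )
  cfg <- utils::modifyList(defaults, list(...))
  cfg$programme <- programme
  probs <- c(cfg$participation, unlist(cfg$sensitivity), cfg$fp_rate,
             cfg$followup_completion)
  if (any(probs < 0 | probs > 1)) {
    stop("programme probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$interval <= 0) stop("screening interval must be positive", call. = FALSE)
  structure(cfg, class = "programme_config")
}

#' Next routine screening due month
#'
#' Vectorised over a history tibble. Never-screened individuals are due at
#' the invitation age (or immediately if already older). Previously
#' screened individuals are due one routine interval after the last
#' screen. Cervical transition rules: women who have already attended a
#' primary HPV test are due five years after it; women still on the
#' cytology pathway are due their first HPV test two years after their
#' last cytology test.
#'
#' @param history Tibble with `birth_month` and `last_screen_month`
#'   (NA = never screened); for cervix also `hpv_transitioned`,
#'   `first_hpv_month`, `last_cytology_month`.
#' @param config A [programme_config()].
#' @param current_month Month index "now".
#' @return Integer vector of due months.
#' @export
due_date <- function(history, config, current_month) {
  age <- (current_month - history$birth_month) / 12
  if (any(age < config$age_range[1] | age > config$age_range[2] + 1)) {
    stop("individual not eligible for this programme", call. = FALSE)
  }
  invite <- history$birth_month + config$invitation_age * 12L
  if (config$programme == "cervix") {
    due <- ifelse(
      !is.na(history$last_screen_month),
      history$last_screen_month + config$interval,
      ifelse(history$hpv_transitioned,
             history$first_hpv_month + config$interval,
             history$last_cytology_month + 24L)
    )
  } else {
    due <- ifelse(is.na(history$last_screen_month),
                  pmax(invite, current_month),
                  history$last_screen_month + config$interval)
  }
  as.integer(due)
}

#' Perform screening tests and sample outcomes
#'
#' Vectorised over attendees. `state` gives each person's true disease
#' state at the screen month (programme-specific labels: breast
#' "healthy"/"small"/"large"; bowel "healthy"/"adenoma"/"crc_12"/"crc_34";
#' cervix "healthy"/"hpv"/"cin"/"localised"/"regional"/"distant").
#' Detection probability is the state-specific sensitivity; disease-free
#' attendees test positive with the false-positive rate. Uniform draws may
#' be supplied (`u_test`, `u_fp`) for common-random-number pairing;
#' otherwise they are drawn from the session RNG.
#'
#' @param state Character vector of true states.
#' @param config A [programme_config()].
#' @param month Screen month (scalar or vector).
#' @param u_test,u_fp Optional uniform draws, one per attendee.
#' @return Tibble with `month`, `modality`, `outcome` (one of "negative",
#'   "positive", "detected-precursor", "detected-cancer"), and
#'   `true_state`.
#' @export
perform_screen <- function(state, config, month,
                           u_test = NULL, u_fp = NULL) {
  n <- length(state)
  if (is.null(u_test)) u_test <- stats::runif(n)
  if (is.null(u_fp)) u_fp <- stats::runif(n)
  modality <- switch(config$programme, breast = "mammogram",
                     bowel = "iFOBT", cervix = "HPV test")
  sens <- screen_sensitivity(state, config)
  hit <- u_test < sens
  fp <- state == "healthy" & u_fp < config$fp_rate
  precursor_states <- c("adenoma", "hpv", "cin")
  outcome <- rep("negative", n)
  outcome[hit & state %in% precursor_states] <- "detected-precursor"
  outcome[hit & !(state %in% precursor_states)] <- "detected-cancer"
  outcome[fp] <- "positive"
  tibble::tibble(month = as.integer(month), modality = modality,
                 outcome = outcome, true_state = state)
}

screen_sensitivity <- function(state, config) {
  s <- config$sensitivity
  switch(config$programme,
    breast = dplyr::case_match(state, "small" ~ s$small, "large" ~ s$large,
                               .default = 0),
    bowel = dplyr::case_match(state, "adenoma" ~ s$adenoma,
                              "crc_12" ~ s$crc, "crc_34" ~ s$crc,
                              .default = 0),
    cervix = dplyr::case_match(state, "hpv" ~ s$hpv, "cin" ~ s$cin,
                               "localised" ~ s$cancer, "regional" ~ s$cancer,
                               "distant" ~ s$cancer, .default = 0)
  )
}

#' Resolve follow-up of a positive or recalled screen
#'
#' Vectorised. Bowel: a follow-up colonoscopy occurs with the configured
#' completion probability (~70%); findings route the person to
#' surveillance colonoscopy (precursor found) or back to routine iFOBT
#' after 4 years (clear). Breast: assessment within the programme in the
#' same month. Cervix: colposcopy referral (collapsed triage pathway),
#' then 12-month surveillance testing.
#'
#' @param outcome Character vector of screen outcomes (must not contain
#'   "negative").
#' @param config A [programme_config()].
#' @param month Screen month.
#' @param u Optional uniform draws for follow-up completion.
#' @return Tibble with `completes` (logical), `followup_month`, `pathway`
#'   (one of "assessment", "surveillance", "return-to-iFOBT-4y",
#'   "triage-colposcopy").
#' @export
resolve_followup <- function(outcome, config, month, u = NULL) {
  if (any(outcome == "negative")) {
    stop("follow-up applies to positive or recalled screens only",
         call. = FALSE)
  }
  n <- length(outcome)
  if (is.null(u)) u <- stats::runif(n)
  completes <- u < config$followup_completion
  pathway <- switch(config$programme,
    breast = rep("assessment", n),
    bowel = ifelse(outcome == "detected-precursor", "surveillance",
                   "return-to-iFOBT-4y"),
    cervix = rep("triage-colposcopy", n)
  )
  delay <- switch(config$programme, breast = 0L,
                  bowel = config$colonoscopy_delay, cervix = 0L)
  tibble::tibble(
    completes = completes,
    followup_month = as.integer(month + delay),
    pathway = pathway
  )
}
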