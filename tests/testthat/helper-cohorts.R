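# Small cohorts and runs shared across test files. Sizes are chosen so the
# whole suite stays fast while binomial checks still have power.

tiny_cohort <- function(programme, size = 2000, seed = 42,
                        participation = NULL, ...) {
  cfg <- programme_config(programme)
  if (is.null(participation)) participation <- cfg$participation
  ch <- cohort_spec(programme, size = size, scale = size /
                      c(breast = 3538000, bowel = 7100000,
                        cervix = 8200000)[[programme]]) |>
    generate_cohort(seed = seed) |>
    assign_screening_behaviour(participation, seed = seed, ...)
  if (programme == "cervix") ch <- assign_hpv_history(ch, seed = seed)
  ch
}

# a paired bowel run at 1:500 scale, memoised across tests
.run_cache <- new.env(parent = emptyenv())
cached_paired <- function(programme, duration, scale = 0.002, seed = 42) {
  key <- paste(programme, duration, scale, seed, sep = "_")
  if (is.null(.run_cache[[key]])) {
    ch <- cohort_spec(programme, scale = scale) |>
      generate_cohort(seed = seed) |>
      assign_screening_behaviour(programme_config(programme)$participation,
                                 seed = seed)
    if (programme == "cervix") ch <- assign_hpv_history(ch, seed = seed)
    .run_cache[[key]] <- run_paired(
      ch, disruption_scenario(programme, duration), seed = seed)
  }
  .run_cache[[key]]
}
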