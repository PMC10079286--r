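test_that("detection-mode classification follows the window rules", {
  ev <- dplyr::bind_rows(
    tibble::tibble(id = 1L, month = ym(2020, 1), type = "screen",
                   outcome = "negative"),
    tibble::tibble(id = 1L, month = ym(2020, 11), type = "diagnosis",
                   outcome = NA, mode = "symptomatic", stage = "large"),
    tibble::tibble(id = 2L, month = ym(2020, 5), type = "diagnosis",
                   outcome = NA, mode = "symptomatic", stage = "large"),
    tibble::tibble(id = 3L, month = ym(2019, 1), type = "screen",
                   outcome = "negative"),
    tibble::tibble(id = 3L, month = ym(2020, 8), type = "diagnosis",
                   outcome = NA, mode = "symptomatic", stage = "large"),
    tibble::tibble(id = 4L, month = ym(2020, 3), type = "diagnosis",
                   outcome = NA, mode = "screen", stage = "small")
  )
  cls <- classify_detection_mode(ev)
  get <- function(i) cls[cls$id == i, ]
  expect_true(get(1)$interval_12 && get(1)$interval_27)   # 10 months
  expect_equal(get(2)$mode, "other")                      # never screened
  expect_false(get(3)$interval_12)                        # 19 months
  expect_true(get(3)$interval_27)
  expect_equal(get(4)$mode, "screen-detected")
})

test_that("classification equals a brute-force rule application", {
  oracle <- function(ev) {
    dx <- ev[ev$type == "diagnosis", ]
    out <- data.frame(id = dx$id, month = dx$month,
                      mode = NA_character_, i12 = NA, i27 = NA)
    for (r in seq_len(nrow(dx))) {
      if (dx$mode[r] == "screen") {
        out$mode[r] <- "screen-detected"; out$i12[r] <- FALSE; out$i27[r] <- FALSE
      } else {
        negs <- ev$month[ev$type == "screen" & ev$outcome == "negative" &
                           ev$id == dx$id[r] & ev$month < dx$month[r]]
        gap <- if (length(negs)) dx$month[r] - max(negs) else Inf
        out$i12[r] <- gap <= 12
        out$i27[r] <- gap <= 27
        out$mode[r] <- if (gap <= 27) "interval" else "other"
      }
    }
    out[order(out$id, out$month), ]
  }
  for (s in 1:10) {
    ev <- withr::with_seed(s, {
      n <- sample(3:8, 1)
      dplyr::bind_rows(
        tibble::tibble(id = sample(4, n, TRUE),
                       month = sample(0:40, n), type = "screen",
                       outcome = sample(c("negative", "positive"), n, TRUE)),
        tibble::tibble(id = 1:3, month = sample(30:60, 3),
                       type = "diagnosis",
                       mode = sample(c("screen", "symptomatic"), 3, TRUE),
                       stage = "x")
      )
    })
    got <- classify_detection_mode(ev)
    exp <- oracle(ev)
    expect_equal(got$mode, exp$mode)
    expect_equal(got$interval_12, exp$i12)
    expect_equal(got$interval_27, exp$i27)
  }
})

test_that("programme sensitivity is the screen-detected share", {
  expect_equal(programme_sensitivity(117, 35), 100 * 117 / 152)
  expect_equal(round(programme_sensitivity(117, 35), 1), 77.0)
  expect_equal(programme_sensitivity(10, 0), 100)
  expect_equal(programme_sensitivity(0, 10), 0)
  expect_warning(out <- programme_sensitivity(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("upstaging attribution reproduces the printed example", {
  # status quo 1878 cervical cancers; 18 upstaged localised->regional and
  # 9 regional->distant give 1.4% of status quo cases
  sq <- tibble::tibble(stage = c("localised", "regional", "distant"),
                       count = c(1100, 600, 178))
  sc <- tibble::tibble(stage = c("localised", "regional", "distant"),
                       count = c(1100 + 51, 600 + 9, 178 + 9))
  rec <- upstaging_attribution(sq, sc)
  expect_equal(rec$loc_to_reg, 18)
  expect_equal(rec$reg_to_dist, 9)
  expect_equal(rec$additional, 69)
  expect_equal(round(rec$pct_upstaged, 1), 1.4)
  ident <- upstaging_attribution(sq, sq)
  expect_equal(ident$loc_to_reg + ident$reg_to_dist + ident$additional, 0)
  bad <- tibble::tibble(stage = c("early", "late"), count = c(1, 2))
  expect_error(upstaging_attribution(sq, bad), "stage sets")
})

test_that("attribution equals the sequential bookkeeping oracle", {
  oracle <- function(sq, sc) {
    d <- sapply(c("localised", "regional", "distant"), function(s) {
      sum(sc$count[sc$stage == s]) - sum(sq$count[sq$stage == s])
    })
    excess <- sum(d)                       # rule 1: additional at localised
    r2d <- max(d[["distant"]], 0)          # rule 2: distant excess
    l2r <- max(d[["regional"]] + r2d, 0)   # rule 3: residual lower-stage flow
    c(l2r = l2r, r2d = r2d, excess = excess)
  }
  for (s in 1:20) {
    tabs <- withr::with_seed(s, {
      sq <- tibble::tibble(stage = c("localised", "regional", "distant"),
                           count = sample(0:20, 3, TRUE))
      list(sq = sq,
           sc = dplyr::mutate(sq, count = pmax(count + sample(-3:5, 3, TRUE), 0)))
    })
    got <- upstaging_attribution(tabs$sq, tabs$sc)
    exp <- oracle(tabs$sq, tabs$sc)
    expect_equal(got$loc_to_reg, unname(exp[["l2r"]]))
    expect_equal(got$reg_to_dist, unname(exp[["r2d"]]))
    expect_equal(got$additional, unname(exp[["excess"]]))
  }
})

test_that("interval-12 cancers are a subset of interval-27 cancers", {
  for (prog in c("breast", "bowel")) {
    cls <- classify_detection_mode(cached_paired(prog, 0)$status_quo$events)
    expect_true(all(!cls$interval_12 | cls$interval_27))
    expect_lte(sum(cls$interval_12), sum(cls$interval_27))
  }
})

test_that("demand summaries count service volumes exactly", {
  ev <- dplyr::bind_rows(
    tibble::tibble(id = 1:3, month = 5L, type = "colonoscopy",
                   mode = "followup", outcome = "clear"),
    tibble::tibble(id = 4:5, month = 6L, type = "colonoscopy",
                   mode = "surveillance", outcome = "clear"),
    tibble::tibble(id = 6L, month = 7L, type = "colposcopy",
                   outcome = "clear")
  )
  d <- demand_summary(ev, c(0L, 12L))
  expect_equal(d$colonoscopies_followup, 3)
  expect_equal(d$colonoscopies_surveillance, 2)
  expect_equal(d$colonoscopies_programme, 5)
  expect_equal(d$colposcopies, 1)
  empty <- demand_summary(ev, c(20L, 30L))
  expect_true(all(unlist(empty) == 0))
})

test_that("outcome tables are zero-change against a paired self run", {
  pr <- cached_paired("bowel", 0)
  tab <- tabulate_outcomes(pr)
  expect_true(all(tab$change == 0))
  expect_true(all(tab$scenario == tab$status_quo))
  # count metrics rescale by the cohort scale factor
  kits <- tab[tab$metric == "screens_provided", ]
  expect_equal(kits$status_quo_rescaled, kits$status_quo / 0.002)
  # unpaired runs are rejected
  other <- cached_paired("breast", 0)
  expect_error(
    tabulate_outcomes(list(status_quo = pr$status_quo,
                           scenario = other$scenario)),
    "pair")
})

test_that("tidy, glance and autoplot methods cover run objects", {
  pr <- cached_paired("bowel", 6)
  expect_identical(tidy(pr$status_quo), pr$status_quo$events)
  g <- glance(pr$status_quo)
  expect_equal(g$screens, sum(pr$status_quo$events$type == "screen"))
  tt <- tidy(pr)
  expect_true(all(c("metric", "status_quo", "scenario") %in% names(tt)))
  gp <- glance(pr)
  expect_lt(gp$screens_pct_of_status_quo, 100)
  expect_s3_class(autoplot(pr$status_quo), "ggplot")
  expect_s3_class(autoplot(pr), "ggplot")
})
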