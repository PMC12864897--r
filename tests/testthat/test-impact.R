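seg_of <- function(groups) data.table::data.table(
  stay_id = "S", ward_id = "W", ward_group = groups,
  start_ts = ts_utc("2022-01-01") + seq_along(groups) * 3600,
  end_ts = ts_utc("2022-01-01") + (seq_along(groups) + 1) * 3600)

test_that("cohort rules assign and partition stays correctly", {
  expect_equal(assign_cohort(seg_of(c("MED", "GIS"))),
               "stays_limited_to_slhs")
  expect_equal(assign_cohort(seg_of(c("MED", "CONTROL"))),
               "stays_including_slhs")
  expect_equal(assign_cohort(seg_of("CONTROL")), "control")
  expect_equal(assign_cohort(seg_of(c("OTHER", "CONTROL"))), "other")
  expect_error(assign_cohort(seg_of(character(0))), "no ward segments")
  mem <- cohort_membership(small_registry())
  # limited is a subset of including; control and including disjoint
  expect_true(all(mem$including[mem$limited]))
  expect_false(any(mem$control & mem$including))
  expect_false(any(mem$limited & mem$control))
  expect_equal(nrow(mem), nrow(small_registry()$stays))
})

test_that("cohort indicators equal hand counts on a constructed fixture", {
  reg <- small_registry()
  mem <- cohort_membership(reg)
  pred <- data.table::data.table(stay_id = reg$stays$stay_id,
                                 cs_prob = 0, label = "NS",
                                 flagged = FALSE)
  set.seed(12)
  pred$flagged[sample.int(nrow(pred), 40)] <- TRUE
  ind <- cohort_indicators(reg, pred, run_config())
  cov <- slhs:::stay_covariates(reg, run_config())
  d <- merge(merge(cov, mem, by = "stay_id"), pred, by = "stay_id")
  for (r in sample(seq_len(nrow(ind)), 6)) {
    row <- ind[r]
    dd <- switch(row$cohort,
                 stays_including_slhs = d[d$including == TRUE],
                 stays_limited_to_slhs = d[d$limited == TRUE],
                 control = d[d$control == TRUE])
    dd <- dd[dd$year == row$year]
    expect_equal(row$n_stays, nrow(dd))
    expect_equal(row$pct_sepsis_coded, 100 * mean(dd$sepsis_coded))
    expect_equal(row$pct_flagged, 100 * mean(dd$flagged))
    if (!any(dd$flagged)) {
      expect_true(is.na(row$mort_inhosp_flagged))
    } else {
      expect_equal(row$mort_inhosp_flagged,
                   100 * mean(dd$in_hospital_death[dd$flagged]))
    }
  }
})

test_that("adjusted odds ratios behave under null and degenerate outcomes", {
  set.seed(19)
  n <- 2000
  d <- data.table::data.table(
    year = sample(2020:2024, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = round(runif(n, 20, 95)),
    charlson = rpois(n, 1.5))
  d$dead <- runif(n) < 0.1                 # independent of everything
  r <- adjusted_odds_ratio(d, "dead")
  expect_true(r$converged)
  expect_false(r$separation)
  expect_true(r$ci[1] <= 1 && 1 <= r$ci[2])
  expect_true(r$ci[1] <= r$or && r$or <= r$ci[2])
  d$never <- FALSE
  expect_error(adjusted_odds_ratio(d, "never"), "degenerate")
  expect_error(adjusted_odds_ratio(d, "absent_col"), "not found")
  # categorical-year variant runs and reports a contrast
  rc <- adjusted_odds_ratio(d, "dead", year_categorical = TRUE)
  expect_true(rc$or > 0)
})

test_that("propensity-matched time-to-antibiotics detects a planted pathway effect", {
  mk <- function(n, mean_h, group, seed) {
    set.seed(seed)
    data.table::data.table(
      stay_id = sprintf("%s%03d", group, 1:n), group = group,
      delay_h = rexp(n, 1 / mean_h),
      age = round(runif(n, 30, 90)),
      sex = sample(c("M", "F"), n, replace = TRUE),
      charlson = rpois(n, 1.5))
  }
  tta <- rbind(mk(120, 0.5, "pathway", 1), mk(120, 4, "control", 2))
  r1 <- tta_matched_comparison(tta, threshold_hours = 1)
  expect_gt(r1$prop_within["pathway"], r1$prop_within["control"])
  expect_lt(r1$p_value, 0.05)
  expect_equal(sum(r1$table), 2 * r1$n_pairs)
  # identical delay distributions: no systematic effect (seeded check)
  set.seed(33)
  ps <- replicate(40, {
    t2 <- rbind(mk(60, 2, "pathway", sample.int(1e6, 1)),
                mk(60, 2, "control", sample.int(1e6, 1)))
    tta_matched_comparison(t2, 1)$p_value
  })
  expect_gt(median(ps), 0.15)
  expect_gt(mean(ps > 0.05), 0.7)
  # antibiotic before onset counts as delay 0, within any threshold
  t3 <- rbind(mk(30, 1, "pathway", 4), mk(30, 1, "control", 5))
  t3$delay_h[1] <- 0
  r3 <- tta_matched_comparison(t3, 1)
  expect_true(r3$n_pairs > 0)
})

test_that("the delay convention floors pre-onset antibiotics at zero", {
  reg <- tiny_registry()
  # antibiotic at 10:00 precedes onset 20:00 -> delay 0
  tt <- tta_table(reg)
  expect_equal(tt$delay_h[tt$stay_id == "S1"], 0)
  expect_equal(tt$group[tt$stay_id == "S1"], "pathway")
})

test_that("reports are deterministic and mark uncomputed sections", {
  reg <- small_registry()
  pred <- data.table::data.table(stay_id = reg$stays$stay_id,
                                 cs_prob = runif(nrow(reg$stays)),
                                 label = "NS", flagged = FALSE)
  cfg <- run_config()
  imp <- impact_report(reg, pred, cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(imp, NULL, d1)
  write_report(imp, NULL, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "report.txt")),
                   readLines(file.path(d2, "report.txt")))
  js <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(js$evaluation$status, "not computed")
  expect_equal(js$impact$status, "computed")
  # impact fields mirrored one-to-one
  expect_setequal(names(js$impact$indicators[[1]]),
                  names(imp$indicators))
  expect_setequal(names(js$impact$odds_ratios[[1]]),
                  names(imp$odds_ratios))
})
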