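test_that("window grid resamples by last-value within half-open windows", {
  reg <- tiny_registry()
  g <- build_grid(reg, "S1")
  expect_equal(nrow(g), 20L)            # 5 days of 6-h windows
  expect_equal(g$window_index, 0:19)
  # observation at admit+5h lands in window 0; two HR values -> last wins
  expect_equal(g$hr[1], 100)            # 09:00 then 13:00 in window 0
  expect_true(all(is.na(g$hr[-1])))
  # unobserved concept entirely missing
  expect_false("platelets" %in% names(g) && any(!is.na(g$platelets)))
  # medication count lands in its window
  expect_equal(g$med_antibiotic[1], 1L)
  expect_equal(sum(g$med_antibiotic), 1L)
  expect_error(build_windows(reg, window_hours = 5), "divide 24")
})

test_that("rolling aggregates match closed-form oracles", {
  reg <- tiny_registry()
  # constant series: min = max = mean = last
  obs <- data.frame(stay_id = "S2", concept_id = "hr",
                    ts = ts_utc("2022-05-10 10:00") + (0:7) * 6 * 3600,
                    value = 77, unit = "/min")
  reg$observations <- data.table::as.data.table(obs)
  g <- build_grid(reg, "S2")
  ft <- rolling_features(g, reg,
                         feature_registry = data.frame(
                           concept_id = "hr",
                           aggregators = "last,min,max,mean,count,slope"))
  X <- ft$X
  k <- nrow(g)
  expect_equal(unname(X[k, "hr.last"]), 77)
  expect_equal(unname(X[k, "hr.min"]), 77)
  expect_equal(unname(X[k, "hr.max"]), 77)
  expect_equal(unname(X[k, "hr.mean"]), 77)
  expect_equal(unname(X[k, "hr.slope"]), 0)
  expect_equal(unname(X[k, "hr.count"]), 8)
  # count of an absent concept is 0
  ft2 <- rolling_features(g, reg, feature_registry = data.frame(
    concept_id = "lactate", aggregators = "count"))
  expect_true(all(ft2$X[, "lactate.count"] == 0))
  # slope equals the least-squares slope over window index
  obs$value <- c(1, 2, 3, 4, 5, 6, 7, 8)
  reg$observations <- data.table::as.data.table(obs)
  g <- build_grid(reg, "S2")
  ft3 <- rolling_features(g, reg, feature_registry = data.frame(
    concept_id = "hr", aggregators = "slope,mean"))
  ls_fit <- coef(lm(v ~ k, data.frame(v = obs$value, k = 0:7)))[2]
  expect_equal(unname(ft3$X[8, "hr.slope"]), unname(ls_fit))
  expect_gt(ft3$X[8, "hr.slope"], 0)
  # demographics appended: age at admission and male indicator
  expect_equal(unname(ft3$X[1, "age"]), 2022 - 1950)
  expect_equal(unname(ft3$X[1, "sex_male"]), 1)
})

test_that("feature dimension follows the registry formula and admission anchoring makes features shift-invariant", {
  reg <- small_registry()
  g <- build_windows(reg)
  fr <- default_feature_registry()
  ft <- rolling_features(g, reg, fr)
  expect_equal(ncol(ft$X), nrow(fr) * 6 + 2)
  expect_equal(ncol(ft$X), 242)         # ~240 clinical features + demographics
  # translate every timestamp by 3 whole days
  shift <- 3 * 86400
  reg2 <- reg
  for (tb in c("stays", "ward_segments", "observations", "medications",
               "events")) {
    for (cc in names(reg2[[tb]]))
      if (inherits(reg2[[tb]][[cc]], "POSIXct"))
        reg2[[tb]][[cc]] <- reg2[[tb]][[cc]] + shift
  }
  g2 <- build_windows(reg2)
  ft2 <- rolling_features(g2, reg2, fr)
  expect_equal(ft2$X[, setdiff(colnames(ft2$X), "age")],
               ft$X[, setdiff(colnames(ft$X), "age")])
})

test_that("sequence tensors are right-aligned with padding and honest masks", {
  reg <- tiny_registry()
  g <- build_grid(reg, "S1")
  m0 <- build_sequence(g, concepts = c("hr", "lactate"), k = 0)
  expect_equal(dim(m0), c(28L, 4L))
  # window 0: 27 pre-admission padded steps, one real step
  expect_equal(sum(m0[, "hr.mask"]), 1)
  expect_equal(unname(m0[28, "hr"]), 100)
  expect_true(all(m0[1:27, c("hr.mask", "lactate.mask")] == 0))
  # masks count exactly the observed (concept, step) pairs in span
  sq <- build_sequence(g, concepts = c("hr", "lactate"))
  mask_total <- sum(vapply(sq$steps, function(s)
    sum(s[, c("hr.mask", "lactate.mask")]), numeric(1)))
  # brute force: hr observed in window 0 for windows 0..19 (28-step span
  # always reaches back to admission), lactate in window 4
  expect_equal(mask_total, nrow(g) * 1 + sum(g$window_index >= 4))
  # imputation fills but never alters observed windows
  expect_equal(unname(sq$steps[[28]][1, "hr"]), 100)
  lac_w <- which(!is.na(g$lactate)) - 1
  expect_equal(unname(sq$steps[[28]][lac_w + 1, "lactate"]), 1.1)
})

test_that("forward fill stops at 48 h and falls back to population medians", {
  reg <- tiny_registry()
  g <- build_grid(reg, "S1")
  sq <- build_sequence(g, concepts = c("hr", "lactate"))
  last <- sq$steps[[28]]               # step aligned at each target window
  # hr observed in window 0 (value 100): windows 1..8 carried forward,
  # window 9+ (>48 h) median-imputed
  expect_equal(last[2:9, "hr"], rep(100, 8))
  expect_equal(unname(last[10, "hr"]), unname(sq$medians["hr"]))
  expect_equal(unname(last[10, "hr.mask"]), 0)
})
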