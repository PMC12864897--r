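normal_snapshot <- function(...) {
  args <- list(pf_ratio = 450, platelets = 250, bilirubin = 10, map = 85,
               vasopressor_class = "none", gcs = 15, creatinine = 70,
               rr = 16, spo2 = 97, on_oxygen = FALSE, temp = 37.0,
               sbp = 120, hr = 70, consciousness_impaired = FALSE)
  do.call(score_snapshot, modifyList(args, list(...)))
}

test_that("SOFA scores canonical band cases", {
  expect_equal(as.integer(sofa_total(normal_snapshot())), 0L)
  s <- sofa_total(normal_snapshot(platelets = 90))
  expect_equal(as.integer(s), 2L)
  expect_equal(attr(s, "subscores")[["coag"]], 2L)
  s <- sofa_total(normal_snapshot(gcs = 5))
  expect_equal(as.integer(s), 4L)
  expect_equal(attr(s, "subscores")[["cns"]], 4L)
  expect_equal(as.integer(sofa_total(normal_snapshot(
    vasopressor_class = "high"))), 4L)
  expect_equal(as.integer(sofa_total(normal_snapshot(map = 60))), 1L)
  # missing organs score 0 and are counted
  s <- sofa_total(score_snapshot(platelets = 40))
  expect_equal(as.integer(s), 3L)
  expect_equal(attr(s, "n_imputed"), 5L)
  expect_error(score_snapshot(gcs = 17), "gcs")
  expect_error(score_snapshot(spo2 = 102), "spo2")
})

test_that("NEWS2 scores canonical band cases", {
  expect_equal(as.integer(news2_score(normal_snapshot())), 0L)
  expect_equal(as.integer(news2_score(normal_snapshot(rr = 25))), 3L)
  expect_equal(as.integer(news2_score(normal_snapshot(sbp = 85))), 3L)
  expect_equal(as.integer(news2_score(normal_snapshot(on_oxygen = TRUE))), 2L)
  expect_equal(as.integer(news2_score(normal_snapshot(
    consciousness_impaired = TRUE))), 3L)
  expect_equal(as.integer(news2_score(normal_snapshot(temp = 35.0))), 3L)
})

test_that("worsening a single input never decreases SOFA or NEWS2", {
  set.seed(31)
  worse <- list(platelets = -20, bilirubin = 30, map = -8, creatinine = 60,
                gcs = -2, pf_ratio = -50)
  for (i in 1:200) {
    snap <- random_snapshot()
    v <- names(worse)[sample.int(length(worse), 1)]
    if (is.na(snap[[v]])) next
    s0 <- as.integer(sofa_total(snap))
    snap2 <- snap
    snap2[[v]] <- max(snap[[v]] + worse[[v]],
                      c(platelets = 5, bilirubin = 0, map = 10,
                        creatinine = 1, gcs = 3, pf_ratio = 1)[[v]])
    expect_gte(as.integer(sofa_total(snap2)), s0)
  }
  # heart-rate banding is U-shaped: worsening means moving away from the
  # normal band, here tested in the tachycardic direction
  for (i in 1:200) {
    snap <- random_snapshot()
    if (is.na(snap$hr) || snap$hr < 51) next
    s0 <- as.integer(news2_score(snap))
    snap2 <- snap; snap2$hr <- min(snap$hr + 25, 350)
    expect_gte(as.integer(news2_score(snap2)), s0)
  }
})

test_that("Charlson index follows weights, hierarchy and is duplication-invariant", {
  expect_equal(as.integer(charlson_index(character(0))), 0L)
  expect_equal(as.integer(charlson_index(c("I21", "E119"))), 2L)
  expect_equal(as.integer(charlson_index("C780")), 6L)
  # hierarchy: metastatic supersedes malignancy, severe liver mild liver
  expect_equal(as.integer(charlson_index(c("C189", "C780"))), 6L)
  expect_equal(as.integer(charlson_index(c("K703", "K721"))), 3L)
  expect_equal(as.integer(charlson_index(c("E119", "E112"))), 2L)
  # duplication and order invariance; unknown codes ignored
  expect_equal(charlson_index(c("I21", "I21", "E119", "ZZZ9")),
               charlson_index(c("E119", "I21")))
  # dotted codes accepted
  expect_equal(as.integer(charlson_index("I25.2")), 1L)
})

test_that("delta-SOFA computes baseline-to-peak increase with missing markers", {
  admit <- ts_utc("2022-01-01 00:00")
  disc <- ts_utc("2022-01-06 00:00")
  t0 <- ts_utc("2022-01-02 12:00")
  base_obs <- data.table::data.table(
    stay_id = "S", concept_id = rep(c("platelets", "creatinine",
                                      "bilirubin", "map", "gcs"), each = 2),
    ts = rep(c(admit + 3600, t0 + 7200), 5),
    value = c(250, 80, 80, 250, 10, 10, 85, 85, 15, 15),
    unit = "u")
  d <- delta_sofa(base_obs, t0, c(admit, disc))
  # baseline 0; post: platelets 80 (coag 2) + creatinine 250 (renal 2)
  expect_false(d$missing)
  expect_equal(d$baseline, 0L)
  expect_equal(d$delta, 4L)
  # no post-onset data at all -> missing, never zero
  pre_only <- base_obs[ts <= t0]
  d2 <- delta_sofa(pre_only, t0, c(admit, disc))
  expect_true(d2$missing)
  expect_true(is.na(d2$delta))
  # too few organs observed -> missing
  thin <- base_obs[concept_id %in% c("map", "gcs")]
  d3 <- delta_sofa(thin, t0, c(admit, disc))
  expect_true(d3$missing)
  expect_error(delta_sofa(base_obs, disc + 60, c(admit, disc)), "outside")
})

test_that("vasopressor activity raises the cardiovascular subscore", {
  admit <- ts_utc("2022-01-01 00:00")
  disc <- ts_utc("2022-01-04 00:00")
  t0 <- ts_utc("2022-01-02 00:00")
  obs <- data.table::data.table(
    stay_id = "S", concept_id = rep(c("platelets", "creatinine",
                                      "bilirubin", "map", "gcs"), each = 2),
    ts = rep(c(admit + 3600, t0 + 7200), 5),
    value = c(250, 250, 80, 80, 10, 10, 85, 85, 15, 15), unit = "u")
  med <- data.table::data.table(stay_id = "S", drug_class = "vasopressor",
                                admin_ts = t0 + 3600)
  d <- delta_sofa(obs, t0, c(admit, disc), medications = med)
  expect_equal(d$delta, 2L)
})
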