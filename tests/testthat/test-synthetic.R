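test_that("identical configurations generate identical registries", {
  cfg <- generator_config(n_stays = 80, seed = 13)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  for (tb in c("patients", "stays", "ward_segments", "observations",
               "medications", "events", "icd_codes"))
    expect_identical(as.data.frame(r1[[tb]]), as.data.frame(r2[[tb]]),
                     info = tb)
  expect_equal(nrow(r1$stays), 80L)
})

test_that("zero prevalence yields an event-free registry", {
  reg <- generate_registry(generator_config(n_stays = 40,
                                            sepsis_prevalence = 0,
                                            seed = 3))
  expect_equal(nrow(reg$events), 0L)
  expect_true(all(window_labels(reg, build_windows(reg)) == "NS"))
})

test_that("generated registries satisfy the structural invariants", {
  reg <- small_registry()
  expect_silent(validate_registry(reg))
  # in-hospital death implies 90-day death (death_ts within stay)
  st <- reg$stays
  ih <- st[st$in_hospital_death == TRUE]
  expect_true(all(!is.na(ih$death_ts)))
  expect_true(all(as.numeric(ih$death_ts - ih$admit_ts,
                             units = "days") <= 90))
})

test_that("every injected label is recovered from the generated facts", {
  # force all six labels to appear
  reg <- generate_registry(generator_config(
    n_stays = 250, sepsis_prevalence = 0.25, seed = 21,
    label_mix = c("0_no_infection" = 1 / 6, "0_infection" = 1 / 6,
                  "1a_sepsis_like" = 1 / 6, "1b_sepsis_sensu_lato" = 1 / 6,
                  "2a_sepsis_sensu_stricto" = 1 / 6,
                  "2b_septic_shock" = 1 / 6)))
  expect_setequal(unique(reg$events$fine_label), fine_label_levels())
  for (i in seq_len(nrow(reg$events))) {
    f <- derive_event_facts(reg, reg$events[i])
    expect_equal(classify_event(f), reg$events$fine_label[i],
                 info = reg$events$event_id[i])
  }
})

test_that("septic-shock injection forces vasopressor and lactate facts", {
  reg <- small_registry()
  shock <- reg$events[reg$events$fine_label == "2b_septic_shock"]
  expect_gt(nrow(shock), 0)
  for (i in seq_len(nrow(shock))) {
    sid <- shock$stay_id[i]; t0 <- shock$t0[i]
    med <- reg$medications[reg$medications$stay_id == sid]
    expect_true(any(med$drug_class == "vasopressor" & med$admin_ts >= t0))
    lac <- reg$observations[
      reg$observations$stay_id == sid &
        reg$observations$concept_id == "lactate" &
        reg$observations$ts >= t0]
    expect_gt(max(lac$value), 2.0)
  }
  # infection without sepsis keeps delta-SOFA < 2
  noinf <- reg$events[reg$events$fine_label == "0_infection"]
  for (i in seq_len(nrow(noinf))) {
    st <- reg$stays[reg$stays$stay_id == noinf$stay_id[i]]
    d <- delta_sofa(reg$observations[reg$observations$stay_id == st$stay_id],
                    noinf$t0[i], c(st$admit_ts, st$discharge_ts),
                    reg$medications[reg$medications$stay_id == st$stay_id])
    expect_false(d$missing)
    expect_lt(d$delta, 2)
  }
  # sensu stricto forces delta-SOFA >= 2 when recomputed
  strict <- reg$events[reg$events$fine_label == "2a_sepsis_sensu_stricto"]
  for (i in seq_len(nrow(strict))) {
    st <- reg$stays[reg$stays$stay_id == strict$stay_id[i]]
    d <- delta_sofa(reg$observations[reg$observations$stay_id == st$stay_id],
                    strict$t0[i], c(st$admit_ts, st$discharge_ts),
                    reg$medications[reg$medications$stay_id == st$stay_id])
    expect_gte(d$delta, 2)
  }
})

test_that("ICD coding sensitivity hits its binomial band", {
  set.seed(17)
  n <- 600
  stays <- data.table::data.table(stay_id = sprintf("S%04d", 1:n))
  events <- data.table::data.table(
    event_id = sprintf("E%04d", 1:n), stay_id = stays$stay_id,
    fine_label = "2a_sepsis_sensu_stricto")
  cfg <- generator_config(icd_sensitivity = 1, icd_fp_rate = 0)
  codes <- assign_icd_codes(stays, events, cfg)
  coded <- vapply(stays$stay_id, function(s)
    has_sepsis_code(codes$code[codes$stay_id == s]), logical(1))
  expect_true(all(coded))
  cfg0 <- generator_config(icd_sensitivity = 0, icd_fp_rate = 0)
  codes0 <- assign_icd_codes(stays, events, cfg0)
  coded0 <- vapply(stays$stay_id, function(s)
    has_sepsis_code(codes0$code[codes0$stay_id == s]), logical(1))
  expect_false(any(coded0))
})

test_that("intercept-only mortality recovers its configured rate", {
  set.seed(23)
  n <- 1000
  tab <- data.table::data.table(
    stay_id = sprintf("S%04d", 1:n),
    admit_ts = ts_utc("2022-01-01") + 1:n,
    discharge_ts = ts_utc("2022-01-05") + 1:n,
    age = 65, year_index = 0, sepsis_cs = FALSE, timely = FALSE)
  cfg <- generator_config(
    mortality_inhosp = c(intercept = 0, sepsis = 0, age = 0, year = 0,
                         timely = 0),
    mortality_90d = c(intercept = -30, sepsis = 0, age = 0, year = 0,
                      timely = 0))
  out <- simulate_outcomes(tab, cfg)
  p_hat <- mean(out$in_hospital_death)
  band <- qnorm(0.995) * sqrt(0.25 / n)     # 99% binomial interval at 0.5
  expect_lt(abs(p_hat - 0.5), band)
  # zero-probability model produces no deaths
  cfg0 <- generator_config(
    mortality_inhosp = c(intercept = -30, sepsis = 0, age = 0, year = 0,
                         timely = 0),
    mortality_90d = c(intercept = -30, sepsis = 0, age = 0, year = 0,
                      timely = 0))
  out0 <- simulate_outcomes(tab, cfg0)
  expect_false(any(out0$in_hospital_death))
  expect_true(all(is.na(out0$death_ts)))
})

test_that("configuration bounds are enforced", {
  expect_error(generator_config(sepsis_prevalence = 1.4), "probabilities")
  expect_error(generator_config(calendar_years = 0.5), "calendar")
  expect_error(generator_config(ward_mix = c(control = 0.5,
                                             slhs_only = 0.2,
                                             mixed = 0.2, other = 0.2)),
               "sum to 1")
  expect_error(generate_registry(list(n_stays = 10)), "generator_config")
})
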