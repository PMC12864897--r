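# Synthetic multi-ward EHR registry generator.
#
# Emulates the statistical structure the pipeline assumes: multi-year
# calendar, ward transfer structure, vitals/labs at realistic sampling
# intervals, clinician-adjudicated sepsis events whose supporting facts are
# consistent with the six-level label logic, under-sensitive ICD coding,
# and mortality / time-to-antibiotics processes with configurable period
# effects.

#' Generator configuration
#'
#' Defaults define the reference study conditions: 2000 stays over a
#' 2020--2024 calendar, 10% of stays carrying one adjudicated sepsis event,
#' ICD sepsis-coding sensitivity 0.833 for confirmed sepsis, a per-year
#' mortality odds ratio of 0.85, and antibiotic delays of mean 0.5 h for
#' pathway (order-set) events versus 4 h otherwise.
#'
#' @param n_stays Number of stays to generate.
#' @param stays_per_patient_mean Mean stays per patient (patients are
#'   derived from this ratio).
#' @param calendar_start Calendar origin (date string).
#' @param calendar_years Calendar span in years (>= 1).
#' @param los_meanlog,los_sdlog Log-normal length-of-stay parameters (days).
#' @param los_min_days,los_max_days Truncation of length of stay.
#' @param ward_mix Named probabilities for stay types `control`,
#'   `slhs_only`, `mixed`, `other`; must sum to 1.
#' @param emd_first_frac Fraction of program-ward stays that start in EMD.
#' @param sepsis_prevalence Fraction of stays with one adjudicated event.
#' @param label_mix Named probabilities over the six fine labels.
#' @param episode_recovery_hours Exponential-recovery horizon of the
#'   physiologic perturbation after onset.
#' @param icd_sensitivity P(sepsis ICD code | confirmed sepsis stay).
#' @param icd_ps_rate P(sepsis ICD code | possible sepsis stay).
#' @param icd_fp_rate P(sepsis ICD code | other stay).
#' @param mortality_inhosp,mortality_90d Named coefficient vectors
#'   (`intercept`, `sepsis`, `age`, `year`, `timely`) of the logistic
#'   outcome models; `year` is per calendar year since the origin, `age`
#'   per year of age centred at 65, `timely` the effect of an antibiotic
#'   within 1 h of onset.
#' @param abx_delay_pathway_mean,abx_delay_other_mean Exponential means (h)
#'   of onset-to-antibiotic delay for order-set vs consult events.
#' @param orderset_frac Fraction of events documented via the order set.
#' @param background_abx_rate Fraction of event-free stays with an
#'   incidental antibiotic.
#' @param n_aux_labs Number of uninformative auxiliary laboratory channels.
#' @param seed Integer seed; identical configs generate identical registries.
#' @return A `slhs_generator_config` list.
#' @export
generator_config <- function(n_stays = 2000L,
                             stays_per_patient_mean = 1.7,
                             calendar_start = "2020-01-01",
                             calendar_years = 5L,
                             los_meanlog = log(5), los_sdlog = 0.8,
                             los_min_days = 0.5, los_max_days = 30,
                             ward_mix = c(control = 0.20, slhs_only = 0.45,
                                          mixed = 0.20, other = 0.15),
                             emd_first_frac = 0.5,
                             sepsis_prevalence = 0.10,
                             label_mix = c("0_no_infection" = 0.11,
                                           "0_infection" = 0.11,
                                           "1a_sepsis_like" = 0.20,
                                           "1b_sepsis_sensu_lato" = 0.13,
                                           "2a_sepsis_sensu_stricto" = 0.30,
                                           "2b_septic_shock" = 0.15),
                             episode_recovery_hours = 72,
                             icd_sensitivity = 0.833,
                             icd_ps_rate = 0.355,
                             icd_fp_rate = 0.005,
                             mortality_inhosp = c(intercept = -4.2,
                                                  sepsis = 2.2, age = 0.02,
                                                  year = log(0.85),
                                                  timely = -0.3),
                             mortality_90d = c(intercept = -3.2,
                                               sepsis = 1.2, age = 0.03,
                                               year = log(0.9),
                                               timely = -0.2),
                             abx_delay_pathway_mean = 0.5,
                             abx_delay_other_mean = 4,
                             orderset_frac = 0.7,
                             background_abx_rate = 0.2,
                             n_aux_labs = 28L,
                             seed = 42L) {
  cfg <- as.list(environment())
  probs <- c(cfg$ward_mix, cfg$sepsis_prevalence, cfg$label_mix,
             cfg$icd_sensitivity, cfg$icd_ps_rate, cfg$icd_fp_rate,
             cfg$emd_first_frac, cfg$orderset_frac, cfg$background_abx_rate)
  if (any(probs < 0 | probs > 1)) .stopf("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$ward_mix) - 1) > 1e-8) .stopf("ward_mix must sum to 1")
  if (abs(sum(cfg$label_mix) - 1) > 1e-8) .stopf("label_mix must sum to 1")
  if (cfg$calendar_years < 1) .stopf("calendar span must be >= 1 year")
  if (!setequal(names(cfg$label_mix), fine_label_levels()))
    .stopf("label_mix must name all six fine labels")
  structure(cfg, class = "slhs_generator_config")
}

# Concept sampling design: set-point mean/sd between patients, within-stay
# noise, sampling interval (h). Vitals ~4 h, labs ~24 h.
.physiology <- function(n_aux_labs) {
  base <- data.table(
    concept_id = c("hr", "rr", "sbp", "map", "temp", "spo2", "gcs",
                   "platelets", "bilirubin", "creatinine", "lactate",
                   "pf_ratio"),
    mean = c(78, 16, 122, 88, 36.8, 96.5, 15, 250, 10, 80, 1.2, 440),
    sd_between = c(7, 1.5, 9, 5, 0.2, 1, 0, 30, 3, 10, 0.15, 25),
    sd_within = c(6, 1.5, 8, 4, 0.25, 1, 0, 15, 2, 6, 0.15, 15),
    interval_h = c(4, 4, 4, 4, 4, 4, 8, 24, 24, 24, 24, 24),
    unit = c("/min", "/min", "mmHg", "mmHg", "degC", "%", "score",
             "1e9/L", "umol/L", "umol/L", "mmol/L", "mmHg"),
    presence = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0.3))
  if (n_aux_labs > 0) {
    aux <- data.table(concept_id = sprintf("lab%02d", seq_len(n_aux_labs)),
                      mean = 100, sd_between = 10, sd_within = 8,
                      interval_h = 24, unit = "au", presence = 0.9)
    base <- rbind(base, aux)
  }
  base
}

# Clamp helper keeping physiologic values positive and plausible.
.phys_clamp <- function(dt) {
  cl <- function(cid, lo, hi) dt[concept_id == cid,
                                 value := pmin(pmax(value, lo), hi)]
  cl("hr", 30, 220); cl("rr", 6, 60); cl("sbp", 50, 250); cl("map", 35, 160)
  cl("temp", 33, 42.5); cl("spo2", 60, 100); cl("gcs", 3, 15)
  cl("platelets", 5, 1200); cl("bilirubin", 1, 600); cl("creatinine", 20, 1200)
  cl("lactate", 0.3, 18); cl("pf_ratio", 40, 600)
  invisible(dt)
}

# Concepts whose post-onset values must stay normal for labels that demand
# delta-SOFA < 2 (values clamped into score-0 bands).
.sofa_normal_bounds <- data.table(
  concept_id = c("platelets", "bilirubin", "creatinine", "map", "gcs",
                 "pf_ratio"),
  lo = c(160, 1, 20, 72, 15, 410),
  hi = c(1200, 18, 105, 160, 15, 600))

#' Inject a sepsis episode into one stay's data
#'
#' Perturbs the stay's observation series after onset so that the injected
#' fine label's defining facts hold when re-derived from the data:
#' delta-SOFA >= 2 labels receive explicit post-onset organ-dysfunction
#' laboratory values (platelets 80, creatinine 250); delta-SOFA < 2 labels
#' have their post-onset score-relevant values clamped into normal bands;
#' the missing-SOFA variant of the sepsis-like label removes the stay's
#' SOFA laboratory series entirely; septic shock adds a vasopressor
#' administration and a lactate above 2 mmol/L after onset. Vitals (heart
#' and respiratory rate, temperature, blood pressure, saturation) take a
#' severity-scaled step at onset with exponential recovery.
#'
#' @param obs Observation rows of the stay.
#' @param med Medication rows of the stay.
#' @param stay One row of the stays table.
#' @param fine_label Injected fine label.
#' @param t0 Onset time, inside the stay.
#' @param config A [generator_config()].
#' @param sofa_missing For the sepsis-like label, use the missing-SOFA
#'   variant rather than the organ-failure-with-small-delta variant.
#' @return List with modified `obs`, `med`, and the clinician-form fields
#'   `infection`, `organ_failure`, `alt_etiology`.
#' @export
inject_sepsis_episode <- function(obs, med, stay, fine_label, t0, config,
                                  sofa_missing = FALSE) {
  if (t0 < stay$admit_ts || t0 >= stay$discharge_ts)
    .stopf("t0 outside the stay interval")
  obs <- copy(obs); med <- copy(med)
  lvl <- fine_label
  sev <- c("0_no_infection" = 0.2, "0_infection" = 0.4,
           "1a_sepsis_like" = 0.6, "1b_sepsis_sensu_lato" = 1.0,
           "2a_sepsis_sensu_stricto" = 1.0, "2b_septic_shock" = 1.3)[lvl]
  rec_h <- config$episode_recovery_hours
  tnum <- as.numeric(obs$ts); t0n <- as.numeric(t0)
  post <- tnum >= t0n & tnum < t0n + .hrs(rec_h)
  decay <- exp(-pmax(tnum - t0n, 0) / .hrs(rec_h / 3))
  bump <- function(cid, delta) {
    i <- post & obs$concept_id == cid
    obs[i, value := value + delta * sev * decay[i]]
  }
  if (lvl != "0_no_infection") {
    bump("hr", 32); bump("rr", 9); bump("temp", 1.8)
    bump("sbp", -24); bump("spo2", -4)
  }
  .phys_clamp(obs)

  needs_delta2 <- lvl %in% c("1b_sepsis_sensu_lato", "2a_sepsis_sensu_stricto",
                             "2b_septic_shock")
  sofa_cids <- .sofa_normal_bounds$concept_id
  # normal baseline before onset for every event stay
  pre <- as.numeric(obs$ts) < t0n
  for (r in seq_len(nrow(.sofa_normal_bounds))) {
    b <- .sofa_normal_bounds[r]
    i <- pre & obs$concept_id == b$concept_id
    obs[i, value := pmin(pmax(value, b$lo), b$hi)]
  }
  if (lvl == "1a_sepsis_like" && sofa_missing) {
    obs <- obs[!concept_id %in% c("platelets", "bilirubin", "creatinine",
                                  "pf_ratio")]
  } else if (needs_delta2) {
    # organ dysfunction must dominate the full assessment window: clamp the
    # natural post-onset series too, or carried-forward normal values could
    # mask the dysfunction at later assessment points
    win <- as.numeric(obs$ts) >= t0n & as.numeric(obs$ts) < t0n + .hrs(72)
    obs[win & concept_id == "platelets", value := pmin(value, 85)]
    obs[win & concept_id == "creatinine", value := pmax(value, 245)]
    add <- data.table(stay_id = stay$stay_id,
                      concept_id = c("platelets", "creatinine"),
                      ts = t0 + .hrs(2), value = c(80, 250),
                      unit = c("1e9/L", "umol/L"))
    obs <- rbind(obs, add)
  } else {
    # delta-SOFA must stay < 2: clamp post-onset score inputs into normal
    # bands and guarantee one valid post-onset assessment
    postn <- as.numeric(obs$ts) >= t0n
    for (r in seq_len(nrow(.sofa_normal_bounds))) {
      b <- .sofa_normal_bounds[r]
      i <- postn & obs$concept_id == b$concept_id
      obs[i, value := pmin(pmax(value, b$lo), b$hi)]
    }
    add <- data.table(stay_id = stay$stay_id,
                      concept_id = c("platelets", "creatinine", "bilirubin"),
                      ts = t0 + .hrs(2), value = c(250, 80, 10),
                      unit = c("1e9/L", "umol/L", "umol/L"))
    obs <- rbind(obs, add)
  }
  # lactate and vasopressors: only septic shock carries both facts
  if (lvl == "2b_septic_shock") {
    obs <- rbind(obs, data.table(stay_id = stay$stay_id,
                                 concept_id = "lactate", ts = t0 + .hrs(2),
                                 value = 3.5, unit = "mmol/L"))
    med <- rbind(med, data.table(stay_id = stay$stay_id,
                                 drug_class = "vasopressor",
                                 admin_ts = t0 + .hrs(1)))
  } else {
    i <- as.numeric(obs$ts) >= t0n & obs$concept_id == "lactate"
    obs[i, value := pmin(value, 1.8)]
    med <- med[drug_class != "vasopressor"]
  }
  setorder(obs, concept_id, ts)
  list(obs = obs, med = med,
       infection = lvl != "0_no_infection",
       organ_failure = needs_delta2 ||
         (lvl == "1a_sepsis_like" && !sofa_missing),
       alt_etiology = lvl == "1b_sepsis_sensu_lato")
}

#' Assign ICD-10 codes to stays
#'
#' Confirmed-sepsis stays receive a sepsis code with probability
#' `icd_sensitivity` (the under-coding the registry exhibits), possible
#' sepsis stays with `icd_ps_rate`, all other stays with `icd_fp_rate`.
#' Comorbidity codes are drawn per stay from representative codes of the
#' Charlson categories to support index computation.
#'
#' @param stays Stays table.
#' @param events Events table (for per-stay coarse labels).
#' @param config A [generator_config()]; its `icd_*` fields are used.
#' @return data.table (`stay_id`, `code`).
#' @export
assign_icd_codes <- function(stays, events, config) {
  coarse <- rep("NS", nrow(stays))
  if (nrow(events) > 0) {
    ev <- events[, .(sev = max(fine_severity(fine_label))), by = stay_id]
    m <- match(stays$stay_id, ev$stay_id)
    coarse[!is.na(m)] <- collapse_label(fine_label_levels()[ev$sev[m[!is.na(m)]]])
  }
  p <- ifelse(coarse == "CS", config$icd_sensitivity,
              ifelse(coarse == "PS", config$icd_ps_rate, config$icd_fp_rate))
  sep <- runif(nrow(stays)) < p
  out <- list(data.table(stay_id = stays$stay_id[sep],
                         code = sample(c("A419", "A412", "R652", "R572"),
                                       sum(sep), replace = TRUE,
                                       prob = c(0.6, 0.1, 0.25, 0.05))))
  comorb <- data.table(
    code = c("I21", "I500", "I702", "I639", "F03", "J449", "M059", "K259",
             "K703", "E119", "E112", "G811", "N183", "C189", "K721",
             "C780", "B20"),
    prob = c(0.075, 0.13, 0.05, 0.07, 0.11, 0.11, 0.02, 0.01, 0.04, 0.11,
             0.03, 0.02, 0.13, 0.13, 0.015, 0.08, 0.03))
  for (r in seq_len(nrow(comorb))) {
    has <- runif(nrow(stays)) < comorb$prob[r]
    out[[length(out) + 1L]] <- data.table(stay_id = stays$stay_id[has],
                                          code = comorb$code[r])
  }
  rbindlist(out)[order(stay_id, code)]
}

#' Simulate mortality outcomes
#'
#' In-hospital death is drawn from a logistic model on confirmed-sepsis
#' status, age (centred at 65), calendar year since the origin and
#' antibiotic timeliness; among survivors, death by day 90 from admission
#' is drawn from a second logistic model. In-hospital death implies 90-day
#' death.
#'
#' @param stay_tab data.table with columns `stay_id`, `admit_ts`,
#'   `discharge_ts`, `age`, `year_index`, `sepsis_cs` (logical), `timely`
#'   (logical).
#' @param config A [generator_config()].
#' @return `stay_tab` with `in_hospital_death`, `death_ts` added.
#' @export
simulate_outcomes <- function(stay_tab, config) {
  co <- config$mortality_inhosp
  lp <- co["intercept"] + co["sepsis"] * stay_tab$sepsis_cs +
    co["age"] * (stay_tab$age - 65) + co["year"] * stay_tab$year_index +
    co["timely"] * stay_tab$timely
  died_ih <- runif(nrow(stay_tab)) < plogis(lp)
  co9 <- config$mortality_90d
  lp9 <- co9["intercept"] + co9["sepsis"] * stay_tab$sepsis_cs +
    co9["age"] * (stay_tab$age - 65) + co9["year"] * stay_tab$year_index +
    co9["timely"] * stay_tab$timely
  died_90 <- !died_ih & runif(nrow(stay_tab)) < plogis(lp9)
  out <- copy(stay_tab)
  out[, in_hospital_death := died_ih]
  out[, death_ts := as.POSIXct(NA_real_, tz = "UTC",
                               origin = "1970-01-01")]
  out[died_ih == TRUE, death_ts := discharge_ts - 60]
  if (any(died_90)) {
    los_d <- as.numeric(out$discharge_ts - out$admit_ts, units = "days")
    extra <- runif(nrow(out), pmin(los_d + 0.5, 89), 90)
    out[died_90 == TRUE,
        death_ts := admit_ts + extra[died_90] * 86400]
  }
  out
}

#' Generate a synthetic sepsis registry
#'
#' Draws patients, stays, ward segments, vitals and laboratory series,
#' injects adjudicated sepsis events label-consistently, administers
#' antibiotics with pathway-dependent delays, assigns under-sensitive ICD
#' coding, and simulates mortality with a configurable period effect.
#' Identical configurations (including seed) produce identical registries.
#'
#' @param config A [generator_config()].
#' @return A validated `slhs_registry`.
#' @export
generate_registry <- function(config = generator_config()) {
  if (!inherits(config, "slhs_generator_config"))
    .stopf("config must come from generator_config()")
  set.seed(config$seed)
  n <- config$n_stays
  n_pat <- max(1L, as.integer(round(n / config$stays_per_patient_mean)))
  patients <- data.table(
    patient_id = sprintf("P%05d", seq_len(n_pat)),
    sex = sample(c("M", "F"), n_pat, replace = TRUE, prob = c(0.53, 0.47)),
    birth_year = as.integer(round(2024 - pmin(pmax(rnorm(n_pat, 67, 16),
                                                   18), 100))))

  cal0 <- .ts(paste0(config$calendar_start, " 00:00:00"))
  span_s <- config$calendar_years * 365.25 * 86400
  los_d <- pmin(pmax(rlnorm(n, config$los_meanlog, config$los_sdlog),
                     config$los_min_days), config$los_max_days)
  admit <- cal0 + round(runif(n, 0, span_s - los_d * 86400) / 60) * 60
  stays <- data.table(
    stay_id = sprintf("S%05d", seq_len(n)),
    patient_id = sample(patients$patient_id, n, replace = TRUE),
    admit_ts = admit,
    discharge_ts = admit + round(los_d * 1440) * 60)

  # ward segments
  stype <- sample(names(config$ward_mix), n, replace = TRUE,
                  prob = config$ward_mix)
  seg_list <- vector("list", n)
  slhs_groups <- c("MED", "GIS", "EMD")
  for (i in seq_len(n)) {
    k <- sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
    if (stype[i] == "mixed") k <- max(k, 2L)
    groups <- switch(stype[i],
      control = rep("CONTROL", k),
      other = rep("OTHER", k),
      slhs_only = {
        g <- sample(slhs_groups, k, replace = TRUE)
        if (runif(1) < config$emd_first_frac) g[1] <- "EMD"
        g
      },
      mixed = {
        g <- sample(c(slhs_groups, "OTHER", "CONTROL"), k, replace = TRUE)
        g[1] <- sample(slhs_groups, 1)
        g[2] <- sample(c("OTHER", "CONTROL"), 1)
        sample(g)
      })
    cuts <- sort(runif(k - 1, 0.2, 0.8))
    frac <- diff(c(0, cuts, 1))
    los_s <- as.numeric(stays$discharge_ts[i] - stays$admit_ts[i],
                        units = "secs")
    bounds <- round(cumsum(c(0, frac)) * los_s / 60) * 60
    bounds[k + 1] <- los_s
    bounds <- cummax(bounds)
    keep <- which(bounds[seq_len(k) + 1] > bounds[seq_len(k)])
    seg_list[[i]] <- data.table(
      stay_id = stays$stay_id[i],
      ward_id = paste0(substr(groups[keep], 1, 1), sample(10:39, length(keep), TRUE)),
      ward_group = groups[keep],
      start_ts = stays$admit_ts[i] + bounds[keep],
      end_ts = stays$admit_ts[i] + bounds[keep + 1])
  }
  ward_segments <- rbindlist(seg_list)
  ward_segments <- ward_segments[end_ts > start_ts]

  # observations
  phys <- .physiology(config$n_aux_labs)
  los_h <- as.numeric(stays$discharge_ts - stays$admit_ts, units = "hours")
  obs_list <- vector("list", nrow(phys))
  for (r in seq_len(nrow(phys))) {
    p <- phys[r]
    present <- runif(n) < p$presence
    nrep <- ifelse(present, pmax(1L, ceiling(los_h / p$interval_h)), 0L)
    idx <- rep(seq_len(n), nrep)
    seqs <- sequence(nrep)
    setp <- p$mean + rnorm(n, 0, p$sd_between)
    ts <- stays$admit_ts[idx] +
      round(((seqs - 1) * p$interval_h +
               runif(length(idx), 0.05, 0.95 * p$interval_h)) * 60) * 60
    val <- setp[idx] + rnorm(length(idx), 0, p$sd_within)
    if (p$concept_id == "gcs")
      val <- ifelse(runif(length(idx)) < 0.97, 15, 14)
    keep <- ts < stays$discharge_ts[idx] & ts >= stays$admit_ts[idx]
    obs_list[[r]] <- data.table(stay_id = stays$stay_id[idx][keep],
                                concept_id = p$concept_id,
                                ts = ts[keep],
                                value = round(val[keep], 2),
                                unit = p$unit)
  }
  observations <- rbindlist(obs_list)
  .phys_clamp(observations)

  # antibiotic background
  med_bg <- {
    has <- runif(n) < config$background_abx_rate
    idx <- which(has)
    data.table(stay_id = stays$stay_id[idx],
               drug_class = "antibiotic",
               admin_ts = stays$admit_ts[idx] +
                 round(runif(length(idx), 1, pmax(2, los_h[idx] - 1)) * 60) * 60)
  }
  medications <- med_bg[!is.na(admin_ts)]

  # events: one per selected stay, onset early in the stay
  eligible <- which(los_h >= 24)
  n_ev <- min(round(config$sepsis_prevalence * n), length(eligible))
  ev_stay <- sort(sample(eligible, n_ev))
  events <- NULL
  if (n_ev > 0) {
    lab <- sample(names(config$label_mix), n_ev, replace = TRUE,
                  prob = config$label_mix)
    t0_off <- pmin(pmax(rexp(n_ev, 1 / 36), 2), (los_h[ev_stay] - 14))
    t0 <- stays$admit_ts[ev_stay] + round(t0_off * 60) * 60
    missing_variant <- runif(n_ev) < 0.5
    src <- ifelse(runif(n_ev) < config$orderset_frac, "orderset",
                  "id_consult")
    ev_rows <- vector("list", n_ev)
    setkey(observations, stay_id)
    setkey(medications, stay_id)
    new_obs <- vector("list", n_ev)
    new_med <- vector("list", n_ev)
    for (j in seq_len(n_ev)) {
      sid <- stays$stay_id[ev_stay[j]]
      inj <- inject_sepsis_episode(observations[.(sid)][!is.na(concept_id)],
                                   medications[.(sid)][!is.na(drug_class)],
                                   stays[ev_stay[j]], lab[j], t0[j], config,
                                   sofa_missing = missing_variant[j])
      new_obs[[j]] <- inj$obs
      new_med[[j]] <- inj$med
      ev_rows[[j]] <- data.table(event_id = sprintf("E%04d", j),
                                 stay_id = sid, t0 = t0[j],
                                 fine_label = lab[j], source = src[j],
                                 infection = inj$infection,
                                 organ_failure = inj$organ_failure,
                                 alt_etiology = inj$alt_etiology)
    }
    ev_sids <- stays$stay_id[ev_stay]
    observations <- rbind(observations[!stay_id %in% ev_sids],
                          rbindlist(new_obs))
    medications <- rbind(medications[!stay_id %in% ev_sids],
                         rbindlist(new_med))
    events <- rbindlist(ev_rows)
    # pathway-dependent antibiotic delay from onset
    delay_h <- ifelse(events$source == "orderset",
                      rexp(n_ev, 1 / config$abx_delay_pathway_mean),
                      rexp(n_ev, 1 / config$abx_delay_other_mean))
    abx_ts <- events$t0 + round(delay_h * 60) * 60
    disc <- stays$discharge_ts[ev_stay]
    abx_ts <- pmin(abx_ts, disc - 60)
    medications <- rbind(medications,
                         data.table(stay_id = events$stay_id,
                                    drug_class = "antibiotic",
                                    admin_ts = abx_ts))
  } else {
    events <- data.table(event_id = character(0), stay_id = character(0),
                         t0 = as.POSIXct(character(0), tz = "UTC"),
                         fine_label = character(0), source = character(0),
                         infection = logical(0), organ_failure = logical(0),
                         alt_etiology = logical(0))
  }

  icd_codes <- assign_icd_codes(stays, events, config)

  # outcomes
  pt <- merge(stays, patients, by = "patient_id")
  setkey(pt, stay_id)
  cs_stays <- if (nrow(events)) events[collapse_label(fine_label) == "CS",
                                       unique(stay_id)] else character(0)
  timely_stays <- character(0)
  if (nrow(events)) {
    first_abx <- medications[drug_class == "antibiotic",
                             .(abx = min(admin_ts)), by = stay_id]
    evf <- merge(events, first_abx, by = "stay_id", all.x = TRUE)
    timely_stays <- evf[!is.na(abx) & as.numeric(abx - t0, units = "hours") <= 1,
                        unique(stay_id)]
  }
  stay_tab <- data.table(
    stay_id = pt$stay_id, admit_ts = pt$admit_ts,
    discharge_ts = pt$discharge_ts,
    age = as.numeric(format(pt$admit_ts, "%Y")) - pt$birth_year,
    year_index = as.numeric(format(pt$admit_ts, "%Y")) -
      as.numeric(format(cal0, "%Y")),
    sepsis_cs = pt$stay_id %in% cs_stays,
    timely = pt$stay_id %in% timely_stays)
  outc <- simulate_outcomes(stay_tab, config)
  stays <- merge(stays, outc[, .(stay_id, in_hospital_death, death_ts)],
                 by = "stay_id")
  setorder(stays, stay_id)
  setorder(observations, stay_id, concept_id, ts)
  setorder(medications, stay_id, admin_ts)

  registry(patients, stays, ward_segments, observations, medications,
           events, icd_codes)
}
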