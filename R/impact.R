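# Before/after quality-of-care analytics: cohort assignment, per-year
# indicators, covariate-adjusted odds ratios, and the propensity-matched
# time-to-antibiotics comparison.

#' Assign a stay to an evaluation cohort
#'
#' A stay is `stays_limited_to_slhs` when every ward segment lies in a
#' program ward group, `stays_including_slhs` when at least one does,
#' `control` when all segments lie in control groups (and none in program
#' groups), `other` otherwise. The returned name is the most specific
#' rule; limited stays are a subset of including stays.
#'
#' @param segments Ward segments of one stay.
#' @param slhs_groups Program ward groups.
#' @param control_groups Control ward groups.
#' @return One of `"stays_limited_to_slhs"`, `"stays_including_slhs"`,
#'   `"control"`, `"other"`.
#' @export
assign_cohort <- function(segments, slhs_groups = c("MED", "GIS", "EMD"),
                          control_groups = "CONTROL") {
  if (nrow(segments) == 0) .stopf("stay has no ward segments")
  g <- segments$ward_group
  if (all(g %in% slhs_groups)) return("stays_limited_to_slhs")
  if (any(g %in% slhs_groups)) return("stays_including_slhs")
  if (all(g %in% control_groups)) return("control")
  "other"
}

#' Cohort membership for every stay
#'
#' @param reg Registry.
#' @param slhs_groups,control_groups Ward group sets.
#' @return data.table: `stay_id`, `cohort` (most specific), `including`,
#'   `limited`, `control` logical flags.
#' @export
cohort_membership <- function(reg, slhs_groups = c("MED", "GIS", "EMD"),
                              control_groups = "CONTROL") {
  seg <- reg$ward_segments
  mem <- seg[, .(any_slhs = any(ward_group %in% slhs_groups),
                 all_slhs = all(ward_group %in% slhs_groups),
                 all_ctrl = all(ward_group %in% control_groups)),
             by = stay_id]
  mem[, cohort := ifelse(all_slhs, "stays_limited_to_slhs",
                  ifelse(any_slhs, "stays_including_slhs",
                  ifelse(all_ctrl, "control", "other")))]
  out <- mem[, .(stay_id, cohort, including = any_slhs,
                 limited = all_slhs,
                 control = all_ctrl & !any_slhs)]
  merge(data.table(stay_id = reg$stays$stay_id), out, by = "stay_id",
        all.x = TRUE)[is.na(cohort), `:=`(cohort = "other",
                                          including = FALSE,
                                          limited = FALSE,
                                          control = FALSE)][]
}

# stay-level covariate/outcome table used across the impact analyses
stay_covariates <- function(reg, config = run_config()) {
  pt <- merge(reg$stays, reg$patients, by = "patient_id")
  codes <- split(reg$icd_codes$code, reg$icd_codes$stay_id)
  map <- charlson_map()
  cci <- vapply(pt$stay_id, function(s)
    as.integer(charlson_index(codes[[s]] %||% character(0), map)),
    integer(1))
  sep_code <- vapply(pt$stay_id, function(s)
    has_sepsis_code(codes[[s]] %||% character(0),
                    config$icd_sepsis_prefixes), logical(1))
  data.table(
    stay_id = pt$stay_id,
    patient_id = pt$patient_id,
    admit_ts = pt$admit_ts, discharge_ts = pt$discharge_ts,
    year = as.integer(format(pt$admit_ts, "%Y")),
    sex = pt$sex,
    age = as.numeric(format(pt$admit_ts, "%Y")) - pt$birth_year,
    charlson = cci,
    sepsis_coded = sep_code,
    in_hospital_death = pt$in_hospital_death,
    death_30d = !is.na(pt$death_ts) &
      as.numeric(pt$death_ts - pt$admit_ts, units = "days") <= 30,
    death_90d = !is.na(pt$death_ts) &
      as.numeric(pt$death_ts - pt$admit_ts, units = "days") <= 90)
}

#' Per-cohort, per-year quality-of-care indicators
#'
#' For each cohort and admission year: percentage of stays with a sepsis
#' ICD code, percentage of flagged stays (stay-level confirmed-sepsis
#' probability above the calibrated threshold), and in-hospital / 30-day /
#' 90-day mortality among flagged and unflagged stays. Rates over empty
#' denominators are `NA` (explicitly undefined, never 0).
#'
#' @param reg Registry.
#' @param predictions Stay predictions from [predict_stays()].
#' @param config A [run_config()].
#' @return data.table, one row per cohort-year.
#' @export
cohort_indicators <- function(reg, predictions, config = run_config()) {
  cov <- stay_covariates(reg, config)
  mem <- cohort_membership(reg, config$slhs_ward_groups,
                           config$control_ward_groups)
  d <- merge(cov, mem[, .(stay_id, including, limited, control)],
             by = "stay_id")
  d <- merge(d, predictions[, .(stay_id, flagged)], by = "stay_id",
             all.x = TRUE)
  d[is.na(flagged), flagged := FALSE]
  rate <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  one <- function(dd, cname) dd[, .(
    cohort = cname, n_stays = .N,
    pct_sepsis_coded = rate(sepsis_coded),
    pct_flagged = rate(flagged),
    mort_inhosp_flagged = rate(in_hospital_death[flagged]),
    mort_30d_flagged = rate(death_30d[flagged]),
    mort_90d_flagged = rate(death_90d[flagged]),
    mort_inhosp_unflagged = rate(in_hospital_death[!flagged]),
    mort_90d_unflagged = rate(death_90d[!flagged])), by = year]
  out <- rbind(one(d[including == TRUE], "stays_including_slhs"),
               one(d[limited == TRUE], "stays_limited_to_slhs"),
               one(d[control == TRUE], "control"))
  setorder(out, cohort, year)
  setcolorder(out, c("cohort", "year"))
  out[]
}

#' Covariate-adjusted odds ratio for a yearly trend
#'
#' Maximum-likelihood logistic regression of a binary outcome on year of
#' admission (continuous by default), sex, age and Charlson index; the
#' reported odds ratio is the exponentiated year coefficient (per year),
#' with a Wald 95% confidence interval. Non-convergence and separation
#' are flagged, never silently reported.
#'
#' @param d Stay table with the outcome column plus `year`, `sex`, `age`,
#'   `charlson`.
#' @param outcome Name of the binary outcome column.
#' @param year_categorical Fit year as a factor instead (no single OR is
#'   then reported for the trend; the last-year contrast is returned).
#' @param conf_level Confidence level.
#' @return List of class `slhs_or`: `outcome`, `or`, `ci`, `n`,
#'   `converged`, `separation`, `covariates`.
#' @export
adjusted_odds_ratio <- function(d, outcome, year_categorical = FALSE,
                                conf_level = 0.95) {
  y <- d[[outcome]]
  if (is.null(y)) .stopf("outcome column '%s' not found", outcome)
  y <- as.logical(y)
  if (all(y) || !any(y))
    .stopf("degenerate outcome '%s': no variation", outcome)
  dd <- data.frame(y = y,
                   year = if (year_categorical) factor(d$year)
                          else as.numeric(d$year),
                   sex = factor(d$sex), age = as.numeric(d$age),
                   charlson = as.numeric(d$charlson))
  fit <- suppressWarnings(glm(y ~ year + sex + age + charlson,
                              data = dd, family = binomial()))
  cn <- if (year_categorical)
    grep("^year", names(coef(fit)), value = TRUE) |> tail(1) else "year"
  beta <- coef(fit)[cn]
  se <- sqrt(diag(vcov(fit)))[cn]
  z <- qnorm(1 - (1 - conf_level) / 2)
  separation <- !is.finite(se) || se > 10 || abs(beta) > 10
  structure(list(outcome = outcome,
                 or = exp(unname(beta)),
                 ci = exp(unname(c(beta - z * se, beta + z * se))),
                 n = nrow(dd),
                 converged = isTRUE(fit$converged),
                 separation = separation,
                 covariates = c("year", "sex", "age", "charlson")),
            class = "slhs_or")
}

#' @export
print.slhs_or <- function(x, ...) {
  cat(sprintf("%s: OR/year %.3f (%.3f-%.3f), n=%d%s%s\n", x$outcome,
              x$or, x$ci[1], x$ci[2], x$n,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$separation) " [SEPARATION]" else ""))
  invisible(x)
}

#' Time-to-antibiotics table from the registry
#'
#' One row per documented sepsis event: pathway group (order-set events)
#' versus controls (infectious-disease consult events), onset-to-first-
#' antibiotic delay in hours (an antibiotic at or before onset counts as
#' delay 0), and the matching covariates age, sex and Charlson index.
#'
#' @param reg Registry.
#' @param config A [run_config()].
#' @return data.table: `stay_id`, `group`, `delay_h` (NA when censored),
#'   `age`, `sex`, `charlson`.
#' @export
tta_table <- function(reg, config = run_config()) {
  if (nrow(reg$events) == 0) .stopf("registry has no sepsis events")
  cov <- stay_covariates(reg, config)
  ev <- merge(reg$events, cov[, .(stay_id, age, sex, charlson)],
              by = "stay_id")
  abx <- reg$medications[drug_class == "antibiotic"]
  delay <- vapply(seq_len(nrow(ev)), function(i) {
    a <- abx[stay_id == ev$stay_id[i], admin_ts]
    if (length(a) == 0) return(NA_real_)
    if (any(a <= ev$t0[i])) return(0)
    min(as.numeric(a[a > ev$t0[i]] - ev$t0[i], units = "hours"))
  }, numeric(1))
  data.table(stay_id = ev$stay_id,
             group = ifelse(ev$source == "orderset", "pathway", "control"),
             delay_h = delay, age = ev$age, sex = ev$sex,
             charlson = ev$charlson)
}

#' Propensity-matched time-to-antibiotics comparison
#'
#' 1:1 nearest-neighbour matching of pathway to control events on the
#' logit propensity score from (age, sex, Charlson), without replacement,
#' caliper 0.2 standard deviations of the logit score, pathway rows
#' processed in decreasing score order. On the matched pairs, a 2x2 table
#' of group by antibiotics-within-threshold is tested with a chi-squared
#' test. Censored delays count as not within threshold.
#'
#' @param tta Table from [tta_table()] (or equivalent columns).
#' @param threshold_hours Timeliness threshold, conventionally 1 or 3.
#' @param caliper_sd Caliper in SD of the logit score.
#' @param correct Continuity correction for the chi-squared test.
#' @return List of class `slhs_tta`: `threshold_hours`, `n_pairs`,
#'   `table`, `statistic`, `p_value`, `prop_within` (per group).
#' @export
tta_matched_comparison <- function(tta, threshold_hours = 1,
                                   caliper_sd = 0.2, correct = FALSE) {
  d <- as.data.table(tta)
  if (!all(c("group", "delay_h", "age", "sex", "charlson") %in% names(d)))
    .stopf("tta table lacks required columns")
  d[, trt := group == "pathway"]
  ps <- glm(trt ~ age + factor(sex) + charlson, data = d,
            family = binomial())
  lp <- predict(ps, type = "link")
  cal <- caliper_sd * sd(lp)
  ti <- which(d$trt); ci <- which(!d$trt)
  if (length(ti) == 0 || length(ci) == 0)
    .stopf("both a pathway and a control group are required")
  ti <- ti[order(lp[ti], decreasing = TRUE)]
  avail <- rep(TRUE, length(lp))
  pairs <- list()
  for (i in ti) {
    cand <- ci[avail[ci]]
    if (length(cand) == 0) break
    dist <- abs(lp[cand] - lp[i])
    j <- cand[which.min(dist)]
    if (min(dist) <= cal) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
      avail[j] <- FALSE
    }
  }
  if (length(pairs) == 0) .stopf("no matchable pairs within the caliper")
  pm <- do.call(rbind, pairs)
  idx <- c(pm[, 1], pm[, 2])
  within <- !is.na(d$delay_h[idx]) & d$delay_h[idx] <= threshold_hours
  grp <- factor(ifelse(d$trt[idx], "pathway", "control"),
                levels = c("pathway", "control"))
  tab <- table(group = grp, within = factor(within, c(FALSE, TRUE)))
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(list(threshold_hours = threshold_hours, n_pairs = nrow(pm),
                 table = unclass(tab),
                 statistic = unname(ct$statistic),
                 p_value = ct$p.value,
                 prop_within = c(pathway = mean(within[grp == "pathway"]),
                                 control = mean(within[grp == "control"]))),
            class = "slhs_tta")
}

#' @export
print.slhs_tta <- function(x, ...) {
  cat(sprintf("time-to-antibiotics <= %g h: %d matched pairs, %.0f%% vs %.0f%% (pathway vs control), X2=%.2f, p=%.3g\n",
              x$threshold_hours, x$n_pairs, 100 * x$prop_within["pathway"],
              100 * x$prop_within["control"], x$statistic, x$p_value))
  invisible(x)
}

#' Full impact report
#'
#' Per-cohort-year indicators plus the adjusted per-year odds ratios for
#' sepsis coding, flagged-stay fraction and mortality among flagged
#' stays, per cohort, and the two time-to-antibiotics comparisons
#' (1 h and 3 h) when events are present.
#'
#' @param reg Registry.
#' @param predictions Stay predictions from [predict_stays()].
#' @param config A [run_config()].
#' @return List of class `slhs_impact`: `indicators`, `odds_ratios`
#'   (data.table), `tta` (list or NULL).
#' @export
impact_report <- function(reg, predictions, config = run_config()) {
  ind <- cohort_indicators(reg, predictions, config)
  cov <- stay_covariates(reg, config)
  mem <- cohort_membership(reg, config$slhs_ward_groups,
                           config$control_ward_groups)
  d <- merge(cov, mem[, .(stay_id, including, limited, control)],
             by = "stay_id")
  d <- merge(d, predictions[, .(stay_id, flagged)], by = "stay_id",
             all.x = TRUE)
  d[is.na(flagged), flagged := FALSE]
  ors <- list()
  for (coh in c("stays_including_slhs", "stays_limited_to_slhs",
                "control")) {
    dd <- switch(coh, stays_including_slhs = d[including == TRUE],
                 stays_limited_to_slhs = d[limited == TRUE],
                 control = d[control == TRUE])
    for (oc in c("sepsis_coded", "flagged")) {
      r <- tryCatch(adjusted_odds_ratio(dd, oc), error = function(e) NULL)
      if (!is.null(r))
        ors[[length(ors) + 1L]] <- data.table(
          cohort = coh, outcome = oc, subgroup = "all", or = r$or,
          ci_low = r$ci[1], ci_high = r$ci[2], n = r$n,
          converged = r$converged, separation = r$separation)
    }
    for (oc in c("in_hospital_death", "death_90d")) {
      df <- dd[flagged == TRUE]
      r <- tryCatch(adjusted_odds_ratio(df, oc), error = function(e) NULL)
      if (!is.null(r))
        ors[[length(ors) + 1L]] <- data.table(
          cohort = coh, outcome = oc, subgroup = "flagged", or = r$or,
          ci_low = r$ci[1], ci_high = r$ci[2], n = r$n,
          converged = r$converged, separation = r$separation)
    }
  }
  tta <- NULL
  if (nrow(reg$events) > 0) {
    tt <- tta_table(reg, config)
    tta <- lapply(c(1, 3), function(th)
      tryCatch(tta_matched_comparison(tt, th), error = function(e) NULL))
    names(tta) <- c("within_1h", "within_3h")
  }
  structure(list(indicators = ind,
                 odds_ratios = rbindlist(ors),
                 tta = tta), class = "slhs_impact")
}
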