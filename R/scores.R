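# Clinical severity and comorbidity scores.
#
# SOFA and NEWS2 banding follows the canonical published tables (Sepsis-3 /
# RCP NEWS2); the Charlson ICD-10 mapping ships as an editable fixture under
# extdata so sites can align it with local coding practice.

.sofa_organs <- c("resp", "coag", "liver", "cardio", "cns", "renal")

#' Build a clinical score snapshot
#'
#' A snapshot holds the latest observed value of each score-relevant concept
#' at a reference time. Any field may be `NA` (explicitly missing); values
#' outside physiologic range raise an error.
#'
#' @param pf_ratio PaO2/FiO2 ratio (mmHg).
#' @param platelets Platelet count (10^9/L).
#' @param bilirubin Total bilirubin (umol/L).
#' @param map Mean arterial pressure (mmHg).
#' @param vasopressor_class Ordinal dose class: `"none"`, `"low"`, `"mid"`,
#'   `"high"`. Registries that record only a drug class (no dose) map any
#'   active vasopressor to `"low"`.
#' @param gcs Glasgow Coma Scale, integer 3--15.
#' @param creatinine Serum creatinine (umol/L).
#' @param urine_output_24h 24-h urine output (mL), optional.
#' @param rr Respiratory rate (/min).
#' @param spo2 Peripheral oxygen saturation (%), in (0, 100].
#' @param on_oxygen Logical, supplemental oxygen in use.
#' @param temp Temperature (degrees C).
#' @param sbp Systolic blood pressure (mmHg).
#' @param hr Heart rate (/min).
#' @param consciousness_impaired Logical, any new confusion / V, P or U on
#'   the ACVPU scale.
#' @return A `score_snapshot` list.
#' @export
score_snapshot <- function(pf_ratio = NA_real_, platelets = NA_real_,
                           bilirubin = NA_real_, map = NA_real_,
                           vasopressor_class = "none", gcs = NA_real_,
                           creatinine = NA_real_, urine_output_24h = NA_real_,
                           rr = NA_real_, spo2 = NA_real_, on_oxygen = NA,
                           temp = NA_real_, sbp = NA_real_, hr = NA_real_,
                           consciousness_impaired = NA) {
  snap <- list(
    pf_ratio = pf_ratio, platelets = platelets, bilirubin = bilirubin,
    map = map, vasopressor_class = vasopressor_class, gcs = gcs,
    creatinine = creatinine, urine_output_24h = urine_output_24h,
    rr = rr, spo2 = spo2, on_oxygen = on_oxygen, temp = temp, sbp = sbp,
    hr = hr, consciousness_impaired = consciousness_impaired
  )
  validate_snapshot(snap)
  structure(snap, class = "score_snapshot")
}

validate_snapshot <- function(snap) {
  chk <- function(x, lo, hi, name) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) .stopf("%s out of physiologic range [%s, %s]: %s",
                         name, lo, hi, paste(x[bad], collapse = ", "))
  }
  chk(snap$gcs, 3, 15, "gcs")
  bad_spo2 <- !is.na(snap$spo2) & (snap$spo2 <= 0 | snap$spo2 > 100)
  if (any(bad_spo2)) .stopf("spo2 out of physiologic range (0, 100]")
  chk(snap$pf_ratio, 1, 1000, "pf_ratio")
  chk(snap$platelets, 0, 5000, "platelets")
  chk(snap$bilirubin, 0, 2000, "bilirubin")
  chk(snap$map, 10, 300, "map")
  chk(snap$creatinine, 1, 5000, "creatinine")
  chk(snap$rr, 0, 120, "rr")
  chk(snap$temp, 20, 45, "temp")
  chk(snap$sbp, 20, 350, "sbp")
  chk(snap$hr, 0, 350, "hr")
  vc <- snap$vasopressor_class
  if (any(!is.na(vc) & !vc %in% c("none", "low", "mid", "high")))
    .stopf("vasopressor_class must be one of none/low/mid/high")
  invisible(TRUE)
}

# Vectorised per-organ SOFA subscores. Inputs are equal-length vectors; NA
# means the organ's data are absent and scores 0 with an imputed flag.
sofa_subscores <- function(pf_ratio, platelets, bilirubin, map,
                           vasopressor_class, gcs, creatinine,
                           urine_output_24h = NULL) {
  n <- max(length(pf_ratio), length(platelets), length(bilirubin),
           length(map), length(vasopressor_class), length(gcs),
           length(creatinine))
  rec <- function(x) rep_len(if (length(x) == 0) NA else x, n)
  pf <- rec(pf_ratio); plt <- rec(platelets); bili <- rec(bilirubin)
  mp <- rec(map); vc <- rec(vasopressor_class); g <- rec(gcs)
  cr <- rec(creatinine)
  uo <- if (is.null(urine_output_24h)) rep(NA_real_, n) else rec(urine_output_24h)
  vc[is.na(vc)] <- "none"

  resp <- ifelse(pf < 100, 4L, ifelse(pf < 200, 3L,
          ifelse(pf < 300, 2L, ifelse(pf < 400, 1L, 0L))))
  coag <- ifelse(plt < 20, 4L, ifelse(plt < 50, 3L,
          ifelse(plt < 100, 2L, ifelse(plt < 150, 1L, 0L))))
  liver <- ifelse(bili >= 205, 4L, ifelse(bili >= 102, 3L,
           ifelse(bili >= 33, 2L, ifelse(bili >= 20, 1L, 0L))))
  cardio <- ifelse(vc == "high", 4L, ifelse(vc == "mid", 3L,
            ifelse(vc == "low", 2L, ifelse(!is.na(mp) & mp < 70, 1L, 0L))))
  # on vasopressors the MAP value is irrelevant, so cardio is only missing
  # when no vasopressor is recorded and MAP is absent
  cardio[vc == "none" & is.na(mp)] <- NA_integer_
  cns <- ifelse(g < 6, 4L, ifelse(g <= 9, 3L,
         ifelse(g <= 12, 2L, ifelse(g <= 14, 1L, 0L))))
  renal_cr <- ifelse(cr >= 441, 4L, ifelse(cr >= 300, 3L,
              ifelse(cr >= 171, 2L, ifelse(cr >= 110, 1L, 0L))))
  renal_uo <- ifelse(is.na(uo), NA_integer_,
              ifelse(uo < 200, 4L, ifelse(uo < 500, 3L, 0L)))
  renal <- pmax(renal_cr, renal_uo, na.rm = TRUE)
  renal[is.na(cr) & is.na(uo)] <- NA_integer_

  data.table(resp = resp, coag = coag, liver = liver, cardio = cardio,
             cns = cns, renal = renal)
}

#' Total SOFA score
#'
#' Sum of the six organ subscores (respiration, coagulation, liver,
#' cardiovascular, central nervous system, renal), each 0--4. An organ with
#' no data scores 0 and is flagged imputed; the number of imputed organs is
#' attached so downstream logic can treat heavily imputed assessments as
#' missing.
#'
#' @param snapshot A [score_snapshot()].
#' @return Integer total in 0--24 with attributes `subscores` (named integer
#'   vector) and `n_imputed` (organs scored without data).
#' @export
sofa_total <- function(snapshot) {
  validate_snapshot(snapshot)
  sub <- sofa_subscores(snapshot$pf_ratio, snapshot$platelets,
                        snapshot$bilirubin, snapshot$map,
                        snapshot$vasopressor_class, snapshot$gcs,
                        snapshot$creatinine, snapshot$urine_output_24h)
  v <- unlist(sub[1, ])
  n_imp <- sum(is.na(v))
  v[is.na(v)] <- 0L
  structure(sum(v), subscores = v, n_imputed = n_imp)
}

#' NEWS2 early-warning score
#'
#' Sum of the seven canonical NEWS2 sub-scores (respiratory rate, oxygen
#' saturation on scale 1, supplemental oxygen, temperature, systolic blood
#' pressure, heart rate, consciousness), range 0--20. Missing vitals score 0
#' and are counted in the `n_imputed` attribute.
#'
#' @inheritParams sofa_total
#' @return Integer 0--20 with attributes `subscores`, `n_imputed`.
#' @export
news2_score <- function(snapshot) {
  validate_snapshot(snapshot)
  s <- snapshot
  band <- c(
    rr = ifelse(s$rr <= 8, 3L, ifelse(s$rr <= 11, 1L,
         ifelse(s$rr <= 20, 0L, ifelse(s$rr <= 24, 2L, 3L)))),
    spo2 = ifelse(s$spo2 <= 91, 3L, ifelse(s$spo2 <= 93, 2L,
           ifelse(s$spo2 <= 95, 1L, 0L))),
    oxygen = ifelse(isTRUE(as.logical(s$on_oxygen)), 2L, 0L),
    temp = ifelse(s$temp <= 35, 3L, ifelse(s$temp <= 36, 1L,
           ifelse(s$temp <= 38, 0L, ifelse(s$temp <= 39, 1L, 2L)))),
    sbp = ifelse(s$sbp <= 90, 3L, ifelse(s$sbp <= 100, 2L,
          ifelse(s$sbp <= 110, 1L, ifelse(s$sbp <= 219, 0L, 3L)))),
    hr = ifelse(s$hr <= 40, 3L, ifelse(s$hr <= 50, 1L,
         ifelse(s$hr <= 90, 0L, ifelse(s$hr <= 110, 1L,
         ifelse(s$hr <= 130, 2L, 3L))))),
    consciousness = ifelse(isTRUE(as.logical(s$consciousness_impaired)), 3L, 0L)
  )
  n_imp <- sum(is.na(band))
  band[is.na(band)] <- 0L
  structure(sum(band), subscores = band, n_imputed = n_imp)
}

# SOFA snapshots on a 6-h grid from a stay's observation series, carrying the
# last observed value forward. `medications` supplies vasopressor activity: a
# vasopressor administration keeps the cardiovascular class at "low" for
# `vaso_active_hours` after the dose (the registry stores drug class only).
sofa_series <- function(observations, from_ts, to_ts, medications = NULL,
                        grid_hours = 6, vaso_active_hours = 24) {
  stopifnot(to_ts > from_ts)
  grid <- seq(from = as.numeric(from_ts), to = as.numeric(to_ts),
              by = .hrs(grid_hours))
  concepts <- c("pf_ratio", "platelets", "bilirubin", "map", "gcs",
                "creatinine")
  obs <- observations[concept_id %in% concepts]
  last_at <- function(cid, t) {
    o <- obs[concept_id == cid]
    if (nrow(o) == 0) return(rep(NA_real_, length(t)))
    o <- o[order(ts)]
    idx <- findInterval(t, as.numeric(o$ts))
    ifelse(idx == 0, NA_real_, o$value[pmax(idx, 1L)])
  }
  vals <- lapply(concepts, last_at, t = grid)
  names(vals) <- concepts
  vaso <- rep("none", length(grid))
  if (!is.null(medications) && nrow(medications) > 0) {
    vt <- as.numeric(medications[drug_class == "vasopressor", admin_ts])
    if (length(vt) > 0) {
      active <- vapply(grid, function(g)
        any(vt <= g & g < vt + .hrs(vaso_active_hours)), logical(1))
      vaso[active] <- "low"
    }
  }
  sub <- sofa_subscores(vals$pf_ratio, vals$platelets, vals$bilirubin,
                        vals$map, vaso, vals$gcs, vals$creatinine)
  n_imp <- rowSums(is.na(sub))
  total <- rowSums(sub, na.rm = TRUE)
  data.table(ts = as.POSIXct(grid, tz = "UTC", origin = "1970-01-01"),
             total = as.integer(total), n_imputed = as.integer(n_imp))
}

#' Delta SOFA around a sepsis onset
#'
#' Maximum SOFA in the post-onset assessment window minus the baseline SOFA,
#' the organ-dysfunction criterion of the Sepsis-3 definition (increase of
#' two or more points). Baseline is the maximum SOFA over the 24 h preceding
#' onset; with no pre-onset data the baseline is taken as zero
#' (`baseline_policy = "zero_if_absent"`, the Sepsis-3 convention for
#' patients not known to have pre-existing organ dysfunction). Assessments
#' where three or more organs lack any data are considered missing; if no
#' valid post-onset assessment exists the result is `NA` (an explicit
#' missing marker, never silently 0).
#'
#' @param observations Observation rows of one stay (`concept_id`, `ts`,
#'   `value`).
#' @param t0 Onset timestamp (POSIXct); must lie within the stay.
#' @param stay_interval Length-2 POSIXct `c(admit_ts, discharge_ts)`.
#' @param medications Optional medication rows of the stay (for vasopressor
#'   activity in the cardiovascular subscore).
#' @param baseline_policy `"zero_if_absent"` (default) or `"strict"` (missing
#'   baseline makes delta missing).
#' @param baseline_hours Lookback for the baseline assessment (default 24).
#' @param post_hours Post-onset assessment horizon (default 72).
#' @return A list with `delta` (integer or `NA`), `baseline`, `post_max`,
#'   and `missing` (logical).
#' @export
delta_sofa <- function(observations, t0, stay_interval, medications = NULL,
                       baseline_policy = c("zero_if_absent", "strict"),
                       baseline_hours = 24, post_hours = 72) {
  baseline_policy <- match.arg(baseline_policy)
  if (t0 < stay_interval[1] || t0 >= stay_interval[2])
    .stopf("t0 outside the stay interval")
  post_end <- min(as.numeric(t0) + .hrs(post_hours),
                  as.numeric(stay_interval[2]))
  ser <- sofa_series(observations, stay_interval[1],
                     as.POSIXct(post_end, tz = "UTC", origin = "1970-01-01"),
                     medications)
  ok <- ser$n_imputed < 3
  pre <- ser[ok & ts > t0 - .hrs(baseline_hours) & ts <= t0]
  post <- ser[ok & ts > t0]
  # an assessment needs fresh data: carried-forward values alone do not
  # make a post-onset assessment
  sofa_cids <- c("pf_ratio", "platelets", "bilirubin", "map", "gcs",
                 "creatinine")
  any_post_obs <- nrow(observations[concept_id %in% sofa_cids &
                                      as.numeric(ts) > as.numeric(t0) &
                                      as.numeric(ts) <= post_end]) > 0
  if (!any_post_obs) post <- post[0]
  if (nrow(post) == 0)
    return(list(delta = NA_integer_, baseline = NA_integer_,
                post_max = NA_integer_, missing = TRUE))
  baseline <- if (nrow(pre) > 0) max(pre$total) else
    if (baseline_policy == "zero_if_absent") 0L else NA_integer_
  if (is.na(baseline))
    return(list(delta = NA_integer_, baseline = NA_integer_,
                post_max = max(post$total), missing = TRUE))
  list(delta = as.integer(max(0L, max(post$total) - baseline)),
       baseline = as.integer(baseline), post_max = max(post$total),
       missing = FALSE)
}

#' Charlson comorbidity mapping fixture
#'
#' The 17-category Charlson map with original weights and ICD-10 prefix
#' lists, read from the package's editable fixture file.
#'
#' @param path Optional path to an alternative mapping CSV with columns
#'   `category`, `weight`, `supersedes`, `prefixes` (semicolon-separated).
#' @return data.table with one row per category.
#' @export
charlson_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "charlson_icd10.csv",
                                package = "slhs")
  m <- as.data.table(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("category", "weight", "supersedes", "prefixes") %in%
                  names(m)))
  m
}

#' Charlson comorbidity index
#'
#' Sum of category weights over the distinct comorbidity categories present
#' in a stay's ICD-10 code list, with hierarchical exclusions (severe liver
#' disease supersedes mild, complicated diabetes supersedes uncomplicated,
#' metastatic disease supersedes non-metastatic malignancy). Codes matching
#' no category are ignored.
#'
#' @param icd_codes Character vector of ICD-10 codes (dots optional).
#' @param mapping A mapping table from [charlson_map()].
#' @return Integer index >= 0, with attribute `categories`.
#' @export
charlson_index <- function(icd_codes, mapping = charlson_map()) {
  if (length(icd_codes) == 0) return(structure(0L, categories = character(0)))
  codes <- toupper(gsub("\\.", "", unique(as.character(icd_codes))))
  hit <- vapply(seq_len(nrow(mapping)), function(i) {
    pre <- strsplit(mapping$prefixes[i], ";", fixed = TRUE)[[1]]
    any(vapply(pre, function(p) any(startsWith(codes, p)), logical(1)))
  }, logical(1))
  cats <- mapping$category[hit]
  sup <- mapping$supersedes[hit]
  cats <- setdiff(cats, sup[nzchar(sup)])
  w <- mapping$weight[match(cats, mapping$category)]
  structure(as.integer(sum(w)), categories = cats)
}
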