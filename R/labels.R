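# Sepsis event label logic and projection onto the 6-hour window grid.

#' Fine and coarse sepsis label levels
#'
#' Fine labels, in increasing severity: no infection; infection without
#' sepsis; sepsis-like (organ failure with delta-SOFA < 2 or missing SOFA
#' information); sepsis sensu lato (delta-SOFA >= 2 with an alternative
#' aetiology for the organ dysfunction); sepsis sensu stricto (delta-SOFA
#' >= 2, no alternative aetiology); septic shock (sensu stricto plus
#' vasopressor plus lactate > 2 mmol/L). Coarse labels collapse these to
#' no / possible / confirmed sepsis.
#'
#' @export
fine_label_levels <- function() {
  c("0_no_infection", "0_infection", "1a_sepsis_like",
    "1b_sepsis_sensu_lato", "2a_sepsis_sensu_stricto", "2b_septic_shock")
}

#' @rdname fine_label_levels
#' @export
coarse_label_levels <- function() c("NS", "PS", "CS")

fine_severity <- function(fine) match(fine, fine_label_levels())

#' Event facts supporting label assignment
#'
#' The minimal fact set the label logic consumes. `infection` and
#' `alt_etiology` are clinician judgments from the standardized sepsis form;
#' `delta_sofa`, `vasopressor_given` and `lactate_gt_2` are computed from
#' registry data. `delta_sofa = NA` is the explicit missing-SOFA marker.
#'
#' @param infection Logical: infection suspected or confirmed.
#' @param organ_failure Logical: organ failure documented.
#' @param delta_sofa Integer >= 0 or `NA` (missing SOFA information).
#' @param alt_etiology Logical: alternative aetiology for the organ
#'   dysfunction.
#' @param vasopressor_given Logical: vasopressor administered after onset.
#' @param lactate_gt_2 Logical: any post-onset serum lactate > 2.0 mmol/L.
#' @return A validated `event_facts` list.
#' @export
event_facts <- function(infection, organ_failure, delta_sofa = NA_integer_,
                        alt_etiology = FALSE, vasopressor_given = FALSE,
                        lactate_gt_2 = FALSE) {
  f <- list(infection = isTRUE(infection),
            organ_failure = isTRUE(organ_failure),
            delta_sofa = if (is.na(delta_sofa)) NA_integer_
                         else as.integer(delta_sofa),
            alt_etiology = isTRUE(alt_etiology),
            vasopressor_given = isTRUE(vasopressor_given),
            lactate_gt_2 = isTRUE(lactate_gt_2))
  if (!is.na(f$delta_sofa) && f$delta_sofa < 0)
    .stopf("delta_sofa must be >= 0 when present")
  if (!f$infection && f$organ_failure)
    .stopf("inconsistent facts: organ failure attributed to infection but no infection recorded")
  if (!is.na(f$delta_sofa) && f$delta_sofa >= 2 && !f$organ_failure)
    .stopf("inconsistent facts: delta_sofa >= 2 requires organ_failure")
  structure(f, class = "event_facts")
}

#' Classify a suspected-sepsis event
#'
#' Deterministic mapping from event facts to the six fine labels. Without
#' infection the event is no-infection. With infection: delta-SOFA >= 2
#' gives sepsis sensu stricto (2a) when no alternative aetiology explains
#' the organ dysfunction — upgraded to septic shock (2b) when a vasopressor
#' was given and lactate exceeded 2 mmol/L — and sepsis sensu lato (1b)
#' when an alternative aetiology exists. Missing SOFA information gives
#' sepsis-like (1a), as does documented organ failure with delta-SOFA < 2.
#' Infection with neither organ failure nor a qualifying delta is infection
#' without sepsis. When several readings apply the most severe label wins.
#'
#' @param facts An [event_facts()] object.
#' @return A fine label string.
#' @export
classify_event <- function(facts) {
  if (!inherits(facts, "event_facts")) facts <- do.call(event_facts, facts)
  if (!facts$infection) return("0_no_infection")
  d <- facts$delta_sofa
  if (!is.na(d) && d >= 2) {
    if (!facts$alt_etiology) {
      if (facts$vasopressor_given && facts$lactate_gt_2)
        return("2b_septic_shock")
      return("2a_sepsis_sensu_stricto")
    }
    return("1b_sepsis_sensu_lato")
  }
  if (is.na(d)) return("1a_sepsis_like")
  if (facts$organ_failure) return("1a_sepsis_like")
  "0_infection"
}

#' Collapse a fine label to the coarse three-class label
#'
#' No-infection and infection-without-sepsis map to NS, sepsis-like and
#' sensu lato to PS (possible sepsis), sensu stricto and septic shock to CS
#' (confirmed sepsis).
#'
#' @param fine Fine label string(s).
#' @return Coarse label string(s) in \{NS, PS, CS\}.
#' @export
collapse_label <- function(fine) {
  map <- c("0_no_infection" = "NS", "0_infection" = "NS",
           "1a_sepsis_like" = "PS", "1b_sepsis_sensu_lato" = "PS",
           "2a_sepsis_sensu_stricto" = "CS", "2b_septic_shock" = "CS")
  out <- unname(map[fine])
  if (anyNA(out)) .stopf("unknown fine label: %s",
                         paste(fine[is.na(out)], collapse = ", "))
  out
}

#' Derive event facts from registry data
#'
#' Combines the clinician-form fields stored on the event row (infection,
#' organ failure, alternative aetiology) with facts computed from the data:
#' delta-SOFA via [delta_sofa()], vasopressor administration after onset,
#' and any post-onset lactate above 2 mmol/L (both within `post_hours`).
#'
#' @param registry A validated registry.
#' @param event One row of the events table.
#' @param post_hours Post-onset horizon for the computed facts (default 72).
#' @return An [event_facts()] object.
#' @export
derive_event_facts <- function(registry, event, post_hours = 72) {
  sid <- event$stay_id
  stay <- registry$stays[stay_id == sid]
  if (nrow(stay) != 1) .stopf("event cites unknown stay %s", sid)
  obs <- registry$observations[stay_id == sid]
  med <- registry$medications[stay_id == sid]
  t0 <- event$t0
  post_end <- t0 + .hrs(post_hours)
  ds <- delta_sofa(obs, t0, c(stay$admit_ts, stay$discharge_ts),
                   medications = med, post_hours = post_hours)
  vaso <- nrow(med[drug_class == "vasopressor" & admin_ts >= t0 &
                     admin_ts < post_end]) > 0
  lact <- obs[concept_id == "lactate" & ts >= t0 & ts < post_end, value]
  event_facts(infection = event$infection,
              organ_failure = event$organ_failure,
              delta_sofa = if (ds$missing) NA_integer_ else ds$delta,
              alt_etiology = event$alt_etiology,
              vasopressor_given = vaso,
              lactate_gt_2 = length(lact) > 0 && max(lact) > 2.0)
}

#' Label the 6-hour windows of a stay
#'
#' A window is labeled with the collapsed most-severe fine label among
#' events whose onset falls inside the window's lookback span — the
#' `lookback_days`-day interval ending at the window's close (half-open,
#' `(close - lookback, close]`). Windows whose span contains no event onset
#' are NS.
#'
#' @param grid A window grid for one stay (columns `stay_id`,
#'   `window_index`, `window_start_ts`) as built by [build_grid()].
#' @param events Event rows for the stay (`t0`, `fine_label`); may be empty.
#' @param window_hours Window width in hours (default 6).
#' @param lookback_days Lookback span in days (default 7).
#' @param stay_interval Optional `c(admit_ts, discharge_ts)` to validate
#'   event onsets against.
#' @return Character vector of coarse labels, one per window row.
#' @export
label_windows <- function(grid, events, window_hours = 6, lookback_days = 7,
                          stay_interval = NULL) {
  n <- nrow(grid)
  lab <- rep("NS", n)
  if (is.null(events) || nrow(events) == 0) return(lab)
  if (!is.null(stay_interval)) {
    bad <- events$t0 < stay_interval[1] | events$t0 >= stay_interval[2]
    if (any(bad)) .stopf("event t0 outside the stay interval")
  }
  close <- as.numeric(grid$window_start_ts) + .hrs(window_hours)
  open <- close - lookback_days * 86400
  sev <- fine_severity(events$fine_label)
  t0n <- as.numeric(events$t0)
  for (i in seq_len(n)) {
    inside <- t0n > open[i] & t0n <= close[i]
    if (any(inside))
      lab[i] <- collapse_label(fine_label_levels()[max(sev[inside])])
  }
  lab
}
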