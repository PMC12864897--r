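# 6-hour window grids, 7-day rolling aggregate features and right-aligned
# sequence tensors. Grids are anchored at admission (stay-relative), windows
# half-open [start, start + 6 h).

#' Core physiologic concepts
#'
#' The vital-sign and laboratory concepts used by the clinical scores and
#' fed to the sequence sub-model.
#' @export
core_concepts <- function() {
  c("hr", "rr", "sbp", "map", "temp", "spo2", "gcs", "platelets",
    "bilirubin", "creatinine", "lactate", "pf_ratio")
}

#' Default rolling-feature registry
#'
#' A declarative concept-by-aggregator table of comparable scale to the
#' deployed system's 240-feature set: 40 concepts (12 core physiologic
#' concepts plus 28 auxiliary laboratory channels) times 6 aggregators
#' (last, min, max, mean, count, slope), plus age and sex appended at
#' feature-building time.
#'
#' @return data.table with columns `concept_id`, `aggregators`.
#' @export
default_feature_registry <- function() {
  concepts <- c(core_concepts(), sprintf("lab%02d", 1:28))
  data.table(concept_id = concepts,
             aggregators = "last,min,max,mean,count,slope")
}

.all_aggregators <- c("last", "min", "max", "mean", "count", "slope")

#' Build the 6-hour window grid for a registry
#'
#' Resamples every stay's observation series onto contiguous half-open
#' windows anchored at admission: per window and concept the last observed
#' value (or NA), plus per-window medication counts. Windows cover
#' `[admit_ts, discharge_ts)`.
#'
#' @param reg An `slhs_registry`.
#' @param window_hours Window width; must divide 24.
#' @return data.table keyed by (`stay_id`, `window_index`) with
#'   `window_start_ts`, one column per observed concept, and
#'   `med_antibiotic`, `med_vasopressor`, `med_other` counts.
#' @export
build_windows <- function(reg, window_hours = 6) {
  if (24L %% window_hours != 0L) .stopf("window_hours must divide 24")
  wsec <- .hrs(window_hours)
  st <- reg$stays[, .(stay_id, admit_ts, discharge_ts)]
  st[, n_win := as.integer(ceiling(
    (as.numeric(discharge_ts) - as.numeric(admit_ts)) / wsec))]
  grid <- st[, .(window_index = seq_len(n_win) - 1L), by = .(stay_id)]
  grid <- merge(grid, st[, .(stay_id, admit_ts)], by = "stay_id")
  grid[, window_start_ts := admit_ts + window_index * wsec]
  grid[, admit_ts := NULL]
  setkey(grid, stay_id, window_index)

  obs <- merge(reg$observations, st[, .(stay_id, admit_ts)], by = "stay_id")
  if (nrow(obs) > 0) {
    obs[, window_index := as.integer(floor(
      (as.numeric(ts) - as.numeric(admit_ts)) / wsec))]
    obs <- obs[window_index >= 0]
    setorder(obs, stay_id, concept_id, window_index, ts)
    last_obs <- obs[, .(value = value[.N]),
                    by = .(stay_id, concept_id, window_index)]
    wide <- dcast(last_obs, stay_id + window_index ~ concept_id,
                  value.var = "value")
    grid <- merge(grid, wide, by = c("stay_id", "window_index"),
                  all.x = TRUE)
  }
  med <- merge(reg$medications, st[, .(stay_id, admit_ts)], by = "stay_id")
  for (cls in c("antibiotic", "vasopressor", "other")) {
    col <- paste0("med_", cls)
    if (nrow(med) > 0) {
      m <- med[drug_class == cls]
      m[, window_index := as.integer(floor(
        (as.numeric(admin_ts) - as.numeric(admit_ts)) / wsec))]
      cnt <- m[window_index >= 0, .N, by = .(stay_id, window_index)]
      setnames(cnt, "N", col)
      grid <- merge(grid, cnt, by = c("stay_id", "window_index"),
                    all.x = TRUE)
      grid[is.na(get(col)), (col) := 0L]
    } else grid[, (col) := 0L]
  }
  setkey(grid, stay_id, window_index)
  grid[]
}

#' Window grid for a single stay
#'
#' @param reg An `slhs_registry`.
#' @param stay_id_ Stay identifier.
#' @param window_hours Window width in hours.
#' @return The stay's rows of [build_windows()].
#' @export
build_grid <- function(reg, stay_id_, window_hours = 6) {
  sub <- registry(reg$patients, reg$stays[stay_id == stay_id_],
                  reg$ward_segments[stay_id == stay_id_],
                  reg$observations[stay_id == stay_id_],
                  reg$medications[stay_id == stay_id_],
                  reg$events[stay_id == stay_id_],
                  reg$icd_codes[stay_id == stay_id_], validate = FALSE)
  if (nrow(sub$stays) != 1) .stopf("unknown stay '%s'", stay_id_)
  build_windows(sub, window_hours)
}

# One pass over lags 0..(span-1) accumulating all rolling statistics.
# V: numeric matrix windows x concepts, rows sorted by (stay, window_index),
# k: integer window_index per row (0-based within stay). Lag j rows with
# k < j fall before admission and are excluded (clipping at admission).
.rolling_stats <- function(V, k, span) {
  n <- nrow(V); p <- ncol(V)
  cnt <- matrix(0, n, p); s <- matrix(0, n, p)
  sx <- matrix(0, n, p); sxx <- matrix(0, n, p); sxy <- matrix(0, n, p)
  mx <- matrix(-Inf, n, p); mn <- matrix(Inf, n, p)
  last <- matrix(NA_real_, n, p)
  for (j in 0:(span - 1)) {
    if (j == 0) Sj <- V
    else if (j >= n) Sj <- matrix(NA_real_, n, p)
    else {
      Sj <- rbind(matrix(NA_real_, j, p), V[seq_len(n - j), , drop = FALSE])
      Sj[k < j, ] <- NA_real_
    }
    o <- !is.na(Sj)
    Vz <- Sj; Vz[!o] <- 0
    cnt <- cnt + o
    s <- s + Vz
    sx <- sx - j * o
    sxx <- sxx + j * j * o
    sxy <- sxy - j * Vz
    mx <- pmax(mx, Sj, na.rm = TRUE)
    mn <- pmin(mn, Sj, na.rm = TRUE)
    fill <- is.na(last) & o
    last[fill] <- Sj[fill]
  }
  none <- cnt == 0
  mx[none] <- NA_real_; mn[none] <- NA_real_
  mean_ <- s / cnt; mean_[none] <- NA_real_
  den <- cnt * sxx - sx * sx
  slope <- (cnt * sxy - sx * s) / den
  slope[cnt < 2 | den == 0] <- NA_real_
  list(last = last, min = mn, max = mx, mean = mean_, count = cnt,
       slope = slope)
}

#' Rolling-window aggregate features
#'
#' For every window (or one window `k`) of the grid, aggregates each
#' registered concept over the lookback span of `lookback_days * 24 /
#' window_hours` windows ending at (and including) the window, clipped at
#' admission: last, min, max, mean, count and the least-squares slope over
#' window index. Age at admission and a male-sex indicator are appended.
#' Aggregates of concepts unobserved in the span are NA (count 0); the
#' returned matrix is un-imputed — model training imputes and records the
#' imputation constants.
#'
#' @param windows Grid from [build_windows()].
#' @param reg The registry (for demographics).
#' @param feature_registry Concept-by-aggregator table; default
#'   [default_feature_registry()].
#' @param lookback_days Lookback in days (default 7).
#' @param window_hours Window width used to build the grid.
#' @param k Optional single window index: restrict output to that window of
#'   a single-stay grid.
#' @return List with `X` (numeric matrix, one row per grid row) and
#'   `feature_names`.
#' @export
rolling_features <- function(windows, reg,
                             feature_registry = default_feature_registry(),
                             lookback_days = 7, window_hours = 6, k = NULL) {
  span <- as.integer(lookback_days * 24 / window_hours)
  concepts <- feature_registry$concept_id
  V <- matrix(NA_real_, nrow(windows), length(concepts),
              dimnames = list(NULL, concepts))
  for (cc in concepts) if (cc %in% names(windows))
    V[, cc] <- windows[[cc]]
  stats <- .rolling_stats(V, windows$window_index, span)

  cols <- list(); nm <- character(0)
  for (i in seq_along(concepts)) {
    aggs <- strsplit(feature_registry$aggregators[i], ",", fixed = TRUE)[[1]]
    aggs <- trimws(aggs)
    bad <- setdiff(aggs, .all_aggregators)
    if (length(bad)) .stopf("unknown aggregator '%s'", bad[1])
    for (a in aggs) {
      cols[[length(cols) + 1L]] <- stats[[a]][, i]
      nm <- c(nm, paste0(concepts[i], ".", a))
    }
  }
  demo <- merge(windows[, .(stay_id)],
                merge(reg$stays[, .(stay_id, patient_id, admit_ts)],
                      reg$patients[, .(patient_id, sex, birth_year)],
                      by = "patient_id"),
                by = "stay_id", sort = FALSE)
  cols[[length(cols) + 1L]] <-
    as.numeric(format(demo$admit_ts, "%Y")) - demo$birth_year
  cols[[length(cols) + 1L]] <- as.numeric(demo$sex == "M")
  nm <- c(nm, "age", "sex_male")
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  if (!is.null(k)) {
    idx <- which(windows$window_index == k)
    if (length(idx) != 1) .stopf("window index %d not unique in grid", k)
    X <- X[idx, , drop = FALSE]
  }
  list(X = X, feature_names = nm)
}

# Forward-fill each concept within stay up to `max_gap` windows, then
# impute the supplied population medians. Returns values plus observed
# masks; imputation never alters observed windows.
.impute_sequences <- function(V, k, max_gap, medians) {
  n <- nrow(V); p <- ncol(V)
  M <- !is.na(V)
  Vf <- V
  carry <- V[1, , drop = TRUE]
  age <- rep(0L, p)
  if (n >= 2) for (i in 2:n) {
    if (k[i] == 0L) { carry <- rep(NA_real_, p); age <- rep(0L, p) }
    obs <- !is.na(V[i, ])
    age <- ifelse(obs, 0L, age + 1L)
    use <- !obs & !is.na(carry) & age <= max_gap
    Vf[i, use] <- carry[use]
    carry <- ifelse(obs, V[i, ], carry)
  }
  for (jj in seq_len(p)) Vf[is.na(Vf[, jj]), jj] <- medians[jj]
  list(values = Vf, mask = M)
}

#' Build right-aligned sequence tensors
#'
#' For each target window, the sequence of the preceding
#' `lookback_days * 24 / window_hours` steps (default 28: seven days of
#' four 6-h windows), right-aligned at the target window. Each step carries
#' the imputed channel values (forward-fill within stay up to
#' `ffill_max_hours`, then population medians) and a binary observed mask
#' per channel; steps before admission are zero-valued with mask 0.
#'
#' @param windows Grid from [build_windows()].
#' @param concepts Channel concepts (default [core_concepts()]).
#' @param lookback_days,window_hours Span definition (defaults 7 and 6).
#' @param ffill_max_hours Maximum forward-fill horizon (default 48).
#' @param medians Optional named vector of per-concept imputation medians
#'   (recorded at training time); computed from the grid when NULL.
#' @param k Optional single window index (single-stay grid): return one
#'   `steps x 2*channels` matrix instead of the full step list.
#' @return For `k = NULL`: list with `steps` (list of `span` matrices, each
#'   `n x 2*channels`, ordered oldest to newest), `medians`, and
#'   `channel_names`. For a single `k`: a `span x 2*channels` matrix.
#' @export
build_sequence <- function(windows, concepts = core_concepts(),
                           lookback_days = 7, window_hours = 6,
                           ffill_max_hours = 48, medians = NULL, k = NULL) {
  span <- as.integer(lookback_days * 24 / window_hours)
  max_gap <- as.integer(ffill_max_hours / window_hours)
  n <- nrow(windows); p <- length(concepts)
  V <- matrix(NA_real_, n, p, dimnames = list(NULL, concepts))
  for (cc in concepts) if (cc %in% names(windows)) V[, cc] <- windows[[cc]]
  if (is.null(medians)) {
    medians <- apply(V, 2, median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
  } else medians <- medians[concepts]
  imp <- .impute_sequences(V, windows$window_index, max_gap, medians)
  kvec <- windows$window_index
  steps <- vector("list", span)
  for (s in seq_len(span)) {
    j <- span - s                      # lag of step s behind the target
    if (j == 0) { val <- imp$values; msk <- imp$mask }
    else if (j >= n) {
      val <- matrix(NA_real_, n, p); msk <- matrix(FALSE, n, p)
    } else {
      val <- rbind(matrix(NA_real_, j, p),
                   imp$values[seq_len(n - j), , drop = FALSE])
      msk <- rbind(matrix(FALSE, j, p),
                   imp$mask[seq_len(n - j), , drop = FALSE])
      pre <- kvec < j                  # step precedes admission: padding
      val[pre, ] <- NA_real_
      msk[pre, ] <- FALSE
    }
    val[is.na(val)] <- 0
    steps[[s]] <- cbind(val, msk * 1)
  }
  ch <- c(concepts, paste0(concepts, ".mask"))
  for (s in seq_len(span)) colnames(steps[[s]]) <- ch
  if (!is.null(k)) {
    idx <- which(windows$window_index == k)
    if (length(idx) != 1) .stopf("window index %d not unique in grid", k)
    out <- do.call(rbind, lapply(steps, function(m) m[idx, ]))
    rownames(out) <- NULL
    return(out)
  }
  list(steps = steps, medians = medians, channel_names = ch)
}
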