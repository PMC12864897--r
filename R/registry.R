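# The tabular sepsis registry: container, validation, and delimited I/O.
#
# One CSV per table, ISO-8601 UTC timestamps at minute resolution, all
# intervals half-open [start, end). Inspectable and diff-able by design.

.registry_tables <- c("patients", "stays", "ward_segments", "observations",
                      "medications", "events", "icd_codes")

.registry_schema <- list(
  patients = c(patient_id = "character", sex = "character",
               birth_year = "integer"),
  stays = c(stay_id = "character", patient_id = "character",
            admit_ts = "POSIXct", discharge_ts = "POSIXct",
            in_hospital_death = "logical", death_ts = "POSIXct"),
  ward_segments = c(stay_id = "character", ward_id = "character",
                    ward_group = "character", start_ts = "POSIXct",
                    end_ts = "POSIXct"),
  observations = c(stay_id = "character", concept_id = "character",
                   ts = "POSIXct", value = "numeric", unit = "character"),
  medications = c(stay_id = "character", drug_class = "character",
                  admin_ts = "POSIXct"),
  events = c(event_id = "character", stay_id = "character", t0 = "POSIXct",
             fine_label = "character", source = "character",
             infection = "logical", organ_failure = "logical",
             alt_etiology = "logical"),
  icd_codes = c(stay_id = "character", code = "character")
)

.ward_groups <- c("MED", "GIS", "EMD", "CONTROL", "OTHER")

#' Construct a sepsis registry
#'
#' Bundles the seven registry tables (patients, stays, ward segments,
#' observations, medications, clinician-adjudicated sepsis events, ICD
#' codes) into a validated `slhs_registry` object. All timestamps are
#' POSIXct UTC at minute resolution; intervals are half-open.
#'
#' @param patients,stays,ward_segments,observations,medications,events,icd_codes
#'   data.frames conforming to the documented schema.
#' @param validate Run [validate_registry()] (default TRUE).
#' @return An `slhs_registry` object (a named list of data.tables).
#' @export
registry <- function(patients, stays, ward_segments, observations,
                     medications, events, icd_codes, validate = TRUE) {
  reg <- list(patients = as.data.table(patients),
              stays = as.data.table(stays),
              ward_segments = as.data.table(ward_segments),
              observations = as.data.table(observations),
              medications = as.data.table(medications),
              events = as.data.table(events),
              icd_codes = as.data.table(icd_codes))
  class(reg) <- "slhs_registry"
  if (validate) validate_registry(reg)
  reg
}

#' @export
print.slhs_registry <- function(x, ...) {
  cat("<slhs_registry>\n")
  for (tb in .registry_tables)
    cat(sprintf("  %-13s %8d rows\n", tb, nrow(x[[tb]])))
  yrs <- format(range(x$stays$admit_ts), "%Y")
  cat(sprintf("  calendar %s-%s; %d patients, %d stays, %d sepsis events\n",
              yrs[1], yrs[2], nrow(x$patients), nrow(x$stays),
              nrow(x$events)))
  invisible(x)
}

#' Validate a registry
#'
#' Checks the documented schema (presence and type of every column) and the
#' structural invariants: referential integrity of `stay_id`/`patient_id`,
#' admission before discharge, ward segments non-overlapping and inside
#' their stay, event onsets inside their stay, death timestamps present
#' exactly for recorded deaths, and valid categorical codes. Violations
#' raise a classed error (`slhs_schema_error` or `slhs_integrity_error`)
#' naming the table, column and offending rows.
#'
#' @param reg An `slhs_registry`.
#' @return Invisibly TRUE on success.
#' @export
validate_registry <- function(reg) {
  schema_err <- function(fmt, ...) {
    stop(structure(class = c("slhs_schema_error", "error", "condition"),
                   list(message = sprintf(fmt, ...), call = NULL)))
  }
  integ_err <- function(fmt, ...) {
    stop(structure(class = c("slhs_integrity_error", "error", "condition"),
                   list(message = sprintf(fmt, ...), call = NULL)))
  }
  for (tb in .registry_tables) {
    if (is.null(reg[[tb]])) schema_err("missing table '%s'", tb)
    sch <- .registry_schema[[tb]]
    for (col in names(sch)) {
      if (!col %in% names(reg[[tb]]))
        schema_err("table '%s' lacks column '%s'", tb, col)
      x <- reg[[tb]][[col]]
      ok <- switch(sch[[col]],
                   character = is.character(x),
                   integer = is.integer(x) || (is.numeric(x) && all(x == as.integer(x), na.rm = TRUE)),
                   numeric = is.numeric(x),
                   logical = is.logical(x),
                   POSIXct = inherits(x, "POSIXct"))
      if (!ok) schema_err("table '%s' column '%s' has wrong type (want %s)",
                          tb, col, sch[[col]])
    }
  }
  st <- reg$stays
  if (anyDuplicated(st$stay_id))
    integ_err("stays: duplicated stay_id")
  if (anyDuplicated(reg$patients$patient_id))
    integ_err("patients: duplicated patient_id")
  bad <- which(!(st$admit_ts < st$discharge_ts))
  if (length(bad))
    integ_err("stays: admit_ts >= discharge_ts at rows %s",
              paste(head(bad, 5), collapse = ", "))
  orphan <- function(tab, name) {
    miss <- which(!(reg[[tab]]$stay_id %in% st$stay_id))
    if (length(miss))
      integ_err("%s: unknown stay_id at rows %s (e.g. '%s')", name,
                paste(head(miss, 5), collapse = ", "),
                reg[[tab]]$stay_id[miss[1]])
  }
  for (tb in c("ward_segments", "observations", "medications", "events",
               "icd_codes")) orphan(tb, tb)
  miss <- which(!(st$patient_id %in% reg$patients$patient_id))
  if (length(miss))
    integ_err("stays: unknown patient_id at rows %s",
              paste(head(miss, 5), collapse = ", "))

  ws <- merge(reg$ward_segments, st[, .(stay_id, admit_ts, discharge_ts)],
              by = "stay_id")
  bad <- which(ws$start_ts < ws$admit_ts | ws$end_ts > ws$discharge_ts |
                 ws$start_ts >= ws$end_ts)
  if (length(bad))
    integ_err("ward_segments: segment outside stay or empty at rows %s",
              paste(head(bad, 5), collapse = ", "))
  if (!all(ws$ward_group %in% .ward_groups))
    integ_err("ward_segments: invalid ward_group")
  ovl <- ws[order(stay_id, start_ts)][,
    any(head(end_ts, -1) > tail(start_ts, -1)), by = stay_id]
  if (any(ovl$V1))
    integ_err("ward_segments: overlapping segments in stay '%s'",
              ovl[which(ovl$V1)[1], stay_id])

  ev <- merge(reg$events, st[, .(stay_id, admit_ts, discharge_ts)],
              by = "stay_id")
  bad <- which(ev$t0 < ev$admit_ts | ev$t0 >= ev$discharge_ts)
  if (length(bad))
    integ_err("events: t0 outside stay interval at rows %s",
              paste(head(bad, 5), collapse = ", "))
  if (!all(reg$events$fine_label %in% fine_label_levels()))
    integ_err("events: invalid fine_label")
  if (!all(reg$events$source %in% c("orderset", "id_consult")))
    integ_err("events: invalid source")
  if (anyDuplicated(reg$events$event_id))
    integ_err("events: duplicated event_id")

  if (!all(reg$patients$sex %in% c("M", "F")))
    integ_err("patients: sex must be M or F")
  if (!all(reg$medications$drug_class %in%
             c("antibiotic", "vasopressor", "other")))
    integ_err("medications: invalid drug_class")
  bad <- which(st$in_hospital_death & is.na(st$death_ts))
  if (length(bad))
    integ_err("stays: in_hospital_death without death_ts at rows %s",
              paste(head(bad, 5), collapse = ", "))
  bad <- which(st$in_hospital_death & !is.na(st$death_ts) &
                 (st$death_ts > st$discharge_ts | st$death_ts < st$admit_ts))
  if (length(bad))
    integ_err("stays: in-hospital death_ts outside stay at rows %s",
              paste(head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

.ts_fmt <- "%Y-%m-%dT%H:%M:%SZ"

#' Write a registry to a directory of CSV files
#'
#' One CSV per table with a documented header; timestamps serialized
#' ISO-8601 UTC. [read_registry()] on the output reconstructs a
#' structurally identical registry.
#'
#' @param reg An `slhs_registry`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_registry <- function(reg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in .registry_tables) {
    d <- as.data.frame(reg[[tb]])
    for (col in names(d))
      if (inherits(d[[col]], "POSIXct"))
        d[[col]] <- format(d[[col]], .ts_fmt, tz = "UTC")
    write.csv(d, file.path(dir, paste0(tb, ".csv")), row.names = FALSE,
              na = "")
  }
  invisible(dir)
}

#' Read a registry from a directory of CSV files
#'
#' Reads the seven table files written by [write_registry()], restores
#' column types, and validates. Missing files, schema mismatches and
#' integrity violations raise distinct classed errors.
#'
#' @param dir Directory containing `patients.csv`, `stays.csv`, etc.
#' @return A validated `slhs_registry`.
#' @export
read_registry <- function(dir) {
  tabs <- list()
  for (tb in .registry_tables) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(f))
      stop(structure(class = c("slhs_schema_error", "error", "condition"),
                     list(message = sprintf("missing registry file '%s'", f),
                          call = NULL)))
    d <- fread(f, colClasses = "character", na.strings = "")
    sch <- .registry_schema[[tb]]
    for (col in names(sch)) {
      if (!col %in% names(d))
        stop(structure(class = c("slhs_schema_error", "error", "condition"),
                       list(message = sprintf(
                         "file '%s' lacks column '%s'", f, col), call = NULL)))
      d[[col]] <- switch(sch[[col]],
                         character = as.character(d[[col]]),
                         integer = as.integer(d[[col]]),
                         numeric = as.numeric(d[[col]]),
                         logical = as.logical(d[[col]]),
                         POSIXct = as.POSIXct(d[[col]], format = .ts_fmt,
                                              tz = "UTC"))
    }
    tabs[[tb]] <- d[, names(sch), with = FALSE]
  }
  do.call(registry, c(tabs, list(validate = TRUE)))
}

#' Run configuration
#'
#' Central configuration for the pipeline: windowing, lookback, calibration
#' floor, cross-validation folds, feature registry, cohort definitions,
#' sepsis ICD-10 code prefixes and model hyperparameters. Defaults mirror
#' the deployed system: 6-h windows, 7-day lookback, recall floor 0.7,
#' 5-fold patient-grouped cross-validation.
#'
#' @param seed Integer seed for all stochastic steps.
#' @param window_hours Window width (must divide 24).
#' @param lookback_days Rolling lookback in days (>= 1).
#' @param recall_floor Minimum training-set recall for confirmed sepsis,
#'   in (0, 1].
#' @param cv_folds Number of cross-validation folds.
#' @param feature_registry data.frame (`concept_id`, `aggregators`
#'   comma-separated) defining the rolling feature set; default
#'   [default_feature_registry()].
#' @param sequence_concepts Concepts fed to the sequence sub-model.
#' @param slhs_ward_groups Ward groups where the program is deployed.
#' @param control_ward_groups Control ward groups.
#' @param icd_sepsis_prefixes Sepsis ICD-10 code prefixes (the study's own
#'   supplementary list is site-specific; this default is overridable).
#' @param num_trees,max_depth Random-forest sub-model size.
#' @param rnn_hidden,rnn_epochs,rnn_learning_rate Recurrent sub-model size
#'   and training schedule.
#' @param train_ward_groups Optional restriction of training rows to stays
#'   touching these ward groups (department-specific variants).
#' @return A validated `slhs_config` list.
#' @export
run_config <- function(seed = 1L, window_hours = 6L, lookback_days = 7L,
                       recall_floor = 0.7, cv_folds = 5L,
                       feature_registry = default_feature_registry(),
                       sequence_concepts = core_concepts(),
                       slhs_ward_groups = c("MED", "GIS", "EMD"),
                       control_ward_groups = "CONTROL",
                       icd_sepsis_prefixes = c("A40", "A41", "R652", "R572"),
                       num_trees = 200L, max_depth = 12L,
                       rnn_hidden = 16L, rnn_epochs = 12L,
                       rnn_learning_rate = 0.02,
                       train_ward_groups = NULL) {
  cfg <- list(seed = as.integer(seed), window_hours = as.integer(window_hours),
              lookback_days = as.integer(lookback_days),
              recall_floor = recall_floor, cv_folds = as.integer(cv_folds),
              feature_registry = as.data.table(feature_registry),
              sequence_concepts = sequence_concepts,
              slhs_ward_groups = slhs_ward_groups,
              control_ward_groups = control_ward_groups,
              icd_sepsis_prefixes = icd_sepsis_prefixes,
              num_trees = as.integer(num_trees),
              max_depth = as.integer(max_depth),
              rnn_hidden = as.integer(rnn_hidden),
              rnn_epochs = as.integer(rnn_epochs),
              rnn_learning_rate = rnn_learning_rate,
              train_ward_groups = train_ward_groups)
  if (24L %% cfg$window_hours != 0L) .stopf("window_hours must divide 24")
  if (cfg$lookback_days < 1L) .stopf("lookback_days must be >= 1")
  if (!(cfg$recall_floor > 0 && cfg$recall_floor <= 1))
    .stopf("recall_floor must be in (0, 1]")
  if (cfg$cv_folds < 2L) .stopf("cv_folds must be >= 2")
  structure(cfg, class = "slhs_config")
}

#' Read a run configuration from a YAML file
#'
#' Any field of [run_config()] may be set; unset fields keep their
#' defaults. The feature registry may be given as a list of
#' `concept_id`/`aggregators` entries.
#'
#' @param path YAML file path.
#' @return An `slhs_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$feature_registry))
    raw$feature_registry <- rbindlist(lapply(raw$feature_registry,
                                             as.data.table))
  do.call(run_config, raw)
}

#' Does a stay carry a sepsis ICD code?
#'
#' @param codes Character vector of ICD-10 codes.
#' @param prefixes Sepsis code prefixes (dots ignored).
#' @return Logical scalar.
#' @export
has_sepsis_code <- function(codes, prefixes = c("A40", "A41", "R652", "R572")) {
  if (length(codes) == 0) return(FALSE)
  cl <- toupper(gsub("\\.", "", codes))
  pr <- toupper(gsub("\\.", "", prefixes))
  any(vapply(pr, function(p) any(startsWith(cl, p)), logical(1)))
}
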