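# Shared fixtures, generated in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the reference study-scale registry (default generator conditions)
study_registry <- function() cached("study2000", {
  generate_registry(generator_config())
})

small_registry <- function() cached("small300", {
  generate_registry(generator_config(n_stays = 300, seed = 7))
})

# a trained bundle on the study-scale registry (reused across tests)
study_bundle <- function() cached("bundle2000", {
  train_sepsis_model(study_registry(), run_config(seed = 1))
})

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# a minimal hand-built registry: two patients, three stays
tiny_registry <- function() {
  patients <- data.frame(patient_id = c("P1", "P2"), sex = c("M", "F"),
                         birth_year = c(1950L, 1980L))
  stays <- data.frame(
    stay_id = c("S1", "S2", "S3"),
    patient_id = c("P1", "P1", "P2"),
    admit_ts = ts_utc(c("2021-03-01 08:00", "2022-05-10 10:00",
                        "2023-01-05 12:00")),
    discharge_ts = ts_utc(c("2021-03-06 08:00", "2022-05-12 10:00",
                            "2023-01-15 12:00")),
    in_hospital_death = c(FALSE, FALSE, TRUE),
    death_ts = ts_utc(c(NA, NA, "2023-01-15 11:00")))
  ward_segments <- data.frame(
    stay_id = c("S1", "S1", "S2", "S3"),
    ward_id = c("E10", "M11", "C20", "M12"),
    ward_group = c("EMD", "MED", "CONTROL", "MED"),
    start_ts = ts_utc(c("2021-03-01 08:00", "2021-03-02 08:00",
                        "2022-05-10 10:00", "2023-01-05 12:00")),
    end_ts = ts_utc(c("2021-03-02 08:00", "2021-03-06 08:00",
                      "2022-05-12 10:00", "2023-01-15 12:00")))
  observations <- data.frame(
    stay_id = c("S1", "S1", "S1", "S2", "S3"),
    concept_id = c("hr", "hr", "lactate", "hr", "platelets"),
    ts = ts_utc(c("2021-03-01 09:00", "2021-03-01 13:00",
                  "2021-03-02 09:00", "2022-05-10 11:00",
                  "2023-01-06 09:00")),
    value = c(80, 100, 1.1, 72, 240),
    unit = c("/min", "/min", "mmol/L", "/min", "1e9/L"))
  medications <- data.frame(
    stay_id = "S1", drug_class = "antibiotic",
    admin_ts = ts_utc("2021-03-01 10:00"))
  events <- data.frame(
    event_id = "E1", stay_id = "S1",
    t0 = ts_utc("2021-03-01 20:00"),
    fine_label = "2a_sepsis_sensu_stricto", source = "orderset",
    infection = TRUE, organ_failure = TRUE, alt_etiology = FALSE)
  icd_codes <- data.frame(stay_id = c("S1", "S3"),
                          code = c("A41.9", "I21"))
  registry(patients, stays, ward_segments, observations, medications,
           events, icd_codes)
}

# small synthetic training design with a planted separable signal, for
# sub-model and stacker tests without a full registry
toy_training <- function(n = 300, d = 5, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("f", 1:d)))
  lab <- ifelse(X[, 1] > 0.8, "CS", ifelse(X[, 1] < -0.8, "PS", "NS"))
  steps <- lapply(1:4, function(s) {
    m <- matrix(rnorm(n * 3), n, 3)
    m[, 1] <- m[, 1] + 2 * (lab == "CS") - 2 * (lab == "PS")
    colnames(m) <- c("c1", "c2", "c3")
    m
  })
  fold <- rep_len(1:3, n)
  list(X = X, steps = steps, labels = lab, fold = fold)
}
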