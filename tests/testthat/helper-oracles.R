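# Independent oracles: fixture-driven band lookups for the clinical scores,
# an exhaustive rule-table for event classification, and brute-force
# reference implementations for aggregation and ranking metrics.

band_lookup <- function(bands, var_col, var, x) {
  b <- bands[bands[[var_col]] == var, ]
  if (is.na(x)) return(NA_integer_)
  hit <- which(x >= b$lo & x < b$hi)
  stopifnot(length(hit) == 1)
  as.integer(b$score[hit])
}

sofa_oracle <- function(snap) {
  bands <- cached("sofa_bands", read.csv(system.file(
    "extdata", "sofa_bands.csv", package = "slhs")))
  sc <- c(resp = band_lookup(bands, "organ", "resp", snap$pf_ratio),
          coag = band_lookup(bands, "organ", "coag", snap$platelets),
          liver = band_lookup(bands, "organ", "liver", snap$bilirubin),
          cns = band_lookup(bands, "organ", "cns", snap$gcs),
          renal = band_lookup(bands, "organ", "renal", snap$creatinine))
  vc <- snap$vasopressor_class
  cardio <- if (is.na(vc) || vc == "none") {
    if (is.na(snap$map)) NA_integer_ else if (snap$map < 70) 1L else 0L
  } else switch(vc, low = 2L, mid = 3L, high = 4L)
  sc <- c(sc, cardio = cardio)
  sum(sc, na.rm = TRUE)
}

news2_oracle <- function(snap) {
  bands <- cached("news2_bands", read.csv(system.file(
    "extdata", "news2_bands.csv", package = "slhs")))
  s <- c(band_lookup(bands, "vital", "rr", snap$rr),
         band_lookup(bands, "vital", "spo2", snap$spo2),
         if (is.na(snap$on_oxygen)) NA_integer_ else
           if (snap$on_oxygen) 2L else 0L,
         band_lookup(bands, "vital", "temp", snap$temp),
         band_lookup(bands, "vital", "sbp", snap$sbp),
         band_lookup(bands, "vital", "hr", snap$hr),
         if (is.na(snap$consciousness_impaired)) NA_integer_ else
           if (snap$consciousness_impaired) 3L else 0L)
  sum(s, na.rm = TRUE)
}

charlson_oracle <- function(codes) {
  m <- cached("charlson_map_csv", read.csv(
    system.file("extdata", "charlson_icd10.csv", package = "slhs"),
    stringsAsFactors = FALSE))
  codes <- toupper(gsub("\\.", "", codes))
  present <- character(0)
  for (i in seq_len(nrow(m))) {
    for (p in strsplit(m$prefixes[i], ";")[[1]]) {
      if (any(substr(codes, 1, nchar(p)) == p)) {
        present <- c(present, m$category[i]); break
      }
    }
  }
  present <- unique(present)
  for (i in seq_len(nrow(m)))
    if (nzchar(m$supersedes[i]) && m$category[i] %in% present)
      present <- setdiff(present, m$supersedes[i])
  sum(m$weight[match(present, m$category)])
}

# rule-table oracle for event classification, written as a literal
# severity-ordered scan over the six definition rows
classify_oracle <- function(infection, organ_failure, delta, alt, vaso,
                            lact) {
  delta_ge2 <- !is.na(delta) && delta >= 2
  rows <- list(
    list(lab = "2b_septic_shock",
         ok = infection && delta_ge2 && !alt && vaso && lact),
    list(lab = "2a_sepsis_sensu_stricto",
         ok = infection && delta_ge2 && !alt),
    list(lab = "1b_sepsis_sensu_lato",
         ok = infection && delta_ge2 && alt),
    list(lab = "1a_sepsis_like",
         ok = infection && (is.na(delta) || (organ_failure && delta < 2))),
    list(lab = "0_infection", ok = infection),
    list(lab = "0_no_infection", ok = !infection))
  for (r in rows) if (r$ok) return(r$lab)
  stop("no rule matched")
}

auroc_oracle <- function(truth, score, positive, negative) {
  p <- score[truth %in% positive]
  n <- score[truth %in% negative]
  tot <- 0
  for (a in p) for (b in n)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(p) * length(n))
}

kappa_oracle <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  n <- length(a)
  po <- mean(a == b)
  pe <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l),
                   numeric(1)))
  (po - pe) / (1 - pe)
}

random_snapshot <- function() {
  score_snapshot(
    pf_ratio = sample(c(NA, round(runif(1, 50, 550))), 1, prob = c(.3, .7)),
    platelets = sample(c(NA, round(runif(1, 5, 450))), 1, prob = c(.2, .8)),
    bilirubin = sample(c(NA, round(runif(1, 2, 350))), 1, prob = c(.2, .8)),
    map = sample(c(NA, round(runif(1, 40, 120))), 1, prob = c(.2, .8)),
    vasopressor_class = sample(c("none", "low", "mid", "high"), 1,
                               prob = c(.7, .1, .1, .1)),
    gcs = sample(c(NA, sample(3:15, 1)), 1, prob = c(.2, .8)),
    creatinine = sample(c(NA, round(runif(1, 30, 600))), 1, prob = c(.2, .8)),
    rr = sample(c(NA, sample(5:45, 1)), 1, prob = c(.2, .8)),
    spo2 = sample(c(NA, sample(80:100, 1)), 1, prob = c(.2, .8)),
    on_oxygen = sample(c(NA, TRUE, FALSE), 1, prob = c(.2, .3, .5)),
    temp = sample(c(NA, round(runif(1, 34, 41), 1)), 1, prob = c(.2, .8)),
    sbp = sample(c(NA, sample(60:230, 1)), 1, prob = c(.2, .8)),
    hr = sample(c(NA, sample(30:160, 1)), 1, prob = c(.2, .8)),
    consciousness_impaired = sample(c(NA, TRUE, FALSE), 1,
                                    prob = c(.2, .2, .6)))
}
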