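# Machine-readable and human-readable reporting (the static stand-in for
# the system's daily dashboards).

.metrics_to_list <- function(m) {
  if (is.null(m)) return(list(status = "not computed"))
  list(status = "computed",
       n = m$n,
       confusion = as.data.frame.matrix(m$confusion),
       per_class = as.data.frame(m$per_class),
       macro_f1 = m$macro_f1,
       auroc_cs_vs_ns = m$auroc_cs_vs_ns %||% NA_real_,
       auroc_csps_vs_ns = m$auroc_csps_vs_ns %||% NA_real_)
}

#' Write the impact and evaluation report
#'
#' Emits `report.json` (machine-readable; impact fields mirrored
#' one-to-one) and `report.txt` (human-readable summary). Re-running on
#' identical inputs produces byte-identical files; sections that were not
#' computed are marked explicitly.
#'
#' @param impact An `slhs_impact` (or NULL).
#' @param eval An `slhs_metrics` from [metrics_report()] (or NULL).
#' @param path Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(impact, eval, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tta_l <- function(x) {
    if (is.null(x)) return(list(status = "not computed"))
    list(status = "computed", threshold_hours = x$threshold_hours,
         n_pairs = x$n_pairs,
         table = as.data.frame.matrix(x$table),
         statistic = x$statistic, p_value = x$p_value,
         prop_within = as.list(x$prop_within))
  }
  imp_l <- if (is.null(impact)) list(status = "not computed") else
    list(status = "computed",
         indicators = as.data.frame(impact$indicators),
         odds_ratios = as.data.frame(impact$odds_ratios),
         tta = lapply(impact$tta %||%
                        list(within_1h = NULL, within_3h = NULL), tta_l))
  out <- list(impact = imp_l, evaluation = .metrics_to_list(eval))
  jf <- file.path(path, "report.json")
  jsonlite::write_json(out, jf, auto_unbox = TRUE, digits = 8,
                       na = "string", pretty = TRUE)

  lines <- c("SLHS report", "===========")
  if (is.null(eval)) {
    lines <- c(lines, "", "Evaluation: not computed")
  } else {
    lines <- c(lines, "", "Evaluation (stay level)",
               sprintf("  n = %d stays", eval$n),
               sprintf("  macro F1 %.3f", eval$macro_f1),
               sprintf("  AUROC CS vs NS %.3f",
                       eval$auroc_cs_vs_ns %||% NA),
               sprintf("  AUROC CS+PS vs NS %.3f",
                       eval$auroc_csps_vs_ns %||% NA),
               utils::capture.output(print(eval$confusion)))
  }
  if (is.null(impact)) {
    lines <- c(lines, "", "Impact: not computed")
  } else {
    lines <- c(lines, "", "Impact indicators (per cohort-year)",
               utils::capture.output(print(impact$indicators,
                                           class = FALSE)),
               "", "Adjusted odds ratios (per year)",
               utils::capture.output(print(impact$odds_ratios,
                                           class = FALSE)))
    for (nmx in names(impact$tta %||% list())) {
      x <- impact$tta[[nmx]]
      lines <- c(lines, if (is.null(x))
        sprintf("Time-to-antibiotics %s: not computed", nmx)
        else utils::capture.output(print(x)))
    }
  }
  tf <- file.path(path, "report.txt")
  writeLines(lines, tf)
  invisible(c(jf, tf))
}
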