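# The stacked sepsis classifier: random-forest and recurrent sub-models
# over 6-h windows, a second-stage forest over their six class
# probabilities, per-stay aggregation by maximum confirmed-sepsis
# probability, and recall-floor threshold calibration.

.coarse_int <- function(lab) match(lab, coarse_label_levels())

# reindex a probability matrix onto the three coarse classes
.prob3 <- function(P, have = colnames(P)) {
  out <- matrix(0, nrow(P), 3, dimnames = list(NULL, coarse_label_levels()))
  for (lv in intersect(have, coarse_label_levels()))
    out[, lv] <- P[, lv]
  out
}

#' Truth labels for every window of a grid
#'
#' Applies [label_windows()] per stay: a window is labeled by the collapsed
#' most-severe event whose onset falls in its lookback span; event-free
#' stays are all NS.
#'
#' @param reg Registry.
#' @param windows Grid from [build_windows()].
#' @param window_hours,lookback_days Span definition.
#' @return Character vector of NS/PS/CS, one per grid row.
#' @export
window_labels <- function(reg, windows, window_hours = 6, lookback_days = 7) {
  lab <- rep("NS", nrow(windows))
  if (nrow(reg$events) == 0) return(lab)
  idx_by_stay <- split(seq_len(nrow(windows)), windows$stay_id)
  for (sid in unique(reg$events$stay_id)) {
    idx <- idx_by_stay[[sid]]
    if (is.null(idx)) next
    st <- reg$stays[stay_id == sid]
    lab[idx] <- label_windows(windows[idx], reg$events[stay_id == sid],
                              window_hours, lookback_days,
                              c(st$admit_ts, st$discharge_ts))
  }
  lab
}

#' Stay-level truth labels
#'
#' The collapsed most-severe event label of each stay; stays without
#' events are NS.
#'
#' @param reg Registry.
#' @return data.table (`stay_id`, `truth`).
#' @export
stay_labels <- function(reg) {
  out <- data.table(stay_id = reg$stays$stay_id, truth = "NS")
  if (nrow(reg$events) > 0) {
    ev <- reg$events[, .(sev = max(fine_severity(fine_label))), by = stay_id]
    m <- match(ev$stay_id, out$stay_id)
    out$truth[m] <- collapse_label(fine_label_levels()[ev$sev])
  }
  out
}

#' Train the two sub-models with out-of-fold probabilities
#'
#' Fits the random-forest sub-model (on the rolling-feature matrix) and
#' the recurrent sub-model (on the sequence tensors) within a
#' patient-grouped K-fold split, returning strictly out-of-fold
#' probability triples for stacker training plus the per-fold fitted
#' models. Deployment predictions average the fold models. The recurrent
#' sub-model trains on all positive windows plus a subsampled negative
#' background (`rnn_neg_ratio` negatives per positive) with
#' inverse-frequency class weights.
#'
#' @param X Rolling-feature matrix (may contain NA; median-imputed with
#'   the imputation constants recorded for prediction).
#' @param steps Sequence step list from [build_sequence()].
#' @param labels Window labels (NS/PS/CS).
#' @param fold Integer fold id per row (patient-grouped).
#' @param config An [run_config()].
#' @param rnn_neg_ratio Negative subsampling ratio for the recurrent
#'   sub-model.
#' @return List: `oof` (n x 6 matrix: RF then RNN triples), `rf_models`,
#'   `rnn_models`, `x_medians`, `seq_center`, `seq_scale`.
#' @export
train_submodels <- function(X, steps, labels, fold, config,
                            rnn_neg_ratio = 5) {
  lv <- coarse_label_levels()
  if (length(unique(labels)) < 2) .stopf("training labels are single-class")
  if (nrow(X) == 0) .stopf("empty training input")
  y <- factor(labels, levels = lv)
  x_medians <- apply(X, 2, median, na.rm = TRUE)
  x_medians[is.na(x_medians)] <- 0
  Xi <- X
  for (j in seq_len(ncol(Xi))) {
    nas <- is.na(Xi[, j])
    if (any(nas)) Xi[nas, j] <- x_medians[j]
  }
  # channel-wise standardization of sequence values (masks untouched)
  nch <- ncol(steps[[1]])
  flat <- do.call(rbind, steps)
  seq_center <- colMeans(flat)
  seq_scale <- apply(flat, 2, sd)
  mask_cols <- grepl("\\.mask$", colnames(steps[[1]]))
  seq_center[mask_cols] <- 0
  seq_scale[mask_cols | seq_scale < 1e-8] <- 1
  steps_z <- lapply(steps, function(m)
    sweep(sweep(m, 2, seq_center, "-"), 2, seq_scale, "/"))

  tab <- table(y)
  cw <- as.numeric(sum(tab) / (length(lv) * pmax(tab, 1)))
  names(cw) <- lv
  folds <- sort(unique(fold))
  oof <- matrix(NA_real_, nrow(X), 6)
  colnames(oof) <- c(paste0("rf_", lv), paste0("rnn_", lv))
  rf_models <- list(); rnn_models <- list()
  for (f in folds) {
    tr <- which(fold != f); te <- which(fold == f)
    rf <- ranger::ranger(x = Xi[tr, , drop = FALSE], y = droplevels(y[tr]),
                         probability = TRUE,
                         num.trees = config$num_trees,
                         max.depth = config$max_depth,
                         class.weights = cw[levels(droplevels(y[tr]))],
                         seed = config$seed + f, num.threads = 1)
    oof[te, 1:3] <- .prob3(predict(rf, Xi[te, , drop = FALSE],
                                   num.threads = 1)$predictions)
    # negative subsampling for the recurrent net
    yi <- as.integer(y)
    pos <- tr[yi[tr] > 1]
    neg <- tr[yi[tr] == 1]
    set.seed(config$seed + 100 + f)
    n_neg <- min(length(neg), max(rnn_neg_ratio * max(length(pos), 50), 200))
    sub <- c(pos, sample(neg, n_neg))
    xs_tr <- lapply(steps_z, function(m) m[sub, , drop = FALSE])
    rnn <- rnn_fit(xs_tr, yi[sub], k = 3, hidden = config$rnn_hidden,
                   epochs = config$rnn_epochs,
                   learning_rate = config$rnn_learning_rate,
                   seed = config$seed + 200 + f)
    xs_te <- lapply(steps_z, function(m) m[te, , drop = FALSE])
    oof[te, 4:6] <- predict(rnn, xs_te)
    rf_models[[as.character(f)]] <- rf
    rnn_models[[as.character(f)]] <- rnn
  }
  list(oof = oof, rf_models = rf_models, rnn_models = rnn_models,
       x_medians = x_medians, seq_center = seq_center,
       seq_scale = seq_scale)
}

#' Train the stacking layer
#'
#' Second-stage random forest over exactly six inputs: the two sub-models'
#' out-of-fold class probability triples.
#'
#' @param P6 n x 6 matrix of sub-model probabilities.
#' @param labels Window labels.
#' @param config An [run_config()].
#' @param seed_offset Added to the configured seed.
#' @return A fitted ranger probability forest.
#' @export
train_stacker <- function(P6, labels, config, seed_offset = 0) {
  if (ncol(P6) != 6)
    .stopf("stacking layer requires exactly 6 probability inputs, got %d",
           ncol(P6))
  if (is.null(colnames(P6)))
    colnames(P6) <- c(paste0("rf_", coarse_label_levels()),
                      paste0("rnn_", coarse_label_levels()))
  y <- factor(labels, levels = coarse_label_levels())
  tab <- table(y)
  cw <- as.numeric(sum(tab) / (3 * pmax(tab, 1)))
  names(cw) <- coarse_label_levels()
  ranger::ranger(x = P6, y = droplevels(y), probability = TRUE,
                 num.trees = max(100L, config$num_trees %/% 2L),
                 class.weights = cw[levels(droplevels(y))],
                 seed = config$seed + 300 + seed_offset, num.threads = 1)
}

#' Calibrate the decision threshold to a recall floor
#'
#' Returns the largest threshold tau such that flagging stays with
#' confirmed-sepsis probability >= tau attains at least the configured
#' recall for confirmed-sepsis stays on the training set (the construction
#' rule "minimum recall for confirmed sepsis in the training set").
#'
#' @param cs_prob Stay-level confirmed-sepsis probabilities.
#' @param truth Stay-level truth labels.
#' @param recall_floor Required minimum recall, in (0, 1].
#' @return List `threshold`, `recall`, `precision`, `recall_floor`.
#' @export
calibrate_threshold <- function(cs_prob, truth, recall_floor = 0.7) {
  if (!(recall_floor > 0 && recall_floor <= 1))
    .stopf("recall_floor must be in (0, 1]")
  cs <- cs_prob[truth == "CS"]
  if (length(cs) == 0) .stopf("no confirmed-sepsis stay in training data")
  need <- ceiling(recall_floor * length(cs))
  tau <- sort(cs, decreasing = TRUE)[need]
  if (is.na(tau) || tau <= 0)
    .stopf("recall floor %.2f unattainable: confirmed-sepsis probabilities not produced",
           recall_floor)
  flag <- cs_prob >= tau
  list(threshold = tau,
       recall = mean(cs >= tau),
       precision = if (any(flag)) mean(truth[flag] == "CS") else NA_real_,
       recall_floor = recall_floor)
}

# per-stay aggregation: max CS probability; 3-class label of the window
# attaining it, ties toward higher severity
.aggregate_stays <- function(stay_ids, Pw) {
  dt <- data.table(stay_id = stay_ids, ns = Pw[, 1], ps = Pw[, 2],
                   cs = Pw[, 3])
  dt[, w := seq_len(.N)]
  agg <- dt[, {
    i <- which.max(cs)
    trip <- c(ns[i], ps[i], cs[i])
    cls <- max(which(trip == max(trip)))   # tie toward higher severity
    .(cs_prob = cs[i], label = coarse_label_levels()[cls])
  }, by = stay_id]
  agg
}

#' Train the full stacked sepsis model
#'
#' End-to-end training on a registry: builds the window grid, labels,
#' rolling features and sequence tensors; fits both sub-models with
#' patient-grouped K-fold out-of-fold probabilities; trains the stacking
#' layer on the out-of-fold triples; aggregates window probabilities to
#' stays (maximum confirmed-sepsis probability); calibrates the decision
#' threshold to the configured recall floor; and computes the
#' cross-validated metrics report. Optionally restricts training to stays
#' touching configured ward groups (department-specific variants).
#'
#' @param reg Registry.
#' @param config A [run_config()].
#' @return An `slhs_model` bundle.
#' @export
train_sepsis_model <- function(reg, config = run_config()) {
  set.seed(config$seed)
  windows <- build_windows(reg, config$window_hours)
  if (!is.null(config$train_ward_groups)) {
    keep_stays <- unique(reg$ward_segments[
      ward_group %in% config$train_ward_groups, stay_id])
    windows <- windows[stay_id %in% keep_stays]
  }
  wl <- window_labels(reg, windows, config$window_hours,
                      config$lookback_days)
  feat <- rolling_features(windows, reg, config$feature_registry,
                           config$lookback_days, config$window_hours)
  sq <- build_sequence(windows, config$sequence_concepts,
                       config$lookback_days, config$window_hours)
  # patient-grouped folds
  pat <- reg$stays[match(windows$stay_id, stay_id), patient_id]
  upat <- unique(pat)
  pfold <- sample(rep_len(seq_len(config$cv_folds), length(upat)))
  fold <- pfold[match(pat, upat)]
  sub <- train_submodels(feat$X, sq$steps, wl, fold, config)
  stacker <- train_stacker(sub$oof, wl, config)
  Pw <- .prob3(predict(stacker, sub$oof, num.threads = 1)$predictions)
  agg <- .aggregate_stays(windows$stay_id, Pw)
  truth <- stay_labels(reg)
  agg <- merge(agg, truth, by = "stay_id")
  cal <- calibrate_threshold(agg$cs_prob, agg$truth, config$recall_floor)
  agg[, flagged := cs_prob >= cal$threshold]

  # per-fold validation: stacker refitted without the fold, applied to the
  # fold's out-of-fold sub-model probabilities
  stay_fold <- data.table(stay_id = windows$stay_id, fold = fold)[
    , .(fold = fold[1]), by = stay_id]
  per_fold <- vector("list", config$cv_folds)
  cv_pred <- vector("list", config$cv_folds)
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- fold == f
    stk <- train_stacker(sub$oof[tr, , drop = FALSE], wl[tr], config,
                         seed_offset = f)
    Pf <- .prob3(predict(stk, sub$oof[te, , drop = FALSE],
                         num.threads = 1)$predictions)
    aggf <- .aggregate_stays(windows$stay_id[te], Pf)
    aggf <- merge(aggf, truth, by = "stay_id")
    aggf[, fold := f]
    per_fold[[f]] <- metrics_report(aggf$truth, aggf$label, aggf$cs_prob)
    cv_pred[[f]] <- aggf
  }
  cv_pred <- rbindlist(cv_pred)
  cv <- structure(list(per_fold = per_fold,
                       pooled = .pool_cv(per_fold),
                       predictions = cv_pred,
                       folds = config$cv_folds),
                  class = "slhs_cv_report")

  structure(list(
    rf_models = sub$rf_models, rnn_models = sub$rnn_models,
    stacker = stacker, threshold = cal$threshold, calibration = cal,
    config = config, x_medians = sub$x_medians,
    seq_center = sub$seq_center, seq_scale = sub$seq_scale,
    seq_medians = sq$medians, feature_names = feat$feature_names,
    version = sprintf("stacked-seed%d-n%d", config$seed,
                      nrow(reg$stays)),
    fingerprint = sprintf("%d stays / %d windows", nrow(reg$stays),
                          nrow(windows)),
    cv_report = cv, train_stays = agg), class = "slhs_model")
}

.pool_cv <- function(per_fold) {
  pull <- function(m) {
    pc <- m$per_class
    c(setNames(pc$f1, paste0("f1_", tolower(pc$class))),
      setNames(pc$precision, paste0("precision_", tolower(pc$class))),
      setNames(pc$recall, paste0("recall_", tolower(pc$class))),
      macro_f1 = m$macro_f1, auroc_cs_vs_ns = m$auroc_cs_vs_ns,
      auroc_csps_vs_ns = m$auroc_csps_vs_ns)
  }
  M <- do.call(rbind, lapply(per_fold, pull))
  data.table(metric = colnames(M),
             mean = colMeans(M, na.rm = TRUE),
             sd = apply(M, 2, sd, na.rm = TRUE))
}

#' @export
print.slhs_model <- function(x, ...) {
  cat("<slhs_model>", x$version, "\n")
  cat(sprintf("  threshold %.4f (recall floor %.2f, training recall %.3f)\n",
              x$threshold, x$calibration$recall_floor, x$calibration$recall))
  cat(sprintf("  CV (%d folds) CS F1 %.3f, AUROC CS-vs-NS %.3f\n",
              x$cv_report$folds,
              x$cv_report$pooled[metric == "f1_cs", mean],
              x$cv_report$pooled[metric == "auroc_cs_vs_ns", mean]))
  invisible(x)
}

#' Cross-validated metrics for a registry
#'
#' Patient-grouped K-fold validation of the full stack (the spec of the
#' monthly internal validation): per-fold per-class precision/recall/F1,
#' both AUROC contrasts, and pooled means with dispersion.
#'
#' @param reg Registry.
#' @param config A [run_config()].
#' @return An `slhs_cv_report`.
#' @export
cross_validate <- function(reg, config = run_config()) {
  train_sepsis_model(reg, config)$cv_report
}

#' @export
print.slhs_cv_report <- function(x, ...) {
  cat("<slhs_cv_report>", x$folds, "folds,", nrow(x$predictions),
      "stays\n")
  print(x$pooled, digits = 3)
  invisible(x)
}

#' Predict stays with a trained bundle
#'
#' Builds the window grid and features for the given registry, averages
#' the fold sub-models' probability triples, applies the stacking layer,
#' aggregates per stay by maximum confirmed-sepsis probability, and flags
#' stays at the calibrated threshold.
#'
#' @param bundle An `slhs_model`.
#' @param reg Registry to predict.
#' @return data.table: `stay_id`, `cs_prob`, `label`, `flagged`.
#' @export
predict_stays <- function(bundle, reg) {
  cfg <- bundle$config
  windows <- build_windows(reg, cfg$window_hours)
  feat <- rolling_features(windows, reg, cfg$feature_registry,
                           cfg$lookback_days, cfg$window_hours)
  Xi <- feat$X
  for (j in seq_len(ncol(Xi))) {
    nas <- is.na(Xi[, j])
    if (any(nas)) Xi[nas, j] <- bundle$x_medians[j]
  }
  sq <- build_sequence(windows, cfg$sequence_concepts, cfg$lookback_days,
                       cfg$window_hours, medians = bundle$seq_medians)
  steps_z <- lapply(sq$steps, function(m)
    sweep(sweep(m, 2, bundle$seq_center, "-"), 2, bundle$seq_scale, "/"))
  Prf <- Reduce(`+`, lapply(bundle$rf_models, function(m)
    .prob3(predict(m, Xi, num.threads = 1)$predictions))) /
    length(bundle$rf_models)
  Prnn <- Reduce(`+`, lapply(bundle$rnn_models, function(m)
    predict(m, steps_z))) / length(bundle$rnn_models)
  P6 <- cbind(Prf, Prnn)
  colnames(P6) <- c(paste0("rf_", coarse_label_levels()),
                    paste0("rnn_", coarse_label_levels()))
  Pw <- .prob3(predict(bundle$stacker, P6, num.threads = 1)$predictions)
  agg <- .aggregate_stays(windows$stay_id, Pw)
  agg[, flagged := cs_prob >= bundle$threshold]
  agg[]
}

#' Predict a single stay
#'
#' @param bundle An `slhs_model`.
#' @param reg Registry.
#' @param stay_id_ Stay identifier.
#' @return One-row data.table as in [predict_stays()].
#' @export
predict_stay <- function(bundle, reg, stay_id_) {
  if (!stay_id_ %in% reg$stays$stay_id) .stopf("unknown stay '%s'", stay_id_)
  sub <- registry(reg$patients, reg$stays[stay_id == stay_id_],
                  reg$ward_segments[stay_id == stay_id_],
                  reg$observations[stay_id == stay_id_],
                  reg$medications[stay_id == stay_id_],
                  reg$events[stay_id == stay_id_],
                  reg$icd_codes[stay_id == stay_id_], validate = FALSE)
  predict_stays(bundle, sub)
}

#' Champion-challenger deployment gate
#'
#' Deploys the challenger only on strict improvement of the selection
#' metric (default: pooled confirmed-sepsis F1); ties keep the champion.
#'
#' @param challenger,champion `slhs_cv_report` objects.
#' @param metric Metric name in the pooled table (e.g. `"f1_cs"`,
#'   `"macro_f1"`, `"auroc_cs_vs_ns"`).
#' @return List `deploy` (logical), `challenger_metric`,
#'   `champion_metric`, `metric`.
#' @export
champion_challenger_gate <- function(challenger, champion,
                                     metric = "f1_cs") {
  gv <- function(rep) {
    p <- as.data.frame(rep$pooled)
    v <- p$mean[p$metric == metric]
    if (length(v) != 1 || is.na(v))
      .stopf("metric '%s' missing from report", metric)
    v
  }
  cm <- gv(champion); ch <- gv(challenger)
  list(deploy = ch > cm, challenger_metric = ch, champion_metric = cm,
       metric = metric)
}

#' Save / load a trained bundle
#'
#' The bundle is persisted as a versioned directory holding the serialized
#' model and a plain-text manifest (version, threshold, seed, pooled CV
#' metrics).
#'
#' @param bundle An `slhs_model`.
#' @param dir Target directory.
#' @return `save_model`: the directory, invisibly. `load_model`: the
#'   bundle.
#' @export
save_model <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(bundle, file.path(dir, "model.rds"))
  man <- c(sprintf("version: %s", bundle$version),
           sprintf("threshold: %.6f", bundle$threshold),
           sprintf("recall_floor: %.2f", bundle$calibration$recall_floor),
           sprintf("seed: %d", bundle$config$seed),
           sprintf("fingerprint: %s", bundle$fingerprint),
           sprintf("cv_f1_cs: %.4f",
                   bundle$cv_report$pooled[metric == "f1_cs", mean]))
  writeLines(man, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) readRDS(file.path(dir, "model.rds"))
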