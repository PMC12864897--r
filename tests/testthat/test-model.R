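test_that("threshold calibration is the largest threshold meeting the recall floor", {
  # brute-force over candidate thresholds
  brute <- function(cs_prob, truth, floor) {
    cand <- sort(unique(cs_prob), decreasing = TRUE)
    for (tau in cand) {
      rec <- mean(cs_prob[truth == "CS"] >= tau)
      if (rec >= floor) return(tau)
    }
    NA_real_
  }
  truth <- c("CS", "CS", "CS", "NS", "NS")
  prob <- c(0.9, 0.8, 0.2, 0.5, 0.1)
  cal <- calibrate_threshold(prob, truth, 0.7)
  expect_equal(cal$threshold, 0.2)
  expect_equal(cal$threshold, brute(prob, truth, 0.7))
  expect_equal(cal$recall, 1.0)
  # at the floor exactly 2/3 < 0.7 fails, so tau drops to 0.2
  expect_lt(mean(prob[truth == "CS"] >= 0.8), 0.7)
  # floor 1 forces tau to the smallest confirmed-sepsis probability
  cal1 <- calibrate_threshold(prob, truth, 1.0)
  expect_equal(cal1$threshold, min(prob[truth == "CS"]))
  set.seed(8)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    truth_i <- sample(c("CS", "NS", "PS"), n, replace = TRUE)
    if (!any(truth_i == "CS")) next
    prob_i <- round(runif(n), 2)
    if (all(prob_i[truth_i == "CS"] == 0)) next
    fl <- runif(1, 0.3, 1)
    cal_i <- calibrate_threshold(prob_i, truth_i, fl)
    expect_equal(cal_i$threshold, brute(prob_i, truth_i, fl))
    expect_gte(cal_i$recall, fl)
  }
  expect_error(calibrate_threshold(prob, truth, 0), "recall_floor")
  expect_error(calibrate_threshold(c(0.2), c("NS"), 0.7), "no confirmed")
  expect_error(calibrate_threshold(c(0, 0), c("CS", "CS"), 0.7),
               "unattainable")
})

test_that("sub-models produce normalized out-of-fold probabilities and learn a separable signal", {
  toy <- toy_training()
  cfg <- run_config(seed = 4, num_trees = 100, rnn_hidden = 6,
                    rnn_epochs = 15)
  sub <- train_submodels(toy$X, toy$steps, toy$labels, toy$fold, cfg)
  expect_equal(dim(sub$oof), c(300L, 6L))
  expect_equal(rowSums(sub$oof[, 1:3]), rep(1, 300), tolerance = 1e-6)
  expect_equal(rowSums(sub$oof[, 4:6]), rep(1, 300), tolerance = 1e-6)
  # the planted threshold rule is recovered out-of-fold by the forest
  pred <- coarse_label_levels()[max.col(sub$oof[, 1:3])]
  expect_gt(mean(pred == toy$labels), 0.9)
  # determinism
  sub2 <- train_submodels(toy$X, toy$steps, toy$labels, toy$fold, cfg)
  expect_identical(sub$oof, sub2$oof)
  expect_error(train_submodels(toy$X, toy$steps, rep("NS", 300), toy$fold,
                               cfg), "single-class")
})

test_that("the stacking layer requires exactly six probability inputs", {
  toy <- toy_training()
  cfg <- run_config(seed = 4)
  expect_error(train_stacker(toy$X[, 1:5], toy$labels, cfg), "exactly 6")
  # consistent perfect sub-models are reproduced by the stacker
  P <- matrix(0, 300, 3)
  P[cbind(1:300, match(toy$labels, coarse_label_levels()))] <- 1
  PP <- cbind(P, P)
  colnames(PP) <- c(paste0("rf_", coarse_label_levels()),
                    paste0("rnn_", coarse_label_levels()))
  stk <- train_stacker(PP, toy$labels, cfg)
  out <- predict(stk, PP, num.threads = 1)$predictions
  pred <- colnames(out)[max.col(out)]
  expect_gt(mean(pred == toy$labels), 0.99)
})

test_that("stacking complementary sub-models loses little against the best single model", {
  # sub-model A informative on half the windows, B on the other half
  set.seed(14)
  n <- 600
  truth <- sample(c("NS", "CS"), n, replace = TRUE)
  half <- rep(c(TRUE, FALSE), length.out = n)
  pa <- ifelse(half, ifelse(truth == "CS", 0.9, 0.1), 0.5) +
    runif(n, -0.05, 0.05)
  pb <- ifelse(!half, ifelse(truth == "CS", 0.9, 0.1), 0.5) +
    runif(n, -0.05, 0.05)
  P6 <- cbind(1 - pa, 0, pa, 1 - pb, 0, pb)
  colnames(P6) <- c(paste0("rf_", coarse_label_levels()),
                    paste0("rnn_", coarse_label_levels()))
  cfg <- run_config(seed = 5)
  stk <- train_stacker(P6[1:400, ], truth[1:400], cfg)
  ps <- slhs:::.prob3(predict(stk, P6[401:n, ],
                              num.threads = 1)$predictions)
  au_stack <- pairwise_auroc(truth[401:n], ps[, "CS"])
  au_a <- pairwise_auroc(truth[401:n], pa[401:n])
  au_b <- pairwise_auroc(truth[401:n], pb[401:n])
  expect_gte(au_stack, max(au_a, au_b) - 0.02)
})

test_that("stay aggregation takes the maximum confirmed-sepsis window", {
  Pw <- rbind(c(0.7, 0.1, 0.2), c(0.05, 0.05, 0.9), c(0.3, 0.2, 0.5))
  agg <- slhs:::.aggregate_stays(c("A", "A", "B"), Pw)
  expect_equal(agg[agg$stay_id == "A", cs_prob], 0.9)
  expect_equal(agg[agg$stay_id == "A", label], "CS")
  # single-window stay: prediction equals that window's
  expect_equal(agg[agg$stay_id == "B", cs_prob], 0.5)
  expect_equal(agg[agg$stay_id == "B", label], "CS")
  # tie between classes resolves toward higher severity
  agg2 <- slhs:::.aggregate_stays("C", rbind(c(0.4, 0.4, 0.2)))
  expect_equal(agg2$label, "PS")
  # brute force across random inputs
  set.seed(6)
  for (i in 1:20) {
    m <- matrix(runif(30), 10, 3)
    m <- m / rowSums(m)
    ids <- sort(sample(c("x", "y", "z"), 10, replace = TRUE))
    agg3 <- slhs:::.aggregate_stays(ids, m)
    for (s in unique(ids))
      expect_equal(agg3[agg3$stay_id == s, cs_prob],
                   max(m[ids == s, 3]))
  }
})

test_that("the deployment gate requires strict improvement", {
  rep_with <- function(f1) structure(
    list(pooled = data.table::data.table(metric = "f1_cs", mean = f1,
                                         sd = 0)),
    class = "slhs_cv_report")
  g <- champion_challenger_gate(rep_with(0.70), rep_with(0.68))
  expect_true(g$deploy)
  expect_equal(g$challenger_metric, 0.70)
  expect_false(champion_challenger_gate(rep_with(0.68),
                                        rep_with(0.68))$deploy)
  expect_false(champion_challenger_gate(rep_with(0.60),
                                        rep_with(0.68))$deploy)
  expect_error(champion_challenger_gate(rep_with(0.7), rep_with(0.6),
                                        metric = "auroc_cs_vs_ns"),
               "missing")
})

test_that("training, prediction and persistence work end-to-end on a small registry", {
  reg <- small_registry()
  cfg <- run_config(seed = 6, num_trees = 60, rnn_epochs = 4,
                    rnn_hidden = 6, cv_folds = 3)
  bundle <- train_sepsis_model(reg, cfg)
  expect_s3_class(bundle, "slhs_model")
  expect_gte(bundle$calibration$recall, cfg$recall_floor)
  expect_true(bundle$threshold > 0 && bundle$threshold <= 1)
  # patient-grouped folds: stays of one patient never split
  cvp <- bundle$cv_report$predictions
  pp <- merge(cvp, reg$stays[, c("stay_id", "patient_id")], by = "stay_id")
  split_check <- tapply(pp$fold, pp$patient_id,
                        function(f) length(unique(f)))
  expect_true(all(split_check == 1))
  # every stay validated exactly once
  expect_setequal(cvp$stay_id, reg$stays$stay_id)
  expect_equal(anyDuplicated(cvp$stay_id), 0L)
  # prediction on the training registry carries sane outputs
  pred <- predict_stays(bundle, reg)
  expect_setequal(pred$stay_id, reg$stays$stay_id)
  expect_true(all(pred$cs_prob >= 0 & pred$cs_prob <= 1))
  expect_equal(pred$flagged, pred$cs_prob >= bundle$threshold)
  # single-stay prediction agrees with the batch path
  one <- predict_stay(bundle, reg, reg$stays$stay_id[5])
  expect_equal(one$cs_prob, pred[pred$stay_id == reg$stays$stay_id[5],
                                 cs_prob])
  # persistence round trip
  dir <- withr::local_tempdir()
  save_model(bundle, dir)
  b2 <- load_model(dir)
  expect_equal(b2$threshold, bundle$threshold)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  # ward-group restriction trains on the restricted stays only
  cfg2 <- run_config(seed = 6, num_trees = 40, rnn_epochs = 3,
                     rnn_hidden = 6, cv_folds = 3,
                     train_ward_groups = c("MED", "GIS", "EMD"))
  b3 <- train_sepsis_model(reg, cfg2)
  slhs_stays <- unique(reg$ward_segments[
    reg$ward_segments$ward_group %in% c("MED", "GIS", "EMD"), stay_id])
  expect_true(all(b3$train_stays$stay_id %in% slhs_stays))
})
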