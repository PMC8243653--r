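# model_cv: folds, capping, forest behavior, metrics, cross-validation.

test_that("make_folds partitions patients and balances S counts", {
  pats <- data.frame(patient_id = sprintf("p%02d", 1:10),
                     s_count = rep(50L, 10))
  plan <- make_folds(pats, k = 10, seed = 1)
  expect_equal(sort(table(plan$fold)), sort(rep(1L, 10)),
               ignore_attr = TRUE)               # one patient per fold
  expect_setequal(plan$patient_id, pats$patient_id)
  # patient atomicity: a single S-heavy patient stays whole and alone
  # determines the max-S fold
  pats2 <- data.frame(patient_id = sprintf("p%02d", 1:20),
                      s_count = c(100L, rep(0L, 19)))
  plan2 <- make_folds(pats2, k = 10, seed = 1)
  s_per_fold <- attr(plan2, "s_per_fold")
  expect_equal(max(s_per_fold), 100)
  expect_equal(sum(s_per_fold == 100), 1L)
  heavy_fold <- plan2$fold[plan2$patient_id == "p01"]
  expect_equal(s_per_fold[heavy_fold], 100)
  # partition property across random S counts
  set.seed(41)
  pats3 <- data.frame(patient_id = sprintf("q%03d", 1:57),
                      s_count = rpois(57, 30))
  plan3 <- make_folds(pats3, k = 10, seed = 7)
  expect_setequal(plan3$patient_id, pats3$patient_id)
  expect_equal(anyDuplicated(plan3$patient_id), 0L)
  # balance: relative spread of fold S proportions within 20% of mean
  spf <- attr(plan3, "s_per_fold")
  expect_lt((max(spf) - min(spf)) / mean(spf), 0.20)
  expect_error(make_folds(pats[1:5, ], k = 10), "fewer patients")
})

test_that("cap_training subsamples only over-cap classes, reproducibly", {
  df <- data.frame(label = c(rep("N", 30000), rep("S", 2000),
                             rep("V", 1500)),
                   x = seq_len(33500))
  capped <- cap_training(df, cap = 10000L, seed = 3)
  expect_equal(as.vector(table(capped$label)[c("N", "S", "V")]),
               c(10000L, 2000L, 1500L))
  capped2 <- cap_training(df, cap = 10000L, seed = 3)
  expect_identical(capped, capped2)              # same seed, same rows
  small <- df[df$label != "N", ]
  expect_identical(cap_training(small, cap = 10000L, seed = 3), small)
})

test_that("random forest: separable fit, determinism, importance, contract", {
  set.seed(42)
  x <- matrix(rnorm(300 * 5), 300, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- ifelse(x[, 3] > 0, "S", "N")
  cfg <- rf_config(n_trees = 100L, seed = 9L)
  m <- train_rf(x, y, cfg)
  expect_equal(mean(predict(m, x) == y), 1)      # separable data
  expect_equal(sum(m$importance), 1, tolerance = 1e-9)
  expect_identical(feature_importance(m)$feature[1], "f3")
  # vote fractions are proper distributions
  p <- predict(m, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 300), tolerance = 1e-9)
  expect_true(all(p >= 0 & p <= 1))
  # determinism: fixed seed + data -> identical predictions
  m2 <- train_rf(x, y, cfg)
  expect_identical(predict(m2, x, type = "prob"), p)
  # degenerate labels
  expect_error(train_rf(x, rep("N", 300), cfg), "one class")
  # binary mode relabels N/V -> Other
  y3 <- c("N", "S", "V")[1 + (seq_len(300) %% 3)]
  mb <- train_rf(x, y3, cfg, mode = "binary")
  expect_setequal(mb$classes, c("Other", "S"))
})

test_that("feature_importance ranks are reported per model with top-10", {
  set.seed(43)
  x <- matrix(rnorm(400 * 15), 400, 15,
              dimnames = list(NULL, paste0("f", 1:15)))
  y <- ifelse(x[, 7] + 0.1 * rnorm(400) > 0, "S", "N")
  m <- train_rf(x, y, rf_config(n_trees = 100L, seed = 4L))
  top <- feature_importance(m, top = 10L)
  expect_equal(nrow(top), 10L)
  expect_identical(top$feature[1], "f7")
  expect_true(all(diff(top$importance) <= 0))
})

test_that("metrics match hand-computed values on a toy confusion", {
  # truth 100 of each class; diagonal 90/80/70; off-diagonal split:
  # N: 5 S, 5 V;  S: 10 N, 10 V;  V: 15 N, 15 S
  truth <- rep(c("N", "S", "V"), each = 100)
  pred <- c(rep("N", 90), rep("S", 5), rep("V", 5),
            rep("N", 10), rep("S", 80), rep("V", 10),
            rep("N", 15), rep("S", 15), rep("V", 70))
  m <- evaluate_metrics(truth, pred, classes = c("N", "S", "V"))
  expect_equal(rowSums(m$confusion_pct), rep(100, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  per <- m$per_class
  # hand-computed: Se(N) = 90/100; FP(N) = 10 + 15 = 25;
  # Sp(N) = 175/200; PPV(N) = 90/115; NPV(N) = 175/185
  expect_equal(per$sensitivity, c(90, 80, 70))
  expect_equal(per$specificity[1], 100 * 175 / 200)
  expect_equal(per$ppv[1], 100 * 90 / 115)
  expect_equal(per$npv[1], 100 * 175 / 185)
  # S: FP = 5 + 15 = 20 -> Sp = 180/200, PPV = 80/100
  expect_equal(per$specificity[2], 100 * 180 / 200)
  expect_equal(per$ppv[2], 100 * 80 / 100)
  expect_equal(per$accuracy[3], 100 * (70 + 185) / 300)
})

test_that("patient-wise summaries exclude patients lacking a class", {
  df <- data.frame(
    patient_id = c(rep("a", 4), rep("b", 4)),
    truth = c("N", "N", "S", "S", "N", "N", "N", "N"),
    pred = c("N", "N", "S", "N", "N", "N", "S", "N"))
  pm <- patient_metrics(df, classes = c("N", "S"))
  s_se <- pm[pm$class == "S" & pm$metric == "sensitivity", ]
  expect_equal(s_se$n_patients, 1L)              # only patient a has S
  expect_equal(s_se$median, 50)                  # 1 of 2 S found
  n_se <- pm[pm$class == "N" & pm$metric == "sensitivity", ]
  expect_equal(n_se$n_patients, 2L)
  expect_equal(n_se$median, 100 * mean(c(1, 3 / 4)))
})

test_that("cross_validate keeps patients disjoint and covers each beat once", {
  f <- small_cohort_features()
  res <- cross_validate(f, k = 2, cfg = rf_config(n_trees = 60L, seed = 11))
  for (a in res$audit) {
    expect_true(a$disjoint)
    expect_length(intersect(a$train_patients, a$test_patients), 0L)
  }
  # every non-trimmed beat predicted exactly once
  expect_equal(nrow(res$predictions), nrow(f))
  key <- paste(res$predictions$patient_id, res$predictions$beat_sample)
  expect_equal(anyDuplicated(key), 0L)
  expect_setequal(key, paste(f$patient_id, f$beat_sample))
  # pooled confusion equals the sum of per-fold confusions
  per_fold <- lapply(split(res$predictions, res$predictions$fold),
                     function(d) evaluate_metrics(d$truth, d$pred,
                                                  c("N", "S", "V"))$confusion)
  expect_equal(Reduce(`+`, per_fold), res$beat_metrics$confusion)
  # binary run on the same features differs only in label handling
  resb <- cross_validate(f, k = 2, cfg = rf_config(n_trees = 60L, seed = 11),
                         mode = "binary")
  expect_setequal(unique(resb$predictions$truth), c("Other", "S"))
  expect_equal(nrow(resb$predictions), nrow(f))
})
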