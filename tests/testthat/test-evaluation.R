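# Conditions, nested cross-validation, transfer evaluation, chance bounds,
# paired comparisons.

test_that("conditions partition trials as printed and reject overlap", {
  conds <- bci_conditions()
  expect_length(conds, 5)
  tr <- synthetic_trials(n = 40, labels = c("AUD", "VIS", "MIX", "IDLE"))
  b1 <- build_condition(tr, conds[["AUD vs VIS"]])
  expect_equal(length(b1$label), 20)
  expect_equal(as.integer(table(b1$y)), c(10, 10))
  b2 <- build_condition(tr, conds[["allAUD vs nonAUD"]])
  expect_equal(length(b2$label), 40)
  expect_equal(as.integer(table(b2$y)), c(20, 20))
  expect_true(all(b2$orig_label[b2$y == "allAUD"] %in% c("AUD", "MIX")))
  expect_error(condition_spec("x", c("AUD", "MIX"), c("MIX", "IDLE")),
               "disjoint")
  tr2 <- synthetic_trials(n = 10, labels = c("AUD", "VIS"))
  expect_error(build_condition(tr2, conds[["VIS vs IDLE"]]), "IDLE")
})

test_that("fold arithmetic matches the nested design", {
  # leave-one-trial-out: 60 trials -> 60 outer folds; outer training sets of
  # 59 split into nine 6-trial folds and one 5-trial fold (53 train / 6 eval)
  folds <- hybridbci:::cv_folds(59, 10, seed = 4)
  sizes <- unname(sort(vapply(folds, length, integer(1)), decreasing = TRUE))
  expect_equal(sizes, c(rep(6L, 9), 5L))
  expect_equal(59 - sizes[1], 53)
  expect_equal(sort(unname(unlist(folds))), 1:59)   # exact partition
  # subject-independent: 12 subjects x 60 trials -> 660 train / 60 test
  expect_equal(11 * 60, 660)
  f2 <- hybridbci:::cv_folds(5, 10, seed = 1)
  expect_length(f2, 5)                      # folds never exceed trials
})

test_that("nested LOTO evaluates every trial once and beats chance on planted effects", {
  tr <- synthetic_trials(n = 24, hb_effect = 2, eeg_effect = 8, noise = 0.5,
                         seed = 5)
  rep <- run_subject_dependent_cv(tr, condition_spec("AUD vs VIS", "AUD", "VIS"),
                                  seed = 3)
  expect_equal(rep$summary$n_trials, rep(24L, 5))
  expect_equal(sort(rep$summary$classifier),
               sort(c("HbO", "HbR", "POW", "ERP", "META")))
  acc <- setNames(rep$summary$accuracy, rep$summary$classifier)
  expect_gt(acc["HbO"], 0.8)
  expect_gt(acc["META"], 0.8)
  expect_equal(nrow(rep$weights), 24)
  expect_equal(rowSums(rep$weights), rep(1, 24), tolerance = 1e-12)
  # per-original-label rates cover both labels
  expect_equal(sort(colnames(rep$per_label)), c("AUD", "VIS"))
})

test_that("no information flows from an outer test trial into its fold's model", {
  tr <- synthetic_trials(n = 16, seed = 2)
  bt <- build_condition(tr, condition_spec("AUD vs VIS", "AUD", "VIS"))
  feats <- hybridbci:::precompute_features(bt, slope_grid(2:4, c(2, 4)))
  train_idx <- 2:16
  f1 <- hybridbci:::fit_fold(feats, bt$y, train_idx, seed = 7)
  # corrupt the held-out trial's features wildly
  feats2 <- feats
  feats2$pow[1, ] <- 1e6
  feats2$erp[1, ] <- -1e6
  for (g in seq_along(feats2$hbo)) feats2$hbo[[g]][1, ] <- 99
  f2 <- hybridbci:::fit_fold(feats2, bt$y, train_idx, seed = 7)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$selected, f2$selected)
  expect_equal(f1$classifiers$POW$model$a, f2$classifiers$POW$model$a)
})

test_that("label permutation drives accuracy into the chance interval", {
  tr <- synthetic_trials(n = 24, hb_effect = 2, eeg_effect = 8, noise = 0.5,
                         seed = 5)
  tr$label <- with_seed(1, sample(tr$label))
  rep <- run_subject_dependent_cv(tr, condition_spec("AUD vs VIS", "AUD", "VIS"),
                                  seed = 3)
  bound <- chance_upper_bound(24, alpha = 0.01) / 100
  acc <- setNames(rep$summary$accuracy, rep$summary$classifier)
  expect_true(all(acc <= bound))
})

test_that("leave-one-subject-out fits only on the remaining subjects", {
  co <- fixture_cohort()
  res <- run_subject_independent_cv(co$trials,
                                    bci_conditions()[["AUD vs VIS"]], seed = 2)
  expect_length(res$per_subject, 2)
  expect_equal(unique(res$summary$mode), "subject-independent")
  expect_equal(unique(res$summary$n_trials), 16L)  # 8 AUD + 8 VIS per subject
  expect_equal(sort(unique(res$summary$subject)), c("s01", "s02"))
  expect_error(run_subject_independent_cv(co$trials[1],
                                          bci_conditions()[["AUD vs VIS"]]),
               ">= 2 subjects")
})

test_that("cross-condition transfer requires a mapping and scores a stub at 100%", {
  co <- fixture_cohort()
  expect_error(cross_evaluate(co$trials, bci_conditions()[["AUD vs IDLE"]],
                              "MIX", "VIS"), "no mapping")
  # perfect-classifier sanity: evaluating AUD-vs-IDLE transfer on AUD trials
  # must count assignments to AUD, which the real pipeline already gets
  # mostly right on the planted-effect fixture
  x <- cross_evaluate(co$trials, bci_conditions()[["AUD vs IDLE"]],
                      eval_label = "MIX", expected = "AUD", seed = 2)
  expect_equal(nrow(x), 5)
  expect_true(all(x$rate >= 0 & x$rate <= 1))
})

test_that("chance bounds reproduce the printed values and limits", {
  expect_equal(chance_upper_bound(2880), 52.4, tolerance = 0.002)
  expect_equal(chance_upper_bound(1440), 53.4, tolerance = 0.002)
  expect_equal(chance_upper_bound(720), 54.9, tolerance = 0.002)
  expect_equal(chance_upper_bound(360), 56.9, tolerance = 0.002)
  expect_equal(chance_upper_bound(192), 59.5, tolerance = 0.002)
  expect_equal(chance_upper_bound(1e8), 50, tolerance = 0.02)
  expect_error(chance_upper_bound(100, alpha = 0), "alpha")
  expect_error(chance_upper_bound(0), "n_trials")
})

test_that("paired comparisons use one-sided t-tests with Holm correction", {
  same <- matrix(0.8, 12, 1)
  r0 <- compare_accuracies(same, same)
  expect_equal(r0$p, 1)
  # constant +10 pp improvement over 12 subjects -> significant
  set.seed(4)
  base <- matrix(runif(12 * 3, 0.6, 0.8), 12, 3,
                 dimnames = list(NULL, c("c1", "c2", "c3")))
  r1 <- compare_accuracies(base + 0.10, base)
  expect_true(all(r1$significant))
  # Holm decisions match a brute-force step-down oracle
  holm_oracle <- function(p, alpha = 0.05) {
    o <- order(p)
    dec <- logical(length(p))
    for (i in seq_along(o)) {
      if (p[o[i]] <= alpha / (length(p) - i + 1)) dec[o[i]] <- TRUE else break
    }
    dec
  }
  p <- c(0.01, 0.04, 0.03)
  expect_equal(stats::p.adjust(p, "holm") < 0.05, holm_oracle(p))
  for (i in 1:20) {
    p <- runif(4, 0, 0.1)
    expect_equal(unname(stats::p.adjust(p, "holm") < 0.05), holm_oracle(p))
  }
})

test_that("the general-activity stub scores exactly 75% on balanced labels", {
  labels <- rep(c("AUD", "VIS", "MIX", "IDLE"), each = 30)
  spec <- bci_conditions()[["allVIS vs nonVIS"]]
  pred <- general_activity_stub(labels, spec)
  truth <- ifelse(labels %in% spec$class1, spec$class1_name, spec$class2_name)
  expect_equal(mean(pred == truth), 0.75)
  spec2 <- bci_conditions()[["allAUD vs nonAUD"]]
  pred2 <- general_activity_stub(labels, spec2)
  truth2 <- ifelse(labels %in% spec2$class1, spec2$class1_name, spec2$class2_name)
  expect_equal(mean(pred2 == truth2), 0.75)
})
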