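## Condition construction, nested cross-validation, cross-condition transfer,
## continuous-data evaluation, chance bounds and significance testing.
##
## Nested design: the outer loop is leave-one-trial-out (subject-dependent)
## or leave-one-subject-out (subject-independent). Within each outer training
## set an inner 10-fold cross-validation selects the slope-feature parameters
## (t_opt, w) and provides the per-classifier evaluation accuracies that
## become the META fusion weights. Normalizers and classifiers are always
## refit on outer training data only.

#' Binary classification condition
#'
#' @param name condition name.
#' @param class1,class2 disjoint label sets drawn from AUD/VIS/MIX/IDLE.
#' @param class1_name,class2_name binary class names used in reports.
#' @return object of class `bci_condition`.
#' @export
condition_spec <- function(name, class1, class2,
                           class1_name = paste(class1, collapse = "+"),
                           class2_name = paste(class2, collapse = "+")) {
  if (length(intersect(class1, class2)) > 0)
    stop_param("condition label sets must be disjoint")
  if (!all(c(class1, class2) %in% STIMULUS_LABELS))
    stop_param("labels must be drawn from {AUD, VIS, MIX, IDLE}")
  structure(list(name = name, class1 = class1, class2 = class2,
                 class1_name = class1_name, class2_name = class2_name),
            class = "bci_condition")
}

#' The five standard evaluation conditions
#'
#' AUD vs VIS, AUD vs IDLE, VIS vs IDLE, allAUD (= AUD+MIX) vs nonAUD
#' (= VIS+IDLE), and allVIS (= VIS+MIX) vs nonVIS (= AUD+IDLE).
#' @return named list of [condition_spec()] objects.
#' @export
bci_conditions <- function() {
  list(
    "AUD vs VIS"        = condition_spec("AUD vs VIS", "AUD", "VIS", "AUD", "VIS"),
    "AUD vs IDLE"       = condition_spec("AUD vs IDLE", "AUD", "IDLE", "AUD", "IDLE"),
    "VIS vs IDLE"       = condition_spec("VIS vs IDLE", "VIS", "IDLE", "VIS", "IDLE"),
    "allAUD vs nonAUD"  = condition_spec("allAUD vs nonAUD", c("AUD", "MIX"),
                                         c("VIS", "IDLE"), "allAUD", "nonAUD"),
    "allVIS vs nonVIS"  = condition_spec("allVIS vs nonVIS", c("VIS", "MIX"),
                                         c("AUD", "IDLE"), "allVIS", "nonVIS"))
}

#' Restrict a trial set to a binary condition
#'
#' Keeps only trials whose label belongs to either class set, attaches the
#' binary relabeling as `$y` and preserves the original labels in
#' `$orig_label` for confusion reporting.
#'
#' @param trials a `bci_trials` object.
#' @param spec a [condition_spec()].
#' @return the subsetted trial set.
#' @export
build_condition <- function(trials, spec) {
  stopifnot(inherits(spec, "bci_condition"))
  in1 <- trials$label %in% spec$class1
  in2 <- trials$label %in% spec$class2
  if (!any(in1)) stop_param("condition class '", spec$class1_name, "' is empty")
  if (!any(in2)) stop_param("condition class '", spec$class2_name, "' is empty")
  out <- subset_trials(trials, which(in1 | in2))
  out$orig_label <- out$label
  out$y <- factor(ifelse(out$label %in% spec$class1,
                         spec$class1_name, spec$class2_name),
                  levels = c(spec$class1_name, spec$class2_name))
  out$condition <- spec$name
  out
}

## ---- cross-validation machinery -------------------------------------------

## Shuffled sequential folds; the first (n mod k) folds are one larger.
cv_folds <- function(n, k, seed = 1L) {
  k <- min(k, n)
  idx <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  split(idx, rep(seq_len(k), sizes))
}

## Lean z-normalize + shrinkage-LDA cross-validation (hot path: runs tens of
## thousands of times during nested parameter selection). Mirrors
## fit_normalizer + train_lda exactly, without the object overhead.
fast_cv_lda <- function(X, y1, folds, gamma = 0.5) {
  n <- nrow(X); d <- ncol(X)
  correct <- 0L; total <- 0L
  for (f in folds) {
    tr <- seq_len(n)[-f]
    ytr <- y1[tr]
    n1 <- sum(ytr); n2 <- length(tr) - n1
    if (n1 < 1L || n2 < 1L) next
    ntr <- length(tr)
    Xtr <- X[tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- sqrt(pmax(colMeans(Xtr * Xtr) - mu * mu, 0) * ntr / (ntr - 1))
    sdv[sdv < 1e-12] <- 1
    Z <- (Xtr - rep(mu, each = ntr)) / rep(sdv, each = ntr)
    m1 <- colMeans(Z[ytr, , drop = FALSE])
    m2 <- colMeans(Z[!ytr, , drop = FALSE])
    Zc <- Z
    Zc[ytr, ] <- Z[ytr, , drop = FALSE] - rep(m1, each = n1)
    Zc[!ytr, ] <- Z[!ytr, , drop = FALSE] - rep(m2, each = n2)
    tr_d <- sum(Zc * Zc) / (ntr - 2) / d
    if (tr_d <= 0) tr_d <- 1
    a <- solve_shrunk(Zc, m1 - m2, gamma, tr_d, ntr - 2)
    b <- -0.5 * sum((m1 + m2) * a) + log(n1 / n2)
    Ze <- (X[f, , drop = FALSE] - rep(mu, each = length(f))) / rep(sdv, each = length(f))
    pred1 <- drop(Ze %*% a) + b >= 0
    correct <- correct + sum(pred1 == y1[f])
    total <- total + length(f)
  }
  if (total == 0L) 0.5 else correct / total
}

## Mean held-out accuracy of a classifier kind over inner folds.
inner_cv_accuracy <- function(X, y, folds, kind = c("lda", "svm"),
                              shrinkage = 0.5) {
  kind <- match.arg(kind)
  X <- unclass(X)
  if (kind == "lda")
    return(fast_cv_lda(X, y == levels(factor(y))[1], folds, shrinkage))
  correct <- 0L; total <- 0L
  for (f in folds) {
    tr <- setdiff(seq_len(nrow(X)), f)
    if (length(unique(y[tr])) < 2L) next
    nz <- fit_normalizer(X[tr, , drop = FALSE])
    Xt <- apply_normalizer(nz, X[tr, , drop = FALSE])
    Xe <- apply_normalizer(nz, X[f, , drop = FALSE])
    ## inner accuracy only needs the margin sign, not calibrated
    ## probabilities, so the Platt step is skipped here
    fit <- e1071::svm(Xt, factor(y[tr]), kernel = "linear", cost = 1,
                      scale = FALSE, na.action = stats::na.pass)
    pred <- as.character(stats::predict(fit, Xe))
    correct <- correct + sum(pred == as.character(y[f]))
    total <- total + length(f)
  }
  if (total == 0L) return(0.5)
  correct / total
}

## Slope features for every grid point, computed once per trial set (the
## extraction is a fixed linear map of the epoch, so it can be precomputed
## and subset per fold without information leakage).
precompute_features <- function(trials, grid = slope_grid(),
                                pow_par = pow_params(),
                                erp_par = erp_params()) {
  list(
    grid = grid,
    hbo = lapply(seq_len(nrow(grid)), function(i)
      unclass(slope_feature(trials, grid$t_opt[i], grid$w[i], "hbo"))),
    hbr = lapply(seq_len(nrow(grid)), function(i)
      unclass(slope_feature(trials, grid$t_opt[i], grid$w[i], "hbr"))),
    pow = unclass(pow_feature(trials, pow_par)),
    erp = unclass(erp_feature(trials, erp_par)))
}

## Pick the grid point with maximal inner-CV accuracy; ties break to the
## smaller t_opt, then the smaller w (the grid is sorted that way). All grid
## feature sets are evaluated in one pass per fold (shared normalization
## statistics computation; identical arithmetic to fast_cv_lda per grid).
select_slope_best <- function(feat_list, y, grid, folds, shrinkage = 0.5) {
  y1 <- y == levels(factor(y))[1]
  X <- do.call(cbind, feat_list)
  dc <- ncol(feat_list[[1]])
  G <- length(feat_list)
  n <- nrow(X)
  correct <- integer(G)
  total <- 0L
  for (f in folds) {
    tr <- seq_len(n)[-f]
    ytr <- y1[tr]
    n1 <- sum(ytr); nn <- length(tr)
    if (n1 < 1L || n1 == nn) next
    Xtr <- X[tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- sqrt(pmax(colMeans(Xtr * Xtr) - mu * mu, 0) * nn / (nn - 1))
    sdv[sdv < 1e-12] <- 1
    Z <- (Xtr - rep(mu, each = nn)) / rep(sdv, each = nn)
    m1 <- colMeans(Z[ytr, , drop = FALSE])
    m2 <- colMeans(Z[!ytr, , drop = FALSE])
    Zc <- Z
    Zc[ytr, ] <- Z[ytr, , drop = FALSE] - rep(m1, each = n1)
    Zc[!ytr, ] <- Z[!ytr, , drop = FALSE] - rep(m2, each = nn - n1)
    Ze <- (X[f, , drop = FALSE] - rep(mu, each = length(f))) /
      rep(sdv, each = length(f))
    for (g in seq_len(G)) {
      cols <- ((g - 1L) * dc + 1L):(g * dc)
      Zg <- Zc[, cols, drop = FALSE]
      tr_d <- sum(Zg * Zg) / (nn - 2) / dc
      if (tr_d <= 0) tr_d <- 1
      a <- solve_shrunk(Zg, m1[cols] - m2[cols], shrinkage, tr_d, nn - 2)
      b <- -0.5 * sum((m1[cols] + m2[cols]) * a) + log(n1 / (nn - n1))
      pred1 <- drop(Ze[, cols, drop = FALSE] %*% a) + b >= 0
      correct[g] <- correct[g] + sum(pred1 == y1[f])
    }
    total <- total + length(f)
  }
  accs <- if (total == 0L) rep(0.5, G) else correct / total
  best <- which.max(accs)
  list(index = best, t_opt = grid$t_opt[best], w = grid$w[best],
       accuracy = accs[best])
}

#' Select slope-feature parameters by inner cross-validation
#'
#' Runs an inner k-fold cross-validation of the shrinkage-LDA classifier for
#' every admissible `(t_opt, w)` grid point on the training trials and
#' returns the maximizer; ties break to the smaller `t_opt`, then smaller `w`.
#'
#' @param trials a `bci_trials` object carrying a binary `$y` (see
#'   [build_condition()]).
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param grid a [slope_grid()].
#' @param inner_folds number of inner folds (reduced with a warning when
#'   there are fewer trials).
#' @param seed fold-assignment seed.
#' @param shrinkage LDA shrinkage factor.
#' @return list with `t_opt`, `w`, `accuracy`.
#' @export
select_slope_params <- function(trials, chromophore = "hbo",
                                grid = slope_grid(), inner_folds = 10L,
                                seed = 1L, shrinkage = 0.5) {
  if (nrow(grid) == 0L) stop_param("empty parameter grid")
  if (min(table(trials$y)) < 2L) stop_param("need >= 2 trials per class")
  n <- length(trials$y)
  if (n < inner_folds) {
    warning("fewer trials than inner folds; using ", n, " folds")
    inner_folds <- n
  }
  feats <- lapply(seq_len(nrow(grid)), function(i)
    unclass(slope_feature(trials, grid$t_opt[i], grid$w[i], chromophore)))
  folds <- cv_folds(n, inner_folds, seed)
  sel <- select_slope_best(feats, trials$y, grid, folds, shrinkage)
  sel[c("t_opt", "w", "accuracy")]
}

## Fit all four feature classifiers + fusion weights on training indices.
fit_fold <- function(feats, y, train_idx, inner_folds = 10L, seed = 1L,
                     shrinkage = 0.5) {
  yt <- y[train_idx]
  n <- length(train_idx)
  k <- inner_folds
  if (n < k) {
    warning("fewer training trials than inner folds; using ", n, " folds")
    k <- n
  }
  folds <- cv_folds(n, k, seed)
  sel_hbo <- select_slope_best(lapply(feats$hbo, function(m)
    m[train_idx, , drop = FALSE]), yt, feats$grid, folds, shrinkage)
  sel_hbr <- select_slope_best(lapply(feats$hbr, function(m)
    m[train_idx, , drop = FALSE]), yt, feats$grid, folds, shrinkage)
  acc_pow <- inner_cv_accuracy(feats$pow[train_idx, , drop = FALSE], yt, folds,
                               "lda", shrinkage)
  acc_erp <- inner_cv_accuracy(feats$erp[train_idx, , drop = FALSE], yt, folds,
                               "svm")
  weights <- estimate_fusion_weights(c(HbO = sel_hbo$accuracy,
                                       HbR = sel_hbr$accuracy,
                                       POW = acc_pow, ERP = acc_erp))
  fc <- list()
  X <- list(HbO = feats$hbo[[sel_hbo$index]], HbR = feats$hbr[[sel_hbr$index]],
            POW = feats$pow, ERP = feats$erp)
  for (m in names(X)) {
    nz <- fit_normalizer(X[[m]][train_idx, , drop = FALSE])
    Xt <- apply_normalizer(nz, X[[m]][train_idx, , drop = FALSE])
    model <- if (m == "ERP") train_svm(Xt, yt) else train_lda(Xt, yt, shrinkage)
    fc[[m]] <- list(nz = nz, model = model)
  }
  list(classifiers = fc, weights = weights, features = X,
       selected = list(HbO = sel_hbo[c("t_opt", "w")],
                       HbR = sel_hbr[c("t_opt", "w")]))
}

## Probabilities of all classifiers (+ META) for trial indices.
predict_fold <- function(fold, idx) {
  probs <- lapply(names(fold$classifiers), function(m) {
    fc <- fold$classifiers[[m]]
    predict(fc$model, apply_normalizer(fc$nz, fold$features[[m]][idx, , drop = FALSE]))
  })
  names(probs) <- names(fold$classifiers)
  meta <- fuse_predict(probs, fold$weights)
  pred <- lapply(probs, function(p) colnames(p)[ifelse(p[, 1] >= p[, 2], 1L, 2L)])
  pred$META <- meta$class
  list(probs = probs, meta = meta, pred = pred)
}

CLASSIFIER_SET <- c("HbO", "HbR", "POW", "ERP", "META")

## Assemble a per-classifier accuracy report.
eval_report <- function(pred_by_clf, y, orig, condition, mode, subject = NA) {
  acc <- vapply(CLASSIFIER_SET, function(m)
    mean(pred_by_clf[[m]] == as.character(y)), numeric(1))
  per_label <- NULL
  if (!is.null(orig)) {
    labs <- sort(unique(orig))
    per_label <- sapply(labs, function(l) {
      i <- orig == l
      vapply(CLASSIFIER_SET, function(m)
        mean(pred_by_clf[[m]][i] == as.character(y)[i]), numeric(1))
    })
  }
  structure(list(
    summary = data.frame(condition = condition, mode = mode, subject = subject,
                         classifier = CLASSIFIER_SET, accuracy = unname(acc),
                         n_trials = length(y), stringsAsFactors = FALSE),
    per_label = per_label), class = "bci_eval")
}

#' @export
print.bci_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s [%s]%s, n = %d:\n", s$condition[1], s$mode[1],
              if (!is.na(s$subject[1])) paste0(" subject ", s$subject[1]) else "",
              s$n_trials[1]))
  cat(paste(sprintf("  %-4s %5.1f%%", s$classifier, 100 * s$accuracy),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Subject-dependent nested leave-one-trial-out cross-validation
#'
#' One outer fold per trial. Within each outer training set an inner
#' `inner_folds`-fold cross-validation selects `(t_opt, w)` per chromophore
#' and yields the per-classifier accuracies that become the fusion weights;
#' normalizers and classifiers are refit on the outer training set only.
#'
#' @param trials one subject's `bci_trials`.
#' @param condition a [condition_spec()].
#' @param grid slope parameter grid.
#' @param inner_folds inner folds (10).
#' @param seed fold/shuffling seed.
#' @param shrinkage LDA shrinkage.
#' @param pow_par,erp_par feature parameters.
#' @return a `bci_eval` report (includes per-original-label rates and the
#'   per-fold selected parameters and weights).
#' @export
run_subject_dependent_cv <- function(trials, condition, grid = slope_grid(),
                                     inner_folds = 10L, seed = 1L,
                                     shrinkage = 0.5,
                                     pow_par = pow_params(),
                                     erp_par = erp_params()) {
  bt <- build_condition(trials, condition)
  if (min(table(bt$y)) < 2L) stop_param("need >= 2 trials per class")
  feats <- precompute_features(bt, grid, pow_par, erp_par)
  n <- length(bt$y)
  pred <- lapply(CLASSIFIER_SET, function(m) character(n))
  names(pred) <- CLASSIFIER_SET
  selected <- vector("list", n)
  weights <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("HbO", "HbR", "POW", "ERP")))
  for (i in seq_len(n)) {
    fold <- fit_fold(feats, bt$y, setdiff(seq_len(n), i), inner_folds,
                     seed = derive_seed(seed, paste0("outer-", i)), shrinkage)
    p <- predict_fold(fold, i)
    for (m in CLASSIFIER_SET) pred[[m]][i] <- p$pred[[m]]
    selected[[i]] <- fold$selected
    weights[i, ] <- as.numeric(fold$weights)
  }
  rep <- eval_report(pred, bt$y, bt$orig_label, condition$name,
                     "subject-dependent", trials$subject)
  rep$selected <- selected
  rep$weights <- weights
  rep
}

#' Subject-independent nested leave-one-subject-out cross-validation
#'
#' One fold per subject: all fitting (slope parameters, normalizers, models,
#' fusion weights) uses the remaining subjects. Slope parameters are selected
#' by inner 10-fold cross-validation on the pooled training trials; fusion
#' weights come from the accuracy on one held-out training subject, after
#' which the models are refit on all training subjects.
#'
#' @param trials_list list of `bci_trials`, one per subject.
#' @param condition a [condition_spec()].
#' @inheritParams run_subject_dependent_cv
#' @return list of per-subject `bci_eval` reports plus a pooled summary
#'   data.frame in `$summary`.
#' @export
run_subject_independent_cv <- function(trials_list, condition,
                                       grid = slope_grid(), inner_folds = 10L,
                                       seed = 1L, shrinkage = 0.5,
                                       pow_par = pow_params(),
                                       erp_par = erp_params()) {
  if (length(trials_list) < 2L)
    stop_param("leave-one-subject-out needs >= 2 subjects")
  bts <- lapply(trials_list, build_condition, spec = condition)
  feats <- lapply(bts, precompute_features, grid = grid, pow_par = pow_par,
                  erp_par = erp_par)
  n_sub <- length(bts)
  reports <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    train_subj <- setdiff(seq_len(n_sub), s)
    heldout <- max(train_subj)  # fusion evaluation subject
    core <- setdiff(train_subj, heldout)
    if (length(core) == 0L) core <- train_subj  # 2-subject edge case
    pooled <- pool_features(feats[train_subj], bts[train_subj])
    folds <- cv_folds(length(pooled$y), min(inner_folds, length(pooled$y)),
                      derive_seed(seed, paste0("loso-", s)))
    sel_hbo <- select_slope_best(pooled$hbo, pooled$y, pooled$grid, folds, shrinkage)
    sel_hbr <- select_slope_best(pooled$hbr, pooled$y, pooled$grid, folds, shrinkage)
    ## fusion weights from the held-out training subject
    core_pool <- pool_features(feats[core], bts[core])
    ho_acc <- heldout_accuracies(core_pool, feats[[heldout]], bts[[heldout]]$y,
                                 sel_hbo$index, sel_hbr$index, shrinkage)
    weights <- estimate_fusion_weights(ho_acc)
    ## refit on all training subjects, predict the test subject
    model <- final_models(pooled, sel_hbo$index, sel_hbr$index, shrinkage)
    pred <- apply_models(model, feats[[s]], sel_hbo$index, sel_hbr$index, weights)
    rep <- eval_report(pred, bts[[s]]$y, bts[[s]]$orig_label, condition$name,
                       "subject-independent", trials_list[[s]]$subject)
    rep$selected <- list(HbO = sel_hbo[c("t_opt", "w")],
                         HbR = sel_hbr[c("t_opt", "w")])
    rep$weights <- weights
    reports[[s]] <- rep
  }
  summary <- do.call(rbind, lapply(reports, function(r) r$summary))
  pooled_acc <- stats::aggregate(accuracy ~ condition + mode + classifier,
                                 summary, mean)
  list(per_subject = reports, summary = summary, mean_accuracy = pooled_acc)
}

## Row-bind per-subject precomputed features.
pool_features <- function(feat_list, bt_list) {
  list(grid = feat_list[[1]]$grid,
       hbo = lapply(seq_len(nrow(feat_list[[1]]$grid)), function(i)
         do.call(rbind, lapply(feat_list, function(f) f$hbo[[i]]))),
       hbr = lapply(seq_len(nrow(feat_list[[1]]$grid)), function(i)
         do.call(rbind, lapply(feat_list, function(f) f$hbr[[i]]))),
       pow = do.call(rbind, lapply(feat_list, function(f) f$pow)),
       erp = do.call(rbind, lapply(feat_list, function(f) f$erp)),
       y = factor(unlist(lapply(bt_list, function(b) as.character(b$y))),
                  levels = levels(bt_list[[1]]$y)))
}

final_models <- function(pooled, i_hbo, i_hbr, shrinkage = 0.5) {
  X <- list(HbO = pooled$hbo[[i_hbo]], HbR = pooled$hbr[[i_hbr]],
            POW = pooled$pow, ERP = pooled$erp)
  out <- list()
  for (m in names(X)) {
    nz <- fit_normalizer(X[[m]])
    Xt <- apply_normalizer(nz, X[[m]])
    model <- if (m == "ERP") train_svm(Xt, pooled$y)
             else train_lda(Xt, pooled$y, shrinkage)
    out[[m]] <- list(nz = nz, model = model)
  }
  out
}

apply_models <- function(models, feats, i_hbo, i_hbr, weights) {
  X <- list(HbO = feats$hbo[[i_hbo]], HbR = feats$hbr[[i_hbr]],
            POW = feats$pow, ERP = feats$erp)
  probs <- lapply(names(models), function(m)
    predict(models[[m]]$model, apply_normalizer(models[[m]]$nz, X[[m]])))
  names(probs) <- names(models)
  meta <- fuse_predict(probs, weights)
  pred <- lapply(probs, function(p) colnames(p)[ifelse(p[, 1] >= p[, 2], 1L, 2L)])
  pred$META <- meta$class
  pred
}

heldout_accuracies <- function(core_pool, ho_feats, ho_y, i_hbo, i_hbr,
                               shrinkage = 0.5) {
  models <- final_models(core_pool, i_hbo, i_hbr, shrinkage)
  pred <- apply_models(models, ho_feats, i_hbo, i_hbr,
                       estimate_fusion_weights(c(HbO = 1, HbR = 1, POW = 1, ERP = 1)))
  c(HbO = mean(pred$HbO == as.character(ho_y)),
    HbR = mean(pred$HbR == as.character(ho_y)),
    POW = mean(pred$POW == as.character(ho_y)),
    ERP = mean(pred$ERP == as.character(ho_y)))
}

#' Cross-condition transfer evaluation
#'
#' Trains detectors on one condition (leave-one-subject-out) and evaluates
#' them on trials with labels outside the training set (e.g. an AUD-vs-IDLE
#' detector on MIX trials, which a perfect auditory detector should assign to
#' its AUD class). Reports the fraction of evaluation trials assigned to the
#' expected class, per classifier.
#'
#' @param trials_list list of per-subject `bci_trials`.
#' @param condition training [condition_spec()].
#' @param eval_label label of the transfer trials.
#' @param expected the class (one of the condition's class names) a correct
#'   detector should assign.
#' @inheritParams run_subject_dependent_cv
#' @return data.frame of per-classifier expected-class rates.
#' @export
cross_evaluate <- function(trials_list, condition, eval_label, expected,
                           grid = slope_grid(), inner_folds = 10L, seed = 1L,
                           shrinkage = 0.5, pow_par = pow_params(),
                           erp_par = erp_params()) {
  if (!expected %in% c(condition$class1_name, condition$class2_name))
    stop_param("no mapping from label '", eval_label,
               "' to a class of condition '", condition$name, "'")
  if (length(trials_list) < 2L) stop_param("needs >= 2 subjects")
  bts <- lapply(trials_list, build_condition, spec = condition)
  feats <- lapply(bts, precompute_features, grid = grid, pow_par = pow_par,
                  erp_par = erp_par)
  n_sub <- length(bts)
  hits <- matrix(0, n_sub, length(CLASSIFIER_SET),
                 dimnames = list(NULL, CLASSIFIER_SET))
  counts <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    ev_idx <- which(trials_list[[s]]$label == eval_label)
    if (length(ev_idx) == 0L) next
    ev <- subset_trials(trials_list[[s]], ev_idx)
    ev_feats <- precompute_features(ev, grid, pow_par, erp_par)
    train_subj <- setdiff(seq_len(n_sub), s)
    heldout <- max(train_subj)
    core <- setdiff(train_subj, heldout)
    if (length(core) == 0L) core <- train_subj
    pooled <- pool_features(feats[train_subj], bts[train_subj])
    folds <- cv_folds(length(pooled$y), min(inner_folds, length(pooled$y)),
                      derive_seed(seed, paste0("xeval-", s)))
    sel_hbo <- select_slope_best(pooled$hbo, pooled$y, pooled$grid, folds, shrinkage)
    sel_hbr <- select_slope_best(pooled$hbr, pooled$y, pooled$grid, folds, shrinkage)
    core_pool <- pool_features(feats[core], bts[core])
    ho_acc <- heldout_accuracies(core_pool, feats[[heldout]], bts[[heldout]]$y,
                                 sel_hbo$index, sel_hbr$index, shrinkage)
    weights <- estimate_fusion_weights(ho_acc)
    models <- final_models(pooled, sel_hbo$index, sel_hbr$index, shrinkage)
    pred <- apply_models(models, ev_feats, sel_hbo$index, sel_hbr$index, weights)
    for (m in CLASSIFIER_SET) hits[s, m] <- mean(pred[[m]] == expected)
    counts[s] <- length(ev_idx)
  }
  data.frame(condition = condition$name, eval_label = eval_label,
             expected = expected, classifier = CLASSIFIER_SET,
             rate = colMeans(hits[counts > 0, , drop = FALSE]),
             n_trials = sum(counts), stringsAsFactors = FALSE)
}

#' Upper chance bound for balanced binary classification
#'
#' Upper limit of the two-sided `(1 - alpha)` binomial confidence interval
#' around 50 % accuracy for `n` trials, using the continuity-corrected normal
#' approximation
#' `50 + 100 * (z_{1-alpha/2} * sqrt(0.25 / n) + 1 / (2n))` percent
#' (the correction is what makes the bound agree with the exact binomial
#' quantiles to one decimal across the window counts used here). Set
#' `continuity = FALSE` for the plain Wald bound.
#'
#' @param n_trials number of evaluated trials.
#' @param alpha significance level (default 0.01).
#' @param continuity apply the 1/(2n) continuity correction.
#' @return upper bound in percent.
#' @export
chance_upper_bound <- function(n_trials, alpha = 0.01, continuity = TRUE) {
  if (n_trials < 1) stop_param("n_trials must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_param("alpha must be in (0, 1)")
  cc <- if (continuity) 1 / (2 * n_trials) else 0
  100 * (0.5 + stats::qnorm(1 - alpha / 2) * sqrt(0.25 / n_trials) + cc)
}

#' Paired one-sided comparisons with Holm correction
#'
#' For each condition, a paired one-sided t-test of META against the best
#' individual classifier across subjects, with Bonferroni-Holm step-down
#' adjustment over conditions.
#'
#' @param meta,other matrices (subjects x conditions) or vectors of paired
#'   per-subject accuracies.
#' @param alpha family-wise level.
#' @return data.frame with raw and adjusted p-values and decisions.
#' @export
compare_accuracies <- function(meta, other, alpha = 0.05) {
  meta <- as.matrix(meta); other <- as.matrix(other)
  stopifnot(identical(dim(meta), dim(other)), nrow(meta) >= 2L)
  conds <- colnames(meta) %||% paste0("condition", seq_len(ncol(meta)))
  p <- numeric(ncol(meta))
  tstat <- numeric(ncol(meta))
  for (j in seq_len(ncol(meta))) {
    d <- meta[, j] - other[, j]
    if (stats::sd(d) < 1e-15) {
      tstat[j] <- if (mean(d) > 0) Inf else 0
      p[j] <- if (mean(d) > 0) 0 else 1
    } else {
      tt <- stats::t.test(d, alternative = "greater")
      tstat[j] <- unname(tt$statistic)
      p[j] <- tt$p.value
    }
  }
  p_adj <- stats::p.adjust(p, method = "holm")
  data.frame(condition = conds, t = tstat, p = p, p_holm = p_adj,
             significant = p_adj < alpha, stringsAsFactors = FALSE)
}

#' Analytic "general activity only" stub classifier
#'
#' A degenerate detector that can only tell active (AUD/VIS/MIX) from
#' inactive (IDLE) trials and assigns every active trial to whichever
#' condition class contains activity. On balanced trials of all four labels
#' this stub attains exactly 75 % for the allVIS-vs-nonVIS (and
#' allAUD-vs-nonAUD) design - the analytic baseline any genuinely
#' modality-specific detector must beat.
#'
#' @param labels original trial labels.
#' @param spec a [condition_spec()].
#' @return predicted class names.
#' @export
general_activity_stub <- function(labels, spec) {
  active <- labels %in% c("AUD", "VIS", "MIX")
  active_class <- if ("IDLE" %in% spec$class2) spec$class1_name else spec$class2_name
  idle_class <- setdiff(c(spec$class1_name, spec$class2_name), active_class)
  ifelse(active, active_class, idle_class)
}
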