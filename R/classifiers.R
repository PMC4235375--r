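## Per-feature classifiers and probabilistic decision fusion. The HbO, HbR
## and POW classifiers are shrinkage-regularized LDA; the ERP classifier is a
## soft-margin linear SVM with a Platt-calibrated probability output. The
## META classifier takes the weighted sum of the per-classifier class
## probabilities and picks the maximum; exact ties resolve to class 1.

## Solve (gamma*c*I + (1-gamma)*Z'Z/(n-2)) a = b. For d >> n the Woodbury
## identity turns the d x d solve into an n x n one.
solve_shrunk <- function(Z, b, gamma, tr_d, n2) {
  d <- ncol(Z)
  alpha <- gamma * tr_d
  beta <- (1 - gamma) / n2
  if (gamma > 0 && beta > 0 && d > 2 * nrow(Z)) {
    Zb <- drop(Z %*% b)
    G <- Z %*% t(Z)
    diag(G) <- diag(G) + alpha / beta
    (b - drop(crossprod(Z, solve(G, Zb)))) / alpha
  } else {
    S <- crossprod(Z) * beta
    diag(S) <- diag(S) + alpha
    solve(S, b)
  }
}

#' Train a shrinkage-regularized LDA classifier
#'
#' Class-conditional Gaussians with a pooled covariance shrunk toward the
#' scaled identity: `S_reg = (1 - gamma) * S + gamma * (tr(S)/d) * I`.
#' Posterior probabilities come from the two linear discriminants.
#'
#' @param x trials x features matrix.
#' @param y two-level factor (or character) of trial labels.
#' @param shrinkage shrinkage factor gamma in `[0, 1]`.
#' @return object of class `slda`.
#' @export
train_lda <- function(x, y, shrinkage = 0.5) {
  y <- factor(y)
  if (nlevels(y) != 2L) stop_param("LDA needs exactly two classes in training data")
  if (min(table(y)) < 2L) stop_param("need >= 2 trials per class")
  x <- unclass(x)
  lv <- levels(y)
  i1 <- y == lv[1]
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[!i1, , drop = FALSE])
  n <- nrow(x); d <- ncol(x)
  xc <- x
  xc[i1, ] <- sweep(x[i1, , drop = FALSE], 2, m1)
  xc[!i1, ] <- sweep(x[!i1, , drop = FALSE], 2, m2)
  tr_d <- sum(xc * xc) / (n - 2) / d
  if (tr_d <= 0) tr_d <- 1  # fully degenerate features
  a <- solve_shrunk(xc, m1 - m2, shrinkage, tr_d, n - 2)
  prior <- mean(i1)
  b <- -0.5 * sum((m1 + m2) * a) + log(prior / (1 - prior))
  structure(list(a = a, b = b, levels = lv, shrinkage = shrinkage),
            class = "slda")
}

#' @export
predict.slda <- function(object, newdata, ...) {
  score <- drop(unclass(newdata) %*% object$a) + object$b
  p1 <- stats::plogis(score)
  out <- cbind(p1, 1 - p1)
  colnames(out) <- object$levels
  out
}

#' @export
print.slda <- function(x, ...) {
  cat(sprintf("Shrinkage LDA (gamma = %.2f), %d features, classes %s vs %s\n",
              x$shrinkage, length(x$a), x$levels[1], x$levels[2]))
  invisible(x)
}

## Platt scaling: sigmoid calibration of decision values with smoothed
## targets, fitted by Newton steps (deterministic).
platt_fit <- function(d, y1) {
  n1 <- sum(y1); n0 <- sum(!y1)
  t <- ifelse(y1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  ab <- c(0, log((n0 + 1) / (n1 + 1)))
  for (it in 1:100) {
    z <- ab[1] * d + ab[2]
    p <- stats::plogis(z)
    g <- c(sum((p - t) * d), sum(p - t))
    w <- pmax(p * (1 - p), 1e-12)
    H <- matrix(c(sum(w * d * d) + 1e-9, sum(w * d),
                  sum(w * d), sum(w) + 1e-9), 2, 2)
    step <- solve(H, g)
    ab <- ab - step
    if (max(abs(step)) < 1e-10) break
  }
  ab
}

#' Train a soft-margin linear SVM classifier
#'
#' libsvm (via e1071) with a linear kernel and default cost 1; class
#' probabilities come from a monotone sigmoid (Platt) calibration of the
#' decision values, fitted on the training data only.
#'
#' @param x trials x features matrix.
#' @param y two-level factor of trial labels.
#' @param cost soft-margin cost parameter.
#' @return object of class `lsvm`.
#' @export
train_svm <- function(x, y, cost = 1) {
  y <- factor(y)
  if (nlevels(y) != 2L) stop_param("SVM needs exactly two classes in training data")
  x <- unclass(x)
  if (anyNA(x)) stop_param("features contain missing values")
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                    na.action = stats::na.pass)
  d <- drop(attr(stats::predict(fit, x, decision.values = TRUE), "decision.values"))
  ## the Platt fit is sign-agnostic: it learns the margin-to-class direction
  lv <- levels(y)
  ab <- platt_fit(d, y == lv[1])
  structure(list(fit = fit, platt = ab, levels = lv), class = "lsvm")
}

#' @export
predict.lsvm <- function(object, newdata, ...) {
  d <- drop(attr(stats::predict(object$fit, unclass(newdata),
                                decision.values = TRUE), "decision.values"))
  p1 <- stats::plogis(object$platt[1] * d + object$platt[2])
  out <- cbind(p1, 1 - p1)
  colnames(out) <- object$levels
  out
}

#' @export
print.lsvm <- function(x, ...) {
  cat(sprintf("Linear SVM (cost 1), classes %s vs %s\n",
              x$levels[1], x$levels[2]))
  invisible(x)
}

#' Estimate decision-fusion weights from evaluation accuracies
#'
#' Accuracies above chance are mapped affinely onto `[0, 1]`
#' (`raw = (acc - baseline) / (1 - baseline)`), accuracies at or below chance
#' get weight 0, and the raw vector is divided by its 1-norm. If no
#' classifier beats chance the weights fall back to uniform.
#'
#' @param accuracies named numeric vector of per-classifier accuracies in
#'   `[0, 1]`.
#' @param baseline chance level (0.5 for balanced binary conditions).
#' @return object of class `fusion_weights` (named, sums to 1).
#' @export
estimate_fusion_weights <- function(accuracies, baseline = 0.5) {
  if (any(accuracies < 0 | accuracies > 1)) stop_param("accuracies must be in [0, 1]")
  raw <- pmax(0, (accuracies - baseline) / (1 - baseline))
  w <- if (sum(raw) == 0) rep(1 / length(raw), length(raw)) else raw / sum(raw)
  names(w) <- names(accuracies)
  structure(w, class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat("META fusion weights:",
      paste(sprintf("%s=%.3f", names(x), as.numeric(x)), collapse = " "), "\n")
  invisible(x)
}

#' Fuse per-classifier class probabilities
#'
#' `p_meta = sum_m w_m * p_m`; the class with the higher fused probability is
#' selected, with exact ties resolved to class 1.
#'
#' @param probs named list of trials x 2 probability matrices (same classes,
#'   same trials; names must match the weights).
#' @param weights a [estimate_fusion_weights()] vector.
#' @return list with `class` (character vector) and `prob` (fused matrix).
#' @export
fuse_predict <- function(probs, weights) {
  if (!setequal(names(probs), names(weights)))
    stop_param("classifier sets of probabilities and weights differ")
  lv <- colnames(probs[[1]])
  p <- Reduce(`+`, lapply(names(probs), function(m) {
    if (!identical(colnames(probs[[m]]), lv))
      stop_param("probability matrices have mismatched classes")
    unclass(weights)[[m]] * probs[[m]]
  }))
  cls <- lv[ifelse(p[, 1] >= p[, 2], 1L, 2L)]
  list(class = cls, prob = p)
}
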