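# Score-based detection analysis and the experiment harnesses.

#' Score set
#'
#' Per-subject unified log-likelihood-ratio scores paired with true
#' labels. Positive scores call pathological.
#'
#' @param lambda Numeric scores.
#' @param labels `"pathological"` / `"normative"` per subject.
#' @return Object of class `score_set`.
#' @export
score_set <- function(lambda, labels) {
  if (length(lambda) != length(labels)) stop_input("scores and labels must align")
  if (!all(is.finite(lambda))) stop_input("scores must be finite")
  if (!all(labels %in% c("pathological", "normative"))) {
    stop_input("labels must be 'pathological' or 'normative'")
  }
  structure(list(lambda = as.numeric(lambda), labels = as.character(labels)),
            class = "score_set")
}

check_both_classes <- function(s) {
  if (length(unique(s$labels)) < 2L) {
    stop_input("both classes must be present in the score set")
  }
}

# Confusion rates for "call pathological iff lambda > threshold".
rates_at <- function(s, thr) {
  pos <- s$labels == "pathological"
  called <- s$lambda > thr
  tp <- sum(called & pos); fn <- sum(!called & pos)
  tn <- sum(!called & !pos); fp <- sum(called & !pos)
  c(sens = tp / (tp + fn), spec = tn / (tn + fp),
    acc = (tp + tn) / length(pos),
    fpr = fp / (tn + fp), fnr = fn / (tp + fn))
}

threshold_grid <- function(s, n_steps = NULL) {
  u <- sort(unique(s$lambda))
  if (is.null(n_steps)) {
    # exact sweep: midpoints between consecutive unique scores, plus
    # sentinels outside the score range
    mid <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
    c(min(u) - 1, mid, max(u) + 1)
  } else {
    # step-wise sweep across the score span
    seq(min(u) - 1e-9, max(u) + 1e-9, length.out = n_steps)
  }
}

#' Threshold sweep
#'
#' Sweeps the decision threshold across the score span and records
#' sensitivity, specificity and accuracy at each step.
#'
#' @param s A [score_set()].
#' @param n_steps Optional fixed number of steps; by default the exact
#'   sweep over all midpoints between sorted unique scores is used.
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity`, `accuracy`, `fpr`, `fnr`.
#' @export
sweep_thresholds <- function(s, n_steps = NULL) {
  stopifnot(inherits(s, "score_set"))
  check_both_classes(s)
  thr <- threshold_grid(s, n_steps)
  m <- t(vapply(thr, function(th) rates_at(s, th), numeric(5)))
  data.frame(threshold = thr, sensitivity = m[, "sens"],
             specificity = m[, "spec"], accuracy = m[, "acc"],
             fpr = m[, "fpr"], fnr = m[, "fnr"])
}

#' ROC curve and AUC
#'
#' ROC points over the exact threshold sweep; the area under the curve by
#' the trapezoidal rule, which equals the normalised Mann-Whitney U
#' statistic (ties counted half).
#'
#' @param s A [score_set()].
#' @return List with `roc` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(s) {
  stopifnot(inherits(s, "score_set"))
  check_both_classes(s)
  sw <- sweep_thresholds(s)
  ord <- order(sw$fpr, sw$sensitivity)
  roc <- data.frame(fpr = c(1, sw$fpr[ord], 0),
                    tpr = c(1, sw$sensitivity[ord], 0),
                    threshold = c(-Inf, sw$threshold[ord], Inf))
  roc <- roc[order(roc$fpr, roc$tpr), ]
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' DET curve, equal error rate and optimal threshold
#'
#' The detection-error trade-off pairs (false-positive rate,
#' false-negative rate) over the threshold sweep; the equal error rate at
#' the FNR/FPR crossing, linearly interpolated between the bracketing
#' thresholds, and the threshold `theta_rop` achieving it. Ties at the
#' crossing are broken toward the lower threshold (favouring
#' sensitivity — the clinically conservative side).
#'
#' @param s A [score_set()].
#' @param n_steps Optional fixed sweep resolution (default: exact sweep).
#' @return List with `det` (data frame `threshold`, `fpr`, `fnr`), `eer`
#'   and `theta_rop`.
#' @export
det_eer <- function(s, n_steps = NULL) {
  stopifnot(inherits(s, "score_set"))
  check_both_classes(s)
  sw <- sweep_thresholds(s, n_steps)
  if (length(unique(s$lambda)) == 1L) {
    warning("all scores identical: EER = 0.5 by convention")
    return(list(det = sw[c("threshold", "fpr", "fnr")], eer = 0.5,
                theta_rop = s$lambda[1]))
  }
  d <- sw$fnr - sw$fpr   # increases with threshold
  cross <- which(d[-1] >= 0 & d[-length(d)] <= 0)
  if (length(cross) == 0L) {
    # no sign change: take the sweep point minimising the gap
    i <- which.min(abs(d))
    eer <- (sw$fnr[i] + sw$fpr[i]) / 2
    theta <- sw$threshold[i]
  } else {
    i <- cross[1]
    d0 <- d[i]; d1 <- d[i + 1]
    w <- if (d1 == d0) 0 else -d0 / (d1 - d0)
    eer <- (1 - w) * sw$fpr[i] + w * sw$fpr[i + 1]
    fnr_c <- (1 - w) * sw$fnr[i] + w * sw$fnr[i + 1]
    eer <- (eer + fnr_c) / 2
    theta <- (1 - w) * sw$threshold[i] + w * sw$threshold[i + 1]
  }
  list(det = sw[c("threshold", "fpr", "fnr")], eer = eer, theta_rop = theta)
}

#' Full detection report
#'
#' Threshold sweep, ROC/AUC, DET/EER and the confusion matrix at the
#' optimal threshold, bundled.
#'
#' @param s A [score_set()].
#' @param n_steps Optional sweep resolution.
#' @return Object of class `detection_report`.
#' @export
detection_report <- function(s, n_steps = NULL) {
  sw <- sweep_thresholds(s, n_steps)
  ra <- roc_auc(s)
  de <- det_eer(s, n_steps)
  at_op <- rates_at(s, de$theta_rop)
  structure(list(sweep = sw, roc = ra$roc, auc = ra$auc, det = de$det,
                 eer = de$eer, theta_rop = de$theta_rop,
                 sensitivity = at_op[["sens"]], specificity = at_op[["spec"]],
                 accuracy = at_op[["acc"]]),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("detection_report: AUC %.4f, EER %.4f at theta_rop %.4f\n",
              x$auc, x$eer, x$theta_rop))
  cat(sprintf("  at theta_rop: sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Leave-one-out run
#'
#' Scores every subject with a network trained on all the others. The
#' random hidden layer `W1` is drawn once from `seed` and held fixed
#' across folds; only the closed-form output layer `W2` is refit per
#' fold, so one run has one well-defined operating behaviour.
#'
#' @param features Feature matrix `n_s x n_f`.
#' @param labels Class labels per row.
#' @param n_h Hidden width.
#' @param seed Seed for the hidden layer.
#' @return A [score_set()] of `n_s` held-out scores.
#' @export
loo_run <- function(features, labels, n_h = 200, seed = 1L) {
  features <- as.matrix(features)
  n_s <- nrow(features)
  if (n_s != length(labels)) stop_input("features and labels must align")
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop_input("need at least 2 subjects per class for leave-one-out")
  }
  W1 <- init_hidden(ncol(features), n_h, seed)
  lambda <- numeric(n_s)
  for (i in seq_len(n_s)) {
    model <- rlsfn_train(features[-i, , drop = FALSE], labels[-i],
                         n_h = n_h, seed = seed, W1 = W1)
    Z <- predict(model, features[i, , drop = FALSE])
    lambda[i] <- llr_scores(Z)
  }
  score_set(lambda, labels)
}

#' Monte Carlo stability analysis
#'
#' Repeats the leave-one-out experiment over independently re-randomised
#' hidden layers and summarises the distribution of the equal error rate
#' and optimal threshold across epochs: medians, quartiles, and the
#' Pearson correlation between per-epoch EER and threshold.
#'
#' @param features,labels Cohort as in [loo_run()].
#' @param n_epochs Number of Monte Carlo epochs.
#' @param n_h Hidden width.
#' @param master_seed Seed from which all epoch seeds are derived.
#' @return Object of class `mc_report`: per-epoch `eer`, `theta_rop`,
#'   `auc`, `epoch_seeds`, summary quartiles and the EER-threshold
#'   correlation with its p-value.
#' @export
monte_carlo <- function(features, labels, n_epochs = 200, n_h = 200,
                        master_seed = 1L) {
  eer <- numeric(n_epochs)
  theta <- numeric(n_epochs)
  auc <- numeric(n_epochs)
  seeds <- vapply(seq_len(n_epochs), function(e) derive_seed(master_seed, e),
                  integer(1))
  for (e in seq_len(n_epochs)) {
    s <- loo_run(features, labels, n_h = n_h, seed = seeds[e])
    de <- det_eer(s)
    eer[e] <- de$eer
    theta[e] <- de$theta_rop
    auc[e] <- roc_auc(s)$auc
  }
  q <- function(x) unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
  corr <- if (n_epochs >= 2 && stats::sd(eer) > 0 && stats::sd(theta) > 0) {
    ct <- stats::cor.test(eer, theta)
    list(rho = unname(ct$estimate), p_value = ct$p.value)
  } else {
    if (n_epochs < 2) warning("fewer than 2 epochs: correlation undefined")
    list(rho = NA_real_, p_value = NA_real_)
  }
  structure(list(
    eer = eer, theta_rop = theta, auc = auc, epoch_seeds = seeds,
    eer_quartiles = q(eer), theta_quartiles = q(theta),
    median_eer = stats::median(eer), median_theta = stats::median(theta),
    median_auc = stats::median(auc),
    correlation = corr, n_epochs = n_epochs, n_h = n_h,
    master_seed = as.integer(master_seed)),
    class = "mc_report")
}

#' @export
print.mc_report <- function(x, ...) {
  cat(sprintf("mc_report: %d epochs, n_h = %d\n", x$n_epochs, x$n_h))
  cat(sprintf("  EER median %.4f [Q1 %.4f, Q3 %.4f]\n",
              x$median_eer, x$eer_quartiles[1], x$eer_quartiles[3]))
  cat(sprintf("  theta_rop median %.4f [Q1 %.4f, Q3 %.4f]\n",
              x$median_theta, x$theta_quartiles[1], x$theta_quartiles[3]))
  cat(sprintf("  median AUC %.4f; cor(EER, theta) = %.4f (p = %.3g)\n",
              x$median_auc, x$correlation$rho, x$correlation$p_value))
  invisible(x)
}

#' Hidden-width sweep
#'
#' Median equal error rate (over seeds) as a function of the hidden-layer
#' width; used to locate the width beyond which the EER settles.
#'
#' @param features,labels Cohort.
#' @param n_h_grid Vector of hidden widths to try.
#' @param seeds Seeds over which the median is taken.
#' @return Data frame with `n_h` and `median_eer`.
#' @export
sweep_hidden_width <- function(features, labels, n_h_grid = c(20, 60, 80, 200),
                               seeds = 1:5) {
  if (length(n_h_grid) == 0L) stop_input("n_h grid must be non-empty")
  med <- vapply(n_h_grid, function(nh) {
    stats::median(vapply(seeds, function(sd) {
      det_eer(loo_run(features, labels, n_h = nh, seed = sd))$eer
    }, numeric(1)))
  }, numeric(1))
  data.frame(n_h = n_h_grid, median_eer = med)
}
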