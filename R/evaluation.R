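# ROC/AUC machinery, Youden operating point, bootstrap CIs, leave-one-out
# cross-validation of the entire construction, and external-cohort evaluation.

#' Area under the ROC curve
#'
#' The Mann-Whitney probability estimate: the proportion of (case, control)
#' pairs in which the case scores higher, with ties counted 1/2. Computed from
#' midranks, so it is exact and invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (1/TRUE = case); both classes required.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))   # 1
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels == 1 | labels == TRUE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop_gf("auc: both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve vertices
#'
#' Builds the ROC over all distinct score thresholds (no binning), with the
#' decision rule \code{score >= threshold -> positive}. The curve starts at
#' (0, 0) (threshold \code{Inf}) and ends at (1, 1) (threshold \code{-Inf}),
#' and is non-decreasing in both axes.
#'
#' @inheritParams auc
#' @return Data frame of class \code{gf_roc} with columns \code{threshold},
#'   \code{fpr}, \code{tpr}.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels == 1 | labels == TRUE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop_gf("roc_curve: both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n1, 1)
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n0, 1)
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1) {
    out <- rbind(out, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  class(out) <- c("gf_roc", "data.frame")
  out
}

#' @export
plot.gf_roc <- function(x, ...) {
  args <- list(...)
  if (is.null(args$main)) args$main <- "ROC curve"
  do.call(graphics::plot,
          c(list(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity"), args))
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Youden operating point
#'
#' The ROC vertex maximising the Youden J index (sensitivity + specificity -
#' 1). Ties are broken toward higher sensitivity, then toward the higher
#' threshold.
#'
#' @param roc A \code{gf_roc} data frame from [roc_curve()].
#' @return List: \code{threshold}, \code{sensitivity}, \code{specificity},
#'   \code{J}.
#' @export
youden_point <- function(roc) {
  j <- roc$tpr - roc$fpr
  # tolerance on J ties: vertices with mathematically equal J can differ in
  # the last floating-point digit
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) best <- best[roc$tpr[best] == max(roc$tpr[best])]
  if (length(best) > 1L) best <- best[which.max(roc$threshold[best])]
  list(threshold = roc$threshold[best], sensitivity = roc$tpr[best],
       specificity = 1 - roc$fpr[best], J = j[best])
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile bootstrap, resampling cases and controls separately (stratified)
#' so every resample retains both classes. Seeded and reproducible; the
#' caller's RNG state is untouched.
#'
#' @inheritParams auc
#' @param reps Bootstrap replicates (>= 200; default 2000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector \code{c(lo, hi)}.
#' @export
auc_ci <- function(scores, labels, reps = 2000L, seed = 1L, level = 0.95) {
  if (reps < 200L) stop_gf("auc_ci: reps must be >= 200")
  labels <- as.logical(labels == 1 | labels == TRUE)
  i1 <- which(labels); i0 <- which(!labels)
  if (!length(i1) || !length(i0)) stop_gf("auc_ci: both classes must be present")
  boots <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  unname(stats::quantile(boots, c(alpha, 1 - alpha)))
}

#' Evaluate scores against labels
#'
#' Assembles the full evaluation report: ROC vertices, AUC with a stratified
#' bootstrap confidence interval, the Youden operating point, and sensitivity
#' / specificity / accuracy at that point.
#'
#' @inheritParams auc_ci
#' @param ci Compute the bootstrap CI (disable for speed in inner loops).
#' @return Object of class \code{gf_report}: \code{roc}, \code{auc},
#'   \code{auc_ci}, \code{youden} (threshold/sensitivity/specificity/J),
#'   \code{sensitivity}, \code{specificity}, \code{accuracy},
#'   \code{n_cases}, \code{n_controls}.
#' @export
evaluate_scores <- function(scores, labels, reps = 2000L, seed = 1L, ci = TRUE) {
  labels <- as.logical(labels == 1 | labels == TRUE)
  roc <- roc_curve(scores, labels)
  y <- youden_point(roc)
  n1 <- sum(labels); n0 <- sum(!labels)
  acc <- (y$sensitivity * n1 + y$specificity * n0) / (n1 + n0)
  structure(list(
    roc = roc, auc = auc(scores, labels),
    auc_ci = if (ci) auc_ci(scores, labels, reps = reps, seed = seed) else NULL,
    youden = y, sensitivity = y$sensitivity, specificity = y$specificity,
    accuracy = acc, n_cases = n1, n_controls = n0),
    class = "gf_report")
}

#' @export
print.gf_report <- function(x, ...) {
  cat(sprintf("Evaluation: %d cases / %d controls\n", x$n_cases, x$n_controls))
  if (!is.null(x$auc_ci)) {
    cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  } else {
    cat(sprintf("  AUC = %.3f\n", x$auc))
  }
  cat(sprintf("  Youden point: threshold %.3f, sensitivity %.2f, specificity %.2f, accuracy %.2f\n",
              x$youden$threshold, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Leave-one-out cross-validation of the entire construction
#'
#' For every labelled participant, refits the \emph{whole} best-fit
#' construction - candidate extraction, the four sub-algorithms, the merges,
#' modality selection and the final blend - on the remaining participants, and
#' scores the held-out participant with that fold's model. The pooled
#' out-of-sample scores yield the cross-validated ROC/AUC; each fold's 0.5
#' call is also recorded as that participant's "vote". A fold whose removal
#' empties a class-band cell (or otherwise cannot be fitted) is skipped with a
#' warning and excluded from the pooled report.
#'
#' @param attr_mat A \code{gf_attributes} object.
#' @param cohort Cohort data frame; labelled rows are cross-validated.
#' @param config A [bestfit_config()].
#' @param reps,seed Bootstrap parameters for the pooled report's AUC CI.
#' @param progress Print a dot per fold.
#' @return Object of class \code{gf_loo}: \code{folds} (data frame of
#'   per-participant out-of-sample \code{score}, \code{vote} and true
#'   \code{label}), \code{report} (pooled \code{gf_report}), \code{skipped}.
#' @export
loo_bestfit <- function(attr_mat, cohort, config = bestfit_config(),
                        reps = 2000L, seed = 1L, progress = FALSE) {
  if (!"age_band" %in% names(cohort)) cohort$age_band <- age_band(cohort$age_years)
  train <- labelled_training_rows(cohort, attr_mat$values)
  if (nrow(train) < 10L) stop_gf("loo_bestfit: need at least 10 labelled participants")

  ids <- train$participant_id
  scores <- rep(NA_real_, length(ids)); names(scores) <- ids
  skipped <- character(0)
  for (id in ids) {
    rest <- train[train$participant_id != id, , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(bestfit(attr_mat, rest, config = config)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("LOO fold for '", id, "' skipped: ", conditionMessage(fit))
      skipped <- c(skipped, id)
    } else {
      age <- train$age_years[train$participant_id == id]
      scores[id] <- bestfit_score(fit, attr_mat$values[id, , drop = FALSE], age)
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  ok <- !is.na(scores)
  folds <- data.frame(participant_id = ids, score = unname(scores),
                      vote = as.integer(scores >= 0.5),
                      label = train$asd_label, stringsAsFactors = FALSE)
  report <- evaluate_scores(scores[ok], train$asd_label[ok], reps = reps, seed = seed)
  structure(list(folds = folds, report = report, skipped = skipped),
            class = "gf_loo")
}

#' @export
print.gf_loo <- function(x, ...) {
  cat("Leave-one-out cross-validation:", nrow(x$folds), "folds",
      if (length(x$skipped)) paste0("(", length(x$skipped), " skipped)") else "", "\n")
  print(x$report)
  invisible(x)
}

#' Evaluate a fitted model on an external cohort
#'
#' Applies a fitted best-fit algorithm, without any refitting, to an
#' independent cohort and reports its discrimination. Participants that
#' overlap the model's training set are rejected.
#'
#' @param object A fitted \code{bestfit} model.
#' @param attr_mat A \code{gf_attributes} object for the external cohort.
#' @param cohort External cohort data frame with \code{asd_label}.
#' @param reps,seed Bootstrap parameters for the AUC CI.
#' @return A \code{gf_report}.
#' @export
evaluate_external <- function(object, attr_mat, cohort, reps = 2000L, seed = 1L) {
  overlap <- intersect(cohort$participant_id, object$training$ids)
  if (length(overlap)) {
    stop_gf("external cohort overlaps the training set: ",
            paste(utils::head(overlap, 5L), collapse = ", "))
  }
  rows <- cohort[!is.na(cohort$asd_label), , drop = FALSE]
  pred <- predict(object, attr_mat, rows)
  labels <- rows$asd_label[match(pred$participant_id, rows$participant_id)]
  evaluate_scores(pred$score, labels, reps = reps, seed = seed)
}
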