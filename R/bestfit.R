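# The best-fit diagnostic algorithm: four sub-algorithms (age band x score
# family), each a sigmoid over an oriented, normalised attribute aggregate;
# the two bands of each family merged along age with a logistic age weight;
# the better modality per band chosen by AUC; a final age-continuous blend.
#
# The sigmoid family, loss and optimiser are design choices of this package:
# logistic function, mean binary cross-entropy, L-BFGS-B over a fixed
# deterministic multistart grid (no RNG in any fit, so refits are
# bit-reproducible by construction).

#' Fit a scalar sigmoid score
#'
#' Fits \eqn{\sigma(a x + b)} to binary labels by minimising the mean binary
#' cross-entropy, with the slope constrained \code{a >= 0} (the aggregate fed
#' to it is oriented so that larger means more ASD-like). Optimisation is
#' L-BFGS-B from a fixed grid of starting points; no randomness is involved.
#'
#' @param x Numeric aggregate values.
#' @param y Binary labels (0/1 or logical), both classes present.
#' @param max_iter Iteration cap per start (default 500).
#' @param tol Convergence tolerance on the projected gradient (default 1e-8).
#' @return List of class \code{gf_sigmoid}: \code{a}, \code{b}, \code{loss},
#'   \code{converged}.
#' @export
fit_sigmoid <- function(x, y, max_iter = 500L, tol = 1e-8) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop_gf("fit_sigmoid: both classes must be present")
  stopifnot(length(x) == length(y), all(y %in% 0:1))

  nll <- function(par) bce(stats::plogis(par[1] * x + par[2]), y)
  grad <- function(par) {
    p <- stats::plogis(par[1] * x + par[2])
    c(mean((p - y) * x), mean(p - y))
  }
  b0 <- stats::qlogis(mean(y))
  # scale-aware slope grid: cover flat through near-separating fits
  sx <- stats::sd(x); if (!is.finite(sx) || sx == 0) sx <- 1
  starts <- expand.grid(a = c(0, 0.5, 2, 8, 32) / sx, b = c(b0, 0))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$a[i], starts$b[i]), nll, gr = grad,
                   method = "L-BFGS-B", lower = c(0, -50), upper = c(500, 50),
                   control = list(maxit = max_iter, pgtol = tol, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_gf("fit_sigmoid: optimisation failed")
  structure(list(a = best$par[1], b = best$par[2], loss = best$value,
                 converged = best$convergence == 0),
            class = "gf_sigmoid")
}

#' Aggregate candidate attributes into a scalar
#'
#' One participant-level value per row: for the rate family, the mean over
#' candidates of \code{orientation * value / SD}, where SD is the
#' per-attribute training standard deviation (a zero training SD makes that
#' attribute contribute 0, flagged at fit time); for the count family, the
#' mean of orientation-aligned 0/1 values (\code{value} when the orientation
#' is +1, \code{1 - value} when it is -1). Higher always means more ASD-like.
#'
#' @param sub A \code{gf_subalgo} (fitted sub-algorithm), or a list with
#'   \code{candidates} (a \code{gf_candidates} frame), \code{family} and, for
#'   the rate family, \code{normalizers} (named SD vector).
#' @param values Attribute values: a \code{gf_attributes} object or a numeric
#'   matrix with attribute-id column names.
#' @return Numeric vector, one aggregate per row of \code{values}.
#' @export
aggregate_attributes <- function(sub, values) {
  if (inherits(values, "gf_attributes")) values <- values$values
  cand <- sub$candidates
  if (!nrow(cand)) stop_gf("aggregate_attributes: empty candidate set")
  v <- values[, cand$attr_id, drop = FALSE]
  if (sub$family == "rate") {
    sds <- sub$normalizers[cand$attr_id]
    scale <- ifelse(sds > 0, cand$orientation / sds, 0)
    contrib <- sweep(v, 2L, scale, "*")
  } else {
    contrib <- sweep(v, 2L, cand$orientation, "*") +
      rep(ifelse(cand$orientation < 0, 1, 0), each = nrow(v))
  }
  rowMeans(contrib)
}

#' Fit one sub-algorithm (age band x score family)
#'
#' Runs candidate selection on the band's labelled training rows, computes the
#' per-attribute training SDs (rate family), aggregates, and fits the sigmoid
#' against the ASD labels of the band.
#'
#' @inheritParams select_candidates
#' @param ... Passed to [select_candidates()].
#' @return Object of class \code{gf_subalgo}: \code{band}, \code{family},
#'   \code{candidates}, \code{normalizers}, \code{degenerate} (ids of rate
#'   candidates with zero training SD), \code{sigmoid}, \code{training_ids}.
#' @export
fit_subalgorithm <- function(attr_mat, cohort, band, family, ...) {
  cand <- select_candidates(attr_mat, cohort, band = band, family = family, ...)
  if (!nrow(cand)) {
    stop_gf("no candidate attributes for the ", band, "/", family, " cell")
  }
  rows <- labelled_training_rows(cohort, attr_mat$values)
  rows <- rows[rows$age_band == band, , drop = FALSE]
  vals <- attr_mat$values[rows$participant_id, , drop = FALSE]

  normalizers <- NULL; degenerate <- character(0)
  if (family == "rate") {
    normalizers <- apply(vals[, cand$attr_id, drop = FALSE], 2L, stats::sd)
    degenerate <- names(normalizers)[normalizers == 0]
  }
  sub <- list(band = band, family = family, candidates = cand,
              normalizers = normalizers, degenerate = degenerate)
  agg <- aggregate_attributes(sub, vals)
  sub$sigmoid <- fit_sigmoid(agg, rows$asd_label)
  sub$training_ids <- rows$participant_id
  structure(sub, class = "gf_subalgo")
}

# sub-algorithm score in (0,1) for arbitrary rows
subalgo_score <- function(sub, values) {
  agg <- aggregate_attributes(sub, values)
  stats::plogis(sub$sigmoid$a * agg + sub$sigmoid$b)
}

# ---- age blend -------------------------------------------------------------

# Fit s(age) = sigma(A * (w * s1 + (1 - w) * s2) + B) with the logistic age
# weight w(age) = 1 / (1 + exp(k * (age - a0))): w -> 1 for young ages and
# -> 0 for old ages. A >= 0 and k >= 0 keep the blend ASD-oriented and the
# weight monotone in age; a0 starts at the 10-year band boundary.
fit_age_blend <- function(s1, s2, age, y, max_iter = 500L, tol = 1e-8) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop_gf("age blend: both classes must be present")
  nll <- function(par) {
    w <- stats::plogis(-par[3] * (age - par[4]))
    bce(stats::plogis(par[1] * (w * s1 + (1 - w) * s2) + par[2]), y)
  }
  b0 <- stats::qlogis(mean(y))
  starts <- expand.grid(A = c(2, 8, 32), B = b0, k = c(0.3, 1.5, 6), a0 = 10)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = c(0, -50, 0, 5), upper = c(500, 50, 10, 17),
                   control = list(maxit = max_iter, pgtol = tol, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_gf("age blend: optimisation failed from every start")
  list(A = best$par[1], B = best$par[2], k = best$par[3], a0 = best$par[4],
       loss = best$value, converged = best$convergence == 0)
}

age_blend_score <- function(blend, s1, s2, age) {
  w <- stats::plogis(-blend$k * (age - blend$a0))
  stats::plogis(blend$A * (w * s1 + (1 - w) * s2) + blend$B)
}

#' Merge the two age bands of one score family
#'
#' Blends the younger-band and older-band sub-algorithms of one family into a
#' single age-continuous score: an outer sigmoid of the logistic-age-weighted
#' combination of the two sub-algorithm scores, with all four coefficients
#' (outer slope/intercept, age-weight steepness and centre) estimated by
#' cross-entropy on \emph{all} labelled training rows (both bands).
#'
#' @param young,old Fitted \code{gf_subalgo} objects of the same family.
#' @param attr_mat A \code{gf_attributes} object.
#' @param cohort Cohort data frame (labelled rows are used).
#' @return Object of class \code{gf_merged}: \code{family}, \code{young},
#'   \code{old}, \code{blend} (A, B, k, a0, loss).
#' @export
merge_bands <- function(young, old, attr_mat, cohort) {
  stopifnot(young$family == old$family, young$band == "younger", old$band == "older")
  rows <- labelled_training_rows(cohort, attr_mat$values)
  vals <- attr_mat$values[rows$participant_id, , drop = FALSE]
  s_y <- subalgo_score(young, vals)
  s_o <- subalgo_score(old, vals)
  blend <- fit_age_blend(s_y, s_o, rows$age_years, rows$asd_label)
  structure(list(family = young$family, young = young, old = old, blend = blend),
            class = "gf_merged")
}

# merged (final per-family) score for arbitrary rows
merged_score <- function(merged, values, age) {
  if (inherits(values, "gf_attributes")) values <- values$values
  s_y <- subalgo_score(merged$young, values)
  s_o <- subalgo_score(merged$old, values)
  age_blend_score(merged$blend, s_y, s_o, age)
}

#' Choose the better score family per age band
#'
#' For each band, computes the within-band training AUC of the merged rate
#' score and the merged count score and picks the family with the higher AUC;
#' exact ties go to the rate family.
#'
#' @param rate_merged,count_merged Fitted \code{gf_merged} objects.
#' @param attr_mat A \code{gf_attributes} object.
#' @param cohort Cohort data frame.
#' @return Named character vector \code{c(younger = ..., older = ...)} with
#'   values \code{"rate"}/\code{"count"}, carrying the per-band AUCs as the
#'   \code{"auc"} attribute.
#' @export
select_modality <- function(rate_merged, count_merged, attr_mat, cohort) {
  rows <- labelled_training_rows(cohort, attr_mat$values)
  vals <- attr_mat$values[rows$participant_id, , drop = FALSE]
  s_rate <- merged_score(rate_merged, vals, rows$age_years)
  s_count <- merged_score(count_merged, vals, rows$age_years)

  choice <- c(younger = NA_character_, older = NA_character_)
  aucs <- matrix(NA_real_, 2, 2, dimnames = list(c("younger", "older"),
                                                 c("rate", "count")))
  for (band in c("younger", "older")) {
    in_band <- rows$age_band == band
    aucs[band, "rate"] <- auc(s_rate[in_band], rows$asd_label[in_band])
    aucs[band, "count"] <- auc(s_count[in_band], rows$asd_label[in_band])
    choice[band] <- if (aucs[band, "count"] > aucs[band, "rate"]) "count" else "rate"
  }
  attr(choice, "auc") <- aucs
  choice
}

#' Default configuration for the best-fit construction
#'
#' @param alpha Significance level of the selection rule (default 0.05, with
#'   no multiple-testing correction - the rule is deliberately permissive so
#'   that no potential candidate is missed; the per-AOI deduplication and the
#'   fixation floor then prune it).
#' @param d_threshold Effect-size arm of the selection rule (default 0.5).
#' @param fixation_threshold AOI-level pooled fixation floor in percent
#'   (default 20).
#' @param test Group-comparison test for rate attributes (\code{"welch"} or
#'   \code{"wilcox"}).
#' @param fixation_floor Per-participant overall fixation percentage under
#'   which predictions are flagged unreliable (default 70).
#' @return A list of class \code{gf_config}.
#' @export
bestfit_config <- function(alpha = 0.05, d_threshold = 0.5,
                           fixation_threshold = 20, test = "welch",
                           fixation_floor = 70) {
  structure(list(alpha = alpha, d_threshold = d_threshold,
                 fixation_threshold = fixation_threshold, test = test,
                 fixation_floor = fixation_floor),
            class = "gf_config")
}

#' Fit the best-fit diagnostic algorithm
#'
#' Executes the whole construction on labelled (ASD/TD) training rows:
#' candidate selection in the four age-band x score-family cells, four
#' sub-algorithm sigmoid fits, the two per-family age-band merges, AUC-based
#' modality selection per band, and the final age-continuous blend of the two
#' chosen score streams. The fitted object predicts an ASD probability-like
#' score in (0,1); a score of 0.5 or higher calls ASD. The construction is
#' deterministic given the data and configuration.
#'
#' @param attr_mat A \code{gf_attributes} object (see
#'   [build_attribute_matrix()]).
#' @param cohort Cohort data frame with \code{participant_id},
#'   \code{age_years}, \code{asd_label} (and \code{age_band}, added by
#'   [read_cohort_table()] / [as_cohort]); rows with missing labels are
#'   ignored for training.
#' @param config A [bestfit_config()] list.
#' @return An object of class \code{bestfit}.
#' @examples
#' \donttest{
#' stim <- gf_stimulus()
#' sim <- simulate_cohort(stim, sim_config(n_asd = 20, n_td = 40,
#'                                         n_second_control = 0, seed = 7))
#' m <- build_attribute_matrix(sim$gaze, stim)
#' fit <- bestfit(m, sim$cohort)
#' fit
#' }
#' @export
bestfit <- function(attr_mat, cohort, config = bestfit_config()) {
  stopifnot(inherits(attr_mat, "gf_attributes"))
  if (!"age_band" %in% names(cohort)) cohort$age_band <- age_band(cohort$age_years)
  train <- labelled_training_rows(cohort, attr_mat$values)
  for (band in c("younger", "older")) {
    lab <- train$asd_label[train$age_band == band]
    if (sum(lab == 1) < 2L || sum(lab == 0) < 2L) {
      stop_gf("bestfit: need >= 2 participants per class in the ", band, " band")
    }
  }

  sel_args <- list(alpha = config$alpha, d_threshold = config$d_threshold,
                   fixation_threshold = config$fixation_threshold,
                   test = config$test)
  subs <- list()
  for (family in c("rate", "count")) {
    for (band in c("younger", "older")) {
      subs[[paste(family, band, sep = "_")]] <- do.call(
        fit_subalgorithm, c(list(attr_mat, train, band = band, family = family),
                            sel_args))
    }
  }
  rate_merged <- merge_bands(subs$rate_younger, subs$rate_older, attr_mat, train)
  count_merged <- merge_bands(subs$count_younger, subs$count_older, attr_mat, train)
  modality <- select_modality(rate_merged, count_merged, attr_mat, train)

  vals <- attr_mat$values[train$participant_id, , drop = FALSE]
  s_rate <- merged_score(rate_merged, vals, train$age_years)
  s_count <- merged_score(count_merged, vals, train$age_years)
  stream_of <- function(fam) if (fam == "rate") s_rate else s_count
  final <- fit_age_blend(stream_of(modality[["younger"]]),
                         stream_of(modality[["older"]]),
                         train$age_years, train$asd_label)

  scores <- age_blend_score(final, stream_of(modality[["younger"]]),
                            stream_of(modality[["older"]]), train$age_years)
  obj <- structure(list(
    subalgorithms = subs,
    rate_merged = rate_merged, count_merged = count_merged,
    modality = modality, final_blend = final,
    threshold = 0.5, config = config,
    training = list(ids = train$participant_id, labels = train$asd_label,
                    age = train$age_years, scores = scores,
                    auc = auc(scores, train$asd_label)),
    call = match.call()),
    class = "bestfit")
  obj
}

# final best-fit score for arbitrary rows
bestfit_score <- function(object, values, age) {
  if (inherits(values, "gf_attributes")) values <- values$values
  s_rate <- merged_score(object$rate_merged, values, age)
  s_count <- merged_score(object$count_merged, values, age)
  stream_of <- function(fam) if (fam == "rate") s_rate else s_count
  age_blend_score(object$final_blend,
                  stream_of(object$modality[["younger"]]),
                  stream_of(object$modality[["older"]]), age)
}

#' Predict from a fitted best-fit algorithm
#'
#' Scores participants and calls ASD at score >= 0.5 (the threshold is
#' inclusive). Participants whose overall gaze fixation percentage falls below
#' the configured floor (default 70 percent) are still scored but flagged
#' \code{low_fixation}: predictions from such degraded recordings are
#' considered unreliable.
#'
#' @param object A \code{bestfit} model.
#' @param attr_mat A \code{gf_attributes} object covering the participants to
#'   score.
#' @param cohort Cohort data frame supplying ages for those participants.
#' @param fixation_floor Override of the reliability floor, in percent.
#' @param ... Unused.
#' @return Data frame: \code{participant_id}, \code{age_years}, \code{score},
#'   \code{label} (1 = ASD call), \code{fixation_pct}, \code{low_fixation}.
#' @export
predict.bestfit <- function(object, attr_mat, cohort,
                            fixation_floor = object$config$fixation_floor, ...) {
  stopifnot(inherits(attr_mat, "gf_attributes"))
  ids <- intersect(cohort$participant_id, rownames(attr_mat$values))
  if (!length(ids)) stop_gf("predict.bestfit: no cohort participants in the attribute matrix")
  age <- cohort$age_years[match(ids, cohort$participant_id)]
  scores <- bestfit_score(object, attr_mat$values[ids, , drop = FALSE], age)
  fix <- attr_mat$fixation_pct[ids]
  data.frame(participant_id = ids, age_years = age, score = scores,
             label = as.integer(scores >= object$threshold),
             fixation_pct = unname(fix),
             low_fixation = unname(fix < fixation_floor),
             stringsAsFactors = FALSE)
}

#' @export
print.bestfit <- function(x, ...) {
  cat("Best-fit gaze diagnostic algorithm\n")
  n_cand <- vapply(x$subalgorithms, function(s) nrow(s$candidates), 1L)
  cat(sprintf("  candidates: rate %d (younger) / %d (older); count %d / %d\n",
              n_cand[["rate_younger"]], n_cand[["rate_older"]],
              n_cand[["count_younger"]], n_cand[["count_older"]]))
  cat(sprintf("  modality: younger = %s, older = %s\n",
              x$modality[["younger"]], x$modality[["older"]]))
  cat(sprintf("  training: n = %d (%d ASD / %d TD), AUC = %.3f\n",
              length(x$training$ids), sum(x$training$labels == 1),
              sum(x$training$labels == 0), x$training$auc))
  cat("  decision threshold: score >=", x$threshold, "-> ASD\n")
  invisible(x)
}

#' @export
summary.bestfit <- function(object, ...) {
  aucs <- attr(object$modality, "auc")
  out <- list(
    n_train = length(object$training$ids),
    n_asd = sum(object$training$labels == 1),
    n_td = sum(object$training$labels == 0),
    candidates = lapply(object$subalgorithms, function(s) s$candidates),
    band_aucs = aucs, modality = object$modality,
    final_blend = object$final_blend,
    training_auc = object$training$auc)
  class(out) <- "summary.bestfit"
  out
}

#' @export
print.summary.bestfit <- function(x, ...) {
  cat("Best-fit gaze diagnostic algorithm -", x$n_train, "training participants (",
      x$n_asd, "ASD /", x$n_td, "TD )\n\n")
  cat("Within-band AUCs of the merged per-family scores:\n")
  print(round(x$band_aucs, 3))
  cat("\nModality per band:", paste(names(x$modality), x$modality,
                                    sep = " = ", collapse = ", "), "\n")
  cat(sprintf("Final age blend: A = %.3f, B = %.3f, k = %.3f, a0 = %.2f years\n",
              x$final_blend$A, x$final_blend$B, x$final_blend$k, x$final_blend$a0))
  cat(sprintf("Training AUC: %.3f\n", x$training_auc))
  for (cell in names(x$candidates)) {
    cand <- x$candidates[[cell]]
    cat("\nCandidates [", cell, "]: ",
        paste(sprintf("%s (d=%.2f)", cand$attr_id, cand$d), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.bestfit <- function(object, ...) {
  sig <- lapply(object$subalgorithms,
                function(s) c(a = s$sigmoid$a, b = s$sigmoid$b))
  list(subalgorithms = sig,
       rate_blend = unlist(object$rate_merged$blend[c("A", "B", "k", "a0")]),
       count_blend = unlist(object$count_merged$blend[c("A", "B", "k", "a0")]),
       final_blend = unlist(object$final_blend[c("A", "B", "k", "a0")]))
}

#' Plot the training ROC curve of a best-fit model
#'
#' @param x A \code{bestfit} model.
#' @param ... Passed to \code{plot}.
#' @export
plot.bestfit <- function(x, ...) {
  r <- roc_curve(x$training$scores, x$training$labels)
  plot(r, main = sprintf("Training ROC (AUC = %.2f)", x$training$auc), ...)
  invisible(x)
}
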