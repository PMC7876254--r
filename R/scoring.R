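# AOI scoring: rate scores over three windows, count scores, overall gaze
# fixation percentage, and the participants x attributes matrix.
#
# Scores are computed directly on the raw 50 Hz samples: each valid sample
# inside an AOI contributes exactly 20 ms of dwell, with no interpolation and
# no velocity-based fixation filter. Invalid samples always count in the
# (time-based) denominator and never in the numerator.

MS_PER_SAMPLE <- 20

# subset a gf_gaze frame to one participant, erroring otherwise
one_participant <- function(gaze) {
  ids <- unique(gaze$participant_id)
  if (length(ids) != 1L) {
    stop_gf("expected a single participant's recording, got ",
            length(ids), " participants")
  }
  ids
}

#' AOI rate score
#'
#' The fraction of an analysis window's duration spent gazing inside an AOI.
#' For window \code{"full"} the denominator is the clip duration; for
#' \code{"first_1s"} / \code{"first_2s"} it is 1.0 s / 2.0 s, so every rate
#' score lives on the same `[0, 1]` scale. Windows are half-open
#' \verb{[0, w)} in clip time. Each valid sample inside the AOI contributes
#' 20 ms of dwell; invalid samples never count as inside.
#'
#' @param gaze A \code{gf_gaze} data frame for a single participant.
#' @param aoi A single-row AOI data frame (from \code{gf_stimulus()$aois}).
#' @param window One of \code{"full"}, \code{"first_1s"}, \code{"first_2s"}.
#' @param stimulus The \code{gf_stimulus} the recording refers to.
#' @return A number in `[0, 1]`.
#' @export
aoi_rate_score <- function(gaze, aoi, window = c("full", "first_1s", "first_2s"),
                           stimulus) {
  window <- match.arg(window)
  if (is.data.frame(aoi)) {
    stopifnot(nrow(aoi) == 1L)
    aoi <- as.list(aoi)
  }
  one_participant(gaze)
  dur_ms <- stimulus$clips$duration_s[stimulus$clips$clip_id == aoi$clip_id] * 1000
  if (!length(dur_ms)) stop_gf("AOI '", aoi$aoi_id, "': clip not in stimulus set")
  w_ms <- switch(window, full = dur_ms, first_1s = 1000, first_2s = 2000)
  if (w_ms > dur_ms) {
    stop_gf("window (", w_ms, " ms) longer than clip '", aoi$clip_id, "' (", dur_ms, " ms)")
  }
  g <- gaze[gaze$clip_id == aoi$clip_id, , drop = FALSE]
  inside <- g$valid & g$t_ms < w_ms & point_in_aoi(aoi, g$x_px, g$y_px)
  sum(inside) * MS_PER_SAMPLE / w_ms
}

#' AOI count score
#'
#' Binary presence/absence of a fixed gaze on an AOI over the full clip,
#' regardless of total duration: 1 iff the recording contains at least one run
#' of \code{min_run} consecutive valid samples inside the AOI. With the default
#' \code{min_run = 1} a single 20 ms sample counts; larger values require a
#' sustained fixation (e.g. \code{min_run = 10} is 200 ms, a conventional
#' minimum fixation duration).
#'
#' @inheritParams aoi_rate_score
#' @param min_run Minimum run length in samples (>= 1).
#' @return 0 or 1.
#' @export
aoi_count_score <- function(gaze, aoi, min_run = 1L) {
  stopifnot(min_run >= 1L)
  if (is.data.frame(aoi)) {
    stopifnot(nrow(aoi) == 1L)
    aoi <- as.list(aoi)
  }
  one_participant(gaze)
  g <- gaze[gaze$clip_id == aoi$clip_id, , drop = FALSE]
  if (!nrow(g)) return(0L)
  g <- g[order(g$t_ms), , drop = FALSE]
  inside <- g$valid & point_in_aoi(aoi, g$x_px, g$y_px)
  r <- rle(inside)
  as.integer(any(r$values & r$lengths >= min_run))
}

#' Overall gaze fixation percentage
#'
#' The share of the whole stimulus period with valid on-screen gaze:
#' 100 x (valid samples over all clips) / (expected samples, i.e. the sum of
#' clip durations times the 50 Hz sampling rate). This is the data-quality
#' metric used to flag unreliable recordings (a 70 percent floor is the
#' default reliability threshold at prediction time).
#'
#' @inheritParams aoi_rate_score
#' @return A percentage in `[0, 100]`.
#' @export
overall_fixation_percentage <- function(gaze, stimulus) {
  one_participant(gaze)
  missing <- setdiff(stimulus$clips$clip_id, unique(gaze$clip_id))
  if (length(missing)) {
    stop_gf("recording is missing clip(s): ", paste(missing, collapse = ", "))
  }
  expected <- sum(clip_sample_counts(stimulus))
  100 * sum(gaze$valid) / expected
}

#' Build the participants x attributes matrix
#'
#' Computes, for every participant and every attribute enumerated by
#' [attribute_space()], the AOI rate scores (full clip, first 1.0 s, first
#' 2.0 s) and the AOI count score, plus each participant's overall gaze
#' fixation percentage. Every participant must have samples for every clip
#' (possibly all invalid).
#'
#' @param gaze A \code{gf_gaze} data frame (any number of participants).
#' @param stimulus The \code{gf_stimulus}.
#' @param count_min_run Minimum run length (consecutive valid in-AOI samples)
#'   for the count score. The default of 25 samples (500 ms) reads "presence
#'   of a fixed gaze" as a sustained, deliberate fixation rather than a
#'   single-sample crossing, which keeps the count family informative on
#'   frequently-viewed AOIs.
#' @return An object of class \code{gf_attributes}: a list with \code{values}
#'   (numeric matrix, participants x attributes, columns in
#'   [attribute_space()] order), \code{fixation_pct} (named vector),
#'   \code{specs} (the attribute space), and \code{count_min_run}.
#' @export
build_attribute_matrix <- function(gaze, stimulus, count_min_run = 25L) {
  stopifnot(inherits(stimulus, "gf_stimulus"), count_min_run >= 1L)
  specs <- attribute_space(stimulus)
  participants <- sort(unique(gaze$participant_id))
  if (!length(participants)) stop_gf("gaze table has no participants")

  have <- unique(gaze[, c("participant_id", "clip_id")])
  n_clips <- table(factor(have$participant_id, levels = participants))
  if (any(n_clips < nrow(stimulus$clips))) {
    bad <- names(n_clips)[n_clips < nrow(stimulus$clips)]
    stop_gf("participant(s) missing clips: ", paste(bad, collapse = ", "))
  }

  n <- length(participants)
  values <- matrix(0, nrow = n, ncol = nrow(specs),
                   dimnames = list(participants, specs$attr_id))
  valid_counts <- numeric(n)

  for (ci in seq_len(nrow(stimulus$clips))) {
    cid <- stimulus$clips$clip_id[ci]
    dur_ms <- stimulus$clips$duration_s[ci] * 1000
    g <- gaze[gaze$clip_id == cid, , drop = FALSE]
    g <- g[order(g$participant_id, g$t_ms), , drop = FALSE]
    pidx <- match(g$participant_id, participants)
    valid_counts <- valid_counts + tabulate(pidx[g$valid], nbins = n)
    new_p <- c(TRUE, pidx[-1L] != pidx[-length(pidx)])

    for (aid in sort(stimulus$aois$aoi_id[stimulus$aois$clip_id == cid])) {
      aoi <- as.list(stimulus$aois[stimulus$aois$aoi_id == aid, ])
      ins <- g$valid & point_in_aoi(aoi, g$x_px, g$y_px)
      values[, paste0(aid, ".rate_full")] <-
        tabulate(pidx[ins], nbins = n) * MS_PER_SAMPLE / dur_ms
      values[, paste0(aid, ".rate_1s")] <-
        tabulate(pidx[ins & g$t_ms < 1000], nbins = n) * MS_PER_SAMPLE / 1000
      values[, paste0(aid, ".rate_2s")] <-
        tabulate(pidx[ins & g$t_ms < 2000], nbins = n) * MS_PER_SAMPLE / 2000

      if (count_min_run == 1L) {
        values[, paste0(aid, ".count")] <- as.numeric(tabulate(pidx[ins], nbins = n) > 0)
      } else {
        # run-length scan vectorised across participants: a run starts where
        # `ins` turns on or the participant changes
        start <- ins & (new_p | !c(FALSE, ins[-length(ins)]))
        run_id <- cumsum(start)
        run_len <- tabulate(run_id[ins], nbins = max(run_id, 1L))
        hit_runs <- which(run_len >= count_min_run)
        hit_p <- unique(pidx[start][hit_runs])
        col <- numeric(n); col[hit_p] <- 1
        values[, paste0(aid, ".count")] <- col
      }
    }
  }

  fixation <- 100 * valid_counts / sum(clip_sample_counts(stimulus))
  names(fixation) <- participants
  structure(list(values = values, fixation_pct = fixation, specs = specs,
                 count_min_run = as.integer(count_min_run)),
            class = "gf_attributes")
}

#' @export
print.gf_attributes <- function(x, ...) {
  cat("Attribute matrix:", nrow(x$values), "participants x",
      ncol(x$values), "attributes (",
      sum(x$specs$family == "rate"), "rate,",
      sum(x$specs$family == "count"), "count )\n")
  cat("Count score min run:", x$count_min_run, "samples;",
      "mean fixation:", round(mean(x$fixation_pct), 1), "%\n")
  invisible(x)
}

# subset an attribute matrix to a set of participant ids (keeps class)
subset_attributes <- function(attr_mat, ids) {
  stopifnot(all(ids %in% rownames(attr_mat$values)))
  structure(list(values = attr_mat$values[ids, , drop = FALSE],
                 fixation_pct = attr_mat$fixation_pct[ids],
                 specs = attr_mat$specs,
                 count_min_run = attr_mat$count_min_run),
            class = "gf_attributes")
}
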