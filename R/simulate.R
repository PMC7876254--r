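# Synthetic gaze-cohort simulator.
#
# Gaze over each clip is a first-order Markov chain at 50 Hz whose states are
# the clip's AOIs plus "elsewhere on-screen" and "off-screen". A participant's
# stationary state weights are drawn from a Dirichlet around clip-level base
# weights (label-driven: faces and geometric figures attract most dwell); for
# ASD participants the weights of designated signal AOIs are shifted on the
# log scale, which plants a group difference in dwell whose realised Cohen's d
# can be measured with realized_effects(). A high self-transition probability
# creates multi-sample fixation runs, so rate scores and sustained-fixation
# count scores decouple as they do in real gaze.

# relative dwell attraction per semantic label; scaled per clip so that AOI
# states leave room for the elsewhere and off-screen states
LABEL_WEIGHTS <- c(eyes = 0.28, face = 0.12, human = 0.05,
                   geometric = 0.11, object = 0.03, other = 0.02)

#' Default planted signal AOIs
#'
#' Eight AOIs with planted ASD/TD dwell differences, mirroring the two
#' paradigms' expected signatures: reduced dwell on eye/face regions of social
#' and preferential clips (negative shift) and increased dwell on geometric
#' halves of preferential clips (positive shift). The magnitude \code{delta}
#' is the shift of the dwell weight on the log scale; the package default is
#' calibrated so that the realised full-window rate-score effect is
#' approximately |d| = 1.2 at 100 participants per group.
#'
#' @param delta Dwell-logit shift magnitude.
#' @return Data frame: \code{aoi_id}, \code{scope} (\code{younger},
#'   \code{older} or \code{both}), \code{delta} (signed; negative = less ASD
#'   dwell).
#' @export
default_signal_aois <- function(delta = 1.1) {
  data.frame(
    aoi_id = c("still_eyes", "drawing_eyes_r", "classroom_teacher_face",
               "pref_b_eyes", "pref_e1_eyes",
               "pref_a_geo_half", "pref_c_geo_half", "pref_f2_geo_half"),
    scope = "both",
    delta = delta * c(-1, -1, -1, -1, -1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 39 ASD and 102 TD training
#' participants plus 24 second-control participants (17 of 24 ASD-like,
#' generated with extra heterogeneity), ages uniform over 5-17 years,
#' fixation stickiness rho = 0.95 (about 0.4 s mean fixation at 50 Hz), an
#' off-screen base weight of 0.08 (cohort mean overall fixation about 90
#' percent), and 2.5 percent of participants with degraded tracking (bursty
#' off-screen gaze pushing their overall fixation percentage below 70).
#'
#' @param n_asd,n_td,n_second_control Group sizes.
#' @param age_range Age range (uniform draw).
#' @param signal_aois Data frame as [default_signal_aois()]; \code{NULL} for
#'   the default set, or a zero-row frame for a null cohort.
#' @param rho Self-transition probability of the gaze chain, in (0,1).
#' @param offscreen_rate Base weight of the off-screen state, in (0,1).
#' @param elsewhere_min Minimum base weight reserved for the elsewhere state.
#' @param concentration Dirichlet concentration of between-participant
#'   propensity variation (larger = more homogeneous).
#' @param sc_concentration Dirichlet concentration for the second-control
#'   group (smaller = the extra heterogeneity of that mixed group).
#' @param sc_asd_rate Fraction of second-control participants generated from
#'   the ASD gaze model (and labelled ASD).
#' @param low_fixation_fraction Fraction of participants simulated with
#'   degraded tracking.
#' @param low_fixation_offscreen Off-screen weight used for degraded
#'   participants (0.5 puts their expected fixation near 50 percent, well
#'   under the 70 percent reliability floor).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   it.
#' @return A list of class \code{gf_simconfig}.
#' @export
sim_config <- function(n_asd = 39L, n_td = 102L, n_second_control = 24L,
                       age_range = c(5, 17), signal_aois = NULL,
                       rho = 0.95, offscreen_rate = 0.08, elsewhere_min = 0.12,
                       concentration = 50, sc_concentration = 12,
                       sc_asd_rate = 17 / 24,
                       low_fixation_fraction = 0.025,
                       low_fixation_offscreen = 0.5, seed = 1L) {
  if (is.null(signal_aois)) signal_aois <- default_signal_aois()
  stopifnot(rho > 0, rho < 1, offscreen_rate > 0, offscreen_rate < 1,
            low_fixation_fraction >= 0, low_fixation_fraction <= 1,
            low_fixation_offscreen > 0, low_fixation_offscreen < 1,
            all(signal_aois$scope %in% c("younger", "older", "both")))
  structure(list(n_asd = n_asd, n_td = n_td, n_second_control = n_second_control,
                 age_range = age_range, signal_aois = signal_aois, rho = rho,
                 offscreen_rate = offscreen_rate, elsewhere_min = elsewhere_min,
                 concentration = concentration, sc_concentration = sc_concentration,
                 sc_asd_rate = sc_asd_rate,
                 low_fixation_fraction = low_fixation_fraction,
                 low_fixation_offscreen = low_fixation_offscreen,
                 seed = as.integer(seed)),
            class = "gf_simconfig")
}

# TRUE iff AOI `inner`'s region lies entirely within AOI `outer`'s region
region_contained <- function(inner, outer) {
  if (is.data.frame(inner)) inner <- as.list(inner)
  if (is.data.frame(outer)) outer <- as.list(outer)
  if (inner$shape == "circle" && outer$shape == "circle") {
    sqrt((inner$cx - outer$cx)^2 + (inner$cy - outer$cy)^2) + inner$r <= outer$r
  } else if (inner$shape == "circle") {
    inner$cx - inner$r >= outer$x & inner$cx + inner$r <= outer$x + outer$w &
      inner$cy - inner$r >= outer$y & inner$cy + inner$r <= outer$y + outer$h
  } else {
    cx <- c(inner$x, inner$x + inner$w, inner$x, inner$x + inner$w)
    cy <- c(inner$y, inner$y, inner$y + inner$h, inner$y + inner$h)
    all(point_in_aoi(outer, cx, cy))
  }
}

# per-clip state table: AOI states with base weights scaled to leave room for
# elsewhere/off-screen, plus the indices of states affected by each signal AOI
# (the AOI itself and any AOI state whose centre lies inside it)
clip_states <- function(stimulus, cfg) {
  sig <- cfg$signal_aois
  missing <- setdiff(sig$aoi_id, stimulus$aois$aoi_id)
  if (length(missing)) {
    stop_gf("sim config: signal AOI(s) not in the stimulus set: ",
            paste(missing, collapse = ", "))
  }
  lapply(stimulus$clips$clip_id, function(cid) {
    aois <- stimulus$aois[stimulus$aois$clip_id == cid, , drop = FALSE]
    aois <- aois[order(aois$aoi_id), , drop = FALSE]
    w <- unname(LABEL_WEIGHTS[aois$label])
    budget <- 1 - cfg$offscreen_rate - cfg$elsewhere_min
    if (sum(w) > budget) w <- w * budget / sum(w)
    elsewhere <- 1 - cfg$offscreen_rate - sum(w)

    # a signal shift applies to the signal AOI's own state and to any AOI
    # state whose region is geometrically contained in it (e.g. an eye region
    # inside a shifted face region)
    shift <- matrix(0, nrow = nrow(aois), ncol = 2,
                    dimnames = list(aois$aoi_id, c("younger", "older")))
    sig_here <- sig[sig$aoi_id %in% aois$aoi_id, , drop = FALSE]
    for (k in seq_len(nrow(sig_here))) {
      target <- stimulus$aois[stimulus$aois$aoi_id == sig_here$aoi_id[k], ]
      affected <- vapply(seq_len(nrow(aois)), function(i) {
        region_contained(aois[i, ], target)
      }, logical(1))
      bands <- if (sig_here$scope[k] == "both") c("younger", "older") else sig_here$scope[k]
      shift[affected, bands] <- shift[affected, bands] + sig_here$delta[k]
    }
    list(clip_id = cid, aois = aois,
         base = c(w, elsewhere = elsewhere, offscreen = cfg$offscreen_rate),
         shift = shift)
  })
}

# uniform point(s) within one AOI region
emit_in_aoi <- function(aoi, m) {
  if (aoi$shape == "circle") {
    r <- aoi$r * sqrt(stats::runif(m))
    ang <- stats::runif(m, 0, 2 * pi)
    cbind(aoi$cx + r * cos(ang), aoi$cy + r * sin(ang))
  } else {
    cbind(stats::runif(m, aoi$x, aoi$x + aoi$w),
          stats::runif(m, aoi$y, aoi$y + aoi$h))
  }
}

# uniform on-screen points outside every AOI of the clip (rejection sampling)
emit_elsewhere <- function(aois, monitor, m) {
  out <- matrix(NA_real_, m, 2)
  need <- m
  while (need > 0) {
    cand_x <- stats::runif(2 * need + 16, 0, monitor[["width"]] - 1e-9)
    cand_y <- stats::runif(2 * need + 16, 0, monitor[["height"]] - 1e-9)
    ok <- !Reduce(`|`, lapply(seq_len(nrow(aois)), function(i) {
      point_in_aoi(aois[i, ], cand_x, cand_y)
    }), accumulate = FALSE)
    take <- min(sum(ok), need)
    if (take > 0) {
      out[(m - need + 1):(m - need + take), ] <-
        cbind(cand_x[ok][seq_len(take)], cand_y[ok][seq_len(take)])
      need <- need - take
    }
  }
  out
}

# one participant x one clip: Markov chain + emissions -> gaze data frame
simulate_clip <- function(pid, st, weights, n, rho) {
  K <- length(weights)
  new_draw <- c(TRUE, stats::runif(n - 1) >= rho)
  drawn <- sample.int(K, sum(new_draw), replace = TRUE, prob = weights)
  state <- drawn[cumsum(new_draw)]

  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  n_aoi <- nrow(st$aois)
  for (s in seq_len(n_aoi)) {
    idx <- which(state == s)
    if (length(idx)) {
      pt <- emit_in_aoi(as.list(st$aois[s, ]), length(idx))
      x[idx] <- pt[, 1]; y[idx] <- pt[, 2]
    }
  }
  idx <- which(state == n_aoi + 1L)  # elsewhere
  if (length(idx)) {
    pt <- emit_elsewhere(st$aois, attr(st, "monitor"), length(idx))
    x[idx] <- pt[, 1]; y[idx] <- pt[, 2]
  }
  valid <- state != n_aoi + 2L
  data.frame(participant_id = pid, clip_id = st$clip_id,
             t_ms = as.integer(seq.int(0L, by = 20L, length.out = n)),
             x_px = x, y_px = y, valid = valid, stringsAsFactors = FALSE)
}

#' Simulate a synthetic gaze cohort
#'
#' Generates a full cohort - participant table, 50 Hz gaze recordings over the
#' whole stimulus sequence, and the ground truth needed for recovery testing -
#' as a deterministic function of the seed in the configuration.
#'
#' @param stimulus A \code{gf_stimulus}.
#' @param cfg A [sim_config()].
#' @return List of class \code{gf_sim}: \code{cohort} (a \code{gf_cohort}
#'   frame), \code{gaze} (a \code{gf_gaze} frame), and \code{truth} (planted
#'   signal table, degraded participant ids, per-participant dwell-weight
#'   list, and the config).
#' @examples
#' \donttest{
#' sim <- simulate_cohort(gf_stimulus(),
#'                        sim_config(n_asd = 3, n_td = 3,
#'                                   n_second_control = 0, seed = 1))
#' table(sim$cohort$group)
#' }
#' @export
simulate_cohort <- function(stimulus, cfg = sim_config()) {
  stopifnot(inherits(stimulus, "gf_stimulus"), inherits(cfg, "gf_simconfig"))
  states <- clip_states(stimulus, cfg)
  for (i in seq_along(states)) attr(states[[i]], "monitor") <- stimulus$monitor
  n_samples <- clip_sample_counts(stimulus)

  n_total <- cfg$n_asd + cfg$n_td + cfg$n_second_control
  if (n_total < 1L) stop_gf("sim config: empty cohort")

  with_seed(cfg$seed, {
    group <- rep(c("ASD", "TD", "second_control"),
                 c(cfg$n_asd, cfg$n_td, cfg$n_second_control))
    ids <- sprintf("s%03d", seq_len(n_total))
    age <- stats::runif(n_total, cfg$age_range[1], cfg$age_range[2])
    asd_label <- ifelse(group == "ASD", 1L, ifelse(group == "TD", 0L, NA))
    sc <- which(group == "second_control")
    asd_label[sc] <- stats::rbinom(length(sc), 1L, cfg$sc_asd_rate)
    degraded <- stats::runif(n_total) < cfg$low_fixation_fraction

    cohort <- as_cohort(data.frame(
      participant_id = ids, age_years = age, group = group,
      asd_label = as.integer(asd_label), stringsAsFactors = FALSE))

    gaze_parts <- vector("list", n_total * length(states))
    propensities <- vector("list", n_total); names(propensities) <- ids
    for (i in seq_len(n_total)) {
      asd_like <- !is.na(asd_label[i]) && asd_label[i] == 1L
      band <- age_band(age[i])
      conc <- if (group[i] == "second_control") cfg$sc_concentration else cfg$concentration
      pw <- vector("list", length(states))
      for (ci in seq_along(states)) {
        st <- states[[ci]]
        g <- stats::rgamma(length(st$base), shape = conc * st$base)
        w <- g / sum(g)
        if (asd_like) {
          mult <- exp(c(st$shift[, band], 0, 0))
          w <- w * mult / sum(w * mult)
        }
        if (degraded[i]) {
          w_rest <- w[-length(w)]
          w <- c(w_rest * (1 - cfg$low_fixation_offscreen) / sum(w_rest),
                 cfg$low_fixation_offscreen)
        }
        names(w) <- c(st$aois$aoi_id, "elsewhere", "offscreen")
        pw[[ci]] <- w
        gaze_parts[[(i - 1) * length(states) + ci]] <-
          simulate_clip(ids[i], st, w, n_samples[[st$clip_id]], cfg$rho)
      }
      names(pw) <- vapply(states, `[[`, "", "clip_id")
      propensities[[i]] <- pw
    }
    gaze <- do.call(rbind, gaze_parts)
    ord <- order(gaze$participant_id,
                 match(gaze$clip_id, stimulus$clips$clip_id), gaze$t_ms)
    gaze <- gaze[ord, , drop = FALSE]
    rownames(gaze) <- NULL
    class(gaze) <- c("gf_gaze", "data.frame")

    structure(list(cohort = cohort, gaze = gaze,
                   truth = list(signal_aois = cfg$signal_aois,
                                degraded = ids[degraded],
                                propensities = propensities, config = cfg)),
              class = "gf_sim")
  })
}

#' Simulate one participant with degraded tracking
#'
#' Generates a single recording whose off-screen weight equals the
#' configuration's degraded level, so its overall fixation percentage falls
#' below the 70 percent reliability floor. Used to exercise the low-fixation
#' flag path of [predict.bestfit()].
#'
#' @param stimulus A \code{gf_stimulus}.
#' @param cfg A [sim_config()].
#' @param participant_id Id for the simulated participant.
#' @param age Age in years.
#' @param asd_like Simulate from the ASD gaze model.
#' @return A \code{gf_gaze} data frame for one participant.
#' @export
simulate_degraded <- function(stimulus, cfg = sim_config(), participant_id = "deg001",
                              age = 8, asd_like = TRUE) {
  cfg2 <- cfg
  cfg2$n_asd <- if (asd_like) 1L else 0L
  cfg2$n_td <- if (asd_like) 0L else 1L
  cfg2$n_second_control <- 0L
  cfg2$low_fixation_fraction <- 1
  cfg2$age_range <- c(age, age)
  sim <- simulate_cohort(stimulus, cfg2)
  gaze <- sim$gaze
  gaze$participant_id <- participant_id
  gaze
}

#' Realised per-AOI effect sizes of a simulated cohort
#'
#' Cohen's d (ASD minus TD, pooled SD) of the full-window rate score of every
#' AOI, over the cohort's ASD and TD groups. This is the empirical
#' delta-to-d map used to calibrate the planted dwell-logit shifts: recovery
#' tests quote realised, not nominal, effects.
#'
#' @param gaze A \code{gf_gaze} frame (e.g. from [simulate_cohort()]).
#' @param cohort The matching cohort frame.
#' @param stimulus The \code{gf_stimulus}.
#' @param attr_mat Optional pre-computed \code{gf_attributes} (skips
#'   re-scoring).
#' @return Data frame: \code{aoi_id}, \code{d}, \code{mean_asd},
#'   \code{mean_td}, ordered by decreasing |d|.
#' @export
realized_effects <- function(gaze, cohort, stimulus, attr_mat = NULL) {
  if (is.null(attr_mat)) attr_mat <- build_attribute_matrix(gaze, stimulus)
  rows <- cohort[cohort$group %in% c("ASD", "TD") & !is.na(cohort$asd_label), ,
                 drop = FALSE]
  rows <- rows[rows$participant_id %in% rownames(attr_mat$values), , drop = FALSE]
  is_asd <- rows$asd_label == 1
  aoi_ids <- sort(unique(stimulus$aois$aoi_id))
  cols <- paste0(aoi_ids, ".rate_full")
  vals <- attr_mat$values[rows$participant_id, cols, drop = FALSE]
  cmp <- compare_columns(vals, is_asd, rep("rate", length(cols)))
  out <- data.frame(aoi_id = aoi_ids, d = unname(cmp$d),
                    mean_asd = unname(cmp$mean_asd),
                    mean_td = unname(cmp$mean_td), stringsAsFactors = FALSE)
  out[order(-abs(out$d)), ]
}
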