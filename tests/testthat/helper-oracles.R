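# Test helpers: a small in-code stimulus, gaze builders, and independent
# naive-loop oracles for every score and evaluation statistic.

# A 2-clip stimulus written to a temp YAML and loaded through the real
# parser. tiny_big contains both tiny_circle and tiny_rect (for containment
# properties); both clips are at least 2 s so all three rate windows exist.
tiny_stimulus <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    cfg <- list(
      monitor = list(width = 1280L, height = 1024L),
      sample_rate_hz = 50L, grabber_s = 2.0,
      clips = list(
        list(id = "clipA", paradigm = "social", duration_s = 3.0, order = 1L,
             aois = list(
               list(id = "tiny_circle", shape = "circle", cx = 100, cy = 100,
                    r = 50, label = "face"),
               list(id = "tiny_rect", shape = "rect", x = 200, y = 200,
                    w = 100, h = 80, label = "eyes"),
               list(id = "tiny_big", shape = "rect", x = 40, y = 40,
                    w = 420, h = 420, label = "human"))),
        list(id = "clipB", paradigm = "preferential", duration_s = 2.5, order = 2L,
             aois = list(
               list(id = "tiny_geo", shape = "circle", cx = 900, cy = 500,
                    r = 120, label = "geometric")))))
    path <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, path)
    cached <<- gf_stimulus(path)
    cached
  }
})

# build a gf_gaze frame directly (arguments recycled to n samples)
make_gaze <- function(pid, clip_id, n, x, y, valid = TRUE) {
  df <- data.frame(participant_id = pid, clip_id = clip_id,
                   t_ms = as.integer(seq.int(0L, by = 20L, length.out = n)),
                   x_px = rep_len(as.numeric(x), n),
                   y_px = rep_len(as.numeric(y), n),
                   valid = rep_len(as.logical(valid), n),
                   stringsAsFactors = FALSE)
  df$x_px[!df$valid] <- NA_real_
  df$y_px[!df$valid] <- NA_real_
  class(df) <- c("gf_gaze", "data.frame")
  df
}

# a random full recording over every clip of a stimulus (partial grid allowed)
random_recording <- function(stim, pid = "r1", p_valid = 0.85, frac = 1) {
  parts <- lapply(seq_len(nrow(stim$clips)), function(ci) {
    n <- max(2L, round(stim$clips$duration_s[ci] * stim$sample_rate * frac))
    make_gaze(pid, stim$clips$clip_id[ci], n,
              x = runif(n, 0, stim$monitor[["width"]] - 1),
              y = runif(n, 0, stim$monitor[["height"]] - 1),
              valid = runif(n) < p_valid)
  })
  out <- do.call(rbind, parts)
  class(out) <- c("gf_gaze", "data.frame")
  out
}

naive_point_in <- function(aoi, x, y) {
  if (is.data.frame(aoi)) aoi <- as.list(aoi)
  if (is.na(x) || is.na(y)) return(FALSE)
  if (aoi$shape == "circle") {
    (x - aoi$cx)^2 + (y - aoi$cy)^2 <= aoi$r^2
  } else {
    x >= aoi$x && x <= aoi$x + aoi$w && y >= aoi$y && y <= aoi$y + aoi$h
  }
}

naive_rate <- function(gaze, aoi, window, stim) {
  if (is.data.frame(aoi)) aoi <- as.list(aoi)
  dur_ms <- stim$clips$duration_s[stim$clips$clip_id == aoi$clip_id] * 1000
  w_ms <- switch(window, full = dur_ms, first_1s = 1000, first_2s = 2000)
  g <- gaze[gaze$clip_id == aoi$clip_id, ]
  hits <- 0
  for (i in seq_len(nrow(g))) {
    if (g$valid[i] && g$t_ms[i] < w_ms && naive_point_in(aoi, g$x_px[i], g$y_px[i])) {
      hits <- hits + 1
    }
  }
  hits * 20 / w_ms
}

naive_count <- function(gaze, aoi, min_run) {
  if (is.data.frame(aoi)) aoi <- as.list(aoi)
  g <- gaze[gaze$clip_id == aoi$clip_id, ]
  g <- g[order(g$t_ms), ]
  run <- 0
  for (i in seq_len(nrow(g))) {
    if (g$valid[i] && naive_point_in(aoi, g$x_px[i], g$y_px[i])) {
      run <- run + 1
      if (run >= min_run) return(1L)
    } else {
      run <- 0
    }
  }
  0L
}

naive_fixation_pct <- function(gaze, stim) {
  expected <- sum(round(stim$clips$duration_s * stim$sample_rate))
  100 * sum(gaze$valid) / expected
}

# exhaustive concordant-pair AUC with ties counted 1/2
naive_auc <- function(scores, labels) {
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# brute-force Youden scan over every candidate threshold (rule: score >= t)
naive_youden <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- NULL
  for (t in thr) {
    sens <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spec <- sum(scores < t & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$J + 1e-12 ||
        (abs(j - best$J) <= 1e-12 && sens > best$sensitivity + 1e-12)) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec, J = j)
    }
  }
  best
}

# a quick labelled cohort frame for constructed attribute matrices
toy_cohort <- function(ids, ages, labels, group = NULL) {
  if (is.null(group)) group <- ifelse(labels == 1, "ASD", "TD")
  df <- data.frame(participant_id = ids, age_years = ages, group = group,
                   asd_label = as.integer(labels), stringsAsFactors = FALSE)
  df$age_band <- age_band(df$age_years)
  df
}

# wrap a values matrix as a gf_attributes object for selection/model tests
as_attr_mat <- function(values, stim, fixation_pct = NULL) {
  specs <- attribute_space(stim)
  stopifnot(identical(colnames(values), specs$attr_id))
  if (is.null(fixation_pct)) {
    fixation_pct <- stats::setNames(rep(95, nrow(values)), rownames(values))
  }
  structure(list(values = values, fixation_pct = fixation_pct, specs = specs,
                 count_min_run = 25L),
            class = "gf_attributes")
}

# fast small simulated cohort + matrix used by several model tests
sim_fixture <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    stim <- gf_stimulus()
    sim <- simulate_cohort(stim, sim_config(n_asd = 14, n_td = 26,
                                            n_second_control = 8,
                                            low_fixation_fraction = 0, seed = 2024))
    m <- build_attribute_matrix(sim$gaze, stim)
    cached <<- list(stim = stim, sim = sim, matrix = m)
    cached
  }
})
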