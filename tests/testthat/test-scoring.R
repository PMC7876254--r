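stim <- tiny_stimulus()
circA <- stim$aois[stim$aois$aoi_id == "tiny_circle", ]
rectA <- stim$aois[stim$aois$aoi_id == "tiny_rect", ]
bigA <- stim$aois[stim$aois$aoi_id == "tiny_big", ]

test_that("rate scores saturate, scale with dwell, and respect windows", {
  # all 150 samples of the 3 s clip inside the AOI -> 1.0
  g <- make_gaze("p1", "clipA", 150, 100, 100)
  expect_equal(aoi_rate_score(g, circA, "full", stim), 1.0)

  # 30 of 150 samples inside, window = full -> 30*20/3000 = 0.2
  g <- make_gaze("p1", "clipA", 150, c(rep(100, 30), rep(600, 120)), 100)
  expect_equal(aoi_rate_score(g, circA, "full", stim), 0.2)

  # first 50 samples (the whole first second) inside -> first_1s saturates
  g <- make_gaze("p1", "clipA", 150, c(rep(100, 50), rep(600, 100)), 100)
  expect_equal(aoi_rate_score(g, circA, "first_1s", stim), 1.0)
  expect_equal(aoi_rate_score(g, circA, "first_2s", stim), 0.5)

  # invalid samples never count as inside
  g <- make_gaze("p1", "clipA", 150, 100, 100, valid = FALSE)
  expect_equal(aoi_rate_score(g, circA, "full", stim), 0)
})

test_that("a window longer than the clip is an error", {
  short_cfg <- list(monitor = list(width = 1280L, height = 1024L),
                    sample_rate_hz = 50L, grabber_s = 2.0,
                    clips = list(list(id = "blip", paradigm = "other",
                                      duration_s = 1.5, order = 1L,
                                      aois = list(list(id = "b1", shape = "circle",
                                                       cx = 100, cy = 100, r = 30,
                                                       label = "other")))))
  p <- tempfile(fileext = ".yaml"); yaml::write_yaml(short_cfg, p)
  short <- gf_stimulus(p)
  g <- make_gaze("p1", "blip", 75, 100, 100)
  expect_equal(aoi_rate_score(g, short$aois[1, ], "first_1s", short), 1)
  expect_error(aoi_rate_score(g, short$aois[1, ], "first_2s", short),
               "longer than clip")
})

test_that("count score detects runs of the required length", {
  g <- make_gaze("p1", "clipA", 10, c(100, rep(600, 9)), 100)
  expect_equal(aoi_count_score(g, circA, min_run = 1), 1)  # single sample
  g <- make_gaze("p1", "clipA", 10, 600, 600)
  expect_equal(aoi_count_score(g, circA, min_run = 1), 0)  # never inside
  # runs of length 3 only -> min_run 5 misses, min_run 3 hits
  xs <- rep(c(100, 100, 100, 600, 600), 4)
  g <- make_gaze("p1", "clipA", 20, xs, 100)
  expect_equal(aoi_count_score(g, circA, min_run = 5), 0)
  expect_equal(aoi_count_score(g, circA, min_run = 3), 1)
  # an invalid sample breaks a run
  g <- make_gaze("p1", "clipA", 6, 100, 100, valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(aoi_count_score(g, circA, min_run = 4), 0)
  expect_equal(aoi_count_score(g, circA, min_run = 3), 1)
})

test_that("overall fixation percentage counts valid samples on the full grid", {
  full <- rbind(make_gaze("p1", "clipA", 150, 100, 100),
                make_gaze("p1", "clipB", 125, 900, 500))
  class(full) <- c("gf_gaze", "data.frame")
  expect_equal(overall_fixation_percentage(full, stim), 100)
  half <- full; half$valid <- rep(c(TRUE, FALSE), length.out = nrow(half))
  expect_equal(overall_fixation_percentage(half, stim), 50, tolerance = 0.01)
  expect_error(overall_fixation_percentage(full[full$clip_id == "clipA", ], stim),
               "missing clip.*clipB")
})

test_that("every score equals its naive per-sample oracle on random recordings", {
  set.seed(71)
  for (i in 1:60) {
    g <- random_recording(stim, p_valid = runif(1, 0.5, 1), frac = runif(1, 0.2, 1))
    for (j in seq_len(nrow(stim$aois))) {
      aoi <- stim$aois[j, ]
      for (w in c("full", "first_1s", "first_2s")) {
        expect_equal(aoi_rate_score(g, aoi, w, stim), naive_rate(g, aoi, w, stim))
      }
      mr <- sample(1:6, 1)
      expect_identical(aoi_count_score(g, aoi, min_run = mr),
                       naive_count(g, aoi, mr))
    }
  }
})

test_that("containment and prefix properties hold on random recordings", {
  set.seed(72)
  for (i in 1:25) {
    g <- random_recording(stim)
    # tiny_circle and tiny_rect both lie inside tiny_big
    for (w in c("full", "first_1s", "first_2s")) {
      expect_lte(aoi_rate_score(g, circA, w, stim),
                 aoi_rate_score(g, bigA, w, stim))
      expect_lte(aoi_rate_score(g, rectA, w, stim),
                 aoi_rate_score(g, bigA, w, stim))
    }
    # early-window scores are prefix functions of the recording
    trunc <- g[g$t_ms < 2000, ]
    class(trunc) <- c("gf_gaze", "data.frame")
    expect_equal(aoi_rate_score(trunc, circA, "first_1s", stim),
                 aoi_rate_score(g, circA, "first_1s", stim))
    expect_equal(aoi_rate_score(trunc, circA, "first_2s", stim),
                 aoi_rate_score(g, circA, "first_2s", stim))
    # with min_run = 1, presence is exactly "any dwell at all"
    expect_equal(aoi_count_score(g, circA, min_run = 1),
                 as.integer(aoi_rate_score(g, circA, "full", stim) > 0))
  }
})

test_that("the attribute matrix matches the scalar scores and is order-invariant", {
  set.seed(73)
  gaze <- do.call(rbind, lapply(sprintf("p%02d", 1:5), function(pid) {
    random_recording(stim, pid = pid)
  }))
  class(gaze) <- c("gf_gaze", "data.frame")
  m <- build_attribute_matrix(gaze, stim, count_min_run = 3)
  expect_equal(dim(m$values), c(5, 4 * nrow(stim$aois)))
  expect_equal(colnames(m$values), attribute_space(stim)$attr_id)

  for (pid in c("p01", "p04")) {
    g <- gaze[gaze$participant_id == pid, ]
    class(g) <- c("gf_gaze", "data.frame")
    for (j in c(1, 2, nrow(stim$aois))) {
      aoi <- stim$aois[stim$aois$aoi_id == sort(stim$aois$aoi_id)[j], ]
      aoi <- stim$aois[stim$aois$aoi_id == aoi$aoi_id, ]
      expect_equal(m$values[pid, paste0(aoi$aoi_id, ".rate_full")],
                   aoi_rate_score(g, aoi, "full", stim), ignore_attr = TRUE)
      expect_equal(m$values[pid, paste0(aoi$aoi_id, ".count")],
                   as.numeric(aoi_count_score(g, aoi, min_run = 3)),
                   ignore_attr = TRUE)
    }
    expect_equal(m$fixation_pct[[pid]], overall_fixation_percentage(g, stim))
  }

  # permuting input row order changes nothing
  perm <- gaze[sample(nrow(gaze)), ]
  class(perm) <- c("gf_gaze", "data.frame")
  m2 <- build_attribute_matrix(perm, stim, count_min_run = 3)
  expect_identical(m$values, m2$values)

  # an all-invalid participant yields a zero row and 0% fixation
  dead <- rbind(make_gaze("pz", "clipA", 150, 1, 1, valid = FALSE),
                make_gaze("pz", "clipB", 125, 1, 1, valid = FALSE))
  both <- rbind(gaze, dead)
  class(both) <- c("gf_gaze", "data.frame")
  m3 <- build_attribute_matrix(both, stim)
  expect_true(all(m3$values["pz", ] == 0))
  expect_equal(m3$fixation_pct[["pz"]], 0)

  # a participant missing a clip is an error naming them
  expect_error(build_attribute_matrix(rbind(gaze, dead[dead$clip_id == "clipA", ]),
                                      stim), "missing clips: pz")
})
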