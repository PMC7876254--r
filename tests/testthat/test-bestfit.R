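test_that("attribute aggregation orients, normalises and averages", {
  cand1 <- structure(data.frame(attr_id = "a.count", aoi_id = "a", kind = "count",
                                d = -1, p = 0.01, orientation = -1),
                     class = c("gf_candidates", "data.frame"))
  sub <- list(family = "count", candidates = cand1)
  v <- matrix(0, 1, 1, dimnames = list("p1", "a.count"))
  expect_equal(aggregate_attributes(sub, v), c(p1 = 1))   # orientation flip

  cand2 <- structure(data.frame(attr_id = c("a.count", "b.count"),
                                aoi_id = c("a", "b"), kind = "count",
                                d = 1, p = 0.01, orientation = 1),
                     class = c("gf_candidates", "data.frame"))
  v2 <- matrix(c(1, 0), 1, 2, dimnames = list("p1", c("a.count", "b.count")))
  expect_equal(aggregate_attributes(list(family = "count", candidates = cand2), v2),
               c(p1 = 0.5))

  # rate: value equal to the training SD standardises to exactly 1
  cand3 <- structure(data.frame(attr_id = "a.rate_full", aoi_id = "a",
                                kind = "rate_full", d = 1, p = 0.01,
                                orientation = 1),
                     class = c("gf_candidates", "data.frame"))
  sub3 <- list(family = "rate", candidates = cand3,
               normalizers = c(a.rate_full = 0.07))
  v3 <- matrix(0.07, 1, 1, dimnames = list("p1", "a.rate_full"))
  expect_equal(aggregate_attributes(sub3, v3), c(p1 = 1))

  # zero training SD: the attribute contributes 0 but stays in the average
  sub4 <- list(family = "rate",
               candidates = structure(rbind(cand3,
                 data.frame(attr_id = "b.rate_full", aoi_id = "b",
                            kind = "rate_full", d = 1, p = 0.01, orientation = 1)),
                 class = c("gf_candidates", "data.frame")),
               normalizers = c(a.rate_full = 0.07, b.rate_full = 0))
  v4 <- matrix(c(0.14, 9), 1, 2,
               dimnames = list("p1", c("a.rate_full", "b.rate_full")))
  expect_equal(aggregate_attributes(sub4, v4), c(p1 = 1))  # mean(2, 0)
})

test_that("fit_sigmoid matches an unconstrained logistic regression oracle", {
  set.seed(301)
  for (i in 1:10) {
    x <- stats::rnorm(80)
    y <- stats::rbinom(80, 1, stats::plogis(1.2 * x - 0.3))
    fit <- fit_sigmoid(x, y)
    ref <- stats::glm(y ~ x, family = stats::binomial())
    ref_loss <- gazedx:::bce(stats::fitted(ref), y)
    if (unname(stats::coef(ref)[2]) >= 0) {
      # oracle is feasible for the constrained problem: losses must agree
      expect_equal(fit$loss, ref_loss, tolerance = 1e-5)
    } else {
      expect_gte(fit$loss + 1e-9, ref_loss)
      expect_lt(fit$a, 0.02)   # constraint active
    }
    # never worse than the null model sigma(0*x + logit(prevalence))
    null_loss <- gazedx:::bce(rep(mean(y), 80), y)
    expect_lte(fit$loss, null_loss + 1e-9)
  }
})

test_that("sigmoid scores separate perfectly separable aggregates", {
  x <- c(1, 2, 3, 11, 12, 13)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_sigmoid(x, y)
  s <- stats::plogis(fit$a * x + fit$b)
  expect_true(all(s[y == 1] > 0.5))
  expect_true(all(s[y == 0] < 0.5))
  expect_error(fit_sigmoid(x, rep(1, 6)), "both classes")
})

test_that("permuted labels give a near-flat sigmoid at the class prevalence", {
  set.seed(302)
  for (i in 1:5) {
    x <- stats::rnorm(100)
    y <- sample(rep(c(1, 0), c(30, 70)))   # independent of x by construction
    fit <- fit_sigmoid(x, y)
    s <- stats::plogis(fit$a * x + fit$b)
    ref <- stats::glm(y ~ x, family = stats::binomial())
    expect_equal(mean(s), 0.3, tolerance = 0.05)
    if (unname(stats::coef(ref)[2]) >= 0) {
      # chance correlation is positive: constrained fit equals the glm oracle
      expect_equal(fit$loss, gazedx:::bce(stats::fitted(ref), y), tolerance = 1e-5)
    } else {
      # chance correlation is negative: the slope constraint clamps to flat
      expect_lt(fit$a, 0.05)
    }
    # never steeper than the unconstrained oracle's spread
    expect_lte(stats::sd(s), stats::sd(stats::fitted(ref)) + 0.02)
  }
})

test_that("the fitted construction has four sub-algorithms and is deterministic", {
  fx <- sim_fixture()
  fit <- bestfit(fx$matrix, fx$sim$cohort)
  expect_s3_class(fit, "bestfit")
  expect_length(fit$subalgorithms, 4)
  bands <- vapply(fit$subalgorithms, `[[`, "", "band")
  fams <- vapply(fit$subalgorithms, `[[`, "", "family")
  expect_equal(sort(paste(fams, bands)),
               sort(c("rate younger", "rate older", "count younger", "count older")))
  expect_true(all(vapply(fit$subalgorithms, function(s) s$sigmoid$a, 1) >= 0))
  expect_true(all(fit$modality %in% c("rate", "count")))
  # training scores strictly inside (0,1)
  expect_true(all(fit$training$scores > 0 & fit$training$scores < 1))
  # second-control participants are not in the training set
  sc <- fx$sim$cohort$participant_id[fx$sim$cohort$group == "second_control"]
  expect_length(intersect(fit$training$ids, sc), 0)

  # refitting on identical inputs is bit-identical (model file level)
  fit2 <- bestfit(fx$matrix, fx$sim$cohort)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_bestfit(fit, f1); write_bestfit(fit2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("merging bands is at least as good as the hard band split oracle", {
  fx <- sim_fixture()
  fit <- bestfit(fx$matrix, fx$sim$cohort)
  train <- fx$sim$cohort[fx$sim$cohort$group %in% c("ASD", "TD"), ]
  vals <- fx$matrix$values[train$participant_id, ]
  for (merged in list(fit$rate_merged, fit$count_merged)) {
    s_y <- gazedx:::subalgo_score(merged$young, vals)
    s_o <- gazedx:::subalgo_score(merged$old, vals)
    s_merged <- gazedx:::merged_score(merged, vals, train$age_years)
    # fixed-weight oracle: w = 1{age < 10}
    s_hard <- ifelse(train$age_years < 10, s_y, s_o)
    expect_gte(auc(s_merged, train$asd_label),
               auc(s_hard, train$asd_label) - 0.02)
  }
})

test_that("the age blend is continuous in age and respects its limits", {
  blend <- list(A = 10, B = -5, k = 8, a0 = 10)
  s_y <- 0.9; s_o <- 0.2
  # far below / above the centre, the blend hands over to one band
  expect_equal(gazedx:::age_blend_score(blend, s_y, s_o, 5),
               stats::plogis(10 * 0.9 - 5), tolerance = 1e-4)
  expect_equal(gazedx:::age_blend_score(blend, s_y, s_o, 17),
               stats::plogis(10 * 0.2 - 5), tolerance = 1e-4)
  # continuity across a fine age grid, including the 10-year boundary
  ages <- seq(5, 17, by = 0.001)
  s <- gazedx:::age_blend_score(blend, s_y, s_o, ages)
  expect_lt(max(abs(diff(s))), 0.01)

  fx <- sim_fixture()
  fit <- bestfit(fx$matrix, fx$sim$cohort)
  row <- fx$matrix$values[fit$training$ids[1], , drop = FALSE]
  s10 <- gazedx:::bestfit_score(fit, row, 10 - 1e-9)
  s10b <- gazedx:::bestfit_score(fit, row, 10 + 1e-9)
  expect_equal(s10, s10b, tolerance = 1e-6)
})

test_that("modality selection picks the higher within-band AUC, ties to rate", {
  fx <- sim_fixture()
  fit <- bestfit(fx$matrix, fx$sim$cohort)
  aucs <- attr(fit$modality, "auc")
  for (band in c("younger", "older")) {
    expected <- if (aucs[band, "count"] > aucs[band, "rate"]) "count" else "rate"
    expect_equal(unname(fit$modality[band]), expected)
  }
})

test_that("increasing an ASD-oriented active attribute never lowers the score", {
  fx <- sim_fixture()
  fit <- bestfit(fx$matrix, fx$sim$cohort)
  fam <- fit$modality[["younger"]]
  sub <- fit$subalgorithms[[paste0(fam, "_younger")]]
  cand <- sub$candidates[1, ]
  row <- fx$matrix$values[fit$training$ids[1], , drop = FALSE]
  grid <- if (cand$orientation > 0) seq(0, 1, by = 0.1) else seq(1, 0, by = -0.1)
  scores <- vapply(grid, function(v) {
    r <- row; r[, cand$attr_id] <- v
    gazedx:::bestfit_score(fit, r, age = 7)
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("prediction applies the inclusive 0.5 call and the fixation flag", {
  fx <- sim_fixture()
  fit <- bestfit(fx$matrix, fx$sim$cohort)
  pred <- predict(fit, fx$matrix, fx$sim$cohort)
  expect_identical(pred$label, as.integer(pred$score >= 0.5))
  expect_false(any(pred$low_fixation))   # clean cohort

  # a degraded recording is scored but flagged unreliable
  deg <- simulate_degraded(fx$stim, sim_config(seed = 5), participant_id = "deg01",
                           age = 8)
  m2 <- build_attribute_matrix(deg, fx$stim)
  expect_lt(m2$fixation_pct[["deg01"]], 70)
  cohort2 <- data.frame(participant_id = "deg01", age_years = 8,
                        group = "unknown", asd_label = NA)
  p2 <- predict(fit, m2, cohort2)
  expect_true(p2$low_fixation)
  expect_true(p2$score > 0 && p2$score < 1)
})

test_that("models survive a JSON round trip with identical predictions", {
  fx <- sim_fixture()
  fit <- bestfit(fx$matrix, fx$sim$cohort)
  path <- tempfile(fileext = ".json")
  write_bestfit(fit, path)
  back <- read_bestfit(path)
  ids <- fit$training$ids
  p1 <- gazedx:::bestfit_score(fit, fx$matrix$values[ids, ],
                               fx$sim$cohort$age_years[match(ids, fx$sim$cohort$participant_id)])
  p2 <- gazedx:::bestfit_score(back, fx$matrix$values[ids, ],
                               fx$sim$cohort$age_years[match(ids, fx$sim$cohort$participant_id)])
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(back$modality, fit$modality, ignore_attr = TRUE)
})
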