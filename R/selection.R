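# Candidate-attribute extraction: per age band and score family, keep
# attributes whose ASD/TD contrast is significant (p < 0.05) OR has
# |Cohen's d| >= 0.5, drop attributes on AOIs with a pooled gaze fixation
# percentage below 20, and keep only the largest-|d| attribute per AOI.

#' Cohen's d (pooled-SD standardised mean difference)
#'
#' \code{(mean(a) - mean(b)) / s_p} with the pooled standard deviation
#' \code{s_p = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))}.
#' When the pooled SD is zero the effect is degenerate: the result is
#' \code{Inf * sign(mean difference)} if the means differ, or \code{NA} (with
#' attribute \code{degenerate = TRUE}) if the samples are constant and equal.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return A number; possibly \code{NA} with attribute \code{degenerate}.
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))   # -2
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop_gf("cohens_d: need >= 2 values per group")
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  diff <- mean(a) - mean(b)
  if (sp == 0) {
    if (diff == 0) return(structure(NA_real_, degenerate = TRUE))
    return(Inf * sign(diff))
  }
  diff / sp
}

# Vectorised group comparison over the columns of a values matrix.
# Returns d, p, mean_asd, mean_td for each column. Rate attributes use
# Welch's t-test (or Mann-Whitney with test = "wilcox"); binary count
# attributes use Fisher's exact test.
compare_columns <- function(values, is_asd, family, test = c("welch", "wilcox")) {
  test <- match.arg(test)
  a <- values[is_asd, , drop = FALSE]
  b <- values[!is_asd, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 2L || nb < 2L) stop_gf("group comparison: need >= 2 participants per group")
  m1 <- colMeans(a); m0 <- colMeans(b)
  v1 <- apply(a, 2L, stats::var); v0 <- apply(b, 2L, stats::var)
  sp <- sqrt(((na - 1) * v1 + (nb - 1) * v0) / (na + nb - 2))
  d <- ifelse(sp > 0, (m1 - m0) / sp,
              ifelse(m1 != m0, Inf * sign(m1 - m0), NA_real_))

  p <- rep(NA_real_, ncol(values))
  is_count <- family == "count"
  if (any(!is_count)) {
    idx <- which(!is_count)
    if (test == "welch") {
      se2 <- v1[idx] / na + v0[idx] / nb
      tt <- (m1[idx] - m0[idx]) / sqrt(se2)
      dfree <- se2^2 / ((v1[idx] / na)^2 / (na - 1) + (v0[idx] / nb)^2 / (nb - 1))
      p[idx] <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), dfree), NA_real_)
    } else {
      p[idx] <- vapply(idx, function(j) {
        if (sp[j] == 0 && m1[j] == m0[j]) return(NA_real_)
        stats::wilcox.test(a[, j], b[, j], exact = FALSE)$p.value
      }, numeric(1))
    }
  }
  if (any(is_count)) {
    idx <- which(is_count)
    p[idx] <- vapply(idx, function(j) {
      tab <- table(factor(values[, j], levels = 0:1),
                   factor(is_asd, levels = c(FALSE, TRUE)))
      stats::fisher.test(tab)$p.value
    }, numeric(1))
  }
  list(d = d, p = p, mean_asd = m1, mean_td = m0)
}

#' Compare one attribute between the ASD and TD groups
#'
#' Computes Cohen's d (ASD minus TD, pooled SD) and a two-sided p-value for a
#' single attribute over the given participants: Welch's t-test for rate
#' attributes (optionally the Mann-Whitney test), Fisher's exact test for
#' binary count attributes. Also reports the AOI's pooled gaze fixation
#' percentage (the ASD+TD mean of 100 x the full-window rate score), the
#' quantity governing the 20 percent exclusion rule.
#'
#' @param attr_mat A \code{gf_attributes} object.
#' @param cohort A cohort data frame whose \code{asd_label} supplies the
#'   groups; only rows with non-missing labels are used.
#' @param attr_id One attribute id.
#' @param test \code{"welch"} or \code{"wilcox"} for rate attributes.
#' @return A one-row data frame: \code{attr_id}, \code{aoi_id}, \code{kind},
#'   \code{d}, \code{p}, \code{mean_asd}, \code{mean_td},
#'   \code{fixation_pct}.
#' @export
group_compare <- function(attr_mat, cohort, attr_id, test = c("welch", "wilcox")) {
  stopifnot(inherits(attr_mat, "gf_attributes"))
  spec <- attr_mat$specs[attr_mat$specs$attr_id == attr_id, ]
  if (!nrow(spec)) stop_gf("unknown attribute: ", attr_id)
  rows <- labelled_training_rows(cohort, attr_mat$values)
  keep <- rows$participant_id
  is_asd <- rows$asd_label == 1
  vals <- attr_mat$values[keep, attr_id, drop = FALSE]
  cmp <- compare_columns(vals, is_asd, spec$family, test = match.arg(test))
  fix_col <- paste0(spec$aoi_id, ".rate_full")
  data.frame(attr_id = attr_id, aoi_id = spec$aoi_id, kind = spec$kind,
             d = unname(cmp$d), p = unname(cmp$p),
             mean_asd = unname(cmp$mean_asd), mean_td = unname(cmp$mean_td),
             fixation_pct = 100 * mean(attr_mat$values[keep, fix_col]),
             stringsAsFactors = FALSE)
}

#' Extract candidate attributes for one age band and score family
#'
#' Within the band's labelled (ASD/TD) training participants, an attribute of
#' the requested family becomes a candidate when its group contrast is
#' significant (\code{p < alpha}) \emph{or} its effect size satisfies
#' \code{|d| >= d_threshold}. Attributes on AOIs whose pooled gaze fixation
#' percentage is below \code{fixation_threshold} are dropped (guarding against
#' chance findings on rarely-viewed regions), and within each AOI only the
#' attribute with the largest \code{|d|} is kept - this also collapses the
#' three rate windows sharing one AOI. Each candidate carries an orientation,
#' \code{sign(d)}, so that oriented attribute values are always ASD-high.
#'
#' Ties on \code{|d|} within an AOI are broken deterministically: window
#' preference \code{rate_full} > \code{rate_1s} > \code{rate_2s} >
#' \code{count}, then lexical attribute id.
#'
#' @param attr_mat A \code{gf_attributes} object.
#' @param cohort Cohort data frame; rows with non-missing \code{asd_label}
#'   and \code{age_band == band} form the training set for this call.
#' @param band \code{"younger"} or \code{"older"}.
#' @param family \code{"rate"} or \code{"count"}.
#' @param alpha Significance level (default 0.05).
#' @param d_threshold Effect-size threshold (default 0.5).
#' @param fixation_threshold Minimum pooled AOI fixation percentage
#'   (default 20).
#' @param test Test for rate attributes, \code{"welch"} or \code{"wilcox"}.
#' @return An object of class \code{gf_candidates}: a data frame of selected
#'   attributes (\code{attr_id}, \code{aoi_id}, \code{kind}, \code{d},
#'   \code{p}, \code{orientation}, \code{mean_asd}, \code{mean_td},
#'   \code{fixation_pct}) with attributes \code{band} and \code{family}.
#'   Empty selections are valid (with a warning).
#' @export
select_candidates <- function(attr_mat, cohort, band = c("younger", "older"),
                              family = c("rate", "count"), alpha = 0.05,
                              d_threshold = 0.5, fixation_threshold = 20,
                              test = c("welch", "wilcox")) {
  stopifnot(inherits(attr_mat, "gf_attributes"))
  band <- match.arg(band); family <- match.arg(family); test <- match.arg(test)

  rows <- labelled_training_rows(cohort, attr_mat$values)
  rows <- rows[rows$age_band == band, , drop = FALSE]
  is_asd <- rows$asd_label == 1
  if (sum(is_asd) < 2L || sum(!is_asd) < 2L) {
    stop_gf("select_candidates(", band, ", ", family,
            "): need >= 2 participants per group in the band")
  }

  specs <- attr_mat$specs[attr_mat$specs$family == family, , drop = FALSE]
  vals <- attr_mat$values[rows$participant_id, specs$attr_id, drop = FALSE]
  cmp <- compare_columns(vals, is_asd, specs$family, test = test)

  # pooled fixation percentage per AOI over the band's ASD+TD training rows
  fix_cols <- paste0(unique(specs$aoi_id), ".rate_full")
  aoi_fix <- 100 * colMeans(attr_mat$values[rows$participant_id, fix_cols, drop = FALSE])
  names(aoi_fix) <- unique(specs$aoi_id)

  res <- data.frame(attr_id = specs$attr_id, aoi_id = specs$aoi_id,
                    kind = specs$kind, d = unname(cmp$d), p = unname(cmp$p),
                    mean_asd = unname(cmp$mean_asd), mean_td = unname(cmp$mean_td),
                    fixation_pct = unname(aoi_fix[specs$aoi_id]),
                    stringsAsFactors = FALSE)

  pass_p <- !is.na(res$p) & res$p < alpha
  pass_d <- !is.na(res$d) & abs(res$d) >= d_threshold
  res <- res[(pass_p | pass_d) & res$fixation_pct >= fixation_threshold, , drop = FALSE]
  res <- res[!is.na(res$d) & res$d != 0, , drop = FALSE]  # orientation requires sign(d)

  if (nrow(res)) {
    kind_pref <- match(res$kind, c("rate_full", "rate_1s", "rate_2s", "count"))
    res <- res[order(res$aoi_id, -abs(res$d), kind_pref, res$attr_id), , drop = FALSE]
    res <- res[!duplicated(res$aoi_id), , drop = FALSE]
    res$orientation <- sign(res$d)
  } else {
    res$orientation <- numeric(0)
    warning("select_candidates(", band, ", ", family, "): empty candidate set")
  }
  rownames(res) <- NULL
  structure(res, band = band, family = family,
            class = c("gf_candidates", "data.frame"))
}
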