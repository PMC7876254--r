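#' Read a gaze recording table
#'
#' Reads 50 Hz gaze recordings from CSV. The file must have columns
#' \code{participant_id}, \code{clip_id}, \code{t_ms} (integer milliseconds
#' from clip onset, on a nominal 20 ms grid), \code{x_px}, \code{y_px}, and
#' \code{valid} (0/1 or logical; an invalid sample means the eye was not
#' detected or gaze was off-screen, and its coordinates may be blank).
#' Rows are validated against the stimulus schema: unknown clip ids are
#' rejected, timestamps must be strictly increasing within each participant and
#' clip and smaller than the clip duration, and valid samples must lie on the
#' monitor. Invalid samples are retained (with \code{valid = FALSE}) so that
#' the 50 Hz sample grid - the denominator of every rate score - is preserved.
#'
#' @param path CSV file path.
#' @param stimulus A \code{gf_stimulus} object the recordings refer to.
#' @return A data frame of class \code{gf_gaze}, ordered by participant, clip
#'   presentation order, and time.
#' @seealso [write_gaze_table()], [build_attribute_matrix()]
#' @export
read_gaze_table <- function(path, stimulus) {
  stopifnot(inherits(stimulus, "gf_stimulus"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("participant_id", "clip_id", "t_ms", "x_px", "y_px", "valid"),
              "gaze table")
  df$participant_id <- as.character(df$participant_id)
  df$clip_id <- as.character(df$clip_id)
  df$t_ms <- as.integer(df$t_ms)
  df$x_px <- as.numeric(df$x_px)
  df$y_px <- as.numeric(df$y_px)
  v <- df$valid
  if (is.character(v)) v <- utils::type.convert(v, as.is = TRUE)
  if (is.numeric(v)) v <- v == 1
  df$valid <- as.logical(v)
  if (nrow(df) == 0L) {
    class(df) <- c("gf_gaze", "data.frame")
    return(df)
  }

  unknown <- setdiff(unique(df$clip_id), stimulus$clips$clip_id)
  if (length(unknown)) stop_gf("gaze table: unknown clip id(s): ", paste(unknown, collapse = ", "))
  if (anyNA(df$t_ms) || any(df$t_ms < 0)) stop_gf("gaze table: t_ms must be non-negative integers")
  if (anyNA(df$valid)) stop_gf("gaze table: 'valid' must be 0/1")

  w <- stimulus$monitor[["width"]]; h <- stimulus$monitor[["height"]]
  bad <- df$valid & (is.na(df$x_px) | is.na(df$y_px) |
                     df$x_px < 0 | df$x_px >= w | df$y_px < 0 | df$y_px >= h)
  if (any(bad)) {
    stop_gf("gaze table: valid sample off the monitor at row(s) ",
            paste(utils::head(which(bad), 5L), collapse = ", "))
  }

  dur_ms <- stimulus$clips$duration_s[match(df$clip_id, stimulus$clips$clip_id)] * 1000
  over <- df$t_ms >= dur_ms
  if (any(over)) {
    i <- which(over)[1L]
    stop_gf("gaze table: timestamp ", df$t_ms[i], " ms exceeds clip '",
            df$clip_id[i], "' duration (participant ", df$participant_id[i], ")")
  }

  grp <- paste(df$participant_id, df$clip_id, sep = "\r")
  nonmono <- c(FALSE, diff(df$t_ms) <= 0 & grp[-1L] == grp[-nrow(df)])
  if (any(nonmono)) {
    i <- which(nonmono)[1L]
    stop_gf("gaze table: non-monotone timestamps for participant '",
            df$participant_id[i], "', clip '", df$clip_id[i], "'")
  }

  ord <- order(df$participant_id,
               match(df$clip_id, stimulus$clips$clip_id), df$t_ms)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gf_gaze", "data.frame")
  df
}

#' Write a gaze recording table
#'
#' Writes recordings in the CSV dialect read by [read_gaze_table()]. Invalid
#' samples are written with blank coordinates; \code{valid} is written as 0/1.
#' A written file read back reproduces the recording exactly (integer
#' timestamps, coordinates as written).
#'
#' @param gaze A \code{gf_gaze} data frame (or compatible data frame).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_gaze_table <- function(gaze, path) {
  out <- data.frame(
    participant_id = gaze$participant_id,
    clip_id = gaze$clip_id,
    t_ms = as.integer(gaze$t_ms),
    x_px = ifelse(gaze$valid, gaze$x_px, NA_real_),
    y_px = ifelse(gaze$valid, gaze$y_px, NA_real_),
    valid = as.integer(gaze$valid))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table
#'
#' Reads participant metadata from CSV with columns \code{participant_id},
#' \code{age_years} (decimal), \code{group} (\code{ASD}, \code{TD},
#' \code{second_control} or \code{unknown}) and \code{asd_label} (0/1 confirmed
#' diagnosis, the supervised target; may be blank for unknowns). Participants
#' must be aged 5-17 years (the protocol's range) unless \code{permissive} is
#' set. An \code{age_band} column is added: \code{younger} for age < 10 years,
#' \code{older} for age >= 10 (10.0 falls in the older band).
#'
#' @param path CSV file path.
#' @param permissive Allow ages outside `[5, 17]`.
#' @return A data frame of class \code{gf_cohort}.
#' @export
read_cohort_table <- function(path, permissive = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("participant_id", "age_years", "group", "asd_label"), "cohort table")
  df$participant_id <- as.character(df$participant_id)
  df$age_years <- as.numeric(df$age_years)
  df$asd_label <- as.integer(df$asd_label)
  as_cohort(df, permissive = permissive)
}

# validate a cohort data frame and add the age_band column
as_cohort <- function(df, permissive = FALSE) {
  if (anyDuplicated(df$participant_id)) {
    stop_gf("cohort table: duplicate participant id(s): ",
            paste(unique(df$participant_id[duplicated(df$participant_id)]), collapse = ", "))
  }
  bad_group <- setdiff(unique(df$group), c("ASD", "TD", "second_control", "unknown"))
  if (length(bad_group)) stop_gf("cohort table: unknown group(s): ", paste(bad_group, collapse = ", "))
  if (anyNA(df$age_years)) stop_gf("cohort table: missing age_years")
  if (!permissive && any(df$age_years < 5 | df$age_years > 17)) {
    stop_gf("cohort table: age_years outside [5, 17] (use permissive = TRUE to allow)")
  }
  if (any(!is.na(df$asd_label) & !df$asd_label %in% 0:1)) {
    stop_gf("cohort table: asd_label must be 0, 1 or blank")
  }
  df$age_band <- age_band(df$age_years)
  rownames(df) <- NULL
  class(df) <- unique(c("gf_cohort", class(df)))
  df
}

#' Write a cohort table
#' @param cohort A cohort data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(
    cohort[, c("participant_id", "age_years", "group", "asd_label")],
    path, row.names = FALSE, na = "")
  invisible(path)
}

#' Age band of a participant
#'
#' The cohort is split at 10 years (the training cohort's median age):
#' \code{younger} is age < 10.0, \code{older} is age >= 10.0. Ages are decimal
#' years, not truncated integers.
#'
#' @param age_years Numeric vector of ages.
#' @return Character vector, \code{"younger"} or \code{"older"}.
#' @examples
#' age_band(c(9.9, 10, 10.1))
#' @export
age_band <- function(age_years) {
  ifelse(age_years < 10, "younger", "older")
}
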