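#' Load a stimulus configuration
#'
#' Reads a YAML description of the stimulus sequence: the monitor, the sampling
#' rate, the attention-grabber duration, and the ordered list of movie clips
#' with their areas of interest (AOIs). The packaged default describes the
#' 12-clip sequence used by the Gazefinder-style protocol (3 social clips,
#' 9 preferential clips) carrying 100 AOIs in total. AOI geometry in the
#' packaged file is plausible stand-in geometry - the device's real AOI shapes
#' are unpublished - and can be replaced by pointing \code{path} at a custom
#' configuration with the same schema.
#'
#' The schema is: top-level keys \code{monitor} (\code{width}, \code{height},
#' pixels), \code{sample_rate_hz}, \code{grabber_s}, and \code{clips}, a list of
#' \code{id}, \code{paradigm} (\code{social}/\code{preferential}/\code{other}),
#' \code{duration_s}, \code{order}, and \code{aois}. Each AOI has \code{id},
#' \code{shape} (\code{circle}: \code{cx}, \code{cy}, \code{r}; \code{rect}:
#' \code{x}, \code{y}, \code{w}, \code{h}), and a semantic \code{label} among
#' \code{eyes}, \code{face}, \code{human}, \code{geometric}, \code{object},
#' \code{other}. Coordinates are pixels with the origin at the monitor's
#' top-left corner, x rightward, y downward. AOIs may overlap (an eye region
#' typically lies inside a face region).
#'
#' @param path Path to a YAML stimulus configuration. \code{NULL} (default)
#'   loads the packaged fixture.
#' @return An object of class \code{gf_stimulus}: a list with \code{monitor}
#'   (named width/height vector), \code{sample_rate}, \code{grabber_s},
#'   \code{clips} (data frame: \code{clip_id}, \code{paradigm},
#'   \code{duration_s}, \code{order}, \code{n_aois}, ordered by presentation
#'   order) and \code{aois} (data frame of AOI geometry).
#' @examples
#' stim <- gf_stimulus()
#' nrow(stim$clips)   # 12
#' nrow(stim$aois)    # 100
#' @export
gf_stimulus <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gazefinder_stimulus.yaml",
                        package = "gazedx", mustWork = TRUE)
  }
  if (!file.exists(path)) stop_gf("stimulus config not found: ", path)
  raw <- yaml::read_yaml(path)

  for (key in c("monitor", "sample_rate_hz", "grabber_s", "clips")) {
    if (is.null(raw[[key]])) stop_gf("stimulus config: missing field '", key, "'")
  }
  mon <- raw$monitor
  if (is.null(mon$width) || is.null(mon$height)) {
    stop_gf("stimulus config: 'monitor' must have 'width' and 'height'")
  }
  width <- as.numeric(mon$width); height <- as.numeric(mon$height)
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0) {
    stop_gf("stimulus config: monitor dimensions must be positive")
  }

  clip_rows <- list(); aoi_rows <- list()
  for (cl in raw$clips) {
    for (key in c("id", "paradigm", "duration_s", "order", "aois")) {
      if (is.null(cl[[key]])) stop_gf("stimulus config: clip missing field '", key, "'")
    }
    if (!cl$paradigm %in% c("social", "preferential", "other")) {
      stop_gf("stimulus config: clip '", cl$id, "': unknown paradigm '", cl$paradigm, "'")
    }
    if (as.numeric(cl$duration_s) <= 0) {
      stop_gf("stimulus config: clip '", cl$id, "': duration_s must be > 0")
    }
    clip_rows[[length(clip_rows) + 1L]] <- data.frame(
      clip_id = as.character(cl$id), paradigm = cl$paradigm,
      duration_s = as.numeric(cl$duration_s), order = as.integer(cl$order),
      n_aois = length(cl$aois), stringsAsFactors = FALSE)
    for (a in cl$aois) {
      if (is.null(a$id) || is.null(a$shape) || is.null(a$label)) {
        stop_gf("stimulus config: clip '", cl$id, "': AOI missing 'id', 'shape' or 'label'")
      }
      if (!a$label %in% c("eyes", "face", "human", "geometric", "object", "other")) {
        stop_gf("stimulus config: AOI '", a$id, "': unknown label '", a$label, "'")
      }
      row <- data.frame(aoi_id = as.character(a$id), clip_id = as.character(cl$id),
                        shape = a$shape, cx = NA_real_, cy = NA_real_, r = NA_real_,
                        x = NA_real_, y = NA_real_, w = NA_real_, h = NA_real_,
                        label = a$label, stringsAsFactors = FALSE)
      if (identical(a$shape, "circle")) {
        for (key in c("cx", "cy", "r")) {
          if (is.null(a[[key]])) stop_gf("stimulus config: circle AOI '", a$id, "': missing '", key, "'")
        }
        row$cx <- as.numeric(a$cx); row$cy <- as.numeric(a$cy); row$r <- as.numeric(a$r)
        if (row$r <= 0) stop_gf("stimulus config: AOI '", a$id, "': radius must be > 0")
        if (row$cx - row$r < 0 || row$cx + row$r > width ||
            row$cy - row$r < 0 || row$cy + row$r > height) {
          stop_gf("stimulus config: AOI '", a$id, "' lies outside the ",
                  width, " x ", height, " monitor")
        }
      } else if (identical(a$shape, "rect")) {
        for (key in c("x", "y", "w", "h")) {
          if (is.null(a[[key]])) stop_gf("stimulus config: rect AOI '", a$id, "': missing '", key, "'")
        }
        row$x <- as.numeric(a$x); row$y <- as.numeric(a$y)
        row$w <- as.numeric(a$w); row$h <- as.numeric(a$h)
        if (row$w <= 0 || row$h <= 0) stop_gf("stimulus config: AOI '", a$id, "': width/height must be > 0")
        if (row$x < 0 || row$y < 0 || row$x + row$w > width || row$y + row$h > height) {
          stop_gf("stimulus config: AOI '", a$id, "' lies outside the ",
                  width, " x ", height, " monitor")
        }
      } else {
        stop_gf("stimulus config: AOI '", a$id, "': shape must be 'circle' or 'rect'")
      }
      aoi_rows[[length(aoi_rows) + 1L]] <- row
    }
  }
  clips <- do.call(rbind, clip_rows)
  aois <- do.call(rbind, aoi_rows)
  if (anyDuplicated(clips$clip_id)) stop_gf("stimulus config: duplicate clip id")
  if (anyDuplicated(aois$aoi_id)) {
    stop_gf("stimulus config: duplicate AOI id: ",
            paste(unique(aois$aoi_id[duplicated(aois$aoi_id)]), collapse = ", "))
  }
  clips <- clips[order(clips$order), , drop = FALSE]
  rownames(clips) <- NULL
  if (any(clips$order != seq_len(nrow(clips)))) {
    stop_gf("stimulus config: clip 'order' values must be a permutation of 1..",
            nrow(clips))
  }

  structure(list(
    monitor = c(width = width, height = height),
    sample_rate = as.numeric(raw$sample_rate_hz),
    grabber_s = as.numeric(raw$grabber_s),
    clips = clips, aois = aois, path = path
  ), class = "gf_stimulus")
}

#' @export
print.gf_stimulus <- function(x, ...) {
  cat("Stimulus set:", nrow(x$clips), "clips,", nrow(x$aois), "AOIs\n")
  cat("Monitor:", x$monitor[["width"]], "x", x$monitor[["height"]],
      "px; sampling", x$sample_rate, "Hz; grabbers", x$grabber_s, "s\n")
  cat("Clips:", paste(sprintf("%s (%.1fs)", x$clips$clip_id, x$clips$duration_s),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Point-in-AOI membership
#'
#' Tests whether monitor coordinates fall inside an AOI. Boundary points count
#' as inside. The coordinate origin is the monitor's top-left corner, x
#' rightward, y downward (the eye tracker's own convention). Vectorised over
#' \code{x} and \code{y}; \code{NA} coordinates give \code{FALSE}.
#'
#' @param aoi A single-row AOI data frame (one row of
#'   \code{gf_stimulus()$aois}) or a list with the same fields.
#' @param x,y Numeric vectors of pixel coordinates.
#' @return Logical vector.
#' @examples
#' stim <- gf_stimulus()
#' a <- stim$aois[stim$aois$aoi_id == "still_face", ]
#' point_in_aoi(a, 640, 400)
#' @export
point_in_aoi <- function(aoi, x, y) {
  if (is.data.frame(aoi)) {
    stopifnot(nrow(aoi) == 1L)
    aoi <- as.list(aoi)
  }
  x <- as.numeric(x); y <- as.numeric(y)
  out <- if (identical(aoi$shape, "circle")) {
    (x - aoi$cx)^2 + (y - aoi$cy)^2 <= aoi$r^2
  } else if (identical(aoi$shape, "rect")) {
    x >= aoi$x & x <= aoi$x + aoi$w & y >= aoi$y & y <= aoi$y + aoi$h
  } else {
    stop_gf("unknown AOI shape: ", aoi$shape)
  }
  out & !is.na(x) & !is.na(y)
}

#' Enumerate the attribute space of a stimulus set
#'
#' Every AOI yields four attributes: three rate scores (over the full clip,
#' the first 1.0 s, and the first 2.0 s of the clip) and one count score, so a
#' stimulus set with 100 AOIs defines 300 rate attributes and 100 count
#' attributes. The enumeration is deterministic: clips in presentation order,
#' AOIs in lexical order of id within each clip, kinds in the fixed order
#' \code{rate_full}, \code{rate_1s}, \code{rate_2s}, \code{count}.
#'
#' @param stimulus A \code{gf_stimulus} object.
#' @return Data frame with columns \code{attr_id} (\code{"<aoi_id>.<kind>"}),
#'   \code{aoi_id}, \code{clip_id}, \code{kind}, and \code{family}
#'   (\code{"rate"} or \code{"count"}).
#' @examples
#' specs <- attribute_space(gf_stimulus())
#' table(specs$family)   # 300 rate, 100 count
#' @export
attribute_space <- function(stimulus) {
  stopifnot(inherits(stimulus, "gf_stimulus"))
  kinds <- c("rate_full", "rate_1s", "rate_2s", "count")
  rows <- lapply(stimulus$clips$clip_id, function(cid) {
    ids <- sort(stimulus$aois$aoi_id[stimulus$aois$clip_id == cid])
    data.frame(
      aoi_id = rep(ids, each = length(kinds)),
      clip_id = cid,
      kind = rep(kinds, times = length(ids)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$attr_id <- paste(out$aoi_id, out$kind, sep = ".")
  out$family <- ifelse(out$kind == "count", "count", "rate")
  out[, c("attr_id", "aoi_id", "clip_id", "kind", "family")]
}

# expected number of 50 Hz samples for each clip (named by clip id)
clip_sample_counts <- function(stimulus) {
  n <- round(stimulus$clips$duration_s * stimulus$sample_rate)
  names(n) <- stimulus$clips$clip_id
  n
}
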