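# JSON serialisation of fitted models and evaluation reports.
# Numbers are written at full precision so identical refits give
# byte-identical files.

candidates_to_list <- function(cand) {
  list(band = attr(cand, "band"), family = attr(cand, "family"),
       attributes = as.data.frame(cand)[, c("attr_id", "aoi_id", "kind", "d",
                                            "p", "orientation", "fixation_pct")])
}

subalgo_to_list <- function(sub) {
  list(band = sub$band, family = sub$family,
       candidates = candidates_to_list(sub$candidates),
       normalizers = as.list(sub$normalizers),
       degenerate = sub$degenerate,
       sigmoid = list(a = sub$sigmoid$a, b = sub$sigmoid$b, loss = sub$sigmoid$loss))
}

blend_to_list <- function(b) b[c("A", "B", "k", "a0", "loss")]

#' Write a fitted best-fit model to JSON
#'
#' Serialises the full model with provenance - candidate attribute ids with
#' effect sizes and orientations, the rate-family normalising SDs, every
#' sigmoid and blend coefficient, the modality choice, and the configuration -
#' at full numeric precision: refitting on identical data and configuration
#' reproduces the file byte for byte.
#'
#' @param object A \code{bestfit} model.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @seealso [read_bestfit()]
#' @export
write_bestfit <- function(object, path) {
  stopifnot(inherits(object, "bestfit"))
  payload <- list(
    format = "gazedx-bestfit",
    version = 1L,
    subalgorithms = lapply(object$subalgorithms, subalgo_to_list),
    rate_blend = blend_to_list(object$rate_merged$blend),
    count_blend = blend_to_list(object$count_merged$blend),
    modality = as.list(object$modality),
    final_blend = blend_to_list(object$final_blend),
    threshold = object$threshold,
    config = unclass(object$config),
    training = list(ids = object$training$ids,
                    auc = object$training$auc))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

list_to_candidates <- function(x) {
  cand <- as.data.frame(x$attributes, stringsAsFactors = FALSE)
  structure(cand, band = x$band, family = x$family,
            class = c("gf_candidates", "data.frame"))
}

list_to_subalgo <- function(x) {
  structure(list(band = x$band, family = x$family,
                 candidates = list_to_candidates(x$candidates),
                 normalizers = unlist(x$normalizers),
                 degenerate = unlist(x$degenerate) %||% character(0),
                 sigmoid = structure(list(a = x$sigmoid$a, b = x$sigmoid$b,
                                          loss = x$sigmoid$loss),
                                     class = "gf_sigmoid")),
            class = "gf_subalgo")
}

#' Read a best-fit model from JSON
#'
#' Reconstructs a \code{bestfit} object written by [write_bestfit()],
#' sufficient for prediction and external evaluation.
#'
#' @param path Path to a model JSON file.
#' @return A \code{bestfit} object.
#' @export
read_bestfit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(x$format, "gazedx-bestfit")) {
    stop_gf("not a gazedx best-fit model file: ", path)
  }
  subs <- lapply(x$subalgorithms, list_to_subalgo)
  mk_merged <- function(family, blend) {
    structure(list(family = family,
                   young = subs[[paste0(family, "_younger")]],
                   old = subs[[paste0(family, "_older")]],
                   blend = as.list(blend)),
              class = "gf_merged")
  }
  modality <- unlist(x$modality)
  structure(list(
    subalgorithms = subs,
    rate_merged = mk_merged("rate", x$rate_blend),
    count_merged = mk_merged("count", x$count_blend),
    modality = modality,
    final_blend = as.list(x$final_blend),
    threshold = x$threshold,
    config = structure(as.list(x$config), class = "gf_config"),
    training = list(ids = x$training$ids, auc = x$training$auc)),
    class = "bestfit")
}

#' Write an evaluation report to JSON
#'
#' @param report A \code{gf_report} (or the \code{report} element of a
#'   \code{gf_loo}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "gf_report"))
  payload <- list(
    format = "gazedx-report",
    auc = report$auc,
    auc_ci = report$auc_ci,
    youden = report$youden,
    sensitivity = report$sensitivity,
    specificity = report$specificity,
    accuracy = report$accuracy,
    n_cases = report$n_cases, n_controls = report$n_controls,
    roc = as.data.frame(report$roc))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
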