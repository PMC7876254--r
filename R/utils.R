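# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

# numerically safe binary cross-entropy; p clamped away from {0,1}
bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

stop_gf <- function(...) stop(..., call. = FALSE)

# Rows of a cohort usable for supervised training: labelled, and - when a
# group column is present - restricted to the ASD/TD groups (second-control
# participants are an external validation sample, never training data).
labelled_training_rows <- function(cohort, values = NULL) {
  rows <- cohort[!is.na(cohort$asd_label), , drop = FALSE]
  if ("group" %in% names(rows)) {
    rows <- rows[rows$group %in% c("ASD", "TD"), , drop = FALSE]
  }
  if (!is.null(values)) {
    rows <- rows[rows$participant_id %in% rownames(values), , drop = FALSE]
  }
  rows
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_gf(what, ": missing column(s): ", paste(miss, collapse = ", "))
  }
}
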