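# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed pathsig error
#'
#' All user-facing failures are classed conditions so callers (and the CLI)
#' can distinguish configuration, calibration, parsing, and sizing problems.
#'
#' @noRd
pathsig_error <- function(msg, class) {
  stop(structure(
    class = c(class, "pathsig_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores (or removes) the global \code{.Random.seed} afterwards so that
#' seeded generators never leak RNG state into the session.
#'
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed)) {
    pathsig_error("a single finite `seed` is required (no global RNG state is used)",
                  "pathsig_config_error")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# probability strictly inside (0,1)
check_prob_open <- function(p, what) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    pathsig_error(sprintf("%s must lie strictly inside (0, 1)", what),
                  "pathsig_config_error")
  }
  invisible(p)
}

log2_odds <- function(p) log2(p / (1 - p))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# canonical ground-truth labels: named character, values "active"/"inactive"
check_labels <- function(labels) {
  if (is.factor(labels)) labels <- setNames(as.character(labels), names(labels))
  if (!is.character(labels) || is.null(names(labels)) || any(names(labels) == "")) {
    pathsig_error("labels must be a named character vector (sample_id -> label)",
                  "pathsig_config_error")
  }
  lab <- tolower(labels)
  bad <- setdiff(unique(lab), c("active", "inactive"))
  if (length(bad)) {
    pathsig_error(sprintf("unknown label value(s): %s (allowed: active, inactive)",
                          paste(bad, collapse = ", ")),
                  "pathsig_parse_error")
  }
  if (anyDuplicated(names(labels))) {
    pathsig_error("duplicated sample_id in labels", "pathsig_parse_error")
  }
  setNames(lab, names(labels))
}

check_matrix <- function(x, what = "expression matrix") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    pathsig_error(sprintf("%s must be a numeric matrix (probes x samples)", what),
                  "pathsig_config_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    pathsig_error(sprintf("%s must have probe rownames and sample colnames", what),
                  "pathsig_config_error")
  }
  if (anyDuplicated(rownames(x))) {
    pathsig_error(sprintf("duplicate probe IDs in %s: %s", what,
                          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")),
                  "pathsig_config_error")
  }
  if (anyDuplicated(colnames(x))) {
    pathsig_error(sprintf("duplicate sample IDs in %s", what), "pathsig_config_error")
  }
  x
}
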