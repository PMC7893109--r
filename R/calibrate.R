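# Calibration of the measurement (second) layer on ground-truth samples.
#
# The latent TG state of each gene is hard-assigned from the sample label and
# the gene's direction ("up" in active-labeled samples for induced genes, in
# inactive-labeled samples for repressed genes); thresholds and emission
# probabilities are then deterministic functions of the data. No EM.

# samples usable for calibration: present in both matrix and labels
calib_samples <- function(x, labels) {
  common <- intersect(colnames(x), names(labels))
  if (!length(common)) {
    pathsig_error("no overlap between matrix samples and labeled samples",
                  "pathsig_calibration_error")
  }
  labels[common]
}

#' Derive per-probe dichotomization thresholds
#'
#' For each panel probe the threshold is the midpoint of the two
#' class-conditional medians (active-labeled vs inactive-labeled samples).
#' Medians make the rule robust to outliers; the midpoint is symmetric in
#' the two classes, so gene direction does not change the threshold value
#' (it changes which class counts as the "up" state downstream).
#'
#' @param x Numeric matrix, probes x samples (missing values allowed).
#' @param labels Named character vector, sample_id -> "active"/"inactive".
#' @param panel A [gene_panel()].
#' @return Named numeric vector of thresholds, one per panel probe.
#' @export
derive_thresholds <- function(x, labels, panel) {
  x <- check_matrix(x)
  labels <- check_labels(labels)
  labels <- calib_samples(x, labels)
  if (!all(c("active", "inactive") %in% labels)) {
    pathsig_error("both label classes (active, inactive) are required for calibration",
                  "pathsig_calibration_error")
  }
  pp <- panel_probes(panel)
  miss <- setdiff(pp$probe, rownames(x))
  if (length(miss)) {
    pathsig_error(sprintf("panel probe(s) absent from matrix: %s",
                          paste(miss, collapse = ", ")),
                  "pathsig_config_error")
  }
  act <- names(labels)[labels == "active"]
  ina <- names(labels)[labels == "inactive"]
  th <- vapply(pp$probe, function(p) {
    va <- x[p, act]; vi <- x[p, ina]
    if (all(is.na(va)) || all(is.na(vi))) {
      pathsig_error(sprintf("probe %s has no observed values in one label class", p),
                    "pathsig_calibration_error")
    }
    (median(va, na.rm = TRUE) + median(vi, na.rm = TRUE)) / 2
  }, 1)
  setNames(th, pp$probe)
}

#' Fit emission probabilities by smoothed counting
#'
#' With target-gene states hard-assigned from labels and gene direction,
#' `p_high_given_up = (n_high_in_up + alpha) / (n_up + 2 alpha)` (Laplace
#' smoothing; analogously for the down state). Values at the threshold
#' dichotomize as "high" (`value >= t`). Smoothing with `alpha > 0` keeps
#' every probability strictly inside (0,1) so likelihood ratios stay finite.
#'
#' @inheritParams derive_thresholds
#' @param thresholds Named per-probe thresholds, e.g. from
#'   [derive_thresholds()].
#' @param alpha Laplace smoothing pseudo-count (> 0, default 1).
#' @param min_samples_per_class Minimum labeled samples required per class
#'   (default 2).
#' @return An [emission_parameters()] object with count metadata in
#'   `attr(, "counts")`.
#' @export
fit_emissions <- function(x, labels, panel, thresholds, alpha = 1,
                          min_samples_per_class = 2) {
  x <- check_matrix(x)
  labels <- check_labels(labels)
  labels <- calib_samples(x, labels)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    pathsig_error("smoothing `alpha` must be a single value > 0", "pathsig_config_error")
  }
  n_act <- sum(labels == "active")
  n_ina <- sum(labels == "inactive")
  if (n_act < min_samples_per_class || n_ina < min_samples_per_class) {
    pathsig_error(sprintf(
      "calibration needs >= %d samples per class (got %d active, %d inactive)",
      min_samples_per_class, n_act, n_ina),
      "pathsig_calibration_error")
  }
  pp <- panel_probes(panel)
  miss <- setdiff(pp$probe, names(thresholds))
  if (length(miss)) {
    pathsig_error(sprintf("no threshold for probe(s): %s", paste(miss, collapse = ", ")),
                  "pathsig_config_error")
  }
  miss <- setdiff(pp$probe, rownames(x))
  if (length(miss)) {
    pathsig_error(sprintf("panel probe(s) absent from matrix: %s",
                          paste(miss, collapse = ", ")),
                  "pathsig_config_error")
  }
  act <- names(labels)[labels == "active"]
  ina <- names(labels)[labels == "inactive"]
  counts <- lapply(seq_len(nrow(pp)), function(i) {
    p <- pp$probe[i]
    t <- thresholds[[p]]
    # label class whose hard-assigned TG state is "up"
    up_s <- if (pp$direction[i] == 1L) act else ina
    dn_s <- if (pp$direction[i] == 1L) ina else act
    v_up <- x[p, up_s]; v_dn <- x[p, dn_s]
    v_up <- v_up[!is.na(v_up)]; v_dn <- v_dn[!is.na(v_dn)]
    if (!length(v_up) || !length(v_dn)) {
      pathsig_error(sprintf("probe %s has no observed values in one class", p),
                    "pathsig_calibration_error")
    }
    list(probe = p,
         n_up = length(v_up), n_high_up = sum(v_up >= t),
         n_down = length(v_dn), n_high_down = sum(v_dn >= t))
  })
  em <- emission_parameters(
    probe = pp$probe,
    threshold = unname(thresholds[pp$probe]),
    p_high_given_up = vapply(counts, function(cn) (cn$n_high_up + alpha) / (cn$n_up + 2 * alpha), 1),
    p_high_given_down = vapply(counts, function(cn) (cn$n_high_down + alpha) / (cn$n_down + 2 * alpha), 1)
  )
  attr(em, "counts") <- do.call(rbind, lapply(counts, as.data.frame))
  em
}

#' Calibrate a pathway model on ground-truth samples
#'
#' The fitting function of the package: derives per-probe dichotomization
#' thresholds ([derive_thresholds()]), fits emission probabilities
#' ([fit_emissions()]), and assembles the [pathway_model()], recording
#' calibration provenance (per-class sample counts, smoothing, threshold
#' rule) in the model.
#'
#' @inheritParams fit_emissions
#' @param priors First-layer parameters; default literature-style coupling
#'   from [default_priors()].
#' @param platform Measurement platform tag; defaults to the matrix's
#'   `platform` attribute (`"cq-normalized"` maps to `"cq"`), else
#'   `"intensity"`.
#' @return A calibrated [pathway_model()].
#' @examples
#' panel <- gene_panel("demo", paste0("G", 1:4))
#' sim <- simulate_cohort(panel, 20, 20, seed = 1)
#' m <- calibrate(panel, sim$expression, sim$labels)
#' @export
calibrate <- function(panel, x, labels, priors = default_priors(panel),
                      alpha = 1, min_samples_per_class = 2, platform = NULL) {
  x <- check_matrix(x)
  if (is.null(platform)) {
    platform <- switch(attr(x, "platform") %||% "intensity",
                       "cq-normalized" = "cq", "cq" = "cq", "intensity")
  }
  labels_used <- check_labels(labels)
  labels_used <- calib_samples(x, labels_used)
  th <- derive_thresholds(x, labels_used, panel)
  em <- fit_emissions(x, labels_used, panel, th, alpha = alpha,
                      min_samples_per_class = min_samples_per_class)
  prov <- list(
    n_active = sum(labels_used == "active"),
    n_inactive = sum(labels_used == "inactive"),
    smoothing_alpha = alpha,
    min_samples_per_class = min_samples_per_class,
    threshold_rule = "class-median-midpoint"
  )
  pathway_model(panel, priors, em, platform = platform, calibration = prov)
}

#' Port a calibrated model to a new measurement platform
#'
#' Re-derives thresholds and emission probabilities from the very same
#' calibration samples re-measured on a new platform (e.g. delta-Cq
#' normalized qPCR), keeping the first-layer priors and gene directions
#' unchanged. The panel may be a reduced subset of the original (the ~12-gene
#' qPCR panels); reduced-panel genes absent from the new matrix are an error.
#'
#' @param model A calibrated [pathway_model()].
#' @param new_x Matrix of the calibration samples re-measured on the new
#'   platform.
#' @param labels Ground-truth labels of those samples.
#' @param panel Optional reduced [gene_panel()]; must be a subset of the
#'   model's panel genes with identical directions. Defaults to the model's
#'   full panel.
#' @param alpha,min_samples_per_class As in [calibrate()].
#' @param platform Platform tag of the new measurements (default `"cq"`).
#' @return A re-calibrated [pathway_model()] on the new platform.
#' @export
port_platform <- function(model, new_x, labels, panel = NULL, alpha = 1,
                          min_samples_per_class = 2, platform = "cq") {
  if (!inherits(model, "pathway_model")) {
    pathsig_error("`model` must be a pathway_model", "pathsig_config_error")
  }
  if (is.null(new_x) || length(new_x) == 0L ||
      (is.matrix(new_x) && ncol(new_x) == 0L)) {
    pathsig_error("new platform matrix is empty", "pathsig_config_error")
  }
  panel <- panel %||% model$panel
  extra <- setdiff(panel$genes$gene, model$panel$genes$gene)
  if (length(extra)) {
    pathsig_error(sprintf("ported panel gene(s) not in the original model: %s",
                          paste(extra, collapse = ", ")),
                  "pathsig_config_error")
  }
  md <- model$panel$genes$direction[match(panel$genes$gene, model$panel$genes$gene)]
  if (!all(md == panel$genes$direction)) {
    pathsig_error("ported panel changes gene directions", "pathsig_config_error")
  }
  # retain the original first-layer priors, restricted to the kept genes
  pg <- model$priors$genes
  pg <- pg[pg$gene %in% panel$genes$gene, , drop = FALSE]
  priors <- pathway_priors(model$priors$p_tf_active, pg$gene,
                           pg$p_up_given_active, pg$p_up_given_inactive)
  calibrate(panel, new_x, labels, priors = priors, alpha = alpha,
            min_samples_per_class = min_samples_per_class, platform = platform)
}

#' Calibration report of a fitted model
#'
#' A JSON-ready summary of a calibrated model: per-probe thresholds and
#' emission probabilities plus the recorded per-class sample counts and
#' configuration, for audit trails.
#'
#' @param model A calibrated [pathway_model()].
#' @param path Optional path; when given, the report is written as JSON.
#' @return The report list, invisibly when written to `path`.
#' @export
calibration_report <- function(model, path = NULL) {
  rep <- list(
    pathway = model$panel$pathway,
    platform = model$platform,
    emissions = as.data.frame(model$emissions),
    bounds = list(l_min = model$l_min, l_max = model$l_max),
    calibration = model$calibration
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "rows")
    return(invisible(rep))
  }
  rep
}
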