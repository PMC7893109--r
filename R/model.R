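#' Build a pathway activity model from explicit parameters
#'
#' Assembles the two-layer Bayesian network for one pathway: a binary
#' transcription-factor (TF) node, one binary target-gene (TG) node per panel
#' gene, and one dichotomized measurement node per probe, conditionally
#' independent given the TG state. Score-normalization bounds `l_min`/`l_max`
#' (the extreme achievable log2 odds over all complete evidence assignments)
#' are computed at build time so that the 0-100 score mapping is
#' model-intrinsic.
#'
#' Models are normally produced by [calibrate()]; use this constructor when
#' parameters come from elsewhere (e.g. a model file, or a designed
#' simulation study).
#'
#' @param panel A [gene_panel()].
#' @param priors First-layer parameters, see [default_priors()]. Every panel
#'   gene must have an entry, and the coupling must respect the gene's
#'   direction (`p_up_given_active > p_up_given_inactive` for +1 genes,
#'   reversed for -1).
#' @param emissions Second-layer parameters, see [emission_parameters()].
#'   Every panel probe must have an entry.
#' @param platform `"intensity"` for log2 microarray-style values,
#'   `"cq"` for delta-Cq-normalized qPCR values.
#' @param calibration Optional calibration provenance (recorded, not
#'   interpreted).
#'
#' @return An object of class `pathway_model`.
#' @examples
#' p <- gene_panel("demo", c("G1", "G2"))
#' m <- pathway_model(p, default_priors(p),
#'                    emission_parameters(c("G1", "G2"), 6,
#'                                        0.9, 0.1))
#' m$l_max  # 2 * log2(0.86/0.14)
#' @export
pathway_model <- function(panel, priors = default_priors(panel), emissions,
                          platform = c("intensity", "cq"),
                          calibration = NULL) {
  if (!inherits(panel, "gene_panel")) {
    pathsig_error("`panel` must be a gene_panel", "pathsig_config_error")
  }
  if (!inherits(priors, "pathway_priors")) {
    pathsig_error("`priors` must be pathway_priors", "pathsig_config_error")
  }
  if (!inherits(emissions, "emission_parameters")) {
    pathsig_error("`emissions` must be emission_parameters", "pathsig_config_error")
  }
  platform <- match.arg(platform)

  miss <- setdiff(panel$genes$gene, priors$genes$gene)
  if (length(miss)) {
    pathsig_error(sprintf("no prior parameters for gene(s): %s",
                          paste(miss, collapse = ", ")),
                  "pathsig_config_error")
  }
  pp <- panel_probes(panel)
  miss <- setdiff(pp$probe, emissions$probe)
  if (length(miss)) {
    genes <- pp$gene[match(miss, pp$probe)]
    pathsig_error(sprintf("no emission parameters for probe(s): %s",
                          paste(sprintf("%s (gene %s)", miss, genes), collapse = ", ")),
                  "pathsig_config_error")
  }

  # keep only panel rows, in panel order
  priors$genes <- priors$genes[match(panel$genes$gene, priors$genes$gene), , drop = FALSE]
  rownames(priors$genes) <- NULL
  emissions <- emissions[match(pp$probe, emissions$probe), , drop = FALSE]
  rownames(emissions) <- NULL
  class(emissions) <- c("emission_parameters", "data.frame")

  # direction invariant on the first layer
  dir <- panel$genes$direction
  ok <- ifelse(dir == 1L,
               priors$genes$p_up_given_active > priors$genes$p_up_given_inactive,
               priors$genes$p_up_given_active < priors$genes$p_up_given_inactive)
  if (!all(ok)) {
    pathsig_error(sprintf(
      "first-layer coupling contradicts gene direction for: %s",
      paste(panel$genes$gene[!ok], collapse = ", ")),
      "pathsig_config_error")
  }

  model <- structure(
    list(panel = panel, priors = priors, emissions = emissions,
         platform = platform, l_min = NA_real_, l_max = NA_real_,
         calibration = calibration, format = "pathsig-model/1"),
    class = "pathway_model"
  )
  b <- compute_bounds(model)
  model$l_min <- b[["l_min"]]
  model$l_max <- b[["l_max"]]
  model
}

# per-gene parameter bundle used by the inference kernels
gene_params <- function(model, gene) {
  pr <- model$priors$genes
  i <- match(gene, pr$gene)
  probes <- model$panel$probes[[gene]]
  em <- model$emissions[match(probes, model$emissions$probe), , drop = FALSE]
  list(gene = gene,
       p_up_a = pr$p_up_given_active[i],
       p_up_i = pr$p_up_given_inactive[i],
       probes = probes,
       threshold = em$threshold,
       ph_up = em$p_high_given_up,
       ph_down = em$p_high_given_down)
}

#' Per-gene log2 likelihood ratio of the evidence
#'
#' Marginalizes the latent target-gene state:
#' \deqn{LR_g = \frac{\sum_s P(e_g \mid TG=s) P(TG=s \mid TF=active)}
#'                   {\sum_s P(e_g \mid TG=s) P(TG=s \mid TF=inactive)}}
#' Probes with missing evidence contribute a likelihood factor of 1, so an
#' unmeasured (or unexpressed, hence undetected) gene is neutral evidence,
#' never evidence of inactivity.
#'
#' @param gp A gene parameter bundle (internal) or gene symbol.
#' @param evidence Integer/logical vector over the gene's probes: 1 = high,
#'   0 = low, NA = missing.
#' @param model The [pathway_model()] (used when `gp` is a gene symbol).
#' @return The gene's log2 likelihood ratio (0 when all evidence is missing).
#' @export
gene_log2_lr <- function(gp, evidence, model = NULL) {
  if (is.character(gp)) {
    if (is.null(model)) {
      pathsig_error("supply `model` when naming a gene by symbol", "pathsig_config_error")
    }
    gp <- gene_params(model, gp)
  }
  obs <- !is.na(evidence)
  if (!any(obs)) return(0)
  e <- as.numeric(evidence[obs])
  lik_up <- prod(ifelse(e == 1, gp$ph_up[obs], 1 - gp$ph_up[obs]))
  lik_dn <- prod(ifelse(e == 1, gp$ph_down[obs], 1 - gp$ph_down[obs]))
  num <- gp$p_up_a * lik_up + (1 - gp$p_up_a) * lik_dn
  den <- gp$p_up_i * lik_up + (1 - gp$p_up_i) * lik_dn
  log2(num / den)
}

#' Score-normalization bounds of a model
#'
#' The minimum and maximum achievable log2 odds over all complete evidence
#' assignments (every probe observed high or low). Because the likelihood
#' factorizes over genes, the extremes are the prior log2 odds plus the sum
#' of per-gene extreme log2 likelihood ratios; per gene the extreme is taken
#' over the 2^(number of probes) complete assignments.
#'
#' @param model A [pathway_model()].
#' @return Named numeric vector `c(l_min = ..., l_max = ...)`.
#' @export
compute_bounds <- function(model) {
  prior_lo <- log2_odds(model$priors$p_tf_active)
  lo <- hi <- prior_lo
  for (gene in model$panel$genes$gene) {
    gp <- gene_params(model, gene)
    np <- length(gp$probes)
    combos <- as.matrix(expand.grid(rep(list(c(0, 1)), np)))
    lrs <- apply(combos, 1L, function(e) gene_log2_lr(gp, e))
    lo <- lo + min(lrs)
    hi <- hi + max(lrs)
  }
  c(l_min = lo, l_max = hi)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("Pathway activity model: %s (%s platform)\n",
              x$panel$pathway, x$platform))
  cat(sprintf("  %d target genes, %d probes; prior P(active) = %.3g\n",
              nrow(x$panel$genes), nrow(x$emissions), x$priors$p_tf_active))
  cat(sprintf("  log2-odds bounds: [%.3f, %.3f]\n", x$l_min, x$l_max))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibrated on %d active / %d inactive samples (alpha = %g)\n",
                x$calibration$n_active, x$calibration$n_inactive,
                x$calibration$smoothing_alpha))
  }
  invisible(x)
}

#' @export
coef.pathway_model <- function(object, ...) {
  pp <- panel_probes(object$panel)
  pr <- object$priors$genes[match(pp$gene, object$priors$genes$gene), , drop = FALSE]
  em <- object$emissions[match(pp$probe, object$emissions$probe), , drop = FALSE]
  out <- cbind(pp, em[, c("threshold", "p_high_given_up", "p_high_given_down")],
               pr[, c("p_up_given_active", "p_up_given_inactive")])
  rownames(out) <- NULL
  out
}

#' @export
summary.pathway_model <- function(object, ...) {
  cf <- coef(object)
  # per-probe informativeness: |log2 LR| of a "high" reading
  lr_high <- vapply(seq_len(nrow(cf)), function(i) {
    gp <- gene_params(object, cf$gene[i])
    j <- match(cf$probe[i], gp$probes)
    e <- rep(NA_real_, length(gp$probes)); e[j] <- 1
    gene_log2_lr(gp, e)
  }, 1)
  cf$log2_lr_high <- lr_high
  out <- list(model = object, coef = cf)
  class(out) <- "summary.pathway_model"
  out
}

#' @export
print.summary.pathway_model <- function(x, ...) {
  print(x$model)
  cat("\nPer-probe parameters (log2_lr_high = evidence weight of a high reading):\n")
  print(x$coef, digits = 4)
  invisible(x)
}

#' Save / load a pathway model
#'
#' Models serialize to a single self-describing, schema-versioned JSON
#' document (`format` = `"pathsig-model/1"`), with probabilities stored as
#' decimals for auditability. `load_model()` refuses files from a newer
#' major format version rather than misparsing them.
#'
#' @param model A [pathway_model()].
#' @param path File path.
#' @return `load_model()` returns the reconstructed [pathway_model()];
#'   `save_model()` returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  panel <- model$panel
  obj <- list(
    format = model$format,
    platform = model$platform,
    panel = list(
      pathway = panel$pathway,
      target_genes = lapply(seq_len(nrow(panel$genes)), function(i) {
        g <- panel$genes$gene[i]
        list(gene = g, direction = panel$genes$direction[i],
             probes = as.list(panel$probes[[g]]))
      }),
      reference_genes = as.list(panel$reference_genes),
      inverse_of = panel$inverse_of
    ),
    priors = list(p_tf_active = model$priors$p_tf_active,
                  genes = model$priors$genes),
    emissions = as.data.frame(model$emissions),
    bounds = list(l_min = model$l_min, l_max = model$l_max),
    calibration = model$calibration
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null",
                       dataframe = "rows")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    pathsig_error(sprintf("cannot parse model file '%s': %s",
                                          path, conditionMessage(e)),
                                  "pathsig_schema_error")
                  })
  fmt <- obj$format
  if (is.null(fmt) || !grepl("^pathsig-model/[0-9]+$", fmt)) {
    pathsig_error("model file has no valid 'format' field (expected pathsig-model/<major>)",
                  "pathsig_schema_error")
  }
  major <- as.integer(sub("^pathsig-model/", "", fmt))
  if (major != 1L) {
    pathsig_error(sprintf(
      "model file format '%s' is not supported by this version (supports pathsig-model/1)",
      fmt), "pathsig_version_error")
  }
  need <- c("platform", "panel", "priors", "emissions")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    pathsig_error(sprintf("model file missing key(s): %s", paste(miss, collapse = ", ")),
                  "pathsig_schema_error")
  }
  tg <- obj$panel$target_genes
  if (is.data.frame(tg)) {
    genes <- tg$gene
    directions <- tg$direction
    probes <- setNames(lapply(tg$probes, function(p) as.character(unlist(p))), genes)
  } else {
    genes <- vapply(tg, function(e) as.character(e$gene), "")
    directions <- vapply(tg, function(e) as.integer(e$direction), 1L)
    probes <- setNames(lapply(tg, function(e) as.character(unlist(e$probes))), genes)
  }
  panel <- gene_panel(obj$panel$pathway, genes, directions, probes,
                      reference_genes = as.character(obj$panel$reference_genes %||% character()),
                      inverse_of = obj$panel$inverse_of %||% NULL)
  pg <- obj$priors$genes
  priors <- pathway_priors(obj$priors$p_tf_active, pg$gene,
                           pg$p_up_given_active, pg$p_up_given_inactive)
  em <- obj$emissions
  emissions <- emission_parameters(em$probe, em$threshold,
                                   em$p_high_given_up, em$p_high_given_down)
  pathway_model(panel, priors, emissions, platform = obj$platform,
                calibration = obj$calibration %||% NULL)
}
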