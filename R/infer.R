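# Per-sample inference: dichotomize measurements against model thresholds,
# marginalize latent TG states per gene, sum log2 likelihood ratios with the
# prior log2 odds, and rescale to the 0-100 activity score.

# evidence for one sample: named numeric vector -> 1/0/NA per model probe
sample_evidence <- function(model, values) {
  pp <- panel_probes(model$panel)
  v <- values[match(pp$probe, names(values))]
  t <- model$emissions$threshold[match(pp$probe, model$emissions$probe)]
  e <- ifelse(is.na(v), NA_real_, as.numeric(v >= t))
  setNames(e, pp$probe)
}

score_from_l <- function(model, L) {
  rng <- model$l_max - model$l_min
  if (!is.finite(rng) || rng < 1e-12) return(50)
  clamp(100 * (L - model$l_min) / rng, 0, 100)
}

# core single-sample inference; returns list(L, score, contributions, n_missing)
infer_one <- function(model, values, require_evidence = TRUE) {
  evid <- sample_evidence(model, values)
  if (require_evidence && all(is.na(evid))) {
    pathsig_error("no evidence: none of the model probes is measured in this sample",
                  "pathsig_no_evidence_error")
  }
  genes <- model$panel$genes$gene
  contrib <- vapply(genes, function(g) {
    gp <- gene_params(model, g)
    gene_log2_lr(gp, evid[gp$probes])
  }, 1)
  n_missing <- sum(vapply(genes, function(g) {
    all(is.na(evid[model$panel$probes[[g]]]))
  }, TRUE))
  L <- log2_odds(model$priors$p_tf_active) + sum(contrib)
  list(log2_odds = L, score = score_from_l(model, L),
       contributions = contrib, n_missing_genes = n_missing)
}

as_scores_df <- function(model, sample_ids, rows, errors) {
  df <- data.frame(
    sample_id = sample_ids,
    pathway = rep(model$panel$pathway, length(sample_ids)),
    log2_odds = vapply(rows, function(r) if (is.null(r)) NA_real_ else r$log2_odds, 1),
    score = vapply(rows, function(r) if (is.null(r)) NA_real_ else r$score, 1),
    n_missing_genes = vapply(rows, function(r) if (is.null(r)) NA_integer_ else as.integer(r$n_missing_genes), 1L),
    error = vapply(errors, function(e) if (is.null(e)) NA_character_ else e, ""),
    stringsAsFactors = FALSE
  )
  genes <- model$panel$genes$gene
  contrib <- vapply(rows, function(r) {
    if (is.null(r)) rep(NA_real_, length(genes)) else unname(r$contributions)
  }, numeric(length(genes)))
  contrib <- matrix(contrib, nrow = length(genes),
                    dimnames = list(genes, sample_ids))
  structure(df,
            contributions = contrib,
            l_min = model$l_min, l_max = model$l_max,
            inverse_of = model$panel$inverse_of,
            class = c("pathway_scores", "data.frame"))
}

#' Infer pathway activity for samples
#'
#' Computes, per sample, the log2 odds `L` that the pathway's transcription
#' factor is active given the dichotomized target-gene measurements, the
#' 0-100 activity score `S = 100 (L - l_min) / (l_max - l_min)` (clamped),
#' and per-gene log2 likelihood-ratio contributions for interpretability.
#' Missing measurements are neutral evidence (likelihood factor 1); a sample
#' in which no model probe is measured at all raises a "no evidence" error.
#'
#' For a matrix, per-sample failures are collected in the `error` column
#' (with `NA` score) rather than aborting the batch; column order is
#' preserved and results are independent of it.
#'
#' @param model A [pathway_model()].
#' @param x Either a named numeric vector (one sample; names are probe IDs)
#'   or a probes x samples numeric matrix. Probes may be a subset of the
#'   panel.
#' @return A `pathway_scores` data frame with columns `sample_id`,
#'   `pathway`, `log2_odds`, `score`, `n_missing_genes`, `error`, and a
#'   genes x samples matrix of contributions in `attr(, "contributions")`.
#' @examples
#' panel <- gene_panel("demo", c("G1", "G2"))
#' m <- pathway_model(panel, default_priors(panel),
#'                    emission_parameters(c("G1", "G2"), 6, 0.9, 0.1))
#' infer_activity(m, c(G1 = 8, G2 = 7.5))  # both high -> score 100
#' @export
infer_activity <- function(model, x) {
  if (!inherits(model, "pathway_model")) {
    pathsig_error("`model` must be a pathway_model", "pathsig_config_error")
  }
  if (is.numeric(x) && !is.matrix(x)) {
    if (is.null(names(x))) {
      pathsig_error("a single-sample vector must have probe names", "pathsig_config_error")
    }
    r <- infer_one(model, x)
    return(as_scores_df(model, "sample", list(r), list(NULL)))
  }
  if ((is.matrix(x) || is.data.frame(x)) && ncol(x) == 0L) {
    return(as_scores_df(model, character(), list(), list()))
  }
  x <- check_matrix(x)
  ids <- colnames(x)
  rows <- vector("list", length(ids))
  errs <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    res <- tryCatch(infer_one(model, x[, j]),
                    pathsig_error = function(e) e)
    if (inherits(res, "condition")) {
      errs[[j]] <- conditionMessage(res)
    } else {
      rows[[j]] <- res
    }
  }
  as_scores_df(model, ids, rows, errs)
}

#' @param object A [pathway_model()].
#' @param newdata Samples to score, as in [infer_activity()].
#' @param ... Ignored.
#' @rdname infer_activity
#' @export
predict.pathway_model <- function(object, newdata, ...) {
  infer_activity(object, newdata)
}

#' Brute-force inference oracle
#'
#' Computes the posterior log2 odds by explicit summation of the full joint
#' \eqn{P(TF, TG_1..TG_n, evidence)} over all `2^n` target-gene
#' configurations, without exploiting the factorization over genes. Used to
#' verify [infer_activity()]; refuses panels above 16 genes. Unlike
#' [infer_activity()], empty evidence is legal and returns the prior log2
#' odds exactly.
#'
#' @param model A [pathway_model()] with at most 16 genes.
#' @param values Named numeric vector for one sample.
#' @return A one-row `pathway_scores` data frame.
#' @export
brute_force_infer <- function(model, values) {
  genes <- model$panel$genes$gene
  n <- length(genes)
  if (n > 16L) {
    pathsig_error(sprintf(
      "brute-force enumeration limited to 16 genes (panel has %d)", n),
      "pathsig_size_error")
  }
  evid <- sample_evidence(model, values)
  gps <- lapply(genes, gene_params, model = model)
  # per gene and TG state: P(evidence | TG = state), missing probes factor 1
  lik <- vapply(gps, function(gp) {
    e <- evid[gp$probes]
    obs <- !is.na(e)
    if (!any(obs)) return(c(up = 1, down = 1))
    eo <- as.numeric(e[obs])
    c(up = prod(ifelse(eo == 1, gp$ph_up[obs], 1 - gp$ph_up[obs])),
      down = prod(ifelse(eo == 1, gp$ph_down[obs], 1 - gp$ph_down[obs])))
  }, c(up = 1, down = 1))
  p_a <- model$priors$p_tf_active
  if (all(is.na(evid))) {
    # unobserved measurement nodes marginalize to 1 exactly: posterior = prior
    r <- list(log2_odds = log2_odds(p_a), score = score_from_l(model, log2_odds(p_a)),
              contributions = setNames(rep(0, n), genes), n_missing_genes = n)
    return(as_scores_df(model, "sample", list(r), list(NULL)))
  }
  joint_a <- 0
  joint_i <- 0
  for (cfg in 0:(2^n - 1)) {
    up <- as.logical(bitwAnd(bitwShiftR(cfg, 0:(n - 1)), 1L))
    term_a <- p_a
    term_i <- 1 - p_a
    for (g in seq_len(n)) {
      gp <- gps[[g]]
      ps_a <- if (up[g]) gp$p_up_a else 1 - gp$p_up_a
      ps_i <- if (up[g]) gp$p_up_i else 1 - gp$p_up_i
      le <- lik[if (up[g]) "up" else "down", g]
      term_a <- term_a * ps_a * le
      term_i <- term_i * ps_i * le
    }
    joint_a <- joint_a + term_a
    joint_i <- joint_i + term_i
  }
  L <- log2(joint_a / joint_i)
  contrib <- vapply(seq_len(n), function(g) gene_log2_lr(gps[[g]], evid[gps[[g]]$probes]), 1)
  r <- list(log2_odds = L, score = score_from_l(model, L),
            contributions = setNames(contrib, genes),
            n_missing_genes = sum(vapply(gps, function(gp) all(is.na(evid[gp$probes])), TRUE)))
  as_scores_df(model, "sample", list(r), list(NULL))
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf("Pathway activity scores: %s (%d sample%s)\n",
              x$pathway[1] %||% "?", nrow(x), if (nrow(x) == 1) "" else "s"))
  inv <- attr(x, "inverse_of")
  if (!is.null(inv)) {
    cat(sprintf("  note: %s pathway activity is the inverse of this measured activity\n", inv))
  }
  n_err <- sum(!is.na(x$error))
  if (n_err) cat(sprintf("  %d sample(s) failed (see $error)\n", n_err))
  print.data.frame(head(as.data.frame(x), 20), digits = 4, row.names = FALSE)
  if (nrow(x) > 20) cat(sprintf("  ... %d more rows\n", nrow(x) - 20))
  invisible(x)
}

#' Strip-plot of activity scores
#'
#' @param x A `pathway_scores` data frame.
#' @param labels Optional named character vector of class labels used to
#'   group samples (e.g. ground truth).
#' @param ... Passed to [graphics::stripchart()].
#' @export
plot.pathway_scores <- function(x, labels = NULL, ...) {
  s <- x$score
  if (is.null(labels)) {
    stripchart(s, method = "jitter", pch = 16, vertical = TRUE,
               ylab = "pathway activity score", ylim = c(0, 100), ...)
  } else {
    grp <- factor(labels[x$sample_id])
    stripchart(split(s, grp), method = "jitter", pch = 16, vertical = TRUE,
               ylab = "pathway activity score", ylim = c(0, 100), ...)
  }
  invisible(x)
}
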