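# Synthetic cohorts with the statistical structure the assay assumes:
# class-conditional target-gene expression on the log2 scale, conflicting
# genes, qPCR measurement noise and low-input dropout. All generators take a
# mandatory seed and never touch global RNG state.

#' Simulate a ground-truth calibration/test cohort
#'
#' Per sample and gene, the latent transcription state is drawn from the
#' first-layer coupling (an induced gene is "up" with probability
#' `p_up_given_active` in an active-labeled sample; repressed genes swap the
#' classes). A fraction of genes per sample have their state flipped,
#' emulating conflicting data (target genes contradicting the pathway
#' state). Each probe then measures `Normal(mean_up, sd)` or
#' `Normal(mean_down, sd)` on the log2 scale.
#'
#' @param panel A [gene_panel()].
#' @param n_active,n_inactive Number of samples per class (>= 0).
#' @param mean_up,mean_down Class-conditional means on the log2 scale
#'   (defaults 8 and 5: a 3 log2-unit effect).
#' @param sd Within-state standard deviation (> 0, default 1).
#' @param frac_conflicting Probability that a gene's state is flipped in a
#'   given sample (default 0).
#' @param p_up_given_active,p_up_given_inactive First-layer coupling used by
#'   the generator (defaults match [default_priors()]).
#' @param seed Mandatory RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @param prefix Sample-ID prefix.
#' @return A list with `expression` (probes x samples matrix, platform
#'   `"intensity"`), `labels` (named character) and `states` (genes x samples
#'   logical matrix of latent "up" states).
#' @examples
#' panel <- gene_panel("demo", paste0("G", 1:3))
#' sim <- simulate_cohort(panel, 5, 5, seed = 42)
#' dim(sim$expression)
#' @export
simulate_cohort <- function(panel, n_active, n_inactive, mean_up = 8,
                            mean_down = 5, sd = 1, frac_conflicting = 0,
                            p_up_given_active = 0.95,
                            p_up_given_inactive = 0.05, seed = NULL,
                            prefix = "S") {
  if (n_active < 0 || n_inactive < 0) {
    pathsig_error("sample counts must be >= 0", "pathsig_config_error")
  }
  if (!is.finite(sd) || sd <= 0) {
    pathsig_error("`sd` must be > 0", "pathsig_config_error")
  }
  if (frac_conflicting < 0 || frac_conflicting > 1) {
    pathsig_error("`frac_conflicting` must lie in [0, 1]", "pathsig_config_error")
  }
  check_prob_open(c(p_up_given_active, p_up_given_inactive), "first-layer coupling")
  n <- n_active + n_inactive
  labels <- setNames(rep(c("active", "inactive"), c(n_active, n_inactive)),
                     sprintf("%s%03d", prefix, seq_len(n)))
  genes <- panel$genes$gene
  dirs <- panel$genes$direction
  pp <- panel_probes(panel)
  with_seed(seed, {
    # P(up | label), direction-resolved, per gene x sample
    p_up <- outer(dirs == 1L, labels == "active",
                  function(d, a) ifelse(d == a, p_up_given_active, p_up_given_inactive))
    states <- matrix(runif(length(genes) * n) < p_up, nrow = length(genes),
                     dimnames = list(genes, names(labels)))
    if (frac_conflicting > 0) {
      flip <- matrix(runif(length(states)) < frac_conflicting, nrow = nrow(states))
      states <- xor(states, flip)
    }
    mu <- ifelse(states[pp$gene, , drop = FALSE], mean_up, mean_down)
    x <- mu + matrix(rnorm(nrow(pp) * n, sd = sd), nrow = nrow(pp))
    dimnames(x) <- list(pp$probe, names(labels))
    attr(x, "platform") <- "intensity"
    list(expression = x, labels = labels, states = states)
  })
}

#' Degrade a matrix to emulate low-input measurement
#'
#' Emulates the stochastic signal loss of very small analytes (FFPE scrapes,
#' circulating tumor cells, diluted input): each measurement is independently
#' set missing with probability `dropout_rate`, and surviving values are
#' perturbed with extra Gaussian noise. Purely a statistical noise model; no
#' pre-amplification chemistry is simulated.
#'
#' @param x Probes x samples matrix.
#' @param dropout_rate Per-measurement missingness probability in [0, 1].
#' @param extra_sd Standard deviation of added noise (>= 0).
#' @param seed Mandatory RNG seed.
#' @return The degraded matrix (attributes preserved).
#' @export
degrade_low_input <- function(x, dropout_rate, extra_sd = 0, seed = NULL) {
  if (dropout_rate < 0 || dropout_rate > 1) {
    pathsig_error("`dropout_rate` must lie in [0, 1]", "pathsig_config_error")
  }
  if (extra_sd < 0) {
    pathsig_error("`extra_sd` must be >= 0", "pathsig_config_error")
  }
  out <- x
  with_seed(seed, {
    drop <- matrix(runif(length(out)) < dropout_rate, nrow = nrow(out))
    noise <- matrix(rnorm(length(out), sd = extra_sd), nrow = nrow(out))
    out[] <- ifelse(drop, NA_real_, out + noise)
    out
  })
}

#' Simulate qPCR re-measurement of an expression matrix
#'
#' Converts relative log2 expression to raw Cq cycles —
#' `Cq(gene) = target_base_cq - expression + Normal(0, sd_cq)` — and adds
#' reference-gene rows at `ref_base_cq + Normal(0, sd_cq)`, so the very same
#' samples can be "re-measured" on the qPCR platform for platform-port
#' studies. [normalize_cq()] recovers the expression up to noise and the
#' constant offset `ref_base_cq - target_base_cq`. Raising `ref_base_cq`
#' toward the 32-35.5 range emulates diluted, low-input material.
#'
#' @param expression Probes x samples matrix of relative log2 expression.
#' @param panel A [gene_panel()] whose `reference_genes` are non-empty.
#' @param ref_base_cq Baseline Cq of the reference genes (default 28).
#' @param target_base_cq Cq of a target at expression 0 (default 28).
#' @param sd_cq Measurement noise in cycles (default 0.2).
#' @param seed Mandatory RNG seed.
#' @return A [cq_table()] with the panel's reference-gene rows appended.
#' @export
simulate_cq <- function(expression, panel, ref_base_cq = 28,
                        target_base_cq = 28, sd_cq = 0.2, seed = NULL) {
  x <- check_matrix(expression)
  refs <- panel$reference_genes
  if (!length(refs)) {
    pathsig_error("the panel defines no reference genes", "pathsig_config_error")
  }
  if (ref_base_cq <= 0 || ref_base_cq >= 40 || target_base_cq <= 0 || target_base_cq >= 40) {
    pathsig_error("base Cq values must lie in (0, 40)", "pathsig_config_error")
  }
  with_seed(seed, {
    cq_t <- target_base_cq - x +
      matrix(rnorm(length(x), sd = sd_cq), nrow = nrow(x))
    cq_r <- matrix(ref_base_cq + rnorm(length(refs) * ncol(x), sd = sd_cq),
                   nrow = length(refs),
                   dimnames = list(refs, colnames(x)))
    cq_table(rbind(cq_t, cq_r), reference_genes = refs)
  })
}

#' Simulate measurements from a fitted model's own parameters
#'
#' Generates a labeled cohort that is consistent with the model: per probe,
#' values are Gaussian around the calibrated threshold with means chosen so
#' that `P(value >= threshold | state)` equals the model's emission
#' probability exactly (`mean = threshold + sd * qnorm(p_high)`). Because
#' calibration hard-assigns target-gene states from labels, the default
#' generator does the same (`latent = "hard"`), making the emission
#' probabilities directly recoverable by re-calibration; `latent =
#' "stochastic"` draws the states from the first-layer coupling instead,
#' for robustness studies (the label-conditional dichotomization probability
#' is then a mixture, not the raw emission parameter).
#'
#' @param object A [pathway_model()].
#' @param nsim Samples per class (used for both unless `n_active` /
#'   `n_inactive` are given).
#' @param seed Mandatory RNG seed.
#' @param n_active,n_inactive Per-class sample counts.
#' @param sd Within-state measurement standard deviation (default 1).
#' @param latent `"hard"` (default) or `"stochastic"`, see above.
#' @param prefix Sample-ID prefix.
#' @param ... Ignored.
#' @return As [simulate_cohort()]: list with `expression`, `labels`,
#'   `states`.
#' @export
simulate.pathway_model <- function(object, nsim = 100, seed = NULL,
                                   n_active = nsim, n_inactive = nsim,
                                   sd = 1, latent = c("hard", "stochastic"),
                                   prefix = "S", ...) {
  latent <- match.arg(latent)
  if (!is.finite(sd) || sd <= 0) {
    pathsig_error("`sd` must be > 0", "pathsig_config_error")
  }
  panel <- object$panel
  genes <- panel$genes$gene
  dirs <- panel$genes$direction
  pp <- panel_probes(panel)
  em <- object$emissions[match(pp$probe, object$emissions$probe), , drop = FALSE]
  pr <- object$priors$genes
  n <- n_active + n_inactive
  labels <- setNames(rep(c("active", "inactive"), c(n_active, n_inactive)),
                     sprintf("%s%03d", prefix, seq_len(n)))
  with_seed(seed, {
    if (latent == "hard") {
      states <- outer(dirs == 1L, labels == "active", `==`)
    } else {
      p_up <- matrix(ifelse(rep(labels == "active", each = length(genes)),
                            pr$p_up_given_active, pr$p_up_given_inactive),
                     nrow = length(genes))
      states <- matrix(runif(length(genes) * n) < p_up, nrow = length(genes))
    }
    dimnames(states) <- list(genes, names(labels))
    mu_up <- em$threshold + sd * qnorm(em$p_high_given_up)
    mu_dn <- em$threshold + sd * qnorm(em$p_high_given_down)
    up <- states[pp$gene, , drop = FALSE]
    mu <- ifelse(up, mu_up[row(up)], mu_dn[row(up)])
    x <- mu + matrix(rnorm(nrow(pp) * n, sd = sd), nrow = nrow(pp))
    dimnames(x) <- list(pp$probe, names(labels))
    attr(x, "platform") <- if (object$platform == "cq") "cq-normalized" else "intensity"
    list(expression = x, labels = labels, states = states)
  })
}
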