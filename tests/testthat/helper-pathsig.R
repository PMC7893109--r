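# Shared fixtures: panels, models with known parameters, random valid models
# for property tests, and a rank-based AUC oracle.

make_panel <- function(n_genes = 12, directions = 1, pathway = "Wnt",
                       n_probes = 1, reference_genes = character()) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  probes <- NULL
  if (any(n_probes > 1)) {
    np <- rep_len(n_probes, n_genes)
    probes <- setNames(lapply(seq_len(n_genes), function(i) {
      sprintf("%s_p%d", genes[i], seq_len(np[i]))
    }), genes)
  }
  gene_panel(pathway, genes, directions, probes,
             reference_genes = reference_genes)
}

default_emissions <- function(panel, threshold = 6.5, p_high_up = 0.9,
                              p_high_down = 0.1) {
  emission_parameters(unlist(panel$probes, use.names = FALSE),
                      threshold, p_high_up, p_high_down)
}

default_model <- function(n_genes = 2, directions = 1, threshold = 6.5, ...) {
  panel <- make_panel(n_genes, directions = directions, ...)
  pathway_model(panel, default_priors(panel),
                default_emissions(panel, threshold = threshold))
}

# default-parameter per-gene evidence weight: log2(0.86/0.14)
DEFAULT_LR <- log2((0.95 * 0.9 + 0.05 * 0.1) / (0.05 * 0.9 + 0.95 * 0.1))

# Wilcoxon/Mann-Whitney AUC of active vs inactive scores
auc_score <- function(scores, labels) {
  a <- scores[labels == "active"]
  b <- scores[labels == "inactive"]
  cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  mean(cmp)
}

# random valid model under the current RNG state: directions, priors and
# emissions all respect the model invariants (informative orientation)
random_model <- function(n_genes = sample(2:12, 1), max_probes = 2,
                         pathway = "rand") {
  dirs <- sample(c(1L, -1L), n_genes, replace = TRUE)
  np <- sample(seq_len(max_probes), n_genes, replace = TRUE)
  panel <- local({
    genes <- sprintf("G%02d", seq_len(n_genes))
    probes <- setNames(lapply(seq_len(n_genes), function(i) {
      sprintf("%s_p%d", genes[i], seq_len(np[i]))
    }), genes)
    gene_panel(pathway, genes, dirs, probes)
  })
  p_hi <- runif(n_genes, 0.6, 0.99)
  p_lo <- runif(n_genes, 0.01, 0.4)
  priors <- pathway_priors(runif(1, 0.2, 0.8), panel$genes$gene,
                           ifelse(dirs == 1L, p_hi, p_lo),
                           ifelse(dirs == 1L, p_lo, p_hi))
  probes <- unlist(panel$probes, use.names = FALSE)
  emissions <- emission_parameters(
    probes,
    threshold = runif(length(probes), 4, 9),
    p_high_given_up = runif(length(probes), 0.55, 0.99),
    p_high_given_down = runif(length(probes), 0.01, 0.45)
  )
  pathway_model(panel, priors, emissions)
}

# random sample values for a model's probes; missing with prob p_missing
random_values <- function(model, p_missing = 0.2) {
  em <- model$emissions
  v <- em$threshold + sample(c(-1, 1), nrow(em), replace = TRUE) * runif(nrow(em), 0.1, 3)
  v[runif(nrow(em)) < p_missing] <- NA_real_
  setNames(v, em$probe)
}
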