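#' Define a pathway gene panel
#'
#' A gene panel names the direct target genes of one pathway's transcription
#' factor, the regulation direction of each gene, and the measurement
#' probes/assays that report on it. Panels are curated inputs: evidence
#' grading of target genes is out of scope for this package.
#'
#' @param pathway Pathway name, e.g. `"Wnt"` or `"ER"`.
#' @param genes Character vector of target gene symbols (at least 2, unique).
#' @param directions Regulation sign per gene: `+1` if the gene is induced by
#'   the active transcription factor, `-1` if repressed. Recycled if scalar.
#' @param probes Named list mapping each gene to a non-empty character vector
#'   of probe/assay identifiers. Defaults to one probe per gene, named after
#'   the gene itself (the qPCR convention).
#' @param reference_genes Character vector of stably expressed reference
#'   (housekeeping) genes used for Cq normalization; must be disjoint from
#'   `genes`. May be empty for intensity platforms.
#' @param inverse_of Optional pathway name whose activity is reported as the
#'   inverse of this panel's readout (e.g. PI3K activity is the inverse of
#'   measured FOXO activity). Carried through to results as an annotation
#'   only; scores are never numerically inverted.
#'
#' @return An object of class `gene_panel`.
#' @examples
#' gene_panel("Wnt", c("AXIN2", "LGR5", "ASCL2"), directions = 1)
#' @export
gene_panel <- function(pathway, genes, directions = 1, probes = NULL,
                       reference_genes = character(), inverse_of = NULL) {
  if (!is.character(pathway) || length(pathway) != 1L || !nzchar(pathway)) {
    pathsig_error("`pathway` must be a single non-empty string", "pathsig_config_error")
  }
  genes <- as.character(genes)
  if (length(genes) < 2L) {
    pathsig_error("a gene panel needs at least 2 target genes", "pathsig_config_error")
  }
  if (anyDuplicated(genes)) {
    pathsig_error(sprintf("duplicate target gene(s): %s",
                          paste(unique(genes[duplicated(genes)]), collapse = ", ")),
                  "pathsig_config_error")
  }
  directions <- as.integer(rep_len(directions, length(genes)))
  if (!all(directions %in% c(-1L, 1L))) {
    pathsig_error("`directions` must be +1 or -1 per gene", "pathsig_config_error")
  }
  if (is.null(probes)) probes <- setNames(as.list(genes), genes)
  if (!is.list(probes) || is.null(names(probes)) ||
      !setequal(names(probes), genes) || anyDuplicated(names(probes))) {
    pathsig_error("`probes` must be a list with exactly one entry per target gene",
                  "pathsig_config_error")
  }
  probes <- lapply(probes[genes], as.character)
  if (any(vapply(probes, length, 1L) == 0L)) {
    empty <- genes[vapply(probes, length, 1L) == 0L]
    pathsig_error(sprintf("gene(s) without probes: %s", paste(empty, collapse = ", ")),
                  "pathsig_config_error")
  }
  all_probes <- unlist(probes, use.names = FALSE)
  if (anyDuplicated(all_probes)) {
    pathsig_error(sprintf("probe IDs must be unique within a panel; duplicated: %s",
                          paste(unique(all_probes[duplicated(all_probes)]), collapse = ", ")),
                  "pathsig_config_error")
  }
  reference_genes <- as.character(reference_genes)
  if (length(intersect(reference_genes, genes))) {
    pathsig_error("reference genes must be disjoint from target genes",
                  "pathsig_config_error")
  }
  if (!is.null(inverse_of) &&
      (!is.character(inverse_of) || length(inverse_of) != 1L)) {
    pathsig_error("`inverse_of` must be NULL or a single pathway name",
                  "pathsig_config_error")
  }
  structure(
    list(pathway = pathway,
         genes = data.frame(gene = genes, direction = directions,
                            stringsAsFactors = FALSE),
         probes = probes,
         reference_genes = reference_genes,
         inverse_of = inverse_of),
    class = "gene_panel"
  )
}

# long view: one row per probe, with its gene and direction
panel_probes <- function(panel) {
  g <- panel$genes
  n <- vapply(panel$probes[g$gene], length, 1L)
  data.frame(probe = unlist(panel$probes[g$gene], use.names = FALSE),
             gene = rep(g$gene, n),
             direction = rep(g$direction, n),
             stringsAsFactors = FALSE)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("Gene panel for the %s pathway\n", x$pathway))
  cat(sprintf("  %d target genes (%d induced, %d repressed), %d probes\n",
              nrow(x$genes), sum(x$genes$direction == 1),
              sum(x$genes$direction == -1),
              length(unlist(x$probes))))
  if (length(x$reference_genes)) {
    cat("  reference genes:", paste(x$reference_genes, collapse = ", "), "\n")
  }
  if (!is.null(x$inverse_of)) {
    cat(sprintf("  note: %s activity is reported as the inverse of measured %s activity\n",
                x$inverse_of, x$pathway))
  }
  invisible(x)
}

#' First-layer (literature) prior parameters
#'
#' The first network layer encodes how tightly each target gene's
#' transcription state is coupled to transcription-factor activity. The
#' defaults express a strong but non-degenerate literature-based coupling;
#' repressed (direction -1) genes get the swapped probabilities, so the
#' measurement layer stays purely about measurement behaviour.
#'
#' @param panel A [gene_panel()].
#' @param p_tf_active Prior probability that the pathway is active; the
#'   default 0.5 makes log2 odds 0 the neutral point.
#' @param p_up_given_active,p_up_given_inactive Probability that a
#'   direction +1 gene is transcribed "up" given the active resp. inactive
#'   transcription factor (swapped for direction -1 genes).
#'
#' @return An object of class `pathway_priors`.
#' @export
default_priors <- function(panel, p_tf_active = 0.5,
                           p_up_given_active = 0.95,
                           p_up_given_inactive = 0.05) {
  check_prob_open(c(p_tf_active, p_up_given_active, p_up_given_inactive),
                  "prior probabilities")
  g <- panel$genes
  up_act <- ifelse(g$direction == 1L, p_up_given_active, p_up_given_inactive)
  up_inact <- ifelse(g$direction == 1L, p_up_given_inactive, p_up_given_active)
  pathway_priors(p_tf_active, g$gene, up_act, up_inact)
}

#' Construct first-layer prior parameters explicitly
#'
#' @param p_tf_active Prior probability of transcription-factor activation.
#' @param gene Character vector of gene symbols.
#' @param p_up_given_active,p_up_given_inactive Per-gene probabilities that
#'   the gene's transcription state is "up" given the active resp. inactive
#'   transcription factor. These are direction-resolved: for a repressed
#'   gene, `p_up_given_active < p_up_given_inactive`.
#'
#' @return An object of class `pathway_priors`.
#' @export
pathway_priors <- function(p_tf_active, gene, p_up_given_active,
                           p_up_given_inactive) {
  check_prob_open(p_tf_active, "p_tf_active")
  check_prob_open(p_up_given_active, "p_up_given_active")
  check_prob_open(p_up_given_inactive, "p_up_given_inactive")
  gene <- as.character(gene)
  if (anyDuplicated(gene)) {
    pathsig_error("duplicate gene in priors", "pathsig_config_error")
  }
  structure(
    list(p_tf_active = p_tf_active,
         genes = data.frame(gene = gene,
                            p_up_given_active = rep_len(p_up_given_active, length(gene)),
                            p_up_given_inactive = rep_len(p_up_given_inactive, length(gene)),
                            stringsAsFactors = FALSE)),
    class = "pathway_priors"
  )
}

#' Construct second-layer (emission) parameters explicitly
#'
#' One record per probe: the dichotomization threshold (same units as the
#' measurements) and the probabilities that the dichotomized measurement
#' reads "high" given the latent target-gene state. Usually produced by
#' [calibrate()] or [fit_emissions()] rather than by hand.
#'
#' @param probe Character vector of probe identifiers.
#' @param threshold Numeric dichotomization threshold per probe; a value
#'   `>= threshold` reads "high".
#' @param p_high_given_up,p_high_given_down Per-probe probabilities of a
#'   "high" reading given the target gene is up resp. down; strictly inside
#'   (0,1), which calibration enforces by Laplace smoothing.
#'
#' @return An object of class `emission_parameters` (a data frame).
#' @export
emission_parameters <- function(probe, threshold, p_high_given_up,
                                p_high_given_down) {
  probe <- as.character(probe)
  if (anyDuplicated(probe)) {
    pathsig_error("duplicate probe in emission parameters", "pathsig_config_error")
  }
  if (any(!is.finite(threshold))) {
    pathsig_error("emission thresholds must be finite", "pathsig_config_error")
  }
  check_prob_open(p_high_given_up, "p_high_given_up")
  check_prob_open(p_high_given_down, "p_high_given_down")
  structure(
    data.frame(probe = probe,
               threshold = rep_len(as.numeric(threshold), length(probe)),
               p_high_given_up = rep_len(p_high_given_up, length(probe)),
               p_high_given_down = rep_len(p_high_given_down, length(probe)),
               stringsAsFactors = FALSE),
    class = c("emission_parameters", "data.frame")
  )
}

#' Read / write a panel configuration file
#'
#' Panels are exchanged as self-describing JSON with keys `pathway`,
#' `target_genes` (objects with `gene`, `direction`, `probes`),
#' `reference_genes` and optional `inverse_of`.
#'
#' @param path File path.
#' @return `read_panel()` returns a [gene_panel()]; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    pathsig_error(sprintf("cannot parse panel file '%s': %s",
                                          path, conditionMessage(e)),
                                  "pathsig_parse_error")
                  })
  need <- c("pathway", "target_genes")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    pathsig_error(sprintf("panel file missing key(s): %s", paste(miss, collapse = ", ")),
                  "pathsig_schema_error")
  }
  tg <- obj$target_genes
  if (is.data.frame(tg)) {
    genes <- tg$gene
    directions <- tg$direction
    probes <- setNames(lapply(seq_len(nrow(tg)), function(i) {
      p <- tg$probes[[i]] %||% tg$gene[[i]]
      as.character(unlist(p))
    }), genes)
  } else {
    genes <- vapply(tg, function(e) as.character(e$gene), "")
    directions <- vapply(tg, function(e) as.integer(e$direction), 1L)
    probes <- setNames(lapply(tg, function(e) as.character(unlist(e$probes %||% e$gene))),
                       genes)
  }
  gene_panel(obj$pathway, genes, directions, probes,
             reference_genes = as.character(obj$reference_genes %||% character()),
             inverse_of = obj$inverse_of %||% NULL)
}

#' @param panel A [gene_panel()].
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  obj <- list(
    pathway = panel$pathway,
    target_genes = lapply(seq_len(nrow(panel$genes)), function(i) {
      g <- panel$genes$gene[i]
      list(gene = g, direction = panel$genes$direction[i],
           probes = as.list(panel$probes[[g]]))
    }),
    reference_genes = as.list(panel$reference_genes)
  )
  if (!is.null(panel$inverse_of)) obj$inverse_of <- panel$inverse_of
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}
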