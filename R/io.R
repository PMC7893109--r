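# Plain-text I/O: expression matrices, Cq tables, ground-truth labels,
# results and reference score files. Parsing is deliberately strict
# (duplicate IDs, ragged rows and non-numeric cells are errors with line
# numbers) and locale-independent (decimal point only).

NA_TOKENS <- c("", "NA", "NaN")

split_fields <- function(line, sep) strsplit(line, sep, fixed = TRUE)[[1]]

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample IDs and a first column of probe IDs. Cells
#' are numeric on a log2-like scale; `NA` or empty cells are missing values
#' (propagated downstream as missing evidence, never as "low").
#'
#' @param path File path.
#' @param sep Field separator; by default inferred from the extension
#'   (`.csv` -> comma, otherwise tab).
#' @return A probes x samples numeric matrix with
#'   `attr(, "platform") = "intensity"`.
#' @export
read_expression <- function(path, sep = NULL) {
  m <- parse_matrix(path, sep, what = "expression matrix")
  if (any(is.infinite(m))) {
    pathsig_error(sprintf("non-finite values in '%s'", path), "pathsig_parse_error")
  }
  attr(m, "platform") <- "intensity"
  m
}

# shared strict matrix parser
parse_matrix <- function(path, sep = NULL, what = "matrix") {
  sep <- infer_sep(path, sep)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > 1 & lines == "")]  # ignore trailing blanks
  if (length(lines) < 2L) {
    pathsig_error(sprintf("%s '%s' has no data rows", what, path), "pathsig_parse_error")
  }
  header <- split_fields(lines[1], sep)
  rows <- lapply(lines[-1], split_fields, sep = sep)
  widths <- vapply(rows, length, 1L)
  # header may or may not carry a leading corner label for the probe column
  n_fields <- widths[1]
  samples <- if (length(header) == n_fields - 1L) header else header[-1]
  if (length(header) %in% c(n_fields - 1L, n_fields) == FALSE) {
    pathsig_error(sprintf("line 1: header has %d fields, data rows have %d",
                          length(header), n_fields),
                  "pathsig_parse_error")
  }
  bad <- which(widths != n_fields)
  if (length(bad)) {
    pathsig_error(sprintf("line %d: ragged row (%d fields, expected %d)",
                          bad[1] + 1L, widths[bad[1]], n_fields),
                  "pathsig_parse_error")
  }
  if (anyDuplicated(samples)) {
    pathsig_error(sprintf("duplicate sample ID(s) in header: %s",
                          paste(unique(samples[duplicated(samples)]), collapse = ", ")),
                  "pathsig_parse_error")
  }
  probes <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(probes)) {
    pathsig_error(sprintf("duplicate probe row(s): %s",
                          paste(unique(probes[duplicated(probes)]), collapse = ", ")),
                  "pathsig_parse_error")
  }
  m <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
              dimnames = list(probes, samples))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1L]
    miss <- cells %in% NA_TOKENS
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !miss)
    if (length(bad)) {
      pathsig_error(sprintf("line %d: non-numeric cell '%s' (column %s)",
                            i + 1L, cells[bad[1]], samples[bad[1]]),
                    "pathsig_parse_error")
    }
    vals[miss] <- NA_real_
    m[i, ] <- vals
  }
  m
}

#' Construct a raw qPCR Cq table
#'
#' A Cq table is an assays x samples matrix of raw quantification cycles
#' (lower Cq = more transcript) together with the designated reference-gene
#' rows used for delta-Cq normalization.
#'
#' @param x Numeric matrix of Cq values (positive or missing), assays x
#'   samples. Rows must include the reference genes.
#' @param reference_genes Character vector (>= 1) of reference-gene row
#'   names.
#' @return An object of class `cq_table` (a matrix with attributes).
#' @export
cq_table <- function(x, reference_genes) {
  x <- check_matrix(x, what = "Cq table")
  reference_genes <- as.character(reference_genes)
  if (!length(reference_genes)) {
    pathsig_error("at least one reference gene is required", "pathsig_config_error")
  }
  miss <- setdiff(reference_genes, rownames(x))
  if (length(miss)) {
    pathsig_error(sprintf("reference gene(s) absent from Cq table: %s",
                          paste(miss, collapse = ", ")),
                  "pathsig_config_error")
  }
  if (any(x <= 0, na.rm = TRUE)) {
    pathsig_error("Cq values must be positive", "pathsig_config_error")
  }
  structure(x, reference_genes = reference_genes, class = c("cq_table", "matrix"))
}

#' @rdname cq_table
#' @param path File path of a TSV/CSV Cq table (layout as in
#'   [read_expression()]).
#' @param sep Field separator, see [read_expression()].
#' @export
read_cq <- function(path, reference_genes, sep = NULL) {
  cq_table(parse_matrix(path, sep, what = "Cq table"), reference_genes)
}

#' Reference-gene delta-Cq normalization
#'
#' Converts raw Cq values to relative log2 expression:
#' `expr(gene) = mean(Cq of reference genes) - Cq(gene)`, per sample, so that
#' larger values mean more transcript (matching the intensity-scale
#' orientation — one calibration code path serves both platforms). Cq values
#' above `cq_max` (no-amplification convention) or missing become missing
#' expression. Samples without any valid reference gene are dropped, listed
#' in `attr(, "dropped_samples")` and in a warning. The transform is
#' shift-invariant: a constant added to every Cq of a sample (a global
#' efficiency shift) cancels out. Amplification efficiency is assumed to be
#' 2.0 (no efficiency correction).
#'
#' @param cq A [cq_table()].
#' @param reference_genes Reference-gene rows; defaults to the table's own.
#' @param cq_max No-amplification cutoff (default 40 cycles).
#' @return Targets x samples expression matrix with
#'   `attr(, "platform") = "cq-normalized"`; reference-gene rows are not
#'   included.
#' @examples
#' cq <- cq_table(matrix(c(24, 26, 22), 3, 1,
#'                       dimnames = list(c("R1", "R2", "G1"), "s1")),
#'                reference_genes = c("R1", "R2"))
#' normalize_cq(cq)  # G1: 25 - 22 = +3
#' @export
normalize_cq <- function(cq, reference_genes = attr(cq, "reference_genes"),
                         cq_max = 40) {
  if (!inherits(cq, "cq_table")) cq <- cq_table(cq, reference_genes)
  x <- unclass(cq)
  attr(x, "reference_genes") <- NULL
  x[!is.na(x) & x > cq_max] <- NA_real_
  refs <- x[reference_genes, , drop = FALSE]
  ref_mean <- colMeans(refs, na.rm = TRUE)  # NaN when all refs invalid
  valid <- is.finite(ref_mean)
  dropped <- colnames(x)[!valid]
  if (length(dropped)) {
    warning(sprintf("dropping sample(s) without a valid reference gene: %s",
                    paste(dropped, collapse = ", ")))
  }
  targets <- setdiff(rownames(x), reference_genes)
  out <- sweep(-x[targets, valid, drop = FALSE], 2L, ref_mean[valid], `+`)
  attr(out, "platform") <- "cq-normalized"
  attr(out, "dropped_samples") <- dropped
  out
}

#' Read ground-truth labels
#'
#' A two-column TSV (`sample_id`, `label`) with a header row. Labels are
#' case-insensitive `active`/`inactive` and are canonicalized to lower case;
#' anything else is a parse error.
#'
#' @param path File path.
#' @return Named character vector, sample_id -> "active"/"inactive".
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    pathsig_error(sprintf("labels file '%s' has no data rows", path),
                  "pathsig_parse_error")
  }
  rows <- lapply(lines[-1], split_fields, sep = "\t")
  bad <- which(vapply(rows, length, 1L) != 2L)
  if (length(bad)) {
    pathsig_error(sprintf("line %d: expected 2 tab-separated fields", bad[1] + 1L),
                  "pathsig_parse_error")
  }
  labels <- setNames(vapply(rows, `[[`, "", 2L), vapply(rows, `[[`, "", 1L))
  check_labels(labels)
}

#' @rdname read_labels
#' @param labels Named character vector of labels.
#' @export
write_labels <- function(labels, path) {
  labels <- check_labels(labels)
  df <- data.frame(sample_id = names(labels), label = unname(labels))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV/CSV
#'
#' @param x Probes x samples matrix.
#' @param path File path (extension decides the separator unless `sep` is
#'   given).
#' @param sep Field separator override.
#' @export
write_expression <- function(x, path, sep = NULL) {
  x <- check_matrix(x)
  sep <- infer_sep(path, sep)
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read pathway activity results
#'
#' The results TSV carries `sample_id`, `pathway`, `log2_odds`, `score`,
#' `n_missing_genes` and `error`; values round-trip to at least 6 decimals.
#' Per-gene evidence contributions can be written alongside with
#' [write_contributions()].
#'
#' @param results A `pathway_scores` data frame from [infer_activity()].
#' @param path File path.
#' @return `path` invisibly (writes); a `pathway_scores`-shaped data frame
#'   (reads).
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 10, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pathway", "log2_odds", "score", "n_missing_genes")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    pathsig_error(sprintf("results file missing column(s): %s",
                          paste(miss, collapse = ", ")),
                  "pathsig_schema_error")
  }
  if (is.null(df$error)) df$error <- NA_character_
  df
}

#' @rdname write_results
#' @export
write_contributions <- function(results, path) {
  contrib <- attr(results, "contributions")
  if (is.null(contrib)) {
    pathsig_error("results carry no contribution matrix", "pathsig_config_error")
  }
  df <- data.frame(gene = rownames(contrib), contrib, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read reference score files
#'
#' Reference scores travel as a TSV with columns `tissue`, `pathway`,
#' `sample_id`, `score`; [read_reference()] rebuilds one
#' [reference_distribution()] per (tissue, pathway) group, recomputing the
#' threshold deterministically from the scores.
#'
#' @param ref A [reference_distribution()] or list of them.
#' @param path File path.
#' @param q Percentile used when rebuilding distributions (default 95).
#' @return `path` invisibly (writes); a list of [reference_distribution()]
#'   (reads).
#' @export
write_reference <- function(ref, path) {
  if (inherits(ref, "reference_distribution")) ref <- list(ref)
  df <- do.call(rbind, lapply(ref, function(r) {
    data.frame(tissue = r$tissue, pathway = r$pathway,
               sample_id = sprintf("ref%03d", seq_along(r$scores)),
               score = r$scores, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path, q = 95) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tissue", "pathway", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    pathsig_error(sprintf("reference file missing column(s): %s",
                          paste(miss, collapse = ", ")),
                  "pathsig_schema_error")
  }
  groups <- split(df, paste(df$tissue, df$pathway, sep = "\r"))
  unname(lapply(groups, function(g) {
    reference_distribution(g$score, pathway = g$pathway[1],
                           tissue = g$tissue[1], q = q)
  }))
}
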