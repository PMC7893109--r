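# Healthy-tissue reference distributions, the 95th-percentile-of-normal
# abnormality threshold, and multi-pathway patient reports.

# pinned percentile rule: linear interpolation between order statistics at
# rank h = 1 + (n - 1) * q / 100 (identical to stats::quantile type 7)
percentile_interp <- function(scores, q) {
  s <- sort(scores)
  n <- length(s)
  h <- 1 + (n - 1) * q / 100
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

#' Build a healthy-tissue reference distribution
#'
#' Collects pathway activity scores measured on healthy reference tissue and
#' fixes the abnormality threshold at the `q`-th percentile (default the 95th
#' percentile of normal). The percentile is computed by linear interpolation
#' between order statistics at rank `h = 1 + (n - 1) q / 100`; different
#' percentile conventions shift thresholds, so this one is pinned and tested.
#'
#' @param scores Numeric vector of reference activity scores (n >= 5, finite).
#' @param pathway Pathway name the scores belong to.
#' @param tissue Reference tissue label.
#' @param q Percentile in (0, 100); default 95.
#' @return An object of class `reference_distribution` with the computed
#'   `threshold`.
#' @examples
#' r <- reference_distribution(seq(10, 100, by = 10), pathway = "ER")
#' r$threshold  # 95.5
#' @export
reference_distribution <- function(scores, pathway, tissue = "unspecified",
                                   q = 95) {
  scores <- as.numeric(scores)
  if (length(scores) < 5L || any(!is.finite(scores))) {
    pathsig_error("a reference distribution needs >= 5 finite scores",
                  "pathsig_config_error")
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 100) {
    pathsig_error("`q` must lie strictly between 0 and 100", "pathsig_config_error")
  }
  structure(
    list(tissue = tissue, pathway = pathway, scores = scores, q = q,
         threshold = percentile_interp(scores, q)),
    class = "reference_distribution"
  )
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("Reference distribution: %s pathway in %s tissue (n = %d)\n",
              x$pathway, x$tissue, length(x$scores)))
  cat(sprintf("  %gth percentile of normal (threshold): %.3f\n", x$q, x$threshold))
  invisible(x)
}

#' Classify a pathway activity score against a reference
#'
#' A score strictly above the reference threshold is called
#' `"above-threshold"` — the pathway's activity is considered abnormal and
#' potentially tumor driving (and targetable); a score at or below the
#' threshold is `"within-normal"`.
#'
#' @param result Either a single-row `pathway_scores` data frame (its
#'   `pathway` must match the reference's) or a bare numeric score.
#' @param ref A [reference_distribution()].
#' @return An object of class `pathway_call`.
#' @export
classify_activity <- function(result, ref) {
  if (!inherits(ref, "reference_distribution")) {
    pathsig_error("`ref` must be a reference_distribution", "pathsig_config_error")
  }
  if (is.data.frame(result)) {
    if (nrow(result) != 1L) {
      pathsig_error("classify one sample at a time (one-row result expected)",
                    "pathsig_config_error")
    }
    if (!identical(result$pathway[[1]], ref$pathway)) {
      pathsig_error(sprintf("pathway mismatch: result is %s, reference is %s",
                            result$pathway[[1]], ref$pathway),
                    "pathsig_config_error")
    }
    score <- result$score[[1]]
  } else if (is.numeric(result) && length(result) == 1L) {
    score <- result
  } else {
    pathsig_error("`result` must be a one-row pathway_scores or a numeric score",
                  "pathsig_config_error")
  }
  if (!is.finite(score)) {
    pathsig_error("cannot classify a missing score", "pathsig_config_error")
  }
  call <- if (score > ref$threshold) "above-threshold" else "within-normal"
  structure(
    list(pathway = ref$pathway, score = score, threshold = ref$threshold,
         call = call,
         potentially_tumor_driving = call == "above-threshold"),
    class = "pathway_call"
  )
}

#' @export
print.pathway_call <- function(x, ...) {
  cat(sprintf("%s pathway: score %.2f vs threshold %.2f -> %s\n",
              x$pathway, x$score, x$threshold, x$call))
  if (x$potentially_tumor_driving) {
    cat("  activity is considered potentially tumor driving and targetable\n")
  }
  invisible(x)
}

#' Assemble a multi-pathway patient report
#'
#' One call per analyzed pathway: the measured activity score, the
#' healthy-reference threshold, and the within-normal / above-threshold
#' call, in stable (alphabetical) pathway order. Optionally, cancer-type
#' score sets provide descriptive context (median and quartiles) per pathway.
#'
#' @param sample_id Identifier of the patient sample.
#' @param results Scores for this sample: a `pathway_scores` data frame with
#'   one row per pathway (rows from several models may be `rbind`ed), or a
#'   list of such one-row frames.
#' @param refs A list of [reference_distribution()] objects (or a single
#'   one); every result pathway must have a matching reference.
#' @param tissue Optional tissue label for the report header.
#' @param cancer_refs Optional named list (pathway -> numeric score set) of
#'   cancer-type score distributions for context.
#' @return An object of class `patient_report`.
#' @export
patient_report <- function(sample_id, results, refs, tissue = NULL,
                           cancer_refs = NULL) {
  if (inherits(refs, "reference_distribution")) refs <- list(refs)
  if (!length(refs) || !all(vapply(refs, inherits, TRUE, "reference_distribution"))) {
    pathsig_error("`refs` must be reference_distribution objects", "pathsig_config_error")
  }
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (!is.data.frame(results) || !all(c("pathway", "score") %in% names(results))) {
    pathsig_error("`results` must carry `pathway` and `score` columns",
                  "pathsig_config_error")
  }
  if (anyDuplicated(results$pathway)) {
    pathsig_error("one result per pathway expected", "pathsig_config_error")
  }
  ref_paths <- vapply(refs, function(r) r$pathway, "")
  miss <- setdiff(results$pathway, ref_paths)
  if (length(miss)) {
    pathsig_error(sprintf("no reference distribution for pathway(s): %s",
                          paste(miss, collapse = ", ")),
                  "pathsig_config_error")
  }
  ord <- order(results$pathway)
  calls <- do.call(rbind, lapply(ord, function(i) {
    ref <- refs[[match(results$pathway[i], ref_paths)]]
    pc <- classify_activity(results$score[i], ref)
    data.frame(pathway = ref$pathway, score = pc$score,
               threshold = pc$threshold, call = pc$call,
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  context <- NULL
  if (!is.null(cancer_refs)) {
    context <- do.call(rbind, lapply(names(cancer_refs), function(p) {
      s <- as.numeric(cancer_refs[[p]])
      data.frame(pathway = p, n = length(s),
                 q25 = unname(quantile(s, 0.25, type = 7)),
                 median = median(s),
                 q75 = unname(quantile(s, 0.75, type = 7)),
                 stringsAsFactors = FALSE)
    }))
    context <- context[order(context$pathway), , drop = FALSE]
    rownames(context) <- NULL
  }
  structure(
    list(sample_id = sample_id, tissue = tissue, calls = calls,
         context = context, format = "pathsig-report/1"),
    class = "patient_report"
  )
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("Patient report for sample %s%s\n", x$sample_id,
              if (is.null(x$tissue)) "" else sprintf(" (%s tissue)", x$tissue)))
  print(x$calls, digits = 4, row.names = FALSE)
  n_above <- sum(x$calls$call == "above-threshold")
  if (n_above) {
    cat(sprintf("  %d pathway(s) above the normal threshold: potentially tumor driving\n",
                n_above))
  }
  invisible(x)
}

#' Plot a patient report
#'
#' Scores (points) against healthy-reference thresholds (segments) per
#' pathway; above-threshold calls are highlighted.
#'
#' @param x A [patient_report()].
#' @param ... Ignored.
#' @export
plot.patient_report <- function(x, ...) {
  calls <- x$calls
  n <- nrow(calls)
  plot(NA, xlim = c(0, 100), ylim = c(0.5, n + 0.5), yaxt = "n",
       xlab = "pathway activity score", ylab = "",
       main = sprintf("Sample %s", x$sample_id))
  axis(2, at = seq_len(n), labels = calls$pathway, las = 1)
  segments(calls$threshold, seq_len(n) - 0.3, calls$threshold, seq_len(n) + 0.3,
           lty = 2)
  points(calls$score, seq_len(n), pch = 16,
         col = ifelse(calls$call == "above-threshold", "red3", "grey30"))
  invisible(x)
}

#' Write / read a patient report
#'
#' JSON (`format` = `"pathsig-report/1"`, round-trips via [read_report()]) or
#' a flat TSV of the calls table.
#'
#' @param report A [patient_report()].
#' @param path File path.
#' @param format `"json"` (default) or `"tsv"`.
#' @return `path` (write) or the reconstructed [patient_report()] (read),
#'   invisibly for writes.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(format = report$format, sample_id = report$sample_id,
                tissue = report$tissue, calls = report$calls,
                context = report$context)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "rows")
  } else {
    df <- cbind(sample_id = report$sample_id, report$calls)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    pathsig_error(sprintf("cannot parse report file '%s': %s",
                                          path, conditionMessage(e)),
                                  "pathsig_schema_error")
                  })
  fmt <- obj$format
  if (is.null(fmt) || !grepl("^pathsig-report/[0-9]+$", fmt)) {
    pathsig_error("report file has no valid 'format' field", "pathsig_schema_error")
  }
  if (as.integer(sub("^pathsig-report/", "", fmt)) != 1L) {
    pathsig_error(sprintf("report format '%s' is not supported", fmt),
                  "pathsig_version_error")
  }
  calls <- as.data.frame(obj$calls)
  context <- if (!is.null(obj$context)) as.data.frame(obj$context) else NULL
  structure(
    list(sample_id = obj$sample_id, tissue = obj$tissue, calls = calls,
         context = context, format = fmt),
    class = "patient_report"
  )
}
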