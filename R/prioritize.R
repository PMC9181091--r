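# Merge proximity and reversal results, filter by significance, apply the
# combined three-key ordering and export ranked / radial-plot tables.

#' Keep only drug-disease associations below a significance threshold
#'
#' Strict filter `p_emp < alpha`; kept and total counts are reported in a
#' "K of M" message.
#'
#' @param results Data frame from [score_all()] (needs a `p_emp` column).
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @return The kept subset, rows in their original order.
#' @export
filter_significant <- function(results, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  keep <- results$p_emp < alpha
  message(sprintf("significant associations: %d of %d at p < %g",
                  sum(keep), nrow(results), alpha))
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank repurposing candidates by similarity, reversal score and name
#'
#' The combined prioritization: candidates are sorted by network-based
#' similarity (descending, 1 is best), then by reversal (GSEA) score
#' (descending; a missing score sorts below 0), then alphabetically by
#' drug name (case-insensitive) and finally by drug id. Ranks are assigned
#' 1..K with no gaps. The ordering is total, so permuting the input rows
#' never changes the output.
#'
#' @param results Data frame with at least `drug_id`, `drug_name`,
#'   `similarity`, `p_emp` (typically the output of [filter_significant()]).
#' @param gsea_scores Optional data frame with `drug_id` and `gsea`
#'   columns (from [score_signatures()]); drugs without a row get `NA`.
#' @param annotations Optional named character vector, drug id to a target
#'   annotation carried into the output (e.g. "HNMT", "H1 receptor").
#' @return Data frame of ranked candidates: `rank`, `drug_id`, `drug_name`,
#'   `similarity`, `p_emp`, `gsea`, `target_annotation`.
#' @export
rank_candidates <- function(results, gsea_scores = NULL, annotations = NULL) {
  if (anyDuplicated(results$drug_id)) {
    stop("duplicate drug_id in results: ",
         paste(unique(results$drug_id[duplicated(results$drug_id)]),
               collapse = ", "))
  }
  gsea <- rep(NA_integer_, nrow(results))
  if (!is.null(gsea_scores)) {
    idx <- match(results$drug_id, gsea_scores$drug_id)
    gsea <- as.integer(gsea_scores$gsea[idx])
  }
  ann <- rep(NA_character_, nrow(results))
  if (!is.null(annotations)) {
    hit <- results$drug_id %in% names(annotations)
    ann[hit] <- unname(annotations[results$drug_id[hit]])
  }
  gsea_key <- ifelse(is.na(gsea), -1L, gsea)    # NA sorts below 0
  ord <- order(-results$similarity, -gsea_key,
               tolower(results$drug_name), results$drug_id)
  out <- data.frame(
    rank = seq_len(nrow(results)),
    drug_id = results$drug_id[ord],
    drug_name = results$drug_name[ord],
    similarity = results$similarity[ord],
    p_emp = results$p_emp[ord],
    gsea = gsea[ord],
    target_annotation = ann[ord],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export a radial-plot table of ranked candidates
#'
#' Radial-plot convention: radius `1 - similarity`, so the most proximal
#' drugs sit at the center and the most distant at the rim; the color key
#' is the reversal-score bucket (`"na"` for drugs without a profile).
#'
#' @param candidates Data frame from [rank_candidates()].
#' @param class_filter Optional target-annotation value; only candidates
#'   with that `target_annotation` are exported when given.
#' @return Data frame with `drug_id`, `drug_name`, `radius`, `color_key`.
#' @export
export_radial <- function(candidates, class_filter = NULL) {
  keep <- rep(TRUE, nrow(candidates))
  if (!is.null(class_filter)) {
    keep <- !is.na(candidates$target_annotation) &
      candidates$target_annotation == class_filter
  }
  cc <- candidates[keep, , drop = FALSE]
  out <- data.frame(
    drug_id = cc$drug_id,
    drug_name = cc$drug_name,
    radius = 1 - cc$similarity,
    color_key = ifelse(is.na(cc$gsea), "na", as.character(cc$gsea)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a ranked candidate table
#'
#' Plain TSV round-trip of the [rank_candidates()] output.
#'
#' @param candidates Data frame from [rank_candidates()].
#' @param path TSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_ranked <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_ranked
#' @export
read_ranked <- function(path) {
  out <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c(drug_id = "character",
                                   drug_name = "character",
                                   target_annotation = "character"))
  out$gsea <- as.integer(out$gsea)
  out$rank <- as.integer(out$rank)
  out
}
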