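# Differential-expression gene selection, signature-reversal (connectivity)
# scoring against drug expression profiles, and the integer per-drug
# reversal count over several disease datasets.

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure
#' (`q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' input order).
#'
#' @param pvalues Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NAs")
  }
  stats::p.adjust(p, method = "BH")
}

#' Construct a disease expression signature
#'
#' @param dataset_id Identifier of the expression dataset.
#' @param up,down Character vectors of genes higher / lower in disease;
#'   must be disjoint and not both empty.
#' @param alpha Adjusted-p threshold the signature was selected at.
#' @return A `disease_signature` object.
#' @export
disease_signature <- function(dataset_id, up, down, alpha = 0.05) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0L) {
    stop("up and down gene sets overlap in dataset ", dataset_id)
  }
  structure(list(dataset_id = dataset_id, up = up, down = down, alpha = alpha),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat(sprintf("<disease_signature> %s: %d up, %d down (alpha %g)\n",
              x$dataset_id, length(x$up), length(x$down), x$alpha))
  invisible(x)
}

#' Read a per-dataset differential-expression table
#'
#' TSV with header columns `gene_id`, `effect` (log fold change or just its
#' sign) and `p_raw`, one row per gene -- the shape of a GEO2R/limma export.
#'
#' @param path Path to the TSV.
#' @return Data frame with those three columns.
#' @export
read_de_table <- function(path) {
  tb <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c(gene_id = "character"))
  need <- c("gene_id", "effect", "p_raw")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0L) {
    stop("DE table ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  tb
}

#' @rdname read_de_table
#' @param table Data frame as returned by `read_de_table`.
#' @export
write_de_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select differentially expressed genes into a disease signature
#'
#' BH-adjusts the raw p-values and keeps genes with adjusted p strictly
#' below `alpha`, split into up- and down-regulated by the sign of
#' `effect`. Genes with a zero effect cannot be assigned a direction and
#' are dropped with a message.
#'
#' @param table Data frame with columns `gene_id`, `effect`, `p_raw`.
#' @param alpha Adjusted-p threshold in (0, 1) (default 0.05).
#' @param dataset_id Identifier stored on the resulting signature.
#' @return A `disease_signature`; empty signatures trigger a warning.
#' @export
select_de_genes <- function(table, alpha = 0.05, dataset_id = "dataset") {
  if (nrow(table) == 0L) stop("empty DE table")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  adj <- bh_adjust(table$p_raw)
  sig <- adj < alpha
  zero <- sig & table$effect == 0
  if (any(zero)) {
    message(sprintf("%d significant gene(s) with zero effect dropped", sum(zero)))
  }
  up <- table$gene_id[sig & table$effect > 0]
  down <- table$gene_id[sig & table$effect < 0]
  message(sprintf("%s: %d of %d genes pass BH < %g (%d up, %d down)",
                  dataset_id, length(up) + length(down), nrow(table), alpha,
                  length(up), length(down)))
  if (length(up) + length(down) == 0L) {
    warning("no genes survive the adjusted-p threshold in ", dataset_id)
  }
  structure(list(dataset_id = dataset_id, up = unique(up),
                 down = unique(down), alpha = alpha),
            class = "disease_signature")
}

#' Construct a drug expression signature
#'
#' @param drug_id Drug identifier.
#' @param scores Named numeric vector of per-gene differential statistics
#'   under drug treatment (positive = up-regulated by the drug); genes are
#'   stored sorted by decreasing score. Duplicate genes are an error.
#' @return A `drug_signature` object.
#' @export
drug_signature <- function(drug_id, scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be a named numeric vector of genes")
  }
  if (anyDuplicated(names(scores))) {
    stop("duplicate genes in the signature of drug ", drug_id)
  }
  ord <- order(-scores, names(scores))   # ties broken by gene id: deterministic
  structure(list(drug_id = drug_id, genes = names(scores)[ord],
                 scores = unname(scores[ord])),
            class = "drug_signature")
}

#' @export
print.drug_signature <- function(x, ...) {
  cat(sprintf("<drug_signature> %s: %d genes\n", x$drug_id, length(x$genes)))
  invisible(x)
}

#' Read a drug-signature library from a long TSV
#'
#' TSV with header columns `drug_id`, `gene_id`, `score`, one row per
#' drug-gene pair; each drug's rows become one ranked signature.
#'
#' @param path Path to the TSV.
#' @return Named list of `drug_signature` objects.
#' @export
read_drug_signatures <- function(path) {
  tb <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c(drug_id = "character", gene_id = "character"))
  need <- c("drug_id", "gene_id", "score")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0L) {
    stop("drug-signature table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  lapply(split(tb, tb$drug_id), function(rows) {
    drug_signature(rows$drug_id[1L], setNames(rows$score, rows$gene_id))
  })
}

#' @rdname read_drug_signatures
#' @param sigs Named list of `drug_signature` objects.
#' @export
write_drug_signatures <- function(sigs, path) {
  rows <- do.call(rbind, lapply(sigs, function(s) {
    data.frame(drug_id = s$drug_id, gene_id = s$genes, score = s$scores,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-signature library from paired GMT sets
#'
#' Alternative library format: a GMT file holding, per drug, sets named
#' `<drug_id>_UP` and `<drug_id>_DN`. Up genes get score +1, down genes
#' score -1 (an unweighted ranking with the up block first).
#'
#' @param path Path to the GMT file.
#' @return Named list of `drug_signature` objects.
#' @export
read_drug_signatures_gmt <- function(path) {
  sets <- read_gmt(path)
  ids <- sub("_(UP|DN)$", "", names(sets))
  out <- list()
  for (did in unique(ids)) {
    up <- sets[[paste0(did, "_UP")]]
    dn <- sets[[paste0(did, "_DN")]]
    scores <- c(
      if (!is.null(up)) setNames(rep(1, length(up$members)), up$members),
      if (!is.null(dn)) setNames(rep(-1, length(dn$members)), dn$members))
    if (is.null(scores)) next
    out[[did]] <- drug_signature(did, scores)
  }
  out
}

#' Weighted Kolmogorov-Smirnov running-sum enrichment score
#'
#' Classic GSEA statistic: walking the drug's ranked gene list from most
#' up-regulated to most down-regulated, the running sum increases by
#' `|score|^w / sum(|score|^w)` at members of `gene_set` and decreases by
#' `1 / (L - n_set)` elsewhere; the signed extremum is returned. Positive
#' values mean the set concentrates at the top of the ranking (the drug
#' up-regulates it), negative at the bottom.
#'
#' @param ranked A `drug_signature`.
#' @param gene_set Character vector of genes; must intersect the ranking.
#' @param weight Exponent `w` on the score weights (default 1).
#' @return Numeric in [-1, 1].
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(inherits(ranked, "drug_signature"))
  hit <- ranked$genes %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set does not intersect the ranked signature")
  L <- length(ranked$genes)
  if (n_hit == L) stop("gene set covers the whole ranking; score undefined")
  w <- abs(ranked$scores[hit])^weight
  if (sum(w) == 0) w <- rep(1, n_hit)
  steps <- numeric(L)
  steps[hit] <- w / sum(w)
  steps[!hit] <- -1 / (L - n_hit)
  running <- cumsum(steps)
  running[which.max(abs(running))]
}

#' Connectivity (signature-reversal) score of a drug against a disease
#'
#' Two-sided weighted-KS connectivity in the WTCS convention:
#' `ES_up` and `ES_dn` are the enrichment of the disease up- and
#' down-regulated sets in the drug's ranking; when their signs disagree the
#' score is `(ES_up - ES_dn) / 2`, otherwise 0. A negative score means the
#' drug's signature reverses the disease signature (it down-regulates the
#' disease-up genes and vice versa) -- the repurposing-relevant direction.
#'
#' @param drug A `drug_signature`.
#' @param disease A `disease_signature`; both its up and down sets must
#'   intersect the drug ranking (otherwise the pair is unusable and the
#'   caller should record a missing value).
#' @param weight KS weight exponent (default 1).
#' @return Numeric in [-1, 1].
#' @export
connectivity_score <- function(drug, disease, weight = 1) {
  stopifnot(inherits(drug, "drug_signature"),
            inherits(disease, "disease_signature"))
  if (!any(disease$up %in% drug$genes) || !any(disease$down %in% drug$genes)) {
    stop("disease up/down sets do not both intersect the drug ranking")
  }
  es_up <- enrichment_score(drug, disease$up, weight = weight)
  es_dn <- enrichment_score(drug, disease$down, weight = weight)
  if (es_up == 0 && es_dn == 0) return(0)
  if (sign(es_up) != sign(es_dn)) (es_up - es_dn) / 2 else 0
}

#' Integer reversal score of one drug over N disease datasets
#'
#' Counts the disease expression datasets whose signature the drug reverses
#' (connectivity strictly negative; zero does not count). `NA` if and only
#' if the drug has no signature in the library at all (`connectivities`
#' is `NULL`); unusable drug-dataset pairs enter as `NA` elements and are
#' not counted.
#'
#' @param drug_id Drug identifier.
#' @param connectivities Numeric vector of per-dataset connectivity scores
#'   (may contain `NA`), or `NULL` when the drug is absent from the
#'   signature library.
#' @param n_datasets Total number of disease datasets N (score range 0..N).
#' @return List with `drug_id`, integer `score` (or `NA`), `n_datasets`.
#' @export
gsea_score <- function(drug_id, connectivities, n_datasets) {
  if (n_datasets < 1L) stop("n_datasets must be >= 1")
  if (is.null(connectivities)) {
    return(list(drug_id = drug_id, score = NA_integer_,
                n_datasets = as.integer(n_datasets)))
  }
  if (length(connectivities) > n_datasets) {
    stop("more connectivity values than datasets for drug ", drug_id)
  }
  score <- sum(connectivities < 0, na.rm = TRUE)
  list(drug_id = drug_id, score = as.integer(score),
       n_datasets = as.integer(n_datasets))
}

#' Reversal scores for a whole drug library over all disease datasets
#'
#' Runs [connectivity_score()] for every (drug, dataset) pair and
#' aggregates with [gsea_score()]. Drugs listed in `drug_ids` but absent
#' from `drug_sigs` get `NA` (no profile available); pairs where a disease
#' signature does not intersect the drug ranking get a missing
#' connectivity that is not counted.
#'
#' @param drug_sigs Named list of `drug_signature` objects.
#' @param disease_sigs List of `disease_signature` objects (the N datasets).
#' @param drug_ids Drugs to report; default: all drugs in `drug_sigs`.
#' @param weight KS weight exponent (default 1).
#' @return Data frame with `drug_id`, one `conn_<dataset>` column per
#'   dataset, `gsea` (integer or NA) and `n_datasets`.
#' @export
score_signatures <- function(drug_sigs, disease_sigs,
                             drug_ids = names(drug_sigs), weight = 1) {
  n <- length(disease_sigs)
  ds_ids <- vapply(disease_sigs, function(s) s$dataset_id, "")
  rows <- lapply(drug_ids, function(did) {
    sig <- drug_sigs[[did]]
    if (is.null(sig)) {
      conn <- rep(NA_real_, n)
      score <- NA_integer_
    } else {
      conn <- vapply(disease_sigs, function(ds) {
        tryCatch(connectivity_score(sig, ds, weight = weight),
                 error = function(e) NA_real_)
      }, numeric(1L))
      score <- gsea_score(did, conn, n)$score
    }
    row <- data.frame(drug_id = did, stringsAsFactors = FALSE)
    for (j in seq_len(n)) row[[paste0("conn_", ds_ids[j])]] <- conn[j]
    row$gsea <- score
    row$n_datasets <- as.integer(n)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
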