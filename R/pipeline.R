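# End-to-end driver: files in, ranked tables out.

#' Run the full repurposing pipeline from input files
#'
#' Loads the interactome edge list, restricts it to its largest connected
#' component, scores every drug against the disease gene set
#' (closest-distance proximity, degree-preserving permutation significance,
#' min-max similarity), selects per-dataset disease signatures by BH at
#' `alpha`, computes signature-reversal scores for all drugs present in the
#' signature library, filters to significant associations, applies the
#' three-key ranking and writes `scores.tsv`, `gsea.tsv`, `ranked.tsv` and
#' `radial.tsv` to `outdir`. All randomness derives from `seed`, so two
#' runs with the same inputs and seed produce byte-identical tables.
#'
#' @param edge_list Path to the interactome edge list.
#' @param disease_gmt Path to a GMT file; its first set is the disease.
#' @param drug_targets Path to the drug-target TSV.
#' @param de_tables Character vector of per-dataset DE table paths.
#' @param drug_sigs Path to the drug-signature library TSV.
#' @param outdir Output directory (created if needed).
#' @param alpha Significance threshold for both the BH DE selection and
#'   the proximity p-value filter (default 0.05).
#' @param n_perm Permutations per drug (default 1000).
#' @param seed Master integer seed.
#' @param min_bin_size Degree-bin size for the permutation null
#'   (default 100).
#' @param idmap Optional path to an identifier-map TSV applied to drug
#'   targets.
#' @return Invisible list with the four output paths and the in-memory
#'   `scores`, `gsea`, `ranked` and `radial` tables.
#' @export
run_pipeline <- function(edge_list, disease_gmt, drug_targets, de_tables,
                         drug_sigs, outdir, alpha = 0.05, n_perm = 1000,
                         seed = 1, min_bin_size = 100, idmap = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- load_edge_list(edge_list)
  g <- largest_connected_component(g)
  disease <- read_gmt(disease_gmt)[[1L]]
  map <- if (is.null(idmap)) NULL else read_id_map(idmap)
  drugs <- read_drug_targets(drug_targets, idmap = map)
  bins <- build_degree_bins(
    g, min_bin_size = min(min_bin_size, igraph::vcount(g$graph)))

  scores <- score_all(g, bins, drugs, disease, n_perm = n_perm, seed = seed)

  disease_sigs <- lapply(seq_along(de_tables), function(i) {
    tb <- read_de_table(de_tables[i])
    ds_id <- sub("\\.tsv$", "", basename(de_tables[i]))
    select_de_genes(tb, alpha = alpha, dataset_id = ds_id)
  })
  lib <- read_drug_signatures(drug_sigs)
  gsea <- score_signatures(lib, disease_sigs, drug_ids = scores$drug_id)

  kept <- filter_significant(scores, alpha = alpha)
  ranked <- rank_candidates(kept, gsea_scores = gsea)
  radial <- export_radial(ranked)

  paths <- list(scores = file.path(outdir, "scores.tsv"),
                gsea = file.path(outdir, "gsea.tsv"),
                ranked = file.path(outdir, "ranked.tsv"),
                radial = file.path(outdir, "radial.tsv"))
  write_scores(scores, paths$scores)
  write.table(gsea, paths$gsea, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  write_ranked(ranked, paths$ranked)
  write.table(radial, paths$radial, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, list(scores_table = scores, gsea_table = gsea,
                          ranked_table = ranked, radial_table = radial)))
}
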