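# Synthetic-data generator: interactomes with a planted disease module,
# drugs at controlled proximity, and disease/drug signature libraries with
# controlled reversal structure. Every stage of the pipeline can be
# exercised end-to-end on its output, with ground-truth labels kept in a
# sidecar table so the pipeline readers never see them.

#' Configuration of the synthetic benchmark
#'
#' Defaults describe the standard study conditions used throughout the
#' package's validation: a 2,000-node preferential-attachment graph with a
#' 25-gene planted disease module, 10 module-proximal and 40 random
#' (degree-matched) drugs with 3 targets each, and 3 disease expression
#' datasets whose signatures the proximal drugs reverse with probability
#' `reversal_strength`.
#'
#' @param n_nodes Number of interactome nodes.
#' @param edges_per_node Preferential-attachment edges added per node
#'   (controls density; degree distribution is heavy-tailed like a PPI
#'   network).
#' @param module_size Size of the planted connected disease module.
#' @param n_drugs_proximal,n_drugs_random Counts of module-proximal and
#'   degree-matched random drugs.
#' @param targets_per_drug Targets per drug.
#' @param n_datasets Number of disease expression datasets N.
#' @param n_genes Size of the expression gene universe per dataset.
#' @param genes_per_signature Differentially expressed genes planted per
#'   dataset (half up, half down).
#' @param sig_overlap Fraction of each dataset's DE genes shared across all
#'   datasets (the rest are dataset-specific).
#' @param reversal_strength Probability in [0, 1] that a reversing drug
#'   places a planted disease gene at the reversing extreme of its ranking.
#' @param noise_p Probability in [0, 1] of flipping an individual planted
#'   gene's placement in a drug signature.
#' @param seed Master seed; everything derived from the config is
#'   bit-reproducible.
#' @return A `synthetic_config` object (validated list).
#' @export
synthetic_config <- function(n_nodes = 2000, edges_per_node = 4,
                             module_size = 25, n_drugs_proximal = 10,
                             n_drugs_random = 40, targets_per_drug = 3,
                             n_datasets = 3, n_genes = 1000,
                             genes_per_signature = 50, sig_overlap = 0.5,
                             reversal_strength = 0.8, noise_p = 0.05,
                             seed = 1) {
  cfg <- list(n_nodes = as.integer(n_nodes),
              edges_per_node = as.integer(edges_per_node),
              module_size = as.integer(module_size),
              n_drugs_proximal = as.integer(n_drugs_proximal),
              n_drugs_random = as.integer(n_drugs_random),
              targets_per_drug = as.integer(targets_per_drug),
              n_datasets = as.integer(n_datasets),
              n_genes = as.integer(n_genes),
              genes_per_signature = as.integer(genes_per_signature),
              sig_overlap = as.numeric(sig_overlap),
              reversal_strength = as.numeric(reversal_strength),
              noise_p = as.numeric(noise_p),
              seed = as.integer(seed))
  if (cfg$module_size >= cfg$n_nodes) stop("module_size must be < n_nodes")
  counts <- c(cfg$n_nodes, cfg$edges_per_node, cfg$module_size,
              cfg$n_drugs_proximal, cfg$n_drugs_random, cfg$targets_per_drug,
              cfg$n_datasets, cfg$n_genes, cfg$genes_per_signature)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  for (f in c("sig_overlap", "reversal_strength", "noise_p")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic interactome with a planted disease module
#'
#' Draws a preferential-attachment graph (heavy-tailed degrees, one
#' connected component) and grows a connected disease module of
#' `module_size` nodes by random neighborhood expansion from a random
#' start node.
#'
#' @param cfg A `synthetic_config`.
#' @return List with `graph` (an `interactome`) and `module` (a
#'   `gene_set` with id `"DIS1"`).
#' @export
generate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(derive_seed(cfg$seed, "interactome"), {
    gg <- igraph::sample_pa(cfg$n_nodes, power = 1, m = cfg$edges_per_node,
                            directed = FALSE)
    gg <- igraph::simplify(gg)
    igraph::V(gg)$name <- sprintf("G%05d", seq_len(cfg$n_nodes))
    g <- new_interactome(gg)
    module <- grow_connected_module(g, cfg$module_size)
    list(graph = g,
         module = gene_set("DIS1", "planted disease module", module))
  })
}

neighbor_names <- function(g, nodes) {
  unique(unlist(lapply(igraph::adjacent_vertices(g$graph, nodes),
                       function(v) v$name), use.names = FALSE))
}

# random connected subgraph of the requested size, grown by repeatedly
# adding a uniform random neighbor of the current frontier
grow_connected_module <- function(g, size, max_attempts = 100L) {
  nodes <- graph_nodes(g)
  if (size > length(nodes)) stop("module larger than the graph")
  for (attempt in seq_len(max_attempts)) {
    mod <- sample(nodes, 1L)
    while (length(mod) < size) {
      nb <- neighbor_names(g, mod)
      frontier <- setdiff(nb, mod)
      if (length(frontier) == 0L) break
      mod <- c(mod, sample(frontier, 1L))
    }
    if (length(mod) == size) return(sort(mod))
  }
  stop("could not grow a connected module of size ", size,
       " in ", max_attempts, " attempts")
}

#' Plant drugs at controlled proximity to the disease module
#'
#' Proximal drugs draw their targets from the module and its first graph
#' neighborhood; random drugs draw degree-matched targets anywhere
#' (matched to the target-degree profile of the proximal drugs, so the
#' two classes differ in proximity but not in degree). The class label is
#' returned in a separate truth table, never inside the drug records.
#'
#' @param g An `interactome` object.
#' @param module A `gene_set` (the planted disease module).
#' @param cfg A `synthetic_config`.
#' @return List with `drugs` (named list of `drug_record`) and `truth`
#'   (data frame `drug_id`, `label` in `"proximal"`/`"random"`).
#' @export
plant_drugs <- function(g, module, cfg) {
  stopifnot(inherits(g, "interactome"), inherits(module, "gene_set"),
            inherits(cfg, "synthetic_config"))
  withr::with_seed(derive_seed(cfg$seed, "drugs"), {
    nodes <- graph_nodes(g)
    pool <- union(module$members, neighbor_names(g, module$members))
    if (length(pool) < cfg$targets_per_drug) {
      stop("module neighborhood too small for targets_per_drug")
    }
    bins <- build_degree_bins(
      g, min_bin_size = max(1L, min(100L, length(nodes) %/% 20L)))
    drugs <- list(); labels <- character(0)
    prox_targets <- vector("list", cfg$n_drugs_proximal)
    for (i in seq_len(cfg$n_drugs_proximal)) {
      did <- sprintf("DBP%03d", i)
      prox_targets[[i]] <- sample(pool, cfg$targets_per_drug)
      drugs[[did]] <- drug_record(did, sprintf("proxdrug-%03d", i),
                                  prox_targets[[i]])
      labels[did] <- "proximal"
    }
    for (i in seq_len(cfg$n_drugs_random)) {
      did <- sprintf("DBR%03d", i)
      template <- prox_targets[[((i - 1L) %% cfg$n_drugs_proximal) + 1L]]
      tgt <- suppressMessages(sample_degree_matched(g, bins, template))
      drugs[[did]] <- drug_record(did, sprintf("randdrug-%03d", i), tgt)
      labels[did] <- "random"
    }
    list(drugs = drugs,
         truth = data.frame(drug_id = names(labels), label = unname(labels),
                            stringsAsFactors = FALSE))
  })
}

#' Plant single-class drugs at graded distances from the module
#'
#' Benchmark for monotone recovery: drug k gets targets drawn from the
#' BFS shell at hop distance `k mod (max shell + 1)` from the module, so
#' the planted distance is known exactly and increases in repeating steps.
#'
#' @param g An `interactome` object.
#' @param module A `gene_set`.
#' @param n_drugs Number of drugs to plant.
#' @param targets_per_drug Targets per drug, all in the same shell.
#' @param seed Integer seed.
#' @return List with `drugs` and `truth` (data frame `drug_id`,
#'   `planted_distance`).
#' @export
plant_graded_drugs <- function(g, module, n_drugs = 20, targets_per_drug = 1,
                               seed = 1) {
  stopifnot(inherits(g, "interactome"), inherits(module, "gene_set"))
  withr::with_seed(seed, {
    dist <- shortest_path_lengths_from(g, module$members)
    dist <- dist[is.finite(dist)]
    shells <- split(names(dist), dist)
    usable <- which(lengths(shells) >= targets_per_drug)
    shells <- shells[usable]
    ks <- as.numeric(names(shells))
    drugs <- list()
    truth <- data.frame(drug_id = character(0), planted_distance = numeric(0),
                        stringsAsFactors = FALSE)
    for (i in seq_len(n_drugs)) {
      j <- ((i - 1L) %% length(shells)) + 1L
      did <- sprintf("DBG%03d", i)
      drugs[[did]] <- drug_record(did, sprintf("graded-%03d", i),
                                  sample(shells[[j]], targets_per_drug))
      truth <- rbind(truth, data.frame(drug_id = did,
                                       planted_distance = ks[j],
                                       stringsAsFactors = FALSE))
    }
    list(drugs = drugs, truth = truth)
  })
}

#' Generate disease DE tables and a drug-signature library with known
#' reversal structure
#'
#' Each of the N disease datasets gets a DE table over the gene universe:
#' planted up/down genes carry near-zero raw p-values (they survive BH at
#' any practical threshold) and signed effects; unplanted genes carry raw
#' p-values bounded away from zero so the selected signature equals the
#' planted one exactly. A `sig_overlap` fraction of each dataset's DE
#' genes is shared across all datasets, the rest is dataset-specific, and
#' shared genes keep a consistent direction everywhere.
#'
#' Drug signatures are rankings over the same universe: a `reversing` drug
#' places each planted disease-up gene at the bottom and each disease-down
#' gene at the top of its ranking with probability `reversal_strength`
#' (independently per gene); a `mimicking` drug does the opposite; a
#' `null` drug ranks all genes by noise alone. `noise_p` then flips each
#' placed gene's extreme with that probability.
#'
#' @param cfg A `synthetic_config`.
#' @param classes Named character vector mapping drug ids to
#'   `"reversing"`, `"mimicking"` or `"null"`. When derived from
#'   [plant_drugs()] truth, map `proximal` to reversing and `random` to
#'   null before calling (see [write_synthetic_fixtures()]).
#' @return List with `de_tables` (named list of data frames, one per
#'   dataset `ds1..dsN`), `drug_sigs` (named list of `drug_signature`),
#'   and `truth` (data frame `drug_id`, `reversal_class`).
#' @export
generate_signatures <- function(cfg, classes) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(names(classes)) ||
      !all(classes %in% c("reversing", "mimicking", "null"))) {
    stop("classes must be a named vector of reversing/mimicking/null")
  }
  withr::with_seed(derive_seed(cfg$seed, "signatures"), {
    universe <- sprintf("T%05d", seq_len(cfg$n_genes))
    n_up <- cfg$genes_per_signature %/% 2L
    n_dn <- cfg$genes_per_signature - n_up
    n_shared_up <- round(cfg$sig_overlap * n_up)
    n_shared_dn <- round(cfg$sig_overlap * n_dn)
    n_own_up <- n_up - n_shared_up
    n_own_dn <- n_dn - n_shared_dn
    need <- n_shared_up + n_shared_dn +
      cfg$n_datasets * (n_own_up + n_own_dn)
    if (need > cfg$n_genes) {
      stop("gene universe too small for the requested signatures")
    }
    planted <- sample(universe, need)
    take <- function(k) {
      out <- planted[seq_len(k)]
      planted <<- planted[-seq_len(k)]
      out
    }
    shared_up <- take(n_shared_up)
    shared_dn <- take(n_shared_dn)
    up_sets <- list(); dn_sets <- list()
    de_tables <- list()
    for (d in seq_len(cfg$n_datasets)) {
      up <- c(shared_up, take(n_own_up))
      dn <- c(shared_dn, take(n_own_dn))
      up_sets[[d]] <- up; dn_sets[[d]] <- dn
      effect <- stats::runif(cfg$n_genes, -0.5, 0.5)
      p_raw <- stats::runif(cfg$n_genes, 0.05, 1)
      iu <- match(up, universe); idn <- match(dn, universe)
      effect[iu] <- stats::runif(length(iu), 1, 2)
      effect[idn] <- -stats::runif(length(idn), 1, 2)
      p_raw[c(iu, idn)] <- stats::runif(length(iu) + length(idn), 0, 1e-8)
      de_tables[[sprintf("ds%d", d)]] <- data.frame(
        gene_id = universe, effect = effect, p_raw = p_raw,
        stringsAsFactors = FALSE)
    }
    all_up <- unique(unlist(up_sets))    # consistent direction by construction
    all_dn <- unique(unlist(dn_sets))
    drug_sigs <- list()
    for (did in names(classes)) {
      base <- stats::rnorm(cfg$n_genes, 0, 0.5)
      names(base) <- universe
      cls <- classes[[did]]
      if (cls != "null") {
        flip <- if (cls == "reversing") 1 else -1
        place <- function(genes, sign_hi) {
          placed <- genes[stats::runif(length(genes)) < cfg$reversal_strength]
          noise <- stats::runif(length(placed)) < cfg$noise_p
          s <- sign_hi * ifelse(noise, -1, 1)
          base[placed] <<- s * stats::runif(length(placed), 8, 10)
        }
        # reversing: disease-up genes pushed to the bottom (drug lowers
        # them), disease-down genes to the top
        place(all_up, -flip)
        place(all_dn, flip)
      }
      drug_sigs[[did]] <- drug_signature(did, base)
    }
    list(de_tables = de_tables, drug_sigs = drug_sigs,
         truth = data.frame(drug_id = names(classes),
                            reversal_class = unname(classes),
                            stringsAsFactors = FALSE))
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' Generates the interactome, module, drugs and signatures for `cfg` and
#' writes every pipeline input in its standard on-disk format: the edge
#' list, the disease GMT, the drug-target TSV, one DE table per dataset,
#' the drug-signature TSV, and a ground-truth sidecar TSV (the one file no
#' pipeline reader consumes). Proximal drugs are reversing, random drugs
#' null, so network proximity and signature reversal agree on the planted
#' positives.
#'
#' @param cfg A `synthetic_config`.
#' @param outdir Output directory (created if needed).
#' @return Named list of file paths (`edge_list`, `disease_gmt`,
#'   `drug_targets`, `de_tables` (vector), `drug_sigs`, `truth`),
#'   invisibly.
#' @export
write_synthetic_fixtures <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_interactome(cfg)
  pl <- plant_drugs(net$graph, net$module, cfg)
  classes <- setNames(
    ifelse(pl$truth$label == "proximal", "reversing", "null"),
    pl$truth$drug_id)
  sigs <- generate_signatures(cfg, classes)

  edge_path <- file.path(outdir, "edge_list.tsv")
  el <- igraph::as_edgelist(net$graph$graph)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), edge_path)

  gmt_path <- file.path(outdir, "disease.gmt")
  write_gmt(list(net$module), gmt_path)

  drug_path <- file.path(outdir, "drug_targets.tsv")
  write_drug_targets(pl$drugs, drug_path)

  de_paths <- character(0)
  for (ds in names(sigs$de_tables)) {
    p <- file.path(outdir, paste0("de_", ds, ".tsv"))
    write_de_table(sigs$de_tables[[ds]], p)
    de_paths[ds] <- p
  }

  sig_path <- file.path(outdir, "drug_signatures.tsv")
  write_drug_signatures(sigs$drug_sigs, sig_path)

  truth_path <- file.path(outdir, "truth.tsv")
  truth <- merge(pl$truth, sigs$truth, by = "drug_id")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(edge_list = edge_path, disease_gmt = gmt_path,
                 drug_targets = drug_path, de_tables = de_paths,
                 drug_sigs = sig_path, truth = truth_path))
}
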