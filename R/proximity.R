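# Closest-distance drug-disease proximity, degree-preserving permutation
# significance and min-max similarity -- the network-scoring core.

row_mins <- function(m) {
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Closest-distance proximity between drug targets and disease genes
#'
#' The canonical "closest" proximity: the average, over drug targets `T`,
#' of the shortest-path distance from each target to its nearest disease
#' gene in `D`:
#' \deqn{d(T, D) = \frac{1}{|T|} \sum_{t \in T} \min_{v \in D} sp(t, v)}
#' Zero iff every in-graph target is itself a disease gene.
#'
#' @param g An `interactome` object.
#' @param targets Character vector of target gene ids (subset of the graph).
#' @param disease Character vector of disease gene ids (subset of the graph).
#' @param dist_cache Optional all-pairs matrix from [precompute_distances()];
#'   when supplied, distances are looked up instead of recomputed by BFS.
#' @return Non-negative numeric scalar (hops).
#' @export
closest_proximity <- function(g, targets, disease, dist_cache = NULL) {
  targets <- unique(as.character(targets))
  disease <- unique(as.character(disease))
  if (length(targets) == 0L) stop("empty target set")
  if (length(disease) == 0L) stop("empty disease gene set")
  if (!is.null(dist_cache)) {
    m <- dist_cache[targets, disease, drop = FALSE]
    return(mean(row_mins(m)))
  }
  nodes <- graph_nodes(g)
  missing <- setdiff(c(targets, disease), nodes)
  if (length(missing) > 0L) {
    stop("node(s) not in the interactome: ", paste(missing, collapse = ", "))
  }
  d <- shortest_path_lengths_from(g, disease)
  mean(d[targets])
}

#' Degree-preserving permutation significance of a proximity
#'
#' Draws `n_perm` degree-matched random target sets and `n_perm`
#' degree-matched random disease sets, recomputes the closest proximity for
#' each random pair, and reports
#' `z = (d_obs - mean(d_rand)) / sd(d_rand)` together with the empirical
#' p-value `(#\{d_rand <= d_obs\} + 1) / (n_perm + 1)` (the pseudocount
#' keeps p in (0, 1]). Low p means the drug's targets sit closer to the
#' disease genes than degree-matched chance.
#'
#' @param g An `interactome` object.
#' @param bins `degree_bins` from [build_degree_bins()].
#' @param targets,disease Character vectors of node ids.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the whole draw is reproducible.
#' @param dist_cache Optional matrix from [precompute_distances()].
#' @return List with `d_obs`, `z`, `p_emp`, `n_perm`, `seed`.
#' @export
permutation_significance <- function(g, bins, targets, disease,
                                     n_perm = 1000, seed = 1,
                                     dist_cache = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  d_obs <- closest_proximity(g, targets, disease, dist_cache = dist_cache)
  d_rand <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      t_i <- sample_degree_matched(g, bins, targets)
      d_i <- sample_degree_matched(g, bins, disease)
      closest_proximity(g, t_i, d_i, dist_cache = dist_cache)
    }, numeric(1L))
  })
  s <- sd(d_rand)
  if (is.na(s) || s == 0) {
    warning("null proximity distribution has zero spread; z reported as 0")
    z <- 0
  } else {
    z <- (d_obs - mean(d_rand)) / s
  }
  p_emp <- (sum(d_rand <= d_obs) + 1) / (n_perm + 1)
  list(d_obs = d_obs, z = z, p_emp = p_emp,
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Rescale a batch of proximities to network similarities on [0, 1]
#'
#' Within one scored batch (one disease against many drugs), similarity is
#' the min-max rescaling `s = (d_max - d) / (d_max - d_min)`, so the most
#' proximal drug(s) score exactly 1 and the most distant 0. When all
#' distances are equal every similarity is 1. Ties in distance yield
#' identical similarities. Idempotent and order-invariant.
#'
#' @param results Data frame with a `d_closest` column (one disease batch).
#' @return The same data frame with `similarity` filled.
#' @export
normalize_similarity <- function(results) {
  if (nrow(results) == 0L) stop("empty result batch")
  d <- results$d_closest
  rng <- range(d)
  results$similarity <- if (rng[1L] == rng[2L]) {
    rep(1, length(d))
  } else {
    (rng[2L] - d) / (rng[2L] - rng[1L])
  }
  results
}

#' Sigmoid cluster adjustment of similarities (optional stage)
#'
#' Rewards drug-disease pairs that fall in the same community of the
#' similarity network and penalizes cross-community pairs:
#' same cluster `s' = s * sigma(s)`, different cluster
#' `s' = s * (1 - sigma(s))` with
#' `sigma(x) = 1 / (1 + exp(-steepness * (x - midpoint)))`.
#' Off by default in [score_all()]; this stage is a reconstruction of the
#' adjusted-similarity idea and is clearly labelled as such in the package
#' vignette.
#'
#' @param results Data frame with `drug_id`, `disease_id`, `similarity`.
#' @param partition Named vector mapping every drug id and disease id in
#'   `results` to a cluster id (e.g. from
#'   [detect_similarity_communities()]).
#' @param steepness,midpoint Sigmoid parameters (defaults 30 and 0.5).
#' @return `results` with `similarity` replaced by the adjusted value.
#' @export
cluster_adjust <- function(results, partition, steepness = 30, midpoint = 0.5) {
  need <- unique(c(results$drug_id, results$disease_id))
  miss <- setdiff(need, names(partition))
  if (length(miss) > 0L) {
    stop("missing cluster assignment for: ", paste(miss, collapse = ", "))
  }
  s <- results$similarity
  sig <- 1 / (1 + exp(-steepness * (s - midpoint)))
  same <- partition[results$drug_id] == partition[results$disease_id]
  results$similarity <- ifelse(same, s * sig, s * (1 - sig))
  results
}

#' Louvain communities of the drug-disease similarity network
#'
#' Builds the weighted bipartite graph of drugs and diseases with
#' similarity as edge weight (zero-similarity pairs omitted) and runs
#' Louvain community detection, yielding the partition consumed by
#' [cluster_adjust()].
#'
#' @param results Data frame with `drug_id`, `disease_id`, `similarity`.
#' @param seed Integer seed for the (stochastic) community detection.
#' @return Named integer vector mapping each drug id and disease id to a
#'   cluster id.
#' @export
detect_similarity_communities <- function(results, seed = 1) {
  dr <- paste0("drug\r", results$drug_id)
  di <- paste0("disease\r", results$disease_id)
  keep <- results$similarity > 0
  if (!any(keep)) stop("no positive similarities to cluster")
  gg <- igraph::graph_from_data_frame(
    data.frame(from = dr[keep], to = di[keep],
               weight = results$similarity[keep]),
    directed = FALSE,
    vertices = unique(c(dr, di)))
  memb <- withr::with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(gg))
  })
  setNames(as.integer(memb), sub("^(drug|disease)\r", "", names(memb)))
}

#' Score a drug library against one disease gene set
#'
#' The batch driver: restricts the disease genes and each drug's targets
#' to the interactome, computes the observed closest proximity and its
#' degree-preserving permutation significance for every scoreable drug, and
#' fills in the batch-wise min-max similarity. Drugs with no in-graph
#' targets are excluded and counted. Per-drug seeds are derived
#' deterministically from `seed` and the drug id, so the result table is
#' byte-reproducible for a fixed master seed.
#'
#' @param g An `interactome` object (use the largest connected component).
#' @param bins `degree_bins` from [build_degree_bins()].
#' @param drugs Named list of `drug_record` objects.
#' @param disease A `gene_set` of disease-associated genes.
#' @param n_perm Permutations per drug (default 1000).
#' @param seed Master integer seed.
#' @param dist_cache Optional matrix from [precompute_distances()]; when
#'   `NULL` and the graph has at most `auto_cache_max` nodes, the matrix is
#'   precomputed automatically.
#' @param auto_cache_max Node-count limit for automatic precomputation
#'   (default 4000; above it, per-set BFS is used instead).
#' @return Data frame with one row per scored drug: `drug_id`, `drug_name`,
#'   `disease_id`, `d_closest`, `z`, `p_emp`, `similarity`,
#'   `n_permutations`, `seed`; attribute `n_excluded` counts skipped drugs.
#' @export
score_all <- function(g, bins, drugs, disease, n_perm = 1000, seed = 1,
                      dist_cache = NULL, auto_cache_max = 4000) {
  stopifnot(inherits(g, "interactome"), inherits(disease, "gene_set"))
  dis <- restrict_to_graph(disease$members, g)
  if (length(dis$kept) == 0L) stop("no disease genes left after restriction")
  if (is.null(dist_cache) && igraph::vcount(g$graph) <= auto_cache_max) {
    dist_cache <- precompute_distances(g)
  }
  nodes <- graph_nodes(g)
  rows <- vector("list", length(drugs))
  n_excluded <- 0L
  for (i in seq_along(drugs)) {
    d <- drugs[[i]]
    tgt <- intersect(d$targets, nodes)
    if (length(tgt) == 0L) {
      n_excluded <- n_excluded + 1L
      next
    }
    drug_seed <- derive_seed(seed, d$drug_id)
    res <- suppressMessages(
      permutation_significance(g, bins, tgt, dis$kept,
                               n_perm = n_perm, seed = drug_seed,
                               dist_cache = dist_cache))
    rows[[i]] <- data.frame(
      drug_id = d$drug_id, drug_name = d$name, disease_id = disease$set_id,
      d_closest = res$d_obs, z = res$z, p_emp = res$p_emp,
      similarity = NA_real_, n_permutations = res$n_perm, seed = res$seed,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) stop("no scoreable drugs (all lacked in-graph targets)")
  message(sprintf("scored %d drug(s); %d excluded (no in-graph targets)",
                  length(rows), n_excluded))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- normalize_similarity(out)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write / read a proximity score table
#'
#' @param results Data frame from [score_all()].
#' @param path TSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_scores <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  read.delim(path, header = TRUE, sep = "\t",
             colClasses = c(drug_id = "character", drug_name = "character",
                            disease_id = "character"))
}
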