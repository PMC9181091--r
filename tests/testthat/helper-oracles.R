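# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the code paths they check: distances come from
# Floyd-Warshall instead of BFS, BH from the direct min-over-tails
# definition instead of the step-up recursion.

# all-pairs hop distances by Floyd-Warshall on a node-name edge data frame
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    D[a, b] <- 1; D[b, a] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# mean over targets of the min Floyd-Warshall distance to the disease set
fw_closest_proximity <- function(D, targets, disease) {
  m <- D[targets, disease, drop = FALSE]
  mean(apply(m, 1L, min))
}

# BH adjusted p-values straight from the definition:
# q_i = min over j with rank(j) >= rank(i) of p_(j) * m / rank(j)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1L))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# random connected simple graph written as an edge-list file; returns the
# path plus the node/edge inventory for oracle use
random_graph_fixture <- function(n, p_edge = NULL, dir = tempdir()) {
  if (is.null(p_edge)) p_edge <- min(1, 2.5 / n)
  repeat {
    gg <- igraph::sample_gnp(n, p_edge)
    if (igraph::ecount(gg) > 0L) break
  }
  igraph::V(gg)$name <- sprintf("N%03d", seq_len(n))
  el <- igraph::as_edgelist(gg)
  path <- tempfile("graph", tmpdir = dir, fileext = ".tsv")
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  list(path = path, nodes = igraph::V(gg)$name, edges = el)
}

# tiny path graph A-B-C-D-E as an interactome
path_graph <- function(nodes = LETTERS[1:5]) {
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(nodes[-length(nodes)], nodes[-1L], sep = "\t"), f)
  suppressMessages(load_edge_list(f))
}

# rank-sum AUC of scores for the positive class
rank_auc <- function(score, positive) {
  r <- rank(score)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# the nine histaminergic multiple-sclerosis candidates with their published
# similarity, empirical p and reversal scores -- the worked ranking example
table2_rows <- function() {
  data.frame(
    drug_id = c("DB00613", "DB11614", "DB01075", "DB08801", "DB09016",
                "DB01242", "DB00751", "DB00434", "DB00656"),
    drug_name = c("Amodiaquine", "Rupatadine", "Diphenhydramine",
                  "Dimetindene", "Butriptyline", "Clomipramine",
                  "Epinastine", "Cyproheptadine", "Trazodone"),
    similarity = c(1, 0.62791, 0.62791, 0.62791, 0.50388, 0.37984,
                   0.37984, 0.36213, 0.36213),
    p_emp = c(0.00806, 0.01412, 0.01571, 0.01654, 0.02857, 0.03232,
              0.0044, 0.01584, 0.03221),
    gsea = c(3L, 3L, 2L, NA, NA, 3L, 2L, 3L, 3L),
    stringsAsFactors = FALSE)
}

# drug signature over a labelled universe with chosen blocks at the top
# and bottom (everything else in shuffled middle order)
block_signature <- function(drug_id, universe, top = character(0),
                            bottom = character(0), seed = 1) {
  withr::with_seed(seed, {
    middle <- setdiff(universe, c(top, bottom))
    scores <- c(setNames(sort(runif(length(top), 8, 10), decreasing = TRUE), top),
                setNames(runif(length(middle), -1, 1), sample(middle)),
                setNames(-sort(runif(length(bottom), 8, 10)), bottom))
    drug_signature(drug_id, scores)
  })
}
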