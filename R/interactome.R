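#' @importFrom stats sd setNames
#' @importFrom utils read.delim write.table
NULL

new_interactome <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  structure(list(graph = graph), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node identifiers of an interactome
#'
#' @param g An `interactome` object.
#' @return Character vector of gene identifiers.
#' @export
graph_nodes <- function(g) {
  stopifnot(inherits(g, "interactome"))
  igraph::V(g$graph)$name
}

#' Node degrees of an interactome
#'
#' @param g An `interactome` object.
#' @return Named integer vector, node identifier to degree.
#' @export
graph_degree <- function(g) {
  stopifnot(inherits(g, "interactome"))
  d <- igraph::degree(g$graph)
  setNames(as.integer(d), igraph::V(g$graph)$name)
}

#' Underlying igraph object
#'
#' @param g An `interactome` object.
#' @return The `igraph` graph the interactome wraps.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "interactome"))
  g$graph
}

#' Load a protein-protein interaction network from an edge list
#'
#' Reads a plain-text edge list (one interaction per line, two gene
#' identifiers separated by whitespace or a fixed delimiter; `#` lines are
#' comments) into a simple undirected graph. Self-loops are dropped and
#' duplicate or reversed edges are collapsed, so the result is the binary
#' interactome the proximity computations assume.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter; `NULL` (default) splits on any run of
#'   spaces or tabs.
#' @return An `interactome` object.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B C", "# comment", "B A", "A A"), f)
#' g <- load_edge_list(f)
#' graph_nodes(g)
#' @export
load_edge_list <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty graph: no edges in ", path)
  split_re <- if (is.null(delimiter)) "[ \t]+" else delimiter
  parts <- strsplit(trimws(lines[idx]), split_re, fixed = !is.null(delimiter) && delimiter != "")
  nf <- lengths(parts)
  bad <- which(nf < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge-list line %d in %s: fewer than 2 fields",
                 idx[bad[1L]], path))
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  n_raw <- length(a)
  loop <- a == b
  n_loops <- sum(loop)
  a <- a[!loop]; b <- b[!loop]
  if (length(a) == 0L) stop("empty graph: all edges were self-loops in ", path)
  # collapse duplicates, treating {a,b} == {b,a}
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]
  graph <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  message(sprintf(
    "loaded %d nodes, %d edges (%d lines read; %d self-loops and %d duplicate edges dropped)",
    igraph::vcount(graph), igraph::ecount(graph), n_raw, n_loops, n_dup))
  new_interactome(graph)
}

#' Restrict an interactome to its largest connected component
#'
#' Proximity between drug targets and disease genes is only defined on a
#' connected graph; this keeps the largest component (ties broken by the
#' component containing the lexicographically smallest node identifier).
#'
#' @param g An `interactome` object.
#' @return An `interactome` induced on the largest component. Idempotent.
#' @export
largest_connected_component <- function(g) {
  stopifnot(inherits(g, "interactome"))
  comp <- igraph::components(g$graph)
  if (comp$no == 1L) return(g)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # tie-break: component holding the lexicographically smallest member
    first_member <- vapply(biggest, function(ci) {
      min(igraph::V(g$graph)$name[comp$membership == ci])
    }, "")
    biggest <- biggest[order(first_member)][1L]
  }
  keep <- which(comp$membership == biggest)
  sub <- igraph::induced_subgraph(g$graph, keep)
  message(sprintf("largest connected component: kept %d nodes, removed %d",
                  igraph::vcount(sub), igraph::vcount(g$graph) - igraph::vcount(sub)))
  new_interactome(sub)
}

#' Hop distances from a set of source nodes
#'
#' Multi-source breadth-first search: for every node, the minimum number of
#' hops to any node of `sources`. Nodes in other components get `Inf`.
#'
#' @param g An `interactome` object.
#' @param sources Character vector of node identifiers; must all be in `g`.
#' @return Named numeric vector over all nodes of `g`.
#' @export
shortest_path_lengths_from <- function(g, sources) {
  stopifnot(inherits(g, "interactome"))
  sources <- unique(as.character(sources))
  missing <- setdiff(sources, graph_nodes(g))
  if (length(missing) > 0L) {
    stop("unknown source node(s): ", paste(missing, collapse = ", "))
  }
  dm <- igraph::distances(g$graph, v = sources, mode = "all")
  d <- do.call(pmin, lapply(seq_len(nrow(dm)), function(i) dm[i, ]))
  setNames(as.numeric(d), colnames(dm))
}

#' All-pairs hop-distance matrix
#'
#' Precomputes the full shortest-path matrix so that permutation nulls can
#' be evaluated by indexing instead of repeated BFS. Memory is
#' `8 * n^2` bytes, so this is intended for graphs up to a few thousand
#' nodes.
#'
#' @param g An `interactome` object.
#' @return Numeric matrix with node identifiers as dimnames.
#' @export
precompute_distances <- function(g) {
  stopifnot(inherits(g, "interactome"))
  igraph::distances(g$graph, mode = "all")
}

#' Group nodes into degree bins for degree-preserving sampling
#'
#' Nodes are sorted by degree and grouped greedily into contiguous bins of
#' at least `min_bin_size` nodes; an undersized final remainder is merged
#' into the previous bin. Nodes of equal degree always share a bin, so the
#' degree ranges are contiguous and non-overlapping.
#'
#' @param g An `interactome` object.
#' @param min_bin_size Minimum nodes per bin (default 100, the usual choice
#'   on interactome-scale graphs; lower it for small graphs).
#' @return A `degree_bins` object with members, degree ranges and a
#'   node-to-bin index.
#' @export
build_degree_bins <- function(g, min_bin_size = 100) {
  stopifnot(inherits(g, "interactome"))
  deg <- graph_degree(g)
  n <- length(deg)
  if (min_bin_size < 1L) stop("min_bin_size must be >= 1")
  if (min_bin_size > n) {
    stop(sprintf("min_bin_size (%d) exceeds node count (%d)", min_bin_size, n))
  }
  by_deg <- split(names(deg), deg)           # ascending unique degree
  degs <- as.integer(names(by_deg))
  bins <- list(); ranges <- list()
  cur <- character(0); cur_lo <- degs[1L]
  for (i in seq_along(by_deg)) {
    if (length(cur) == 0L) cur_lo <- degs[i]
    cur <- c(cur, by_deg[[i]])
    if (length(cur) >= min_bin_size) {
      bins[[length(bins) + 1L]] <- cur
      ranges[[length(ranges) + 1L]] <- c(cur_lo, degs[i])
      cur <- character(0)
    }
  }
  if (length(cur) > 0L) {
    if (length(bins) == 0L) {
      bins[[1L]] <- cur
      ranges[[1L]] <- c(cur_lo, degs[length(degs)])
    } else {
      k <- length(bins)
      bins[[k]] <- c(bins[[k]], cur)
      ranges[[k]][2L] <- degs[length(degs)]
    }
  }
  node2bin <- integer(n)
  names(node2bin) <- unlist(bins, use.names = FALSE)
  node2bin[] <- rep.int(seq_along(bins), lengths(bins))
  structure(list(bins = bins, ranges = ranges, node2bin = node2bin,
                 min_bin_size = as.integer(min_bin_size)),
            class = "degree_bins")
}

#' @export
print.degree_bins <- function(x, ...) {
  cat(sprintf("<degree_bins> %d bins (min size %d)\n",
              length(x$bins), x$min_bin_size))
  for (i in seq_along(x$bins)) {
    cat(sprintf("  bin %d: degree %d-%d, %d nodes\n", i,
                x$ranges[[i]][1L], x$ranges[[i]][2L], length(x$bins[[i]])))
  }
  invisible(x)
}

#' Draw a degree-matched random node set
#'
#' Samples one node from the degree bin of each template node, without
#' replacement within the draw, so the returned set has the template's
#' cardinality and its degree-bin profile. This is the degree-preserving
#' null used by the permutation significance test.
#'
#' @param g An `interactome` object.
#' @param bins `degree_bins` from [build_degree_bins()].
#' @param template Character vector of node identifiers to match.
#' @param seed Optional integer seed; `NULL` (default) draws from the
#'   current RNG stream (the caller controls reproducibility).
#' @return Character vector of `length(template)` distinct node ids.
#' @export
sample_degree_matched <- function(g, bins, template, seed = NULL) {
  stopifnot(inherits(g, "interactome"), inherits(bins, "degree_bins"))
  template <- unique(as.character(template))
  missing <- setdiff(template, names(bins$node2bin))
  if (length(missing) > 0L) {
    stop("template node(s) missing from degree bins: ",
         paste(missing, collapse = ", "))
  }
  draw <- function() {
    need <- table(bins$node2bin[template])
    out <- character(0)
    for (bi in names(need)) {
      pool <- bins$bins[[as.integer(bi)]]
      k <- as.integer(need[[bi]])
      if (length(pool) == k) {
        message(sprintf(
          "degree bin %s has exactly %d node(s); forced to return them all", bi, k))
        out <- c(out, pool)
      } else {
        out <- c(out, sample(pool, k))
      }
    }
    sort(out)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# deterministic per-entity seed derived from a master seed and a string id
derive_seed <- function(master_seed, id) {
  h <- 0
  for (c in utf8ToInt(as.character(id))) h <- (h * 31 + c) %% 2147483647
  as.integer((as.numeric(master_seed) + h) %% 2147483647)
}
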