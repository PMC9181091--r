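# Readers and validation for disease gene sets, drug-target tables and
# identifier maps, plus their restriction to the interactome.

#' Construct a gene set
#'
#' @param set_id Identifier of the set (unique within a collection).
#' @param name Human-readable description.
#' @param members Character vector of gene identifiers; duplicates are
#'   collapsed and whitespace trimmed.
#' @return A `gene_set` object.
#' @export
gene_set <- function(set_id, name, members) {
  members <- unique(trimws(as.character(members)))
  members <- members[nzchar(members)]
  if (length(members) == 0L) stop("gene set ", set_id, " has no members")
  if (!nzchar(trimws(set_id))) stop("gene set id must be a non-empty string")
  structure(list(set_id = set_id, name = name, members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%s): %d members\n",
              x$set_id, x$name, length(x$members)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard Broad GMT: one set per line, `set_id TAB description TAB
#' member1 TAB member2 ...`. Duplicate members within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @return Named list of `gene_set` objects (names are set ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("GMT parse error at line %d of %s: fewer than 3 fields", i, path))
    }
    ids[i] <- f[1L]
    out[[i]] <- gene_set(f[1L], f[2L], f[-(1:2)])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene set id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(out) <- ids
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets List of `gene_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$name, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a drug record
#'
#' @param drug_id Accession (e.g. a DrugBank-style `DB00613`).
#' @param name Drug name.
#' @param targets Character vector of target gene identifiers.
#' @return A `drug_record` object.
#' @export
drug_record <- function(drug_id, name, targets) {
  targets <- unique(trimws(as.character(targets)))
  targets <- targets[nzchar(targets)]
  if (length(targets) == 0L) stop("drug ", drug_id, " has no targets")
  structure(list(drug_id = drug_id, name = name, targets = targets),
            class = "drug_record")
}

#' @export
print.drug_record <- function(x, ...) {
  cat(sprintf("<drug_record> %s (%s): %d target(s)\n",
              x$drug_id, x$name, length(x$targets)))
  invisible(x)
}

#' Read a two-column identifier map
#'
#' A TSV with columns `source_id` and `target_id` (header required),
#' emulating e.g. a Uniprot-to-Entrez export. Many-to-one is permitted;
#' duplicate source ids must agree.
#'
#' @param path Path to the TSV.
#' @return Named character vector, source id to target id.
#' @export
read_id_map <- function(path) {
  tb <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("source_id", "target_id")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0L) {
    stop("id map ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  src <- trimws(tb$source_id); tgt <- trimws(tb$target_id)
  ok <- nzchar(src) & nzchar(tgt)
  if (!all(ok)) stop("id map ", path, " has empty source or target ids")
  dup <- duplicated(src)
  if (any(dup)) {
    m1 <- setNames(tgt[!dup], src[!dup])
    if (any(m1[src[dup]] != tgt[dup])) {
      stop("id map ", path, " maps the same source id to different targets")
    }
  }
  setNames(tgt[!dup], src[!dup])
}

#' Read a drug-target table
#'
#' TSV with header columns `drug_id`, `drug_name`, `target_id`, one row per
#' drug-target pair (DrugBank-shaped). Rows are grouped by drug; target ids
#' are passed through `idmap` when given, with unmapped ids dropped. Drugs
#' whose mapped target set ends up empty are excluded and counted in a
#' message. Several tables (e.g. a primary library plus a supplemental one)
#' can be merged by reading each and combining with [merge_drug_libraries()].
#'
#' @param path Path to the TSV.
#' @param idmap Optional named character vector from [read_id_map()].
#' @return Named list of `drug_record` objects (names are drug ids).
#' @export
read_drug_targets <- function(path, idmap = NULL) {
  tb <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("drug_id", "drug_name", "target_id")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0L) {
    stop("drug-target table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tb$target_id <- trimws(tb$target_id)
  if (!is.null(idmap)) {
    tb$target_id <- unname(idmap[tb$target_id])   # unmapped -> NA, dropped
  }
  split_rows <- split(tb, tb$drug_id)
  out <- list(); n_excluded <- 0L
  for (did in names(split_rows)) {
    rows <- split_rows[[did]]
    targets <- rows$target_id[!is.na(rows$target_id) & nzchar(rows$target_id)]
    if (length(targets) == 0L) {
      n_excluded <- n_excluded + 1L
      next
    }
    out[[did]] <- drug_record(did, rows$drug_name[1L], targets)
  }
  message(sprintf("read %d drug(s) from %s; %d excluded (no mapped targets)",
                  length(out), path, n_excluded))
  out
}

#' Write a drug library as a drug-target TSV
#'
#' @param drugs Named list of `drug_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_targets <- function(drugs, path) {
  rows <- do.call(rbind, lapply(drugs, function(d) {
    data.frame(drug_id = d$drug_id, drug_name = d$name,
               target_id = d$targets, stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge drug libraries by target union
#'
#' Drugs appearing in several libraries keep the first name seen and the
#' union of their target sets.
#'
#' @param ... Named lists of `drug_record` objects.
#' @return A single merged named list of `drug_record` objects.
#' @export
merge_drug_libraries <- function(...) {
  libs <- list(...)
  out <- list()
  for (lib in libs) {
    for (d in lib) {
      if (is.null(out[[d$drug_id]])) {
        out[[d$drug_id]] <- d
      } else {
        out[[d$drug_id]]$targets <- union(out[[d$drug_id]]$targets, d$targets)
      }
    }
  }
  out
}

#' Restrict a gene collection to interactome nodes
#'
#' @param members Character vector of gene identifiers.
#' @param g An `interactome` object.
#' @return List with `kept` (members present in the graph) and `dropped`.
#'   A message reports both counts; an all-dropped set triggers a warning
#'   and the caller decides whether to skip the entity.
#' @export
restrict_to_graph <- function(members, g) {
  stopifnot(inherits(g, "interactome"))
  members <- unique(as.character(members))
  nodes <- graph_nodes(g)
  kept <- intersect(members, nodes)
  dropped <- setdiff(members, nodes)
  message(sprintf("restrict_to_graph: kept %d of %d, dropped %d",
                  length(kept), length(members), length(dropped)))
  if (length(kept) == 0L && length(members) > 0L) {
    warning("no members of the set are present in the interactome")
  }
  list(kept = kept, dropped = dropped)
}
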