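#' @importFrom igraph graph_from_edgelist simplify V ecount vcount neighbors
#'   as_edgelist cliques degree gorder
#' @importFrom stats quantile setNames
#' @importFrom utils head write.table
NULL

# ---- protein id handling ----------------------------------------------------

assert_protein_ids <- function(ids, what = "protein id") {
  ids <- as.character(ids)
  bad <- !nzchar(ids) | grepl("[[:space:]]", ids)
  if (any(bad)) {
    stop(sprintf("invalid %s: %s", what,
                 paste(sQuote(head(ids[bad], 3L)), collapse = ", ")),
         call. = FALSE)
  }
  ids
}

# ---- interaction network ----------------------------------------------------

#' Build an undirected protein interaction network
#'
#' Constructs a simple undirected graph over protein identifiers from a
#' two-column matrix or data frame of interacting pairs. Self-interactions
#' are dropped and duplicate pairs (in either orientation) are collapsed,
#' so the result is always a simple graph.
#'
#' @param pairs two-column character matrix or data frame; each row is one
#'   interacting protein pair.
#' @return an undirected simple [igraph::graph] whose vertex names are the
#'   protein identifiers.
#' @examples
#' g <- interaction_network(cbind(c("A", "B", "B"), c("B", "C", "A")))
#' igraph::vcount(g)  # 3
#' igraph::ecount(g)  # 2
#' @export
interaction_network <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) < 2L) stop("'pairs' needs two columns", call. = FALSE)
  pairs <- pairs[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "character"
  assert_protein_ids(as.vector(pairs))
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a protein interaction network from an edge list
#'
#' Parses a whitespace- or tab-delimited edge list (the common DIP/BioGRID
#' pair-list export) into an undirected simple graph. Only the first two
#' columns are used; extra columns (confidence scores, PubMed ids, ...) are
#' ignored. Lines starting with `#` and blank lines are skipped. Duplicate
#' pairs, reversed duplicates and self-loops are collapsed/dropped, and a
#' short summary of what was read is emitted via [message()] when
#' `verbose = TRUE`.
#'
#' Isolated proteins cannot be represented in an edge list, so the vertex
#' set is exactly the set of proteins appearing in at least one interaction.
#'
#' @param path file path or connection holding the edge list.
#' @param verbose emit a one-line parse summary?
#' @return an undirected simple [igraph::graph] with named vertices.
#' @seealso [write_edge_list()], [read_cluster_file()]
#' @export
read_edge_list <- function(path, verbose = FALSE) {
  lines <- readLines(path, warn = FALSE)
  n_raw <- length(lines)
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  lines <- lines[keep]
  lineno <- seq_len(n_raw)[keep]
  if (length(lines) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  short <- lengths(toks) < 2L
  if (any(short)) {
    stop(sprintf("edge list line %d: expected at least two ids, got %s",
                 lineno[which(short)[1L]],
                 sQuote(lines[which(short)[1L]])), call. = FALSE)
  }
  a <- vapply(toks, `[[`, "", 1L)
  b <- vapply(toks, `[[`, "", 2L)
  loops <- a == b
  pairs <- cbind(a[!loops], b[!loops])
  # orientation-independent key for duplicate counting
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  dup <- duplicated(key)
  g <- interaction_network(pairs[!dup, , drop = FALSE])
  if (verbose) {
    message(sprintf(
      "edge list: %d lines read, %d edges kept, %d self-loops dropped, %d duplicates dropped",
      n_raw, igraph::ecount(g), sum(loops), sum(dup)))
  }
  g
}

#' Write a network as a two-column tab-delimited edge list
#'
#' @param g an [igraph::graph] with named vertices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

# ---- cluster sets -----------------------------------------------------------

#' Construct a cluster set
#'
#' A cluster set is an ordered, possibly duplicate-containing collection of
#' clusters, each a set of protein identifiers with a provenance label.
#' Duplicate clusters are deliberately preserved: overlap statistics treat
#' the collection as non-unique, so two identical clusters overlap each
#' other fully.
#'
#' @param clusters list of character vectors (cluster member ids). Ids
#'   within a cluster are de-duplicated and sorted; empty clusters are an
#'   error.
#' @param labels optional character vector of labels, recycled from
#'   `"cluster-<k>"` when missing.
#' @return an object of class `cluster_set`: a named list of sorted
#'   character vectors.
#' @examples
#' cs <- cluster_set(list(c("A", "B"), c("B", "C")))
#' length(cs)  # 2
#' @export
cluster_set <- function(clusters, labels = NULL) {
  if (!is.list(clusters)) stop("'clusters' must be a list", call. = FALSE)
  clusters <- lapply(clusters, function(m) sort(unique(as.character(m))))
  sizes <- lengths(clusters)
  if (any(sizes == 0L)) {
    stop(sprintf("cluster %d is empty", which(sizes == 0L)[1L]), call. = FALSE)
  }
  lapply(clusters, assert_protein_ids)
  if (is.null(labels)) labels <- sprintf("cluster-%d", seq_along(clusters))
  if (length(labels) != length(clusters)) {
    stop("'labels' must match 'clusters' in length", call. = FALSE)
  }
  structure(stats::setNames(clusters, as.character(labels)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d clusters, %d distinct proteins\n",
              length(x), length(unique(unlist(x)))))
  show <- head(seq_along(x), 6L)
  for (i in show) {
    cat(sprintf("  %s (%d): %s%s\n", names(x)[i], length(x[[i]]),
                paste(head(x[[i]], 6L), collapse = " "),
                if (length(x[[i]]) > 6L) " ..." else ""))
  }
  if (length(x) > 6L) cat(sprintf("  ... and %d more\n", length(x) - 6L))
  invisible(x)
}

#' @export
`[.cluster_set` <- function(x, i) {
  structure(unclass(x)[i], class = "cluster_set")
}

#' Read a cluster file (one cluster per line)
#'
#' Reads the MCL-style format used by most graph-clustering tools: one
#' cluster per line, members separated by whitespace. An optional leading
#' label terminated by a colon (`"name : id id ..."`) is honoured; unlabeled
#' lines are auto-numbered `cluster-<k>`. Duplicate ids within a line are
#' collapsed; duplicate lines are preserved as distinct clusters, keeping
#' the file's cluster order.
#'
#' @param path file path or connection.
#' @return a [cluster_set].
#' @export
read_cluster_file <- function(path) {
  parsed <- parse_member_lines(path, what = "cluster")
  labels <- parsed$labels
  labels[is.na(labels)] <- paste0("cluster-", which(is.na(labels)))
  cluster_set(parsed$members, labels)
}

#' Write a cluster set to a cluster file
#'
#' @param clusters a [cluster_set].
#' @param path output file path.
#' @param labels write the `"label :"` prefix on each line?
#' @return `path`, invisibly.
#' @export
write_cluster_file <- function(clusters, path, labels = TRUE) {
  stopifnot(inherits(clusters, "cluster_set"))
  body <- vapply(clusters, paste, "", collapse = " ")
  lines <- if (labels) paste(names(clusters), ":", body) else body
  writeLines(lines, path)
  invisible(path)
}

# shared line parser for cluster files and complex catalogs:
# "label : id id ..." / "label<TAB>id id ..." / bare "id id ..."
parse_member_lines <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  n_raw <- length(lines)
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  lines <- lines[keep]
  lineno <- seq_len(n_raw)[keep]
  labels <- rep(NA_character_, length(lines))
  members <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (grepl(":", ln, fixed = TRUE)) {
      labels[k] <- trimws(sub(":.*$", "", ln))
      ln <- trimws(sub("^[^:]*:", "", ln))
    } else if (grepl("\t", ln, fixed = TRUE)) {
      labels[k] <- trimws(sub("\t.*$", "", ln))
      ln <- trimws(sub("^[^\t]*\t", "", ln))
    }
    ids <- strsplit(ln, "[[:space:]]+")[[1L]]
    ids <- ids[nzchar(ids)]
    if (length(ids) == 0L) {
      stop(sprintf("%s file line %d: no members", what, lineno[k]),
           call. = FALSE)
    }
    members[[k]] <- ids
  }
  list(labels = labels, members = members)
}

# ---- complex catalogs -------------------------------------------------------

#' Construct a gold-standard complex catalog
#'
#' @param complexes list of character vectors, one per complex.
#' @param names unique complex names; auto-generated when `NULL`.
#' @return an object of class `complex_catalog`: a named list of sorted
#'   character vectors with unique names.
#' @export
complex_catalog <- function(complexes, names = NULL) {
  if (is.null(names)) names <- sprintf("complex-%d", seq_along(complexes))
  if (anyDuplicated(names)) {
    stop(sprintf("duplicate complex name: %s",
                 sQuote(names[duplicated(names)][1L])), call. = FALSE)
  }
  cs <- cluster_set(complexes, names)
  # a catalog is a cluster set with unique names, so it also answers to the
  # cluster-set generics (overlap profiles, scoring, file writers)
  structure(unclass(cs), class = c("complex_catalog", "cluster_set"))
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("Complex catalog: %d complexes, %d distinct proteins\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Read a complex catalog
#'
#' Accepts `"name<TAB>id id ..."`, `"name : id id ..."` or bare member
#' lines (auto-named `complex-<k>`). Complex names must be unique.
#'
#' @param path file path or connection.
#' @return a [complex_catalog].
#' @export
read_complex_catalog <- function(path) {
  parsed <- parse_member_lines(path, what = "catalog")
  labels <- parsed$labels
  labels[is.na(labels)] <- paste0("complex-", which(is.na(labels)))
  complex_catalog(parsed$members, labels)
}

# ---- triangles --------------------------------------------------------------

#' Enumerate all triangles of a network
#'
#' Lists every 3-clique of the graph, each as a sorted triple of vertex
#' names; triples are returned in lexicographic order. Triangles are the
#' seeds of the triangle-seeded entropy clustering variant.
#'
#' @param g an [igraph::graph] with named vertices.
#' @return list of sorted character triples (possibly empty).
#' @export
enumerate_triangles <- function(g) {
  if (igraph::gorder(g) < 3L) return(list())
  cl <- igraph::cliques(g, min = 3L, max = 3L)
  tri <- lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  if (length(tri) == 0L) return(list())
  key <- vapply(tri, paste, "", collapse = "\r")
  tri[order(key)]
}
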