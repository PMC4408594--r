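#' Construct a similarity graph
#'
#' A `similarity_graph` holds a set of protein identifiers together with the
#' best (smallest) pairwise BLAST E-value observed for each unordered pair,
#' capped at a relaxed ceiling. It is the substrate of the agglomerative
#' clustering: proteins are nodes, E-values are (dis)similarity weights, and
#' proteins without any admissible edge remain future singletons.
#'
#' @param proteins character vector of protein identifiers (opaque strings,
#'   duplicates removed, input order preserved).
#' @param edges data frame with columns `p1`, `p2`, `evalue`. Pairs are
#'   unordered: rows are canonicalised so that `p1 < p2` lexicographically and
#'   duplicate pairs keep the minimum E-value. Self-pairs are an error here
#'   (the parser drops them silently).
#' @param e_ceiling maximal admissible E-value; edges above it are rejected.
#'   The default 100 is the deliberately relaxed threshold under which the
#'   family trees are grown.
#' @param species_of optional named character vector mapping protein id to a
#'   species identifier; needed only for species-composition statistics.
#' @return an object of class `similarity_graph`.
#' @seealso [parse_blast_tabular()], [restrict_to_components()]
#' @export
similarity_graph <- function(proteins, edges = NULL, e_ceiling = 100,
                             species_of = NULL) {
  proteins <- as.character(proteins)
  proteins <- proteins[!duplicated(proteins)]
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(p1 = character(), p2 = character(),
                        evalue = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(p1 = as.character(edges$p1),
                        p2 = as.character(edges$p2),
                        evalue = as.numeric(edges$evalue),
                        stringsAsFactors = FALSE)
    if (any(edges$p1 == edges$p2))
      stop("self-edges are not allowed in a similarity graph")
    if (any(!is.finite(edges$evalue)) || any(edges$evalue < 0))
      stop("E-values must be finite and non-negative")
    if (any(edges$evalue > e_ceiling))
      stop("edge E-value exceeds e_ceiling (", e_ceiling, ")")
    swap <- edges$p1 > edges$p2
    tmp <- edges$p1[swap]; edges$p1[swap] <- edges$p2[swap]; edges$p2[swap] <- tmp
    key <- paste(edges$p1, edges$p2, sep = "\r")
    if (anyDuplicated(key)) {
      ev <- tapply(edges$evalue, key, min)
      parts <- strsplit(names(ev), "\r", fixed = TRUE)
      edges <- data.frame(p1 = vapply(parts, `[`, "", 1L),
                          p2 = vapply(parts, `[`, "", 2L),
                          evalue = as.numeric(ev), stringsAsFactors = FALSE)
    }
    missing <- setdiff(unique(c(edges$p1, edges$p2)), proteins)
    if (length(missing))
      stop("edge endpoints not in protein set: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    edges <- edges[order(edges$p1, edges$p2), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (!is.null(species_of)) {
    species_of <- species_of[intersect(names(species_of), proteins)]
  }
  structure(list(proteins = proteins, edges = edges,
                 e_ceiling = e_ceiling, species_of = species_of),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph: ", length(x$proteins), " proteins, ",
      nrow(x$edges), " edges (E <= ", x$e_ceiling, ")\n", sep = "")
  invisible(x)
}

#' Parse all-vs-all BLAST tabular output into a similarity graph
#'
#' Accepts the standard 12-column BLAST tabular format (`-outfmt 6`: query,
#' subject, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore) or the package's 3-column edge-list dialect (query,
#' subject, evalue). Comment lines starting with `#` are ignored. For every
#' unordered protein pair the minimum E-value over all HSPs and both hit
#' directions is kept; self-hits are dropped; rows with E above `e_ceiling`
#' are dropped but their endpoints are still registered as (edge-less) nodes.
#'
#' @param path path to the tab-separated hit table. An empty file yields an
#'   empty graph.
#' @param e_ceiling maximal admissible E-value (default 100).
#' @param species_of optional named character vector (protein -> species), as
#'   read by [read_species_map()].
#' @return a [similarity_graph()].
#' @export
parse_blast_tabular <- function(path, e_ceiling = 100, species_of = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(similarity_graph(character(), NULL, e_ceiling, species_of))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ncol <- nf[1L]
  if (!ncol %in% c(3L, 12L))
    stop("line ", lineno[1L], ": expected 3 or 12 tab-separated columns, got ",
         ncol)
  bad <- which(nf != ncol)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": expected ", ncol,
         " columns, got ", nf[bad[1L]])
  ecol <- if (ncol == 12L) 11L else 3L
  q <- vapply(fields, `[`, "", 1L)
  s <- vapply(fields, `[`, "", 2L)
  ev <- suppressWarnings(as.numeric(vapply(fields, `[`, "", ecol)))
  bad <- which(is.na(ev))
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": non-numeric E-value '",
         vapply(fields, `[`, "", ecol)[bad[1L]], "'")
  proteins <- unique(c(rbind(q, s)))          # first-seen order, both columns
  ok <- q != s & ev <= e_ceiling
  edges <- data.frame(p1 = q[ok], p2 = s[ok], evalue = ev[ok],
                      stringsAsFactors = FALSE)
  similarity_graph(proteins, edges, e_ceiling, species_of)
}

#' Write a similarity graph as a canonical 3-column edge list
#'
#' @param graph a [similarity_graph()].
#' @param path output path. One `#`-comment header line records the ceiling.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "similarity_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# protofam edge list\te_ceiling=", graph$e_ceiling), con)
  # isolated proteins are kept as degenerate self-comment rows so that a
  # round-trip preserves the node set
  iso <- setdiff(graph$proteins, unique(c(graph$edges$p1, graph$edges$p2)))
  if (length(iso))
    writeLines(paste0("# node\t", iso), con)
  if (nrow(graph$edges))
    writeLines(paste(graph$edges$p1, graph$edges$p2,
                     format(graph$edges$evalue, digits = 17, trim = TRUE,
                            scientific = NA),
                     sep = "\t"), con)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' Recovers isolated nodes from the `# node` comment lines, so
#' `read_edge_list(write_edge_list(g))` reproduces `g` exactly.
#'
#' @inheritParams parse_blast_tabular
#' @export
read_edge_list <- function(path, e_ceiling = 100, species_of = NULL) {
  g <- parse_blast_tabular(path, e_ceiling = e_ceiling, species_of = species_of)
  lines <- readLines(path)
  node_lines <- grep("^# node\t", lines, value = TRUE)
  hdr <- grep("^# protofam edge list\te_ceiling=", lines, value = TRUE)
  if (length(hdr))
    e_ceiling <- as.numeric(sub(".*e_ceiling=", "", hdr[1L]))
  iso <- sub("^# node\t", "", node_lines)
  similarity_graph(c(g$proteins, setdiff(iso, g$proteins)), g$edges,
                   e_ceiling, species_of)
}

#' Read a protein-to-species map
#'
#' @param path 2-column TSV (protein, species); `#` comments allowed.
#' @return named character vector, names are protein ids.
#' @export
read_species_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein", "species"),
                          colClasses = "character", comment.char = "#",
                          quote = "")
  stats::setNames(df$species, df$protein)
}

#' Split a similarity graph into connected components
#'
#' The merge forest arises naturally from the components of the similarity
#' graph: clusters in different components share no edge and can never merge,
#' so each component grows its own tree. Isolated proteins come back as
#' size-1 components.
#'
#' @param graph a [similarity_graph()].
#' @return list of `similarity_graph` objects whose protein sets partition
#'   the input protein set.
#' @export
restrict_to_components <- function(graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (!length(graph$proteins)) return(list())
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("p1", "p2")], directed = FALSE,
    vertices = data.frame(name = graph$proteins))
  comp <- igraph::components(ig)
  member <- comp$membership[graph$proteins]
  lapply(seq_len(comp$no), function(ci) {
    prots <- graph$proteins[member == ci]
    e <- graph$edges[graph$edges$p1 %in% prots, , drop = FALSE]
    similarity_graph(prots, e, graph$e_ceiling,
                     graph$species_of[intersect(names(graph$species_of), prots)])
  })
}
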