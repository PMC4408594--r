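#' @title Bottom-up merge forest construction
#'
#' @description Agglomerative clustering of a similarity graph: starting from
#' singletons, the two most similar admissible clusters are joined at each
#' step, until no admissible pair remains. A cluster pair is *admissible* iff
#' at least one real cross-cluster edge exists in the graph, so disconnected
#' components never merge and the result is a *forest* of binary merge trees
#' rather than a single tree.
#'
#' Dissimilarity between clusters is controlled by `linkage`:
#' \describe{
#'   \item{`geometric-mean-E`}{geometric mean of the pairwise E-values across
#'     the two clusters, i.e. the arithmetic mean of `log10(E)`; cross pairs
#'     without a recorded edge contribute the ceiling `e_ceiling`. Default.}
#'   \item{`arithmetic-mean-negloge`}{arithmetic mean of `-log10(E)` with the
#'     same missing-pair convention. This orders cluster pairs identically to
#'     `geometric-mean-E` (one is a monotone transform of the other), so the
#'     two names produce the same forest; both are accepted.}
#'   \item{`single`}{minimum pairwise E-value.}
#'   \item{`complete`}{maximum pairwise E-value, with missing cross pairs at
#'     the ceiling.}
#' }
#' Reported E-values of exactly 0 are clamped to `1e-180` before the log
#' transform. Ties in dissimilarity are broken deterministically: among tied
#' pairs the one whose `(smaller node id, larger node id)` is
#' lexicographically smallest merges first, so the forest is a pure function
#' of the graph and the linkage rule.
#'
#' Node ids follow the linkage-table convention: leaves get `0..N-1` in
#' protein input order and the internal node created at merge step `m` gets
#' `N + m - 1`.
#'
#' @param graph a [similarity_graph()].
#' @param linkage one of `"geometric-mean-E"`, `"arithmetic-mean-negloge"`,
#'   `"single"`, `"complete"`.
#' @return an object of class `merge_forest`: a list with `leaves` (protein
#'   ids in node-id order), `merges` (one row per merge: `step`, `child1`,
#'   `child2`, `new_id`, `linkage_value` on the `log10(E)` scale), `M` (total
#'   merge count), `e_ceiling`, `linkage` and `species_of`.
#' @export
build_forest <- function(graph, linkage = "geometric-mean-E") {
  stopifnot(inherits(graph, "similarity_graph"))
  linkage <- match.arg(linkage, c("geometric-mean-E", "arithmetic-mean-negloge",
                                  "single", "complete"))
  mode <- if (linkage %in% c("geometric-mean-E", "arithmetic-mean-negloge"))
    "mean" else linkage
  N <- length(graph$proteins)
  logceil <- log10(graph$e_ceiling)
  empty <- data.frame(step = integer(), child1 = integer(), child2 = integer(),
                      new_id = integer(), linkage_value = numeric())
  if (N == 0L)
    return(new_merge_forest(character(), empty, graph))

  idx <- stats::setNames(seq_len(N) - 1L, graph$proteins)
  e <- graph$edges
  le <- log10(pmax(e$evalue, 1e-180))
  i <- idx[e$p1]; j <- idx[e$p2]
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }

  # pair store: one row per admissible active cluster pair (pi < pj)
  pi <- as.integer(i); pj <- as.integer(j)
  cnt <- rep(1, length(pi)); slog <- le; mnlog <- le; mxlog <- le
  active <- rep(TRUE, length(pi))
  size <- rep(1, 2L * N)                      # indexed by node_id + 1
  merges <- vector("list", max(N - 1L, 0L))
  m <- 0L

  pair_d <- function(sel) {
    prod <- size[pi[sel] + 1L] * size[pj[sel] + 1L]
    switch(mode,
      mean = (slog[sel] + (prod - cnt[sel]) * logceil) / prod,
      single = mnlog[sel],
      complete = ifelse(cnt[sel] < prod, logceil, mxlog[sel]))
  }

  repeat {
    act <- which(active)
    if (!length(act)) break
    d <- pair_d(act)
    best <- act[order(d, pi[act], pj[act])[1L]]
    a <- pi[best]; b <- pj[best]
    m <- m + 1L
    new_id <- N + m - 1L
    merges[[m]] <- c(step = m, child1 = a, child2 = b, new_id = new_id,
                     linkage_value = pair_d(best))
    size[new_id + 1L] <- size[a + 1L] + size[b + 1L]

    touched <- which(active & (pi == a | pi == b | pj == a | pj == b))
    active[touched] <- FALSE
    touched <- setdiff(touched, best)
    if (length(touched)) {
      nbr <- ifelse(pi[touched] %in% c(a, b), pj[touched], pi[touched])
      u <- unique(nbr)
      grp <- match(nbr, u)
      n_cnt <- as.numeric(tapply(cnt[touched], grp, sum))
      n_slog <- as.numeric(tapply(slog[touched], grp, sum))
      n_mn <- as.numeric(tapply(mnlog[touched], grp, min))
      n_mx <- as.numeric(tapply(mxlog[touched], grp, max))
      k <- length(u)
      pi <- c(pi, u); pj <- c(pj, rep(new_id, k))
      cnt <- c(cnt, n_cnt); slog <- c(slog, n_slog)
      mnlog <- c(mnlog, n_mn); mxlog <- c(mxlog, n_mx)
      active <- c(active, rep(TRUE, k))
    }
    if (length(active) > 4L * length(pi[active]) + 1024L) {
      keep <- which(active)
      pi <- pi[keep]; pj <- pj[keep]; cnt <- cnt[keep]; slog <- slog[keep]
      mnlog <- mnlog[keep]; mxlog <- mxlog[keep]
      active <- rep(TRUE, length(keep))
    }
  }
  merges <- if (m) as.data.frame(do.call(rbind, merges[seq_len(m)])) else empty
  merges$step <- as.integer(merges$step)
  merges$child1 <- as.integer(merges$child1)
  merges$child2 <- as.integer(merges$child2)
  merges$new_id <- as.integer(merges$new_id)
  new_merge_forest(graph$proteins, merges, graph, linkage)
}

new_merge_forest <- function(leaves, merges, graph = NULL,
                             linkage = "geometric-mean-E") {
  structure(list(leaves = as.character(leaves),
                 merges = merges,
                 M = nrow(merges),
                 e_ceiling = if (is.null(graph)) 100 else graph$e_ceiling,
                 linkage = linkage,
                 species_of = if (is.null(graph)) NULL else graph$species_of),
            class = "merge_forest")
}

#' @export
print.merge_forest <- function(x, ...) {
  n <- length(x$leaves)
  cat("merge_forest: ", n, " proteins, ", x$M, " merges, ",
      n - x$M, " roots (linkage ", x$linkage, ")\n", sep = "")
  invisible(x)
}

#' ProtoLevel of a merge step
#'
#' ProtoLevel (PL) is the depth axis of the merge forest: the percentage of
#' merge steps completed, `100 * m / M`. PL0 is the all-singleton state and
#' PL100 the fully merged forest (its roots). `M` is counted forest-wide over
#' a single global merge ordering.
#'
#' @param m merge index (0 for leaves), vectorised.
#' @param M total number of merges; when `M = 0` (degenerate all-singleton
#'   forest) PL is defined as 0.
#' @return numeric in `[0, 100]`.
#' @export
protolevel <- function(m, M) {
  if (M == 0) return(rep(0, length(m)))
  stopifnot(all(m >= 0), all(m <= M))
  100 * m / M
}

#' Node table of a merge forest
#'
#' One row per node (leaf and internal) with its size, creation and
#' termination merge steps, ProtoLevel at creation, and LifeTime. A node
#' terminates at the step where it is absorbed into its parent; roots never
#' terminate and their LifeTime runs to PL100. LifeTime is
#' `PL(terminated) - PL(created)`; along any leaf-to-root path LifeTimes
#' telescope to exactly 100.
#'
#' @param forest a `merge_forest`.
#' @return data frame: `node_id`, `size`, `created_step`,
#'   `terminated_step` (`NA` for roots), `pl`, `lt`, `is_leaf`.
#' @export
node_table <- function(forest) {
  stopifnot(inherits(forest, "merge_forest"))
  N <- length(forest$leaves)
  M <- forest$M
  ids <- c(seq_len(N) - 1L, if (M) forest$merges$new_id)
  created <- c(rep(0L, N), if (M) forest$merges$step)
  size <- rep(1L, N + M)
  terminated <- rep(NA_integer_, N + M)
  if (M) {
    for (r in seq_len(M)) {
      c1 <- forest$merges$child1[r]; c2 <- forest$merges$child2[r]
      nid <- forest$merges$new_id[r]
      size[nid + 1L] <- size[c1 + 1L] + size[c2 + 1L]
      terminated[c1 + 1L] <- forest$merges$step[r]
      terminated[c2 + 1L] <- forest$merges$step[r]
    }
  }
  pl <- protolevel(created, M)
  term_pl <- ifelse(is.na(terminated), 100, protolevel(
    ifelse(is.na(terminated), 0L, terminated), M))
  if (M == 0) term_pl <- ifelse(is.na(terminated), 0, term_pl)
  data.frame(node_id = ids, size = size, created_step = created,
             terminated_step = terminated, pl = pl, lt = term_pl - pl,
             is_leaf = ids < N)
}

#' LifeTime of a node
#'
#' @param forest a `merge_forest`.
#' @param node_id node id(s); leaves are `0..N-1`.
#' @return LifeTime in `[0, 100]` (difference between the ProtoLevel at
#'   termination — absorption into the parent, or PL100 for roots — and the
#'   ProtoLevel at creation).
#' @export
lifetime <- function(forest, node_id) {
  nt <- node_table(forest)
  nt$lt[match(node_id, nt$node_id)]
}

#' Members of a forest node
#'
#' @param forest a `merge_forest`.
#' @param node_id a single node id.
#' @return character vector of protein ids in the cluster.
#' @export
node_members <- function(forest, node_id) {
  N <- length(forest$leaves)
  if (!all(node_id %in% c(seq_len(N + forest$M) - 1L)))
    stop("unknown node id: ", node_id[1L])
  mem <- all_members(forest)
  mem[[node_id + 1L]]
}

# list of member index vectors for every node (1-based list index = id + 1)
all_members <- function(forest) {
  N <- length(forest$leaves)
  mem <- vector("list", N + forest$M)
  for (i in seq_len(N)) mem[[i]] <- forest$leaves[i]
  if (forest$M)
    for (r in seq_len(forest$M))
      mem[[forest$merges$new_id[r] + 1L]] <-
        c(mem[[forest$merges$child1[r] + 1L]],
          mem[[forest$merges$child2[r] + 1L]])
  mem
}

#' Cut a merge forest into disjoint families
#'
#' The clusters alive after `m* = floor(pl * M / 100)` merges — nodes with
#' `created_step <= m*` and termination after `m*` (or never) — form a
#' disjoint partition of the proteins. Clusters smaller than `min_size` are
#' separated out as excluded singletons/smalls, matching the convention of
#' counting families excluding singletons.
#'
#' @param x a `merge_forest`.
#' @param pl ProtoLevel of the cut, in `[0, 100]` (default 70, the default
#'   family-resolution cut).
#' @param min_size minimum family size (default 2).
#' @param ... unused.
#' @return object of class `family_partition`: list with `cut_pl`, `m_star`,
#'   `min_size`, `families` (named list of protein-id vectors, names are the
#'   originating node ids) and `excluded` (same shape, clusters below
#'   `min_size`).
#' @export
cut.merge_forest <- function(x, pl = 70, min_size = 2L, ...) {
  stopifnot(pl >= 0, pl <= 100)
  nt <- node_table(x)
  m_star <- if (x$M == 0) 0L else as.integer(floor(pl * x$M / 100))
  alive <- nt$created_step <= m_star &
    (is.na(nt$terminated_step) | nt$terminated_step > m_star)
  mem <- all_members(x)
  fams <- mem[nt$node_id[alive] + 1L]
  names(fams) <- nt$node_id[alive]
  big <- vapply(fams, length, 1L) >= min_size
  structure(list(cut_pl = pl, m_star = m_star, min_size = as.integer(min_size),
                 families = fams[big], excluded = fams[!big]),
            class = "family_partition")
}

#' @export
print.family_partition <- function(x, ...) {
  cat("family_partition at PL", x$cut_pl, ": ", length(x$families),
      " families (size >= ", x$min_size, "), ", length(x$excluded),
      " excluded small clusters\n", sep = "")
  invisible(x)
}

#' All clusters of a partition (families plus excluded smalls)
#' @param partition a `family_partition`.
#' @return named list of protein-id vectors.
#' @export
all_clusters <- function(partition) c(partition$families, partition$excluded)

#' Membership vector of a partition
#'
#' @param partition a `family_partition`.
#' @return named character vector: for every protein, the id of its cluster
#'   (families and excluded smalls alike).
#' @export
partition_membership <- function(partition) {
  cl <- all_clusters(partition)
  stats::setNames(rep(names(cl), lengths(cl)), unlist(cl, use.names = FALSE))
}

#' Condense a forest by LifeTime
#'
#' Splices out every internal node whose LifeTime is below `lt_min`,
#' attaching its children to its nearest surviving ancestor. `lt_min = 0`
#' returns the binary forest unchanged; leaves and roots always survive.
#' Member sets of surviving nodes are unchanged, as is the ancestor relation
#' among survivors — only short-lived intermediate nodes disappear, so the
#' condensed view is generally multiway.
#'
#' @param forest a `merge_forest`.
#' @param lt_min minimum LifeTime (in PL units) an internal node needs to
#'   survive.
#' @return object of class `condensed_forest`: `nodes` (node table rows of
#'   survivors plus a `parent` column, `NA` for roots) and `children` (named
#'   list of child-id vectors).
#' @export
condense <- function(forest, lt_min = 0) {
  stopifnot(inherits(forest, "merge_forest"), lt_min >= 0)
  nt <- node_table(forest)
  N <- length(forest$leaves)
  parent <- rep(NA_integer_, N + forest$M)
  if (forest$M)
    for (r in seq_len(forest$M)) {
      parent[forest$merges$child1[r] + 1L] <- forest$merges$new_id[r]
      parent[forest$merges$child2[r] + 1L] <- forest$merges$new_id[r]
    }
  is_root <- is.na(parent[nt$node_id + 1L])
  survive <- nt$is_leaf | is_root | nt$lt >= lt_min
  surv_ids <- nt$node_id[survive]
  surv_set <- logical(N + forest$M)
  surv_set[surv_ids + 1L] <- TRUE
  new_parent <- vapply(surv_ids, function(id) {
    p <- parent[id + 1L]
    while (!is.na(p) && !surv_set[p + 1L]) p <- parent[p + 1L]
    if (is.na(p)) NA_integer_ else p
  }, 1L)
  nodes <- nt[survive, , drop = FALSE]
  nodes$parent <- new_parent
  rownames(nodes) <- NULL
  kids <- split(nodes$node_id[!is.na(nodes$parent)],
                nodes$parent[!is.na(nodes$parent)])
  structure(list(nodes = nodes, children = kids, lt_min = lt_min,
                 leaves = forest$leaves),
            class = "condensed_forest")
}

#' @export
print.condensed_forest <- function(x, ...) {
  cat("condensed_forest (lt_min = ", x$lt_min, "): ", nrow(x$nodes),
      " nodes, ", sum(is.na(x$nodes$parent)), " roots\n", sep = "")
  invisible(x)
}

#' Export / import the merge table
#'
#' The merge table is the complete, lossless record of the forest: one row
#' per merge (`step`, `child1`, `child2`, `new_id`, `linkage_value`, `pl`).
#' When written to a file, `#leaf` comment lines record the node-id-to-
#' protein mapping so that [import_merge_table()] reconstructs an identical
#' forest.
#'
#' @param forest a `merge_forest`.
#' @param path optional output path; when `NULL` the data frame is returned
#'   only.
#' @return the merge table data frame, invisibly when writing.
#' @export
export_merge_table <- function(forest, path = NULL) {
  stopifnot(inherits(forest, "merge_forest"))
  tab <- forest$merges
  tab$pl <- protolevel(tab$step, forest$M)
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# protofam merge table\tlinkage=", forest$linkage,
                      "\te_ceiling=", forest$e_ceiling), con)
    writeLines(paste0("#leaf\t", seq_along(forest$leaves) - 1L, "\t",
                      forest$leaves), con)
    writeLines(paste("step", "child1", "child2", "new_id", "linkage_value",
                     "pl", sep = "\t"), con)
    if (nrow(tab))
      writeLines(paste(tab$step, tab$child1, tab$child2, tab$new_id,
                       format(tab$linkage_value, digits = 17, trim = TRUE),
                       format(tab$pl, digits = 10, trim = TRUE),
                       sep = "\t"), con)
    return(invisible(tab))
  }
  tab
}

#' @rdname export_merge_table
#' @param leaves protein ids in node-id order; taken from `#leaf` lines when
#'   importing from a file.
#' @param x path to a written merge table, or a merge-table data frame.
#' @export
import_merge_table <- function(x, leaves = NULL) {
  linkage <- "geometric-mean-E"; e_ceiling <- 100
  if (is.character(x) && length(x) == 1L) {
    lines <- readLines(x)
    hdr <- grep("^# protofam merge table", lines, value = TRUE)
    if (length(hdr)) {
      linkage <- sub(".*linkage=([^\t]+).*", "\\1", hdr[1L])
      e_ceiling <- as.numeric(sub(".*e_ceiling=", "", hdr[1L]))
    }
    leaf_lines <- grep("^#leaf\t", lines, value = TRUE)
    if (length(leaf_lines)) {
      parts <- strsplit(leaf_lines, "\t", fixed = TRUE)
      ids <- as.integer(vapply(parts, `[`, "", 2L))
      leaves <- vapply(parts, `[`, "", 3L)[order(ids)]
    }
    body <- lines[!grepl("^#", lines)]
    tab <- utils::read.table(text = body, sep = "\t", header = TRUE)
  } else {
    tab <- as.data.frame(x)
  }
  if (is.null(leaves)) stop("leaf mapping required to rebuild a forest")
  N <- length(leaves)
  tab <- tab[order(tab$step), , drop = FALSE]
  if (nrow(tab)) {
    if (!identical(as.integer(tab$step), seq_len(nrow(tab))))
      stop("inconsistent merge table: steps must be 1..M")
    seen_term <- logical(N + nrow(tab))
    exists_node <- c(rep(TRUE, N), rep(FALSE, nrow(tab)))
    for (r in seq_len(nrow(tab))) {
      c1 <- tab$child1[r]; c2 <- tab$child2[r]; nid <- tab$new_id[r]
      if (nid != N + r - 1L)
        stop("inconsistent merge table: new_id must be N + step - 1")
      for (ch in c(c1, c2)) {
        if (ch < 0 || ch >= nid || !exists_node[ch + 1L] || seen_term[ch + 1L])
          stop("inconsistent merge table: child ", ch, " at step ", r)
        seen_term[ch + 1L] <- TRUE
      }
      exists_node[nid + 1L] <- TRUE
    }
  }
  merges <- data.frame(step = as.integer(tab$step),
                       child1 = as.integer(tab$child1),
                       child2 = as.integer(tab$child2),
                       new_id = as.integer(tab$new_id),
                       linkage_value = as.numeric(tab$linkage_value))
  f <- new_merge_forest(leaves, merges, NULL, linkage)
  f$e_ceiling <- e_ceiling
  f
}

#' Export a forest (or condensed view) as annotated Newick text
#'
#' Internal nodes carry a `[&id=..,pl=..,lt=..]` comment tag; branch lengths
#' are ProtoLevel differences between parent and child. One Newick string per
#' root; single-protein trees degenerate to `name[&...];`.
#'
#' @param x a `merge_forest` or `condensed_forest`.
#' @param path optional file to write the strings to, one per line.
#' @param digits significant digits for branch lengths.
#' @return character vector of Newick strings (invisibly when writing).
#' @export
export_newick <- function(x, path = NULL, digits = 6) {
  if (inherits(x, "merge_forest")) x <- condense(x, 0)
  stopifnot(inherits(x, "condensed_forest"))
  nodes <- x$nodes
  N <- length(x$leaves)
  fmt <- function(v) format(v, digits = digits, trim = TRUE)
  rec <- function(id, parent_pl) {
    row <- nodes[nodes$node_id == id, ]
    # leaves sit at PL0; internal nodes at their creation PL
    own_pl <- if (row$is_leaf) 0 else row$pl
    blen <- fmt(abs(parent_pl - own_pl))
    tag <- paste0("[&id=", id, ",pl=", fmt(own_pl), ",lt=", fmt(row$lt), "]")
    kids <- x$children[[as.character(id)]]
    if (is.null(kids) || !length(kids))
      paste0(x$leaves[id + 1L], tag, ":", blen)
    else
      paste0("(", paste(vapply(kids, rec, "", parent_pl = own_pl),
                        collapse = ","), ")", tag, ":", blen)
  }
  roots <- nodes$node_id[is.na(nodes$parent)]
  out <- vapply(roots, function(r) {
    row <- nodes[nodes$node_id == r, ]
    own_pl <- if (row$is_leaf) 0 else row$pl
    tag <- paste0("[&id=", r, ",pl=", fmt(own_pl), ",lt=", fmt(row$lt), "]")
    kids <- x$children[[as.character(r)]]
    if (is.null(kids) || !length(kids))
      paste0(x$leaves[r + 1L], tag, ";")
    else
      paste0("(", paste(vapply(kids, rec, "", parent_pl = own_pl),
                        collapse = ","), ")", tag, ";")
  }, "")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
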