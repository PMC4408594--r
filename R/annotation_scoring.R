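#' Annotation table
#'
#' A protein-to-keyword multimap (e.g. Pfam domain/family/repeat assignments)
#' over a fixed protein universe. Proteins of the universe with no keyword
#' form the *unannotated* set — the raw material of annotation gain.
#'
#' @param assignments data frame with columns `protein`, `keyword` and
#'   optionally `match_length` (mean matched length in amino acids for that
#'   protein/keyword pair).
#' @param universe character vector of all protein ids under consideration;
#'   defaults to the proteins seen in `assignments`.
#' @return object of class `annotation_table` with elements `assignments`
#'   (unique protein/keyword rows), `universe`, `keywords` (the keyword
#'   universe) and `unannotated`.
#' @export
annotation_table <- function(assignments, universe = NULL) {
  a <- data.frame(protein = as.character(assignments$protein),
                  keyword = as.character(assignments$keyword),
                  stringsAsFactors = FALSE)
  a$match_length <- if ("match_length" %in% names(assignments))
    as.numeric(assignments$match_length) else rep(NA_real_, nrow(a))
  if (nrow(a)) {
    key <- paste(a$protein, a$keyword, sep = "\r")
    if (anyDuplicated(key)) {
      ml <- tapply(a$match_length, key, function(v)
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
      a <- a[!duplicated(key), , drop = FALSE]
      a$match_length <- as.numeric(ml[paste(a$protein, a$keyword, sep = "\r")])
    }
  }
  if (is.null(universe)) universe <- unique(a$protein)
  universe <- as.character(universe)
  stray <- setdiff(a$protein, universe)
  if (length(stray))
    stop("annotated proteins outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  if (any(!is.na(a$match_length) & a$match_length <= 0))
    stop("match lengths must be positive")
  rownames(a) <- NULL
  structure(list(assignments = a, universe = universe,
                 keywords = sort(unique(a$keyword)),
                 unannotated = setdiff(universe, a$protein)),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table: ", length(x$universe), " proteins, ",
      length(x$keywords), " keywords, ", length(x$unannotated),
      " unannotated (",
      round(100 * (1 - length(x$unannotated) / max(length(x$universe), 1))),
      "% coverage)\n", sep = "")
  invisible(x)
}

#' Load a protein-to-keyword annotation table
#'
#' Reads a TSV with columns `protein`, `keyword` and optionally
#' `match_start`, `match_end` (1-based inclusive coordinates, as emitted by
#' Pfam-scanning tools). Repeated (protein, keyword) rows are allowed: the
#' match length `end - start + 1` is averaged over the repeats.
#'
#' @param path input TSV; `#` comments allowed; no header.
#' @param universe protein universe; proteins present here but absent from
#'   the file are recorded as unannotated.
#' @return an [annotation_table()].
#' @export
load_annotations <- function(path, universe = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(annotation_table(data.frame(protein = character(),
                                       keyword = character()), universe))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% c(2L, 4L)))
    stop("line ", lineno[which(!nf %in% c(2L, 4L))[1L]],
         ": expected 2 or 4 tab-separated columns")
  protein <- vapply(fields, `[`, "", 1L)
  keyword <- vapply(fields, `[`, "", 2L)
  ml <- rep(NA_real_, length(fields))
  four <- nf == 4L
  if (any(four)) {
    st <- suppressWarnings(as.numeric(vapply(fields, function(f)
      if (length(f) >= 4L) f[3L] else NA_character_, "")))
    en <- suppressWarnings(as.numeric(vapply(fields, function(f)
      if (length(f) >= 4L) f[4L] else NA_character_, "")))
    bad <- which(four & (is.na(st) | is.na(en)))
    if (length(bad))
      stop("line ", lineno[bad[1L]], ": non-numeric match coordinates")
    bad <- which(four & en < st)
    if (length(bad))
      stop("line ", lineno[bad[1L]], ": match end < start")
    ml[four] <- en[four] - st[four] + 1
  }
  annotation_table(data.frame(protein = protein, keyword = keyword,
                              match_length = ml, stringsAsFactors = FALSE),
                   universe)
}

#' Proteins carrying a keyword
#' @param annotations an [annotation_table()].
#' @param keyword a keyword accession.
#' @return character vector of protein ids (possibly empty).
#' @export
keyword_proteins <- function(annotations, keyword) {
  a <- annotations$assignments
  unique(a$protein[a$keyword == keyword])
}

#' Correspondence score between a cluster and a keyword set
#'
#' `CS(C, K) = |c ∩ k| / |c ∪ k|` — the Jaccard overlap between the
#' cluster's protein set `c` and the set `k` of proteins annotated with
#' keyword `K`. It ranges from 0 (no correspondence) to 1 (the cluster is
#' exactly the set of proteins carrying the keyword), is symmetric in its
#' arguments, and equals `TP / (TP + FP + FN)` in confusion-matrix terms.
#'
#' @param cluster character vector of protein ids (non-empty).
#' @param k character vector of proteins carrying the keyword.
#' @return CS in `[0, 1]`; an empty `k` gives 0 with a warning.
#' @export
correspondence_score <- function(cluster, k) {
  cluster <- unique(cluster); k <- unique(k)
  if (!length(cluster)) stop("cluster must be non-empty")
  if (!length(k)) {
    warning("empty keyword set; CS is 0")
    return(0)
  }
  tp <- length(intersect(cluster, k))
  tp / (length(cluster) + length(k) - tp)
}

#' Confusion counts and scores for a cluster/keyword pair
#'
#' @param cluster character vector of protein ids.
#' @param keyword keyword accession.
#' @param annotations an [annotation_table()].
#' @return one-row data frame: `keyword`, `TP`, `FP`, `TN`, `FN`, `cs`,
#'   `specificity_annotated` (`NA` when no member is annotated),
#'   `specificity_all`.
#' @export
keyword_cluster_score <- function(cluster, keyword, annotations) {
  cluster <- unique(cluster)
  k <- keyword_proteins(annotations, keyword)
  U <- length(annotations$universe)
  tp <- length(intersect(cluster, k))
  fp <- length(cluster) - tp
  fn <- length(k) - tp
  tn <- U - tp - fp - fn
  annotated <- setdiff(cluster, annotations$unannotated)
  data.frame(keyword = keyword, TP = tp, FP = fp, TN = tn, FN = fn,
             cs = if (tp + fp + fn > 0) tp / (tp + fp + fn) else 0,
             specificity_annotated = if (length(annotated))
               tp / length(annotated) else NA_real_,
             specificity_all = tp / length(cluster),
             stringsAsFactors = FALSE)
}

#' Specificity (purity) of a family for a keyword
#'
#' In `annotated-only` mode: the fraction of the family's *annotated*
#' members (those carrying at least one keyword) that carry `keyword`;
#' undefined (`NA`) when no member is annotated. In `all-as-fp` mode the
#' denominator is the full family size, i.e. unannotated members count as
#' false positives.
#'
#' @inheritParams keyword_cluster_score
#' @param mode `"annotated-only"` or `"all-as-fp"`.
#' @return specificity in `[0, 1]`, or `NA`.
#' @export
family_specificity <- function(cluster, keyword, annotations,
                               mode = c("annotated-only", "all-as-fp")) {
  mode <- match.arg(mode)
  cluster <- unique(cluster)
  if (!length(cluster)) stop("cluster must be non-empty")
  with_k <- length(intersect(cluster, keyword_proteins(annotations, keyword)))
  if (mode == "all-as-fp") return(with_k / length(cluster))
  annotated <- setdiff(cluster, annotations$unannotated)
  if (!length(annotated)) return(NA_real_)
  with_k / length(annotated)
}

#' Name a cluster by its best-corresponding keyword
#'
#' Scans the keywords carried by the cluster's members and returns the one
#' maximizing CS, provided CS reaches the naming floor; ties are broken
#' lexicographically by keyword accession.
#'
#' @inheritParams keyword_cluster_score
#' @param floor minimal CS needed for a name (default 0.2, aligned with the
#'   annotation-gain purity floor).
#' @return one-row data frame `keyword`, `cs`; keyword is `NA` ("unnamed")
#'   when no keyword reaches the floor.
#' @export
name_cluster <- function(cluster, annotations, floor = 0.2) {
  cluster <- unique(cluster)
  if (!length(cluster)) stop("cluster must be non-empty")
  a <- annotations$assignments
  cand <- sort(unique(a$keyword[a$protein %in% cluster]))
  if (!length(cand))
    return(data.frame(keyword = NA_character_, cs = NA_real_))
  cs <- vapply(cand, function(K)
    correspondence_score(cluster, keyword_proteins(annotations, K)), 0)
  best <- which(cs == max(cs))[1L]          # cand is sorted: lexicographic tie
  if (cs[best] < floor)
    return(data.frame(keyword = NA_character_, cs = max(cs)))
  data.frame(keyword = cand[best], cs = cs[best], stringsAsFactors = FALSE)
}

#' Guilt-by-association annotation gain
#'
#' For every family and keyword whose annotated-only specificity exceeds
#' `purity_min`, each *unannotated* member (a protein carrying no keyword at
#' all) is assigned that keyword. Proteins that already carry any keyword are
#' never gain targets.
#'
#' @param partition a `family_partition`.
#' @param annotations an [annotation_table()].
#' @param purity_min purity floor, strict (`> purity_min`); default 0.2.
#' @return object of class `annotation_gain`: list with `gains` (one row per
#'   qualifying family/keyword: `family`, `keyword`, `n_gained`, `TP`, `FP`),
#'   `gained_fraction` (fraction of formerly unannotated proteins in the
#'   partition that received at least one keyword) and `augmented` (the
#'   annotation table extended with the inferred assignments).
#' @export
annotation_gain <- function(partition, annotations, purity_min = 0.2) {
  stopifnot(inherits(partition, "family_partition"),
            purity_min > 0, purity_min <= 1)
  a <- annotations$assignments
  rows <- list(); new_assign <- list()
  for (fid in names(partition$families)) {
    fam <- partition$families[[fid]]
    ann <- fam[!fam %in% annotations$unannotated]
    un <- setdiff(fam, ann)
    if (!length(ann)) next
    kws <- sort(unique(a$keyword[a$protein %in% ann]))
    for (K in kws) {
      tp <- length(intersect(ann, keyword_proteins(annotations, K)))
      purity <- tp / length(ann)
      if (purity > purity_min) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = fid, keyword = K, n_gained = length(un),
          TP = tp, FP = length(ann) - tp, stringsAsFactors = FALSE)
        if (length(un))
          new_assign[[length(new_assign) + 1L]] <- data.frame(
            protein = un, keyword = K,
            match_length = mean(a$match_length[a$keyword == K &
                                                 a$protein %in% ann]),
            stringsAsFactors = FALSE)
      }
    }
  }
  gains <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(), keyword = character(),
               n_gained = integer(), TP = integer(), FP = integer())
  part_prots <- unlist(all_clusters(partition), use.names = FALSE)
  unann <- intersect(annotations$unannotated, part_prots)
  gained_prots <- unique(unlist(lapply(new_assign, `[[`, "protein")))
  augmented <- annotation_table(
    rbind(a, if (length(new_assign)) do.call(rbind, new_assign)),
    annotations$universe)
  structure(list(gains = gains,
                 gained_fraction = if (length(unann))
                   length(gained_prots) / length(unann) else NA_real_,
                 augmented = augmented),
            class = "annotation_gain")
}

#' @export
print.annotation_gain <- function(x, ...) {
  cat("annotation_gain: ", nrow(x$gains), " family/keyword transfers, ",
      if (is.na(x$gained_fraction)) "no unannotated proteins" else
        paste0(round(100 * x$gained_fraction, 1),
               "% of unannotated proteins annotated"), "\n", sep = "")
  invisible(x)
}

#' Report keywords with pure families in a size band
#'
#' For every keyword, collects the families in `[min_size, max_size]` whose
#' annotated-only specificity for that keyword reaches `specificity_floor`,
#' and aggregates: mean match length, numbers of annotated and unannotated
#' proteins, total proteins, and number of clusters.
#'
#' @inheritParams annotation_gain
#' @param min_size,max_size family-size band (defaults 100 and 300).
#' @param specificity_floor minimal annotated-only specificity (default 1.0,
#'   i.e. fully pure families).
#' @return data frame: `keyword`, `avg_match_length`, `n_annotated`,
#'   `n_unannotated`, `n_proteins`, `n_clusters`.
#' @export
report_pure_families <- function(partition, annotations, min_size = 100,
                                 max_size = 300, specificity_floor = 1.0) {
  stopifnot(min_size <= max_size)
  a <- annotations$assignments
  acc <- list()
  for (fid in names(partition$families)) {
    fam <- partition$families[[fid]]
    if (length(fam) < min_size || length(fam) > max_size) next
    ann <- fam[!fam %in% annotations$unannotated]
    if (!length(ann)) next
    for (K in sort(unique(a$keyword[a$protein %in% ann]))) {
      inK <- intersect(ann, keyword_proteins(annotations, K))
      if (length(inK) / length(ann) >= specificity_floor) {
        ml <- a$match_length[a$keyword == K & a$protein %in% fam]
        acc[[length(acc) + 1L]] <- data.frame(
          keyword = K,
          avg_match_length = if (all(is.na(ml))) NA_real_ else
            mean(ml, na.rm = TRUE),
          n_annotated = length(inK),
          n_unannotated = length(fam) - length(ann),
          n_proteins = length(fam), n_clusters = 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(acc))
    return(data.frame(keyword = character(), avg_match_length = numeric(),
                      n_annotated = integer(), n_unannotated = integer(),
                      n_proteins = integer(), n_clusters = integer()))
  d <- do.call(rbind, acc)
  out <- do.call(rbind, lapply(split(d, d$keyword), function(g) data.frame(
    keyword = g$keyword[1L],
    avg_match_length = stats::weighted.mean(g$avg_match_length, g$n_annotated,
                                            na.rm = TRUE),
    n_annotated = sum(g$n_annotated),
    n_unannotated = sum(g$n_unannotated),
    n_proteins = sum(g$n_proteins),
    n_clusters = nrow(g), stringsAsFactors = FALSE)))
  out <- out[order(-out$n_proteins, out$keyword), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report safe annotation-gain candidates
#'
#' Family/keyword pairs suitable for automatic keyword transfer: the family
#' has at least `min_proteins` members, the false-positive rate
#' `FP / (TP + FP)` is strictly below `max_fp_rate`, and the mean matched
#' domain length of the keyword within the family is strictly above
#' `min_domain_len` amino acids.
#'
#' @inheritParams annotation_gain
#' @param min_proteins minimal family size (default 40).
#' @param max_fp_rate maximal false-positive rate, strict (default 0.05).
#' @param min_domain_len minimal mean match length in aa, strict (default
#'   75); requires 4-column annotation input when positive.
#' @return data frame: `family`, `keyword`, `n_gain`, `TP`, `FP`,
#'   `fp_rate`, `avg_match_length`.
#' @export
report_gain_candidates <- function(partition, annotations, min_proteins = 40,
                                   max_fp_rate = 0.05, min_domain_len = 75) {
  stopifnot(min_proteins > 0, max_fp_rate > 0)
  a <- annotations$assignments
  acc <- list()
  for (fid in names(partition$families)) {
    fam <- partition$families[[fid]]
    if (length(fam) < min_proteins) next
    ann <- fam[!fam %in% annotations$unannotated]
    if (!length(ann)) next
    for (K in sort(unique(a$keyword[a$protein %in% ann]))) {
      tp <- length(intersect(ann, keyword_proteins(annotations, K)))
      if (tp == 0L) next
      fp <- length(ann) - tp
      fp_rate <- fp / (tp + fp)
      if (fp_rate >= max_fp_rate) next
      ml <- a$match_length[a$keyword == K & a$protein %in% fam]
      mlen <- if (all(is.na(ml))) NA_real_ else mean(ml, na.rm = TRUE)
      if (min_domain_len > 0) {
        if (is.na(mlen))
          stop("match lengths are required when min_domain_len > 0; ",
               "2-column annotation input carries none")
        if (mlen <= min_domain_len) next
      }
      acc[[length(acc) + 1L]] <- data.frame(
        family = fid, keyword = K, n_gain = length(fam) - length(ann),
        TP = tp, FP = fp, fp_rate = fp_rate, avg_match_length = mlen,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(acc))
    return(data.frame(family = character(), keyword = character(),
                      n_gain = integer(), TP = integer(), FP = integer(),
                      fp_rate = numeric(), avg_match_length = numeric()))
  out <- do.call(rbind, acc)
  out <- out[order(-out$n_gain, out$family, out$keyword), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trace a keyword through the merge forest
#'
#' Computes the correspondence score of every node in the forest for one
#' keyword and returns the `top_n` nodes ranked by CS (ties: smaller cluster
#' first, then smaller node id). Nodes whose LifeTime exceeds `stable_lt`
#' are flagged as interim-stable: long-lived clusters along the merge
#' trajectory of the keyword.
#'
#' @param forest a `merge_forest`.
#' @param keyword keyword accession.
#' @param annotations an [annotation_table()].
#' @param top_n number of clusters to report (default 100).
#' @param stable_lt LifeTime floor (in PL units) for the interim-stable flag
#'   (default 10).
#' @return data frame: `node_id`, `cs`, `size`, `pl`, `lt`,
#'   `interim_stable`; empty (with a warning) when the keyword is absent.
#' @export
keyword_trace <- function(forest, keyword, annotations, top_n = 100,
                          stable_lt = 10) {
  stopifnot(inherits(forest, "merge_forest"), top_n >= 1)
  k <- keyword_proteins(annotations, keyword)
  if (!length(k)) {
    warning("keyword '", keyword, "' absent from the annotation table")
    return(data.frame(node_id = integer(), cs = numeric(), size = integer(),
                      pl = numeric(), lt = numeric(),
                      interim_stable = logical()))
  }
  nt <- node_table(forest)
  N <- length(forest$leaves)
  inter <- as.numeric(forest$leaves %in% k)
  inter <- c(inter, numeric(forest$M))
  if (forest$M)
    for (r in seq_len(forest$M))
      inter[forest$merges$new_id[r] + 1L] <-
        inter[forest$merges$child1[r] + 1L] +
        inter[forest$merges$child2[r] + 1L]
  inter <- inter[nt$node_id + 1L]
  cs <- inter / (nt$size + length(k) - inter)
  ord <- order(-cs, nt$size, nt$node_id)
  top <- utils::head(ord, top_n)
  data.frame(node_id = nt$node_id[top], cs = cs[top], size = nt$size[top],
             pl = nt$pl[top], lt = nt$lt[top],
             interim_stable = nt$lt[top] > stable_lt)
}
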