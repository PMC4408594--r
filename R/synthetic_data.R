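#' Configuration for the synthetic-data generator
#'
#' Describes a planted-family world: species and proteome sizes, a partition
#' of the proteins into families, within-family similarity strength, a rate
#' of spurious between-family edges near the E-value ceiling, and a keyword
#' annotation with controlled coverage and noise. The defaults emulate the
#' regime the clustering is meant for: families strongly connected at
#' E-values far below the ceiling (`-log10 E` in `[20, 120]`), no or rare
#' cross-family similarity just under the ceiling, and 73% keyword coverage
#' (the typical fraction of arthropod proteins carrying a Pfam assignment).
#'
#' @param n_species number of species (default 18).
#' @param proteins_per_species scalar or per-species vector of proteome
#'   sizes (default 40 per species).
#' @param n_families number of planted families (default 40).
#' @param family_size_distribution list: `name` (only `"geometric-tail"`),
#'   `mean_size`, `tail_prob`, `tail_mult` — geometric sizes with a
#'   heavy-tail component so a few families dwarf the rest, echoing real
#'   family-size distributions.
#' @param within_family_logE interval of `-log10 E` for within-family pairs.
#' @param between_family_edge_rate probability of a spurious cross-family
#'   edge (default 0).
#' @param between_family_logE interval of `-log10 E` for spurious edges,
#'   near the ceiling (default `c(-2, 0)`, i.e. E in `[1, 100]`).
#' @param annotation_coverage fraction of each family annotated (default
#'   0.73).
#' @param annotation_noise probability that an annotated protein carries a
#'   wrong (other family's) keyword (default 0).
#' @param e_ceiling E-value ceiling of the generated graph (default 100).
#' @param seed integer seed; mandatory, every stochastic draw goes through
#'   one generator keyed by it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 18L,
                             proteins_per_species = 40L,
                             n_families = 40L,
                             family_size_distribution = list(
                               name = "geometric-tail", mean_size = 12,
                               tail_prob = 0.08, tail_mult = 8),
                             within_family_logE = c(20, 120),
                             between_family_edge_rate = 0,
                             between_family_logE = c(-2, 0),
                             annotation_coverage = 0.73,
                             annotation_noise = 0,
                             e_ceiling = 100,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  counts <- if (length(proteins_per_species) == 1L)
    rep(as.integer(proteins_per_species), n_species) else
      as.integer(proteins_per_species)
  if (length(counts) != n_species)
    stop("proteins_per_species must be scalar or length n_species")
  stopifnot(all(counts > 0), n_families >= 1,
            annotation_coverage >= 0, annotation_coverage <= 1,
            annotation_noise >= 0, annotation_noise <= 1,
            between_family_edge_rate >= 0, between_family_edge_rate <= 1,
            within_family_logE[1] <= within_family_logE[2],
            between_family_logE[1] <= between_family_logE[2])
  if (sum(counts) < 2L * n_families)
    stop("infeasible family sizes: fewer than 2 proteins per family")
  structure(list(n_species = as.integer(n_species), counts = counts,
                 n_families = as.integer(n_families),
                 family_size_distribution = family_size_distribution,
                 within_family_logE = within_family_logE,
                 between_family_edge_rate = between_family_edge_rate,
                 between_family_logE = between_family_logE,
                 annotation_coverage = annotation_coverage,
                 annotation_noise = annotation_noise,
                 e_ceiling = e_ceiling, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a planted-family similarity world
#'
#' Generates, deterministically under the config seed: a similarity graph
#' whose within-family pairs are fully connected at strong E-values and
#' whose cross-family edges (if any) sit near the ceiling; a per-family
#' keyword annotation applied to a coverage fraction of members and
#' corrupted at the noise rate; the species catalog (proteins assigned to
#' species by weighted round-robin); and the ground-truth partition.
#'
#' @param config a [synthetic_config()].
#' @return list with `graph` (a [similarity_graph()]), `annotations` (an
#'   [annotation_table()]), `catalog` (a [proteome_catalog()]), `truth` (a
#'   `family_partition` holding the planted families) and `species_of`.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, simulate_families_impl(config))
}

simulate_families_impl <- function(config) {
  counts <- config$counts
  N <- sum(counts)
  species <- sprintf("sp%02d", seq_len(config$n_species))
  proteins <- sprintf("P%05d", seq_len(N))

  # weighted round-robin species assignment: species s occupies the sorted
  # fractional positions (k - 1/2) / count_s, so proteomes interleave evenly
  pos <- unlist(lapply(seq_along(counts), function(s)
    (seq_len(counts[s]) - 0.5) / counts[s]))
  sp_idx <- rep(seq_along(counts), counts)[order(pos, rep(seq_along(counts),
                                                          counts))]
  species_of <- stats::setNames(species[sp_idx], proteins)

  # family sizes: truncated geometric with a heavy-tail component, rescaled
  # to the protein total by largest remainder, floor of 2
  fd <- config$family_size_distribution
  nf <- config$n_families
  raw <- stats::rgeom(nf, 1 / max(fd$mean_size, 2)) + 2
  tail_hit <- stats::runif(nf) < fd$tail_prob
  raw[tail_hit] <- raw[tail_hit] * fd$tail_mult
  target <- raw / sum(raw) * N
  sizes <- pmax(floor(target), 2)
  shortfall <- N - sum(sizes)
  if (shortfall > 0) {
    frac <- target - floor(target)
    add <- order(-frac)[seq_len(shortfall)]
    sizes[add] <- sizes[add] + 1
  } else if (shortfall < 0) {
    for (i in order(-sizes)) {
      if (shortfall == 0) break
      take <- min(sizes[i] - 2, -shortfall)
      sizes[i] <- sizes[i] - take
      shortfall <- shortfall + take
    }
    if (shortfall != 0) stop("infeasible family sizes for ", N, " proteins")
  }
  perm <- sample.int(N)
  fam_of <- integer(N)
  fam_of[perm] <- rep(seq_len(nf), sizes)
  families <- split(proteins, fam_of)
  names(families) <- sprintf("F%03d", seq_len(nf))

  # within-family clique edges
  lo <- config$within_family_logE[1]; hi <- config$within_family_logE[2]
  edge_list <- lapply(families, function(fam) {
    n <- length(fam)
    if (n < 2L) return(NULL)
    pr <- t(utils::combn(fam, 2L))
    data.frame(p1 = pr[, 1L], p2 = pr[, 2L],
               evalue = 10^(-stats::runif(nrow(pr), lo, hi)),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_list)

  # spurious cross-family edges near the ceiling
  rate <- config$between_family_edge_rate
  if (rate > 0) {
    n_cross <- sum(as.numeric(sizes) %*% t(as.numeric(sizes))) / 2 -
      sum(as.numeric(sizes)^2) / 2
    want <- stats::rbinom(1L, round(n_cross), rate)
    got <- character(0); acc <- list()
    while (length(acc) < want) {
      i <- sample.int(N, 1L); j <- sample.int(N, 1L)
      if (i == j || fam_of[i] == fam_of[j]) next
      key <- paste(min(i, j), max(i, j))
      if (key %in% got) next
      got <- c(got, key)
      acc[[length(acc) + 1L]] <- data.frame(
        p1 = proteins[min(i, j)], p2 = proteins[max(i, j)],
        evalue = 10^(-stats::runif(1L, config$between_family_logE[1],
                                   config$between_family_logE[2])),
        stringsAsFactors = FALSE)
    }
    if (length(acc)) edges <- rbind(edges, do.call(rbind, acc))
  }
  edges$evalue <- pmin(edges$evalue, config$e_ceiling)

  # one keyword per family, coverage fraction annotated, noise-corrupted
  keywords <- sprintf("KW%04d", seq_len(nf))
  dom_len <- round(stats::runif(nf, 80, 400))
  ann_rows <- list()
  for (f in seq_len(nf)) {
    fam <- families[[f]]
    n_ann <- round(config$annotation_coverage * length(fam))
    if (n_ann == 0L) next
    chosen <- sample(fam, n_ann)
    kw <- rep(keywords[f], n_ann)
    if (config$annotation_noise > 0 && nf > 1L) {
      flip <- stats::runif(n_ann) < config$annotation_noise
      kw[flip] <- vapply(which(flip), function(i)
        sample(keywords[-f], 1L), "")
    }
    ann_rows[[f]] <- data.frame(protein = chosen, keyword = kw,
                                match_length = dom_len[match(kw, keywords)],
                                stringsAsFactors = FALSE)
  }
  assignments <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(protein = character(), keyword = character(),
               match_length = numeric())

  graph <- similarity_graph(proteins, edges, config$e_ceiling, species_of)
  truth <- structure(list(cut_pl = NA_real_, m_star = NA_integer_,
                          min_size = 2L, families = families,
                          excluded = list()),
                     class = "family_partition")
  list(graph = graph,
       annotations = annotation_table(assignments, proteins),
       catalog = proteome_catalog(species, counts),
       truth = truth,
       species_of = species_of)
}

#' Bundled 18-species arthropod proteome catalog
#'
#' The packaged catalog of 18 completely sequenced arthropod proteomes
#' (UniProtKB and Hymenoptera Genome Database releases; includes
#' *Daphnia pulex* as outgroup) with per-species protein counts. It drives
#' the multinomial species-occupancy null. The transcribed counts reconcile
#' exactly with the collection's documented totals: 287 405 proteins overall,
#' 206 615 from UniProtKB plus 80 790 from HGD, and 138 762 Hymenoptera
#' proteins.
#'
#' @return a [proteome_catalog()] whose species are organism names; the full
#'   table (taxon id, source database, clade) is attached as attribute
#'   `"table"`.
#' @export
arthropod_catalog <- function() {
  path <- system.file("extdata", "arthropod_proteomes.tsv",
                      package = "protofam", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  cat <- proteome_catalog(df$organism, df$n_proteins)
  attr(cat, "table") <- df
  cat
}
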