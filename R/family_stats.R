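#' Proteome catalog
#'
#' A catalog of species and their proteome sizes. The proportions
#' `p_s = count_s / total` define the multinomial null model for the number
#' of distinct species represented in a random cluster of a given size.
#'
#' @param species character vector of species identifiers.
#' @param counts positive integer protein counts, one per species.
#' @return object of class `proteome_catalog` with elements `species`,
#'   `counts` and `proportions`.
#' @export
proteome_catalog <- function(species, counts) {
  species <- as.character(species)
  counts <- as.numeric(counts)
  if (length(species) != length(counts))
    stop("species and counts must have equal length")
  if (anyDuplicated(species)) stop("duplicated species identifiers")
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("protein counts must be positive integers")
  p <- counts / sum(counts)
  stopifnot(abs(sum(p) - 1) < 1e-12)
  structure(list(species = species, counts = counts, proportions = p),
            class = "proteome_catalog")
}

#' @export
print.proteome_catalog <- function(x, ...) {
  cat("proteome_catalog: ", length(x$species), " species, ",
      format(sum(x$counts), big.mark = " "), " proteins\n", sep = "")
  invisible(x)
}

#' Read a proteome catalog from a 2-column TSV (species, protein_count)
#' @param path input path; `#` comments allowed.
#' @export
read_proteome_catalog <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("species", "count"),
                          comment.char = "#", quote = "",
                          colClasses = c("character", "numeric"))
  proteome_catalog(df$species, df$count)
}

#' Species-composition summary of a family partition
#'
#' @param partition a `family_partition` (see [cut.merge_forest()]).
#' @param species_of named character vector mapping protein id to species.
#' @return list with `per_family` (family, size, n_species), `per_family_species`
#'   (long table family x species member counts) and `per_species` (species,
#'   n_families: number of families containing at least one of its proteins).
#' @export
species_summary <- function(partition, species_of) {
  stopifnot(inherits(partition, "family_partition"))
  fams <- partition$families
  if (!length(fams))
    return(list(per_family = data.frame(family = character(), size = integer(),
                                        n_species = integer()),
                per_family_species = data.frame(family = character(),
                                                species = character(),
                                                n = integer()),
                per_species = data.frame(species = character(),
                                         n_families = integer())))
  prots <- unlist(fams, use.names = FALSE)
  missing <- setdiff(prots, names(species_of))
  if (length(missing))
    stop("proteins without a species label: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)",
                                            length(missing) - 10L))
  fam_id <- rep(names(fams), lengths(fams))
  sp <- unname(species_of[prots])
  long <- as.data.frame(table(family = fam_id, species = sp),
                        responseName = "n", stringsAsFactors = FALSE)
  long <- long[long$n > 0, , drop = FALSE]
  rownames(long) <- NULL
  per_family <- data.frame(
    family = names(fams),
    size = unname(lengths(fams)),
    n_species = as.integer(tapply(long$species, long$family,
                                  function(x) length(unique(x)))[names(fams)]))
  per_species <- as.data.frame(table(species = unique(long[c("family", "species")])$species),
                               responseName = "n_families",
                               stringsAsFactors = FALSE)
  list(per_family = per_family, per_family_species = long,
       per_species = per_species)
}

#' Expected number of distinct species in a random cluster
#'
#' Under multinomial sampling with replacement of `n` proteins with species
#' probabilities `p_s`, the expected number of distinct species represented
#' is `sum_s (1 - (1 - p_s)^n)`.
#'
#' @param catalog a [proteome_catalog()].
#' @param n cluster size (number of proteins drawn), `n >= 1`.
#' @return expected occupancy (numeric).
#' @export
expected_distinct_species <- function(catalog, n) {
  stopifnot(inherits(catalog, "proteome_catalog"), n >= 1)
  sum(1 - (1 - catalog$proportions)^n)
}

#' Exact occupancy distribution of distinct species counts
#'
#' Computes `P(#distinct species = d)` for `d = 1..S` under multinomial
#' sampling of `n` proteins, by inclusion-exclusion over species subsets:
#' with `A_t = sum over subsets T of size t of (sum_{s in T} p_s)^n`,
#' `P(D = d) = sum_{t<=d} (-1)^(d-t) * choose(S-t, d-t) * A_t`.
#'
#' Subset enumeration is `2^S`; the computation is guarded to `S <= 25`.
#'
#' @inheritParams expected_distinct_species
#' @return numeric vector of length `S`, names `1..S`, summing to 1.
#' @export
occupancy_distribution <- function(catalog, n) {
  stopifnot(inherits(catalog, "proteome_catalog"), n >= 1)
  p <- catalog$proportions
  S <- length(p)
  if (S > 25) stop("exact occupancy is limited to 25 species (2^S subsets)")
  # subset sums by doubling: q[m] = sum of p over the bits of m
  q <- 0; sz <- 0L
  for (s in seq_len(S)) {
    q <- c(q, q + p[s])
    sz <- c(sz, sz + 1L)
  }
  A <- vapply(0:S, function(t) sum(q[sz == t]^n), 0)
  Pd <- vapply(1:S, function(d) {
    t <- 0:d
    sum((-1)^(d - t) * choose(S - t, d - t) * A[t + 1L])
  }, 0)
  # the signed sums can leave tiny negative residue at machine precision
  stats::setNames(pmin(pmax(Pd, 0), 1), 1:S)
}

#' Tail probability of species occupancy
#'
#' Probability that a random cluster of `n` proteins, sampled multinomially
#' with the catalog's species proportions, contains at least `k` distinct
#' species. The exact method uses the inclusion-exclusion occupancy
#' distribution; the Monte-Carlo method draws `reps` multinomial samples and
#' returns the empirical frequency with a binomial standard error attached as
#' attribute `"se"`.
#'
#' @inheritParams expected_distinct_species
#' @param k species threshold, `1 <= k` (values above the species count
#'   return 0 with a warning).
#' @param method `"exact"` or `"monte-carlo"`.
#' @param reps number of Monte-Carlo draws (at least 1000).
#' @param seed integer seed for the Monte-Carlo draws.
#' @return probability; for `"monte-carlo"` with attribute `"se"`.
#' @export
tail_prob_distinct_species <- function(catalog, n, k,
                                       method = c("exact", "monte-carlo"),
                                       reps = 1e5, seed = NULL) {
  stopifnot(inherits(catalog, "proteome_catalog"), n >= 1, k >= 1)
  method <- match.arg(method)
  S <- length(catalog$proportions)
  if (k > S) {
    warning("k exceeds the number of species; probability is 0")
    return(0)
  }
  if (method == "exact") {
    Pd <- occupancy_distribution(catalog, n)
    return(min(1, sum(Pd[k:S])))
  }
  if (reps < 1000) stop("monte-carlo requires at least 1000 replicates")
  hits <- 0; done <- 0
  with_seed(seed, {
    while (done < reps) {
      chunk <- min(1e5, reps - done)
      draws <- stats::rmultinom(chunk, n, catalog$proportions)
      hits <- hits + sum(colSums(draws > 0) >= k)
      done <- done + chunk
    }
  })
  p <- hits / reps
  structure(p, se = sqrt(p * (1 - p) / reps))
}

# run expr under a temporary RNG state seeded with `seed` (NULL = leave RNG
# alone), restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
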