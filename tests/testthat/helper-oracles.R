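# Independent oracles: deliberately naive implementations used to check the
# package's efficient code paths.

# naive O(n^3) re-scan agglomerative clustering: every step recomputes every
# cluster-pair linkage from the raw leaf-pair matrix
naive_build_forest <- function(graph, linkage = "geometric-mean-E") {
  mode <- if (linkage %in% c("geometric-mean-E", "arithmetic-mean-negloge"))
    "mean" else linkage
  N <- length(graph$proteins)
  logceil <- log10(graph$e_ceiling)
  L <- matrix(logceil, N, N)          # filled with ceiling for missing pairs
  P <- matrix(FALSE, N, N)            # which leaf pairs have a real edge
  idx <- setNames(seq_len(N), graph$proteins)
  e <- graph$edges
  if (nrow(e)) {
    i <- idx[e$p1]; j <- idx[e$p2]
    v <- log10(pmax(e$evalue, 1e-180))
    L[cbind(i, j)] <- v; L[cbind(j, i)] <- v
    P[cbind(i, j)] <- TRUE; P[cbind(j, i)] <- TRUE
  }
  clusters <- lapply(seq_len(N), identity)   # leaf indices per cluster
  ids <- seq_len(N) - 1L
  merges <- NULL
  m <- 0L
  repeat {
    nc <- length(clusters)
    best <- NULL
    if (nc >= 2L) {
      for (a in seq_len(nc - 1L)) for (b in (a + 1L):nc) {
        ma <- clusters[[a]]; mb <- clusters[[b]]
        if (!any(P[ma, mb])) next
        d <- switch(mode,
                    mean = mean(L[ma, mb, drop = FALSE]),
                    single = min(L[ma, mb][P[ma, mb]]),
                    complete = max(L[ma, mb, drop = FALSE]))
        lo <- min(ids[a], ids[b]); hi <- max(ids[a], ids[b])
        cand <- c(d, lo, hi)
        if (is.null(best) ||
            cand[1] < best[1] ||
            (cand[1] == best[1] && (cand[2] < best[2] ||
                                    (cand[2] == best[2] && cand[3] < best[3])))) {
          best <- cand; ba <- a; bb <- b
        }
      }
    }
    if (is.null(best)) break
    m <- m + 1L
    new_id <- N + m - 1L
    merges <- rbind(merges,
                    data.frame(step = m, child1 = min(ids[ba], ids[bb]),
                               child2 = max(ids[ba], ids[bb]),
                               new_id = new_id, linkage_value = best[1]))
    clusters[[ba]] <- c(clusters[[ba]], clusters[[bb]])
    ids[ba] <- new_id
    clusters[[bb]] <- NULL
    ids <- ids[-bb]
  }
  merges
}

# brute-force connected components by flood fill
flood_fill_components <- function(graph) {
  prots <- graph$proteins
  adj <- setNames(vector("list", length(prots)), prots)
  for (r in seq_len(nrow(graph$edges))) {
    a <- graph$edges$p1[r]; b <- graph$edges$p2[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(0)
  comps <- list()
  for (p in prots) {
    if (p %in% seen) next
    queue <- p; comp <- character(0)
    while (length(queue)) {
      q <- queue[1L]; queue <- queue[-1L]
      if (q %in% comp) next
      comp <- c(comp, q)
      queue <- c(queue, setdiff(adj[[q]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# random sparse similarity graph for oracle equivalence checks
random_graph <- function(seed, n_min = 5L, n_max = 50L) {
  set.seed(seed)
  n <- if (n_min == n_max) n_min else sample(n_min:n_max, 1L)
  prots <- sprintf("q%03d", seq_len(n))
  pairs <- t(combn(prots, 2L))
  keep <- runif(nrow(pairs)) < runif(1L, 0.1, 0.6)
  edges <- data.frame(p1 = pairs[keep, 1L], p2 = pairs[keep, 2L],
                      evalue = 10^(-runif(sum(keep), -2, 80)),
                      stringsAsFactors = FALSE)
  similarity_graph(prots, edges, e_ceiling = 100)
}

# exact occupancy tail by full enumeration of all S^n outcome sequences
enumerate_tail_prob <- function(p, n, k) {
  S <- length(p)
  grid <- do.call(expand.grid, rep(list(seq_len(S)), n))
  probs <- apply(grid, 1L, function(seq) prod(p[seq]))
  distinct <- apply(grid, 1L, function(seq) length(unique(seq)))
  sum(probs[distinct >= k])
}

# set-based correspondence score, computed from first principles
brute_cs <- function(c_set, k_set) {
  length(intersect(c_set, k_set)) / length(union(c_set, k_set))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
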