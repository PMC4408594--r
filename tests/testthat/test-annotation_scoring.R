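toy_partition <- function(fams) {
  structure(list(cut_pl = 70, m_star = NA_integer_, min_size = 1L,
                 families = fams, excluded = list()),
            class = "family_partition")
}

ann_from <- function(df, universe) annotation_table(df, universe)

test_that("annotation loading builds the multimap with averaged lengths", {
  path <- withr::local_tempfile()
  writeLines(c("p1\tK1", "p1\tK2", "p2\tK1"), path)
  a <- load_annotations(path, universe = c("p1", "p2", "p3"))
  expect_setequal(keyword_proteins(a, "K1"), c("p1", "p2"))
  expect_equal(sum(a$assignments$protein == "p1"), 2L)
  expect_equal(a$unannotated, "p3")

  writeLines(c("p1\tK1\t10\t189"), path)
  a <- load_annotations(path)
  expect_equal(a$assignments$match_length, 180)

  writeLines(c("p1\tK1\t10\t100", "p1\tK1\t20\t59"), path)
  a <- load_annotations(path)
  expect_equal(a$assignments$match_length, mean(c(91, 40)))

  writeLines(c("p1\tK1\t100\t10"), path)
  expect_error(load_annotations(path), "line 1.*end < start")

  writeLines(character(0), path)
  a <- load_annotations(path, universe = sprintf("p%d", 1:5))
  expect_length(a$unannotated, 5L)
})

test_that("correspondence score is the Jaccard overlap", {
  expect_equal(correspondence_score(c("p1", "p2"), c("p1", "p2")), 1.0)
  expect_equal(correspondence_score("p1", "p2"), 0.0)
  expect_equal(correspondence_score(c("p1", "p2", "p3"),
                                    c("p2", "p3", "p4")), 0.5)
  expect_warning(cs <- correspondence_score("p1", character(0)), "empty")
  expect_equal(cs, 0)
})

test_that("CS is symmetric, bounded, and agrees with brute force", {
  set.seed(7)
  pool <- sprintf("x%03d", 1:60)
  for (i in 1:200) {
    c_set <- sample(pool, sample(1:30, 1L))
    k_set <- sample(pool, sample(1:30, 1L))
    cs <- correspondence_score(c_set, k_set)
    expect_gte(cs, 0); expect_lte(cs, 1)
    expect_equal(cs, correspondence_score(k_set, c_set))
    expect_equal(cs, brute_cs(c_set, k_set))
    # and equals TP / (TP + FP + FN)
    tp <- length(intersect(c_set, k_set))
    expect_equal(cs, tp / (length(c_set) + length(k_set) - tp))
  }
})

test_that("confusion counts satisfy the marginal identities", {
  universe <- sprintf("u%02d", 1:30)
  a <- ann_from(data.frame(protein = universe[1:12], keyword = "K1"),
                universe)
  cl <- universe[9:20]
  sc <- keyword_cluster_score(cl, "K1", a)
  expect_equal(sc$TP + sc$FN, 12L)
  expect_equal(sc$TP + sc$FP, length(cl))
  expect_equal(sc$TP + sc$FP + sc$TN + sc$FN, 30L)
  expect_equal(sc$cs, sc$TP / (sc$TP + sc$FP + sc$FN))
})

test_that("specificity distinguishes annotated-only and all-as-fp modes", {
  fam <- sprintf("m%02d", 1:10)
  a <- ann_from(data.frame(protein = c(fam[1:6], fam[7:8]),
                           keyword = c(rep("K", 6), rep("Other", 2))), fam)
  expect_equal(family_specificity(fam, "K", a, "annotated-only"), 0.75)
  expect_equal(family_specificity(fam, "K", a, "all-as-fp"), 0.6)

  all_k <- ann_from(data.frame(protein = fam, keyword = "K"), fam)
  expect_equal(family_specificity(fam, "K", all_k, "annotated-only"), 1.0)
  expect_equal(family_specificity(fam, "K", all_k, "all-as-fp"), 1.0)

  none <- ann_from(data.frame(protein = character(), keyword = character()),
                   fam)
  expect_true(is.na(family_specificity(fam, "K", none, "annotated-only")))
  expect_equal(family_specificity(fam, "K", none, "all-as-fp"), 0.0)
})

test_that("cluster naming maximizes CS with a floor and lexicographic ties", {
  universe <- sprintf("n%02d", 1:10)
  a <- ann_from(data.frame(protein = universe[1:4], keyword = "K1"), universe)
  nm <- name_cluster(universe[1:4], a)
  expect_equal(nm$keyword, "K1"); expect_equal(nm$cs, 1.0)

  unannotated <- name_cluster(universe[5:8], a)
  expect_true(is.na(unannotated$keyword))

  tie <- ann_from(data.frame(protein = rep(universe[1:2], 2),
                             keyword = rep(c("KB", "KA"), each = 2)),
                  universe)
  expect_equal(name_cluster(universe[1:2], tie)$keyword, "KA")

  # below the naming floor -> unnamed
  weak <- ann_from(data.frame(protein = universe[1], keyword = "K1"),
                   universe)
  expect_true(is.na(name_cluster(universe, weak, floor = 0.2)$keyword))
})

test_that("annotation gain transfers keywords above the purity floor only", {
  fam <- sprintf("g%02d", 1:10)
  a <- ann_from(data.frame(protein = fam[1:3], keyword = "K"), fam)
  g <- annotation_gain(toy_partition(list(f1 = fam)), a)
  expect_equal(g$gains$n_gained, 7L)
  expect_equal(g$gains$TP, 3L)
  expect_equal(g$gained_fraction, 1.0)
  expect_length(g$augmented$unannotated, 0L)

  # purity 0.1 (1 of 10 annotated members) stays below the floor
  a2 <- ann_from(data.frame(protein = fam, keyword = c("K", rep("Z", 9))),
                 fam)
  g2 <- annotation_gain(toy_partition(list(f1 = fam)), a2)
  expect_false("K" %in% g2$gains$keyword)

  # fully annotated family gains nothing
  g3 <- annotation_gain(toy_partition(list(f1 = fam)), a2)
  expect_true(all(g3$gains$n_gained == 0L))
})

test_that("gain targets only unannotated proteins and is idempotent", {
  set.seed(31)
  prots <- sprintf("h%03d", 1:60)
  fams <- split(prots, rep(1:5, each = 12))
  names(fams) <- paste0("f", 1:5)
  rows <- do.call(rbind, lapply(seq_along(fams), function(i)
    data.frame(protein = sample(fams[[i]], 8), keyword = paste0("K", i))))
  a <- ann_from(rows, prots)
  part <- toy_partition(fams)
  g <- annotation_gain(part, a)
  gained <- setdiff(a$unannotated, g$augmented$unannotated)
  expect_true(all(gained %in% a$unannotated))
  expect_lte(length(g$augmented$unannotated), length(a$unannotated))
  # re-running on the augmented table adds nothing at the same floor
  g2 <- annotation_gain(part, g$augmented)
  expect_true(all(g2$gains$n_gained == 0L))
  expect_true(is.na(g2$gained_fraction) || g2$gained_fraction == 0)
})

test_that("pure-family report filters by size band and specificity", {
  fams <- list(inband = sprintf("a%03d", 1:120),
               small = sprintf("b%03d", 1:20))
  rows <- rbind(
    data.frame(protein = fams$inband, keyword = "KP",
               match_length = 150),
    data.frame(protein = fams$small, keyword = "KS", match_length = 90))
  a <- annotation_table(rows, unlist(fams, use.names = FALSE))
  rep1 <- report_pure_families(toy_partition(fams), a,
                               min_size = 100, max_size = 300)
  expect_equal(rep1$keyword, "KP")
  expect_equal(rep1$n_proteins, 120L)
  expect_equal(rep1$n_unannotated, 0L)
  expect_equal(rep1$avg_match_length, 150)
})

test_that("pure-family report row counts equal a brute-force filter", {
  set.seed(8)
  sim <- simulate_families(synthetic_config(
    seed = 8, n_species = 5, proteins_per_species = 60, n_families = 10,
    annotation_coverage = 0.8))
  part <- sim$truth
  a <- sim$annotations
  rep2 <- report_pure_families(part, a, min_size = 10, max_size = 100,
                               specificity_floor = 1.0)
  brute <- 0L
  for (fid in names(part$families)) {
    fam <- part$families[[fid]]
    if (length(fam) < 10 || length(fam) > 100) next
    ann <- fam[!fam %in% a$unannotated]
    if (!length(ann)) next
    kws <- unique(a$assignments$keyword[a$assignments$protein %in% ann])
    for (K in kws)
      if (length(intersect(ann, keyword_proteins(a, K))) == length(ann))
        brute <- brute + 1L
  }
  expect_equal(sum(rep2$n_clusters), brute)
})

test_that("gain-candidate report applies strict thresholds", {
  mk_fam <- function(id, n, n_ann, n_fp, len) {
    prots <- sprintf("%s%03d", id, seq_len(n))
    ann <- data.frame(protein = prots[seq_len(n_ann)],
                      keyword = paste0("K", id), match_length = len)
    if (n_fp > 0)
      ann$keyword[seq_len(n_fp)] <- "Kother"
    list(prots = prots, ann = ann)
  }
  f1 <- mk_fam("a", 50, 30, 0, 120)    # passes all filters
  f2 <- mk_fam("b", 50, 30, 5, 120)    # FP 5/30 > 5%
  f3 <- mk_fam("c", 30, 20, 0, 120)    # too small
  f4 <- mk_fam("d", 50, 30, 0, 60)     # domain too short
  fams <- list(fa = f1$prots, fb = f2$prots, fc = f3$prots, fd = f4$prots)
  a <- annotation_table(rbind(f1$ann, f2$ann, f3$ann, f4$ann),
                        unlist(fams, use.names = FALSE))
  out <- report_gain_candidates(toy_partition(fams), a)
  expect_equal(out$family[out$keyword != "Kother"], "fa")

  # FP rate of exactly 5% is excluded (strict <)
  f5 <- mk_fam("e", 60, 40, 2, 120)    # 2/40 = 5%
  a5 <- annotation_table(f5$ann, f5$prots)
  out5 <- report_gain_candidates(toy_partition(list(fe = f5$prots)), a5,
                                 max_fp_rate = 0.05)
  expect_false(paste0("K", "e") %in% out5$keyword)

  # permissive thresholds admit every (family, keyword) with >= 1 TP
  out_all <- report_gain_candidates(toy_partition(fams), a,
                                    min_proteins = 1, max_fp_rate = 1,
                                    min_domain_len = 0)
  want <- 0L
  for (fid in names(fams)) {
    ann <- fams[[fid]][!fams[[fid]] %in% a$unannotated]
    want <- want +
      length(unique(a$assignments$keyword[a$assignments$protein %in% ann]))
  }
  expect_equal(nrow(out_all), want)

  # missing lengths with a positive length filter is an error
  a2 <- annotation_table(data.frame(protein = f1$prots[1:30],
                                    keyword = "Ka"), f1$prots)
  expect_error(report_gain_candidates(toy_partition(list(fa = f1$prots)),
                                      a2, min_domain_len = 75),
               "2-column")
})

test_that("keyword trace ranks nodes by CS and flags stable clusters", {
  sim <- simulate_families(synthetic_config(
    seed = 12, n_species = 4, proteins_per_species = 30, n_families = 6,
    annotation_coverage = 1, annotation_noise = 0))
  f <- build_forest(sim$graph)
  a <- sim$annotations
  K <- a$assignments$keyword[1L]
  tr <- keyword_trace(f, K, a, top_n = 10)
  # the planted family's node attains the maximal CS: verify exhaustively
  nt <- node_table(f)
  best <- max(vapply(nt$node_id, function(id)
    correspondence_score(node_members(f, id), keyword_proteins(a, K)), 0))
  expect_equal(tr$cs[1L], best)
  expect_equal(tr$cs[1L], 1.0)   # full coverage, clean separation
  expect_true(all(diff(tr$cs) <= 1e-12))
  expect_true(all(tr$interim_stable == (tr$lt > 10)))

  # a keyword matching exactly one leaf ranks that leaf first with CS 1
  leaf_a <- annotation_table(data.frame(protein = f$leaves[1L],
                                        keyword = "Kleaf"), f$leaves)
  tr1 <- keyword_trace(f, "Kleaf", leaf_a, top_n = 5)
  expect_equal(tr1$node_id[1L], 0L)
  expect_equal(tr1$cs[1L], 1.0)

  # top_n larger than the node count returns all nodes
  trall <- keyword_trace(f, K, a, top_n = 1e6)
  expect_equal(nrow(trall), nrow(nt))

  expect_warning(tr0 <- keyword_trace(f, "missing", a), "absent")
  expect_equal(nrow(tr0), 0L)
})

test_that("CS degrades monotonically toward the root once k is contained", {
  sim <- simulate_families(synthetic_config(
    seed = 13, n_species = 3, proteins_per_species = 30, n_families = 5,
    annotation_coverage = 1, between_family_edge_rate = 0.05))
  f <- build_forest(sim$graph)
  a <- sim$annotations
  K <- a$assignments$keyword[1L]
  k <- keyword_proteins(a, K)
  checked <- 0L
  parent <- rep(NA_integer_, length(f$leaves) + f$M)
  for (r in seq_len(f$M)) {
    parent[f$merges$child1[r] + 1L] <- f$merges$new_id[r]
    parent[f$merges$child2[r] + 1L] <- f$merges$new_id[r]
  }
  nt <- node_table(f)
  for (id in nt$node_id) {
    if (!all(k %in% node_members(f, id))) next
    cs <- correspondence_score(node_members(f, id), k)
    p <- parent[id + 1L]
    while (!is.na(p)) {
      cs_p <- correspondence_score(node_members(f, p), k)
      expect_lte(cs_p, cs + 1e-12)
      checked <- checked + 1L
      cs <- cs_p
      p <- parent[p + 1L]
    }
  }
  expect_gt(checked, 0L)
})
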