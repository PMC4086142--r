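test_that("AUC hits its boundary and tie values", {
  scores <- setNames(c(5, 4, 1, 0.5), c("p1", "p2", "n1", "n2"))
  perfect <- roc_auc(scores, c("p1", "p2"), c("n1", "n2"))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$points[1, ], data.frame(fpr = 0, tpr = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(perfect$points[nrow(perfect$points), ]),
               c(fpr = 1, tpr = 1))

  tied <- roc_auc(setNames(rep(1, 6), letters[1:6]), letters[1:3],
                  letters[4:6])
  expect_equal(tied$auc, 0.5)

  # pos {2} vs neg {1, 3}: one win, one loss
  mid <- roc_auc(setNames(c(2, 1, 3), c("p", "n1", "n2")), "p",
                 c("n1", "n2"))
  expect_equal(mid$auc, 0.5)

  # unscored items count as -Inf
  lowest <- roc_auc(setNames(c(1), "n1"), "p_missing", "n1")
  expect_equal(lowest$auc, 0)

  expect_error(roc_auc(scores, character(), "n1"), "non-empty")
  expect_error(roc_auc(scores, c("p1"), c("p1", "n1")), "disjoint")
})

test_that("AUC equals the trapezoidal area of its own ROC points", {
  set.seed(3)
  for (i in 1:10) {
    pos <- round(rnorm(20, 1), 1)  # coarse rounding forces ties
    neg <- round(rnorm(50, 0), 1)
    roc <- cofnet:::roc_from_scores(pos, neg)
    trap <- sum(diff(roc$points$fpr) *
                  (head(roc$points$tpr, -1) + tail(roc$points$tpr, -1)) / 2)
    expect_equal(roc$auc, trap)
    expect_true(!is.unsorted(roc$points$fpr) && !is.unsorted(roc$points$tpr))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  scores <- setNames(runif(60, 0, 5), sprintf("i%02d", 1:60))
  pos <- sprintf("i%02d", 1:20)
  neg <- sprintf("i%02d", 21:60)
  base <- roc_auc(scores, pos, neg)$auc
  expect_equal(roc_auc(exp(scores), pos, neg)$auc, base)
  expect_equal(roc_auc(rank(scores), pos, neg)$auc, base)
})

test_that("seed-set AUC separates clique seeds from scattered seeds", {
  set.seed(12)
  clique_genes <- sprintf("c%d", 1:6)
  cl <- t(combn(clique_genes, 2))
  noise_a <- sprintf("z%02d", sample(40, 80, TRUE))
  noise_b <- sprintf("y%02d", sample(40, 80, TRUE))
  net <- make_net(c(cl[, 1], noise_a), c(cl[, 2], noise_b),
                  c(rep(5, nrow(cl)), runif(80, 0.01, 0.2)))
  strong <- seed_set_auc(net, clique_genes)
  expect_gt(strong$auc, 0.9)

  scattered <- seed_set_auc(net, c("c1", "z01", "y02", "z03"))
  expect_lt(abs(scattered$auc - 0.5), 0.35)  # no mutual structure, near chance

  h1 <- seed_set_auc(net, clique_genes, mode = "holdout", rng_seed = 42)
  h2 <- seed_set_auc(net, clique_genes, mode = "holdout", rng_seed = 42)
  expect_identical(h1, h2)
  expect_error(seed_set_auc(net, c("c1", "c2")), "at least 3")
})

test_that("precision-coverage walks the ranked edge list correctly", {
  # every edge joins two genes sharing a phenotype -> precision 1 throughout
  net <- make_net(c("a", "b"), c("b", "c"), c(2, 1))
  ann_all <- annotation_table(data.frame(gene = c("a", "b", "c"),
                                         term = "P1"))
  cv <- precision_coverage(net, ann_all, genome_size = 10, n_points = 2,
                           min_term_size = 1)
  expect_true(all(cv$precision == 1))
  expect_equal(cv$coverage[nrow(cv)], 3 / 10)

  # hand-enumerated 4-gene / 3-edge case
  net4 <- make_net(c("a", "b", "c"), c("b", "c", "d"), c(3, 2, 1))
  ann4 <- annotation_table(data.frame(
    gene = c("a", "b", "c", "d"),
    term = c("P1", "P1", "P2", "P2")))
  cv4 <- precision_coverage(net4, ann4, genome_size = 8, n_points = 3,
                            min_term_size = 1)
  # edge walk: a-b (share P1), b-c (no share), c-d (share P2)
  expect_equal(cv4$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(cv4$coverage, c(2, 3, 4) / 8)

  # restricting admissible term sizes removes terms and unscores pairs
  ann_mix <- annotation_table(data.frame(
    gene = c("a", "b", "b", "c", "d"),
    term = c("big", "big", "small", "small", "big")))
  cv_all <- precision_coverage(net4, ann_mix, genome_size = 8,
                               n_points = 3, min_term_size = 1)
  cv_big <- precision_coverage(net4, ann_mix, genome_size = 8,
                               n_points = 3, min_term_size = 3)
  # all terms: a-b share big, b-c share small, c-d share nothing
  expect_equal(cv_all$precision, c(1, 1, 2 / 3))
  expect_equal(cv_all$n_scored_pairs, c(1L, 2L, 3L))
  # only 'big' (3 genes) admissible: c unannotated, b-c and c-d unscored
  expect_equal(cv_big$precision, c(1, 1, 1))
  expect_equal(cv_big$n_scored_pairs, c(1L, 1L, 1L))
  expect_error(precision_coverage(net4, ann4, genome_size = 2),
               "genome_size")
})

test_that("precision at full coverage equals the global sharing fraction", {
  gen <- generate_network(synthetic_spec(n_genes = 60, n_modules = 6,
                                         rng_seed = 44))
  ann <- generate_annotations(gen$modules, rng_seed = 44)
  cv <- precision_coverage(gen$network, ann, genome_size = 100,
                           n_points = 10, min_term_size = 1)
  e <- network_edges(gen$network)
  mods <- gen$modules
  share_frac <- mean(mods[e$a] == mods[e$b])  # every gene annotated
  expect_equal(cv$precision[nrow(cv)], share_frac)
})

test_that("leave-one-out phenotype prediction recovers a dominant neighbor phenotype", {
  # g's 5 neighbors all carry P; P is rare elsewhere
  net <- star_net("g", 5, 2)
  net <- gene_network(rbind(network_edges(net),
                            data.frame(a = "u1", b = "u2", lls = 1)))
  ann <- annotation_table(data.frame(
    gene = c(sprintf("s%03d", 1:5), "g", "u1"),
    term = c(rep("P", 5), "P", "Q")))  # u2 unannotated: u1 has no annotated neighbor
  rep <- loo_phenotype_prediction(net, ann, top_k = 1)
  d <- rep$detail
  expect_equal(d$top_predictions[d$gene == "g"], "P")
  expect_equal(d$n_correct[d$gene == "g"], 1L)
  # masked gene with no annotated neighbors predicts nothing
  expect_equal(d$n_correct[d$gene == "u1"], 0L)
  expect_true(rep$n_correct_at_k <= rep$n_associations_tested)
})

test_that("leave-one-out totals match a brute-force re-ranking oracle", {
  gen <- generate_network(synthetic_spec(n_genes = 30, n_modules = 3,
                                         term_noise = 0.3, rng_seed = 55))
  ann <- generate_annotations(gen$modules, term_noise = 0.3, rng_seed = 55)
  top_k <- 1L
  rep <- loo_phenotype_prediction(gen$network, ann, top_k = top_k)

  gt <- unique(as.data.frame(ann)[, c("gene", "term")])
  universe <- sort(intersect(unique(gt$gene), network_nodes(gen$network)))
  terms <- sort(unique(gt$term))
  n_correct <- 0L
  for (g in universe) {
    nb <- intersect(network_neighbors(gen$network, g)$gene, universe)
    if (!length(nb)) next
    others <- setdiff(universe, g)
    p <- vapply(terms, function(t) {
      K <- sum(gt$gene %in% others & gt$term == t)
      k <- sum(gt$gene %in% nb & gt$term == t)
      hyper_tail_oracle(k, K, length(others), length(nb))
    }, numeric(1))
    k_cnt <- vapply(terms, function(t) sum(gt$gene %in% nb & gt$term == t),
                    numeric(1))
    cand <- terms[k_cnt >= 1]
    cand <- cand[order(p[match(cand, terms)], cand)]
    preds <- head(cand, top_k)
    n_correct <- n_correct + sum(gt$term[gt$gene == g] %in% preds)
  }
  expect_equal(rep$n_correct_at_k, n_correct)
  expect_equal(rep$n_associations_tested, nrow(gt[gt$gene %in% universe, ]))
})

test_that("success rate is exact arithmetic over top candidates", {
  ranking <- ranked_list(sprintf("g%02d", 1:50), 50:1)
  known <- c(sprintf("g%02d", 1:12), "seedA")
  expect_equal(success_rate(ranking, known, top_n = 50), 24)
  expect_equal(success_rate(ranking, c("zz1", "zz2"), top_n = 50), 0)
  # seeds in the known list earn no credit
  expect_equal(success_rate(ranking, c("g01", "g02"), seeds = "g01",
                            top_n = 50), 2)
  expect_error(success_rate(ranking, known, top_n = 0), "top_n")
  expect_equal(random_success_rate(372, 20389), 100 * 372 / 20389)
})

test_that("randomization preserves node set, edge count and degree sequence", {
  gen <- generate_network(synthetic_spec(n_genes = 80, n_modules = 4,
                                         rng_seed = 66))
  net <- gen$network
  r1 <- randomize_network(net, rng_seed = 1)
  expect_equal(network_nodes(r1), network_nodes(net))
  expect_equal(edge_count(r1), edge_count(net))
  expect_equal(network_degrees(r1), network_degrees(net))
  # weight multiset preserved
  expect_equal(sort(network_edges(r1)$lls), sort(network_edges(net)$lls))
  # determinism per seed; different seeds give different edge sets
  r1b <- randomize_network(net, rng_seed = 1)
  expect_same_network(r1, r1b)
  r2 <- randomize_network(net, rng_seed = 2)
  expect_false(identical(network_edges(r1), network_edges(r2)))
  # too-small network returned unchanged with a warning
  tiny <- make_net("a", "b", 1)
  expect_warning(rt <- randomize_network(tiny, rng_seed = 1), "unchanged")
  expect_same_network(rt, tiny)
})
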