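# Tie-aware ROC from two score vectors. AUC is the Mann-Whitney U statistic
# normalized by n_pos * n_neg, ties credited 1/2, which equals the
# trapezoidal area under the tie-aware ROC curve.
roc_from_scores <- function(pos, neg) {
  n_pos <- length(pos)
  n_neg <- length(neg)
  scores <- c(pos, neg)
  r <- rank(scores)  # average ranks on ties
  auc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  o <- order(scores, decreasing = TRUE)
  lab <- c(rep(1L, n_pos), rep(0L, n_neg))[o]
  grp_end <- cumsum(rle(scores[o])$lengths)  # one ROC vertex per tie group
  tpr <- c(0, cumsum(lab)[grp_end] / n_pos)
  fpr <- c(0, cumsum(1L - lab)[grp_end] / n_neg)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d points)\n", x$auc,
              nrow(x$points)))
  invisible(x)
}

#' Tie-aware ROC curve and AUC
#'
#' AUC 1 means every positive outranks every negative (perfect prediction);
#' 0.5 is random chance. Ties contribute half credit (Mann-Whitney
#' convention), so the value is well defined on the heavily tied score
#' distributions that LLS sums produce. Items missing from `scores` are
#' treated as scoring below everything (`-Inf`).
#'
#' @param scores named numeric vector: item -> score.
#' @param positives,negatives disjoint, non-empty item sets.
#' @return object of class `roc_result`: `points` (data.frame `fpr`, `tpr`
#'   from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, positives, negatives) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (!length(positives) || !length(negatives))
    stop_user("positives and negatives must both be non-empty")
  if (length(intersect(positives, negatives)))
    stop_user("positives and negatives must be disjoint")
  lookup <- function(items) {
    s <- as.numeric(scores[match(items, names(scores))])
    s[is.na(s)] <- -Inf
    s
  }
  roc_from_scores(lookup(positives), lookup(negatives))
}

#' Network prediction power for a seed set (ROC/AUC)
#'
#' Estimates how well guilt-by-association retrieves the submitted seed
#' genes from the network. In `"loo"` mode (default) each usable seed is
#' withheld in turn and scored by the summed LLS to the remaining seeds; the
#' withheld-seed scores are pooled as positives against all non-seed network
#' genes (scored once against the full seed set) as negatives, and one
#' tie-aware AUC is computed. In `"holdout"` mode a random fraction of seeds
#' is withheld once (seeded by `rng_seed`).
#'
#' @param network a [gene_network()].
#' @param seeds a [gene_set()] or character vector; at least 3 seeds must be
#'   in the network.
#' @param mode `"loo"` (default) or `"holdout"`.
#' @param holdout_fraction fraction of seeds withheld in holdout mode.
#' @param rng_seed integer seed for the holdout split (ignored in loo mode).
#' @return a `roc_result` (see [roc_auc()]) with attribute `n_seeds_used`.
#' @export
seed_set_auc <- function(network, seeds, mode = c("loo", "holdout"),
                         holdout_fraction = 0.3, rng_seed = NULL) {
  mode <- match.arg(mode)
  seeds <- intersect(as_gene_members(seeds), network$nodes)
  if (length(seeds) < 3L)
    stop_user("need at least 3 seed genes present in the network (got %d)",
              length(seeds))
  if (mode == "loo") {
    pos <- vapply(seq_along(seeds), function(i) {
      s <- seed_scores(network, seeds[-i])
      unname(s[seeds[i]])
    }, numeric(1))
    neg <- unname(seed_scores(network, seeds))
  } else {
    n_hold <- max(1L, round(holdout_fraction * length(seeds)))
    if (n_hold >= length(seeds)) stop_user("holdout_fraction leaves no training seed")
    held <- with_seed(rng_seed, sort_c(sample(seeds, n_hold)))
    train <- setdiff(seeds, held)
    s <- seed_scores(network, train)
    pos <- unname(s[held])
    neg <- unname(s[setdiff(names(s), held)])
  }
  out <- roc_from_scores(pos, neg)
  attr(out, "n_seeds_used") <- length(seeds)
  out
}

#' Precision versus genome coverage along the ranked edge list
#'
#' Assesses network quality the way integrated networks are benchmarked
#' against held-out phenotype data: edges are walked in order of descending
#' LLS; at each point, coverage is the fraction of the coding genome touched
#' by the edges so far and precision is the fraction of scored pairs (both
#' genes carrying at least one admissible phenotype annotation) that share
#' an admissible phenotype. Terms are admissible when their gene count lies
#' in `[min_term_size, max_term_size]` (default 5--500, the usual bounds for
#' informative phenotype sets). Unannotated genes cannot be scored for
#' sharing but still count toward coverage.
#'
#' @param network a [gene_network()].
#' @param phenotypes an [annotation_table()] of held-out annotations.
#' @param genome_size coding-genome size; must be >= the number of network
#'   genes.
#' @param n_points number of sample points along the edge walk (default 50).
#' @param min_term_size,max_term_size admissible term size bounds.
#' @return data.frame of class `precision_curve`: columns `n_edges`,
#'   `coverage`, `precision`, `n_scored_pairs`; attribute `genome_size`.
#'   Precision is `NA` before the first scored pair.
#' @export
precision_coverage <- function(network, phenotypes, genome_size,
                               n_points = 50L, min_term_size = 5L,
                               max_term_size = 500L) {
  if (genome_size < length(network$nodes))
    stop_user("genome_size (%d) smaller than the network's gene count (%d)",
              genome_size, length(network$nodes))
  if (!edge_count(network)) stop_user("network has no edges")
  ann <- as.data.frame(phenotypes)
  adm <- admissible_terms(ann, min_term_size, max_term_size)
  gt <- unique(ann[ann$term %in% adm, c("gene", "term")])
  genes_ann <- sort_c(unique(gt$gene))
  e <- network$edges
  e <- e[order(-e$lls, e$a, e$b, method = "radix"), , drop = FALSE]

  # term incidence over annotated genes
  M <- matrix(FALSE, nrow = length(genes_ann), ncol = length(adm),
              dimnames = list(genes_ann, sort_c(adm)))
  M[cbind(match(gt$gene, genes_ann), match(gt$term, colnames(M)))] <- TRUE

  ia <- match(e$a, genes_ann)
  ib <- match(e$b, genes_ann)
  scored <- !is.na(ia) & !is.na(ib)
  if (!any(scored))
    stop_user("no network edge joins two annotated genes; nothing to score")
  share <- logical(nrow(e))
  share[scored] <- rowSums(M[ia[scored], , drop = FALSE] &
                             M[ib[scored], , drop = FALSE]) > 0

  v <- as.vector(rbind(e$a, e$b))            # genes in edge-walk order
  cum_genes <- cumsum(!duplicated(v))
  genes_after <- cum_genes[2 * seq_len(nrow(e))]
  cum_scored <- cumsum(scored)
  cum_share <- cumsum(share)

  idx <- unique(round(seq(1, nrow(e), length.out = min(n_points, nrow(e)))))
  out <- data.frame(n_edges = idx,
                    coverage = genes_after[idx] / genome_size,
                    precision = ifelse(cum_scored[idx] > 0,
                                       cum_share[idx] / cum_scored[idx],
                                       NA_real_),
                    n_scored_pairs = cum_scored[idx])
  attr(out, "genome_size") <- genome_size
  class(out) <- c("precision_curve", "data.frame")
  out
}

#' Leave-one-out phenotype prediction
#'
#' Benchmarks neighbor-based function inference: for each annotated network
#' gene, its own annotations are masked and phenotypes are re-predicted from
#' the enrichment of each phenotype among the gene's network neighbors
#' (one-sided Fisher's exact test over the background of all other
#' annotated network genes). A known gene--phenotype association counts as
#' correctly predicted when the phenotype ranks within the `top_k`
#' predictions for that gene (top 20 is the conventional report). Only
#' phenotypes carried by at least one neighbor are predicted; genes with no
#' annotated neighbor contribute zero correct predictions but their
#' associations still count as tested.
#'
#' @param network a [gene_network()].
#' @param phenotypes an [annotation_table()].
#' @param top_k rank cutoff for a correct prediction (default 20).
#' @param min_lls strict lower LLS bound for neighbor edges (default
#'   `-Inf`).
#' @param min_term_size,max_term_size admissible phenotype size bounds
#'   (defaults keep every term).
#' @return object of class `loo_report`: `n_associations_tested`,
#'   `n_correct_at_k`, `k`, and `detail` (per-gene data.frame with masked
#'   and predicted terms).
#' @export
loo_phenotype_prediction <- function(network, phenotypes, top_k = 20L,
                                     min_lls = -Inf, min_term_size = 1L,
                                     max_term_size = Inf) {
  ann <- as.data.frame(phenotypes)
  adm <- admissible_terms(ann, min_term_size, max_term_size)
  gt <- unique(ann[ann$term %in% adm, c("gene", "term")])
  universe <- sort_c(intersect(unique(gt$gene), network$nodes))
  if (length(universe) < 2L)
    stop_user("need at least 2 annotated genes in the network")
  terms <- sort_c(unique(gt$term))
  M <- matrix(FALSE, nrow = length(universe), ncol = length(terms),
              dimnames = list(universe, terms))
  in_univ <- gt$gene %in% universe
  M[cbind(match(gt$gene[in_univ], universe),
          match(gt$term[in_univ], terms))] <- TRUE
  term_totals <- colSums(M)

  e <- network$edges[network$edges$lls > min_lls, , drop = FALSE]
  adj <- split(c(e$b, e$a), c(e$a, e$b))

  detail <- vector("list", length(universe))
  n_correct <- 0L
  for (gi in seq_along(universe)) {
    g <- universe[gi]
    masked <- terms[M[gi, ]]
    nb <- intersect(adj[[g]], universe)
    preds <- character()
    if (length(nb)) {
      K <- term_totals - M[gi, ]          # term counts with g masked
      k <- colSums(M[match(nb, universe), , drop = FALSE])
      N <- length(universe) - 1L
      p <- fisher_enrichment_p(k, K, N, length(nb))
      cand <- which(k >= 1L)
      cand <- cand[order(p[cand], terms[cand], method = "radix")]
      preds <- terms[head(cand, top_k)]
    }
    hits <- sum(masked %in% preds)
    n_correct <- n_correct + hits
    detail[[gi]] <- data.frame(
      gene = g, n_masked = length(masked), n_annotated_neighbors = length(nb),
      n_correct = hits,
      masked_terms = paste(masked, collapse = ","),
      top_predictions = paste(preds, collapse = ","),
      stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, detail)
  structure(list(n_associations_tested = sum(detail$n_masked),
                 n_correct_at_k = n_correct,
                 k = as.integer(top_k),
                 detail = detail),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("loo_report: %d / %d associations correct within top %d (%.1f%%)\n",
              x$n_correct_at_k, x$n_associations_tested, x$k,
              100 * x$n_correct_at_k / max(1L, x$n_associations_tested)))
  invisible(x)
}

#' Success rate of a candidate ranking
#'
#' Percentage of the top `top_n` ranked candidates that are known genes for
#' the phenotype, excluding the seeds used to generate the ranking
#' ("recapitulated non-seed genes"). A ranking shorter than `top_n` is
#' treated as padded with misses, so the denominator is always `top_n`.
#'
#' @param ranking a [ranked_list()] (or character vector already in rank
#'   order).
#' @param known known genes for the phenotype ([gene_set()] or character).
#' @param seeds seed genes to exclude from credit (default none).
#' @param top_n number of top candidates assessed.
#' @return percentage in `[0, 100]`.
#' @export
success_rate <- function(ranking, known, seeds = character(), top_n) {
  if (top_n <= 0) stop_user("top_n must be positive")
  items <- if (inherits(ranking, "ranked_list")) ranking$item
           else as.character(ranking)
  items <- head(items, top_n)
  eligible <- setdiff(as_gene_members(known), as_gene_members(seeds))
  100 * sum(items %in% eligible) / top_n
}

#' Expected success rate of uniform random candidate selection
#'
#' Baseline for [success_rate()]: picking candidates uniformly at random
#' from a genome of `genome_size` genes recovers known genes at rate
#' `100 * n_known / genome_size` percent, e.g. 372 known genes in a
#' 20,389-gene coding genome give 1.82%.
#'
#' @param n_known number of known genes for the phenotype.
#' @param genome_size number of genes in the selection pool.
#' @return expected percentage.
#' @export
random_success_rate <- function(n_known, genome_size) {
  if (genome_size <= 0 || n_known < 0 || n_known > genome_size)
    stop_user("need 0 <= n_known <= genome_size, genome_size > 0")
  100 * n_known / genome_size
}

#' Degree-preserving network randomization
#'
#' Null model for signal-vs-chance comparisons: the edge set is rewired by
#' double-edge swaps that preserve every gene's degree exactly (no
#' self-loops or multi-edges introduced), and the multiset of LLS weights is
#' shuffled onto the rewired edges. Node set, edge count and degree sequence
#' are invariant; reproducible for a given `rng_seed`.
#'
#' @param network a [gene_network()] with at least 2 edges (smaller networks
#'   are returned unchanged with a warning).
#' @param rng_seed integer seed.
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @return a randomized [gene_network()].
#' @export
randomize_network <- function(network, rng_seed = NULL,
                              n_swaps_per_edge = 10L) {
  m <- edge_count(network)
  if (m < 2L) {
    warning("network has fewer than 2 edges; returning it unchanged")
    return(network)
  }
  g <- igraph::graph_from_data_frame(network$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = network$nodes)
  res <- with_seed(rng_seed, {
    rew <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps_per_edge * m))
    list(rew = rew, perm = sample.int(m))
  })
  el <- igraph::as_edgelist(res$rew, names = TRUE)
  gene_network(data.frame(a = el[, 1L], b = el[, 2L],
                          lls = network$edges$lls[res$perm],
                          stringsAsFactors = FALSE),
               nodes = network$nodes)
}
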