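# Truncated-normal draw bounded below at 0: edge LLS weights of retained
# links are positive in practice.
rtrunc0 <- function(n, mean, sd) {
  lo <- pnorm(0, mean = mean, sd = sd)
  qnorm(runif(n, min = lo, max = 1), mean = mean, sd = sd)
}

#' Specification of a synthetic planted-module benchmark
#'
#' Describes a planted-partition ("stochastic block model") gene network:
#' genes are split into co-functional modules; within-module gene pairs are
#' linked with probability `p_within` and weighted from the signal
#' distribution, between-module pairs with probability `p_between` from the
#' noise distribution. This emulates the statistical structure
#' network-assisted prediction relies on — genes for the same
#' loss-of-function phenotype are proximal and strongly linked — while the
#' planted module map provides exact ground truth for every oracle. All
#' outputs are fully determined by `rng_seed`.
#'
#' Defaults (200 genes in 10 modules, `p_within` 0.5 vs `p_between` 0.01,
#' signal weights ~ N(2, 0.5) truncated at 0 vs noise ~ N(0.5, 0.3)
#' truncated at 0) give modules that are dense and clearly above an LLS = 1
#' threshold, with sparse weak background links.
#'
#' @param n_genes total number of genes.
#' @param n_modules number of planted modules (near-equal sizes).
#' @param p_within,p_between edge probabilities inside / between modules.
#' @param lls_signal,lls_noise length-2 numeric `c(mean, sd)` of the
#'   truncated-normal weight distributions.
#' @param imp_fraction probability that an annotation record carries the
#'   excluded IMP evidence code (see [generate_annotations()]).
#' @param term_noise per-gene probability of one extra off-module annotation.
#' @param rng_seed integer seed; identical specs and seeds give
#'   byte-identical outputs.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200L, n_modules = 10L, p_within = 0.5,
                           p_between = 0.01, lls_signal = c(2, 0.5),
                           lls_noise = c(0.5, 0.3), imp_fraction = 0,
                           term_noise = 0, rng_seed = 1L) {
  if (n_modules < 1L || n_genes < n_modules)
    stop_user("need 1 <= n_modules <= n_genes")
  probs <- c(p_within, p_between, imp_fraction, term_noise)
  if (any(probs < 0 | probs > 1))
    stop_user("probabilities must lie in [0, 1]")
  structure(list(n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 p_within = p_within, p_between = p_between,
                 lls_signal = as.numeric(lls_signal),
                 lls_noise = as.numeric(lls_noise),
                 imp_fraction = imp_fraction, term_noise = term_noise,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate a planted-module gene network
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (a [gene_network()]), `modules` (named
#'   character vector gene -> module identifier, the ground truth) and
#'   `ledger` (exact within/between edge counts for bookkeeping oracles).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  mod_idx <- sort(rep_len(seq_len(spec$n_modules), spec$n_genes))
  modules <- setNames(sprintf("M%03d", mod_idx), genes)
  pairs <- combn(spec$n_genes, 2L)
  within <- mod_idx[pairs[1L, ]] == mod_idx[pairs[2L, ]]
  with_seed(spec$rng_seed, {
    keep <- runif(ncol(pairs)) < ifelse(within, spec$p_within, spec$p_between)
    a <- genes[pairs[1L, keep]]
    b <- genes[pairs[2L, keep]]
    w_in <- within[keep]
    lls <- numeric(length(a))
    lls[w_in] <- rtrunc0(sum(w_in), spec$lls_signal[1], spec$lls_signal[2])
    lls[!w_in] <- rtrunc0(sum(!w_in), spec$lls_noise[1], spec$lls_noise[2])
    net <- gene_network(data.frame(a = a, b = b, lls = lls,
                                   stringsAsFactors = FALSE), nodes = genes)
    list(network = net, modules = modules,
         ledger = list(n_within_edges = sum(w_in),
                       n_between_edges = sum(!w_in),
                       module_sizes = as.integer(table(mod_idx))))
  })
}

#' Generate a synthetic annotation table from a planted module map
#'
#' Every gene is annotated to its module's term; with probability
#' `term_noise` a gene receives one additional annotation to a random other
#' module's term. Each record independently carries the excluded IMP
#' evidence code with probability `imp_fraction`, otherwise a code drawn
#' from `codes`. Exact counts are recorded in the `ledger` attribute so
#' bookkeeping oracles never re-derive them.
#'
#' @param modules named character vector gene -> module term (from
#'   [generate_network()]).
#' @param term_noise per-gene probability of one extra off-module record.
#' @param imp_fraction per-record probability of the IMP code.
#' @param rng_seed integer seed.
#' @param codes non-excluded evidence codes to sample from.
#' @return an [annotation_table()] with attribute `ledger` (list of counts).
#' @export
generate_annotations <- function(modules, term_noise = 0, imp_fraction = 0,
                                 rng_seed = 1L,
                                 codes = c("IDA", "IGI", "IPI", "IEP",
                                           "TAS", "ISS")) {
  genes <- names(modules)
  terms <- sort_c(unique(unname(modules)))
  with_seed(rng_seed, {
    gene <- genes
    term <- unname(modules)
    noisy <- runif(length(genes)) < term_noise
    if (any(noisy) && length(terms) > 1L) {
      extra_term <- vapply(modules[noisy], function(own)
        sample(setdiff(terms, own), 1L), character(1))
      gene <- c(gene, genes[noisy])
      term <- c(term, unname(extra_term))
    }
    n_rec <- length(gene)
    is_imp <- runif(n_rec) < imp_fraction
    evidence <- character(n_rec)
    evidence[is_imp] <- "IMP"
    evidence[!is_imp] <- sample(codes, sum(!is_imp), replace = TRUE)
    tab <- annotation_table(data.frame(gene = gene, term = term,
                                       evidence = evidence,
                                       stringsAsFactors = FALSE))
    attr(tab, "ledger") <- list(n_records = n_rec,
                                n_noise_records = sum(noisy),
                                n_imp_records = sum(is_imp))
    tab
  })
}

#' Generate a noisy evidence dataset from a true network
#'
#' Emulates one heterogeneous data type: each true edge's gene pair is
#' reported with probability `sensitivity`, and
#' `round(false_pair_rate * n_true_edges)` uniformly sampled non-edge pairs
#' are added as false reports. Ground-truth labels are recorded in the
#' `truth` attribute.
#'
#' @param network the true [gene_network()].
#' @param sensitivity per-edge report probability in `[0, 1]`.
#' @param false_pair_rate false pairs added, as a fraction of the true edge
#'   count.
#' @param rng_seed integer seed.
#' @param name dataset label.
#' @return an [evidence_dataset()] (binary); attribute `truth` is a
#'   data.frame `a`, `b`, `is_true`.
#' @export
generate_evidence <- function(network, sensitivity = 0.8,
                              false_pair_rate = 0.2, rng_seed = 1L,
                              name = "synthetic_evidence") {
  if (sensitivity < 0 || sensitivity > 1 || false_pair_rate < 0)
    stop_user("sensitivity in [0,1] and false_pair_rate >= 0 required")
  e <- network$edges
  nodes <- network$nodes
  edge_keys <- pair_key(e$a, e$b)
  with_seed(rng_seed, {
    keep <- runif(nrow(e)) < sensitivity
    true_a <- e$a[keep]
    true_b <- e$b[keep]
    n_false <- round(false_pair_rate * nrow(e))
    fa <- character(0)
    fb <- character(0)
    got <- character(0)
    while (length(got) < n_false) {
      need <- n_false - length(got)
      i <- sample.int(length(nodes), 2L * need, replace = TRUE)
      j <- sample.int(length(nodes), 2L * need, replace = TRUE)
      ok <- i != j
      cp <- canonical_pairs(nodes[i[ok]], nodes[j[ok]])
      k <- pair_key(cp$a, cp$b)
      new <- !(k %in% c(edge_keys, got)) & !duplicated(k)
      take <- which(new)[seq_len(min(need, sum(new)))]
      fa <- c(fa, cp$a[take])
      fb <- c(fb, cp$b[take])
      got <- c(got, k[take])
    }
    ev <- evidence_dataset(name, data.frame(a = c(true_a, fa),
                                            b = c(true_b, fb),
                                            stringsAsFactors = FALSE))
    truth <- data.frame(a = c(true_a, fa), b = c(true_b, fb),
                        is_true = rep(c(TRUE, FALSE),
                                      c(length(true_a), length(fa))),
                        stringsAsFactors = FALSE)
    attr(ev, "truth") <- truth
    ev
  })
}

#' Generate a DEG set around a planted hub
#'
#' Emulates a differential-expression experiment whose context is mediated
#' by one hub gene: the set contains a `recall` fraction of the hub's
#' qualifying neighbors (`lls > min_lls`) plus `contamination` random genes
#' that are not neighbors of the hub (and not the hub itself).
#'
#' @param network a [gene_network()].
#' @param hub the planted hub gene; must have at least one qualifying
#'   neighbor.
#' @param recall fraction of qualifying neighbors included.
#' @param contamination number of random non-neighbor genes added.
#' @param rng_seed integer seed.
#' @param min_lls strict LLS bound defining the hub's neighborhood
#'   (default 1).
#' @return a [gene_set()]; attribute `truth` records the hub and the
#'   neighbor / contaminant split.
#' @export
generate_deg_set <- function(network, hub, recall = 0.8, contamination = 10L,
                             rng_seed = 1L, min_lls = 1) {
  if (recall < 0 || recall > 1) stop_user("recall must lie in [0, 1]")
  nbh <- network_neighbors(network, hub, min_lls = min_lls)$gene
  if (!length(nbh))
    stop_user("hub '%s' has no neighbor with lls > %g", hub, min_lls)
  all_nbh <- network_neighbors(network, hub, min_lls = -Inf)$gene
  pool <- setdiff(network$nodes, c(hub, all_nbh))
  with_seed(rng_seed, {
    n_take <- round(recall * length(nbh))
    taken <- if (n_take > 0L) sort_c(sample(nbh, n_take)) else character()
    contam <- if (contamination > 0L)
      sort_c(sample(pool, min(contamination, length(pool)))) else character()
    out <- gene_set(paste0("deg_", hub), c(taken, contam))
    attr(out, "truth") <- list(hub = hub, neighbors_included = taken,
                               contaminants = contam,
                               n_qualifying_neighbors = length(nbh))
    out
  })
}
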