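# One-sided (enrichment) Fisher exact p-value for a 2x2 table drawn from a
# universe of N items, K successes, n draws, k observed successes:
# P(X >= k), X ~ Hypergeom(N, K, n). Vectorized over its arguments.
fisher_enrichment_p <- function(k, K, N, n) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Guilt-by-association scores of every non-seed gene: sum of edge LLS to
# the seed set. Genes without any seed edge score 0. Returns a named vector
# over all non-seed network genes (byte-order).
seed_scores <- function(network, seeds) {
  e <- network$edges
  non_seed <- setdiff(network$nodes, seeds)
  s <- setNames(numeric(length(non_seed)), non_seed)
  sel_a <- e$a %in% seeds & !(e$b %in% seeds)
  sel_b <- e$b %in% seeds & !(e$a %in% seeds)
  tgt <- c(e$b[sel_a], e$a[sel_b])
  w <- c(e$lls[sel_a], e$lls[sel_b])
  if (length(tgt)) {
    agg <- rowsum(w, tgt)
    s[rownames(agg)] <- agg[, 1L]
  }
  s
}

#' Ranked result lists
#'
#' Common container for ranked candidate genes, terms or phenotypes:
#' entries sorted by non-increasing score, ties broken by item identifier
#' (byte order), ranks `1..n`, optionally truncated with the pre-truncation
#' length recorded.
#'
#' @param items character vector of item identifiers.
#' @param scores numeric scores, same length.
#' @param top_n keep at most this many entries (default: all).
#' @return data.frame of class `ranked_list` with columns `item`, `score`,
#'   `rank`; attribute `total_items` holds the pre-truncation length.
#' @export
ranked_list <- function(items, scores, top_n = Inf) {
  stopifnot(length(items) == length(scores))
  o <- order(-scores, items, method = "radix")
  k <- min(length(items), top_n)
  out <- data.frame(item = as.character(items)[o][seq_len(k)],
                    score = as.numeric(scores)[o][seq_len(k)],
                    rank = seq_len(k),
                    stringsAsFactors = FALSE)
  attr(out, "total_items") <- length(items)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Find new members for a pathway (seed-based candidate ranking)
#'
#' Phenotype-centric guilt-by-association: each non-seed gene is scored by
#' the sum of its edge LLS values to the submitted seed genes, and the
#' top-scoring candidates are returned (top 200 by default, as served for
#' pathway-member prediction). Seeds never appear as candidates; genes with
#' no seed edge (score 0) are omitted.
#'
#' @param network a [gene_network()].
#' @param seeds a [gene_set()] or character vector of seed genes. Seeds
#'   absent from the network are dropped and recorded in the
#'   `unmatched_seeds` attribute; if none match, an error lists them.
#' @param top_n number of candidates to return (default 200).
#' @return a [ranked_list()] of candidate genes; attributes
#'   `matched_seeds`, `unmatched_seeds`.
#' @export
find_new_members <- function(network, seeds, top_n = 200L) {
  seeds <- as_gene_members(seeds)
  matched <- intersect(seeds, network$nodes)
  unmatched <- setdiff(seeds, network$nodes)
  if (!length(matched))
    stop_user("no seed gene found in the network; unmatched: %s",
              paste(sort_c(unmatched), collapse = ", "))
  s <- seed_scores(network, matched)
  s <- s[s > 0]
  out <- ranked_list(names(s), unname(s), top_n = top_n)
  attr(out, "matched_seeds") <- sort_c(matched)
  attr(out, "unmatched_seeds") <- sort_c(unmatched)
  out
}

#' Infer functions from network neighbors
#'
#' Gene-centric function prediction: collects the terms annotated to the
#' query gene's network neighbors and ranks each term by the summed LLS of
#' the query's edges to neighbors carrying it (top 10 by default, as served
#' for GO-BP inference). Terms already annotated to the query are flagged in
#' the `known` column but retained.
#'
#' @param network a [gene_network()].
#' @param annotations an [annotation_table()].
#' @param query a gene identifier; must be present in the network.
#' @param top_n number of terms to return (default 10).
#' @param min_lls strict lower LLS bound for neighbor edges (default
#'   `-Inf`: every neighbor counts).
#' @return a [ranked_list()] of terms with an extra logical column `known`.
#'   A query with no annotated neighbors yields an empty (0-row) result.
#' @export
infer_functions <- function(network, annotations, query, top_n = 10L,
                            min_lls = -Inf) {
  if (!(query %in% network$nodes))
    stop_user("query gene '%s' is not in the network", query)
  nb <- network_neighbors(network, query, min_lls = min_lls)
  gt <- unique(as.data.frame(annotations)[, c("gene", "term")])
  hit <- gt[gt$gene %in% nb$gene, , drop = FALSE]
  known_terms <- gt$term[gt$gene == query]
  if (!nrow(hit)) {
    out <- ranked_list(character(), numeric())
    out$known <- logical(0)
    return(out)
  }
  hit$lls <- nb$lls[match(hit$gene, nb$gene)]
  agg <- rowsum(hit$lls, hit$term)
  out <- ranked_list(rownames(agg), agg[, 1L], top_n = top_n)
  out$known <- out$item %in% known_terms
  out
}

#' Identify hub genes by strict-threshold neighborhood size
#'
#' A hub is the center of a pre-defined subnetwork: the gene plus its
#' neighbors connected by `lls > min_lls` (strict, the "LLS > 1"
#' convention). The degree criterion direction is configurable because the
#' published phrase "no >15 neighbors" is ambiguous: the default
#' `"at_least"` reads hubs as high-degree genes (`degree >=
#' degree_threshold`); `"at_most"` is the literal cap (`1 <= degree <=
#' degree_threshold` — a gene with no qualifying neighbor centers no
#' subnetwork either way).
#'
#' @param network a [gene_network()].
#' @param min_lls strict lower LLS bound defining the neighborhood
#'   (default 1).
#' @param degree_threshold neighborhood-size threshold (default 15).
#' @param direction `"at_least"` (default) or `"at_most"`.
#' @return character vector of hub genes, byte-order sorted.
#' @export
identify_hubs <- function(network, min_lls = 1, degree_threshold = 15L,
                          direction = c("at_least", "at_most")) {
  direction <- match.arg(direction)
  if (degree_threshold < 1L) stop_user("degree_threshold must be >= 1")
  d <- network_degrees(network, min_lls = min_lls)
  keep <- if (direction == "at_least") d >= degree_threshold
          else d >= 1L & d <= degree_threshold
  sort_c(names(d)[keep])
}

#' Find context-associated hub genes
#'
#' Context-centric prediction: a set of differentially expressed genes
#' (DEGs) characterizes a biological context, and each hub gene is tested
#' for association with that context by one-sided Fisher's exact test
#' (enrichment) of its strict-threshold neighborhood among the DEGs. Per
#' hub, the 2x2 table classifies the background universe (minus the hub
#' itself) by neighbor/non-neighbor and DEG/non-DEG; Benjamini-Hochberg
#' q-values are computed across all tested hubs.
#'
#' @param network a [gene_network()].
#' @param degs a [gene_set()] or character vector of DEGs. DEGs absent from
#'   the network are dropped from the tables and reported via the
#'   `dropped_degs` attribute.
#' @param hubs hub genes to test (default: [identify_hubs()] with this
#'   `min_lls`). Hubs with an empty qualifying neighborhood are skipped and
#'   reported via the `skipped_hubs` attribute.
#' @param background `NULL` to use all network genes as the universe, or a
#'   single integer giving a custom (e.g. genome) universe size, which must
#'   be at least the number of network genes.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param min_lls strict lower LLS bound for hub neighborhoods (default 1).
#' @param adjust `"BH"` (default) flags hubs with q <= alpha; `"none"` flags
#'   raw p <= alpha (q-values are reported either way).
#' @return data.frame of class `hub_results`, one row per tested hub, with
#'   columns `hub`, `neighborhood_size`, `deg_overlap`, `p_value`,
#'   `q_value`, `significant`, `overlapping_genes` (comma-joined); sorted by
#'   ascending p, then descending overlap, then hub identifier.
#' @export
find_context_hubs <- function(network, degs, hubs = NULL, background = NULL,
                              alpha = 0.05, min_lls = 1,
                              adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  degs <- as_gene_members(degs)
  deg_in <- intersect(degs, network$nodes)
  dropped <- setdiff(degs, network$nodes)
  if (!length(deg_in))
    stop_user("no submitted DEG is present in the network")
  if (is.null(hubs)) hubs <- identify_hubs(network, min_lls = min_lls)
  n_universe <- if (is.null(background)) {
    length(network$nodes)
  } else {
    background <- as.integer(background)
    if (background < length(network$nodes))
      stop_user("custom background (%d) smaller than the network (%d genes)",
                background, length(network$nodes))
    background
  }

  rows <- vector("list", length(hubs))
  skipped <- character()
  for (i in seq_along(hubs)) {
    h <- hubs[i]
    nbh <- network_neighbors(network, h, min_lls = min_lls)$gene
    if (!length(nbh)) {
      skipped <- c(skipped, h)
      next
    }
    deg_eff <- setdiff(deg_in, h)     # hub excluded from all cells
    ov <- intersect(nbh, deg_eff)
    N <- n_universe - 1L
    p <- fisher_enrichment_p(length(ov), length(nbh), N, length(deg_eff))
    rows[[i]] <- data.frame(hub = h, neighborhood_size = length(nbh),
                            deg_overlap = length(ov), p_value = p,
                            overlapping_genes = paste(sort_c(ov),
                                                      collapse = ","),
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop_user("no hub with a qualifying neighborhood at lls > %g", min_lls)
  res <- do.call(rbind, rows)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- if (adjust == "BH") res$q_value <= alpha
                     else res$p_value <= alpha
  res <- res[order(res$p_value, -res$deg_overlap, res$hub, method = "radix"),
             c("hub", "neighborhood_size", "deg_overlap", "p_value",
               "q_value", "significant", "overlapping_genes")]
  rownames(res) <- NULL
  attr(res, "dropped_degs") <- sort_c(dropped)
  attr(res, "skipped_hubs") <- skipped
  attr(res, "n_deg_effective") <- length(deg_in)
  class(res) <- c("hub_results", "data.frame")
  res
}
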