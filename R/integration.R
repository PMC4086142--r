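#' Build a gold standard of positive and negative gene pairs
#'
#' Positive pairs are pairs of genes co-annotated to at least one admissible
#' term (distinct-gene count within `[min_term_size, max_term_size]`) where
#' both genes carry that term with at least one non-excluded evidence code.
#' The default exclusion of IMP (inferred from mutant phenotype) removes
#' between-pathway pairs created by organism-level morphology phenotypes:
#' such pairs share a term, so they are not negatives either — they are left
#' out of the gold standard entirely. Negative pairs are pairs of annotated
#' genes that share no admissible term at all. Records with a missing
#' evidence code count as non-excluded.
#'
#' @param annotations an [annotation_table()].
#' @param excluded_codes evidence codes whose support never makes a shared
#'   term count toward positivity (default `"IMP"`).
#' @param min_term_size,max_term_size admissible term size bounds
#'   (distinct genes per term).
#' @return object of class `gold_standard`: list with `positives` and
#'   `negatives` (canonical pair data.frames `a`, `b`), plus bookkeeping
#'   counts. Positives and negatives are disjoint by construction and this
#'   is asserted.
#' @export
build_gold_standard <- function(annotations, excluded_codes = "IMP",
                                min_term_size = 2L, max_term_size = Inf) {
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  adm <- admissible_terms(ann, min_term_size, max_term_size)
  if (!length(adm))
    stop_user(paste0("no admissible terms with size in [%s, %s]; ",
                     "loosen min_term_size/max_term_size"),
              format(min_term_size), format(max_term_size))
  genes <- sort_c(unique(ann$gene))

  all_pairs_of <- function(g) {
    g <- sort_c(unique(g))
    if (length(g) < 2L) return(character())
    m <- combn(g, 2L)
    pair_key(m[1L, ], m[2L, ])
  }

  non_excluded <- is.na(ann$evidence) | !(ann$evidence %in% excluded_codes)
  share_keys <- character()
  pos_keys <- character()
  for (t in adm) {
    in_t <- ann$term == t
    g_all <- ann$gene[in_t]
    g_strong <- ann$gene[in_t & non_excluded]
    share_keys <- c(share_keys, all_pairs_of(g_all))
    pos_keys <- c(pos_keys, all_pairs_of(g_strong))
  }
  share_keys <- unique(share_keys)
  pos_keys <- sort_c(unique(pos_keys))
  neg_keys <- sort_c(setdiff(all_pairs_of(genes), share_keys))
  stopifnot(length(intersect(pos_keys, neg_keys)) == 0L)

  keys_to_df <- function(k) {
    if (!length(k)) {
      return(data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(k, "\r", fixed = TRUE)
    data.frame(a = vapply(parts, `[[`, character(1), 1L),
               b = vapply(parts, `[[`, character(1), 2L),
               stringsAsFactors = FALSE)
  }
  structure(list(positives = keys_to_df(pos_keys),
                 negatives = keys_to_df(neg_keys),
                 n_genes = length(genes),
                 n_admissible_terms = length(adm),
                 excluded_codes = excluded_codes),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard: %d positive / %d negative pairs (%d genes, %d admissible terms)\n",
              nrow(x$positives), nrow(x$negatives), x$n_genes,
              x$n_admissible_terms))
  invisible(x)
}

#' An evidence dataset of gene pairs
#'
#' One heterogeneous data type (e.g. co-expression, protein interaction,
#' genomic context) reduced to gene pairs, optionally with a raw confidence
#' score. Either every pair is scored or none is.
#'
#' @param name dataset label.
#' @param pairs data.frame-like: gene A, gene B, optional raw score.
#' @return object of class `evidence_dataset` with fields `name`, `pairs`
#'   (canonical unique pairs `a`, `b` and, when present, `score`), `scored`.
#' @export
evidence_dataset <- function(name, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop_user("evidence needs at least 2 columns")
  scored <- ncol(pairs) >= 3L
  pairs <- pairs[, if (scored) 1:3 else 1:2]
  names(pairs) <- if (scored) c("a", "b", "score") else c("a", "b")
  cp <- canonical_pairs(pairs$a, pairs$b)
  pairs$a <- cp$a
  pairs$b <- cp$b
  if (scored) {
    pairs$score <- as.numeric(pairs$score)
    if (anyNA(pairs$score))
      stop_user("evidence '%s': either all pairs are scored or none", name)
  }
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  pairs <- pairs[!duplicated(pair_key(pairs$a, pairs$b)), , drop = FALSE]
  pairs <- pairs[order(pairs$a, pairs$b, method = "radix"), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(name = as.character(name)[1], pairs = pairs, scored = scored),
            class = "evidence_dataset")
}

#' Read an evidence dataset (TSV: geneA, geneB, optional raw score)
#'
#' @param path file path.
#' @param name dataset label (defaults to file name).
#' @return an [evidence_dataset()].
#' @export
read_evidence <- function(path, name = basename(path)) {
  sc <- strip_comment_lines(readLines(path))
  if (!length(sc$lines))
    return(evidence_dataset(name, data.frame(a = character(), b = character())))
  fields <- strsplit(sc$lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop_user("line %d of %s: expected geneA<TAB>geneB[<TAB>score]",
              sc$lineno[which(nf < 2L)[1L]], path)
  scored <- all(nf >= 3L)
  df <- data.frame(a = vapply(fields, `[[`, character(1), 1L),
                   b = vapply(fields, `[[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  if (scored) {
    df$score <- suppressWarnings(as.numeric(vapply(fields, `[[`,
                                                   character(1), 3L)))
    if (anyNA(df$score)) {
      i <- which(is.na(df$score))[1L]
      stop_user("line %d of %s: non-numeric score", sc$lineno[i], path)
    }
  }
  evidence_dataset(name, df)
}

# LLS of one contingency cell against the gold-standard prior:
# ln[ ((pos_E + c)/(neg_E + c)) / ((pos_tot + c)/(neg_tot + c)) ]
lls_cell <- function(pos_e, neg_e, pos_tot, neg_tot, pseudocount) {
  val <- log(((pos_e + pseudocount) / (neg_e + pseudocount)) /
               ((pos_tot + pseudocount) / (neg_tot + pseudocount)))
  if (any(!is.finite(val)))
    stop_user(paste0("infinite LLS: an empty contingency cell with ",
                     "pseudocount 0; use pseudocount > 0"))
  val
}

#' Calibrate an evidence dataset to log-likelihood scores
#'
#' Bayesian calibration of one evidence type against a gold standard. For a
#' gene pair linked by evidence E, the log-likelihood score is
#' \deqn{LLS = \ln\frac{P(L|E)/P(\neg L|E)}{P(L)/P(\neg L)}}
#' where \eqn{L} means the pair is a gold-standard positive. Frequencies are
#' estimated by counting evidence pairs that hit the positive and negative
#' sets, with `pseudocount` added to all four cells so the score stays
#' finite. Unscored ("binary") evidence gets a single LLS; scored evidence
#' is split into `n_bins` equal-frequency bins over descending raw score and
#' calibrated per bin. Bin monotonicity is reported, not enforced.
#'
#' @param evidence an [evidence_dataset()].
#' @param gold a [build_gold_standard()] result, non-empty on both sides.
#' @param n_bins number of equal-frequency score bins for scored evidence.
#' @param pseudocount added to all four contingency cells (default 1).
#' @return object of class `lls_model`: fields `type` (`"binary"` or
#'   `"scored"`), `bins` (data.frame with per-bin counts and LLS; one row for
#'   binary evidence), `pos_total`, `neg_total`, `pseudocount`, `monotone`.
#' @export
calibrate_lls <- function(evidence, gold, n_bins = 10L, pseudocount = 1) {
  if (pseudocount < 0) stop_user("pseudocount must be >= 0")
  pos_tot <- nrow(gold$positives)
  neg_tot <- nrow(gold$negatives)
  if (pos_tot == 0L || neg_tot == 0L)
    stop_user("gold standard must have both positive and negative pairs")
  pos_keys <- pair_key(gold$positives$a, gold$positives$b)
  neg_keys <- pair_key(gold$negatives$a, gold$negatives$b)
  ev <- evidence$pairs
  key <- pair_key(ev$a, ev$b)
  is_pos <- key %in% pos_keys
  is_neg <- key %in% neg_keys
  if (!any(is_pos | is_neg))
    stop_user("evidence '%s' has no overlap with the gold standard",
              evidence$name)

  if (!evidence$scored) {
    bins <- data.frame(bin = 1L, score_lo = NA_real_, score_hi = NA_real_,
                       n_pairs = nrow(ev), n_pos = sum(is_pos),
                       n_neg = sum(is_neg), stringsAsFactors = FALSE)
    bins$lls <- lls_cell(bins$n_pos, bins$n_neg, pos_tot, neg_tot, pseudocount)
    model <- list(type = "binary", bins = bins)
  } else {
    n <- nrow(ev)
    n_bins <- max(1L, min(as.integer(n_bins), n))
    o <- order(-ev$score, ev$a, ev$b, method = "radix")
    bin_of_rank <- ceiling(seq_len(n) * n_bins / n)
    bin <- integer(n)
    bin[o] <- bin_of_rank
    bins <- do.call(rbind, lapply(seq_len(n_bins), function(bi) {
      sel <- bin == bi
      data.frame(bin = bi,
                 score_lo = min(ev$score[sel]),
                 score_hi = max(ev$score[sel]),
                 n_pairs = sum(sel),
                 n_pos = sum(is_pos & sel),
                 n_neg = sum(is_neg & sel),
                 stringsAsFactors = FALSE)
    }))
    bins$lls <- lls_cell(bins$n_pos, bins$n_neg, pos_tot, neg_tot, pseudocount)
    model <- list(type = "scored", bins = bins)
  }
  model$pos_total <- pos_tot
  model$neg_total <- neg_tot
  model$pseudocount <- pseudocount
  model$monotone <- !is.unsorted(rev(model$bins$lls))
  class(model) <- "lls_model"
  model
}

#' @export
print.lls_model <- function(x, ...) {
  cat(sprintf("lls_model (%s): %d bin(s), LLS in [%.4g, %.4g]%s\n",
              x$type, nrow(x$bins), min(x$bins$lls), max(x$bins$lls),
              if (x$type == "scored" && !x$monotone) " [non-monotone]" else ""))
  invisible(x)
}

#' Annotate evidence pairs with calibrated LLS
#'
#' Applies an [calibrate_lls()] model to an evidence dataset, producing a
#' weighted [gene_network()] ready for integration. For scored evidence each
#' pair takes the LLS of the bin containing its raw score (scores beyond the
#' observed range are clamped to the extreme bins).
#'
#' @param evidence an [evidence_dataset()].
#' @param model an `lls_model` calibrated on evidence of the same type.
#' @return a [gene_network()] with one edge per evidence pair.
#' @export
evidence_to_network <- function(evidence, model) {
  ev <- evidence$pairs
  if (model$type == "binary") {
    lls <- rep(model$bins$lls[1L], nrow(ev))
  } else {
    if (!evidence$scored)
      stop_user("scored lls_model applied to unscored evidence '%s'",
                evidence$name)
    # bin b covers [score_lo_b, score_hi_b], bins ordered by descending score
    lo <- model$bins$score_lo
    idx <- vapply(ev$score, function(s) {
      i <- which(s >= lo)
      if (length(i)) min(i) else nrow(model$bins)
    }, integer(1))
    lls <- model$bins$lls[idx]
  }
  gene_network(data.frame(a = ev$a, b = ev$b, lls = lls,
                          stringsAsFactors = FALSE))
}

#' Integrate LLS networks by a rank-weighted sum
#'
#' For each unordered gene pair, the LLS values it receives from the input
#' networks that are at least `T` are sorted descending as
#' \eqn{L_0 \ge L_1 \ge \dots} and combined as
#' \deqn{WS = \sum_{i \ge 0} L_i / D^i}{WS = sum_i L_i / D^i}
#' (geometric decay, default) or
#' \eqn{WS = L_0 + \sum_{i \ge 1} L_i/(D\,i)} (linear decay). `D >= 1`
#' down-weights weaker, partially redundant lines of evidence; `D = 1` with
#' geometric decay is a plain sum and `D -> Inf` keeps only the best
#' evidence. A pair enters the output iff at least one input LLS reaches
#' `T`. Nodes are the union of all input node sets.
#'
#' @param networks list of [gene_network()] objects (a single network is
#'   also accepted).
#' @param D decay parameter, `>= 1` (default 2).
#' @param T minimum per-input LLS for a value to enter the sum (default 0).
#' @param decay_form `"geometric"` (default) or `"linear"`.
#' @return integrated [gene_network()].
#' @export
integrate_weighted_sum <- function(networks, D = 2, T = 0,
                                   decay_form = c("geometric", "linear")) {
  decay_form <- match.arg(decay_form)
  if (inherits(networks, "gene_network")) networks <- list(networks)
  if (!length(networks)) stop_user("need at least one input network")
  if (!is.numeric(D) || length(D) != 1L || D < 1)
    stop_user("decay parameter D must be a single number >= 1")
  all_nodes <- sort_c(unique(unlist(lapply(networks, network_nodes))))
  ed <- do.call(rbind, lapply(networks, network_edges))
  ed <- ed[ed$lls >= T, , drop = FALSE]
  if (!nrow(ed)) return(gene_network(NULL, nodes = all_nodes))
  key <- pair_key(ed$a, ed$b)
  o <- order(key, -ed$lls, method = "radix")
  ed <- ed[o, , drop = FALSE]
  key <- key[o]
  i <- sequence(rle(key)$lengths) - 1L  # 0-based rank within pair
  w <- if (decay_form == "geometric") {
    ed$lls / D^i
  } else {
    ifelse(i == 0L, ed$lls, ed$lls / (D * i))
  }
  first <- !duplicated(key)
  ws <- rowsum(w, key, reorder = FALSE)
  gene_network(data.frame(a = ed$a[first], b = ed$b[first],
                          lls = as.numeric(ws[, 1L]),
                          stringsAsFactors = FALSE),
               nodes = all_nodes)
}
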