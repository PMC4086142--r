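#' Construct a weighted gene network
#'
#' The central container of the package: an undirected graph over gene
#' identifiers whose edges carry a log-likelihood score (LLS, natural-log
#' units). Gene identifiers are opaque, case-sensitive tokens; no
#' organism-specific validation is applied. Edges are stored in canonical
#' orientation (byte-order `a < b`) with unique unordered pairs, so two
#' networks are equal iff their node sets and canonical edge tables are equal.
#'
#' Self-loops are dropped (the count is kept on the object) and duplicate
#' unordered pairs are resolved by `dedup`: `"max"` keeps the largest LLS
#' (conservative union of evidence files), `"first"` keeps the first
#' occurrence in input order, `"error"` refuses duplicates.
#'
#' @param edges data.frame-like with three columns: gene A, gene B, LLS.
#'   `NULL` gives an edgeless network.
#' @param nodes additional (possibly isolated) gene identifiers to include.
#' @param dedup duplicate unordered-pair policy: `"max"` (default), `"first"`
#'   or `"error"`.
#' @return An object of class `gene_network` with fields `nodes` (sorted
#'   character), `edges` (data.frame `a`, `b`, `lls`), `n_self_loops`,
#'   `n_duplicates`.
#' @examples
#' net <- gene_network(data.frame(a = c("g1", "g2"), b = c("g2", "g3"),
#'                                lls = c(1.5, 2)))
#' edge_count(net)
#' @export
gene_network <- function(edges = NULL, nodes = character(),
                         dedup = c("max", "first", "error")) {
  dedup <- match.arg(dedup)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(a = character(), b = character(), lls = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 3L) stop_user("edge table needs 3 columns (a, b, lls)")
    edges <- edges[, 1:3]
    names(edges) <- c("a", "b", "lls")
    edges$a <- as.character(edges$a)
    edges$b <- as.character(edges$b)
    edges$lls <- as.numeric(edges$lls)
  }
  ids <- c(edges$a, edges$b, as.character(nodes))
  if (any(!nzchar(ids)) || any(grepl("[[:space:]]", ids)))
    stop_user("gene identifiers must be non-empty tokens without whitespace")
  if (any(!is.finite(edges$lls)))
    stop_user("all edge LLS values must be finite")

  self <- edges$a == edges$b
  n_self <- sum(self)
  nodes <- c(as.character(nodes), edges$a[self])  # self-loop genes stay nodes
  edges <- edges[!self, , drop = FALSE]

  cp <- canonical_pairs(edges$a, edges$b)
  edges$a <- cp$a
  edges$b <- cp$b
  key <- pair_key(edges$a, edges$b)
  n_dup <- sum(duplicated(key))
  if (n_dup > 0L) {
    if (dedup == "error")
      stop_user("%d duplicate unordered gene pair(s) in edge input", n_dup)
    if (dedup == "max") {
      o <- order(key, -edges$lls, method = "radix")
      edges <- edges[o, , drop = FALSE]
      edges <- edges[!duplicated(key[o]), , drop = FALSE]
    } else {
      edges <- edges[!duplicated(key), , drop = FALSE]
    }
  }
  edges <- edges[order(edges$a, edges$b, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = sort_c(unique(c(nodes, edges$a, edges$b))),
         edges = edges,
         n_self_loops = as.integer(n_self),
         n_duplicates = as.integer(n_dup)),
    class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(sprintf("  LLS range [%.4g, %.4g]\n",
                min(x$edges$lls), max(x$edges$lls)))
  }
  invisible(x)
}

#' Network accessors
#'
#' @param network a [gene_network()].
#' @return `network_nodes()`: sorted character vector of gene identifiers;
#'   `network_edges()`: the canonical edge data.frame (`a`, `b`, `lls`);
#'   `node_count()` / `edge_count()`: integers.
#' @export
network_nodes <- function(network) network$nodes

#' @rdname network_nodes
#' @export
network_edges <- function(network) network$edges

#' @rdname network_nodes
#' @export
node_count <- function(network) length(network$nodes)

#' @rdname network_nodes
#' @export
edge_count <- function(network) nrow(network$edges)

#' Degree of every gene above an LLS threshold
#'
#' Thresholding is strict (`lls > min_lls`), matching the "connected by
#' LLS > 1" convention used throughout hub definitions.
#'
#' @inheritParams network_nodes
#' @param min_lls strict lower bound on edge LLS; `-Inf` counts every edge.
#' @return Named integer vector over all network genes (isolated genes get 0).
#' @export
network_degrees <- function(network, min_lls = -Inf) {
  e <- network$edges[network$edges$lls > min_lls, , drop = FALSE]
  d <- setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(e)) {
    tab <- table(c(e$a, e$b))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Neighbors of a gene above an LLS threshold
#'
#' @inheritParams network_degrees
#' @param gene a gene identifier; a gene absent from the network yields an
#'   empty result (not an error).
#' @return data.frame with columns `gene`, `lls`, sorted by gene identifier.
#' @export
network_neighbors <- function(network, gene, min_lls = -Inf) {
  e <- network$edges
  sel_a <- e$a == gene
  sel_b <- e$b == gene
  out <- data.frame(gene = c(e$b[sel_a], e$a[sel_b]),
                    lls = c(e$lls[sel_a], e$lls[sel_b]),
                    stringsAsFactors = FALSE)
  out <- out[out$lls > min_lls, , drop = FALSE]
  out <- out[order(out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

strip_comment_lines <- function(lines) {
  keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
  list(lines = trimws(lines[keep]), lineno = which(keep))
}

#' Read a weighted edge list (TSV)
#'
#' Expects at least three whitespace/tab-separated columns per line:
#' `geneA geneB LLS`; `#`-prefixed comment lines and blank lines are ignored.
#' Extra columns are ignored. Self-loops are dropped and duplicate unordered
#' pairs resolved per `dedup`, each with a warning giving the count.
#'
#' @param path file path.
#' @param dedup duplicate-pair policy, see [gene_network()].
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path, dedup = c("max", "first", "error")) {
  dedup <- match.arg(dedup)
  sc <- strip_comment_lines(readLines(path))
  fields <- strsplit(sc$lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1L]
    stop_user("line %d of %s: expected 3 columns (geneA, geneB, LLS), found %d",
              sc$lineno[i], path, nf[i])
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  lls <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(lls)) {
    i <- which(is.na(lls))[1L]
    stop_user("line %d of %s: non-numeric LLS value '%s'",
              sc$lineno[i], path, fields[[i]][3L])
  }
  net <- gene_network(data.frame(a = a, b = b, lls = lls,
                                 stringsAsFactors = FALSE), dedup = dedup)
  if (net$n_self_loops > 0L)
    warning(sprintf("%s: dropped %d self-loop(s)", path, net$n_self_loops))
  if (net$n_duplicates > 0L)
    warning(sprintf("%s: merged %d duplicate pair(s) with policy '%s'",
                    path, net$n_duplicates, dedup))
  net
}

#' Write a weighted edge list (TSV)
#'
#' One tab-separated line per edge, sorted by descending LLS then by gene
#' pair (byte order), so output is byte-identical for a given network. LLS is
#' printed with full double precision (17 significant digits), which makes
#' `read_edge_list(write_edge_list(net))` an exact round trip.
#'
#' @inheritParams network_nodes
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  e <- network$edges
  o <- order(-e$lls, e$a, e$b, method = "radix")
  e <- e[o, , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%s", e$a, e$b, sprintf("%.17g", e$lls)), path)
  invisible(path)
}

#' Gene sets (named ordered lists of genes)
#'
#' @param name set label.
#' @param members gene identifiers; duplicates are removed keeping first
#'   occurrence, input order is preserved.
#' @return object of class `gene_set` with fields `name`, `members`.
#' @export
gene_set <- function(name, members) {
  members <- as.character(members)
  if (any(!nzchar(members)) || any(grepl("[[:space:]]", members)))
    stop_user("gene identifiers must be non-empty tokens without whitespace")
  structure(list(name = as.character(name)[1],
                 members = members[!duplicated(members)]),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$members)))
  invisible(x)
}

as_gene_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}

#' Read a plain-text gene list
#'
#' One gene identifier per line; `#` comments and blank lines ignored;
#' duplicates removed preserving first-seen order.
#'
#' @param path file path.
#' @param name set label (defaults to the file name).
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  sc <- strip_comment_lines(readLines(path))
  gene_set(name, sc$lines)
}

#' @rdname read_gene_list
#' @param genes a [gene_set()] or character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as_gene_members(genes), path)
  invisible(path)
}
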