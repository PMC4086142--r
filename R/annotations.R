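#' Gene-to-term annotation tables
#'
#' Holds records `(gene, term, evidence)` in the style of GO biological
#' process or RNAi-phenotype annotation files. Evidence codes (IMP, IDA, IGI,
#' IPI, IEP, TAS, ISS, ...) record how an annotation was inferred and drive
#' the gold-standard exclusion rules; they are optional (`NA` when absent).
#' Records are unique; the same `(gene, term)` pair may carry several
#' evidence codes as separate records.
#'
#' @param records data.frame-like with columns gene, term and optionally
#'   evidence.
#' @return data.frame of class `annotation_table` with columns `gene`,
#'   `term`, `evidence`.
#' @export
annotation_table <- function(records = NULL) {
  if (is.null(records) || NROW(records) == 0L) {
    records <- data.frame(gene = character(), term = character(),
                          evidence = character(), stringsAsFactors = FALSE)
  } else {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    if (ncol(records) < 2L)
      stop_user("annotation table needs at least columns gene and term")
    if (ncol(records) == 2L) records$evidence <- NA_character_
    records <- records[, 1:3]
    names(records) <- c("gene", "term", "evidence")
    records$gene <- as.character(records$gene)
    records$term <- as.character(records$term)
    records$evidence <- as.character(records$evidence)
  }
  records <- unique(records)
  records <- records[order(records$gene, records$term, records$evidence,
                           method = "radix"), , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("annotation_table", "data.frame")
  records
}

#' Summary counts of an annotation table
#'
#' @param annotations an [annotation_table()].
#' @return list with `n_genes`, `n_terms`, `n_annotations` (unique
#'   gene--term pairs, evidence merged) and `n_records`.
#' @export
annotation_counts <- function(annotations) {
  gt <- unique(annotations[, c("gene", "term")])
  list(n_genes = length(unique(annotations$gene)),
       n_terms = length(unique(annotations$term)),
       n_annotations = nrow(gt),
       n_records = nrow(annotations))
}

#' Read / write an annotation table (TSV)
#'
#' Lines have 2 or 3 whitespace/tab-separated columns:
#' `gene term [evidence]`; `#` comments and blank lines are ignored.
#'
#' @param path file path.
#' @return [read_annotations()]: an [annotation_table()].
#' @export
read_annotations <- function(path) {
  sc <- strip_comment_lines(readLines(path))
  if (!length(sc$lines)) return(annotation_table())
  fields <- strsplit(sc$lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    i <- which(nf < 2L)[1L]
    stop_user("line %d of %s: expected columns gene<TAB>term[<TAB>evidence]",
              sc$lineno[i], path)
  }
  annotation_table(data.frame(
    gene = vapply(fields, `[[`, character(1), 1L),
    term = vapply(fields, `[[`, character(1), 2L),
    evidence = vapply(fields, function(f)
      if (length(f) >= 3L) f[[3L]] else NA_character_, character(1)),
    stringsAsFactors = FALSE))
}

#' @rdname read_annotations
#' @param annotations an [annotation_table()] to write.
#' @export
write_annotations <- function(annotations, path) {
  ev <- ifelse(is.na(annotations$evidence), "", annotations$evidence)
  lines <- ifelse(nzchar(ev),
                  paste(annotations$gene, annotations$term, ev, sep = "\t"),
                  paste(annotations$gene, annotations$term, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# terms whose distinct-gene count lies in [min_size, max_size]
admissible_terms <- function(annotations, min_size, max_size) {
  gt <- unique(annotations[, c("gene", "term")])
  sizes <- table(gt$term)
  names(sizes)[sizes >= min_size & sizes <= max_size]
}
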