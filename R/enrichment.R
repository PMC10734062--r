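#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least the given overlap between a
#' query gene list and an annotated set when the query is drawn without
#' replacement from the universe (the features measured on the array, not
#' the genome).
#'
#' @param query character vector of query genes (or the query size, when
#'   `overlap` is supplied directly).
#' @param annotated character vector of genes carrying the annotation (or
#'   its size).
#' @param universe_size total number of genes in the sampling frame.
#' @param overlap optional observed overlap; computed from the vectors when
#'   omitted.
#' @return one-sided p-value `P(X >= overlap)`.
#' @export
hypergeometric_ora <- function(query, annotated, universe_size,
                               overlap = NULL) {
  k_query <- if (is.character(query)) length(unique(query)) else query
  k_annot <- if (is.character(annotated)) length(unique(annotated)) else
    annotated
  if (is.null(overlap)) {
    abort_if(!is.character(query) || !is.character(annotated),
             "overlap must be given when sets are passed as sizes")
    overlap <- length(intersect(unique(query), unique(annotated)))
  }
  abort_if(overlap > min(k_query, k_annot),
           "overlap (%d) exceeds a set size", overlap)
  abort_if(max(k_query, k_annot) > universe_size,
           "set size exceeds the universe")
  hypergeom_upper(overlap, k_annot, k_query, universe_size)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; the output keeps
#' the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same order as `pvals`.
#' @export
bh_adjust <- function(pvals) {
  abort_if(any(pvals < 0 | pvals > 1, na.rm = TRUE),
           "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Over-representation analysis of a query list against a collection
#'
#' One hypergeometric test per gene set, BH-adjusted across the
#' collection, sorted by p-value.
#'
#' @param query character vector of query genes.
#' @param collection a `gene_set_collection` (named list of gene vectors).
#' @param universe character vector of all genes in the sampling frame
#'   (query and set members outside it are ignored).
#' @return data.frame with columns `set`, `set_size`, `overlap`, `p`, `q`,
#'   sorted by `p`.
#' @export
enrich_collection <- function(query, collection, universe) {
  abort_if(length(universe) == 0L, "universe must be non-empty")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(unique(collection[[nm]]), universe)
    ov <- length(intersect(query, members))
    data.frame(set = nm, set_size = length(members), overlap = ov,
               p = hypergeometric_ora(query, members, length(universe),
                                      overlap = ov),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
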