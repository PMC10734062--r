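#' Assemble lnc/circRNA-miRNA-mRNA circuits from co-expression edges
#'
#' A ceRNA circuit is a retained sponge-mRNA co-expression edge whose two
#' endpoints share at least `min_shared` predicted miRNAs: the sponge can
#' then de-repress the mRNA by sequestering those miRNAs. Circuits are
#' keyed by the (sponge, mRNA) pair; the complete shared miRNA set is an
#' attribute of the circuit, not a multiplier of it.
#'
#' @param edges co-expression edge data.frame from
#'   [build_coexpression_network()] (already threshold-filtered).
#' @param targets a `target_table`.
#' @param min_shared minimum number of shared miRNAs (default 1).
#' @return a `cerna_circuits` data.frame: `sponge_id`, `mrna_id`,
#'   `shared_mirnas` (comma-joined), `n_shared`, `pcc`, `pcc_p`,
#'   `enrichment_p`, `sponge_host_escapes_xci`, `mrna_in_filter_set`.
#' @export
assemble_circuits <- function(edges, targets, min_shared = 1L) {
  abort_if(is.null(targets), "targets must be a target_table")
  targets <- target_table(as.data.frame(targets))
  by_target <- mirnas_by_target(targets)
  shared <- lapply(seq_len(nrow(edges)), function(i) {
    sort(intersect(by_target[[edges$sponge_id[i]]] %||% character(),
                   by_target[[edges$mrna_id[i]]] %||% character()))
  })
  n_shared <- vapply(shared, length, 1L)
  keep <- n_shared >= min_shared
  out <- data.frame(
    sponge_id = edges$sponge_id[keep],
    mrna_id = edges$mrna_id[keep],
    shared_mirnas = vapply(shared[keep], paste, character(1L),
                           collapse = ","),
    n_shared = n_shared[keep],
    pcc = edges$pcc[keep],
    pcc_p = edges$p_value[keep],
    enrichment_p = rep(NA_real_, sum(keep)),
    sponge_host_escapes_xci = rep(NA, sum(keep)),
    mrna_in_filter_set = rep(NA, sum(keep)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cerna_circuits", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hypergeometric enrichment of shared miRNAs between two transcripts
#'
#' Optional stringency beyond the >= 1 shared-miRNA rule: the upper-tail
#' probability that two transcripts targeted by `k_sponge` and `k_mrna`
#' miRNAs out of a universe of `mirna_universe_size` share at least the
#' observed number by chance.
#'
#' @param sponge_id,mrna_id feature ids to look up in `targets`.
#' @param targets a `target_table`.
#' @param mirna_universe_size total number of distinct miRNAs that could
#'   target either transcript (at least the larger per-endpoint count).
#' @return upper-tail hypergeometric p-value `P(X >= observed shared)`.
#' @export
shared_mirna_enrichment <- function(sponge_id, mrna_id, targets,
                                    mirna_universe_size) {
  by_target <- mirnas_by_target(target_table(as.data.frame(targets)))
  ms <- by_target[[sponge_id]] %||% character()
  mm <- by_target[[mrna_id]] %||% character()
  k <- length(intersect(ms, mm))
  abort_if(mirna_universe_size < max(length(ms), length(mm)),
           "miRNA universe (%d) smaller than a per-endpoint count",
           mirna_universe_size)
  hypergeom_upper(k, length(ms), length(mm), mirna_universe_size)
}

# P(X >= k) for X ~ Hypergeometric(draws = k_query, successes = k_annot,
# universe = n); shared helper for circuit stringency and ORA
hypergeom_upper <- function(k, k_annot, k_query, n) {
  if (k == 0L) return(1)
  stats::phyper(k - 1L, m = k_annot, n = n - k_annot, k = k_query,
                lower.tail = FALSE)
}

#' Filter circuits on sponge XCI-escape status and mRNA gene sets
#'
#' Implements the biological focusing step: keep circuits whose sponge is
#' hosted by an X-inactivation escaping gene (dose-reduced in 45,X cells)
#' and whose mRNA belongs to a user-supplied set of genes of interest
#' (e.g. cardiovascular development, cardiomyocyte or mitochondrial
#' function). Escape calls are version-dependent, so they come from the
#' annotation table rather than a bundled list.
#'
#' @param circuits a `cerna_circuits` data.frame.
#' @param annotation feature annotation covering every circuit endpoint.
#' @param escape_required drop circuits whose sponge host does not escape
#'   XCI.
#' @param mrna_filter_set character vector of gene symbols to keep
#'   (`NULL` = no mRNA filter; an empty vector keeps nothing).
#' @return the filtered `cerna_circuits`, with
#'   `sponge_host_escapes_xci`/`mrna_in_filter_set` flags populated.
#' @export
filter_circuits <- function(circuits, annotation, escape_required = TRUE,
                            mrna_filter_set = NULL) {
  annotation <- validate_feature_annotation(annotation)
  ends <- unique(c(circuits$sponge_id, circuits$mrna_id))
  miss <- setdiff(ends, annotation$feature_id)
  abort_if(length(miss) > 0L, "circuit endpoint(s) missing annotation: %s",
           paste(utils::head(miss, 5L), collapse = ", "))
  idx_s <- match(circuits$sponge_id, annotation$feature_id)
  idx_m <- match(circuits$mrna_id, annotation$feature_id)
  circuits$sponge_host_escapes_xci <- annotation$xci_escape[idx_s]
  mrna_symbol <- annotation$gene_symbol[idx_m]
  circuits$mrna_in_filter_set <- if (is.null(mrna_filter_set)) NA else
    mrna_symbol %in% mrna_filter_set
  keep <- rep(TRUE, nrow(circuits))
  if (escape_required) keep <- keep & circuits$sponge_host_escapes_xci
  if (!is.null(mrna_filter_set)) keep <- keep & circuits$mrna_in_filter_set
  out <- circuits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Add hypergeometric shared-miRNA enrichment p-values to circuits
#'
#' @param circuits a `cerna_circuits` data.frame.
#' @param targets the `target_table` the circuits were assembled from.
#' @param mirna_universe_size total number of distinct miRNAs in play
#'   (default: the number observed in `targets`).
#' @return `circuits` with the `enrichment_p` column populated.
#' @export
add_circuit_enrichment <- function(circuits, targets,
                                   mirna_universe_size = NULL) {
  targets <- target_table(as.data.frame(targets))
  if (is.null(mirna_universe_size))
    mirna_universe_size <- length(unique(targets$mirna_id))
  circuits$enrichment_p <- vapply(seq_len(nrow(circuits)), function(i) {
    shared_mirna_enrichment(circuits$sponge_id[i], circuits$mrna_id[i],
                            targets, mirna_universe_size)
  }, numeric(1L))
  circuits
}
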