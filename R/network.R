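#' Construct a ceRNA/co-expression network object
#'
#' A light container around node and edge tables, exported to the formats
#' understood by network-visualization tools such as Cytoscape.
#'
#' @param nodes data.frame with columns `id`, `rna_class`, `de_direction`.
#' @param edges data.frame with columns `from`, `to`, `pcc`, `p_value`,
#'   `edge_kind` (`"coexpression"` or `"targeting"`); `pcc`/`p_value` may be
#'   `NA` on targeting edges.
#' @return an object of class `rna_network`.
#' @export
rna_network <- function(nodes, edges) {
  check_columns(nodes, c("id", "rna_class", "de_direction"), "node table")
  check_columns(edges, c("from", "to", "pcc", "p_value", "edge_kind"),
                "edge table")
  check_unique(nodes$id, "node id")
  dangling <- setdiff(c(edges$from, edges$to), nodes$id)
  abort_if(length(dangling) > 0L, "edge endpoint(s) not in node table: %s",
           paste(utils::head(dangling, 5L), collapse = ", "))
  bad_r <- which(!is.na(edges$pcc) & abs(edges$pcc) > 1)
  abort_if(length(bad_r) > 0L, "pcc out of [-1,1] on edge %d", bad_r[1L])
  bad_p <- which(!is.na(edges$p_value) &
                   (edges$p_value < 0 | edges$p_value > 1))
  abort_if(length(bad_p) > 0L, "p_value out of [0,1] on edge %d", bad_p[1L])
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "rna_network")
}

#' @export
print.rna_network <- function(x, ...) {
  cat(sprintf("rna_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a network to SIF or GraphML
#'
#' SIF rows are `source<TAB>edge_kind<TAB>target` in edge-table order;
#' GraphML (written through igraph) carries all node and edge attributes.
#' Output is byte-stable for identical input.
#'
#' @param net an [rna_network()].
#' @param path output path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml")) {
  abort_if(!inherits(net, "rna_network"), "net must be an rna_network")
  format <- check_choice(tolower(format[1L]), c("sif", "graphml"),
                         "network format")
  if (format == "sif") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (nrow(net$edges) > 0L) {
      writeLines(paste(net$edges$from, net$edges$edge_kind, net$edges$to,
                       sep = "\t"), con)
    }
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert an rna_network to an igraph graph
#' @param net an [rna_network()].
#' @return an undirected igraph graph with node/edge attributes.
#' @export
as_igraph <- function(net) {
  nodes <- net$nodes
  names(nodes)[1L] <- "name"
  edges <- net$edges
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Read a GraphML network back into an rna_network
#' @param path GraphML file written by [write_network()].
#' @return an [rna_network()].
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  names(nodes)[names(nodes) == "name"] <- "id"
  edges <- igraph::as_data_frame(g, what = "edges")
  rna_network(nodes[, c("id", "rna_class", "de_direction")],
              edges[, c("from", "to", "pcc", "p_value", "edge_kind")])
}

#' Write ceRNA circuits as a two-layer Sankey document (JSON)
#'
#' Each circuit contributes sponge -> miRNA and miRNA -> mRNA links for every
#' shared miRNA; link weight counts the circuits contributing that link, and
#' each node is emitted once with its layer (`sponge`, `mirna`, `mrna`).
#'
#' @param circuits a `cerna_circuits` data.frame (see [assemble_circuits()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sankey <- function(circuits, path) {
  links <- data.frame(source = character(), target = character(),
                      value = integer(), stringsAsFactors = FALSE)
  nodes <- data.frame(id = character(), layer = character(),
                      stringsAsFactors = FALSE)
  if (nrow(circuits) > 0L) {
    per <- lapply(seq_len(nrow(circuits)), function(i) {
      mirs <- split_mirnas(circuits$shared_mirnas[i])
      rbind(data.frame(source = circuits$sponge_id[i], target = mirs,
                       stringsAsFactors = FALSE),
            data.frame(source = mirs, target = circuits$mrna_id[i],
                       stringsAsFactors = FALSE))
    })
    all_links <- do.call(rbind, per)
    agg <- stats::aggregate(list(value = rep(1L, nrow(all_links))),
                            by = all_links[c("source", "target")], FUN = sum)
    links <- agg[order(agg$source, agg$target), , drop = FALSE]
    rownames(links) <- NULL
    mirs_all <- unique(unlist(lapply(circuits$shared_mirnas, split_mirnas)))
    nodes <- rbind(
      data.frame(id = unique(circuits$sponge_id), layer = "sponge",
                 stringsAsFactors = FALSE),
      data.frame(id = mirs_all, layer = "mirna", stringsAsFactors = FALSE),
      data.frame(id = unique(circuits$mrna_id), layer = "mrna",
                 stringsAsFactors = FALSE))
  }
  doc <- list(nodes = nodes, links = links)
  jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# shared-miRNA sets are stored as comma-joined strings in the flat table
split_mirnas <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else
    strsplit(x, ",", fixed = TRUE)[[1L]]
}

#' Write circuits as a flat TSV
#' @param circuits a `cerna_circuits` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_circuits <- function(circuits, path) {
  write_tsv_plain(as.data.frame(circuits), path, num_digits = 6L)
}
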