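#' Stack expression matrices from several RNA classes
#'
#' @param mats named list of [expression_matrix()] objects sharing the same
#'   samples and scale.
#' @return one [expression_matrix()] with all features.
#' @export
combine_expression <- function(mats) {
  abort_if(length(mats) == 0L, "no matrices to combine")
  ref <- mats[[1L]]
  for (m in mats[-1L]) {
    abort_if(!identical(colnames(m$values), colnames(ref$values)),
             "matrices have different samples")
    abort_if(m$scale != ref$scale, "matrices are on different scales")
  }
  expression_matrix(do.call(rbind, lapply(mats, `[[`, "values")),
                    ref$groups, ref$scale)
}

#' The three standard contrasts of the study design
#'
#' @param groups sample sheet data.frame.
#' @return named list; each element holds `a`, `b` (sample-id vectors) and
#'   `paired`. Differentiation contrasts (CM vs iPSC within genotype) pair
#'   on cell line; the cross-genotype contrast is unpaired (no natural
#'   pairing exists between different individuals).
#' @export
standard_contrasts <- function(groups) {
  pick <- function(genotype, state)
    groups$sample_id[groups$genotype == genotype & groups$state == state]
  list(
    WT_CM_vs_WT_iPSC = list(a = pick("WT", "CM"), b = pick("WT", "iPSC"),
                            paired = TRUE),
    TS_CM_vs_TS_iPSC = list(a = pick("TS", "CM"), b = pick("TS", "iPSC"),
                            paired = TRUE),
    TS_CM_vs_WT_CM = list(a = pick("TS", "CM"), b = pick("WT", "CM"),
                          paired = FALSE))
}

#' Run the full ceRNA analysis on in-memory objects
#'
#' Stage order: quantile normalization per RNA class, sample QC,
#' differential expression for the three standard contrasts per class,
#' seven-region Venn partition per class, sponge/mRNA DE list assembly,
#' co-expression network over the cross-genotype CM samples, circuit
#' assembly by shared predicted miRNAs, optional biological filters, and
#' optional over-representation analysis of the DE mRNAs.
#'
#' @param expression named list of linear-scale [expression_matrix()]
#'   objects, with at least an `mRNA` element; `lncRNA`/`circRNA` supply
#'   sponge candidates.
#' @param targets a `target_table` of miRNA-transcript interactions.
#' @param annotation optional feature annotation (required for escape
#'   filtering).
#' @param gene_sets optional `gene_set_collection` for enrichment.
#' @param fc_hi,fc_lo,alpha DE thresholds (defaults 2, 0.5, 0.05).
#' @param r_min,coexpr_alpha co-expression thresholds (defaults 0.2, 0.05).
#' @param min_shared minimum shared miRNAs per circuit.
#' @param de_scope `"union"` (DE in any contrast) or one contrast name.
#' @param coexpr_state cell state whose samples enter the correlations
#'   (default `"CM"`: both genotypes' cardiomyocytes).
#' @param paired_differentiation pair differentiation contrasts by line.
#' @param escape_required,mrna_filter_set passed to [filter_circuits()]
#'   when `annotation` is supplied; `mrna_filter_set` may name a set in
#'   `gene_sets`.
#' @return list with `normalized`, `qc`, `de`, `venn`, `de_lists`,
#'   `coexpression`, `circuits`, `circuits_filtered`, `enrichment`.
#' @export
analyze_cerna <- function(expression, targets, annotation = NULL,
                          gene_sets = NULL,
                          fc_hi = 2, fc_lo = 0.5, alpha = 0.05,
                          r_min = 0.2, coexpr_alpha = 0.05,
                          min_shared = 1L,
                          de_scope = "union", coexpr_state = "CM",
                          paired_differentiation = TRUE,
                          escape_required = FALSE,
                          mrna_filter_set = NULL) {
  abort_if(!"mRNA" %in% names(expression),
           "expression must contain an 'mRNA' matrix")
  # normalize all classes together, as a single array would be: with the
  # regulated fraction small relative to the whole feature set, forcing a
  # common distribution removes technical scale without eating real signal
  combined <- quantile_normalize(combine_expression(expression))
  normalized <- lapply(expression, function(m)
    expression_matrix(combined$values[rownames(m$values), , drop = FALSE],
                      combined$groups, "linear"))
  groups <- combined$groups

  qc <- list(sample_correlation = sample_correlation_matrix(
               convert_scale(normalized$mRNA, "log2")),
             dendrogram = hierarchical_cluster_samples(
               convert_scale(normalized$mRNA, "log2")),
             pca = pca_scores(convert_scale(normalized$mRNA, "log2"),
                              k = min(4L, ncol(normalized$mRNA$values) - 1L)))

  contrasts <- standard_contrasts(groups)
  if (!paired_differentiation) {
    contrasts <- lapply(contrasts, function(ct) {
      ct$paired <- FALSE
      ct
    })
  }
  de <- lapply(normalized, function(m) {
    lapply(names(contrasts), function(cn) {
      ct <- contrasts[[cn]]
      run_contrast(m, ct$a, ct$b, paired = ct$paired, fc_hi = fc_hi,
                   fc_lo = fc_lo, alpha = alpha, contrast = cn)
    }) |> stats::setNames(names(contrasts))
  })
  venn <- lapply(de, function(d)
    venn_partition(d[[1L]], d[[2L]], d[[3L]]))

  de_called <- function(class_de) {
    if (identical(de_scope, "union")) {
      unique(unlist(lapply(class_de, de_features)))
    } else {
      abort_if(!de_scope %in% names(class_de), "unknown de_scope '%s'",
               de_scope)
      de_features(class_de[[de_scope]])
    }
  }
  de_sponges <- sort(unique(unlist(lapply(
    de[intersect(c("lncRNA", "circRNA"), names(de))], de_called))))
  de_mrnas <- sort(de_called(de$mRNA))

  samples <- select_samples(combined, state = coexpr_state)
  coexpr <- build_coexpression_network(combined, de_sponges, de_mrnas,
                                       samples, r_min = r_min,
                                       alpha = coexpr_alpha)
  circuits <- assemble_circuits(coexpr$edges, targets,
                                min_shared = min_shared)

  circuits_filtered <- NULL
  if (!is.null(annotation)) {
    filter_genes <- NULL
    if (!is.null(mrna_filter_set)) {
      filter_genes <- if (length(mrna_filter_set) == 1L &&
                          !is.null(gene_sets) &&
                          mrna_filter_set %in% names(gene_sets))
        gene_sets[[mrna_filter_set]] else mrna_filter_set
    }
    circuits_filtered <- filter_circuits(circuits, annotation,
                                         escape_required = escape_required,
                                         mrna_filter_set = filter_genes)
  }

  enrichment <- NULL
  if (!is.null(gene_sets) && length(gene_sets) > 0L) {
    if (!is.null(annotation)) {
      sym <- annotation$gene_symbol[match(rownames(normalized$mRNA$values),
                                          annotation$feature_id)]
      universe <- sym[!is.na(sym)]
      query <- annotation$gene_symbol[match(de_mrnas,
                                            annotation$feature_id)]
    } else {
      universe <- rownames(normalized$mRNA$values)
      query <- de_mrnas
    }
    enrichment <- enrich_collection(query, gene_sets, universe)
  }

  list(normalized = normalized, qc = qc, de = de, venn = venn,
       de_lists = list(sponges = de_sponges, mrnas = de_mrnas),
       coexpression = coexpr, circuits = circuits,
       circuits_filtered = circuits_filtered, enrichment = enrichment,
       thresholds = list(fc_hi = fc_hi, fc_lo = fc_lo, alpha = alpha,
                         r_min = r_min, coexpr_alpha = coexpr_alpha,
                         min_shared = min_shared))
}

#' Read a pipeline configuration file
#'
#' YAML with an `inputs` block (paths to the expression matrices, sample
#' sheet and target table, plus optional annotation, gene sets and miRNA /
#' transcript FASTA files), an optional `thresholds` block (defaults:
#' fc_hi 2, fc_lo 0.5, alpha 0.05, r_min 0.2, coexpr_alpha 0.05,
#' min_shared 1) and an optional `options` block.
#'
#' @param path YAML config path.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  abort_if(!file.exists(path), "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  abort_if(is.null(cfg$inputs), "config needs an 'inputs' block")
  defaults <- list(fc_hi = 2, fc_lo = 0.5, alpha = 0.05, r_min = 0.2,
                   coexpr_alpha = 0.05, min_shared = 1L)
  cfg$thresholds <- utils::modifyList(defaults,
                                      cfg$thresholds %||% list())
  cfg$options <- utils::modifyList(
    list(de_scope = "union", coexpr_state = "CM",
         paired_differentiation = TRUE, escape_required = FALSE,
         mrna_filter_set = NULL, target_merge = "intersection"),
    cfg$options %||% list())
  cfg
}

#' Run the pipeline from a config file into a run directory
#'
#' Reads every input up front (aborting before any stage runs if a file is
#' missing), executes [analyze_cerna()], and writes DE tables, the Venn
#' partition, QC exports, the co-expression edge list and network files,
#' circuits (flat TSV and Sankey JSON), enrichment results, a stage log
#' and a schema-tagged manifest. Identical config and inputs give
#' byte-identical outputs; the log carries no timestamps for that reason.
#'
#' @param config path to a YAML config, or a list from
#'   [read_pipeline_config()].
#' @param out_dir run directory to create.
#' @param force overwrite an existing non-empty run directory.
#' @return (invisibly) the [analyze_cerna()] result.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force) {
    stop("run directory ", out_dir,
         " already exists; use force = TRUE to overwrite", call. = FALSE)
  }
  inp <- config$inputs
  paths <- unlist(inp[c("expression", "sample_sheet", "annotation",
                        "targets", "gene_sets", "mirna_fasta",
                        "transcript_fasta")], use.names = TRUE)
  missing <- paths[!vapply(paths, file.exists, TRUE)]
  abort_if(length(missing) > 0L, "missing input file(s): %s",
           paste(missing, collapse = ", "))

  expression <- lapply(inp$expression, read_expression_matrix,
                       sample_sheet = inp$sample_sheet)
  annotation <- if (!is.null(inp$annotation))
    read_feature_annotation(inp$annotation) else NULL
  gene_sets <- if (!is.null(inp$gene_sets))
    read_gene_sets(inp$gene_sets) else NULL
  targets <- NULL
  if (!is.null(inp$targets)) targets <- read_target_table(inp$targets)
  if (!is.null(inp$mirna_fasta)) {
    predicted <- predict_targets_seed(
      inp$mirna_fasta, inp$transcript_fasta,
      circular_ids = if (!is.null(annotation))
        annotation$feature_id[annotation$rna_class == "circRNA"] else
        character())
    targets <- if (is.null(targets)) predicted else
      merge_target_tables(list(predicted, targets),
                          mode = config$options$target_merge)
  }
  abort_if(is.null(targets),
           "config must provide 'targets' and/or FASTA inputs")

  th <- config$thresholds
  op <- config$options
  res <- analyze_cerna(expression, targets, annotation = annotation,
                       gene_sets = gene_sets,
                       fc_hi = th$fc_hi, fc_lo = th$fc_lo,
                       alpha = th$alpha, r_min = th$r_min,
                       coexpr_alpha = th$coexpr_alpha,
                       min_shared = th$min_shared,
                       de_scope = op$de_scope,
                       coexpr_state = op$coexpr_state,
                       paired_differentiation = op$paired_differentiation,
                       escape_required = op$escape_required,
                       mrna_filter_set = op$mrna_filter_set)
  write_run_dir(res, out_dir, config)
  invisible(res)
}

write_run_dir <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "qc"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "de"), showWarnings = FALSE)
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  for (cls in names(res$normalized)) {
    m <- res$normalized[[cls]]
    write_expression_matrix(m, file.path(out_dir,
                                         paste0("normalized_", cls, ".tsv")),
                            digits = 6L)
    note("normalize %s: %d features x %d samples", cls, nrow(m$values),
         ncol(m$values))
  }
  corr <- res$qc$sample_correlation
  write_tsv_plain(data.frame(sample_id = rownames(corr),
                             as.data.frame(corr), check.names = FALSE),
                  file.path(out_dir, "qc", "sample_correlation.tsv"),
                  num_digits = 6L)
  write_dendrogram_newick(res$qc$dendrogram,
                          file.path(out_dir, "qc", "dendrogram.nwk"))
  sc <- res$qc$pca$scores
  write_tsv_plain(data.frame(sample_id = rownames(sc),
                             as.data.frame(sc), check.names = FALSE),
                  file.path(out_dir, "qc", "pca_scores.tsv"),
                  num_digits = 6L)
  note("qc: correlation, dendrogram, pca written")

  for (cls in names(res$de)) {
    for (cn in names(res$de[[cls]])) {
      d <- res$de[[cls]][[cn]]
      write_tsv_plain(as.data.frame(d),
                      file.path(out_dir, "de",
                                sprintf("%s_%s.tsv", cls, cn)),
                      num_digits = 6L)
      write_tsv_plain(volcano_data(d),
                      file.path(out_dir, "de",
                                sprintf("%s_%s_volcano.tsv", cls, cn)),
                      num_digits = 6L)
      note("de %s %s: %d up, %d down", cls, cn,
           sum(d$direction == "up"), sum(d$direction == "down"))
    }
    v <- res$venn[[cls]]
    venn_df <- data.frame(region = names(v$regions),
                          label = unname(v$labels),
                          n = unname(v$counts),
                          features = vapply(v$regions, paste,
                                            character(1L), collapse = ","),
                          stringsAsFactors = FALSE)
    write_tsv_plain(venn_df, file.path(out_dir,
                                       sprintf("venn_%s.tsv", cls)))
    note("venn %s: %d features across 7 regions", cls, sum(v$counts))
  }

  write_tsv_plain(res$coexpression$edges,
                  file.path(out_dir, "coexpression_edges.tsv"),
                  num_digits = 6L)
  write_network(res$coexpression$network,
                file.path(out_dir, "network.sif"), "sif")
  write_network(res$coexpression$network,
                file.path(out_dir, "network.graphml"), "graphml")
  note("coexpression: %d sponges x %d mRNAs tested, %d edges retained",
       length(res$de_lists$sponges), length(res$de_lists$mrnas),
       nrow(res$coexpression$edges))

  write_circuits(res$circuits, file.path(out_dir, "circuits.tsv"))
  write_sankey(res$circuits, file.path(out_dir, "sankey.json"))
  note("circuits: %d assembled", nrow(res$circuits))
  if (!is.null(res$circuits_filtered)) {
    write_circuits(res$circuits_filtered,
                   file.path(out_dir, "circuits_filtered.tsv"))
    note("circuits filtered: %d kept", nrow(res$circuits_filtered))
  }
  if (!is.null(res$enrichment)) {
    write_tsv_plain(res$enrichment, file.path(out_dir, "enrichment.tsv"),
                    num_digits = 6L)
    note("enrichment: %d sets tested", nrow(res$enrichment))
  }

  manifest <- list(schema = "cernet-run/1",
                   thresholds = res$thresholds,
                   options = config$options %||% list())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  con <- file(file.path(out_dir, "log.txt"), open = "wb")
  writeLines(log, con)
  close(con)
  invisible(out_dir)
}

#' End-to-end circuit recovery on synthetic data
#'
#' Generates a bundle, runs the analysis at the given thresholds and
#' scores called circuits against the truth manifest. This is the
#' package's main self-check: with default thresholds it answers "would
#' the pipeline find the planted sponge-mRNA circuits?".
#'
#' @param config a [sim_config()].
#' @param ... thresholds forwarded to [analyze_cerna()].
#' @return list with `score` (from [score_recovery()]), `result` (the
#'   [analyze_cerna()] output) and `dataset`.
#' @export
recover_planted_circuits <- function(config = sim_config(), ...) {
  dataset <- generate_dataset(config)
  res <- analyze_cerna(dataset$expression, dataset$targets,
                       annotation = dataset$annotation,
                       gene_sets = dataset$gene_sets, ...)
  list(score = score_recovery(res$circuits, dataset$truth),
       result = res, dataset = dataset)
}
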