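#' Expression matrix with sample-group metadata
#'
#' The central container of the pipeline: a features x samples intensity
#' matrix plus a sample sheet assigning every sample to a genotype
#' (`WT` = 46,XX wild type, `TS` = 45,X Turner syndrome), a cell state
#' (`iPSC` or `CM`, cardiomyocyte) and a cell-line identifier used for
#' pairing in paired tests.
#'
#' @param values numeric matrix, features in rows, samples in columns, both
#'   dimensions named. All values must be finite; missing values are not
#'   supported and raise an error.
#' @param groups data.frame with columns `sample_id`, `genotype`, `state`,
#'   `line_id` covering every column of `values`.
#' @param scale `"linear"` for intensities or `"log2"`; downstream stages
#'   check this tag rather than guessing.
#'
#' @return An object of class `expression_matrix` with elements `values`,
#'   `groups` (row order matching the columns of `values`) and `scale`.
#' @export
expression_matrix <- function(values, groups,
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  abort_if(!is.matrix(values) || !is.numeric(values),
           "values must be a numeric matrix")
  abort_if(is.null(rownames(values)) || is.null(colnames(values)),
           "values must have feature (row) and sample (column) names")
  check_unique(rownames(values), "feature id")
  check_unique(colnames(values), "sample id")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  abort_if(nrow(bad) > 0L,
           "non-finite value at feature '%s', sample '%s'",
           rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]])
  check_columns(groups, c("sample_id", "genotype", "state", "line_id"),
                "sample sheet")
  check_unique(groups$sample_id, "sample sheet sample_id")
  miss <- setdiff(colnames(values), groups$sample_id)
  abort_if(length(miss) > 0L, "sample(s) without group assignment: %s",
           paste(miss, collapse = ", "))
  bad_geno <- setdiff(unique(groups$genotype), c("WT", "TS"))
  abort_if(length(bad_geno) > 0L, "unknown genotype(s): %s",
           paste(bad_geno, collapse = ", "))
  bad_state <- setdiff(unique(groups$state), c("iPSC", "CM"))
  abort_if(length(bad_state) > 0L, "unknown state(s): %s",
           paste(bad_state, collapse = ", "))
  groups <- groups[match(colnames(values), groups$sample_id),
                   c("sample_id", "genotype", "state", "line_id"),
                   drop = FALSE]
  rownames(groups) <- NULL
  structure(list(values = values, groups = groups, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$groups$genotype, x$groups$state)
  print(tab)
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Select sample ids by group
#'
#' @param m an [expression_matrix()].
#' @param genotype,state optional filters (`"WT"`/`"TS"`, `"iPSC"`/`"CM"`).
#' @return character vector of sample ids in matrix column order.
#' @export
select_samples <- function(m, genotype = NULL, state = NULL) {
  keep <- rep(TRUE, nrow(m$groups))
  if (!is.null(genotype)) keep <- keep & m$groups$genotype %in% genotype
  if (!is.null(state)) keep <- keep & m$groups$state %in% state
  m$groups$sample_id[keep]
}

#' Convert an expression matrix between linear and log2 scales
#'
#' log2 transform uses `log2(x + offset)`; the offset guards small
#' intensities and defaults to 1. The inverse applies `2^x - offset`.
#'
#' @param m an [expression_matrix()].
#' @param scale target scale.
#' @param offset pseudo-intensity added before taking log2.
#' @return an [expression_matrix()] on the requested scale.
#' @export
convert_scale <- function(m, scale = c("linear", "log2"), offset = 1) {
  scale <- match.arg(scale)
  if (m$scale == scale) return(m)
  v <- if (scale == "log2") log2(m$values + offset) else 2^m$values - offset
  expression_matrix(v, m$groups, scale)
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix file holds feature ids in the first column and one named
#' column per sample; the sidecar sample sheet maps `sample_id` to
#' `genotype`, `state` and `line_id`. Ordering of both files is preserved.
#'
#' @param path matrix file (first column feature ids, header row sample ids).
#' @param sample_sheet path to the sample sheet (always tab-delimited).
#' @param dialect `"tsv"` or `"csv"` for the matrix file.
#' @param scale scale tag recorded on the result.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sample_sheet,
                                   dialect = c("tsv", "csv"),
                                   scale = c("linear", "log2")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  sep <- if (dialect == "tsv") "\t" else ","
  abort_if(!file.exists(path), "file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  check_unique(header[-1L], "sample id in header")
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "",
                          colClasses = "character")
  abort_if(ncol(df) < 2L, "matrix file must have at least one sample column")
  check_unique(df[[1L]], "feature id")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  abort_if(nrow(bad) > 0L,
           "non-numeric value '%s' at row %d (feature '%s'), column '%s'",
           vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
           df[[1L]][bad[1L, 1L]], colnames(vals)[bad[1L, 2L]])
  abort_if(anyNA(num), "missing values are not supported (feature '%s')",
           df[[1L]][which(is.na(rowSums(num)))[1L]])
  dimnames(num) <- list(df[[1L]], colnames(vals))
  groups <- read_sample_sheet(sample_sheet)
  expression_matrix(num, groups, scale)
}

#' Read a sample sheet
#'
#' @param path tab-delimited file with columns `sample_id`, `genotype`,
#'   `state`, `line_id`.
#' @return data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_plain(path)
  check_columns(df, c("sample_id", "genotype", "state", "line_id"),
                "sample sheet")
  df$line_id <- as.character(df$line_id)
  df
}

#' Write an expression matrix (and optionally its sample sheet)
#'
#' Values are written at full double precision so that a read-back is
#' value-identical.
#'
#' @param m an [expression_matrix()].
#' @param path output matrix file.
#' @param sample_sheet optional path for the sample sheet.
#' @param dialect `"tsv"` or `"csv"`.
#' @param digits significant digits written (17 round-trips doubles
#'   exactly; use fewer for byte-stable report artifacts).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, sample_sheet = NULL,
                                    dialect = c("tsv", "csv"),
                                    digits = 17L) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(m$values)), collapse = sep), con)
  body <- apply(m$values, 1L, function(r)
    paste(format_num(r, digits), collapse = sep))
  writeLines(paste(rownames(m$values), body, sep = sep), con)
  if (!is.null(sample_sheet)) write_tsv_plain(m$groups, sample_sheet)
  invisible(path)
}

#' Read a feature annotation table
#'
#' Columns: `feature_id`, `rna_class` (mRNA/lncRNA/circRNA), `gene_symbol`,
#' `host_gene` (the hosting gene for lnc/circRNAs, e.g. lnc-KDM5C-4:1 is
#' hosted by KDM5C), `chromosome`, and logical `xci_escape` marking
#' X-inactivation escaping host genes. Escape status is only meaningful on
#' chromosome X; a `TRUE` flag on an autosomal feature is rejected.
#'
#' @param path tab-delimited annotation file.
#' @return validated annotation data.frame.
#' @export
read_feature_annotation <- function(path) {
  df <- read_tsv_plain(path)
  validate_feature_annotation(df)
}

#' Validate a feature annotation table
#'
#' @param df candidate annotation data.frame.
#' @return the validated (type-normalised) data.frame.
#' @export
validate_feature_annotation <- function(df) {
  check_columns(df, c("feature_id", "rna_class", "gene_symbol",
                      "host_gene", "chromosome", "xci_escape"),
                "feature annotation")
  check_unique(df$feature_id, "annotation feature_id")
  bad <- setdiff(unique(df$rna_class), c("mRNA", "lncRNA", "circRNA"))
  abort_if(length(bad) > 0L, "unknown rna_class: %s",
           paste(bad, collapse = ", "))
  if (is.character(df$xci_escape)) {
    df$xci_escape <- df$xci_escape %in% c("TRUE", "true", "1")
  }
  df$xci_escape[is.na(df$xci_escape)] <- FALSE
  off <- df$feature_id[df$xci_escape & df$chromosome != "X"]
  abort_if(length(off) > 0L,
           "xci_escape flagged on non-X feature(s): %s",
           paste(utils::head(off, 5L), collapse = ", "))
  df
}

#' Write a feature annotation table
#' @param df annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_annotation <- function(df, path) {
  write_tsv_plain(validate_feature_annotation(df), path)
}

#' Collapse probe-level rows to one row per gene
#'
#' Microarrays carry several probes per gene; downstream gene-level stages
#' need one row each. The default keeps, per gene, the probe with the
#' highest mean intensity; `method = "mean"` averages all probes instead.
#'
#' @param m an [expression_matrix()].
#' @param gene_map named character vector mapping feature_id to gene symbol.
#' @param method `"max_mean"` (default) or `"mean"`.
#' @return an [expression_matrix()] with one row per gene, rownames the gene
#'   symbols.
#' @export
collapse_probes <- function(m, gene_map, method = c("max_mean", "mean")) {
  method <- match.arg(method)
  ids <- rownames(m$values)
  miss <- setdiff(ids, names(gene_map))
  abort_if(length(miss) > 0L, "feature(s) missing from gene_map: %s",
           paste(utils::head(miss, 5L), collapse = ", "))
  genes <- gene_map[ids]
  if (method == "max_mean") {
    means <- rowMeans(m$values)
    keep <- unlist(lapply(split(seq_along(ids), genes),
                          function(i) i[which.max(means[i])]),
                   use.names = FALSE)
    out <- m$values[keep, , drop = FALSE]
    rownames(out) <- genes[keep]
  } else {
    out <- rowsum(m$values, group = genes) /
      as.vector(table(genes)[sort(unique(genes))])
  }
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_matrix(out, m$groups, m$scale)
}
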