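#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene symbols, all
#' tab-delimited. Members are deduplicated preserving first-occurrence
#' order.
#'
#' @param path GMT file.
#' @return a named list of character vectors (class `gene_set_collection`);
#'   descriptions are kept in the `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty gene set file: ", path, call. = FALSE)
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  abort_if(length(short) > 0L,
           "GMT line %d has fewer than 3 fields", short[1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  gene_set_collection(sets, desc)
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector, one per set.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0L) {
    abort_if(is.null(names(sets)) || any(!nzchar(names(sets))),
             "every gene set needs a name")
    check_unique(names(sets), "gene set name")
    empty <- names(sets)[vapply(sets, length, 1L) == 0L]
    abort_if(length(empty) > 0L, "empty gene set(s): %s",
             paste(empty, collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' Write gene sets to GMT
#'
#' @param sets a `gene_set_collection` (or named list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(sets)) {
    writeLines(paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a miRNA target table
#'
#' Tab-delimited with header `mirna_id`, `target_id`, `site_type`,
#' `position`, `score`, `source` (`position`/`score` may be `NA`, e.g. for
#' interactions imported from external predictors).
#'
#' @param path TSV path.
#' @return validated data.frame (class `target_table`).
#' @export
read_target_table <- function(path) {
  df <- read_tsv_plain(path)
  target_table(df)
}

#' Construct/validate a target table
#'
#' @param df data.frame with at least `mirna_id`, `target_id`, `site_type`,
#'   `source`; `position` and `score` are added as `NA` when absent.
#' @return validated data.frame of class `target_table`.
#' @export
target_table <- function(df) {
  if (is.null(df$position)) df$position <- NA_integer_
  if (is.null(df$score)) df$score <- NA_real_
  # all-NA columns come back logical from delimited files
  df$position <- as.integer(df$position)
  df$score <- as.numeric(df$score)
  check_columns(df, c("mirna_id", "target_id", "site_type", "position",
                      "score", "source"), "target table")
  ok_types <- c("6mer", "7mer-A1", "7mer-m8", "8mer", "imported")
  bad <- setdiff(unique(df$site_type), ok_types)
  abort_if(length(bad) > 0L, "unknown site_type: %s",
           paste(bad, collapse = ", "))
  key <- paste(df$mirna_id, df$target_id, df$position, df$source, sep = "\r")
  check_unique(key, "target table row (mirna, target, position, source)")
  df <- df[, c("mirna_id", "target_id", "site_type", "position", "score",
               "source")]
  rownames(df) <- NULL
  class(df) <- c("target_table", "data.frame")
  df
}

#' Write a target table
#' @param df a `target_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(df, path) {
  write_tsv_plain(as.data.frame(target_table(df)), path, num_digits = 6L)
}
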