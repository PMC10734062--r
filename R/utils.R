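#' @keywords internal
"_PACKAGE"

# Shared validation helpers. All user-facing errors are plain conditions with
# messages that name the offending record, so pipeline aborts are actionable.

abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  abort_if(length(dup) > 0L, "duplicate %s: %s", what,
           paste(utils::head(dup, 5L), collapse = ", "))
  invisible(x)
}

check_choice <- function(x, choices, what) {
  abort_if(!(length(x) == 1L && x %in% choices), "%s must be one of: %s",
           what, paste(choices, collapse = ", "))
  invisible(x)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  abort_if(length(miss) > 0L, "%s is missing column(s): %s", what,
           paste(miss, collapse = ", "))
  invisible(df)
}

# Deterministic numeric formatting for on-disk artifacts.  Full precision
# ("%.17g") round-trips doubles exactly; reporting precision ("%.6g") keeps
# pipeline outputs byte-stable.
format_num <- function(x, digits = 17L) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[is.na(x)] <- "NA"
  out
}

# write.table wrapper with fixed conventions (tab, no quotes, unix newlines)
write_tsv_plain <- function(df, path, num_digits = 17L) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- format_num(df2[[j]], num_digits)
    if (is.logical(df2[[j]])) df2[[j]] <- ifelse(df2[[j]], "TRUE", "FALSE")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df2, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  abort_if(!file.exists(path), "file not found: %s", path)
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    na.strings = "NA")
}
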