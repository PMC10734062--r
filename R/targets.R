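#' Read RNA sequences from FASTA
#'
#' Sequences are upper-cased and DNA `T` is converted to RNA `U`; any other
#' non-ACGU character is a parse error.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_rna_fasta <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  normalize_rna(stats::setNames(as.character(set), names(set)))
}

normalize_rna <- function(seqs) {
  out <- chartr("T", "U", toupper(seqs))
  bad <- grepl("[^ACGU]", out)
  abort_if(any(bad), "non-nucleotide characters in sequence '%s'",
           names(out)[which(bad)[1L]])
  out
}

rc_rna <- function(x) {
  vapply(strsplit(chartr("ACGU", "UGCA", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

#' Predict miRNA target sites by canonical seed match
#'
#' Scans transcripts for Watson-Crick matches to the miRNA seed region
#' (5' nucleotides 2-7/2-8), the site classes used by TargetScan-style
#' predictors:
#' * `8mer` - match to the reverse complement of miRNA nt 2-8 followed by
#'   an `A` opposite miRNA nt 1;
#' * `7mer-m8` - match to the reverse complement of nt 2-8;
#' * `7mer-A1` - match to the reverse complement of nt 2-7 followed by `A`;
#' * `6mer` - match to the reverse complement of nt 2-7.
#'
#' Each transcript window is reported once under the most specific class it
#' satisfies (an 8mer window is not additionally a 7mer). For circRNAs the
#' back-splice junction is handled by scanning the doubled sequence and
#' keeping only sites whose start lies in the first (linear) copy, so
#' junction-spanning sites are found and linear sites are not duplicated.
#' Scores rank the site class (8mer = 4 ... 6mer = 1).
#'
#' @param mirnas named character vector (or FASTA path) of mature miRNA
#'   sequences, 5'->3', length >= 8.
#' @param transcripts named character vector (or FASTA path) of transcript
#'   sequences. `T`/`U` and case are interchangeable.
#' @param site_types which site classes to report.
#' @param circular_ids transcript names to treat as circRNAs.
#' @return a `target_table` with 1-based `position` of each site start.
#' @export
predict_targets_seed <- function(mirnas, transcripts,
                                 site_types = c("8mer", "7mer-m8",
                                                "7mer-A1", "6mer"),
                                 circular_ids = character()) {
  if (is.character(mirnas) && length(mirnas) == 1L && file.exists(mirnas))
    mirnas <- read_rna_fasta(mirnas)
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts))
    transcripts <- read_rna_fasta(transcripts)
  abort_if(is.null(names(mirnas)) || is.null(names(transcripts)),
           "mirnas and transcripts must be named")
  site_types <- match.arg(site_types, several.ok = TRUE)
  mirnas <- normalize_rna(mirnas)
  transcripts <- normalize_rna(transcripts)
  short <- names(mirnas)[nchar(mirnas) < 8L]
  abort_if(length(short) > 0L, "miRNA(s) shorter than 8 nt: %s",
           paste(short, collapse = ", "))
  rows <- list()
  for (mi in names(mirnas)) {
    core6 <- rc_rna(substr(mirnas[[mi]], 2L, 7L))
    m8 <- chartr("ACGU", "UGCA", substr(mirnas[[mi]], 8L, 8L))
    for (tx in names(transcripts)) {
      circ <- tx %in% circular_ids
      s <- transcripts[[tx]]
      len <- nchar(s)
      scan_seq <- if (circ) paste0(s, s) else s
      hits <- gregexpr(core6, scan_seq, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      for (p in as.integer(hits)) {
        has_m8 <- p > 1L && substr(scan_seq, p - 1L, p - 1L) == m8
        has_a1 <- p + 6L <= nchar(scan_seq) &&
          substr(scan_seq, p + 6L, p + 6L) == "A"
        type <- if (has_m8 && has_a1) "8mer"
                else if (has_m8) "7mer-m8"
                else if (has_a1) "7mer-A1"
                else "6mer"
        start <- if (has_m8) p - 1L else p
        if (circ && start > len) next    # duplicate of a first-copy site
        if (!(type %in% site_types)) next
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mi, target_id = tx, site_type = type,
          position = start,
          score = c(`6mer` = 1, `7mer-A1` = 2, `7mer-m8` = 3, `8mer` = 4)[[type]],
          source = "seed_match", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(target_table(data.frame(
      mirna_id = character(), target_id = character(),
      site_type = character(), position = integer(), score = numeric(),
      source = character(), stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  target_table(out[order(out$mirna_id, out$target_id, out$position), ])
}

#' Merge miRNA target tables from several sources
#'
#' `union` keeps every (miRNA, target) pair seen in any table, deduplicated;
#' `intersection` keeps only pairs present in all tables (the conservative
#' default when combining independent predictors). Source provenance is
#' concatenated on the retained row.
#'
#' @param tables list of `target_table` objects (at least one).
#' @param mode `"union"` or `"intersection"`.
#' @return a `target_table` with one row per retained (miRNA, target) pair.
#' @export
merge_target_tables <- function(tables, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  abort_if(length(tables) < 1L, "need at least one target table")
  tables <- lapply(tables, target_table)
  if (length(tables) == 1L) return(tables[[1L]])
  keys <- lapply(tables, function(t)
    unique(paste(t$mirna_id, t$target_id, sep = "\r")))
  keep <- if (mode == "union") Reduce(union, keys) else
    Reduce(intersect, keys)
  all_rows <- do.call(rbind, lapply(tables, as.data.frame))
  key_all <- paste(all_rows$mirna_id, all_rows$target_id, sep = "\r")
  src_by_key <- vapply(split(all_rows$source, key_all), function(s)
    paste(sort(unique(s)), collapse = "+"), character(1L))
  first <- all_rows[match(keep, key_all), , drop = FALSE]
  first$source <- unname(src_by_key[keep])
  first$position <- rep(NA_integer_, nrow(first))
  first <- first[order(first$mirna_id, first$target_id), , drop = FALSE]
  target_table(first)
}

#' miRNAs targeting each feature
#'
#' @param targets a `target_table`.
#' @return named list: for each target feature, the unique miRNAs with at
#'   least one site on it.
#' @export
mirnas_by_target <- function(targets) {
  lapply(split(targets$mirna_id, targets$target_id), unique)
}
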