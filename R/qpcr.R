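#' Relative expression by the 2^-ddCt method
#'
#' Comparative-Ct quantification with a reference (housekeeping) target,
#' e.g. GAPDH for mRNA/lnc/circRNA assays or U6 for miRNA assays:
#' `ddCt = (Ct_target_sample - Ct_ref_sample) -
#'         (Ct_target_calibrator - Ct_ref_calibrator)`
#' and the fold change is `efficiency^-ddCt` (efficiency 2 assumes perfect
#' doubling per cycle; no standard-curve correction is applied).
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample of
#'   interest for the gene of interest and the reference gene.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the
#'   calibrator (control) sample.
#' @param efficiency amplification efficiency per cycle (default 2).
#' @return linear fold change of the target in the sample relative to the
#'   calibrator. Vectorized over its arguments.
#' @export
delta_delta_ct <- function(ct_target_sample, ct_ref_sample,
                           ct_target_calibrator, ct_ref_calibrator,
                           efficiency = 2) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  abort_if(any(!is.finite(cts)), "all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  efficiency^(-ddct)
}

#' Mitochondrial DNA copies per nucleus
#'
#' Comparative qPCR of a mitochondrial amplicon (e.g. 16S rRNA gene)
#' against a single-copy nuclear gene (e.g. GAPDH): assuming equal
#' amplification efficiency, each cycle difference is a factor of
#' `efficiency`, and the nuclear gene is present at
#' `nuclear_copies_per_diploid_genome` copies per nucleus.
#'
#' @param ct_mt Ct of the mitochondrial target.
#' @param ct_nuc Ct of the nuclear single-copy target.
#' @param nuclear_copies_per_diploid_genome copies of the nuclear amplicon
#'   per diploid genome (default 2).
#' @param efficiency amplification efficiency per cycle (default 2).
#' @return estimated mtDNA copies per nucleus. Vectorized.
#' @export
mtdna_copies_per_nucleus <- function(ct_mt, ct_nuc,
                                     nuclear_copies_per_diploid_genome = 2,
                                     efficiency = 2) {
  abort_if(any(!is.finite(c(ct_mt, ct_nuc))), "all Ct values must be finite")
  nuclear_copies_per_diploid_genome * efficiency^(ct_nuc - ct_mt)
}

#' Read a qPCR Ct table
#'
#' Tab-delimited with columns `sample_id`, `assay_id`, `target`
#' (`"goi"` for the gene of interest or `"reference"`), `ct`, `replicate`.
#'
#' @param path TSV path.
#' @return validated data.frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv_plain(path)
  ct_table(df)
}

#' Validate a Ct table
#' @param df data.frame with columns `sample_id`, `assay_id`, `target`,
#'   `ct`, `replicate`.
#' @return the validated data.frame (class `ct_table`).
#' @export
ct_table <- function(df) {
  check_columns(df, c("sample_id", "assay_id", "target", "ct", "replicate"),
                "Ct table")
  bad <- setdiff(unique(df$target), c("goi", "reference"))
  abort_if(length(bad) > 0L, "unknown target label(s): %s",
           paste(bad, collapse = ", "))
  out <- which(!is.finite(df$ct) | df$ct <= 0 | df$ct >= 45)
  abort_if(length(out) > 0L,
           "Ct out of (0, 45) at row %d (sample '%s')",
           out[1L], df$sample_id[out[1L]])
  both <- tapply(df$target, paste(df$sample_id, df$assay_id, sep = "\r"),
                 function(t) all(c("goi", "reference") %in% t))
  abort_if(any(!both), "sample/assay without both goi and reference Ct: %s",
           gsub("\r", " / ", names(both)[!both][1L]))
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Fold changes for every sample/assay in a Ct table
#'
#' Technical replicates are averaged on the Ct scale (geometric-mean
#' behavior on the linear scale) before the ddCt ratio is formed against
#' the calibrator sample.
#'
#' @param ct a `ct_table`.
#' @param calibrator sample_id of the calibrator.
#' @param efficiency amplification efficiency per cycle (default 2).
#' @return data.frame `sample_id`, `assay_id`, `fold`, `log2_fold`.
#' @export
qpcr_fold_changes <- function(ct, calibrator, efficiency = 2) {
  ct <- ct_table(as.data.frame(ct))
  abort_if(!calibrator %in% ct$sample_id, "unknown calibrator '%s'",
           calibrator)
  mean_ct <- stats::aggregate(ct ~ sample_id + assay_id + target,
                              data = as.data.frame(ct), FUN = mean)
  rows <- list()
  for (assay in sort(unique(mean_ct$assay_id))) {
    sub <- mean_ct[mean_ct$assay_id == assay, ]
    get_ct <- function(s, targ) sub$ct[sub$sample_id == s & sub$target == targ]
    for (s in sort(unique(sub$sample_id))) {
      fold <- delta_delta_ct(get_ct(s, "goi"), get_ct(s, "reference"),
                             get_ct(calibrator, "goi"),
                             get_ct(calibrator, "reference"),
                             efficiency = efficiency)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, assay_id = assay, fold = fold,
        log2_fold = log2(fold), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
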