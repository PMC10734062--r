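#' Per-feature linear fold change between two sample groups
#'
#' Fold change is the ratio of group mean intensities on the linear scale
#' (`mean(groupA) / mean(groupB)`), matching the `|FC (linear)| >= 2` /
#' `<= 0.5` calling convention. A log2 matrix is anti-logged first.
#'
#' @param m an [expression_matrix()].
#' @param group_a,group_b disjoint, non-empty character vectors of sample
#'   ids; `group_a` is the numerator.
#' @return named numeric vector of fold changes, one per feature.
#' @export
fold_change <- function(m, group_a, group_b) {
  check_groups(m, group_a, group_b)
  lin <- convert_scale(m, "linear")$values
  num <- rowMeans(lin[, group_a, drop = FALSE])
  den <- rowMeans(lin[, group_b, drop = FALSE])
  zero <- which(den == 0)
  abort_if(length(zero) > 0L,
           "zero denominator mean for feature '%s'",
           rownames(lin)[zero[1L]])
  num / den
}

check_groups <- function(m, group_a, group_b) {
  abort_if(length(group_a) == 0L || length(group_b) == 0L,
           "both groups must be non-empty")
  overlap <- intersect(group_a, group_b)
  abort_if(length(overlap) > 0L, "groups overlap in sample(s): %s",
           paste(overlap, collapse = ", "))
  miss <- setdiff(c(group_a, group_b), colnames(m$values))
  abort_if(length(miss) > 0L, "unknown sample(s): %s",
           paste(miss, collapse = ", "))
  invisible(NULL)
}

#' Two-tailed Student t-test per feature
#'
#' Testing is done on the log2 scale (a linear matrix is converted first).
#' Paired tests pair samples by `line_id` and use `df = n - 1` on the
#' within-line differences; unpaired tests use the Welch statistic.
#' Degenerate features are guarded: when a feature has no variance at all,
#' `p = 1` if the group difference is exactly zero and the smallest
#' representable double otherwise.
#'
#' @param m an [expression_matrix()].
#' @param group_a,group_b disjoint sample-id vectors, each of size >= 2.
#' @param paired pair by cell line (`line_id`); requires the two groups to
#'   cover the same multiset of lines.
#' @return named numeric vector of two-tailed p-values, one per feature.
#' @export
de_test <- function(m, group_a, group_b, paired = FALSE) {
  check_groups(m, group_a, group_b)
  abort_if(length(group_a) < 2L || length(group_b) < 2L,
           "each group needs at least 2 samples")
  v <- convert_scale(m, "log2")$values
  p_min <- .Machine$double.xmin
  if (paired) {
    la <- m$groups$line_id[match(group_a, m$groups$sample_id)]
    lb <- m$groups$line_id[match(group_b, m$groups$sample_id)]
    abort_if(length(group_a) != length(group_b) ||
               !identical(sort(la), sort(lb)),
             "paired test requires the same lines in both groups")
    a <- v[, group_a[order(la)], drop = FALSE]
    b <- v[, group_b[order(lb)], drop = FALSE]
    d <- a - b
    n <- ncol(d)
    md <- rowMeans(d)
    sdd <- sqrt(rowSums((d - md)^2) / (n - 1L))
    p <- rep(NA_real_, nrow(v))
    degen <- sdd == 0
    p[degen & md == 0] <- 1
    p[degen & md != 0] <- p_min
    ok <- !degen
    tstat <- md[ok] / (sdd[ok] / sqrt(n))
    p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  } else {
    a <- v[, group_a, drop = FALSE]
    b <- v[, group_b, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2) / (na - 1L)
    vb <- rowSums((b - mb)^2) / (nb - 1L)
    p <- rep(NA_real_, nrow(v))
    degen <- va == 0 & vb == 0
    p[degen & (ma == mb)] <- 1
    p[degen & (ma != mb)] <- p_min
    ok <- !degen
    se2 <- va[ok] / na + vb[ok] / nb
    tstat <- (ma[ok] - mb[ok]) / sqrt(se2)
    df <- se2^2 / ((va[ok] / na)^2 / (na - 1L) + (vb[ok] / nb)^2 / (nb - 1L))
    p[ok] <- 2 * stats::pt(-abs(tstat), df = df)
  }
  stats::setNames(p, rownames(v))
}

#' Call differential expression from fold change and p-value
#'
#' A feature is called `up` when `FC >= fc_hi` and `p < alpha`, `down` when
#' `FC <= fc_lo` and `p < alpha`, otherwise `none`. Fold-change thresholds
#' are inclusive, the p threshold strict.
#'
#' @param fc named linear fold changes from [fold_change()].
#' @param p named p-values from [de_test()] over the same features.
#' @param fc_hi,fc_lo,alpha calling thresholds (defaults 2, 0.5, 0.05).
#' @param contrast optional label stored on the result.
#' @return a `de_result` data.frame: `feature_id`, `fc`, `p_value`,
#'   `direction`.
#' @export
call_de <- function(fc, p, fc_hi = 2, fc_lo = 0.5, alpha = 0.05,
                    contrast = NA_character_) {
  abort_if(length(fc) != length(p) || !identical(names(fc), names(p)),
           "fc and p must be aligned over the same features")
  abort_if(any(fc <= 0), "fold changes must be positive")
  direction <- rep("none", length(fc))
  direction[fc >= fc_hi & p < alpha] <- "up"
  direction[fc <= fc_lo & p < alpha] <- "down"
  out <- data.frame(feature_id = names(fc), fc = unname(fc),
                    p_value = unname(p), direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", "data.frame")
  out
}

#' Run one differential-expression contrast
#'
#' Convenience wrapper: fold change on linear intensities, t-test on log2,
#' then threshold calling.
#'
#' @inheritParams de_test
#' @inheritParams call_de
#' @return a `de_result` data.frame.
#' @export
run_contrast <- function(m, group_a, group_b, paired = FALSE,
                         fc_hi = 2, fc_lo = 0.5, alpha = 0.05,
                         contrast = NA_character_) {
  fc <- fold_change(m, group_a, group_b)
  p <- de_test(m, group_a, group_b, paired = paired)
  call_de(fc, p, fc_hi = fc_hi, fc_lo = fc_lo, alpha = alpha,
          contrast = contrast)
}

#' Features called differentially expressed
#' @param de a `de_result`.
#' @param direction `"any"`, `"up"` or `"down"`.
#' @return character vector of feature ids.
#' @export
de_features <- function(de, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "any") de$direction != "none"
          else de$direction == direction
  de$feature_id[keep]
}

#' Seven-region partition of three DE sets
#'
#' Partitions the union of three DE calls (typically A = WT differentiation,
#' B = TS differentiation, C = TS-CM vs WT-CM) into the seven disjoint
#' regions of a three-set Venn diagram. Region names record exact
#' membership (`"AB"` = in A and B but not C). The mapping of regions to
#' display labels Set1..Set7 is configurable because the biological
#' semantics of each region depend on the contrast choice.
#'
#' @param de_a,de_b,de_c `de_result` objects over the same feature universe
#'   (or plain character vectors of called features, in which case the
#'   universe check is skipped).
#' @param labels named character vector mapping region names
#'   (`A,B,C,AB,AC,BC,ABC`) to display labels; the default assigns
#'   Set1..Set7 in lexicographic region order.
#' @return list with `regions` (named list of feature-id vectors), `labels`
#'   and `counts`.
#' @export
venn_partition <- function(de_a, de_b, de_c, labels = NULL) {
  grab <- function(x) if (inherits(x, "de_result")) de_features(x) else x
  universe_of <- function(x) if (inherits(x, "de_result")) x$feature_id else
    NULL
  ua <- universe_of(de_a); ub <- universe_of(de_b); uc <- universe_of(de_c)
  if (!is.null(ua) && !is.null(ub) && !is.null(uc)) {
    abort_if(!identical(sort(ua), sort(ub)) || !identical(sort(ua), sort(uc)),
             "DE results cover different feature universes")
  }
  a <- grab(de_a); b <- grab(de_b); c_ <- grab(de_c)
  all_feat <- union(union(a, b), c_)
  code <- paste0(ifelse(all_feat %in% a, "A", ""),
                 ifelse(all_feat %in% b, "B", ""),
                 ifelse(all_feat %in% c_, "C", ""))
  region_names <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  regions <- lapply(region_names, function(rn) sort(all_feat[code == rn]))
  names(regions) <- region_names
  default_labels <- stats::setNames(paste0("Set", seq_len(7L)),
                                    sort(region_names))
  if (is.null(labels)) {
    labels <- default_labels[region_names]
  } else {
    miss <- setdiff(region_names, names(labels))
    abort_if(length(miss) > 0L, "label map missing region(s): %s",
             paste(miss, collapse = ", "))
    labels <- labels[region_names]
  }
  list(regions = regions, labels = labels,
       counts = vapply(regions, length, 1L))
}

#' Volcano-plot data for a contrast
#'
#' @param de a `de_result`.
#' @return data.frame with `feature_id`, `log2_fc`, `neg_log10_p`,
#'   `direction`, ready for plotting or TSV export.
#' @export
volcano_data <- function(de) {
  data.frame(feature_id = de$feature_id,
             log2_fc = log2(de$fc),
             neg_log10_p = -log10(pmax(de$p_value, .Machine$double.xmin)),
             direction = de$direction,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values for a DE result
#'
#' Off by default in the calling path (raw p < alpha mirrors common
#' microarray practice); use this to add a `q_value` column when control of
#' the false discovery rate is wanted.
#'
#' @param de a `de_result`.
#' @return the `de_result` with a `q_value` column appended.
#' @export
add_bh_qvalues <- function(de) {
  de$q_value <- stats::p.adjust(de$p_value, method = "BH")
  de
}
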