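#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both non-constant.
#' @return the Pearson product-moment correlation.
#' @export
pcc <- function(x, y) {
  abort_if(length(x) != length(y), "x and y must have equal length")
  abort_if(length(x) < 3L, "need at least 3 observations")
  abort_if(stats::sd(x) == 0 || stats::sd(y) == 0,
           "constant vector: correlation undefined")
  stats::cor(x, y)
}

#' Two-tailed p-value for a Pearson correlation
#'
#' Uses the exact null distribution of
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' At `|r| = 1` the statistic degenerates; the smallest representable
#' double is returned with a warning.
#'
#' @param r correlation in `[-1, 1]`.
#' @param n number of paired observations, `n >= 3`.
#' @return two-tailed p-value.
#' @export
pcc_pvalue <- function(r, n) {
  abort_if(any(abs(r) > 1, na.rm = TRUE), "r out of [-1, 1]")
  abort_if(any(n < 3L), "need n >= 3")
  p <- rep(NA_real_, length(r))
  sat <- !is.na(r) & abs(r) == 1
  if (any(sat)) {
    warning("|r| = 1: returning smallest representable p", call. = FALSE)
    p[sat] <- .Machine$double.xmin
  }
  ok <- !is.na(r) & !sat
  tstat <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

#' Build a sponge-mRNA co-expression network
#'
#' Tests every DE lnc/circRNA (sponge candidate) against every DE mRNA by
#' Pearson correlation of log2 expression over the samples of a contrast,
#' retaining pairs with `r > r_min` and `p < alpha`. The default threshold
#' is signed (positive co-expression only), matching ceRNA logic where a
#' sponge and the target it de-represses move together; set
#' `absolute = TRUE` to threshold on `|r|`. `method = "spearman"` is
#' available for rank-based networks.
#'
#' @param m an [expression_matrix()] (converted to log2 internally).
#' @param de_sponges,de_mrnas character vectors of DE feature ids present
#'   in `m`.
#' @param samples sample ids over which correlations are computed
#'   (at least 4).
#' @param r_min correlation threshold, exceeded strictly (default 0.2).
#' @param alpha p-value threshold, strict (default 0.05).
#' @param contrast label recorded on each edge.
#' @param absolute threshold on `|r|` instead of signed `r`.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `edges` (data.frame `sponge_id`, `mrna_id`, `pcc`,
#'   `p_value`, `contrast`, `n_samples`) and `network` (an [rna_network()]).
#' @export
build_coexpression_network <- function(m, de_sponges, de_mrnas, samples,
                                       r_min = 0.2, alpha = 0.05,
                                       contrast = NA_character_,
                                       absolute = FALSE,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  abort_if(length(samples) < 4L, "need at least 4 samples")
  miss <- setdiff(samples, colnames(m$values))
  abort_if(length(miss) > 0L, "unknown sample(s): %s",
           paste(miss, collapse = ", "))
  missf <- setdiff(c(de_sponges, de_mrnas), rownames(m$values))
  abort_if(length(missf) > 0L, "feature(s) not in matrix: %s",
           paste(utils::head(missf, 5L), collapse = ", "))
  empty_edges <- data.frame(sponge_id = character(), mrna_id = character(),
                            pcc = numeric(), p_value = numeric(),
                            contrast = character(), n_samples = integer(),
                            stringsAsFactors = FALSE)
  if (length(de_sponges) == 0L || length(de_mrnas) == 0L) {
    warning("empty DE list: returning empty co-expression network",
            call. = FALSE)
    return(list(edges = empty_edges,
                network = coexpression_network(empty_edges)))
  }
  v <- convert_scale(m, "log2")$values[, samples, drop = FALSE]
  xs <- t(v[de_sponges, , drop = FALSE])
  xm <- t(v[de_mrnas, , drop = FALSE])
  # features constant over `samples` (possible after quantile ties) have no
  # defined correlation: they produce NA entries and contribute no edges
  r <- withCallingHandlers(
    stats::cor(xs, xm, method = method),
    warning = function(w) {
      if (grepl("standard deviation is zero", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  r <- pmin(pmax(r, -1), 1)
  n <- length(samples)
  p <- matrix(pcc_pvalue(as.vector(r), n), nrow = nrow(r))
  pass <- if (absolute) abs(r) > r_min & p < alpha else r > r_min & p < alpha
  idx <- which(pass, arr.ind = TRUE)
  edges <- empty_edges
  if (nrow(idx) > 0L) {
    edges <- data.frame(sponge_id = de_sponges[idx[, 1L]],
                        mrna_id = de_mrnas[idx[, 2L]],
                        pcc = r[idx], p_value = p[idx],
                        contrast = contrast, n_samples = n,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$sponge_id, edges$mrna_id), , drop = FALSE]
    rownames(edges) <- NULL
  }
  list(edges = edges, network = coexpression_network(edges))
}

coexpression_network <- function(edges, annotation = NULL) {
  ids <- unique(c(edges$sponge_id, edges$mrna_id))
  cls <- rep(NA_character_, length(ids))
  if (!is.null(annotation)) {
    cls <- annotation$rna_class[match(ids, annotation$feature_id)]
  } else if (length(ids) > 0L) {
    cls <- ifelse(ids %in% edges$mrna_id, "mRNA", "ncRNA")
  }
  nodes <- data.frame(id = ids, rna_class = cls,
                      de_direction = rep(NA_character_, length(ids)),
                      stringsAsFactors = FALSE)
  e <- data.frame(from = edges$sponge_id, to = edges$mrna_id,
                  pcc = edges$pcc, p_value = edges$p_value,
                  edge_kind = rep("coexpression", nrow(edges)),
                  stringsAsFactors = FALSE)
  rna_network(nodes, e)
}
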