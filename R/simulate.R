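#' Configuration for the synthetic study generator
#'
#' Describes a two-genotype (WT 46,XX vs TS 45,X) by two-state (iPSC vs
#' cardiomyocyte) design with `n_lines` cell lines per genotype, one sample
#' per line and state. The generator plants three kinds of structure on
#' the log2 scale:
#' * differentiation: a fraction of features in every RNA class shift by a
#'   signed log2 effect in CM samples;
#' * X dosage: features whose host escapes X inactivation are multiplied
#'   by `ts_dosage_factor` (default 0.5, the two-active-copies-to-one
#'   haploinsufficiency ratio) in TS samples;
#' * ceRNA circuits: each planted circuit couples one autosomal mRNA to an
#'   X-escape, differentiation-regulated sponge lnc/circRNA with slope
#'   `beta`, and registers the sponge and mRNA as targets of the same
#'   miRNA(s) in the emitted target table, alongside uniformly sampled
#'   decoy interactions.
#'
#' @param n_lines cell lines per genotype (default 3, one sample per line
#'   and state).
#' @param n_mrna,n_lncrna,n_circrna features per RNA class.
#' @param cm_fraction fraction of features per class given a
#'   differentiation effect.
#' @param state_effect_mean,state_effect_sd log2 differentiation effect
#'   magnitude distribution (sign random per feature).
#' @param ts_dosage_factor linear dosage multiplier of X-escape features in
#'   TS samples, in (0, 1].
#' @param n_escape_extra X-escape features beyond the planted sponges.
#' @param n_circuits planted ceRNA circuits.
#' @param mirnas_per_circuit shared miRNAs per planted circuit.
#' @param n_mirnas size of the miRNA universe.
#' @param decoy_ratio decoy:truth ratio of miRNA-target interactions.
#' @param beta target log2 slope on sponge log2 deviation, in [0, 2].
#' @param sigma residual noise sd on the log2 scale.
#' @param line_sd sd of the per-line random intercept (gives paired tests
#'   something to pair on).
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution.
#' @param seed RNG seed; identical seed and config give a byte-identical
#'   bundle.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 3L,
                       n_mrna = 2000L, n_lncrna = 800L, n_circrna = 400L,
                       cm_fraction = 0.1,
                       state_effect_mean = 2.0, state_effect_sd = 0.5,
                       ts_dosage_factor = 0.5,
                       n_escape_extra = 40L,
                       n_circuits = 10L,
                       mirnas_per_circuit = 2L,
                       n_mirnas = 1000L,
                       decoy_ratio = 5,
                       beta = 0.9,
                       sigma = 0.3,
                       line_sd = 0.1,
                       baseline_mean = 8, baseline_sd = 1.5,
                       seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), n_mrna = as.integer(n_mrna),
              n_lncrna = as.integer(n_lncrna),
              n_circrna = as.integer(n_circrna),
              cm_fraction = cm_fraction,
              state_effect_mean = state_effect_mean,
              state_effect_sd = state_effect_sd,
              ts_dosage_factor = ts_dosage_factor,
              n_escape_extra = as.integer(n_escape_extra),
              n_circuits = as.integer(n_circuits),
              mirnas_per_circuit = as.integer(mirnas_per_circuit),
              n_mirnas = as.integer(n_mirnas),
              decoy_ratio = decoy_ratio,
              beta = beta, sigma = sigma, line_sd = line_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  with(cfg, {
    abort_if(any(c(n_lines, n_mrna, n_lncrna, n_circrna, n_mirnas) < 1L),
             "all counts must be positive")
    abort_if(ts_dosage_factor <= 0 || ts_dosage_factor > 1,
             "ts_dosage_factor must lie in (0, 1]")
    abort_if(sigma < 0 || line_sd < 0, "noise sds must be >= 0")
    abort_if(beta < 0 || beta > 2, "beta must lie in [0, 2]")
    abort_if(cm_fraction < 0 || cm_fraction > 1,
             "cm_fraction must lie in [0, 1]")
    abort_if(n_circuits > min(n_lncrna + n_circrna, n_mrna),
             "n_circuits (%d) exceeds available sponge or mRNA features",
             n_circuits)
    abort_if(n_circuits * mirnas_per_circuit > n_mirnas,
             "not enough miRNAs for %d circuits", n_circuits)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic study bundle with known truth
#'
#' See [sim_config()] for the generative model. Planted circuit sponges
#' are made both differentiation-regulated and X-escape, so they are
#' differentially expressed in the differentiation contrasts and
#' dose-reduced in TS; their target mRNAs carry no direct effect of their
#' own - all of their group structure is inherited through the `beta`
#' coupling, exactly the signal a ceRNA analysis is supposed to pick up.
#'
#' @param config a [sim_config()].
#' @return list with elements `expression` (named list of
#'   [expression_matrix()] per RNA class, linear scale), `annotation`
#'   (feature annotation data.frame), `targets` (`target_table` of planted
#'   plus decoy interactions), `gene_sets` (a `gene_set_collection` whose
#'   `PLANTED_TARGETS` set holds the circuit mRNA symbols), and `truth`
#'   (planted DE effects, circuits and escape features).
#' @export
generate_dataset <- function(config = sim_config()) {
  abort_if(!inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n_lines <- config$n_lines

  # ---- features and annotation -------------------------------------------
  mrna_ids <- sprintf("mRNA_%04d", seq_len(config$n_mrna))
  lnc_ids <- sprintf("lnc-LHOST%04d-1:1", seq_len(config$n_lncrna))
  circ_ids <- sprintf("hsa_circ_9%05d", seq_len(config$n_circrna))
  ids <- c(mrna_ids, lnc_ids, circ_ids)
  classes <- rep(c("mRNA", "lncRNA", "circRNA"),
                 c(config$n_mrna, config$n_lncrna, config$n_circrna))
  symbols <- c(sprintf("GENE%04d", seq_len(config$n_mrna)), lnc_ids,
               circ_ids)
  hosts <- c(sprintf("GENE%04d", seq_len(config$n_mrna)),
             sprintf("LHOST%04d", seq_len(config$n_lncrna)),
             sprintf("CHOST%04d", seq_len(config$n_circrna)))
  chrom <- sample(as.character(1:22), length(ids), replace = TRUE)

  # differentiation-regulated features per class
  pick_cm <- function(class_ids) {
    k <- floor(config$cm_fraction * length(class_ids))
    sort(sample(class_ids, k))
  }
  cm_set <- c(pick_cm(mrna_ids), pick_cm(lnc_ids), pick_cm(circ_ids))

  # planted circuits: sponges from lnc/circ, targets from unregulated mRNAs
  sponge_pool <- c(lnc_ids, circ_ids)
  sponges <- if (config$n_circuits > 0L)
    sort(sample(sponge_pool, config$n_circuits)) else character()
  target_pool <- setdiff(mrna_ids, cm_set)
  abort_if(length(target_pool) < config$n_circuits,
           "not enough unregulated mRNAs for %d circuit targets",
           config$n_circuits)
  targets_mrna <- if (config$n_circuits > 0L)
    sort(sample(target_pool, config$n_circuits)) else character()
  cm_set <- sort(union(cm_set, sponges))

  # escape features: all sponges plus extras drawn from the rest
  extra_pool <- setdiff(ids, c(sponges, targets_mrna))
  escape <- sort(c(sponges,
                   sample(extra_pool, min(config$n_escape_extra,
                                          length(extra_pool)))))
  chrom[ids %in% escape] <- "X"

  annotation <- data.frame(feature_id = ids, rna_class = classes,
                           gene_symbol = symbols, host_gene = hosts,
                           chromosome = chrom,
                           xci_escape = ids %in% escape,
                           stringsAsFactors = FALSE)

  # ---- samples ------------------------------------------------------------
  groups <- expand.grid(line = seq_len(n_lines), state = c("iPSC", "CM"),
                        genotype = c("WT", "TS"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  groups <- data.frame(
    sample_id = sprintf("%s_%s_L%02d", groups$genotype, groups$state,
                        groups$line),
    genotype = groups$genotype, state = groups$state,
    line_id = sprintf("%s_L%02d", groups$genotype, groups$line),
    stringsAsFactors = FALSE)
  is_cm <- groups$state == "CM"
  is_ts <- groups$genotype == "TS"
  lines <- unique(groups$line_id)

  # ---- log2 expression ----------------------------------------------------
  nf <- length(ids); ns <- nrow(groups)
  baseline <- stats::rnorm(nf, config$baseline_mean, config$baseline_sd)
  effect <- stats::setNames(rep(0, nf), ids)
  eff_draw <- sample(c(-1, 1), length(cm_set), replace = TRUE) *
    stats::rnorm(length(cm_set), config$state_effect_mean,
                 config$state_effect_sd)
  effect[cm_set] <- eff_draw
  u_line <- matrix(stats::rnorm(nf * length(lines), 0, config$line_sd),
                   nrow = nf, dimnames = list(ids, lines))
  eps <- matrix(stats::rnorm(nf * ns, 0, config$sigma), nrow = nf,
                dimnames = list(ids, groups$sample_id))
  x <- baseline +
    outer(effect, as.numeric(is_cm)) +
    outer(as.numeric(ids %in% escape) * log2(config$ts_dosage_factor),
          as.numeric(is_ts)) +
    u_line[, groups$line_id, drop = FALSE] + eps
  dimnames(x) <- list(ids, groups$sample_id)

  # overwrite circuit targets: all group structure flows through the sponge
  for (i in seq_along(sponges)) {
    s <- x[sponges[i], ]
    x[targets_mrna[i], ] <- baseline[match(targets_mrna[i], ids)] +
      config$beta * (s - mean(s)) +
      u_line[targets_mrna[i], groups$line_id] + eps[targets_mrna[i], ]
  }

  # ---- miRNA target table -------------------------------------------------
  mirna_pool <- sprintf("sim-miR-%04d", seq_len(config$n_mirnas))
  circuit_mirnas <- if (config$n_circuits > 0L)
    split(sample(mirna_pool, config$n_circuits * config$mirnas_per_circuit),
          rep(seq_len(config$n_circuits), each = config$mirnas_per_circuit))
  else list()
  truth_rows <- do.call(rbind, lapply(seq_along(sponges), function(i) {
    mirs <- sort(circuit_mirnas[[i]])
    data.frame(mirna_id = rep(mirs, 2L),
               target_id = rep(c(sponges[i], targets_mrna[i]),
                               each = length(mirs)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth_rows))
    truth_rows <- data.frame(mirna_id = character(),
                             target_id = character(),
                             stringsAsFactors = FALSE)
  n_decoy <- round(config$decoy_ratio * nrow(truth_rows))
  decoys <- data.frame(mirna_id = sample(mirna_pool, n_decoy,
                                         replace = TRUE),
                       target_id = sample(ids, n_decoy, replace = TRUE),
                       stringsAsFactors = FALSE)
  tt <- rbind(cbind(truth_rows,
                    source = rep("simulated_truth", nrow(truth_rows)),
                    stringsAsFactors = FALSE),
              cbind(decoys, source = rep("simulated_decoy", nrow(decoys)),
                    stringsAsFactors = FALSE))
  tt <- tt[!duplicated(paste(tt$mirna_id, tt$target_id, sep = "\r")), ,
           drop = FALSE]
  tt$site_type <- rep("imported", nrow(tt))
  tt$position <- rep(NA_integer_, nrow(tt))
  tt$score <- rep(NA_real_, nrow(tt))
  tt <- tt[order(tt$mirna_id, tt$target_id), ]
  targets <- target_table(tt)

  # ---- truth manifest and outputs -----------------------------------------
  de_truth <- rbind(
    data.frame(feature_id = cm_set,
               contrast = rep("CM_vs_iPSC", length(cm_set)),
               log2_effect = unname(effect[cm_set]),
               stringsAsFactors = FALSE),
    data.frame(feature_id = escape,
               contrast = rep("TS_vs_WT", length(escape)),
               log2_effect = rep(log2(config$ts_dosage_factor),
                                 length(escape)),
               stringsAsFactors = FALSE))
  circuits_truth <- data.frame(
    sponge_id = sponges,
    mirna_ids = vapply(circuit_mirnas, function(m)
      paste(sort(m), collapse = ","), character(1L)),
    mrna_id = targets_mrna,
    beta = rep(config$beta, length(sponges)),
    stringsAsFactors = FALSE)
  target_symbols <- annotation$gene_symbol[match(targets_mrna,
                                                 annotation$feature_id)]
  other_symbols <- setdiff(annotation$gene_symbol[annotation$rna_class ==
                                                    "mRNA"],
                           target_symbols)
  gs <- list()
  if (length(target_symbols) > 0L) gs$PLANTED_TARGETS <- target_symbols
  gs$RANDOM_SET_A <- sort(sample(other_symbols,
                                 min(25L, length(other_symbols))))
  gs$RANDOM_SET_B <- sort(sample(other_symbols,
                                 min(40L, length(other_symbols))))
  make_em <- function(class_ids) {
    expression_matrix(2^x[class_ids, , drop = FALSE], groups, "linear")
  }
  list(expression = list(mRNA = make_em(mrna_ids),
                         lncRNA = make_em(lnc_ids),
                         circRNA = make_em(circ_ids)),
       annotation = annotation,
       targets = targets,
       gene_sets = gene_set_collection(gs),
       truth = list(de = de_truth, circuits = circuits_truth,
                    escape = escape),
       config = config)
}

#' Write a synthetic bundle to disk in pipeline input formats
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cls in names(dataset$expression)) {
    write_expression_matrix(dataset$expression[[cls]],
                            file.path(dir, paste0(cls, "_expression.tsv")))
  }
  write_tsv_plain(dataset$expression[[1L]]$groups,
                  file.path(dir, "sample_sheet.tsv"))
  write_feature_annotation(dataset$annotation,
                           file.path(dir, "feature_annotation.tsv"))
  write_target_table(dataset$targets, file.path(dir, "targets.tsv"))
  write_gene_sets(dataset$gene_sets, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Sensitivity and false-discovery proportion of circuit recovery
#'
#' Circuits match on the (sponge, mRNA) pair; the shared miRNA set is not
#' compared.
#'
#' @param called a `cerna_circuits` data.frame (or any data.frame with
#'   `sponge_id` and `mrna_id` columns).
#' @param truth the `truth` element of [generate_dataset()] output (or its
#'   `circuits` data.frame).
#' @return list with `sensitivity`, `fdp`, `n_called`, `n_planted`.
#' @export
score_recovery <- function(called, truth) {
  abort_if(is.null(called) || is.null(truth),
           "called and truth must be non-null")
  planted <- if (!is.null(truth$circuits)) truth$circuits else truth
  key <- function(df) unique(paste(df$sponge_id, df$mrna_id, sep = "\r"))
  called_keys <- if (nrow(called) > 0L) key(called) else character()
  planted_keys <- key(planted)
  hits <- intersect(called_keys, planted_keys)
  list(sensitivity = length(hits) / length(planted_keys),
       fdp = length(setdiff(called_keys, planted_keys)) /
         max(length(called_keys), 1L),
       n_called = length(called_keys),
       n_planted = length(planted_keys))
}
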