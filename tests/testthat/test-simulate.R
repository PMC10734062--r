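small_cfg <- function(...) {
  sim_config(n_mrna = 200L, n_lncrna = 60L, n_circrna = 30L,
             n_mirnas = 100L, n_escape_extra = 8L, n_circuits = 4L, ...)
}

test_that("generation is deterministic in the seed", {
  a <- generate_dataset(small_cfg(seed = 5L))
  b <- generate_dataset(small_cfg(seed = 5L))
  expect_identical(a$expression$mRNA$values, b$expression$mRNA$values)
  expect_identical(as.data.frame(a$targets), as.data.frame(b$targets))
  expect_identical(a$truth, b$truth)
  c2 <- generate_dataset(small_cfg(seed = 6L))
  expect_false(identical(a$expression$mRNA$values,
                         c2$expression$mRNA$values))
})

test_that("the bundle has the configured shape and consistent annotation", {
  ds <- generate_dataset(small_cfg(seed = 5L))
  expect_identical(dim(ds$expression$mRNA$values), c(200L, 12L))
  expect_identical(dim(ds$expression$lncRNA$values), c(60L, 12L))
  expect_identical(dim(ds$expression$circRNA$values), c(30L, 12L))
  expect_identical(ds$expression$mRNA$scale, "linear")
  expect_true(all(ds$expression$mRNA$values > 0))
  # annotation covers every feature exactly once and passes validation
  ids <- unlist(lapply(ds$expression, function(m) rownames(m$values)))
  expect_setequal(ds$annotation$feature_id, ids)
  expect_silent(validate_feature_annotation(ds$annotation))
  # planted sponges are X-escape, differentiation-regulated non-mRNAs
  cls <- ds$annotation$rna_class[match(ds$truth$circuits$sponge_id,
                                       ds$annotation$feature_id)]
  expect_true(all(cls %in% c("lncRNA", "circRNA")))
  expect_true(all(ds$truth$circuits$sponge_id %in% ds$truth$escape))
  de_cm <- ds$truth$de$feature_id[ds$truth$de$contrast == "CM_vs_iPSC"]
  expect_true(all(ds$truth$circuits$sponge_id %in% de_cm))
  # circuit mRNAs carry no direct planted effect of their own
  expect_false(any(ds$truth$circuits$mrna_id %in% ds$truth$de$feature_id))
  # truth interactions are a subset of the emitted target table
  key <- paste(ds$targets$mirna_id, ds$targets$target_id)
  for (i in seq_len(nrow(ds$truth$circuits))) {
    mirs <- strsplit(ds$truth$circuits$mirna_ids[i], ",")[[1]]
    expect_identical(length(mirs), 2L)
    expect_true(all(paste(mirs, ds$truth$circuits$sponge_id[i]) %in% key))
    expect_true(all(paste(mirs, ds$truth$circuits$mrna_id[i]) %in% key))
  }
  # decoys dominate the table roughly decoy_ratio : 1 (before dedup)
  expect_gt(sum(ds$targets$source == "simulated_decoy"),
            3 * sum(ds$targets$source == "simulated_truth") / 2)
})

test_that("noise-free data shows the exact planted effects", {
  ds <- generate_dataset(small_cfg(seed = 9L, sigma = 0, line_sd = 0))
  all_log2 <- log2(do.call(rbind, lapply(ds$expression,
                                         function(m) m$values)))
  groups <- ds$expression$mRNA$groups
  wt_ipsc <- groups$sample_id[groups$genotype == "WT" &
                                groups$state == "iPSC"]
  ts_ipsc <- groups$sample_id[groups$genotype == "TS" &
                                groups$state == "iPSC"]
  # escape features sit at exactly half dose in TS (outside CM effects)
  esc <- setdiff(ds$truth$escape, ds$truth$circuits$sponge_id)
  expect_equal(unname(all_log2[esc, ts_ipsc[1]] - all_log2[esc, wt_ipsc[1]]),
               rep(log2(0.5), length(esc)), tolerance = 1e-10)
  # non-escape, non-regulated, non-target features are flat everywhere
  quiet <- setdiff(rownames(all_log2),
                   c(ds$truth$escape, ds$truth$de$feature_id,
                     ds$truth$circuits$mrna_id))
  expect_lt(max(apply(all_log2[quiet, ], 1, function(r) diff(range(r)))),
            1e-10)
  # sponge and its target correlate perfectly on the log2 scale
  for (i in seq_len(nrow(ds$truth$circuits))) {
    expect_equal(cor(all_log2[ds$truth$circuits$sponge_id[i], ],
                     all_log2[ds$truth$circuits$mrna_id[i], ]), 1,
                 tolerance = 1e-10)
  }
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(ts_dosage_factor = 0), "\\(0, 1\\]")
  expect_error(sim_config(ts_dosage_factor = 1.2), "\\(0, 1\\]")
  expect_error(sim_config(beta = 2.5), "beta")
  expect_error(sim_config(sigma = -1), ">= 0")
  expect_error(sim_config(cm_fraction = 1.5), "cm_fraction")
  expect_error(sim_config(n_mrna = 10, n_lncrna = 4, n_circrna = 2,
                          n_circuits = 8), "exceeds available")
  expect_error(sim_config(n_circuits = 10, mirnas_per_circuit = 3,
                          n_mirnas = 20), "not enough miRNAs")
})

test_that("recovery scoring computes sensitivity and FDP on pairs", {
  truth <- list(circuits = data.frame(
    sponge_id = paste0("s", 1:5), mrna_id = paste0("g", 1:5),
    stringsAsFactors = FALSE))
  called <- data.frame(sponge_id = c(paste0("s", 1:4), "s9"),
                       mrna_id = c(paste0("g", 1:4), "g9"),
                       stringsAsFactors = FALSE)
  sc <- score_recovery(called, truth)
  expect_equal(sc$sensitivity, 0.8)
  expect_equal(sc$fdp, 0.2)
  expect_identical(sc$n_called, 5L)
  expect_identical(sc$n_planted, 5L)
  # duplicated calls count once; empty call set has FDP 0
  sc2 <- score_recovery(rbind(called, called[1, ]), truth)
  expect_identical(sc2$n_called, 5L)
  sc0 <- score_recovery(called[0, ], truth)
  expect_equal(sc0$sensitivity, 0)
  expect_equal(sc0$fdp, 0)
})

test_that("the written bundle round-trips through the readers", {
  ds <- generate_dataset(small_cfg(seed = 5L))
  dir <- withr::local_tempdir()
  write_synthetic_bundle(ds, dir)
  back <- read_expression_matrix(file.path(dir, "mRNA_expression.tsv"),
                                 file.path(dir, "sample_sheet.tsv"))
  expect_identical(back$values, ds$expression$mRNA$values)
  expect_identical(back$groups, ds$expression$mRNA$groups)
  expect_identical(read_feature_annotation(
    file.path(dir, "feature_annotation.tsv")), ds$annotation)
  tt <- read_target_table(file.path(dir, "targets.tsv"))
  expect_identical(as.data.frame(tt), as.data.frame(ds$targets),
                   ignore_attr = TRUE)
  gs <- read_gene_sets(file.path(dir, "gene_sets.gmt"))
  expect_identical(gs$PLANTED_TARGETS, ds$gene_sets$PLANTED_TARGETS)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$circuits$sponge_id, ds$truth$circuits$sponge_id)
})
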