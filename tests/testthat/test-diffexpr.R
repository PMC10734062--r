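test_that("fold change is the ratio of linear group means", {
  v <- named_matrix(c(4, 2, 1, 6, 4, 3, 1, 1, 1, 3, 1, 1), nrow = 3,
                    samples = paste0("S", 1:4))
  em <- make_simple_em(v, scale = "linear")
  fc <- fold_change(em, c("S1", "S2"), c("S3", "S4"))
  expect_equal(unname(fc), c(5 / 2, 3 / 1, 2 / 1))
  # single-sample groups are ratios of the values themselves
  expect_equal(unname(fold_change(em, "S3", "S4")), c(1 / 3, 1, 1))
  # log2 input is anti-logged (offset-aware) before the ratio
  em_log <- convert_scale(em, "log2")
  expect_equal(fold_change(em_log, c("S1", "S2"), c("S3", "S4")), fc)
  expect_error(fold_change(em, "S1", "S1"), "overlap")
  zero <- v; zero[1, 3:4] <- 0
  expect_error(fold_change(make_simple_em(zero, scale = "linear"),
                           c("S1", "S2"), c("S3", "S4")),
               "zero denominator")
})

test_that("paired t-test matches the t-distribution oracle", {
  groups <- make_groups(3L)
  wt_ipsc <- groups$sample_id[groups$genotype == "WT" &
                                groups$state == "iPSC"]
  wt_cm <- groups$sample_id[groups$genotype == "WT" & groups$state == "CM"]
  v <- matrix(0, nrow = 2, ncol = 12,
              dimnames = list(c("fa", "fb"), groups$sample_id))
  v["fa", wt_cm] <- c(1, 2, 3); v["fa", wt_ipsc] <- c(2, 3, 5)
  v["fb", wt_cm] <- c(4, 5, 6); v["fb", wt_ipsc] <- c(4, 5, 6)
  em <- expression_matrix(v, groups, "log2")
  p <- de_test(em, wt_cm, wt_ipsc, paired = TRUE)
  # d = (-1,-1,-2): t = -4 on 2 df
  expect_equal(unname(p["fa"]), 2 * pt(-4, df = 2), tolerance = 1e-12)
  expect_equal(unname(p["fa"]), 0.0572, tolerance = 1e-3)
  # identical paired values: p = 1
  expect_equal(unname(p["fb"]), 1)
  # two-tailed symmetry under label swap
  expect_equal(de_test(em, wt_ipsc, wt_cm, paired = TRUE), p)
  # agreement with stats::t.test on random data
  set.seed(21)
  v2 <- matrix(rnorm(24, 8), nrow = 2,
               dimnames = list(c("fa", "fb"), groups$sample_id))
  em2 <- expression_matrix(v2, groups, "log2")
  p2 <- de_test(em2, wt_cm, wt_ipsc, paired = TRUE)
  ref <- t.test(v2["fa", wt_cm], v2["fa", wt_ipsc], paired = TRUE)$p.value
  expect_equal(unname(p2["fa"]), ref, tolerance = 1e-12)
})

test_that("unpaired test is Welch and guards degenerate features", {
  groups <- make_groups(3L)
  ts_cm <- groups$sample_id[groups$genotype == "TS" & groups$state == "CM"]
  wt_cm <- groups$sample_id[groups$genotype == "WT" & groups$state == "CM"]
  set.seed(22)
  v <- matrix(rnorm(36, 8), nrow = 3,
              dimnames = list(c("fa", "fb", "fc"), groups$sample_id))
  v["fb", ] <- 5                      # flat everywhere -> p = 1
  v["fc", ] <- 5; v["fc", ts_cm] <- 4 # exact shift, zero variance -> min p
  em <- expression_matrix(v, groups, "log2")
  p <- de_test(em, ts_cm, wt_cm, paired = FALSE)
  ref <- t.test(v["fa", ts_cm], v["fa", wt_cm])$p.value
  expect_equal(unname(p["fa"]), ref, tolerance = 1e-12)
  expect_equal(unname(p["fb"]), 1)
  expect_equal(unname(p["fc"]), .Machine$double.xmin)
  expect_error(de_test(em, ts_cm[1], wt_cm), "at least 2")
  # paired across genotypes has no shared lines
  expect_error(de_test(em, ts_cm, wt_cm, paired = TRUE), "same lines")
})

test_that("DE calling applies inclusive FC and strict p thresholds", {
  fc <- c(a = 2.0, b = 1.99, c = 0.5, d = 4, e = 0.1, f = 3)
  p <- c(a = 0.049, b = 0.001, c = 0.01, d = 0.05, e = 0.04, f = 0.2)
  de <- call_de(fc, p)
  expect_identical(de$direction,
                   c("up", "none", "down", "none", "down", "none"))
  # thresholds are parameters
  de2 <- call_de(fc, p, fc_hi = 1.5, fc_lo = 2 / 3, alpha = 0.3)
  expect_identical(de2$direction[match("f", de2$feature_id)], "up")
  expect_error(call_de(fc, p[1:3]), "aligned")
  expect_identical(de_features(de), c("a", "c", "e"))
  expect_identical(de_features(de, "up"), "a")
})

test_that("venn partition enumerates the seven regions", {
  a <- c("g1", "g2", "g3"); b <- c("g1", "g2", "g4"); cc <- c("g2", "g4", "g5")
  vp <- venn_partition(a, b, cc)
  expect_identical(vp$regions$AB, "g1")
  expect_identical(vp$regions$ABC, "g2")
  expect_identical(vp$regions$A, "g3")
  expect_identical(vp$regions$BC, "g4")
  expect_identical(vp$regions$C, "g5")
  expect_identical(unname(vp$counts[c("AC", "B")]), c(0L, 0L))
  expect_identical(sum(vp$counts), length(unique(c(a, b, cc))))
  # degenerate configurations
  same <- venn_partition(a, a, a)
  expect_identical(sum(same$counts), 3L)
  expect_identical(same$regions$ABC, sort(a))
  disj <- venn_partition("x", "y", "z")
  expect_identical(unname(disj$counts[c("A", "B", "C")]), c(1L, 1L, 1L))
  # default label map is lexicographic in region name; override respected
  expect_identical(unname(vp$labels["A"]), "Set1")
  expect_identical(unname(vp$labels["ABC"]), "Set3")
  custom <- setNames(paste0("R", 1:7), c("A", "B", "C", "AB", "AC", "BC",
                                         "ABC"))
  expect_identical(unname(venn_partition(a, b, cc,
                                         labels = custom)$labels["AB"]),
                   "R4")
  # region sizes always sum to the union (property over random sets)
  set.seed(31)
  for (i in 1:20) {
    u <- paste0("g", 1:30)
    aa <- sample(u, 10); bb <- sample(u, 12); ccc <- sample(u, 8)
    expect_identical(sum(venn_partition(aa, bb, ccc)$counts),
                     length(unique(c(aa, bb, ccc))))
  }
})

test_that("mismatched DE universes are rejected", {
  fc <- c(a = 2, b = 1); p <- c(a = 0.01, b = 0.5)
  d1 <- call_de(fc, p)
  fc2 <- c(a = 2, c = 1); p2 <- c(a = 0.01, c = 0.5)
  d2 <- call_de(fc2, p2)
  expect_error(venn_partition(d1, d1, d2), "universes")
})

test_that("volcano data and BH columns derive from the DE table", {
  fc <- c(a = 4, b = 0.25); p <- c(a = 0.01, b = 0.02)
  de <- call_de(fc, p)
  v <- volcano_data(de)
  expect_equal(v$log2_fc, c(2, -2))
  expect_equal(v$neg_log10_p, -log10(c(0.01, 0.02)))
  expect_equal(add_bh_qvalues(de)$q_value, p.adjust(p, "BH"),
               ignore_attr = TRUE)
})
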