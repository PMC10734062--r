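# independent brute-force re-scan: slide every window and compare substrings
# against explicitly built site strings (no shared code with the predictor)
oracle_sites <- function(mirna, transcript, circular = FALSE) {
  comp <- function(s) chartr("ACGU", "UGCA", s)
  rc <- function(s) paste(rev(strsplit(comp(s), "")[[1]]), collapse = "")
  mirna <- chartr("T", "U", toupper(mirna))
  tx <- chartr("T", "U", toupper(transcript))
  len <- nchar(tx)
  scan <- if (circular) paste0(tx, tx) else tx
  site_8 <- paste0(rc(substr(mirna, 2, 8)), "A")
  site_m8 <- rc(substr(mirna, 2, 8))
  site_a1 <- paste0(rc(substr(mirna, 2, 7)), "A")
  site_6 <- rc(substr(mirna, 2, 7))
  out <- NULL
  for (i in seq_len(nchar(scan))) {
    win8 <- substr(scan, i, i + 7)
    win7 <- substr(scan, i, i + 6)
    win6 <- substr(scan, i, i + 5)
    type <- if (win8 == site_8) "8mer"
            else if (win7 == site_m8 &&
                     substr(scan, i + 7, i + 7) != "A") "7mer-m8"
            else if (win7 == site_a1 &&
                     substr(scan, i - 1, i - 1) != comp(substr(mirna, 8, 8)))
              "7mer-A1"
            else if (win6 == site_6 &&
                     substr(scan, i - 1, i - 1) != comp(substr(mirna, 8, 8)) &&
                     substr(scan, i + 6, i + 6) != "A") "6mer"
            else NA
    if (!is.na(type) && i <= len)
      out <- rbind(out, data.frame(site_type = type, position = i))
  }
  out
}

test_that("seed predictor finds the canonical worked examples", {
  mir <- c(m = "UAGCUUAUCAGACUGAUGUUGA")
  # 8mer: rc(nt2-8 AGCUUAU) = AUAAGCU followed by A, at position 4
  tt <- predict_targets_seed(mir, c(t = "GGGAUAAGCUAGGG"))
  expect_identical(nrow(tt), 1L)
  expect_identical(tt$site_type, "8mer")
  expect_identical(tt$position, 4L)
  expect_equal(tt$score, 4)
  # transcript exactly the 7mer-m8 site: one 7mer-m8, no 8mer
  tt2 <- predict_targets_seed(mir, c(t = "AUAAGCU"))
  expect_identical(tt2$site_type, "7mer-m8")
  expect_identical(tt2$position, 1L)
  # 7mer-A1 and 6mer classes
  tt3 <- predict_targets_seed(mir, c(t = "GGUAAGCUAGG"))
  expect_identical(tt3$site_type, "7mer-A1")
  tt4 <- predict_targets_seed(mir, c(t = "GGUAAGCUGGG"))
  expect_identical(tt4$site_type, "6mer")
  # no complementary window -> empty table
  tt5 <- predict_targets_seed(mir, c(t = "CCCCCCCCCCCC"))
  expect_identical(nrow(tt5), 0L)
  # restricting site types filters the report
  tt6 <- predict_targets_seed(mir, c(t = "GGGAUAAGCUAGGG"),
                              site_types = c("7mer-m8", "6mer"))
  expect_identical(nrow(tt6), 0L)
})

test_that("predictor is insensitive to case and T/U alphabet", {
  mir_u <- c(m = "UAGCUUAUCAGACUGAUGUUGA")
  mir_t <- c(m = "tagcttatcagactgatgttga")
  tx_u <- c(t = "GGGAUAAGCUAGGG")
  tx_t <- c(t = "gggataagctaggg")
  expect_identical(predict_targets_seed(mir_u, tx_u),
                   predict_targets_seed(mir_t, tx_t))
  expect_error(predict_targets_seed(c(m = "UAGCNUAUCAG"), tx_u),
               "non-nucleotide")
  expect_error(predict_targets_seed(c(m = "UAGCUUA"), tx_u), "shorter")
})

test_that("every reported site reproduces under the brute-force oracle", {
  set.seed(41)
  mirnas <- setNames(
    vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
            collapse = ""), ""),
    paste0("miR-", 1:5))
  txs <- setNames(
    vapply(1:8, function(i)
      paste(sample(c("A", "C", "G", "U"), 120, replace = TRUE),
            collapse = ""), ""),
    paste0("tx", 1:8))
  pred <- predict_targets_seed(mirnas, txs)
  for (mi in names(mirnas)) {
    for (tx in names(txs)) {
      got <- as.data.frame(pred)[pred$mirna_id == mi & pred$target_id == tx,
                                 c("site_type", "position")]
      rownames(got) <- NULL
      want <- oracle_sites(mirnas[[mi]], txs[[tx]])
      if (is.null(want)) {
        expect_identical(nrow(got), 0L)
      } else {
        want <- want[order(want$position), ]
        rownames(want) <- NULL
        expect_identical(got[order(got$position), ], want,
                         info = paste(mi, tx))
      }
    }
  }
})

test_that("circRNA scanning finds junction sites without duplicating linear ones", {
  mir <- c(m = "UAGCUUAUCAGACUGAUGUUGA")   # core site AUAAGCU + A
  # split the 8mer site across the back-splice junction: end ...AUAA / GCUA...
  circ <- c(circ1 = "GCUAGGGGGGGGAUAA")
  lin <- predict_targets_seed(mir, circ)
  expect_identical(nrow(lin), 0L)
  tt <- predict_targets_seed(mir, circ, circular_ids = "circ1")
  expect_identical(tt$site_type, "8mer")
  expect_identical(tt$position, 13L)       # starts in the first copy
  # a site in the linear body is reported exactly once
  circ2 <- c(circ2 = "GGGAUAAGCUAGGG")
  tt2 <- predict_targets_seed(mir, circ2, circular_ids = "circ2")
  expect_identical(nrow(tt2), 1L)
  expect_identical(tt2$position, 4L)
  # brute-force equivalence on random circular sequences
  set.seed(42)
  txs <- setNames(
    vapply(1:6, function(i)
      paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE),
            collapse = ""), ""),
    paste0("c", 1:6))
  pred <- predict_targets_seed(mir, txs, circular_ids = names(txs))
  for (tx in names(txs)) {
    got <- as.data.frame(pred)[pred$target_id == tx,
                               c("site_type", "position")]
    rownames(got) <- NULL
    want <- oracle_sites(mir[[1]], txs[[tx]], circular = TRUE)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      rownames(want) <- NULL
      expect_identical(got[order(got$position), ], want, info = tx)
    }
  }
})

test_that("merging target tables unions or intersects (miRNA, target) pairs", {
  t1 <- target_table(data.frame(
    mirna_id = c("m1", "m1", "m2"), target_id = c("a", "b", "c"),
    site_type = "imported", position = NA_integer_, score = NA_real_,
    source = "imported_1", stringsAsFactors = FALSE))
  t2 <- target_table(data.frame(
    mirna_id = c("m1", "m3"), target_id = c("b", "d"),
    site_type = "imported", position = NA_integer_, score = NA_real_,
    source = "imported_2", stringsAsFactors = FALSE))
  un <- merge_target_tables(list(t1, t2), mode = "union")
  expect_identical(nrow(un), 4L)     # (m1,a) (m1,b) (m2,c) (m3,d)
  expect_identical(un$source[un$mirna_id == "m1" & un$target_id == "b"],
                   "imported_1+imported_2")
  inter <- merge_target_tables(list(t1, t2), mode = "intersection")
  expect_identical(nrow(inter), 1L)
  expect_identical(inter$target_id, "b")
  # disjoint tables: union is the sum of sizes, intersection empty
  t3 <- target_table(data.frame(
    mirna_id = "m9", target_id = "z", site_type = "imported",
    position = NA_integer_, score = NA_real_, source = "imported_2",
    stringsAsFactors = FALSE))
  expect_identical(nrow(merge_target_tables(list(t1, t3), "union")), 4L)
  expect_identical(nrow(merge_target_tables(list(t1, t3), "intersection")),
                   0L)
  expect_identical(merge_target_tables(list(t1)), t1)
})

test_that("FASTA input reaches the predictor unchanged", {
  mir_fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">m", "UAGCUUAUCAGACUGAUGUUGA"), mir_fa)
  tx_fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t", "GGGATAAGCTAGGG"), tx_fa)   # DNA alphabet on purpose
  tt <- predict_targets_seed(mir_fa, tx_fa)
  expect_identical(tt$site_type, "8mer")
  expect_identical(tt$position, 4L)
})
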