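# Alignment analytics: column maps, gap filtering, consensus,
# conservation, identity, expansion columns, and bridge-cysteine homolog
# mapping with the expansion false-positive rule.

test_that("alignment construction builds bijective column maps", {
  aln <- new_alignment(c("r1", "r2"), c("AC-", "A-C"))
  expect_equal(aln$n_cols, 3)
  expect_equal(aln$col2res[[1]], c(1L, 2L, NA))
  expect_equal(aln$col2res[[2]], c(1L, NA, 2L))
  # bijection between non-gap columns and residue indices
  for (i in 1:2) {
    nc <- which(!is.na(aln$col2res[[i]]))
    expect_equal(aln$col2res[[i]][nc], seq_along(nc))
    expect_equal(aln$res2col[[i]], nc)
  }
  expect_error(new_alignment(c("a", "b"), c("AC-", "AC")), "ragged")
})

test_that("aligned FASTA round-trips and gold rows ungap to their sequences", {
  g <- gen_gold_alignment(n_rows = 6, ancestor_len = 150,
                          insertions = list(list(row = 2, anchor = 75,
                                                 len = 12)),
                          sub_rate = 0.05, seed = 61)
  p <- tempfile(fileext = ".fasta")
  write_alignment(g$alignment, p)
  back <- read_alignment(p)
  expect_identical(back$gapped, g$alignment$gapped)
  expect_identical(back$ids, g$alignment$ids)
  # empty stream errors
  p0 <- tempfile(); writeLines(character(0), p0)
  expect_error(read_alignment(p0), "empty")
})

test_that("gap filter removes gappy columns and lifts coordinates back", {
  g <- gen_gold_alignment(n_rows = 10, ancestor_len = 100,
                          insertions = list(list(row = 3, anchor = 50,
                                                 len = 25)),
                          seed = 62)
  gf <- gap_filter(g$alignment, max_gap_frac = 0.8)
  # the 25 insertion columns have gap fraction 0.9 > 0.8: removed
  expect_equal(gf$alignment$n_cols, 100)
  ins <- g$truth$insertions
  expect_true(all(!(ins$col_start:ins$col_end %in% gf$kept_cols)))
  # lift-back: filtered column j is original column kept_cols[j]
  m_orig <- do.call(rbind, strsplit(g$alignment$gapped, ""))
  m_filt <- do.call(rbind, strsplit(gf$alignment$gapped, ""))
  expect_identical(m_filt, m_orig[, gf$kept_cols])
  # no gaps: identity filter
  g0 <- gen_gold_alignment(n_rows = 4, ancestor_len = 50, seed = 63)
  gf0 <- gap_filter(g0$alignment)
  expect_equal(gf0$kept_cols, 1:50)
})

test_that("consensus emits modal residues above the occupancy cut", {
  a <- new_alignment(paste0("r", 1:5), rep("ACDEF", 5))
  expect_equal(consensus(a), "ACDEF")
  # column {A, A, C, -}: occupancy 0.75, mode A
  b <- new_alignment(paste0("r", 1:4), c("A", "A", "C", "-"))
  expect_equal(consensus(b), "A")
  # residue in 2 of 10 rows: omitted at the 0.5 default
  g <- new_alignment(paste0("r", 1:10), c(rep("K", 2), rep("-", 8)))
  expect_equal(consensus(g), "")
  # alphabetical tie-break
  tie <- new_alignment(paste0("r", 1:4), c("C", "C", "A", "A"))
  expect_equal(consensus(tie), "A")
})

test_that("conservation is modal count over all rows with a 40% mask", {
  a <- new_alignment(paste0("r", 1:10),
                     c(rep("AC", 4), rep("AG", 4), rep("A-", 2)))
  cons <- conservation(a)
  expect_equal(cons[1], 1.0)
  expect_equal(cons[2], 0.4)
  expect_true(cons[2] >= 0.40)
  allgap <- new_alignment(c("r1", "r2"), c("-", "-"))
  expect_equal(conservation(allgap), 0)
})

test_that("pairwise identity uses co-occupied columns and matches 1/20 nulls", {
  a <- new_alignment(c("r1", "r2"), c("AAAA", "AAAA"))
  expect_equal(mean_pairwise_identity(a)$mean, 1.0)
  b <- new_alignment(c("r1", "r2"), c("AAAA", "AATT"))
  expect_equal(mean_pairwise_identity(b)$mean, 0.5)
  expect_error(mean_pairwise_identity(new_alignment("r1", "AA")), "2 rows")
  # 20 random length-200 rows: mean identity ~ 1/20
  set.seed(64)
  rows <- replicate(20, random_aa_seq(200))
  mpi <- mean_pairwise_identity(new_alignment(paste0("r", 1:20), rows))
  expect_equal(mpi$mean, 0.05, tolerance = 0.15)
  # brute-force check of one pair
  r1 <- strsplit(rows[1], "")[[1]]; r2 <- strsplit(rows[2], "")[[1]]
  expect_equal(mpi$pairs$identity[1], mean(r1 == r2))
})

test_that("expansion-column detection recovers planted insertions", {
  g <- gen_gold_alignment(n_rows = 8, ancestor_len = 200,
                          insertions = list(list(row = 5, anchor = 120,
                                                 len = 25)),
                          seed = 65)
  ex <- detect_expansion_columns(g$alignment, "row1")
  expect_equal(nrow(ex), 1)
  expect_equal(ex$seq_id, "row5")
  expect_equal(ex$n_residues, 25)
  expect_equal(ex$col_start, g$truth$insertions$col_start)
  expect_equal(ex$ref_before, 120L)
  expect_equal(ex$ref_after, 121L)
  # no insertions: empty; below min_run: empty
  g0 <- gen_gold_alignment(n_rows = 4, ancestor_len = 100, seed = 66)
  expect_equal(nrow(detect_expansion_columns(g0$alignment, "row1")), 0)
  g8 <- gen_gold_alignment(n_rows = 4, ancestor_len = 100,
                           insertions = list(list(row = 2, anchor = 50,
                                                  len = 8)),
                           seed = 67)
  expect_equal(nrow(detect_expansion_columns(g8$alignment, "row1",
                                             min_run = 10)), 0)
  expect_error(detect_expansion_columns(g8$alignment, "ghost"), "unknown")
})

test_that("bridge cysteines: present / absent / excluded_expansion", {
  # conserved pair in all rows
  g <- gen_gold_alignment(n_rows = 6, ancestor_len = 200,
                          cys_pairs = list(c(60, 140), c(80, 170)),
                          seed = 68)
  b <- map_bridge_cysteines(g$alignment, "row1", list(c(60, 140), c(80, 170)))
  expect_true(all(b$status == "present"))
  expect_equal(nrow(b), 5 * 2)

  # one row's cysteines only inside its planted expansion: excluded
  ins_seq <- paste0("CC", strrep("G", 23))
  g2 <- gen_gold_alignment(n_rows = 5, ancestor_len = 200,
                           cys_pairs = list(c(60, 140)),
                           insertions = list(list(row = 3, anchor = 140,
                                                  seq = ins_seq, len = 25)),
                           mutations = list(list(row = 3, pos = 60, aa = "S"),
                                            list(row = 3, pos = 140, aa = "S")),
                           seed = 69)
  b2 <- map_bridge_cysteines(g2$alignment, "row1", list(c(60, 140)))
  expect_equal(b2$status[b2$seq_id == "row3"], "excluded_expansion")
  expect_true(all(b2$status[b2$seq_id != "row3"] == "present"))

  # a row with no cysteines at all: absent
  g3 <- gen_gold_alignment(n_rows = 3, ancestor_len = 200,
                           cys_pairs = list(c(60, 140)),
                           mutations = list(list(row = 2, pos = 60, aa = "S"),
                                            list(row = 2, pos = 140, aa = "S")),
                           seed = 70)
  b3 <- map_bridge_cysteines(g3$alignment, "row1", list(c(60, 140)))
  expect_equal(b3$status[b3$seq_id == "row2"], "absent")

  # non-cysteine reference position errors
  expect_error(map_bridge_cysteines(g3$alignment, "row1", list(c(61, 140))),
               "not cysteine")
})
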