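# TM-CD36-TM architecture census: parsers, the hydropathy TM predictor,
# duplicate removal, and the classifier against fixture ground truth.

make_proteome <- function(...) {
  prot <- gen_synthetic_proteome(...)
  d <- tempfile()
  write_proteome_fixture(prot, d)
  list(prot = prot, dir = d,
       seqs = read_fasta_records(file.path(d, "sequences.fasta")),
       hits = read_domain_hits(file.path(d, "hits.domtblout")),
       tms = read_tm_table(file.path(d, "tm.tmhmm")))
}

test_that("domain-hit parsing round-trips through the fixture writer", {
  fx <- make_proteome(n_taxa = 1, seqs_per_taxon = 3, seed = 11)
  expect_equal(nrow(fx$hits), 3)
  expect_equal(fx$hits$env_start, fx$prot$hits$env_start)
  expect_equal(fx$hits$env_end, fx$prot$hits$env_end)
  expect_true(all(fx$hits$included))

  # empty file
  p <- tempfile(); writeLines("#", p)
  expect_equal(nrow(read_domain_hits(p)), 0)

  # malformed rows error with a line number
  p2 <- tempfile(); writeLines(c("# comment", "too few fields"), p2)
  expect_error(read_domain_hits(p2), "line 2")
  bad <- fx$prot$hits; bad$env_start <- bad$env_end + 10L
  p3 <- tempfile(); write_domtblout(bad, p3)
  expect_error(read_domain_hits(p3), "invalid envelope")
})

test_that("TM tables parse in both dialects", {
  fx <- make_proteome(n_taxa = 1, seqs_per_taxon = 2, seed = 12)
  expect_equal(nrow(fx$tms), 4)  # two TMs per SR-B
  expect_equal(fx$tms$start, fx$prot$tms$start)
  p <- tempfile()
  write_tsv(fx$prot$tms, p)
  tsv <- read_tm_table(p, dialect = "tsv")
  expect_equal(tsv$end, fx$prot$tms$end)
})

test_that("hydropathy predictor finds hydrophobic runs and nothing else", {
  seq1 <- paste0(strrep("D", 30), strrep("I", 30), strrep("D", 30))
  seg <- predict_tm_hydropathy(seq1)
  expect_equal(nrow(seg), 1)
  expect_lte(abs(seg$start - 31), 4)
  expect_lte(abs(seg$end - 60), 4)

  expect_equal(nrow(predict_tm_hydropathy(strrep("D", 80))), 0)
  # shorter than window: empty, not an error
  expect_equal(nrow(predict_tm_hydropathy("ACDEF")), 0)
})

test_that("hydropathy window means agree with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:20) {
    s <- random_aa_seq(sample(30:120, 1))
    means <- brute_kd_means(s, 19)
    seg <- predict_tm_hydropathy(s, window = 19, cutoff = 1.6)
    # reconstruct segments from oracle means with the same rules
    mask <- means >= 1.6
    r <- rle(mask); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    centers <- 10:(nchar(s) - 9)
    exp_runs <- data.frame(start = centers[starts[r$values]],
                           end = centers[ends[r$values]])
    exp_runs <- exp_runs[exp_runs$end - exp_runs$start + 1 >= 12, , drop = FALSE]
    expect_equal(nrow(seg), nrow(exp_runs))
    if (nrow(seg) > 0 && all(exp_runs$end - exp_runs$start + 1 <= 40)) {
      expect_equal(seg$start, exp_runs$start)
      expect_equal(seg$end, exp_runs$end)
    }
  }
})

test_that("fixture SR-Bs yield exactly two predicted TM segments at truth spans", {
  fx <- make_proteome(n_taxa = 1, seqs_per_taxon = 4, seed = 13)
  for (i in 1:4) {
    seg <- predict_tm_hydropathy(fx$prot$seqs$seq[i])
    tr <- fx$prot$truth[i, ]
    expect_equal(nrow(seg), 2)
    expect_true(seg$start[1] >= tr$tm1_start - 4 && seg$end[1] <= tr$tm1_end + 4)
    expect_true(seg$start[2] >= tr$tm2_start - 4 && seg$end[2] <= tr$tm2_end + 4)
  }
})

test_that("dedupe collapses within-taxon duplicates only, idempotently", {
  seqs <- data.frame(
    id = c("B", "A", "C", "D"),
    taxon = c("t1", "t1", "t2", "t1"),
    seq = c("MKV", "MKV", "MKV", "QQQ"),
    stringsAsFactors = FALSE)
  out <- dedupe_identical(seqs)
  expect_setequal(out$id, c("A", "C", "D"))       # smallest id kept
  expect_true("C" %in% out$id)                     # cross-taxon retained
  expect_identical(dedupe_identical(out), out)     # idempotent
  un <- data.frame(id = letters[1:10], taxon = "t",
                   seq = replicate(10, random_aa_seq(20)),
                   stringsAsFactors = FALSE)
  expect_equal(nrow(dedupe_identical(un)), 10)
})

test_that("architecture classification reproduces fixture truth exactly", {
  fx <- make_proteome(n_taxa = 3, seqs_per_taxon = 10,
                      decoy_mix = c(no_tm = 0.2, single_tm = 0.2,
                                    fused = 0.1, non_cd36 = 0.1),
                      seed = 21)
  calls <- classify_cohort(fx$seqs, fx$hits, fx$tms)
  tr <- fx$prot$truth
  expect_equal(calls$label[match(tr$id, calls$seq_id)], tr$label)
  srb <- calls[calls$label == "SR-B", ]
  tr_srb <- tr[tr$label == "SR-B", ]
  expect_equal(srb$ecto_start[match(tr_srb$id, srb$seq_id)], tr_srb$ecto_start)
  expect_equal(srb$ecto_end[match(tr_srb$id, srb$seq_id)], tr_srb$ecto_end)
  # unknown seq_id in hits errors
  bad_hits <- fx$hits; bad_hits$seq_id[1] <- "ghost"
  expect_error(classify_cohort(fx$seqs, bad_hits, fx$tms), "unknown seq_id")
})

test_that("census summary counts SR-Bs per taxon and respects the hit bound", {
  fx <- make_proteome(n_taxa = 3, seqs_per_taxon = 4, seed = 31)
  calls <- classify_cohort(fx$seqs, fx$hits, fx$tms)
  cm <- data.frame(taxon = sprintf("taxon%02d", 1:3), clade = "cladeA",
                   stringsAsFactors = FALSE)
  s <- census_summary(calls, cm)
  expect_equal(s$per_taxon$n_srb, c(4, 4, 4))
  expect_lte(s$totals$n_srb, s$totals$n_cd36_hit)

  # half no-TM decoys: SR-B count is half the CD36-hit count
  fx2 <- make_proteome(n_taxa = 1, seqs_per_taxon = 10,
                       decoy_mix = c(no_tm = 0.5), seed = 32)
  calls2 <- classify_cohort(fx2$seqs, fx2$hits, fx2$tms)
  s2 <- census_summary(calls2, data.frame(taxon = "taxon01", clade = "c"))
  expect_equal(s2$totals$n_srb, s2$totals$n_cd36_hit / 2)

  expect_error(census_summary(calls, data.frame(taxon = "x", clade = "y")),
               "without clade")
  empty <- census_summary(calls[0, ], cm)
  expect_equal(nrow(empty$per_taxon), 0)
})
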