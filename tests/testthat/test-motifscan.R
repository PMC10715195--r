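# PWM motif scanning: MEME I/O, site-derived PWMs, best-window sequence
# scores against the exhaustive oracle, and the 0-100 scaling.

test_that("PWMs from sites match brute-force column counting", {
  set.seed(71)
  sites <- replicate(12, random_aa_seq(9))
  pwm <- pwm_from_sites(sites, "m")
  m <- do.call(rbind, strsplit(sites, ""))
  for (j in 1:9) {
    counts <- table(factor(m[, j], levels = AA20_TEST))
    expect_equal(unname(pwm$probs[j, AA20_TEST]),
                 as.numeric(counts) / 12, tolerance = 1e-12)
  }
  # all-identical sites: consensus window is the maximal possible score
  pwm2 <- pwm_from_sites(rep("ACDEFGHK", 10), "m2")
  h <- score_sequence("ACDEFGHK", pwm2)
  expect_equal(h$raw, unname(pwm_score_range(pwm2)["max"]))
  expect_error(pwm_from_sites(c("ACD", "AC")), "ragged")
})

test_that("MEME minimal format round-trips weights to 1e-9", {
  set.seed(72)
  pwms <- list(pwm_from_sites(replicate(8, random_aa_seq(8)), "M1",
                              match_threshold = 3.5),
               pwm_from_sites(replicate(5, random_aa_seq(12)), "M2"))
  p <- tempfile(fileext = ".meme")
  write_meme_motifs(pwms, p)
  back <- read_meme_motifs(p)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$width, 8)
  expect_equal(back[[1]]$match_threshold, 3.5)
  for (k in 1:2) {
    expect_equal(back[[k]]$weights, pwms[[k]]$weights, tolerance = 1e-9)
  }
  # uniform probabilities over uniform background: all weights 0
  uni <- new_pwm("u", matrix(1 / 20, 6, 20, dimnames = list(NULL, AA20_TEST)))
  expect_true(all(abs(uni$weights) < 1e-12))
  # rows not summing to 1 error
  badp <- matrix(1 / 20, 4, 20, dimnames = list(NULL, AA20_TEST))
  badp[2, 1] <- 0.5
  expect_error(new_pwm("bad", badp), "sums to")
})

test_that("best-window score equals the exhaustive oracle", {
  set.seed(73)
  for (rep in 1:200) {
    w <- sample(8:30, 1)
    pwm <- pwm_from_sites(replicate(sample(3:10, 1), random_aa_seq(w)), "m")
    s <- random_aa_seq(sample(w:(w + 150), 1))
    got <- score_sequence(s, pwm)
    want <- brute_pwm_scan(s, pwm)
    expect_equal(got$raw, want$raw, tolerance = 1e-12)
    expect_equal(got$start, want$start)
  }
})

test_that("short sequences yield the defined no-hit result", {
  pwm <- pwm_from_sites(rep("ACDEFGHK", 3), "m")
  h <- score_sequence("ACDEFGH", pwm)  # width - 1
  expect_equal(h$raw, -Inf)
  expect_false(h$passes)
  expect_true(is.na(h$start))
})

test_that("0-100 scaling hits the extrema and is affine-invariant", {
  set.seed(74)
  pwm <- pwm_from_sites(replicate(6, random_aa_seq(10)), "m")
  consensus_seq <- paste(apply(pwm$weights, 1, function(r)
    names(r)[which.max(r)]), collapse = "")
  anti_seq <- paste(apply(pwm$weights, 1, function(r)
    names(r)[which.min(r)]), collapse = "")
  expect_equal(scale_scores(score_sequence(consensus_seq, pwm)$raw, pwm), 100)
  expect_equal(scale_scores(score_sequence(anti_seq, pwm)$raw, pwm), 0)
  expect_equal(scale_scores(-Inf, pwm), 0)

  # adding a constant to all weights of a position leaves scaling unchanged
  seq60 <- random_aa_seq(60)
  raw <- score_sequence(seq60, pwm)$raw
  shifted <- pwm
  shifted$weights[3, ] <- shifted$weights[3, ] + 2.5
  expect_equal(scale_scores(raw, pwm),
               scale_scores(score_sequence(seq60, shifted)$raw, shifted),
               tolerance = 1e-9)

  # midpoint of a constructed 1-position motif scales to 50
  w1 <- matrix(0, 1, 20, dimnames = list(NULL, AA20_TEST))
  w1[1, "C"] <- 4; w1[1, "D"] <- 2
  p1 <- structure(list(motif_id = "mid", width = 1L, weights = w1,
                       match_threshold = 0), class = "srb_pwm")
  expect_equal(scale_scores(score_sequence("D", p1)$raw, p1), 50)
})

test_that("pass decisions are monotone in the match threshold", {
  set.seed(75)
  pwm <- pwm_from_sites(replicate(8, random_aa_seq(9)), "m")
  seqs <- replicate(30, random_aa_seq(80))
  raws <- vapply(seqs, function(s) score_sequence(s, pwm)$raw, numeric(1))
  thresholds <- sort(runif(10, min(raws) - 1, max(raws) + 1))
  passes <- vapply(thresholds, function(t) sum(raws >= t), integer(1))
  expect_true(all(diff(passes) <= 0))
})

test_that("presence heatmap reports planted-motif pass fractions", {
  consensus <- "QDKGSNTE"
  prot <- gen_synthetic_proteome(n_taxa = 2, seqs_per_taxon = 5,
                                 motif_specs = list(list(id = "M1",
                                                         consensus = consensus,
                                                         pos = 50)),
                                 seed = 76)
  calls <- classify_cohort(prot$seqs, prot$hits, prot$tms)
  ectos <- vapply(seq_len(nrow(calls)), function(i)
    extract_ectodomain(prot$seqs$seq[i], calls[i, ])$sequence, "")
  names(ectos) <- calls$seq_id
  pwm_in <- pwm_from_sites(rep(consensus, 10), "M1", match_threshold = 20)
  pwm_out <- pwm_from_sites(rep("CWMCWMCW", 10), "M0", match_threshold = 20)
  hm <- motif_presence(ectos, list(pwm_in, pwm_out))
  expect_equal(unname(hm$pass_fraction["M1"]), 1.0)
  expect_equal(unname(hm$pass_fraction["M0"]), 0.0)
  expect_true(all(hm$scaled >= 0 & hm$scaled <= 100))
  # empty motif list: empty table
  hm0 <- motif_presence(ectos, list())
  expect_equal(ncol(hm0$scaled), 0)
})
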