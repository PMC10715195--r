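# Structure comparison: PDB round-trips, pLDDT classes, Kabsch against
# the quaternion oracle, iterative spatial pairing, RMSD binning and
# structural expansion detection.

test_that("PDB writing and reading round-trip a fixture structure", {
  s <- gen_synthetic_structure(n_strands = 0, strand_len = 0,
                               apex_helices = c(50), seed = 81)$structure
  p <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, p)
  back <- read_structure(p, predicted = TRUE)
  expect_equal(length(back$resno), 50)
  expect_equal(nrow(back$ca), 50)
  expect_equal(unname(back$ca), unname(s$ca), tolerance = 1e-3)
  expect_equal(back$plddt, rep(75, 50))
  # empty stream errors
  p0 <- tempfile(fileext = ".pdb"); writeLines("END", p0)
  expect_error(read_structure(p0), "")
})

test_that("pLDDT classes follow the 90/70 convention, lower bound inclusive", {
  s <- gen_synthetic_structure(n_strands = 0, strand_len = 0,
                               apex_helices = c(5), seed = 82,
                               plddt = c(95, 90, 70, 69.9, 10))$structure
  expect_equal(classify_plddt(s),
               c("high", "high", "moderate", "low", "low"))
  s2 <- gen_synthetic_structure(n_strands = 0, strand_len = 0,
                                apex_helices = c(5), seed = 82)$structure
  s2$plddt <- NULL
  expect_error(classify_plddt(s2), "no pLDDT")
})

test_that("kabsch recovers exact rigid motions and rejects degenerate input", {
  set.seed(83)
  P <- matrix(rnorm(45), 15, 3)
  f0 <- kabsch(P, P)
  expect_lt(f0$rmsd, 1e-10)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-10)

  Rz <- rotation_matrix(c(0, 0, 1), pi / 2)
  Q <- P %*% t(Rz) + rep(c(3, -1, 7), each = 15)
  f <- kabsch(P, Q)
  expect_lt(f$rmsd, 1e-10)
  moved <- sweep(Q %*% t(f$rotation), 2, f$translation, "+")
  expect_equal(moved, P, tolerance = 1e-8)

  expect_error(kabsch(P[1:2, ], P[1:2, ]), "3 points")
  line <- cbind(1:10, 2 * (1:10), -(1:10))
  expect_error(kabsch(line, line + 0.0), "degenerate")
})

test_that("kabsch RMSD matches the quaternion oracle on random point sets", {
  set.seed(84)
  for (rep in 1:50) {
    n <- sample(10:200, 1)
    P <- matrix(rnorm(3 * n), n, 3) * runif(1, 1, 10)
    Q <- P %*% t(rotation_matrix(rnorm(3), runif(1, 0, pi))) +
      matrix(rnorm(3 * n, 0, 0.5), n, 3)
    expect_equal(kabsch(P, Q)$rmsd, horn_superpose(P, Q)$rmsd,
                 tolerance = 1e-8)
  }
})

test_that("kabsch RMSD is invariant under rigid pre-transforms", {
  set.seed(85)
  P <- matrix(rnorm(90), 30, 3)
  Q <- P + matrix(rnorm(90, 0, 0.4), 30, 3)
  base <- kabsch(P, Q)$rmsd
  for (rep in 1:5) {
    Rr <- rotation_matrix(rnorm(3), runif(1, 0, pi))
    t1 <- rnorm(3, 0, 20)
    expect_equal(kabsch(P %*% t(Rr) + rep(t1, each = 30), Q)$rmsd, base,
                 tolerance = 1e-9)
    expect_equal(kabsch(P, Q %*% t(Rr) + rep(t1, each = 30))$rmsd, base,
                 tolerance = 1e-9)
  }
})

test_that("self-superposition pairs everything at distance zero", {
  s <- gen_synthetic_structure(seed = 86)$structure
  sup <- superpose_iterative(s, s)
  expect_equal(nrow(sup$pairs), length(s$resno))
  expect_true(all(sup$pairs$dist < 1e-8))
  expect_equal(length(sup$unaligned_query), 0)
  expect_equal(length(sup$unaligned_ref), 0)
  expect_true(all(sup$pairs$bin == "high"))
  expect_true(sup$converged)
  expect_equal(global_rmsd(sup, "calpha"), 0, tolerance = 1e-8)
  expect_equal(global_rmsd(sup, "all_atom"), 0, tolerance = 1e-8)
})

test_that("noise-free rigid pairs recover the exact truth mapping", {
  ref <- gen_synthetic_structure(seed = 87)$structure
  qry <- gen_synthetic_structure(seed = 87, rot_axis = c(1, 1, 0),
                                 rot_angle = 2.1,
                                 translation = c(25, -8, 12))$structure
  sup <- superpose_iterative(ref, qry)
  expect_equal(sup$pairs$ref_res, sup$pairs$query_res)
  expect_equal(nrow(sup$pairs), length(ref$resno))
  expect_lt(sup$rmsd_ca, 1e-6)
})

test_that("planted insertions appear as unaligned runs with true anchors", {
  ref <- gen_synthetic_structure(seed = 88)$structure
  g <- gen_synthetic_structure(seed = 88, expansion_len = 30,
                               noise_sigma = 0.3, rot_axis = c(0, 1, 2),
                               rot_angle = 1.2, translation = c(5, 5, -10))
  sup <- superpose_iterative(ref, g$structure)
  ex <- detect_structural_expansions(sup)
  expect_equal(nrow(ex), 1)
  expect_lte(abs(ex$query_start - g$truth$insertion_start), 2)
  expect_lte(abs(ex$query_end - g$truth$insertion_end), 2)
  expect_lt(sup$rmsd_ca, 0.7)  # paired core stays tight at sigma = 0.3

  # identical structures: no expansions; short insertions stay below min_run
  expect_equal(nrow(detect_structural_expansions(
    superpose_iterative(ref, ref))), 0)
  g6 <- gen_synthetic_structure(seed = 88, expansion_len = 6)
  sup6 <- superpose_iterative(ref, g6$structure)
  expect_equal(nrow(detect_structural_expansions(sup6, min_run = 10)), 0)
})

test_that("bins partition pairs and respect the 1.5/2.7 edges", {
  expect_equal(bin_residue_pairs(c(0.2, 2.0, 5.0)),
               c("high", "medium", "low"))
  # boundary membership: closed middle interval
  expect_equal(bin_residue_pairs(c(1.5, 2.7)), c("medium", "medium"))
  expect_error(bin_residue_pairs(-1), "negative")
  s <- gen_synthetic_structure(seed = 89)$structure
  q <- gen_synthetic_structure(seed = 89, noise_sigma = 1.2)$structure
  sup <- superpose_iterative(s, q)
  tb <- table(factor(sup$pairs$bin, levels = c("high", "medium", "low")))
  expect_equal(sum(tb), nrow(sup$pairs))
})

test_that("global RMSD follows the isotropic-noise expectation", {
  # single pair at 2 A
  a <- matrix(c(0, 0, 0), 1, 3); b <- matrix(c(2, 0, 0), 1, 3)
  fake <- structure(list(pairs = data.frame(dist = 2), rmsd_ca = 2,
                         rmsd_all_atom = 2), class = "srb_superposition")
  expect_equal(global_rmsd(fake, "calpha"), 2.0)
  expect_error(global_rmsd(structure(list(pairs = data.frame()),
                                     class = "srb_superposition")),
               "empty")
  # sigma = 0.3 per coordinate: E[RMSD-ca] ~ sigma * sqrt(3), within 20%
  ref <- gen_synthetic_structure(seed = 90)$structure
  q_base <- gen_synthetic_structure(seed = 90)$structure  # same base geometry
  set.seed(91)
  rmsds <- vapply(1:25, function(k) {
    q <- q_base
    q$ca <- q$ca + matrix(rnorm(length(q$ca), 0, 0.3), ncol = 3)
    superpose_iterative(ref, q, seed = "identity")$rmsd_ca
  }, numeric(1))
  expect_equal(mean(rmsds), 0.3 * sqrt(3), tolerance = 0.2)
})
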