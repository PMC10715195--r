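# Synthetic-data generators.  Every downstream stage is testable without
# external data: sequences with known TM-CD36-TM architecture and planted
# motifs/cysteines/expansions, gold alignments built constructively (so
# truth columns are exact), idealized beta-barrel + apex-helix structures
# with optional planted insertions, and cavity test shapes with analytic
# void volumes.

# background alphabet for ectodomains and tails: hydrophilic enough that
# the Kyte-Doolittle predictor can never call a TM inside them, and free
# of cysteine so planted cysteine pairs are unambiguous
SOLUBLE_AA <- c("D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T", "Y")
# TM segments are built from strongly hydrophobic residues (KD >= 3.8)
# so the hydropathy predictor and the truth labels cannot disagree even
# in the worst-case window composition
TM_AA <- c("I", "L", "V")
TM_LEN <- 21L

rand_seq <- function(n, alphabet = SOLUBLE_AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# sample one integer uniformly from [lo, hi] (safe for lo == hi)
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

plant <- function(seq, at, insert) {
  # overwrite substring starting at `at` (1-based) with `insert`
  paste0(substr(seq, 1, at - 1L), insert,
         substr(seq, at + nchar(insert), nchar(seq)))
}

#' Generate a synthetic proteome with known architecture labels
#'
#' SR-B-like sequences have the layout N-tail | TM1 | ectodomain (with
#' planted motifs, cysteine pairs and an optional expansion insertion) |
#' TM2 | C-tail.  Decoys each violate exactly one architecture condition:
#' `no_tm` lacks both TM helices, `single_tm` lacks TM2, `fused` has an
#' over-long N-terminal tail (a suspected gene-model fusion), and
#' `non_cd36` has the SR-B layout but no CD36 domain hit.
#'
#' @param n_taxa Number of taxa.
#' @param seqs_per_taxon Sequences per taxon.
#' @param ecto_len_range Length-2 vector: ectodomain base-length range in
#'   residues (min >= 50).
#' @param expansion_len Length of the lineage-specific insertion planted
#'   into each SR-B ectodomain (0 = none).
#' @param expansion_anchor Ectodomain position after which the insertion
#'   is placed.
#' @param motif_specs List of `list(id, consensus, pos)` motifs planted at
#'   ectodomain positions.
#' @param cys_pairs List of length-2 integer vectors: ectodomain positions
#'   of planted cysteine pairs.
#' @param decoy_mix Named fractions `c(no_tm=, single_tm=, fused=,
#'   non_cd36=)` summing to at most 1; the remainder are SR-Bs.
#' @param fused_tail_len N-tail length of fused decoys (default 800).
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return A list with `seqs` (id, taxon, seq), `truth` (per-sequence
#'   label and spans), `hits` (domain-hit rows) and `tms` (TM rows).
#' @export
gen_synthetic_proteome <- function(n_taxa = 3L, seqs_per_taxon = 4L,
                                   ecto_len_range = c(367L, 616L),
                                   expansion_len = 0L,
                                   expansion_anchor = 200L,
                                   motif_specs = list(),
                                   cys_pairs = list(),
                                   decoy_mix = c(no_tm = 0, single_tm = 0,
                                                 fused = 0, non_cd36 = 0),
                                   fused_tail_len = 800L,
                                   seed = 1L) {
  stopifnot(ecto_len_range[1] >= 50L, sum(decoy_mix) <= 1)
  decoy_mix <- decoy_mix[c("no_tm", "single_tm", "fused", "non_cd36")]
  decoy_mix[is.na(decoy_mix)] <- 0
  names(decoy_mix) <- c("no_tm", "single_tm", "fused", "non_cd36")
  set.seed(seed)
  seq_rows <- list(); truth_rows <- list(); hit_rows <- list(); tm_rows <- list()
  for (t in seq_len(n_taxa)) {
    taxon <- sprintf("taxon%02d", t)
    n_decoy <- floor(decoy_mix * seqs_per_taxon)
    labels <- c(rep("cd36_no_tm", n_decoy["no_tm"]),
                rep("cd36_partial_tm", n_decoy["single_tm"]),
                rep("fused_suspect", n_decoy["fused"]),
                rep("non_cd36", n_decoy["non_cd36"]))
    labels <- c(labels, rep("SR-B", seqs_per_taxon - length(labels)))
    for (j in seq_len(seqs_per_taxon)) {
      id <- sprintf("t%02d_s%03d", t, j)
      label <- labels[j]
      n_tail_len <- if (label == "fused_suspect") fused_tail_len
                    else sample_range(10L, 60L)
      c_tail_len <- sample_range(10L, 60L)
      ecto_len <- sample_range(ecto_len_range[1], ecto_len_range[2])
      ecto <- rand_seq(ecto_len)
      # plant motifs and cysteines into the base ectodomain
      spans <- list()
      for (ms in motif_specs) {
        w <- nchar(ms$consensus)
        if (ms$pos < 1 || ms$pos + w - 1L > ecto_len) {
          stop(sprintf("infeasible motif planting: %s at %d (ectodomain %d aa)",
                       ms$id, ms$pos, ecto_len), call. = FALSE)
        }
        for (sp in spans) {
          if (ms$pos <= sp[2] && ms$pos + w - 1L >= sp[1]) {
            stop("infeasible planting: overlapping planted elements",
                 call. = FALSE)
          }
        }
        spans[[length(spans) + 1L]] <- c(ms$pos, ms$pos + w - 1L)
        ecto <- plant(ecto, ms$pos, ms$consensus)
      }
      for (cp in cys_pairs) {
        if (any(cp < 1 | cp > ecto_len)) {
          stop("infeasible cysteine planting outside ectodomain", call. = FALSE)
        }
        for (p in cp) ecto <- plant(ecto, p, "C")
      }
      # expansion insertion shifts everything after the anchor
      exp_span_ecto <- c(NA_integer_, NA_integer_)
      has_expansion <- expansion_len > 0L && label == "SR-B"
      if (has_expansion) {
        if (expansion_anchor < 1L || expansion_anchor >= ecto_len) {
          stop("expansion_anchor outside ectodomain", call. = FALSE)
        }
        ins <- rand_seq(expansion_len)
        ecto <- paste0(substr(ecto, 1, expansion_anchor), ins,
                       substr(ecto, expansion_anchor + 1L, ecto_len))
        exp_span_ecto <- c(expansion_anchor + 1L,
                           expansion_anchor + expansion_len)
        ecto_len <- ecto_len + expansion_len
      }
      shift_pos <- function(p) {
        p <- as.integer(p)
        if (has_expansion && p > expansion_anchor) p + as.integer(expansion_len) else p
      }
      tm1 <- rand_seq(TM_LEN, TM_AA)
      tm2 <- rand_seq(TM_LEN, TM_AA)
      n_tail <- rand_seq(n_tail_len)
      c_tail <- rand_seq(c_tail_len)
      has_tm1 <- !(label == "cd36_no_tm")
      has_tm2 <- !(label %in% c("cd36_no_tm", "cd36_partial_tm"))
      seg1 <- if (has_tm1) tm1 else rand_seq(TM_LEN)
      seg2 <- if (has_tm2) tm2 else rand_seq(TM_LEN)
      full <- paste0(n_tail, seg1, ecto, seg2, c_tail)
      tm1_span <- c(n_tail_len + 1L, n_tail_len + TM_LEN)
      ecto_span <- c(n_tail_len + TM_LEN + 1L, n_tail_len + TM_LEN + ecto_len)
      tm2_span <- c(ecto_span[2] + 1L, ecto_span[2] + TM_LEN)
      if (has_tm1) {
        tm_rows[[length(tm_rows) + 1L]] <- data.frame(
          seq_id = id, start = tm1_span[1], end = tm1_span[2],
          stringsAsFactors = FALSE)
      }
      if (has_tm2) {
        tm_rows[[length(tm_rows) + 1L]] <- data.frame(
          seq_id = id, start = tm2_span[1], end = tm2_span[2],
          stringsAsFactors = FALSE)
      }
      if (label != "non_cd36") {
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          seq_id = id, domain_name = "CD36", seq_len = nchar(full),
          env_start = ecto_span[1] + 5L, env_end = ecto_span[2] - 5L,
          bit_score = 250.0, e_value = 1e-50, included = TRUE,
          stringsAsFactors = FALSE)
      }
      seq_rows[[length(seq_rows) + 1L]] <- data.frame(
        id = id, taxon = taxon, seq = full, stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        id = id, taxon = taxon, label = label,
        tm1_start = if (has_tm1) tm1_span[1] else NA_integer_,
        tm1_end = if (has_tm1) tm1_span[2] else NA_integer_,
        ecto_start = if (label %in% c("SR-B", "fused_suspect")) ecto_span[1] else NA_integer_,
        ecto_end = if (label %in% c("SR-B", "fused_suspect")) ecto_span[2] else NA_integer_,
        tm2_start = if (has_tm2) tm2_span[1] else NA_integer_,
        tm2_end = if (has_tm2) tm2_span[2] else NA_integer_,
        expansion_start = exp_span_ecto[1], expansion_end = exp_span_ecto[2],
        cys_ecto = paste(vapply(cys_pairs, function(cp)
          paste(vapply(cp, shift_pos, 0L), collapse = ","), ""),
          collapse = ";"),
        motifs_ecto = paste(vapply(motif_specs, function(ms)
          sprintf("%s:%d", ms$id, shift_pos(ms$pos)), ""), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  list(seqs = do.call(rbind, seq_rows),
       truth = do.call(rbind, truth_rows),
       hits = do.call(rbind, hit_rows),
       tms = do.call(rbind, tm_rows))
}

#' Write a synthetic proteome fixture to disk
#'
#' Writes `sequences.fasta`, `hits.domtblout` (HMMER per-domain table
#' dialect), `tm.tmhmm` (TMHMM long-output dialect), and `truth.tsv`.
#'
#' @param prot Result of [gen_synthetic_proteome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_proteome_fixture <- function(prot, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_records(prot$seqs$id, prot$seqs$seq,
                      file.path(dir, "sequences.fasta"), taxa = prot$seqs$taxon)
  write_domtblout(prot$hits, file.path(dir, "hits.domtblout"))
  write_tmhmm(prot$tms, file.path(dir, "tm.tmhmm"))
  write_tsv(prot$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Write domain hits in the HMMER domtblout dialect
#'
#' @param hits Data frame with `seq_id`, `domain_name`, `seq_len`,
#'   `env_start`, `env_end`, `bit_score`, `e_value`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domtblout <- function(hits, path) {
  header <- c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target")
  lines <- character(0)
  if (!is.null(hits) && nrow(hits) > 0) {
    lines <- sprintf(
      "%-20s -          %5d %-20s PF01130.10 %6d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d 0.98 -",
      hits$seq_id, hits$seq_len, hits$domain_name, 400L,
      hits$e_value, hits$bit_score, 0.1, 1L, 1L, hits$e_value, hits$e_value,
      hits$bit_score, 0.1, 1L, 400L,
      hits$env_start + 2L, hits$env_end - 2L, hits$env_start, hits$env_end)
  }
  writeLines(c(header, lines, "#"), path)
  invisible(path)
}

#' Write TM segments in the TMHMM long-output dialect
#'
#' @param tms Data frame with `seq_id`, `start`, `end`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tmhmm <- function(tms, path) {
  lines <- character(0)
  if (!is.null(tms) && nrow(tms) > 0) {
    lines <- sprintf("%s\tTMHMM2.0\tTMhelix\t%d\t%d",
                     tms$seq_id, tms$start, tms$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a gold alignment with exact truth columns
#'
#' All rows descend from one ancestor sequence; per-row point
#' substitutions and lineage-specific insertions are applied, and the
#' alignment is built constructively (ancestor columns plus one gap-column
#' block per insertion), so expansion columns and planted cysteine
#' columns are known exactly rather than estimated by an aligner.
#'
#' @param n_rows Number of rows; ids are `row1..rowN` (row1 is commonly
#'   used as the reference).
#' @param ancestor_len Ancestor length in residues (ignored when
#'   `ancestor` is given).
#' @param ancestor Optional explicit ancestor residue string.
#' @param cys_pairs List of length-2 vectors of ancestor positions where
#'   cysteine pairs are planted (all rows inherit them unless mutated).
#' @param insertions List of `list(row, anchor, len, seq = NULL)`:
#'   insertion of `len` residues (or the explicit `seq`) after ancestor
#'   position `anchor` in one row.
#' @param mutations List of `list(row, pos, aa)`: point substitutions at
#'   ancestor positions.
#' @param sub_rate Per-site random substitution probability applied to
#'   every non-reference row (planted cysteine sites are protected).
#' @param seed Integer seed.
#' @return A list with `alignment` (`srb_alignment`), `truth`: `ancestor`,
#'   `cys_cols` (alignment columns of each planted pair),
#'   `insertions` (data frame row id, col_start, col_end, len, anchor).
#' @export
gen_gold_alignment <- function(n_rows = 5L, ancestor_len = 300L,
                               ancestor = NULL,
                               cys_pairs = list(),
                               insertions = list(),
                               mutations = list(),
                               sub_rate = 0,
                               seed = 1L) {
  set.seed(seed)
  if (is.null(ancestor)) ancestor <- rand_seq(ancestor_len)
  ancestor_len <- nchar(ancestor)
  for (cp in cys_pairs) for (p in cp) ancestor <- plant(ancestor, p, "C")
  protected <- unlist(cys_pairs)
  anc_res <- split_residues(ancestor)
  rows_res <- replicate(n_rows, anc_res, simplify = FALSE)
  ids <- sprintf("row%d", seq_len(n_rows))
  if (sub_rate > 0) {
    for (i in 2:n_rows) {
      hit <- which(stats::runif(ancestor_len) < sub_rate)
      hit <- setdiff(hit, protected)
      if (length(hit) > 0) {
        rows_res[[i]][hit] <- sample(SOLUBLE_AA, length(hit), replace = TRUE)
      }
    }
  }
  for (mu in mutations) rows_res[[mu$row]][mu$pos] <- mu$aa
  # resolve insertion sequences
  ins <- lapply(insertions, function(x) {
    if (is.null(x$seq)) x$seq <- rand_seq(x$len)
    x$len <- nchar(x$seq)
    x
  })
  ord <- order(vapply(ins, function(x) x$anchor, 0),
               vapply(ins, function(x) x$row, 0))
  ins <- ins[ord]
  # assemble alignment columns: ancestor columns with insertion blocks
  gapped <- lapply(rows_res, function(r) r)
  # build per-row lists of column characters
  out_rows <- vector("list", n_rows)
  for (i in seq_len(n_rows)) out_rows[[i]] <- character(0)
  truth_ins <- list()
  pos_cursor <- 0L
  col_of_anc <- integer(ancestor_len)
  cur_col <- 0L
  k <- 1L
  for (p in 0:ancestor_len) {
    if (p > 0) {
      cur_col <- cur_col + 1L
      col_of_anc[p] <- cur_col
      for (i in seq_len(n_rows)) {
        out_rows[[i]] <- c(out_rows[[i]], rows_res[[i]][p])
      }
    }
    while (k <= length(ins) && ins[[k]]$anchor == p) {
      block <- ins[[k]]
      bl <- block$len
      bres <- split_residues(block$seq)
      for (i in seq_len(n_rows)) {
        out_rows[[i]] <- c(out_rows[[i]],
                           if (i == block$row) bres else rep("-", bl))
      }
      truth_ins[[length(truth_ins) + 1L]] <- data.frame(
        row_id = ids[block$row], col_start = cur_col + 1L,
        col_end = cur_col + bl, len = bl, anchor = block$anchor,
        stringsAsFactors = FALSE)
      cur_col <- cur_col + bl
      k <- k + 1L
    }
  }
  gapped <- vapply(out_rows, paste, "", collapse = "")
  aln <- new_alignment(ids, gapped)
  cys_cols <- lapply(cys_pairs, function(cp) col_of_anc[cp])
  truth_ins_df <- if (length(truth_ins) == 0) {
    data.frame(row_id = character(), col_start = integer(),
               col_end = integer(), len = integer(), anchor = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, truth_ins)
  }
  list(alignment = aln,
       truth = list(ancestor = ancestor, cys_cols = cys_cols,
                    insertions = truth_ins_df, col_of_ancestor = col_of_anc))
}

# points of an ideal alpha helix: rise 1.5 A/residue, 100 deg/residue,
# radius 2.3 A, axis `u` (unit), starting at `origin`
ideal_helix_points <- function(n, origin, u, phase = 0) {
  u <- u / sqrt(sum(u^2))
  # orthonormal frame
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u; v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  i <- seq_len(n) - 1
  ang <- phase + i * 100 * pi / 180
  t(vapply(seq_len(n), function(k) {
    origin + u * (1.5 * i[k]) + 2.3 * (cos(ang[k]) * v + sin(ang[k]) * w)
  }, numeric(3)))
}

#' Generate an idealized SR-B-like structure
#'
#' A CA-trace toy of the CD36 ectodomain fold: an asymmetric beta-barrel
#' core (cylinder-wall strands, alternating direction, 3.3 A rise with a
#' 0.94 A zigzag so consecutive CA-CA distances are ~3.8 A) topped by an
#' apex helix stack of ideal alpha-helices, with an optional expansion
#' hairpin (two antiparallel ideal helices excursing away from the apex)
#' inserted at a declared residue position.  An optional rigid transform
#' and isotropic Gaussian coordinate noise are applied last.
#'
#' @param n_strands Number of barrel strands (default 8).
#' @param strand_len Residues per strand (default 10).
#' @param barrel_radius Barrel radius in Angstrom (default 9).
#' @param apex_helices Integer vector of apex helix lengths (default
#'   `c(12, 12, 12)`, a three-helix bundle).
#' @param expansion_len Residues in the inserted expansion hairpin
#'   (0 = none).
#' @param expansion_at Residue index after which the expansion is
#'   inserted (default: middle of the last apex helix).
#' @param noise_sigma Gaussian noise standard deviation per coordinate in
#'   Angstrom.
#' @param rot_axis,rot_angle,translation Optional rigid transform
#'   (axis-angle rotation in radians plus translation) applied to all
#'   coordinates.
#' @param plddt Optional per-residue confidence; default constant 75.
#' @param id Structure id.
#' @param seed Integer seed (controls residue types, insertion types and
#'   noise; the base geometry and sequence are identical across calls
#'   that share a seed, regardless of `expansion_len`).
#' @return A list with `structure` (`srb_structure`) and `truth`
#'   (`insertion_start`, `insertion_end` in residue numbering, NA when
#'   no expansion).
#' @export
gen_synthetic_structure <- function(n_strands = 8L, strand_len = 10L,
                                    barrel_radius = 9,
                                    apex_helices = c(12L, 12L, 12L),
                                    expansion_len = 0L, expansion_at = NULL,
                                    noise_sigma = 0,
                                    rot_axis = NULL, rot_angle = 0,
                                    translation = c(0, 0, 0),
                                    plddt = NULL, id = "synthetic",
                                    seed = 1L) {
  stopifnot(noise_sigma >= 0)
  set.seed(seed)
  pts <- list()
  # barrel: strands on a cylinder wall, alternating direction
  for (s in seq_len(n_strands)) {
    theta <- 2 * pi * (s - 1) / n_strands
    zig <- 0.94 * (-1)^(seq_len(strand_len))
    rr <- barrel_radius + zig
    z <- (seq_len(strand_len) - 1) * 3.3
    if (s %% 2 == 0) z <- rev(z)
    pts[[s]] <- cbind(rr * cos(theta), rr * sin(theta), z)
  }
  z_top <- (strand_len - 1) * 3.3
  # apex: stacked ideal helices above the barrel mouth
  for (h in seq_along(apex_helices)) {
    len <- apex_helices[h]
    u <- if (h %% 2 == 1) c(1, 0, 0) else c(0, 1, 0)
    origin <- c(-0.75 * len * u[1], -0.75 * len * u[2],
                z_top + 4 + (h - 1) * 5.5)
    pts[[length(pts) + 1L]] <- ideal_helix_points(len, origin, u)
  }
  xyz <- do.call(rbind, pts)
  n_base <- nrow(xyz)
  aa <- sample(AA20, n_base, replace = TRUE)
  truth <- c(NA_integer_, NA_integer_)
  if (expansion_len > 0L) {
    if (is.null(expansion_at)) {
      expansion_at <- n_base - floor(apex_helices[length(apex_helices)] / 2)
    }
    anchor <- xyz[expansion_at, ]
    outward <- c(anchor[1], anchor[2], 0)
    no <- sqrt(sum(outward^2))
    outward <- if (no > 1e-6) outward / no else c(1, 0, 0)
    u <- c(0.4 * outward[1], 0.4 * outward[2], 1)
    u <- u / sqrt(sum(u^2))
    v <- c(-outward[2], outward[1], 0)
    l1 <- ceiling(expansion_len / 2)
    l2 <- expansion_len - l1
    leg1 <- ideal_helix_points(l1, anchor + 4.2 * u, u)
    ins_xyz <- leg1
    if (l2 > 0) {
      leg2 <- ideal_helix_points(l2, leg1[l1, ] + 4.5 * v, -u)
      ins_xyz <- rbind(leg1, leg2)
    }
    ins_aa <- sample(AA20, expansion_len, replace = TRUE)
    xyz <- rbind(xyz[seq_len(expansion_at), , drop = FALSE], ins_xyz,
                 xyz[(expansion_at + 1L):n_base, , drop = FALSE])
    aa <- c(aa[seq_len(expansion_at)], ins_aa,
            aa[(expansion_at + 1L):n_base])
    truth <- c(expansion_at + 1L, expansion_at + expansion_len)
  }
  if (!is.null(rot_axis) && rot_angle != 0) {
    xyz <- xyz %*% t(rotation_matrix(rot_axis, rot_angle))
  }
  xyz <- sweep(xyz, 2, translation, "+")
  if (noise_sigma > 0) {
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma),
                        ncol = 3)
  }
  n <- nrow(xyz)
  if (is.null(plddt)) plddt <- rep(75, n)
  atoms <- data.frame(resno = seq_len(n), aa = aa, atom = "CA",
                      element = "C", x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], b = plddt, stringsAsFactors = FALSE)
  list(structure = new_structure(id, atoms, plddt = plddt),
       truth = list(insertion_start = truth[1], insertion_end = truth[2]))
}

#' Axis-angle rotation matrix
#'
#' @param axis Length-3 axis (normalized internally).
#' @param angle Angle in radians.
#' @return A 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + s_ * K + (1 - c_) * (K %*% K)
}

#' Generate a pseudo-atom cavity test shape
#'
#' Shapes with analytic ground truth under the default probe radii and
#' van der Waals table (carbon pseudo-atoms, r = 1.7 A; small probe
#' 0.9 A): `rod` is a solid cylinder with zero internal void, `tube` is
#' an open hollow cylinder whose channel classifies as a tunnel, and
#' `shell` is a closed hollow sphere whose internal void volume is
#' `4/3 * pi * inner_radius^3`.
#'
#' @param shape `"rod"`, `"tube"` or `"shell"`.
#' @param dims Named list: `radius` and `length` for rod/tube (tube
#'   `radius` is the wall-center radius), `inner_radius` for shell (the
#'   void radius under the default probes; wall centers sit at
#'   `inner_radius + 1.7 + 0.9`).
#' @param spacing_hint Approximate pseudo-atom spacing in Angstrom
#'   (default 1.2; rod uses a 1.5 A lattice).
#' @param id Structure id.
#' @return An `srb_structure`-classed pseudo-atom cloud (no CA trace)
#'   with a `truth` attribute (`class`, `void_volume`).
#' @export
gen_cavity_shape <- function(shape = c("rod", "tube", "shell"),
                             dims = list(), spacing_hint = 1.2,
                             id = shape[1]) {
  shape <- match.arg(shape)
  if (shape == "rod") {
    r <- dims$radius %||% 4
    L <- dims$length %||% 20
    g <- expand.grid(x = seq(-r, r, by = 1.5),
                     y = seq(-r, r, by = 1.5),
                     z = seq(0, L, by = 1.5))
    g <- g[g$x^2 + g$y^2 <= r^2, , drop = FALSE]
    xyz <- as.matrix(g)
    truth <- list(class = "none", void_volume = 0)
  } else if (shape == "tube") {
    r <- dims$radius %||% 4
    L <- dims$length %||% 20
    n_ring <- ceiling(2 * pi * r / spacing_hint)
    zs <- seq(0, L, by = spacing_hint)
    xyz <- do.call(rbind, lapply(zs, function(z) {
      ang <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
      cbind(r * cos(ang), r * sin(ang), z)
    }))
    truth <- list(class = "tunnel",
                  void_volume = pi * max(0, r - 2.6)^2 * L)
  } else {
    ir <- dims$inner_radius %||% 6
    R <- ir + VDW_DEFAULT + 0.9
    n <- ceiling(4 * pi * R^2 / spacing_hint^2)
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    xyz <- cbind(R * sin(phi) * cos(theta), R * sin(phi) * sin(theta),
                 R * cos(phi))
    truth <- list(class = "cavity", void_volume = 4 / 3 * pi * ir^3)
  }
  n <- nrow(xyz)
  atoms <- data.frame(resno = seq_len(n), aa = "X", atom = "PS",
                      element = "C", x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], b = 0, stringsAsFactors = FALSE)
  out <- structure(list(id = id, atoms = atoms, resno = seq_len(n),
                        aa = NULL, ca = NULL, plddt = NULL, ptm = NULL),
                   class = "srb_structure")
  attr(out, "truth") <- truth
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
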