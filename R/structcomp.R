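# Structure comparison: PDB I/O, per-residue confidence classes, Kabsch
# superposition, iterative spatial-adjacency residue pairing, RMSD-calpha
# binning, and detection of unaligned expansion segments.

#' Construct a structure object
#'
#' @param id Structure identifier.
#' @param atoms Data frame with columns `resno`, `aa` (one-letter),
#'   `atom` (atom name, e.g. `"CA"`), `element`, `x`, `y`, `z`, `b`.
#' @param plddt Optional per-residue confidence in `[0, 100]` (one value
#'   per residue, in residue order).
#' @param ptm Optional model-level predicted TM score in `[0, 1]`.
#' @return An object of class `srb_structure`: the atom table plus
#'   `resno` (ordered residue numbers), `aa` (per-residue types), `ca`
#'   (n x 3 coordinate matrix) and the confidence fields.
#' @export
new_structure <- function(id, atoms, plddt = NULL, ptm = NULL) {
  stopifnot(all(c("resno", "aa", "atom", "element", "x", "y", "z", "b")
                %in% names(atoms)))
  if (nrow(atoms) == 0) stop("empty structure", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  resno <- unique(atoms$resno)
  ca_rows <- atoms[atoms$atom == "CA", , drop = FALSE]
  missing_ca <- setdiff(resno, ca_rows$resno)
  if (length(missing_ca) > 0) {
    stop("residue(s) without CA atom: ",
         paste(utils::head(missing_ca, 5), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(ca_rows$resno)
  if (any(dup)) {
    warning("duplicate CA atoms; keeping first occurrence")
    ca_rows <- ca_rows[!dup, , drop = FALSE]
  }
  ca <- as.matrix(ca_rows[c("x", "y", "z")])
  rownames(ca) <- ca_rows$resno
  aa <- ca_rows$aa
  if (!is.null(plddt)) stopifnot(length(plddt) == length(resno))
  structure(list(id = id, atoms = atoms, resno = resno, aa = aa, ca = ca,
                 plddt = plddt, ptm = ptm),
            class = "srb_structure")
}

#' @export
print.srb_structure <- function(x, ...) {
  cat(sprintf("srb_structure %s: %d residues, %d atoms%s%s\n",
              x$id, length(x$resno), nrow(x$atoms),
              if (!is.null(x$plddt)) sprintf(", mean pLDDT %.1f", mean(x$plddt)) else "",
              if (!is.null(x$ptm)) sprintf(", pTM %.2f", x$ptm) else ""))
  invisible(x)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM records via [bio3d::read.pdb()].  For predicted models
#' (`predicted = TRUE`) the B-factor column is stored as per-residue
#' pLDDT (the value at each residue's CA atom), following the ColabFold
#' convention.
#'
#' @param path PDB file path.
#' @param chain Optional chain selector.
#' @param predicted Treat B-factors as pLDDT (default FALSE).
#' @param ptm Optional model-level pTM to attach.
#' @param id Structure id (default: file name without extension).
#' @param require_ca Require one CA per residue (default TRUE; disable
#'   for pseudo-atom shapes).
#' @return An `srb_structure` (or, with `require_ca = FALSE`, a
#'   structure whose `ca`/`aa` fields may be incomplete).
#' @export
read_structure <- function(path, chain = NULL, predicted = FALSE, ptm = NULL,
                           id = NULL, require_ca = TRUE) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot read PDB ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path, call. = FALSE)
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  aa1[is.na(aa1) | !(aa1 %in% AA_WITH_X)] <- "X"
  atoms <- data.frame(resno = at$resno, aa = aa1, atom = at$elety,
                      element = ifelse(is.na(at$elesy) | at$elesy == "",
                                       substr(at$elety, 1, 1), at$elesy),
                      x = at$x, y = at$y, z = at$z, b = at$b,
                      stringsAsFactors = FALSE)
  dup <- duplicated(atoms[c("resno", "atom")])
  if (any(dup)) {
    warning("duplicate atoms in ", id, "; keeping first occurrence")
    atoms <- atoms[!dup, , drop = FALSE]
  }
  if (!require_ca) {
    return(structure(list(id = id, atoms = atoms,
                          resno = unique(atoms$resno), aa = NULL, ca = NULL,
                          plddt = NULL, ptm = ptm), class = "srb_structure"))
  }
  plddt <- NULL
  if (predicted) {
    ca_rows <- atoms[atoms$atom == "CA", , drop = FALSE]
    plddt <- ca_rows$b[!duplicated(ca_rows$resno)]
  }
  new_structure(id, atoms, plddt = plddt, ptm = ptm)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-width ATOM records; per-residue confidence (when present)
#' is written into the B-factor column, else `b` is used.
#'
#' @param struct An `srb_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure_pdb <- function(struct, path) {
  at <- struct$atoms
  aa3 <- vapply(at$aa, function(a) {
    out <- suppressWarnings(bio3d::aa123(a))
    if (is.na(out) || nchar(out) != 3) "UNK" else out
  }, "")
  b <- at$b
  if (!is.null(struct$plddt)) {
    b <- struct$plddt[match(at$resno, struct$resno)]
  }
  lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom),
    aa3, at$resno, at$x, at$y, at$z, 1.0, b, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Classify per-residue pLDDT confidence
#'
#' @param struct An `srb_structure` with pLDDT present.
#' @param hi Lower bound of the high class (default 90).
#' @param lo Lower bound of the moderate class (default 70; the lower
#'   bound is inclusive).
#' @return Character vector over residues: `high` (`pLDDT >= hi`),
#'   `moderate` (`lo <= pLDDT < hi`) or `low`.
#' @export
classify_plddt <- function(struct, hi = 90, lo = 70) {
  if (is.null(struct$plddt)) stop("structure has no pLDDT", call. = FALSE)
  ifelse(struct$plddt >= hi, "high",
         ifelse(struct$plddt >= lo, "moderate", "low"))
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `ref` and the transformed `mov` (`mov %*% t(R) + t`), with the
#' reflection corrected via the SVD determinant sign.
#'
#' @param ref,mov Numeric n x 3 matrices of paired points (n >= 3,
#'   non-degenerate).
#' @return A list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3), `rmsd`.
#' @export
kabsch <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  stopifnot(ncol(ref) == 3, ncol(mov) == 3)
  n <- nrow(ref)
  if (n != nrow(mov)) stop("point sets differ in size", call. = FALSE)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  cr <- colMeans(ref); cm <- colMeans(mov)
  A <- sweep(ref, 2, cr); B <- sweep(mov, 2, cm)
  if (any(svd(B)$d[2] < 1e-9, svd(A)$d[2] < 1e-9)) {
    stop("degenerate (collinear) point set", call. = FALSE)
  }
  H <- t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  moved <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - A)^2)))
  translation <- as.numeric(cr - cm %*% t(R))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

# apply a kabsch fit to an n x 3 coordinate matrix
apply_transform <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
}

# Monotone (order-preserving) residue matching over a distance matrix.
# Global DP maximizing sum over pairs of (d_pair - d_ij), pairs allowed
# only when d_ij <= d_pair; gaps cost 0.  Rows are vectorized (the
# within-row max-propagation is a cummax), traceback recomputes choices.
monotone_match <- function(D, d_pair) {
  n <- nrow(D); m <- ncol(D)
  S <- d_pair - D
  S[D > d_pair] <- -Inf
  M <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    diag_score <- M[i, 1:m] + S[i, ]
    a <- pmax(diag_score, M[i, 2:(m + 1L)])
    M[i + 1L, 2:(m + 1L)] <- cummax(pmax(a, M[i + 1L, 1L]))
  }
  # traceback (prefer the diagonal so tied registers keep maximal pairs)
  pairs_i <- integer(0); pairs_j <- integer(0)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    here <- M[i + 1L, j + 1L]
    if (is.finite(S[i, j]) && abs(M[i, j] + S[i, j] - here) < 1e-12 &&
        S[i, j] >= 0) {
      pairs_i <- c(pairs_i, i); pairs_j <- c(pairs_j, j)
      i <- i - 1L; j <- j - 1L
    } else if (abs(M[i, j + 1L] - here) < 1e-12) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  cbind(ref = rev(pairs_i), query = rev(pairs_j))
}

# Seed pairing from a global sequence alignment of residue types.
seed_pairs_sequence <- function(ref_aa, query_aa) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(ref_aa, collapse = "")),
    Biostrings::AAString(paste(query_aa, collapse = "")),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  p <- split_residues(as.character(Biostrings::alignedPattern(pa)))
  s <- split_residues(as.character(Biostrings::alignedSubject(pa)))
  pi_ <- cumsum(p != "-"); si <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  cbind(ref = pi_[keep], query = si[keep])
}

#' Superpose two structures with iterative spatial-adjacency pairing
#'
#' Starting from a seed residue pairing (a global sequence alignment of
#' the residue types, or the identity mapping), alternates (i) a Kabsch
#' fit on the current pairs with (ii) re-pairing by a monotone matching
#' that maximizes spatial adjacency subject to every CA-CA pair distance
#' being at most `d_pair`.  Iteration stops when the pair set is stable
#' or after `max_iter` rounds.
#'
#' @param ref,query `srb_structure` objects with CA traces.
#' @param seed `"sequence"` or `"identity"`.
#' @param d_pair Maximum CA-CA distance for a residue pair in Angstrom
#'   (default 5.0).
#' @param max_iter Maximum iterations (default 20).
#' @param bin_edges RMSD-calpha bin edges in Angstrom (default
#'   `c(1.5, 2.7)`).
#' @return An object of class `srb_superposition`: `rotation`,
#'   `translation` (mapping query onto ref), `pairs` (data frame
#'   `ref_res`, `query_res`, `dist`, `bin`), `rmsd_ca`, `rmsd_all_atom`,
#'   `unaligned_ref`, `unaligned_query` (residue numbers in no pair),
#'   `converged`, `n_iter`.
#' @export
superpose_iterative <- function(ref, query, seed = c("sequence", "identity"),
                                d_pair = 5.0, max_iter = 20L,
                                bin_edges = c(1.5, 2.7)) {
  seed <- match.arg(seed)
  if (is.null(ref$ca) || is.null(query$ca)) {
    stop("both structures need CA traces", call. = FALSE)
  }
  nr <- nrow(ref$ca); nq <- nrow(query$ca)
  pairs <- if (seed == "identity") {
    n <- min(nr, nq)
    cbind(ref = seq_len(n), query = seq_len(n))
  } else {
    seed_pairs_sequence(ref$aa, query$aa)
  }
  if (nrow(pairs) < 3) stop("no usable seed pairs found", call. = FALSE)
  converged <- FALSE
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- kabsch(ref$ca[pairs[, "ref"], , drop = FALSE],
                  query$ca[pairs[, "query"], , drop = FALSE])
    moved <- apply_transform(query$ca, fit)
    D2 <- outer(rowSums(ref$ca^2), rep(1, nq)) +
      outer(rep(1, nr), rowSums(moved^2)) -
      2 * ref$ca %*% t(moved)
    D2[D2 < 0] <- 0   # guard tiny negative values from cancellation
    D <- sqrt(D2)
    new_pairs <- monotone_match(D, d_pair)
    if (nrow(new_pairs) == nrow(pairs) &&
        all(new_pairs == pairs)) {
      converged <- TRUE
      pairs <- new_pairs
      break
    }
    pairs <- new_pairs
    if (nrow(pairs) < 3) stop("pairing collapsed below 3 residues", call. = FALSE)
  }
  n_iter <- if (converged) it else max_iter
  fit <- kabsch(ref$ca[pairs[, "ref"], , drop = FALSE],
                query$ca[pairs[, "query"], , drop = FALSE])
  moved_ca <- apply_transform(query$ca, fit)
  dists <- sqrt(rowSums((ref$ca[pairs[, "ref"], , drop = FALSE] -
                           moved_ca[pairs[, "query"], , drop = FALSE])^2))
  bins <- bin_residue_pairs(dists, edges = bin_edges)
  pair_df <- data.frame(ref_res = ref$resno[pairs[, "ref"]],
                        query_res = query$resno[pairs[, "query"]],
                        dist = dists, bin = bins, stringsAsFactors = FALSE)
  rmsd_ca <- sqrt(mean(dists^2))
  rmsd_aa <- all_atom_rmsd(ref, query, pairs, fit)
  structure(list(ref_id = ref$id, query_id = query$id,
                 rotation = fit$rotation, translation = fit$translation,
                 pairs = pair_df, rmsd_ca = rmsd_ca, rmsd_all_atom = rmsd_aa,
                 unaligned_ref = setdiff(ref$resno, pair_df$ref_res),
                 unaligned_query = setdiff(query$resno, pair_df$query_res),
                 query_resno = query$resno,
                 converged = converged, n_iter = n_iter),
            class = "srb_superposition")
}

# all-atom RMSD over atoms shared by name within paired residues
all_atom_rmsd <- function(ref, query, pairs, fit) {
  ra <- ref$atoms; qa <- query$atoms
  rxyz <- list(); qxyz <- list()
  for (k in seq_len(nrow(pairs))) {
    rres <- ref$resno[pairs[k, "ref"]]
    qres <- query$resno[pairs[k, "query"]]
    r <- ra[ra$resno == rres, , drop = FALSE]
    q <- qa[qa$resno == qres, , drop = FALSE]
    common <- intersect(r$atom, q$atom)
    if (length(common) == 0) next
    rxyz[[k]] <- as.matrix(r[match(common, r$atom), c("x", "y", "z")])
    qxyz[[k]] <- as.matrix(q[match(common, q$atom), c("x", "y", "z")])
  }
  R <- do.call(rbind, rxyz); Q <- do.call(rbind, qxyz)
  if (is.null(R) || nrow(R) == 0) return(NA_real_)
  moved <- apply_transform(Q, fit)
  sqrt(mean(rowSums((R - moved)^2)))
}

#' @export
print.srb_superposition <- function(x, ...) {
  cat(sprintf("srb_superposition %s vs %s: %d pairs, RMSD-ca %.3f A%s\n",
              x$ref_id, x$query_id, nrow(x$pairs), x$rmsd_ca,
              if (x$converged) "" else " (not converged)"))
  tb <- table(factor(x$pairs$bin, levels = c("high", "medium", "low")))
  cat(sprintf("  bins: high %d, medium %d, low %d; unaligned: %d ref, %d query\n",
              tb["high"], tb["medium"], tb["low"],
              length(x$unaligned_ref), length(x$unaligned_query)))
  invisible(x)
}

#' Bin residue-pair RMSD-calpha distances
#'
#' Distances are binned by the crystallographic-resolution scheme:
#' `high` below `edges[1]`, `medium` in the closed interval
#' `[edges[1], edges[2]]`, `low` above `edges[2]`.
#'
#' @param d Non-negative distances in Angstrom.
#' @param edges Bin edges (default `c(1.5, 2.7)`).
#' @return Character vector of bin labels.
#' @export
bin_residue_pairs <- function(d, edges = c(1.5, 2.7)) {
  if (any(d < 0)) stop("negative distance", call. = FALSE)
  ifelse(d < edges[1], "high", ifelse(d <= edges[2], "medium", "low"))
}

#' Detect unaligned expansion segments in a superposition
#'
#' Maximal runs of at least `min_run` consecutive unaligned query
#' residues, each anchored by the last paired reference residue before
#' and the first after the run; runs touching a chain terminus carry a
#' one-sided anchor and are flagged `terminal`.
#'
#' @param result An `srb_superposition`.
#' @param min_run Minimum run length in residues (default 10).
#' @return Data frame with columns `query_start`, `query_end`, `length`,
#'   `ref_before`, `ref_after`, `terminal`.
#' @export
detect_structural_expansions <- function(result, min_run = 10L) {
  resno <- result$query_resno
  unal <- resno %in% result$unaligned_query
  runs <- logical_runs(unal)
  runs <- runs[runs$length >= min_run, , drop = FALSE]
  out <- lapply(seq_len(nrow(runs)), function(k) {
    qs <- resno[runs$start[k]]; qe <- resno[runs$end[k]]
    paired <- result$pairs
    before <- paired$ref_res[paired$query_res < qs]
    after <- paired$ref_res[paired$query_res > qe]
    data.frame(query_start = qs, query_end = qe, length = runs$length[k],
               ref_before = if (length(before)) max(before) else NA_integer_,
               ref_after = if (length(after)) min(after) else NA_integer_,
               terminal = length(before) == 0 || length(after) == 0,
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0) {
    return(data.frame(query_start = integer(), query_end = integer(),
                      length = integer(), ref_before = integer(),
                      ref_after = integer(), terminal = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Global RMSD of a superposition
#'
#' @param result An `srb_superposition`.
#' @param scope `"calpha"` (over paired CA atoms) or `"all_atom"` (over
#'   atoms shared by name within paired residues).
#' @return RMSD in Angstrom.
#' @export
global_rmsd <- function(result, scope = c("calpha", "all_atom")) {
  scope <- match.arg(scope)
  if (nrow(result$pairs) == 0) stop("empty pairing", call. = FALSE)
  if (scope == "calpha") result$rmsd_ca else result$rmsd_all_atom
}
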