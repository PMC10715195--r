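# Alignment analytics: coordinate maps, gap filtering, consensus,
# conservation, identity, lineage-specific expansion columns, and
# disulfide-bridge cysteine homolog mapping.

#' Construct an alignment object
#'
#' @param ids Row identifiers.
#' @param gapped Equal-length gapped residue strings (`-` for gaps).
#' @return An object of class `srb_alignment`: `ids`, `gapped`, `n_cols`,
#'   `col2res` (per row, alignment column -> ungapped residue index, NA at
#'   gaps) and `res2col` (per row, residue index -> alignment column).
#' @export
new_alignment <- function(ids, gapped) {
  stopifnot(length(ids) == length(gapped), length(ids) > 0)
  ids <- unname(ids); gapped <- unname(gapped)
  widths <- nchar(gapped)
  if (length(unique(widths)) != 1) {
    bad <- ids[widths != widths[1]][1]
    stop(sprintf("ragged alignment: row %s has width %d (expected %d)",
                 bad, nchar(gapped[ids == bad][1]), widths[1]), call. = FALSE)
  }
  col2res <- lapply(gapped, function(s) {
    ch <- split_residues(s)
    idx <- cumsum(ch != "-")
    idx[ch == "-"] <- NA_integer_
    as.integer(idx)
  })
  res2col <- lapply(col2res, function(m) which(!is.na(m)))
  structure(list(ids = ids, gapped = gapped, n_cols = widths[1],
                 col2res = col2res, res2col = res2col),
            class = "srb_alignment")
}

#' @export
print.srb_alignment <- function(x, ...) {
  cat(sprintf("srb_alignment: %d rows x %d columns\n",
              length(x$ids), x$n_cols))
  invisible(x)
}

#' Ungapped sequences of an alignment
#'
#' @param aln An `srb_alignment`.
#' @return Named character vector of ungapped residue strings.
#' @export
ungap_alignment <- function(aln) {
  setNames(gsub("-", "", aln$gapped, fixed = TRUE), aln$ids)
}

#' Read an aligned FASTA file
#'
#' @param path Aligned FASTA path.
#' @return An `srb_alignment` with column maps built.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0) stop("empty alignment stream", call. = FALSE)
  ids <- vapply(strsplit(names(ss), "[ \t]+"), `[`, "", 1L)
  new_alignment(ids, as.character(ss))
}

#' Write an alignment to aligned FASTA
#'
#' @param aln An `srb_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  write_fasta_records(aln$ids, aln$gapped, path)
}

# character matrix view (rows x columns) of an alignment
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$gapped, "", fixed = TRUE))
}

#' Filter alignment columns by gap fraction
#'
#' A declared simplification of block-based alignment trimming: a column
#' is kept iff its gap fraction is at most `max_gap_frac`.  The surviving
#' original column indices are returned so downstream coordinates can be
#' lifted back to the unfiltered alignment.
#'
#' @param aln An `srb_alignment`.
#' @param max_gap_frac Maximum tolerated gap fraction (default 0.8).
#' @return A list with `alignment` (filtered `srb_alignment`) and
#'   `kept_cols` (original column indices).
#' @export
gap_filter <- function(aln, max_gap_frac = 0.8) {
  stopifnot(max_gap_frac > 0, max_gap_frac <= 1)
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == "-")
  kept <- which(gap_frac <= max_gap_frac)
  gapped <- apply(m[, kept, drop = FALSE], 1, paste, collapse = "")
  list(alignment = new_alignment(aln$ids, gapped), kept_cols = kept)
}

#' Majority-rule consensus sequence
#'
#' Columns whose non-gap occupancy is at least `min_occupancy` emit their
#' modal residue (ties broken alphabetically); other columns emit
#' nothing.
#'
#' @param aln An `srb_alignment`.
#' @param min_occupancy Minimum non-gap fraction for a column to be
#'   represented (default 0.5).
#' @return A single residue string.
#' @export
consensus <- function(aln, min_occupancy = 0.5) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) / n >= min_occupancy && length(res) > 0) {
      tab <- table(res)
      cand <- names(tab)[tab == max(tab)]
      out <- c(out, sort(cand)[1])
    }
  }
  paste(out, collapse = "")
}

#' Per-column conservation
#'
#' Conservation of a column is the count of its modal non-gap residue
#' divided by the total number of rows (so gappy columns score low); an
#' all-gap column scores 0.  The 40% mask used for structure coloring is
#' `conservation(aln) >= 0.40`.
#'
#' @param aln An `srb_alignment`.
#' @return Numeric vector in `[0, 1]`, one value per column.
#' @export
conservation <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  vapply(seq_len(ncol(m)), function(j) {
    res <- m[, j][m[, j] != "-"]
    if (length(res) == 0) return(0)
    max(table(res)) / n
  }, numeric(1))
}

#' Mean pairwise sequence identity
#'
#' For each unordered row pair, identity is the number of columns with
#' identical residues divided by the number of columns where both rows
#' have residues (gap columns are excluded from the denominator).  Pairs
#' with zero co-occupied columns contribute 0 and are flagged.
#'
#' @param aln An `srb_alignment` with at least two rows.
#' @return A list with `mean` (mean pairwise identity), `pairs` (data
#'   frame id_a, id_b, identity, n_cooccupied) and `n_flagged` (pairs
#'   with no co-occupied columns).
#' @export
mean_pairwise_identity <- function(aln) {
  n <- length(aln$ids)
  if (n < 2) stop("mean_pairwise_identity needs at least 2 rows", call. = FALSE)
  m <- aln_matrix(aln)
  out <- list(); k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      nb <- sum(both)
      ident <- if (nb == 0) 0 else sum(m[i, both] == m[j, both]) / nb
      k <- k + 1L
      out[[k]] <- data.frame(id_a = aln$ids[i], id_b = aln$ids[j],
                             identity = ident, n_cooccupied = nb,
                             stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out)
  list(mean = mean(pairs$identity), pairs = pairs,
       n_flagged = sum(pairs$n_cooccupied == 0))
}

#' Detect lineage-specific expansion columns
#'
#' For every non-reference row, finds maximal runs of at least `min_run`
#' consecutive columns that are gaps in the reference row and residues in
#' the focal row — the alignment signature of a lineage-specific
#' insertion.  Each run is anchored by the reference residue indices
#' immediately before and after it.
#'
#' @param aln An `srb_alignment`.
#' @param ref_id Reference row id.
#' @param min_run Minimum insertion length in residues (default 10).
#' @return Data frame with columns `seq_id`, `col_start`, `col_end`,
#'   `n_residues`, `res_start`, `res_end` (focal-row residue span),
#'   `ref_before`, `ref_after` (anchoring reference residue indices, NA
#'   at termini).
#' @export
detect_expansion_columns <- function(aln, ref_id, min_run = 10L) {
  ri <- match(ref_id, aln$ids)
  if (is.na(ri)) stop("unknown ref_id: ", ref_id, call. = FALSE)
  m <- aln_matrix(aln)
  ref_gap <- m[ri, ] == "-"
  ref_map <- aln$col2res[[ri]]
  out <- list()
  for (i in seq_along(aln$ids)) {
    if (i == ri) next
    mask <- ref_gap & m[i, ] != "-"
    runs <- logical_runs(mask)
    runs <- runs[runs$length >= min_run, , drop = FALSE]
    for (k in seq_len(nrow(runs))) {
      cs <- runs$start[k]; ce <- runs$end[k]
      before_cols <- which(!is.na(ref_map[seq_len(cs - 1)]))
      after_cols <- which(!is.na(ref_map)) ; after_cols <- after_cols[after_cols > ce]
      out[[length(out) + 1L]] <- data.frame(
        seq_id = aln$ids[i], col_start = cs, col_end = ce,
        n_residues = runs$length[k],
        res_start = aln$col2res[[i]][cs], res_end = aln$col2res[[i]][ce],
        ref_before = if (length(before_cols)) ref_map[max(before_cols)] else NA_integer_,
        ref_after = if (length(after_cols)) ref_map[min(after_cols)] else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(seq_id = character(), col_start = integer(),
                      col_end = integer(), n_residues = integer(),
                      res_start = integer(), res_end = integer(),
                      ref_before = integer(), ref_after = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Map disulfide-bridge cysteine homologs across an alignment
#'
#' Reference cysteine pair positions are lifted to alignment columns;
#' each row is scanned at those columns plus/minus `tolerance` for a
#' cysteine.  A pair is `present` when both positions match; any matched
#' cysteine that sits inside one of the row's lineage-specific expansion
#' runs makes the call `excluded_expansion` (the false-positive rule);
#' otherwise the pair is `absent`.
#'
#' @param aln An `srb_alignment`.
#' @param ref_id Reference row id.
#' @param ref_pairs List of length-2 integer vectors: reference residue
#'   positions of each bridge's cysteines.
#' @param tolerance Column jitter tolerance (default 2).
#' @param expansions Optional expansion-run data frame from
#'   [detect_expansion_columns()] for this alignment; when NULL it is
#'   computed with the default `min_run`.
#' @return Data frame with columns `seq_id`, `bridge_id`, `col_a`,
#'   `col_b`, `pos_a`, `pos_b` (query residue indices, NA when
#'   unmatched), `status`.
#' @export
map_bridge_cysteines <- function(aln, ref_id, ref_pairs, tolerance = 2L,
                                 expansions = NULL) {
  ri <- match(ref_id, aln$ids)
  if (is.na(ri)) stop("unknown ref_id: ", ref_id, call. = FALSE)
  ref_seq <- split_residues(ungap_alignment(aln)[[ri]])
  for (p in ref_pairs) {
    if (any(ref_seq[p] != "C")) {
      stop(sprintf("reference position(s) %s are not cysteine",
                   paste(p[ref_seq[p] != "C"], collapse = ", ")),
           call. = FALSE)
    }
  }
  if (is.null(expansions)) expansions <- detect_expansion_columns(aln, ref_id)
  m <- aln_matrix(aln)
  res2col_ref <- aln$res2col[[ri]]
  out <- list()
  for (i in seq_along(aln$ids)) {
    if (i == ri) next
    exp_i <- expansions[expansions$seq_id == aln$ids[i], , drop = FALSE]
    in_expansion <- function(col) {
      nrow(exp_i) > 0 && any(col >= exp_i$col_start & col <= exp_i$col_end)
    }
    find_cys <- function(col) {
      win <- max(1L, col - tolerance):min(aln$n_cols, col + tolerance)
      hits <- win[m[i, win] == "C"]
      if (length(hits) == 0) return(NA_integer_)
      hits[which.min(abs(hits - col))]
    }
    for (b in seq_along(ref_pairs)) {
      cols <- res2col_ref[ref_pairs[[b]]]
      hit_a <- find_cys(cols[1]); hit_b <- find_cys(cols[2])
      in_exp <- (!is.na(hit_a) && in_expansion(hit_a)) ||
        (!is.na(hit_b) && in_expansion(hit_b))
      status <- if (in_exp) "excluded_expansion"
        else if (!is.na(hit_a) && !is.na(hit_b)) "present" else "absent"
      out[[length(out) + 1L]] <- data.frame(
        seq_id = aln$ids[i], bridge_id = b,
        col_a = cols[1], col_b = cols[2],
        pos_a = if (is.na(hit_a)) NA_integer_ else aln$col2res[[i]][hit_a],
        pos_b = if (is.na(hit_b)) NA_integer_ else aln$col2res[[i]][hit_b],
        status = status, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
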