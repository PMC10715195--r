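# Position-weight-matrix motif scanning with STREME-style sequence
# scores.  The sequence score of a motif match is the sum of the PWM
# position weights over the best-scoring window; scores below the motif's
# match threshold are disregarded, and raw scores are reported on a 0-100
# scale for heatmaps.

#' Construct a motif PWM object
#'
#' Weights are log2 odds of position probabilities versus the background,
#' both regularized with an additive pseudocount:
#' `w = log2((p + pseudocount) / (bg + pseudocount))`.
#'
#' @param motif_id Motif identifier.
#' @param probs Numeric matrix, width x 20 (columns named by residue),
#'   rows summing to ~1.
#' @param background Named background frequencies over the 20 residues
#'   (default uniform).
#' @param match_threshold Raw-score cutoff below which a match is
#'   disregarded (default 0).
#' @param pseudocount Additive pseudocount (default 0.01).
#' @param p_value,e_value Discovery statistics carried as metadata.
#' @return An object of class `srb_pwm` with elements `motif_id`,
#'   `width`, `probs`, `weights`, `background`, `match_threshold`,
#'   `p_value`, `e_value`.
#' @export
new_pwm <- function(motif_id, probs, background = NULL,
                    match_threshold = 0, pseudocount = 0.01,
                    p_value = NA_real_, e_value = NA_real_) {
  stopifnot(is.matrix(probs), ncol(probs) == 20)
  if (is.null(colnames(probs))) colnames(probs) <- AA20
  probs <- probs[, AA20, drop = FALSE]
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA20)
  background <- background[AA20]
  if (abs(sum(background) - 1) > 0.01) {
    stop("background frequencies must sum to 1", call. = FALSE)
  }
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 0.01)) {
    stop(sprintf("PWM row %d sums to %.4f (expected ~1)",
                 which(abs(rs - 1) > 0.01)[1], rs[abs(rs - 1) > 0.01][1]),
         call. = FALSE)
  }
  weights <- log2(sweep(probs + pseudocount, 2, background + pseudocount, "/"))
  structure(list(motif_id = motif_id, width = nrow(probs), probs = probs,
                 weights = weights, background = background,
                 match_threshold = match_threshold,
                 p_value = p_value, e_value = e_value),
            class = "srb_pwm")
}

#' @export
print.srb_pwm <- function(x, ...) {
  cat(sprintf("srb_pwm %s: width %d, match_threshold %.3f\n",
              x$motif_id, x$width, x$match_threshold))
  invisible(x)
}

#' Build a PWM from aligned motif sites
#'
#' Column frequencies of the (equal-length, ungapped) site sequences are
#' converted to log2-odds weights against the background, with the same
#' pseudocount convention as [new_pwm()].
#'
#' @param sites Character vector of equal-length ungapped sites.
#' @param motif_id Motif identifier.
#' @inheritParams new_pwm
#' @return An `srb_pwm`.
#' @export
pwm_from_sites <- function(sites, motif_id = "motif", background = NULL,
                           match_threshold = 0, pseudocount = 0.01) {
  stopifnot(length(sites) > 0)
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("ragged motif sites", call. = FALSE)
  for (s in sites) check_residues(s, allow_x = FALSE, what = "motif site")
  m <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  probs <- t(vapply(seq_len(w), function(j) {
    tab <- table(factor(m[, j], levels = AA20))
    as.numeric(tab) / length(sites)
  }, numeric(20)))
  colnames(probs) <- AA20
  new_pwm(motif_id, probs, background = background,
          match_threshold = match_threshold, pseudocount = pseudocount)
}

#' Read motifs from a MEME minimal motif file
#'
#' Parses the MEME minimal format (version line, `ALPHABET=`, optional
#' `Background letter frequencies` block, `MOTIF` blocks with
#' `letter-probability matrix:` headers).  An optional `threshold=` token
#' on the letter-probability line sets the match threshold (0 when
#' absent).  Probabilities are converted to log2-odds weights with the
#' package pseudocount convention.
#'
#' @param path MEME-format file path.
#' @param pseudocount Additive pseudocount (default 0.01).
#' @return A list of `srb_pwm` objects.
#' @export
read_meme_motifs <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- setNames(rep(1 / 20, 20), AA20)
  bg_line <- grep("^Background letter frequencies", lines)
  if (length(bg_line) == 1) {
    toks <- character(0)
    k <- bg_line + 1
    while (k <= length(lines) && !grepl("^\\s*$", lines[k]) &&
           !grepl("^MOTIF", lines[k])) {
      toks <- c(toks, strsplit(trimws(lines[k]), "\\s+")[[1]])
      k <- k + 1
    }
    if (length(toks) %% 2 == 0 && length(toks) > 0) {
      letters <- toks[seq(1, length(toks), by = 2)]
      freqs <- as.numeric(toks[seq(2, length(toks), by = 2)])
      bg[letters[letters %in% AA20]] <- freqs[letters %in% AA20]
      bg <- bg / sum(bg)
    }
  }
  motif_at <- grep("^MOTIF\\s", lines)
  pwms <- list()
  for (mi in seq_along(motif_at)) {
    i <- motif_at[mi]
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    j <- i + 1
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) j <- j + 1
    if (j > length(lines)) stop("MOTIF block without letter-probability matrix: ", id,
                                call. = FALSE)
    hdr <- lines[j]
    getnum <- function(key, default = NA_real_) {
      m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([0-9eE.+-]+)"), hdr))[[1]]
      if (length(m) == 2) as.numeric(m[2]) else default
    }
    w <- as.integer(getnum("w"))
    if (is.na(w)) stop("letter-probability header without w= for motif ", id,
                       call. = FALSE)
    evalue <- getnum("E")
    thresh <- getnum("threshold", 0)
    probs <- matrix(NA_real_, w, 20, dimnames = list(NULL, AA20))
    for (r in seq_len(w)) {
      vals <- as.numeric(strsplit(trimws(lines[j + r]), "\\s+")[[1]])
      if (length(vals) != 20) {
        stop(sprintf("motif %s: probability row %d has %d values (expected 20)",
                     id, r, length(vals)), call. = FALSE)
      }
      probs[r, ] <- vals
    }
    pwms[[mi]] <- new_pwm(id, probs, background = bg,
                          match_threshold = thresh,
                          pseudocount = pseudocount, e_value = evalue)
  }
  pwms
}

#' Write motifs in MEME minimal motif format
#'
#' @param pwms A list of `srb_pwm` objects (their probability matrices
#'   are written; the match threshold is stored as a `threshold=` token).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_meme_motifs <- function(pwms, path) {
  bg <- pwms[[1]]$background
  out <- c("MEME version 5", "",
           paste0("ALPHABET= ", paste(AA20, collapse = "")), "",
           "Background letter frequencies",
           paste(sprintf("%s %.6f", AA20, bg), collapse = " "), "")
  for (p in pwms) {
    out <- c(out, paste("MOTIF", p$motif_id),
             sprintf("letter-probability matrix: alength= 20 w= %d threshold= %.12g E= %.3g",
                     p$width, p$match_threshold,
                     if (is.na(p$e_value)) 1 else p$e_value),
             apply(p$probs, 1, function(r) paste(sprintf("%.12g", r), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

# integer encoding of a residue string against AA20; 0 = unknown (X etc.)
encode_residues <- function(seq) {
  idx <- match(split_residues(seq), AA20)
  idx[is.na(idx)] <- 0L
  idx
}

#' Score a sequence against a motif PWM
#'
#' The raw sequence score is the maximum over all windows of the summed
#' position weights (residues outside the 20-letter alphabet contribute
#' 0).  Sequences shorter than the motif width yield a defined no-hit
#' result with raw score `-Inf`.
#'
#' @param seq Residue string.
#' @param pwm An `srb_pwm`.
#' @return A one-row data frame: `motif_id`, `start` (best window start,
#'   NA for no-hit), `raw`, `passes` (`raw >= match_threshold`).
#' @export
score_sequence <- function(seq, pwm) {
  n <- nchar(seq)
  w <- pwm$width
  if (n < w) {
    return(data.frame(motif_id = pwm$motif_id, start = NA_integer_,
                      raw = -Inf, passes = FALSE, stringsAsFactors = FALSE))
  }
  idx <- encode_residues(seq)
  n_win <- n - w + 1L
  scores <- numeric(n_win)
  W <- pwm$weights
  for (j in seq_len(w)) {
    r <- idx[j:(j + n_win - 1L)]
    contrib <- numeric(n_win)
    known <- r > 0L
    contrib[known] <- W[j, ][r[known]]
    scores <- scores + contrib
  }
  best <- which.max(scores)
  data.frame(motif_id = pwm$motif_id, start = best, raw = scores[best],
             passes = scores[best] >= pwm$match_threshold,
             stringsAsFactors = FALSE)
}

#' Theoretical score range of a PWM
#'
#' @param pwm An `srb_pwm`.
#' @return Numeric vector `c(min, max)`: sums of per-position minimum and
#'   maximum weights.
#' @export
pwm_score_range <- function(pwm) {
  c(min = sum(apply(pwm$weights, 1, min)),
    max = sum(apply(pwm$weights, 1, max)))
}

#' Scale raw motif scores to 0-100
#'
#' Per-motif linear min-max map against the motif's theoretical score
#' extrema: `scaled = 100 * (raw - min) / (max - min)`, clipped to
#' `[0, 100]`; the no-hit sentinel (`-Inf`) maps to 0.  Degenerate motifs
#' (zero score range) scale everything to 0 with a warning.
#'
#' @param raw Numeric vector of raw scores for one motif.
#' @param pwm The corresponding `srb_pwm`.
#' @return Numeric vector of scaled scores in `[0, 100]`.
#' @export
scale_scores <- function(raw, pwm) {
  rng <- pwm_score_range(pwm)
  if (rng["max"] - rng["min"] <= 0) {
    warning("degenerate motif ", pwm$motif_id, ": zero score range")
    return(rep(0, length(raw)))
  }
  scaled <- 100 * (raw - rng["min"]) / (rng["max"] - rng["min"])
  scaled[!is.finite(raw)] <- 0
  pmin(100, pmax(0, scaled))
}

#' Motif presence heatmap across a sequence cohort
#'
#' @param seqs Named character vector of sequences (names are ids) or a
#'   data frame with columns `id`, `seq`.
#' @param pwms List of `srb_pwm` objects.
#' @return A list with `scaled` (sequence x motif matrix of 0-100
#'   scores), `raw`, `passes` (logical matrix), `starts`, and
#'   `pass_fraction` (per-motif fraction of sequences passing their
#'   match threshold).
#' @export
motif_presence <- function(seqs, pwms) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  ids <- names(seqs)
  nm <- vapply(pwms, function(p) p$motif_id, "")
  raw <- matrix(NA_real_, length(seqs), length(pwms), dimnames = list(ids, nm))
  starts <- matrix(NA_integer_, length(seqs), length(pwms),
                   dimnames = list(ids, nm))
  passes <- matrix(FALSE, length(seqs), length(pwms), dimnames = list(ids, nm))
  scaled <- raw
  for (k in seq_along(pwms)) {
    for (i in seq_along(seqs)) {
      h <- score_sequence(seqs[[i]], pwms[[k]])
      raw[i, k] <- h$raw; starts[i, k] <- h$start; passes[i, k] <- h$passes
    }
    if (length(seqs) > 0) scaled[, k] <- scale_scores(raw[, k], pwms[[k]])
  }
  pf <- if (length(seqs) == 0) setNames(numeric(length(pwms)), nm)
        else colMeans(passes)
  list(scaled = scaled, raw = raw, passes = passes, starts = starts,
       pass_fraction = pf)
}
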