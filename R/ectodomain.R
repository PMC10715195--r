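# Ectodomain extraction, sanitization, and length analytics.

#' Extract the CD36 ectodomain from an architecture call
#'
#' Returns the substring strictly between TM1 and TM2.  For sequences
#' with multiple CD36 domains the call already anchors on the first
#' (smallest `env_start`) domain, so the span flanking that domain is
#' used.
#'
#' @param seq Full-length residue string.
#' @param call One-row architecture-call data frame (label must be
#'   `"SR-B"`).
#' @return A list with `seq_id`, `start`, `end`, `sequence`, `length`.
#' @export
extract_ectodomain <- function(seq, call) {
  stopifnot(nrow(call) == 1)
  if (is.na(call$label) || call$label != "SR-B") {
    stop(sprintf("cannot extract ectodomain from non-SR-B call (label %s)",
                 call$label), call. = FALSE)
  }
  st <- call$ecto_start; en <- call$ecto_end
  if (is.na(st) || is.na(en) || st > en || en > nchar(seq)) {
    stop("invalid ectodomain span in call", call. = FALSE)
  }
  list(seq_id = call$seq_id, start = st, end = en,
       sequence = substr(seq, st, en), length = en - st + 1L)
}

#' Replace undetermined residues with alanine
#'
#' Every `X` is replaced by `A` (a nonbulky, nonreactive residue), the
#' convention used before structure-prediction input.  Any character
#' outside the 20 amino acids and `X` is an error.
#'
#' @param seq Residue string.
#' @return A list with `sequence` (sanitized string) and `n_replaced`.
#' @export
sanitize_sequence <- function(seq) {
  check_residues(seq, allow_x = TRUE)
  n_x <- lengths(regmatches(seq, gregexpr("X", seq, fixed = TRUE)))
  list(sequence = gsub("X", "A", seq, fixed = TRUE),
       n_replaced = as.integer(n_x))
}

#' Ectodomain length analytics and the expansion flag
#'
#' Per-clade length summaries and a per-sequence flag marking ectodomains
#' longer than `flag_threshold` residues; long ectodomains carry
#' lineage-specific sequence expansions, so the default threshold is
#' 500 aa.
#'
#' @param ecto Data frame with columns `seq_id`, `length`, `taxon`.
#' @param clade_map Data frame with columns `taxon`, `clade`.
#' @param flag_threshold Length strictly above which `expansion_flag` is
#'   set (default 500).
#' @return A list with `per_seq` (seq_id, taxon, clade, length,
#'   expansion_flag) and `per_clade` (clade, n, min, median, max,
#'   n_flagged).
#' @export
length_stats <- function(ecto, clade_map, flag_threshold = 500L) {
  stopifnot(all(c("seq_id", "length", "taxon") %in% names(ecto)))
  unmapped <- setdiff(unique(ecto$taxon), clade_map$taxon)
  if (length(unmapped) > 0) {
    stop("taxon without clade mapping: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  per_seq <- data.frame(
    seq_id = ecto$seq_id, taxon = ecto$taxon,
    clade = clade_map$clade[match(ecto$taxon, clade_map$taxon)],
    length = as.integer(ecto$length),
    expansion_flag = ecto$length > flag_threshold,
    stringsAsFactors = FALSE)
  if (nrow(per_seq) == 0) {
    return(list(per_seq = per_seq,
                per_clade = data.frame(clade = character(), n = integer(),
                                       min = integer(), median = numeric(),
                                       max = integer(), n_flagged = integer())))
  }
  per_clade <- do.call(rbind, lapply(split(per_seq, per_seq$clade), function(d) {
    data.frame(clade = d$clade[1], n = nrow(d), min = min(d$length),
               median = stats::median(d$length), max = max(d$length),
               n_flagged = sum(d$expansion_flag), stringsAsFactors = FALSE)
  }))
  rownames(per_clade) <- NULL
  list(per_seq = per_seq, per_clade = per_clade)
}
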