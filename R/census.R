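# Census of CD36-domain proteins by transmembrane architecture.
#
# A bona fide class B scavenger receptor (SR-B) is operationally a protein
# with a CD36 ectodomain flanked by two transmembrane helices
# (TM-CD36-TM).  This module parses domain-hit and TM-topology tables (or
# predicts TM helices from hydropathy), removes exact duplicates within a
# taxon, and classifies each sequence.

#' Read a domain-hit table
#'
#' Parses either the HMMER `domtblout` per-domain table (whitespace
#' delimited, `#` comment lines) or a generic TSV with columns `seq_id`,
#' `domain_name`, `env_start`, `env_end`, `bit_score`, `e_value` and
#' optionally `included`.  Envelope coordinates define the domain span.
#'
#' For `domtblout` input the `included` flag is derived by comparing the
#' per-domain independent E-value against `inc_threshold` (the hmmsearch
#' default domain inclusion threshold), since that format carries no
#' explicit inclusion column.
#'
#' @param path Input file path.
#' @param dialect `"domtblout"` or `"tsv"`.
#' @param inc_threshold Independent E-value at or below which a domtblout
#'   row is marked included (default 0.01).
#' @return A data frame with columns `seq_id`, `domain_name`, `env_start`,
#'   `env_end`, `bit_score`, `e_value`, `included`.
#' @export
read_domain_hits <- function(path, dialect = c("domtblout", "tsv"),
                             inc_threshold = 0.01) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read_tsv(path)
    need <- c("seq_id", "domain_name", "env_start", "env_end",
              "bit_score", "e_value")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0) {
      stop("TSV hit table missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(df$included)) df$included <- df$e_value <= inc_threshold
    hits <- df[c(need, "included")]
  } else {
    lines <- readLines(path)
    hits_list <- list()
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (grepl("^\\s*#", ln) || !nzchar(trimws(ln))) next
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 22) {
        stop(sprintf("malformed domtblout row at line %d (%d fields)",
                     i, length(f)), call. = FALSE)
      }
      env_start <- suppressWarnings(as.integer(f[20]))
      env_end <- suppressWarnings(as.integer(f[21]))
      i_eval <- suppressWarnings(as.numeric(f[13]))
      score <- suppressWarnings(as.numeric(f[14]))
      if (anyNA(c(env_start, env_end, i_eval, score))) {
        stop(sprintf("malformed domtblout row at line %d", i), call. = FALSE)
      }
      hits_list[[length(hits_list) + 1L]] <- data.frame(
        seq_id = f[1], domain_name = f[4],
        env_start = env_start, env_end = env_end,
        bit_score = score, e_value = i_eval,
        included = i_eval <= inc_threshold,
        stringsAsFactors = FALSE, row.names = NULL)
    }
    hits <- if (length(hits_list) == 0) {
      data.frame(seq_id = character(), domain_name = character(),
                 env_start = integer(), env_end = integer(),
                 bit_score = numeric(), e_value = numeric(),
                 included = logical(), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, hits_list)
    }
  }
  bad <- which(hits$env_start < 1 | hits$env_end < hits$env_start)
  if (length(bad) > 0) {
    stop(sprintf("invalid envelope coordinates in hit table (row %d)", bad[1]),
         call. = FALSE)
  }
  hits
}

#' Read a transmembrane-segment table
#'
#' Accepts the TMHMM long-output dialect (whitespace-delimited rows whose
#' third field is `TMhelix`, with start/end as the last two fields) or a
#' generic TSV with columns `seq_id`, `start`, `end`.
#'
#' @param path Input file path.
#' @param dialect `"tmhmm"` or `"tsv"`.
#' @return A data frame with columns `seq_id`, `start`, `end`, `source`.
#' @export
read_tm_table <- function(path, dialect = c("tmhmm", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read_tsv(path)
    miss <- setdiff(c("seq_id", "start", "end"), names(df))
    if (length(miss) > 0) {
      stop("TM TSV missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    out <- data.frame(seq_id = df$seq_id, start = as.integer(df$start),
                      end = as.integer(df$end), source = "table",
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    keep <- grepl("TMhelix", lines, fixed = TRUE)
    rows <- lapply(which(keep), function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      n <- length(f)
      st <- suppressWarnings(as.integer(f[n - 1]))
      en <- suppressWarnings(as.integer(f[n]))
      if (anyNA(c(st, en))) {
        stop(sprintf("malformed TMhelix row at line %d", i), call. = FALSE)
      }
      data.frame(seq_id = f[1], start = st, end = en, source = "table",
                 stringsAsFactors = FALSE)
    })
    out <- if (length(rows) == 0) {
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 source = character(), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, rows)
    }
  }
  bad <- which(out$end < out$start)
  if (length(bad) > 0) {
    stop(sprintf("TM segment with end < start (row %d)", bad[1]),
         call. = FALSE)
  }
  out
}

#' Predict transmembrane segments from Kyte-Doolittle hydropathy
#'
#' A fallback TM predictor so the census runs without external topology
#' tools.  Mean hydropathy is computed over a sliding window; maximal runs
#' of window centers at or above `cutoff` become candidate segments.  Runs
#' shorter than 12 residues are discarded; runs longer than 40 residues
#' are trimmed to the 21-residue subwindow of maximal mean hydropathy.
#'
#' @param seq Residue string (20 amino acids + X; X scores 0).
#' @param window Odd window width (default 19).
#' @param cutoff Mean-hydropathy cutoff for a window center (default 1.6).
#' @return A data frame with columns `start`, `end`, `source`
#'   (`"hydropathy"`); empty when the sequence is shorter than the window.
#' @export
predict_tm_hydropathy <- function(seq, window = 19L, cutoff = 1.6) {
  stopifnot(window %% 2 == 1, window >= 3)
  res <- split_residues(seq)
  check_residues(seq)
  n <- length(res)
  if (n < window) {
    return(data.frame(start = integer(), end = integer(),
                      source = character(), stringsAsFactors = FALSE))
  }
  h <- unname(KD_SCALE[res])
  cs <- c(0, cumsum(h))
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(n - half)
  means <- (cs[centers + half + 1L] - cs[centers - half]) / window
  mask <- means >= cutoff
  runs <- logical_runs(mask)
  if (nrow(runs) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      source = character(), stringsAsFactors = FALSE))
  }
  # translate run indices (over centers) to residue coordinates
  runs$start <- centers[runs$start]
  runs$end <- centers[runs$end]
  runs$length <- runs$end - runs$start + 1L
  runs <- runs[runs$length >= 12L, , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(runs))) {
    st <- runs$start[k]; en <- runs$end[k]
    if (en - st + 1L > 40L) {
      # best 21-residue subwindow by mean hydropathy
      starts <- st:(en - 20L)
      sums <- cs[starts + 21L] - cs[starts]
      b <- starts[which.max(sums)]
      st <- b; en <- b + 20L
    }
    out[[k]] <- data.frame(start = st, end = en, source = "hydropathy",
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Collapse exact duplicate sequences within each taxon
#'
#' Within each taxon, sequences with identical residue strings are
#' collapsed to a single record; the lexicographically smallest id is
#' kept.  Identical sequences in different taxa are retained.
#'
#' @param seqs Data frame with columns `id`, `taxon`, `seq`.
#' @return The deduplicated data frame, in the original row order of the
#'   kept records.
#' @export
dedupe_identical <- function(seqs) {
  stopifnot(all(c("id", "taxon", "seq") %in% names(seqs)))
  if (nrow(seqs) == 0) return(seqs)
  key <- paste(seqs$taxon, seqs$seq, sep = "\r")
  keep_id <- tapply(seqs$id, key, function(ids) sort(ids)[1])
  out <- seqs[seqs$id %in% unname(keep_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the transmembrane architecture of one sequence
#'
#' Applies the TM-CD36-TM rule: a sequence is labeled `SR-B` when it has
#' at least one included CD36 domain hit and TM segments on both sides of
#' the first (smallest `env_start`) hit, each allowed to overlap the
#' domain envelope by at most `max_overlap` residues.  The ectodomain
#' span is the region strictly between those two TM segments.  Sequences
#' whose N-terminal region before TM1 exceeds `max_tail` residues are
#' labeled `fused_suspect` (suspected gene-model fusions).
#'
#' @param seq_id Sequence identifier.
#' @param seq_len Sequence length in residues.
#' @param hits Domain-hit data frame (see [read_domain_hits()]), already
#'   restricted to the CD36 domain name.
#' @param tms TM-segment data frame for this sequence, merged and sorted.
#' @param max_overlap Maximum TM/domain-envelope overlap (default 10).
#' @param max_tail N-tail length above which a sequence is flagged as a
#'   suspected fusion (default 400).
#' @return A one-row data frame: `seq_id`, `label` (one of `SR-B`,
#'   `cd36_no_tm`, `cd36_partial_tm`, `fused_suspect`, `non_cd36`),
#'   `n_cd36_domains`, `ecto_start`, `ecto_end`, `tm1_start`, `tm1_end`,
#'   `tm2_start`, `tm2_end` (NA where absent).
#' @export
classify_architecture <- function(seq_id, seq_len, hits, tms,
                                  max_overlap = 10L, max_tail = 400L) {
  empty <- data.frame(seq_id = seq_id, label = NA_character_,
                      n_cd36_domains = 0L,
                      ecto_start = NA_integer_, ecto_end = NA_integer_,
                      tm1_start = NA_integer_, tm1_end = NA_integer_,
                      tm2_start = NA_integer_, tm2_end = NA_integer_,
                      stringsAsFactors = FALSE)
  hits <- hits[hits$seq_id == seq_id & hits$included, , drop = FALSE]
  if (nrow(hits) == 0) {
    empty$label <- "non_cd36"
    return(empty)
  }
  if (any(hits$env_end > seq_len)) {
    stop(sprintf("domain hit extends beyond sequence %s", seq_id),
         call. = FALSE)
  }
  empty$n_cd36_domains <- nrow(hits)
  first <- hits[which.min(hits$env_start), , drop = FALSE]
  tms <- tms[tms$seq_id == seq_id | is.null(tms$seq_id), , drop = FALSE]
  tms <- tms[order(tms$start), , drop = FALSE]
  # qualifying flanks: TM1 ends before (env_start + max_overlap) and starts
  # before the domain; TM2 starts after (env_end - max_overlap)
  left <- tms[tms$end < first$env_start + max_overlap &
                tms$start < first$env_start, , drop = FALSE]
  right <- tms[tms$start > first$env_end - max_overlap, , drop = FALSE]
  has_left <- nrow(left) > 0
  has_right <- nrow(right) > 0
  if (has_left && has_right) {
    a <- left[which.max(left$end), , drop = FALSE]
    b <- right[which.min(right$start), , drop = FALSE]
    if (a$end >= b$start) {
      has_left <- FALSE; has_right <- FALSE
    } else if (a$start - 1L > max_tail) {
      empty$label <- "fused_suspect"
      empty$tm1_start <- a$start; empty$tm1_end <- a$end
      empty$tm2_start <- b$start; empty$tm2_end <- b$end
      return(empty)
    } else {
      empty$label <- "SR-B"
      empty$tm1_start <- a$start; empty$tm1_end <- a$end
      empty$tm2_start <- b$start; empty$tm2_end <- b$end
      empty$ecto_start <- a$end + 1L
      empty$ecto_end <- b$start - 1L
      return(empty)
    }
  }
  empty$label <- if (!has_left && !has_right) "cd36_no_tm" else "cd36_partial_tm"
  empty
}

#' Classify a whole cohort of sequences
#'
#' Vectorized wrapper around [classify_architecture()].
#'
#' @param seqs Data frame with columns `id`, `taxon`, `seq`.
#' @param hits Domain-hit data frame.
#' @param tms TM-segment data frame.
#' @param domain_name Domain to census (default `"CD36"`).
#' @inheritParams classify_architecture
#' @return A data frame with one architecture call per sequence plus the
#'   `taxon` column.
#' @export
classify_cohort <- function(seqs, hits, tms, domain_name = "CD36",
                            max_overlap = 10L, max_tail = 400L) {
  unknown <- setdiff(unique(hits$seq_id), seqs$id)
  if (length(unknown) > 0) {
    stop("hit table references unknown seq_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  hits <- hits[hits$domain_name == domain_name, , drop = FALSE]
  calls <- lapply(seq_len(nrow(seqs)), function(i) {
    classify_architecture(seqs$id[i], nchar(seqs$seq[i]), hits, tms,
                          max_overlap = max_overlap, max_tail = max_tail)
  })
  out <- do.call(rbind, calls)
  out$taxon <- seqs$taxon[match(out$seq_id, seqs$id)]
  out
}

#' Summarize a census of architecture calls
#'
#' @param calls Architecture-call data frame from [classify_cohort()].
#' @param clade_map Data frame with columns `taxon`, `clade`.
#' @return A list with `per_taxon` (taxon, clade, n_srb, n_cd36_hit),
#'   `per_clade` (clade, n_srb), and `totals` (n_cd36_hit vs n_srb).
#' @export
census_summary <- function(calls, clade_map) {
  if (nrow(calls) == 0) {
    return(list(per_taxon = data.frame(taxon = character(),
                                       clade = character(),
                                       n_srb = integer(),
                                       n_cd36_hit = integer()),
                per_clade = data.frame(clade = character(), n_srb = integer()),
                totals = data.frame(n_cd36_hit = 0L, n_srb = 0L)))
  }
  unmapped <- setdiff(unique(calls$taxon), clade_map$taxon)
  if (length(unmapped) > 0) {
    stop("taxon without clade mapping: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  calls$clade <- clade_map$clade[match(calls$taxon, clade_map$taxon)]
  is_hit <- calls$label != "non_cd36"
  is_srb <- calls$label == "SR-B"
  per_taxon <- aggregate(cbind(n_srb = is_srb, n_cd36_hit = is_hit),
                         by = list(taxon = calls$taxon, clade = calls$clade),
                         FUN = sum)
  per_taxon <- per_taxon[order(per_taxon$taxon), , drop = FALSE]
  rownames(per_taxon) <- NULL
  per_clade <- aggregate(list(n_srb = is_srb),
                         by = list(clade = calls$clade), FUN = sum)
  totals <- data.frame(n_cd36_hit = sum(is_hit), n_srb = sum(is_srb))
  list(per_taxon = per_taxon, per_clade = per_clade, totals = totals)
}
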