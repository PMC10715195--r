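# Pipeline orchestration: census -> ectodomain -> alignment/motif ->
# structure stages driven by one declarative config, with a
# machine-readable manifest so dataset-scale runs can be audited
# (counts in/out at every filter stage).

#' Build a run configuration
#'
#' Merges user settings over the package defaults.  Every
#' threshold used by the pipeline lives here rather than in code:
#' `flag_threshold` (ectodomain expansion flag, 500 aa),
#' `conservation_threshold` (0.40), `bin_edges` (RMSD-calpha bins 1.5 and
#' 2.7 A), `probe_small` (cavity probe 0.9 A), `ptm_gate` (structures
#' with pTM at or below 0.7 are skipped), `min_run` (expansion run length,
#' 10), `d_pair` (pairing cutoff 5 A), `max_overlap`, `max_tail`.
#'
#' @param ... Named overrides, or a single list/YAML path in `file`.
#' @param file Optional YAML file of settings.
#' @return A named list of class `srb_config`.
#' @export
srb_config <- function(..., file = NULL) {
  defaults <- list(
    fasta = NULL, hits = NULL, hits_dialect = "domtblout",
    tm = NULL, tm_dialect = "tmhmm", use_hydropathy = FALSE,
    clade_map = NULL, domain_name = "CD36",
    alignment = NULL, ref_id = NULL, bridge_pairs = NULL,
    motifs = NULL, structure_dir = NULL, ref_structure = NULL,
    ptm_table = NULL,
    out_dir = "srb_run",
    flag_threshold = 500, conservation_threshold = 0.40,
    bin_edges = c(1.5, 2.7), probe_small = 0.9, probe_bulk = 3.0,
    grid_spacing = 1.0, ptm_gate = 0.7, min_run = 10L,
    d_pair = 5.0, max_overlap = 10L, max_tail = 400L,
    bridge_tolerance = 2L, seed = 1L)
  user <- list(...)
  if (!is.null(file)) user <- utils::modifyList(yaml::read_yaml(file), user)
  cfg <- utils::modifyList(defaults, user)
  stopifnot(cfg$flag_threshold > 0, cfg$probe_small > 0,
            all(cfg$bin_edges > 0), cfg$ptm_gate > 0)
  structure(cfg, class = "srb_config")
}

check_inputs_exist <- function(paths) {
  paths <- unlist(paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the SR-B census stage
#'
#' Reads sequences, domain hits and TM segments (or predicts TM helices
#' from hydropathy), removes exact duplicates within each taxon, applies
#' the TM-CD36-TM architecture rule, extracts ectodomains from SR-B
#' calls, and writes the report bundle: `architecture.tsv`,
#' `census_per_taxon.tsv`, `census_per_clade.tsv`, `ectodomains.fasta`,
#' `lengths.tsv` and `manifest.json` (stage in/out counts).
#'
#' @param config An `srb_config` with at least `fasta`, `hits` (or
#'   `use_hydropathy = TRUE` and no `tm`), `clade_map`, `out_dir`.
#' @return Invisibly, a list with the architecture calls, census
#'   summary, length stats and the manifest.
#' @export
run_census <- function(config) {
  cfg <- if (inherits(config, "srb_config")) config else do.call(srb_config, config)
  check_inputs_exist(Filter(Negate(is.null),
                            cfg[c("fasta", "hits", "tm", "clade_map")]))
  seqs <- read_fasta_records(cfg$fasta)
  n_input <- nrow(seqs)
  seqs <- dedupe_identical(seqs)
  n_dedup <- nrow(seqs)
  hits <- read_domain_hits(cfg$hits, dialect = cfg$hits_dialect)
  tms <- if (!is.null(cfg$tm)) {
    read_tm_table(cfg$tm, dialect = cfg$tm_dialect)
  } else if (isTRUE(cfg$use_hydropathy)) {
    pred <- do.call(rbind, lapply(seq_len(nrow(seqs)), function(i) {
      p <- predict_tm_hydropathy(seqs$seq[i])
      if (nrow(p) > 0) cbind(seq_id = seqs$id[i], p) else NULL
    }))
    if (is.null(pred)) {
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 source = character(), stringsAsFactors = FALSE)
    } else {
      pred
    }
  } else {
    stop("either a TM table or use_hydropathy = TRUE is required",
         call. = FALSE)
  }
  calls <- classify_cohort(seqs, hits, tms, domain_name = cfg$domain_name,
                           max_overlap = cfg$max_overlap,
                           max_tail = cfg$max_tail)
  clade_map <- read_tsv(cfg$clade_map)
  summary <- census_summary(calls, clade_map)
  srb <- calls[calls$label == "SR-B", , drop = FALSE]
  ecto <- lapply(seq_len(nrow(srb)), function(i) {
    extract_ectodomain(seqs$seq[match(srb$seq_id[i], seqs$id)],
                       srb[i, , drop = FALSE])
  })
  ecto_df <- data.frame(
    seq_id = vapply(ecto, `[[`, "", "seq_id"),
    taxon = srb$taxon,
    length = vapply(ecto, `[[`, 0L, "length"),
    stringsAsFactors = FALSE)
  lengths <- length_stats(ecto_df, clade_map,
                          flag_threshold = cfg$flag_threshold)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  write_tsv(calls, out("architecture.tsv"))
  write_tsv(summary$per_taxon, out("census_per_taxon.tsv"))
  write_tsv(summary$per_clade, out("census_per_clade.tsv"))
  if (nrow(srb) > 0) {
    write_fasta_records(vapply(ecto, `[[`, "", "seq_id"),
                        vapply(ecto, `[[`, "", "sequence"),
                        out("ectodomains.fasta"), taxa = srb$taxon)
  } else {
    writeLines(character(0), out("ectodomains.fasta"))
  }
  write_tsv(lengths$per_seq, out("lengths.tsv"))
  manifest <- list(
    stage = "census",
    counts = list(input_sequences = n_input, after_dedupe = n_dedup,
                  cd36_hit = unname(summary$totals$n_cd36_hit),
                  srb = unname(summary$totals$n_srb)),
    settings = cfg[c("domain_name", "max_overlap", "max_tail",
                     "flag_threshold")],
    outputs = c("architecture.tsv", "census_per_taxon.tsv",
                "census_per_clade.tsv", "ectodomains.fasta", "lengths.tsv"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(calls = calls, summary = summary, lengths = lengths,
                 manifest = manifest))
}

parse_bridge_pairs <- function(x) {
  if (is.list(x)) return(lapply(x, as.integer))
  # "120,260;150,300" string form (YAML/CLI friendly)
  lapply(strsplit(x, ";", fixed = TRUE)[[1]],
         function(p) as.integer(strsplit(p, ",", fixed = TRUE)[[1]]))
}

#' Run the comparative stage
#'
#' From an ectodomain alignment, a motif file and a directory of
#' predicted structures: computes per-column conservation and the
#' consensus, the motif presence heatmap (0-100 scaled sequence scores
#' plus pass flags), sequence-space expansion runs and bridge-cysteine
#' calls, then superposes every structure onto the designated reference
#' (structures failing the pTM gate are listed and skipped), bins
#' per-residue RMSD-calpha, detects structure-space expansion segments,
#' and runs the cavity detector.  All results are written as TSV/JSON
#' under `out_dir`.
#'
#' @param config An `srb_config` with `alignment`, `ref_id`,
#'   `bridge_pairs`, `motifs`, `structure_dir`, `ref_structure`,
#'   optionally `ptm_table`.
#' @return Invisibly, a list of the computed tables and the manifest.
#' @export
run_compare <- function(config) {
  cfg <- if (inherits(config, "srb_config")) config else do.call(srb_config, config)
  check_inputs_exist(Filter(Negate(is.null),
                            cfg[c("alignment", "motifs", "ptm_table")]))
  aln <- read_alignment(cfg$alignment)
  if (is.null(cfg$ref_id) || !(cfg$ref_id %in% aln$ids)) {
    stop("ref_id missing or not present in the alignment", call. = FALSE)
  }
  cons <- conservation(aln)
  cons_df <- data.frame(column = seq_along(cons), conservation = cons,
                        conserved = cons >= cfg$conservation_threshold)
  consensus_seq <- consensus(aln)
  expansions <- detect_expansion_columns(aln, cfg$ref_id,
                                         min_run = cfg$min_run)
  bridges <- NULL
  if (!is.null(cfg$bridge_pairs)) {
    bridges <- map_bridge_cysteines(aln, cfg$ref_id,
                                    parse_bridge_pairs(cfg$bridge_pairs),
                                    tolerance = cfg$bridge_tolerance,
                                    expansions = expansions)
  }
  pwms <- read_meme_motifs(cfg$motifs)
  heat <- motif_presence(ungap_alignment(aln), pwms)

  # structures: pTM gate, superposition vs reference, cavities
  skip <- data.frame(structure_id = character(), ptm = numeric(),
                     stringsAsFactors = FALSE)
  sup_rows <- list(); exp_rows <- list(); cav_reports <- list()
  sup_results <- list()
  if (!is.null(cfg$structure_dir)) {
    if (is.null(cfg$ref_structure)) {
      stop("reference structure not designated", call. = FALSE)
    }
    pdbs <- sort(list.files(cfg$structure_dir, pattern = "\\.pdb$",
                            full.names = TRUE))
    ptm <- NULL
    if (!is.null(cfg$ptm_table)) ptm <- read_tsv(cfg$ptm_table)
    get_ptm <- function(sid) {
      if (is.null(ptm)) return(NA_real_)
      v <- ptm$ptm[match(sid, ptm$structure_id)]
      if (length(v) == 0) NA_real_ else v
    }
    ids <- sub("\\.pdb$", "", basename(pdbs))
    if (!(cfg$ref_structure %in% ids)) {
      stop("reference structure ", cfg$ref_structure, " not found in ",
           cfg$structure_dir, call. = FALSE)
    }
    ref <- read_structure(pdbs[match(cfg$ref_structure, ids)],
                          predicted = TRUE)
    for (k in seq_along(pdbs)) {
      sid <- ids[k]
      if (sid == cfg$ref_structure) next
      p <- get_ptm(sid)
      if (!is.na(p) && p <= cfg$ptm_gate) {
        skip <- rbind(skip, data.frame(structure_id = sid, ptm = p,
                                       stringsAsFactors = FALSE))
        next
      }
      qry <- read_structure(pdbs[k], predicted = TRUE, ptm = p)
      sup <- superpose_iterative(ref, qry, d_pair = cfg$d_pair,
                                 bin_edges = cfg$bin_edges)
      sup_results[[sid]] <- sup
      tb <- table(factor(sup$pairs$bin, levels = c("high", "medium", "low")))
      sup_rows[[sid]] <- data.frame(
        structure_id = sid, n_pairs = nrow(sup$pairs),
        rmsd_ca = sup$rmsd_ca, rmsd_all_atom = sup$rmsd_all_atom,
        n_high = unname(tb["high"]), n_medium = unname(tb["medium"]),
        n_low = unname(tb["low"]),
        n_unaligned_query = length(sup$unaligned_query),
        converged = sup$converged, stringsAsFactors = FALSE)
      ex <- detect_structural_expansions(sup, min_run = cfg$min_run)
      if (nrow(ex) > 0) exp_rows[[sid]] <- cbind(structure_id = sid, ex)
      cav <- grid_voids(qry, probe_small = cfg$probe_small,
                        probe_bulk = cfg$probe_bulk,
                        spacing = cfg$grid_spacing)
      cav_reports[[sid]] <- cav
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  write_tsv(cons_df, out("conservation.tsv"))
  writeLines(c(">consensus", consensus_seq), out("consensus.fasta"))
  utils::write.table(
    data.frame(seq_id = rownames(heat$scaled), heat$scaled,
               check.names = FALSE),
    out("heatmap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(seq_id = rownames(heat$passes), heat$passes,
               check.names = FALSE),
    out("passes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bridges)) write_tsv(bridges, out("bridges.tsv"))
  write_tsv(expansions, out("expansions_seq.tsv"))
  exp_struct <- if (length(exp_rows) > 0) do.call(rbind, exp_rows) else
    data.frame(structure_id = character(), query_start = integer(),
               query_end = integer(), length = integer(),
               ref_before = integer(), ref_after = integer(),
               terminal = logical(), stringsAsFactors = FALSE)
  write_tsv(exp_struct, out("expansions_struct.tsv"))
  write_tsv(skip, out("ptm_skipped.tsv"))
  if (length(sup_rows) > 0) {
    write_tsv(do.call(rbind, sup_rows), out("superpositions.tsv"))
    for (sid in names(sup_results)) {
      s <- sup_results[[sid]]
      jsonlite::write_json(
        list(ref_id = s$ref_id, query_id = s$query_id,
             rotation = s$rotation, translation = s$translation,
             rmsd_ca = s$rmsd_ca, rmsd_all_atom = s$rmsd_all_atom,
             n_pairs = nrow(s$pairs), converged = s$converged),
        out(sprintf("superposition_%s.json", sid)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  if (length(cav_reports) > 0) {
    cav_df <- do.call(rbind, lapply(names(cav_reports), function(sid) {
      cm <- cav_reports[[sid]]$components
      if (nrow(cm) == 0) return(NULL)
      cbind(structure_id = sid, cm)
    }))
    if (is.null(cav_df)) {
      cav_df <- data.frame(structure_id = character(), id = integer(),
                           n_points = integer(), volume = numeric(),
                           n_mouths = integer(), class = character())
    }
    write_tsv(cav_df, out("cavity.tsv"))
  }
  manifest <- list(
    stage = "compare",
    counts = list(alignment_rows = length(aln$ids),
                  alignment_cols = aln$n_cols,
                  motifs = length(pwms),
                  structures_compared = length(sup_rows),
                  structures_skipped_ptm = nrow(skip)),
    settings = cfg[c("conservation_threshold", "min_run", "d_pair",
                     "bin_edges", "probe_small", "grid_spacing",
                     "ptm_gate", "bridge_tolerance")],
    outputs = c("conservation.tsv", "consensus.fasta", "heatmap.tsv",
                "passes.tsv", "expansions_seq.tsv", "expansions_struct.tsv",
                "ptm_skipped.tsv"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(conservation = cons_df, consensus = consensus_seq,
                 heatmap = heat, bridges = bridges,
                 expansions_seq = expansions, expansions_struct = exp_struct,
                 superpositions = sup_results, cavities = cav_reports,
                 skipped = skip, manifest = manifest))
}
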