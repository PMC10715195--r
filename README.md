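# srbkit

Comparative sequence and structure analysis of class B scavenger
receptors (SR-Bs) across eukaryotes.

SR-B proteins (CD36, SCARB1/SCARB2-like receptors and their many
non-metazoan relatives) share a distinctive domain architecture: a large
extracellular CD36 ectodomain flanked by two transmembrane helices
(TM-CD36-TM). The ectodomain folds into an asymmetric beta barrel topped
by a membrane-distal "apex" helix bundle that mediates ligand
recognition, and it is exactly this apex that accumulates
lineage-specific sequence expansions in divergent eukaryotic lineages.
`srbkit` implements the full desk-side pipeline needed to characterize
such a family:

* **Census** — parse HMMER `domtblout` domain hits and TMHMM topology
  tables (or predict TM helices from Kyte–Doolittle hydropathy), remove
  exact within-taxon duplicates, and classify every sequence by the
  TM-CD36-TM rule into `SR-B`, `cd36_no_tm`, `cd36_partial_tm`,
  `fused_suspect` (over-long N-tail, suspected gene-model fusion) or
  `non_cd36`.
* **Ectodomain analytics** — extract the region between the TM helices
  (first-domain rule for multi-CD36 proteins), replace undetermined
  residues (X → A) before structure export, and flag ectodomains longer
  than 500 aa, the length regime associated with apex expansions.
* **Alignment analytics** — column coordinate maps, gap-fraction
  filtering, majority consensus, per-column conservation (with the ≥40%
  mask used for structure coloring), mean pairwise identity,
  lineage-specific insertion columns, and disulfide-bridge cysteine
  homolog mapping with an expansion false-positive exclusion rule.
* **Motif scanning** — MEME-format PWMs, STREME-style sequence scores
  (best window sum of position weights, match thresholds), and 0–100
  scaled presence heatmaps.
* **Structure comparison** — PDB input with pLDDT in the B-factor
  column, pTM gating, Kabsch superposition with iterative
  spatial-adjacency residue pairing (monotone matching under a 5 Å
  cutoff), per-residue RMSD-cα bins (high < 1.5 Å, medium 1.5–2.7 Å,
  low > 2.7 Å), and detection of unaligned expansion segments.
* **Cavity detection** — a grid two-probe detector (probe radius 0.9 Å)
  classifying internal voids as pocket, tunnel or enclosed cavity.
* **Synthetic data** — generators for all of the above with exact
  ground truth, so every stage is testable without external data.

## Worked example

Generate a small synthetic proteome with decoys, run the census, and
look at what survives the TM-CD36-TM rule:

```r
library(srbkit)

prot <- gen_synthetic_proteome(
  n_taxa = 2, seqs_per_taxon = 10,
  decoy_mix = c(no_tm = 0.2, single_tm = 0.2, fused = 0.1, non_cd36 = 0.1),
  seed = 3)
d <- tempfile(); write_proteome_fixture(prot, d)

seqs  <- read_fasta_records(file.path(d, "sequences.fasta"))
hits  <- read_domain_hits(file.path(d, "hits.domtblout"))
tms   <- read_tm_table(file.path(d, "tm.tmhmm"))
calls <- classify_cohort(seqs, hits, tms)
table(truth = prot$truth$label, called = calls$label)
#>                  called
#> truth             cd36_no_tm cd36_partial_tm fused_suspect non_cd36 SR-B
#>   cd36_no_tm               4               0             0        0    0
#>   cd36_partial_tm          0               4             0        0    0
#>   fused_suspect            0               0             2        0    0
#>   non_cd36                 0               0             0        2    0
#>   SR-B                     0               0             0        0    8
```

Every decoy violates exactly one architecture condition, so the
classifier reproduces the truth labels exactly; the 8 SR-Bs per this mix
are the sequences with an included CD36 hit and both flanking TM
helices.

Superpose an idealized barrel+apex structure against a copy carrying a
planted 30-residue apex insertion (with 0.3 Å coordinate noise and a
rigid transform):

```r
ref <- gen_synthetic_structure(seed = 11)
qry <- gen_synthetic_structure(seed = 11, expansion_len = 30,
                               noise_sigma = 0.3, rot_axis = c(0, 1, 1),
                               rot_angle = 1.0, translation = c(10, -5, 3))
sup <- superpose_iterative(ref$structure, qry$structure)
sup
#> srb_superposition synthetic vs synthetic: 116 pairs, RMSD-ca 0.515 A
#>   bins: high 116, medium 0, low 0; unaligned: 0 ref, 30 query
detect_structural_expansions(sup)
#>   query_start query_end length ref_before ref_after terminal
#> 1         111       140     30        110       111    FALSE
```

The 30 inserted residues are exactly the unaligned run (truth span
111–140), the paired core sits in the high bin, and the RMSD-cα of
0.515 Å matches the isotropic-noise expectation σ·√3 ≈ 0.52 Å.

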