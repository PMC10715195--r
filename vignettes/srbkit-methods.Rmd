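---
title: "Methods behind srbkit: censusing, comparing and probing class B scavenger receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind srbkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srbkit)
```

`srbkit` is a toolkit for the comparative characterization of class B
scavenger receptors (SR-Bs): membrane proteins whose CD36 ectodomain —
an asymmetric beta barrel crowned by an apex helix bundle — sits between
two transmembrane (TM) helices. This vignette records the models,
parameter choices and numerical conventions behind each stage, what the
synthetic-data generators do and do not emulate, and the limitations a
user should keep in mind.

## The architecture census

A sequence is called a bona fide SR-B when it satisfies the operational
TM-CD36-TM rule: at least one included CD36 domain hit, and TM segments
on both sides of the first (smallest envelope start) hit. Two
conventions matter here:

* **Envelope coordinates** define the domain span. In the HMMER
  per-domain table the envelope bounds the region of homology, which is
  what the flanking-TM test should bracket.
* **`max_overlap` (default 10 aa)** lets a TM segment overlap the
  domain envelope slightly. Domain and TM predictions routinely abut
  with small overlaps; 10 aa absorbs that jitter without letting a TM
  sit inside the domain proper. The value is configurable and has no
  effect on the synthetic cohorts, where hits and TM tables are exact.

The ectodomain is the region strictly between TM1 and TM2. Sequences
whose N-terminal tail before TM1 exceeds `max_tail` (default 400 aa)
are labeled `fused_suspect` rather than SR-B: in real data, over-long
cytoplasmic regions carrying unrelated domains are the signature of
gene-model fusions, which deserve manual review rather than silent
acceptance. Exact duplicate removal is restricted to identical residue
strings *within* one taxon (the lexicographically smallest id is kept, a
deterministic tie-break); cross-taxon duplicates are biological signal
and retained. Isoform collapse beyond exact duplicates is deliberately
*not* automated — in practice it needs trees and genome browsers, which
are not reproducible computation — but ids sharing a locus prefix can be
flagged downstream.

The built-in TM predictor is a Kyte–Doolittle sliding-window scan
(window 19, cutoff 1.6 on the window mean): maximal runs of qualifying
window centers become segments, runs shorter than 12 aa are discarded
(shorter than any plausible TM helix) and runs longer than 40 aa are
trimmed to the best 21-aa window. It is a fallback so the pipeline runs
with no external topology tool; when TMHMM-style tables are available
they take precedence, and the call records its source either way.

## Ectodomain analytics

Ectodomain lengths are summarized per clade, and each ectodomain longer
than `flag_threshold = 500` aa is flagged: long ectodomains are the
length regime in which lineage-specific apex expansions occur.
Undetermined residues are replaced by alanine (X → A; small, nonbulky,
nonreactive) and the number of replacements is logged — the
substitution is applied only where a downstream consumer requires a
fully determined sequence (structure-prediction input), never silently
to the census itself. For proteins with multiple CD36 domains only the
first domain's flanking span is used, matching how multi-domain
proteins are handled in comparative alignments.

## Alignment analytics

Alignments are consumed, never computed, by this package. The column
map (alignment column ↔ ungapped residue index) is the backbone of all
coordinate lifting and is bijective on non-gap columns by construction.

* **Gap filter.** A column survives iff its gap fraction is at most
  `max_gap_frac = 0.8`. This is a declared simplification of block-based
  trimming heuristics; the surviving original column indices are
  returned so anything computed downstream can be lifted back to
  unfiltered coordinates exactly.
* **Consensus.** Per column, the modal residue is emitted when non-gap
  occupancy is ≥ 0.5, ties broken alphabetically. No standard exists
  for consensus construction; this is the simplest reproducible rule
  and both knobs are parameters.
* **Conservation.** Modal non-gap count divided by the *total* number
  of rows, so gappy columns score low; the mask at 0.40 reproduces the
  ≥40% coloring convention used for structure figures.
* **Pairwise identity.** Identical columns divided by co-occupied
  columns (columns where either row is gapped are excluded from the
  denominator). Identity values are convention-dependent; this
  denominator choice is stated because reported family-wide identities
  (on the order of ~13% for deep eukaryotic CD36 alignments) cannot be
  interpreted without it. Pairs with no co-occupied columns contribute 0
  and are flagged.
* **Expansion columns.** For each row, maximal runs of ≥ `min_run = 10`
  columns that are reference gaps and focal-row residues. The run
  anchors (reference residue before/after) let sequence-space calls be
  compared with structure-space calls.
* **Bridge cysteines.** Reference cysteine positions are lifted to
  columns and each row is scanned at those columns ± 2. The tolerance
  absorbs alignment jitter; the gross failure mode — a cysteine that
  aligns near a bridge column but belongs to a lineage-specific
  insertion — is handled by the exclusion rule: any matched cysteine
  inside the row's expansion run makes the call `excluded_expansion`
  rather than `present`. Reference pair positions are runtime inputs,
  not constants baked into the package.

## Motif scanning

Motifs arrive as MEME-format letter-probability matrices. Weights are
log2 odds against the file's background with an additive pseudocount of
0.01 (`log2((p + 0.01)/(bg + 0.01))`) — the pseudocount convention is
stated because the weight definition is otherwise underdetermined. The
*sequence score* of a motif in a sequence is the maximum over windows of
the summed position weights (one value per sequence, matching
one-cell-per-sequence heatmap semantics), and a match below the motif's
match threshold is disregarded. For display, raw scores are mapped to
0–100 per motif by min–max scaling against the motif's theoretical
extrema (the sums of per-position minimum and maximum weights), clipped,
with the no-hit sentinel at 0. This transform is deterministic and
dataset-independent — scaling against observed extrema would make a
sequence's score depend on its cohort. Scores are affine-invariant:
adding a constant to all weights of a position changes nothing after
scaling.

## Structure comparison

Predicted structures carry per-residue confidence (pLDDT, 0–100) in the
PDB B-factor column; model-level pTM gates entry into comparisons
(models at or below 0.7 are listed and skipped, not silently dropped).
pLDDT classes use the community 90/70 bounds, lower bound inclusive;
the bounds are configurable because they are a convention, not a
measurement.

Superposition is the classical two-step iterated to a fixed point:

1. **Kabsch fit** (SVD with reflection correction) on the current
   residue pairs.
2. **Re-pairing** by a monotone (order-preserving) matching over the
   cα distance matrix that maximizes `Σ (d_pair − d_ij)` subject to
   every pair being within `d_pair = 5 Å` — a dynamic program identical
   in structure to global sequence alignment with zero gap cost.
   Monotonicity preserves chain order; 5 Å is permissive enough to keep
   diverged-but-homologous residues paired.

The seed pairing is a global sequence alignment of the residue types
(BLOSUM62, affine gaps), or the identity mapping for same-length
controls. Iteration stops when the pair set is unchanged (typically 2–4
rounds) or at `max_iter = 20`, in which case the last result is flagged
non-converged. Per-pair distances are binned by the crystallographic
resolution scheme — high < 1.5 Å, medium 1.5–2.7 Å (closed interval, so
both edges fall in medium), low > 2.7 Å — and maximal runs of ≥ 10
consecutive unaligned query residues become expansion segments with
flanking reference anchors (one-sided and flagged at termini). RMSD is
reported over paired cα or over all atoms shared by name within paired
residues; the latter is well-defined under differing side chains.

## Cavity detection

Internal voids are found on a grid with a two-probe definition: a grid
point is accessible to a probe of radius r iff no atom center is within
(van der Waals radius + r). Bulk solvent is the flood fill of
bulk-probe-accessible points (bulk probe 3.0 Å) from the box boundary,
morphologically closed by the bulk-probe radius so the thin accessible
skin hugging the outer surface belongs to solvent. Candidate void
points are small-probe accessible (probe 0.9 Å, matching the probe
radius used for cavity prediction on these receptors) and outside bulk
solvent; 6-connected components are classified by the number of mouths
(26-connected interface patches to bulk): ≥ 2 mouths is a tunnel, 1 a
pocket, 0 an enclosed cavity. Atom-to-grid distances are computed
against the exact atom coordinates, not grid-snapped centers, so volume
estimates are unbiased at the 1–2% level for 0.5 Å spacing. Van der
Waals radii are a fixed table (C 1.7, N 1.55, O 1.52, S 1.8 Å, default
1.7 Å) declared for reproducibility. Alpha-shape methods define pockets
differently; absolute volumes from this detector are comparable only to
themselves, while presence/classification semantics (pocket vs tunnel
vs cavity) are robust.

## What the synthetic data emulates — and what it does not

The generators exist so that every stage has exact ground truth:

* **Proteomes.** SR-B-like sequences are N-tail | TM1 | ectodomain |
  TM2 | C-tail, with ectodomain lengths drawn from the metazoan-like
  367–616 aa range by default, planted motifs and cysteine pairs, and
  optional expansion insertions. TM segments are built from {I, L, V}
  (Kyte–Doolittle ≥ 3.8) and the background alphabet is hydrophilic and
  cysteine-free, so the hydropathy predictor, motif scanner and bridge
  mapper can never disagree with the truth labels by construction. Each
  decoy class violates exactly one architecture condition, giving the
  classifier a well-defined truth.
* **Gold alignments.** All rows descend from one ancestor; insertions
  become explicit gap-column blocks, so expansion columns and cysteine
  columns are known exactly rather than estimated by an aligner. The
  price is realism: there is no alignment error, which is precisely why
  a ± 2 column tolerance and the expansion-exclusion rule still need
  real-data validation.
* **Structures.** cα-only toys: barrel strands on a cylinder wall
  (3.3 Å rise with a 0.94 Å zigzag, giving ~3.8 Å consecutive cα
  spacing), ideal apex helices (1.5 Å rise, 100°/residue, 2.3 Å
  radius), and expansion hairpins excursing away from the apex. The
  ~3.8 Å spacing invariant holds within each segment; junctions between
  segments are geometric jumps, as no loop closure is attempted.
  Coordinate noise is isotropic Gaussian per coordinate — the simplest
  model that exercises superposition, with the useful closed form
  E[RMSD-cα] ≈ σ√3 after fitting. Real predicted structures have
  correlated, confidence-dependent error; passing on these fixtures
  shows the algorithms are correct, not that they are robust to every
  failure mode of structure prediction.
* **Cavity shapes.** Solid rod (no void), open tube (tunnel by
  construction), closed shell (cavity of analytic volume 4/3·π·r³).

Problem sizes in the tests and the acceptance script — 200 random point
sets for the geometry oracle, 100–200 simulated structure pairs with
15–60 residue insertions at σ = 0.3 Å, 500 random sequence/PWM pairs, a
250-sequence census cohort — were chosen as the smallest sizes at which
the Monte-Carlo properties stabilize.

## Degenerate inputs and tie-breaks

* Sequences shorter than the hydropathy window yield an empty TM list,
  not an error; sequences shorter than a motif width yield a defined
  no-hit (raw score −∞, scaled 0).
* Kabsch requires ≥ 3 non-collinear points and errors otherwise;
  reflection is corrected via the SVD determinant sign.
* Monotone matching traceback prefers the diagonal, so tied registers
  keep the maximal number of pairs.
* Consensus ties break alphabetically; duplicate ids in dedupe keep the
  lexicographically smallest; duplicate atoms keep the first and warn.
* Degenerate motifs (zero score range) scale everything to 0 with a
  warning rather than dividing by zero.

## Known limitations

* The census automates only what is reproducible: exact duplicate
  removal and the architecture rule. Isoform curation, gene-model
  repair and topology-orientation calls are out of scope.
* The gap filter is a per-column rule, not a block heuristic; trimmed
  alignments will differ from block-based tools near block edges.
* The iterative superposition is a local optimizer; a catastrophically
  wrong seed alignment (e.g. between near-repeat structures) can
  converge to a shifted register. The sequence-based seed makes this
  unlikely for homologous pairs but cannot exclude it.
* The cavity detector's volumes depend on grid spacing and the probe
  pair; only classifications are comparable across parameter settings.
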