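---
title: "Mining, classifying and mass-matching cyclotide precursors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining, classifying and mass-matching cyclotide precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclominer)
```

## The problem

Cyclotides are ~30-residue plant defence proteins with a head-to-tail
cyclic backbone and a knotted core of three disulfide bonds formed by six
conserved cysteines (the cyclic cystine knot).  They are expressed as
multi-domain precursors — an endoplasmic-reticulum signal (ER), an
N-terminal propeptide (NTPP), an N-terminal repeat (NTR), the cyclotide
domain (CD) and a C-terminal tail (CTR), with the NTR/CD unit repeatable
up to three times.  `cyclominer` implements a complete, testable pipeline
around two observations about these precursors:

1. The *prodomain* (NTPP + NTR) carries a sequence signature — a pattern
   of insertions and deletions in the NTPP plus two diagnostic residues
   in the NTR — that classifies precursors into evolutionary lineages
   (Möbius vs. bracelet), structural subfamilies (archetypal, hybrid,
   linear) and two finer ranks called molecular series and molecular
   species.
2. The mature peptide's monoisotopic mass, predictable from the precursor
   sequence, can be cross-referenced against LC-MS peak lists of plant
   extracts, with a +348.18 Da carbamidomethylation shift confirming the
   three disulfides.

## Consensus coordinates

All positional logic lives in one coordinate system: position 0 is the
N-terminal cleavage site of the (first) cyclotide domain and prodomain
positions are negative; intervals are inclusive.  The shipped layout
spans positions −76..54: ER at [−76,−58], NTPP at [−57,−20], NTR at
[−19,−1], CD at [0,44] (six cysteine columns at 4, 12, 19, 28, 31, 38 and
the loop-6 Asn/Asp cyclization residue at column 44), CTR at [45,54].
The signature windows are:

* the NTPP indel window [−56,−38], with Möbius-diagnostic deletion
  blocks [−56,−54] and [−50,−38];
* the hybrid-insertion pair [−32,−31] (occupied in hybrid and
  linear-Möbius precursors, deleted in archetypal Möbius ones);
* the linear-bracelet marks (P/A/L at −49, N/A at −48, D/E at −39)
  flanking a deletion at [−47,−40];
* the NTR dipeptide [−9,−8], which names the molecular series.

## Pipeline stages

**Mining** (`mine_precursors()`).  Transcripts shorter than 200 nt are
discarded; the rest are translated in six frames into maximal
stop-to-stop ORFs (not ATG-anchored, because assemblies truncate 5'
ends).  A cystine-knot motif scan finds six-cysteine placements whose
five internal gaps fall in configurable loop windows (defaults: loop 1
[2,7], loop 2 [3,6], loop 3 [2,8], loop 4 [1,2], loop 5 [3,6]; loop 6
crosses the domain boundary and is unconstrained at scan time).
Overlapping placements are resolved smallest-span-first, then leftmost.
Candidates must additionally resemble the curated references:
Smith–Waterman local alignment (BLOSUM62, gap open 11, extend 1, via
Biostrings) against the bundled mature sequences, with a prodomain-level
rescue for divergent domains.  The default `min_similarity` of 77 is the
smallest score that produced zero false positives among 10,000
shuffled-sequence decoys scored against the bundled mature references;
the prodomain rescue threshold (150) sits midway between that null and
the scores of true prodomains (≥ 260 on the bundled set).  Candidates
with five or seven cysteines are not found by the scanner; they enter
via the similarity rescue and are flagged abnormal downstream.

**Anchoring** (`anchor_to_profile()`).  The cyclotide domain is placed by
convention: cysteines on the six curated columns, loop residues
left-justified in their blocks, the pre-Cys-I stretch right-justified,
and a cyclic domain's terminal N/D on the nd column.  The fixed-width
NTR window sits immediately upstream.  The remaining N-terminal stretch
is aligned globally to a position-specific profile built from the
bundle's column frequencies.  Two design choices matter here:

* *Affine, occupancy-weighted deletions.*  Opening a block of skipped
  columns costs `gap_open` (default 2) and each skipped column adds
  `gap_extend` (default 2) scaled by the column's occupancy, so skipping
  a mostly-gapped column is nearly free and the bundle's indel blocks
  are recovered as contiguous deletions.
* *Nearest-reference conditioning.*  The profile gives 70% of its weight
  to the curated row most similar to the candidate's prodomain and
  spreads the rest over the bundle.  A flat frequency profile cannot
  decide between minority signatures (e.g. the linear-bracelet marks)
  and the majority pattern; conditioning on the nearest reference makes
  the recovered indel pattern follow homology rather than majority
  vote.  Weighted scores are deliberately not renormalised, so columns
  occupied by few rows both score low and cost little to skip.

Repeated NTR/CD units reuse the single consensus CD block; consensus
positions are reported for the first unit and per-domain maps for the
rest.  A candidate whose six cysteines cannot sit on the cysteine
columns (a loop longer than its block) is reported `unanchorable` and
excluded downstream.  Precursors whose coverage starts below the NTPP
are flagged `partial`; their unknown signature positions are reported as
`?`, never guessed.

**Classification** (`classify_precursors()`).  Lineage: Möbius if both
deletion windows are ≥ 80% gapped; bracelet if the insertion region is
≥ 50% occupied, or — regardless of occupancy — if the
linear-bracelet marks are present with the deletion between them (those
precursors occupy only ~4/13 of the window, so the occupancy rule alone
would strand them; the rescue is recorded in the rationale).  Subfamily:
in the Möbius lineage Y−9/Y−8 marks linear precursors, a cyclic-pool
dipeptide is hybrid or archetypal according to the [−32,−31] insertion;
in the bracelet lineage the linear dipeptide pool plus NTPP marks gives
linear bracelets, the cyclic pool gives cyclic bracelets.  The dipeptide
pools extend the published sets — (Y/F/H)(S/A/Y/F) and
(H/N/S/T/G/K/P/R)(L/N/S/F/A/P) — because series named in the source
material (HF, GP, RS) carry residues outside the narrower sets.  The
molecular series is the NTR dipeptide; molecular species are connected
components, within a series, of "identical indel-window occupancy and
window-residue identity ≥ 0.80".  The 80% gap, 50% occupancy and 0.80
identity thresholds are free parameters standing in for what was
originally expert judgment; they are configurable
(`classify_config()`).  Tripartite names (`assign_names()`) combine a
five-letter organism code, a per-(organism, species) rank and the
species key, with a `prc-` prefix for previously unnamed precursors and
verbatim reuse of published names.

**Mass prediction** (`enumerate_matures()`, `monoisotopic_mass()`).  Per
cyclotide domain, six candidates at N-terminal start offsets −3..2
(inclusive; negative offsets retain up to three NTR residues).  Cyclic
candidates end at the loop-6 N/D; without one the domain is linear and
runs to its last residue.  A cyclic mass is the residue-mass sum minus
two hydrogens per disulfide; linear adds one water.  Constants are kept
at six decimals and comparisons always use unrounded values; reported
masses are rounded to one decimal, matching the precision of the
spectra annotations.  Odd cysteine counts default to (n−1)/2 disulfides
and are flagged; X makes a candidate mass-indeterminate (flagged,
excluded from matching).

**MS matching** (`detect_envelopes()`, `deconvolute()`,
`match_predicted()`).  Peaks outside m/z 1000–2000 are dropped.  Within
0.2-min retention-time bins, envelope grouping is greedy from the most
intense unassigned peak, extending at spacings of 1.00336/z (z = 3
before z = 2; other charges are never assigned) within a 0.05 Da
spacing tolerance and requiring at least 3 peaks.  Two safeguards keep
nearby envelopes in one bin from coalescing: extension is
intensity-monotonic (climbing towards the monoisotopic peak on the
left, falling on the right, matching the geometric-decay envelope model
below), and a collected chain is split wherever successive spacings
deviate from 1.00336/z by more than `spacing_split` (default 0.02 Da) —
peaks of one envelope share a single calibration offset, so their
internal spacings are far more precise than the absolute matching
tolerance.
The monoisotopic peak is the leftmost accepted peak; no averagine
fitting.  Neutral masses (z·mono_mz − z·proton) agreeing within 0.40 Da
in the same bin merge into one observation; observations outside
2700–3300 Da are dropped (the alkylated set may exceed the upper bound
by 400 Da).  The signal intensity SI sums the 3+ envelope; abundance is
low below 250, high above 1000, with the boundary values assigned to
the closed middle bin.  Alkylation is confirmed at ±0.75 Da around the
+348.18 Da shift — wider than the 0.40 Da match tolerance because the
shift compounds the errors of two independent observations, and the
reference worked example itself deviates by 0.42 Da.  Predicted-to-
observed matching is strict (<0.40 Da), many-to-many, with the
minimal-|Δ| candidate flagged best per observation.

**Expression** (`fpkm_tier()`, `cross_level_table()`,
`section_sharing()`).  FPKM is consumed, never computed; the tier cutoff
is a strict >150.  Cross-level (transcript + peptide) detection counts
only best matches, so many-to-many mass coincidences cannot inflate
concordance.  Species sharing across taxonomic sections is summarised
both by species count and by precursor count.

## The synthetic generator and what it does (not) show

`cyclotide_templates()` ships 46 synthetic molecular-species templates —
14 Möbius species in 5 series (YS, YY, YA, HF, FA) and 32 bracelet
species in 8 series (HS, NS, NL, GA, GP, RS cyclic; PN, QD linear) —
mirroring the published tally.  The real curated alignment is not
redistributable, so the templates are synthetic stand-ins built to
satisfy the same signature system; the shipped reference bundle is one
sampled representative per template plus the two published mature
sequences (kalata B1, cycloviolacin O2).  Within a series, cyclic
bracelet species differ by distinct minor-gap patterns and by a
five-residue window variation chosen from a distance-≥3 code, Möbius
species by their fixed residue triple at [−53,−51], and linear bracelet
species by their tag and mark residues — so species are identifiable by
construction.  Prodomain positions are consensus-fixed per template;
sampling variation lives in the cyclotide-domain loops, where
mature-mass diversity matters.  One template detail is deliberate: the
YY-series cyclic species is shipped as linear, because Y−9/Y−8 is the
linear-Möbius signature and a cyclic YY template would contradict the
signature system the classifier implements (the real family contains
exactly such an exception, which signature-only classification cannot
express).

`build_transcriptome()` embeds sampled precursor CDSs (back-translated
with uniform synonymous codons, stop-flanked) in random-UTR transcripts
with randomised strand, plus length-matched uniform-random decoys, and
draws log-normal FPKM (meanlog 4.5, sdlog 1.5, so roughly a third of
transcripts exceed the 150 cutoff).  `simulate_peaklist()` emits 2+ and
3+ envelopes per expressed mature peptide with spacings 1.00336/z,
five peaks decaying geometrically (ratio 0.8) and scaled so the 3+
envelope sums to the tier's SI (low 100, medium 500, high 1500 —
matching the three abundance bins), uniform noise peaks, and an
optional alkylated companion shifted by the cysteine-dependent delta.
Mass jitter is drawn once per envelope (a coherent calibration error,
N(0, 0.05 Da) by default), not per peak — per-peak jitter of that size
would destroy the spacing structure the charge logic depends on.

Passing the recovery tests on these simulations shows that the pipeline
is internally consistent end to end: every stage inverts what the
generator did, under the generator's assumptions.  It does not show
robustness to real assembly artifacts (chimeric or frame-shifted
transcripts), genuinely novel signatures absent from the bundle,
averagine-shaped isotope envelopes, chromatographic co-elution, or
charge states outside {2,3}.  The classifier applied to real curated
alignments depends on the bundle shipped; replicating the published
Viola tallies requires the original curated alignment, which must be
supplied by the user.

## Numerical choices and degenerate inputs

* Gap character in alignments is `-` only; `.` is rejected.
* Sequence ids must be unique per file (they key all joins).
* Tie-breaks are deterministic everywhere: lexicographic reference id
  for equal similarity scores, smallest-span-then-leftmost for motif
  placements, first-seen order for species numbering, first candidate
  for equal |Δ| in matching.
* The loop-6 N/D site is the residue on the nd column when it is N or
  D, otherwise the last N/D in the loop-6 block; linear domains simply
  have none.
* Boundary values: SI of exactly 250 or 1000 is medium; FPKM of exactly
  150 is below; a mass delta of exactly 0.40 Da is not a match.
* Empty inputs (no candidates, empty match table, missing peak file)
  produce empty tables or transcriptome-only runs, never errors.

## Reproducibility

Every generator takes an integer seed and derives independent
sub-streams from it; callers' RNG state is never disturbed.
`run_pipeline()` writes TSV outputs plus a manifest (input checksum and
full configuration), and two runs with identical inputs and seeds are
byte-identical — this is asserted in the test suite.  The simulation
sizes used by the tests (46 species × 2 precursors for end-to-end
recovery, 20 instantiations per template for classification closure,
10,000 shuffles for the similarity-threshold calibration) were chosen
to exercise every template and rule combination at least twice.
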