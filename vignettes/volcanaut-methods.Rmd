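---
title: "Methods and design of volcanaut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of volcanaut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volcanaut)
```

`volcanaut` implements the data-processing layer behind interactive
volcano-plot exploration of differential proteomics and PTM experiments:
import, classification, QC, PTM site harmonization and isoform remapping,
and session persistence. This vignette explains the procedures, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data generators do and do not emulate.

## Scope and division of labour

The package deliberately consumes, rather than computes, differential
statistics. Fold changes and p-values arrive from an external statistics
program (Perseus, MSstats, limma, ...) as a tab-delimited file; `volcanaut`
transforms them into plot space, classifies them, and manages everything
downstream. The one exception is the synthetic generator, which uses a plain
two-sample t-test to fabricate a plausible differential table for its own
simulated intensities — generator plumbing, not an analysis recommendation.

Column roles and scales are always declared through `column_map()`, never
guessed from headers. Search-engine exports differ across programs and
versions; silent header guessing is how wrong axes end up on volcano plots.
For the same reason the four PTM dialect converters implement one
representative column layout each (documented on the converter help pages)
rather than attempting version autodetection: rename columns upstream, or
adjust the preset, and the behaviour stays inspectable.

## Volcano classification

A feature with log2 fold change $x$ and $-\log_{10}$ significance $y$ is
*significant* iff $y > c_{sig}$ and *changed* iff $|x| > c_{fc}$. The four
conjunctions (`NS_NC`, `S_NC`, `NS_C`, `S_C`) partition any table.
Comparisons are strict: the dotted cutoff lines mark boundaries, and a point
lying exactly on a line falls in the less-extreme class. Strictness is the
deterministic choice — with `>=` on one axis and `>` on the other, two
points with tied coordinates could classify differently after a
scale-preserving rewrite of the input.

The shipped defaults ($c_{fc} = 0.6$, $c_{sig} = 1.301$, i.e. ~1.5-fold and
p < 0.05) are presets in the ordinary sense: common, defensible, and not a
substitute for the cutoffs used in the actual differential analysis.

Batch gene selection matches case-insensitively but exactly: `RAB10`
matches `Rab10` (human vs mouse casing) but not `RAB10B`. Substring matching
was rejected as too noisy for curated pathway lists.

Per-feature summaries report the sample standard deviation ($n-1$
denominator) and SEM $= s/\sqrt{n}$ per condition, excluding missing
values. With a single non-missing replicate both are reported as 0 and
flagged `insufficient_replicates` instead of erroring, so single-replicate
pilot data still renders; the flag keeps the 0 from masquerading as a
measured spread.

## Missing values and QC

Intensities of exactly 0 are converted to missing at import. MaxQuant-style
outputs encode "not detected" as 0, and a genuine measured zero does not
occur on an intensity scale; leaving zeros in place would poison both log
transforms and correlations.

The correlation matrix is computed on $\log_2$ intensities (Pearson by
default, Spearman selectable) over the features non-missing in **both**
samples of each pair. Pairwise-complete observation was chosen over
complete-case because label-free data routinely has 5–30% missingness;
complete-case would discard most features in wide matrices. A pair sharing
fewer than 3 features has no meaningful coefficient and is reported as `NA`
— never as 0, which would read as "uncorrelated" on a heatmap. The diagonal
is fixed at 1.

Profile plots rank each sample's non-missing $\log_2$ intensities in
descending order; the plotted multiset is exactly the observed multiset
(tested as a permutation property), with highlighted features annotated
only in samples where they were detected.

## PTM site harmonization

All converters emit the same table: accession, stripped peptide, 1-based
in-peptide and in-protein positions, residue, localization probability,
modification, per-sample quantification, plus `ambiguous` and `valid`
flags. All residue coordinates in the package are 1-based and inclusive.

The localization annotation grammar is residue letters with `(p)`
immediately after a modified residue (`"AAS(0.98)PT(0.02)K"`), probabilities
in $[0,1]$; engine-specific decoration (Spectronaut's `_` anchors) is
normalized away by the reader before parsing.

Engine-specific handling:

* **MaxQuant** site tables already carry protein-level positions; the
  converter selects one intensity multiplicity (`___1`/`___2`/`___3`)
  explicitly, defaulting to 1, since site tables quantify singly and
  multiply modified peptides separately and no universal choice exists.
* **MS-Fragger** reports the peptide's start in the protein:
  `position_in_protein = peptide_start + position_in_peptide - 1`, with the
  peptide verified against the protein sequence at that start.
* **Spectronaut** reports only the modified peptide; it is located by exact
  substring search in the protein. Multiple occurrences use the first and
  set `ambiguous = TRUE` — the flag is carried, never dropped, because a
  repeated tryptic peptide genuinely cannot be localized from the report
  alone. One combined file covers all modification types; rows keep their
  type and `split_by_modification()` separates them.
* **DIA-NN** splits quantification and probabilities across two files; they
  are merged by inner join on the precursor key. Unmatched keys are
  reported, not imputed, and a key whose accession differs between files is
  an error rather than a silent pick.

Records whose residue disagrees with the protein sequence (or whose peptide
cannot be placed) are flagged `valid = FALSE` and counted in the run
report; they are excluded from downstream analysis by default but remain in
the table for auditing.

Class-I filtering retains sites with localization probability **strictly**
greater than the threshold (0.75 by convention): the conventional
high-confidence tier is defined by exceeding 0.75, so a site at exactly
0.75 is excluded.

Multi-accession protein groups (`"P1;P2"`) use the first accession for any
sequence or annotation lookup while retaining the full group string as the
identifier.

## Isoform remapping by global alignment

Search databases and public PTM resources can number residues on different
splice variants. Exactly two sequences are ever compared — the experimental
isoform and the canonical one — so a pairwise global alignment is the
appropriate tool. The implementation is Needleman–Wunsch with affine gaps
(Gotoh three-state recursion, in C++ via Rcpp): BLOSUM62, gap open −10, gap
extend −0.5, a gap of length $L$ scoring $open + L \cdot extend$. These are
conventional protein-alignment parameters; for the near-identical sequences
this step sees (isoforms of the same protein), any standard parameter set
recovers the same block structure, and the values are configurable through
`alignment_params()`.

Traceback ties are broken deterministically — match state preferred over a
gap in the canonical sequence, preferred over a gap in the experimental
sequence ("diagonal > up > left") — so the same input always yields the
same map. Identical sequences short-circuit to the identity map. The
resulting position map is strictly monotone; experimental residues aligned
to gaps remap to `UNALIGNED` (`NA`) with both residues reported for
mismatch auditing. Residues absent from the substitution matrix (e.g.
selenocysteine U) score as X.

Database comparison classifies every canonical position carrying a PTM:
`BOTH` requires coincidence in **position and modification type**;
otherwise `EXPERIMENT_ONLY` / `DATABASE_ONLY`; a user-selected site
overrides to `SELECTED` while retaining its database-presence record, and
sites in the `S_C` differential class carry an independent
`significant_flag`. When position and modification match but the residue
letter disagrees after remapping, the position is *not* reported as `BOTH`:
it is demoted to `EXPERIMENT_ONLY` with `residue_conflict = TRUE`. The
alternative — trusting the coincidence despite the letter mismatch — would
hide exactly the remapping errors this step exists to surface. This
behaviour is a package choice; reference resources do not prescribe one.

Motif windows are `2 * halfwidth + 1` residues centered on the site, padded
with `_` beyond sequence ends; halfwidth 7 (a 15-mer) is the convention of
the major kinase-substrate resources. The position frequency matrix has 21
rows (20 standard residues + pad) and errors on other letters rather than
silently re-bucketing them.

## Session persistence

A session document embeds the complete state — metadata, column map,
annotations, cutoffs, selections, style, and data payloads — under a
`schema_version` and a UUID4 `session_id`. Design points:

* **Exact round trip.** Numbers are serialized at 17 significant digits,
  which reproduces IEEE doubles exactly; `load(save(state))` equals the
  state value-for-value (a property tested over randomized states).
* **No clock values.** Two saves of one state differ only in the session
  id, so shared documents diff cleanly.
* **Strict versioning.** An unsupported `schema_version` refuses to load.
  A silent partial load of a shared analysis is worse than an explicit
  failure.
* **Forward compatibility.** Unknown top-level fields are preserved
  verbatim in `state$extras` and written back on the next save.

## Synthetic generators: what they emulate

`gen_proteome()` draws per-feature baselines $\mathcal{N}(26, 2)$ on the
log2 scale (typical LFQ intensity magnitudes), adds a condition effect of
`effect_size` log2 units with random sign to a `de_fraction` of features,
replicate noise $\mathcal{N}(0, noise\_sd)$, and uniform random
missingness. Defaults (500 features, 2 conditions × 4 replicates, 10%
differential at 3 log2 units, noise 0.2, 2% missing) describe a clean,
strong-effect designed experiment — the regime in which cutoff-based hit
calling is expected to work essentially perfectly, which is what makes
ground-truth recovery a meaningful correctness check: at these settings a
20-seed calibration put both sensitivity and specificity of the `S_C` class
at 1.0, and the recovery test asserts ≥ 0.95.

`gen_ptm()` plants S/T/Y sites in random sequences, draws localization
probabilities uniformly (rounded to 4 decimals so the text renderings are
exact), renders the same truth into all four dialect layouts, and builds
canonical isoforms differing by known N-terminal extensions or deletions so
remapping has closed-form answers.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: intensity-dependent (left-censored) missingness,
correlated noise and batch effects, shared peptides across protein groups,
multiply-phosphorylated peptides with probability mass split across
candidate residues, version drift in engine export headers, and
decoy/contaminant rows. Tests built on these generators verify the
*mechanics* (parsing, coordinate arithmetic, classification, round trips),
not robustness to the full messiness of instrument data.

All generators are seed-deterministic; identical parameters and seed yield
byte-identical rendered files.

## Numerical and degenerate-input choices

* Linear fold changes and raw p-values that cannot produce a finite
  transformed value (FC ≤ 0, p ≤ 0, unparseable text) drop the row, with a
  count and the ids in the drop report: there is no defensible finite
  substitute, and clamping would distort the volcano silently. The
  invariant `kept + dropped = source rows` always holds.
* Duplicate feature ids keep the first occurrence with a warning
  (deterministic and order-stable); duplicate FASTA accessions are an
  error, since silently shadowing a sequence corrupts residue checks.
* Empty selection sets, empty databases, and a 0-row site table are valid
  inputs flowing through unchanged; an empty differential table is an
  error for plot construction.
* Correlation ties in Spearman use R's default midranks.

## Problem sizes in the test suite

The suite exercises alignment oracle equivalence on 1,000 random pairs of
length ≤ 12 against an independently written brute-force dynamic program,
classification on 10,000 random volcano points against a re-derivation,
100 randomized session round trips, and full-pipeline determinism on
80-feature simulations — sizes chosen so the whole suite completes in well
under a minute while each property still covers its input space densely.

## Known limitations

* Converter presets cover one representative export layout per engine;
  real exports may need a column rename step.
* Ambiguous peptide placement uses the first occurrence; no protein-level
  inference re-ranks occurrences.
* The annotation provider is offline-only as shipped; a live web provider
  is an extension point, and fabricating annotations for unknown ids is
  deliberately refused.
* No batch-effect correction, no re-localization of sites, no
  spectral-level modelling.
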