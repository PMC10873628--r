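# volcanaut

Headless exploration of processed mass-spectrometry proteomics and
PTM (posttranslational-modification) data.

Differential proteomics results usually reach collaborators as a static
volcano plot plus a wide search-engine spreadsheet. The numbers behind that
plot — which features pass which cutoffs, how the replicates behave, where a
phosphosite sits once splice-variant numbering is reconciled with the
canonical isoform — are locked inside files that only the original analyst
can comfortably reopen. `volcanaut` is an R toolkit for exactly that
post-processing layer: it is aimed at proteomics bioinformaticians who need
scriptable, reproducible versions of the operations an interactive volcano
explorer performs, without a browser or a server.

It does **not** compute differential statistics (that is Perseus / MSstats /
limma territory); it consumes their output.

## What it implements

* **Import with explicit column maps** — tab-delimited differential tables
  (any fold-change/significance columns, declared as `log2`/`linear` and
  `neglog10`/`raw_p`) and raw intensity matrices with per-sample
  condition/replicate annotation. Zero intensities are treated as missing
  (the MaxQuant "not detected" convention); untransformable rows are
  dropped and counted, never clamped.
* **Volcano classification** — each feature with log2 fold change *x* and
  −log10 significance *y* falls in one of four classes under cutoffs
  (*c*<sub>fc</sub>, *c*<sub>sig</sub>):
  significant ⇔ *y* > *c*<sub>sig</sub>, changed ⇔ |*x*| > *c*<sub>fc</sub>
  (strict comparisons; boundary points are less extreme). Selection sets,
  curated batch gene lists, fading of non-selected points, per-feature
  replicate summaries (mean ± SD / SEM), ggplot2 rendering and SVG export.
* **QC** — ranked per-sample log2 profile plots and the global
  sample-sample correlation matrix (Pearson or Spearman on log2
  intensities, pairwise-complete; pairs with < 3 shared features are
  undefined, never 0).
* **PTM harmonization** — MaxQuant site tables plus the three dialects that
  need preprocessing (MS-Fragger, Spectronaut, DIA-NN) converted into one
  canonical site table: accession, stripped peptide, 1-based in-peptide and
  in-protein positions, residue, localization probability, per-sample
  quantification. Residues are cross-checked against the protein sequence;
  class-I filtering keeps sites with probability strictly > 0.75.
* **Isoform remapping** — global Needleman–Wunsch alignment (BLOSUM62,
  affine gaps, deterministic traceback) between the experimental sequence
  and the canonical isoform; site numbers are remapped through the
  alignment, compared against reference/custom PTM databases
  (`BOTH` / `EXPERIMENT_ONLY` / `DATABASE_ONLY` / `SELECTED`), and ±7
  motif windows are extracted for logo rendering.
* **Sessions** — the whole analysis state round-trips exactly through a
  versioned JSON document with a UUID4 session id.
* **Synthetic fixtures** — generators that render a known ground truth into
  every supported input dialect, so the entire toolchain is testable
  offline.

## Worked example

```r
library(volcanaut)

# a two-condition experiment with known truth: 500 features, 10% truly
# differential at 3 log2 units effect, replicate noise 0.2
sim <- gen_proteome(proteome_sim_params(n_features = 500, seed = 42))

vd <- build_volcano(sim$diff, cutoff_config())   # |log2FC|>0.6, -log10 p>1.301
vapply(vd$series, nrow, integer(1))
#> NS_NC  S_NC  NS_C   S_C
#>   433    17     0    50
```

50 features land in the significant-and-changed class (the 10% injected
effects), 17 are significant without passing the fold-change line, and
nothing is changed-but-nonsignificant at this noise level.

```r
round(unclass(correlation_matrix(sim$raw))[1:4, 1:4], 3)
#>            control_R1 control_R2 control_R3 control_R4
#> control_R1      1.000      0.989      0.989      0.989
#> control_R2      0.989      1.000      0.989      0.989
#> control_R3      0.989      0.989      1.000      0.990
#> control_R4      0.989      0.989      0.990      1.000

summarize_feature(sim$raw, "PROT0004")
#> feature_summary for 'PROT0004':
#>  condition n      mean        sd      sem insufficient_replicates
#>    control 4  96922280   9248123  4624062                   FALSE
#>  treatment 4 791661216 146766520 73383260                   FALSE
```

Replicates correlate at ~0.99, and the per-feature summary shows the ~8-fold
intensity shift behind one hit. The PTM side works the same way:

```r
ptm <- gen_ptm(ptm_sim_params(seed = 42))
sites <- convert_maxquant(ptm$files$maxquant, sequences = ptm$sequences_exp)
sites
#> ptm_sites: 18 site(s) on 6 protein(s); 0 invalid, 0 ambiguous
nrow(filter_class1(sites))   # localization probability strictly > 0.75
#> [1] 4

# protein PTMP02's canonical isoform lacks this variant's 3 N-terminal
# residues; alignment recovers the -3 renumbering
m <- align_isoforms(unclass(ptm$sequences_exp)[["PTMP02"]],
                    unclass(ptm$sequences_canonical)[["PTMP02"]])
m
#> alignment_map: 117 -> 114 residues, 97.4% identity, score 629.5
remap_site(m, 22)
#>   exp_position canonical_position exp_residue canonical_residue unaligned
#> 1           22                 19           T                 T     FALSE
```

A command-line wrapper covers the same pipeline
(`inst/exec/volcanaut simulate|import|qc|volcano|convert|ptm-map|session`).

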