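---
title: "Methods: multiplexed TMT phosphoproteomics with phosphoTMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed TMT phosphoproteomics with phosphoTMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

phosphoTMT implements a complete analysis chain for multiplexed
isobaric-label (TMT) phosphoproteomics with pooled bridge channels, as used
to profile thrombin-stimulated, p38-inhibitor-modulated signaling in
endothelial cells: two-step reporter-ion normalization, phosphosite
localization filtering and protein-coordinate mapping, per-phosphopeptide
differential statistics with pi-score prioritization, k-means temporal
clustering with elbow model selection, motif-x style consensus-motif
discovery, kinase-consensus assignment with per-cluster enrichment, and
annotation-set over-representation. A synthetic multi-plex generator with
planted ground truth drives validation.

The experimental design emulated throughout is four conditions — vehicle
(DMSO) and p38-inhibitor (SB203580) pretreatment arms, each unstimulated
(0 min) or thrombin-stimulated (10 min) — with replicate counts
(2, 2, 3, 3), multiplexed across two TMT plexes that each reserve reporter
126 for a bridge channel pooled from all samples.

```{r}
library(phosphoTMT)
res <- runPipeline(paperSimConfig(seed = 1), outDir = "run1")
```

# Normalization model

Reporter signal-to-noise values are processed in a fixed stage order,
enforced by the `TMTQuant` container's stage tag:

1. **Bridge normalization.** Every sample channel is divided row-wise by the
   bridge channel of its plex. Because the bridge is the same pooled material
   in every plex, this cancels per-plex batch effects; a planted noise-free
   2-fold plex factor is removed exactly. Rows with a missing or zero bridge
   are dropped and counted.
2. **Channel-median normalization.** Each channel is divided by its median
   and rescaled by the grand median of the pre-normalization channel
   medians, so channel medians become equal (relative deviation below 1e-9)
   while the values keep a signal-to-noise-like scale. Pure division to a
   median of 1 is available (`medianNormalizeRaw`); downstream ratios are
   unaffected either way.
3. **Phosphopeptide aggregation.** PSM rows sharing the key (peptide
   sequence, set of localized site positions) are summed channel-wise.
   Aggregation after channel normalization is valid because TMT ratios are
   scale-free; the PSM count per phosphopeptide is retained.
4. **Protein correction.** Each phosphopeptide profile is divided by its
   parent protein's *relative* profile (the protein's normalized channel
   values divided by their own mean), computed from the non-phospho peptide
   table aggregated per protein. Dividing by relative rather than absolute
   protein values removes protein-abundance trends without rescaling the
   phosphopeptide; a planted 2-fold protein-abundance change with unchanged
   phosphosite stoichiometry yields a corrected fold change of exactly 1.
   Phosphopeptides without a protein-table entry pass through flagged.

Missing cells are read as missing, never as zero: zero-imputation would
fabricate infinite fold changes. Rows with a missing value in a compared
condition are excluded from that comparison only.

# Site handling

Sites with a localization score strictly greater than 50 percent are
considered confidently localized; peptides that lose every site remain in
quantitation but leave site-level analyses. Peptides are mapped to their
protein by exact substring search; the absolute position of a
peptide-relative site is `offset + position - 1` (1-based everywhere).
Multi-match peptides take the lowest offset and carry an ambiguity flag that
excludes them from motif analyses, preventing double-counted flanks.
Flanking windows are 13-mers (half-width `h = 6`, the motif-x convention),
padded with `_` past the termini; the pad character can never match a motif
constraint. Isoleucine/leucine are deliberately not collapsed during
matching, since the peptides derive from the same sequence database.

# Differential statistics

Group comparisons (vehicle thrombin response, inhibitor-arm thrombin
response, and the between-arm contrast at 10 min) are made per
phosphopeptide on log2-transformed relative abundances: a pooled-variance
Student t test when a two-sided F test of variance equality is not rejected
at 0.05, otherwise Welch's t test with Satterthwaite degrees of freedom.
Fold changes are ratios of linear group means, reported as log2. The
pi-score `log2FC x (-log10 p)` provides a single signed prioritization
value. The headline significance filter is the raw `p < 0.01`, matching the
source analysis; BH q-values are reported alongside without changing the
filter. Per-site condition summaries are scaled to the vehicle 0-min mean
and tested with a sequential two-factor ANOVA (pretreatment x stimulation).

**Known property — conservative calibration.** On null simulations with the
default generator the observed fraction of `p < 0.01` is about 0.006-0.008
rather than 0.010. This is not a defect of the test machinery (on
independent log-normal draws the same code is calibrated to 0.0100 at n =
15,000); it is a structural property of bridge-ratio designs: all sample
channels of a plex share the bridge measurement's noise, so within-group
variance across plex-spanning replicates overestimates the variance of the
group-mean contrast. Real bridged TMT experiments inherit the same mild
conservatism.

# Temporal clustering

Profiles are response ratios to the pooled vehicle 0-min control mean,
min-max scaled to [0, 1] per row. The vehicle reference (rather than each
arm's own 0-min control) is deliberate: inhibitor-induced *basal* shifts at
0 min are part of the temporal phenotypes of interest, and normalizing each
arm to itself would erase them, collapsing distinct archetypes onto
identical profiles. The per-arm mode remains available
(`reference = "arm"`).

Clustering operates on the four condition-mean columns by default
(`mode = "mean"`); replicate-resolved columns (`mode = "sample"`) are kept
for heat-map-style display. Averaging replicates before clustering keeps
replicate noise from defining cluster structure — with per-sample columns
the recovery of five planted archetypes drops from an adjusted Rand index of
about 0.95 to about 0.79 at the default noise level.

`kmeansFit` wraps Lloyd's algorithm (`stats::kmeans`) in seeded random
restarts (default 50), keeping the lowest within-cluster sum of squares;
restarts that produce an empty cluster are discarded. Fits are
bit-reproducible for a fixed seed. `elbowSelectK` selects the k with the
maximum second difference of **log** WSS over a contiguous scan. The log
scale matters: it measures the change in *relative* improvement and locates
the flattening point of the curve, whereas the linear second difference is
dominated by the earliest, coarsest split (for these archetypes it selects
the up/down/mixed 3-way split at any noise level). The full inertia curve is
returned for audit, and is non-increasing in k.

The clustering input is the significant set (union of the three
comparisons at `p < 0.01`), mirroring the source analysis' clustered
significant phosphopeptides; clustering all quantified peptides is a flag
away (`clusterInput = "all"`).

# Motif discovery and enrichment

`motifX` re-implements the iterative binomial motif-building idea: at each
step the (position, residue) pair with the smallest binomial tail
probability — `P(X >= k)` with n the current foreground size and success
probability the current background frequency — is fixed, provided
`p < threshold` and at least `minOcc` foreground occurrences (ties: larger
count, then leftmost position); both sets are reduced to matching sequences
and the search repeats, emitting the motif and removing its matches when no
candidate remains. Defaults (1e-6, 20) follow common motif-x practice for
datasets of a few thousand sites; the synthetic-scale pipeline preset
relaxes to (1e-3, 5). The default background is the flanks of all quantified
phosphosites of the same center residue, which controls for phosphoproteome
composition — using only the significant set as background would contain
the foreground and suppress real enrichment.

Kinase assignment is a pluggable consensus-pattern library (editable YAML;
PKA, proline-directed CDK, strict CDK, MAPK, CK2, MK2 classes) or an
external prediction table joined on (accession, position); trained
predictor models are out of scope. Per-cluster kinase enrichment combines a
one-sided hypergeometric p with the proportion fold change into
`fold x (-log10 p)`, after dropping pairs with fewer than 3 in-cluster
sites: a 1-of-1 overlap produces an arbitrarily large, statistically
unsupported fold that would otherwise dominate the ranking. Annotation-set
over-representation uses the same hypergeometric machinery with BH
correction within each cluster.

# The synthetic generator

`simConfig()` defaults encode the emulated study: replicate counts
(2, 2, 3, 3) over two bridged plexes; S/T/Y site mix (84.6, 13.5, 1.9
percent); 1/2/3-site peptide mix (78.5, 19.9, 1.6 percent); five temporal
archetypes over an unregulated background, with per-cluster sizes
(150, 120, 100, 80, 50) against 4,500 background phosphopeptides (the
source reports no per-cluster counts; these are configurable defaults).
The measurement model on the log2 scale adds per-peptide base abundance
(centred so raw values sit near 100 signal-to-noise units), the archetype's
condition offset, an optional per-protein condition effect, a per-plex batch
factor (sd 0.3), a per-channel loading factor (sd 0.1), and per-measurement
noise (sd 0.25). The bridge channel is the arithmetic mean of the noise-free
sample signals, times the plex batch factor and its own noise draw —
mirroring an equal-amount pool of every sample. A configurable PSM
duplication fraction (default 0.1) exercises aggregation, and 90 percent of
sites draw localization scores above the 50 percent threshold.

Archetype shapes follow the observed cluster behaviours: C1
thrombin-induced and inhibitor-suppressed (0, +1.5, 0, +0.4 over
DMSO 0/DMSO 10/SB 0/SB 10); C2 modestly induced, inhibitor-enhanced
(0, +0.8, 0, +1.8); C3 thrombin-reduced with raised inhibitor basal
(0, -1.2, +1.2, -0.6); C4 thrombin-reduced, inhibitor-independent
(0, -1.0, 0, -1.0); C5 thrombin-reduced with lowered inhibitor basal
(0, -0.8, -1.5, -1.9). The magnitudes are free parameters chosen once so
that all five shapes stay mutually distinguishable after profile scaling at
the default noise level — in particular the basal offsets of C3 and C5 are
strong enough that row scaling does not collapse them onto C4. Kinase
motifs are embedded by writing R at -3/-2 (RRxS) around 60 percent of C1
primary sites and P at -2/+1 (PxSP) around 60 percent of C2 primary sites,
with the central residue forced to serine.

What the generator does *not* emulate: isotopic impurity and ratio
compression, missed cleavages, retention-time effects, peptide-specific
ionization efficiency, missing-value structure from MS sampling, and
database-search errors. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated noise model, not robustness to
every artefact of real spectra.

# Numerical and reproducibility choices

* One global seed fans out to per-stage seeds through a fixed integer
  derivation (stage name hashed into an offset, kept below 2^31), so stages
  are reproducible standalone and a rerun with the same configuration is
  numerically identical (manifest hashes are compared in the tests).
* Degenerate inputs have defined behaviour: constant profile rows scale to
  0.5 and are flagged; zero-variance equal-mean groups give p = 1;
  zero-variance separated groups give the smallest representable p; p = 0 is
  clamped to the machine minimum with a warning before `-log10`; constant
  replicate vectors yield a missing Spearman coefficient with a warning.
* Validation runs use scaled-down designs chosen to keep the full suite
  fast while preserving the study's structure: archetype recovery uses 20
  seeds of a 200-regulated / 600-background design, calibration uses one
  3,400-peptide null dataset (10,200 tests), batch-effect removal uses 100
  seeds of a 60-peptide two-plex design, and the dataset-descriptor checks
  use the full 5,000-peptide preset.

# Limitations

* Kinase assignment by consensus pattern is deliberately coarse; a trained
  site-specificity model will disagree on individual sites. The enrichment
  arithmetic, not the predictor, is the tested contribution.
* GO-style enrichment treats annotation sets as flat (no DAG propagation).
* The elbow criterion, like every unsupervised model-selection rule, can
  return a coarser k when cluster separations are strongly hierarchical;
  the inertia curve is always returned so the choice can be audited.
* The conservative null calibration discussed above is inherent to
  bridge-ratio normalization with plex-spanning replicates.
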