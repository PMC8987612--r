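# phosphoTMT

Quantitative analysis of multiplexed TMT phosphoproteomics experiments with
pooled bridge channels, built for time-course designs that compare an
agonist response with and without a kinase inhibitor — the motivating case
is thrombin-stimulated endothelial signaling modulated by a p38 MAPK
inhibitor, profiled as four conditions (vehicle/inhibitor × 0 min/10 min)
across two TMT 10-plexes bridged in reporter 126.

It is aimed at proteomics analysts who have peptide-level reporter-ion
quantitation (e.g. a Proteome Discoverer export) plus a channel layout and a
protein FASTA, and want a reproducible route from raw signal-to-noise values
to regulated phosphopeptides, temporal clusters, consensus motifs and kinase
enrichment. A synthetic data generator with planted ground truth makes every
stage testable.

## What it computes

* **Two-step normalization.** Each channel is divided row-wise by its plex's
  pooled bridge channel (cancelling plex batch effects), then channels are
  scaled to equal medians. PSMs are summed to unique phosphopeptides
  (key: sequence + localized site set) and corrected by the relative protein
  profile from the non-phospho peptides:
  `x̂_pc = x_pc / (y_{prot(p),c} / ȳ_{prot(p)})`.
* **Differential phosphorylation.** Per phosphopeptide and comparison, a
  two-sample t test on log2 relative abundances — pooled-variance Student
  unless an F test rejects variance equality at α = 0.05, then Welch — a
  linear-mean log2 fold change, BH q-values, and the pi-score
  π = log2FC · (−log10 p). The significant set is p < 0.01.
* **Temporal clustering.** Profiles are ratios to the vehicle 0-min control,
  min-max scaled per row; k-means (Lloyd, seeded multi-restart) with the
  cluster count chosen at the elbow of the log within-cluster
  sum-of-squares curve. Spearman replicate-correlation matrices provide QC.
* **Motif discovery.** An iterative binomial (motif-x style) search fixes
  the most over-represented (position, residue) pairs in 13-mer flanking
  windows against the quantified-phosphosite background, emitting motifs
  such as RRxS and PxSP.
* **Kinase and annotation enrichment.** Consensus-library (or external
  table) kinase assignment, per-cluster hypergeometric enrichment scored by
  fold × (−log10 p), and GMT over-representation analysis.

## Worked example

A scaled-down synthetic experiment (1,500 background + 300 regulated
phosphopeptides over the two-plex study layout), simulated, normalized,
tested, clustered and mined in one call:

```r
library(phosphoTMT)
cfg <- simConfig(seed = 42, nProteins = 150, nBackground = 1500,
                 clusterSizes = c(C1 = 80, C2 = 70, C3 = 60, C4 = 50, C5 = 40))
res <- runPipeline(cfg, outDir = "readme_run")
cat(readLines("readme_run/report.txt"), sep = "\n")
```

```
phosphoTMT run report
========================================

Phosphosite statistics:
  residue_S    85.0%
  residue_T    13.2%
  residue_Y    1.9%
  sites_1      80.6%
  sites_2      17.9%
  sites_3+     1.5%

Significant phosphopeptides (p < 0.01):
  DMSO_Th10_vs_DMSO_0      up 37 (33 proteins), down 37 (34 proteins)
  SB_Th10_vs_SB_0          up 35 (31 proteins), down 43 (38 proteins)
  DMSO_Th10_vs_SB_Th10     up 51 (45 proteins), down 40 (32 proteins)

Temporal clustering: k = 4
  cluster 1: 56 phosphopeptides
  cluster 2: 29 phosphopeptides
  cluster 3: 46 phosphopeptides
  cluster 4: 46 phosphopeptides

Top motifs:
  cluster 3: PxSP     score 17.5 (16/48 fg)
  cluster 4: RRxS     score 15.6 (15/41 fg)
  cluster 1: TxxxxS   score 4.3 (14/60 fg)

Top kinase enrichment:
  PKA        cluster 4: fold 2.92, p 3.31e-10, score 27.71
  MAPK       cluster 3: fold 2.65, p 3.26e-10, score 25.14
  CDK        cluster 3: fold 2.15, p 1.5e-07, score 14.64
  CK2        cluster 1: fold 2.42, p 0.00297, score 6.13
  CK2        cluster 2: fold 1.78, p 0.139, score 1.53
```

Reading the report: the phosphosite distribution matches the configured
S/T/Y and sites-per-peptide mixes; roughly 5% of peptides change
significantly in each comparison; the significant set clusters into four
temporal groups at this reduced scale (the clustering here pools weakly
captured archetypes — at full scale, and on the planted profiles, five are
recovered); the basophilic RRxS motif surfaces in the cluster enriched for
PKA substrates while PxSP marks the proline-directed (MAPK/CDK) cluster,
with the combined enrichment score ranking PKA and MAPK/CDK on top of their
respective clusters.

Real data enter through the same interface: `runPipeline(quantFile = ...,
layoutFile = ..., fastaFile = ...)`, or the individual stage functions
(`readQuantTable`, `bridgeNormalize`, `medianNormalize`,
`aggregateToPhosphopeptide`, `normalizeToProtein`, `filterLocalization`,
`buildSiteTable`, `differentialTest`, `buildProfileMatrix`, `kmeansFit`,
`elbowSelectK`, `motifX`, `assignKinases`, `kinaseClusterEnrichment`,
`annotationOra`). A thin command-line wrapper with `simulate`, `run` and
`report` subcommands ships in `inst/scripts/phosphotmt`.

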