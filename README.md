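# mztdecay

Maternal mRNA decay dynamics and small-RNA regulation during the
maternal-to-zygotic transition (MZT), as a tested R package plus an
analysis workflow.

During the mouse MZT, maternally deposited mRNAs are cleared in two
waves around zygotic genome activation (ZGA): one before the 2-cell
stage and one between the 2-cell and 4-cell stages. `mztdecay`
implements the computational side of dissecting that programme:

* **Decay clustering.** Maternal mRNAs (FPKM > 2 in MII oocytes) are
  classified in `log2(FPKM + 1)` space with a single margin
  δ (default 1 log2 unit):
  * cluster I (MII/2C degradation): `e(MII) > e(2C) + δ` and
    `|e(2C) − e(4C)| < δ`
  * cluster II (2C/4C degradation): `|e(MII) − e(2C)| ≤ δ` and
    `e(2C) > e(4C) + δ`
  * cluster III (continuous): `e(MII) > e(2C) + δ` and
    `e(2C) > e(4C) + δ`
* **Dependence calls.** A gene's decay leg is *AGO2-dependent* when its
  expression is increased-or-stable (not down by more than δ) in the
  AGO2-knockdown series relative to the control reference stage, and
  *ZGA-dependent* when the same rule holds under DRB transcription
  block; the intersection of the two 2C/4C sets is reported.
* **Antisense target mapping.** A native short-match engine with the
  classic report-all / mismatch-bound / multimap-cap semantics
  (`-a -m 20 -v 2`-style): every ungapped placement of a small RNA on
  every transcript, both orientations, Hamming distance ≤ v; queries
  with more than m total placements are suppressed. Antisense hits
  define the endosiRNA → maternal-mRNA target table. A declared
  seed-match stand-in (exact match to the reverse complement of miRNA
  positions 2–8) covers the microRNA comparison.
* **CMR-lncRNA screen.** lncRNAs passing an ORF-length coding-potential
  stand-in are screened for long ungapped antisense blocks (≥ 20 nt,
  ≤ 5% mismatch) against targeted mRNAs; pairs whose blocks cover
  > 90% of the lncRNA are reported, and lncRNA loci are labelled by
  majority genomic context (intron / coding exon / UTR exon /
  intergenic).
* **saRNA promoter screen.** Expressed 18–30 nt small RNAs (RPM > 1 at
  zygote or 2-cell) are matched into strand-aware 1-kb TSS-upstream
  windows of ZGA genes; offsets are measured from the TSS to the
  TSS-proximal end of the hit and histogrammed (the biological
  expectation is a 200–400 bp mode).
* **Kinetics and qPCR.** First-order decay `N(t) = N0·e^(−kt)` fitted
  by log-linear least squares with `T1/2 = ln 2 / k`, and 2^−ΔΔCt
  relative quantification with reference-gene Ct averaging.
* **Synthetic data.** A generator plants all of the above — cluster
  dynamics, dependence flags, antisense guides with 0–2 mismatches,
  complementary lncRNA blocks straddling the 90% threshold, promoter
  saRNA placements, decay constants — and records exact ground truth,
  so the whole pipeline runs and is scored offline.

## Worked example

```r
library(mztdecay)

cfg <- synth_config(seed = 20260923)          # study-scale defaults
dir <- "results/synthetic"
write_synthetic_dataset(cfg, dir)
res <- run_all(dir, "results/pipeline")
print(res$summary)
```

which prints (seed 20260923):

```
                     quantity count
1                   cluster_I   500
2                  cluster_II   400
3                 cluster_III   299
4                        none   801
5    ago2_dep_MII_2C_clusterI   252
6  ago2_dep_MII_2C_clusterIII   157
7    ago2_dep_2C_4C_clusterII   203
8   ago2_dep_2C_4C_clusterIII   154
9               zga_dependent   359
10           zga_ago2_overlap   189
```

2,000 genes were planted as 500/400/300/800 across clusters
I/II/III/none with log2-noise 0.2: the classifier recovers 99.9% of the
planted labels (two genes cross a margin under noise at this seed);
the dependence counts match the planted knockdown/DRB stabilisation
flags. The same run maps 2,000 planted antisense guides onto 397
maternal transcripts with zero suppressions and 100% recovery, reports
exactly the 50 lncRNAs planted above the 90% coverage threshold, and
recovers all 150 planted promoter saRNAs with the histogram mode in
the 200–400 bp band.

The step-by-step version of this analysis lives in `analysis/01…07`,
each a short driver that prints what it found and writes TSVs (with
provenance headers) under `results/`.

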