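---
title: "Methods: maternal mRNA decay classification and small-RNA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maternal mRNA decay classification and small-RNA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mztdecay)
```

This vignette is the package's account of its methods: the models and
rules implemented, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices made where the design was genuinely open.

## The decay-classification model

All expression comparisons operate on `log2(FPKM + c)` with
pseudocount `c = 1`. The pseudocount bounds the transform at zero for
unexpressed genes and damps ratios at low expression; every rule below
is a difference of such log values, so classification is invariant to
multiplicative rescaling of a gene's profile (only the maternal FPKM
threshold sees the absolute scale).

Maternal mRNAs are the transcripts with FPKM strictly above 2 in MII
oocytes. A single margin δ (`log_delta`, default 1 log2 unit, i.e. a
two-fold change) serves as the significance surrogate everywhere:

* a *drop* between consecutive stages is `e1 > e2 + δ`;
* *stable* is `|e1 − e2|` within δ;
* under a perturbation (AGO2 knockdown, DRB transcription block),
  *increased or stable* means the treated value has not fallen more
  than δ below the control reference stage.

Clusters I/II/III are conjunctions of these primitives (see
`?classify_decay`). Two remarks belong on the record:

1. **Cluster-II repair.** The printed form of the cluster-II criteria
   in the source methods is self-contradictory (it requires MII to be
   simultaneously more than one unit above and more than one unit
   below the 2-cell value). The narrative description of cluster II —
   no significant MII-to-2C change followed by a sharp 4-cell drop —
   is unambiguous, so the implementation uses
   `|e(MII) − e(2C)| ≤ δ` and `e(2C) > e(4C) + δ`.
2. **No differential-expression test.** The δ-margin rules are the
   sole significance criterion. A count-based test (e.g. a negative
   binomial model) is out of scope here and would require replicate
   structure the stage-wise FPKM tables do not carry.

The three cluster conditions are mutually exclusive by construction
(clusters I and III disagree on the second leg, cluster II's stable
first leg excludes the other two), and cluster III membership is
non-increasing in δ; both facts are asserted as property tests.

Dependence flags reuse δ: the comparison baseline for the knockdown
2-cell value is the *control MII* stage (taken literally from the
described contrast), and for the knockdown 4-cell and DRB values the
*control 2-cell* stage. Boundary values fall outside clusters
(strict inequalities as printed); the perturbation rule is inclusive
(`≥ reference − δ`) so that "exactly stable" counts as blocked decay.

## The antisense matcher

The endosiRNA target screen is a native reimplementation of the
classic ungapped short-match semantics: report **all** placements
(`-a`), Hamming distance at most `v = 2`, and total-placement cap
`m = 20` above which the query is suppressed entirely rather than
truncated. Both orientations are enumerated and count toward the cap
(guide-strand ambiguity; the original screen's strand handling is not
stated), but only antisense placements are targeting evidence
downstream. `N` never matches anything, including `N` — a conservative
choice that cannot inflate hit counts. Hits are sorted by
(transcript, start, orientation) so output order is reproducible.

The matcher is a compiled early-exit scan; its independent oracle in
the test suite is Biostrings pattern matching, and the two are
required to be set-identical over randomized instances at the study
scale (100 transcripts × 500 nt, 200 queries, all v/m combinations).

The microRNA side uses a **declared stand-in**: a transcript is a
target iff it contains the exact reverse complement of the miRNA seed
(positions 2–8). This exists so the endosiRNA-versus-microRNA
comparison runs offline; it does not reproduce external target-scoring
pipelines, and no conclusion in this package depends on its absolute
counts.

## The CMR-lncRNA screen

"Complementary to a maternal mRNA" is operationalised as ungapped
antisense blocks between the reverse complement of the lncRNA and the
mRNA: maximal diagonal runs of length ≥ `min_block` (20 nt) with a
per-block mismatch fraction ≤ 5%. Blocks are grown greedily from match
runs, absorbing a mismatch gap only while the block still begins and
ends on a match and stays under the mismatch budget. A non-overlapping
subset of blocks maximising covered lncRNA length is chosen by
weighted-interval scheduling, and the pair is reported when coverage —
covered bases over lncRNA length — strictly exceeds 90%. The
denominator choice (lncRNA length) is an interpretation of the
original "alignment ratio" and is recorded as such; the thresholds are
exposed as arguments.

For speed, only diagonals that carry a shared exact k-mer between the
reverse-complemented lncRNA and the mRNA are scanned. With defaults,
any admissible block (≥ 20 nt, ≤ 1 mismatch per 20) must contain an
exact run of at least ⌈(20−1)/2⌉ = 9 bases by pigeonhole, so k = 9
seeding cannot lose a reportable block; the equivalence with a full
all-diagonal scan is itself a test.

The coding-potential step is a second **declared stand-in**: sequences
whose longest six-frame ATG→stop ORF is under 100 codons are retained
as noncoding. ORFs require an in-frame stop; open-ended reading
frames are not counted.

Genomic context uses majority labelling: a locus takes the class
(CDS, exon-minus-CDS, gene-minus-exon, intergenic) covering more than
half of its span, else `mixed`; unplaced loci are excluded from the
fraction table.

## The saRNA screen

Candidates are small RNAs of 18–30 nt with RPM strictly above 1 at the
zygote or 2-cell stage. Promoter windows are strand-aware 1-kb
upstream regions whose last base is TSS-adjacent: genomic
`[TSS−1000, TSS)` on `+`, reverse-complemented `(TSS, TSS+1000]` on
`−`; chromosome-edge windows are truncated and flagged. Matching
reuses the antisense matcher with `v = 0` — the original pipeline
states alignment without parameters, and exactness is the conservative
default (v is exposed). The reported offset is the distance from the
TSS to the hit's TSS-proximal end (convention unstated in the source;
this one makes "200–400 bp upstream" readable directly), and both
promoter strands are scanned with orientation recorded. Histograms use
half-open 100-bp bins and conserve the hit count.

## Kinetics and qPCR

Time courses are relative abundances after transcription block, with
t = 0 at treatment and abundance renormalised to 1 at t = 0. The decay
model is first-order, `N(t) = N0·e^(−kt)`; the source names only a
curve-fitting package, so the model family is this package's choice,
and fitting is done on the log scale where least squares is closed
form and multiplicative noise becomes additive. `T1/2 = ln 2 / k`
exactly; a non-positive `k` yields an infinite half-life and a flag
(infinite = most stable in comparisons). A nonlinear refit on the
linear scale (`method = "nls"`, Gauss–Newton initialised from the
log-linear fit, `scaleOffset` so perfect fits converge) is available
for users who prefer untransformed residuals.

ΔΔCt follows the textbook form: ΔCt is the target Ct minus the
*arithmetic mean* of the reference Cts (equivalent to a geometric mean
of linear quantities; the source lists two reference genes without an
aggregation rule), and the result is `2^−(ΔCt − calibrator ΔCt)`.
Amplification-efficiency correction is out of scope.

## What the generator emulates — and what it does not

The generator plants every ground truth the pipeline is scored on:

* **Expression**: 2,000 genes, cluster proportions 0.25/0.2/0.15/0.4,
  baseline `log2(FPKM+1)` between 3 and 8, planted decay steps drawn
  from [1.5δ, 3δ] so effects stay separable under the default
  log2-noise sd of 0.2. The baseline is additionally drawn above
  (total planted decay + 0.5): the linear scale floors FPKM at zero,
  and without this constraint a deeply decayed gene's final level
  would be clamped and its planted margin eroded. Half of the eligible
  cluster genes are planted AGO2-dependent per leg and half of the
  2C/4C-degrading genes ZGA-dependent; the knockdown/DRB matrices hold
  the pre-decay level for stabilised genes.
* **Sequences**: 400 transcripts × 500 nt; 5,000 small RNAs of which
  40% are antisense guides copied from transcript windows with
  0/1/2 mismatches (probabilities 0.5/0.3/0.2) and the rest decoys;
  50 microRNAs, half with planted seed sites; 200 lncRNAs, half
  carrying complementary blocks at coverages 0.95/0.93/0.85/0.80
  cycling (straddling the 0.9 threshold), plus 100 scrambled decoys;
  a ~1 Mb toy chromosome with 300 genes
  (UTR/intron/CDS/intron/UTR structure) and 150 saRNAs written into
  promoter windows, 70% at 200–400 bp offsets; 50 lncRNA loci placed
  at exact 40/20/10/30% intron/CDS/UTR/intergenic proportions.
* **Kinetics**: control k = ln 2/2 per hour (2 h half-life), mimic 2×,
  inhibitor 0.5×, six timepoints over 8 h, multiplicative log-normal
  noise at 5% CV, 200 replicates per condition.

Two generator-side choices keep the truth tables *exact* rather than
probabilistic: planted guides and decoys are rejection-sampled until
their placement sets are exactly as recorded (a random decoy has a
~2×10⁻⁴ chance of a spurious ≤2-mismatch placement, which would
otherwise contaminate exact-recovery checks), and the padding around
planted lncRNA blocks is drawn to mismatch the mRNA along the planted
diagonal so greedy block extension cannot inflate the planted
coverage. Promoter plantings never overlap within a window. One global
seed fans out to fixed per-component substreams, so regenerating one
component never perturbs the others.

What the generator does **not** emulate: empirical FPKM distributions
(real stage matrices are heavy-tailed and replicate-structured),
read-level noise and mapping artefacts, transcript families and
repeats (which drive real multimap suppression), genomic base
composition, RNA secondary structure, and any coupling between a
gene's expression and its sequence. Passing tests therefore
demonstrate that the implementations compute their definitions
correctly and recover planted structure at realistic noise — not that
the thresholds would reproduce counts from real sequencing data.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; GFF3's
  1-based closed convention is converted only at the parse/serialise
  boundary, and BED passes through unchanged.
* U→T normalisation and upper-casing happen at parse time; all
  matching operates on the DNA alphabet.
* Output TSVs carry `#` provenance headers (package version,
  parameters) and serialise doubles at 6 significant digits; the run
  manifest records input checksums. Identical inputs and parameters
  give byte-identical outputs.
* Ties and order: hits sort by (transcript, start, orientation);
  context labelling breaks exact ties as `mixed` (no majority).
* Degenerate inputs: empty matrices classify to empty assignments;
  an empty small-RNA pool gives an empty target map; empty hit lists
  give empty histograms with a warning; a gene missing from a
  perturbation matrix is unassessable (`NA` flag plus warning) rather
  than silently false.
* Problem sizes in the checked examples (50 matcher instances of
  100 × 500 nt with 200 queries; 2,000-gene matrices; the default
  generator scale above) were chosen as the smallest sizes at which
  every screen is exercised with planted positives and negatives on
  either side of its threshold; they complete in minutes on one CPU.

## Known limitations

* The δ-margin rules are deliberate simplifications of
  replicate-aware differential testing; absolute cluster counts on
  real data would differ from any count-based pipeline.
* The seed-match and ORF-length stand-ins are placeholders for
  external tools and should not be interpreted beyond "the comparison
  is exercisable".
* The block-based complementarity screen approximates local alignment
  without gaps; a lncRNA complementary through a gapped alignment
  would be under-covered.
* Half-life fitting assumes single-exponential decay; biphasic decay
  would bias `k` toward the slower phase on late timepoints.
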