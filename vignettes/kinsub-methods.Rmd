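---
title: "Predicting site-specific kinase-substrate relationships with multi-kernel ridge classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting site-specific kinase-substrate relationships with multi-kernel ridge classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsub)
```

## The problem

A site-specific kinase–substrate relationship (ssKSR) is the assertion that
kinase $K$ phosphorylates residue $P$ of substrate protein $S$.
High-throughput phosphoproteomics discovers phosphosites far faster than the
responsible kinases can be assigned experimentally, so computational ranking
of candidate kinases for each site is a standard step in pathway analysis.
Most predictors rely on the local sequence around the site, sometimes
filtered by protein–protein interaction (PPI) evidence.  `kinsub`
additionally exploits the bipartite network of *known* site–kinase
annotations: kinases are pleiotropic and sites are frequently phosphorylated
by several kinases, so a site's annotation profile carries information about
which further kinases are plausible.

## The model

Each phosphosite $s_i$ is represented three ways, and each representation
yields an $n \times n$ site-similarity kernel:

1. **Sequence kernel** $K_\mathrm{seq}$.  The 15-residue window (7 up- and
   7 downstream of the site) is compared positionwise with BLOSUM62:
   $S_\mathrm{seq}(i,j) = \sum_{k=1}^{15} \mathrm{BLOSUM62}(s_i(k), s_j(k))$,
   then min–max normalized over the whole matrix to $[0,1]$.
2. **PPI kernel** $K_\mathrm{ppi}$.  A site inherits its substrate's
   STRING-style interaction-partner set $J_p$ (edges kept at combined
   confidence $\ge 0.4$); similarity is the Jaccard index
   $|J_{p_i} \cap J_{p_j}| / |J_{p_i} \cup J_{p_j}|$.  Sites on the same
   substrate are maximally similar whenever the substrate has any partner.
3. **Network-profile (pSKN) kernel** $K_\mathrm{net}$.  With $Y$ the binary
   site-by-kinase adjacency ($y_{ij} = 1$ when site $i$ is annotated to
   kinase $j$), each site's profile is its row $y_{s_i}$ and
   $K_\mathrm{net}(i,j) = \exp(-\gamma_s \lVert y_{s_i} - y_{s_j}\rVert^2)$
   with bandwidth
   $\gamma_s = \gamma_s' \big/ \tfrac{1}{n}\sum_i \lVert y_{s_i}\rVert^2$,
   i.e. a base bandwidth rescaled by the mean annotation density.

The kernels are combined elementwise,
$K = \sum_\varphi \eta_\varphi K_\varphi$ with equal weights
$\eta_\varphi = 1/3$ (weights are renormalized to sum to one when an
ablation drops a component).  For each kinase with at least 15 annotated
sites, a kernel ridge classifier is fitted on 0/1 labels (annotated sites of
that kinase versus *all* other sites, with no residue-type filtering of
negatives): the dual coefficients solve $(K + \lambda I)\alpha = y$ and a
query with kernel row $k_x$ scores $f(x) = \alpha^\top k_x$.  Scores are
used for ranking only; no probability calibration is attempted.

## Leakage and the mask policy

The network profile of a site contains, among other entries, its label for
the target kinase.  Training and evaluating with the raw profiles therefore
lets the classifier read its own answers.  `kinsub`'s default policy,
`mask_target_column`, deletes the target kinase's column from $Y$ before
both the bandwidth and the kernel are computed, for training and scoring
alike.  Two further policies are provided for ablation studies:
`strict_zero_test_rows` additionally zeroes the full profiles of held-out
sites (the most conservative reading, in which a test site's other-kinase
annotations are also treated as unknown), and `none` reproduces the naive
transductive computation.  The package's test suite pins this behaviour
quantitatively: on data with no planted signal, the network-only model
reaches AUC $\ge 0.95$ under `none` and chance level under
`mask_target_column`.

## Cross-validation protocol

Evaluation uses seeded, stratified 10-fold cross-validation per kinase.
Inside each fold every kernel is rebuilt from training-fold information
only: the sequence min/max comes from the training submatrix (test rows are
mapped with the stored range and clipped to $[0,1]$); the network bandwidth
is computed from the training rows of the masked adjacency; the PPI kernel
is static because it never involves labels.  Folds are stratified because
kinases near the 15-positive floor would otherwise regularly produce
single-class test folds; a fold that is single-class anyway has its AUC
skipped with a warning, while the pooled AUC is unaffected.

Two AUC summaries are reported: the mean of per-fold AUCs and the AUC of
the pooled out-of-fold predictions.  Pooled predictions are also the basis
of the stringency-level metrics, because pooling admits a single
well-defined threshold per specificity target.  At a target specificity
(medium 0.90, high 0.95 by default) the threshold is chosen among the
achievable operating points — no ROC interpolation — maximizing sensitivity
subject to $\mathrm{Sp} \ge$ target; ties resolve to the lowest feasible
threshold so the realized specificity sits as close to the target as the
finite negative set allows, and the realized value is always reported.
Confusion metrics follow the usual definitions (Sn, Sp, Pre, F1, MCC); any
zero denominator yields 0 with an explicit `degenerate` flag rather than an
`NaN` in batch tables.  Top-percentile retrieval counts known positives
among the top $\lfloor p/100 \cdot n\rfloor$ ranks with ties broken by
stable site order.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lambda` | 1 | ridge regularizer; no tuning by default so runs are deterministic |
| `kernel_weights` | 1/3 each | combination weights over seq/ppi/net |
| `gamma_prime` | 1 | base bandwidth of the network kernel, the Gaussian interaction-profile convention |
| `cutoff` | 0.4 | STRING combined-confidence threshold (medium confidence) |
| `min_positives` | 15 | annotation floor for a kinase to be modeled |
| `flank`, `pad` | 7, `"X"` | window half-width and terminal pad character |

The pad character scores zero against every residue, so windows truncated
by a protein terminus are neither rewarded nor punished.  With the default
pad `"X"`, a genuine X ambiguity residue also scores zero — the pad rule
takes precedence over the BLOSUM62 X row; choose a non-residue pad such as
`"-"` to keep that row live.  Coordinates are 1-based throughout, matching
UniProt convention.

## Numerical choices

The ridge system is solved by Cholesky factorization, never by explicit
inversion; a single jitter retry ($+10^{-8}$ on the diagonal) handles
borderline conditioning and is logged loudly, and the solve is verified to
a residual below $10^{-8}$.  The sequence and PPI kernels are not
guaranteed positive semidefinite; the ridge term regularizes the solve and
no spectral correction is applied.  Empty-versus-empty partner sets have
Jaccard similarity 0, so substrates without any PPI evidence do not appear
maximally similar to one another.  Sequence-kernel normalization is
degenerate when all pairwise raw scores coincide; this raises an explicit
error rather than returning a constant matrix.

## What the synthetic benchmark emulates

Because curated phosphosite/kinase/PPI extracts cannot be shipped or
downloaded at test time, the package carries a seeded generator
(`synth_spec()`, `generate_dataset()`) that plants exactly the three kinds
of structure the method exploits:

* **Sequence motifs** — each kinase has a preferred phosphoacceptor and 4
  informative flank positions; a positive site's window is drawn from the
  motif with probability `motif_strength` (preferred residue with
  probability 0.8 at informative positions, background elsewhere).
* **Correlated profiles** — each positive site is co-assigned to the
  kinase's designated partner (the cyclic successor) with probability
  `kinase_overlap`, emulating shared-site pleiotropy.
* **PPI coherence** — each kinase owns 12 hub proteins; a substrate
  carrying that kinase's positives attaches to the hub set with
  probability `ppi_coherence`, on top of 8 background partners per
  substrate and a batch of sub-cutoff edges that exercise the confidence
  filter.

The default composition is 150 substrates with 2 sites each (300 sites),
5 kinases with 30 positives apiece, and knob settings 0.7/0.5/0.5.
Positives are sampled site-wise and independently across kinases: with
every knob at zero the dataset then carries no label structure at all, which
keeps the chance-level calibration tests meaningful.  (An earlier
block-per-substrate design was rejected precisely because substrate
membership alone then predicted labels through the same-substrate PPI
rule.)  Two sites per substrate keeps the realistic same-substrate PPI
ambiguity — a negative site on a positive substrate looks identical to the
PPI kernel — without letting it drown the hub signal.  Problem sizes
throughout the test suite and the acceptance script (300 sites, 10
replicates, 10 folds) were chosen so the full evaluation remains a
desk-scale computation.

What the generator does **not** emulate: real phosphoproteome amino-acid
composition, STRING's degree distribution, kinase families with shared
motifs, and redundancy between substrate sequences.  Passing the benchmark
therefore demonstrates that the implementation recovers planted structure
of the right kind with the expected ordering
(sequence < sequence+profiles < full), not that the same margins would be
observed on curated databases.

## Design points that were genuinely open

* **Window truncation at termini** is handled by zero-scoring pads; any
  other convention (dropping positions, repeating terminal residues) would
  couple window length to position, which the positionwise sum does not
  expect.
* **Sequence-kernel normalization scope**: the min/max is learned on the
  training matrix and *applied* (with clipping) to test rows, rather than
  normalizing train and test jointly; the transductive alternative leaks
  the test distribution into training scale.
* **Labels** are 0/1 rather than $\pm 1$; thresholds are always derived
  from operating points, never hard-coded at 0.5.
* **All negatives are used** — negatives are every other modeled site
  regardless of residue type, including chemically impossible acceptors
  for the kinase at hand; a `residue_filter` exists but defaults to off.
  Class imbalance is absorbed by the ridge penalty, not by subsampling or
  reweighting.
* **Redundancy removal is consumed, not computed**: an optional cluster
  map (member → representative accession) restricts a bundle to
  representative substrates; no clustering is performed in-package.
* **`lambda` is fixed at 1** for headline runs; a CV-based grid search
  would be easy to add but makes results seed-dependent in a way that
  hinders reproduction.

## Known limitations

Scores are uncalibrated and comparable only within one kinase's model.
Kinases below the annotation floor are not modeled at all.  The network
kernel is only informative for query sites that already have *some*
annotations (to non-target kinases); truly novel sites fall back on
sequence and PPI information, with the network component contributing a
constant.  The PPI kernel cannot distinguish sites on the same substrate.
Dense kernels mean memory grows quadratically in the number of sites; the
intended scale is $10^3$–$10^4$ sites.

## Reproducing the package's own numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates the default
benchmark (10 replicates), runs the three ablations over every modeled
kinase, and writes the mean pooled AUCs, the two ablation gaps, the
leakage-guard pair, the permutation null, and the medium-stringency
sensitivity as JSON.  Every number is recomputed at run time; nothing is
cached or tabulated in the repository.
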