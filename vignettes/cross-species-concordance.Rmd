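---
title: "Cross-species transcriptome concordance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species transcriptome concordance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossConcord)
```

# The problem

A recurring question in cancer genomics is whether a genetically
engineered mouse model actually recapitulates the human disease it is
meant to model. crossConcord implements a comparative functional genomics
workflow that answers this at the transcriptome level for a two-platform
microarray study: a four-group mouse liver cohort (wild-type and knockout
at 6 and 24 months, three replicates each, with tumors in the aged
knockouts) and a human hepatocellular carcinoma cohort (2 normal livers,
4 early-stage T1 tumors, 6 advanced T3 tumors). The two platforms use
different probe-set identifiers, linked only by a many-to-many
probe-to-ortholog annotation.

The workflow has five stages, each exposed as ordinary functions so any
stage can be rerun in isolation:

1. **Differential expression (SAM).** Two-class unpaired Significance
   Analysis of Microarrays with permutation-estimated FDR and a separate
   fold-change gate.
2. **Gene-pattern clustering.** Unsupervised hierarchical clustering of
   the standardized per-group mean profiles of the union of
   differentially expressed genes, with a consensus of three
   cluster-number indices.
3. **Ortholog mapping.** Collapse of probe-level expression onto shared
   gene symbols with exclusion / average / split rules.
4. **Integration and co-clustering.** Per-species standardization,
   clipping to [-3, 3], and clustering of the samples of the combined
   matrix to see which human disease stage the mouse tumors join.
5. **Concordance.** Direction agreement of tumor-vs-normal fold changes
   across species.

# The SAM statistic and its FDR

For groups A and B with $n_A$ and $n_B$ samples, each feature gets the
relative difference

$$d_i = \frac{\bar{x}_{B,i} - \bar{x}_{A,i}}{s_i + s_0},\qquad
s_i = \sqrt{\tfrac{1}{n_A} + \tfrac{1}{n_B}}
      \sqrt{\frac{SS_{A,i} + SS_{B,i}}{n_A + n_B - 2}},$$

where $s_0$ is the exchangeability ("fudge") factor that keeps
low-variance features from dominating. `tuneS0()` selects $s_0$ among the
percentiles $\{0, 5, \dots, 95\}$ of the $s$ distribution by minimizing
the coefficient of variation of $\mathrm{mad}(d)$ across windows of the
$s$ distribution; below 50 features that criterion is too noisy and the
median of $s$ is used. Fold change is computed on the linear scale from
the log2 group means, $fc_i = 2^{\bar{x}_{B,i} - \bar{x}_{A,i}}$.

`permutationFdr()` permutes the group labels of the pooled samples. When
the number of distinct balanced assignments is within the permutation
budget (20 for a 3-vs-3 design) all of them are used exactly once;
otherwise a seeded sample is drawn. Sorting each permuted $d$ vector and
averaging order statistics gives the expected null $\bar{d}_{(i)}$. For a
threshold $\delta$, features are called *asymmetrically*: sorted features
with $d_{(i)} - \bar{d}_{(i)} > \delta$ (above the upper cutpoint) or
$< -\delta$ (below the lower cutpoint). The estimated FDR at $\delta$ is
$\pi_0$ times the median permutation count of values beyond the cutpoints
divided by the number called; $\pi_0$ is fixed at the conservative 1 by
default. The selected $\delta$ is the smallest value on the grid of
observed exceedances with estimated FDR at or below the bound — the most
permissive calling set that still meets it. Whether the original analysis
used symmetric or asymmetric exceedance is not documented anywhere we
could check; the asymmetric two-cutpoint form of the published method is
used and stated here rather than guessed silently.

Two deliberate contracts: the fold-change gate is applied *after*
$\delta$ selection, so relaxing the gate from 3-fold (within-species
screen) to 2-fold (cross-species screen) can only enlarge the significant
set; and order-statistic ties are broken by feature-id lexicographic
order so a fixed seed makes the whole run bit-reproducible. When no
$\delta$ meets the bound the run records $\delta = \infty$ and an empty
calling set — a legitimate outcome on null data, not an error.

# Clustering and the cluster-number consensus

Distances are $1 - r$ (Pearson) between standardized profiles.
Standardization uses the population (n) denominator; this only rescales
rows, so correlation distances are identical under either convention, and
it is stated here purely for reproducibility. Constant profiles cannot be
correlated and are zeroed and flagged upstream.

Average linkage is implemented directly: at each step the pair of
clusters with the smallest mean cross-cluster distance merges; distances
are recomputed from the raw matrix as block means rather than via the
incremental Lance-Williams update, so merge heights carry no accumulated
rounding drift and can be checked exactly against a brute-force
re-implementation. Ties break toward the lexicographically smallest pair
of cluster ids (leaves are numbered 1..n in input order, the merge at
step t is n+t), which fixes the dendrogram even on degenerate distance
matrices.

Gene-pattern clustering runs on the per-group mean profiles (four
coordinates in the mouse design) of the SAM union set, standardized row
by row. Three indices score each candidate k after cutting the tree:

* **Silhouette**: mean of $(b_i - a_i)/\max(a_i, b_i)$; singletons score
  0 by convention.
* **Weighted inter/intra ratio**: mean distance over all between-cluster
  point pairs divided by the mean over all within-cluster pairs. "Weighted"
  is interpreted as pair-count weighting — every point pair counts once,
  so large clusters weigh proportionally. The index is not
  formula-specified in the literature trail available to us; this
  interpretation is a declared design choice.
* **Homogeneity - separation**: mean item-to-own-centroid correlation
  minus the size-pair-weighted mean centroid-to-centroid correlation.

Silhouette and homogeneity-separation nominate their argmax k. The
inter/intra ratio grows monotonically in k, so its nomination is the
*knee* of the curve. We define the knee as the interior k with the
largest drop in marginal gain, i.e. the maximum discrete concavity
$(r_k - r_{k-1}) - (r_{k+1} - r_k)$. An earlier draft used the maximum of
the second difference itself (maximum convexity); on curves that jump at
the true cluster number and then flatten — exactly the planted-archetype
shape — that lands systematically one below the jump, so the concavity
form was adopted. The consensus is the majority nomination, the median
when all three differ, and any residual ambiguity resolves toward the
silhouette nominee. With four-coordinate standardized profiles the
centroids are strongly negatively correlated at small k, which biases the
homogeneity-separation argmax low; the consensus absorbs this because the
other two indices agree on well-separated structure.

# Ortholog mapping: exclusion, average, split

Probes without any link in the ortholog table are excluded. A probe
linked to $m$ genes contributes $x/m$ to each (the split is performed on
the log2-scale values — a scale oddity inherited from the procedure being
reimplemented, absorbed downstream by per-species standardization; a
`replicate` mode that copies the full value instead sits behind
`splitMode`). A gene's value is the arithmetic mean of its incoming
contributions. The procedure is stated in the source material as a
sequential per-probe loop, which would be order-dependent; the
implementation is the order-independent closed form
$g = \mathrm{mean}_{p \in P_g}(x_p / \deg p)$, and a property test checks
that the per-sample contribution mass exactly reconstructs the mapped
probe values. Symbol matching at integration is case-canonical (trimmed
upper-case) with no alias or synonym resolution — resolving aliases would
require a live annotation database, which is out of scope.

Integration keeps the symbol intersection of the two species' mapped DE
gene sets, standardizes each species' block row-wise so the expression
scales are comparable, concatenates (first species then second), and
clips to [-3, 3]. Whether clipping preceded or followed integration in
the original procedure is not documented; here standardization is per
species, then integration, then clipping, and the clip range is a config
knob.

# Concordance

Tumor-vs-normal log2 fold change per species is a plain difference of
group means on the log2 scale. "Similar expression profile" is
operationalized as *sign agreement* of the two fold changes; genes with
an exactly zero fold change in either species are flagged and counted
non-concordant. A stricter variant requiring at least 2-fold magnitude in
both species sits behind `concordance_mode = "sign_and_magnitude"`.

The human screen pools T1 and T3 tumors against normal by default — the
original contrast is not documented, so the pooled contrast is declared
in the config where per-stage contrasts can be substituted.

The rate is reported three ways: the raw fraction; the half-up integer
percent; and a display percent that first rounds to the nearest 0.5
percent and then half-up to an integer. The display rule exists because a
rate of 117/151 = 77.483% is conventionally quoted as 78%: 77.483 rounds
to 77.5 at 0.5-percent resolution and then up to 78. All three renderings
are emitted side by side so the discrepancy between 77 (strict half-up)
and 78 (display) stays visible rather than silently resolved.

# qPCR validation

`ddctAnalysis()` implements relative quantification for a profiler
plate: per sample, each gene's Ct is normalized by the arithmetic mean Ct
of the housekeeping set (Gusb, Hprt1, Hsp90ab1, Gapdh, Actb by
convention; arithmetic mean of Ct equals the geometric mean of linear
quantities); the group difference of normalized values gives
$\Delta\Delta Ct$ and $FC = 2^{-\Delta\Delta Ct}$. The per-gene test is a
two-sided Welch t-test on the per-sample $\Delta Ct$ values — the plate
template's test is not documented, and the unequal-variance form is the
safer default. Selection requires both the fold-change cutoff (3 by
default) and p < 0.05. Zero within-group variance (possible on noiseless
synthetic plates) is guarded: equal means give p = 1, different means
p = 0. Undetermined wells are expected to be encoded at a configurable
Ct ceiling (40) before import. Efficiency-corrected models and melt-curve
QC are out of scope.

# The synthetic study generators

`simulateTwoSpecies()` emulates the dual-cohort structure: 2000 shared
ortholog symbols behind 2500 probes per platform, per-gene baselines
N(8, 2²) log2 units, replicate noise sd 0.25 (a bulk-microarray
convention), 155 planted differentially expressed genes with |log2 FC|
uniform on [1.6, 4.4] (roughly 3- to 21-fold, the magnitude range the
workflow is designed around), and cross-species direction agreement with
probability 0.78. Mouse effects apply to the aged-knockout (KO24) tumor
group; human effects apply to tumors with T1 attenuated to 0.6 of the T3
effect, encoding disease progression. Probe wiring is many-to-many at
rate 0.15 per side (a second probe per gene / a second gene per probe);
gene symbols are styled mouse title-case versus human upper-case so the
case-canonical matching path is always exercised. The planted count of
155 was chosen so that, after both species' 2-fold SAM screens, the
surviving ortholog intersection sits near the 151-gene scale of the
target study design.

`simulateFourGroup()` plants group-mean archetypes (KO24-high, KO24-low,
age-up, age-down, KO-up, ...) with per-feature amplitudes from the same
fold-change range plus a 0.1-sd pattern jitter, enabling cluster-number
recovery tests. `simulateQpcr()` plants the 11-gene Wnt-pathway readout
(8 up, 3 down) among 84 panel genes with Ct noise sd 0.2 cycles and
per-sample loading offsets that housekeeping normalization must remove.

One global seed drives everything; each generator stream derives a child
seed as `(seed * 48271 + stream * 9973 + 1) mod (2^31 - 1)`, so
individual pieces of a study can be regenerated independently and all
seeds remain valid 32-bit integers. Every generator returns a truth
ledger (also written as JSON alongside the study files); recovery tests
read planted truth only from the ledger.

What the generators deliberately do **not** model: probe-level affinity
effects and background (the pipeline starts from summarized probe-set
matrices, so CEL-level realism adds nothing testable here), batch
effects, and array spatial artifacts. Tests passing on these simulations
therefore certify the statistical machinery and its contracts — FDR
control under exchangeable Gaussian noise, recovery of planted structure
— not robustness to the full messiness of archival array data.

# Problem sizes used by the test suite

The acceptance-style checks run at sizes chosen to keep the suite fast
while leaving the statistics meaningful: SAM null control over 20 seeded
5000-feature 3-vs-3 null studies; power on 200 features planted at
8-fold; linkage oracle equivalence on 100 random instances of up to 12
items (brute force is cubic, so small n suffices for an exact check);
consensus recovery over 25 seeded four-group studies; concordance
recovery over 100 seeded dual-species studies at the default scale
(~145–155 surviving orthologs per run); co-clustering recovery over 25
studies.

# Known limitations

* The FDR estimate is the global median-based SAM estimate; no per-gene
  q-values or local FDR.
* Only the two-class unpaired SAM variant is implemented (no paired,
  multiclass or survival forms), matching the study designs handled.
* Ortholog mapping trusts the annotation table; no synonym resolution,
  and annotation provenance is the caller's responsibility.
* The consensus rule (majority, then median, then silhouette preference)
  is a reproducibility convention; other defensible rules exist and can
  disagree on weakly separated data.
* Heat-map rendering is out of scope; the package exports the clustered
  matrices and Newick dendrograms from which figures can be drawn.
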