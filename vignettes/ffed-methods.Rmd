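---
title: "Fractional factorial exposure designs for multiplexed omics: methods and design choices"
author: "ffedomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional factorial exposure designs for multiplexed omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffedomics)
```

# The problem

Testing six environmental exposures one at a time in human neural
progenitor cells is expensive: six factors across four cell lines with five
replicates each needs 120 samples before a single interaction can be
examined. A two-level fractional factorial design does far better. The L8
orthogonal array assigns each of eight culture runs a combination of all
six exposures simultaneously, so that every factor is applied to exactly
half the runs and any two factors vary independently of one another.
Thirty-two samples (8 runs x 4 cell lines) then support estimates of every
main effect, and — at the cost of aliasing — a subset of two-way
interactions.

`ffedomics` implements that design algebra together with the downstream
analysis layers such a study needs: negative-binomial differential
expression at four stratification levels, preranked gene-set enrichment
with similarity networks, a permutation test for spatio-temporal
enrichment of gene groups, a differential exon usage test, and
internal-standard quantification of metabolite features. A first-class
synthetic-data module generates every input with known ground truth, so
each layer is validated end to end without any external data.

# The design algebra

## Construction and labelling

The L8 array is built from three generator columns. Column labels 1..7 are
binary encodings of which generators multiply to form each column: the
entry for run $r$ in column $j$ is $(-1)^{\mathrm{popcount}((r-1)
\wedge j)}$. Two invariants follow by construction and are enforced by the
`DesignTable` validity method:

* **balance** — every column sums to zero (four control, four treated runs);
* **orthogonality** — every pair of columns has zero dot product.

The payoff of the labelling is exact alias arithmetic: the elementwise
product of columns $a$ and $b$ is the column labelled $a \oplus b$ (XOR).
An interaction between two factors is therefore confounded with whatever
effect sits on the XOR of their columns. `aliasStructure()` enumerates
this map for all main effects and two-way interactions.

With six factors on six of the seven columns, the fifteen two-way
interactions distribute so that exactly three land on the single free
column. Those three pairs always partition the six factors (the test suite
checks all 5040 injective assignments). Under the default assignment —
factors in the order Pb, VPA, BPA, EtOH, FH, Zn- on columns 1..6 — the
free-column pairs are Pb:Zn-, VPA:FH and BPA:EtOH, the combinations the
study analysed. The actual laboratory layout lives in supplementary
material we do not reproduce; because only the *set* of aliased pairs is
identifiable from the main text, the assignment is configurable via
`columnMap` and the default is chosen to reproduce those pairs.

```{r}
design <- assignFactors(buildL8())
subset(aliasStructure(design), status == "estimable (mutually aliased)")
```

Note that the three pairs share one contrast column: they are mutually
aliased, and the package reports them as such. A study can interpret the
free-column contrast through any of the three pairs, but the data cannot
distinguish them — this is stated rather than hidden.

## Level coding and doses

All factors use -1 = control, +1 = treated, including zinc deficiency,
where the *control* medium carries the 1.5 uM zinc sulphate supplement and
the treated level is its absence. A uniform sign convention keeps effect
directions comparable across factors. Doses default to 3 uM (Pb, VPA, BPA,
FH) and 3 mM (EtOH). Sample sheets are emitted in Yates (standard) run
order; randomized run order is available behind a recorded seed.

The study's sheet (`ffedStudySheet()`) has 44 rows: the full array across
four lines, one extra full replicate for CTRL_Male and a four-run partial
replicate for CTRL_Female. (The source study analysed 43 samples; the
odd one out is unexplained there, presumably a quality failure, so the
generator emits the full 44.)

# The count model and the four analysis levels

## Simulation

`simulateCounts()` draws
$$K_{ij} \sim \mathrm{NB}\!\left(\mu_{ij},\ \alpha_i\right),\qquad
\mu_{ij} = s_j\, 2^{\,b_i + l_{i,\mathrm{line}(j)} + \sum_f (x_{jf}/2)\beta_{if} + \sum_{fg}(x_{jf}x_{jg}/2)\gamma_{ifg}}$$
with variance $\mu + \alpha\mu^2$. Effect sizes $\beta$, $\gamma$ are
treated-vs-control log2 fold changes, split symmetrically so the baseline
is the grand mean. Defaults: 2,000 genes, baseline log2 mean 5 (sd 2),
dispersion trend $\alpha(\mu) = 4/\mu + 0.05$ with lognormal noise (sd
0.25), cell-line offsets with sd 1.0 log2 units, library sizes uniform on
0.5–2x. The line-offset sd is deliberately large: in the motivating data
the genetic background of the samples, not the exposures, dominated the
variance, and the generator reproduces that qualitative structure (a
property test verifies it).

What the generator does *not* emulate: GC or length biases, batch
chemistry, outlier samples, correlated gene modules, UMI structure. Tests
passing on these simulations therefore demonstrate correctness of the
estimators under the stated model, not robustness to every artefact of
real RNA-seq.

## Differential expression

The expression stage is a deliberately transparent NB-Wald pipeline:

1. **Size factors** — median-of-ratios against the geometric-mean
   reference; when no gene is positive everywhere, the estimator falls
   back to genes positive in at least half the samples (with a message).
2. **Dispersion** — per-gene method of moments on normalized counts with
   means from a Poisson GLM pre-fit (the model is multiplicative, so
   linear-scale mean fits would bias the residual moments),
   residual-df corrected, then blended 50/50 with a robust trend
   $\alpha(\mu) = a_0/\mu + a_1$ fitted to per-decile medians. Estimates
   are floored at $10^{-8}$. The decile-median trend exists because the
   raw moment estimator has a heavy right tail that ruins a naive
   regression.
3. **GLM** — log-link IRLS with known dispersion and log size-factor
   offset; convergence at max coefficient change $< 10^{-6}$ or 100
   iterations, non-convergence flagged. Coefficients are reported in
   log2. Rank-deficient model matrices raise an error naming the
   collinear columns — this is how aliased contrasts surface to the user
   rather than being silently dropped.
4. **Testing** — Wald $W = \widehat{\beta}/\mathrm{SE}$, two-sided normal
   p, BH adjustment over genes passing an independent-filtering floor
   (base mean >= 5, configurable). The floor stabilizes the small-sample
   dispersion estimates; genes below it are reported untestable (NA).

This is not a reimplementation of DESeq2: there is no Cox–Reid
adjustment, no outlier replacement and no fold-change shrinkage. The
scientific contract — NB GLM, Wald test, BH at adj. p < 0.05 — is
preserved and is what the tests check.

The four levels stratify the data before fitting:

| Level | Subset | Model |
|---|---|---|
| I | all samples | `~ exposure` |
| II | one clinical background | `~ exposure` |
| III | one cell line | `~ exposure` |
| IV | all samples | `~ cellLine + replicate + inter + cellLine:inter` |

The methods text of the source study states only `~ exposure` with
level-based filtering, so levels I/II do **not** include a cell-line
covariate by default; `blockCellLine = TRUE` adds one (and markedly
improves power when line effects dominate — both behaviours are exposed
because the original description underdetermines the model). Level IV
codes the aliased interaction contrast as a 0/1 indicator of the
free-column product, uses sum-to-zero cell-line contrasts so the tested
`inter` coefficient is the across-line average, and materializes the
replicate term literally: on a single-replicate sheet that term is a
constant column and the fit aborts with a rank-deficiency error — the
algebraic form of the study's observation that interactions were only
detectable where two full replicates existed.

# Enrichment and networks

`gseaES()` implements the weighted Kolmogorov–Smirnov running sum (hits
weighted by $|score|^p$ normalized to one, misses by $1/(N - N_h)$; ES =
extremum of largest magnitude). The significance machinery uses a
*gene-permutation* null — the standard null for preranked input — with
add-one-corrected tail p on the matching sign, NES = ES over the mean
same-sign null ES, and a GSEA-style FDR q from the ratio of null to
observed NES tail frequencies, clipped to [0, 1]. The weighting exponent
(default 1) and permutation count (default 1000) follow the desktop-tool
conventions since the study does not state them.

Similarity networks take the sets passing q < 0.05, join pairs whose
combined coefficient (0.5 Jaccard + 0.5 overlap) reaches 0.375 — the
EnrichmentMap defaults, adopted where the study is silent — and an empty
node set returns an explicit "no network" object (the study's ASD
downregulation contrast is exactly this case, and it should print as a
result, not an error). Global metrics (nodes, edges, diameter on the
largest component, density, clustering coefficient, average degree) are
computed with igraph and cross-checked in the tests against a brute-force
BFS/triangle oracle. "Clustering coefficient" is ambiguous between mean
local and global transitivity in the upstream tooling; mean local is the
default and both are exposed. Cluster labels are deterministic token
frequencies over member set names — reproducibility was preferred over
the cosmetic word-cloud labelling of the original toolchain.

Over-representation against curated lists uses the exact hypergeometric
upper tail with the expressed-gene background (base mean > 20), and
errors — rather than silently renormalizing — when hits fall outside the
background.

# Spatio-temporal permutation enrichment

Expression across four brain regions and eight developmental periods is
filtered (samples: RIN >= 9; genes: >= 1 FPKM in >= 2 samples, and not
both rarely detected (< 50% of samples) and flat (CV < 0.25) — the
filter sentence in the source is ambiguous between conjunction and
disjunction, so the conjunctive reading is the default and the other is a
flag). Gene groups come from average-linkage hierarchical clustering on
correlation distance of z-standardized region-by-period mean profiles,
cut at k = 2; standardization happens after averaging into cells (the
alternative order is not stated upstream; after-averaging matches the
"standardized mean expression pattern" wording).

For each of the 32 cells the observed statistic is the group's mean
expression; the null re-draws B size-matched random gene sets. The
upstream description literally scores the *proportion of permutations
where the group mean is higher than random* — a quantity near 1 for
enriched cells. The package reports the standard complement
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(B + 1)$ so that small p
means enrichment, with ties counted conservatively against the group, and
exposes the literal reading as `score = 1 - p`. BH runs across the 32
cells. One subtlety the tests document: within a single grid the 32
p-values share the group's baseline offset and are strongly correlated,
so null uniformity is a statement *across* independent groups, which is
how the suite checks it.

# Differential exon usage

`flattenAnnotation()` projects all transcript exons of a gene onto the
genome and splits them at every boundary (IRanges `disjoin`), dropping
genes whose exons overlap another gene on the same strand (aggregate
exclusion). Input follows GFF 1-based inclusive coordinates; bins are
0-based half-open with ids `gene:E001`-style. Flattening is idempotent.

The usage test pairs each bin with the rest of its gene and compares NB
models *sample + exon + cellLine:exon + exposure:exon* versus the reduced
model without the exposure term by likelihood ratio (chi-squared, 1 df),
with per-bin dispersions from the expression stage's estimator. This
bin-vs-rest reduction keeps the tested hypothesis of the full per-gene
machinery — exposure-dependent relative usage with cell-line blocking —
at a fraction of the cost; numeric parity with DEXSeq is a non-goal.
Usage log2FC is the log2 ratio of bin fractions (treated over control,
with a half-count guard), and a gene is called when at least one bin has
adj. p < 0.05, base mean >= 10 and |log2FC| >= 1.5, inclusive bounds on
the latter two per the rule's ">=" wording. Single-bin genes are skipped;
replicate structure is absorbed by the sample term.

The planted-switch scenarios in the tests move 25% of a gene's reads from
a dominant bin (share 0.50) into a minor bin (share 0.05) on treated
samples, on genes simulated at adequate depth (baseline log2 mean 8.5,
sd 1): the base-mean floor in the calling rule presumes moderately
expressed exons, and the scenario is defined to satisfy it.

# Metabolite quantification

One-point calibration is the stated identity
$C = C_{IS} \cdot I_{met}/I_{IS}$, applied per feature through a
class-level internal-standard map (one standard per lipid class, with
per-feature override). It is exactly invariant to instrument gain, and a
zero-intensity standard marks the feature unquantifiable rather than
producing an infinity. The signal filter removes features whose median
intensity falls below a threshold that is deliberately a required
configuration parameter — the source reduced >2,500 signals to 79
reported metabolites without stating the cutoff, so no default is
endorsed. Testing is literally `lm(concentration ~ exposure)` per feature
within each stratum (global, clinical background, cell line) with BH
across features; the OLS slope test on a two-level factor is numerically
the pooled-variance t-test, which the suite verifies to $10^{-10}$. The
metabolomics sheet reproduces the study layout: 3 technical replicates x
treated/untreated x 4 cell lines = 24 samples.

# Problem sizes and numerical choices

The validation suite runs at desk scale, chosen as the smallest sizes at
which the statistical claims are meaningful: 2,000 genes x 44 samples for
expression calibration (type-I error, KS uniformity, spike recovery);
30-gene, 4-bin exon sets; 40 metabolite features; 500-gene
spatio-temporal matrices with B = 2,000 permutations (the study's
B = 10,000 remains the function default). IRLS clamps the linear
predictor to [-30, 30]; dispersion moments floor fitted means at 0.1
counts and cap raw estimates at 20; BH ties resolve by the standard
step-up on sorted p-values. All generators are pure functions of (config,
seed), and the pipeline stamps every output with the config hash and seed
so equal configurations give byte-identical reports.

# Known limitations

* The NB pipeline's Wald test is slightly anticonservative or
  conservative at the tails for very low counts; the independent-filter
  floor mitigates but does not remove this.
* Main-effect estimates for different factors are exactly uncorrelated
  only at equal sequencing depth; unequal library sizes reweight samples
  identically across genes and induce a small systematic correlation
  between contrasts (see the property test for the statement tested).
* The GSEA FDR q is the classic tail-ratio estimate; it is noisy for
  small collections and small permutation counts.
* Aliased interactions are reported, never disentangled: with six factors
  in an L8, the three free-column interactions are one contrast with
  three interpretations.
* The spatio-temporal module emulates the *structure* of a
  region-by-period atlas, not its content; nothing here reproduces
  numbers that depend on the real resource.
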