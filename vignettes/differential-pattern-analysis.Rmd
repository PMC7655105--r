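---
title: "Differential pattern analysis of time-course expression: models and design choices"
author: "diffpat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential pattern analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diffpat)
```

This vignette explains the statistical model behind `diffpat`, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where several defensible
choices existed. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## 1. The problem

In a circadian or diel RNA-seq time course (here: leaf tissue sampled
every 2 h for 48 h under constant conditions, after entrainment to light
or temperature cycles, two biological replicates), the biologically
interesting differences between two conditions are often changes in the
*shape* of the temporal profile — a phase shift of a few hours, a damped
amplitude, loss of rhythm — while the abundance at any single timepoint
changes only subtly. A per-timepoint two-group test throws away the
profile structure; spline or impulse models impose a parametric shape.
`diffpat` instead encodes every profile against the experiment's own
repertoire of patterns and tests the encoding.

## 2. Model

### 2.1 Normalization

Raw counts are normalized by trimmed-mean-of-M-values (TMM; 30% M-trim,
5% A-trim, reference column chosen by upper-quartile proximity, factors
rescaled to geometric mean 1 — delegated to edgeR's `calcNormFactors`)
and converted to log2 FPKM with an *unscaled* prior count:

$$ y_{gs} = \log_2 \frac{c_{gs} + p}{(N_s f_s / 10^6)(L_g/10^3)}, \qquad p = 0.1 . $$

Bit-exact parity with any particular library's prior-scaling scheme is a
non-goal; the unscaled prior keeps the transform elementary and
documented. Annotated gene length is used (effective length would require
fragment-length information that a count table does not carry). A dropped
outlier library can be imputed as the mean of the two flanking timepoints
of the other replicate (`impute_neighbor_mean`).

### 2.2 Modules, eigengenes, kME

The co-expression network uses the unsigned adjacency
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ (the conventional default; a
signed option exists) and the topological overlap

$$ \mathrm{TOM}_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}, $$

with the adjacency diagonal treated as zero. Genes are clustered by
average linkage on $1 - \mathrm{TOM}$ and a *static* cut produces the
modules; clusters below `min_module_size` (default 30) become unassigned
(label 0), and modules whose eigengenes correlate above `merge_corr`
(default 0.85) are merged. Modules are renumbered by the ZT phase of
their eigengene peak (mean over replicates; ties to the earlier ZT).

**Choosing the cut height.** A fixed cut constant does not transfer
across noise levels: on low-noise toy data the within-module merge
heights sit near 0.1, while at realistic count dispersion the whole
dendrogram lives above 0.6 and merge heights form a continuum. The
default therefore scans the quantiles of the merge heights and picks the
height that maximizes the number of clusters reaching
`min_module_size` (ties broken by more genes assigned, then the lower
height). This is deterministic, has no tuning constant, and reduces to
the obvious answer on cleanly separated data; an explicit numeric
`cut_height` overrides it.

An eigengene is the first right singular vector of the row-standardized
member submatrix, standardized to zero mean and unit variance and
sign-oriented so the mean correlation with member genes is non-negative.
In an unsigned network two antiphase gene groups can share a module; the
eigengene then picks one direction and the opposite group carries kME
near −1, which the encoding below represents without loss.

The kME encoding is computed per `(treatment, replicate)` course:
`kME[g, m, T, r] = cor(x_g, E_m)` over the course's timepoints. Keeping
replicates separate (rather than averaging them first) supplies the
within-treatment replication the moderated fit needs; the eigengenes come
from a single network built on all samples of the analysis set.

### 2.3 Moderated contrasts and scores

The kME array is flattened into a genes × (module, treatment, replicate)
response. A cell-means linear model with one coefficient per
(module, treatment) group — plus optional additive covariate factors,
e.g. entrainment when two datasets are combined — is fitted per gene, and
empirical-Bayes variance shrinkage gives moderated t-statistics for the
per-module treatment contrasts:
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, with $(d_0, s_0^2)$
estimated by moment-matching the marginal distribution of $\log s_g^2$ to
a scaled log-F (digamma/trigamma inversion). The fitting is delegated to
limma; the test suite checks the whole path against an independently
coded closed-form implementation at 1e-8.

The pattern-change score is $S_g = \sum_m |t_{g,m}|$ (an alternative
max-|t| mode is available through the returned fit); the signed sum
$\sum_m t_{g,m}$ is kept for direction. The score deliberately pools
evidence across modules: a phase shift moves membership out of some
modules and into others, producing several moderate |t| values rather
than one large one.

### 2.4 Permutation null and empirical p

The null re-assigns gene labels to expression patterns independently
within each input dataset block — each treatment, and each covariate
level within treatment when a covariate is modeled — then re-runs the
full scoring pipeline; `n_perm_sets` full-size sets are pooled and

$$ p_g = \frac{1 + \#\{\text{null} \ge S_g\}}{1 + N_\text{null}} . $$

Two properties of this null are worth stating plainly:

* **Its H0 is "gene identity carries no cross-block pattern
  information".** On data where unperturbed genes keep identical phases
  in both treatments, the test is *conservative*: the null population
  consists of completely re-paired patterns, which differ far more than
  replicate noise. Calibration (significant fraction ≈ α on null data)
  holds exactly when the data are generated under the permutation H0 —
  the generator's `paired = FALSE` mode exists for exactly this check.
* **For pair tests the block is (member × entrainment).** This mirrors
  re-assigning accessions separately per input dataset: a null pair
  member combines the LD pattern of one gene with the HC pattern of
  another, which correctly prices in how coherent a real member is across
  entrainments. Shuffling whole members instead (re-pairing real genes)
  makes the null tail as heavy as the alternative whenever the phase
  population is broad, and the test loses essentially all power.

The median (abundance) test applies the same machinery to per-course
median log2 values, after centering each gene's median vector; without
centering, the cross-gene permutation null is dominated by between-gene
baseline differences (orders of magnitude larger than any treatment
offset) and the test degenerates. Even centered, re-pairings of two
shifted genes enter the null at rate (fraction shifted)², which bounds
the attainable power at `p < α` — with 10% of genes shifted the ceiling
is about 1 − 1/21 ≈ 0.95, and replicate noise takes a few more points.

The combined score is the raw sum of the pattern and median scores. A
null-SD-standardized variant exists, but note the pattern null is
intrinsically much wider than the observed score spread (it represents
"completely different pattern"), so null-SD standardization down-weights
the pattern component heavily; the raw sum is the default.

### 2.5 Pattern clustering

Significant genes (or pair members, with the two member profiles
concatenated) are represented by z-scored mean time profiles, clustered
by average linkage on 1 − Pearson correlation with a cut at 0.5, clusters
under 20 members absorbed into label 0, and the clusters labeled
`pDif_01 …` in order of the phase of their mean profile — grouping genes
by the time of day their divergence manifests.

## 3. Paralog pairs

Three-copy paralog groups are expanded into the three two-member
comparisons (ab, bc, ac) so one analysis covers two- and three-copy
genes; pairs are kept only when both members are expressed. The pair test
runs the pattern machinery with "treatment" replaced by pair member and
entrainment as covariate. Pairs are canonicalized internally (lexicographic
member order) so the result is exactly symmetric; `Br1` — the member named
first by convention — is assigned by the sign of the summed t-statistics
and only for significant pairs. `high_low_split` ranks members by mean
log2 expression (highest and lowest kept, the middle copy of a triplet
excluded; ties broken by gene id), with a seeded random pairing of
single-copy genes as the matched control.

`response_enrichment` asks whether a subset of pairs (e.g. the divergent
ones) is enriched for condition-responsive genes: the null resamples
same-size subsets of the full pair list without replacement (10,000 by
default) and three statistics are tracked — responsive genes covered,
pairs with exactly one responsive member, pairs with both. Upper-tail
p-values by default; the observed/expected direction of each statistic is
reported so depletion is visible too.

## 4. GRN comparison

`infer_grn` regresses each target's standardized profile on all TF
profiles with a random forest (1000 trees by default, mtry = √n_TF,
impurity importance = summed variance reduction), normalizing each
target's weights to sum 1. The edge threshold comes from a permuted
network: target profiles are shuffled across samples, the inference is
re-run, and FDR(w) = (permuted count ≥ w, floored at one) / (real count ≥
w), monotonized by a running minimum over ascending thresholds; the
threshold is the smallest weight at or below the requested FDR (default
5%), or +∞ when no weight qualifies. The floor keeps a lone real edge
beyond the permuted maximum from being read as FDR 0 — without it, pure
noise data yields a spurious finite threshold in about half of runs.

Cross-species target-set overlap is a hypergeometric upper tail after
mapping one species' targets through the ortholog map (collisions
collapse). The divergence test between two paralogous copies compares
$\Delta = |\log_{10} p_A - \log_{10} p_B|$ with a null built from random
target groups of the observed sizes (10,000 draws; sizes sorted
internally so the result is exactly symmetric under copy swap). Two
caveats are documented rather than hidden: the species-A target set is
held fixed during the permutation, and the null's H0 is "both regulons
are random sets" — when both copies share one regulon and the two sets
are merely noisy inferences of it, deeply overlapping p-values can differ
by more than random sets do, and the test over-calls divergence. The
acceptance checks therefore test nominal level under the test's own H0
and perfect-identity degeneracy, not the full-chain shared-regulon case.

CNS utilities implement the published filtering scheme (drop bitscore ≤
28.2, drop query coverage < 60%, then drop *all* hits of any CNS
exceeding the per-species multiplicity cap — 1 for a diploid reference, 3
for a triplicated one; the bitscore rule is read as "at or below the
minimal reportable tier", with an exact-equality mode available), signed
nearest-gene association on the same strand (negative before the gene,
positive after, 0 intragenic, all ties reported), and projection of gene
target sets into CNS space by union.

## 5. Rhythm detection

The built-in rhythm test is a fixed-period cosinor:
$y = m + a\cos(2\pi t/\tau) + b\sin(2\pi t/\tau)$, amplitude
$\sqrt{a^2+b^2}$, phase $\mathrm{atan2}(b,a)\,\tau/2\pi$ (mod $\tau$), an
F-test of the joint rhythm term and BH selection at q ≤ 0.01. It is a
substitute interface, not a reimplementation of nonparametric umbrella
tests; externally computed rhythm p-values can be supplied as a
two-column (gene, p) file through `read_external_rhythm_calls` so a
published detector's calls drive the cycling filter instead. Period
search is out of scope; τ = 24 h everywhere. Both the cosinor phase and
the module-based phase (module numbering) are available; module phase on
the combined dataset is the default frame for pair comparisons.

## 6. The synthetic-data generator

`simulate_timecourse` draws genes in `n_modules = 12` evenly spaced phase
modules (jitter SD 0.75 h), log-normal baselines (log-mean 4, log-SD
1.2), relative amplitudes uniform on [0.3, 1], and negative-binomial
counts with variance $\mu + \alpha\mu^2$, $\alpha = 0.05$, per-sample
depth factors log-normal(0, 0.1), over the circadian design (2
treatments × 24 two-hour timepoints × 2 replicates = 96 samples).
Perturbations affect the second treatment only: phase shifts of
{2, 4, 8} h, amplitude factors {0.75, 0.5, 0.25}, or loss of rhythm, at
weak/medium/strong intensity — a "various intensities over predefined
patterns" benchmark in the tradition of published time-course DE
comparisons, with 1200 of 10,000 genes perturbed at full scale. The
test suite runs the benchmark at 3000 genes / 360 perturbed and the
calibration at 2000 genes, sizes chosen so the full suite completes in
about a minute while estimates remain stable across seeds.

What the generator does *not* emulate: unequal module sizes and the
morning-heavy phase distribution of real transcriptomes, batch effects,
library-preparation artifacts, unexpressed genes, and median-level
perturbation classes (a pure phase or amplitude change leaves the median
over ~2 cycles nearly unchanged, so the median test carries almost no
signal on this benchmark — its value shows on real data where abundance
changes are common). Passing tests therefore demonstrate the machinery's
correctness and calibration under the stated model, not performance on
any particular real dataset.

`simulate_grn` gives TFs random smooth rhythms (three-harmonic random
Fourier series plus an equally weighted smooth idiosyncratic component —
the idiosyncratic part keeps ten TFs from being mutually collinear,
without which no inference method can attribute a target to the right
TF); targets are linear mixes of their regulators plus noise. Species B
duplicates each TF into a conserved copy (inheriting the orthologous
out-edges) and a divergent copy (a stated fraction rewired), with each
target mixed in a single pass from all of its drivers so conserved and
divergent edges carry comparable signal.

## 7. Numerical and degenerate-input conventions

Constant gene rows are dropped from network construction with a warning;
constant courses yield missing kME values and the affected genes are
dropped from the fit (warned, not silently). Phases numerically equal to
τ collapse to 0. Empirical p-values never fall below
$1/(N_\text{null}+1)$. Ties in high/low splits break by gene id;
nearest-gene ties are all reported; module phase ties break to the
earlier ZT. All stochastic entry points take explicit seeds, restore the
caller's RNG state, and write the seed into their outputs or the run
manifest; the pipeline (`run_full_analysis`) records every stage,
parameter and seed in `manifest.json` and preserves partial outputs with
a `FAILED` marker on error.

## 8. Known limitations

* The pattern test's power is defined relative to the "unrelated
  patterns" null; subtle within-gene changes that stay well inside the
  cross-gene pattern spread will not reach small empirical p even when
  they are real. This conservatism is inherent to the permutation design.
* The kME encoding is only as expressive as the module repertoire; a
  pattern class absent from the network (e.g. a transient spike in a
  dataset with no spiking module) is encoded poorly.
* Unsigned networks merge antiphase groups; the encoding compensates via
  negative kME, but module counts should not be over-interpreted.
* The divergence permutation test over-calls divergence for copies
  sharing one regulon (Section 4); significant calls should be read
  together with both overlap p-values.
* Fixed 24 h period throughout; no period estimation.
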