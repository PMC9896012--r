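---
title: "crossbind: methods and modelling notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crossbind: methods and modelling notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `crossbind`, the
choices made where the design was genuinely open, and what the synthetic
data can and cannot tell you about real experiments.

## The occupancy model

Three alpha-class bHLH-PAS factors (AHR, HIF-1α, HIF-2α) compete for a
single limiting dimerization partner (HIF-1β/ARNT). We do not simulate
molecules; we summarise the competition at the level of dimer fractions.
With condition-specific activities $a_X(c) \ge 0$ and a competition
constant $K > 0$,

$$f_X(c) = \frac{a_X(c)}{K + \sum_Y a_Y(c)},$$

which saturates like a Michaelis–Menten pool: each factor's dimer
fraction falls monotonically as any competitor's activity rises, and
$\sum_X f_X < 1$ always. Site occupancy multiplies the dimer fraction by
a per-site strength $S_s$ (log-normal around a mean of 10, CV ≈ 25%, a
typical spread of ChIP enrichment across true sites) and, at sites
carrying motifs for two factors, by a cis-cooperation term
$1 + \gamma f_P$, where $f_P$ is the co-binding partner's dimer fraction.
$\gamma = 0$ gives pure competition; $\gamma > 0$ lets bound partners
stabilise each other, which is the mechanism the shared-vs-individual
stratified analysis is designed to detect. The partner pool size itself
is absorbed into $S_s$ and the count scale, so it is not a separate
parameter.

Assumptions worth stating: activities act only through the common pool
(no factor-specific cofactors), cooperation is symmetric within a shared
site, and occupancy maps linearly into expected ChIP counts. These are
the minimal assumptions that reproduce the qualitative phenomena of
interest with recoverable parameters.

### Condition design and default activities

The default design is the six-condition factorial
{normoxia, hypoxia} × {vehicle, ITE, FICZ}. No quantitative dimerization
affinities are available to set the activity scales, so the relative
activities are free parameters of the simulation, chosen once:
AHR activity 1.0 under ITE and 0.7 under FICZ (the weaker of the two
ligand responses), 0.02 at vehicle; HIF-1α 1.0 and HIF-2α 0.8 under
hypoxia, 0.02 in normoxia (a small basal leak rather than exact zero,
reflecting residual pathway activity). $K = 1$ places the conditions in
the responsive part of the saturation curve.

## The synthetic dataset

`simulate_sites()` places sites of six classes (three single-factor,
three pairwise-shared) at least 2 kb apart on a single 2 Mb chromosome —
collision-free by construction, so peak-calling errors are attributable
to the callers, not the geometry. Defaults: 140 sites
(40/40/20 single, 20/10/10 shared). Shared sites plant the two factor
motifs 40 bp apart, on the order of the summit separations reported for
co-bound enhancers, which makes the summit-distance statistic
meaningfully testable. The genome is i.i.d. uniform ACGT with GCGTG
planted at AHR motifs and ACGTG at HIF motifs; background sequence
occasionally contains NCGTG by chance, which is exactly what the
enrichment test is supposed to overcome.

`simulate_chip()` draws per-site counts from a negative binomial with
mean $\lambda_s = \text{background} + \text{scale}\cdot occ_s$ and
variance $\lambda + \alpha\lambda^2$, and shapes coverage as triangular
kernels of the fragment width (200 bp) centred on the planted motifs,
with the same NB noise per bin (10 bp bins). Dataset defaults are
`scale = 40`, `background = 5` and `alpha = 0.02`: at the mean site
strength this gives roughly 50-fold enrichment of the peak apex over the
local background, i.e. a clean transcription-factor ChIP with tightly
correlated technical duplicates. The dispersion enters both the
generator and the Wald tests, but the tests re-estimate it from data.

`simulate_rna()` drives gene means as
$\mu_g(c) = \text{base}_g \cdot 2^{\beta_g\, occ(c)/occ_{\max}}$ with NB
noise, six replicates per condition, $\beta_g = 3$ for site-linked genes
(a two- to three-fold swing across the observed occupancy range, typical
of direct targets) and $\beta_g = 0$ for 300 background genes.
Gene-to-site linkage is one responsive gene per site with its TSS 500 bp
away, plus unlinked background TSSs, so nearest-TSS assignment is exact
by construction — the annotation code is tested separately against
brute-force search.

`simulate_cohort()` emulates a paired tumour/normal expression cohort of
72 pairs. Tumours shift HIF-signature genes by $+\delta_{HIF}$ (default
+0.5 log2) and AHR-signature genes by $\delta_{AHR}$ (default −0.5),
scaled by an ordered copy-number dose (0.6/1.0/1.4 for 0/−1/−2 copies
lost) and by a shared per-patient activation factor (SD 0.4). That
shared factor is what couples the two signatures within a patient and
produces the negative score correlation; without it the two scores would
be independent even with opposite mean shifts.

### What the generator does *not* emulate

Mappability and GC bias, copy-number effects on ChIP signal, fragment
length variation, read-level artefacts, correlated sites (enhancer
clusters), tumour purity and cohort batch effects. Passing tests on this
generator therefore demonstrates that the statistical machinery is
correct and calibrated under its stated model — not that the pipeline is
robust to every artefact of real sequencing data.

## Peak calling

Consensus calling needs two callers with independent decision rules;
rather than depending on external tools (MACS, T-PIC), the package ships
two deliberately different in-house callers, so the consensus step — the
part of the procedure that carries the scientific weight — is fully
self-contained and testable:

* **Enrichment caller**: bins are flagged when the library-size-scaled
  sample/control fold change is ≥ 4 *and* the Poisson upper-tail
  p-value (control rate as expectation) is < 1e-4; flagged runs merge
  within 100 bp and must span ≥ 50 bp.
* **Shape caller**: a running-mean smooth (50 bp) followed by local
  maxima whose prominence over flanking minima exceeds 5 depth units;
  peak extent runs to the half-prominence level.

Consensus keeps caller-A peaks overlapping a caller-B peak by ≥ 1 bp and
retains caller-A coordinates (the choice is not documented in standard
practice; one caller's coordinates must be picked and we pick the
enrichment caller's). Summits are located on coverage smoothed with a
half-fragment-width window — the raw argmax of NB-noisy bins wanders by
several bins, while smoothing recovers the kernel apex; plateau ties
resolve to the floor of the midpoint of the leftmost maximal run, which
is deterministic and symmetric for symmetric peaks.

The background filter is the type-7 (linear interpolation) empirical
quantile, default level 0.9999, of counts over random background
regions, applied per condition; peaks must *strictly* exceed it. In
synthetic mode the background regions are non-overlapping windows of the
median peak width sampled away from planted sites — the same statistic
as a DNase-cluster background, at desk scale. A 2 Mb genome supports
only a few thousand such windows, far fewer than $1/(1-q)$, so the
filter effectively thresholds at the background maximum and the code
warns accordingly; the warning is informative, not an error, because the
threshold remains a valid (if coarse) quantile estimate.

## Quantification and normalisation

Counting is a coverage-level surrogate for fragment counting: area under
the track within a region divided by the fragment width (the read-shift
used upstream is carried as metadata). RPKM is the usual
count/(kb·M-reads). MA normalisation is reduced to a closed-form
per-sample linear transform: over features occupied in both samples, OLS
of the reference on the sample on the log2 scale (pseudocount 0.5), then
$x' = u + v\,x$. This makes the normalisation exactly testable — the
post-condition mean(M) ≈ 0 and slope(M on A) ≈ 0 holds to 1e-8 on
noiseless fixtures — at the cost of the mean–variance modelling a full
MAnorm2 fit would add. Below 10 common features the code falls back to a
median-of-ratios shift with a warning; a zero-variance sample is an
error, not a silent identity.

## Differential binding and expression

Dispersion is method-of-moments per feature,
$\hat\alpha = \max(0, (s^2-m)/m^2)$ on size-factor-scaled counts, shrunk
50/50 toward the 10%-trimmed mean across features — a deliberately
simple stand-in for empirical-Bayes moderation that is exact in the
Poisson limit. The Wald test uses
$\varphi = \log_2\frac{m_2+\varepsilon}{m_1+\varepsilon}$ with the delta
method on NB variances and a standard normal reference; $\varepsilon =
0.5$ keeps fold changes finite at zero counts. Benjamini–Hochberg is
`p.adjust`. The shared-vs-individual strata are compared by a two-sided
Mann–Whitney test: the per-site q-values describe site-level tests, not
the strata contrast, so a rank test on the fold-change distributions is
the appropriate instrument (a difference-in-means Wald would also work;
the rank test is robust to the fold-change outliers that low-count
sites produce).

Gene-level DE reuses the same machinery after median-of-ratios size
factors. Two readings of the "fold change combined with significance"
ranking statistic circulate in practice: the difference
$\varphi - \log_{10} p$ ranks strongly *down*-regulated significant
genes *positively*, which contradicts using the ranking to detect
depletion. The default is therefore the sign-aware product
$\pi = \varphi \cdot (-\log_{10} p)$, with the difference form available
via `rank_genes(mode = "literal")`. P-values are
floored at 1e-300 before logs; ties break by gene ID.

Pre-ranked GSEA uses the weighted running sum (weight 1), gene-set
permutation (the only valid null for a pre-ranked list), and a
same-signed permutation p-value with the +1 correction, so p ≥
1/(nperm+1) and exact zeros are impossible. The enrichment score is
checked against an independent step-by-step running-sum oracle to 1e-12
and against `fgsea::calcGseaStat`.

## Cohort scoring

Composite scores are per-gene z-standardisation of log2 expression
across all cohort samples followed by an unweighted mean over signature
genes — the simplest scheme consistent with "normalise, then combine";
median aggregation is available. Standardisation uses all samples
(tumour and normal) rather than normals only; with paired designs this
only shifts scores by a constant per gene and does not affect paired
tests. Signatures enforce disjointness: genes in both single-factor
candidate lists are excluded from both, and common targets are scored
separately. Paired tumour/normal comparisons use the Wilcoxon
signed-rank test (zero differences dropped; exact null when ≤ 25
informative untied pairs, else normal approximation with continuity
correction; all-zero input returns p = 1 with a message). Copy-number
strata are *unpaired ordered groups*, so a paired test is not defined
there; the package substitutes a Jonckheere–Terpstra trend test with a
seeded permutation null (2,000 permutations, two-sided), with pairwise
Mann–Whitney tests as secondary output. Score correlation defaults to
Spearman for rank-robustness; Pearson is a config switch.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; `run_pipeline()` expands one global
seed into fixed per-stage child seeds so a stage's output is reproducible
independently of other stages, and the run manifest records the resolved
configuration plus per-stage MD5 checksums of the stage outputs —
identical seeds give identical checksums. The default run uses the 2 Mb
genome, 140 sites, two ChIP replicates, six RNA replicates, 2,000
background regions, 2,000 GSEA permutations and a 72-pair cohort, which
completes in about a minute on one CPU; the test suite uses smaller
geometries (0.2–0.3 Mb, 30–60 sites) chosen so each property remains
cleanly detectable.

## Known limitations

* The two callers are surrogates; absolute peak counts on real data will
  differ from MACS/T-PIC, though the consensus/filter/reproducibility
  logic is caller-agnostic.
* The MA transform is affine per sample; strongly non-linear inter-sample
  distortions would need the full mean–variance treatment.
* Dispersion shrinkage is a fixed 50/50 blend, not empirical Bayes; with
  two ChIP replicates per condition the Wald test leans on the
  cross-feature centre.
* The occupancy model has no chromatin state, no indirect (tethered)
  binding, and treats cooperation as a single multiplicative term.
* The cohort generator plants log-additive shifts with Gaussian noise;
  real tumour expression has heavier tails and confounders (purity,
  batch) that the paired design only partly absorbs.
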