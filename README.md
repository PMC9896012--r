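# crossbind

Analysis of competitive and cooperative chromatin-binding interactions
between bHLH-PAS transcription factors that share a limiting dimerization
partner — the HIF-1α / HIF-2α / AHR / ARNT system of hypoxic and
xenobiotic signalling, whose crosstalk matters in clear cell renal cell
carcinoma (ccRCC), where VHL loss constitutively activates HIF.

## Who this is for

Regulatory genomicists who have per-factor ChIP-seq coverage (or region
counts) across stimulus conditions and want to quantify:

* **trans-competition** — does activating factor B repress factor A's
  chromatin binding genome-wide, as expected when both compete for a
  limiting pool of ARNT?
* **cis-cooperation** — at sites bound by both factors, is that repression
  weaker than at sites bound by one factor alone?
* **motif partitioning** — do co-bound regions carry distinct ACGTG
  (hypoxia response element) and GCGTG (xenobiotic response element)
  variants of the shared NCGTG core at separate summits?
* **downstream consequences** — target-gene enrichment under each
  stimulus, and pathway-activation scores in a paired tumour/normal
  cohort.

## The model at the core

Factor activities `a_X(c)` in condition `c` compete for the shared
partner with Michaelis-like saturation. The dimer fraction of factor
`X ∈ {AHR, HIF1, HIF2}` is

    f_X(c) = a_X(c) / (K + Σ_Y a_Y(c))

and occupancy at site `s` is

    occ_{X,s}(c) = S_s · f_X(c) · m_{X,s} · (1 + γ · f_P(s,c))

with site strength `S_s`, motif indicator `m_{X,s}`, cis-cooperation
coefficient `γ ≥ 0` and `f_P` the co-binding partner's dimer fraction at
shared sites. Raising any competing activity strictly lowers every other
factor's occupancy; `γ > 0` partially shields shared sites. ChIP counts
are negative-binomial around `background + scale · occ`; the same model
drives simulated RNA-seq and a paired cohort, so every pipeline stage is
testable without any external data.

The analysis stages mirror standard ChIP-seq practice: two independent
peak callers with different decision rules whose consensus is filtered
against an empirical background quantile (default 99.99%), replicate
reproducibility and canonical-site definition (factor peak + ARNT peak in
both replicates), Venn classification, nearest-TSS annotation, MA
normalisation, negative-binomial Wald tests with Benjamini–Hochberg
correction, NCGTG variant enrichment, pre-ranked weighted GSEA with the
ranking statistic `π = φ · (−log10 p)`, and composite
(mean z of log2 expression) pathway scores with paired Wilcoxon and
ordered copy-number trend tests.

## Worked example

```r
library(crossbind)

m <- occupancy_model(gamma = 0.5)   # six-condition study design
round(dimer_fractions(m, "normoxia_ITE"), 3)
#>  AHR HIF1 HIF2
#> 0.49 0.01 0.01
round(dimer_fractions(m, "hypoxia_ITE"), 3)
#>   AHR  HIF1  HIF2
#> 0.263 0.263 0.211

run <- run_pipeline(default_config(seed = 1))
print(run)
#> crossbind pipeline run (seed 1)
#>   canonical sites: AHR = 70  HIF1 = 70  HIF2 = 39
#>   Venn union: 139 distinct sites; 40 multi-factor
#>   AHR hypoxic repression: median phi(shared) = -0.657 vs phi(individual) = -0.852
#>   median AHR-HIF1 summit distance: 40 bp
run$motifs
#>   class top_variant fold      p_value
#> 1   AHR           G  200 6.485581e-45
#> 2  HIF1           A  200 6.485581e-45
#> 3  HIF2           A  200 1.764262e-27
run$cohort$correlation$rho
#> [1] -0.6697858
```

Reading the output: hypoxia halves AHR's dimer fraction (0.49 → 0.26) —
trans-competition; the hypoxic drop in AHR binding is milder at shared
sites (−0.66) than at AHR-only sites (−0.85) — cis-cooperation; 139 of
the 140 planted sites are recovered as canonical sites with the planted
40 bp AHR–HIF summit offset; AHR sites prefer the GCGTG variant and HIF
sites the ACGTG variant; and the simulated paired cohort shows the
negative correlation between HIF and AHR pathway scores expected under
competition.

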