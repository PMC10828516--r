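---
title: "Methods: methylome remodeling, epigenetic QTL mapping and heterosis in epihybrid panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome remodeling, epigenetic QTL mapping and heterosis in epihybrid panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epihybridr)
```

## The experimental system this package models

An *epihybrid* panel is built by crossing a single recurrent, fully
methylated maternal parent (a male-sterile Columbia wild type, "msCol") to a
panel of epigenetic recombinant inbred lines (epiRILs). The epiRILs descend
from a cross between a wild-type plant and a *ddm1* mutant: they are nearly
isogenic in DNA sequence but segregate thousands of heritable hypomethylated
regions. At any segregating locus an epiRIL is epihomozygous either for the
wild-type methylated state (MM) or for the *ddm1*-derived unmethylated state
(UU). Because every family shares the same maternal genome, any molecular or
phenotypic variation among F1 families must trace back to the paternal
methylome. The package provides, as composable functions over data frames:

1. a **synthetic-data generator** reproducing the pedigree, marker map,
   methylome, phenotype and count structure of such a panel;
2. a **trio classifier** assigning each 200-bp region of each
   (mother, father, F1) trio to one of five remodeling scenarios;
3. **co-remodeling** statistics (pairwise divergence correlations,
   arm/pericentromere compartments, SMR-to-DMR proximity);
4. **epigenetic QTL interval mapping** of methylation traits by
   Haley–Knott regression with permutation thresholds;
5. **heterosis analysis**: mid-parent heterosis, transgression
   classification, variance components, a phenotypic QTL scan and a
   conditional epigenome-wide association study (EWAS);
6. **omics utilities**: TMM count normalization, divergence, gene linking
   and the candidate-gene filtering chain;
7. **causal model selection** among four fixed DAGs relating epigenotype,
   methylation and expression; and
8. the **quantitative-genetic decomposition** of the QTL contrast into
   dominance and background-epistasis terms.

## The pedigree and why UU frequency is 25%

`simulate_epiril_pedigree()` propagates each line through the derivation
design: F1 (MU everywhere) backcrossed to the wild type, then six rounds of
single-seed descent, with Haldane (no-interference) recombination applied at
every meiosis on the map's centimorgan distances. A backcross progeny is MU
at a locus with probability 1/2; six selfings leave a fraction
$(1/2)^6$ of those still heterozygous, i.e. $\tfrac12 (1/2)^6 = 1/128
\approx 0.78\%$ of lines. These residual heterozygotes are resolved to a
random homozygote by drawing one further gamete from the line's own
haplotypes (this preserves linkage between loci; the real population was
simply propagated further, and the published map is fully homozygous).
Summing the paths gives exactly $P(\mathrm{UU}) = 1/4$, which is the
segregation ratio reported for the real panel and what the acceptance
analysis measures at 50,000 simulated lines.

One consequence of simulating every meiosis is *map expansion*: the
population-scale recombination fraction between two markers exceeds the
single-meiosis Haldane value, approaching the selfing-RIL limit
$2r/(1+2r)$. The property tests therefore bracket the observed fraction
between those two quantities rather than equating it to $r$.

## Region states and the five remodeling scenarios

Parents are binary per 200-bp region (0 unmethylated, 1 methylated);
hybrids may also be intermediate (0.5). Upstream of this package a
hidden-Markov state caller produces these calls; `call_region_states()`
provides a deliberately simple two-threshold discretization
(defaults $t_{low} = 0.2$, $t_{high} = 0.8$) so the pipeline is exercisable
end-to-end: the analysis itself only consumes the state matrix. Parental
levels falling in the middle band are resolved to the nearer bound and
flagged; the exact midpoint resolves upward (a documented tie-break, made
robust to floating-point representation by comparing against
$(t_{low}+t_{high})/2$).

For each region and family the classifier computes the parental divergence
$PD = s_{mother} - s_{father}$, the mid-parent value
$MPV = (s_{mother}+s_{father})/2$ and the hybrid divergence
$HD = s_{F1} - MPV$. The scenario label is forced by sign arithmetic:
additivity iff $HD = 0$; trans-chromosomal methylation (TCM) iff $HD > 0$;
trans-chromosomal demethylation (TCdM) iff $HD < 0$; suffixed `_DMR` iff
$PD \ne 0$ (the parents differ) and `_SMR` otherwise. Enumerating the 12
valid state combinations yields exactly these five labels, the map is total
and single-valued, and the labels swap TCM ↔ TCdM under the state
reflection $s \mapsto 1-s$; all three facts are asserted in the tests.

**Percent mid-parent divergence.** The published ratio formula
$(H - MPV)/MPV \times 100$ is stated for expression; for methylation states
a TCM event in an SMR-unmethylated region has $MPV = 0$ and the ratio is
undefined. The default mode is therefore ratio-with-fallback: records with
$MPV = 0$ use the difference $(H - MPV)\times 100$ and carry a flag. A pure
difference mode is available. Both state calls and continuous levels are
supported as inputs, since published tables mention levels but the
classification itself is state-based.

## DMR enrichment, sharing labels, window tracks

`enrichment_bootstrap()` asks whether non-additive (NAD) records are
enriched for parental DMRs: it compares the observed DMR frequency inside
the NAD set against `n_boot` random draws of the same size from all
records, with $p = (1 + \#\{null \ge obs\})/(n_{boot}+1)$ — the standard
add-one empirical p-value, which can never be exactly zero. A region is
`shared` when remodeled in ≥ 2 families (configurable) and `private` when
remodeled in exactly one; density tracks count region midpoints in
half-open sliding windows (default 10 kb / 10 kb).

## Co-remodeling

`pairwise_nad_correlations()` correlates the per-family % divergence of
every pair of regions remodeled in at least 10 families (Pearson, two-sided
t p-values, raw $p < 0.05$ as published; a Benjamini–Yekutieli switch
exists but is off by default at this stage). The stricter published filter
— both regions remodeled in at least half the families — is recorded as a
flag rather than applied, because the two filters interact with the QTL
stage and the published description leaves the combination partly implicit; both thresholds
are configuration keys. Compartment categories (`arm-arm`, `arm-peri`,
`peri-peri`) derive solely from a pericentromere BED; a region is
pericentromeric when its midpoint lies in a half-open pericentromere
interval. Distances from SMR remodeling events to the nearest DMR event of
the matching direction are edge-to-edge in bp (0 when overlapping) — no
precise definition of the distance is published, and edge-to-edge is robust to
the 50-bp step overlap structure of the region grid.

## Epigenetic QTL mapping

Traits are the % mid-parent divergence of regions remodeled in at least
half of the families (the published filter; the value is 0 in families
where the region is additive). Each trait is normalized by the ordered
quantile transform `orq_normalize()` — average ranks mapped to
$\Phi^{-1}(r/(n+1))$ — which is invariant to strictly monotone input
transforms and errors on constant input.

`genotype_probabilities()` computes, for a fully homozygous two-class
population, $P(\mathrm{UU})$ at every 2-cM pseudomarker from the flanking
marker epigenotypes via Haldane recombination fractions,
$P = P(g_L \to g)\,P(g \to g_R)/P(g_L \to g_R)$; at markers the probability
is the observed genotype. Physical positions are interpolated piecewise
linearly in cM, which is needed because LOD-drop confidence intervals must
be compared with bp-coordinate targets. `hk_scan()` then regresses the
trait on the expected genotype: $LOD = (n/2)\log_{10}(RSS_0/RSS_1)$. A
perfect fit is capped at a finite sentinel (default 50) instead of
infinity; monomorphic pseudomarkers score 0. At marker positions the scan
equals exhaustive single-marker regression to $10^{-9}$, which the tests
assert against a brute-force `lm()` oracle.

Genome-wide significance is empirical: `permutation_threshold()` permutes
the trait across lines (default 1,000 permutations) and takes the 95th
percentile of the null genome-wide maximum LOD, targeting a 5% genome-wide
false-positive rate. Peaks are the highest pseudomarker per chromosome
above the threshold (leftmost wins ties — relevant when several capped
positions tie), with the confidence interval the widest contiguous run
around the peak within a 2-LOD drop. A target is `cis` exactly when its
body is contained in the interval on the same chromosome; straddling the
boundary is `trans`. Effects are summarized by $R^2$ and slope sign of the
regression on the peak-nearest marker, coded MM = 0, UU = 1 (the published analysis does
not state a coding; with this one, a positive sign means hypomethylated
paternal parents show the larger divergence). Across traits, each trait's
best-peak p-value (chi-square approximation $p = P(\chi^2_1 \ge 2\ln 10
\cdot LOD)$; the published analysis is silent on the LOD-to-p conversion) is adjusted by
Benjamini–Yekutieli, and the permutation and FDR filters are applied
conjunctively.

## Heterosis

Raw plant measurements are cleaned of > 3 SD outliers and adjusted for
experiment, block and germination date by fixed-effects least squares
(the published model lists only fixed factors, so no random terms are
fitted); residuals plus the grand mean feed all downstream steps.
`compute_mph()` requires at least five plants per group per family and
excludes families with near-zero mid-parent values before computing
$MPH = (\bar y_{F1} - MPV)/MPV \times 100$, which is scale-invariant.

Transgression is classified per family by Gaussian AIC comparison between
a model constraining the F1 mean to the mid-parent value and a model
freeing it; the free model wins only if it also places the F1 mean outside
the parental range (above → `high_parent`, below → `low_parent`). A free
F1 mean *within* the parental range keeps the additive call, a deliberate
choice since the cited likelihood approach does not resolve that case.

`variance_components()` decomposes plant-level MPH replicates by the
one-way method of moments with the unbalanced-design coefficient $n_0$,
truncating negative estimates at zero with a flag; the tests cross-check it
against an REML fit. MPH replicates are plant-level by default (each F1
sibling's % divergence from the family MPV) — how replicates entered the
published decomposition is not stated, so the replicate table is an
explicit input.

The phenotypic QTL scan reuses the mapping engine on family-level MPH and
additionally requires a one-way ANOVA of MPH on the peak marker at
$p < 0.05$; the double filter is partially redundant but retained as
described. The conditional EWAS compares, for each "de novo" region (one
without its own QTL), the core model $MPH \sim$ core-marker epigenotypes
against core + that region's % methylation divergence by a 1-df likelihood
ratio test, adjusts across regions by Benjamini–Yekutieli, clusters the
significant regions by Ward hierarchical clustering on principal-component
scores — the cluster count maximizes the average silhouette over
$k = 2..10$, since the published analysis reports four clusters but no
rule — and keeps one proxy per cluster (largest added $R^2$) for the final
variance split into core and de novo components.

## Omics

Count filtering and normalization follow the standard TMM recipe (CPM ≥ 1
in ≥ 2 samples; 30% M-trim, 5% A-trim) via edgeR, and divergence is the
same mid-parent ratio as for expression, with MPV = 0 records flagged
missing. Region–gene linking is edge-to-edge distance ≤ 1 kb,
strand-ignored, from the region interval to the gene body (the published
"within 1 kb" specifies neither anchor nor strand); GFF3 input (1-based
closed) is converted to the package's 0-based half-open convention at parse
time. `candidate_gene_chain()` composes the published filtering chain —
QTL targets → ≤ 1 kb gene links → re-test in a trio subset by either a
methylation–expression divergence correlation or a direct
expression–epigenotype association → unique gene list — as a pure function
of its inputs.

## Causal model selection

Four Gaussian DAG factorizations relate the QTL epigenotype $Q$,
methylation divergence $M$ and expression divergence $E$: (i) saturated
$f(M|Q)f(E|Q,M)$, (ii) independent $f(M|Q)f(E|Q)$, (iii) $Q \to E \to M$,
(iv) $Q \to M \to E$. Each conditional is an OLS regression;
$AIC = -2\log L + 2k$ counts coefficients plus the two residual variances,
ties break toward fewer parameters and then fixed model order. The final
call resamples trios with replacement (default 1,000 bootstraps), selects
the min-AIC structure per resample and reports the modal model with its
support ("modal vote"; whether the original selection used modal vote or
mean AIC is not stated, so the alternative is one line of code away).

Two structural facts matter for interpreting recovery rates. First, when
$Q$ has no effect and $(M, E)$ are bivariate normal, structures iii and iv
factorize the same joint density and are likelihood-equivalent — an oracle
check in the tests. Second, the saturated structure i *nests* each directed
structure with one extra parameter, so under a directed truth AIC selects i
with asymptotic probability $P(\chi^2_1 > 2) \approx 15.7\%$ no matter how
strong the effects; bootstrap voting does not remove this, because
resamples share the original data. Recovery is therefore assessed — and
achieved at ≥ 90% under strong effects at $n = 200$ — *among the directed
structures* ii–iv, which is the identifiable and scientifically relevant
contrast; the saturated model's capture rate is itself tested against its
chi-square prediction. At the 36-trio scale of the real expression subset,
accuracy degrades and the tests assert only above-chance performance rather
than hiding it.

## Quantitative-genetic decomposition of the QTL contrast

For the asymmetric design (every epiRIL crossed to the same recurrent MM
parent, phenotype defined as divergence from the mid-parent value), the
expected MM-minus-UU contrast at a focal locus, after integrating the
unknown background MM frequency $p$ uniformly over $[0,1]$ and collapsing
$N\beta \to \beta$, is

$$\mathrm{QTL}^{\bullet}_{F1,l} = 2\beta_{l:D} - \tfrac12\beta_{l:A\times A}
+ 2\beta_{l:A\times D} - 2\beta_{l:D\times A}.$$

The dominance-by-dominance term integrates out. The displayed
pre-integration expression in the source material is typographically
garbled (its parenthesization does not integrate to the printed result
term-by-term), so the integrated form is treated as normative and
`integrate_unit()` provides exact quadrature for explicitly parenthesized
integrands (e.g. $\int_0^1 (p-1)\,dp = -\tfrac12$ to $10^{-10}$).
`contrast_forward_sim()` is an independent oracle that simulates the cross
under an explicit indicator coding (additive code $+1/0/-1$ for MM/MU/UU,
dominance code = heterozygote indicator). Under that coding the
dominance-only contrast is $-\beta_{l:D}$ and independent of $p$; the
factor-2 coefficients of the integrated form correspond to a different,
unstated effect scaling, so the simulator verifies structural properties —
superposition, $p$-independence without epistasis, $p$-dependence with it,
zero under zero effects — rather than coefficient scale. The practical
message survives either coding: dominance and background epistasis enter
the observable contrast as a confounded mixture.

## Generator defaults — the study conditions

The default configuration mirrors the study design: 169 lines (the
sequenced panel; 190 for phenotyping), 144 markers on 5 chromosomes with
Arabidopsis-scale cM/bp lengths, ~25% UU per marker by pedigree
construction, 200-bp regions on a 50-bp grid with the ≥ 10-cytosine filter
recorded as an upstream precondition, 6 siblings per family, between-family
and residual MPH variances of 30 and 70 (so the between-family fraction is
the published 30%), and negative-binomial counts whose means scale with
methylation state (default 4× for methylated vs unmethylated 24-nt sRNA,
dispersion 0.1). Pericentromeres default to the middle 40% of each
synthetic chromosome, as no coordinates are published. Every published
threshold (200 bp, 50 bp, 10 cytosines, ≥ 2 shared, ≥ 10 families, ≥ 50%
families, 2 cM, 1,000 permutations, 2-LOD and 1-LOD drops, $p<0.05$,
FDR < 0.05, 1 kb, CPM ≥ 1 in ≥ 2) is a named configuration key with the
published default.

One planted-effect caveat: a fully penetrant effect fires only in the UU
families, i.e. ~25% of the panel, so a single planted target can never meet
the 50% sharing filter. The demonstration pipeline configuration
(`demo_config()`) therefore lowers the sharing filter to 0.15 for its own
synthetic run, while `default_config()` keeps the published 50%.

**What the generator does and does not emulate.** It reproduces the
segregation structure, marker linkage, planted local/distal remodeling with
configurable penetrance, family-structured heterosis and state-coupled
counts. It does not emulate spatial autocorrelation of methylation along
real chromosomes, context-specific remodeling rates, the pericentromeric
concentration of real hypomethylated haplotypes, bisulphite-read noise, or
TE mobilization. Passing tests therefore demonstrate the correctness and
calibration of the statistical machinery under the stated generative
assumptions, not biological conclusions about any real panel.

## Problem sizes and numerical choices

The test suite and acceptance analysis run at deliberately chosen desk
scales: pedigree segregation at 50,000 lines for a tight binomial check;
permutation-threshold calibration on 400 (tests) or 500 (acceptance
analysis) null traits with 1,000 permutations each, judged against binomial
Monte-Carlo bands; distal-QTL recovery over 20 replicates at the panel size
of 169; variance-component recovery at 500 families; causal recovery over
30–60 replicates at $n = 200$. Randomness is always drawn through function
`seed` arguments; the pipeline derives per-stage seeds from one root seed
by name, restores the caller's RNG state, and re-running with the same
configuration and seed produces byte-identical output files (checksummed in
the run manifest). Degenerate inputs error early and explicitly: constant
traits, monomorphic markers, empty region universes, non-positive
dispersions, BED intervals with `start >= end`.

## Known limitations

- The two-threshold state caller is a stand-in; applying the package to
  real data should start from HMM-based state calls.
- Single-QTL interval mapping only: no multiple-QTL models, composite
  interval mapping or epistasis scans.
- The fixed-effects environment adjustment ignores possible random
  replicate structure.
- Causal structures are the four fixed DAGs; no latent confounders, and
  direction is only weakly identifiable at small trio counts.
- The quantitative-genetic contrast is a decomposition, not an estimator:
  no attempt is made to estimate the β terms from data.
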