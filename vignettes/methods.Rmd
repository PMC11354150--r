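---
title: "Models and methods behind raprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind raprs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raprs)
```

raprs implements the statistical core of a candidate-gene case-control
association study of rheumatoid arthritis: 11 biallelic markers (SNPs and
one indel) in nine genes, typed in 137 cases and 150 controls, analysed for
per-locus association under several inheritance models, for haplotype
effects at the VDR and HLA-DRB1/TNF regions, and summarised into a
polygenic risk score (PRS). This vignette explains the models, the
numerical choices, and what the synthetic-data machinery does and does not
emulate.

## The cohort model and dosage coding

Everything operates on a `cohort()`: a locus panel, per-individual
phenotype/covariate records, and a genotype matrix coded as **risk-allele
dosage** g ∈ {0, 1, 2}. Dosage is the natural coding here because every
downstream formula consumes counts: the PRS is a weighted dosage sum, the
log-additive model regresses on g, and dominant/recessive models are
indicator collapses of g. Recoding a locus to the other allele maps
g → 2 − g (`swap_risk_allele()`), an involution the test suite checks.

Missing genotypes have no single published convention, so the package's own
rule is: per-locus analyses drop individuals locus-wise; the PRS drops an
individual entirely if any scored locus is missing (a partial dosage sum is
not comparable across individuals). Smoking is accepted as a covariate but
is allowed to be wholly missing, in which case adjustment drops it with a
warning — the study's own covariate table omits smoking even though its
association table adjusts for it. Alcohol intake is an ordered band
(0, 1–6, 7–13, 14+ units/week) entered in regressions as scores 0–3; the
source study does not state its coding, so the simplest ordinal score is
used and recorded in the run manifest.

## Frequencies and Hardy–Weinberg equilibrium

`locus_summary()` tabulates genotype counts per group, converts them to
allele frequencies ((n₁ + 2n₂) / 2n), and tests Hardy–Weinberg equilibrium.
Two tests are provided:

* `hwe_chi_square()` — Pearson goodness of fit against p², 2pq, q² on 1 df;
* `hwe_exact()` — the conditional exact test: given the observed allele
  counts, heterozygote counts follow the classical hypergeometric-type
  distribution, and the p-value sums the probabilities of all outcomes no
  more probable than the observed one.

The exact test is the default in summaries because rare risk-allele
homozygotes (expected counts ≪ 5) occur at several loci. At the study's
sample sizes both tests hold their nominal 5% level within ±0.015 under
simulated equilibrium genotypes; the exact test sits slightly below 0.05,
as exact tests do by construction on a discrete outcome space.

The published frequency table prints values to 2 decimals, which loses the
underlying integer counts. `reconstruct_counts()` inverts the rounding:
it enumerates every genotype-count triple summing to the group size whose
frequencies round (half away from zero, matching the table's display
convention) to the printed values, ordered by distance to n × freqs.
Ambiguity is surfaced as a candidate list, never resolved silently; rows
whose printed frequencies sum too far from 1 (one control row sums to
0.97) admit no candidates and return an empty list.

## Association models

For each locus, `association_scan()` fits:

* **codominant** — indicators for g = 1 and g = 2 against g = 0;
* **dominant** — 1{g ≥ 1}; **recessive** — 1{g = 2};
* **log-additive** — g as a linear dosage term;
* **allelic 2×2** — the allele-count table (2n₂ + n₁ vs 2n₀ + n₁), reported
  alongside the log-additive model since published tables often label the
  row "log-additive/allelic"; the two differ unless genotypes are exactly
  in equilibrium.

Crude dominant/recessive/allelic results come from the 2×2 table:
OR = ad/bc with the Woolf interval exp(ln OR ± 1.96·√Σ1/cell), the
Haldane–Anscombe +0.5 correction (flagged) when a cell is empty, and a
Pearson chi-square p-value. Crude codominant/log-additive and all adjusted
results come from logistic regression; p-values are likelihood-ratio tests
of the genotype term(s) against the covariate-only null — the convention of
the SNPstats-style tools this package mirrors — with Wald intervals for the
ORs. Calling the scan without covariates copies the crude results into the
adjusted columns, so the two routes can be compared bitwise.

`fit_logistic()` is a plain IRLS Newton iteration with step-halving.
Convergence is declared when the score max-norm falls below 1e-8 or the
relative log-likelihood change below 1e-10, capped at 100 iterations. A
coefficient exceeding 15 on the log-odds scale is treated as complete or
quasi-complete separation: the fit warns, flags itself non-converged, and
still returns the estimates so callers can report the degeneracy (no Firth
penalisation — separation is flagged, not repaired). On a saturated 2×2
design the fitted slope equals the contingency log-OR to at least 10
significant digits, which the acceptance suite asserts.

Multiple testing uses the Bonferroni threshold α/m; with α = 0.05 over the
11-locus panel this displays as 0.0045 (4 decimals, half away from zero).

## Haplotypes and linkage disequilibrium

`em_haplotypes()` runs the standard EM for 2–3 biallelic loci: the E-step
distributes each multi-heterozygote over its compatible phase pairs with
weights proportional to products of current haplotype frequencies, the
M-step re-estimates frequencies from expected counts. Initialisation is
the uniform distribution, which is deterministic; seeded random restarts
are available but rarely needed at these dimensions. The log-likelihood is
asserted non-decreasing at every iteration, and on instances small enough
to exhaustively maximise (the MLE fixes haplotype margins at the sample
allele frequencies, leaving one free parameter for two loci) EM agrees with
a 1e-3 grid search to |Δh| ≤ 1e-3. On phase-unambiguous data EM reduces to
direct haplotype counting.

`ld_stats()` computes D = h(AB) − p_A·p_B, D′ = |D|/D_max and
r² = D²/(p_A q_A p_B q_B), with a chi-square test of D = 0 using 2n·r².
D′ and r² are invariant to allele relabelling (tested); LD is undefined at
a monomorphic locus.

`haplotype_association()` follows the expected-dosage convention: the EM is
fit on cases and controls pooled, each individual receives the posterior
expected dosage of every haplotype, and status is regressed on all
non-reference dosages jointly (the most frequent haplotype is the
reference; ties break lexicographically with a warning). Haplotypes under
a 1% frequency floor — the usual reporting threshold — are pooled as
"rare". Per-haplotype p-values are drop-one likelihood-ratio tests.
Group-specific refits are available by subsetting the cohort.

## Polygenic risk scores

The unweighted score is the dosage sum Σ g_l; the weighted score multiplies
each locus by its per-allele odds ratio. **Raw odds ratios, not log-odds,
are the weights**: that is how the source analysis defines its weighted
score, and the closed-form identity below reproduces the published weighted
mean difference under raw-OR weights (≈ 2.72 vs the printed 2.75, the gap
attributable to 2-decimal frequency rounding) whereas log-OR weights give
≈ 0.8. The default weight source is the adjusted allelic ORs; crude and
external weights are selectable.

Because the group mean of a dosage sum is 2·Σ w_l·p_l (mean dosage is twice
the allele frequency), the expected case−control mean difference is

> Δ = 2 · Σ_l w_l · (p_case,l − p_control,l),

computable from a published frequency table alone. With unit weights and
the published frequencies this gives exactly 1.48, the study's unweighted
mean difference; `compare_groups()` then supplies the pooled-variance
t-test (df = n₁ + n₂ − 2 = 285 at the study sizes). The sample analogue of
the identity holds to machine precision on any cohort, which the tests
assert.

Risk alleles default to the six susceptibility alleles named by the study
(TNFR2 G, TRAF1 A, PTPN22 T, HLA-DRB1 G, TNF-α A, IL4-590 T) plus, for the
five loci left unnamed, the allele in the direction of the reported effect
(ACE D, BsmI T, FokI C, TaqI G, STAT4 T). STAT4's direction is internally
inconsistent in the source (the T allele is rarer in patients yet carries
an OR above 1); the default keeps T and the panel is fully overridable, so
this is a configuration choice, not a hard-coded resolution. The same
applies to the VDR haplotype allele lettering, which the source tables use
inconsistently: haplotype labels here are always derived from the
`locus_set()` in force.

## The synthetic cohort generator

No individual-level data are deposited for this study, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes. Controls draw genotypes locus-wise from Hardy–Weinberg
proportions at the configured control allele frequencies, or jointly from
haplotype blocks where linkage is wanted; covariates draw from
group-specific distributions (the published ones by default: mean ages
49.0/58.9, 27%/43% male, the printed diet and alcohol bands normalised
where the printed percentages do not sum to 100). Cases are rejection
samples from the control model accepted with probability
min(1, exp(b0 + Σ ln(OR_l)·g_l + covariate terms)). Tilting the control
distribution by the disease odds is exactly the case distribution a
logistic disease model implies — f(g|case) ∝ f(g|control)·e^η — so the
configured control frequencies remain the control distribution and a
case-control logistic refit recovers ln(OR_l) without any rare-disease
approximation (verified at n = 50,000 to ±0.05, with 95% Wald coverage
within 95% ± 2% over 1,000 replicates). A plogis-shaped acceptance was
considered and rejected: it treats the control model as the population, which
attenuates refitted effects unless disease is rare. The intercept b0 is
solved on a fixed Monte-Carlo pool for a target mean acceptance (default
0.25) and capped so acceptance stays a probability; an acceptance rate
driven near zero raises a simulation error after a bounded number of
batches. All randomness flows from one seed; the same seed reproduces the
cohort byte for byte.

`simulate_from_published_tables()` is simpler still: each group draws
genotypes locus-wise from that group's *printed genotype frequencies* — no
disease model, no linkage. It is the fixture behind the PRS identity
checks: averaged over replicates at 137/150, the unweighted mean difference
centres on the closed-form value (≈ 1.49 rather than 1.48 exactly, because
the one inconsistent printed row is renormalised). Printed rows are
accepted within a 0.03 deviation from unit sum — the least consistent
published row sums to 0.97 — renormalised with a warning; anything worse is
a configuration error.

What the generator deliberately does **not** emulate: population
stratification, genotyping error, missingness mechanisms, realistic
genome-wide LD (only explicit haplotype blocks), or covariate-genotype
correlation. Passing tests therefore demonstrate the correctness of the
estimators under the stated model, not robustness to those real-data
complications.

## Numerical conventions and problem sizes

* Display rounding is half away from zero: 2 decimals for ORs/CIs, 4 for
  p-values (`format_or()`, `format_p()`), matching the conventions of the
  published tables and avoiding R's banker's rounding at ties.
* EM tolerance 1e-8 on the max frequency change, 1000-iteration cap; IRLS
  tolerances as above; reconstruction uses a 1e-9 epsilon to keep exact
  rational ties stable in floating point.
* Monomorphic loci: HWE tests return the degenerate statistic 0 / p = 1;
  LD and odds ratios on a zero margin raise errors rather than NaN.
* Simulation-based checks use n = 50,000 for point recovery, 1,000
  replicates at n = 2,000 for interval coverage, and 10,000 replicates at
  the study's own sizes (137/150) for type-I-error calibration — sizes at
  which Monte-Carlo error is well below the tolerances being checked while
  the whole suite stays fast on a laptop.

## Known limitations

The package reproduces the published summary quantities that are derivable
from printed tables (frequency arithmetic, the Bonferroni threshold, the
PRS identities, crude log-additive ORs within the resolution the rounded
tables allow). Quantities that require the individual-level data — adjusted
ORs, the haplotype ORs, the t statistics — are validated property-wise
(parameter recovery, calibration, closed-form identities) instead, and the
published HWE p-values are not reproducible from the paper's own rounded
frequencies under either test, so they are reported but never asserted.
Exact conditional logistic regression, Firth penalisation, multi-allelic
loci, pedigrees, imputation and genome-wide scale are out of scope.
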