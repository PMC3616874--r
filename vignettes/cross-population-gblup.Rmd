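---
title: "Cross-population genomic prediction with a joint reference: models, simulator and design choices"
author: "jointGBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-population genomic prediction with a joint reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
statistical models and their assumptions, what the synthetic-data generator
does and does not emulate, the numerical choices, and the design decisions
taken where the design was genuinely open.

## The scientific setting

A small dairy-cattle population — tens of progeny-tested bulls and one or
two thousand cows with low-reliability phenotypes — cannot support accurate
genomic prediction on its own. A much larger foreign population of
progeny-tested bulls can, in principle, lend information, provided two
conditions hold: linkage disequilibrium (LD) between adjacent markers must
be consistent across the populations (so marker effects transfer), and the
trait must be genetically correlated across environments. The package
quantifies both: an LD-consistency statistic on the marker side, and a
two-trait across-population GBLUP on the phenotype side, with validation
designs that measure the realized gain in prediction reliability.

## Models

### Linkage disequilibrium

For two loci with alleles A/a and B/b, signed LD is

\[ r_{LD} = \frac{f(AB) - f(A)f(B)}{\sqrt{f(A)f(a)f(B)f(b)}} , \]

with all frequencies counted over pooled maternal and paternal haplotypes
(two per animal). `r2 = r_LD^2`. Monomorphic loci give an undefined r,
which is propagated as `NA`, never coerced to zero. **LD consistency**
between two populations is the Pearson correlation of the signed r of
adjacent marker pairs, per chromosome, over pairs polymorphic in both; the
overall value is the unweighted mean across chromosomes. Signed r (not r²)
is used because the sign carries the phase information that determines
whether marker effects transfer; this makes allele harmonization
(`harmonizeAlleles()`) mandatory upstream — a systematic allele flip in one
population turns a consistency of +1 into −1. Pairs monomorphic in either
population are excluded; chromosomes with fewer than three usable pairs are
omitted with a warning.

When phased haplotypes are unavailable, `emPairwiseHaplotypeFreq()`
estimates f(AB) from unphased genotypes by EM under Hardy–Weinberg and
random mating; only double heterozygotes are phase-ambiguous, so the EM
reduces to direct counting whenever they are absent.

### Genomic relationships and GBLUP

The genomic relationship matrix follows VanRaden's method 1:
\( G = MM' / \sum_i 2 p_i (1 - p_i) \), where column *i* of *M* holds
dosages centered by \(2p_i\) and \(p_i\) is the frequency of the counted
allele. Missing dosages are mean-imputed (set to \(2p_i\), i.e. zero after
centering) inside G only. A ridge (default `1e-6`) is added to the diagonal
so the mixed-model equations stay invertible; with frequencies estimated
from the genotyped sample itself, the ones-vector is an exact null vector
of the unridged G, so this is a structural necessity, not a tuning knob.

The prediction model is

\[ y = 1\mu + Zg + e, \qquad g \sim N(0, G\sigma^2_g), \qquad
   e \sim N(0, D\sigma^2_e), \]

with phenotypes `y` the deregressed proofs (DRP) and *D* diagonal with
per-record weights \( d_i = (1 - r^2_{DRP,i}) / r^2_{DRP,i} \), so each
record's residual precision is proportional to its effective information
(d = 1 at reliability 0.5; d = 1/9 at 0.9). The weight formula is the
standard DRP convention in this literature; a reliability of exactly 1
would give an infinite-precision record and is floored at `d = 1e-8` with a
warning. Fixed effects are one mean per trait only; genetic trend is
handled post hoc in validation rather than in the model.

In the **two-trait across-population model**, one biological trait is
treated as two correlated traits, one per population, over a single GRM
spanning both populations:

\[ \mathrm{Var}\begin{pmatrix} g_1 \\ g_2 \end{pmatrix}
   = \begin{pmatrix} \sigma^2_{g1} & \sigma_{g12} \\
                     \sigma_{g12} & \sigma^2_{g2} \end{pmatrix} \otimes G .
\]

No animal has records for both traits (the traits are population-exclusive),
so the residual covariance is not identifiable and is structurally fixed at
zero. The derived genetic correlation
\( r_G = \sigma_{g12} / \sqrt{\sigma^2_{g1}\sigma^2_{g2}} \) measures how
well marker effects transfer; the trait-1 breeding values of this model are
the joint-reference predictions for population-A animals. Breeding values
are obtained from Henderson's mixed-model equations for **all** animals in
the GRM — test animals carry no records and are predicted through G; their
solutions equal the G-projection \( \hat g_{test} = G_{test,ref}
G_{ref,ref}^{-1} \hat g_{ref} \), which the test suite checks numerically,
along with the exact equivalence of GBLUP to SNP-BLUP (ridge regression on
centered marker covariates with matched variance ratio).

### AI-REML

Variance components are estimated by average-information REML on the dense
V-parameterization (records at package scale number at most a few
thousand, so a Cholesky of the n×n phenotypic covariance per iteration is
cheap). Numerical choices:

* parameters are updated on transformed scales — log variances and
  atanh(r_G) — so bounds are respected by construction;
* Newton steps use the AI matrix with step-halving (up to 25 halvings);
  accepted steps never decrease the restricted log-likelihood;
* convergence is declared when the relative parameter change drops below
  `tol` (default `1e-8`; the pipeline uses `1e-6` for its larger fits);
* start values assign half the weighted phenotypic variance to each
  component, with the genetic covariance starting at
  \( 0.5\sqrt{\sigma^2_{g1}\sigma^2_{g2}} \);
* variances are floored at `1e-8` of the phenotypic variance; zero-variance
  phenotypes return floor estimates with `converged = FALSE`;
* asymptotic standard errors come from the inverse AI matrix at the
  solution.

The AI fixed point is verified against an independent EM-REML
implementation on a small instance. At very small n the REML optimum often
sits at the \(\sigma^2_g = 0\) boundary for perfectly ordinary draws; the
fixed-point comparison therefore uses a draw with an interior optimum,
while boundary behavior is tested separately.

### Validation

Two designs mirror practice in dairy genomic evaluation:

* **bull test set**: candidate bulls without genotyped daughters, excluding
  those whose maximum genomic relationship to any reference bull reaches
  0.45 (default). The threshold sits between first-degree relationships
  (~0.5) and half-sib relationships (~0.25). Note that realized
  parent–offspring genomic relationships in a contemporary-frequency GRM
  center near 0.48 with SD ≈ 0.03 even on a 30-Morgan genome, so a 0.45
  filter removes most but not all first-degree kin — the package's tests
  assert the separation actually delivered by simulation rather than a
  nominal 100%;
* **cow cross-validation**: whole half-sib families are assigned to folds
  (never split), because a test cow with a large half-sib group in the
  reference would be predicted through family membership rather than
  marker–QTL LD. Reliability is computed on predictions pooled over folds.

The reliability statistic is \( \mathrm{Cor}^2(GEBV, DRP) /
\overline{r^2_{DRP}} \). It is a contract, not a probability: with GEBV
identical to DRP and mean reliability 0.5 it equals 2.0, and it is
invariant to affine transformations of GEBV. Selection-induced genetic
trend inflates the naive correlation when test animals span birth years, so
for bull validation both GEBV and DRP are detrended by ordinary
least-squares regression on birth year first.

The deterministic expectation used for context is

\[ E(r^2_{GEBV}) = 1 - \frac{\lambda}{2N\sqrt{a}}
   \ln\!\frac{1 + a + 2\sqrt{a}}{1 + a - 2\sqrt{a}}, \qquad
   a = 1 + \frac{2\lambda}{N}, \quad \lambda = \frac{M_e k}{h^2}, \quad
   M_e = 2 N_e L, \quad k = \frac{1}{\ln(2N_e)} . \]

Natural logarithms are used in both *k* and the main term; this convention
reproduces the worked value 0.175 at L = 30 Morgans, Ne = 100, N = 1500,
h² = 0.50 (verified by independent evaluation in the tests). The formula is
strictly increasing in N and h², strictly decreasing in Ne, and maps valid
parameters into (0, 1). With DRP phenotypes, their reliability plays the
role of h².

## The synthetic-data generator

`simulateBasePopulation()` initializes allele frequencies from
U(0.05, 0.95) and runs Wright–Fisher random mating at diploid size Ne with
recombination. Recombination uses the Haldane map function with no
interference — the standard neutral choice — on a map of equally spaced
loci (bp assigned at 1 Mb/cM). Drift builds LD towards the
drift–recombination equilibrium \( E(r^2) \approx 1/(1 + 4 N_e c) \), which
the tests verify within a factor of two. `splitAndDiverge()` founds two
populations from (by default disjoint) samples of the base and mates each
separately; LD consistency between them decays with divergence time.

`assignTraitArchitecture()` samples QTL and draws per-QTL effect pairs from
a bivariate normal whose correlation targets the cross-population genetic
correlation; effects are scaled so TBV variance equals h² in each
population on a unit total-variance scale. `buildFamilyStructure()` builds
bull cohorts across birth years — later cohorts bred from
truncation-selected sires, the selected proportion calibrated from the
requested trend via the selection-intensity identity
\( \Delta G = i\,\sigma_g/2 \) (sire path only, accuracy 1 on TBV) — and
generates cows as genuine meiotic daughters of a subset of the bulls, so
daughter–sire (~0.5) and half-sib (~0.25) genomic relationships are
realized in the marker data, and opposing-homozygote parentage checks work
exactly as they would on real genotypes. `generateDrp()` produces
\( DRP_i = TBV_i + \varepsilon_i \) with
\( \mathrm{Var}(\varepsilon_i) = \sigma^2_g (1 - r^2_i)/r^2_i \), an exact,
testable reliability contract (DRP are generated directly rather than by
deregressing simulated EBV, whose deregression formula would itself be a
modeling choice).

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes × 1 Morgan, 500 loci each | scaled-down 54K-chip-like density; adjacent-pair r² ≈ 0.2–0.4 as on real chips |
| Ne | 100 | Holstein-like effective size |
| burn-in | 200 generations | approaches drift–recombination equilibrium at Ne = 100 |
| divergence | 5 generations | "shared ancestry a few generations back"; gives LD consistency ≈ 0.94 |
| population A | 80 bulls, 13 sires, 1572 cows, families 63–358 | the small-national-population structure |
| population B | 4398 bulls | the large foreign bull reference |
| h² | 0.3 | milk-yield-like heritability |
| r_G | 0.8 | within the 0.7–0.9 range typical for across-country dairy traits |
| DRP reliability | bulls 0.90, cows 0.35 | progeny-tested bulls vs own-performance cows; the cow value is a configurable assumption |
| trend | 0.1 genetic-SD/year | a moderate realized selection trend |
| QTL | 100, excluded from the panel | prediction must act through marker–QTL LD, as with a real chip whose causal variants are not genotyped |

What the generator does **not** emulate: mutation, realistic bovine map
heterogeneity (marker gaps are uniform, unlike the real chip's 3 bp–3.8 Mb
range), genotyping error, genotype-by-environment structure beyond the
cross-population effect correlation, and the deregression machinery of
national evaluations. Passing tests therefore demonstrate correctness of
the statistical machinery and directional behavior of the design — not that
real 54K data would give the same numbers.

## Problem sizes used by the automated experiments

The package's own validation experiments (`smallScenarioConfig()`) run the
full pipeline at roughly quarter linear scale: population A of 50 bulls (3
sires of 390 cows), population B of 500 bulls, 2 × 300 loci with 100 QTL
excluded, 150 burn-in generations. A full scenario completes in tens of
seconds, so ten-seed replications of the joint-versus-single comparison and
its unrelated-population negative control stay cheap. These sizes preserve
the information ratio that drives the design (population B carries roughly
17× the record information of population A's reference, versus ~40× in the
full-size configuration) while keeping every record×record matrix small.

## Pipeline conventions

* All randomness flows from one root seed through fixed-offset sub-streams
  (simulation, architecture, families, DRP noise, fold assignment, cow
  removal), so any stage can be re-run in isolation and a scenario is
  bit-reproducible end to end.
* Joint-reference GRMs use allele frequencies pooled over both populations
  (per-population frequencies are available via the `p` argument);
  single-reference runs build G from population A alone.
* QC follows strict inequalities: markers removed when MAF < 0.01 or call
  rate < 0.90, animals when missingness > 0.10; boundary values are
  retained. The marker call-rate threshold is an explicit parameter — its
  0.90 default is documented rather than hard-coded, as the sensible
  reading of a retention rule that is ambiguous in this literature.
* Variance components for the cow cross-validation are estimated once on
  the full reference and held fixed across folds (re-estimating within each
  fold changes the predictions negligibly at these sizes and quintuples the
  cost).
* Every stage persists its intermediates as plain TSV; an audit test
  re-derives every reported reliability from the persisted files.

## Known limitations

* The dense V-based AI-REML is quadratic in memory and cubic in time in the
  number of records; beyond ~10⁴ records an MME-based sparse implementation
  would be required.
* The two-trait model supports exactly two population-traits; more
  populations would need a general multi-trait covariance structure.
* The bull-validation reliability at the package's scaled sizes is noisy
  (tens of test bulls); conclusions rest on seed-replicated directional
  comparisons, not on single-run values.
* Parentage checking assumes error-free genotypes; a genotyping-error model
  would soften the opposing-homozygote count.
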