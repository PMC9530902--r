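---
title: "Methods: linking bacterial mutation and growth rates across genotypes and media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking bacterial mutation and growth rates across genotypes and media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutgrowth)
```

## The scientific question

Growth fitness and mutability are the two primary quantitative traits of a
bacterial population: the growth rate \(\mu\) (h^-1) measures adaptiveness,
the mutation rate M (per bp per division) measures evolvability. This package implements, as a fully testable pipeline on
synthetic data, the analysis linking the two across *Escherichia coli*
genotypes — wild type, genome-reduced strains, mismatch-repair (MMR)
deficient mutators, and genome-reduced mutators — grown in three media of
decreasing nutritional richness (LB, MAA = minimal + 20 amino acids, M63 =
minimal).

The core empirical law is a per-medium log-linear trade-off:

$$\log_{10} M_i \;=\; \log_{10} M_\infty \;+\; \alpha\,\mu_i ,$$

where \(M_\infty\) is the maximal mutation rate as the growth rate drops to
zero and \(\alpha < 0\) is the slope coupling log mutation rate to growth
rate. Both parameters are properties of the medium, not of the genotype:
all genotypes fall on a common trajectory once the medium is fixed. The
reference values used as generative truth throughout are
\(\alpha\) = (−9.5, −12.6, −12.8) and \(M_\infty\) = (1e-3, 4e-4, 7e-6)
bp^-1 division^-1 for LB, MAA and M63. With a genome of ~4×10^6 bp the
rich-medium maximum corresponds to thousands of mutations per genome per
division, the poor-medium maximum to only a few — nutritional richness sets
the ceiling on mutability.

A note on the law's algebraic form: the logarithm base matters and is
easy to get wrong. We use base-10 logarithms because only that reading
makes the reference slopes (−9.5 … −12.8) consistent with the reference
intercepts (1e-3 … 7e-6) over the observed rate range of roughly 1e-10–1e-7: e.g.
\(\log_{10}M = -3 - 9.5\mu\) spans 1e-10.6 to 1e-6.8 for
\(\mu \in (0.4, 0.8)\) h^-1, whereas a natural-log reading would place the
rates many decades outside anything observable.

## What the synthetic-data generator emulates

No measured dataset ships with the package; the generator instead
produces data with the same statistical structure, so
every downstream stage can be tested against known truth.

**Strain panels.** Three collections: MDS (default 14 = 13 MMR/proofreading
deletion mutators plus the genome-reduced parent MDS42; the size is
configurable), KHK (10
reduced genomes derived from wild-type W3110), and MG (MG1655 plus 9
mutators). Genotype is summarised by two binary flags — genome reduction
and MMR deficiency — whose combinations give the four genotype classes.

**True rates.** Each strain carries a latent growth quantile shared across
media. Quantiles are stratified across the panel (a jittered grid rather
than i.i.d. uniform draws) because the real collections were deliberately
assembled to span a range of growth abilities — varied genome sizes, varied
fidelity deletions — so a panel covers the growth axis evenly rather than
clustering by chance. Collection parents draw from the upper quantile range
(U(0.6, 0.95)): parents are healthy laboratory strains and consistently
out-grow their disturbed derivatives. Each disturbance flag scales the
quantile down by 25%. The quantile maps into the medium-specific growth
range — LB (0.4, 0.8), MAA (0.25, 0.6), M63 (0.1, 0.45) h^-1, chosen so
generated mutation rates span the observed 1e-10–1e-7 decade range — and a
small per-medium jitter (SD 0.02 h^-1) is re-sorted so the universal
ordering LB ≥ MAA ≥ M63 of growth rates is preserved per strain. The
mutation rate then follows the trade-off law with Gaussian noise (default
SD 0.2) on the log10 scale — the simplest noise model consistent with
rate tables that carry per-condition standard errors.

**Raw measurements.** Fluctuation assays are simulated by the brute-force
Lea–Coulson process, not by inverting the probability mass function: the
number of mutation events per culture is Poisson with mean
m = M × (target size) × N_final, and each event founds a clone of final
size floor(N_final/x) with x uniform on (1, N_final) — deterministic
exponential growth with mutations uniform over divisions, which yields the
classic clone-size law q_k = 1/(k(k+1)). CFU plates are Poisson counts at
recorded dilutions. Growth curves are logistic trajectories read every
30 min for 48 h with Gaussian OD noise (SD 0.002) truncated at zero.

Two constants that real assays leave implicit are exposed as explicit parameters
used identically by generator and estimator, so round-trip recovery is
well-defined: the effective mutational target size for nalidixic-acid
resistance (default 30 bp) and the final population size per culture. The
end-to-end pipeline picks N_final per strain so the expected mutations per
culture is ~2 (clamped to 1e5–1e9 cells), emulating the experimental
practice of shrinking culture volume for mutators so mutant counts stay
countable.

**What the generator does not emulate.** No sequence-level mutation events,
no phenotypic lag or differential mutant fitness, no plating-efficiency
loss, no collection-specific reversal of the medium response of mutation
rates beyond what the common law plus growth shifts induce (the real MDS
and KHK collections shift in opposite directions between LB and M63; the
generator reproduces the sign tendency but not its strength), and no
correlation structure in OD noise. Passing tests therefore demonstrate
correctness of the estimators and analysis under this idealised model, not
robustness to every artefact of real plate data.

## Mutation-rate estimation

The mutant-count distribution is computed by the Ma–Sandri–Sarkar (MSS)
recursion — the compound-Poisson (Panjer) recursion over the Lea–Coulson
clone-size law:

$$p_0 = e^{-m}, \qquad
  p_n = \frac{m}{n}\sum_{j=0}^{n-1} \frac{p_j}{\,n-j+1\,}.$$

The per-culture expected mutation number m is estimated by maximum
likelihood over the observed counts, with counts above a truncation point
n_max (default 1,500; 500 in the end-to-end pipeline for speed) lumped into
the jackpot-tail mass 1 − Σp. The likelihood is unimodal; we maximise over
log m by bracketed scalar optimisation on (1e-3, 1e2) and report a 95%
profile-likelihood interval (log-likelihood drop of 1.92). The P0 method,
m = −ln(fraction of cultures without mutants), serves as fallback and
diagnostic. All-zero assays return m = 0 with the exact binomial-style
upper bound −ln(0.05)/n from p0^n. Population size comes from the CFU
plates after the reliability filter — only plates with 10–500 colonies
count — as the mean of count/dilution; the rate is m / (N_final × target
size), and replicate assays (default 3) are combined by the arithmetic mean
with the SE over replicates (N = 3–6 replicate assays is the typical
design; the mean, rather than the median, is used).

The simulator and the recursion are verified against each other by
chi-square goodness of fit on 1e5 simulated cultures at m ∈ {0.5, 1, 4}
(the simulator is the independent brute-force oracle for the analytic
pmf), and the MLE recovers m = 1 within 5% at 1e4 cultures.

## Growth-rate estimation

Rates are the maximal specific growth rate from windowed log-linear
fitting: least-squares lines of ln(OD) over every contiguous window, take
the maximal slope among qualifying windows. Defaults: window of 7 reads
(3 h at 30-min intervals), r² ≥ 0.98, and a window's mean OD must exceed
3% of the curve's maximum. The OD gate is relative, which keeps the
estimate invariant to rescaling the OD axis, and it is dropped for wells
that never clear it, so flat wells (blanks, non-growers) still return
rate 0. These defaults were calibrated on simulated curves: short windows
combined with max-slope selection amplify read noise near the detection
floor into a +5…+50% bias (worst for slow growers), while the chosen
setting keeps the bias within ±2% across mu = 0.1–0.7 h^-1 at the default
noise level. Lag and stationary phases are handled implicitly by the
max-slope selection, not by changepoint detection; curves are
blank-corrected and floored at OD 1e-3 so logarithms are defined.

## The analysis layer

**Trade-off fits.** Per medium, unweighted OLS of log10(M) on mu pooled
across all collections and genotypes (the pooling is the point: the law is
genotype-independent). M is the response because \(M_\infty\) is defined as
the mu→0 intercept. Pearson r and its two-sided p are reported on the same
pairs. Noiseless tables are interpolated exactly; on the standard recovery
protocol (20 strains per medium, noise SD 0.2), the median recovered slope
over 50 seeded replicates is within 5% of truth per medium and the 95% CI
covers truth at a nominal rate. A single 20-strain draw recovers each
slope within ±10% for most seeds; the intercept \(\log_{10} M_\infty\) is
harder (it extrapolates to mu = 0 from growth ranges bounded well away
from zero — its SE is ≈ 0.25 decades in LB under these conditions), which
is worth remembering when comparing single-panel intercepts.

**Distribution shifts and correlations.** The LB-vs-M63 shift of per-strain
log10 mutation rates is tested by the paired two-sided Wilcoxon signed-rank
test (the choice of test is recorded in the output metadata). Cross-media correlations are Pearson on the
plotted scales (log10 for mutation rates, raw for growth rates), per
collection and pooled; genetic-disturbance effects are log10 ratios of
derivative over parent, per medium.

**Multiple linear regression.** Features per (strain, medium) row: mu,
log10 M, the ordinal medium code (LB 1, MAA 0, M63 −1) and a composite
genotype value — the two binary flags multiplied ("interactive": 1 only
for genome-reduced mutators) or added ("additive": 0/1/2). OLS with
intercept predicts log10 M from (mu, medium, genotype) or mu from
(log10 M, medium, genotype), reporting per-coefficient t-tests (raw,
uncorrected) and adjusted R². A constant genotype column (interactive
coding with no doubly disturbed strains) is flagged non-informative and
dropped rather than crashing; any other constant or collinear predictor is
an error naming the column.

**Classification.** A support vector machine on exactly two features,
(mu, log10 M), classifies the medium (3 classes) or the genotype (4
classes). Protocol per repeat: stratified random 60/40 train/test split
(stratification prevents empty classes at these panel sizes); 5-fold nested cross-validation over C, and gamma for
the RBF kernel, on the grid 0.001–100 in 10-fold increments, scored by
macro-averaged recall; accuracy from the test confusion matrix; five
repeats. Features are standardised with training-split statistics — the
source is silent, but an RBF kernel on raw scales (mu ≈ 0.5 vs
log10 M ≈ −8) would degenerate — and the scaling constants are recorded in
the report. A fixed-hyperparameter mode uses the fixed reference
values (linear: C = 10 medium / 100 genotype; RBF: (10, 1) medium /
(100, 0.01) genotype). Decision landscapes evaluate the trained classifier
on a lattice over the rate plane.

On the default synthetic panel the three media are nearly separable in the
rate plane, so medium accuracy saturates near 1.0 for both kernels (the
directional claim RBF ≥ linear holds as a tie), while genotype accuracy is
far lower (~0.45, chance 0.25). Real measured panels are noisier than
the generator's idealisation, so medium accuracies there sit below 1.0,
but the ordering — medium much easier than genotype, RBF at least as good
as linear for the medium — is the robust feature.

## Numerical choices and degenerate inputs

* MSS pmf truncation: mass above n_max is lumped, never discarded; the
  captured mass is ≈ 1 − m/n_max (≥ 0.999 at the default n_max = 1500 for
  m = 1), reflecting the heavy 1/n² jackpot tail.
* MLE search space m ∈ (1e-3, 1e2) on the log scale; profile-CI roots by
  bisection within the same bracket; boundary cases (all-zero counts)
  short-circuit before optimisation.
* Ties in the CV grid break toward the smallest (C, gamma) — the least
  complex model at equal score.
* A train/test split that loses a class is redrawn with a derived sub-seed
  (possible only for singleton classes, which stratification otherwise
  protects).
* Every random step derives its seed deterministically from the global
  seed and a stage label (`stage_seed`), so stages are independently
  reproducible and editing one does not reshuffle another.
* Fits on constant growth rates raise a singular-fit error; media pairs
  with fewer than 3 shared strains are skipped with a warning in the
  correlation matrix and are an error in the paired shift test.

## Problem sizes

Default study conditions: 34 strains × 3 media; per condition 3
fluctuation assays of 30 cultures with 4 CFU plates, and 6 growth wells
read every 30 min for 48 h. The verification suite uses 1e5 simulated
cultures for the pmf cross-check and 1e4 for estimator consistency, and 50
replicates of the 20-strain recovery protocol; the full default pipeline
(simulate → estimate → fit → predict → report) runs in well under a minute
on a single core.

## Known limitations

* Absolute mutation rates depend on the unstated nalidixic-acid target
  size; only relative comparisons are meaningful unless target_size_bp is
  calibrated externally.
* The Lea–Coulson simulation assumes constant relative fitness, no death,
  and deterministic growth; rates near the detection limit (all-zero
  assays) carry only an upper bound.
* The generator's media are more separable in the rate plane than real
  data, so classification accuracies here are optimistic; directional
  comparisons (RBF vs linear, medium vs genotype difficulty) are the
  meaningful output.
* The growth fitter reports the maximal specific rate only — no lag time,
  yield, or full logistic/Gompertz parameter estimation.
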