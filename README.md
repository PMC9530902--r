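# mutgrowth

Quantitative linkage of bacterial **mutation rate** and **growth rate**
across genotypes and growth media, implemented as a tested R pipeline on
synthetic data.

Bacterial fitness (growth rate μ, h⁻¹) and mutability (mutation rate M,
bp⁻¹ division⁻¹) trade off against each other. Across *E. coli* strain
collections — wild type, genome-reduced strains, mismatch-repair-deficient
mutators, and genome-reduced mutators — the two rates follow a common
per-medium log-linear law,

    log10(M_i) = log10(M_inf) + alpha * mu_i ,        alpha < 0

whose parameters depend on the medium but not the genotype: the maximal
mutation rate M∞ (the μ→0 intercept) and the slope α are
(α, M∞) = (−9.5, 1e-3), (−12.6, 4e-4), (−12.8, 7e-6) in rich LB,
amino-acid-supplemented MAA, and minimal M63 medium respectively. With a
~4 Mb genome, the rich-medium ceiling corresponds to thousands of mutations
per genome per division; the poor-medium ceiling to only a few.

The package provides every stage needed to reproduce this analysis
end-to-end without any external data:

* **synthetic data** — seeded strain panels (MDS / KHK / MG collections),
  true rates obeying the trade-off law, raw Luria–Delbrück fluctuation
  assays simulated by the brute-force clone-size process, CFU dilution
  plates, and logistic OD595 growth curves;
* **fluctuation analysis** — the Ma–Sandri–Sarkar (Lea–Coulson)
  probability mass function, maximum-likelihood and P0 estimators of the
  expected mutations per culture with profile-likelihood CIs, CFU sizing
  with the 10–500 colony plate filter, conversion to bp⁻¹ division⁻¹;
* **growth rates** — windowed log-linear fitting of ln(OD) with quality
  gates and replicate aggregation;
* **trade-off analysis** — per-medium OLS fits of the law (α, M∞,
  Pearson r), paired Wilcoxon medium-shift tests, cross-media rate
  correlations, parent-vs-derivative fold changes, mutations-per-genome
  arithmetic;
* **prediction** — multiple linear regression of either rate from (other
  rate, medium code 1/0/−1, genotype coded interactively or additively),
  and SVM classification of medium or genotype from (μ, log10 M) with
  linear/RBF kernels under the stated protocol (stratified 60/40 splits,
  5 repeats, 5-fold nested CV over C, γ ∈ 0.001…100, macro-averaged
  recall), plus decision landscapes.

## Worked example

```r
library(mutgrowth)
report <- run_pipeline(default_config(seed = 1), quiet = TRUE)
cat(summarize(report), sep = "\n")
```

```
== mutation-growth trade-off pipeline ==

Per-medium trade-off law  log10(M) = log10(M_inf) + alpha * mu:
  LB   alpha true   -9.5  recovered  -9.47 (err  +0.3%) | log10 M_inf true  -3.00  recovered  -3.06
  MAA  alpha true  -12.6  recovered -13.37 (err  -6.1%) | log10 M_inf true  -3.40  recovered  -3.16
  M63  alpha true  -12.8  recovered -12.27 (err  +4.1%) | log10 M_inf true  -5.15  recovered  -5.30

Expected mutations per genome per division at M_inf:
  LB   4e+03
  MAA  1.6e+03
  M63  28

Multiple linear regression (adjusted R2):
  mutation.interactive   0.930
  mutation.additive      0.930
  growth.interactive     0.977
  growth.additive        0.977

Classification (mean test accuracy over repeats):
  medium.linear      1.000
  medium.rbf         1.000
  genotype.linear    0.478
  genotype.rbf       0.459
```

Reading it: the pipeline simulated 34 strains × 3 media, ran 306 simulated
fluctuation assays and 612 growth curves through the estimators, refit the
trade-off law per medium — recovering each slope within a few percent of
the generative truth — and then ran the prediction layer. The mutation
rate is highly predictable from growth rate, medium and genotype
(adjusted R² ≈ 0.93); the medium is recoverable from the two rates alone
(accuracy ~1.0 on this idealised panel), while the four-level genotype is
much harder (~0.46 vs a 0.25 chance floor), the same ordering seen in real
data.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → estimate → trade-off → regression → classification),
printing what each stage found and writing its tables under `results/`
(bulky raw CSVs are regenerated by `analysis/01_simulate.R` rather than
checked in).

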