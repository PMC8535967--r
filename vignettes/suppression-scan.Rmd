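---
title: "Detecting suppression effects in quantitative-trait GWAS"
author: "suppscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting suppression effects in quantitative-trait GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suppscan)
```

## The problem

A conventional genome-wide association scan regresses a quantitative outcome
on each SNP's minor-allele dosage and declares hits by p-value. This misses a
whole class of real genetic effects: when a genotype influences the outcome
through a mediator whose indirect contribution *opposes* the direct one, the
two paths cancel in the marginal regression and the SNP looks null. The
mediator then acts as a *suppressor*. The canonical biological example built
into this package's defaults is the adiponectin/HDL-C system: a variant that
lowers circulating adiponectin (which itself raises HDL-C) while directly
raising HDL-C shows essentially no marginal association with HDL-C, yet a
strong association once adiponectin is adjusted for.

`suppscan` implements the full detection path: quality control, a scan under
adjustment sets with and without the mediator, a four-criterion mediation
analysis with the Sobel test, two-locus haplotype/LD support, and a synthetic
cohort generator so that every stage is testable without access-controlled
biobank genotypes.

## The model

For sample $i$ with dosage $G_i \in \{0,1,2\}$, mediator $M_i$, outcome
$Y_i$ and covariates $X_i$ (age, sex, BMI, smoking), three nested linear
models are fitted on the identical list-wise-deleted sample:

$$\log M_i = \mu + \alpha G_i + c_M' X_i + \epsilon_{M,i}$$
$$\log Y_i = \nu + \beta \log M_i + \gamma' G_i + c_Y' X_i + \epsilon_{Y,i}$$
$$\log Y_i = \tau_0 + \tau G_i + c' X_i + \epsilon_i$$

The indirect (mediation) effect is $\alpha\beta$, the direct effect is
$\gamma'$, and the total effect $\tau$ satisfies the algebraic identity
$\tau = \alpha\beta + \gamma'$ exactly when all three regressions use the
same rows and covariates (asserted to $10^{-10}$ in the test suite). Four
criteria are evaluated at a configurable significance level (default 0.05):

1. $\alpha$ significant (genotype predicts the mediator);
2. $\beta$ significant (mediator predicts the outcome, genotype-adjusted);
3. the total effect $\tau$ significant;
4. the indirect effect significant by the Sobel test,
   $z = \alpha\beta \big/ \sqrt{\alpha^2 se_\beta^2 + \beta^2 se_\alpha^2}$.

Classification: **suppression** requires criteria 1, 2 and 4 together with
$|\gamma'| > |\tau|$ and $\mathrm{sign}(\alpha\beta) \ne
\mathrm{sign}(\gamma')$ — the defining feature is that removing the mediator
*shrinks* the association, so criterion 3 typically fails. **Full mediation**
requires all four criteria with a non-significant direct effect, **partial
mediation** all four with a significant, same-signed direct effect; anything
else is **none**.

The first-order Sobel variance is the default because the package's worked
reference decomposition ($\alpha = -0.079$, $se_\alpha = 0.006$,
$\beta = 0.21$, $se_\beta = 0.01$) yields $z = -11.156$ under it, matching
the reference value of $-11.16$ to two decimals; the Aroian variant (which
adds the $se_\alpha^2 se_\beta^2$ cross term, giving $-11.147$ here) is
available via `sobel_test(..., variant = "aroian")`.

## What the synthetic cohort emulates

`simulation_config()` defines a reference scenario: 2,199 adults (55%
female), per-sex age, BMI and smoking distributions typical of an East-Asian
population biobank (men 48.6 ± 11.1 y, BMI 25.1 ± 3.4, 33.4% smokers; women
48.2 ± 10.7 y, BMI 23.4 ± 3.5, 5.5% smokers), raw-scale adiponectin means of
2.88 (men) and 4.01 (women) mg/L and HDL-C means of 49.7 and 59.4 mg/dL, a
focal SNP pair with MAFs 0.32 and 0.22 in LD at $D' = 0.9$ (positive
coupling of the minor alleles), and a panel of phenotype-independent null
SNPs under Hardy-Weinberg equilibrium.

Choices that matter, and why:

* **Path coefficients** default to $\alpha = -0.079$, $\beta = 0.21$,
  $\gamma' = 0.015$: an indirect effect of $-0.0166$ that almost exactly
  cancels the direct $0.015$, the textbook suppression geometry.
* **Noise SDs** default to $\sigma_M = 0.186$ and $\sigma_Y = 0.087$ on the
  log scale. These make the three path-coefficient standard errors at
  $n = 2199$ approximately 0.006, 0.01 and 0.003 — jointly consistent, since
  $se(\gamma') \approx \sigma_Y/\sqrt{n \cdot 2p(1-p)}$ and
  $se(\beta) \approx \sigma_Y/(\sigma_M\sqrt{n})$ — so the focal SNP's
  marginal outcome p is non-significant while its mediator-adjusted p falls
  below $10^{-6}$, the pattern the scan is designed to expose.
* **Log transforms.** HDL-C and adiponectin are generated on the natural-log
  scale and exponentiated for output; the analysis log-transforms them back
  by default. Natural log is used throughout (base is a convention; all
  coefficients are interpreted on that scale). Whether the mediator is
  log-transformed is configurable (`log_mediator`), since practice varies.
* **Centering.** Inside the generator, age/BMI are centered at per-sex
  means, smoking at per-sex prevalence, and dosage at $2 \cdot$MAF. This
  lets the per-sex intercepts be calibrated analytically
  ($\mu_s = \log(\text{target mean}) - V_s/2$, with $V_s$ the linear
  predictor variance) so that raw-scale means hit their targets, and it
  changes no regression coefficient — the analysis models are exactly
  correctly specified and recover $\alpha$, $\beta$, $\gamma'$ unbiasedly.
* **Missingness** is completely at random (default 0.5% per call). A single
  integer seed drives sex, covariates, haplotypes, null SNPs, noise and
  missingness in a fixed documented order, so runs are byte-reproducible.

What the generator does *not* emulate: population structure and relatedness,
genotyping batch effects, informative missingness, non-additive genetic
effects, X-chromosome dosage, and mediator measurement error. Passing tests
on synthetic cohorts therefore demonstrate correctness of the estimators
under the assumed structural model, not robustness to those real-data
complications.

## Quality control

`apply_qc()` filters samples first (call rate $\ge$ 0.97 by default), then
computes SNP statistics on the retained samples: missingness ($\le$ 3%),
minor allele frequency ($\ge$ 0.05) and the Hardy-Weinberg conditional exact
test ($p \ge 10^{-6}$). The sample-first order is fixed so that reported SNP
statistics describe the analyzed sample set. The exact test enumerates
heterozygote counts conditional on the allele counts by a numerically stable
recurrence and sums the probabilities of all configurations no more likely
than the observed one (plain tail summation, no mid-p); monomorphic sites
return $p = 1$ by convention. Being discrete, the test is conservative: its
rejection rate at a nominal level sits at or slightly below that level,
which the calibration tests assert as an upper bound.

## Haplotype frequencies and LD

For a SNP pair, phase is ambiguous only in double heterozygotes.
`em_haplotype_freqs()` starts from linkage-equilibrium frequencies (a
deterministic start), alternates posterior splitting of double heterozygotes
with frequency re-counting, stops when the largest frequency change is below
$10^{-10}$ (cap 1000 iterations), and verifies at every step that the
log-likelihood did not decrease. Fitted frequencies reproduce the observed
allele frequencies exactly (the EM preserves the margins), so the likelihood
is effectively one-dimensional in $f_{11}$ — which is how the test suite
checks it, against a grid search at $10^{-5}$ resolution.

Reported LD: $D = f_{11} - p_1 p_2$, $D'$ as $|D|$ over its admissible
maximum, and $r^2 = D^2 / (p_1 q_1 p_2 q_2)$. Note that the haplotype-based
$r^2$ and the squared Pearson correlation of dosages (the composite
estimate) are distinct finite-sample statistics that estimate the same
population quantity; they coincide exactly only in degenerate cases such as
complete LD, and asymptotically otherwise — the tests treat their agreement
as a large-$n$ consistency check, not an identity. Haplotype association
uses expected per-sample haplotype dosages (posterior counts), not
best-guess phase, to avoid bias at moderate LD; the most frequent haplotype
is the reference, and haplotypes with expected count below 5 are flagged
unstable.

## Numerical and interface conventions

* OLS is QR-based with classical homoscedastic standard errors and
  t-distribution p-values (the conventions of standard GWAS tooling);
  rank-deficient designs raise an error naming the collinear columns.
* Additive genotype coding (0/1/2 minor-allele copies); sex 0 = male,
  1 = female; smoking 0/1.
* List-wise deletion over all model variables; SNPs monomorphic after
  deletion are flagged untestable rather than erroring, so scans never
  abort on a degenerate marker.
* Genome-wide significance defaults to $5 \times 10^{-8}$, reported as a
  flag next to the raw p-value — the package reports both and adjudicates
  nothing beyond that.
* With $D'$ constrained to $[0,1]$ and minor-minor coupling, all four
  implied haplotype frequencies are non-negative for any valid MAF pair;
  the frequency computation still rejects infeasible combinations
  defensively.
* `run_pipeline()` writes every stage output plus a manifest of md5 hashes;
  a rerun with the same config and seed reproduces the manifest bit for bit
  (no timestamps enter any output file).

## Problem sizes used in the test suite

Unit tests run on cohorts of 50-500 samples; statistical calibration uses
1,000 null SNPs at $n = 500$ (scan uniformity, suppression false-positive
rate) and 200 replicate cohorts at the reference size $n = 2199$ for
parameter recovery and classification rates; LD round-trips use $10^5$
haplotype draws. These sizes give Monte-Carlo standard errors a small
fraction of the tested tolerances while keeping the default suite fast.

## A worked run

```{r demo, eval = FALSE}
cfg <- run_config(simulation = simulation_config(seed = 42), out_dir = "demo")
manifest <- run_pipeline(cfg)
read.delim(file.path("demo", "mediation.tsv"))
```

The mediation table classifies the focal SNP as `suppression`: its marginal
scan p-value is far from significance while the mediator-adjusted p-value is
several orders of magnitude smaller, and the Sobel test on
$\widehat{\alpha}\widehat{\beta}$ is strongly significant with
$\mathrm{sign}(\widehat{\alpha}\widehat{\beta}) \ne
\mathrm{sign}(\widehat{\gamma}')$.

## Known limitations

Single mediator, linear Gaussian models, no bootstrap confidence intervals
for the indirect effect, no sensitivity analysis for unmeasured confounding,
no mixed models or kinship correction, two-locus haplotypes only. The
suppression classification inherits the usual caveat of mediation analysis:
it is a statistical pattern consistent with a causal structure, not proof of
one.
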