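---
title: "Methods: gradual differential expression and gene-set-constrained prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradual differential expression and gene-set-constrained prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hepatocellular carcinoma (HCC) usually arises in a liver that is already
cirrhotic, so the tissue adjacent to a tumor ("pericancerous", sampled a
few centimeters away) is not a clean normal reference. When a cohort
contains three tissue classes — normal liver from unaffected donors,
pericancerous liver, and tumor — genes can be followed along the gradual
trajectory normal → pericancerous → cancer. `gradprog` implements a
discovery pipeline built around that design:

1. moderated-t differential expression for the three pairwise
   comparisons Cancer/Normal (C/N), Cancer/Pericancerous (C/P) and
   Pericancerous/Normal (P/N), with DEGs split into up/down groups and
   partitioned in three-way Venn diagrams;
2. dual-criterion gene-set enrichment: a set counts as enriched with a
   DEG group only when both the hypergeometric over-representation test
   and permutation GSEA are significant after BH adjustment;
3. consensus miRNA-target mapping (an edge needs support from at least
   3 of 6 databases) and substitution of miRNAs for the DEG members of
   enriched sets;
4. survival association of set-constrained expression signatures via
   Cox regression, Kaplan-Meier curves and the log-rank test, with
   validation on an independent cohort.

Every stage is testable offline because the package also ships a
synthetic-cohort generator with planted ground truth.

## Differential expression

For two groups of log2 intensities the package computes the
empirical-Bayes moderated t. Per gene, the pooled variance $s_g^2$ with
$d_g$ degrees of freedom is shrunk towards a prior $(d_0, s_0^2)$
estimated by moment-matching the log variances: with $z_g = \log s_g^2$,

$$\operatorname{Var}(z) - \psi'(d_g/2) = \psi'(d_0/2), \qquad
\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and $\tilde t_g = (\bar x_a - \bar x_b) / (\tilde s_g \sqrt{1/n_a + 1/n_b})$
is referred to $t_{d_0 + d_g}$, two-sided. The trigamma equation is
solved by bisection to a tolerance of 1e-8; if the spread of log
variances falls at or below its theoretical minimum $\psi'(d_g/2)$ the
prior degrees of freedom are infinite and every posterior variance
equals $s_0^2$. Genes with zero residual variance are excluded from the
prior fit but still receive a finite moderated statistic through the
posterior formula — convenient for noise-free synthetic constructions.
Forcing `prior_df = 0` recovers the ordinary pooled-variance Student t,
which the tests use as a reduction check (and the limma implementation
as an independent cross-check).

DEG selection uses strict thresholds |log2FC| > 2 and BH-adjusted
p < 0.001, the working definition of a DEG throughout. All three
comparisons run **unpaired**, although pericancerous and cancer samples
are paired within patients: the contrast structure treats each
comparison symmetrically, and pairing is exploited only where it
matters scientifically — in the C/P profile mode of the survival
classifiers. A gene may be up-regulated in one comparison and
down-regulated in another; that is why the up-diagram and down-diagram
Venn totals may sum to more than the all-DEG total, a structural
phenomenon the acceptance suite reproduces with a planted
sign-switching gene (shifts 0/+6/+3 across normal/peri/cancer, giving
P/N up, C/N up, C/P down).

## Dual-criterion enrichment

The hypergeometric test is upper-tail inclusive, $P(X \ge k)$, over the
universe of all measured genes (gene sets are intersected with the
universe first). GSEA uses the weighted running-sum statistic: walking
down the ranked list, member genes add $|r_i|^p / N_R$ and non-members
subtract $1/(N - N_H)$; the enrichment score is the signed maximum
deviation. The ranking metric is the comparison's moderated t over all
measured genes (effect size blended with precision); ties break by gene
ID to keep permutations reproducible; the weight exponent defaults to 1
(exponent 0 reduces the statistic to the classical two-sample KS
distance, a property the tests verify).

The permutation null draws random gene-label sets of matching size
(1000 permutations by default, shared across sets of equal size — the
standard choice for small cohorts where sample permutation would be
underpowered). The p-value uses add-one two-sided extremeness,

$$p = \frac{1 + \#\{|ES_{null}| \ge |ES|\}}{1 + n_{perm}},$$

which is never zero and is uniform for null sets; a sign-conditioned
count over all permutations was rejected because with a near-symmetric
null it doubles the nominal rate at any cutoff. The normalized score
divides ES by the mean magnitude of same-sign null scores. BH
adjustment runs separately within each (DEG group, criterion) family,
and a set is *enriched* only when both adjusted p-values are strictly
below 0.05.

## Consensus targets and miRNA substitution

Six miRNA-target edge tables are combined by voting: an edge survives
when at least `min_votes = 3` distinct tables contain it. Matching is
at the (miRNA, gene) interaction level with light normalization —
miRNA IDs are case-insensitive and species prefixes (`hsa-`) are
stripped for matching only; gene symbols are upper-cased; first-seen
spellings are preserved in output. `-5p/-3p`-style suffixes are *not*
collapsed, since no family-level merging is described for the printed
signatures. Raising the vote threshold can only remove edges, and
perfect databases (recall 1, false-positive rate 0) reproduce the
planted truth exactly — both are tested invariants. The miRNA
counterpart of a gene signature is the union of consensus-map miRNAs
targeting any DEG member, scored on absolute cancer miRNA expression.

## Survival association

A classifier is a feature list plus a profile mode: `C` scores absolute
cancer expression, `C/P` the paired cancer-minus-pericancerous log
ratio, `P/N` the pericancerous sample minus the mean over normal
reference samples, and `C/N` the analogous cancer-minus-normal-mean
profile (needed by one published signature). The per-patient risk score
is the mean of per-feature z-scores (standardized within cohort):
scale-free, direction-preserving, and safe under degenerate features
(zero-variance features contribute zero rather than NaN). Features
absent from a cohort are dropped and counted, so a signature can still
be evaluated on a platform that lacks some of its genes.

The primary statistic is the univariate Cox partial-likelihood fit on
the continuous score with Efron tie handling (ties are expected at
month resolution); the Wald test and the sign convention "positive log
hazard ratio = higher expression, worse prognosis" are reported. The
median-split Kaplan-Meier curves and log-rank test are presentational
companions ("high" is strictly above the median, leaving group sizes
within one of each other for distinct scores). A classifier discovered
at Wald p < 0.05 *validates* on a second cohort when it is again
significant with the same coefficient sign. The log-rank chi-square
equals the Cox score test at $\beta = 0$ for the binary group indicator
— exactly so for untied event times, which is how the identity is
tested; with ties the hypergeometric variance and the Breslow score
variance differ slightly.

## The synthetic generator

The generator emulates the cohort structure the pipeline targets: 10
normal donors and 45 patients contributing paired pericancerous/cancer
samples. Its defaults are the package's study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_normal`, `n_pairs` | 10, 45 | cohort layout |
| `n_genes`, `n_mirnas` | 2000, 150 | universe sizes |
| `frac_gradual_up/down` | 0.05 each | planted gradual genes |
| `delta` | 5 | full C/N log2 shift; peri gets `delta/2` |
| `noise_sd` | 0.5 | residual log2 SD |
| `beta_surv` | 1 | log-hazard per unit planted risk |
| `censor_frac` | 0.2 | target censoring fraction |
| `db_recall`, `db_fpr` | 0.7, 0.01 | per-database edge probabilities |

Baselines are $\mu_g \sim N(8, 1.5)$ on the log2 scale (typical array
intensities, keeping values positive without modeling raw
fluorescence). `delta = 5` was chosen from the threshold arithmetic:
the pericancerous half-shift (2.5) must clear the strict fold-change
cutoff (2) for all three comparisons to yield DEGs, which is the
structure of the real design; array-level effect sizes and noise are
not published for the original cohorts, so these values are chosen for
testability, not fitted. Gene sets: 20% of the collection (at least
one) is "enriched" by construction, drawing 75% of members from the
gradual genes, alternating up- and down-type; the remainder are
uniform draws. The enriched sets double as planted prognostic sets.

Survival times are exponential with hazard $h_0 e^{\beta z}$, where
$z$ is the standardized mean cancer expression of the first planted
prognostic set and $h_0 = \log 2 / 24$ (median survival 24 months at
$z = 0$, a realistic post-operative scale). Censoring is independent
uniform on $(0, u)$ with $u$ solved numerically so the expected
censored fraction matches `censor_frac`; the closed-form hazard makes
recovery targets analytic. miRNA expression is anti-correlated
(coefficient $-0.5$) with the standardized mean of each miRNA's true
targets, giving the substitution stage real signal. Each stage draws
from its own RNG stream derived from the master seed, so adding a
stage never perturbs earlier draws and identical seeds give
bit-identical studies.

What the generator does **not** emulate: probe-level effects, batch and
platform differences, correlated gene-gene noise, non-exponential
hazards, or informative censoring. Passing tests therefore demonstrate
the pipeline's statistical correctness and calibration under a clean
generative model, not performance on any real cohort.

## Numerical choices and degenerate inputs

- Trigamma inversion by bisection (tolerance 1e-8); prior df
  $\to \infty$ when log-variance spread is at the theoretical minimum.
- Cox fits run Newton iterations to tolerance 1e-9 with at most 50
  iterations; fewer than two events, zero score variance, or
  non-convergence raise errors rather than returning garbage.
- GSEA ranking ties break by gene ID (stable radix sort); permutation
  p-values are add-one; a set covering the whole universe or disjoint
  from it is an error, and a constant metric is rejected as degenerate.
- Median splits with all-identical scores are an error (no meaningful
  grouping exists); C/P scoring drops patients missing one of the pair
  with a warning.
- Duplicate probe IDs are collapsed to the highest-mean row at load
  time, keeping the statistics modules free of platform concerns.

## Verification scale

The checks in `tests/testthat/` and `scripts/acceptance.R` use sizes
chosen to make Monte-Carlo bands tight while staying desk-scale: 2000
null genes for the type-I rate, 200 random sets (sizes 10-49, 1000
permutations) for GSEA calibration, 100 simulated cohorts for the null
classifier rate, 50 cohorts of 45 patients for Cox log-HR recovery and
planted-signature log-rank power, and 500 planted edges for consensus
recall against the Binomial(6, recall) $\ge 3$-votes tail. Oracles are
deliberately naive: exhaustive hypergeometric enumeration, hand
running sums, brute-force BH, 1-D partial-likelihood maximization, and
hand 2x2 log-rank tables.

## Known limitations

The published headline counts of the original analyses (DEG totals,
numbers of enriched sets) depend on the specific microarray cohorts
and on gene-set and target-database versions, and are not reproducible
from a generative model; the package instead reproduces the printed
signature tables as fixtures and the method's structural and
statistical properties. The packaged consensus map reproducing the
miRNA substitution tables is synthetic at the edge level (the source
tables print set-level lists only). Real-cohort import is limited to
plain TSV adapters; series-matrix download and probe annotation are
out of scope.
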