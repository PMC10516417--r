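---
title: "Gene-based rare-variant association with Bayes-factor statistics: models and methods"
author: "rvbf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rvbf methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rare variants (RVs; minor allele frequency below 1%) are individually
untestable in realistic case-control cohorts — a site with ten carriers
cannot, by itself, produce genome-wide significant evidence. Gene-based
tests aggregate the RVs of a gene into one statistic, and
discovery-replication designs control the error rate of declaring a gene
associated in two cohorts jointly. `rvbf` implements that full chain:
exome-style quality control, a gene-level Bayes-factor statistic with an
informative prior, Firth-regression single-variant follow-up, and
permutation-calibrated two-stage significance thresholds.

## The gene-level statistic

For a gene with $m$ RVs and dosage block $G$ ($n$ samples $\times\ m$
variants), case-control status $y$ and optional covariates $X$:

$$ T = 2\log BF = 2\log BF_0 - 2\log p_{\mathrm{prior}}, \qquad
   T \overset{H_0}{\sim} \chi^2(3). $$

**Burden component.** $2\log BF_0$ is the likelihood-ratio statistic for
adding the per-sample burden $b_i = \sum_v G_{iv}$ to the null logistic
model (`burdenBF`, backend `"lrt"`). Under $H_0$ it is $\chi^2(1)$. The
Bayes-factor algebra is deliberately isolated behind this backend: a
conjugate beta-binomial marginal-likelihood backend (`"betabinom"`,
Beta(0.5, 0.5) priors on the case and control minor-allele rates, no
covariates) is provided, and an alternative construction can replace either
without touching callers. The binding, testable contract is the printed
one — $T \sim \chi^2(3)$ under the null — and the default construction
($\chi^2(1)$ burden evidence plus an approximately independent prior
contributing $-2\log p \sim \chi^2(2)$) is the simplest one satisfying it.

**KS prior.** The one-sided Kolmogorov–Smirnov statistic
$D^+ = \max_i (i/m - p_{(i)})$ over the gene's single-variant p-values
detects an *excess of small p-values* — a count signal, insensitive to how
extreme any single variant is (an ECDF moves by at most $1/m$ per variant).
Orientation is one-sided by design; `twoSided = TRUE` is available.

**SKAT prior.** The variance-component score statistic
$Q = (y-\hat y)^\top G W G^\top (y-\hat y)$ with
$W = \mathrm{diag}(w_j^2)$, $w_j = \mathrm{Beta}(\widehat{MAF}_j; 1, 25)$
(the field-standard weight; alternative weights can be supplied), whose
null is a weighted mixture of $\chi^2(1)$ variables — a magnitude signal,
strongest when allelic differences are systematic or one variant carries a
large score. The two priors therefore rank architectures differently, and
the test suite asserts exactly that mechanism.

### Why the KS prior needs an exact conditional null

Per-variant p-values of rare variants are *discrete*: a site with $k$ minor
alleles admits only $k+1$ case/control splits. Feeding such p-values to the
continuous Birnbaum–Tingey distribution of $D^+$ produces a non-uniform
prior p-value, and $T$ drifts off $\chi^2(3)$ — the package's own
calibration suite detects this reliably at 2,000 null genes. The default
unadjusted KS path therefore:

1. scores each variant by the **mid-p** of its hypergeometric case-allele
   count (the exact conditional test given the site's minor-allele count,
   with half the observed atom's probability — the standard discreteness
   correction);
2. refers the gene's $D^+$ to a Monte-Carlo sample (size `priorB`, default
   2,000) of its **own conditional null**, generated from the per-site
   allele counts under a fixed internal stream. Allele counts are invariant
   under phenotype permutation, so this null is computed once per gene and
   reused across permutation replicates; the stream seed is derived from
   the counts themselves, so `genomeScan()` and `geneTestFactory()` agree
   bit-for-bit.

The resulting prior p-value is uniform to Monte-Carlo resolution
($\approx 1/priorB$) by construction. Covariate-adjusted scans, scans of
data with missing genotypes, and calls supplying `variantP` use
covariate-adjusted Rao score tests referred to Birnbaum–Tingey (exact for
$m \le 50$, the asymptotic tail $e^{-2md^2}$ beyond); the hypergeometric
null does not condition on covariates, so the exact path is restricted to
the unadjusted case.

Two approximations are knowingly accepted and gated by the calibration
suite: per-variant allele counts are treated as independent across sites
within a gene (exact only in the no-LD regime the generator produces), and
homozygous carriers contribute two exchangeable alleles to the
hypergeometric draw.

### Independence of the components

$2\log BF_0$ and $p_{\mathrm{prior}}$ are computed from the same genotypes
and are only approximately independent. At the default calibration sizes
the acceptance run measures the consequence directly: type-I error at
nominal 0.05 lands slightly above nominal (the `bfks_null_typeI_005` /
`bfskat_null_typeI_005` values in the acceptance output, typically
0.05–0.065), while the goodness-of-fit of $T$ against $\chi^2(3)$ passes.
Orthogonalizing the prior against the burden was evaluated and did not
improve calibration; the dependence is accepted, as the two-stage
permutation calibration (below) is in any case exact by construction.

## SKAT p-values: inversion, fallback, small samples

`chisqMixturePvalue` evaluates $P(\sum_k \lambda_k \chi^2_{1,k} > q)$ by
Imhof characteristic-function inversion with: eigenvalue normalization by
$\lambda_{\max}$ (the integrand's oscillation scale is otherwise missed by
adaptive quadrature — silently, returning $p \approx 0.5$); an exact
$\chi^2(k)$ shortcut when all eigenvalues coincide; a finite truncation
point chosen from an explicit envelope bound on the oscillatory tail; and a
Liu moment-matching fallback (flagged via `attr(, "method")`) when the
integration error plus tail bound exceeds `absTol` ($10^{-6}$).

For a *binary* trait the score residuals take two values, and at small $n$
the exact permutation null of $Q$ deviates from the Gaussian-based mixture
by more than Monte-Carlo error at any practical resampling depth — no
moment-matched chi-square family closes the gap (we verified the analytic
p equals a Gaussian-residual simulation and that mean/variance/skewness
matching to the permutation null still leaves systematic error at
$n = 60$). `skatPvalue` therefore refers cohorts of at most 200 samples to
a high-resolution residual-permutation null (`nullDist = "auto"`;
$B = 200{,}000$, fixed internal stream, deterministic; Freedman–Lane-style
residual permutation when covariates are present). Above that size the
asymptotic inversion is used and the rank-1 identity —
single variant, unit weight $\Rightarrow$ SKAT p equals the score-test
$\chi^2(1)$ p — holds exactly.

## Quality control

Two presets encode the cascades of the two cohort types this pipeline
targets (see `?qcConfig` for the exact thresholds). Fixed choices:

- **Order**: genotype masking first (missing rate and MAF are computed from
  masked data), then site quality → structure (bi-allelic, sex chromosome)
  → singleton carrier quality → HWE in controls → missing rate → MAF, with
  first-failure attribution so the report buckets partition the input.
  Mean GQ uses pre-mask GQ values.
- **Strict inequalities** exactly as the rules are stated; boundary values
  (QUAL = 100, GQ = 30, MAF = 0.01, singleton GQ = 50/DP = 20) survive.
- A genotype with absent GQ/DP fails the mask (conservative).
- Singleton = exactly one minor allele among non-missing genotypes after
  masking; the carrier is the single heterozygote whichever allele is minor.
- HWE: exact conditional test (all heterozygote counts compatible with the
  minor-allele count; p sums probabilities $\le$ the observed
  configuration's). Monomorphic sites give p = 1.
- Sex chromosomes: names in {X, Y, chrX, chrY}.
- Sample QC: missing rate > 10% first, then heterozygosity more than 6 SD
  (n−1 denominator) below the mean of the remaining samples; SD = 0 means
  no outliers.
- Gene regions: annotated spans extended ±1 kb, 1-based inclusive at both
  ends; a variant may belong to several overlapping genes; genes with fewer
  than 20 member RVs (counted after QC) are excluded per cohort.

## Two-stage replication

Thresholds $(\gamma, \lambda)$ on the discovery and replication gene
p-values are calibrated by permutation: for each of $B$ replicates
(default 100) the phenotype of each cohort is permuted — exactly the
printed procedure; this also breaks phenotype-covariate links, which is
faithful to it — and all gene p-values recomputed. The least stringent grid
pair (largest $\gamma$, then largest $\lambda$) whose count of
replicates-with-any-joint-hit is $\le B\alpha$ is returned; with
$B = 100, \alpha = 0.05$ the admissibility cutoff is 5. The
replicates-with-any-hit criterion is the empirical version of
$\Pr(V \ge 1) \le \alpha$; a total-hits variant is available
(`criterion = "total"`). The default grid
$\gamma \in \{10^{-3}, 5\times10^{-4}, 10^{-4}, 5\times10^{-5}\}$,
$\lambda \in \{0.05, 0.01\}$ spans the conventional operating range.
$\lambda$ applies to the replication cohort's gene p-value, not its prior
p-value. Fisher's method combines the two cohorts' p-values through
$\chi^2(4)$; replication-cohort MAFs are recomputed in that cohort rather
than carried over from discovery.

## The synthetic cohort generator

`simulateCohort` draws a super-population, assigns disease by
$\mathrm{logit}\,P = \beta_0 + \sum_v \beta_v G_v + \gamma'X$, and samples
cases and controls retrospectively — failing loudly, naming the population
cap, if the requested case count is unattainable. Defaults:

- **MAF spectrum**: a four-component mixture with weights 10.12% / 75.79% /
  4.47% / 9.62% over monomorphic, (0, 0.01), [0.01, 0.05) and [0.05, 0.5)
  population MAF, log-uniform within each bin — the rare-dominated make-up
  of an exome call set. `rareSpectrum()` gives the polymorphic-rare-only
  spectrum used by the calibration studies.
- **Covariates**: age $\mathcal N(60, 10)$ (effect 0.02 per year,
  centered), sex Bernoulli(0.5) (log-OR 0.2), three-level smoking
  (never/former/current 45/35/20%, log-ORs 0/1.0/1.6 — deliberately strong
  so adjusted and unadjusted analyses differ measurably, mirroring the
  heavy smoking imbalance of lung-cancer cohorts), five standard-normal
  PCs with zero default effects. Baseline intercept −3 (≈ 8% prevalence
  for a never-smoking female of mean age).
- **Quality fields**: QUAL = 100 + Gamma(2, scale 200), GQ = 50 +
  min(Poisson(20), 49), DP = 20 + Poisson(30) — chosen so that with zero
  corruption no site- or genotype-level rule of either preset fires and the
  simulated Ts/Tv is ≈ 2 (transitions drawn with probability 2/3).
  Corruption rates engineer violations (site QUAL below the preset floor,
  site-wide GQ below the mean-GQ threshold, genotype GQ below the mask) and
  are recorded in a ledger so QC attribution is testable.
- **Reproducibility**: one master seed fans out to named substreams
  (layout, spectrum, covariates, phenotype, genotypes, quality), so
  identical configs are byte-identical and stages can be varied
  independently.

What it does **not** emulate: linkage disequilibrium between sites, family
structure or kinship, the family-history/early-onset enrichment of real
discovery cohorts (no quantitative model is available for it), sequencing
reads, or population stratification beyond the supplied PC effects.
Passing calibration on these cohorts therefore demonstrates correctness of
the statistical machinery under independence and HWE, not robustness to LD
or relatedness.

## Study sizes used by the test and acceptance runs

Null calibration of both gene statistics uses 2,000 genes of 25 RVs in
cohorts of 1,000 cases + 1,000 controls, with population MAFs log-uniform
on [0.002, 0.01) — rare by definition yet with enough expected carriers
(8–40 minor alleles) that per-variant statistics are in the asymptotic
regime the $\chi^2(3)$ claim addresses. FWER validation calibrates on a
200-gene pair of 500 + 500 cohorts with $B = 100$ permutations and
re-evaluates the returned pair on 500 fresh permutation replicates. The
Firth solver is checked against derivative-free maximization on 100 random
small designs and against the 0.5-cell-correction identity on a saturated
2×2 at replication-cohort scale; the HWE test against full enumeration for
all configurations of up to 30 individuals; the SKAT engine against
$\chi^2(k)$ closed forms and a 20,000-permutation oracle at $n = 60$.

## Firth regression details

Damped Newton iterations on the Jeffreys-penalized likelihood (modified
score $U^*_j = \sum_i (y_i - \mu_i + h_i(1/2 - \mu_i)) x_{ij}$), maximum 50
iterations, step-halving on the penalized likelihood, convergence at
gradient norm $10^{-8}$. P-values are penalized likelihood-ratio tests (the
reduced fit fixes one coefficient at zero and re-maximizes the rest under
the full design's penalty); confidence intervals are profile penalized
likelihood by default, with a flagged Wald fallback when profiling fails.
Rank-deficient designs fail naming the collinear columns. Missing dosages
are mean-imputed ($2\widehat{MAF}$) to keep $n$ constant. Benjamini–
Hochberg q-values gate selection at $q \le 0.01$; BH is the deterministic
default, with a Storey-style smoother $\pi_0$ option — reference-method
ambiguity resolved in favor of determinism.

## Known limitations

- The gene statistic's type-I error runs ≈ 0.5–1.5 points above nominal at
  $\alpha = 0.05$ under the default calibration sizes (burden/prior
  dependence); the two-stage permutation calibration is unaffected, being
  exact by construction.
- The exact KS prior has resolution $1/priorB$; single-cohort gene
  p-values below ≈ $10^{-7}$ require raising `priorB` (the burden
  component is unaffected).
- Frequency-based QC removes strongly enriched causal variants whose
  *sample* MAF crosses 1% — visible in the README example family; this
  mirrors what the same filters do on real data.
- With a single large-effect variant the SKAT prior dominates the KS prior;
  the KS prior's advantage is specific to an excess of moderately small
  p-values.
- The replication-cohort scale of real studies (hundreds of thousands of
  samples) is emulated only in the arithmetic checks, not the simulations.
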