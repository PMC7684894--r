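---
title: "Mixed logistic regression for binary-trait GWAS: models, estimators and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed logistic regression for binary-trait GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlrgwas)
```

## The problem

Case-control GWAS cohorts are rarely homogeneous: allele frequencies drift
across population strata, relatives hide in the sample, and the disease
prevalence itself can differ between strata (different environments,
lifestyles, ascertainment sites). The standard fix for quantitative traits
— a linear mixed model (MLM) with a genomic relationship matrix (GRM) — is
tempting for 0/1 status too, but it models a binary outcome with a
homoscedastic Gaussian error. When prevalence differs between strata, the
Bernoulli variance $p(1-p)$ differs too, and the MLM mis-calibrates:
variants whose genotype variance is larger in the high-prevalence stratum
get inflated statistics, variants with the opposite pattern get deflated
ones, while the genome-wide average looks perfectly fine. The right model
is the **mixed logistic regression** (MLR)

$$\mathrm{logit}\,P(Y_i = 1) = X_i\beta + G_i\gamma + \omega_i,\qquad
\omega \sim MVN(0, \tau K),$$

with $X$ the covariates (intercept, top genotype PCs, ...), $G$ the dosage
of the tested variant, and $K$ the GRM (or twice the pedigree kinship
matrix, $K = 2\Phi$). Fitting this model per SNP is far too slow for
millions of variants; this package implements the strategy of fitting the
null MLR ($\gamma = 0$) **once** and then confronting every variant with
the null-model residuals, which yields per-SNP effect *estimates* and not
only p-values.

## The null fit: PQL with AI-REML updates

`fit_pql_null()` fits the null model by penalized quasi-likelihood: the MLR
is approximated by a sequence of working linear mixed models for
$z = \eta + W^{-1}(y - \mu)$ with weights $W = \mathrm{diag}(\mu(1-\mu))$.
Each outer iteration performs a GLS update of $(\beta, \omega)$ under
$\Sigma = \tau K + W^{-1}$ and one average-information REML step for
$\tau$. Numerical choices:

* convergence when $\max(|\Delta\beta|, |\Delta\tau|) < 10^{-6}$, at most
  200 outer iterations; non-convergence and separation-driven divergence
  raise errors (class `mlrgwas_convergence_error`) rather than returning a
  silent result;
* $\tau$ constrained to $[0, 50]$; initialization from a plain logistic
  fit with $\tau = 0.1$, $\omega = 0$ (a previous fit can be supplied via
  `init =` to warm-start replicate loops);
* fitted probabilities clipped to $[10^{-8}, 1-10^{-8}]$ before forming
  $W$, so the working covariance stays invertible;
* $\Sigma^{-1}$ always via Cholesky (`chol`/`chol2inv`), never via an
  explicit inverse of $W$; the AI-REML trace $\mathrm{tr}(PK)$ is obtained
  from the identity $\mathrm{tr}(P\Sigma) = n - p$, which costs $O(n^2)$
  given $\Sigma^{-1}$.

The fit stores everything the per-SNP tests need: $\hat\mu_0$,
$\hat\eta_0 = X\hat\beta_0 + \hat\omega_0$, $\Sigma$, and the projection
$P = \Sigma^{-1} - \Sigma^{-1}X(X'\Sigma^{-1}X)^{-1}X'\Sigma^{-1}$, kept
dense — the package targets cohorts up to roughly $10^4$ individuals,
where an $n \times n$ matrix is perfectly manageable and the $O(n^3)$
initial fit, not memory, is the limiting factor.

## Per-SNP estimators

**AMLE** (`amle_test`). A second-order expansion of the working
log-likelihood around $\gamma = 0$, with the nuisance parameters frozen at
the null fit, maximizes at $\hat\gamma = -\ell'(0)/\ell''(0)$. In the
working LMM this is

$$U = G'(y - \hat\mu_0), \qquad v = G'PG, \qquad \hat\gamma = U/v,\qquad
se = v^{-1/2},$$

and the Wald statistic $\hat\gamma^2/se^2 = U^2/v$ **is** the mixed-model
score statistic: the test is numerically identical to the score test used
by GMMAT, while additionally providing an effect estimate. Cost: one
$n \times n$ mat-vec per SNP, $O(n^2)$.

**Offset** (`offset_test`). Two steps: residualize the dosages on the
covariates, $\tilde G = G - X\hat\delta$ (ordinary least squares), then
fit the one-parameter logistic regression
$\mathrm{logit}\,E(Y) = \hat\eta_0 + \tilde G\gamma$ by IRLS with
$\hat\eta_0$ held constant as an offset. Each iteration is $O(n)$. Two
design details deserve a note. First, the final regression uses the
*residualized* $\tilde G$: this is what makes the linear-model analogue of
the procedure collapse exactly onto the multiple-regression OLS
coefficient (Frisch–Waugh–Lovell; `offset_linear_coef()` exposes the
identity, and the test suite asserts it to $10^{-10}$). Second, the offset
regression has no free intercept — the offset already contains
$X\hat\beta_0$.

**Baselines.** `lr_test` (plain logistic regression), `mlm_score_test`
(score test in the REML-fitted LMM, the deliberately misspecified
comparator; its effect estimate is on the probability scale and flagged as
such). `fit_pql_snp` refits the whole MLR per SNP — the slow, essentially
unbiased reference used in the bias experiments.

`gwas_scan()` drives any of these over a genotype matrix; per-variant
failures become `NA` rows with a status message, never a crash, and no
$O(n^3)$ work happens inside the loop.

## Stratified QQ diagnostics

A pooled QQ-plot cannot reveal the MLM pathology because inflation in one
group of SNPs compensates deflation in another. `snp_categories()`
implements the variance-ratio categorization: with a stratifying variable
$Z \in [0,1]^n$,

$$q_1 = \frac{Z'G}{2\,Z'\mathbf 1},\quad
q_0 = \frac{(\mathbf 1 - Z)'G}{2\,(\mathbf 1 - Z)'\mathbf 1},\quad
r = \frac{2q_1(1-q_1)}{2q_0(1-q_0)},$$

and categories $1$ ($r < th$), $2$ ($th \le r \le 1/th$, boundaries
inclusive) and $3$ ($r > 1/th$), default $th = 0.8$. With a binary $Z$ the
$q_i$ are exactly the within-stratum allele frequencies; with strata
unknown, a top PC min-max rescaled to $[0,1]$ (`pc_strata`) serves as a
continuous proxy. SNPs monomorphic in stratum 0 but not in stratum 1 are
assigned category 3 (the "more variance in the high-risk stratum" side);
SNPs with zero variance in both strata are left unassigned. The
categorization is equivariant: relabeling the strata maps $r \mapsto 1/r$
and swaps categories 1 and 3.

`stratified_qq()` returns the plot-ready table (observed vs expected
$-\log_{10} p$ per category plus pooled) and `genomic_inflation()` the
median-based $\lambda$; the figure itself is rendered separately by
`plot_stratified_qq()` so everything computes headless. The $\lambda$
estimator divides the median of the $\chi^2(1)$-equivalents of the
p-values by the null median $0.4549$ — the field-standard genomic-control
choice.

## The synthetic cohort generator

The experiments need cohorts with (i) smooth spatial allele-frequency
structure, (ii) cryptic first-degree relatedness, and (iii) a two-strata
binary phenotype with heterogeneous prevalence. The generator mirrors a
stepping-stone design on a grid of demes:

* **Founder genotypes** (`simulate_grid_genotypes`): each SNP draws an
  ancestral frequency from $U(0.05, 0.95)$ and per-deme frequencies
  deviate on the logit scale by a unit-variance spatial field — a random
  large-scale gradient across the grid plus independent per-deme noise,
  mixed half-and-half — scaled by `structure_param`. The default (0.3) was
  calibrated once so that splitting the default $20 \times 20$ grid into
  two halves gives Hudson $F_{ST} \approx 0.007 < 0.01$, the
  within-Europe-like differentiation level the simulations target. The
  generator is seeded and bit-reproducible.
* **Relatives** (`gene_drop`): disjoint founder couples per deme, each
  offspring allele drawn uniformly from the parent's two alleles per SNP;
  the pedigree kinship $\Phi$ is computed exactly (founders unrelated and
  non-inbred, so $K = 2\Phi$ has 1 on the diagonal, 0.5 for parent-
  offspring and full-sib pairs), and the cohort is a uniform sample of
  founders plus offspring.
* **Phenotype** (`simulate_phenotype`):
  $\mathrm{logit}(p_i) = a_0 + a_1 Z_i + \gamma \tilde G_i + \omega_i$
  with $a_0 = \mathrm{logit}(p_0)$, $a_1 = \mathrm{logit}(p_1) -
  \mathrm{logit}(p_0)$, $\omega \sim MVN(0, \tau K)$ drawn through a
  symmetric eigen-factorization with eigenvalues floored at zero (pedigree
  $K$ is numerically semi-definite), and the causal dosage centered so
  the prescribed prevalences are preserved. The high-risk stratum
  ($Z = 1$) is the top-left quarter of the grid.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
independent), coalescent allele-frequency spectra, mutation/recombination
processes, multi-generation pedigrees, and genotyping error. Passing tests
therefore demonstrate the estimators' behavior under spatial structure,
heterogeneous prevalence and first-degree relatedness — not under LD or
rare-variant architectures.

## Experiment harnesses and the scales used

Three harnesses wrap the full designs; every one is deterministic given
`seed` and reports Monte-Carlo standard errors.

* `run_type1_experiment`: null phenotypes on a structured cohort, scans
  with each method, rejection rates tabulated per SNP category. The
  phenotype random effect uses the pedigree $K = 2\Phi$ while the
  analyses use a GRM (and 10 PCs) estimated from a few thousand random
  SNPs — the deliberate model/analysis mismatch of a real GWAS.
* `run_power_experiment`: causal SNP redrawn per replicate from a MAF
  bin; power at a chosen $\alpha$.
* `run_bias_experiment`: scenarios A ($p_0=0.10, p_1=0.20, \tau=0.3$),
  B ($p_0=0.10, p_1=0.20, \tau=1$) and C ($p_0=0.05, p_1=0.30, \tau=0.3$)
  crossed with MAF bins $(0.05,0.10]$, $(0.20,0.25]$, $(0.45,0.50]$;
  mean of $\hat\gamma - \gamma$ per method. Here phenotype and analysis
  share the GRM computed from all cohort SNPs, mirroring a single-panel
  design. The causal genotype is redrawn each replicate together with the
  random effects, so the reported bias averages over SNPs in the bin
  rather than conditioning on one arbitrary variant.

The default problem sizes are desk-scale choices: cohorts of 800–1000
individuals sampled from a $10\times10$ grid with gene-dropped offspring,
8000 SNPs for the bias experiments (enough that the causal SNP's own
contribution to the GRM is negligible — with only a couple of thousand
SNPs the random-effect BLUP visibly absorbs part of the causal effect and
manufactures spurious downward bias), 4000 GRM SNPs and 2000 test SNPs
for the type-I experiment, and 100 replicates per condition. The power
comparison defaults to a reduced smoke configuration ($n = 1000$, 100
replicates, $\alpha = 10^{-3}$ so the comparison is informative at this
sample size) that checks the AMLE $\ge$ Offset ordering; the full-scale
table ($n = 5000$, 1000 replicates, $\alpha = 5\times10^{-8}$) runs
behind the `--full-power` flag of `scripts/acceptance.R`.

## Other design decisions

* `filter_maf` keeps the boundary (variants with MAF exactly at the
  threshold are retained).
* Missing dosages are mean-imputed per variant before GRM computation,
  PCA and association testing.
* GRM allele frequencies come from the full sample, not per stratum, and
  PCs are the unit-norm eigenvectors of the GRM, computed from the same
  (MAF-filtered) panel as the GRM itself.
* Two-sided p-values from $\chi^2(1)$ throughout; the scan applies no
  multiple-testing correction — the genome-wide threshold is a reporting
  convention left to the caller.
* VCF positions are 1-based per the standard; PLINK A1 is the counted
  (alt) allele.

## Limitations

The PQL's $O(n^3)$ initial fit caps practical cohort sizes around $10^4$;
biobank-scale workarounds are out of scope. The estimators are not suited
to rare variants in highly unbalanced case-control designs (no
saddle-point correction is implemented). The AMLE effect estimate is a
small-effect approximation: for odds ratios around 2 it acquires a
moderate downward bias (the bias experiments quantify it), while the full
PQL refit remains essentially unbiased at the cost of a full fit per SNP.
The Offset method is sensitive to strong familial structure: on
grid/pedigree cohorts with many first-degree relatives it is both more
conservative and more downward-biased than the AMLE, so its advertised
O(n) speed comes with a robustness caveat on heavily related samples.
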