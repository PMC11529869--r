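---
title: "Sketched linear mixed models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketched linear mixed models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Genome-wide association with a linear mixed model (LMM) starts from

$$ y = X\beta + Zu + e, $$

where $y \in \mathbb{R}^n$ is the phenotype, $X \in \mathbb{R}^{n\times k}$
holds covariates (intercept, principal components, age, sex, ...) with fixed
effects $\beta$, $Z \in \mathbb{R}^{n\times m}$ is the normalized genotype
matrix of $n$ individuals at $m$ markers, $u$ the vector of random marker
effects and $e$ the residual. With $u$ and $e$ independent Gaussians with
variances $\sigma_g^2$ and $\sigma_e^2$, the phenotypic covariance is
$\sigma_g^2 H_\tau$ with

$$ H_\tau = \tfrac{1}{m} K + \tau I, \qquad
   K = Z Z^\top, \qquad \tau = \sigma_e^2 / \sigma_g^2, $$

so the narrow-sense heritability is $h^2 = \sigma_g^2 / (\sigma_g^2 +
\sigma_e^2) = 1/(1+\tau)$. The genetic relationship matrix (GRM) $K$ is the
expensive object: $O(n^2 m)$ to build and $O(n^3)$ to decompose.

## Sketching

This package reduces both dimensions of $Z$ with seeded Gaussian random
projections before any LMM algebra happens. A *sample sketch*
$S_1 \in \mathbb{R}^{s_1\times n}$ and a *marker sketch*
$S_2 \in \mathbb{R}^{m\times s_2}$ have i.i.d. entries with mean zero and
variance $1/s_1$ and $1/s_2$ respectively, which makes
$\mathbb{E}[S_1^\top S_1] = I_n$ and $\mathbb{E}[S_2 S_2^\top] = I_m$:
sketched inner products are unbiased for the original ones, with noise that
shrinks as the sketch dimensions grow. The pipeline computes

* $Z_{s_1} = S_1 Z$ and $y_{s_1} = S_1 y$ (sample-sketched genotypes and
  response),
* $B = S_1 Z S_2$ and $K = B B^\top \in \mathbb{R}^{s_1\times s_1}$ (the
  sketched GRM, symmetric PSD by construction),

all in streaming marker blocks, so the $n \times m$ matrix never resides in
memory. Every entry of a sketch operator is a deterministic function of
(seed, global row/column index, orientation): each sample column of $S_1$
and marker row of $S_2$ owns its own RNG substream. Block size and request
order therefore cannot change any result — a property the test suite
asserts exactly.

Default sketch dimensions are $s_1 = \lceil 0.1\,n \rceil$ and
$s_2 = \lceil 0.5\,m \rceil$: small enough for a large speedup, large
enough that the sketch is not dominated by projection noise. Both are
user-controlled (fractions, absolute sizes, or the string `"identity"`).
The `identity` kind ($s = d$, operator $= I$) is a documented test mode
that turns sketching off so the whole pipeline can be compared against
exact dense computations; it is also what "sketch fraction 1.0" means in
the trade-off experiments, whose endpoint is *no sketching*.

## Covariates in sketched space

After sketching, the model lives in $s_1$ dimensions, so covariates must
too. `build_covariates()` assembles
$X = [\,S_1 \mathbf{1} \mid \mathrm{PCs} \mid S_1 C\,]$: the intercept and
any user covariates $C$ are pushed through the *same* $S_1$ (the unsketched
intercept maps exactly to the column $S_1\mathbf{1}$ under left
multiplication), while the principal components are computed directly from
the column-centered $Z_{s_1}$ — scores are the top left singular vectors
scaled by their singular values, with signs fixed deterministically.
Column centering is needed because per-marker normalization centers
original samples, not sketched rows. Default: 10 PCs.

## Variance components

One symmetric eigendecomposition $K = U \Lambda U^\top$ makes
$H_\tau = U(\Lambda/m + \tau I)U^\top$ diagonal in the rotated basis for
*every* $\tau$, so each likelihood evaluation is $O(s_1 k^2)$ after an
$O(s_1^3)$ setup. With $d_i = \lambda_i/m + \tau$,
$\tilde y = U^\top y_{s_1}$, $\tilde X = U^\top X$:

* GLS fixed effects
  $\hat\beta = (\tilde X^\top D^{-1}\tilde X)^{-1}\tilde X^\top D^{-1}\tilde y$,
* profiled genetic variance $\hat\sigma_g^2 = r^\top D^{-1} r / \nu$ with
  $r = \tilde y - \tilde X\hat\beta$, $\nu = s_1$ (ML) or $s_1 - k$ (REML),
* profile log-likelihood
  $\ell(\tau) = -\tfrac12\left[\nu \log(2\pi\hat\sigma_g^2) + \sum_i \log d_i
  + \nu\right]$, with REML adding
  $-\tfrac12 \log\det(\tilde X^\top D^{-1}\tilde X)$.

Optimization runs in $\theta = \log\tau$, which enforces $\tau > 0$ without
constraints. First and second derivatives in $\theta$ are analytic sums
over the eigenvalues (the envelope theorem handles $\hat\beta$'s dependence
for the gradient; the Hessian carries the extra
$\partial\hat\beta/\partial\theta$ term explicitly), and both are verified
against central finite differences in the tests. Newton steps are halved
until the likelihood does not decrease, $\theta$ is boxed in
$[\log 10^{-8}, \log 10^{8}]$, and convergence requires the step or
gradient below `tol` ($10^{-6}$ by default, at most 100 iterations,
initial guess $\tau_0 = 1$, i.e. $h^2 = 0.5$). If Newton fails, a
golden-section search over $\theta \in [\log 10^{-6}, \log 10^{6}]$
supplies the estimate and the fit is flagged unconverged. Degenerate
spectra are handled: with $K = 0$ the profile collapses to the ordinary
least-squares Gaussian likelihood and is constant in $\theta$ (asserted in
the tests), and tiny negative eigenvalues from floating point are clipped
at zero with a logged count.

**Why REML is the default.** The restricted likelihood divides the
residual quadratic form by $s_1 - k$ rather than $s_1$. After sketching,
$s_1$ is deliberately small (often ~100) while $k$ is 11 with the default
10 PCs plus intercept, so the ML variance estimate is biased low by the
factor $(s_1-k)/s_1 \approx 0.89$; that bias propagates directly into the
score statistics, inflating them by $s_1/(s_1-k)$ and pushing the null
type-I error at $\alpha = 0.05$ to roughly 0.065. REML removes this
degrees-of-freedom loss, keeps the genomic inflation factor near 1 at the
default sketch dimensions, and is the convention of standard
variance-component software. ML remains available via `mode = "ML"` and is
tested with the same rigor.

## The association statistic

For each retained marker column $z$ of $Z_{s_1}$, with
$V = \hat\sigma_g^2 H_{\hat\tau}$,

$$ \chi^2 = \frac{(\tilde z^\top V^{-1} \tilde y)^2}
                 {\tilde z^\top V^{-1} \tilde z}, $$

where $\tilde y$ and $\tilde z$ are the residuals of $y_{s_1}$ and $z$
after GLS projection on $X$ under the $V^{-1}$ inner product. Residualizing
both vectors is the standard generalized-least-squares score test; it
reduces to the bare ratio when $X$ is empty, and makes the statistic exactly
invariant to rescaling of the response. $V^{-1}$ is applied through the
stored spectrum, never formed. P-values are upper-tail $\chi^2_1$; markers
with residual norm below $10^{-12}$ are flagged and reported with
$\chi^2 = 0$, $p = 1$. No multiple-testing correction or significance
filter is applied — the conventional genome-wide thresholds
($5\times10^{-8}$ for real data, and $10^{-12}$ is sometimes used in large
simulation studies) are reporting conventions left to the user. Leave-one-
chromosome-out (LOCO) is deliberately not implemented; the candidate
marker's contribution to the sketched GRM (proximal contamination) is
accepted, which mainly costs a little power at heavily sketched GRMs.

## Genotype input and normalization

PLINK 1 binary filesets are read and written directly (SNP-major BED with
magic bytes `6C 1B 01`; two-bit codes counting A1 copies, `01` = missing;
individual-major files are rejected). Markers stream in blocks; per-marker
allele frequencies $p_j$ are computed once (on the analysis samples, i.e.
after dropping missing phenotypes) and cached. Normalization imputes
missing calls to $2p_j$, centers by $2p_j$ and scales by
$\sqrt{2p_j(1-p_j)}$ — the binomial unit-variance convention that makes
$\mathrm{diag}(ZZ^\top/m) \approx 1$. Markers with minor allele frequency
below `maf_min` (default 0.01) or zero variance are dropped before
sketching; a zero-variance marker has no defined $\chi^2$. Phenotypes and
covariates are whitespace-delimited, FID/IID-keyed; `-9` and `NA` are
missing; the phenotype is centered and scaled to unit variance over the
analysis samples.

## The simulator

The simulator provides the study conditions for every end-to-end test, so
its defaults are fixed, not tuning knobs:

* **Founders** (default 100): synthetic, two populations split evenly,
  Balding–Nichols allele frequencies around ancestral
  $p \sim U(0.05, 0.5)$ at a target $F_{ST}$ (default 0.01; the
  construction degenerates to identical populations at 0). Founder dosages
  are $\mathrm{Binomial}(2, p_{\mathrm{pop}})$. The founders stand in for
  the genetically distinct real-biobank individuals such schemes start
  from, which cannot ship with a package.
* **Mosaic individuals**: the marker axis is cut into consecutive segments
  of 2000 variants (the last may be shorter) and each individual copies
  every segment's dosages from a founder of its own population — chosen
  uniformly for unrelated individuals, and from a sibship-shared ancestor
  subset (size `ancestors_per_related`, sibships of `sibship_size` = 2)
  for related ones; fewer ancestors means closer relatedness. A ledger
  records every (individual, segment) source so the mosaic replays
  exactly. Copying operates on dosages, not haplotypes.
* **Traits** (GCTA-style): `n_causal` markers (default 25) drawn uniformly
  among polymorphic markers, effects $u_c \sim N(0,1)$ on binomially
  normalized dosages, noise variance set to
  $\mathrm{var}(g)(1-h^2)/h^2$ so the realized heritability is centred on
  the target (default 0.5). Binary traits threshold the liability at its
  empirical $(1-\mathrm{prevalence})$ quantile, giving exactly
  $\lfloor \mathrm{prevalence}\cdot n\rfloor$ cases.

What the simulator does *not* emulate: linkage disequilibrium beyond
founder sharing (founder genotypes are independent across loci),
recombination maps, allele-frequency spectra with rare variants,
genotyping error, or imputation dosages. Tests passing on these data show
the *algebra and inference machinery* are correct and calibrated under
population structure and relatedness; they do not certify behavior on the
LD structure of real genotypes.

## Problem sizes used by the test suite

Chosen as the package's own desk-scale study conditions:

* heritability recovery: 20 replicates of $n=500$, $m=5000$, 25 causal,
  $h^2=0.5$, identity sample sketch, 50% marker sketch;
* brute-force equivalence: $n=100$, $m=300$ with identity sketches against
  explicit dense $V$;
* null calibration: one $n=1000$, $m=5000$ pure-noise trait at default
  sketches (genomic inflation within [0.85, 1.15]; type-I error at 5%
  within its 99% binomial interval);
* sketch-fraction trade-off: $n=2000$, $m=3000$ (two full 2000-marker
  segments plus a short one, exercising the boundary case), 10 seeds,
  sample-sketch fractions 0.1 / 0.5 / 1.0.

## Known limitations

Binary phenotypes are analyzed as 0/1 quantitative traits (no logistic or
saddlepoint correction); hard-call genotypes only (no VCF/BGEN/PGEN, no
imputation dosages); no LOCO; a single random effect; Gaussian sketches
only (no subsampled randomized Hadamard or count-min constructions). The
sketched model treats $y_{s_1}$ as Gaussian even for binary input — at the
default sketch dimensions the projection makes this a good approximation,
but heavily unbalanced case-control data at small $s_1$ will behave like
any linear-model GWAS on rare traits.
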