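---
title: "Reduced-dimension genomic prediction: models, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-dimension genomic prediction: models, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdgp)
```

## The problem

Genomic prediction estimates the additive genetic merit (breeding value) of
individuals from dense SNP genotypes. Two model families dominate: marker
effect models (SNP-BLUP), whose equation system has the dimension of the
number of loci $k$, and genomic animal models (GBLUP), whose system has the
dimension of the number of genotyped individuals $N$ and whose single-step
variants need the *inverse* of the genomic relationship matrix (GRM).
Both directions are eventually crushed by scale: $k$ can reach full-sequence
density, and $N$ grows into the millions in livestock programs, making a
dense $N \times N$ inversion (cubic work, quadratic memory) impossible.

The way out exploited here is that in populations of limited effective size
$N_e$, genomic variation is carried by a limited number of segregating
haplotype segments — roughly $M_e = 2 N_e L / \ln(2 N_e)$ effective loci for
a genome of $L$ Morgans (`effective_loci()`). A singular value decomposition
(SVD) of the genotype matrix therefore concentrates nearly all genomic
variance in a number of principal components (PC) far below both $N$ and
$k$, and everything downstream can be done on the scores.

## Models

Let $\mathbf{X}$ be the $N \times k$ column-centered dosage matrix
(entries $g_{ij} - 2p_j$), $\mathbf{y}$ phenotypes, and
$\sigma^2_g, \sigma^2_e$ the additive and residual variances.

**SNP-BLUP** (`solve_snp_blup()`): $\mathbf{y} = \mathbf{Xb} + \mathbf{e}$
with $\mathbf{b} \sim N(0, \mathbf{I}\sigma^2_m)$,
$\sigma^2_m = \sigma^2_g / \rho$, $\rho = 2\sum_j p_j(1-p_j)$; solved from
$[\mathbf{X'X} + \lambda\mathbf{I}]\hat{\mathbf{b}} = \mathbf{X'y}$ with
$\lambda = \sigma^2_e/\sigma^2_m$.

**GBLUP** (`solve_gblup()`): $\mathbf{y} = \mathbf{g} + \mathbf{e}$,
$\mathbf{g} \sim N(0, \mathbf{G}\sigma^2_g)$ with
$\mathbf{G} = \mathbf{XX'}/\rho$ (VanRaden Method 1, `build_grm()`).
Because $\mathbf{G}$ is typically rank-deficient, a regularized
$\tilde{\mathbf{G}} = \mathbf{G} + \mathbf{I}\theta$ (default
$\theta = 10^{-3}$) is used whenever an inverse is required
($[\mathbf{I} + \lambda_g\tilde{\mathbf{G}}^{-1}]\hat{\mathbf{g}} =
\mathbf{y}$); the inverse-free form
$[\mathbf{G} + \lambda_g\mathbf{I}]\hat{\mathbf{g}} = \mathbf{Gy}$ is also
provided and the two agree up to $O(\theta)$.

**PCRR** (`solve_pcrr()`): writing $\mathbf{X} = \mathbf{USV'}$
(`economy_svd()`), the reparameterization $\mathbf{s} = \mathbf{V'b}$ turns
SNP-BLUP into a ridge regression on the scores $\mathbf{T} = \mathbf{US}$
with a *diagonal* system $[\mathbf{S}^2 + \lambda\mathbf{I}]\hat{\mathbf{s}}
= \mathbf{T'y}$. SNP effects are recovered as
$\hat{\mathbf{b}} = \mathbf{V}\hat{\mathbf{s}}$
(`back_transform_snp_effects()`), which satisfies
$\hat{\mathbf{b}} = \mathbf{VV'}\hat{\mathbf{b}}$ even though
$\mathbf{VV'} \ne \mathbf{I}$.

## Core-sample and chromosome-wise reduction

For large $N$ the SVD itself is the bottleneck, so it is performed on a
*core sample* of $n$ individuals (`core_svd()`), optionally independently
per chromosome. The core's right singular vectors $\mathbf{V}_{nq}$ (the
$q$ leading components per block, chosen so the core variance explained
reaches a threshold, default 99%) approximate the population's, and the
whole population is projected to reduced scores
$\mathbf{C} = \mathbf{XV}_{nq}$ (`project_scores()`; chromosome blocks are
concatenated). $\mathbf{C'C}$ is not diagonal, so either the dense
$\sum q_i \times \sum q_i$ ridge system is solved directly, or a
second-stage SVD $\mathbf{C} = \mathbf{U_C S_C V_C'}$
(`two_stage_svd()`) yields diagonalized scores
$\hat{\mathbf{T}} = \mathbf{U_C S_C}$ with
$\hat{\mathbf{T}}'\hat{\mathbf{T}} = \mathbf{S_C^2}$ and identical fits
($\mathbf{CC'} = \hat{\mathbf{T}}\hat{\mathbf{T}}'$ exactly).

A key structural point: chromosome-wise SVD can retain *more* components in
total than there are core animals ($\sum q_i \le n \times c$), because it
models the segregating haplotype blocks rather than the core animals'
breeding values. This is what makes the chromosome-wise variants robust to
small cores, and it is asserted as a property in the test suite.

## Exact inverses of approximated GRMs

With $\mathbf{G} \approx \mathbf{CC'}/\rho$ the regularized matrix
$\tilde{\mathbf{G}} = (\mathbf{CC'} + \mathbf{I}\rho\theta)/\rho$ has the
exact Woodbury inverse

$$\tilde{\mathbf{G}}^{-1} = \tfrac{1}{\theta}\left(\mathbf{I} -
\mathbf{C}(\mathbf{C'C} + \mathbf{I}\rho\theta)^{-1}\mathbf{C'}\right),$$

in which only a $\sum q_i$-dimensional system is ever factored — diagonal
($\mathbf{S_C^2} + \mathbf{I}\rho\theta$) when two-stage scores are used
(`pcig_inverse()`). The inverse is exact for the approximated matrix: all
approximation error lives in the score basis. Rows can be materialized
independently (`inverse_row()`, `export_inverse()`), which suits
iteration-on-data solvers that never store the full inverse. The same
tall-factor form covers: the marker-side inverse with
$\mathbf{A} = \mathbf{X}$ when $k < N$ (`woodbury_inverse_markers()`); the
QR variant with $\mathbf{A} = \hat{\mathbf{R}}'$ from
$\mathbf{X}_n' = \mathbf{Q}_n\mathbf{R}_n$,
$\hat{\mathbf{R}}_{-n}' = \mathbf{X}_{-n}\mathbf{Q}_n$ (`qrig_inverse()`,
with a second-stage QR combining per-chromosome factors); and the weighted
GRM $\mathbf{G} = \mathbf{XDX'}/\rho$ with inner matrix
$\mathbf{C'C} + \mathbf{F}_n^{-1}\rho\theta$,
$\mathbf{F}_n = \mathbf{V}_{nq}'\mathbf{DV}_{nq}$
(`weighted_pcig_inverse()`).

`apy_inverse()` implements the standard algorithm-for-proven-and-young
baseline (non-core block of the inverse assumed diagonal, conditional
variances floored at $\theta$). Unlike the operators above it is an
*approximate* inverse whenever non-core animals exist; it is included as
the comparison baseline, not as a contribution of this package.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `theta` | 1e-3 | diagonal added to the GRM; guarantees positive definiteness; solutions differ from unregularized ones by $O(\theta)$ |
| `threshold` | 0.99 | per-block fraction of core variance retained (cumulative squared singular values, non-strict comparison; boundary ties kept) |
| `lambda` | $\sigma^2_e/\sigma^2_m$ | ridge ratio of the marker-scale models |
| `lambda_g` | $\sigma^2_e/\sigma^2_g$ | ridge ratio of the animal-scale models |
| `validation_fraction` | 0.10 | per-animal masking probability among non-core animals |

Variance components are *inputs* (as in routine evaluations); REML
estimation is out of scope. `variance_components()` derives any of
$\{\sigma^2_g, \sigma^2_e, h^2\}$ from the other two and
$\sigma^2_m = \sigma^2_g/\rho$ when a scaling constant is available.

## Numerical choices

* **Rank cutoff.** "Components with nonzero singular values" is implemented
  as $S_i > \max(N,k)\,\varepsilon\,S_1$ (the standard numerical-rank
  rule); no source gives an explicit cutoff.
* **Sign convention.** Singular vectors are sign-arbitrary. The default
  output keeps the deterministic LAPACK signs, which is also what
  conventional solvers print; an optional canonicalization
  (`canonicalize = TRUE`, largest-magnitude entry of each right vector
  positive) is available for cross-platform serialization of factors. It
  is *not* the default because it silently flips the sign of individual
  coefficient estimates ($\hat{s}_j$, $\hat{t}_j$) relative to conventional
  output; all tests compare singular vectors up to per-column sign.
* **Threshold semantics.** "more than 99%" is implemented as cumulative
  fraction $\ge$ threshold (strict comparison available); components tied
  with the boundary one are always kept, so selection is
  order-independent.
* **Solvers.** All desk-scale systems use dense symmetric-positive-definite
  factorizations (Cholesky); diagonal systems use elementwise division.
  Rank-deficient cores in the QR route are handled by the $\theta$ term,
  never by pivoting columns away.
* **Mean handling.** The fixed mean can be bypassed (worked examples),
  pre-subtracted, or absorbed jointly into the normal equations; joint and
  precentered fits agree to correlation $\ge 0.999$ on balanced data.
* **Masking.** Validation phenotypes are removed from the equations (the
  incidence matrix loses those rows) rather than zero-filled; masked
  animals are predicted through their relationships/scores only.
* **Containers.** Bases, scores and operators can be written once and
  reused via `write_svd_container()`. The container is R native
  serialization holding the grouped layout (per-chromosome V and S blocks
  plus metadata); an HDF5 container was considered but the HDF5 R stack is
  not part of the supported dependency set, and these containers are
  runtime artifacts, never distribution files.

## The simulator: what it emulates and what it does not

`simulate_population()` is a forward Wright–Fisher simulator: discrete
generations, random mating with selfing allowed, per-meiosis recombination
as Poisson crossovers (rate = map length, uniform positions, no
interference), infinite-sites mutation at `mutation_rate * genome_bp` per
gamete per chromosome, a long neutral burn-in to mutation–drift
equilibrium, a bottleneck in which the census declines linearly to
`Ne_final` (the decline schedule is a package choice; sources state only
the endpoints), and a large final cohort bred from the post-bottleneck
parents. True breeding values are built on *standardized* genotypes from
per-chromosome sampled causative loci (MAF > 0.01) with standard-normal
effects, rescaled so the cohort variance of TBV is exactly 1; residuals
give $\sigma^2_e = (1-h^2)/h^2$. The reference cohort for the rescaling is
the final cohort itself — the generation bred immediately after the
bottleneck completes.

The `"paper"`-scale preset (20 chromosomes, $N_e$ 1000 for 10,000
generations, 10,000 animals) is supported but deliberately not the
default: the `"scaled"` preset (2 chromosomes, $N_e$ 100 for 500
generations with `genome_bp = 2.5e7`, i.e. population-scaled mutation rate
$4N_e\mu L_{bp} = 100$ per chromosome, bottleneck to 50, 1000 animals)
runs in seconds on one CPU while preserving the features the methods rely
on: mutation–drift equilibrium (pairwise diversity near $4N_e\mu L_{bp}$),
LD decaying with map distance, a bottleneck that prunes segregating loci,
and family structure in the final cohort. The acceptance configuration
scales up to $N_e$ 200 → 100 and 2000 animals. What the generator does
*not* emulate: selection, non-random mating, overlapping generations,
genotyping error, multi-breed structure, and genome-scale site counts — so
a green scaled test establishes the *algorithmic* claims (equivalences,
exact inverses, robustness ordering of the methods) but not the paper-scale
accuracy figures, which are checked only directionally.

## Design choices made where the design was open

* **Allele frequencies** default to estimates from all genotyped
  individuals (not the core); the frequency source is recorded on the
  object and can be overridden (`freq_source`, supplied `p`).
* **Centered vs standardized genotypes:** both are supported; GBLUP/GRM
  construction defaults to centered dosages (Method 1) while the simulator
  builds TBV on standardized genotypes, matching how each is specified.
  Method-2 weighting of centered dosages reproduces the standardized
  cross-product exactly (tested).
* **Missing genotypes** are an error unless mean imputation
  ($g \to 2p_j$) is explicitly requested; monomorphic loci are kept as
  zero columns under centering and dropped (with a count) before
  standardization.
* **Per-cell reproducibility:** the comparison harness derives one seed per
  (core size, $h^2$, replicate) cell from the master seed with a counter
  scheme, so any cell can be rerun in isolation; the trait architecture
  (causative loci, effects, TBV) is fixed once per dataset and only
  residuals are redrawn across cells.
* **QRIG row order:** the extended factor is computed in the population's
  own row order (core rows recover $\mathbf{R}_n$ by construction), so no
  physical sorting of the genotype file is required.

## Known limitations

Single trait, identity incidence and residual structure, no pedigree or
single-step H-matrix assembly, no REML, no selection in the simulator. The
dense GBLUP reference implementation is meant for $N$ up to a few
thousand; beyond that, use the operators' row-wise interface with an
iterative solver. The forward simulator is quadratic-ish in $N_e$ and
generations and is intended for desk-scale verification, not for
generating paper-scale datasets (use the `"paper"` preset only on a
workstation with patience).

## A worked session

```{r example}
ex <- worked_example(2)
basis <- core_svd(ex$gm, core_ids = ex$gm$ids[1:4], threshold = 1,
                  by_chromosome = FALSE)
scores <- project_scores(ex$gm, basis)
sol <- solve_pcrr(scores, ex$y, lambda = 1)
round(sol$g_hat, 3)

op <- pcig_inverse(two_stage_svd(scores), rho = 1, theta = 1e-3)
round(inverse_row(op, 1), 3)
```
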