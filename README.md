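# svdgp — reduced-dimension genomic prediction via SVD

`svdgp` is an R package for genomic prediction when either the number of
markers or the number of genotyped individuals makes the standard equation
systems impractical. It is aimed at quantitative geneticists and breeding
program analysts who need estimated breeding values (EBV) — or the inverse
genomic relationship matrix (GRM) that single-step evaluations consume —
for populations where a dense N×N inversion is out of reach.

## The idea

In a population of limited effective size N<sub>e</sub>, genomic variation
is carried by roughly M<sub>e</sub> = 2N<sub>e</sub>L / ln(2N<sub>e</sub>)
effective haplotype segments (L = genome length in Morgans), which is far
smaller than both the marker count k and the population size N. A singular
value decomposition of the centered dosage matrix **X** = **USV**′
therefore captures nearly all genomic variance in a limited number of
principal components, and:

* **PCRR** — SNP-BLUP, [**X**′**X** + λ**I**]**b̂** = **X**′**y**,
  reparameterized on the scores **T** = **US** becomes a *diagonal* ridge
  system [**S**² + λ**I**]**ŝ** = **T**′**y**, with **b̂** = **Vŝ**.
* **Core-sample, chromosome-wise SVD** — the SVD is computed on a core of
  n individuals, independently per chromosome, and the whole population is
  projected to reduced scores **C** = **XV**<sub>nq</sub> (components per
  chromosome chosen to explain ≥ 99% of core variance). A second-stage SVD
  re-diagonalizes **C** without changing any fit.
* **PCIG** — the PC-approximated GRM **G̃** = (**CC**′ + **I**ρθ)/ρ has the
  *exact* Woodbury inverse
  (1/θ)(**I** − **C**(**C**′**C** + **I**ρθ)⁻¹**C**′), requiring only a
  Σq<sub>i</sub>-dimensional (or diagonal) inner factorization, and can be
  materialized row by row for iteration-on-data solvers. QR-based (QRIG),
  weighted-GRM and marker-side (k < N) variants share the same operator
  form; APY is provided as the standard comparison baseline.

A forward Wright–Fisher simulator (burn-in to mutation–drift equilibrium,
bottleneck, QTL architecture at chosen heritability) and a
core/validation model-comparison harness reproduce the statistical design
used to validate the methods, at desk scale.

## Worked example

Five individuals, five loci, centered genotypes; the first four individuals
form the core sample (the fifth duplicates the first):

```r
library(svdgp)
ex <- worked_example(2)
basis  <- core_svd(ex$gm, core_ids = ex$gm$ids[1:4], threshold = 1,
                   by_chromosome = FALSE)
scores <- project_scores(ex$gm, basis)
sol    <- solve_pcrr(scores, ex$y, lambda = 1)
round(sol$s_hat, 3)
#> [1] -0.111 -0.497  0.025
round(sol$g_hat, 3)
#> [1] -0.522 -0.222  0.222  0.789 -0.522
```

Three PC regression coefficients (one per retained component of the
4-animal core) reproduce the genetic values of all five animals; the
duplicate animals 1 and 5 get identical EBV, and the two-stage route
(`solve_pcrr(two_stage_svd(scores), ...)`) returns exactly the same
`g_hat` from a diagonal system. On the 4×5 example, full-rank SNP-BLUP
gives `b_hat = (-0.0556, -0.0354, -0.1717, -0.3737, 0.2273)` with singular
values `(2.82843, 1.90211, 1.17557)` — identities like **b̂** = **VV**′**b̂**
and the SNP-BLUP/PCRR/GBLUP equivalences are enforced in the test suite.

A simulated end-to-end comparison:

```r
sim    <- simulate_dataset(sim_config("scaled", seed = 1))
design <- comparison_design(core_sizes = 200, h2_levels = 0.5,
                            methods = c("gblup", "pcrr", "pcig_c", "apy"))
res    <- run_comparison(sim, design)
```

`res` is a tidy frame of per-method validation-set correlations with full
GBLUP EBV and with true breeding values, plus component counts.

## Command line

```sh
inst/scripts/svdgp simulate --preset scaled --seed 1 --out-dir sim_out
inst/scripts/svdgp svd --genotypes sim_out/genotypes.tsv \
    --chrom-map sim_out/chrom_map.tsv --by-chromosome --out svd.rds
inst/scripts/svdgp ginverse --container svd.rds --algorithm pcig \
    --rho 123.4 --theta 1e-3 --out ginv.txt
inst/scripts/svdgp predict --model snp-blup --genotypes sim_out/genotypes.tsv \
    --phenotypes sim_out/phenotypes.tsv --h2 0.5 --sigma-g2 1 --out ebv.tsv
```

Every run writes a `manifest.json` sufficient to re-execute it. Inverse
GRMs are exported as 1-based lower-triangle `i j value` triplets.

## Documentation

See the methods vignette (`vignettes/svd-genomic-prediction.Rmd`) for the
model derivations, parameter meanings, simulator design and its
limitations, and the numerical conventions (rank cutoffs, sign handling,
threshold semantics).
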