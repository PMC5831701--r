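# Shared fixtures: random genotype generators and small cached simulations.

# Raw 0/1/2 dosages with independent loci at uniform-ish allele frequencies.
random_geno <- function(n, k, n_chrom = 1, seed = 1, maf = c(0.1, 0.9)) {
  set.seed(seed)
  p <- runif(k, maf[1], maf[2])
  X <- vapply(p, function(pj) rbinom(n, 2L, pj), numeric(n))
  chrom <- sort(rep_len(as.character(seq_len(n_chrom)), k))
  geno_matrix(X, chrom = chrom, coding = "raw")
}

# One small Wright-Fisher simulation with genuine LD/relatedness, cached
# across test files (forward simulation is the expensive part).
.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- sim_config(preset = "scaled", Ne_historical = 50L, Ne_final = 25L,
                      n_burnin_generations = 200L, n_chromosomes = 2L,
                      genome_bp = 2e7, n_final_animals = 300L,
                      n_qtl_per_chrom = 20L, seed = 11L)
    .fixture_cache$small <- assign_qtl_and_phenotypes(simulate_population(cfg))
  }
  .fixture_cache$small
}

# The scaled replication dataset used by the acceptance criteria: ~2000
# animals, 2 chromosomes of 1 Morgan, final Ne 100 after a bottleneck from
# Ne 200, seed fixed once.
acceptance_sim <- function() {
  if (is.null(.fixture_cache$acc)) {
    cfg <- sim_config(preset = "scaled", Ne_historical = 200L,
                      Ne_final = 100L, n_burnin_generations = 800L,
                      n_chromosomes = 2L, genome_bp = 1.25e7,
                      n_final_animals = 2000L, n_qtl_per_chrom = 50L,
                      h2 = 0.5, seed = 1L)
    .fixture_cache$acc <- assign_qtl_and_phenotypes(simulate_population(cfg))
  }
  .fixture_cache$acc
}

expect_equal_upto_sign <- function(actual, expected, tolerance = 1e-6) {
  stopifnot(ncol(actual) == ncol(expected))
  for (j in seq_len(ncol(expected))) {
    a <- actual[, j]; e <- expected[, j]
    d <- min(max(abs(a - e)), max(abs(a + e)))
    expect_lt(d, tolerance)
  }
}
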