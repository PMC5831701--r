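#' Simulation configuration
#'
#' Forward Wright-Fisher simulation of a diploid population with
#' infinite-sites mutation and Poisson recombination, a long neutral burn-in
#' to mutation-drift equilibrium, a bottleneck mimicking a livestock
#' population, and a large final cohort bred from the post-bottleneck
#' parents.
#'
#' Two presets are provided. `"paper"` is the full-scale parameterization
#' (20 chromosomes of 1 Morgan, historical Ne 1000 for 10,000 generations,
#' bottleneck to Ne 100 over 10 generations, 10,000 final animals, mutation
#' rate 1e-8 per bp per meiosis over 1e8 bp per chromosome, 200 causative
#' loci per chromosome with MAF > 0.01). `"scaled"` keeps the same
#' structure at desk scale: 2 chromosomes, Ne 100 for 500 burn-in
#' generations (>= 4 Ne, close to equilibrium), bottleneck to Ne 50 over 10
#' generations, 1000 final animals, 2.5e7 bp per chromosome (so the
#' population-scaled mutation rate 4*Ne*mu*bp = 100 per chromosome yields on
#' the order of several hundred segregating sites), and 50 causative loci
#' per chromosome.
#'
#' @param preset `"scaled"` (default) or `"paper"`.
#' @param ... named overrides of any field below.
#' @return object of class `sim_config` with fields `n_chromosomes`,
#'   `chrom_length_L` (Morgans), `Ne_historical`, `n_burnin_generations`,
#'   `Ne_final`, `bottleneck_generations`, `mutation_rate` (per bp per
#'   meiosis), `genome_bp` (per chromosome), `n_final_animals`,
#'   `n_qtl_per_chrom`, `qtl_maf_min`, `h2`, `seed`.
#' @export
sim_config <- function(preset = c("scaled", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper") {
    list(n_chromosomes = 20L, chrom_length_L = 1, Ne_historical = 1000L,
         n_burnin_generations = 10000L, Ne_final = 100L,
         bottleneck_generations = 10L, mutation_rate = 1e-8,
         genome_bp = 1e8, n_final_animals = 10000L, n_qtl_per_chrom = 200L,
         qtl_maf_min = 0.01, h2 = 0.5, seed = 1L)
  } else {
    list(n_chromosomes = 2L, chrom_length_L = 1, Ne_historical = 100L,
         n_burnin_generations = 500L, Ne_final = 50L,
         bottleneck_generations = 10L, mutation_rate = 1e-8,
         genome_bp = 2.5e7, n_final_animals = 1000L, n_qtl_per_chrom = 50L,
         qtl_maf_min = 0.01, h2 = 0.5, seed = 1L)
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$preset <- preset
  for (f in c("n_chromosomes", "Ne_historical", "n_burnin_generations",
              "Ne_final", "bottleneck_generations", "n_final_animals",
              "n_qtl_per_chrom"))
    if (cfg[[f]] < 0 || (f != "bottleneck_generations" && cfg[[f]] < 1))
      stop(f, " must be positive")
  if (cfg$Ne_final > cfg$Ne_historical)
    stop("Ne_final must not exceed Ne_historical")
  if (cfg$h2 <= 0 || cfg$h2 >= 1) stop("h2 must lie in (0, 1)")
  if (cfg$qtl_maf_min < 0 || cfg$qtl_maf_min >= 0.5)
    stop("qtl_maf_min must lie in [0, 0.5)")
  if (cfg$mutation_rate < 0) stop("mutation_rate must be non-negative")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> preset %s: %d chromosomes x %g M, Ne %d -> %d",
                     " (%d + %d generations), %d final animals, h2 = %g, seed = %d\n"),
              x$preset, x$n_chromosomes, x$chrom_length_L, x$Ne_historical,
              x$Ne_final, x$n_burnin_generations, x$bottleneck_generations,
              x$n_final_animals, x$h2, x$seed))
  invisible(x)
}

#' Effective number of loci
#'
#' `M_e = 2 Ne L / ln(2 Ne)`: the number of effectively independent
#' chromosome segments segregating in a population of effective size `Ne`
#' with genome length `L` Morgans. It bounds how many principal components
#' are needed to capture the genomic variation.
#'
#' @param Ne effective population size (> 0, with `2 Ne != 1`).
#' @param L genome length in Morgans (> 0).
#' @return numeric effective locus count.
#' @examples
#' effective_loci(200, 20)  # about 1335
#' @export
effective_loci <- function(Ne, L) {
  if (any(Ne <= 0) || any(L <= 0)) stop("Ne and L must be positive")
  if (any(2 * Ne == 1)) stop("2 * Ne must differ from 1")
  2 * Ne * L / log(2 * Ne)
}

# One meiosis: recombine the two parental haplotypes of one chromosome.
# H is sites x haplotypes (logical); pos sorted? not required (findInterval
# needs sorted breakpoints only).
make_gamete <- function(h1, h2, pos, L) {
  if (stats::runif(1) < 0.5) { tmp <- h1; h1 <- h2; h2 <- tmp }
  nx <- stats::rpois(1, L)
  if (nx > 0 && length(pos)) {
    br <- sort(stats::runif(nx, 0, L))
    swap <- findInterval(pos, br) %% 2L == 1L
    h1[swap] <- h2[swap]
  }
  h1
}

# Advance one chromosome one generation: parents (index pairs into columns
# of H), returning the offspring haplotype matrix with new mutations
# appended.
advance_chrom <- function(H, pos, parent_of, L, mu_chrom) {
  n_off <- length(parent_of)
  Hn <- matrix(FALSE, nrow(H), 2L * n_off)
  for (j in seq_len(n_off)) {
    p1 <- parent_of[[j]][1]; p2 <- parent_of[[j]][2]
    Hn[, 2L * j - 1L] <- make_gamete(H[, 2L * p1 - 1L], H[, 2L * p1], pos, L)
    Hn[, 2L * j]      <- make_gamete(H[, 2L * p2 - 1L], H[, 2L * p2], pos, L)
  }
  nh <- ncol(Hn)
  nm <- stats::rpois(1, nh * mu_chrom)
  if (nm > 0) {
    M <- matrix(FALSE, nm, nh)
    M[cbind(seq_len(nm), sample.int(nh, nm, replace = TRUE))] <- TRUE
    Hn <- rbind(Hn, M)
    pos <- c(pos, stats::runif(nm, 0, L))
  }
  cnt <- rowSums(Hn)
  keep <- cnt > 0L & cnt < nh
  list(H = Hn[keep, , drop = FALSE], pos = pos[keep])
}

#' Simulate a population
#'
#' Discrete generations of random mating (Wright's idealized structure,
#' selfing allowed): per meiosis, crossovers are Poisson with mean `L` per
#' chromosome at uniform positions without interference; mutations follow
#' the infinite-sites model at rate `mutation_rate * genome_bp` per gamete
#' per chromosome. After `n_burnin_generations` at `Ne_historical`, the
#' census declines linearly to `Ne_final` over `bottleneck_generations`;
#' the final generation consists of `n_final_animals` offspring of the
#' `Ne_final` post-bottleneck parents. Sites fixed or lost are pruned each
#' generation, so the returned loci all segregate in the final cohort's
#' source population (loci monomorphic within the cohort sample may remain).
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_result` with the final-cohort genotypes as a
#'   raw-coded [geno_matrix()] (derived-allele dosage), locus positions in
#'   Morgans (`positions`), per-chromosome segregating-site counts at the
#'   end of burn-in (`n_seg_burnin_end`) and in the final cohort
#'   (`n_seg_final`), mean pairwise diversity per chromosome at the end of
#'   burn-in (`pi_burnin_end`), and the configuration.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  mu_chrom <- cfg$mutation_rate * cfg$genome_bp
  sched <- round(seq(cfg$Ne_historical, cfg$Ne_final,
                     length.out = cfg$bottleneck_generations + 1L))[-1L]
  sizes <- c(rep(cfg$Ne_historical, cfg$n_burnin_generations), sched)
  chroms <- as.character(seq_len(cfg$n_chromosomes))
  H <- lapply(chroms, function(ch) matrix(FALSE, 0, 2L * cfg$Ne_historical))
  pos <- lapply(chroms, function(ch) numeric(0))
  n_seg_burnin <- NULL
  pi_burnin <- NULL
  Nprev <- cfg$Ne_historical
  for (g in seq_along(sizes)) {
    Ncur <- sizes[g]
    parent_of <- lapply(seq_len(Ncur), function(j)
      sample.int(Nprev, 2L, replace = TRUE))
    for (ci in seq_along(chroms)) {
      step <- advance_chrom(H[[ci]], pos[[ci]], parent_of,
                            cfg$chrom_length_L, mu_chrom)
      H[[ci]] <- step$H
      pos[[ci]] <- step$pos
    }
    Nprev <- Ncur
    if (g == cfg$n_burnin_generations) {
      n_seg_burnin <- vapply(H, nrow, integer(1))
      pi_burnin <- vapply(H, function(h) {
        if (nrow(h) == 0) return(0)
        nh <- ncol(h)
        f <- rowSums(h) / nh
        sum(2 * f * (1 - f)) * nh / (nh - 1)
      }, numeric(1))
    }
  }
  # final cohort bred from the post-bottleneck parents
  n_fin <- cfg$n_final_animals
  parent_of <- lapply(seq_len(n_fin), function(j)
    sample.int(Nprev, 2L, replace = TRUE))
  dos_parts <- vector("list", length(chroms))
  pos_parts <- vector("list", length(chroms))
  chrom_parts <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    step <- advance_chrom(H[[ci]], pos[[ci]], parent_of,
                          cfg$chrom_length_L, mu_chrom)
    h <- step$H
    if (nrow(h)) {
      odd <- seq(1L, ncol(h), by = 2L)
      dos <- h[, odd, drop = FALSE] + h[, odd + 1L, drop = FALSE]
      dos_parts[[ci]] <- t(dos)
    } else dos_parts[[ci]] <- matrix(0, n_fin, 0)
    pos_parts[[ci]] <- step$pos
    chrom_parts[[ci]] <- rep(chroms[ci], length(step$pos))
  }
  dosages <- do.call(cbind, dos_parts)
  storage.mode(dosages) <- "double"
  chrom <- unlist(chrom_parts)
  positions <- unlist(pos_parts)
  colnames(dosages) <- sprintf("chr%s_%07.0f", chrom, positions * 1e6)
  # deterministic column order within chromosome: by map position
  ord <- order(as.integer(chrom), positions)
  dosages <- dosages[, ord, drop = FALSE]
  chrom <- chrom[ord]
  positions <- positions[ord]
  gm <- geno_matrix(dosages, ids = paste0("ind", seq_len(n_fin)),
                    chrom = chrom, coding = "raw")
  structure(
    list(genotypes = gm, positions = positions,
         n_seg_burnin_end = n_seg_burnin,
         n_seg_final = vapply(split(seq_along(chrom), chrom), length, integer(1)),
         pi_burnin_end = pi_burnin,
         cfg = cfg),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d animals x %d segregating loci (%d chromosomes)\n",
              x$genotypes$n, x$genotypes$k, x$cfg$n_chromosomes))
  if (!is.null(x$tbv))
    cat(sprintf("  h2 = %g, sigma_e2 = %g, var(TBV) = %.4f\n",
                x$h2, x$sigma_e2, stats::var(x$tbv)))
  invisible(x)
}

#' Assign causative loci and phenotypes
#'
#' Per chromosome, `n_qtl_per_chrom` causative loci are sampled uniformly
#' without replacement among loci whose minor allele frequency in the final
#' cohort exceeds `qtl_maf_min` (fewer, with a warning, when a chromosome
#' has too few qualifying loci). Effects are standard normal on the
#' standardized genotype scale; true breeding values `TBV = alpha X b` are
#' rescaled by `alpha` so that the cohort variance of TBV is exactly 1
#' (sigma_g2 = 1). Phenotypes add independent residuals with
#' `sigma_e2 = (1 - h2) / h2`, giving the requested heritability; no fixed
#' effects are simulated.
#'
#' @param sim a [simulate_population()] result.
#' @param h2 heritability (default: from the configuration).
#' @param seed optional seed for QTL/effect/residual sampling (default: a
#'   value derived from the configuration seed, so the whole pipeline is
#'   reproducible from `cfg$seed` alone).
#' @return `sim` with fields `qtl_idx`, `qtl_effects` (length-k, zero off
#'   the QTL), `alpha`, `tbv`, `phenotypes` (`y`), `sigma_e2`, `h2`.
#' @export
assign_qtl_and_phenotypes <- function(sim, h2 = NULL, seed = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  cfg <- sim$cfg
  if (is.null(h2)) h2 <- cfg$h2
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  if (is.null(seed)) seed <- (cfg$seed * 1009L + 77L) %% .Machine$integer.max
  set.seed(seed)
  gm <- sim$genotypes
  maf <- pmin(gm$p, 1 - gm$p)
  qualified <- which(maf > cfg$qtl_maf_min)
  if (length(qualified) == 0) stop("no loci qualify as causative")
  qtl <- integer(0)
  for (ch in sort(unique(gm$chrom))) {
    cand <- qualified[gm$chrom[qualified] == ch]
    take <- min(cfg$n_qtl_per_chrom, length(cand))
    if (take < cfg$n_qtl_per_chrom)
      warning(sprintf("chromosome %s: only %d of %d requested causative loci available",
                      ch, take, cfg$n_qtl_per_chrom))
    qtl <- c(qtl, if (length(cand) == 1) cand else sample(cand, take))
  }
  qtl <- sort(qtl)
  b <- numeric(gm$k)
  b[qtl] <- stats::rnorm(length(qtl))
  std <- standardize_genotypes(gm)
  # standardization may drop cohort-monomorphic loci; map effects onto it
  kept <- which(!(gm$p == 0 | gm$p == 1))
  tbv_raw <- as.numeric(std$dosages %*% b[kept])
  v <- stats::var(tbv_raw)
  if (v == 0) stop("degenerate simulation: zero genetic variance")
  alpha <- 1 / sqrt(v)
  tbv <- alpha * tbv_raw
  sigma_e2 <- (1 - h2) / h2
  y <- tbv + stats::rnorm(gm$n, 0, sqrt(sigma_e2))
  sim$qtl_idx <- qtl
  sim$qtl_effects <- b
  sim$alpha <- alpha
  sim$tbv <- tbv
  sim$phenotypes <- y
  sim$sigma_e2 <- sigma_e2
  sim$h2 <- h2
  sim$pheno_seed <- seed
  sim
}

#' Regenerate phenotypes at a new heritability
#'
#' Keeps the causative loci, effects and true breeding values of a completed
#' simulation and redraws only the residuals at the requested heritability
#' (the trait architecture is a property of the dataset; the heritability is
#' a property of the measurement).
#'
#' @param sim a completed `sim_result` (with `tbv`).
#' @param h2 heritability in `(0, 1)`.
#' @param seed optional residual seed.
#' @return `sim` with updated `phenotypes`, `sigma_e2`, `h2`.
#' @export
regenerate_phenotypes <- function(sim, h2, seed = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  if (is.null(sim$tbv)) stop("run assign_qtl_and_phenotypes first")
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  sigma_e2 <- (1 - h2) / h2
  sim$phenotypes <- sim$tbv + stats::rnorm(length(sim$tbv), 0, sqrt(sigma_e2))
  sim$sigma_e2 <- sigma_e2
  sim$h2 <- h2
  sim
}

#' Simulate genotypes and phenotypes in one call
#'
#' @param cfg a [sim_config()].
#' @return a completed `sim_result` (see [assign_qtl_and_phenotypes()]).
#' @export
simulate_dataset <- function(cfg) {
  assign_qtl_and_phenotypes(simulate_population(cfg))
}

#' Export a simulation result as plain-text files
#'
#' Writes `genotypes.tsv` (dosage table readable by [read_genotypes()]),
#' `chrom_map.tsv`, `phenotypes.tsv`, `truth.tsv` (`id`, `tbv`),
#' `qtl.tsv` (`locus`, `effect`) and `config.txt` (key = value echo).
#'
#' @param sim a completed `sim_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_sim_result <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gm <- sim$genotypes
  gdf <- data.frame(ID = gm$ids, gm$dosages, check.names = FALSE)
  utils::write.table(gdf, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(snp_id = colnames(gm$dosages), chrom = gm$chrom),
                     file.path(dir, "chrom_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$phenotypes))
    utils::write.table(data.frame(id = gm$ids, y = sim$phenotypes),
                       file.path(dir, "phenotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(sim$tbv))
    utils::write.table(data.frame(id = gm$ids, tbv = sim$tbv),
                       file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(sim$qtl_idx))
    utils::write.table(data.frame(locus = colnames(gm$dosages)[sim$qtl_idx],
                                  effect = sim$qtl_effects[sim$qtl_idx]),
                       file.path(dir, "qtl.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  cfgv <- unclass(sim$cfg)
  extra <- list(sigma_e2 = sim$sigma_e2, realized_h2 = if (!is.null(sim$tbv))
    stats::var(sim$tbv) / stats::var(sim$phenotypes) else NA)
  writeLines(c(paste0(names(cfgv), " = ", unlist(cfgv)),
               paste0(names(extra), " = ", unlist(extra))),
             file.path(dir, "config.txt"))
  invisible(dir)
}
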