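#' Model-comparison design
#'
#' Describes a core-sample/validation comparison: for each combination of
#' core size, heritability and replicate, a core is drawn uniformly without
#' replacement, each non-core animal is independently assigned to the
#' validation set with probability `validation_fraction`, validation
#' phenotypes are masked (their records removed from the equations), and all
#' requested methods are fitted on the identical training data.
#'
#' @param core_sizes integer vector of core sample sizes.
#' @param h2_levels heritabilities to evaluate.
#' @param validation_fraction probability in `(0, 1)` that a non-core animal
#'   is a validation animal (default 0.10).
#' @param methods subset of `c("gblup", "pcrr", "pcig_c", "pcig_g", "qrig",
#'   "apy")`.
#' @param replicates replicate partitions per cell.
#' @param seed master seed; per-cell seeds are derived from it by a counter
#'   scheme so any cell can be reproduced in isolation.
#' @param threshold per-chromosome explained-variance threshold for the
#'   chromosome-wise methods (default 0.99).
#' @param theta GRM regularization for the inverse-based methods.
#' @return object of class `comparison_design`.
#' @export
comparison_design <- function(core_sizes, h2_levels = 0.5,
                              validation_fraction = 0.10,
                              methods = c("gblup", "pcrr", "pcig_c",
                                          "pcig_g", "qrig", "apy"),
                              replicates = 1L, seed = 1L, threshold = 0.99,
                              theta = 1e-3) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in [0, 1)")
  if (any(h2_levels <= 0 | h2_levels >= 1)) stop("h2 levels must lie in (0, 1)")
  structure(
    list(core_sizes = as.integer(core_sizes), h2_levels = h2_levels,
         validation_fraction = validation_fraction, methods = methods,
         replicates = as.integer(replicates), seed = as.integer(seed),
         threshold = threshold, theta = theta),
    class = "comparison_design"
  )
}

cell_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 9973) %% 2147483563) + 1L
}

#' Draw core and validation sets
#'
#' The core is drawn uniformly without replacement; every non-core animal is
#' independently a validation animal with probability `validation_fraction`.
#' Core and validation sets are disjoint by construction.
#'
#' @param ids population identifiers.
#' @param core_size number of core animals (< length(ids)).
#' @param validation_fraction probability for non-core animals.
#' @param seed optional seed (uses the current RNG state when `NULL`).
#' @return list with character vectors `core` and `validation`.
#' @export
sample_core_and_validation <- function(ids, core_size,
                                       validation_fraction = 0.10,
                                       seed = NULL) {
  ids <- as.character(ids)
  if (core_size >= length(ids)) stop("core_size must be smaller than the population")
  if (!is.null(seed)) set.seed(seed)
  core <- sample(ids, core_size)
  noncore <- setdiff(ids, core)
  val <- noncore[stats::runif(length(noncore)) < validation_fraction]
  list(core = core, validation = val)
}

#' Pearson correlation between EBV vectors on a subset
#'
#' @param a,b numeric vectors of equal length (EBV vs EBV, or EBV vs TBV).
#' @param subset indices or logical mask of the animals to compare (default
#'   all).
#' @return Pearson correlation, or `NA` (with a warning) when fewer than 3
#'   animals are selected or either vector has zero variance.
#' @export
ebv_correlation <- function(a, b, subset = NULL) {
  if (!is.null(subset)) { a <- a[subset]; b <- b[subset] }
  if (length(a) < 3) { warning("fewer than 3 animals in subset"); return(NA_real_) }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

fit_one_method <- function(method, gm_c, y, obs, lambda_g, lambda_snp,
                           core, threshold, theta) {
  n_components <- NA_integer_
  g <- switch(method,
    gblup = {
      grm <- build_grm(gm_c, theta = theta)
      solve_gblup(grm, y, lambda_g = lambda_g, observed = obs)$g_hat
    },
    pcrr = {
      basis <- core_svd(gm_c, core, threshold = threshold, by_chromosome = TRUE)
      sc <- project_scores(gm_c, basis)
      n_components <- sum(basis$q)
      solve_pcrr(sc, y, lambda = lambda_snp, observed = obs)$g_hat
    },
    pcig_c = {
      basis <- core_svd(gm_c, core, threshold = threshold, by_chromosome = TRUE)
      sc <- two_stage_svd(project_scores(gm_c, basis))
      n_components <- sum(basis$q)
      op <- pcig_inverse(sc, rho = rho_scaling(gm_c), theta = theta)
      solve_gblup(op, y, lambda_g = lambda_g, observed = obs)$g_hat
    },
    pcig_g = {
      basis <- core_svd(gm_c, core, threshold = 1, by_chromosome = FALSE)
      sc <- two_stage_svd(project_scores(gm_c, basis))
      n_components <- sum(basis$q)
      op <- pcig_inverse(sc, rho = rho_scaling(gm_c), theta = theta)
      solve_gblup(op, y, lambda_g = lambda_g, observed = obs)$g_hat
    },
    qrig = {
      op <- qrig_inverse(gm_c, core, theta = theta)
      n_components <- length(core)
      solve_gblup(op, y, lambda_g = lambda_g, observed = obs)$g_hat
    },
    apy = {
      grm <- build_grm(gm_c, theta = theta)
      op <- apy_inverse(grm, core_ids = core)
      n_components <- length(core)
      solve_gblup(op, y, lambda_g = lambda_g, observed = obs)$g_hat
    },
    stop("unknown method: ", method)
  )
  list(g_hat = g, n_components = n_components)
}

#' Run a model comparison on simulated data
#'
#' For every (core size, heritability, replicate) cell: phenotypes are
#' regenerated at the requested heritability from the simulated true
#' breeding values, a core/validation partition is drawn, validation records
#' are removed from the equations, and each method is fitted on the same
#' training data. Reported metrics are the Pearson correlation of each
#' method's validation EBV with the full GBLUP validation EBV
#' (`ebv_correlation_vs_gblup`) and with the true breeding values
#' (`accuracy_vs_tbv`), plus the number of components used.
#'
#' Chromosome-wise methods (`pcrr`, `pcig_c`) retain per-chromosome
#' components at the design threshold; `pcig_g` uses the genome-wide
#' economy SVD of the core (component count = core rank, at most the core
#' size); `qrig` and `apy` use the core sample directly.
#'
#' @param sim a [simulate_population()] result (phenotypes are regenerated
#'   per cell, so [assign_qtl_and_phenotypes()] need not have been called
#'   with matching `h2`).
#' @param design a [comparison_design()].
#' @return a `comparison_result` data frame with columns `method`,
#'   `core_size`, `h2`, `replicate`, `metric`, `value`. Method failures are
#'   recorded as `NA` values with metric `error` and the run continues.
#' @export
run_comparison <- function(sim, design) {
  stopifnot(inherits(sim, "sim_result"), inherits(design, "comparison_design"))
  if (is.null(sim$tbv)) sim <- assign_qtl_and_phenotypes(sim)
  gm <- sim$genotypes
  gm_c <- center_genotypes(gm)
  rho <- rho_scaling(gm_c)
  rows <- list()
  counter <- 0L
  for (core_size in design$core_sizes) {
    for (h2 in design$h2_levels) {
      for (rep_i in seq_len(design$replicates)) {
        counter <- counter + 1L
        seed_i <- cell_seed(design$seed, counter)
        simh <- regenerate_phenotypes(sim, h2 = h2, seed = seed_i)
        part <- sample_core_and_validation(gm$ids, core_size,
                                           design$validation_fraction,
                                           seed = seed_i + 1L)
        val_idx <- match(part$validation, gm$ids)
        obs <- setdiff(seq_len(gm$n), val_idx)
        mu <- mean(simh$phenotypes[obs])
        y <- simh$phenotypes[obs] - mu
        lambda_g <- simh$sigma_e2 / 1.0
        lambda_snp <- simh$sigma_e2 / (1.0 / rho)
        fits <- list()
        for (method in union("gblup", design$methods)) {
          fits[[method]] <- tryCatch(
            fit_one_method(method, gm_c, y, obs, lambda_g, lambda_snp,
                           part$core, design$threshold, design$theta),
            error = function(e) e)
        }
        for (method in design$methods) {
          f <- fits[[method]]
          base <- list(method = method, core_size = core_size, h2 = h2,
                       replicate = rep_i)
          if (inherits(f, "error")) {
            rows[[length(rows) + 1L]] <- c(base, metric = "error", value = NA_real_)
            warning(sprintf("method %s failed: %s", method, conditionMessage(f)))
            next
          }
          gb <- fits[["gblup"]]
          r_gblup <- if (inherits(gb, "error")) NA_real_ else
            ebv_correlation(f$g_hat, gb$g_hat, val_idx)
          acc <- ebv_correlation(f$g_hat, simh$tbv, val_idx)
          rows[[length(rows) + 1L]] <- c(base, metric = "ebv_correlation_vs_gblup",
                                         value = r_gblup)
          rows[[length(rows) + 1L]] <- c(base, metric = "accuracy_vs_tbv",
                                         value = acc)
          rows[[length(rows) + 1L]] <- c(base, metric = "n_components",
                                         value = as.numeric(f$n_components))
        }
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(method = r$method, core_size = r$core_size, h2 = r$h2,
               replicate = r$replicate, metric = r$metric, value = r$value,
               stringsAsFactors = FALSE)))
  class(out) <- c("comparison_result", class(out))
  out
}

#' Write a comparison result as CSV
#'
#' @param result a [run_comparison()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
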