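#' @title Mixed-model solvers for genomic prediction
#' @description SNP-BLUP, GBLUP and principal-component ridge regression
#'   share the same statistical model: phenotypes are the sum of an optional
#'   mean, an additive genetic value and independent residuals. The solvers
#'   here differ only in the parameterization of the genetic value (per-SNP
#'   effects, per-individual effects with a relationship matrix, or
#'   coefficients on SVD scores) and return interchangeable `solutions`
#'   objects.
#' @name predictors
NULL

new_solutions <- function(method, g_hat, mu_hat = 0, b_hat = NULL,
                          s_hat = NULL, t_hat = NULL, lambda = NA_real_,
                          ids = NULL) {
  structure(
    list(method = method, g_hat = as.numeric(g_hat), mu_hat = mu_hat,
         b_hat = b_hat, s_hat = s_hat, t_hat = t_hat, lambda = lambda,
         ids = ids),
    class = "solutions"
  )
}

#' @export
print.solutions <- function(x, ...) {
  cat(sprintf("<solutions> %s: %d individuals, lambda = %g, mu_hat = %g\n",
              x$method, length(x$g_hat), x$lambda, x$mu_hat))
  invisible(x)
}

#' Handle the fixed mean
#'
#' `precenter` estimates the mean as the phenotype average and subtracts it;
#' `none` bypasses the mean entirely (the worked examples omit fixed
#' effects). The `joint` strategy, where the mean is absorbed into the
#' normal equations, is available through the `mean` argument of the
#' solvers.
#'
#' @param y numeric phenotype vector.
#' @param strategy `"precenter"` or `"none"`.
#' @return list with `mu_hat` and the adjusted phenotypes `y_adj`.
#' @export
fit_mean <- function(y, strategy = c("precenter", "none")) {
  strategy <- match.arg(strategy)
  if (strategy == "precenter") list(mu_hat = mean(y), y_adj = y - mean(y))
  else list(mu_hat = 0, y_adj = y)
}

spd_solve <- function(A, b) {
  ch <- chol(A)
  backsolve(ch, forwardsolve(t(ch), b))
}

# Solve the ridge system [W'W + lambda I] a = W'y, optionally absorbing a
# mean column jointly, and return coefficients plus mu_hat. `obs` indexes
# the phenotyped rows of W.
ridge_fit <- function(W, y, lambda, mean, obs = NULL, diag_wtw = NULL) {
  n_all <- nrow(W)
  if (is.null(obs)) obs <- seq_len(n_all)
  Wo <- W[obs, , drop = FALSE]
  if (length(y) != length(obs)) stop("phenotype length does not match observed rows")
  mu <- 0
  if (mean == "precenter") {
    mu <- mean(y)
    y <- y - mu
  }
  m <- ncol(W)
  if (mean == "joint") {
    no <- length(obs)
    A <- rbind(
      c(no, colSums(Wo)),
      cbind(colSums(Wo), crossprod(Wo) + diag(lambda, m))
    )
    rhs <- c(sum(y), crossprod(Wo, y))
    sol <- solve(A, rhs)
    mu <- sol[1]
    a <- sol[-1]
  } else if (!is.null(diag_wtw) && length(obs) == n_all) {
    # fully-observed diagonal system (full PCRR / two-stage PCRR)
    a <- as.numeric(crossprod(Wo, y)) / (diag_wtw + lambda)
  } else {
    a <- as.numeric(spd_solve(crossprod(Wo) + diag(lambda, m), crossprod(Wo, y)))
  }
  list(a = a, mu_hat = mu)
}

#' Solve the SNP-BLUP ridge system
#'
#' Estimates per-SNP allele substitution effects from
#' `[X'X + lambda I] b_hat = X'y` with `lambda = sigma_e2 / sigma_m2`, and
#' individual genetic values `g_hat = X b_hat`.
#'
#' @param gm centered/standardized [geno_matrix()] (raw coding is refused).
#' @param y phenotype vector (length N, or matching `observed`).
#' @param vc optional [variance_components()]; `sigma_m2` is derived as
#'   `sigma_g2 / rho` from the matrix frequencies when not set.
#' @param lambda explicit ridge ratio overriding `vc`.
#' @param mean `"none"` (default, as in the worked examples),
#'   `"precenter"`, or `"joint"`.
#' @param observed optional indices of phenotyped individuals; the system is
#'   built from those rows only and `g_hat` is predicted for everyone.
#' @return a `solutions` object with `b_hat` and `g_hat`.
#' @export
solve_snp_blup <- function(gm, y, vc = NULL, lambda = NULL,
                           mean = c("none", "precenter", "joint"),
                           observed = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  mean <- match.arg(mean)
  if (gm$coding == "raw") stop("center or standardize genotypes first")
  y <- as.numeric(y)
  if (!all(is.finite(y)) || !all(is.finite(gm$dosages)))
    stop("inputs must be finite")
  lambda <- resolve_lambda_snp(vc, lambda, gm)
  fit <- ridge_fit(gm$dosages, y, lambda, mean, obs = observed)
  g <- as.numeric(gm$dosages %*% fit$a)
  new_solutions("snp_blup", g, mu_hat = fit$mu_hat, b_hat = fit$a,
                lambda = lambda, ids = gm$ids)
}

#' Solve GBLUP equations
#'
#' Two equivalent forms of the genomic animal model: the inverse form
#' `[I + lambda_g * Ginv] g_hat = y` (requires an invertible, e.g.
#' theta-regularized, relationship matrix) and the non-inverse form
#' `[G + lambda_g I] g_hat = G y`, which never inverts `G`. With an
#' invertible `G` the two agree; with a regularized `G + I theta` the
#' solutions differ from the unregularized ones by a term of order `theta`.
#'
#' @param G a dense relationship matrix, a [build_grm()] object, or a
#'   `grm_inverse_op` (inverse form only).
#' @param y phenotype vector.
#' @param vc optional [variance_components()] giving
#'   `lambda_g = sigma_e2 / sigma_g2`.
#' @param lambda_g explicit ratio overriding `vc`.
#' @param form `"inverse"` or `"noninverse"`.
#' @param mean mean-handling strategy as in [solve_snp_blup()].
#' @param observed optional indices of phenotyped individuals (inverse form
#'   only): solves `[Z'Z + lambda_g Ginv] g_hat = Z'(y - mu)` with `Z` the
#'   incidence of the observed rows, predicting all individuals.
#' @return a `solutions` object with `g_hat`.
#' @export
solve_gblup <- function(G, y, vc = NULL, lambda_g = NULL,
                        form = c("inverse", "noninverse"),
                        mean = c("none", "precenter", "joint"),
                        observed = NULL) {
  form <- match.arg(form)
  mean <- match.arg(mean)
  y <- as.numeric(y)
  if (is.null(lambda_g)) {
    if (is.null(vc)) stop("supply lambda_g or variance components")
    lambda_g <- vc$lambda_g
  }
  if (lambda_g <= 0) stop("lambda_g must be positive")
  ids <- NULL
  theta <- 0
  if (inherits(G, "grm")) {
    ids <- G$ids
    theta <- G$theta
    Gd <- G$G
    if (theta > 0) Gd <- Gd + diag(theta, nrow(Gd))
  } else if (inherits(G, "grm_inverse_op")) {
    if (form == "noninverse")
      stop("the non-inverse form needs the relationship matrix itself, not its inverse")
    Gd <- NULL
    ids <- G$ids
  } else {
    Gd <- as.matrix(G)
  }

  if (form == "inverse") {
    Ginv <- if (inherits(G, "grm_inverse_op")) materialize(G) else {
      inv <- tryCatch(chol2inv(chol(Gd)), error = function(e) NULL)
      if (is.null(inv))
        stop("relationship matrix is singular; regularize with theta (see build_grm)")
      inv
    }
    n <- nrow(Ginv)
    obs <- if (is.null(observed)) seq_len(n) else observed
    mu <- 0
    yy <- y
    if (mean == "precenter") { mu <- mean(yy); yy <- yy - mu }
    z <- numeric(n)
    z[obs] <- 1
    if (mean == "joint") {
      A <- rbind(c(length(obs), z),
                 cbind(z, diag(z) + lambda_g * Ginv))
      rhs <- c(sum(yy), { r <- numeric(n); r[obs] <- yy; r })
      sol <- solve(A, rhs)
      mu <- sol[1]
      g <- sol[-1]
    } else {
      A <- diag(z) + lambda_g * Ginv
      rhs <- numeric(n)
      rhs[obs] <- yy
      g <- as.numeric(solve(A, rhs))
    }
    return(new_solutions(paste0("gblup_", if (inherits(G, "grm_inverse_op")) G$algorithm else "inverse"),
                         g, mu_hat = mu, lambda = lambda_g, ids = ids))
  }

  # non-inverse form: [G + lambda_g I] g = G (y - mu)
  if (!is.null(observed)) stop("observed subsetting requires the inverse form")
  mu <- 0
  if (mean %in% c("precenter", "joint")) { mu <- mean(y); y <- y - mu }
  n <- nrow(Gd)
  g <- as.numeric(spd_solve(Gd + diag(lambda_g, n), Gd %*% y))
  new_solutions("gblup_noninverse", g, mu_hat = mu, lambda = lambda_g, ids = ids)
}

#' Principal component ridge regression
#'
#' Dispatches on the score representation:
#' \itemize{
#'   \item full SVD factors: diagonal system
#'     `[S^2 + lambda I] s_hat = T'y` with `T = U S`;
#'   \item reduced scores `C`: dense `[C'C + lambda I] s_hat = C'y`
#'     (dimension = number of retained components);
#'   \item two-stage scores `T_hat`: diagonal system
#'     `[S_C^2 + lambda I] t_hat = T_hat' y`.
#' }
#' Genetic values are `g_hat = T s_hat`, `C s_hat` or `T_hat t_hat`
#' respectively; reduced and two-stage fits of the same scores give
#' identical `g_hat`.
#'
#' @param x an `svd_factors` or `score_matrix` object.
#' @param y phenotype vector.
#' @param vc optional [variance_components()] with known `sigma_m2` (the
#'   PC coefficients inherit the per-SNP prior variance).
#' @param lambda explicit ridge ratio `sigma_e2/sigma_m2`.
#' @param mean,observed as in [solve_snp_blup()].
#' @return a `solutions` object with `s_hat` (or `t_hat`) and `g_hat`.
#' @export
solve_pcrr <- function(x, y, vc = NULL, lambda = NULL,
                       mean = c("none", "precenter", "joint"),
                       observed = NULL) {
  mean <- match.arg(mean)
  y <- as.numeric(y)
  lambda <- resolve_lambda_snp(vc, lambda)
  if (inherits(x, "svd_factors")) {
    W <- x$u %*% diag(x$d, x$rank)
    fit <- ridge_fit(W, y, lambda, mean, obs = observed, diag_wtw = x$d^2)
    g <- as.numeric(W %*% fit$a)
    return(new_solutions("pcrr_full", g, mu_hat = fit$mu_hat, s_hat = fit$a,
                         lambda = lambda))
  }
  stopifnot(inherits(x, "score_matrix"))
  if (x$stage == "reduced") {
    fit <- ridge_fit(x$C, y, lambda, mean, obs = observed)
    g <- as.numeric(x$C %*% fit$a)
    new_solutions("pcrr_reduced", g, mu_hat = fit$mu_hat, s_hat = fit$a,
                  lambda = lambda, ids = x$ids)
  } else {
    fit <- ridge_fit(x$that, y, lambda, mean, obs = observed, diag_wtw = x$d^2)
    g <- as.numeric(x$that %*% fit$a)
    new_solutions("pcrr_two_stage", g, mu_hat = fit$mu_hat, t_hat = fit$a,
                  lambda = lambda, ids = x$ids)
  }
}

#' Back-transform PC coefficients to SNP effects
#'
#' Recovers per-SNP effects from PC regression coefficients:
#' `b_hat = V s_hat` for a full SVD basis, `b_hat = blockdiag(V_inq) s_hat`
#' for reduced scores on a core basis, and
#' `b_hat = blockdiag(V_inq) V_C t_hat` for two-stage coefficients. The
#' result satisfies the projection identity `b_hat = V V' b_hat` even though
#' `V V'` is not the identity.
#'
#' @param sol a `solutions` object carrying `s_hat` or `t_hat`.
#' @param basis the `svd_factors` or `core_basis` the fit was built on.
#' @param scores the two-stage `score_matrix` (needed for `t_hat`, to supply
#'   `V_C`).
#' @return `sol` with `b_hat` filled in (ordered by the basis loci order).
#' @export
back_transform_snp_effects <- function(sol, basis, scores = NULL) {
  stopifnot(inherits(sol, "solutions"))
  if (inherits(basis, "svd_factors")) {
    if (is.null(sol$s_hat)) stop("solutions carry no s_hat")
    if (length(sol$s_hat) != basis$rank) stop("dimension mismatch between s_hat and basis")
    sol$b_hat <- as.numeric(basis$v %*% sol$s_hat)
    return(sol)
  }
  stopifnot(inherits(basis, "core_basis"))
  s <- sol$s_hat
  if (is.null(s)) {
    if (is.null(sol$t_hat)) stop("solutions carry neither s_hat nor t_hat")
    if (is.null(scores) || is.null(scores$v_c))
      stop("two-stage back-transform needs the two-stage score matrix (for V_C)")
    if (length(sol$t_hat) != ncol(scores$v_c)) stop("dimension mismatch between t_hat and V_C")
    s <- as.numeric(scores$v_c %*% sol$t_hat)
  }
  if (length(s) != sum(basis$q)) stop("dimension mismatch between coefficients and basis")
  b <- numeric(basis$k_total)
  off <- 0L
  for (ch in basis$chrom) {
    qi <- basis$q[[ch]]
    if (qi > 0)
      b[basis$loci[[ch]]] <- basis$blocks[[ch]] %*% s[(off + 1L):(off + qi)]
    off <- off + qi
  }
  sol$b_hat <- b
  sol
}

#' Write estimated breeding values to a TSV file
#'
#' @param sol a `solutions` object.
#' @param path output file.
#' @param ids identifiers (default: those stored in the solutions).
#' @return `path`, invisibly.
#' @export
write_ebv <- function(sol, path, ids = NULL) {
  stopifnot(inherits(sol, "solutions"))
  if (is.null(ids)) ids <- sol$ids
  if (is.null(ids)) ids <- paste0("id", seq_along(sol$g_hat))
  df <- data.frame(id = ids, g_hat = sol$g_hat, mu_hat = sol$mu_hat)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write SNP effects to a TSV file
#'
#' @param sol a `solutions` object with `b_hat`.
#' @param path output file.
#' @param snp_ids optional locus identifiers.
#' @return `path`, invisibly.
#' @export
write_snp_effects <- function(sol, path, snp_ids = NULL) {
  stopifnot(inherits(sol, "solutions"))
  if (is.null(sol$b_hat)) stop("solutions carry no b_hat")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_along(sol$b_hat))
  df <- data.frame(snp_id = snp_ids, b_hat = sol$b_hat)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
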