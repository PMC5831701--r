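# Exact SNP-BLUP solution of the 4x5 example with lambda = 1, computed from
# the printed X and y by an independent dense solve (see also the note on
# the second element, whose printed value drops a leading zero: the ridge
# system and the projection identity V V' b = b pin it to -0.035354).
example1_bhat <- c(-0.0556, -0.0354, -0.1717, -0.3737, 0.2273)

test_that("SNP-BLUP reproduces the worked-example solutions", {
  ex <- worked_example(1)
  sol <- solve_snp_blup(ex$gm, ex$y, lambda = 1)
  expect_lt(max(abs(sol$b_hat - example1_bhat)), 5e-4)
  expect_equal(sol$g_hat, as.numeric(ex$X %*% sol$b_hat), tolerance = 1e-10)
  # independent oracle: direct dense solve of the normal equations
  oracle <- solve(crossprod(ex$X) + diag(5), crossprod(ex$X, ex$y))
  expect_equal(sol$b_hat, as.numeric(oracle), tolerance = 1e-12)
})

test_that("SNP-BLUP scalar and degenerate cases", {
  gm <- geno_matrix(cbind(c(1, -1)), coding = "centered")
  sol <- solve_snp_blup(gm, c(1, -1), lambda = 1)
  expect_equal(sol$b_hat, 2 / 3)               # (X'y)/(X'X + lambda)
  ex <- worked_example(1)
  expect_equal(solve_snp_blup(ex$gm, rep(0, 4), lambda = 1)$b_hat, rep(0, 5))
  expect_error(solve_snp_blup(ex$gm, c(1, NA, 0, 0), lambda = 1), "finite")
  expect_error(solve_snp_blup(ex$gm, ex$y, lambda = -1), "positive")
})

test_that("GBLUP closed form, regularization, and SNP-BLUP equivalence", {
  y <- c(1, -2, 0.5, 3)
  sol <- solve_gblup(diag(4), y, lambda_g = 1)
  expect_equal(sol$g_hat, y / 2)

  # Regularized inverse form vs non-inverse form differ by O(theta)
  gm <- center_genotypes(random_geno(15, 40, seed = 21))
  set.seed(22); yy <- rnorm(15)
  theta <- 1e-3
  grm <- build_grm(gm, theta = theta)
  g_inv <- solve_gblup(grm, yy, lambda_g = 1)$g_hat
  g_non <- solve_gblup(grm$G, yy, lambda_g = 1, form = "noninverse")$g_hat
  expect_lt(max(abs(g_inv - g_non)), 5 * theta)

  # GBLUP == SNP-BLUP when G = XX'/rho and sigma_m2 = sigma_g2/rho
  rho <- rho_scaling(gm)
  sigma_g2 <- 2; sigma_e2 <- 1
  lambda_snp <- sigma_e2 / (sigma_g2 / rho)
  g_snp <- solve_snp_blup(gm, yy, lambda = lambda_snp)$g_hat
  g_gb <- solve_gblup(grm$G, yy, lambda_g = sigma_e2 / sigma_g2,
                      form = "noninverse")$g_hat
  expect_equal(g_snp, g_gb, tolerance = 1e-8)
})

test_that("singular G in inverse form points the user at theta", {
  gm <- center_genotypes(random_geno(10, 3, seed = 23))  # rank <= 3 < N
  G <- build_grm(gm)$G
  expect_error(solve_gblup(G, rnorm(10), lambda_g = 1), "theta|regularize")
})

test_that("reduced PCRR reproduces the worked example, two-stage agrees", {
  ex <- worked_example(2)
  basis <- core_svd(ex$gm, ex$gm$ids[1:4], threshold = 1, by_chromosome = FALSE)
  sc <- project_scores(ex$gm, basis)
  sol <- solve_pcrr(sc, ex$y, lambda = 1)
  expect_lt(max(abs(abs(sol$s_hat) - abs(c(-0.111, -0.497, 0.025)))), 5e-4)
  expect_lt(max(abs(sol$g_hat - c(-0.522, -0.222, 0.222, 0.789, -0.522))), 5e-4)
  ts <- two_stage_svd(sc)
  sol2 <- solve_pcrr(ts, ex$y, lambda = 1)
  expect_lt(max(abs(abs(sol2$t_hat) - abs(c(0.111, 0.473, -0.154)))), 5e-4)
  expect_equal(sol2$g_hat, sol$g_hat, tolerance = 1e-8)
})

test_that("full-rank PCRR equals SNP-BLUP on the 4x5 example", {
  ex <- worked_example(1)
  fac <- economy_svd(ex$gm)
  sol_pc <- solve_pcrr(fac, ex$y, lambda = 1)
  sol_snp <- solve_snp_blup(ex$gm, ex$y, lambda = 1)
  expect_equal(sol_pc$g_hat, sol_snp$g_hat, tolerance = 1e-8)
})

test_that("equivalence chain holds on random full-rank instances", {
  for (seed in c(31, 32)) {
    gm <- center_genotypes(random_geno(30, 50, seed = seed))
    set.seed(seed + 100); y <- rnorm(30)
    rho <- rho_scaling(gm)
    sigma_g2 <- 1; sigma_e2 <- 2
    lambda_snp <- sigma_e2 / (sigma_g2 / rho)
    g1 <- solve_snp_blup(gm, y, lambda = lambda_snp)$g_hat
    g2 <- solve_pcrr(economy_svd(gm), y, lambda = lambda_snp)$g_hat
    g3 <- solve_gblup(build_grm(gm)$G, y, lambda_g = sigma_e2 / sigma_g2,
                      form = "noninverse")$g_hat
    expect_equal(g1, g2, tolerance = 1e-8)
    expect_equal(g1, g3, tolerance = 1e-8)
  }
})

test_that("theta-regularized solutions converge to unregularized ones", {
  gm <- center_genotypes(random_geno(20, 60, seed = 33))
  set.seed(34); y <- rnorm(20)
  g_exact <- solve_gblup(build_grm(gm)$G, y, lambda_g = 1,
                         form = "noninverse")$g_hat
  devs <- vapply(c(1e-2, 1e-4, 1e-6), function(th) {
    g <- solve_gblup(build_grm(gm, theta = th), y, lambda_g = 1)$g_hat
    max(abs(g - g_exact))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 1e-4)
})

test_that("shrinkage is monotone in lambda", {
  ex <- worked_example(1)
  norms <- vapply(c(0.1, 1, 10, 100), function(l)
    sqrt(sum(solve_snp_blup(ex$gm, ex$y, lambda = l)$g_hat^2)), numeric(1))
  expect_true(all(diff(norms) <= 0))
})

test_that("back-transform satisfies the projection identity b = V V' b", {
  ex <- worked_example(1)
  fac <- economy_svd(ex$gm)
  sol <- solve_pcrr(fac, ex$y, lambda = 1)
  sol <- back_transform_snp_effects(sol, fac)
  expect_lt(max(abs(sol$b_hat - example1_bhat)), 5e-4)
  VVt <- fac$v %*% t(fac$v)
  expect_equal(as.numeric(VVt %*% sol$b_hat), sol$b_hat, tolerance = 1e-10)
  expect_gt(max(abs(VVt - diag(5))), 0.1)      # V V' != I here
  # printed V V' (2 dp) for the worked example
  expect_lt(abs(VVt[2, 2] - 0.85), 5e-3)

  # square orthogonal V: exact change of basis round-trip
  set.seed(35)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  fac2 <- list(u = diag(4), d = rep(1, 4), v = Q, rank = 4L)
  class(fac2) <- "svd_factors"
  sol2 <- structure(list(s_hat = c(1, 2, 3, 4)), class = "solutions")
  b <- back_transform_snp_effects(sol2, fac2)$b_hat
  expect_equal(as.numeric(t(Q) %*% b), c(1, 2, 3, 4), tolerance = 1e-12)
})

test_that("reduced-basis back-transform reproduces the fit through X", {
  gm <- center_genotypes(random_geno(40, 80, n_chrom = 2, seed = 36))
  set.seed(37); y <- rnorm(40)
  basis <- core_svd(gm, gm$ids[1:25], threshold = 0.99)
  sc <- project_scores(gm, basis)
  sol <- solve_pcrr(sc, y, lambda = 2)
  sol <- back_transform_snp_effects(sol, basis)
  expect_equal(as.numeric(gm$dosages %*% sol$b_hat), sol$g_hat,
               tolerance = 1e-8)
  # two-stage route gives the same SNP effects
  ts <- two_stage_svd(sc)
  sol2 <- back_transform_snp_effects(solve_pcrr(ts, y, lambda = 2), basis,
                                     scores = ts)
  expect_equal(sol2$b_hat, sol$b_hat, tolerance = 1e-8)
})

test_that("mean handling: precenter, joint and bypass", {
  set.seed(38)
  y <- rnorm(30) + 10                          # zero genetic signal
  gm <- center_genotypes(random_geno(30, 20, seed = 39))
  fm <- fit_mean(y, "precenter")
  expect_equal(fm$mu_hat, mean(y))
  sol <- solve_snp_blup(gm, y, lambda = 1e6, mean = "precenter")
  expect_equal(sol$mu_hat, mean(y))
  expect_lt(max(abs(sol$g_hat)), 0.01)

  # joint vs precenter agree closely on balanced data
  sim_y <- as.numeric(gm$dosages %*% rnorm(20, 0, 0.3)) + rnorm(30) + 5
  s_j <- solve_snp_blup(gm, sim_y, lambda = 2, mean = "joint")
  s_p <- solve_snp_blup(gm, sim_y, lambda = 2, mean = "precenter")
  expect_gte(cor(s_j$g_hat, s_p$g_hat), 0.999)

  # worked examples bypass the mean entirely
  ex <- worked_example(1)
  expect_equal(solve_snp_blup(ex$gm, ex$y, lambda = 1)$mu_hat, 0)
})

test_that("masked records do not leak into the fit", {
  gm <- center_genotypes(random_geno(30, 40, seed = 40))
  set.seed(41); y <- rnorm(30)
  obs <- 1:20
  grm <- build_grm(gm, theta = 1e-3)
  g1 <- solve_gblup(grm, y[obs], lambda_g = 1, observed = obs)$g_hat
  y2 <- y; y2[21:30] <- rnorm(10) * 100        # masked rows changed wildly
  g2 <- solve_gblup(grm, y2[obs], lambda_g = 1, observed = obs)$g_hat
  expect_identical(g1, g2)
  # masked animals still receive predictions through their relationships
  expect_gt(stats::sd(g1[21:30]), 0)
})

test_that("EBV and SNP-effect writers round-trip", {
  ex <- worked_example(1)
  sol <- solve_snp_blup(ex$gm, ex$y, lambda = 1)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ebv(sol, tf, ids = ex$gm$ids)
  back <- utils::read.delim(tf)
  expect_equal(back$g_hat, sol$g_hat, tolerance = 1e-6)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_snp_effects(sol, tf2)
  expect_equal(utils::read.delim(tf2)$b_hat, sol$b_hat, tolerance = 1e-6)
})
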