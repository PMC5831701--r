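# Dense inversion is the oracle throughout: every operator must agree with
# solve()/chol2inv() of its own approximated-and-regularized matrix.

dense_inverse <- function(M) chol2inv(chol(M))

test_that("GRM construction: Method 1, weights, and degenerate inputs", {
  gm <- center_genotypes(random_geno(12, 30, seed = 51))
  g1 <- build_grm(gm)
  gw <- build_grm(gm, method = "weighted", D = rep(1, 30))
  expect_equal(gw$G, g1$G, tolerance = 1e-12)
  expect_equal(gw$rho, g1$rho)
  expect_true(isSymmetric(g1$G))

  # identical individuals share identical rows
  raw <- random_geno(6, 20, seed = 52)
  raw$dosages[2, ] <- raw$dosages[1, ]
  G <- build_grm(center_genotypes(raw))$G
  expect_equal(G[1, ], G[2, ], tolerance = 1e-12)

  # Method-2 weighting: trace identity gives mean diagonal ~ 1
  gm2 <- center_genotypes(random_geno(10, 100, seed = 53))
  D2 <- vanraden2_weights(gm2)
  Gw <- build_grm(gm2, method = "weighted", D = D2)
  expect_equal(mean(diag(Gw$G)), 1, tolerance = 0.15)

  expect_error(build_grm(random_geno(5, 5)), "center")
  expect_error(build_grm(gm, method = "weighted"), "weights")
})

test_that("positive (semi)definiteness of the regularized GRM", {
  gm <- center_genotypes(random_geno(25, 15, seed = 54))  # rank-deficient
  grm <- build_grm(gm, theta = 1e-3)
  Gt <- gtilde(grm)
  set.seed(55)
  for (i in 1:5) {
    z <- rnorm(25)
    expect_gt(drop(t(z) %*% Gt %*% z), 0)
  }
  expect_gte(min(eigen(Gt, symmetric = TRUE, only.values = TRUE)$values),
             1e-3 - 1e-10)
})

make_scores <- function(gm, core_frac = 0.6, threshold = 0.95,
                        by_chromosome = TRUE, two_stage = FALSE) {
  core <- gm$ids[seq_len(ceiling(gm$n * core_frac))]
  basis <- core_svd(gm, core, threshold = threshold,
                    by_chromosome = by_chromosome)
  sc <- project_scores(gm, basis)
  if (two_stage) sc <- two_stage_svd(sc)
  list(basis = basis, scores = sc)
}

test_that("PCIG operator equals dense inversion of its own Gtilde", {
  gm <- center_genotypes(random_geno(30, 200, n_chrom = 2, seed = 56))
  rho <- rho_scaling(gm)
  theta <- 1e-3
  ms <- make_scores(gm, two_stage = TRUE)
  op <- pcig_inverse(ms$scores, rho = rho, theta = theta)
  oracle <- dense_inverse(tcrossprod(ms$scores$that) / rho + diag(theta, 30))
  expect_lt(max(abs(materialize(op) - oracle)), 1e-9)
  # Gtilde * inverse = I
  expect_equal(operator_gtilde(op) %*% materialize(op), diag(30),
               tolerance = 1e-8)
})

test_that("C-path and two-stage path give the same operator action", {
  gm <- center_genotypes(random_geno(25, 120, n_chrom = 2, seed = 57))
  rho <- rho_scaling(gm)
  ms <- make_scores(gm)
  op_c <- pcig_inverse(ms$scores, rho = rho, theta = 1e-3)
  op_t <- pcig_inverse(two_stage_svd(ms$scores), rho = rho, theta = 1e-3)
  set.seed(58)
  for (i in 1:3) {
    z <- rnorm(25)
    expect_lt(max(abs(materialize(op_c) %*% z - materialize(op_t) %*% z)),
              1e-10 * max(abs(materialize(op_c) %*% z)) + 1e-10)
  }
})

test_that("zero scores give the pure-ridge inverse I / theta", {
  sc <- structure(list(C = matrix(0, 6, 0), stage = "reduced", n = 6L,
                       ids = paste0("i", 1:6)), class = "score_matrix")
  op <- pcig_inverse(sc, rho = 3, theta = 1e-3)
  expect_equal(materialize(op), diag(6) / 1e-3)
  expect_error(pcig_inverse(sc, rho = 3, theta = 0), "positive")
})

test_that("marker-side Woodbury inverse agrees with the dense oracle", {
  gm <- center_genotypes(random_geno(50, 10, seed = 59))
  rho <- rho_scaling(gm)
  theta <- 1e-3
  op <- woodbury_inverse_markers(gm, theta = theta)
  Gt <- tcrossprod(gm$dosages) / rho + diag(theta, 50)
  expect_lt(max(abs(materialize(op) - solve(Gt))), 1e-9)
  expect_warning(woodbury_inverse_markers(center_genotypes(random_geno(5, 10, seed = 60))),
                 "dense")
  # theta controls the deviation of the resulting GBLUP solutions
  set.seed(61); y <- rnorm(50)
  g_ref <- solve_gblup(tcrossprod(gm$dosages) / rho, y, lambda_g = 1,
                       form = "noninverse")$g_hat
  d3 <- max(abs(solve_gblup(woodbury_inverse_markers(gm, theta = 1e-3), y,
                            lambda_g = 1)$g_hat - g_ref))
  d6 <- max(abs(solve_gblup(woodbury_inverse_markers(gm, theta = 1e-6), y,
                            lambda_g = 1)$g_hat - g_ref))
  expect_lt(d6, d3)
})

test_that("QRIG: dense oracle, duplicates, chromosome-wise combine", {
  gm <- center_genotypes(random_geno(20, 80, n_chrom = 2, seed = 62))
  rho <- rho_scaling(gm)
  theta <- 1e-3
  # core = everyone: G approximation is exact, so the operator must match
  # the dense inverse of G + I theta
  op_all <- qrig_inverse(gm, gm$ids, theta = theta)
  Gt <- tcrossprod(gm$dosages) / rho + diag(theta, 20)
  expect_lt(max(abs(materialize(op_all) - solve(Gt))), 1e-9)

  # a non-core duplicate of a core animal gets that animal's R-hat column
  raw <- random_geno(10, 40, seed = 63)
  raw$dosages[10, ] <- raw$dosages[1, ]
  gmd <- center_genotypes(raw)
  opd <- qrig_inverse(gmd, gmd$ids[1:6], theta = theta)
  expect_equal(opd$A[10, ], opd$A[1, ], tolerance = 1e-10)

  # chromosome-wise path equals the genome-wide operator
  op_chr <- qrig_inverse(gm, gm$ids[1:12], theta = theta, by_chromosome = TRUE)
  op_gw <- qrig_inverse(gm, gm$ids[1:12], theta = theta, by_chromosome = FALSE)
  expect_lt(max(abs(materialize(op_chr) - materialize(op_gw))), 1e-9)
})

test_that("weighted PCIG: identity weights reduce to PCIG, oracle holds", {
  gm <- center_genotypes(random_geno(20, 60, n_chrom = 2, seed = 64))
  ms <- make_scores(gm, threshold = 0.98)
  rho <- rho_scaling(gm)
  theta <- 1e-3
  op_w <- weighted_pcig_inverse(ms$scores, ms$basis, D = rep(1, 60),
                                rho = rho, theta = theta)
  op_p <- pcig_inverse(ms$scores, rho = rho, theta = theta)
  expect_lt(max(abs(materialize(op_w) - materialize(op_p))), 1e-10)

  D <- vanraden2_weights(gm)
  rho_w <- rho_scaling(gm, D)
  op_w2 <- weighted_pcig_inverse(ms$scores, ms$basis, D = D, rho = rho_w,
                                 theta = theta)
  # oracle: dense inverse of (C F C' / rho + I theta)
  Fn <- op_w2$F_n
  Gt <- ms$scores$C %*% Fn %*% t(ms$scores$C) / rho_w + diag(theta, 20)
  expect_lt(max(abs(materialize(op_w2) - solve(Gt))), 1e-9)
  expect_equal(operator_gtilde(op_w2), Gt, tolerance = 1e-12)
})

test_that("weighted GRM on centered dosages tracks Method 1 on standardized", {
  raw <- random_geno(15, 80, seed = 65)
  gm_c <- center_genotypes(raw)
  gm_s <- standardize_genotypes(raw)
  D <- vanraden2_weights(gm_c)
  Gw <- build_grm(gm_c, method = "weighted", D = D)
  Gs <- build_grm(gm_s)
  # X D X' with D = 1/(2p(1-p)) is exactly the standardized cross-product;
  # the two differ only through rho (k vs 2 sum p(1-p) of the standardized
  # matrix's own scaling), both equal k here
  expect_equal(rho_scaling(gm_c, D), 80)
  expect_equal(Gw$G, tcrossprod(gm_s$dosages) / 80, tolerance = 1e-10)
  expect_equal(Gw$G, Gs$G * Gs$rho / 80, tolerance = 1e-10)
})

test_that("APY: exact with full core, duplicate handling, approximation", {
  gm <- center_genotypes(random_geno(15, 60, seed = 66))
  grm <- build_grm(gm, theta = 1e-3)
  op <- apy_inverse(grm, core_ids = gm$ids)
  expect_lt(max(abs(materialize(op) - dense_inverse(gtilde(grm)))), 1e-8)

  # a non-core duplicate of a core animal has conditional variance <= theta
  raw <- random_geno(10, 50, seed = 67)
  raw$dosages[10, ] <- raw$dosages[2, ]
  grm_d <- build_grm(center_genotypes(raw), theta = 1e-3)
  op_d <- apy_inverse(grm_d, core_ids = grm_d$ids[1:8])
  dup_pos <- match(10L, op_d$noncore_idx)
  # theta enters both the core block and the non-core diagonal (the
  # regularization is G + I theta on the whole matrix), so the duplicate's
  # conditional variance is bounded by ~2 theta rather than theta
  expect_lte(op_d$d_nc[dup_pos], 2e-3 + 1e-6)

  # parts interface matches the grm interface
  core <- gm$ids[1:8]
  cidx <- 1:8; nidx <- 9:15
  op_parts <- apy_inverse(grm$G[cidx, cidx], G_nc = grm$G[nidx, cidx],
                          g_nn = diag(grm$G)[nidx], theta = 1e-3)
  op_grm <- apy_inverse(grm, core_ids = core)
  expect_equal(materialize(op_parts), materialize(op_grm), tolerance = 1e-12)
})

test_that("APY GBLUP tracks dense GBLUP on structured genotypes", {
  sim <- small_sim()
  gm <- center_genotypes(sim$genotypes)
  grm <- build_grm(gm, theta = 1e-3)
  y <- sim$phenotypes - mean(sim$phenotypes)
  lambda_g <- sim$sigma_e2
  g_dense <- solve_gblup(grm, y, lambda_g = lambda_g)$g_hat
  op <- apy_inverse(grm, core_ids = gm$ids[1:100])
  g_apy <- solve_gblup(op, y, lambda_g = lambda_g)$g_hat
  expect_gte(cor(g_dense, g_apy), 0.95)
})

test_that("row-wise inversion equals full materialization", {
  gm <- center_genotypes(random_geno(20, 70, n_chrom = 2, seed = 68))
  rho <- rho_scaling(gm)
  ops <- list(
    pcig = pcig_inverse(make_scores(gm, two_stage = TRUE)$scores, rho, 1e-3),
    qrig = qrig_inverse(gm, gm$ids[1:10], theta = 1e-3),
    apy = apy_inverse(build_grm(gm, theta = 1e-3), core_ids = gm$ids[1:10])
  )
  for (nm in names(ops)) {
    op <- ops[[nm]]
    full <- materialize(op)
    stacked <- t(vapply(1:20, function(i) inverse_row(op, i), numeric(20)))
    expect_equal(stacked, full, tolerance = 1e-9, info = nm)
    expect_equal(inverse_row(op, 7), full[, 7], tolerance = 1e-9, info = nm)
    expect_error(inverse_row(op, 21), "range")
  }
  # dense oracle for one row
  op <- ops$pcig
  oracle <- solve(operator_gtilde(op))
  expect_lt(max(abs(inverse_row(op, 7) - oracle[7, ])), 1e-9)
})

test_that("lossless QRIG, PCIG and dense inversion coincide pairwise", {
  gm <- center_genotypes(random_geno(18, 50, n_chrom = 2, seed = 69))
  rho <- rho_scaling(gm)
  theta <- 1e-3
  dense <- dense_inverse(tcrossprod(gm$dosages) / rho + diag(theta, 18))
  basis <- core_svd(gm, gm$ids, threshold = 1, by_chromosome = FALSE)
  op_pcig <- pcig_inverse(project_scores(gm, basis), rho, theta)
  op_qrig <- qrig_inverse(gm, gm$ids, theta = theta)
  expect_lt(max(abs(materialize(op_pcig) - dense)), 1e-8)
  expect_lt(max(abs(materialize(op_qrig) - dense)), 1e-8)
  expect_lt(max(abs(materialize(op_pcig) - materialize(op_qrig))), 1e-8)
})

test_that("triplet export: streaming, filtering and round-trip", {
  gm <- center_genotypes(random_geno(12, 40, seed = 70))
  op <- qrig_inverse(gm, gm$ids[1:8], theta = 1e-3)
  tf_rows <- withr::local_tempfile(fileext = ".txt")
  tf_dense <- withr::local_tempfile(fileext = ".txt")
  export_inverse(op, tf_rows, method = "rows")
  export_inverse(op, tf_dense, method = "dense")
  expect_identical(readLines(tf_rows), readLines(tf_dense))
  back <- read_triplets(tf_rows, 12)
  expect_equal(back, materialize(op), tolerance = 1e-8)

  # pure-diagonal operator exports exactly N diagonal triplets
  sc0 <- structure(list(C = matrix(0, 5, 0), stage = "reduced", n = 5L,
                        ids = paste0("i", 1:5)), class = "score_matrix")
  op0 <- pcig_inverse(sc0, rho = 1, theta = 0.5)
  tf0 <- withr::local_tempfile(fileext = ".txt")
  export_inverse(op0, tf0)
  lines <- readLines(tf0)
  expect_length(lines, 5)
  expect_identical(lines[1], "1 1 2")

  # partial row export
  tf_part <- withr::local_tempfile(fileext = ".txt")
  export_inverse(op, tf_part, rows = 3:5)
  got <- utils::read.table(tf_part, col.names = c("i", "j", "value"))
  expect_setequal(unique(got$i), 3:5)
})
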