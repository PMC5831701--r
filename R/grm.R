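#' Build a genomic relationship matrix
#'
#' VanRaden Method 1, `G = X X' / rho` with `rho = 2 sum p_i (1 - p_i)`
#' from centered dosages, or the weighted form `G = X D X' / rho` with
#' per-locus weights `D` and `rho = 2 sum D_i p_i (1 - p_i)`. A small
#' `theta` added to the diagonal (`G + I theta`) makes the matrix strictly
#' positive definite; it is stored and applied by the solvers and the dense
#' inverse, not baked into `G`.
#'
#' @param gm centered [geno_matrix()] (raw coding is refused).
#' @param method `"vanraden1"` or `"weighted"`.
#' @param D per-locus weights (required for `"weighted"`; `D = 1` reduces
#'   exactly to Method 1).
#' @param theta diagonal regularization kept alongside the matrix
#'   (default 0; use e.g. `1e-3` when an inverse is needed).
#' @return object of class `grm` with fields `G`, `rho`, `theta`,
#'   `weighted`, `D`, `ids`.
#' @export
build_grm <- function(gm, method = c("vanraden1", "weighted"), D = NULL,
                      theta = 0) {
  stopifnot(inherits(gm, "geno_matrix"))
  method <- match.arg(method)
  if (gm$coding == "raw")
    stop("center first: the relationship matrix is defined on centered dosages")
  if (theta < 0) stop("theta must be non-negative")
  X <- gm$dosages
  if (method == "weighted") {
    if (is.null(D)) stop("weighted GRM needs per-locus weights D")
    D <- as.numeric(D)
    if (length(D) == 1) D <- rep(D, gm$k)
    if (length(D) != gm$k) stop("weights D must have one entry per locus")
    if (any(D <= 0)) stop("weights D must be positive")
    rho <- rho_scaling(gm, D)
    G <- tcrossprod(sweep(X, 2L, D, `*`), X) / rho
  } else {
    rho <- rho_scaling(gm)
    G <- tcrossprod(X) / rho
  }
  G <- (G + t(G)) / 2
  structure(
    list(G = G, rho = rho, theta = theta, weighted = method == "weighted",
         D = D, ids = gm$ids),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d x %d, rho = %g, theta = %g%s\n", nrow(x$G), ncol(x$G),
              x$rho, x$theta, if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' Regularized relationship matrix
#'
#' @param x a [build_grm()] object.
#' @return dense `G + I theta`.
#' @export
gtilde <- function(x) {
  stopifnot(inherits(x, "grm"))
  x$G + diag(x$theta, nrow(x$G))
}

# ---------------------------------------------------------------------------
# Inverse operators: implicit representations of
#   Gtilde^{-1} = (1/theta) (I - A M A')
# with A an N x m tall factor and M the m x m inner inverse (a vector when
# diagonal). APY uses its own blockwise representation.
# ---------------------------------------------------------------------------

new_ginv_op <- function(algorithm, theta, rho, n, A = NULL, M = NULL,
                        M_diag = NULL, ids = NULL, extra = list()) {
  structure(
    c(list(algorithm = algorithm, theta = theta, rho = rho, n = n, A = A,
           M = M, M_diag = M_diag, ids = ids), extra),
    class = "grm_inverse_op"
  )
}

#' @export
print.grm_inverse_op <- function(x, ...) {
  m <- if (!is.null(x$A)) ncol(x$A) else if (x$algorithm == "apy")
    length(x$core_idx) else 0L
  cat(sprintf("<grm_inverse_op> %s: N = %d, inner dimension = %d, theta = %g\n",
              x$algorithm, x$n, m, x$theta))
  invisible(x)
}

#' PC-based inverse of the approximated GRM (PCIG)
#'
#' The PC approximation `G ~ T_hat T_hat' / rho` (equivalently `C C' / rho`,
#' since `C C' = T_hat T_hat'`) is regularized to
#' `Gtilde = (T_hat T_hat' + I rho theta) / rho` and inverted exactly by the
#' Woodbury identity:
#' `Gtilde^{-1} = (1/theta) (I - T_hat (S_C^2 + I rho theta)^{-1} T_hat')`.
#' With two-stage scores the inner matrix is diagonal; with reduced scores
#' `C` the dense `sum(q) x sum(q)` system `(C'C + I rho theta)` is factored
#' once. The approximation error of the inverse lives entirely in the score
#' basis: the inversion itself is exact.
#'
#' @param scores a `score_matrix` (reduced or two-stage).
#' @param rho relationship scaling constant (from [rho_scaling()]).
#' @param theta diagonal regularization, strictly positive (default 1e-3).
#' @return a `grm_inverse_op` supporting [materialize()], [inverse_row()]
#'   and [export_inverse()].
#' @export
pcig_inverse <- function(scores, rho, theta = 1e-3) {
  stopifnot(inherits(scores, "score_matrix"))
  if (theta <= 0) stop("theta must be positive")
  if (rho <= 0) stop("rho must be positive")
  if (scores$stage == "two_stage") {
    A <- scores$that
    new_ginv_op("pcig", theta, rho, scores$n, A = A,
                M_diag = 1 / (scores$d^2 + rho * theta), ids = scores$ids)
  } else {
    A <- scores$C
    m <- ncol(A)
    M <- if (m == 0) matrix(0, 0, 0) else
      chol2inv(chol(crossprod(A) + diag(rho * theta, m)))
    new_ginv_op("pcig", theta, rho, scores$n, A = A, M = M, ids = scores$ids)
  }
}

#' Marker-side Woodbury inverse of the regularized GRM
#'
#' When the number of loci is smaller than the number of individuals,
#' `Gtilde = (X X' + I rho theta)/rho` is inverted through the k x k system:
#' `Gtilde^{-1} = (1/theta)(I - X (X'X + I_k rho theta)^{-1} X')`.
#' Valid for any k; a warning notes when `k >= N` and the dense path would
#' be cheaper.
#'
#' @param gm centered [geno_matrix()].
#' @param rho scaling constant (default computed from the frequencies).
#' @param theta positive regularization.
#' @return a `grm_inverse_op`.
#' @export
woodbury_inverse_markers <- function(gm, rho = NULL, theta = 1e-3) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$coding == "raw") stop("center first")
  if (theta <= 0) stop("theta must be positive")
  if (is.null(rho)) rho <- rho_scaling(gm)
  if (gm$k >= gm$n)
    warning("k >= N: dense inversion of the N x N matrix would be cheaper")
  A <- gm$dosages
  M <- chol2inv(chol(crossprod(A) + diag(rho * theta, gm$k)))
  new_ginv_op("woodbury_markers", theta, rho, gm$n, A = A, M = M, ids = gm$ids)
}

#' QR-based inverse of the approximated GRM (QRIG)
#'
#' Genotypes of all individuals are expressed in the row space of a core
#' sample via a QR factorization `X_n' = Q_n R_n`: the extended factor has
#' columns `R_n` for core individuals and `R_hat_{-n}' = X_{-n} Q_n` for the
#' others, so `G ~ R_hat' R_hat / rho` with `R_hat` of size n x N. The
#' regularized inverse follows the same tall-factor Woodbury form as PCIG
#' with `A = R_hat'` and an n x n inner system. With `by_chromosome = TRUE`
#' the factorization is done per chromosome and the stacked `R_in` blocks
#' are combined by a second-stage QR, which yields the identical operator.
#'
#' @param gm centered [geno_matrix()] of the whole population (any row
#'   order; operator rows follow `gm`).
#' @param core_ids core individual identifiers.
#' @param rho scaling constant (default from the frequencies).
#' @param theta positive regularization; rank deficiency of the core is
#'   handled by `theta`, never by dropping columns.
#' @param by_chromosome factorize per chromosome and combine.
#' @return a `grm_inverse_op`.
#' @export
qrig_inverse <- function(gm, core_ids, rho = NULL, theta = 1e-3,
                         by_chromosome = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$coding == "raw") stop("center first")
  if (theta <= 0) stop("theta must be positive")
  if (is.null(rho)) rho <- rho_scaling(gm)
  core_ids <- as.character(core_ids)
  idx <- match(core_ids, gm$ids)
  if (anyNA(idx)) stop("core_ids not in the population")
  n <- length(idx)
  if (n == 0) stop("core sample is empty")
  X <- gm$dosages
  if (by_chromosome) {
    labels <- sort(unique(gm$chrom))
    Wparts <- vector("list", length(labels))
    Rparts <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      cols <- which(gm$chrom == labels[i])
      qr_i <- qr(t(X[idx, cols, drop = FALSE]))
      Q_i <- qr.Q(qr_i)
      Rparts[[i]] <- qr.R(qr_i)              # n x n
      Wparts[[i]] <- X[, cols, drop = FALSE] %*% Q_i   # N x n
    }
    qr2 <- qr(do.call(rbind, Rparts))        # (c*n) x n stacked R blocks
    Q2 <- qr.Q(qr2)
    # genome Q_n = blockdiag(Q_i) %*% Q2, so X %*% Q_n = [W_1 ... W_c] %*% Q2
    Rhat_t <- do.call(cbind, Wparts) %*% Q2  # N x n
  } else {
    qr_n <- qr(t(X[idx, , drop = FALSE]))
    Rhat_t <- X %*% qr.Q(qr_n)               # N x n; core rows recover R_n'
  }
  M <- chol2inv(chol(crossprod(Rhat_t) + diag(rho * theta, n)))
  new_ginv_op("qrig", theta, rho, gm$n, A = Rhat_t, M = M, ids = gm$ids,
              extra = list(core_ids = core_ids))
}

#' Weighted PC-based inverse
#'
#' For a weighted relationship matrix approximated on the core basis,
#' `G ~ C F_n C' / rho` with `F_n = V_nq' D V_nq` (block diagonal over
#' chromosomes for a chromosome-wise basis), the exact regularized inverse
#' is `(1/theta)(I - C (C'C + F_n^{-1} rho theta)^{-1} C')`. With `D = I`
#' this reduces exactly to [pcig_inverse()] on the reduced scores.
#'
#' @param scores reduced `score_matrix` (projection of the population on
#'   `basis`).
#' @param basis the [core_svd()] basis the scores came from.
#' @param D per-locus weights (length k, positive).
#' @param rho weighted scaling constant `2 p' D (1 - p)` (see
#'   [rho_scaling()]).
#' @param theta positive regularization.
#' @return a `grm_inverse_op` (algorithm `"weighted_pcig"`, carrying `F_n`).
#' @export
weighted_pcig_inverse <- function(scores, basis, D, rho, theta = 1e-3) {
  stopifnot(inherits(scores, "score_matrix"), inherits(basis, "core_basis"))
  if (scores$stage != "reduced")
    stop("weighted inverse needs the reduced scores C")
  if (theta <= 0) stop("theta must be positive")
  D <- as.numeric(D)
  if (length(D) != basis$k_total) stop("weights D must have one entry per locus")
  if (any(D <= 0)) stop("weights D must be positive")
  # F_n = V' D V is block diagonal over chromosome blocks
  Fblocks <- lapply(basis$chrom, function(ch) {
    V <- basis$blocks[[ch]]
    crossprod(V, V * D[basis$loci[[ch]]])
  })
  m <- sum(basis$q)
  Fn <- matrix(0, m, m)
  off <- 0L
  for (i in seq_along(Fblocks)) {
    qi <- ncol(Fblocks[[i]])
    if (qi > 0) Fn[(off + 1L):(off + qi), (off + 1L):(off + qi)] <- Fblocks[[i]]
    off <- off + qi
  }
  Fn_inv <- tryCatch(chol2inv(chol(Fn)), error = function(e) NULL)
  if (is.null(Fn_inv)) {
    ev <- eigen(Fn, symmetric = TRUE, only.values = TRUE)$values
    stop("F_n is singular (", sum(ev < max(ev) * 1e-12),
         " null components); check weights and basis rank")
  }
  A <- scores$C
  M <- chol2inv(chol(crossprod(A) + Fn_inv * rho * theta))
  new_ginv_op("weighted_pcig", theta, rho, scores$n, A = A, M = M,
              ids = scores$ids, extra = list(F_n = Fn))
}

#' APY inverse of the regularized GRM
#'
#' The algorithm-for-proven-and-young baseline: genetic values of non-core
#' individuals are modelled as regressions on the core,
#' `g_i = G_ic Gcc^{-1} g_c + eps_i`, with mutually independent residuals,
#' so the non-core block of the inverse is diagonal. The conditional
#' variances `g_ii - G_ic Gcc^{-1} G_ci` are floored at `theta`. `theta` is
#' first added to the diagonal of the supplied relationship parts, matching
#' the regularization used elsewhere. Unlike the Woodbury-family operators
#' this inverse is approximate whenever non-core individuals remain.
#'
#' @param x a [build_grm()] object (its `theta` is used unless overridden),
#'   or a core block `G_cc` when the parts are given explicitly.
#' @param core_ids core identifiers (grm input) or `NULL` (parts input,
#'   where everything in `x` is core).
#' @param G_nc,g_nn non-core x core cross block and non-core diagonal when
#'   calling with explicit parts.
#' @param theta diagonal regularization (default: the grm's own, else 1e-3).
#' @return a `grm_inverse_op` (algorithm `"apy"`); rows/columns follow the
#'   original order of the grm (parts input: core first, then non-core).
#' @export
apy_inverse <- function(x, core_ids = NULL, G_nc = NULL, g_nn = NULL,
                        theta = NULL) {
  if (inherits(x, "grm")) {
    if (is.null(theta)) theta <- if (x$theta > 0) x$theta else 1e-3
    core_ids <- as.character(core_ids)
    cidx <- match(core_ids, x$ids)
    if (anyNA(cidx)) stop("core_ids not in the relationship matrix")
    nidx <- setdiff(seq_along(x$ids), cidx)
    Gcc <- x$G[cidx, cidx, drop = FALSE]
    Gnc <- x$G[nidx, cidx, drop = FALSE]
    gnn <- diag(x$G)[nidx]
    ids <- x$ids
  } else {
    if (is.null(theta)) theta <- 1e-3
    Gcc <- as.matrix(x)
    Gnc <- if (is.null(G_nc)) matrix(0, 0, nrow(Gcc)) else as.matrix(G_nc)
    gnn <- if (is.null(g_nn)) numeric(0) else as.numeric(g_nn)
    cidx <- seq_len(nrow(Gcc))
    nidx <- nrow(Gcc) + seq_along(gnn)
    ids <- NULL
  }
  if (theta <= 0) stop("theta must be positive")
  n_core <- nrow(Gcc)
  Gcc_t <- Gcc + diag(theta, n_core)
  Gcc_inv <- tryCatch(chol2inv(chol(Gcc_t)), error = function(e)
    stop("core relationship block not invertible even after theta"))
  P <- Gnc %*% Gcc_inv                         # n_nc x n_core
  d <- (gnn + theta) - rowSums(P * Gnc)        # conditional variances
  d <- pmax(d, theta)
  new_ginv_op("apy", theta, rho = NA_real_, n = n_core + length(d),
              ids = ids,
              extra = list(core_idx = cidx, noncore_idx = nidx,
                           Gcc_inv = Gcc_inv, P = P, d_nc = d))
}

#' Materialize a GRM inverse operator
#'
#' Forms the dense inverse the operator represents. Intended for moderate N
#' (tests, desk-scale analyses); large analyses should use
#' [inverse_row()] or [export_inverse()] instead.
#'
#' @param op a `grm_inverse_op`.
#' @return dense N x N matrix.
#' @export
materialize <- function(op) {
  stopifnot(inherits(op, "grm_inverse_op"))
  n <- op$n
  if (op$algorithm == "apy") {
    out <- matrix(0, n, n)
    ci <- op$core_idx; ni <- op$noncore_idx
    Dinv <- 1 / op$d_nc
    PtD <- t(op$P) * rep(Dinv, each = ncol(op$P))
    out[ci, ci] <- op$Gcc_inv + PtD %*% op$P
    if (length(ni)) {
      out[ci, ni] <- -PtD
      out[ni, ci] <- -t(PtD)
      out[cbind(ni, ni)] <- Dinv
    }
    return(out)
  }
  A <- op$A
  inner <- if (!is.null(op$M_diag)) A %*% (op$M_diag * t(A)) else
    A %*% op$M %*% t(A)
  (diag(n) - inner) / op$theta
}

#' Single row of a GRM inverse operator
#'
#' Computes row `i` of the materialized inverse without forming the full
#' matrix, enabling row-wise streaming during iteration on data.
#'
#' @param op a `grm_inverse_op`.
#' @param i row index in `1..N`.
#' @return numeric length-N vector.
#' @export
inverse_row <- function(op, i) {
  stopifnot(inherits(op, "grm_inverse_op"))
  n <- op$n
  if (length(i) != 1 || i < 1 || i > n) stop("row index out of range")
  i <- as.integer(i)
  if (op$algorithm == "apy") {
    row <- numeric(n)
    ci <- op$core_idx; ni <- op$noncore_idx
    pos_c <- match(i, ci)
    if (!is.na(pos_c)) {
      Dinv <- 1 / op$d_nc
      v_core <- op$Gcc_inv[pos_c, ] +
        as.numeric(t(op$P) %*% (Dinv * op$P[, pos_c]))
      row[ci] <- v_core
      if (length(ni)) row[ni] <- -(Dinv * op$P[, pos_c])
    } else {
      pos_n <- match(i, ni)
      Dinv_i <- 1 / op$d_nc[pos_n]
      row[ci] <- -Dinv_i * op$P[pos_n, ]
      row[ni[pos_n]] <- Dinv_i
    }
    return(row)
  }
  e <- numeric(n); e[i] <- 1
  ai <- op$A[i, ]
  w <- if (!is.null(op$M_diag)) op$M_diag * ai else as.numeric(op$M %*% ai)
  (e - as.numeric(op$A %*% w)) / op$theta
}

#' The approximated, regularized GRM an operator inverts
#'
#' Returns the dense `Gtilde` whose exact inverse the operator represents:
#' `(A A' / rho) + I theta` for the Woodbury-family algorithms (with the
#' weight matrix `F_n` interposed for the weighted form). Not defined for
#' APY, whose inverse is approximate rather than the exact inverse of a
#' modified matrix.
#'
#' @param op a `grm_inverse_op`.
#' @return dense N x N matrix.
#' @export
operator_gtilde <- function(op) {
  stopifnot(inherits(op, "grm_inverse_op"))
  if (op$algorithm == "apy")
    stop("APY is approximate: it has no exact Gtilde counterpart")
  A <- op$A
  G <- if (op$algorithm == "weighted_pcig") A %*% op$F_n %*% t(A) / op$rho
       else tcrossprod(A) / op$rho
  G + diag(op$theta, op$n)
}

#' Export an inverse operator as sparse triplets
#'
#' Writes the lower triangle (including the diagonal) as whitespace-
#' delimited `i j value` with 1-based indices, streamed row by row so the
#' full matrix is never held (with `method = "dense"` the matrix is
#' materialized first; both paths produce byte-identical files).
#'
#' @param op a `grm_inverse_op`.
#' @param path output file.
#' @param tol magnitude filter; entries with `|value| <= tol` are dropped
#'   (default 0 keeps everything nonzero; the diagonal is always kept).
#' @param method `"rows"` (streamed) or `"dense"`.
#' @param rows optional integer range of rows to export.
#' @return `path`, invisibly.
#' @export
export_inverse <- function(op, path, tol = 0, method = c("rows", "dense"),
                           rows = NULL) {
  stopifnot(inherits(op, "grm_inverse_op"))
  method <- match.arg(method)
  if (is.null(rows)) rows <- seq_len(op$n)
  con <- file(path, "w")
  on.exit(close(con))
  dense <- if (method == "dense") materialize(op) else NULL
  for (i in rows) {
    ri <- if (is.null(dense)) inverse_row(op, i) else dense[i, ]
    j <- seq_len(i)
    v <- ri[j]
    keep <- abs(v) > tol | j == i
    lines <- sprintf("%d %d %.10g", i, j[keep], v[keep])
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a triplet file back into a dense symmetric matrix
#'
#' @param path file written by [export_inverse()].
#' @param n matrix dimension.
#' @return dense symmetric N x N matrix (unstored entries are zero).
#' @export
read_triplets <- function(path, n) {
  df <- utils::read.table(path, col.names = c("i", "j", "value"))
  out <- matrix(0, n, n)
  out[cbind(df$i, df$j)] <- df$value
  out[cbind(df$j, df$i)] <- df$value
  out
}
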