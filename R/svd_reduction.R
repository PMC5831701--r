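#' Economy-sized singular value decomposition
#'
#' Decomposes `X = U S V'` keeping only components whose singular values are
#' numerically nonzero. The cutoff follows the standard numerical-rank rule:
#' a singular value is zero when `S_i <= max(N, k) * eps * S_1` (machine
#' epsilon `eps`), unless an absolute tolerance is given.
#'
#' Singular vectors are defined only up to a per-column sign. By default the
#' factors are returned with the deterministic signs produced by LAPACK;
#' `canonicalize = TRUE` additionally flips each component so that the
#' largest-magnitude entry of its right singular vector is positive, which
#' makes serialized factors comparable across platforms at the cost of
#' possibly differing in sign from conventional solver output.
#'
#' @param X numeric matrix, or a centered/standardized [geno_matrix()].
#' @param tol optional absolute cutoff on singular values.
#' @param canonicalize flip singular-vector signs to a canonical convention.
#' @return object of class `svd_factors` with fields `u` (N x r), `d`
#'   (length r, descending), `v` (k x r) and `rank` r.
#' @export
economy_svd <- function(X, tol = NULL, canonicalize = FALSE) {
  if (inherits(X, "geno_matrix")) {
    if (X$coding == "raw")
      warning("economy_svd on raw dosages; center or standardize first for model use")
    X <- X$dosages
  }
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (min(dim(X)) == 0 || all(X == 0)) {
    return(structure(list(u = matrix(0, nrow(X), 0), d = numeric(0),
                          v = matrix(0, ncol(X), 0), rank = 0L),
                     class = "svd_factors"))
  }
  s <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * .Machine$double.eps * s$d[1]
  r <- sum(s$d > tol)
  out <- structure(
    list(u = s$u[, seq_len(r), drop = FALSE], d = s$d[seq_len(r)],
         v = s$v[, seq_len(r), drop = FALSE], rank = r),
    class = "svd_factors"
  )
  if (canonicalize) canonicalize_signs(out) else out
}

#' Canonicalize singular-vector signs
#'
#' Flips each component so the largest-magnitude entry of its right singular
#' vector is positive (ties broken by the first such entry).
#'
#' @param factors an `svd_factors` object.
#' @return the same object with consistent column signs.
#' @export
canonicalize_signs <- function(factors) {
  stopifnot(inherits(factors, "svd_factors"))
  if (factors$rank == 0L) return(factors)
  flip <- vapply(seq_len(factors$rank), function(j) {
    col <- factors$v[, j]
    col[which.max(abs(col))] < 0
  }, logical(1))
  factors$v[, flip] <- -factors$v[, flip, drop = FALSE]
  factors$u[, flip] <- -factors$u[, flip, drop = FALSE]
  factors
}

#' @export
print.svd_factors <- function(x, ...) {
  cat(sprintf("<svd_factors> rank %d, singular values: %s\n", x$rank,
              paste(signif(utils::head(x$d, 5), 6), collapse = ", ")))
  invisible(x)
}

#' Number of components needed for a variance fraction
#'
#' Returns the smallest `q` such that the leading `q` squared singular
#' values account for at least (`strict`: strictly more than) `threshold`
#' of their total. Components tied (to within numerical tolerance) with the
#' one at the boundary are kept as well, so the choice does not depend on
#' the ordering of ties.
#'
#' @param x an `svd_factors` object or a numeric vector of singular values.
#' @param threshold variance fraction in `(0, 1]`.
#' @param strict require the cumulative fraction to exceed the threshold
#'   strictly rather than reach it.
#' @return integer count of retained components.
#' @export
select_rank <- function(x, threshold, strict = FALSE) {
  d <- if (inherits(x, "svd_factors")) x$d else as.numeric(x)
  if (length(d) == 0) stop("no components to select from")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  frac <- cumsum(d^2) / sum(d^2)
  ok <- if (strict) frac > threshold else frac >= threshold
  q <- if (any(ok)) which(ok)[1] else length(d)
  # keep components tied with the boundary one
  tol <- max(d) * .Machine$double.eps^0.5
  while (q < length(d) && abs(d[q + 1] - d[q]) <= tol) q <- q + 1L
  as.integer(q)
}

#' Core-sample SVD basis
#'
#' Estimates right-singular-vector bases from a core subset of individuals,
#' either genome-wide or independently per chromosome. The genotype matrix
#' must already be centered or standardized with frequencies fixed on the
#' full population, so that core rows and non-core rows share the same
#' column coding. Per block, the number of retained components is the
#' smallest count explaining at least `threshold` of the core variance (see
#' [select_rank()]).
#'
#' @param gm centered/standardized [geno_matrix()] of the whole population.
#' @param core_ids identifiers of the core individuals (a subset of
#'   `gm$ids`).
#' @param threshold per-block explained-variance fraction (default 0.99).
#' @param by_chromosome estimate one basis per chromosome (the default) or a
#'   single genome-wide basis.
#' @param strict,canonicalize passed to [select_rank()] / [economy_svd()].
#' @return object of class `core_basis`: per-chromosome blocks `blocks`
#'   (k_i x q_i matrices with orthonormal columns, chromosome labels in
#'   sorted order), singular values `d`, retained counts `q`, explained
#'   fractions `variance_explained`, `core_ids`, `n_core`, `loci` (column
#'   indices of each block in `gm`), and the selection `threshold`.
#' @export
core_svd <- function(gm, core_ids, threshold = 0.99, by_chromosome = TRUE,
                     strict = FALSE, canonicalize = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$coding == "raw")
    stop("center or standardize the genotype matrix before core_svd")
  core_ids <- as.character(core_ids)
  if (length(core_ids) == 0) stop("core sample is empty")
  if (length(core_ids) > gm$n) stop("core sample larger than the population")
  idx <- match(core_ids, gm$ids)
  if (anyNA(idx)) stop("core_ids not in the population: ",
                       paste(core_ids[is.na(idx)], collapse = ", "))
  Xn <- gm$dosages[idx, , drop = FALSE]
  labels <- if (by_chromosome) sort(unique(gm$chrom)) else "genome"
  loci <- if (by_chromosome) {
    lapply(labels, function(ch) which(gm$chrom == ch))
  } else list(seq_len(gm$k))
  names(loci) <- labels
  blocks <- vector("list", length(labels))
  dlist <- vector("list", length(labels))
  q <- integer(length(labels))
  ve <- numeric(length(labels))
  for (i in seq_along(labels)) {
    fac <- economy_svd(Xn[, loci[[i]], drop = FALSE], canonicalize = canonicalize)
    qi <- if (fac$rank == 0L) 0L else min(select_rank(fac, threshold, strict), fac$rank)
    blocks[[i]] <- fac$v[, seq_len(qi), drop = FALSE]
    dlist[[i]] <- fac$d[seq_len(qi)]
    q[i] <- qi
    ve[i] <- if (fac$rank == 0L) 1 else sum(fac$d[seq_len(qi)]^2) / sum(fac$d^2)
  }
  names(blocks) <- names(dlist) <- names(q) <- names(ve) <- labels
  structure(
    list(blocks = blocks, d = dlist, q = q, variance_explained = ve,
         n_core = length(core_ids), core_ids = core_ids, loci = loci,
         chrom = labels, by_chromosome = by_chromosome, threshold = threshold,
         k_total = gm$k),
    class = "core_basis"
  )
}

#' @export
print.core_basis <- function(x, ...) {
  cat(sprintf("<core_basis> %d core individuals, %s, total components %d\n",
              x$n_core,
              if (x$by_chromosome) sprintf("%d chromosome blocks", length(x$chrom))
              else "genome-wide",
              sum(x$q)))
  for (ch in x$chrom)
    cat(sprintf("  %s: q = %d (%.4f of core variance)\n", ch, x$q[[ch]],
                x$variance_explained[[ch]]))
  invisible(x)
}

#' Project a population onto a core basis
#'
#' Computes the reduced score matrix `C = X V_nq`, per chromosome
#' (`C_i = X_i V_inq`, concatenated in sorted chromosome order) when the
#' basis is chromosome-wise. The genotype matrix must use the same loci,
#' ordering and centering as the one the basis was estimated from.
#'
#' @param gm centered/standardized [geno_matrix()].
#' @param basis a [core_svd()] basis.
#' @return object of class `score_matrix` with fields `C` (N x sum(q)),
#'   `stage = "reduced"`, per-block column counts `q`, and `ids`.
#' @export
project_scores <- function(gm, basis) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(basis, "core_basis"))
  if (gm$coding == "raw") stop("center or standardize before projecting")
  if (gm$k != basis$k_total)
    stop("locus count mismatch between genotype matrix and basis")
  if (basis$by_chromosome) {
    have <- sort(unique(gm$chrom))
    if (!identical(have, basis$chrom))
      stop("chromosome mismatch between genotype matrix and basis")
    for (ch in basis$chrom)
      if (!identical(which(gm$chrom == ch), basis$loci[[ch]]))
        stop("locus-to-chromosome layout differs from the basis")
  }
  parts <- lapply(basis$chrom, function(ch)
    gm$dosages[, basis$loci[[ch]], drop = FALSE] %*% basis$blocks[[ch]])
  C <- do.call(cbind, parts)
  structure(
    list(C = C, stage = "reduced", q = basis$q, chrom = basis$chrom,
         ids = gm$ids, n = gm$n),
    class = "score_matrix"
  )
}

#' Second-stage SVD of the score matrix
#'
#' Decomposes the reduced score matrix `C = U_C S_C V_C'` without further
#' rank reduction (only numerically-zero singular values are dropped) and
#' returns the diagonalized scores `T_hat = U_C S_C`, for which
#' `T_hat' T_hat = S_C^2` is diagonal while `C C' = T_hat T_hat'` is
#' preserved exactly.
#'
#' @param scores a `score_matrix` with `stage = "reduced"`.
#' @param canonicalize passed to [economy_svd()].
#' @return a `score_matrix` with `stage = "two_stage"` carrying `that`
#'   (`T_hat`), singular values `d` (`S_C`), right vectors `v_c` (`V_C`),
#'   and the original `C`.
#' @export
two_stage_svd <- function(scores, canonicalize = FALSE) {
  stopifnot(inherits(scores, "score_matrix"))
  if (scores$stage != "reduced")
    stop("two_stage_svd expects a reduced score matrix")
  fac <- economy_svd(scores$C, canonicalize = canonicalize)
  out <- scores
  out$stage <- "two_stage"
  out$that <- fac$u %*% (if (fac$rank) diag(fac$d, fac$rank) else matrix(0, 0, 0))
  out$d <- fac$d
  out$v_c <- fac$v
  out
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d individuals x %d components (%s)\n",
              x$n, ncol(x$C), x$stage))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Serialization container (write once, reuse): a grouped list saved with R's
# native serializer; layout mirrors /chrom/<label>/{V,S} plus metadata.
# ---------------------------------------------------------------------------

#' Save a core basis and scores to a container file
#'
#' @param path output file.
#' @param basis optional [core_svd()] basis.
#' @param scores optional score matrix.
#' @param operator optional GRM inverse operator.
#' @param metadata optional named list stored verbatim.
#' @return `path`, invisibly.
#' @export
write_svd_container <- function(path, basis = NULL, scores = NULL,
                                operator = NULL, metadata = list()) {
  payload <- list(format = "svdgp-container", version = 1L,
                  basis = basis, scores = scores, operator = operator,
                  metadata = metadata)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a container written by [write_svd_container()]
#'
#' @param path container file.
#' @return list with elements `basis`, `scores`, `operator`, `metadata`.
#' @export
read_svd_container <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "svdgp-container"))
    stop(path, " is not an svdgp container")
  payload
}
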