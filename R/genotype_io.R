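#' Genotype matrix container
#'
#' Holds an N x k matrix of SNP dosages together with the bookkeeping needed
#' by the downstream models: per-locus allele frequencies of the '1' allele,
#' a locus-to-chromosome map, and the coding state of the matrix (raw 0/1/2
#' counts, centered deviations `g - 2p`, or unit-variance standardized
#' deviations).
#'
#' @param dosages numeric N x k matrix. Under `coding = "raw"` entries must
#'   lie in `[0, 2]` (allele counts, or fractional imputed dosages).
#' @param ids character vector of individual identifiers (default: rownames,
#'   else `"id1"..."idN"`).
#' @param chrom length-k chromosome labels (default: a single chromosome
#'   `"1"`). Every locus maps to exactly one chromosome.
#' @param p optional length-k allele frequencies in `[0, 1]`. For raw coding
#'   they default to column means / 2; for pre-centered or standardized input
#'   they cannot be recovered and stay `NA` unless supplied.
#' @param coding one of `"raw"`, `"centered"`, `"standardized"`.
#' @return an object of class `geno_matrix`.
#' @seealso [center_genotypes()], [standardize_genotypes()], [rho_scaling()]
#' @export
geno_matrix <- function(dosages, ids = NULL, chrom = NULL, p = NULL,
                        coding = c("raw", "centered", "standardized")) {
  coding <- match.arg(coding)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  k <- ncol(dosages)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(dosages))) rownames(dosages) else paste0("id", seq_len(n))
  }
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) must equal nrow(dosages)")
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (is.null(chrom)) chrom <- rep("1", k)
  chrom <- as.character(chrom)
  if (length(chrom) != k) stop("chrom must have one label per locus")
  if (anyNA(dosages)) stop("dosages contain missing values; impute or filter first")
  if (coding == "raw") {
    if (length(dosages) && (min(dosages) < 0 || max(dosages) > 2))
      stop("raw dosages must lie in [0, 2]")
    if (is.null(p)) p <- colMeans(dosages) / 2
  }
  if (is.null(p)) p <- rep(NA_real_, k)
  p <- as.numeric(p)
  if (length(p) != k) stop("p must have one frequency per locus")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("allele frequencies must lie in [0, 1]")
  structure(
    list(dosages = dosages, ids = ids, chrom = chrom, p = p, coding = coding,
         n = n, k = k),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d loci, coding: %s\n",
              x$n, x$k, x$coding))
  cat(sprintf("  chromosomes: %s\n", paste(unique(x$chrom), collapse = ", ")))
  mono <- monomorphic_loci(x)
  if (any(mono, na.rm = TRUE))
    cat(sprintf("  monomorphic loci: %d\n", sum(mono, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(x$n, x$k)

#' Flag monomorphic loci
#'
#' A locus is monomorphic when its allele frequency is exactly 0 or 1; such
#' loci carry no genomic variance, become all-zero columns under centering
#' and cannot be standardized.
#'
#' @param gm a [geno_matrix()].
#' @return logical length-k vector (`NA` where the frequency is unknown).
#' @export
monomorphic_loci <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  gm$p == 0 | gm$p == 1
}

resolve_freq <- function(gm, freq_source, p, core_ids) {
  switch(freq_source,
    self = {
      if (gm$coding != "raw")
        stop("freq_source = 'self' needs raw dosages to estimate frequencies")
      colMeans(gm$dosages) / 2
    },
    core = {
      if (is.null(core_ids)) stop("freq_source = 'core' requires core_ids")
      idx <- match(core_ids, gm$ids)
      if (anyNA(idx)) stop("core_ids not found among individuals")
      colMeans(gm$dosages[idx, , drop = FALSE]) / 2
    },
    supplied = {
      if (is.null(p)) stop("freq_source = 'supplied' requires p")
      p <- as.numeric(p)
      if (length(p) != gm$k) stop("supplied p has wrong length")
      p
    }
  )
}

#' Center genotype dosages
#'
#' Replaces each raw dosage column by `g - 2 p_j`, the deviation from its
#' expectation under Hardy-Weinberg at allele frequency `p_j`. Centered
#' columns have mean approximately zero when `p` was estimated from the same
#' individuals. Re-centering an already centered or standardized matrix is
#' rejected rather than silently applied.
#'
#' @param gm a raw-coded [geno_matrix()].
#' @param freq_source where the frequencies come from: the whole matrix
#'   (`"self"`, the default), a core subset (`"core"`), or a supplied vector
#'   (`"supplied"`).
#' @param p frequencies when `freq_source = "supplied"`.
#' @param core_ids core individual ids when `freq_source = "core"`.
#' @return a centered `geno_matrix`; monomorphic loci become all-zero
#'   columns and stay in place.
#' @export
center_genotypes <- function(gm, freq_source = c("self", "core", "supplied"),
                             p = NULL, core_ids = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  freq_source <- match.arg(freq_source)
  if (gm$coding != "raw")
    stop("cannot center a matrix with coding '", gm$coding, "': centering applies to raw dosages only")
  pf <- resolve_freq(gm, freq_source, p, core_ids)
  out <- gm
  out$dosages <- sweep(gm$dosages, 2L, 2 * pf, `-`)
  out$p <- pf
  out$coding <- "centered"
  out$freq_source <- freq_source
  out
}

#' Standardize genotype dosages
#'
#' Maps genotype `g` at locus `j` to `(g - 2 p_j) / sqrt(2 p_j (1 - p_j))`,
#' so each column has unit variance under Hardy-Weinberg when `p` matches the
#' sample. Monomorphic loci (`p` of 0 or 1) have zero variance and are
#' dropped first (with a reported count) when `drop_monomorphic = TRUE`,
#' otherwise they are an error.
#'
#' @inheritParams center_genotypes
#' @param drop_monomorphic drop loci with `p` in `{0, 1}` before scaling.
#' @return a standardized `geno_matrix` (possibly with fewer loci).
#' @export
standardize_genotypes <- function(gm, freq_source = c("self", "core", "supplied"),
                                  p = NULL, core_ids = NULL,
                                  drop_monomorphic = TRUE) {
  stopifnot(inherits(gm, "geno_matrix"))
  freq_source <- match.arg(freq_source)
  if (gm$coding != "raw")
    stop("cannot standardize a matrix with coding '", gm$coding, "'")
  pf <- resolve_freq(gm, freq_source, p, core_ids)
  mono <- pf == 0 | pf == 1
  if (any(mono)) {
    if (!drop_monomorphic)
      stop("monomorphic locus cannot be standardized (", sum(mono), " found)")
    message(sum(mono), " monomorphic loci dropped before standardization")
    gm <- subset_loci(gm, !mono)
    pf <- pf[!mono]
  }
  out <- gm
  out$dosages <- sweep(sweep(gm$dosages, 2L, 2 * pf, `-`), 2L,
                       sqrt(2 * pf * (1 - pf)), `/`)
  out$p <- pf
  out$coding <- "standardized"
  out$freq_source <- freq_source
  out
}

#' Subset a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param loci logical or integer index over loci.
#' @return a `geno_matrix` restricted to the selected loci.
#' @export
subset_loci <- function(gm, loci) {
  stopifnot(inherits(gm, "geno_matrix"))
  out <- gm
  out$dosages <- gm$dosages[, loci, drop = FALSE]
  out$chrom <- gm$chrom[loci]
  out$p <- gm$p[loci]
  out$k <- ncol(out$dosages)
  out
}

#' Subset individuals of a genotype matrix
#'
#' Frequencies and coding are carried over unchanged: subsetting rows of a
#' centered matrix keeps the centering frequencies of the full population,
#' which is what a core-sample analysis requires.
#'
#' @param gm a [geno_matrix()].
#' @param ids individual identifiers to keep (order preserved as given).
#' @return a `geno_matrix` restricted to the selected individuals.
#' @export
subset_individuals <- function(gm, ids) {
  stopifnot(inherits(gm, "geno_matrix"))
  idx <- match(as.character(ids), gm$ids)
  if (anyNA(idx)) stop("unknown individual ids: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  out <- gm
  out$dosages <- gm$dosages[idx, , drop = FALSE]
  out$ids <- gm$ids[idx]
  out$n <- length(idx)
  out
}

#' Scaling constant rho of the genomic relationship matrix
#'
#' Computes `rho = 2 * sum(p_i (1 - p_i))`, the expected variance sum that
#' scales `X X'` to the relationship scale (VanRaden Method 1), or its
#' weighted form `2 * sum(D_i p_i (1 - p_i))`. With the reciprocal
#' heterozygosity weights of [vanraden2_weights()] the weighted constant is
#' exactly the number of loci `k`.
#'
#' @param gm a [geno_matrix()] with known allele frequencies.
#' @param D optional per-locus weights (diagonal of the weight matrix).
#' @return scalar scaling constant.
#' @export
rho_scaling <- function(gm, D = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (anyNA(gm$p))
    stop("allele frequencies unavailable; supply p when constructing the matrix")
  h <- gm$p * (1 - gm$p)
  if (is.null(D)) 2 * sum(h) else {
    D <- as.numeric(D)
    if (length(D) != gm$k) stop("weights D must have one entry per locus")
    2 * sum(D * h)
  }
}

#' VanRaden Method-2 locus weights
#'
#' `D_i = 1 / (2 p_i (1 - p_i))`, giving every locus the same expected
#' contribution to the relationship matrix.
#'
#' @param gm a [geno_matrix()] with known, polymorphic frequencies.
#' @return length-k numeric weight vector.
#' @export
vanraden2_weights <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (anyNA(gm$p)) stop("allele frequencies unavailable")
  if (any(gm$p == 0 | gm$p == 1))
    stop("monomorphic loci have undefined Method-2 weights; drop them first")
  1 / (2 * gm$p * (1 - gm$p))
}

#' Variance components for the ridge systems
#'
#' Bundles the additive genetic variance `sigma_g2`, residual variance
#' `sigma_e2` and heritability `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`;
#' any one of the three can be derived from the other two. The per-SNP
#' effect variance defaults to `sigma_m2 = sigma_g2 / rho` (with
#' `rho = 2 sum p_i(1-p_i)`) once a scaling constant is known, and can be
#' overridden.
#'
#' @param sigma_g2,sigma_e2,h2 supply any two.
#' @param sigma_m2 optional explicit per-SNP effect variance.
#' @param rho optional scaling constant used to derive `sigma_m2`.
#' @return object of class `variance_components` with fields `sigma_g2`,
#'   `sigma_e2`, `h2`, `sigma_m2` (possibly `NA`), `lambda_g`
#'   (`sigma_e2/sigma_g2`) and `lambda_snp` (`sigma_e2/sigma_m2`, `NA`
#'   until `sigma_m2` is known).
#' @export
variance_components <- function(sigma_g2 = NULL, sigma_e2 = NULL, h2 = NULL,
                                sigma_m2 = NULL, rho = NULL) {
  given <- !vapply(list(sigma_g2, sigma_e2, h2), is.null, logical(1))
  if (sum(given) < 2)
    stop("supply at least two of sigma_g2, sigma_e2, h2")
  if (is.null(sigma_g2)) sigma_g2 <- h2 / (1 - h2) * sigma_e2
  if (is.null(sigma_e2)) sigma_e2 <- sigma_g2 * (1 - h2) / h2
  h2 <- sigma_g2 / (sigma_g2 + sigma_e2)
  if (sigma_g2 <= 0 || sigma_e2 <= 0) stop("variances must be positive")
  if (is.null(sigma_m2) && !is.null(rho)) sigma_m2 <- sigma_g2 / rho
  if (!is.null(sigma_m2) && sigma_m2 <= 0) stop("sigma_m2 must be positive")
  structure(
    list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, h2 = h2,
         sigma_m2 = if (is.null(sigma_m2)) NA_real_ else sigma_m2,
         lambda_g = sigma_e2 / sigma_g2,
         lambda_snp = if (is.null(sigma_m2)) NA_real_ else sigma_e2 / sigma_m2),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> sigma_g2 = %g, sigma_e2 = %g, h2 = %.4g\n",
              x$sigma_g2, x$sigma_e2, x$h2))
  if (!is.na(x$sigma_m2))
    cat(sprintf("  sigma_m2 = %g (lambda_snp = %g)\n", x$sigma_m2, x$lambda_snp))
  cat(sprintf("  lambda_g = %g\n", x$lambda_g))
  invisible(x)
}

resolve_lambda_snp <- function(vc, lambda, gm = NULL) {
  if (!is.null(lambda)) {
    if (lambda <= 0) stop("lambda must be positive")
    return(lambda)
  }
  if (is.null(vc)) stop("supply either lambda or variance components")
  if (!is.na(vc$lambda_snp)) return(vc$lambda_snp)
  if (!is.null(gm)) {
    sm2 <- vc$sigma_g2 / rho_scaling(gm)
    return(vc$sigma_e2 / sm2)
  }
  stop("sigma_m2 unknown: supply sigma_m2, rho, or a genotype matrix with frequencies")
}

# ---------------------------------------------------------------------------
# File readers
# ---------------------------------------------------------------------------

#' Read a genotype matrix from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`tsv`}{header `ID <snp1> <snp2> ...`, one individual per row,
#'     tab-delimited dosages.}
#'   \item{`plink_raw`}{PLINK `.raw` dialect: columns
#'     `FID IID PAT MAT SEX PHENOTYPE` followed by per-SNP allele counts;
#'     `IID` becomes the identifier.}
#'   \item{`vcf`}{VCF v4.x read with `VariantAnnotation::readVcf`. The `DS`
#'     (dosage) FORMAT field is preferred when present, else diploid `GT`
#'     calls are counted. Records that are not biallelic SNP-like are
#'     skipped with a warning reporting the count; chromosome labels come
#'     from `CHROM`.}
#' }
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"plink_raw"`, `"vcf"`.
#' @param coding coding of the stored values; `"centered"` allows loading a
#'   pre-centered matrix (as in the worked examples), in which case allele
#'   frequencies are unknown unless `p` is supplied.
#' @param p optional allele frequencies overriding estimation from the data.
#' @param chrom_map optional path to a sidecar TSV `snp_id<TAB>chrom`, or a
#'   named character vector, mapping loci to chromosomes (VCF input carries
#'   its own chromosomes).
#' @param impute_missing mean-impute missing genotypes to `2 p_j`; without
#'   the flag missing genotypes are an error.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_raw", "vcf"),
                           coding = "raw", p = NULL, chrom_map = NULL,
                           impute_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- switch(format,
    tsv = read_genotypes_tsv(path),
    plink_raw = read_genotypes_plink_raw(path),
    vcf = read_genotypes_vcf(path)
  )
  X <- parsed$X
  chrom <- parsed$chrom
  if (!is.null(chrom_map)) {
    map <- if (is.character(chrom_map) && length(chrom_map) == 1 && file.exists(chrom_map)) {
      df <- utils::read.delim(chrom_map, header = TRUE, colClasses = "character")
      stats::setNames(df[[2]], df[[1]])
    } else chrom_map
    hit <- map[colnames(X)]
    if (anyNA(hit)) stop("chromosome map misses loci: ",
                         paste(colnames(X)[is.na(hit)], collapse = ", "))
    chrom <- unname(hit)
  }
  if (anyNA(X)) {
    if (!impute_missing)
      stop("missing genotypes present; set impute_missing = TRUE to mean-impute")
    if (coding != "raw") stop("mean imputation requires raw coding")
    pj <- if (is.null(p)) colMeans(X, na.rm = TRUE) / 2 else p
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- 2 * pj[j]
  }
  geno_matrix(X, chrom = chrom, p = p, coding = coding)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  list(X = X, chrom = NULL)
}

read_genotypes_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(df)[seq_along(meta)]))
    stop("not a PLINK .raw file: expected leading columns ",
         paste(meta, collapse = " "))
  X <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(df$IID)
  list(X = X, chrom = NULL)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  nalt <- lengths(altl)
  alt1 <- rep(NA_character_, length(nalt))
  alt1[nalt == 1] <- as.character(unlist(altl[nalt == 1]))
  biallelic <- nalt == 1 & nchar(ref) == 1 & nchar(alt1) == 1
  if (any(!biallelic))
    warning(sum(!biallelic), " non-biallelic VCF records skipped")
  vcf <- vcf[biallelic, ]
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    D <- gen$DS
    storage.mode(D) <- "double"
  } else if ("GT" %in% names(gen)) {
    gt <- gen$GT
    D <- matrix(NA_real_, nrow(gt), ncol(gt))
    clean <- gsub("\\|", "/", gt)
    D[clean == "0/0"] <- 0
    D[clean %in% c("0/1", "1/0")] <- 1
    D[clean == "1/1"] <- 2
    D[clean %in% c("./.", ".")] <- NA_real_
  } else stop("VCF has neither DS nor GT genotype fields")
  X <- t(D)
  colnames(X) <- rownames(vcf)
  rownames(X) <- colnames(gen[[1]])
  chrom <- as.character(GenomeInfoDb::seqnames(SummarizedExperiment::rowRanges(vcf)))
  list(X = X, chrom = chrom)
}

#' Read a phenotype table
#'
#' Tab-delimited with a header; first column individual id, second column the
#' trait value.
#'
#' @param path file path.
#' @return data.frame with columns `id` (character) and `y` (numeric).
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE)
  out <- data.frame(id = as.character(df[[1]]), y = as.numeric(df[[2]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$y)) stop("non-numeric phenotype values in ", path)
  out
}

#' Align phenotypes to a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param pheno data.frame as returned by [read_phenotypes()], or a numeric
#'   vector already in matrix row order.
#' @return numeric vector of trait values in the row order of `gm`.
#' @export
align_phenotypes <- function(gm, pheno) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.numeric(pheno)) {
    if (length(pheno) != gm$n) stop("phenotype length does not match individuals")
    return(as.numeric(pheno))
  }
  idx <- match(gm$ids, pheno$id)
  if (anyNA(idx)) stop("phenotypes missing for: ",
                       paste(gm$ids[is.na(idx)], collapse = ", "))
  pheno$y[idx]
}
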