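#' Worked-example fixtures
#'
#' Two small centered genotype matrices used throughout the documentation
#' and tests: a 4-individual x 5-locus matrix of rank 3 (more loci than
#' animals, linearly dependent genotypes) and its 5-individual extension in
#' which the added animal duplicates the first, so the first four
#' individuals form a natural core sample. Phenotypes accompany both.
#' The fixtures are shipped as TSV files under `extdata` and loaded through
#' [read_genotypes()] with the `"centered"` coding override.
#'
#' @param which `1` (4 x 5) or `2` (5 x 5).
#' @return list with elements `gm` (a centered [geno_matrix()]), `X` (its
#'   dosage matrix) and `y` (phenotypes in row order).
#' @examples
#' ex <- worked_example(1)
#' solve_snp_blup(ex$gm, ex$y, lambda = 1)
#' @export
worked_example <- function(which = 1) {
  stopifnot(which %in% c(1, 2))
  gfile <- system.file("extdata",
                       sprintf("example%d_genotypes.tsv", which),
                       package = "svdgp", mustWork = TRUE)
  pfile <- system.file("extdata",
                       sprintf("example%d_phenotypes.tsv", which),
                       package = "svdgp", mustWork = TRUE)
  gm <- read_genotypes(gfile, format = "tsv", coding = "centered")
  ph <- read_phenotypes(pfile)
  list(gm = gm, X = gm$dosages, y = align_phenotypes(gm, ph))
}
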