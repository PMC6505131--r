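#' Construct a genotype matrix
#'
#' The central container of the package: per-site metadata plus a sites x
#' samples matrix of diploid genotypes coded as copies of the FIRST (reference)
#' allele -- 2 = homozygous reference, 1 = heterozygous, 0 = homozygous
#' alternate, `NA` = missing call.  This mirrors the flat "gd_snp" genotype
#' coding used by the Galaxy Genome Diversity tools.
#'
#' @param sites data.frame with one row per variant and at least columns
#'   `scaffold`, `pos` (1-based), `ref`, `alt`.  Optional numeric columns
#'   `qual`, `total_depth`, `mean_mapq`, `mq0_fraction` are used by the site
#'   filters.
#' @param geno integer matrix, `nrow(sites)` rows, one column per sample
#'   (column names are the sample ids); entries in `{0, 1, 2, NA}`.
#' @return an object of class `genotype_matrix` with elements `sites`,
#'   `geno` and `samples`.
#' @export
genotype_matrix <- function(sites, geno) {
  stopifnot(is.data.frame(sites), is.matrix(geno))
  need <- c("scaffold", "pos", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(sites) != nrow(geno))
    stop("sites and geno disagree on the number of variants")
  if (is.null(colnames(geno))) stop("geno must have sample ids as column names")
  if (any(sites$pos < 1)) stop("positions must be 1-based (>= 1)")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotypes must be copies of the first allele in {0, 1, 2} or NA")
  storage.mode(geno) <- "integer"
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno, samples = colnames(geno)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  cat(sprintf("  scaffolds: %s\n",
              paste(unique(x$sites$scaffold), collapse = ", ")))
  nm <- sum(is.na(x$geno))
  cat(sprintf("  missing genotypes: %d (%.2f%%)\n",
              nm, 100 * nm / max(1L, length(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a genotype matrix by site index
#'
#' @param gm a [genotype_matrix()]
#' @param i integer or logical index over sites
#' @return a `genotype_matrix` with the selected sites, order preserved
#' @export
subset_sites <- function(gm, i) {
  stopifnot(inherits(gm, "genotype_matrix"))
  genotype_matrix(gm$sites[i, , drop = FALSE],
                  gm$geno[i, , drop = FALSE])
}

#' Read a two-column sample-to-population table
#'
#' @param path TSV with columns `sample` and `population` (header optional if
#'   exactly two columns).
#' @return named character vector mapping sample id to population label
#' @export
read_pop_map <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(tab))) {
    tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("sample", "population"))
  }
  stats::setNames(as.character(tab$population), as.character(tab$sample))
}

# Split a pop map into exactly two sample-id sets, in label order of first
# appearance.  Used by every two-population contrast.
pop_split <- function(gm, pops) {
  if (is.data.frame(pops))
    pops <- stats::setNames(as.character(pops$population), as.character(pops$sample))
  absent <- setdiff(names(pops), gm$samples)
  if (length(absent))
    stop("sample(s) not present in the genotype matrix: ",
         paste(absent, collapse = ", "))
  labs <- unique(unname(pops))
  if (length(labs) != 2L)
    stop("exactly two population labels are required, got: ",
         paste(labs, collapse = ", "))
  lapply(stats::setNames(labs, labs), function(l) names(pops)[pops == l])
}
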