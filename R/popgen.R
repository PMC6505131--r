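#' Per-site allele counts by population
#'
#' Aggregates a genotype matrix into per-site, per-population allele counts:
#' `a` = observed copies of the first (reference) allele over non-missing
#' samples, `n` = number of chromosomes sampled (2 x non-missing diploids).
#' Sites where either population is entirely missing are flagged
#' (`valid = FALSE`) and excluded from F_ST downstream.
#'
#' @param gm a [genotype_matrix()]
#' @param pops named vector (sample -> population label) or two-column
#'   data.frame; exactly two labels
#' @return data.frame with one row per site: `scaffold`, `pos`, `a1`, `n1`,
#'   `a2`, `n2`, `valid`
#' @export
aggregate_counts <- function(gm, pops) {
  stopifnot(inherits(gm, "genotype_matrix"))
  grp <- pop_split(gm, pops)
  g1 <- gm$geno[, grp[[1L]], drop = FALSE]
  g2 <- gm$geno[, grp[[2L]], drop = FALSE]
  a1 <- rowSums(g1, na.rm = TRUE); n1 <- 2L * rowSums(!is.na(g1))
  a2 <- rowSums(g2, na.rm = TRUE); n2 <- 2L * rowSums(!is.na(g2))
  out <- data.frame(scaffold = gm$sites$scaffold, pos = gm$sites$pos,
                    a1 = a1, n1 = n1, a2 = a2, n2 = n2,
                    valid = n1 > 0L & n2 > 0L,
                    stringsAsFactors = FALSE)
  attr(out, "populations") <- names(grp)
  out
}

#' Reich-Patterson unbiased per-site F_ST
#'
#' The finite-sample-corrected estimator for two populations with `a_i`
#' copies of an allele out of `n_i` sampled chromosomes.  With
#' `p_i = a_i / n_i` and `h_i = a_i (n_i - a_i) / (n_i (n_i - 1))`:
#' \deqn{N = (p_1 - p_2)^2 - h_1/n_1 - h_2/n_2, \quad D = N + h_1 + h_2,
#'       \quad F_{ST} = N / D.}
#' The estimate can be negative for undifferentiated sites and equals 1
#' exactly at a reciprocally fixed site.  When `D = 0` (both populations
#' monomorphic for the same allele) the estimate is undefined and returned
#' as `NA`.
#'
#' All arguments are vectorized over sites.
#'
#' @param a1,n1 allele copies and chromosomes sampled in population 1
#' @param a2,n2 same for population 2
#' @return data.frame with columns `N`, `D`, `fst`
#' @export
fst_reich <- function(a1, n1, a2, n2) {
  if (any(n1 < 2L | n2 < 2L, na.rm = TRUE))
    stop("F_ST requires at least 2 chromosomes sampled per population")
  p1 <- a1 / n1; p2 <- a2 / n2
  h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
  h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
  N <- (p1 - p2)^2 - h1 / n1 - h2 / n2
  D <- N + h1 + h2
  fst <- ifelse(D == 0, NA_real_, N / D)
  data.frame(N = N, D = D, fst = fst)
}

#' Per-site F_ST table for a genotype matrix
#'
#' Convenience wrapper: [aggregate_counts()] followed by [fst_reich()].
#' Sites with an all-missing population or an undefined estimate (`D = 0`)
#' carry `fst = NA` and are excluded from [fst_overall()] and the island
#' scan.
#'
#' @inheritParams aggregate_counts
#' @return data.frame: `scaffold`, `pos`, `a1`, `n1`, `a2`, `n2`, `N`, `D`,
#'   `fst`
#' @export
fst_table <- function(gm, pops) {
  cnt <- aggregate_counts(gm, pops)
  est <- data.frame(N = NA_real_, D = NA_real_, fst = NA_real_)[rep(1L, nrow(cnt)), ]
  if (any(cnt$valid))
    est[cnt$valid, ] <- fst_reich(cnt$a1[cnt$valid], cnt$n1[cnt$valid],
                                  cnt$a2[cnt$valid], cnt$n2[cnt$valid])
  out <- cbind(cnt[c("scaffold", "pos", "a1", "n1", "a2", "n2")], est)
  rownames(out) <- NULL
  out
}

#' Genome-wide F_ST
#'
#' Combines per-site Reich-Patterson components into a genome-wide estimate
#' as the ratio of sums `sum(N) / sum(D)` over all defined sites (the
#' standard way to combine this estimator).  The mean of the per-site ratios
#' is also reported, since genome-wide averages of per-SNV F_ST are often
#' quoted; the two differ whenever information content varies across sites.
#'
#' @param fst_tab a [fst_table()] result (or any data.frame with `N`, `D`,
#'   `fst`)
#' @return list: `ratio_of_sums`, `mean_of_ratios`, `n_sites` (sites with a
#'   defined estimate)
#' @export
fst_overall <- function(fst_tab) {
  ok <- !is.na(fst_tab$fst)
  if (!any(ok)) stop("no sites with a defined F_ST estimate")
  sD <- sum(fst_tab$D[ok])
  if (sD == 0) stop("sum of denominators is zero; overall F_ST undefined")
  list(ratio_of_sums = sum(fst_tab$N[ok]) / sD,
       mean_of_ratios = mean(fst_tab$fst[ok]),
       n_sites = sum(ok))
}

#' Windowed nucleotide diversity, d_XY and mean F_ST
#'
#' Cuts each scaffold into fixed-width non-overlapping windows and, per
#' window, averages over its SNVs: within-population diversity
#' `pi = 2 p (1 - p) n / (n - 1)` for each population, absolute divergence
#' `dxy = p1 (1 - p2) + p2 (1 - p1)`, and the mean per-site F_ST.  Averages
#' are per SNV (the window's polymorphic-site denominator), and the SNV
#' count is reported so a per-base normalization can be recomputed.  Sites
#' monomorphic across both populations carry no information and are ignored;
#' windows with fewer than `min_snvs` informative SNVs are omitted.
#'
#' @inheritParams aggregate_counts
#' @param window window width in bases (default 500)
#' @param min_snvs minimum SNVs per retained window (default 10)
#' @return data.frame of class `window_stats`: `scaffold`, `start`, `end`
#'   (1-based inclusive), `n_snvs`, `pi_pop1`, `pi_pop2`, `dxy`, `mean_fst`
#' @export
window_stats <- function(gm, pops, window = 500L, min_snvs = 10L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  s <- gm$sites
  blocks <- rle(as.character(s$scaffold))$values
  if (any(duplicated(blocks)) ||
      any(vapply(split(s$pos, s$scaffold), is.unsorted, logical(1L))))
    stop("sites must be sorted by position within contiguous scaffold blocks")
  cnt <- aggregate_counts(gm, pops)
  fst <- fst_table(gm, pops)
  tot_a <- cnt$a1 + cnt$a2; tot_n <- cnt$n1 + cnt$n2
  informative <- cnt$valid & tot_a > 0L & tot_a < tot_n
  p1 <- cnt$a1 / cnt$n1; p2 <- cnt$a2 / cnt$n2
  pi1 <- 2 * p1 * (1 - p1) * cnt$n1 / (cnt$n1 - 1)
  pi2 <- 2 * p2 * (1 - p2) * cnt$n2 / (cnt$n2 - 1)
  dxy <- p1 * (1 - p2) + p2 * (1 - p1)
  win <- (s$pos - 1L) %/% as.integer(window)
  key <- paste(s$scaffold, win, sep = "\r")
  res <- lapply(split(which(informative), key[informative]), function(idx) {
    data.frame(scaffold = s$scaffold[idx[1L]],
               start = (win[idx[1L]]) * window + 1L,
               end = (win[idx[1L]] + 1L) * window,
               n_snvs = length(idx),
               pi_pop1 = mean(pi1[idx]), pi_pop2 = mean(pi2[idx]),
               dxy = mean(dxy[idx]),
               mean_fst = mean(fst$fst[idx], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(scaffold = character(), start = integer(),
                                      end = integer(), n_snvs = integer(),
                                      pi_pop1 = numeric(), pi_pop2 = numeric(),
                                      dxy = numeric(), mean_fst = numeric())
  out <- out[out$n_snvs >= min_snvs, , drop = FALSE]
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Pairwise genotype distance matrix
#'
#' The genetic distance between two diploid samples at one SNV is the
#' absolute difference of their reference-allele copy counts (so genotypes
#' 2 and 1 are at distance 1); the overall distance is the sum over all
#' sites where both calls are non-missing.
#'
#' @param gm a [genotype_matrix()] with at least two samples
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames
#' @export
pairwise_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ns <- length(gm$samples)
  if (ns < 2L) stop("at least two samples are required")
  d <- matrix(0, ns, ns, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    diff <- abs(gm$geno[, i] - gm$geno[, j])
    d[i, j] <- d[j, i] <- sum(diff, na.rm = TRUE)
  }
  d
}

#' Identity-by-state matrix
#'
#' `IBS(i, j) = 1 - sum(|g_i - g_j|) / (2 * sites compared)`, the genome-wide
#' average allele sharing between two samples; 1 for identical genotypes,
#' 0 for reciprocally fixed homozygotes at every site.  Pairs with no
#' jointly called site get `NA`.
#'
#' @inheritParams pairwise_distance
#' @return symmetric matrix in `[0, 1]` with unit diagonal
#' @export
ibs_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ns <- length(gm$samples)
  if (ns < 2L) stop("at least two samples are required")
  m <- matrix(1, ns, ns, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    both <- !is.na(gm$geno[, i]) & !is.na(gm$geno[, j])
    nc <- sum(both)
    m[i, j] <- m[j, i] <- if (nc == 0L) NA_real_ else
      1 - sum(abs(gm$geno[both, i] - gm$geno[both, j])) / (2 * nc)
  }
  m
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]) with a post-pass that
#' clamps any negative branch length to zero and transfers the deficit to
#' the sister edge at the same node, preserving path lengths through the
#' node — the usual remedy for the small negative branches NJ can produce
#' on noisy or non-additive distances.
#'
#' @param dm symmetric distance matrix with zero diagonal (e.g. from
#'   [pairwise_distance()]); at least 3 taxa
#' @return an [ape] `phylo` object (unrooted)
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("neighbour joining needs at least 3 taxa")
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs))
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
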