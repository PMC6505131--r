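#' Read a gene-to-pathway membership table
#'
#' @param path TSV with columns `gene` and `pathway` (one membership per
#'   row)
#' @return named list: pathway id -> character vector of member genes
#' @export
read_pathways <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway") %in% names(tab)))
    stop("pathway table needs columns gene and pathway")
  lapply(split(as.character(tab$gene), tab$pathway), unique)
}

#' Two-tailed Fisher's exact test for pathway membership
#'
#' Probability, under the hypergeometric null, of drawing a 2x2 table at
#' least as unlikely as the observed one: `k` of the `n` target genes fall
#' in a pathway of `K` genes out of a universe of `N`.  The two-tailed
#' p-value sums the probabilities of all values of `k` whose point
#' probability does not exceed the observed one (the convention used by
#' [stats::fisher.test()]).
#'
#' @param k target genes in the pathway
#' @param K pathway size
#' @param n target-set size
#' @param N universe size
#' @return two-tailed p-value
#' @export
fisher_pathway <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || k < max(0L, n - (N - K)) ||
      any(c(k, K, n, N) < 0L))
    stop("inconsistent margins: k=", k, " K=", K, " n=", n, " N=", N)
  if (N == 0L) return(1)
  support <- max(0L, n - (N - K)):min(n, K)
  pr <- dhyper(support, K, N - K, n)
  obs <- dhyper(k, K, N - K, n)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Rank pathways by over-representation of a target gene set
#'
#' One row per pathway: pathway size `K`, overlap `k` with the target set,
#' fraction `k / K`, and the two-tailed Fisher p-value against the
#' hypergeometric null over the gene universe (by default every gene
#' annotated to any pathway).  Target genes outside the universe are
#' dropped with a message.
#'
#' @param target_genes character vector of genes of interest (e.g. genes
#'   carrying fixed differences)
#' @param pathways named list, pathway id -> member genes (see
#'   [read_pathways()])
#' @param universe gene universe; default is the union of all pathway
#'   members
#' @return data.frame of class `pathway_ranking`, sorted by p-value:
#'   `pathway`, `K`, `k`, `fraction`, `p`
#' @export
rank_pathways <- function(target_genes, pathways,
                          universe = unique(unlist(pathways))) {
  if (!length(universe)) stop("empty gene universe")
  if (!length(pathways)) stop("no pathways to test")
  target_genes <- unique(target_genes)
  outside <- setdiff(target_genes, universe)
  if (length(outside)) {
    message(length(outside), " target gene(s) outside the universe dropped")
    target_genes <- intersect(target_genes, universe)
  }
  N <- length(universe); n <- length(target_genes)
  K <- vapply(pathways, function(g) length(intersect(g, universe)), integer(1L))
  k <- vapply(pathways, function(g)
    length(intersect(intersect(g, universe), target_genes)), integer(1L))
  p <- mapply(fisher_pathway, k, K, MoreArgs = list(n = n, N = N))
  out <- data.frame(pathway = names(pathways), K = K, k = k,
                    fraction = ifelse(K > 0L, k / K, NA_real_), p = p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_target") <- n
  attr(out, "n_universe") <- N
  class(out) <- c("pathway_ranking", "data.frame")
  out
}

#' @export
print.pathway_ranking <- function(x, ...) {
  cat(sprintf("pathway_ranking: %d pathway(s), %d target genes in a universe of %d\n",
              nrow(x), attr(x, "n_target"), attr(x, "n_universe")))
  print.data.frame(head(x, 10L), digits = 4)
  invisible(x)
}

#' Randomization estimate of expected false discoveries and FDR
#'
#' Fisher's exact p-values across many pathways are not independent and the
#' discrete null makes analytic corrections awkward, so the false-discovery
#' burden is estimated empirically: `reps` random gene sets of the same size
#' as the target list are drawn uniformly (without replacement) from the
#' universe, each is ranked with [rank_pathways()], and for every p-value
#' threshold the expected number of false discoveries is the mean count of
#' pathways reaching that threshold in the random sets.  The FDR at a
#' threshold is that expectation divided by the observed discovery count
#' (`NA` when nothing is observed).  Each observed pathway is also
#' annotated with the expected false positives and FDR at its own p-value.
#'
#' @param ranking a [rank_pathways()] result for the real target set
#' @param pathways,universe as in [rank_pathways()]
#' @param reps number of random sets (default 1000)
#' @param thresholds p-value thresholds to tabulate (default 0.01 and 0.05)
#' @param seed integer seed; results are reproducible per seed
#' @return list of class `randomization_fdr`: `table` (data.frame
#'   `threshold`, `expected_fp`, `observed`, `fdr`), `ranking` (the input
#'   with `expected_fp` and `fdr` columns added), `reps`
#' @export
randomization_fdr <- function(ranking, pathways,
                              universe = unique(unlist(pathways)),
                              reps = 1000L, thresholds = c(0.01, 0.05),
                              seed = 1L) {
  stopifnot(inherits(ranking, "pathway_ranking"))
  if (reps < 1L) stop("reps must be at least 1")
  size <- attr(ranking, "n_target")
  if (size > length(universe)) stop("target size exceeds the universe")
  set.seed(seed)
  # indexed membership + p-value cache: p depends only on (k, K) here
  N <- length(universe)
  memb <- lapply(pathways, function(g) which(universe %in% g))
  Ks <- lengths(memb)
  pcache <- new.env(parent = emptyenv())
  p_of <- function(k, K) {
    key <- paste(k, K)
    if (is.null(pcache[[key]])) pcache[[key]] <- fisher_pathway(k, K, size, N)
    pcache[[key]]
  }
  null_p <- vector("list", reps)
  inset <- logical(N)
  for (r in seq_len(reps)) {
    tgt <- sample.int(N, size)
    inset[] <- FALSE; inset[tgt] <- TRUE
    ks <- vapply(memb, function(m) sum(inset[m]), integer(1L))
    null_p[[r]] <- mapply(p_of, ks, Ks)
  }
  null_p <- unlist(null_p)
  efp <- function(t) sum(null_p <= t) / reps
  tab <- data.frame(threshold = thresholds,
                    expected_fp = vapply(thresholds, efp, numeric(1L)),
                    observed = vapply(thresholds, function(t) sum(ranking$p <= t),
                                      numeric(1L)))
  tab$fdr <- ifelse(tab$observed > 0, pmin(tab$expected_fp / tab$observed, Inf),
                    NA_real_)
  ann <- ranking
  ann$expected_fp <- vapply(ann$p, efp, numeric(1L))
  obs_at <- vapply(ann$p, function(t) sum(ranking$p <= t), numeric(1L))
  ann$fdr <- ann$expected_fp / obs_at
  structure(list(table = tab, ranking = ann, reps = reps),
            class = "randomization_fdr")
}

#' @export
print.randomization_fdr <- function(x, ...) {
  cat(sprintf("randomization_fdr: %d random gene sets\n", x$reps))
  print.data.frame(x$table, digits = 4)
  cat("top pathways:\n")
  print.data.frame(head(x$ranking, 5L), digits = 4)
  invisible(x)
}
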