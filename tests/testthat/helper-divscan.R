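# Shared fixture builders and independent oracles.

# Tiny genotype matrix from a plain matrix (sites x samples); metadata filled
# with defaults unless overridden.
tiny_gm <- function(g, pos = seq_len(nrow(g)), scaffold = "sc1",
                    qual = 1000, depth = 500, mapq = 50, mq0 = 0.01,
                    ref = "A", alt = "G") {
  g <- as.matrix(g)
  if (is.null(colnames(g))) colnames(g) <- sprintf("s%02d", seq_len(ncol(g)))
  n <- nrow(g)
  genotype_matrix(
    data.frame(scaffold = rep_len(scaffold, n), pos = pos,
               ref = rep_len(ref, n), alt = rep_len(alt, n),
               qual = rep_len(qual, n), total_depth = rep_len(depth, n),
               mean_mapq = rep_len(mapq, n), mq0_fraction = rep_len(mq0, n),
               stringsAsFactors = FALSE),
    g)
}

# Two-population map over the columns of a tiny_gm: first half pop1.
tiny_pops <- function(gm) {
  ns <- length(gm$samples)
  stats::setNames(rep(c("pop1", "pop2"), c(ceiling(ns / 2), floor(ns / 2))),
                  gm$samples)
}

# Genotype matrix where every pop1 sample is 2 and every pop2 sample is 0
# (reciprocal fixation) at each of n sites.
fixed_gm <- function(n_sites = 1L, n_per_pop = 21L, ...) {
  tiny_gm(cbind(matrix(2L, n_sites, n_per_pop), matrix(0L, n_sites, n_per_pop)),
          ...)
}

# A small simulated dataset reused across tests (cached per session).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_scaffolds = 2L, scaffold_length = 30000L,
                        island_specs = data.frame(scaffold = 1L, start = 8001L,
                                                  end = 10000L,
                                                  differential = 0.95),
                        n_fixed_sites = 12L,
                        low_complexity_tracts = data.frame(scaffold = 2L,
                                                           start = 5001L,
                                                           end = 5060L),
                        gap_tracts = data.frame(scaffold = 2L, start = 15001L,
                                                end = 15200L),
                        seed = 11L)
      ref <- simulate_reference(cfg)
      cache <<- simulate_genotypes(cfg, ref)
    }
    cache
  }
})

# Independent maximal-subsegment oracle: brute-force extraction of the
# highest-sum contiguous subsegment (O(n^2) scan of all (i, j)), recursing on
# the flanks.
oracle_segments <- function(x) {
  n <- length(x)
  if (n == 0L) return(data.frame(start_idx = integer(), end_idx = integer(),
                                 score = numeric()))
  S <- c(0, cumsum(x))
  M <- outer(S[-1L], S[-(n + 1L)], "-")   # M[j, i] = sum(x[i..j])
  M[upper.tri(M)] <- -Inf
  hit <- which(M == max(M), arr.ind = TRUE)[1L, ]
  j <- hit[[1L]]; i <- hit[[2L]]
  if (M[j, i] <= 0)
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      score = numeric()))
  right <- if (j < n) oracle_segments(x[(j + 1L):n]) else NULL
  if (!is.null(right) && nrow(right)) {
    right$start_idx <- right$start_idx + j
    right$end_idx <- right$end_idx + j
  }
  out <- rbind(if (i > 1L) oracle_segments(x[seq_len(i - 1L)]),
               data.frame(start_idx = i, end_idx = j, score = M[j, i]),
               right)
  rownames(out) <- NULL
  out
}

# Independent Fisher two-tailed oracle: explicit binomial-coefficient
# enumeration of every table with the given margins.
oracle_fisher <- function(k, K, n, N) {
  support <- max(0L, n - (N - K)):min(n, K)
  pr <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  obs <- pr[match(k, support)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Independent IUPAC matcher built on regex only: does any placement of the
# motif (either strand) overlapping position `at` match the sequence?
oracle_motif_at <- function(motif, seq, at) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
             S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
             D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  as_regex <- function(m)
    paste(iupac[strsplit(m, "")[[1]]], collapse = "")
  revcomp <- function(m)
    chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
           paste(rev(strsplit(m, "")[[1]]), collapse = ""))
  W <- nchar(motif)
  for (m in unique(c(motif, revcomp(motif)))) {
    rx <- paste0("^", as_regex(m), "$")
    for (s in max(1L, at - W + 1L):min(at, nchar(seq) - W + 1L)) {
      if (grepl(rx, substr(seq, s, s + W - 1L))) return(TRUE)
    }
  }
  FALSE
}

# A small deterministic pathway annotation: 20 pathways over 400 genes.
toy_pathways <- function(n_path = 20L, n_gene = 400L, size = 25L, seed = 33L) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_gene))
  pw <- lapply(seq_len(n_path), function(i) sample(genes, size))
  names(pw) <- sprintf("path%02d", seq_len(n_path))
  list(pathways = pw, genes = genes)
}

# Mann-Whitney U by full pair enumeration.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}
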