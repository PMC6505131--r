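#' Configuration for the two-population genotype simulator
#'
#' Defines a small synthetic study: a handful of reference scaffolds carrying
#' low-complexity tracts and assembly gaps, and a two-population diploid
#' sample set genotyped at SNVs and short indels.  Background allele-frequency
#' differentiation follows a Balding-Nichols model whose parameter equals the
#' expected F_ST, so estimator recovery is directly testable; divergence
#' islands are implanted as runs of sites with a prescribed allele-frequency
#' differential, and a chosen number of sites is made reciprocally fixed
#' between the populations.
#'
#' Defaults emulate a desk-scale version of a two-coral-species resequencing
#' design: 21 diploids per population, background F_ST 0.25, and implanted
#' near-fixed islands, at a SNV density high enough that 500-b windows hold
#' ten or more SNVs.
#'
#' @param n_scaffolds number of reference scaffolds
#' @param scaffold_length length of each scaffold in bases
#' @param n_samples_per_pop diploid samples per population (>= 2)
#' @param background_fst Balding-Nichols differentiation parameter in `[0, 1)`
#' @param island_specs data.frame with columns `scaffold` (index), `start`,
#'   `end` (1-based inclusive) and `differential` (target absolute
#'   allele-frequency difference, in `(0, 1]`) — one row per implanted island
#' @param n_fixed_sites number of reciprocally fixed inter-population sites
#' @param snv_density expected SNVs per base
#' @param indel_density expected short indels (1-20 b) per base
#' @param low_complexity_tracts data.frame `scaffold`, `start`, `end`:
#'   homopolymer/dinucleotide repeat tracts written into the reference
#' @param gap_tracts data.frame `scaffold`, `start`, `end`: assembly gaps
#'   (N runs); no variant is ever placed inside a gap
#' @param seed integer seed; identical configurations give byte-identical
#'   output files
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_scaffolds = 4L,
                       scaffold_length = 50000L,
                       n_samples_per_pop = 21L,
                       background_fst = 0.25,
                       island_specs = data.frame(
                         scaffold = c(1L, 2L),
                         start = c(10001L, 30001L),
                         end = c(12000L, 32500L),
                         differential = c(0.95, 0.95)),
                       n_fixed_sites = 20L,
                       snv_density = 0.02,
                       indel_density = 0.002,
                       low_complexity_tracts = data.frame(
                         scaffold = c(1L, 2L),
                         start = c(5001L, 20001L),
                         end = c(5060L, 20070L)),
                       gap_tracts = data.frame(
                         scaffold = c(1L, 3L),
                         start = c(40001L, 15001L),
                         end = c(40200L, 15300L)),
                       seed = 1L) {
  cfg <- list(n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = as.integer(scaffold_length),
              n_samples_per_pop = as.integer(n_samples_per_pop),
              background_fst = background_fst,
              island_specs = island_specs,
              n_fixed_sites = as.integer(n_fixed_sites),
              snv_density = snv_density,
              indel_density = indel_density,
              low_complexity_tracts = low_complexity_tracts,
              gap_tracts = gap_tracts,
              seed = as.integer(seed))
  if (cfg$n_samples_per_pop < 2L) stop("n_samples_per_pop must be >= 2")
  if (cfg$snv_density <= 0 || cfg$indel_density < 0)
    stop("densities must be positive")
  if (cfg$background_fst < 0 || cfg$background_fst >= 1)
    stop("background_fst must lie in [0, 1)")
  chk_tracts <- function(tr, what) {
    if (is.null(tr) || nrow(tr) == 0L) return(invisible())
    if (any(tr$scaffold < 1L | tr$scaffold > cfg$n_scaffolds))
      stop(what, " reference a scaffold outside 1..n_scaffolds")
    if (any(tr$start < 1L | tr$end > cfg$scaffold_length | tr$start > tr$end))
      stop(what, " fall outside scaffold bounds")
  }
  chk_tracts(cfg$island_specs, "island_specs")
  chk_tracts(cfg$low_complexity_tracts, "low_complexity_tracts")
  chk_tracts(cfg$gap_tracts, "gap_tracts")
  if (nrow(cfg$island_specs) &&
      (any(cfg$island_specs$differential <= 0) ||
       any(cfg$island_specs$differential > 1)))
    stop("island differential must lie in (0, 1]")
  if (.tracts_overlap(cfg$gap_tracts, cfg$island_specs))
    stop("gap tracts overlap implanted islands; variants cannot be placed ",
         "inside gaps, so this configuration is rejected")
  class(cfg) <- "sim_config"
  cfg
}

.tracts_overlap <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0L || nrow(b) == 0L) return(FALSE)
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      if (a$scaffold[i] == b$scaffold[j] &&
          a$start[i] <= b$end[j] && b$start[j] <= a$end[i]) return(TRUE)
  FALSE
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d scaffold(s) x %d b, 2 x %d diploids\n",
              x$n_scaffolds, x$scaffold_length, x$n_samples_per_pop))
  cat(sprintf("  background F_ST %.3g, %d islands, %d fixed sites, seed %d\n",
              x$background_fst, nrow(x$island_specs), x$n_fixed_sites, x$seed))
  invisible(x)
}

scaffold_names <- function(cfg) sprintf("scaffold_%d", seq_len(cfg$n_scaffolds))

#' Simulate the reference sequence set
#'
#' Draws each scaffold uniformly over `{A,C,G,T}`, then overwrites the
#' configured low-complexity tracts with a homopolymer or dinucleotide repeat
#' (chosen at random per tract) and the gap tracts with runs of `N`.
#'
#' @param cfg a [sim_config()]
#' @return an object of class `sim_reference`: a list with `seq`
#'   (a [Biostrings::DNAStringSet]) and `tracts` (data.frame `scaffold`,
#'   `start`, `end`, `type` with type `"low_complexity"` or `"gap"`,
#'   1-based inclusive coordinates)
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$scaffold_length
  seqs <- character(cfg$n_scaffolds)
  for (s in seq_len(cfg$n_scaffolds)) {
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    lc <- cfg$low_complexity_tracts
    if (!is.null(lc) && nrow(lc)) {
      for (i in which(lc$scaffold == s)) {
        unit <- if (runif(1) < 0.5) sample(c("A", "C", "G", "T"), 1L) else
          paste(sample(c("A", "C", "G", "T"), 2L, replace = FALSE), collapse = "")
        span <- lc$start[i]:lc$end[i]
        fill <- strsplit(strrep(unit, ceiling(length(span) / nchar(unit))), "")[[1]]
        bases[span] <- fill[seq_along(span)]
      }
    }
    gp <- cfg$gap_tracts
    if (!is.null(gp) && nrow(gp))
      for (i in which(gp$scaffold == s)) bases[gp$start[i]:gp$end[i]] <- "N"
    seqs[s] <- paste(bases, collapse = "")
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- scaffold_names(cfg)
  tr <- rbind(
    if (!is.null(cfg$low_complexity_tracts) && nrow(cfg$low_complexity_tracts))
      cbind(cfg$low_complexity_tracts[c("scaffold", "start", "end")],
            type = "low_complexity"),
    if (!is.null(cfg$gap_tracts) && nrow(cfg$gap_tracts))
      cbind(cfg$gap_tracts[c("scaffold", "start", "end")], type = "gap"))
  if (is.null(tr)) tr <- data.frame(scaffold = integer(), start = integer(),
                                    end = integer(), type = character())
  tr$scaffold_name <- scaffold_names(cfg)[tr$scaffold]
  structure(list(seq = dna, tracts = tr, config = cfg),
            class = "sim_reference")
}

# Balding-Nichols population frequency around ancestral p with parameter F.
bn_freq <- function(p, fst) {
  if (fst <= 0) return(p)
  rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Simulate two-population diploid genotypes with known truth
#'
#' Places SNVs and short (1-20 b) indels uniformly along the scaffolds
#' (never inside assembly gaps), assigns each site population allele
#' frequencies, and draws diploid genotypes binomially per sample.
#' Background sites take their two population frequencies from a
#' Balding-Nichols model with parameter `background_fst` around a shared
#' ancestral frequency drawn uniformly on `[0.05, 0.95]`; sites inside an
#' implanted island get frequencies `(1 +- d)/2` pushed apart by the island
#' differential `d` (orientation random per site); the configured number of
#' reciprocally fixed sites get frequencies `(1, 0)` or `(0, 1)`.
#'
#' Genotypes are copies of the reference allele.  Sites at which no
#' alternate allele is observed in any sample are dropped (a variant caller
#' would not report them); fixed and island sites always segregate between
#' the populations and are never lost this way.  Site QUAL, total depth,
#' mapping quality and MQ0 fraction are drawn from simple lognormal/mixture
#' models so that downstream site filters have realistic work to do; fixed
#' inter-population sites are given QUAL of at least 950, reflecting the deep
#' joint support such calls have in practice, so that the high-quality subset
#' never silently loses the planted truth.
#'
#' @param cfg a [sim_config()]
#' @param ref the matching [simulate_reference()] output
#' @return an object of class `sim_dataset`: list with `sites` (metadata
#'   data.frame), `geno` (sites x samples matrix of reference-allele copy
#'   counts), `truth` (per-site data.frame: `scaffold`, `pos`, `ancestral`,
#'   `p1`, `p2`, `in_island`, `fixed_diff`, `is_indel`), `pops` (named
#'   vector sample -> population), `reference`, `config`
#' @export
simulate_genotypes <- function(cfg, ref) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ref, "sim_reference"))
  if (nrow(cfg$island_specs) && any(cfg$island_specs$differential > 1))
    stop("island differential must not exceed 1")
  set.seed(cfg$seed + 1L)
  L <- cfg$scaffold_length
  n <- cfg$n_samples_per_pop
  samples <- c(sprintf("p1_s%02d", seq_len(n)), sprintf("p2_s%02d", seq_len(n)))
  pops <- stats::setNames(rep(c("pop1", "pop2"), each = n), samples)

  gap_mask <- vector("list", cfg$n_scaffolds)
  for (s in seq_len(cfg$n_scaffolds)) {
    m <- rep(FALSE, L)
    gp <- cfg$gap_tracts
    if (!is.null(gp) && nrow(gp))
      for (i in which(gp$scaffold == s)) m[gp$start[i]:gp$end[i]] <- TRUE
    gap_mask[[s]] <- m
  }

  site_list <- list()
  for (s in seq_len(cfg$n_scaffolds)) {
    free <- which(!gap_mask[[s]])
    n_snv <- rbinom(1L, L, cfg$snv_density)
    n_ind <- rbinom(1L, L, cfg$indel_density)
    pos_all <- sort(sample(free, min(n_snv + n_ind, length(free))))
    is_ind <- rep(FALSE, length(pos_all))
    if (n_ind > 0L && length(pos_all))
      is_ind[sample(length(pos_all), min(n_ind, length(pos_all)))] <- TRUE
    site_list[[s]] <- data.frame(scaffold_i = s, pos = pos_all, is_indel = is_ind)
  }
  sites <- do.call(rbind, site_list)

  # island membership and fixed-site selection
  sites$in_island <- FALSE
  sites$differential <- NA_real_
  isl <- cfg$island_specs
  if (!is.null(isl) && nrow(isl)) {
    for (i in seq_len(nrow(isl))) {
      hit <- sites$scaffold_i == isl$scaffold[i] &
        sites$pos >= isl$start[i] & sites$pos <= isl$end[i]
      sites$in_island[hit] <- TRUE
      sites$differential[hit] <- isl$differential[i]
    }
  }
  sites$fixed_diff <- FALSE
  eligible <- which(!sites$in_island & !sites$is_indel)
  if (cfg$n_fixed_sites > length(eligible))
    stop("not enough background SNVs to place ", cfg$n_fixed_sites,
         " fixed sites; increase snv_density or scaffold_length")
  if (cfg$n_fixed_sites > 0L)
    sites$fixed_diff[sample(eligible, cfg$n_fixed_sites)] <- TRUE

  # population frequencies of the reference allele
  m <- nrow(sites)
  anc <- runif(m, 0.05, 0.95)
  p1 <- bn_freq(anc, cfg$background_fst)
  p2 <- bn_freq(anc, cfg$background_fst)
  ii <- which(sites$in_island)
  if (length(ii)) {
    d <- sites$differential[ii]
    hi_first <- runif(length(ii)) < 0.5
    p1[ii] <- ifelse(hi_first, (1 + d) / 2, (1 - d) / 2)
    p2[ii] <- ifelse(hi_first, (1 - d) / 2, (1 + d) / 2)
  }
  fi <- which(sites$fixed_diff)
  if (length(fi)) {
    one_first <- runif(length(fi)) < 0.5
    p1[fi] <- as.numeric(one_first)
    p2[fi] <- as.numeric(!one_first)
  }

  geno <- matrix(NA_integer_, m, 2L * n, dimnames = list(NULL, samples))
  for (j in seq_len(n)) geno[, j] <- rbinom(m, 2L, p1)
  for (j in seq_len(n)) geno[, n + j] <- rbinom(m, 2L, p2)

  # a caller only reports sites where the alternate allele was observed
  seen_alt <- rowSums(geno < 2L) > 0L
  keep <- seen_alt | sites$fixed_diff
  sites <- sites[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  p1 <- p1[keep]; p2 <- p2[keep]; anc <- anc[keep]
  m <- nrow(sites)

  # alleles from the reference sequence
  ref_allele <- alt_allele <- character(m)
  drop_row <- rep(FALSE, m)
  other <- c("A", "C", "G", "T")
  seq_chr <- as.character(ref$seq)
  for (i in seq_len(m)) {
    s <- sites$scaffold_i[i]; pos <- sites$pos[i]
    base <- substr(seq_chr[s], pos, pos)
    if (!sites$is_indel[i]) {
      ref_allele[i] <- base
      alt_allele[i] <- sample(setdiff(other, base), 1L)
    } else {
      len <- sample(1:20, 1L)
      if (runif(1) < 0.5 || pos + len > L ||
          any(gap_mask[[s]][pos:min(L, pos + len)])) {
        # insertion after pos
        ins <- paste(sample(other, len, replace = TRUE), collapse = "")
        ref_allele[i] <- base
        alt_allele[i] <- paste0(base, ins)
      } else {
        ref_allele[i] <- substr(seq_chr[s], pos, pos + len)
        alt_allele[i] <- base
      }
    }
    if (base == "N") drop_row[i] <- TRUE    # defensive; gaps are excluded above
  }
  if (any(drop_row)) {
    sites <- sites[!drop_row, , drop = FALSE]; geno <- geno[!drop_row, , drop = FALSE]
    p1 <- p1[!drop_row]; p2 <- p2[!drop_row]; anc <- anc[!drop_row]
    ref_allele <- ref_allele[!drop_row]; alt_allele <- alt_allele[!drop_row]
    m <- nrow(sites)
  }

  qual <- round(pmin(3000, rlnorm(m, log(1800), 0.5)), 1)
  qual[sites$fixed_diff] <- pmax(qual[sites$fixed_diff], 950)
  depth <- as.integer(round(rlnorm(m, log(600), 0.45)))
  low_mq <- runif(m) < 0.05
  mapq <- round(ifelse(low_mq, rnorm(m, 25, 4), rnorm(m, 50, 5)), 2)
  mapq <- pmin(pmax(mapq, 0), 60)
  mq0f <- round(pmin(pmax(rbeta(m, 1, 40), 0), 1), 4)

  meta <- data.frame(scaffold = scaffold_names(cfg)[sites$scaffold_i],
                     pos = sites$pos,
                     ref = ref_allele, alt = alt_allele,
                     qual = qual, total_depth = depth,
                     mean_mapq = mapq, mq0_fraction = mq0f,
                     stringsAsFactors = FALSE)
  truth <- data.frame(scaffold = meta$scaffold, pos = meta$pos,
                      ancestral = ref_allele, p1 = p1, p2 = p2,
                      in_island = sites$in_island,
                      fixed_diff = sites$fixed_diff,
                      is_indel = sites$is_indel,
                      stringsAsFactors = FALSE)
  ord <- order(sites$scaffold_i, sites$pos)
  structure(list(sites = meta[ord, , drop = FALSE],
                 geno = geno[ord, , drop = FALSE],
                 truth = truth[ord, , drop = FALSE],
                 pops = pops, reference = ref, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d variant sites (%d indels, %d fixed, %d in islands), 2 x %d diploids\n",
              nrow(x$sites), sum(x$truth$is_indel), sum(x$truth$fixed_diff),
              sum(x$truth$in_island), x$config$n_samples_per_pop))
  invisible(x)
}

#' Extract the genotype matrix from a simulated dataset
#'
#' @param sim a [simulate_genotypes()] result
#' @return a [genotype_matrix()] over all simulated sites (SNVs and indels)
#' @export
sim_genotype_matrix <- function(sim) {
  stopifnot(inherits(sim, "sim_dataset"))
  genotype_matrix(sim$sites, sim$geno)
}

gt_string <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 2L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 0L] <- "1/1"
  out
}

#' Write a simulated dataset to standard flat files
#'
#' Emits `reference.fasta`, `variants.vcf` (VCFv4.2 with QUAL, `INFO/DP`,
#' `INFO/MQ`, `INFO/MQ0F` and per-sample `GT`), `tracts.bed` (0-based
#' half-open, name column `low_complexity`/`gap`), `truth.tsv` and
#' `pops.tsv`.  Output is byte-deterministic for a given configuration.
#'
#' @param sim a [simulate_genotypes()] result
#' @param dir output directory (created if needed)
#' @return named character vector of the five file paths, invisibly
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "reference.fasta"),
             vcf = file.path(dir, "variants.vcf"),
             bed = file.path(dir, "tracts.bed"),
             truth = file.path(dir, "truth.tsv"),
             pops = file.path(dir, "pops.tsv"))
  Biostrings::writeXStringSet(sim$reference$seq, paths["fasta"], width = 70L)

  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(sim$reference$seq),
                   Biostrings::width(sim$reference$seq)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth over all samples\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
           "##INFO=<ID=MQ0F,Number=1,Type=Float,Description=\"Fraction of reads with mapping quality zero\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", names(sim$pops)), collapse = "\t"))
  gt <- apply(sim$geno, 1L, function(g) paste(gt_string(g), collapse = "\t"))
  body <- paste(sim$sites$scaffold, sim$sites$pos, ".", sim$sites$ref,
                sim$sites$alt, format(sim$sites$qual, trim = TRUE), ".",
                sprintf("DP=%d;MQ=%s;MQ0F=%s", sim$sites$total_depth,
                        format(sim$sites$mean_mapq, trim = TRUE),
                        format(sim$sites$mq0_fraction, trim = TRUE)),
                "GT", gt, sep = "\t")
  writeLines(c(hdr, body), paths["vcf"])

  tr <- sim$reference$tracts
  writeLines(sprintf("%s\t%d\t%d\t%s", tr$scaffold_name, tr$start - 1L,
                     tr$end, tr$type), paths["bed"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = names(sim$pops),
                         population = unname(sim$pops)),
              paths["pops"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
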