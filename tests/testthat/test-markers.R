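# A controlled 101-b core: poly-T flanks (free of any panel recognition
# motif), an AC..T context around the centre so that allele G completes the
# HpyCH4IV site ACGT and allele A does not.
hpy_candidate <- function() {
  core <- paste0(strrep("T", 48), "AC", "G", "TA", strrep("T", 48))
  stopifnot(nchar(core) == 101L)
  data.frame(scaffold = "sc1", pos = 500L, ref = "G", alt = "A", qual = 1000,
             allele_pop1 = "G", allele_pop2 = "A", site_index = 1L,
             pass = TRUE, reason = NA_character_, core_seq = core,
             stringsAsFactors = FALSE)
}

test_that("fixed differences require reciprocal homozygosity and quality", {
  gm <- fixed_gm(2L, n_per_pop = 21L, qual = c(950, 800))
  fd <- fixed_differences(gm, tiny_pops(gm))
  expect_identical(nrow(fd), 1L)           # qual 800 fails the 900 floor
  expect_identical(fd$allele_pop1, "A")    # pop1 homozygous reference
  expect_identical(fd$allele_pop2, "G")

  # one heterozygote in pop1 disqualifies the site
  het <- fixed_gm(1L, n_per_pop = 21L)
  het$geno[1L, 3L] <- 1L
  expect_identical(nrow(fixed_differences(het, tiny_pops(het))), 0L)

  # orientation is symmetric: pop1 may carry the alternate allele
  flip <- tiny_gm(cbind(matrix(0L, 1L, 4L), matrix(2L, 1L, 4L)))
  fdf <- fixed_differences(flip, tiny_pops(flip))
  expect_identical(fdf$allele_pop1, "G")
  expect_identical(fdf$allele_pop2, "A")
})

test_that("missing genotypes disqualify under strict mode but not lenient mode", {
  gm <- fixed_gm(1L, n_per_pop = 4L)
  gm$geno[1L, 2L] <- NA_integer_
  expect_identical(nrow(fixed_differences(gm, tiny_pops(gm))), 0L)
  expect_identical(nrow(fixed_differences(gm, tiny_pops(gm), strict = FALSE)), 1L)
})

test_that("deep-sample concordance anchors are validated and applied", {
  gm <- fixed_gm(1L, n_per_pop = 4L)
  pops <- tiny_pops(gm)
  expect_error(fixed_differences(gm, pops,
                                 deep_samples = c(pop1 = "s08")),
               "not a member")
  ok <- fixed_differences(gm, pops,
                          deep_samples = c(pop1 = "s01", pop2 = "s05"))
  expect_identical(nrow(ok), 1L)
  # lenient mode still refuses a site whose anchor sample is uncalled
  gm$geno[1L, 1L] <- NA_integer_
  lax <- fixed_differences(gm, pops, strict = FALSE,
                           deep_samples = c(pop1 = "s01", pop2 = "s05"))
  expect_identical(nrow(lax), 0L)
})

test_that("the simulator's planted fixed sites are recovered exactly", {
  sim <- shared_sim()
  gm <- subset_sites(sim_genotype_matrix(sim), !sim$truth$is_indel)
  fd <- fixed_differences(gm, sim$pops, min_qual = 0)
  truth <- sim$truth[!sim$truth$is_indel, ]
  want <- paste(truth$scaffold, truth$pos)[truth$fixed_diff]
  expect_setequal(paste(fd$scaffold, fd$pos), want)
  # planted fixed sites carry high QUAL, so the default floor keeps them all
  fd900 <- fixed_differences(gm, sim$pops)
  expect_true(all(want %in% paste(fd900$scaffold, fd900$pos)))
})

test_that("PCR-ready screening applies the inclusive 50-b exclusion window", {
  set.seed(41)
  chrom <- paste(sample(c("A", "C", "G", "T"), 1000L, replace = TRUE),
                 collapse = "")
  refset <- Biostrings::DNAStringSet(c(sc1 = chrom))
  fixed <- data.frame(scaffold = "sc1", pos = c(500L, 30L, 700L, 900L),
                      ref = "A", alt = "G", qual = 1000,
                      allele_pop1 = "A", allele_pop2 = "G",
                      site_index = 1:4, stringsAsFactors = FALSE)
  snvs <- tiny_gm(matrix(1L, 6L, 2L), scaffold = "sc1",
                  pos = c(500L, 30L, 700L, 900L, 750L, 849L))
  indels <- tiny_gm(matrix(1L, 0L, 2L), pos = integer())
  tracts <- data.frame(scaffold = "sc1", start = 940L, end = 960L)
  out <- pcr_ready(fixed, snvs, indels, refset, tracts)
  # site 500: clean -> 101-b core equal to the reference slice
  expect_true(out$pass[1L])
  expect_identical(nchar(out$core_seq[1L]), 101L)
  expect_identical(out$core_seq[1L], substr(chrom, 450L, 550L))
  # site 30: too close to the scaffold start
  expect_identical(out$reason[2L], "edge")
  # site 700: another SNV at distance 50 is still within the window
  expect_identical(out$reason[3L], "variant")
  # site 900: low-complexity tract base within 50 b
  expect_identical(out$reason[4L], "tract")

  # distance 51 is outside the window: site 700 passes once 750 moves to 751
  snvs2 <- tiny_gm(matrix(1L, 2L, 2L), scaffold = "sc1", pos = c(700L, 751L))
  out2 <- pcr_ready(fixed[3L, ], snvs2, indels, refset, NULL)
  expect_true(out2$pass[1L])

  # an indel's whole reference span is excluded, not just its start
  indel_far <- tiny_gm(matrix(1L, 1L, 2L), scaffold = "sc1", pos = 760L,
                       ref = strrep("A", 15L), alt = "A")
  # span 760-774 stays clear of 700+50; shifting start to 745 intrudes
  expect_true(pcr_ready(fixed[3L, ], tiny_gm(matrix(1L, 1L, 2L), pos = 700L),
                        indel_far, refset, NULL)$pass[1L])
  indel_near <- tiny_gm(matrix(1L, 1L, 2L), scaffold = "sc1", pos = 745L,
                        ref = strrep("A", 15L), alt = "A")
  expect_identical(pcr_ready(fixed[3L, ],
                             tiny_gm(matrix(1L, 1L, 2L), pos = 700L),
                             indel_near, refset, NULL)$reason[1L], "variant")
})

test_that("gap bases inside the core are rejected and survivors never contain them", {
  chrom <- paste0(strrep("A", 480L), strrep("N", 10L), strrep("C", 510L))
  refset <- Biostrings::DNAStringSet(c(sc1 = chrom))
  fixed <- data.frame(scaffold = "sc1", pos = 520L, ref = "C", alt = "G",
                      qual = 1000, allele_pop1 = "C", allele_pop2 = "G",
                      site_index = 1L, stringsAsFactors = FALSE)
  empty <- tiny_gm(matrix(1L, 0L, 2L), pos = integer())
  snv_self <- tiny_gm(matrix(1L, 1L, 2L), scaffold = "sc1", pos = 520L)
  out <- pcr_ready(fixed, snv_self, empty, refset, NULL)
  expect_identical(out$reason[1L], "gap")
})

test_that("every passing core on simulated data is clean by construction", {
  sim <- shared_sim()
  snv <- subset_sites(sim_genotype_matrix(sim), !sim$truth$is_indel)
  ind <- subset_sites(sim_genotype_matrix(sim), sim$truth$is_indel)
  fd <- fixed_differences(snv, sim$pops)
  gaps <- sim$reference$tracts[sim$reference$tracts$type == "gap", ]
  tracts <- rbind(low_complexity_scan(sim$reference),
                  data.frame(scaffold = gaps$scaffold_name, start = gaps$start,
                             end = gaps$end, type = "gap"))
  out <- pcr_ready(fd, snv, ind, sim$reference, tracts)
  ok <- out[out$pass, ]
  all_pos <- paste(sim$sites$scaffold, sim$sites$pos)
  for (i in seq_len(nrow(ok))) {
    expect_identical(nchar(ok$core_seq[i]), 101L)
    expect_false(grepl("N", ok$core_seq[i], fixed = TRUE))
    near <- paste(ok$scaffold[i], (ok$pos[i] - 50L):(ok$pos[i] + 50L))
    expect_identical(sum(all_pos %in% near), 1L)  # only the site itself
  }
})

test_that("a diagnostic enzyme is found exactly when one allele carries the site", {
  cand <- hpy_candidate()
  assay <- find_rflp(cand)
  expect_identical(assay$enzyme, "HpyCH4IV")
  expect_identical(assay$cut_pop, "pop1")
  expect_identical(assay$cut_allele, "G")
  expect_identical(assay$site_start_core, 49L)   # ACGT starting at the A

  # both alleles completing the motif is not diagnostic
  both <- cand
  both$allele_pop2 <- "G"
  expect_null(find_rflp(both))

  # relabelling the alleles swaps which population is cut
  flip <- cand
  flip$allele_pop1 <- "A"; flip$allele_pop2 <- "G"
  assay2 <- find_rflp(flip)
  expect_identical(assay2$cut_pop, "pop2")
  expect_identical(assay2$cut_allele, "G")
})

test_that("enzyme qualification matches a regex IUPAC oracle on random cores", {
  set.seed(59)
  enz <- default_enzymes()
  for (t in 1:40) {
    core <- paste(sample(c("A", "C", "G", "T"), 101L, replace = TRUE),
                  collapse = "")
    alleles <- sample(c("A", "C", "G", "T"), 2L)
    cand <- data.frame(scaffold = "sc1", pos = 1000L, ref = alleles[1L],
                       alt = alleles[2L], qual = 1000,
                       allele_pop1 = alleles[1L], allele_pop2 = alleles[2L],
                       site_index = 1L, pass = TRUE, reason = NA_character_,
                       core_seq = core, stringsAsFactors = FALSE)
    s1 <- core; substr(s1, 51L, 51L) <- alleles[1L]
    s2 <- core; substr(s2, 51L, 51L) <- alleles[2L]
    for (e in seq_len(nrow(enz))) {
      got <- find_rflp(cand, enz[e, , drop = FALSE])
      m1 <- oracle_motif_at(enz$motif[e], s1, 51L)
      m2 <- oracle_motif_at(enz$motif[e], s2, 51L)
      if (xor(m1, m2)) {
        expect_false(is.null(got))
        expect_identical(got$cut_pop, if (m1) "pop1" else "pop2")
      } else {
        expect_null(got)
      }
    }
  }
})

test_that("amplicons extend to the next recognition site and digest into two fragments", {
  # scaffold: GATC planted at 101-104 and 701-704; the diagnostic context
  # GACC at 499-502 becomes GATC when the SNV at 501 carries the cut allele T;
  # DpnII cuts before the G (offset 0)
  chrom <- paste0(strrep("T", 100), "GATC", strrep("T", 100), strrep("A", 294),
                  "GACC", strrep("T", 198), "GATC", strrep("T", 296))
  stopifnot(nchar(chrom) == 1000L, substr(chrom, 101, 104) == "GATC",
            substr(chrom, 499, 502) == "GACC", substr(chrom, 701, 704) == "GATC")
  refset <- Biostrings::DNAStringSet(c(sc1 = chrom))
  assay <- data.frame(scaffold = "sc1", pos = 501L, enzyme = "DpnII",
                      motif = "GATC", cut_offset = 0L, cut_pop = "pop1",
                      cut_allele = "T", site_start_core = 50L, strand = "+",
                      stringsAsFactors = FALSE)
  class(assay) <- c("marker_assay", "data.frame")
  ext <- extend_amplicon(assay, refset)
  expect_identical(ext$amp_start, 105L)   # just after the upstream GATC
  expect_identical(ext$amp_end, 700L)     # just before the downstream GATC
  expect_false(ext$truncated)
  # digest of the cut-allele amplicon yields exactly two fragments
  chrom_cut <- chrom; substr(chrom_cut, 501L, 501L) <- "T"
  amp <- substr(chrom_cut, ext$amp_start, ext$amp_end)
  frags <- digest_fragments(amp, "GATC", 0L)
  expect_length(frags, 2L)
  expect_identical(sum(frags), nchar(amp))
  expect_setequal(frags, c(ext$frag_cut_left, ext$frag_cut_right))

  # with no second site the amplicon runs to the scaffold edges, flagged
  lone <- paste0(strrep("T", 498), "GACC", strrep("T", 498))
  ref2 <- Biostrings::DNAStringSet(c(sc1 = lone))
  assay2 <- assay
  ext2 <- extend_amplicon(assay2, ref2)
  expect_true(ext2$truncated)
  expect_identical(ext2$amp_start, 1L)
  expect_identical(ext2$amp_end, 1000L)
})

test_that("band patterns follow the 1/2/3-band rule and conserve length", {
  assay <- data.frame(scaffold = "sc1", pos = 500L, enzyme = "DpnII",
                      motif = "GATC", cut_offset = 0L, cut_pop = "pop1",
                      cut_allele = "T", site_start_core = 50L, strand = "+",
                      amp_start = 201L, amp_end = 500L, amp_length = 300L,
                      cut_at = 300L, frag_cut_left = 100L,
                      frag_cut_right = 200L, truncated = FALSE,
                      stringsAsFactors = FALSE)
  class(assay) <- c("marker_assay", "data.frame")
  expect_identical(predict_bands(assay, "hom_pop2")$n_bands, 1L)
  expect_identical(predict_bands(assay, "hom_pop2")$fragments, 300L)
  expect_identical(predict_bands(assay, "hom_pop1")$n_bands, 2L)
  het <- predict_bands(assay, "het")
  expect_identical(het$n_bands, 3L)
  expect_identical(het$fragments, c(300L, 200L, 100L))
  # length conservation per source allele
  expect_identical(sum(predict_bands(assay, "hom_pop1", min_frag = 0L)$fragments),
                   assay$amp_length)
  expect_identical(sum(predict_bands(assay, "hom_pop2", min_frag = 0L)$fragments),
                   assay$amp_length)
  # tiny fragments are suppressed at the default gel resolution
  short <- assay
  short$frag_cut_left <- 10L; short$frag_cut_right <- 290L
  expect_identical(predict_bands(short, "hom_pop1")$n_bands, 1L)

  expect_identical(genotype_from_bands(assay, 1L), "hom_pop2")
  expect_identical(genotype_from_bands(assay, 2L), "hom_pop1")
  expect_identical(genotype_from_bands(assay, 3L), "het")
})

test_that("multilocus genotypes assign to parents, F1-like hybrids or mixed", {
  expect_identical(assign_taxon(rep("het", 8L))$assignment, "F1-like")
  expect_identical(assign_taxon(rep("hom_pop1", 8L))$assignment, "pop1")
  expect_identical(assign_taxon(rep("hom_pop2", 5L))$assignment, "pop2")
  mixed <- assign_taxon(c(rep("hom_pop1", 5L), rep("het", 3L)))
  expect_identical(mixed$assignment, "mixed")
  expect_identical(unname(mixed$counts["hom_pop1"]), 5L)
  expect_warning(out <- assign_taxon(c("het", NA, "het")), "unscored")
  expect_identical(out$n_loci, 2L)
  expect_error(suppressWarnings(assign_taxon(NA_character_)), "no scored loci")
})
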