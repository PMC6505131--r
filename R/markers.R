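#' Restriction enzyme motif tables
#'
#' `default_enzymes()` returns the five-enzyme panel used for diagnostic
#' assay design (HaeIII, DpnII, HinfI, EcoRV, HpyCH4IV) with IUPAC
#' recognition motifs and the top-strand cut offset (bases from the motif
#' start to the cut point, e.g. HpyCH4IV A^CGT has offset 1).
#' `read_enzymes()` reads the same three columns from a TSV.
#'
#' @param path TSV with columns `name`, `motif`, `cut_offset`
#' @return data.frame `name`, `motif`, `cut_offset`
#' @export
default_enzymes <- function() {
  data.frame(name = c("HaeIII", "DpnII", "HinfI", "EcoRV", "HpyCH4IV"),
             motif = c("GGCC", "GATC", "GANTC", "GATATC", "ACGT"),
             cut_offset = c(2L, 0L, 1L, 3L, 1L),
             stringsAsFactors = FALSE)
}

#' @rdname default_enzymes
#' @export
read_enzymes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("name", "motif", "cut_offset") %in% names(tab)))
    stop("enzyme table needs columns name, motif, cut_offset")
  if (any(nchar(tab$motif) < 4L)) stop("recognition motifs must be >= 4 b")
  if (any(tab$cut_offset < 0L | tab$cut_offset > nchar(tab$motif)))
    stop("cut offset must lie within the motif")
  tab
}

ref_seqs <- function(reference) {
  if (inherits(reference, "sim_reference")) reference$seq
  else if (inherits(reference, "DNAStringSet")) reference
  else Biostrings::DNAStringSet(unlist(reference))
}

# IUPAC motif matches on both strands of a subject; ambiguity codes are
# honoured in the pattern only, so N runs in the subject never match.
# Returns start/end (subject coordinates, 1-based) and strand.
match_motif <- function(motif, subject) {
  subj <- Biostrings::DNAString(subject)
  pat <- Biostrings::DNAString(motif)
  hits <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subj, fixed = "subject")
    if (!length(m)) return(NULL)
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m),
               strand = strand, stringsAsFactors = FALSE)
  }
  plus <- hits(pat, "+")
  rc <- Biostrings::reverseComplement(pat)
  minus <- if (as.character(rc) == as.character(pat)) NULL else hits(rc, "-")
  out <- rbind(plus, minus)
  if (is.null(out)) data.frame(start = integer(), end = integer(),
                               strand = character())
  else out[order(out$start, out$strand), , drop = FALSE]
}

#' Detect fixed inter-population differences
#'
#' A fixed difference is a site where every non-missing sample of one
#' population is homozygous for one allele and every sample of the other
#' population is homozygous for the alternate allele, with site quality of
#' at least `min_qual`.  Under `strict` mode (default) any missing genotype
#' disqualifies the site; under lenient mode missing samples are ignored.
#' If `deep_samples` names one reference (deeply sequenced) sample per
#' population, every other ("shallow") sample must match its population's
#' deep genotype — with fully fixed sites this is implied, but the check
#' guards against calling a site fixed when the anchor sample itself is
#' missing.
#'
#' @inheritParams aggregate_counts
#' @param min_qual inclusive minimum Phred site quality (default 900)
#' @param deep_samples optional named character vector, population label ->
#'   sample id
#' @param strict logical; disqualify sites with missing genotypes
#' @return data.frame: `scaffold`, `pos`, `ref`, `alt`, `qual`,
#'   `allele_pop1`, `allele_pop2`, `site_index` (row in `gm`)
#' @export
fixed_differences <- function(gm, pops, min_qual = 900, deep_samples = NULL,
                              strict = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  grp <- pop_split(gm, pops)
  if (!is.null(deep_samples)) {
    for (lab in names(deep_samples))
      if (!deep_samples[[lab]] %in% grp[[lab]])
        stop("deep sample '", deep_samples[[lab]],
             "' is not a member of population '", lab, "'")
  }
  g1 <- gm$geno[, grp[[1L]], drop = FALSE]
  g2 <- gm$geno[, grp[[2L]], drop = FALSE]
  qual <- if (is.null(gm$sites$qual)) rep(NA_real_, nrow(gm$sites)) else gm$sites$qual

  all_eq <- function(g, val) {
    hit <- rowSums(g == val, na.rm = TRUE)
    nm <- rowSums(!is.na(g))
    if (strict) hit == ncol(g) else (nm > 0L & hit == nm)
  }
  fwd <- all_eq(g1, 2L) & all_eq(g2, 0L)   # pop1 carries ref, pop2 carries alt
  bwd <- all_eq(g1, 0L) & all_eq(g2, 2L)
  keep <- (fwd | bwd) & !is.na(qual) & qual >= min_qual
  if (!is.null(deep_samples)) {
    for (lab in names(deep_samples)) {
      dg <- gm$geno[, deep_samples[[lab]]]
      keep <- keep & !is.na(dg)
    }
  }
  idx <- which(keep)
  out <- data.frame(scaffold = gm$sites$scaffold[idx], pos = gm$sites$pos[idx],
                    ref = gm$sites$ref[idx], alt = gm$sites$alt[idx],
                    qual = qual[idx],
                    allele_pop1 = ifelse(fwd[idx], gm$sites$ref[idx],
                                         gm$sites$alt[idx]),
                    allele_pop2 = ifelse(fwd[idx], gm$sites$alt[idx],
                                         gm$sites$ref[idx]),
                    site_index = idx, stringsAsFactors = FALSE)
  attr(out, "populations") <- names(grp)
  rownames(out) <- NULL
  out
}

#' Scan a reference for low-complexity tracts
#'
#' DUST-style windowed triplet score: within each window the score is
#' `sum(c_t (c_t - 1) / 2) / (k - 1)` over trinucleotide counts `c_t`
#' (`k` = triplets in the window).  Uniform random sequence scores about
#' 0.4; homopolymers and dinucleotide repeats score an order of magnitude
#' higher, so detection is robust to the exact threshold.  Overlapping
#' flagged windows are merged into tracts.  Triplets containing N are not
#' counted.
#'
#' @param reference a [Biostrings::DNAStringSet] or [simulate_reference()]
#'   result
#' @param window window width in bases (default 48)
#' @param step window step (default 8)
#' @param threshold flag windows scoring above this (default 2)
#' @return data.frame `scaffold`, `start`, `end` (1-based inclusive),
#'   `type = "low_complexity"`
#' @export
low_complexity_scan <- function(reference, window = 48L, step = 8L,
                                threshold = 2) {
  seqs <- ref_seqs(reference)
  out <- list()
  for (sc in names(seqs)) {
    chars <- strsplit(as.character(seqs[[sc]]), "")[[1]]
    L <- length(chars)
    if (L < window) next
    code <- match(chars, c("A", "C", "G", "T")) - 1L
    trip <- code[seq_len(L - 2L)] * 16L + code[seq_len(L - 2L) + 1L] * 4L +
      code[seq_len(L - 2L) + 2L]
    starts <- seq(1L, L - window + 1L, by = step)
    flagged <- logical(length(starts))
    for (w in seq_along(starts)) {
      t <- trip[starts[w]:(starts[w] + window - 3L)]
      t <- t[!is.na(t)]
      if (length(t) < 2L) next
      cc <- tabulate(t + 1L, nbins = 64L)
      flagged[w] <- sum(cc * (cc - 1) / 2) / (length(t) - 1L) > threshold
    }
    if (!any(flagged)) next
    ws <- starts[flagged]; we <- ws + window - 1L
    merged <- list(); cs <- ws[1L]; ce <- we[1L]
    for (i in seq_along(ws)[-1L]) {
      if (ws[i] <= ce + 1L) ce <- max(ce, we[i])
      else { merged[[length(merged) + 1L]] <- c(cs, ce); cs <- ws[i]; ce <- we[i] }
    }
    merged[[length(merged) + 1L]] <- c(cs, ce)
    out[[sc]] <- data.frame(scaffold = sc,
                            start = vapply(merged, `[`, integer(1L), 1L),
                            end = vapply(merged, `[`, integer(1L), 2L),
                            type = "low_complexity", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(scaffold = character(), start = integer(),
                                      end = integer(), type = character())
  rownames(res) <- NULL
  res
}

#' Select PCR-ready marker candidates
#'
#' A fixed difference is "PCR-ready" when nothing that would disturb primer
#' or probe design lies within `flank` bases on either side: no other SNV or
#' indel (indels disturb every base of their reference span), no
#' low-complexity tract base, no assembly gap (N) base, and no scaffold
#' edge.  Distance exactly `flank` counts as within the exclusion window
#' (conservative).  Surviving sites are emitted with their
#' `2 * flank + 1`-base core sequence (the 101-b core at the default 50-b
#' flank).
#'
#' @param fixed a [fixed_differences()] result
#' @param snv_gm,indel_gm genotype matrices of all observed SNVs and indels
#'   (the full call set, before quality subsetting)
#' @param reference [Biostrings::DNAStringSet] or [simulate_reference()]
#'   result
#' @param tracts data.frame of exclusion tracts (`scaffold`, `start`, `end`,
#'   1-based inclusive; e.g. [low_complexity_scan()] output and/or gap
#'   tracts), or `NULL`
#' @param flank exclusion / extraction radius in bases (default 50)
#' @return `fixed` with additional columns `pass` (logical), `reason`
#'   (`NA`, `"edge"`, `"variant"`, `"tract"` or `"gap"`: first rule failed)
#'   and `core_seq` (for passing sites)
#' @export
pcr_ready <- function(fixed, snv_gm, indel_gm, reference, tracts = NULL,
                      flank = 50L) {
  seqs <- ref_seqs(reference)
  if (!is.null(tracts) && nrow(tracts) && !is.null(tracts$scaffold_name))
    tracts$scaffold <- tracts$scaffold_name
  var_pos <- rbind(
    data.frame(scaffold = snv_gm$sites$scaffold,
               start = snv_gm$sites$pos, end = snv_gm$sites$pos),
    data.frame(scaffold = indel_gm$sites$scaffold,
               start = indel_gm$sites$pos,
               end = indel_gm$sites$pos + nchar(indel_gm$sites$ref) - 1L))
  out <- fixed
  out$pass <- FALSE
  out$reason <- NA_character_
  out$core_seq <- NA_character_
  seq_chr <- stats::setNames(as.character(seqs), names(seqs))
  for (i in seq_len(nrow(out))) {
    sc <- out$scaffold[i]; pos <- out$pos[i]
    L <- nchar(seq_chr[[sc]])
    lo <- pos - flank; hi <- pos + flank
    if (lo < 1L || hi > L) { out$reason[i] <- "edge"; next }
    near <- var_pos$scaffold == sc & var_pos$end >= lo & var_pos$start <= hi &
      !(var_pos$start == pos & var_pos$end == pos)
    if (any(near)) { out$reason[i] <- "variant"; next }
    if (!is.null(tracts) && nrow(tracts)) {
      hit <- tracts$scaffold == sc & tracts$end >= lo & tracts$start <= hi
      if (any(hit)) { out$reason[i] <- "tract"; next }
    }
    core <- substr(seq_chr[[sc]], lo, hi)
    if (grepl("N", core, fixed = TRUE)) { out$reason[i] <- "gap"; next }
    out$pass[i] <- TRUE
    out$core_seq[i] <- core
  }
  attr(out, "flank") <- flank
  out
}

sub_base <- function(seq, at, base) {
  substr(seq, at, at) <- base
  seq
}

#' Find a diagnostic restriction enzyme for a marker candidate
#'
#' Builds the two allelic versions of the candidate's core sequence (the
#' fixed SNV substituted with each population's allele) and searches each
#' enzyme's IUPAC recognition motif, on both strands, for a placement
#' overlapping the SNV.  An enzyme is diagnostic when such a placement
#' exists in exactly one allele: that allele's PCR product is cut, the
#' other is not.  Enzymes are tried in table order; the first diagnostic
#' one is returned.
#'
#' @param candidate one passing row of a [pcr_ready()] result (must carry
#'   `core_seq`, `allele_pop1`, `allele_pop2`)
#' @param enzymes data.frame as [default_enzymes()]
#' @param flank flank used to build the core (centre at `flank + 1`)
#' @return one-row data.frame of class `marker_assay` — `scaffold`, `pos`,
#'   `enzyme`, `motif`, `cut_offset`, `cut_pop`, `cut_allele`,
#'   `site_start_core`, `strand` — or `NULL` when no enzyme is diagnostic
#' @export
find_rflp <- function(candidate, enzymes = default_enzymes(), flank = 50L) {
  stopifnot(nrow(candidate) == 1L, !is.na(candidate$core_seq))
  centre <- flank + 1L
  seq1 <- sub_base(candidate$core_seq, centre, candidate$allele_pop1)
  seq2 <- sub_base(candidate$core_seq, centre, candidate$allele_pop2)
  for (e in seq_len(nrow(enzymes))) {
    at_snv <- function(s) {
      m <- match_motif(enzymes$motif[e], s)
      m[m$start <= centre & m$end >= centre, , drop = FALSE]
    }
    m1 <- at_snv(seq1); m2 <- at_snv(seq2)
    if ((nrow(m1) > 0L) == (nrow(m2) > 0L)) next   # neither or both: not diagnostic
    cut_first <- nrow(m1) > 0L
    m <- if (cut_first) m1 else m2
    m <- m[order(m$strand != "+", m$start), , drop = FALSE]
    out <- data.frame(scaffold = candidate$scaffold, pos = candidate$pos,
                      enzyme = enzymes$name[e], motif = enzymes$motif[e],
                      cut_offset = enzymes$cut_offset[e],
                      cut_pop = if (cut_first) "pop1" else "pop2",
                      cut_allele = if (cut_first) candidate$allele_pop1
                                   else candidate$allele_pop2,
                      site_start_core = m$start[1L], strand = m$strand[1L],
                      stringsAsFactors = FALSE)
    class(out) <- c("marker_assay", "data.frame")
    return(out)
  }
  NULL
}

# top-strand cut point (cut falls between cut_at and cut_at + 1) for a motif
# occurrence at [start, end] on the given strand
cut_point <- function(start, end, strand, cut_offset) {
  if (strand == "+") start + cut_offset - 1L else end - cut_offset
}

#' Extend a marker assay to its full amplicon
#'
#' Starting from the diagnostic recognition site, extends left and right
#' along the scaffold (with the SNV substituted by the cut allele) until
#' another occurrence of the same recognition site is encountered on either
#' strand; the amplicon ends just before those occurrences, so the cut
#' allele's amplicon contains exactly one diagnostic site.  If no further
#' occurrence exists the amplicon runs to the scaffold edge and is flagged
#' truncated.
#'
#' @param assay a [find_rflp()] result
#' @param reference [Biostrings::DNAStringSet] or [simulate_reference()]
#'   result
#' @return the assay with columns added: `amp_start`, `amp_end` (1-based
#'   inclusive), `amp_length`, `cut_at` (top-strand cut point, cut falls
#'   after this base), `frag_cut_left`, `frag_cut_right`, `truncated`
#' @export
extend_amplicon <- function(assay, reference) {
  stopifnot(inherits(assay, "marker_assay"))
  seqs <- ref_seqs(reference)
  chrom <- as.character(seqs[[assay$scaffold]])
  chrom <- sub_base(chrom, assay$pos, assay$cut_allele)
  occ <- match_motif(assay$motif, chrom)
  diag <- occ$start <= assay$pos & occ$end >= assay$pos
  if (!any(diag))
    stop("diagnostic recognition site not found on the scaffold; ",
         "reference and assay disagree")
  dstart <- occ$start[which(diag)[1L]]; dend <- occ$end[which(diag)[1L]]
  left <- occ[occ$end < dstart, , drop = FALSE]
  right <- occ[occ$start > dend, , drop = FALSE]
  truncated <- FALSE
  if (nrow(left)) amp_start <- max(left$end) + 1L
  else { amp_start <- 1L; truncated <- TRUE }
  if (nrow(right)) amp_end <- min(right$start) - 1L
  else { amp_end <- nchar(chrom); truncated <- TRUE }
  d <- which(diag)[1L]
  cut_at <- cut_point(occ$start[d], occ$end[d], occ$strand[d], assay$cut_offset)
  assay$amp_start <- amp_start
  assay$amp_end <- amp_end
  assay$amp_length <- amp_end - amp_start + 1L
  assay$cut_at <- cut_at
  assay$frag_cut_left <- cut_at - amp_start + 1L
  assay$frag_cut_right <- amp_end - cut_at
  assay$truncated <- truncated
  assay
}

#' In-silico digest of a sequence with one enzyme
#'
#' Cuts at every top-strand cut point implied by motif occurrences on either
#' strand and returns the fragment lengths in order.
#'
#' @param seq character sequence
#' @param motif IUPAC recognition motif
#' @param cut_offset top-strand cut offset within the motif
#' @return integer vector of fragment lengths (sums to `nchar(seq)`)
#' @export
digest_fragments <- function(seq, motif, cut_offset) {
  occ <- match_motif(motif, seq)
  if (!nrow(occ)) return(nchar(seq))
  cuts <- sort(unique(mapply(cut_point, occ$start, occ$end, occ$strand,
                             MoreArgs = list(cut_offset = cut_offset))))
  cuts <- cuts[cuts >= 1L & cuts < nchar(seq)]
  diff(c(0L, cuts, nchar(seq)))
}

#' Predict RFLP band patterns per genotype class
#'
#' The uncut homozygote yields the whole amplicon (1 band); the cut
#' homozygote yields the two digestion fragments (2 bands); a heterozygote
#' carries both templates and yields their union (3 bands).  Fragments
#' shorter than `min_frag` are dropped as unresolvable on a gel.
#'
#' @param assay an [extend_amplicon()] result
#' @param genotype `"hom_pop1"`, `"hom_pop2"` or `"het"`
#' @param min_frag smallest reportable fragment (default 20 b)
#' @return list with `fragments` (decreasing lengths) and `n_bands`
#' @export
predict_bands <- function(assay, genotype = c("hom_pop1", "hom_pop2", "het"),
                          min_frag = 20L) {
  genotype <- match.arg(genotype)
  stopifnot(!is.null(assay$amp_length))
  cut_frags <- c(assay$frag_cut_left, assay$frag_cut_right)
  frags <- if (genotype == "het") c(assay$amp_length, cut_frags)
  else if (genotype == paste0("hom_", assay$cut_pop)) cut_frags
  else assay$amp_length
  frags <- sort(unique(frags[frags >= min_frag]), decreasing = TRUE)
  list(fragments = frags, n_bands = length(frags))
}

#' Decode an observed band count into a genotype class
#'
#' @param assay an [extend_amplicon()] result (supplies which population's
#'   allele is cut)
#' @param n_bands observed band count, 1, 2 or 3
#' @return `"hom_pop1"`, `"hom_pop2"` or `"het"`
#' @export
genotype_from_bands <- function(assay, n_bands) {
  if (!n_bands %in% 1:3) stop("band count must be 1, 2 or 3")
  uncut <- setdiff(c("pop1", "pop2"), assay$cut_pop)
  switch(n_bands, paste0("hom_", uncut), paste0("hom_", assay$cut_pop), "het")
}

#' Assign a sample to a taxon from a multilocus RFLP genotype
#'
#' A sample scoring homozygous for population 1's allele at every locus is
#' assigned to population 1 (likewise for population 2); heterozygous at
#' every locus is consistent with a first-generation inter-population
#' hybrid ("F1-like"); any other combination is reported as mixed with the
#' per-class locus counts.
#'
#' @param calls character vector of per-locus genotype classes
#'   (`"hom_pop1"`, `"hom_pop2"`, `"het"`); `NA` loci are excluded with a
#'   warning
#' @return list: `assignment` (`"pop1"`, `"pop2"`, `"F1-like"` or
#'   `"mixed"`), `n_loci`, `counts`
#' @export
assign_taxon <- function(calls) {
  if (any(is.na(calls))) {
    warning(sum(is.na(calls)), " unscored locus/loci excluded")
    calls <- calls[!is.na(calls)]
  }
  if (!length(calls)) stop("no scored loci")
  bad <- setdiff(unique(calls), c("hom_pop1", "hom_pop2", "het"))
  if (length(bad)) stop("unknown genotype class: ", paste(bad, collapse = ", "))
  counts <- c(hom_pop1 = sum(calls == "hom_pop1"),
              hom_pop2 = sum(calls == "hom_pop2"),
              het = sum(calls == "het"))
  assignment <- if (counts["hom_pop1"] == length(calls)) "pop1"
  else if (counts["hom_pop2"] == length(calls)) "pop2"
  else if (counts["het"] == length(calls)) "F1-like"
  else "mixed"
  list(assignment = assignment, n_loci = length(calls), counts = counts)
}
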