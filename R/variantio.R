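#' Site filter thresholds
#'
#' Thresholds for the joint-calling site filters: keep a site when its total
#' read depth over all samples is strictly below `max_total_depth` (guards
#' against collapsed repeats and duplicated regions), its mean mapping
#' quality is strictly above `min_mean_mapq`, and the fraction of reads
#' mapped with quality zero is strictly below `max_mq0_fraction`.
#' `min_qual_highquality` is the inclusive Phred-scaled site quality cutoff
#' for the "high quality" subset used in marker design.
#'
#' @param max_total_depth maximum summed depth, exclusive (default 1200)
#' @param min_mean_mapq minimum mean mapping quality, exclusive (default 30)
#' @param max_mq0_fraction maximum MQ0 fraction, exclusive (default 0.05)
#' @param min_qual_highquality minimum site QUAL, inclusive (default 900)
#' @return a list of class `filter_config`
#' @export
filter_config <- function(max_total_depth = 1200,
                          min_mean_mapq = 30,
                          max_mq0_fraction = 0.05,
                          min_qual_highquality = 900) {
  fc <- list(max_total_depth = max_total_depth,
             min_mean_mapq = min_mean_mapq,
             max_mq0_fraction = max_mq0_fraction,
             min_qual_highquality = min_qual_highquality)
  if (any(unlist(fc) < 0)) stop("all filter thresholds must be >= 0")
  structure(fc, class = "filter_config")
}

info_num <- function(vcf, key) {
  v <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
  v
}

#' Read a multi-sample VCF into genotype matrices
#'
#' Parses biallelic SNV and short-indel records into two [genotype_matrix()]
#' objects (substitutions and indels separately).  Genotypes are stored as
#' copies of the first (reference) allele: `0/0 -> 2`, `0/1 -> 1`,
#' `1/1 -> 0`, `./. -> NA`.  A record is an indel when its REF and ALT
#' lengths differ by 1-20 bases; length differences above 20 are skipped.
#' Records with symbolic alleles (`<...>`) are skipped with a message.
#'
#' @param path VCF file (v4.x, plain text or bgzipped)
#' @param sample_map named character vector (sample id -> population label),
#'   a data.frame with columns `sample` and `population`, or `NULL` to keep
#'   all samples.  Samples named in the map but absent from the VCF are an
#'   error; VCF samples not in the map are dropped.
#' @param multiallelic `"error"` (default) to reject records with more than
#'   one ALT allele, or `"split"` to expand each ALT into its own biallelic
#'   record (reference-allele copy counts are computed against REF, so a
#'   genotype carrying two different ALT alleles contributes 0).
#' @return list with elements `snv` and `indel`, both `genotype_matrix`
#'   objects carrying `qual`, `total_depth` (INFO/DP), `mean_mapq` (INFO/MQ)
#'   and `mq0_fraction` (INFO/MQ0F) site columns
#' @export
read_vcf <- function(path, sample_map = NULL,
                     multiallelic = c("error", "split")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0L) stop("VCF contains no variant records")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L,
                                     dimnames = list(NULL, names(gt)))

  if (!is.null(sample_map)) {
    if (is.data.frame(sample_map))
      sample_map <- stats::setNames(as.character(sample_map$population),
                                    as.character(sample_map$sample))
    absent <- setdiff(names(sample_map), colnames(gt))
    if (length(absent))
      stop("sample(s) in the population map are absent from the VCF: ",
           paste(absent, collapse = ", "))
    gt <- gt[, names(sample_map), drop = FALSE]
  }

  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  dp <- info_num(vcf, "DP"); mq <- info_num(vcf, "MQ"); mq0f <- info_num(vcf, "MQ0F")

  symbolic <- grepl("^<", alt) | grepl("\\*", alt)
  if (any(symbolic))
    message(sum(symbolic), " record(s) with symbolic alleles skipped")
  multi <- !symbolic & grepl(",", alt, fixed = TRUE)
  if (any(multi) && multiallelic == "error")
    stop(sum(multi), " multiallelic record(s) found; this analysis is ",
         "restricted to biallelic sites (use multiallelic = \"split\" to expand)")

  # copies of the first (reference) allele per call; identical for every
  # biallelic row a multiallelic record is split into, since only REF copies
  # are counted
  gvals <- unique(as.vector(gt))
  cnt_map <- vapply(gvals, function(g) {
    if (is.na(g) || !grepl("^[0-9]+([/|][0-9]+)?$", g)) return(NA_integer_)
    sum(strsplit(g, "[/|]")[[1]] == "0")
  }, integer(1L))
  cnt <- matrix(cnt_map[match(as.vector(gt), gvals)], nrow = nrow(gt),
                dimnames = dimnames(gt))

  idx_keep <- which(!symbolic)
  if (!length(idx_keep))
    stop("no usable variant records after skipping symbolic alleles")
  alts <- strsplit(alt[idx_keep], ",", fixed = TRUE)
  n_alts <- lengths(alts)
  rep_idx <- rep(idx_keep, n_alts)
  sites <- data.frame(scaffold = chrom[rep_idx], pos = pos[rep_idx],
                      ref = ref[rep_idx], alt = unlist(alts),
                      qual = qual[rep_idx], total_depth = dp[rep_idx],
                      mean_mapq = mq[rep_idx], mq0_fraction = mq0f[rep_idx],
                      stringsAsFactors = FALSE)
  geno <- cnt[rep_idx, , drop = FALSE]

  len_diff <- abs(nchar(sites$ref) - nchar(sites$alt))
  too_long <- len_diff > 20L
  if (any(too_long))
    message(sum(too_long), " record(s) with length difference > 20 b skipped")
  is_indel <- len_diff >= 1L & !too_long
  is_snv <- len_diff == 0L & nchar(sites$ref) == 1L
  list(snv = genotype_matrix(sites[is_snv, , drop = FALSE],
                             geno[is_snv, , drop = FALSE]),
       indel = genotype_matrix(sites[is_indel, , drop = FALSE],
                               geno[is_indel, , drop = FALSE]))
}

#' Apply the joint-calling site filters
#'
#' Retains sites whose total depth, mean mapping quality and MQ0 fraction all
#' pass the [filter_config()] thresholds (depth and MQ0 strictly below their
#' maxima, mapping quality strictly above its minimum).  The three predicates
#' are conjunctive, so the operation is idempotent and order-independent.
#'
#' @param gm a [genotype_matrix()] whose sites carry `total_depth`,
#'   `mean_mapq` and `mq0_fraction`
#' @param fc a [filter_config()]
#' @return the filtered `genotype_matrix`, site order preserved, with an
#'   attribute `"rejections"`: named counts of sites failing each filter
#'   (a site may count against several)
#' @export
apply_site_filters <- function(gm, fc = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  for (col in c("total_depth", "mean_mapq", "mq0_fraction"))
    if (is.null(gm$sites[[col]]) || all(is.na(gm$sites[[col]])))
      stop("site annotation field missing: ", col)
  s <- gm$sites
  pass_depth <- !is.na(s$total_depth) & s$total_depth < fc$max_total_depth
  pass_mapq <- !is.na(s$mean_mapq) & s$mean_mapq > fc$min_mean_mapq
  pass_mq0 <- !is.na(s$mq0_fraction) & s$mq0_fraction < fc$max_mq0_fraction
  keep <- pass_depth & pass_mapq & pass_mq0
  out <- subset_sites(gm, keep)
  attr(out, "rejections") <- c(total_depth = sum(!pass_depth),
                               mean_mapq = sum(!pass_mapq),
                               mq0_fraction = sum(!pass_mq0))
  out
}

#' High-quality site subset
#'
#' Retains sites whose Phred-scaled QUAL is at least
#' `fc$min_qual_highquality` (inclusive, default 900).
#'
#' @inheritParams apply_site_filters
#' @return the filtered `genotype_matrix`, site order preserved
#' @export
high_quality_subset <- function(gm, fc = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$sites$qual)) stop("site annotation field missing: qual")
  subset_sites(gm, !is.na(gm$sites$qual) &
                 gm$sites$qual >= fc$min_qual_highquality)
}

#' Write / read the flat gd_snp-style genotype table
#'
#' A tab-separated table with one row per site: `scaffold`, `pos` (1-based),
#' `ref`, `alt`, `qual`, then one reference-allele copy-count column per
#' sample (missing calls written as `-1`).  The round trip
#' `read_gdsnp(write_gdsnp(gm))` is lossless for those fields.
#'
#' @param gm a [genotype_matrix()]
#' @param path output / input file path
#' @return `write_gdsnp`: `path`, invisibly.  `read_gdsnp`: a
#'   `genotype_matrix`.
#' @export
write_gdsnp <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  g[is.na(g)] <- -1L
  tab <- cbind(gm$sites[, c("scaffold", "pos", "ref", "alt")],
               qual = if (is.null(gm$sites$qual)) NA_real_ else gm$sites$qual,
               as.data.frame(g))
  names(tab) <- c("scaffold", "pos", "ref", "alt", "qual", gm$samples)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gdsnp
#' @export
read_gdsnp <- function(path) {
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE, colClasses = NA),
    error = function(e) stop("malformed gd_snp table '", path, "': ",
                             conditionMessage(e)))
  need <- c("scaffold", "pos", "ref", "alt", "qual")
  if (!all(need %in% names(tab)) || ncol(tab) < 6L)
    stop("gd_snp table must have columns scaffold, pos, ref, alt, qual and ",
         "at least one sample column")
  sample_cols <- setdiff(names(tab), need)
  g <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (!is.numeric(g)) {
    bad <- which(apply(tab[, sample_cols, drop = FALSE], 1L,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))) & r != "")))
    stop("malformed genotype value at line ", bad[1L] + 1L, " of ", path)
  }
  storage.mode(g) <- "integer"
  g[g < 0L] <- NA_integer_
  genotype_matrix(data.frame(scaffold = as.character(tab$scaffold),
                             pos = as.integer(tab$pos),
                             ref = as.character(tab$ref),
                             alt = as.character(tab$alt),
                             qual = as.numeric(tab$qual),
                             stringsAsFactors = FALSE),
                  g)
}
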