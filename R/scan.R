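#' Score-shift per-site F_ST values
#'
#' Subtracts a constant shift (default 0.90) from each per-SNV F_ST so that
#' runs of strongly differentiated SNVs accumulate positive score and the
#' background drags the score down.  Sites with an undefined F_ST are
#' dropped here, so they neither break nor join runs.
#'
#' @param fst_tab a [fst_table()] result
#' @param shift constant subtracted from each F_ST (default 0.90)
#' @return data.frame `scaffold`, `pos`, `fst`, `score`, ordered as the
#'   input, undefined sites removed
#' @export
shift_scores <- function(fst_tab, shift = 0.90) {
  ok <- !is.na(fst_tab$fst)
  out <- data.frame(scaffold = fst_tab$scaffold[ok], pos = fst_tab$pos[ok],
                    fst = fst_tab$fst[ok],
                    score = fst_tab$fst[ok] - shift,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "shift") <- shift
  out
}

# Ruzzo-Tompa all-maximal-scoring-subsequences decomposition of one numeric
# vector.  Returns start/end indices and total score of every maximal
# positive-scoring subsequence, in left-to-right order.
rt_decompose <- function(x) {
  n <- length(x)
  l <- r <- integer(0L); Lc <- Rc <- numeric(0L)
  cum <- 0
  for (i in seq_len(n)) {
    before <- cum
    cum <- cum + x[i]
    if (is.na(x[i])) stop("scores must not contain NA")
    if (x[i] <= 0) next
    kl <- i; kr <- i; kL <- before; kR <- cum
    repeat {
      cand <- which(Lc < kL)
      if (!length(cand)) { # no containing run: new maximal subsequence
        l <- c(l, kl); r <- c(r, kr); Lc <- c(Lc, kL); Rc <- c(Rc, kR)
        break
      }
      j <- max(cand)
      if (Rc[j] >= kR) { # previous run dominates: keep new one separately
        l <- c(l, kl); r <- c(r, kr); Lc <- c(Lc, kL); Rc <- c(Rc, kR)
        break
      }
      # merge: runs j..current are absorbed into one, then retry
      kl <- l[j]; kL <- Lc[j]
      keep <- seq_len(j - 1L)
      l <- l[keep]; r <- r[keep]; Lc <- Lc[keep]; Rc <- Rc[keep]
    }
  }
  data.frame(start_idx = l, end_idx = r, score = Rc - Lc)
}

#' Maximal-scoring intervals of consecutive SNVs
#'
#' Decomposes the score-shifted SNV sequence of each scaffold into all
#' maximal-scoring subsequences (Ruzzo-Tompa): every returned interval has a
#' positive total score that cannot be increased by adding or removing SNVs
#' at either end, intervals are disjoint, and no interval spans a scaffold
#' boundary.  These are the "genomic islands of divergence" candidates.
#'
#' @param scored a [shift_scores()] result (positional order per scaffold)
#' @return data.frame of class `divergence_intervals`: `scaffold`,
#'   `start`/`end` (positions of the first/last member SNV, 1-based
#'   inclusive), `n_snvs`, `segment_score`, `mean_fst`, and `i_start`/`i_end`
#'   (row range in `scored`)
#' @export
maximal_segments <- function(scored) {
  if (nrow(scored) == 0L) {
    out <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), n_snvs = integer(),
                      segment_score = numeric(), mean_fst = numeric(),
                      i_start = integer(), i_end = integer())
    class(out) <- c("divergence_intervals", "data.frame")
    return(out)
  }
  res <- list()
  for (sc in unique(scored$scaffold)) {
    idx <- which(scored$scaffold == sc)
    if (is.unsorted(scored$pos[idx]))
      stop("scores must be in positional order within scaffold ", sc)
    seg <- rt_decompose(scored$score[idx])
    if (!nrow(seg)) next
    gi <- idx[seg$start_idx]; gj <- idx[seg$end_idx]
    res[[sc]] <- data.frame(
      scaffold = sc,
      start = scored$pos[gi], end = scored$pos[gj],
      n_snvs = seg$end_idx - seg$start_idx + 1L,
      segment_score = seg$score,
      mean_fst = mapply(function(a, b) mean(scored$fst[a:b]), gi, gj),
      i_start = gi, i_end = gj,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(scaffold = character(), start = integer(),
                                      end = integer(), n_snvs = integer(),
                                      segment_score = numeric(),
                                      mean_fst = numeric(),
                                      i_start = integer(), i_end = integer())
  rownames(out) <- NULL
  class(out) <- c("divergence_intervals", "data.frame")
  out
}

#' @export
print.divergence_intervals <- function(x, ...) {
  cat(sprintf("divergence_intervals: %d interval(s)", nrow(x)))
  if (nrow(x))
    cat(sprintf(", spans %d-%d b, %d-%d SNVs, top score %.3f",
                min(x$end - x$start), max(x$end - x$start),
                min(x$n_snvs), max(x$n_snvs), max(x$segment_score)))
  cat("\n")
  if (nrow(x)) print.data.frame(head(x[order(-x$segment_score), ], 6L))
  invisible(x)
}

#' Summarize a divergence interval
#'
#' @param intervals a [maximal_segments()] result
#' @param scored the [shift_scores()] table the intervals were derived from
#' @return data.frame: `scaffold`, `start`, `end`, `span` (end - start, in
#'   bases, matching the convention that a 4-SNV interval at 321729-321734
#'   spans 5 b), `n_snvs`, `segment_score`, `mean_fst`; member SNV positions
#'   in a list column `positions`
#' @export
interval_summary <- function(intervals, scored) {
  stopifnot(inherits(intervals, "divergence_intervals"))
  out <- intervals[, c("scaffold", "start", "end", "n_snvs",
                       "segment_score", "mean_fst")]
  out$span <- out$end - out$start
  out$positions <- mapply(function(a, b) scored$pos[a:b],
                          intervals$i_start, intervals$i_end, SIMPLIFY = FALSE)
  out[, c("scaffold", "start", "end", "span", "n_snvs", "segment_score",
          "mean_fst", "positions")]
}

#' Export intervals as BED
#'
#' @param intervals a [maximal_segments()] result
#' @param path output path; 0-based half-open coordinates, score column
#'   carries the segment score
#' @return `path`, invisibly
#' @export
write_intervals_bed <- function(intervals, path) {
  writeLines(sprintf("%s\t%d\t%d\tinterval_%d\t%g", intervals$scaffold,
                     intervals$start - 1L, intervals$end,
                     seq_len(nrow(intervals)), intervals$segment_score),
              path)
  invisible(path)
}

overlaps_any <- function(wst, ivs) {
  hit <- rep(FALSE, nrow(wst))
  for (i in seq_len(nrow(ivs))) {
    hit <- hit | (wst$scaffold == ivs$scaffold[i] &
                    wst$start <= ivs$end[i] & wst$end >= ivs$start[i])
  }
  hit
}

#' Contrast divergence islands with random background intervals
#'
#' Draws length-matched random intervals (same SNV count as each detected
#' interval, placed at a uniformly chosen SNV of the same scaffold), then
#' compares 500-b windows overlapping the detected islands against windows
#' overlapping the random intervals with two-sided Mann-Whitney U tests
#' (normal approximation) on within-population nucleotide diversity and on
#' d_XY.  Divergence islands shaped by a sweep are expected to show lower
#' diversity and higher absolute divergence than the background.
#'
#' @param intervals a [maximal_segments()] result
#' @param wstats a [window_stats()] result
#' @param scored the [shift_scores()] table (supplies SNV positions for
#'   random placement)
#' @param n_random number of random intervals (default: one per detected
#'   interval, lengths recycled)
#' @param seed integer seed for the random placement
#' @return object of class `island_contrast`: data.frame with one row per
#'   statistic (`pi_pop1`, `pi_pop2`, `dxy`): `U`, `p`, `n_island`,
#'   `n_background`, `median_island`, `median_background`
#' @export
islands_vs_background <- function(intervals, wstats, scored,
                                  n_random = nrow(intervals), seed = 1L) {
  stopifnot(inherits(intervals, "divergence_intervals"))
  if (nrow(intervals) == 0L) stop("no intervals to contrast")
  set.seed(seed)
  lens <- rep_len(intervals$n_snvs, n_random)
  rnd <- vector("list", n_random)
  scafs <- unique(scored$scaffold)
  for (i in seq_len(n_random)) {
    sc <- sample(scafs, 1L)
    idx <- which(scored$scaffold == sc)
    k <- min(lens[i], length(idx))
    a <- idx[sample.int(length(idx) - k + 1L, 1L)]
    b <- idx[match(a, idx) + k - 1L]
    rnd[[i]] <- data.frame(scaffold = sc, start = scored$pos[a],
                           end = scored$pos[b])
  }
  rnd <- do.call(rbind, rnd)
  isl_w <- overlaps_any(wstats, intervals)
  bgd_w <- overlaps_any(wstats, rnd)
  if (sum(isl_w) < 2L || sum(bgd_w) < 2L)
    stop("too few windows overlap the island or background intervals; ",
         "lower min_snvs or simulate denser data")
  one <- function(var) {
    x <- wstats[[var]][isl_w]; y <- wstats[[var]][bgd_w]
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    data.frame(statistic = var, U = unname(wt$statistic), p = wt$p.value,
               n_island = length(x), n_background = length(y),
               median_island = stats::median(x),
               median_background = stats::median(y),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("pi_pop1", "pi_pop2", "dxy"), one))
  rownames(out) <- NULL
  class(out) <- c("island_contrast", "data.frame")
  out
}

#' @export
print.island_contrast <- function(x, ...) {
  cat("island vs background window contrast (Mann-Whitney U, two-sided)\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Per-scaffold F_ST track plot
#'
#' Minimal convenience plot: per-SNV F_ST along one scaffold with detected
#' intervals shaded.
#'
#' @param fst_tab a [fst_table()] result
#' @param scaffold scaffold to draw
#' @param intervals optional [maximal_segments()] result
#' @param ... passed to [graphics::plot()]
#' @return invisibly, `NULL`
#' @export
plot_fst_track <- function(fst_tab, scaffold, intervals = NULL, ...) {
  s <- fst_tab[fst_tab$scaffold == scaffold & !is.na(fst_tab$fst), ]
  graphics::plot(s$pos, s$fst, pch = 16, cex = 0.4, col = "grey40",
                 xlab = sprintf("%s position (b)", scaffold),
                 ylab = expression(F[ST]), ylim = c(min(0, s$fst), 1), ...)
  if (!is.null(intervals)) {
    iv <- intervals[intervals$scaffold == scaffold, ]
    if (nrow(iv))
      graphics::rect(iv$start, graphics::par("usr")[3], iv$end,
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor("steelblue", 0.25),
                     border = NA)
  }
  invisible(NULL)
}
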