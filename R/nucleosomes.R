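#' Sliding windows tiling a genome
#'
#' Half-open windows of `size` bp every `step` bp; the final window of each
#' chromosome is truncated at the chromosome end.
#'
#' @param genome a [comp_genome()].
#' @param size window size (bp).
#' @param step step between window starts (bp).
#' @param chroms optional subset of chromosomes.
#' @return `data.frame` with `chrom`, `start`, `end`.
#' @export
sliding_windows <- function(genome, size = 1000L, step = 500L,
                            chroms = NULL) {
  lens <- chrom_lengths(genome)
  if (!is.null(chroms)) lens <- lens[chroms]
  out <- lapply(names(lens), function(ch) {
    starts <- seq(0L, lens[[ch]] - 1L, by = step)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + size, lens[[ch]])))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Windows centered on anchors (e.g. TSSs)
#'
#' @param genome a [comp_genome()].
#' @param anchors `data.frame` with `chrom`, `pos`.
#' @param size window size (bp); windows are clipped at chromosome ends.
#' @return `data.frame` with `chrom`, `start`, `end`.
#' @export
anchor_windows <- function(genome, anchors, size = 1000L) {
  lens <- chrom_lengths(genome)
  half <- size %/% 2L
  data.frame(chrom = anchors$chrom,
             start = pmax(0L, anchors$pos - half),
             end = pmin(as.integer(lens[anchors$chrom]),
                        anchors$pos + half))
}

# Smoothed density of nucleosomal fragment midpoints along one chromosome.
# Gaussian kernel truncated at 5 bandwidths, so the density at a position
# depends only on fragments within that radius; this makes per-window calling
# exactly equal to whole-chromosome calling on window interiors.
midpoint_density <- function(mids, weights, chrom_len, bw) {
  cnt <- numeric(chrom_len)
  if (length(mids) > 0) {
    agg <- rowsum(weights, mids)
    cnt[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  half <- ceiling(5 * bw)
  kern <- dnorm(seq(-half, half), sd = bw)
  padded <- c(rep(0, half), cnt, rep(0, half))
  sm <- stats::filter(padded, kern, sides = 2)
  as.numeric(sm[(half + 1):(half + chrom_len)])
}

#' Call positioned nucleosome dyads
#'
#' Within each window, midpoints of nucleosome-sized fragments (length in
#' `nuc_len_range`) are Gaussian-kernel smoothed; local maxima whose density
#' exceeds `threshold_mult` times the chromosome's uniform-placement
#' expectation become candidate dyads. Candidates from overlapping windows
#' are deduplicated: within `min_separation` bp, only the highest-scoring
#' candidate survives. This midpoint-density caller reproduces dyad positions
#' and fragment-size bands; it is not an occupancy model.
#'
#' @param fragments fragment `data.frame`.
#' @param windows `data.frame` with `chrom`, `start`, `end` (from
#'   [sliding_windows()] or [anchor_windows()]).
#' @param genome a [comp_genome()].
#' @param nuc_len_range numeric length-2; nucleosome-spanning fragment
#'   lengths (bp).
#' @param kernel_bw Gaussian kernel bandwidth (bp).
#' @param threshold_mult score threshold in units of the expected density
#'   under uniform placement of the chromosome's nucleosomal fragments.
#' @param min_separation minimum distance between called dyads (bp).
#' @return `data.frame` of dyad calls: `chrom`, `pos`, `score`.
#' @export
call_dyads <- function(fragments, windows, genome,
                       nuc_len_range = c(160L, 250L), kernel_bw = 20,
                       threshold_mult = 2, min_separation = 120L) {
  if (nuc_len_range[1] > nuc_len_range[2])
    stop2("nuc_len_range must be increasing")
  if (nrow(fragments) == 0) stop2("empty fragment set")
  lens <- chrom_lengths(genome)
  fw <- fragments$weight %||% rep(1, nrow(fragments))
  len <- fragments$end - fragments$start
  nuc <- len >= nuc_len_range[1] & len <= nuc_len_range[2]
  cands <- list()
  for (ch in unique(windows$chrom)) {
    n <- lens[[ch]]
    sel <- which(fragments$chrom == ch & nuc)
    mids <- (fragments$start[sel] + fragments$end[sel]) %/% 2L
    dens <- midpoint_density(mids, fw[sel], n, kernel_bw)
    thr <- threshold_mult * sum(fw[sel]) / n
    wch <- windows[windows$chrom == ch, , drop = FALSE]
    # local maxima over the union of windows; neighbours taken from the
    # whole-chromosome density so window boundaries do not create maxima
    pos_all <- integer(0)
    for (j in seq_len(nrow(wch)))
      pos_all <- c(pos_all, seq(wch$start[j], wch$end[j] - 1L))
    pos_all <- sort(unique(pos_all))
    p <- pos_all[pos_all >= 1L & pos_all <= n - 2L]   # need both neighbours
    i <- p + 1L                                        # 1-based index
    is_max <- dens[i] > dens[i - 1L] & dens[i] >= dens[i + 1L] &
      dens[i] >= thr
    if (any(is_max))
      cands[[ch]] <- data.frame(chrom = ch, pos = p[is_max],
                                score = dens[i[is_max]])
  }
  if (length(cands) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      score = numeric()))
  cand <- do.call(rbind, cands)
  dedup_dyads(cand, min_separation)
}

# Greedy dedup: keep the highest-scoring candidate, drop all others within
# min_separation, repeat. Ties broken toward the leftmost position.
dedup_dyads <- function(cand, min_separation) {
  out <- list()
  for (ch in unique(cand$chrom)) {
    cc <- cand[cand$chrom == ch, , drop = FALSE]
    cc <- cc[order(-cc$score, cc$pos), , drop = FALSE]
    kept <- integer(0)
    for (j in seq_len(nrow(cc))) {
      if (all(abs(cc$pos[j] - kept) >= min_separation))
        kept <- c(kept, cc$pos[j])
    }
    keep_rows <- cc[cc$pos %in% kept, , drop = FALSE]
    out[[ch]] <- keep_rows[order(keep_rows$pos), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' V-plot matrix: fragment length vs midpoint offset
#'
#' For every fragment-anchor incidence with midpoint offset in `[-W, W]` and
#' fragment length inside `length_range`, the cell (length, offset) is
#' incremented by the fragment weight. Offsets are strand-oriented when the
#' anchors carry a `strand` column. Positioned nucleosomes appear as a
#' V-shaped density centered at offset 0 in the nucleosomal length rows.
#'
#' @param fragments fragment `data.frame`.
#' @param anchors `data.frame` with `chrom`, `pos`, optional `strand`
#'   (dyads or TSSs).
#' @param W half-window (bp).
#' @param length_range numeric length-2, rows of the matrix.
#' @return an object of class `vplot_matrix`: list with `matrix`
#'   (lengths x offsets), `lengths`, `offsets`, `total` (mass = number of
#'   weighted incidences).
#' @export
make_vplot <- function(fragments, anchors, W = 200L,
                       length_range = c(20L, 300L)) {
  W <- as.integer(W)
  lens_rows <- seq(length_range[1], length_range[2])
  offs <- seq(-W, W)
  mat <- matrix(0, nrow = length(lens_rows), ncol = length(offs),
                dimnames = list(lens_rows, offs))
  if (is.null(anchors$strand)) anchors$strand <- "+"
  fw <- fragments$weight %||% rep(1, nrow(fragments))
  flen <- fragments$end - fragments$start
  mid <- (fragments$start + fragments$end) %/% 2L
  for (ch in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == ch)
    fi <- which(fragments$chrom == ch & flen >= length_range[1] &
                  flen <= length_range[2])
    if (length(fi) == 0) next
    m <- mid[fi]
    ord <- order(m)
    fi <- fi[ord]; m <- m[ord]
    for (a in ai) {
      p <- anchors$pos[a]
      j1 <- findInterval(p - W - 1L, m) + 1L
      j2 <- findInterval(p + W, m)
      if (j2 < j1) next
      sgn <- if (anchors$strand[a] == "-") -1L else 1L
      for (j in j1:j2) {
        off <- sgn * (m[j] - p)
        if (abs(off) > W) next
        r <- flen[fi[j]] - length_range[1] + 1L
        c_ <- off + W + 1L
        mat[r, c_] <- mat[r, c_] + fw[fi[j]]
      }
    }
  }
  structure(list(matrix = mat, lengths = lens_rows, offsets = offs,
                 total = sum(mat)),
            class = "vplot_matrix")
}

#' @export
print.vplot_matrix <- function(x, ...) {
  cat(sprintf("vplot_matrix: lengths %d-%d x offsets [%d, %d], mass %.1f\n",
              min(x$lengths), max(x$lengths), min(x$offsets),
              max(x$offsets), x$total))
  invisible(x)
}

#' Dyad-to-TSS offset distribution
#'
#' Aggregates strand-oriented offsets of called dyads around anchors, with
#' every dyad extended by +/- 5 bp (an 11-bp footprint), matching the usual
#' plotting convention for positioned-nucleosome maps.
#'
#' @param dyads `data.frame` with `chrom`, `pos` (from [call_dyads()]).
#' @param anchors `data.frame` with `chrom`, `pos`, `strand`.
#' @param W half-window (bp).
#' @param extend half-width of the dyad footprint (bp; default 5).
#' @return `data.frame` with `offset` (-W..W) and `count`.
#' @export
dyad_tss_distribution <- function(dyads, anchors, W = 500L, extend = 5L) {
  offs <- seq(-W, W)
  counts <- numeric(length(offs))
  if (nrow(dyads) == 0) {
    warning("empty dyad list", call. = FALSE)
    return(data.frame(offset = offs, count = counts))
  }
  if (is.null(anchors$strand)) anchors$strand <- "+"
  for (ch in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == ch)
    dp <- sort(dyads$pos[dyads$chrom == ch])
    if (length(dp) == 0) next
    for (a in ai) {
      p <- anchors$pos[a]
      sgn <- if (anchors$strand[a] == "-") -1L else 1L
      j1 <- findInterval(p - W - extend - 1L, dp) + 1L
      j2 <- findInterval(p + W + extend, dp)
      if (j2 < j1) next
      for (j in j1:j2) {
        off <- sgn * (dp[j] - p)
        lo <- max(-W, off - extend); hi <- min(W, off + extend)
        if (hi < lo) next
        idx <- (lo + W + 1L):(hi + W + 1L)
        counts[idx] <- counts[idx] + 1
      }
    }
  }
  data.frame(offset = offs, count = counts)
}
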