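#' Per-anchor coverage matrix and TSS metaplot
#'
#' Builds the matrix of weighted fragment coverage around a set of anchors
#' (typically TSSs), one row per anchor and one column per position in
#' `[-W, W]`. Rows of minus-strand anchors are flipped so that positive
#' offsets always point in the direction of transcription. Coverage counts
#' full fragment spans; set `cut_sites = TRUE` to count only the two
#' fragment ends (transposase insertion points).
#'
#' @param fragments fragment `data.frame`.
#' @param anchors `data.frame` with `chrom`, `pos` (0-based) and optionally
#'   `strand` (defaults to `"+"`).
#' @param W half-window in bp.
#' @param bin aggregation bin width (bp); `W` must be a multiple of `bin`.
#' @param cut_sites count fragment end points instead of spans.
#' @return an object of class `profile_matrix`: list with `matrix`
#'   (anchors x positions), `positions` (bin-center offsets), `anchors`, and
#'   `metaplot` (column means).
#' @export
tss_profile <- function(fragments, anchors, W = 500L, bin = 1L,
                        cut_sites = FALSE) {
  W <- as.integer(W); bin <- as.integer(bin)
  if (W %% bin != 0) stop2("W must be a multiple of bin")
  if (is.null(anchors$strand)) anchors$strand <- "+"
  n_pos <- 2L * W + 1L
  fw <- fragments$weight %||% rep(1, nrow(fragments))
  mat <- matrix(0, nrow = nrow(anchors), ncol = n_pos)
  maxlen <- if (nrow(fragments) > 0) max(fragments$end - fragments$start)
            else 0L
  for (ch in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == ch)
    fi <- which(fragments$chrom == ch)
    if (length(fi) == 0) next
    fs <- fragments$start[fi]; fe <- fragments$end[fi]; w <- fw[fi]
    ord <- order(fs)
    fs <- fs[ord]; fe <- fe[ord]; w <- w[ord]
    for (a in ai) {
      p <- anchors$pos[a]
      lo <- p - W; hi <- p + W              # window [lo, hi] inclusive
      j1 <- findInterval(lo - maxlen - 1L, fs) + 1L
      j2 <- findInterval(hi, fs)
      if (j2 < j1) next
      jj <- j1:j2
      jj <- jj[fe[jj] > lo]                  # overlap [lo, hi+1)
      row <- numeric(n_pos)
      for (j in jj) {
        if (cut_sites) {
          for (cp in c(fs[j], fe[j] - 1L)) {
            if (cp >= lo && cp <= hi)
              row[cp - lo + 1L] <- row[cp - lo + 1L] + w[j]
          }
        } else {
          c1 <- max(fs[j], lo); c2 <- min(fe[j] - 1L, hi)
          if (c2 >= c1)
            row[(c1 - lo + 1L):(c2 - lo + 1L)] <-
              row[(c1 - lo + 1L):(c2 - lo + 1L)] + w[j]
        }
      }
      if (anchors$strand[a] == "-") row <- rev(row)
      mat[a, ] <- row
    }
  }
  positions <- seq(-W, W)
  if (bin > 1L) {
    grp <- rep(seq_len(ceiling(n_pos / bin)), each = bin)[seq_len(n_pos)]
    mat <- t(apply(mat, 1, function(r) tapply(r, grp, mean)))
    positions <- as.numeric(tapply(positions, grp, mean))
  }
  structure(list(matrix = mat, positions = positions, anchors = anchors,
                 metaplot = colMeans(mat)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d anchors x %d positions [%d, %d]\n",
              nrow(x$matrix), ncol(x$matrix), min(x$positions),
              max(x$positions)))
  invisible(x)
}

#' Per-gene signal quantification
#'
#' RPKM over promoters (`TSS +/- promoter_half` bp) or gene bodies, with
#' optional mappability correction, as used to relate accessibility to
#' transcription gene by gene.
#'
#' @param fragments fragment `data.frame`.
#' @param genes gene table as in [comp_genome()].
#' @param genome a [comp_genome()] (for chromosome bounds).
#' @param mode `"promoter"` or `"gene_body"`.
#' @param promoter_half promoter half-width in bp.
#' @param track optional `mappability_track`.
#' @return named numeric vector of corrected RPKM per gene id.
#' @export
quantify_gene_signal <- function(fragments, genes, genome,
                                 mode = c("promoter", "gene_body"),
                                 promoter_half = 250L, track = NULL) {
  mode <- match.arg(mode)
  lens <- chrom_lengths(genome)
  if (mode == "promoter") {
    tss <- gene_tss(genes)
    start <- pmax(0L, tss$pos - promoter_half)
    end <- pmin(as.integer(lens[tss$chrom]), tss$pos + promoter_half + 1L)
    regions <- data.frame(chrom = tss$chrom, start = start, end = end)
  } else {
    regions <- data.frame(chrom = genes$chrom, start = genes$start,
                          end = genes$end)
  }
  r <- compute_rpkm(fragments, regions, track)
  setNames(r$rpkm_corrected, genes$id)
}

#' Spearman rank correlation with midrank ties
#'
#' @param x,y numeric vectors of equal length; pairs with `NA` are dropped.
#' @return rho in `[-1, 1]`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Simplified Poisson peak caller
#'
#' Slides windows of `window` bp in steps of `step` along each chromosome,
#' counts fragment midpoints, and tests each count against
#' `Poisson(lambda_local)` where `lambda_local` is the larger of the
#' genome-wide rate and the local rate in `+/- local_bg_span` around the
#' window center (both scaled to the window size). Overlapping significant
#' windows are merged; the summit is the base of maximum fragment coverage.
#' This is a deliberately small stand-in for a full peak caller: no fragment
#' shifting model and only a two-level background hierarchy.
#'
#' @param fragments fragment `data.frame`.
#' @param genome a [comp_genome()].
#' @param window window size (bp, `>= 50`).
#' @param step step between window starts (default `window / 2`).
#' @param local_bg_span half-span of the local background (bp).
#' @param p_threshold Poisson upper-tail significance threshold.
#' @return `data.frame` of peaks: `chrom`, `start`, `end`, `summit`,
#'   `fold_enrichment`, `p_value`. Zero rows (with a warning) on an empty
#'   library.
#' @export
call_peaks_simple <- function(fragments, genome, window = 300L,
                              step = window %/% 2L, local_bg_span = 5000L,
                              p_threshold = 1e-5) {
  if (window < 50) stop2("window must be >= 50 bp")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      fold_enrichment = numeric(), p_value = numeric())
  if (nrow(fragments) == 0) {
    warning("empty fragment library: no peaks", call. = FALSE)
    return(empty)
  }
  scan <- scan_windows(fragments, genome, window, step, local_bg_span)
  sig <- scan[scan$p_value <= p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  peaks <- list()
  fw <- fragments$weight %||% rep(1, nrow(fragments))
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, s$start[-1] > cummax(s$end[-nrow(s)])))
    fi <- which(fragments$chrom == ch)
    n <- chrom_lengths(genome)[[ch]]
    cov <- numeric(n)
    for (j in fi) {
      cov[(fragments$start[j] + 1L):fragments$end[j]] <-
        cov[(fragments$start[j] + 1L):fragments$end[j]] + fw[j]
    }
    for (g in split(seq_len(nrow(s)), grp)) {
      st <- min(s$start[g]); en <- max(s$end[g])
      summit <- st + which.max(cov[(st + 1L):en]) - 1L
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ch, start = st, end = en, summit = summit,
        fold_enrichment = max(s$fold[g]), p_value = min(s$p_value[g]))
    }
  }
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Sliding-window Poisson scan (all windows, with p-values)
#'
#' The per-window scan behind [call_peaks_simple()], exposed for calibration
#' studies of the caller's type-I error.
#'
#' @inheritParams call_peaks_simple
#' @return `data.frame` with one row per window: `chrom`, `start`, `end`,
#'   `count`, `lambda`, `fold`, `p_value`.
#' @export
scan_windows <- function(fragments, genome, window = 300L,
                         step = window %/% 2L, local_bg_span = 5000L) {
  lens <- chrom_lengths(genome)
  fw <- fragments$weight %||% rep(1, nrow(fragments))
  total_w <- sum(fw)
  genome_len <- sum(lens)
  out <- list()
  for (ch in names(lens)) {
    n <- lens[[ch]]
    fi <- which(fragments$chrom == ch)
    mid <- (fragments$start[fi] + fragments$end[fi]) %/% 2L
    cnt <- numeric(n)
    if (length(fi) > 0) {
      agg <- rowsum(fw[fi], mid)
      cnt[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    }
    S <- cumsum(c(0, cnt))
    starts <- seq(0L, max(0L, n - window), by = step)
    wc <- S[pmin(starts + window, n) + 1L] - S[starts + 1L]
    centers <- starts + window %/% 2L
    bg_lo <- pmax(0L, centers - local_bg_span)
    bg_hi <- pmin(n, centers + local_bg_span)
    bg_rate <- (S[bg_hi + 1L] - S[bg_lo + 1L]) / (bg_hi - bg_lo)
    lambda <- pmax(total_w / genome_len, bg_rate) * window
    p <- ppois(ceiling(wc) - 1L, lambda, lower.tail = FALSE)
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = pmin(starts + window, n),
                            count = wc, lambda = lambda,
                            fold = wc / lambda, p_value = p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Random control "peaks" from fixed-width genome bins
#'
#' Splits each chromosome into `bin`-bp bins and returns the boundary
#' coordinates of every bin (deduplicated), giving a position set with no
#' relation to the annotation -- the flat-background control for peak-to-TSS
#' distance histograms.
#'
#' @param genome a [comp_genome()].
#' @param bin bin width in bp (default 500).
#' @return `data.frame` with `chrom` and `pos`.
#' @export
random_control_peaks <- function(genome, bin = 500L) {
  lens <- chrom_lengths(genome)
  out <- lapply(names(lens), function(ch) {
    pos <- unique(c(seq(0L, lens[[ch]], by = bin), lens[[ch]]))
    data.frame(chrom = ch, pos = as.integer(pos))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signed peak-to-nearest-TSS distance histogram
#'
#' For each peak summit, the signed strand-oriented distance to the nearest
#' anchor (positive = downstream of the anchor). Ties between two equidistant
#' anchors are broken toward the upstream anchor (positive distance). Values
#' beyond `+/- R` are pooled into the edge bins.
#'
#' @param peaks `data.frame` with `chrom` and `summit` (or `pos`).
#' @param anchors `data.frame` with `chrom`, `pos`, `strand`.
#' @param R histogram half-range (bp).
#' @param bin histogram bin width (bp).
#' @return `data.frame` with `mid` (bin center), `count`; attribute
#'   `distances` holds the raw signed distances.
#' @export
peak_tss_distances <- function(peaks, anchors, R = 2000L, bin = 100L) {
  pos <- peaks$summit %||% peaks$pos
  if (is.null(anchors$strand)) anchors$strand <- "+"
  d <- rep(NA_real_, length(pos))
  for (ch in unique(peaks$chrom)) {
    pi_ <- which(peaks$chrom == ch)
    ai <- which(anchors$chrom == ch)
    if (length(ai) == 0) next
    ap <- anchors$pos[ai]
    sgn <- ifelse(anchors$strand[ai] == "+", 1, -1)
    for (i in pi_) {
      delta <- pos[i] - ap
      sd_ <- delta * sgn                     # strand-oriented
      best <- which(abs(sd_) == min(abs(sd_)))
      if (length(best) > 1) best <- best[which.max(sd_[best])]
      d[i] <- sd_[best]
    }
  }
  d <- d[!is.na(d)]
  clipped <- pmax(pmin(d, R), -R)
  mids <- seq(-R, R, by = bin)
  idx <- round((clipped + R) / bin) + 1L
  idx <- pmax(1L, pmin(idx, length(mids)))
  out <- data.frame(mid = mids,
                    count = tabulate(idx, nbins = length(mids)))
  attr(out, "distances") <- d
  out
}
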