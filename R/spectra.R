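#' Fragment-length spectrum of a compartment
#'
#' Weighted histogram of fragment lengths (end - start) for the fragments
#' mapping to one compartment. In ATAC-seq these spectra are diagnostic of
#' chromatin state: nucleosomal compartments show a subnucleosomal peak plus
#' a nucleosomal peak or shoulder, while naked-DNA compartments
#' (mitochondrion, plastid) are unimodal.
#'
#' @param fragments fragment `data.frame`.
#' @param genome a [comp_genome()].
#' @param compartment compartment label to select.
#' @return an object of class `fragment_spectrum`: list with `compartment`,
#'   `length` (1..max), `count` (weighted), `total` and `density`
#'   (sums to 1).
#' @export
length_spectrum <- function(fragments, genome, compartment) {
  fragments <- validate_fragments(fragments, genome)
  sel <- genome$compartment[fragments$chrom] == compartment
  if (!any(sel)) stop2("no fragments in compartment ", compartment)
  len <- (fragments$end - fragments$start)[sel]
  w <- (fragments$weight %||% rep(1, nrow(fragments)))[sel]
  maxlen <- max(len)
  count <- vapply(split(w, factor(len, levels = 1:maxlen)), sum, numeric(1))
  count[is.na(count)] <- 0
  total <- sum(w)
  structure(list(compartment = compartment, length = 1:maxlen,
                 count = unname(count), total = total,
                 density = unname(count) / total),
            class = "fragment_spectrum")
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat(sprintf("fragment_spectrum (%s): total weight %.1f, lengths 1-%d\n",
              x$compartment, x$total, max(x$length)))
  invisible(x)
}

# Gaussian smoothing of a density over the integer length grid, with
# reflective boundary at length 0.
smooth_density <- function(density, bw) {
  n <- length(density)
  half <- ceiling(4 * bw)
  kern <- dnorm(seq(-half, half), sd = bw)
  kern <- kern / sum(kern)
  pad_left <- c(rep(0, max(0L, half - n)), rev(density[seq_len(min(half, n))]))
  padded <- c(pad_left, density, rep(0, half))
  sm <- stats::filter(padded, kern, sides = 2)
  as.numeric(sm[(half + 1):(half + n)])
}

#' Detect modes of a fragment-length spectrum
#'
#' Local maxima of the kernel-smoothed density whose prominence (height above
#' the higher of the two flanking minima) exceeds `min_prominence` times the
#' maximum smoothed density. Smoothing uses a Gaussian kernel with reflective
#' boundary at length 0.
#'
#' @param spectrum a `fragment_spectrum` from [length_spectrum()].
#' @param smoothing_bw Gaussian kernel bandwidth in bp (default 10).
#' @param min_prominence minimum relative prominence (default 0.05).
#' @return `data.frame` with columns `mode` (bp) and `prominence`
#'   (relative), sorted by length.
#' @export
detect_modes <- function(spectrum, smoothing_bw = 10, min_prominence = 0.05) {
  if (smoothing_bw <= 0) stop2("smoothing_bw must be positive")
  if (spectrum$total <= 0) stop2("empty spectrum")
  d <- smooth_density(spectrum$density, smoothing_bw)
  n <- length(d)
  if (n < 3)
    return(data.frame(mode = which.max(d), prominence = 1))
  is_max <- c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] &
                d[2:(n - 1)] >= d[3:n], FALSE)
  # endpoints can be maxima too
  is_max[1] <- d[1] > d[2]
  is_max[n] <- d[n] > d[n - 1]
  cand <- which(is_max)
  if (length(cand) == 0) cand <- which.max(d)
  peak <- max(d)
  # topographic prominence: base = lowest point between the peak and the
  # nearest higher point on each side (or the spectrum boundary)
  prom <- vapply(cand, function(p) {
    higher_left <- which(d[seq_len(p - 1)] > d[p])
    il <- if (length(higher_left) > 0) max(higher_left) else 1L
    left <- if (p == 1) 0 else min(d[il:p])
    higher_right <- if (p < n) p + which(d[(p + 1):n] > d[p]) else integer(0)
    ir <- if (length(higher_right) > 0) min(higher_right) else n
    right <- if (p == n) 0 else min(d[p:ir])
    (d[p] - max(left, right)) / peak
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(mode = cand[keep], prominence = prom[keep])
}
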