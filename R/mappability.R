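#' Genome mappability tracks
#'
#' A genome is tiled with reads ("tiles") of a fixed length L at every start
#' position fully inside a chromosome. A tile is uniquely mapping iff its
#' sequence occurs exactly once in the whole genome, counting occurrences of
#' the sequence and of its reverse complement on the forward strands of all
#' chromosomes (a read can align to either strand). The mappability of a
#' position is the number of unique tiles covering it divided by the number
#' of tiles covering it -- R/L in chromosome interiors, with the denominator
#' reduced near chromosome ends so that a fully unique genome scores 1
#' everywhere.
#'
#' Uniqueness is decided by exact k-mer multiplicity; unlike an aligner, no
#' mismatches are tolerated, so this is a slightly stricter criterion than
#' mismatch-tolerant mapping.
#'
#' @param genome a [comp_genome()], or a named character vector of sequences.
#' @param read_length tile length L in bp (`>= 1`).
#' @return an object of class `mappability_track`: a list with `read_length`
#'   and `score`, a named list of per-position numeric vectors in `[0, 1]`.
#' @export
compute_mappability <- function(genome, read_length) {
  seqs <- if (inherits(genome, "comp_genome")) genome$sequences else genome
  L <- as.integer(read_length)
  if (L < 1) stop2("read_length must be >= 1")
  if (length(seqs) == 0 || any(!nzchar(seqs))) stop2("genome is empty")
  lens <- nchar(seqs)
  short <- names(seqs)[lens < L]
  if (length(short) > 0)
    stop2("read_length ", L, " exceeds chromosome length for: ",
          paste(short, collapse = ", "))
  # all tiles genome-wide, then per-tile multiplicity incl. reverse strand
  tiles <- lapply(seqs, function(s) {
    st <- seq_len(nchar(s) - L + 1L)
    substring(s, st, st + L - 1L)
  })
  all_tiles <- unlist(tiles, use.names = FALSE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(all_tiles)))
  keys <- unique(c(all_tiles, rc))
  fwd <- match(all_tiles, keys)
  rev <- match(rc, keys)
  cnt <- tabulate(fwd, nbins = length(keys))
  is_unique <- (cnt[fwd] + cnt[rev]) == 1L
  score <- list()
  off <- 0L
  for (ch in names(seqs)) {
    nt <- lens[[ch]] - L + 1L
    uniq <- as.numeric(is_unique[(off + 1L):(off + nt)])
    off <- off + nt
    # tiles covering position i: starts in [i-L+1, i]; windowed sums of the
    # start indicators give numerator and denominator in O(n)
    cu <- cumsum(c(0, uniq))
    num <- cu[pmin(seq_len(lens[[ch]]), nt) + 1L] -
      cu[pmax(seq_len(lens[[ch]]) - L, 0L) + 1L]
    den <- pmin(seq_len(lens[[ch]]), nt) - pmax(seq_len(lens[[ch]]) - L, 0L)
    score[[ch]] <- num / den
  }
  structure(list(read_length = L, score = score),
            class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  cat(sprintf("mappability_track: L = %d, %d chromosomes, mean M = %.4f\n",
              x$read_length, length(x$score),
              mean(unlist(x$score, use.names = FALSE))))
  invisible(x)
}

# Mean mappability over a 0-based half-open region; 1 if track is NULL.
region_mean_mappability <- function(track, chrom, start, end) {
  if (is.null(track)) return(1)
  v <- track$score[[chrom]]
  if (is.null(v)) stop2("mappability track has no chromosome ", chrom)
  mean(v[(start + 1L):end])
}

#' Mappability correction of an RPKM value
#'
#' Multiplies an RPKM by the reciprocal of the region's average mappability.
#'
#' @param rpkm uncorrected RPKM value(s).
#' @param region list or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param track a `mappability_track` from [compute_mappability()].
#' @return corrected RPKM; `NA` with a warning if the region's mean
#'   mappability is 0 (unquantifiable region).
#' @export
mappability_correct_rpkm <- function(rpkm, region, track) {
  m <- region_mean_mappability(track, region$chrom, region$start, region$end)
  if (m == 0) {
    warning("region ", region$chrom, ":", region$start, "-", region$end,
            " has zero mappability; RPKM unquantifiable", call. = FALSE)
    return(NA_real_)
  }
  rpkm / m
}
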