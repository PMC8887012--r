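#' Bin Hi-C pairs into a contact matrix
#'
#' Builds a genome-wide bin table at the given resolution and counts each
#' pair once into its (bin1, bin2) cell, symmetrized. The stored matrix is
#' dense and symmetric; [contact_sum()] (upper triangle including the
#' diagonal) equals the number of pairs exactly.
#'
#' @param pairs pairs `data.frame` (`chrom1`, `pos1`, `chrom2`, `pos2`).
#' @param genome a [comp_genome()].
#' @param resolution bin size in bp (`>= 1`).
#' @return an object of class `contact_matrix`: list with `resolution`,
#'   `bins` (`chrom`, `start`, `end`), `matrix`, `normalization` (`"NONE"`),
#'   `weights` (`NULL` until balanced) and `mask` (logical, excluded bins).
#' @export
bin_contacts <- function(pairs, genome, resolution) {
  resolution <- as.integer(resolution)
  if (resolution < 1) stop2("resolution must be >= 1")
  lens <- chrom_lengths(genome)
  bins <- do.call(rbind, lapply(names(lens), function(ch) {
    starts <- seq(0L, lens[[ch]] - 1L, by = resolution)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + resolution, lens[[ch]])),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  offset <- c(0, cumsum(tapply(rep(1, nrow(bins)),
                               factor(bins$chrom, levels = names(lens)),
                               sum)))
  names(offset) <- c(names(lens), "..end")
  nb <- nrow(bins)
  mat <- matrix(0, nb, nb)
  if (nrow(pairs) > 0) {
    i <- offset[pairs$chrom1] + pairs$pos1 %/% resolution + 1L
    j <- offset[pairs$chrom2] + pairs$pos2 %/% resolution + 1L
    for (k in seq_along(i)) {
      mat[i[k], j[k]] <- mat[i[k], j[k]] + 1
      if (i[k] != j[k]) mat[j[k], i[k]] <- mat[j[k], i[k]] + 1
    }
  }
  structure(list(resolution = resolution, bins = bins, matrix = mat,
                 normalization = "NONE", weights = NULL,
                 mask = rep(FALSE, nb)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "contact_matrix: %d bins @ %d bp, %s pairs, normalization %s\n",
    nrow(x$bins), x$resolution,
    format(contact_sum(x), big.mark = ","), x$normalization))
  invisible(x)
}

#' Total contact mass of a matrix (upper triangle incl. diagonal)
#' @param cm a `contact_matrix`.
#' @return numeric scalar.
#' @export
contact_sum <- function(cm) {
  m <- cm$matrix
  sum(m[upper.tri(m, diag = TRUE)])
}

# Indices of a chromosome's bins in the global bin table.
bin_index <- function(cm, chrom) {
  which(cm$bins$chrom == chrom)
}

#' Balance a contact matrix
#'
#' `NONE` returns the matrix unchanged. `VC` divides each cell by the product
#' of its row and column sums and `VC_SQRT` by the square root of that
#' product; both are rescaled to preserve the total contact mass. `KR`
#' (Knight-Ruiz) finds a positive vector `x` with `x_i * (C x)_i = 1` over
#' unmasked bins and returns `x_i c_ij x_j`, whose nonzero row sums are all
#' equal (to 1) at convergence. Bins with zero coverage are always masked;
#' for KR, bins with fewer than `mask_min` raw contacts are masked as well
#' (sparse rows stall the iteration).
#'
#' @param cm a `contact_matrix` with raw counts.
#' @param method `"NONE"`, `"VC"`, `"VC_SQRT"` or `"KR"`.
#' @param mask_min minimum raw row sum for a bin to enter KR balancing.
#' @param tol convergence tolerance on `max |x_i (Cx)_i - 1|`.
#' @param max_iter maximum iterations for KR.
#' @return a `contact_matrix` with balanced `matrix`, `weights` and updated
#'   `normalization` tag; masked rows/columns are zero.
#' @export
balance <- function(cm, method = c("NONE", "VC", "VC_SQRT", "KR"),
                    mask_min = 5, tol = 1e-7, max_iter = 5000L) {
  method <- match.arg(method)
  if (cm$normalization != "NONE")
    stop2("matrix is already normalized (", cm$normalization, ")")
  if (method == "NONE") return(cm)
  m <- cm$matrix
  rs <- rowSums(m)
  if (all(rs == 0)) stop2("matrix has no nonzero row")
  mask <- rs == 0
  if (method == "KR") mask <- mask | rs < mask_min
  if (all(mask)) stop2("all bins masked; lower mask_min")
  out <- cm
  out$mask <- mask
  keep <- !mask
  if (method %in% c("VC", "VC_SQRT")) {
    denom <- outer(rs, rs)
    if (method == "VC_SQRT") denom <- sqrt(denom)
    b <- matrix(0, nrow(m), ncol(m))
    b[keep, keep] <- m[keep, keep] / denom[keep, keep]
    total_raw <- sum(m[upper.tri(m, diag = TRUE)])
    total_b <- sum(b[upper.tri(b, diag = TRUE)])
    b <- b * (total_raw / total_b)
    out$matrix <- b
    out$weights <- ifelse(keep, 1 / if (method == "VC") rs else sqrt(rs),
                          NA_real_)
    out$normalization <- method
    return(out)
  }
  # KR: symmetric fixed-point iteration x <- x / sqrt(x * (Cx))
  sub <- m[keep, keep, drop = FALSE]
  x <- rep(1, nrow(sub))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- x * as.vector(sub %*% x)
    if (max(abs(r - 1)) < tol) { converged <- TRUE; break }
    x <- x / sqrt(r)
  }
  if (!converged)
    stop2("KR balancing did not converge in ", max_iter,
          " iterations; consider masking sparse bins (raise mask_min)")
  b <- matrix(0, nrow(m), ncol(m))
  b[keep, keep] <- sub * outer(x, x)
  w <- rep(NA_real_, nrow(m))
  w[keep] <- x
  out$matrix <- b
  out$weights <- w
  out$normalization <- "KR"
  out
}

#' Contact frequency as a function of genomic separation
#'
#' Mean contact value over all bin pairs at each separation within one
#' chromosome, the standard cis distance-decay curve P(s).
#'
#' @param cm a `contact_matrix` (raw or balanced).
#' @param chrom chromosome name.
#' @param log_bins if `TRUE`, pool separations into log2-spaced bins.
#' @return `data.frame` with `separation` (bp), `mean_contact` and
#'   `n_pairs` (bin pairs averaged).
#' @export
distance_decay <- function(cm, chrom, log_bins = FALSE) {
  idx <- bin_index(cm, chrom)
  sub <- cm$matrix[idx, idx, drop = FALSE]
  nb <- length(idx)
  seps <- 0:(nb - 1)
  mean_contact <- vapply(seps, function(s) {
    v <- sub[cbind(seq_len(nb - s), seq_len(nb - s) + s)]
    mean(v)
  }, numeric(1))
  n_pairs <- nb - seps
  out <- data.frame(separation = seps * cm$resolution,
                    mean_contact = mean_contact, n_pairs = n_pairs)
  if (log_bins) {
    grp <- floor(log2(pmax(out$separation / cm$resolution, 0.5)))
    agg <- data.frame(
      separation = tapply(out$separation, grp, mean),
      mean_contact = tapply(out$mean_contact * out$n_pairs, grp, sum) /
        tapply(out$n_pairs, grp, sum),
      n_pairs = tapply(out$n_pairs, grp, sum))
    rownames(agg) <- NULL
    out <- agg
  }
  out
}

#' Trans-contact profile of one chromosome
#'
#' For each target chromosome, the summed contact between source and target
#' bins divided by the number of (unmasked) source x target bin pairs -- the
#' per-bin-pair trans contact frequency used to rank a chromosome's physical
#' neighbours.
#'
#' @param cm a `contact_matrix` (raw or balanced).
#' @param source_chrom source chromosome name.
#' @return `data.frame` with `target`, `frequency`, `normalization`.
#' @export
trans_profile <- function(cm, source_chrom) {
  src <- bin_index(cm, source_chrom)
  src <- src[!cm$mask[src]]
  if (length(src) == 0) stop2("all source bins are masked")
  targets <- setdiff(unique(cm$bins$chrom), source_chrom)
  freq <- vapply(targets, function(tg) {
    ti <- bin_index(cm, tg)
    ti <- ti[!cm$mask[ti]]
    if (length(ti) == 0) return(NA_real_)
    sum(cm$matrix[src, ti]) / (length(src) * length(ti))
  }, numeric(1))
  data.frame(target = targets, frequency = unname(freq),
             normalization = cm$normalization, stringsAsFactors = FALSE)
}

#' Telomere interaction network score
#'
#' Quantifies telomere-to-telomere contact enrichment. For every pair of
#' distinct telomere-annotated chromosomes, the observed contact mass between
#' telomeric bins is compared with the mass expected if the pair's trans
#' contacts were spread uniformly over its bin pairs (total trans mass times
#' the telomeric bin-pair fraction). The global ratio pools observed and
#' expected over all pairs; a ratio > 1 indicates a telomeric interaction
#' network. The per-chromosome cis end-to-end fold (first vs last telomere
#' of the same chromosome, relative to the cis average) is also reported.
#'
#' @param cm a `contact_matrix`.
#' @param telomeres `data.frame` with `chrom`, `start`, `end`; defaults to
#'   the outermost `default_width` bp of every nucleomorph chromosome when a
#'   genome is supplied instead.
#' @param genome optional [comp_genome()] used to derive default telomeres.
#' @param default_width width of the default telomere windows (bp).
#' @return list with `ratio` (global observed/expected), `pairs` (per
#'   chromosome-pair table) and `cis_end_fold` (per chromosome).
#' @export
telomere_network_score <- function(cm, telomeres = NULL, genome = NULL,
                                   default_width = 10000L) {
  if (is.null(telomeres)) {
    if (is.null(genome) || nrow(genome$telomeres) == 0) {
      if (is.null(genome)) stop2("need telomeres or a genome")
      lens <- chrom_lengths(genome)
      nm <- names(lens)[genome$compartment == "nucleomorph"]
      telomeres <- do.call(rbind, lapply(nm, function(ch) {
        data.frame(chrom = ch, start = c(0L, lens[[ch]] - default_width),
                   end = c(default_width, lens[[ch]]))
      }))
    } else {
      telomeres <- genome$telomeres
    }
  }
  chroms <- unique(telomeres$chrom)
  if (length(chroms) < 2) stop2("need telomeres on at least 2 chromosomes")
  tel_bins <- lapply(setNames(chroms, chroms), function(ch) {
    ti <- bin_index(cm, ch)
    b <- cm$bins[ti, ]
    tl <- telomeres[telomeres$chrom == ch, , drop = FALSE]
    hit <- rep(FALSE, length(ti))
    for (j in seq_len(nrow(tl)))
      hit <- hit | (b$start < tl$end[j] & b$end > tl$start[j])
    ti[hit]
  })
  pairs_tab <- list()
  obs_tot <- 0; exp_tot <- 0
  for (a in seq_along(chroms)) {
    for (b in seq_along(chroms)) {
      if (b <= a) next
      ia <- bin_index(cm, chroms[a]); ib <- bin_index(cm, chroms[b])
      ta <- tel_bins[[chroms[a]]]; tb <- tel_bins[[chroms[b]]]
      tot <- sum(cm$matrix[ia, ib])
      obs <- sum(cm$matrix[ta, tb])
      frac <- (length(ta) * length(tb)) / (length(ia) * length(ib))
      expd <- tot * frac
      obs_tot <- obs_tot + obs; exp_tot <- exp_tot + expd
      pairs_tab[[length(pairs_tab) + 1L]] <- data.frame(
        chrom_a = chroms[a], chrom_b = chroms[b], observed = obs,
        expected = expd,
        ratio = if (expd > 0) obs / expd else NA_real_)
    }
  }
  cis_fold <- vapply(setNames(chroms, chroms), function(ch) {
    ti <- bin_index(cm, ch)
    tl <- telomeres[telomeres$chrom == ch, , drop = FALSE]
    if (nrow(tl) < 2) return(NA_real_)
    b <- cm$bins[ti, ]
    e1 <- ti[b$start < tl$end[1] & b$end > tl$start[1]]
    e2 <- ti[b$start < tl$end[nrow(tl)] & b$end > tl$start[nrow(tl)]]
    e2 <- setdiff(e2, e1)
    if (length(e1) == 0 || length(e2) == 0) return(NA_real_)
    obs <- sum(cm$matrix[e1, e2])
    tot <- sum(cm$matrix[ti, ti])
    frac <- 2 * length(e1) * length(e2) / length(ti)^2
    if (tot * frac > 0) 2 * obs / (tot * frac) else NA_real_
  }, numeric(1))
  list(ratio = if (exp_tot > 0) obs_tot / exp_tot else NA_real_,
       pairs = do.call(rbind, pairs_tab),
       cis_end_fold = cis_fold)
}

#' Write a contact matrix as dense TSV (+ optional weights)
#'
#' @param cm a `contact_matrix`.
#' @param path output TSV path; row/column names are `chrom:start`.
#' @param weights_path optional TSV of per-bin balancing weights.
#' @return the path, invisibly.
#' @export
write_contact_matrix <- function(cm, path, weights_path = NULL) {
  lab <- paste0(cm$bins$chrom, ":", cm$bins$start)
  m <- cm$matrix
  dimnames(m) <- list(lab, lab)
  dt <- data.table::as.data.table(m, keep.rownames = "bin")
  data.table::fwrite(dt, path, sep = "\t")
  if (!is.null(weights_path)) {
    w <- data.frame(bin = lab,
                    weight = cm$weights %||% rep(NA_real_, nrow(cm$bins)),
                    masked = cm$mask)
    data.table::fwrite(w, weights_path, sep = "\t")
  }
  invisible(path)
}
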