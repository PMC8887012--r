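#' Multimapper weight assignment
#'
#' Reads aligned with unlimited multimappers are normalized by splitting each
#' fragment's unit weight uniformly across its candidate placements: each
#' placement of a k-way multimapper receives weight 1/k, so total weight per
#' fragment is 1 and genome-wide weight equals the number of fragments. This
#' uniform split is a simple, conservative stand-in for model-based
#' multimapper reallocation schemes.
#'
#' @param placements a list; element i is a `data.frame` of candidate
#'   placements (`chrom`, `start`, `end`) for fragment i.
#' @return fragment `data.frame` with a `weight` column.
#' @export
assign_multimapper_weights <- function(placements) {
  if (length(placements) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), weight = numeric()))
  k <- vapply(placements, nrow, integer(1))
  if (any(k == 0)) stop2("fragment ", which(k == 0)[1],
                         " has an empty placement list")
  out <- do.call(rbind, placements)
  out$weight <- rep(1 / k, k)
  rownames(out) <- NULL
  out
}

# Sum of fragment-midpoint weights falling in each region (single assignment
# per fragment, so total weight is conserved across a partition).
region_weights <- function(fragments, regions) {
  w <- numeric(nrow(regions))
  mid <- (fragments$start + fragments$end) %/% 2L
  fw <- fragments$weight %||% rep(1, nrow(fragments))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    fi <- which(fragments$chrom == ch)
    if (length(fi) == 0) next
    m <- mid[fi]
    for (j in ri)
      w[j] <- sum(fw[fi][m >= regions$start[j] & m < regions$end[j]])
  }
  w
}

#' Mappability-corrected RPKM per region
#'
#' RPKM = (fragment weight in region) / (region kbp x library size / 1e6),
#' multiplied by the reciprocal of the region's mean mappability. A fragment
#' belongs to a region iff its midpoint does, so fragments are never double
#' counted across a partition of the genome.
#'
#' @param fragments fragment `data.frame` (`chrom`, `start`, `end`,
#'   optional `weight`).
#' @param regions `data.frame` with `chrom`, `start`, `end` and optionally
#'   `id` (0-based half-open).
#' @param track optional `mappability_track`; `NULL` means no correction.
#' @param library_size total fragment weight of the library; defaults to
#'   `sum(fragments$weight)`.
#' @return `regions` with columns `weight`, `rpkm` (uncorrected),
#'   `mean_mappability` and `rpkm_corrected` appended.
#' @export
compute_rpkm <- function(fragments, regions, track = NULL,
                         library_size = NULL) {
  if (any(regions$end <= regions$start))
    stop2("zero- or negative-length region")
  fw <- fragments$weight %||% rep(1, nrow(fragments))
  library_size <- library_size %||% sum(fw)
  if (library_size <= 0) stop2("library size must be positive")
  regions$weight <- region_weights(fragments, regions)
  kb <- (regions$end - regions$start) / 1000
  regions$rpkm <- regions$weight / (kb * library_size / 1e6)
  regions$mean_mappability <- vapply(seq_len(nrow(regions)), function(j) {
    region_mean_mappability(track, regions$chrom[j], regions$start[j],
                            regions$end[j])
  }, numeric(1))
  regions$rpkm_corrected <- ifelse(
    regions$mean_mappability > 0,
    regions$rpkm / regions$mean_mappability, NA_real_)
  if (anyNA(regions$rpkm_corrected))
    warning("region(s) with zero mappability are unquantifiable",
            call. = FALSE)
  regions
}

#' Fraction of library weight per compartment
#'
#' @param fragments fragment `data.frame`.
#' @param genome a [comp_genome()].
#' @return named numeric vector over the genome's compartments, summing to 1.
#' @export
compartment_read_fractions <- function(fragments, genome) {
  fragments <- validate_fragments(fragments, genome)
  fw <- fragments$weight %||% rep(1, nrow(fragments))
  comp <- genome$compartment[fragments$chrom]
  tot <- tapply(fw, factor(comp, levels = unique(genome$compartment)), sum,
                default = 0)
  out <- tot / sum(fw)
  setNames(as.numeric(out), names(tot))
}

#' Relative copy-number estimates from an input library
#'
#' Computes mappability-corrected RPKM per chromosome from a DNA-mass input
#' library and rescales so the median nuclear chromosome equals 1 (haploid
#' nucleus reference).
#'
#' @param fragments input fragment `data.frame`.
#' @param genome a [comp_genome()].
#' @param track optional `mappability_track`.
#' @return named numeric vector of relative copy numbers per chromosome.
#' @export
estimate_copy_numbers <- function(fragments, genome, track = NULL) {
  lens <- chrom_lengths(genome)
  regions <- data.frame(chrom = names(lens), start = 0L,
                        end = as.integer(lens))
  r <- compute_rpkm(fragments, regions, track)
  nuc <- r$rpkm_corrected[genome$compartment[r$chrom] == "nucleus"]
  if (length(nuc) == 0 || all(is.na(nuc)))
    stop2("no nuclear chromosome to anchor copy-number estimates")
  setNames(r$rpkm_corrected / median(nuc, na.rm = TRUE), r$chrom)
}

# Region sets for the supported enrichment groupings.
enrichment_groups <- function(genome, group_by) {
  lens <- chrom_lengths(genome)
  chrom_regions <- data.frame(chrom = names(lens), start = 0L,
                              end = as.integer(lens),
                              stringsAsFactors = FALSE)
  if (group_by == "chromosome") {
    chrom_regions$group <- chrom_regions$chrom
    return(chrom_regions)
  }
  if (group_by == "compartment") {
    chrom_regions$group <- unname(genome$compartment[chrom_regions$chrom])
    return(chrom_regions)
  }
  if (group_by == "region_class") {
    rd <- genome$genes[genome$genes$is_rdna, , drop = FALSE]
    if (nrow(rd) == 0) stop2("genome has no rDNA annotation")
    rdna <- data.frame(chrom = rd$chrom, start = rd$start, end = rd$end,
                       group = "rdna", stringsAsFactors = FALSE)
    nm <- names(lens)[genome$compartment == "nucleomorph"]
    rest <- list()
    for (ch in nm) {
      cuts <- sort(unique(c(0L, rd$start[rd$chrom == ch],
                            rd$end[rd$chrom == ch], lens[[ch]])))
      iv <- data.frame(chrom = ch, start = head(cuts, -1),
                       end = tail(cuts, -1), stringsAsFactors = FALSE)
      # drop the rDNA pieces themselves
      in_rdna <- vapply(seq_len(nrow(iv)), function(j) {
        any(rd$chrom == ch & rd$start <= iv$start[j] & rd$end >= iv$end[j])
      }, logical(1))
      rest[[ch]] <- iv[!in_rdna, , drop = FALSE]
    }
    rest <- do.call(rbind, rest)
    rest$group <- "nucleomorph_rest"
    return(rbind(rdna, rest))
  }
  stop2("unknown grouping: ", group_by)
}

#' Treatment-versus-input enrichment table
#'
#' For each group (compartment, chromosome, or rDNA vs the rest of the
#' nucleomorph), computes the mappability-corrected RPKM of the treatment and
#' input libraries and their ratio. Group RPKM pools fragment weight and
#' region length across the group's regions (it is not a mean of
#' per-chromosome ratios), and both libraries are normalized by their own
#' size, so enrichment is invariant to sequencing depth.
#'
#' @param treatment,input fragment `data.frame`s (e.g. ATAC or KAS vs a
#'   DNA-mass input).
#' @param genome a [comp_genome()].
#' @param track optional `mappability_track` applied to both libraries.
#' @param group_by `"compartment"`, `"chromosome"` or `"region_class"`.
#' @param normalize_to optional group name; the `enrichment` column is
#'   divided by this group's enrichment (e.g. `"nucleus"` to express
#'   organellar enrichment relative to the host genome).
#' @return `data.frame` with one row per group: `group`, `treatment_rpkm`,
#'   `input_rpkm`, `enrichment`. Groups with zero input weight get `NA`
#'   enrichment with a warning.
#' @export
compute_enrichment <- function(treatment, input, genome, track = NULL,
                               group_by = c("compartment", "chromosome",
                                            "region_class"),
                               normalize_to = NULL) {
  group_by <- match.arg(group_by)
  if (nrow(treatment) == 0 || nrow(input) == 0)
    stop2("treatment and input libraries must be non-empty")
  regions <- enrichment_groups(genome, group_by)
  tw <- treatment$weight %||% rep(1, nrow(treatment))
  iw <- input$weight %||% rep(1, nrow(input))
  rt <- compute_rpkm(treatment, regions, track, library_size = sum(tw))
  ri <- compute_rpkm(input, regions, track, library_size = sum(iw))
  # pool weight and length over each group's regions, then correct by the
  # group's length-weighted mean mappability
  pool <- function(r) {
    kb <- tapply((r$end - r$start) / 1000, r$group, sum)
    w <- tapply(r$weight, r$group, sum)
    mlen <- tapply(r$mean_mappability * (r$end - r$start), r$group, sum) /
      tapply(r$end - r$start, r$group, sum)
    data.frame(group = names(kb), kb = as.numeric(kb), w = as.numeric(w),
               m = as.numeric(mlen), stringsAsFactors = FALSE)
  }
  pt <- pool(rt); pn <- pool(ri)
  stopifnot(identical(pt$group, pn$group))
  t_rpkm <- pt$w / (pt$kb * sum(tw) / 1e6) / pt$m
  i_rpkm <- pn$w / (pn$kb * sum(iw) / 1e6) / pn$m
  enr <- ifelse(i_rpkm > 0, t_rpkm / i_rpkm, NA_real_)
  if (anyNA(enr))
    warning("group(s) with zero input weight: enrichment undefined",
            call. = FALSE)
  if (!is.null(normalize_to)) {
    ref <- enr[match(normalize_to, pt$group)]
    if (is.na(ref)) stop2("normalize_to group not found: ", normalize_to)
    enr <- enr / ref
  }
  data.frame(group = pt$group, treatment_rpkm = t_rpkm,
             input_rpkm = i_rpkm, enrichment = enr,
             stringsAsFactors = FALSE)
}
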