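#' Compartmentalized genome container
#'
#' Bundles the sequences and annotations of a genome whose chromosomes belong
#' to distinct cellular compartments (nucleus, nucleomorph, mitochondrion,
#' plastid), each with its own relative copy number.
#'
#' @param sequences named character vector of uppercase DNA sequences, one
#'   per chromosome.
#' @param compartment named character vector mapping each chromosome to one
#'   of `"nucleus"`, `"nucleomorph"`, `"mitochondrion"`, `"plastid"`.
#' @param copy_number named numeric vector of positive relative copy numbers
#'   (haploid nucleus = 1).
#' @param genes `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `id`, `is_rdna` (logical). May have
#'   zero rows.
#' @param telomeres `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open). May have zero rows.
#'
#' @return An object of class `comp_genome`.
#' @export
comp_genome <- function(sequences, compartment, copy_number,
                        genes = NULL, telomeres = NULL) {
  valid <- c("nucleus", "nucleomorph", "mitochondrion", "plastid")
  chroms <- names(sequences)
  if (is.null(chroms) || anyDuplicated(chroms))
    stop2("sequences must be uniquely named by chromosome")
  if (!all(chroms %in% names(compartment)))
    stop2("every chromosome needs a compartment label")
  if (!all(compartment[chroms] %in% valid))
    stop2("compartment labels must be one of: ", paste(valid, collapse = ", "))
  if (!all(chroms %in% names(copy_number)) || any(copy_number[chroms] <= 0))
    stop2("copy_number must be a positive value for every chromosome")
  if (is.null(genes))
    genes <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        id = character(), is_rdna = logical())
  if (is.null(telomeres))
    telomeres <- data.frame(chrom = character(), start = integer(),
                            end = integer())
  lens <- nchar(sequences)
  if (nrow(genes) > 0) {
    bad <- genes$start < 0 | genes$end > lens[genes$chrom] |
      genes$start >= genes$end
    if (any(bad))
      stop2("gene(s) outside chromosome bounds: ",
            paste(genes$id[bad], collapse = ", "))
  }
  if (nrow(telomeres) > 0) {
    bad <- telomeres$start < 0 | telomeres$end > lens[telomeres$chrom]
    if (any(bad)) stop2("telomere interval outside chromosome bounds")
  }
  structure(list(
    sequences = sequences,
    compartment = compartment[chroms],
    copy_number = copy_number[chroms],
    genes = genes,
    telomeres = telomeres
  ), class = "comp_genome")
}

#' @export
print.comp_genome <- function(x, ...) {
  lens <- chrom_lengths(x)
  cat(sprintf("comp_genome: %d chromosomes, %s bp total\n",
              length(lens), format(sum(lens), big.mark = ",")))
  tab <- tapply(lens, x$compartment, sum)
  for (cp in names(tab))
    cat(sprintf("  %-13s %9d bp (copy number %s)\n", cp, tab[[cp]],
                paste(unique(x$copy_number[x$compartment == cp]),
                      collapse = "/")))
  cat(sprintf("  %d genes (%d rDNA), %d telomere intervals\n",
              nrow(x$genes), sum(x$genes$is_rdna), nrow(x$telomeres)))
  invisible(x)
}

#' Chromosome lengths of a compartmentalized genome
#' @param genome a [comp_genome()] object.
#' @return named integer vector of chromosome lengths (bp).
#' @export
chrom_lengths <- function(genome) {
  nchar(genome$sequences)
}

#' Strand-aware TSS positions of annotated genes
#'
#' Returns the annotated 5' end of each gene as a 0-based position: `start`
#' for `+` strand genes, `end - 1` for `-` strand genes. Note that in compact
#' genome annotations the recorded 5' end is often the translation start
#' rather than the true transcription start.
#'
#' @param genes gene table as in [comp_genome()].
#' @return `data.frame` with columns `chrom`, `pos`, `strand`, `id`.
#' @export
gene_tss <- function(genes) {
  data.frame(
    chrom = genes$chrom,
    pos = ifelse(genes$strand == "+", genes$start, genes$end - 1L),
    strand = genes$strand,
    id = genes$id,
    stringsAsFactors = FALSE
  )
}

# Validate a fragment table against a genome; returns the table invisibly.
validate_fragments <- function(fragments, genome) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(fragments)))
    stop2("fragments need columns chrom, start, end")
  if (is.null(fragments$weight)) fragments$weight <- 1
  lens <- chrom_lengths(genome)
  unknown <- setdiff(unique(fragments$chrom), names(lens))
  if (length(unknown) > 0)
    stop2("fragments on unknown chromosome(s): ",
          paste(unknown, collapse = ", "))
  bad <- fragments$start < 0 | fragments$end > lens[fragments$chrom] |
    fragments$start >= fragments$end
  if (any(bad))
    stop2(sum(bad), " fragment(s) violate chromosome bounds")
  if (any(fragments$weight <= 0 | fragments$weight > 1))
    stop2("fragment weights must lie in (0, 1]")
  invisible(fragments)
}
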