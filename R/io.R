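#' File readers and writers
#'
#' All on-disk formats use their standard conventions (BED and bedGraph are
#' 0-based half-open; GFF3 and `.pairs` are 1-based and are converted to the
#' internal 0-based half-open convention exactly once at the file boundary).
#'
#' @name nucleochrom-io
NULL

#' Write a genome to FASTA / GFF3 / compartment TSV
#'
#' @param genome a [comp_genome()] object.
#' @param fasta,gff3,compartments output paths; any may be `NULL` to skip.
#' @param width FASTA line wrap width.
#' @return invisibly, the genome.
#' @export
write_genome <- function(genome, fasta = NULL, gff3 = NULL,
                         compartments = NULL, width = 60L) {
  if (!is.null(fasta)) {
    dss <- Biostrings::DNAStringSet(genome$sequences)
    Biostrings::writeXStringSet(dss, fasta, width = width)
  }
  if (!is.null(gff3)) write_gff3(genome, gff3)
  if (!is.null(compartments)) {
    ct <- data.frame(chrom = names(genome$sequences),
                     compartment = unname(genome$compartment),
                     copy_number = unname(genome$copy_number))
    data.table::fwrite(ct, compartments, sep = "\t")
  }
  invisible(genome)
}

write_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lens <- chrom_lengths(genome)
  for (ch in names(lens))
    writeLines(sprintf("##sequence-region %s 1 %d", ch, lens[[ch]]), con)
  rows <- character(0)
  g <- genome$genes
  if (nrow(g) > 0) {
    rows <- c(rows, sprintf(
      "%s\tnucleochrom\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chrom, ifelse(g$is_rdna, "rRNA_gene", "gene"),
      g$start + 1L, g$end, g$strand, g$id))
  }
  tl <- genome$telomeres
  if (nrow(tl) > 0) {
    rows <- c(rows, sprintf(
      "%s\tnucleochrom\ttelomere\t%d\t%d\t.\t.\t.\tID=telomere_%s_%d",
      tl$chrom, tl$start + 1L, tl$end, tl$chrom, seq_len(nrow(tl))))
  }
  writeLines(rows, con)
}

#' Read a genome from FASTA + compartment TSV (+ optional GFF3)
#'
#' @param fasta path to a FASTA file.
#' @param compartments path to a TSV with columns `chrom`, `compartment`,
#'   `copy_number`.
#' @param gff3 optional GFF3 with `gene`/`rRNA_gene` and `telomere` features.
#' @return a [comp_genome()] object.
#' @export
read_genome <- function(fasta, compartments, gff3 = NULL) {
  dss <- Biostrings::readDNAStringSet(fasta)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ct <- data.table::fread(compartments, sep = "\t", data.table = FALSE)
  comp <- setNames(ct$compartment, ct$chrom)
  cn <- setNames(ct$copy_number, ct$chrom)
  genes <- NULL
  telomeres <- NULL
  if (!is.null(gff3)) {
    ann <- read_gff3(gff3, chrom_lengths = nchar(seqs))
    genes <- ann$genes
    telomeres <- ann$telomeres
  }
  comp_genome(seqs, comp, cn, genes, telomeres)
}

read_gff3 <- function(path, chrom_lengths = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0)
    return(list(genes = NULL, telomeres = NULL))
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 9))
    stop2("malformed GFF3 record at line ",
          which(!startsWith(lines, "#") & nzchar(lines))[which(nf != 9)[1]])
  m <- do.call(rbind, f)
  start <- as.integer(m[, 4]) - 1L   # to 0-based half-open
  end <- as.integer(m[, 5])
  if (!is.null(chrom_lengths)) {
    bad <- which(start < 0 | end > chrom_lengths[m[, 1]])
    if (length(bad) > 0)
      stop2("GFF3 coordinate outside chromosome bounds at record ", bad[1])
  }
  id <- sub("^.*ID=([^;]+).*$", "\\1", m[, 9])
  is_gene <- m[, 3] %in% c("gene", "rRNA_gene")
  genes <- data.frame(chrom = m[is_gene, 1], start = start[is_gene],
                      end = end[is_gene], strand = m[is_gene, 7],
                      id = id[is_gene],
                      is_rdna = m[is_gene, 3] == "rRNA_gene",
                      stringsAsFactors = FALSE)
  is_tel <- m[, 3] == "telomere"
  telomeres <- data.frame(chrom = m[is_tel, 1], start = start[is_tel],
                          end = end[is_tel], stringsAsFactors = FALSE)
  list(genes = genes, telomeres = telomeres)
}

#' Write / read fragment BED files
#'
#' Fragments are stored as BED3 plus a fourth numeric column holding the
#' fragment weight (1 for unique mappers, 1/k for k-way multimappers).
#'
#' @param fragments `data.frame` with `chrom`, `start`, `end` and optional
#'   `weight`.
#' @param path file path.
#' @return `write_fragments_bed` returns the path invisibly;
#'   `read_fragments_bed` returns a fragment `data.frame`.
#' @export
write_fragments_bed <- function(fragments, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  out <- data.frame(chrom = fragments$chrom,
                    start = as.integer(fragments$start),
                    end = as.integer(fragments$end),
                    weight = fragments$weight %||% rep(1, nrow(fragments)))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           data.table = FALSE)
  if (ncol(bed) < 3) stop2("BED file needs at least 3 columns: ", path)
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed$weight <- if (ncol(bed) >= 4) as.numeric(bed[[4]]) else 1
  bad <- which(bed$end <= bed$start)
  if (length(bad) > 0)
    stop2("BED record with end <= start at line ", bad[1], " of ", path)
  bed[, c("chrom", "start", "end", "weight")]
}

#' Write / read a bedGraph track
#'
#' Runs of equal value are merged; intervals are 0-based half-open.
#'
#' @param track a `mappability_track` or a named list of numeric vectors
#'   (one per chromosome).
#' @param path file path.
#' @return `write_bedgraph` returns the path invisibly; `read_bedgraph`
#'   returns a named list of per-position numeric vectors.
#' @export
write_bedgraph <- function(track, path) {
  scores <- if (inherits(track, "mappability_track")) track$score else track
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(scores)) {
    v <- scores[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts, ends,
                       format(r$values, trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  bg <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  out <- list()
  for (ch in unique(bg$chrom)) {
    b <- bg[bg$chrom == ch, ]
    v <- numeric(max(b$end))
    for (i in seq_len(nrow(b))) v[(b$start[i] + 1):b$end[i]] <- b$value[i]
    out[[ch]] <- v
  }
  out
}

#' Write / read 4DN-style .pairs files
#'
#' Columns: `readID chr1 pos1 chr2 pos2 strand1 strand2`. Positions are
#' 1-based on disk and converted to the internal 0-based convention on read.
#' Pairs are stored in canonical (upper-triangular) order.
#'
#' @param pairs `data.frame` with `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `strand1`, `strand2` (0-based positions).
#' @param genome a [comp_genome()] used to write `#chromsize` headers and to
#'   validate coordinates on read.
#' @param path file path.
#' @return `write_pairs` returns the path invisibly; `read_pairs` returns a
#'   pairs `data.frame` in canonical order.
#' @export
write_pairs <- function(pairs, genome, path) {
  lens <- chrom_lengths(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  writeLines("#shape: upper triangle", con)
  writeLines(sprintf("#chromsize: %s %d", names(lens), lens), con)
  writeLines("#columns: readID chr1 pos1 chr2 pos2 strand1 strand2", con)
  if (nrow(pairs) > 0) {
    writeLines(sprintf("pair%d\t%s\t%d\t%s\t%d\t%s\t%s",
                       seq_len(nrow(pairs)),
                       pairs$chrom1, pairs$pos1 + 1L,
                       pairs$chrom2, pairs$pos2 + 1L,
                       pairs$strand1, pairs$strand2), con)
  }
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path, genome = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) {
    pairs <- data.frame(chrom1 = character(), pos1 = integer(),
                        chrom2 = character(), pos2 = integer(),
                        strand1 = character(), strand2 = character())
    return(pairs)
  }
  f <- data.table::fread(text = body, sep = "\t", header = FALSE,
                         data.table = FALSE)
  pairs <- data.frame(chrom1 = f[[2]], pos1 = as.integer(f[[3]]) - 1L,
                      chrom2 = f[[4]], pos2 = as.integer(f[[5]]) - 1L,
                      strand1 = as.character(f[[6]]),
                      strand2 = as.character(f[[7]]),
                      stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    bad <- which(pairs$pos1 < 0 | pairs$pos2 < 0 |
                   pairs$pos1 >= lens[pairs$chrom1] |
                   pairs$pos2 >= lens[pairs$chrom2])
    if (length(bad) > 0)
      stop2(".pairs coordinate outside chromosome bounds at record ", bad[1])
  }
  canonicalize_pairs(pairs, chrom_order = if (is.null(genome)) NULL
                     else names(chrom_lengths(genome)))
}

# Put each pair in canonical (upper-triangular) order and sort records.
canonicalize_pairs <- function(pairs, chrom_order = NULL) {
  lev <- chrom_order %||% sort(unique(c(pairs$chrom1, pairs$chrom2)))
  i1 <- match(pairs$chrom1, lev)
  i2 <- match(pairs$chrom2, lev)
  flip <- i1 > i2 | (i1 == i2 & pairs$pos1 > pairs$pos2)
  out <- pairs
  out$chrom1[flip] <- pairs$chrom2[flip]
  out$pos1[flip] <- pairs$pos2[flip]
  out$strand1[flip] <- pairs$strand2[flip]
  out$chrom2[flip] <- pairs$chrom1[flip]
  out$pos2[flip] <- pairs$pos1[flip]
  out$strand2[flip] <- pairs$strand1[flip]
  ord <- order(match(out$chrom1, lev), out$pos1,
               match(out$chrom2, lev), out$pos2)
  out[ord, , drop = FALSE]
}

#' Write a table as TSV
#' @param x a data.frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}
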