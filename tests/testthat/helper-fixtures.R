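# Shared fixtures: everything is generated in code, nothing read from disk.

rand_seq <- function(n, seed, at = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# Minimal genome wrapper for ad-hoc sequences.
toy_genome <- function(seqs, comp = NULL, copy = NULL, genes = NULL,
                       telomeres = NULL) {
  chroms <- names(seqs)
  comp <- comp %||% setNames(rep("nucleus", length(seqs)), chroms)
  copy <- copy %||% setNames(rep(1, length(seqs)), chroms)
  comp_genome(seqs, comp, copy, genes, telomeres)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

frag_df <- function(chrom, start, end, weight = 1) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), weight = weight,
             stringsAsFactors = FALSE)
}

# Single-chromosome, gene-free config: the uniform null world.
flat_config <- function(seed = 1, len = 100000L, comp = "mitochondrion",
                        depth = list(atac = 1e5, kas = 1e4, input = 1e5,
                                     hic = 2e4)) {
  plan <- data.frame(name = "c1", length = len, compartment = comp,
                     copy_number = 1, at_fraction = 0.6)
  sim_config(seed = seed, chrom_plan = plan,
             genes_per_chrom = c(nucleus = 0L, nucleomorph = 0L,
                                 mitochondrion = 0L, plastid = 0L),
             rdna_subtelomere_bp = 0L, telomere_bp = 0L,
             depth = depth)
}

# Independent mappability oracle: per-tile occurrence counts by exact string
# search (Biostrings pattern matching) over both strands, then a direct
# per-position covering-tile average computed by explicit loops.
oracle_mappability <- function(seqs, L) {
  subjects <- lapply(seqs, Biostrings::DNAString)
  out <- list()
  for (ch in names(seqs)) {
    n <- nchar(seqs[[ch]])
    nt <- n - L + 1L
    starts <- seq_len(nt)
    tiles <- Biostrings::DNAStringSet(
      substring(seqs[[ch]], starts, starts + L - 1L))
    pd <- Biostrings::PDict(tiles)
    pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(tiles))
    cnt <- integer(nt)
    for (s in subjects) {
      cnt <- cnt + Biostrings::countPDict(pd, s) +
        Biostrings::countPDict(pd_rc, s)
    }
    uniq <- cnt == 1L
    m <- numeric(n)
    for (i in seq_len(n)) {
      cov <- max(1L, i - L + 1L):min(i, nt)
      m[i] <- mean(uniq[cov])
    }
    out[[ch]] <- m
  }
  out
}

# Fragments scattered around planted dyads: `per_dyad` nucleosomal fragments
# per dyad, midpoints jittered by `sd`.
dyad_fragments <- function(chrom, dyads, per_dyad, sd = 20,
                           len_range = c(180L, 240L), seed = 1) {
  set.seed(seed)
  ctr <- rep(dyads, each = per_dyad) +
    round(rnorm(length(dyads) * per_dyad, 0, sd))
  len <- sample(seq(len_range[1], len_range[2]), length(ctr), replace = TRUE)
  start <- pmax(0L, as.integer(ctr - len %/% 2L))
  frag_df(chrom, start, start + len)
}
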