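#' Simulation configuration for a multi-compartment genome
#'
#' Builds the full parameter set for the synthetic-data generator. Defaults
#' describe a miniature genome with the hallmarks of a chlorarachniophyte
#' cell: a haploid nucleus, a diploid AT-rich nucleomorph split over three
#' chromosomes (~380 kbp total) with subtelomeric rDNA arrays occupying ~11%
#' of it, and high-copy organelles. Accessibility multipliers default to the
#' compartment enrichments observed in real ATAC-seq data (nucleus 1,
#' nucleomorph 10, plastid 50, mitochondrion 100); nuclear and nucleomorph
#' promoters carry an upstream nucleosome-depleted region and phased +1/+2/-1
#' nucleosomes; ATAC fragment lengths are bimodal in the nucleus (~100/200
#' bp) and nucleomorph (~90/220 bp) and unimodal in the organelles; Hi-C
#' pairs decay as a power law in cis and carry configurable trans-contact
#' multipliers plus a telomere-to-telomere boost among nucleomorph
#' chromosomes.
#'
#' @param seed integer master seed; each library derives its own stream.
#' @param chrom_plan `data.frame` with columns `name`, `length`,
#'   `compartment`, `copy_number`, `at_fraction`.
#' @param genes_per_chrom integer, or named integer vector per compartment.
#' @param intergenic_bp spacing between tiled genes (bp).
#' @param rdna_subtelomere_bp width of each subtelomeric rDNA window on
#'   nucleomorph chromosomes (bp); two windows per chromosome.
#' @param telomere_bp telomere width at each end of nuclear and nucleomorph
#'   chromosomes (bp).
#' @param accessibility_multiplier named positive vector per compartment;
#'   scales ATAC fragment yield per unit DNA mass.
#' @param transcription list with `default` (rate of ordinary genes), `rdna`
#'   (rate of rDNA genes) and optional `overrides` (named vector by gene id).
#' @param frag_len_mixture named list per compartment; each element a
#'   `data.frame` with columns `mode`, `sd`, `weight` (weights sum to 1).
#' @param ndr_width,ndr_boost width (bp) and fold-elevation of the
#'   nucleosome-depleted region upstream of each TSS.
#' @param nucleosome_dip multiplicative suppression of ATAC start-site
#'   probability across each 147-bp nucleosome footprint.
#' @param nucleosome_spacing distance between +1 and +2 dyads (bp).
#' @param positioning_sd jitter of nucleosome dyads (bp).
#' @param plus_one_offset,minus_one_offset strand-oriented dyad offsets of
#'   the +1 and -1 nucleosomes from the TSS (bp).
#' @param rdna_accessibility fold-elevation of accessibility over rDNA genes
#'   relative to the rest of their chromosome.
#' @param dyad_prob probability that a nucleosome-sized fragment is centered
#'   on a planted dyad rather than drawn from the accessibility profile.
#' @param nucleosomal_range fragment-length range (bp) treated as
#'   nucleosome-spanning.
#' @param kas_frag_len,input_frag_len `(mean, sd)` of sheared fragment
#'   lengths for KAS and input libraries.
#' @param hic list with `decay_exponent` (cis power-law exponent),
#'   `telomere_boost` (fold-boost of both-ends-telomeric nucleomorph trans
#'   pairs), `trans_multiplier` (named vector, names of the form
#'   `"compA|compB"` with compartments sorted alphabetically), `cis_weight`
#'   (cis mass relative to normalized trans mass) and `min_separation`
#'   (smallest cis separation, bp).
#' @param depth list of library sizes: `atac`, `kas`, `input` (fragments)
#'   and `hic` (pairs).
#' @param phased_compartments compartments whose promoters carry the
#'   NDR/phased-nucleosome architecture.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    chrom_plan = default_chrom_plan(),
    genes_per_chrom = c(nucleus = 60L, nucleomorph = 80L,
                        mitochondrion = 20L, plastid = 40L),
    intergenic_bp = 200L,
    rdna_subtelomere_bp = 7000L,
    telomere_bp = 10000L,
    accessibility_multiplier = c(nucleus = 1, nucleomorph = 10,
                                 plastid = 50, mitochondrion = 100),
    transcription = list(default = 1, rdna = 20, overrides = NULL),
    frag_len_mixture = default_frag_len_mixture(),
    ndr_width = 150L, ndr_boost = 5,
    nucleosome_dip = 0.2,
    nucleosome_spacing = 175L,
    positioning_sd = 20,
    plus_one_offset = 110L, minus_one_offset = -130L,
    rdna_accessibility = 2,
    dyad_prob = 0.8,
    nucleosomal_range = c(160L, 250L),
    kas_frag_len = c(250, 50),
    input_frag_len = c(200, 50),
    hic = list(decay_exponent = 1, telomere_boost = 5,
               trans_multiplier = c("mitochondrion|nucleomorph" = 3,
                                    "mitochondrion|plastid" = 3),
               cis_weight = 3, min_separation = 1000),
    depth = list(atac = 2e5, kas = 1e5, input = 2e5, hic = 1e5),
    phased_compartments = c("nucleus", "nucleomorph")) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_chrom_plan <- function() {
  data.frame(
    name = c("nuc1", "nuc2", "NM1", "NM2", "NM3", "chrP", "chrM"),
    length = c(300000L, 300000L, 140000L, 130000L, 110000L, 70000L, 40000L),
    compartment = c("nucleus", "nucleus", "nucleomorph", "nucleomorph",
                    "nucleomorph", "plastid", "mitochondrion"),
    copy_number = c(1, 1, 2, 2, 2, 20, 50),
    at_fraction = c(0.55, 0.55, 0.75, 0.75, 0.75, 0.65, 0.65),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_frag_len_mixture <- function() {
  list(
    nucleus = data.frame(mode = c(100, 200), sd = c(25, 35),
                         weight = c(0.65, 0.35)),
    nucleomorph = data.frame(mode = c(90, 220), sd = c(25, 30),
                             weight = c(0.5, 0.5)),
    mitochondrion = data.frame(mode = 80, sd = 30, weight = 1),
    plastid = data.frame(mode = 80, sd = 30, weight = 1)
  )
}

validate_sim_config <- function(cfg) {
  cp <- cfg$chrom_plan
  req <- c("name", "length", "compartment", "copy_number", "at_fraction")
  if (!all(req %in% names(cp))) stop2("chrom_plan needs columns: ",
                                      paste(req, collapse = ", "))
  if (any(cp$length <= 0)) stop2("chromosome lengths must be positive")
  if (any(cp$copy_number <= 0)) stop2("copy numbers must be positive")
  if (any(cp$at_fraction < 0 | cp$at_fraction > 1))
    stop2("at_fraction must lie in [0, 1]")
  valid <- c("nucleus", "nucleomorph", "mitochondrion", "plastid")
  if (!all(cp$compartment %in% valid))
    stop2("unknown compartment in chrom_plan")
  for (comp in unique(cp$compartment)) {
    mix <- cfg$frag_len_mixture[[comp]]
    if (is.null(mix)) stop2("frag_len_mixture missing compartment ", comp)
    if (abs(sum(mix$weight) - 1) > 1e-9)
      stop2("frag_len_mixture weights for ", comp, " must sum to 1")
    if (is.na(cfg$accessibility_multiplier[comp]) ||
        cfg$accessibility_multiplier[comp] <= 0)
      stop2("accessibility_multiplier must be positive for ", comp)
  }
  if (cfg$ndr_width < 0 || cfg$telomere_bp < 0 || cfg$rdna_subtelomere_bp < 0)
    stop2("widths must be non-negative")
  if (cfg$hic$decay_exponent <= 0) stop2("decay_exponent must be positive")
  if (cfg$hic$telomere_boost < 1) stop2("telomere_boost must be >= 1")
  invisible(cfg)
}

genes_for <- function(cfg, comp) {
  g <- cfg$genes_per_chrom
  n <- if (length(g) == 1 && is.null(names(g))) g else g[[comp]]
  if (is.null(n) || is.na(n)) 0L else as.integer(n)
}

#' Simulate a multi-compartment genome
#'
#' Generates random sequences at the configured AT fraction, tiles genes
#' through each chromosome interior with the configured intergenic spacing,
#' places rDNA genes inside the subtelomeric windows of nucleomorph
#' chromosomes, and records telomere intervals for nuclear and nucleomorph
#' chromosomes. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [comp_genome()].
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genome"))
  cp <- config$chrom_plan
  seqs <- character(nrow(cp))
  names(seqs) <- cp$name
  genes <- list()
  telomeres <- list()
  for (i in seq_len(nrow(cp))) {
    ch <- cp$name[i]; n <- cp$length[i]
    comp <- cp$compartment[i]; at <- cp$at_fraction[i]
    seqs[ch] <- paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
                             prob = c(at / 2, at / 2,
                                      (1 - at) / 2, (1 - at) / 2)),
                      collapse = "")
    has_tel <- comp %in% c("nucleus", "nucleomorph") && config$telomere_bp > 0
    tel <- if (has_tel) config$telomere_bp else 0L
    rdna <- if (comp == "nucleomorph") config$rdna_subtelomere_bp else 0L
    if (has_tel) {
      telomeres[[length(telomeres) + 1L]] <- data.frame(
        chrom = ch, start = c(0L, n - tel), end = c(tel, n))
    }
    chrom_genes <- list()
    if (rdna > 0) {
      # one rDNA array gene filling each subtelomeric window
      chrom_genes[[1L]] <- data.frame(
        chrom = ch, start = c(tel, n - tel - rdna),
        end = c(tel + rdna, n - tel), strand = c("+", "-"),
        id = paste0(ch, "_rdna_", c("L", "R")), is_rdna = TRUE)
    }
    ng <- genes_for(config, comp)
    if (ng > 0) {
      lo <- tel + rdna
      hi <- n - tel - rdna
      span <- hi - lo
      glen <- (span - (ng + 1L) * config$intergenic_bp) %/% ng
      if (glen < 50L)
        stop2("configuration error: genes do not fit on chromosome ", ch,
              " (computed gene length ", glen, " bp)")
      starts <- lo + config$intergenic_bp +
        (seq_len(ng) - 1L) * (glen + config$intergenic_bp)
      chrom_genes[[length(chrom_genes) + 1L]] <- data.frame(
        chrom = ch, start = as.integer(starts),
        end = as.integer(starts + glen),
        strand = rep(c("+", "-"), length.out = ng),
        id = sprintf("%s_g%03d", ch, seq_len(ng)), is_rdna = FALSE)
    }
    if (length(chrom_genes) > 0)
      genes[[length(genes) + 1L]] <- do.call(rbind, chrom_genes)
  }
  genes <- if (length(genes) > 0) do.call(rbind, genes) else NULL
  telomeres <- if (length(telomeres) > 0) do.call(rbind, telomeres) else NULL
  comp_genome(seqs,
              setNames(cp$compartment, cp$name),
              setNames(cp$copy_number, cp$name),
              genes, telomeres)
}

# Per-gene transcription rates implied by a config.
gene_rates <- function(genome, config) {
  g <- genome$genes
  if (nrow(g) == 0) return(numeric(0))
  r <- ifelse(g$is_rdna, config$transcription$rdna,
              config$transcription$default)
  names(r) <- g$id
  ov <- config$transcription$overrides
  if (!is.null(ov)) r[names(ov)] <- ov
  if (any(r < 0)) stop2("transcription rates must be non-negative")
  r
}

#' Ground-truth dyads planted by the generator
#'
#' For every non-rDNA gene in a phased compartment, the generator plants a
#' +1 nucleosome downstream of the TSS, a +2 one spacing further, and a -1
#' nucleosome upstream.
#'
#' @param genome a simulated [comp_genome()].
#' @param config the [sim_config()] used to simulate it.
#' @return `data.frame` with columns `chrom`, `pos`, `gene`, `label`.
#' @export
planted_dyads <- function(genome, config) {
  g <- genome$genes
  keep <- !g$is_rdna &
    genome$compartment[g$chrom] %in% config$phased_compartments
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      gene = character(), label = character()))
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  sgn <- ifelse(g$strand == "+", 1L, -1L)
  offs <- c(`+1` = config$plus_one_offset,
            `+2` = config$plus_one_offset + config$nucleosome_spacing,
            `-1` = config$minus_one_offset)
  out <- do.call(rbind, lapply(names(offs), function(lb) {
    data.frame(chrom = g$chrom, pos = as.integer(tss + sgn * offs[[lb]]),
               gene = g$id, label = lb, stringsAsFactors = FALSE)
  }))
  lens <- chrom_lengths(genome)
  out <- out[out$pos >= 0 & out$pos < lens[out$chrom], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-base ATAC start-site profile shape for one chromosome, normalized to
# mean 1. Captures the NDR elevation, nucleosome footprint dips and rDNA
# hyper-accessibility; the compartment multiplier scales the chromosome
# total, not the shape.
accessibility_shape <- function(genome, config, chrom) {
  n <- chrom_lengths(genome)[[chrom]]
  s <- rep(1, n)
  comp <- genome$compartment[[chrom]]
  g <- genome$genes[genome$genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) > 0) {
    rd <- g[g$is_rdna, , drop = FALSE]
    for (j in seq_len(nrow(rd)))
      s[(rd$start[j] + 1):rd$end[j]] <-
        s[(rd$start[j] + 1):rd$end[j]] * config$rdna_accessibility
    if (comp %in% config$phased_compartments) {
      gg <- g[!g$is_rdna, , drop = FALSE]
      if (nrow(gg) > 0) {
        tss <- ifelse(gg$strand == "+", gg$start, gg$end - 1L)
        sgn <- ifelse(gg$strand == "+", 1L, -1L)
        for (j in seq_len(nrow(gg))) {
          ndr <- if (sgn[j] > 0) {
            seq(tss[j] - config$ndr_width, tss[j] - 1L)
          } else {
            seq(tss[j] + 1L, tss[j] + config$ndr_width)
          }
          ndr <- ndr[ndr >= 0 & ndr < n]
          s[ndr + 1L] <- s[ndr + 1L] * config$ndr_boost
        }
        dy <- planted_dyads(genome, config)
        dy <- dy[dy$chrom == chrom, , drop = FALSE]
        for (j in seq_len(nrow(dy))) {
          fp <- seq(dy$pos[j] - 73L, dy$pos[j] + 73L)
          fp <- fp[fp >= 0 & fp < n]
          s[fp + 1L] <- s[fp + 1L] * config$nucleosome_dip
        }
      }
    }
  }
  s * (n / sum(s))
}

# Draw fragment lengths from a compartment's truncated-normal mixture.
draw_lengths <- function(m, mix, max_len) {
  comp <- sample.int(nrow(mix), m, replace = TRUE, prob = mix$weight)
  len <- round(rtnorm_min(m, mix$mode[comp], mix$sd[comp], min = 20))
  pmin(as.integer(len), max_len)
}

# Sample fragment start positions proportional to a profile shape, subject
# to the fragment fitting inside the chromosome.
sample_starts <- function(shape, len) {
  S <- cumsum(shape)
  n <- length(shape)
  top <- S[pmax(n - len, 1L)]
  u <- runif(length(len)) * top
  findInterval(u, S)
}

#' Simulate an ATAC-seq fragment library
#'
#' Fragment counts per chromosome are proportional to length x copy number x
#' accessibility multiplier. Within a chromosome, start sites follow the
#' per-base accessibility shape (NDR-elevated, nucleosome-suppressed);
#' fragment lengths are drawn from the compartment's length mixture, and
#' nucleosome-sized fragments are, with probability `dyad_prob`, centered on
#' a planted dyad jittered by `positioning_sd`.
#'
#' @param genome a simulated [comp_genome()].
#' @param config the matching [sim_config()].
#' @param depth optional override of `config$depth$atac`.
#' @return fragment `data.frame` (`chrom`, `start`, `end`, `weight`).
#' @export
simulate_atac_fragments <- function(genome, config, depth = NULL) {
  set.seed(derive_seed(config$seed, "atac"))
  depth <- as.integer(depth %||% config$depth$atac)
  lens <- chrom_lengths(genome)
  w <- lens * genome$copy_number *
    config$accessibility_multiplier[genome$compartment]
  if (sum(w) <= 0) stop2("zero total fragment rate")
  counts <- as.vector(rmultinom(1, depth, w))
  dyads <- planted_dyads(genome, config)
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    m <- counts[i]
    if (m == 0L) next
    ch <- names(lens)[i]
    n <- lens[[i]]
    mix <- config$frag_len_mixture[[genome$compartment[[ch]]]]
    len <- draw_lengths(m, mix, max_len = n)
    D <- dyads$pos[dyads$chrom == ch]
    on_dyad <- if (length(D) > 0) {
      len >= config$nucleosomal_range[1] & len <= config$nucleosomal_range[2] &
        runif(m) < config$dyad_prob
    } else rep(FALSE, m)
    start <- integer(m)
    if (any(on_dyad)) {
      k <- sum(on_dyad)
      ctr <- D[sample.int(length(D), k, replace = TRUE)] +
        round(rnorm(k, 0, config$positioning_sd))
      st <- ctr - len[on_dyad] %/% 2L
      start[on_dyad] <- pmax(0L, pmin(st, n - len[on_dyad]))
    }
    if (any(!on_dyad)) {
      shape <- accessibility_shape(genome, config, ch)
      start[!on_dyad] <- sample_starts(shape, len[!on_dyad])
    }
    out[[i]] <- data.frame(chrom = ch, start = as.integer(start),
                           end = as.integer(start + len), weight = 1,
                           stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, out)
  rownames(frags) <- NULL
  validate_fragments(frags, genome)
  frags
}

#' Simulate a KAS-seq (transcription) fragment library
#'
#' Each gene yields fragments at a rate proportional to its transcription
#' rate x copy number x gene length, with fragment midpoints uniform within
#' the gene body, emulating uniformly distributed polymerase density.
#'
#' @inheritParams simulate_atac_fragments
#' @return fragment `data.frame`.
#' @export
simulate_kas_fragments <- function(genome, config, depth = NULL) {
  set.seed(derive_seed(config$seed, "kas"))
  depth <- as.integer(depth %||% config$depth$kas)
  g <- genome$genes
  if (nrow(g) == 0) stop2("genome has no genes to transcribe")
  rates <- gene_rates(genome, config)
  w <- rates[g$id] * genome$copy_number[g$chrom] * (g$end - g$start)
  if (sum(w) <= 0) stop2("zero total transcription rate")
  counts <- as.vector(rmultinom(1, depth, w))
  lens <- chrom_lengths(genome)
  idx <- rep(seq_len(nrow(g)), counts)
  m <- length(idx)
  len <- as.integer(round(rtnorm_min(m, config$kas_frag_len[1],
                                     config$kas_frag_len[2], min = 20)))
  len <- pmin(len, lens[g$chrom[idx]])
  mid <- g$start[idx] + floor(runif(m) * (g$end[idx] - g$start[idx]))
  start <- pmax(0L, pmin(as.integer(mid - len %/% 2L),
                         lens[g$chrom[idx]] - len))
  frags <- data.frame(chrom = g$chrom[idx], start = start,
                      end = as.integer(start + len), weight = 1,
                      stringsAsFactors = FALSE)
  ord <- order(match(frags$chrom, names(lens)), frags$start)
  frags <- frags[ord, , drop = FALSE]
  rownames(frags) <- NULL
  validate_fragments(frags, genome)
  frags
}

#' Simulate an input (DNA-mass) fragment library
#'
#' Start sites are uniform within each chromosome; chromosome totals are
#' proportional to length x copy number, as expected from sequencing naked
#' genomic DNA.
#'
#' @inheritParams simulate_atac_fragments
#' @return fragment `data.frame`.
#' @export
simulate_input_fragments <- function(genome, config, depth = NULL) {
  set.seed(derive_seed(config$seed, "input"))
  depth <- as.integer(depth %||% config$depth$input)
  lens <- chrom_lengths(genome)
  w <- lens * genome$copy_number
  counts <- as.vector(rmultinom(1, depth, w))
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    m <- counts[i]
    if (m == 0L) next
    n <- lens[[i]]
    len <- as.integer(round(rtnorm_min(m, config$input_frag_len[1],
                                       config$input_frag_len[2], min = 20)))
    len <- pmin(len, n)
    start <- floor(runif(m) * (n - len + 1))
    out[[i]] <- data.frame(chrom = names(lens)[i], start = as.integer(start),
                           end = as.integer(start + len), weight = 1,
                           stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, out)
  rownames(frags) <- NULL
  validate_fragments(frags, genome)
  frags
}

trans_mult <- function(map, comp_a, comp_b) {
  key <- paste(sort(c(comp_a, comp_b)), collapse = "|")
  if (!is.null(map) && key %in% names(map)) map[[key]] else 1
}

# Uniform position within a set of intervals (0-based half-open rows).
sample_in_intervals <- function(m, iv) {
  w <- iv$end - iv$start
  S <- cumsum(w)
  u <- runif(m) * S[length(S)]
  j <- findInterval(u, S) + 1L
  as.integer(iv$start[j] + floor(u - c(0, S)[j]))
}

#' Simulate a Hi-C pair library
#'
#' Cis pairs have separations drawn from `P(s) ~ s^-decay_exponent`; each
#' chromosome's cis pair mass is proportional to its DNA mass (length x
#' copy). Trans pair mass between chromosomes A and B is proportional to
#' `mass_A x mass_B x trans_multiplier(comp_A, comp_B)`. Among trans pairs
#' between nucleomorph chromosomes, pairs with both ends inside telomere
#' intervals are boosted `telomere_boost`-fold over the area expectation.
#' Pairs are returned in canonical (upper-triangular) order.
#'
#' @inheritParams simulate_atac_fragments
#' @param depth optional override of `config$depth$hic` (pair count).
#' @return pairs `data.frame` (`chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `strand1`, `strand2`).
#' @export
simulate_hic_pairs <- function(genome, config, depth = NULL) {
  set.seed(derive_seed(config$seed, "hic"))
  depth <- as.integer(depth %||% config$depth$hic)
  lens <- chrom_lengths(genome)
  chroms <- names(lens)
  mass <- lens * genome$copy_number
  M <- sum(mass)
  combos <- list(); wts <- numeric(0)
  for (a in seq_along(chroms)) {
    for (b in a:length(chroms)) {
      if (a == b) {
        wt <- config$hic$cis_weight * mass[a]
      } else {
        wt <- mass[a] * mass[b] / M *
          trans_mult(config$hic$trans_multiplier,
                     genome$compartment[[a]], genome$compartment[[b]])
      }
      combos[[length(combos) + 1L]] <- c(a, b)
      wts <- c(wts, wt)
    }
  }
  if (sum(wts) <= 0) stop2("zero total pair rate")
  counts <- as.vector(rmultinom(1, depth, wts))
  alpha <- config$hic$decay_exponent
  s_min <- config$hic$min_separation
  out <- vector("list", length(combos))
  for (k in seq_along(combos)) {
    m <- counts[k]
    if (m == 0L) next
    a <- combos[[k]][1]; b <- combos[[k]][2]
    if (a == b) {
      n <- lens[[a]]
      s_max <- n - 1
      u <- runif(m)
      s <- if (abs(alpha - 1) < 1e-12) {
        exp(log(s_min) + u * (log(s_max) - log(s_min)))
      } else {
        (s_min^(1 - alpha) +
           u * (s_max^(1 - alpha) - s_min^(1 - alpha)))^(1 / (1 - alpha))
      }
      s <- pmin(as.integer(round(s)), n - 1L)
      pos1 <- floor(runif(m) * (n - s))
      df <- data.frame(chrom1 = chroms[a], pos1 = as.integer(pos1),
                       chrom2 = chroms[a], pos2 = as.integer(pos1 + s),
                       stringsAsFactors = FALSE)
    } else {
      boosted <- rep(FALSE, m)
      tel <- genome$telomeres
      both_nm <- genome$compartment[[a]] == "nucleomorph" &&
        genome$compartment[[b]] == "nucleomorph"
      tela <- tel[tel$chrom == chroms[a], , drop = FALSE]
      telb <- tel[tel$chrom == chroms[b], , drop = FALSE]
      if (both_nm && config$hic$telomere_boost > 1 &&
          nrow(tela) > 0 && nrow(telb) > 0) {
        fa <- sum(tela$end - tela$start) / lens[[a]]
        fb <- sum(telb$end - telb$start) / lens[[b]]
        ex <- (config$hic$telomere_boost - 1) * fa * fb
        boosted <- runif(m) < ex / (1 + ex)
      }
      pos1 <- integer(m); pos2 <- integer(m)
      nb <- sum(boosted)
      if (nb > 0) {
        pos1[boosted] <- sample_in_intervals(nb, tela)
        pos2[boosted] <- sample_in_intervals(nb, telb)
      }
      if (nb < m) {
        pos1[!boosted] <- floor(runif(m - nb) * lens[[a]])
        pos2[!boosted] <- floor(runif(m - nb) * lens[[b]])
      }
      df <- data.frame(chrom1 = chroms[a], pos1 = pos1,
                       chrom2 = chroms[b], pos2 = pos2,
                       stringsAsFactors = FALSE)
    }
    df$strand1 <- ifelse(runif(m) < 0.5, "+", "-")
    df$strand2 <- ifelse(runif(m) < 0.5, "+", "-")
    out[[k]] <- df
  }
  pairs <- do.call(rbind, out)
  pairs <- canonicalize_pairs(pairs, chrom_order = chroms)
  rownames(pairs) <- NULL
  pairs
}

#' Ground truth of a simulation
#'
#' Collects the planted parameters a test suite needs to score parameter
#' recovery: per-gene transcription rates, planted dyads, accessibility
#' multipliers, copy numbers and Hi-C parameters.
#'
#' @inheritParams simulate_atac_fragments
#' @return a list, serializable with [jsonlite::write_json()].
#' @export
simulation_truth <- function(genome, config) {
  list(
    seed = config$seed,
    copy_number = as.list(genome$copy_number),
    compartment = as.list(genome$compartment),
    accessibility_multiplier = as.list(config$accessibility_multiplier),
    transcription_rate = as.list(gene_rates(genome, config)),
    dyads = planted_dyads(genome, config),
    frag_len_modes = lapply(config$frag_len_mixture, function(m) m$mode),
    hic = list(decay_exponent = config$hic$decay_exponent,
               telomere_boost = config$hic$telomere_boost,
               trans_multiplier = as.list(config$hic$trans_multiplier)),
    positioning_sd = config$positioning_sd,
    ndr_width = config$ndr_width
  )
}

#' Run the whole generator and write its outputs
#'
#' Writes `genome.fa`, `genes.gff3`, `compartments.tsv`, `atac.bed`,
#' `kas.bed`, `input.bed`, `hic.pairs` and `truth.json` into `outdir`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the genome, fragment sets and pairs.
#' @export
simulate_all <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config)
  write_genome(genome,
               fasta = file.path(outdir, "genome.fa"),
               gff3 = file.path(outdir, "genes.gff3"),
               compartments = file.path(outdir, "compartments.tsv"))
  atac <- simulate_atac_fragments(genome, config)
  kas <- simulate_kas_fragments(genome, config)
  input <- simulate_input_fragments(genome, config)
  pairs <- simulate_hic_pairs(genome, config)
  write_fragments_bed(atac, file.path(outdir, "atac.bed"))
  write_fragments_bed(kas, file.path(outdir, "kas.bed"))
  write_fragments_bed(input, file.path(outdir, "input.bed"))
  write_pairs(pairs, genome, file.path(outdir, "hic.pairs"))
  jsonlite::write_json(simulation_truth(genome, config),
                       file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genome = genome, atac = atac, kas = kas, input = input,
                 pairs = pairs))
}
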