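test_that("config validation catches bad plans", {
  expect_error(sim_config(chrom_plan = within(default_chrom_plan(),
                                              copy_number[1] <- 0)),
               "copy numbers")
  bad_mix <- default_frag_len_mixture()
  bad_mix$nucleus$weight <- c(0.5, 0.6)
  expect_error(sim_config(frag_len_mixture = bad_mix), "sum to 1")
  # features that do not fit name the offending chromosome
  plan <- data.frame(name = "tiny", length = 5000L,
                     compartment = "nucleomorph", copy_number = 2,
                     at_fraction = 0.75)
  cfg <- sim_config(chrom_plan = plan)
  expect_error(simulate_genome(cfg), "tiny")
})

test_that("simulate_genome is deterministic and honours composition", {
  plan <- data.frame(name = c("NM1", "c2"), length = c(60000L, 60000L),
                     compartment = c("nucleomorph", "nucleus"),
                     copy_number = c(2, 1), at_fraction = c(1.0, 0.5))
  cfg <- sim_config(seed = 11, chrom_plan = plan,
                    genes_per_chrom = c(nucleus = 10L, nucleomorph = 10L,
                                        mitochondrion = 0L, plastid = 0L),
                    rdna_subtelomere_bp = 3000L, telomere_bp = 2000L)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$genes, g2$genes)
  # AT_fraction = 1 => only A/T
  expect_false(grepl("[CG]", g1$sequences[["NM1"]]))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_genome(g1, file.path(dir1, "g.fa"), file.path(dir1, "g.gff3"),
               file.path(dir1, "c.tsv"))
  write_genome(g2, file.path(dir2, "g.fa"), file.path(dir2, "g.gff3"),
               file.path(dir2, "c.tsv"))
  for (f in c("g.fa", "g.gff3", "c.tsv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("default plan realizes AT content and the rDNA fraction", {
  cfg <- sim_config(seed = 3)
  g <- simulate_genome(cfg)
  lens <- chrom_lengths(g)
  for (ch in names(lens)[lens >= 50000]) {
    at <- mean(strsplit(g$sequences[[ch]], "")[[1]] %in% c("A", "T"))
    target <- cfg$chrom_plan$at_fraction[cfg$chrom_plan$name == ch]
    expect_lt(abs(at - target), 0.02)
  }
  # rDNA genes sit inside subtelomeric windows of nucleomorph chromosomes
  rd <- g$genes[g$genes$is_rdna, ]
  expect_true(all(g$compartment[rd$chrom] == "nucleomorph"))
  tel <- cfg$telomere_bp; win <- cfg$rdna_subtelomere_bp
  inside <- mapply(function(ch, s, e) {
    n <- lens[[ch]]
    (s >= tel && e <= tel + win) || (s >= n - tel - win && e <= n - tel)
  }, rd$chrom, rd$start, rd$end)
  expect_true(all(inside))
  # rDNA occupies ~11% of the nucleomorph
  nm_len <- sum(lens[g$compartment == "nucleomorph"])
  rdna_len <- sum(rd$end - rd$start)
  expect_equal(rdna_len / nm_len, 0.11, tolerance = 0.01)
})

test_that("fragment libraries conserve depth, bounds and determinism", {
  cfg <- sim_config(seed = 5, depth = list(atac = 20000, kas = 10000,
                                           input = 20000, hic = 5000))
  g <- simulate_genome(cfg)
  for (fn in list(simulate_atac_fragments, simulate_kas_fragments,
                  simulate_input_fragments)) {
    f1 <- fn(g, cfg)
    f2 <- fn(g, cfg)
    expect_identical(f1, f2)
    expect_true(nrow(f1) %in% c(20000L, 10000L))
    lens <- chrom_lengths(g)
    expect_true(all(f1$start >= 0 & f1$end <= lens[f1$chrom] &
                      f1$start < f1$end))
  }
  p1 <- simulate_hic_pairs(g, cfg)
  expect_identical(p1, simulate_hic_pairs(g, cfg))
  expect_equal(nrow(p1), 5000L)
})

test_that("gene-free uniform world yields uniform ATAC starts", {
  cfg <- flat_config(seed = 1)
  g <- simulate_genome(cfg)
  fr <- simulate_atac_fragments(g, cfg, depth = 1e5)
  # restrict to starts where every fragment length fits (no edge effect)
  s <- fr$start[fr$start < 99000]
  bins <- table(cut(s, breaks = seq(0, 99000, by = 1000)))
  p <- stats::chisq.test(as.numeric(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("ATAC fragment lengths reproduce the mixture modes", {
  cfg <- flat_config(seed = 2, comp = "nucleomorph")
  g <- simulate_genome(cfg)
  fr <- simulate_atac_fragments(g, cfg, depth = 1e5)
  md <- detect_modes(length_spectrum(fr, g, "nucleomorph"))
  expect_equal(nrow(md), 2L)
  expect_lt(abs(md$mode[1] - 90), 5.5)
  expect_lt(abs(md$mode[2] - 220), 5.5)
})

test_that("nucleosome-sized fragment midpoints pile on planted dyads", {
  plan <- data.frame(name = "NM1", length = 50000L,
                     compartment = "nucleomorph", copy_number = 2,
                     at_fraction = 0.75)
  cfg <- sim_config(seed = 4, chrom_plan = plan,
                    genes_per_chrom = c(nucleomorph = 5L, nucleus = 0L,
                                        mitochondrion = 0L, plastid = 0L),
                    rdna_subtelomere_bp = 0L, telomere_bp = 1000L)
  g <- simulate_genome(cfg)
  fr <- simulate_atac_fragments(g, cfg, depth = 5e4)
  truth <- planted_dyads(g, cfg)
  len <- fr$end - fr$start
  mid <- (fr$start + fr$end) %/% 2
  nuc_mid <- mid[len >= 160 & len <= 250]
  # density of nucleosomal midpoints at planted dyads vs genome average
  near <- vapply(truth$pos, function(p) sum(abs(nuc_mid - p) <= 10),
                 numeric(1))
  background <- length(nuc_mid) * 21 / 50000
  expect_true(all(near > 3 * background))
})

test_that("KAS libraries track transcription rates", {
  plan <- data.frame(name = "NM1", length = 100000L,
                     compartment = "nucleomorph", copy_number = 2,
                     at_fraction = 0.75)
  cfg <- sim_config(seed = 6, chrom_plan = plan,
                    genes_per_chrom = c(nucleomorph = 40L, nucleus = 0L,
                                        mitochondrion = 0L, plastid = 0L),
                    rdna_subtelomere_bp = 4000L, telomere_bp = 2000L)
  g <- simulate_genome(cfg)
  kas <- simulate_kas_fragments(g, cfg, depth = 1e5)
  sig <- quantify_gene_signal(kas, g$genes, g, mode = "gene_body")
  rd <- g$genes$is_rdna
  # rDNA rate 20x => RPKM ratio 20 +/- 15%
  ratio <- mean(sig[rd]) / mean(sig[!rd])
  expect_lt(abs(ratio / 20 - 1), 0.15)
  # equal-rate genes: CV < 0.1
  expect_lt(sd(sig[!rd]) / mean(sig[!rd]), 0.1)
  # a silenced gene gets no midpoints
  cfg2 <- cfg
  silenced <- g$genes$id[10]
  cfg2$transcription$overrides <- setNames(0, silenced)
  kas2 <- simulate_kas_fragments(g, cfg2, depth = 2e4)
  sig2 <- quantify_gene_signal(kas2, g$genes, g, mode = "gene_body")
  expect_equal(unname(sig2[silenced]), 0)
})

test_that("input libraries follow length x copy number", {
  plan <- data.frame(name = c("a", "b"), length = c(50000L, 50000L),
                     compartment = c("nucleus", "nucleomorph"),
                     copy_number = c(1, 2), at_fraction = 0.5)
  cfg <- sim_config(seed = 7, chrom_plan = plan,
                    genes_per_chrom = c(nucleus = 0L, nucleomorph = 0L,
                                        mitochondrion = 0L, plastid = 0L),
                    rdna_subtelomere_bp = 0L, telomere_bp = 0L)
  g <- simulate_genome(cfg)
  inp <- simulate_input_fragments(g, cfg, depth = 1e5)
  ratio <- sum(inp$chrom == "b") / sum(inp$chrom == "a")
  expect_lt(abs(ratio / 2 - 1), 0.05)
})

test_that("Hi-C cis decay follows the configured exponent", {
  plan <- data.frame(name = "big", length = 1000000L,
                     compartment = "nucleus", copy_number = 1,
                     at_fraction = 0.5)
  cfg <- sim_config(seed = 8, chrom_plan = plan,
                    genes_per_chrom = c(nucleus = 0L, nucleomorph = 0L,
                                        mitochondrion = 0L, plastid = 0L),
                    rdna_subtelomere_bp = 0L, telomere_bp = 0L,
                    depth = list(atac = 1, kas = 1, input = 1, hic = 1e5))
  g <- simulate_genome(cfg)
  pairs <- simulate_hic_pairs(g, cfg)
  cm <- bin_contacts(pairs, g, 5000)
  dd <- distance_decay(cm, "big")
  sel <- dd$separation >= 10000 & dd$separation <= 100000 &
    dd$mean_contact > 0
  fit <- stats::lm(log(mean_contact) ~ log(separation), data = dd[sel, ])
  expect_lt(abs(unname(fit$coefficients[2]) + 1), 0.1)
})

test_that("exchangeable trans world gives equal trans shares", {
  plan <- data.frame(name = c("x", "y", "z"), length = 50000L,
                     compartment = "nucleus", copy_number = 1,
                     at_fraction = 0.5)
  cfg <- sim_config(seed = 9, chrom_plan = plan,
                    genes_per_chrom = c(nucleus = 0L, nucleomorph = 0L,
                                        mitochondrion = 0L, plastid = 0L),
                    rdna_subtelomere_bp = 0L, telomere_bp = 0L,
                    hic = list(decay_exponent = 1, telomere_boost = 1,
                               trans_multiplier = NULL, cis_weight = 3,
                               min_separation = 1000),
                    depth = list(atac = 1, kas = 1, input = 1, hic = 6e4))
  g <- simulate_genome(cfg)
  pairs <- simulate_hic_pairs(g, cfg)
  trans <- pairs[pairs$chrom1 != pairs$chrom2, ]
  combos <- table(paste(trans$chrom1, trans$chrom2))
  expect_equal(length(combos), 3L)
  expect_lt(max(combos) / min(combos), 1.1)
})

test_that("simulate_all writes the full file set deterministically", {
  cfg <- flat_config(seed = 10, len = 30000L,
                     depth = list(atac = 2000, kas = 1, input = 2000,
                                  hic = 1000))
  cfg$genes_per_chrom <- c(nucleus = 0L, nucleomorph = 0L,
                           mitochondrion = 5L, plastid = 0L)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  simulate_all(cfg, dir1)
  simulate_all(cfg, dir2)
  files <- c("genome.fa", "genes.gff3", "compartments.tsv", "atac.bed",
             "kas.bed", "input.bed", "hic.pairs", "truth.json")
  expect_setequal(list.files(dir1), files)
  for (f in files)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     info = f)
})
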