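test_that("multimapper weights split 1/k and conserve totals", {
  pl <- list(frag_df("c1", 0, 100))
  expect_equal(assign_multimapper_weights(pl)$weight, 1)
  pl4 <- list(frag_df(rep("c1", 4), c(0, 200, 400, 600),
                      c(100, 300, 500, 700)))
  w <- assign_multimapper_weights(pl4)$weight
  expect_equal(w, rep(0.25, 4))
  expect_equal(sum(w), 1)
  set.seed(31)
  lib <- lapply(1:100, function(i) {
    k <- sample(1:5, 1)
    frag_df(rep("c1", k), seq(0, by = 1000, length.out = k),
            seq(100, by = 1000, length.out = k))
  })
  out <- assign_multimapper_weights(lib)
  expect_equal(sum(out$weight), 100)
  expect_error(assign_multimapper_weights(list(frag_df("c1", 1, 2)[0, ])),
               "empty placement")
})

test_that("compute_rpkm matches its unit definition and correction", {
  g <- toy_genome(c(c1 = rand_seq(2000, 32)))
  frags <- frag_df("c1", 450, 550)
  regions <- data.frame(chrom = "c1", start = 0L, end = 1000L)
  r <- compute_rpkm(frags, regions, track = NULL, library_size = 1e6)
  expect_equal(r$rpkm, 1.0)
  expect_equal(r$rpkm_corrected, 1.0)
  half <- structure(list(read_length = 36,
                         score = list(c1 = rep(0.5, 2000))),
                    class = "mappability_track")
  r2 <- compute_rpkm(frags, regions, track = half, library_size = 1e6)
  expect_equal(r2$rpkm_corrected, 2.0)
  expect_error(compute_rpkm(frags, data.frame(chrom = "c1", start = 5L,
                                              end = 5L)),
               "zero")
})

test_that("uniform fragments give statistically flat bin RPKM", {
  cfg <- flat_config(seed = 33, len = 100000L)
  g <- simulate_genome(cfg)
  fr <- simulate_input_fragments(g, cfg, depth = 5e4)
  bins <- data.frame(chrom = "c1", start = seq(0L, 94000L, by = 2000L))
  bins$end <- bins$start + 2000L
  r <- compute_rpkm(fr, bins)
  z <- (r$weight - mean(r$weight)) / sqrt(mean(r$weight))
  expect_lt(mean(abs(z) > 3), 0.03)   # ~0.3% expected beyond 3 SD
})

test_that("compartment fractions are a normalized partition", {
  seqs <- c(n1 = rand_seq(3000, 34), m1 = rand_seq(1000, 35))
  g <- toy_genome(seqs,
                  comp = c(n1 = "nucleus", m1 = "nucleomorph"),
                  copy = c(n1 = 1, m1 = 2))
  fr <- frag_df(c("m1", "m1"), c(0, 100), c(80, 200))
  expect_equal(compartment_read_fractions(fr, g),
               c(nucleus = 0, nucleomorph = 1))
  fr2 <- frag_df(c("n1", "m1", "m1"), c(0, 0, 10), c(50, 60, 70),
                 weight = c(0.5, 1, 0.25))
  expect_equal(sum(compartment_read_fractions(fr2, g)), 1, tolerance = 1e-12)
})

test_that("copy-number estimates are 1 for a uniform single-copy genome", {
  plan <- data.frame(name = c("a", "b", "c"), length = 40000L,
                     compartment = "nucleus", copy_number = 1,
                     at_fraction = 0.5)
  cfg <- sim_config(seed = 36, chrom_plan = plan,
                    genes_per_chrom = c(nucleus = 0L, nucleomorph = 0L,
                                        mitochondrion = 0L, plastid = 0L),
                    rdna_subtelomere_bp = 0L, telomere_bp = 0L)
  g <- simulate_genome(cfg)
  inp <- simulate_input_fragments(g, cfg, depth = 6e4)
  cn <- estimate_copy_numbers(inp, g)
  expect_true(all(abs(cn - 1) < 0.05))
})

test_that("enrichment of a library against itself is exactly 1", {
  cfg <- flat_config(seed = 37, len = 50000L)
  g <- simulate_genome(cfg)
  fr <- simulate_input_fragments(g, cfg, depth = 5000)
  enr <- compute_enrichment(fr, fr, g, group_by = "chromosome")
  expect_equal(enr$enrichment, rep(1, nrow(enr)))
})

test_that("enrichment is invariant to library depth scaling", {
  seqs <- c(n1 = rand_seq(4000, 38), p1 = rand_seq(2000, 39))
  g <- toy_genome(seqs, comp = c(n1 = "nucleus", p1 = "plastid"),
                  copy = c(n1 = 1, p1 = 5))
  set.seed(40)
  tre <- frag_df(sample(names(seqs), 300, TRUE, prob = c(0.3, 0.7)), 10, 200)
  inp <- frag_df(sample(names(seqs), 400, TRUE, prob = c(0.6, 0.4)), 10, 200)
  e1 <- compute_enrichment(tre, inp, g)
  e2 <- compute_enrichment(rbind(tre, tre, tre), rbind(inp, inp), g)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("compartment enrichment pools weight, not per-chromosome ratios", {
  seqs <- c(a = rand_seq(2000, 41), b = rand_seq(6000, 42),
            x = rand_seq(3000, 43))
  g <- toy_genome(seqs,
                  comp = c(a = "nucleomorph", b = "nucleomorph",
                           x = "nucleus"),
                  copy = c(a = 2, b = 2, x = 1))
  set.seed(44)
  tre <- frag_df(sample(names(seqs), 500, TRUE, prob = c(0.5, 0.2, 0.3)),
                 10, 100)
  inp <- frag_df(sample(names(seqs), 500, TRUE, prob = c(0.1, 0.6, 0.3)),
                 10, 100)
  by_comp <- compute_enrichment(tre, inp, g, group_by = "compartment")
  # manual pooled computation over the compartment's chromosomes
  t_nm <- sum(tre$chrom %in% c("a", "b")) / (8 * nrow(tre) / 1e6)
  i_nm <- sum(inp$chrom %in% c("a", "b")) / (8 * nrow(inp) / 1e6)
  expect_equal(by_comp$enrichment[by_comp$group == "nucleomorph"],
               t_nm / i_nm)
  # and it differs from the mean of per-chromosome ratios in general
  by_chr <- compute_enrichment(tre, inp, g, group_by = "chromosome")
  mean_ratio <- mean(by_chr$enrichment[by_chr$group %in% c("a", "b")])
  expect_false(isTRUE(all.equal(
    by_comp$enrichment[by_comp$group == "nucleomorph"], mean_ratio)))
})

test_that("groups without input weight get NA enrichment with a warning", {
  seqs <- c(a = rand_seq(1000, 45), b = rand_seq(1000, 46))
  g <- toy_genome(seqs, comp = c(a = "nucleus", b = "plastid"),
                  copy = c(a = 1, b = 1))
  tre <- frag_df(c("a", "b"), c(0, 0), c(100, 100))
  inp <- frag_df("a", 0, 100)
  expect_warning(enr <- compute_enrichment(tre, inp, g), "zero input")
  expect_true(is.na(enr$enrichment[enr$group == "plastid"]))
})
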