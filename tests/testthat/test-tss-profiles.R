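test_that("a single fragment gives a rectangular profile", {
  fr <- frag_df("c1", 950, 1051)
  anchors <- data.frame(chrom = "c1", pos = 1000L, strand = "+")
  p <- tss_profile(fr, anchors, W = 100)
  expect_equal(sum(p$matrix > 0), 101L)
  expect_equal(unname(p$metaplot[p$positions >= -50 & p$positions <= 50]),
               rep(1, 101))
  expect_equal(sum(p$metaplot), 101)
})

test_that("profiles are strand-aware and symmetric when placement is", {
  anchors <- data.frame(chrom = "c1", pos = c(1000L, 5000L),
                        strand = c("+", "-"))
  # one fragment 100-199 bp downstream of each TSS in gene orientation
  fr <- frag_df("c1", c(1100, 4801), c(1200, 4901))
  p <- tss_profile(fr, anchors, W = 300)
  expect_equal(p$matrix[1, ], p$matrix[2, ])  # flip maps them together
  # symmetric placement about the anchor gives a symmetric metaplot
  fr2 <- frag_df("c1", c(900, 1051), c(950, 1101))
  p2 <- tss_profile(fr2, anchors[1, ], W = 200)
  expect_equal(p2$metaplot, rev(p2$metaplot), tolerance = 1e-9)
})

test_that("profile matrices are additive over library splits", {
  set.seed(61)
  fr <- frag_df("c1", sample(0:3000, 200, TRUE), 0)
  fr$end <- fr$start + sample(50:250, 200, TRUE)
  anchors <- data.frame(chrom = "c1", pos = c(500L, 1500L, 2500L),
                        strand = c("+", "-", "+"))
  pall <- tss_profile(fr, anchors, W = 400)
  p1 <- tss_profile(fr[1:100, ], anchors, W = 400)
  p2 <- tss_profile(fr[101:200, ], anchors, W = 400)
  expect_equal(pall$matrix, p1$matrix + p2$matrix)
  expect_equal(pall$metaplot, colMeans(pall$matrix))
})

test_that("gene signal quantification is scale-invariant and zero-safe", {
  g <- toy_genome(c(c1 = rand_seq(10000, 62)),
                  genes = data.frame(chrom = "c1",
                                     start = c(1000L, 6000L),
                                     end = c(3000L, 8000L),
                                     strand = c("+", "-"),
                                     id = c("g1", "g2"),
                                     is_rdna = FALSE))
  fr <- frag_df("c1", seq(1000, 2800, by = 100), 0)
  fr$end <- fr$start + 150L
  sig <- quantify_gene_signal(fr, g$genes, g, mode = "gene_body")
  expect_equal(unname(sig["g2"]), 0)
  fr2 <- fr; fr2$weight <- 2
  sig2 <- quantify_gene_signal(fr2, g$genes, g, mode = "gene_body")
  expect_equal(sig, sig2)   # weight doubling cancels via library size
  prom <- quantify_gene_signal(fr, g$genes, g, mode = "promoter",
                               promoter_half = 250)
  expect_true(prom["g1"] > 0)
})

test_that("rank correlation matches the brute-force midrank formula", {
  expect_equal(rank_correlation(1:10, 1:10), 1.0)
  expect_equal(rank_correlation(1:10, -(1:10)), -1.0)
  x <- c(3.2, 1.5, 1.5, 7.0, 4.1)
  y <- c(10, 8, 12, 2, 2)
  # brute force: midranks by hand, then Pearson on ranks
  rx <- c(3, 1.5, 1.5, 5, 4)
  ry <- c(4, 3, 5, 1.5, 1.5)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(rank_correlation(x, y), brute)
})

test_that("the peak caller recovers an enriched region and only it", {
  g <- toy_genome(c(c1 = rand_seq(100000, 63)))
  set.seed(64)
  bg <- frag_df("c1", sample(0:99800, 2000, TRUE), 0)
  bg$end <- bg$start + 100L
  hot <- frag_df("c1", sample(50000:50200, 200, TRUE), 0)
  hot$end <- hot$start + 100L
  peaks <- call_peaks_simple(rbind(bg, hot), g, window = 300,
                             p_threshold = 1e-5)
  expect_equal(nrow(peaks), 1L)
  expect_true(peaks$start <= 50000 && peaks$end >= 50300)
  expect_true(peaks$summit >= 50000 && peaks$summit <= 50400)
  expect_warning(empty <- call_peaks_simple(bg[0, ], g), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("uniform libraries produce no peaks at stringent thresholds", {
  g <- toy_genome(c(c1 = rand_seq(100000, 65)))
  set.seed(66)
  fr <- frag_df("c1", sample(0:99800, 10000, TRUE), 0)
  fr$end <- fr$start + 100L
  peaks <- call_peaks_simple(fr, g, window = 300, p_threshold = 1e-5)
  expect_equal(nrow(peaks), 0L)
})

test_that("random control peak arithmetic matches bin boundaries", {
  g1 <- toy_genome(c(c1 = strrep("A", 10000)))
  expect_equal(nrow(random_control_peaks(g1)), 21L)
  g2 <- toy_genome(c(c1 = strrep("A", 10250)))
  expect_equal(nrow(random_control_peaks(g2)), 22L)
  g3 <- toy_genome(c(c1 = strrep("A", 10000), c2 = strrep("A", 2000)))
  rc <- random_control_peaks(g3)
  expect_equal(nrow(rc), 26L)   # 21 + 5
  expect_setequal(unique(rc$chrom), c("c1", "c2"))
})

test_that("peak-TSS distances are signed, oriented and tie-broken upstream", {
  anchors <- data.frame(chrom = "c1", pos = c(1000L, 3000L),
                        strand = c("+", "-"))
  peaks <- data.frame(chrom = "c1", summit = c(1000L, 3000L))
  h <- peak_tss_distances(peaks, anchors, R = 500, bin = 50)
  expect_equal(sum(h$count[h$mid != 0]), 0)
  expect_equal(h$count[h$mid == 0], 2)
  # peak at 1100: 100 downstream of +TSS at 1000
  h2 <- peak_tss_distances(data.frame(chrom = "c1", summit = 1100L),
                           anchors, R = 500, bin = 100)
  expect_equal(h2$count[h2$mid == 100], 1)
  # peak at 2900: 100 downstream of -TSS at 3000
  h3 <- peak_tss_distances(data.frame(chrom = "c1", summit = 2900L),
                           anchors, R = 500, bin = 100)
  expect_equal(h3$count[h3$mid == 100], 1)
  # equidistant between the two anchors: tie goes to the upstream anchor
  d <- attr(peak_tss_distances(data.frame(chrom = "c1", summit = 2000L),
                               anchors, R = 2000, bin = 100), "distances")
  expect_equal(d, 1000)
  # far-away peaks pool into the edge bins
  h4 <- peak_tss_distances(data.frame(chrom = "c1", summit = 90000L),
                           anchors, R = 500, bin = 100)
  expect_equal(h4$count[h4$mid == -500], 1)
})
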