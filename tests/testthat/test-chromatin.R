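test_that("enhancer state follows H3K27ac overlap", {
  genes <- toy_genes()
  k4me1 <- tibble(chrom = "chr1", start = c(30000L, 34000L),
                  end = c(31000L, 35000L), name = c("e1", "e2"))
  k27ac <- tibble(chrom = "chr1", start = 30500L, end = 30800L)
  calls <- classify_enhancers(k4me1, k27ac, genes)
  expect_equal(calls$state[calls$name == "e1"], "active")
  expect_equal(calls$state[calls$name == "e2"], "poised")
  # partition: every candidate gets exactly one state
  expect_setequal(calls$state, c("active", "poised"))
  expect_equal(nrow(calls), 2)
})

test_that("promoter-proximal H3K4me1 peaks are excluded by default only", {
  genes <- toy_genes()
  # center 10100, 100 bp from gA's TSS
  prox <- tibble(chrom = "chr1", start = 9600L, end = 10600L,
                 name = "prox")
  none <- tibble(chrom = "chr1", start = integer(), end = integer())
  with_excl <- classify_enhancers(prox, none, genes)
  expect_equal(nrow(with_excl), 0)
  without <- classify_enhancers(prox, none, genes,
                                exclude_promoter_proximal = FALSE)
  expect_equal(nrow(without), 1)
  expect_equal(without$state, "poised")
})

test_that("minimum-overlap fraction tightens the active call", {
  genes <- toy_genes()
  k4me1 <- tibble(chrom = "chr1", start = 30000L, end = 31000L,
                  name = "e1")
  sliver <- tibble(chrom = "chr1", start = 30990L, end = 31500L)
  loose <- classify_enhancers(k4me1, sliver, genes)
  strict <- classify_enhancers(k4me1, sliver, genes,
                               min_overlap_frac = 0.5)
  expect_equal(loose$state, "active")
  expect_equal(strict$state, "poised")
})

test_that("cluster class sets partition the clustered regions", {
  x <- matrix(c(rep(0, 40), rep(10, 40)), nrow = 8, byrow = TRUE)
  rownames(x) <- sprintf("e%d", 1:8)
  cl <- kmeans_cluster(x, k = 2, seed = 1)
  regions <- tibble(chrom = "chr1",
                    start = seq(1000L, by = 5000L, length.out = 8),
                    end = seq(2000L, by = 5000L, length.out = 8),
                    name = sprintf("e%d", 1:8))
  sets <- enhancer_class_sets(regions, cl)
  expect_length(sets, 2)
  expect_equal(sum(vapply(sets, nrow, 0L)), 8)
  expect_setequal(unlist(lapply(sets, function(s) s$name)), regions$name)
  bad <- mutate(regions, name = paste0("x", name))
  expect_error(enhancer_class_sets(bad, cl), "do not match")
})

test_that("bivalent promoters require both marks at the promoter", {
  genes <- toy_genes()
  k4me3 <- tibble(chrom = "chr1", start = c(9500L, 49000L),
                  end = c(10200L, 50200L))
  k27me3 <- tibble(chrom = "chr1", start = 9000L, end = 10100L)
  out <- call_bivalent_promoters(k4me3, k27me3, genes)
  st <- out$states
  expect_true(st$bivalent[st$gene_id == "gA"])
  expect_false(st$bivalent[st$gene_id == "gB"])  # K4me3 only
  expect_false(st$bivalent[st$gene_id == "gC"])  # no marks
  expect_equal(out$n_bivalent, 1L)
  expect_equal(st$bivalent, st$has_k4me3 & st$has_k27me3)
})

test_that("bivalent count is monotone under peak-set shrinkage", {
  g <- small_genome()
  chip4 <- simulate_chip_assay(g, "H3K4me3", "FGSC")
  chip27 <- simulate_chip_assay(g, "H3K27me3", "FGSC")
  full <- call_bivalent_promoters(chip4$peaks, chip27$peaks, g$genes)
  set.seed(4)
  for (frac in c(0.7, 0.4)) {
    sub4 <- chip4$peaks[sample(nrow(chip4$peaks),
                               round(frac * nrow(chip4$peaks))), ]
    sub27 <- chip27$peaks[sample(nrow(chip27$peaks),
                                 round(frac * nrow(chip27$peaks))), ]
    expect_lte(call_bivalent_promoters(sub4, chip27$peaks,
                                       g$genes)$n_bivalent,
               full$n_bivalent)
    expect_lte(call_bivalent_promoters(chip4$peaks, sub27,
                                       g$genes)$n_bivalent,
               full$n_bivalent)
  }
})

test_that("peak-promoter fraction is a plain overlap fraction", {
  genes <- toy_genes()
  inside <- tibble(chrom = "chr1",
                   start = rep(9000L, 9), end = rep(9100L, 9))
  outside <- tibble(chrom = "chr1", start = 30000L, end = 30100L)
  expect_equal(peak_promoter_fraction(inside, genes), 1.0)
  expect_equal(peak_promoter_fraction(outside, genes), 0.0)
  expect_equal(peak_promoter_fraction(bind_rows(inside, outside), genes),
               0.9)
  expect_error(peak_promoter_fraction(inside[0, ], genes), "empty")
})

test_that("TSS distance histogram counts every call once", {
  calls <- tibble(tss_distance = c(-1000L, -6000L, 100L, 7000L))
  h <- tss_distance_histogram(calls, breaks = c(-5000L, 0L, 5000L))
  expect_equal(sum(h$count), nrow(calls))
  expect_equal(h$count[h$lower == -5000], 1L)   # the -1000 call
  expect_equal(h$count[is.infinite(h$lower)], 1L)  # -6000 underflow
  expect_equal(h$count[h$upper == Inf], 1L)        # 7000 overflow
  empty <- tss_distance_histogram(calls[0, ], breaks = c(-5000L, 0L))
  expect_true(all(empty$count == 0))
  expect_error(tss_distance_histogram(calls, c(0L, 0L)), "increasing")
})
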