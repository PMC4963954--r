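test_that("genome generation is deterministic and validates sizing", {
  cfg <- sim_config(seed = 5, genome_length = 3e6, n_genes = 100,
                    n_enhancers_per_class = 25, n_te_per_family = 10,
                    n_dmrs = 6, signal_depth = 3e5)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$cpg_positions, g2$cpg_positions)
  expect_identical(g1$truth, g2$truth)

  empty <- simulate_genome(sim_config(n_genes = 0,
                                      n_enhancers_per_class = 0,
                                      n_te_per_family = 0, n_dmrs = 0))
  expect_equal(nrow(empty$genes), 0)

  expect_error(simulate_genome(sim_config(genome_length = 1e5,
                                          n_genes = 100)),
               "too small")
})

test_that("generated layout satisfies its own invariants", {
  g <- small_genome()
  genes <- arrange(g$genes, body_start)
  # gene bodies do not overlap
  expect_true(all(head(genes$body_end, -1) <= tail(genes$body_start, -1)))
  # enhancer classes partition the enhancer set
  expect_equal(sort(unique(g$truth$enhancers$class)),
               c("esc_specific", "fgsc_specific", "shared", "weak"))
  expect_equal(nrow(g$truth$enhancers), 100)
  # six TE families present
  expect_setequal(unique(g$annotations$transposons$name),
                  c("LINE_L1", "LTR_ERV1", "IAP", "DNA", "SINE_B1",
                    "SINE_B2"))
  # some TEs overlap CpG islands (as annotated)
  te <- g$annotations$transposons
  expect_true(any(overlaps_any(te, g$annotations$cpg_islands)))
  # promoter/body truth states partition the gene set per cell type
  pm <- g$truth$promoter_methyl
  expect_equal(nrow(pm), 2 * nrow(genes))
  expect_true(all(pm$state %in% c("methylated", "unmethylated")))
})

test_that("ChIP tracks are elevated over planted peaks", {
  g <- small_genome()
  assay <- simulate_chip_assay(g, "H3K4me1", "FGSC")
  tr <- assay$track
  bw <- tr$bin_width
  v <- tr$signal[[1]]
  n_ok <- 0
  for (i in seq_len(nrow(assay$peaks))) {
    lo <- assay$peaks$start[i] %/% bw + 1
    hi <- (assay$peaks$end[i] - 1) %/% bw + 1
    flank_lo <- max(lo - 40, 1):(lo - 21)
    inside <- mean(v[lo:hi])
    flank <- mean(v[flank_lo])
    if (inside > flank) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / nrow(assay$peaks), 0.99)
  # simple threshold recovery: in-peak mean clears 3x the genome median
  med <- median(v[v > 0])
  frac <- mean(vapply(seq_len(nrow(assay$peaks)), function(i) {
    lo <- assay$peaks$start[i] %/% bw + 1
    hi <- (assay$peaks$end[i] - 1) %/% bw + 1
    mean(v[lo:hi]) > 3 * med
  }, logical(1)))
  expect_gte(frac, 0.99)
  expect_error(simulate_chip_assay(g, "H3K9me3", "FGSC"), "unknown mark")
  expect_error(simulate_chip_assay(g, "H3K4me1", "NPC"),
               "unknown cell type")
})

test_that("bisulfite counts reflect planted CpG states", {
  g <- small_genome()
  m <- simulate_methylation_assays(g)
  bs <- inner_join(m$bisulfite, g$truth$cpg_methyl,
                   by = c("chrom", "pos"))
  ratio_m <- with(filter(bs, methylated_mgsc),
                  sum(count_C) / sum(count_C + count_T))
  ratio_u <- with(filter(bs, !methylated_mgsc),
                  sum(count_C) / sum(count_C + count_T))
  expect_equal(ratio_m, 0.8, tolerance = 0.05)
  expect_equal(ratio_u, 0.05, tolerance = 0.5)
  expect_lt(ratio_u, 0.1)
})

test_that("written study files validate against the package readers", {
  outdir <- withr::local_tempdir()
  cfg <- sim_config(seed = 5, genome_length = 2e6, n_genes = 60,
                    n_enhancers_per_class = 15, n_te_per_family = 6,
                    n_dmrs = 4, signal_depth = 2e5)
  study <- simulate_study(cfg, outdir)
  genes <- read_gene_models(file.path(outdir, "genes.tsv"))
  expect_equal(genes$gene_id, study$genome$genes$gene_id)
  expect_equal(genes$promoter_start, study$genome$genes$promoter_start)
  peaks <- read_bed(file.path(outdir, "peaks_H3K4me1_FGSC.bed"))
  expect_equal(nrow(peaks), nrow(study$chip$H3K4me1_FGSC$peaks))
  track <- read_bedgraph(file.path(outdir, "track_H3K4me1_FGSC.bedGraph"),
                         study$genome$chrom_lengths)
  expect_equal(track$signal[[1]], study$chip$H3K4me1_FGSC$track$signal[[1]])
  sites <- read_bisulfite(file.path(outdir, "bisulfite_MGSC.tsv"))
  expect_equal(sites$pos, study$methylation$bisulfite$pos)
  expect_equal(sites$count_C, study$methylation$bisulfite$count_C)
  truth <- jsonlite::read_json(file.path(outdir, "ground_truth.json"))
  expect_true(all(c("enhancers", "bivalent", "promoter_methyl") %in%
                    names(truth)))
})

test_that("correlated score generator hits the requested latent structure", {
  sc <- simulate_correlated_scores(5000, 0.9, seed = 4)
  expect_gt(cor(sc$cap_score, sc$bs_score), 0.8)
  sc0 <- simulate_correlated_scores(5000, 0, seed = 4)
  expect_lt(abs(cor(sc0$cap_score, sc0$bs_score)), 0.05)
  expect_identical(simulate_correlated_scores(100, 0.3, seed = 2),
                   simulate_correlated_scores(100, 0.3, seed = 2))
})
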