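test_that("promoter windows tile the promoter strand-aware", {
  g <- gene_promoters(tibble(
    gene_id = "gP", chrom = "chr1", strand = "+", tss = 10000L,
    body_start = 10000L, body_end = 15000L))
  w <- promoter_windows(g)
  expect_equal(nrow(w), 5)
  expect_equal(w$start, seq(8000L, 10000L, by = 500L))
  expect_equal(w$end, w$start + 500L)
  expect_equal(w$name, sprintf("gP:%d", 1:5))

  gm <- gene_promoters(tibble(
    gene_id = "gM", chrom = "chr1", strand = "-", tss = 10000L,
    body_start = 5000L, body_end = 10001L))
  wm <- promoter_windows(gm)
  # window 1 is most upstream = highest coordinates on the minus strand
  expect_equal(wm$start[1], 10000L + 2001L - 500L)
  expect_equal(sort(wm$start), seq(min(wm$start), by = 500L,
                                   length.out = 5))
  both <- promoter_windows(bind_rows(g, gm))
  expect_equal(nrow(both), 10)
  expect_error(promoter_windows(g, window_width = 300L), "divide")
})

test_that("genome tiling is disjoint and exhaustive with truncated tails", {
  t1 <- tile_genome(c(chrA = 2500L), 1000L)
  expect_equal(t1$start, c(0L, 1000L, 2000L))
  expect_equal(t1$end, c(1000L, 2000L, 2500L))
  t2 <- tile_genome(c(chrA = 700L), 1000L)
  expect_equal(nrow(t2), 1)
  expect_equal(t2$end, 700L)
  t3 <- tile_genome(c(chrA = 10000L, chrB = 3333L), 1000L)
  expect_equal(sum(t3$end - t3$start), 13333L)
  expect_true(all((t3 |> group_by(chrom) |>
                     summarise(gap = sum(end - start) == max(end)))$gap))
})

test_that("capture rms divides window RPKM by CpG count", {
  # one raw read in each of the first 10 bins, RPKM-normalized at 1e6
  tr <- binned_track(list(chr1 = c(rep(1, 10), rep(0, 90)) /
                            ((50 / 1000) * (1e6 / 1e6))), 50L,
                     c(chr1 = 5000L), "rpkm", 1e6)
  w <- tibble(chrom = "chr1", start = 0L, end = 500L, name = "w1")
  cpg <- tibble(chrom = "chr1", pos = c(10L, 100L, 200L, 400L))
  out <- capture_rms(w, tr, cpg)
  # window RPKM = 10 / (0.5 kb * 1 M) = 20; 4 CpGs -> rms 5
  expect_equal(out$score, 20 / 4)
  expect_equal(out$cpg_count, 4L)
  # doubling counts at fixed library doubles rms
  tr2 <- tr
  tr2$signal$chr1 <- tr$signal$chr1 * 2
  expect_equal(capture_rms(w, tr2, cpg)$score, 2 * out$score)
  # zero CpGs -> no_data
  no_cpg <- capture_rms(w, tr, cpg[0, ])
  expect_equal(no_cpg$call, "no_data")
  expect_true(is.na(no_cpg$score))
})

test_that("bisulfite ams pools counts and honours the coverage floor", {
  w <- tibble(chrom = "chr1", start = 0L, end = 1000L, name = "w1")
  sites <- tibble(chrom = "chr1", pos = c(10L, 500L), strand = "+",
                  count_C = c(9L, 3L), count_T = c(1L, 7L))
  out <- bisulfite_ams(w, sites)
  expect_equal(out$score, 12 / 20)
  expect_equal(out$coverage, 20)
  expect_equal(out$call, "unscored")
  # all converted reads -> ams 0
  allT <- mutate(sites, count_C = 0L, count_T = 10L)
  expect_equal(bisulfite_ams(w, allT)$score, 0)
  # no sites -> no_data
  expect_equal(bisulfite_ams(w, sites[0, ])$call, "no_data")
  # below min coverage -> no_data
  low <- mutate(sites, count_C = c(1L, 0L), count_T = c(1L, 1L))
  expect_equal(bisulfite_ams(w, low)$call, "no_data")
  # splitting a site's counts across duplicate records changes nothing
  split_sites <- tibble(chrom = "chr1", pos = c(10L, 10L, 500L),
                        strand = "+", count_C = c(4L, 5L, 3L),
                        count_T = c(1L, 0L, 7L))
  expect_equal(bisulfite_ams(w, split_sites)$score, out$score)
  # per-site averaging option
  expect_equal(bisulfite_ams(w, sites, per_site_mean = TRUE)$score,
               mean(c(0.9, 0.3)))
})

test_that("exact binomial tail matches pmf summation and closed forms", {
  expect_equal(binomial_methylation_call(6, 10, 0.25), 0.0197277069091797,
               tolerance = 1e-10)
  expect_equal(binomial_methylation_call(0, 10, 0.25), 1.0)
  expect_equal(binomial_methylation_call(4, 4, 0.25), 0.25^4)
  expect_true(is.na(binomial_methylation_call(0, 0, 0.25)))
})

test_that("BH adjustment equals the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.04, 0.2)),
               c(0.004, 0.04, 0.04 * 4 / 3, 0.2))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.5)), "\\[0, 1\\]")
  # permutation invariance
  set.seed(31)
  p <- runif(50)
  o <- sample(50)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("bisulfite region calls use two separately adjusted test families", {
  # 100-window family: one clearly highly methylated, one clearly low,
  # the rest intermediate noise
  set.seed(8)
  n <- 100
  w <- tibble(chrom = "chr1", start = seq(0L, by = 1000L, length.out = n),
              end = seq(1000L, by = 1000L, length.out = n),
              name = sprintf("w%03d", 1:n))
  cov <- rep(100L, n)
  cc <- rbinom(n, cov, 0.5)
  cc[1] <- 95L
  cc[2] <- 10L
  win <- mutate(w, assay = "bisulfite", score = cc / cov, coverage = cov,
                cpg_count = 10L, count_C = cc, count_T = cov - cc,
                call = "unscored")
  win$call[3] <- "no_data"
  out <- call_bisulfite_regions(win)
  expect_equal(out$call[1], "highly_methylated")
  expect_equal(out$call[2], "unmethylated")
  expect_equal(out$call[3], "no_data")
  expect_true(is.na(out$p_methylated[3]))
  # ratio-0.5 windows clear the 0.25 test but not the 0.75 test
  mid <- out$call[cc > 40 & cc < 60 & win$call != "no_data"]
  expect_true(all(mid %in% c("methylated", "unmethylated")))
  expect_true(any(mid == "methylated"))
  # highly_methylated implies the 0.25-family also passes
  hm <- filter(out, call == "highly_methylated")
  expect_true(all(hm$q_methylated < 0.01))
})

test_that("capture HMR calling needs both FDR and fold change", {
  lib <- 1e6
  mk_track <- function(counts) {
    binned_track(list(chr1 = counts / ((50 / 1000) * (lib / 1e6))), 50L,
                 c(chr1 = length(counts) * 50L), "rpkm", lib)
  }
  # 20 tiles of 1 kb = 400 bins; tile 1 holds 100 capture vs 10 input
  cap_counts <- rep(5, 400)
  inp_counts <- rep(5, 400)
  cap_counts[1:20] <- 100 / 20
  inp_counts[1:20] <- 10 / 20
  tiles <- tile_genome(c(chr1 = 20000L), 1000L)
  out <- call_capture_hmrs(tiles, mk_track(cap_counts),
                           mk_track(inp_counts))
  expect_equal(out$call[1], "highly_methylated")
  expect_true(all(out$call[-1] == "unmethylated"))
  # identical tracks: fold 1 everywhere, nothing called
  same <- call_capture_hmrs(tiles, mk_track(cap_counts),
                            mk_track(cap_counts))
  expect_true(all(same$call == "unmethylated"))
  expect_error(call_capture_hmrs(tiles, mk_track(cap_counts), NULL),
               "input track")
  # adding capture reads to a called tile never un-calls it
  more <- cap_counts
  more[1:20] <- more[1:20] + 5
  out2 <- call_capture_hmrs(tiles, mk_track(more), mk_track(inp_counts))
  expect_equal(out2$call[1], "highly_methylated")
})

test_that("cross-platform correlation drops uncovered pairs and flags degeneracy", {
  w <- sprintf("w%d", 1:6)
  capw <- tibble(name = w, score = c(1, 2, 3, 4, 5, 6),
                 call = c(rep("unscored", 5), "no_data"))
  bsw <- tibble(name = w, score = c(1, 2, 3, 4, 5, 100),
                call = "unscored")
  out <- cross_platform_correlation(capw, bsw)
  expect_equal(out$n_windows, 5)
  expect_equal(out$r, 1.0)
  const <- mutate(bsw, score = 1)
  expect_error(cross_platform_correlation(capw, const), "constant")
  expect_error(cross_platform_correlation(capw[1:2, ], bsw[1:2, ]),
               "fewer than 3")
})

test_that("promoter comparison partitions genes by agreement", {
  a <- tibble(gene_id = c("g1", "g2", "g3", "g4"),
              methylated = c(TRUE, TRUE, FALSE, FALSE))
  b <- tibble(gene_id = c("g1", "g2", "g3", "g4"),
              methylated = c(TRUE, FALSE, TRUE, FALSE))
  cmp <- compare_promoter_calls(a, b)
  expect_equal(unname(cmp$counts),
               c(1L, 1L, 1L))
  expect_equal(cmp$genes$category[cmp$genes$gene_id == "g1"], "shared")
  expect_equal(cmp$genes$category[cmp$genes$gene_id == "g2"], "a_specific")
  expect_equal(cmp$genes$category[cmp$genes$gene_id == "g3"], "b_specific")
  expect_false("g4" %in% cmp$genes$gene_id)
  expect_equal(sum(cmp$counts), nrow(cmp$genes))
  expect_error(compare_promoter_calls(a, b[1:3, ]), "universe")
})

test_that("gene methylation categories give promoter precedence", {
  prom <- tibble(gene_id = c("g1", "g2", "g3"),
                 methylated = c(TRUE, FALSE, FALSE))
  body <- tibble(gene_id = c("g1", "g2", "g3"),
                 methylated = c(TRUE, TRUE, FALSE))
  out <- categorize_genes_by_methylation(prom, body)
  expect_equal(out$genes$category, c("promoter_methylated", "body_only",
                                     "hypomethylated"))
  expect_equal(out$fraction_promoter_with_body, 1.0)
})

test_that("annotation methylation frequency restricts and reports no-data", {
  ann <- tibble(chrom = "chr1",
                start = c(0L, 2000L, 4000L), end = c(1000L, 3000L, 5000L),
                name = c("famA", "famA", "famB"))
  calls <- tibble(chrom = "chr1", start = 0L, end = 500L,
                  call = "methylated")
  out <- annotation_methylation_frequency(ann, calls)
  expect_equal(out$frequency[out$family == "famA"], 0.5)
  expect_equal(out$frequency[out$family == "famB"], 0.0)
  cgi <- tibble(chrom = "chr1", start = 100L, end = 200L)
  restricted <- annotation_methylation_frequency(
    ann, calls, require_cpg_island_overlap = TRUE, cpg_islands = cgi)
  expect_equal(restricted$n_loci[restricted$family == "famA"], 1L)
  expect_equal(restricted$frequency[restricted$family == "famA"], 1.0)
  expect_true(is.na(restricted$frequency[restricted$family == "famB"]))
  expect_true(all(restricted$n_loci <= out$n_loci))
})
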