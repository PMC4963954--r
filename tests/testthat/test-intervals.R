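test_that("read_bed parses BED conventions and rejects bad intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", f)
  expect_equal(read_bed(f)$strand, ".")  # BED3: unstranded
  writeLines(c("chr1\t100\t200\ta\t0\t+", "chr1\t400\t600\tpk\t5\t-"), f)
  x <- read_bed(f)
  expect_equal(x$start, c(100L, 400L))
  expect_equal(x$end, c(200L, 600L))
  expect_equal(x$strand, c("+", "-"))

  writeLines(character(0), f)
  expect_equal(nrow(read_bed(f)), 0)

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f), "line 1")

  writeLines("chr1\t100", f)
  expect_error(read_bed(f), "3 columns")
})

test_that("write_bed / read_bed round-trips canonical records", {
  x <- genomic_intervals("chr1", c(0L, 150L), c(100L, 400L),
                         strand = c("+", "-"),
                         name = c("a", "b"), score = c(1, 2))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$name, x$name)
  expect_equal(y$strand, x$strand)
})

test_that("interval overlap is half-open", {
  a <- tibble(chrom = "chr1", start = 100L, end = 200L)
  expect_true(interval_overlaps(a, tibble(chrom = "chr1", start = 199L,
                                          end = 300L)))
  expect_false(interval_overlaps(a, tibble(chrom = "chr1", start = 200L,
                                           end = 300L)))
  expect_false(interval_overlaps(a, tibble(chrom = "chr2", start = 100L,
                                           end = 200L)))
})

test_that("overlap queries agree with brute-force scan on random sets", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(50:1000, 1)
    mk <- function(n) {
      s <- sample.int(1e5, n)
      tibble(chrom = sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
             start = s, end = s + sample.int(500, n, replace = TRUE))
    }
    q <- mk(n)
    s <- mk(sample(50:1000, 1))
    expect_equal(overlaps_any(q, s), overlaps_brute(q, s))
  }
})

test_that("nearest TSS distance is signed by gene strand with stated tie-breaks", {
  genes <- toy_genes()
  # peak center 5000 is 1 kb upstream of gA (+ strand, TSS 10000)
  pk <- tibble(chrom = "chr1", start = 4500L, end = 5500L)
  d <- nearest_tss_distance(pk, genes)
  expect_equal(d$tss_distance, -5000L)
  expect_equal(d$nearest_gene, "gA")

  # center exactly at the TSS
  pk0 <- tibble(chrom = "chr1", start = 9500L, end = 10500L)
  expect_equal(nearest_tss_distance(pk0, genes)$tss_distance, 0L)

  # equidistant TSSs: lexicographically smaller gene id wins
  g2 <- gene_promoters(tibble(
    gene_id = c("gB", "gA"), chrom = "chr1", strand = "+",
    tss = c(9000L, 11000L), body_start = c(9000L, 11000L),
    body_end = c(9500L, 11500L)))
  pk1 <- tibble(chrom = "chr1", start = 9750L, end = 10250L)
  expect_equal(nearest_tss_distance(pk1, g2)$nearest_gene, "gA")

  # minus-strand gene: peak right of TSS is upstream (negative)
  gm <- toy_genes()[2, ]
  pkm <- tibble(chrom = "chr1", start = 51500L, end = 52500L)
  expect_equal(nearest_tss_distance(pkm, gm)$tss_distance, 50000L - 52000L)

  # unsigned option
  expect_equal(nearest_tss_distance(pkm, gm, signed = FALSE)$tss_distance,
               2000L)
})

test_that("nearest TSS distance is invariant under genome-wide translation", {
  set.seed(7)
  genes <- toy_genes()
  pk <- tibble(chrom = "chr1",
               start = sample.int(60000L, 20), end = 0L)
  pk$end <- pk$start + 1000L
  shift <- 12345L
  d0 <- nearest_tss_distance(pk, genes)
  genes_s <- mutate(genes, tss = tss + shift, body_start = body_start + shift,
                    body_end = body_end + shift,
                    promoter_start = promoter_start + shift,
                    promoter_end = promoter_end + shift)
  pk_s <- mutate(pk, start = start + shift, end = end + shift)
  d1 <- nearest_tss_distance(pk_s, genes_s)
  expect_equal(d0$tss_distance, d1$tss_distance)
  expect_equal(d0$nearest_gene, d1$nearest_gene)
})

test_that("nearest gene respects the 200-kb cutoff", {
  genes <- gene_promoters(tibble(
    gene_id = c("near", "far"), chrom = "chr1", strand = "+",
    tss = c(50000L, 310000L), body_start = c(50000L, 310000L),
    body_end = c(60000L, 320000L)))
  pk <- tibble(chrom = "chr1", start = 99500L, end = 100500L)
  expect_equal(nearest_gene_within(pk, genes)$nearest_gene, "near")

  pk_far <- tibble(chrom = "chr1", start = 559500L, end = 560500L)
  expect_true(is.na(nearest_gene_within(pk_far, genes)$nearest_gene))

  # peak inside a gene body, TSS close by
  pk_in <- tibble(chrom = "chr1", start = 50005L, end = 50015L)
  expect_equal(nearest_gene_within(pk_in, genes)$nearest_gene, "near")
})

test_that("promoters are strand-aware and exactly 2500 bp", {
  genes <- toy_genes()
  expect_equal(genes$promoter_end - genes$promoter_start,
               rep(2500L, 3))
  # + strand: [tss - 2000, tss + 500)
  expect_equal(genes$promoter_start[1], 8000L)
  expect_equal(genes$promoter_end[1], 10500L)
  # - strand mirror: covers [tss - 499, tss + 2001)
  expect_equal(genes$promoter_start[2], 50000L - 499L)
  expect_equal(genes$promoter_end[2], 50000L + 2001L)
  expect_error(
    gene_promoters(tibble(gene_id = "x", chrom = "chr1", strand = "+",
                          tss = 100L, body_start = 200L, body_end = 300L)),
    "TSS outside"
  )
})
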