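suppressPackageStartupMessages(library(dplyr))

# Shared full-scale synthetic study (defaults, seed 17), built once.
.fixtures <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulate_study_memory(sim_config(seed = 17))
  }
  .fixtures$study
}

small_genome <- function(seed = 3) {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_genome(sim_config(
      seed = seed, genome_length = 3e6, n_genes = 100,
      n_enhancers_per_class = 25, n_te_per_family = 10, n_dmrs = 6,
      signal_depth = 3e5, n_knockdown_responsive = 10))
  }
  .fixtures$small
}

toy_genes <- function() {
  gene_promoters(tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(10000L, 50000L, 20000L),
    body_start = c(10000L, 40000L, 20000L),
    body_end = c(20000L, 50001L, 30000L)
  ))
}

# ---- independent oracles ----

# Brute-force all-pairs half-open overlap
overlaps_brute <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(query$chrom[i] == subject$chrom &
          query$start[i] < subject$end &
          subject$start < query$end[i])
  }, logical(1))
}

# Upper binomial tail by explicit pmf summation
binom_tail_brute <- function(C, n, p0) {
  if (C > n) return(0)
  sum(dbinom(seq.int(C, n), n, p0))
}

# Benjamini-Hochberg step-up written independently
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- p[o] * m / seq_len(m)
  qs <- pmin(rev(cummin(rev(qs))), 1)
  q <- numeric(m)
  q[o] <- qs
  q
}

# Exact signed-rank p by full enumeration of 2^n sign assignments
wilcoxon_enum_p <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  p_ge <- mean(vs >= v - 1e-9)
  p_le <- mean(vs <= v + 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_ge, p_le)),
         greater = p_ge,
         less = p_le)
}

precision_recall <- function(called, truth) {
  c(precision = if (length(called)) mean(called %in% truth) else NA_real_,
    recall = if (length(truth)) mean(truth %in% called) else NA_real_)
}
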