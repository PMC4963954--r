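#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test for paired samples. Zero differences are dropped
#' (the standard Wilcoxon convention); |differences| are ranked with
#' midranks for ties. For `n <= exact_limit` remaining pairs the exact
#' null distribution of the positive-rank sum is computed by
#' convolution over the (possibly tied) rank multiset — identical to
#' enumerating all 2^n sign assignments; above that, a normal
#' approximation with tie-corrected variance and continuity correction
#' is used. Two-sided by default.
#'
#' @param x,y Equal-length numeric vectors (paired observations).
#' @param alternative `"two.sided"`, `"greater"` (x > y) or `"less"`.
#' @param exact_limit Largest n using the exact distribution
#'   (default 25).
#' @return Tibble with `statistic` (positive-rank sum `V`), `n_used`,
#'   `p_value`, `method`, `alternative`.
#' @export
#' @examples
#' paired_wilcoxon(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))  # p = 0.0625
paired_wilcoxon <- function(x, y, alternative = c("two.sided", "greater",
                                                  "less"),
                            exact_limit = 25L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) abort("all paired differences are zero; test degenerate")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of V over random signs: convolve over doubled ranks
    # (midranks are half-integers; doubling keeps the support integral)
    r2 <- as.integer(round(2 * r))
    probs <- numeric(sum(r2) + 1L)  # index i -> P(2V = i - 1)
    probs[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), probs[seq_len(length(probs) - ri)])
      probs <- 0.5 * (probs + shifted)
    }
    v2 <- as.integer(round(2 * v))
    p_ge <- sum(probs[(v2 + 1L):length(probs)])
    p_le <- sum(probs[1:(v2 + 1L)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge,
                less = p_le)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    cc <- 0.5
    z_ge <- (v - mu - cc) / sqrt(sigma2)
    z_le <- (v - mu + cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pnorm(z_ge, lower.tail = FALSE),
                                           pnorm(z_le))),
                greater = pnorm(z_ge, lower.tail = FALSE),
                less = pnorm(z_le))
    method <- "normal_approx"
  }
  tibble(statistic = v, n_used = n, p_value = p, method = method,
         alternative = alternative, test_name = "paired_wilcoxon")
}

#' Compare expression between conditions within gene classes
#'
#' For each gene class (e.g. genes nearest to cell-type-specific active
#' enhancers) plus an always-present `"all"` baseline, runs a paired
#' Wilcoxon test of per-gene FPKM between two conditions and reports
#' box-plot summaries.
#'
#' @param expr Expression tibble: `gene_id` plus one numeric column per
#'   condition (FPKM).
#' @param gene_sets Named list of gene-id vectors.
#' @param cond_a,cond_b Condition column names.
#' @return Tibble: one row per class with `n_genes`, medians and
#'   quartiles per condition, `statistic`, `p_value`, and a `skipped`
#'   flag for empty or degenerate classes.
#' @export
class_expression_comparison <- function(expr, gene_sets, cond_a, cond_b) {
  stopifnot(all(c(cond_a, cond_b) %in% names(expr)))
  sets <- c(list(all = expr$gene_id), gene_sets)
  list_rbind(imap(sets, function(ids, cls) {
    sub <- expr[expr$gene_id %in% ids, ]
    base <- tibble(
      class = cls, n_genes = nrow(sub),
      median_a = NA_real_, q1_a = NA_real_, q3_a = NA_real_,
      median_b = NA_real_, q1_b = NA_real_, q3_b = NA_real_,
      statistic = NA_real_, p_value = NA_real_, skipped = TRUE
    )
    if (nrow(sub) == 0) {
      warning(sprintf("class '%s': no genes in expression table", cls))
      return(base)
    }
    a <- sub[[cond_a]]
    b <- sub[[cond_b]]
    qa <- quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
    qb <- quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    base$q1_a <- qa[1]; base$median_a <- qa[2]; base$q3_a <- qa[3]
    base$q1_b <- qb[1]; base$median_b <- qb[2]; base$q3_b <- qb[3]
    if (all(a == b)) {
      warning(sprintf("class '%s': identical conditions, test degenerate",
                      cls))
      return(base)
    }
    w <- paired_wilcoxon(a, b)
    base$statistic <- w$statistic
    base$p_value <- w$p_value
    base$skipped <- FALSE
    base
  }))
}

#' Two-library differential expression
#'
#' Replicate-free comparison of two count libraries: per gene, an exact
#' two-sided binomial test of the library-A count against the total,
#' with null proportion equal to library A's share of the summed
#' depths; BH-adjusted q-values; fold change on pseudocounted,
#' depth-normalized counts.
#'
#' @param counts_a,counts_b Integer count vectors (same gene order).
#' @param gene_ids Optional gene ids.
#' @param alpha Significance threshold used for the `significant` flag
#'   (on unadjusted p, default 0.05) and `significant_fdr` (on q).
#' @param pseudocount Added to both counts for the fold ratio.
#' @return Tibble: `gene_id`, `count_a`, `count_b`, `fold_change`
#'   (a over b), `p_value`, `q_value`, `direction`, `significant`,
#'   `significant_fdr`.
#' @export
two_library_de <- function(counts_a, counts_b, gene_ids = NULL,
                           alpha = 0.05, pseudocount = 1) {
  stopifnot(length(counts_a) == length(counts_b))
  lib_a <- sum(counts_a)
  lib_b <- sum(counts_b)
  if (lib_a <= 0 || lib_b <= 0) abort("both libraries need positive depth")
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_along(counts_a))
  share <- lib_a / (lib_a + lib_b)
  n <- counts_a + counts_b
  p <- vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(1)
    binom.test(counts_a[i], n[i], p = share)$p.value
  }, 0)
  fold <- ((counts_a + pseudocount) / (counts_b + pseudocount)) *
    (lib_b / lib_a)
  tibble(
    gene_id = gene_ids,
    count_a = counts_a, count_b = counts_b,
    fold_change = fold,
    p_value = p,
    q_value = bh_adjust(p),
    direction = dplyr::case_when(fold > 1 ~ "up", fold < 1 ~ "down",
                                 TRUE ~ "none"),
    significant = p < alpha,
    significant_fdr = q_value < alpha
  )
}
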