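#' Attach strand-aware promoter windows to gene models
#'
#' The promoter is defined as -2 kb to +500 bp around the TSS in the
#' direction of transcription (2500 bp exactly): `[tss-2000, tss+500)` on
#' the plus strand and the reflected window on the minus strand. This
#' single definition is used everywhere (bivalent calling, peak-promoter
#' fractions, methylation windows).
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `tss`,
#'   `body_start`, `body_end` (0-based).
#' @param upstream,downstream Promoter extent in bases relative to the
#'   TSS (defaults 2000 and 500).
#' @return `genes` with `promoter_start` and `promoter_end` columns.
#' @export
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
#'                     tss = 10000L, body_start = 10000L, body_end = 15000L)
#' gene_promoters(g)
gene_promoters <- function(genes, upstream = 2000L, downstream = 500L) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  bad <- which(!(genes$body_start < genes$body_end &
                   genes$tss >= genes$body_start &
                   genes$tss <= genes$body_end))
  if (length(bad)) {
    abort(sprintf("gene %s: TSS outside gene body", genes$gene_id[bad[1]]))
  }
  mutate(
    genes,
    promoter_start = if_else(.data$strand == "+",
                             .data$tss - upstream,
                             .data$tss - downstream + 1L),
    promoter_end = if_else(.data$strand == "+",
                           .data$tss + downstream,
                           .data$tss + upstream + 1L)
  )
}

# Promoter intervals as a plain interval tibble (one row per gene).
promoter_intervals <- function(genes) {
  if (!"promoter_start" %in% names(genes)) genes <- gene_promoters(genes)
  tibble(chrom = genes$chrom,
         start = pmax(genes$promoter_start, 0L),
         end = genes$promoter_end,
         strand = genes$strand,
         name = genes$gene_id)
}

#' Signed distance from peak centers to the nearest TSS
#'
#' For each peak the nearest TSS (by absolute distance from the peak
#' center) is found and the distance signed relative to gene orientation:
#' negative means the peak lies upstream of the TSS, positive downstream.
#' Ties are broken by smaller absolute distance, then lexicographically
#' smaller `gene_id`.
#'
#' @param peaks Interval tibble.
#' @param genes Gene tibble.
#' @param signed If `FALSE`, return absolute distances.
#' @return A tibble with one row per peak: `chrom`, `start`, `end`,
#'   `center`, `nearest_gene`, `tss_distance`.
#' @export
nearest_tss_distance <- function(peaks, genes, signed = TRUE) {
  stopifnot(nrow(genes) > 0)
  centers <- peak_center(peaks)
  out <- tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                center = centers,
                nearest_gene = NA_character_,
                tss_distance = NA_integer_)
  for (ch in unique(peaks$chrom)) {
    g <- genes[genes$chrom == ch, ]
    pi <- which(peaks$chrom == ch)
    if (nrow(g) == 0 || length(pi) == 0) next
    # order TSSs; for each center find the flanking TSSs and pick by
    # (|distance|, gene_id)
    ord <- order(g$tss, g$gene_id)
    g <- g[ord, ]
    idx_right <- findInterval(centers[pi], g$tss) + 1L
    for (j in seq_along(pi)) {
      cand <- unique(pmin(pmax(c(idx_right[j] - 1L, idx_right[j],
                                 idx_right[j] + 1L), 1L), nrow(g)))
      d <- abs(g$tss[cand] - centers[pi[j]])
      best <- cand[order(d, g$gene_id[cand])][1]
      signed_d <- if (g$strand[best] == "+") {
        centers[pi[j]] - g$tss[best]
      } else {
        g$tss[best] - centers[pi[j]]
      }
      out$nearest_gene[pi[j]] <- g$gene_id[best]
      out$tss_distance[pi[j]] <- if (signed) as.integer(signed_d) else
        as.integer(abs(signed_d))
    }
  }
  out
}

#' Nearest gene within a distance cutoff
#'
#' Single-nearest-gene assignment: the gene whose TSS is closest to the
#' peak center, provided the distance does not exceed `max_dist`
#' (200 kb by default); peaks farther from every TSS get `NA`.
#'
#' @inheritParams nearest_tss_distance
#' @param max_dist Maximum |distance| in bases.
#' @return The `nearest_tss_distance()` tibble with `nearest_gene` set to
#'   `NA` beyond `max_dist`.
#' @export
nearest_gene_within <- function(peaks, genes, max_dist = 200000L) {
  stopifnot(max_dist > 0)
  out <- nearest_tss_distance(peaks, genes)
  out$nearest_gene[is.na(out$tss_distance) |
                     abs(out$tss_distance) > max_dist] <- NA_character_
  out
}
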