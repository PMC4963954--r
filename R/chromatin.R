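#' Classify enhancers as active or poised
#'
#' Candidate enhancers are H3K4me1 peaks, optionally excluding peaks
#' whose center lies within `proximal_dist` of a TSS (promoter-proximal
#' H3K4me1 mostly reflects promoter chromatin, not enhancers). A
#' candidate is *active* when any H3K27ac peak overlaps it (>= 1 bp by
#' default) and *poised* otherwise. The nearest gene within 200 kb and
#' the signed TSS distance are attached.
#'
#' @param k4me1 H3K4me1 peak tibble.
#' @param k27ac H3K27ac peak tibble (same cell type).
#' @param genes Gene tibble.
#' @param exclude_promoter_proximal Drop TSS-proximal candidates
#'   (default `TRUE`).
#' @param proximal_dist Distance defining "proximal" (default 2000 bp).
#' @param min_overlap_frac Minimum fraction of the H3K4me1 peak that the
#'   H3K27ac overlap must cover (default 0: any overlap).
#' @param max_gene_dist Nearest-gene cutoff (default 200 kb).
#' @return Tibble of enhancer calls: interval columns, `state`
#'   (`"active"`/`"poised"`), `nearest_gene`, `tss_distance`.
#' @export
classify_enhancers <- function(k4me1, k27ac, genes,
                               exclude_promoter_proximal = TRUE,
                               proximal_dist = 2000L,
                               min_overlap_frac = 0,
                               max_gene_dist = 200000L) {
  validate_intervals(k4me1, "H3K4me1")
  validate_intervals(k27ac, "H3K27ac")
  cand <- k4me1
  ann <- nearest_gene_within(cand, genes, max_dist = max_gene_dist)
  if (exclude_promoter_proximal && nrow(cand)) {
    dist_any <- nearest_tss_distance(cand, genes)$tss_distance
    keep <- abs(dist_any) > proximal_dist
    cand <- cand[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), state = character(),
                  nearest_gene = character(), tss_distance = integer()))
  }
  if (min_overlap_frac > 0 && nrow(k27ac)) {
    hits <- overlap_pairs(cand, k27ac)
    ov <- pmin(cand$end[hits$query_idx], k27ac$end[hits$subject_idx]) -
      pmax(cand$start[hits$query_idx], k27ac$start[hits$subject_idx])
    frac <- ov / (cand$end[hits$query_idx] - cand$start[hits$query_idx])
    active <- seq_len(nrow(cand)) %in% hits$query_idx[frac >= min_overlap_frac]
  } else {
    active <- overlaps_any(cand, k27ac)
  }
  tibble(
    chrom = cand$chrom, start = cand$start, end = cand$end,
    name = if ("name" %in% names(cand)) cand$name else
      sprintf("%s:%d-%d", cand$chrom, cand$start, cand$end),
    state = if_else(active, "active", "poised"),
    nearest_gene = ann$nearest_gene,
    tss_distance = ann$tss_distance
  )
}

#' Partition clustered enhancers into per-class peak sets
#'
#' Maps a clustering of the union active-enhancer set back onto genomic
#' intervals, producing one BED-exportable peak set per class (the basis
#' for per-class nearest-gene expression comparison and GO export).
#'
#' @param regions Interval tibble whose `name` column matches the
#'   clustering's region ids.
#' @param clusters A `signal_clusters` object over the same regions.
#' @return Named list of interval tibbles, `class_1` ... `class_k`
#'   (empty tibbles allowed for degenerate classes).
#' @export
enhancer_class_sets <- function(regions, clusters) {
  ids <- if ("name" %in% names(regions)) regions$name else
    sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  m <- match(ids, clusters$assignments$region_id)
  if (anyNA(m)) abort("region ids do not match clustering row ids")
  cls <- clusters$assignments$class[m]
  out <- lapply(seq_len(clusters$k), function(j) {
    regions[cls == j, , drop = FALSE]
  })
  names(out) <- sprintf("class_%d", seq_len(clusters$k))
  out
}

#' Call bivalent promoters
#'
#' A promoter carries a mark when any peak of that mark overlaps the
#' strand-aware promoter window; a gene is *bivalent* when both H3K4me3
#' and H3K27me3 are present.
#'
#' @param k4me3,k27me3 Peak tibbles.
#' @param genes Gene tibble.
#' @return List with `states` (tibble: `gene_id`, `has_k4me3`,
#'   `has_k27me3`, `bivalent`) and `n_bivalent`.
#' @export
call_bivalent_promoters <- function(k4me3, k27me3, genes) {
  prom <- promoter_intervals(genes)
  states <- tibble(
    gene_id = genes$gene_id,
    has_k4me3 = overlaps_any(prom, k4me3),
    has_k27me3 = overlaps_any(prom, k27me3)
  )
  states$bivalent <- states$has_k4me3 & states$has_k27me3
  list(states = states, n_bivalent = sum(states$bivalent))
}

#' Fraction of peaks overlapping promoters
#'
#' @param peaks Non-empty peak tibble.
#' @param genes Gene tibble.
#' @return Fraction in `[0, 1]` of peaks overlapping any promoter.
#' @export
peak_promoter_fraction <- function(peaks, genes) {
  if (nrow(peaks) == 0) abort("peak set is empty; fraction undefined")
  mean(overlaps_any(peaks, promoter_intervals(genes)))
}

#' Histogram of enhancer-to-TSS distances
#'
#' Bins signed TSS distances over the given breaks; distances outside
#' the break range are counted in open-ended flanking bins.
#'
#' @param calls Enhancer-call tibble with a `tss_distance` column.
#' @param breaks Strictly increasing integer breakpoints.
#' @return Tibble with `bin` labels, `lower`, `upper` and `count`; the
#'   counts sum to `nrow(calls)`.
#' @export
tss_distance_histogram <- function(calls, breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    abort("breaks must be strictly increasing")
  }
  lower <- c(-Inf, breaks)
  upper <- c(breaks, Inf)
  counts <- if (nrow(calls) == 0) {
    integer(length(lower))
  } else {
    idx <- findInterval(calls$tss_distance, breaks) + 1L
    tabulate(idx, nbins = length(lower))
  }
  tibble(
    bin = sprintf("[%s, %s)", lower, upper),
    lower = lower, upper = upper, count = as.integer(counts)
  )
}
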