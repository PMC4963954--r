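#' Split promoters into 500-bp windows
#'
#' Each 2500-bp promoter is divided into five consecutive 500-bp windows
#' ordered strand-aware (window 1 most upstream of the TSS), labelled
#' `gene_id:index`. These windows are the unit of the cross-platform
#' methylation comparison.
#'
#' @param genes Gene tibble.
#' @param window_width Window width; must divide the promoter length.
#' @return Interval tibble with `name` = `gene_id:index`, plus `gene_id`
#'   and `window_index` columns.
#' @export
promoter_windows <- function(genes, window_width = 500L) {
  if (!"promoter_start" %in% names(genes)) genes <- gene_promoters(genes)
  prom_len <- genes$promoter_end[1] - genes$promoter_start[1]
  if (nrow(genes) && prom_len %% window_width != 0) {
    abort("window_width must divide the promoter length")
  }
  nw <- if (nrow(genes)) prom_len %/% window_width else 0L
  if (nrow(genes) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), name = character(),
                  gene_id = character(), window_index = integer()))
  }
  idx <- rep(seq_len(nw), times = nrow(genes))
  g <- genes[rep(seq_len(nrow(genes)), each = nw), ]
  start <- if_else(g$strand == "+",
                   g$promoter_start + (idx - 1L) * window_width,
                   g$promoter_end - idx * window_width)
  tibble(
    chrom = g$chrom,
    start = as.integer(start),
    end = as.integer(start + window_width),
    strand = g$strand,
    name = sprintf("%s:%d", g$gene_id, idx),
    gene_id = g$gene_id,
    window_index = as.integer(idx)
  )
}

#' Tile the genome into fixed-width windows
#'
#' Non-overlapping, exhaustive tiling; the last tile of each chromosome
#' is truncated at the chromosome end.
#'
#' @param chrom_lengths Named integer vector.
#' @param width Tile width in bases (default 1000).
#' @return Interval tibble covering the genome.
#' @export
tile_genome <- function(chrom_lengths, width = 1000L) {
  stopifnot(width > 0)
  list_rbind(imap(as.list(chrom_lengths), function(len, ch) {
    starts <- seq.int(0L, len - 1L, by = width)
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(pmin(starts + width, len)), strand = ".")
  }))
}

# Raw read count of a track inside each window (partial bins prorated).
window_track_counts <- function(windows, track) {
  counts <- numeric(nrow(windows))
  scale <- if (track$normalization == "rpkm") {
    (track$bin_width / 1000) * (track$library_size / 1e6)
  } else 1
  for (ch in unique(windows$chrom)) {
    v <- track$signal[[ch]]
    if (is.null(v)) next
    sel <- which(windows$chrom == ch)
    cs <- c(0, cumsum(v))
    bw <- track$bin_width
    for (i in sel) {
      lo <- windows$start[i] / bw
      hi <- windows$end[i] / bw
      lo_f <- floor(lo); hi_c <- ceiling(hi)
      lo_f <- max(lo_f, 0); hi_c <- min(hi_c, length(v))
      if (hi_c <= lo_f) next
      total <- cs[hi_c + 1] - cs[lo_f + 1]
      # prorate partial first/last bins
      if (lo > lo_f && lo_f < length(v)) total <- total - (lo - lo_f) * v[lo_f + 1]
      if (hi < hi_c && hi_c >= 1) total <- total - (hi_c - hi) * v[hi_c]
      counts[i] <- total * scale
    }
  }
  counts
}

count_cpgs_in_windows <- function(windows, cpg_positions) {
  n <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    pos <- sort(cpg_positions$pos[cpg_positions$chrom == ch])
    sel <- which(windows$chrom == ch)
    if (!length(pos) || !length(sel)) next
    n[sel] <- findInterval(windows$end[sel] - 1L, pos) -
      findInterval(windows$start[sel] - 1L, pos)
  }
  n
}

#' Relative methylation score (rms) for capture assays
#'
#' Capture (MethylCap/MeDIP) signal scales with both methylation and
#' local CpG density, so window signal is normalized by CpG count:
#' `rms = window RPKM / cpg_count`. Windows with no CpGs carry no
#' interpretable capture signal and are flagged `no_data`.
#'
#' @param windows Interval tibble.
#' @param capture_track `binned_track` of the capture library.
#' @param cpg_positions Tibble with `chrom`, `pos` of CpG sites.
#' @return Tibble of methylation windows: interval columns, `assay`,
#'   `score` (rms), `coverage` (raw read count), `cpg_count`, `call`.
#' @export
capture_rms <- function(windows, capture_track, cpg_positions) {
  counts <- window_track_counts(windows, capture_track)
  denom <- ((windows$end - windows$start) / 1000) *
    (capture_track$library_size / 1e6)
  rpkm <- ifelse(denom > 0, counts / denom, 0)
  cpg <- count_cpgs_in_windows(windows, cpg_positions)
  out <- windows
  out$assay <- "capture"
  out$score <- ifelse(cpg >= 1, rpkm / cpg, NA_real_)
  out$coverage <- counts
  out$cpg_count <- cpg
  out$call <- ifelse(cpg >= 1, "unscored", "no_data")
  as_tibble(out)
}

#' Absolute methylation signal (ams) for bisulfite assays
#'
#' Pools per-CpG counts within each window:
#' `ams = sum(count_C) / sum(count_C + count_T)`. Windows whose summed
#' coverage falls below `min_coverage` are flagged `no_data`.
#'
#' @param windows Interval tibble.
#' @param sites Bisulfite site tibble (`chrom`, `pos` 0-based,
#'   `count_C`, `count_T`).
#' @param min_coverage Minimum summed coverage (default 10).
#' @param per_site_mean If `TRUE`, average per-site ratios instead of
#'   pooling counts.
#' @return Tibble of methylation windows: `score` (ams in `[0, 1]`),
#'   `coverage`, `cpg_count`, `count_C`, `count_T`, `call`.
#' @export
bisulfite_ams <- function(windows, sites, min_coverage = 10L,
                          per_site_mean = FALSE) {
  sumC <- numeric(nrow(windows))
  sumT <- numeric(nrow(windows))
  nsite <- integer(nrow(windows))
  ratio_sum <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    s <- sites[sites$chrom == ch, ]
    s <- s[order(s$pos), ]
    sel <- which(windows$chrom == ch)
    if (!nrow(s) || !length(sel)) next
    csC <- c(0, cumsum(s$count_C))
    csT <- c(0, cumsum(s$count_T))
    r <- s$count_C / pmax(s$count_C + s$count_T, 1)
    csR <- c(0, cumsum(r))
    lo <- findInterval(windows$start[sel] - 1L, s$pos)
    hi <- findInterval(windows$end[sel] - 1L, s$pos)
    sumC[sel] <- csC[hi + 1] - csC[lo + 1]
    sumT[sel] <- csT[hi + 1] - csT[lo + 1]
    nsite[sel] <- hi - lo
    ratio_sum[sel] <- csR[hi + 1] - csR[lo + 1]
  }
  cov <- sumC + sumT
  out <- windows
  out$assay <- "bisulfite"
  out$score <- if (per_site_mean) {
    ifelse(nsite > 0, ratio_sum / nsite, NA_real_)
  } else {
    ifelse(cov > 0, sumC / cov, NA_real_)
  }
  out$coverage <- cov
  out$cpg_count <- nsite
  out$count_C <- sumC
  out$count_T <- sumT
  out$call <- ifelse(cov >= min_coverage, "unscored", "no_data")
  as_tibble(out)
}

#' One-sided exact binomial tail for a methylation ratio
#'
#' `P(X >= C | n, p0)` for the pooled window counts: the exact binomial
#' test of whether the methylated fraction C/(C+T) exceeds `p0`.
#'
#' @param count_C Successes (methylated reads), vectorized.
#' @param coverage Trials (C + T), vectorized.
#' @param p0 Null ratio in (0, 1).
#' @return Upper-tail p-values; `NA` where coverage is 0.
#' @export
#' @examples
#' binomial_methylation_call(6, 10, 0.25)  # 0.0197...
binomial_methylation_call <- function(count_C, coverage, p0) {
  stopifnot(p0 > 0, p0 < 1)
  ifelse(coverage >= 1,
         pbinom(count_C - 1, coverage, p0, lower.tail = FALSE),
         NA_real_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; invariant to
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Call methylation state of bisulfite windows
#'
#' Two one-sided exact-binomial test families on the pooled window
#' ratio: against `p0 = 0.25` (methylated) and `p0 = 0.75` (highly
#' methylated), each BH-adjusted separately across all covered windows.
#' A window is `highly_methylated` when the 0.75-family q-value is below
#' `alpha`, else `methylated` when the 0.25-family q-value is, else
#' `unmethylated`; `no_data` windows are passed through untested.
#'
#' @param windows Output of [bisulfite_ams()].
#' @param alpha FDR threshold (default 0.01).
#' @param p0_methylated,p0_highly Null ratios (defaults 0.25, 0.75).
#' @return `windows` with `p_methylated`, `q_methylated`, `p_highly`,
#'   `q_highly` and a final `call`.
#' @export
call_bisulfite_regions <- function(windows, alpha = 0.01,
                                   p0_methylated = 0.25,
                                   p0_highly = 0.75) {
  tested <- windows$call != "no_data"
  p1 <- rep(NA_real_, nrow(windows))
  p2 <- rep(NA_real_, nrow(windows))
  p1[tested] <- binomial_methylation_call(windows$count_C[tested],
                                          windows$coverage[tested],
                                          p0_methylated)
  p2[tested] <- binomial_methylation_call(windows$count_C[tested],
                                          windows$coverage[tested],
                                          p0_highly)
  windows$p_methylated <- p1
  windows$q_methylated <- bh_adjust(p1)
  windows$p_highly <- p2
  windows$q_highly <- bh_adjust(p2)
  windows$call <- dplyr::case_when(
    !tested ~ "no_data",
    windows$q_highly < alpha ~ "highly_methylated",
    windows$q_methylated < alpha ~ "methylated",
    TRUE ~ "unmethylated"
  )
  windows
}

#' Call highly methylated regions from a capture track
#'
#' Per window, compares the capture library against the matched input
#' library with a one-sided exact binomial split test: under no
#' enrichment, capture reads in a window follow
#' `Binomial(capture + input, capture_library_share)`. Fold change is
#' computed on pseudocounted RPKM. A window is `highly_methylated` when
#' the BH-adjusted p-value is below `alpha` *and* fold change exceeds
#' `min_fold`; otherwise `unmethylated`.
#'
#' @param windows Interval tibble (typically 1-kb genome tiles or
#'   promoter windows).
#' @param capture_track,input_track `binned_track`s on the same bin grid.
#' @param alpha FDR threshold (default 0.01).
#' @param min_fold Fold-change threshold (default 2).
#' @param pseudocount Count added to both libraries before the fold
#'   ratio (default 1).
#' @return Methylation-window tibble with `score` (capture RPKM),
#'   `fold_change`, `p_value`, `q_value`, `call`.
#' @export
call_capture_hmrs <- function(windows, capture_track, input_track,
                              alpha = 0.01, min_fold = 2.0,
                              pseudocount = 1) {
  if (is.null(input_track)) abort("input track is required for HMR calling")
  if (capture_track$bin_width != input_track$bin_width) {
    abort("capture and input tracks must share a bin grid")
  }
  cap <- round(window_track_counts(windows, capture_track))
  inp <- round(window_track_counts(windows, input_track))
  lib_c <- capture_track$library_size
  lib_i <- input_track$library_size
  share <- lib_c / (lib_c + lib_i)
  n <- cap + inp
  p <- ifelse(n > 0,
              pbinom(cap - 1, n, share, lower.tail = FALSE),
              1)
  fold <- ((cap + pseudocount) / (inp + pseudocount)) * (lib_i / lib_c)
  width_kb <- (windows$end - windows$start) / 1000
  out <- windows
  out$assay <- "capture"
  out$score <- cap / (width_kb * lib_c / 1e6)
  out$coverage <- cap
  out$fold_change <- fold
  out$p_value <- p
  out$q_value <- bh_adjust(p)
  out$call <- if_else(out$q_value < alpha & fold > min_fold,
                      "highly_methylated", "unmethylated")
  as_tibble(out)
}

#' Pearson correlation of methylation across platforms
#'
#' Correlates capture and bisulfite window scores over promoter windows
#' where both assays have data; `no_data` pairs are dropped and the
#' paired-window count reported.
#'
#' @param capture_windows,bisulfite_windows Methylation-window tibbles
#'   over the same windows (matched by `name`).
#' @param covered_only If `TRUE` (default), drop `no_data` pairs; if
#'   `FALSE`, only pairs with `NA` scores are dropped.
#' @return List with `r` and `n_windows`.
#' @export
cross_platform_correlation <- function(capture_windows, bisulfite_windows,
                                       covered_only = TRUE) {
  m <- inner_join(
    select(capture_windows, "name", cap_score = "score", cap_call = "call"),
    select(bisulfite_windows, "name", bs_score = "score", bs_call = "call"),
    by = "name"
  )
  if (covered_only) {
    m <- filter(m, .data$cap_call != "no_data", .data$bs_call != "no_data")
  }
  m <- filter(m, !is.na(.data$cap_score), !is.na(.data$bs_score))
  if (nrow(m) < 3) abort("fewer than 3 paired windows with data")
  if (stats::sd(m$cap_score) == 0 || stats::sd(m$bs_score) == 0) {
    abort("correlation undefined: a score vector is constant")
  }
  list(r = cor(m$cap_score, m$bs_score, method = "pearson"),
       n_windows = nrow(m))
}

#' Collapse window calls to a per-gene promoter call
#'
#' A gene's promoter is considered methylated when any of its windows is
#' called methylated or higher.
#'
#' @param windows Methylation-window tibble carrying `gene_id` and
#'   `call`.
#' @return Tibble `gene_id`, `methylated` (logical), `n_windows_called`.
#' @export
gene_level_call <- function(windows) {
  windows |>
    group_by(.data$gene_id) |>
    summarise(
      methylated = any(.data$call %in% c("methylated", "highly_methylated")),
      n_windows_called = sum(.data$call %in%
                               c("methylated", "highly_methylated")),
      .groups = "drop"
    )
}

#' Compare per-gene promoter methylation between two samples
#'
#' Partitions genes methylated in either sample into `a_specific`,
#' `b_specific` and `shared`.
#'
#' @param calls_a,calls_b Per-gene call tibbles from [gene_level_call()]
#'   over the same gene universe.
#' @return List with `genes` (tibble `gene_id`, `category`) and `counts`.
#' @export
compare_promoter_calls <- function(calls_a, calls_b) {
  m <- inner_join(select(calls_a, "gene_id", a = "methylated"),
                  select(calls_b, "gene_id", b = "methylated"),
                  by = "gene_id")
  if (nrow(m) != nrow(calls_a) || nrow(m) != nrow(calls_b)) {
    abort("call tables must share the same gene universe")
  }
  genes <- m |>
    filter(.data$a | .data$b) |>
    mutate(category = dplyr::case_when(
      .data$a & .data$b ~ "shared",
      .data$a ~ "a_specific",
      TRUE ~ "b_specific"
    )) |>
    select("gene_id", "category")
  counts <- c(
    a_specific = sum(genes$category == "a_specific"),
    b_specific = sum(genes$category == "b_specific"),
    shared = sum(genes$category == "shared")
  )
  list(genes = genes, counts = counts)
}

#' Categorize genes by promoter/body methylation
#'
#' Three-way partition: `promoter_methylated` (promoter called,
#' regardless of body), `body_only`, `hypomethylated`. Also reports the
#' fraction of promoter-methylated genes whose body is methylated.
#'
#' @param promoter_calls,body_calls Per-gene call tibbles
#'   ([gene_level_call()]) over the same genes.
#' @return List with `genes` (tibble `gene_id`, `category`) and
#'   `fraction_promoter_with_body`.
#' @export
categorize_genes_by_methylation <- function(promoter_calls, body_calls) {
  m <- inner_join(select(promoter_calls, "gene_id", prom = "methylated"),
                  select(body_calls, "gene_id", body = "methylated"),
                  by = "gene_id")
  genes <- mutate(m, category = dplyr::case_when(
    .data$prom ~ "promoter_methylated",
    .data$body ~ "body_only",
    TRUE ~ "hypomethylated"
  ))
  frac <- if (any(m$prom)) mean(m$body[m$prom]) else NA_real_
  list(genes = select(genes, "gene_id", "category"),
       fraction_promoter_with_body = frac)
}

#' Methylation frequency of annotation families
#'
#' For each annotation family (e.g. the TE families LINE L1, LTR ERV1,
#' IAP, DNA, SINE B1, SINE B2), the fraction of loci overlapping at
#' least one methylated-or-higher window, optionally restricted to loci
#' overlapping a CpG island.
#'
#' @param annotations Interval tibble with a `name` column carrying the
#'   family label.
#' @param calls Methylation-window tibble with a `call` column.
#' @param require_cpg_island_overlap Restrict the locus denominator to
#'   CpG-island-overlapping loci.
#' @param cpg_islands Interval tibble (required when restricting).
#' @return Tibble `family`, `n_loci`, `n_methylated`, `frequency`
#'   (`NA` for families with no qualifying loci).
#' @export
annotation_methylation_frequency <- function(annotations, calls,
                                             require_cpg_island_overlap = FALSE,
                                             cpg_islands = NULL) {
  ann <- annotations
  if (require_cpg_island_overlap) {
    if (is.null(cpg_islands)) abort("cpg_islands required for restriction")
    ann <- ann[overlaps_any(ann, cpg_islands), , drop = FALSE]
  }
  called <- calls[calls$call %in% c("methylated", "highly_methylated"), ,
                  drop = FALSE]
  hit <- overlaps_any(ann, called)
  fams <- sort(unique(annotations$name))
  list_rbind(map(fams, function(f) {
    sel <- ann$name == f
    tibble(family = f,
           n_loci = sum(sel),
           n_methylated = sum(hit[sel]),
           frequency = if (sum(sel) > 0) mean(hit[sel]) else NA_real_)
  }))
}
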