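#' Simulation configuration
#'
#' Parameters of the synthetic multi-assay, multi-cell-type study: one
#' synthetic chromosome carrying genes, enhancers of four planted
#' classes (shared / FGSC-specific / ESC-specific / weak), CpG islands,
#' six transposable-element families and imprinted-like DMRs; ChIP-seq
#' tracks with negative-binomial read noise; a capture methylation assay
#' with matched input for FGSCs and a per-CpG bisulfite assay for
#' MGSCs; expression coupled to promoter methylation and enhancers.
#'
#' @param seed Integer master seed; every assay derives its own stream.
#' @param genome_length Length of the synthetic chromosome (default
#'   1e7).
#' @param n_genes Number of genes (default 500).
#' @param bin_width Track bin width in bases (default 50).
#' @param n_enhancers_per_class Enhancers per planted class (default
#'   100).
#' @param peak_width_mean Mean enhancer peak width (default 1000).
#' @param signal_depth Expected reads per sequencing library (default
#'   1e6).
#' @param noise_dispersion Negative-binomial dispersion of read counts
#'   (variance = mu + dispersion * mu^2; default 0.05).
#' @param methyl_beta_params Beta-binomial mean methylation at
#'   methylated and unmethylated CpGs (defaults 0.8 and 0.05).
#' @param bs_concentration Beta concentration (a + b) of per-CpG
#'   methylation (default 10).
#' @param fraction_promoter_methylated Fraction of promoters methylated
#'   in FGSCs (default 0.3).
#' @param bisulfite_depth_mean Mean per-CpG bisulfite coverage
#'   (default 30).
#' @param cpg_island_fraction Fraction of promoters carrying a CpG
#'   island (default 0.6).
#' @param enhancer_enrichment In-peak over background read density for
#'   ChIP tracks (default 20).
#' @param capture_cpg_weight Capture read density contributed per
#'   methylated CpG, relative to background (default 1.5).
#' @param fraction_bivalent Named fractions of bivalent genes per cell
#'   type (default FGSC 0.10, ESC 0.25: bivalency is less prevalent in
#'   germline stem cells).
#' @param expression_ratio Median FPKM ratio of unmethylated over
#'   promoter-methylated genes (default 4).
#' @param n_knockdown_responsive Genes up-regulated >= 2-fold in the
#'   knockdown condition (default 50).
#' @param n_te_per_family Loci per TE family (default 40).
#' @param n_dmrs Imprinted-like DMRs (default 10).
#' @param background_methylation Per-CpG probability of methylation
#'   outside planted regions (default 0.3).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e7,
                       n_genes = 500L,
                       bin_width = 50L,
                       n_enhancers_per_class = 100L,
                       peak_width_mean = 1000L,
                       signal_depth = 1e6,
                       noise_dispersion = 0.05,
                       methyl_beta_params = c(methylated = 0.8,
                                              unmethylated = 0.05),
                       bs_concentration = 10,
                       fraction_promoter_methylated = 0.3,
                       bisulfite_depth_mean = 30,
                       cpg_island_fraction = 0.6,
                       enhancer_enrichment = 20,
                       capture_cpg_weight = 1.5,
                       fraction_bivalent = c(FGSC = 0.10, ESC = 0.25),
                       expression_ratio = 4,
                       n_knockdown_responsive = 50L,
                       n_te_per_family = 40L,
                       n_dmrs = 10L,
                       background_methylation = 0.3) {
  cfg <- list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes), bin_width = as.integer(bin_width),
    n_enhancers_per_class = as.integer(n_enhancers_per_class),
    peak_width_mean = as.integer(peak_width_mean),
    signal_depth = signal_depth, noise_dispersion = noise_dispersion,
    methyl_beta_params = methyl_beta_params,
    bs_concentration = bs_concentration,
    fraction_promoter_methylated = fraction_promoter_methylated,
    bisulfite_depth_mean = bisulfite_depth_mean,
    cpg_island_fraction = cpg_island_fraction,
    enhancer_enrichment = enhancer_enrichment,
    capture_cpg_weight = capture_cpg_weight,
    fraction_bivalent = fraction_bivalent,
    expression_ratio = expression_ratio,
    n_knockdown_responsive = as.integer(n_knockdown_responsive),
    n_te_per_family = as.integer(n_te_per_family),
    n_dmrs = as.integer(n_dmrs),
    background_methylation = background_methylation
  )
  stopifnot(cfg$genome_length > 0, cfg$n_genes >= 0, cfg$bin_width > 0,
            cfg$noise_dispersion > 0,
            cfg$fraction_promoter_methylated >= 0,
            cfg$fraction_promoter_methylated <= 1,
            all(cfg$fraction_bivalent >= 0 & cfg$fraction_bivalent <= 1),
            cfg$cpg_island_fraction >= 0, cfg$cpg_island_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

TE_FAMILIES <- c("LINE_L1", "LTR_ERV1", "IAP", "DNA", "SINE_B1", "SINE_B2")
SIM_CHROM <- "chrS"

# minimum slot size for a gene: 2500-bp body plus 2200-bp margins so
# promoters of neighbouring genes can never collide
MIN_GENE_SLOT <- 2500 + 2 * 2200

#' Generate the synthetic genome and ground truth
#'
#' Lays out genes, enhancers, TE loci and DMRs on disjoint slots of one
#' synthetic chromosome, places CpG sites (dense in islands, promoters,
#' methylated gene bodies, TEs and DMRs; sparse elsewhere) and draws
#' the planted truth: enhancer classes, bivalent genes per cell type,
#' promoter/body methylation per cell type, sex-specific region labels
#' and TE/DMR methylation states. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list: `genes`, `cpg_positions`, `annotations` (list of
#'   `cpg_islands`, `transposons`, `dmrs`), `truth` (tibbles
#'   `enhancers`, `bivalent`, `promoter_methyl`, `body_methyl`,
#'   `te_methyl`, `dmr_methyl`, `sex_specific`, `cpg_methyl`),
#'   `chrom_lengths`.
#' @export
simulate_genome <- function(config = sim_config()) {
  L <- config$genome_length
  n_enh <- 4L * config$n_enhancers_per_class
  n_te <- 6L * config$n_te_per_family
  n_feat <- config$n_genes + n_enh + n_te + config$n_dmrs
  if (n_feat == 0) {
    return(empty_genome(config))
  }
  slot <- floor(L / n_feat)
  if (config$n_genes > 0 && slot < MIN_GENE_SLOT) {
    abort(sprintf(
      "genome too small: %d features need slots of %d bp, have %d",
      n_feat, MIN_GENE_SLOT, slot))
  }
  if (slot < 3000) {
    abort("genome too small for the requested feature count")
  }

  with_local_seed(derive_seed(config$seed, 1L), {
    types <- sample(c(
      rep("gene", config$n_genes),
      rep("enhancer", n_enh),
      rep("te", n_te),
      rep("dmr", config$n_dmrs)
    ))
    slot_start <- (seq_len(n_feat) - 1L) * slot

    # --- genes ---
    gi <- which(types == "gene")
    genes <- if (length(gi)) {
      body_len <- round(runif(length(gi), 2500, slot - 4400))
      margin <- floor((slot - body_len) / 2)
      strand <- sample(c("+", "-"), length(gi), replace = TRUE)
      body_start <- as.integer(slot_start[gi] + margin)
      body_end <- as.integer(body_start + body_len)
      gene_promoters(tibble(
        gene_id = sprintf("gene_%04d", seq_along(gi)),
        chrom = SIM_CHROM,
        strand = strand,
        tss = as.integer(ifelse(strand == "+", body_start, body_end - 1L)),
        body_start = body_start,
        body_end = body_end
      ))
    } else {
      gene_promoters(tibble(gene_id = character(), chrom = character(),
                            strand = character(), tss = integer(),
                            body_start = integer(), body_end = integer())[0, ])
    }

    # --- enhancers ---
    ei <- which(types == "enhancer")
    enh_class <- sample(rep(c("shared", "fgsc_specific", "esc_specific",
                              "weak"), config$n_enhancers_per_class))
    enh_w <- pmax(300, pmin(round(rnorm(length(ei), config$peak_width_mean,
                                        config$peak_width_mean / 5)),
                            slot - 2000))
    enh_center <- slot_start[ei] + slot %/% 2L
    enhancers <- tibble(
      chrom = SIM_CHROM,
      start = as.integer(enh_center - enh_w %/% 2L),
      end = as.integer(enh_center + (enh_w - enh_w %/% 2L)),
      strand = ".",
      name = sprintf("enh_%04d", seq_along(ei)),
      class = enh_class
    )

    # --- TE loci ---
    ti <- which(types == "te")
    te_fam <- sample(rep(TE_FAMILIES, config$n_te_per_family))
    te_w <- round(runif(length(ti), 500, 2000))
    te_center <- slot_start[ti] + slot %/% 2L
    transposons <- tibble(
      chrom = SIM_CHROM,
      start = as.integer(te_center - te_w %/% 2L),
      end = as.integer(te_center + (te_w - te_w %/% 2L)),
      strand = ".",
      name = te_fam,
      locus_id = sprintf("te_%04d", seq_along(ti))
    )
    te_has_island <- seq_len(nrow(transposons)) %% 2L == 1L

    # --- DMRs ---
    di <- which(types == "dmr")
    dmrs <- tibble(
      chrom = SIM_CHROM,
      start = as.integer(slot_start[di] + slot %/% 2L - 500L),
      end = as.integer(slot_start[di] + slot %/% 2L + 500L),
      strand = ".",
      name = sprintf("dmr_%02d", seq_along(di))
    )

    # --- CpG islands: a fraction of promoters, plus half the TE loci ---
    island_genes <- genes$gene_id[
      runif(nrow(genes)) < config$cpg_island_fraction]
    prom_islands <- genes |>
      filter(.data$gene_id %in% island_genes) |>
      mutate(start = pmax(.data$tss - 300L, 0L), end = .data$tss + 300L) |>
      select("chrom", "start", "end") |>
      mutate(strand = ".", name = "cgi_promoter")
    te_islands <- transposons[te_has_island, ] |>
      mutate(mid = (.data$start + .data$end) %/% 2L,
             start = .data$mid - 200L, end = .data$mid + 200L) |>
      select("chrom", "start", "end") |>
      mutate(strand = ".", name = "cgi_te")
    cpg_islands <- arrange(bind_rows(prom_islands, te_islands),
                           .data$start)

    # --- planted methylation truth ---
    meth_fgsc <- runif(nrow(genes)) < config$fraction_promoter_methylated
    # among FGSC-methylated promoters half are shared with MGSCs; a
    # further share of FGSC-unmethylated promoters is MGSC-only
    meth_mgsc <- rep(FALSE, nrow(genes))
    meth_mgsc[meth_fgsc] <- runif(sum(meth_fgsc)) < 0.5
    meth_mgsc[!meth_fgsc] <- runif(sum(!meth_fgsc)) < 0.15
    body_fgsc <- rep(FALSE, nrow(genes))
    body_fgsc[meth_fgsc] <- runif(sum(meth_fgsc)) < 0.9
    body_fgsc[!meth_fgsc] <- runif(sum(!meth_fgsc)) < 0.1
    body_mgsc <- rep(FALSE, nrow(genes))
    body_mgsc[meth_mgsc] <- runif(sum(meth_mgsc)) < 0.9
    body_mgsc[!meth_mgsc] <- runif(sum(!meth_mgsc)) < 0.1

    promoter_methyl <- bind_rows(
      tibble(gene_id = genes$gene_id, cell_type = "FGSC",
             state = if_else(meth_fgsc, "methylated", "unmethylated")),
      tibble(gene_id = genes$gene_id, cell_type = "MGSC",
             state = if_else(meth_mgsc, "methylated", "unmethylated"))
    )
    body_methyl <- bind_rows(
      tibble(gene_id = genes$gene_id, cell_type = "FGSC",
             state = if_else(body_fgsc, "methylated", "unmethylated")),
      tibble(gene_id = genes$gene_id, cell_type = "MGSC",
             state = if_else(body_mgsc, "methylated", "unmethylated"))
    )
    sex_specific <- tibble(
      gene_id = genes$gene_id,
      label = dplyr::case_when(
        meth_fgsc & !meth_mgsc ~ "female_only",
        !meth_fgsc & meth_mgsc ~ "male_only",
        meth_fgsc & meth_mgsc ~ "both",
        TRUE ~ "neither"
      )
    )

    # --- bivalent genes per cell type ---
    bivalent <- list_rbind(imap(
      as.list(config$fraction_bivalent),
      function(frac, ct) {
        tibble(gene_id = genes$gene_id[runif(nrow(genes)) < frac],
               cell_type = ct)
      }))

    # --- TE methylation frequencies: opposite family biases by sex ---
    fam_freq <- tibble(
      family = TE_FAMILIES,
      FGSC = c(0.3, 0.3, 0.3, 0.8, 0.8, 0.8),
      MGSC = c(0.8, 0.8, 0.8, 0.3, 0.3, 0.3)
    )
    te_methyl <- transposons |>
      left_join(fam_freq, by = c(name = "family")) |>
      mutate(
        methylated_fgsc = runif(n()) < .data$FGSC,
        methylated_mgsc = runif(n()) < .data$MGSC
      ) |>
      select("locus_id", family = "name", "methylated_fgsc",
             "methylated_mgsc") |>
      mutate(has_island = te_has_island)

    # --- DMR states: alternating parental origin ---
    dmr_methyl <- dmrs |>
      mutate(label = if_else(row_number() %% 2L == 1L,
                             "female_only", "male_only"),
             methylated_fgsc = .data$label == "female_only",
             methylated_mgsc = .data$label == "male_only") |>
      select("name", "label", "methylated_fgsc", "methylated_mgsc")

    # --- CpG sites ---
    cpg <- cpg_positions_for(L, genes, cpg_islands, transposons, dmrs,
                             body_fgsc | body_mgsc)

    # --- per-CpG methylation state per cell type ---
    cpg_state <- plant_cpg_states(cpg, config, genes, meth_fgsc, meth_mgsc,
                                  body_fgsc, body_mgsc, transposons,
                                  te_methyl, dmrs, dmr_methyl)

    list(
      genes = genes,
      cpg_positions = cpg,
      annotations = list(
        cpg_islands = cpg_islands,
        transposons = select(transposons, "chrom", "start", "end",
                             "strand", "name", "locus_id"),
        dmrs = dmrs
      ),
      truth = list(
        enhancers = enhancers,
        bivalent = bivalent,
        promoter_methyl = promoter_methyl,
        body_methyl = body_methyl,
        te_methyl = te_methyl,
        dmr_methyl = dmr_methyl,
        sex_specific = sex_specific,
        cpg_methyl = cpg_state
      ),
      chrom_lengths = setNames(as.integer(L), SIM_CHROM),
      config = config
    )
  })
}

empty_genome <- function(config) {
  list(
    genes = gene_promoters(tibble(gene_id = character(),
                                  chrom = character(), strand = character(),
                                  tss = integer(), body_start = integer(),
                                  body_end = integer())[0, ]),
    cpg_positions = tibble(chrom = character(), pos = integer()),
    annotations = list(
      cpg_islands = tibble(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           name = character()),
      transposons = tibble(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           name = character(), locus_id = character()),
      dmrs = tibble(chrom = character(), start = integer(),
                    end = integer(), strand = character(),
                    name = character())
    ),
    truth = list(
      enhancers = tibble(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         name = character(), class = character()),
      bivalent = tibble(gene_id = character(), cell_type = character()),
      promoter_methyl = tibble(gene_id = character(),
                               cell_type = character(),
                               state = character()),
      body_methyl = tibble(gene_id = character(), cell_type = character(),
                           state = character()),
      te_methyl = tibble(), dmr_methyl = tibble(),
      sex_specific = tibble(gene_id = character(), label = character()),
      cpg_methyl = tibble(chrom = character(), pos = integer(),
                          methylated_fgsc = logical(),
                          methylated_mgsc = logical())
    ),
    chrom_lengths = setNames(as.integer(config$genome_length), SIM_CHROM),
    config = config
  )
}

# CpG positions: sparse background plus dense placement in islands,
# promoters, methylated gene bodies, TE loci and DMRs. Density is
# deliberately co-located with plantable regions so that every scored
# window carries CpG-borne signal.
cpg_positions_for <- function(L, genes, cpg_islands, transposons, dmrs,
                              dense_body) {
  bg <- sort(sample.int(L, floor(L / 150))) - 1L
  seq_in <- function(s, e, by) {
    unlist(Map(function(a, b) seq.int(a, b - 1L, by = by), s, e),
           use.names = FALSE)
  }
  pos <- c(
    bg,
    if (nrow(genes)) seq_in(pmax(genes$promoter_start, 0L),
                            genes$promoter_end, 25L),
    if (nrow(cpg_islands)) seq_in(cpg_islands$start, cpg_islands$end, 10L),
    if (any(dense_body)) seq_in(genes$body_start[dense_body],
                                genes$body_end[dense_body], 40L),
    if (nrow(transposons)) seq_in(transposons$start, transposons$end, 50L),
    if (nrow(dmrs)) seq_in(dmrs$start, dmrs$end, 20L)
  )
  pos <- sort(unique(pos[pos >= 0 & pos < L]))
  tibble(chrom = SIM_CHROM, pos = as.integer(pos))
}

plant_cpg_states <- function(cpg, config, genes, meth_fgsc, meth_mgsc,
                             body_fgsc, body_mgsc, transposons, te_methyl,
                             dmrs, dmr_methyl) {
  n <- nrow(cpg)
  f <- runif(n) < config$background_methylation
  m <- runif(n) < config$background_methylation
  set_state <- function(v, regions, value) {
    if (nrow(regions) == 0) return(v)
    hits <- overlap_pairs(tibble(chrom = cpg$chrom, start = cpg$pos,
                                 end = cpg$pos + 1L), regions)
    v[hits$query_idx] <- value[hits$subject_idx]
    v
  }
  prom <- promoter_intervals(genes)
  body <- tibble(chrom = genes$chrom, start = genes$body_start,
                 end = genes$body_end)
  f <- set_state(f, prom, meth_fgsc)
  m <- set_state(m, prom, meth_mgsc)
  # bodies override background but not promoter windows, which come last
  f <- set_state(f, body, body_fgsc)
  m <- set_state(m, body, body_mgsc)
  f <- set_state(f, prom, meth_fgsc)
  m <- set_state(m, prom, meth_mgsc)
  f <- set_state(f, transposons, te_methyl$methylated_fgsc)
  m <- set_state(m, transposons, te_methyl$methylated_mgsc)
  f <- set_state(f, dmrs, dmr_methyl$methylated_fgsc)
  m <- set_state(m, dmrs, dmr_methyl$methylated_mgsc)
  tibble(chrom = cpg$chrom, pos = cpg$pos,
         methylated_fgsc = f, methylated_mgsc = m)
}

#' Simulate one ChIP-seq assay
#'
#' Plants peaks according to the ground truth (enhancer classes for
#' H3K4me1/H3K27ac, promoters for H3K4me3, bivalent promoters and
#' decoy intergenic domains for H3K27me3) and draws a binned read-count
#' track with negative-binomial noise, elevated
#' `enhancer_enrichment`-fold inside peaks, then RPKM-normalizes it.
#'
#' @param genome Output of [simulate_genome()].
#' @param mark One of `"H3K4me1"`, `"H3K27ac"`, `"H3K4me3"`,
#'   `"H3K27me3"`.
#' @param cell_type `"FGSC"` or `"ESC"`.
#' @return List with `peaks` (interval tibble) and `track`
#'   (`binned_track`, RPKM).
#' @export
simulate_chip_assay <- function(genome, mark, cell_type) {
  config <- genome$config
  if (!mark %in% c("H3K4me1", "H3K27ac", "H3K4me3", "H3K27me3")) {
    abort(sprintf("unknown mark '%s'", mark))
  }
  if (!cell_type %in% c("FGSC", "ESC")) {
    abort(sprintf("unknown cell type '%s' for ChIP assays", cell_type))
  }
  enh <- genome$truth$enhancers
  genes <- genome$genes
  biv <- genome$truth$bivalent$gene_id[
    genome$truth$bivalent$cell_type == cell_type]
  offset <- 100L + match(mark, c("H3K4me1", "H3K27ac", "H3K4me3",
                                 "H3K27me3")) * 10L +
    match(cell_type, c("FGSC", "ESC"))

  with_local_seed(derive_seed(config$seed, offset), {
    peaks <- switch(
      mark,
      H3K4me1 = {
        keep <- switch(cell_type,
                       FGSC = c("shared", "fgsc_specific", "weak"),
                       ESC = c("shared", "esc_specific", "weak"))
        enh[enh$class %in% keep, c("chrom", "start", "end", "strand",
                                   "name")]
      },
      H3K27ac = {
        keep <- switch(cell_type,
                       FGSC = c("shared", "fgsc_specific"),
                       ESC = c("shared", "esc_specific"))
        e <- enh[enh$class %in% keep, ]
        # K27ac peaks sit inside the K4me1 domain, slightly narrower
        tibble(chrom = e$chrom,
               start = as.integer(e$start + (e$end - e$start) %/% 10L),
               end = as.integer(e$end - (e$end - e$start) %/% 10L),
               strand = ".", name = paste0(e$name, "_ac"))
      },
      H3K4me3 = {
        # promoters of ~90 % of genes (always including bivalent ones)
        # plus a handful of distal sites inside TE slots
        n <- nrow(genes)
        non_biv <- setdiff(genes$gene_id, biv)
        drop <- sample(non_biv, min(length(non_biv), round(0.1 * n)))
        g <- genes[!genes$gene_id %in% drop, ]
        prom_peaks <- tibble(chrom = g$chrom,
                             start = pmax(g$tss - 500L, 0L),
                             end = g$tss + 500L,
                             strand = ".",
                             name = paste0(g$gene_id, "_k4me3"))
        te <- genome$annotations$transposons
        n_distal <- min(nrow(te), round(nrow(prom_peaks) / 9))
        distal <- if (n_distal > 0) {
          idx <- sample.int(nrow(te), n_distal)
          mid <- (te$start[idx] + te$end[idx]) %/% 2L
          tibble(chrom = te$chrom[idx], start = mid - 500L,
                 end = mid + 500L, strand = ".",
                 name = sprintf("distal_k4me3_%03d", seq_len(n_distal)))
        } else NULL
        bind_rows(prom_peaks, distal)
      },
      H3K27me3 = {
        g <- genes[genes$gene_id %in% biv, ]
        prom_peaks <- tibble(chrom = g$chrom,
                             start = pmax(g$promoter_start, 0L),
                             end = g$promoter_end,
                             strand = ".",
                             name = paste0(g$gene_id, "_k27me3"))
        # broad decoy domains over weak-enhancer slots (never promoters)
        weak <- enh[enh$class == "weak", ]
        n_decoy <- min(nrow(weak), 30L)
        decoy <- if (n_decoy > 0) {
          idx <- sample.int(nrow(weak), n_decoy)
          tibble(chrom = weak$chrom[idx],
                 start = weak$start[idx] - 500L,
                 end = weak$end[idx] + 500L, strand = ".",
                 name = sprintf("domain_k27me3_%03d", seq_len(n_decoy)))
        } else NULL
        bind_rows(prom_peaks, decoy)
      }
    )
    peaks <- arrange(peaks, .data$chrom, .data$start, .data$end)
    track <- nb_track_for_peaks(peaks, config, genome$chrom_lengths)
    list(peaks = peaks, track = track)
  })
}

nb_track_for_peaks <- function(peaks, config, chrom_lengths) {
  bw <- config$bin_width
  counts <- lapply(names(chrom_lengths), function(ch) {
    nbin <- ceiling(chrom_lengths[[ch]] / bw)
    w <- rep(1, nbin)
    p <- peaks[peaks$chrom == ch, ]
    if (nrow(p)) {
      for (i in seq_len(nrow(p))) {
        lo <- p$start[i] %/% bw + 1L
        hi <- min((p$end[i] - 1L) %/% bw + 1L, nbin)
        w[lo:hi] <- config$enhancer_enrichment
      }
    }
    mu <- config$signal_depth * w / sum(w)
    as.numeric(rnbinom(nbin, mu = mu, size = 1 / config$noise_dispersion))
  })
  names(counts) <- names(chrom_lengths)
  track_from_counts(counts, bw, chrom_lengths)
}

#' Simulate the methylation assays
#'
#' FGSCs are assayed by capture sequencing: per-bin read counts
#' proportional to the number of methylated CpGs in the bin (weight
#' `capture_cpg_weight` each) over a uniform background, with
#' negative-binomial noise and a matched uniform input library. MGSCs
#' are assayed by bisulfite sequencing: per-CpG coverage is
#' Poisson(`bisulfite_depth_mean`) and methylated read counts are
#' beta-binomial around 0.8 (methylated) or 0.05 (unmethylated).
#'
#' @param genome Output of [simulate_genome()].
#' @return List with `capture_track`, `input_track` (both
#'   `binned_track`, RPKM) and `bisulfite` (site tibble with `chrom`,
#'   `pos`, `strand`, `count_C`, `count_T`).
#' @export
simulate_methylation_assays <- function(genome) {
  config <- genome$config
  cpg <- genome$truth$cpg_methyl
  bw <- config$bin_width
  chrom_lengths <- genome$chrom_lengths

  capture <- with_local_seed(derive_seed(config$seed, 201L), {
    counts <- lapply(names(chrom_lengths), function(ch) {
      nbin <- ceiling(chrom_lengths[[ch]] / bw)
      mcpg <- tabulate(cpg$pos[cpg$chrom == ch & cpg$methylated_fgsc] %/%
                         bw + 1L, nbins = nbin)
      w <- 0.3 + config$capture_cpg_weight * mcpg
      mu <- config$signal_depth * w / sum(w)
      as.numeric(rnbinom(nbin, mu = mu,
                         size = 1 / config$noise_dispersion))
    })
    names(counts) <- names(chrom_lengths)
    track_from_counts(counts, bw, chrom_lengths)
  })

  input <- with_local_seed(derive_seed(config$seed, 202L), {
    counts <- lapply(names(chrom_lengths), function(ch) {
      nbin <- ceiling(chrom_lengths[[ch]] / bw)
      mu <- rep(config$signal_depth / nbin, nbin)
      as.numeric(rnbinom(nbin, mu = mu,
                         size = 1 / config$noise_dispersion))
    })
    names(counts) <- names(chrom_lengths)
    track_from_counts(counts, bw, chrom_lengths)
  })

  bisulfite <- with_local_seed(derive_seed(config$seed, 203L), {
    n <- nrow(cpg)
    depth <- rpois(n, config$bisulfite_depth_mean)
    mean_m <- ifelse(cpg$methylated_mgsc,
                     config$methyl_beta_params[["methylated"]],
                     config$methyl_beta_params[["unmethylated"]])
    conc <- config$bs_concentration
    m <- rbeta(n, mean_m * conc, (1 - mean_m) * conc)
    cC <- rbinom(n, depth, m)
    tibble(chrom = cpg$chrom, pos = cpg$pos, strand = "+",
           count_C = as.integer(cC),
           count_T = as.integer(depth - cC))
  })

  list(capture_track = capture, input_track = input, bisulfite = bisulfite)
}

#' Simulate expression coupled to the planted epigenome
#'
#' FPKM is log-normal; genes with an FGSC-methylated promoter are
#' `expression_ratio`-fold lower in FGSCs, genes nearest to an
#' FGSC-specific active enhancer are elevated in FGSCs, and a planted
#' set of knockdown-responsive genes rises >= 2-fold in the knockdown
#' condition. Raw counts are Poisson draws proportional to FPKM.
#'
#' @param genome Output of [simulate_genome()].
#' @param count_depth_factor Expected counts per FPKM unit (default 5).
#' @return List with `expression` (tibble: `gene_id`, `fpkm_FGSC`,
#'   `fpkm_ESC`, `fpkm_knockdown`, `counts_control`,
#'   `counts_knockdown`) and `truth` (tibble of planted effects:
#'   `enhancer_target`, `knockdown_responsive`).
#' @export
simulate_expression <- function(genome, count_depth_factor = 5) {
  config <- genome$config
  genes <- genome$genes
  if (nrow(genes) == 0) {
    return(list(expression = tibble(gene_id = character(),
                                    fpkm_FGSC = numeric(),
                                    fpkm_ESC = numeric(),
                                    fpkm_knockdown = numeric(),
                                    counts_control = integer(),
                                    counts_knockdown = integer()),
                truth = tibble(gene_id = character(),
                               enhancer_target = logical(),
                               knockdown_responsive = logical())))
  }
  enh <- genome$truth$enhancers
  meth <- genome$truth$promoter_methyl
  meth_fgsc <- genes$gene_id %in%
    meth$gene_id[meth$cell_type == "FGSC" & meth$state == "methylated"]

  fg_enh <- enh[enh$class == "fgsc_specific", ]
  esc_enh <- enh[enh$class == "esc_specific", ]
  fg_targets <- if (nrow(fg_enh)) {
    unique(stats::na.omit(nearest_gene_within(fg_enh, genes)$nearest_gene))
  } else character()
  esc_targets <- if (nrow(esc_enh)) {
    unique(stats::na.omit(nearest_gene_within(esc_enh, genes)$nearest_gene))
  } else character()

  with_local_seed(derive_seed(config$seed, 301L), {
    n <- nrow(genes)
    base <- rlnorm(n, meanlog = log(10), sdlog = 1)
    fpkm_fgsc <- base
    fpkm_fgsc[meth_fgsc] <- fpkm_fgsc[meth_fgsc] / config$expression_ratio
    fpkm_fgsc[genes$gene_id %in% fg_targets] <-
      fpkm_fgsc[genes$gene_id %in% fg_targets] * 4
    fpkm_esc <- base * rlnorm(n, 0, 0.2)
    fpkm_esc[genes$gene_id %in% esc_targets] <-
      fpkm_esc[genes$gene_id %in% esc_targets] * 4
    kd_genes <- sample(genes$gene_id,
                       min(config$n_knockdown_responsive, n))
    fpkm_kd <- fpkm_fgsc * rlnorm(n, 0, 0.1)
    kd_fold <- runif(length(kd_genes), 2, 6)
    kd_idx <- match(kd_genes, genes$gene_id)
    fpkm_kd[kd_idx] <- fpkm_fgsc[kd_idx] * kd_fold
    counts_control <- rpois(n, fpkm_fgsc * count_depth_factor)
    counts_kd <- rpois(n, fpkm_kd * count_depth_factor)
    list(
      expression = tibble(
        gene_id = genes$gene_id,
        fpkm_FGSC = fpkm_fgsc,
        fpkm_ESC = fpkm_esc,
        fpkm_knockdown = fpkm_kd,
        counts_control = as.integer(counts_control),
        counts_knockdown = as.integer(counts_kd)
      ),
      truth = tibble(
        gene_id = genes$gene_id,
        enhancer_target = genes$gene_id %in% fg_targets,
        knockdown_responsive = genes$gene_id %in% kd_genes
      )
    )
  })
}

#' Simulate the full study and write it to disk
#'
#' Runs [simulate_genome()], all ChIP assays (four marks in FGSC, four
#' in ESC), the methylation assays and expression, and writes BED
#' (peaks, islands, TEs, DMRs), bedGraph (tracks), TSV (gene models,
#' bisulfite counts, expression), a ground-truth JSON and the config
#' YAML under `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the in-memory study list (see
#'   [simulate_study_memory()]).
#' @export
simulate_study <- function(config = sim_config(), outdir) {
  study <- simulate_study_memory(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_gene_models(study$genome$genes, p("genes.tsv"))
  write_bed(study$genome$annotations$cpg_islands, p("cpg_islands.bed"))
  write_bed(select(study$genome$annotations$transposons, -"locus_id"),
            p("transposons.bed"))
  write_bed(study$genome$annotations$dmrs, p("dmrs.bed"))
  readr::write_tsv(study$genome$cpg_positions, p("cpg_positions.tsv"))
  for (nm in names(study$chip)) {
    write_bed(study$chip[[nm]]$peaks, p(sprintf("peaks_%s.bed", nm)))
    write_bedgraph(study$chip[[nm]]$track, p(sprintf("track_%s.bedGraph",
                                                     nm)))
  }
  write_bedgraph(study$methylation$capture_track,
                 p("track_methylcap_FGSC.bedGraph"))
  write_bedgraph(study$methylation$input_track,
                 p("track_input_FGSC.bedGraph"))
  write_bisulfite(study$methylation$bisulfite, p("bisulfite_MGSC.tsv"))
  readr::write_tsv(study$expression$expression, p("expression.tsv"))
  jsonlite::write_json(
    lapply(study$genome$truth, function(x) as.data.frame(x)),
    p("ground_truth.json"), dataframe = "columns", digits = NA
  )
  yaml::write_yaml(unclass(config), p("sim_config.yaml"))
  invisible(study)
}

#' Simulate the full study in memory
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `chip` (named `mark_cellType` list of
#'   peaks + track), `methylation`, `expression`, `config`.
#' @export
simulate_study_memory <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  chip <- list()
  for (ct in c("FGSC", "ESC")) {
    for (mk in c("H3K4me1", "H3K27ac", "H3K4me3", "H3K27me3")) {
      chip[[sprintf("%s_%s", mk, ct)]] <- simulate_chip_assay(genome, mk, ct)
    }
  }
  list(
    genome = genome,
    chip = chip,
    methylation = simulate_methylation_assays(genome),
    expression = simulate_expression(genome),
    config = config
  )
}

#' Paired methylation scores under a latent Gaussian copula
#'
#' Draws `n` paired capture/bisulfite window scores whose latent
#' bivariate-normal correlation is `rho`; marginals are mapped through
#' monotone transforms to an rms-like positive scale and an ams-like
#' `[0, 1]` scale. Used to check that the cross-platform Pearson
#' estimate recovers a planted association.
#'
#' @param n Number of windows.
#' @param rho Latent correlation.
#' @param seed Integer seed.
#' @return Tibble `name`, `cap_score`, `bs_score`.
#' @export
simulate_correlated_scores <- function(n, rho, seed = 1L) {
  stopifnot(abs(rho) <= 1)
  with_local_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    tibble(
      name = sprintf("w%06d", seq_len(n)),
      cap_score = 50 * pnorm(z1),
      bs_score = pnorm(z2)
    )
  })
}
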