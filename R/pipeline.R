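#' Default pipeline configuration
#'
#' @param seed Master seed for simulation and clustering.
#' @param outdir Output directory for all pipeline artifacts.
#' @param ... Overrides for any default field (`k_enhancer`,
#'   `k_promoter`, `blur_half_width`, `flank`, `alpha`, `min_fold`,
#'   `min_coverage`, `tile_width`, plus any [sim_config()] argument
#'   under `sim`).
#' @return A named list usable as [run_pipeline()] config.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("epigsc_run_"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = TRUE,
    sim = list(),
    k_enhancer = 4L,
    k_promoter = 3L,
    blur_half_width = 1L,
    flank = 5000L,
    alpha = 0.01,
    min_fold = 2.0,
    min_coverage = 10L,
    tile_width = 1000L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (or load) inputs, signal
#' clustering, chromatin-state classification, methylation analysis,
#' expression integration — writing TSV/BED outputs, a machine-readable
#' `summary.json` of all headline counts/fractions/correlations, and a
#' `pipeline.log`. Each stage is cached on an md5 digest of its inputs:
#' re-running with unchanged inputs is a no-op, and deleting a stage's
#' outputs (or changing its inputs) triggers exactly that stage's
#' recompute.
#'
#' @param config A list from [pipeline_config()], or the path of a YAML
#'   file holding one.
#' @return Invisibly, the parsed `summary.json` content.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, ".cache"), showWarnings = FALSE)
  log_file <- file.path(outdir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = log_file, append = TRUE)
  }
  logf("pipeline start, seed %d, package epigsc %s", config$seed,
       as.character(utils::packageVersion("epigsc")))

  inputs <- file.path(outdir, "inputs")
  run_stage(outdir, "simulate",
            key_parts = list(config$seed, config$sim),
            outputs = file.path(inputs, c("genes.tsv", "expression.tsv",
                                          "bisulfite_MGSC.tsv",
                                          "ground_truth.json")),
            logf = logf, {
    sim_cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    simulate_study(sim_cfg, inputs)
  })

  # ---- load inputs ----
  genes <- read_gene_models(file.path(inputs, "genes.tsv"))
  chrom_lengths <- stats::setNames(
    as.integer(do.call(sim_config,
                       c(list(seed = config$seed), config$sim))$genome_length),
    SIM_CHROM)
  read_peaks <- function(nm) read_bed(file.path(
    inputs, sprintf("peaks_%s.bed", nm)))
  read_track <- function(nm) read_bedgraph(
    file.path(inputs, sprintf("track_%s.bedGraph", nm)), chrom_lengths)

  in_md5 <- function(...) unname(tools::md5sum(file.path(inputs, ...)))

  # ---- stage: clustering ----
  cluster_file <- file.path(outdir, "enhancer_clusters.tsv")
  run_stage(outdir, "clustering",
            key_parts = list(config$seed, config$k_enhancer,
                             config$blur_half_width, config$flank,
                             in_md5(sprintf("peaks_H3K4me1_%s.bed",
                                            c("FGSC", "ESC"))),
                             in_md5(sprintf("track_%s_%s.bedGraph",
                                            rep(c("H3K4me1", "H3K27ac"), 2),
                                            rep(c("FGSC", "ESC"),
                                                each = 2)))),
            outputs = cluster_file, logf = logf, {
    union_peaks <- bind_rows(read_peaks("H3K4me1_FGSC"),
                             read_peaks("H3K4me1_ESC")) |>
      distinct(.data$name, .keep_all = TRUE) |>
      arrange(.data$chrom, .data$start)
    mats <- lapply(c("H3K4me1_FGSC", "H3K27ac_FGSC",
                     "H3K4me1_ESC", "H3K27ac_ESC"), function(nm) {
      tr <- read_track(nm)
      tr <- sqrt_transform(blur_rectangular(tr, config$blur_half_width))
      extract_signal_matrix(union_peaks, tr, config$flank)
    })
    cl <- kmeans_cluster(mats, k = config$k_enhancer, seed = config$seed)
    readr::write_tsv(left_join(tidy(cl),
                               select(union_peaks, "name", "chrom",
                                      "start", "end"),
                               by = c(region_id = "name")),
                     cluster_file)
  })
  clusters <- readr::read_tsv(cluster_file, col_types = "cicii",
                              progress = FALSE)

  # ---- stage: chromatin state ----
  chromatin_files <- file.path(outdir, c("enhancer_calls_FGSC.tsv",
                                         "enhancer_calls_ESC.tsv",
                                         "bivalent_FGSC.tsv",
                                         "bivalent_ESC.tsv",
                                         "chromatin_summary.json"))
  run_stage(outdir, "chromatin",
            key_parts = list(in_md5("genes.tsv"),
                             in_md5(sprintf(
                               "peaks_%s_%s.bed",
                               rep(c("H3K4me1", "H3K27ac", "H3K4me3",
                                     "H3K27me3"), 2),
                               rep(c("FGSC", "ESC"), each = 4)))),
            outputs = chromatin_files, logf = logf, {
    chrom_summary <- list()
    for (ct in c("FGSC", "ESC")) {
      calls <- classify_enhancers(read_peaks(paste0("H3K4me1_", ct)),
                                  read_peaks(paste0("H3K27ac_", ct)),
                                  genes)
      readr::write_tsv(calls, file.path(
        outdir, sprintf("enhancer_calls_%s.tsv", ct)))
      biv <- call_bivalent_promoters(read_peaks(paste0("H3K4me3_", ct)),
                                     read_peaks(paste0("H3K27me3_", ct)),
                                     genes)
      readr::write_tsv(biv$states, file.path(
        outdir, sprintf("bivalent_%s.tsv", ct)))
      chrom_summary[[ct]] <- list(
        n_enhancers = nrow(calls),
        n_active = sum(calls$state == "active"),
        n_poised = sum(calls$state == "poised"),
        n_bivalent = biv$n_bivalent,
        k4me3_promoter_fraction = peak_promoter_fraction(
          read_peaks(paste0("H3K4me3_", ct)), genes)
      )
    }
    jsonlite::write_json(chrom_summary,
                         file.path(outdir, "chromatin_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  # ---- stage: methylation ----
  methyl_files <- file.path(outdir, c("promoter_capture_calls.tsv",
                                      "promoter_bisulfite_calls.tsv",
                                      "gene_methylation_categories.tsv",
                                      "te_methylation_frequency.tsv",
                                      "dmr_status.tsv",
                                      "methylation_summary.json"))
  run_stage(outdir, "methylation",
            key_parts = list(config$alpha, config$min_fold,
                             config$min_coverage, config$tile_width,
                             in_md5("genes.tsv", "cpg_positions.tsv",
                                    "bisulfite_MGSC.tsv",
                                    "track_methylcap_FGSC.bedGraph",
                                    "track_input_FGSC.bedGraph",
                                    "transposons.bed", "cpg_islands.bed",
                                    "dmrs.bed")),
            outputs = methyl_files, logf = logf, {
    cpg <- readr::read_tsv(file.path(inputs, "cpg_positions.tsv"),
                           col_types = "ci", progress = FALSE)
    sites <- read_bisulfite(file.path(inputs, "bisulfite_MGSC.tsv"))
    cap_track <- read_bedgraph(file.path(inputs,
                                         "track_methylcap_FGSC.bedGraph"),
                               chrom_lengths)
    inp_track <- read_bedgraph(file.path(inputs,
                                         "track_input_FGSC.bedGraph"),
                               chrom_lengths)
    pw <- promoter_windows(genes)

    cap_calls <- call_capture_hmrs(pw, cap_track, inp_track,
                                   alpha = config$alpha,
                                   min_fold = config$min_fold)
    cap_rms <- capture_rms(pw, cap_track, cpg)
    cap_calls$rms <- cap_rms$score
    cap_calls$cpg_count <- cap_rms$cpg_count
    cap_calls$call[cap_rms$call == "no_data"] <- "no_data"
    bs_calls <- call_bisulfite_regions(
      bisulfite_ams(pw, sites, min_coverage = config$min_coverage),
      alpha = config$alpha)
    readr::write_tsv(cap_calls, methyl_files[1])
    readr::write_tsv(bs_calls, methyl_files[2])

    corr <- cross_platform_correlation(
      mutate(cap_rms, call = if_else(cap_rms$cpg_count > 0, "unscored",
                                     "no_data")),
      bs_calls)

    gene_cap <- gene_level_call(cap_calls)
    gene_bs <- gene_level_call(bs_calls)
    cmp <- compare_promoter_calls(gene_cap, gene_bs)

    body_tiles <- gene_body_tiles(genes, config$tile_width)
    body_calls <- call_capture_hmrs(body_tiles, cap_track, inp_track,
                                    alpha = config$alpha,
                                    min_fold = config$min_fold)
    gene_body <- gene_level_call(body_calls)
    cats <- categorize_genes_by_methylation(gene_cap, gene_body)
    readr::write_tsv(cats$genes, methyl_files[3])

    tiles <- tile_genome(chrom_lengths, config$tile_width)
    tile_calls <- call_capture_hmrs(tiles, cap_track, inp_track,
                                    alpha = config$alpha,
                                    min_fold = config$min_fold)
    te <- read_bed(file.path(inputs, "transposons.bed"))
    cgi <- read_bed(file.path(inputs, "cpg_islands.bed"))
    te_freq <- annotation_methylation_frequency(
      te, tile_calls, require_cpg_island_overlap = TRUE,
      cpg_islands = cgi)
    readr::write_tsv(te_freq, methyl_files[4])

    dmr <- read_bed(file.path(inputs, "dmrs.bed"))
    dmr_status <- tibble(
      name = dmr$name,
      methylated_fgsc = overlaps_any(
        dmr, filter(tile_calls, .data$call == "highly_methylated")),
      methylated_mgsc = overlaps_any(
        dmr, filter(bs_windows_genome(sites, chrom_lengths,
                                      config$tile_width, config$alpha,
                                      config$min_coverage),
                    .data$call %in% c("methylated", "highly_methylated")))
    )
    readr::write_tsv(dmr_status, methyl_files[5])

    jsonlite::write_json(list(
      cross_platform_r = corr$r,
      cross_platform_n = corr$n_windows,
      n_methylated_either = sum(cmp$counts),
      counts = as.list(cmp$counts),
      fraction_shared = unname(cmp$counts["shared"] / sum(cmp$counts)),
      fraction_promoter_with_body = cats$fraction_promoter_with_body,
      n_capture_hmr_tiles = sum(tile_calls$call == "highly_methylated")
    ), methyl_files[6], auto_unbox = TRUE, digits = NA)
  })

  # ---- stage: integration ----
  integration_files <- file.path(outdir, c("expression_comparison.tsv",
                                           "knockdown_de.tsv",
                                           "integration_summary.json"))
  run_stage(outdir, "integration",
            key_parts = list(config$seed,
                             in_md5("expression.tsv"),
                             unname(tools::md5sum(cluster_file)),
                             unname(tools::md5sum(file.path(
                               outdir, "enhancer_calls_FGSC.tsv")))),
            outputs = integration_files, logf = logf, {
    expr <- readr::read_tsv(file.path(inputs, "expression.tsv"),
                            col_types = "cdddii", progress = FALSE)
    calls_fgsc <- readr::read_tsv(
      file.path(outdir, "enhancer_calls_FGSC.tsv"),
      col_types = "ciicci", progress = FALSE)
    class_sets <- split(clusters$region_id, clusters$class)
    active_fgsc <- filter(calls_fgsc, .data$state == "active")
    gene_sets <- lapply(class_sets, function(ids) {
      unique(stats::na.omit(
        active_fgsc$nearest_gene[active_fgsc$name %in% ids]))
    })
    names(gene_sets) <- sprintf("class_%s", names(class_sets))
    comp <- class_expression_comparison(expr, gene_sets,
                                        "fpkm_FGSC", "fpkm_ESC")
    readr::write_tsv(comp, integration_files[1])
    de <- two_library_de(expr$counts_knockdown, expr$counts_control,
                         gene_ids = expr$gene_id)
    readr::write_tsv(de, integration_files[2])
    jsonlite::write_json(list(
      n_up_knockdown = sum(de$significant & de$direction == "up"),
      n_down_knockdown = sum(de$significant & de$direction == "down"),
      class_p_values = setNames(as.list(comp$p_value), comp$class)
    ), integration_files[3], auto_unbox = TRUE, digits = NA)
  })

  # ---- final summary ----
  summary <- c(
    list(seed = config$seed,
         k_enhancer = config$k_enhancer,
         n_clustered_enhancers = nrow(clusters),
         cluster_sizes = as.list(table(clusters$class))),
    list(chromatin = jsonlite::read_json(file.path(
      outdir, "chromatin_summary.json"))),
    list(methylation = jsonlite::read_json(file.path(
      outdir, "methylation_summary.json"))),
    list(integration = jsonlite::read_json(file.path(
      outdir, "integration_summary.json")))
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("pipeline complete")
  invisible(jsonlite::read_json(file.path(outdir, "summary.json")))
}

# 1-kb tiling of each gene body, labelled with the gene id. The 500 bp
# at the TSS end lie inside the promoter window and are excluded so the
# body call does not simply restate the promoter call.
gene_body_tiles <- function(genes, width = 1000L) {
  eff_start <- ifelse(genes$strand == "+", genes$body_start + 500L,
                      genes$body_start)
  eff_end <- ifelse(genes$strand == "+", genes$body_end,
                    genes$body_end - 500L)
  keep <- which(eff_start < eff_end)
  list_rbind(map(keep, function(i) {
    starts <- seq.int(eff_start[i], eff_end[i] - 1L, by = width)
    tibble(chrom = genes$chrom[i], start = as.integer(starts),
           end = as.integer(pmin(starts + width, eff_end[i])),
           strand = genes$strand[i],
           name = sprintf("%s_body_%d", genes$gene_id[i],
                          seq_along(starts)),
           gene_id = genes$gene_id[i])
  }))
}

# genome-wide bisulfite tile calls (used for DMR status on the MGSC side)
bs_windows_genome <- function(sites, chrom_lengths, width, alpha,
                              min_coverage) {
  call_bisulfite_regions(
    bisulfite_ams(tile_genome(chrom_lengths, width), sites,
                  min_coverage = min_coverage),
    alpha = alpha)
}

# Run `code` unless the stage's cache key matches and outputs exist.
run_stage <- function(outdir, name, key_parts, outputs, logf, code) {
  key_file <- file.path(outdir, ".cache", paste0(name, ".key"))
  tmp <- tempfile()
  saveRDS(key_parts, tmp)
  key <- unname(tools::md5sum(tmp))
  unlink(tmp)
  if (file.exists(key_file) &&
      identical(readLines(key_file, warn = FALSE), key) &&
      all(file.exists(outputs))) {
    logf("stage %s: cache hit, skipped", name)
    return(invisible(FALSE))
  }
  logf("stage %s: running", name)
  force(code)
  writeLines(key, key_file)
  invisible(TRUE)
}
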