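#' Read a BED file of intervals
#'
#' Accepts BED3 to BED6; columns beyond the sixth are ignored. Coordinates
#' are kept in the native BED convention (0-based, half-open).
#'
#' @param path Path to a tab-separated BED file.
#' @return An interval tibble sorted by (chrom, start); `name`/`score`/
#'   `strand` columns are present when the file carries them.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 columns",
                  which(ncol < 3)[1]))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed BED line %d: non-integer coordinates",
                  which(is.na(start) | is.na(end))[1]))
  }
  x <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = start,
    end = end
  )
  if (all(ncol >= 4)) x$name <- vapply(fields, `[[`, "", 4)
  if (all(ncol >= 5)) {
    x$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
  }
  x$strand <- if (all(ncol >= 6)) vapply(fields, `[[`, "", 6) else "."
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    abort(sprintf("invalid interval at BED line %d: start %d >= end %d",
                  bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  validate_intervals(x, "BED")
  arrange(x, .data$chrom, .data$start, .data$end)
}

#' Write intervals to a BED file
#'
#' Writes BED6 when `name`/`score`/`strand` are available, BED3 otherwise.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  has_meta <- any(c("name", "score") %in% names(x)) ||
    ("strand" %in% names(x) && any(x$strand != "."))
  if (has_meta) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     x$chrom, x$start, x$end,
                     if ("name" %in% names(x)) x$name else ".",
                     if ("score" %in% names(x)) format(x$score) else "0",
                     if ("strand" %in% names(x)) x$strand else ".")
  } else {
    lines <- sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-model table
#'
#' Expects a tab-separated file with header
#' `gene_id chrom strand tss body_start body_end` (0-based coordinates).
#' Promoter boundaries are attached via [gene_promoters()].
#'
#' @param path Path to TSV.
#' @return A gene tibble with promoter columns.
#' @export
read_gene_models <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    chrom = readr::col_character(),
    strand = readr::col_character(),
    tss = readr::col_integer(),
    body_start = readr::col_integer(),
    body_end = readr::col_integer()
  ))
  gene_promoters(x)
}

#' Write a gene-model table
#' @param genes Gene tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  readr::write_tsv(
    select(genes, "gene_id", "chrom", "strand", "tss",
           "body_start", "body_end"),
    path
  )
  invisible(path)
}

#' Read per-CpG bisulfite counts
#'
#' Expects a tab-separated file with header
#' `chrom pos strand count_C count_T` where `pos` is 1-based (the common
#' bisulfite caller convention); positions are converted to 0-based at
#' this boundary so that all downstream arithmetic shares one convention.
#'
#' @param path Path to TSV.
#' @return Tibble with columns `chrom`, `pos` (0-based), `strand`,
#'   `count_C`, `count_T`.
#' @export
read_bisulfite <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    strand = readr::col_character(),
    count_C = readr::col_integer(),
    count_T = readr::col_integer()
  ))
  if (any(x$pos < 1)) abort("bisulfite pos column must be 1-based (>= 1)")
  if (any(x$count_C < 0) || any(x$count_T < 0)) {
    abort("bisulfite counts must be non-negative")
  }
  mutate(x, pos = .data$pos - 1L)
}

#' Write per-CpG bisulfite counts (1-based positions on disk)
#' @param sites Bisulfite site tibble (0-based `pos`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bisulfite <- function(sites, path) {
  readr::write_tsv(
    mutate(select(sites, "chrom", "pos", "strand", "count_C", "count_T"),
           pos = .data$pos + 1L),
    path
  )
  invisible(path)
}
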