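#' Build a genomic-interval tibble
#'
#' Intervals follow the BED convention throughout the package: 0-based
#' start, exclusive end, strand one of `"+"`, `"-"`, `"."`. Every function
#' that consumes regions accepts a tibble with at least `chrom`, `start`
#' and `end` columns.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand Strand, recycled; one of `"+"`, `"-"`, `"."`.
#' @param name Optional feature names.
#' @param score Optional numeric scores.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, and
#'   optionally `name`, `score`, sorted by (chrom, start).
#' @export
#' @examples
#' genomic_intervals("chr1", c(100, 400), c(200, 600))
genomic_intervals <- function(chrom, start, end, strand = ".",
                              name = NULL, score = NULL) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom))
  )
  if (!is.null(name)) x$name <- as.character(name)
  if (!is.null(score)) x$score <- as.numeric(score)
  validate_intervals(x)
  arrange(x, .data$chrom, .data$start, .data$end)
}

validate_intervals <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("%s table needs chrom/start/end columns", what))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(sprintf("%s table has empty chromosome names", what))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort(sprintf(
      "invalid %s at row %d: start %d, end %d (need 0 <= start < end)",
      what, bad[1], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) {
      ifelse(x$strand == ".", "*", x$strand)
    } else "*"
  )
}

#' Do two intervals overlap?
#'
#' Vectorized half-open overlap test: intervals sharing only a boundary
#' coordinate do not overlap.
#'
#' @param a,b Interval tibbles (recycled against each other row-wise).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  a$chrom[idx_a] == b$chrom[idx_b] &
    a$start[idx_a] < b$end[idx_b] &
    b$start[idx_b] < a$end[idx_a]
}

#' Which query intervals overlap any subject interval?
#'
#' @param query,subject Interval tibbles.
#' @return Logical vector along rows of `query`.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges(query), as_granges(subject),
                       ignore.strand = TRUE)
}

# Hits table (query_idx, subject_idx) for any-overlap, strand-blind.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query_idx = integer(), subject_idx = integer()))
  }
  h <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                   ignore.strand = TRUE)
  tibble(query_idx = S4Vectors::queryHits(h),
         subject_idx = S4Vectors::subjectHits(h))
}

#' Peak center coordinate
#'
#' The center of a peak is the floor of its coordinate midpoint.
#'
#' @param x Interval tibble.
#' @return Integer vector of center positions.
#' @export
peak_center <- function(x) {
  as.integer(floor((x$start + x$end) / 2))
}
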