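#' Binned coverage tracks
#'
#' A `binned_track` holds genome-wide fixed-width bins of signal for one
#' assay in one cell type: a named list of dense per-chromosome vectors
#' plus the bin width, normalization mode and library size. Signal is
#' either raw read counts or RPKM (reads per kilobase per million mapped
#' reads), the normalization used throughout the analysis.
#'
#' @param signal Named list of numeric vectors, one per chromosome.
#' @param bin_width Bin width in bases.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param normalization `"raw_counts"` or `"rpkm"`.
#' @param library_size Total mapped reads in the library.
#' @return A `binned_track` object.
#' @export
binned_track <- function(signal, bin_width, chrom_lengths,
                         normalization = c("raw_counts", "rpkm"),
                         library_size) {
  normalization <- match.arg(normalization)
  stopifnot(is.list(signal), !is.null(names(signal)),
            all(names(signal) %in% names(chrom_lengths)))
  for (ch in names(signal)) {
    expected <- ceiling(chrom_lengths[[ch]] / bin_width)
    if (length(signal[[ch]]) != expected) {
      abort(sprintf("track %s: %d bins, expected %d",
                    ch, length(signal[[ch]]), expected))
    }
    if (any(signal[[ch]] < 0)) abort("track signal must be non-negative")
  }
  structure(
    list(signal = signal, bin_width = as.integer(bin_width),
         chrom_lengths = chrom_lengths, normalization = normalization,
         library_size = as.numeric(library_size)),
    class = "binned_track"
  )
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %d-bp bins, %s, library %.0f reads, %d chrom\n",
              x$bin_width, x$normalization, x$library_size,
              length(x$signal)))
  invisible(x)
}

#' @method as_tibble binned_track
#' @export
as_tibble.binned_track <- function(x, ...) {
  list_rbind(imap(x$signal, function(v, ch) {
    tibble(chrom = ch,
           start = as.integer((seq_along(v) - 1L) * x$bin_width),
           end = as.integer(pmin(seq_along(v) * x$bin_width,
                                 x$chrom_lengths[[ch]])),
           value = v)
  }))
}

#' Bin read positions and normalize to RPKM
#'
#' Reads are point positions (5' ends); each read falls in the 50-bp
#' (by default) bin containing its position and per-bin counts are
#' normalized to reads per kilobase per million mapped reads:
#' `RPKM = count / (bin_width/1000 * library_size/1e6)`.
#'
#' @param reads Tibble with `chrom` and `pos` (0-based positions).
#' @param chrom_lengths Named integer vector.
#' @param bin_width Bin width in bases (default 50).
#' @param mode `"rpkm"` or `"raw_counts"`.
#' @return A `binned_track`.
#' @export
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", pos = rep(10L, 10))
#' tr <- bin_and_normalize(reads, c(chr1 = 1000L), bin_width = 50)
#' tr$signal$chr1[1]  # 10 reads / (0.05 kb * 1e-5 M reads)
bin_and_normalize <- function(reads, chrom_lengths, bin_width = 50L,
                              mode = c("rpkm", "raw_counts")) {
  mode <- match.arg(mode)
  stopifnot(all(reads$chrom %in% names(chrom_lengths)))
  oob <- reads$pos < 0 |
    reads$pos >= unname(chrom_lengths[reads$chrom])
  if (any(oob)) {
    abort(sprintf("read position out of chromosome bounds (row %d)",
                  which(oob)[1]))
  }
  library_size <- nrow(reads)
  signal <- lapply(names(chrom_lengths), function(ch) {
    nbin <- ceiling(chrom_lengths[[ch]] / bin_width)
    pos <- reads$pos[reads$chrom == ch]
    counts <- tabulate(pos %/% bin_width + 1L, nbins = nbin)
    as.numeric(counts)
  })
  names(signal) <- names(chrom_lengths)
  if (mode == "rpkm") {
    denom <- (bin_width / 1000) * (library_size / 1e6)
    signal <- lapply(signal, function(v) if (denom > 0) v / denom else v)
  }
  binned_track(signal, bin_width, chrom_lengths,
               normalization = mode, library_size = library_size)
}

# Build a track directly from per-bin counts (the simulator's path).
track_from_counts <- function(counts, bin_width, chrom_lengths,
                              normalize = TRUE) {
  library_size <- sum(vapply(counts, sum, 0))
  if (normalize) {
    denom <- (bin_width / 1000) * (library_size / 1e6)
    signal <- lapply(counts, function(v) if (denom > 0) v / denom else v)
    binned_track(signal, bin_width, chrom_lengths, "rpkm", library_size)
  } else {
    binned_track(counts, bin_width, chrom_lengths, "raw_counts",
                 library_size)
  }
}

#' Rectangular mean blur
#'
#' Replaces each value by the mean over a window of `half_width` bins to
#' either side. Edges use the truncated window (the mean over the bins
#' that exist), so constant signal is preserved exactly.
#'
#' @param x A numeric vector, matrix (blurred along rows), or
#'   `binned_track`.
#' @param half_width Half-width of the kernel in bins (>= 0).
#' @return Same shape as the input.
#' @export
#' @examples
#' blur_rectangular(c(0, 0, 9, 0, 0), 1)  # 0 3 3 3 0
blur_rectangular <- function(x, half_width = 1L) {
  stopifnot(half_width >= 0)
  if (inherits(x, "binned_track")) {
    x$signal <- lapply(x$signal, blur_vector, w = half_width)
    return(x)
  }
  if (is.matrix(x)) {
    return(t(apply(x, 1, blur_vector, w = half_width)))
  }
  blur_vector(x, half_width)
}

blur_vector <- function(v, w) {
  if (w == 0 || length(v) == 0) return(v)
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - w, 1L)
  hi <- pmin(seq_len(n) + w, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Square-root transform
#'
#' Elementwise square root, applied after blurring to damp the effect of
#' noise and outliers before clustering.
#'
#' @param x Numeric vector/matrix or `binned_track` with non-negative
#'   values.
#' @return Same shape as the input.
#' @export
sqrt_transform <- function(x) {
  if (inherits(x, "binned_track")) {
    x$signal <- lapply(x$signal, sqrt_transform)
    return(x)
  }
  if (any(x < 0)) abort("sqrt_transform requires non-negative values")
  sqrt(x)
}

#' Extract a signal matrix around peak centers
#'
#' One row per region, columns spanning `[center - flank, center + flank)`
#' in track bins; positions beyond the chromosome are filled with 0.
#'
#' @param regions Interval tibble.
#' @param track A `binned_track`.
#' @param flank Half-window in bases (default 5000, i.e. a 10-kb window);
#'   must be a multiple of the bin width.
#' @return A numeric matrix of class `signal_matrix` with region ids as
#'   rownames and attributes `flank` and `bin_width`.
#' @export
extract_signal_matrix <- function(regions, track, flank = 5000L) {
  stopifnot(flank %% track$bin_width == 0)
  ncol <- as.integer(2L * flank / track$bin_width)
  centers <- peak_center(regions)
  ids <- if ("name" %in% names(regions) && !anyNA(regions$name)) {
    regions$name
  } else {
    sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  }
  m <- matrix(0, nrow = nrow(regions), ncol = ncol, dimnames = list(ids, NULL))
  for (i in seq_len(nrow(regions))) {
    v <- track$signal[[regions$chrom[i]]]
    if (is.null(v)) next
    first_bin <- (centers[i] - flank) %/% track$bin_width
    idx <- first_bin + seq_len(ncol) - 1L  # 0-based bin indices
    ok <- idx >= 0L & idx < length(v)
    m[i, ok] <- v[idx[ok] + 1L]
  }
  structure(m, class = c("signal_matrix", "matrix", "array"),
            flank = as.integer(flank), bin_width = track$bin_width)
}

#' Write a track as bedGraph
#'
#' Writes 0-based half-open `chrom start end value` lines for every
#' non-zero bin.
#'
#' @param track A `binned_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# bin_width=%d library_size=%.0f normalization=%s",
                     track$bin_width, track$library_size,
                     track$normalization), con)
  for (ch in names(track$signal)) {
    v <- track$signal[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch,
                       (nz - 1L) * track$bin_width,
                       pmin(nz * track$bin_width,
                            track$chrom_lengths[[ch]]),
                       format(v[nz], digits = 10, trim = TRUE,
                              scientific = FALSE)), con)
  }
  invisible(path)
}

#' Read a bedGraph track written by [write_bedgraph()]
#'
#' @param path Path to bedGraph.
#' @param chrom_lengths Named integer vector; inferred from the maximum
#'   end coordinate when omitted.
#' @return A `binned_track`.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  hdr <- readLines(path, n = 1)
  meta <- list(bin_width = 50L, library_size = NA_real_,
               normalization = "rpkm")
  if (startsWith(hdr, "#")) {
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
    for (p in kv) {
      parts <- strsplit(p, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- parts[2]
    }
  }
  bin_width <- as.integer(meta$bin_width)
  body <- readr::read_tsv(path, comment = "#",
                          col_names = c("chrom", "start", "end", "value"),
                          col_types = "ciid", progress = FALSE)
  chrom <- body$chrom
  start <- body$start
  end <- body$end
  value <- body$value
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(end, chrom), max, 0L)
  }
  signal <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(ceiling(chrom_lengths[[ch]] / bin_width))
    sel <- chrom == ch
    v[start[sel] %/% bin_width + 1L] <- value[sel]
    v
  })
  names(signal) <- names(chrom_lengths)
  binned_track(signal, bin_width, chrom_lengths,
               normalization = meta$normalization,
               library_size = as.numeric(meta$library_size))
}
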