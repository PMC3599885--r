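#' Partition a genome into fixed-width bins
#'
#' Tiles each chromosome with non-overlapping windows of `window` bp. Every
#' bin except possibly the last one per chromosome has width exactly
#' `window`; the last bin is truncated at the chromosome end. Coordinates are
#' 1-based inclusive throughout, so bin `k` of a chromosome covers
#' `[(k-1)*window + 1, min(k*window, length)]`.
#'
#' @param chrom_sizes either a two-column data frame (name, length) as
#'   returned by [read_chrom_sizes()], or a named numeric vector of
#'   chromosome lengths in bp.
#' @param window bin width in bp (default 1 Mb, the resolution at which
#'   region-level interaction frequencies are usually analysed).
#' @return an object of class `binned_genome`: a list with elements
#'   `chroms`, `lengths`, `window`, `bins_per_chrom`, `offsets` (0-based
#'   global index offset of each chromosome's first bin), `bins` (data frame
#'   with columns chrom/start/end, one row per bin in genome order) and
#'   `n_bins`.
#' @examples
#' g <- bin_genome(c(chrA = 3e6), window = 1e6)
#' g$bins
#' @export
bin_genome <- function(chrom_sizes, window = 1e6) {
  if (is.data.frame(chrom_sizes)) {
    chroms <- as.character(chrom_sizes[[1]])
    lengths <- as.numeric(chrom_sizes[[2]])
  } else {
    if (is.null(names(chrom_sizes)))
      stop("chrom_sizes must be a data frame or a named vector")
    chroms <- names(chrom_sizes)
    lengths <- as.numeric(chrom_sizes)
  }
  if (length(window) != 1L || !is.finite(window) || window < 1)
    stop(sprintf("window must be a positive integer number of bp, got %s",
                 format(window)))
  if (anyDuplicated(chroms))
    stop(sprintf("duplicated chromosome name: '%s'",
                 chroms[anyDuplicated(chroms)]))
  bad <- which(!is.finite(lengths) | lengths < 1)
  if (length(bad))
    stop(sprintf("chromosome '%s' has non-positive length (%s)",
                 chroms[bad[1]], format(lengths[bad[1]])))
  window <- as.numeric(window)
  nb <- as.integer(ceiling(lengths / window))
  offsets <- c(0L, cumsum(nb))[seq_along(chroms)]
  names(offsets) <- chroms
  names(nb) <- chroms
  names(lengths) <- chroms

  chrom_col <- rep(chroms, nb)
  k <- unlist(lapply(nb, seq_len), use.names = FALSE)
  start <- (k - 1) * window + 1
  end <- pmin(k * window, rep(lengths, nb))
  structure(list(
    chroms = chroms,
    lengths = lengths,
    window = window,
    bins_per_chrom = nb,
    offsets = offsets,
    bins = data.frame(chrom = chrom_col, start = start, end = end,
                      stringsAsFactors = FALSE),
    n_bins = sum(nb)
  ), class = "binned_genome")
}

#' @export
print.binned_genome <- function(x, ...) {
  cat(sprintf("binned_genome: %d chromosome(s), window %s bp, %d bins\n",
              length(x$chroms), format(x$window, big.mark = ","), x$n_bins))
  show <- utils::head(x$bins, 4L)
  for (i in seq_len(nrow(show)))
    cat(sprintf("  %s:%s-%s\n", show$chrom[i],
                format(show$start[i], scientific = FALSE),
                format(show$end[i], scientific = FALSE)))
  if (x$n_bins > 4L) cat(sprintf("  ... (%d more bins)\n", x$n_bins - 4L))
  invisible(x)
}

#' Map genomic positions to global bin indices
#'
#' @param genome a [bin_genome()] object.
#' @param chrom,pos equal-length vectors of chromosome names and 1-based
#'   positions.
#' @param what label used in error messages to identify offending records.
#' @return integer vector of global bin indices (1-based, genome order).
#' @export
bin_index <- function(genome, chrom, pos, what = "position") {
  chrom <- as.character(chrom)
  ci <- match(chrom, genome$chroms)
  if (anyNA(ci)) {
    i <- which(is.na(ci))[1]
    stop(sprintf("%s %d: unknown chromosome '%s'", what, i, chrom[i]))
  }
  len <- unname(genome$lengths[ci])
  bad <- which(!is.finite(pos) | pos < 1 | pos > len)
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf("%s %d: coordinate %s outside chromosome '%s' (1-%s)",
                 what, i, format(pos[i], scientific = FALSE), chrom[i],
                 format(len[i], scientific = FALSE)))
  }
  as.integer(unname(genome$offsets[ci]) + (pos - 1) %/% genome$window + 1)
}

#' Coordinates of bins by global index
#'
#' Inverse of [bin_index()] at bin resolution: returns the 1-based inclusive
#' span of each requested bin.
#'
#' @param genome a [bin_genome()] object.
#' @param idx integer vector of global bin indices.
#' @return data frame with columns chrom, start, end.
#' @export
bin_coords <- function(genome, idx) {
  if (any(idx < 1 | idx > genome$n_bins))
    stop("bin index out of range")
  genome$bins[idx, , drop = FALSE]
}

#' Bin labels of the form "chrom:start-end"
#' @param genome a [bin_genome()] object.
#' @return character vector, one label per bin.
#' @export
bin_labels <- function(genome) {
  sprintf("%s:%s-%s", genome$bins$chrom,
          format(genome$bins$start, scientific = FALSE, trim = TRUE),
          format(genome$bins$end, scientific = FALSE, trim = TRUE))
}

# chromosome index of every bin (integer vector, length n_bins)
bin_chrom_index <- function(genome) {
  rep(seq_along(genome$chroms), genome$bins_per_chrom)
}

# within-chromosome 0-based offset of every bin
bin_chrom_offset <- function(genome) {
  unlist(lapply(genome$bins_per_chrom, function(n) seq_len(n) - 1L),
         use.names = FALSE)
}
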