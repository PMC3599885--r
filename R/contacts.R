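#' Build a binned contact matrix from Hi-C read pairs
#'
#' Assigns both ends of every read pair to genome bins and accumulates a
#' symmetric count matrix. Pairs are unordered: the two ends are put into
#' canonical order (chromosome order, then position) before anything else,
#' so `(a, b)` and `(b, a)` are the same pair. With `dedup = TRUE` pairs
#' with identical coordinates after canonical ordering are counted once,
#' which removes PCR/optical duplicates and damps the effect of amplified
#' genomic segments.
#'
#' @param pairs data frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (1-based bp), e.g. from [read_bedpe()] or [simulate_pairs()].
#' @param genome a [bin_genome()] object.
#' @param dedup remove coordinate-identical pairs (default `TRUE`).
#' @param condition optional condition label (e.g. `"T0"` control,
#'   `"T1"` treated) carried through downstream results.
#' @return an object of class `contact_matrix`: list with the `genome`, the
#'   symmetric integer `counts` matrix, `condition`, and bookkeeping counts
#'   `n_input`, `n_duplicates`, `n_retained`.
#' @export
build_contact_matrix <- function(pairs, genome, dedup = TRUE,
                                 condition = NA_character_) {
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns chrom1, pos1, chrom2, pos2")
  n_input <- nrow(pairs)
  nb <- genome$n_bins
  M <- matrix(0, nb, nb)
  n_dup <- 0L
  if (n_input > 0) {
    c1 <- as.character(pairs$chrom1); c2 <- as.character(pairs$chrom2)
    p1 <- as.numeric(pairs$pos1);     p2 <- as.numeric(pairs$pos2)
    i1 <- match(c1, genome$chroms); i2 <- match(c2, genome$chroms)
    if (anyNA(i1) || anyNA(i2)) {
      i <- which(is.na(i1) | is.na(i2))[1]
      stop(sprintf("pair %d: unknown chromosome '%s'", i,
                   if (is.na(i1[i])) c1[i] else c2[i]))
    }
    swap <- i1 > i2 | (i1 == i2 & p1 > p2)
    t1 <- ifelse(swap, c2, c1); t2 <- ifelse(swap, c1, c2)
    q1 <- ifelse(swap, p2, p1); q2 <- ifelse(swap, p1, p2)
    if (dedup) {
      dup <- duplicated(paste(t1, q1, t2, q2, sep = "\r"))
      n_dup <- sum(dup)
      t1 <- t1[!dup]; t2 <- t2[!dup]; q1 <- q1[!dup]; q2 <- q2[!dup]
    }
    b1 <- bin_index(genome, t1, q1, what = "pair")
    b2 <- bin_index(genome, t2, q2, what = "pair")
    lo <- pmin(b1, b2); hi <- pmax(b1, b2)
    tab <- tabulate((lo - 1L) * nb + hi, nbins = nb * nb)
    M <- matrix(as.numeric(tab), nb, nb, byrow = TRUE)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
  }
  structure(list(genome = genome, counts = M, condition = condition,
                 n_input = n_input, n_duplicates = n_dup,
                 n_retained = n_input - n_dup),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix (%s): %d bins, %d pairs retained (%d duplicates removed)\n",
              ifelse(is.na(x$condition), "unlabelled", x$condition),
              x$genome$n_bins, x$n_retained, x$n_duplicates))
  cat(sprintf("  observed bin pairs: %d of %d\n",
              sum(x$counts[upper.tri(x$counts, diag = TRUE)] > 0),
              x$genome$n_bins * (x$genome$n_bins + 1) / 2))
  invisible(x)
}

#' Expected contact level for every bin pair
#'
#' The observed/expected background model. In `"distance"` mode (default)
#' the expected count of an intra-chromosomal bin pair at bin separation
#' `d` is the genome-wide mean raw count over all intra-chromosomal bin
#' pairs at that separation, and the expected count of an
#' inter-chromosomal pair is the global mean over all inter-chromosomal
#' pairs. `"uniform"` mode uses the single global mean for every cell,
#' for comparison. Cells whose contact class has zero mean carry an
#' unusable flag (attribute `"usable"`).
#'
#' @param contacts a [build_contact_matrix()] object.
#' @param mode `"distance"` (distance-stratified intra, global inter) or
#'   `"uniform"`.
#' @return numeric matrix of expected counts with logical attribute
#'   `"usable"` (same dimensions) marking cells with positive expectation.
#' @export
expected_matrix <- function(contacts, mode = c("distance", "uniform")) {
  mode <- match.arg(mode)
  g <- contacts$genome
  C <- contacts$counts
  nb <- g$n_bins
  ut <- upper.tri(C, diag = TRUE)
  E <- matrix(0, nb, nb)
  if (mode == "uniform") {
    E[] <- mean(C[ut])
  } else {
    ci <- bin_chrom_index(g)
    oi <- bin_chrom_offset(g)
    intra <- outer(ci, ci, "==")
    D <- abs(outer(oi, oi, "-"))
    sel <- ut & intra
    mean_by_d <- tapply(C[sel], D[sel], mean)
    dmax <- max(D[sel])
    mvec <- numeric(dmax + 1)
    mvec[as.integer(names(mean_by_d)) + 1] <- mean_by_d
    E[intra] <- mvec[D[intra] + 1]
    E[!intra] <- mean(C[ut & !intra])
  }
  attr(E, "usable") <- E > 0
  E
}

#' Z-score transform of a contact matrix
#'
#' Divides raw counts by the expected level and standardizes the resulting
#' observed/expected ratios to Z-scores: how many standard deviations a bin
#' pair's contact ratio lies above or below the mean ratio. Intra- and
#' inter-chromosomal cells form separate standardization populations (their
#' ratio scales are not comparable), and only observed cells (raw count
#' greater than 0) enter the mean/SD, computed with the population SD over
#' the unique (upper-triangle) cells. Unobserved cells carry the sentinel
#' Z = 0 with `mask = FALSE`; an observed cell whose Z happens to be 0
#' still has `mask = TRUE` and counts as an interaction everywhere
#' downstream. If the ratio SD of a class is 0, all Z in that class are 0
#' with the mask preserved.
#'
#' @param contacts a [build_contact_matrix()] object.
#' @param expected expected-count matrix from [expected_matrix()]; computed
#'   with defaults when omitted.
#' @return object of class `zscore_matrix`: list with `genome`, symmetric
#'   numeric `z`, logical `mask` (TRUE where raw count > 0) and
#'   `condition`.
#' @export
zscore_transform <- function(contacts, expected = NULL) {
  if (is.null(expected)) expected <- expected_matrix(contacts)
  g <- contacts$genome
  C <- contacts$counts
  nb <- g$n_bins
  mask <- C > 0
  usable <- attr(expected, "usable")
  if (is.null(usable)) usable <- expected > 0
  bad <- mask & !usable
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("expected level is unusable at observed cell (%d, %d)",
                 min(ij), max(ij)))
  }
  ci <- bin_chrom_index(g)
  intra <- outer(ci, ci, "==")
  ut <- upper.tri(C, diag = TRUE)
  Z <- matrix(0, nb, nb)
  ratio <- matrix(0, nb, nb)
  ratio[mask] <- C[mask] / expected[mask]
  for (cls in list(intra, !intra)) {
    cells <- mask & cls & ut
    if (!any(cells)) next
    v <- ratio[cells]
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))  # population SD
    zc <- if (s == 0) 0 else (ratio - m) / s
    sel <- mask & cls
    Z[sel] <- if (s == 0) 0 else zc[sel]
  }
  Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
  structure(list(genome = g, z = Z, mask = mask, condition = contacts$condition),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  ut <- upper.tri(x$z, diag = TRUE)
  cat(sprintf("zscore_matrix (%s): %d bins, %d observed bin pairs, Z range [%.2f, %.2f]\n",
              ifelse(is.na(x$condition), "unlabelled", x$condition),
              x$genome$n_bins, sum(x$mask & ut),
              min(x$z[x$mask]), max(x$z[x$mask])))
  invisible(x)
}
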