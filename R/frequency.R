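#' Per-bin chromosomal interaction frequency
#'
#' For every bin, the number of bins (anywhere in the genome) with which it
#' has an observed interaction, divided by the total number of bins. A bin
#' pair is "observed" when its raw contact count is positive (the observed
#' mask of the Z-score matrix), so a genuinely observed cell with a
#' numerical Z of 0 still counts. By default the self-pair (diagonal) is
#' excluded from the numerator while the bin itself stays in the
#' denominator; set `include_self = TRUE` for the other convention (the two
#' differ by under one denominator unit per bin).
#'
#' @param z a [zscore_transform()] object.
#' @param include_self count the diagonal cell when observed (default
#'   `FALSE`).
#' @return object of class `freq_profile`: data frame with columns `bin`,
#'   `chrom`, `start`, `end`, `n_obs`, `frequency` (fraction in \[0, 1\]),
#'   plus attributes `condition` and `genome`.
#' @export
interaction_frequency <- function(z, include_self = FALSE) {
  g <- z$genome
  n_obs <- rowSums(z$mask)
  if (!include_self) n_obs <- n_obs - diag(z$mask)
  out <- data.frame(bin = seq_len(g$n_bins),
                    chrom = g$bins$chrom,
                    start = g$bins$start,
                    end = g$bins$end,
                    n_obs = as.integer(n_obs),
                    frequency = n_obs / g$n_bins,
                    stringsAsFactors = FALSE)
  structure(out, condition = z$condition, genome = g,
            class = c("freq_profile", "data.frame"))
}

#' Count bins at or above interaction-frequency thresholds
#'
#' The genome-wide frequency-distribution table: for each threshold, the
#' number of bins whose interaction frequency is greater than or equal to
#' it. Counts are non-increasing in the threshold.
#'
#' @param profile a [interaction_frequency()] profile.
#' @param thresholds ascending percentages (default the conventional
#'   1/5/10/20/30/40/50/60).
#' @return data frame with columns `threshold_pct` and `n_regions`.
#' @export
frequency_table <- function(profile,
                            thresholds = c(1, 5, 10, 20, 30, 40, 50, 60)) {
  if (is.unsorted(thresholds))
    stop("thresholds must be sorted ascending")
  pct <- profile$frequency * 100
  data.frame(threshold_pct = thresholds,
             n_regions = vapply(thresholds, function(t) sum(pct >= t),
                                integer(1)))
}

#' Call hot and cold interaction regions
#'
#' Hot regions are bins with interaction frequency at or above
#' `hot_threshold` percent, ranked by descending frequency; cold regions
#' are bins at or below `cold_threshold` percent, ranked ascending. Each
#' list is truncated to `top_n`. Ties are broken by genome order
#' (chromosome order, then start), making ranks deterministic.
#'
#' @param profile a [interaction_frequency()] profile.
#' @param hot_threshold,cold_threshold percent cutoffs (defaults 30 and
#'   0.5, the conventional hot/cold definitions); `hot_threshold` must
#'   exceed `cold_threshold`.
#' @param top_n maximum regions per call class (default 10).
#' @return data frame of class `region_calls` with columns `chrom`,
#'   `start`, `end`, `frequency_pct`, `call` ("hot"/"cold"), `rank`.
#' @export
call_regions <- function(profile, hot_threshold = 30, cold_threshold = 0.5,
                         top_n = 10) {
  if (hot_threshold <= cold_threshold)
    stop("hot_threshold must be greater than cold_threshold")
  pct <- profile$frequency * 100
  take <- function(idx, decreasing) {
    ord <- idx[order(pct[idx] * if (decreasing) -1 else 1, idx)]
    utils::head(ord, top_n)
  }
  hot <- take(which(pct >= hot_threshold), decreasing = TRUE)
  cold <- take(which(pct <= cold_threshold), decreasing = FALSE)
  idx <- c(hot, cold)
  out <- data.frame(bin = idx,
                    chrom = profile$chrom[idx],
                    start = profile$start[idx],
                    end = profile$end[idx],
                    frequency_pct = pct[idx],
                    call = rep(c("hot", "cold"), c(length(hot), length(cold))),
                    rank = c(seq_along(hot), seq_along(cold)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("region_calls", "data.frame")
  out
}

#' Row-correlation matrices of intra-chromosomal interaction blocks
#'
#' Pearson correlation between the Z-score rows of one chromosome's
#' intra-chromosomal block, within each condition and across the two —
#' the correlation heat maps used to compare a chromosome's interaction
#' pattern before and after treatment. Entry (i, j) of the cross matrix is
#' the correlation between row i of `zA`'s block and row j of `zB`'s.
#' Rows with zero variance yield `NA` entries (undefined, not silently 0).
#'
#' @param zA,zB [zscore_transform()] objects on the same genome.
#' @param chrom chromosome name.
#' @return list with elements `within_a`, `within_b`, `cross`.
#' @export
correlation_matrices <- function(zA, zB, chrom) {
  if (!identical(zA$genome$bins, zB$genome$bins))
    stop("zA and zB must share a genome")
  g <- zA$genome
  if (!chrom %in% g$chroms) stop(sprintf("unknown chromosome '%s'", chrom))
  idx <- which(g$bins$chrom == chrom)
  A <- zA$z[idx, idx, drop = FALSE]
  B <- zB$z[idx, idx, drop = FALSE]
  corr <- function(X, Y) suppressWarnings(stats::cor(t(X), t(Y)))
  list(within_a = corr(A, A), within_b = corr(B, B), cross = corr(A, B))
}
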