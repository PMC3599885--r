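#' Fit the two-condition differential chromatin-interaction model
#'
#' The central estimator of the package. Starting from raw Hi-C read
#' pairs of a control (`T0`) and a treated (`T1`) condition, it
#' (i) bins the genome and builds deduplicated contact matrices,
#' (ii) normalizes each to observed/expected Z-scores,
#' (iii) computes per-bin interaction frequencies and calls hot/cold
#' regions in the control condition, and (iv) evaluates the bounded
#' relative-ratio statistic cellwise and classifies strong differential
#' interactions into the four gain/loss x intra/inter types, together
#' with the per-bin gain/loss profile.
#'
#' @param pairs_T0,pairs_T1 read-pair data frames (`chrom1`, `pos1`,
#'   `chrom2`, `pos2`), e.g. from [read_bedpe()] or [simulate_pairs()].
#' @param chrom_sizes chromosome sizes (data frame or named vector), or a
#'   ready-made [bin_genome()] object.
#' @param window bin width in bp (ignored when a genome is supplied).
#' @param dedup remove duplicated pairs (default `TRUE`).
#' @param expected expected-contact model, `"distance"` or `"uniform"`.
#' @param ratio_cut,z_cut,mode differential thresholds, see
#'   [classify_differential()].
#' @param hot_threshold,cold_threshold,top_n region-calling thresholds,
#'   see [call_regions()].
#' @param include_self count diagonal cells in interaction frequencies.
#' @return an object of class `hic_diff`: list with `genome`, the two
#'   `contact_matrix` objects (`cm0`, `cm1`), the two `zscore_matrix`
#'   objects (`z0`, `z1`), the relative-`ratio` matrix, `calls`
#'   (differential calls), `freq0`/`freq1` (frequency profiles),
#'   `regions` (hot/cold calls at T0), `gain_loss` (per-bin profile) and
#'   the thresholds used.
#' @examples
#' cfg <- sim_config(seed = 7)
#' fit <- hic_differential(simulate_pairs(cfg, "T0"),
#'                         simulate_pairs(cfg, "T1"),
#'                         cfg$genome)
#' fit
#' @export
hic_differential <- function(pairs_T0, pairs_T1, chrom_sizes,
                             window = 1e6, dedup = TRUE,
                             expected = c("distance", "uniform"),
                             ratio_cut = 2, z_cut = 1,
                             mode = c("strict", "relaxed"),
                             hot_threshold = 30, cold_threshold = 0.5,
                             top_n = 10, include_self = FALSE) {
  expected <- match.arg(expected)
  mode <- match.arg(mode)
  genome <- if (inherits(chrom_sizes, "binned_genome")) chrom_sizes
            else bin_genome(chrom_sizes, window)
  cm0 <- build_contact_matrix(pairs_T0, genome, dedup = dedup,
                              condition = "T0")
  cm1 <- build_contact_matrix(pairs_T1, genome, dedup = dedup,
                              condition = "T1")
  z0 <- zscore_transform(cm0, expected_matrix(cm0, mode = expected))
  z1 <- zscore_transform(cm1, expected_matrix(cm1, mode = expected))
  calls <- classify_differential(z0, z1, ratio_cut = ratio_cut,
                                 z_cut = z_cut, mode = mode)
  freq0 <- interaction_frequency(z0, include_self = include_self)
  freq1 <- interaction_frequency(z1, include_self = include_self)
  structure(list(
    genome = genome, cm0 = cm0, cm1 = cm1, z0 = z0, z1 = z1,
    ratio = relative_ratio_matrix(z0, z1),
    calls = calls, freq0 = freq0, freq1 = freq1,
    regions = call_regions(freq0, hot_threshold = hot_threshold,
                           cold_threshold = cold_threshold, top_n = top_n),
    gain_loss = gain_loss_profile(calls, genome),
    thresholds = list(ratio_cut = ratio_cut, z_cut = z_cut, mode = mode,
                      hot_threshold = hot_threshold,
                      cold_threshold = cold_threshold, top_n = top_n,
                      expected = expected)
  ), class = "hic_diff")
}

#' @export
print.hic_diff <- function(x, ...) {
  cat("Differential chromatin-interaction fit\n")
  cat(sprintf("  genome: %d bins (%d chromosomes, %s bp window)\n",
              x$genome$n_bins, length(x$genome$chroms),
              format(x$genome$window, big.mark = ",")))
  cat(sprintf("  pairs retained: T0 %d, T1 %d (duplicates removed: %d / %d)\n",
              x$cm0$n_retained, x$cm1$n_retained,
              x$cm0$n_duplicates, x$cm1$n_duplicates))
  tb <- table(factor(x$calls$type, levels = c("gain-intra", "loss-intra",
                                              "gain-inter", "loss-inter")))
  cat(sprintf("  strong differential calls (|ratio| >= %g, Z > %g): %d\n",
              x$thresholds$ratio_cut, x$thresholds$z_cut, nrow(x$calls)))
  cat(sprintf("    %s\n", paste(sprintf("%s %d", names(tb), tb),
                                collapse = ", ")))
  nh <- sum(x$regions$call == "hot")
  cat(sprintf("  hot regions (>= %g%% at T0): %d; cold (<= %g%%): %d\n",
              x$thresholds$hot_threshold, nh,
              x$thresholds$cold_threshold, sum(x$regions$call == "cold")))
  invisible(x)
}

#' @export
summary.hic_diff <- function(object, ...) {
  structure(list(
    fit = object,
    freq_table = data.frame(
      threshold_pct = frequency_table(object$freq0)$threshold_pct,
      T0 = frequency_table(object$freq0)$n_regions,
      T1 = frequency_table(object$freq1)$n_regions),
    type_counts = table(factor(object$calls$type,
                               levels = c("gain-intra", "loss-intra",
                                          "gain-inter", "loss-inter"))),
    top_changed = top_changed_regions(object$gain_loss)
  ), class = "summary.hic_diff")
}

#' @export
print.summary.hic_diff <- function(x, ...) {
  print(x$fit)
  cat("\nInteraction-frequency distribution (bins at or above threshold):\n")
  print(x$freq_table, row.names = FALSE)
  cat("\nHot/cold regions (T0):\n")
  print(as.data.frame(x$fit$regions)[, c("chrom", "start", "end",
                                         "frequency_pct", "call", "rank")],
        row.names = FALSE, digits = 6)
  cat("\nRegions with most gained/lost interactions:\n")
  print(x$top_changed[, c("chrom", "start", "end", "gains", "losses",
                          "total")], row.names = FALSE)
  invisible(x)
}

#' Plot the per-bin gain/loss profile of a fit
#'
#' Gained interactions per bin above the axis, lost below, along the
#' concatenated genome with chromosome boundaries marked.
#'
#' @param x a [hic_differential()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hic_diff <- function(x, ...) {
  gl <- x$gain_loss
  ylim <- range(c(gl$gains, gl$losses, -1, 1))
  graphics::plot(gl$bin, gl$gains, type = "h", col = "firebrick",
                 ylim = ylim, xlab = "genome bin",
                 ylab = "interactions gained (+) / lost (-)", ...)
  graphics::segments(gl$bin, 0, gl$bin, gl$losses, col = "steelblue")
  graphics::abline(h = 0, col = "grey40")
  bounds <- cumsum(x$genome$bins_per_chrom)
  graphics::abline(v = utils::head(bounds, -1) + 0.5, lty = 3,
                   col = "grey70")
  graphics::mtext(x$genome$chroms, side = 3, at = bounds -
                    x$genome$bins_per_chrom / 2, cex = 0.7)
  invisible(x)
}
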