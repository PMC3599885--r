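#' Exponential interaction strength
#'
#' Maps a cell's Z-score to a positive interaction strength `exp(z)` when
#' the cell is observed, and to 0 when it is not (the no-interaction
#' sentinel). The zero on unobserved cells is what makes the relative
#' ratio saturate at exactly +/-2 for condition-exclusive contacts.
#'
#' @param z numeric Z-score(s).
#' @param observed logical flag(s), recycled against `z`.
#' @return numeric strength(s), 0 where unobserved.
#' @export
exp_strength <- function(z, observed) {
  ifelse(observed, exp(z), 0)
}

#' Relative ratio of interaction change between two conditions
#'
#' The bounded differential statistic
#' `r = (E1 - E0) / ((E1 + E0) / 2)` on exponential strengths
#' `E = exp_strength(z, observed)`, with condition 1 (treated) minus
#' condition 0 (control), so positive `r` means a treatment-specific gain.
#' For a fold change `k = E1/E0` this is `r = 2(k - 1)/(k + 1)`: 2-, 5-
#' and 10-fold changes map to 0.67, 1.33 and 18/11 (printed 1.63), and a
#' contact observed in only one condition maps to exactly +2 (gain) or -2
#' (loss). Cells unobserved in both conditions return 0 and are excluded
#' from analysis (attribute handled by [relative_ratio_matrix()]).
#'
#' @param z0,z1 Z-scores in the control and treated condition.
#' @param obs0,obs1 observed flags for the two conditions.
#' @return numeric relative ratio(s) in \[-2, 2\].
#' @seealso [fold_change_to_ratio()], [ratio_to_fold_change()]
#' @export
relative_ratio <- function(z0, obs0, z1, obs1) {
  e0 <- exp_strength(z0, obs0)
  e1 <- exp_strength(z1, obs1)
  s <- e0 + e1
  ifelse(s == 0, 0, (e1 - e0) / (s / 2))
}

#' Relative ratio as a function of fold change, and its inverse
#'
#' `fold_change_to_ratio(k) = 2(k - 1)/(k + 1)` is strictly increasing in
#' `k > 0`; `ratio_to_fold_change(r) = (2 + r)/(2 - r)` inverts it.
#'
#' @param k positive fold change(s) `E1/E0`.
#' @param r relative ratio(s) in (-2, 2).
#' @return the corresponding ratio / fold change.
#' @export
fold_change_to_ratio <- function(k) 2 * (k - 1) / (k + 1)

#' @rdname fold_change_to_ratio
#' @export
ratio_to_fold_change <- function(r) (2 + r) / (2 - r)

#' Relative-ratio matrix for two conditions
#'
#' Applies [relative_ratio()] cellwise to two Z-score matrices on the same
#' genome. Cells observed in neither condition are fixed at 0 and flagged
#' in the logical attribute `"excluded"`.
#'
#' @param z0,z1 [zscore_transform()] objects (control, treated).
#' @return numeric matrix of relative ratios with attribute `"excluded"`.
#' @export
relative_ratio_matrix <- function(z0, z1) {
  if (!identical(z0$genome$bins, z1$genome$bins))
    stop("z0 and z1 must share a genome")
  r <- relative_ratio(z0$z, z0$mask, z1$z, z1$mask)
  attr(r, "excluded") <- !z0$mask & !z1$mask
  r
}

#' Classify strong differential chromosomal interactions
#'
#' Calls the bin pairs whose interaction changed strongly between the two
#' conditions and classifies each call as gain or loss (sign of the
#' relative ratio, treated minus control) and intra- or inter-chromosomal
#' (chromosome equality of the two bins). Under the strict criterion
#' (default) a cell is called when its absolute relative ratio reaches
#' `ratio_cut = 2` — i.e. the contact is observed in exactly one
#' condition — and the Z-score of the condition in which it is observed
#' exceeds `z_cut = 1` (strict inequality). `mode = "relaxed"` reproduces
#' the secondary criterion: absolute relative ratio of at least 2/3 (the
#' value printed as 0.67, a 2-fold change) with any observed Z-score,
#' where "observed" is the mask, not a literal Z != 0.
#'
#' @param z0,z1 [zscore_transform()] objects (control, treated) on the
#'   same genome.
#' @param ratio_cut minimum absolute relative ratio, in (0, 2\];
#'   default 2 (strict) / 2/3 (relaxed).
#' @param z_cut Z threshold applied to the largest observed-condition
#'   Z-score, strict inequality; default 1 (strict), none (relaxed).
#' @param mode `"strict"` or `"relaxed"`.
#' @return data frame of class `differential_calls`, one row per unordered
#'   bin pair: `bin1`, `bin2`, coordinates of both bins, `type`
#'   (gain-intra / loss-intra / gain-inter / loss-inter), `ratio`, `z0`,
#'   `z1`.
#' @export
classify_differential <- function(z0, z1,
                                  ratio_cut = if (mode == "strict") 2 else 2 / 3,
                                  z_cut = if (mode == "strict") 1 else -Inf,
                                  mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  if (!identical(z0$genome$bins, z1$genome$bins))
    stop("z0 and z1 must share a genome")
  if (ratio_cut <= 0 || ratio_cut > 2)
    stop("ratio_cut must be in (0, 2]")
  g <- z0$genome
  r <- relative_ratio(z0$z, z0$mask, z1$z, z1$mask)
  zmax <- pmax(ifelse(z0$mask, z0$z, -Inf), ifelse(z1$mask, z1$z, -Inf))
  ut <- upper.tri(r, diag = TRUE)
  called <- ut & (z0$mask | z1$mask) & abs(r) >= ratio_cut & zmax > z_cut
  idx <- which(called, arr.ind = TRUE)
  ci <- bin_chrom_index(g)
  b1 <- idx[, 1]; b2 <- idx[, 2]
  type <- paste0(ifelse(r[called] > 0, "gain", "loss"),
                 ifelse(ci[b1] == ci[b2], "-intra", "-inter"))
  out <- data.frame(bin1 = b1, bin2 = b2,
                    chrom1 = g$bins$chrom[b1], start1 = g$bins$start[b1],
                    end1 = g$bins$end[b1],
                    chrom2 = g$bins$chrom[b2], start2 = g$bins$start[b2],
                    end2 = g$bins$end[b2],
                    type = type,
                    ratio = r[called],
                    z0 = z0$z[called], z1 = z1$z[called],
                    stringsAsFactors = FALSE)
  out <- out[order(out$bin1, out$bin2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("differential_calls", "data.frame")
  attr(out, "ratio_cut") <- ratio_cut
  attr(out, "z_cut") <- z_cut
  attr(out, "mode") <- mode
  out
}

#' Per-bin gain/loss interaction profile
#'
#' Counts, for every bin, the differential calls it participates in: each
#' call increments both of its endpoint bins (once, if the two endpoints
#' coincide). Gains are stored as positive counts and losses as negative,
#' matching the convention of plotting gained interactions above and lost
#' interactions below the axis along the genome.
#'
#' @param calls a [classify_differential()] result.
#' @param genome the [bin_genome()] the calls refer to.
#' @return data frame with columns `bin`, `chrom`, `start`, `end`,
#'   `gains` (>= 0), `losses` (<= 0).
#' @export
gain_loss_profile <- function(calls, genome) {
  nb <- genome$n_bins
  count_ends <- function(sel) {
    b <- c(calls$bin1[sel], calls$bin2[sel & calls$bin2 != calls$bin1])
    tabulate(b, nbins = nb)
  }
  gain <- count_ends(grepl("^gain", calls$type))
  loss <- count_ends(grepl("^loss", calls$type))
  data.frame(bin = seq_len(nb),
             chrom = genome$bins$chrom,
             start = genome$bins$start,
             end = genome$bins$end,
             gains = gain,
             losses = -loss,
             stringsAsFactors = FALSE)
}

#' Regions with the most gained or lost interactions
#'
#' Ranks bins by total differential activity `gains + |losses|` and
#' returns the top `n`, ties broken by genome order.
#'
#' @param profile a [gain_loss_profile()] data frame.
#' @param n number of regions (default 10).
#' @return the top rows of `profile`, with a `total` column.
#' @export
top_changed_regions <- function(profile, n = 10) {
  total <- profile$gains + abs(profile$losses)
  ord <- order(-total, profile$bin)
  out <- profile[utils::head(ord, n), , drop = FALSE]
  out$total <- total[utils::head(ord, n)]
  rownames(out) <- NULL
  out
}
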