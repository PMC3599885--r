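# Shared fixtures and independent oracles.

toy_genome <- function(lengths = c(chrA = 5e6), window = 1e6) {
  bin_genome(lengths, window)
}

# Construct a zscore_matrix object directly from a Z matrix and mask,
# bypassing the transform — used to probe downstream operations with
# exactly controlled inputs.
as_zscore <- function(genome, z, mask = z != 0, condition = NA_character_) {
  z <- as.matrix(z)
  mask <- as.matrix(mask)
  structure(list(genome = genome, z = z, mask = mask, condition = condition),
            class = "zscore_matrix")
}

# Minimal signal_summary carrying per-gene values only (what
# enrichment_test consumes).
make_summary <- function(genes, values, mark = "mk", part = "body",
                         condition = NA_character_) {
  structure(list(per_gene = data.frame(gene = genes, bin = 1L,
                                       count = NA_integer_, value = values,
                                       stringsAsFactors = FALSE),
                 per_bin = NULL, excluded_bins = integer(0), part = part,
                 mark = mark, condition = condition, log_base = 2,
                 pseudocount = 1),
            class = "signal_summary")
}

# Independent log-space binomial upper-tail oracle via explicit
# logsumexp over lchoose terms (no pbinom).
log10_binom_tail <- function(k, n, p) {
  kk <- k:n
  lt <- lchoose(n, kk) + kk * log(p) + (n - kk) * log1p(-p)
  m <- max(lt)
  (m + log(sum(exp(lt - m)))) / log(10)
}

# Brute-force differential classification over every cell of a small
# genome, straight from the definitions.
brute_force_calls <- function(z0, z1, ratio_cut = 2, z_cut = 1) {
  g <- z0$genome
  ci <- rep(seq_along(g$chroms), g$bins_per_chrom)
  out <- list()
  for (i in seq_len(g$n_bins)) for (j in i:g$n_bins) {
    e0 <- if (z0$mask[i, j]) exp(z0$z[i, j]) else 0
    e1 <- if (z1$mask[i, j]) exp(z1$z[i, j]) else 0
    if (e0 == 0 && e1 == 0) next
    r <- (e1 - e0) / ((e1 + e0) / 2)
    zz <- c(if (z0$mask[i, j]) z0$z[i, j], if (z1$mask[i, j]) z1$z[i, j])
    if (abs(r) >= ratio_cut && max(zz) > z_cut)
      out[[length(out) + 1]] <- data.frame(
        bin1 = i, bin2 = j,
        type = paste0(if (r > 0) "gain" else "loss",
                      if (ci[i] == ci[j]) "-intra" else "-inter"),
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(bin1 = integer(0), bin2 = integer(0),
                                      type = character(0)))
  do.call(rbind, out)
}

# Random symmetric Z-score fixture on a genome (observed cells get
# non-degenerate Z values).
random_zscore <- function(genome, p_obs = 0.4) {
  nb <- genome$n_bins
  mask <- matrix(FALSE, nb, nb)
  ut <- which(upper.tri(mask, diag = TRUE), arr.ind = TRUE)
  on <- runif(nrow(ut)) < p_obs
  z <- matrix(0, nb, nb)
  zval <- rnorm(sum(on))
  for (k in seq_len(sum(on))) {
    i <- ut[on, 1][k]; j <- ut[on, 2][k]
    mask[i, j] <- mask[j, i] <- TRUE
    z[i, j] <- z[j, i] <- zval[k]
  }
  as_zscore(genome, z, mask)
}

# Tiny default-like config scaled down for fast unit tests.
small_config <- function(seed = 1, depth = 600, hot_boost = 12, ...) {
  sim_config(chrom_lengths = c(chrA = 20e6, chrB = 16e6),
             depth = depth, n_hot = 3, hot_boost = hot_boost,
             n_planted = c("gain-intra" = 2, "loss-intra" = 1,
                           "gain-inter" = 1, "loss-inter" = 2),
             n_genes = 120, n_breakpoints = 50, peak_depth = 400,
             seed = seed, ...)
}
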