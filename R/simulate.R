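# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

# Evenly spaced default hot bins, avoiding chromosome-first bins.
default_hot_bins <- function(genome, n) {
  nb <- genome$n_bins
  if (nb < n + 2) stop("genome too small for the requested hot-bin count")
  idx <- unique(round(seq(2, nb - 1, length.out = n)))
  i <- 2
  while (length(idx) < n && i < nb) {  # fill collisions on tiny genomes
    if (!(i %in% idx)) idx <- sort(c(idx, i))
    i <- i + 1
  }
  idx[seq_len(n)]
}

# Deterministic default planted gain/loss cells (fixed internal seed),
# avoiding hot bins, the diagonal and duplicates.
default_planted <- function(genome, hot_bins, n_planted, strength) {
  ci <- bin_chrom_index(genome)
  ok <- setdiff(seq_len(genome$n_bins), hot_bins)
  cand_intra <- list(); cand_inter <- list()
  for (a in ok) for (b in ok) if (a < b) {
    if (ci[a] == ci[b] && (b - a) >= 2) cand_intra[[length(cand_intra) + 1]] <- c(a, b)
    if (ci[a] != ci[b]) cand_inter[[length(cand_inter) + 1]] <- c(a, b)
  }
  cand_intra <- do.call(rbind, cand_intra)
  cand_inter <- do.call(rbind, cand_inter)
  types <- names(n_planted)
  with_seed(8191, {
    pick <- function(cand, n, used) {
      avail <- setdiff(seq_len(nrow(cand)), used)
      sample(avail, n)
    }
    used_intra <- integer(0); used_inter <- integer(0)
    rows <- list()
    for (ty in types) {
      n <- n_planted[[ty]]
      if (n == 0) next
      intra <- grepl("intra", ty)
      cand <- if (intra) cand_intra else cand_inter
      if (is.null(cand) || nrow(cand) < n)
        stop(sprintf("genome too small to plant %d %s cells", n, ty))
      sel <- pick(cand, n, if (intra) used_intra else used_inter)
      if (intra) used_intra <- c(used_intra, sel) else used_inter <- c(used_inter, sel)
      rows[[ty]] <- data.frame(bin1 = cand[sel, 1], bin2 = cand[sel, 2],
                               type = ty, strength = strength,
                               stringsAsFactors = FALSE)
    }
    if (!length(rows))
      return(data.frame(bin1 = integer(0), bin2 = integer(0),
                        type = character(0), strength = numeric(0),
                        stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Configuration of the synthetic two-condition Hi-C study
#'
#' Bundles every parameter of the synthetic-data generators: the genome,
#' sequencing depth, the intra-chromosomal distance decay, the sparse
#' inter-chromosomal background, a set of "hot" bins whose trans contacts
#' are boosted, planted condition-specific gain/loss cells, negative
#' binomial epigenomic tracks with condition shifts, gene/peak/break-point
#' annotations and expression tables. The defaults describe a compact
#' two-condition study: a 170 Mb genome of four chromosomes binned at
#' 1 Mb, ~3,500 expected pairs per condition with contact probability
#' decaying as (d+1)^-alpha, ten hot bins whose trans-contact rate is
#' boosted 15-fold (reproducing the observed contrast between hot-region
#' and typical interaction frequencies), and planted strong changes with
#' the real study's qualitative composition (gain-intra > loss-intra,
#' loss-inter > gain-inter, total losses > total gains).
#'
#' The background contact architecture is shared between the two
#' conditions — both receive the identical background pair stream derived
#' from `seed` — and the conditions differ only through the planted cells
#' (gains emitted only under T1, losses only under T0, background
#' suppressed at planted cells). Treatment is thus modelled as a targeted
#' re-organization on a common architecture; see the package vignette for
#' what this does and does not emulate.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window bin width in bp.
#' @param depth expected total read-pair count per condition (background).
#' @param alpha intra-chromosomal distance-decay exponent.
#' @param inter_rate expected background count per inter-chromosomal bin
#'   pair (before hot boost).
#' @param n_hot,hot_bins,hot_boost number of hot bins (placed evenly when
#'   `hot_bins` is `NULL`), their global indices, and the multiplier
#'   applied to the trans-contact rate of each hot endpoint.
#' @param planted data frame (`bin1`, `bin2`, `type`, `strength`) of
#'   condition-specific cells, or `NULL` to build the default layout.
#' @param n_planted named counts of default planted cells per type.
#' @param planted_strength pair count emitted at each planted cell.
#' @param mark_effects named log2 shifts applied in T1 to genes in
#'   differential regions, signs following the canonical estrogen
#'   response (activating marks up, H3K9me3 and Pol-II down, H3K4me1
#'   unchanged).
#' @param mark_baseline_log2,mark_baseline_sd,mark_dispersion negative
#'   binomial track model: per-gene-part baseline log2 mean, its SD, and
#'   the NB size parameter (larger = closer to Poisson).
#' @param n_genes,gene_length,gene_desert_frac gene count, length range
#'   in bp, and the fraction of bins left without genes (mirroring the
#'   gene-free regions excluded from signal summaries).
#' @param peak_depth,peak_coupling expected total peak count and the
#'   strength of the coupling between per-bin peak rate and the bin's
#'   expected interaction frequency.
#' @param n_breakpoints,breakpoint_hot_prob break-point count and the
#'   probability that a break-point is placed inside a hot bin.
#' @param expr_mean,expr_sd,expr_noise_sd log2 expression model: shared
#'   gene signal and per-condition noise (defaults give cross-condition
#'   correlation ~0.99).
#' @param seed integer seed; all generators are pure functions of the
#'   configuration, so identical configurations give identical data.
#' @return object of class `sim_config` (a list of the above plus the
#'   derived `genome`).
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 50e6, chr2 = 45e6,
                                         chr3 = 40e6, chr4 = 35e6),
                       window = 1e6,
                       depth = 3500,
                       alpha = 1,
                       inter_rate = 0.05,
                       n_hot = 10, hot_bins = NULL, hot_boost = 15,
                       planted = NULL,
                       n_planted = c("gain-intra" = 9, "loss-intra" = 3,
                                     "gain-inter" = 4, "loss-inter" = 12),
                       planted_strength = 25,
                       mark_effects = c(H3K4me3 = 1, H3K27me3 = 1,
                                        H3K9ac = 1, H3K14ac = 1,
                                        H3K9me3 = -1, PolII = -1,
                                        H3K4me1 = 0),
                       mark_baseline_log2 = 5, mark_baseline_sd = 1,
                       mark_dispersion = 8,
                       n_genes = 800, gene_length = c(5e3, 1.2e5),
                       gene_desert_frac = 0.15,
                       peak_depth = 3000, peak_coupling = 3,
                       n_breakpoints = 314, breakpoint_hot_prob = 0.22,
                       expr_mean = 8, expr_sd = 2, expr_noise_sd = 0.15,
                       seed = 1) {
  genome <- bin_genome(chrom_lengths, window)
  if (depth < 0 || inter_rate < 0 || hot_boost < 0 || peak_depth < 0 ||
      planted_strength < 0)
    stop("rates, depths and boosts must be non-negative")
  if (breakpoint_hot_prob < 0 || breakpoint_hot_prob > 1)
    stop("breakpoint_hot_prob must be in [0, 1]")
  if (is.null(hot_bins)) hot_bins <- default_hot_bins(genome, n_hot)
  if (any(hot_bins < 1 | hot_bins > genome$n_bins))
    stop("hot_bins out of genome bounds")
  if (is.null(planted))
    planted <- default_planted(genome, hot_bins, as.list(n_planted),
                               planted_strength)
  if (any(planted$bin1 < 1 | planted$bin2 > genome$n_bins))
    stop("planted cells out of genome bounds")
  structure(list(
    genome = genome, chrom_lengths = genome$lengths, window = window,
    depth = depth, alpha = alpha, inter_rate = inter_rate,
    hot_bins = sort(hot_bins), hot_boost = hot_boost,
    planted = planted, planted_strength = planted_strength,
    mark_effects = mark_effects, mark_baseline_log2 = mark_baseline_log2,
    mark_baseline_sd = mark_baseline_sd, mark_dispersion = mark_dispersion,
    n_genes = n_genes, gene_length = gene_length,
    gene_desert_frac = gene_desert_frac,
    peak_depth = peak_depth, peak_coupling = peak_coupling,
    n_breakpoints = n_breakpoints,
    breakpoint_hot_prob = breakpoint_hot_prob,
    expr_mean = expr_mean, expr_sd = expr_sd,
    expr_noise_sd = expr_noise_sd, seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d bins (%d chromosomes, %s bp window), depth %s pairs/condition\n",
    x$genome$n_bins, length(x$genome$chroms),
    format(x$window, big.mark = ","), format(x$depth, big.mark = ",")))
  cat(sprintf("  %d hot bins (boost %g), planted cells: %s; seed %d\n",
              length(x$hot_bins), x$hot_boost,
              paste(sprintf("%s=%d", names(table(x$planted$type)),
                            table(x$planted$type)), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Background contact-rate matrix implied by a configuration
#'
#' Expected background count for every bin pair (identical for both
#' conditions): intra-chromosomal rates proportional to
#' `(d + 1)^-alpha`, scaled so that the total expected pair count equals
#' `depth`; inter-chromosomal rates `inter_rate` times the hot-boost
#' factor of each endpoint; zero at planted cells (they are
#' condition-specific and emitted separately).
#'
#' @param config a [sim_config()].
#' @return symmetric numeric matrix of expected counts per unordered bin
#'   pair (the upper triangle carries the per-cell rates).
#' @export
contact_rate_matrix <- function(config) {
  g <- config$genome
  nb <- g$n_bins
  ci <- bin_chrom_index(g)
  oi <- bin_chrom_offset(g)
  intra <- outer(ci, ci, "==")
  D <- abs(outer(oi, oi, "-"))
  ut <- upper.tri(D, diag = TRUE)

  boost <- rep(1, nb)
  boost[config$hot_bins] <- config$hot_boost
  rate <- matrix(0, nb, nb)
  rate[!intra] <- config$inter_rate * outer(boost, boost)[!intra]
  inter_total <- sum(rate[ut])
  if (config$depth > 0) {
    intra_total <- config$depth - inter_total
    if (intra_total <= 0)
      stop(sprintf(
        "depth (%g) does not exceed the expected inter-chromosomal count (%.1f)",
        config$depth, inter_total))
    w <- matrix(0, nb, nb)
    w[intra] <- (D[intra] + 1)^(-config$alpha)
    rate[intra] <- intra_total * w[intra] / sum(w[ut & intra])
  } else {
    rate[] <- 0
  }
  for (i in seq_len(nrow(config$planted))) {
    b1 <- config$planted$bin1[i]; b2 <- config$planted$bin2[i]
    rate[b1, b2] <- 0; rate[b2, b1] <- 0
  }
  rate
}

# draw one read-pair row per count at the given cells, positions uniform
# within each bin (assumes RNG already seeded by the caller)
cells_to_pairs <- function(genome, bin1, bin2, counts) {
  keep <- counts > 0
  b1 <- rep(bin1[keep], counts[keep])
  b2 <- rep(bin2[keep], counts[keep])
  rand_pos <- function(b) {
    s <- genome$bins$start[b]; e <- genome$bins$end[b]
    s + floor(stats::runif(length(b)) * (e - s + 1))
  }
  data.frame(chrom1 = genome$bins$chrom[b1], pos1 = rand_pos(b1),
             chrom2 = genome$bins$chrom[b2], pos2 = rand_pos(b2),
             stringsAsFactors = FALSE)
}

#' Simulate Hi-C read pairs for one condition
#'
#' Draws background cell counts as independent Poissons from the
#' configuration's rate matrix — using a background stream derived only
#' from `config$seed`, so both conditions receive the identical
#' background — and then appends the planted condition-specific cells:
#' gain cells emit `strength` pairs only under T1, loss cells only under
#' T0. Read positions are uniform within their bin. Fixed configuration
#' implies byte-identical output.
#'
#' @param config a [sim_config()].
#' @param condition `"T0"` (control) or `"T1"` (treated).
#' @return data frame of read pairs (`chrom1`, `pos1`, `chrom2`, `pos2`).
#' @export
simulate_pairs <- function(config, condition = c("T0", "T1")) {
  condition <- match.arg(condition)
  g <- config$genome
  empty <- data.frame(chrom1 = character(0), pos1 = numeric(0),
                      chrom2 = character(0), pos2 = numeric(0),
                      stringsAsFactors = FALSE)
  if (config$depth == 0) return(empty)
  rate <- contact_rate_matrix(config)
  ut <- which(upper.tri(rate, diag = TRUE), arr.ind = TRUE)
  bg <- with_seed(config$seed, {
    counts <- stats::rpois(nrow(ut), rate[ut])
    cells_to_pairs(g, ut[, 1], ut[, 2], counts)
  })
  want <- if (condition == "T1") "^gain" else "^loss"
  pl <- config$planted[grepl(want, config$planted$type), , drop = FALSE]
  planted <- with_seed(config$seed + if (condition == "T1") 2L else 1L, {
    cells_to_pairs(g, pl$bin1, pl$bin2, pl$strength)
  })
  out <- rbind(bg, planted)
  rownames(out) <- NULL
  out
}

#' Ground-truth planted differential cells
#'
#' @param config a [sim_config()].
#' @return data frame `bin1`, `bin2`, `type`, `strength` (the truth that
#'   [classify_differential()] should recover on simulated data).
#' @export
planted_calls <- function(config) config$planted

#' Bins touched by planted cells, per interaction type
#'
#' @param config a [sim_config()].
#' @return named list of sorted bin-index vectors, one per type present.
#' @export
planted_type_bins <- function(config) {
  sp <- split(config$planted, config$planted$type)
  lapply(sp, function(d) sort(unique(c(d$bin1, d$bin2))))
}

#' Genes located in each interaction-type region
#'
#' Assigns genes to the four differential-interaction classes by TSS bin;
#' a gene whose bin belongs to several classes is attributed to the first
#' in the order gain-intra, loss-intra, gain-inter, loss-inter.
#'
#' @param config a [sim_config()].
#' @param genes gene models (from [simulate_annotations()]).
#' @return named list of gene-name vectors.
#' @export
genes_by_type <- function(config, genes) {
  tb <- planted_type_bins(config)
  order_types <- intersect(c("gain-intra", "loss-intra",
                             "gain-inter", "loss-inter"), names(tb))
  bin <- bin_index(config$genome, genes$chrom, gene_tss(genes),
                   what = "gene")
  assigned <- rep(NA_character_, nrow(genes))
  for (ty in order_types)
    assigned[is.na(assigned) & bin %in% tb[[ty]]] <- ty
  sets <- lapply(order_types, function(ty) genes$name[which(assigned == ty)])
  names(sets) <- order_types
  sets
}

#' Simulate epigenomic track counts per gene part
#'
#' Negative binomial read counts for every (mark, gene, part) triple. The
#' per-gene-part baseline log2 mean is drawn once from the configuration
#' seed and shared by both conditions (the paired structure of a
#' two-condition design); in the treated condition the mean of genes
#' located in planted differential regions is shifted by the mark's
#' configured log2 effect. Dispersion is controlled by the NB size
#' parameter; size -> infinity approaches Poisson.
#'
#' @param config a [sim_config()].
#' @param genes gene models (from [simulate_annotations()]).
#' @param condition `"T0"` or `"T1"`.
#' @return data frame with columns `mark`, `gene`, `part`, `count`.
#' @export
simulate_tracks <- function(config, genes, condition = c("T0", "T1")) {
  condition <- match.arg(condition)
  marks <- names(config$mark_effects)
  parts <- c("upstream", "body", "downstream")
  ng <- nrow(genes)
  grid <- expand.grid(gene = genes$name, part = parts, mark = marks,
                      stringsAsFactors = FALSE)
  base_log2 <- with_seed(config$seed + 101L, {
    stats::rnorm(nrow(grid), config$mark_baseline_log2,
                 config$mark_baseline_sd)
  })
  in_diff <- genes$name %in% unlist(genes_by_type(config, genes),
                                    use.names = FALSE)
  shift <- if (condition == "T1") {
    config$mark_effects[grid$mark] *
      as.numeric(grid$gene %in% genes$name[in_diff])
  } else 0
  counts <- with_seed(config$seed + 211L + (condition == "T1"), {
    stats::rnbinom(nrow(grid), size = config$mark_dispersion,
                   mu = 2^(base_log2 + shift))
  })
  data.frame(mark = grid$mark, gene = grid$gene, part = grid$part,
             count = counts, stringsAsFactors = FALSE)
}

#' Signal summary from simulated track counts
#'
#' Builds the same `signal_summary` object as [aggregate_signal()], but
#' starting from per-gene-part counts (the native output of
#' [simulate_tracks()]) instead of read intervals.
#'
#' @param tracks a [simulate_tracks()] data frame.
#' @param genes gene models.
#' @param genome a [bin_genome()].
#' @param mark,part which track to summarize.
#' @param condition condition label.
#' @param log_base,pseudocount as in [aggregate_signal()].
#' @return a `signal_summary` object.
#' @export
tracks_to_summary <- function(tracks, genes, genome, mark,
                              part = c("body", "upstream", "downstream"),
                              condition = NA_character_,
                              log_base = 2, pseudocount = 1) {
  part <- match.arg(part)
  tr <- tracks[tracks$mark == mark & tracks$part == part, , drop = FALSE]
  counts <- tr$count[match(genes$name, tr$gene)]
  value <- log(counts + pseudocount, base = log_base)
  bin <- bin_index(genome, genes$chrom, gene_tss(genes), what = "gene")
  per_gene <- data.frame(gene = genes$name, bin = bin, count = counts,
                         value = value, stringsAsFactors = FALSE)
  have <- sort(unique(bin))
  per_bin <- data.frame(
    bin = have, chrom = genome$bins$chrom[have],
    start = genome$bins$start[have], end = genome$bins$end[have],
    n_genes = vapply(have, function(b) sum(bin == b), integer(1)),
    mean_log = vapply(have, function(b) mean(value[bin == b]), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(per_gene = per_gene, per_bin = per_bin,
                 excluded_bins = setdiff(seq_len(genome$n_bins), have),
                 part = part, mark = mark, condition = condition,
                 log_base = log_base, pseudocount = pseudocount),
            class = "signal_summary")
}

#' Simulate gene models, peaks, break-points and expression tables
#'
#' Genes are placed uniformly over the non-desert bins (a configured
#' fraction of bins stays gene-free, mirroring the gene deserts excluded
#' from signal summaries) with uniform lengths and random strands. Peak
#' counts per bin are Poisson with rate proportional to
#' `1 + coupling * f_i`, where `f_i` is the bin's expected interaction
#' frequency under the configuration's contact-rate matrix. Break-points
#' are placed inside a random hot bin with the configured probability and
#' uniformly otherwise. Expression tables share a per-gene signal across
#' conditions with independent per-condition noise.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (name/chrom/start/end/strand), `peaks`
#'   (chrom/start/end), `breakpoints` (chrom/pos), `expression` (gene/
#'   T0/T1) and `desert_bins`.
#' @export
simulate_annotations <- function(config) {
  g <- config$genome
  nb <- g$n_bins

  gene_out <- with_seed(config$seed + 301L, {
    n_desert <- floor(config$gene_desert_frac * nb)
    desert <- sort(sample(nb, n_desert))
    okbins <- setdiff(seq_len(nb), desert)
    bins <- sample(okbins, config$n_genes, replace = TRUE)
    s <- g$bins$start[bins]; e <- g$bins$end[bins]
    tss <- s + floor(stats::runif(config$n_genes) * (e - s + 1))
    len <- round(stats::runif(config$n_genes, config$gene_length[1],
                              config$gene_length[2]))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    chrom <- g$bins$chrom[bins]
    chrlen <- unname(g$lengths[match(chrom, g$chroms)])
    start <- ifelse(strand == "+", tss, pmax(1, tss - len + 1))
    end <- ifelse(strand == "+", pmin(chrlen, tss + len - 1), tss)
    list(genes = data.frame(
           name = sprintf("g%04d", seq_len(config$n_genes)),
           chrom = chrom, start = start, end = end, strand = strand,
           stringsAsFactors = FALSE),
         desert = desert)
  })

  rate <- contact_rate_matrix(config)
  freq_proxy <- rowSums(1 - exp(-rate)) / nb
  peaks <- with_seed(config$seed + 401L, {
    w <- 1 + config$peak_coupling * freq_proxy / max(freq_proxy)
    lam <- config$peak_depth * w / sum(w)
    counts <- stats::rpois(nb, lam)
    b <- rep(seq_len(nb), counts)
    s <- g$bins$start[b]; e <- g$bins$end[b]
    mid <- s + floor(stats::runif(length(b)) * pmax(e - s - 199, 1))
    data.frame(chrom = g$bins$chrom[b], start = mid, end = mid + 199,
               stringsAsFactors = FALSE)
  })

  breakpoints <- with_seed(config$seed + 501L, {
    n <- config$n_breakpoints
    in_hot <- stats::runif(n) < config$breakpoint_hot_prob
    b <- ifelse(in_hot,
                config$hot_bins[sample.int(length(config$hot_bins), n,
                                           replace = TRUE)],
                sample.int(nb, n, replace = TRUE))
    s <- g$bins$start[b]; e <- g$bins$end[b]
    data.frame(chrom = g$bins$chrom[b],
               pos = s + floor(stats::runif(n) * (e - s + 1)),
               stringsAsFactors = FALSE)
  })

  expression <- with_seed(config$seed + 601L, {
    base <- stats::rnorm(config$n_genes, config$expr_mean, config$expr_sd)
    data.frame(gene = gene_out$genes$name,
               T0 = base + stats::rnorm(config$n_genes, 0,
                                        config$expr_noise_sd),
               T1 = base + stats::rnorm(config$n_genes, 0,
                                        config$expr_noise_sd),
               stringsAsFactors = FALSE)
  })

  list(genes = gene_out$genes, peaks = peaks, breakpoints = breakpoints,
       expression = expression, desert_bins = gene_out$desert)
}

#' Simulate the complete study dataset, optionally writing it to disk
#'
#' Convenience wrapper generating read pairs for both conditions, the
#' annotations and the epigenomic tracks. With `dir` set, the dataset is
#' written in the formats the pipeline reads (chrom.sizes, BEDPE pairs,
#' BED peaks/break-points, TSV genes/expression/tracks) together with a
#' `manifest.json` recording the configuration and seed.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return (invisibly, when writing) a list with `pairs_T0`, `pairs_T1`,
#'   `genes`, `peaks`, `breakpoints`, `expression`, `tracks_T0`,
#'   `tracks_T1`, `desert_bins` and the `config`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  ann <- simulate_annotations(config)
  out <- list(pairs_T0 = simulate_pairs(config, "T0"),
              pairs_T1 = simulate_pairs(config, "T1"),
              genes = ann$genes, peaks = ann$peaks,
              breakpoints = ann$breakpoints, expression = ann$expression,
              tracks_T0 = simulate_tracks(config, ann$genes, "T0"),
              tracks_T1 = simulate_tracks(config, ann$genes, "T1"),
              desert_bins = ann$desert_bins, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_chrom_sizes(config$genome, file.path(dir, "genome.chrom.sizes"))
    write_bedpe(out$pairs_T0, file.path(dir, "pairs_T0.bedpe"))
    write_bedpe(out$pairs_T1, file.path(dir, "pairs_T1.bedpe"))
    utils::write.table(out$genes, file.path(dir, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(out$peaks, file.path(dir, "peaks.bed"))
    utils::write.table(out$breakpoints, file.path(dir, "breakpoints.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$expression, file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$tracks_T0, file.path(dir, "tracks_T0.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$tracks_T1, file.path(dir, "tracks_T1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- config[setdiff(names(config), "genome")]
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}
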