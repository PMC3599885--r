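#' Partition genes into regulatory parts anchored at the 5' TSS
#'
#' Splits each gene into three strand-aware regulatory regions relative to
#' its 5' transcription start site: `flank` bp immediately upstream of the
#' TSS, `flank` bp downstream starting at the TSS, and the full gene body.
#' On the + strand the TSS is the gene start and upstream means lower
#' coordinates; on the - strand the TSS is the gene end and the layout is
#' mirrored. Intervals are clipped to chromosome bounds when a genome is
#' supplied; a part clipped away entirely (e.g. upstream of a TSS at
#' position 1) has `start > end` and zero width.
#'
#' @param genes data frame with columns `name`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` ("+"/"-").
#' @param flank flank size in bp (default 5000).
#' @param genome optional [bin_genome()] used to clip at chromosome ends.
#' @return data frame with one row per gene and part: `name`, `chrom`,
#'   `strand`, `part` ("upstream"/"body"/"downstream"), `start`, `end`.
#' @export
partition_genes <- function(genes, flank = 5000, genome = NULL) {
  if (flank <= 0) stop("flank must be positive")
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  up_s <- ifelse(plus, tss - flank, tss + 1)
  up_e <- ifelse(plus, tss - 1, tss + flank)
  dn_s <- ifelse(plus, tss, tss - flank + 1)
  dn_e <- ifelse(plus, tss + flank - 1, tss)
  out <- data.frame(
    name = rep(genes$name, 3),
    chrom = rep(genes$chrom, 3),
    strand = rep(genes$strand, 3),
    part = rep(c("upstream", "body", "downstream"), each = nrow(genes)),
    start = c(up_s, genes$start, dn_s),
    end = c(up_e, genes$end, dn_e),
    stringsAsFactors = FALSE)
  out$start <- pmax(out$start, 1)
  if (!is.null(genome)) {
    len <- genome$lengths[match(out$chrom, genome$chroms)]
    out$end <- pmin(out$end, unname(len))
  }
  rownames(out) <- NULL
  out
}

# strand-aware TSS of each gene
gene_tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)

# count read midpoints falling inside each query interval (same chromosome
# namespace); reads and queries are 1-based inclusive
count_midpoints <- function(reads, chrom, start, end) {
  mid <- floor((as.numeric(reads$start) + as.numeric(reads$end)) / 2)
  out <- integer(length(chrom))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    m <- sort(mid[reads$chrom == cc])
    if (!length(m)) next
    out[sel] <- findInterval(end[sel], m) - findInterval(start[sel] - 1, m)
  }
  pmax(out, 0L)
}

#' Aggregate an epigenomic read track over a gene part, per genome bin
#'
#' For one mark and condition: counts the reads (by midpoint) in the
#' requested regulatory part of every gene, log-transforms the counts with
#' a pseudocount, and averages the per-gene values over the genes whose
#' TSS falls in each genome bin. Bins containing no gene TSS are excluded
#' from the per-bin summary (and reported), since there is nothing to
#' average there; the excluded set depends only on the gene annotation,
#' not on the mark or condition.
#'
#' @param reads data frame of aligned-read intervals with columns `chrom`,
#'   `start`, `end` (1-based inclusive, e.g. from [read_bed()]).
#' @param genes gene models as in [partition_genes()].
#' @param genome a [bin_genome()] object.
#' @param part `"upstream"`, `"body"` or `"downstream"`.
#' @param flank flank size passed to [partition_genes()].
#' @param log_base,pseudocount transform `log(count + pseudocount)`;
#'   defaults log2 with pseudocount 1.
#' @param mark,condition optional labels carried into the result.
#' @return object of class `signal_summary`: list with `per_gene` (gene,
#'   bin, count, value), `per_bin` (bin, chrom, start, end, n_genes,
#'   mean_log), `excluded_bins` (bins with no gene), and the labels and
#'   transform parameters.
#' @export
aggregate_signal <- function(reads, genes, genome,
                             part = c("body", "upstream", "downstream"),
                             flank = 5000, log_base = 2, pseudocount = 1,
                             mark = NA_character_, condition = NA_character_) {
  part <- match.arg(part)
  parts <- partition_genes(genes, flank = flank, genome = genome)
  parts <- parts[parts$part == part, , drop = FALSE]
  parts <- parts[match(genes$name, parts$name), , drop = FALSE]
  empty <- parts$start > parts$end
  counts <- count_midpoints(reads, parts$chrom, parts$start, parts$end)
  counts[empty] <- 0L
  value <- log(counts + pseudocount, base = log_base)
  bin <- bin_index(genome, genes$chrom, gene_tss(genes), what = "gene")
  per_gene <- data.frame(gene = genes$name, bin = bin, count = counts,
                         value = value, stringsAsFactors = FALSE)
  have <- sort(unique(bin))
  mean_log <- vapply(have, function(b) mean(value[bin == b]), numeric(1))
  n_genes <- vapply(have, function(b) sum(bin == b), integer(1))
  per_bin <- data.frame(bin = have,
                        chrom = genome$bins$chrom[have],
                        start = genome$bins$start[have],
                        end = genome$bins$end[have],
                        n_genes = n_genes, mean_log = mean_log,
                        stringsAsFactors = FALSE)
  structure(list(per_gene = per_gene, per_bin = per_bin,
                 excluded_bins = setdiff(seq_len(genome$n_bins), have),
                 part = part, mark = mark, condition = condition,
                 log_base = log_base, pseudocount = pseudocount),
            class = "signal_summary")
}

#' @export
print.signal_summary <- function(x, ...) {
  cat(sprintf(
    "signal_summary: mark %s, condition %s, part %s; %d genes, %d bins (%d excluded, no gene)\n",
    ifelse(is.na(x$mark), "?", x$mark),
    ifelse(is.na(x$condition), "?", x$condition), x$part,
    nrow(x$per_gene), nrow(x$per_bin), length(x$excluded_bins)))
  invisible(x)
}

#' Test condition shifts of a mark over interaction-type gene sets
#'
#' For each gene set (typically the genes located in the bins of one of
#' the four differential-interaction types), compares the per-gene
#' log-transformed read counts between the treated and control conditions
#' with a two-sided t-test (default) or Mann-Whitney/Wilcoxon test. The
#' same genes are measured in both conditions, so the tests are paired on
#' gene name (a signed-rank test in the Mann-Whitney case); genes present
#' in only one condition are dropped. The reported T statistic is
#' positive exactly when the treated mean exceeds the control mean. Sets
#' with fewer than 2 shared genes yield an undefined (`NA`) result.
#'
#' @param summary_T1,summary_T0 [aggregate_signal()] summaries of the same
#'   mark and part in the treated and control condition.
#' @param gene_sets named list mapping a label (e.g. interaction type) to
#'   a character vector of gene names.
#' @param test `"t"` or `"mann-whitney"`.
#' @return data frame with columns `mark`, `part`, `set`, `n_genes`,
#'   `statistic`, `p_value`, `direction` (+1/-1, sign of treated minus
#'   control mean).
#' @export
enrichment_test <- function(summary_T1, summary_T0, gene_sets,
                            test = c("t", "mann-whitney")) {
  test <- match.arg(test)
  one <- function(set_name) {
    gs <- gene_sets[[set_name]]
    pg1 <- summary_T1$per_gene; pg0 <- summary_T0$per_gene
    shared <- intersect(intersect(pg1$gene, pg0$gene), gs)
    x1 <- pg1$value[match(shared, pg1$gene)]
    x0 <- pg0$value[match(shared, pg0$gene)]
    n <- length(shared)
    if (n < 2)
      return(data.frame(mark = summary_T1$mark, part = summary_T1$part,
                        set = set_name, n_genes = n, statistic = NA_real_,
                        p_value = NA_real_, direction = NA_real_,
                        stringsAsFactors = FALSE))
    dirn <- sign(mean(x1) - mean(x0))
    if (test == "t") {
      ht <- tryCatch(stats::t.test(x1, x0, paired = TRUE),
                     error = function(e) NULL)
    } else {
      ht <- tryCatch(suppressWarnings(stats::wilcox.test(x1, x0,
                                                         paired = TRUE)),
                     error = function(e) NULL)
    }
    if (is.null(ht) || !is.finite(ht$statistic)) {
      # zero-variance degenerate samples: no evidence of change
      stat <- 0; p <- 1
      if (identical(mean(x1), mean(x0))) dirn <- 0
    } else {
      stat <- unname(ht$statistic); p <- ht$p.value
      if (identical(x1, x0)) { stat <- 0; p <- 1; dirn <- 0 }
    }
    data.frame(mark = summary_T1$mark, part = summary_T1$part,
               set = set_name, n_genes = n, statistic = stat,
               p_value = p, direction = dirn, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(gene_sets), one))
  rownames(out) <- NULL
  out
}

#' Assign peaks to genome bins by midpoint
#'
#' @param peaks data frame of peak intervals (`chrom`, `start`, `end`,
#'   1-based inclusive).
#' @param genome a [bin_genome()] object.
#' @return integer vector of peak counts, one per bin.
#' @export
peaks_per_bin <- function(peaks, genome) {
  if (nrow(peaks) == 0) return(integer(genome$n_bins))
  mid <- floor((as.numeric(peaks$start) + as.numeric(peaks$end)) / 2)
  b <- bin_index(genome, peaks$chrom, mid, what = "peak")
  tabulate(b, nbins = genome$n_bins)
}

#' Rank association between per-bin counts and interaction frequency
#'
#' Spearman correlation between a per-bin count vector (e.g. binding-site
#' peaks per bin) and the interaction-frequency profile, quantifying
#' whether binding concentrates in highly interacting regions.
#'
#' @param counts numeric vector, one value per bin.
#' @param profile a [interaction_frequency()] profile on the same genome.
#' @return Spearman rho, or `NA` when either vector is constant
#'   (undefined).
#' @export
rank_association <- function(counts, profile) {
  if (length(counts) != nrow(profile))
    stop("counts must have one value per bin")
  if (stats::sd(counts) == 0 || stats::sd(profile$frequency) == 0)
    return(NA_real_)
  stats::cor(counts, profile$frequency, method = "spearman")
}

#' Break-point enrichment in hot regions
#'
#' Counts rearrangement break-points falling inside the called hot bins
#' and computes the upper-tail probability of at least that many under a
#' uniform null in which each break-point lands in a hot bin with
#' probability (number of hot bins) / (total bins). The binomial tail is
#' evaluated in log space, so probabilities far below double underflow
#' (e.g. 1e-80) are still resolved via `log10_p`. A hypergeometric tail
#' (break-points as draws of distinct bins) is available as an
#' alternative.
#'
#' @param breakpoints data frame with columns `chrom`, `pos` (1-based bp).
#' @param hot_calls hot rows of a [call_regions()] result (rows with
#'   `call == "hot"` are selected automatically).
#' @param genome a [bin_genome()] object.
#' @param test `"binomial"` (default) or `"hypergeometric"`.
#' @return list of class `overlap_test`: `overlap` (k), `n`
#'   (break-points), `hot_bins`, `total_bins`, `p_value`, `log10_p`,
#'   `test`.
#' @export
breakpoint_overlap <- function(breakpoints, hot_calls, genome,
                               test = c("binomial", "hypergeometric")) {
  test <- match.arg(test)
  if ("call" %in% names(hot_calls))
    hot_calls <- hot_calls[hot_calls$call == "hot", , drop = FALSE]
  n <- nrow(breakpoints)
  nh <- nrow(hot_calls)
  nb <- genome$n_bins
  if (nh == 0)
    return(structure(list(overlap = 0L, n = n, hot_bins = 0L,
                          total_bins = nb, p_value = NA_real_,
                          log10_p = NA_real_, test = test),
                     class = "overlap_test"))
  hot_bins <- bin_index(genome, hot_calls$chrom, hot_calls$start,
                        what = "hot region")
  k <- if (n > 0) {
    b <- bin_index(genome, breakpoints$chrom, breakpoints$pos,
                   what = "breakpoint")
    sum(b %in% hot_bins)
  } else 0L
  if (test == "binomial") {
    logp <- stats::pbinom(k - 1, n, nh / nb, lower.tail = FALSE,
                          log.p = TRUE)
  } else {
    logp <- stats::phyper(k - 1, m = nh, n = nb - nh, k = min(n, nb),
                          lower.tail = FALSE, log.p = TRUE)
  }
  structure(list(overlap = as.integer(k), n = n, hot_bins = nh,
                 total_bins = nb, p_value = exp(logp),
                 log10_p = logp / log(10), test = test),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "breakpoint overlap: %d of %d in %d hot bins of %d (%s tail p = %.3g, log10 p = %.1f)\n",
    x$overlap, x$n, x$hot_bins, x$total_bins, x$test, x$p_value, x$log10_p))
  invisible(x)
}

#' Cross-condition expression correlation over a gene set
#'
#' Pearson correlation of expression values between the two conditions
#' over the genes shared by both tables (optionally restricted to a gene
#' set), used to ask whether treatment changes the expression of genes in
#' a region class.
#'
#' @param expr_T0,expr_T1 named numeric vectors, or data frames whose
#'   first column is the gene name and second the expression value.
#' @param gene_set optional character vector restricting the comparison.
#' @return list with `r` (Pearson correlation, `NA` if either side has
#'   zero variance) and `n_genes`.
#' @export
expression_correlation <- function(expr_T0, expr_T1, gene_set = NULL) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(as.numeric(x[[2]]),
                                          as.character(x[[1]]))
    else x
  }
  e0 <- as_vec(expr_T0); e1 <- as_vec(expr_T1)
  shared <- intersect(names(e0), names(e1))
  if (!is.null(gene_set)) shared <- intersect(shared, gene_set)
  if (length(shared) < 3)
    stop("need at least 3 shared genes")
  x <- e0[shared]; y <- e1[shared]
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
       else stats::cor(x, y)
  list(r = r, n_genes = length(shared))
}

#' Chi-square enrichment of differential expression in a region gene set
#'
#' 2x2 contingency test (inside vs outside the region gene set, crossed
#' with differentially expressed vs not) asking whether genes in a region
#' class are more subject to expression change than genes overall. No
#' continuity correction by default.
#'
#' @param de_genes character vector of differentially expressed genes.
#' @param region_genes genes located in the region class (must be a
#'   subset of `all_genes`).
#' @param all_genes the gene universe.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `p_value`, `table` (2x2 counts),
#'   `expected_warning` (`TRUE` when any expected cell is below 1).
#' @export
de_enrichment_chisq <- function(de_genes, region_genes, all_genes,
                                correct = FALSE) {
  if (!all(region_genes %in% all_genes))
    stop("region_genes must be a subset of all_genes")
  de <- intersect(de_genes, all_genes)
  a <- length(intersect(region_genes, de))
  b <- length(region_genes) - a
  c_ <- length(de) - a
  d <- length(all_genes) - length(region_genes) - c_
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(region = c("in", "out"),
                                expression = c("DE", "not_DE")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = 0, p_value = 1, table = tab,
                expected_warning = TRUE))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, table = tab,
       expected_warning = any(ht$expected < 1))
}
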