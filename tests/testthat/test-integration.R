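test_that("gene partition is strand-aware, TSS-anchored and clipped", {
  g <- bin_genome(c(c = 1e6), window = 1e6)
  genes <- data.frame(name = c("p", "m"), chrom = "c",
                      start = c(10001, 10001), end = c(20000, 20000),
                      strand = c("+", "-"))
  parts <- partition_genes(genes, flank = 5000, genome = g)
  get <- function(nm, pt) parts[parts$name == nm & parts$part == pt, ]
  expect_equal(unlist(get("p", "upstream")[, c("start", "end")],
                      use.names = FALSE), c(5001, 10000))
  expect_equal(unlist(get("p", "downstream")[, c("start", "end")],
                      use.names = FALSE), c(10001, 15000))
  expect_equal(unlist(get("p", "body")[, c("start", "end")],
                      use.names = FALSE), c(10001, 20000))
  # minus strand mirrors around the 5' TSS at the gene end
  expect_equal(unlist(get("m", "upstream")[, c("start", "end")],
                      use.names = FALSE), c(20001, 25000))
  expect_equal(unlist(get("m", "downstream")[, c("start", "end")],
                      use.names = FALSE), c(15001, 20000))

  # TSS at position 1: upstream clipped to empty
  g1 <- data.frame(name = "e", chrom = "c", start = 1, end = 500,
                   strand = "+")
  pe <- partition_genes(g1, genome = g)
  up <- pe[pe$part == "upstream", ]
  expect_true(up$start > up$end)
  expect_error(partition_genes(genes, flank = 0), "flank")
})

test_that("signal aggregation log-transforms per-part counts and excludes geneless bins", {
  g <- bin_genome(c(c = 3e6), window = 1e6)
  genes <- data.frame(name = c("g1", "g2"), chrom = "c",
                      start = c(100001, 1200001), end = c(160000, 1250000),
                      strand = "+")
  # 7 reads in g1's body, none elsewhere
  reads <- data.frame(chrom = "c", start = seq(110000, 140000, 5000),
                      end = seq(110000, 140000, 5000) + 35)
  s <- aggregate_signal(reads, genes, g, part = "body")
  expect_equal(s$per_gene$value[s$per_gene$gene == "g1"], log2(7 + 1))
  expect_equal(s$per_gene$value[s$per_gene$gene == "g2"], log2(0 + 1))
  expect_equal(s$per_bin$mean_log[s$per_bin$bin == 1], 3)
  expect_equal(s$excluded_bins, 3L)              # bin 3 has no gene TSS
  # zero reads everywhere: all included bins at log2(1) = 0
  s0 <- aggregate_signal(reads[0, ], genes, g, part = "body")
  expect_true(all(s0$per_bin$mean_log == 0))
  # excluded set identical across parts for a fixed annotation
  for (pt in c("upstream", "downstream"))
    expect_equal(aggregate_signal(reads, genes, g, part = pt)$excluded_bins,
                 s$excluded_bins)
})

test_that("enrichment test recovers planted shifts and is null on identity", {
  same <- make_summary(sprintf("g%d", 1:50), rnorm(50))
  res <- enrichment_test(same, same, list(all = sprintf("g%d", 1:50)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(19)
  genes <- sprintf("g%03d", 1:200)
  x0 <- rnorm(200, 5, 1)
  x1 <- rnorm(200, 6, 1)                         # +1 log-unit planted shift
  s0 <- make_summary(genes, x0); s1 <- make_summary(genes, x1)
  res <- enrichment_test(s1, s0, list("gain-intra" = genes))
  expect_gt(res$statistic, 0)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$direction, 1)
  # T sign agrees with the mean difference, both directions
  res_dn <- enrichment_test(s0, s1, list(x = genes))
  expect_lt(res_dn$statistic, 0)
  # Mann-Whitney agrees in direction
  mw <- enrichment_test(s1, s0, list(x = genes), test = "mann-whitney")
  expect_equal(mw$direction, 1)
  expect_lt(mw$p_value, 0.01)
  # sets below 2 members are undefined
  tiny <- enrichment_test(s1, s0, list(x = "g001"))
  expect_true(is.na(tiny$statistic))
})

test_that("peaks are assigned to bins by midpoint", {
  g <- bin_genome(c(c = 3e6), window = 1e6)
  expect_equal(peaks_per_bin(data.frame(chrom = character(0),
                                        start = numeric(0),
                                        end = numeric(0)), g),
               integer(3))
  peaks <- data.frame(chrom = "c",
                      start = c(100, 999000, 2100000),
                      end = c(300, 999400, 2100200))
  expect_equal(peaks_per_bin(peaks, g), c(2L, 0L, 1L))
  # midpoint rule: a peak straddling a boundary goes to its midpoint bin
  straddle <- data.frame(chrom = "c", start = 999900, end = 1000300)
  expect_equal(peaks_per_bin(straddle, g), c(0L, 1L, 0L))
})

test_that("rank association recovers planted peak-frequency coupling", {
  set.seed(23)
  g <- bin_genome(c(a = 60e6, b = 60e6), window = 1e6)
  prof <- interaction_frequency(as_zscore(g, matrix(0, 120, 120),
                                          matrix(FALSE, 120, 120)))
  rho <- replicate(20, {
    prof$frequency <- runif(120, 0.02, 0.4)
    counts <- rpois(120, 5 + 200 * prof$frequency)
    rank_association(counts, prof)
  })
  expect_true(all(rho > 0.8))
  # no peaks: association undefined
  expect_true(is.na(rank_association(rep(0, 120), prof)))
})

test_that("break-point enrichment reproduces closed forms and the oracle tail", {
  g <- bin_genome(c(c = 20e6), window = 1e6)
  prof <- interaction_frequency(as_zscore(g, matrix(0, 20, 20),
                                          matrix(FALSE, 20, 20)))
  prof$frequency <- rep(0.01, 20); prof$frequency[1:2] <- 0.5
  hot <- call_regions(prof, hot_threshold = 30)
  # zero overlap with many break-points: p ~ 1
  bp_none <- data.frame(chrom = "c", pos = seq(3e6, 19e6, 1e6) + 5)
  r0 <- breakpoint_overlap(bp_none, hot, g)
  expect_equal(r0$overlap, 0L)
  expect_gt(r0$p_value, 0.4)
  # all break-points inside hot bins: p = (hot fraction)^n exactly
  bp_all <- data.frame(chrom = "c", pos = rep(c(5e5, 15e5), 3))
  r1 <- breakpoint_overlap(bp_all, hot, g)
  expect_equal(r1$overlap, 6L)
  expect_equal(r1$p_value, (2 / 20)^6, tolerance = 1e-12)
  # log-space tail matches an independent logsumexp oracle
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(50:400, 1); k <- sample(10:40, 1); p <- runif(1, 0.002, 0.02)
    lp <- stats::pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
    expect_equal(lp, log10_binom_tail(k, n, p), tolerance = 1e-9)
  }
  # monotone decreasing in the overlap count
  tails <- sapply(1:6, function(k)
    stats::pbinom(k - 1, 6, 0.1, lower.tail = FALSE, log.p = TRUE))
  expect_true(all(diff(tails) < 0))
  # empty hot set: undefined
  r_na <- breakpoint_overlap(bp_all, hot[0, ], g)
  expect_true(is.na(r_na$p_value))
})

test_that("expression correlation over shared genes matches direct Pearson", {
  e0 <- c(a = 1, b = 2, c = 3, d = 5)
  expect_equal(expression_correlation(e0, e0)$r, 1)
  expect_equal(expression_correlation(e0, 2 * e0)$r, 1)   # affine invariance
  e1 <- c(a = 2, b = 1, c = 5, d = 4)
  byhand <- sum((e0 - mean(e0)) * (e1 - mean(e1))) /
    sqrt(sum((e0 - mean(e0))^2) * sum((e1 - mean(e1))^2))
  expect_equal(expression_correlation(e0, e1)$r, byhand)
  expect_equal(expression_correlation(e0, e1, gene_set = c("a", "b", "c"))$n_genes, 3)
  expect_true(is.na(expression_correlation(e0, c(a = 1, b = 1, c = 1, d = 1))$r))
  expect_error(expression_correlation(e0, c(a = 1, b = 2)), "3 shared")
})

test_that("DE enrichment chi-square matches the textbook formula", {
  all_genes <- sprintf("g%03d", 1:200)
  region <- all_genes[1:100]
  de <- c(all_genes[1:30], all_genes[101:110])   # table [[30,70],[10,90]]
  res <- de_enrichment_chisq(de, region, all_genes)
  O <- matrix(c(30, 70, 10, 90), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E))
  expect_equal(res$p_value,
               stats::pchisq(sum((O - E)^2 / E), 1, lower.tail = FALSE))
  expect_false(res$expected_warning)
  # identical DE proportion inside and outside: statistic 0, p 1
  de_even <- c(all_genes[1:20], all_genes[101:120])
  res0 <- de_enrichment_chisq(de_even, region, all_genes)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # empty DE set: degenerate margin handled
  res_e <- de_enrichment_chisq(character(0), region, all_genes)
  expect_equal(res_e$statistic, 0)
  expect_error(de_enrichment_chisq(de, c(region, "zz"), all_genes), "subset")
})
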