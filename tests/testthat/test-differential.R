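test_that("exponential strength honours the no-interaction sentinel", {
  expect_equal(exp_strength(5, FALSE), 0)
  expect_equal(exp_strength(-3, FALSE), 0)
  expect_equal(exp_strength(0, TRUE), 1)
  expect_equal(exp_strength(log(2), TRUE), 2)
})

test_that("relative ratio maps fold changes to the calibration anchors", {
  # 2-fold
  expect_equal(round(relative_ratio(0, TRUE, log(2), TRUE), 2), 0.67)
  # 5-fold
  expect_equal(round(relative_ratio(0, TRUE, log(5), TRUE), 2), 1.33)
  # 10-fold: exact value 18/11
  expect_equal(relative_ratio(0, TRUE, log(10), TRUE), 18 / 11)
  # equal strengths
  expect_equal(relative_ratio(1.3, TRUE, 1.3, TRUE), 0)
  # condition-exclusive cells saturate at +/-2
  expect_equal(relative_ratio(0.4, FALSE, -1, TRUE), 2)
  expect_equal(relative_ratio(-1, TRUE, 0.4, FALSE), -2)
  # both unobserved: excluded zero
  expect_equal(relative_ratio(3, FALSE, -3, FALSE), 0)
})

test_that("ratio is bounded, antisymmetric and inverts the fold-change form", {
  set.seed(13)
  z0 <- rnorm(500, 0, 2); z1 <- rnorm(500, 0, 2)
  o0 <- runif(500) < 0.8; o1 <- runif(500) < 0.8
  r <- relative_ratio(z0, o0, z1, o1)
  expect_true(all(abs(r) <= 2))
  expect_equal(relative_ratio(z1, o1, z0, o0), -r)
  # closed form and round trip on doubly observed cells
  both <- o0 & o1
  k <- exp(z1 - z0)[both]
  expect_equal(r[both], fold_change_to_ratio(k))
  expect_lt(max(abs(ratio_to_fold_change(r[both]) - k) / k), 1e-12)
  # strict monotonicity in the fold change
  ks <- sort(runif(100, 0.01, 50))
  expect_true(all(diff(fold_change_to_ratio(ks)) > 0))
})

test_that("relative-ratio matrix flags cells unobserved in both conditions", {
  g <- bin_genome(c(a = 2e6, b = 1e6), window = 1e6)
  m0 <- matrix(FALSE, 3, 3); m0[1, 2] <- m0[2, 1] <- TRUE
  m1 <- matrix(FALSE, 3, 3); m1[1, 3] <- m1[3, 1] <- TRUE
  z0 <- as_zscore(g, matrix(0.5, 3, 3) * m0, m0)
  z1 <- as_zscore(g, matrix(1.5, 3, 3) * m1, m1)
  r <- relative_ratio_matrix(z0, z1)
  expect_equal(r[1, 2], -2)
  expect_equal(r[1, 3], 2)
  expect_equal(r[2, 3], 0)
  expect_true(attr(r, "excluded")[2, 3])
  expect_false(attr(r, "excluded")[1, 2])
})

test_that("identical conditions yield no differential calls", {
  set.seed(3)
  g <- bin_genome(c(a = 5e6, b = 4e6), window = 1e6)
  z <- random_zscore(g)
  expect_equal(nrow(classify_differential(z, z)), 0L)
})

test_that("a condition-exclusive cell is called iff its Z clears the cut", {
  g <- bin_genome(c(a = 2e6, b = 2e6), window = 1e6)
  m0 <- matrix(FALSE, 4, 4)
  m1 <- matrix(FALSE, 4, 4); m1[1, 2] <- m1[2, 1] <- TRUE
  z1v <- matrix(0, 4, 4); z1v[1, 2] <- z1v[2, 1] <- 1.5
  z0 <- as_zscore(g, matrix(0, 4, 4), m0)
  z1 <- as_zscore(g, z1v, m1)
  calls <- classify_differential(z0, z1)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "gain-intra")
  expect_equal(calls$ratio, 2)
  expect_equal(calls$bin1, 1L); expect_equal(calls$bin2, 2L)

  # threshold boundary: Z = 0.5 fails z_cut = 1, passes z_cut = 0.4
  z1v[1, 2] <- z1v[2, 1] <- 0.5
  z1b <- as_zscore(g, z1v, m1)
  expect_equal(nrow(classify_differential(z0, z1b)), 0L)
  expect_equal(nrow(classify_differential(z0, z1b, z_cut = 0.4)), 1L)
  expect_error(classify_differential(z0, z1b, ratio_cut = 0), "ratio_cut")
})

test_that("classification matches the brute-force oracle and partitions cells", {
  set.seed(17)
  for (rep in 1:8) {
    g <- bin_genome(c(a = sample(3:8, 1) * 1e6, b = sample(2:6, 1) * 1e6,
                      c = sample(2:6, 1) * 1e6)[1:3], window = 1e6)
    z0 <- random_zscore(g, p_obs = 0.5)
    z1 <- random_zscore(g, p_obs = 0.5)
    for (cuts in list(c(2, 1), c(0.67, -Inf), c(1.2, 0))) {
      got <- classify_differential(z0, z1, ratio_cut = cuts[1],
                                   z_cut = cuts[2])
      want <- brute_force_calls(z0, z1, ratio_cut = cuts[1],
                                z_cut = cuts[2])
      expect_equal(nrow(got), nrow(want))
      key <- function(d) sort(paste(d$bin1, d$bin2, d$type))
      expect_equal(key(got), key(want))
      # partition: each unordered pair at most once, one type each
      expect_false(any(duplicated(got[, c("bin1", "bin2")])))
      # intra/inter agrees with chromosome equality
      expect_equal(grepl("intra", got$type),
                   got$chrom1 == got$chrom2)
    }
  }
})

test_that("relaxed mode lowers the ratio cut and drops the Z cut", {
  g <- bin_genome(c(a = 2e6), window = 1e6)
  m <- matrix(TRUE, 2, 2)
  z0 <- as_zscore(g, matrix(c(0, 0, 0, 0), 2), m)
  z1 <- as_zscore(g, matrix(c(0, log(2), log(2), 0), 2), m)  # 2-fold, r = 0.67
  expect_equal(nrow(classify_differential(z0, z1, mode = "strict")), 0L)
  relaxed <- classify_differential(z0, z1, mode = "relaxed")
  expect_equal(nrow(relaxed), 1L)
  expect_equal(relaxed$type, "gain-intra")
})

test_that("gain/loss profile increments both endpoint bins", {
  g <- bin_genome(c(a = 4e6, b = 4e6), window = 1e6)
  empty <- classify_differential(as_zscore(g, matrix(0, 8, 8), matrix(FALSE, 8, 8)),
                                 as_zscore(g, matrix(0, 8, 8), matrix(FALSE, 8, 8)))
  gl0 <- gain_loss_profile(empty, g)
  expect_true(all(gl0$gains == 0) && all(gl0$losses == 0))

  calls <- data.frame(bin1 = c(7, 2, 3, 3), bin2 = c(8, 7, 6, 3),
                      type = c("gain-intra", "gain-inter", "loss-inter",
                               "gain-intra"))
  gl <- gain_loss_profile(calls, g)
  expect_equal(gl$gains[7], 2)                   # two gain calls touch bin 7
  expect_equal(gl$gains[3], 1)                   # self-pair counted once
  expect_equal(gl$losses[3], -1)
  expect_equal(gl$losses[6], -1)
  expect_equal(sum(gl$gains) - sum(abs(gl$losses)),
               2 * 2 + 1 - 2)                    # endpoint bookkeeping
  top <- top_changed_regions(gl, n = 2)
  expect_equal(top$bin, c(3L, 7L))               # both total 2, tie by position
  expect_equal(top$total, c(2, 2))
})
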