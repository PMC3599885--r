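test_that("contact matrix counts pairs per unordered bin pair with dedup", {
  g <- bin_genome(c(c1 = 3e6, c2 = 2e6), window = 1e6)
  empty <- data.frame(chrom1 = character(0), pos1 = numeric(0),
                      chrom2 = character(0), pos2 = numeric(0))
  cm <- build_contact_matrix(empty, g)
  expect_true(all(cm$counts == 0))

  pairs <- data.frame(chrom1 = c("c1", "c1", "c1"),
                      pos1 = c(10, 10, 10),
                      chrom2 = c("c1", "c1", "c2"),
                      pos2 = c(20, 20, 5))
  cm <- build_contact_matrix(pairs, g, dedup = TRUE)
  expect_equal(cm$n_retained, 2L)
  expect_equal(cm$counts[1, 1], 2 - 1)          # c1:10-c1:20 deduplicated
  expect_equal(cm$counts[1, 4], 1)              # c1:10-c2:5
  expect_equal(sum(cm$counts[upper.tri(cm$counts, diag = TRUE)]), 2)

  # same-bin pair increments the diagonal once
  cm2 <- build_contact_matrix(
    data.frame(chrom1 = "c1", pos1 = 100, chrom2 = "c1", pos2 = 900), g)
  expect_equal(cm2$counts[1, 1], 1)
})

test_that("pairs are unordered and deduplication is idempotent", {
  g <- bin_genome(c(a = 4e6, b = 3e6), window = 1e6)
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    p <- data.frame(chrom1 = sample(c("a", "b"), n, TRUE),
                    pos1 = sample(3e6, n),
                    chrom2 = sample(c("a", "b"), n, TRUE),
                    pos2 = sample(3e6, n))
    swapped <- data.frame(chrom1 = p$chrom2, pos1 = p$pos2,
                          chrom2 = p$chrom1, pos2 = p$pos1)
    expect_equal(build_contact_matrix(p, g)$counts,
                 build_contact_matrix(swapped, g)$counts)
    once <- build_contact_matrix(p, g, dedup = TRUE)
    twice <- build_contact_matrix(rbind(p, p), g, dedup = TRUE)
    expect_equal(once$counts, twice$counts)
    expect_equal(once$n_retained, twice$n_retained)
    # symmetry and nonnegativity
    expect_equal(once$counts, t(once$counts))
    expect_true(all(once$counts >= 0))
  }
})

test_that("out-of-bounds and unknown-chromosome pairs fail with the pair index", {
  g <- bin_genome(c(a = 1e6), window = 1e6)
  expect_error(build_contact_matrix(
    data.frame(chrom1 = "a", pos1 = 10, chrom2 = "zz", pos2 = 10), g),
    "unknown chromosome 'zz'")
  expect_error(build_contact_matrix(
    data.frame(chrom1 = c("a", "a"), pos1 = c(5, 5),
               chrom2 = c("a", "a"), pos2 = c(10, 2e6)), g),
    "pair 2")
})

test_that("expected matrix gives per-distance intra means and global inter mean", {
  # 4-bin single chromosome with explicit counts; per-distance means by hand
  g <- bin_genome(c(c = 4e6), window = 1e6)
  C <- matrix(0, 4, 4)
  C[1, 2] <- 2; C[2, 3] <- 4; C[3, 4] <- 0     # d = 1: mean (2+4+0)/3 = 2
  C[1, 3] <- 5; C[2, 4] <- 1                   # d = 2: mean 3
  C[1, 4] <- 7                                 # d = 3: mean 7
  diag(C) <- c(1, 1, 1, 1)                     # d = 0: mean 1
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  cm <- structure(list(genome = g, counts = C, condition = NA), class = "contact_matrix")
  E <- expected_matrix(cm)
  expect_equal(diag(E), rep(1, 4))
  expect_equal(E[1, 2], 2); expect_equal(E[3, 4], 2)
  expect_equal(E[1, 3], 3); expect_equal(E[2, 4], 3)
  expect_equal(E[1, 4], 7)
  expect_true(attr(E, "usable")[1, 2])

  # constant intra counts => expected equals that constant everywhere
  C2 <- matrix(3, 4, 4)
  cm2 <- structure(list(genome = g, counts = C2, condition = NA), class = "contact_matrix")
  expect_true(all(expected_matrix(cm2) == 3))

  # all-zero matrix => every cell unusable
  cm0 <- structure(list(genome = g, counts = matrix(0, 4, 4), condition = NA),
                   class = "contact_matrix")
  expect_false(any(attr(expected_matrix(cm0), "usable")))
})

test_that("inter-chromosomal expectation is the global inter mean", {
  g <- bin_genome(c(a = 2e6, b = 2e6), window = 1e6)
  C <- matrix(0, 4, 4)
  C[1, 3] <- 2; C[1, 4] <- 4; C[2, 3] <- 0; C[2, 4] <- 6
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  cm <- structure(list(genome = g, counts = C, condition = NA), class = "contact_matrix")
  E <- expected_matrix(cm)
  expect_equal(E[1, 3], 3); expect_equal(E[2, 4], 3)  # (2+4+0+6)/4
})

test_that("zscore transform standardizes observed ratios with population SD", {
  g <- bin_genome(c(c = 3e6), window = 1e6)
  # three observed intra cells with ratios 1, 2, 3 (expected forced to 1)
  C <- matrix(0, 3, 3)
  C[1, 2] <- 1; C[1, 3] <- 2; C[2, 3] <- 3
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  cm <- structure(list(genome = g, counts = C, condition = NA), class = "contact_matrix")
  E <- matrix(1, 3, 3)
  attr(E, "usable") <- matrix(TRUE, 3, 3)
  z <- zscore_transform(cm, E)
  s <- sqrt(2 / 3)                               # population SD of {1,2,3}
  expect_equal(z$z[1, 2], (1 - 2) / s)
  expect_equal(z$z[1, 3], 0)
  expect_equal(z$z[2, 3], (3 - 2) / s)
  expect_equal(z$z, t(z$z))
  # sentinel: unobserved cells are 0 with mask FALSE
  expect_false(z$mask[1, 1])
  expect_equal(z$z[1, 1], 0)
  # observed-cell count equals mask cardinality
  expect_equal(sum(z$mask[upper.tri(z$mask, diag = TRUE)]), 3L)
})

test_that("counts equal to expected give all-zero Z with mask preserved", {
  g <- bin_genome(c(c = 3e6), window = 1e6)
  C <- matrix(2, 3, 3)
  cm <- structure(list(genome = g, counts = C, condition = NA), class = "contact_matrix")
  z <- zscore_transform(cm, expected_matrix(cm))
  expect_true(all(z$z == 0))
  expect_true(all(z$mask))                       # distinguishable from sentinel
})

test_that("unusable expectation under an observed count is an error naming the cell", {
  g <- bin_genome(c(c = 2e6), window = 1e6)
  C <- matrix(c(0, 3, 3, 0), 2, 2)
  cm <- structure(list(genome = g, counts = C, condition = NA), class = "contact_matrix")
  E <- matrix(0, 2, 2)
  attr(E, "usable") <- matrix(FALSE, 2, 2)
  expect_error(zscore_transform(cm, E), "\\(1, 2\\)")
})

test_that("Z-scores are invariant to uniform count rescaling", {
  set.seed(5)
  g <- bin_genome(c(a = 6e6, b = 4e6), window = 1e6)
  n <- 120
  p <- data.frame(chrom1 = sample(c("a", "b"), n, TRUE),
                  pos1 = sample(4e6, n),
                  chrom2 = sample(c("a", "b"), n, TRUE),
                  pos2 = sample(4e6, n))
  cm <- build_contact_matrix(p, g, dedup = FALSE)
  z1 <- zscore_transform(cm, expected_matrix(cm))
  cm3 <- cm
  cm3$counts <- cm$counts * 3
  z3 <- zscore_transform(cm3, expected_matrix(cm3))
  expect_equal(z1$z, z3$z, tolerance = 1e-12)
  expect_equal(z1$mask, z3$mask)
})
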