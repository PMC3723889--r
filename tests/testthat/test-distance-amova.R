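test_that("pairwise distances: trivial cases and exact squared-Euclidean equivalence", {
  mm <- make_mm(rbind(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(unname(pairwise_distance(mm)[1, 2]), 0)
  mm2 <- make_mm(rbind(c(1, 1, 0), c(0, 1, 0)))
  expect_equal(unname(pairwise_distance(mm2)[1, 2]), 1)
  withr::with_seed(3, {
    x <- matrix(rbinom(120, 1, 0.5), 8, 15)
    d <- pairwise_distance(make_mm(x))
    expect_equal(unname(as.matrix(dist(x))^2), unname(unclass(d)[, ]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("missing-data rescaling matches the naive double-loop oracle", {
  withr::with_seed(7, {
    for (rep in 1:4) {
      x <- matrix(rbinom(200, 1, 0.5), 10, 20)
      x[matrix(runif(200) < 0.2, 10, 20)] <- NA
      d <- pairwise_distance(make_mm(x))
      expect_equal(unname(unclass(d)[, ]), oracle_distance(x),
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  })
})

test_that("a pair with no shared informative locus is an error naming the pair", {
  x <- rbind(c(1, NA), c(NA, 0), c(1, 0))
  expect_error(pairwise_distance(make_mm(x)), "share no informative locus")
})

test_that("AMOVA recovers null and saturated structure", {
  # no among-group structure: both groups drawn from one distribution
  withr::with_seed(37, {
    x <- matrix(rbinom(24 * 40, 1, 0.5), 24, 40)
    d <- pairwise_distance(make_mm(x))
    fit <- amova(d, rep(c("g1", "g2"), each = 12), n_permutations = 199,
                 seed = 3)
    expect_lt(abs(fit$phi_st), 0.15)
    expect_gt(fit$permutation_p, 0.05)
  })
  # two internally identical, mutually distinct groups
  a <- c(1, 1, 0, 0, 1); b <- c(0, 0, 1, 1, 0)
  y <- rbind(a, a, a, a, b, b, b, b)
  d2 <- pairwise_distance(make_mm(y))
  fit2 <- amova(d2, rep(c("g1", "g2"), each = 4), n_permutations = 0)
  expect_equal(fit2$phi_st, 1)
  expect_error(amova(d2, c(rep("g1", 7), "g2"), 0), "size 1")
})

test_that("variance components match the explicit pair-loop oracle", {
  withr::with_seed(13, {
    for (rep in 1:4) {
      x <- matrix(rbinom(12 * 20, 1, 0.5), 12, 20)
      d <- pairwise_distance(make_mm(x))
      g <- sample(rep(c("A", "B", "C"), each = 4))
      fit <- amova(d, g, n_permutations = 0)
      ref <- oracle_amova(unclass(d)[, ], g)
      expect_equal(unname(fit$ss["ss_among"]), ref$ss_among, tolerance = 1e-10)
      expect_equal(unname(fit$ss["ss_within"]), ref$ss_within, tolerance = 1e-10)
      expect_equal(fit$sigma2_among, ref$sigma2_among, tolerance = 1e-10)
      expect_equal(fit$sigma2_within, ref$sigma2_within, tolerance = 1e-10)
      expect_equal(fit$phi_st, ref$phi_st, tolerance = 1e-10)
    }
  })
})

test_that("permutation p-values are uniform under the null", {
  withr::with_seed(29, {
    ps <- replicate(250, {
      x <- matrix(rbinom(12 * 12, 1, 0.5), 12, 12)
      d <- pairwise_distance(make_mm(x))
      amova(d, rep(c("A", "B"), each = 6), n_permutations = 19,
            seed = sample.int(1e6, 1))$permutation_p
    })
    # p takes values k/20; chi-square GOF over four equal bins
    counts <- table(cut(ps, breaks = c(0, 0.25, 0.5, 0.75, 1)))
    expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.001)
  })
})

test_that("pairwise Phi-st equals AMOVA on each subset and ignores label names", {
  withr::with_seed(31, {
    x <- matrix(rbinom(15 * 25, 1, 0.5), 15, 25)
    d <- pairwise_distance(make_mm(x))
    g <- rep(c("A", "B", "C"), each = 5)
    pw <- pairwise_phist(d, g, n_permutations = 49, seed = 5)
    expect_equal(nrow(pw), 3)
    idx <- g %in% c("A", "B")
    direct <- amova(unclass(d)[idx, idx], g[idx], n_permutations = 49, seed = 5)
    expect_equal(pw$phi_st[pw$group1 == "A" & pw$group2 == "B"],
                 direct$phi_st, tolerance = 1e-12)
    # renaming groups leaves the values unchanged
    g2 <- c(A = "Z", B = "Y", C = "X")[g]
    pw2 <- pairwise_phist(d, g2, n_permutations = 49, seed = 5)
    expect_equal(sort(pw2$phi_st), sort(pw$phi_st), tolerance = 1e-12)
  })
})
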