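# Build a methylation matrix realising a given 2 x k site-by-state table.
mm_from_table <- function(tab) {
  k <- ncol(tab)
  states <- unlist(lapply(seq_len(k), function(j) {
    c(rep(0L, tab[1, j]), rep(1L, tab[2, j]))
  }))
  sites <- rep(paste0("S", seq_len(k)), colSums(tab))
  make_mm(matrix(states, ncol = 1), sites = sites)
}

test_that("Fisher site test: homogeneous sites give p = 1", {
  tab <- matrix(10, 2, 3)
  mm <- mm_from_table(tab)
  res <- fisher_site_test(mm, mm$loci$id[1])
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  expect_false(res$flagged)
})

test_that("Fisher p equals complete enumeration of margin-fixed tables", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  mm <- mm_from_table(tab)
  expect_equal(fisher_site_test(mm, mm$loci$id[1])$p_value,
               oracle_fisher(tab), tolerance = 1e-12)
  withr::with_seed(17, {
    for (rep in 1:20) {
      tab <- matrix(rbinom(6, 10, runif(1, 0.2, 0.8)) + 1, 2, 3)
      mm <- mm_from_table(tab)
      expect_equal(fisher_site_test(mm, mm$loci$id[1])$p_value,
                   oracle_fisher(tab), tolerance = 1e-9)
    }
  })
})

test_that("monomorphic locus is flagged with p = 1", {
  mm <- make_mm(matrix(0L, 12, 1), sites = rep(c("A", "B"), each = 6))
  res <- fisher_site_test(mm, mm$loci$id[1])
  expect_true(res$flagged)
  expect_equal(res$p_value, 1)
})

test_that("q-values reduce to Benjamini-Hochberg at pi0 = 1 and are monotone", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      p <- runif(40)^2
      q <- qvalues(p, pi0 = 1)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
    # estimated pi0 <= 1 implies q <= BH
    p <- c(runif(60)^3, runif(40))
    expect_true(all(qvalues(p) <= oracle_bh(p) + 1e-12))
  })
  expect_equal(qvalues(rep(1, 20), pi0 = 0.7), rep(0.7, 20))
  expect_warning(q_small <- qvalues(c(0.01, 0.5)), "pi0 = 1")
  expect_equal(q_small, oracle_bh(c(0.01, 0.5)))
})

test_that("expected false positives among significant tests is q x count", {
  tests <- data.frame(locus = paste0("l", 1:30),
                      p_value = c(rep(0.01, 24), rep(0.8, 6)),
                      q_value = c(rep(0.0024, 24), rep(0.9, 6)),
                      significant = c(rep(TRUE, 24), rep(FALSE, 6)))
  expect_equal(round(expected_false_positives(tests), 3), 0.058)
})

test_that("polymorphism summary matches an exhaustive column scan", {
  x <- cbind(rep(0L, 30), c(1L, rep(0L, 29)), rep(1L, 30))
  mm <- make_mm(x)
  pol <- polymorphism_summary(mm)
  expect_equal(pol$n_polymorphic[pol$combination == "all"], 1)
  expect_equal(attr(pol, "polymorphic"), mm$loci$id[2])
  # minority-frequency cutoff excludes the singleton
  pol5 <- polymorphism_summary(mm, min_freq = 0.05)
  expect_equal(pol5$n_polymorphic[pol5$combination == "all"], 0)
  withr::with_seed(19, {
    y <- matrix(rbinom(300, 1, 0.2), 15, 20)
    y[matrix(runif(300) < 0.1, 15, 20)] <- NA
    mm2 <- make_mm(y)
    scan <- sum(apply(y, 2, function(col) {
      col <- col[!is.na(col)]
      length(col) > 0 && length(unique(col)) == 2
    }))
    pol2 <- polymorphism_summary(mm2)
    expect_equal(pol2$n_polymorphic[pol2$combination == "all"], scan)
  })
})

test_that("significant-locus union reports sizes of both sets and their overlap", {
  mk <- function(sig, all = paste0("l", 1:60)) {
    data.frame(locus = all, p_value = 0.5, q_value = 0.5,
               significant = all %in% sig)
  }
  a <- paste0("l", 1:24)
  b <- paste0("l", c(10:24, 40:44))   # 20 loci, 15 shared
  un <- significant_locus_union(mk(a), mk(b))
  expect_equal(un$n1, 24); expect_equal(un$n2, 20)
  expect_equal(un$n_intersection, 15); expect_equal(un$n_union, 29)
  expect_equal(significant_locus_union(mk(a), mk(paste0("l", 30:35)))$n_union,
               30)
  expect_equal(significant_locus_union(mk(a), mk(paste0("l", 1:5)))$n_union,
               24)
})
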