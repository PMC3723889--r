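mm_pair <- function(sporo, gameto, sites = NULL) {
  sporo <- as.matrix(sporo); gameto <- as.matrix(gameto)
  list(
    s = make_mm(sporo, sites = sites, generation = "sporophyte", prefix = "L"),
    g = make_mm(gameto, sites = sites, generation = "gametophyte",
                prefix = "P")
  )
}

test_that("change outcomes follow the comparison and resolution rules", {
  p <- mm_pair(rbind(c(0, NA, NA, 1, 0)), rbind(c(1, NA, 0, 1, 0)))
  ct <- build_change_table(p$s, p$g)
  expect_equal(ct$outcome, c("change_0to1", "excluded", "resolved_1to0",
                             "no_change", "no_change"))
  expect_equal(ct$change, c(TRUE, NA, TRUE, FALSE, FALSE))
  # copy resolution never registers a change at resolved comparisons
  ct2 <- build_change_table(p$s, p$g, resolve = "copy")
  expect_equal(ct2$outcome[3], "resolved_no_change")
  # single-missing with methylated partner resolves to no change
  p2 <- mm_pair(rbind(c(NA, 1)), rbind(c(1, NA)))
  ct3 <- build_change_table(p2$s, p2$g)
  expect_equal(ct3$outcome, c("resolved_no_change", "resolved_no_change"))
})

test_that("full design with no exclusions keeps individuals x loci rows", {
  withr::with_seed(53, {
    x <- matrix(rbinom(60 * 107, 1, 0.5), 60, 107)
    y <- matrix(rbinom(60 * 107, 1, 0.5), 60, 107)
    p <- mm_pair(x, y, sites = rep(c("A", "B", "C"), each = 20))
    ct <- build_change_table(p$s, p$g)
    expect_equal(nrow(ct), 6420)
    expect_equal(sum(ct$outcome == "excluded"), 0)
    # conservation: retained + excluded = individuals x loci, and per-locus
    # change counts sum to the overall numerator
    x[sample(length(x), 500)] <- NA
    y[sample(length(y), 500)] <- NA
    p2 <- mm_pair(x, y, sites = rep(c("A", "B", "C"), each = 20))
    ct2 <- build_change_table(p2$s, p2$g)
    cs <- change_summary(ct2)
    expect_equal(cs$n_retained + cs$n_excluded, 6420)
    inst <- locus_instability(ct2)
    expect_equal(sum(inst$n_changed), cs$n_changed)
    expect_equal(sum(inst$n_compared), cs$n_retained)
  })
})

test_that("unpaired individuals are a hard error naming them", {
  p <- mm_pair(matrix(0, 2, 3), matrix(0, 2, 3))
  p$g$samples$individual[2] <- "stranger"
  expect_error(build_change_table(p$s, p$g), "ind2|stranger")
})

test_that("change summary counts rates and direction shares", {
  # 10 comparisons, 3 changes: 2 up, 1 down
  p <- mm_pair(matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0, 0), 1),
               matrix(c(1, 1, 0, 0, 0, 1, 1, 1, 0, 0), 1))
  cs <- change_summary(build_change_table(p$s, p$g))
  expect_equal(cs$rate, 0.3)
  expect_equal(cs$prop_0to1, 2 / 3)
  expect_equal(cs$prop_1to0, 1 / 3)
  # no changes: rate 0, directions flagged undefined
  p0 <- mm_pair(matrix(0, 2, 4), matrix(0, 2, 4))
  cs0 <- change_summary(build_change_table(p0$s, p0$g))
  expect_equal(cs0$rate, 0)
  expect_true(cs0$degenerate)
  expect_true(is.na(cs0$prop_0to1))
})

test_that("locus instability uses exact binomial intervals and the arcsin transform", {
  s <- matrix(0L, 60, 2)
  g <- s; g[1:30, 2] <- 1L
  p <- mm_pair(s, g, sites = rep(c("A", "B", "C"), each = 20))
  inst <- locus_instability(build_change_table(p$s, p$g))
  # 0 of 60: Clopper-Pearson closed form for the zero-count bound
  expect_equal(inst$instability[1], 0)
  expect_equal(inst$ci_low[1], 0)
  expect_equal(inst$ci_high[1], 1 - 0.025^(1 / 60), tolerance = 1e-9)
  # 30 of 60: p = 1/2, arcsin(sqrt(1/2)) = pi/4
  expect_equal(inst$instability[2], 0.5)
  expect_equal(inst$arcsin[2], pi / 4, tolerance = 1e-12)
  # random tables match an exhaustive tally
  withr::with_seed(59, {
    x <- matrix(rbinom(300, 1, 0.5), 20, 15)
    y <- matrix(rbinom(300, 1, 0.5), 20, 15)
    x[sample(300, 40)] <- NA; y[sample(300, 40)] <- NA
    pp <- mm_pair(x, y, sites = rep(c("A", "B"), each = 10))
    ct <- build_change_table(pp$s, pp$g)
    inst2 <- locus_instability(ct)
    for (j in sample(15, 5)) {
      rows <- ct[ct$locus == pp$s$loci$id[j] & ct$outcome != "excluded", ]
      expect_equal(inst2$instability[inst2$locus == pp$s$loci$id[j]],
                   mean(rows$change))
    }
  })
})

test_that("per-individual rates and Kruskal-Wallis match a rank-based oracle", {
  withr::with_seed(61, {
    x <- matrix(rbinom(18 * 40, 1, 0.5), 18, 40)
    y <- matrix(rbinom(18 * 40, 1, 0.5), 18, 40)
    p <- mm_pair(x, y, sites = rep(c("A", "B", "C"), each = 6))
    res <- individual_change_rates(build_change_table(p$s, p$g))
    expect_equal(res$kruskal$statistic,
                 oracle_kruskal(res$per_individual$proportion,
                                res$per_individual$site),
                 tolerance = 1e-10)
    expect_equal(res$kruskal$df, 2)
  })
  # identical proportions everywhere: degenerate, H = 0
  s <- matrix(0L, 6, 4); g <- s; g[, 1] <- 1L
  p0 <- mm_pair(s, g, sites = rep(c("A", "B", "C"), each = 2))
  res0 <- individual_change_rates(build_change_table(p0$s, p0$g))
  expect_true(res0$degenerate)
  expect_equal(res0$kruskal$statistic, 0)
  # a site with a single individual is an error
  p1 <- mm_pair(matrix(0, 3, 4), matrix(0, 3, 4), sites = c("A", "A", "B"))
  expect_error(individual_change_rates(build_change_table(p1$s, p1$g)),
               "fewer than 2")
})
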