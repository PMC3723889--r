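test_that("size filter keeps fragments at or above the cutoff, order preserved", {
  bm <- make_bm(matrix(0, 2, 3), sizes = c(120, 150, 300))
  kept <- filter_fragments_by_size(bm, 150)
  expect_equal(kept$fragments$size_bp, c(150, 300))
  expect_identical(filter_fragments_by_size(bm, 0)$fragments, bm$fragments)
  expect_equal(ncol(filter_fragments_by_size(make_bm(matrix(0, 2, 1),
                                                     sizes = 149))$values), 0)
  expect_error(filter_fragments_by_size(bm, -1), "min_bp")
})

test_that("replicate error rates are discordance ratios", {
  # 36 replicate pairs; fragment 1 discordant in 2 samples per enzyme arm,
  # fragment 2 fully concordant
  n <- 36
  v <- matrix(0L, n, 2)
  orig <- list(hpa = make_bm(v), msp = make_bm(v, enzyme = "MspI"))
  vr_h <- v; vr_h[1:2, 1] <- 1L
  vr_m <- v; vr_m[3:4, 1] <- 1L
  repl <- list(hpa = make_bm(vr_h), msp = make_bm(vr_m, enzyme = "MspI"))
  prof <- estimate_error_rates(orig, repl)
  expect_equal(prof$per_fragment$rate[1], 4 / 72, tolerance = 1e-12)
  expect_equal(round(prof$per_fragment$rate[1], 4), 0.0556)
  expect_equal(prof$per_fragment$rate[2], 0)
  expect_equal(prof$replicate_count, 36)
  # all concordant -> all-zero rates
  prof0 <- estimate_error_rates(orig, list(hpa = make_bm(v),
                                           msp = make_bm(v, enzyme = "MspI")))
  expect_true(all(prof0$per_fragment$rate == 0))
})

test_that("overall error rate is the locus-weighted mean across combinations", {
  # per-combination rates and locus counts as in a four-combination assay
  rates <- c(C1 = 0.041, C2 = 0.042, C3 = 0.046, C4 = 0.052)
  counts <- c(C1 = 36, C2 = 44, C3 = 47, C4 = 16)
  pf <- do.call(rbind, lapply(names(rates), function(cc) {
    data.frame(id = paste0(cc, ":f", seq_len(counts[[cc]]), ":200"),
               combination = cc, size_bp = 200, n_scored = 72,
               n_discordant = 3, rate = rates[[cc]], flagged = FALSE)
  }))
  prof <- structure(list(per_fragment = pf, median_rate = median(pf$rate),
                         replicate_count = 36, pooling = "pooled"),
                    class = "error_profile")
  cr <- combination_error_rates(prof)
  expect_equal(cr$rate, unname(rates[cr$combination]))
  expect_equal(round(100 * overall_error_rate(prof), 1), 4.4)
})

test_that("error filter retains rates strictly below the median", {
  bm <- make_bm(matrix(0, 2, 4))
  pf <- data.frame(id = bm$fragments$id, combination = "C1", size_bp = 200,
                   n_scored = 72, n_discordant = 0,
                   rate = c(0.02, 0.04, 0.06, 0.08), flagged = FALSE)
  prof <- structure(list(per_fragment = pf, median_rate = median(pf$rate),
                         replicate_count = 36, pooling = "pooled"),
                    class = "error_profile")
  expect_equal(filter_fragments_by_error(bm, prof)$fragments$id,
               bm$fragments$id[1:2])
  # all rates tied at the median: strict rule drops everything
  prof$per_fragment$rate <- rep(0.05, 4)
  prof$median_rate <- 0.05
  expect_equal(ncol(filter_fragments_by_error(bm, prof)$values), 0)
  expect_equal(ncol(filter_fragments_by_error(bm, prof, strict = FALSE)$values),
               4)
})

test_that("error filter matches a sort-based oracle on random rates", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      k <- 21
      rates <- round(runif(k, 0, 0.2), 3)
      bm <- make_bm(matrix(0, 2, k))
      pf <- data.frame(id = bm$fragments$id, combination = "C1", size_bp = 200,
                       n_scored = 72, n_discordant = 0, rate = rates,
                       flagged = FALSE)
      prof <- structure(list(per_fragment = pf, median_rate = median(rates),
                             replicate_count = 36, pooling = "pooled"),
                        class = "error_profile")
      expected <- bm$fragments$id[rates < sort(rates)[(k + 1) / 2]]
      expect_equal(filter_fragments_by_error(bm, prof)$fragments$id, expected)
    }
  })
})

test_that("locus classification separates methylation-variable from genotype-only loci", {
  # 30 methylation-variable + 30 genotype-only loci, 60 samples, 4% error
  withr::with_seed(21, {
    n <- 60; e_meas <- 0.04
    e_flip <- (1 - sqrt(1 - 2 * e_meas)) / 2
    truth_ms <- c(rep(TRUE, 30), rep(FALSE, 30))
    h <- m <- matrix(0L, n, 60)
    for (l in 1:60) {
      if (truth_ms[l]) {
        state <- rbinom(n, 1, 0.5)             # methylated -> one-arm band
        arm <- rbinom(n, 1, 0.5)
        h[, l] <- ifelse(state == 1, arm, 1L)
        m[, l] <- ifelse(state == 1, 1L - arm, 1L)
      } else {
        pres <- rbinom(n, 1, 0.8)              # same pattern in both arms
        h[, l] <- pres; m[, l] <- pres
      }
    }
    flip <- function(x) ifelse(matrix(runif(length(x)), nrow(x)) < e_flip,
                               1L - x, x)
    hpa <- make_bm(flip(h)); msp <- make_bm(flip(m), enzyme = "MspI")
    pf <- data.frame(id = hpa$fragments$id, combination = "C1", size_bp = 200,
                     n_scored = 72, n_discordant = 3, rate = e_meas,
                     flagged = FALSE)
    prof <- structure(list(per_fragment = pf, median_rate = e_meas,
                           replicate_count = 36, pooling = "pooled"),
                      class = "error_profile")
    cls <- classify_loci(hpa, msp, prof)
    got_ms <- cls$loci$class == "methylation_susceptible"
    expect_gte(sum(got_ms == truth_ms), 55)
    # discordance equals the mean element-wise XOR (oracle)
    expect_equal(cls$loci$discordance,
                 unname(colMeans(xor(hpa$values == 1, msp$values == 1))))
    # compound threshold
    expect_equal(unique(cls$loci$threshold), 1 - (1 - e_meas)^2)
  })
})

test_that("zero discordance is non-methylated; clear exceedance is MS; zero error implies zero MS", {
  h <- matrix(c(1, 1, 1, 1, 1, 0, 0, 1), 4, 2)
  m <- matrix(c(1, 1, 1, 1, 0, 1, 1, 0), 4, 2)
  hpa <- make_bm(h); msp <- make_bm(m, enzyme = "MspI")
  pf <- data.frame(id = hpa$fragments$id, combination = "C1", size_bp = 200,
                   n_scored = 72, n_discordant = 3, rate = 0.045,
                   flagged = FALSE)
  prof <- structure(list(per_fragment = pf, median_rate = 0.045,
                         replicate_count = 36, pooling = "pooled"),
                    class = "error_profile")
  cls <- classify_loci(hpa, msp, prof)
  expect_equal(cls$loci$class,
               c("non_methylated", "methylation_susceptible"))
  # no scoring error + no methylation variation -> zero MS loci
  hpa0 <- make_bm(matrix(rbinom(80, 1, 0.5), 8, 10))
  msp0 <- make_bm(hpa0$values, enzyme = "MspI")
  pf0 <- data.frame(id = hpa0$fragments$id, combination = "C1", size_bp = 200,
                    n_scored = 72, n_discordant = 0, rate = 0, flagged = FALSE)
  prof0 <- structure(list(per_fragment = pf0, median_rate = 0,
                          replicate_count = 36, pooling = "pooled"),
                     class = "error_profile")
  cls0 <- classify_loci(hpa0, msp0, prof0)
  expect_true(all(cls0$loci$class == "non_methylated"))
})

test_that("three-condition scoring maps band pairs to states deterministically", {
  h <- matrix(c(1, 1, 0, 0), 4, 1)
  m <- matrix(c(1, 0, 1, 0), 4, 1)
  hpa <- make_bm(h); msp <- make_bm(m, enzyme = "MspI")
  mm <- score_methylation(hpa, msp)
  expect_equal(as.vector(mm$values), c(0L, 1L, 1L, NA))
  # purity: re-applying to identical inputs yields identical output
  expect_identical(mm$values, score_methylation(hpa, msp)$values)
  # three-state partition covers every cell
  withr::with_seed(5, {
    hb <- make_bm(matrix(rbinom(200, 1, 0.5), 10, 20))
    mb <- make_bm(matrix(rbinom(200, 1, 0.5), 10, 20), enzyme = "MspI")
    mm2 <- score_methylation(hb, mb)
    counts <- c(sum(mm2$values == 0, na.rm = TRUE),
                sum(mm2$values == 1, na.rm = TRUE), sum(is.na(mm2$values)))
    expect_equal(sum(counts), 10 * 20)
  })
  # misaligned matrices are a hard error
  expect_error(score_methylation(hpa, bm_subset(msp, sample_ids = "s1")),
               "mismatched sample")
})
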