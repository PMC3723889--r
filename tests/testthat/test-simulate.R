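quiet_cfg <- function(...) sim_config(..., calibrate = FALSE)

test_that("identical configuration and seed give byte-identical datasets", {
  cfg <- quiet_cfg()
  d1 <- simulate_msap(cfg, seed = 99)
  d2 <- simulate_msap(cfg, seed = 99)
  expect_identical(d1$hpa$values, d2$hpa$values)
  expect_identical(d1$msp$values, d2$msp$values)
  expect_identical(d1$replicates$hpa$values, d2$replicates$hpa$values)
  expect_identical(d1$truth$sporophyte, d2$truth$sporophyte)
  d3 <- simulate_msap(cfg, seed = 100)
  expect_false(identical(d1$hpa$values, d3$hpa$values))
})

test_that("with all noise channels off, scoring inverts the rendering exactly", {
  cfg <- quiet_cfg(error_rates = c(C1 = 0, C2 = 0, C3 = 0, C4 = 0),
                   fragment_absence = 0, hyper_prob = 0)
  ds <- simulate_msap(cfg, seed = 7)
  mm <- score_methylation(ds$hpa, ds$msp)   # no classification filter
  ms_ids <- colnames(ds$truth$sporophyte)
  leaf <- paste0(rownames(ds$truth$sporophyte), "_L")
  pollen <- paste0(rownames(ds$truth$gametophyte), "_P")
  expect_equal(unname(mm$values[leaf, ms_ids]),
               unname(ds$truth$sporophyte))
  expect_equal(unname(mm$values[pollen, ms_ids]),
               unname(ds$truth$gametophyte))
  expect_false(anyNA(mm$values[, ms_ids]))
})

test_that("zero site offsets give near-zero Phi-st; zero change rates copy the sporophyte", {
  cfg0 <- quiet_cfg(site_offset_sd = 0)
  phis <- vapply(1:8, function(i) {
    tr <- generate_sporophytes(cfg0, seed = 200 + i)
    d <- pairwise_distance(tr$sporophyte)
    amova(d, tr$individuals$site, n_permutations = 0)$phi_st
  }, numeric(1))
  expect_lt(abs(mean(phis)), 0.03)

  cfg_null <- quiet_cfg(change_rates = c(TEJ = 0, NAV = 0, PLL = 0))
  tr <- generate_sporophytes(cfg_null, seed = 5)
  tr <- generate_gametophytes(tr, seed = 5)
  expect_identical(tr$gametophyte, tr$sporophyte)
  expect_false(any(tr$change))
})

test_that("replicate re-scoring recovers the configured per-fragment error rates", {
  cfg <- quiet_cfg()
  ds <- simulate_msap(cfg, seed = 11)
  prof <- estimate_error_rates(list(hpa = ds$hpa, msp = ds$msp),
                               ds$replicates)
  pf <- prof$per_fragment
  truth <- ds$truth$fragments
  true_rate <- 2 * truth$flip_rate * (1 - truth$flip_rate)
  true_rate <- true_rate[match(pf$id, truth$id)]
  # per fragment, the measured discordance count should be binomially
  # consistent with the truth-implied replicate discordance probability
  # (which equals the fragment's configured discordance-scale rate)
  covered <- mapply(function(x, n, p) {
    binom.test(x, n, p)$p.value > 0.01
  }, pf$n_discordant, pf$n_scored, pmin(true_rate, 0.999))
  expect_gt(mean(covered), 0.9)
  # and the overall mean tracks the configured scale
  expect_lt(abs(mean(pf$rate) - mean(true_rate)), 0.005)
})

test_that("at uniform 4% scoring error, most non-methylated loci classify correctly", {
  cfg <- quiet_cfg(error_rates = c(C1 = 0.04, C2 = 0.04, C3 = 0.04,
                                   C4 = 0.04), error_sdlog = 0.1)
  ds <- simulate_msap(cfg, seed = 31)
  prof <- estimate_error_rates(list(hpa = ds$hpa, msp = ds$msp),
                               ds$replicates)
  sp <- ds$metadata$sample_id[ds$metadata$generation == "sporophyte"]
  hpa <- bm_subset(filter_fragments_by_size(ds$hpa), sample_ids = sp)
  msp <- bm_subset(filter_fragments_by_size(ds$msp), sample_ids = sp)
  cls <- classify_loci(hpa, msp, prof)$loci
  truth <- ds$truth$fragments
  true_nm <- truth$class[match(cls$id, truth$id)] == "NM"
  expect_gte(mean(cls$class[true_nm] == "non_methylated"), 0.9)
  # and methylation-variable loci are essentially all recovered
  expect_gte(mean(cls$class[!true_nm] == "methylation_susceptible"), 0.95)
})

test_that("realized change rate and direction on truth match the latent process", {
  cfg <- default_config()
  tr <- generate_sporophytes(cfg, seed = 301)
  tr <- generate_gametophytes(tr, seed = 301)
  chg <- tr$change
  stab <- tr$fragments$stability[match(colnames(chg), tr$fragments$id)]
  # unstable loci change much more often than stable loci
  rate_stable <- mean(chg[, stab == "stable"])
  rate_unstable <- mean(chg[, stab == "unstable"])
  expect_gt(rate_unstable, 5 * rate_stable)
  # direction of true changes is predominantly 0 -> 1
  up <- tr$sporophyte == 0 & chg
  expect_gt(sum(up) / sum(chg), 0.85)
})
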