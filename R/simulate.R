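#' Configuration for the MSAP study simulator
#'
#' Defines the study conditions emulated by the generator: three sites of 20
#' individuals sampled in two generations (sporophyte leaf and descendant
#' pollen gametophyte), four primer combinations whose retained loci follow
#' the 36/44/47/16 allocation with 22/37/36/12 methylation-susceptible (MS)
#' loci, per-combination scoring error rates of 4.1-5.2% (replicate
#' discordance scale), site-differentiated methylation frequencies tuned to a
#' target multilocus Phi-st, a gametogenesis change process with ~75% stable
#' loci, measured per-site change rates of 0.137/0.180/0.162, and an 80.3%
#' bias of changes toward the methylated state.
#'
#' Because the observable quantities are measured through noisy band scoring
#' (scoring error alone induces apparent changes), the latent process
#' parameters that realise the configured *measured* targets are obtained by
#' empirical calibration: bisection on the site-offset scale until the
#' pipeline-measured sporophyte Phi-st hits `target_phist`, and a fixed-point
#' iteration on the latent site rates and direction bias until the measured
#' change rate and direction share hit their targets.  Calibration is
#' deterministic given `seed` and cached within the session.
#'
#' @param sites site names (default the three study sites).
#' @param n_individuals individuals per site (default 20).
#' @param locus_allocation named integer vector: target retained loci per
#'   primer combination.
#' @param ms_allocation named integer vector: target retained MS loci per
#'   combination (rest are non-methylated).
#' @param error_rates named vector: mean scoring error rate (replicate
#'   discordance proportion) of retained fragments per combination.
#' @param oversample fragments rendered per retained target; the error-rate
#'   median filter removes about half, so 2 reproduces the retained counts.
#' @param n_undersized extra fragments below the size cutoff (exercise the
#'   size filter; default 12).
#' @param size_range retained fragment size range in bp.
#' @param target_phist measured multilocus sporophyte Phi-st aimed for by
#'   calibration (default 0.3).
#' @param site_offset_sd logit-scale SD of per-site frequency offsets at
#'   polymorphic MS loci; set by calibration unless `calibrate = FALSE`.
#' @param ms_poly_fraction fraction of MS loci with intermediate (variable)
#'   methylation frequency; the rest are near-fixed methylated.
#' @param poly_freq_range baseline frequency range of variable MS loci.
#' @param fixed_meth_freq methylation frequency of near-fixed MS loci.
#' @param nm_poly_fraction fraction of non-methylated loci with a
#'   genotypically polymorphic fragment.
#' @param nm_poly_freq_range fragment-presence frequency range of polymorphic
#'   non-methylated loci.
#' @param fragment_absence probability that an individual genotypically lacks
#'   an MS fragment (contributes uninformative double absences).
#' @param hyper_prob probability that a methylated cell renders as a double
#'   absence (hypermethylation), per generation.
#' @param stable_fraction fraction of MS loci in the stable class (default
#'   0.748).
#' @param unstable_multiplier change-rate multiplier of unstable loci; the
#'   stable multiplier is set so the class mixture preserves the overall rate.
#' @param change_rates named vector of target measured per-site change rates
#'   (proportion of retained comparisons registering a change).
#' @param direction_bias target measured share of changes that go
#'   non-methylated to methylated (default 0.803).
#' @param replicate_fraction fraction of samples re-assayed for error
#'   estimation (default 0.30).
#' @param error_sdlog log-scale SD of the per-fragment error-rate
#'   distribution.
#' @param seed master seed; all generator randomness derives from it.
#' @param calibrate run the empirical calibration (default TRUE).
#' @param calibration_reps simulated datasets per calibration evaluation.
#' @param calibration_tol tolerance on the calibrated measured Phi-st.
#' @return Object of class `sim_config`; `$latent` holds the calibrated
#'   latent parameters (`site_offset_sd`, `site_rates`, `bias`).
#' @export
sim_config <- function(sites = c("TEJ", "NAV", "PLL"),
                       n_individuals = 20,
                       locus_allocation = c(C1 = 36, C2 = 44, C3 = 47, C4 = 16),
                       ms_allocation = c(C1 = 22, C2 = 37, C3 = 36, C4 = 12),
                       error_rates = c(C1 = 0.041, C2 = 0.042, C3 = 0.046,
                                       C4 = 0.052),
                       oversample = 2,
                       n_undersized = 12,
                       size_range = c(150, 500),
                       target_phist = 0.3,
                       site_offset_sd = 1.2,
                       ms_poly_fraction = 0.45,
                       poly_freq_range = c(0.15, 0.85),
                       fixed_meth_freq = 0.95,
                       nm_poly_fraction = 0.222,
                       nm_poly_freq_range = c(0.3, 0.9),
                       fragment_absence = 0.12,
                       hyper_prob = 0.15,
                       stable_fraction = 0.748,
                       unstable_multiplier = 3.7,
                       change_rates = c(TEJ = 0.137, NAV = 0.180, PLL = 0.162),
                       direction_bias = 0.803,
                       replicate_fraction = 0.30,
                       error_sdlog = 0.6,
                       seed = 1,
                       calibrate = TRUE,
                       calibration_reps = 8,
                       calibration_tol = 0.02) {
  stopifnot(length(sites) >= 2, n_individuals >= 2,
            identical(names(locus_allocation), names(ms_allocation)),
            identical(names(locus_allocation), names(error_rates)),
            all(ms_allocation <= locus_allocation),
            all(error_rates >= 0 & error_rates < 0.5))
  probs <- c(ms_poly_fraction, nm_poly_fraction, fragment_absence, hyper_prob,
             stable_fraction, direction_bias, replicate_fraction,
             change_rates)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(sites %in% names(change_rates))) {
    stop("change_rates must be named by site")
  }
  mult_stable <- (1 - (1 - stable_fraction) * unstable_multiplier) /
    stable_fraction
  if (mult_stable <= 0) {
    stop("unstable_multiplier too large for stable_fraction")
  }

  cfg <- structure(
    list(sites = sites, n_individuals = n_individuals,
         locus_allocation = locus_allocation, ms_allocation = ms_allocation,
         error_rates = error_rates, oversample = oversample,
         n_undersized = n_undersized, size_range = size_range,
         target_phist = target_phist,
         ms_poly_fraction = ms_poly_fraction,
         poly_freq_range = poly_freq_range,
         fixed_meth_freq = fixed_meth_freq,
         nm_poly_fraction = nm_poly_fraction,
         nm_poly_freq_range = nm_poly_freq_range,
         fragment_absence = fragment_absence, hyper_prob = hyper_prob,
         stable_fraction = stable_fraction,
         unstable_multiplier = unstable_multiplier,
         mult_stable = mult_stable,
         change_rates = change_rates[sites],
         direction_bias = direction_bias,
         replicate_fraction = replicate_fraction,
         error_sdlog = error_sdlog, seed = as.integer(seed),
         calibrated = FALSE,
         latent = list(site_offset_sd = site_offset_sd,
                       site_rates = change_rates[sites],
                       bias = direction_bias)),
    class = "sim_config"
  )
  if (calibrate) {
    cfg <- calibrate_generator(cfg, reps = calibration_reps,
                               tol = calibration_tol)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "MSAP simulation config: %d sites x %d individuals x 2 generations, %d+%d target loci\n",
    length(x$sites), x$n_individuals, sum(x$ms_allocation),
    sum(x$locus_allocation) - sum(x$ms_allocation)
  ))
  cat(sprintf(
    "  target Phi-st %.2f | change rates %s | bias %.3f | %scalibrated\n",
    x$target_phist,
    paste(sprintf("%s=%.3f", names(x$change_rates), x$change_rates),
          collapse = " "),
    x$direction_bias, if (x$calibrated) "" else "NOT "
  ))
  invisible(x)
}

# deterministic sub-seeds below 2^31
sub_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647
}

#' Generate sporophyte ground truth
#'
#' Draws the fragment catalogue (combinations, sizes, MS/NM classes,
#' per-fragment error rates), per-locus methylation frequencies with
#' site-specific logit offsets at polymorphic MS loci, genotypic fragment
#' presence, and the true sporophyte methylation states (independent
#' Bernoulli per locus and individual).
#'
#' @param config a [sim_config()].
#' @param seed seed for this draw (default `config$seed`).
#' @return Object of class `ground_truth` (sporophyte part filled).
#' @export
generate_sporophytes <- function(config, seed = config$seed) {
  withr::with_seed(sub_seed(seed, 1), {
    combos <- names(config$locus_allocation)
    frag_list <- list()
    for (cc in combos) {
      n_c <- round(config$oversample * config$locus_allocation[[cc]])
      n_ms_c <- round(config$oversample * config$ms_allocation[[cc]])
      sizes <- sample(seq(config$size_range[1], config$size_range[2]), n_c,
                      replace = TRUE)
      cls <- c(rep("MS", n_ms_c), rep("NM", n_c - n_ms_c))
      frag_list[[cc]] <- data.frame(
        combination = cc, fragment = sprintf("f%03d", seq_len(n_c)),
        size_bp = sizes, class = cls, stringsAsFactors = FALSE
      )
    }
    # undersized fragments (size-filter fodder), spread over combinations
    if (config$n_undersized > 0) {
      cc <- rep(combos, length.out = config$n_undersized)
      frag_list[["undersized"]] <- data.frame(
        combination = cc,
        fragment = sprintf("u%03d", seq_len(config$n_undersized)),
        size_bp = sample(100:149, config$n_undersized, replace = TRUE),
        class = "NM", stringsAsFactors = FALSE
      )
    }
    frag <- do.call(rbind, frag_list)
    rownames(frag) <- NULL
    frag$id <- fragment_id(frag$combination, frag$fragment, frag$size_bp)

    # per-fragment error on the replicate-discordance scale; the lognormal
    # location is chosen so that the retained (below-median) half averages
    # the configured combination rate: E[X | X < median] = t requires
    # exp(mu) = t / (exp(s^2/2) * 2 * pnorm(-s))
    target <- config$error_rates[frag$combination]
    if (all(target == 0)) {
      frag$error_rate <- rep(0, nrow(frag))
    } else {
      s <- config$error_sdlog
      loc_mult <- 1 / (exp(s^2 / 2) * 2 * pnorm(-s))
      frag$error_rate <- pmin(0.45, pmax(
        0.002, rlnorm(nrow(frag), log(loc_mult * pmax(target, 1e-4)), s)))
      frag$error_rate[target == 0] <- 0
    }
    frag$flip_rate <- (1 - sqrt(1 - 2 * frag$error_rate)) / 2

    ms_idx <- which(frag$class == "MS")
    n_ms <- length(ms_idx)
    n_poly <- round(config$ms_poly_fraction * n_ms)
    poly <- rep(FALSE, n_ms)
    poly[sample(n_ms, n_poly)] <- TRUE
    p <- ifelse(poly,
                runif(n_ms, config$poly_freq_range[1],
                      config$poly_freq_range[2]),
                config$fixed_meth_freq)

    # unstable loci drawn among low-frequency polymorphic loci so that the
    # strongly up-biased change process stays per-cell feasible (no capping)
    n_unstable <- round((1 - config$stable_fraction) * n_ms)
    eligible <- which(poly & p <= 0.35)
    if (length(eligible) < n_unstable) {
      eligible <- order(ifelse(poly, p, 1 + p))[seq_len(max(n_unstable,
                                                            length(eligible)))]
    }
    unstable <- rep(FALSE, n_ms)
    unstable[sample(eligible, n_unstable)] <- TRUE

    frag$stability <- NA_character_
    frag$stability[ms_idx] <- ifelse(unstable, "unstable", "stable")
    frag$baseline_freq <- NA_real_
    frag$baseline_freq[ms_idx] <- p

    # site-differentiation offsets act on stable polymorphic loci; unstable
    # loci keep their baseline frequency so the change process stays
    # per-cell feasible at every site
    n_sites <- length(config$sites)
    tau <- config$latent$site_offset_sd
    z <- matrix(0, n_ms, n_sites, dimnames = list(frag$id[ms_idx],
                                                  config$sites))
    offs <- which(!unstable)
    if (length(offs) > 0) {
      zi <- matrix(abs(rnorm(length(offs) * n_sites)), length(offs))
      signs <- matrix(sample(c(-1, 1), length(offs) * n_sites, TRUE),
                      length(offs))
      # a differentiated locus must contrast at least two sites: flip one
      # site's sign where the pattern came out constant
      const <- rowSums(signs == signs[, 1]) == n_sites
      if (any(const)) {
        flip <- cbind(which(const),
                      sample(n_sites, sum(const), replace = TRUE))
        signs[flip] <- -signs[flip]
      }
      z[offs, ] <- signs * zi
    }
    site_freqs <- plogis(qlogis(p) + tau * z)

    # genotype fragment-presence frequency
    nm_idx <- which(frag$class == "NM")
    q <- rep(1, nrow(frag))
    nm_poly <- runif(length(nm_idx)) < config$nm_poly_fraction
    q[nm_idx[nm_poly]] <- runif(sum(nm_poly), config$nm_poly_freq_range[1],
                                config$nm_poly_freq_range[2])
    q[ms_idx] <- 1 - config$fragment_absence
    frag$presence_freq <- q

    individuals <- data.frame(
      individual = paste0(rep(config$sites, each = config$n_individuals),
                          sprintf("%02d", seq_len(config$n_individuals))),
      site = rep(config$sites, each = config$n_individuals),
      stringsAsFactors = FALSE
    )
    n_ind <- nrow(individuals)
    site_i <- match(individuals$site, config$sites)

    pm <- matrix(runif(n_ind * nrow(frag)), n_ind) <
      matrix(q, n_ind, nrow(frag), byrow = TRUE)
    dimnames(pm) <- list(individuals$individual, frag$id)

    sp <- matrix(runif(n_ind * n_ms), n_ind) < site_freqs[, site_i, drop = FALSE] |>
      t()
    sp <- matrix(as.integer(sp), n_ind,
                 dimnames = list(individuals$individual, frag$id[ms_idx]))

    structure(
      list(config = config, fragments = frag, individuals = individuals,
           site_freqs = site_freqs, presence = pm, sporophyte = sp,
           gametophyte = NULL, change = NULL),
      class = "ground_truth"
    )
  })
}

#' Generate gametophyte ground truth from sporophyte truth
#'
#' Applies the gametogenesis change process: each (individual, MS locus) cell
#' changes state with a probability equal to the latent site rate times the
#' locus stability-class multiplier, split between the two directions so that
#' the expected direction share of changes equals the latent bias (a cell in
#' state 0 changes at rate `c*b/(1-p)`, a cell in state 1 at rate
#' `c*(1-b)/p`, with `p` the site-level methylation frequency of the locus).
#'
#' @param truth a `ground_truth` with the sporophyte part filled.
#' @param seed seed for this draw.
#' @return The `ground_truth` with `gametophyte` (state matrix) and `change`
#'   (logical matrix of true change events) filled.
#' @export
generate_gametophytes <- function(truth, seed = truth$config$seed) {
  config <- truth$config
  withr::with_seed(sub_seed(seed, 2), {
    sp <- truth$sporophyte
    n_ind <- nrow(sp)
    ms_ids <- colnames(sp)
    frag <- truth$fragments
    stab <- frag$stability[match(ms_ids, frag$id)]
    mult <- ifelse(stab == "unstable", config$unstable_multiplier,
                   config$mult_stable)
    site_i <- match(truth$individuals$site, config$sites)
    rates <- config$latent$site_rates[site_i]          # per individual
    b <- config$latent$bias

    p_ls <- pmin(0.97, pmax(0.03, truth$site_freqs[, site_i, drop = FALSE]))
    # cell change probabilities: rows loci, cols individuals
    c_cell <- sweep(matrix(mult, length(ms_ids), n_ind), 2, rates, `*`)
    r0 <- pmin(0.95, c_cell * b / (1 - p_ls))
    r1 <- pmin(0.95, c_cell * (1 - b) / p_ls)

    u <- matrix(runif(n_ind * length(ms_ids)), length(ms_ids), n_ind)
    spt <- t(sp)
    chg <- ifelse(spt == 0, u < r0, u < r1)
    gam <- ifelse(chg, 1L - spt, spt)

    truth$gametophyte <- t(gam)
    truth$change <- t(chg)
    dimnames(truth$gametophyte) <- dimnames(sp)
    dimnames(truth$change) <- dimnames(sp)
    truth
  })
}

#' Render observed band matrices from ground truth
#'
#' Inverts the three-condition scoring rule to produce the true HpaII/MspI
#' band pattern of every cell (non-methylated: both bands; methylated: one
#' band, arm chosen uniformly; hypermethylated or genotypically absent: no
#' band), then overlays independent per-cell scoring errors (bit flips at the
#' fragment's flip rate) and re-scores a replicate subset of samples for
#' error estimation.
#'
#' @param truth a complete `ground_truth` (both generations).
#' @param seed seed for this draw.
#' @return Object of class `msap_dataset`: band matrices `hpa`, `msp` over
#'   all samples (both generations), `replicates` (list of re-scored
#'   `hpa`/`msp` band matrices), `metadata`, and `truth` (with the noiseless
#'   band `patterns` attached).
#' @export
render_bands <- function(truth, seed = truth$config$seed) {
  config <- truth$config
  if (is.null(truth$gametophyte)) stop("gametophyte truth missing")
  withr::with_seed(sub_seed(seed, 3), {
    frag <- truth$fragments
    n_frag <- nrow(frag)
    ind <- truth$individuals
    n_ind <- nrow(ind)
    ms_ids <- colnames(truth$sporophyte)
    ms_col <- match(ms_ids, frag$id)

    pattern_one <- function(states) {
      # returns list(hpa, msp) 0/1 matrices n_ind x n_frag
      hpa <- matrix(0L, n_ind, n_frag, dimnames = list(ind$individual, frag$id))
      msp <- hpa
      nm <- which(frag$class == "NM")
      hpa[, nm] <- truth$presence[, nm]
      msp[, nm] <- truth$presence[, nm]
      pres <- truth$presence[, ms_col, drop = FALSE]
      st <- states
      hyper <- matrix(runif(n_ind * length(ms_ids)), n_ind) < config$hyper_prob
      arm_hpa <- matrix(runif(n_ind * length(ms_ids)), n_ind) < 0.5
      visible <- pres & !(st == 1 & hyper)
      h <- ifelse(visible & (st == 0 | arm_hpa), 1L, 0L)
      m <- ifelse(visible & (st == 0 | !arm_hpa), 1L, 0L)
      hpa[, ms_col] <- h
      msp[, ms_col] <- m
      list(hpa = hpa, msp = msp)
    }

    pat_s <- pattern_one(truth$sporophyte)
    pat_g <- pattern_one(truth$gametophyte)

    sample_ids <- c(paste0(ind$individual, "_L"), paste0(ind$individual, "_P"))
    metadata <- data.frame(
      sample_id = sample_ids,
      individual = rep(ind$individual, 2),
      site = rep(ind$site, 2),
      generation = rep(c("sporophyte", "gametophyte"), each = n_ind),
      stringsAsFactors = FALSE
    )
    stack <- function(a, b) {
      out <- rbind(a, b)
      rownames(out) <- sample_ids
      out
    }
    pat_hpa <- stack(pat_s$hpa, pat_g$hpa)
    pat_msp <- stack(pat_s$msp, pat_g$msp)

    flip <- function(pattern) {
      fr <- matrix(frag$flip_rate, nrow(pattern), n_frag, byrow = TRUE)
      flips <- matrix(runif(length(pattern)), nrow(pattern)) < fr
      out <- ifelse(flips, 1L - pattern, pattern)
      dimnames(out) <- dimnames(pattern)
      out
    }
    obs_hpa <- flip(pat_hpa)
    obs_msp <- flip(pat_msp)

    n_rep <- round(config$replicate_fraction * length(sample_ids))
    rep_ids <- sort(sample(sample_ids, n_rep))
    rep_hpa <- flip(pat_hpa[rep_ids, , drop = FALSE])
    rep_msp <- flip(pat_msp[rep_ids, , drop = FALSE])

    frag_df <- frag[, c("id", "combination", "size_bp")]
    meta_rep <- metadata[match(rep_ids, metadata$sample_id), , drop = FALSE]
    rownames(meta_rep) <- NULL
    truth$patterns <- list(hpa = pat_hpa, msp = pat_msp)
    structure(
      list(hpa = band_matrix(obs_hpa, metadata, frag_df, "HpaII"),
           msp = band_matrix(obs_msp, metadata, frag_df, "MspI"),
           replicates = list(
             hpa = band_matrix(rep_hpa, meta_rep, frag_df, "HpaII"),
             msp = band_matrix(rep_msp, meta_rep, frag_df, "MspI")),
           metadata = metadata,
           truth = truth),
      class = "msap_dataset"
    )
  })
}

#' Simulate a complete MSAP dataset
#'
#' Runs [generate_sporophytes()], [generate_gametophytes()] and
#' [render_bands()] in sequence.  Fully deterministic: identical
#' `(config, seed)` yield byte-identical datasets.
#'
#' @param config a [sim_config()].
#' @param seed seed for this dataset (default `config$seed`).
#' @return An `msap_dataset` with ground truth attached.
#' @export
simulate_msap <- function(config, seed = config$seed) {
  truth <- generate_sporophytes(config, seed = seed)
  truth <- generate_gametophytes(truth, seed = seed)
  render_bands(truth, seed = seed)
}

#' @export
print.msap_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated MSAP dataset: %d samples x %d fragments (+%d replicate samples)\n",
    nrow(x$hpa$values), ncol(x$hpa$values), nrow(x$replicates$hpa$values)
  ))
  invisible(x)
}

# ---- calibration ----------------------------------------------------------

.epimsap_cache <- new.env(parent = emptyenv())

config_key <- function(config) {
  core <- config[setdiff(names(config), c("latent", "calibrated"))]
  paste(deparse(core), collapse = "")
}

# Measured sporophyte Phi-st of one simulated dataset, through the full
# scoring pipeline (no permutations).
measure_phist <- function(config, rep_seed) {
  truth <- generate_sporophytes(config, seed = rep_seed)
  truth$gametophyte <- truth$sporophyte    # gametophytes irrelevant here
  truth$change <- truth$sporophyte * 0
  ds <- render_bands(truth, seed = rep_seed)
  sc <- score_msap(ds)
  mm_s <- mm_subset(sc$methylation,
                    sample_ids = sc$methylation$samples$sample_id[
                      sc$methylation$samples$generation == "sporophyte"])
  d <- pairwise_distance(mm_s)
  amova(d, mm_s$samples$site, n_permutations = 0)$phi_st
}

measure_change <- function(config, rep_seed) {
  ds <- simulate_msap(config, seed = rep_seed)
  sc <- score_msap(ds)
  mm <- sc$methylation
  split_mm <- function(gen) {
    mm_subset(mm, sample_ids = mm$samples$sample_id[mm$samples$generation == gen])
  }
  ct <- build_change_table(split_mm("sporophyte"), split_mm("gametophyte"))
  cs <- change_summary(ct)
  retained <- ct[ct$outcome != "excluded", , drop = FALSE]
  site_rate <- tapply(as.numeric(retained$change), retained$site, mean)
  list(rate = cs$rate, bias = cs$prop_0to1,
       site_rates = site_rate[config$sites])
}

#' Calibrate the generator's latent parameters
#'
#' Stage 1 bisects the logit-scale site-offset SD until the mean
#' pipeline-measured sporophyte Phi-st over `reps` simulated datasets hits
#' `target_phist` (within `tol`); an unattainable target is an error
#' reporting the attainable range.  Stage 2 runs a fixed-point iteration on
#' the latent per-site change rates and latent direction bias until the
#' measured per-site change rates and direction share match their configured
#' targets.  Deterministic given `config$seed`; results are cached per
#' configuration within the session.
#'
#' @param config a `sim_config`.
#' @param reps datasets per evaluation (default 8).
#' @param tol Phi-st tolerance (default 0.02).
#' @param max_iter bisection / fixed-point iteration caps.
#' @return The config with `$latent` replaced by calibrated values and
#'   `$calibrated = TRUE`.
#' @export
calibrate_generator <- function(config, reps = 8, tol = 0.02, max_iter = 12) {
  key <- config_key(config)
  hit <- .epimsap_cache[[key]]
  if (!is.null(hit)) {
    config$latent <- hit
    config$calibrated <- TRUE
    return(config)
  }
  rep_seeds <- vapply(seq_len(reps), function(i) sub_seed(config$seed, 100 + i),
                      numeric(1))

  mean_phi <- function(tau) {
    config$latent$site_offset_sd <- tau
    mean(vapply(rep_seeds, function(s) measure_phist(config, s), numeric(1)))
  }
  lo <- 0; hi <- 4
  phi_lo <- mean_phi(lo)
  phi_hi <- mean_phi(hi)
  if (config$target_phist > phi_hi + tol || config$target_phist < phi_lo - tol) {
    stop(sprintf(
      "target Phi-st %.3f unattainable; attainable range about [%.3f, %.3f]",
      config$target_phist, phi_lo, phi_hi))
  }
  tau <- hi
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    phi_mid <- mean_phi(mid)
    if (abs(phi_mid - config$target_phist) < tol) { tau <- mid; break }
    if (phi_mid < config$target_phist) lo <- mid else hi <- mid
    tau <- mid
  }
  config$latent$site_offset_sd <- tau

  # fixed point on latent site rates and bias; the final iterations use more
  # replicates so the residual per-site rate error stays well below the
  # between-site differences
  latent_rates <- config$change_rates
  latent_bias <- config$direction_bias
  for (it in 1:5) {
    config$latent$site_rates <- latent_rates
    config$latent$bias <- latent_bias
    it_seeds <- if (it <= 3) rep_seeds else {
      vapply(seq_len(3 * reps),
             function(i) sub_seed(config$seed, 300 * it + i), numeric(1))
    }
    meas <- lapply(it_seeds, function(s) measure_change(config, s))
    m_sites <- colMeans(do.call(rbind, lapply(meas, `[[`, "site_rates")))
    m_bias <- mean(vapply(meas, `[[`, numeric(1), "bias"))
    latent_rates <- pmin(0.6, pmax(
      1e-3, latent_rates * config$change_rates / m_sites))
    latent_bias <- pmin(0.99, pmax(0.5, latent_bias +
                                     (config$direction_bias - m_bias)))
  }
  config$latent$site_rates <- latent_rates
  config$latent$bias <- latent_bias
  config$calibrated <- TRUE
  .epimsap_cache[[key]] <- config$latent
  config
}
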