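#' Score an MSAP dataset into a methylation matrix
#'
#' The standard scoring stage: replicate-based error estimation, size
#' filtering, error-rate (below-median) filtering, locus classification on
#' the sporophyte samples, and three-condition methylation scoring of all
#' samples at the methylation-susceptible loci.
#'
#' @param dataset an `msap_dataset` (from [simulate_msap()] or
#'   [read_msap_dataset()]).
#' @param min_bp minimum fragment size (default 150).
#' @param strict strict below-median error filtering (default TRUE).
#' @param threshold_rule,combination_stat passed to [classify_loci()].
#' @return List: `error_profile`, `classification`, `methylation`
#'   (a `methylation_matrix` over all samples), `n_retained_fragments`.
#' @export
score_msap <- function(dataset, min_bp = 150, strict = TRUE,
                       threshold_rule = "compound",
                       combination_stat = "mean") {
  prof <- estimate_error_rates(list(hpa = dataset$hpa, msp = dataset$msp),
                               dataset$replicates)
  hpa <- filter_fragments_by_size(dataset$hpa, min_bp)
  msp <- filter_fragments_by_size(dataset$msp, min_bp)
  hpa <- filter_fragments_by_error(hpa, prof, strict)
  msp <- filter_fragments_by_error(msp, prof, strict)
  if (ncol(hpa$values) == 0) stop("no fragments retained after filtering")
  sp_ids <- dataset$metadata$sample_id[
    dataset$metadata$generation == "sporophyte"]
  cls <- classify_loci(bm_subset(hpa, sample_ids = sp_ids),
                       bm_subset(msp, sample_ids = sp_ids),
                       prof, threshold_rule = threshold_rule,
                       combination_stat = combination_stat)
  meth <- score_methylation(hpa, msp, cls)
  list(error_profile = prof, classification = cls, methylation = meth,
       n_retained_fragments = ncol(hpa$values))
}

#' Differentiation analyses for one generation
#'
#' Pairwise squared distances, one-level AMOVA with permutation-tested
#' Phi-st, pairwise Phi-st between all site pairs, per-locus Fisher tests
#' with q-values, polymorphism summary, and a two-dimensional NMDS
#' ordination.
#'
#' @param mm a `methylation_matrix` for one generation.
#' @param n_permutations AMOVA/pairwise permutations (default 9999).
#' @param seed RNG seed.
#' @param n_restarts NMDS restarts.
#' @return List: `distance`, `amova`, `pairwise`, `tests`, `polymorphism`,
#'   `nmds`.
#' @export
differentiate_msap <- function(mm, n_permutations = 9999, seed = 1,
                               n_restarts = 20) {
  d <- pairwise_distance(mm)
  fit <- amova(d, mm$samples$site, n_permutations = n_permutations,
               seed = seed)
  pw <- pairwise_phist(d, mm$samples$site, n_permutations = n_permutations,
                       seed = seed)
  tests <- fisher_site_tests(mm)
  poly <- polymorphism_summary(mm)
  ord <- nmds(d, n_restarts = n_restarts, seed = seed)
  list(distance = d, amova = fit, pairwise = pw, tests = tests,
       polymorphism = poly, nmds = ord)
}

#' Transgenerational (sporophyte to gametophyte) analyses
#'
#' Change table with ambiguity resolution, overall change summary, per-locus
#' instability, dip test of unimodality, stable/unstable mixture
#' classification, binomial GLM of change probability, per-individual change
#' rates with Kruskal-Wallis site test, the union of significantly
#' site-differentiated loci, and the joint sporophyte+gametophyte NMDS with
#' per-individual displacement vectors.
#'
#' @param meth_sporo,meth_gameto generation-specific `methylation_matrix`
#'   objects.
#' @param sporo_tests,gameto_tests per-locus test tables from
#'   [fisher_site_tests()].
#' @param n_null_reps dip-test Monte-Carlo replicates.
#' @param seed RNG seed.
#' @param n_restarts NMDS restarts.
#' @param resolve ambiguity resolution rule, see [build_change_table()].
#' @return List of stage results (see the individual functions).
#' @export
transgen_msap <- function(meth_sporo, meth_gameto, sporo_tests, gameto_tests,
                          n_null_reps = 2000, seed = 1, n_restarts = 20,
                          resolve = "hypermethylation") {
  ct <- build_change_table(meth_sporo, meth_gameto, resolve = resolve)
  cs <- change_summary(ct)
  inst <- locus_instability(ct)
  dip <- dip_test(inst$arcsin, n_null_reps = n_null_reps, seed = seed)
  stab <- classify_stability(inst, seed = seed)
  glm_fit <- change_glm(ct)
  rates <- individual_change_rates(ct)
  un <- significant_locus_union(sporo_tests, gameto_tests)
  joint <- if (un$n_union >= 2) {
    # with very few shared informative loci the restricted distance matrix
    # can be undefined for some pair; the joint ordination is then skipped
    tryCatch(
      joint_ordination(meth_sporo, meth_gameto, un$loci,
                       n_restarts = n_restarts, seed = seed),
      error = function(e) {
        warning("joint ordination skipped: ", conditionMessage(e))
        NULL
      })
  } else NULL
  list(change_table = ct, summary = cs, instability = inst, dip = dip,
       stability = stab, glm = glm_fit, individual_rates = rates,
       union = un, joint = joint)
}

#' Run the complete MSAP analysis pipeline
#'
#' Scoring, per-generation differentiation, and the transgenerational stage,
#' plus the cross-generation analyses on the significantly differentiated
#' locus subset (gametophyte AMOVA and the sporophyte/gametophyte Mantel
#' test).  Optionally writes all stage outputs, a JSON run summary and a run
#' manifest to a directory.
#'
#' @param x an `msap_dataset`.
#' @param n_permutations permutations for AMOVA/pairwise/Mantel
#'   (default 9999).
#' @param seed RNG seed for every stochastic stage.
#' @param n_restarts NMDS restarts.
#' @param dip_reps dip-test Monte-Carlo replicates.
#' @param out_dir optional output directory.
#' @param resolve ambiguity resolution rule for the change table.
#' @return Object of class `msap_run`: `scoring`, `sporophyte`,
#'   `gametophyte` (differentiation stages), `transgen`, `mantel`,
#'   `gametophyte_union_amova`, and `summary` (flat list of headline
#'   quantities).
#' @export
run_msap <- function(x, n_permutations = 9999, seed = 1, n_restarts = 20,
                     dip_reps = 2000, out_dir = NULL,
                     resolve = "hypermethylation") {
  if (!inherits(x, "msap_dataset")) stop("expected an msap_dataset")
  t0 <- Sys.time()
  sc <- score_msap(x)
  mm <- sc$methylation
  gen <- mm$samples$generation
  mm_s <- mm_subset(mm, sample_ids = mm$samples$sample_id[gen == "sporophyte"])
  mm_g <- mm_subset(mm, sample_ids = mm$samples$sample_id[gen == "gametophyte"])

  diff_s <- differentiate_msap(mm_s, n_permutations, seed, n_restarts)
  diff_g <- differentiate_msap(mm_g, n_permutations, seed, n_restarts)
  tg <- transgen_msap(mm_s, mm_g, diff_s$tests, diff_g$tests,
                      n_null_reps = dip_reps, seed = seed,
                      n_restarts = n_restarts, resolve = resolve)

  # cross-generation analyses on the significant-locus union
  un <- tg$union
  mantel_res <- NULL
  amova_g_union <- NULL
  if (un$n_union >= 2) {
    rel <- function(m) {
      d <- pairwise_distance(mm_subset(m, locus_ids = un$loci))
      dimnames(d) <- list(m$samples$individual, m$samples$individual)
      d
    }
    cross <- tryCatch({
      d_su <- rel(mm_s)
      d_gu <- rel(mm_g)[rownames(d_su), rownames(d_su)]
      list(
        mantel = tryCatch(
          mantel_test(d_su, d_gu, n_permutations = n_permutations,
                      seed = seed),
          error = function(e) NULL),
        amova = amova(d_gu, mm_g$samples$site[
          match(rownames(d_gu), mm_g$samples$individual)],
          n_permutations = n_permutations, seed = seed))
    }, error = function(e) {
      warning("union-locus cross-generation analyses skipped: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(cross)) {
      mantel_res <- cross$mantel
      amova_g_union <- cross$amova
    }
  }

  cls_tab <- table(sc$classification$loci$class)
  poly_s <- diff_s$polymorphism
  summary <- list(
    n_fragments_scored = ncol(x$hpa$values),
    n_retained_fragments = sc$n_retained_fragments,
    n_ms_loci = unname(cls_tab["methylation_susceptible"]),
    n_nm_loci = unname(cls_tab["non_methylated"]),
    pct_ms_polymorphic_sporophyte =
      poly_s$pct_polymorphic[poly_s$combination == "all"],
    phist_sporophyte = diff_s$amova$phi_st,
    phist_sporophyte_p = diff_s$amova$permutation_p,
    phist_gametophyte = diff_g$amova$phi_st,
    phist_gametophyte_p = diff_g$amova$permutation_p,
    pairwise_phist_sporophyte_range = range(diff_s$pairwise$phi_st),
    pairwise_phist_gametophyte_range = range(diff_g$pairwise$phi_st),
    n_significant_sporophyte = un$n1,
    n_significant_gametophyte = un$n2,
    n_significant_intersection = un$n_intersection,
    n_significant_union = un$n_union,
    n_comparisons_max = tg$summary$n_max,
    n_comparisons_retained = tg$summary$n_retained,
    change_rate = tg$summary$rate,
    prop_changes_0to1 = tg$summary$prop_0to1,
    dip_D = tg$dip$D,
    dip_p = tg$dip$p_value,
    n_stable = sum(tg$stability$cluster == "stable"),
    n_unstable = sum(tg$stability$cluster == "unstable"),
    stable_fraction = tg$stability$stable_fraction,
    glm_site_p = tg$glm$site_test$p_value,
    glm_locus_p = tg$glm$locus_test$p_value,
    site_change_probabilities = setNames(
      tg$glm$site_probabilities$probability, tg$glm$site_probabilities$site),
    kruskal_chisq = tg$individual_rates$kruskal$statistic,
    kruskal_df = tg$individual_rates$kruskal$df,
    kruskal_p = tg$individual_rates$kruskal$p_value,
    mantel_r = if (is.null(mantel_res)) NA_real_ else mantel_res$r,
    mantel_p = if (is.null(mantel_res)) NA_real_ else mantel_res$p_value,
    phist_gametophyte_union =
      if (is.null(amova_g_union)) NA_real_ else amova_g_union$phi_st,
    phist_gametophyte_union_p =
      if (is.null(amova_g_union)) NA_real_ else amova_g_union$permutation_p
  )

  run <- structure(
    list(scoring = sc, sporophyte = diff_s, gametophyte = diff_g,
         transgen = tg, mantel = mantel_res,
         gametophyte_union_amova = amova_g_union,
         summary = summary,
         settings = list(n_permutations = n_permutations, seed = seed,
                         n_restarts = n_restarts, dip_reps = dip_reps,
                         resolve = resolve),
         started = t0, finished = Sys.time()),
    class = "msap_run"
  )
  if (!is.null(out_dir)) write_msap_run(run, x, out_dir)
  run
}

#' @export
print.msap_run <- function(x, ...) {
  s <- x$summary
  cat("MSAP pipeline run\n")
  cat(sprintf("  retained fragments: %d (%d MS + %d NM)\n",
              s$n_retained_fragments, s$n_ms_loci, s$n_nm_loci))
  cat(sprintf("  Phi-st sporophyte %.3f (P=%.4g) | gametophyte %.3f (P=%.4g)\n",
              s$phist_sporophyte, s$phist_sporophyte_p,
              s$phist_gametophyte, s$phist_gametophyte_p))
  cat(sprintf("  change rate %.3f | share 0->1 %.3f | stable loci %.1f%%\n",
              s$change_rate, s$prop_changes_0to1, 100 * s$stable_fraction))
  cat(sprintf("  dip D = %.4f (P=%.4g) | Mantel r = %.3f (P=%.4g)\n",
              s$dip_D, s$dip_p, s$mantel_r, s$mantel_p))
  invisible(x)
}

#' Write pipeline outputs, summary and manifest to a directory
#'
#' @param run an `msap_run`.
#' @param dataset the `msap_dataset` analysed (digested into the manifest).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_msap_run <- function(run, dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_methylation_matrix(run$scoring$methylation, fp("methylation.tsv"))
  tsv(run$scoring$classification$loci, fp("locus_classification.tsv"))
  tsv(run$scoring$error_profile$per_fragment, fp("error_rates.tsv"))
  tsv(run$sporophyte$tests, fp("site_tests_sporophyte.tsv"))
  tsv(run$gametophyte$tests, fp("site_tests_gametophyte.tsv"))
  tsv(run$sporophyte$pairwise, fp("pairwise_phist_sporophyte.tsv"))
  tsv(run$gametophyte$pairwise, fp("pairwise_phist_gametophyte.tsv"))
  coords <- function(ord, path) {
    df <- data.frame(sample_id = rownames(ord$points), ord$points)
    names(df)[-1] <- paste0("MDS", seq_len(ncol(ord$points)))
    con <- file(path, "w")
    writeLines(sprintf("# stress-1 = %.6f", ord$stress), con)
    close(con)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
  }
  coords(run$sporophyte$nmds, fp("nmds_sporophyte.tsv"))
  coords(run$gametophyte$nmds, fp("nmds_gametophyte.tsv"))
  tsv(run$transgen$change_table, fp("change_table.tsv"))
  inst <- run$transgen$instability
  inst$cluster <- run$transgen$stability$cluster[inst$locus]
  tsv(inst, fp("instability.tsv"))
  if (!is.null(run$transgen$joint)) {
    coords(run$transgen$joint$ordination, fp("nmds_joint.tsv"))
    tsv(run$transgen$joint$displacement, fp("displacement.tsv"))
  }
  jw <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  jw(list(dip = unclass(run$transgen$dip),
          glm = list(site_test = run$transgen$glm$site_test,
                     locus_test = run$transgen$glm$locus_test,
                     site_probabilities = run$transgen$glm$site_probabilities,
                     separated_loci = run$transgen$glm$separated_loci),
          kruskal = run$transgen$individual_rates$kruskal),
     fp("transgen_tests.json"))
  jw(run$summary, fp("summary.json"))

  digest_bm <- function(bm) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    write_band_matrix(bm, tf)
    unname(tools::md5sum(tf))
  }
  manifest <- list(
    package = "epimsap",
    version = as.character(packageVersion("epimsap")),
    settings = run$settings,
    input_digests = list(hpa = digest_bm(dataset$hpa),
                         msp = digest_bm(dataset$msp),
                         replicates_hpa = digest_bm(dataset$replicates$hpa),
                         replicates_msp = digest_bm(dataset$replicates$msp)),
    started = format(run$started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(run$finished, "%Y-%m-%dT%H:%M:%S%z")
  )
  jw(manifest, fp("manifest.json"))
  invisible(out_dir)
}

#' Read or write a complete MSAP dataset as TSV files
#'
#' `write_msap_dataset()` writes the band matrices, replicate matrices,
#' sample metadata and (for simulated data) the ground-truth bundle;
#' `read_msap_dataset()` reads them back.
#'
#' @param dataset an `msap_dataset`.
#' @param dir directory.
#' @return The dataset (read) or `dir` (write, invisibly).
#' @export
write_msap_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_band_matrix(dataset$hpa, fp("hpa.tsv"))
  write_band_matrix(dataset$msp, fp("msp.tsv"))
  write_band_matrix(dataset$replicates$hpa, fp("replicates_hpa.tsv"))
  write_band_matrix(dataset$replicates$msp, fp("replicates_msp.tsv"))
  write_sample_metadata(dataset$metadata, fp("metadata.tsv"))
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    write.table(tr$fragments, fp("truth_fragments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    st <- function(m, path) {
      write.table(data.frame(individual = rownames(m), m, check.names = FALSE),
                  path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    st(tr$sporophyte, fp("truth_sporophyte.tsv"))
    st(tr$gametophyte, fp("truth_gametophyte.tsv"))
  }
  invisible(dir)
}

#' @rdname write_msap_dataset
#' @export
read_msap_dataset <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  meta <- read_sample_metadata(fp("metadata.tsv"))
  ds <- list(
    hpa = read_band_matrix(fp("hpa.tsv"), meta, "HpaII"),
    msp = read_band_matrix(fp("msp.tsv"), meta, "MspI"),
    replicates = list(
      hpa = read_band_matrix(fp("replicates_hpa.tsv"), meta, "HpaII"),
      msp = read_band_matrix(fp("replicates_msp.tsv"), meta, "MspI")),
    metadata = meta,
    truth = NULL
  )
  class(ds) <- "msap_dataset"
  ds
}
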