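#' Filter fragments by minimum size
#'
#' Retains only fragments whose size is at least `min_bp` base pairs.  Small
#' fragments are discarded to limit size homoplasy in AFLP-type assays.
#'
#' @param x a `band_matrix` or a fragment data frame with a `size_bp` column.
#' @param min_bp minimum fragment length in base pairs (default 150).
#' @return Object of the same type as `x`, restricted to retained fragments,
#'   order preserved.
#' @export
filter_fragments_by_size <- function(x, min_bp = 150) {
  if (min_bp < 0) stop("min_bp must be >= 0")
  UseMethod("filter_fragments_by_size")
}

#' @export
filter_fragments_by_size.band_matrix <- function(x, min_bp = 150) {
  keep <- x$fragments$id[x$fragments$size_bp >= min_bp]
  bm_subset(x, fragment_ids = keep)
}

#' @export
filter_fragments_by_size.data.frame <- function(x, min_bp = 150) {
  x[x$size_bp >= min_bp, , drop = FALSE]
}

#' Estimate per-fragment scoring error rates from replicate assays
#'
#' A subset of samples is assayed twice; the error rate of a fragment is the
#' proportion of discordant scores between the two independent analyses.  By
#' default discordances are pooled across the HpaII and MspI arms of each
#' replicate pair; `pooling = "per_arm"` averages the two arm-specific rates
#' instead (identical when both arms score the same replicate set).
#'
#' @param original named list with elements `hpa` and `msp`: the primary
#'   `band_matrix` objects (full sample set).
#' @param replicate named list with elements `hpa` and `msp`: re-assayed
#'   scores for a subset of the samples, same fragments.
#' @param pooling `"pooled"` or `"per_arm"`.
#' @return An object of class `error_profile`: a list with `per_fragment`
#'   (data frame: `id`, `combination`, `size_bp`, `n_scored`, `n_discordant`,
#'   `rate`, `flagged`), `median_rate` (median of unflagged per-fragment
#'   rates), `replicate_count` and `pooling`.  Fragments with zero scored
#'   replicate samples are flagged and excluded from the median.
#' @export
estimate_error_rates <- function(original, replicate,
                                 pooling = c("pooled", "per_arm")) {
  pooling <- match.arg(pooling)
  for (nm in c("hpa", "msp")) {
    if (!inherits(original[[nm]], "band_matrix") ||
        !inherits(replicate[[nm]], "band_matrix")) {
      stop("original and replicate must be lists of band_matrix ('hpa','msp')")
    }
  }
  check_aligned(original$hpa, original$msp)
  check_aligned(replicate$hpa, replicate$msp)
  if (!identical(colnames(original$hpa$values),
                 colnames(replicate$hpa$values))) {
    stop("replicate scores cover a different fragment set")
  }
  rep_ids <- rownames(replicate$hpa$values)
  miss <- setdiff(rep_ids, rownames(original$hpa$values))
  if (length(miss)) {
    stop("replicate sample(s) absent from original scores: ",
         paste(miss, collapse = ", "))
  }

  arm_disc <- function(arm) {
    ov <- original[[arm]]$values[rep_ids, , drop = FALSE]
    rv <- replicate[[arm]]$values
    colSums(ov != rv)
  }
  d_hpa <- arm_disc("hpa")
  d_msp <- arm_disc("msp")
  n_rep <- length(rep_ids)

  frag <- original$hpa$fragments
  if (pooling == "pooled") {
    n_scored <- rep.int(2L * n_rep, nrow(frag))
    n_disc <- d_hpa + d_msp
    rate <- ifelse(n_scored > 0, n_disc / n_scored, NA_real_)
  } else {
    n_scored <- rep.int(2L * n_rep, nrow(frag))
    n_disc <- d_hpa + d_msp
    rate <- ifelse(n_rep > 0, (d_hpa / n_rep + d_msp / n_rep) / 2, NA_real_)
  }
  flagged <- n_scored == 0
  if (any(flagged)) {
    warning(sum(flagged), " fragment(s) with zero scored replicate samples")
  }
  per_fragment <- data.frame(
    id = frag$id, combination = frag$combination, size_bp = frag$size_bp,
    n_scored = n_scored, n_discordant = as.integer(n_disc), rate = rate,
    flagged = flagged, stringsAsFactors = FALSE
  )
  structure(
    list(per_fragment = per_fragment,
         median_rate = median(per_fragment$rate[!flagged]),
         replicate_count = n_rep, pooling = pooling),
    class = "error_profile"
  )
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(
    "MSAP error profile: %d fragments, %d replicate pairs, median rate %.4f\n",
    nrow(x$per_fragment), x$replicate_count, x$median_rate
  ))
  invisible(x)
}

#' Per-combination error-rate summaries
#'
#' Summarises per-fragment error rates by primer combination, restricted to a
#' given fragment set (typically the fragments retained after size and error
#' filtering, so that the summaries are locus-weighted means over retained
#' fragments).
#'
#' @param profile an `error_profile`.
#' @param fragment_ids fragments to summarise; default all unflagged.
#' @param stat `"mean"` (default) or `"median"` within combination.
#' @return Data frame with columns `combination`, `rate`, `n_loci`.
#' @export
combination_error_rates <- function(profile, fragment_ids = NULL,
                                    stat = c("mean", "median")) {
  stat <- match.arg(stat)
  pf <- profile$per_fragment[!profile$per_fragment$flagged, , drop = FALSE]
  if (!is.null(fragment_ids)) {
    miss <- setdiff(fragment_ids, pf$id)
    if (length(miss)) {
      stop("no (unflagged) error rate for fragment(s): ",
           paste(miss, collapse = ", "))
    }
    pf <- pf[match(fragment_ids, pf$id), , drop = FALSE]
  }
  agg <- tapply(pf$rate, pf$combination,
                if (stat == "mean") mean else median)
  data.frame(
    combination = names(agg), rate = as.numeric(agg),
    n_loci = as.integer(table(pf$combination)[names(agg)]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Overall locus-weighted mean error rate
#'
#' The locus-weighted mean of per-combination mean error rates over a fragment
#' set, i.e. the plain mean of the per-fragment rates of those fragments.
#'
#' @inheritParams combination_error_rates
#' @return A single proportion.
#' @export
overall_error_rate <- function(profile, fragment_ids = NULL) {
  cr <- combination_error_rates(profile, fragment_ids)
  weighted.mean(cr$rate, cr$n_loci)
}

#' Filter fragments by replicate error rate
#'
#' Retains fragments whose estimated error rate is lower than the median of
#' the error-rate distribution over the whole fragment set.  The comparison is
#' strict by default (ties at the median are dropped); set `strict = FALSE`
#' for `<=`.
#'
#' @param x a `band_matrix` or fragment data frame with an `id` column.
#' @param profile an `error_profile` covering every fragment of `x`.
#' @param strict drop fragments whose rate equals the median (default TRUE).
#' @return `x` restricted to retained fragments.  Flagged fragments (no
#'   replicate coverage) are always dropped.
#' @export
filter_fragments_by_error <- function(x, profile, strict = TRUE) {
  ids <- if (inherits(x, "band_matrix")) x$fragments$id else x$id
  pf <- profile$per_fragment
  miss <- setdiff(ids, pf$id)
  if (length(miss)) {
    stop("no error rate for fragment(s): ", paste(miss, collapse = ", "))
  }
  rate <- pf$rate[match(ids, pf$id)]
  flagged <- pf$flagged[match(ids, pf$id)]
  keep <- !flagged &
    (if (strict) rate < profile$median_rate else rate <= profile$median_rate)
  keep_ids <- ids[keep]
  if (inherits(x, "band_matrix")) bm_subset(x, fragment_ids = keep_ids)
  else x[x$id %in% keep_ids, , drop = FALSE]
}

#' Classify loci as methylation-susceptible or non-methylated
#'
#' Compares the HpaII and MspI scores of every fragment element-wise.  A
#' fragment is methylation-susceptible (MS) when its HpaII/MspI discordance
#' proportion exceeds the threshold expected from scoring error alone in its
#' primer combination; otherwise it is non-methylated.  With the default
#' `threshold_rule = "compound"` a spurious mismatch arises when at least one
#' of the two independent scores errs, so the threshold for combination c is
#' `1 - (1 - e_c)^2`, with `e_c` the combination's mean (or median) retained
#' per-fragment error rate; `"plain"` uses `e_c` itself.
#'
#' @param hpa,msp aligned `band_matrix` objects (same samples, same
#'   fragments), typically restricted to sporophyte samples and to fragments
#'   that survived the size and error filters.
#' @param error_profile an `error_profile` covering the fragments.
#' @param threshold_rule `"compound"` (default) or `"plain"`.
#' @param combination_stat `"mean"` (default) or `"median"` per-fragment rate
#'   summary within combination.
#' @return Object of class `locus_classification`: list with `loci` (data
#'   frame: `id`, `combination`, `size_bp`, `discordance`, `threshold`,
#'   `class`), `thresholds` (per combination) and the rule settings.
#' @export
classify_loci <- function(hpa, msp, error_profile,
                          threshold_rule = c("compound", "plain"),
                          combination_stat = c("mean", "median")) {
  threshold_rule <- match.arg(threshold_rule)
  combination_stat <- match.arg(combination_stat)
  check_aligned(hpa, msp)
  disc <- colMeans(hpa$values != msp$values)
  cr <- combination_error_rates(error_profile, hpa$fragments$id,
                                stat = combination_stat)
  thr <- if (threshold_rule == "compound") 1 - (1 - cr$rate)^2 else cr$rate
  names(thr) <- cr$combination
  frag <- hpa$fragments
  threshold <- thr[frag$combination]
  loci <- data.frame(
    id = frag$id, combination = frag$combination, size_bp = frag$size_bp,
    discordance = as.numeric(disc), threshold = as.numeric(threshold),
    class = ifelse(disc > threshold, "methylation_susceptible",
                   "non_methylated"),
    stringsAsFactors = FALSE
  )
  structure(
    list(loci = loci,
         thresholds = data.frame(combination = cr$combination,
                                 error_rate = cr$rate,
                                 threshold = as.numeric(thr),
                                 stringsAsFactors = FALSE),
         threshold_rule = threshold_rule,
         combination_stat = combination_stat,
         n_samples = nrow(hpa$values)),
    class = "locus_classification"
  )
}

#' @export
print.locus_classification <- function(x, ...) {
  tab <- table(x$loci$class)
  cat(sprintf(
    "Locus classification (%d samples): %d methylation-susceptible, %d non-methylated\n",
    x$n_samples,
    sum(x$loci$class == "methylation_susceptible"),
    sum(x$loci$class == "non_methylated")
  ))
  invisible(x)
}

#' @rdname classify_loci
#' @param classification a `locus_classification`.
#' @return `ms_loci()`: character vector of methylation-susceptible locus IDs.
#' @export
ms_loci <- function(classification) {
  with(classification$loci, id[class == "methylation_susceptible"])
}

#' Construct a methylation-state matrix
#'
#' @param values matrix over `{0, 1, NA}`: 1 = methylated, 0 = non-methylated,
#'   `NA` = uninformative.
#' @param samples sample metadata data frame (as in [band_matrix()]).
#' @param loci data frame of locus annotations (`id`, `combination`,
#'   `size_bp`), or `NULL` to parse from column names.
#' @return Object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(values, samples, loci = NULL) {
  values <- as.matrix(values)
  ok <- is.na(values) | values == 0 | values == 1
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid methylation state at sample '%s', locus '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  storage.mode(values) <- "integer"
  if (is.null(loci)) loci <- parse_fragment_ids(colnames(values))
  samples <- as.data.frame(samples)
  if (is.null(rownames(values))) rownames(values) <- samples$sample_id
  structure(list(values = values, samples = samples, loci = loci),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf(
    "Methylation matrix: %d samples x %d MS loci (%.1f%% uninformative)\n",
    nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' Score methylation states from paired band matrices
#'
#' Applies the three-condition rule to each (sample, locus) band pair at the
#' methylation-susceptible loci: bands present in both products denote the
#' non-methylated state (0); a band in exactly one product denotes the
#' methylated state (1, hemimethylation or internal-cytosine methylation);
#' absence from both products is uninformative (`NA`), since it can reflect
#' either fragment absence or hypermethylation.  The methylated state is thus
#' scored as an imperfectly assessed dominant marker.
#'
#' @param hpa,msp aligned `band_matrix` objects.
#' @param classification a `locus_classification`; only its MS loci are
#'   scored.  Pass `NULL` to score every fragment.
#' @return A `methylation_matrix` over the MS loci.
#' @export
score_methylation <- function(hpa, msp, classification = NULL) {
  check_aligned(hpa, msp)
  if (!is.null(classification)) {
    keep <- ms_loci(classification)
    hpa <- bm_subset(hpa, fragment_ids = keep)
    msp <- bm_subset(msp, fragment_ids = keep)
  }
  h <- hpa$values
  m <- msp$values
  vals <- matrix(NA_integer_, nrow(h), ncol(h), dimnames = dimnames(h))
  vals[h == 1 & m == 1] <- 0L
  vals[xor(h == 1, m == 1)] <- 1L
  methylation_matrix(vals, hpa$samples, hpa$fragments)
}

#' Subset a methylation matrix
#'
#' @param mm a `methylation_matrix`.
#' @param sample_ids,locus_ids identifiers to keep.
#' @export
mm_subset <- function(mm, sample_ids = NULL, locus_ids = NULL) {
  if (!is.null(sample_ids)) {
    keep <- match(sample_ids, mm$samples$sample_id)
    if (anyNA(keep)) stop("unknown sample(s)")
    mm$values <- mm$values[keep, , drop = FALSE]
    mm$samples <- mm$samples[keep, , drop = FALSE]
    rownames(mm$samples) <- NULL
  }
  if (!is.null(locus_ids)) {
    keep <- match(locus_ids, mm$loci$id)
    if (anyNA(keep)) stop("unknown locus/loci")
    mm$values <- mm$values[, keep, drop = FALSE]
    mm$loci <- mm$loci[keep, , drop = FALSE]
    rownames(mm$loci) <- NULL
  }
  mm
}

#' Read and write methylation matrices as TSV
#'
#' Same dialect as band matrices, with `NA` allowed for the uninformative
#' state.
#'
#' @param path TSV file.
#' @param metadata_path metadata TSV file or data frame.
#' @export
read_methylation_matrix <- function(path, metadata_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id") stop("first column must be 'sample_id'")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- as.character(tab$sample_id)
  meta <- if (is.data.frame(metadata_path)) metadata_path
          else read_sample_metadata(metadata_path)
  meta <- meta[match(rownames(vals), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  methylation_matrix(vals, meta)
}

#' @rdname read_methylation_matrix
#' @param mm a `methylation_matrix`.
#' @export
write_methylation_matrix <- function(mm, path) {
  out <- data.frame(sample_id = mm$samples$sample_id, mm$values,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
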