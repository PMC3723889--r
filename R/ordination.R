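#' Nonmetric multidimensional scaling of an epigenetic distance matrix
#'
#' Kruskal's nonmetric MDS (isotonic regression of configuration distances on
#' the rank order of the input distances, stress-1 loss) via
#' [MASS::isoMDS()], run from a classical-scaling start plus random restarts;
#' the configuration with the lowest stress is returned.  Deterministic under
#' a fixed seed.
#'
#' @param d squared-distance matrix (e.g. [pairwise_distance()]); square
#'   roots are taken internally so that the input ranks are preserved on a
#'   metric scale.  Zero off-diagonal distances (identical epigenotypes) are
#'   nudged to a tiny positive value as required by the isotonic fit.
#' @param k target dimensionality (default 2).
#' @param n_restarts random restarts in addition to the classical-scaling
#'   start (default 20).
#' @param seed RNG seed.
#' @return Object of class `nmds_result`: `points` (n x k coordinate matrix),
#'   `stress` (Kruskal stress-1, in `[0, 1]`), `n_restarts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) stop("need at least 4 samples for NMDS")
  dis <- sqrt(d)
  off <- dis[lower.tri(dis)]
  if (any(off == 0)) {
    eps <- min(off[off > 0]) / 1000
    dis[dis == 0] <- eps
    diag(dis) <- 0
  }
  dd <- as.dist(dis)
  withr::with_seed(seed, {
    best <- NULL
    fit0 <- try(suppressWarnings(MASS::isoMDS(dd, k = k, trace = FALSE)),
                silent = TRUE)
    if (!inherits(fit0, "try-error")) best <- fit0
    for (i in seq_len(n_restarts)) {
      init <- matrix(rnorm(n * k), n, k)
      fit <- try(suppressWarnings(MASS::isoMDS(dd, y = init, k = k,
                                               trace = FALSE)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    if (is.null(best)) stop("NMDS failed to produce a configuration")
    rownames(best$points) <- rownames(d)
    structure(
      list(points = best$points, stress = best$stress / 100,
           n_restarts = n_restarts, seed = seed),
      class = "nmds_result"
    )
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS configuration: %d samples, %d dimensions, stress-1 = %.4f\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance from
#' simultaneous row/column permutations of one matrix
#' (p = (1 + #\{r_perm >= r_obs\}) / (1 + n_permutations)).
#'
#' @param d1,d2 distance matrices with identical sample labels and order.
#' @param n_permutations permutations (default 9999).
#' @param seed RNG seed.
#' @return List with `r`, `p_value`, `n_permutations`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 9999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2))) stop("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("distance matrices must share the same labels in the same order")
  }
  v1 <- d1[lower.tri(d1)]
  v2 <- d2[lower.tri(d2)]
  if (sd(v1) == 0 || sd(v2) == 0) {
    stop("constant off-diagonal distances: Mantel correlation undefined")
  }
  fit <- withr::with_seed(seed, {
    vegan::mantel(as.dist(d1), as.dist(d2), method = "pearson",
                  permutations = n_permutations)
  })
  list(r = unname(fit$statistic), p_value = fit$signif,
       n_permutations = n_permutations)
}

#' Joint sporophyte-gametophyte ordination with displacement vectors
#'
#' Combines the sporophyte and gametophyte methylation matrices (restricted
#' to a locus subset, typically the loci with significant site
#' differentiation in either generation), computes a single pairwise distance
#' matrix over the 2n combined samples, ordinates them in one common NMDS
#' space, and derives for each individual the displacement vector from its
#' sporophyte to its gametophyte position.
#'
#' @param meth_sporo,meth_gameto `methylation_matrix` objects over the same
#'   loci, pairable by `individual`.
#' @param locus_subset loci to use (non-empty).
#' @param k,n_restarts,seed passed to [nmds()].
#' @return List with `ordination` (an `nmds_result` over the combined
#'   samples, row names `<individual>|<generation>`) and `displacement`
#'   (data frame: `individual`, `site`, per-axis displacement and `length`).
#' @export
joint_ordination <- function(meth_sporo, meth_gameto, locus_subset,
                             k = 2, n_restarts = 20, seed = 1) {
  if (length(locus_subset) == 0) stop("locus_subset is empty")
  ms <- mm_subset(meth_sporo, locus_ids = locus_subset)
  mg <- mm_subset(meth_gameto, locus_ids = locus_subset)
  ind_s <- ms$samples$individual
  ind_g <- mg$samples$individual
  if (!setequal(ind_s, ind_g)) {
    stop("sporophyte and gametophyte matrices cover different individuals")
  }
  mg <- mm_subset(mg, sample_ids = mg$samples$sample_id[match(ind_s, ind_g)])
  comb <- rbind(ms$values, mg$values)
  rownames(comb) <- c(paste(ind_s, "sporophyte", sep = "|"),
                      paste(ind_s, "gametophyte", sep = "|"))
  d <- pairwise_distance(comb)
  ord <- nmds(d, k = k, n_restarts = n_restarts, seed = seed)
  n <- length(ind_s)
  delta <- ord$points[n + seq_len(n), , drop = FALSE] -
    ord$points[seq_len(n), , drop = FALSE]
  disp <- data.frame(
    individual = ind_s, site = ms$samples$site, delta,
    length = sqrt(rowSums(delta^2)), row.names = NULL
  )
  names(disp)[2 + seq_len(k)] <- paste0("d", seq_len(k))
  list(ordination = ord, displacement = disp)
}
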