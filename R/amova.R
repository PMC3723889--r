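#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions the molecular variance of a set of samples into among-group and
#' within-group components from a matrix of pairwise squared distances, using
#' the standard sums-of-squared-deviations decomposition:
#' `SS_total = sum_{i<j} d_ij / N` over all pairs, `SS_within` the analogous
#' per-group sums divided by the group sizes, `SS_among` their difference.
#' Expected mean squares give the variance components, and
#' `Phi_st = sigma2_among / (sigma2_among + sigma2_within)`, the fraction of
#' total molecular variance attributable to between-group differences (the
#' molecular analogue of Fst for dominant epigenetic markers).  Significance
#' is assessed by permuting group labels; the p-value uses add-one smoothing,
#' `p = (1 + #{Phi_perm >= Phi_obs}) / (1 + n_permutations)`.
#'
#' @param d symmetric matrix of pairwise squared distances (zero diagonal),
#'   e.g. from [pairwise_distance()].
#' @param groups factor/character vector of group memberships, one per sample
#'   in the row order of `d`.  At least two groups, each of size two or more.
#' @param n_permutations number of label permutations (default 9999); 0 skips
#'   the permutation test.
#' @param seed RNG seed for the permutations (required when permuting).
#' @return Object of class `amova_result`: sums of squares, degrees of
#'   freedom, mean squares, `sigma2_among`, `sigma2_within`, `phi_st`,
#'   `permutation_p`, `n_permutations`, `seed` and group sizes.
#' @export
amova <- function(d, groups, n_permutations = 9999, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(groups) != n) stop("groups length must match distance matrix")
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) {
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }

  comp <- amova_components(d, as.integer(groups), nlevels(groups), n)
  obs_phi <- comp["phi_st"]

  perm_p <- NA_real_
  if (n_permutations > 0) {
    gi <- as.integer(groups)
    k <- nlevels(groups)
    perm_phi <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        amova_components(d, sample(gi), k, n)["phi_st"]
      }, numeric(1))
    })
    perm_p <- (1 + sum(perm_phi >= obs_phi)) / (1 + n_permutations)
  }

  structure(
    list(ss = comp[c("ss_among", "ss_within", "ss_total")],
         df = c(among = unname(comp["df_among"]),
                within = unname(comp["df_within"])),
         ms = c(among = unname(comp["ms_among"]),
                within = unname(comp["ms_within"])),
         sigma2_among = unname(comp["sigma2_among"]),
         sigma2_within = unname(comp["sigma2_within"]),
         phi_st = unname(obs_phi),
         permutation_p = perm_p,
         n_permutations = n_permutations,
         seed = if (n_permutations > 0) seed else NA,
         group_sizes = sizes),
    class = "amova_result"
  )
}

# Variance components from a squared-distance matrix and integer group codes.
amova_components <- function(d, gi, k, n) {
  ss_total <- sum(d) / (2 * n)
  ss_within <- 0
  ssq <- 0
  for (g in seq_len(k)) {
    idx <- gi == g
    ng <- sum(idx)
    ss_within <- ss_within + sum(d[idx, idx]) / (2 * ng)
    ssq <- ssq + ng^2
  }
  ss_among <- ss_total - ss_within
  df_among <- k - 1
  df_within <- n - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (n - ssq / n) / df_among
  sigma2_within <- ms_within
  sigma2_among <- (ms_among - ms_within) / n0
  phi <- sigma2_among / (sigma2_among + sigma2_within)
  c(ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
    df_among = df_among, df_within = df_within,
    ms_among = ms_among, ms_within = ms_within,
    sigma2_among = sigma2_among, sigma2_within = sigma2_within,
    phi_st = phi)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("One-level AMOVA\n")
  cat(sprintf("  sigma2 among:  %.5f\n", x$sigma2_among))
  cat(sprintf("  sigma2 within: %.5f\n", x$sigma2_within))
  cat(sprintf("  Phi_st: %.4f", x$phi_st))
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  (P = %.4g, %d permutations)", x$permutation_p,
                x$n_permutations))
  }
  cat("\n")
  invisible(x)
}

#' Pairwise Phi-st between all group pairs
#'
#' Runs [amova()] on every unordered pair of groups.
#'
#' @inheritParams amova
#' @return Data frame with one row per unordered group pair: `group1`,
#'   `group2`, `phi_st`, `permutation_p`; the full `amova_result` objects are
#'   attached as the `"amova"` attribute (named `"A|B"`).
#' @export
pairwise_phist <- function(d, groups, n_permutations = 9999, seed = 1) {
  d <- as.matrix(d)
  groups <- factor(groups)
  levs <- levels(groups)
  if (length(levs) < 2) stop("need at least two groups")
  pairs <- utils::combn(levs, 2)
  res <- vector("list", ncol(pairs))
  out <- data.frame(group1 = character(0), group2 = character(0),
                    phi_st = numeric(0), permutation_p = numeric(0))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    idx <- groups %in% c(a, b)
    fit <- amova(d[idx, idx, drop = FALSE], droplevels(groups[idx]),
                 n_permutations = n_permutations, seed = seed)
    res[[j]] <- fit
    out[j, c("group1", "group2")] <- c(a, b)
    out$phi_st[j] <- fit$phi_st
    out$permutation_p[j] <- fit$permutation_p
  }
  names(res) <- paste(pairs[1, ], pairs[2, ], sep = "|")
  attr(out, "amova") <- res
  out
}
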