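#' Fisher exact test of site heterogeneity at one locus
#'
#' Builds the site-by-state contingency table of informative scores at one
#' locus and tests homogeneity of methylation frequency across sites with
#' Fisher's exact test (probability-ordering two-sided convention: the
#' p-value sums the probabilities of all margin-fixed tables no more probable
#' than the observed one).
#'
#' @param mm a `methylation_matrix`.
#' @param locus locus ID.
#' @param sites optional site labels (defaults to `mm$samples$site`).
#' @return List with `locus`, `contingency` (2 x k: rows non-methylated /
#'   methylated), `p_value` and `flagged` (`TRUE` for a locus monomorphic
#'   across informative scores, where p = 1 by convention).
#' @export
fisher_site_test <- function(mm, locus, sites = NULL) {
  if (is.null(sites)) sites <- mm$samples$site
  x <- mm$values[, locus]
  keep <- !is.na(x)
  if (sum(keep) == 0) stop("locus '", locus, "' has no informative scores")
  sites <- factor(sites[keep])
  if (nlevels(droplevels(sites)) < 2) {
    stop("need informative scores from at least two sites at locus ", locus)
  }
  x <- x[keep]
  tab <- table(factor(x, levels = c(0, 1),
                      labels = c("non_methylated", "methylated")),
               droplevels(sites))
  if (any(rowSums(tab) == 0)) {
    return(list(locus = locus, contingency = tab, p_value = 1, flagged = TRUE))
  }
  p <- fisher.test(tab, workspace = 2e7)$p.value
  list(locus = locus, contingency = tab, p_value = min(p, 1), flagged = FALSE)
}

#' Per-locus site-heterogeneity tests with q-value FDR control
#'
#' Applies [fisher_site_test()] to a set of loci (by default the polymorphic
#' ones), estimates q-values from the p-value set, and flags as significant
#' the loci with p-value and q-value simultaneously below `alpha`.
#'
#' @param mm a `methylation_matrix`.
#' @param loci loci to test; default: polymorphic loci (both states present
#'   among informative scores).
#' @param alpha significance threshold applied to both p and q (default 0.05).
#' @param ... passed to [qvalues()].
#' @return Data frame: `locus`, `p_value`, `q_value`, `significant`,
#'   `flagged`.
#' @export
fisher_site_tests <- function(mm, loci = NULL, alpha = 0.05, ...) {
  if (is.null(loci)) {
    pol <- polymorphism_summary(mm)
    loci <- attr(pol, "polymorphic")
  }
  if (length(loci) == 0) stop("no loci to test")
  tests <- lapply(loci, function(l) fisher_site_test(mm, l))
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  flagged <- vapply(tests, `[[`, logical(1), "flagged")
  q <- qvalues(p, ...)
  data.frame(
    locus = loci, p_value = p, q_value = q,
    significant = p < alpha & q < alpha, flagged = flagged,
    stringsAsFactors = FALSE
  )
}

#' Storey q-values
#'
#' Estimates per-test false discovery rates.  The proportion of true nulls
#' `pi0` is estimated by the smoother method: `pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda))` is computed over a grid of lambda and a
#' cubic smoothing spline is evaluated at the largest lambda.  Q-values are
#' `pi0 * m * p_(i) / i` with step-up monotonicity enforcement; with
#' `pi0 = 1` they reduce exactly to Benjamini-Hochberg adjusted p-values.
#' For fewer than 10 p-values the smoother is unreliable, so `pi0` is fixed
#' at 1 with a warning.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param lambda grid for the smoother (default `seq(0.05, 0.95, 0.05)`).
#' @param pi0 optional fixed value overriding estimation.
#' @return Vector of q-values, same order as `p`.
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0,1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 10) {
      warning("fewer than 10 p-values; fixing pi0 = 1 (Benjamini-Hochberg)")
      pi0 <- 1
    } else {
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                           numeric(1))
      fit <- smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(p)
  ro <- order(o)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[ro]
}

#' Polymorphism summary of a methylation matrix
#'
#' A locus is polymorphic when both methylation states occur among its
#' informative scores; `min_freq` optionally requires the minority state to
#' exceed a frequency cutoff (e.g. 0.05).
#'
#' @param mm a `methylation_matrix`.
#' @param min_freq minority-state frequency that must be strictly exceeded
#'   (default 0: any second state counts).
#' @return Data frame with one row per primer combination plus a combined
#'   row: `combination`, `n_loci`, `n_polymorphic`, `pct_polymorphic`.  The
#'   polymorphic locus IDs are attached as attribute `"polymorphic"`.
#' @export
polymorphism_summary <- function(mm, min_freq = 0) {
  x <- mm$values
  minority <- apply(x, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(0)
    min(mean(col == 1), mean(col == 0))
  })
  poly <- minority > min_freq
  comb <- mm$loci$combination
  per <- lapply(split(seq_along(poly), comb), function(idx) {
    data.frame(n_loci = length(idx), n_polymorphic = sum(poly[idx]))
  })
  out <- do.call(rbind, per)
  out <- data.frame(combination = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(combination = "all", n_loci = length(poly),
                               n_polymorphic = sum(poly)))
  out$pct_polymorphic <- 100 * out$n_polymorphic / out$n_loci
  attr(out, "polymorphic") <- mm$loci$id[poly]
  out
}

#' Expected number of false positives among significant tests
#'
#' The q-value of a test bounds the expected false-discovery proportion of
#' the set of tests at least as significant, so the expected number of false
#' positives among the significant loci is at most the largest significant
#' q-value times the number of significant loci.
#'
#' @param tests data frame from [fisher_site_tests()].
#' @return A single number (0 when nothing is significant).
#' @export
expected_false_positives <- function(tests) {
  q <- tests$q_value[tests$significant]
  if (length(q) == 0) return(0)
  max(q) * length(q)
}

#' Union of significant loci across two test sets
#'
#' @param tests1,tests2 data frames from [fisher_site_tests()] over the same
#'   locus universe (e.g. sporophyte and gametophyte tests).
#' @return List with the union of significant locus IDs (`loci`) and the set
#'   sizes `n1`, `n2`, `n_intersection`, `n_union`.
#' @export
significant_locus_union <- function(tests1, tests2) {
  s1 <- tests1$locus[tests1$significant]
  s2 <- tests2$locus[tests2$significant]
  u <- union(s1, s2)
  list(loci = u, n1 = length(s1), n2 = length(s2),
       n_intersection = length(intersect(s1, s2)), n_union = length(u))
}
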