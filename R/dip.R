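#' Hartigan-Hartigan dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and the class of unimodal CDFs (convex below the mode,
#' concave above it, an atom permitted at the mode).  It is computed exactly
#' by minimising, over candidate mode locations, the minimal half-width of
#' the ECDF band that admits a convex/concave interpolant on either side
#' (greatest-convex-minorant / least-concave-majorant geometry).  The dip is
#' invariant under affine transforms of the data and bounded below by
#' `1/(2n)`.
#'
#' @param x numeric vector (n >= 1); ties allowed.
#' @return The dip statistic `D`.
#' @export
dip_stat <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values in input")
  dip_stat_cpp(sort(x))
}

#' Dip test of unimodality with Monte-Carlo p-value
#'
#' Tests the null hypothesis that the values (e.g. arcsin-transformed
#' per-locus instabilities) are drawn from a unimodal distribution against a
#' multimodal alternative.  The null reference is the uniform distribution,
#' the asymptotically least favourable unimodal case, so the p-value is the
#' Monte-Carlo tail probability of the dip among uniform samples of the same
#' size; for non-uniform unimodal data the test is conservative.
#'
#' @param x numeric vector, n >= 4.
#' @param n_null_reps Monte-Carlo replicates (default 2000).
#' @param seed RNG seed.
#' @return List of class `dip_test`: `D`, `p_value`, `n`, `n_null_reps`.
#'   All-identical input gives the minimal dip `1/(2n)` with p = 1.
#' @export
dip_test <- function(x, n_null_reps = 2000, seed = 1) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("need at least 4 values")
  D <- dip_stat(x)
  if (length(unique(x)) == 1) {
    return(structure(list(D = D, p_value = 1, n = n,
                          n_null_reps = 0L), class = "dip_test"))
  }
  null <- withr::with_seed(seed, dip_null_cpp(n, n_null_reps))
  p <- (1 + sum(null >= D)) / (1 + n_null_reps)
  structure(list(D = D, p_value = p, n = n, n_null_reps = n_null_reps),
            class = "dip_test")
}

#' @export
print.dip_test <- function(x, ...) {
  cat(sprintf("Hartigans' dip test: D = %.4f, P = %.4g (n = %d, %d null reps)\n",
              x$D, x$p_value, x$n, x$n_null_reps))
  invisible(x)
}
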