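#' Classify loci into stable and unstable clusters
#'
#' After bimodality of the per-locus instability distribution has been
#' established (see [dip_test()]), fits a two-component Gaussian mixture to
#' the arcsin-transformed instabilities by EM (equal- and unequal-variance
#' models compared by BIC, via \pkg{mclust}) and assigns each locus to its
#' maximum-posterior component.  The component with the lower mean is
#' labelled `stable`, the other `unstable`.
#'
#' @param instability_profile an `instability_profile` from
#'   [locus_instability()] (or a numeric vector of arcsin values).
#' @param seed RNG seed (used for jittered restarts if the EM degenerates).
#' @importFrom mclust Mclust mclustBIC
#' @return List of class `stability_fit`: `cluster` (named character vector
#'   `stable`/`unstable` per locus), `means`, `variances`, `proportions` (on
#'   the arcsin scale, stable first), `model` (`"E"` or `"V"`), `bic`,
#'   `stable_fraction`.
#' @export
classify_stability <- function(instability_profile, seed = 1) {
  if (inherits(instability_profile, "instability_profile")) {
    values <- instability_profile$arcsin
    names(values) <- instability_profile$locus
  } else {
    nm <- names(instability_profile)
    values <- as.numeric(instability_profile)
    names(values) <- if (is.null(nm)) seq_along(values) else nm
  }
  if (length(values) < 6) stop("need at least 6 loci for mixture classification")

  fit <- NULL
  withr::with_seed(seed, {
    x <- values
    for (attempt in 1:10) {
      f <- try(suppressWarnings(
        Mclust(x, G = 2, modelNames = c("E", "V"), verbose = FALSE)
      ), silent = TRUE)
      if (!inherits(f, "try-error") && !is.null(f) &&
          all(is.finite(f$parameters$variance$sigmasq)) &&
          all(f$parameters$variance$sigmasq > 0)) {
        fit <- f
        break
      }
      # degenerate EM (component collapsed): jitter and retry
      x <- values + rnorm(length(values), sd = sd(values) / 1000)
    }
  })
  if (is.null(fit)) stop("EM failed to fit a two-component mixture")

  mu <- fit$parameters$mean
  stable_comp <- which.min(mu)
  cluster <- ifelse(fit$classification == stable_comp, "stable", "unstable")
  names(cluster) <- names(values)
  sigsq <- fit$parameters$variance$sigmasq
  if (length(sigsq) == 1) sigsq <- rep(sigsq, 2)
  ord <- order(mu)
  structure(
    list(cluster = cluster,
         means = unname(mu[ord]),
         variances = unname(sigsq[ord]),
         proportions = unname(fit$parameters$pro[ord]),
         model = fit$modelName,
         bic = unname(fit$bic),
         stable_fraction = mean(cluster == "stable")),
    class = "stability_fit"
  )
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf(
    "Stability mixture (%s model): %d stable / %d unstable loci (%.1f%% stable)\n",
    x$model, sum(x$cluster == "stable"), sum(x$cluster == "unstable"),
    100 * x$stable_fraction
  ))
  cat(sprintf("  component means (arcsin scale): %.3f / %.3f\n",
              x$means[1], x$means[2]))
  invisible(x)
}
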