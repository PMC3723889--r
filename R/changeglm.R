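#' Binomial GLM of methylation-change probability
#'
#' Models the probability that a single (individual, locus) comparison
#' registers a sporophyte-to-gametophyte methylation change as a function of
#' sampling site and locus: a fixed-effects binomial GLM with logit link,
#' `change ~ site + locus`, fitted to the retained comparisons (aggregated
#' to site-by-locus counts, which is likelihood-equivalent).  The site and
#' locus effects are tested by likelihood-ratio deviance (chi-square) tests.
#' Per-site change probabilities are the inverse-logit site estimates
#' averaged over loci on the link scale, with delta-method standard errors
#' on the response scale (via \pkg{emmeans}).
#'
#' A locus whose comparisons are all changes or all non-changes is completely
#' separated; its cells receive a half-success/half-failure pseudo-count
#' (a weak ridge toward 1/2) and the locus is flagged.
#'
#' @param change_table a `change_table` with at least two sites and two loci.
#' @return List of class `change_glm`: `site_test` and `locus_test`
#'   (`statistic`, `df`, `p_value`), `site_probabilities` (data frame:
#'   `site`, `probability`, `se`), `separated_loci`, and the fitted `model`.
#' @export
change_glm <- function(change_table) {
  retained <- change_table[change_table$outcome != "excluded", , drop = FALSE]
  if (length(unique(retained$site)) < 2) stop("need at least two sites")
  if (length(unique(retained$locus)) < 2) stop("need at least two loci")

  agg <- stats::aggregate(
    cbind(changed = as.numeric(retained$change),
          total = rep(1, nrow(retained))),
    by = list(site = retained$site, locus = retained$locus), FUN = sum
  )
  agg$unchanged <- agg$total - agg$changed

  by_locus <- tapply(agg$changed, agg$locus, sum)
  tot_locus <- tapply(agg$total, agg$locus, sum)
  separated <- names(by_locus)[by_locus == 0 | by_locus == tot_locus]
  if (length(separated)) {
    sep <- agg$locus %in% separated
    ncell <- tapply(agg$total, agg$locus, length)[agg$locus[sep]]
    agg$changed[sep] <- agg$changed[sep] + 0.5 / as.numeric(ncell)
    agg$unchanged[sep] <- agg$unchanged[sep] + 0.5 / as.numeric(ncell)
  }

  agg$site <- factor(agg$site)
  agg$locus <- factor(agg$locus)
  # fractional pseudo-counts from the ridge are intentional
  fit <- suppressWarnings(glm(cbind(changed, unchanged) ~ site + locus,
                              family = binomial(link = "logit"), data = agg))
  lr <- suppressWarnings(drop1(fit, test = "Chisq"))
  site_row <- match("site", rownames(lr))
  locus_row <- match("locus", rownames(lr))
  site_test <- list(statistic = lr$LRT[site_row], df = lr$Df[site_row],
                    p_value = lr$`Pr(>Chi)`[site_row])
  locus_test <- list(statistic = lr$LRT[locus_row], df = lr$Df[locus_row],
                     p_value = lr$`Pr(>Chi)`[locus_row])

  em <- summary(emmeans::emmeans(fit, "site", type = "response"))
  prob_col <- intersect(c("prob", "response"), names(em))[1]
  site_prob <- data.frame(site = as.character(em$site),
                          probability = em[[prob_col]], se = em$SE,
                          stringsAsFactors = FALSE)

  structure(
    list(site_test = site_test, locus_test = locus_test,
         site_probabilities = site_prob,
         separated_loci = as.character(separated),
         model = fit),
    class = "change_glm"
  )
}

#' @export
print.change_glm <- function(x, ...) {
  cat("Binomial GLM of change probability (change ~ site + locus)\n")
  cat(sprintf("  site:  LR chi2 = %.2f, df = %d, P = %.4g\n",
              x$site_test$statistic, x$site_test$df, x$site_test$p_value))
  cat(sprintf("  locus: LR chi2 = %.2f, df = %d, P = %.4g\n",
              x$locus_test$statistic, x$locus_test$df, x$locus_test$p_value))
  for (i in seq_len(nrow(x$site_probabilities))) {
    cat(sprintf("  P(change | %s) = %.4f (SE %.4f)\n",
                x$site_probabilities$site[i],
                x$site_probabilities$probability[i],
                x$site_probabilities$se[i]))
  }
  if (length(x$separated_loci)) {
    cat("  ridge-penalised separated loci:",
        length(x$separated_loci), "\n")
  }
  invisible(x)
}
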