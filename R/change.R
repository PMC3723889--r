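#' Build the sporophyte-to-gametophyte change table
#'
#' Compares the methylation state of every (individual, locus) pair between
#' the sporophyte (leaf) and its descendant male gametophyte (pollen)
#' samples.  Comparisons where both generations are uninformative are
#' discarded.  When exactly one generation is uninformative, the partner's
#' informative score shows the individual carries the fragment, so the double
#' band absence on the uninformative side is read as hypermethylation and
#' resolved to the methylated state (default); `resolve = "copy"` instead
#' copies the partner's state (so such comparisons can never register a
#' change).
#'
#' @param meth_sporo,meth_gameto `methylation_matrix` objects over identical
#'   loci; each individual must have exactly one sample in each.
#' @param resolve `"hypermethylation"` (default) or `"copy"`.
#' @return A data frame of class `change_table` with one row per
#'   (individual, locus): `individual`, `site`, `locus`, `sporophyte_state`,
#'   `gametophyte_state` (original scores, `NA` = uninformative), `outcome`
#'   (`no_change`, `change_0to1`, `change_1to0`, the `resolved_*` variants
#'   for single-missing comparisons, or `excluded`), and `change`
#'   (logical; `NA` for excluded rows).
#' @export
build_change_table <- function(meth_sporo, meth_gameto,
                               resolve = c("hypermethylation", "copy")) {
  resolve <- match.arg(resolve)
  if (!identical(meth_sporo$loci$id, meth_gameto$loci$id)) {
    stop("sporophyte and gametophyte matrices differ in loci")
  }
  ind_s <- meth_sporo$samples$individual
  ind_g <- meth_gameto$samples$individual
  if (anyDuplicated(ind_s)) {
    stop("individual with multiple sporophyte samples: ",
         ind_s[duplicated(ind_s)][1])
  }
  if (anyDuplicated(ind_g)) {
    stop("individual with multiple gametophyte samples: ",
         ind_g[duplicated(ind_g)][1])
  }
  unpaired <- c(setdiff(ind_s, ind_g), setdiff(ind_g, ind_s))
  if (length(unpaired)) {
    stop("unpaired individual(s): ", paste(unpaired, collapse = ", "))
  }
  mg <- mm_subset(meth_gameto,
                  sample_ids = meth_gameto$samples$sample_id[match(ind_s, ind_g)])
  s <- meth_sporo$values
  g <- mg$values
  n_ind <- nrow(s); n_loc <- ncol(s)

  sporo <- as.vector(s)  # column-major: individuals fastest
  gameto <- as.vector(g)
  both_na <- is.na(sporo) & is.na(gameto)
  one_na <- xor(is.na(sporo), is.na(gameto))

  # resolved states used for the comparison
  rs <- sporo; rg <- gameto
  if (resolve == "hypermethylation") {
    rs[is.na(sporo) & !is.na(gameto)] <- 1L
    rg[is.na(gameto) & !is.na(sporo)] <- 1L
  } else {
    rs[is.na(sporo) & !is.na(gameto)] <- gameto[is.na(sporo) & !is.na(gameto)]
    rg[is.na(gameto) & !is.na(sporo)] <- sporo[is.na(gameto) & !is.na(sporo)]
  }

  outcome <- rep(NA_character_, length(sporo))
  outcome[both_na] <- "excluded"
  dir <- function(a, b) {
    ifelse(a == b, "no_change", ifelse(a == 0, "change_0to1", "change_1to0"))
  }
  plain <- !both_na & !one_na
  outcome[plain] <- dir(rs[plain], rg[plain])
  outcome[one_na] <- c(no_change = "resolved_no_change",
                       change_0to1 = "resolved_0to1",
                       change_1to0 = "resolved_1to0")[dir(rs[one_na], rg[one_na])]

  change <- rep(NA, length(sporo))
  change[!both_na] <- outcome[!both_na] %in%
    c("change_0to1", "change_1to0", "resolved_0to1", "resolved_1to0")

  out <- data.frame(
    individual = rep(ind_s, times = n_loc),
    site = rep(meth_sporo$samples$site, times = n_loc),
    locus = rep(meth_sporo$loci$id, each = n_ind),
    sporophyte_state = sporo,
    gametophyte_state = gameto,
    outcome = outcome,
    change = change,
    stringsAsFactors = FALSE
  )
  class(out) <- c("change_table", class(out))
  attr(out, "resolve") <- resolve
  out
}

is_up_change <- function(outcome) {
  outcome %in% c("change_0to1", "resolved_0to1")
}
is_down_change <- function(outcome) {
  outcome %in% c("change_1to0", "resolved_1to0")
}

#' Summarise methylation changes across all comparisons
#'
#' @param change_table a `change_table`.
#' @return List: `n_max` (individuals x loci), `n_retained`, `n_excluded`,
#'   `n_changed`, `rate` (changes / retained comparisons), `prop_0to1` and
#'   `prop_1to0` (direction shares among changes; `NA` and `degenerate =
#'   TRUE` when no change occurred).
#' @export
change_summary <- function(change_table) {
  retained <- change_table$outcome != "excluded"
  n_ret <- sum(retained)
  if (n_ret == 0) stop("no retained comparisons")
  up <- sum(is_up_change(change_table$outcome))
  down <- sum(is_down_change(change_table$outcome))
  n_changed <- up + down
  list(
    n_max = nrow(change_table),
    n_retained = n_ret,
    n_excluded = sum(!retained),
    n_changed = n_changed,
    rate = n_changed / n_ret,
    prop_0to1 = if (n_changed > 0) up / n_changed else NA_real_,
    prop_1to0 = if (n_changed > 0) down / n_changed else NA_real_,
    degenerate = n_changed == 0
  )
}

#' Per-locus methylation instability
#'
#' Instability of a locus is the proportion of individuals (all sites
#' combined) whose methylation state changed between the sporophyte and the
#' descendant gametophyte, with an exact (Clopper-Pearson) binomial
#' confidence interval and the variance-stabilising `asin(sqrt(p))`
#' transform.
#'
#' @param change_table a `change_table`.
#' @param conf_level confidence level (default 0.95).
#' @return Data frame of class `instability_profile`: `locus`, `n_compared`,
#'   `n_changed`, `instability`, `ci_low`, `ci_high`, `arcsin`.  Loci with
#'   zero retained comparisons are dropped with a warning.
#' @export
locus_instability <- function(change_table, conf_level = 0.95) {
  retained <- change_table[change_table$outcome != "excluded", , drop = FALSE]
  n_comp <- tapply(retained$change, retained$locus, length)
  n_chg <- tapply(retained$change, retained$locus, sum)
  all_loci <- unique(change_table$locus)
  dropped <- setdiff(all_loci, names(n_comp))
  if (length(dropped)) {
    warning(length(dropped), " locus/loci with zero retained comparisons dropped")
  }
  loci <- intersect(all_loci, names(n_comp))  # keep original locus order
  n_comp <- as.integer(n_comp[loci])
  n_chg <- as.integer(n_chg[loci])
  ci <- t(vapply(seq_along(loci), function(i) {
    binom.test(n_chg[i], n_comp[i], conf.level = conf_level)$conf.int
  }, numeric(2)))
  p <- n_chg / n_comp
  out <- data.frame(
    locus = loci, n_compared = n_comp, n_changed = n_chg, instability = p,
    ci_low = ci[, 1], ci_high = ci[, 2], arcsin = asin(sqrt(p)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("instability_profile", class(out))
  attr(out, "conf_level") <- conf_level
  out
}

#' Per-individual change rates and Kruskal-Wallis site comparison
#'
#' Computes for each individual the proportion of its retained comparisons
#' that registered a methylation change, and tests for differences in mean
#' proportion across sampling sites with the Kruskal-Wallis rank sum test
#' (tie-corrected H statistic, chi-square reference on k - 1 df).
#'
#' @param change_table a `change_table`.
#' @return List: `per_individual` (data frame: `individual`, `site`,
#'   `n_retained`, `n_changed`, `proportion`), `site_means` (named vector),
#'   `kruskal` (`statistic`, `df`, `p_value`), `degenerate` (`TRUE` when all
#'   proportions are equal, in which case H = 0 and p = 1).
#' @export
individual_change_rates <- function(change_table) {
  retained <- change_table[change_table$outcome != "excluded", , drop = FALSE]
  site_of <- tapply(as.character(change_table$site), change_table$individual,
                    `[[`, 1)
  n_ret <- tapply(retained$change, retained$individual, length)
  n_chg <- tapply(retained$change, retained$individual, sum)
  ind <- names(n_ret)
  per <- data.frame(
    individual = ind, site = as.character(site_of[ind]),
    n_retained = as.integer(n_ret), n_changed = as.integer(n_chg),
    proportion = as.numeric(n_chg / n_ret),
    row.names = NULL, stringsAsFactors = FALSE
  )
  sites <- factor(per$site)
  if (nlevels(sites) < 2) stop("need individuals from at least two sites")
  small <- table(sites) < 2
  if (any(small)) {
    stop("site(s) with fewer than 2 individuals: ",
         paste(names(small)[small], collapse = ", "))
  }
  site_means <- tapply(per$proportion, sites, mean)
  if (length(unique(per$proportion)) == 1) {
    kr <- list(statistic = 0, df = nlevels(sites) - 1, p_value = 1)
    degenerate <- TRUE
  } else {
    fit <- kruskal.test(per$proportion, sites)
    kr <- list(statistic = unname(fit$statistic),
               df = unname(fit$parameter), p_value = fit$p.value)
    degenerate <- FALSE
  }
  list(per_individual = per, site_means = site_means, kruskal = kr,
       degenerate = degenerate)
}
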