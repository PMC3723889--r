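# Small in-code fixtures shared across test files.

make_samples <- function(n, sites = NULL, generation = "sporophyte",
                         prefix = "s") {
  if (is.null(sites)) sites <- rep("A", n)
  data.frame(
    sample_id = paste0(prefix, seq_len(n)),
    individual = paste0("ind", seq_len(n)),
    site = sites, generation = generation,
    stringsAsFactors = FALSE
  )
}

make_bm <- function(values, sites = NULL, enzyme = "HpaII",
                    combination = "C1", sizes = NULL,
                    generation = "sporophyte", prefix = "s") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(sizes)) sizes <- 150 + seq_len(ncol(values))
  frag <- data.frame(
    id = fragment_id(combination, paste0("f", seq_len(ncol(values))), sizes),
    combination = combination, size_bp = sizes, stringsAsFactors = FALSE
  )
  colnames(values) <- frag$id
  samples <- make_samples(n, sites, generation, prefix)
  rownames(values) <- samples$sample_id
  band_matrix(values, samples, frag, enzyme)
}

make_mm <- function(values, sites = NULL, generation = "sporophyte",
                    prefix = "s", combination = "C1") {
  values <- as.matrix(values)
  sizes <- 150 + seq_len(ncol(values))
  loci <- data.frame(
    id = fragment_id(combination, paste0("f", seq_len(ncol(values))), sizes),
    combination = combination, size_bp = sizes, stringsAsFactors = FALSE
  )
  colnames(values) <- loci$id
  samples <- make_samples(nrow(values), sites, generation, prefix)
  rownames(values) <- samples$sample_id
  methylation_matrix(values, samples, loci)
}

# Expand per-(site, locus) change counts into a change_table-shaped frame.
glm_table <- function(changed, total, sites, loci) {
  rows <- do.call(rbind, lapply(seq_along(changed), function(i) {
    n <- total[i]
    data.frame(
      individual = paste0(sites[i], "_", seq_len(n)),
      site = sites[i], locus = loci[i],
      sporophyte_state = 0L, gametophyte_state = 0L,
      outcome = c(rep("change_0to1", changed[i]),
                  rep("no_change", n - changed[i])),
      change = c(rep(TRUE, changed[i]), rep(FALSE, n - changed[i])),
      stringsAsFactors = FALSE
    )
  }))
  class(rows) <- c("change_table", class(rows))
  rows
}

# Default calibrated configuration, computed once per session (cached in the
# package environment by configuration key).
default_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- sim_config()
    cfg
  }
})
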