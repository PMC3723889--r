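#' Pairwise squared epigenetic distances
#'
#' Computes the matrix of squared Euclidean distances between the binary
#' methylation-score vectors of all sample pairs, as required by AMOVA on
#' dominant markers.  Uninformative (`NA`) scores are handled by proportional
#' rescaling: with `L` loci in total and `L_ij` loci informative in both
#' members of a pair,
#' `d(i,j) = (L / L_ij) * sum over shared loci of (x_i - x_j)^2`.
#' With no missing data this is exactly the squared Euclidean distance.
#'
#' @param mm a `methylation_matrix` (or a plain 0/1/NA matrix).
#' @return A symmetric matrix of squared distances with zero diagonal and
#'   sample IDs as dimnames; attribute `"n_shared"` holds the `L_ij` counts.
#'   A pair with zero shared informative loci is an error naming the pair.
#' @export
pairwise_distance <- function(mm) {
  x <- if (inherits(mm, "methylation_matrix")) mm$values else as.matrix(mm)
  if (nrow(x) < 2) stop("need at least two samples")
  L <- ncol(x)
  w <- !is.na(x)
  x0 <- x
  x0[!w] <- 0
  storage.mode(x0) <- "double"
  wn <- matrix(as.numeric(w), nrow(x))
  cross <- tcrossprod(x0)              # sum_l x_i x_j over shared loci
  sq <- tcrossprod(x0^2, wn)           # sum_l x_i^2 w_j
  shared <- tcrossprod(wn)             # L_ij
  d_raw <- sq + t(sq) - 2 * cross
  off <- shared == 0 & row(shared) != col(shared)
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "samples '%s' and '%s' share no informative locus",
      rownames(x)[idx[1]], rownames(x)[idx[2]]
    ))
  }
  d <- d_raw * (L / shared)
  diag(d) <- 0
  d[d < 0] <- 0  # guard against numerical noise
  dimnames(d) <- list(rownames(x), rownames(x))
  attr(d, "n_shared") <- shared
  attr(d, "metric") <- "squared_euclidean"
  d
}
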