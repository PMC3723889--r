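#' Construct a band matrix for one enzyme arm
#'
#' A band matrix holds the presence/absence (1/0) scores of AFLP fragments for
#' one restriction-enzyme arm of an MSAP assay (MseI+HpaII or MseI+MspI),
#' together with sample metadata and fragment annotations.  The HpaII and MspI
#' matrices of one dataset must share identical sample and fragment orderings;
#' all pairwise operations check this.
#'
#' @param values integer/numeric matrix of 0/1 scores, samples in rows and
#'   fragments in columns.  Row names must be sample IDs, column names fragment
#'   IDs of the form `"<combination>:<fragment>:<size_bp>"`.
#' @param samples data frame with columns `sample_id`, `individual`, `site`,
#'   `generation` (`"sporophyte"` or `"gametophyte"`), one row per row of
#'   `values`, in the same order.
#' @param fragments data frame with columns `id`, `combination`, `size_bp`,
#'   one row per column of `values`, in the same order.  If `NULL`, it is
#'   parsed from the column names of `values`.
#' @param enzyme `"HpaII"` or `"MspI"`.
#' @return An object of class `band_matrix`.
#' @export
band_matrix <- function(values, samples, fragments = NULL,
                        enzyme = c("HpaII", "MspI")) {
  enzyme <- match.arg(enzyme)
  values <- as.matrix(values)
  bad <- arrayInd(which(!(values %in% c(0, 1))), dim(values))
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-binary band score %s at sample '%s', fragment '%s'",
      format(values[bad[1, 1], bad[1, 2]]),
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]
    ))
  }
  storage.mode(values) <- "integer"
  samples <- as.data.frame(samples)
  req <- c("sample_id", "individual", "site", "generation")
  if (!all(req %in% names(samples))) {
    stop("sample metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1])
  }
  if (nrow(samples) != nrow(values)) stop("samples/values row mismatch")
  if (is.null(rownames(values))) rownames(values) <- samples$sample_id
  if (!identical(as.character(samples$sample_id), rownames(values))) {
    stop("sample metadata order does not match matrix rows")
  }
  if (is.null(fragments)) fragments <- parse_fragment_ids(colnames(values))
  fragments <- as.data.frame(fragments)
  if (!all(c("id", "combination", "size_bp") %in% names(fragments))) {
    stop("fragments must have columns id, combination, size_bp")
  }
  if (nrow(fragments) != ncol(values)) stop("fragments/values column mismatch")
  if (anyDuplicated(fragments$id)) stop("duplicated fragment id")
  if (any(fragments$size_bp <= 0)) stop("fragment size_bp must be positive")
  colnames(values) <- fragments$id
  structure(
    list(enzyme = enzyme, values = values, samples = samples,
         fragments = fragments),
    class = "band_matrix"
  )
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf(
    "MSAP band matrix (%s): %d samples x %d fragments, %d combination(s)\n",
    x$enzyme, nrow(x$values), ncol(x$values),
    length(unique(x$fragments$combination))
  ))
  invisible(x)
}

#' Compose and parse fragment identifiers
#'
#' Fragment IDs serialise as `"<combination>:<fragment>:<size_bp>"`.
#'
#' @param combination,fragment,size_bp components of the identifier.
#' @return `fragment_id()` a character vector; `parse_fragment_ids()` a data
#'   frame with columns `id`, `combination`, `size_bp`.
#' @export
fragment_id <- function(combination, fragment, size_bp) {
  paste(combination, fragment, size_bp, sep = ":")
}

#' @rdname fragment_id
#' @param ids character vector of serialised fragment IDs.
#' @export
parse_fragment_ids <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("fragment IDs must be '<combination>:<fragment>:<size_bp>'")
  }
  data.frame(
    id = ids,
    combination = vapply(parts, `[[`, "", 1L),
    size_bp = as.integer(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

check_aligned <- function(hpa, msp) {
  if (!inherits(hpa, "band_matrix") || !inherits(msp, "band_matrix")) {
    stop("expected band_matrix objects")
  }
  if (!identical(rownames(hpa$values), rownames(msp$values))) {
    stop("HpaII and MspI matrices have mismatched sample sets or order")
  }
  if (!identical(colnames(hpa$values), colnames(msp$values))) {
    stop("HpaII and MspI matrices have mismatched fragment sets or order")
  }
  invisible(TRUE)
}

#' Subset a band matrix
#'
#' @param bm a `band_matrix`.
#' @param sample_ids,fragment_ids identifiers to keep (order preserved as
#'   given).
#' @return A `band_matrix`.
#' @export
bm_subset <- function(bm, sample_ids = NULL, fragment_ids = NULL) {
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, rownames(bm$values))
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    keep <- match(sample_ids, bm$samples$sample_id)
    bm$values <- bm$values[keep, , drop = FALSE]
    bm$samples <- bm$samples[keep, , drop = FALSE]
    rownames(bm$samples) <- NULL
  }
  if (!is.null(fragment_ids)) {
    miss <- setdiff(fragment_ids, colnames(bm$values))
    if (length(miss)) stop("unknown fragment(s): ", paste(miss, collapse = ", "))
    keep <- match(fragment_ids, bm$fragments$id)
    bm$values <- bm$values[, keep, drop = FALSE]
    bm$fragments <- bm$fragments[keep, , drop = FALSE]
    rownames(bm$fragments) <- NULL
  }
  bm
}

#' Read and write band matrices as TSV
#'
#' The TSV dialect has a first column `sample_id` followed by one column per
#' fragment, named `"<combination>:<fragment>:<size_bp>"`, with strictly 0/1
#' values.  Sample metadata live in a separate TSV with columns `sample_id`,
#' `individual`, `site`, `generation`.
#'
#' @param path band matrix TSV file.
#' @param metadata_path sample metadata TSV file (or a data frame already
#'   read via [read_sample_metadata()]).
#' @param enzyme `"HpaII"` or `"MspI"`.
#' @return A `band_matrix`.
#' @export
read_band_matrix <- function(path, metadata_path, enzyme = c("HpaII", "MspI")) {
  enzyme <- match.arg(enzyme)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id") stop("first column must be 'sample_id'")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- as.character(tab$sample_id)
  bad <- arrayInd(which(!(vals %in% c(0, 1))), dim(vals))
  if (nrow(bad) > 0) {
    stop(sprintf("non-binary value '%s' in %s at row %d (sample '%s'), column '%s'",
                 format(vals[bad[1, 1], bad[1, 2]]), path, bad[1, 1],
                 rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  meta <- if (is.data.frame(metadata_path)) metadata_path
          else read_sample_metadata(metadata_path)
  miss <- setdiff(rownames(vals), meta$sample_id)
  if (length(miss)) {
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  }
  meta <- meta[match(rownames(vals), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  band_matrix(vals, meta, enzyme = enzyme)
}

#' @rdname read_band_matrix
#' @param bm a `band_matrix` to serialise.
#' @export
write_band_matrix <- function(bm, path) {
  out <- data.frame(sample_id = bm$samples$sample_id, bm$values,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_band_matrix
#' @export
read_sample_metadata <- function(metadata_path) {
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  req <- c("sample_id", "individual", "site", "generation")
  if (!all(req %in% names(meta))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta
}

#' @rdname read_band_matrix
#' @param meta sample metadata data frame.
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
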