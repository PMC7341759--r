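# The expression container: a features x samples matrix of log2 intensities
# plus an optional same-shaped matrix of detection calls.  Kept as a light
# S3 wrapper (limma-style) rather than a heavier assay container so that
# writers can guarantee byte-stable text round trips.


#' Construct an expression matrix
#'
#' Bundles a numeric log2-intensity matrix (features in rows, samples in
#' columns) with an optional grid of detection calls.  Both matrices must
#' carry unique feature and sample identifiers as dimnames; all intensity
#' values must be finite.
#'
#' @param values Numeric matrix of log2 intensities, features x samples,
#'   with unique rownames (feature ids) and colnames (sample ids).
#' @param flags Optional character matrix of detection calls over exactly
#'   the same grid, with entries in `"Present"`, `"Marginal"`, `"Absent"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `flags`.
#' @examples
#' m <- matrix(rnorm(6, 8), 2, 3,
#'             dimnames = list(c("LNC1", "MRNA1"), c("s1", "s2", "s3")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, flags = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  # an empty subset drops its dimnames; restore the empty id vectors
  if (is.null(fid) && nrow(values) == 0L) fid <- character(0L)
  if (is.null(sid) && ncol(values) == 0L) sid <- character(0L)
  if (is.null(fid) || is.null(sid))
    stop("`values` must carry feature ids (rownames) and sample ids (colnames)")
  dimnames(values) <- list(fid, sid)
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (!is.null(flags)) {
    if (!is.matrix(flags) || !is.character(flags))
      stop("`flags` must be a character matrix")
    if (all(dim(flags) == dim(values)) && nrow(flags) == 0L)
      dimnames(flags) <- dimnames(values)
    if (!identical(dimnames(flags), dimnames(values)))
      stop("`flags` must cover exactly the same feature x sample grid as `values`")
    bad <- setdiff(unique(as.vector(flags)), .FLAG_LEVELS)
    if (length(bad))
      stop("invalid detection flag value: ", bad[1L])
  }
  structure(list(values = values, flags = flags), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s detection flags)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$flags)) "no" else "with"))
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  f <- if (is.null(x$flags)) NULL else x$flags[i, j, drop = FALSE]
  expression_matrix(v, f)
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
feature_ids <- function(x) {
  ids <- rownames(.values(x))
  if (is.null(ids)) character(0L) else ids
}

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) {
  ids <- colnames(.values(x))
  if (is.null(ids)) character(0L) else ids
}

# Accept either an expr_matrix or a bare named numeric matrix.
.values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected an `expr_matrix` or a numeric matrix")
}

# Sample design ----------------------------------------------------------

#' Validate a sample design table
#'
#' A design table maps each array/sample column to its patient and tissue
#' (`"T"` tumor or `"NT"` adjacent non-tumor).  With `paired = TRUE` every
#' patient must contribute exactly one tumor and one non-tumor sample.
#'
#' @param design Data frame with columns `sample_id`, `patient_id`,
#'   `tissue`.
#' @param sample_ids Optional vector of known sample ids; design rows
#'   referencing unknown samples are an error.
#' @param paired Require the one-T/one-NT-per-patient invariant.
#' @return The design, invisibly, after validation.
#' @export
validate_design <- function(design, sample_ids = NULL, paired = TRUE) {
  req <- c("sample_id", "patient_id", "tissue")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample id in design: ",
         design$sample_id[duplicated(design$sample_id)][1L])
  bad <- setdiff(unique(design$tissue), c("T", "NT"))
  if (length(bad))
    stop("tissue must be 'T' or 'NT', found: ", bad[1L])
  if (!is.null(sample_ids)) {
    unknown <- setdiff(design$sample_id, sample_ids)
    if (length(unknown))
      stop("design references unknown sample(s): ",
           paste(head(unknown, 3), collapse = ", "))
  }
  if (paired) {
    tab <- table(design$patient_id, factor(design$tissue, c("T", "NT")))
    off <- rownames(tab)[tab[, "T"] != 1L | tab[, "NT"] != 1L]
    if (length(off))
      stop("pairing error: patient(s) without exactly one T and one NT sample: ",
           paste(head(off, 3), collapse = ", "))
  }
  invisible(design)
}

# Matched tumor / non-tumor sample ids, one row per patient, stable order.
.paired_samples <- function(design) {
  validate_design(design, paired = TRUE)
  pts <- sort(unique(design$patient_id))
  data.frame(
    patient_id = pts,
    tumor = design$sample_id[match(paste0(pts, ".T"),
                                   paste0(design$patient_id, ".", design$tissue))],
    nontumor = design$sample_id[match(paste0(pts, ".NT"),
                                      paste0(design$patient_id, ".", design$tissue))],
    stringsAsFactors = FALSE
  )
}
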