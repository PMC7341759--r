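# Readers and writers for every external representation the pipeline
# touches: expression/design/clinical TSV, BED6+biotype annotation, GMT
# gene sets, SIF edge lists, JSON truth records.  Readers reject rather
# than coerce malformed input; writers are deterministic byte-for-byte.

# -- internal TSV plumbing ----------------------------------------------

.check_rectangular <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) stop("empty file: ", path)
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop(sprintf("parse error in %s: ragged row at line %d (%d fields, expected %d)",
                 path, bad[1L], nf[bad[1L]], nf[1L]))
  nf[1L]
}

.read_tsv <- function(path) {
  .check_rectangular(path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             colClasses = "character", quote = "", na.strings = NULL,
             stringsAsFactors = FALSE)
}

# format doubles so that write -> read round-trips to full precision
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a data frame as a plain deterministic TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

# -- expression + design -------------------------------------------------

#' Read an expression matrix (and optionally its sample design)
#'
#' The expression TSV has a header row of sample ids and one feature per
#' row, first column `feature_id`.  Duplicate ids, non-numeric cells and
#' ragged rows are parse errors reported with their line number.
#'
#' @param path Expression TSV.
#' @param design_path Optional design TSV (`sample_id`, `patient_id`,
#'   `tissue`); when given, the design may reference only samples present
#'   in the matrix and the return value is `list(expr, design)`.
#' @param flags_path Optional TSV of detection calls over the same grid.
#' @param paired Passed to [validate_design()] when a design is read.
#' @return An `expr_matrix`, or `list(expr =, design =)` when
#'   `design_path` is given.
#' @export
read_expression <- function(path, design_path = NULL, flags_path = NULL,
                            paired = TRUE) {
  df <- .read_tsv(path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    stop(sprintf("parse error in %s: duplicated feature id '%s' at line %d",
                 path, d, max(which(ids == d)) + 1L))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("parse error in %s: non-numeric value '%s' at line %d, sample '%s'",
                 path, raw[i, j], i + 1L, colnames(raw)[j]))
  }
  dimnames(num) <- list(ids, colnames(raw))
  flags <- NULL
  if (!is.null(flags_path)) {
    fdf <- .read_tsv(flags_path)
    flags <- as.matrix(fdf[, -1L, drop = FALSE])
    dimnames(flags) <- list(fdf[[1L]], colnames(flags))
    if (!identical(dimnames(flags), dimnames(num)))
      stop("parse error: detection flags do not cover the same feature x sample grid")
  }
  expr <- expression_matrix(num, flags)
  if (is.null(design_path)) return(expr)
  design <- read_design(design_path)
  validate_design(design, sample_ids = sample_ids(expr), paired = paired)
  list(expr = expr, design = design)
}

#' Write an expression matrix (inverse of [read_expression()])
#'
#' @param expr An `expr_matrix`.
#' @param path Output TSV path.
#' @param flags_path Optional path for the detection-flag grid.
#' @export
write_expression <- function(expr, path, flags_path = NULL) {
  v <- .values(expr)
  header <- paste(c("feature_id", colnames(v)), collapse = "\t")
  body <- paste(rownames(v),
                apply(matrix(.fmt_num(v), nrow(v)), 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  if (!is.null(flags_path) && !is.null(expr$flags)) {
    f <- expr$flags
    bodyf <- paste(rownames(f), apply(f, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, bodyf), flags_path)
  }
  invisible(path)
}

#' Read / write a sample design table
#' @param path TSV with columns `sample_id`, `patient_id`, `tissue`.
#' @return Data frame.
#' @export
read_design <- function(path) {
  df <- .read_tsv(path)
  validate_design(df, paired = FALSE)
  df
}

#' @rdname read_design
#' @param design Design data frame.
#' @export
write_design <- function(design, path) write_tsv(design, path)

# -- clinical ------------------------------------------------------------

.CLINICAL_COLS <- c("patient_id", "tumor_size_cm", "vascular_invasion",
                    "stage", "grade", "encapsulation", "invasion",
                    "os_time", "os_event")

.parse_logical <- function(x, field) {
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "True", "1", "yes")] <- TRUE
  out[x %in% c("FALSE", "False", "0", "no")] <- FALSE
  bad <- which(!(x %in% c("NA", "")) & is.na(out))
  if (length(bad))
    stop(sprintf("parse error: invalid %s value '%s' at line %d",
                 field, x[bad[1L]], bad[1L] + 1L))
  out
}

.parse_num <- function(x, field) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!(x %in% c("NA", "")) & is.na(out))
  if (length(bad))
    stop(sprintf("parse error: non-numeric %s value '%s' at line %d",
                 field, x[bad[1L]], bad[1L] + 1L))
  out
}

#' Read a per-patient clinical table
#'
#' Expects the eight raw characteristics used by the five phenotype
#' groups: tumor size (cm), vascular invasion, stage (1-4), Edmondson
#' grade (1-4), encapsulation (`complete`/`incomplete`/`none`), tumor
#' invasion, and overall-survival time/status.  Any field may be missing
#' (`NA`); values outside their domain are errors.
#'
#' @param path Clinical TSV keyed by `patient_id`.
#' @return Data frame with typed columns.
#' @export
read_clinical <- function(path) {
  df <- .read_tsv(path)
  miss <- setdiff(.CLINICAL_COLS, names(df))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient id: ", df$patient_id[duplicated(df$patient_id)][1L])
  out <- data.frame(patient_id = df$patient_id, stringsAsFactors = FALSE)
  out$tumor_size_cm <- .parse_num(df$tumor_size_cm, "tumor_size_cm")
  out$vascular_invasion <- .parse_logical(df$vascular_invasion, "vascular_invasion")
  for (f in c("stage", "grade")) {
    v <- .parse_num(df[[f]], f)
    bad <- which(!is.na(v) & !(v %in% 1:4))
    if (length(bad))
      stop(sprintf("domain error: %s %s at line %d (must be 1-4)",
                   f, v[bad[1L]], bad[1L] + 1L))
    out[[f]] <- as.integer(v)
  }
  enc <- df$encapsulation
  enc[enc %in% c("NA", "")] <- NA
  bad <- which(!is.na(enc) & !(enc %in% c("complete", "incomplete", "none")))
  if (length(bad))
    stop(sprintf("domain error: encapsulation '%s' at line %d", enc[bad[1L]],
                 bad[1L] + 1L))
  out$encapsulation <- enc
  out$invasion <- .parse_logical(df$invasion, "invasion")
  out$os_time <- .parse_num(df$os_time, "os_time")
  if (any(!is.na(out$os_time) & out$os_time <= 0))
    stop("domain error: os_time must be positive")
  out$os_event <- .parse_logical(df$os_event, "os_event")
  out
}

#' @rdname read_clinical
#' @param clinical Clinical data frame.
#' @export
write_clinical <- function(clinical, path) write_tsv(clinical, path)

# -- feature annotation (BED6 + biotype [+ symbol]) ----------------------

#' Read feature annotation from a BED6+1 file
#'
#' Columns: chrom, start, end, name (feature id), score, strand, biotype
#' (`lncRNA` or `protein_coding`), optional symbol.  Coordinates are kept
#' 0-based half-open, BED native.
#'
#' @param path BED path (no header).
#' @return Data frame with columns `feature_id`, `biotype`, `chrom`,
#'   `start`, `end`, `strand`, `symbol`.
#' @export
read_bed <- function(path) {
  nfield <- .check_rectangular(path)
  if (nfield < 7L)
    stop("parse error: BED annotation needs at least 7 columns (BED6 + biotype)")
  df <- read.delim(path, sep = "\t", header = FALSE, quote = "",
                   colClasses = "character", stringsAsFactors = FALSE)
  start <- .parse_num(df[[2L]], "start")
  end <- .parse_num(df[[3L]], "end")
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("parse error: malformed coordinate at line %d (start must be >= 0 and < end)",
                 bad[1L]))
  strand <- df[[6L]]
  bads <- which(!(strand %in% c("+", "-", ".")))
  if (length(bads))
    stop(sprintf("parse error: invalid strand '%s' at line %d", strand[bads[1L]], bads[1L]))
  bt <- df[[7L]]
  badb <- which(!(bt %in% c("lncRNA", "protein_coding")))
  if (length(badb))
    stop(sprintf("parse error: unknown biotype '%s' at line %d", bt[badb[1L]], badb[1L]))
  data.frame(feature_id = df[[4L]], biotype = bt, chrom = df[[1L]],
             start = as.integer(start), end = as.integer(end), strand = strand,
             symbol = if (nfield >= 8L) df[[8L]] else df[[4L]],
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param annotation Annotation data frame as returned by `read_bed()`.
#' @export
write_bed <- function(annotation, path) {
  lines <- with(annotation, paste(chrom, start, end, feature_id, 0L, strand,
                                  biotype, symbol, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# -- GMT gene sets -------------------------------------------------------

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#' Lines with no members are parse errors.
#'
#' @param path GMT path.
#' @return Named list of character vectors; descriptions are kept in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop(sprintf("parse error: empty gene set at line %d", short[1L]))
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("parse error: duplicated gene-set name: ", nm[duplicated(nm)][1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional named descriptions (defaults to set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# -- SIF edge lists ------------------------------------------------------

#' Write / read co-expression edges in simple interaction format
#'
#' One `lnc coexp mrna` line per pair, tab-separated, ordered
#' lexicographically by lncRNA then mRNA so output is diffable.  An empty
#' edge set yields an empty file.
#'
#' @param edges Data frame with columns `lnc_id` and `mrna_id`.
#' @param path Output path.
#' @param annotation Optional annotation; edges referencing features
#'   absent from it are an error.
#' @export
write_sif <- function(edges, path, annotation = NULL) {
  if (!is.null(annotation)) {
    unknown <- setdiff(c(edges$lnc_id, edges$mrna_id), annotation$feature_id)
    if (length(unknown))
      stop("edge references unknown feature: ", unknown[1L])
  }
  if (nrow(edges) == 0L) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  o <- order(edges$lnc_id, edges$mrna_id)
  writeLines(paste(edges$lnc_id[o], "coexp", edges$mrna_id[o], sep = "\t"), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(lnc_id = character(0L), mrna_id = character(0L),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("parse error: malformed SIF line %d", bad[1L]))
  data.frame(lnc_id = vapply(parts, `[[`, "", 1L),
             mrna_id = vapply(parts, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}
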