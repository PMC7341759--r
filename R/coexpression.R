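# Guilt-by-association co-expression: all-pairs Pearson correlation
# between differentially expressed lncRNAs and mRNAs, pair calling at
# |r| >= 0.9, and cis annotation against the genome.

#' Pearson correlation with an undefined-correlation sentinel
#'
#' Standard product-moment correlation; a constant vector has no defined
#' correlation and returns `NA` with a warning (callers skip such pairs).
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("correlation needs at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("undefined correlation: constant vector; pair skipped")
    return(NA_real_)
  }
  cor(x, y)
}

#' Call strongly co-expressed lncRNA-mRNA pairs
#'
#' Computes the full lncRNA x mRNA Pearson correlation matrix over the
#' chosen sample set (all tumor and non-tumor columns pooled by default)
#' restricted to differentially expressed features, and emits every pair
#' with `|r| >= threshold`.  Each pair records whether its correlation
#' sign is concordant with the two DE directions (same directions and
#' r > 0, or opposite directions and r < 0).
#'
#' @param expr An `expr_matrix` holding both biotypes.
#' @param de_lnc,de_mrna DE tables from [run_de()] for each biotype; only
#'   `is_de` features are correlated.
#' @param threshold Absolute-correlation calling threshold (default 0.9).
#' @param samples `"all"` pools tumor and non-tumor columns; `"tumor"`
#'   restricts to tumor columns (requires `design`).
#' @param design Sample design, needed for `samples = "tumor"`.
#' @return Data frame with `lnc_id`, `mrna_id`, `r`, `n_samples`,
#'   `de_concordant`, `is_cis` (NA until [annotate_cis()]), ordered
#'   lexicographically.
#' @export
call_pairs <- function(expr, de_lnc, de_mrna, threshold = 0.9,
                       samples = c("all", "tumor"), design = NULL) {
  samples <- match.arg(samples)
  v <- .values(expr)
  if (samples == "tumor") {
    if (is.null(design)) stop("tumor-only correlation needs a `design`")
    v <- v[, design$sample_id[design$tissue == "T"], drop = FALSE]
  }
  lnc <- de_lnc$feature_id[de_lnc$is_de]
  mrna <- de_mrna$feature_id[de_mrna$is_de]
  empty <- data.frame(lnc_id = character(0L), mrna_id = character(0L),
                      r = numeric(0L), n_samples = integer(0L),
                      de_concordant = logical(0L), is_cis = logical(0L),
                      stringsAsFactors = FALSE)
  if (length(lnc) == 0L || length(mrna) == 0L) {
    warning("no differentially expressed features on one side; no pairs")
    return(empty)
  }
  lm_ <- v[lnc, , drop = FALSE]
  mm <- v[mrna, , drop = FALSE]
  keep_l <- apply(lm_, 1L, sd) > 0
  keep_m <- apply(mm, 1L, sd) > 0
  if (!all(keep_l) || !all(keep_m))
    warning("constant feature(s) skipped: undefined correlation")
  lm_ <- lm_[keep_l, , drop = FALSE]
  mm <- mm[keep_m, , drop = FALSE]
  if (nrow(lm_) == 0L || nrow(mm) == 0L) return(empty)
  rmat <- cor(t(lm_), t(mm))
  hit <- which(abs(rmat) >= threshold, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  dir_l <- setNames(de_lnc$direction, de_lnc$feature_id)
  dir_m <- setNames(de_mrna$direction, de_mrna$feature_id)
  out <- data.frame(
    lnc_id = rownames(rmat)[hit[, 1L]],
    mrna_id = colnames(rmat)[hit[, 2L]],
    r = rmat[hit], n_samples = ncol(v),
    stringsAsFactors = FALSE)
  same_dir <- dir_l[out$lnc_id] == dir_m[out$mrna_id]
  out$de_concordant <- unname((out$r > 0 & same_dir) | (out$r < 0 & !same_dir))
  out$is_cis <- NA
  out <- out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gap between two genomic intervals
#'
#' Intervals are 0-based half-open (BED convention); overlapping or
#' book-ended intervals have gap 0.  Vectorized over the second interval.
#'
#' @param s1,e1 Start/end of the first interval.
#' @param s2,e2 Starts/ends of the second interval(s).
#' @return Non-negative gap in bases.
#' @export
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2))
}

#' Annotate co-expressed pairs with cis relationships
#'
#' A pair is cis when the mRNA is the lncRNA's nearest protein-coding
#' gene: same chromosome, minimal interval gap (0 when overlapping),
#' ties broken by the smaller start coordinate.  Nearest-gene search is
#' strand-agnostic and considers protein-coding features only.
#'
#' @param pairs Pair table from [call_pairs()].
#' @param annotation Feature annotation (see [read_bed()]).
#' @return The pair table with `is_cis` filled in (NA, with a warning,
#'   for pairs whose members lack coordinates).
#' @export
annotate_cis <- function(pairs, annotation) {
  if (nrow(pairs) == 0L) return(pairs)
  coding <- annotation[annotation$biotype == "protein_coding", , drop = FALSE]
  lncs <- unique(pairs$lnc_id)
  ann_idx <- match(lncs, annotation$feature_id)
  if (any(is.na(ann_idx))) {
    warning("un-annotated lncRNA(s); is_cis left missing: ",
            paste(head(lncs[is.na(ann_idx)], 3), collapse = ", "))
  }
  nearest_of <- setNames(rep(NA_character_, length(lncs)), lncs)
  for (i in which(!is.na(ann_idx))) {
    la <- annotation[ann_idx[i], ]
    cand <- coding[coding$chrom == la$chrom, , drop = FALSE]
    if (nrow(cand) == 0L) next
    gap <- interval_gap(la$start, la$end, cand$start, cand$end)
    cand <- cand[gap == min(gap), , drop = FALSE]
    nearest_of[lncs[i]] <- cand$feature_id[which.min(cand$start)]
  }
  mrna_known <- pairs$mrna_id %in% annotation$feature_id
  if (!all(mrna_known))
    warning("un-annotated mRNA(s); is_cis left missing: ",
            paste(head(unique(pairs$mrna_id[!mrna_known]), 3), collapse = ", "))
  near <- nearest_of[pairs$lnc_id]
  pairs$is_cis <- ifelse(is.na(near) | !mrna_known, NA,
                         pairs$mrna_id == near)
  pairs
}
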