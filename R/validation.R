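# Cross-cohort validation: trend concordance between a discovery and a
# validation cohort, and integration of an lncRNA-overexpression
# perturbation experiment with patient-cohort correlations.

#' Trend concordance between discovery and validation effects
#'
#' Over the discovery-significant features present in both tables,
#' counts how often the signed effects (log2 fold changes, or log HR /
#' log OR) agree in sign.  Features absent from the validation cohort
#' are excluded from the denominator and reported; discovery effects of
#' exactly zero have no sign and are excluded too.
#'
#' @param discovery Data frame with `feature_id`, `effect`, and
#'   optionally `significant` (all rows used when absent or when
#'   `require_significant = FALSE`).
#' @param validation Data frame with `feature_id`, `effect`.
#' @param require_significant Restrict to discovery-significant features
#'   (default TRUE when the column exists).
#' @param require_validation_significant Strict-replication mode: also
#'   require validation significance (needs a `significant` column
#'   there).
#' @return List of class `trend_report`: `n_discovery`, `n_matched`,
#'   `n_same_trend`, `percent`, `unmatched` (ids).
#' @export
trend_concordance <- function(discovery, validation,
                              require_significant = TRUE,
                              require_validation_significant = FALSE) {
  d <- discovery
  if (require_significant && !is.null(d$significant))
    d <- d[d$significant, , drop = FALSE]
  d <- d[!is.na(d$effect) & d$effect != 0, , drop = FALSE]
  v <- validation
  if (require_validation_significant) {
    if (is.null(v$significant))
      stop("strict replication needs a `significant` column in `validation`")
    v <- v[v$significant, , drop = FALSE]
  }
  if (!length(intersect(d$feature_id, v$feature_id)))
    stop("no overlapping feature ids between cohorts")
  idx <- match(d$feature_id, v$feature_id)
  matched <- !is.na(idx) & !is.na(v$effect[idx]) & v$effect[idx] != 0
  same <- sign(d$effect[matched]) == sign(v$effect[idx[matched]])
  structure(list(n_discovery = nrow(d), n_matched = sum(matched),
                 n_same_trend = sum(same),
                 percent = 100 * sum(same) / sum(matched),
                 unmatched = d$feature_id[!matched]),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf("trend concordance: %d/%d matched features same trend (%.1f%%); %d unmatched\n",
              x$n_same_trend, x$n_matched, x$percent, length(x$unmatched)))
  invisible(x)
}

#' Integrate a perturbation DE table with patient-cohort correlations
#'
#' Implements the overexpression strategy: genes altered at least
#' `fc_threshold`-fold when the lncRNA is over-expressed AND correlated
#' with that lncRNA in the patients at `|r| >= r_threshold` in the same
#' direction.  Up and down lists are disjoint by construction.
#'
#' @param oe_de Data frame of the perturbation experiment with `gene`
#'   and signed linear `fc` columns (overexpression vs control).
#' @param target_lnc The perturbed lncRNA id.
#' @param cor_table Patient-cohort correlations: data frame with
#'   `lnc_id`, `mrna_id` (or `gene`), `r`.
#' @param fc_threshold Absolute fold-change gate (default 2).
#' @param r_threshold Correlation gate (default 0.6).
#' @return List with sorted `up` and `down` gene vectors.
#' @export
perturbation_integrate <- function(oe_de, target_lnc, cor_table,
                                   fc_threshold = 2, r_threshold = 0.6) {
  gene_col <- if (!is.null(cor_table$mrna_id)) "mrna_id" else "gene"
  ct <- cor_table[cor_table$lnc_id == target_lnc, , drop = FALSE]
  if (nrow(ct) == 0L)
    stop("lncRNA absent from the correlation table: ", target_lnc)
  r_of <- setNames(ct$r, ct[[gene_col]])
  r <- r_of[oe_de$gene]
  up <- oe_de$gene[!is.na(r) & oe_de$fc >= fc_threshold & r >= r_threshold]
  down <- oe_de$gene[!is.na(r) & oe_de$fc <= -fc_threshold & r <= -r_threshold]
  list(up = sort(unique(up)), down = sort(unique(down)))
}
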