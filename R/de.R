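# Paired tumor-vs-non-tumor differential expression: per-feature paired t
# statistics, Benjamini-Hochberg control, and signed fold change, with
# the |FC| >= 2 / FDR < 0.05 calling rule.

#' Paired t-test on matched tumor / non-tumor values
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` on the per-patient
#' differences `d = T - NT` with a two-sided p-value from Student's t on
#' `n - 1` degrees of freedom.  Degenerate inputs follow an explicit
#' contract: zero-variance differences give `t = +/-Inf, p = 0` when the
#' mean difference is non-zero and `t = 0, p = 1` when it is zero.
#'
#' @param t_vals,nt_vals Matched numeric vectors (same patient order),
#'   length >= 2.
#' @return List with `t_stat`, `p`, `df`, `n`.
#' @export
paired_t_test <- function(t_vals, nt_vals) {
  if (length(t_vals) != length(nt_vals))
    stop("tumor and non-tumor vectors must be matched (equal length)")
  d <- t_vals - nt_vals
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("paired t-test needs at least 2 complete pairs")
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) return(list(t_stat = 0, p = 1, df = n - 1L, n = n))
    return(list(t_stat = sign(m) * Inf, p = 0, df = n - 1L, n = n))
  }
  t_stat <- m / (s / sqrt(n))
  list(t_stat = t_stat, p = 2 * pt(-abs(t_stat), n - 1L), df = n - 1L, n = n)
}

# Row-wise paired t over matrices (features x patients), NA-tolerant.
.row_paired_t <- function(tm, ntm) {
  d <- tm - ntm
  n <- rowSums(!is.na(d))
  if (any(n < 2L)) stop("paired t-test needs at least 2 complete pairs per feature")
  m <- rowMeans(d, na.rm = TRUE)
  ss <- rowSums(d * d, na.rm = TRUE) - n * m * m
  s2 <- pmax(ss, 0) / (n - 1L)
  s <- sqrt(s2)
  t_stat <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf),
                   m / (s / sqrt(n)))
  p <- ifelse(is.infinite(t_stat), 0, 2 * pt(-abs(t_stat), n - 1L))
  list(t_stat = t_stat, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in input order: `q_i` is the smallest
#' `m * p_(j) / j` over ranks `j` with `p_(j) >= p_(i)`, capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Run paired differential expression over a cohort
#'
#' Tests every feature with a paired t-test across the patient pairs,
#' adjusts p-values by Benjamini-Hochberg (jointly across all tested
#' features by default, or within each biotype), and calls a feature
#' differentially expressed when `q < fdr_threshold` and
#' `|fc| >= fc_threshold` (strict `>` optional).
#'
#' @param expr An `expr_matrix` (filtered/normalized upstream).
#' @param design Paired sample design (see [validate_design()]).
#' @param fc_threshold Absolute signed linear fold-change threshold
#'   (default 2).
#' @param fdr_threshold BH-adjusted significance level (default 0.05).
#' @param strict_fc Use `>` instead of `>=` for the fold-change gate.
#' @param biotype Optional named character vector (or annotation data
#'   frame) giving each feature's biotype; required for
#'   `fdr_family = "per_biotype"`.
#' @param fdr_family `"joint"` adjusts across all features in one family;
#'   `"per_biotype"` adjusts lncRNAs and mRNAs separately.
#' @return Data frame with one row per feature: `feature_id`, `mean_T`,
#'   `mean_NT`, `log2fc`, `fc`, `t_stat`, `p`, `q`, `direction`
#'   (`up`/`down`/`none`), `is_de`.
#' @export
run_de <- function(expr, design, fc_threshold = 2, fdr_threshold = 0.05,
                   strict_fc = FALSE, biotype = NULL,
                   fdr_family = c("joint", "per_biotype")) {
  fdr_family <- match.arg(fdr_family)
  v <- .values(expr)
  validate_design(design, sample_ids = colnames(v), paired = TRUE)
  pairs <- .paired_samples(design)
  tm <- v[, pairs$tumor, drop = FALSE]
  ntm <- v[, pairs$nontumor, drop = FALSE]
  tt <- .row_paired_t(tm, ntm)
  mean_t <- rowMeans(tm, na.rm = TRUE)
  mean_nt <- rowMeans(ntm, na.rm = TRUE)
  fc <- fold_change(mean_t, mean_nt)
  if (fdr_family == "joint") {
    q <- benjamini_hochberg(tt$p)
  } else {
    if (is.null(biotype)) stop("per-biotype FDR needs a `biotype` mapping")
    bt <- .biotype_of(rownames(v), biotype)
    q <- numeric(length(tt$p))
    for (b in unique(bt)) {
      idx <- bt == b
      q[idx] <- benjamini_hochberg(tt$p[idx])
    }
  }
  fc_pass <- if (strict_fc) abs(fc) > fc_threshold else abs(fc) >= fc_threshold
  is_de <- q < fdr_threshold & fc_pass
  data.frame(feature_id = rownames(v), mean_T = mean_t, mean_NT = mean_nt,
             log2fc = mean_t - mean_nt, fc = fc, t_stat = tt$t_stat,
             p = tt$p, q = q,
             direction = ifelse(!is_de, "none", ifelse(fc > 0, "up", "down")),
             is_de = is_de, row.names = NULL, stringsAsFactors = FALSE)
}

# biotype lookup from a named vector or an annotation data frame
.biotype_of <- function(ids, biotype) {
  if (is.data.frame(biotype))
    biotype <- setNames(biotype$biotype, biotype$feature_id)
  bt <- biotype[ids]
  if (any(is.na(bt)))
    stop("missing biotype for feature(s): ",
         paste(head(ids[is.na(bt)], 3), collapse = ", "))
  unname(bt)
}
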