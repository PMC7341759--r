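# Clinical-phenotype association: dichotomize the eight raw
# characteristics into five groups (tumor properties, grade, capsule,
# invasion, overall survival), test each feature's tumor expression
# against every group, and classify features as potentially oncogenic or
# tumor-suppressive when differential expression and clinical
# association point the same way.


#' Dichotomize raw clinical characteristics into good/poor groups
#'
#' Good characteristics are tumor size < 5 cm, no vascular invasion,
#' stage 1/2, grade 1/2, complete encapsulation and no tumor invasion.
#' The composite `tumor_properties` group (size, vascular invasion,
#' stage) is poor when any available sub-phenotype is poor, good when all
#' available ones are good, and missing only when no sub-phenotype is
#' available.
#'
#' @param clinical Clinical data frame (see [read_clinical()]).
#' @return Data frame with `patient_id`, one `good`/`poor`/`NA` column
#'   per t-test group, plus `os_time` and `os_event` carried through.
#' @export
dichotomize <- function(clinical) {
  poor_of <- function(x) ifelse(is.na(x), NA, ifelse(x, "poor", "good"))
  subs <- cbind(size = clinical$tumor_size_cm >= 5,
                vasc = clinical$vascular_invasion,
                stage = clinical$stage %in% c(3L, 4L) &
                  !is.na(clinical$stage))
  subs[is.na(clinical$stage), "stage"] <- NA
  any_poor <- apply(subs, 1L, function(r) {
    if (all(is.na(r))) NA else any(r, na.rm = TRUE)
  })
  data.frame(
    patient_id = clinical$patient_id,
    tumor_properties = poor_of(any_poor),
    grade = poor_of(clinical$grade %in% c(3L, 4L) |
                      ifelse(is.na(clinical$grade), NA, FALSE)),
    capsule = poor_of(clinical$encapsulation %in% c("incomplete", "none") |
                        ifelse(is.na(clinical$encapsulation), NA, FALSE)),
    invasion = poor_of(clinical$invasion),
    os_time = clinical$os_time, os_event = clinical$os_event,
    stringsAsFactors = FALSE)
}

#' Two-sample Student t-test of poor vs good tumor expression
#'
#' Pooled-variance two-sided t-test; the effect is the signed linear fold
#' change of the poor-arm mean over the good-arm mean (log2 domain).  An
#' arm with fewer than 2 samples yields a not-testable sentinel; zero
#' pooled variance is handled like the paired test's degenerate contract.
#'
#' @param poor_vals,good_vals Tumor log2 intensities in each arm.
#' @return List with `fc`, `log2fc`, `t_stat`, `p`, `df`, `testable`.
#' @export
group_t_test <- function(poor_vals, good_vals) {
  poor_vals <- poor_vals[!is.na(poor_vals)]
  good_vals <- good_vals[!is.na(good_vals)]
  n1 <- length(poor_vals); n2 <- length(good_vals)
  if (n1 < 2L || n2 < 2L)
    return(list(fc = NA_real_, log2fc = NA_real_, t_stat = NA_real_,
                p = NA_real_, df = NA_integer_, testable = FALSE))
  m1 <- mean(poor_vals); m2 <- mean(good_vals)
  sp2 <- ((n1 - 1) * var(poor_vals) + (n2 - 1) * var(good_vals)) / (n1 + n2 - 2)
  d <- m1 - m2
  if (sp2 == 0) {
    t_stat <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    t_stat <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(t_stat), n1 + n2 - 2L)
  }
  list(fc = fold_change(m1, m2), log2fc = d, t_stat = t_stat, p = p,
       df = n1 + n2 - 2L, testable = TRUE)
}

# Row-wise pooled-variance t over tumor matrices split into arms.
.row_group_t <- function(xpoor, xgood) {
  n1 <- ncol(xpoor); n2 <- ncol(xgood)
  m1 <- rowMeans(xpoor); m2 <- rowMeans(xgood)
  v1 <- rowSums((xpoor - m1)^2) / (n1 - 1L)
  v2 <- rowSums((xgood - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  d <- m1 - m2
  t_stat <- ifelse(sp2 == 0, ifelse(d == 0, 0, sign(d) * Inf),
                   d / sqrt(sp2 * (1 / n1 + 1 / n2)))
  p <- ifelse(is.infinite(t_stat), 0,
              ifelse(sp2 == 0 & d == 0, 1, 2 * pt(-abs(t_stat), n1 + n2 - 2L)))
  list(log2fc = d, t_stat = t_stat, p = p)
}

#' Univariate Cox proportional-hazards regression
#'
#' Fits overall survival on a single continuous covariate, Breslow tie
#' handling, two-sided Wald p-value.  Constant covariates or fewer than
#' two events yield a not-testable sentinel; monotone likelihood
#' (perfect separation of risk) sets a divergence flag.
#'
#' @param values Per-patient covariate (e.g. tumor expression).
#' @param os_time,os_event Survival time and event indicator.
#' @return List with `beta`, `hr`, `se`, `p`, `testable`, `diverged`.
#' @export
cox_univariate <- function(values, os_time, os_event) {
  keep <- complete.cases(values, os_time, os_event)
  x <- values[keep]; ti <- os_time[keep]; ev <- as.logical(os_event[keep])
  sentinel <- list(beta = NA_real_, hr = NA_real_, se = NA_real_,
                   p = NA_real_, testable = FALSE, diverged = FALSE)
  if (sum(ev) < 2L || length(unique(x)) < 2L) return(sentinel)
  diverged <- FALSE
  fit <- withCallingHandlers(
    tryCatch(coxph(Surv(ti, ev) ~ x, ties = "breslow",
                   control = coxph.control(iter.max = 50L)),
             error = function(e) NULL),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit)) return(sentinel)
  beta <- unname(coef(fit)[1L])
  se <- sqrt(fit$var[1L, 1L])
  z <- beta / se
  list(beta = beta, hr = exp(beta), se = se, p = 2 * pnorm(-abs(z)),
       testable = TRUE, diverged = diverged)
}

#' Univariate logistic regression of a binary label on expression
#'
#' Maximum-likelihood slope with Wald p-value; used for validation-style
#' cohorts where categorical phenotypes are modeled by logistic rather
#' than t-tests.  One class absent is an error; complete separation sets
#' a divergence flag.
#'
#' @param values Continuous covariate.
#' @param binary_label Logical (or 0/1) outcome.
#' @return List with `beta`, `or`, `se`, `p`, `testable`, `diverged`.
#' @export
logistic_univariate <- function(values, binary_label) {
  keep <- complete.cases(values, binary_label)
  x <- values[keep]; y <- as.numeric(binary_label[keep])
  if (length(unique(y)) < 2L)
    stop("logistic regression needs both outcome classes present")
  if (length(unique(x)) < 2L)
    return(list(beta = NA_real_, or = NA_real_, se = NA_real_, p = NA_real_,
                testable = FALSE, diverged = FALSE))
  diverged <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  beta <- unname(coef(fit)["x"])
  list(beta = beta, or = exp(beta), se = sm["x", "Std. Error"],
       p = sm["x", "Pr(>|z|)"], testable = TRUE, diverged = diverged)
}

#' Associate every feature with the five clinical groups
#'
#' For the four categorical groups, compares tumor expression between
#' poor and good patients with a pooled-variance Student t-test
#' (significant when `|fc| >= fc_threshold` and `p < p_threshold`,
#' unadjusted).  For overall survival, fits a univariate Cox model on
#' tumor expression (significant when `p < p_threshold` and HR differs
#' from 1).  Only tumor samples enter, since phenotypes describe the
#' tumor.  Patients missing a phenotype are dropped from that group only.
#'
#' @param expr An `expr_matrix` (normalized).
#' @param design Paired sample design.
#' @param clinical Clinical table; dichotomized internally.
#' @param features Optional feature subset to test (default: all).
#' @param fc_threshold,p_threshold Calling thresholds (defaults 1.5 and
#'   0.05).
#' @return Data frame with `feature_id`, `group`, `effect` (signed fold
#'   change for t-test groups, hazard ratio for survival), `log2fc`,
#'   `p`, `q` (BH within group, informational), `direction`
#'   (`up_in_poor`/`down_in_poor`), `significant`, `testable`.
#' @export
run_clinical_association <- function(expr, design, clinical, features = NULL,
                                     fc_threshold = 1.5, p_threshold = 0.05) {
  v <- .values(expr)
  validate_design(design, sample_ids = colnames(v), paired = TRUE)
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  groups <- dichotomize(clinical)
  pairs <- .paired_samples(design)
  pairs <- pairs[pairs$patient_id %in% groups$patient_id, , drop = FALSE]
  tv <- v[, pairs$tumor, drop = FALSE]      # tumor columns, patient order
  gidx <- match(pairs$patient_id, groups$patient_id)
  out <- list()
  for (g in .PHENO_GROUPS) {
    lab <- groups[[g]][gidx]
    poor <- which(!is.na(lab) & lab == "poor")
    good <- which(!is.na(lab) & lab == "good")
    if (length(poor) < 2L || length(good) < 2L) {
      out[[g]] <- data.frame(feature_id = rownames(tv), group = g,
                             effect = NA_real_, log2fc = NA_real_,
                             p = NA_real_, q = NA_real_,
                             direction = NA_character_, significant = FALSE,
                             testable = FALSE, stringsAsFactors = FALSE)
      next
    }
    tt <- .row_group_t(tv[, poor, drop = FALSE], tv[, good, drop = FALSE])
    fc <- ifelse(tt$log2fc >= 0, 2^tt$log2fc, -(2^(-tt$log2fc)))
    sig <- abs(fc) >= fc_threshold & tt$p < p_threshold
    out[[g]] <- data.frame(
      feature_id = rownames(tv), group = g, effect = fc, log2fc = tt$log2fc,
      p = tt$p, q = benjamini_hochberg(tt$p),
      direction = ifelse(fc > 0, "up_in_poor", "down_in_poor"),
      significant = sig, testable = TRUE, stringsAsFactors = FALSE)
  }
  os_time <- groups$os_time[gidx]
  os_event <- groups$os_event[gidx]
  cox <- lapply(seq_len(nrow(tv)), function(i)
    cox_univariate(tv[i, ], os_time, os_event))
  hr <- vapply(cox, `[[`, 0, "hr")
  pv <- vapply(cox, `[[`, 0, "p")
  testable <- vapply(cox, `[[`, TRUE, "testable")
  qv <- rep(NA_real_, length(pv))
  if (any(testable)) qv[testable] <- benjamini_hochberg(pv[testable])
  out$survival <- data.frame(
    feature_id = rownames(tv), group = "survival", effect = hr,
    log2fc = NA_real_, p = pv, q = qv,
    direction = ifelse(!testable, NA_character_,
                       ifelse(hr > 1, "up_in_poor", "down_in_poor")),
    significant = testable & !is.na(pv) & pv < p_threshold & hr != 1,
    testable = testable, stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify features as potentially oncogenic or tumor-suppressive
#'
#' A feature is potentially oncogenic when it is up-regulated in tumors
#' and significantly associated, in the same (poor) direction, with at
#' least one clinical group; potentially tumor-suppressive when it is
#' down-regulated and associated with the good direction (i.e. lower
#' expression tracks poorer characteristics).  `groups` lists only
#' direction-concordant significant groups.
#'
#' @param de DE table from [run_de()].
#' @param assoc Association table from [run_clinical_association()].
#' @return Data frame with `feature_id`, `cls`
#'   (`oncogenic`/`suppressor`/`none`), `groups` (comma-collapsed).
#' @export
classify_relevance <- function(de, assoc) {
  want <- ifelse(de$direction == "up", "up_in_poor",
                 ifelse(de$direction == "down", "down_in_poor", NA))
  sig <- assoc[assoc$significant & !is.na(assoc$direction), , drop = FALSE]
  grp <- vapply(seq_len(nrow(de)), function(i) {
    if (is.na(want[i])) return("")
    g <- sig$group[sig$feature_id == de$feature_id[i] &
                     sig$direction == want[i]]
    paste(sort(unique(g)), collapse = ",")
  }, "")
  cls <- ifelse(!de$is_de | grp == "", "none",
                ifelse(de$direction == "up", "oncogenic", "suppressor"))
  grp[cls == "none"] <- ""
  data.frame(feature_id = de$feature_id, cls = cls, groups = grp,
             stringsAsFactors = FALSE)
}

# split the comma-collapsed groups column back into a list
.relevance_groups <- function(relevance) {
  setNames(strsplit(relevance$groups, ",", fixed = TRUE),
           relevance$feature_id)
}
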