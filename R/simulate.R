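# Paired tumor/non-tumor cohort simulator with planted co-expression
# modules, tumor shifts, phenotype links and proportional-hazards
# survival.  Module members follow a single-factor model
#   x_fs = mu_f + b * z_s + delta * 1[tumor] + phenotype effect + eps_fs
# with one latent factor z per module drawn independently per sample, so
# that the within-module correlation implied by the loading/noise pair is
# r = b^2 / (b^2 + sigma^2).


#' Specify one planted co-expression module
#'
#' @param n_lnc_members,n_mrna_members Member counts per biotype.
#' @param target_r Within-module Pearson correlation implied by the
#'   latent-factor model, in (0, 1); the loading is derived from it and
#'   the cohort noise level via `b = sigma * sqrt(r / (1 - r))`.
#' @param tumor_shift Signed tumor-vs-non-tumor shift in log2 units
#'   (|shift| < 6).
#' @param linked_group Clinical group the module drives: one of
#'   `"tumor_properties"`, `"grade"`, `"capsule"`, `"invasion"`,
#'   `"survival"`, `"none"`.
#' @param phenotype_effect Extra log2 units added to tumor samples of
#'   poor-phenotype patients of the linked group (sign follows
#'   `tumor_shift`, so an up module is higher in poor tumors and a down
#'   module lower).
#' @param hazard_beta Log-hazard per unit of the patient's tumor-sample
#'   latent factor (used when `linked_group = "survival"`).
#' @return A `module_spec` list.
#' @export
module_spec <- function(n_lnc_members, n_mrna_members, target_r = 0.9,
                        tumor_shift = 0, linked_group = "none",
                        phenotype_effect = 0, hazard_beta = 0) {
  if (!is.numeric(n_lnc_members) || n_lnc_members < 1)
    .cfg_stop("n_lnc_members", "must be a positive count")
  if (!is.numeric(n_mrna_members) || n_mrna_members < 1)
    .cfg_stop("n_mrna_members", "must be a positive count")
  if (!is.numeric(target_r) || target_r <= 0 || target_r >= 1)
    .cfg_stop("target_r", "must lie in (0, 1)")
  if (abs(tumor_shift) >= 6)
    .cfg_stop("tumor_shift", "|tumor_shift| must be < 6 log2 units")
  if (!linked_group %in% .LINK_GROUPS)
    .cfg_stop("linked_group", paste("must be one of",
                                    paste(.LINK_GROUPS, collapse = ", ")))
  if (phenotype_effect < 0)
    .cfg_stop("phenotype_effect", "must be non-negative")
  structure(list(n_lnc_members = as.integer(n_lnc_members),
                 n_mrna_members = as.integer(n_mrna_members),
                 target_r = target_r, tumor_shift = tumor_shift,
                 linked_group = linked_group,
                 phenotype_effect = phenotype_effect,
                 hazard_beta = hazard_beta),
            class = "module_spec")
}

#' Simulation configuration for a paired cohort
#'
#' Defaults mirror the study design the package targets: 49 patients with
#' one tumor and one matched non-tumor sample each, microarray-like log2
#' baselines drawn uniformly on (6, 14), and a sparse background of
#' tumor-shifted features emulating a global tumor program.
#'
#' @param n_patients Number of patients (>= 3); each contributes a tumor
#'   and a matched non-tumor column.
#' @param n_lnc,n_mrna Feature counts per biotype.
#' @param modules List of [module_spec()] objects; member counts must fit
#'   within `n_lnc` / `n_mrna`, and at most one module may drive each
#'   non-survival clinical group.
#' @param baseline_mean_range Interval for per-feature baseline means
#'   (log2 units).
#' @param feature_noise_sd Per-observation Gaussian noise, log2 units.
#' @param de_background_fraction Fraction of non-module features of each
#'   biotype given a tumor-vs-non-tumor shift of `de_background_shift`
#'   log2 units with random sign.
#' @param de_background_shift Magnitude of the background shift.
#' @param censoring_rate Expected fraction of patients censored.
#' @param baseline_median_survival Median survival (days) at a zero
#'   linear predictor.
#' @param phenotype_quantile Latent-factor quantile that splits linked
#'   groups into good/poor (default median).
#' @param flag_absent_quantile Fraction of lowest-intensity cells marked
#'   `Absent` (0 = all Present).
#' @param seed Integer seed; identical configs generate byte-identical
#'   cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 49, n_lnc = 2000, n_mrna = 2000,
                       modules = list(), baseline_mean_range = c(6, 14),
                       feature_noise_sd = 0.35,
                       de_background_fraction = 0.05,
                       de_background_shift = 1.0,
                       censoring_rate = 0.3,
                       baseline_median_survival = 730,
                       phenotype_quantile = 0.5,
                       flag_absent_quantile = 0,
                       seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 3)
    .cfg_stop("n_patients", "must be >= 3")
  if (n_lnc < 1) .cfg_stop("n_lnc", "must be a positive count")
  if (n_mrna < 1) .cfg_stop("n_mrna", "must be a positive count")
  if (length(baseline_mean_range) != 2L ||
      baseline_mean_range[1L] >= baseline_mean_range[2L])
    .cfg_stop("baseline_mean_range", "must be an increasing interval")
  if (feature_noise_sd < 0) .cfg_stop("feature_noise_sd", "must be >= 0")
  for (f in c("de_background_fraction", "censoring_rate",
              "phenotype_quantile", "flag_absent_quantile")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) .cfg_stop(f, "must lie in [0, 1]")
  }
  if (baseline_median_survival <= 0)
    .cfg_stop("baseline_median_survival", "must be positive")
  if (!is.list(modules) ||
      !all(vapply(modules, inherits, TRUE, "module_spec")))
    .cfg_stop("modules", "must be a list of module_spec objects")
  if (length(modules)) {
    if (sum(vapply(modules, `[[`, 1L, "n_lnc_members")) > n_lnc)
      .cfg_stop("modules", "module lncRNA member counts exceed n_lnc")
    if (sum(vapply(modules, `[[`, 1L, "n_mrna_members")) > n_mrna)
      .cfg_stop("modules", "module mRNA member counts exceed n_mrna")
    lg <- vapply(modules, `[[`, "", "linked_group")
    lg <- lg[lg %in% .PHENO_GROUPS]
    if (anyDuplicated(lg))
      .cfg_stop("modules", paste("clinical group linked by more than one module:",
                                 lg[duplicated(lg)][1L]))
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_lnc = as.integer(n_lnc), n_mrna = as.integer(n_mrna),
                 modules = modules, baseline_mean_range = baseline_mean_range,
                 feature_noise_sd = feature_noise_sd,
                 de_background_fraction = de_background_fraction,
                 de_background_shift = de_background_shift,
                 censoring_rate = censoring_rate,
                 baseline_median_survival = baseline_median_survival,
                 phenotype_quantile = phenotype_quantile,
                 flag_absent_quantile = flag_absent_quantile,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Within-module correlation implied by a loading/noise pair
#'
#' Two features sharing a unit-variance latent factor with loading `b`
#' and independent noise of standard deviation `sigma` have Pearson
#' correlation `b^2 / (b^2 + sigma^2)`.
#'
#' @param loading Latent-factor loading `b`.
#' @param noise_sd Noise standard deviation `sigma` (>= 0).
#' @return The implied correlation.
#' @examples
#' expected_module_r(1, 1)  # 0.5
#' expected_module_r(3, 1)  # 0.9
#' @export
expected_module_r <- function(loading, noise_sd) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (loading == 0 && noise_sd == 0)
    stop("undefined correlation: loading and noise_sd are both zero")
  loading^2 / (loading^2 + noise_sd^2)
}

# loading that realizes target_r at noise sigma; any positive loading
# gives r = 1 when sigma = 0.
.loading_for <- function(target_r, sigma) {
  if (sigma == 0) return(1)
  sigma * sqrt(target_r / (1 - target_r))
}

#' Generate a synthetic paired tumor/non-tumor cohort
#'
#' Produces the full input bundle the analysis pipeline consumes --
#' expression matrix with detection flags, paired sample design, clinical
#' table, BED-style feature annotation (each module contributes one
#' cis-adjacent lncRNA/mRNA pair on its own chromosome), a GMT collection
#' holding one pathway per module plus decoy sets -- together with a
#' machine-readable truth record of everything that was planted.
#'
#' @param config A [sim_config()].
#' @return A list of class `lnc_cohort` with elements `expr`, `design`,
#'   `clinical`, `annotation`, `gene_sets`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be created with sim_config()")
  set.seed(config$seed)
  np <- config$n_patients
  width <- max(2L, nchar(as.character(np)))
  pid <- sprintf(paste0("P%0", width, "d"), seq_len(np))
  sample_id <- as.vector(rbind(paste0(pid, "_T"), paste0(pid, "_NT")))
  tissue <- rep(c("T", "NT"), np)
  patient_of <- rep(pid, each = 2L)
  is_t <- tissue == "T"
  ns <- length(sample_id)
  design <- data.frame(sample_id = sample_id, patient_id = patient_of,
                       tissue = tissue, stringsAsFactors = FALSE)

  lnc_ids <- sprintf("LNC%05d", seq_len(config$n_lnc))
  mrna_ids <- sprintf("MRNA%05d", seq_len(config$n_mrna))
  fid <- c(lnc_ids, mrna_ids)
  nf <- length(fid)
  sigma <- config$feature_noise_sd

  # module membership: consecutive blocks from the front of each biotype
  mods <- config$modules
  lnc_ptr <- 0L; mrna_ptr <- 0L
  members <- lapply(mods, function(m) {
    li <- lnc_ids[lnc_ptr + seq_len(m$n_lnc_members)]
    mi <- mrna_ids[mrna_ptr + seq_len(m$n_mrna_members)]
    lnc_ptr <<- lnc_ptr + m$n_lnc_members
    mrna_ptr <<- mrna_ptr + m$n_mrna_members
    list(lnc_ids = li, mrna_ids = mi)
  })

  # 1. baselines, 2. latent factors, 3. noise -- fixed RNG order
  mu <- runif(nf, config$baseline_mean_range[1L], config$baseline_mean_range[2L])
  z <- if (length(mods)) matrix(rnorm(length(mods) * ns), length(mods), ns)
       else matrix(numeric(0L), 0L, ns)
  # center each module factor within the tumor and non-tumor sample
  # groups: the realized tumor/non-tumor contrast then equals the
  # configured shift exactly instead of inheriting the cohort-level
  # luck of the latent draw
  if (length(mods)) {
    z[, is_t] <- z[, is_t, drop = FALSE] -
      rowMeans(z[, is_t, drop = FALSE])
    z[, !is_t] <- z[, !is_t, drop = FALSE] -
      rowMeans(z[, !is_t, drop = FALSE])
  }
  x <- matrix(rnorm(nf * ns, sd = sigma), nf, ns,
              dimnames = list(fid, sample_id)) + mu

  tumor_cols <- which(is_t)                 # column of patient i's tumor
  pheno_labels <- matrix(NA_character_, np, length(.PHENO_GROUPS),
                         dimnames = list(pid, .PHENO_GROUPS))
  module_truth <- vector("list", length(mods))
  for (k in seq_along(mods)) {
    m <- mods[[k]]
    b <- .loading_for(m$target_r, sigma)
    rows <- match(c(members[[k]]$lnc_ids, members[[k]]$mrna_ids), fid)
    zk <- z[k, ]
    x[rows, ] <- x[rows, ] +
      rep(b * zk + m$tumor_shift * is_t, each = length(rows))
    s <- if (m$tumor_shift < 0) -1 else 1
    poor_pat <- character(0L)
    if (m$linked_group %in% .PHENO_GROUPS) {
      zt <- zk[tumor_cols] * s
      poor <- zt > quantile(zt, config$phenotype_quantile)
      poor_pat <- pid[poor]
      pheno_labels[, m$linked_group] <- ifelse(poor, "poor", "good")
      if (m$phenotype_effect > 0) {
        cols <- which(is_t & patient_of %in% poor_pat)
        x[rows, cols] <- x[rows, cols] + s * m$phenotype_effect
      }
    }
    module_truth[[k]] <- list(
      module = k, lnc_ids = members[[k]]$lnc_ids,
      mrna_ids = members[[k]]$mrna_ids, loading = b,
      target_r = m$target_r, tumor_shift = m$tumor_shift,
      de_direction = if (m$tumor_shift > 0) "up"
                     else if (m$tumor_shift < 0) "down" else "none",
      linked_group = m$linked_group, phenotype_effect = m$phenotype_effect,
      hazard_beta = m$hazard_beta, poor_patients = poor_pat)
  }

  # 4. background tumor shifts on non-module features
  in_module <- fid %in% unlist(lapply(members, unlist), use.names = FALSE)
  bg <- data.frame(feature_id = character(0L), direction = character(0L),
                   stringsAsFactors = FALSE)
  if (config$de_background_fraction > 0) {
    pick <- function(ids) {
      free <- ids[!(ids %in% fid[in_module])]
      nsel <- floor(config$de_background_fraction * length(free))
      if (nsel > 0) sort(sample(free, nsel)) else character(0L)
    }
    bg_ids <- c(pick(lnc_ids), pick(mrna_ids))
    if (length(bg_ids)) {
      sgn <- sample(c(-1, 1), length(bg_ids), replace = TRUE)
      rows <- match(bg_ids, fid)
      x[rows, ] <- x[rows, ] +
        outer(sgn * config$de_background_shift, as.numeric(is_t))
      bg <- data.frame(feature_id = bg_ids,
                       direction = ifelse(sgn > 0, "up", "down"),
                       stringsAsFactors = FALSE)
    }
  }

  # 5. unlinked clinical groups get coin-flip labels
  for (g in .PHENO_GROUPS) {
    if (all(is.na(pheno_labels[, g])))
      pheno_labels[, g] <- ifelse(runif(np) < 0.5, "poor", "good")
  }

  # 6. raw clinical fields consistent with the assigned labels
  clinical <- .labels_to_clinical(pid, pheno_labels)

  # 7. survival: exponential hazard lambda0 * exp(sum beta_m * z_m,T)
  lp <- rep(0, np)
  for (k in seq_along(mods)) {
    if (mods[[k]]$linked_group == "survival" && mods[[k]]$hazard_beta != 0)
      lp <- lp + mods[[k]]$hazard_beta * z[k, tumor_cols]
  }
  lambda0 <- log(2) / config$baseline_median_survival
  t_true <- rexp(np, rate = lambda0 * exp(lp))
  # independent exponential censoring calibrated so a baseline-hazard
  # patient is censored with probability censoring_rate
  if (config$censoring_rate > 0) {
    mu <- lambda0 * config$censoring_rate / (1 - config$censoring_rate)
    c_time <- rexp(np, rate = mu)
  } else {
    c_time <- rep(Inf, np)
  }
  censored <- c_time < t_true
  os_time <- pmax(pmin(t_true, c_time), 0.5)
  clinical$os_time <- os_time
  clinical$os_event <- !censored

  # detection flags
  flags <- matrix("Present", nf, ns, dimnames = dimnames(x))
  if (config$flag_absent_quantile > 0) {
    thr <- quantile(x, config$flag_absent_quantile)
    flags[x < thr] <- "Absent"
  }

  annotation <- .simulate_annotation(members, lnc_ids, mrna_ids)
  gene_sets <- .simulate_gene_sets(members, mrna_ids)

  truth <- list(
    modules = module_truth,
    background_de = bg,
    phenotype_labels = data.frame(patient_id = pid,
                                  as.data.frame(pheno_labels),
                                  row.names = NULL,
                                  stringsAsFactors = FALSE),
    latent = if (length(mods)) {
      data.frame(patient_id = pid,
                 setNames(as.data.frame(t(z[, tumor_cols, drop = FALSE])),
                          paste0("z_module", seq_along(mods))),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = pid, stringsAsFactors = FALSE)
    },
    survival = data.frame(patient_id = pid, linear_predictor = lp,
                          os_time = os_time, os_event = !censored,
                          censored = censored, stringsAsFactors = FALSE),
    seed = config$seed)

  structure(list(expr = expression_matrix(x, flags), design = design,
                 clinical = clinical, annotation = annotation,
                 gene_sets = gene_sets, truth = truth, config = config),
            class = "lnc_cohort")
}

# raw clinical fields whose dichotomization reproduces the planted labels
.labels_to_clinical <- function(pid, labels) {
  np <- length(pid)
  size <- numeric(np); vasc <- logical(np); stage <- integer(np)
  tp_poor <- labels[, "tumor_properties"] == "poor"
  # poor composite: at least one sub-phenotype poor, chosen at random
  which_poor <- matrix(runif(np * 3L) < 0.5, np, 3L)
  none <- !rowSums(which_poor)
  which_poor[none, 1L] <- TRUE
  size <- ifelse(tp_poor & which_poor[, 1L], runif(np, 5, 12), runif(np, 1, 4.9))
  vasc <- tp_poor & which_poor[, 2L]
  stage <- ifelse(tp_poor & which_poor[, 3L],
                  sample(3:4, np, replace = TRUE),
                  sample(1:2, np, replace = TRUE))
  gr_poor <- labels[, "grade"] == "poor"
  grade <- ifelse(gr_poor, sample(3:4, np, replace = TRUE),
                  sample(1:2, np, replace = TRUE))
  cp_poor <- labels[, "capsule"] == "poor"
  enc <- ifelse(cp_poor, sample(c("incomplete", "none"), np, replace = TRUE),
                "complete")
  data.frame(patient_id = pid, tumor_size_cm = round(size, 1),
             vascular_invasion = vasc, stage = as.integer(stage),
             grade = as.integer(grade), encapsulation = enc,
             invasion = labels[, "invasion"] == "poor",
             os_time = NA_real_, os_event = NA,
             stringsAsFactors = FALSE)
}

# Each module gets its own chromosome carrying exactly its first lncRNA
# and first mRNA as an adjacent cis pair; every other feature goes to a
# shared pool of chromosomes with 100 kb spacing.
.simulate_annotation <- function(members, lnc_ids, mrna_ids) {
  nmod <- length(members)
  cis_lnc <- vapply(members, function(m) m$lnc_ids[1L], "")
  cis_mrna <- vapply(members, function(m) m$mrna_ids[1L], "")
  rows <- list()
  for (k in seq_len(nmod)) {
    chrom <- paste0("chr", k)
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = c(cis_lnc[k], cis_mrna[k]),
      biotype = c("lncRNA", "protein_coding"), chrom = chrom,
      start = c(1000L, 3000L), end = c(2000L, 4000L), strand = "+",
      symbol = c(cis_lnc[k], cis_mrna[k]), stringsAsFactors = FALSE)
  }
  rest <- c(setdiff(lnc_ids, cis_lnc), setdiff(mrna_ids, cis_mrna))
  if (length(rest)) {
    shared <- paste0("chr", nmod + 1L + (seq_along(rest) - 1L) %% 10L)
    pos <- 1000L + ((seq_along(rest) - 1L) %/% 10L) * 100000L
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = rest,
      biotype = ifelse(rest %in% lnc_ids, "lncRNA", "protein_coding"),
      chrom = shared, start = pos, end = pos + 1000L, strand = "+",
      symbol = rest, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.simulate_gene_sets <- function(members, mrna_ids, n_decoys = 15L,
                                decoy_size = 25L) {
  sets <- list(); desc <- character(0L)
  for (k in seq_along(members)) {
    nm <- sprintf("MODULE%d_PATHWAY", k)
    sets[[nm]] <- members[[k]]$mrna_ids
    desc[nm] <- "planted"
  }
  free <- setdiff(mrna_ids, unlist(lapply(members, `[[`, "mrna_ids")))
  if (length(free) >= 2L) {
    for (d in seq_len(n_decoys)) {
      nm <- sprintf("DECOY%02d", d)
      sets[[nm]] <- sort(sample(free, min(decoy_size, length(free))))
      desc[nm] <- "decoy"
    }
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a simulated cohort to a directory
#'
#' Emits the external representations of every cohort part: expression
#' and flag TSVs, design TSV, clinical TSV, BED annotation, GMT gene
#' sets, and the truth record as JSON (full numeric precision, so the
#' truth round-trips losslessly through [read_truth()]).
#'
#' @param cohort An `lnc_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lnc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression(cohort$expr, p("expression.tsv"), p("flags.tsv"))
  write_design(cohort$design, p("design.tsv"))
  write_clinical(cohort$clinical, p("clinical.tsv"))
  write_bed(cohort$annotation, p("annotation.bed"))
  write_gmt(cohort$gene_sets, p("gene_sets.gmt"),
            attr(cohort$gene_sets, "description"))
  write_truth(cohort$truth, p("truth.json"))
  cfg <- cohort$config
  cfg$modules <- lapply(cfg$modules, unclass)
  write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE, digits = I(17),
             pretty = TRUE)
  invisible(dir)
}

#' Write / read the planted-truth record
#' @param truth Truth list from a generated cohort.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  write_json(truth, path, auto_unbox = TRUE, digits = I(17),
             dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (f in c("background_de", "phenotype_labels", "latent", "survival"))
    tr[[f]] <- as.data.frame(tr[[f]], stringsAsFactors = FALSE)
  tr
}
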