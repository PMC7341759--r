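# End-to-end orchestration of the staged funnel: preprocess -> paired DE
# -> clinical association -> relevance -> correlation -> cis -> network
# -> master regulators -> phenotype-unique lncRNAs -> enrichment, with a
# file-per-stage run directory and a deterministic JSON summary.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow.  Defaults are the
#' discovery-cohort calling rules: |FC| >= 2 at FDR < 0.05 for
#' differential expression, |FC| >= 1.5 at unadjusted p < 0.05 for
#' clinical association, |r| >= 0.9 for strong co-expression (0.6 for
#' perturbation integration), ORA p < 0.01, and the "large network"
#' gates for master regulators (>= 20 mRNAs, concordance > 0.8).
#'
#' @param fc_de,fdr_de Differential-expression gates.
#' @param fc_clin,p_clin Clinical-association gates.
#' @param r_strong,r_weak Strong / perturbation correlation thresholds,
#'   each in (0, 1].
#' @param alpha_enrich ORA significance level.
#' @param min_mrna,concordance_min,cover_fraction Master-regulator gates.
#' @param detect_min_fraction,detect_strict Detection-filter rule.
#' @param normalize Quantile-normalize after filtering.
#' @param cor_samples Sample set for correlation: `"all"` or `"tumor"`.
#' @return A validated list of class `lncnet_config`.
#' @export
pipeline_config <- function(fc_de = 2, fdr_de = 0.05, fc_clin = 1.5,
                            p_clin = 0.05, r_strong = 0.9, r_weak = 0.6,
                            alpha_enrich = 0.01, min_mrna = 20,
                            concordance_min = 0.8, cover_fraction = 1.0,
                            detect_min_fraction = 0.5, detect_strict = FALSE,
                            normalize = TRUE, cor_samples = c("all", "tumor")) {
  cor_samples <- match.arg(cor_samples)
  for (f in c("fc_de", "fdr_de", "fc_clin", "p_clin", "alpha_enrich",
              "min_mrna", "cover_fraction")) {
    if (get(f) <= 0) .cfg_stop(f, "must be positive")
  }
  for (f in c("r_strong", "r_weak")) {
    v <- get(f)
    if (v <= 0 || v > 1) .cfg_stop(f, "must lie in (0, 1]")
  }
  if (concordance_min < 0 || concordance_min > 1)
    .cfg_stop("concordance_min", "must lie in [0, 1]")
  if (detect_min_fraction < 0 || detect_min_fraction > 1)
    .cfg_stop("detect_min_fraction", "must lie in [0, 1]")
  structure(list(fc_de = fc_de, fdr_de = fdr_de, fc_clin = fc_clin,
                 p_clin = p_clin, r_strong = r_strong, r_weak = r_weak,
                 alpha_enrich = alpha_enrich, min_mrna = min_mrna,
                 concordance_min = concordance_min,
                 cover_fraction = cover_fraction,
                 detect_min_fraction = detect_min_fraction,
                 detect_strict = detect_strict, normalize = normalize,
                 cor_samples = cor_samples),
            class = "lncnet_config")
}

.stage <- function(name, log_con, code) {
  if (!is.null(log_con)) writeLines(paste0("stage: ", name), log_con)
  tryCatch(code, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full co-expression network workflow
#'
#' Executes every stage on a cohort (in-memory `lnc_cohort`, or explicit
#' inputs / file paths), writing one inspectable table per stage plus a
#' deterministic `summary.json` into `out_dir`.  Re-running with
#' identical inputs and configuration reproduces identical outputs.
#'
#' @param cohort An `lnc_cohort` from [generate_cohort()], or `NULL` if
#'   the individual inputs are given.
#' @param expr,design,clinical,annotation,gene_sets Individual inputs
#'   (objects, or file paths to their external representations); ignored
#'   when `cohort` is given.
#' @param out_dir Run directory (created; `NULL` skips writing files).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage table (`filtered`, `de`,
#'   `assoc`, `relevance`, `pairs`, `components`, `master_regulators`,
#'   `enrichment`, `phenotype_unique`, `unique_gene_sets`) and the
#'   `summary` count list.
#' @export
run_pipeline <- function(cohort = NULL, expr = NULL, design = NULL,
                         clinical = NULL, annotation = NULL,
                         gene_sets = NULL, out_dir = NULL,
                         config = pipeline_config()) {
  if (!inherits(config, "lncnet_config"))
    stop("`config` must be created with pipeline_config()")
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "lnc_cohort"))
    expr <- cohort$expr; design <- cohort$design
    clinical <- cohort$clinical; annotation <- cohort$annotation
    gene_sets <- cohort$gene_sets
  }
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(design)) design <- read_design(design)
  if (is.character(clinical)) clinical <- read_clinical(clinical)
  if (is.character(annotation)) annotation <- read_bed(annotation)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "run.log"), open = "wt")
    on.exit(close(log_con), add = TRUE)
  }
  biotype <- setNames(annotation$biotype, annotation$feature_id)

  filtered <- .stage("preprocess", log_con, {
    e <- if (is.null(expr$flags)) expr
         else filter_detected(expr, config$detect_min_fraction,
                              config$detect_strict)
    if (config$normalize) quantile_normalize(e) else e
  })

  de <- .stage("differential_expression", log_con,
               run_de(filtered, design, fc_threshold = config$fc_de,
                      fdr_threshold = config$fdr_de))
  bt <- .biotype_of(de$feature_id, biotype)
  de_lnc <- de[bt == "lncRNA", , drop = FALSE]
  de_mrna <- de[bt == "protein_coding", , drop = FALSE]

  de_ids <- de$feature_id[de$is_de]
  assoc <- .stage("clinical_association", log_con, {
    if (length(de_ids) == 0L) stop("no differentially expressed features")
    run_clinical_association(filtered, design, clinical, features = de_ids,
                             fc_threshold = config$fc_clin,
                             p_threshold = config$p_clin)
  })

  relevance <- .stage("relevance", log_con,
                      classify_relevance(de[de$is_de, , drop = FALSE], assoc))

  pairs <- .stage("coexpression", log_con,
                  suppressWarnings(
                    call_pairs(filtered, de_lnc, de_mrna,
                               threshold = config$r_strong,
                               samples = config$cor_samples,
                               design = design)))
  pairs <- .stage("cis_annotation", log_con, annotate_cis(pairs, annotation))

  components <- .stage("network", log_con,
                       build_network(pairs, relevance, assoc))

  universe <- .stage("enrichment_universe", log_con, {
    mrna_feats <- feature_ids(filtered)[
      .biotype_of(feature_ids(filtered), biotype) == "protein_coding"]
    intersect(mrna_feats, unique(unlist(gene_sets, use.names = FALSE)))
  })
  enrich <- .stage("enrichment", log_con, {
    lapply(components, function(cc)
      suppressWarnings(run_ora(cc$mrna_ids, gene_sets, universe,
                               alpha = config$alpha_enrich)))
  })
  masters <- .stage("master_regulators", log_con, {
    lapply(seq_along(components), function(i)
      find_master_regulators(components[[i]], enrich[[i]],
                             min_mrna = config$min_mrna,
                             concordance_min = config$concordance_min,
                             cover_fraction = config$cover_fraction,
                             alpha = config$alpha_enrich))
  })
  for (i in seq_along(components)) {
    components[[i]]$master_set <- masters[[i]]
    components[[i]]$enriched_sets <-
      enrich[[i]]$set_name[enrich[[i]]$significant]
  }

  uniq <- .stage("phenotype_unique", log_con,
                 phenotype_unique(relevance, de_lnc$feature_id))
  uniq_sets <- .stage("unique_gene_sets", log_con,
                      unique_phenotype_gene_sets(uniq, pairs, de_mrna))

  summary <- .pipeline_summary(filtered, de, bt, assoc, relevance, pairs,
                               components, config)

  if (!is.null(out_dir)) {
    .stage("write_outputs", log_con, {
      p <- function(f) file.path(out_dir, f)
      write_tsv(de, p("de.tsv"))
      write_tsv(assoc, p("clinical_association.tsv"))
      write_tsv(relevance, p("relevance.tsv"))
      write_tsv(pairs, p("pairs.tsv"))
      write_tsv(.components_table(components), p("components.tsv"))
      for (cc in components)
        write_sif(cc$edges, p(sprintf("network_%s.sif", cc$id)))
      for (i in seq_along(components))
        write_tsv(enrich[[i]], p(sprintf("enrichment_%s.tsv",
                                         components[[i]]$id)))
      write_json(lapply(components, function(cc)
        list(id = cc$id, cls = cc$cls, master_set = cc$master_set)),
        p("master_regulators.json"), auto_unbox = FALSE, pretty = TRUE)
      write_json(uniq, p("phenotype_unique.json"), pretty = TRUE)
      write_json(summary, p("summary.json"), auto_unbox = TRUE,
                 digits = I(17), pretty = TRUE)
    })
  }
  invisible(list(filtered = filtered, de = de, assoc = assoc,
                 relevance = relevance, pairs = pairs,
                 components = components, master_regulators = masters,
                 enrichment = enrich, phenotype_unique = uniq,
                 unique_gene_sets = uniq_sets, summary = summary))
}

# one row per network node, diffable
.components_table <- function(components) {
  if (!length(components))
    return(data.frame(component = character(0L), feature_id = character(0L),
                      biotype = character(0L), cls = character(0L),
                      concordance = numeric(0L), stringsAsFactors = FALSE))
  do.call(rbind, lapply(components, function(cc) {
    data.frame(component = cc$id,
               feature_id = c(cc$lnc_ids, cc$mrna_ids),
               biotype = rep(c("lncRNA", "protein_coding"),
                             c(cc$n_lnc, cc$n_mrna)),
               cls = cc$cls, concordance = cc$concordance,
               stringsAsFactors = FALSE)
  }))
}

.pipeline_summary <- function(filtered, de, bt, assoc, relevance, pairs,
                              components, config) {
  cnt <- function(b, dir) sum(bt == b & de$direction == dir)
  n_conc_mrna <- sum(vapply(components, function(cc)
    length(cc$concordant_mrnas), 0L))
  n_mrna_nodes <- sum(vapply(components, `[[`, 0L, "n_mrna"))
  list(
    n_features = nrow(de),
    n_features_lnc = sum(bt == "lncRNA"),
    n_features_mrna = sum(bt == "protein_coding"),
    de_lnc_up = cnt("lncRNA", "up"), de_lnc_down = cnt("lncRNA", "down"),
    de_lnc_total = sum(bt == "lncRNA" & de$is_de),
    de_mrna_up = cnt("protein_coding", "up"),
    de_mrna_down = cnt("protein_coding", "down"),
    de_mrna_total = sum(bt == "protein_coding" & de$is_de),
    n_pairs = nrow(pairs),
    n_cis_pairs = sum(pairs$is_cis %in% TRUE),
    relevant_lnc_oncogenic = sum(relevance$cls == "oncogenic" &
                                   bt[match(relevance$feature_id,
                                            de$feature_id)] == "lncRNA"),
    relevant_lnc_suppressor = sum(relevance$cls == "suppressor" &
                                    bt[match(relevance$feature_id,
                                             de$feature_id)] == "lncRNA"),
    n_components = length(components),
    components_oncogenic = sum(vapply(components, `[[`, "", "cls") ==
                                 "oncogenic"),
    components_suppressive = sum(vapply(components, `[[`, "", "cls") ==
                                   "suppressive"),
    components_mixed = sum(vapply(components, `[[`, "", "cls") == "mixed"),
    concordance_overall = if (n_mrna_nodes)
      n_conc_mrna / n_mrna_nodes else NA,
    concordance_per_component = lapply(components, function(cc)
      list(id = cc$id, concordance = cc$concordance)),
    master_sets = lapply(components, function(cc)
      list(id = cc$id, master_set = as.list(cc$master_set))),
    thresholds = unclass(config))
}
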