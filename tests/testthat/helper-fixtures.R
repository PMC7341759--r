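# Small programmatic fixtures shared across the suite.

make_expr <- function(nf = 4, ns = 6, seed = 1, mean = 8, sd = 1,
                      flags = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(nf * ns, mean, sd), nf, ns,
              dimnames = list(sprintf("F%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  expression_matrix(m, flags)
}

make_design <- function(n_patients) {
  pid <- sprintf("P%02d", seq_len(n_patients))
  data.frame(sample_id = as.vector(rbind(paste0(pid, "_T"),
                                         paste0(pid, "_NT"))),
             patient_id = rep(pid, each = 2L),
             tissue = rep(c("T", "NT"), n_patients),
             stringsAsFactors = FALSE)
}

# paired cohort matrix whose columns follow make_design() ordering
make_paired_expr <- function(nf, n_patients, seed = 1, mean = 8, sd = 1) {
  design <- make_design(n_patients)
  set.seed(seed)
  m <- matrix(rnorm(nf * 2 * n_patients, mean, sd), nf,
              2 * n_patients,
              dimnames = list(sprintf("F%03d", seq_len(nf)),
                              design$sample_id))
  list(expr = expression_matrix(m), design = design)
}

# one grade-linked oncogenic module at a realistically sparse planted
# fraction (~4% of features)
small_planted_config <- function(seed = 1, n_patients = 49,
                                 n_lnc = 300, n_mrna = 300) {
  sim_config(
    n_patients = n_patients, n_lnc = n_lnc, n_mrna = n_mrna,
    modules = list(module_spec(3, 12, target_r = 0.95, tumor_shift = 1.5,
                               linked_group = "grade",
                               phenotype_effect = 1.0)),
    seed = seed)
}
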