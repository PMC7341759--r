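.clin_row <- function(patient_id = "P01", tumor_size_cm = 3,
                      vascular_invasion = FALSE, stage = 1L, grade = 2L,
                      encapsulation = "complete", invasion = FALSE,
                      os_time = 500, os_event = TRUE) {
  data.frame(patient_id = patient_id, tumor_size_cm = tumor_size_cm,
             vascular_invasion = vascular_invasion, stage = stage,
             grade = grade, encapsulation = encapsulation,
             invasion = invasion, os_time = os_time, os_event = os_event,
             stringsAsFactors = FALSE)
}

test_that("dichotomization applies the good/poor rules of the five groups", {
  cl <- rbind(
    .clin_row("P01", tumor_size_cm = 6, stage = 2L),          # size >= 5
    .clin_row("P02", grade = 3L),                             # high grade
    .clin_row("P03", encapsulation = "incomplete"),
    .clin_row("P04", invasion = TRUE),
    .clin_row("P05"))                                         # all good
  g <- dichotomize(cl)
  expect_identical(g$tumor_properties,
                   c("poor", "good", "good", "good", "good"))
  expect_identical(g$grade, c("good", "poor", "good", "good", "good"))
  expect_identical(g$capsule, c("good", "good", "poor", "good", "good"))
  expect_identical(g$invasion, c("good", "good", "good", "poor", "good"))
})

test_that("missing sub-phenotypes only yield missing when nothing is poor", {
  cl <- rbind(.clin_row("P01"), .clin_row("P02"), .clin_row("P03"))
  cl$tumor_size_cm <- c(NA, NA, NA)
  cl$vascular_invasion <- c(NA, NA, NA)
  cl$stage <- c(3L, 1L, NA)
  g <- dichotomize(cl)
  expect_identical(g$tumor_properties, c("poor", "good", NA))
  cl$grade <- NA_integer_
  expect_true(all(is.na(dichotomize(cl)$grade)))
})

test_that("the two-sample t-test matches hand-derived values and sentinels", {
  r <- group_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$fc, 1)
  expect_equal(r$p, 1)
  r <- group_t_test(c(3, 4, 5), c(1, 2, 3))
  expect_equal(r$fc, 4)
  expect_equal(r$t_stat, 2 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(r$p, 0.070484, tolerance = 1e-5)
  expect_false(group_t_test(1, c(1, 2))$testable)
})

test_that("the two-sample t-test equals the pooled-variance oracle", {
  set.seed(77)
  for (i in 1:100) {
    a <- rnorm(sample(2:8, 1), 8)
    b <- rnorm(sample(2:8, 1), 8)
    got <- group_t_test(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("univariate Cox handles sentinels and matches the grid oracle", {
  expect_false(cox_univariate(rep(1, 6), 1:6, rep(TRUE, 6))$testable)
  expect_false(cox_univariate(1:6, 1:6, c(TRUE, rep(FALSE, 5)))$testable)
  x <- c(1, 0, 1, 0)
  got <- cox_univariate(x, c(5, 2, 3, 9), rep(TRUE, 4))
  expect_false(got$diverged)
  expect_equal(got$beta, oracle_cox_grid(x, c(5, 2, 3, 9), rep(1, 4)),
               tolerance = 1e-4)
  expect_equal(got$hr, exp(got$beta))
  # every event in one covariate class precedes the other: monotone
  # partial likelihood, flagged as divergent
  expect_true(cox_univariate(x, c(2, 5, 3, 9), rep(TRUE, 4))$diverged)
})

test_that("univariate logistic is symmetric, flags errors, detects strong links", {
  got <- logistic_univariate(c(-1, 1, -1, 1), c(0, 0, 1, 1))
  expect_equal(got$beta, 0, tolerance = 1e-6)
  expect_error(logistic_univariate(rnorm(5), rep(1, 5)), "both outcome classes")
  set.seed(9)
  y <- rep(c(0, 1), c(24, 25))
  x <- y * 2 + rnorm(49)
  got <- logistic_univariate(x, y)
  expect_gt(got$or, 1)
  expect_lt(got$p, 0.05)
})

test_that("relevance classification requires direction-concordant significance", {
  de <- data.frame(feature_id = c("L1", "L2", "L3"),
                   direction = c("up", "up", "down"),
                   is_de = TRUE, stringsAsFactors = FALSE)
  assoc <- data.frame(
    feature_id = c("L1", "L2", "L3"),
    group = c("grade", "grade", "survival"),
    effect = c(1.8, -1.8, 0.6), p = c(0.01, 0.01, 0.02),
    direction = c("up_in_poor", "down_in_poor", "down_in_poor"),
    significant = TRUE, stringsAsFactors = FALSE)
  rel <- classify_relevance(de, assoc)
  expect_identical(rel$cls, c("oncogenic", "none", "suppressor"))
  expect_identical(rel$groups, c("grade", "", "survival"))
})

test_that("planted phenotype links are recovered as oncogenic associations", {
  hits <- 0L
  contradicted <- 0L
  for (s in 1:20) {
    co <- generate_cohort(sim_config(
      n_patients = 49, n_lnc = 20, n_mrna = 30,
      modules = list(module_spec(2, 4, target_r = 0.95, tumor_shift = 1.5,
                                 linked_group = "grade",
                                 phenotype_effect = 1.0)),
      de_background_fraction = 0, seed = 500 + s))
    e <- quantile_normalize(co$expr)
    ids <- co$truth$modules[[1]]$lnc_ids
    assoc <- run_clinical_association(e, co$design, co$clinical,
                                      features = ids)
    grade <- assoc[assoc$group == "grade", ]
    hits <- hits + all(grade$significant & grade$direction == "up_in_poor")
    de <- run_de(e, co$design)
    rel <- classify_relevance(de, run_clinical_association(
      e, co$design, co$clinical, features = de$feature_id))
    # labels never contradict the planted direction
    contradicted <- contradicted +
      sum(rel$cls[match(ids, rel$feature_id)] == "suppressor")
  }
  expect_gte(hits, 18)   # sensitivity >= 0.9 across seeds
  expect_identical(contradicted, 0L)
})

test_that("simulated hazards are recovered by the Cox model", {
  betas <- vapply(1:10, function(s) {
    co <- generate_cohort(sim_config(
      n_patients = 49, n_lnc = 10, n_mrna = 10,
      modules = list(module_spec(2, 3, target_r = 0.9,
                                 linked_group = "survival",
                                 hazard_beta = 0.8)),
      seed = 700 + s))
    cox_univariate(co$truth$latent$z_module1, co$truth$survival$os_time,
                   co$truth$survival$os_event)$beta
  }, 0)
  expect_lt(abs(mean(betas) - 0.8), 0.25)
})
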