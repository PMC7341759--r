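test_that("pearson_r matches hand computation and flags constant input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- pearson_r(x, rep(2, 4)), "undefined correlation")
  expect_true(is.na(r))
  # symmetry and affine invariance
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(pearson_r(a, b), pearson_r(b, a))
  expect_equal(pearson_r(3 * a - 2, b), pearson_r(a, b), tolerance = 1e-12)
  expect_equal(pearson_r(-3 * a, b), -pearson_r(a, b), tolerance = 1e-12)
})

.de_stub <- function(ids, direction = "up") {
  data.frame(feature_id = ids,
             direction = rep_len(direction, length(ids)),
             is_de = rep_len(TRUE, length(ids)),
             stringsAsFactors = FALSE)
}

test_that("pair calling emits |r| >= threshold pairs and matches per-pair cor", {
  co <- generate_cohort(sim_config(
    n_patients = 30, n_lnc = 20, n_mrna = 20,
    modules = list(module_spec(4, 10, target_r = 0.95, tumor_shift = 1)),
    de_background_fraction = 0, seed = 21))
  lnc <- feature_ids(co$expr)[1:20]
  mrna <- feature_ids(co$expr)[21:40]
  pairs <- call_pairs(co$expr, .de_stub(lnc), .de_stub(mrna), threshold = 0.9)
  expect_true(all(abs(pairs$r) >= 0.9))
  expect_true(all(pairs$lnc_id %in% lnc) && all(pairs$mrna_id %in% mrna))
  # blocked matrix route equals the feature-by-feature route
  v <- co$expr$values
  for (i in seq_len(nrow(pairs))) {
    expect_equal(pairs$r[i],
                 cor(v[pairs$lnc_id[i], ], v[pairs$mrna_id[i], ]),
                 tolerance = 1e-9)
  }
  # an impossible threshold yields no pairs
  none <- call_pairs(co$expr, .de_stub(lnc), .de_stub(mrna), threshold = 1.01)
  expect_identical(nrow(none), 0L)
  # empty DE sets warn and return an empty table
  expect_warning(
    empty <- call_pairs(co$expr, .de_stub(character(0)), .de_stub(mrna)),
    "no differentially expressed")
  expect_identical(nrow(empty), 0L)
})

test_that("planted modules yield nearly all within-module pairs", {
  found <- 0L; total <- 0L
  for (s in 1:10) {
    co <- generate_cohort(sim_config(
      n_patients = 49, n_lnc = 10, n_mrna = 15,
      modules = list(module_spec(4, 10, target_r = 0.95, tumor_shift = 1.5)),
      de_background_fraction = 0, seed = 40 + s))
    m <- co$truth$modules[[1]]
    pairs <- call_pairs(co$expr, .de_stub(m$lnc_ids), .de_stub(m$mrna_ids))
    total <- total + length(m$lnc_ids) * length(m$mrna_ids)
    found <- found + nrow(pairs)
  }
  expect_gte(found / total, 0.95)
})

test_that("DE-direction concordance of a pair follows the correlation sign", {
  set.seed(11)
  base <- rnorm(30)
  v <- rbind(L1 = base + rnorm(30, sd = 0.05),
             M1 = base + rnorm(30, sd = 0.05),
             M2 = -base + rnorm(30, sd = 0.05))
  colnames(v) <- paste0("s", 1:30)
  de_l <- .de_stub("L1", "up")
  de_m <- data.frame(feature_id = c("M1", "M2"), direction = c("up", "down"),
                     is_de = TRUE, stringsAsFactors = FALSE)
  pairs <- call_pairs(expression_matrix(v), de_l, de_m, threshold = 0.8)
  expect_true(pairs$de_concordant[pairs$mrna_id == "M1"])  # r > 0, both up
  expect_true(pairs$de_concordant[pairs$mrna_id == "M2"])  # r < 0, opposite
})

test_that("cis annotation picks the nearest protein-coding gene", {
  ann <- data.frame(
    feature_id = c("lnc", "A", "B", "C", "D"),
    biotype = c("lncRNA", rep("protein_coding", 4)),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    start = c(1000L, 3000L, 10000L, 500L, 1500L),
    end = c(2000L, 4000L, 11000L, 1500L, 1800L),
    strand = "+", symbol = c("lnc", "A", "B", "C", "D"),
    stringsAsFactors = FALSE)
  pair_with <- function(m) data.frame(lnc_id = "lnc", mrna_id = m, r = 0.95,
                                      n_samples = 10L, de_concordant = TRUE,
                                      is_cis = NA, stringsAsFactors = FALSE)
  # overlapping gene D (gap 0) is nearest -> cis
  out <- annotate_cis(rbind(pair_with("A"), pair_with("B"), pair_with("D")),
                      ann)
  expect_identical(out$is_cis[out$mrna_id == "D"], TRUE)
  expect_identical(out$is_cis[out$mrna_id == "A"], FALSE)
  expect_identical(out$is_cis[out$mrna_id == "B"], FALSE)
  # without the overlapping gene, the smaller gap wins (A at 1000 < B at 8000)
  out <- annotate_cis(rbind(pair_with("A"), pair_with("B")),
                      ann[ann$feature_id != "D", ])
  expect_identical(out$is_cis, c(TRUE, FALSE))
  # a different-chromosome partner is never cis
  out <- annotate_cis(pair_with("C"), ann[ann$feature_id != "D", ])
  expect_identical(out$is_cis, FALSE)
  # equidistant tie broken by the smaller start coordinate
  tie <- data.frame(
    feature_id = c("lnc2", "E", "F"),
    biotype = c("lncRNA", "protein_coding", "protein_coding"),
    chrom = "chr3", start = c(5000L, 7000L, 2000L),
    end = c(6000L, 8000L, 4000L), strand = "+",
    symbol = c("lnc2", "E", "F"), stringsAsFactors = FALSE)
  p <- data.frame(lnc_id = "lnc2", mrna_id = "F", r = 0.95, n_samples = 10L,
                  de_concordant = TRUE, is_cis = NA, stringsAsFactors = FALSE)
  expect_identical(annotate_cis(p, tie)$is_cis, TRUE)
  # un-annotated members leave is_cis missing with a warning
  expect_warning(out <- annotate_cis(
    data.frame(lnc_id = "ghost", mrna_id = "A", r = 0.95, n_samples = 10L,
               de_concordant = TRUE, is_cis = NA, stringsAsFactors = FALSE),
    ann), "un-annotated")
  expect_true(is.na(out$is_cis))
})

test_that("interval gaps agree with the established ranges implementation", {
  skip_if_not_installed("GenomicRanges")
  set.seed(66)
  for (i in 1:50) {
    s1 <- sample(1e5, 1); e1 <- s1 + sample(5e3, 1)
    s2 <- sample(1e5, 1); e2 <- s2 + sample(5e3, 1)
    # GRanges is 1-based closed; convert from 0-based half-open
    g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s1 + 1, e1))
    g2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s2 + 1, e2))
    expect_identical(interval_gap(s1, e1, s2, e2),
                     GenomicRanges::distance(g1, g2))
  }
})

test_that("each simulated module carries a recoverable cis pair", {
  co <- generate_cohort(sim_config(
    n_patients = 20, n_lnc = 30, n_mrna = 30,
    modules = list(module_spec(3, 5, target_r = 0.95, tumor_shift = 1)),
    seed = 2))
  m <- co$truth$modules[[1]]
  pairs <- call_pairs(co$expr, .de_stub(m$lnc_ids), .de_stub(m$mrna_ids))
  pairs <- annotate_cis(pairs, co$annotation)
  cis <- pairs[pairs$is_cis %in% TRUE, ]
  # the designed adjacent lncRNA/mRNA pair of the module is called cis
  expect_true(any(cis$lnc_id == m$lnc_ids[1] & cis$mrna_id == m$mrna_ids[1]))
  # every cis call names the lncRNA's genuinely nearest coding gene
  for (i in seq_len(nrow(cis))) {
    la <- co$annotation[co$annotation$feature_id == cis$lnc_id[i], ]
    cod <- co$annotation[co$annotation$biotype == "protein_coding" &
                           co$annotation$chrom == la$chrom, ]
    gaps <- interval_gap(la$start, la$end, cod$start, cod$end)
    expect_identical(cis$mrna_id[i], cod$feature_id[which.min(gaps)])
  }
})
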