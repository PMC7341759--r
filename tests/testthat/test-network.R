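.pairs_df <- function(lnc, mrna, r = 0.95) {
  data.frame(lnc_id = lnc, mrna_id = mrna, r = r, n_samples = 20L,
             de_concordant = TRUE, is_cis = NA, stringsAsFactors = FALSE)
}

.rel_df <- function(ids, cls = "oncogenic", groups = "grade") {
  data.frame(feature_id = ids, cls = cls, groups = groups,
             stringsAsFactors = FALSE)
}

.assoc_df <- function(ids, group = "grade", direction = "up_in_poor",
                      significant = TRUE) {
  data.frame(feature_id = ids, group = group, effect = 2, log2fc = 1,
             p = 0.01, q = 0.05, direction = direction,
             significant = significant, testable = TRUE,
             stringsAsFactors = FALSE)
}

test_that("bipartite components are extracted with deterministic ordering", {
  pairs <- .pairs_df(c("L1", "L1", "L2", "L3"), c("M1", "M2", "M2", "M3"))
  rel <- .rel_df(c("L1", "L2", "L3"))
  assoc <- .assoc_df(c("L1", "L2", "L3", "M1", "M2", "M3"))
  comps <- build_network(pairs, rel, assoc)
  expect_length(comps, 2L)
  expect_identical(comps[[1]]$lnc_ids, c("L1", "L2"))
  expect_identical(comps[[1]]$mrna_ids, c("M1", "M2"))
  expect_identical(comps[[2]]$lnc_ids, "L3")
  expect_identical(comps[[2]]$mrna_ids, "M3")
  expect_identical(comps[[1]]$id, "C01")
  # pairs whose lncRNA is not clinically relevant are dropped
  rel2 <- .rel_df(c("L1", "L2", "L3"), cls = c("oncogenic", "none", "none"),
                  groups = c("grade", "", ""))
  comps2 <- build_network(pairs, rel2, assoc)
  expect_length(comps2, 1L)
  expect_identical(comps2[[1]]$lnc_ids, "L1")
  expect_identical(build_network(pairs[0, ], rel, assoc), list())
})

test_that("component extraction agrees with a union-find oracle", {
  set.seed(31)
  for (i in 1:30) {
    n_l <- sample(2:10, 1); n_m <- sample(2:10, 1)
    ne <- sample(1:25, 1)
    lnc <- paste0("L", sample(n_l, ne, replace = TRUE))
    mrna <- paste0("M", sample(n_m, ne, replace = TRUE))
    keep <- !duplicated(paste(lnc, mrna))
    pairs <- .pairs_df(lnc[keep], mrna[keep])
    ids <- unique(c(lnc, mrna))
    comps <- build_network(pairs, .rel_df(unique(lnc)), .assoc_df(ids))
    got <- lapply(comps, function(cc) sort(c(cc$lnc_ids, cc$mrna_ids)))
    ref <- oracle_components(pairs$lnc_id, pairs$mrna_id)
    expect_setequal(vapply(got, paste, "", collapse = "+"),
                    vapply(ref, paste, "", collapse = "+"))
  }
})

test_that("component class reflects member lncRNA DE directions", {
  pairs <- .pairs_df(c("L1", "L2"), c("M1", "M1"))
  assoc <- .assoc_df(c("L1", "L2", "M1"))
  up <- build_network(pairs, .rel_df(c("L1", "L2"), "oncogenic"), assoc)
  expect_identical(up[[1]]$cls, "oncogenic")
  down <- build_network(pairs, .rel_df(c("L1", "L2"), "suppressor"), assoc)
  expect_identical(down[[1]]$cls, "suppressive")
  mixed <- build_network(pairs, .rel_df(c("L1", "L2"),
                                        c("oncogenic", "suppressor")), assoc)
  expect_identical(mixed[[1]]$cls, "mixed")
})

test_that("concordance counts mRNAs sharing a concordant significant group", {
  pairs <- .pairs_df(c("L1", "L1"), c("M1", "M2"))
  rel <- .rel_df("L1")
  # L1 and M1 grade-up significant; M2 not significant -> concordance 0.5
  assoc <- rbind(.assoc_df(c("L1", "M1")),
                 .assoc_df("M2", significant = FALSE))
  comps <- build_network(pairs, rel, assoc)
  expect_equal(comps[[1]]$concordance, 0.5)
  # all concordant -> 1; discordant direction -> 0
  comps <- build_network(pairs, rel, .assoc_df(c("L1", "M1", "M2")))
  expect_equal(comps[[1]]$concordance, 1)
  assoc0 <- rbind(.assoc_df("L1"),
                  .assoc_df(c("M1", "M2"), direction = "down_in_poor"))
  comps <- build_network(pairs, rel, assoc0)
  expect_equal(comps[[1]]$concordance, 0)
})

test_that("greedy master-regulator cover follows the hand-traced path", {
  edges <- .pairs_df(c("L1", "L1", "L1", "L2", "L2", "L3"),
                     c("a", "b", "c", "c", "d", "a"))
  comp <- list(id = "C01", lnc_ids = c("L1", "L2", "L3"),
               mrna_ids = c("a", "b", "c", "d"), edges = edges,
               cls = "oncogenic", concordance = 1, n_lnc = 3L, n_mrna = 4L)
  enr <- data.frame(set_name = "S", p = 1e-5, significant = TRUE)
  got <- find_master_regulators(comp, enr, min_mrna = 2)
  expect_identical(got, c("L1", "L2"))
  # the cover is minimal-by-greedy and satisfies the coverage constraint
  covered <- unique(edges$mrna_id[edges$lnc_id %in% got])
  expect_setequal(covered, comp$mrna_ids)
  expect_lte(length(got), comp$n_lnc)
})

test_that("master regulators require size, concordance and enrichment gates", {
  edges <- .pairs_df(rep("L1", 5), paste0("M", 1:5))
  comp <- list(id = "C01", lnc_ids = "L1", mrna_ids = paste0("M", 1:5),
               edges = edges, cls = "oncogenic", concordance = 1,
               n_lnc = 1L, n_mrna = 5L)
  enr <- data.frame(set_name = "S", p = 1e-5, significant = TRUE)
  expect_identical(find_master_regulators(comp, enr, min_mrna = 20),
                   character(0))
  expect_identical(find_master_regulators(comp, enr, min_mrna = 2,
                                          concordance_min = 1),
                   character(0))
  expect_identical(find_master_regulators(
    comp, data.frame(set_name = "S", p = 0.5, significant = FALSE),
    min_mrna = 2), character(0))
  expect_identical(find_master_regulators(comp, enr, min_mrna = 2), "L1")
})

test_that("phenotype-unique lncRNAs and their gene lists are extracted", {
  rel <- data.frame(
    feature_id = c("L1", "L2", "L3", "L4"),
    cls = c("oncogenic", "oncogenic", "suppressor", "none"),
    groups = c("grade", "grade,capsule", "invasion", ""),
    stringsAsFactors = FALSE)
  uniq <- phenotype_unique(rel)
  expect_identical(uniq$grade, "L1")          # single-group only
  expect_identical(uniq$invasion, "L3")
  expect_false("L2" %in% unlist(uniq))        # multi-group: listed nowhere
  expect_false("L4" %in% unlist(uniq))        # no groups: listed nowhere
  pairs <- .pairs_df(c("L1", "L1", "L3", "L3"), c("M1", "M2", "M1", "M3"))
  de_m <- data.frame(feature_id = c("M1", "M2", "M3"),
                     direction = c("up", "up", "down"), is_de = TRUE,
                     stringsAsFactors = FALSE)
  gs <- unique_phenotype_gene_sets(uniq, pairs, de_m)
  expect_identical(gs$grade$up, c("M1", "M2"))
  expect_identical(gs$invasion$up, "M1")      # shared gene listed once
  expect_identical(gs$invasion$down, "M3")
  expect_identical(gs$survival$up, character(0))
})
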