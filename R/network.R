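# Clinically relevant bipartite lncRNA-mRNA networks: connected
# components of the strong-correlation graph restricted to clinically
# relevant lncRNAs, concordance scoring, greedy master-regulator
# detection, and phenotype-unique lncRNA extraction.

#' Build clinically relevant network components
#'
#' Keeps the pairs whose lncRNA is clinically relevant (class not
#' `none`), forms the bipartite graph, and extracts its connected
#' components.  Each component is classified `oncogenic` when all member
#' lncRNAs are up-regulated, `suppressive` when all are down-regulated,
#' `mixed` otherwise, and scored for clinical concordance: the fraction
#' of member mRNAs that share at least one direction-concordant
#' significant clinical group with at least one of their correlated
#' lncRNAs.
#'
#' @param pairs Pair table from [call_pairs()].
#' @param relevance Relevance table from [classify_relevance()] (must
#'   cover the lncRNAs).
#' @param assoc Clinical-association table covering both biotypes, used
#'   for concordance scoring.
#' @return List of components, ordered by size (descending) then by
#'   smallest member id; each has `id`, `lnc_ids`, `mrna_ids`, `edges`,
#'   `cls`, `concordance`, `n_lnc`, `n_mrna`.
#' @export
build_network <- function(pairs, relevance, assoc) {
  cls_of <- setNames(relevance$cls, relevance$feature_id)
  keep <- !is.na(cls_of[pairs$lnc_id]) & cls_of[pairs$lnc_id] != "none"
  edges <- pairs[keep, , drop = FALSE]
  if (nrow(edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    edges[, c("lnc_id", "mrna_id")], directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  sig <- assoc[assoc$significant & !is.na(assoc$direction), , drop = FALSE]
  sig_key <- paste(sig$feature_id, sig$group, sig$direction)
  comps <- lapply(seq_len(comp$no), function(k) {
    nodes <- names(membership)[membership == k]
    e <- edges[edges$lnc_id %in% nodes & edges$mrna_id %in% nodes, ,
               drop = FALSE]
    lnc_ids <- sort(unique(e$lnc_id))
    mrna_ids <- sort(unique(e$mrna_id))
    lcls <- unique(cls_of[lnc_ids])
    cls <- if (identical(lcls, "oncogenic")) "oncogenic"
           else if (identical(lcls, "suppressor")) "suppressive"
           else "mixed"
    conc <- .component_concordance(e, mrna_ids, sig, sig_key)
    list(id = NA_character_, lnc_ids = lnc_ids, mrna_ids = mrna_ids,
         edges = e, cls = cls, concordance = conc$fraction,
         concordant_mrnas = conc$concordant, n_lnc = length(lnc_ids),
         n_mrna = length(mrna_ids))
  })
  sizes <- vapply(comps, function(cc) cc$n_lnc + cc$n_mrna, 0L)
  firsts <- vapply(comps, function(cc) min(c(cc$lnc_ids, cc$mrna_ids)), "")
  o <- order(-sizes, firsts)
  comps <- comps[o]
  for (i in seq_along(comps))
    comps[[i]]$id <- sprintf("C%02d", i)
  comps
}

# mRNA-level concordance: an mRNA counts when some correlated lncRNA in
# the component is significantly associated with the same group in the
# same direction.
.component_concordance <- function(edges, mrna_ids, sig, sig_key) {
  concordant <- vapply(mrna_ids, function(m) {
    partners <- edges$lnc_id[edges$mrna_id == m]
    msig <- sig[sig$feature_id == m, , drop = FALSE]
    if (nrow(msig) == 0L) return(FALSE)
    any(paste(rep(partners, each = nrow(msig)), msig$group, msig$direction)
        %in% sig_key)
  }, TRUE)
  list(fraction = if (length(mrna_ids)) mean(concordant) else NA_real_,
       concordant = mrna_ids[concordant])
}

#' Identify the master-regulator lncRNA set of a component
#'
#' A component qualifies only when it is large (`n_mrna >= min_mrna`),
#' clinically coherent (`concordance > concordance_min`), and its member
#' mRNAs are enriched in at least one gene set at the given level.  The
#' master set is then the minimal lncRNA subset covering at least
#' `cover_fraction` of the member mRNAs, found by greedy set cover
#' (largest marginal coverage first, ties by total degree then
#' lexicographic order).
#'
#' @param component One component from [build_network()].
#' @param enrichment Enrichment table for the component's mRNAs (from
#'   [run_ora()]).
#' @param min_mrna Minimum mRNA count for a "large" network (default 20).
#' @param concordance_min Concordance that must be exceeded (default 0.8).
#' @param cover_fraction Fraction of member mRNAs the set must cover.
#' @param alpha Enrichment significance level (default 0.01).
#' @return Character vector of master-regulator lncRNA ids (possibly
#'   empty).
#' @export
find_master_regulators <- function(component, enrichment, min_mrna = 20,
                                   concordance_min = 0.8,
                                   cover_fraction = 1.0, alpha = 0.01) {
  if (component$n_mrna < min_mrna) return(character(0L))
  if (is.na(component$concordance) ||
      component$concordance <= concordance_min) return(character(0L))
  if (is.null(enrichment) || nrow(enrichment) == 0L ||
      !any(enrichment$p < alpha)) return(character(0L))
  covers <- lapply(split(component$edges$mrna_id, component$edges$lnc_id),
                   unique)
  degree <- lengths(covers)
  target <- ceiling(cover_fraction * component$n_mrna)
  covered <- character(0L)
  chosen <- character(0L)
  remaining <- sort(names(covers))
  while (length(covered) < target && length(remaining)) {
    gain <- vapply(remaining,
                   function(l) length(setdiff(covers[[l]], covered)), 0L)
    if (max(gain) == 0L) break
    best <- remaining[gain == max(gain)]
    best <- best[degree[best] == max(degree[best])]
    pick <- sort(best)[1L]
    chosen <- c(chosen, pick)
    covered <- union(covered, covers[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  chosen
}

#' LncRNAs uniquely associated with a single clinical phenotype
#'
#' @param relevance Relevance table from [classify_relevance()].
#' @param lnc_ids Character vector restricting the map to lncRNAs.
#' @return Named list, one sorted lncRNA vector per clinical group; an
#'   lncRNA appears under group `g` only when its concordant significant
#'   groups are exactly `{g}`.
#' @export
phenotype_unique <- function(relevance, lnc_ids = NULL) {
  rel <- relevance[relevance$cls != "none", , drop = FALSE]
  if (!is.null(lnc_ids)) rel <- rel[rel$feature_id %in% lnc_ids, , drop = FALSE]
  out <- setNames(vector("list", length(.ALL_GROUPS)), .ALL_GROUPS)
  single <- rel[!grepl(",", rel$groups, fixed = TRUE) & rel$groups != "", ,
                drop = FALSE]
  for (g in .ALL_GROUPS)
    out[[g]] <- sort(single$feature_id[single$groups == g])
  out
}

#' Gene lists correlated with phenotype-unique lncRNAs
#'
#' For each clinical group and DE direction, collects the union of mRNAs
#' strongly correlated with that group's unique lncRNAs.
#'
#' @param unique_map Output of [phenotype_unique()].
#' @param pairs Pair table from [call_pairs()].
#' @param de_mrna mRNA DE table (for the up/down split).
#' @return Named list: per group, a list with sorted `up` and `down`
#'   mRNA vectors.
#' @export
unique_phenotype_gene_sets <- function(unique_map, pairs, de_mrna) {
  dir_m <- setNames(de_mrna$direction, de_mrna$feature_id)
  lapply(unique_map, function(lncs) {
    m <- unique(pairs$mrna_id[pairs$lnc_id %in% lncs])
    list(up = sort(m[dir_m[m] == "up"]), down = sort(m[dir_m[m] == "down"]))
  })
}
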