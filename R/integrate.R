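#' Cross-disease synthesis
#'
#' Shared-gene overlap matrices between disease signatures, the
#' hypergeometric test for shared re-ranked drug candidates between a
#' reference disease and each other disease, and the drug-target-pathway
#' linkage that prioritizes drugs hitting the key pathways (those
#' highlighted exclusively through the gene map, not through network
#' topology).
#'
#' @name integratemod
NULL

#' Shared-gene overlap counts between disease signatures
#'
#' @param signatures named list: disease -> list with `over` and `under`
#'   character vectors (e.g. from [aggregate_signatures()]).
#' @param direction `"over"` or `"under"`.
#' @return Symmetric integer matrix of pairwise intersection sizes; the
#'   diagonal holds the list sizes.
#' @export
disease_gene_overlap <- function(signatures, direction = c("over", "under")) {
  direction <- match.arg(direction)
  lists <- lapply(signatures, `[[`, direction)
  n <- length(lists)
  out <- matrix(0L, n, n, dimnames = list(names(lists), names(lists)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- if (i == j) length(lists[[i]]) else
        length(intersect(lists[[i]], lists[[j]]))
    }
  }
  out
}

#' Hypergeometric point probability for shared drug candidates
#'
#' The probability of drawing exactly `x` marked items in `k` draws
#' without replacement from `m` marked and `n` unmarked:
#' C(m,x) C(n,k-x) / C(m+n,k), computed in log-gamma space. In the
#' shared-drug construction, `x` is the number of re-ranked drugs shared
#' with the reference disease, `m` the reference's re-ranked drugs present
#' in the query disease's unfiltered repurposing output, `n` the query's
#' remaining unfiltered drugs and `k` the query's re-ranked drug count.
#' The point probability (not an upper tail) is the reproduced behavior;
#' an upper-tail variant is available behind `tail = "upper"`.
#'
#' @param x,m,n,k non-negative integers with `k <= m + n` and
#'   `x <= min(m, k)`.
#' @param tail `"point"` (default) or `"upper"` (P[X >= x]).
#' @return Probability in [0, 1].
#' @export
hypergeometric_overlap <- function(x, m, n, k, tail = c("point", "upper")) {
  tail <- match.arg(tail)
  vals <- c(x, m, n, k)
  assert_that(all(vals >= 0) && all(vals == round(vals)),
              "x, m, n, k must be non-negative integers")
  assert_that(k <= m + n, "infeasible draw: k > m + n")
  assert_that(x <= min(m, k) && x >= max(0, k - n),
              "infeasible (x, m, n, k) combination")
  point <- function(xx)
    exp(lchoose(m, xx) + lchoose(n, k - xx) - lchoose(m + n, k))
  if (tail == "point") point(x)
  else sum(point(seq(x, min(m, k))))
}

#' Operational definition of key pathways
#'
#' Key pathways are those highlighted for a disease exclusively through
#' the gene map: present in the guided top-5%, significant by odds
#' ratio and adjusted p, and not flagged as topology-favored (top-5%
#' betweenness or degree).
#'
#' @param highlighted character vector of guided top-5% pathways.
#' @param significance output of [pathway_significance()].
#' @param topology output of [topology_profile()].
#' @return Character vector of key pathway ids.
#' @export
key_pathways <- function(highlighted, significance, topology) {
  sig <- significance$pathway[significance$significant]
  topo <- topology$pathway[topology$top_betweenness | topology$top_degree]
  sort(setdiff(intersect(highlighted, sig), topo))
}

#' Drug-target-pathway linkage and prioritization
#'
#' Enumerates every (pathway, gene, drug) combination where the drug
#' targets a gene that is a member of a highlighted pathway. A drug is
#' prioritized when it targets, through at least one gene each, at least
#' `min_key` distinct key pathways. Also emits a drug-drug functional
#' similarity edge list weighted by the number of shared in-pathway
#' target genes.
#'
#' @param drug_targets named list: drug id -> character vector of target
#'   gene ids. Targets not present in any pathway universe are reported
#'   via message and skipped.
#' @param pathway_members named list: pathway id -> member genes.
#' @param highlighted_pathways character vector of highlighted pathways.
#' @param key_pathways character vector, subset of the highlighted set.
#' @param min_key distinct key pathways a drug must hit to be prioritized.
#' @return A list with `linkage` (data.frame pathway, gene, drug_id),
#'   `pathways_hit` (per-drug counts of distinct highlighted and key
#'   pathways), `prioritized` (drug ids) and `functional_edges`
#'   (data.frame drug_a, drug_b, shared_targets).
#' @export
drug_target_pathway_linkage <- function(drug_targets, pathway_members,
                                        highlighted_pathways,
                                        key_pathways, min_key = 2) {
  assert_that(all(key_pathways %in% highlighted_pathways),
              "key_pathways must be a subset of highlighted_pathways")
  universe <- unique(unlist(pathway_members))
  rows <- list()
  for (d in names(drug_targets)) {
    targets <- drug_targets[[d]]
    unknown <- setdiff(targets, universe)
    if (length(unknown))
      message("drug ", d, ": ", length(unknown),
              " target gene(s) not in the pathway universe; skipped")
    targets <- intersect(targets, universe)
    for (pw in highlighted_pathways) {
      hit <- intersect(targets, pathway_members[[pw]])
      if (length(hit))
        rows[[length(rows) + 1]] <- data.frame(pathway = pw, gene = hit,
                                               drug_id = d,
                                               stringsAsFactors = FALSE)
    }
  }
  linkage <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway = character(0), gene = character(0),
               drug_id = character(0), stringsAsFactors = FALSE)

  drugs <- sort(unique(linkage$drug_id))
  pathways_hit <- data.frame(
    drug_id = drugs,
    n_highlighted = vapply(drugs, function(d)
      length(unique(linkage$pathway[linkage$drug_id == d])), integer(1)),
    n_key = vapply(drugs, function(d)
      length(unique(intersect(linkage$pathway[linkage$drug_id == d],
                              key_pathways))), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  prioritized <- pathways_hit$drug_id[pathways_hit$n_key >= min_key]

  # shared in-pathway target genes between drug pairs
  in_path_targets <- lapply(drugs, function(d)
    unique(linkage$gene[linkage$drug_id == d]))
  names(in_path_targets) <- drugs
  fe <- list()
  if (length(drugs) >= 2) {
    for (i in seq_len(length(drugs) - 1)) {
      for (j in seq(i + 1, length(drugs))) {
        shared <- length(intersect(in_path_targets[[i]],
                                   in_path_targets[[j]]))
        if (shared > 0)
          fe[[length(fe) + 1]] <- data.frame(drug_a = drugs[i],
                                             drug_b = drugs[j],
                                             shared_targets = shared,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  functional_edges <- if (length(fe)) do.call(rbind, fe) else
    data.frame(drug_a = character(0), drug_b = character(0),
               shared_targets = integer(0), stringsAsFactors = FALSE)

  list(linkage = linkage, pathways_hit = pathways_hit,
       prioritized = prioritized, functional_edges = functional_edges)
}

#' Export a disease-pathway-gene-drug layering as JSON
#'
#' Four-layer export (disease, pathway, gene, drug with the linkage rows
#' as inter-layer edges) for external multi-layer network viewers.
#'
#' @param disease disease id.
#' @param linkage linkage data.frame from
#'   [drug_target_pathway_linkage()].
#' @param path output file.
#' @export
write_layered_json <- function(disease, linkage, path) {
  obj <- list(
    layers = list(disease = disease,
                  pathways = sort(unique(linkage$pathway)),
                  genes = sort(unique(linkage$gene)),
                  drugs = sort(unique(linkage$drug_id))),
    edges = linkage)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
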