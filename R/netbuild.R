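#' Gene map and pathway network construction
#'
#' The disease gene map is a weighted undirected gene-gene graph built by
#' summing, per gene pair, the normalized weights contributed by each
#' functional network type (co-expression, physical interaction, pathway
#' co-membership). The pathway network links pathways whose member sets
#' share at least one gene, with the shared-gene count as the edge weight.
#' Topology diagnostics (betweenness centrality on inverse-weight shortest
#' paths, strength, degree, top-5% flags) identify pathways the walk engine
#' will favor for structural rather than biological reasons.
#'
#' @name netbuild
NULL

#' Build the gene map from functional records
#'
#' @param records data.frame with columns gene_a, gene_b, network_type,
#'   weight; pairs are unordered and each (pair, type) may occur only once.
#' @param genes optional gene ids to retain as nodes even when isolated
#'   (genes with no surviving edge).
#' @return An [igraph::graph] with edge attribute `weight` (summed across
#'   types), class `gene_map` prepended.
#' @export
build_gene_map <- function(records, genes = NULL) {
  needed <- c("gene_a", "gene_b", "network_type", "weight")
  assert_that(all(needed %in% names(records)),
              "records needs gene_a, gene_b, network_type, weight")
  assert_that(!any(records$gene_a == records$gene_b),
              "self-pair rows are not allowed")
  assert_that(all(records$weight > 0 & records$weight <= 1),
              "weights must lie in (0, 1]")
  a <- pmin(records$gene_a, records$gene_b)
  b <- pmax(records$gene_a, records$gene_b)
  key <- paste(a, b, records$network_type, sep = "\r")
  assert_that(!anyDuplicated(key),
              "duplicate (pair, network_type) rows in records")
  nodes <- sort(unique(c(genes, a, b)))
  assert_that(length(nodes) > 0, "no genes in records or gene list")
  edges <- if (nrow(records)) {
    pair <- paste(a, b, sep = "\r")
    w <- tapply(records$weight, pair, sum)
    ab <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    data.frame(from = ab[, 1], to = ab[, 2], weight = as.numeric(w),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), weight = numeric(0))
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  class(g) <- c("gene_map", class(g))
  g
}

#' Build the shared-gene pathway network
#'
#' @param pathways named list of member-gene character vectors (each with
#'   at least 2 members, unique ids).
#' @return A `pathway_network`: list with `graph` (igraph, edge weight =
#'   shared-gene count) and `members` (the input list, de-duplicated).
#' @export
build_pathway_network <- function(pathways) {
  assert_that(is.list(pathways) && !is.null(names(pathways)),
              "pathways must be a named list")
  assert_that(!anyDuplicated(names(pathways)), "duplicate pathway ids")
  pathways <- lapply(pathways, unique)
  assert_that(all(lengths(pathways) >= 2),
              "each pathway needs at least 2 member genes")
  ids <- names(pathways)
  n <- length(ids)
  edges <- list()
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      shared <- length(intersect(pathways[[i]], pathways[[j]]))
      if (shared >= 1) {
        k <- k + 1L
        edges[[k]] <- c(i, j, shared)
      }
    }
  }
  em <- if (k) do.call(rbind, edges) else matrix(numeric(0), ncol = 3)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[em[, 1]], to = ids[em[, 2]], weight = em[, 3]),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  structure(list(graph = g, members = pathways), class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("Pathway network: ", igraph::vcount(x$graph), " pathways, ",
      igraph::ecount(x$graph), " shared-gene edges\n", sep = "")
  invisible(x)
}

# deterministic top-k flag: order by score desc, ties by id, first ceil(frac*N)
top_frac_flag <- function(scores, ids, frac) {
  k <- ceiling(frac * length(ids))
  ord <- order(-scores, ids)
  flag <- logical(length(ids))
  flag[ord[seq_len(k)]] <- TRUE
  flag
}

#' Topology diagnostics for a pathway network
#'
#' Betweenness centrality is computed on shortest paths with edge length
#' 1/weight (the same convention as the walk engine), strength is the sum
#' of incident edge weights, and the top-5% flags mark exactly
#' `ceiling(top_frac * N)` pathways each (ties at the boundary broken by
#' pathway id).
#'
#' @param net a `pathway_network` (or igraph with `weight` edges).
#' @param top_frac fraction flagged as topology-favored.
#' @return data.frame: pathway, betweenness, strength, degree,
#'   top_betweenness, top_degree.
#' @export
topology_profile <- function(net, top_frac = 0.05) {
  g <- if (inherits(net, "pathway_network")) net$graph else net
  assert_that(igraph::vcount(g) > 0, "empty graph")
  w <- igraph::E(g)$weight
  btw <- igraph::betweenness(g, weights = if (length(w)) 1 / w else NULL,
                             directed = FALSE)
  strength <- igraph::strength(g, weights = w)
  degree <- igraph::degree(g)
  ids <- igraph::V(g)$name
  out <- data.frame(pathway = ids,
                    betweenness = as.numeric(btw),
                    strength = as.numeric(strength),
                    degree = as.integer(degree),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$top_betweenness <- top_frac_flag(out$betweenness, out$pathway, top_frac)
  out$top_degree <- top_frac_flag(as.numeric(out$degree), out$pathway,
                                  top_frac)
  out[order(out$pathway), , drop = FALSE]
}

#' Translate gene symbols through a lookup table
#'
#' Maps gene ids into the pathway id space with a plain two-column table;
#' unmapped genes are dropped with a message reporting the count.
#'
#' @param genes character vector of gene ids.
#' @param lookup data.frame with columns `from`, `to`.
#' @return Character vector of mapped ids (unique, order preserved).
#' @export
translate_genes <- function(genes, lookup) {
  assert_that(all(c("from", "to") %in% names(lookup)),
              "lookup needs columns from, to")
  hit <- match(genes, lookup$from)
  n_miss <- sum(is.na(hit))
  if (n_miss > 0)
    message(n_miss, " gene id(s) had no mapping and were dropped")
  unique(lookup$to[hit[!is.na(hit)]])
}
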