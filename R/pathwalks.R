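#' Gene-map-guided random walks on the pathway network
#'
#' The walk engine repeatedly picks a target pathway and traverses the
#' weighted shortest path to it from the current position, tallying every
#' pathway visited. In guided mode the target is chosen through the gene
#' map: a gene is sampled with probability proportional to its strength in
#' the map, then one of its pathway memberships uniformly. In random mode
#' the target is uniform over pathways, which serves as the topology-only
#' null. Edge lengths are the inverse of the shared-gene edge weights, so
#' strongly overlapping pathways are "close"; among equal-cost paths the
#' lexicographically smallest node sequence is taken, making every
#' execution reproducible from its seed.
#'
#' The precise selection and traversal rules implemented here
#' (strength-proportional gene sampling, uniform pathway choice per gene,
#' inverse-weight path costs, origin-exclusive visit counting with the
#' target always counted, current position updated to the target) are this
#' package's own faithful-in-spirit reconstruction of the guided-walk idea;
#' no claim of line-for-line equivalence with the original software is
#' made.
#'
#' @name pathwalks
NULL

no_path_error <- function(src, dst) {
  stop(structure(class = c("fibropath_no_path", "error", "condition"),
                 list(message = sprintf("no path between %s and %s",
                                        src, dst),
                      call = NULL)))
}

as_weighted_graph <- function(network) {
  g <- if (inherits(network, "pathway_network")) network$graph else network
  assert_that(igraph::vcount(g) > 0, "empty network")
  g
}

# adjacency list with inverse-weight lengths, nodes addressed by sorted id
build_adjacency <- function(g) {
  ids <- sort(igraph::V(g)$name)
  ends <- igraph::as_edgelist(g)
  len <- 1 / igraph::E(g)$weight
  ia <- match(ends[, 1], ids)
  ib <- match(ends[, 2], ids)
  adj <- vector("list", length(ids))
  for (k in seq_along(len)) {
    adj[[ia[k]]] <- rbind(adj[[ia[k]]], c(ib[k], len[k]))
    adj[[ib[k]]] <- rbind(adj[[ib[k]]], c(ia[k], len[k]))
  }
  list(ids = ids, adj = adj)
}

# lexicographically smallest shortest path (indices) given distance matrix
extract_path <- function(s, t, D, adj) {
  if (!is.finite(D[s, t])) return(NULL)
  eps <- 1e-9 * max(1, D[s, t])
  path <- s
  cur <- s
  while (cur != t) {
    nb <- adj[[cur]]
    ok <- nb[, 1][abs(D[cur, t] - (nb[, 2] + D[nb[, 1], t])) <= eps]
    nxt <- min(ok)
    path <- c(path, nxt)
    cur <- nxt
  }
  path
}

#' Deterministic weighted shortest path
#'
#' Minimizes the sum of inverse edge weights along the path; among
#' equal-cost paths the lexicographically smallest node sequence is
#' returned. A disconnected pair raises a condition of class
#' `fibropath_no_path`.
#'
#' @param network a `pathway_network` or weighted igraph.
#' @param src,dst node names.
#' @return Character vector of node names from `src` to `dst` (a single
#'   node when `src == dst`).
#' @export
shortest_path <- function(network, src, dst) {
  g <- as_weighted_graph(network)
  ids <- sort(igraph::V(g)$name)
  assert_that(all(c(src, dst) %in% ids), "src and dst must be in network")
  if (src == dst) return(src)
  ad <- build_adjacency(g)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  D <- D[ids, ids, drop = FALSE]
  p <- extract_path(match(src, ids), match(dst, ids), D, ad$adj)
  if (is.null(p)) no_path_error(src, dst)
  ids[p]
}

#' Sample target pathways through the gene map
#'
#' Samples a gene with probability proportional to its strength in the
#' gene map (isolated genes receive `floor_weight`), then one of that
#' gene's pathway memberships uniformly. Genes with no pathway membership
#' are excluded from sampling (the rejection-and-resample rule); if no
#' gene maps to any pathway the call fails.
#'
#' @param gene_map igraph gene map (weighted).
#' @param membership named list: gene id -> character vector of pathways.
#' @param n number of draws.
#' @param floor_weight sampling weight assigned to isolated genes.
#' @param pathway_ids optional restriction of admissible target pathways.
#' @return Character vector of `n` pathway ids.
#' @export
select_target_guided <- function(gene_map, membership, n = 1,
                                 floor_weight = 0.1, pathway_ids = NULL) {
  genes <- igraph::V(gene_map)$name
  assert_that(length(genes) > 0, "gene map is empty")
  s <- igraph::strength(gene_map, weights = igraph::E(gene_map)$weight)
  s[s == 0] <- floor_weight
  mem <- membership[genes[genes %in% names(membership)]]
  if (!is.null(pathway_ids))
    mem <- lapply(mem, function(p) p[p %in% pathway_ids])
  mem <- mem[lengths(mem) > 0]
  assert_that(length(mem) > 0, "no gene in the map maps to any pathway")
  w <- s[names(mem)]
  gi <- sample.int(length(mem), n, replace = TRUE, prob = w)
  # uniform membership choice, vectorized over the flattened membership list
  flat <- unlist(mem, use.names = FALSE)
  off <- c(0L, cumsum(lengths(mem)))
  pick <- off[gi] + ceiling(stats::runif(n) * lengths(mem)[gi])
  flat[pick]
}

# tally node and edge visits for consecutive (prev, target) pairs
count_visits <- function(prev, tgt, paths, n_nodes) {
  pair_id <- (prev - 1L) * n_nodes + tgt
  tab <- tabulate(pair_id, nbins = n_nodes * n_nodes)
  used <- which(tab > 0L)
  node_counts <- integer(n_nodes)
  edge_counts <- list()
  for (pid in used) {
    s <- ((pid - 1L) %/% n_nodes) + 1L
    t <- ((pid - 1L) %% n_nodes) + 1L
    cnt <- tab[pid]
    p <- paths[[pid]]
    visited <- if (length(p) == 1L) p else p[-1L]
    node_counts[visited] <- node_counts[visited] + cnt
    if (length(p) > 1L) {
      a <- p[-length(p)]
      b <- p[-1L]
      ekey <- paste(pmin(a, b), pmax(a, b))
      edge_counts[[length(edge_counts) + 1L]] <-
        data.frame(key = ekey, count = cnt, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edge_counts)) {
    ec <- do.call(rbind, edge_counts)
    agg <- tapply(ec$count, ec$key, sum)
    data.frame(key = names(agg), count = as.integer(agg),
               stringsAsFactors = FALSE)
  } else data.frame(key = character(0), count = integer(0))
  list(nodes = node_counts, edges = edges)
}

#' Run a guided or random walk execution
#'
#' Walks are confined to the largest connected component of the pathway
#' network; excluded pathways are reported in the result (with zero
#' counts), never silently dropped. Per iteration: a target is drawn
#' (guided through the gene map, or uniform in random mode), the shortest
#' path from the current pathway to the target is traversed, every pathway
#' on the path excluding the origin and including the target gets one
#' visit (a target equal to the origin still counts one visit), traversed
#' edges are tallied, and the current position moves to the target. The
#' start position is uniform over the component. A convergence diagnostic
#' (L1 distance between the visit distributions of the two halves of the
#' run) is attached.
#'
#' @param pathway_network a `pathway_network`.
#' @param gene_map igraph gene map (guided mode).
#' @param membership named list gene -> pathway ids (guided mode).
#' @param n_iterations number of walk iterations (>= 1).
#' @param mode `"guided"` or `"random"`.
#' @param seed integer seed.
#' @param floor_weight passed to [select_target_guided()].
#' @return A `walk_counts`: mode, times_walked (named counts over all
#'   pathways), edge_visits (data.frame from, to, count),
#'   total_times_walked, n_iterations, seed, excluded (pathways outside
#'   the component), convergence_l1.
#' @export
run_pathwalks <- function(pathway_network, gene_map = NULL,
                          membership = NULL, n_iterations = 5e4,
                          mode = c("guided", "random"), seed = 1,
                          floor_weight = 0.1) {
  mode <- match.arg(mode)
  assert_that(n_iterations >= 1, "n_iterations must be >= 1")
  g <- as_weighted_graph(pathway_network)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  excluded <- sort(setdiff(igraph::V(g)$name, igraph::V(g)$name[keep]))
  sub <- igraph::induced_subgraph(g, keep)
  ad <- build_adjacency(sub)
  ids <- ad$ids
  n <- length(ids)
  D <- igraph::distances(sub, weights = 1 / igraph::E(sub)$weight)
  D <- D[ids, ids, drop = FALSE]
  paths <- vector("list", n * n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      paths[[(s - 1L) * n + t]] <- if (s == t) s else extract_path(s, t, D,
                                                                   ad$adj)
    }
  }

  set.seed(seed)
  N <- as.integer(n_iterations)
  if (mode == "random") {
    tgt <- sample.int(n, N, replace = TRUE)
  } else {
    assert_that(!is.null(gene_map) && !is.null(membership),
                "guided mode needs gene_map and membership")
    tgt_ids <- select_target_guided(gene_map, membership, n = N,
                                    floor_weight = floor_weight,
                                    pathway_ids = ids)
    tgt <- match(tgt_ids, ids)
  }
  start <- sample.int(n, 1)
  prev <- c(start, tgt[-N])

  half <- N %/% 2
  c1 <- count_visits(prev[seq_len(half)], tgt[seq_len(half)], paths, n)
  c2 <- count_visits(prev[seq(half + 1, N)], tgt[seq(half + 1, N)], paths, n)
  nodes <- c1$nodes + c2$nodes
  f1 <- c1$nodes / max(1, sum(c1$nodes))
  f2 <- c2$nodes / max(1, sum(c2$nodes))
  l1 <- sum(abs(f1 - f2))

  ec <- rbind(c1$edges, c2$edges)
  edge_visits <- if (nrow(ec)) {
    agg <- tapply(ec$count, ec$key, sum)
    ij <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
    data.frame(from = ids[as.integer(ij[, 1])], to = ids[as.integer(ij[, 2])],
               count = as.integer(agg), stringsAsFactors = FALSE,
               row.names = NULL)
  } else data.frame(from = character(0), to = character(0),
                    count = integer(0))

  times_walked <- integer(n + length(excluded))
  names(times_walked) <- c(ids, excluded)
  times_walked[seq_len(n)] <- nodes
  times_walked <- times_walked[order(names(times_walked))]

  structure(list(mode = mode, times_walked = times_walked,
                 edge_visits = edge_visits,
                 total_times_walked = sum(nodes),
                 n_iterations = N, seed = seed, excluded = excluded,
                 convergence_l1 = l1),
            class = "walk_counts")
}

#' @export
print.walk_counts <- function(x, ...) {
  cat("Walk counts (", x$mode, " mode): ", x$n_iterations,
      " iterations, ", x$total_times_walked, " visits over ",
      length(x$times_walked), " pathways\n", sep = "")
  if (length(x$excluded))
    cat("  excluded from component: ", length(x$excluded), " pathways\n",
        sep = "")
  invisible(x)
}

#' Top-visited pathways of a walk execution
#'
#' @param walk_counts a `walk_counts`.
#' @param frac fraction of pathways returned (`ceiling(frac * N)` entries;
#'   ties at the boundary broken by pathway id).
#' @return Character vector of pathway ids, most-visited first.
#' @export
top_pathways <- function(walk_counts, frac = 0.05) {
  assert_that(walk_counts$total_times_walked > 0, "no visits recorded")
  tw <- walk_counts$times_walked
  k <- ceiling(frac * length(tw))
  ord <- order(-tw, names(tw))
  names(tw)[ord[seq_len(k)]]
}

#' Invert pathway definitions into a gene membership list
#'
#' @param pathways named list of member-gene vectors.
#' @return Named list: gene id -> character vector of pathway ids.
#' @export
membership_from_pathways <- function(pathways) {
  genes <- unlist(pathways, use.names = FALSE)
  pw <- rep(names(pathways), lengths(pathways))
  split(pw, genes)
}
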