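# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive each quantity from first principles
# (exhaustive enumeration, closed forms) and never call the package
# functions they are checking.

# all simple paths s -> t in a weighted undirected graph given as an
# edge data.frame (from, to, weight); returns list of name vectors
oracle_all_paths <- function(edges, nodes, s, t) {
  nbr <- function(v) {
    rows <- edges$from == v | edges$to == v
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  }
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (u in nbr(v)) if (!u %in% path) walk(c(path, u))
  }
  walk(s)
  out
}

oracle_path_cost <- function(edges, path) {
  if (length(path) < 2) return(0)
  cost <- 0
  for (i in seq_len(length(path) - 1)) {
    a <- path[i]; b <- path[i + 1]
    w <- edges$weight[(edges$from == a & edges$to == b) |
                        (edges$from == b & edges$to == a)]
    cost <- cost + 1 / w[1]
  }
  cost
}

# lexicographically smallest minimum-cost path (NULL when disconnected)
oracle_shortest_path <- function(edges, nodes, s, t) {
  if (s == t) return(s)
  paths <- oracle_all_paths(edges, nodes, s, t)
  if (!length(paths)) return(NULL)
  costs <- vapply(paths, function(p) oracle_path_cost(edges, p), numeric(1))
  best <- paths[costs <= min(costs) + 1e-12]
  keys <- vapply(best, paste, character(1), collapse = "\r")
  best[[order(keys)[1]]]
}

# betweenness centrality by exhaustive shortest-path enumeration
oracle_betweenness <- function(edges, nodes) {
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      paths <- oracle_all_paths(edges, nodes, nodes[i], nodes[j])
      if (!length(paths)) next
      costs <- vapply(paths, function(p) oracle_path_cost(edges, p),
                      numeric(1))
      sp <- paths[costs <= min(costs) + 1e-12]
      inner <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        tab <- table(inner) / length(sp)
        btw[names(tab)] <- btw[names(tab)] + tab
      }
    }
  }
  btw
}

# Benjamini-Hochberg by the literal step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Pearson chi-square statistic and p for a 2x2 table, closed form
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# hypergeometric point probability by exhaustive draw enumeration
oracle_hyper <- function(x, m, n, k) {
  items <- c(rep(1, m), rep(0, n))
  draws <- utils::combn(m + n, k)
  mean(colSums(matrix(items[draws], nrow = k)) == x)
}

# O(n^2) threshold scan for the similarity network edge set
oracle_simnet_edges <- function(cand, failed, base, attach) {
  tani <- function(a, b) sum(a & b) / sum(a | b)
  out <- list()
  cn <- rownames(cand)
  if (nrow(cand) >= 2) {
    for (i in seq_len(nrow(cand) - 1)) {
      for (j in seq(i + 1, nrow(cand))) {
        s <- tani(cand[i, ], cand[j, ])
        if (s >= base)
          out[[length(out) + 1]] <- data.frame(from = cn[i], to = cn[j],
                                               similarity = s)
      }
    }
  }
  if (!is.null(failed)) {
    fn <- rownames(failed)
    for (i in seq_len(nrow(failed))) {
      for (j in seq_len(nrow(cand))) {
        s <- tani(failed[i, ], cand[j, ])
        if (s >= attach)
          out[[length(out) + 1]] <- data.frame(from = fn[i], to = cn[j],
                                               similarity = s)
      }
    }
  }
  if (!length(out))
    return(data.frame(from = character(0), to = character(0),
                      similarity = numeric(0)))
  do.call(rbind, out)
}

# step-by-step trimmed-mean-of-M-values factors (reference = sample whose
# upper-quartile count fraction is closest to the mean across samples)
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, p = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    obs <- counts[, j]; rf <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f / exp(mean(log(f)))
}

# random connected weighted graph as an edge data.frame
random_weighted_graph <- function(n_nodes, p_edge = 0.6,
                                  weights = 1:5) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  edges <- list()
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      if (stats::runif(1) < p_edge || j == i + 1)  # chain keeps it connected
        edges[[length(edges) + 1]] <-
          data.frame(from = nodes[i], to = nodes[j],
                     weight = sample(weights, 1),
                     stringsAsFactors = FALSE)
    }
  }
  list(nodes = nodes, edges = do.call(rbind, edges))
}

edges_to_igraph <- function(gr) {
  igraph::graph_from_data_frame(gr$edges, directed = FALSE,
                                vertices = data.frame(name = gr$nodes))
}

random_fps <- function(n, bits, p = 0.3) {
  m <- matrix(stats::rbinom(n * bits, 1, p), n, bits)
  # guard against the degenerate all-zero fingerprint
  m[rowSums(m) == 0, 1] <- 1L
  rownames(m) <- sprintf("F%03d", seq_len(n))
  m
}
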