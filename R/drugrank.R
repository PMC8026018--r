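#' Signature-inversion candidate filtering and drug re-ranking
#'
#' Candidate inhibitors are drugs whose expression effect inverts the
#' disease signature: connectivity-score drugs with a summary score below
#' -50 in any experiment, plus every entry of the fixed-size
#' reverse-signature inclusion lists. Candidates are then scored for
#' drugability (Lipinski + Veber rules), combined with their functional
#' association and binding affinity into a composite rank, clustered
#' structurally by affinity propagation on Tanimoto similarities, and the
#' top-ranked inhibitor of each cluster is flagged as its representative.
#'
#' @name drugrank
NULL

#' Filter signature-inverting drug candidates
#'
#' Keeps the union of (i) connectivity-score drugs with score strictly
#' below `threshold` in at least one experiment (the summary score across
#' experiments of one disease is taken as the minimum, configurable) and
#' (ii) all drugs on the inclusion lists, regardless of score. Provenance
#' records which route admitted each drug.
#'
#' @param cmap_scores data.frame with columns drug_id, experiment, score
#'   (scores in [-100, 100]; -100 is maximal inhibition).
#' @param l1000_entries data.frame with column drug_id (inclusion lists),
#'   or NULL.
#' @param threshold strict upper bound on the summary score.
#' @param aggregate how per-experiment scores are summarized per drug
#'   (`"min"`: a drug qualifies if any experiment is below threshold).
#' @return data.frame: drug_id, source (`"cmap"`, `"l1000"` or `"both"`),
#'   summary_score.
#' @export
filter_inhibitors <- function(cmap_scores, l1000_entries = NULL,
                              threshold = -50, aggregate = c("min")) {
  aggregate <- match.arg(aggregate)
  cmap_ids <- character(0)
  summary_score <- numeric(0)
  if (!is.null(cmap_scores) && nrow(cmap_scores)) {
    assert_that(all(cmap_scores$score >= -100 & cmap_scores$score <= 100),
                "connectivity scores must lie in [-100, 100]")
    s <- tapply(cmap_scores$score, cmap_scores$drug_id, min)
    cmap_ids <- names(s)[s < threshold]
    summary_score <- s
  }
  l1000_ids <- if (!is.null(l1000_entries) && nrow(l1000_entries))
    unique(l1000_entries$drug_id) else character(0)
  ids <- sort(union(cmap_ids, l1000_ids))
  if (!length(ids))
    return(data.frame(drug_id = character(0), source = character(0),
                      summary_score = numeric(0), stringsAsFactors = FALSE))
  source <- ifelse(ids %in% cmap_ids & ids %in% l1000_ids, "both",
                   ifelse(ids %in% cmap_ids, "cmap", "l1000"))
  data.frame(drug_id = ids, source = source,
             summary_score = unname(summary_score[ids]),
             stringsAsFactors = FALSE)
}

#' Drugability score from Lipinski and Veber rules
#'
#' The score is the fraction of six oral-drugability rules satisfied:
#' Lipinski's MW <= 500 Da, cLogP <= 5, H-bond donors <= 5, H-bond
#' acceptors <= 10, and Veber's rotatable bonds <= 10 and TPSA <= 140 A^2.
#' Boundary values satisfy their rule (<= convention).
#'
#' @param descriptors data.frame with columns MW, cLogP, HBD, HBA, RotB,
#'   TPSA (all required; a missing or NA descriptor is an error, never a
#'   silent zero).
#' @return Numeric vector of scores in {0, 1/6, ..., 1}.
#' @export
drugability_score <- function(descriptors) {
  needed <- c("MW", "cLogP", "HBD", "HBA", "RotB", "TPSA")
  missing <- setdiff(needed, names(descriptors))
  assert_that(length(missing) == 0,
              paste("missing descriptor column(s):",
                    paste(missing, collapse = ", ")))
  d <- descriptors[needed]
  assert_that(!anyNA(d), "NA descriptor values are not allowed")
  rules <- cbind(d$MW <= 500, d$cLogP <= 5, d$HBD <= 5, d$HBA <= 10,
                 d$RotB <= 10, d$TPSA <= 140)
  rowSums(rules) / 6
}

#' Composite candidate ranking
#'
#' The composite score is a weighted mean (equal weights by default) of
#' the functional-association, binding-affinity and drugability scores,
#' each in [0, 1]. The exact integration formula of the original
#' re-ranking service is unpublished; this explicit weighted mean is the
#' package's stand-in, isolated here with configurable weights.
#'
#' @param candidates data.frame with columns drug_id,
#'   functional_association, binding_affinity, drugability.
#' @param weights length-3 non-negative weights summing to 1.
#' @return The table sorted by composite descending (ties by drug_id),
#'   with a `composite` column.
#' @export
composite_rank <- function(candidates, weights = rep(1 / 3, 3)) {
  assert_that(abs(sum(weights) - 1) < 1e-8, "weights must sum to 1")
  cols <- c("functional_association", "binding_affinity", "drugability")
  assert_that(all(cols %in% names(candidates)),
              "candidates needs functional_association, binding_affinity, drugability")
  s <- as.matrix(candidates[cols])
  assert_that(all(s >= 0 & s <= 1), "scores must lie in [0, 1]")
  candidates$composite <- as.numeric(s %*% weights)
  candidates[order(-candidates$composite, candidates$drug_id), ,
             drop = FALSE]
}

# affinity propagation on a similarity matrix (Frey & Dueck message passing)
affinity_propagation <- function(S, damping = 0.9, max_iter = 1000,
                                 conv_iter = 50, preference = NULL) {
  n <- nrow(S)
  off <- S[row(S) != col(S)]
  preference <- preference %||% stats::median(off)
  diag(S) <- preference
  R <- A <- matrix(0, n, n)
  stable <- 0L
  exemplars_prev <- integer(0)
  for (iter in seq_len(max_iter)) {
    AS <- A + S
    i1 <- max.col(AS, ties.method = "first")
    y1 <- AS[cbind(seq_len(n), i1)]
    AS2 <- AS
    AS2[cbind(seq_len(n), i1)] <- -Inf
    y2 <- apply(AS2, 1, max)
    Rnew <- S - y1
    Rnew[cbind(seq_len(n), i1)] <- S[cbind(seq_len(n), i1)] - y2
    R <- damping * R + (1 - damping) * Rnew

    Rp <- pmax(R, 0)
    diag(Rp) <- 0
    colS <- colSums(Rp)
    Anew <- pmin(matrix(diag(R), n, n, byrow = TRUE) +
                   matrix(colS, n, n, byrow = TRUE) - Rp, 0)
    diag(Anew) <- colS
    A <- damping * A + (1 - damping) * Anew

    exemplars <- which(diag(A + R) > 0)
    if (identical(exemplars, exemplars_prev) && length(exemplars) > 0) {
      stable <- stable + 1L
      if (stable >= conv_iter) break
    } else {
      stable <- 0L
    }
    exemplars_prev <- exemplars
  }
  exemplars <- which(diag(A + R) > 0)
  if (!length(exemplars)) return(NULL)
  assign <- apply(S[, exemplars, drop = FALSE], 1, which.max)
  assign[exemplars] <- seq_along(exemplars)
  labels <- as.integer(assign)
  list(labels = labels, exemplars = exemplars,
       converged = stable >= conv_iter)
}

#' Structural clustering by affinity propagation
#'
#' Clusters candidate fingerprints on their pairwise Tanimoto similarity
#' matrix (preference = median off-diagonal similarity, damping 0.9, at
#' most 1000 iterations). If message passing does not converge, the
#' fallback partition is the connected components of the similarity graph
#' at similarity >= 0.5 (reported with a message).
#'
#' @param fingerprints 0/1 matrix (one row per drug, rownames = drug ids)
#'   or character vector of 0/1 strings.
#' @param damping,max_iter,conv_iter message-passing controls.
#' @return Named integer vector of cluster labels, plus attributes
#'   `exemplars` (drug ids) and `converged`.
#' @export
cluster_structures <- function(fingerprints, damping = 0.9, max_iter = 1000,
                               conv_iter = 50) {
  fps <- if (is.character(fingerprints)) fp_to_matrix(fingerprints)
         else fingerprints
  assert_that(nrow(fps) >= 2, "need at least 2 candidates to cluster")
  ids <- rownames(fps) %||% sprintf("drug%03d", seq_len(nrow(fps)))
  S <- tanimoto_matrix(fps)
  ap <- affinity_propagation(S, damping = damping, max_iter = max_iter,
                             conv_iter = conv_iter)
  if (is.null(ap) || !ap$converged) {
    message("affinity propagation did not converge; ",
            "falling back to connected components at similarity >= 0.5")
    g <- igraph::graph_from_adjacency_matrix(S >= 0.5, mode = "undirected",
                                             diag = FALSE)
    labels <- as.integer(igraph::components(g)$membership)
    exemplars <- vapply(split(seq_along(labels), labels), min, integer(1))
  } else {
    labels <- ap$labels
    exemplars <- ap$exemplars
  }
  names(labels) <- ids
  attr(labels, "exemplars") <- ids[exemplars]
  attr(labels, "converged") <- if (is.null(ap)) FALSE else ap$converged
  labels
}

#' Select the representative inhibitor of each cluster
#'
#' @param ranked output of [composite_rank()] (needs drug_id, composite).
#' @param clusters named integer vector of cluster labels covering every
#'   ranked drug.
#' @return data.frame: drug_id, composite, cluster, representative (TRUE
#'   for the highest-composite drug of each cluster, ties broken by the
#'   lexicographically smaller id).
#' @export
select_representatives <- function(ranked, clusters) {
  assert_that(all(ranked$drug_id %in% names(clusters)),
              "every ranked drug needs a cluster label")
  out <- data.frame(drug_id = ranked$drug_id,
                    composite = ranked$composite,
                    cluster = as.integer(clusters[ranked$drug_id]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$cluster, -out$composite, out$drug_id), , drop = FALSE]
  out$representative <- !duplicated(out$cluster)
  rownames(out) <- NULL
  out
}
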