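#' Structural screening against failed drugs
#'
#' Candidate inhibitors structurally similar to drugs that already failed
#' in clinical trials against fibrotic diseases are deprioritized, since
#' structurally similar compounds tend to share a mode of action. The
#' screen builds a Tanimoto similarity network: candidate-candidate edges
#' at similarity >= 0.5 form the base network, failed drugs attach with
#' edges at similarity >= 0.7, and every candidate adjacent to a failed
#' drug is flagged (advisory - flagged candidates are kept in the output,
#' only given lower testing priority). A Soergel-distance Ward clustering
#' places the candidates into structural families.
#'
#' @name chemscreen
NULL

#' Tanimoto similarity of two fingerprint bit vectors
#'
#' |a AND b| / |a OR b|. Undefined (error) when both fingerprints are
#' all-zero.
#'
#' @param fp_a,fp_b equal-length 0/1 vectors.
#' @return Similarity in [0, 1].
#' @export
tanimoto <- function(fp_a, fp_b) {
  assert_that(length(fp_a) == length(fp_b),
              "fingerprints must have equal length")
  both <- sum(fp_a & fp_b)
  either <- sum(fp_a | fp_b)
  assert_that(either > 0, "Tanimoto undefined for two all-zero fingerprints")
  both / either
}

#' Soergel distance (Tanimoto complement)
#'
#' @inheritParams tanimoto
#' @return 1 - Tanimoto similarity.
#' @export
soergel <- function(fp_a, fp_b) 1 - tanimoto(fp_a, fp_b)

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps 0/1 matrix, one fingerprint per row.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
tanimoto_matrix <- function(fps) {
  fps <- as.matrix(fps)
  ones <- rowSums(fps)
  assert_that(all(ones > 0), "all-zero fingerprint in the library")
  inter <- tcrossprod(fps)
  union <- outer(ones, ones, "+") - inter
  S <- inter / union
  dimnames(S) <- list(rownames(fps), rownames(fps))
  S
}

#' Build the candidate / failed-drug similarity network
#'
#' Candidate-candidate edges where Tanimoto similarity >= `base_threshold`
#' (the base network); failed-to-candidate edges where similarity >=
#' `attach_threshold`. Failed drugs never link to each other, and failed
#' drugs with no attachment are omitted from the node set.
#'
#' @param candidates 0/1 fingerprint matrix or named character vector of
#'   0/1 strings for the re-ranked candidates.
#' @param failed same, for the failed drugs.
#' @param base_threshold candidate-candidate similarity cutoff.
#' @param attach_threshold failed-attachment similarity cutoff.
#' @return A `similarity_network`: list with `nodes` (data.frame drug_id,
#'   role) and `edges` (data.frame from, to, similarity).
#' @export
build_similarity_network <- function(candidates, failed = NULL,
                                     base_threshold = 0.5,
                                     attach_threshold = 0.7) {
  cf <- if (is.character(candidates)) fp_to_matrix(candidates) else candidates
  cand_ids <- rownames(cf)
  assert_that(!is.null(cand_ids), "candidate fingerprints must be named")
  ff <- NULL
  if (!is.null(failed) && NROW(failed)) {
    ff <- if (is.character(failed)) fp_to_matrix(failed) else failed
    assert_that(ncol(ff) == ncol(cf),
                "fingerprint lengths differ between lists")
    assert_that(!any(rownames(ff) %in% cand_ids),
                "id collision between candidate and failed lists")
  }

  edges <- list()
  n <- nrow(cf)
  if (n >= 2) {
    S <- tanimoto_matrix(cf)
    idx <- which(upper.tri(S) & S >= base_threshold, arr.ind = TRUE)
    if (nrow(idx))
      edges[[1]] <- data.frame(from = cand_ids[idx[, 1]],
                               to = cand_ids[idx[, 2]],
                               similarity = S[idx],
                               stringsAsFactors = FALSE)
  }
  attached <- character(0)
  if (!is.null(ff)) {
    ones_c <- rowSums(cf)
    ones_f <- rowSums(ff)
    inter <- tcrossprod(ff, cf)
    un <- outer(ones_f, ones_c, "+") - inter
    Sx <- inter / un
    idx <- which(Sx >= attach_threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      edges[[length(edges) + 1]] <-
        data.frame(from = rownames(ff)[idx[, 1]],
                   to = cand_ids[idx[, 2]],
                   similarity = Sx[idx],
                   stringsAsFactors = FALSE)
      attached <- unique(rownames(ff)[idx[, 1]])
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               similarity = numeric(0), stringsAsFactors = FALSE)
  nodes <- rbind(
    data.frame(drug_id = cand_ids, role = "candidate",
               stringsAsFactors = FALSE),
    if (length(attached)) data.frame(drug_id = sort(attached),
                                     role = "failed",
                                     stringsAsFactors = FALSE))
  structure(list(nodes = nodes, edges = edges,
                 base_threshold = base_threshold,
                 attach_threshold = attach_threshold),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("Similarity network: ", sum(x$nodes$role == "candidate"),
      " candidates, ", sum(x$nodes$role == "failed"),
      " attached failed drugs, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Flag candidates similar to failed drugs
#'
#' Every candidate adjacent to at least one failed drug in the similarity
#' network is flagged for lower testing priority. Flags are advisory: the
#' candidate list is never truncated, mirroring the position that such
#' compounds may still act at other doses or in combinations.
#'
#' @param network a `similarity_network`.
#' @return data.frame: drug_id, n_failed_neighbors, failed_neighbors
#'   (comma-separated ids); empty when no candidate is affected.
#' @export
flag_failed_similar <- function(network) {
  stopifnot(inherits(network, "similarity_network"))
  failed_ids <- network$nodes$drug_id[network$nodes$role == "failed"]
  e <- network$edges[network$edges$from %in% failed_ids, , drop = FALSE]
  if (!nrow(e))
    return(data.frame(drug_id = character(0),
                      n_failed_neighbors = integer(0),
                      failed_neighbors = character(0),
                      stringsAsFactors = FALSE))
  by_cand <- split(e$from, e$to)
  data.frame(drug_id = sort(names(by_cand)),
             n_failed_neighbors = lengths(by_cand)[sort(names(by_cand))],
             failed_neighbors = vapply(by_cand[sort(names(by_cand))],
                                       function(v) paste(sort(v),
                                                         collapse = ","),
                                       character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hierarchical structural clustering (Soergel distance, Ward linkage)
#'
#' Agglomerative Ward clustering on Soergel distances (1 - Tanimoto),
#' with flat clusters cut at the given height. Ward linkage on a
#' non-Euclidean distance follows the recipe of the original screening
#' tool; the metric caveat is documented rather than silently substituted.
#'
#' @param fingerprints 0/1 matrix or character vector of 0/1 strings.
#' @param distance distance name; only `"soergel"` is available.
#' @param threshold linkage-height cut.
#' @param linkage hclust method (default `"ward.D2"`).
#' @return Named integer vector of cluster labels.
#' @export
ward_cluster <- function(fingerprints, distance = "soergel", threshold = 1.0,
                         linkage = "ward.D2") {
  assert_that(identical(distance, "soergel"),
              paste("unknown distance:", distance))
  fps <- if (is.character(fingerprints)) fp_to_matrix(fingerprints)
         else fingerprints
  assert_that(nrow(fps) >= 2, "need at least 2 fingerprints")
  D <- stats::as.dist(1 - tanimoto_matrix(fps))
  hc <- stats::hclust(D, method = linkage)
  labels <- stats::cutree(hc, h = threshold)
  names(labels) <- rownames(fps)
  labels
}
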