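#' Synthetic inputs with planted truth
#'
#' The generators in this module emulate every input the analysis pipeline
#' consumes: expression matrices (microarray-like intensities or RNA-Seq-like
#' counts), per-network-type functional gene-pair weight tables, GMT pathway
#' definitions and a drug library with fingerprints, physicochemical
#' descriptors, repurposing scores and clinical-trial failure records. Each
#' generator is fully determined by its seed, and the planted truth (which
#' genes are differentially expressed, which pathways carry them, how drugs
#' cluster structurally) is returned alongside the data so downstream stages
#' can be tested for recovery.
#'
#' @name synthdata
NULL

new_synthetic_truth <- function(de_genes = NULL, pathways = character(0),
                                drug_clusters = NULL, seed = NA_integer_) {
  structure(list(planted_de_genes = de_genes,
                 planted_pathways = pathways,
                 planted_drug_clusters = drug_clusters,
                 seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth (seed ", x$seed, ")\n", sep = "")
  cat("  planted DE genes: ", NROW(x$planted_de_genes), "\n", sep = "")
  cat("  planted pathways: ", length(x$planted_pathways), "\n", sep = "")
  if (!is.null(x$planted_drug_clusters))
    cat("  planted drug clusters: ",
        length(unique(x$planted_drug_clusters)), "\n", sep = "")
  invisible(x)
}

#' Write / read a planted-truth record as YAML
#'
#' One truth file accompanies every generated bundle so recovery tests can
#' assert against it without re-deriving the planted signal.
#'
#' @param truth a `synthetic_truth` object.
#' @param path file path.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obj <- list(
    seed = truth$seed,
    planted_pathways = as.list(truth$planted_pathways),
    planted_de_genes = if (is.null(truth$planted_de_genes)) list() else
      lapply(seq_len(nrow(truth$planted_de_genes)), function(i)
        as.list(truth$planted_de_genes[i, , drop = FALSE])),
    planted_drug_clusters = if (is.null(truth$planted_drug_clusters)) list()
      else as.list(truth$planted_drug_clusters))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  de <- if (length(obj$planted_de_genes))
    do.call(rbind, lapply(obj$planted_de_genes, as.data.frame)) else NULL
  clusters <- if (length(obj$planted_drug_clusters))
    unlist(obj$planted_drug_clusters) else NULL
  new_synthetic_truth(de, unlist(obj$planted_pathways) %||% character(0),
                      clusters, obj$seed)
}

#' Generate a synthetic expression dataset with planted DE genes
#'
#' Intensity data mimic log2-scale microarray values: a per-gene baseline
#' drawn from N(7, 1.5^2) plus i.i.d. Gaussian noise. Count data follow a
#' negative binomial model (gamma-Poisson) with log-uniform per-sample
#' library sizes spanning a 4-fold range, mirroring the RNA composition
#' effects that make TMM factors matter. A fraction `frac_de` of genes is
#' planted as differentially expressed: shifted by `effect_size` log2 units
#' in the case group (direction drawn at random unless supplied).
#'
#' @param n_genes number of genes (>= 10).
#' @param n_case,n_control samples per group (each >= 2).
#' @param platform `"intensity"` (microarray-like, log2 scale) or
#'   `"counts"` (RNA-Seq-like raw counts).
#' @param effect_size planted shift in log2 units.
#' @param noise_sd intensity noise standard deviation (log2 scale); for
#'   counts, biological noise is governed by `bcv` instead.
#' @param frac_de fraction of genes planted as differentially expressed
#'   (ignored when `de_genes` is supplied).
#' @param seed integer seed; fully determines the output.
#' @param gene_ids optional gene id vector (defaults to `g0001`...).
#' @param de_genes optional data.frame (gene, direction) fixing the planted
#'   set, as used by [generate_bundle()] to tie DE genes to pathways.
#' @param lib_size_range range of expected library sizes for counts.
#' @param bcv biological coefficient of variation for the count model.
#' @return A list with `matrix` (genes x samples), `groups` (data.frame of
#'   sample and group) and `truth` (a `synthetic_truth`).
#' @export
generate_expression_dataset <- function(n_genes = 1000, n_case = 10,
                                        n_control = 10,
                                        platform = c("intensity", "counts"),
                                        effect_size = 2, noise_sd = 0.25,
                                        frac_de = 0.05, seed = 1,
                                        gene_ids = NULL, de_genes = NULL,
                                        lib_size_range = c(5e5, 2e6),
                                        bcv = 0.2) {
  platform <- match.arg(platform)
  assert_that(n_genes >= 10, "n_genes must be >= 10")
  assert_that(n_case >= 2 && n_control >= 2,
              "each group needs at least 2 samples")
  assert_that(frac_de >= 0 && frac_de <= 1, "frac_de must lie in [0, 1]")
  set.seed(seed)

  gene_ids <- gene_ids %||% sprintf("g%04d", seq_len(n_genes))
  assert_that(length(gene_ids) == n_genes, "gene_ids length mismatch")
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_control)))
  groups <- data.frame(sample = samples,
                       group = rep(c("case", "control"), c(n_case, n_control)),
                       stringsAsFactors = FALSE)

  if (is.null(de_genes)) {
    n_de <- round(frac_de * n_genes)
    de_genes <- if (n_de > 0)
      data.frame(gene = sample(gene_ids, n_de),
                 direction = sample(c("over", "under"), n_de, replace = TRUE),
                 stringsAsFactors = FALSE)
    else NULL
  } else {
    assert_that(all(de_genes$gene %in% gene_ids),
                "planted genes must lie in the gene universe")
  }
  shift <- numeric(n_genes)
  names(shift) <- gene_ids
  if (!is.null(de_genes))
    shift[de_genes$gene] <- ifelse(de_genes$direction == "over",
                                   effect_size, -effect_size)

  n_s <- n_case + n_control
  if (platform == "intensity") {
    base <- stats::rnorm(n_genes, mean = 7, sd = 1.5)
    m <- base + matrix(stats::rnorm(n_genes * n_s, sd = noise_sd),
                       n_genes, n_s)
    m[, seq_len(n_case)] <- m[, seq_len(n_case)] + shift
  } else {
    rel <- exp(stats::rnorm(n_genes, mean = 3, sd = 1.2))
    rel <- rel / sum(rel)
    lib <- exp(stats::runif(n_s, log(lib_size_range[1]),
                            log(lib_size_range[2])))
    mu <- outer(rel, lib)
    mu[, seq_len(n_case)] <- mu[, seq_len(n_case)] * 2^shift
    disp <- bcv^2
    m <- matrix(stats::rpois(n_genes * n_s,
                             lambda = mu * stats::rgamma(n_genes * n_s,
                                                         shape = 1 / disp,
                                                         scale = disp)),
                n_genes, n_s)
  }
  dimnames(m) <- list(gene_ids, samples)

  truth <- new_synthetic_truth(
    de_genes = if (is.null(de_genes)) NULL else
      data.frame(de_genes, effect_size = effect_size,
                 stringsAsFactors = FALSE),
    seed = seed)
  list(matrix = m, groups = groups, truth = truth)
}

# unrank k-th unordered pair (1-based, row-major over i < j) for n items
unrank_pairs <- function(k, n) {
  csum <- cumsum(seq(n - 1, 1))
  i <- findInterval(k - 0.5, c(0, csum))
  j <- i + (k - c(0, csum)[i])
  cbind(i, j)
}

#' Generate per-network-type functional gene-pair records
#'
#' Emulates the per-type normalized edge-weight export of a functional gene
#' network service: for each network type, a `density` fraction of all
#' unordered gene pairs receives a weight in (0, 1]. Pairs are stored once
#' (undirected semantics, `gene_a` < `gene_b` lexically) with at most one
#' row per (pair, type).
#'
#' @param genes character vector of gene ids.
#' @param n_types number of network types (defaults to the first
#'   `n_types` of co-expression, physical, pathways).
#' @param density fraction of pairs connected per type, in (0, 1].
#' @param seed integer seed.
#' @param types optional type names overriding the defaults.
#' @return data.frame with columns gene_a, gene_b, network_type, weight.
#' @export
generate_functional_records <- function(genes, n_types = 3, density = 0.05,
                                        seed = 1, types = NULL) {
  assert_that(density > 0 && density <= 1, "density must lie in (0, 1]")
  n <- length(genes)
  assert_that(n >= 2, "need at least 2 genes")
  set.seed(seed)
  default_types <- c("co-expression", "physical", "pathways")
  types <- types %||% if (n_types <= 3) default_types[seq_len(n_types)] else
    c(default_types, sprintf("type%02d", seq_len(n_types - 3)))
  genes <- sort(genes)
  npairs <- n * (n - 1) / 2
  m <- max(1L, round(density * npairs))
  out <- lapply(types, function(tp) {
    ij <- unrank_pairs(sort(sample(npairs, m)), n)
    data.frame(gene_a = genes[ij[, 1]], gene_b = genes[ij[, 2]],
               network_type = tp,
               weight = stats::runif(m, min = 1e-6, max = 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate GMT-style pathway definitions
#'
#' Each pathway receives between `size_range[1]` and `size_range[2]` member
#' genes: a private core drawn from a reserved disjoint block plus a
#' fraction `overlap_factor` of slots drawn uniformly from the remaining
#' gene universe. With `overlap_factor = 0` pathways are pairwise
#' disjoint; raising the factor raises the expected shared-gene count
#' between pathway pairs roughly as `(s * overlap_factor)^2 / |universe|`,
#' which at the defaults keeps the downstream pathway network connected
#' without concentrating overlap on a few hub pathways.
#'
#' @param genes gene universe (character).
#' @param n_pathways number of pathways.
#' @param size_range integer range of member counts; lower bound >= 2.
#' @param overlap_factor fraction in [0, 1] of slots drawn from the shared
#'   universe.
#' @param seed integer seed.
#' @return Named list of member-gene character vectors.
#' @export
generate_pathway_definitions <- function(genes, n_pathways = 50,
                                         size_range = c(10, 30),
                                         overlap_factor = 0.7, seed = 1) {
  assert_that(size_range[1] >= 2, "pathways need at least 2 member genes")
  assert_that(overlap_factor >= 0 && overlap_factor <= 1,
              "overlap_factor must lie in [0, 1]")
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_pathways,
                  replace = TRUE)
  ids <- sprintf("P%03d", seq_len(n_pathways))
  cores <- round(sizes * (1 - overlap_factor))
  assert_that(sum(cores) <= length(genes),
              "gene universe too small for the private pathway cores")
  core_block <- sample(genes, sum(cores))
  shared_pool <- setdiff(genes, core_block)
  stops <- cumsum(cores)
  starts <- c(1, utils::head(stops, -1) + 1)
  sets <- lapply(seq_len(n_pathways), function(i) {
    core <- if (cores[i] > 0) core_block[starts[i]:stops[i]] else character(0)
    n_sh <- sizes[i] - cores[i]
    shared <- if (n_sh > 0) sample(shared_pool, n_sh) else character(0)
    c(core, shared)
  })
  names(sets) <- ids
  sets
}

#' Fingerprint bit-string helpers
#'
#' Fingerprints are serialized as strings of 0/1 characters and handled
#' internally as 0/1 integer matrices (one row per compound).
#'
#' @param strings character vector of 0/1 strings.
#' @param mat 0/1 integer matrix, one fingerprint per row.
#' @name fingerprints
NULL

#' @rdname fingerprints
#' @export
fp_to_matrix <- function(strings) {
  lens <- nchar(strings)
  assert_that(length(unique(lens)) == 1L,
              "fingerprint lengths differ across the library")
  m <- do.call(rbind, lapply(strsplit(strings, "", fixed = TRUE), as.integer))
  rownames(m) <- names(strings)
  m
}

#' @rdname fingerprints
#' @export
fp_to_string <- function(mat) {
  apply(mat, 1, paste, collapse = "")
}

#' Generate a synthetic drug library with planted structural clusters
#'
#' Fingerprints are generated directly as bit vectors around `n_clusters`
#' random prototypes (each bit flipped with a small probability), so that
#' within-cluster Tanimoto similarity is high (>= 0.7 in expectation) and
#' between-cluster similarity low (< 0.5). Physicochemical descriptors, two
#' per-experiment repurposing score tables (a connectivity-score table in
#' [-100, 100] and a fixed-size inclusion list emulating a reverse-signature
#' query) and a clinical-trial failure table accompany the library. One
#' failed drug can be planted structurally inside the first candidate
#' cluster to exercise the failure-similarity screen.
#'
#' @param n_drugs number of candidate drugs.
#' @param fp_bits fingerprint length (>= 32).
#' @param n_clusters number of planted structural clusters.
#' @param n_failed number of failed drugs (< n_drugs).
#' @param seed integer seed.
#' @param n_experiments number of repurposing experiments per table.
#' @param flip_prob per-bit flip probability around the cluster prototype.
#' @param cluster_sizes optional integer vector summing to `n_drugs`.
#' @param gene_universe optional gene ids to draw drug targets from.
#' @param targets_per_drug number of gene targets per drug.
#' @param l1000_n entries kept per inclusion-list experiment.
#' @param plant_failed_near if TRUE, the first failed drug is a structural
#'   near-duplicate of cluster 1.
#' @return A list with `drugs` (data.frame), `cmap_scores`, `l1000`,
#'   `failed` (status table), `failed_fps` (named fingerprint strings) and
#'   `truth` (a `synthetic_truth` carrying the planted cluster labels).
#' @export
generate_drug_library <- function(n_drugs = 60, fp_bits = 128, n_clusters = 3,
                                  n_failed = 8, seed = 1, n_experiments = 3,
                                  flip_prob = 0.04, cluster_sizes = NULL,
                                  gene_universe = NULL, targets_per_drug = 2,
                                  l1000_n = 50, plant_failed_near = TRUE) {
  assert_that(fp_bits >= 32, "fp_bits must be >= 32")
  assert_that(n_failed < n_drugs, "n_failed must be < n_drugs")
  if (is.null(cluster_sizes)) {
    cluster_sizes <- rep(n_drugs %/% n_clusters, n_clusters)
    cluster_sizes[seq_len(n_drugs %% n_clusters)] <-
      cluster_sizes[seq_len(n_drugs %% n_clusters)] + 1L
  }
  assert_that(sum(cluster_sizes) == n_drugs && length(cluster_sizes) == n_clusters,
              "inconsistent cluster sizes")
  set.seed(seed)

  ids <- sprintf("D%03d", seq_len(n_drugs))
  labels <- rep(seq_len(n_clusters), cluster_sizes)
  # block-structured prototypes: each chemical family is dense on its own
  # stretch of the fingerprint, keeping families well separated
  block <- rep(seq_len(n_clusters), length.out = fp_bits)
  protos <- t(vapply(seq_len(n_clusters), function(k)
    stats::rbinom(fp_bits, 1, ifelse(block == k, 0.8, 0.08)),
    integer(fp_bits)))
  fps <- protos[labels, , drop = FALSE]
  flips <- matrix(stats::rbinom(n_drugs * fp_bits, 1, flip_prob),
                  n_drugs, fp_bits)
  fps <- abs(fps - flips)
  rownames(fps) <- ids

  drugs <- data.frame(
    drug_id = ids,
    fingerprint = fp_to_string(fps),
    MW = round(stats::runif(n_drugs, 150, 650), 1),
    cLogP = round(stats::runif(n_drugs, -2, 7), 2),
    HBD = sample(0:8, n_drugs, replace = TRUE),
    HBA = sample(0:14, n_drugs, replace = TRUE),
    RotB = sample(0:14, n_drugs, replace = TRUE),
    TPSA = round(stats::runif(n_drugs, 20, 180), 1),
    functional_association = round(stats::runif(n_drugs), 3),
    binding_affinity = round(stats::runif(n_drugs), 3),
    stringsAsFactors = FALSE)
  if (!is.null(gene_universe))
    drugs$targets <- vapply(seq_len(n_drugs), function(i)
      paste(sample(gene_universe, targets_per_drug), collapse = ","),
      character(1))

  cmap_scores <- do.call(rbind, lapply(seq_len(n_experiments), function(e)
    data.frame(drug_id = ids, experiment = sprintf("exp%02d", e),
               score = round(stats::runif(n_drugs, -100, 100), 2),
               stringsAsFactors = FALSE)))
  l1000 <- do.call(rbind, lapply(seq_len(n_experiments), function(e) {
    keep <- sample(ids, min(l1000_n, n_drugs))
    data.frame(drug_id = keep, experiment = sprintf("exp%02d", e),
               stringsAsFactors = FALSE)
  }))

  failed_ids <- sprintf("FAIL%02d", seq_len(n_failed))
  failed_fps <- matrix(stats::rbinom(n_failed * fp_bits, 1, 0.3),
                       n_failed, fp_bits)
  if (plant_failed_near && n_failed >= 1) {
    flips1 <- stats::rbinom(fp_bits, 1, flip_prob)
    failed_fps[1, ] <- abs(protos[1, ] - flips1)
  }
  rownames(failed_fps) <- failed_ids
  failed <- data.frame(
    drug_id = failed_ids, disease = "fibrosis",
    status = sample(c("Suspended", "Terminated", "Withdrawn"), n_failed,
                    replace = TRUE),
    stringsAsFactors = FALSE)

  names(labels) <- ids
  truth <- new_synthetic_truth(drug_clusters = labels, seed = seed)
  list(drugs = drugs, cmap_scores = cmap_scores, l1000 = l1000,
       failed = failed, failed_fps = fp_to_string(failed_fps), truth = truth)
}

# Choose the planted pathway set: a mutually overlapping triple (or
# n-tuple) of pathways that are not topology-favored. Functionally
# related pathways perturbed by one disease share member genes, so the
# planted set is drawn from tuples whose pairwise shared-gene count is
# >= 2 (falling back to >= 1, then to unconstrained sampling when the
# generated universe offers no such tuple); pathways in the top-5% by
# betweenness or degree are excluded so that recovering the planted set
# reflects gene-map guidance rather than network topology.
sample_planted_pathways <- function(pathways, n_planted) {
  net <- build_pathway_network(pathways)
  topo <- topology_profile(net)
  top_strength <- topo$pathway[order(-topo$strength,
                                     topo$pathway)][
    seq_len(ceiling(0.05 * nrow(topo)))]
  eligible <- topo$pathway[!topo$top_betweenness & !topo$top_degree &
                             !topo$pathway %in% top_strength]
  for (min_w in c(2, 1)) {
    g <- igraph::subgraph_from_edges(
      net$graph, igraph::E(net$graph)[igraph::E(net$graph)$weight >= min_w],
      delete.vertices = FALSE)
    g <- igraph::induced_subgraph(g, eligible)
    if (n_planted == 3) {
      tri <- matrix(igraph::triangles(g), nrow = 3)
      if (ncol(tri)) {
        pick <- tri[, sample.int(ncol(tri), 1)]
        return(sort(igraph::V(g)$name[pick]))
      }
    } else {
      # general n: greedy clique-ish draw from the densest neighborhoods
      cl <- igraph::largest_cliques(g)
      cl <- cl[lengths(cl) >= n_planted]
      if (length(cl)) {
        pick <- cl[[sample.int(length(cl), 1)]]
        return(sort(sample(igraph::V(g)$name[pick], n_planted)))
      }
    }
  }
  sort(sample(eligible, n_planted))
}

#' Generate a complete synthetic study bundle
#'
#' Ties the individual generators into one internally consistent study:
#' a gene universe, pathway definitions with `n_planted` planted pathways,
#' an expression dataset whose planted DE genes are drawn from the planted
#' pathways' members, functional gene-pair records over the whole universe
#' (subset to the recovered signature downstream, mirroring how a gene-list
#' query drives the functional network service), and a drug library whose
#' first drugs target planted-pathway genes so the drug-target-pathway
#' linkage has signal.
#'
#' @param seed integer master seed; stage seeds are derived with
#'   [derive_seed()].
#' @param n_genes,n_pathways,n_planted,de_per_pathway study dimensions.
#' @param n_case,n_control,effect_size,noise_sd passed to
#'   [generate_expression_dataset()].
#' @param platform expression platform.
#' @param density functional-record density per network type.
#' @param n_drugs,n_failed drug library dimensions.
#' @return A list with elements `expression` (matrix, groups, truth),
#'   `pathways`, `records`, `drugs` and `truth` (merged).
#' @export
generate_bundle <- function(seed = 1, n_genes = 1000, n_pathways = 50,
                            n_planted = 3, de_per_pathway = 15,
                            n_case = 10, n_control = 10, effect_size = 2,
                            noise_sd = 0.25,
                            platform = c("intensity", "counts"),
                            density = 0.02, n_drugs = 60, n_failed = 8,
                            size_range = c(20, 40), overlap_factor = 1) {
  platform <- match.arg(platform)
  genes <- sprintf("g%04d", seq_len(n_genes))
  pathways <- generate_pathway_definitions(genes, n_pathways = n_pathways,
                                           size_range = size_range,
                                           overlap_factor = overlap_factor,
                                           seed = derive_seed(seed, 1))
  set.seed(derive_seed(seed, 2))
  planted <- sample_planted_pathways(pathways, n_planted)
  # perturb pathway-specific members: genes shared with unplanted
  # pathways would spread guidance to them, so each planted pathway
  # contributes its least-shared members first (exclusive genes, then
  # genes shared only within the planted set, then the rest)
  unplanted_members <- table(unlist(pathways[setdiff(names(pathways),
                                                     planted)]))
  all_members <- table(unlist(pathways))
  de_genes <- unique(unlist(lapply(planted, function(pw) {
    mem <- pathways[[pw]]
    n_out <- as.vector(unplanted_members[mem])
    n_out[is.na(n_out)] <- 0L
    ord <- order(n_out, as.vector(all_members[mem]),
                 stats::runif(length(mem)))
    mem[ord][seq_len(min(de_per_pathway, length(mem)))]
  })))
  de <- data.frame(gene = de_genes,
                   direction = sample(c("over", "under"), length(de_genes),
                                      replace = TRUE),
                   stringsAsFactors = FALSE)
  expr <- generate_expression_dataset(
    n_genes = n_genes, n_case = n_case, n_control = n_control,
    platform = platform, effect_size = effect_size, noise_sd = noise_sd,
    seed = derive_seed(seed, 3), gene_ids = genes, de_genes = de)
  records <- generate_functional_records(genes, density = density,
                                         seed = derive_seed(seed, 4))
  # disease genes are mutually co-regulated: overlay a dense block of
  # strong co-expression records among the planted DE genes, as a
  # functional-network query over a disease gene list would report
  extra <- generate_functional_records(de$gene, n_types = 1,
                                       density = 0.4,
                                       seed = derive_seed(seed, 7))
  extra$weight <- stats::runif(nrow(extra), 0.5, 1)
  pair_key <- function(d) paste(pmin(d$gene_a, d$gene_b),
                                pmax(d$gene_a, d$gene_b), d$network_type)
  records <- rbind(records[!pair_key(records) %in% pair_key(extra), ],
                   extra)
  drugs <- generate_drug_library(n_drugs = n_drugs, n_failed = n_failed,
                                 seed = derive_seed(seed, 5),
                                 gene_universe = genes)
  # point some drugs at planted-pathway genes so linkage stages see signal
  set.seed(derive_seed(seed, 6))
  planted_members <- unique(unlist(pathways[planted]))
  n_link <- min(10L, nrow(drugs$drugs))
  drugs$drugs$targets[seq_len(n_link)] <- vapply(seq_len(n_link), function(i)
    paste(sample(planted_members, 2), collapse = ","), character(1))

  truth <- new_synthetic_truth(de_genes = expr$truth$planted_de_genes,
                               pathways = planted,
                               drug_clusters = drugs$truth$planted_drug_clusters,
                               seed = seed)
  list(expression = expr, pathways = pathways, records = records,
       drugs = drugs, truth = truth)
}
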