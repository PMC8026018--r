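#' Pipeline configuration and end-to-end orchestration
#'
#' `default_config()` collects every tunable threshold of the pipeline
#' with its canonical default: DE significance alpha = .05, top 150 genes
#' per direction, CPM >= 1 in >= 2 libraries, connectivity-score cutoff
#' -50, odds ratio > 1.3, top 5% of walk results, similarity thresholds
#' 0.5 (base) / 0.7 (failed-drug attachment), Ward cut height 1.0 and the
#' >= 2 key-pathway prioritization rule. Configurations round-trip
#' losslessly through YAML, and per-stage seeds are derived from the
#' master seed with [derive_seed()] so stages can be rerun independently.
#'
#' @name pipeline
NULL

#' @rdname pipeline
#' @param seed master seed.
#' @param n_iterations walk iterations per execution.
#' @return `default_config()`: a named list of settings.
#' @export
default_config <- function(seed = 1, n_iterations = 5e4) {
  list(
    seed = as.integer(seed),
    alpha = 0.05,
    top_n = 150L,
    min_cpm = 1,
    min_libs = 2L,
    cmap_threshold = -50,
    or_threshold = 1.3,
    top_frac = 0.05,
    base_similarity = 0.5,
    attach_similarity = 0.7,
    ward_threshold = 1.0,
    min_key = 2L,
    n_iterations = as.integer(n_iterations),
    synth = list(n_genes = 1000L, n_pathways = 50L, n_planted = 3L,
                 n_case = 10L, n_control = 10L, effect_size = 2,
                 noise_sd = 0.25, density = 0.02, n_drugs = 60L,
                 n_failed = 8L))
}

#' @rdname pipeline
#' @param config configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname pipeline
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ints <- c("seed", "top_n", "min_libs", "min_key", "n_iterations")
  for (f in ints) cfg[[f]] <- as.integer(cfg[[f]])
  for (f in c("n_genes", "n_pathways", "n_planted", "n_case", "n_control",
              "n_drugs", "n_failed"))
    cfg$synth[[f]] <- as.integer(cfg$synth[[f]])
  cfg
}

# polynomial rolling hash of the YAML serialization, for provenance stamps
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(config))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% (2^31 - 1)
  sprintf("%08x", h)
}

#' Run the full pipeline on a synthetic bundle
#'
#' Executes the stages in order: synthesis, differential expression and
#' signature extraction, gene map and pathway network construction,
#' guided and random walk executions, odds-ratio significance, drug
#' candidate filtering and re-ranking, structural screening against
#' failed drugs, and drug-target-pathway integration. When `out_dir` is
#' given, every stage output is written there as TSV together with a
#' machine-readable `summary.json` stamped with the configuration hash
#' and seed; a rerun with the same configuration produces identical
#' files.
#'
#' @param config configuration list from [default_config()].
#' @param out_dir optional output directory (created if missing).
#' @return A list with the stage outputs and a `summary` list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seed <- config$seed
  bundle <- generate_bundle(
    seed = seed,
    n_genes = config$synth$n_genes, n_pathways = config$synth$n_pathways,
    n_planted = config$synth$n_planted, n_case = config$synth$n_case,
    n_control = config$synth$n_control,
    effect_size = config$synth$effect_size,
    noise_sd = config$synth$noise_sd, density = config$synth$density,
    n_drugs = config$synth$n_drugs, n_failed = config$synth$n_failed)

  de <- normalize_and_test(bundle$expression$matrix,
                           bundle$expression$groups,
                           platform = "intensity", log2_state = "log2")
  signature <- extract_signature(de, alpha = config$alpha,
                                 top_n = config$top_n,
                                 disease = "synthetic")
  if (nrow(signature$over) + nrow(signature$under) == 0)
    warning("empty signature at alpha = ", config$alpha,
            "; downstream guidance falls back to random targets",
            call. = FALSE)
  sig_genes <- union(signature$over$gene, signature$under$gene)

  rec <- bundle$records
  rec <- rec[rec$gene_a %in% sig_genes & rec$gene_b %in% sig_genes, ,
             drop = FALSE]
  gene_map <- if (length(sig_genes))
    build_gene_map(rec, genes = sig_genes) else NULL
  pw_net <- build_pathway_network(bundle$pathways)
  membership <- membership_from_pathways(bundle$pathways)
  topo <- topology_profile(pw_net, top_frac = config$top_frac)

  guided_possible <- length(sig_genes) > 0 &&
    any(vapply(membership[intersect(sig_genes, names(membership))],
               length, integer(1)) > 0)
  guided <- if (guided_possible)
    run_pathwalks(pw_net, gene_map, membership,
                  n_iterations = config$n_iterations, mode = "guided",
                  seed = derive_seed(seed, 11))
  else run_pathwalks(pw_net, n_iterations = config$n_iterations,
                     mode = "random", seed = derive_seed(seed, 11))
  random <- run_pathwalks(pw_net, n_iterations = config$n_iterations,
                          mode = "random", seed = derive_seed(seed, 12))
  significance <- pathway_significance(guided, random, topology = topo,
                                       or_threshold = config$or_threshold,
                                       alpha = config$alpha)
  highlighted <- top_pathways(guided, frac = config$top_frac)
  keys <- key_pathways(highlighted, significance, topo)

  candidates <- filter_inhibitors(bundle$drugs$cmap_scores,
                                  bundle$drugs$l1000,
                                  threshold = config$cmap_threshold)
  drug_tab <- bundle$drugs$drugs
  drug_tab <- drug_tab[drug_tab$drug_id %in% candidates$drug_id, ,
                       drop = FALSE]
  drug_tab$drugability <- drugability_score(drug_tab)
  ranked <- composite_rank(drug_tab)
  fps <- fp_to_matrix(stats::setNames(ranked$fingerprint, ranked$drug_id))
  clusters <- cluster_structures(fps)
  rerank <- select_representatives(ranked, clusters)

  simnet <- build_similarity_network(fps,
                                     fp_to_matrix(bundle$drugs$failed_fps),
                                     base_threshold = config$base_similarity,
                                     attach_threshold = config$attach_similarity)
  flags <- flag_failed_similar(simnet)
  ward <- ward_cluster(fps, threshold = config$ward_threshold)

  targets <- strsplit(stats::setNames(ranked$targets, ranked$drug_id), ",")
  linkage <- drug_target_pathway_linkage(targets, bundle$pathways,
                                         highlighted, keys,
                                         min_key = config$min_key)

  summary <- list(
    config_hash = config_hash(config),
    seed = seed,
    n_signature_genes = length(sig_genes),
    planted_pathways = bundle$truth$planted_pathways,
    highlighted_pathways = highlighted,
    planted_in_top = all(bundle$truth$planted_pathways %in% highlighted),
    key_pathways = keys,
    n_candidates = nrow(ranked),
    n_clusters = length(unique(clusters)),
    n_flagged = nrow(flags),
    prioritized_drugs = linkage$prioritized,
    walk_convergence_l1 = guided$convergence_l1)

  out <- list(bundle = bundle, de = de, signature = signature,
              gene_map = gene_map, pathway_network = pw_net,
              topology = topo, guided = guided, random = random,
              significance = significance, highlighted = highlighted,
              key_pathways = keys, rerank = rerank, clusters = clusters,
              similarity_network = simnet, flags = flags, ward = ward,
              linkage = linkage, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_tsv(bundle$expression$matrix,
                         file.path(out_dir, "expression.tsv"))
    write_tsv(bundle$expression$groups, file.path(out_dir, "groups.tsv"))
    write_gmt(bundle$pathways, file.path(out_dir, "pathways.gmt"))
    write_tsv(de, file.path(out_dir, "de_results.tsv"))
    write_tsv(significance, file.path(out_dir, "pathway_significance.tsv"))
    wf <- data.frame(pathway = names(guided$times_walked),
                     count = as.integer(guided$times_walked),
                     frequency = as.numeric(guided$times_walked) /
                       guided$total_times_walked)
    write_tsv(wf, file.path(out_dir, "walk_counts_guided.tsv"))
    write_tsv(guided$edge_visits, file.path(out_dir, "edge_visits.tsv"))
    write_tsv(rerank, file.path(out_dir, "rerank.tsv"))
    write_tsv(simnet$edges, file.path(out_dir, "similarity_edges.tsv"))
    write_tsv(simnet$nodes, file.path(out_dir, "similarity_nodes.tsv"))
    write_tsv(linkage$linkage, file.path(out_dir, "linkage.tsv"))
    write_truth_yaml(bundle$truth, file.path(out_dir, "truth.yaml"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
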