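test_that("expression generator is deterministic and respects frac_de", {
  a <- generate_expression_dataset(n_genes = 50, n_case = 3, n_control = 3,
                                   seed = 7)
  b <- generate_expression_dataset(n_genes = 50, n_case = 3, n_control = 3,
                                   seed = 7)
  expect_identical(a, b)

  none <- generate_expression_dataset(n_genes = 50, n_case = 4,
                                      n_control = 4, frac_de = 0, seed = 3)
  expect_null(none$truth$planted_de_genes)
  gm <- rowMeans(none$matrix[, none$groups$group == "case"]) -
    rowMeans(none$matrix[, none$groups$group == "control"])
  expect_lt(max(abs(gm)), 1)  # noise-only differences at noise_sd = 0.25
})

test_that("planted genes are recovered with high power", {
  hits <- vapply(1:20, function(s) {
    d <- generate_expression_dataset(n_genes = 200, n_case = 10,
                                     n_control = 10, effect_size = 2,
                                     noise_sd = 0.1, frac_de = 0.1,
                                     seed = s)
    de <- normalize_and_test(d$matrix, d$groups, platform = "intensity")
    mean(de$p[match(d$truth$planted_de_genes$gene, de$gene)] < 0.05)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("count matrices are NB-like with library sizes in range", {
  d <- generate_expression_dataset(n_genes = 300, n_case = 5, n_control = 5,
                                   platform = "counts", seed = 11,
                                   lib_size_range = c(5e5, 2e6))
  expect_true(all(d$matrix >= 0))
  expect_true(all(d$matrix == round(d$matrix)))
  cs <- colSums(d$matrix)
  # library sizes concentrate around the configured expected range
  expect_true(all(cs > 5e5 / 2 & cs < 2e6 * 2))
  expect_error(generate_expression_dataset(n_genes = 5),
               "n_genes")
  expect_error(generate_expression_dataset(n_case = 1), "2 samples")
})

test_that("functional records form a valid undirected weighted table", {
  genes <- c("g3", "g1", "g2")
  r <- generate_functional_records(genes, n_types = 1, density = 1,
                                   seed = 1)
  expect_equal(nrow(r), 3)  # complete graph on 3 genes
  expect_true(all(r$gene_a < r$gene_b))
  expect_true(all(r$weight > 0 & r$weight <= 1))

  r2 <- generate_functional_records(sprintf("g%02d", 1:12), n_types = 3,
                                    density = 0.4, seed = 5)
  key <- paste(r2$gene_a, r2$gene_b, r2$network_type)
  expect_false(anyDuplicated(key) > 0)
  expect_identical(r2, generate_functional_records(sprintf("g%02d", 1:12),
                                                   n_types = 3,
                                                   density = 0.4, seed = 5))
  expect_error(generate_functional_records(genes, density = 0), "density")
})

test_that("pathway definitions honour disjointness and determinism", {
  genes <- sprintf("g%03d", 1:400)
  dis <- generate_pathway_definitions(genes, n_pathways = 10,
                                      size_range = c(5, 10),
                                      overlap_factor = 0, seed = 2)
  all_members <- unlist(dis)
  expect_equal(length(all_members), length(unique(all_members)))

  ov <- generate_pathway_definitions(genes, n_pathways = 10,
                                     size_range = c(10, 20),
                                     overlap_factor = 0.8, seed = 2)
  expect_true(all(lengths(ov) >= 2))
  expect_identical(ov, generate_pathway_definitions(genes, n_pathways = 10,
                                                    size_range = c(10, 20),
                                                    overlap_factor = 0.8,
                                                    seed = 2))
  expect_error(generate_pathway_definitions(genes, size_range = c(1, 5)),
               "at least 2")
})

test_that("drug library plants separated structural clusters", {
  lib <- generate_drug_library(n_drugs = 30, fp_bits = 128, n_clusters = 3,
                               n_failed = 5, seed = 4)
  expect_identical(lib, generate_drug_library(n_drugs = 30, fp_bits = 128,
                                              n_clusters = 3, n_failed = 5,
                                              seed = 4))
  fps <- fp_to_matrix(stats::setNames(lib$drugs$fingerprint,
                                      lib$drugs$drug_id))
  S <- tanimoto_matrix(fps)
  lab <- lib$truth$planted_drug_clusters
  same <- outer(lab, lab, "==")
  off <- upper.tri(S)
  expect_gt(mean(S[off & same]), 0.7)
  expect_lt(mean(S[off & !same]), 0.5)
  expect_true(all(lib$cmap_scores$score >= -100 & lib$cmap_scores$score <= 100))
  expect_true(all(lib$failed$status %in%
                    c("Suspended", "Terminated", "Withdrawn")))
  expect_error(generate_drug_library(n_drugs = 10, cluster_sizes = c(4, 4)),
               "inconsistent cluster sizes")
})

test_that("bundle ties planted DE genes to planted pathways", {
  b <- generate_bundle(seed = 3, n_genes = 400, n_pathways = 15,
                       n_planted = 2, n_drugs = 20, n_failed = 4)
  planted_members <- unique(unlist(b$pathways[b$truth$planted_pathways]))
  expect_true(all(b$truth$planted_de_genes$gene %in% planted_members))
  expect_true(all(b$truth$planted_pathways %in% names(b$pathways)))
  expect_identical(b$truth$seed, 3)
})

test_that("truth records round-trip through YAML", {
  b <- generate_bundle(seed = 5, n_genes = 300, n_pathways = 10,
                       n_planted = 2, n_drugs = 12, n_failed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth_yaml(b$truth, path)
  back <- read_truth_yaml(path)
  expect_equal(back$planted_pathways, b$truth$planted_pathways)
  expect_equal(back$seed, b$truth$seed)
  expect_equal(sort(back$planted_de_genes$gene),
               sort(b$truth$planted_de_genes$gene))
})
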