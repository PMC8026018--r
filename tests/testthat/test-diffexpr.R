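test_that("quantile normalization equalizes column distributions", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  qn <- quantile_normalize(m)
  # sorted-row means of columns (1,2,3) and (4,5,6) are (2.5, 3.5, 4.5)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))
  expect_equal(dimnames(qn), dimnames(m))

  set.seed(42)
  r <- matrix(rnorm(60), ncol = 4)
  rn <- quantile_normalize(r)
  for (j in 2:4) expect_equal(sort(rn[, 1]), sort(rn[, j]))
  expect_equal(quantile_normalize(rn), rn)  # idempotent

  same <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(unname(quantile_normalize(same)), unname(same))
  expect_error(quantile_normalize(matrix(1:3, ncol = 1)), "2 columns")
})

test_that("normalize_and_test matches Welch test gene by gene", {
  set.seed(8)
  m <- matrix(rnorm(200, mean = 7), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  groups <- data.frame(sample = colnames(m),
                       group = rep(c("case", "control"), each = 5))
  de <- normalize_and_test(m, groups, platform = "intensity")
  for (g in c("g01", "g07", "g20")) {
    tt <- t.test(m[g, 1:5], m[g, 6:10])
    i <- match(g, de$gene)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$logFC[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  # swapping labels negates every logFC
  swapped <- groups
  swapped$group <- ifelse(groups$group == "case", "control", "case")
  de2 <- normalize_and_test(m, swapped, platform = "intensity")
  expect_equal(de2$logFC, -de$logFC)
  expect_equal(de2$p, de$p)
})

test_that("constant genes give logFC 0 and p 1; planted shifts are detected", {
  m <- matrix(rnorm(80, sd = 0.1) + 5, nrow = 8)
  rownames(m) <- paste0("g", 1:8); colnames(m) <- paste0("s", 1:10)
  m["g1", ] <- 5
  groups <- data.frame(sample = colnames(m),
                       group = rep(c("case", "control"), each = 5))
  de <- normalize_and_test(m, groups, platform = "intensity")
  expect_equal(de$logFC[de$gene == "g1"], 0)
  expect_equal(de$p[de$gene == "g1"], 1)

  set.seed(9)
  d <- generate_expression_dataset(n_genes = 100, n_case = 10,
                                   n_control = 10, effect_size = 2,
                                   noise_sd = 0.1, frac_de = 0.1, seed = 9)
  de2 <- normalize_and_test(d$matrix, d$groups, platform = "intensity")
  planted <- match(d$truth$planted_de_genes$gene, de2$gene)
  expect_true(all(de2$p[planted] < 0.001))
})

test_that("unnormalized log2 input is unlogged, normalized and relogged", {
  set.seed(10)
  base <- matrix(rnorm(60, mean = 8), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  scaled <- base
  scaled[, 1] <- scaled[, 1] + 1.5  # one sample on a shifted scale
  groups <- data.frame(sample = colnames(base),
                       group = rep(c("case", "control"), each = 3))
  de <- normalize_and_test(scaled, groups, platform = "intensity",
                           log2_state = "log2_unnormalized")
  manual <- log2(quantile_normalize(2^scaled))
  sp_case <- rowMeans(manual[, 1:3]); sp_ctrl <- rowMeans(manual[, 4:6])
  expect_equal(de$logFC, unname(sp_case - sp_ctrl), tolerance = 1e-12)
})

test_that("CPM filter applies the per-group library rule", {
  counts <- rbind(
    allzero = c(0, 0, 0, 0),
    both    = c(1, 1, 2, 2),
    one_grp = c(5, 5, 0, 0),
    high    = c(10, 10, 10, 10))
  # library sizes forced to 1e6 so CPM equals the raw count
  filler <- matrix(0, nrow = 1, ncol = 4,
                   dimnames = list("filler", NULL))
  filler[1, ] <- 1e6 - colSums(counts)
  m <- rbind(counts, filler)
  colnames(m) <- paste0("s", 1:4)
  groups <- data.frame(sample = colnames(m),
                       group = rep(c("case", "control"), each = 2))
  kept <- cpm_filter(m, groups, min_cpm = 1, min_libs = 2)
  expect_true("both" %in% rownames(kept))
  expect_true("high" %in% rownames(kept))
  expect_false("allzero" %in% rownames(kept))
  expect_false("one_grp" %in% rownames(kept))  # passes in one group only
  expect_equal(rownames(kept), c("both", "high", "filler"))  # order kept
})

test_that("TMM factors match a step-by-step trimmed-mean computation", {
  set.seed(12)
  counts <- matrix(rnbinom(20 * 4, mu = 100, size = 5) + 1, nrow = 20,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  counts[1:5, 2] <- counts[1:5, 2] * 8  # composition shift on a minority
  f <- tmm_factors(counts)
  expect_equal(unname(f), oracle_tmm(counts), tolerance = 1e-10)
  expect_equal(prod(f)^(1 / length(f)), 1, tolerance = 1e-12)

  # identical libraries and pure depth changes leave factors at 1
  same <- matrix(rep(c(5, 10, 20, 40, 80), 3), ncol = 3,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  expect_equal(unname(tmm_factors(same)), rep(1, 3))
  depth <- same; depth[, 2] <- depth[, 2] * 2
  expect_equal(unname(tmm_factors(depth)), rep(1, 3), tolerance = 1e-10)
})

test_that("signature extraction applies the probe filtering rules in order", {
  de <- data.frame(
    gene  = c("dual", "dual", "dup", "dup", "weak", "up", "down"),
    logFC = c(1, -1, 2, 1.5, 3, 0.5, -2),
    p     = c(0.01, 0.01, 0.01, 0.001, 0.2, 0.04, 0.03))
  sig <- extract_signature(de, alpha = 0.05, top_n = 150)
  expect_false("dual" %in% c(sig$over$gene, sig$under$gene))   # dual-sign
  expect_false("weak" %in% c(sig$over$gene, sig$under$gene))   # p >= alpha
  expect_equal(sig$over$p[sig$over$gene == "dup"], 0.001)       # lowest p
  expect_equal(sig$over$logFC[sig$over$gene == "dup"], 1.5)
  expect_equal(sig$under$gene, "down")

  # duplicate resolution runs after the significance filter: a dual-sign
  # gene whose opposing probe is non-significant is not dual
  de2 <- data.frame(gene = c("a", "a"), logFC = c(1, -1), p = c(0.01, 0.5))
  sig2 <- extract_signature(de2)
  expect_equal(sig2$over$gene, "a")
})

test_that("signatures are capped at top_n ranked by |logFC|", {
  set.seed(13)
  n <- 300
  de <- data.frame(gene = sprintf("g%03d", 1:n),
                   logFC = runif(n, 0.1, 5), p = runif(n, 0, 0.04))
  sig <- extract_signature(de, top_n = 150)
  expect_equal(nrow(sig$over), 150)
  expect_equal(nrow(sig$under), 0)
  ord <- de[order(-de$logFC), ]
  expect_equal(sig$over$gene, ord$gene[1:150])
  expect_length(intersect(sig$over$gene, sig$under$gene), 0)

  empty <- extract_signature(de[de$p > 1, ])
  expect_equal(nrow(empty$over) + nrow(empty$under), 0)
})

test_that("signature aggregation unions or intersects across experiments", {
  s1 <- extract_signature(data.frame(gene = c("a", "b"), logFC = c(1, 2),
                                     p = c(0.01, 0.01)))
  s2 <- extract_signature(data.frame(gene = c("b", "c"), logFC = c(1, -1),
                                     p = c(0.01, 0.01)))
  u <- aggregate_signatures(list(s1, s2), method = "union")
  expect_equal(u$over, c("a", "b"))
  expect_equal(u$under, "c")
  i <- aggregate_signatures(list(s1, s2), method = "intersection")
  expect_equal(i$over, "b")
  expect_equal(i$under, character(0))
  expect_true(all(c("gene", "direction", "experiment") %in%
                    names(u$provenance)))
})
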