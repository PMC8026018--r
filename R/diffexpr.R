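#' Differential-expression signature extraction
#'
#' Per-disease over-/under-expressed gene signatures are extracted with the
#' normalization and filtering rules used throughout the pipeline:
#' microarray-like intensities are quantile normalized (with the unlog /
#' normalize / relog dance for datasets that arrive log2-transformed but
#' unnormalized), RNA-Seq counts are filtered at 1 CPM in at least 2
#' libraries per group and scaled with TMM factors, a per-gene two-sided
#' Welch test supplies p-values, and the signature keeps the top 150 over-
#' and under-expressed genes by absolute log2 fold change after dropping
#' dual-sign probes and resolving duplicates to the most significant row.
#'
#' @name diffexpr
NULL

#' Quantile normalization
#'
#' Forces every column to share one empirical distribution: each column's
#' sorted values are replaced by the row means of the column-sorted matrix.
#' A thin wrapper over [limma::normalizeQuantiles()], kept as its own
#' operation so the normalization used is explicit and testable.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return Matrix of the same shape with row/column names preserved.
#' @export
quantile_normalize <- function(m) {
  assert_that(is.matrix(m) && is.numeric(m), "m must be a numeric matrix")
  assert_that(ncol(m) >= 2, "quantile normalization needs >= 2 columns")
  out <- limma::normalizeQuantiles(m)
  dimnames(out) <- dimnames(m)
  out
}

# vectorized two-sided Welch two-sample test, one gene per row
welch_rows <- function(x_case, x_ctrl) {
  n1 <- ncol(x_case); n2 <- ncol(x_ctrl)
  m1 <- rowMeans(x_case); m2 <- rowMeans(x_ctrl)
  v1 <- rowSums((x_case - m1)^2) / (n1 - 1)
  v2 <- rowSums((x_ctrl - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # constant gene in both groups: no evidence
  data.frame(logFC = m1 - m2, t = tstat, df = df, p = p)
}

split_groups <- function(m, groups) {
  assert_that(all(c("sample", "group") %in% names(groups)),
              "groups needs columns sample and group")
  assert_that(setequal(groups$sample, colnames(m)),
              "group table and matrix columns disagree")
  g <- groups$group[match(colnames(m), groups$sample)]
  assert_that(setequal(unique(g), c("case", "control")),
              "groups must be labelled case/control")
  assert_that(min(table(g)) >= 2, "each group needs at least 2 samples")
  list(case = m[, g == "case", drop = FALSE],
       ctrl = m[, g == "control", drop = FALSE])
}

#' Normalize an expression matrix and test each gene
#'
#' For intensity data, `log2_state` declares how the matrix arrives:
#' `"raw"` (unnormalized, unlogged: quantile normalize, then log2),
#' `"log2"` (already normalized and logged: used as is) or
#' `"log2_unnormalized"` (logged but not normalized: unlog, quantile
#' normalize, relog). For counts, genes are CPM-filtered, TMM factors are
#' computed and the test runs on log2 CPM with a 0.5 pseudo-count. The
#' per-gene test is a two-sided Welch two-sample test; logFC is
#' mean(case) - mean(control) on the log2 scale.
#'
#' @param m numeric matrix, genes x samples.
#' @param groups data.frame with columns sample, group (case/control).
#' @param platform `"intensity"` or `"counts"`.
#' @param log2_state state of intensity input (ignored for counts).
#' @param min_cpm,min_libs CPM filter settings for counts.
#' @return data.frame with gene, logFC, p, direction (over/under).
#' @export
normalize_and_test <- function(m, groups,
                               platform = c("intensity", "counts"),
                               log2_state = c("log2", "raw",
                                              "log2_unnormalized"),
                               min_cpm = 1, min_libs = 2) {
  platform <- match.arg(platform)
  log2_state <- match.arg(log2_state)
  sp <- split_groups(m, groups)

  if (platform == "intensity") {
    x <- switch(log2_state,
      log2 = m,
      raw = {
        assert_that(all(m > 0), "raw intensities must be positive to log2")
        log2(quantile_normalize(m))
      },
      log2_unnormalized = log2(quantile_normalize(2^m)))
  } else {
    assert_that(all(m >= 0), "counts must be non-negative")
    m <- cpm_filter(m, groups, min_cpm = min_cpm, min_libs = min_libs)
    nf <- tmm_factors(m)
    eff <- colSums(m) * nf
    x <- log2(sweep(m + 0.5, 2, eff, "/") * 1e6)
  }
  sp <- split_groups(x, groups)
  res <- welch_rows(sp$case, sp$ctrl)
  data.frame(gene = rownames(x), logFC = res$logFC, p = res$p,
             direction = ifelse(res$logFC > 0, "over", "under"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' CPM expression filter for count data
#'
#' Keeps a gene only if, within each group separately, its counts reach
#' `min_cpm` counts per million in at least `min_libs` libraries of that
#' group (CPM = count / library size * 1e6, library size = column sum of
#' the unfiltered matrix).
#'
#' @param counts non-negative count matrix, genes x samples.
#' @param groups data.frame with columns sample, group.
#' @param min_cpm CPM threshold.
#' @param min_libs minimum number of libraries per group reaching it.
#' @return The filtered count matrix, row order preserved.
#' @export
cpm_filter <- function(counts, groups, min_cpm = 1, min_libs = 2) {
  assert_that(all(counts >= 0), "counts must be non-negative")
  lib <- colSums(counts)
  assert_that(all(lib > 0), "zero library size")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  g <- groups$group[match(colnames(counts), groups$sample)]
  keep <- rep(TRUE, nrow(counts))
  for (grp in unique(g)) {
    n_pass <- rowSums(cpm[, g == grp, drop = FALSE] >= min_cpm)
    keep <- keep & (n_pass >= min_libs)
  }
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors between each sample and a
#' reference (the sample whose upper-quartile CPM is closest to the mean),
#' with the standard 30%/5% trims on M and A values and inverse
#' approximate-variance weights, rescaled so the factors multiply to 1.
#' Delegates to [edgeR::calcNormFactors()].
#'
#' @param counts count matrix with >= 2 samples.
#' @return Named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts) {
  assert_that(ncol(counts) >= 2, "need at least 2 samples")
  assert_that(all(colSums(counts) > 0), "a sample has zero total count")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  names(f) <- colnames(counts)
  f
}

#' Extract an over-/under-expressed gene signature
#'
#' Applies, in order: (1) the significance cutoff `p < alpha`; (2) removal
#' of genes whose surviving rows (probes) disagree in fold-change sign;
#' (3) resolution of duplicate same-sign rows to the lowest p-value; and
#' (4) ranking by absolute log2 fold change, keeping at most `top_n` genes
#' per direction. An input that empties out yields an empty (not failed)
#' signature.
#'
#' @param de data.frame with columns gene, logFC, p (possibly several rows
#'   per gene from distinct probes).
#' @param alpha significance cutoff (strict `p < alpha`).
#' @param top_n maximum genes kept per direction.
#' @param disease optional disease id stored on the result.
#' @return A `gene_signature`: list with `over` and `under` data.frames
#'   (gene, logFC, p, ordered by |logFC| descending) and `disease`.
#' @export
extract_signature <- function(de, alpha = 0.05, top_n = 150,
                              disease = NA_character_) {
  assert_that(all(c("gene", "logFC", "p") %in% names(de)),
              "de needs columns gene, logFC, p")
  de <- de[de$p < alpha, , drop = FALSE]
  if (nrow(de)) {
    sign_tab <- tapply(sign(de$logFC), de$gene,
                       function(s) length(unique(s[s != 0])))
    dual <- names(sign_tab)[sign_tab > 1]
    de <- de[!de$gene %in% dual, , drop = FALSE]
  }
  if (nrow(de)) {
    de <- de[order(de$p), , drop = FALSE]
    de <- de[!duplicated(de$gene), , drop = FALSE]
  }
  take <- function(d) {
    d <- d[order(-abs(d$logFC), d$gene), , drop = FALSE]
    utils::head(d, top_n)
  }
  over <- take(de[de$logFC > 0, c("gene", "logFC", "p"), drop = FALSE])
  under <- take(de[de$logFC < 0, c("gene", "logFC", "p"), drop = FALSE])
  rownames(over) <- rownames(under) <- NULL
  structure(list(disease = disease, over = over, under = under),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature", if (!is.na(x$disease)) paste0(" [", x$disease, "]"),
      ": ", nrow(x$over), " over / ", nrow(x$under),
      " under-expressed genes\n", sep = "")
  invisible(x)
}

#' Aggregate signatures across experiments of one disease
#'
#' Combines several per-experiment signatures into one per-disease gene
#' list. The default is the union of the per-experiment lists (the most
#' inclusive reading); `"intersection"` keeps only genes seen in every
#' experiment. Per-gene provenance (which experiments contributed) is
#' retained.
#'
#' @param signatures list of `gene_signature` objects.
#' @param method `"union"` or `"intersection"`.
#' @return A list with `over` and `under` character vectors and
#'   `provenance`, a data.frame (gene, direction, experiment).
#' @export
aggregate_signatures <- function(signatures, method = c("union",
                                                        "intersection")) {
  method <- match.arg(method)
  stopifnot(length(signatures) >= 1)
  prov <- do.call(rbind, lapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    rbind(
      if (nrow(s$over)) data.frame(gene = s$over$gene, direction = "over",
                                   experiment = i) else NULL,
      if (nrow(s$under)) data.frame(gene = s$under$gene, direction = "under",
                                    experiment = i) else NULL)
  }))
  pick <- function(dir) {
    sub <- prov[prov$direction == dir, , drop = FALSE]
    if (!nrow(sub)) return(character(0))
    counts <- table(sub$gene)
    if (method == "union") sort(names(counts))
    else sort(names(counts)[counts == length(signatures)])
  }
  list(over = pick("over"), under = pick("under"),
       provenance = prov[order(prov$gene), , drop = FALSE])
}
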