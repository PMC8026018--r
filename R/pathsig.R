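#' Odds-ratio significance of guided vs random walk results
#'
#' For every pathway, the visit frequency in the guided execution is
#' compared with its frequency in the unguided (random-target) execution:
#' Freq = timesWalked / totalTimesWalked, Odds = Freq / (1 - Freq) and
#' OddsRatio = MapOdds / RandomOdds. A Pearson chi-square test on the
#' 2x2 visit table supplies per-pathway p-values, Benjamini-Hochberg
#' adjustment controls the FDR across the pathways of one run, and a
#' pathway is called significant when OddsRatio > 1.3 and adjusted
#' p < .05 (both strict).
#'
#' @name pathsig
NULL

#' Compute per-pathway odds ratios from two walk executions
#'
#' Pathways never visited in the random execution receive a Haldane-style
#' continuity correction: 0.5 is added to all four cells of that pathway's
#' 2x2 visit table before the odds are formed (reported in the
#' `corrected` column).
#'
#' @param guided,random `walk_counts` from [run_pathwalks()], over the
#'   same pathway set.
#' @return data.frame: pathway, guided_count, random_count, Freq,
#'   RandomFreq, MapOdds, RandomOdds, OddsRatio, corrected.
#' @export
compute_odds_ratios <- function(guided, random) {
  assert_that(inherits(guided, "walk_counts") &&
                inherits(random, "walk_counts"),
              "inputs must be walk_counts objects")
  assert_that(setequal(names(guided$times_walked),
                       names(random$times_walked)),
              "mismatched pathway sets")
  assert_that(guided$total_times_walked > 0 && random$total_times_walked > 0,
              "both executions need positive totals")
  ids <- sort(names(guided$times_walked))
  gc <- as.numeric(guided$times_walked[ids])
  rc <- as.numeric(random$times_walked[ids])
  gt <- guided$total_times_walked
  rt <- random$total_times_walked

  freq_g <- gc / gt
  freq_r <- rc / rt
  corrected <- rc == 0
  odds <- function(f) f / (1 - f)
  map_odds <- odds(freq_g)
  rand_odds <- odds(freq_r)
  if (any(corrected)) {
    fg <- (gc[corrected] + 0.5) / (gt + 1)
    fr <- (rc[corrected] + 0.5) / (rt + 1)
    map_odds[corrected] <- odds(fg)
    rand_odds[corrected] <- odds(fr)
  }
  data.frame(pathway = ids, guided_count = gc, random_count = rc,
             Freq = freq_g, RandomFreq = freq_r,
             MapOdds = map_odds, RandomOdds = rand_odds,
             OddsRatio = map_odds / rand_odds,
             corrected = corrected,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chi-square tests with Benjamini-Hochberg adjustment
#'
#' Per pathway, a Pearson chi-square test (1 degree of freedom, no
#' continuity correction) on the 2x2 table of guided vs random visit
#' counts against their complements; p-values are then BH-adjusted across
#' all pathways of the run. Tables with a zero margin get p = 1 with a
#' warning.
#'
#' @param or_table output of [compute_odds_ratios()], which carries the
#'   counts and totals needed for the tables.
#' @param guided_total,random_total execution totals; recovered from the
#'   table when it was built by [compute_odds_ratios()] on full counts.
#' @return The table with chi2, p and adj_p columns appended.
#' @export
chi_square_bh <- function(or_table,
                          guided_total = sum(or_table$guided_count),
                          random_total = sum(or_table$random_count)) {
  n <- nrow(or_table)
  chi2 <- p <- numeric(n)
  for (i in seq_len(n)) {
    tab <- rbind(c(or_table$guided_count[i],
                   guided_total - or_table$guided_count[i]),
                 c(or_table$random_count[i],
                   random_total - or_table$random_count[i]))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("zero-margin table for pathway ", or_table$pathway[i],
              "; p set to 1", call. = FALSE)
      chi2[i] <- 0
      p[i] <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi2[i] <- unname(ct$statistic)
      p[i] <- ct$p.value
    }
  }
  or_table$chi2 <- chi2
  or_table$p <- p
  or_table$adj_p <- stats::p.adjust(p, method = "BH")
  or_table
}

#' Flag significant pathways
#'
#' @param table output of [chi_square_bh()].
#' @param or_threshold odds-ratio threshold (strict `>`).
#' @param alpha adjusted-p threshold (strict `<`).
#' @return The table with a logical `significant` column appended.
#' @export
flag_significant <- function(table, or_threshold = 1.3, alpha = 0.05) {
  assert_that(all(c("OddsRatio", "adj_p") %in% names(table)),
              "table needs OddsRatio and adj_p columns")
  table$significant <- table$OddsRatio > or_threshold & table$adj_p < alpha
  table
}

#' Full pathway significance table for one disease run
#'
#' Convenience wrapper: odds ratios, chi-square/BH and significance flags,
#' with the topology-profile flags merged in when supplied (mirroring the
#' per-disease significance table layout: pathway, odds ratio, adjusted p,
#' top-5% betweenness/degree flags).
#'
#' @param guided,random `walk_counts`.
#' @param topology optional output of [topology_profile()].
#' @param or_threshold,alpha significance thresholds.
#' @return data.frame, one row per pathway.
#' @export
pathway_significance <- function(guided, random, topology = NULL,
                                 or_threshold = 1.3, alpha = 0.05) {
  tab <- flag_significant(chi_square_bh(compute_odds_ratios(guided, random)),
                          or_threshold = or_threshold, alpha = alpha)
  if (!is.null(topology)) {
    idx <- match(tab$pathway, topology$pathway)
    tab$top_betweenness <- topology$top_betweenness[idx]
    tab$top_degree <- topology$top_degree[idx]
  }
  tab
}
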