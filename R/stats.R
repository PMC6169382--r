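#' Pearson chi-square test of a contingency table
#'
#' Pearson statistic (no continuity correction) with expected counts from
#' the products of the marginals, df = (r-1)(c-1), upper-tail p. A
#' Monte-Carlo p-value is available for sparse tables.
#'
#' @param table Matrix (>= 2x2) of non-negative counts.
#' @param monte_carlo Use a simulated p-value instead of the chi-square
#'   tail (default FALSE).
#' @param B Monte-Carlo replicates (default 2000).
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_contingency <- function(table, monte_carlo = FALSE, B = 2000L) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("table must be >= 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal")
  }
  ct <- suppressWarnings(
    stats::chisq.test(table, correct = FALSE,
                      simulate.p.value = monte_carlo, B = B)
  )
  df <- if (monte_carlo) {
    (nrow(table) - 1L) * (ncol(table) - 1L)
  } else {
    as.integer(ct$parameter)
  }
  list(statistic = unname(ct$statistic), df = df, p = unname(ct$p.value))
}

#' Egg viability percentages
#'
#' Hatch percentage per row, `100 * hatched / scored`, rounded to one
#' decimal place as reported in hatch-rate tables.
#'
#' @param scored Integer vector of eggs scored (> 0).
#' @param hatched Integer vector of eggs hatched (`<= scored`).
#' @param labels Optional row labels.
#' @return data.frame with `scored`, `hatched`, `viability_pct`.
#' @export
viability_summary <- function(scored, hatched, labels = NULL) {
  stopifnot(length(scored) == length(hatched))
  if (any(scored == 0)) stop("scored must be > 0")
  if (any(hatched > scored)) stop("hatched cannot exceed scored")
  out <- data.frame(
    scored = scored, hatched = hatched,
    viability_pct = round(100 * hatched / scored, 1)
  )
  if (!is.null(labels)) out <- cbind(label = labels, out)
  out
}

#' Per-colony three-allele proportions
#'
#' For each colony, the percentage of progeny carrying three alleles at
#' multiple loci among all classified progeny; plus the unweighted mean
#' across colonies and the extremes. Headline figures (`mean_pct`,
#' `min_pct`, `max_pct`) are rounded to integers, matching how such
#' proportions are reported; exact one-decimal values are returned
#' alongside.
#'
#' @param two_allele Integer vector of two-allele progeny counts per colony.
#' @param three_allele Integer vector of three-allele progeny counts.
#' @param colony Optional colony labels.
#' @return List with `per_colony` (data.frame incl. `pct`, one decimal),
#'   `mean_pct`, `min_pct`, `max_pct` (integers) and `mean_pct_exact`,
#'   `min_pct_exact`, `max_pct_exact`.
#' @export
colony_proportions <- function(two_allele, three_allele, colony = NULL) {
  stopifnot(length(two_allele) == length(three_allele),
            length(two_allele) >= 1L)
  total <- two_allele + three_allele
  if (any(total == 0)) stop("each colony needs > 0 classified progeny")
  pct <- 100 * three_allele / total
  if (is.null(colony)) colony <- letters[seq_along(total)]
  list(
    per_colony = data.frame(colony = colony, two_allele = two_allele,
                            three_allele = three_allele,
                            pct = round(pct, 1), stringsAsFactors = FALSE),
    mean_pct = round(mean(pct)),
    min_pct = round(min(pct)),
    max_pct = round(max(pct)),
    mean_pct_exact = mean(pct),
    min_pct_exact = min(pct),
    max_pct_exact = max(pct)
  )
}
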