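# Group-level summaries: nonparametric two-group tests, 2x2 fraction
# comparisons, and false-discovery-rate adjustment across a report family.

#' Summarize a continuous metric across two groups
#'
#' Means with SEM per group and a two-tailed nonparametric test: Wilcoxon
#' rank-sum for independent groups, signed-rank when `paired = TRUE`.
#'
#' @param values numeric vector of the per-cell or per-session metric.
#' @param groups factor or character vector of group labels (two levels).
#' @param paired logical; use the signed-rank test on matched values.
#' @return one-row data.frame: group means and SEMs, `test`, `statistic`, `p`.
#' @export
compare_groups <- function(values, groups, paired = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  g <- levels(groups)
  v1 <- values[groups == g[1]]
  v2 <- values[groups == g[2]]
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  ht <- suppressWarnings(stats::wilcox.test(v1, v2, paired = paired,
                                            exact = FALSE))
  data.frame(group1 = g[1], n1 = length(v1), mean1 = mean(v1), sem1 = sem(v1),
             group2 = g[2], n2 = length(v2), mean2 = mean(v2), sem2 = sem(v2),
             test = if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum",
             statistic = unname(ht$statistic), p = ht$p.value,
             stringsAsFactors = FALSE)
}

#' Compare two fractions with an exact 2x2 test
#'
#' @param tab 2x2 matrix of counts: rows = groups, columns = outcome
#'   (e.g. classified / not classified).
#' @return list with the sample `odds_ratio` (`ad / bc`), Fisher's exact `p`,
#'   and the per-group fractions.
#' @export
fraction_comparison <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be a 2x2 count matrix")
  ht <- stats::fisher.test(tab)
  list(odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       p = ht$p.value,
       fraction1 = tab[1, 1] / sum(tab[1, ]),
       fraction2 = tab[2, 1] / sum(tab[2, ]))
}

#' Assemble a group summary with FDR adjustment
#'
#' Runs the supplied comparisons and adjusts their p-values with the
#' Benjamini-Hochberg procedure; the adjustment family is the set of tests
#' within one report section.
#'
#' @param comparisons named list; each element is a list with fields
#'   `values`, `groups`, and optionally `paired` (passed to
#'   [compare_groups()]).
#' @return data.frame with one row per comparison plus a `q` column
#'   (BH-adjusted p).
#' @export
summarize_groups <- function(comparisons) {
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    out <- compare_groups(cmp$values, cmp$groups,
                          paired = isTRUE(cmp$paired))
    cbind(metric = nm, out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
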