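# frequency comparisons of host-feeding patterns: period chi-square tests,
# land-use Kruskal-Wallis tests, pairwise trap-method tests

new_test_result <- function(test, statistic, df, p_value,
                            correction = "none", warnings = character()) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 correction = correction, warnings = warnings),
            class = "feeding_test_result")
}

#' @export
print.feeding_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.5g, df = %d, P = %.4g%s\n",
              x$test, x$statistic, x$df, x$p_value,
              if (x$correction == "continuity") " (continuity-corrected)" else ""))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Chi-square test of a contingency table
#'
#' Pearson chi-square test of independence with expected counts from the
#' marginals. Rows and columns with zero marginal totals are dropped first
#' (degrees of freedom reflect the reduced table). Yates' continuity
#' correction is applied automatically iff the reduced table is 2 x 2,
#' matching standard practice. Low expected counts (< 5) raise a warning
#' flag on the result, never an error.
#'
#' @param table matrix of non-negative counts, at least 2 x 2 after
#'   dropping zero-margin rows/columns.
#' @return a `feeding_test_result` with `statistic`, `df`, `p_value`,
#'   `correction` (`"none"` or `"continuity"`) and `warnings`.
#' @examples
#' chi_square(rbind(c(3, 5, 6), c(25, 30, 31)))
#' @export
chi_square <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("counts must be non-negative")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("degenerate table: fewer than 2 rows or columns with positive totals")
  }
  is2x2 <- nrow(m) == 2 && ncol(m) == 2
  ht <- suppressWarnings(chisq.test(m, correct = is2x2))
  warnings <- character()
  if (any(ht$expected < 5)) {
    warnings <- sprintf("%d expected cell count(s) below 5; the chi-square approximation may be inaccurate",
                        sum(ht$expected < 5))
  }
  new_test_result("chi-square", ht$statistic, as.integer(ht$parameter),
                  ht$p.value,
                  correction = if (is2x2) "continuity" else "none",
                  warnings = warnings)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (df = k - 1), used to compare host-group percentages across land-use
#' classes. When all observations are identical the tie-correction
#' denominator vanishes; the statistic is then reported as 0 with a ties
#' warning rather than NaN.
#'
#' @param groups list of numeric vectors, each non-empty, length >= 2.
#' @return a `feeding_test_result`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  warnings <- character()
  if (any(lengths(groups) < 5)) {
    warnings <- c(warnings,
                  "group size below 5; chi-square approximation is rough")
  }
  if (length(unique(x)) == 1) {
    return(new_test_result("Kruskal-Wallis", 0, length(groups) - 1L, 1,
                           warnings = c(warnings, "all observations identical (complete ties)")))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- kruskal.test(x, g)
  new_test_result("Kruskal-Wallis", ht$statistic,
                  as.integer(ht$parameter), ht$p.value, warnings = warnings)
}

#' Period comparison of host-feeding groups for one mosquito taxon
#'
#' Builds the sampling-period x host-group contingency table for one
#' mosquito taxon (early = January--June, late = July--December) and tests
#' it with [chi_square()]. Host groups never observed for the taxon drop
#' out of the table (and the degrees of freedom).
#'
#' @param dataset a [survey_dataset()].
#' @param taxon mosquito taxon name.
#' @return list with elements `table` (counts, periods x host groups) and
#'   `result` (a `feeding_test_result`).
#' @export
period_comparison <- function(dataset, taxon) {
  rec <- identified_records(dataset)
  rec <- rec[rec$mosquito_taxon == taxon, , drop = FALSE]
  if (nrow(rec) == 0) stop("taxon not present in dataset: ", taxon)
  tab <- table(factor(rec$period, levels = PERIODS),
               factor(rec$host_group, levels = HOST_GROUPS))
  tab <- unclass(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  list(table = tab, result = chi_square(tab))
}

#' Pairwise trap-method comparisons of bird vs mammal blood meals
#'
#' For every unordered pair of trapping methods present in the dataset, a
#' 2 x 2 table of bird vs non-human-mammal blood-meal counts is tested with
#' [chi_square()]; p-values are adjusted for multiple comparisons over the
#' family of pairs. Human blood meals are not part of this comparison.
#' Trap methods with no bird-or-mammal records are excluded.
#'
#' @param dataset a [survey_dataset()].
#' @param adjust adjustment method: `"BH"` (Benjamini-Hochberg, default),
#'   `"holm"` or `"bonferroni"`.
#' @return data frame with one row per pair: `trap_a`, `trap_b`,
#'   `statistic`, `df`, `p_value`, `p_adjusted`, `correction`, `warning`.
#' @export
pairwise_trap_tests <- function(dataset, adjust = c("BH", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  rec <- identified_records(dataset)
  rec <- rec[rec$host_group %in% c("bird", "non-human mammal"), , drop = FALSE]
  counts <- table(rec$trap_method, factor(rec$host_group,
                                          levels = c("bird", "non-human mammal")))
  counts <- unclass(counts)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(counts) < 2) {
    stop("need at least 2 trap methods with bird-or-mammal records")
  }
  pairs <- combn(rownames(counts), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    tab <- counts[pairs[, k], , drop = FALSE]
    res <- tryCatch(chi_square(tab), error = function(e) NULL)
    data.frame(trap_a = pairs[1, k], trap_b = pairs[2, k],
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               df = if (is.null(res)) NA_integer_ else res$df,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               correction = if (is.null(res)) NA_character_ else res$correction,
               warning = if (is.null(res)) "degenerate table"
               else paste(res$warnings, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out[, c("trap_a", "trap_b", "statistic", "df", "p_value", "p_adjusted",
          "correction", "warning")]
}
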