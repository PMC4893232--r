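# C-score null-model analysis of host-feeding patterns.
#
# The observed binary host-occurrence matrix is compared against
# fixed-equiprobable randomizations: each host row keeps its number of
# occurrences, re-placed uniformly at random over the columns. A C-score
# below the null distribution indicates aggregation of mosquito taxa (or
# sites) around shared hosts; above it, segregation.

#' Build a binary host-occurrence matrix from a survey dataset
#'
#' Rows are host species; columns are mosquito taxa (survey-wide analysis)
#' or trapping sites (per-taxon analysis). A cell is 1 iff at least one
#' blood-meal record links the row host to the column entity. All-zero rows
#' and columns are dropped.
#'
#' @param dataset a [survey_dataset()].
#' @param columns `"mosquito_taxon"` or `"site_id"`.
#' @param rows row axis; default `"host_species"`, or `"host_group"`.
#' @param filter_taxon optional mosquito taxon name; records are restricted
#'   to it before building (used with `columns = "site_id"`).
#' @return integer 0/1 matrix with host row names and column names.
#' @export
build_matrix <- function(dataset, columns = c("mosquito_taxon", "site_id"),
                         rows = c("host_species", "host_group"),
                         filter_taxon = NULL) {
  columns <- match.arg(columns)
  rows <- match.arg(rows)
  rec <- identified_records(dataset)
  if (!is.null(filter_taxon)) {
    rec <- rec[rec$mosquito_taxon %in% filter_taxon, , drop = FALSE]
  }
  if (nrow(rec) == 0) stop("no records left after filtering")
  m <- table(rec[[rows]], rec[[columns]]) > 0
  m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("degenerate matrix: ", nrow(m), " row(s) x ", ncol(m),
         " column(s) after dropping empty rows/columns; ",
         "need at least 2 x 2")
  }
  m
}

#' C-score of a binary matrix
#'
#' The mean number of checkerboard units over all unordered row pairs:
#' for rows i and j with row totals `r_i`, `r_j` sharing `S_ij` columns,
#' the pair contributes `(r_i - S_ij) * (r_j - S_ij)`. Low values mean rows
#' share many columns (aggregation); high values mean mutual exclusion
#' (segregation).
#'
#' @param m binary (0/1) matrix with at least 2 rows.
#' @return non-negative number.
#' @examples
#' c_score(rbind(c(1, 0), c(0, 1)))  # 1: one full checkerboard
#' c_score(rbind(c(1, 1), c(1, 1)))  # 0: identical rows
#' @export
c_score <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("C-score needs at least 2 rows")
  if (!all(m %in% c(0, 1))) stop("matrix cells must be 0 or 1")
  r <- rowSums(m)
  s <- m %*% t(m)                       # S_ij = shared columns
  cu <- outer(r, r, function(a, b) a * b) - s * outer(r, r, "+") + s^2
  # (r_i - S)(r_j - S) = r_i r_j - S (r_i + r_j) + S^2
  sum(cu[upper.tri(cu)]) / choose(nrow(m), 2)
}

#' Fixed-equiprobable randomization of a binary matrix
#'
#' Each row's total is preserved exactly; its 1s are re-placed uniformly at
#' random into distinct columns, all columns equiprobable, rows independent.
#' Randomness comes from R's global RNG stream (seed it before calling, or
#' use [run_null_model()] which requires an explicit seed).
#'
#' @param m binary (0/1) matrix.
#' @return a matrix of the same dimension and row sums.
#' @export
fixed_equiprobable_randomize <- function(m) {
  m <- as.matrix(m)
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  nc <- ncol(m)
  r <- rowSums(m)
  for (i in seq_len(nrow(m))) {
    if (r[i] > 0) out[i, sample.int(nc, r[i])] <- 1L
  }
  out
}

#' Null-model test of host-feeding aggregation
#'
#' Compares the observed C-score of a binary host-occurrence matrix to its
#' distribution under fixed-equiprobable randomization. Tail probabilities
#' use the add-one convention (the observed matrix counts as one
#' realization), so p is in (0, 1] and with 5000 iterations the smallest
#' reportable p is about 2e-4. Ties between null and observed values count
#' toward both tails. The pattern is `"aggregated"` if `p_low < alpha`,
#' `"segregated"` if `p_high < alpha`, else `"random"`.
#'
#' @param m binary (0/1) matrix, at least 2 x 2.
#' @param n_iterations number of randomizations (default 5000).
#' @param seed integer seed; required, so results are reproducible.
#' @param alpha significance level for the verdict (default 0.05).
#' @return object of class `null_model_result`: list with
#'   `observed_c_score`, `null_mean`, `null_variance`, `p_low`, `p_high`,
#'   `n_iterations`, `seed`, `alpha`, `pattern`.
#' @examples
#' m <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1))
#' run_null_model(m, n_iterations = 200, seed = 1)
#' @export
run_null_model <- function(m, n_iterations = 5000, seed, alpha = 0.05) {
  if (missing(seed)) stop("an explicit integer seed is required")
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("degenerate matrix: need >= 2 x 2")
  stopifnot(n_iterations >= 1)
  obs <- c_score(m)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_iterations),
           function(i) c_score(fixed_equiprobable_randomize(m)),
           numeric(1))
  })
  eps <- 1e-9
  p_low <- (sum(null <= obs + eps) + 1) / (n_iterations + 1)
  p_high <- (sum(null >= obs - eps) + 1) / (n_iterations + 1)
  pattern <- if (p_low < alpha) "aggregated"
  else if (p_high < alpha) "segregated"
  else "random"
  structure(list(observed_c_score = obs,
                 null_mean = mean(null),
                 null_variance = stats::var(null),
                 p_low = p_low, p_high = p_high,
                 n_iterations = n_iterations, seed = seed, alpha = alpha,
                 pattern = pattern),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf(
    "C-score %.4g, null mean %.4g +/- %.4g (variance), P<exp %.4g, P>exp %.4g: %s\n",
    x$observed_c_score, x$null_mean, x$null_variance,
    x$p_low, x$p_high, x$pattern))
  invisible(x)
}

#' Serialize a null-model result to JSON
#'
#' @param x a `null_model_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_null_model_result <- function(x, path) {
  stopifnot(inherits(x, "null_model_result"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
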