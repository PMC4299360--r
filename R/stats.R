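#' Pearson chi-squared test of independence (no continuity correction)
#'
#' Computes the classical statistic \eqn{\sum (O - E)^2 / E} over all cells,
#' with expected counts from the product of the observed margins, degrees of
#' freedom (R-1)(C-1), and the upper-tail chi-squared p-value.  No Yates
#' continuity correction is applied, for 2 x 2 tables included.
#'
#' @param x integer matrix of counts (any R x C with R, C >= 2).
#' @return object of classes `cow_test` and `htest` with `statistic`,
#'   `parameter` (df), `p.value` and `expected`.
#' @examples
#' pearson_chi2(rbind(c(1237, 375), c(528, 106)))
#' @export
pearson_chi2 <- function(x) {
  dname <- deparse(substitute(x))
  x <- .check_counts(x)
  rs <- rowSums(x); cs <- colSums(x); N <- sum(x)
  if (any(rs == 0) || any(cs == 0)) {
    empty <- c(rownames(x)[rs == 0], colnames(x)[cs == 0],
               paste0("row ", which(rs == 0)), paste0("column ", which(cs == 0)))
    stop("empty margin: ", empty[!is.na(empty)][1])
  }
  expected <- outer(rs, cs) / N
  stat <- sum((x - expected)^2 / expected)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  .cow_test(statistic = c("X-squared" = stat), parameter = c(df = df),
            p.value = stats::pchisq(stat, df, lower.tail = FALSE),
            method = "Pearson chi-squared test (no continuity correction)",
            data.name = dname, expected = expected)
}

#' Linear-by-linear association (trend) statistic
#'
#' The one-degree-of-freedom Mantel--Haenszel trend statistic
#' \eqn{(N - 1) r^2}, where r is the Pearson correlation of the row and
#' column scores weighted by the cell counts.  Default scores are
#' consecutive integers in category order: rows 1..R and columns 0..C-1
#' (column scoring starts at zero because the first column is typically a
#' reference/"none" category); the statistic is invariant under any affine
#' rescaling of either score vector, so the defaults only fix a convention.
#'
#' @param x integer matrix of counts.
#' @param row_scores,col_scores numeric score vectors; must be
#'   non-degenerate (non-constant over categories with observations).
#' @return `cow_test`/`htest` object with df = 1.
#' @examples
#' t6 <- cow_printed_table("T6")
#' linear_by_linear(t6)  # rows 1..4, columns 0..4
#' @export
linear_by_linear <- function(x, row_scores = seq_len(nrow(x)),
                             col_scores = seq_len(ncol(x)) - 1) {
  dname <- deparse(substitute(x))
  x <- .check_counts(x)
  stopifnot(length(row_scores) == nrow(x), length(col_scores) == ncol(x))
  N <- sum(x)
  w <- as.vector(x)
  u <- rep(row_scores, times = ncol(x))
  v <- rep(col_scores, each = nrow(x))
  su <- sum(w * u); sv <- sum(w * v)
  ssu <- sum(w * u^2) - su^2 / N
  ssv <- sum(w * v^2) - sv^2 / N
  if (ssu <= 0 || ssv <= 0)
    stop("degenerate scores: ",
         if (ssu <= 0) "row" else "column",
         " scores are constant over the observed cells")
  r <- (sum(w * u * v) - su * sv / N) / sqrt(ssu * ssv)
  stat <- (N - 1) * r^2
  .cow_test(statistic = c("X-squared" = stat), parameter = c(df = 1L),
            p.value = stats::pchisq(stat, 1L, lower.tail = FALSE),
            method = "linear-by-linear association ((N-1) r^2)",
            data.name = dname,
            estimate = c(correlation = r))
}

#' Tie-corrected rank-sum test on ordered categories
#'
#' Wilcoxon--Mann--Whitney comparison of two groups observed on the same
#' ordered categories, given as count vectors.  All observations in a
#' category share that category's midrank; the normal approximation uses the
#' tie-corrected variance
#' \deqn{Var(W) = \frac{n_1 n_2}{12}\Big[(N + 1) -
#'   \frac{\sum_k (t_k^3 - t_k)}{N (N - 1)}\Big]}
#' over tie-block sizes \eqn{t_k}, with no continuity correction.  The
#' reported Z is \eqn{|W - E[W]| / \sqrt{Var(W)}} and the p-value is
#' two-sided.
#'
#' @param group1,group2 non-negative integer count vectors over the same
#'   ordered categories (same length, same order).
#' @return `cow_test`/`htest` object; `statistic` is Z (no df),
#'   `estimate` holds the two group mean ranks.
#' @examples
#' ranksum_ordered(c(2041, 135, 56, 14), c(1817, 198, 150, 81))
#' @export
ranksum_ordered <- function(group1, group2) {
  stopifnot(length(group1) == length(group2), all(group1 >= 0),
            all(group2 >= 0))
  n1 <- sum(group1); n2 <- sum(group2); N <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("empty group")
  if (N < 2) stop("need at least two observations in total")
  t <- group1 + group2
  midrank <- cumsum(c(0, t[-length(t)])) + (t + 1) / 2
  W1 <- sum(group1 * midrank)
  mean_ranks <- c(group1 = W1 / n1, group2 = sum(group2 * midrank) / n2)
  EW <- n1 * (N + 1) / 2
  V <- n1 * n2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  z <- if (V > 0) abs(W1 - EW) / sqrt(V) else 0
  .cow_test(statistic = c(Z = z),
            p.value = 2 * stats::pnorm(-z),
            method = paste("tie-corrected rank-sum test on ordered",
                           "categories (normal approximation)"),
            data.name = paste(deparse(substitute(group1)), "vs",
                              deparse(substitute(group2))),
            estimate = mean_ranks)
}

.check_counts <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  if (any(x < 0) || anyNA(x)) stop("counts must be non-negative and complete")
  x
}

.cow_test <- function(...) {
  obj <- list(...)
  structure(obj[!vapply(obj, is.null, logical(1))],
            class = c("cow_test", "htest"))
}

#' Serialize a test result to a JSON-ready list
#'
#' @param x a `cow_test` object.
#' @return plain named list with `method`, `statistic`, `df` (if any),
#'   `p_value`, and `mean_ranks` when present.
#' @export
as_report <- function(x) {
  stopifnot(inherits(x, "cow_test"))
  out <- list(method = x$method, statistic = unname(x$statistic),
              p_value = x$p.value)
  if (!is.null(x$parameter)) out$df <- unname(x$parameter)
  if (!is.null(x$estimate) && identical(names(x$statistic), "Z"))
    out$mean_ranks <- as.list(x$estimate)
  out
}
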