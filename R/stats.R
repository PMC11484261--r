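## Group-comparison statistics implemented from their textbook formulas.
## Tail probabilities go through the regularized incomplete beta/gamma
## functions directly (see utils.R); R's t.test/chisq.test/aov are used
## only as independent cross-checks in the test suite.

.newTest <- function(name, statistic, df, p, groups) {
  new("TCRTestResult", testName = name, statistic = statistic,
      df = df, pValue = p, groupSummaries = groups)
}

.checkSample <- function(x, label) {
  if (!is.numeric(x) || length(x) < 2L)
    bail(label, " must be a numeric sample with n >= 2")
  if (any(!is.finite(x)))
    bail(label, " contains non-finite values")
}

#' Two-sample t test (Welch or Student)
#'
#' Compares the means of two independent samples. Welch's variant
#' (default) uses per-sample variances with Welch-Satterthwaite degrees
#' of freedom and is the safer choice for small samples with unequal
#' spread; Student's variant pools the variances with
#' \code{n1 + n2 - 2} degrees of freedom. The p-value is two-sided.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param variant \code{"welch"} (default) or \code{"student"}.
#' @return A \code{\linkS4class{TCRTestResult}}.
#' @examples
#' independentT(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6), variant = "student")
#' @export
independentT <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  .checkSample(x, "x"); .checkSample(y, "y")
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0)
    bail("both samples have zero variance; t is undefined")
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (mean(x) - mean(y)) / se
  groups <- data.frame(group = c("x", "y"), n = c(n1, n2),
                       mean = c(mean(x), mean(y)),
                       sd = c(sqrt(v1), sqrt(v2)))
  .newTest("independent_t", t, df, tTail2(t, df), groups)
}

#' Paired t test
#'
#' Tests whether the mean within-pair difference (after - before) is
#' zero. When \code{ids} are supplied the \code{after} sample is aligned
#' to the ordering of \code{before} by id; misaligned or non-matching ids
#' are an error, as are zero-variance differences (e.g. a constant shift
#' applied to every pair), for which no t statistic exists.
#'
#' @param before,after Numeric samples of equal length >= 2.
#' @param ids Optional list of two id vectors (or one vector used for
#'   both) pairing the observations.
#' @return A \code{\linkS4class{TCRTestResult}} whose statistic changes
#'   sign when the samples are swapped.
#' @export
pairedT <- function(before, after, ids = NULL) {
  .checkSample(before, "before"); .checkSample(after, "after")
  if (length(before) != length(after))
    bail("before and after must have equal length")
  if (!is.null(ids)) {
    if (!is.list(ids)) ids <- list(ids, ids)
    idb <- as.character(ids[[1L]]); ida <- as.character(ids[[2L]])
    if (length(idb) != length(before) || length(ida) != length(after))
      bail("ids must match sample lengths")
    if (!setequal(idb, ida) || anyDuplicated(idb) || anyDuplicated(ida))
      bail("before/after ids do not pair up one-to-one")
    after <- after[match(idb, ida)]
  }
  d <- after - before
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0)
    bail("within-pair differences have zero variance; t is undefined")
  t <- mean(d) / (sdd / sqrt(n))
  groups <- data.frame(group = c("before", "after", "diff"),
                       n = n,
                       mean = c(mean(before), mean(after), mean(d)),
                       sd = c(stats::sd(before), stats::sd(after), sdd))
  .newTest("paired_t", t, n - 1, tTail2(t, n - 1), groups)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction:
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with expected counts from the
#' product of the margins and \eqn{(r-1)(c-1)} degrees of freedom. A zero
#' expected count (empty row or column margin) is an error.
#'
#' @param table A numeric matrix of counts with at least two rows and two
#'   columns.
#' @return A \code{\linkS4class{TCRTestResult}}; \code{groupSummaries}
#'   holds the observed table.
#' @examples
#' chiSquareTest(matrix(c(10, 20, 20, 10), nrow = 2))
#' @export
chiSquareTest <- function(table) {
  tab <- as.matrix(table)
  if (!is.numeric(tab) || any(tab < 0) || anyNA(tab))
    bail("table must be a matrix of non-negative counts")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    bail("table must be at least 2 x 2")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0))
    bail("zero expected count (empty row or column margin)")
  x2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  .newTest("chi_square", x2, df, chisqTail(x2, df),
           as.data.frame(tab))
}

#' One-way analysis of variance
#'
#' Partitions the total sum of squares into between- and within-group
#' components: \eqn{F = (SSB/(k-1)) / (SSW/(N-k))} with degrees of
#' freedom \eqn{(k-1, N-k)}. Fewer than two groups, any group with fewer
#' than two observations, or zero within-group variance (where F is
#' undefined) are errors.
#'
#' @param groups A list of numeric samples, one per group.
#' @return A \code{\linkS4class{TCRTestResult}} with \code{df} of length
#'   2.
#' @examples
#' anovaOneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
#' @export
anovaOneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    bail("need at least 2 groups")
  for (i in seq_along(groups)) .checkSample(groups[[i]], paste("group", i))
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1L))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  if (ssw == 0)
    bail("zero within-group variance; F is undefined")
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  summaries <- data.frame(group = nm, n = ns, mean = means,
                          sd = vapply(groups, stats::sd, numeric(1L)))
  .newTest("anova_oneway", f, c(k - 1, N - k),
           fTail(f, k - 1, N - k), summaries)
}

#' Adjust a vector of p-values
#'
#' Convenience wrapper used by the pipeline's comparison stage. The
#' default is no correction, matching the fixed 0.05 significance
#' convention of the analyses this package reproduces;
#' Benjamini-Hochberg is available for users running many usage
#' comparisons at once.
#'
#' @param p Numeric vector of p-values.
#' @param method \code{"none"} (default) or \code{"BH"}.
#' @return Adjusted p-values.
#' @export
adjustPValues <- function(p, method = c("none", "BH")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}
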