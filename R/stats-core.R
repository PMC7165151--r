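#' Welch two-sample t test
#'
#' Unequal-variance (Welch) two-sample t test with Satterthwaite degrees of
#' freedom; the default everywhere the pipeline compares a continuous
#' measurement between two groups (TMB, marker expression, protein levels).
#' When both groups have zero variance, the convention is p = 1 for equal
#' means and p = 0 for separated constants (the test statistic is infinite).
#'
#' @param x,y Numeric vectors, each with at least 2 finite values.
#' @return A [test_result()] with `effect` = mean(x) - mean(y).
#' @examples
#' welch_t_test(rnorm(10), rnorm(10, 1))
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t_test needs >= 2 observations per group", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("welch_t_test: non-finite values", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    return(test_result(statistic = if (d == 0) 0 else sign(d) * Inf,
                       p_value = if (d == 0) 1 else 0,
                       method = "Welch two-sample t test",
                       df = length(x) + length(y) - 2, effect = d))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  test_result(statistic = unname(ht$statistic), p_value = ht$p.value,
              method = "Welch two-sample t test", df = unname(ht$parameter),
              effect = mean(x) - mean(y))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test of association in a 2x2 contingency table (rows =
#' group, columns = outcome). The two-sided p-value is the sum of
#' probabilities of all tables, under fixed margins, whose hypergeometric
#' point probability does not exceed that of the observed table. The effect
#' is the sample odds ratio a*d / (b*c), with 0.5 added to every cell when
#' any cell is zero (flagged in `extra$continuity`).
#'
#' @param a,b,c,d Nonnegative integer cell counts: `a`,`b` = row 1, `c`,`d` =
#'   row 2. Alternatively `a` may be a 2x2 matrix.
#' @return A [test_result()] with `effect` = odds ratio.
#' @examples
#' fisher_exact_two_sided(10, 2, 3, 9)
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2, 2)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("all-zero 2x2 table", call. = FALSE)
  ht <- stats::fisher.test(tab, alternative = "two.sided")
  continuity <- any(tab == 0)
  or_tab <- if (continuity) tab + 0.5 else tab
  or <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
  test_result(statistic = tab[1, 1], p_value = ht$p.value,
              method = "Fisher exact test (two-sided)", effect = or,
              extra = list(continuity = continuity))
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square test on an r x c count table, df = (r-1)(c-1), no
#' continuity correction. A warning is raised when any expected count falls
#' below 5; a zero row/column margin is an error under `strict = TRUE`
#' (default) or silently dropped otherwise.
#'
#' @param tab Integer matrix of counts, at least 2x2.
#' @param strict Error on zero margins instead of dropping them.
#' @return A [test_result()].
#' @export
chi_square_test <- function(tab, strict = TRUE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  if (sum(tab) == 0) stop("zero grand total", call. = FALSE)
  zero_r <- rowSums(tab) == 0; zero_c <- colSums(tab) == 0
  if (any(zero_r) || any(zero_c)) {
    if (strict) stop("zero row/column margin in chi-square table", call. = FALSE)
    tab <- tab[!zero_r, !zero_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("chi-square test needs at least a 2x2 table", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("chi-square approximation: expected count(s) below 5",
            call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(statistic = unname(ht$statistic), p_value = ht$p.value,
              method = "Pearson chi-square test", df = unname(ht$parameter))
}

#' Point-biserial correlation
#'
#' Correlation between a continuous measurement and a dichotomy coded 0/1 —
#' algebraically the Pearson correlation with the 0/1 coding; p-value from
#' the t transform with n - 2 df. With `latent = TRUE` the biserial variant
#' (assuming a latent normal behind the dichotomy) is returned instead:
#' r_b = r_pb * sqrt(p*q) / dnorm(qnorm(p)).
#'
#' @param binary 0/1 (or logical) vector with both classes present.
#' @param x Numeric vector, same length.
#' @param latent Return the latent-normal biserial coefficient.
#' @return A [test_result()] with `effect` = r.
#' @export
point_biserial <- function(binary, x, latent = FALSE) {
  binary <- as.numeric(binary); x <- as.numeric(x)
  if (length(binary) != length(x)) stop("length mismatch", call. = FALSE)
  if (!all(binary %in% c(0, 1))) stop("binary vector must be 0/1", call. = FALSE)
  if (length(unique(binary)) < 2) stop("both classes must be present", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(test_result(statistic = 0, p_value = 1,
                       method = "point-biserial correlation",
                       df = length(x) - 2, effect = 0))
  }
  ht <- stats::cor.test(x, binary, method = "pearson")
  r <- unname(ht$estimate)
  method <- "point-biserial correlation"
  if (latent) {
    p <- mean(binary); q <- 1 - p
    r <- r * sqrt(p * q) / stats::dnorm(stats::qnorm(p))
    method <- "biserial correlation (latent normal)"
  }
  test_result(statistic = unname(ht$statistic), p_value = ht$p.value,
              method = method, df = unname(ht$parameter), effect = r)
}

#' Linear fold difference between two sample groups
#'
#' For log2-scale expression, the linear fold difference of one gene between
#' two groups: 2^(mean(A) - mean(B)).
#'
#' @param expr An [expression_matrix()].
#' @param gene Gene identifier present in `expr`.
#' @param group_a,group_b Disjoint, nonempty sample-id sets.
#' @return The linear fold (group A over group B).
#' @export
log2_fold_difference <- function(expr, gene, group_a, group_b) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!gene %in% rownames(expr)) stop("unknown gene id: ", gene, call. = FALSE)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("groups must be nonempty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss) > 0) stop("unknown sample id(s): ",
                             paste(utils::head(miss, 5), collapse = ", "),
                             call. = FALSE)
  2^(mean(expr[gene, group_a]) - mean(expr[gene, group_b]))
}

# Vectorized per-gene Welch t: rows of `mat` split by logical `in_a` columns.
# Returns data.frame(gene_id, statistic, df, p_value, mean_diff). Used by the
# differential-expression screen where per-row t.test() calls would dominate
# runtime.
row_welch_t <- function(mat, in_a) {
  a <- mat[, in_a, drop = FALSE]
  b <- mat[, !in_a, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stop("both groups need >= 2 samples", call. = FALSE)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  # zero-variance-in-both convention: equal means -> t = 0, p = 1
  degenerate <- se2 == 0
  stat[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 0,
                             sign(ma - mb)[degenerate] * Inf)
  df[degenerate] <- na + nb - 2
  p <- 2 * stats::pt(-abs(stat), df)
  p[degenerate & stat == 0] <- 1
  p[degenerate & is.infinite(stat)] <- 0
  data.frame(gene_id = rownames(mat), statistic = stat, df = df, p_value = p,
             mean_diff = ma - mb, row.names = NULL, stringsAsFactors = FALSE)
}
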