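#' Hypothesis-test result container
#'
#' Uniform container for every test the pipeline reports: statistic, degrees
#' of freedom, two-sided p-value, optional effect measure (mean difference,
#' odds ratio, correlation, ...) and the method name.
#'
#' @param statistic Test statistic.
#' @param p_value Two-sided p-value in \[0, 1\].
#' @param method Nonempty method label.
#' @param df Degrees of freedom, or `NA`.
#' @param effect Effect estimate, or `NA`.
#' @param extra Optional named list of method-specific extras.
#' @return A list of class `"test_result"`.
#' @export
test_result <- function(statistic, p_value, method, df = NA_real_,
                        effect = NA_real_, extra = list()) {
  if (!nzchar(method)) stop("method must be nonempty", call. = FALSE)
  p_value <- min(max(as.numeric(p_value), 0), 1)
  if (is.na(p_value)) stop("p_value is NA", call. = FALSE)
  structure(list(statistic = as.numeric(statistic), df = as.numeric(df),
                 p_value = p_value, effect = as.numeric(effect),
                 method = method, extra = extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g", x$method, x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %.4g", x$df))
  cat(sprintf(", p = %.4g", x$p_value))
  if (!is.na(x$effect)) cat(sprintf(", effect = %.4g", x$effect))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.test_result <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic, df = x$df,
             p_value = x$p_value, effect = x$effect,
             stringsAsFactors = FALSE)
}

#' Cox model result container
#'
#' Per-covariate coefficients, hazard ratios, 95% Wald confidence intervals
#' and Wald p-values from a proportional-hazards fit, plus fit metadata.
#'
#' @param terms Data.frame with columns `term`, `coef`, `se`, `hr`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @param loglik Model partial log-likelihood at the solution.
#' @param n Number of complete-case rows used.
#' @param n_events Number of events among them.
#' @param n_dropped Rows dropped for missing covariates.
#' @param ties Tie-handling method (`"efron"` or `"breslow"`).
#' @param iter Iteration count of the fitter.
#' @param score Score (log-rank-type) chi-square statistic at beta = 0.
#' @return A list of class `"cox_result"`.
#' @export
cox_result <- function(terms, loglik, n, n_events, n_dropped = 0L,
                       ties = "efron", iter = NA_integer_, score = NA_real_) {
  stopifnot(is.data.frame(terms),
            all(c("term", "coef", "se", "hr", "ci_lower", "ci_upper",
                  "p_value") %in% names(terms)))
  structure(list(terms = terms, loglik = loglik, n = n, n_events = n_events,
                 n_dropped = n_dropped, ties = ties, iter = iter,
                 score = score),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties), n = %d, events = %d",
              x$ties, x$n, x$n_events))
  if (x$n_dropped > 0) cat(sprintf(" (%d rows dropped: missing covariates)",
                                   x$n_dropped))
  cat("\n")
  tab <- x$terms
  tab$hr_ci <- sprintf("%.3g (%.3g-%.3g)", tab$hr, tab$ci_lower, tab$ci_upper)
  print(tab[, c("term", "coef", "se", "hr_ci", "p_value")], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cox_result <- function(x, ...) x$terms

# serialize any result object into plain lists for JSON export
result_to_list <- function(x) {
  if (inherits(x, "test_result")) {
    out <- x[c("statistic", "df", "p_value", "effect", "method")]
    if (length(x$extra) > 0) out$extra <- x$extra
    return(out)
  }
  if (inherits(x, "cox_result")) {
    return(list(terms = x$terms, loglik = x$loglik, n = x$n,
                n_events = x$n_events, n_dropped = x$n_dropped,
                ties = x$ties, score = x$score))
  }
  x
}
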