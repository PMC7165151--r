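#' Kaplan-Meier product-limit estimate
#'
#' @param times Nonnegative follow-up times (months).
#' @param events Logical/0-1 event indicators (censoring ties at an event
#'   time are handled as censored-after-event, the standard convention).
#' @return A data.frame of class `"km_curve"` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` — one row per distinct observed time.
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times); events <- as.logical(events)
  if (length(times) == 0) stop("no observations", call. = FALSE)
  if (any(times < 0)) stop("negative survival time", call. = FALSE)
  if (anyNA(times) || anyNA(events)) stop("missing time/event values", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Observed-minus-expected chi-square test (hypergeometric variance,
#' df = 1) comparing survival between two groups.
#'
#' @param times,events As in [km_estimate()].
#' @param group Two-level vector (factor/character/0-1) assigning each
#'   subject to a group.
#' @return A [test_result()].
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0)) {
    stop("logrank_test needs two nonempty groups", call. = FALSE)
  }
  if (any(times < 0)) stop("negative survival time", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(as.numeric(times),
                                          as.logical(events)) ~ group)
  test_result(statistic = sd$chisq,
              p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
              method = "log-rank test", df = 1)
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model by partial-likelihood maximization (via
#' `survival::coxph`), reporting per-covariate hazard ratios, 95% Wald
#' confidence intervals and Wald p-values. Rows with missing covariates are
#' dropped (complete-case) and counted; constant covariates and monotone
#' likelihoods (complete separation) are errors.
#'
#' @param covariates Data.frame (or matrix) of numeric/binary covariate
#'   columns; ordered factors should be coded ordinally beforehand.
#' @param times,events Survival outcome.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A [cox_result()].
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0) stop("no covariates", call. = FALSE)
  times <- as.numeric(times); events <- as.logical(events)
  stopifnot(nrow(covariates) == length(times), length(times) == length(events))
  cc <- stats::complete.cases(covariates) & !is.na(times) & !is.na(events)
  n_dropped <- sum(!cc)
  covariates <- covariates[cc, , drop = FALSE]
  times <- times[cc]; events <- events[cc]
  if (sum(events) < 1) stop("no events in complete cases", call. = FALSE)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.logical(v)) covariates[[nm]] <- as.numeric(v)
    if (is.character(v) || is.factor(v)) {
      stop("covariate '", nm, "' must be numeric (code factors beforehand)",
           call. = FALSE)
    }
    if (stats::var(covariates[[nm]]) == 0) {
      stop("constant covariate: ", nm, call. = FALSE)
    }
  }
  dat <- cbind(covariates, .time = times, .event = events)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|did not converge|out of iterations", msg,
                ignore.case = TRUE)) {
        stop("Cox fit failed (monotone likelihood / non-convergence): ", msg,
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  terms <- data.frame(term = names(stats::coef(fit)),
                      coef = unname(stats::coef(fit)),
                      se = unname(s$coefficients[, "se(coef)"]),
                      hr = unname(exp(stats::coef(fit))),
                      ci_lower = unname(s$conf.int[, "lower .95"]),
                      ci_upper = unname(s$conf.int[, "upper .95"]),
                      p_value = unname(s$coefficients[, "Pr(>|z|)"]),
                      stringsAsFactors = FALSE)
  terms$term <- gsub("`", "", terms$term)
  cox_result(terms, loglik = fit$loglik[2], n = fit$n, n_events = fit$nevent,
             n_dropped = n_dropped, ties = ties, iter = fit$iter,
             score = unname(fit$score))
}

#' Backward elimination for a Cox model
#'
#' Starting from the full model, repeatedly refits after dropping the
#' covariate with the largest Wald p-value above `retain_p`, stopping when
#' every remaining covariate satisfies p <= `retain_p`. Covariates in
#' `force` are never dropped.
#'
#' @inheritParams cox_fit
#' @param retain_p Retention threshold on the Wald p-value (default 0.05).
#' @param force Covariate names exempt from elimination.
#' @return A list: `model` (final [cox_result()], or `NULL` when everything
#'   was eliminated), `retained`, `dropped` (in elimination order).
#' @export
backward_select <- function(covariates, times, events, retain_p = 0.05,
                            force = character(0), ties = "efron") {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 1) stop("need >= 1 candidate covariate", call. = FALSE)
  bad <- setdiff(force, names(covariates))
  if (length(bad) > 0) stop("forced covariate(s) not among candidates: ",
                            paste(bad, collapse = ", "), call. = FALSE)
  dropped <- character(0)
  current <- names(covariates)
  model <- NULL
  repeat {
    if (length(current) == 0) { model <- NULL; break }
    model <- cox_fit(covariates[current], times, events, ties = ties)
    p <- model$terms$p_value
    names(p) <- model$terms$term
    removable <- setdiff(names(p), force)
    if (length(removable) == 0) break
    worst <- removable[which.max(p[removable])]
    if (p[worst] <= retain_p) break
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
  }
  list(model = model, retained = current, dropped = dropped)
}

#' Chemotherapy-by-subtype interaction analysis
#'
#' Reproduces the treatment-interaction design: (i) a chemotherapy-only Cox
#' model within each subtype stratum (the stratum hazard ratios), and (ii) a
#' pooled model with subtype, chemotherapy and their product term, whose
#' product-term Wald p is the interaction p-value. A stratum with no treated
#' or no untreated patients yields `NULL` for that stratum (flagged, no
#' error); the pooled model requires all four subtype x treatment cells
#' nonempty.
#'
#' @param subtype Character vector, `"INT"`/`"COD"` per patient.
#' @param chemo Logical treatment flags.
#' @param times,events Survival outcome.
#' @param ties Passed to [cox_fit()].
#' @return A list: `stratum` (named list INT/COD of [cox_result()] or
#'   `NULL`), `interaction` ([cox_result()] for the pooled model, or `NULL`
#'   with an empty cell), `interaction_p`.
#' @export
interaction_analysis <- function(subtype, chemo, times, events,
                                 ties = "efron") {
  stopifnot(all(subtype %in% c("INT", "COD")))
  chemo <- as.logical(chemo)
  stratum <- list(INT = NULL, COD = NULL)
  for (st in c("INT", "COD")) {
    idx <- subtype == st
    if (sum(idx) == 0 || length(unique(chemo[idx])) < 2 ||
        sum(events[idx]) == 0) next
    stratum[[st]] <- tryCatch(
      cox_fit(data.frame(chemo = as.numeric(chemo[idx])),
              times[idx], events[idx], ties = ties),
      error = function(e) NULL)
  }
  cells <- table(factor(subtype, c("INT", "COD")), factor(chemo, c(FALSE, TRUE)))
  interaction <- NULL
  interaction_p <- NA_real_
  if (all(cells > 0)) {
    cod <- as.numeric(subtype == "COD")
    X <- data.frame(subtype_cod = cod, chemo = as.numeric(chemo),
                    subtype_x_chemo = cod * as.numeric(chemo))
    interaction <- tryCatch(cox_fit(X, times, events, ties = ties),
                            error = function(e) NULL)
    if (!is.null(interaction)) {
      interaction_p <-
        interaction$terms$p_value[interaction$terms$term == "subtype_x_chemo"]
    }
  }
  list(stratum = stratum, interaction = interaction,
       interaction_p = interaction_p)
}

#' Export a Kaplan-Meier curve as TSV
#'
#' @param km A `"km_curve"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(km, path) {
  utils::write.table(as.data.frame(km), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
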