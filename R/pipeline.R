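#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list), fills in
#' defaults, range-checks every threshold and rejects unknown keys with a
#' closest-match suggestion. Referenced input files must exist unless
#' `simulate` is `TRUE`.
#'
#' Top-level keys: `seed` (integer), `out_dir`, `simulate` (logical),
#' `simulation` (fields of [simulation_config()]), `inputs` (`expression`,
#' `clinical`, `mutations` paths), `thresholds` (`sd_threshold` 0.9, `de_p`
#' 0.001, `screen_alpha` 0.05, `retain_p` 0.05), `clustering` (`distance`,
#' `linkage`), `stages` (`derive`, `classify`, `survival`, `mutations`
#' logicals), `endpoint` (`"os"` or `"dfs"`), `classify_method`.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A list of class `"pipeline_config"` with all defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))

  defaults <- list(
    seed = 1L, out_dir = NULL, simulate = FALSE, simulation = list(),
    inputs = list(expression = NULL, clinical = NULL, mutations = NULL,
                  signature = NULL),
    thresholds = list(sd_threshold = 0.9, de_p = 0.001,
                      screen_alpha = 0.05, retain_p = 0.05),
    clustering = list(distance = "one_minus_pearson", linkage = "average"),
    stages = list(derive = TRUE, classify = TRUE, survival = TRUE,
                  mutations = TRUE),
    endpoint = "os", classify_method = "two_cluster")

  check_keys <- function(given, allowed, where) {
    unknown <- setdiff(names(given), allowed)
    if (length(unknown) > 0) {
      hint <- vapply(unknown, function(k) {
        cand <- allowed[utils::adist(k, allowed) <= 2]
        if (length(cand) > 0) sprintf(" (did you mean '%s'?)", cand[1]) else ""
      }, "")
      stop("unknown ", where, " key(s): ",
           paste0("'", unknown, "'", hint, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(config, names(defaults), "config")
  for (grp in c("inputs", "thresholds", "clustering", "stages")) {
    if (!is.null(config[[grp]])) {
      check_keys(config[[grp]], names(defaults[[grp]]), grp)
    }
  }
  if (!is.null(config$simulation)) {
    check_keys(config$simulation, names(formals(simulation_config)),
               "simulation")
  }

  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)

  th <- cfg$thresholds
  if (th$sd_threshold < 0) stop("sd_threshold must be >= 0", call. = FALSE)
  for (nm in c("de_p", "screen_alpha", "retain_p")) {
    if (th[[nm]] <= 0 || th[[nm]] > 1) {
      stop(nm, " must be in (0, 1]", call. = FALSE)
    }
  }
  if (!cfg$endpoint %in% c("os", "dfs")) {
    stop("endpoint must be 'os' or 'dfs'", call. = FALSE)
  }
  if (!cfg$classify_method %in% c("two_cluster", "centroid")) {
    stop("classify_method must be 'two_cluster' or 'centroid'", call. = FALSE)
  }
  if (!cfg$clustering$distance %in% c("one_minus_pearson", "euclidean")) {
    stop("unknown clustering distance", call. = FALSE)
  }
  if (!cfg$clustering$linkage %in% c("average", "complete", "ward")) {
    stop("unknown clustering linkage", call. = FALSE)
  }
  if (!isTRUE(cfg$simulate)) {
    for (nm in c("expression", "clinical")) {
      p <- cfg$inputs[[nm]]
      if (is.null(p)) stop("inputs$", nm, " required when simulate is FALSE",
                           call. = FALSE)
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
  }
  for (nm in c("mutations", "signature")) {
    if (!is.null(cfg$inputs[[nm]]) && !file.exists(cfg$inputs[[nm]])) {
      stop("input file not found: ", cfg$inputs[[nm]], call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes the requested stages end to end: simulate (or load) the cohort,
#' derive the signature, classify the diffuse-type samples into INT/COD,
#' run the survival analyses (Kaplan-Meier per subtype, log-rank,
#' univariate and backward-selected multivariate Cox, chemotherapy
#' interaction) and the mutation analyses (TMB contrast, per-gene screen,
#' molecular-subtype association). Writes, under `out_dir` (if set):
#' `report.json` (machine-readable, deterministic given the seed),
#' `report.md` (human summary), `signature.json` and `subtypes.tsv`.
#'
#' @param config A [validate_config()] result, YAML path, or named list.
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_all <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  report <- list(package_version = as.character(utils::packageVersion("codsig")),
                 seed = config$seed,
                 parameters = list(thresholds = config$thresholds,
                                   clustering = config$clustering,
                                   endpoint = config$endpoint,
                                   classify_method = config$classify_method))

  if (isTRUE(config$simulate)) {
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(list(seed = config$seed),
                                         config$simulation))
    cohort <- simulate_cohort(sim_cfg)
    expr <- cohort$expression
    clinical <- cohort$clinical
    mut <- cohort$mutations
    report$cohort <- list(source = "simulated",
                          n_samples = ncol(expr), n_genes = nrow(expr))
  } else {
    expr <- read_expression_matrix(config$inputs$expression)
    clinical <- read_clinical_table(config$inputs$clinical)
    mut <- if (!is.null(config$inputs$mutations)) {
      read_mutation_table(config$inputs$mutations)
    }
    report$cohort <- list(source = "files",
                          n_samples = ncol(expr), n_genes = nrow(expr))
  }

  sig <- NULL
  if (!is.null(config$inputs$signature)) {
    sig <- read_signature(config$inputs$signature)
    report$signature <- list(source = config$inputs$signature,
                             n_signature_genes = length(sig$gene_ids))
  }
  if (isTRUE(config$stages$derive)) {
    sig <- derive_signature(expr, clinical,
                            sd_threshold = config$thresholds$sd_threshold,
                            p_threshold = config$thresholds$de_p,
                            distance = config$clustering$distance,
                            linkage = config$clustering$linkage)
    report$signature <- list(
      n_filtered_genes = sig$n_filtered_genes,
      partition_counts = as.list(sig$partition$counts),
      n_signature_genes = length(sig$gene_ids))
  }

  assignment <- NULL
  if (isTRUE(config$stages$classify)) {
    if (is.null(sig)) {
      stop("classify stage requires the derive stage or a saved signature",
           call. = FALSE)
    }
    is_diffuse <- !is.na(clinical$histology) & clinical$histology == "diffuse"
    d_ids <- clinical$sample_id[is_diffuse]
    d_expr <- expression_matrix(unclass(expr)[, d_ids, drop = FALSE])
    assignment <- classify_cohort(d_expr, sig,
                                  method = config$classify_method)
    report$classification <- list(
      method = attr(assignment, "method"),
      overlap = attr(assignment, "overlap"),
      n_int = sum(assignment$subtype == "INT"),
      n_cod = sum(assignment$subtype == "COD"))
  }

  if (isTRUE(config$stages$survival)) {
    if (is.null(assignment)) stop("survival stage requires the classify stage",
                                  call. = FALSE)
    tcol <- paste0(config$endpoint, "_time")
    ecol <- paste0(config$endpoint, "_event")
    idx <- match(assignment$sample_id, clinical$sample_id)
    times <- clinical[[tcol]][idx]
    events <- clinical[[ecol]][idx]
    ok <- !is.na(times) & !is.na(events)
    labs <- assignment$subtype[ok]
    times <- times[ok]; events <- as.logical(events[ok])

    lr <- logrank_test(times, events, labs)
    uni <- cox_fit(data.frame(subtype_cod = as.numeric(labs == "COD")),
                   times, events)
    covs <- data.frame(subtype_cod = as.numeric(labs == "COD"))
    clin_ok <- clinical[idx, ][ok, ]
    if ("age" %in% names(clin_ok)) covs$age <- clin_ok$age
    if ("sex" %in% names(clin_ok)) covs$sex_male <- as.numeric(clin_ok$sex == "male")
    if ("ajcc_stage" %in% names(clin_ok)) {
      covs$ajcc_stage <- as.numeric(clin_ok$ajcc_stage)
    }
    if ("tumor_site" %in% names(clin_ok)) {
      covs$tumor_site <- as.numeric(factor(clin_ok$tumor_site,
                                           c("cardia", "body", "antrum", "whole")))
    }
    sel <- backward_select(covs, times, events,
                           retain_p = config$thresholds$retain_p,
                           force = "subtype_cod")
    report$survival <- list(
      endpoint = config$endpoint, n = length(times), n_events = sum(events),
      logrank = result_to_list(lr),
      cox_univariate = result_to_list(uni),
      cox_multivariate = result_to_list(sel$model),
      covariates_retained = sel$retained, covariates_dropped = sel$dropped)

    if ("chemo" %in% names(clin_ok) && !all(is.na(clin_ok$chemo))) {
      has_chemo <- !is.na(clin_ok$chemo)
      ia <- interaction_analysis(labs[has_chemo], clin_ok$chemo[has_chemo],
                                 times[has_chemo], events[has_chemo])
      report$survival$chemo_interaction <- list(
        stratum_int = if (!is.null(ia$stratum$INT))
          result_to_list(ia$stratum$INT),
        stratum_cod = if (!is.null(ia$stratum$COD))
          result_to_list(ia$stratum$COD),
        interaction_p = ia$interaction_p)
    }

    km <- lapply(split(seq_along(times), labs), function(i) {
      as.data.frame(km_estimate(times[i], events[i]))
    })
    report$survival$km <- km
  }

  if (isTRUE(config$stages$mutations) && !is.null(mut) && nrow(mut) > 0) {
    if (is.null(assignment)) stop("mutations stage requires the classify stage",
                                  call. = FALSE)
    labs <- assignment$subtype
    names(labs) <- assignment$sample_id
    tmb <- suppressWarnings(compute_tmb(mut, samples = names(labs)))
    tmb_test <- compare_tmb(tmb, labs)
    screen <- per_gene_mutation_screen(mut, labs,
                                       alpha = config$thresholds$screen_alpha)
    report$mutations <- list(
      tmb_test = result_to_list(tmb_test),
      n_genes_screened = nrow(screen),
      n_significant = sum(screen$significant),
      top_genes = utils::head(screen$gene_id, 10))
    mol <- clinical$molecular_subtype[match(names(labs), clinical$sample_id)]
    names(mol) <- names(labs)
    if (sum(!is.na(mol)) >= 10 && length(unique(stats::na.omit(mol))) >= 2) {
      assoc <- molecular_subtype_association(mol, labs)
      report$mutations$molecular_association <- list(
        test = result_to_list(assoc$test),
        table = as.data.frame.matrix(assoc$table))
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    if (!is.null(sig)) write_signature(sig, file.path(config$out_dir,
                                                      "signature.json"))
    if (!is.null(assignment)) {
      write_subtypes(assignment, file.path(config$out_dir, "subtypes.tsv"))
    }
    writeLines(render_report_md(report), file.path(config$out_dir, "report.md"))
  }
  invisible(report)
}

# Human-readable summary; every number comes straight out of the JSON report.
render_report_md <- function(report) {
  ln <- c(sprintf("# codsig pipeline report (seed %d)", report$seed),
          sprintf("_Generated %s; package %s_", format(Sys.time()),
                  report$package_version), "")
  ln <- c(ln, sprintf("Cohort: %d samples x %d genes (%s).",
                      report$cohort$n_samples, report$cohort$n_genes,
                      report$cohort$source), "")
  if (!is.null(report$signature)) {
    pc <- report$signature$partition_counts
    ln <- c(ln, "## Signature derivation",
            sprintf("- %d genes passed the variance filter",
                    report$signature$n_filtered_genes),
            sprintf("- DE lists: |A| = %d, |B| = %d; only-A %d, A-and-B %d, only-B %d",
                    pc$a, pc$b, pc$only_a, pc$a_and_b, pc$only_b),
            sprintf("- signature size: %d genes",
                    report$signature$n_signature_genes), "")
  }
  if (!is.null(report$classification)) {
    ln <- c(ln, "## Classification",
            sprintf("- %d INT, %d COD (%s; %.0f%% signature-gene overlap)",
                    report$classification$n_int, report$classification$n_cod,
                    report$classification$method,
                    100 * report$classification$overlap), "")
  }
  if (!is.null(report$survival)) {
    sv <- report$survival
    ln <- c(ln, "## Survival",
            sprintf("- endpoint %s: n = %d, events = %d", sv$endpoint, sv$n,
                    sv$n_events),
            sprintf("- log-rank COD vs INT: chi-square = %.3g, p = %.3g",
                    sv$logrank$statistic, sv$logrank$p_value),
            sprintf("- univariate Cox subtype HR = %.3g (p = %.3g)",
                    sv$cox_univariate$terms$hr[1],
                    sv$cox_univariate$terms$p_value[1]))
    if (!is.null(sv$cox_multivariate)) {
      i <- which(sv$cox_multivariate$terms$term == "subtype_cod")
      ln <- c(ln, sprintf("- multivariate Cox subtype HR = %.3g (%.3g-%.3g), p = %.3g",
                          sv$cox_multivariate$terms$hr[i],
                          sv$cox_multivariate$terms$ci_lower[i],
                          sv$cox_multivariate$terms$ci_upper[i],
                          sv$cox_multivariate$terms$p_value[i]))
    }
    ci <- sv$chemo_interaction
    if (!is.null(ci)) {
      if (!is.null(ci$stratum_cod)) {
        ln <- c(ln, sprintf("- chemo HR within COD = %.3g (p = %.3g)",
                            ci$stratum_cod$terms$hr[1],
                            ci$stratum_cod$terms$p_value[1]))
      }
      if (!is.null(ci$stratum_int)) {
        ln <- c(ln, sprintf("- chemo HR within INT = %.3g (p = %.3g)",
                            ci$stratum_int$terms$hr[1],
                            ci$stratum_int$terms$p_value[1]))
      }
      ln <- c(ln, sprintf("- subtype x chemo interaction p = %.3g",
                          ci$interaction_p))
    }
    ln <- c(ln, "")
  }
  if (!is.null(report$mutations)) {
    mu <- report$mutations
    ln <- c(ln, "## Mutations",
            sprintf("- TMB %s: t = %.3g, p = %.3g (means INT %.3g, COD %.3g)",
                    mu$tmb_test$extra$direction, mu$tmb_test$statistic,
                    mu$tmb_test$p_value, mu$tmb_test$extra$mean_int,
                    mu$tmb_test$extra$mean_cod),
            sprintf("- per-gene screen: %d of %d genes significant",
                    mu$n_significant, mu$n_genes_screened))
    if (!is.null(mu$molecular_association)) {
      ln <- c(ln, sprintf("- molecular-subtype association: chi-square = %.3g, p = %.3g",
                          mu$molecular_association$test$statistic,
                          mu$molecular_association$test$p_value))
    }
    ln <- c(ln, "")
  }
  ln
}
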