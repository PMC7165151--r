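#' Simulation configuration for synthetic gastric-cancer cohorts
#'
#' Describes a cohort with the latent structure the signature pipeline
#' assumes: three expression groups (normal-like, intestinal-like, core
#' diffuse-type) carrying group-specific gene modules, subtype-dependent
#' proportional-hazards survival with independent right-censoring, a
#' chemotherapy effect concentrated in the COD subtype, and higher mutation
#' burden in the INT subtype with designated marker loci.
#'
#' Default sample counts mirror a 150-sample discovery cohort (20 normal,
#' 23 intestinal-type, 107 diffuse-type); default module sizes are 252
#' (INT module, proliferation/DNA-repair-like) and 397 (COD module,
#' EMT-like). Default per-subtype chemotherapy hazard ratios are 0.333 (COD)
#' and 0.576 (INT).
#'
#' @param n_normal,n_intestinal,n_diffuse Sample counts per histology.
#' @param n_genes Total genes simulated.
#' @param n_int_module,n_cod_module Module sizes (disjoint gene sets).
#' @param effect_size Mean log2 up-shift of module genes in their subtype.
#' @param noise_sd Per-gene Gaussian noise SD (log2 units).
#' @param diffuse_subtype_props Length-3 proportions of diffuse samples that
#'   are latently N-like / INT-like / COD-like; must sum to 1.
#' @param normal_fraction Mixing weight of the normal profile in N-like
#'   diffuse tumors (these tumors express mostly normal stomach patterns;
#'   the remainder leaks from the COD profile).
#' @param baseline_hazard Event hazard (per month) in the INT reference arm.
#' @param true_hr_cod Hazard ratio of COD vs INT.
#' @param censor_rate Independent exponential censoring rate (per month);
#'   0 disables random censoring.
#' @param admin_horizon Administrative censoring time in months (`Inf` to
#'   disable).
#' @param weibull_shape Weibull shape for event times; 1 = exponential
#'   (proportional hazards hold exactly for any shape).
#' @param chemo_assign_prob Probability a diffuse-type patient received
#'   adjuvant chemotherapy.
#' @param chemo_hr_cod,chemo_hr_int Chemotherapy hazard ratios within the
#'   COD and INT subtypes.
#' @param dfs_hazard_mult Hazard multiplier for the disease-free-survival
#'   endpoint relative to overall survival (recurrence precedes death).
#' @param tmb_mean_int,tmb_mean_cod Mean nonsynonymous mutation counts per
#'   sample by subtype.
#' @param tmb_dispersion Negative-binomial size parameter for mutation
#'   counts (overdispersion; `Inf` approximates Poisson).
#' @param marker_gene_freqs Named list `gene -> c(freq_int, freq_cod)` of
#'   per-subtype mutation probabilities for designated loci. Defaults emulate
#'   a MUC16-like locus enriched in COD and PIK3CA/ARID1A-like loci enriched
#'   in INT.
#' @param stage_hr Per-stage hazard ratio (AJCC stage treated as ordinal);
#'   1 = stage carries no survival information.
#' @param age_log_hr Log hazard ratio per year of age (centred at 60);
#'   0 = age carries no survival information.
#' @param seed Integer seed; every random draw flows from it.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_normal = 20, n_intestinal = 23, n_diffuse = 107,
                              n_genes = 2000,
                              n_int_module = 252, n_cod_module = 397,
                              effect_size = 1.0, noise_sd = 1.0,
                              diffuse_subtype_props = c(0.15, 0.35, 0.50),
                              normal_fraction = 0.9,
                              baseline_hazard = 0.01, true_hr_cod = 2.0,
                              censor_rate = 0.006, admin_horizon = Inf,
                              weibull_shape = 1,
                              chemo_assign_prob = 0.5,
                              chemo_hr_cod = 0.333, chemo_hr_int = 0.576,
                              dfs_hazard_mult = 1.3,
                              tmb_mean_int = 8, tmb_mean_cod = 2,
                              tmb_dispersion = 2,
                              marker_gene_freqs = list(
                                MUC16_like  = c(0.15, 0.42),
                                PIK3CA_like = c(0.25, 0.05),
                                ARID1A_like = c(0.30, 0.08)),
                              stage_hr = 1, age_log_hr = 0,
                              seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_normal, n_intestinal, n_diffuse, n_genes,
              n_int_module, n_cod_module)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("sample/gene counts must be positive integers", call. = FALSE)
  }
  if (n_int_module + n_cod_module > n_genes) {
    stop("module sizes exceed n_genes", call. = FALSE)
  }
  if (length(diffuse_subtype_props) != 3 ||
      abs(sum(diffuse_subtype_props) - 1) > 1e-8 ||
      any(diffuse_subtype_props < 0)) {
    stop("diffuse_subtype_props must be 3 nonnegative proportions summing to 1",
         call. = FALSE)
  }
  if (normal_fraction < 0 || normal_fraction > 1) {
    stop("normal_fraction must be in [0, 1]", call. = FALSE)
  }
  if (baseline_hazard < 0 || censor_rate < 0) {
    stop("hazard rates must be nonnegative", call. = FALSE)
  }
  hrs <- c(true_hr_cod, chemo_hr_cod, chemo_hr_int, stage_hr, dfs_hazard_mult)
  if (any(hrs <= 0)) stop("hazard ratios must be positive", call. = FALSE)
  if (noise_sd < 0 || effect_size < 0) {
    stop("noise_sd and effect_size must be nonnegative", call. = FALSE)
  }
  if (chemo_assign_prob < 0 || chemo_assign_prob > 1) {
    stop("chemo_assign_prob must be a probability", call. = FALSE)
  }
  if (weibull_shape <= 0 || tmb_dispersion <= 0) {
    stop("weibull_shape and tmb_dispersion must be positive", call. = FALSE)
  }
  if (any(vapply(marker_gene_freqs, length, 1L) != 2) ||
      any(unlist(marker_gene_freqs) < 0) || any(unlist(marker_gene_freqs) > 1)) {
    stop("marker_gene_freqs entries must be c(freq_int, freq_cod) probabilities",
         call. = FALSE)
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic split of n into groups by proportions (largest-remainder).
proportion_counts <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Event-time draw under a Weibull proportional-hazards model:
# S(t) = exp(-rate * t^shape), so T = (E / rate)^(1/shape), E ~ Exp(1).
ph_weibull_times <- function(rates, shape) {
  e <- stats::rexp(length(rates))
  ifelse(rates > 0, (e / rates)^(1 / shape), Inf)
}

# Core survival generator; assumes the RNG state is already seeded.
generate_survival <- function(hr, config, hazard_mult = 1) {
  n <- length(hr)
  rates <- config$baseline_hazard * hr * hazard_mult
  t_event <- ph_weibull_times(rates, config$weibull_shape)
  t_cens <- if (config$censor_rate > 0) stats::rexp(n, config$censor_rate)
            else rep(Inf, n)
  t_cens <- pmin(t_cens, config$admin_horizon)
  if (any(is.infinite(t_event) & is.infinite(t_cens))) {
    stop("baseline_hazard = 0 requires a finite censor_rate or admin_horizon",
         call. = FALSE)
  }
  list(time = pmin(t_event, t_cens), event = t_event <= t_cens)
}

#' Simulate survival outcomes for labelled samples
#'
#' Draws event times from the configured proportional-hazards model
#' (hazard = `baseline_hazard` x `true_hr_cod`^[COD] x per-subtype
#' chemotherapy HR for treated patients), with independent exponential
#' and/or administrative censoring.
#'
#' @param labels Character vector of subtype labels, `"INT"` or `"COD"`.
#' @param config A [simulation_config()].
#' @param chemo Optional logical vector of treatment flags; drawn Bernoulli
#'   (`chemo_assign_prob`) when `NULL`.
#' @param seed Seed for this draw (defaults to `config$seed`).
#' @return A data.frame with columns `time` (months), `event` (logical),
#'   `chemo` (logical).
#' @export
simulate_survival <- function(labels, config = simulation_config(),
                              chemo = NULL, seed = config$seed) {
  if (length(labels) == 0) stop("empty label vector", call. = FALSE)
  if (!all(labels %in% c("INT", "COD"))) {
    stop("labels must be 'INT' or 'COD'", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(chemo)) {
    chemo <- stats::runif(length(labels)) < config$chemo_assign_prob
  }
  stopifnot(length(chemo) == length(labels))
  hr <- ifelse(labels == "COD", config$true_hr_cod, 1) *
    ifelse(chemo, ifelse(labels == "COD", config$chemo_hr_cod,
                         config$chemo_hr_int), 1)
  s <- generate_survival(hr, config)
  data.frame(time = s$time, event = s$event, chemo = chemo)
}

#' Simulate a full synthetic cohort
#'
#' Generates, from one seed, the three pipeline inputs plus ground truth:
#' \itemize{
#'   \item expression: per-gene baseline ~ N(6, 1) plus module shifts plus
#'     N(0, `noise_sd`) noise. INT-module genes are shifted up by
#'     `effect_size` in intestinal-type samples and INT-like diffuse tumors;
#'     COD-module genes in COD-like diffuse tumors. N-like diffuse tumors are
#'     a `normal_fraction` : (1 - `normal_fraction`) mixture of the normal
#'     and COD profiles.
#'   \item clinical: histology, PCC flag (enriched in COD-like tumors), age,
#'     sex, AJCC stage, tumor site, chemotherapy flag, OS and DFS under the
#'     configured hazards, and a TCGA-style molecular subtype (MSI/EBV
#'     enriched in INT-like, GS in COD-like tumors).
#'   \item mutations: per diffuse sample a negative-binomial nonsynonymous
#'     background count (INT-like mean `tmb_mean_int`, others
#'     `tmb_mean_cod`) spread uniformly over genes, plus marker loci drawn
#'     at their per-subtype frequencies.
#' }
#'
#' @param config A [simulation_config()].
#' @return A list with elements `expression` ([expression_matrix()]),
#'   `clinical` ([cohort_annotation()]), `mutations` ([mutation_table()])
#'   and `truth` (list: `latent` data.frame of per-sample latent classes,
#'   `int_module_genes`, `cod_module_genes`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  module_idx <- sample.int(config$n_genes,
                           config$n_int_module + config$n_cod_module)
  int_genes <- gene_ids[module_idx[seq_len(config$n_int_module)]]
  cod_genes <- gene_ids[module_idx[config$n_int_module + seq_len(config$n_cod_module)]]

  sample_ids <- c(sprintf("N%03d", seq_len(config$n_normal)),
                  sprintf("I%03d", seq_len(config$n_intestinal)),
                  sprintf("D%03d", seq_len(config$n_diffuse)))
  histology <- rep(c("normal", "intestinal", "diffuse"),
                   c(config$n_normal, config$n_intestinal, config$n_diffuse))
  d_counts <- proportion_counts(config$n_diffuse, config$diffuse_subtype_props)
  latent_diffuse <- sample(rep(c("n_like", "int_like", "cod_like"), d_counts))
  latent <- c(rep("normal", config$n_normal),
              rep("intestinal", config$n_intestinal), latent_diffuse)
  n <- length(sample_ids)

  # expression: baseline + module shifts + noise
  baseline <- stats::rnorm(config$n_genes, 6, 1)
  shift <- matrix(0, config$n_genes, n, dimnames = list(gene_ids, sample_ids))
  int_up <- latent %in% c("intestinal", "int_like")
  shift[int_genes, int_up] <- config$effect_size
  shift[cod_genes, latent == "cod_like"] <- config$effect_size
  shift[cod_genes, latent == "n_like"] <-
    (1 - config$normal_fraction) * config$effect_size
  values <- baseline + shift +
    matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
           config$n_genes, n)
  expr <- expression_matrix(values, gene_ids, sample_ids)

  # clinical covariates
  age <- pmin(pmax(round(stats::rnorm(n, 62, 11)), 28), 90)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.6, 0.4))
  stage <- rep(NA_character_, n)
  tumor <- histology != "normal"
  stage[tumor] <- sample(c("I", "II", "III", "IV"), sum(tumor), replace = TRUE,
                         prob = c(0.15, 0.3, 0.4, 0.15))
  site <- rep(NA_character_, n)
  site[tumor] <- sample(c("cardia", "body", "antrum", "whole"), sum(tumor),
                        replace = TRUE, prob = c(0.1, 0.4, 0.4, 0.1))
  pcc <- rep(NA, n)
  pcc[tumor] <- stats::runif(sum(tumor)) <
    ifelse(latent[tumor] == "cod_like", 0.45, 0.10)

  # molecular subtype (diffuse only): MSI/EBV lean INT-like, GS leans COD-like
  mol <- rep(NA_character_, n)
  is_d <- histology == "diffuse"
  int_like <- latent == "int_like"
  mol[is_d & int_like] <- sample(c("MSI", "EBV", "CIN", "GS"),
                                 sum(is_d & int_like), replace = TRUE,
                                 prob = c(0.20, 0.15, 0.45, 0.20))
  mol[is_d & !int_like] <- sample(c("MSI", "EBV", "CIN", "GS"),
                                  sum(is_d & !int_like), replace = TRUE,
                                  prob = c(0.01, 0.04, 0.35, 0.60))

  # survival (diffuse-type patients): COD-like carries true_hr_cod; optional
  # stage/age effects; chemotherapy benefit differs by subtype
  chemo <- rep(NA, n)
  chemo[is_d] <- stats::runif(sum(is_d)) < config$chemo_assign_prob
  stage_ord <- as.integer(factor(stage, levels = c("I", "II", "III", "IV")))
  hr <- rep(NA_real_, n)
  is_cod <- latent == "cod_like"
  hr[is_d] <- ifelse(is_cod[is_d], config$true_hr_cod, 1) *
    ifelse(chemo[is_d],
           ifelse(is_cod[is_d], config$chemo_hr_cod, config$chemo_hr_int), 1) *
    config$stage_hr^(stage_ord[is_d] - 2) *
    exp(config$age_log_hr * (age[is_d] - 60))
  os_time <- os_event <- dfs_time <- dfs_event <- rep(NA_real_, n)
  os <- generate_survival(hr[is_d], config)
  dfs <- generate_survival(hr[is_d], config, hazard_mult = config$dfs_hazard_mult)
  os_time[is_d] <- round(os$time, 2); os_event[is_d] <- as.numeric(os$event)
  dfs_time[is_d] <- round(dfs$time, 2); dfs_event[is_d] <- as.numeric(dfs$event)

  clinical <- cohort_annotation(data.frame(
    sample_id = sample_ids, histology = histology, pcc = pcc, age = age,
    sex = sex, ajcc_stage = stage, tumor_site = site, chemo = chemo,
    dfs_time = dfs_time, dfs_event = dfs_event,
    os_time = os_time, os_event = os_event,
    molecular_subtype = mol, stringsAsFactors = FALSE))

  # mutations (diffuse samples): NB background counts + marker loci
  d_ids <- sample_ids[is_d]
  mu <- ifelse(int_like[is_d], config$tmb_mean_int, config$tmb_mean_cod)
  counts <- stats::rnbinom(length(d_ids), size = config$tmb_dispersion, mu = mu)
  classes <- c("missense_mutation", "nonsense_mutation", "frame_shift_del",
               "splice_site")
  recs <- vector("list", length(d_ids))
  marker_names <- names(config$marker_gene_freqs)
  background <- setdiff(gene_ids, marker_names)
  for (i in seq_along(d_ids)) {
    g <- if (counts[i] > 0) sample(background, min(counts[i], length(background)))
         else character(0)
    freq_col <- if (int_like[is_d][i]) 1L else 2L
    hits <- marker_names[stats::runif(length(marker_names)) <
                           vapply(config$marker_gene_freqs, `[`, 0, freq_col)]
    g <- c(g, hits)
    if (length(g) == 0) next
    recs[[i]] <- data.frame(
      sample_id = d_ids[i], gene_id = g,
      variant_class = sample(classes, length(g), replace = TRUE,
                             prob = c(0.7, 0.1, 0.1, 0.1)),
      stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  mut <- mutation_table(if (length(recs)) do.call(rbind, recs)
                        else data.frame(sample_id = character(0),
                                        gene_id = character(0),
                                        variant_class = character(0)))

  list(expression = expr, clinical = clinical, mutations = mut,
       truth = list(latent = data.frame(sample_id = sample_ids,
                                        latent_class = latent,
                                        stringsAsFactors = FALSE),
                    int_module_genes = int_genes,
                    cod_module_genes = cod_genes))
}
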