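test_that("config invariants are enforced", {
  expect_error(simulation_config(n_genes = 100, n_int_module = 80,
                                 n_cod_module = 30), "module sizes")
  expect_error(simulation_config(diffuse_subtype_props = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(simulation_config(true_hr_cod = -1), "positive")
  expect_error(simulation_config(n_diffuse = 0), "positive integers")
})

test_that("zero-noise limit gives exact module shifts", {
  cfg <- simulation_config(noise_sd = 0, effect_size = 1,
                           n_genes = 200, n_int_module = 20, n_cod_module = 30,
                           n_normal = 5, n_intestinal = 5, n_diffuse = 20,
                           seed = 3)
  co <- simulate_cohort(cfg)
  lat <- co$truth$latent
  cod_s <- lat$sample_id[lat$latent_class == "cod_like"]
  int_s <- lat$sample_id[lat$latent_class == "int_like"]
  diffs <- rowMeans(unclass(co$expression)[co$truth$cod_module_genes, cod_s]) -
    rowMeans(unclass(co$expression)[co$truth$cod_module_genes, int_s])
  expect_equal(unname(diffs), rep(1, length(diffs)))
})

test_that("censoring controls behave at the boundaries", {
  cfg0 <- simulation_config(censor_rate = 0, seed = 4)
  s <- simulate_survival(rep(c("INT", "COD"), 50), cfg0)
  expect_true(all(s$event))

  cfg_h <- simulation_config(baseline_hazard = 0, censor_rate = 0,
                             admin_horizon = 60, seed = 4)
  s2 <- simulate_survival(rep("INT", 40), cfg_h)
  expect_true(all(!s2$event))
  expect_true(all(s2$time == 60))
})

test_that("identical config and seed reproduce the cohort bit-identically", {
  cfg <- simulation_config(n_genes = 300, n_int_module = 20, n_cod_module = 30,
                           n_normal = 5, n_intestinal = 5,
                           n_diffuse = 30, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(simulate_survival(rep(c("INT", "COD"), 10), cfg),
                   simulate_survival(rep(c("INT", "COD"), 10), cfg))
})

test_that("survival times follow the configured exponential law", {
  cfg <- simulation_config(censor_rate = 0, baseline_hazard = 0.02, seed = 12)
  s <- simulate_survival(rep("INT", 5000), cfg, chemo = rep(FALSE, 5000))
  ks <- ks.test(s$time, "pexp", rate = 0.02)
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical event-rate ratio recovers the configured hazard ratio", {
  cfg <- simulation_config(censor_rate = 0, true_hr_cod = 2, seed = 21)
  labs <- rep(c("INT", "COD"), each = 1000)
  s <- simulate_survival(labs, cfg, chemo = rep(FALSE, 2000))
  rate <- function(g) sum(s$event[labs == g]) / sum(s$time[labs == g])
  expect_lt(abs(rate("COD") / rate("INT") - 2), 0.2) # exponential MLE, +-10%
})

test_that("mean TMB ordering matches the config in nearly all replicates", {
  hits <- vapply(1:40, function(i) {
    cfg <- simulation_config(n_genes = 150, n_int_module = 10,
                             n_cod_module = 15, n_normal = 3, n_intestinal = 3,
                             n_diffuse = 400,
                             diffuse_subtype_props = c(0, 0.5, 0.5),
                             seed = 1000 + i)
    co <- simulate_cohort(cfg)
    lat <- co$truth$latent
    tmb <- suppressWarnings(
      compute_tmb(co$mutations,
                  samples = lat$sample_id[lat$latent_class != "normal" &
                                            startsWith(lat$sample_id, "D")]))
    int_s <- lat$sample_id[lat$latent_class == "int_like"]
    cod_s <- lat$sample_id[lat$latent_class == "cod_like"]
    mean(tmb[int_s]) > mean(tmb[cod_s])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("larger effect sizes never blur the latent groups", {
  sep <- function(effect, seed) {
    cfg <- simulation_config(n_genes = 120, n_int_module = 15,
                             n_cod_module = 20, n_normal = 6, n_intestinal = 6,
                             n_diffuse = 24, effect_size = effect,
                             noise_sd = 0.6, seed = seed)
    co <- simulate_cohort(cfg)
    lat <- co$truth$latent$latent_class
    # mean between-group minus mean within-group euclidean distance
    d <- as.matrix(dist(t(unclass(co$expression))))
    same <- outer(lat, lat, "==") & upper.tri(d)
    diffr <- (!outer(lat, lat, "==")) & upper.tri(d)
    mean(d[diffr]) - mean(d[same])
  }
  gaps <- vapply(1:20, function(i) {
    sep(2, 500 + i) - sep(0.5, 500 + i)
  }, 0)
  expect_gt(mean(gaps), 0) # separation grows with effect size in expectation
})

test_that("marker loci hit their per-subtype mutation frequencies", {
  cfg <- simulation_config(n_genes = 200, n_int_module = 10, n_cod_module = 10,
                           n_normal = 3, n_intestinal = 3, n_diffuse = 2000,
                           diffuse_subtype_props = c(0, 0.5, 0.5), seed = 31)
  co <- simulate_cohort(cfg)
  lat <- co$truth$latent
  int_s <- lat$sample_id[lat$latent_class == "int_like"]
  cod_s <- lat$sample_id[lat$latent_class == "cod_like"]
  expect_lt(abs(mutation_rate(co$mutations, "MUC16_like", cod_s) - 0.42), 0.05)
  expect_lt(abs(mutation_rate(co$mutations, "MUC16_like", int_s) - 0.15), 0.05)
  expect_gt(mutation_rate(co$mutations, "PIK3CA_like", int_s),
            mutation_rate(co$mutations, "PIK3CA_like", cod_s))
})

test_that("simulate_survival validates its inputs", {
  cfg <- simulation_config()
  expect_error(simulate_survival(character(0), cfg), "empty")
  expect_error(simulate_survival(c("INT", "weird"), cfg), "INT")
})
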