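toy_mutations <- function() {
  mutation_table(data.frame(
    sample_id = c("s1", "s1", "s1", "s1", "s1", "s2", "s2"),
    gene_id = c("gA", "gA", "gB", "gC", "gC", "gA", "gB"),
    variant_class = c("missense_mutation", "missense_mutation",
                      "missense_mutation", "silent", "silent",
                      "missense_mutation", "silent")))
}

test_that("compute_tmb counts included classes per sample", {
  mut <- toy_mutations()
  tmb <- suppressWarnings(compute_tmb(mut, samples = c("s1", "s2", "s3")))
  expect_equal(unname(tmb["s1"]), 3) # 3 missense, 2 silent excluded
  expect_equal(unname(tmb["s2"]), 1)
  expect_equal(unname(tmb["s3"]), 0)
  expect_warning(compute_tmb(mut, samples = c("s1", "s3")), "absent")

  per_mb <- suppressWarnings(compute_tmb(
    mutation_table(data.frame(sample_id = "s1", gene_id = sprintf("g%d", 1:76),
                              variant_class = "missense_mutation")),
    per_mb = TRUE, exome_size_mb = 38))
  expect_equal(unname(per_mb["s1"]), 2)
  expect_error(compute_tmb(mut, classes = character(0)), "empty")
})

test_that("compute_tmb is additive over a split by gene", {
  cfg <- simulation_config(n_genes = 150, n_int_module = 10, n_cod_module = 10,
                           n_normal = 3, n_intestinal = 3, n_diffuse = 40,
                           seed = 8)
  mut <- simulate_cohort(cfg)$mutations
  samples <- sort(unique(mut$sample_id))
  total <- compute_tmb(mut, samples = samples)
  parts <- lapply(split(seq_len(nrow(mut)), mut$gene_id), function(i) {
    m <- mutation_table(as.data.frame(mut)[i, ])
    suppressWarnings(compute_tmb(m, samples = samples))
  })
  expect_equal(unname(Reduce(`+`, parts)), unname(total))
})

test_that("compare_tmb reports direction and reacts to real differences", {
  labs <- setNames(rep(c("INT", "COD"), each = 30), sprintf("x%d", 1:60))
  set.seed(4)
  same <- structure(setNames(rnbinom(60, mu = 5, size = 3), names(labs)),
                    class = "tmb_vector")
  r0 <- compare_tmb(same, labs)
  expect_gt(r0$p_value, 0.001)

  tied <- structure(setNames(rep(c(2, 2), 30), names(labs)), class = "tmb_vector")
  expect_equal(compare_tmb(tied, labs)$extra$direction, "none")

  hits <- vapply(1:40, function(i) {
    set.seed(100 + i)
    tmb <- structure(setNames(c(rnbinom(30, mu = 8, size = 2),
                                rnbinom(30, mu = 2, size = 2)), names(labs)),
                     class = "tmb_vector")
    compare_tmb(tmb, labs)$p_value < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  one <- setNames(c(5, rnbinom(30, mu = 5, size = 2)),
                  c("a", sprintf("x%d", 31:60)))
  expect_error(compare_tmb(structure(one, class = "tmb_vector"),
                           c(setNames("INT", "a"), labs[31:60])), ">= 2")
})

test_that("per-gene screen builds correct tables and flags planted markers", {
  labs <- setNames(rep(c("INT", "COD"), each = 4), sprintf("p%d", 1:8))
  mut <- mutation_table(data.frame(
    sample_id = c(sprintf("p%d", 1:8), "p1", "p2", "p5"),
    gene_id = c(rep("everywhere", 8), "intish", "intish", "codish"),
    variant_class = "missense_mutation"))
  res <- per_gene_mutation_screen(mut, labs)
  expect_equal(res$p_value[res$gene_id == "everywhere"], 1)
  row <- res[res$gene_id == "intish", ]
  expect_equal(unname(unlist(row[c("mut_int", "wt_int", "mut_cod", "wt_cod")])),
               c(2, 2, 0, 4))
  # record order invariance
  shuffled <- mutation_table(as.data.frame(mut)[sample(nrow(mut)), ])
  expect_equal(per_gene_mutation_screen(shuffled, labs), res)

  # a strongly contrasted marker is flagged in nearly all replicates
  hits <- vapply(1:40, function(i) {
    set.seed(300 + i)
    carriers <- c(sprintf("i%d", which(runif(30) < 0.05)),
                  sprintf("c%d", which(runif(30) < 0.5)))
    labs2 <- setNames(rep(c("INT", "COD"), each = 30),
                      c(sprintf("i%d", 1:30), sprintf("c%d", 1:30)))
    if (length(carriers) == 0) return(FALSE)
    m <- mutation_table(data.frame(sample_id = carriers, gene_id = "marker",
                                   variant_class = "missense_mutation"))
    out <- per_gene_mutation_screen(m, labs2, alpha = 0.05)
    out$significant[out$gene_id == "marker"]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("mutation_rate reproduces a printed-style percentage", {
  mut <- mutation_table(data.frame(sample_id = sprintf("s%d", 1:14),
                                   gene_id = "MUC16_like",
                                   variant_class = "missense_mutation"))
  rate <- mutation_rate(mut, "MUC16_like", sprintf("s%d", 1:45))
  expect_equal(round(100 * rate, 1), 31.1) # 14 mutated of 45
  expect_equal(mutation_rate(mut, "MUC16_like", sprintf("s%d", 1:14)), 1)
  expect_warning(r0 <- mutation_rate(mut, "nope", sprintf("s%d", 1:5)), "absent")
  expect_equal(r0, 0)
  expect_error(mutation_rate(mut, "MUC16_like", character(0)), "empty")
})

test_that("molecular-subtype association detects planted structure", {
  # all MSI in INT, all GS in COD, CIN split
  labs <- setNames(rep(c("INT", "COD"), each = 30), sprintf("m%d", 1:60))
  mol <- setNames(c(rep("MSI", 7), rep("EBV", 4), rep("CIN", 19),
                    rep("GS", 12), rep("EBV", 2), rep("CIN", 16)),
                  names(labs))
  res <- molecular_subtype_association(mol, labs)
  expect_lt(res$test$p_value, 0.01)
  expect_equal(unname(res$table["MSI", "COD"]), 0)
  expect_equal(unname(res$composition["MSI"]), 1)

  expect_error(molecular_subtype_association(
    setNames(rep("GS", 60), names(labs)), labs), ">= 2 molecular classes")

  # independence: p roughly uniform under the null
  set.seed(9)
  ps <- replicate(30, {
    mol0 <- setNames(sample(c("MSI", "CIN", "GS"), 60, replace = TRUE,
                            prob = c(0.2, 0.4, 0.4)), names(labs))
    molecular_subtype_association(mol0, labs)$test$p_value
  })
  # chi-square p-values are discrete here; a coarse calibration check only
  expect_lte(mean(ps < 0.05), 0.25)
  expect_gte(mean(ps > 0.2), 0.4)
})
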