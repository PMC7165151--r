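test_that("variance_filter applies a strict SD cutoff", {
  # per-gene sample SDs engineered by hand
  mk <- function(sd_target) c(-1, 1) * sd_target / sqrt(2)
  expr <- tiny_expr(rbind(mk(1.2), mk(0.9), mk(0.3), mk(2.0), c(0, 0)),
                    sprintf("g%d", 1:5))
  expect_equal(variance_filter(expr, 0.9), c("g1", "g4"))
  expect_equal(variance_filter(expr, 0), c("g1", "g2", "g3", "g4"))
  expect_error(variance_filter(tiny_expr(matrix(1, 2, 1)), 0.5), ">= 2 samples")
})

test_that("lowering the SD threshold never removes genes", {
  set.seed(23)
  expr <- tiny_expr(matrix(rnorm(400, sd = rep(runif(40, 0, 2), 10)), 40, 10))
  ths <- sort(runif(6, 0, 1.5), decreasing = TRUE)
  sets <- lapply(ths, function(t) variance_filter(expr, t))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("hierarchical clustering recovers separated groups deterministically", {
  sc <- separated_cohort()
  model <- hierarchical_cluster(sc$expr, k = 3)
  expect_equal(rand_index(model$cluster, sc$groups), 1)

  # k = n: every sample its own cluster
  kn <- hierarchical_cluster(sc$expr, k = ncol(sc$expr))
  expect_equal(length(unique(kn$cluster)), ncol(sc$expr))

  # column permutation leaves the partition unchanged up to relabeling
  perm <- sample(ncol(sc$expr))
  permuted <- expression_matrix(unclass(sc$expr)[, perm])
  m2 <- hierarchical_cluster(permuted, k = 3)
  expect_equal(rand_index(m2$cluster[colnames(sc$expr)], model$cluster), 1)

  flat <- tiny_expr(cbind(matrix(rnorm(20), 10), rep(1, 10)))
  expect_error(hierarchical_cluster(flat, k = 2), "zero-variance sample")
})

test_that("label_clusters maps composition to N/INT/COD and detects ties", {
  sc <- separated_cohort()
  model <- hierarchical_cluster(sc$expr, k = 3)
  ann <- cohort_annotation(data.frame(
    sample_id = colnames(sc$expr),
    histology = c("normal", "normal", "normal", "diffuse",
                  "intestinal", "intestinal", "intestinal", "diffuse",
                  "diffuse", "diffuse", "diffuse", "diffuse")))
  labels <- label_clusters(model, ann)
  expect_setequal(labels, c("N", "INT", "COD"))
  expect_equal(unname(labels[as.character(model$cluster[1]) ]), "N")
  expect_equal(unname(labels[as.character(model$cluster[5]) ]), "INT")
  expect_equal(unname(labels[as.character(model$cluster[9]) ]), "COD")

  # all-diffuse composition: normal and intestinal fractions tie at 0
  ann_tie <- cohort_annotation(data.frame(sample_id = colnames(sc$expr),
                                          histology = "diffuse"))
  expect_error(label_clusters(model, ann_tie), "ambiguous")
  expect_error(label_clusters(hierarchical_cluster(sc$expr, k = 2), ann),
               "k = 3")
})

test_that("differential_genes finds planted shifts and respects thresholds", {
  set.seed(9)
  mat <- matrix(rnorm(50 * 40), 50, 40,
                dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:40)))
  mat["g7", 1:20] <- mat["g7", 1:20] + 10
  expr <- expression_matrix(mat)
  hits <- differential_genes(expr, sprintf("s%d", 1:20), sprintf("s%d", 21:40),
                             p_threshold = 0.001)
  expect_true("g7" %in% hits)
  expect_equal(differential_genes(expr, sprintf("s%d", 1:20),
                                  sprintf("s%d", 21:40), p_threshold = 0),
               character(0))
  expect_error(differential_genes(expr, c("s1", "s2"), c("s2", "s3"), 0.05),
               "overlap")
  # BH mode is at least as conservative as the unadjusted screen
  bh <- differential_genes(expr, sprintf("s%d", 1:20), sprintf("s%d", 21:40),
                           p_threshold = 0.001, adjust = "BH")
  expect_true(all(bh %in% hits))
})

test_that("venn_partition reproduces the worked example and its identities", {
  a <- sprintf("a%d", 1:737)
  b <- c(a[1:147], sprintf("b%d", 1:1922))
  part <- venn_partition(a, b)
  expect_equal(unname(part$counts["only_a"]), 590)
  expect_equal(unname(part$counts["a_and_b"]), 147)
  expect_equal(unname(part$counts["only_b"]), 1922)

  same <- venn_partition(a, a)
  expect_equal(length(same$only_a), 0)
  expect_equal(length(same$only_b), 0)

  disj <- venn_partition(c("x", "y"), c("z"))
  expect_equal(length(disj$a_and_b), 0)
  expect_equal(disj$only_a, c("x", "y"))

  set.seed(13)
  for (i in 1:30) {
    u <- sprintf("g%d", 1:60)
    A <- sample(u, sample(0:40, 1)); B <- sample(u, sample(0:40, 1))
    p <- venn_partition(A, B)
    expect_equal(length(p$only_a) + length(p$a_and_b), length(unique(A)))
    expect_equal(length(p$only_b) + length(p$a_and_b), length(unique(B)))
    expect_equal(length(intersect(p$only_a, p$only_b)), 0)
    expect_equal(length(intersect(p$only_a, p$a_and_b)), 0)
  }
})

test_that("derive_signature composes the stages and is deterministic", {
  cfg <- simulation_config(n_genes = 500, n_int_module = 40, n_cod_module = 60,
                           n_normal = 8, n_intestinal = 8, n_diffuse = 60,
                           effect_size = 2, noise_sd = 0.5, seed = 14)
  co <- simulate_cohort(cfg)
  sig1 <- derive_signature(co$expression, co$clinical)
  sig2 <- derive_signature(co$expression, co$clinical)
  expect_identical(sig1, sig2)
  expect_gt(mean(co$truth$cod_module_genes %in% sig1$gene_ids), 0.8)
  expect_true(all(sig1$directions %in% c(-1L, 1L)))
  expect_true(all(names(sig1$directions) == sig1$gene_ids))
  # planted COD-module genes are up in COD
  planted <- intersect(co$truth$cod_module_genes, sig1$gene_ids)
  expect_true(all(sig1$directions[planted] == 1L))
})

test_that("derive_signature fails at the DE stage without diffuse samples", {
  cfg <- simulation_config(n_genes = 300, n_int_module = 20, n_cod_module = 30,
                           n_normal = 10, n_intestinal = 10, n_diffuse = 20,
                           effect_size = 3, noise_sd = 0.3, seed = 15)
  co <- simulate_cohort(cfg)
  clin <- co$clinical
  clin$histology[clin$histology == "diffuse"] <- NA
  expect_error(derive_signature(co$expression, clin),
               "\\[differential_genes\\].*diffuse")
})

test_that("signature JSON round-trips", {
  sig <- structure(list(gene_ids = c("gA", "gB"),
                        directions = c(gA = 1L, gB = -1L),
                        partition = venn_partition("x", c("gA", "gB", "x")),
                        cluster_labels = NULL, clusters = NULL,
                        sd_threshold = 0.9, p_threshold = 0.001,
                        distance = "one_minus_pearson", linkage = "average",
                        n_filtered_genes = 10L),
                   class = "cod_signature")
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$gene_ids, sig$gene_ids)
  expect_equal(back$directions, sig$directions)
  expect_equal(back$sd_threshold, 0.9)
})
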