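# shared fixture builders and independent oracles

tiny_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  expression_matrix(m, genes, samples)
}

# three well-separated sample groups, each with its own gene module so the
# separation survives any distance choice; returns an expression matrix plus
# the group of each sample
separated_cohort <- function(n_per = 4, n_genes = 30, shift = 5, sd = 0.1,
                             seed = 11) {
  set.seed(seed)
  groups <- rep(c("A", "B", "C"), each = n_per)
  base <- matrix(rnorm(n_genes * length(groups), 5, sd), n_genes)
  base[1:10, groups == "A"] <- base[1:10, groups == "A"] + shift
  base[11:20, groups == "B"] <- base[11:20, groups == "B"] + shift
  base[21:30, groups == "C"] <- base[21:30, groups == "C"] + shift
  list(expr = tiny_expr(base), groups = groups)
}

# exhaustive hypergeometric enumeration: two-sided Fisher p for a 2x2 table
# with fixed margins, summing point probabilities <= that of the observed
# table (independent of stats::fisher.test)
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  logp <- lchoose(r1, xs) + lchoose(n - r1, c1 - xs) - lchoose(n, c1)
  p_obs <- logp[xs == a]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# adjusted Rand index of two partitions (independent of any clustering code)
rand_index <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  s <- function(v) sum(choose(v, 2))
  a <- s(tab); b <- s(rowSums(tab)); c <- s(colSums(tab)); d <- choose(n, 2)
  exp_a <- b * c / d
  (a - exp_a) / ((b + c) / 2 - exp_a)
}

# classification accuracy against latent truth, over samples whose latent
# class defines an INT/COD ground truth (int_like / cod_like)
classify_accuracy <- function(assignment, truth) {
  lat <- truth$latent$latent_class[match(assignment$sample_id,
                                         truth$latent$sample_id)]
  keep <- lat %in% c("int_like", "cod_like")
  truth_lab <- ifelse(lat[keep] == "cod_like", "COD", "INT")
  mean(assignment$subtype[keep] == truth_lab)
}

# diffuse-only expression submatrix of a simulated cohort
diffuse_expr <- function(cohort) {
  ids <- cohort$clinical$sample_id[!is.na(cohort$clinical$histology) &
                                     cohort$clinical$histology == "diffuse"]
  expression_matrix(unclass(cohort$expression)[, ids, drop = FALSE])
}
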