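#' Tumor mutation burden per sample
#'
#' Counts mutation records in the included variant classes per sample.
#' Samples listed in `samples` but absent from the table get TMB 0 with a
#' warning. With `per_mb = TRUE` the counts are divided by the exome size.
#'
#' @param mut A [mutation_table()].
#' @param samples Sample universe; defaults to samples present in `mut`.
#' @param classes Variant classes counted (default: the table's
#'   nonsynonymous set).
#' @param per_mb Normalize to mutations per megabase.
#' @param exome_size_mb Exome footprint in Mb (default 38).
#' @return Named numeric vector of class `"tmb_vector"` (one value per
#'   sample) with a `normalization` attribute.
#' @export
compute_tmb <- function(mut, samples = NULL,
                        classes = attr(mut, "nonsyn_classes"),
                        per_mb = FALSE, exome_size_mb = 38) {
  stopifnot(inherits(mut, "mutation_table"))
  if (is.null(classes) || length(classes) == 0) {
    stop("empty variant-class set", call. = FALSE)
  }
  if (is.null(samples)) samples <- sort(unique(mut$sample_id))
  keep <- mut$variant_class %in% classes & mut$sample_id %in% samples
  counts <- table(factor(mut$sample_id[keep], levels = samples))
  out <- as.numeric(counts)
  names(out) <- samples
  absent <- setdiff(samples, unique(mut$sample_id))
  if (length(absent) > 0) {
    warning(length(absent), " sample(s) absent from the mutation table; TMB 0",
            call. = FALSE)
  }
  if (per_mb) out <- out / exome_size_mb
  structure(out, normalization = if (per_mb) "per_mb" else "raw_count",
            class = "tmb_vector")
}

# resolve a subtype label vector out of a subtype_assignment or named vector
subtype_labels <- function(subtypes) {
  if (inherits(subtypes, "subtype_assignment")) {
    out <- subtypes$subtype
    names(out) <- subtypes$sample_id
  } else {
    out <- as.character(subtypes)
    names(out) <- names(subtypes)
  }
  if (is.null(names(out))) stop("subtypes must carry sample ids", call. = FALSE)
  if (!all(out %in% c("INT", "COD"))) {
    stop("subtype labels must be 'INT' or 'COD'", call. = FALSE)
  }
  out
}

#' Compare tumor mutation burden between subtypes
#'
#' Welch t test of per-sample TMB between the INT and COD subtypes, by
#' default on the log10(TMB + 1) scale (mutation counts are heavy-tailed);
#' `log_transform = FALSE` compares raw counts.
#'
#' @param tmb A [compute_tmb()] vector.
#' @param subtypes A `"subtype_assignment"` or named INT/COD label vector
#'   covering the TMB samples.
#' @param log_transform Compare on log10(TMB + 1) scale (default `TRUE`).
#' @return A [test_result()]; `extra` holds per-group means (original
#'   count scale) and the direction of the difference.
#' @export
compare_tmb <- function(tmb, subtypes, log_transform = TRUE) {
  labs <- subtype_labels(subtypes)
  common <- intersect(names(tmb), names(labs))
  if (length(common) == 0) stop("no samples shared by TMB and subtypes",
                                call. = FALSE)
  x <- as.numeric(tmb[common]); g <- labs[common]
  if (sum(g == "INT") < 2 || sum(g == "COD") < 2) {
    stop("both subtypes need >= 2 samples", call. = FALSE)
  }
  v <- if (log_transform) log10(x + 1) else x
  res <- welch_t_test(v[g == "INT"], v[g == "COD"])
  m_int <- mean(x[g == "INT"]); m_cod <- mean(x[g == "COD"])
  res$extra <- list(mean_int = m_int, mean_cod = m_cod,
                    scale = if (log_transform) "log10(TMB+1)" else "raw",
                    direction = if (m_int > m_cod) "INT > COD"
                                else if (m_cod > m_int) "COD > INT" else "none")
  res
}

#' Per-gene mutation-frequency screen
#'
#' For every gene, builds the 2x2 table (mutated / wild-type x INT / COD)
#' over the classified samples and applies the two-sided Fisher exact test.
#' Significance is unadjusted p < `alpha`; a Benjamini-Hochberg column is
#' reported alongside.
#'
#' @param mut A [mutation_table()].
#' @param subtypes A `"subtype_assignment"` or named INT/COD label vector;
#'   defines the sample universe (samples without records count as
#'   wild-type).
#' @param alpha Significance threshold (default 0.05).
#' @return Data.frame, sorted by p then gene id, with columns `gene_id`,
#'   `mut_int`, `wt_int`, `mut_cod`, `wt_cod`, `odds_ratio`, `p_value`,
#'   `p_bh`, `significant`.
#' @export
per_gene_mutation_screen <- function(mut, subtypes, alpha = 0.05) {
  labs <- subtype_labels(subtypes)
  ind <- mutation_matrix(mut, samples = names(labs), form = "indicator")
  if (ncol(ind) == 0) {
    return(data.frame(gene_id = character(0), mut_int = integer(0),
                      wt_int = integer(0), mut_cod = integer(0),
                      wt_cod = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), p_bh = numeric(0),
                      significant = logical(0)))
  }
  is_int <- labs[rownames(ind)] == "INT"
  n_int <- sum(is_int); n_cod <- sum(!is_int)
  mut_int <- colSums(ind[is_int, , drop = FALSE])
  mut_cod <- colSums(ind[!is_int, , drop = FALSE])
  res <- data.frame(gene_id = colnames(ind),
                    mut_int = mut_int, wt_int = n_int - mut_int,
                    mut_cod = mut_cod, wt_cod = n_cod - mut_cod,
                    odds_ratio = NA_real_, p_value = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    ft <- fisher_exact_two_sided(res$mut_int[i], res$wt_int[i],
                                 res$mut_cod[i], res$wt_cod[i])
    res$odds_ratio[i] <- ft$effect
    res$p_value[i] <- ft$p_value
  }
  res$p_bh <- stats::p.adjust(res$p_value, "BH")
  res$significant <- res$p_value < alpha
  res[order(res$p_value, res$gene_id), , drop = FALSE]
}

#' Mutation rate of a gene in a sample set
#'
#' Fraction of samples carrying at least one record for the gene. An
#' unknown gene yields rate 0 with a warning.
#'
#' @param mut A [mutation_table()].
#' @param gene Gene id.
#' @param samples Nonempty sample-id vector (the denominator).
#' @return Proportion in \[0, 1\].
#' @export
mutation_rate <- function(mut, gene, samples) {
  if (length(samples) == 0) stop("empty sample set", call. = FALSE)
  if (!gene %in% mut$gene_id) {
    warning("gene '", gene, "' absent from the mutation table", call. = FALSE)
    return(0)
  }
  carriers <- unique(mut$sample_id[mut$gene_id == gene])
  mean(samples %in% carriers)
}

#' Association between molecular subtypes and signature subtypes
#'
#' Chi-square test on the r x 2 contingency table of TCGA-style molecular
#' classes (EBV/MSI/GS/CIN) against the signature's INT/COD assignment,
#' with the per-class composition reported.
#'
#' @param molecular Named character vector (sample -> molecular class);
#'   `NA` entries are dropped.
#' @param subtypes A `"subtype_assignment"` or named INT/COD label vector.
#' @return A list: `test` ([test_result()]), `table` (classes x INT/COD
#'   counts), `composition` (per-class INT fraction).
#' @export
molecular_subtype_association <- function(molecular, subtypes) {
  labs <- subtype_labels(subtypes)
  common <- intersect(names(molecular)[!is.na(molecular)], names(labs))
  if (length(common) == 0) stop("no overlapping samples", call. = FALSE)
  mol <- factor(molecular[common])
  if (nlevels(mol) < 2) {
    stop("need >= 2 molecular classes for an association test", call. = FALSE)
  }
  tab <- table(molecular = mol, subtype = factor(labs[common], c("INT", "COD")))
  res <- suppressWarnings(chi_square_test(as.matrix(tab)))
  comp <- prop.table(as.matrix(tab), 1)[, "INT"]
  list(test = res, table = as.matrix(tab), composition = comp)
}
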