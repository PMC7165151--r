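#' Somatic mutation table
#'
#' Canonical record form of a MAF-lite table: one row per
#' (sample, gene, variant class) call. A wide 0/1 sample x gene indicator
#' matrix is also accepted and converted to records with variant class
#' `"unspecified"`.
#'
#' @param records Data.frame with columns `sample_id`, `gene_id`,
#'   `variant_class`.
#' @param nonsyn_classes Character vector of variant classes counted as
#'   nonsynonymous (used by [compute_tmb()]); stored as an attribute.
#' @param strict Error on variant classes outside the known vocabulary.
#' @return Data.frame of class `"mutation_table"`, sorted by sample then gene.
#' @export
mutation_table <- function(records,
                           nonsyn_classes = default_nonsyn_classes(),
                           strict = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "gene_id", "variant_class")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) stop("mutation table missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  records <- records[need]
  records$sample_id <- as.character(records$sample_id)
  records$gene_id <- as.character(records$gene_id)
  records$variant_class <- normalize_variant_class(records$variant_class)
  if (strict) {
    bad <- setdiff(unique(records$variant_class), known_variant_classes())
    if (length(bad) > 0) stop("unknown variant class(es): ",
                              paste(bad, collapse = ", "), call. = FALSE)
  }
  records <- records[order(records$sample_id, records$gene_id,
                           records$variant_class), , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "nonsyn_classes") <- nonsyn_classes
  class(records) <- c("mutation_table", "data.frame")
  records
}

known_variant_classes <- function() {
  c("missense_mutation", "nonsense_mutation", "frame_shift_del",
    "frame_shift_ins", "in_frame_del", "in_frame_ins", "splice_site",
    "nonstop_mutation", "translation_start_site", "silent", "unspecified")
}

#' Default nonsynonymous variant classes
#'
#' The variant classes counted toward tumor mutation burden by default:
#' everything protein-altering (silent calls are excluded).
#' @return Character vector of class names.
#' @export
default_nonsyn_classes <- function() {
  setdiff(known_variant_classes(), "silent")
}

normalize_variant_class <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("", "na")] <- "unspecified"
  gsub("[ -]", "_", x)
}

#' Read a mutation table (MAF-lite TSV or wide 0/1 matrix)
#'
#' Record form is detected by the presence of `sample_id`, `gene_id` and
#' `variant_class` columns; any other layout is treated as a wide indicator
#' matrix (first column sample ids, remaining columns genes, cells 0/1).
#'
#' @inheritParams mutation_table
#' @param path Path to the file.
#' @return A `mutation_table`.
#' @export
read_mutation_table <- function(path, nonsyn_classes = default_nonsyn_classes(),
                                strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("sample_id", "gene_id", "variant_class") %in% names(df))) {
    return(mutation_table(df, nonsyn_classes, strict))
  }
  # wide indicator matrix
  if (ncol(df) < 2L) stop("wide mutation matrix needs sample ids plus >=1 gene",
                          call. = FALSE)
  samples <- as.character(df[[1]])
  ind <- as.matrix(df[, -1, drop = FALSE])
  mode(ind) <- "numeric"
  if (!all(ind %in% c(0, 1))) {
    bad <- which(!ind %in% c(0, 1))[1]
    stop("wide mutation matrix must be 0/1; found value ", ind[bad],
         call. = FALSE)
  }
  hit <- which(ind == 1, arr.ind = TRUE)
  records <- data.frame(sample_id = samples[hit[, 1]],
                        gene_id = colnames(ind)[hit[, 2]],
                        variant_class = "unspecified",
                        stringsAsFactors = FALSE)
  mutation_table(records, nonsyn_classes, strict)
}

#' Write a mutation table as MAF-lite TSV
#'
#' @param mut A `mutation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mut, path) {
  utils::write.table(as.data.frame(mut), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a mutation table to a sample x gene matrix
#'
#' @param mut A `mutation_table`.
#' @param samples Sample universe (rows); defaults to samples present in
#'   `mut`. Samples without records get all-zero rows.
#' @param form `"indicator"` (0/1 presence) or `"count"` (number of records).
#' @return Integer matrix, samples x genes.
#' @export
mutation_matrix <- function(mut, samples = NULL,
                            form = c("indicator", "count")) {
  form <- match.arg(form)
  if (is.null(samples)) samples <- sort(unique(mut$sample_id))
  genes <- sort(unique(mut$gene_id))
  out <- matrix(0L, length(samples), max(length(genes), 1L),
                dimnames = list(samples, if (length(genes)) genes else "none"))
  if (nrow(mut) == 0 || length(genes) == 0) return(out[, 0, drop = FALSE])
  keep <- mut$sample_id %in% samples
  tab <- table(factor(mut$sample_id[keep], levels = samples),
               factor(mut$gene_id[keep], levels = genes))
  out <- matrix(as.integer(tab), length(samples), length(genes),
                dimnames = list(samples, genes))
  if (form == "indicator") out[out > 1L] <- 1L
  out
}
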