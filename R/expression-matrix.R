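#' Construct a validated expression matrix
#'
#' The substrate of every downstream stage: a genes x samples matrix of
#' log2-scale, library-normalized expression values with unique gene and
#' sample identifiers and no non-finite entries.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#' @return A numeric matrix of class `"expr_matrix"` with gene row names and
#'   sample column names.
#' @examples
#' m <- matrix(rnorm(6), 3, 2)
#' expression_matrix(m, c("g1", "g2", "g3"), c("s1", "s2"))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) != nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) != ncol(values)", call. = FALSE)
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0) {
    stop("duplicate gene identifier(s): ", paste(utils::head(dup_g, 5), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    stop("duplicate sample identifier(s): ", paste(utils::head(dup_s, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (log2 scale)\n",
              nrow(x), ncol(x)))
  cat("genes:   ", paste(utils::head(rownames(x), 4), collapse = ", "),
      if (nrow(x) > 4) ", ..." else "", "\n", sep = "")
  cat("samples: ", paste(utils::head(colnames(x), 4), collapse = ", "),
      if (ncol(x) > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

collapse_duplicate_genes <- function(values, gene_ids, rule = c("max_mean", "mean")) {
  rule <- match.arg(rule)
  if (!anyDuplicated(gene_ids)) {
    rownames(values) <- gene_ids
    return(values)
  }
  groups <- split(seq_along(gene_ids), gene_ids)
  out <- t(vapply(groups, function(idx) {
    if (length(idx) == 1L) return(values[idx, ])
    block <- values[idx, , drop = FALSE]
    if (rule == "mean") colMeans(block)
    else block[which.max(rowMeans(block)), ] # row with largest mean expression
  }, numeric(ncol(values))))
  # split() sorts by gene id; restore first-appearance order
  out[unique(gene_ids), , drop = FALSE]
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: first column gene identifiers, header row sample identifiers.
#' GCT 1.2 layout: `#1.2` version line, a `n_genes<TAB>n_samples` line, then a
#' table whose first two columns are Name and Description.
#' Duplicate gene rows are collapsed (default: keep the row with the largest
#' mean expression); missing values are rejected unless `impute = TRUE`, in
#' which case they are replaced by the per-gene median.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"gct"`.
#' @param collapse Rule for duplicate gene rows: `"max_mean"` or `"mean"`.
#' @param impute Impute missing entries with the per-gene median instead of
#'   failing. Default `FALSE`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct"),
                                   collapse = c("max_mean", "mean"),
                                   impute = FALSE) {
  dialect <- match.arg(dialect)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (dialect == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || !startsWith(header[1], "#1.2")) {
      stop("malformed GCT header: expected '#1.2' on line 1, got '",
           header[1], "'", call. = FALSE)
    }
    dims <- suppressWarnings(as.integer(strsplit(header[2], "\t", fixed = TRUE)[[1]]))
    if (length(dims) < 2L || anyNA(dims[1:2])) {
      stop("malformed GCT dimension line: '", header[2], "'", call. = FALSE)
    }
    tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2]) {
      stop(sprintf("GCT dimension mismatch: declared %d x %d, found %d x %d",
                   dims[1], dims[2], nrow(tab), ncol(tab) - 2L), call. = FALSE)
    }
    gene_ids <- as.character(tab[[1]])
    sample_ids <- colnames(tab)[-(1:2)]
    raw <- tab[, -(1:2), drop = FALSE]
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("expression TSV needs a gene column plus >=1 sample",
                             call. = FALSE)
    gene_ids <- as.character(tab[[1]])
    sample_ids <- colnames(tab)[-1] # before subsetting: `[.data.frame`
    raw <- tab[, -1, drop = FALSE]  # uniquifies duplicate column names
  }

  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    stop("duplicate sample identifier(s) in header: ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  values <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    col <- raw[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & trimws(as.character(col)) != "" &
                   !toupper(trimws(as.character(col))) %in% c("NA", "NAN"))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric expression value '%s' at row %d (gene '%s'), column '%s'",
                   col[bad[1]], bad[1], gene_ids[bad[1]], sample_ids[j]),
           call. = FALSE)
    }
    values[, j] <- num
  }
  if (anyNA(values)) {
    if (!impute) {
      bad <- which(is.na(values), arr.ind = TRUE)[1, ]
      stop(sprintf(paste0("missing expression value at gene '%s', sample '%s';",
                          " set impute = TRUE for per-gene median imputation"),
                   gene_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
    }
    for (i in which(rowSums(is.na(values)) > 0)) {
      med <- stats::median(values[i, ], na.rm = TRUE)
      if (is.na(med)) stop("gene '", gene_ids[i], "' has no observed values",
                           call. = FALSE)
      values[i, is.na(values[i, ])] <- med
    }
  }
  values <- collapse_duplicate_genes(values, gene_ids, collapse)
  colnames(values) <- sample_ids
  expression_matrix(values)
}

#' Write an expression matrix
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @param dialect `"tsv"` (gene column + samples) or `"gct"` (GCT 1.2).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(gene_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  if (dialect == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
    df <- data.frame(Name = rownames(expr), Description = "na",
                     as.data.frame(unclass(expr)), check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
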