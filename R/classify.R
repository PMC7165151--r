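#' Classify a cohort into INT and COD subtypes
#'
#' Applies a derived signature to a new cohort. Signature genes present in
#' the cohort are z-scored per gene across the cohort (so platform-level
#' location/scale shifts cancel); samples are then either
#' \describe{
#'   \item{two_cluster}{agglomeratively clustered (same distance/linkage
#'     defaults as derivation) and cut at k = 2, with the two clusters
#'     oriented by [orient_clusters()]; or}
#'   \item{centroid}{labelled by the sign of their orientation score — the
#'     mean direction-weighted z-score over signature genes — which also
#'     works for a single sample.}
#' }
#'
#' @param expr An [expression_matrix()] for the new cohort.
#' @param sig A `"cod_signature"`.
#' @param method `"two_cluster"` (default) or `"centroid"`.
#' @param min_overlap Minimum fraction of signature genes that must be
#'   present in `expr` (default 0.25).
#' @return A data.frame of class `"subtype_assignment"` with columns
#'   `sample_id`, `subtype` (`"INT"`/`"COD"`) and `orientation_score`;
#'   attributes `method` and `overlap` (fraction of signature genes used).
#' @export
classify_cohort <- function(expr, sig, method = c("two_cluster", "centroid"),
                            min_overlap = 0.25) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sig, "cod_signature"))
  method <- match.arg(method)
  if (length(sig$gene_ids) == 0) stop("empty signature", call. = FALSE)
  present <- intersect(sig$gene_ids, rownames(expr))
  overlap <- length(present) / length(sig$gene_ids)
  if (overlap < min_overlap) {
    stop(sprintf("only %.1f%% of signature genes present in the cohort (floor %.0f%%)",
                 100 * overlap, 100 * min_overlap), call. = FALSE)
  }
  if (method == "two_cluster" && ncol(expr) < 4) {
    stop("two_cluster classification needs >= 4 samples", call. = FALSE)
  }
  mat <- unclass(expr)[present, , drop = FALSE]
  mu <- rowMeans(mat)
  sdv <- sqrt(rowSums((mat - mu)^2) / (ncol(mat) - 1))
  informative <- sdv > 0
  if (!any(informative)) {
    stop("degenerate cohort: every signature gene is constant across samples",
         call. = FALSE)
  }
  z <- (mat[informative, , drop = FALSE] - mu[informative]) / sdv[informative]
  dirs <- sig$directions[rownames(z)]
  score <- colMeans(z * as.numeric(dirs))

  if (method == "centroid") {
    subtype <- ifelse(score > 0, "COD", "INT")
  } else {
    zm <- expression_matrix(z, rownames(z), colnames(z))
    model <- hierarchical_cluster(zm, rownames(zm), k = 2,
                                  distance = sig$distance %||% "one_minus_pearson",
                                  linkage = sig$linkage %||% "average")
    labmap <- orient_clusters_impl(score, model$cluster)
    subtype <- unname(labmap[as.character(model$cluster)])
  }
  out <- data.frame(sample_id = colnames(expr), subtype = subtype,
                    orientation_score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "overlap") <- overlap
  class(out) <- c("subtype_assignment", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

orient_clusters_impl <- function(score, cluster) {
  cls <- sort(unique(cluster))
  if (length(cls) != 2) stop("exactly 2 clusters required", call. = FALSE)
  means <- vapply(cls, function(cl) mean(score[cluster == cl]), 0)
  if (means[1] == means[2]) {
    stop("cluster orientation is an exact tie; orient manually", call. = FALSE)
  }
  # lower direction-weighted mean -> INT, higher -> COD
  out <- stats::setNames(c("INT", "COD"), cls[order(means)])
  out[order(as.integer(names(out)))]
}

#' Orient a two-cluster partition as INT vs COD
#'
#' The cluster whose samples have the higher mean direction-weighted
#' signature z-score (EMT-like COD-module expression) is labelled COD, the
#' other INT. An exact tie is an error.
#'
#' @param expr An [expression_matrix()].
#' @param sig A `"cod_signature"`.
#' @param cluster Named integer vector (sample -> cluster index) with
#'   exactly two clusters, covering samples of `expr`.
#' @return Named character vector mapping cluster index to `"INT"`/`"COD"`.
#' @export
orient_clusters <- function(expr, sig, cluster) {
  stopifnot(inherits(expr, "expr_matrix"))
  present <- intersect(sig$gene_ids, rownames(expr))
  if (length(present) == 0) stop("no signature genes present", call. = FALSE)
  mat <- unclass(expr)[present, names(cluster), drop = FALSE]
  mu <- rowMeans(mat)
  sdv <- sqrt(rowSums((mat - mu)^2) / (ncol(mat) - 1))
  keep <- sdv > 0
  if (!any(keep)) stop("all signature genes constant", call. = FALSE)
  z <- (mat[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  score <- colMeans(z * as.numeric(sig$directions[rownames(z)]))
  orient_clusters_impl(score, cluster)
}

#' Write a subtype assignment as TSV
#'
#' @param assignment A `"subtype_assignment"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subtypes <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
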