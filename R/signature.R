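#' Variance filter
#'
#' Selects genes whose across-sample standard deviation (denominator n - 1)
#' strictly exceeds a threshold — the first step of signature derivation
#' (default threshold 0.9 on log2 data).
#'
#' @param expr An [expression_matrix()].
#' @param sd_threshold Nonnegative SD cutoff (strict inequality).
#' @return Character vector of retained gene ids, in matrix row order.
#' @export
variance_filter <- function(expr, sd_threshold = 0.9) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (sd_threshold < 0) stop("sd_threshold must be >= 0", call. = FALSE)
  if (ncol(expr) < 2) stop("variance filter needs >= 2 samples", call. = FALSE)
  m <- rowMeans(expr)
  sds <- sqrt(rowSums((expr - m)^2) / (ncol(expr) - 1))
  rownames(expr)[sds > sd_threshold]
}

#' Agglomerative clustering of samples
#'
#' Hierarchical clustering of samples on a gene subset, with the distance
#' and linkage used throughout the pipeline (default 1 - Pearson correlation,
#' average linkage), cut into exactly `k` groups.
#'
#' @param expr An [expression_matrix()].
#' @param genes Gene ids to cluster on (>= 2).
#' @param k Number of clusters (2 <= k <= n samples).
#' @param distance `"one_minus_pearson"` or `"euclidean"`.
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2).
#' @return A list of class `"cluster_model"`: `cluster` (named integer
#'   vector of cluster indices 1..k), `hclust` (the merge tree), and the
#'   parameters used.
#' @export
hierarchical_cluster <- function(expr, genes = rownames(expr), k,
                                 distance = c("one_minus_pearson", "euclidean"),
                                 linkage = c("average", "complete", "ward")) {
  stopifnot(inherits(expr, "expr_matrix"))
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  miss <- setdiff(genes, rownames(expr))
  if (length(miss) > 0) stop("unknown gene id(s): ",
                             paste(utils::head(miss, 5), collapse = ", "),
                             call. = FALSE)
  if (length(genes) < 2) stop("need >= 2 genes to cluster on", call. = FALSE)
  if (k < 1 || k > ncol(expr)) stop("k must be in [1, n_samples]", call. = FALSE)
  mat <- unclass(expr)[genes, , drop = FALSE]
  if (distance == "one_minus_pearson") {
    sds <- apply(mat, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance sample(s) under correlation distance: ",
           paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
    }
    d <- stats::as.dist(1 - stats::cor(mat))
  } else {
    d <- stats::dist(t(mat))
  }
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  cl <- stats::cutree(hc, k = k)
  structure(list(cluster = cl, hclust = hc, k = k, distance = distance,
                 linkage = linkage, genes = genes),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d samples, k = %d, %s distance, %s linkage\n",
              length(x$cluster), x$k, x$distance, x$linkage))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Label a 3-cluster solution as N / INT / COD
#'
#' Assigns discovery labels by histological composition: the cluster with
#' the highest fraction of normal tissue becomes N, the cluster with the
#' highest intestinal-type fraction among the remainder becomes INT, and the
#' last is COD. Ties on both criteria are an error (manual labels required).
#'
#' @param model A `"cluster_model"` with k = 3.
#' @param annotations A [cohort_annotation()] with a `histology` column.
#' @return Named character vector mapping cluster index (`"1".."3"`) to
#'   `"N"`, `"INT"` or `"COD"`.
#' @export
label_clusters <- function(model, annotations) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 3) stop("label_clusters requires k = 3", call. = FALSE)
  if (!"histology" %in% names(annotations)) {
    stop("annotations need a histology column", call. = FALSE)
  }
  hist <- annotations$histology[match(names(model$cluster),
                                      annotations$sample_id)]
  if (all(is.na(hist))) stop("no histology available for clustered samples",
                             call. = FALSE)
  frac <- function(cl, type) {
    h <- hist[model$cluster == cl]
    if (all(is.na(h))) return(0)
    mean(h == type, na.rm = TRUE)
  }
  cls <- sort(unique(model$cluster))
  nf <- vapply(cls, frac, 0, type = "normal")
  itf <- vapply(cls, frac, 0, type = "intestinal")

  n_cand <- cls[nf == max(nf)]
  if (length(n_cand) > 1) {
    # break a normal-fraction tie by the lower intestinal fraction
    sub <- itf[match(n_cand, cls)]
    if (sum(sub == min(sub)) > 1) {
      stop("cluster labelling is ambiguous (tied normal and intestinal ",
           "fractions); provide manual labels", call. = FALSE)
    }
    n_cand <- n_cand[which.min(sub)]
  }
  rest <- setdiff(cls, n_cand)
  itf_rest <- itf[match(rest, cls)]
  if (itf_rest[1] == itf_rest[2]) {
    stop("cluster labelling is ambiguous (tied intestinal fractions); ",
         "provide manual labels", call. = FALSE)
  }
  int_cl <- rest[which.max(itf_rest)]
  cod_cl <- setdiff(rest, int_cl)
  out <- c("N", "INT", "COD")
  names(out) <- c(n_cand, int_cl, cod_cl)
  out[order(as.integer(names(out)))]
}

#' Differential-expression screen between two sample groups
#'
#' Per-gene Welch t tests between two disjoint sample groups; genes with
#' (by default unadjusted) p below `p_threshold` are returned. An optional
#' Benjamini-Hochberg mode thresholds the FDR-adjusted p instead.
#'
#' @param expr An [expression_matrix()].
#' @param group_a,group_b Disjoint sample-id sets, each >= 2 samples.
#' @param p_threshold Significance cutoff (strict `<`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Character vector of significant gene ids.
#' @export
differential_genes <- function(expr, group_a, group_b, p_threshold = 0.001,
                               adjust = c("none", "BH")) {
  stopifnot(inherits(expr, "expr_matrix"))
  adjust <- match.arg(adjust)
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap", call. = FALSE)
  }
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss) > 0) stop("unknown sample id(s): ",
                             paste(utils::head(miss, 5), collapse = ", "),
                             call. = FALSE)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  mat <- unclass(expr)[, c(group_a, group_b), drop = FALSE]
  res <- row_welch_t(mat, seq_len(ncol(mat)) <= length(group_a))
  p <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  res$gene_id[p < p_threshold]
}

#' Venn partition of two gene lists
#'
#' Decomposes differential-expression lists A and B into only-A (A \\ B),
#' A-and-B (intersection) and only-B (B \\ A). In signature derivation, A is
#' the N-vs-INT list, B the INT-vs-COD list, and only-B is the COD signature.
#'
#' @param list_a,list_b Character vectors of gene ids (duplicates ignored).
#' @return A list of class `"gene_list_partition"` with elements `list_a`,
#'   `list_b`, `only_a`, `a_and_b`, `only_b` and a `counts` vector.
#' @export
venn_partition <- function(list_a, list_b) {
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  out <- list(list_a = list_a, list_b = list_b,
              only_a = setdiff(list_a, list_b),
              a_and_b = intersect(list_a, list_b),
              only_b = setdiff(list_b, list_a))
  out$counts <- c(a = length(list_a), b = length(list_b),
                  only_a = length(out$only_a), a_and_b = length(out$a_and_b),
                  only_b = length(out$only_b))
  class(out) <- "gene_list_partition"
  out
}

#' @export
print.gene_list_partition <- function(x, ...) {
  cat(sprintf("<gene_list_partition> |A| = %d, |B| = %d: only-A %d, A-and-B %d, only-B %d\n",
              x$counts["a"], x$counts["b"], x$counts["only_a"],
              x$counts["a_and_b"], x$counts["only_b"]))
  invisible(x)
}

#' Derive the COD signature from a discovery cohort
#'
#' Runs the full derivation: variance filter (SD > `sd_threshold`) ->
#' 3-cluster agglomerative clustering of samples -> histology-based N/INT/COD
#' cluster labelling -> per-gene Welch differential expression between the
#' N and INT clusters (list A) and between the INT and COD clusters (list B)
#' at p < `p_threshold`, computed on diffuse-type samples only (the cluster
#' memberships come from the full-cohort clustering) -> Venn partition.
#' The signature is the only-B gene set, with per-gene direction +1 when the
#' gene's mean expression is higher in the COD cluster than in the INT
#' cluster (diffuse samples), else -1.
#'
#' @param expr An [expression_matrix()] covering the discovery cohort.
#' @param annotations A [cohort_annotation()] with a `histology` column.
#' @param sd_threshold Variance-filter cutoff (default 0.9).
#' @param p_threshold Differential-expression cutoff (default 0.001).
#' @param distance,linkage Clustering parameters (see
#'   [hierarchical_cluster()]).
#' @param diffuse_only Restrict differential expression to diffuse-type
#'   samples (default `TRUE`).
#' @param adjust Multiple-testing mode for the DE screens (`"none"` default).
#' @return A list of class `"cod_signature"`: `gene_ids` (sorted only-B
#'   genes), `directions` (named +1/-1), `partition`
#'   (the [venn_partition()]), `cluster_labels`, `clusters` (per-sample),
#'   and the thresholds/parameters used.
#' @export
derive_signature <- function(expr, annotations, sd_threshold = 0.9,
                             p_threshold = 0.001,
                             distance = "one_minus_pearson",
                             linkage = "average",
                             diffuse_only = TRUE,
                             adjust = "none") {
  stage <- function(name, x) {
    tryCatch(force(x), error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  filtered <- stage("variance_filter", variance_filter(expr, sd_threshold))
  if (length(filtered) < 2) {
    stop("[variance_filter] fewer than 2 genes pass SD > ", sd_threshold,
         call. = FALSE)
  }
  model <- stage("hierarchical_cluster",
                 hierarchical_cluster(expr, filtered, k = 3,
                                      distance = distance, linkage = linkage))
  labels <- stage("label_clusters", label_clusters(model, annotations))
  cl_lab <- unname(labels[as.character(model$cluster)])
  names(cl_lab) <- names(model$cluster)

  keep <- names(cl_lab)
  if (diffuse_only) {
    hist <- annotations$histology[match(keep, annotations$sample_id)]
    keep <- keep[!is.na(hist) & hist == "diffuse"]
    if (length(keep) == 0) {
      stop("[differential_genes] no diffuse-type samples in the cohort",
           call. = FALSE)
    }
  }
  grp <- cl_lab[keep]
  g_n <- names(grp)[grp == "N"]
  g_int <- names(grp)[grp == "INT"]
  g_cod <- names(grp)[grp == "COD"]
  list_a <- stage("differential_genes",
                  differential_genes(expr, g_n, g_int, p_threshold, adjust))
  list_b <- stage("differential_genes",
                  differential_genes(expr, g_int, g_cod, p_threshold, adjust))
  part <- venn_partition(list_a, list_b)

  sig_genes <- sort(part$only_b)
  dirs <- integer(0)
  if (length(sig_genes) > 0) {
    d <- rowMeans(unclass(expr)[sig_genes, g_cod, drop = FALSE]) -
      rowMeans(unclass(expr)[sig_genes, g_int, drop = FALSE])
    dirs <- ifelse(d >= 0, 1L, -1L)
    names(dirs) <- sig_genes
  }
  structure(list(gene_ids = sig_genes, directions = dirs, partition = part,
                 cluster_labels = labels, clusters = cl_lab,
                 sd_threshold = sd_threshold, p_threshold = p_threshold,
                 distance = distance, linkage = linkage,
                 n_filtered_genes = length(filtered)),
            class = "cod_signature")
}

#' @export
print.cod_signature <- function(x, ...) {
  cat(sprintf("<cod_signature> %d genes (only-B), SD > %g filter kept %d genes, DE p < %g\n",
              length(x$gene_ids), x$sd_threshold, x$n_filtered_genes,
              x$p_threshold))
  print(x$partition)
  invisible(x)
}

#' Write a signature to JSON
#'
#' @param sig A `"cod_signature"` (or any signature-like list with
#'   `gene_ids` and `directions`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  jsonlite::write_json(list(
    gene_ids = sig$gene_ids,
    directions = as.list(sig$directions),
    sd_threshold = sig$sd_threshold,
    p_threshold = sig$p_threshold,
    distance = sig$distance,
    linkage = sig$linkage,
    partition_counts = as.list(sig$partition$counts)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a signature from JSON
#'
#' @param path Path written by [write_signature()].
#' @return A `"cod_signature"` list (partition counts only; the full gene
#'   lists of the derivation cohort are not stored).
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dirs <- as.integer(unlist(x$directions))
  names(dirs) <- names(x$directions)
  structure(list(gene_ids = as.character(x$gene_ids), directions = dirs,
                 partition = NULL, cluster_labels = NULL, clusters = NULL,
                 sd_threshold = x$sd_threshold, p_threshold = x$p_threshold,
                 distance = x$distance, linkage = x$linkage,
                 n_filtered_genes = NA_integer_),
            class = "cod_signature")
}
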