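#' Hierarchically cluster per-drug coefficient vectors
#'
#' Clusters the columns of a coefficient matrix (one model vector per drug)
#' by Ward's minimum-variance criterion on Euclidean distances — `hclust`
#' with method `"ward.D"` applied to squared Euclidean distances, the
#' classic "ward" dialect. Drugs whose learned models are similar (e.g.
#' sharing a mechanism of action under trace-norm training) merge early.
#'
#' @param W Numeric matrix, features x drugs; column names label the
#'   drugs.
#' @return Object of class `drug_cluster`: list with `tree` (an
#'   [stats::hclust] object over drugs) and `linkage` metadata.
#' @export
cluster_drug_models <- function(W) {
  W <- as.matrix(W)
  if (any(!is.finite(W))) {
    stop("coefficient matrix must be finite", call. = FALSE)
  }
  if (ncol(W) < 2L) stop("need at least 2 drugs to cluster", call. = FALSE)
  d <- stats::dist(t(W), method = "euclidean")
  tree <- stats::hclust(d^2, method = "ward.D")
  structure(list(tree = tree,
                 linkage = "ward.D on squared Euclidean distances"),
            class = "drug_cluster")
}

#' Cut a drug cluster tree into k flat groups
#'
#' @param clust A [cluster_drug_models()] result (or an `hclust` tree).
#' @param k Number of groups, between 1 and the number of drugs.
#' @return Named integer vector of cluster labels.
#' @export
flat_cut <- function(clust, k) {
  tree <- if (inherits(clust, "drug_cluster")) clust$tree else clust
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1L || k > n) {
    stop(sprintf("k must be between 1 and %d", n), call. = FALSE)
  }
  stats::cutree(tree, k = k)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table under the permutation model:
#' `(Index - E[Index]) / (MaxIndex - E[Index])` over item pairs. 1 means
#' identical partitions, 0 is the expectation for independent labelings.
#'
#' @param labels_a,labels_b Vectors of equal length (any label type).
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("partitions must label the same items", call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_nij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_nij - expected) / (max_index - expected)
}

#' Hypergeometric gene-set enrichment of a model's top features
#'
#' Selects the `n_top` features with the largest weights of one drug's
#' model vector — by absolute weight (`mode = "absolute"`, natural for
#' dense trace-norm models) or by positive weight (`mode = "positive"`;
#' when a sparse model carries fewer than `n_top` positive weights, all
#' positive-weight features are used) — then tests each gene set for
#' over-representation among the selection with an upper-tail
#' hypergeometric test against the collection's background. Raw p-values
#' are reported; no multiplicity correction is applied.
#'
#' @param w Named numeric vector of feature weights (one model column).
#' @param gene_sets A [gene_set_collection()].
#' @param n_top Number of top features to select (default 100).
#' @param mode `"absolute"` or `"positive"`.
#' @return Data frame with one row per gene set: `set_name`, `overlap`
#'   (k), `set_size` (K), `selected` (n), `background` (M), `p_value`.
#' @export
top_feature_enrichment <- function(w, gene_sets, n_top = 100L,
                                   mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  if (is.null(names(w))) stop("weights must be named by feature id",
                              call. = FALSE)
  bg <- intersect(names(w), gene_sets$background)
  if (length(bg) == 0L) {
    stop("no model features present in the gene-set background",
         call. = FALSE)
  }
  w <- w[bg]
  sel <- if (mode == "absolute") {
    names(sort(abs(w), decreasing = TRUE))[seq_len(min(n_top, length(w)))]
  } else {
    pos <- w[w > 0]
    if (length(pos) == 0L) {
      stop("no positive-weight features to select", call. = FALSE)
    }
    names(sort(pos, decreasing = TRUE))[seq_len(min(n_top, length(pos)))]
  }
  M <- length(bg)
  n <- length(sel)
  rows <- lapply(names(gene_sets$sets), function(nm) {
    members <- intersect(gene_sets$sets[[nm]], bg)
    K <- length(members)
    k <- length(intersect(sel, members))
    p <- stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K, selected = n,
               background = M, p_value = p)
  })
  do.call(rbind, rows)
}

#' Export a drug clustering as flat labels plus a Newick string
#'
#' @param clust A [cluster_drug_models()] result.
#' @param k Number of flat groups to cut.
#' @param path Output TSV path for the flat labels.
#' @param newick_path Optional output path for a Newick rendering of the
#'   tree (merge heights as branch lengths).
#' @return `path` invisibly.
#' @export
write_cluster_result <- function(clust, k, path, newick_path = NULL) {
  labels <- flat_cut(clust, k)
  utils::write.table(data.frame(drug_id = names(labels),
                                cluster = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(newick_path)) {
    writeLines(hclust_to_newick(clust$tree), newick_path)
  }
  invisible(path)
}

hclust_to_newick <- function(tree) {
  lab <- tree$labels
  build <- function(i) {
    if (i < 0) return(lab[-i])
    m <- tree$merge[i, ]
    sprintf("(%s,%s):%g", build(m[1L]), build(m[2L]), tree$height[i])
  }
  paste0(build(nrow(tree$merge)), ";")
}
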