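## Promoter sensitivity clustering: the 6-column LFC signature
## (3 doses x 2 windows) per affected TSS, k = 4 clustering, canonical
## category naming from the strongest-dose centroids, and cross-model
## cluster overlap.

#' Build the per-TSS LFC signature matrix
#'
#' Rows are TSSs significant (adjusted p < `fdr`, negative LFC unless
#' `two_sided_affected`) in at least one window x dose contrast; columns
#' are the six (dose, window) LFCs ordered dose-major
#' (`lfc_<dose>_core`, `lfc_<dose>_pause`). Untested LFCs are imputed as
#' 0 and flagged in the `n_imputed` attribute.
#'
#' @param results a `db_result` from [diffbind_all_doses()].
#' @param fdr significance threshold on adjusted p (default 0.05).
#' @param two_sided_affected include significant gains as well as losses.
#' @return numeric matrix (rownames = transcript ids) with attributes
#'   `gene_id` and `n_imputed`.
#' @export
build_lfc_matrix <- function(results, fdr = 0.05,
                             two_sided_affected = FALSE) {
  sig <- !is.na(results$padj) & results$padj < fdr
  if (!two_sided_affected) sig <- sig & results$lfc < 0
  ids <- sort(unique(results$transcript_id[sig]))
  doses <- sort(unique(results$dose))
  cols <- as.vector(outer(c("core", "pause"), doses,
                          function(w, d) paste0("lfc_", d, "_", w)))
  mat <- matrix(0, nrow = length(ids), ncol = length(cols),
                dimnames = list(ids, cols))
  if (length(ids) == 0) return(mat)
  n_imputed <- 0L
  for (d in doses) {
    for (w in c("core", "pause")) {
      sub <- results[results$dose == d & results$window == w, ]
      j <- paste0("lfc_", d, "_", w)
      idx <- match(ids, sub$transcript_id)
      v <- sub$lfc[idx]
      untested <- is.na(v) | !sub$tested[idx]
      n_imputed <- n_imputed + sum(untested)
      v[untested] <- 0
      mat[, j] <- v
    }
  }
  gene_map <- unique(results[, c("transcript_id", "gene_id")])
  attr(mat, "gene_id") <- gene_map$gene_id[match(ids,
                                                 gene_map$transcript_id)]
  attr(mat, "n_imputed") <- n_imputed
  mat
}

#' Cluster affected TSSs into k groups on their LFC signatures
#'
#' k-means on the raw (unscaled) LFC matrix -- the signature lives in
#' signed magnitudes, so row scaling would erase the sensitive vs highly
#' sensitive distinction. Best of `n_restarts` by within-cluster sum of
#' squares, seeded. A Ward-linkage hierarchical alternative (cut at `k`)
#' is available via `method = "ward"`.
#'
#' @param mat matrix from [build_lfc_matrix()].
#' @param k number of clusters (default 4).
#' @param seed integer seed.
#' @param n_restarts k-means restarts (default 25).
#' @param method `"kmeans"` (default) or `"ward"`.
#' @return list of class `cluster_assignment`: `transcript_id`,
#'   `cluster` (1..k), `centroids` (k x 6), `method`.
#' @export
cluster_tss <- function(mat, k = 4, seed = 1, n_restarts = 25,
                        method = c("kmeans", "ward")) {
  method <- match.arg(method)
  if (nrow(mat) < k) stop("fewer rows than clusters")
  if (method == "kmeans") {
    set.seed(.stage_seed(seed, "cluster"))
    km <- kmeans(mat, centers = k, nstart = n_restarts, iter.max = 100)
    cl <- km$cluster
    centroids <- km$centers
  } else {
    hc <- hclust(dist(mat), method = "ward.D")
    cl <- cutree(hc, k = k)
    centroids <- do.call(rbind, lapply(seq_len(k), function(i) {
      colMeans(mat[cl == i, , drop = FALSE])
    }))
    colnames(centroids) <- colnames(mat)
  }
  structure(list(transcript_id = rownames(mat),
                 gene_id = attr(mat, "gene_id"),
                 cluster = unname(cl), centroids = centroids,
                 method = method, k = k),
            class = "cluster_assignment")
}

#' Assign canonical sensitivity-category names to clusters
#'
#' Names are derived from the strongest-dose (highest concentration)
#' centroid coordinates (mean core LFC c, mean pause LFC p):
#' the cluster with the largest `c - p` (pause-specific loss) is
#' `highly-sensitive-pause`; of the rest, the largest `p - c` is
#' `highly-sensitive-core`; of the remaining two, the lower `c + p` is
#' `highly-sensitive-both` and the other `sensitive-both`. Ties break by
#' cluster index; the labeling is invariant to cluster re-indexing.
#'
#' @param assignment a [cluster_tss()] result with k = 4.
#' @return the assignment with `label` (per TSS) and `cluster_labels`
#'   (index -> name bijection) added.
#' @export
name_clusters <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            assignment$k == 4)
  cen <- assignment$centroids
  cols <- colnames(cen)
  doses <- unique(sub("^lfc_([^_]+)_.*$", "\\1", cols))
  top <- doses[which.max(as.numeric(doses))]
  cbar <- cen[, paste0("lfc_", top, "_core")]
  pbar <- cen[, paste0("lfc_", top, "_pause")]
  labels <- rep(NA_character_, 4)
  remaining <- seq_len(4)
  pick <- function(score, rem) rem[which.max(score[rem])]
  i_pause <- pick(cbar - pbar, remaining)
  labels[i_pause] <- "highly-sensitive-pause"
  remaining <- setdiff(remaining, i_pause)
  i_core <- pick(pbar - cbar, remaining)
  labels[i_core] <- "highly-sensitive-core"
  remaining <- setdiff(remaining, i_core)
  i_hboth <- remaining[which.min((cbar + pbar)[remaining])]
  labels[i_hboth] <- "highly-sensitive-both"
  labels[setdiff(remaining, i_hboth)] <- "sensitive-both"
  assignment$cluster_labels <- labels
  assignment$label <- labels[assignment$cluster]
  assignment
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment (", x$method, "): ",
      length(x$transcript_id), " TSSs in ", x$k, " clusters\n", sep = "")
  if (!is.null(x$label)) print(table(x$label))
  invisible(x)
}

#' Shared gene counts between equivalently labeled clusters
#'
#' Counts gene ids shared per label pair across two models' assignments;
#' the diagonal holds the equivalent-cluster overlaps.
#'
#' @param a,b labeled [name_clusters()] assignments.
#' @return 4x4 integer matrix (rows = labels of `a`, columns = `b`).
#' @export
cluster_overlap <- function(a, b) {
  stopifnot(!is.null(a$label), !is.null(b$label))
  labs <- c("sensitive-both", "highly-sensitive-both",
            "highly-sensitive-pause", "highly-sensitive-core")
  out <- matrix(0L, 4, 4, dimnames = list(labs, labs))
  ga <- if (is.null(a$gene_id)) a$transcript_id else a$gene_id
  gb <- if (is.null(b$gene_id)) b$transcript_id else b$gene_id
  for (i in labs) {
    for (j in labs) {
      out[i, j] <- length(intersect(ga[a$label == i], gb[b$label == j]))
    }
  }
  out
}
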