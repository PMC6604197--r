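## Expression integration: NB differential expression (reusing the
## diffbind Wald machinery), DB/DE overlap statistics, and cluster-wise
## paired Wilcoxon comparisons of expression fold changes across models.

#' Negative-binomial differential expression, one dose versus vehicle
#'
#' Same NB Wald machinery as the binding test; a gene is flagged
#' significant when adjusted p < `fdr` AND |LFC| > `lfc_cut` (the dual
#' threshold convention for expression).
#'
#' @param counts gene x sample count matrix.
#' @param coldata data.frame with `sample`, `dose`, `replicate`.
#' @param dose treated dose to contrast against vehicle.
#' @param fdr adjusted-p threshold (default 0.05).
#' @param lfc_cut absolute log2-fold-change threshold (default 1).
#' @param min_count minimum total normalized count (default 10).
#' @return data.frame of class `de_result`: `gene_id`, `base_mean`,
#'   `lfc`, `se`, `p`, `padj`, `significant`, `direction`.
#' @export
differential_expression <- function(counts, coldata, dose, fdr = 0.05,
                                    lfc_cut = 1, min_count = 10) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  sf <- size_factors(counts)
  g0 <- which(coldata$dose == 0)
  g1 <- which(coldata$dose == dose)
  res <- .nb_wald_core(counts, g0, g1, sf, min_count = min_count)
  res$padj <- bh_adjust(res$p)
  res$significant <- !is.na(res$padj) & res$padj < fdr &
    abs(res$lfc) > lfc_cut
  res$direction <- ifelse(res$lfc < 0, "down", "up")
  out <- cbind(data.frame(gene_id = rownames(counts)), dose = dose, res)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Overlap between differentially bound and differentially expressed genes
#'
#' Maps affected transcripts to genes, intersects with the significantly
#' deregulated genes in the requested direction, and reports the overlap
#' count and its percentage of the deregulated set.
#'
#' @param affected an [affected_tss_table()] result (or a character
#'   vector of affected transcript ids).
#' @param de a `de_result` from [differential_expression()].
#' @param tx2gene data.frame mapping `transcript_id` to `gene_id`
#'   (e.g. the annotation's `genes` table); unnecessary when `affected`
#'   already carries gene ids via `windows`.
#' @param direction `"down"` (default) or `"up"`.
#' @return list: `n_overlap`, `n_de`, `percentage`, `genes`.
#' @export
db_de_overlap <- function(affected, de, tx2gene, direction = "down") {
  ids <- if (is.list(affected)) affected$affected_ids else affected
  db_genes <- unique(tx2gene$gene_id[match(ids, tx2gene$transcript_id)])
  de_genes <- de$gene_id[de$significant & de$direction == direction]
  ov <- intersect(db_genes, de_genes)
  list(n_overlap = length(ov), n_de = length(de_genes),
       percentage = if (length(de_genes) == 0) 0 else
         round(100 * length(ov) / length(de_genes), 1),
       genes = ov)
}

## Wilcoxon signed-rank with Pratt handling of zero differences:
## zeros are ranked with the rest, then their ranks are discarded from
## the statistic; normal approximation with tie/zero variance correction.
.wilcoxon_pratt <- function(d, alternative = "two.sided") {
  n_all <- length(d)
  r <- rank(abs(d))
  nz <- d != 0
  if (!any(nz)) {
    return(list(p = NA_real_, statistic = NA_real_, n = 0,
                untested = TRUE))
  }
  w_pos <- sum(r[nz & d > 0])
  n0 <- sum(!nz)
  mu <- (n_all * (n_all + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(r)
  sigma2 <- n_all * (n_all + 1) * (2 * n_all + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(list(p = NA_real_, statistic = w_pos, n = sum(nz),
                untested = TRUE))
  }
  z <- (w_pos - mu) / sqrt(sigma2)
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  list(p = min(p, 1), statistic = w_pos, n = sum(nz), untested = FALSE)
}

#' Cluster-wise paired comparison of expression fold changes
#'
#' For each sensitivity cluster, pairs every gene's expression LFC in
#' model A with its LFC in model B and applies a two-sided Wilcoxon
#' signed-rank test (Pratt zero handling). Clusters with fewer than
#' `min_pairs` shared tested genes are flagged untested.
#'
#' @param assignment labeled [name_clusters()] result.
#' @param de_a,de_b `de_result` tables for the two models (same dose).
#' @param min_pairs minimum paired genes (default 6).
#' @param alternative test sidedness for (A - B) differences.
#' @return data.frame: `label`, `n_pairs`, `median_lfc_a`,
#'   `median_lfc_b`, `p`, `untested`.
#' @export
cluster_expression_compare <- function(assignment, de_a, de_b,
                                       min_pairs = 6,
                                       alternative = "two.sided") {
  stopifnot(!is.null(assignment$label))
  ga <- if (is.null(assignment$gene_id)) assignment$transcript_id else
    assignment$gene_id
  out <- lapply(unique(assignment$label), function(lab) {
    genes <- unique(ga[assignment$label == lab])
    a <- de_a$lfc[match(genes, de_a$gene_id)]
    b <- de_b$lfc[match(genes, de_b$gene_id)]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_pairs) {
      return(data.frame(label = lab, n_pairs = sum(ok),
                        median_lfc_a = NA_real_, median_lfc_b = NA_real_,
                        p = NA_real_, untested = TRUE))
    }
    wt <- .wilcoxon_pratt(a[ok] - b[ok], alternative = alternative)
    data.frame(label = lab, n_pairs = sum(ok),
               median_lfc_a = median(a[ok]), median_lfc_b = median(b[ok]),
               p = wt$p, untested = wt$untested)
  })
  do.call(rbind, out)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}
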