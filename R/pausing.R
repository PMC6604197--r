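## RNA Pol II pausing: traveling ratio (pausing index) from coverage,
## treatment-induced TR shifts, and the two-sample proportion test used
## to compare gained fractions across promoter sensitivity clusters.

## Per-base mean of a binned track over the 0-based half-open region
## [a, b); partial bins are weighted by their overlap.
.region_mean <- function(track, chrom, a, b) {
  bs <- track$bin_size
  v <- track$cov[[chrom]]
  first <- floor(a / bs) + 1
  last <- floor((b - 1) / bs) + 1
  if (first < 1 || last > length(v)) return(NA_real_)
  vals <- as.numeric(v[first:last])
  w <- rep(bs, length(vals))
  w[1] <- w[1] - (a - (first - 1) * bs)
  w[length(w)] <- w[length(w)] - (last * bs - b)
  if (length(w) == 1) w <- b - a
  sum(vals * w) / (b - a)
}

#' Traveling ratio (pausing index) of a gene
#'
#' Promoter density is the mean coverage over \[TSS-100, TSS+300\]
#' (401 bp, transcription-oriented); body density is the mean from
#' 301 bp past the TSS to the TES. TR = promoter density / body density.
#' The record is invalid when the body density is zero, the gene body is
#' shorter than `min_body` bp past the promoter, or a region leaves the
#' chromosome.
#'
#' @param track a `coverage_track`.
#' @param gene one row of an annotation's `genes` table.
#' @param min_body minimum body length in bp (default 200).
#' @return data.frame: `gene_id`, `promoter_density`, `body_density`,
#'   `tr`, `valid`.
#' @export
traveling_ratio <- function(track, gene, min_body = 200) {
  t <- gene$tss
  if (gene$strand == "+") {
    prom <- c(t - 100, t + 301)
    body <- c(t + 301, gene$tes)
  } else {
    prom <- c(t - 300, t + 101)
    body <- c(gene$tes, t - 300)
  }
  invalid <- function() data.frame(gene_id = gene$gene_id,
                                   promoter_density = NA_real_,
                                   body_density = NA_real_,
                                   tr = NA_real_, valid = FALSE)
  if (body[2] - body[1] < min_body) return(invalid())
  len <- track$chrom_sizes[[gene$chrom]]
  if (prom[1] < 0 || body[1] < 0 || prom[2] > len || body[2] > len) {
    return(invalid())
  }
  pd <- .region_mean(track, gene$chrom, prom[1], prom[2])
  bd <- .region_mean(track, gene$chrom, body[1], body[2])
  if (is.na(pd) || is.na(bd) || bd <= 0) return(invalid())
  data.frame(gene_id = gene$gene_id, promoter_density = pd,
             body_density = bd, tr = pd / bd, valid = TRUE)
}

#' Traveling ratios for all genes in an annotation
#'
#' @param track a `coverage_track`.
#' @param annotation a [genome_annotation()].
#' @param min_body minimum body length in bp.
#' @return data.frame with one row per gene (invalid genes flagged).
#' @export
traveling_ratio_all <- function(track, annotation, min_body = 200) {
  g <- annotation$genes
  out <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    traveling_ratio(track, g[i, ], min_body = min_body)
  }))
  rownames(out) <- NULL
  out
}

#' Treatment-induced traveling-ratio shift
#'
#' Fold change of TR (treated / vehicle) per gene; a gene "gains" in TR
#' when the fold change exceeds `gain_threshold` (`gain_mode = "fold"`,
#' the default) or when the post-treatment TR itself exceeds the
#' threshold (`gain_mode = "absolute"`).
#'
#' @param vehicle,treated TR tables from [traveling_ratio_all()] for the
#'   two conditions.
#' @param gain_threshold threshold (default 2).
#' @param gain_mode `"fold"` or `"absolute"`.
#' @return data.frame: `gene_id`, `tr_vehicle`, `tr_treated`, `fold`,
#'   `gained`; genes invalid in either condition are dropped.
#' @export
tr_shift <- function(vehicle, treated, gain_threshold = 2,
                     gain_mode = c("fold", "absolute")) {
  gain_mode <- match.arg(gain_mode)
  common <- intersect(vehicle$gene_id[vehicle$valid],
                      treated$gene_id[treated$valid])
  v <- vehicle[match(common, vehicle$gene_id), ]
  t <- treated[match(common, treated$gene_id), ]
  fold <- t$tr / v$tr
  gained <- if (gain_mode == "fold") fold > gain_threshold else
    t$tr > gain_threshold
  data.frame(gene_id = common, tr_vehicle = v$tr, tr_treated = t$tr,
             fold = fold, gained = gained)
}

#' Two-sample test of equal proportions
#'
#' Chi-square test with Yates continuity correction by default (the
#' convention of standard statistical software for a 2x2 proportion
#' comparison); an uncorrected two-sample z-test is available with
#' `correct = FALSE`. Symmetric in the two groups.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @param correct apply continuity correction (default TRUE).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (group 1 proportion vs group 2).
#' @return two-sided (or one-sided) p-value.
#' @export
proportion_test <- function(k1, n1, k2, n2, correct = TRUE,
                            alternative = "two.sided") {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if (correct) {
    suppressWarnings(
      prop.test(c(k1, k2), c(n1, n2), correct = TRUE,
                alternative = alternative)$p.value)
  } else {
    p1 <- k1 / n1; p2 <- k2 / n2
    p <- (k1 + k2) / (n1 + n2)
    se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
    if (se == 0) return(1)
    z <- (p1 - p2) / se
    switch(alternative,
           two.sided = 2 * pnorm(-abs(z)),
           greater = pnorm(z, lower.tail = FALSE),
           less = pnorm(z))
  }
}

#' Compare TR-gain fractions between two promoter clusters
#'
#' @param shift a [tr_shift()] table.
#' @param assignment labeled [name_clusters()] result.
#' @param label1,label2 cluster labels to compare.
#' @param alternative passed to [proportion_test()] (group 1 = `label1`).
#' @return list: per-cluster gained counts/totals and the p-value.
#' @export
tr_gain_by_cluster <- function(shift, assignment, label1, label2,
                               alternative = "two.sided") {
  ga <- if (is.null(assignment$gene_id)) assignment$transcript_id else
    assignment$gene_id
  pick <- function(lab) {
    genes <- ga[assignment$label == lab]
    sub <- shift[shift$gene_id %in% genes, ]
    c(gained = sum(sub$gained), n = nrow(sub))
  }
  a <- pick(label1); b <- pick(label2)
  p <- proportion_test(a["gained"], a["n"], b["gained"], b["n"],
                       alternative = alternative)
  list(cluster1 = a, cluster2 = b, p = unname(p))
}
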