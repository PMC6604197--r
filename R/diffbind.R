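## Differential binding at promoter windows: fragment counting,
## median-of-ratios size factors, and a per-row negative-binomial Wald
## test (moment dispersion shrunk 50% toward a fitted mean-dispersion
## trend) with Benjamini-Hochberg correction, plus the affected-TSS
## tabulation.

#' Count fragments in promoter windows
#'
#' A fragment is counted in every window it overlaps by at least one
#' base, so a fragment spanning the TSS contributes to both the core and
#' pause windows, and possibly to windows of nearby TSSs.
#'
#' @param samples named list of fragment sets (inputs excluded by the
#'   caller).
#' @param windows a [tss_windows()] result.
#' @return integer matrix, rows `transcript:window`, columns samples;
#'   sample metadata in `attr(, "coldata")`, window metadata in
#'   `attr(, "rowdata")`.
#' @export
count_in_windows <- function(samples, windows) {
  stopifnot(length(samples) > 0, nrow(windows) > 0)
  row_id <- paste(windows$transcript_id, windows$window, sep = ":")
  counts <- sapply(samples, function(s) {
    f <- s$fragments
    out <- integer(nrow(windows))
    for (chr in unique(windows$chrom)) {
      wi <- which(windows$chrom == chr)
      fi <- which(f$chrom == chr)
      if (length(fi) == 0) next
      out[wi] <- IRanges::countOverlaps(
        .as_iranges(windows[wi, , drop = FALSE]),
        .as_iranges(f[fi, , drop = FALSE]))
    }
    out
  })
  counts <- matrix(as.integer(counts), nrow = nrow(windows),
                   dimnames = list(row_id, names(samples)))
  coldata <- do.call(rbind, lapply(names(samples), function(nm) {
    m <- samples[[nm]]$meta
    data.frame(sample = nm, model = m$model, dose = m$dose,
               replicate = m$replicate)
  }))
  attr(counts, "coldata") <- coldata
  attr(counts, "rowdata") <- data.frame(
    row_id = row_id, transcript_id = windows$transcript_id,
    gene_id = windows$gene_id, window = windows$window)
  counts
}

#' Median-of-ratios size factors
#'
#' Per-sample factor = median over rows (restricted to rows with an
#' all-positive geometric mean) of `count / geometric row mean`,
#' rescaled so the factors have geometric mean 1.
#'
#' @param counts count matrix (rows features, columns samples).
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  log_gm <- rowMeans(log(counts))
  ok <- is.finite(log_gm)
  if (!any(ok)) stop("no rows with all-positive counts")
  sf <- apply(counts[ok, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_gm[ok]))
  })
  sf / exp(mean(log(sf)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment; `NA`s (untested rows) are preserved.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

## Core NB Wald machinery shared by differential binding and expression.
## Returns lfc/se/p per row for one two-group contrast.
.nb_wald_core <- function(counts, g0, g1, sf, min_count = 10,
                          shrink = 0.5) {
  q <- sweep(counts, 2, sf, "/")
  n0 <- length(g0); n1 <- length(g1)
  if (n0 < 2 || n1 < 2) stop("need >= 2 replicates per group")
  m0 <- rowMeans(q[, g0, drop = FALSE])
  m1 <- rowMeans(q[, g1, drop = FALSE])
  m <- rowMeans(q[, c(g0, g1), drop = FALSE])
  tested <- rowSums(q[, c(g0, g1), drop = FALSE]) >= min_count
  ## moment dispersion from pooled within-group variance of normalized
  ## counts: E[s2] ~ mu * mean(1/sf) + disp * mu^2
  ss <- rowSums((q[, g0, drop = FALSE] - m0)^2) +
    rowSums((q[, g1, drop = FALSE] - m1)^2)
  s2 <- ss / (n0 + n1 - 2)
  inv_sf <- mean(1 / sf[c(g0, g1)])
  d_raw <- pmax((s2 - m * inv_sf) / m^2, 1e-8)
  d_raw[!is.finite(d_raw)] <- 1e-8
  ## mean-dispersion trend disp ~ a + b/mu, fitted on tested rows
  fit_rows <- which(tested & m > 0 & d_raw > 1e-8)
  if (length(fit_rows) >= 10) {
    fit <- lm(d_raw[fit_rows] ~ I(1 / m[fit_rows]))
    d_trend <- pmax(coef(fit)[1] + coef(fit)[2] / m, 1e-8)
  } else {
    d_trend <- rep(max(mean(d_raw[tested]), 1e-8), length(d_raw))
  }
  if (all(s2 == 0)) {
    warning("zero variance everywhere; dispersion floored at 1e-8")
  }
  disp <- (1 - shrink) * d_raw + shrink * d_trend
  ## pseudo-mean guard for zero groups (only possible near min_count)
  eps <- 0.5
  m0g <- ifelse(m0 > 0 & m1 > 0, m0, m0 + eps)
  m1g <- ifelse(m0 > 0 & m1 > 0, m1, m1 + eps)
  lfc <- log2(m1g / m0g)
  v0 <- (m0g * sum(1 / sf[g0]) / n0 + disp * m0g^2) / n0
  v1 <- (m1g * sum(1 / sf[g1]) / n1 + disp * m1g^2) / n1
  se <- sqrt(v0 / m0g^2 + v1 / m1g^2) / log(2)
  ## Wald t: the dispersion is only (1 - shrink) data-driven, so the
  ## effective df are the residual df scaled by 1/(1-shrink)^2
  ## (Satterthwaite-style); with 2v2 and shrink 0.5 this gives df = 8.
  df_eff <- (n0 + n1 - 2) / (1 - shrink)^2
  stat <- lfc / se
  p <- 2 * pt(-abs(stat), df = df_eff)
  p[!tested] <- NA_real_
  data.frame(base_mean = m, lfc = lfc, se = se, stat = stat, p = p,
             dispersion = disp, tested = tested)
}

#' Negative-binomial Wald test per window, one dose versus vehicle
#'
#' Normalizes by size factors, estimates a per-row moment dispersion
#' shrunk 50% toward a fitted mean-dispersion trend, and reports a Wald
#' test on the log2 fold change (treated vs vehicle). Rows whose total
#' normalized count is below `min_count` are filtered (`p = NA`).
#'
#' @param counts matrix from [count_in_windows()] (or any count matrix
#'   with a `coldata` attribute; alternatively pass `coldata`).
#' @param dose treated dose to contrast against vehicle (dose 0).
#' @param coldata sample metadata (defaults to the matrix attribute).
#' @param sf size factors (defaults to [size_factors()] of the full
#'   matrix).
#' @param min_count minimum total normalized count (default 10).
#' @param shrink dispersion shrinkage weight toward the trend
#'   (default 0.5).
#' @return data.frame of class `db_result`: identifiers, `dose`,
#'   `base_mean`, `lfc`, `se`, `p`, `padj`, `tested`.
#' @export
nb_wald_test <- function(counts, dose, coldata = attr(counts, "coldata"),
                         sf = NULL, min_count = 10, shrink = 0.5) {
  stopifnot(!is.null(coldata), dose %in% coldata$dose,
            0 %in% coldata$dose)
  if (is.null(sf)) sf <- size_factors(counts)
  g0 <- which(coldata$dose == 0)
  g1 <- which(coldata$dose == dose)
  res <- .nb_wald_core(counts, g0, g1, sf, min_count = min_count,
                       shrink = shrink)
  res$padj <- bh_adjust(res$p)
  rd <- attr(counts, "rowdata")
  if (!is.null(rd)) {
    res <- cbind(rd, dose = dose, res)
  } else {
    res <- cbind(data.frame(row_id = rownames(counts)), dose = dose, res)
  }
  rownames(res) <- NULL
  class(res) <- c("db_result", "data.frame")
  res
}

#' Run the per-dose differential binding analysis
#'
#' Convenience wrapper: one [nb_wald_test()] per non-vehicle dose, with
#' size factors estimated once from the full matrix.
#'
#' @inheritParams nb_wald_test
#' @return a single `db_result` data.frame stacking all dose contrasts.
#' @export
diffbind_all_doses <- function(counts, coldata = attr(counts, "coldata"),
                               min_count = 10) {
  sf <- size_factors(counts)
  doses <- sort(setdiff(unique(coldata$dose), 0))
  out <- do.call(rbind, lapply(doses, function(d) {
    nb_wald_test(counts, d, coldata = coldata, sf = sf,
                 min_count = min_count)
  }))
  class(out) <- c("db_result", "data.frame")
  out
}

#' Tabulate affected TSSs per dose and window
#'
#' A TSS is affected at a window if any dose contrast has adjusted
#' p < `fdr` with negative LFC (displacement); with
#' `two_sided_affected = TRUE` the sign condition is dropped. Reports
#' per-dose and overall counts for core-only, pause-only, both, and any,
#' with percentages of the total TSS universe.
#'
#' @param results a `db_result` from [diffbind_all_doses()].
#' @param fdr adjusted-p threshold (default 0.05).
#' @param two_sided_affected count increases as well as losses.
#' @return list: `per_dose` data.frame, `overall` data.frame,
#'   `affected_ids` (transcript ids affected at any window/dose),
#'   `affected_window_ids` (per-window id lists), `n_tss`.
#' @export
affected_tss_table <- function(results, fdr = 0.05,
                               two_sided_affected = FALSE) {
  sig <- !is.na(results$padj) & results$padj < fdr
  if (!two_sided_affected) sig <- sig & results$lfc < 0
  n_tss <- length(unique(results$transcript_id))
  tab_for <- function(rows) {
    core <- unique(results$transcript_id[rows & results$window == "core"])
    pause <- unique(results$transcript_id[rows & results$window == "pause"])
    both <- intersect(core, pause)
    any_ <- union(core, pause)
    data.frame(core_only = length(setdiff(core, pause)),
               pause_only = length(setdiff(pause, core)),
               both = length(both), any = length(any_),
               pct_any = round(100 * length(any_) / n_tss, 1))
  }
  per_dose <- do.call(rbind, lapply(sort(unique(results$dose)),
                                    function(d) {
    cbind(dose = d, tab_for(sig & results$dose == d))
  }))
  overall <- tab_for(sig)
  core_ids <- unique(results$transcript_id[sig & results$window == "core"])
  pause_ids <- unique(results$transcript_id[sig & results$window == "pause"])
  list(per_dose = per_dose, overall = overall,
       affected_ids = union(core_ids, pause_ids),
       affected_window_ids = list(core = core_ids, pause = pause_ids),
       n_tss = n_tss)
}
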