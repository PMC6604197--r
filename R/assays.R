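## Wet-lab assay models: efficiency-corrected qPCR quantification with
## vehicle-mean normalization and paired t-tests, reference-gene
## selection, and the proliferation response-area statistic.

#' Efficiency-corrected relative abundance from qPCR Ct values
#'
#' `X = (1 + EffR)^CtR / (1 + EffX)^CtX`, the Delta-Ct method corrected
#' for per-primer amplification efficiency (X = target, R = reference).
#' Efficiencies are fractions in (0, 1\]; Eff = 1 recovers the classic
#' `2^(CtR - CtX)`.
#'
#' @param ct_x,ct_r threshold cycles of target and reference (> 0).
#' @param eff_x,eff_r amplification efficiencies in (0, 1\].
#' @return relative abundance (vectorized).
#' @export
qpcr_expression <- function(ct_x, ct_r, eff_x, eff_r) {
  if (any(eff_x <= 0) || any(eff_x > 1) || any(eff_r <= 0) ||
      any(eff_r > 1)) {
    stop("efficiencies must lie in (0, 1]")
  }
  if (any(ct_x <= 0) || any(ct_r <= 0)) stop("Ct values must be > 0")
  (1 + eff_r)^ct_r / (1 + eff_x)^ct_x
}

#' Scale expression values so the vehicle-group mean is 1
#'
#' Every value is divided by the mean of the DMSO (vehicle) group, the
#' convention for displaying qPCR comparisons.
#'
#' @param values numeric vector.
#' @param condition factor/character with `"DMSO"` marking the vehicle
#'   group.
#' @return rescaled values.
#' @export
normalize_to_dmso <- function(values, condition) {
  stopifnot(length(values) == length(condition),
            any(condition == "DMSO"))
  m <- mean(values[condition == "DMSO"])
  if (m == 0) stop("DMSO mean is zero; cannot normalize")
  values / m
}

#' Paired t-test with significance stars
#'
#' Two-sided paired t-test between replicate-paired vehicle and treated
#' values; stars: `**` for p < 0.005, `*` for p < 0.05, `""` otherwise.
#' Identical vectors (zero variance of differences) are flagged with
#' `p = NA` and no star.
#'
#' @param dmso,treated equal-length (>= 2) paired numeric vectors.
#' @return list: `p`, `star`, `mean_ratio` (treated/vehicle means).
#' @export
paired_expression_test <- function(dmso, treated) {
  stopifnot(length(dmso) == length(treated), length(dmso) >= 2)
  d <- treated - dmso
  if (sd(d) == 0) {
    return(list(p = NA_real_, star = "",
                mean_ratio = mean(treated) / mean(dmso)))
  }
  p <- t.test(treated, dmso, paired = TRUE)$p.value
  star <- if (p < 0.005) "**" else if (p < 0.05) "*" else ""
  list(p = p, star = star, mean_ratio = mean(treated) / mean(dmso))
}

#' Estimate fold change from a simulated/measured qPCR Ct table
#'
#' Applies [qpcr_expression()] per well, normalizes to the DMSO mean,
#' and tests treated vs vehicle with a paired t-test.
#'
#' @param ct_table data.frame as produced by [simulate_qpcr()].
#' @return list: `fold` (mean treated relative abundance after DMSO
#'   normalization), `p`, `star`, `values`.
#' @export
qpcr_fold_change <- function(ct_table) {
  x <- qpcr_expression(ct_table$CtX, ct_table$CtR, ct_table$EffX,
                       ct_table$EffR)
  xn <- normalize_to_dmso(x, ct_table$condition)
  dmso <- xn[ct_table$condition == "DMSO"]
  trt <- xn[ct_table$condition != "DMSO"]
  test <- paired_expression_test(dmso, trt)
  list(fold = mean(trt), p = test$p, star = test$star, values = xn)
}

#' Rank reference-gene candidates from differential expression results
#'
#' Implements the stated selection criteria: candidates must be
#' non-significant at every dose up to `max_dose` in both models and
#' expressed above the `expr_quantile` quantile of base means in both;
#' candidates are returned ranked by their largest absolute LFC (most
#' stable first).
#'
#' @param de_list list of `de_result` tables (all models x doses to
#'   screen).
#' @param max_dose highest dose at which stability is required
#'   (default 500).
#' @param expr_quantile expression quantile floor (default 0.8).
#' @return data.frame: `gene_id`, `max_abs_lfc`, ranked ascending.
#' @export
select_reference_genes <- function(de_list, max_dose = 500,
                                   expr_quantile = 0.8) {
  screened <- lapply(de_list, function(de) de[de$dose <= max_dose, ])
  screened <- screened[vapply(screened, nrow, 1L) > 0]
  stopifnot(length(screened) > 0)
  genes <- Reduce(intersect, lapply(screened, function(de) de$gene_id))
  ok <- rep(TRUE, length(genes))
  max_lfc <- rep(0, length(genes))
  for (de in screened) {
    idx <- match(genes, de$gene_id)
    ok <- ok & !de$significant[idx] &
      de$base_mean[idx] >= quantile(de$base_mean, expr_quantile,
                                    na.rm = TRUE)
    max_lfc <- pmax(max_lfc, abs(de$lfc[idx]), na.rm = TRUE)
  }
  out <- data.frame(gene_id = genes[ok], max_abs_lfc = max_lfc[ok])
  out[order(out$max_abs_lfc), , drop = FALSE]
}

#' Dose-response area (1 - viability)
#'
#' Normalized trapezoidal integral of the response `1 - viability` over
#' log10 concentration, divided by the log-range: the fraction of the
#' maximal possible response. 0 for full viability everywhere, 1 for
#' complete killing everywhere.
#'
#' @param concentrations strictly increasing positive concentrations
#'   (nM).
#' @param viability viability fractions in \[0, 1\] (small overshoot
#'   tolerated and clipped).
#' @return response area in \[0, 1\].
#' @export
response_area <- function(concentrations, viability) {
  stopifnot(length(concentrations) == length(viability),
            length(concentrations) >= 2,
            all(diff(concentrations) > 0), all(concentrations > 0))
  if (any(viability < -0.05) || any(viability > 1.05)) {
    stop("viability outside [0, 1] beyond tolerance")
  }
  v <- pmin(pmax(viability, 0), 1)
  x <- log10(concentrations)
  .trapz(x, 1 - v) / (max(x) - min(x))
}
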