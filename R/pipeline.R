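## End-to-end orchestration: simulate -> coverage -> peaks -> differential
## binding -> clustering -> Pol II pausing -> expression, with per-stage
## seeds derived from one global seed, a manifest of written artifacts,
## and a summary of the record counts a reviewer would compare across
## runs.

#' Run the full analysis pipeline on synthetic data
#'
#' Stages execute in dependency order; every artifact is written under
#' `outdir` as plain text and recorded in `manifest.tsv` with stage name
#' and md5 hash, so a rerun with the same config and seed is
#' bit-identical for the deterministic stages.
#'
#' @param config a [sim_config()]; its `seed` drives all stages.
#' @param outdir output directory (created if missing); `NULL` skips
#'   artifact writing and returns results in memory only.
#' @param mode `"full"` (default), `"simulate"` (data + truth only) or
#'   `"analyze"` (requires `sim` from a previous run).
#' @param sim optional pre-computed [simulate_chip()] result.
#' @param fdr significance threshold for differential binding.
#' @param tr_dose dose (nM) at which traveling-ratio shifts are
#'   assessed (default 500).
#' @return list of class `betshift_run` with elements per stage
#'   (`sim`, `profile`, `modes`, `peaks`, `db`, `affected`, `clusters`,
#'   `tr`, `de`, `summary`).
#' @export
run_pipeline <- function(config, outdir = NULL,
                         mode = c("full", "simulate", "analyze"),
                         sim = NULL, fdr = 0.05, tr_dose = 500) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  manifest <- list()
  emit <- function(obj, name, stage, writer = NULL) {
    if (is.null(outdir)) return(invisible(NULL))
    path <- file.path(outdir, name)
    if (is.null(writer)) {
      write.table(obj, path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else {
      writer(obj, path)
    }
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, artifact = name,
      md5 = unname(tools::md5sum(path)))
    invisible(path)
  }

  ## stage 1: simulation -------------------------------------------------
  if (is.null(sim)) {
    if (mode == "analyze") stop("mode 'analyze' requires a `sim` object")
    sim <- simulate_chip(config)
  }
  ann <- sim$annotation
  emit(ann$genes, "genes.tsv", "simulate")
  emit(sim$truth$classes, "truth_classes.tsv", "simulate")
  emit(sim$truth$fractions, "truth_fractions.tsv", "simulate")
  message(sprintf("[simulate] %d TSSs, %d samples, model=%s",
                  nrow(ann$genes), length(sim$samples),
                  config$cell_model))
  if (mode == "simulate") {
    out <- list(config = config, sim = sim,
                manifest = do.call(rbind, manifest))
    class(out) <- "betshift_run"
    return(out)
  }
  chip <- sim$samples[!vapply(sim$samples,
                              function(s) s$meta$is_input, logical(1))]
  input <- sim$samples[[grep("input", names(sim$samples))[1]]]

  ## stage 2: coverage + TSS metaprofile (vehicle replicate 1) -----------
  veh_name <- names(chip)[vapply(chip, function(s) s$meta$dose == 0 &&
                                   s$meta$replicate == 1, logical(1))][1]
  track <- rpgc_normalize(extend_and_bin(chip[[veh_name]],
                                         config$chrom_sizes))
  itrack <- rpgc_normalize(extend_and_bin(input, config$chrom_sizes))
  strack <- subtract_input(track, itrack)
  anchors <- data.frame(chrom = ann$genes$chrom, pos = ann$genes$tss,
                        strand = ann$genes$strand)
  profile <- metaprofile(strack, anchors)
  modes <- profile_modes(profile)
  emit(data.frame(offset = profile$offsets, signal = profile$signal),
       "tss_metaprofile.tsv", "coverage")
  message(sprintf(paste0("[coverage] modes: upstream %s bp, downstream",
                         " %s bp, ratio %.2f"),
                  modes$upstream_mode, modes$downstream_mode,
                  modes$height_ratio))

  ## stage 3: consensus peaks (vehicle condition) ------------------------
  veh_reps <- chip[vapply(chip, function(s) s$meta$dose == 0,
                          logical(1))]
  peaks <- consensus_peak_pipeline(veh_reps, input, ann,
                                   seed = config$seed)
  emit(peaks, "peaks_vehicle.tsv", "peaks")
  message(sprintf("[peaks] %d consensus peaks (vehicle)", nrow(peaks)))

  ## stage 4: differential binding ---------------------------------------
  windows <- tss_windows(ann)
  counts <- count_in_windows(chip, windows)
  db <- diffbind_all_doses(counts)
  affected <- affected_tss_table(db, fdr = fdr)
  emit(db, "diffbind_results.tsv", "diffbind")
  emit(affected$per_dose, "affected_tss_per_dose.tsv", "diffbind")
  message(sprintf("[diffbind] %d/%d TSSs affected (%.1f%%)",
                  affected$overall$any, affected$n_tss,
                  affected$overall$pct_any))

  ## stage 5: sensitivity clustering -------------------------------------
  lfc_mat <- build_lfc_matrix(db, fdr = fdr)
  clusters <- NULL
  n_distinct <- nrow(unique(lfc_mat))
  if (nrow(lfc_mat) >= 8 && n_distinct >= 4) {
    clusters <- name_clusters(cluster_tss(lfc_mat, seed = config$seed))
    emit(data.frame(transcript_id = clusters$transcript_id,
                    gene_id = clusters$gene_id,
                    cluster = clusters$cluster,
                    label = clusters$label),
         "clusters.tsv", "cluster")
    message(paste0("[cluster] sizes: ",
                   paste(names(table(clusters$label)),
                         table(clusters$label), sep = "=",
                         collapse = ", ")))
  }

  ## stage 6: Pol II traveling ratio -------------------------------------
  polii <- simulate_polii(config, sim$truth, ann,
                          doses = c(0, tr_dose))
  tr_veh <- traveling_ratio_all(polii[["0"]], ann)
  tr_trt <- traveling_ratio_all(polii[[as.character(tr_dose)]], ann)
  shift <- tr_shift(tr_veh, tr_trt)
  emit(shift, "tr_shift.tsv", "pausing")
  message(sprintf("[pausing] %d/%d genes gained in TR at %g nM",
                  sum(shift$gained), nrow(shift), tr_dose))

  ## stage 7: expression --------------------------------------------------
  expr <- simulate_expression(config, sim$truth)
  de <- lapply(setdiff(config$doses, 0), function(d) {
    differential_expression(expr$counts, expr$coldata, d)
  })
  names(de) <- as.character(setdiff(config$doses, 0))
  top <- de[[as.character(max(config$doses))]]
  ov <- db_de_overlap(affected, top, ann$genes)
  emit(do.call(rbind, de), "de_results.tsv", "expression")
  message(sprintf(
    "[expression] %d DE genes at top dose; DB/DE overlap %d/%d (%.1f%%)",
    sum(top$significant), ov$n_overlap, ov$n_de, ov$percentage))

  summary <- list(
    n_tss = nrow(ann$genes),
    modes = modes,
    n_peaks_vehicle = nrow(peaks),
    affected = affected$overall,
    cluster_sizes = if (!is.null(clusters)) table(clusters$label),
    tr_gained = c(gained = sum(shift$gained), n = nrow(shift)),
    de_top_dose = sum(top$significant),
    db_de_overlap = ov[c("n_overlap", "n_de", "percentage")])
  out <- list(config = config, sim = sim, profile = profile,
              modes = modes, peaks = peaks, counts = counts, db = db,
              affected = affected, lfc_matrix = lfc_mat,
              clusters = clusters, tr = shift, de = de,
              expression = expr, summary = summary,
              manifest = do.call(rbind, manifest))
  if (!is.null(outdir)) {
    write.table(out$manifest, file.path(outdir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  class(out) <- "betshift_run"
  out
}

#' @export
print.betshift_run <- function(x, ...) {
  cat("betshift pipeline run (seed ", x$config$seed, ", model ",
      x$config$cell_model, ")\n", sep = "")
  if (!is.null(x$summary)) utils::str(x$summary, max.level = 1)
  invisible(x)
}
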