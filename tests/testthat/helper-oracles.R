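## Brute-force oracles and shared fixtures. Oracles are deliberately
## naive (all-pairs scans, per-base loops) and independent of the
## package's vectorized implementations.

## does interval (s1,e1) overlap (s2,e2) by >= 1 base? (0-based half-open)
ov1 <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

## all-pairs overlap scan: logical per query row
oracle_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(vapply(seq_len(nrow(subject)), function(j) {
      query$chrom[i] == subject$chrom[j] &&
        ov1(query$start[i], query$end[i],
            subject$start[j], subject$end[j])
    }, logical(1)))
  }, logical(1))
}

## per-base depth of extended fragments, binned means
oracle_binned_depth <- function(starts, ends, chrom_len, bin_size) {
  depth <- numeric(chrom_len)
  for (i in seq_along(starts)) {
    s <- max(starts[i], 0) + 1
    e <- min(ends[i], chrom_len)
    if (s <= e) depth[s:e] <- depth[s:e] + 1
  }
  n_bins <- ceiling(chrom_len / bin_size)
  vapply(seq_len(n_bins), function(b) {
    mean(depth[((b - 1) * bin_size + 1):min(b * bin_size, chrom_len)])
  }, numeric(1))
}

## naive GSEA running-sum enrichment score
oracle_gsea_es <- function(metric, set_genes, weight = 1) {
  ord <- order(-metric, names(metric))
  m <- metric[ord]
  hit <- names(m) %in% set_genes
  nr <- sum(abs(m[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_along(m)) {
    if (hit[i]) {
      run <- run + abs(m[i])^weight / nr
    } else {
      run <- run - 1 / (length(m) - sum(hit))
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

## small deterministic annotation: handful of genes on one chromosome
tiny_annotation <- function(chrom_len = 100000) {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    transcript_id = c("tA", "tB", "tC"),
    chrom = "chr1", strand = c("+", "-", "+"),
    tss = c(5000, 40000, 70000),
    tes = c(15000, 30000, 82000),
    biotype = c("coding", "coding", "noncoding"))
  genome_annotation(c(chr1 = chrom_len), genes)
}

## fragment set builder
frags <- function(chrom, start, end, strand = "+") {
  list(meta = list(model = "sensitive", track = "BRD4", dose = 0,
                   replicate = 1, is_input = FALSE),
       fragments = data.frame(chrom = chrom, start = start, end = end,
                              strand = strand))
}

## one default-scale pipeline run, computed lazily and cached for the
## whole test session (used by the recovery and geometry suites)
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$run)) {
    .run_cache$run <- suppressMessages(
      run_pipeline(sim_config(seed = 101), outdir = NULL))
  }
  .run_cache$run
}
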