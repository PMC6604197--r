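## Genome model: annotation container, promoter-window construction,
## enhancer/peak categorization, and plain-text interval I/O.
##
## All coordinates are 0-based half-open (BED convention). A gene's `tss`
## is always the transcription start (so tss < tes on '+', tes < tss on
## '-'); "upstream" and "downstream" are in transcription orientation.

#' Construct a genome annotation
#'
#' Bundles chromosome sizes, gene models and the interval sets the pipeline
#' needs (blacklist, enhancers, H3K27ac regions) into one validated object.
#' Gene records identical in (chrom, strand, tss) are collapsed to a single
#' record, keeping the lexicographically smallest `transcript_id` —
#' duplicate TSS entries in reference gene tables carry no extra
#' information for promoter-window analysis.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param genes data.frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand` (`+`/`-`), `tss`, `tes`, `biotype`
#'   (`coding`/`noncoding`).
#' @param blacklist,enhancers,h3k27ac optional interval data.frames
#'   (`chrom`, `start`, `end`).
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_sizes, genes,
                              blacklist = empty_intervals(),
                              enhancers = empty_intervals(),
                              h3k27ac = empty_intervals()) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0))
  req <- c("gene_id", "transcript_id", "chrom", "strand", "tss", "tes")
  stopifnot(is.data.frame(genes), all(req %in% names(genes)))
  if (!"biotype" %in% names(genes)) genes$biotype <- "coding"
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  bad <- (genes$strand == "+" & genes$tss >= genes$tes) |
         (genes$strand == "-" & genes$tes >= genes$tss)
  if (any(bad)) stop("tss/tes inconsistent with strand for ",
                     sum(bad), " gene record(s)")
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    stop("gene(s) on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  ## duplicate-TSS collapse: smallest transcript_id wins
  genes <- genes[order(genes$chrom, genes$strand, genes$tss,
                       genes$transcript_id), , drop = FALSE]
  key <- paste(genes$chrom, genes$strand, genes$tss)
  genes <- genes[!duplicated(key), , drop = FALSE]
  rownames(genes) <- NULL
  for (nm in c("blacklist", "enhancers", "h3k27ac")) {
    validate_intervals(get(nm), chrom_sizes)
  }
  structure(list(chrom_sizes = chrom_sizes, genes = genes,
                 blacklist = blacklist, enhancers = enhancers,
                 h3k27ac = h3k27ac),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chrom_sizes), "chromosome(s),",
      format(sum(x$chrom_sizes), big.mark = ","), "bp;",
      nrow(x$genes), "gene model(s);",
      nrow(x$blacklist), "blacklist,",
      nrow(x$enhancers), "enhancer,",
      nrow(x$h3k27ac), "H3K27ac interval(s)\n")
  invisible(x)
}

#' An empty interval data.frame
#' @return zero-row data.frame with columns `chrom`, `start`, `end`.
#' @export
empty_intervals <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
}

#' Core-promoter and pause-site windows around every TSS
#'
#' Builds, for each transcript, the 1 Kb upstream window ("core promoter")
#' and the 1 Kb downstream window ("Pol II pause site"), oriented by
#' strand and clipped to chromosome bounds. The two windows abut at the
#' TSS and never overlap.
#'
#' @param annotation a [genome_annotation()].
#' @param flank window size in bp (default 1000).
#' @return data.frame of class `promoter_windows`, one row per
#'   (transcript, window) with columns `transcript_id`, `gene_id`,
#'   `window` (`core`/`pause`), `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
tss_windows <- function(annotation, flank = 1000) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (flank <= 0) stop("flank must be > 0")
  g <- annotation$genes
  len <- annotation$chrom_sizes[g$chrom]
  plus <- g$strand == "+"
  core_start <- ifelse(plus, g$tss - flank, g$tss)
  core_end   <- ifelse(plus, g$tss,         g$tss + flank)
  pause_start <- ifelse(plus, g$tss,         g$tss - flank)
  pause_end   <- ifelse(plus, g$tss + flank, g$tss)
  clip <- function(v) pmin(pmax(v, 0), len)
  out <- rbind(
    data.frame(transcript_id = g$transcript_id, gene_id = g$gene_id,
               window = "core", chrom = g$chrom,
               start = clip(core_start), end = clip(core_end),
               strand = g$strand, tss = g$tss),
    data.frame(transcript_id = g$transcript_id, gene_id = g$gene_id,
               window = "pause", chrom = g$chrom,
               start = clip(pause_start), end = clip(pause_end),
               strand = g$strand, tss = g$tss))
  keep <- out$start < out$end
  if (any(!keep)) {
    warning(sum(!keep), " zero-length window(s) at chromosome edges dropped")
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("promoter_windows", "data.frame")
  out
}

## The union window TSS +/- flank per transcript, used for enhancer
## filtering and peak categorization.
.tss_union_windows <- function(annotation, flank = 1000) {
  g <- annotation$genes
  len <- annotation$chrom_sizes[g$chrom]
  data.frame(chrom = g$chrom,
             start = pmax(g$tss - flank, 0),
             end = pmin(g$tss + flank, len))
}

#' Keep enhancers with no TSS-proximal overlap
#'
#' Retains exactly the enhancers that share no base with any TSS +/- `flank`
#' window ("intergenic" enhancers in the promoter-proximal sense); input
#' order is preserved.
#'
#' @param enhancers interval data.frame.
#' @param annotation a [genome_annotation()].
#' @param flank promoter-window half-width in bp.
#' @return the retained subset of `enhancers`.
#' @export
filter_intergenic_enhancers <- function(enhancers, annotation, flank = 1000) {
  validate_intervals(enhancers, annotation$chrom_sizes)
  if (nrow(enhancers) == 0) return(enhancers)
  win <- .tss_union_windows(annotation, flank)
  keep <- !.overlaps_any(enhancers, win)
  out <- enhancers[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize peaks by genomic context
#'
#' Assigns each peak exactly one category with priority TSS > H3K27ac:
#' `"TSS+/-1Kb"` if it overlaps any TSS +/- `flank` window,
#' `"H3K27ac-non-TSS"` if it overlaps an H3K27ac region but no TSS window,
#' `"other"` otherwise.
#'
#' @param peaks interval data.frame.
#' @param annotation a [genome_annotation()].
#' @param flank promoter-window half-width in bp.
#' @return character vector of categories, one per peak.
#' @export
categorize_peaks <- function(peaks, annotation, flank = 1000) {
  validate_intervals(peaks, annotation$chrom_sizes)
  if (nrow(peaks) == 0) return(character(0))
  win <- .tss_union_windows(annotation, flank)
  in_tss <- .overlaps_any(peaks, win)
  in_ac <- .overlaps_any(peaks, annotation$h3k27ac)
  ifelse(in_tss, "TSS+/-1Kb", ifelse(in_ac, "H3K27ac-non-TSS", "other"))
}

## ---- plain-text I/O ----

#' Read/write BED intervals
#'
#' Minimal BED3/BED6 support: columns chrom, start, end and optionally
#' name, score, strand. Coordinates stay 0-based half-open.
#'
#' @param path file path.
#' @return data.frame of intervals.
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 6) names(x)[4:6] <- c("name", "score", "strand")
  validate_intervals(x)
  x
}

#' @param x interval data.frame (with optional `name`, `score`, `strand`).
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(x))) {
    cols <- c(cols, "name", "score", "strand")
  }
  write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene table (TSV)
#'
#' Expects a header line with columns `gene_id`, `transcript_id`, `chrom`,
#' `strand`, `tss`, `tes`, `biotype`.
#'
#' @param path file path.
#' @return data.frame of gene models.
#' @export
read_gene_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a two-column chrom.sizes file
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  setNames(as.numeric(x[[2]]), x[[1]])
}
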