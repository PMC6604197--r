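## Coverage tracks: fragment extension + binning, RPGC (1x) normalization,
## input subtraction, strand-oriented metaprofiles and mode detection.
##
## A coverage_track stores one run-length-encoded vector per chromosome;
## bin values are the mean per-base read depth within the bin (the
## convention of the standard coverage tooling this mirrors), so RPGC
## scaling makes the genome-wide mean per-base coverage exactly 1.

.coverage_track <- function(cov, bin_size, norm, chrom_sizes,
                            n_fragments, extension,
                            effective_genome_size = sum(chrom_sizes)) {
  structure(list(cov = cov, bin_size = bin_size, norm = norm,
                 chrom_sizes = chrom_sizes, n_fragments = n_fragments,
                 extension = extension,
                 effective_genome_size = effective_genome_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", x$norm, "| bin", x$bin_size, "bp |",
      length(x$cov), "chromosome(s) |",
      if (is.na(x$n_fragments)) "synthetic" else
        paste(x$n_fragments, "fragments"), "\n")
  invisible(x)
}

#' Extend fragments and bin into a raw coverage track
#'
#' Each fragment is extended to `extension` bp from its 5' end
#' (strand-aware), clipped at chromosome bounds, and converted to
#' per-base depth averaged within fixed `bin_size` bins.
#'
#' @param sample fragment set (list with `fragments` data.frame having
#'   `chrom`, `start`, `end` and optionally `strand`).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param bin_size bin width in bp (default 50).
#' @param extension extended fragment length in bp (default 300).
#' @return a `coverage_track` with `norm = "raw"`.
#' @export
extend_and_bin <- function(sample, chrom_sizes, bin_size = 50,
                           extension = 300) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (extension <= 0) stop("extension must be > 0")
  f <- sample$fragments
  validate_intervals(f, chrom_sizes)
  if (is.null(f$strand)) f$strand <- "+"
  plus <- f$strand != "-"
  ext_start <- ifelse(plus, f$start, f$end - extension)
  ext_end <- ifelse(plus, f$start + extension, f$end)
  ext_start <- pmax(ext_start, 0)
  ext_end <- pmin(ext_end, chrom_sizes[f$chrom])
  cov <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    n_bins <- ceiling(len / bin_size)
    ci <- which(f$chrom == chr)
    if (length(ci) == 0) return(S4Vectors::Rle(0, n_bins))
    ir <- IRanges::IRanges(start = ext_start[ci] + 1L, end = ext_end[ci])
    depth <- IRanges::coverage(ir, width = len)
    starts <- seq(1L, len, by = bin_size)
    v <- IRanges::Views(depth, start = starts,
                        width = pmin(bin_size, len - starts + 1L))
    S4Vectors::Rle(IRanges::viewMeans(v))
  })
  names(cov) <- names(chrom_sizes)
  .coverage_track(cov, bin_size, "raw", chrom_sizes,
                  n_fragments = nrow(f), extension = extension)
}

#' RPGC (1x genomic content) normalization
#'
#' Scales a raw track by `effective_genome_size / (n_fragments *
#' extension)` so that the mean per-base coverage over the effective
#' genome equals 1.
#'
#' @param track a raw `coverage_track`.
#' @param effective_genome_size effective genome size in bp; defaults to
#'   the track's full genome.
#' @return a `coverage_track` with `norm = "RPGC"`.
#' @export
rpgc_normalize <- function(track,
                           effective_genome_size =
                             track$effective_genome_size) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.na(track$n_fragments) || track$n_fragments == 0) {
    stop("cannot RPGC-normalize an empty or synthetic track: ",
         "scale undefined")
  }
  scale <- effective_genome_size / (track$n_fragments * track$extension)
  track$cov <- lapply(track$cov, function(r) r * scale)
  track$norm <- "RPGC"
  track$effective_genome_size <- effective_genome_size
  track
}

#' Subtract an input track from a treatment track
#'
#' Element-wise difference of two RPGC-normalized tracks on the same bin
#' grid. Negative values are preserved: they indicate bins where input
#' exceeds treatment and are informative for visualization; downstream
#' counting works from fragments, never from subtracted tracks.
#'
#' @param treatment,input RPGC-normalized `coverage_track`s.
#' @return a `coverage_track` with `norm = "RPGC-minus-input"`.
#' @export
subtract_input <- function(treatment, input) {
  stopifnot(inherits(treatment, "coverage_track"),
            inherits(input, "coverage_track"))
  if (treatment$bin_size != input$bin_size ||
      !identical(names(treatment$cov), names(input$cov)) ||
      !identical(lengths(treatment$cov), lengths(input$cov))) {
    stop("treatment and input tracks are on different bin grids")
  }
  treatment$cov <- Map(function(a, b) a - b, treatment$cov, input$cov)
  treatment$norm <- "RPGC-minus-input"
  treatment
}

#' Strand-oriented metaprofile around anchor points
#'
#' Averages track signal over anchors (e.g. TSSs) at offsets
#' `-flank..+flank` in steps of the track bin size. Minus-strand anchors
#' are flipped so positive offsets are always downstream of
#' transcription. The anchor bin is `floor(position / bin_size)`; offset
#' 0 is the bin containing the anchor. Anchors whose window leaves the
#' chromosome are dropped and counted.
#'
#' @param track a `coverage_track`.
#' @param anchors data.frame with columns `chrom`, `pos`, `strand`.
#' @param flank half-width of the profile in bp (default 4000).
#' @return list of class `meta_profile`: `offsets`, `signal`,
#'   `n_anchors`, `n_dropped`, `bin_size`.
#' @export
metaprofile <- function(track, anchors, flank = 4000) {
  stopifnot(inherits(track, "coverage_track"),
            all(c("chrom", "pos", "strand") %in% names(anchors)))
  unknown <- setdiff(unique(anchors$chrom), names(track$cov))
  if (length(unknown) > 0) {
    stop("anchor(s) on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  b <- track$bin_size
  offsets <- seq(-flank, flank, by = b)
  k <- offsets / b
  acc <- numeric(length(offsets))
  n_used <- 0L
  n_dropped <- 0L
  for (chr in unique(anchors$chrom)) {
    v <- as.numeric(track$cov[[chr]])
    ai <- which(anchors$chrom == chr)
    minus <- anchors$strand[ai] == "-"
    ## the anchor bin holds the first transcribed base: for a minus-strand
    ## anchor that base is pos - 1, which keeps oriented offsets aligned
    ## to the same bin grid as the plus strand
    a0 <- ifelse(minus, floor((anchors$pos[ai] - 1) / b),
                 floor(anchors$pos[ai] / b))
    sign <- ifelse(minus, -1, 1)
    ## bin indices per anchor x offset (1-based into v)
    idx <- outer(a0, rep(1, length(k))) + outer(sign, k) + 1
    ok <- rowSums(idx < 1 | idx > length(v)) == 0
    n_dropped <- n_dropped + sum(!ok)
    if (any(ok)) {
      sub <- idx[ok, , drop = FALSE]
      acc <- acc + colSums(matrix(v[sub], nrow = nrow(sub)))
      n_used <- n_used + sum(ok)
    }
  }
  if (n_used == 0) stop("no usable anchors within chromosome bounds")
  structure(list(offsets = offsets, signal = acc / n_used,
                 n_anchors = n_used, n_dropped = n_dropped,
                 bin_size = b),
            class = "meta_profile")
}

#' Locate the upstream and downstream modes of a bimodal TSS profile
#'
#' After 3-bin moving-average smoothing, the upstream mode is the argmax
#' over offsets < -bin_size and the downstream mode the argmax over
#' offsets > +bin_size; `height_ratio` is downstream/upstream mode
#' height. A profile that is monotone (or constant) after smoothing is
#' flagged unimodal.
#'
#' @param profile a `meta_profile`.
#' @return list: `upstream_mode`, `downstream_mode`, `height_ratio`,
#'   `unimodal`.
#' @export
profile_modes <- function(profile) {
  stopifnot(inherits(profile, "meta_profile"))
  y <- profile$signal
  if (any(!is.finite(y))) stop("profile contains non-finite values")
  n <- length(y)
  sm <- vapply(seq_len(n), function(i) {
    mean(y[max(1, i - 1):min(n, i + 1)])
  }, numeric(1))
  d <- diff(sm)
  eps <- 1e-12 * max(abs(sm), 1)
  if (all(d >= -eps) || all(d <= eps)) {
    return(list(upstream_mode = NA_real_, downstream_mode = NA_real_,
                height_ratio = NA_real_, unimodal = TRUE))
  }
  b <- profile$bin_size
  up_i <- which(profile$offsets < -b)
  down_i <- which(profile$offsets > b)
  ui <- up_i[which.max(sm[up_i])]
  di <- down_i[which.max(sm[down_i])]
  list(upstream_mode = profile$offsets[ui],
       downstream_mode = profile$offsets[di],
       height_ratio = sm[di] / sm[ui],
       unimodal = FALSE)
}

#' Write/read a binned coverage track as bedGraph
#'
#' Adjacent equal-valued bins are merged into single bedGraph records on
#' the way out; the fixed bin grid is reconstructed on the way in.
#'
#' @param track a `coverage_track`.
#' @param path file path.
#' @return the path (write) or a `coverage_track` (read).
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$cov)) {
    r <- track$cov[[chr]]
    ends <- cumsum(S4Vectors::runLength(r)) * track$bin_size
    ends <- pmin(ends, track$chrom_sizes[[chr]])
    starts <- c(0, head(ends, -1))
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%g", chr, starts[keep],
                         ends[keep], vals[keep]), con)
    }
  }
  invisible(path)
}

#' @param chrom_sizes,bin_size grid on which the bedGraph was written.
#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_size) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "value"))
  cov <- lapply(names(chrom_sizes), function(chr) {
    n_bins <- ceiling(chrom_sizes[[chr]] / bin_size)
    v <- numeric(n_bins)
    xi <- x[x$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(xi))) {
      b1 <- xi$start[i] / bin_size + 1
      b2 <- ceiling(xi$end[i] / bin_size)
      v[b1:b2] <- xi$value[i]
    }
    S4Vectors::Rle(v)
  })
  names(cov) <- names(chrom_sizes)
  .coverage_track(cov, bin_size, "raw", chrom_sizes,
                  n_fragments = NA, extension = NA)
}
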