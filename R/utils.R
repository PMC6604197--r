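## Shared internal helpers: interval plumbing on top of IRanges, seed
## derivation, and small numeric utilities.

## Intervals are data.frames with columns chrom, start, end (0-based,
## half-open) and optionally strand. IRanges is 1-based closed, so the
## conversion is start+1 on the way in.
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Validate a set of genomic intervals
#'
#' Checks the 0-based half-open interval invariants: `0 <= start < end`
#' and, when chromosome sizes are supplied, `end <= chrom length` with
#' every chromosome known.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (and optionally
#'   `strand`).
#' @param chrom_sizes named numeric vector of chromosome lengths, or `NULL`
#'   to skip the bounds check.
#' @return `x`, invisibly, after passing validation.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$start >= x$end)) {
    stop("invalid interval: require 0 <= start < end")
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown) > 0) {
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    }
    if (any(x$end > chrom_sizes[x$chrom])) {
      stop("interval end exceeds chromosome length")
    }
  }
  invisible(x)
}

## Logical vector: does each row of `query` overlap (>= 1 shared base) any
## row of `subject`? Chromosome-aware.
.overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  hit <- rep(FALSE, nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (length(si) == 0) next
    ov <- IRanges::overlapsAny(.as_iranges(query[qi, , drop = FALSE]),
                               .as_iranges(subject[si, , drop = FALSE]))
    hit[qi] <- ov
  }
  hit
}

## Derive a per-stage seed from a global seed; keeps results < 2^31 and
## makes each pipeline stage independently reproducible.
.stage_seed <- function(seed, stage) {
  offsets <- c(annotation = 101L, chip = 211L, polii = 307L,
               expression = 401L, qpcr = 503L, peaks = 601L,
               cluster = 701L, gsea = 809L, misc = 907L)
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}

## Trapezoidal integral of y over x.
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones. Used to score recovery of simulated promoter sensitivity classes.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
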