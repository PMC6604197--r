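## Broad-domain Poisson peak calling and the pseudo-replicate consensus
## procedure: call peaks on the merged replicates and on a random
## equal-sized split, keep merged-set peaks supported by both
## pseudo-replicates, then remove blacklisted regions.
##
## The caller is a transparent Poisson bin scan (treatment counts tested
## against a depth-scaled local/global control rate), not a port of any
## published caller; the consensus logic is the part that matters here.

#' Split a merged fragment set into two random pseudo-replicates
#'
#' Random partition into halves whose sizes differ by at most one (the
#' larger half comes first when the total is odd); the union equals the
#' input and the halves are disjoint. Seeded for reproducibility.
#'
#' @param merged fragment set (union of the true replicates).
#' @param seed integer seed.
#' @return list of two fragment sets.
#' @export
split_pseudoreplicates <- function(merged, seed = 1) {
  f <- merged$fragments
  n <- nrow(f)
  if (n < 2) stop("need at least 2 fragments to split")
  set.seed(.stage_seed(seed, "peaks"))
  n1 <- ceiling(n / 2)
  idx <- sample(n, n1)
  mk <- function(rows, tag) {
    meta <- merged$meta
    meta$pseudo_replicate <- tag
    list(meta = meta, fragments = f[rows, , drop = FALSE])
  }
  list(mk(sort(idx), 1L), mk(sort(setdiff(seq_len(n), idx)), 2L))
}

## Integer fragment counts per bin (number of extended fragments
## overlapping each bin) -- the counting basis for the Poisson scan.
.bin_fragment_counts <- function(sample, chrom_sizes, bin_size,
                                 extension) {
  f <- sample$fragments
  if (is.null(f$strand)) f$strand <- "+"
  plus <- f$strand != "-"
  s <- ifelse(plus, f$start, pmax(f$end - extension, 0))
  e <- pmin(ifelse(plus, f$start + extension, f$end),
            chrom_sizes[f$chrom])
  out <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    n_bins <- ceiling(len / bin_size)
    ci <- which(f$chrom == chr)
    if (length(ci) == 0) return(integer(n_bins))
    first <- pmax(floor(s[ci] / bin_size), 0) + 1L
    last <- pmin(ceiling(e[ci] / bin_size), n_bins)
    ## difference-array accumulation of [first, last] runs
    add <- tabulate(first, n_bins + 1L)
    rem <- tabulate(last + 1L, n_bins + 1L)
    cumsum(add - rem)[seq_len(n_bins)]
  })
  names(out) <- names(chrom_sizes)
  out
}

#' Call broad peaks by a Poisson bin scan
#'
#' Tests each bin's treatment fragment count against a local Poisson rate
#' `lambda = max(genome-wide control rate, 10 Kb-window control rate)`,
#' control scaled to treatment depth. Bins with upper-tail `p <= p_cutoff`
#' are merged into broad peaks when separated by gaps of at most
#' `max_gap` bp; each peak is scored by its best bin.
#'
#' @param treatment,control fragment sets; if `control` is empty the
#'   treatment's own genome-wide rate is used as background (with a
#'   warning).
#' @param chrom_sizes named chromosome lengths.
#' @param p_cutoff per-bin Poisson p-value cutoff (default 1e-3).
#' @param bin_size bin width bp (default 50).
#' @param extension fragment extension bp (default 300).
#' @param max_gap maximum gap (bp) bridged when merging significant bins
#'   (default 500).
#' @param local_window width (bp) of the local background window
#'   (default 10000).
#' @return data.frame of peaks: `chrom`, `start`, `end`, `score`
#'   (-log10 of best-bin p) and `fold` (mean fold over local background).
#' @export
call_broad_peaks <- function(treatment, control, chrom_sizes,
                             p_cutoff = 1e-3, bin_size = 50,
                             extension = 300, max_gap = 500,
                             local_window = 10000) {
  if (nrow(treatment$fragments) == 0) stop("treatment sample is empty")
  tcnt <- .bin_fragment_counts(treatment, chrom_sizes, bin_size, extension)
  have_ctrl <- !is.null(control) && nrow(control$fragments) > 0
  if (!have_ctrl) {
    warning("empty control: falling back to genome-wide treatment ",
            "background")
    ccnt <- tcnt
    scale <- 1
  } else {
    ccnt <- .bin_fragment_counts(control, chrom_sizes, bin_size, extension)
    scale <- nrow(treatment$fragments) / nrow(control$fragments)
  }
  lambda_bg <- scale * sum(unlist(lapply(ccnt, sum))) /
    sum(lengths(ccnt))
  half_w <- floor(local_window / bin_size / 2)
  peaks <- list()
  for (chr in names(chrom_sizes)) {
    tc <- tcnt[[chr]]
    cc <- ccnt[[chr]]
    n <- length(tc)
    ## centered moving average of control counts over the local window
    cs <- cumsum(c(0, cc))
    lo <- pmax(seq_len(n) - half_w, 1)
    hi <- pmin(seq_len(n) + half_w, n)
    local_mean <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    lambda <- pmax(lambda_bg, scale * local_mean)
    p <- ppois(tc - 1, lambda, lower.tail = FALSE)
    sig <- which(p <= p_cutoff)
    if (length(sig) == 0) next
    gap_bins <- floor(max_gap / bin_size)
    brk <- c(0, which(diff(sig) > gap_bins + 1), length(sig))
    for (i in seq_len(length(brk) - 1)) {
      members <- sig[(brk[i] + 1):brk[i + 1]]
      b1 <- members[1]; b2 <- members[length(members)]
      run <- b1:b2
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = chr,
        start = (b1 - 1) * bin_size,
        end = min(b2 * bin_size, chrom_sizes[[chr]]),
        score = -log10(max(min(p[members]), 1e-300)),
        fold = mean(tc[run]) / mean(lambda[run]))
    }
  }
  if (length(peaks) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), score = numeric(0),
                      fold = numeric(0)))
  }
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Pseudo-replicate consensus peaks
#'
#' A merged-set peak is retained iff it overlaps (>= 1 bp) at least one
#' peak in EACH pseudo-replicate set; retained peaks keep the merged
#' set's coordinates and scores.
#'
#' @param merged_peaks,pr1_peaks,pr2_peaks peak data.frames from
#'   [call_broad_peaks()] on the merged set and the two
#'   pseudo-replicates.
#' @return the retained subset of `merged_peaks`.
#' @export
consensus_peaks <- function(merged_peaks, pr1_peaks, pr2_peaks) {
  if (nrow(merged_peaks) == 0) return(merged_peaks)
  keep <- .overlaps_any(merged_peaks, pr1_peaks) &
    .overlaps_any(merged_peaks, pr2_peaks)
  out <- merged_peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove peaks overlapping blacklisted regions
#'
#' @param peaks peak data.frame.
#' @param blacklist interval data.frame.
#' @return peaks with zero blacklist overlap.
#' @export
remove_blacklisted <- function(peaks, blacklist) {
  if (nrow(peaks) == 0 || nrow(blacklist) == 0) return(peaks)
  out <- peaks[!.overlaps_any(peaks, blacklist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full consensus peak-calling pipeline for one condition
#'
#' Merges the replicates, splits pseudo-replicates, calls broad peaks on
#' all three sets against the input, intersects, and blacklist-filters.
#'
#' @param replicates list of fragment sets (the condition's replicates).
#' @param input input fragment set (control).
#' @param annotation a [genome_annotation()] (supplies chromosome sizes
#'   and the blacklist).
#' @param seed integer seed for the pseudo-replicate split.
#' @param ... passed to [call_broad_peaks()].
#' @return final peak data.frame.
#' @export
consensus_peak_pipeline <- function(replicates, input, annotation,
                                    seed = 1, ...) {
  merged <- list(meta = replicates[[1]]$meta,
                 fragments = do.call(rbind, lapply(replicates,
                                                   `[[`, "fragments")))
  prs <- split_pseudoreplicates(merged, seed = seed)
  sizes <- annotation$chrom_sizes
  pk_m <- call_broad_peaks(merged, input, sizes, ...)
  pk_1 <- call_broad_peaks(prs[[1]], input, sizes, ...)
  pk_2 <- call_broad_peaks(prs[[2]], input, sizes, ...)
  remove_blacklisted(consensus_peaks(pk_m, pk_1, pk_2),
                     annotation$blacklist)
}
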