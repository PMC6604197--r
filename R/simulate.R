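## Synthetic-data generator.
##
## Emulates the study design: two cell models (inhibitor-sensitive and
## -resistant), four doses (vehicle, 50, 500, 5000 nM), two replicates per
## condition, bimodal ChIP occupancy around each TSS (upstream mode near
## -300 bp, stronger downstream mode near +165 bp), per-TSS sensitivity
## classes whose occupancy is displaced dose-dependently and independently
## at the core-promoter and pause-site windows, Pol II coverage whose
## promoter/body ratio rises as pause-site occupancy is displaced, and
## NB-distributed expression counts downregulated in proportion to
## pause-site displacement. Ground truth (class labels, remaining-occupancy
## fractions, true expression LFCs) is returned alongside every dataset.

## The five sensitivity classes and their displacement parameters.
## depth = maximal displaced fraction at saturating dose; ec50 in nM.
.class_params <- function() {
  data.frame(
    class = c("unaffected", "sensitive-both", "highly-sensitive-both",
              "highly-sensitive-pause", "highly-sensitive-core"),
    depth_core  = c(0, 0.75, 0.95, 0.00, 0.95),
    depth_pause = c(0, 0.75, 0.95, 0.95, 0.00),
    ec50_core   = c(Inf, 500, 100, Inf, 100),
    ec50_pause  = c(Inf, 500, 100, 100, Inf),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 4 doses x 2 replicates, a
#' downstream occupancy mode at +165 bp (within the 150-180 bp band) twice
#' as high as the upstream mode at -300 bp in the sensitive model, and
#' ~2e5 fragments per sample on a 2 x 5 Mb genome.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_tss number of TSSs to place.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param doses treatment concentrations in nM (first must be 0 = vehicle).
#' @param n_replicates replicates per condition.
#' @param class_proportions named fractions over the five sensitivity
#'   classes; must sum to 1.
#' @param upstream_offset,downstream_offset occupancy mode centers in bp
#'   relative to the TSS (transcription orientation).
#' @param peak_sd Gaussian spread of fragment centers around a mode (bp).
#' @param amp_up,amp_down expected fragments per TSS at the upstream /
#'   downstream mode at dose 0 (sensitive model).
#' @param hill Hill exponent of the displacement law.
#' @param frag_len fragment length in bp.
#' @param noise_dispersion NB (Gamma-Poisson) dispersion of expression
#'   counts.
#' @param chip_dispersion NB dispersion of per-window ChIP fragment
#'   counts between replicates (technical-quality replicates are less
#'   dispersed than expression counts).
#' @param background_frags uniform background fragments per ChIP sample.
#' @param input_frags fragments in the matched input sample.
#' @param expr_mean_range range of baseline expression means (loguniform).
#' @param coupling_beta expression log2FC per unit pause-site displacement.
#' @param tr_coupling Pol II promoter-density gain per unit pause-site
#'   displacement.
#' @param tr_body_floor lower bound on the Pol II gene-body density scale.
#' @param cell_model `"sensitive"` or `"resistant"`. The resistant model
#'   has ~50-fold higher EC50s and a weaker downstream mode, emulating
#'   globally stronger binding and more displacement in the sensitive line.
#' @param qpcr_noise_sd Gaussian Ct noise (cycles).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_tss = 2000,
                       chrom_sizes = c(chrS1 = 5e6, chrS2 = 5e6),
                       doses = c(0, 50, 500, 5000),
                       n_replicates = 2,
                       class_proportions = c(
                         "unaffected" = 0.89,
                         "sensitive-both" = 0.040,
                         "highly-sensitive-both" = 0.014,
                         "highly-sensitive-pause" = 0.023,
                         "highly-sensitive-core" = 0.033),
                       upstream_offset = -300,
                       downstream_offset = 165,
                       peak_sd = 25,
                       amp_up = 40,
                       amp_down = 80,
                       hill = 1,
                       frag_len = 300,
                       noise_dispersion = 0.05,
                       chip_dispersion = 0.02,
                       background_frags = 20000,
                       input_frags = 100000,
                       expr_mean_range = c(50, 2000),
                       coupling_beta = 2,
                       tr_coupling = 1,
                       tr_body_floor = 0.1,
                       cell_model = c("sensitive", "resistant"),
                       qpcr_noise_sd = 0.05) {
  cell_model <- match.arg(cell_model)
  stopifnot(doses[1] == 0, all(doses >= 0),
            n_replicates >= 1, n_tss >= 1, hill > 0, frag_len > 0,
            upstream_offset < 0, downstream_offset > 0)
  cp <- class_proportions[.class_params()$class]
  if (any(is.na(cp)) || any(cp < 0) || abs(sum(cp) - 1) > 1e-8) {
    stop("class_proportions must be named over the five classes, be ",
         ">= 0 and sum to 1")
  }
  structure(list(
    seed = as.integer(seed), n_tss = n_tss, chrom_sizes = chrom_sizes,
    doses = doses, n_replicates = n_replicates, class_proportions = cp,
    upstream_offset = upstream_offset,
    downstream_offset = downstream_offset, peak_sd = peak_sd,
    amp_up = amp_up, amp_down = amp_down, hill = hill,
    frag_len = frag_len, noise_dispersion = noise_dispersion,
    chip_dispersion = chip_dispersion,
    background_frags = background_frags, input_frags = input_frags,
    expr_mean_range = expr_mean_range, coupling_beta = coupling_beta,
    tr_coupling = tr_coupling, tr_body_floor = tr_body_floor,
    cell_model = cell_model, qpcr_noise_sd = qpcr_noise_sd),
    class = "sim_config")
}

## Resistant model: EC50s x50 (less displacement at a given dose) and a
## weaker downstream mode (amp_down scaled to 1.2x amp_up instead of 2x).
.model_adjust <- function(config) {
  if (config$cell_model == "resistant") {
    list(ec50_mult = 50, amp_down = 1.2 * config$amp_up)
  } else {
    list(ec50_mult = 1, amp_down = config$amp_down)
  }
}

#' Remaining-occupancy fraction under a Hill displacement law
#'
#' `r = 1 / (1 + (dose/ec50)^hill)`: the fraction of chromatin-bound
#' protein remaining at a given inhibitor dose. `r(0) = 1` and r is
#' strictly decreasing for dose > 0 (finite ec50).
#'
#' @param dose concentration in nM (>= 0).
#' @param ec50 half-displacement concentration in nM (> 0; `Inf` means
#'   no displacement).
#' @param hill Hill exponent (> 0).
#' @return remaining fraction in (0, 1].
#' @export
displacement_fraction <- function(dose, ec50, hill = 1) {
  if (any(ec50 <= 0)) stop("ec50 must be > 0")
  if (any(dose < 0)) stop("dose must be >= 0")
  if (any(hill <= 0)) stop("hill must be > 0")
  ratio <- ifelse(is.infinite(ec50), 0, dose / ec50)
  1 / (1 + ratio^hill)
}

## Per-class remaining fraction with partial maximal displacement:
## r = 1 - depth * (1 - hill_r). Keeps r(0)=1, monotone non-increasing.
.class_remaining <- function(dose, depth, ec50, hill) {
  1 - depth * (1 - displacement_fraction(dose, ec50, hill))
}

#' Simulate a genome annotation for the generator
#'
#' Places `n_tss` TSSs in equal-width slots along the synthetic genome
#' (guaranteeing non-overlapping gene bodies), assigns strands, gene
#' lengths (1.5-3.5 Kb), biotypes (10% noncoding), a small blacklist,
#' intergenic enhancers and H3K27ac intervals covering promoters plus
#' enhancers.
#'
#' @param config a [sim_config()].
#' @return a [genome_annotation()].
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "annotation"))
  sizes <- config$chrom_sizes
  n <- config$n_tss
  slot <- floor(sum(sizes) / n)
  gene_max <- 3500
  ## margin keeps neighboring genes' Pol II promoter/body regions (300 bp
  ## upstream extent) disjoint; +/-1 Kb count windows may still overlap
  ## neighbors, as in real genomes
  margin <- 500
  if (slot < gene_max + 2 * margin) {
    stop("n_tss exceeds placeable capacity of chrom_sizes")
  }
  ## distribute slots over chromosomes proportionally to length
  n_per <- floor(sizes / slot)
  while (sum(n_per) > n) n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1
  while (sum(n_per) < n) n_per[which.min(n_per)] <- n_per[which.min(n_per)] + 1
  rows <- lapply(names(sizes), function(chr) {
    k <- n_per[[chr]]
    if (k == 0) return(NULL)
    slot_w <- floor(sizes[[chr]] / k)
    strand <- sample(c("+", "-"), k, replace = TRUE)
    glen <- round(runif(k, 1500, gene_max))
    ## place the gene span inside the slot, then orient the TSS by strand
    lo <- (seq_len(k) - 1) * slot_w + margin
    hi <- seq_len(k) * slot_w - margin - glen
    a <- round(lo + runif(k) * pmax(hi - lo, 1))
    tss <- ifelse(strand == "+", a, a + glen)
    tes <- ifelse(strand == "+", a + glen, a)
    data.frame(chrom = chr, strand = strand, tss = tss, tes = tes)
  })
  g <- do.call(rbind, rows)
  ord <- sample(nrow(g))  # decouple ids from genomic order
  g <- g[ord, , drop = FALSE]
  g$gene_id <- sprintf("gene%04d", seq_len(nrow(g)))
  g$transcript_id <- sprintf("tx%04d", seq_len(nrow(g)))
  g$biotype <- sample(c("coding", "noncoding"), nrow(g),
                      replace = TRUE, prob = c(0.9, 0.1))
  ## enhancers: midway between adjacent slots (intergenic by construction)
  enh <- do.call(rbind, lapply(names(sizes), function(chr) {
    k <- max(n_per[[chr]] %/% 4, 1)
    slot_w <- floor(sizes[[chr]] / max(n_per[[chr]], 1))
    centers <- sort(sample(seq_len(max(n_per[[chr]] - 1, 1)), k)) * slot_w
    w <- round(runif(k, 500, 1500))
    data.frame(chrom = chr, start = pmax(centers - w, 0),
               end = pmin(centers + w, sizes[[chr]]))
  }))
  ## blacklist: a few fixed troublesome intervals per chromosome
  bl <- do.call(rbind, lapply(names(sizes), function(chr) {
    s <- round(runif(3, 0, sizes[[chr]] - 6000))
    data.frame(chrom = chr, start = s, end = s + round(runif(3, 1000, 5000)))
  }))
  ## H3K27ac: promoters of a random 70% of genes, plus all enhancers
  acc_idx <- sample(nrow(g), round(0.7 * nrow(g)))
  ac <- rbind(
    data.frame(chrom = g$chrom[acc_idx],
               start = pmax(g$tss[acc_idx] - 800, 0),
               end = pmin(g$tss[acc_idx] + 800, sizes[g$chrom[acc_idx]])),
    enh)
  genes <- g[, c("gene_id", "transcript_id", "chrom", "strand",
                 "tss", "tes", "biotype")]
  genome_annotation(sizes, genes, blacklist = bl, enhancers = enh,
                    h3k27ac = ac)
}

## Ground-truth table: per-TSS class plus remaining fractions r for every
## dose and window, and the implied true expression LFC per dose.
.make_truth <- function(config, annotation) {
  set.seed(.stage_seed(config$seed, "annotation") + 7L)
  g <- annotation$genes
  cls <- sample(names(config$class_proportions), nrow(g), replace = TRUE,
                prob = config$class_proportions)
  cp <- .class_params()
  adj <- .model_adjust(config)
  idx <- match(cls, cp$class)
  per_dose <- lapply(config$doses, function(d) {
    r_core <- .class_remaining(d, cp$depth_core[idx],
                               cp$ec50_core[idx] * adj$ec50_mult,
                               config$hill)
    r_pause <- .class_remaining(d, cp$depth_pause[idx],
                                cp$ec50_pause[idx] * adj$ec50_mult,
                                config$hill)
    data.frame(transcript_id = g$transcript_id, gene_id = g$gene_id,
               dose = d, r_core = r_core, r_pause = r_pause,
               true_lfc = -config$coupling_beta * (1 - r_pause))
  })
  structure(list(
    classes = data.frame(transcript_id = g$transcript_id,
                         gene_id = g$gene_id, class = cls,
                         stringsAsFactors = FALSE),
    fractions = do.call(rbind, per_dose)),
    class = "sim_truth")
}

#' Simulate ChIP fragment sets with known ground truth
#'
#' For every (dose, replicate) draws per-TSS fragment counts at the two
#' occupancy modes from a Gamma-Poisson (NB) model with expected counts
#' `amp_up * r_core` and `amp_down * r_pause`, where r is the class- and
#' dose-specific remaining fraction; fragment centers are Gaussian around
#' the strand-oriented mode positions. Uniform background fragments and a
#' uniform input sample are added. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param annotation optional pre-built [simulate_annotation()] result.
#' @return list with elements `samples` (list of fragment sets: `meta`
#'   list + `fragments` data.frame), `truth` (classes, remaining
#'   fractions, true LFCs) and `annotation`.
#' @export
simulate_chip <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  truth <- .make_truth(config, annotation)
  set.seed(.stage_seed(config$seed, "chip"))
  g <- annotation$genes
  sizes <- config$chrom_sizes
  adj <- .model_adjust(config)
  strand_sign <- ifelse(g$strand == "+", 1, -1)
  half <- config$frag_len / 2
  shape <- 1 / config$chip_dispersion
  samples <- list()
  for (d in config$doses) {
    fr <- truth$fractions[truth$fractions$dose == d, ]
    fr <- fr[match(g$transcript_id, fr$transcript_id), ]
    lam_core <- config$amp_up * fr$r_core
    lam_pause <- adj$amp_down * fr$r_pause
    for (rep_i in seq_len(config$n_replicates)) {
      draw_mode <- function(lambda, offset) {
        mult <- rgamma(length(lambda), shape = shape, rate = shape)
        n <- rpois(length(lambda), lambda * mult)
        tss_i <- rep(seq_len(nrow(g)), n)
        centers <- g$tss[tss_i] + strand_sign[tss_i] * offset +
          rnorm(sum(n), 0, config$peak_sd)
        data.frame(chrom = g$chrom[tss_i],
                   start = round(centers - half), end = NA)
      }
      up <- draw_mode(lam_core, config$upstream_offset)
      down <- draw_mode(lam_pause, config$downstream_offset)
      bg <- .uniform_fragments(config$background_frags, sizes)
      frags <- rbind(up, down, bg[, c("chrom", "start", "end")])
      frags$end <- frags$start + config$frag_len
      frags <- .clip_fragments(frags, sizes)
      frags$strand <- sample(c("+", "-"), nrow(frags), replace = TRUE)
      meta <- list(model = config$cell_model, track = "BRD4", dose = d,
                   replicate = rep_i, is_input = FALSE)
      samples[[sprintf("%s_BRD4_%g_rep%d", config$cell_model, d, rep_i)]] <-
        list(meta = meta, fragments = frags)
    }
  }
  inp <- .uniform_fragments(config$input_frags, sizes)
  inp$end <- inp$start + config$frag_len
  inp <- .clip_fragments(inp, sizes)
  inp$strand <- sample(c("+", "-"), nrow(inp), replace = TRUE)
  samples[[sprintf("%s_input", config$cell_model)]] <-
    list(meta = list(model = config$cell_model, track = "input", dose = 0,
                     replicate = 1, is_input = TRUE),
         fragments = inp)
  list(samples = samples, truth = truth, annotation = annotation)
}

.uniform_fragments <- function(n, sizes) {
  chr <- sample(names(sizes), n, replace = TRUE,
                prob = sizes / sum(sizes))
  data.frame(chrom = chr, start = round(runif(n) * (sizes[chr] - 1)),
             end = NA)
}

.clip_fragments <- function(frags, sizes) {
  frags$start <- pmax(frags$start, 0)
  frags$end <- pmin(frags$end, sizes[frags$chrom])
  frags <- frags[frags$start < frags$end, , drop = FALSE]
  rownames(frags) <- NULL
  frags
}

#' Simulate noiseless Pol II coverage coupled to pause-site displacement
#'
#' Builds, per dose, a base-resolution coverage track in which each gene's
#' promoter region (\[TSS-100, TSS+301) transcription-oriented) has density
#' `1 + tr_coupling * (1 - r_pause)` and its body (301 bp past the TSS to
#' the TES) has density `max(r_pause, tr_body_floor)`; intergenic
#' background is 0. The true traveling-ratio fold change versus vehicle is
#' therefore computable in closed form from the ground truth.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_chip()].
#' @param annotation the matching annotation.
#' @param doses doses to emit (default all in `config`).
#' @return named list (one per dose) of `coverage_track` objects
#'   (bin_size 1).
#' @export
simulate_polii <- function(config, truth, annotation,
                           doses = config$doses) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  g <- annotation$genes
  sizes <- config$chrom_sizes
  out <- list()
  for (d in doses) {
    fr <- truth$fractions[truth$fractions$dose == d, ]
    fr <- fr[match(g$transcript_id, fr$transcript_id), ]
    prom_den <- 1 + config$tr_coupling * (1 - fr$r_pause)
    body_den <- pmax(fr$r_pause, config$tr_body_floor)
    cov <- lapply(names(sizes), function(chr) {
      v <- numeric(sizes[[chr]])
      gi <- which(g$chrom == chr)
      for (i in gi) {
        if (g$strand[i] == "+") {
          prom <- c(g$tss[i] - 100, g$tss[i] + 301)
          body <- c(g$tss[i] + 301, g$tes[i])
        } else {
          prom <- c(g$tss[i] - 300, g$tss[i] + 101)
          body <- c(g$tes[i], g$tss[i] - 300)
        }
        v[(prom[1] + 1):prom[2]] <- prom_den[i]
        if (body[2] > body[1]) v[(body[1] + 1):body[2]] <- body_den[i]
      }
      S4Vectors::Rle(v)
    })
    names(cov) <- names(sizes)
    out[[as.character(d)]] <- .coverage_track(
      cov, bin_size = 1, norm = "raw", chrom_sizes = sizes,
      n_fragments = NA, extension = NA)
  }
  out
}

#' Simulate NB expression counts coupled to pause-site displacement
#'
#' Gene baseline means are loguniform on `expr_mean_range`; treated means
#' are scaled by `2^(-coupling_beta * (1 - r_pause(dose)))`; counts are
#' NB with dispersion `noise_dispersion`. Vehicle replicates share the
#' baseline mean.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_chip()].
#' @return list: `counts` (gene x sample integer matrix), `coldata`
#'   (sample metadata), `true_lfc` (gene x dose table).
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(.stage_seed(config$seed, "expression"))
  genes <- unique(truth$classes$gene_id)
  mu <- exp(runif(length(genes), log(config$expr_mean_range[1]),
                  log(config$expr_mean_range[2])))
  names(mu) <- genes
  cols <- expand.grid(replicate = seq_len(config$n_replicates),
                      dose = config$doses)
  cols$sample <- sprintf("%s_expr_%g_rep%d", config$cell_model,
                         cols$dose, cols$replicate)
  lfc_tab <- truth$fractions[, c("gene_id", "dose", "true_lfc")]
  counts <- sapply(seq_len(nrow(cols)), function(j) {
    fr <- lfc_tab[lfc_tab$dose == cols$dose[j], ]
    lfc <- fr$true_lfc[match(genes, fr$gene_id)]
    rnbinom(length(genes), mu = mu * 2^lfc,
            size = 1 / config$noise_dispersion)
  })
  rownames(counts) <- genes
  colnames(counts) <- cols$sample
  list(counts = counts,
       coldata = data.frame(sample = cols$sample, dose = cols$dose,
                            replicate = cols$replicate,
                            model = config$cell_model),
       true_lfc = lfc_tab)
}

#' Simulate an efficiency-corrected qPCR Ct table
#'
#' Inverts the efficiency-corrected Delta-Ct relation
#' `X = (1+EffR)^CtR / (1+EffX)^CtX` to generate target Ct values
#' consistent with a configured fold change, then adds Gaussian Ct noise.
#'
#' @param fold_change treated/vehicle relative abundance of the target.
#' @param eff_x,eff_r amplification efficiencies in (0, 1\].
#' @param ct_ref reference-transcript Ct (cycles).
#' @param baseline_x vehicle relative abundance of the target.
#' @param n_rep replicates per condition (default 4).
#' @param noise_sd Gaussian Ct noise sd in cycles.
#' @param seed integer seed.
#' @return data.frame with columns `condition`, `replicate`, `CtX`,
#'   `CtR`, `EffX`, `EffR`.
#' @export
simulate_qpcr <- function(fold_change, eff_x = 0.95, eff_r = 0.95,
                          ct_ref = 20, baseline_x = 1, n_rep = 4,
                          noise_sd = 0.05, seed = 1) {
  stopifnot(fold_change > 0, eff_x > 0, eff_x <= 1, eff_r > 0, eff_r <= 1)
  set.seed(.stage_seed(seed, "qpcr"))
  ct_for <- function(x) {
    (ct_ref * log(1 + eff_r) - log(x)) / log(1 + eff_x)
  }
  out <- rbind(
    data.frame(condition = "DMSO", replicate = seq_len(n_rep),
               CtX = ct_for(baseline_x), CtR = ct_ref),
    data.frame(condition = "treated", replicate = seq_len(n_rep),
               CtX = ct_for(baseline_x * fold_change), CtR = ct_ref))
  out$CtX <- out$CtX + rnorm(nrow(out), 0, noise_sd)
  out$CtR <- out$CtR + rnorm(nrow(out), 0, noise_sd)
  out$EffX <- eff_x
  out$EffR <- eff_r
  out
}

#' Write a fragment set as BED6
#'
#' @param sample a fragment set from [simulate_chip()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fragments_bed <- function(sample, path) {
  f <- sample$fragments
  f$name <- "."
  f$score <- 0
  write_bed(f, path)
}
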