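test_that("displacement_fraction follows the Hill law", {
  expect_equal(displacement_fraction(0, 50), 1)       # vehicle
  expect_equal(displacement_fraction(50, 50, 1), 0.5) # midpoint
  expect_equal(displacement_fraction(500, 50, 2), 1 / 101)
  ## strictly decreasing in dose
  d <- displacement_fraction(c(0, 50, 500, 5000), 100, 1)
  expect_true(all(diff(d) < 0))
  expect_error(displacement_fraction(10, -1), "ec50")
  expect_error(displacement_fraction(-1, 10), "dose")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(class_proportions = c(unaffected = 0.5)),
               "class_proportions")
  expect_error(sim_config(doses = c(50, 0)))
  expect_error(sim_config(upstream_offset = 100))
  cfg <- sim_config()
  expect_true(cfg$downstream_offset >= 150 && cfg$downstream_offset <= 180)
  expect_lt(cfg$upstream_offset, 0)
})

test_that("simulate_chip is reproducible and conserves fragment draws", {
  cfg <- sim_config(seed = 5, n_tss = 60,
                    chrom_sizes = c(c1 = 3e5, c2 = 3e5),
                    background_frags = 500, input_frags = 1000)
  a <- simulate_chip(cfg)
  b <- simulate_chip(cfg)
  expect_identical(a$samples, b$samples)   # byte-identical with same seed
  expect_identical(a$truth, b$truth)
  ## different seed changes the draws
  c <- simulate_chip(sim_config(seed = 6, n_tss = 60,
                                chrom_sizes = c(c1 = 3e5, c2 = 3e5),
                                background_frags = 500,
                                input_frags = 1000))
  expect_false(identical(a$samples[[1]]$fragments,
                         c$samples[[1]]$fragments))
  ## metadata complete, fragment lengths = frag_len unless edge-clipped
  for (s in a$samples) {
    expect_true(all(c("model", "track", "dose", "replicate", "is_input")
                    %in% names(s$meta)))
    len <- s$fragments$end - s$fragments$start
    expect_true(all(len <= cfg$frag_len & len > 0))
  }
})

test_that("ground-truth remaining fractions are 1 at vehicle and monotone", {
  cfg <- sim_config(seed = 5, n_tss = 80,
                    chrom_sizes = c(c1 = 5e5),
                    background_frags = 100, input_frags = 100)
  sim <- simulate_chip(cfg)
  fr <- sim$truth$fractions
  v <- fr[fr$dose == 0, ]
  expect_true(all(v$r_core == 1 & v$r_pause == 1))
  ## per TSS, r non-increasing in dose for both windows
  for (col in c("r_core", "r_pause")) {
    wide <- do.call(cbind, lapply(sort(unique(fr$dose)), function(d) {
      sub <- fr[fr$dose == d, ]
      sub[[col]][match(v$transcript_id, sub$transcript_id)]
    }))
    expect_true(all(apply(wide, 1, function(r) all(diff(r) <= 1e-12))))
  }
  ## unaffected class: lambda unchanged at every dose
  un <- sim$truth$classes$transcript_id[sim$truth$classes$class ==
                                          "unaffected"]
  fu <- fr[fr$transcript_id %in% un, ]
  expect_true(all(fu$r_core == 1 & fu$r_pause == 1))
})

test_that("generator mode geometry matches its configuration", {
  ## amp_down/amp_up = 2 at dose 0 -> metaprofile mode-height ratio ~ 2
  cfg <- sim_config(seed = 8, n_tss = 400,
                    chrom_sizes = c(c1 = 1e6, c2 = 1e6),
                    background_frags = 1000, input_frags = 5000)
  sim <- simulate_chip(cfg)
  veh <- sim$samples[[which(vapply(sim$samples, function(s)
    s$meta$dose == 0 && !s$meta$is_input && s$meta$replicate == 1,
    logical(1)))[1]]]
  track <- rpgc_normalize(extend_and_bin(veh, cfg$chrom_sizes))
  g <- sim$annotation$genes
  prof <- metaprofile(track, data.frame(chrom = g$chrom, pos = g$tss,
                                        strand = g$strand))
  m <- profile_modes(prof)
  expect_false(m$unimodal)
  ## background-corrected mode heights: ratio within 10% of amp ratio
  bgl <- mean(prof$signal[abs(prof$offsets) > 2500])
  y <- prof$signal
  sm <- vapply(seq_along(y), function(i)
    mean(y[max(1, i - 1):min(length(y), i + 1)]), numeric(1))
  up_h <- max(sm[prof$offsets < -50]) - bgl
  down_h <- max(sm[prof$offsets > 50]) - bgl
  expect_equal(down_h / up_h, cfg$amp_down / cfg$amp_up, tolerance = 0.1)
})

test_that("unaffected TSSs show no dose effect in the NB test", {
  cfg <- sim_config(seed = 13, n_tss = 300,
                    chrom_sizes = c(c1 = 8e5, c2 = 8e5),
                    class_proportions = c(
                      "unaffected" = 1, "sensitive-both" = 0,
                      "highly-sensitive-both" = 0,
                      "highly-sensitive-pause" = 0,
                      "highly-sensitive-core" = 0),
                    background_frags = 1000, input_frags = 2000)
  sim <- simulate_chip(cfg)
  win <- tss_windows(sim$annotation)
  chip <- sim$samples[!vapply(sim$samples, function(s) s$meta$is_input,
                              logical(1))]
  cnt <- count_in_windows(chip, win)
  db <- nb_wald_test(cnt, 5000)
  ## > 95% of all-unaffected windows non-significant at FDR 0.05
  expect_gt(mean(db$padj >= 0.05, na.rm = TRUE), 0.95)
})

test_that("simulate_polii encodes the traveling-ratio coupling law", {
  cfg <- sim_config(seed = 5, n_tss = 40, chrom_sizes = c(c1 = 4e5),
                    background_frags = 10, input_frags = 10)
  sim <- simulate_chip(cfg)
  tracks <- simulate_polii(cfg, sim$truth, sim$annotation,
                           doses = c(0, 500))
  ## vehicle: r_pause = 1 everywhere -> TR = 1 for every valid gene
  tr0 <- traveling_ratio_all(tracks[["0"]], sim$annotation)
  expect_true(all(abs(tr0$tr[tr0$valid] - 1) < 1e-12))
  ## treated: TR fold equals (1 + c*(1-r)) / max(r, floor) exactly
  tr1 <- traveling_ratio_all(tracks[["500"]], sim$annotation)
  fr <- sim$truth$fractions[sim$truth$fractions$dose == 500, ]
  fr <- fr[match(tr1$gene_id, fr$gene_id), ]
  want <- (1 + cfg$tr_coupling * (1 - fr$r_pause)) /
    pmax(fr$r_pause, cfg$tr_body_floor)
  ok <- tr1$valid
  expect_equal(tr1$tr[ok], want[ok], tolerance = 1e-12)
})

test_that("simulate_expression couples true LFC to pause displacement", {
  cfg <- sim_config(seed = 5, n_tss = 50, chrom_sizes = c(c1 = 4e5))
  sim <- simulate_chip(cfg)
  ## coupling_beta = 0 -> all true LFC 0
  cfg0 <- sim_config(seed = 5, n_tss = 50, chrom_sizes = c(c1 = 4e5),
                     coupling_beta = 0)
  sim0 <- simulate_chip(cfg0)
  expect_true(all(sim0$truth$fractions$true_lfc == 0))
  ## r_pause = 0.25, beta = 2 -> LFC = -1.5 (closed form)
  expect_equal(-2 * (1 - 0.25), -1.5)
  fr <- sim$truth$fractions
  expect_equal(fr$true_lfc, -cfg$coupling_beta * (1 - fr$r_pause))
  ## seeded reproducibility of counts
  e1 <- simulate_expression(cfg, sim$truth)
  e2 <- simulate_expression(cfg, sim$truth)
  expect_identical(e1$counts, e2$counts)
  ## vehicle columns share the baseline mean: no dose-0 LFC
  expect_true(all(fr$true_lfc[fr$dose == 0] == 0))
})

test_that("simulate_qpcr inverts the efficiency-corrected Delta-Ct", {
  ## noise 0, fold 1: treated and vehicle Ct identical
  t0 <- simulate_qpcr(1, eff_x = 1, eff_r = 1, noise_sd = 0, seed = 2)
  expect_equal(t0$CtX[t0$condition == "DMSO"],
               t0$CtX[t0$condition == "treated"])
  ## noise 0, Eff = 1, fold 0.5: CtX(treated) = CtX(vehicle) + 1
  t1 <- simulate_qpcr(0.5, eff_x = 1, eff_r = 1, noise_sd = 0, seed = 2)
  expect_equal(unique(t1$CtX[t1$condition == "treated"]) -
                 unique(t1$CtX[t1$condition == "DMSO"]), 1)
  ## recovery: estimated fold within 5% of truth at sd = 0.05, n = 4
  t2 <- simulate_qpcr(0.4, noise_sd = 0.05, seed = 9)
  est <- qpcr_fold_change(t2)
  expect_equal(est$fold, 0.4, tolerance = 0.05)
})

test_that("resistant model binds less downstream and displaces less", {
  cfg_s <- sim_config(seed = 4, n_tss = 50, chrom_sizes = c(c1 = 4e5))
  cfg_r <- sim_config(seed = 4, n_tss = 50, chrom_sizes = c(c1 = 4e5),
                      cell_model = "resistant")
  s <- simulate_chip(cfg_s)
  r <- simulate_chip(cfg_r)
  fs <- s$truth$fractions[s$truth$fractions$dose == 500, ]
  fr <- r$truth$fractions[r$truth$fractions$dose == 500, ]
  ## same TSS classes (same seed), but less displacement in resistant
  expect_true(mean(fr$r_pause) > mean(fs$r_pause))
})
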