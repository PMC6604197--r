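test_that("extend_and_bin matches per-base depth oracle", {
  sizes <- c(chr1 = 2000)
  ## one fragment [0, 300), bin 50: bins 1..6 have depth 1
  tr <- extend_and_bin(frags("chr1", 0, 300), sizes)
  v <- as.numeric(tr$cov$chr1)
  expect_equal(v[1:6], rep(1, 6))
  expect_true(all(v[7:40] == 0))
  ## linearity: duplicated fragment doubles the track
  tr2 <- extend_and_bin(frags("chr1", c(0, 0), c(300, 300), c("+", "+")),
                        sizes)
  expect_equal(as.numeric(tr2$cov$chr1), 2 * v)
  ## randomized oracle comparison (plus- and minus-strand extension)
  set.seed(31)
  st <- sample(0:1600, 100, replace = TRUE)
  strand <- sample(c("+", "-"), 100, replace = TRUE)
  fr <- frags("chr1", st, st + 120, strand)
  got <- extend_and_bin(fr, sizes, bin_size = 50, extension = 300)
  ext_s <- ifelse(strand == "+", st, pmax(st + 120 - 300, 0))
  ext_e <- pmin(ifelse(strand == "+", st + 300, st + 120), 2000)
  want <- oracle_binned_depth(ext_s, ext_e, 2000, 50)
  expect_equal(as.numeric(got$cov$chr1), want)
  expect_error(extend_and_bin(fr, sizes, bin_size = 0), "bin_size")
})

test_that("rpgc_normalize scales mean per-base coverage to exactly 1", {
  sizes <- c(chr1 = 1e5)
  set.seed(11)
  st <- sample(0:(1e5 - 301), 1000, replace = TRUE)
  tr <- extend_and_bin(frags("chr1", st, st + 300), sizes)
  rp <- rpgc_normalize(tr)
  ## scale formula: G / (n * extension)
  expect_equal(mean(as.numeric(rp$cov$chr1)), 1, tolerance = 1e-6)
  ## fixed point: a track already at mean 1 is unchanged
  rp2 <- rpgc_normalize(tr, effective_genome_size = 1e5)
  expect_equal(as.numeric(rp2$cov$chr1), as.numeric(rp$cov$chr1))
  ## scale invariance: k-fold duplicated fragments normalize identically
  tr_k <- extend_and_bin(frags("chr1", rep(st, 3), rep(st + 300, 3)),
                         sizes)
  expect_equal(as.numeric(rpgc_normalize(tr_k)$cov$chr1),
               as.numeric(rp$cov$chr1), tolerance = 1e-12)
})

test_that("subtract_input is element-wise and preserves negatives", {
  sizes <- c(chr1 = 5000)
  set.seed(12)
  s1 <- sample(0:4600, 50, TRUE)
  s2 <- sample(0:4600, 80, TRUE)
  a <- rpgc_normalize(extend_and_bin(frags("chr1", s1, s1 + 100), sizes))
  b <- rpgc_normalize(extend_and_bin(frags("chr1", s2, s2 + 100), sizes))
  d <- subtract_input(a, b)
  expect_equal(as.numeric(d$cov$chr1),
               as.numeric(a$cov$chr1) - as.numeric(b$cov$chr1))
  expect_true(any(as.numeric(d$cov$chr1) < 0))  # negatives retained
  ## identical tracks -> all zero
  z <- subtract_input(a, a)
  expect_true(all(as.numeric(z$cov$chr1) == 0))
  ## mismatched grids rejected
  c2 <- extend_and_bin(frags("chr1", 0, 300), sizes, bin_size = 100)
  expect_error(subtract_input(a, c2), "grid")
})

test_that("metaprofile flips minus-strand anchors and drops edge anchors", {
  sizes <- c(chr1 = 20000)
  tr <- extend_and_bin(frags("chr1", 0, 300), sizes)
  ## delta of coverage at +165 downstream of a minus-strand anchor at
  ## 10000 means genomic position 10000-165; profile mode must appear at
  ## POSITIVE offset
  tr$cov$chr1 <- S4Vectors::Rle(numeric(400))
  tr$cov$chr1[floor((10000 - 165) / 50) + 1] <- 5
  prof <- metaprofile(tr, data.frame(chrom = "chr1", pos = 10000,
                                     strand = "-"), flank = 2000)
  expect_equal(prof$offsets[which.max(prof$signal)], 150)  # bin of +165
  ## uniform track -> flat profile at the uniform value
  tru <- tr; tru$cov$chr1 <- S4Vectors::Rle(rep(2.5, 400))
  p2 <- metaprofile(tru, data.frame(chrom = "chr1", pos = 10000,
                                    strand = "+"), flank = 2000)
  expect_true(all(p2$signal == 2.5))
  ## anchor too close to the edge is dropped and counted
  p3 <- metaprofile(tru, data.frame(chrom = "chr1",
                                    pos = c(100, 10000),
                                    strand = "+"), flank = 2000)
  expect_equal(p3$n_anchors, 1)
  expect_equal(p3$n_dropped, 1)
  expect_error(metaprofile(tru, data.frame(chrom = "chr1", pos = 10,
                                           strand = "+"), flank = 2000),
               "anchors")
  ## permutation invariance in anchor order
  anc <- data.frame(chrom = "chr1", pos = c(6000, 10000, 14000),
                    strand = c("+", "-", "+"))
  p4 <- metaprofile(tr, anc, flank = 2000)
  p5 <- metaprofile(tr, anc[c(3, 1, 2), ], flank = 2000)
  expect_equal(p4$signal, p5$signal)
})

test_that("profile_modes finds bimodal structure and flags flat profiles", {
  offs <- seq(-4000, 4000, 50)
  ## two Gaussian bumps at -300 / +165, heights 1:2
  y <- exp(-(offs + 300)^2 / (2 * 100^2)) +
    2 * exp(-(offs - 165)^2 / (2 * 100^2))
  prof <- structure(list(offsets = offs, signal = y, n_anchors = 10,
                         n_dropped = 0, bin_size = 50),
                    class = "meta_profile")
  m <- profile_modes(prof)
  expect_false(m$unimodal)
  expect_lte(abs(m$upstream_mode - (-300)), 50)
  expect_lte(abs(m$downstream_mode - 165), 50)
  expect_equal(m$height_ratio, 2, tolerance = 0.1)
  ## symmetric profile: ratio exactly 1
  ys <- exp(-(offs + 300)^2 / (2 * 80^2)) +
    exp(-(offs - 300)^2 / (2 * 80^2))
  ms <- profile_modes(structure(list(offsets = offs, signal = ys,
                                     n_anchors = 1, n_dropped = 0,
                                     bin_size = 50),
                                class = "meta_profile"))
  expect_equal(ms$height_ratio, 1)
  ## flat profile flagged unimodal
  mf <- profile_modes(structure(list(offsets = offs,
                                     signal = rep(1, length(offs)),
                                     n_anchors = 1, n_dropped = 0,
                                     bin_size = 50),
                                class = "meta_profile"))
  expect_true(mf$unimodal)
})

test_that("bedGraph round-trips a binned track", {
  sizes <- c(chr1 = 4000, chr2 = 2000)
  set.seed(5)
  st <- sample(0:3600, 40, replace = TRUE)
  fr <- list(meta = list(), fragments = data.frame(
    chrom = sample(c("chr1", "chr2"), 40, TRUE, prob = c(0.8, 0.2)),
    start = st %% 1700, end = st %% 1700 + 100, strand = "+"))
  tr <- extend_and_bin(fr, sizes, bin_size = 50, extension = 100)
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, sizes, 50)
  expect_equal(lapply(back$cov, as.numeric), lapply(tr$cov, as.numeric))
})
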