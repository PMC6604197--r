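test_that("count_in_windows matches brute-force overlap counting", {
  ann <- tiny_annotation()
  win <- tss_windows(ann)
  ## fragment spanning the TSS of tA is counted in both windows
  s1 <- frags("chr1", 4900, 5200)
  cnt1 <- count_in_windows(list(a = s1), win)
  rd <- attr(cnt1, "rowdata")
  expect_equal(cnt1[rd$transcript_id == "tA" & rd$window == "core", "a"],
               1L)
  expect_equal(cnt1[rd$transcript_id == "tA" & rd$window == "pause", "a"],
               1L)
  ## no fragments -> all-zero matrix
  cnt0 <- count_in_windows(list(a = frags("chr1", 1, 2)), win)
  expect_equal(sum(cnt0), 0L)
  ## randomized oracle
  set.seed(51)
  st <- sample(0:99000, 300, replace = TRUE)
  s2 <- frags("chr1", st, st + sample(50:400, 300, TRUE))
  got <- count_in_windows(list(x = s2), win)
  want <- vapply(seq_len(nrow(win)), function(i) {
    sum(s2$fragments$start < win$end[i] & win$start[i] < s2$fragments$end)
  }, numeric(1))
  expect_equal(as.numeric(got[, "x"]), want)
  ## additivity: counts of merged set = sum of per-replicate counts
  half <- 1:150
  sa <- frags("chr1", st[half], s2$fragments$end[half])
  sb <- frags("chr1", st[-half], s2$fragments$end[-half])
  ca <- count_in_windows(list(x = sa), win)
  cb <- count_in_windows(list(x = sb), win)
  expect_equal(as.numeric(ca + cb), as.numeric(got))
})

test_that("size_factors implements median-of-ratios", {
  set.seed(61)
  m <- matrix(rnbinom(400, mu = 100, size = 10), ncol = 4)
  ## identical samples -> all factors 1
  mm <- cbind(m[, 1], m[, 1])
  expect_equal(unname(size_factors(mm)), c(1, 1))
  ## sample B = 2 x A: factor ratio exactly 2
  m2 <- cbind(m[, 1], 2 * m[, 1])
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[2] / sf2[1]), 2)
  ## random matrix equals an independent median-of-ratios oracle
  sf <- size_factors(m)
  log_gm <- rowMeans(log(m))
  ok <- is.finite(log_gm)
  want <- apply(m, 2, function(col) {
    exp(median(log(col[ok]) - log_gm[ok]))
  })
  want <- want / exp(mean(log(want)))
  expect_equal(unname(sf), unname(want))
})

test_that("bh_adjust reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- sort(runif(20))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj) >= 0))   # monotone on sorted input
  expect_true(all(adj <= 1))
  expect_true(all(adj >= p))
})

test_that("nb_wald_test is calibrated under the null and powered", {
  set.seed(71)
  n <- 5000
  counts <- matrix(rnbinom(n * 4, mu = 200, size = 1 / 0.05), nrow = n)
  rownames(counts) <- paste0("r", seq_len(n))
  coldata <- data.frame(sample = paste0("s", 1:4),
                        dose = c(0, 0, 500, 500), replicate = c(1, 2, 1, 2))
  attr(counts, "coldata") <- coldata
  res <- nb_wald_test(counts, 500)
  t1 <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gte(t1, 0.03)
  expect_lte(t1, 0.07)
  ## power: true 4-fold drop at mean 200, dispersion 0.05
  set.seed(72)
  k <- cbind(matrix(rnbinom(500 * 2, mu = 200, size = 20), 500),
             matrix(rnbinom(500 * 2, mu = 50, size = 20), 500))
  rownames(k) <- paste0("g", 1:500)
  attr(k, "coldata") <- coldata
  ## unit size factors: the fixture tests the statistic, not depth
  ## normalization (median-of-ratios would absorb an all-row shift)
  resp <- nb_wald_test(k, 500, sf = rep(1, 4))
  expect_gte(mean(resp$padj < 0.05 & resp$lfc < 0, na.rm = TRUE), 0.9)
  ## all-zero row filtered, not tested
  k2 <- rbind(k, zero = 0L)
  attr(k2, "coldata") <- coldata
  res2 <- nb_wald_test(k2, 500)
  expect_true(is.na(res2$p[res2$row_id == "zero"]))
  expect_false(res2$tested[res2$row_id == "zero"])
})

test_that("nb_wald_test is invariant to a global depth rescaling", {
  set.seed(81)
  counts <- matrix(rnbinom(800, mu = 150, size = 20), ncol = 4)
  rownames(counts) <- paste0("r", 1:200)
  coldata <- data.frame(sample = paste0("s", 1:4),
                        dose = c(0, 0, 50, 50), replicate = c(1, 2, 1, 2))
  attr(counts, "coldata") <- coldata
  res1 <- nb_wald_test(counts, 50)
  ## triple the depth of one sample
  counts2 <- counts
  counts2[, 3] <- counts[, 3] * 3L
  attr(counts2, "coldata") <- coldata
  res2 <- nb_wald_test(counts2, 50)
  expect_equal(res2$lfc, res1$lfc, tolerance = 0.15)
  expect_gt(cor(res1$lfc, res2$lfc), 0.98)
})

test_that("NB Wald agrees with DESeq2 on a shared fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(91)
  n <- 300
  mu <- exp(runif(n, log(100), log(800)))
  lfc_true <- c(rep(0, 250), rep(-2, 50))
  counts <- cbind(
    matrix(rnbinom(n * 2, mu = mu, size = 25), n),
    matrix(rnbinom(n * 2, mu = mu * 2^lfc_true, size = 25), n))
  storage.mode(counts) <- "integer"
  rownames(counts) <- paste0("g", seq_len(n))
  colnames(counts) <- paste0("s", 1:4)
  coldata <- data.frame(sample = colnames(counts),
                        dose = c(0, 0, 500, 500), replicate = c(1, 2, 1, 2))
  attr(counts, "coldata") <- coldata
  mine <- nb_wald_test(counts, 500)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, data.frame(cond = factor(c("a", "a", "b", "b"))), ~cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  ## effect estimates track the reference implementation closely
  expect_gt(cor(mine$lfc, ref$log2FoldChange, use = "complete.obs"), 0.95)
  ## and both recover the planted 4-fold drops
  planted <- which(lfc_true < 0)
  expect_gt(mean(mine$padj[planted] < 0.05, na.rm = TRUE), 0.9)
})

test_that("affected_tss_table counts displaced TSSs by window", {
  ## constructed results: tx1 core-only, tx2 pause-only, tx3 both,
  ## tx4 nothing, tx5 significant but positive LFC (not displacement)
  res <- data.frame(
    row_id = paste0("r", 1:10),
    transcript_id = rep(paste0("tx", 1:5), each = 2),
    gene_id = rep(paste0("g", 1:5), each = 2),
    window = rep(c("core", "pause"), 5),
    dose = 500,
    lfc = c(-2, 0, 0, -2, -2, -2, 0, 0, 3, 3),
    padj = c(0.01, 0.9, 0.9, 0.01, 0.01, 0.01, 0.9, 0.9, 0.01, 0.01),
    tested = TRUE)
  tab <- affected_tss_table(res)
  expect_equal(tab$overall$core_only, 1)
  expect_equal(tab$overall$pause_only, 1)
  expect_equal(tab$overall$both, 1)
  expect_equal(tab$overall$any, 3)
  expect_equal(tab$overall$pct_any, 60)
  expect_setequal(tab$affected_ids, c("tx1", "tx2", "tx3"))
  ## two-sided mode counts tx5 as well
  tab2 <- affected_tss_table(res, two_sided_affected = TRUE)
  expect_equal(tab2$overall$any, 4)
  ## no significant rows -> all zeros
  res0 <- res; res0$padj <- 0.9
  expect_equal(affected_tss_table(res0)$overall$any, 0)
})

test_that("percentage arithmetic matches the published worked example", {
  ## 3531 affected of 32091 total is reported as 11.0%
  res_pct <- round(100 * 3531 / 32091, 1)
  expect_equal(res_pct, 11)
})
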