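test_that("peak merging follows the support and width rules exactly", {
  ## hand-computed toy: chr1 has a 200 bp peak in s1+s2 (support 2, kept)
  ## and a 100 bp peak in s1+s2 (width <= 146, dropped); chr2 has a peak
  ## present only in s1 and s3 with partial overlap (support 2, union
  ## 100..420 = 320 bp, kept)
  merged <- merge_peaks(toy_peak_samples())
  expect_equal(nrow(merged), 2L)
  chr1 <- merged[merged$chrom == "chr1", ]
  expect_equal(c(chr1$start, chr1$end, chr1$support), c(1000L, 1200L, 2L))
  chr2 <- merged[merged$chrom == "chr2", ]
  expect_equal(c(chr2$start, chr2$end, chr2$support), c(100L, 420L, 2L))

  ## single-sample peaks are dropped even when wide
  lone <- list(s1 = data.frame(chrom = "chr1", start = 0L, end = 1000L))
  expect_equal(nrow(merge_peaks(lone)), 0L)

  ## overlapping peaks within one sample count as a single contribution
  within <- list(
    s1 = data.frame(chrom = "chr1", start = c(0L, 100L), end = c(150L, 300L)),
    s2 = data.frame(chrom = "chr1", start = 0L, end = 300L)
  )
  m2 <- merge_peaks(within)
  expect_equal(m2$support, 2L)
  expect_equal(m2$width, 300L)
})

test_that("merging is order-independent", {
  p <- toy_peak_samples()
  m1 <- merge_peaks(p)
  m2 <- merge_peaks(p[c(3, 1, 2)])
  expect_equal(m1[, c("chrom", "start", "end", "width", "support")],
               m2[, c("chrom", "start", "end", "width", "support")])
})

test_that("merged peaks always satisfy the invariants on synthetic data", {
  cfg <- simulation_config(seed = 23, n_peaks = 25, n_genes = 40)
  pk <- simulate_peaks(cfg)
  merged <- merge_peaks(pk$peaks)
  expect_true(all(merged$width > 146))
  expect_true(all(merged$support >= 2 & merged$support <= nrow(pk$design)))
})

test_that("FPKM follows its closed form", {
  merged <- data.frame(peak_id = "p1", chrom = "chr1", start = 0L,
                       end = 500L, width = 500L, support = 2L)
  cnt <- matrix(c(10L, 0L), 1, dimnames = list("p1", c("s1", "s2")))
  res <- count_and_fpkm(merged, cnt, library_sizes = c(s1 = 1e6, s2 = 1e6))
  expect_equal(unname(res$fpkm["p1", "s1"]), 20)
  expect_equal(unname(res$fpkm["p1", "s2"]), 0)
  ## doubling the library halves FPKM
  res2 <- count_and_fpkm(merged, cnt, library_sizes = c(s1 = 2e6, s2 = 2e6))
  expect_equal(res2$fpkm["p1", "s1"], res$fpkm["p1", "s1"] / 2,
               ignore_attr = TRUE)
  expect_error(count_and_fpkm(merged, cnt, c(s1 = 0, s2 = 1)), "> 0")
})

test_that("background correction subtracts each sample's median and floors at 0", {
  genome <- data.frame(chrom = "chr1", length = 10000L)
  merged <- data.frame(peak_id = "p1", chrom = "chr1", start = 0L,
                       end = 500L, width = 500L, support = 2L)
  ## uniform background: one 50 bp read at the start of every non-peak kb
  bg_starts <- seq(1000L, 9000L, by = 1000L)
  bg <- data.frame(chrom = "chr1", start = bg_starts, end = bg_starts + 50L)
  reads <- list(s1 = bg, s2 = bg)
  fpkm <- matrix(c(20, 20), 1, dimnames = list("p1", c("s1", "s2")))
  libs <- c(s1 = 1e6, s2 = 1e6)
  bc <- background_correct(fpkm, reads, merged, genome, libs,
                           normalize = FALSE)
  b <- 1 / ((1000 / 1000) * (1e6 / 1e6))  # 1 read per kb bin, lib 1e6 -> FPKM 1
  expect_equal(bc$background$median_fpkm, c(b, b))
  expect_equal(unname(bc$corrected["p1", ]), c(20 - b, 20 - b))

  ## zero background reads: the correction is the identity
  none <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0))
  bc0 <- background_correct(fpkm, list(s1 = none, s2 = none), merged,
                            genome, libs, normalize = FALSE)
  expect_equal(bc0$corrected, fpkm)

  ## flooring: background larger than the signal clips to zero
  big_bg <- do.call(rbind, replicate(30, bg, simplify = FALSE))
  bc2 <- background_correct(matrix(c(5, 5), 1,
                                   dimnames = list("p1", c("s1", "s2"))),
                            list(s1 = big_bg, s2 = big_bg), merged, genome,
                            libs, normalize = FALSE)
  expect_true(all(bc2$corrected == 0))
})

test_that("sample-specific background offsets are removed for equal-height peaks", {
  genome <- data.frame(chrom = "chr1", length = 20000L)
  merged <- data.frame(peak_id = c("p1", "p2"), chrom = "chr1",
                       start = c(0L, 600L), end = c(500L, 1100L),
                       width = c(500L, 500L), support = c(2L, 2L))
  bin_starts <- seq(2000L, 19000L, by = 1000L)
  one_per_bin <- data.frame(chrom = "chr1", start = bin_starts,
                            end = bin_starts + 50L)
  reads <- list(s1 = one_per_bin,
                s2 = rbind(one_per_bin,
                           transform(one_per_bin, start = start + 100L,
                                     end = end + 100L)))
  fpkm <- matrix(c(10, 7, 11, 8), 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  bc <- background_correct(fpkm, reads, merged, genome,
                           c(s1 = 1e6, s2 = 1e6), normalize = FALSE)
  ## s1 background median 1, s2 background median 2: planted equal heights
  expect_equal(unname(bc$corrected["p1", ]), c(9, 9))
  expect_equal(unname(bc$corrected["p2", ]), c(6, 6))
  ## no non-peak space is an error
  tiny <- data.frame(chrom = "chr1", length = 1000L)
  expect_error(background_correct(fpkm, reads,
                                  data.frame(peak_id = "p", chrom = "chr1",
                                             start = 0L, end = 1000L,
                                             width = 1000L, support = 2L),
                                  tiny, c(s1 = 1e6, s2 = 1e6)),
               "non-peak")
})

test_that("gene assignment respects the 2 kb window boundaries", {
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    start = c(10000L, 50000L), end = c(12000L, 52000L))
  peak <- function(s, e) data.frame(peak_id = "pk", chrom = "chr1",
                                    start = s, end = e, width = e - s,
                                    support = 2L)
  ## peak ending 1 bp inside the upstream flank: assigned
  expect_equal(assign_genes(peak(7800L, 8001L), ann)$gene_id, "gA")
  ## peak starting exactly at gene end + 2000: excluded
  expect_equal(nrow(assign_genes(peak(14000L, 14200L), ann)), 0L)
  ## peak just inside the downstream flank: assigned
  expect_equal(assign_genes(peak(13999L, 14200L), ann)$gene_id, "gA")

  ## hand-counted genes per peak on a toy layout
  ann2 <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                     start = c(1000L, 4000L, 20000L),
                     end = c(2000L, 5000L, 21000L))
  pk <- data.frame(peak_id = c("a", "b"), chrom = "chr1",
                   start = c(2500L, 30000L), end = c(2700L, 30200L),
                   width = c(200L, 200L), support = c(2L, 2L))
  asg <- assign_genes(pk, ann2)
  ## peak a sits between g1 and g2, within 2 kb of both; peak b hits none
  expect_setequal(asg$gene_id[asg$peak_id == "a"], c("g1", "g2"))
  expect_equal(sum(asg$peak_id == "b"), 0L)
  expect_equal(nrow(asg) / nrow(pk), 1)      # mean genes per peak
})

test_that("corrected chip signal feeds the shared differential engine", {
  cfg <- simulation_config(seed = 27, n_peaks = 20, n_genes = 30,
                           peak_recurrence = 1)
  pk <- simulate_peaks(cfg)
  merged <- merge_peaks(pk$peaks)
  cf <- count_and_fpkm(merged, pk$reads, pk$library_sizes)
  bc <- background_correct(cf$fpkm, pk$reads, merged, pk$genome,
                           pk$library_sizes)
  ## after correction + quantile normalization every column carries the
  ## same total signal (tied ranks share averaged values, so the exact
  ## sorted vectors are certified on tie-free data elsewhere)
  cs <- colSums(bc$corrected)
  expect_equal(unname(cs), rep(cs[[1]], ncol(bc$corrected)))
  da <- differential_analysis(bc$corrected, pk$design, normalize = FALSE,
                              seed = 1)
  expect_equal(nrow(da), nrow(merged))
})
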