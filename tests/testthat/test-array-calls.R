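test_that("state_of_segment applies thresholds inclusively toward abnormal", {
  t <- call_thresholds()  # loss_max -0.2, deletion_max -0.8
  expect_equal(state_of_segment(0, t)$state, "NORMAL")
  expect_equal(state_of_segment(-0.2, t)$state, "LOSS_DELETION")
  expect_equal(state_of_segment(-0.2, t)$sub_state, "loss")
  d <- state_of_segment(-1, t)
  expect_equal(d$state, "LOSS_DELETION")
  expect_equal(d$sub_state, "deletion")
  expect_equal(state_of_segment(0.15, t)$sub_state, "gain")
  expect_equal(state_of_segment(0.9, t)$sub_state, "amplification")
  expect_error(call_thresholds(loss_max = 0.1))
})

make_segments <- function(rows, sample_id = "s1", chrom = "chr1") {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = sample_id, chrom = chrom, start_idx = 0L,
               end_idx = r$n, start_pos = r$start, end_pos = r$end,
               n_markers = r$n, mean_lrr = r$mean,
               copy_value = 2 * 2^r$mean, stringsAsFactors = FALSE)
  }))
}

test_that("gene_call reports NORMAL on flat segmentation and errors off-chrom", {
  region <- simple_region()
  probes <- make_probe_map(seq(1100, 8900, by = 400))
  segs <- make_segments(list(list(start = 0, end = 10000, n = 25, mean = 0)))
  call <- gene_call(segs, region, probes)
  expect_equal(call$state, "NORMAL")
  expect_equal(call$provenance, "cbs")
  segs2 <- segs
  segs2$chrom <- "chr9"
  expect_error(gene_call(segs2, region, probes), "chr1")
})

test_that("gene_call reports the deletion with its exon extent", {
  region <- simple_region()  # exons ex1..ex5 at 1500,3000,4500,6000,7500
  probes <- make_probe_map(seq(1100, 8900, by = 400))
  segs <- make_segments(list(
    list(start = 0, end = 4400, n = 12, mean = 0),
    list(start = 4400, end = 7700, n = 8, mean = -1),
    list(start = 7700, end = 10000, n = 8, mean = 0)))
  call <- gene_call(segs, region, probes)
  expect_equal(call$state, "LOSS_DELETION")
  expect_equal(call$sub_state, "deletion")
  expect_equal(call$exon_first, "ex3")
  expect_equal(call$exon_last, "ex5")
})

test_that("nested mixed-direction events resolve to the larger |mean|", {
  region <- simple_region()
  probes <- make_probe_map(seq(1100, 8900, by = 400))
  segs <- make_segments(list(
    list(start = 0, end = 3000, n = 8, mean = 0.85),   # gain, copy ~3.6
    list(start = 3000, end = 6000, n = 8, mean = -0.75),  # nested loss
    list(start = 6000, end = 10000, n = 9, mean = 0)))
  expect_equal(gene_call(segs, region, probes)$state, "GAIN_AMPLIFICATION")
  segs$mean_lrr[2] <- -1.2  # now the deletion is the more extreme event
  segs$copy_value <- 2 * 2^segs$mean_lrr
  expect_equal(gene_call(segs, region, probes)$state, "LOSS_DELETION")
})

test_that("gene_call ignores segments below the marker cut-off", {
  region <- simple_region()
  probes <- make_probe_map(seq(1100, 8900, by = 400))
  segs <- make_segments(list(
    list(start = 0, end = 4000, n = 10, mean = 0),
    list(start = 4000, end = 5600, n = 4, mean = -1),
    list(start = 5600, end = 10000, n = 11, mean = 0)))
  expect_equal(gene_call(segs, region, probes, min_markers = 5)$state,
               "NORMAL")
  expect_equal(gene_call(segs, region, probes, min_markers = 4)$state,
               "LOSS_DELETION")
})

test_that("relaxing loss_max toward zero only creates losses, never removes", {
  region <- simple_region()
  probes <- make_probe_map(seq(1100, 8900, by = 400))
  segs <- make_segments(list(
    list(start = 0, end = 10000, n = 25, mean = -0.15)))
  strict <- gene_call(segs, region, probes,
                      call_thresholds(loss_max = -0.2))
  relaxed <- gene_call(segs, region, probes,
                       call_thresholds(loss_max = -0.1))
  expect_equal(strict$state, "NORMAL")
  expect_equal(relaxed$state, "LOSS_DELETION")
})

test_that("focal_rescue recovers the hole-flanking deletion missed by CBS", {
  d <- ikzf1_hole_demo()
  segs <- cbs_segment(d$profile, segmentation_params(nperm = 1000, seed = 5))
  expect_equal(gene_call(segs, d$region, d$probes)$state, "NORMAL")
  r <- focal_rescue(d$profile, d$region)
  expect_equal(r$state, "LOSS_DELETION")
  expect_equal(r$provenance, "rescue")
  # and the matched MLPA data call the same event
  expect_equal(call_gene_mlpa(d$mlpa)$state, "LOSS_DELETION")
})

test_that("focal_rescue returns NULL on clean profiles and single outliers", {
  region <- simple_region()
  pos <- seq(1100, 8900, by = 400)
  clean <- array_profile("s", "chr1", pos, rep(0, length(pos)))
  expect_null(focal_rescue(clean, region))
  # one probe at LRR 1.5 must never drive a rescue, even at window_k = 2
  x <- rep(0, length(pos))
  x[10] <- 1.5
  outlier <- array_profile("s", "chr1", pos, x)
  expect_null(focal_rescue(outlier, region, window_k = 2))
})

test_that("focal_rescue fires on at most 1% of null profiles at noise 0.15", {
  g <- toy_genome()
  ik <- g$regions$IKZF1
  pr <- g$probes[g$probes$chrom == ik$chrom, ]
  set.seed(77)
  fires <- 0L
  for (k in 1:500) {
    prof <- array_profile("s", ik$chrom, pr$start,
                          rnorm(nrow(pr), 0, 0.15))
    if (!is.null(focal_rescue(prof, ik))) fires <- fires + 1L
  }
  expect_lte(fires / 500, 0.01)
})
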