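grid_calls <- function(states, genes = c("A", "B"), manual = NULL,
                       single = FALSE) {
  n <- length(states) / length(genes)
  d <- expand.grid(sample_id = sprintf("s%02d", seq_len(n)), gene = genes,
                   stringsAsFactors = FALSE)
  d$state <- states
  if (!is.null(manual)) d$state_manual <- manual
  d$single_probe_evidence <- single
  d
}

test_that("identical grids are fully concordant; mismatched grids error", {
  snp <- grid_calls(c("NORMAL", "LOSS_DELETION", "NORMAL", "NORMAL"))
  cmp <- compare_calls(snp, snp)
  expect_equal(cmp$discordant, 0L)
  expect_equal(concordance_percent(cmp)$raw, 100)
  expect_error(compare_calls(snp, snp[-1, ]), "missing keys")
})

test_that("direction-aggregated comparison counts gain-vs-loss as concordant", {
  snp <- grid_calls(c("GAIN_AMPLIFICATION", "NORMAL"), genes = "A")
  mlpa <- grid_calls(c("LOSS_DELETION", "NORMAL"), genes = "A")
  cmp <- compare_calls(snp, mlpa)
  expect_equal(cmp$discordant, 0L)
})

test_that("the contingency fixture reproduces the published discordance", {
  fx <- load_published_tables()
  pairs <- fixture_to_pairs(fx$table1)
  snp <- data.frame(sample_id = pairs$sample_id, gene = pairs$gene,
                    state = pairs$snp_state,
                    state_manual = pairs$snp_state_manual)
  mlpa <- data.frame(sample_id = pairs$sample_id, gene = pairs$gene,
                     state = pairs$mlpa_state,
                     single_probe_evidence = pairs$mlpa_single_probe)
  cbs <- compare_calls(snp, mlpa, mode = "cbs")
  man <- compare_calls(snp, mlpa, mode = "manual")
  expect_equal(cbs$total, 1287L)
  expect_equal(cbs$discordant, 25L)
  expect_equal(man$discordant, 16L)
  expect_equal(concordance_percent(cbs)$rounded, 98)
  expect_equal(concordance_percent(man)$rounded, 99)
  # rescue only removes disagreements: manual discordance is a subset
  key <- function(p) paste(p$sample_id, p$gene)
  expect_true(all(key(man$pairs[!man$pairs$concordant, ]) %in%
                    key(cbs$pairs[!cbs$pairs$concordant, ])))
})

test_that("contingency cells reproduce per-gene tables and sum to cohort", {
  fx <- load_published_tables()
  pairs <- fixture_to_pairs(fx$table1)
  snp <- data.frame(sample_id = pairs$sample_id, gene = pairs$gene,
                    state = pairs$snp_state,
                    state_manual = pairs$snp_state_manual)
  mlpa <- data.frame(sample_id = pairs$sample_id, gene = pairs$gene,
                     state = pairs$mlpa_state)
  tab <- tabulate_pairs(compare_calls(snp, mlpa, mode = "manual"))
  ik <- tab[tab$gene == "IKZF1", ]
  expect_equal(ik$count[ik$snp == "Normal" & ik$mlpa == "Normal"], 113)
  expect_equal(ik$count[ik$snp == "Normal" & ik$mlpa == "Abnormal"], 1)
  expect_equal(ik$count[ik$snp == "Abnormal" & ik$mlpa == "Normal"], 0)
  expect_equal(ik$count[ik$snp == "Abnormal" & ik$mlpa == "Abnormal"], 29)
  sums <- tapply(tab$count, tab$gene, sum)
  expect_true(all(sums == 143))
})

test_that("contingency cell sums equal cohort size on randomized grids", {
  set.seed(19)
  for (k in 1:5) {
    n <- sample(5:20, 1)
    genes <- c("G1", "G2", "G3")
    states <- sample(c("NORMAL", "LOSS_DELETION", "GAIN_AMPLIFICATION"),
                     n * 3, replace = TRUE)
    snp <- grid_calls(states, genes = genes)
    mlpa <- grid_calls(sample(states), genes = genes)
    cmp <- compare_calls(snp, mlpa)
    tab <- tabulate_pairs(cmp)
    expect_true(all(tapply(tab$count, tab$gene, sum) == n))
    expect_equal(cmp$concordant + cmp$discordant, cmp$total)
  }
})

disc_pair <- function(mlpa = "LOSS_DELETION", snp = "NORMAL",
                      manual = snp, single = FALSE) {
  data.frame(sample_id = "s1", gene = "G1", snp_state = snp,
             snp_state_manual = manual, mlpa_state = mlpa,
             mlpa_single_probe = single, stringsAsFactors = FALSE)
}

test_that("the discordance cascade assigns categories i, ii, iii, iv, v", {
  snp_probes <- make_probe_map(seq(0, 10000, by = 500))
  mlpa_probes <- make_probe_map(c(2000, 2500, 3000), chrom = "chr1")
  far <- data.frame(chrom = "chr1", start = 50000, end = 60000)
  near <- data.frame(chrom = "chr1", start = 1000, end = 4000)

  # i: MLPA event in a region with no array probes
  expect_equal(classify_discordance(disc_pair(), snp_probes, mlpa_probes,
                                    abnormality_interval = far)$category, "i")
  # ii: single-probe MLPA event over numerous normal array probes
  expect_equal(classify_discordance(disc_pair(single = TRUE), snp_probes,
                                    mlpa_probes,
                                    abnormality_interval = near)$category,
               "ii")
  # iii: automated call NORMAL, rescue-augmented call concordant with MLPA
  expect_equal(classify_discordance(disc_pair(manual = "LOSS_DELETION"),
                                    snp_probes, mlpa_probes,
                                    abnormality_interval = near)$category,
               "iii")
  # v: array event in a region with no MLPA probes
  expect_equal(classify_discordance(disc_pair(mlpa = "NORMAL",
                                              snp = "LOSS_DELETION",
                                              manual = "LOSS_DELETION"),
                                    snp_probes, mlpa_probes,
                                    snp_interval = far)$category, "v")
  # iv: disagreement despite coverage on both sides
  expect_equal(classify_discordance(disc_pair(), snp_probes, mlpa_probes,
                                    abnormality_interval = near)$category,
               "iv")
  expect_error(classify_discordance(disc_pair(mlpa = "NORMAL"), snp_probes,
                                    mlpa_probes), "concordant")
})

test_that("every discordant pair receives exactly one category", {
  snp_probes <- make_probe_map(seq(0, 10000, by = 500))
  mlpa_probes <- make_probe_map(c(2000, 2500, 3000), chrom = "chr1")
  set.seed(29)
  for (k in 1:100) {
    mlpa_abn <- runif(1) < 0.5
    pair <- disc_pair(
      mlpa = if (mlpa_abn) "LOSS_DELETION" else "NORMAL",
      snp = if (mlpa_abn) "NORMAL" else "GAIN_AMPLIFICATION",
      manual = sample(c("NORMAL", "LOSS_DELETION"), 1),
      single = runif(1) < 0.3)
    if (!mlpa_abn) pair$snp_state_manual <- pair$snp_state
    s <- runif(1, 0, 50000)
    iv <- data.frame(chrom = "chr1", start = s, end = s + runif(1, 100, 20000))
    rec <- classify_discordance(pair, snp_probes, mlpa_probes,
                                abnormality_interval = if (mlpa_abn) iv else NULL,
                                snp_interval = if (!mlpa_abn) iv else NULL)
    expect_length(rec$category, 1L)
    expect_true(rec$category %in% c("i", "ii", "iii", "iv", "v"))
  }
})

test_that("category counts over the discordance fixture match the record set", {
  fx <- load_published_tables()
  counts <- category_counts(fx$table2)
  expect_equal(unname(counts), c(5L, 2L, 9L, 6L, 3L))
  expect_equal(sum(counts), 25L)
  expect_equal(unname(category_counts(fx$table2[0, ])), rep(0L, 5))
})

test_that("mlpa_abnormality_interval pads by half the flanking distance", {
  region <- simple_region()
  gene_probes <- make_probe_map(c(2000, 3000, 4000, 5000))
  call <- data.frame(supp_start = 3000, supp_end = 4001)
  iv <- mlpa_abnormality_interval(call, gene_probes, region)
  expect_equal(iv$start, 2500)
  expect_equal(iv$end, 4501)
  # terminal runs pad to the span boundary
  call2 <- data.frame(supp_start = 2000, supp_end = 5001)
  iv2 <- mlpa_abnormality_interval(call2, gene_probes, region)
  expect_equal(iv2$start, region$span$start)
  expect_equal(iv2$end, region$span$end)
})
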