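# Independent oracles used across test files.

# all permutations of a vector (for exact permutation null at tiny n)
enumerate_permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(enumerate_permutations(v[-i]), function(p) c(v[i], p))
  }))
}

# exhaustive arc argmax in plain R, lexicographic tie-break over the
# canonical (j < n) parametrization of each partition
oracle_max_arc <- function(x) {
  n <- length(x)
  best <- list(i = 0L, j = 1L, t = -Inf)
  for (i in 0:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      t <- arc_statistic(x, i, j)
      if (t > best$t) best <- list(i = i, j = j, t = t)
    }
  }
  best
}

# brute-force probe-in-interval count
oracle_probes_in <- function(interval, probes) {
  sum(probes$chrom == interval$chrom &
        probes$start >= interval$start &
        probes$start < interval$end)
}

make_probe_map <- function(pos, chrom = "chr1") {
  data.frame(probe_id = sprintf("p%04d", seq_along(pos)), chrom = chrom,
             start = pos, end = pos + 1, stringsAsFactors = FALSE)
}

# a minimal one-gene region for call tests
simple_region <- function(chrom = "chr1", start = 1000, end = 9000,
                          exon_starts = seq(1500, 8000, by = 1500)) {
  span <- data.frame(chrom = chrom, start = start, end = end, name = "G1")
  exons <- data.frame(chrom = chrom, start = exon_starts,
                      end = exon_starts + 200,
                      name = paste0("ex", seq_along(exon_starts)))
  gene_region("G1", span, exons)
}
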