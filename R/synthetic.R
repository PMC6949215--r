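#' Synthetic paired SNP-array / MLPA cohorts with known truth
#'
#' The generator emulates the study's inputs on a toy genome: nine regions
#' on nine pseudo-chromosomes, 30-120 array probes per region at 1.5 kb
#' spacing, and an MLPA kit with one probe per covered exon. The probe
#' geometry reproduces, at toy scale, the coverage features that drive the
#' discordance taxonomy:
#'
#' * an IKZF1-like region with a ~42 kb probe-free hole in intron 3, so
#'   focal deletions flanking the hole exist;
#' * a CDKN2A-like region with zero array probes inside the gene span
#'   (probes only flank it);
#' * a CDKN2B-like gene with exactly one MLPA kit probe;
#' * EBF1- and PAX5-like genes with exons uncovered by the MLPA kit;
#' * a PAR1-like region whose interior is covered by a single array probe,
#'   with a recurrent event interval containing none.
#'
#' Signal model: a diploid baseline LRR of 0 plus Gaussian probe noise; an
#' event with copy change `delta_cn` present in a clonal fraction `f` of
#' cells shifts the probes it covers by `expected_lrr(delta_cn, f)`. MLPA
#' peak ratios at covered loci are `(2 + f * delta_cn) / 2` plus Gaussian
#' assay noise.
#'
#' @name synthetic-data
NULL

#' Expected LRR of a copy-number event under clonal admixture
#'
#' `log2((2 + f * delta_cn) / 2)`: the standard two-population mixture of
#' tumour cells carrying the event (fraction `f`) with diploid cells.
#'
#' @param delta_cn Integer change in copies (e.g. -1, -2, +1).
#' @param f Clonal fraction in (0, 1].
#' @return Expected LRR shift (log2 units).
#' @export
expected_lrr <- function(delta_cn, f) {
  stopifnot(f > 0, f <= 1)
  mix <- 2 + f * delta_cn
  if (any(mix <= 0)) stop("mixture copy number must be positive")
  log2(mix / 2)
}

# deterministic pseudo-varied GC fraction (no RNG: the map is fixed)
.toy_gc <- function(pos) 0.35 + 0.3 * ((pos %% 9973) / 9973)

.toy_region <- function(name, chrom, span_start, span_end, exon_starts,
                        exon_width = 300, exon_labels = NULL) {
  if (is.null(exon_labels)) exon_labels <- paste0("ex", seq_along(exon_starts))
  exons <- data.frame(chrom = chrom, start = exon_starts,
                      end = exon_starts + exon_width, name = exon_labels,
                      stringsAsFactors = FALSE)
  span <- data.frame(chrom = chrom, start = span_start, end = span_end,
                     name = name, stringsAsFactors = FALSE)
  gene_region(name, span, exons)
}

.probe_positions <- function(from, to, spacing, exclude = NULL) {
  pos <- seq(from, to, by = spacing)
  if (!is.null(exclude)) {
    for (k in seq_len(nrow(exclude))) {
      pos <- pos[pos < exclude$start[k] | pos >= exclude$end[k]]
    }
  }
  pos
}

#' The packaged toy genome
#'
#' @return List with `regions` (named list of [gene_region]s), `probes`
#'   (array probe map), `mlpa_probes` (kit probe map), `holes` (declared
#'   probe-free intervals), `event_templates` (per-region candidate events).
#' @export
toy_genome <- function() {
  spacing <- 1500
  regions <- list(
    IKZF1 = .toy_region("IKZF1", "chr1", 100000, 205000,
                        c(102000, 112000, 120000, 162000, 172000, 182000,
                          192000, 202000)),
    ETV6 = .toy_region("ETV6", "chr2", 100000, 148000,
                       102000 + 6000 * (0:7)),
    CDKN2A = .toy_region("CDKN2A", "chr3", 100000, 130000,
                         c(102000, 112000, 124000)),
    CDKN2B = .toy_region("CDKN2B", "chr4", 100000, 110000,
                         c(102000, 106000)),
    RB1 = .toy_region("RB1", "chr5", 100000, 158000,
                      102000 + 7500 * (0:7)),
    BTG1 = .toy_region("BTG1", "chr6", 100000, 112000,
                       c(102000, 108000)),
    EBF1 = .toy_region("EBF1", "chr7", 100000, 164000,
                       102000 + 8000 * (0:7)),
    PAX5 = .toy_region("PAX5", "chr8", 100000, 180000,
                       102000 + 7500 * (0:9)),
    PAR1 = .toy_region("PAR1", "chr9", 100000, 140000,
                       c(102000, 117000, 132000),
                       exon_labels = c("CRLF2", "CSF2RA", "IL3RA"))
  )
  ikzf1_hole <- data.frame(chrom = "chr1", start = 120400, end = 161900,
                           name = "IKZF1_hole", stringsAsFactors = FALSE)
  pos <- list(
    chr1 = .probe_positions(85000, 220000, spacing,
                            exclude = ikzf1_hole),
    chr2 = .probe_positions(85000, 163000, spacing),
    # CDKN2A analogue: no probes internal to the gene span
    chr3 = .probe_positions(60000, 170000, spacing,
                            exclude = data.frame(start = 99500, end = 130500)),
    chr4 = .probe_positions(85000, 125000, spacing),
    chr5 = .probe_positions(85000, 173000, spacing),
    chr6 = .probe_positions(85000, 127000, spacing),
    chr7 = .probe_positions(85000, 179000, spacing),
    chr8 = .probe_positions(85000, 195000, spacing),
    # PAR1 analogue: one probe inside the span, the rest flanking
    chr9 = sort(c(.probe_positions(60000, 170000, spacing,
                                   exclude = data.frame(start = 99500,
                                                        end = 140500)),
                  104000))
  )
  probes <- do.call(rbind, lapply(names(pos), function(chrom) {
    p <- pos[[chrom]]
    data.frame(probe_id = sprintf("%s_p%04d", chrom, seq_along(p)),
               chrom = chrom, start = p, end = p + 1,
               gc_fraction = .toy_gc(p), stringsAsFactors = FALSE)
  }))
  # MLPA kit: one probe per covered exon; partial coverage by design
  covered <- list(IKZF1 = 1:8, ETV6 = 1:8, CDKN2A = 1:3, CDKN2B = 1,
                  RB1 = c(1, 2, 3, 5, 6, 8), BTG1 = 1:2,
                  EBF1 = c(1, 6, 7, 8), PAX5 = setdiff(1:10, 7), PAR1 = 1:3)
  mlpa_probes <- do.call(rbind, lapply(names(covered), function(g) {
    region <- regions[[g]]
    ex <- region$exons[covered[[g]], , drop = FALSE]
    data.frame(probe_id = sprintf("%s_m%02d", g, covered[[g]]),
               gene = g, exon_label = ex$name, chrom = ex$chrom,
               start = ex$start + 50, end = ex$start + 110,
               stringsAsFactors = FALSE)
  }))
  templates <- list(
    IKZF1 = data.frame(name = c("ex4-7", "ex2-8", "ex1-8"),
                       start = c(161800, 111000, 101000),
                       end = c(192400, 203000, 203000),
                       delta_cn = c(-1, -1, -1), weight = c(0.6, 0.3, 0.1)),
    ETV6 = data.frame(name = c("ex1-8", "ex1-4"),
                      start = c(101000, 101000), end = c(145000, 122000),
                      delta_cn = c(-1, -1), weight = c(0.7, 0.3)),
    CDKN2A = data.frame(name = c("focal", "large"),
                        start = c(101000, 80000), end = c(126000, 150000),
                        delta_cn = c(-1, -1), weight = c(0.7, 0.3)),
    CDKN2B = data.frame(name = "del", start = 95000, end = 115000,
                        delta_cn = -1, weight = 1),
    RB1 = data.frame(name = "ex1-8", start = 101000, end = 156000,
                     delta_cn = -1, weight = 1),
    BTG1 = data.frame(name = "del", start = 95000, end = 117000,
                      delta_cn = -1, weight = 1),
    EBF1 = data.frame(name = c("ex2-5", "ex1-8"),
                      start = c(109000, 101000), end = c(136000, 159000),
                      delta_cn = c(-1, -1), weight = c(0.4, 0.6)),
    PAX5 = data.frame(name = c("ex7", "ex1-10", "gain"),
                      start = c(143000, 101000, 101000),
                      end = c(151000, 172000, 172000),
                      delta_cn = c(-1, -1, 1), weight = c(0.15, 0.55, 0.3)),
    PAR1 = data.frame(name = "par1_del", start = 115000, end = 136000,
                      delta_cn = -1, weight = 1)
  )
  list(regions = regions, probes = probes, mlpa_probes = mlpa_probes,
       holes = ikzf1_hole, event_templates = templates)
}

#' Synthetic cohort specification
#'
#' Defaults emulate the study cohort: 143 samples, LRR probe noise sd 0.15,
#' MLPA ratio noise sd 0.08, per-region event frequencies matching the
#' observed abnormality rates, clonal events (`subclonal_prob = 0`;
#' subclonal admixture with `f` drawn uniformly from `subclonal_f` is
#' available for sensitivity studies).
#'
#' @param n_samples Cohort size.
#' @param noise_sd LRR probe noise standard deviation.
#' @param mlpa_sd MLPA peak-ratio noise standard deviation.
#' @param event_freq Named per-region event probabilities.
#' @param subclonal_prob Probability an injected event is subclonal.
#' @param subclonal_f Range of the subclonal fraction.
#' @param seed RNG seed for [generate_cohort()].
#' @return List with class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_samples = 143, noise_sd = 0.15,
                                  mlpa_sd = 0.08,
                                  event_freq = c(IKZF1 = 0.20, ETV6 = 0.16,
                                                 CDKN2A = 0.42, CDKN2B = 0.40,
                                                 RB1 = 0.08, BTG1 = 0.01,
                                                 EBF1 = 0.07, PAX5 = 0.33,
                                                 PAR1 = 0.03),
                                  subclonal_prob = 0,
                                  subclonal_f = c(0.2, 0.7), seed = 1) {
  stopifnot(n_samples >= 1, noise_sd >= 0, mlpa_sd >= 0,
            all(event_freq >= 0), all(event_freq <= 1),
            subclonal_prob >= 0, subclonal_prob <= 1)
  structure(list(n_samples = as.integer(n_samples), noise_sd = noise_sd,
                 mlpa_sd = mlpa_sd, event_freq = event_freq,
                 subclonal_prob = subclonal_prob, subclonal_f = subclonal_f,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Generate a paired SNP-array / MLPA cohort with known truth
#'
#' Deterministic given `spec$seed`. Probes inside declared holes are absent
#' from the map entirely (they are never generated, mirroring array design).
#'
#' @param spec A [synthetic_cohort_spec].
#' @param genome A genome from [toy_genome()] (the default).
#' @return List: `lrr` (wide data frame `probe_id, chrom, pos, <samples>`),
#'   `mlpa` (long data frame `sample_id, probe_id, gene, exon_label, pos,
#'   peak_ratio`), `truth` (one row per injected event), `genome`, `spec`.
#' @export
generate_cohort <- function(spec = synthetic_cohort_spec(),
                            genome = toy_genome()) {
  set.seed(spec$seed)
  probes <- genome$probes
  mp <- genome$mlpa_probes
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  lrr <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                    pos = probes$start, stringsAsFactors = FALSE)
  mlpa_rows <- list()
  truth_rows <- list()
  for (si in seq_along(samples)) {
    sid <- samples[si]
    x <- rnorm(nrow(probes), 0, spec$noise_sd)
    ratio <- rep(1, nrow(mp))
    for (g in names(genome$event_templates)) {
      freq <- spec$event_freq[[g]]
      if (is.null(freq) || runif(1) >= freq) next
      tmpl <- genome$event_templates[[g]]
      k <- sample.int(nrow(tmpl), 1, prob = tmpl$weight)
      f <- if (runif(1) < spec$subclonal_prob) {
        runif(1, spec$subclonal_f[1], spec$subclonal_f[2])
      } else 1
      chrom <- genome$regions[[g]]$chrom
      shift <- expected_lrr(tmpl$delta_cn[k], f)
      hit <- probes$chrom == chrom & probes$start >= tmpl$start[k] &
        probes$start < tmpl$end[k]
      x[hit] <- x[hit] + shift
      mhit <- mp$chrom == chrom & mp$start >= tmpl$start[k] &
        mp$start < tmpl$end[k]
      ratio[mhit] <- (2 + f * tmpl$delta_cn[k]) / 2
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample_id = sid, region = g, event = tmpl$name[k], chrom = chrom,
        start = tmpl$start[k], end = tmpl$end[k],
        delta_cn = tmpl$delta_cn[k], f = f, stringsAsFactors = FALSE)
    }
    lrr[[sid]] <- x
    ratio <- pmax(0, ratio + rnorm(nrow(mp), 0, spec$mlpa_sd))
    mlpa_rows[[si]] <- data.frame(sample_id = sid, probe_id = mp$probe_id,
                                  gene = mp$gene, exon_label = mp$exon_label,
                                  pos = mp$start, peak_ratio = ratio,
                                  stringsAsFactors = FALSE)
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(sample_id = character(), region = character(),
               event = character(), chrom = character(), start = numeric(),
               end = numeric(), delta_cn = numeric(), f = numeric())
  list(lrr = lrr, mlpa = do.call(rbind, mlpa_rows), truth = truth,
       genome = genome, spec = spec, samples = samples)
}

#' Constructed IKZF1-hole failure-mode fixture
#'
#' A deterministic single-sample fixture reproducing the mechanism by which
#' segmentation misses a focal deletion flanking an intra-gene coverage
#' hole: the array design downstream of the hole is sparse, so the deletion
#' of exons 4-7 covers only four array probes — below the five-marker
#' detection cut-off, hence never emitted by [cbs_segment()] — while the
#' MLPA kit sees four adjacent abnormal exon probes and [focal_rescue()]
#' (window below the CBS cut-off) recovers the event from the LRR data.
#'
#' @param noise_sd LRR probe noise (default 0, fully deterministic).
#' @param delta_lrr LRR shift of the deletion (default -1, clonal
#'   single-copy loss).
#' @param seed Seed used when `noise_sd > 0`.
#' @return List: `profile` ([array_profile] with the deletion applied),
#'   `region` ([gene_region]), `probes` (array map), `mlpa` (kit
#'   measurements with matching ratios), `mlpa_probes`, `event` (the truth
#'   interval).
#' @export
ikzf1_hole_demo <- function(noise_sd = 0, delta_lrr = -1, seed = 1) {
  region <- .toy_region("IKZF1", "chr1", 100000, 210000,
                        c(102000, 112000, 120000, 162000, 172000, 182000,
                          192000, 202000))
  # dense upstream of the hole, four probes across exons 4-7, dense after
  pos <- c(seq(85000, 120400, by = 1500),
           c(163000, 171000, 179000, 187000),
           seq(196000, 220000, by = 1500))
  probes <- data.frame(probe_id = sprintf("chr1_p%04d", seq_along(pos)),
                       chrom = "chr1", start = pos, end = pos + 1,
                       gc_fraction = .toy_gc(pos), stringsAsFactors = FALSE)
  event <- data.frame(chrom = "chr1", start = 162000, end = 192400,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  lrr <- if (noise_sd > 0) rnorm(length(pos), 0, noise_sd) else
    rep(0, length(pos))
  in_event <- pos >= event$start & pos < event$end
  lrr[in_event] <- lrr[in_event] + delta_lrr
  profile <- array_profile("demo", "chr1", pos, lrr,
                           probe_id = probes$probe_id,
                           gc_fraction = probes$gc_fraction)
  ex <- region$exons
  mlpa_probes <- data.frame(probe_id = sprintf("IKZF1_m%02d", seq_len(nrow(ex))),
                            gene = "IKZF1", exon_label = ex$name,
                            chrom = "chr1", start = ex$start + 50,
                            end = ex$start + 110, stringsAsFactors = FALSE)
  m_in <- mlpa_probes$start >= event$start & mlpa_probes$start < event$end
  mlpa <- data.frame(sample_id = "demo", probe_id = mlpa_probes$probe_id,
                     gene = "IKZF1", exon_label = mlpa_probes$exon_label,
                     pos = mlpa_probes$start,
                     peak_ratio = ifelse(m_in, 2^delta_lrr, 1),
                     stringsAsFactors = FALSE)
  list(profile = profile, region = region, probes = probes, mlpa = mlpa,
       mlpa_probes = mlpa_probes, event = event)
}

#' Write a generated cohort to plain-text files
#'
#' Writes `lrr.tsv`, `mlpa.tsv`, `probes.bed`, `mlpa_probes.bed`,
#' `regions.bed`, `exons.bed`, `truth.tsv` under `dir`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(cohort$lrr, "lrr.tsv")
  tsv(cohort$mlpa, "mlpa.tsv")
  tsv(cohort$truth, "truth.tsv")
  write_bed(cohort$genome$probes, file.path(dir, "probes.bed"))
  mp <- cohort$genome$mlpa_probes
  mp$name <- paste(mp$gene, mp$exon_label, sep = "_")
  write_bed(mp, file.path(dir, "mlpa_probes.bed"))
  spans <- do.call(rbind, lapply(cohort$genome$regions, function(r) r$span))
  write_bed(spans, file.path(dir, "regions.bed"))
  exons <- do.call(rbind, lapply(cohort$genome$regions, function(r) {
    e <- r$exons
    e$name <- paste(r$name, e$name, sep = "_")
    e
  }))
  write_bed(exons, file.path(dir, "exons.bed"))
  invisible(dir)
}
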