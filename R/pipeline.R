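#' End-to-end pipeline over a paired cohort
#'
#' Runs the full analysis on matched array and MLPA data: optional GC
#' correction, per-sample per-chromosome segmentation, categorical array
#' calls in both modes (automated, and rescue-augmented "manual"), MLPA
#' calls, cross-platform comparison in both modes, discordance
#' classification of the automated-mode disagreements, and a machine-
#' readable summary. Stage outputs are returned (and optionally written as
#' TSV/JSON) so every summary count is recomputable from them.
#'
#' @param cohort A cohort list from [generate_cohort()], or an equivalent
#'   list with `lrr`, `mlpa`, `genome`, `samples`.
#' @param params [segmentation_params()]; the seed governs all permutation
#'   draws.
#' @param thresholds [call_thresholds()].
#' @param mlpa_thr [mlpa_thresholds()].
#' @param gc_correction Apply [gc_correct()] before segmentation.
#' @param window_k Focal-rescue window (probes).
#' @param gap_threshold Coverage-gap width (bp) splitting rescue runs.
#' @param min_adjacent MLPA adjacency rule.
#' @param out_dir Optional directory for stage TSVs and `summary.json`.
#' @return List: `segments`, `snp_calls` (with `state` and `state_manual`),
#'   `mlpa_calls`, `comparison_cbs`, `comparison_manual`, `discordance`
#'   (classified records, automated mode), `summary`.
#' @export
run_cna_pipeline <- function(cohort, params = segmentation_params(),
                             thresholds = call_thresholds(),
                             mlpa_thr = mlpa_thresholds(),
                             gc_correction = FALSE, window_k = 4,
                             gap_threshold = 10000, min_adjacent = 2,
                             out_dir = NULL) {
  genome <- cohort$genome
  regions <- genome$regions
  probes <- genome$probes
  mlpa_probes <- genome$mlpa_probes
  samples <- cohort$samples
  seg_list <- list()
  snp_list <- list()
  mlpa_list <- list()
  profiles_by_sample <- list()
  for (sid in samples) {
    profs <- profiles_for_sample(cohort$lrr, sid, probes)
    if (gc_correction) profs <- lapply(profs, gc_correct)
    segs <- do.call(rbind, lapply(profs, cbs_segment, params = params))
    profiles_by_sample[[sid]] <- profs
    seg_list[[sid]] <- segs
    cbs_calls <- array_calls_sample(segs, profs, regions, probes, thresholds,
                                    params$min_markers, rescue = FALSE)
    man_calls <- array_calls_sample(segs, profs, regions, probes, thresholds,
                                    params$min_markers, rescue = TRUE,
                                    window_k = window_k,
                                    gap_threshold = gap_threshold)
    cbs_calls$state_manual <- man_calls$state
    cbs_calls$supp_start_manual <- man_calls$supp_start
    cbs_calls$supp_end_manual <- man_calls$supp_end
    cbs_calls$provenance_manual <- man_calls$provenance
    snp_list[[sid]] <- cbs_calls
    m <- cohort$mlpa[cohort$mlpa$sample_id == sid, , drop = FALSE]
    mlpa_list[[sid]] <- mlpa_calls_sample(m, mlpa_thr, min_adjacent)
  }
  segments <- do.call(rbind, seg_list)
  snp_calls <- do.call(rbind, snp_list)
  mlpa_calls <- do.call(rbind, mlpa_list)
  rownames(segments) <- rownames(snp_calls) <- rownames(mlpa_calls) <- NULL
  cmp_cbs <- compare_calls(snp_calls, mlpa_calls, mode = "cbs")
  cmp_man <- compare_calls(snp_calls, mlpa_calls, mode = "manual")
  discordance <- .classify_pipeline_discordance(
    cmp_cbs, snp_calls, mlpa_calls, genome)
  summary <- list(
    n_samples = length(samples),
    total_calls = cmp_cbs$total,
    discordant_cbs = cmp_cbs$discordant,
    discordant_manual = cmp_man$discordant,
    concordance_cbs = concordance_percent(cmp_cbs),
    concordance_manual = concordance_percent(cmp_man),
    category_counts = as.list(category_counts(discordance)),
    parameters = list(alpha = params$alpha, nperm = params$nperm,
                      min_markers = params$min_markers, seed = params$seed,
                      window_k = window_k, gap_threshold = gap_threshold,
                      min_adjacent = min_adjacent,
                      gc_correction = gc_correction)
  )
  result <- list(segments = segments, snp_calls = snp_calls,
                 mlpa_calls = mlpa_calls, comparison_cbs = cmp_cbs,
                 comparison_manual = cmp_man, discordance = discordance,
                 summary = summary)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

.classify_pipeline_discordance <- function(cmp, snp_calls, mlpa_calls,
                                           genome) {
  pairs <- cmp$pairs[!cmp$pairs$concordant, , drop = FALSE]
  if (nrow(pairs) == 0L) return(NULL)
  recs <- lapply(seq_len(nrow(pairs)), function(k) {
    pair <- pairs[k, , drop = FALSE]
    region <- genome$regions[[pair$gene]]
    mc <- mlpa_calls[mlpa_calls$sample_id == pair$sample_id &
                       mlpa_calls$gene == pair$gene, , drop = FALSE]
    sc <- snp_calls[snp_calls$sample_id == pair$sample_id &
                      snp_calls$gene == pair$gene, , drop = FALSE]
    gene_probes <- genome$mlpa_probes[genome$mlpa_probes$gene == pair$gene, ,
                                      drop = FALSE]
    abn_int <- if (.is_abnormal(pair$mlpa_state)) {
      mlpa_abnormality_interval(mc, gene_probes, region)
    } else NULL
    snp_int <- if (.is_abnormal(pair$snp_state) && !is.na(sc$supp_start)) {
      data.frame(chrom = region$chrom, start = sc$supp_start,
                 end = sc$supp_end, stringsAsFactors = FALSE)
    } else NULL
    classify_discordance(pair, genome$probes, genome$mlpa_probes,
                         abnormality_interval = abn_int,
                         snp_interval = snp_int)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) {
    if (!is.null(d)) write.table(d, file.path(out_dir, f), sep = "\t",
                                 quote = FALSE, row.names = FALSE)
  }
  tsv(result$segments, "segments.tsv")
  tsv(result$snp_calls, "snp_calls.tsv")
  tsv(result$mlpa_calls, "mlpa_calls.tsv")
  tsv(result$comparison_cbs$pairs, "pairs_cbs.tsv")
  tsv(result$discordance, "discordant.tsv")
  tsv(tabulate_pairs(result$comparison_cbs), "contingency_cbs.tsv")
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Recovery of generator truth by the pipeline
#'
#' Sensitivity is the fraction of truth events recovered by the
#' rescue-augmented array calls, restricted to events whose intersection
#' with the gene span contains at least `min_markers` array probes — the
#' per-gene calling rule only consumes probes inside the gene span, so
#' events in probe-free geometry (the CDKN2A-like interior, the PAR1-like
#' gap) are invisible to the array by design and belong to the discordance
#' taxonomy, not to the detection rate. Specificity is computed over the
#' truth-normal cells of the (sample, gene) grid.
#'
#' @param result A [run_cna_pipeline()] result.
#' @param cohort The generated cohort (for `truth` and probe maps).
#' @param min_markers Array probes required for an event to be detectable.
#' @return List: `sensitivity`, `specificity`, `per_gene` breakdown,
#'   `n_detectable`, `n_truth_normal`.
#' @export
pipeline_performance <- function(result, cohort, min_markers = 5) {
  truth <- cohort$truth
  probes <- cohort$genome$probes
  calls <- result$snp_calls
  key <- paste(calls$sample_id, calls$gene)
  truth_key <- paste(truth$sample_id, truth$region)
  detectable <- vapply(seq_len(nrow(truth)), function(k) {
    span <- cohort$genome$regions[[truth$region[k]]]$span
    iv <- data.frame(chrom = truth$chrom[k],
                     start = max(truth$start[k], span$start),
                     end = min(truth$end[k], span$end))
    if (iv$end <= iv$start) return(FALSE)
    probes_in(iv, probes)$count >= min_markers
  }, TRUE)
  det <- truth[detectable, , drop = FALSE]
  hit <- .is_abnormal(calls$state_manual[match(paste(det$sample_id,
                                                     det$region), key)])
  normal_cells <- !(key %in% truth_key)
  fp <- .is_abnormal(calls$state_manual[normal_cells])
  per_gene <- do.call(rbind, lapply(sort(unique(calls$gene)), function(g) {
    gsel <- normal_cells & calls$gene == g
    dsel <- det$region == g
    data.frame(gene = g,
               sensitivity = if (any(dsel)) mean(hit[dsel]) else NA_real_,
               specificity = if (any(gsel))
                 mean(!.is_abnormal(calls$state_manual[gsel])) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(sensitivity = if (nrow(det)) mean(hit) else NA_real_,
       specificity = if (any(normal_cells)) 1 - mean(fp) else NA_real_,
       per_gene = per_gene,
       n_detectable = nrow(det), n_truth_normal = sum(normal_cells))
}

#' Reproduce the published headline numbers from the packaged tables
#'
#' Table mode: expands the contingency fixture into a call-pair grid,
#' compares in both modes, counts discordance categories from the
#' discordant-record fixture, and counts reclassified patients from its
#' printed risk labels.
#'
#' @param fixtures Result of [load_published_tables()] (the default loads the
#'   packaged CSVs).
#' @param out_dir Optional directory for `summary.json`.
#' @return List with `pairs`, `comparison_cbs`, `comparison_manual`,
#'   `contingency`, `summary`.
#' @export
run_from_tables <- function(fixtures = load_published_tables(),
                            out_dir = NULL) {
  pairs <- fixture_to_pairs(fixtures$table1)
  snp_calls <- data.frame(sample_id = pairs$sample_id, gene = pairs$gene,
                          state = pairs$snp_state,
                          state_manual = pairs$snp_state_manual,
                          stringsAsFactors = FALSE)
  mlpa_calls <- data.frame(sample_id = pairs$sample_id, gene = pairs$gene,
                           state = pairs$mlpa_state,
                           single_probe_evidence = pairs$mlpa_single_probe,
                           stringsAsFactors = FALSE)
  cmp_cbs <- compare_calls(snp_calls, mlpa_calls, mode = "cbs")
  cmp_man <- compare_calls(snp_calls, mlpa_calls, mode = "manual")
  cats <- category_counts(fixtures$table2)
  summary <- list(
    total_calls = cmp_cbs$total,
    discordant_cbs = cmp_cbs$discordant,
    discordant_manual = cmp_man$discordant,
    concordance_cbs = concordance_percent(cmp_cbs),
    concordance_manual = concordance_percent(cmp_man),
    category_counts = as.list(cats),
    reclassified_manual = count_reclassified(fixtures$table2, "risk_mlpa",
                                             "risk_snp_manual"),
    reclassified_cbs = count_reclassified(fixtures$table2, "risk_mlpa",
                                          "risk_snp_cbs")
  )
  result <- list(pairs = cmp_cbs$pairs, comparison_cbs = cmp_cbs,
                 comparison_manual = cmp_man,
                 contingency = tabulate_pairs(cmp_man),
                 summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}
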