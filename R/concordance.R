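#' Cross-platform concordance and the discordance taxonomy
#'
#' Array and MLPA calls are compared per (sample, gene) on an aggregated
#' Normal/Abnormal axis: a pair is concordant when both platforms are NORMAL
#' or both abnormal (losses/deletions and gains/amplifications count as one
#' event each way). Discordant pairs are classified into five mutually
#' exclusive categories:
#'
#' * **I** — no SNP array probes cover the abnormality (array design gap);
#' * **II** — the MLPA result rests on a single kit probe over numerous
#'   normal array probes;
#' * **III** — segmentation missed a focal event that LRR review (the
#'   focal-rescue operator) recovers concordantly with MLPA;
#' * **IV** — the platforms disagree despite sufficient probe coverage
#'   (residual category);
#' * **V** — the array detects an event in a region with no MLPA probes.
#'
#' The cascade is evaluated in the order I, II, III, V, with IV as the
#' fallback.
#'
#' @name concordance
NULL

.is_abnormal <- function(state) state != "NORMAL"

#' Compare array and MLPA call grids
#'
#' Both call sets must cover the same (sample, gene) grid. `mode` selects the
#' array column: `"cbs"` uses the automated segmentation calls, `"manual"`
#' the rescue-augmented calls (`state_manual`, falling back to `state` where
#' absent).
#'
#' @param snp_calls Data frame `sample_id, gene, state` and optionally
#'   `state_manual`.
#' @param mlpa_calls Data frame `sample_id, gene, state` and optionally
#'   `single_probe_evidence`.
#' @param mode `"cbs"` or `"manual"`.
#' @return List with `pairs` (one row per grid cell, with `concordant`
#'   flag), `total`, `discordant`, `concordant`.
#' @export
compare_calls <- function(snp_calls, mlpa_calls, mode = c("cbs", "manual")) {
  mode <- match.arg(mode)
  key <- function(d) paste(d$sample_id, d$gene, sep = "\r")
  ks <- key(snp_calls)
  km <- key(mlpa_calls)
  missing_in_snp <- setdiff(km, ks)
  missing_in_mlpa <- setdiff(ks, km)
  if (length(missing_in_snp) || length(missing_in_mlpa)) {
    stop("call grids do not match; missing keys: ",
         paste(gsub("\r", "/", c(missing_in_snp, missing_in_mlpa)),
               collapse = ", "))
  }
  m <- mlpa_calls[match(ks, km), , drop = FALSE]
  snp_state <- snp_calls$state
  snp_manual <- if ("state_manual" %in% names(snp_calls)) {
    ifelse(is.na(snp_calls$state_manual), snp_state, snp_calls$state_manual)
  } else snp_state
  used <- if (mode == "cbs") snp_state else snp_manual
  pairs <- data.frame(
    sample_id = snp_calls$sample_id,
    gene = snp_calls$gene,
    snp_state = snp_state,
    snp_state_manual = snp_manual,
    mlpa_state = m$state,
    mlpa_single_probe = if ("single_probe_evidence" %in% names(m))
      m$single_probe_evidence else FALSE,
    stringsAsFactors = FALSE
  )
  pairs$concordant <- .is_abnormal(used) == .is_abnormal(pairs$mlpa_state)
  list(pairs = pairs, total = nrow(pairs),
       discordant = sum(!pairs$concordant),
       concordant = sum(pairs$concordant), mode = mode)
}

#' Concordance percentage
#'
#' @param comparison Result of [compare_calls()], or a list with `total` and
#'   `discordant`.
#' @return List with `raw` (percentage) and `rounded` (nearest integer).
#' @export
concordance_percent <- function(comparison) {
  stopifnot(comparison$total >= 1)
  raw <- 100 * (1 - comparison$discordant / comparison$total)
  list(raw = raw, rounded = round(raw))
}

#' Per-gene 2x2 contingency tables
#'
#' Cells count MLPA state (Normal/Abnormal) against array state
#' (Normal/Abnormal) per gene; each gene's cells sum to the cohort size.
#'
#' @param comparison Result of [compare_calls()].
#' @return Data frame `gene, snp, mlpa, count` (long 2x2 per gene).
#' @export
tabulate_pairs <- function(comparison) {
  pairs <- comparison$pairs
  used <- if (comparison$mode == "cbs") pairs$snp_state else pairs$snp_state_manual
  snp <- ifelse(.is_abnormal(used), "Abnormal", "Normal")
  mlpa <- ifelse(.is_abnormal(pairs$mlpa_state), "Abnormal", "Normal")
  grid <- expand.grid(gene = unique(pairs$gene),
                      snp = c("Normal", "Abnormal"),
                      mlpa = c("Normal", "Abnormal"),
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(g, s, m) {
    sum(pairs$gene == g & snp == s & mlpa == m)
  }, grid$gene, grid$snp, grid$mlpa)
  grid[order(grid$gene), , drop = FALSE]
}

DISCORDANCE_CATEGORIES <- c("i", "ii", "iii", "iv", "v")

#' Classify one discordant call pair
#'
#' @param pair One-row data frame with `snp_state`, `snp_state_manual`,
#'   `mlpa_state`, `mlpa_single_probe` (a discordant pair in CBS mode).
#' @param snp_probes Sorted array-probe map.
#' @param mlpa_probes Sorted MLPA-probe map.
#' @param abnormality_interval Interval of the MLPA-detected event (first to
#'   last abnormal kit probe, padded), or `NULL` when MLPA is normal.
#' @param snp_interval Supporting interval of the array-detected event, or
#'   `NULL` when the array is normal.
#' @param min_snp_probes Normal array probes required inside the interval
#'   for category II's "numerous probes" condition (default 5).
#' @return One-row data frame with `category` and probe-count evidence.
#' @export
classify_discordance <- function(pair, snp_probes, mlpa_probes,
                                 abnormality_interval = NULL,
                                 snp_interval = NULL, min_snp_probes = 5) {
  mlpa_abn <- .is_abnormal(pair$mlpa_state)
  snp_abn <- .is_abnormal(pair$snp_state)
  if (mlpa_abn == snp_abn) stop("pair is concordant; nothing to classify")
  n_snp_in <- NA_integer_
  n_mlpa_in <- NA_integer_
  category <- "iv"
  if (mlpa_abn && !is.null(abnormality_interval)) {
    n_snp_in <- probes_in(abnormality_interval, snp_probes)$count
  }
  if (snp_abn && !is.null(snp_interval)) {
    n_mlpa_in <- probes_in(snp_interval, mlpa_probes)$count
  }
  if (mlpa_abn && !is.na(n_snp_in) && n_snp_in == 0L) {
    category <- "i"
  } else if (mlpa_abn && isTRUE(pair$mlpa_single_probe) &&
             !is.na(n_snp_in) && n_snp_in >= min_snp_probes) {
    category <- "ii"
  } else if (!snp_abn && .is_abnormal(pair$snp_state_manual) && mlpa_abn) {
    category <- "iii"
  } else if (snp_abn && !is.na(n_mlpa_in) && n_mlpa_in == 0L) {
    category <- "v"
  }
  data.frame(sample_id = pair$sample_id, gene = pair$gene,
             mlpa_state = pair$mlpa_state, snp_state = pair$snp_state,
             snp_state_manual = pair$snp_state_manual,
             category = category,
             n_snp_probes_in_interval = n_snp_in,
             n_mlpa_probes_in_interval = n_mlpa_in,
             interval_start = if (mlpa_abn && !is.null(abnormality_interval))
               abnormality_interval$start else if (!is.null(snp_interval))
                 snp_interval$start else NA_real_,
             interval_end = if (mlpa_abn && !is.null(abnormality_interval))
               abnormality_interval$end else if (!is.null(snp_interval))
                 snp_interval$end else NA_real_,
             stringsAsFactors = FALSE)
}

#' Count discordance categories
#'
#' @param records Data frame with a `category` column (`i`..`v`).
#' @return Named integer vector over all five categories (zeros included).
#' @export
category_counts <- function(records) {
  out <- stats::setNames(integer(length(DISCORDANCE_CATEGORIES)),
                         DISCORDANCE_CATEGORIES)
  if (!is.null(records) && nrow(records)) {
    tab <- table(factor(records$category, levels = DISCORDANCE_CATEGORIES))
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' MLPA abnormality interval for coverage queries
#'
#' The span from the first to the last abnormal kit probe, padded on each
#' side by half the distance to the nearest flanking kit probe (or to the
#' region span boundary when the abnormal run is terminal).
#'
#' @param mlpa_call One-row result of [call_gene_mlpa()] with support span.
#' @param gene_probes The gene's kit probes (sorted by position).
#' @param region The [gene_region] (for boundary padding).
#' @return One-row interval data frame, or `NULL` when no support span.
#' @export
mlpa_abnormality_interval <- function(mlpa_call, gene_probes, region) {
  if (is.na(mlpa_call$supp_start)) return(NULL)
  s <- mlpa_call$supp_start
  e <- mlpa_call$supp_end
  before <- gene_probes$start[gene_probes$start < s]
  after <- gene_probes$start[gene_probes$start >= e]
  span <- region$span
  lo <- if (length(before)) s - (s - max(before)) / 2 else
    min(s, span$start)
  hi <- if (length(after)) e + (min(after) - (e - 1)) / 2 else
    max(e, span$end)
  data.frame(chrom = region$chrom, start = lo, end = hi,
             stringsAsFactors = FALSE)
}
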