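#' MLPA peak-ratio calling
#'
#' MLPA reports per-exon relative copy number as a peak ratio against
#' reference probes (~1 at normal copy number). A gene is called abnormal
#' when at least `min_adjacent` consecutive kit probes deviate in the same
#' direction; genes represented by a single probe in the kit are callable
#' from that probe but carry a `single_probe_evidence` flag, which feeds the
#' single-probe discordance category downstream.
#'
#' @name mlpa-calls
NULL

#' MLPA peak-ratio thresholds
#'
#' @param loss_max Ratio at or below which a probe is abnormal-low
#'   (default 0.75).
#' @param gain_min Ratio at or above which a probe is abnormal-high
#'   (default 1.3).
#' @param deletion_max Sub-state bound for (homozygous) deletion
#'   (default 0.25).
#' @param amp_min Sub-state bound for amplification (default 2.0).
#' @return List with class `mlpa_thresholds`.
#' @export
mlpa_thresholds <- function(loss_max = 0.75, gain_min = 1.3,
                            deletion_max = 0.25, amp_min = 2.0) {
  stopifnot(deletion_max <= loss_max, loss_max < 1, 1 < gain_min,
            gain_min <= amp_min)
  structure(list(loss_max = loss_max, gain_min = gain_min,
                 deletion_max = deletion_max, amp_min = amp_min),
            class = "mlpa_thresholds")
}

#' Categorical state of one MLPA probe ratio
#'
#' @param ratio Peak ratio (non-negative, finite).
#' @param thresholds An [mlpa_thresholds].
#' @return List with `state` and `sub_state`.
#' @export
mlpa_call_probe <- function(ratio, thresholds = mlpa_thresholds()) {
  if (!is.finite(ratio) || ratio < 0) stop("peak ratio must be finite and >= 0")
  t <- thresholds
  if (ratio <= t$loss_max) {
    sub <- if (ratio <= t$deletion_max) "deletion" else "loss"
    list(state = "LOSS_DELETION", sub_state = sub)
  } else if (ratio >= t$gain_min) {
    sub <- if (ratio >= t$amp_min) "amplification" else "gain"
    list(state = "GAIN_AMPLIFICATION", sub_state = sub)
  } else {
    list(state = "NORMAL", sub_state = NA_character_)
  }
}

#' Per-gene MLPA call from ordered probe measurements
#'
#' `measurements` must be ordered by probe genomic position ("adjacent"
#' means consecutive in the kit's genomic order). The adjacency rule applies
#' to both directions of abnormality.
#'
#' @param measurements Data frame with columns `sample_id`, `probe_id`,
#'   `gene`, `pos` (or pre-sorted), `peak_ratio` for one gene in one sample.
#' @param thresholds An [mlpa_thresholds].
#' @param min_adjacent Consecutive abnormal probes required for a call
#'   (default 2). Single-probe genes are exempt but flagged.
#' @return One-row data frame: `sample_id`, `gene`, `state`,
#'   `n_supporting_probes`, `single_probe_evidence`, `supp_start`,
#'   `supp_end` (span of the supporting probes, or `NA`).
#' @export
call_gene_mlpa <- function(measurements, thresholds = mlpa_thresholds(),
                           min_adjacent = 2) {
  if (nrow(measurements) == 0L) stop("no MLPA measurements for gene")
  if ("pos" %in% names(measurements)) {
    measurements <- measurements[order(measurements$pos), , drop = FALSE]
  }
  states <- vapply(measurements$peak_ratio,
                   function(r) mlpa_call_probe(r, thresholds)$state, "")
  n_abn <- sum(states != "NORMAL")
  out <- data.frame(sample_id = measurements$sample_id[1L],
                    gene = measurements$gene[1L],
                    state = "NORMAL",
                    n_supporting_probes = 0L,
                    single_probe_evidence = n_abn == 1L,
                    supp_start = NA_real_, supp_end = NA_real_,
                    stringsAsFactors = FALSE)
  # longest run of consecutive same-direction abnormal probes
  best_len <- 0L
  best_state <- "NORMAL"
  best_range <- NULL
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "NORMAL") next
    if (r$lengths[k] > best_len) {
      best_len <- r$lengths[k]
      best_state <- r$values[k]
      best_range <- c(starts[k], ends[k])
    }
  }
  single_probe_gene <- nrow(measurements) == 1L
  if (best_len >= min_adjacent || (single_probe_gene && best_len >= 1L)) {
    out$state <- best_state
    out$n_supporting_probes <- best_len
    if ("pos" %in% names(measurements)) {
      out$supp_start <- measurements$pos[best_range[1L]]
      out$supp_end <- measurements$pos[best_range[2L]] + 1
    }
  }
  out
}

#' Convert an MLPA peak ratio to the LRR scale
#'
#' `log2(ratio)`; a zero ratio (complete absence) maps to a configurable
#' floor with a warning rather than `-Inf`.
#'
#' @param ratio Peak ratio(s), >= 0.
#' @param floor Value substituted for ratio 0 (default -5).
#' @return LRR-scale value(s).
#' @export
mlpa_to_lrr <- function(ratio, floor = -5) {
  stopifnot(all(is.finite(ratio)), all(ratio >= 0))
  out <- suppressWarnings(log2(ratio))
  if (any(ratio == 0)) {
    warning("peak ratio 0 floored at ", floor, " on the LRR scale")
    out[ratio == 0] <- floor
  }
  out
}

#' MLPA gene calls for one sample across the kit
#'
#' @param ratios Long data frame `sample_id, probe_id, gene, pos, peak_ratio`
#'   for one sample.
#' @param thresholds An [mlpa_thresholds].
#' @param min_adjacent Adjacency rule (default 2).
#' @return Data frame of per-gene MLPA calls.
#' @export
mlpa_calls_sample <- function(ratios, thresholds = mlpa_thresholds(),
                              min_adjacent = 2) {
  out <- lapply(split(ratios, ratios$gene), call_gene_mlpa,
                thresholds = thresholds, min_adjacent = min_adjacent)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
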