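#' Read a wide LRR matrix
#'
#' Columns: `probe_id`, `chrom`, `pos`, then one column per sample.
#'
#' @param path TSV path.
#' @return Data frame in file order.
#' @export
read_lrr_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(d))) {
    stop("LRR matrix must have columns ", paste(need, collapse = ", "))
  }
  if (ncol(d) <= 3L) stop("LRR matrix contains no sample columns")
  d
}

#' Read long MLPA peak-ratio measurements
#'
#' Columns: `sample_id`, `probe_id`, `gene`, `exon_label`, `pos`,
#' `peak_ratio`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_mlpa_ratios <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "probe_id", "gene", "peak_ratio")
  if (!all(need %in% names(d))) {
    stop("MLPA table must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(d$peak_ratio) | d$peak_ratio < 0)) {
    stop("peak ratios must be finite and >= 0")
  }
  d
}

#' Build per-chromosome LRR profiles for one sample
#'
#' @param lrr Wide LRR matrix (see [read_lrr_matrix()]).
#' @param sample_id Sample column to extract.
#' @param probes Optional probe map supplying `gc_fraction`.
#' @return Named list of [array_profile]s keyed by chromosome.
#' @export
profiles_for_sample <- function(lrr, sample_id, probes = NULL) {
  if (!sample_id %in% names(lrr)) stop("sample not in LRR matrix: ", sample_id)
  gc_map <- NULL
  if (!is.null(probes) && "gc_fraction" %in% names(probes)) {
    gc_map <- stats::setNames(probes$gc_fraction, probes$probe_id)
  }
  out <- lapply(split(seq_len(nrow(lrr)), lrr$chrom), function(idx) {
    idx <- idx[order(lrr$pos[idx])]
    array_profile(sample_id, lrr$chrom[idx[1L]], lrr$pos[idx],
                  lrr[[sample_id]][idx], probe_id = lrr$probe_id[idx],
                  gc_fraction = if (is.null(gc_map)) NULL else
                    unname(gc_map[lrr$probe_id[idx]]))
  })
  out
}
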