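#' Circular binary segmentation of Log R Ratio profiles
#'
#' A from-scratch implementation of canonical CBS: the change-point statistic
#' is the two-sample t statistic comparing a circular arc of the probe
#' sequence against its complement, maximised over all arcs; significance of
#' the maximal arc is assessed against a permutation reference distribution;
#' accepted splits are applied recursively to the sub-vectors. The
#' hybrid/tail approximations used by production implementations to speed up
#' the permutation step are deliberately omitted — at the per-gene scale of
#' this analysis the full permutation null is affordable and exact in
#' distribution.
#'
#' @name segmentation
NULL

#' Construct an array LRR profile
#'
#' One sample on one chromosome: ordered probe positions and one Log R Ratio
#' (log2 observed/expected intensity) per probe.
#'
#' @param sample_id Sample identifier.
#' @param chrom Chromosome label.
#' @param pos Strictly increasing probe positions (0-based).
#' @param lrr Finite LRR values, one per probe.
#' @param probe_id Optional probe identifiers.
#' @param gc_fraction Optional per-probe GC fraction in \[0, 1\].
#' @return List with class `array_profile`.
#' @export
array_profile <- function(sample_id, chrom, pos, lrr, probe_id = NULL,
                          gc_fraction = NULL) {
  stopifnot(length(pos) == length(lrr))
  if (length(pos) && any(diff(pos) <= 0)) {
    stop("probe positions must be strictly increasing")
  }
  if (!all(is.finite(lrr))) stop("LRR values must be finite")
  if (!is.null(gc_fraction)) {
    stopifnot(length(gc_fraction) == length(lrr))
  }
  structure(list(sample_id = sample_id, chrom = chrom, pos = as.numeric(pos),
                 lrr = as.numeric(lrr), probe_id = probe_id,
                 gc_fraction = gc_fraction),
            class = "array_profile")
}

#' Segmentation parameters
#'
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param nperm Number of permutations for the reference distribution
#'   (default 10000; minimum 100).
#' @param min_markers Minimum probes an emitted event must span (default 5,
#'   the detection cut-off; enforced as a post-acceptance filter, not inside
#'   the arc search).
#' @param seed RNG seed; one seeded generator per segmentation call.
#' @param baseline_ploidy Copies at LRR 0 (default 2, diploid).
#' @return List with class `segmentation_params`.
#' @export
segmentation_params <- function(alpha = 0.01, nperm = 10000, min_markers = 5,
                                seed = 1, baseline_ploidy = 2) {
  stopifnot(alpha > 0, alpha < 1, nperm >= 100, min_markers >= 2)
  structure(list(alpha = alpha, nperm = as.integer(nperm),
                 min_markers = as.integer(min_markers),
                 seed = as.integer(seed), baseline_ploidy = baseline_ploidy),
            class = "segmentation_params")
}

#' GC-covariate correction of an LRR profile
#'
#' Regresses LRR on the per-probe GC fraction (ordinary least squares) and
#' replaces the LRR vector by the residuals re-centred to the input median,
#' removing the GC wave while preserving the profile's overall level. With
#' zero GC variance the regression is degenerate and the input is returned
#' unchanged with a warning.
#'
#' @param profile An [array_profile] carrying `gc_fraction`.
#' @return Corrected `array_profile`.
#' @export
gc_correct <- function(profile) {
  stopifnot(inherits(profile, "array_profile"))
  gc <- profile$gc_fraction
  if (is.null(gc) || anyNA(gc)) stop("gc_correct requires gc_fraction on every probe")
  if (length(profile$lrr) < 10L) stop("gc_correct requires >= 10 probes")
  if (stats::var(gc) == 0) {
    warning("GC fraction has zero variance; returning profile unchanged")
    return(profile)
  }
  fit <- stats::lm(profile$lrr ~ gc)
  profile$lrr <- as.numeric(stats::residuals(fit)) + stats::median(profile$lrr)
  profile
}

#' Arc-vs-complement t statistic
#'
#' For boundary indices `0 <= i < j <= n` the arc is `values[(i+1):j]` (in
#' 1-based R indexing) and the complement is the rest of the vector. Returns
#' `|mean(arc) - mean(comp)| / (s * sqrt(1/k + 1/(n-k)))` with `s` the pooled
#' standard deviation; 0 when both the pooled variance and the mean
#' difference vanish, `Inf` for a perfect zero-variance split.
#'
#' @param values Numeric vector.
#' @param i,j Boundary indices (0-based), `0 <= i < j <= n`,
#'   `1 <= j - i <= n - 1`.
#' @return The statistic (non-negative, possibly `Inf`).
#' @export
arc_statistic <- function(values, i, j) {
  n <- length(values)
  stopifnot(i >= 0, j > i, j <= n)
  if (j - i >= n) stop("arc must be a proper subset of the vector")
  arc <- values[(i + 1):j]
  comp <- values[-((i + 1):j)]
  k <- length(arc)
  diff <- abs(mean(arc) - mean(comp))
  ss <- sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)
  scale <- max(sum(values^2), 1)
  if (n <= 2 || ss < 1e-12 * scale) {
    if (diff <= 1e-12 * (1 + abs(mean(arc)))) return(0)
    return(Inf)
  }
  s2 <- ss / (n - 2)
  diff / sqrt(s2 * (1 / k + 1 / (n - k)))
}

#' Maximal arc of a vector
#'
#' Exhaustive scan of [arc_statistic] over all admissible arcs. The
#' statistic is symmetric under exchanging an arc with its complement, so
#' boundary arcs `(i, n)` (the same probe partition as `(0, i)`) are scored
#' once, under the canonical `j < n` parametrization; ties are broken toward
#' the smallest `i`, then the smallest `j`.
#'
#' @param values Numeric vector of length >= 2.
#' @return List with `i`, `j` (0-based boundaries) and `t_max`.
#' @export
max_arc <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to search for an arc")
  .cbs_scan(as.numeric(values))
}

#' Permutation p-value for an observed maximal arc statistic
#'
#' Shuffles the vector `nperm` times, rescans for the maximal arc statistic,
#' and returns `(1 + #{T_perm >= T_obs}) / (nperm + 1)`. Deterministic given
#' the seed.
#'
#' @param values Numeric vector.
#' @param t_obs Observed maximal statistic (>= 0).
#' @param nperm Number of permutations.
#' @param seed Optional seed; when `NULL` the current RNG state is used
#'   (the parent segmentation call seeds once).
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(values, t_obs, nperm = 10000, seed = NULL) {
  stopifnot(t_obs >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (t_obs == 0) return(1)
  count <- .cbs_perm_count(as.numeric(values), t_obs, as.integer(nperm))
  (1 + count) / (nperm + 1)
}

#' Segment an LRR profile by circular binary segmentation
#'
#' Recursively finds the maximal arc and accepts the split when its
#' permutation p-value is below `alpha`; the minimum-marker detection
#' cut-off is applied after acceptance, not inside the arc search: a
#' significant arc leaving fewer than `min_markers` probes on either side of
#' the split is not emitted as an event, and any residual segment shorter
#' than `min_markers` is merged into the neighbouring segment with the
#' closer mean. The returned segments always partition the probe range and
#' carry the arithmetic mean of their LRR values;
#' `copy_value = baseline_ploidy * 2^mean_lrr`.
#'
#' @param profile An [array_profile].
#' @param params A [segmentation_params].
#' @return Data frame with one row per segment: `sample_id`, `chrom`,
#'   `start_idx`, `end_idx` (0-based half-open probe indices), `start_pos`,
#'   `end_pos`, `n_markers`, `mean_lrr`, `copy_value`.
#' @export
cbs_segment <- function(profile, params = segmentation_params()) {
  stopifnot(inherits(profile, "array_profile"))
  x <- profile$lrr
  n <- length(x)
  if (n == 0L) stop("cannot segment an empty profile")
  set.seed(params$seed)
  breaks <- sort(unique(c(0L, n, .cbs_find_breaks(x, 0L, n, params))))
  segs <- .segments_from_breaks(x, breaks)
  segs <- .merge_short_segments(x, segs, params$min_markers)
  pos <- profile$pos
  data.frame(
    sample_id = profile$sample_id,
    chrom = profile$chrom,
    start_idx = segs$start_idx,
    end_idx = segs$end_idx,
    start_pos = pos[segs$start_idx + 1L],
    end_pos = pos[segs$end_idx] + 1,
    n_markers = segs$end_idx - segs$start_idx,
    mean_lrr = segs$mean_lrr,
    copy_value = params$baseline_ploidy * 2^segs$mean_lrr,
    stringsAsFactors = FALSE
  )
}

# recursive breakpoint search on x[(lo+1):hi] (0-based half-open [lo, hi))
.cbs_find_breaks <- function(x, lo, hi, params) {
  m <- hi - lo
  if (m < 2L) return(integer(0))
  sub <- x[(lo + 1L):hi]
  sc <- .cbs_scan(sub)
  if (sc$t_max == 0) return(integer(0))
  p <- permutation_pvalue(sub, sc$t_max, params$nperm, seed = NULL)
  if (p >= params$alpha) return(integer(0))
  # detection cut-off: a significant arc below min_markers probes (on either
  # side of the split) is not emitted as an event
  k <- sc$j - sc$i
  if (min(k, m - k) < params$min_markers) return(integer(0))
  cuts <- unique(c(sc$i, sc$j))
  cuts <- cuts[cuts > 0L & cuts < m]
  if (length(cuts) == 0L) return(integer(0))
  bounds <- c(0L, sort(cuts), m)
  out <- lo + cuts
  for (b in seq_len(length(bounds) - 1L)) {
    out <- c(out, .cbs_find_breaks(x, lo + bounds[b], lo + bounds[b + 1L], params))
  }
  out
}

.segments_from_breaks <- function(x, breaks) {
  s <- breaks[-length(breaks)]
  e <- breaks[-1L]
  data.frame(start_idx = as.integer(s), end_idx = as.integer(e),
             mean_lrr = vapply(seq_along(s),
                               function(k) mean(x[(s[k] + 1L):e[k]]), 0))
}

# minimum-marker detection cut-off: merge sub-threshold segments into the
# neighbour with the closer mean (ties toward the left neighbour)
.merge_short_segments <- function(x, segs, min_markers) {
  repeat {
    len <- segs$end_idx - segs$start_idx
    if (nrow(segs) <= 1L || all(len >= min_markers)) break
    k <- which(len < min_markers)
    k <- k[which.min(len[k])][1L]
    if (k == 1L) {
      into <- 2L
    } else if (k == nrow(segs)) {
      into <- k - 1L
    } else {
      dl <- abs(segs$mean_lrr[k] - segs$mean_lrr[k - 1L])
      dr <- abs(segs$mean_lrr[k] - segs$mean_lrr[k + 1L])
      into <- if (dl <= dr) k - 1L else k + 1L
    }
    lo <- min(segs$start_idx[k], segs$start_idx[into])
    hi <- max(segs$end_idx[k], segs$end_idx[into])
    keep <- segs[-k, , drop = FALSE]
    row <- which(keep$start_idx == segs$start_idx[into] &
                   keep$end_idx == segs$end_idx[into])
    keep$start_idx[row] <- lo
    keep$end_idx[row] <- hi
    keep$mean_lrr[row] <- mean(x[(lo + 1L):hi])
    segs <- keep[order(keep$start_idx), , drop = FALSE]
    rownames(segs) <- NULL
  }
  segs
}
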