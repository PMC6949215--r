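#' Genomic intervals, probe maps and coverage queries
#'
#' Coordinates are 0-based, half-open (BED convention) everywhere inside the
#' package. Intervals are plain data frames with columns `chrom`, `start`,
#' `end` and optionally `name`; probe maps additionally carry `probe_id` and,
#' for array probes, an optional `gc_fraction` column. Copy number is
#' strand-symmetric, so strand is ignored throughout.
#'
#' @name genomic-model
NULL

#' Construct a genomic interval
#'
#' @param chrom Chromosome label (non-empty string).
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `end > start`.
#' @param name Optional feature name.
#' @return A one-row data frame with class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, name = NA_character_) {
  stopifnot(is.character(chrom), nzchar(chrom))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(end <= start)) {
    stop("interval end must be strictly greater than start (0-based half-open)")
  }
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", "data.frame")
  out
}

#' Read a BED file of intervals
#'
#' Expects >= 3 tab-separated columns (`chrom`, `start`, `end`, optionally
#' `name`). Input is taken as 0-based half-open unless `one_based = TRUE`, in
#' which case 1-based inclusive coordinates are converted on read
#' (`start - 1`, `end` unchanged).
#'
#' @param path Path to a BED file.
#' @param one_based Declare the file's coordinates as 1-based inclusive.
#' @return Data frame of intervals in file order.
#' @export
read_bed <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(genomic_interval("chrNA", 0, 1)[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L],
         ": expected >= 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1L],
         ": non-numeric coordinates")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  if (one_based) start <- start - 1
  bad <- which(end <= start)
  if (length(bad)) {
    stop("invalid interval at line ", bad[1L], ": end <= start")
  }
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", "data.frame")
  out
}

#' Write intervals to a BED file
#'
#' @param x Interval data frame (`chrom`, `start`, `end`, optional `name`).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  stopifnot(all(cols %in% names(x)))
  df <- x[, c(cols, intersect("name", names(x)))]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

assert_sorted_probes <- function(probes) {
  stopifnot(all(c("chrom", "start") %in% names(probes)))
  ord <- order(probes$chrom, probes$start)
  if (!identical(ord, seq_len(nrow(probes)))) {
    stop("probe map must be sorted by (chrom, start)")
  }
  if (anyDuplicated(probes$probe_id)) {
    stop("probe ids must be unique within a map")
  }
  invisible(probes)
}

#' Probes falling inside an interval
#'
#' A probe is inside the interval when its start position lies in
#' `[start, end)` on the same chromosome.
#'
#' @param interval One-row interval data frame.
#' @param probes Probe map sorted by (chrom, start) with unique `probe_id`.
#' @return List with `count` and `probes` (the matching rows).
#' @export
probes_in <- function(interval, probes) {
  assert_sorted_probes(probes)
  stopifnot(nrow(interval) == 1L)
  hit <- probes$chrom == interval$chrom &
    probes$start >= interval$start &
    probes$start < interval$end
  list(count = sum(hit), probes = probes[hit, , drop = FALSE])
}

#' Probe-free gaps within a region
#'
#' Returns the maximal sub-intervals of `region`'s span longer than
#' `threshold` that contain no probe starts. With `threshold = 0` every
#' non-empty inter-probe interval is returned.
#'
#' @param region List or row with `chrom` and a `span` interval (or columns
#'   `chrom`, `start`, `end`).
#' @param probes Sorted probe map.
#' @param threshold Minimum gap width (same units as coordinates).
#' @return Interval data frame of gaps (possibly empty).
#' @export
coverage_gaps <- function(region, probes, threshold = 10000) {
  span <- region_span(region)
  stopifnot(span$end > span$start)
  inside <- probes_in(span, probes)$probes
  bounds <- c(span$start, sort(inside$start), span$end)
  gaps <- data.frame(chrom = span$chrom,
                     start = bounds[-length(bounds)],
                     end = bounds[-1L],
                     stringsAsFactors = FALSE)
  # a probe start occupies one base: gap to its right starts at start + 1
  if (nrow(inside) > 0L) {
    gaps$start[-1L] <- gaps$start[-1L] + 1
  }
  gaps <- gaps[gaps$end - gaps$start > threshold, , drop = FALSE]
  rownames(gaps) <- NULL
  class(gaps) <- c("genomic_interval", "data.frame")
  gaps
}

region_span <- function(region) {
  if (!is.null(region$span)) {
    span <- region$span
  } else {
    span <- region
  }
  data.frame(chrom = span$chrom[1L], start = span$start[1L], end = span$end[1L],
             stringsAsFactors = FALSE)
}

#' Assemble a gene region
#'
#' @param name Region name (one of the comparison regions).
#' @param span One-row interval covering the gene.
#' @param exons Interval data frame of exons: non-overlapping, sorted,
#'   contained in `span`.
#' @return List with class `gene_region`.
#' @export
gene_region <- function(name, span, exons) {
  stopifnot(nrow(span) == 1L)
  if (nrow(exons) > 0L) {
    stopifnot(all(exons$chrom == span$chrom),
              all(exons$start >= span$start), all(exons$end <= span$end))
    if (is.unsorted(exons$start)) stop("exons must be sorted")
    if (any(exons$start[-1L] < exons$end[-nrow(exons)])) {
      stop("exons must be non-overlapping")
    }
  }
  structure(list(name = name, chrom = span$chrom, span = span, exons = exons),
            class = "gene_region")
}
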