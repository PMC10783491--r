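#' Construct an interval set
#'
#' Interval sets are the package's universal container for genomic regions
#' (CDS annotation, repeat masks, planted-truth regions, difficult regions).
#' Coordinates are 0-based half-open throughout the package: an interval
#' `[start, end)` covers `end - start` bases, matching BED semantics.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `start < end` required.
#' @param name optional character vector of per-record labels.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (and `name` if
#'   given), sorted by `(chrom, start)`.
#' @examples
#' intervals("chr1", c(10, 40), c(20, 60))
#' @export
intervals <- function(chrom, start, end, name = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start), length(end))
  if (n > 0L) {
    chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  }
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L)) {
    stop("interval coordinates must be non-negative integers")
  }
  if (any(start >= end)) stop("intervals require start < end")
  iv <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) iv$name <- rep_len(as.character(name), n)
  sort_intervals(iv)
}

sort_intervals <- function(iv) {
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Merge overlapping intervals
#'
#' Collapses overlapping (or bookended) records into their union, per
#' chromosome and, when a `name` column is present, per label.
#'
#' @param iv an interval set from [intervals()] or [read_bed()].
#' @return A merged, sorted interval set.
#' @export
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  by_name <- !is.null(iv$name)
  key <- if (by_name) paste(iv$chrom, iv$name, sep = "\r") else iv$chrom
  parts <- split(seq_len(nrow(iv)), key)
  out <- lapply(parts, function(idx) {
    r <- IRanges::reduce(IRanges::IRanges(iv$start[idx] + 1L, iv$end[idx]))
    d <- data.frame(chrom = iv$chrom[idx][1L],
                    start = IRanges::start(r) - 1L, end = IRanges::end(r),
                    stringsAsFactors = FALSE)
    if (by_name) d$name <- iv$name[idx][1L]
    d
  })
  sort_intervals(do.call(rbind, out))
}

#' Test positions for interval membership
#'
#' @param chrom chromosome of each query position.
#' @param pos 0-based position of each query.
#' @param iv an interval set.
#' @return Logical vector, `TRUE` where the position lies inside some interval.
#' @export
positions_in_intervals <- function(chrom, pos, iv) {
  out <- logical(length(pos))
  if (nrow(iv) == 0L || length(pos) == 0L) return(out)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) next
    hits <- IRanges::countOverlaps(
      IRanges::IRanges(pos[sel] + 1L, width = 1L),
      IRanges::IRanges(sub$start + 1L, sub$end))
    out[sel] <- hits > 0L
  }
  out
}

#' Total bases covered by an interval set
#' @param iv an interval set.
#' @return Integer number of bases in the union of the intervals.
#' @export
interval_bases <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  m <- merge_intervals(iv[, c("chrom", "start", "end")])
  sum(m$end - m$start)
}

#' Intersect two interval sets
#' @param a,b interval sets.
#' @return Interval set of the per-chromosome intersections.
#' @export
intersect_intervals <- function(a, b) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ra <- IRanges::reduce(with(a[a$chrom == ch, ], IRanges::IRanges(start + 1L, end)))
    rb <- IRanges::reduce(with(b[b$chrom == ch, ], IRanges::IRanges(start + 1L, end)))
    ri <- IRanges::intersect(ra, rb)
    if (length(ri)) {
      out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(ri) - 1L,
                              end = IRanges::end(ri), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  sort_intervals(do.call(rbind, out))
}
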