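#' Band thresholds for the difficulty score
#'
#' Percentile-score cutpoints separating the three bands: `difficult`
#' (score at or above the difficult threshold), `error_prone` (at or above
#' the error-prone threshold but below difficult) and `reliable` (below the
#' error-prone threshold). Defaults 0.93 / 0.97.
#'
#' @param error_prone,difficult thresholds, `0 < error_prone < difficult < 1`.
#' @return A list of class `"band_thresholds"`.
#' @export
band_thresholds <- function(error_prone = 0.93, difficult = 0.97) {
  stopifnot(error_prone > 0, error_prone < difficult, difficult < 1)
  structure(list(error_prone = error_prone, difficult = difficult),
            class = "band_thresholds")
}

#' Percentile-rank normalization of raw scores
#'
#' `UNMET(p) = #(raw <= raw(p)) / n` over the scored positions: a
#' non-decreasing map of the raw score onto `(0, 1]` in which, for distinct
#' scores, the top 3% of positions sit at or above 0.97. Ties share the
#' value of their highest member, so a constant input maps to all 1.0.
#'
#' @param raw numeric vector of raw classifier scores.
#' @return Numeric vector of percentile scores in `(0, 1]`.
#' @export
percentile_rank <- function(raw) {
  if (!length(raw)) return(numeric(0))
  rank(raw, ties.method = "max") / length(raw)
}

#' Assign difficulty bands
#'
#' @param unmet numeric vector of percentile scores.
#' @param thresholds a [band_thresholds()].
#' @return Factor with levels `reliable`, `error_prone`, `difficult`.
#' @export
assign_bands <- function(unmet, thresholds = band_thresholds()) {
  cut(unmet, breaks = c(-Inf, thresholds$error_prone, thresholds$difficult, Inf),
      labels = c("reliable", "error_prone", "difficult"), right = FALSE)
}

#' Extract difficult-to-sequence regions
#'
#' Maximal runs of genomically consecutive scored positions whose percentile
#' score is at or above the threshold, kept when the run reaches `min_len`
#' bases. Runs never cross chromosome boundaries or gaps in the scored
#' positions.
#'
#' @param track score track: a `data.frame` with `chrom`, `pos`, `unmet`
#'   (as carried by a fitted [unmet()] object).
#' @param min_len minimum run length in bases.
#' @param threshold percentile-score threshold.
#' @return Interval set of difficult regions.
#' @export
difficult_regions <- function(track, min_len = 50L, threshold = 0.97) {
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    hot <- sub$unmet >= threshold
    # new run at a score-state change or a gap in scored positions
    brk <- c(TRUE, diff(sub$pos) != 1L | hot[-1L] != hot[-length(hot)])
    run <- cumsum(brk)
    for (r in unique(run[hot])) {
      p <- sub$pos[run == r]
      if (length(p) >= min_len) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = p[1L], end = p[length(p)] + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  sort_intervals(do.call(rbind, out))
}

#' Compare percentile scores between two position groups
#'
#' Welch two-sample t-test on the scores of two position sets (e.g. sites
#' with recurrently filtered indels versus other indel sites). Groups whose
#' scores are all equal are compared degenerately: equal constants give
#' `t = 0, p = 1`.
#'
#' @param track score track (`chrom`, `pos`, `unmet`).
#' @param group_a,group_b `data.frame`s with `chrom` and `pos` columns.
#' @return `list(mean_a, sd_a, mean_b, sd_b, n_a, n_b, t, p)`.
#' @export
compare_score_groups <- function(track, group_a, group_b) {
  key <- paste0(track$chrom, ":", track$pos)
  pick <- function(g) {
    v <- track$unmet[match(paste0(g$chrom, ":", g$pos), key)]
    v[!is.na(v)]
  }
  a <- pick(group_a); b <- pick(group_b)
  if (!length(a) || !length(b)) stop("both groups must contain scored positions")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    t <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    ht <- stats::t.test(a, b)            # Welch by default
    t <- unname(ht$statistic); p <- ht$p.value
  }
  list(mean_a = mean(a), sd_a = stats::sd(a), mean_b = mean(b),
       sd_b = stats::sd(b), n_a = length(a), n_b = length(b), t = t, p = p)
}

#' Split indel positions into recurrently-filtered and other groups
#'
#' Group A holds positions carrying two or more filtered indel records;
#' group B holds every other position with at least one indel record.
#'
#' @param sites variant-site table.
#' @return `list(recurrent, other)` of position `data.frame`s.
#' @export
select_indel_groups <- function(sites) {
  ind <- sites[sites$class == "indel", , drop = FALSE]
  if (!nrow(ind)) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        stringsAsFactors = FALSE)
    return(list(recurrent = empty, other = empty))
  }
  key <- paste0(ind$chrom, ":", ind$pos)
  n_filt <- tapply(ind$status == "filtered", key, sum)
  upos <- ind[!duplicated(key), c("chrom", "pos"), drop = FALSE]
  rec <- n_filt[paste0(upos$chrom, ":", upos$pos)] >= 2L
  rownames(upos) <- NULL
  list(recurrent = upos[rec, , drop = FALSE],
       other = upos[!rec, , drop = FALSE])
}

#' Export score and band tracks for genome browsers
#'
#' Writes `unmet.bedgraph` (percentile score per scored position),
#' `bands.bed` (BED4 runs labeled with their band; the band intervals
#' partition the scored positions) and `difficult_regions.bed`.
#'
#' @param track score track (`chrom`, `pos`, `unmet`, `band`).
#' @param outdir output directory (created if needed).
#' @param seqlens named chromosome lengths.
#' @param min_len,threshold arguments of [difficult_regions()].
#' @return Invisibly, the named vector of file paths written.
#' @export
export_tracks <- function(track, outdir, seqlens, min_len = 50L,
                          threshold = 0.97) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(unmet = file.path(outdir, "unmet.bedgraph"),
             bands = file.path(outdir, "bands.bed"),
             difficult = file.path(outdir, "difficult_regions.bed"))
  per_base <- lapply(seqlens, function(L) rep(NA_real_, L))
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, ]
    per_base[[ch]][sub$pos + 1L] <- sub$unmet
  }
  write_bedgraph(per_base, paths[["unmet"]])
  bands <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    b <- as.character(sub$band)
    brk <- c(TRUE, diff(sub$pos) != 1L | b[-1L] != b[-length(b)])
    run <- cumsum(brk)
    firsts <- which(brk)
    lasts <- c(firsts[-1L] - 1L, length(run))
    bands[[ch]] <- data.frame(chrom = ch, start = sub$pos[firsts],
                              end = sub$pos[lasts] + 1L, name = b[firsts],
                              stringsAsFactors = FALSE)
  }
  write_bed(sort_intervals(do.call(rbind, bands)), paths[["bands"]])
  write_bed(difficult_regions(track, min_len, threshold), paths[["difficult"]])
  invisible(paths)
}
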