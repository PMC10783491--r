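#' Feature extraction parameters
#'
#' Collects the tunable parameters of the sequence-derived features and the
#' site-labeling window. Defaults follow the pipeline's standard settings:
#' a 12-bp flank gives the 25-bp window shared by the variant statistics, GC
#' content and entropy; mappability uses 100-mers with up to 2 mismatches;
#' homopolymer tracts are runs of 7+ identical bases; binary repeat masks are
#' extended by 12-bp flanks; the low-complexity detector uses DUST level 30.
#'
#' @param flank_n window flank in bases; the window is `2 * flank_n + 1` wide.
#' @param map_k mappability word length K.
#' @param map_e mappability error budget E (mismatches tolerated).
#' @param homopolymer_min minimum run length of a homopolymer tract.
#' @param mask_flank flank added to homopolymer/tandem mask intervals.
#' @param dust_level low-complexity level threshold (DustMasker convention).
#' @param dust_window sliding window of the low-complexity detector.
#' @param tandem_max_period maximum repeat-unit length of the tandem detector.
#' @param tandem_min_len minimum total tandem-array length.
#' @return A list of class `"feature_params"`.
#' @export
feature_params <- function(flank_n = 12L, map_k = 100L, map_e = 2L,
                           homopolymer_min = 7L, mask_flank = 12L,
                           dust_level = 30, dust_window = 64L,
                           tandem_max_period = 25L, tandem_min_len = 12L) {
  stopifnot(flank_n >= 1L, map_k > map_e, map_e >= 0L,
            homopolymer_min >= 2L, dust_level > 0, dust_window >= 8L,
            tandem_max_period >= 2L, tandem_min_len >= 2L, mask_flank >= 0L)
  structure(list(flank_n = as.integer(flank_n), map_k = as.integer(map_k),
                 map_e = as.integer(map_e),
                 homopolymer_min = as.integer(homopolymer_min),
                 mask_flank = as.integer(mask_flank),
                 dust_level = dust_level, dust_window = as.integer(dust_window),
                 tandem_max_period = as.integer(tandem_max_period),
                 tandem_min_len = as.integer(tandem_min_len)),
            class = "feature_params")
}

#' @export
print.feature_params <- function(x, ...) {
  cat("Feature parameters:\n")
  cat(sprintf("  window: %d bp (flank N = %d)\n", 2L * x$flank_n + 1L, x$flank_n))
  cat(sprintf("  mappability: K = %d, E = %d\n", x$map_k, x$map_e))
  cat(sprintf("  homopolymer: run >= %d bp, flank %d bp\n",
              x$homopolymer_min, x$mask_flank))
  cat(sprintf("  tandem: period <= %d, array >= %d bp, flank %d bp\n",
              x$tandem_max_period, x$tandem_min_len, x$mask_flank))
  cat(sprintf("  low complexity: level %s, window %d bp\n",
              format(x$dust_level), x$dust_window))
  invisible(x)
}

# split a chromosome into a character vector of single bases
chrom_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# windowed count of a logical vector; NA within `n` of either end
windowed_count <- function(flag, n) {
  L <- length(flag)
  w <- 2L * n + 1L
  out <- rep(NA_real_, L)
  if (L < w) return(out)
  cs <- c(0, cumsum(flag))
  idx <- (n + 1L):(L - n)
  out[idx] <- cs[idx + n + 1L] - cs[idx - n]
  out
}

#' Windowed GC content
#'
#' Fraction of G or C bases in the window centered on each position. `N`
#' bases count toward the window size but never toward the GC count.
#' Positions whose window would overrun the chromosome are `NA`.
#'
#' @param genome named character vector of chromosome sequences.
#' @param params a [feature_params()] object; the window is `2*flank_n + 1` bp.
#' @return Named list of per-base numeric tracks in `[0, 1]`.
#' @export
gc_content <- function(genome, params = feature_params()) {
  w <- 2L * params$flank_n + 1L
  lapply(genome, function(seq) {
    ch <- chrom_chars(seq)
    windowed_count(ch == "G" | ch == "C", params$flank_n) / w
  })
}

#' Windowed Shannon sequence entropy
#'
#' Shannon entropy (bits) of the A/C/G/T base frequencies in the centered
#' window, with frequencies taken over the full window length (so `N` bases
#' dilute the distribution) and the convention `0 * log2(0) = 0`. Values lie
#' in `[0, 2]`; edge positions are `NA`.
#'
#' @inheritParams gc_content
#' @return Named list of per-base numeric tracks in `[0, 2]` bits.
#' @export
sequence_entropy <- function(genome, params = feature_params()) {
  w <- 2L * params$flank_n + 1L
  lapply(genome, function(seq) {
    ch <- chrom_chars(seq)
    h <- 0
    for (b in c("A", "C", "G", "T")) {
      p <- windowed_count(ch == b, params$flank_n) / w
      term <- p * log2(p)
      term[p == 0] <- 0
      h <- h - term
    }
    h
  })
}

# rasterize intervals (0-based half-open, single chromosome) with a flank
rasterize_runs <- function(starts, ends, L, flank = 0L) {
  mask <- numeric(L)
  if (length(starts)) {
    s <- pmax(starts - flank, 0L)
    e <- pmin(ends + flank, L)
    for (i in seq_along(s)) if (s[i] < e[i]) mask[(s[i] + 1L):e[i]] <- 1
  }
  mask
}

#' Homopolymer-tract mask
#'
#' Binary track marking every maximal run of one base (A, C, G or T) whose
#' length reaches `homopolymer_min`, extended by `mask_flank` bases on both
#' sides and clipped at the chromosome ends.
#'
#' @inheritParams gc_content
#' @return Named list of 0/1 tracks.
#' @export
homopolymer_mask <- function(genome, params = feature_params()) {
  lapply(genome, function(seq) {
    ch <- chrom_chars(seq)
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths          # 0-based starts
    keep <- r$lengths >= params$homopolymer_min & r$values != "N"
    rasterize_runs(starts[keep], ends[keep], length(ch), params$mask_flank)
  })
}

# maximal exact tandem arrays (period >= 2) on one chromosome;
# returns 0-based half-open (start, end) pairs
find_tandem_arrays <- function(ch, max_period, min_len) {
  L <- length(ch)
  out_s <- integer(0); out_e <- integer(0)
  for (d in 2:max_period) {
    if (L < 2L * d) break
    eq <- ch[seq_len(L - d)] == ch[(d + 1L):L] & ch[seq_len(L - d)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths          # 0-based into eq
    sel <- which(r$values & r$lengths >= d & (r$lengths + d) >= min_len)
    for (i in sel) {
      s <- starts[i]; e <- ends[i] + d  # array spans [s, e) in sequence
      # a run matching at lag d that is a single-base run belongs to the
      # homopolymer feature, not the tandem feature
      if (length(unique(ch[(s + 1L):e])) >= 2L) {
        out_s <- c(out_s, s); out_e <- c(out_e, e)
      }
    }
  }
  list(starts = out_s, ends = out_e)
}

#' Tandem-repeat mask
#'
#' Binary track over exact tandem arrays: maximal runs where the sequence
#' equals itself shifted by a period `2..tandem_max_period`, with at least two
#' full copies and total array length at least `tandem_min_len`. Pure
#' single-base runs are excluded (they belong to [homopolymer_mask()]).
#' Detected arrays (or, when `override` is given, the supplied intervals from
#' an external tandem-repeat finder) are extended by `mask_flank` bases.
#'
#' @inheritParams gc_content
#' @param override optional interval set (e.g. external TRF output as BED)
#'   that replaces the built-in detector.
#' @return Named list of 0/1 tracks.
#' @export
tandem_repeat_mask <- function(genome, params = feature_params(), override = NULL) {
  if (!is.null(override)) {
    return(mask_from_intervals(override, genome, params$mask_flank))
  }
  lapply(genome, function(seq) {
    ch <- chrom_chars(seq)
    ta <- find_tandem_arrays(ch, params$tandem_max_period, params$tandem_min_len)
    rasterize_runs(ta$starts, ta$ends, length(ch), params$mask_flank)
  })
}

# DUST-style score for every sliding window start (1-based starts into seq);
# score = sum c_t (c_t - 1) / 2 over triplet counts, / (valid triplets - 1)
dust_window_scores <- function(codes, w) {
  L <- length(codes) + 2L           # codes has L-2 entries
  k <- w - 2L                       # triplets per window
  n_win <- L - w + 1L
  scores <- numeric(n_win)
  counts <- integer(64L)
  s <- 0; valid <- 0L
  for (i in seq_len(k)) {
    c0 <- codes[i]
    if (!is.na(c0)) { s <- s + counts[c0 + 1L]; counts[c0 + 1L] <- counts[c0 + 1L] + 1L; valid <- valid + 1L }
  }
  scores[1L] <- if (valid >= 2L) s / (valid - 1L) else 0
  if (n_win >= 2L) {
    for (p in 2:n_win) {
      cout <- codes[p - 1L]
      if (!is.na(cout)) { counts[cout + 1L] <- counts[cout + 1L] - 1L; s <- s - counts[cout + 1L]; valid <- valid - 1L }
      cin <- codes[p + k - 2L]
      if (!is.na(cin)) { s <- s + counts[cin + 1L]; counts[cin + 1L] <- counts[cin + 1L] + 1L; valid <- valid + 1L }
      scores[p] <- if (valid >= 2L) s / (valid - 1L) else 0
    }
  }
  scores
}

triplet_codes <- function(ch) {
  v <- match(ch, c("A", "C", "G", "T")) - 1L   # NA for N
  L <- length(v)
  if (L < 3L) return(integer(0))
  16L * v[seq_len(L - 2L)] + 4L * v[2:(L - 1L)] + v[3:L]
}

#' Low-complexity-region mask
#'
#' Symmetric DUST-style detector: within each sliding window the triplet
#' counts `c_t` give a score `sum c_t (c_t - 1) / 2 / (k - 1)` (`k` triplets
#' per window); every position of a window whose score exceeds
#' `dust_level / 10` is masked. Level 30 masks homopolymeric and short-motif
#' sequence while leaving random 50%-GC sequence untouched.
#'
#' @inheritParams tandem_repeat_mask
#' @param override optional interval set (e.g. external DustMasker output)
#'   that replaces the detector; no flank is added to low-complexity calls.
#' @return Named list of 0/1 tracks.
#' @export
low_complexity_mask <- function(genome, params = feature_params(), override = NULL) {
  if (!is.null(override)) {
    return(mask_from_intervals(override, genome, 0L))
  }
  thr <- params$dust_level / 10
  lapply(genome, function(seq) {
    ch <- chrom_chars(seq)
    L <- length(ch)
    w <- min(params$dust_window, L)
    if (w < 4L) return(numeric(L))
    scores <- dust_window_scores(triplet_codes(ch), w)
    hot <- which(scores > thr)          # window starts, 1-based
    mask <- numeric(L)
    for (i in hot) mask[i:(i + w - 1L)] <- 1
    mask
  })
}

#' (K,E)-mappability
#'
#' For each position `p`, the number `occ(p)` of length-`K` windows anywhere
#' in the genome — on either strand — within Hamming distance `E` of the
#' window starting at `p` is counted, and the track value is `1 / occ(p)`.
#' A value of 1 means the window is unique; 0.5 means exactly one other
#' (near-)copy exists. `N` positions mismatch everything, including other
#' `N`s. The last `K - 1` positions of each chromosome, where no full window
#' starts, are `NA`.
#'
#' The search uses pigeonhole seeding (`E + 1` exact chunks) implemented in
#' C++, which is exact: any window within `E` mismatches must agree exactly
#' on at least one chunk.
#'
#' @inheritParams gc_content
#' @return Named list of per-base tracks in `(0, 1]` (with trailing `NA`s).
#' @export
mappability <- function(genome, params = feature_params()) {
  K <- params$map_k
  lens <- seq_lengths(genome)
  if (any(lens < K)) {
    stop("mappability word length K = ", K, " exceeds chromosome length for: ",
         paste(names(genome)[lens < K], collapse = ", "))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(genome)))
  occ <- mappability_occ(unname(c(genome, rc)), length(genome), K, params$map_e)
  out <- vector("list", length(genome))
  names(out) <- names(genome)
  for (i in seq_along(genome)) {
    v <- rep(NA_real_, lens[i])
    v[seq_len(lens[i] - K + 1L)] <- 1 / occ[[i]]
    out[[i]] <- v
  }
  out
}

# rasterize an interval set onto the genome as a per-base 0/1 mask
mask_from_intervals <- function(iv, genome, flank = 0L) {
  lens <- seq_lengths(genome)
  out <- lapply(names(genome), function(ch) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    rasterize_runs(sub$start, sub$end, lens[[ch]], flank)
  })
  names(out) <- names(genome)
  out
}
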