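#' Standardize a coverage track per chromosome
#'
#' Converts raw depth to absolute z-values, `|depth - mean| / sd`, with mean
#' and standard deviation computed per chromosome over its defined positions
#' (population standard deviation: the whole-chromosome track is the
#' population). Per-chromosome standardization absorbs systematic depth
#' differences between chromosomes.
#'
#' @param track named list of per-base depth vectors (`NA` = missing).
#' @return Named list of per-base absolute z-value vectors.
#' @export
standardize_coverage <- function(track) {
  out <- lapply(names(track), function(ch) {
    v <- track[[ch]]
    ok <- !is.na(v)
    if (sum(ok) < 2L) stop("coverage track too short to standardize on ", ch)
    m <- mean(v[ok])
    s <- sqrt(mean((v[ok] - m)^2))           # population sd
    if (s == 0) stop("zero coverage variance on ", ch)
    abs(v - m) / s
  })
  names(out) <- names(track)
  out
}

#' Rasterize annotation intervals as a per-base mask
#'
#' Binary per-base track from a BED-sourced interval set (interspersed
#' repeats, segmental duplications, structural variants, ...), optionally
#' flank-extended; overlapping intervals collapse to their union.
#'
#' @param iv interval set.
#' @param genome named sequence vector defining chromosome lengths.
#' @param flank bases added on both sides of each interval.
#' @return Named list of 0/1 tracks.
#' @export
annotation_mask <- function(iv, genome, flank = 0L) {
  mask_from_intervals(iv, genome, flank)
}

unmet_feature_names <- c("coverage_z", "mappability", "homopolymer", "tandem",
                         "repeatmasker", "segdup", "lcr", "sv", "gc", "entropy")

#' Compute all ten per-base feature tracks
#'
#' Convenience wrapper producing the named list of tracks the feature matrix
#' is assembled from: standardized coverage, (K,E)-mappability, homopolymer,
#' tandem-repeat, interspersed-repeat, segmental-duplication,
#' low-complexity and structural-variant masks, GC content and sequence
#' entropy.
#'
#' @param genome named sequence vector.
#' @param coverage per-base depth track.
#' @param annotations list with interval sets `repeatmasker`, `segdup`, `sv`.
#' @param params a [feature_params()].
#' @param tandem_override,lcr_override optional interval sets replacing the
#'   built-in tandem / low-complexity detectors (e.g. external tool output).
#' @return Named list of ten per-base track lists, in the canonical feature
#'   order.
#' @export
feature_tracks <- function(genome, coverage, annotations,
                           params = feature_params(),
                           tandem_override = NULL, lcr_override = NULL) {
  empty <- intervals(character(), integer(), integer())
  get_ann <- function(nm) {
    iv <- annotations[[nm]]
    if (is.null(iv)) empty else iv
  }
  list(coverage_z = standardize_coverage(coverage),
       mappability = mappability(genome, params),
       homopolymer = homopolymer_mask(genome, params),
       tandem = tandem_repeat_mask(genome, params, tandem_override),
       repeatmasker = annotation_mask(get_ann("repeatmasker"), genome),
       segdup = annotation_mask(get_ann("segdup"), genome),
       lcr = low_complexity_mask(genome, params, lcr_override),
       sv = annotation_mask(get_ann("sv"), genome),
       gc = gc_content(genome, params),
       entropy = sequence_entropy(genome, params))
}

#' Assemble the per-position feature matrix
#'
#' One row per requested position with the ten feature columns in the fixed
#' order `coverage_z, mappability, homopolymer, tandem, repeatmasker,
#' segdup, lcr, sv, gc, entropy`. Positions at which any feature is
#' undefined (chromosome-end windows, missing coverage) are dropped, and the
#' number dropped is reported via a message.
#'
#' @param chrom,pos chromosome and 0-based position of each requested row;
#'   alternatively `chrom` may be an interval set, in which case every base
#'   it covers is requested.
#' @param tracks list of ten per-base track lists from [feature_tracks()].
#' @return A numeric matrix with rownames `chrom:pos` (0-based) and one
#'   column per feature; complete rows only.
#' @export
assemble_feature_matrix <- function(chrom, pos = NULL, tracks) {
  if (is.data.frame(chrom)) {
    iv <- chrom
    pos <- unlist(lapply(seq_len(nrow(iv)),
                         function(i) iv$start[i]:(iv$end[i] - 1L)))
    chrom <- rep.int(iv$chrom, iv$end - iv$start)
  }
  stopifnot(length(chrom) == length(pos),
            identical(names(tracks), unmet_feature_names))
  m <- matrix(NA_real_, nrow = length(pos), ncol = length(tracks),
              dimnames = list(paste0(chrom, ":", pos), unmet_feature_names))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      m[sel, j] <- tr[[ch]][pos[sel] + 1L]
    }
  }
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    message(sum(!complete), " position(s) dropped: undefined feature values")
  }
  m[complete, , drop = FALSE]
}
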