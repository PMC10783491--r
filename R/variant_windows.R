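#' Windowed variant statistics (VD and VFR)
#'
#' For each query position, counts the variant records whose position falls
#' in the closed window `[pos - N, pos + N]` on the same chromosome and
#' derives the two window statistics:
#'
#' * variant density `VD = n_variants / (2N + 1)` — the denominator is the
#'   full window width even when the window overhangs a chromosome end;
#' * variant filter rate `VFR = n_filtered / n_variants`, `NA` when the
#'   window holds no variants.
#'
#' Counting is per variant record (one row per alternate allele), so a
#' biallelic position contributes two to `n_variants`. As the canonical
#' worked example: a 25-bp window holding 8 variants of which 2 are filtered
#' has `VD = 8/25 = 0.32` and `VFR = 2/8 = 0.25`.
#'
#' @param sites variant-site table from [read_vcf_sites()].
#' @param chrom,pos chromosome and 0-based position of each query (recycled
#'   to a common length).
#' @param n window flank N in bases (window width `2N + 1`).
#' @return A `data.frame` with columns `chrom`, `pos`, `n_variants`,
#'   `n_filtered`, `vd`, `vfr`.
#' @export
window_stats <- function(sites, chrom, pos, n = 12L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  len <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), len)
  pos <- rep_len(as.integer(pos), len)
  w <- 2L * n + 1L
  n_var <- integer(len)
  n_fil <- integer(len)
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    sp <- sort(sites$pos[sites$chrom == ch])
    fp <- sort(sites$pos[sites$chrom == ch & sites$status == "filtered"])
    # closed window [pos-n, pos+n]
    n_var[qi] <- findInterval(pos[qi] + n, sp) - findInterval(pos[qi] - n - 1L, sp)
    n_fil[qi] <- findInterval(pos[qi] + n, fp) - findInterval(pos[qi] - n - 1L, fp)
  }
  vfr <- ifelse(n_var > 0L, n_fil / n_var, NA_real_)
  data.frame(chrom = chrom, pos = pos, n_variants = n_var, n_filtered = n_fil,
             vd = n_var / w, vfr = vfr, stringsAsFactors = FALSE)
}

#' Label reliable and unreliable variant-call sites
#'
#' Applies the ground-truth labeling rule to every SNV site inside the CDS
#' intervals: a position is labeled `unreliable` (positive) when its window
#' has `VFR = 1.0` and `VD >= vd_min` (so the focal variant itself is
#' filtered), and `reliable` (negative) when the window has `VFR = 0.0` and
#' `VD >= vd_min` (focal variant passed). With the default 25-bp window,
#' `vd_min = 0.12` requires at least three observed variants. All other
#' sites stay unlabeled; indel sites never receive labels (they are held out
#' for evaluation) although their records still count inside windows, as do
#' variants in exon flanks outside the CDS.
#'
#' Labels attach to positions: multiple alleles at one position share one
#' window and therefore one label, and duplicate positions are collapsed.
#'
#' @param sites variant-site table.
#' @param cds CDS interval set; only positions inside it are labeled.
#' @param n window flank N.
#' @param vd_min minimum variant density for either label.
#' @return A `data.frame` of labeled positions: `chrom`, `pos`, `label`
#'   (`"unreliable"`/`"reliable"`), plus the window statistics columns.
#' @export
label_sites <- function(sites, cds, n = 12L, vd_min = 0.12) {
  if (nrow(cds) == 0L) stop("label_sites requires a non-empty CDS interval set")
  snv <- sites[sites$class == "snv", , drop = FALSE]
  snv <- snv[!duplicated(paste(snv$chrom, snv$pos)), , drop = FALSE]
  keep <- positions_in_intervals(snv$chrom, snv$pos, cds)
  snv <- snv[keep, , drop = FALSE]
  if (nrow(snv) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), label = character(),
                      n_variants = integer(), n_filtered = integer(),
                      vd = numeric(), vfr = numeric(), stringsAsFactors = FALSE))
  }
  st <- window_stats(sites, snv$chrom, snv$pos, n)
  dense <- !is.na(st$vfr) & st$vd >= vd_min
  label <- rep(NA_character_, nrow(st))
  label[dense & st$vfr == 1] <- "unreliable"
  label[dense & st$vfr == 0] <- "reliable"
  out <- cbind(st[, c("chrom", "pos")], label = label,
               st[, c("n_variants", "n_filtered", "vd", "vfr")])
  out <- out[!is.na(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a variant catalog over CDS positions
#'
#' Descriptive counts of CDS positions by variant content: none, passed
#' variants only, filtered only, or mixed (both statuses at one position).
#'
#' @param sites variant-site table.
#' @param cds CDS interval set.
#' @return A `data.frame` with one row per category (`positions`, `fraction`
#'   of all CDS bases).
#' @export
catalog_summary <- function(sites, cds) {
  total <- interval_bases(cds)
  inside <- sites[positions_in_intervals(sites$chrom, sites$pos, cds), , drop = FALSE]
  key <- paste(inside$chrom, inside$pos)
  has_pass <- tapply(inside$status == "passed", key, any)
  has_filt <- tapply(inside$status == "filtered", key, any)
  n_pos <- length(has_pass)
  counts <- c(
    no_variant = total - n_pos,
    passed_only = if (n_pos) sum(has_pass & !has_filt) else 0L,
    filtered_only = if (n_pos) sum(!has_pass & has_filt) else 0L,
    mixed = if (n_pos) sum(has_pass & has_filt) else 0L)
  data.frame(category = names(counts), positions = as.integer(counts),
             fraction = if (total > 0) as.numeric(counts) / total else rep(0, 4L),
             stringsAsFactors = FALSE, row.names = NULL)
}
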