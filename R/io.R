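#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and any symbol outside `{A,C,G,T,N}` is replaced
#' by `N` (with a warning reporting how many symbols were replaced). The
#' result is the package's genome container: a named character vector, one
#' uppercase sequence per chromosome.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  genome <- toupper(as.character(ss))
  names(genome) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(genome))) stop("duplicate chromosome names in ", path)
  n_bad <- sum(vapply(genome, function(s) {
    nchar(s) - sum(charToRaw(s) %in% charToRaw("ACGTN"))
  }, integer(1)))
  if (n_bad > 0L) {
    warning(n_bad, " non-ACGTN symbol(s) replaced by N")
    genome <- vapply(genome, function(s) {
      r <- charToRaw(s)
      r[!(r %in% charToRaw("ACGTN"))] <- charToRaw("N")
      rawToChar(r)
    }, character(1))
  }
  genome
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}

seq_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

#' Read variant sites from a VCF
#'
#' Each VCF record is split per alternate allele into one variant-site row.
#' FILTER values of `PASS` or `.` map to status `passed`; any other value
#' (for example `AC0;AS_VQSR`) maps to `filtered`, the binary dichotomy the
#' labeling stage consumes. VCF 1-based positions are converted to the
#' package's 0-based convention on the way in.
#'
#' @param path path to a VCF (uncompressed or bgzipped).
#' @param region_set interval set restricting which sites are kept
#'   (typically exons with flanks); required and non-empty.
#' @param seqlens optional named integer vector of chromosome lengths; when
#'   given, records outside the genome raise an error.
#' @return A `data.frame` with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `class` (`"snv"` or `"indel"`) and `status` (`"passed"` or
#'   `"filtered"`), sorted by position.
#' @export
read_vcf_sites <- function(path, region_set, seqlens = NULL) {
  if (missing(region_set) || nrow(region_set) == 0L) {
    stop("read_vcf_sites requires a non-empty region_set")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    return(variant_sites(character(), integer(), character(), character(), character()))
  }
  if (!"FILTER" %in% colnames(fix)) stop("VCF is missing the FILTER column")
  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."               # vcfR parses '.' as NA
  if (any(filt == "")) stop("VCF record with empty FILTER value")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"]) - 1L  # VCF 1-based -> internal 0-based
  ref <- fix[, "REF"]
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  sites <- variant_sites(
    chrom = chrom[idx], pos = pos[idx], ref = ref[idx],
    alt = unlist(alts, use.names = FALSE),
    status = ifelse(filt[idx] %in% c("PASS", "."), "passed", "filtered"))
  if (!is.null(seqlens)) {
    bad <- !(sites$chrom %in% names(seqlens)) |
      sites$pos >= seqlens[sites$chrom] | sites$pos < 0L
    if (any(bad)) {
      stop("VCF record outside the genome: ", sites$chrom[which(bad)[1]],
           ":", sites$pos[which(bad)[1]] + 1L)
    }
  }
  keep <- positions_in_intervals(sites$chrom, sites$pos, region_set)
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Construct a variant-site table
#'
#' Low-level constructor used by the VCF reader and the synthetic generator.
#' Variant class is derived from the alleles: both length 1 is an SNV,
#' anything else an indel.
#'
#' @param chrom,pos,ref,alt per-site fields (`pos` 0-based).
#' @param status `"passed"` or `"filtered"` per site.
#' @return Sorted variant-site `data.frame`.
#' @export
variant_sites <- function(chrom, pos, ref, alt, status) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   status = as.character(status), stringsAsFactors = FALSE)
  if (nrow(df) && !all(df$status %in% c("passed", "filtered"))) {
    stop("status must be 'passed' or 'filtered'")
  }
  df$class <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "snv", "indel")
  df <- df[order(df$chrom, df$pos, df$alt), c("chrom", "pos", "ref", "alt",
                                              "class", "status")]
  rownames(df) <- NULL
  df
}

#' Write variant sites as VCF
#' @param sites variant-site table.
#' @param path output path.
#' @param seqlens named chromosome lengths for the header contig lines.
#' @export
write_vcf_sites <- function(sites, path, seqlens = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(seqlens)) {
             sprintf("##contig=<ID=%s,length=%d>", names(seqlens), seqlens)
           },
           "##FILTER=<ID=lowqual,Description=\"Failed variant quality filters\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.",
                  sites$chrom, sites$pos + 1L, sites$ref, sites$alt,
                  ifelse(sites$status == "passed", "PASS", "lowqual"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED file as an interval set
#'
#' BED3 or BED4 (the fourth column becomes the `name` field). BED is already
#' 0-based half-open, matching the internal convention, so coordinates pass
#' through unchanged.
#'
#' @param path path to a BED file.
#' @return Sorted interval set.
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#"),
    error = function(e) stop("malformed BED file ", path, ": ", conditionMessage(e)))
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  intervals(as.character(df[[1]]), df[[2]], df[[3]],
            name = if (ncol(df) >= 4L) as.character(df[[4]]) else NULL)
}

#' Write an interval set as BED
#' @param iv interval set.
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  iv <- sort_intervals(iv)
  cols <- c("chrom", "start", "end", if (!is.null(iv$name)) "name")
  utils::write.table(iv[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-base coverage track from bedGraph
#'
#' The bedGraph must be sorted and non-overlapping per chromosome; positions
#' not covered by any line are `NA` (explicitly missing, not zero).
#'
#' @param path path to a 4-column bedGraph.
#' @param seqlens named integer vector of chromosome lengths, which fixes the
#'   length of each per-base vector.
#' @return Named list of per-base numeric depth vectors.
#' @export
read_coverage <- function(path, seqlens) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"),
                          stringsAsFactors = FALSE)
  track <- lapply(seqlens, function(L) rep(NA_real_, L))
  for (ch in unique(df$chrom)) {
    if (!ch %in% names(seqlens)) stop("bedGraph chromosome not in genome: ", ch)
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (is.unsorted(sub$start) || any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("bedGraph is unsorted or overlapping on ", ch)
    }
    if (any(sub$end > seqlens[[ch]])) stop("bedGraph interval beyond end of ", ch)
    for (i in seq_len(nrow(sub))) {
      track[[ch]][(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    }
  }
  track
}

#' Write a per-base track as bedGraph
#'
#' Runs of equal values are collapsed into single lines; `NA` positions are
#' omitted from the file.
#'
#' @param track named list of per-base numeric vectors.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    v <- track[[ch]]
    r <- rle(ifelse(is.na(v), "NA", format(v, digits = 10, trim = TRUE, scientific = FALSE)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != "NA"
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}
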