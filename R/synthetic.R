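#' Configuration of the synthetic study system
#'
#' The generator emulates the empirical structure the pipeline is built
#' around: a genome carrying difficult-to-sequence features (exact segmental
#' duplications, tandem arrays, homopolymer runs, GC-extreme windows and
#' structural-variant regions), a variant catalog whose filter flags are
#' strongly enriched inside those regions, and a coverage track depressed
#' there. Defaults define the package's standard bundle: two 50-kb
#' chromosomes with plants covering roughly 9% of the genome, a variant
#' record rate of 0.2/bp (the scale at which a 25-bp window typically holds
#' around five records), filter probabilities 0.95 inside / 0.02 outside
#' difficult regions, and 30x Gaussian coverage halved inside them.
#'
#' @param seed integer seed; the same seed reproduces every output byte for
#'   byte. Per-stage sub-seeds are derived from it by fixed small offsets.
#' @param n_chrom,chrom_length chromosome count and length (bp).
#' @param segdup_n,segdup_len number of duplication pairs and copy length.
#' @param tandem_n,tandem_period,tandem_len tandem arrays: count, repeat-unit
#'   length, total array length.
#' @param homopolymer_n,homopolymer_len homopolymer runs: count and length.
#' @param gc_n,gc_len,gc_low,gc_high GC-extreme windows: count per extreme,
#'   window length, and the low/high GC fractions used to draw them.
#' @param sv_n,sv_len structural-variant regions (annotation-only plants).
#' @param variant_rate expected variant records per bp (Poisson).
#' @param indel_fraction fraction of variant records drawn as 1-3 bp indels.
#' @param p_diff,p_bg per-variant filter probability inside / outside planted
#'   difficult regions; `0 <= p_bg < p_diff <= 1`.
#' @param coverage_mean,coverage_sd,coverage_factor Gaussian depth parameters
#'   and the multiplicative depression applied inside difficult regions.
#' @param cds_exon,cds_gap exon length and inter-exon gap of the CDS tiling.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 50000L,
                             segdup_n = 2L, segdup_len = 1500L,
                             tandem_n = 4L, tandem_period = 4L, tandem_len = 60L,
                             homopolymer_n = 6L, homopolymer_len = 15L,
                             gc_n = 2L, gc_len = 500L, gc_low = 0.1, gc_high = 0.9,
                             sv_n = 2L, sv_len = 800L,
                             variant_rate = 0.2, indel_fraction = 0.1,
                             p_diff = 0.95, p_bg = 0.02,
                             coverage_mean = 30, coverage_sd = 5,
                             coverage_factor = 0.5,
                             cds_exon = 300L, cds_gap = 200L) {
  stopifnot(p_bg >= 0, p_bg < p_diff, p_diff <= 1,
            chrom_length > 0L, n_chrom >= 1L, variant_rate >= 0,
            indel_fraction >= 0, indel_fraction <= 1,
            coverage_mean > 0, coverage_sd >= 0, coverage_factor > 0,
            seed < 2^31 - 100)
  structure(as.list(environment()), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic bundle config: %d x %d bp, seed %d\n",
              x$n_chrom, x$chrom_length, x$seed))
  cat(sprintf("  plants: %d segdup pairs (%d bp), %d tandem, %d homopolymer, %d+%d GC, %d SV\n",
              x$segdup_n, x$segdup_len, x$tandem_n, x$homopolymer_n,
              x$gc_n, x$gc_n, x$sv_n))
  cat(sprintf("  variants: %.2g/bp (%.0f%% indel), filter p = %.2f in / %.2f out\n",
              x$variant_rate, 100 * x$indel_fraction, x$p_diff, x$p_bg))
  invisible(x)
}

# sample a placement of `len` bases avoiding `occupied` intervals (with
# margin) on any chromosome; returns list(chrom, start) or errors
place_plant <- function(len, occupied, lens, margin = 200L, tries = 2000L) {
  for (i in seq_len(tries)) {
    ch <- sample(names(lens), 1L)
    L <- lens[[ch]]
    if (L < len + 2L * margin) next
    s <- sample.int(L - len - 2L * margin, 1L) + margin
    occ <- occupied[occupied$chrom == ch, , drop = FALSE]
    if (!nrow(occ) || all(s + len + margin <= occ$start | s >= occ$end + margin)) {
      return(list(chrom = ch, start = s))
    }
  }
  stop("could not place a ", len, "-bp plant; plants exceed the genome length")
}

random_seq <- function(L, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
}

#' Generate the synthetic genome and its planted truth
#'
#' Random ~50%-GC background with planted features overwritten into it:
#' GC-extreme windows, exact tandem arrays, homopolymer runs, and exact-copy
#' segmental duplications (both copies recorded). Structural-variant regions
#' are annotation-only plants (no sequence change). Every plant becomes one
#' record of the truth interval set, labeled by type; the union of truth
#' intervals is the ground-truth difficult region set.
#'
#' @param config a [synthetic_config()].
#' @return `list(genome, truth)` — named sequence vector and labeled
#'   interval set.
#' @export
make_genome <- function(config) {
  set.seed(config$seed)
  lens <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                          sprintf("chr%d", seq_len(config$n_chrom)))
  genome <- vapply(lens, random_seq, character(1))
  occupied <- data.frame(chrom = character(), start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
  truth <- list()
  plant <- function(len, type) {
    p <- place_plant(len, occupied, lens)
    rec <- data.frame(chrom = p$chrom, start = p$start, end = p$start + len,
                      name = type, stringsAsFactors = FALSE)
    occupied <<- rbind(occupied, rec[, 1:3])
    truth[[length(truth) + 1L]] <<- rec
    rec
  }
  splice <- function(rec, s) {
    substr(genome[[rec$chrom]], rec$start + 1L, rec$end) <<- s
  }
  for (i in seq_len(config$gc_n)) {
    splice(plant(config$gc_len, "gc_low"), random_seq(config$gc_len, config$gc_low))
    splice(plant(config$gc_len, "gc_high"), random_seq(config$gc_len, config$gc_high))
  }
  for (i in seq_len(config$tandem_n)) {
    unit <- random_seq(config$tandem_period)
    while (length(unique(strsplit(unit, "")[[1]])) < 2L) {
      unit <- random_seq(config$tandem_period)
    }
    arr <- strtrim(strrep(unit, ceiling(config$tandem_len / config$tandem_period)),
                   config$tandem_len)
    splice(plant(config$tandem_len, "tandem"), arr)
  }
  for (i in seq_len(config$homopolymer_n)) {
    base <- sample(c("A", "C", "G", "T"), 1L)
    splice(plant(config$homopolymer_len, "homopolymer"),
           strrep(base, config$homopolymer_len))
  }
  for (i in seq_len(config$segdup_n)) {
    src <- plant(config$segdup_len, "segdup")
    dst <- plant(config$segdup_len, "segdup")
    splice(dst, substr(genome[[src$chrom]], src$start + 1L, src$end))
  }
  for (i in seq_len(config$sv_n)) plant(config$sv_len, "sv")
  truth <- if (length(truth)) {
    sort_intervals(do.call(rbind, truth))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), stringsAsFactors = FALSE)
  }
  list(genome = genome, truth = truth)
}

#' Generate a CDS annotation for a synthetic genome
#'
#' Non-overlapping exon intervals tiled along each chromosome (default
#' 300-bp exons separated by 200-bp gaps, covering 60% of each chromosome),
#' so that planted regions are straddled by coding sequence the way real
#' difficult regions straddle exons.
#'
#' @param genome named sequence vector from [make_genome()].
#' @param config a [synthetic_config()].
#' @return Interval set of CDS exons.
#' @export
make_cds <- function(genome, config) {
  set.seed(config$seed + 1L)
  out <- list()
  for (ch in names(genome)) {
    L <- nchar(genome[[ch]])
    step <- config$cds_exon + config$cds_gap
    starts <- seq.int(config$cds_gap %/% 2L, L - config$cds_exon, by = step)
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = starts + config$cds_exon,
                            stringsAsFactors = FALSE)
  }
  iv <- sort_intervals(do.call(rbind, out))
  iv$name <- sprintf("cds_%04d", seq_len(nrow(iv)))
  iv
}

#' Generate a flag-annotated variant catalog
#'
#' Variant records are placed by a per-chromosome Poisson process at the
#' configured rate; a configurable fraction are 1-3 bp indels, the rest
#' SNVs. Each record is flagged `filtered` with probability `p_diff` when it
#' lies inside a planted difficult region and `p_bg` otherwise, emulating a
#' catalog in which whole neighbourhoods of filtered-out calls mark the
#' regions a short-read caller cannot handle.
#'
#' @param genome named sequence vector.
#' @param truth planted-truth interval set from [make_genome()].
#' @param config a [synthetic_config()].
#' @return Variant-site `data.frame` (writable with [write_vcf_sites()]).
#' @export
make_variants <- function(genome, truth, config) {
  set.seed(config$seed + 2L)
  lens <- seq_lengths(genome)
  bases <- c("A", "C", "G", "T")
  recs <- list()
  for (ch in names(genome)) {
    L <- lens[[ch]]
    n <- stats::rpois(1L, config$variant_rate * L)
    # leave room at the 3' end for deletion alleles
    pos <- sort(sample.int(L - 4L, min(n, L - 4L)))
    is_indel <- stats::runif(length(pos)) < config$indel_fraction
    chars <- chrom_chars(genome[[ch]])
    ref <- chars[pos + 1L]
    alt <- ref
    for (i in seq_along(pos)) {
      if (is_indel[i]) {
        l <- sample.int(3L, 1L)
        if (stats::runif(1) < 0.5) {          # deletion
          ref[i] <- paste(chars[(pos[i] + 1L):(pos[i] + 1L + l)], collapse = "")
          alt[i] <- chars[pos[i] + 1L]
        } else {                               # insertion
          alt[i] <- paste(c(ref[i], sample(bases, l, replace = TRUE)), collapse = "")
        }
      } else {
        alt[i] <- sample(setdiff(bases, ref[i]), 1L)
      }
    }
    ok <- !grepl("N", ref, fixed = TRUE) & !grepl("N", alt, fixed = TRUE)
    recs[[ch]] <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE)[ok, , drop = FALSE]
  }
  df <- do.call(rbind, recs)
  df <- df[!duplicated(paste(df$chrom, df$pos, df$alt)), , drop = FALSE]
  in_diff <- positions_in_intervals(df$chrom, df$pos, truth)
  p <- ifelse(in_diff, config$p_diff, config$p_bg)
  status <- ifelse(stats::runif(nrow(df)) < p, "filtered", "passed")
  variant_sites(df$chrom, df$pos, df$ref, df$alt, status)
}

#' Generate a synthetic coverage track
#'
#' Gaussian depth around the configured mean, multiplied by
#' `coverage_factor` inside planted difficult regions and clipped at zero.
#'
#' @inheritParams make_variants
#' @return Named list of per-base depth vectors.
#' @export
make_coverage <- function(genome, truth, config) {
  set.seed(config$seed + 3L)
  lens <- seq_lengths(genome)
  diff_mask <- mask_from_intervals(truth, genome)
  out <- lapply(names(genome), function(ch) {
    v <- stats::rnorm(lens[[ch]], config$coverage_mean, config$coverage_sd)
    v <- v * ifelse(diff_mask[[ch]] == 1, config$coverage_factor, 1)
    pmax(v, 0)
  })
  names(out) <- names(genome)
  out
}

#' Generate a complete synthetic bundle
#'
#' Runs all generators under one seed and returns every input the pipeline
#' consumes, plus truth-derived annotation interval sets standing in for the
#' database-sourced masks (segmental duplications; interspersed repeats,
#' represented by the planted tandem and homopolymer regions; structural
#' variants). With `outdir` set, all pieces are also written in their
#' standard formats (FASTA, BED, VCF, bedGraph).
#'
#' @param config a [synthetic_config()].
#' @param outdir optional directory to write the bundle to.
#' @return A list with elements `genome`, `truth`, `cds`, `sites`,
#'   `coverage`, `annotations` (list of `segdup`, `repeatmasker`, `sv`
#'   interval sets) and `config`.
#' @export
simulate_unmet_data <- function(config = synthetic_config(), outdir = NULL) {
  g <- make_genome(config)
  cds <- make_cds(g$genome, config)
  sites <- make_variants(g$genome, g$truth, config)
  coverage <- make_coverage(g$genome, g$truth, config)
  annotations <- list(
    segdup = g$truth[g$truth$name == "segdup", , drop = FALSE],
    repeatmasker = g$truth[g$truth$name %in% c("tandem", "homopolymer"), , drop = FALSE],
    sv = g$truth[g$truth$name == "sv", , drop = FALSE])
  bundle <- list(genome = g$genome, truth = g$truth, cds = cds, sites = sites,
                 coverage = coverage, annotations = annotations, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(g$genome, file.path(outdir, "genome.fa"))
    write_bed(cds, file.path(outdir, "cds.bed"))
    write_bed(g$truth, file.path(outdir, "truth.bed"))
    write_vcf_sites(sites, file.path(outdir, "variants.vcf"),
                    seq_lengths(g$genome))
    write_bedgraph(coverage, file.path(outdir, "coverage.bedgraph"))
    for (nm in names(annotations)) {
      if (nrow(annotations[[nm]])) {
        write_bed(annotations[[nm]], file.path(outdir, paste0(nm, ".bed")))
      }
    }
  }
  bundle
}
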