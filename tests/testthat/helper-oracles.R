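# Independent brute-force oracles and shared fixtures. The oracles
# deliberately use the most direct formulation available (full scans,
# all-pairs counts) so they share no code path with the implementation.

random_genome <- function(lens, seed, gc = 0.5) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(lens, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

random_sites <- function(chrom, L, n, p_filtered, seed) {
  set.seed(seed)
  pos <- sort(sample.int(L, n)) - 1L
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1))
  variant_sites(chrom, pos, ref, alt,
                ifelse(runif(n) < p_filtered, "filtered", "passed"))
}

# direct window scan: count records in [pos-n, pos+n] one by one
brute_window_stats <- function(sites, chrom, pos, n) {
  w <- 2L * n + 1L
  inwin <- sites$chrom == chrom & sites$pos >= pos - n & sites$pos <= pos + n
  nv <- sum(inwin)
  nf <- sum(inwin & sites$status == "filtered")
  list(n_variants = nv, n_filtered = nf, vd = nv / w,
       vfr = if (nv > 0) nf / nv else NA_real_)
}

# O(W^2 K) mappability: compare every query window against every window of
# the forward and reverse-complement sequences
brute_mappability <- function(genome, K, E) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(genome)))
  all_seq <- c(unname(genome), unname(rc))
  wins <- unlist(lapply(all_seq, function(s) {
    L <- nchar(s)
    if (L < K) character(0) else substring(s, 1:(L - K + 1L), K:L)
  }))
  mat <- do.call(rbind, strsplit(wins, ""))
  is_n <- mat == "N"
  lapply(genome, function(s) {
    L <- nchar(s)
    q <- substring(s, 1:(L - K + 1L), K:L)
    occ <- vapply(unname(q), function(wq) {
      a <- strsplit(wq, "")[[1]]
      mm <- rowSums(mat != matrix(a, nrow(mat), K, byrow = TRUE) |
                      is_n | matrix(a == "N", nrow(mat), K, byrow = TRUE))
      sum(mm <= E)
    }, numeric(1), USE.NAMES = FALSE)
    c(1 / occ, rep(NA_real_, K - 1L))
  })
}

# all-pairs AUC with half credit for ties
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# direct definition of the percentile rank
brute_percentile <- function(raw) {
  vapply(raw, function(x) mean(raw <= x), numeric(1))
}

# MCC via the standard TP/TN/FP/FN formulation
standard_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# a light configuration for single-chromosome unit tests
small_config <- function(...) {
  synthetic_config(n_chrom = 1L, chrom_length = 20000L, segdup_n = 1L,
                   segdup_len = 300L, tandem_n = 2L, homopolymer_n = 2L,
                   gc_n = 1L, gc_len = 200L, sv_n = 1L, sv_len = 300L, ...)
}

# the standard synthetic bundle and its fitted model, computed once per run
std_cache <- new.env(parent = emptyenv())

std_bundle <- function() {
  if (is.null(std_cache$bundle)) {
    std_cache$bundle <- simulate_unmet_data(synthetic_config(seed = 1))
  }
  std_cache$bundle
}

std_pipeline <- function() {
  if (is.null(std_cache$pipe)) {
    std_cache$pipe <- suppressMessages(
      run_pipeline(bundle = std_bundle(),
                   control = train_control(grid = "reduced")))
  }
  std_cache$pipe
}
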