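p25 <- feature_params()  # 25-bp window, defaults

test_that("windowed GC content matches direct counting and saturates correctly", {
  g <- c(chr1 = paste0(strrep("G", 25), strrep("A", 25)))
  gc <- gc_content(g, p25)[[1]]
  expect_equal(gc[13], 1.0)       # all-G window centered at position 12 (0-based)
  expect_equal(gc[38], 0.0)       # all-A window
  expect_true(all(is.na(gc[1:12])))
  expect_true(all(is.na(gc[39:50])))
  # random sequence: equals per-window character counts
  g2 <- random_genome(c(chr1 = 200L), seed = 14)
  gc2 <- gc_content(g2, p25)[[1]]
  ch <- strsplit(g2[[1]], "")[[1]]
  for (i in sample(13:188, 20)) {
    win <- ch[(i - 12):(i + 12)]
    expect_equal(gc2[i], sum(win %in% c("G", "C")) / 25)
  }
  # complement identity on N-free windows
  at <- gc_content(c(chr1 = chartr("ACGT", "TGCA", g2[[1]])), p25)[[1]]
  ok <- !is.na(gc2)
  expect_equal(gc2[ok] + (1 - at[ok]), rep(1, sum(ok)))
})

test_that("sequence entropy matches the Shannon formula and its bounds", {
  g <- c(chr1 = strrep("T", 40))
  expect_equal(sequence_entropy(g, p25)[[1]][20], 0)
  # "ACGT" repeated: central windows hold counts 7,6,6,6
  g2 <- c(chr1 = strrep("ACGT", 10))
  h <- sequence_entropy(g2, p25)[[1]]
  expected <- -(7 / 25 * log2(7 / 25) + 3 * (6 / 25 * log2(6 / 25)))
  expect_equal(h[13], expected, tolerance = 1e-12)
  expect_equal(round(expected, 4), 1.9966)
  g3 <- random_genome(c(chr1 = 300L), seed = 3, gc = 0.3)
  h3 <- sequence_entropy(g3, p25)[[1]]
  expect_true(all(h3[!is.na(h3)] >= 0 & h3[!is.na(h3)] <= 2))
})

test_that("homopolymer mask obeys the 7-bp threshold and 12-bp flanks", {
  bg <- strrep("CA", 10)  # run-free background; no T or long A adjacency
  g7 <- c(chr1 = paste0(bg, strrep("T", 7), bg))
  m7 <- homopolymer_mask(g7, p25)[[1]]
  expect_equal(sum(m7), 7 + 12 + 12)
  expect_equal(which(m7 == 1), (20 - 12 + 1):(20 + 7 + 12))
  g6 <- c(chr1 = paste0(bg, strrep("T", 6), bg))
  expect_equal(sum(homopolymer_mask(g6, p25)[[1]]), 0)
  # run at the chromosome start: left flank clipped
  g0 <- c(chr1 = paste0(strrep("A", 8), bg, bg))
  m0 <- homopolymer_mask(g0, p25)[[1]]
  expect_equal(which(m0 == 1), 1:(8 + 12))
})

test_that("tandem detector finds short-period arrays but not homopolymers", {
  bg1 <- random_genome(c(x = 40L), seed = 31, gc = 0.5)
  g <- c(chr1 = paste0(bg1, "ACACACACACAC", bg1))
  m <- tandem_repeat_mask(g, p25)[[1]]
  expect_true(all(m[41:52] == 1))
  g2 <- c(chr1 = paste0(bg1, strrep("A", 12), bg1))
  m2 <- tandem_repeat_mask(g2, p25)[[1]]
  expect_true(all(m2[41:52] == 0))
})

test_that("mask overrides bypass the detectors", {
  g <- random_genome(c(chr1 = 100L), seed = 7)
  ov <- intervals("chr1", 30, 40)
  m <- tandem_repeat_mask(g, p25, override = ov)[[1]]
  expect_equal(which(m == 1), (30 - 12 + 1):(40 + 12))
  ml <- low_complexity_mask(g, p25, override = ov)[[1]]
  expect_equal(which(ml == 1), 31:40)
})

test_that("flank extension is monotone and masks are idempotent", {
  g <- c(chr1 = random_genome(c(x = 120L), seed = 12))
  g <- c(chr1 = paste0(substr(g, 1, 50), strrep("G", 9), substr(g, 51, 120)))
  p_small <- feature_params(mask_flank = 4L)
  p_big <- feature_params(mask_flank = 12L)
  m_small <- homopolymer_mask(g, p_small)[[1]]
  m_big <- homopolymer_mask(g, p_big)[[1]]
  expect_true(all(m_big[m_small == 1] == 1))
  expect_true(all(m_small %in% c(0, 1)))
})

test_that("low-complexity detector separates repetitive from random sequence", {
  reps <- c(chr1 = strtrim(strrep("AAAT", 20), 70))
  m <- low_complexity_mask(reps, p25)[[1]]
  expect_true(all(m[1:64] == 1))
  hp <- c(chr1 = strrep("A", 70))
  expect_true(all(low_complexity_mask(hp, p25)[[1]][1:64] == 1))
  rnd <- random_genome(c(chr1 = 2000L), seed = 99)
  expect_equal(sum(low_complexity_mask(rnd, p25)[[1]]), 0)
})

test_that("low-complexity score agrees with a direct triplet-count oracle", {
  set.seed(8)
  for (case in 1:10) {
    s <- paste(sample(c("A", "C", "T"), 64, replace = TRUE, prob = c(.6, .2, .2)),
               collapse = "")
    trip <- substring(s, 1:62, 3:64)
    counts <- table(trip)
    score <- sum(counts * (counts - 1) / 2) / 61
    masked <- sum(low_complexity_mask(c(chr1 = s), p25)[[1]]) > 0
    expect_equal(masked, score > feature_params()$dust_level / 10)
  }
})

test_that("mappability is 1 on unique sequence and 1/2 on exact duplicates", {
  pm <- feature_params(map_k = 10L, map_e = 0L)
  g <- c(chr1 = random_genome(c(x = 40L), seed = 4))
  m1 <- mappability(g, pm)[[1]]
  expect_equal(m1, brute_mappability(g, 10L, 0L)[[1]])
  expect_true(all(is.na(m1[32:40])))      # no full window starts in the tail
  s <- random_genome(c(x = 60L), seed = 77)
  dup <- c(chr1 = paste0(s, s))
  m2 <- mappability(dup, pm)[[1]]
  # windows fully inside either copy see exactly two occurrences
  expect_true(all(m2[c(1:51, 61:111)] == 0.5))
  expect_error(mappability(c(chr1 = "ACGT"), feature_params(map_k = 10L)),
               "exceeds chromosome length")
})

test_that("mappability is invariant under reverse-complementing the genome", {
  g <- random_genome(c(chr1 = 150L, chr2 = 120L), seed = 5)
  pm <- feature_params(map_k = 12L, map_e = 1L)
  fwd <- mappability(g, pm)
  rc <- vapply(g, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  bwd <- mappability(rc, pm)
  for (ch in names(g)) {
    a <- fwd[[ch]][!is.na(fwd[[ch]])]
    b <- bwd[[ch]][!is.na(bwd[[ch]])]
    # the window starting at p maps to the window ending there on the other
    # strand, so defined values reverse
    expect_equal(a, rev(b))
  }
})

test_that("N-containing windows are counted as mismatching everything", {
  pm <- feature_params(map_k = 8L, map_e = 1L)
  s <- random_genome(c(x = 30L), seed = 13)
  gN <- c(chr1 = paste0(s, "NNNNNNNN", s))
  mN <- mappability(gN, pm)[[1]]
  oracle <- brute_mappability(gN, 8L, 1L)[[1]]
  expect_equal(mN, oracle)
})
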