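test_that("percentile ranks follow the <=-count definition with max-tie sharing", {
  expect_equal(percentile_rank(c(0.1, 0.5, 0.9)), c(1, 2, 3) / 3)
  expect_equal(percentile_rank(rep(0.4, 6)), rep(1, 6))
  set.seed(15)
  raw <- sample(seq(0, 1, 0.05), 200, replace = TRUE)
  expect_equal(percentile_rank(raw), brute_percentile(raw))
  # non-decreasing in the raw score
  o <- order(raw)
  expect_true(all(diff(percentile_rank(raw)[o]) >= 0))
})

test_that("bands cut the percentile score at 0.93 and 0.97", {
  u <- c(0.98, 0.97, 0.95, 0.93, 0.9299, 0.5)
  b <- assign_bands(u)
  expect_equal(as.character(b),
               c("difficult", "difficult", "error_prone", "error_prone",
                 "reliable", "reliable"))
  expect_false(anyNA(b))
  expect_error(band_thresholds(0.97, 0.93))
})

test_that("difficult regions are maximal >=50-bp runs above 0.97", {
  mk_track <- function(unmet, chrom = "chr1", start = 0L) {
    data.frame(chrom = chrom, pos = start + seq_along(unmet) - 1L,
               unmet = unmet, stringsAsFactors = FALSE)
  }
  r1 <- difficult_regions(mk_track(rep(0.98, 60)))
  expect_equal(r1, intervals("chr1", 0, 60))
  expect_equal(nrow(difficult_regions(mk_track(rep(0.98, 40)))), 0L)
  # one sub-threshold base splits the run; each piece judged on its own
  broken <- c(rep(0.99, 55), 0.5, rep(0.99, 45))
  r2 <- difficult_regions(mk_track(broken))
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$end - r2$start, 55L)
  # runs do not span gaps in scored positions
  tr <- mk_track(rep(0.99, 60))
  tr$pos[31:60] <- tr$pos[31:60] + 10L
  expect_equal(nrow(difficult_regions(tr)), 0L)
  # splitting the track by chromosome changes nothing
  tr2 <- rbind(mk_track(rep(0.98, 60), "chr1"), mk_track(rep(0.98, 60), "chr2"))
  r3 <- difficult_regions(tr2)
  expect_equal(nrow(r3), 2L)
  expect_equal(r3$chrom, c("chr1", "chr2"))
})

test_that("score-group comparison reproduces the Welch statistic", {
  track <- data.frame(chrom = "chr1", pos = 0:9,
                      unmet = c(0.9, 0.8, 0.85, 0.95, 0.7, 0.2, 0.3, 0.25, 0.4, 0.1))
  ga <- data.frame(chrom = "chr1", pos = 0:4)
  gb <- data.frame(chrom = "chr1", pos = 5:9)
  res <- compare_score_groups(track, ga, gb)
  # direct Welch formulas
  a <- track$unmet[1:5]; b <- track$unmet[6:10]
  se <- sqrt(var(a) / 5 + var(b) / 5)
  expect_equal(res$t, (mean(a) - mean(b)) / se)
  expect_equal(res$mean_a, mean(a))
  expect_equal(res$sd_b, sd(b))
  expect_lt(res$p, 0.01)
  # identical degenerate groups
  track2 <- data.frame(chrom = "chr1", pos = 0:3, unmet = rep(0.5, 4))
  res2 <- compare_score_groups(track2, data.frame(chrom = "chr1", pos = 0:1),
                               data.frame(chrom = "chr1", pos = 2:3))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
  expect_error(compare_score_groups(track, ga, data.frame(chrom = "chr9", pos = 1L)),
               "both groups")
})

test_that("indel positions split on the two-or-more filtered rule", {
  sites <- variant_sites(
    rep("chr1", 7),
    c(10L, 10L, 20L, 30L, 30L, 40L, 50L),
    c("AT", "AC", "A", "GTT", "GC", "T", "A"),
    c("A", "A", "AG", "G", "G", "TAA", "G"),
    c("filtered", "filtered", "filtered", "filtered", "filtered", "passed",
      "filtered"))
  grp <- select_indel_groups(sites)
  expect_equal(grp$recurrent$pos, c(10L, 30L))   # two filtered indels each
  expect_setequal(grp$other$pos, c(20L, 40L))    # one filtered / one passed
  # position 50 is an SNV: in neither group
  expect_false(50L %in% c(grp$recurrent$pos, grp$other$pos))
  none <- select_indel_groups(variant_sites("chr1", 5L, "A", "G", "passed"))
  expect_equal(nrow(none$recurrent) + nrow(none$other), 0L)
})

test_that("the fitted model object exposes coherent methods", {
  pipe <- std_pipeline()
  fit <- pipe$fit
  expect_s3_class(fit, "unmet")
  expect_equal(sum(coef(fit)), 1.0, tolerance = 1e-9)
  expect_true(all(coef(fit) >= 0))
  # track invariants: UNMET monotone in raw, bands partition
  tr <- predict(fit)
  o <- order(tr$raw)
  expect_true(all(diff(tr$unmet[o]) >= 0))
  expect_false(anyNA(tr$band))
  expect_equal(as.vector(table(tr$band)["difficult"]) +
                 as.vector(table(tr$band)["error_prone"]) +
                 as.vector(table(tr$band)["reliable"]), nrow(tr))
  # predict on new data is consistent with the fitted scale
  newx <- fit$sets$test$x[1:5, , drop = FALSE]
  raw <- predict(fit, newx, type = "raw")
  expect_true(all(raw >= 0 & raw <= 1))
  u <- predict(fit, newx, type = "unmet")
  expect_true(all(abs(u - vapply(raw, function(r) mean(tr$raw <= r), 0)) <= 1e-9))
  b <- predict(fit, newx, type = "band")
  expect_s3_class(b, "factor")
  expect_output(print(fit), "difficulty-to-sequence")
  expect_output(print(summary(fit)), "Feature importance")
  ftd <- fitted(fit)
  expect_equal(unname(ftd), tr$unmet)
})

test_that("exported tracks round-trip and bands partition the scored bases", {
  pipe <- std_pipeline()
  outdir <- withr::local_tempdir()
  paths <- export_tracks(pipe$fit$track, outdir, pipe$fit$seqlens)
  expect_true(all(file.exists(paths)))
  bands <- read_bed(paths[["bands"]])
  # the band intervals cover exactly the scored positions, disjointly
  expect_equal(interval_bases(bands), nrow(pipe$fit$track))
  expect_equal(sum(bands$end - bands$start), interval_bases(bands))
  back <- read_coverage(paths[["unmet"]], pipe$fit$seqlens)
  tr <- pipe$fit$track
  expect_equal(back[[tr$chrom[1]]][tr$pos[1] + 1L], tr$unmet[1],
               tolerance = 1e-8)
  # row counts match a run-length encoding of the per-base band vector
  b1 <- bands[bands$chrom == "chr1", ]
  per_base <- rep(NA_character_, pipe$fit$seqlens[["chr1"]])
  sub <- tr[tr$chrom == "chr1", ]
  per_base[sub$pos + 1L] <- as.character(sub$band)
  r <- rle(per_base)
  expect_equal(nrow(b1), sum(!is.na(r$values)))
})

test_that("rerunning the pipeline reproduces the manifest", {
  p1 <- suppressMessages(run_pipeline(small_config(seed = 30),
                                      control = train_control(grid = "reduced",
                                                              nrounds = 20L)))
  p2 <- suppressMessages(run_pipeline(small_config(seed = 30),
                                      control = train_control(grid = "reduced",
                                                              nrounds = 20L)))
  expect_identical(p1$manifest, p2$manifest)
  expect_true(p1$manifest$auc >= 0 && p1$manifest$auc <= 1)
})
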