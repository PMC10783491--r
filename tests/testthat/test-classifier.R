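# labeled positions + feature matrix with a signal feature separating classes
toy_labeled <- function(n_pos, n_neg, seed = 1, separable = TRUE) {
  set.seed(seed)
  n <- n_pos + n_neg
  lab <- data.frame(chrom = "chr1", pos = seq_len(n) * 30L,
                    label = c(rep("unreliable", n_pos), rep("reliable", n_neg)),
                    stringsAsFactors = FALSE)
  x <- matrix(runif(n * 10), n, 10, dimnames = list(
    paste0(lab$chrom, ":", lab$pos), unmetr:::unmet_feature_names))
  if (separable) {
    x[, "mappability"] <- ifelse(lab$label == "unreliable",
                                 runif(n, 0, 0.45), runif(n, 0.55, 1))
  }
  list(labeled = lab, x = x)
}

test_that("training sets are balanced and split 8:2 with preserved class ratio", {
  d <- toy_labeled(100, 1000)
  sets <- build_training_set(d$labeled, d$x)
  expect_equal(nrow(sets$train$x), 160L)
  expect_equal(nrow(sets$test$x), 40L)
  expect_equal(sum(sets$train$y), 80L)   # half positive in both splits
  expect_equal(sum(sets$test$y), 20L)
  expect_equal(length(intersect(rownames(sets$train$x), rownames(sets$test$x))), 0L)
  # same seeds -> identical splits
  sets2 <- build_training_set(d$labeled, d$x)
  expect_identical(sets, sets2)
  # single-class input is an error
  bad <- d$labeled; bad$label <- "reliable"
  expect_error(build_training_set(bad, d$x), "both")
})

test_that("a 1+1 training set is degenerate but valid, with a warning", {
  d <- toy_labeled(1, 1)
  expect_warning(sets <- build_training_set(d$labeled, d$x), "small")
  expect_equal(nrow(sets$train$x) + nrow(sets$test$x), 2L)
})

test_that("MCC follows its confusion-count formula", {
  expect_equal(mcc(c(CPU = 10, CPR = 10, PU = 0, PR = 0)), 1.0)
  expect_equal(mcc(c(CPU = 3, CPR = 4, PU = 1, PR = 2)), 10 / sqrt(600))
  expect_warning(z <- mcc(c(CPU = 5, CPR = 0, PU = 0, PR = 0)), "zero factor")
  expect_equal(z, 0)
  # random spot agreement with the TP/TN/FP/FN formulation
  set.seed(4)
  for (i in 1:50) {
    v <- sample(0:12, 4, replace = TRUE)
    got <- suppressWarnings(mcc(c(CPU = v[1], CPR = v[2], PU = v[3], PR = v[4])))
    expect_equal(got, standard_mcc(v[1], v[2], v[3], v[4]))
  }
})

test_that("AUC uses midranks and matches the all-pairs oracle", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(9)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # deliberate ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(sc, y), brute_auc(sc, y))
    # invariance under a strictly monotone transform
    expect_equal(auc_score(qlogis(sc / 2 + 0.25), y), auc_score(sc, y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  sc <- runif(60)
  y <- rbinom(60, 1, 0.5)
  expect_equal(auc_score(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                              direction = "<", levels = c(0, 1)))))
})

test_that("grid-search training finds a separator and is deterministic", {
  d <- toy_labeled(60, 600, seed = 2)
  ctrl <- train_control(grid = "reduced", nrounds = 30L)
  sets <- build_training_set(d$labeled, d$x, ctrl)
  m1 <- train_classifier(sets$train, ctrl)
  expect_gte(max(m1$cv_table$cv_accuracy), 0.95)
  ev <- evaluate_classifier(m1, sets$test)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$mcc, 1.0)
  expect_equal(sum(ev$confusion), nrow(sets$test$x))
  # importance concentrates on the separating feature and sums to one
  expect_equal(sum(m1$importance), 1.0, tolerance = 1e-9)
  expect_equal(names(which.max(m1$importance)), "mappability")
  m2 <- train_classifier(sets$train, ctrl)
  expect_identical(m1$best_params, m2$best_params)
  expect_equal(m1$importance, m2$importance)
})

test_that("a single-point grid skips the search", {
  d <- toy_labeled(30, 60, seed = 3)
  ctrl <- train_control(grid = data.frame(max_depth = 3L, eta = 0.1, gamma = 0,
                                          subsample = 1, colsample_bytree = 1),
                        nrounds = 20L)
  sets <- build_training_set(d$labeled, d$x, ctrl)
  m <- train_classifier(sets$train, ctrl)
  expect_true(all(is.na(m$cv_table$cv_accuracy)))
  expect_equal(evaluate_classifier(m, sets$test)$auc, 1.0)
})

test_that("shuffled labels give chance-level held-out AUC", {
  d <- toy_labeled(150, 150, seed = 6, separable = TRUE)
  set.seed(77)
  d$labeled$label <- sample(d$labeled$label)   # break the signal
  ctrl <- train_control(grid = "reduced", nrounds = 30L)
  sets <- build_training_set(d$labeled, d$x, ctrl)
  m <- train_classifier(sets$train, ctrl)
  ev <- suppressWarnings(evaluate_classifier(m, sets$test))
  expect_lt(abs(ev$auc - 0.5), 0.22)
})

test_that("single-class training is rejected", {
  d <- toy_labeled(10, 10)
  sets <- build_training_set(d$labeled, d$x)
  sets$train$y <- rep(1L, length(sets$train$y))
  expect_error(train_classifier(sets$train), "both classes")
})

test_that("the similarity filter removes near-duplicate windows at 80%", {
  base <- random_genome(c(x = 25L), seed = 50)
  mutate <- function(s, k) {        # flip k positions deterministically
    ch <- strsplit(s, "")[[1]]
    idx <- seq_len(k) * 2L
    ch[idx] <- chartr("ACGT", "GTAC", ch[idx])
    paste(ch, collapse = "")
  }
  spacer <- strrep("T", 40)
  # windows centered at 52, 157, 262, 367 (0-based) on a constructed chromosome
  g <- c(chr1 = paste0(spacer, base, spacer, spacer, mutate(base, 5), spacer,
                       spacer, mutate(base, 6), spacer, spacer, base, spacer))
  centers <- c(52L, 157L, 262L, 367L)
  mk <- function(i) list(x = matrix(0, length(i), 1), y = rep(0L, length(i)),
                         sites = data.frame(chrom = rep("chr1", length(i)),
                                            pos = centers[i]))
  train <- mk(1L)
  test <- mk(2:4)
  out <- similarity_filter(test, train, g, n = 12L, threshold = 0.80)
  # 20/25 matches removed, 19/25 kept, exact copy removed
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(out$sites$pos, 262L)
  # empty training set: nothing removed
  out2 <- similarity_filter(test, mk(integer(0)), g, n = 12L)
  expect_equal(nrow(out2$sites), 3L)
})

test_that("univariate analysis ranks the informative feature first", {
  d <- toy_labeled(80, 200, seed = 8)
  ctrl <- train_control(grid = "reduced", nrounds = 20L)
  sets <- build_training_set(d$labeled, d$x, ctrl)
  tab <- suppressWarnings(univariate_analysis(sets$train, sets$test, ctrl))
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$feature[1], "mappability")
  expect_equal(tab$auc, sort(tab$auc, decreasing = TRUE))
  # a constant feature carries no signal
  d$x[, "sv"] <- 0.5
  sets2 <- build_training_set(d$labeled, d$x, ctrl)
  tab2 <- suppressWarnings(univariate_analysis(sets2$train, sets2$test, ctrl))
  expect_equal(tab2$auc[tab2$feature == "sv"], 0.5)
})
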