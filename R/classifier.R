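#' Training protocol configuration
#'
#' Controls training-set assembly and the grid-searched, cross-validated
#' boosted-tree fit. The full hyperparameter grid is
#' `max_depth {3,4,5,6} x learning_rate {0.1,0.01,0.001} x gamma {0,0.1,0.01}
#' x subsample {0.5,0.8,1} x colsample_bytree {0.5,0.8,1}` (324 points)
#' evaluated by 5-fold cross-validated accuracy at the 0.5 threshold; the
#' reduced grid (2 points) keeps the protocol identical at desk scale.
#'
#' @param balance_seed seed for down-sampling the majority class.
#' @param split_ratio fraction of the balanced set used for training.
#' @param split_seed seed for the stratified train/test split and CV folds.
#' @param grid `"full"`, `"reduced"`, or a data.frame with columns
#'   `max_depth`, `eta`, `gamma`, `subsample`, `colsample_bytree`.
#' @param folds number of cross-validation folds.
#' @param nrounds boosting rounds per fit.
#' @param threshold score threshold for class assignment.
#' @return A list of class `"train_control"`.
#' @export
train_control <- function(balance_seed = 101L, split_ratio = 0.8,
                          split_seed = 202L, grid = "full", folds = 5L,
                          nrounds = 100L, threshold = 0.5) {
  if (is.character(grid)) {
    grid <- switch(match.arg(grid, c("full", "reduced")),
      full = expand.grid(max_depth = c(3L, 4L, 5L, 6L),
                         eta = c(0.1, 0.01, 0.001),
                         gamma = c(0, 0.1, 0.01),
                         subsample = c(0.5, 0.8, 1),
                         colsample_bytree = c(0.5, 0.8, 1)),
      reduced = expand.grid(max_depth = c(3L, 6L), eta = 0.1, gamma = 0,
                            subsample = 0.8, colsample_bytree = 0.8))
  }
  stopifnot(nrow(grid) >= 1L, folds >= 2L,
            split_ratio > 0, split_ratio < 1, nrounds >= 1L)
  structure(list(balance_seed = balance_seed, split_ratio = split_ratio,
                 split_seed = split_seed, grid = grid, folds = as.integer(folds),
                 nrounds = as.integer(nrounds), threshold = threshold),
            class = "train_control")
}

#' Assemble balanced train and test sets
#'
#' Down-samples the majority class to the minority count (balance seed),
#' then splits each class `split_ratio : 1 - split_ratio` (split seed) so
#' the class ratio is preserved within one sample in both splits.
#'
#' @param labeled labeled positions from [label_sites()].
#' @param features feature matrix from [assemble_feature_matrix()]; rows are
#'   matched to labeled positions by their `chrom:pos` names.
#' @param control a [train_control()].
#' @return `list(train, test)`, each `list(x, y, sites)` with `y = 1` for
#'   unreliable (positive) sites.
#' @export
build_training_set <- function(labeled, features, control = train_control()) {
  key <- paste0(labeled$chrom, ":", labeled$pos)
  present <- key %in% rownames(features)
  labeled <- labeled[present, , drop = FALSE]
  key <- key[present]
  y <- as.integer(labeled$label == "unreliable")
  pos_idx <- which(y == 1L)
  neg_idx <- which(y == 0L)
  if (!length(pos_idx) || !length(neg_idx)) {
    stop("both an unreliable and a reliable class are required for training")
  }
  n_bal <- min(length(pos_idx), length(neg_idx))
  if (n_bal < 5L) warning("very small balanced class size (", n_bal, ")")
  set.seed(control$balance_seed)
  pos_idx <- sort(sample(pos_idx, n_bal))
  neg_idx <- sort(sample(neg_idx, n_bal))
  set.seed(control$split_seed)
  take <- function(idx) {
    n_tr <- round(control$split_ratio * length(idx))
    tr <- sort(sample(idx, n_tr))
    list(train = tr, test = setdiff(idx, tr))
  }
  p <- take(pos_idx); ng <- take(neg_idx)
  mk <- function(idx) {
    idx <- sample(idx)                     # shuffle class blocks together
    list(x = features[key[idx], , drop = FALSE], y = y[idx],
         sites = labeled[idx, c("chrom", "pos"), drop = FALSE])
  }
  list(train = mk(c(p$train, ng$train)), test = mk(c(p$test, ng$test)))
}

xgb_params <- function(row) {
  list(objective = "binary:logistic", eval_metric = "logloss",
       max_depth = row$max_depth, eta = row$eta, gamma = row$gamma,
       subsample = row$subsample, colsample_bytree = row$colsample_bytree,
       nthread = 1L)
}

xgb_fit <- function(x, y, row, nrounds, seed) {
  set.seed(seed)
  xgboost::xgb.train(params = xgb_params(row),
                     data = xgboost::xgb.DMatrix(x, label = y),
                     nrounds = nrounds, verbose = 0)
}

#' Train the boosted-tree site classifier
#'
#' Grid search over the configured hyperparameters with k-fold
#' cross-validation on the training set; the grid point with the highest
#' mean CV accuracy (fraction correct at the configured threshold) is refit
#' on the full training set. Deterministic given the control seeds.
#'
#' @param train training split from [build_training_set()].
#' @param control a [train_control()].
#' @return An object of class `"unmet_classifier"`: the fitted booster, the
#'   selected hyperparameters, normalized feature importances, and the CV
#'   accuracy table.
#' @export
train_classifier <- function(train, control = train_control()) {
  x <- train$x; y <- train$y
  if (!nrow(x) || length(unique(y)) < 2L) {
    stop("training set must be non-empty and contain both classes")
  }
  grid <- control$grid
  cv_acc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1L) {
    set.seed(control$split_seed + 1L)
    fold <- integer(length(y))           # stratified fold assignment
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(control$folds), length(idx)))
    }
    for (g in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(control$folds)) {
        tr <- fold != f
        bst <- xgb_fit(x[tr, , drop = FALSE], y[tr], grid[g, ],
                       control$nrounds, seed = control$split_seed + 10L + f)
        sc <- stats::predict(bst, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
        correct <- correct + sum((sc >= control$threshold) == (y[!tr] == 1L))
      }
      cv_acc[g] <- correct / length(y)
    }
    best <- which.max(cv_acc)
  } else {
    best <- 1L
  }
  booster <- xgb_fit(x, y, grid[best, ], control$nrounds,
                     seed = control$split_seed + 99L)
  # xgb.importance chokes on single-feature boosters; a lone feature owns
  # all the gain anyway
  imp_tab <- if (ncol(x) > 1L) xgboost::xgb.importance(model = booster)
  importance <- stats::setNames(rep(0, ncol(x)), colnames(x))
  if (ncol(x) == 1L) {
    importance[] <- 1
  } else if (!is.null(imp_tab) && nrow(imp_tab)) {
    importance[imp_tab$Feature] <- imp_tab$Gain
  }
  if (sum(importance) > 0) importance <- importance / sum(importance)
  structure(list(booster = booster,
                 best_params = as.list(grid[best, , drop = FALSE]),
                 importance = importance,
                 cv_table = cbind(grid, cv_accuracy = cv_acc),
                 n_train = nrow(x), features = colnames(x),
                 control = control),
            class = "unmet_classifier")
}

#' @export
print.unmet_classifier <- function(x, ...) {
  cat(sprintf("Boosted-tree site classifier (%d features, %d training sites)\n",
              length(x$features), x$n_train))
  bp <- x$best_params
  cat(sprintf("  selected: max_depth=%d eta=%g gamma=%g subsample=%g colsample=%g\n",
              bp$max_depth, bp$eta, bp$gamma, bp$subsample, bp$colsample_bytree))
  top <- sort(x$importance, decreasing = TRUE)
  top <- top[top > 0]
  cat("  importance:", paste(sprintf("%s %.3f", names(top), top), collapse = ", "),
      "\n")
  invisible(x)
}

#' Raw classifier scores for a feature matrix
#' @param model an `"unmet_classifier"`.
#' @param x feature matrix with the model's columns.
#' @return Numeric scores in `[0, 1]`.
#' @export
classifier_scores <- function(model, x) {
  stats::predict(model$booster,
                 xgboost::xgb.DMatrix(x[, model$features, drop = FALSE]))
}

#' Area under the ROC curve
#'
#' Rank statistic (midrank tie convention): the probability that a random
#' positive scores above a random negative, ties counting one half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = positive).
#' @return AUC in `[0, 1]`; 0.5 for constant scores.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("AUC needs both classes")
  r <- rank(scores)                     # midranks
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Matthews correlation coefficient
#'
#' `MCC = (CPU * CPR - PU * PR) / sqrt((CPU+PU)(CPU+PR)(CPR+PU)(CPR+PR))`
#' over the four confusion counts: CPU = correctly predicted unreliable,
#' CPR = correctly predicted reliable, PU = reliable predicted unreliable,
#' PR = unreliable predicted reliable (i.e. TP/TN/FP/FN under the mapping
#' positive = unreliable). A zero factor in the denominator yields 0 with a
#' warning.
#'
#' @param counts named vector or list with elements `CPU`, `CPR`, `PU`, `PR`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  cpu <- as.numeric(counts[["CPU"]]); cpr <- as.numeric(counts[["CPR"]])
  pu <- as.numeric(counts[["PU"]]); pr <- as.numeric(counts[["PR"]])
  stopifnot(cpu >= 0, cpr >= 0, pu >= 0, pr >= 0)
  den <- (cpu + pu) * (cpu + pr) * (cpr + pu) * (cpr + pr)
  if (den == 0) {
    warning("MCC denominator has a zero factor; returning 0")
    return(0)
  }
  (cpu * cpr - pu * pr) / sqrt(den)
}

#' Evaluate a classifier on a held-out set
#'
#' @param model an `"unmet_classifier"`.
#' @param test test split from [build_training_set()].
#' @param threshold score threshold for the confusion counts.
#' @return `list(auc, mcc, confusion, scores)`; `confusion` holds the counts
#'   `CPU`, `CPR`, `PU`, `PR`.
#' @export
evaluate_classifier <- function(model, test, threshold = 0.5) {
  scores <- classifier_scores(model, test$x)
  pred <- as.integer(scores >= threshold)
  confusion <- c(CPU = sum(pred == 1L & test$y == 1L),
                 CPR = sum(pred == 0L & test$y == 0L),
                 PU = sum(pred == 1L & test$y == 0L),
                 PR = sum(pred == 0L & test$y == 1L))
  list(auc = auc_score(scores, test$y), mcc = mcc(confusion),
       confusion = confusion, scores = scores)
}

kmer_char_matrix <- function(genome, chrom, pos, n) {
  L <- seq_lengths(genome)[chrom]
  ok <- pos - n >= 0L & pos + n < L
  seqs <- rep(NA_character_, length(pos))
  seqs[ok] <- substr(unname(genome[chrom[ok]]), pos[ok] - n + 1L, pos[ok] + n + 1L)
  seqs
}

#' Remove test sites sequence-similar to training sites
#'
#' Information-leakage guard: a test site is removed when the `2N+1`-mer
#' centered on it matches the window of any training site at
#' `ceiling(threshold * (2N+1))` or more positions (ungapped, either
#' strand). With the default 25-bp window and threshold 0.80 that is 20 of
#' 25 positions.
#'
#' @param test,train splits from [build_training_set()].
#' @param genome named sequence vector.
#' @param n window flank N.
#' @param threshold similarity fraction at or above which a site is removed.
#' @return The filtered test split, with attribute `"n_removed"`.
#' @export
similarity_filter <- function(test, train, genome, n = 12L, threshold = 0.80) {
  if (!nrow(train$x)) return(structure(test, n_removed = 0L))
  w <- 2L * n + 1L
  need <- ceiling(threshold * w)
  tr_seq <- kmer_char_matrix(genome, train$sites$chrom, train$sites$pos, n)
  tr_seq <- tr_seq[!is.na(tr_seq)]
  te_seq <- kmer_char_matrix(genome, test$sites$chrom, test$sites$pos, n)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(tr_seq)))
  ref <- t(vapply(c(tr_seq, rc), function(s) strsplit(s, "")[[1]], character(w)))
  drop <- vapply(te_seq, function(s) {
    if (is.na(s)) return(FALSE)
    a <- strsplit(s, "")[[1]]
    any(rowSums(ref == matrix(a, nrow(ref), w, byrow = TRUE)) >= need)
  }, logical(1))
  out <- list(x = test$x[!drop, , drop = FALSE], y = test$y[!drop],
              sites = test$sites[!drop, , drop = FALSE])
  structure(out, n_removed = sum(drop))
}

#' Univariate feature analysis
#'
#' Trains one classifier per single feature under the same protocol (same
#' grid, folds and seeds) and evaluates each on the same test split,
#' quantifying how much of the discrimination each feature carries alone.
#'
#' @param train,test splits from [build_training_set()].
#' @param control a [train_control()].
#' @return A `data.frame` (feature, auc, mcc) sorted by decreasing AUC.
#' @export
univariate_analysis <- function(train, test, control = train_control(grid = "reduced")) {
  res <- lapply(colnames(train$x), function(f) {
    tr1 <- list(x = train$x[, f, drop = FALSE], y = train$y, sites = train$sites)
    te1 <- list(x = test$x[, f, drop = FALSE], y = test$y, sites = test$sites)
    m <- train_classifier(tr1, control)
    ev <- suppressWarnings(evaluate_classifier(m, te1, control$threshold))
    data.frame(feature = f, auc = ev$auc, mcc = ev$mcc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
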