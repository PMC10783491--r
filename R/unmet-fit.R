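#' Fit the per-base difficulty-to-sequence model
#'
#' The package's central fitting function. From a flag-annotated variant
#' catalog, a reference genome, CDS intervals, a coverage track and
#' annotation masks it:
#'
#' 1. labels reliable/unreliable SNV sites from windowed variant density and
#'    filter rate ([label_sites()]);
#' 2. computes the ten per-base features and assembles the feature matrix
#'    over all CDS positions ([feature_tracks()],
#'    [assemble_feature_matrix()]);
#' 3. balances the classes, splits train/test, and fits a grid-searched
#'    cross-validated boosted-tree classifier ([train_classifier()]),
#'    reporting held-out AUC, MCC and confusion counts — optionally also on
#'    a test set stripped of sites sequence-similar to training sites
#'    ([similarity_filter()]);
#' 4. scores every CDS position, converts raw scores to percentile ranks
#'    ([percentile_rank()]) and assigns difficulty bands ([assign_bands()]).
#'
#' @param sites variant-site table from [read_vcf_sites()] or
#'   [make_variants()].
#' @param genome named sequence vector from [read_fasta()].
#' @param cds CDS interval set; labeling and scoring are restricted to it.
#' @param coverage per-base depth track from [read_coverage()].
#' @param annotations list of interval sets `repeatmasker`, `segdup`, `sv`
#'   (missing elements become empty masks).
#' @param params a [feature_params()].
#' @param control a [train_control()].
#' @param thresholds a [band_thresholds()].
#' @param vd_min minimum variant density for labeling.
#' @param leakage_check also evaluate on the similarity-filtered test set.
#' @param tandem_override,lcr_override optional external mask intervals.
#' @return An object of class `"unmet"` with components `model` (the fitted
#'   classifier), `metrics` (held-out AUC/MCC/confusion),
#'   `metrics_leakage_filtered` (when requested), `labels`, `sets`
#'   (train/test splits), `track` (a `data.frame` of scored positions with
#'   `raw`, `unmet` and `band`), `thresholds`, `params`, `control`.
#' @seealso [predict.unmet()], [summary.unmet()], [difficult_regions()],
#'   [export_tracks()], [run_pipeline()]
#' @examples
#' \donttest{
#' bundle <- simulate_unmet_data(synthetic_config(seed = 7))
#' fit <- unmet(bundle$sites, bundle$genome, bundle$cds, bundle$coverage,
#'              bundle$annotations, control = train_control(grid = "reduced"))
#' summary(fit)
#' }
#' @export
unmet <- function(sites, genome, cds, coverage, annotations = list(),
                  params = feature_params(), control = train_control(),
                  thresholds = band_thresholds(), vd_min = 0.12,
                  leakage_check = FALSE,
                  tandem_override = NULL, lcr_override = NULL) {
  cl <- match.call()
  labeled <- label_sites(sites, cds, params$flank_n, vd_min)
  if (!nrow(labeled)) stop("no labelable sites: check the variant catalog and CDS")
  tracks <- feature_tracks(genome, coverage, annotations, params,
                           tandem_override, lcr_override)
  features <- assemble_feature_matrix(cds, tracks = tracks)
  sets <- build_training_set(labeled, features, control)
  model <- train_classifier(sets$train, control)
  metrics <- evaluate_classifier(model, sets$test, control$threshold)
  metrics_filtered <- NULL
  if (leakage_check) {
    kept <- similarity_filter(sets$test, sets$train, genome, params$flank_n)
    metrics_filtered <- if (nrow(kept$x) && length(unique(kept$y)) == 2L) {
      c(evaluate_classifier(model, kept, control$threshold),
        n_removed = attr(kept, "n_removed"))
    } else {
      list(n_removed = attr(kept, "n_removed"))
    }
  }
  raw <- classifier_scores(model, features)
  key <- strsplit(rownames(features), ":", fixed = TRUE)
  track <- data.frame(
    chrom = vapply(key, `[`, character(1), 1L),
    pos = as.integer(vapply(key, `[`, character(1), 2L)),
    raw = raw, unmet = percentile_rank(raw), stringsAsFactors = FALSE)
  track$band <- assign_bands(track$unmet, thresholds)
  structure(list(model = model, metrics = metrics[c("auc", "mcc", "confusion")],
                 metrics_leakage_filtered = metrics_filtered,
                 labels = labeled, sets = sets, track = track,
                 thresholds = thresholds, params = params, control = control,
                 seqlens = seq_lengths(genome), call = cl),
            class = "unmet")
}

#' @export
print.unmet <- function(x, ...) {
  cat("Per-base difficulty-to-sequence model\n")
  cat(sprintf("  labeled sites: %d unreliable / %d reliable\n",
              sum(x$labels$label == "unreliable"),
              sum(x$labels$label == "reliable")))
  cat(sprintf("  held-out AUC %.3f, MCC %.3f\n", x$metrics$auc, x$metrics$mcc))
  cat(sprintf("  scored positions: %d (difficult %d, error-prone %d, reliable %d)\n",
              nrow(x$track), sum(x$track$band == "difficult"),
              sum(x$track$band == "error_prone"),
              sum(x$track$band == "reliable")))
  invisible(x)
}

#' Summarize a fitted difficulty model
#'
#' @param object a fitted [unmet()] object.
#' @param ... unused.
#' @return An object of class `"summary.unmet"`: label counts, held-out
#'   metrics (plus leakage-filtered metrics when computed), selected
#'   hyperparameters, feature importances and band occupancy.
#' @export
summary.unmet <- function(object, ...) {
  structure(list(
    n_labels = table(object$labels$label),
    metrics = object$metrics,
    metrics_leakage_filtered = object$metrics_leakage_filtered,
    best_params = object$model$best_params,
    importance = sort(object$model$importance, decreasing = TRUE),
    bands = table(object$track$band),
    n_scored = nrow(object$track)), class = "summary.unmet")
}

#' @export
print.summary.unmet <- function(x, ...) {
  cat("Labeled sites:\n"); print(x$n_labels)
  cat(sprintf("\nHeld-out AUC %.4f, MCC %.4f\n", x$metrics$auc, x$metrics$mcc))
  print(x$metrics$confusion)
  if (!is.null(x$metrics_leakage_filtered) &&
      !is.null(x$metrics_leakage_filtered$auc)) {
    cat(sprintf("After similarity filter (%d removed): AUC %.4f, MCC %.4f\n",
                x$metrics_leakage_filtered$n_removed,
                x$metrics_leakage_filtered$auc, x$metrics_leakage_filtered$mcc))
  }
  bp <- x$best_params
  cat(sprintf("\nSelected hyperparameters: max_depth=%d eta=%g gamma=%g subsample=%g colsample=%g\n",
              bp$max_depth, bp$eta, bp$gamma, bp$subsample, bp$colsample_bytree))
  cat("\nFeature importance (gain):\n")
  print(round(x$importance, 4))
  cat(sprintf("\n%d scored positions by band:\n", x$n_scored))
  print(x$bands)
  invisible(x)
}

#' Feature importances of a fitted model
#' @param object a fitted [unmet()] object.
#' @param ... unused.
#' @return Named numeric vector of normalized gain importances (sum 1).
#' @export
coef.unmet <- function(object, ...) object$model$importance

#' Fitted percentile scores
#' @param object a fitted [unmet()] object.
#' @param ... unused.
#' @return Numeric vector of percentile scores, named `chrom:pos`.
#' @export
fitted.unmet <- function(object, ...) {
  stats::setNames(object$track$unmet,
                  paste0(object$track$chrom, ":", object$track$pos))
}

#' Predict difficulty scores for new feature rows
#'
#' Raw scores come from the fitted booster; percentile scores place each new
#' raw score on the fitted track's percentile scale (fraction of fitted
#' positions scoring at or below it); bands cut the percentile scores at the
#' fitted thresholds.
#'
#' @param object a fitted [unmet()] object.
#' @param newdata feature matrix with the model's columns; omitted, the
#'   fitted score track is returned.
#' @param type `"unmet"` (percentile), `"raw"`, or `"band"`.
#' @param ... unused.
#' @return Numeric vector (or factor, for `type = "band"`), or the fitted
#'   track `data.frame` when `newdata` is missing.
#' @export
predict.unmet <- function(object, newdata = NULL,
                          type = c("unmet", "raw", "band"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(object$track)
  }
  raw <- classifier_scores(object$model, newdata)
  if (type == "raw") return(raw)
  ref <- sort(object$track$raw)
  u <- findInterval(raw, ref) / length(ref)
  if (type == "unmet") u else assign_bands(u, object$thresholds)
}

#' Plot a fitted difficulty model
#'
#' `type = "scores"` draws the percentile-score histogram with the band
#' thresholds; `type = "importance"` a feature-importance bar chart.
#'
#' @param x a fitted [unmet()] object.
#' @param type which panel to draw.
#' @param ... passed to the underlying graphics call.
#' @export
plot.unmet <- function(x, type = c("scores", "importance"), ...) {
  type <- match.arg(type)
  if (type == "scores") {
    graphics::hist(x$track$unmet, breaks = 50, col = "grey80", border = NA,
                   main = "Percentile difficulty scores",
                   xlab = "UNMET score", ...)
    graphics::abline(v = c(x$thresholds$error_prone, x$thresholds$difficult),
                     col = c("orange", "red"), lty = 2)
  } else {
    imp <- sort(coef(x))
    graphics::barplot(imp, horiz = TRUE, las = 1, col = "steelblue",
                      xlab = "normalized gain", main = "Feature importance", ...)
  }
  invisible(x)
}

#' Run the full pipeline on a configuration
#'
#' Simulates (or accepts) an input bundle, fits the model, extracts
#' difficult regions and, when `outdir` is given, exports the browser
#' tracks, the labels and a JSON manifest recording seeds, sizes, selected
#' hyperparameters and metrics. Re-running with the same configuration
#' reproduces the manifest (including file checksums) exactly.
#'
#' @param config a [synthetic_config()]; ignored when `bundle` is supplied.
#' @param bundle optional pre-built input bundle (as from
#'   [simulate_unmet_data()]).
#' @param outdir optional output directory.
#' @param params,control,thresholds pipeline settings; the default control
#'   uses the reduced hyperparameter grid.
#' @param min_len minimum difficult-region length in bases.
#' @param leakage_check evaluate the similarity-filtered test set as well.
#' @return `list(fit, bundle, regions, manifest)`.
#' @export
run_pipeline <- function(config = synthetic_config(), bundle = NULL,
                         outdir = NULL, params = feature_params(),
                         control = train_control(grid = "reduced"),
                         thresholds = band_thresholds(), min_len = 50L,
                         leakage_check = TRUE) {
  if (is.null(bundle)) bundle <- simulate_unmet_data(config, outdir = outdir)
  fit <- unmet(bundle$sites, bundle$genome, bundle$cds, bundle$coverage,
               bundle$annotations, params = params, control = control,
               thresholds = thresholds, leakage_check = leakage_check)
  regions <- difficult_regions(fit$track, min_len, thresholds$difficult)
  manifest <- list(
    seed = if (!is.null(bundle$config)) bundle$config$seed else NA,
    n_sites = nrow(bundle$sites),
    n_labeled = nrow(fit$labels),
    n_train = nrow(fit$sets$train$x), n_test = nrow(fit$sets$test$x),
    n_scored = nrow(fit$track),
    best_params = fit$model$best_params,
    auc = fit$metrics$auc, mcc = fit$metrics$mcc,
    confusion = as.list(fit$metrics$confusion),
    importance = as.list(round(fit$model$importance, 6)),
    bands = as.list(table(fit$track$band)),
    n_difficult_regions = nrow(regions))
  if (!is.null(fit$metrics_leakage_filtered) &&
      !is.null(fit$metrics_leakage_filtered$auc)) {
    manifest$auc_leakage_filtered <- fit$metrics_leakage_filtered$auc
    manifest$mcc_leakage_filtered <- fit$metrics_leakage_filtered$mcc
    manifest$n_similarity_removed <- fit$metrics_leakage_filtered$n_removed
  }
  if (!is.null(outdir)) {
    files <- export_tracks(fit$track, outdir, fit$seqlens, min_len,
                           thresholds$difficult)
    lab <- fit$labels
    lab$pos <- lab$pos + 1L              # 1-based in the exported TSV
    utils::write.table(lab, file.path(outdir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$files <- as.list(unname(tools::md5sum(files)))
    names(manifest$files) <- basename(files)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(fit = fit, bundle = bundle, regions = regions, manifest = manifest)
}
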