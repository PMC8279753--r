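#' Stratified fold assignment
#'
#' Permutes each class independently and deals fold numbers in round-robin,
#' so fold class proportions match the dataset's as closely as integer
#' arithmetic allows. Uses the current RNG state.
#'
#' @param labels Integer 0/1 vector.
#' @param folds Number of folds.
#' @return Integer vector of fold ids in `1:folds`.
#' @export
stratified_folds <- function(labels, folds = 5L) {
  if (min(table(labels)) < folds)
    stop(sprintf("stratification impossible: a class has fewer than %d members",
                 folds), call. = FALSE)
  assignment <- integer(length(labels))
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    assignment[sample(rows)] <- rep_len(seq_len(folds), length(rows))
  }
  assignment
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs stratified k-fold cross-validation of the sequence-to-label
#' pipeline: length normalization and encoding (deterministic per sample),
#' then per fold — mRMR selection fitted on the training fold only, applied
#' to both splits; noise-adding oversampling of the training rows only; a
#' classifier fit; confusion counts on the untouched test fold. A runtime
#' leakage guard asserts that no test-fold sample ever serves as an
#' augmentation source. Aggregate metrics are unweighted means over folds
#' (undefined fold metrics are dropped from the mean).
#'
#' @param dataset A labeled [peptide_dataset()] with at least `folds`
#'   members per class.
#' @param l_x Normalized peptide length (40 by default).
#' @param feature_set Non-empty subset of `c("bpf", "aaindex", "kmer")`.
#' @param m AAindex features retained by mRMR (50 by default); selection is
#'   skipped when the AAindex block is absent or already no wider than `m`.
#' @param augmentation An [augmentation_config()], or `NULL` to disable.
#' @param classifier A [classifier_spec()].
#' @param folds Number of folds (5 by default).
#' @param seed Integer seed governing fold assignment and all per-fold
#'   randomness (augmentation draws, classifier initialization).
#' @param standardize Center/scale features per fold? On by default: the
#'   scaler is fitted on the (augmented) training rows and applied to both
#'   splits, after augmentation so the perturbation operates on raw feature
#'   values. Raw AAindex columns span several orders of magnitude, which
#'   ill-conditions first-order neural-network training; set `FALSE` to
#'   feed raw values to the classifier. The setting is echoed in the
#'   report config.
#' @param leaky_selection Fit mRMR once on the pooled data instead of per
#'   fold. Off by default (per-fold fitting is the leakage-safe protocol);
#'   available for reproducing protocols that selected features globally.
#' @param table,kmer_conf Encoder assets, see [encode_dataset()].
#' @return A `cv_report`: config echo, per-fold confusion counts and
#'   metrics, and the aggregate metric vector.
#' @export
run_cv <- function(dataset, l_x = 40, feature_set = c("bpf", "aaindex"),
                   m = 50, augmentation = augmentation_config(),
                   classifier = classifier_spec("mlp"), folds = 5L,
                   seed = 1L, standardize = TRUE, leaky_selection = FALSE,
                   table = NULL, kmer_conf = kmer_config()) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  if (any(is.na(dataset$label)))
    stop("run_cv requires a fully labeled dataset", call. = FALSE)
  fm <- encode_dataset(dataset, l_x = l_x, feature_set = feature_set,
                       table = table, config = kmer_conf)
  set.seed(seed)
  fold_id <- stratified_folds(fm$labels, folds)
  has_aaindex <- "aaindex" %in% feature_set
  select_m <- if (has_aaindex && m > 0 && sum(fm$blocks == "aaindex") > m)
    m else NA_integer_
  global_model <- if (!is.na(select_m) && leaky_selection)
    fit_mrmr(fm, m = select_m) else NULL
  fold_counts <- vector("list", folds)
  fold_metrics <- matrix(NA_real_, nrow = folds, ncol = 5L,
                         dimnames = list(NULL,
                                         c("ACC", "PRE", "SN", "SP", "MCC")))
  for (f in seq_len(folds)) {
    fold_seed <- seed * 1000L + f
    test_rows <- which(fold_id == f)
    train <- fm_subset(fm, rows = which(fold_id != f))
    test <- fm_subset(fm, rows = test_rows)
    if (!is.na(select_m)) {
      model <- if (leaky_selection) global_model else
        fit_mrmr(train, m = select_m)
      train <- apply_selection(train, model)
      test <- apply_selection(test, model)
    }
    if (!is.null(augmentation) && augmentation$n_fraction > 0) {
      cfg <- augmentation
      if (is.null(cfg$seed)) cfg$seed <- fold_seed
      train <- augment_training_set(train, cfg)
      leaked <- intersect(train$source, rownames(test$x))
      if (length(leaked) > 0L)
        stop("leakage guard tripped: test sample(s) used as augmentation source: ",
             paste(leaked, collapse = ", "), call. = FALSE)
    }
    x_train <- train$x
    x_test <- test$x
    if (standardize) {
      mu <- colMeans(x_train)
      sdev <- apply(x_train, 2, stats::sd)
      sdev[sdev == 0 | is.na(sdev)] <- 1
      x_train <- scale(x_train, center = mu, scale = sdev)
      x_test <- scale(x_test, center = mu, scale = sdev)
    }
    fit <- fit_classifier(classifier, x_train, train$labels,
                          seed = fold_seed)
    pred <- predict_classifier(fit, x_test)
    fold_counts[[f]] <- confusion_counts(test$labels, pred)
    fold_metrics[f, ] <- compute_metrics(fold_counts[[f]])
  }
  structure(list(
    config = list(l_x = l_x, feature_set = feature_set, m = m,
                  augmentation = augmentation,
                  classifier = classifier, folds = folds, seed = seed,
                  standardize = standardize,
                  leaky_selection = leaky_selection),
    fold_metrics = data.frame(fold = seq_len(folds), fold_metrics),
    fold_counts = fold_counts,
    aggregate = colMeans(fold_metrics, na.rm = TRUE)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cfg <- x$config
  aug <- if (is.null(cfg$augmentation)) "none" else
    sprintf("a=%g, N=%g%%", cfg$augmentation$a,
            100 * cfg$augmentation$n_fraction)
  cat(sprintf("cv_report: %d-fold CV | L_X=%d | features: %s | m=%s | augmentation: %s | %s | seed %d\n",
              cfg$folds, cfg$l_x, paste(cfg$feature_set, collapse = "+"),
              cfg$m, aug, cfg$classifier$kind, cfg$seed))
  cat("  mean metrics (%):\n")
  print(round(x$aggregate, 2))
  invisible(x)
}

#' Sweep peptide length and pseudosample fraction
#'
#' Evaluates every combination of normalized length and augmentation
#' fraction with an otherwise fixed pipeline, and flags the best row by
#' maximum mean MCC (ties broken toward smaller `l_x`, then smaller
#' `n_fraction`).
#'
#' @param dataset A labeled [peptide_dataset()].
#' @param l_x_values,n_fractions Grids to sweep (defaults 40/50/60 and
#'   100/200/300%).
#' @param a Perturbation coefficient for all cells.
#' @param ... Further arguments passed to [run_cv()].
#' @return Data frame with one row per grid cell: `l_x`, `n_fraction`, the
#'   five mean metrics, and logical `best`.
#' @export
parameter_sweep <- function(dataset, l_x_values = c(40, 50, 60),
                            n_fractions = c(1, 2, 3), a = 0.005, ...) {
  grid <- expand.grid(n_fraction = n_fractions, l_x = l_x_values)[, 2:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rep <- run_cv(dataset, l_x = grid$l_x[i],
                  augmentation = augmentation_config(a = a,
                                                     n_fraction = grid$n_fraction[i]),
                  ...)
    c(rep$aggregate)
  })
  out <- cbind(grid, do.call(rbind, rows))
  ord <- order(-out$MCC, out$l_x, out$n_fraction)
  out$best <- FALSE
  out$best[ord[1]] <- TRUE
  rownames(out) <- NULL
  out
}

#' Compare feature blocks and their concatenations
#'
#' Evaluates the seven non-empty subsets of \{bpf, aaindex, kmer\} with a
#' fixed classifier and no augmentation, mirroring the ablation that
#' motivates the default bpf + aaindex representation.
#'
#' @param dataset A labeled [peptide_dataset()].
#' @param classifier A [classifier_spec()] (default MLP).
#' @param ... Further arguments passed to [run_cv()].
#' @return Data frame with one row per feature combination and the five
#'   mean metrics.
#' @export
feature_ablation <- function(dataset, classifier = classifier_spec("mlp"),
                             ...) {
  blocks <- c("bpf", "aaindex", "kmer")
  combos <- unlist(lapply(1:3, function(k)
    utils::combn(blocks, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(combos, function(fs) {
    rep <- run_cv(dataset, feature_set = fs, augmentation = NULL,
                  classifier = classifier, ...)
    c(rep$aggregate)
  })
  data.frame(features = vapply(combos, paste, character(1), collapse = "+"),
             do.call(rbind, rows))
}

#' Effect of augmentation across classifier families
#'
#' For each classifier, runs the pipeline with and without noise-adding
#' oversampling under the same seed — fold assignments are identical across
#' the pair, so each row is a paired comparison of mean MCC.
#'
#' @param dataset A labeled [peptide_dataset()].
#' @param kinds Classifier families to compare.
#' @param augmentation The [augmentation_config()] for the augmented arm.
#' @param ... Further arguments passed to [run_cv()].
#' @return Data frame with columns `classifier`, `mcc_augmented`,
#'   `mcc_plain`, `mcc_gain`.
#' @export
classifier_comparison <- function(dataset,
                                  kinds = c("mlp", "svm", "rf", "dt",
                                            "extratrees"),
                                  augmentation = augmentation_config(), ...) {
  rows <- lapply(kinds, function(kind) {
    with_aug <- run_cv(dataset, classifier = classifier_spec(kind),
                       augmentation = augmentation, ...)
    without <- run_cv(dataset, classifier = classifier_spec(kind),
                      augmentation = NULL, ...)
    data.frame(classifier = kind,
               mcc_augmented = unname(with_aug$aggregate["MCC"]),
               mcc_plain = unname(without$aggregate["MCC"]))
  })
  out <- do.call(rbind, rows)
  out$mcc_gain <- out$mcc_augmented - out$mcc_plain
  out
}
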