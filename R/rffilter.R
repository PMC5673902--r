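## Random-forest true/false call filter with bootstrap precision-recall
## model selection.

#' Train the random-forest call filter
#'
#' Runs `n_boot` bootstrap rounds in which the labelled training data are
#' split into train/test subsets (`split` fraction for training), a forest is
#' fit on the train part and a precision-recall curve computed on the held
#' out part over a fixed score-threshold grid. The operating threshold is
#' then chosen on the mean PR curve as the one maximizing recall subject to
#' precision at or above `precision_target`, and the final model is refit on
#' all of the data.
#'
#' @param features Feature `data.frame` (12 columns, see
#'   [extract_features()]).
#' @param labels Character/factor vector in `{"TP", "FP"}`; at least 20 of
#'   each class are required.
#' @param n_boot Number of bootstrap rounds (default 100).
#' @param split Training fraction per round (default 0.9).
#' @param precision_target Precision floor for operating-point selection
#'   (default 0.82).
#' @param ntree Trees per forest (default 500); `mtry` is the default
#'   square root of the feature count.
#' @param seed RNG seed recorded in the model (default 1).
#' @return Object of class `"sv_rf_filter"`: the fitted forest (`model`),
#'   `threshold`, the PR summary (`pr`: threshold grid with mean and 95%
#'   interval of precision and recall), `schema`, `seed`.
#' @export
train_filter <- function(features, labels, n_boot = 100, split = 0.9,
                         precision_target = 0.82, ntree = 500, seed = 1) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("TP", "FP")))
  if (length(unique(labels)) < 2)
    stop("training labels are degenerate: both TP and FP examples required")
  if (min(table(labels)) < 20)
    stop("need at least 20 examples of each class")
  stopifnot(identical(sort(names(features)), sort(feature_names)))
  features <- features[feature_names]
  y <- factor(labels, levels = c("FP", "TP"))
  thresholds <- seq(0, 1, by = 0.01)
  n <- nrow(features)
  with_seed(seed, {
    boot <- lapply(seq_len(n_boot), function(b) {
      idx <- sample(n, floor(split * n))
      if (length(unique(y[idx])) < 2 || length(idx) == n)
        return(NULL)
      fit <- randomForest::randomForest(features[idx, , drop = FALSE],
                                        y[idx], ntree = ntree)
      prob <- predict(fit, features[-idx, , drop = FALSE],
                      type = "prob")[, "TP"]
      truth <- y[-idx] == "TP"
      t(vapply(thresholds, function(th) {
        called <- prob >= th
        tp <- sum(called & truth)
        c(precision = if (sum(called) == 0) 1 else tp / sum(called),
          recall = if (sum(truth) == 0) NA_real_ else tp / sum(truth))
      }, c(precision = 0, recall = 0)))
    })
    boot <- boot[!vapply(boot, is.null, TRUE)]
    prec <- sapply(boot, function(m) m[, "precision"])
    rec <- sapply(boot, function(m) m[, "recall"])
    pr <- data.frame(
      threshold = thresholds,
      precision_mean = rowMeans(prec, na.rm = TRUE),
      precision_lo = apply(prec, 1, quantile, 0.025, na.rm = TRUE),
      precision_hi = apply(prec, 1, quantile, 0.975, na.rm = TRUE),
      recall_mean = rowMeans(rec, na.rm = TRUE),
      recall_lo = apply(rec, 1, quantile, 0.025, na.rm = TRUE),
      recall_hi = apply(rec, 1, quantile, 0.975, na.rm = TRUE))
    ok <- pr$precision_mean >= precision_target
    threshold <- if (any(ok)) {
      cand <- pr[ok, ]
      ## maximize recall; break recall ties toward higher precision
      best <- cand[cand$recall_mean >= max(cand$recall_mean) - 1e-12, ]
      best$threshold[which.max(best$precision_mean)]
    } else {
      ## precision target unreachable: fall back to the most precise point
      pr$threshold[which.max(pr$precision_mean)]
    }
    final <- randomForest::randomForest(features, y, ntree = ntree,
                                        importance = TRUE)
    structure(list(model = final, threshold = threshold, pr = pr,
                   precision_target = precision_target,
                   schema = feature_names, seed = seed,
                   n_boot = length(boot)),
              class = "sv_rf_filter")
  })
}

#' @export
print.sv_rf_filter <- function(x, ...) {
  cat("sv_rf_filter:", x$model$ntree, "trees;",
      x$n_boot, "bootstrap rounds\n")
  cat("operating threshold:", x$threshold,
      sprintf("(precision target %.2f)\n", x$precision_target))
  i <- which.min(abs(x$pr$threshold - x$threshold))
  cat(sprintf("mean PR at threshold: precision %.3f, recall %.3f\n",
              x$pr$precision_mean[i], x$pr$recall_mean[i]))
  invisible(x)
}

#' Feature importance of a trained filter
#'
#' Mean decrease in Gini impurity per feature, sorted decreasing.
#'
#' @param model `sv_rf_filter` object.
#' @return Named numeric vector.
#' @export
filter_importance <- function(model) {
  stopifnot(is(model, "sv_rf_filter"))
  imp <- randomForest::importance(model$model, type = 2)[, 1]
  sort(imp, decreasing = TRUE)
}

#' Apply a trained filter to calls
#'
#' Scores each call and annotates predicted class. A feature schema mismatch
#' (missing or renamed feature) is an error naming the offending columns.
#'
#' @param model `sv_rf_filter` from [train_filter()].
#' @param features Feature `data.frame` for the calls to classify.
#' @param threshold Score threshold; defaults to the model's operating
#'   threshold.
#' @return `data.frame` with `score` (P(true)) and logical `pass`, rownames
#'   preserved from `features`.
#' @export
apply_filter <- function(model, features, threshold = NULL) {
  stopifnot(is(model, "sv_rf_filter"))
  missing <- setdiff(model$schema, names(features))
  if (length(missing) > 0)
    stop("feature schema mismatch; missing feature(s): ",
         paste(missing, collapse = ", "))
  if (is.null(threshold)) threshold <- model$threshold
  score <- predict(model$model, features[model$schema], type = "prob")[, "TP"]
  data.frame(score = score, pass = score >= threshold,
             row.names = rownames(features))
}

#' Serialize / restore a trained filter
#'
#' The model is stored with its feature schema and a schema hash; loading
#' verifies the hash.
#'
#' @param model `sv_rf_filter` object.
#' @param path File path.
#' @return `path` invisibly; `load_filter` returns the model.
#' @export
save_filter <- function(model, path) {
  stopifnot(is(model, "sv_rf_filter"))
  model$schema_hash <- paste(model$schema, collapse = "|")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_filter
#' @export
load_filter <- function(path) {
  model <- readRDS(path)
  if (!is(model, "sv_rf_filter") ||
      !identical(model$schema_hash, paste(model$schema, collapse = "|")))
    stop("file does not contain a valid sv_rf_filter model")
  model
}

#' Simulate labelled feature data
#'
#' Synthetic stand-in for a curated truth-labelled training set: draws
#' TP and FP feature vectors from class-conditional distributions whose
#' separations follow the qualitative importance ordering seen in real
#' long-read call sets — allele fraction by far the most discriminative,
#' then per-side percent identity and aligned-fraction, then confidence
#' interval widths, with mapping quality least informative.
#'
#' @param n_tp,n_fp Class sizes (defaults 354 and 300).
#' @param seed RNG seed.
#' @return List with `features` (data.frame) and `labels` (`"TP"`/`"FP"`).
#' @export
simulate_feature_data <- function(n_tp = 354, n_fp = 300, seed = 1) {
  with_seed(seed, {
    n <- n_tp + n_fp
    tp <- c(rep(TRUE, n_tp), rep(FALSE, n_fp))
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    features <- data.frame(
      mapq1 = clamp(stats::rnorm(n, ifelse(tp, 58, 56), 6), 0, 60),
      mapq2 = clamp(stats::rnorm(n, ifelse(tp, 58, 56), 6), 0, 60),
      pid1 = clamp(stats::rnorm(n, ifelse(tp, 0.87, 0.80), 0.04), 0, 1),
      pid2 = clamp(stats::rnorm(n, ifelse(tp, 0.87, 0.80), 0.04), 0, 1),
      cipos1 = stats::rpois(n, ifelse(tp, 6, 14)),
      cipos2 = stats::rpois(n, ifelse(tp, 6, 14)),
      plength1 = clamp(stats::rnorm(n, ifelse(tp, 0.55, 0.40), 0.12), 0, 1),
      plength2 = clamp(stats::rnorm(n, ifelse(tp, 0.55, 0.40), 0.12), 0, 1),
      ciend1 = stats::rpois(n, ifelse(tp, 6, 14)),
      ciend2 = stats::rpois(n, ifelse(tp, 6, 14)),
      total_cov_norm = clamp(stats::rnorm(n, ifelse(tp, 2.0, 2.6), 0.5),
                             0.1, 6),
      vaf = clamp(stats::rnorm(n, ifelse(tp, 0.48, 0.07), 0.08), 0, 1))
    list(features = features[feature_names],
         labels = ifelse(tp, "TP", "FP"))
  })
}
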