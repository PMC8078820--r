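#' Feature schema for model quality assessment
#'
#' Nine features per model: global Pcons and QMeanDisCo scores, four
#' summaries of the per-residue QMeanDisCo profile (mean, median, minimum,
#' fraction of residues at or above 0.6), the modelled length and its log,
#' and the alignment Neff. The label, when present, is the model's true
#' TM-score in [0, 1].
#'
#' @return Character vector of the nine feature names.
#' @export
qa_features <- function() {
  c("pcons_global", "qmean_global", "qmean_local_mean", "qmean_local_median",
    "qmean_local_min", "qmean_local_frac06", "length", "log_length", "neff")
}

# validate a QA feature table; label column "tm" optional
check_qa_records <- function(records, labelled = FALSE) {
  missing_feat <- setdiff(qa_features(), names(records))
  if (length(missing_feat))
    stop_param("QA records missing feature(s): %s",
               paste(missing_feat, collapse = ", "))
  feat <- records[, qa_features(), drop = FALSE]
  if (any(!vapply(feat, is.numeric, TRUE)) || any(is.na(as.matrix(feat))))
    stop_param("QA records: features must be numeric with no missing values")
  if (any(records$length < 1)) stop_param("QA records: length must be >= 1")
  if (labelled) {
    if (!("tm" %in% names(records)) || any(is.na(records$tm)))
      stop_param("QA records: labelled records with a 'tm' column required")
    if (any(records$tm < 0 | records$tm > 1))
      stop_param("QA records: TM-score labels must lie in [0, 1]")
  }
  invisible(records)
}

#' Fit a random-forest TM-score regressor
#'
#' Regresses the true TM-score of a structure model on the nine
#' quality-assessment features of [qa_features()], using a random forest
#' with 240 trees and maximum depth 60. Training is fully reproducible
#' given `seed` (single-threaded forest growth).
#'
#' @param records labelled QA feature table (data frame with the
#'   [qa_features()] columns and a `tm` label column); at least 20 rows.
#' @param n_trees number of trees (default 240).
#' @param max_depth maximum tree depth (default 60).
#' @param seed RNG seed for forest growth.
#' @return An object of class `qa_forest` with `print`, `summary`,
#'   [predict.qa_forest()] and [feature_importance()] methods.
#' @export
qa_forest <- function(records, n_trees = 240L, max_depth = 60L, seed = 1L) {
  check_qa_records(records, labelled = TRUE)
  if (nrow(records) < 20L)
    stop_param(paste("qa_forest: need >= 20 labelled records, got %d;",
                     "consider augmenting with make_qa_table()"), nrow(records))
  if (!is_count(n_trees) || n_trees < 1) stop_param("qa_forest: n_trees must be >= 1")
  if (!is_count(max_depth) || max_depth < 1) stop_param("qa_forest: max_depth must be >= 1")
  dat <- records[, c(qa_features(), "tm"), drop = FALSE]
  fit <- ranger::ranger(
    tm ~ ., data = dat, num.trees = n_trees, max.depth = max_depth,
    importance = "impurity", seed = seed, num.threads = 1L)
  structure(list(forest = fit, schema = qa_features(),
                 n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 seed = as.integer(seed), n_train = nrow(records)),
            class = "qa_forest")
}

#' @export
print.qa_forest <- function(x, ...) {
  cat(sprintf("qa_forest: %d trees, max depth %d, %d training models (seed %d)\n",
              x$n_trees, x$max_depth, x$n_train, x$seed))
  cat(sprintf("  OOB MSE: %.4f\n", x$forest$prediction.error))
  invisible(x)
}

#' @export
summary.qa_forest <- function(object, ...) {
  print(object)
  cat("Feature importance (normalized, descending):\n")
  imp <- feature_importance(object)
  for (r in seq_len(nrow(imp)))
    cat(sprintf("  %-22s %.4f\n", imp$feature[r], imp$importance[r]))
  invisible(imp)
}

#' Predict TM-scores for QA records
#'
#' @param object a fitted [qa_forest()].
#' @param newdata QA feature table with the training schema.
#' @param ... unused.
#' @return Numeric vector of predicted TM-scores in [0, 1] (clipped), one
#'   per row of `newdata`, in order.
#' @export
predict.qa_forest <- function(object, newdata, ...) {
  check_qa_records(newdata)
  pred <- stats::predict(object$forest,
                         data = newdata[, object$schema, drop = FALSE],
                         num.threads = 1L, seed = object$seed)$predictions
  clip01(pred)
}

#' Ranked feature importance of a fitted QA forest
#'
#' Impurity importances, normalized to sum to 1 and sorted descending.
#'
#' @param object a fitted [qa_forest()].
#' @return Data frame with columns `feature`, `importance`.
#' @export
feature_importance <- function(object) {
  if (!inherits(object, "qa_forest"))
    stop_param("feature_importance: not a fitted qa_forest")
  imp <- ranger::importance(object$forest)
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  ord <- order(-imp)
  data.frame(feature = names(imp)[ord], importance = as.numeric(imp[ord]),
             row.names = NULL)
}

#' Cross-validate the TM-score regressor
#'
#' Shuffles the records with a seeded permutation, splits them into `folds`
#' disjoint folds of near-equal size (the first `n %% folds` folds take the
#' extra record), and reports per-fold and mean held-out mean absolute
#' error, Pearson correlation, and accuracy at the TM 0.5 correctness
#' threshold (the fraction of held-out models whose predicted and true
#' correct/incorrect calls agree).
#'
#' @param records labelled QA feature table.
#' @param folds number of folds (default 5).
#' @param n_trees,max_depth,seed forest settings as in [qa_forest()].
#' @return A list of class `qa_cv`: `per_fold` data frame (`fold`, `n`,
#'   `mae`, `pearson_r`, `accuracy`) and `mean` named vector.
#' @export
qa_cross_validate <- function(records, folds = 5L, n_trees = 240L,
                              max_depth = 60L, seed = 1L) {
  check_qa_records(records, labelled = TRUE)
  n <- nrow(records)
  if (!is_count(folds) || folds < 2) stop_param("qa_cross_validate: folds must be >= 2")
  if (folds > n) stop_param("qa_cross_validate: folds (%d) exceed records (%d)", folds, n)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% folds, folds) + (seq_len(folds) <= n %% folds)
  assignment <- integer(n)
  assignment[perm] <- rep.int(seq_len(folds), sizes)
  per_fold <- lapply(seq_len(folds), function(f) {
    test <- assignment == f
    fit <- qa_forest(records[!test, , drop = FALSE], n_trees, max_depth,
                     seed = seed + f)
    pred <- predict(fit, records[test, , drop = FALSE])
    truth <- records$tm[test]
    data.frame(fold = f, n = sum(test),
               mae = mean(abs(pred - truth)),
               pearson_r = suppressWarnings(stats::cor(pred, truth)),
               accuracy = mean(call_model_correct(pred) ==
                                 call_model_correct(truth)))
  })
  per_fold <- do.call(rbind, per_fold)
  structure(list(per_fold = per_fold,
                 mean = c(mae = mean(per_fold$mae),
                          pearson_r = mean(per_fold$pearson_r),
                          accuracy = mean(per_fold$accuracy)),
                 folds = folds, seed = seed),
            class = "qa_cv")
}

#' @export
print.qa_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d):\n", x$folds, x$seed))
  print(format(x$per_fold, digits = 4), row.names = FALSE)
  cat(sprintf("mean: MAE %.4f, Pearson r %.4f, accuracy@0.5 %.1f%%\n",
              x$mean[["mae"]], x$mean[["pearson_r"]],
              100 * x$mean[["accuracy"]]))
  invisible(x)
}

#' Persist / restore a fitted QA forest
#'
#' The container records the forest, feature schema, hyperparameters and
#' seed, so a restored model is fully documented.
#'
#' @param object a [qa_forest()].
#' @param path file path.
#' @return `path` invisibly; `read_qa_model` returns the `qa_forest`.
#' @export
write_qa_model <- function(object, path) {
  stopifnot(inherits(object, "qa_forest"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_qa_model
#' @export
read_qa_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "qa_forest")) stop_param("read_qa_model: not a qa_forest container")
  obj
}

#' Read / write QA feature tables
#'
#' Tab-separated with header; columns `model_id`, the nine [qa_features()],
#' and optionally `tm`.
#'
#' @param source,path file paths.
#' @param records data frame to write.
#' @return `read_qa_table`: the data frame; `write_qa_table`: `path`.
#' @export
read_qa_table <- function(source) {
  tab <- utils::read.table(source, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  check_qa_records(tab)
  tab
}

#' @rdname read_qa_table
#' @export
write_qa_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
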