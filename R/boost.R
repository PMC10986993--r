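#' Gradient-boosting tuning protocol
#'
#' Configuration for the boosted-trees comparison: the optimal number of
#' boosting rounds is chosen by 100 random 2/3 train / 1/3 validation
#' partitions of the training data, each run stopping early when the
#' validation negative log-likelihood fails to improve for 4 rounds; the
#' final model is fit on the full training data with the rounded mean of the
#' per-partition best rounds.
#'
#' @param n_partitions Number of random inner partitions (default 100).
#' @param train_fraction Inner training fraction (default 2/3).
#' @param early_stopping_rounds Non-improving rounds before stopping
#'   (default 4).
#' @param max_rounds Upper bound on boosting rounds per run (default 500).
#' @param seed Integer seed.
#' @param params Extra `xgboost` parameters merged over the defaults
#'   (binary logistic objective, log-loss metric, single thread).
#' @return A list of class `boost_config`.
#' @export
boost_config <- function(n_partitions = 100L, train_fraction = 2 / 3,
                         early_stopping_rounds = 4L, max_rounds = 500L,
                         seed = 1L, params = list()) {
  structure(list(n_partitions = as.integer(n_partitions),
                 train_fraction = train_fraction,
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 max_rounds = as.integer(max_rounds),
                 seed = as.integer(seed), params = params),
            class = "boost_config")
}

#' Boosted-trees comparison model
#'
#' Fits a binary-logistic gradient-boosted tree model to a binary antigen,
#' tuning the number of boosting rounds by the protocol in [boost_config()].
#' This is the comparison arm against the random forest pipeline; no
#' importance-based feature selection is applied.
#'
#' @param X Complete numeric matrix (samples x variants).
#' @param y Binary calls (`"positive"` / `"negative"`), one per row.
#' @param config A [boost_config()].
#' @return A list of class `boosted_model`: `model` (the xgboost booster fit
#'   on all data), `best_rounds` (per-partition best iteration),
#'   `final_rounds` (rounded mean, >= 1), `classes`, `config`.
#' @export
fit_boosted_comparison <- function(X, y, config = boost_config()) {
  if (inherits(X, "dosage_matrix")) X <- X$dosages
  if (anyNA(X)) stop("X has missing entries; impute them first (mean_impute_missing)")
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- as.character(y)[keep]
  lev <- class_levels(y)
  if (!identical(lev, c("negative", "positive"))) {
    stop("boosted comparison supports binary antigens only")
  }
  y01 <- as.integer(y == "positive")
  if (length(unique(y01)) < 2L) stop("need both classes to train")

  params <- utils::modifyList(
    list(objective = "binary:logistic", eval_metric = "logloss", nthread = 1),
    config$params
  )
  n <- nrow(X)
  best_rounds <- integer(config$n_partitions)
  for (k in seq_len(config$n_partitions)) {
    idx <- withr::with_seed(config$seed + k, sample(n))
    n_tr <- floor(config$train_fraction * n)
    tr <- idx[seq_len(n_tr)]
    va <- idx[-seq_len(n_tr)]
    # degenerate single-class folds are re-drawn deterministically
    tries <- 0L
    while ((length(unique(y01[tr])) < 2L || length(unique(y01[va])) < 2L) && tries < 100L) {
      tries <- tries + 1L
      idx <- withr::with_seed(config$seed + k + 100000L * tries, sample(n))
      tr <- idx[seq_len(n_tr)]
      va <- idx[-seq_len(n_tr)]
    }
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y01[tr])
    dva <- xgboost::xgb.DMatrix(X[va, , drop = FALSE], label = y01[va])
    fit <- xgboost::xgb.train(params = params, data = dtr,
                              nrounds = config$max_rounds,
                              evals = list(validation = dva),
                              early_stopping_rounds = config$early_stopping_rounds,
                              verbose = 0)
    best_rounds[k] <- xgboost::xgb.attributes(fit)$best_iteration
  }
  final_rounds <- max(1L, as.integer(round(mean(best_rounds))))
  dall <- xgboost::xgb.DMatrix(X, label = y01)
  model <- xgboost::xgb.train(params = params, data = dall,
                              nrounds = final_rounds, verbose = 0)
  structure(list(model = model, best_rounds = best_rounds,
                 final_rounds = final_rounds,
                 classes = lev, config = config),
            class = "boosted_model")
}

#' @rdname fit_boosted_comparison
#' @param object A `boosted_model`.
#' @param newdata Matrix with the training columns.
#' @param ... Unused.
#' @return `predict()` returns the antigen-positive probability per sample.
#' @export
predict.boosted_model <- function(object, newdata, ...) {
  if (inherits(newdata, "dosage_matrix")) newdata <- newdata$dosages
  stats::predict(object$model, xgboost::xgb.DMatrix(newdata))
}
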