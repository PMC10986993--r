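#' Forest hyperparameters
#'
#' Defaults follow the published protocol: 2,000 trees, Gini impurity
#' splits, `mtry` equal to the number of offered variants divided by two
#' (floored, minimum 1), inverse-class-frequency weights for the unbalanced
#' typing classes, and out-of-bag permutation importance.
#'
#' @param n_trees Number of trees (default 2000).
#' @param seed Integer seed; fixes bootstrap, split and permutation RNG.
#' @param mtry Candidate variables per split; `NULL` applies the
#'   variants-divided-by-two rule (recomputed after feature selection).
#' @param class_weights `"inverse_frequency"` or a named numeric vector.
#' @param importance_threshold Strict lower bound on permutation importance
#'   for a variant to be kept (default 0).
#' @param min_node_size Minimal node size; `NULL` uses the ranger default.
#' @param num_threads Threads for tree growing (default 1, deterministic).
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 2000L, seed = 1L, mtry = NULL,
                          class_weights = "inverse_frequency",
                          importance_threshold = 0,
                          min_node_size = NULL, num_threads = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees), seed = as.integer(seed),
                 mtry = mtry, class_weights = class_weights,
                 importance_threshold = importance_threshold,
                 min_node_size = min_node_size,
                 num_threads = as.integer(num_threads)),
            class = "forest_config")
}

mtry_rule <- function(p) max(1L, p %/% 2L)

#' Inverse-frequency class weights
#'
#' For `K` classes with `n_c` calls in class `c` out of `n`, the weight is
#' `n / (K * n_c)`, so that the weighted class totals are equal. Applied to
#' the split criterion to counter the strong class imbalance of rare
#' antigens.
#'
#' @param y Vector of class calls (no missing values).
#' @return Named numeric vector of weights, one per observed class.
#' @examples
#' compute_class_weights(rep(c("positive", "negative"), c(56, 1136)))
#' @export
compute_class_weights <- function(y) {
  tab <- table(as.character(y))
  if (length(tab) < 2L) stop("class weights need at least two classes")
  n <- sum(tab)
  w <- n / (length(tab) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

class_levels <- function(y) {
  u <- unique(as.character(y[!is.na(y)]))
  if (setequal(u, c("negative", "positive"))) c("negative", "positive") else sort(u)
}

#' Train a class-weighted probability forest
#'
#' Grows `config$n_trees` trees on bootstrap samples (size n, with
#' replacement) with per-node Gini splits over `mtry` candidate variants.
#' Terminal nodes store class frequencies, whose average over trees is the
#' posterior probability. Out-of-bag memberships are recorded for error and
#' importance estimation. Fully reproducible for a fixed seed.
#'
#' @param X Complete numeric matrix (samples x variants); missing entries are
#'   an error — run [mean_impute_missing()] first.
#' @param y Class calls, one per row of `X` (at least two classes).
#' @param config A [forest_config()].
#' @param importance `"permutation"` (out-of-bag permutation importance) or
#'   `"none"` (used for the post-selection refit).
#' @return A list of class `trained_forest`: the ranger `fit`, `classes`,
#'   `variant_keys`, `mtry`, `class_weights`, `config`.
#' @export
train_forest <- function(X, y, config = forest_config(), importance = "permutation") {
  if (inherits(X, "dosage_matrix")) X <- X$dosages
  if (anyNA(X)) stop("X has missing entries; impute them first (mean_impute_missing)")
  if (ncol(X) == 0L) stop("no variants offered (p = 0)")
  if (nrow(X) != length(y)) stop("length(y) must equal nrow(X)")
  lev <- class_levels(y)
  if (length(lev) < 2L) stop("need at least two classes to train")
  yf <- factor(as.character(y), levels = lev)

  cw <- config$class_weights
  if (identical(cw, "inverse_frequency")) cw <- compute_class_weights(yf)
  cw <- cw[lev]
  mtry <- if (is.null(config$mtry)) mtry_rule(ncol(X)) else config$mtry

  args <- list(x = X, y = yf, num.trees = config$n_trees, mtry = mtry,
               probability = TRUE, splitrule = "gini",
               importance = importance, class.weights = unname(cw),
               seed = config$seed, num.threads = config$num_threads,
               verbose = FALSE)
  if (!is.null(config$min_node_size)) args$min.node.size <- config$min_node_size
  fit <- do.call(ranger::ranger, args)

  structure(list(fit = fit, classes = lev, variant_keys = colnames(X),
                 mtry = mtry, class_weights = cw, config = config),
            class = "trained_forest")
}

#' Out-of-bag permutation importance
#'
#' The importance of a variant is the mean decrease in out-of-bag accuracy
#' when its values are permuted among each tree's out-of-bag samples. A
#' variant statistically independent of the phenotype has importance ~0 in
#' expectation; informative variants score strictly positive.
#'
#' @param tf A [train_forest()] result (trained with
#'   `importance = "permutation"`).
#' @return Named numeric vector, one importance per offered variant.
#' @export
permutation_importance <- function(tf) {
  stopifnot(inherits(tf, "trained_forest"))
  imp <- tf$fit$variable.importance
  if (is.null(imp)) stop("forest was trained without permutation importance")
  imp
}

#' Importance-based feature selection
#'
#' Keeps the variants with permutation importance strictly greater than the
#' threshold (default 0), sorted by descending importance. The model is then
#' refit on the selected variants only.
#'
#' @param importances Named numeric vector from [permutation_importance()].
#' @param threshold Strict lower bound (default 0; an importance exactly at
#'   the threshold is excluded).
#' @param antigen Optional antigen name used in the error message when no
#'   variant passes — such a model cannot be fit (failed classification).
#' @return Character vector of selected variant keys, most important first.
#' @export
select_important <- function(importances, threshold = 0, antigen = NULL) {
  keep <- importances[!is.na(importances) & importances > threshold]
  if (length(keep) == 0L) {
    stop(sprintf("no variant with importance > %g%s: model cannot be fit",
                 threshold,
                 if (is.null(antigen)) "" else paste0(" for antigen '", antigen, "'")))
  }
  names(sort(keep, decreasing = TRUE))
}

#' Out-of-bag misclassification frequency
#'
#' The fraction of samples whose out-of-bag class call differs from the
#' typing. Binary calls use the posterior rule (`PP > 0.5` positive);
#' multi-class calls take the highest-probability class. Samples that were
#' never out of bag are excluded and counted in the `n_excluded` attribute.
#'
#' @param tf A [train_forest()] result.
#' @param y The training class calls.
#' @return Misclassification fraction in \[0, 1\].
#' @export
oob_prediction_error <- function(tf, y) {
  stopifnot(inherits(tf, "trained_forest"))
  P <- tf$fit$predictions
  never <- apply(P, 1L, function(r) all(is.nan(r)))
  P <- P[!never, , drop = FALSE]
  yy <- as.character(y)[!never]
  pred <- posterior_to_calls(P, tf$classes)
  err <- mean(pred != yy)
  attr(err, "n_excluded") <- sum(never)
  err
}

posterior_to_calls <- function(P, classes, threshold = 0.5) {
  colnames(P) <- classes
  if (identical(classes, c("negative", "positive"))) {
    ifelse(P[, "positive"] > threshold, "positive", "negative")
  } else {
    classes[max.col(P, ties.method = "first")]
  }
}

# Flatten a grown ranger forest into plain arrays: per tree, 1-based child
# pointers (0 = terminal), split variable index, split value, and a
# node x class matrix of terminal class frequencies. This portable form is
# what predict_posterior() traverses and what model bundles serialize.
flatten_forest <- function(tf) {
  f <- tf$fit$forest
  K <- length(tf$classes)
  # terminal class counts are ordered by forest$class.values (integer codes
  # of the factor levels, in training-data order); re-order to level order
  perm <- match(seq_len(K), f$class.values)
  lapply(seq_len(f$num.trees), function(t) {
    left <- f$child.nodeIDs[[t]][[1L]]
    right <- f$child.nodeIDs[[t]][[2L]]
    tc <- f$terminal.class.counts[[t]]
    n_nodes <- length(left)
    probs <- matrix(0, n_nodes, K)
    term <- which(left == 0L & right == 0L)
    for (nd in term) probs[nd, ] <- tc[[nd]][perm]
    list(left = as.integer(left), right = as.integer(right),
         varid = as.integer(f$split.varIDs[[t]]) + 1L,
         split = as.numeric(f$split.values[[t]]),
         probs = probs)
  })
}

#' Fit a per-antigen classification model
#'
#' The full modelling pipeline for one antigen: train an initial
#' class-weighted forest on all offered variants, compute out-of-bag
#' permutation importance, keep the variants with importance strictly above
#' the threshold, and refit on those only (with `mtry` recomputed from the
#' selected count). The refit forest, the selection, the training dosage
#' means (used for reference-mode imputation during cross-cohort transfer)
#' and the out-of-bag error are packaged into a portable model object.
#'
#' @param X Complete dosage matrix (matrix or [dosage_matrix()]) of the
#'   variants offered to the antigen — typically all variants of the owning
#'   blood group system's gene regions, with 2,000 bp flanks.
#' @param y Typing calls aligned with the rows of `X`; samples with missing
#'   calls are dropped.
#' @param antigen,system Antigen and blood group system names.
#' @param config A [forest_config()].
#' @return An object of class `antigen_model`: fields `antigen`, `system`,
#'   `classes`, `input_variants`, `importance` (all offered variants),
#'   `selected` (data frame `key`, `importance`, descending), `trees`
#'   (flattened forest), `training_means`, `oob_error`, `n_train`, `config`.
#'   The live ranger fit is attached as attribute `"ranger_fit"` (not
#'   serialized).
#' @export
fit_antigen_model <- function(X, y, antigen = "antigen", system = "", config = forest_config()) {
  if (inherits(X, "dosage_matrix")) X <- X$dosages
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- as.character(y)[keep]

  initial <- train_forest(X, y, config, importance = "permutation")
  imp <- permutation_importance(initial)
  sel <- select_important(imp, config$importance_threshold, antigen = antigen)

  refit_cfg <- config
  refit_cfg$mtry <- if (is.null(config$mtry)) mtry_rule(length(sel)) else config$mtry
  refit <- train_forest(X[, sel, drop = FALSE], y, refit_cfg, importance = "none")

  model <- structure(list(
    antigen = antigen,
    system = system,
    classes = refit$classes,
    input_variants = colnames(X),
    importance = imp,
    selected = data.frame(key = sel, importance = unname(imp[sel]),
                          stringsAsFactors = FALSE),
    trees = flatten_forest(refit),
    n_trees = config$n_trees,
    training_means = colMeans(X[, sel, drop = FALSE]),
    oob_error = as.numeric(oob_prediction_error(refit, y)),
    n_train = nrow(X),
    class_weights = refit$class_weights,
    config = list(n_trees = config$n_trees, seed = config$seed,
                  mtry_initial = initial$mtry, mtry_refit = refit$mtry,
                  importance_threshold = config$importance_threshold)
  ), class = "antigen_model")
  attr(model, "ranger_fit") <- refit
  model
}

#' @export
print.antigen_model <- function(x, ...) {
  cat(sprintf("<antigen_model> %s (%s): %d/%d variants selected, OOB error %.3g\n",
              x$antigen, x$system, nrow(x$selected), length(x$input_variants),
              x$oob_error))
  invisible(x)
}

#' Posterior antigen probabilities
#'
#' For each sample, the posterior probability of each class is the mean over
#' trees of the terminal-node class frequency the sample lands in. The
#' prediction is an in-package traversal of the stored tree arrays, so a
#' model bundle reloaded from disk predicts identically to the in-run model.
#'
#' @param model An [fit_antigen_model()] result (or reloaded bundle).
#' @param newdata A [dosage_matrix()] or numeric matrix whose columns cover
#'   the model's selected variants (see [harmonize_to_model()]); must be
#'   fully imputed.
#' @return Matrix samples x classes of posterior probabilities; rows sum
#'   to 1. For binary models the `"positive"` column is the antigen-positive
#'   posterior.
#' @export
predict_posterior <- function(model, newdata) {
  stopifnot(inherits(model, "antigen_model"))
  X <- if (inherits(newdata, "dosage_matrix")) newdata$dosages else newdata
  want <- model$selected$key
  if (!all(want %in% colnames(X))) {
    stop("newdata lacks model variants; run harmonize_to_model() first")
  }
  X <- X[, want, drop = FALSE]
  if (anyNA(X)) stop("newdata has missing entries; run mean_impute_missing() first")

  n <- nrow(X)
  K <- length(model$classes)
  acc <- matrix(0, n, K)
  for (tree in model$trees) {
    cur <- rep(1L, n)
    left <- tree$left
    right <- tree$right
    varid <- tree$varid
    split <- tree$split
    repeat {
      term <- left[cur] == 0L & right[cur] == 0L
      if (all(term)) break
      i <- which(!term)
      ci <- cur[i]
      goleft <- X[cbind(i, varid[ci])] <= split[ci]
      cur[i] <- ifelse(goleft, left[ci], right[ci]) + 1L
    }
    acc <- acc + tree$probs[cur, , drop = FALSE]
  }
  pp <- acc / length(model$trees)
  dimnames(pp) <- list(rownames(X), model$classes)
  pp
}

#' Posterior-probability calling
#'
#' Binary rule: a sample is called antigen positive iff its positive-class
#' posterior exceeds the threshold; a posterior exactly at the threshold is
#' called negative (`PP > 0.5` positive, `PP <= 0.5` negative). Multi-class
#' posteriors are called by the highest-probability class.
#'
#' @param pp Posterior matrix from [predict_posterior()], or a numeric
#'   vector of antigen-positive posteriors.
#' @param threshold Binary calling threshold (default 0.5).
#' @return Character vector of calls.
#' @export
classify_calls <- function(pp, threshold = 0.5) {
  if (is.matrix(pp)) {
    classes <- colnames(pp)
    if (is.null(classes)) stop("posterior matrix must carry class names")
    posterior_to_calls(pp, classes, threshold)
  } else {
    ifelse(pp > threshold, "positive", "negative")
  }
}
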