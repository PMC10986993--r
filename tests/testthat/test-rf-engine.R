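sep_toy <- function(n_pos = 30L, n_neg = 70L, p = 6L, seed = 2L) {
  # one perfectly separating variant among noise
  withr::with_seed(seed, {
    X <- matrix(round(runif((n_pos + n_neg) * p, 0, 2) * 1024) / 1024,
                n_pos + n_neg, p)
    y <- c(rep("positive", n_pos), rep("negative", n_neg))
    X[, 1] <- ifelse(y == "positive", 2, 0)
    rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
    colnames(X) <- variant_key("1", seq_len(p) * 100L, "A", "G")
    list(X = X, y = y)
  })
}

test_that("class weights equalize weighted class totals", {
  expect_equal(unname(compute_class_weights(rep(c("a", "b"), each = 50))), c(1, 1))

  # 56 positives vs 1,136 negatives: weight ratio pos:neg = 1136:56
  w <- compute_class_weights(rep(c("positive", "negative"), c(56, 1136)))
  expect_equal(w[["positive"]] / w[["negative"]], 1136 / 56)

  # three classes 10/10/80: weights proportional to inverse frequency
  w3 <- compute_class_weights(rep(c("A", "B", "O"), c(10, 10, 80)))
  expect_equal(unname(w3 / w3[["O"]]), c(8, 8, 1))
  # n / (K * n_c) exactly
  expect_equal(unname(w3), 100 / (3 * c(10, 10, 80)))

  expect_error(compute_class_weights(rep("a", 5)), "two classes")
})

test_that("training demands complete data and applies the mtry rule", {
  toy <- sep_toy(p = 57L)
  cfg <- forest_config(n_trees = 50L, seed = 1L)
  Xna <- toy$X
  Xna[1, 1] <- NA
  expect_error(train_forest(Xna, toy$y, cfg), "impute")
  expect_error(train_forest(toy$X[, 0, drop = FALSE], toy$y, cfg), "p = 0")

  tf <- train_forest(toy$X, toy$y, cfg)
  expect_equal(tf$mtry, 28L)              # floor(57 / 2)
  expect_equal(tf$fit$num.trees, 50L)
  expect_equal(forest_config()$n_trees, 2000L)
})

test_that("a separating variant yields zero OOB error and top importance", {
  toy <- sep_toy()
  tf <- train_forest(toy$X, toy$y, forest_config(n_trees = 200L, seed = 4L))
  err <- oob_prediction_error(tf, toy$y)
  expect_equal(as.numeric(err), 0)
  imp <- permutation_importance(tf)
  expect_length(imp, ncol(toy$X))
  expect_equal(names(which.max(imp)), colnames(toy$X)[1])

  # vote-tally oracle: recount the out-of-bag calls by hand
  P <- tf$fit$predictions
  in_bag <- apply(P, 1, function(r) all(is.nan(r)))
  manual <- mean(ifelse(P[!in_bag, "positive"] > 0.5, "positive", "negative") !=
                   toy$y[!in_bag])
  expect_equal(as.numeric(err), manual)
})

test_that("null variables have near-zero importance in expectation", {
  withr::with_seed(31, {
    imps <- replicate(8, {
      n <- 150
      X <- matrix(sample(0:2, n * 4, replace = TRUE), n, 4)
      rownames(X) <- sprintf("S%03d", 1:n)
      colnames(X) <- variant_key("1", 1:4 * 10L, "A", "G")
      y <- random_calls(n)  # independent of X
      tf <- train_forest(X, y, forest_config(n_trees = 150L, seed = sample.int(1e6, 1)))
      mean(permutation_importance(tf))
    })
  })
  expect_lt(abs(mean(imps)), 0.02)
})

test_that("selection keeps strictly positive importances, sorted", {
  imp <- c(a = 0.5, b = 0, c = -0.1, d = 0.2, e = 1e-9)
  sel <- select_important(imp)
  expect_identical(sel, c("a", "d", "e"))              # 0 excluded: strict
  expect_identical(sel, names(sort(imp[imp > 0], decreasing = TRUE)))
  expect_error(select_important(c(x = -1, y = 0), antigen = "Kn"), "Kn")

  # brute-force filter oracle on random vectors
  withr::with_seed(5, {
    for (i in 1:40) {
      v <- stats::setNames(rnorm(20), paste0("v", 1:20))
      got <- select_important(v, threshold = 0.1)
      expect_setequal(got, names(v)[v > 0.1])
      expect_false(is.unsorted(rev(v[got])))
    }
  })
})

test_that("the fit pipeline selects the causal variant and refits on it", {
  co <- tiny_cohort()
  m <- tiny_k_model()
  expect_true(all(co$truth$K$causal_keys %in% m$selected$key))
  expect_true(all(m$selected$importance > 0))
  expect_true(all(m$selected$key %in% m$input_variants))
  expect_equal(m$config$mtry_refit, max(1L, nrow(m$selected) %/% 2L))
  # training means are the column means of the training matrix
  expect_equal(m$training_means,
               colMeans(co$dosages$dosages[, m$selected$key, drop = FALSE]))
  expect_gte(m$oob_error, 0)
  expect_lte(m$oob_error, 1)
})

test_that("fitting is deterministic for a fixed seed", {
  co <- tiny_cohort()
  cfg <- forest_config(n_trees = 100L, seed = 77L)
  m1 <- fit_antigen_model(co$dosages$dosages, co$phenotypes$K, "K", "Kell", cfg)
  m2 <- fit_antigen_model(co$dosages$dosages, co$phenotypes$K, "K", "Kell", cfg)
  expect_identical(m1$selected, m2$selected)
  expect_identical(predict_posterior(m1, co$dosages$dosages),
                   predict_posterior(m2, co$dosages$dosages))
})

test_that("posteriors equal the independent forest prediction and normalize", {
  co <- tiny_cohort()
  m <- tiny_k_model()
  X <- co$dosages$dosages
  pp <- predict_posterior(m, X)
  expect_true(all(pp >= 0 & pp <= 1))
  expect_equal(unname(rowSums(pp)), rep(1, nrow(pp)))

  ref <- predict(attr(m, "ranger_fit")$fit, X[, m$selected$key, drop = FALSE],
                 num.threads = 1)$predictions
  expect_lt(max(abs(pp - ref)), 1e-12)

  # constant input: every sample receives the identical posterior
  Xc <- X[, m$selected$key, drop = FALSE]
  Xc[] <- rep(m$training_means, each = nrow(Xc))
  ppc <- predict_posterior(m, Xc)
  expect_equal(unname(ppc), matrix(ppc[1, ], nrow(Xc), 2, byrow = TRUE))

  expect_error(predict_posterior(m, X[, 1:3]), "harmonize_to_model")
  Xna <- X[, m$selected$key, drop = FALSE]
  Xna[1, 1] <- NA
  expect_error(predict_posterior(m, Xna), "mean_impute_missing")
})

test_that("posterior calling uses the strict 0.5 rule", {
  expect_equal(classify_calls(c(0.51, 0.5, 0.0)),
               c("positive", "negative", "negative"))
  pp <- matrix(c(0.49, 0.5, 0.51, 0.51, 0.5, 0.49), ncol = 2,
               dimnames = list(NULL, c("negative", "positive")))
  expect_equal(classify_calls(pp), c("positive", "negative", "negative"))
})

test_that("class weighting attains full sensitivity on a 4/400 imbalanced toy", {
  toy <- sep_toy(n_pos = 4L, n_neg = 400L, seed = 8L)
  m <- fit_antigen_model(toy$X, toy$y, "rare", config = forest_config(n_trees = 300L, seed = 6L))
  calls <- classify_calls(predict_posterior(m, toy$X))
  met <- accuracy_metrics(confusion_counts(toy$y, calls))
  expect_equal(met$sensitivity, 1)
})

test_that("dropping the causal variant never helps held-out accuracy", {
  # tag SNPs at r^2 < 1 cannot beat the causal variant itself (in expectation)
  deltas <- vapply(1:10, function(s) {
    cfg <- sim_cohort_config(
      n_samples = 260L,
      genes = list(sim_gene("G1", "Sys1", "2", 1000001L, 12L)),
      antigens = list(antigen_sim_model("Ag", "Sys1", "G1", "dominant", 0.25,
                                        n_tag_snps = 2L, tag_r2 = 0.7)),
      dosage_noise_sd = 0.05, seed = 1000L + s)
    co <- simulate_cohort(cfg)
    plan <- split_cohort(rownames(co$dosages$dosages), 0.5, seed = s)
    X <- co$dosages$dosages
    y <- stats::setNames(co$phenotypes$Ag, co$phenotypes$sample_id)
    ba <- function(cols) {
      m <- fit_antigen_model(X[plan$train_ids, cols, drop = FALSE],
                             y[plan$train_ids], "Ag",
                             config = forest_config(n_trees = 150L, seed = s))
      calls <- classify_calls(predict_posterior(m, X[plan$test_ids, cols, drop = FALSE]))
      accuracy_metrics(confusion_counts(y[plan$test_ids], calls))$balanced_accuracy
    }
    full <- ba(colnames(X))
    no_causal <- ba(setdiff(colnames(X), co$truth$Ag$causal_keys))
    full - no_causal
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})

test_that("model bundles reload to bit-identical predictions", {
  co <- tiny_cohort()
  m <- tiny_k_model()
  dir <- tempfile()
  save_bundle(m, dir)
  m2 <- load_bundle(dir)
  expect_identical(predict_posterior(m2, co$dosages$dosages),
                   predict_posterior(m, co$dosages$dosages))
  expect_identical(m2$training_means, m$training_means)
  expect_identical(m2$selected, m$selected)
  expect_equal(m2$oob_error, m$oob_error)
  expect_error(load_bundle(tempfile()), "bundle")
})
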