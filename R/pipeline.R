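#' Antigen to blood group system mapping
#'
#' Built-in mapping of standard RBC antigen / HPA-1 names to their owning
#' systems, used to pick the gene regions offered to each antigen's model.
#' Unknown antigens fall back to their own name (a system named like the
#' antigen), and a user-supplied map overrides both.
#'
#' @param antigens Character vector of antigen names.
#' @param extra Optional named character vector `antigen -> system`.
#' @return Character vector of system names.
#' @export
antigen_system <- function(antigens, extra = NULL) {
  map <- c(
    K = "Kell", k = "Kell", Kpa = "Kell", Kpb = "Kell", Ula = "Kell",
    Jka = "Kidd", Jkb = "Kidd",
    Fya = "Duffy", Fyb = "Duffy",
    M = "MNS", N = "MNS", S = "MNS", s = "MNS",
    Lua = "Lutheran", Lub = "Lutheran",
    C = "Rh", c = "Rh", Cw = "Rh", Cx = "Rh", D = "Rh", E = "Rh", e = "Rh",
    hrB = "Rh", hrS = "Rh",
    Coa = "Colton", Cob = "Colton",
    Yta = "Cartwright", Ytb = "Cartwright",
    ABO = "ABO", A1 = "ABO", A2 = "ABO",
    Lea = "Lewis", Leb = "Lewis",
    Doa = "Dombrock", Dob = "Dombrock",
    P1 = "P1PK", Kna = "Knops", Knb = "Knops", Vel = "Vel", Lsa = "Gerbich",
    LWa = "Landsteiner-Wiener", LWb = "Landsteiner-Wiener",
    `HPA-1a` = "HPA-1", `HPA-1b` = "HPA-1"
  )
  if (!is.null(extra)) map[names(extra)] <- extra
  out <- map[antigens]
  out[is.na(out)] <- antigens[is.na(out)]
  unname(out)
}

resolve_dosages <- function(x, regions = NULL) {
  if (inherits(x, "dosage_matrix")) x else load_dosages(x, regions)
}

resolve_phenotypes <- function(x) {
  if (inherits(x, "phenotype_table")) x else read_phenotypes(x)
}

resolve_regions <- function(x) {
  if (is.null(x) || inherits(x, "gene_region_table")) x else read_gene_regions(x)
}

system_matrix <- function(dm, regions, system) {
  rows <- which(regions$system == system)
  if (length(rows) == 0L) return(NULL)
  parts <- lapply(rows, function(i) slice_region(dm, regions[i, ])$dosages)
  m <- do.call(cbind, parts)
  m[, !duplicated(colnames(m)), drop = FALSE]
}

#' Train antigen models for a cohort
#'
#' The end-to-end training command: load dosages for the blood-group gene
#' regions, parse the typing table, filter antigens by the
#' four-cases-per-class rule, split the cohort 1:1, fit a per-antigen forest
#' with permutation-importance selection on the training half, evaluate on
#' the held-out half, refit the final model on the full data, and write
#' portable model bundles plus eligibility and accuracy reports.
#'
#' @param vcf VCF path or a [dosage_matrix()].
#' @param phenotypes Typing table path or a `phenotype_table`.
#' @param regions Gene-region table path or a [gene_regions()] table.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param seed Integer seed controlling the split and every forest.
#' @param n_trees,ratio,min_per_class,threshold The published defaults:
#'   2000 trees, 1:1 split, 4 cases per class, posterior call threshold 0.5.
#' @param antigen_map Optional named vector `antigen -> system`.
#' @param write_bundles Write model bundles under `out_dir/models/`
#'   (default `TRUE` when `out_dir` is given).
#' @return Invisibly, a list with `models` (final full-data
#'   `antigen_model`s), `metrics_test`, `metrics_train`, `eligibility`,
#'   `split`, `skipped`.
#' @export
bg_train <- function(vcf, phenotypes, regions, out_dir = NULL, seed = 1L,
                     n_trees = 2000L, ratio = 0.5, min_per_class = 4L,
                     threshold = 0.5, antigen_map = NULL,
                     write_bundles = !is.null(out_dir)) {
  regions <- resolve_regions(regions)
  if (is.null(regions)) stop("a gene-region table is required")
  dm <- resolve_dosages(vcf, regions)
  pt <- resolve_phenotypes(phenotypes)

  elig <- eligibility_report(pt, min_per_class)
  antigens <- elig$antigen[elig$eligible]
  if (length(antigens) == 0L) stop("no eligible antigens")
  systems <- antigen_system(antigens, antigen_map)

  plan <- split_cohort(sample_ids(dm), ratio = ratio, seed = seed)
  models <- list()
  skipped <- list()
  mt_test <- list()
  mt_train <- list()

  for (i in seq_along(antigens)) {
    ag <- antigens[i]
    sys <- systems[i]
    res <- tryCatch(
      train_one_antigen(ag, sys, dm, pt, regions, plan,
                        seed = seed + i * 101L, n_trees = n_trees,
                        threshold = threshold),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "antigen_failure")
    )
    if (inherits(res, "antigen_failure")) {
      skipped[[ag]] <- res$message
      message(sprintf("antigen %s skipped: %s", ag, res$message))
      next
    }
    models[[ag]] <- res$final_model
    mt_test[[ag]] <- res$metrics_test
    mt_train[[ag]] <- res$metrics_train
    if (write_bundles && !is.null(out_dir)) {
      save_bundle(res$final_model, file.path(out_dir, "models", ag))
    }
  }

  metrics_test <- do.call(rbind, mt_test)
  metrics_train <- do.call(rbind, mt_train)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(elig, file.path(out_dir, "eligibility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(metrics_test)) {
      utils::write.table(metrics_test, file.path(out_dir, "metrics_test.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(metrics_train, file.path(out_dir, "metrics_train.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      s <- summarize_balanced_accuracy(metrics_test$balanced_accuracy)
      jsonlite::write_json(
        list(median = s$median, q1 = s$q1, q3 = s$q3, n_models = s$n_models,
             skipped = skipped),
        file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(
      list(command = "train", seed = seed, n_trees = n_trees, ratio = ratio,
           min_per_class = min_per_class, threshold = threshold,
           n_samples = nrow(dm$dosages), n_variants = ncol(dm$dosages)),
      file.path(out_dir, "resolved_config.json"), auto_unbox = TRUE)
  }
  invisible(list(models = models, metrics_test = metrics_test,
                 metrics_train = metrics_train, eligibility = elig,
                 split = plan, skipped = skipped))
}

train_one_antigen <- function(ag, sys, dm, pt, regions, plan, seed, n_trees,
                              threshold = 0.5) {
  X_all <- system_matrix(dm, regions, sys)
  if (is.null(X_all)) stop(sprintf("no gene region for system '%s'", sys))
  y_all <- stats::setNames(pt[[ag]], pt$sample_id)
  samples <- intersect(rownames(X_all), pt$sample_id[!is.na(pt[[ag]])])
  X <- X_all[samples, , drop = FALSE]
  y <- y_all[samples]

  # the published protocol keeps samples with full dosage data
  complete <- rowSums(is.na(X)) == 0L
  if (!all(complete)) {
    X <- X[complete, , drop = FALSE]
    y <- y[complete]
  }

  tr_ids <- intersect(plan$train_ids, rownames(X))
  te_ids <- intersect(plan$test_ids, rownames(X))
  if (length(unique(y[tr_ids])) < 2L) {
    stop("failed classification: training split lacks a typing class")
  }
  cfg <- forest_config(n_trees = n_trees, seed = seed)
  fit <- fit_antigen_model(X[tr_ids, , drop = FALSE], y[tr_ids],
                           antigen = ag, system = sys, config = cfg)

  row_of <- function(ids) {
    pp <- predict_posterior(fit, X[ids, , drop = FALSE])
    calls <- classify_calls(pp, threshold)
    if (identical(fit$classes, c("negative", "positive"))) {
      m <- accuracy_metrics(confusion_counts(y[ids], calls))
      auroc <- tryCatch(roc_pr_curves(pp[, "positive"], y[ids])$auroc,
                        error = function(e) NA_real_)
      cbind(antigen = ag, system = sys, class = "positive", m,
            auroc = auroc, oob_error = fit$oob_error,
            n = length(ids), n_variants_available = length(fit$input_variants),
            n_model_variants = nrow(fit$selected), stringsAsFactors = FALSE)
    } else {
      m <- one_vs_rest_metrics(y[ids], calls, classes = fit$classes)
      cbind(antigen = ag, system = sys, m, auroc = NA_real_,
            oob_error = fit$oob_error, n = length(ids),
            n_variants_available = length(fit$input_variants),
            n_model_variants = nrow(fit$selected), stringsAsFactors = FALSE)
    }
  }
  metrics_test <- row_of(te_ids)
  metrics_train <- row_of(tr_ids)

  # final model on the full data set
  final <- fit_antigen_model(X, y, antigen = ag, system = sys, config = cfg)
  list(final_model = final, train_model = fit,
       metrics_test = metrics_test, metrics_train = metrics_train)
}

#' Apply trained models to a target cohort
#'
#' The transfer command: for every model bundle, harmonize the target
#' panel's variant naming and allele orientation to the model's panel, fill
#' missing or absent variants from the model's training means (reference
#' mode), and emit posterior probabilities and calls per sample.
#'
#' @param models A directory of bundles, a list of `antigen_model`s, or a
#'   single model.
#' @param vcf Target VCF path or [dosage_matrix()].
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param threshold Posterior call threshold (default 0.5).
#' @param flip_palindromic Passed to [harmonize_to_model()].
#' @return Invisibly, a list with `predictions` (data frame `sample_id`,
#'   `system`, `antigen`, `pp`, `call`), `posteriors` (per-model posterior
#'   matrices), `reports` (per-model `harmonization_report`s).
#' @export
bg_predict <- function(models, vcf, out_dir = NULL, threshold = 0.5,
                       flip_palindromic = FALSE) {
  if (is.character(models)) {
    dirs <- list.dirs(models, recursive = FALSE)
    dirs <- dirs[file.exists(file.path(dirs, "bundle.json"))]
    if (length(dirs) == 0L) stop("no model bundles under ", models)
    models <- lapply(dirs, load_bundle)
  }
  if (inherits(models, "antigen_model")) models <- list(models)
  dm <- resolve_dosages(vcf)

  preds <- list()
  posteriors <- list()
  reports <- list()
  for (model in models) {
    h <- harmonize_to_model(dm, parse_variant_key(model$selected$key),
                            flip_palindromic = flip_palindromic)
    reports[[model$antigen]] <- h$report
    if (h$report$matched_exact + h$report$matched_flipped == 0L) {
      message(sprintf("model %s: no matched variants; skipped", model$antigen))
      next
    }
    xm <- mean_impute_missing(h$matrix, reference_means = model$training_means)
    pp <- predict_posterior(model, xm)
    calls <- classify_calls(pp, threshold)
    pp_rep <- if (identical(model$classes, c("negative", "positive"))) {
      pp[, "positive"]
    } else {
      pp[cbind(seq_len(nrow(pp)), max.col(pp, ties.method = "first"))]
    }
    posteriors[[model$antigen]] <- pp
    preds[[model$antigen]] <- data.frame(
      sample_id = rownames(pp), system = model$system, antigen = model$antigen,
      pp = pp_rep, call = calls, stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(predictions, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(reports, function(r) list(
        matched_exact = r$matched_exact, matched_flipped = r$matched_flipped,
        unmatched = r$unmatched, ambiguous = r$ambiguous)),
      file.path(out_dir, "harmonization.json"), auto_unbox = TRUE)
  }
  invisible(list(predictions = predictions, posteriors = posteriors,
                 reports = reports))
}

#' Evaluate predictions against typing truth
#'
#' Joins predicted calls with the typing table and computes the metric suite
#' per antigen (one-vs-rest rows for multi-class phenotypes), plus the
#' median/IQR summary of balanced accuracies across models.
#'
#' @param predictions Predictions data frame (or `predictions.tsv` path)
#'   with columns `sample_id`, `antigen`, `pp`, `call`.
#' @param truth Typing table path or `phenotype_table`.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param compare_with Optional second metrics data frame (or TSV path); the
#'   two sets of balanced accuracies are compared with
#'   [compare_model_sets()].
#' @return Invisibly, a list with `metrics`, `summary`, and optionally
#'   `comparison`.
#' @export
bg_evaluate <- function(predictions, truth, out_dir = NULL, compare_with = NULL) {
  if (is.character(predictions)) {
    predictions <- utils::read.table(predictions, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
  }
  pt <- resolve_phenotypes(truth)
  rows <- list()
  for (ag in unique(predictions$antigen)) {
    if (!ag %in% names(pt)) next
    p <- predictions[predictions$antigen == ag, ]
    tr <- stats::setNames(pt[[ag]], pt$sample_id)[p$sample_id]
    if (all(is.na(tr))) next
    sys <- p$system[1]
    if (all(stats::na.omit(unique(tr)) %in% c("positive", "negative"))) {
      m <- accuracy_metrics(confusion_counts(tr, p$call))
      auroc <- tryCatch(roc_pr_curves(p$pp[!is.na(tr)], tr[!is.na(tr)])$auroc,
                        error = function(e) NA_real_)
      rows[[ag]] <- cbind(antigen = ag, system = sys, class = "positive",
                          m, auroc = auroc, stringsAsFactors = FALSE)
    } else {
      m <- one_vs_rest_metrics(tr, p$call)
      rows[[ag]] <- cbind(antigen = ag, system = sys, m, auroc = NA_real_,
                          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no overlapping samples/antigens between predictions and truth")
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  summ <- summarize_balanced_accuracy(metrics$balanced_accuracy)

  comparison <- NULL
  if (!is.null(compare_with)) {
    if (is.character(compare_with)) {
      compare_with <- utils::read.table(compare_with, header = TRUE, sep = "\t",
                                        stringsAsFactors = FALSE)
    }
    comparison <- compare_model_sets(metrics$balanced_accuracy,
                                     compare_with$balanced_accuracy)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- list(median = summ$median, q1 = summ$q1, q3 = summ$q3,
                n_models = summ$n_models)
    if (!is.null(comparison)) {
      out$comparison <- list(statistic = comparison$statistic,
                             p_value = comparison$p_value)
    }
    jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(metrics = metrics, summary = summ, comparison = comparison))
}

#' Write a synthetic cohort to standard files
#'
#' Runs the simulator and writes the artifacts every other command consumes:
#' `cohort.vcf` (GT + DS), `phenotypes.tsv`, `regions.tsv` and `truth.json`.
#' Identical configurations and seeds produce byte-identical files.
#'
#' @param out_dir Output directory.
#' @param config A [sim_cohort_config()] (default:
#'   [finnish_reference_config()]).
#' @param replication Simulate a replication cohort of `config` via
#'   [simulate_replication_cohort()] (default `FALSE`).
#' @param ... Passed to [simulate_replication_cohort()] when `replication`.
#' @return Invisibly, the `sim_cohort` object.
#' @export
bg_simulate <- function(out_dir, config = finnish_reference_config(),
                        replication = FALSE, ...) {
  cohort <- if (replication) {
    simulate_replication_cohort(config, ...)
  } else {
    simulate_cohort(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(cohort$dosages, file.path(out_dir, "cohort.vcf"))
  utils::write.table(cohort$phenotypes, file.path(out_dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$regions, file.path(out_dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}
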