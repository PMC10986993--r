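#' Portable model bundles
#'
#' An [fit_antigen_model()] result is serialized as a directory of two JSON
#' files: `bundle.json` (antigen, system, classes, configuration, variant
#' keys with importances and training dosage means, out-of-bag error) and
#' `trees.json` (the flattened tree arrays). Numbers are written at full
#' precision, so a reloaded bundle predicts bit-identically to the in-run
#' model — and the format is readable outside R.
#'
#' @param model An `antigen_model`.
#' @param dir Bundle directory (created if needed).
#' @return `save_bundle()` returns `dir` invisibly; `load_bundle()` returns
#'   the reconstructed `antigen_model`.
#' @export
save_bundle <- function(model, dir) {
  stopifnot(inherits(model, "antigen_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "rbcforest-bundle-1",
    antigen = model$antigen,
    system = model$system,
    classes = model$classes,
    input_variants = model$input_variants,
    importance = as.list(model$importance),
    selected = model$selected,
    n_trees = model$n_trees,
    training_means = as.list(model$training_means),
    oob_error = model$oob_error,
    n_train = model$n_train,
    class_weights = as.list(model$class_weights),
    config = model$config
  )
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  jsonlite::write_json(meta, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  trees <- lapply(model$trees, function(tr) {
    list(left = tr$left, right = tr$right, varid = tr$varid,
         split = tr$split, probs = tr$probs)
  })
  jsonlite::write_json(trees, file.path(dir, "trees.json"), digits = I(17))
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  meta_path <- file.path(dir, "bundle.json")
  trees_path <- file.path(dir, "trees.json")
  if (!file.exists(meta_path) || !file.exists(trees_path)) {
    stop("not a model bundle (bundle.json/trees.json missing): ", dir)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "rbcforest-bundle-1")) {
    stop("unrecognized bundle format in ", dir)
  }
  raw_trees <- jsonlite::read_json(trees_path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
  K <- length(meta$classes)
  trees <- lapply(raw_trees, function(tr) {
    probs <- tr$probs
    if (!is.matrix(probs)) probs <- matrix(unlist(probs), ncol = K, byrow = TRUE)
    storage.mode(probs) <- "double"
    list(left = as.integer(tr$left), right = as.integer(tr$right),
         varid = as.integer(tr$varid), split = as.numeric(tr$split),
         probs = probs)
  })
  sel <- as.data.frame(meta$selected, stringsAsFactors = FALSE)
  structure(list(
    antigen = meta$antigen,
    system = meta$system,
    classes = meta$classes,
    input_variants = meta$input_variants,
    importance = unlist(meta$importance),
    selected = sel,
    trees = trees,
    n_trees = meta$n_trees,
    training_means = unlist(meta$training_means),
    oob_error = meta$oob_error,
    n_train = meta$n_train,
    class_weights = unlist(meta$class_weights),
    config = meta$config
  ), class = "antigen_model")
}
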