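#' Harmonize a cohort's dosage matrix to a model's variant panel
#'
#' Reconciles variant naming and allele orientation between a trained model's
#' panel and a target cohort. A target variant matching `chrom:pos:ref:alt`
#' exactly maps directly; one matching `chrom:pos` with ref/alt swapped maps
#' with every dosage `d` replaced by `2 - d` (an allele-orientation flip).
#' Model variants with no match become all-missing columns, to be filled by
#' [mean_impute_missing()] in reference mode.
#'
#' Palindromic (A/T, C/G) variants are strand-ambiguous: a swapped-key match
#' cannot be distinguished from a strand flip, so by default it is treated as
#' unmatched and listed in the report's `ambiguous` field. Set
#' `flip_palindromic = TRUE` to accept such matches as orientation flips.
#'
#' @param dm Target cohort [dosage_matrix()].
#' @param model_variants Data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `key` (as stored in an [antigen_model]), or a character vector of
#'   keys.
#' @param flip_palindromic Accept swapped-allele matches for palindromic
#'   variants (default `FALSE`).
#' @return A list with elements `matrix` (a [dosage_matrix()] whose columns
#'   are exactly `model_variants`, in order) and `report` (a
#'   `harmonization_report`: counts `matched_exact`, `matched_flipped`, and
#'   key lists `unmatched`, `ambiguous`).
#' @export
harmonize_to_model <- function(dm, model_variants, flip_palindromic = FALSE) {
  stopifnot(inherits(dm, "dosage_matrix"))
  if (is.character(model_variants)) model_variants <- parse_variant_key(model_variants)
  if (anyDuplicated(model_variants$key)) stop("duplicate model variant keys")
  if (nrow(model_variants) == 0) stop("model_variants must be non-empty")

  target_keys <- dm$variants$key
  swapped_key <- variant_key(model_variants$chrom, model_variants$pos,
                             model_variants$alt, model_variants$ref)
  exact <- match(model_variants$key, target_keys)
  swap <- match(swapped_key, target_keys)
  palin <- is_palindromic(model_variants$ref, model_variants$alt)

  use_flip <- is.na(exact) & !is.na(swap) & (flip_palindromic | !palin)
  ambiguous <- model_variants$key[is.na(exact) & !is.na(swap) & palin & !flip_palindromic]
  unmatched <- model_variants$key[is.na(exact) & !use_flip]

  n <- nrow(dm$dosages)
  out <- matrix(NA_real_, n, nrow(model_variants),
                dimnames = list(rownames(dm$dosages), model_variants$key))
  has_exact <- which(!is.na(exact))
  if (length(has_exact)) out[, has_exact] <- dm$dosages[, exact[has_exact], drop = FALSE]
  flip_idx <- which(use_flip)
  if (length(flip_idx)) out[, flip_idx] <- 2 - dm$dosages[, swap[flip_idx], drop = FALSE]

  report <- structure(list(
    matched_exact = length(has_exact),
    matched_flipped = length(flip_idx),
    unmatched = unmatched,
    ambiguous = ambiguous
  ), class = "harmonization_report")
  stopifnot(report$matched_exact + report$matched_flipped + length(unmatched) ==
              nrow(model_variants))
  list(matrix = dosage_matrix(out, model_variants), report = report)
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat(sprintf("<harmonization_report> exact %d | flipped %d | unmatched %d",
              x$matched_exact, x$matched_flipped, length(x$unmatched)))
  if (length(x$ambiguous)) cat(sprintf(" | ambiguous palindromic %d", length(x$ambiguous)))
  cat("\n")
  invisible(x)
}

#' Fill missing dosages with column means
#'
#' Replaces each missing entry by the column mean. In *self mode* (no
#' `reference_means`) the mean is taken over the non-missing entries of the
#' same matrix — the protocol used when fitting models within one cohort,
#' applied separately to train and test sets. In *reference mode* the
#' supplied per-variant means (the model's training means) are used — the
#' protocol for cross-cohort transfer, where a model's variants may be absent
#' from the target panel altogether. Non-missing entries are left untouched.
#'
#' @param dm A [dosage_matrix()].
#' @param reference_means Optional named numeric vector of per-variant means;
#'   must cover every column that has missing entries.
#' @return A [dosage_matrix()] with no missing entries. Columns that were
#'   entirely missing in self mode are filled with 1.0 (one expected
#'   alternate allele) and reported via a warning.
#' @export
mean_impute_missing <- function(dm, reference_means = NULL) {
  stopifnot(inherits(dm, "dosage_matrix"))
  d <- dm$dosages
  miss_cols <- which(colSums(is.na(d)) > 0L)
  if (length(miss_cols) == 0L) return(dm)

  if (!is.null(reference_means)) {
    lack <- setdiff(colnames(d)[miss_cols], names(reference_means))
    if (length(lack)) {
      stop("reference_means lacks variant(s) with missing entries: ",
           paste(utils::head(lack, 3), collapse = ", "))
    }
    for (j in miss_cols) {
      nas <- is.na(d[, j])
      d[nas, j] <- reference_means[[colnames(d)[j]]]
    }
  } else {
    all_missing <- character(0)
    for (j in miss_cols) {
      nas <- is.na(d[, j])
      m <- mean(d[!nas, j])
      if (is.nan(m)) {
        m <- 1.0
        all_missing <- c(all_missing, colnames(d)[j])
      }
      d[nas, j] <- m
    }
    if (length(all_missing)) {
      warning("column(s) entirely missing; filled with 1.0: ",
              paste(utils::head(all_missing, 3), collapse = ", "))
    }
  }
  dosage_matrix(d, dm$variants)
}
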