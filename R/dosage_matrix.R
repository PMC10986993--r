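#' Allele dosage matrix
#'
#' The universal model input: a samples x variants matrix of expected
#' alternate-allele counts in \[0, 2\]. Fractional values arise from genotype
#' imputation; `NA` marks a missing dosage (no call and no dosage field).
#'
#' @param dosages Numeric matrix, rows = samples, columns = variants. Row
#'   names are sample identifiers, column names are `chrom:pos:ref:alt` keys.
#' @param variants Optional data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `key` describing the columns; parsed from the column names when
#'   omitted.
#' @return An object of class `dosage_matrix`: a list with elements
#'   `dosages` (the matrix) and `variants` (the variant table).
#' @seealso [load_dosages()], [slice_region()], [harmonize_to_model()],
#'   [mean_impute_missing()]
#' @export
dosage_matrix <- function(dosages, variants = NULL) {
  if (!is.matrix(dosages) || !is.numeric(dosages)) {
    stop("dosages must be a numeric matrix")
  }
  if (is.null(rownames(dosages))) stop("dosages must carry sample ids as row names")
  if (anyDuplicated(rownames(dosages))) stop("duplicate sample ids")
  if (is.null(variants)) {
    if (is.null(colnames(dosages))) stop("variant keys required as column names")
    variants <- parse_variant_key(colnames(dosages))
  }
  if (nrow(variants) != ncol(dosages)) stop("variants table does not match columns")
  if (anyDuplicated(variants$key)) stop("duplicate variant keys")
  colnames(dosages) <- variants$key
  if (length(dosages) > 0 && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages outside [0, 2]")
  }
  structure(list(dosages = dosages, variants = variants), class = "dosage_matrix")
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d samples x %d variants", nrow(x$dosages), ncol(x$dosages)))
  nm <- sum(is.na(x$dosages))
  if (nm > 0) cat(sprintf(" (%d missing entries)", nm))
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.dosage_matrix <- function(x, ...) x$dosages

sample_ids <- function(dm) rownames(dm$dosages)

# Column subset preserving the variant table.
dm_subset_cols <- function(dm, idx) {
  dosage_matrix(dm$dosages[, idx, drop = FALSE], dm$variants[idx, , drop = FALSE])
}

#' Restrict a dosage matrix to one gene region
#'
#' Keeps exactly the variants with
#' `start - flank <= pos <= end + flank` on the region's chromosome; the
#' sample set is unchanged. An empty result is allowed (a message is emitted).
#'
#' @param dm A [dosage_matrix()].
#' @param region A single-row data frame with `chrom`, `start`, `end` and
#'   optionally `flank` (defaults to 2000 bp).
#' @return A [dosage_matrix()] with the retained columns, in input order.
#' @export
slice_region <- function(dm, region) {
  stopifnot(inherits(dm, "dosage_matrix"))
  flank <- if (!is.null(region$flank)) as.integer(region$flank) else 2000L
  keep <- dm$variants$chrom == as.character(region$chrom) &
    dm$variants$pos >= region$start - flank &
    dm$variants$pos <= region$end + flank
  if (!any(keep)) {
    message(sprintf("slice_region: no variants in %s:%d-%d (flank %d)",
                    region$chrom, region$start, region$end, flank))
  }
  dm_subset_cols(dm, which(keep))
}

#' Serialize a dosage matrix to TSV
#'
#' Writes a header row of variant keys and one row per sample (first column
#' `sample_id`). Missing dosages are written as `NA`. Column order is stable
#' under round-trip.
#'
#' @param dm A [dosage_matrix()].
#' @param path Output path.
#' @export
write_dosage_tsv <- function(dm, path) {
  df <- data.frame(sample_id = sample_ids(dm), dm$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  dosage_matrix(m)
}
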