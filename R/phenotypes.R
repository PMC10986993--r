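#' Read an antigen typing table
#'
#' Parses a delimited text file with a sample-ID column and one column per
#' antigen. Binary typing calls are normalized to `"positive"` /
#' `"negative"`; empty cells and `NA` become missing. Recognized positivity
#' encodings (case-insensitive): `+`, `pos`, `positive`, `1`, `yes`, and
#' antigen-suffixed strings such as `Kpa+`. Columns whose values are not
#' covered by the binary encodings (e.g. an `ABO` column with phenotypes
#' `A`/`B`/`AB`/`O`) are kept verbatim as multi-class calls.
#'
#' @param path Path to a TSV/CSV file.
#' @param id_col Name of the sample-ID column (default: first column).
#' @param positive,negative Additional accepted encodings.
#' @return A data frame of class `phenotype_table`: column `sample_id`
#'   followed by one character column per antigen.
#' @export
read_phenotypes <- function(path, id_col = NULL,
                            positive = character(0), negative = character(0)) {
  if (!file.exists(path)) stop("phenotype table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character")
  if (is.null(id_col)) id_col <- names(df)[1]
  if (!id_col %in% names(df)) stop("sample-ID column not found: ", id_col)
  if (anyDuplicated(df[[id_col]])) {
    stop("duplicate sample ID(s): ",
         paste(utils::head(unique(df[[id_col]][duplicated(df[[id_col]])]), 3), collapse = ", "))
  }
  out <- data.frame(sample_id = df[[id_col]], stringsAsFactors = FALSE)
  for (ag in setdiff(names(df), id_col)) {
    out[[ag]] <- normalize_calls(df[[ag]], ag, positive, negative)
  }
  class(out) <- c("phenotype_table", "data.frame")
  out
}

normalize_calls <- function(x, antigen, positive = character(0), negative = character(0)) {
  pos_enc <- tolower(c("+", "pos", "positive", "1", "yes", paste0(antigen, "+"), positive))
  neg_enc <- tolower(c("-", "neg", "negative", "0", "no", paste0(antigen, "-"), negative))
  lx <- tolower(trimws(x))
  known <- is.na(lx) | lx %in% c(pos_enc, neg_enc)
  if (all(known)) {
    out <- ifelse(lx %in% pos_enc, "positive",
                  ifelse(lx %in% neg_enc, "negative", NA_character_))
  } else {
    out <- trimws(x)  # multi-class phenotype (e.g. ABO), kept verbatim
  }
  out
}

#' Antigen eligibility for model fitting
#'
#' An antigen is eligible when every typing class has at least
#' `min_per_class` non-missing calls (default 4) — the floor below which a
#' classifier cannot be trained and evaluated meaningfully. For binary
#' antigens this means at least `min_per_class` positives *and* negatives;
#' a multi-class phenotype needs the floor in each class.
#'
#' @param pt A [read_phenotypes()] table.
#' @param min_per_class Minimum non-missing calls per class (default 4).
#' @return A data frame with one row per antigen: `antigen`, `n_classes`,
#'   `n_total`, `n_min_class`, `eligible`, `reason`. Use
#'   `eligible_antigens()` for the character vector of eligible names.
#' @export
eligibility_report <- function(pt, min_per_class = 4L) {
  stopifnot(inherits(pt, "phenotype_table"))
  ags <- setdiff(names(pt), "sample_id")
  rows <- lapply(ags, function(ag) {
    calls <- pt[[ag]][!is.na(pt[[ag]])]
    tab <- table(calls)
    n_classes <- length(tab)
    n_min <- if (n_classes > 0) min(tab) else 0L
    eligible <- n_classes >= 2L && n_min >= min_per_class
    reason <- if (eligible) "" else if (n_classes < 2L) {
      "fewer than two typing classes"
    } else {
      sprintf("class '%s' has %d < %d cases", names(tab)[which.min(tab)], n_min, min_per_class)
    }
    data.frame(antigen = ag, n_classes = n_classes, n_total = length(calls),
               n_min_class = as.integer(n_min), eligible = eligible,
               reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname eligibility_report
#' @export
eligible_antigens <- function(pt, min_per_class = 4L) {
  rep <- eligibility_report(pt, min_per_class)
  rep$antigen[rep$eligible]
}

#' Random 1:1 cohort partition
#'
#' Divides the sample labels randomly into train and test sets. The split is
#' a single cohort-level partition serving all antigens (not stratified per
#' antigen). Reproducible for a fixed seed.
#'
#' @param ids Character vector of sample labels.
#' @param ratio Fraction assigned to the training set, in (0, 1); default 0.5.
#' @param seed Integer seed.
#' @return A list of class `split_plan`: `train_ids`, `test_ids`, `ratio`,
#'   `seed`. `|train| = round(ratio * n)`; the two sets are disjoint and
#'   jointly exhaustive.
#' @export
split_cohort <- function(ids, ratio = 0.5, seed = 1L) {
  if (length(ids) < 2L) stop("need at least 2 samples to split")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  n_train <- round(ratio * length(ids))
  structure(list(
    train_ids = shuffled[seq_len(n_train)],
    test_ids = shuffled[-seq_len(n_train)],
    ratio = ratio,
    seed = as.integer(seed)
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test (ratio %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$ratio, x$seed))
  invisible(x)
}
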