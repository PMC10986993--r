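#' Published cross-cohort balanced accuracies
#'
#' Balanced accuracies of the per-antigen random forest models reported for
#' a Finnish discovery cohort (1,192 blood donors) and a Danish replication
#' cohort (~111,000 donors): the Finnish models evaluated on the Finnish and
#' Danish full data sets, and the Danish models on the Danish full data set.
#' `NA` marks model/cohort combinations without typing data; 33 models are
#' shared by all three columns. Useful as the reference input for
#' [summarize_balanced_accuracy()] and [compare_model_sets()].
#'
#' @param shared_only Keep only the 33 models present in all three columns.
#' @return Data frame with columns `system`, `antigen`,
#'   `ba_finnish_models_finnish_full`, `ba_finnish_models_danish_full`,
#'   `ba_danish_models_danish_full`.
#' @export
model_transfer_accuracies <- function(shared_only = FALSE) {
  path <- system.file("extdata", "model_transfer_balanced_accuracies.tsv",
                      package = "rbcforest", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (shared_only) df <- df[stats::complete.cases(df), , drop = FALSE]
  df
}
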