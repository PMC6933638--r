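#' Save / load a trained classifier
#'
#' A model bundle is a directory holding the weight arrays in the engine's
#' native checkpoint format (`weights.rds`) plus a JSON sidecar
#' (`model.json`) carrying the architecture spec, label map, encoding
#' metadata and rejection threshold.
#'
#' @param classifier A `trained_classifier`.
#' @param path Bundle directory (created if needed).
#' @return `path` (for save) or the restored `trained_classifier` (for
#'   load).
#' @export
save_classifier <- function(classifier, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(classifier$model$weights, file.path(path, "weights.rds"))
  spec <- classifier$spec
  meta <- list(
    spec = unclass(spec), spec_class = class(spec),
    label_map = as.list(classifier$label_map),
    encoding = classifier$encoding,
    threshold = classifier$threshold,
    history = classifier$history)
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  spec <- meta$spec
  # JSON round-trip turns scalars into length-1 vectors; restore types
  int_fields <- c("input_len", "channels", "conv_kernels", "fc_units",
                  "batch_size", "classes", "filter_widths",
                  "kernels_per_width")
  for (f in intersect(names(spec), int_fields)) {
    spec[[f]] <- as.integer(spec[[f]])
  }
  class(spec) <- meta$spec_class
  weights <- readRDS(file.path(path, "weights.rds"))
  label_map <- unlist(meta$label_map)
  structure(list(
    model = structure(list(spec = spec, weights = weights),
                      class = "cnn_model"),
    spec = spec,
    label_map = stats::setNames(as.integer(label_map), names(label_map)),
    history = meta$history,
    encoding = meta$encoding,
    threshold = meta$threshold,
    config = NULL), class = "trained_classifier")
}

#' Serialize an evaluation report
#'
#' Writes the per-class table as TSV and, optionally, a JSON summary with
#' the accuracy and macro F-score.
#'
#' @param report An `eval_report`.
#' @param tsv Path for the per-class TSV (one row per family).
#' @param json Optional path for the JSON summary.
#' @return `tsv`, invisibly.
#' @export
write_eval_report <- function(report, tsv, json = NULL) {
  utils::write.table(report$per_class, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(accuracy = report$accuracy,
                              macro_fscore = report$macro_fscore),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv)
}
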