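#' Read and write the pipeline's tab-delimited files
#'
#' Thin, column-checked wrappers around [utils::read.delim()] /
#' [utils::write.table()] for the formats the pipeline exchanges:
#' aCGH probe tables (`probe_id`, `chromosome`, `position_bp`,
#' `log2_ratio`), expression tables (`probe_set_id`, `log2_ratio` plus
#' mapping columns), long FISH nucleus-count tables (`tumor_id`,
#' `nucleus_id`, `test_count`, `centromere_count`), survival tables
#' (`patient_id`, `time`, `event`) and compendium matrices with a sample
#' annotation table.
#'
#' @param path file path.
#' @param x object to write.
#' @return Readers return data frames (the compendium reader a
#'   `compendium` list); writers return `path` invisibly.
#' @name pipeline_io
NULL

read_checked <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_cgh_probes <- function(path) {
  df <- read_checked(path, c("probe_id", "chromosome", "position_bp",
                             "log2_ratio"))
  df[order(df$chromosome, df$position_bp), , drop = FALSE]
}

#' @rdname pipeline_io
#' @export
write_cgh_probes <- function(x, path) write_tsv(x, path)

#' @rdname pipeline_io
#' @export
read_expression_table <- function(path) {
  read_checked(path, c("probe_set_id", "log2_ratio"))
}

#' @rdname pipeline_io
#' @export
write_expression_table <- function(x, path) write_tsv(x, path)

#' @rdname pipeline_io
#' @export
read_fish_counts <- function(path) {
  read_checked(path, c("tumor_id", "test_count", "centromere_count"))
}

#' @rdname pipeline_io
#' @export
write_fish_counts <- function(x, path) write_tsv(x, path)

#' @rdname pipeline_io
#' @export
read_survival_table <- function(path) {
  df <- read_checked(path, c("patient_id", "time", "event"))
  df$event <- as.logical(df$event)
  df
}

#' @rdname pipeline_io
#' @export
write_survival_table <- function(x, path) write_tsv(x, path)

#' @rdname pipeline_io
#' @param annotation_path path of the sample annotation TSV (`sample_id`,
#'   `tissue_class`) accompanying the compendium matrix.
#' @export
read_compendium <- function(path, annotation_path) {
  m <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  ann <- read_checked(annotation_path, c("sample_id", "tissue_class"))
  m <- as.matrix(m)
  if (!all(colnames(m) %in% ann$sample_id)) {
    stop("compendium has samples absent from the annotation table",
         call. = FALSE)
  }
  structure(list(expression = m, annotations = ann), class = "compendium")
}

#' @rdname pipeline_io
#' @export
write_compendium <- function(x, path, annotation_path) {
  df <- data.frame(gene = rownames(x$expression), x$expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(x$annotations, annotation_path)
  invisible(path)
}

#' Write the ground truth of a simulation as JSON
#'
#' Records the planted segments, elevated genes and per-tumor latent
#' groups so recovery can be checked against the generator's truth.
#'
#' @param truth a named list (e.g. `planted`, `elevated_genes`,
#'   `groups`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
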