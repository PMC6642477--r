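# Plain TSV readers/writers for the tables exchanged between pipeline stages.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(path, " is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df
}

#' Read / write an MLPA peak table
#'
#' Tab-separated with header `sample_id`, `probe_id`, `peak_height`.
#'
#' @param peaks Peak table data frame.
#' @param path File path.
#' @return `read_peak_table()` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  write_tsv(peaks[, c("sample_id", "probe_id", "peak_height")], path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- read_tsv(path, c("sample_id", "probe_id", "peak_height"))
  df$peak_height <- as.numeric(df$peak_height)
  df
}

#' Read / write a truth table of simulated diplotypes
#'
#' Tab-separated with header `sample_id`, `gene`, `allele1`, `allele2`,
#' `total_copies` (and `label`).
#'
#' @param truth An `mlpa_truth` data frame.
#' @param path File path.
#' @return `read_truth_table()` returns an `mlpa_truth`; the writer returns
#'   `path` invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write_tsv(as.data.frame(truth), path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- read_tsv(path, c("sample_id", "gene", "allele1", "allele2"))
  new_truth(df[, c("sample_id", "gene", "allele1", "allele2")])
}

#' Write gene-level CNV calls
#'
#' @param calls An `mlpa_calls` object or its `gene_calls` data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gene_calls <- function(calls, path) {
  gc <- if (inherits(calls, "mlpa_calls")) calls$gene_calls else calls
  write_tsv(gc, path)
}

#' @rdname write_gene_calls
#' @export
read_gene_calls <- function(path) {
  read_tsv(path, c("sample_id", "gene", "genotype_label"))
}

#' Write a run-metadata JSON
#'
#' Records seed, configuration and counts for a pipeline run so any output can
#' be regenerated.
#'
#' @param meta Named list.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
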