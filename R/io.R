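# Plain-text readers/writers for the pipeline's tabular interfaces.
# All formats are single-header TSV/CSV so fixtures stay text-only.

#' Read an SGA colony-size table
#'
#' TSV with columns plate_id, repeat_id, arm, field, row, col, size_px
#' (empty size_px = absent colony).
#'
#' @param path file path.
#' @return data frame suitable for \code{\link{sga_score}}.
#' @export
read_plate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "repeat_id", "arm", "field", "row", "col", "size_px")
  assert_that(all(need %in% names(df)),
              "plate table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read a two-column polysome trace CSV (position, absorbance)
#' @param path file path.
#' @return data frame with position, absorbance.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "trace CSV needs two columns")
  names(df)[1:2] <- c("position", "absorbance")
  df[order(df$position), 1:2]
}

#' Read a per-fraction Ct table (TSV: sample_id, target_id, fraction, ct)
#' @param path file path.
#' @return data frame; missing/empty ct parsed as NA (undetected).
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "", "undetected"))
  need <- c("sample_id", "target_id", "fraction", "ct")
  assert_that(all(need %in% names(df)),
              "ct table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Write a data frame as TSV with a single header line
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
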