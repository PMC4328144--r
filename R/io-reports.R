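#' Write result tables as deterministic TSV reports
#'
#' Writes each table in `tables` to `<out_dir>/<name>.tsv` with a single
#' header line, tab separation, a fixed column order (as given) and
#' floats printed at a fixed number of significant digits, so re-running
#' on the same input produces byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @param digits Significant digits for numeric columns (default 6).
#' @return Invisibly, a character vector of the paths written.
#' @export
write_reports <- function(tables, out_dir, digits = 6) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- as.data.frame(tables[[nm]])
    df[] <- lapply(df, function(col) {
      if (is.double(col)) {
        ifelse(is.na(col), "NA", formatC(col, digits = digits, format = "g"))
      } else if (is.list(col)) {
        vapply(col, function(v) paste(v, collapse = ","), character(1))
      } else {
        as.character(col)
      }
    })
    lines <- c(paste(names(df), collapse = "\t"),
               if (nrow(df) > 0) do.call(paste, c(df, sep = "\t")))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
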