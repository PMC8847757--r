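#' Write and read per-step series as CSV
#'
#' Series CSVs are plain text with one row per step.  Doubles are written
#' with 17 significant digits (`%.17g`), which round-trips IEEE doubles
#' exactly, so `read_series_csv(write_series_csv(x, f))` reproduces the
#' in-memory values bit for bit — byte-identical files for byte-identical
#' runs.
#'
#' @param series A data.frame (typically a `replicate_series`).
#' @param path File path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a data.frame.
#' @export
write_series_csv <- function(series, path) {
  df <- as.data.frame(series)
  cols <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      # keep whole-valued doubles double-typed on re-read
      whole <- grepl("^-?[0-9]+$", out)
      out[whole] <- paste0(out[whole], ".0")
      out
    } else {
      as.character(col)
    }
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
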