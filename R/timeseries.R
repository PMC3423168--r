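#' Time-series container
#'
#' A thin data-frame subclass holding a strictly increasing `time` column
#' (hours) followed by one named numeric column per model variable or
#' signal. Used for simulator output and signal sampling.
#'
#' @param df A data frame whose first column is `time`.
#' @return The data frame with class `issf_timeseries` prepended.
#' @export
as_timeseries <- function(df) {
  if (!is.data.frame(df) || names(df)[1] != "time")
    stop("a time series needs a data frame whose first column is 'time'")
  if (nrow(df) > 1 && any(diff(df$time) <= 0))
    stop("'time' must be strictly increasing")
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("all time-series columns must be numeric")
  class(df) <- unique(c("issf_timeseries", class(df)))
  df
}

#' Write a time series as CSV
#'
#' Header row: `time` plus one column per series. Full double precision is
#' retained so repeated deterministic runs are bit-identical on disk.
#'
#' @param ts An `issf_timeseries` (or plain data frame with `time` first).
#' @param path Output file path.
#' @export
write_timeseries_csv <- function(ts, path) {
  ts <- as_timeseries(as.data.frame(ts))
  # format explicitly at 17 significant digits: write.csv's default would be
  # locale-stable anyway, but this pins bit-reproducibility of the text file
  out <- vapply(ts, function(col) sprintf("%.17g", col),
                character(nrow(ts)))
  if (nrow(ts) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(ts)))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = names(ts))
  invisible(path)
}

#' Read a time series from CSV
#'
#' @param path CSV file written by [write_timeseries_csv()] (or any CSV with
#'   a leading `time` column).
#' @return An `issf_timeseries`.
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_timeseries(df)
}
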