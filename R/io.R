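#' Read a delimited multi-channel time-series file
#'
#' One header line of channel labels, a time column in seconds (named
#' `time` or `time_s`, or the first column), and one column per channel.
#' Field separator is sniffed among tab, comma and semicolon.
#'
#' @param path File path.
#' @return Data.frame with a `time_s` column first and one numeric column
#'   per channel; the sampling rate inferred from the time column is
#'   attached as attribute `"rate_hz"`.
#' @export
read_timeseries <- function(path) {
  head1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", head1)) "\t" else if (grepl(";", head1)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  tcol <- which(tolower(names(df)) %in% c("time", "time_s"))[1]
  if (is.na(tcol)) tcol <- 1L
  names(df)[tcol] <- "time_s"
  df <- df[, c(tcol, setdiff(seq_along(df), tcol)), drop = FALSE]
  dt <- diff(df$time_s)
  if (length(dt) > 0 && all(dt > 0)) {
    attr(df, "rate_hz") <- 1 / stats::median(dt)
  }
  df
}

#' Write a multi-channel time-series to delimited text
#'
#' @param df Data.frame whose first column is time in seconds.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Extract one channel of a time-series table as a sampled signal
#'
#' @param df Data.frame from [read_timeseries()] (time first).
#' @param channel Column name.
#' @param units Unit label to attach.
#' @return A [sampled_signal()].
#' @export
channel_signal <- function(df, channel, units = "") {
  stopifnot(channel %in% names(df))
  dt <- diff(df$time_s)
  if (length(dt) == 0L || any(dt <= 0) ||
      max(abs(dt - stats::median(dt))) > 1e-6 * stats::median(dt) + 1e-12) {
    stop("channel_signal: time column is not uniformly sampled",
         call. = FALSE)
  }
  sampled_signal(df[[channel]], 1 / stats::median(dt), units = units,
                 label = channel, t0_s = df$time_s[1])
}

#' Read an OpenSim-style MOT/STO tabular file
#'
#' Header lines (`name`, `nRows`, `nColumns`, `inDegrees`, ...) terminated
#' by `endheader`, then a tab-delimited table whose first column is time.
#'
#' @param path File path.
#' @return Data.frame (time first); header key-value pairs in attribute
#'   `"header"`.
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  end <- grep("^\\s*endheader\\s*$", lines)
  if (length(end) == 0L) {
    stop("read_mot: no 'endheader' line found", call. = FALSE)
  }
  end <- end[1]
  hdr <- lines[seq_len(end - 1L)]
  kv <- grep("=", hdr, value = TRUE)
  header <- stats::setNames(
    lapply(kv, function(l) sub("^[^=]*=", "", l)),
    vapply(kv, function(l) sub("=.*$", "", l), character(1))
  )
  df <- utils::read.table(text = lines[(end + 1L):length(lines)],
                          header = TRUE, check.names = FALSE)
  names(df)[1] <- "time_s"
  attr(df, "header") <- header
  df
}

#' Write an OpenSim-style MOT/STO tabular file
#'
#' @param df Data.frame, time first.
#' @param path Output path.
#' @param name Dataset name for the header.
#' @param in_degrees Value of the `inDegrees` header field (default "yes").
#' @return Invisibly, `path`.
#' @export
write_mot <- function(df, path, name = "biomechkit", in_degrees = "yes") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               "version=1",
               sprintf("nRows=%d", nrow(df)),
               sprintf("nColumns=%d", ncol(df)),
               sprintf("inDegrees=%s", in_degrees),
               "endheader"), con)
  nm <- names(df)
  nm[1] <- "time"
  writeLines(paste(nm, collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
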