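#' Timeseries trace container
#'
#' A trace is a plain data frame with mandatory columns `time_s` (strictly
#' increasing), `v_m_V`, `i_nap_nA`, `i_pump_nA` and `na_i_M`, optionally
#' followed by further per-current columns.  Both simulators and the
#' file readers produce this container.
#'
#' @param x data frame with the trace columns.
#' @param params optional generating parameter object, kept as an attribute.
#' @return `x` with class `hn_trace` prepended.
#' @export
as_hn_trace <- function(x, params = NULL) {
  need <- c("time_s", "v_m_V", "i_nap_nA", "i_pump_nA", "na_i_M")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("trace is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(diff(x$time_s) <= 0)) stop("trace time must be strictly increasing")
  if (!inherits(x, "hn_trace")) class(x) <- c("hn_trace", class(x))
  if (!is.null(params)) attr(x, "params") <- params
  x
}

#' @export
print.hn_trace <- function(x, ...) {
  cat(sprintf("<hn_trace> %d samples, %.6g s span, %d channel(s)\n",
              nrow(x), diff(range(x$time_s)), ncol(x) - 1))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Read / write a trace file
#'
#' Columnar plain-text (CSV) with the header
#' `time_s,v_m_V,i_nap_nA,i_pump_nA,na_i_M` plus optional per-current
#' columns.  Values are written with 15 significant digits so that a
#' write/read round trip is lossless for analysis purposes.
#'
#' @param path file path.
#' @return for `read_trace`, an `hn_trace`.
#' @export
read_trace <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  need <- c("time_s", "v_m_V", "i_nap_nA", "i_pump_nA", "na_i_M")
  miss <- setdiff(need, header)
  if (length(miss)) {
    stop("read_trace: header of '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  x <- utils::read.csv(path, colClasses = "numeric")
  bad <- which(!stats::complete.cases(x))
  if (length(bad)) {
    stop("read_trace: malformed row at line ", bad[1] + 1L, " of ", path)
  }
  as_hn_trace(x)
}

#' @param trace an `hn_trace`.
#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hn_trace"))
  df <- as.data.frame(trace)
  df[] <- lapply(df, function(col) signif(col, 15))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
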