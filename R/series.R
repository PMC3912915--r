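## Abundance time series container and CSV input/output.

#' Regularly sampled abundance series
#'
#' @param counts nonnegative abundances.
#' @param times observation times in days; defaults to `0, dt, 2 dt, ...`.
#' @param replicate replicate identifier.
#' @param dt sampling interval in days (default 4, the microcosm sampling
#'   interval the package emulates).
#' @return object of class `"abundance_series"`.
#' @export
abundance_series <- function(counts, times = NULL, replicate = "r1", dt = 4) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  if (is.null(times)) times <- seq(0, by = dt, length.out = length(counts))
  if (length(times) != length(counts))
    stop("times and counts must have equal length")
  if (length(times) >= 2) {
    gaps <- diff(times)
    if (any(gaps <= 0)) stop("times must be strictly increasing")
    if (max(abs(gaps - gaps[1])) > 1e-8 * max(gaps))
      stop("sampling must be regular; irregular gaps after times ",
           paste(times[which(abs(gaps - gaps[1]) > 1e-8 * max(gaps))],
                 collapse = ", "))
    dt <- gaps[1]
  }
  structure(list(times = as.numeric(times), counts = counts,
                 replicate = as.character(replicate), dt = dt),
            class = "abundance_series")
}

#' @export
print.abundance_series <- function(x, ...) {
  cat("Abundance series", x$replicate, "-", length(x$counts),
      "samples every", x$dt, "days\n")
  cat("  counts:", paste(signif(utils::head(x$counts, 8), 4), collapse = " "),
      if (length(x$counts) > 8) "...", "\n")
  invisible(x)
}

## normalise to a list of abundance_series
.as_series_list <- function(series) {
  if (inherits(series, "abundance_series")) return(list(series))
  stopifnot(is.list(series),
            all(vapply(series, inherits, TRUE, "abundance_series")))
  series
}

## retained prefix: everything up to and including the first observation
## below one individual (extinction is absorbing; later values carry no
## additional information)
.retained_counts <- function(s) {
  cnt <- s$counts
  low <- which(cnt < 1)
  if (length(low)) cnt <- cnt[seq_len(low[1])]
  cnt
}

#' Read abundance series from CSV
#'
#' Expects columns `replicate`, `time_days` and `count`; each replicate must
#' be regularly sampled.
#'
#' @param path CSV file path.
#' @return list of [abundance_series()], one per replicate.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "time_days", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$count)) || any(df$count < 0))
    stop("negative or non-numeric count in rows ",
         paste(which(!is.finite(df$count) | df$count < 0), collapse = ", "))
  out <- lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time_days), ]
    abundance_series(d$count, d$time_days, replicate = d$replicate[1])
  })
  out[order(names(out))]
}

#' Write abundance series to CSV
#'
#' @param series an [abundance_series()] or list of them.
#' @param path output file path.
#' @export
write_series_csv <- function(series, path) {
  series <- .as_series_list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(replicate = s$replicate, time_days = s$times,
               count = s$counts)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
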