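#' Flatten a study report to metric/value pairs
#'
#' Numeric leaves of the nested report, with dot-joined metric names. Era
#' tables are included per era; non-numeric entries (scope labels, id
#' lists) are dropped.
#'
#' @param report An `ob_report`.
#' @return Tibble with `metric` and unrounded numeric `value`.
#' @export
flatten_report <- function(report) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x) && !is.data.frame(x)) {
      for (nm in names(x)) {
        walk(x[[nm]], if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm)
      }
    } else if (is.data.frame(x)) {
      key <- if ("era" %in% names(x)) x$era else as.character(seq_len(nrow(x)))
      nums <- names(x)[vapply(x, is.numeric, logical(1))]
      for (i in seq_len(nrow(x))) {
        for (nm in nums) {
          out[[paste(prefix, key[i], nm, sep = ".")]] <<- x[[nm]][i]
        }
      }
    } else if (is.numeric(x) && length(x) == 1L) {
      out[[prefix]] <<- as.numeric(x)
    }
  }
  rep2 <- unclass(report)
  rep2$scope <- NULL
  rep2$quartile_type <- NULL
  walk(rep2, "")
  tibble::tibble(metric = names(out), value = unname(unlist(out)))
}

# Reporting precision: percentages as whole numbers, durations and other
# medians/quartiles to one decimal, counts as integers.
.report_round <- function(metric, value) {
  pct <- grepl("pct", metric)
  yrs <- grepl("(median|q1|q3|_years)", metric) & !pct
  out <- value
  out[pct] <- round_half_up(value[pct], 0)
  out[yrs] <- round_half_up(value[yrs], 1)
  out[!pct & !yrs] <- round_half_up(value[!pct & !yrs], 0)
  out
}

#' Export a study report
#'
#' Serializes an `ob_report` (or an already-flat metric/value tibble) at
#' the reporting precision: durations and quartiles to one decimal,
#' percentages and counts as whole numbers. Re-reading a written report
#' yields exactly the serialized values, so CSV and JSON round-trip each
#' other losslessly at that precision.
#'
#' @param report An `ob_report` or a tibble with `metric` and `value`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  flat <- if (inherits(report, "ob_report")) flatten_report(report) else report
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    rlang::abort(sprintf("unwritable path (no such directory): %s", dir))
  }
  flat$value <- .report_round(flat$metric, flat$value)
  if (format == "csv") {
    utils::write.csv(
      data.frame(metric = flat$metric, value = flat$value),
      path,
      row.names = FALSE, quote = FALSE
    )
  } else {
    jsonlite::write_json(
      as.list(stats::setNames(flat$value, flat$metric)),
      path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

#' Read back an exported report
#'
#' @param path File written by [export_report()].
#' @param format `"csv"` or `"json"`.
#' @return Tibble with `metric` and numeric `value`.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    tibble::tibble(metric = as.character(df$metric), value = as.numeric(df$value))
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    tibble::tibble(metric = names(x), value = as.numeric(unlist(x)))
  }
}
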