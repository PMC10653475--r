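#' Parse Orange Book-style dates
#'
#' Accepts the three date dialects found in Orange Book data files and
#' transcriptions of them: ISO-8601 (`"2000-04-20"`), the data-file style
#' (`"Apr 20, 2000"`), and the table style (`"4/20/2000"`). Values are
#' normalized to `Date` internally; all serialization is ISO-8601.
#'
#' @param x Character vector of dates.
#' @param field Field name used in error messages.
#' @return A `Date` vector. Empty strings and `NA` become `NA`.
#' @examples
#' parse_ob_date(c("Apr 20, 2000", "2015-12-16", "6/14/1996"))
#' @export
parse_ob_date <- function(x, field = "date") {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  blank <- is.na(x) | x == ""
  todo <- which(!blank)
  if (length(todo) == 0L) {
    return(out)
  }
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x[todo])
  mdy <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x[todo])
  out[todo[iso]] <- as.Date(x[todo[iso]], format = "%Y-%m-%d")
  out[todo[mdy]] <- as.Date(x[todo[mdy]], format = "%m/%d/%Y")
  rest <- todo[!iso & !mdy]
  if (length(rest) > 0L) {
    # Month-name dialect; force the C locale so "Apr" parses everywhere
    old <- Sys.getlocale("LC_TIME")
    on.exit(suppressWarnings(Sys.setlocale("LC_TIME", old)), add = TRUE)
    suppressWarnings(Sys.setlocale("LC_TIME", "C"))
    out[rest] <- as.Date(x[rest], format = "%b %d, %Y")
  }
  bad <- which(!blank & is.na(out))
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "Unparseable %s value(s): %s",
      field, paste(utils::head(x[bad], 5L), collapse = ", ")
    ))
  }
  out
}

#' Decimal years between two dates
#'
#' Calendar-day difference divided by 365.25, the convention used for every
#' duration this package reports. Month arithmetic is never used.
#'
#' @param start,end `Date` vectors (recycled).
#' @return Numeric vector of decimal years; negative when `end` precedes
#'   `start`.
#' @examples
#' years_between(as.Date("2000-04-20"), as.Date("2015-12-16"))
#' @export
years_between <- function(start, end) {
  as.numeric(as.Date(end) - as.Date(start)) / 365.25
}

#' Round half away from zero
#'
#' Reporting convention for whole-number percentages (base `round()` rounds
#' half to even, which is not how the source tallies read).
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a whole, as a whole number
#' @param part,whole Numerics.
#' @return Integer-valued percentage (half away from zero); `NA` when
#'   `whole` is zero.
#' @keywords internal
pct_of <- function(part, whole) {
  ifelse(whole == 0, NA_real_, round_half_up(100 * part / whole))
}
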