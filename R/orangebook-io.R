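#' @title Orange Book-style file readers and writers
#'
#' @description
#' The FDA distributes its Orange Book listings as tilde-delimited text files
#' with a header row (`products.txt`, `patent.txt`, `exclusivity.txt`). These
#' functions read and write that layout with a fixed, canonical column set:
#'
#' * products: `Appl_No~Product_No~Trade_Name~Ingredient~DF_Route~Approval_Date~Applicant`
#' * patents: `Appl_No~Product_No~Patent_No~Patent_Expire_Date~Submission_Date~Drug_Substance_Flag~Drug_Product_Flag~Use_Code`
#' * exclusivities: `Appl_No~Product_No~Exclusivity_Code~Exclusivity_Date`
#'
#' Multiple active ingredients within one product field are separated by
#' `";"`. Dates may be ISO-8601, `"Mon DD, YYYY"`, or `"MM/DD/YYYY"` on input
#' and are normalized to `Date`; the writers always emit ISO-8601 so that a
#' generate-read-write cycle is byte-identical.
#'
#' @name orangebook_io
NULL

.ob_product_cols <- c(
  "Appl_No", "Product_No", "Trade_Name", "Ingredient", "DF_Route",
  "Approval_Date", "Applicant"
)
.ob_patent_cols <- c(
  "Appl_No", "Product_No", "Patent_No", "Patent_Expire_Date",
  "Submission_Date", "Drug_Substance_Flag", "Drug_Product_Flag", "Use_Code"
)
.ob_excl_cols <- c("Appl_No", "Product_No", "Exclusivity_Code", "Exclusivity_Date")

# Exclusivity code prefixes recognised without a warning at read time.
.known_excl_prefixes <- c("NCE", "NPP", "NP", "NC", "NR", "PED", "I", "D")

.read_delim_fixed <- function(path, cols, delim = "~", what = "file") {
  if (!file.exists(path)) {
    rlang::abort(sprintf("%s not found: %s", what, path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  if (length(lines) == 0L || !nzchar(lines[1L])) {
    rlang::abort(sprintf("%s has no header row: %s", what, path))
  }
  header <- strsplit(lines[1L], delim, fixed = TRUE)[[1L]]
  if (length(header) != length(cols)) {
    rlang::abort(sprintf(
      "%s header has %d fields, expected %d (%s)",
      what, length(header), length(cols), path
    ))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    out <- as.list(rep(list(character()), length(cols)))
    names(out) <- cols
    return(tibble::as_tibble(out))
  }
  # sentinel keeps trailing empty fields (strsplit drops them otherwise)
  parts <- strsplit(paste0(body, delim, "\x01"), delim, fixed = TRUE)
  parts <- lapply(parts, function(p) p[-length(p)])
  nf <- lengths(parts)
  bad <- which(nf != length(cols))
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "Malformed row at line %d of %s: %d fields, expected %d",
      bad[1L] + 1L, path, nf[bad[1L]], length(cols)
    ))
  }
  mat <- do.call(rbind, parts)
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  names(out) <- cols
  out[] <- lapply(out, trimws)
  out
}

#' Read an Orange Book-style products file
#'
#' @param path Path to a tilde-delimited products file with header.
#' @param delim Field delimiter (default `"~"`, the Orange Book convention).
#' @param ingredient_sep Separator between multiple active ingredients within
#'   the ingredient field (default `";"`).
#' @return A tibble with one row per product: `appl_no`, `product_no`,
#'   `trade_name`, `active_ingredients` (list-column of character vectors),
#'   `dosage_form_route`, `approval_date` (`Date`), `applicant`.
#' @examples
#' f <- tempfile()
#' writeLines(c(
#'   "Appl_No~Product_No~Trade_Name~Ingredient~DF_Route~Approval_Date~Applicant",
#'   "NDA021081~001~LANTUS~INSULIN GLARGINE~INJECTABLE;SUBCUTANEOUS~Apr 20, 2000~SANOFI"
#' ), f)
#' read_products(f)
#' @export
read_products <- function(path, delim = "~", ingredient_sep = ";") {
  raw <- .read_delim_fixed(path, .ob_product_cols, delim, "products file")
  if (any(!nzchar(raw$Appl_No))) {
    rlang::abort("products file has rows with empty Appl_No")
  }
  key <- paste(raw$Appl_No, raw$Product_No, sep = "/")
  if (anyDuplicated(key)) {
    rlang::abort(sprintf(
      "duplicate (Appl_No, Product_No) in products file: %s",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    ))
  }
  tibble::tibble(
    appl_no = raw$Appl_No,
    product_no = raw$Product_No,
    trade_name = raw$Trade_Name,
    active_ingredients = lapply(
      strsplit(raw$Ingredient, ingredient_sep, fixed = TRUE), trimws
    ),
    dosage_form_route = raw$DF_Route,
    approval_date = parse_ob_date(raw$Approval_Date, "Approval_Date"),
    applicant = raw$Applicant
  )
}

#' Read an Orange Book-style patent file
#'
#' Duplicate (`appl_no`, `product_no`, `patent_no`) rows are legitimate in
#' Orange Book data (a patent may cover both the vial and the pen under one
#' NDA) and are preserved; a message flags them for audit.
#'
#' @inheritParams read_products
#' @return A tibble: `appl_no`, `product_no`, `patent_no`,
#'   `patent_expire_date` (`Date`), `submission_date` (`Date`, `NA` when the
#'   first Orange Book listing date is unknown), plus passthrough flag and
#'   use-code columns.
#' @export
read_patents <- function(path, delim = "~") {
  raw <- .read_delim_fixed(path, .ob_patent_cols, delim, "patent file")
  if (any(!nzchar(raw$Patent_No))) {
    rlang::abort("patent file has rows with empty Patent_No")
  }
  key <- paste(raw$Appl_No, raw$Product_No, raw$Patent_No, sep = "/")
  if (anyDuplicated(key)) {
    message(sprintf(
      "read_patents: %d duplicate (appl_no, product_no, patent_no) row(s) retained: %s",
      sum(duplicated(key)),
      paste(unique(key[duplicated(key)]), collapse = ", ")
    ))
  }
  tibble::tibble(
    appl_no = raw$Appl_No,
    product_no = raw$Product_No,
    patent_no = raw$Patent_No,
    patent_expire_date = parse_ob_date(raw$Patent_Expire_Date, "Patent_Expire_Date"),
    submission_date = parse_ob_date(raw$Submission_Date, "Submission_Date"),
    drug_substance_flag = raw$Drug_Substance_Flag,
    drug_product_flag = raw$Drug_Product_Flag,
    use_code = raw$Use_Code
  )
}

#' Read an Orange Book-style exclusivity file
#'
#' @inheritParams read_products
#' @return A tibble: `appl_no`, `product_no`, `exclusivity_code`,
#'   `exclusivity_date` (`Date`, the expiry). Rows whose code prefix is not a
#'   recognised exclusivity category are retained and flagged with a warning;
#'   they map to category `"other"` downstream.
#' @export
read_exclusivities <- function(path, delim = "~") {
  raw <- .read_delim_fixed(path, .ob_excl_cols, delim, "exclusivity file")
  if (any(!nzchar(raw$Exclusivity_Code))) {
    rlang::abort("exclusivity file has rows with empty Exclusivity_Code")
  }
  out <- tibble::tibble(
    appl_no = raw$Appl_No,
    product_no = raw$Product_No,
    exclusivity_code = raw$Exclusivity_Code,
    exclusivity_date = parse_ob_date(raw$Exclusivity_Date, "Exclusivity_Date")
  )
  prefix <- sub("[-0-9].*$", "", out$exclusivity_code)
  unknown <- !(prefix %in% .known_excl_prefixes)
  if (any(unknown)) {
    warning(sprintf(
      "read_exclusivities: unrecognised code(s) retained with category 'other': %s",
      paste(unique(out$exclusivity_code[unknown]), collapse = ", ")
    ), call. = FALSE)
  }
  out
}

#' Read a curated patent-annotation table
#'
#' The annotation table carries the per-patent metadata that, in the source
#' workflow, came from reading each patent at Google Patents: USPTO
#' application date, priority date (start of the 20-year term), whether the
#' patent covers the delivery device, and whether any claim mentions the
#' active ingredient (insulin) or its molecular structure.
#'
#' @param path CSV with columns `patent_no`, `application_date`,
#'   `priority_date`, `is_device`, `mentions_active` and optionally `title`.
#' @return A tibble with parsed dates and strict logical flags. A missing
#'   priority date falls back to the application date with a warning; a
#'   priority date after the application date is an error (the priority date
#'   is by definition the earliest filing in the family).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("annotation file not found: %s", path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("patent_no", "application_date", "priority_date", "is_device", "mentions_active")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    rlang::abort(sprintf(
      "annotation file missing column(s): %s", paste(miss, collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    patent_no = trimws(raw$patent_no),
    application_date = parse_ob_date(raw$application_date, "application_date"),
    priority_date = parse_ob_date(raw$priority_date, "priority_date"),
    is_device = .parse_strict_logical(raw$is_device, "is_device"),
    mentions_active = .parse_strict_logical(raw$mentions_active, "mentions_active"),
    title = if ("title" %in% names(raw)) trimws(raw$title) else NA_character_
  )
  fallback <- is.na(out$priority_date)
  if (any(fallback)) {
    warning(sprintf(
      "read_annotations: missing priority_date for %s; using application_date",
      paste(out$patent_no[fallback], collapse = ", ")
    ), call. = FALSE)
    out$priority_date[fallback] <- out$application_date[fallback]
  }
  bad <- which(!is.na(out$priority_date) & !is.na(out$application_date) &
    out$priority_date > out$application_date)
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "priority_date after application_date for patent(s): %s",
      paste(out$patent_no[bad], collapse = ", ")
    ))
  }
  out
}

.parse_strict_logical <- function(x, field) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "1", "yes")] <- TRUE
  out[x %in% c("false", "0", "no")] <- FALSE
  bad <- which(is.na(out) & !(x %in% c("", "na")))
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "field %s: cannot parse %s as logical (accepted: true/false/1/0/yes/no)",
      field, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  as.logical(out)
}

# ---- canonical writers (used by the synthetic generator and the pipeline) ----

.fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))

#' Write Orange Book-style files in the canonical dialect
#'
#' The canonical dialect is tilde-delimited, UTF-8, ISO-8601 dates, `";"`
#' between ingredients, LF line endings. Reading a written file and writing
#' it again is byte-identical.
#'
#' @param products,patents,exclusivities Tibbles in the shapes produced by
#'   [read_products()], [read_patents()], [read_exclusivities()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path) {
  rows <- vapply(seq_len(nrow(products)), function(i) {
    paste(
      products$appl_no[i], products$product_no[i], products$trade_name[i],
      paste(products$active_ingredients[[i]], collapse = ";"),
      products$dosage_form_route[i], .fmt_date(products$approval_date[i]),
      products$applicant[i],
      sep = "~"
    )
  }, character(1))
  writeLines(c(paste(.ob_product_cols, collapse = "~"), rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_products
#' @export
write_patents <- function(patents, path) {
  rows <- paste(
    patents$appl_no, patents$product_no, patents$patent_no,
    .fmt_date(patents$patent_expire_date), .fmt_date(patents$submission_date),
    patents$drug_substance_flag, patents$drug_product_flag, patents$use_code,
    sep = "~"
  )
  writeLines(c(paste(.ob_patent_cols, collapse = "~"), rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_products
#' @export
write_exclusivities <- function(exclusivities, path) {
  rows <- paste(
    exclusivities$appl_no, exclusivities$product_no,
    exclusivities$exclusivity_code, .fmt_date(exclusivities$exclusivity_date),
    sep = "~"
  )
  writeLines(c(paste(.ob_excl_cols, collapse = "~"), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Write a patent-annotation table
#' @param annotations Tibble as produced by [read_annotations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    patent_no = annotations$patent_no,
    application_date = .fmt_date(annotations$application_date),
    priority_date = .fmt_date(annotations$priority_date),
    is_device = tolower(as.character(annotations$is_device)),
    mentions_active = tolower(as.character(annotations$mentions_active)),
    title = ifelse(is.na(annotations$title), "", annotations$title),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
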