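# Small hand-built inputs used across the unit tests. Everything is
# generated in code; nothing is read from disk except what the tests write
# to tempfiles themselves.

write_lines_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

ob_product_header <- "Appl_No~Product_No~Trade_Name~Ingredient~DF_Route~Approval_Date~Applicant"
ob_patent_header <- "Appl_No~Product_No~Patent_No~Patent_Expire_Date~Submission_Date~Drug_Substance_Flag~Drug_Product_Flag~Use_Code"
ob_excl_header <- "Appl_No~Product_No~Exclusivity_Code~Exclusivity_Date"

# Two-line cohort: LANTUS-ish vial+pen under one NDA plus a vial-only brand,
# and one follow-on line sharing the first line's ingredient.
mini_products <- function() {
  tibble::tibble(
    appl_no = c("NDA1", "NDA1", "NDA2", "NDA3"),
    product_no = c("001", "002", "001", "001"),
    trade_name = c("ALPHA", "ALPHA PEN", "BETA", "GAMMA"),
    active_ingredients = list("INSULIN X", "INSULIN X", "INSULIN Y", "INSULIN X"),
    dosage_form_route = "INJECTABLE;SUBCUTANEOUS",
    approval_date = as.Date(c("2000-04-20", "2007-05-01", "2010-06-15", "2015-12-16")),
    applicant = c("ACME", "ACME", "BMAKER", "CMAKER")
  )
}

mini_metadata <- function() {
  tibble::tibble(
    appl_no = c("NDA1", "NDA1", "NDA2", "NDA3"),
    product_no = c("001", "002", "001", "001"),
    brand_family = c("ALPHA", "ALPHA", "BETA", "GAMMA"),
    insulin_class = c("long", "long", "rapid", "long"),
    presentation = c("vial", "single_use_device", "vial", "single_use_device"),
    originator_or_followon = c("originator", "originator", "originator", "followon"),
    manufacturer = c("ACME", "ACME", "BMAKER", "CMAKER")
  )
}

mini_cohort <- function() {
  build_cohort(mini_products(), cohort_config(), mini_metadata())
}

mini_raw_patents <- function() {
  tibble::tibble(
    appl_no = c("NDA1", "NDA1", "NDA1", "NDA2"),
    product_no = c("001", "002", "002", "001"),
    patent_no = c("US100", "US100", "US200", "US300"),
    patent_expire_date = as.Date(c("2017-01-01", "2017-01-01", "2033-03-16", "2022-08-01")),
    submission_date = as.Date(c("2000-04-20", "2007-05-01", "2012-03-01", "2010-06-15")),
    drug_substance_flag = "Y", drug_product_flag = "Y", use_code = ""
  )
}

mini_annotations <- function() {
  tibble::tibble(
    patent_no = c("US100", "US200", "US300"),
    application_date = as.Date(c("1998-05-01", "2008-09-01", "2006-01-10")),
    priority_date = as.Date(c("1997-05-01", "2008-01-01", "2005-01-10")),
    is_device = c(FALSE, TRUE, FALSE),
    mentions_active = c(FALSE, FALSE, TRUE),
    title = NA_character_
  )
}

mini_raw_exclusivities <- function() {
  tibble::tibble(
    appl_no = c("NDA1", "NDA2"),
    product_no = c("001", "001"),
    exclusivity_code = c("NCE", "PED"),
    exclusivity_date = as.Date(c("2005-04-20", "2016-01-01"))
  )
}

mini_classified <- function(cohort = mini_cohort()) {
  link_and_classify(
    mini_raw_patents(), mini_raw_exclusivities(), mini_annotations(), cohort
  )
}

# Independent brute-force oracles --------------------------------------------

bf_max_date <- function(dates) {
  dates <- dates[!is.na(dates)]
  if (length(dates) == 0L) {
    return(as.Date(NA))
  }
  j <- 1L
  for (i in seq_along(dates)) if (dates[i] > dates[j]) j <- i
  dates[j]
}

bf_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

bf_median_iqr <- function(x) {
  c(
    median = bf_quantile(x, 0.5),
    q1 = bf_quantile(x, 0.25),
    q3 = bf_quantile(x, 0.75)
  )
}
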