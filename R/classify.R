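#' Patent filing and listing timing relative to FDA approval
#'
#' A patent is *pre-approval filed* when its USPTO application date is
#' strictly before the linked product's FDA approval date, otherwise
#' *post-approval filed* (an application filed on the approval day counts as
#' post; the tie rule is a documented strict-inequality convention). The
#' listing axis is independent: a patent is *listed at approval* when its
#' first Orange Book listing date is on or before approval plus `grace`
#' days. When the first listing date is unknown, the listing label defaults
#' to the filing label with a warning.
#'
#' @param application_date,approval_date,first_listing `Date` vectors
#'   (recycled to common length); `first_listing` may be `NA`.
#' @param grace Days after approval still counted as listed at approval
#'   (default 0).
#' @return A tibble with `filing_timing`
#'   (`pre_approval_filed`/`post_approval_filed`) and `listing_timing`
#'   (`listed_at_approval`/`listed_post_approval`).
#' @export
patent_timing <- function(application_date, approval_date,
                          first_listing = as.Date(NA), grace = 0L) {
  n <- max(length(application_date), length(approval_date), length(first_listing))
  application_date <- rep_len(as.Date(application_date), n)
  approval_date <- rep_len(as.Date(approval_date), n)
  first_listing <- rep_len(as.Date(first_listing), n)
  if (any(is.na(application_date))) {
    rlang::abort("patent_timing: application_date must be present")
  }
  filing <- ifelse(application_date < approval_date,
    "pre_approval_filed", "post_approval_filed"
  )
  listing <- ifelse(first_listing <= approval_date + grace,
    "listed_at_approval", "listed_post_approval"
  )
  missing_listing <- is.na(first_listing)
  if (any(missing_listing)) {
    warning(
      "patent_timing: missing first-listing date(s); listing timing defaulted from filing timing",
      call. = FALSE
    )
    listing[missing_listing] <- ifelse(
      filing[missing_listing] == "pre_approval_filed",
      "listed_at_approval", "listed_post_approval"
    )
  }
  tibble::tibble(filing_timing = filing, listing_timing = listing)
}

#' Priority-date timing relative to FDA approval
#'
#' Strict comparison; a priority date equal to the approval date counts as
#' after (same tie convention as [patent_timing()]).
#'
#' @param priority_date,approval_date `Date` vectors (recycled).
#' @return Character vector, `"priority_before_approval"` or
#'   `"priority_after_approval"`.
#' @export
priority_timing <- function(priority_date, approval_date) {
  ifelse(as.Date(priority_date) < as.Date(approval_date),
    "priority_before_approval", "priority_after_approval"
  )
}

.map_excl_category <- function(code, map) {
  prefix <- sub("[-0-9].*$", "", code)
  cat <- map$category[match(prefix, map$code_prefix)]
  ifelse(is.na(cat), "other", cat)
}

#' Link raw listings to the cohort and classify them
#'
#' Merges Orange Book patent and exclusivity rows with the cohort and the
#' curated patent annotations, producing one classified record per
#' (patent, product) pair — a patent listed on both the vial and the pen of
#' one NDA yields two records, matching the per-product tallies used in the
#' analysis; "unique patent" analyses deduplicate by `patent_no` explicitly.
#'
#' Device status is exhaustive and mutually exclusive: `non_device`,
#' `device_mention` (a device patent whose claims mention the active
#' ingredient or its molecular structure), or `device_no_mention`. Listings
#' on products outside the cohort are dropped with a message; a patent
#' without an annotation is an error.
#'
#' Exclusivity categories come from the code-prefix mapping (see
#' [exclusivity_code_map()]). Exclusivity grant timing is inferred from the
#' listed expiry: the grant date is estimated as expiry minus the category's
#' statutory term, and the exclusivity is `at_approval` when that estimate
#' is on or before the product's approval date, otherwise `post_approval`.
#' Pediatric exclusivities extend earlier protection and are always tallied
#' as `post_approval`.
#'
#' @param raw_patents From [read_patents()].
#' @param raw_exclusivities From [read_exclusivities()].
#' @param annotations From [read_annotations()].
#' @param cohort An `ob_cohort`.
#' @param code_map Exclusivity code mapping tibble.
#' @param grace Passed to [patent_timing()].
#' @return A list with tibbles `patents` (one row per patent-product pair,
#'   with `device_status`, `filing_timing`, `listing_timing`,
#'   `priority_timing`, dates, and the linked `product_id`) and
#'   `exclusivities` (with `category` and `timing`).
#' @export
link_and_classify <- function(raw_patents, raw_exclusivities, annotations,
                              cohort, code_map = exclusivity_code_map(),
                              grace = 0L) {
  stopifnot(inherits(cohort, "ob_cohort"))
  prods <- cohort$products

  pat <- raw_patents
  pat$product_id <- paste(pat$appl_no, pat$product_no, sep = "/")
  in_cohort <- pat$product_id %in% prods$product_id
  if (any(!in_cohort)) {
    message(sprintf(
      "link_and_classify: dropped %d patent listing(s) on products outside the cohort",
      sum(!in_cohort)
    ))
  }
  pat <- pat[in_cohort, , drop = FALSE]

  missing_ann <- setdiff(unique(pat$patent_no), annotations$patent_no)
  if (length(missing_ann) > 0L) {
    rlang::abort(sprintf(
      "missing annotation(s) for patent(s): %s", paste(missing_ann, collapse = ", ")
    ))
  }

  ann <- annotations[match(pat$patent_no, annotations$patent_no), , drop = FALSE]
  approval <- prods$approval_date[match(pat$product_id, prods$product_id)]
  timing <- suppressWarnings(
    patent_timing(ann$application_date, approval, pat$submission_date, grace)
  )

  patents <- tibble::tibble(
    product_id = pat$product_id,
    appl_no = pat$appl_no,
    product_no = pat$product_no,
    patent_no = pat$patent_no,
    expiry = pat$patent_expire_date,
    first_listing = pat$submission_date,
    application_date = ann$application_date,
    priority_date = ann$priority_date,
    approval_date = approval,
    device_status = ifelse(!ann$is_device, "non_device",
      ifelse(ann$mentions_active, "device_mention", "device_no_mention")
    ),
    filing_timing = timing$filing_timing,
    listing_timing = timing$listing_timing,
    priority_timing = priority_timing(ann$priority_date, approval)
  )
  patents <- patents[order(patents$product_id, patents$patent_no), , drop = FALSE]

  exc <- raw_exclusivities
  exc$product_id <- paste(exc$appl_no, exc$product_no, sep = "/")
  exc_in <- exc$product_id %in% prods$product_id
  if (any(!exc_in)) {
    message(sprintf(
      "link_and_classify: dropped %d exclusivity listing(s) on products outside the cohort",
      sum(!exc_in)
    ))
  }
  exc <- exc[exc_in, , drop = FALSE]
  category <- .map_excl_category(exc$exclusivity_code, code_map)
  term_years <- code_map$term_years[match(category, code_map$category)]
  approval_e <- prods$approval_date[match(exc$product_id, prods$product_id)]
  grant_est <- exc$exclusivity_date - round(ifelse(is.na(term_years), 3, term_years) * 365.25)
  timing_e <- ifelse(
    category == "pediatric" | grant_est > approval_e,
    "post_approval", "at_approval"
  )
  exclusivities <- tibble::tibble(
    product_id = exc$product_id,
    appl_no = exc$appl_no,
    product_no = exc$product_no,
    code = exc$exclusivity_code,
    category = category,
    expiry = exc$exclusivity_date,
    approval_date = approval_e,
    timing = timing_e
  )
  exclusivities <- exclusivities[order(
    exclusivities$product_id, exclusivities$code
  ), , drop = FALSE]

  list(patents = patents, exclusivities = exclusivities)
}
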