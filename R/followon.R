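#' Match 505(b)(2) follow-on lines to originator lines
#'
#' A follow-on competes with an originator line when the two lines have
#' exactly the same normalized active-ingredient set but different
#' manufacturers. One originator may face several follow-ons (the earliest
#' approval is kept as `first_followon_approval`), and one follow-on may
#' match several originator lines (e.g., human insulin); all matches are
#' reported. A follow-on matching no originator line triggers a warning and
#' is listed in the report.
#'
#' @param cohort An `ob_cohort` containing originator and follow-on lines.
#' @return A list with `matches` (tibble: `originator_line_id`,
#'   `followon_line_id`, `followon_approval`), `first_followon` (tibble:
#'   `originator_line_id`, `first_followon_approval`), and
#'   `unmatched_followons` (character).
#' @export
match_followons <- function(cohort) {
  stopifnot(inherits(cohort, "ob_cohort"))
  lines <- cohort$lines
  orig <- lines[lines$is_originator, , drop = FALSE]
  fol <- lines[!lines$is_originator, , drop = FALSE]
  pairs <- lapply(seq_len(nrow(fol)), function(i) {
    hit <- orig$ingredients_key == fol$ingredients_key[i] &
      orig$manufacturer != fol$manufacturer[i]
    if (!any(hit)) {
      return(NULL)
    }
    tibble::tibble(
      originator_line_id = orig$line_id[hit],
      followon_line_id = fol$line_id[i],
      followon_approval = fol$first_approval[i]
    )
  })
  matched_ids <- vapply(
    seq_len(nrow(fol)), function(i) !is.null(pairs[[i]]), logical(1)
  )
  unmatched <- fol$line_id[!matched_ids]
  if (length(unmatched) > 0L) {
    warning(sprintf(
      "match_followons: follow-on line(s) matching no originator: %s",
      paste(unmatched, collapse = ", ")
    ), call. = FALSE)
  }
  matches <- dplyr::bind_rows(pairs)
  if (nrow(matches) == 0L) {
    matches <- tibble::tibble(
      originator_line_id = character(), followon_line_id = character(),
      followon_approval = as.Date(character())
    )
  }
  matches <- matches[order(matches$originator_line_id, matches$followon_line_id), ,
    drop = FALSE
  ]
  first <- if (nrow(matches) == 0L) {
    tibble::tibble(
      originator_line_id = character(),
      first_followon_approval = as.Date(character())
    )
  } else {
    matches |>
      dplyr::group_by(.data$originator_line_id) |>
      dplyr::summarise(
        first_followon_approval = min(.data$followon_approval), .groups = "drop"
      )
  }
  list(matches = matches, first_followon = first, unmatched_followons = unmatched)
}

#' Protection truncated at first follow-on entry
#'
#' Sensitivity-analysis duration: from FDA approval to the last-to-expire
#' patent or exclusivity *or* the approval of the first follow-on, whichever
#' occurs first. Products (or lines) without a matched follow-on keep their
#' untruncated duration.
#'
#' @param protection A tibble with `last_expiry` and an approval column
#'   (`approval_date` for products, `first_approval` for lines), as
#'   returned by [product_protection()] or [line_protection()].
#' @param first_followon_approval `Date` vector aligned with
#'   `protection` rows; `NA` means no follow-on.
#' @return `protection` with added columns `truncated_expiry` and
#'   `truncated_years`.
#' @export
truncated_protection <- function(protection, first_followon_approval) {
  approval <- if ("approval_date" %in% names(protection)) {
    protection$approval_date
  } else {
    protection$first_approval
  }
  cutoff <- rep_len(as.Date(first_followon_approval), nrow(protection))
  trunc_expiry <- as.Date(pmin(
    as.numeric(protection$last_expiry),
    as.numeric(cutoff),
    na.rm = TRUE
  ), origin = "1970-01-01")
  trunc_expiry[is.na(protection$last_expiry) & is.na(cutoff)] <- as.Date(NA)
  out <- protection
  out$truncated_expiry <- trunc_expiry
  out$truncated_years <- ifelse(
    is.na(trunc_expiry) | is.na(protection$last_expiry),
    NA_real_,
    years_between(approval, trunc_expiry)
  )
  out
}

#' Follow-on sensitivity analysis
#'
#' Runs [match_followons()] and applies the truncation to both product- and
#' line-level protection. A product is truncated at the earliest follow-on
#' matched to its line.
#'
#' @inheritParams product_protection
#' @return A list with `matches`, `products` (product protection with
#'   truncated columns) and `lines` (line protection with truncated
#'   columns).
#' @export
sensitivity_analysis <- function(cohort, patents, exclusivities,
                                 scope = protection_scope()) {
  fm <- match_followons(cohort)
  orig_line_ids <- cohort$lines$line_id[cohort$lines$is_originator]

  prot <- product_protection(cohort, patents, exclusivities, scope)
  # product -> line -> first follow-on date
  pid2line <- stats::setNames(
    rep(cohort$lines$line_id, lengths(cohort$lines$product_ids)),
    unlist(cohort$lines$product_ids)
  )
  line_cutoff <- stats::setNames(
    fm$first_followon$first_followon_approval,
    fm$first_followon$originator_line_id
  )
  prod_cut <- as.Date(unname(line_cutoff[pid2line[prot$product_id]]))
  is_orig_prod <- pid2line[prot$product_id] %in% orig_line_ids
  prod_cut[!is_orig_prod] <- NA
  prod_sens <- truncated_protection(prot, prod_cut)

  lprot <- line_protection(cohort, patents, exclusivities, scope)
  line_cut <- as.Date(unname(line_cutoff[lprot$line_id]))
  line_cut[!(lprot$line_id %in% orig_line_ids)] <- NA
  line_sens <- truncated_protection(lprot, line_cut)

  list(matches = fm, products = prod_sens, lines = line_sens)
}
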