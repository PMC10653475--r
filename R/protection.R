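#' Protection scope
#'
#' Selects which patents and exclusivities enter a duration computation.
#' Filters compose conjunctively. The patent filter has two timing axes —
#' filing with the USPTO (`pre_approval_filed_only`) and first Orange Book
#' listing (`at_approval_only`) — plus device-status subsets used by the
#' device-patent analyses.
#'
#' @param which_patents One of `"all"`, `"at_approval_only"` (listing axis),
#'   `"pre_approval_filed_only"` (filing axis), `"device_only"`,
#'   `"non_device_only"`, `"device_no_mention_only"`,
#'   `"other_than_no_mention"`, or `"none"`.
#' @param include_exclusivities Include regulatory exclusivities?
#' @param exclusivity_timing_filter `"all"` or `"at_approval_only"`.
#' @return A list of class `protection_scope`.
#' @export
protection_scope <- function(which_patents = c(
                               "all", "at_approval_only", "pre_approval_filed_only",
                               "device_only", "non_device_only",
                               "device_no_mention_only", "other_than_no_mention",
                               "none"
                             ),
                             include_exclusivities = TRUE,
                             exclusivity_timing_filter = c("all", "at_approval_only")) {
  structure(
    list(
      which_patents = match.arg(which_patents),
      include_exclusivities = include_exclusivities,
      exclusivity_timing_filter = match.arg(exclusivity_timing_filter)
    ),
    class = "protection_scope"
  )
}

.filter_patents <- function(patents, which) {
  switch(which,
    all = patents,
    at_approval_only = patents[patents$listing_timing == "listed_at_approval", , drop = FALSE],
    pre_approval_filed_only = patents[patents$filing_timing == "pre_approval_filed", , drop = FALSE],
    device_only = patents[patents$device_status != "non_device", , drop = FALSE],
    non_device_only = patents[patents$device_status == "non_device", , drop = FALSE],
    device_no_mention_only = patents[patents$device_status == "device_no_mention", , drop = FALSE],
    other_than_no_mention = patents[patents$device_status != "device_no_mention", , drop = FALSE],
    none = patents[0L, , drop = FALSE]
  )
}

.filter_exclusivities <- function(exclusivities, scope) {
  if (!scope$include_exclusivities) {
    return(exclusivities[0L, , drop = FALSE])
  }
  if (scope$exclusivity_timing_filter == "at_approval_only") {
    exclusivities[exclusivities$timing == "at_approval", , drop = FALSE]
  } else {
    exclusivities
  }
}

#' Last-to-expire date
#'
#' The latest expiry among a set of dated protections; the end of expected
#' protection is defined by the last-to-expire patent or regulatory
#' exclusivity, whichever occurs later.
#'
#' @param expiries A `Date` vector (`NA`s ignored).
#' @return The maximum date, or `NA` (as `Date`) for empty input.
#' @examples
#' last_to_expire(as.Date(c("2024-06-01", "2027-03-10", "2015-01-15")))
#' @export
last_to_expire <- function(expiries) {
  expiries <- as.Date(expiries)
  expiries <- expiries[!is.na(expiries)]
  if (length(expiries) == 0L) {
    return(as.Date(NA))
  }
  max(expiries)
}

# In-scope protection items for one product: expiry + kind, patents ranked
# above exclusivities and device above non-device on expiry ties.
.product_items <- function(product_id, patents, exclusivities, scope) {
  p <- .filter_patents(patents[patents$product_id == product_id, , drop = FALSE],
    scope$which_patents
  )
  e <- .filter_exclusivities(
    exclusivities[exclusivities$product_id == product_id, , drop = FALSE], scope
  )
  tibble::tibble(
    expiry = c(p$expiry, e$expiry),
    kind = c(
      ifelse(p$device_status == "non_device", "patent_non_device", "patent_device"),
      rep("exclusivity", nrow(e))
    ),
    rank = c(
      ifelse(p$device_status == "non_device", 2L, 3L),
      rep(1L, nrow(e))
    )
  )
}

#' Duration of expected protection per product
#'
#' For every cohort product, subtracts the FDA approval date from the
#' last-to-expire in-scope patent or regulatory exclusivity. Durations are
#' decimal years (calendar days / 365.25), unrounded; rounding to one
#' decimal happens only at report serialization. Products with no in-scope
#' protections get `NA` and are flagged for exclusion from duration medians
#' (they still count in cohort totals). A last expiry before approval
#' yields a negative duration with a warning.
#'
#' @param cohort An `ob_cohort`.
#' @param patents,exclusivities Classified tibbles from
#'   [link_and_classify()].
#' @param scope A [protection_scope()].
#' @return A tibble with one row per product: `product_id`, `approval_date`,
#'   `last_expiry`, `duration_years`, `last_item_kind` (`patent_device`,
#'   `patent_non_device`, `exclusivity`, or `none`) and
#'   `excluded_from_medians`.
#' @export
product_protection <- function(cohort, patents, exclusivities,
                               scope = protection_scope()) {
  prods <- if (inherits(cohort, "ob_cohort")) cohort$products else cohort
  rows <- lapply(seq_len(nrow(prods)), function(i) {
    pid <- prods$product_id[i]
    items <- .product_items(pid, patents, exclusivities, scope)
    if (nrow(items) == 0L) {
      return(tibble::tibble(
        product_id = pid, approval_date = prods$approval_date[i],
        last_expiry = as.Date(NA), duration_years = NA_real_,
        last_item_kind = "none", excluded_from_medians = TRUE
      ))
    }
    last <- last_to_expire(items$expiry)
    at_last <- items[items$expiry == last, , drop = FALSE]
    kind <- at_last$kind[which.max(at_last$rank)]
    tibble::tibble(
      product_id = pid, approval_date = prods$approval_date[i],
      last_expiry = last,
      duration_years = years_between(prods$approval_date[i], last),
      last_item_kind = kind, excluded_from_medians = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  neg <- which(!is.na(out$duration_years) & out$duration_years < 0)
  if (length(neg) > 0L) {
    warning(sprintf(
      "product_protection: last expiry precedes approval for %s (negative duration retained)",
      paste(out$product_id[neg], collapse = ", ")
    ), call. = FALSE)
  }
  out
}

#' Extension of protection from post-approval Orange Book listings
#'
#' For each product, the gain in expected protection attributable to
#' patents and exclusivities added after FDA approval: overall duration
#' minus the duration from at-approval listings alone. Reported only when a
#' product has post-approval listings and the gain is positive; otherwise
#' `NA`.
#'
#' @inheritParams product_protection
#' @return Tibble with `product_id` and `extension_years`.
#' @export
post_approval_extension <- function(cohort, patents, exclusivities) {
  all_prot <- product_protection(
    cohort, patents, exclusivities, protection_scope("all")
  )
  at_prot <- product_protection(
    cohort, patents, exclusivities,
    protection_scope("at_approval_only", exclusivity_timing_filter = "at_approval_only")
  )
  has_post <- vapply(all_prot$product_id, function(pid) {
    any(patents$product_id == pid & patents$listing_timing == "listed_post_approval") ||
      any(exclusivities$product_id == pid & exclusivities$timing == "post_approval")
  }, logical(1))
  gain <- ifelse(is.na(at_prot$duration_years),
    all_prot$duration_years,
    all_prot$duration_years - at_prot$duration_years
  )
  ext <- ifelse(has_post & !is.na(gain) & gain > 0, gain, NA_real_)
  tibble::tibble(product_id = all_prot$product_id, extension_years = unname(ext))
}

#' Duration of expected protection per insulin line
#'
#' Line-level span: from the approval of the first product in the line to
#' the last-to-expire in-scope patent or exclusivity across all products in
#' the line. `first_filing` (the earliest priority or application date over
#' the line's patents) is carried for timeline exports.
#'
#' @inheritParams product_protection
#' @return Tibble with one row per line: `line_id`, `first_filing`,
#'   `first_approval`, `last_expiry`, `duration_years`,
#'   `excluded_from_medians`.
#' @export
line_protection <- function(cohort, patents, exclusivities,
                            scope = protection_scope()) {
  stopifnot(inherits(cohort, "ob_cohort"))
  prot <- product_protection(cohort, patents, exclusivities, scope)
  rows <- lapply(seq_len(nrow(cohort$lines)), function(i) {
    ln <- cohort$lines[i, ]
    pids <- ln$product_ids[[1L]]
    sub <- prot[prot$product_id %in% pids, , drop = FALSE]
    lpat <- patents[patents$product_id %in% pids, , drop = FALSE]
    first_filing <- suppressWarnings(
      min(c(lpat$priority_date, lpat$application_date), na.rm = TRUE)
    )
    if (is.infinite(first_filing)) first_filing <- as.Date(NA)
    last <- last_to_expire(sub$last_expiry)
    tibble::tibble(
      line_id = ln$line_id,
      first_filing = as.Date(first_filing),
      first_approval = ln$first_approval,
      last_expiry = last,
      duration_years = if (is.na(last)) {
        NA_real_
      } else {
        years_between(ln$first_approval, last)
      },
      excluded_from_medians = is.na(last)
    )
  })
  dplyr::bind_rows(rows)
}

#' Added protection from device patents
#'
#' For drug-device combination products, the signed difference in years
#' between the last-to-expire device patent and the last-to-expire
#' non-device patent. `NA` when either patent class is absent. Negative
#' values (device frontier expiring first) are retained; reporting layers
#' select the positive subset.
#'
#' @param cohort An `ob_cohort`.
#' @param patents Classified patent tibble.
#' @return Tibble with `product_id`, `added_years`, and the two frontier
#'   dates `device_last`, `non_device_last`.
#' @export
device_added_protection <- function(cohort, patents) {
  prods <- cohort$products[cohort$products$is_drug_device, , drop = FALSE]
  rows <- lapply(prods$product_id, function(pid) {
    p <- patents[patents$product_id == pid, , drop = FALSE]
    dev <- last_to_expire(p$expiry[p$device_status != "non_device"])
    nondev <- last_to_expire(p$expiry[p$device_status == "non_device"])
    tibble::tibble(
      product_id = pid,
      device_last = dev, non_device_last = nondev,
      added_years = if (is.na(dev) || is.na(nondev)) {
        NA_real_
      } else {
        years_between(nondev, dev)
      }
    )
  })
  dplyr::bind_rows(rows)
}

#' Added protection from no-mention device patents
#'
#' The protection afforded by device patents whose claims never mention the
#' active ingredient, over and above all other patents (device patents that
#' do mention it, or non-device patents, whichever expires later). Signed;
#' `NA` when either side is empty.
#'
#' @inheritParams device_added_protection
#' @return Tibble with `product_id`, `added_years`, `no_mention_last`,
#'   `complement_last`.
#' @export
no_mention_added_protection <- function(cohort, patents) {
  prods <- cohort$products[cohort$products$is_drug_device, , drop = FALSE]
  rows <- lapply(prods$product_id, function(pid) {
    p <- patents[patents$product_id == pid, , drop = FALSE]
    nm <- last_to_expire(p$expiry[p$device_status == "device_no_mention"])
    comp <- last_to_expire(p$expiry[p$device_status != "device_no_mention"])
    tibble::tibble(
      product_id = pid,
      no_mention_last = nm, complement_last = comp,
      added_years = if (is.na(nm) || is.na(comp)) {
        NA_real_
      } else {
        years_between(comp, nm)
      }
    )
  })
  dplyr::bind_rows(rows)
}

#' Timeline extract for protection-span plots
#'
#' One row per product and per line with first filing, approval, and last
#' expiry — the data behind approval-to-expiry timeline (Gantt-style)
#' figures.
#'
#' @inheritParams product_protection
#' @return Tibble with `entity_id`, `level` (`"product"`/`"line"`),
#'   `first_filing`, `approval`, `last_expiry`.
#' @export
timeline_extract <- function(cohort, patents, exclusivities,
                             scope = protection_scope()) {
  prot <- product_protection(cohort, patents, exclusivities, scope)
  prod_filing <- vapply(prot$product_id, function(pid) {
    p <- patents[patents$product_id == pid, , drop = FALSE]
    f <- suppressWarnings(min(c(p$priority_date, p$application_date), na.rm = TRUE))
    as.numeric(if (is.infinite(f)) NA else f)
  }, numeric(1))
  lines <- line_protection(cohort, patents, exclusivities, scope)
  dplyr::bind_rows(
    tibble::tibble(
      entity_id = prot$product_id, level = "product",
      first_filing = as.Date(prod_filing, origin = "1970-01-01"),
      approval = prot$approval_date, last_expiry = prot$last_expiry
    ),
    tibble::tibble(
      entity_id = lines$line_id, level = "line",
      first_filing = lines$first_filing,
      approval = lines$first_approval, last_expiry = lines$last_expiry
    )
  )
}
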