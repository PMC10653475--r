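#' Median and interquartile range
#'
#' The reporting convention for every duration and count summary: median
#' with first and third quartiles. The default quartile convention is
#' linear interpolation between order statistics (positions
#' `p * (n - 1)`, i.e., `stats::quantile` type 7); `"discrete"` uses actual
#' order statistics (type 1).
#'
#' @param values Non-empty numeric vector (`NA`s dropped).
#' @param type `"interpolated"` (default) or `"discrete"`.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @examples
#' median_iqr(c(1, 2, 3, 4)) # 2.5, 1.75, 3.25
#' @export
median_iqr <- function(values, type = c("interpolated", "discrete")) {
  type <- match.arg(type)
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    rlang::abort("median_iqr: empty input")
  }
  q <- stats::quantile(values,
    probs = c(0.5, 0.25, 0.75),
    type = if (type == "interpolated") 7L else 1L, names = FALSE
  )
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}

.tercile_eras <- tibble::tibble(
  era = c("1986-1996", "1997-2007", "2008-2019"),
  from = c(1986L, 1997L, 2008L),
  to = c(1996L, 2007L, 2019L)
)

.five_year_eras <- tibble::tibble(
  era = c(
    "1986-1990", "1991-1995", "1996-2000", "2001-2005",
    "2006-2010", "2011-2015", "2016-2019"
  ),
  from = c(1986L, 1991L, 1996L, 2001L, 2006L, 2011L, 2016L),
  to = c(1990L, 1995L, 2000L, 2005L, 2010L, 2015L, 2019L)
)

#' Era summary of pre-approval patents per product
#'
#' Splits the cohort by calendar year of approval — thirds of the study
#' period (1986-1996, 1997-2007, 2008-2019) or 5-year increments — and
#' summarizes the number of pre-approval-filed patents listed per product,
#' in total and counting device patents only. Products with no listed
#' patents count as zero.
#'
#' @param cohort An `ob_cohort` (originator products are summarized).
#' @param patents Classified patent tibble from [link_and_classify()].
#' @param binning `"terciles"` or `"five_year"`.
#' @param type Quartile convention, passed to [median_iqr()].
#' @return Tibble: `era`, `n_products`, then median/q1/q3 for total and
#'   device-only pre-approval patent counts (`NA` for empty eras).
#' @export
era_summary <- function(cohort, patents, binning = c("terciles", "five_year"),
                        type = "interpolated") {
  binning <- match.arg(binning)
  eras <- if (binning == "terciles") .tercile_eras else .five_year_eras
  prods <- cohort$products[cohort$products$is_originator, , drop = FALSE]
  yr <- as.integer(format(prods$approval_date, "%Y"))
  if (nrow(prods) > 0L && (min(yr) < min(eras$from) || max(yr) > max(eras$to))) {
    rlang::abort("era_summary: approval year outside the study window")
  }
  pre <- patents[patents$filing_timing == "pre_approval_filed", , drop = FALSE]
  n_pre <- vapply(
    prods$product_id, function(pid) sum(pre$product_id == pid), integer(1)
  )
  n_dev <- vapply(prods$product_id, function(pid) {
    sum(pre$product_id == pid & pre$device_status != "non_device")
  }, integer(1))
  rows <- lapply(seq_len(nrow(eras)), function(i) {
    sel <- yr >= eras$from[i] & yr <= eras$to[i]
    if (!any(sel)) {
      return(tibble::tibble(
        era = eras$era[i], n_products = 0L,
        patents_median = NA_real_, patents_q1 = NA_real_, patents_q3 = NA_real_,
        device_median = NA_real_, device_q1 = NA_real_, device_q3 = NA_real_
      ))
    }
    mt <- median_iqr(n_pre[sel], type)
    md <- median_iqr(n_dev[sel], type)
    tibble::tibble(
      era = eras$era[i], n_products = sum(sel),
      patents_median = mt[["median"]], patents_q1 = mt[["q1"]],
      patents_q3 = mt[["q3"]],
      device_median = md[["median"]], device_q1 = md[["q1"]],
      device_q3 = md[["q3"]]
    )
  })
  dplyr::bind_rows(rows)
}

.summ <- function(x, type = "interpolated") {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  m <- median_iqr(x, type)
  list(
    n = length(x), median = unname(m[["median"]]),
    q1 = unname(m[["q1"]]), q3 = unname(m[["q3"]])
  )
}

#' Full study report
#'
#' Computes every descriptive result the analysis reports: cohort counts,
#' patent tallies by timing axis and device status, exclusivity tallies by
#' category and timing, duration summaries (overall, at approval,
#' post-approval extensions, device and no-mention added protection,
#' line-level spans), era trends, the per-class duration table, and the
#' follow-on sensitivity summaries. All percentages are whole numbers
#' recomputable from the stored counts; durations are stored unrounded.
#'
#' @param cohort An `ob_cohort`.
#' @param patents,exclusivities Classified tibbles from
#'   [link_and_classify()].
#' @param scope Scope for the overall duration metric.
#' @param type Quartile convention, passed to [median_iqr()].
#' @return An object of class `ob_report` (a nested list; see
#'   [export_report()]).
#' @export
cohort_report <- function(cohort, patents, exclusivities,
                          scope = protection_scope(), type = "interpolated") {
  stopifnot(inherits(cohort, "ob_cohort"))
  prods <- cohort$products
  oprod <- prods[prods$is_originator, , drop = FALSE]
  lines <- cohort$lines

  opat <- patents[patents$product_id %in% oprod$product_id, , drop = FALSE]
  oexc <- exclusivities[exclusivities$product_id %in% oprod$product_id, , drop = FALSE]

  counts <- list(
    products_total = nrow(prods),
    originator_products = nrow(oprod),
    originator_lines = sum(lines$is_originator),
    followon_products = sum(!prods$is_originator),
    followon_lines = sum(!lines$is_originator),
    drug_device_combinations = sum(oprod$is_drug_device),
    drug_device_pct = pct_of(sum(oprod$is_drug_device), nrow(oprod)),
    followon_drug_device = sum(!prods$is_originator & prods$is_drug_device),
    excluded_rows = nrow(cohort$exclusion_log)
  )

  pre <- opat[opat$filing_timing == "pre_approval_filed", , drop = FALSE]
  post <- opat[opat$filing_timing == "post_approval_filed", , drop = FALSE]
  post_listed <- opat[opat$listing_timing == "listed_post_approval", , drop = FALSE]
  patent_tallies <- list(
    pre_approval_filed = nrow(pre),
    pre_approval_filed_device = sum(pre$device_status != "non_device"),
    pre_approval_filed_device_pct = pct_of(
      sum(pre$device_status != "non_device"), nrow(pre)
    ),
    post_approval_filed = nrow(post),
    post_approval_listed = nrow(post_listed),
    post_approval_listed_device = sum(post_listed$device_status != "non_device"),
    post_approval_listed_device_pct = pct_of(
      sum(post_listed$device_status != "non_device"), nrow(post_listed)
    ),
    post_listed_priority_before = sum(
      post_listed$priority_timing == "priority_before_approval"
    ),
    post_listed_priority_after = sum(
      post_listed$priority_timing == "priority_after_approval"
    ),
    unique_device_patents = length(unique(
      opat$patent_no[opat$device_status != "non_device"]
    )),
    unique_device_no_mention = length(unique(
      opat$patent_no[opat$device_status == "device_no_mention"]
    )),
    per_product_pre_approval = .summ(vapply(
      oprod$product_id, function(pid) sum(pre$product_id == pid), integer(1)
    ), type),
    per_product_post_listed = .summ(vapply(
      oprod$product_id, function(pid) sum(post_listed$product_id == pid), integer(1)
    ), type)
  )

  at_exc <- oexc[oexc$timing == "at_approval", , drop = FALSE]
  post_exc <- oexc[oexc$timing == "post_approval" & oexc$category != "pediatric", ,
    drop = FALSE
  ]
  ped_exc <- oexc[oexc$category == "pediatric", , drop = FALSE]
  cat_table <- function(df) {
    if (nrow(df) == 0L) {
      return(list())
    }
    tab <- table(df$category)
    out <- lapply(seq_along(tab), function(i) {
      list(
        count = as.integer(tab[[i]]),
        pct = pct_of(as.integer(tab[[i]]), nrow(df))
      )
    })
    names(out) <- names(tab)
    out
  }
  exclusivity_tallies <- list(
    at_approval_total = nrow(at_exc),
    at_approval_by_category = cat_table(at_exc),
    post_approval_total = nrow(post_exc),
    post_approval_by_category = cat_table(post_exc),
    pediatric_total = nrow(ped_exc),
    per_product_post_approval = .summ(vapply(
      oprod$product_id,
      function(pid) {
        sum(post_exc$product_id == pid) + sum(ped_exc$product_id == pid)
      },
      integer(1)
    ), type)
  )

  ocohort <- cohort
  ocohort$products <- oprod
  ocohort$lines <- lines[lines$is_originator, , drop = FALSE]

  prot_all <- product_protection(ocohort, opat, oexc, scope)
  prot_at <- product_protection(
    ocohort, opat, oexc,
    protection_scope("at_approval_only", exclusivity_timing_filter = "at_approval_only")
  )
  ext <- post_approval_extension(ocohort, opat, oexc)
  dev_add <- device_added_protection(ocohort, opat)
  nm_add <- no_mention_added_protection(ocohort, opat)
  lprot <- line_protection(ocohort, opat, oexc, scope)

  dd_prot <- prot_all[prot_all$product_id %in%
    oprod$product_id[oprod$is_drug_device], , drop = FALSE]
  durations <- list(
    product_overall = .summ(prot_all$duration_years, type),
    product_at_approval = .summ(prot_at$duration_years, type),
    post_approval_extension = .summ(ext$extension_years, type),
    extended_products = sum(!is.na(ext$extension_years)),
    line_overall = .summ(lprot$duration_years, type),
    device_added = .summ(
      dev_add$added_years[!is.na(dev_add$added_years) & dev_add$added_years > 0], type
    ),
    no_mention_added = .summ(
      nm_add$added_years[!is.na(nm_add$added_years) & nm_add$added_years > 0], type
    ),
    last_item_device = sum(prot_all$last_item_kind == "patent_device"),
    last_item_device_pct = pct_of(
      sum(prot_all$last_item_kind == "patent_device"), nrow(prot_all)
    ),
    last_item_device_dd = sum(dd_prot$last_item_kind == "patent_device"),
    last_item_device_dd_pct = pct_of(
      sum(dd_prot$last_item_kind == "patent_device"), nrow(dd_prot)
    )
  )

  per_class <- lapply(split(prot_all$duration_years, oprod$insulin_class), .summ,
    type = type
  )

  sens <- sensitivity_analysis(cohort, patents, exclusivities, scope)
  orig_sens_prod <- sens$products[sens$products$product_id %in% oprod$product_id, ,
    drop = FALSE
  ]
  orig_sens_line <- sens$lines[sens$lines$line_id %in%
    lines$line_id[lines$is_originator], , drop = FALSE]
  sensitivity <- list(
    n_matches = nrow(sens$matches$matches),
    unmatched_followons = sens$matches$unmatched_followons,
    product_truncated = .summ(orig_sens_prod$truncated_years, type),
    line_truncated = .summ(orig_sens_line$truncated_years, type)
  )

  structure(
    list(
      counts = counts,
      patent_tallies = patent_tallies,
      exclusivity_tallies = exclusivity_tallies,
      durations = durations,
      per_class = per_class,
      era_terciles = era_summary(ocohort, opat, "terciles", type),
      era_five_year = era_summary(ocohort, opat, "five_year", type),
      sensitivity = sensitivity,
      scope = unclass(scope),
      quartile_type = type
    ),
    class = "ob_report"
  )
}

#' @export
print.ob_report <- function(x, ...) {
  cat("<ob_report>\n")
  cat(sprintf(
    "  cohort: %d originator products / %d lines; %d follow-on products / %d lines\n",
    x$counts$originator_products, x$counts$originator_lines,
    x$counts$followon_products, x$counts$followon_lines
  ))
  d <- x$durations$product_overall
  if (d$n > 0L) {
    cat(sprintf(
      "  median product protection %.1f y (IQR %.1f to %.1f, n=%d)\n",
      d$median, d$q1, d$q3, d$n
    ))
  }
  l <- x$durations$line_overall
  if (l$n > 0L) {
    cat(sprintf(
      "  median line protection %.1f y (IQR %.1f to %.1f, n=%d)\n",
      l$median, l$q1, l$q3, l$n
    ))
  }
  invisible(x)
}
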