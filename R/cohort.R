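#' Cohort configuration
#'
#' Inclusion and exclusion rules for the biosynthetic-insulin cohort. The
#' study window defaults to approvals from 1986 (the first year with
#' consecutive Orange Book editions listing patent information) through 2019
#' (insulins moved to biologics regulation, and out of the Orange Book, in
#' March 2020). Animal-derived products are excluded by ingredient keyword;
#' the three biosynthetic insulins approved before 1986 (Humulin R, Humulin
#' L, Humulin N) are excluded by explicit trade name.
#'
#' @param window_start,window_end First and last admissible approval dates
#'   (inclusive; the window test uses the approval date only).
#' @param excluded_ingredients Ingredient keywords (case-insensitive
#'   substring match) marking animal-derived products.
#' @param excluded_products Trade names excluded outright (exact,
#'   case-insensitive).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(window_start = as.Date("1986-01-01"),
                          window_end = as.Date("2019-12-31"),
                          excluded_ingredients = c("BEEF", "PORK", "BOVINE", "PORCINE"),
                          excluded_products = c("HUMULIN R", "HUMULIN L", "HUMULIN N")) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  stopifnot(window_start < window_end)
  structure(
    list(
      window_start = window_start,
      window_end = window_end,
      excluded_ingredients = toupper(excluded_ingredients),
      excluded_products = toupper(excluded_products)
    ),
    class = "cohort_config"
  )
}

.insulin_classes <- c(
  "rapid", "short", "intermediate", "long",
  "mixture_long_incretin", "mixture_intermediate_rapid",
  "mixture_intermediate_short"
)

.presentations <- c(
  "vial", "single_use_device", "reusable_device", "inhaled_device",
  "infusion_bag", "other"
)

.device_presentations <- c("single_use_device", "reusable_device", "inhaled_device")

#' Validate an onset-of-action class label
#'
#' Products are categorized by onset of action: rapid-, short-,
#' intermediate- and long-acting insulins, plus three mixture classes
#' (long-acting insulin with an incretin mimetic, intermediate with rapid,
#' intermediate with short).
#'
#' @param label Character vector of class labels.
#' @return The validated label vector.
#' @export
assign_class <- function(label) {
  bad <- setdiff(unique(label), .insulin_classes)
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "unknown insulin class label(s): %s (expected one of %s)",
      paste(bad, collapse = ", "), paste(.insulin_classes, collapse = ", ")
    ))
  }
  label
}

# Normalized ingredient-set key: case-folded, trimmed, sorted, "|"-joined.
.ingredients_key <- function(ingredients) {
  vapply(ingredients, function(v) {
    paste(sort(unique(toupper(trimws(v)))), collapse = "|")
  }, character(1))
}

#' Build the study cohort
#'
#' Applies the inclusion/exclusion rules to raw product rows, attaches the
#' product-level curation metadata (class, presentation, originator versus
#' follow-on status, brand family, manufacturer), and groups products into
#' insulin lines. Every input row ends up either in the cohort or in the
#' exclusion log with a reason, so the build is a partition of its input.
#'
#' @param products Raw product rows from [read_products()].
#' @param config A [cohort_config()].
#' @param metadata Curation table with columns `appl_no`, `product_no`,
#'   `brand_family`, `insulin_class`, `presentation`,
#'   `originator_or_followon`, `manufacturer` (see
#'   [read_product_metadata()]).
#' @return An object of class `ob_cohort`: a list with `products` (fully
#'   typed product tibble), `lines` (from [group_lines()]), `exclusion_log`
#'   (tibble of `appl_no`, `product_no`, `trade_name`, `reason`) and
#'   `config`.
#' @export
build_cohort <- function(products, config = cohort_config(), metadata) {
  stopifnot(inherits(config, "cohort_config"))
  need <- c(
    "appl_no", "product_no", "brand_family", "insulin_class",
    "presentation", "originator_or_followon", "manufacturer"
  )
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("metadata missing column(s): %s", paste(miss, collapse = ", ")))
  }
  assign_class(metadata$insulin_class)
  badp <- setdiff(unique(metadata$presentation), .presentations)
  if (length(badp) > 0L) {
    rlang::abort(sprintf("unknown presentation(s): %s", paste(badp, collapse = ", ")))
  }

  df <- products
  df$product_id <- paste(df$appl_no, df$product_no, sep = "/")

  reason <- rep(NA_character_, nrow(df))
  upper_trade <- toupper(trimws(df$trade_name))
  animal <- vapply(df$active_ingredients, function(v) {
    any(vapply(
      config$excluded_ingredients,
      function(k) any(grepl(k, toupper(v), fixed = TRUE)), logical(1)
    ))
  }, logical(1))
  reason[animal] <- "animal-derived"
  listed <- is.na(reason) & upper_trade %in% config$excluded_products
  reason[listed] <- "excluded product (pre-1986 biosynthetic)"
  outside <- is.na(reason) &
    (df$approval_date < config$window_start | df$approval_date >= config$window_end + 1L)
  reason[outside] <- "outside window"

  exclusion_log <- tibble::tibble(
    appl_no = df$appl_no[!is.na(reason)],
    product_no = df$product_no[!is.na(reason)],
    trade_name = df$trade_name[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  kept <- df[is.na(reason), , drop = FALSE]

  md <- metadata
  md$product_id <- paste(md$appl_no, md$product_no, sep = "/")
  orphan <- setdiff(kept$product_id, md$product_id)
  if (length(orphan) > 0L) {
    rlang::abort(sprintf(
      "product(s) lacking curation metadata: %s", paste(orphan, collapse = ", ")
    ))
  }
  md <- md[match(kept$product_id, md$product_id), , drop = FALSE]

  out <- tibble::tibble(
    product_id = kept$product_id,
    appl_no = kept$appl_no,
    product_no = kept$product_no,
    trade_name = kept$trade_name,
    brand_family = md$brand_family,
    active_ingredients = kept$active_ingredients,
    ingredients_key = .ingredients_key(kept$active_ingredients),
    approval_date = kept$approval_date,
    manufacturer = md$manufacturer,
    insulin_class = md$insulin_class,
    presentation = md$presentation,
    is_drug_device = md$presentation %in% .device_presentations,
    is_originator = md$originator_or_followon == "originator"
  )
  out <- out[order(out$product_id), , drop = FALSE]

  cohort <- structure(
    list(
      products = out,
      lines = NULL,
      exclusion_log = exclusion_log[order(
        exclusion_log$appl_no, exclusion_log$product_no
      ), , drop = FALSE],
      config = config
    ),
    class = "ob_cohort"
  )
  cohort$lines <- group_lines(cohort)
  cohort
}

#' Read a product-curation metadata table
#'
#' @param path CSV with columns `appl_no`, `product_no`, `brand_family`,
#'   `insulin_class`, `presentation`, `originator_or_followon`,
#'   `manufacturer`.
#' @return A tibble.
#' @export
read_product_metadata <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("metadata file not found: %s", path))
  }
  tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  )
}

#' Group cohort products into insulin lines
#'
#' An insulin line groups products that share a brand family, the same
#' active-ingredient set, and the same manufacturer. The grouping key is the
#' brand family rather than the NDA number alone, so that a brand marketed
#' under two NDAs (Humalog) still forms a single line, as in the published
#' line-level analysis.
#'
#' @param cohort An `ob_cohort` (or its `products` tibble).
#' @return A tibble with one row per line: `line_id`, `brand_family`,
#'   `ingredients_key`, `manufacturer`, `is_originator`, `n_products`,
#'   `product_ids` (list-column), `first_approval`.
#' @export
group_lines <- function(cohort) {
  prods <- if (inherits(cohort, "ob_cohort")) cohort$products else cohort
  if (nrow(prods) == 0L) {
    return(tibble::tibble(
      line_id = character(), brand_family = character(),
      ingredients_key = character(), manufacturer = character(),
      is_originator = logical(), n_products = integer(),
      product_ids = list(), first_approval = as.Date(character())
    ))
  }
  conflict <- prods |>
    dplyr::distinct(.data$brand_family, .data$ingredients_key, .data$manufacturer) |>
    dplyr::count(.data$brand_family, .data$ingredients_key) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflict) > 0L) {
    rlang::abort(sprintf(
      "conflicting manufacturers within brand family: %s",
      paste(conflict$brand_family, collapse = ", ")
    ))
  }
  prods |>
    dplyr::group_by(.data$brand_family, .data$ingredients_key, .data$manufacturer) |>
    dplyr::summarise(
      is_originator = unique(.data$is_originator)[1L],
      n_products = dplyr::n(),
      product_ids = list(sort(.data$product_id)),
      first_approval = min(.data$approval_date),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      line_id = paste(.data$brand_family, .data$manufacturer, sep = " :: ")
    ) |>
    dplyr::arrange(.data$line_id) |>
    dplyr::select(
      "line_id", "brand_family", "ingredients_key", "manufacturer",
      "is_originator", "n_products", "product_ids", "first_approval"
    )
}

#' @export
print.ob_cohort <- function(x, ...) {
  p <- x$products
  cat("<ob_cohort>\n")
  cat(sprintf(
    "  %d products (%d originator, %d follow-on) across %d lines\n",
    nrow(p), sum(p$is_originator), sum(!p$is_originator), nrow(x$lines)
  ))
  cat(sprintf(
    "  %d drug-device combinations; %d rows excluded\n",
    sum(p$is_drug_device), nrow(x$exclusion_log)
  ))
  cat(sprintf(
    "  window %s .. %s\n",
    format(x$config$window_start), format(x$config$window_end)
  ))
  invisible(x)
}
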