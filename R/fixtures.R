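#' Packaged cohort tables for biosynthetic insulins, 1986-2019
#'
#' Transcriptions of the published cohort tables for biosynthetic originator
#' insulins (25 brand lines, 56 products, 33 drug-device combinations) and
#' 505(b)(2) follow-on insulins (3 lines, 5 products) approved by the FDA
#' from 1986 through 2019. Each row is one brand line with its active
#' ingredients, onset-of-action class, first approval date, product count,
#' and drug-device combination count. Manufacturers are assigned from the
#' published per-manufacturer line tallies (Novo Nordisk 12, Eli Lilly 7,
#' Sanofi 4, Pfizer 1, MannKind 1).
#'
#' @return A list with tibbles `originators` and `followons`.
#' @examples
#' tabs <- insulin_tables()
#' sum(tabs$originators$n_products) # 56
#' @export
insulin_tables <- function() {
  read_one <- function(f) {
    df <- utils::read.csv(
      system.file("extdata", f, package = "obprotect", mustWork = TRUE),
      stringsAsFactors = FALSE
    )
    df$first_approval <- as.Date(df$first_approval)
    tibble::as_tibble(df)
  }
  list(
    originators = read_one("table1_originator_insulins.csv"),
    followons = read_one("table2_followon_insulins.csv")
  )
}

#' Expand the packaged tables into cohort-pipeline inputs
#'
#' The packaged tables record one row per brand line with a product count;
#' the cohort builder works on one row per product. This helper expands each
#' line into its products (the first `n_device_combinations` of them flagged
#' as drug-device presentations), assigns synthetic NDA numbers, and emits
#' the product-curation metadata the cohort builder requires. Humalog is
#' expanded across two NDAs (3 products + 1 product), matching its published
#' footnote. Only first-approval dates are published at line level, so every
#' product of a line carries the line's first approval date; counts, line
#' structure and follow-on matching are unaffected.
#'
#' @param tables Output of [insulin_tables()].
#' @return A list with `products` (raw product rows as from
#'   [read_products()]) and `metadata` (curation table for
#'   [build_cohort()]).
#' @export
expand_insulin_tables <- function(tables = insulin_tables()) {
  expand_one <- function(df, role, tag) {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      n <- df$n_products[i]
      ndev <- df$n_device_combinations[i]
      appl <- sprintf("NDA-%s-%02d", tag, i)
      appl_no <- rep(appl, n)
      if (df$brand[i] == "Humalog" && n == 4L) {
        # two NDAs: 3 products under one, 1 under another
        appl_no <- c(rep(appl, 3L), paste0(appl, "B"))
      }
      tibble::tibble(
        appl_no = appl_no,
        product_no = sprintf("%03d", seq_len(n)),
        trade_name = df$brand[i],
        ingredients = df$ingredients[i],
        insulin_class = df$insulin_class[i],
        approval_date = df$first_approval[i],
        manufacturer = df$manufacturer[i],
        presentation = c(
          rep("single_use_device", ndev),
          rep("vial", n - ndev)
        ),
        role = role
      )
    })
    dplyr::bind_rows(rows)
  }
  flat <- dplyr::bind_rows(
    expand_one(tables$originators, "originator", "T1"),
    expand_one(tables$followons, "followon", "T2")
  )
  products <- tibble::tibble(
    appl_no = flat$appl_no,
    product_no = flat$product_no,
    trade_name = flat$trade_name,
    active_ingredients = strsplit(flat$ingredients, "/", fixed = TRUE),
    dosage_form_route = "INJECTABLE;SUBCUTANEOUS",
    approval_date = flat$approval_date,
    applicant = flat$manufacturer
  )
  metadata <- tibble::tibble(
    appl_no = flat$appl_no,
    product_no = flat$product_no,
    brand_family = flat$trade_name,
    insulin_class = flat$insulin_class,
    presentation = flat$presentation,
    originator_or_followon = flat$role,
    manufacturer = flat$manufacturer
  )
  list(products = products, metadata = metadata)
}

#' Exclusivity code-to-category mapping
#'
#' The default mapping from Orange Book exclusivity code prefixes to
#' analysis categories, shipped as editable package data. `term_years` is
#' the statutory term associated with the category, used to infer whether an
#' exclusivity was granted at approval or later from its listed expiry date.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `code_prefix`, `category`, `term_years`.
#' @return A tibble with those three columns.
#' @export
exclusivity_code_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "exclusivity_code_map.csv",
      package = "obprotect", mustWork = TRUE
    )
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
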