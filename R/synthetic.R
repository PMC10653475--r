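#' Synthetic cohort configuration
#'
#' Parameters for generating Orange Book-shaped cohorts with known ground
#' truth. Defaults emulate the study conditions for biosynthetic insulins:
#' 25 brand lines with 1-5 products each approved 1986-2019, a 20-year
#' patent term running from the priority date, device fractions and
#' patents-per-product rates that rise over the three eras of the window
#' (matching the observed trend from a median of 0 pre-approval patents in
#' the first era to double digits in the last), a high no-mention fraction
#' among device patents, 5-year new-chemical-entity and 3-year
#' new-product/new-indication exclusivity terms, and sparse follow-on entry.
#' Patent counts are Poisson; filing offsets relative to approval are
#' discretized normal in days, with most mass pre-approval.
#'
#' @param n_lines Number of originator lines.
#' @param products_per_line Integer `c(min, max)` products per line.
#' @param approval_years Integer `c(first, last)` calendar years of
#'   approval.
#' @param device_fraction Probability a product is a drug-device
#'   combination, per third of the approval window.
#' @param patents_per_product Poisson mean patent count per product, per
#'   third of the window (non-decreasing gives the era trend).
#' @param patent_term_years Patent term from the priority date (default 20).
#' @param filing_offset_mean,filing_offset_sd Normal filing-offset
#'   distribution in days relative to product approval (negative mean puts
#'   most filings pre-approval).
#' @param post_listing_prob Probability that a pre-approval-filed patent is
#'   first listed in the Orange Book only after approval.
#' @param priority_gap_days Integer `c(min, max)` days by which the priority
#'   date (earliest family filing) precedes the USPTO application date.
#' @param device_patent_prob Probability a patent on a drug-device product
#'   is a device patent.
#' @param no_mention_prob Probability a device patent makes no mention of
#'   the active ingredient in its claims.
#' @param exclusivity_at_approval_prob Probability the first product of a
#'   line carries an exclusivity granted at approval.
#' @param nce_prob Probability an at-approval exclusivity is a 5-year
#'   new-chemical-entity grant (otherwise a 3-year new-product grant).
#' @param post_exclusivity_rate Poisson mean count of post-approval
#'   (new indication/dosing) exclusivities per product.
#' @param followon_prob Probability an originator line draws a follow-on
#'   competitor.
#' @param followon_delay_years Normal `c(mean, sd)` delay in years from
#'   first originator approval to follow-on approval.
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_lines = 25L,
                             products_per_line = c(1L, 5L),
                             approval_years = c(1986L, 2019L),
                             device_fraction = c(0.15, 0.45, 0.75),
                             patents_per_product = c(0.5, 4, 15),
                             patent_term_years = 20,
                             filing_offset_mean = -1500,
                             filing_offset_sd = 1500,
                             post_listing_prob = 0.1,
                             priority_gap_days = c(0L, 1095L),
                             device_patent_prob = 0.6,
                             no_mention_prob = 0.8,
                             exclusivity_at_approval_prob = 0.5,
                             nce_prob = 0.4,
                             post_exclusivity_rate = 0.5,
                             followon_prob = 0.12,
                             followon_delay_years = c(15, 3),
                             seed = 1L) {
  cfg <- list(
    n_lines = as.integer(n_lines),
    products_per_line = as.integer(products_per_line),
    approval_years = as.integer(approval_years),
    device_fraction = device_fraction,
    patents_per_product = patents_per_product,
    patent_term_years = patent_term_years,
    filing_offset_mean = filing_offset_mean,
    filing_offset_sd = filing_offset_sd,
    post_listing_prob = post_listing_prob,
    priority_gap_days = as.integer(priority_gap_days),
    device_patent_prob = device_patent_prob,
    no_mention_prob = no_mention_prob,
    exclusivity_at_approval_prob = exclusivity_at_approval_prob,
    nce_prob = nce_prob,
    post_exclusivity_rate = post_exclusivity_rate,
    followon_prob = followon_prob,
    followon_delay_years = followon_delay_years,
    seed = as.integer(seed)
  )
  if (cfg$n_lines < 0L) rlang::abort("n_lines must be >= 0")
  if (length(cfg$products_per_line) != 2L ||
    cfg$products_per_line[1L] < 1L ||
    cfg$products_per_line[2L] < cfg$products_per_line[1L]) {
    rlang::abort("products_per_line must be c(min, max) with 1 <= min <= max")
  }
  if (cfg$approval_years[2L] < cfg$approval_years[1L]) {
    rlang::abort("approval_years must be increasing")
  }
  probs <- c(
    cfg$device_fraction, cfg$post_listing_prob, cfg$device_patent_prob,
    cfg$no_mention_prob, cfg$exclusivity_at_approval_prob, cfg$nce_prob,
    cfg$followon_prob
  )
  if (any(probs < 0 | probs > 1)) rlang::abort("probabilities must be in [0, 1]")
  if (any(cfg$patents_per_product < 0) || cfg$post_exclusivity_rate < 0) {
    rlang::abort("rates must be >= 0")
  }
  if (cfg$patent_term_years <= 0) rlang::abort("patent_term_years must be > 0")
  if (length(cfg$priority_gap_days) != 2L || cfg$priority_gap_days[1L] < 0L ||
    cfg$priority_gap_days[2L] < cfg$priority_gap_days[1L]) {
    rlang::abort("priority_gap_days must be c(min, max) with 0 <= min <= max")
  }
  structure(cfg, class = "synthetic_config")
}

# Third of the approval window a calendar year falls in (1-3).
.era_of <- function(year, approval_years) {
  span <- approval_years[2L] - approval_years[1L] + 1L
  idx <- floor((year - approval_years[1L]) / (span / 3)) + 1L
  pmin(pmax(idx, 1L), 3L)
}

# sample() treats a scalar first argument as 1:n; this does not
.resample <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

.rand_date_in_year <- function(year) {
  start <- as.integer(as.Date(sprintf("%d-01-01", year)))
  as.Date(start + sample.int(365L, 1L) - 1L, origin = "1970-01-01")
}

#' Generate a synthetic Orange Book-shaped cohort
#'
#' Writes `products.txt`, `patent.txt`, `exclusivity.txt` (canonical
#' tilde-delimited dialect), `annotations.csv` and `metadata.csv` into
#' `dir`, and returns the recorded ground truth. The truth is computed
#' during generation by direct integer day arithmetic on the drawn dates —
#' a code path fully independent of the protection module — so it can
#' serve as an end-to-end oracle for the pipeline.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (tibbles `products`, `lines`, `device_added`, `followons`), and
#'   `config`.
#' @export
generate_synthetic <- function(config = synthetic_config(), dir = tempfile("syncohort")) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)

  term_days <- round(config$patent_term_years * 365.25)
  window_end_int <- as.integer(as.Date(sprintf("%d-12-31", config$approval_years[2L])))

  prod_rows <- list()
  pat_rows <- list()
  exc_rows <- list()
  ann_rows <- list()
  md_rows <- list()
  truth_prod <- list()
  truth_line <- list()
  truth_dev <- list()
  truth_fol <- list()
  patent_counter <- 0L

  for (i in seq_len(config$n_lines)) {
    appl <- sprintf("NDA9%05d", i)
    brand <- sprintf("SYNBRAND-%03d", i)
    ingredient <- sprintf("INSULIN SYN-%03d", i)
    mfr <- sprintf("MFR-%02d", (i - 1L) %% 6L + 1L)
    n_prod <- .resample(seq(config$products_per_line[1L], config$products_per_line[2L]))
    year1 <- .resample(seq(config$approval_years[1L], config$approval_years[2L]))
    approval0 <- .rand_date_in_year(year1)
    approvals <- as.integer(approval0)
    if (n_prod > 1L) {
      gaps <- sample(180L:2920L, n_prod - 1L, replace = TRUE)
      approvals <- c(approvals, as.integer(approval0) + cumsum(gaps))
      approvals <- pmin(approvals, window_end_int)
    }

    line_expiries <- integer(0)
    for (p in seq_len(n_prod)) {
      pid_no <- sprintf("%03d", p)
      appr_int <- approvals[p]
      appr <- as.Date(appr_int, origin = "1970-01-01")
      era <- .era_of(as.integer(format(appr, "%Y")), config$approval_years)
      is_dev <- stats::runif(1L) < config$device_fraction[era]

      prod_rows[[length(prod_rows) + 1L]] <- tibble::tibble(
        appl_no = appl, product_no = pid_no,
        trade_name = if (is_dev) paste(brand, "PEN") else brand,
        active_ingredients = list(ingredient),
        dosage_form_route = "INJECTABLE;SUBCUTANEOUS",
        approval_date = appr, applicant = mfr
      )
      md_rows[[length(md_rows) + 1L]] <- tibble::tibble(
        appl_no = appl, product_no = pid_no, brand_family = brand,
        insulin_class = c(
          "rapid", "short", "intermediate", "long",
          "mixture_intermediate_rapid"
        )[(i - 1L) %% 5L + 1L],
        presentation = if (is_dev) "single_use_device" else "vial",
        originator_or_followon = "originator", manufacturer = mfr
      )

      expiries <- integer(0)
      dev_expiries <- integer(0)
      nondev_expiries <- integer(0)
      n_pat <- stats::rpois(1L, config$patents_per_product[era])
      for (k in seq_len(n_pat)) {
        patent_counter <- patent_counter + 1L
        application <- appr_int +
          as.integer(round(stats::rnorm(1L, config$filing_offset_mean, config$filing_offset_sd)))
        priority <- application -
          .resample(seq(config$priority_gap_days[1L], config$priority_gap_days[2L]))
        expiry <- priority + term_days
        pat_is_dev <- is_dev && stats::runif(1L) < config$device_patent_prob
        mentions <- pat_is_dev && stats::runif(1L) >= config$no_mention_prob
        listing <- if (application < appr_int) {
          if (stats::runif(1L) < config$post_listing_prob) {
            appr_int + sample(30L:1825L, 1L)
          } else {
            appr_int
          }
        } else {
          application + 30L
        }
        patent_no <- sprintf("USSYN%06d", patent_counter)
        pat_rows[[length(pat_rows) + 1L]] <- tibble::tibble(
          appl_no = appl, product_no = pid_no, patent_no = patent_no,
          patent_expire_date = as.Date(expiry, origin = "1970-01-01"),
          submission_date = as.Date(listing, origin = "1970-01-01"),
          drug_substance_flag = if (pat_is_dev) "" else "Y",
          drug_product_flag = "Y",
          use_code = ""
        )
        ann_rows[[length(ann_rows) + 1L]] <- tibble::tibble(
          patent_no = patent_no,
          application_date = as.Date(application, origin = "1970-01-01"),
          priority_date = as.Date(priority, origin = "1970-01-01"),
          is_device = pat_is_dev, mentions_active = mentions,
          title = if (pat_is_dev) "Medicament delivery device" else "Insulin formulation"
        )
        expiries <- c(expiries, expiry)
        if (pat_is_dev) {
          dev_expiries <- c(dev_expiries, expiry)
        } else {
          nondev_expiries <- c(nondev_expiries, expiry)
        }
      }

      if (p == 1L && stats::runif(1L) < config$exclusivity_at_approval_prob) {
        nce <- stats::runif(1L) < config$nce_prob
        etd <- if (nce) round(5 * 365.25) else round(3 * 365.25)
        exc_rows[[length(exc_rows) + 1L]] <- tibble::tibble(
          appl_no = appl, product_no = pid_no,
          exclusivity_code = if (nce) "NCE" else "NP",
          exclusivity_date = as.Date(appr_int + etd, origin = "1970-01-01")
        )
        expiries <- c(expiries, appr_int + etd)
      }
      n_post_exc <- stats::rpois(1L, config$post_exclusivity_rate)
      for (k in seq_len(n_post_exc)) {
        grant <- appr_int + sample(365L:2920L, 1L)
        etd <- round(3 * 365.25)
        exc_rows[[length(exc_rows) + 1L]] <- tibble::tibble(
          appl_no = appl, product_no = pid_no,
          exclusivity_code = sprintf("I-%d", k),
          exclusivity_date = as.Date(grant + etd, origin = "1970-01-01")
        )
        expiries <- c(expiries, grant + etd)
      }

      # ground truth by direct integer arithmetic
      last <- if (length(expiries) == 0L) NA_integer_ else {
        m <- expiries[1L]
        for (e in expiries) if (e > m) m <- e
        m
      }
      truth_prod[[length(truth_prod) + 1L]] <- tibble::tibble(
        product_id = paste(appl, pid_no, sep = "/"),
        line_id = paste(brand, mfr, sep = " :: "),
        approval_date = appr,
        last_expiry = as.Date(last, origin = "1970-01-01"),
        duration_years = if (is.na(last)) NA_real_ else (last - appr_int) / 365.25
      )
      if (is_dev) {
        dmax <- if (length(dev_expiries) == 0L) NA_integer_ else max(dev_expiries)
        nmax <- if (length(nondev_expiries) == 0L) NA_integer_ else max(nondev_expiries)
        truth_dev[[length(truth_dev) + 1L]] <- tibble::tibble(
          product_id = paste(appl, pid_no, sep = "/"),
          added_years = if (is.na(dmax) || is.na(nmax)) {
            NA_real_
          } else {
            (dmax - nmax) / 365.25
          }
        )
      }
      line_expiries <- c(line_expiries, expiries)
    }

    line_last <- if (length(line_expiries) == 0L) NA_integer_ else max(line_expiries)
    truth_line[[length(truth_line) + 1L]] <- tibble::tibble(
      line_id = paste(brand, mfr, sep = " :: "),
      first_approval = as.Date(approvals[1L], origin = "1970-01-01"),
      last_expiry = as.Date(line_last, origin = "1970-01-01"),
      duration_years = if (is.na(line_last)) {
        NA_real_
      } else {
        (line_last - approvals[1L]) / 365.25
      }
    )

    if (stats::runif(1L) < config$followon_prob) {
      delay <- round(stats::rnorm(
        1L, config$followon_delay_years[1L] * 365.25,
        config$followon_delay_years[2L] * 365.25
      ))
      fol_appr <- min(max(approvals[1L] + as.integer(delay), approvals[1L]), window_end_int)
      fol_appl <- sprintf("NDA8%05d", i)
      fol_brand <- sprintf("SYNFOLLOW-%03d", i)
      fol_mfr <- sprintf("MFR-FO-%02d", (i - 1L) %% 4L + 1L)
      prod_rows[[length(prod_rows) + 1L]] <- tibble::tibble(
        appl_no = fol_appl, product_no = "001", trade_name = fol_brand,
        active_ingredients = list(ingredient),
        dosage_form_route = "INJECTABLE;SUBCUTANEOUS",
        approval_date = as.Date(fol_appr, origin = "1970-01-01"),
        applicant = fol_mfr
      )
      md_rows[[length(md_rows) + 1L]] <- tibble::tibble(
        appl_no = fol_appl, product_no = "001", brand_family = fol_brand,
        insulin_class = "rapid", presentation = "vial",
        originator_or_followon = "followon", manufacturer = fol_mfr
      )
      truth_fol[[length(truth_fol) + 1L]] <- tibble::tibble(
        originator_line_id = paste(brand, mfr, sep = " :: "),
        followon_line_id = paste(fol_brand, fol_mfr, sep = " :: "),
        followon_approval = as.Date(fol_appr, origin = "1970-01-01")
      )
    }
  }

  empty_pat <- tibble::tibble(
    appl_no = character(), product_no = character(), patent_no = character(),
    patent_expire_date = as.Date(character()), submission_date = as.Date(character()),
    drug_substance_flag = character(), drug_product_flag = character(),
    use_code = character()
  )
  empty_exc <- tibble::tibble(
    appl_no = character(), product_no = character(),
    exclusivity_code = character(), exclusivity_date = as.Date(character())
  )
  empty_ann <- tibble::tibble(
    patent_no = character(), application_date = as.Date(character()),
    priority_date = as.Date(character()), is_device = logical(),
    mentions_active = logical(), title = character()
  )
  empty_prod <- tibble::tibble(
    appl_no = character(), product_no = character(), trade_name = character(),
    active_ingredients = list(), dosage_form_route = character(),
    approval_date = as.Date(character()), applicant = character()
  )

  products <- if (length(prod_rows)) dplyr::bind_rows(prod_rows) else empty_prod
  patents <- if (length(pat_rows)) dplyr::bind_rows(pat_rows) else empty_pat
  exclusivities <- if (length(exc_rows)) dplyr::bind_rows(exc_rows) else empty_exc
  annotations <- if (length(ann_rows)) dplyr::bind_rows(ann_rows) else empty_ann
  metadata <- dplyr::bind_rows(md_rows)

  paths <- list(
    products = file.path(dir, "products.txt"),
    patents = file.path(dir, "patent.txt"),
    exclusivities = file.path(dir, "exclusivity.txt"),
    annotations = file.path(dir, "annotations.csv"),
    metadata = file.path(dir, "metadata.csv")
  )
  write_products(products, paths$products)
  write_patents(patents, paths$patents)
  write_exclusivities(exclusivities, paths$exclusivities)
  write_annotations(annotations, paths$annotations)
  utils::write.csv(
    if (nrow(metadata)) {
      metadata
    } else {
      data.frame(
        appl_no = character(), product_no = character(),
        brand_family = character(), insulin_class = character(),
        presentation = character(), originator_or_followon = character(),
        manufacturer = character()
      )
    },
    paths$metadata,
    row.names = FALSE, quote = FALSE
  )

  truth <- list(
    products = if (length(truth_prod)) {
      dplyr::bind_rows(truth_prod)
    } else {
      tibble::tibble(
        product_id = character(), line_id = character(),
        approval_date = as.Date(character()), last_expiry = as.Date(character()),
        duration_years = numeric()
      )
    },
    lines = if (length(truth_line)) {
      dplyr::bind_rows(truth_line)
    } else {
      tibble::tibble(
        line_id = character(), first_approval = as.Date(character()),
        last_expiry = as.Date(character()), duration_years = numeric()
      )
    },
    device_added = if (length(truth_dev)) {
      dplyr::bind_rows(truth_dev)
    } else {
      tibble::tibble(product_id = character(), added_years = numeric())
    },
    followons = if (length(truth_fol)) {
      dplyr::bind_rows(truth_fol)
    } else {
      tibble::tibble(
        originator_line_id = character(), followon_line_id = character(),
        followon_approval = as.Date(character())
      )
    }
  )
  invisible(list(paths = paths, truth = truth, config = config))
}

#' Run the pipeline on generated files and compare against ground truth
#'
#' Reads the generated files back through the ingestion layer, builds the
#' cohort, classifies the listings, computes protection under the full
#' scope, and compares per-product last-expiry dates, per-line spans and
#' cohort counts with the generator's independently computed truth. Date
#' algebra is deterministic, so the expected discrepancy is exactly zero
#' days.
#'
#' @param generated Result of [generate_synthetic()].
#' @param config Cohort configuration; defaults to a window covering the
#'   generated approval years.
#' @return A list with `pass` (logical), `max_day_diff_products`,
#'   `max_day_diff_lines`, `count_delta`, and a per-product `deltas`
#'   tibble.
#' @export
parameter_recovery_check <- function(generated, config = NULL) {
  cfg <- generated$config
  if (is.null(config)) {
    config <- cohort_config(
      window_start = as.Date(sprintf("%d-01-01", cfg$approval_years[1L])),
      window_end = as.Date(sprintf("%d-12-31", cfg$approval_years[2L]))
    )
  }
  products <- read_products(generated$paths$products)
  patents_raw <- read_patents(generated$paths$patents)
  exclusivities_raw <- read_exclusivities(generated$paths$exclusivities)
  annotations <- read_annotations(generated$paths$annotations)
  metadata <- read_product_metadata(generated$paths$metadata)

  cohort <- build_cohort(products, config, metadata)
  cls <- link_and_classify(patents_raw, exclusivities_raw, annotations, cohort)
  prot <- suppressWarnings(
    product_protection(cohort, cls$patents, cls$exclusivities, protection_scope("all"))
  )

  truth <- generated$truth$products
  merged <- dplyr::inner_join(
    prot[, c("product_id", "last_expiry", "duration_years")],
    truth[, c("product_id", "last_expiry", "duration_years")],
    by = "product_id", suffix = c("_pipeline", "_truth")
  )
  day_diff <- abs(as.numeric(merged$last_expiry_pipeline) -
    as.numeric(merged$last_expiry_truth))
  day_diff[is.na(merged$last_expiry_pipeline) & is.na(merged$last_expiry_truth)] <- 0
  max_day <- if (nrow(merged) == 0L) 0 else max(day_diff, na.rm = FALSE)

  lprot <- suppressWarnings(
    line_protection(cohort, cls$patents, cls$exclusivities, protection_scope("all"))
  )
  lmerged <- dplyr::inner_join(
    lprot[, c("line_id", "last_expiry")],
    generated$truth$lines[, c("line_id", "last_expiry")],
    by = "line_id", suffix = c("_pipeline", "_truth")
  )
  lday <- abs(as.numeric(lmerged$last_expiry_pipeline) -
    as.numeric(lmerged$last_expiry_truth))
  lday[is.na(lmerged$last_expiry_pipeline) & is.na(lmerged$last_expiry_truth)] <- 0
  max_lday <- if (nrow(lmerged) == 0L) 0 else max(lday, na.rm = FALSE)

  count_delta <- nrow(cohort$products) - nrow(truth) -
    nrow(generated$truth$followons)

  list(
    pass = isTRUE(max_day == 0) && isTRUE(max_lday == 0) &&
      count_delta == 0L && nrow(merged) == nrow(truth),
    max_day_diff_products = max_day,
    max_day_diff_lines = max_lday,
    count_delta = count_delta,
    deltas = tibble::tibble(
      product_id = merged$product_id, day_diff = day_diff,
      duration_diff = merged$duration_years_pipeline - merged$duration_years_truth
    )
  )
}
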