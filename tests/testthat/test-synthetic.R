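test_that("invalid generator configs fail before writing anything", {
  expect_error(synthetic_config(n_lines = -1), "n_lines")
  expect_error(synthetic_config(products_per_line = c(3L, 1L)), "products_per_line")
  expect_error(synthetic_config(device_fraction = c(0.1, 0.5, 1.7)), "probabilities")
  expect_error(synthetic_config(patent_term_years = 0), "patent_term_years")
  expect_error(synthetic_config(patents_per_product = c(-1, 2, 3)), "rates")
})

test_that("an empty cohort generates valid empty files", {
  gen <- generate_synthetic(synthetic_config(n_lines = 0L), dir = tempfile())
  expect_equal(nrow(read_products(gen$paths$products)), 0L)
  expect_equal(nrow(read_patents(gen$paths$patents)), 0L)
  expect_equal(nrow(read_exclusivities(gen$paths$exclusivities)), 0L)
  expect_equal(nrow(gen$truth$products), 0L)
})

test_that("patents filed on approval day with a 20-year term give ~20-year durations", {
  gen <- generate_synthetic(
    synthetic_config(
      n_lines = 5L, products_per_line = c(1L, 1L),
      patents_per_product = c(3, 3, 3),
      filing_offset_mean = 0, filing_offset_sd = 0,
      priority_gap_days = c(0L, 0L), post_listing_prob = 0,
      exclusivity_at_approval_prob = 0, post_exclusivity_rate = 0,
      followon_prob = 0, seed = 21L
    ),
    dir = tempfile()
  )
  d <- gen$truth$products$duration_years
  d <- d[!is.na(d)]
  expect_gt(length(d), 0L)
  # round(20 * 365.25) = 7305 days; <= 0.1 y leap drift from the convention
  expect_true(all(abs(d - 20) <= 0.1))
  expect_equal(unique(d), 7305 / 365.25)
})

test_that("the same seed reproduces identical bytes and ground truth", {
  a <- generate_synthetic(synthetic_config(n_lines = 8L, seed = 42L), dir = tempfile())
  b <- generate_synthetic(synthetic_config(n_lines = 8L, seed = 42L), dir = tempfile())
  for (key in names(a$paths)) {
    expect_identical(
      readLines(a$paths[[key]]), readLines(b$paths[[key]]),
      label = key
    )
  }
  expect_equal(a$truth, b$truth)
  c2 <- generate_synthetic(synthetic_config(n_lines = 8L, seed = 43L), dir = tempfile())
  expect_false(identical(
    readLines(a$paths$patents), readLines(c2$paths$patents)
  ))
})

test_that("generated files parse through the ingestion layer without warnings", {
  gen <- generate_synthetic(synthetic_config(n_lines = 10L, seed = 2L), dir = tempfile())
  expect_no_warning(read_products(gen$paths$products))
  expect_no_warning(read_patents(gen$paths$patents))
  expect_no_warning(read_exclusivities(gen$paths$exclusivities))
  expect_no_warning(read_annotations(gen$paths$annotations))
})

test_that("pipeline recovers generator ground truth exactly", {
  gen <- generate_synthetic(synthetic_config(n_lines = 30L, seed = 17L), dir = tempfile())
  chk <- parameter_recovery_check(gen)
  expect_true(chk$pass)
  expect_equal(chk$max_day_diff_products, 0)
  expect_equal(chk$max_day_diff_lines, 0)
  expect_equal(chk$count_delta, 0L)
  expect_true(all(abs(chk$deltas$duration_diff) < 1e-12, na.rm = TRUE))
})

test_that("immediate certain follow-on entry truncates every matched duration to zero", {
  gen <- generate_synthetic(
    synthetic_config(
      n_lines = 6L, followon_prob = 1, followon_delay_years = c(0, 0),
      seed = 12L
    ),
    dir = tempfile()
  )
  co <- build_cohort(
    read_products(gen$paths$products), cohort_config(),
    read_product_metadata(gen$paths$metadata)
  )
  cls <- link_and_classify(
    read_patents(gen$paths$patents),
    suppressWarnings(read_exclusivities(gen$paths$exclusivities)),
    read_annotations(gen$paths$annotations), co
  )
  sens <- suppressWarnings(
    sensitivity_analysis(co, cls$patents, cls$exclusivities)
  )
  first <- sens$lines[sens$lines$line_id %in%
    gen$truth$followons$originator_line_id, ]
  expect_true(all(first$truncated_years[!is.na(first$truncated_years)] == 0))
})

test_that("with no post-approval filings, at-approval and overall scopes agree", {
  gen <- generate_synthetic(
    synthetic_config(
      n_lines = 8L, filing_offset_mean = -4000, filing_offset_sd = 0,
      post_listing_prob = 0, post_exclusivity_rate = 0, seed = 6L
    ),
    dir = tempfile()
  )
  co <- build_cohort(
    read_products(gen$paths$products), cohort_config(),
    read_product_metadata(gen$paths$metadata)
  )
  cls <- link_and_classify(
    read_patents(gen$paths$patents),
    suppressWarnings(read_exclusivities(gen$paths$exclusivities)),
    read_annotations(gen$paths$annotations), co
  )
  a <- suppressWarnings(product_protection(
    co, cls$patents, cls$exclusivities, protection_scope("all")
  ))
  b <- suppressWarnings(product_protection(
    co, cls$patents, cls$exclusivities,
    protection_scope("at_approval_only", exclusivity_timing_filter = "at_approval_only")
  ))
  expect_equal(a$duration_years, b$duration_years)
})
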