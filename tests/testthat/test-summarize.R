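test_that("median_iqr matches hand-computed interpolated quartiles", {
  expect_equal(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  expect_equal(median_iqr(c(1, 2, 3, 4)), c(median = 2.5, q1 = 1.75, q3 = 3.25))
  expect_equal(median_iqr(c(1, 1, 10)), c(median = 1, q1 = 1, q3 = 5.5))
  expect_error(median_iqr(numeric()), "empty")
})

test_that("median_iqr agrees with a sort-based brute force on random lists", {
  set.seed(202)
  for (i in 1:60) {
    x <- stats::rnorm(sample(1:500, 1), sd = 10)
    m <- median_iqr(x)
    expect_equal(m, bf_median_iqr(x))
    expect_true(m[["q1"]] <= m[["median"]] && m[["median"]] <= m[["q3"]])
    expect_true(m[["q1"]] >= min(x) && m[["q3"]] <= max(x))
  }
})

test_that("discrete quartiles fall on observed order statistics", {
  x <- c(4, 1, 9, 2, 7)
  m <- median_iqr(x, type = "discrete")
  expect_true(all(m %in% x))
})

test_that("era assignment uses the fixed tercile calendar bounds", {
  prods <- mini_products()
  prods$approval_date <- as.Date(c("1996-12-31", "1997-01-01", "2008-01-01", "2019-12-31"))
  md <- mini_metadata()
  md$originator_or_followon <- "originator"
  co <- build_cohort(prods, cohort_config(), md)
  cls <- mini_classified(co)
  es <- era_summary(co, cls$patents, "terciles")
  expect_equal(es$era, c("1986-1996", "1997-2007", "2008-2019"))
  expect_equal(es$n_products, c(1L, 1L, 2L))
  # empty era reported with zero count and no median
  prods2 <- prods[3:4, ]
  md2 <- md[3:4, ]
  co2 <- build_cohort(prods2, cohort_config(), md2)
  es2 <- era_summary(co2, cls$patents[0, ], "terciles")
  expect_equal(es2$n_products, c(0L, 0L, 2L))
  expect_true(is.na(es2$patents_median[1]))
  expect_equal(es2$patents_median[3], 0)
})

test_that("rising generator rates yield non-decreasing era medians", {
  gen <- generate_synthetic(
    synthetic_config(n_lines = 40L, products_per_line = c(1L, 3L), seed = 8L),
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
  es <- era_summary(co, cls$patents, "terciles")
  med <- es$patents_median[!is.na(es$patents_median)]
  expect_true(all(diff(med) >= 0))
})

test_that("cohort_report fills counts, tallies and duration summaries coherently", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  rep <- suppressWarnings(cohort_report(co, cls$patents, cls$exclusivities))
  expect_s3_class(rep, "ob_report")
  expect_equal(rep$counts$originator_products, 3L)
  expect_equal(rep$counts$followon_products, 1L)
  expect_equal(rep$counts$drug_device_combinations, 1L)
  expect_equal(
    rep$counts$drug_device_pct,
    round(100 * rep$counts$drug_device_combinations / rep$counts$originator_products)
  )
  # mutually exclusive category counts sum to totals
  at_sum <- sum(vapply(
    rep$exclusivity_tallies$at_approval_by_category, function(x) x$count, numeric(1)
  ))
  expect_equal(at_sum, rep$exclusivity_tallies$at_approval_total)
  expect_equal(
    rep$patent_tallies$pre_approval_filed + rep$patent_tallies$post_approval_filed,
    nrow(cls$patents)
  )
  # per-class table covers every represented class
  expect_setequal(names(rep$per_class), unique(co$products$insulin_class[co$products$is_originator]))
})

test_that("report medians on a synthetic cohort equal the generator ground truth", {
  gen <- generate_synthetic(synthetic_config(n_lines = 20L, seed = 13L), dir = tempfile())
  co <- build_cohort(
    read_products(gen$paths$products), cohort_config(),
    read_product_metadata(gen$paths$metadata)
  )
  cls <- link_and_classify(
    read_patents(gen$paths$patents),
    suppressWarnings(read_exclusivities(gen$paths$exclusivities)),
    read_annotations(gen$paths$annotations), co
  )
  rep <- suppressWarnings(cohort_report(co, cls$patents, cls$exclusivities))
  truth_med <- median_iqr(gen$truth$products$duration_years[
    !is.na(gen$truth$products$duration_years)
  ])
  expect_equal(rep$durations$product_overall$median, truth_med[["median"]])
  expect_equal(rep$durations$product_overall$q1, truth_med[["q1"]])
  expect_equal(rep$durations$product_overall$q3, truth_med[["q3"]])
  truth_line <- median_iqr(gen$truth$lines$duration_years[
    !is.na(gen$truth$lines$duration_years)
  ])
  expect_equal(rep$durations$line_overall$median, truth_line[["median"]])
})

test_that("report counts are invariant under permutation of listings", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  a <- suppressWarnings(cohort_report(co, cls$patents, cls$exclusivities))
  b <- suppressWarnings(cohort_report(
    co, cls$patents[sample(nrow(cls$patents)), ],
    cls$exclusivities[c(2, 1), ]
  ))
  expect_equal(flatten_report(a), flatten_report(b))
})
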