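test_that("read_products parses rows, dates and ingredient lists", {
  f <- write_lines_tmp(c(
    ob_product_header,
    "NDA021081~001~LANTUS~INSULIN GLARGINE~INJECTABLE;SUBCUTANEOUS~Apr 20, 2000~SANOFI",
    "NDA000001~001~MIXBRAND~INSULIN A; INSULIN B~INJECTABLE;SUBCUTANEOUS~2010-01-05~MAKER"
  ))
  p <- read_products(f)
  expect_equal(nrow(p), 2L)
  expect_equal(p$appl_no[1], "NDA021081")
  expect_equal(p$approval_date[1], as.Date("2000-04-20"))
  expect_equal(p$active_ingredients[[2]], c("INSULIN A", "INSULIN B"))

  empty <- write_lines_tmp(ob_product_header)
  expect_equal(nrow(read_products(empty)), 0L)
})

test_that("malformed rows and bad dates raise errors naming the location", {
  f <- write_lines_tmp(c(ob_product_header, "NDA1~001~X"))
  expect_error(read_products(f), "line 2")
  f2 <- write_lines_tmp(c(
    ob_product_header,
    "NDA1~001~X~ING~DF~not a date~MAKER"
  ))
  expect_error(read_products(f2), "Approval_Date")
  expect_error(read_products(tempfile()), "not found")
})

test_that("duplicate product keys are rejected but duplicate patent rows are kept", {
  f <- write_lines_tmp(c(
    ob_product_header,
    "NDA1~001~X~ING~DF~2000-01-01~M",
    "NDA1~001~X2~ING~DF~2000-01-02~M"
  ))
  expect_error(read_products(f), "duplicate")

  pf <- write_lines_tmp(c(
    ob_patent_header,
    "NDA1~001~US1~Mar 15, 2033~2000-01-01~Y~Y~",
    "NDA1~001~US1~Mar 15, 2033~2000-01-01~Y~Y~"
  ))
  expect_message(pat <- read_patents(pf), "duplicate")
  expect_equal(nrow(pat), 2L)
  expect_equal(pat$patent_expire_date[1], as.Date("2033-03-15"))
})

test_that("read_exclusivities keeps unknown codes with a warning", {
  f <- write_lines_tmp(c(
    ob_excl_header,
    "NDA1~001~NCE~2005-04-20",
    "NDA1~001~ZZZ~2006-01-01"
  ))
  expect_warning(e <- read_exclusivities(f), "ZZZ")
  expect_equal(nrow(e), 2L)
  expect_equal(e$exclusivity_code[1], "NCE")

  empty <- write_lines_tmp(ob_excl_header)
  expect_equal(nrow(suppressWarnings(read_exclusivities(empty))), 0L)
})

test_that("annotations parse strictly and enforce the priority invariant", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "patent_no,application_date,priority_date,is_device,mentions_active",
    "US1234,1998-05-01,1997-05-01,true,false",
    "US1235,1999-02-01,,1,no"
  ), f)
  expect_warning(a <- read_annotations(f), "priority_date")
  expect_equal(nrow(a), 2L)
  expect_true(a$is_device[1])
  expect_false(a$mentions_active[1])
  expect_equal(a$priority_date[2], a$application_date[2]) # fallback

  bad <- tempfile(fileext = ".csv")
  writeLines(c(
    "patent_no,application_date,priority_date,is_device,mentions_active",
    "US9,2000-01-01,2001-01-01,false,false"
  ), bad)
  expect_error(read_annotations(bad), "priority_date after application_date")

  junk <- tempfile(fileext = ".csv")
  writeLines(c(
    "patent_no,application_date,priority_date,is_device,mentions_active",
    "US9,2000-01-01,1999-01-01,maybe,false"
  ), junk)
  expect_error(read_annotations(junk), "is_device")

  hdr <- tempfile(fileext = ".csv")
  writeLines("patent_no,application_date,priority_date,is_device,mentions_active", hdr)
  expect_equal(nrow(read_annotations(hdr)), 0L)
})

test_that("canonical write-read-write cycle is byte identical and dates round-trip ISO", {
  gen <- generate_synthetic(synthetic_config(n_lines = 6L, seed = 11L), dir = tempfile())
  for (key in c("products", "patents", "exclusivities")) {
    reader <- switch(key,
      products = read_products, patents = read_patents,
      exclusivities = read_exclusivities
    )
    writer <- switch(key,
      products = write_products, patents = write_patents,
      exclusivities = write_exclusivities
    )
    obj <- suppressWarnings(reader(gen$paths[[key]]))
    out <- tempfile()
    writer(obj, out)
    expect_identical(readLines(out), readLines(gen$paths[[key]]), label = key)
  }
  d <- parse_ob_date(c("2033-03-15", "Mar 15, 2033", "3/15/2033"))
  expect_true(all(format(d, "%Y-%m-%d") == "2033-03-15"))
})

test_that("exported reports round-trip between csv and json at reporting precision", {
  flat <- tibble::tibble(
    metric = c("durations.product_overall.median", "counts.drug_device_pct", "counts.n"),
    value = c(15.655, 58.93, 12)
  )
  csvf <- tempfile(fileext = ".csv")
  jsonf <- tempfile(fileext = ".json")
  export_report(flat, csvf, "csv")
  a <- read_report(csvf, "csv")
  expect_equal(a$value, c(15.7, 59, 12)) # stated rounding rules
  export_report(a, jsonf, "json")
  b <- read_report(jsonf, "json")
  export_report(b, csvf, "csv")
  expect_equal(read_report(csvf, "csv"), a)

  empty <- tibble::tibble(metric = character(), value = numeric())
  export_report(empty, csvf, "csv")
  expect_equal(nrow(read_report(csvf, "csv")), 0L)
  expect_error(export_report(flat, file.path(tempfile(), "x", "y.csv")), "unwritable")
})
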