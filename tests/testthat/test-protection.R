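test_that("last_to_expire returns the maximum expiry and NA for empty input", {
  expect_true(is.na(last_to_expire(as.Date(character()))))
  expect_equal(
    last_to_expire(as.Date(c("2024-06-01", "2027-03-10", "2015-01-15"))),
    as.Date("2027-03-10")
  )
})

test_that("last_to_expire equals a brute-force scan on random instances", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(1:1000, 1)
    d <- as.Date("1990-01-01") + sample(0:20000, n, replace = TRUE)
    expect_equal(last_to_expire(d), bf_max_date(d))
  }
})

test_that("product durations use 365.25-day years against the approval date", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  prot <- product_protection(co, cls$patents, cls$exclusivities)
  vial <- prot[prot$product_id == "NDA1/001", ]
  # last item is the non-device patent expiring 2017-01-01
  expect_equal(vial$last_expiry, as.Date("2017-01-01"))
  expect_equal(
    vial$duration_years,
    as.numeric(as.Date("2017-01-01") - as.Date("2000-04-20")) / 365.25
  )
  expect_equal(vial$last_item_kind, "patent_non_device")
  pen <- prot[prot$product_id == "NDA1/002", ]
  expect_equal(
    pen$duration_years,
    as.numeric(as.Date("2033-03-16") - as.Date("2007-05-01")) / 365.25
  )
  expect_equal(pen$last_item_kind, "patent_device")
})

test_that("year algebra is exact for items placed k*365.25 days out", {
  co <- mini_cohort()
  # 4 years = 1461 days exactly under the convention
  pat <- tibble::tibble(
    product_id = "NDA2/001", patent_no = "USK",
    expiry = as.Date("2010-06-15") + 1461L,
    device_status = "non_device",
    filing_timing = "pre_approval_filed", listing_timing = "listed_at_approval",
    priority_timing = "priority_before_approval"
  )
  exc <- mini_classified(co)$exclusivities[0, ]
  prot <- product_protection(co, pat, exc)
  expect_equal(prot$duration_years[prot$product_id == "NDA2/001"], 4)
})

test_that("products with no in-scope protections are flagged, negatives warned", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  prot <- product_protection(co, cls$patents, cls$exclusivities)
  gamma <- prot[prot$product_id == "NDA3/001", ] # follow-on, nothing listed
  expect_true(is.na(gamma$duration_years))
  expect_equal(gamma$last_item_kind, "none")
  expect_true(gamma$excluded_from_medians)

  late <- cls$patents
  late$expiry <- as.Date("1999-01-01") # before every approval
  expect_warning(
    product_protection(co, late, cls$exclusivities[0, ]),
    "negative duration"
  )
})

test_that("scope nesting: at-approval-only never exceeds overall duration", {
  for (seed in c(2L, 9L)) {
    gen <- generate_synthetic(synthetic_config(n_lines = 15L, seed = seed), dir = tempfile())
    co <- build_cohort(
      read_products(gen$paths$products), cohort_config(),
      read_product_metadata(gen$paths$metadata)
    )
    cls <- link_and_classify(
      read_patents(gen$paths$patents),
      suppressWarnings(read_exclusivities(gen$paths$exclusivities)),
      read_annotations(gen$paths$annotations), co
    )
    all_d <- suppressWarnings(
      product_protection(co, cls$patents, cls$exclusivities, protection_scope("all"))
    )
    at_d <- suppressWarnings(product_protection(
      co, cls$patents, cls$exclusivities,
      protection_scope("at_approval_only", exclusivity_timing_filter = "at_approval_only")
    ))
    ok <- is.na(at_d$duration_years) |
      at_d$duration_years <= all_d$duration_years + 1e-12
    expect_true(all(ok))
  }
})

test_that("adding a protection item never decreases overall product duration", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  base <- product_protection(co, cls$patents, cls$exclusivities)
  set.seed(33)
  for (i in 1:20) {
    extra <- cls$patents[1, ]
    extra$patent_no <- paste0("USX", i)
    extra$expiry <- as.Date("1995-01-01") + sample(0:15000, 1)
    more <- suppressWarnings(
      product_protection(co, dplyr::bind_rows(cls$patents, extra), cls$exclusivities)
    )
    row <- extra$product_id
    expect_gte(
      more$duration_years[more$product_id == row],
      base$duration_years[base$product_id == row]
    )
  }
})

test_that("line span dominates member products and matches the date oracle", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  prot <- product_protection(co, cls$patents, cls$exclusivities)
  lines <- line_protection(co, cls$patents, cls$exclusivities)
  alpha <- lines[lines$line_id == "ALPHA :: ACME", ]
  # approvals 2000-04-20/2007-05-01, expiries to 2033-03-16
  expect_equal(
    alpha$duration_years,
    as.numeric(as.Date("2033-03-16") - as.Date("2000-04-20")) / 365.25
  )
  expect_equal(alpha$first_filing, as.Date("1997-05-01"))
  for (i in seq_len(nrow(co$lines))) {
    member <- prot[prot$product_id %in% co$lines$product_ids[[i]], ]
    ln <- lines[lines$line_id == co$lines$line_id[i], ]
    if (!all(is.na(member$duration_years))) {
      expect_gte(ln$duration_years, max(member$duration_years, na.rm = TRUE))
    }
  }
  # single-product line equals that product's duration
  beta <- lines[lines$line_id == "BETA :: BMAKER", ]
  expect_equal(
    beta$duration_years,
    prot$duration_years[prot$product_id == "NDA2/001"]
  )
})

test_that("post-approval listings extend protection only when they add time", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  ext <- post_approval_extension(co, cls$patents, cls$exclusivities)
  # pen: at-approval frontier is US100 (2017-01-01); US200 listed 2012 adds to 2033-03-16
  pen <- ext$extension_years[ext$product_id == "NDA1/002"]
  expect_equal(
    pen,
    as.numeric(as.Date("2033-03-16") - as.Date("2017-01-01")) / 365.25
  )
  # vial has no post-approval listings -> none
  expect_true(is.na(ext$extension_years[ext$product_id == "NDA1/001"]))
  # a post-approval patent expiring before the frontier yields no gain
  cls2 <- cls
  cls2$patents$expiry[cls2$patents$patent_no == "US200"] <- as.Date("2010-01-01")
  ext2 <- post_approval_extension(co, cls2$patents, cls2$exclusivities)
  expect_true(is.na(ext2$extension_years[ext2$product_id == "NDA1/002"]))
})

test_that("device added protection is a signed frontier difference", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  dev <- device_added_protection(co, cls$patents)
  pen <- dev[dev$product_id == "NDA1/002", ]
  expect_equal(
    pen$added_years,
    as.numeric(as.Date("2033-03-16") - as.Date("2017-01-01")) / 365.25
  )
  # equal frontiers -> 0; missing class -> NA
  pats <- cls$patents
  pats$expiry[pats$patent_no == "US200"] <- as.Date("2017-01-01")
  dev2 <- device_added_protection(co, pats)
  expect_equal(dev2$added_years[dev2$product_id == "NDA1/002"], 0)
  nodev <- pats[pats$device_status == "non_device", ]
  expect_true(all(is.na(device_added_protection(co, nodev)$added_years)))
})

test_that("no-mention added protection compares against the full complement", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  nm <- no_mention_added_protection(co, cls$patents)
  pen <- nm[nm$product_id == "NDA1/002", ]
  expect_equal(
    pen$added_years,
    as.numeric(as.Date("2033-03-16") - as.Date("2017-01-01")) / 365.25
  )
  # complement empty -> NA; no-mention expiring first -> negative retained
  only_nm <- cls$patents[cls$patents$device_status == "device_no_mention", ]
  expect_true(all(is.na(no_mention_added_protection(co, only_nm)$added_years)))
  flipped <- cls$patents
  flipped$expiry[flipped$patent_no == "US200"] <- as.Date("2001-01-01")
  neg <- no_mention_added_protection(co, flipped)
  expect_lt(neg$added_years[neg$product_id == "NDA1/002"], 0)
})
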