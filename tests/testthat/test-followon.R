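test_that("follow-ons match originator lines on ingredients, not manufacturer", {
  co <- mini_cohort()
  fm <- match_followons(co)
  # GAMMA (INSULIN X, CMAKER) matches ALPHA (INSULIN X, ACME) but not BETA
  expect_equal(fm$matches$originator_line_id, "ALPHA :: ACME")
  expect_equal(fm$matches$followon_line_id, "GAMMA :: CMAKER")
  expect_equal(fm$first_followon$first_followon_approval, as.Date("2015-12-16"))
  expect_length(fm$unmatched_followons, 0L)
})

test_that("a follow-on with an unmatched ingredient triggers a warning", {
  prods <- mini_products()
  prods$active_ingredients[[4]] <- "INSULIN NOVEL"
  co <- build_cohort(prods, cohort_config(), mini_metadata())
  expect_warning(fm <- match_followons(co), "GAMMA")
  expect_equal(nrow(fm$matches), 0L)
  expect_equal(fm$unmatched_followons, "GAMMA :: CMAKER")
})

test_that("ingredient matching is case-insensitive on normalized sets", {
  prods <- mini_products()
  prods$active_ingredients[[4]] <- "insulin x"
  co <- build_cohort(prods, cohort_config(), mini_metadata())
  fm <- match_followons(co)
  expect_equal(nrow(fm$matches), 1L)
})

test_that("truncation takes the earlier of expiry and follow-on entry", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  prot <- product_protection(co, cls$patents, cls$exclusivities)

  # follow-on after expiry: unchanged
  t1 <- truncated_protection(prot[prot$product_id == "NDA1/001", ], as.Date("2020-01-01"))
  expect_equal(t1$truncated_years, t1$duration_years)
  # follow-on equals approval: zero
  t2 <- truncated_protection(prot[prot$product_id == "NDA1/001", ], as.Date("2000-04-20"))
  expect_equal(t2$truncated_years, 0)
  # printed-dates case: approval 2000-04-20, follow-on 2015-12-16 -> 5718 d
  t3 <- truncated_protection(prot[prot$product_id == "NDA1/002", ], as.Date("2015-12-16"))
  expect_equal(
    t3$truncated_years,
    as.numeric(as.Date("2015-12-16") - as.Date("2007-05-01")) / 365.25
  )
  expect_equal(
    as.numeric(as.Date("2015-12-16") - as.Date("2000-04-20")), 5718
  )
  # no follow-on: unchanged
  t4 <- truncated_protection(prot, as.Date(NA))
  expect_equal(t4$truncated_years, t4$duration_years)
})

test_that("sensitivity analysis truncates originator products at line level", {
  co <- mini_cohort()
  cls <- mini_classified(co)
  sens <- sensitivity_analysis(co, cls$patents, cls$exclusivities)
  pen <- sens$products[sens$products$product_id == "NDA1/002", ]
  expect_equal(pen$truncated_expiry, as.Date("2015-12-16"))
  # BETA line has no matched follow-on: untouched
  beta <- sens$products[sens$products$product_id == "NDA2/001", ]
  expect_equal(beta$truncated_years, beta$duration_years)
  # invariant: truncated <= untruncated wherever both exist
  both <- !is.na(sens$products$truncated_years) & !is.na(sens$products$duration_years)
  expect_true(all(
    sens$products$truncated_years[both] <= sens$products$duration_years[both] + 1e-12
  ))
  alpha_line <- sens$lines[sens$lines$line_id == "ALPHA :: ACME", ]
  expect_equal(alpha_line$truncated_expiry, as.Date("2015-12-16"))
})

test_that("matching is deterministic under permutation of cohort input", {
  prods <- mini_products()
  a <- match_followons(build_cohort(prods, cohort_config(), mini_metadata()))
  b <- match_followons(
    build_cohort(prods[c(4, 2, 3, 1), ], cohort_config(), mini_metadata())
  )
  expect_equal(a$matches, b$matches)
})
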