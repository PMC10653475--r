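# obprotect

Market-exclusivity analytics for FDA Orange Book-listed insulin products.

Brand-name insulin prices in the US are sustained in part by the patents and
regulatory exclusivities that manufacturers list in the FDA's *Approved Drug
Products with Therapeutic Equivalence Evaluations* (the Orange Book). The FDA
cannot approve a competing product until those protections expire or are
successfully challenged, so the **expected protection** on a product runs from
its approval date to its *last-to-expire* listed patent or exclusivity.
`obprotect` implements that analysis as a tested, reusable pipeline for the
1986–2019 cohort of biosynthetic insulins — the window between the first
Orange Book editions carrying patent data and the 2020 move of insulin to
biologics regulation — and for any Orange Book-shaped dataset of the same
form. It is written for pharmaceutical-policy and regulatory-science
researchers who want these duration metrics to be reproducible rather than
spreadsheet artifacts.

## The metrics

For a product with approval date `A` and in-scope protections expiring at
dates `E_1 … E_k`:

* **product protection** `D = (max_i E_i − A) / 365.25` years;
* **line protection** for an insulin line (products sharing a brand family,
  active-ingredient set and manufacturer): from the line's first approval to
  the last-to-expire protection over all member products;
* **post-approval extension**: `D(all listings) − D(listings present at
  approval)`, the exclusivity gained from patents and exclusivities added to
  the Orange Book after approval;
* **device added protection** on drug-device combinations: last-to-expire
  device patent minus last-to-expire non-device patent;
* **no-mention added protection**: the same frontier difference for device
  patents whose claims never mention the active ingredient, against
  everything else;
* **follow-on-truncated protection** (sensitivity): duration to
  `min(last expiry, first 505(b)(2) follow-on approval)` for originator
  lines with an ingredient-matched follow-on from another manufacturer.

Patents are classified per (patent, product) pair along two independent
timing axes — USPTO filing date versus approval, and first Orange Book
listing versus approval — and by device status
(`non_device` / `device_mention` / `device_no_mention`). All summaries are
medians with interquartile ranges; durations are rounded to one decimal and
percentages to whole numbers only at report serialization.

## Worked example

The packaged transcription of the published cohort tables rebuilds the
study cohort:

```r
library(obprotect)

fx <- expand_insulin_tables()
cohort <- build_cohort(fx$products, cohort_config(), fx$metadata)
cohort
#> <ob_cohort>
#>   61 products (56 originator, 5 follow-on) across 28 lines
#>   35 drug-device combinations; 0 rows excluded
#>   window 1986-01-01 .. 2019-12-31

match_followons(cohort)$first_followon
#> # A tibble: 6 × 2
#>   originator_line_id           first_followon_approval
#> 1 Afrezza :: MANNKIND          2019-06-20
#> 2 Exubera :: PFIZER            2019-06-20
#> 3 Humalog :: ELI LILLY         2017-12-11
#> 4 Lantus :: SANOFI             2015-12-16
#> 5 Toujeo :: SANOFI             2015-12-16
#> 6 Velosulin BR :: NOVO NORDISK 2019-06-20
```

Of the 61 products, 56 are originators across 25 originator lines (33 of
them drug-device combinations) and 5 are follow-ons across 3 lines — the
published cohort counts. The follow-on table shows each originator line
facing ingredient-matched 505(b)(2) competition and the date that
competition arrived: Basaglar (glargine, 2015) against Sanofi's Lantus and
Toujeo, Admelog (lispro, 2017) against Humalog, Myxredlin (human insulin,
2019) against every human-insulin originator line.

The full duration analysis needs per-patent dates, which the published
tables do not carry; the packaged synthetic generator produces a complete
Orange Book-shaped cohort with recorded ground truth instead:

```r
gen <- generate_synthetic(synthetic_config(seed = 1), dir = tempfile())
co  <- build_cohort(read_products(gen$paths$products), cohort_config(),
                    read_product_metadata(gen$paths$metadata))
cls <- link_and_classify(read_patents(gen$paths$patents),
                         read_exclusivities(gen$paths$exclusivities),
                         read_annotations(gen$paths$annotations), co)
cohort_report(co, cls$patents, cls$exclusivities)
#> <ob_report>
#>   cohort: 68 originator products / 25 lines; 2 follow-on products / 2 lines
#>   median product protection 19.1 y (IQR 14.6 to 21.0, n=66)
#>   median line protection 27.6 y (IQR 20.4 to 33.0, n=25)

parameter_recovery_check(gen)$max_day_diff_products
#> [1] 0
```

The recovery check re-derives every product's last-expiry date through the
pipeline and compares it with the generator's independently computed truth;
the discrepancy is exactly zero days because the date algebra is
deterministic.

A command-line wrapper lives at `inst/cli/obprotect.R`
(`Rscript obprotect.R report --config config.json`), with subcommands
`ingest`, `cohort`, `compute`, `sensitivity`, `report`, `simulate` and
`reproduce-tables`.

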