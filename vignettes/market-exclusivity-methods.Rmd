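---
title: "Methods: market-exclusivity durations for Orange Book-listed insulins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: market-exclusivity durations for Orange Book-listed insulins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obprotect)
```

## The analysis and its assumptions

`obprotect` measures how long FDA-approved insulin products are expected to
be protected from competition by the patents and regulatory exclusivities
their manufacturers list in the Orange Book. The unit of analysis is the
individual marketed product — a vial and a pen approved under the same New
Drug Application (NDA) count separately, because the delivery device is
itself a major locus of patenting — and, secondarily, the *insulin line*:
all products sharing a brand family, active-ingredient set and
manufacturer.

The core quantity is deliberately simple date algebra. Expected protection
for a product is the span from its FDA approval date to the latest expiry
among its in-scope listed protections; for a line, from the first member
approval to the latest expiry over all members. Everything else in the
package is classification (which protections are in scope) and descriptive
statistics (medians and interquartile ranges; no hypothesis testing, since
the goal is description of a complete cohort rather than inference from a
sample).

Three assumptions are inherited from the data model and worth keeping in
mind:

* The Orange Book listing is taken at face value. Patent validity,
  litigation outcomes, terminal disclaimers and patent-term adjustments are
  not modeled; a listed patent protects until its listed expiry.
* Expected protection is a snapshot. Manufacturers can add listings later
  (which the post-approval-extension metric measures for the observed
  window) and competitors can enter early (which the follow-on sensitivity
  analysis measures for the observed entries).
* Curated patent facts — USPTO application date, priority date, device
  status, whether any claim mentions the active ingredient — are inputs
  supplied in an annotation table, reflecting the manual, dual-reviewer
  reading that produced them. The package validates and consumes them; it
  does not attempt claim-text inference.

## Cohort rules

The default window keeps products approved 1986-01-01 through 2019-12-31
(inclusive; the test uses the approval date only). 1986 is when
consecutive Orange Book editions with patent information begin; 2019 is the
last approval year before insulin moved to biologics regulation and out of
the Orange Book. Animal-derived products are excluded by ingredient
keyword (`BEEF`, `PORK`, `BOVINE`, `PORCINE`), and the three biosynthetic
insulins approved before 1986 (Humulin R, L, N) by explicit trade name.
Every input row lands either in the cohort or in an exclusion log with a
reason, so `|input| = |cohort| + |exclusions|` is an enforced invariant.

The line key is *brand family + ingredient set + manufacturer*, not the NDA
alone. The NDA-only reading fails on Humalog, which spans two NDAs but is
one line in the published line-level analysis; the brand-family key
reproduces the 25 originator lines. The packaged tables record Humalog with
4 products (3 + 1 across two NDAs), following the table footnote; the
corresponding figure caption says 5 + 1, a discrepancy in the source that
the fixture records but does not resolve.

## Classification conventions

**Tie rule.** A patent application, priority date or first listing falling
exactly on the approval date counts as *post*-approval. The source is
silent on ties; a strict-inequality convention is deterministic and applied
uniformly.

**Two timing axes.** Filing timing (USPTO application date vs approval) and
listing timing (first Orange Book listing vs approval) are computed
independently, because the published tallies use both: patent counts "at
approval" are framed on the filing axis, while post-approval *additions* to
the Orange Book are a listing-axis phenomenon. The protection scope object
exposes each axis separately, and reports label which was used. When the
first-listing date is unknown, listing timing falls back to filing timing
with a warning (annual-edition data can only bound the listing date; users
with edition-year granularity are advised to encode December 31 of the
edition year).

**Exclusivity timing.** The Orange Book lists only an exclusivity's expiry.
The grant date is therefore estimated as expiry minus the category's
statutory term (5 years for new chemical entities, 3 years for the other
non-pediatric categories), and the exclusivity is "at approval" when that
estimate is on or before the approval date. Pediatric exclusivities are
always tallied as post-approval, matching their separate treatment in the
source tallies; their listed expiry is consumed as-is, with no six-month
term arithmetic.

**Per-pair classification.** A patent listed on both the vial and the pen
of one NDA yields two records, because the published patent tallies are
per-product listings; analyses of *unique* patents deduplicate by patent
number explicitly.

## Numerical choices

* **Years** are calendar-day differences divided by 365.25. This
  reproduces decimal-year reporting without month-arithmetic ambiguity; a
  patent term of 20 years becomes 7305 days, so "exactly 20 years" computes
  as 19.9986 — a ≤ 0.1-year leap-day drift that the tests treat as exact
  arithmetic, not error.
* **Rounding** to one decimal (durations) and whole numbers (percentages,
  half away from zero) happens only at report serialization, never inside
  computations.
* **Quartiles** default to linear interpolation at positions
  `p × (n − 1)` (the common default in mainstream statistical software,
  `quantile` type 7). The source does not state its convention, so a
  discrete order-statistic option (type 1) is also provided; the packaged
  default is interpolated.
* **Signed differences.** Device added protection and no-mention added
  protection are computed signed and retained even when negative;
  reporting layers select the positive subset. This keeps the raw metric
  lossless and auditable.
* **Degenerate inputs.** Products with no in-scope protections get `NA`
  durations, are flagged, and are excluded from duration medians while
  still counting in cohort totals. A last expiry before approval yields a
  negative duration with a warning rather than silent truncation. Ties at
  the last-to-expire date resolve the "kind of last item" in favor of
  patents over exclusivities and device over non-device patents.

## The synthetic generator

No cohort dataset with per-patent dates is deposited anywhere, so the
package ships a generator that emulates the data shape end to end:
products under NDAs with approval dates across the window, patents with
priority/application dates and 20-year-from-priority expiries, device
flags and no-mention flags, at-approval and post-approval exclusivities
with statutory terms, and sparse follow-on entry. Its defaults mirror the
study conditions: 25 lines of 1–5 products approved 1986–2019, device
fractions rising over the three thirds of the window (0.15/0.45/0.75),
Poisson patents-per-product rates rising (0.5/4/15, echoing the observed
median growth from 0 to double digits), an 80% no-mention fraction among
device patents, 5-year NCE and 3-year new-product exclusivity terms, and a
12% follow-on hazard with a ~15-year entry delay. Counts are Poisson and
filing offsets discretized normal (mean −1500, sd 1500 days); the source
supplies no distributions, so these are the generator's own, chosen once
to look like the real cohort's scale.

The generator records ground truth (per-product and per-line last expiries
and durations, device added protection, follow-on entry dates) computed by
raw integer day arithmetic in a code path separate from the protection
module. Because both sides are deterministic date algebra, the recovery
check demands *exact* agreement — zero days — and gets it; any nonzero
discrepancy is a bug, not noise.

What the generator does not emulate: correlated patent families across
products, litigation and settlement timing, patent-term adjustments,
strength/presentation proliferation within a brand, or realistic brand
names. Passing tests on synthetic cohorts therefore validate the
*pipeline's algebra and bookkeeping*, not any empirical claim about real
insulin data; the real-data claims the package can check are the packaged
published-table counts and the one printed cross-metric consistency value
(the glargine follow-on's 17.3-year head start, reproduced from printed
inputs to within input rounding, ±0.1 years).

## Problem sizes in the test suite

The suite exercises 1000-instance oracle-equivalence sweeps for the
last-to-expire and quantile engines, synthetic cohorts of 4–40 lines for
module tests, and a 100-line cohort (roughly 300 products) for the
end-to-end recovery check — sizes chosen to cover every branch while
keeping the default run around a minute.

## Known limitations

* Exclusivity grant-date inference assumes statutory terms; an exclusivity
  granted with a nonstandard term would be mis-timed (its expiry, and thus
  all durations, remain correct).
* The packaged tables carry line-level first-approval dates only, so
  fixture-derived analyses are restricted to counts and
  approval-date-based checks; duration analyses need real or synthetic
  per-patent inputs.
* Ingredient matching normalizes case and whitespace but relies on the
  curation table for salt/strength canonicalization; distinct ingredient
  spellings in raw files will not match (the human-insulin "regular"
  transcription is one such case, kept faithful to the source tables).
* The window test uses approval dates only; products approved in-window
  but delisted earlier are not tracked.
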