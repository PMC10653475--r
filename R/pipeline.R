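#' Pipeline configuration
#'
#' @param products,patents,exclusivities,annotations,metadata Input file
#'   paths (Orange Book-style files, annotation CSV, product-metadata CSV).
#' @param cohort A [cohort_config()].
#' @param scope A [protection_scope()] for the overall duration metric.
#' @param out Output directory.
#' @param format Report format(s), subset of `c("csv", "json")`.
#' @param seed Seed for the `simulate` subcommand.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(products = NULL, patents = NULL,
                            exclusivities = NULL, annotations = NULL,
                            metadata = NULL, cohort = cohort_config(),
                            scope = protection_scope(), out = "obprotect-out",
                            format = "csv", seed = 1L) {
  structure(
    list(
      products = products, patents = patents, exclusivities = exclusivities,
      annotations = annotations, metadata = metadata, cohort = cohort,
      scope = scope, out = out, format = match.arg(format, c("csv", "json")),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a JSON file
#'
#' Recognised keys: the five input paths, `out`, `format`, `seed`,
#' `window_start`, `window_end`, `which_patents`, `include_exclusivities`,
#' `exclusivity_timing_filter`.
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- cohort_config(
    window_start = if (!is.null(x$window_start)) as.Date(x$window_start) else as.Date("1986-01-01"),
    window_end = if (!is.null(x$window_end)) as.Date(x$window_end) else as.Date("2019-12-31")
  )
  sc <- protection_scope(
    which_patents = x$which_patents %||% "all",
    include_exclusivities = x$include_exclusivities %||% TRUE,
    exclusivity_timing_filter = x$exclusivity_timing_filter %||% "all"
  )
  pipeline_config(
    products = x$products, patents = x$patents,
    exclusivities = x$exclusivities, annotations = x$annotations,
    metadata = x$metadata, cohort = cc, scope = sc,
    out = x$out %||% "obprotect-out", format = x$format %||% "csv",
    seed = x$seed %||% 1L
  )
}

.check_inputs <- function(config, need) {
  paths <- unlist(config[need])
  if (length(paths) < length(need) || any(!nzchar(paths))) {
    rlang::abort(sprintf(
      "missing input path(s): %s",
      paste(setdiff(need, names(paths)[nzchar(paths)]), collapse = ", ")
    ))
  }
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0L) {
    rlang::abort(sprintf("input file(s) not found: %s", paste(absent, collapse = ", ")))
  }
}

.write_manifest <- function(config, subcommand, out, timings) {
  manifest <- list(
    subcommand = subcommand,
    inputs = config[c("products", "patents", "exclusivities", "annotations", "metadata")],
    config_hash = rlang::hash(config[setdiff(names(config), "out")]),
    package_version = as.character(utils::packageVersion("obprotect")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    timings_sec = timings
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  invisible(manifest)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages as subcommands:
#' \describe{
#'   \item{ingest}{Read and validate all inputs; write normalized copies.}
#'   \item{cohort}{Build the cohort; write the product, line and
#'     exclusion-log tables.}
#'   \item{compute}{Cohort + classification + all protection metrics;
#'     write per-product/per-line durations and the timeline extract.}
#'   \item{sensitivity}{Follow-on matching and truncated durations.}
#'   \item{report}{The full study report via [cohort_report()] and
#'     [export_report()].}
#'   \item{simulate}{Generate a synthetic cohort into the output
#'     directory with the configured seed.}
#'   \item{reproduce-tables}{Rebuild the packaged published-cohort tables
#'     and check the printed counts (56 originator products, 25 lines, 33
#'     drug-device combinations, 5 follow-on products, 3 follow-on
#'     lines); nonzero status on any mismatch.}
#' }
#' Every run writes a `manifest.json` (inputs, config hash, versions,
#' timings) into the output directory. Warnings and exclusions carry record
#' identifiers so the exclusion log stays auditable.
#'
#' @param config A `pipeline_config` or path to a JSON config file.
#' @param subcommand One of the stages above.
#' @return A list with `status` (0 on success) and stage artifacts,
#'   invisibly.
#' @export
run_pipeline <- function(config,
                         subcommand = c(
                           "ingest", "cohort", "compute", "sensitivity",
                           "report", "simulate", "reproduce-tables"
                         )) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]

  if (subcommand == "simulate") {
    gen <- generate_synthetic(synthetic_config(seed = config$seed), dir = out)
    timings <- list(simulate = proc.time()[["elapsed"]] - t0)
    .write_manifest(config, subcommand, out, timings)
    return(invisible(list(status = 0L, generated = gen)))
  }

  if (subcommand == "reproduce-tables") {
    fx <- expand_insulin_tables()
    cohort <- build_cohort(fx$products, config$cohort, fx$metadata)
    p <- cohort$products
    checks <- c(
      originator_products = sum(p$is_originator) == 56L,
      originator_lines = sum(cohort$lines$is_originator) == 25L,
      drug_device_combinations = sum(p$is_originator & p$is_drug_device) == 33L,
      followon_products = sum(!p$is_originator) == 5L,
      followon_lines = sum(!cohort$lines$is_originator) == 3L
    )
    utils::write.csv(
      data.frame(check = names(checks), pass = unname(checks)),
      file.path(out, "reproduce_tables.csv"),
      row.names = FALSE
    )
    .write_manifest(config, subcommand, out,
      list(total = proc.time()[["elapsed"]] - t0)
    )
    if (!all(checks)) {
      message(sprintf(
        "reproduce-tables: FAILED check(s): %s",
        paste(names(checks)[!checks], collapse = ", ")
      ))
      return(invisible(list(status = 1L, checks = checks)))
    }
    return(invisible(list(status = 0L, checks = checks)))
  }

  .check_inputs(config, c("products", "patents", "exclusivities", "annotations", "metadata"))
  products <- read_products(config$products)
  patents_raw <- read_patents(config$patents)
  exclusivities_raw <- read_exclusivities(config$exclusivities)
  annotations <- read_annotations(config$annotations)
  metadata <- read_product_metadata(config$metadata)
  timings <- list(ingest = proc.time()[["elapsed"]] - t0)

  if (subcommand == "ingest") {
    write_products(products, file.path(out, "products_normalized.txt"))
    write_patents(patents_raw, file.path(out, "patent_normalized.txt"))
    write_exclusivities(exclusivities_raw, file.path(out, "exclusivity_normalized.txt"))
    .write_manifest(config, subcommand, out, timings)
    return(invisible(list(status = 0L)))
  }

  cohort <- build_cohort(products, config$cohort, metadata)
  utils::write.csv(
    cohort$exclusion_log, file.path(out, "exclusion_log.csv"),
    row.names = FALSE
  )
  if (subcommand == "cohort") {
    prods_flat <- cohort$products
    prods_flat$active_ingredients <- vapply(
      prods_flat$active_ingredients, paste, character(1), collapse = ";"
    )
    utils::write.csv(prods_flat, file.path(out, "cohort_products.csv"), row.names = FALSE)
    lines_flat <- cohort$lines
    lines_flat$product_ids <- vapply(
      lines_flat$product_ids, paste, character(1), collapse = ";"
    )
    utils::write.csv(lines_flat, file.path(out, "cohort_lines.csv"), row.names = FALSE)
    timings$cohort <- proc.time()[["elapsed"]] - t0
    .write_manifest(config, subcommand, out, timings)
    return(invisible(list(status = 0L, cohort = cohort)))
  }

  cls <- link_and_classify(patents_raw, exclusivities_raw, annotations, cohort)

  if (subcommand == "compute") {
    prot <- product_protection(cohort, cls$patents, cls$exclusivities, config$scope)
    lprot <- line_protection(cohort, cls$patents, cls$exclusivities, config$scope)
    tl <- timeline_extract(cohort, cls$patents, cls$exclusivities, config$scope)
    utils::write.csv(prot, file.path(out, "product_protection.csv"), row.names = FALSE)
    utils::write.csv(lprot, file.path(out, "line_protection.csv"), row.names = FALSE)
    utils::write.csv(tl, file.path(out, "timeline.csv"), row.names = FALSE)
    timings$compute <- proc.time()[["elapsed"]] - t0
    .write_manifest(config, subcommand, out, timings)
    return(invisible(list(status = 0L, products = prot, lines = lprot)))
  }

  if (subcommand == "sensitivity") {
    sens <- sensitivity_analysis(cohort, cls$patents, cls$exclusivities, config$scope)
    utils::write.csv(
      sens$matches$matches, file.path(out, "followon_matches.csv"),
      row.names = FALSE
    )
    utils::write.csv(
      sens$products, file.path(out, "product_protection_truncated.csv"),
      row.names = FALSE
    )
    utils::write.csv(
      sens$lines, file.path(out, "line_protection_truncated.csv"),
      row.names = FALSE
    )
    timings$sensitivity <- proc.time()[["elapsed"]] - t0
    .write_manifest(config, subcommand, out, timings)
    return(invisible(list(status = 0L, sensitivity = sens)))
  }

  # report
  rep <- cohort_report(cohort, cls$patents, cls$exclusivities, config$scope)
  export_report(rep, file.path(out, paste0("report.", config$format)), config$format)
  timings$report <- proc.time()[["elapsed"]] - t0
  .write_manifest(config, subcommand, out, timings)
  invisible(list(status = 0L, report = rep))
}
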