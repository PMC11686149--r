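# End-to-end orchestration: simulate -> clean -> dedup -> fit -> report,
# driven by one config whose root seed feeds every stage through named
# substreams, with a manifest of artifacts and hashes.

#' Default pipeline configuration
#'
#' One nested list with per-stage sections. All randomness flows from the
#' root `seed` via named substreams, so a config fully determines every
#' artifact.
#'
#' @param seed root seed.
#' @param sim named list of [sim_params()] overrides.
#' @param model named list of [model_config()] overrides.
#' @param dedup list: `matrix_mode` (`"attributed"` or `"per-source"`).
#' @param report list: `median_lifespan_years`, `per_capita_threshold`.
#' @param geo_file optional path to an external geography CSV (columns
#'   `area`, `region`, `country`, `human_population`); otherwise geography is
#'   simulated.
#' @return a nested config list.
#' @export
pipeline_config <- function(seed = 1L, sim = list(), model = list(),
                            dedup = list(matrix_mode = "attributed"),
                            report = list(median_lifespan_years = c(12, 12.5),
                                          per_capita_threshold = 1.5),
                            geo_file = NULL) {
  list(seed = as.integer(seed), sim = sim, model = model, dedup = dedup,
       report = report, geo_file = geo_file)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  do.call(pipeline_config, config[intersect(names(config),
                                            names(formals(pipeline_config)))])
}

#' Run the full pipeline
#'
#' Executes simulate, clean, dedup (+ inclusion filters), fit, and report in
#' order, writing each stage's artifacts under `out_dir` and returning a run
#' manifest (config hash, seeds, artifact paths with md5 checksums, package
#' version, timestamps, convergence flag). A stage error aborts the run with
#' the stage name, after writing the partial manifest.
#'
#' @param config a [pipeline_config()] list or the path of a YAML file.
#' @param out_dir output directory.
#' @return the manifest, invisibly also written to `manifest.json`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = tempfile("dogpop_")) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = canonical_hash(config),
                   seed = config$seed,
                   package_version = as.character(packageVersion("dogpop")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  note <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      files = files, md5 = unname(tools::md5sum(files)),
      at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  }
  fail <- function(stage, e) {
    manifest$error <<- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # --- simulate ---
  st <- geo <- NULL
  tryCatch({
    sp <- do.call(sim_params, c(config$sim,
                                list(seed = derive_seed(config$seed, 11L))))
    geo <- if (!is.null(config$geo_file)) {
      if (!file.exists(config$geo_file))
        stop("geography file not found: ", config$geo_file)
      g <- read.csv(config$geo_file, stringsAsFactors = FALSE)
      class(g) <- c("geography_map", "data.frame"); g
    } else generate_geography(sp)
    truth <- simulate_truth(geo, sp)
    st <- emit_source_tables(truth, sp)
    files <- write_source_tables(st, file.path(out_dir, "sim"))
    note("simulate", files)
  }, error = function(e) fail("simulate", e))

  # --- clean ---
  cleaned <- NULL
  tryCatch({
    cleaned <- clean_records(st, geo)
    f <- file.path(out_dir, "records_clean.csv")
    write.csv(cleaned, f, row.names = FALSE, na = "")
    note("clean", f)
  }, error = function(e) fail("clean", e))

  # --- dedup + filters + count matrix ---
  y <- linkage <- individuals <- NULL
  tryCatch({
    linkage <- dedup_records(cleaned)
    reps <- cleaned[cleaned$.row %in% linkage$work$.row, ]
    filt <- apply_filters(reps)
    individuals <- filt$records
    keep_clusters <- linkage$clusters[
      linkage$clusters$.row %in% individuals$.row, ]$cluster_id
    flink <- linkage
    flink$clusters <- linkage$clusters[
      linkage$clusters$cluster_id %in% keep_clusters, ]
    y <- build_count_matrix(flink, geo,
                            mode = config$dedup$matrix_mode %||% "attributed")
    fy <- file.path(out_dir, "count_matrix.csv")
    write.csv(as.data.frame(unclass(y)), fy, row.names = TRUE)
    fc <- file.path(out_dir, "clusters.csv")
    write.csv(linkage$clusters, fc, row.names = FALSE, na = "")
    fr <- file.path(out_dir, "dedup_report.json")
    jsonlite::write_json(list(phase_counts = as.list(linkage$phase_counts),
                              unresolved_fraction = linkage$unresolved_fraction,
                              filter_report = filt$report),
                         fr, auto_unbox = TRUE, digits = NA)
    note("dedup", c(fy, fc, fr))
  }, error = function(e) fail("dedup", e))

  # --- fit ---
  draws <- NULL
  tryCatch({
    mc <- do.call(model_config, c(config$model,
                                  list(seed = derive_seed(config$seed, 12L))))
    draws <- fit_nmixture(y, geo, mc)
    rhat <- gelman_rubin(draws)
    manifest$converged <- isTRUE(attr(rhat, "converged"))
    manifest$rhat_max <- max(rhat)
    fd <- file.path(out_dir, "draws.csv")
    long <- do.call(rbind, lapply(seq_along(draws$chains), function(ch) {
      m <- draws$chains[[ch]]
      data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
                 parameter = rep(colnames(m), each = nrow(m)),
                 value = as.vector(m))
    }))
    write.csv(long, fd, row.names = FALSE)
    note("fit", fd)
  }, error = function(e) fail("fit", e))

  # --- report ---
  tryCatch({
    ctry <- posterior_summary(draws, "country", geo)
    regn <- posterior_summary(draws, "region", geo)
    uk <- posterior_summary(draws, "uk")
    pc <- per_capita(draws, geo,
                     config$report$per_capita_threshold %||% 1.5)
    demo <- demographic_table(individuals, "age_group")
    part <- partition_estimates(ctry, demo)
    rr <- ratios_and_replacement(
      ctry, individuals,
      config$report$median_lifespan_years %||% c(12, 12.5))
    files <- character(0)
    for (nm in c("ctry", "regn", "uk", "pc", "part")) {
      f <- file.path(out_dir, paste0("report_", nm, ".csv"))
      write.csv(get(nm), f, row.names = FALSE)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "report_ratios.json")
    jsonlite::write_json(rr, f, auto_unbox = TRUE, digits = NA)
    note("report", c(files, f))
  }, error = function(e) fail("report", e))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Evaluate a targets file against pipeline outputs
#'
#' Each target names a metric, an expected value, and a tolerance; metrics
#' are looked up in `outputs` (a named list, or the path of a JSON file of
#' metric values). Malformed targets are reported, not fatal.
#'
#' @param outputs named list of computed metric values, or path to a JSON
#'   file containing one.
#' @param targets_file path to a JSON array of
#'   `{id, metric, expected, tol}` objects.
#' @return data.frame `id`, `metric`, `value`, `expected`, `delta`, `pass`
#'   (NA for malformed targets).
#' @export
check_acceptance <- function(outputs, targets_file) {
  if (is.character(outputs)) outputs <- jsonlite::read_json(outputs)
  targets <- jsonlite::read_json(targets_file)
  if (!length(targets))
    return(data.frame(id = character(), metric = character(),
                      value = numeric(), expected = numeric(),
                      delta = numeric(), pass = logical()))
  rows <- lapply(targets, function(t) {
    id <- t$id %||% NA_character_
    ok <- is.list(t) && !is.null(t$metric) && !is.null(t$expected) &&
      !is.null(outputs[[t$metric]])
    if (!ok)
      return(data.frame(id = id, metric = t$metric %||% NA_character_,
                        value = NA_real_, expected = NA_real_,
                        delta = NA_real_, pass = NA))
    v <- as.numeric(outputs[[t$metric]])
    e <- as.numeric(t$expected)
    tol <- as.numeric(t$tol %||% 1e-6)
    data.frame(id = id, metric = t$metric, value = v, expected = e,
               delta = v - e, pass = abs(v - e) <= tol)
  })
  do.call(rbind, rows)
}
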