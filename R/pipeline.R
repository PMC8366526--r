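#' Validate a replicate-level observation table
#'
#' Checks the schema contract of the replicate table consumed by
#' [summarize_sites()]: required columns, known metrics, allowed site
#' types and zones (natural marshes have no sill), finite non-negative
#' values where the metric's support demands it, and positive effort for
#' effort-ratio metrics. Violations are reported with their location; no
#' silent coercion is performed.
#'
#' @param observations Replicate-level data frame.
#' @param stop_on_error Abort with the first violations instead of
#'   returning them.
#' @return A tibble of violations (`row`, `column`, `problem`); zero rows
#'   means the table is valid.
#' @export
validate_replicates <- function(observations, stop_on_error = FALSE) {
  problems <- list()
  note <- function(row, column, problem) {
    problems[[length(problems) + 1]] <<-
      tibble::tibble(row = row, column = column, problem = problem)
  }
  req <- c("pair", "site_type", "metric", "replicate", "value")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    note(NA_integer_, missing_cols, "required column missing")
    out <- dplyr::bind_rows(problems)
    if (stop_on_error) abort(paste("Invalid replicate table:",
                                   paste(missing_cols, collapse = ", "),
                                   "missing."))
    return(out)
  }
  if (!"zone" %in% names(observations)) observations$zone <- NA_character_
  if (!"effort" %in% names(observations)) observations$effort <- NA_real_

  defs <- metric_definitions()
  bad_metric <- which(!observations$metric %in% defs$metric)
  for (i in bad_metric) {
    note(i, "metric", sprintf("unknown metric '%s'", observations$metric[i]))
  }
  bad_site <- which(!observations$site_type %in% c("LS", "NM"))
  for (i in bad_site) {
    note(i, "site_type", "site_type must be 'LS' or 'NM'")
  }
  nm_sill <- which(observations$site_type == "NM" &
                     !is.na(observations$zone) &
                     observations$zone == "sill")
  for (i in nm_sill) {
    note(i, "zone", "natural marsh rows cannot carry zone 'sill'")
  }
  bad_val <- which(!is.finite(observations$value))
  for (i in bad_val) note(i, "value", "value must be finite")
  nonneg <- defs$metric[defs$group %in%
                          c("invertebrate", "plant", "soil", "terrapin")]
  neg <- which(observations$metric %in% nonneg & observations$value < 0)
  for (i in neg) {
    note(i, "value",
         sprintf("negative value for non-negative metric '%s'",
                 observations$metric[i]))
  }
  effort_metrics <- defs$metric[defs$aggregation == "effort_ratio"]
  bad_eff <- which(observations$metric %in% effort_metrics &
                     (is.na(observations$effort) | observations$effort <= 0))
  for (i in bad_eff) {
    note(i, "effort", "effort-ratio metrics require effort > 0")
  }
  out <- if (length(problems)) dplyr::bind_rows(problems)
         else tibble::tibble(row = integer(), column = character(),
                             problem = character())
  if (stop_on_error && nrow(out)) {
    abort(sprintf("Invalid replicate table (%d violation(s)); first: row %s, column %s: %s",
                  nrow(out), out$row[1], out$column[1], out$problem[1]))
  }
  out
}

#' Assemble (or read) a pipeline configuration
#'
#' @param path Optional YAML file; entries override the defaults
#'   element-wise.
#' @param ... Named overrides applied after the file.
#' @return A list of class `pipeline_config` with entries `seed`,
#'   `outdir`, `design` (arguments to [study_design()]), `effects`
#'   (arguments to [effect_spec()]), `age_model` (chains, iter, warmup),
#'   `distance` (run, key simulation truth, n_surveys, truncate, n_boot),
#'   and `input` (optional path to a replicate CSV to analyse instead of
#'   simulating).
#' @export
pipeline_config <- function(path = NULL, ...) {
  config <- list(
    seed = 1L,
    outdir = "marshequiv-run",
    input = NULL,
    design = list(n_pairs = 13L),
    effects = list(),
    age_model = list(chains = 4L, iter = 50000L, warmup = 5000L),
    distance = list(run = TRUE, n_surveys = 60L, truncate = 0.05,
                    n_boot = 0L))
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("Config file '%s' not found.", path))
    config <- modifyList(config, yaml::read_yaml(path))
  }
  config <- modifyList(config, list(...))
  structure(config, class = "pipeline_config")
}

#' Run the full equivalence pipeline
#'
#' Simulates (or reads) a replicate-level study, validates it, summarizes
#' sites, builds the pair-by-metric equivalence table, fits the
#' logarithmic age model and its intercept-only null with a LOOIC
#' comparison and posterior predictive checks, and (optionally) runs the
#' terrapin distance-sampling stage. All intermediate tables are written
#' as CSV to `config$outdir` together with a JSON run manifest recording
#' the seed, package version and a hash of the configuration, so a rerun
#' with the same configuration is identical.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file).
#' @return Invisibly, a list with `observations`, `summaries`,
#'   `equivalence`, `age_fit`, `null_fit`, `loo` (comparison tibble),
#'   `ppc`, `distance` (selected fit and effective radius or `NULL`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config or a YAML path.")
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  design <- do.call(study_design,
                    modifyList(config$design, list(seed = seed)))
  effects <- do.call(effect_spec, config$effects)

  observations <- if (!is.null(config$input)) {
    readr::read_csv(config$input, show_col_types = FALSE)
  } else {
    simulate_study(design, effects)
  }
  bad <- validate_replicates(observations)
  if (nrow(bad)) {
    abort(sprintf(
      "Input failed validation (%d violations); first: row %s, column %s: %s",
      nrow(bad), bad$row[1], bad$column[1], bad$problem[1]))
  }

  summaries <- summarize_sites(observations)
  eq <- equivalence_table(summaries)

  ages <- tibble::tibble(pair = seq_len(design$n_pairs), age = design$ages)
  net <- dplyr::inner_join(eq$net_scores, ages, by = "pair")
  am <- config$age_model
  age_fit <- fit_age_model(net, chains = am$chains, iter = am$iter,
                           warmup = am$warmup,
                           seed = sub_seed(seed, "age"))
  null_fit <- fit_null_model(net, chains = am$chains, iter = am$iter,
                             warmup = am$warmup,
                             seed = sub_seed(seed, "null"))
  loo_tbl <- suppressWarnings(compare_loo(age_fit, null_fit))
  ppc <- posterior_predictive_check(age_fit, seed = sub_seed(seed, "ppc"))

  distance <- NULL
  if (isTRUE(config$distance$run)) {
    dspec <- terrapin_sim_spec()
    sim <- simulate_terrapin_distances(dspec, config$distance$n_surveys,
                                       seed = sub_seed(seed, "terrapin"))
    kept <- truncate_distances(sim$distance_m, p = config$distance$truncate)
    sim_kept <- sim[attr(kept, "index"), ]
    cand <- fit_detection_set(sim_kept, covariates = "wind_mps")
    edr <- effective_radius(cand$selected,
                            n_boot = config$distance$n_boot,
                            seed = sub_seed(seed, "boot"))
    distance <- list(sightings = sim, selected = cand$selected,
                     candidates = cand$candidates, edr = edr)
  }

  manifest <- list(
    package = "marshequiv",
    version = as.character(utils::packageVersion("marshequiv")),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  readr::write_csv(observations, file.path(outdir, "replicates.csv"))
  readr::write_csv(summaries, file.path(outdir, "site_summaries.csv"))
  z_wide <- eq$z |>
    dplyr::select("pair", "metric", "z") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "z") |>
    dplyr::left_join(eq$net_scores, by = "pair")
  readr::write_csv(z_wide, file.path(outdir, "z_table.csv"))
  readr::write_csv(eq$metric_means, file.path(outdir, "metric_means.csv"))
  readr::write_csv(net, file.path(outdir, "net_scores.csv"))
  readr::write_csv(age_fit$summary, file.path(outdir, "age_posterior.csv"))
  readr::write_csv(loo_tbl, file.path(outdir, "loo_comparison.csv"))
  if (!is.null(distance)) {
    readr::write_csv(distance$candidates,
                     file.path(outdir, "detection_candidates.csv"))
    jsonlite::write_json(
      list(key = distance$selected$key,
           expansion = distance$selected$expansion,
           sigma = distance$selected$sigma,
           shape = distance$selected$shape,
           AIC = distance$selected$AIC,
           gof_p = distance$selected$gof_p,
           edr_m = distance$edr$rho,
           edr_ci = distance$edr$ci),
      file.path(outdir, "detection_selected.json"),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(observations = observations, summaries = summaries,
                 equivalence = eq, age_fit = age_fit, null_fit = null_fit,
                 loo = loo_tbl, ppc = ppc, distance = distance,
                 manifest = manifest))
}
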