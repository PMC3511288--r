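# Readers/writers for long-format choice data and the end-to-end pipeline.

#' Read a long-format choice dataset from delimited text
#'
#' Expects one row per respondent x task x alternative with columns
#' `resp_id`, `block`, `task_id`, `role`, `alt`, `chosen` plus numeric
#' attribute columns; validation (one chosen alternative per task, two
#' alternatives, numeric attributes) reports the offending task or column.
#'
#' @param path CSV of choices, or a directory containing `choices.csv` and
#'   optionally `covariates.csv` and `provenance.json`.
#' @param covariates Optional path to a covariate CSV (ignored when `path`
#'   is a directory providing one).
#' @return A [choice_dataset()].
#' @export
read_choice_data <- function(path, covariates = NULL) {
  prov <- NULL
  if (dir.exists(path)) {
    cov_path <- file.path(path, "covariates.csv")
    prov_path <- file.path(path, "provenance.json")
    if (file.exists(prov_path))
      prov <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
    covariates <- if (file.exists(cov_path)) cov_path else NULL
    path <- file.path(path, "choices.csv")
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ch <- utils::read.csv(path, stringsAsFactors = FALSE)
  cov <- if (!is.null(covariates))
    utils::read.csv(covariates, stringsAsFactors = FALSE)
  choice_dataset(ch, cov, provenance = prov)
}

#' Write a choice dataset as CSV plus a provenance sidecar
#'
#' @param data A [choice_dataset()].
#' @param dir Output directory (created if needed): writes `choices.csv`,
#'   `covariates.csv` (if present) and `provenance.json`.
#' @return `dir`, invisibly.
#' @export
write_choice_data <- function(data, dir) {
  stopifnot(inherits(data, "choice_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data$choices, file.path(dir, "choices.csv"),
                   row.names = FALSE)
  if (!is.null(data$covariates))
    utils::write.csv(data$covariates, file.path(dir, "covariates.csv"),
                     row.names = FALSE)
  prov <- data$provenance %||% list()
  prov$true_coefficients <- NULL  # matrices stay out of the sidecar
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full design-simulate-validate-fit-report pipeline
#'
#' Stages: build (or load) a design, simulate (or ingest) panel choices,
#' score response validity, fit the panel mixed logit, and compute the
#' report analytics. Every artifact is written under `out_dir` together
#' with a manifest embedding the seed and a hash of the configuration;
#' a re-run with an identical configuration and seed reproduces every
#' artifact byte-for-byte, while a re-run with a different configuration
#' into the same directory refuses to overwrite unless `overwrite = TRUE`.
#'
#' @param config List with elements `seed` (required), `out_dir` (required),
#'   and optionally `n_respondents` (default 161), `n_draws` (default 200),
#'   `draw_type`, `data_dir` (ingest instead of simulate), `overwrite`.
#' @return Invisibly, a list with the design, dataset, validity report, fit
#'   and report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$seed) || is.null(config$out_dir))
    stop("configuration error: `seed` and `out_dir` are required",
         call. = FALSE)
  seed <- as.integer(config$seed)
  out <- config$out_dir
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  hash <- config_hash(cfg_for_hash)
  manifest_path <- file.path(out, "manifest.json")
  if (file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (!identical(prev$config_hash, hash) && !isTRUE(config$overwrite))
      stop("out_dir holds artifacts from a different configuration (hash ",
           prev$config_hash, " != ", hash, "); set overwrite = TRUE",
           call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[pipeline] ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  preset <- stage("design", {
    p <- study_emulation_preset(seed)
    design_to_json(p$design, file.path(out, "design.json"))
    p
  })
  design <- preset$design
  pop <- preset$pop

  data <- stage("simulate", {
    if (!is.null(config$data_dir)) read_choice_data(config$data_dir)
    else {
      n <- as.integer(config$n_respondents %||% pop$n_respondents)
      ds <- simulate_study(pop, design, n = n, seed = seed)
      write_choice_data(ds, file.path(out, "data"))
      ds
    }
  })

  validity <- stage("validate", {
    v <- validity_report(data, design)
    jsonlite::write_json(
      list(monotonicity_pass_rate = v$monotonicity_pass_rate,
           repeat_pass_rate = v$repeat_pass_rate, kappa = v$kappa,
           seed = seed, config_hash = hash),
      file.path(out, "validity.json"), auto_unbox = TRUE, digits = NA)
    v
  })

  fit <- stage("fit", {
    spec <- mixed_logit_spec(
      attributes = names(design$factors),
      mixing = c(side_effect_severity = "normal", future_risk = "normal",
                 symptom_frequency = "normal", death_risk = "normal",
                 cost = "triangular"),
      include_asc = TRUE,
      n_draws = as.integer(config$n_draws %||% 200L),
      draw_type = config$draw_type %||% "halton",
      seed = seed)
    spec <- add_interactions(spec, data, list(c("cost", "PHI")))
    f <- fit_mixed_logit(spec, data)
    jsonlite::write_json(
      list(coefficients = coef_table(f), loglik = f$loglik,
           converged = f$converged, n_parameters = f$n_parameters,
           n_respondents = f$n_respondents,
           draw_settings = f$draw_settings,
           seed = seed, config_hash = hash),
      file.path(out, "fit.json"), auto_unbox = TRUE, digits = NA)
    f
  })

  report <- stage("report", {
    ranges <- design_ranges(design)
    stats <- fit_statistics(fit, data)
    hr <- hit_rate(fit, data)
    imp <- relative_importance(fit, ranges)
    cond <- conditional_individual_coefficients(fit, data)
    hb_factors <- unlist(medication_harm_benefit_groups())
    ind <- relative_importance(cond, ranges[hb_factors])
    hb <- classify_harm_benefit(ind$importance,
                                medication_harm_benefit_groups())
    tr <- tradeoff(fit, "regimen", -3, "future_risk")
    rep <- list(fit_statistics = stats, hit_rate = hr,
                importance = imp, harm_benefit = hb,
                tradeoff_regimen_vs_future_risk =
                  list(delta_u = tr$delta_u,
                       compensating_move = tr$compensating_move),
                seed = seed, config_hash = hash)
    jsonlite::write_json(rep, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })

  jsonlite::write_json(list(seed = seed, config_hash = hash,
                            package_version =
                              as.character(utils::packageVersion("dcemix"))),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(design = design, data = data, validity = validity,
                 fit = fit, report = report))
}
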