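#' Run the trajectory-analysis pipeline
#'
#' Chains the pipeline stages over a configuration: `simulate` (or load
#' existing tables), `cohort`, `classify`, `tabulate`, `fit-msm`, `score`,
#' `fit-regression`, or `all`. Each stage writes its module's CSV outputs
#' into `outdir` and appends a manifest line (file, rows, md5 checksum) to
#' `run.log`; later stages read the earlier stages' files, so running a
#' stage whose inputs are missing is an error naming the stage to run
#' first. All randomness flows from the configuration seed (no wall-clock
#' seeding) and the log carries no timestamps, so identical configuration
#' and seed give byte-identical output trees.
#'
#' @param config either a [sim_config()] (simulated input) or a list with
#'   `patients_path` and `dispensings_path` pointing at delimited tables,
#'   optionally `cohort` (a [cohort_config()]), `window_days`,
#'   `risk_coefficients`, `boot_draws`.
#' @param outdir output directory.
#' @param stage one of `"simulate"`, `"cohort"`, `"classify"`,
#'   `"tabulate"`, `"fit-msm"`, `"score"`, `"fit-regression"`, `"all"`.
#' @param seed optional override of the configuration seed.
#' @return invisibly, the paths written by the requested stage(s).
#' @export
run_pipeline <- function(config, outdir, stage = "all", seed = NULL) {
  stages <- c("simulate", "cohort", "classify", "tabulate", "fit-msm",
              "score", "fit-regression")
  stage <- match.arg(stage, c(stages, "all"))
  todo <- if (stage == "all") stages else stage
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  is_sim <- inherits(config, "sim_config")
  if (!is.null(seed) && is_sim) config$seed <- as.integer(seed)
  ccfg <- if (is_sim) cohort_config() else (config$cohort %||% cohort_config())
  window_days <- if (is_sim) 45 else (config$window_days %||% 45)
  coefs <- if (is_sim) config$risk_coefficients
           else (config$risk_coefficients %||% risk_coefficients_default())
  written <- character(0)

  path <- function(f) file.path(outdir, f)
  log_lines <- character(0)
  manifest <- function(f) {
    n <- length(readLines(path(f), warn = FALSE)) - 1L
    log_lines <<- c(log_lines,
                    sprintf("wrote %s rows=%d md5=%s", f, n,
                            unname(tools::md5sum(path(f)))))
    written <<- c(written, path(f))
  }
  need <- function(f, prior) {
    if (!file.exists(path(f)))
      stop(sprintf("missing %s: run stage '%s' first", f, prior), call. = FALSE)
    utils::read.csv(path(f), stringsAsFactors = FALSE)
  }

  if ("simulate" %in% todo) {
    if (!is_sim) stop("stage 'simulate' needs a sim_config configuration")
    sim <- simulate_population(config)
    write_sim(sim, outdir)
    for (f in c("patients.csv", "dispensings.csv", "latent_states.csv"))
      manifest(f)
    log_lines <- c(log_lines, sprintf("seed=%d n_patients=%d",
                                      config$seed, config$n_patients))
  }

  if ("cohort" %in% todo) {
    if (is_sim || is.null(config$patients_path)) {
      patients <- need("patients.csv", "simulate")
      disp <- need("dispensings.csv", "simulate")
    } else {
      patients <- utils::read.csv(config$patients_path, stringsAsFactors = FALSE)
      disp <- utils::read.csv(config$dispensings_path, stringsAsFactors = FALSE)
    }
    sel <- select_cohort(patients, disp, ccfg)
    utils::write.csv(sel$members, path("cohort.csv"), row.names = FALSE)
    flow <- data.frame(step = names(sel$flow), count = as.integer(sel$flow))
    utils::write.csv(flow, path("cohort_flow.csv"), row.names = FALSE)
    manifest("cohort.csv"); manifest("cohort_flow.csv")
  }

  if ("classify" %in% todo) {
    members <- need("cohort.csv", "cohort")
    disp <- need("dispensings.csv", "simulate (or cohort inputs)")
    events <- annual_states_all(members, disp, window_days = window_days)
    utils::write.csv(events, path("events.csv"), row.names = FALSE)
    net <- net_outcomes_all(members, disp, window_days = window_days)
    utils::write.csv(net, path("net_outcomes.csv"), row.names = FALSE)
    manifest("events.csv"); manifest("net_outcomes.csv")
  }

  if ("tabulate" %in% todo) {
    events <- need("events.csv", "classify")
    members <- need("cohort.csv", "cohort")
    tt <- transition_tables(events)
    utils::write.csv(transition_tables_df(tt), path("transition_tables.csv"),
                     row.names = FALSE)
    utils::write.csv(pooled_subtypes(events), path("pooled_subtypes.csv"),
                     row.names = FALSE)
    utils::write.csv(stratified_rates(events, members),
                     path("stratified_rates.csv"), row.names = FALSE)
    manifest("transition_tables.csv"); manifest("pooled_subtypes.csv")
    manifest("stratified_rates.csv")
  }

  if ("fit-msm" %in% todo) {
    events <- need("events.csv", "classify")
    panel <- events_to_panel(events)
    bd <- if (is_sim) 500 else (config$boot_draws %||% 500)
    sd0 <- if (is_sim) config$seed else (config$seed %||% 1L)
    fit <- fit_msm(panel, boot_draws = bd, seed = sd0)
    utils::write.csv(summary(fit)$table, path("msm_probabilities.csv"),
                     row.names = FALSE)
    utils::write.csv(goodness_of_fit(fit), path("msm_gof.csv"),
                     row.names = FALSE)
    manifest("msm_probabilities.csv"); manifest("msm_gof.csv")
  }

  if ("score" %in% todo) {
    members <- need("cohort.csv", "cohort")
    disp <- need("dispensings.csv", "simulate (or cohort inputs)")
    prof <- build_profiles(members, disp, window_days = window_days)
    sc <- risk_score(prof, coefs)
    utils::write.csv(sc[, c("patient_id", "score", "category")],
                     path("risk_scores.csv"), row.names = FALSE)
    manifest("risk_scores.csv")
  }

  if ("fit-regression" %in% todo) {
    members <- need("cohort.csv", "cohort")
    net <- need("net_outcomes.csv", "classify")
    sc <- need("risk_scores.csv", "score")
    design <- build_design(members, net, sc)
    if (nlevels(droplevels(design$outcome)) < 2) {
      warning("all patients share one outcome category; no regression fitted")
      out <- data.frame(model = integer(0), outcome = character(0),
                        term = character(0), or = numeric(0),
                        ci_low = numeric(0), ci_high = numeric(0),
                        p_value = numeric(0), significant = logical(0))
    } else {
      out <- do.call(rbind, lapply(1:2, function(m) {
        tab <- or_table(fit_outcome_model(design, model = m))
        cbind(model = m, tab)
      }))
    }
    utils::write.csv(out, path("odds_ratios.csv"), row.names = FALSE)
    manifest("odds_ratios.csv")
  }

  cat(log_lines, sep = "\n", file = path("run.log"), append = TRUE)
  cat("\n", file = path("run.log"), append = TRUE)
  invisible(written)
}

# long-format CSV rendering of transition tables
transition_tables_df <- function(tt) {
  do.call(rbind, lapply(tt$periods, function(p) {
    cnt <- p$counts
    rows <- data.frame(period = p$interval,
                       from = rep(rownames(cnt), ncol(cnt)),
                       to = rep(colnames(cnt), each = nrow(cnt)),
                       count = as.integer(cnt))
    sub <- data.frame(period = p$interval, from = "SUBTOTAL",
                      to = tt$states, count = p$subtotals)
    sub$pct <- p$subtotal_pct
    rows$pct <- NA_real_
    rbind(rows, sub)
  }))
}

#' Convert an events table to an annual state panel
#'
#' @param events events table from [annual_states_all()] (five rows per
#'   patient; patients with any other number of rows are an error, named).
#' @return character matrix (patients x 5) of states, suitable for
#'   [fit_msm()].
#' @export
events_to_panel <- function(events) {
  ev <- events[order(events$patient_id, events$interval), ]
  cnt <- table(ev$patient_id)
  bad <- names(cnt)[cnt != 5]
  if (length(bad))
    stop("patients without exactly 5 interval states: ",
         paste(utils::head(bad, 5), collapse = ", "))
  ids <- unique(ev$patient_id)
  matrix(ev$state, ncol = 5, byrow = TRUE,
         dimnames = list(ids, paste0("year", 1:5)))
}

#' Read a pipeline configuration from YAML
#'
#' A configuration file contains either a `simulate:` section (fields of
#' [sim_config()]) or `patients_path`/`dispensings_path`, plus optional
#' `cohort:` (fields of [cohort_config()]), `window_days`, `boot_draws`
#' and `risk_coefficients_path` entries.
#'
#' @param path YAML file.
#' @return a configuration usable by [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    args <- y$simulate
    for (f in c("start_date", "end_date", "index_window_start",
                "index_window_end"))
      if (!is.null(args[[f]])) args[[f]] <- as.Date(args[[f]])
    if (!is.null(args$annual_change_rates))
      args$annual_change_rates <- unlist(args$annual_change_rates)
    if (!is.null(args$refill_interval_days))
      args$refill_interval_days <- unlist(args$refill_interval_days)
    if (!is.null(args$age_distribution))
      args$age_distribution <- unlist(args$age_distribution)
    if (!is.null(args$initial_regimen_probs))
      args$initial_regimen_probs <- unlist(args$initial_regimen_probs)
    return(do.call(sim_config, args))
  }
  if (is.null(y$patients_path) || is.null(y$dispensings_path))
    stop_cfg("config", "needs either a 'simulate' section or input paths")
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_config, y$cohort)
  if (!is.null(y$risk_coefficients_path))
    y$risk_coefficients <- risk_coefficients_default(y$risk_coefficients_path)
  y
}
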