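#' Run the serial-validation pipeline end to end
#'
#' Orchestrates the stages in dependency order — `simulate` (or load a
#' cohort from CSV), `impute` (LOCF + multiple imputation), `evaluate`
#' (consecutive prediction), `metrics` (daily AUCs and likelihood ratios),
#' `dca` (decision curves on selected days), `transitions` (state flows,
#' Sankey export, episode summaries) and `report` — writing every artifact
#' plus a provenance manifest into `out_dir`. All randomness flows from one
#' root seed via fixed per-stage offsets (simulate = seed, impute =
#' seed + 1, bootstrap = seed + 2), so identical config + seed gives
#' byte-identical outputs.
#'
#' @param config A list (or path to a YAML/JSON file) with elements:
#'   `stages` (subset of the above; default all), `seed`, `out_dir`,
#'   `sim` (arguments for [sim_config()], used by the simulate stage),
#'   `cohort` (list with `measurements`/`patients` paths, alternative to
#'   simulate), `model` (`"truth"` or a model-spec file path), `m`
#'   (imputations; 0 disables the impute stage even if listed), `horizon`,
#'   `bootstrap_B`, `dca_days` (default `c(0, 4, 8, 13)`).
#' @param quiet Suppress stage progress messages.
#' @return A `run_manifest`: list with `config`, `seed`, `outputs` (tibble
#'   `file`, `md5`), `results` (the in-memory stage results).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  all_stages <- c("simulate", "impute", "evaluate", "metrics", "dca",
                  "transitions", "report")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("serialrisk_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  horizon <- config$horizon %||% 14L
  dca_days <- config$dca_days %||% c(0L, 4L, 8L, 13L)
  say <- function(...) if (!quiet) message("[serialrisk] ", ...)
  res <- list()
  outputs <- character()
  emit <- function(x, file, writer = readr::write_tsv) {
    path <- file.path(out_dir, file)
    writer(x, path)
    outputs <<- c(outputs, path)
    path
  }

  # --- simulate / load ------------------------------------------------
  truth_model <- NULL
  if ("simulate" %in% stages) {
    say("simulate")
    sim_args <- config$sim %||% list()
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    sim <- generate_cohort(cfg)
    res$sim <- sim
    cohort <- sim$cohort
    truth_model <- cfg$truth_model
    paths <- write_cohort(cohort, out_dir)
    outputs <- c(outputs, unname(paths))
    emit(sim$truth, "truth.csv", readr::write_csv)
    emit(summarize_cohort(cohort)$daily, "daily_counts.tsv")
  } else if (!is.null(config$cohort)) {
    say("load cohort")
    cohort <- read_cohort(config$cohort$measurements, config$cohort$patients)
  } else {
    abort("config must request the simulate stage or name cohort CSVs")
  }
  res$cohort <- cohort

  # --- impute ---------------------------------------------------------
  m <- config$m %||% 20L
  eval_input <- cohort
  if ("impute" %in% stages && m >= 1) {
    say("impute (LOCF + m = ", m, ")")
    filled <- locf_fill(cohort)
    eval_input <- multiple_impute(filled, m = m, seed = seed + 1L)
    res$imputation <- eval_input
  }

  # --- evaluate -------------------------------------------------------
  model <- if (is.null(config$model) || identical(config$model, "truth")) {
    truth_model %||% abort("no model: simulate stage absent and config$model unset")
  } else if (is.character(config$model)) {
    load_model_spec(config$model, schema = cohort$schema)
  } else {
    config$model
  }
  scheme <- config$scheme %||% stratification_scheme()
  pred <- NULL
  if ("evaluate" %in% stages) {
    say("evaluate (consecutive prediction, ", horizon, " days)")
    pred <- run_consecutive_prediction(eval_input, model, scheme,
                                       horizon = horizon)
    res$predictions <- pred
    emit(pred$predictions, "daily_predictions.tsv")
    emit(pred$dropped, "risk_set_log.tsv")
    emit(mean_trajectories(pred, cohort), "trajectories.tsv")
  }
  need_pred <- function(stage) {
    if (is.null(pred)) abort(paste0("stage '", stage,
                                    "' requires the evaluate stage"))
  }

  # --- metrics --------------------------------------------------------
  if ("metrics" %in% stages) {
    need_pred("metrics")
    say("metrics")
    dm <- daily_metrics(pred, B = config$bootstrap_B %||% 500L,
                        seed = seed + 2L)
    res$metrics <- dm
    emit(format_metrics_tsv(dm), "daily_metrics.tsv")
  }

  # --- decision curves ------------------------------------------------
  if ("dca" %in% stages) {
    need_pred("dca")
    say("decision curves, days ", paste(dca_days, collapse = ", "))
    dca <- purrr::map_dfr(dca_days, function(d) {
      pd <- dplyr::filter(pred$predictions, .data$day == d, .data$.imp == 1L)
      if (!nrow(pd) || !any(pd$label == 1) || !any(pd$label == 0)) {
        return(NULL)
      }
      decision_curve(pd$probability, pd$label, scheme, day = d)
    })
    res$dca <- dca
    emit(dca, "decision_curves.tsv")
  }

  # --- transitions ----------------------------------------------------
  if ("transitions" %in% stages) {
    need_pred("transitions")
    say("transitions")
    seqs <- assign_daily_states(pred, cohort)
    flow <- build_flow_table(seqs)
    res$flow <- flow
    episodes <- purrr::map_dfr(scheme$labels, function(g) {
      group_episode_summary(seqs, cohort, g)
    })
    res$episodes <- episodes
    emit(flow$occupancy, "occupancy.tsv")
    emit(episodes, "episodes.tsv")
    sankey_path <- file.path(out_dir, "sankey.json")
    export_sankey(flow, sankey_path)
    outputs <- c(outputs, sankey_path)
  }

  # --- report / manifest ----------------------------------------------
  manifest <- list(
    package = "serialrisk",
    version = as.character(utils::packageVersion("serialrisk")),
    seed = seed,
    stages = stages,
    config = config[setdiff(names(config), c("sim", "out_dir"))],
    model = if (inherits(model, "logistic_model_spec")) {
      list(label = model$label, intercept = model$intercept,
           n_terms = length(model$terms))
    } else "function",
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  structure(list(
    config = config, seed = seed, out_dir = out_dir,
    outputs = tibble::tibble(
      file = basename(c(outputs, manifest_path)),
      md5 = unname(tools::md5sum(c(outputs, manifest_path)))
    ),
    results = res
  ), class = "run_manifest")
}

# Inf -> "Inf", NA -> "NA" in the LR columns, matching the conventional
# table notation; numeric elsewhere
format_metrics_tsv <- function(dm) {
  out <- tibble::as_tibble(dm)
  lr_cols <- grep("^lr_", names(out), value = TRUE)
  for (cl in lr_cols) {
    out[[cl]] <- ifelse(is.infinite(out[[cl]]), "Inf",
                        ifelse(is.na(out[[cl]]), "NA",
                               format(out[[cl]], digits = 6, trim = TRUE)))
  }
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "->", x$out_dir, "\n")
  print(x$outputs)
  invisible(x)
}
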