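## Allowed configuration schema: top-level keys and per-section keys.
config_schema <- function() {
  list(
    seed = NULL, output_dir = NULL, stages = NULL, log_level = NULL,
    window = c("t_start", "t_max"),
    input = c("study_table", "adoption_table"),
    simulation = c("n_diseases", "edge_density", "lambda_low", "lambda_high",
                   "drugs_per_year", "year_span", "alpha_low", "alpha_high",
                   "beta_low", "beta_high"),
    accumulation = c("mode", "aggregator", "min_age"),
    taxonomy = c("min_drugs", "distance"),
    propagation = c("model", "t_cut")
  )
}

#' Validate a pipeline configuration
#'
#' Schema check without execution: unknown keys are rejected with their
#' location, and basic types are verified (`seed` must be an integer,
#' `stages` a character vector of known stage names, window bounds numeric).
#'
#' @param config Path to a YAML file, or an already-parsed list.
#' @return A character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      return(sprintf("config file not found: %s", config))
    }
    config <- tryCatch(yaml::read_yaml(config), error = function(e) e)
    if (inherits(config, "error")) {
      return(sprintf("config parse error: %s", conditionMessage(config)))
    }
  }
  if (!is.list(config)) return("config must be a mapping")
  schema <- config_schema()
  problems <- character(0)
  for (key in names(config)) {
    if (!key %in% names(schema)) {
      problems <- c(problems, sprintf("unknown key: %s", key))
      next
    }
    allowed <- schema[[key]]
    if (!is.null(allowed) && is.list(config[[key]])) {
      bad <- setdiff(names(config[[key]]), allowed)
      for (b in bad) {
        problems <- c(problems, sprintf("unknown key: %s$%s", key, b))
      }
    }
  }
  if (!is.null(config$seed)) {
    s <- config$seed
    if (!is.numeric(s) || length(s) != 1L || s != floor(s)) {
      problems <- c(problems, "seed must be a single integer")
    }
  }
  if (!is.null(config$stages)) {
    known <- c("simulate", "accumulate", "taxonomy", "network")
    bad <- setdiff(config$stages, known)
    if (length(bad) > 0L) {
      problems <- c(problems, sprintf("unknown stage(s): %s",
                                      paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(config$window)) {
    w <- config$window
    if (!is.numeric(w$t_start %||% 0) || !is.numeric(w$t_max %||% 1)) {
      problems <- c(problems, "window$t_start and window$t_max must be numeric")
    } else if (!is.null(w$t_start) && !is.null(w$t_max) &&
               w$t_start >= w$t_max) {
      problems <- c(problems, "window$t_start must be < window$t_max")
    }
  }
  for (p in c("study_table", "adoption_table")) {
    path <- config$input[[p]]
    if (!is.null(path) && !file.exists(path)) {
      problems <- c(problems, sprintf("input$%s does not exist: %s", p, path))
    }
  }
  problems
}

## Per-stage seed derivation: global seed plus a stage-name character hash,
## so adding or removing a stage never perturbs the others' streams.
stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 131L) %% .Machine$integer.max
}

pipeline_log <- function(level, active, fmt, ...) {
  if (!active) return(invisible())
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the file-based analysis pipeline
#'
#' Executes the requested stages in dependency order — `simulate` (or load
#' the configured input tables), `accumulate`, `taxonomy`, `network` — and
#' writes every artifact into `output_dir` together with a
#' `manifest.tsv` listing each output file and its MD5 hash. Identical
#' configuration and seed yield byte-identical artifacts and manifest.
#'
#' @param config Path to a YAML file or an equivalent list. Recognized keys:
#'   `seed`, `output_dir`, `stages` (subset of simulate / accumulate /
#'   taxonomy / network), `window` (`t_start`, `t_max`), `input`
#'   (`study_table`, `adoption_table` TSV paths, used when `simulate` is not
#'   among the stages), and parameter blocks `simulation`, `accumulation`,
#'   `taxonomy`, `propagation`.
#' @return Invisibly, a list with `manifest` (data.frame of file, md5) and
#'   `output_dir`. Any stage failure aborts with an error naming the stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    problems <- validate_config(config)
    if (length(problems) > 0L) {
      stop(paste(c("invalid config:", problems), collapse = "\n  "),
           call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  } else {
    problems <- validate_config(config)
    if (length(problems) > 0L) {
      stop(paste(c("invalid config:", problems), collapse = "\n  "),
           call. = FALSE)
    }
  }

  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir %||% "."
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create output directory: %s", out_dir),
         call. = FALSE)
  }
  stages <- config$stages %||% c("simulate", "accumulate", "taxonomy",
                                 "network")
  verbose <- !identical(config$log_level, "quiet")
  window <- observation_window(config$window$t_start %||% 1900,
                               config$window$t_max %||% 2010.999)

  outputs <- character(0)
  emit <- function(path) outputs[length(outputs) + 1L] <<- path

  run_stage <- function(name, fun) {
    pipeline_log("info", verbose, "stage %s: start", name)
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  studies <- NULL
  adoptions <- NULL

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim_args <- config$simulation %||% list()
      if (!is.null(sim_args$year_span)) {
        sim_args$year_span <- as.numeric(sim_args$year_span)
      }
      sim_args$window <- window
      sim_args$rng_seed <- stage_seed(seed, "simulate")
      cfg <- do.call(simulation_config, sim_args)
      sim <- simulate_dataset(cfg)
      studies <<- sim$studies
      adoptions <<- sim$adoptions
      emit(write_study_table(sim$studies, file.path(out_dir, "studies.tsv")))
      emit(write_adoption_table(sim$adoptions,
                                file.path(out_dir, "adoptions.tsv")))
      gt <- write_ground_truth(sim$ground_truth,
                               file.path(out_dir, "ground_truth_rates.tsv"),
                               file.path(out_dir, "ground_truth_drugs.tsv"))
      for (p in gt) emit(p)
    })
  } else {
    run_stage("load", function() {
      sp <- config$input$study_table
      ap <- config$input$adoption_table
      if (is.null(sp) && is.null(ap)) {
        stop("no input tables configured and 'simulate' not requested")
      }
      if (!is.null(sp)) {
        studies <<- read_study_table(sp, window)
        if (is.null(ap)) adoptions <<- derive_adoptions(studies)
      }
      if (!is.null(ap)) adoptions <<- read_adoption_table(ap, window)
    })
  }

  if ("accumulate" %in% stages) {
    run_stage("accumulate", function() {
      if (is.null(studies)) stop("accumulate requires a study table")
      acc <- config$accumulation %||% list()
      ratio <- studies_per_drug_by_year(studies)
      emit(write_tsv(ratio, file.path(out_dir, "studies_per_drug.tsv")))
      curve <- aligned_curve(studies, mode = acc$mode %||% "studies",
                             aggregator = acc$aggregator %||% "mean",
                             window = window)
      emit(write_tsv(as.data.frame(curve),
                     file.path(out_dir, "aligned_curve.tsv")))
      fit <- fit_power_law(curve, min_age = acc$min_age %||% 1)
      fit_df <- data.frame(alpha = fit$alpha, beta = fit$beta,
                           r_squared = fit$r_squared,
                           age_min = fit$ages_used[1L],
                           age_max = fit$ages_used[2L])
      emit(write_tsv(fit_df, file.path(out_dir, "power_law_fit.tsv")))
    })
  }

  if ("taxonomy" %in% stages) {
    run_stage("taxonomy", function() {
      if (is.null(adoptions)) stop("taxonomy requires an adoption table")
      tx <- config$taxonomy %||% list()
      sets <- build_drug_sets(adoptions, min_drugs = tx$min_drugs %||% 5)
      m <- mi_matrix(sets)
      mi_df <- data.frame(disease_id = rownames(m), m, check.names = FALSE)
      emit(write_tsv(mi_df, file.path(out_dir, "mi_similarity.tsv")))
      d <- mi_to_distance(m, method = tx$distance %||% "imax_minus_i")
      if (nrow(d) >= 2L) {
        hc <- ward_cluster(d)
        nwk <- file.path(out_dir, "taxonomy.nwk")
        export_newick(hc, nwk)
        emit(nwk)
      }
      emit(write_tsv(exclusivity(sets),
                     file.path(out_dir, "exclusivity.tsv")))
    })
  }

  if ("network" %in% stages) {
    run_stage("network", function() {
      if (is.null(adoptions)) stop("network requires an adoption table")
      pr <- config$propagation %||% list()
      est <- infer_network(adoptions, window,
                           model = pr$model %||% "pairwise")
      emit(write_tsv(est, file.path(out_dir, "network_edges.tsv")))
      g <- build_network(est, t_cut = pr$t_cut %||% 100)
      emit(write_tsv(path_metrics(g), file.path(out_dir, "path_metrics.tsv")))
    })
  }

  outputs <- sort(unique(outputs))
  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  pipeline_log("info", verbose, "pipeline complete: %d artifact(s) in %s",
               nrow(manifest), out_dir)
  invisible(list(manifest = manifest, output_dir = out_dir))
}
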