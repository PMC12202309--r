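# Data contracts and the reproducible pipeline.

conc_columns <- c("animal_id", "group", "arm", "compound", "matrix",
                  "time_h", "conc", "unit", "blq_flag")

#' Read and validate a long-format concentration table
#'
#' Reads the CSV interchange format (columns `animal_id`, `group`, `arm`,
#' `compound`, `matrix`, `time_h`, `conc`, `unit`, `blq_flag`) and validates
#' the schema: times nonnegative, concentrations nonnegative or flagged
#' below-limit, compounds in `parent`/`metabolite`, matrices in
#' `plasma`/`brain`, and `(animal, compound, matrix, time)` unique. Violations
#' raise errors naming the offending rows.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of concentration records.
#' @export
read_concentrations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_concentrations(df)
}

#' @rdname read_concentrations
#' @param data A data frame to validate in place.
#' @export
validate_concentrations <- function(data) {
  missing_cols <- setdiff(conc_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("concentration table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  data$blq_flag <- as.logical(data$blq_flag)
  rows <- function(idx) paste(which(idx), collapse = ", ")

  bad <- !is.finite(data$time_h) | data$time_h < 0
  if (any(bad)) {
    stop("nonnegative finite time_h required; offending rows: ", rows(bad),
         call. = FALSE)
  }
  bad <- !data$blq_flag & (is.na(data$conc) | data$conc < 0)
  if (any(bad)) {
    stop("conc must be >= 0 unless blq_flag is set; offending rows: ",
         rows(bad), call. = FALSE)
  }
  bad <- !data$compound %in% c("parent", "metabolite")
  if (any(bad)) {
    stop("compound must be 'parent' or 'metabolite'; offending rows: ",
         rows(bad), call. = FALSE)
  }
  bad <- !data$matrix %in% c("plasma", "brain")
  if (any(bad)) {
    stop("matrix must be 'plasma' or 'brain'; offending rows: ", rows(bad),
         call. = FALSE)
  }
  key <- paste(data$animal_id, data$compound, data$matrix, data$time_h)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicated (animal, compound, matrix, time) records at rows: ",
         rows(dup), call. = FALSE)
  }
  data
}

#' Write a concentration table
#'
#' @param data A validated concentration table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(data, path) {
  validate_concentrations(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes a subset of the stages `simulate`, `nca`, `binding`, `fit`,
#' `contrast`, `expression` in order, writing each stage's output as CSV (or
#' JSON for fits) into `out_dir`, followed by a `manifest.json` recording the
#' configuration snapshot, the seed, input/output file hashes (MD5),
#' package version, per-stage timing and status. Re-running with the same
#' configuration and seed reproduces all stochastic outputs exactly. A stage
#' failure retains partial outputs, writes the manifest with
#' `status: "failed"`, and then re-raises the error.
#'
#' @param config A named list. Recognized entries: `stages` (character vector,
#'   any subset of the stage names above, in order); `design` (a
#'   [study_design()], default [default_study_design()]); `group_medians`
#'   (named list of [pk_parameters()], default the two [default_parameters()]
#'   sets); `variability` (a [variability_model()]); `nca` (list of arguments
#'   for [nca()]: `t_last`, `B`, ...); `dialysis` (data frame for
#'   [dialysis_fu()]); `ct_data` plus `calibrator` (for [ddct()]);
#'   `fit` (list with `init` and optional [fit_spec()] arguments);
#'   `contrast_params` (character vector of parameter names).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest and used by every
#'   stochastic stage.
#' @return Invisibly, a list of stage outputs plus the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  stages <- config$stages %||% character(0)
  known <- c("simulate", "nca", "binding", "fit", "contrast", "expression")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "),
                            call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package = "olzpk",
    version = as.character(utils::packageVersion("olzpk")),
    seed = seed,
    stages = as.list(stages),
    config_snapshot = config_snapshot(config),
    timing_s = list(), outputs = list(), status = "running"
  )
  outputs <- list()
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- fn()
    manifest$timing_s[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  record_output <- function(name, path) {
    manifest$outputs[[name]] <<-
      list(file = basename(path),
           md5 = unname(tools::md5sum(path)))
  }

  result <- tryCatch({
    records <- config$data
    for (stage in stages) {
      message("[olzpk] stage: ", stage)
      if (stage == "simulate") {
        outputs$simulate <- run_stage("simulate", function() {
          design <- config$design %||% default_study_design()
          med <- config$group_medians %||%
            list(control = default_parameters("control"),
                 lps = default_parameters("lps"))
          v <- config$variability %||% variability_model()
          simulate_study(design, med, v, seed = seed)
        })
        records <- outputs$simulate
        path <- file.path(out_dir, "concentrations.csv")
        write_concentrations(records, path)
        record_output("simulate", path)
      } else if (stage == "nca") {
        if (is.null(records)) stop("nca stage needs simulated or input data",
                                   call. = FALSE)
        outputs$nca <- run_stage("nca", function() {
          args <- config$nca %||% list()
          do.call(nca, c(list(data = records, seed = seed), args))
        })
        path <- file.path(out_dir, "auc.csv")
        readr::write_csv(outputs$nca, path)
        record_output("nca", path)
      } else if (stage == "binding") {
        if (is.null(config$dialysis)) {
          stop("binding stage needs config$dialysis", call. = FALSE)
        }
        outputs$binding <- run_stage("binding", function() {
          dialysis_fu(config$dialysis)
        })
        path <- file.path(out_dir, "unbound_fractions.csv")
        readr::write_csv(outputs$binding, path)
        record_output("binding", path)
      } else if (stage == "fit") {
        if (is.null(records)) stop("fit stage needs data", call. = FALSE)
        fit_cfg <- config$fit %||% list()
        outputs$fit <- run_stage("fit", function() {
          groups <- unique(records$group)
          fits <- lapply(stats::setNames(groups, groups), function(g) {
            init <- fit_cfg$init %||% default_parameters(
              if (g %in% c("control", "lps")) g else "control")
            sp <- fit_spec(init,
                           n_starts = fit_cfg$n_starts %||% 8,
                           jitter_sd = fit_cfg$jitter_sd %||% 0.2,
                           seed = seed)
            fit_group(dplyr::filter(records, .data$group == g), sp)
          })
          fits
        })
        for (g in names(outputs$fit)) {
          path <- file.path(out_dir, paste0("fit_", g, ".json"))
          f <- outputs$fit[[g]]
          jsonlite::write_json(
            list(group = g, params = unclass(f$params),
                 derived = as.list(f$derived[1, ]),
                 objective = f$objective, sigma = f$sigma,
                 n_obs = f$n_obs, converged = f$converged, seed = seed),
            path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
          record_output(paste0("fit_", g), path)
        }
      } else if (stage == "contrast") {
        if (is.null(outputs$fit) || length(outputs$fit) < 2) {
          stop("contrast stage needs two fitted groups", call. = FALSE)
        }
        outputs$contrast <- run_stage("contrast", function() {
          params <- config$contrast_params %||%
            c("CL", "CL_dmo", "CL_parent_to_dmo", "F_po")
          gs <- names(outputs$fit)
          purrr::map_dfr(params, function(pp) {
            contrast_groups(outputs$fit[[gs[2]]], outputs$fit[[gs[1]]], pp)
          })
        })
        path <- file.path(out_dir, "contrasts.csv")
        readr::write_csv(outputs$contrast, path)
        record_output("contrast", path)
      } else if (stage == "expression") {
        if (is.null(config$ct_data)) {
          stop("expression stage needs config$ct_data", call. = FALSE)
        }
        outputs$expression <- run_stage("expression", function() {
          ddct(config$ct_data, calibrator = config$calibrator %||% "control")
        })
        path <- file.path(out_dir, "relative_expression.csv")
        readr::write_csv(outputs$expression, path)
        record_output("expression", path)
      }
    }
    manifest$status <- "ok"
    write_manifest()
    outputs$manifest <- manifest
    outputs
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop(e)
  })
  invisible(result)
}

# serializable snapshot of the config (objects reduced to their fields)
config_snapshot <- function(config) {
  strip <- function(x) {
    if (inherits(x, c("pk_parameters", "variability_model", "fit_spec",
                      "arm_design"))) {
      return(lapply(unclass(x), strip))
    }
    if (inherits(x, "study_design")) {
      return(list(groups = x$groups, lloq = as.list(x$lloq),
                  arms = lapply(x$arms, function(a) unclass(a)),
                  kp_brain = x$kp_brain))
    }
    if (is.data.frame(x)) return(list(data_frame_rows = nrow(x)))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(config)
}
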