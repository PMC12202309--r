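# Study design objects: dosing arms, sparse sampling schedules, group sizes,
# censoring limits, and the generator's brain:plasma partition fixtures.

#' Describe one dosing arm of a study
#'
#' @param arm Dosing arm label passed to [dose_event()].
#' @param dose Dose, mg/kg.
#' @param schedule Sampling times, h (sorted, nonnegative). For destructive
#'   sampling the schedule should include the predose time 0; predose records
#'   are structural zeros.
#' @param mode `"destructive"` (animals terminated at an assigned time, each
#'   contributing `samples_per_animal` samples, the last one terminal) or
#'   `"serial"` (each animal contributes `samples_per_animal` samples at an
#'   assigned time triplet; the last is terminal).
#' @param n_animals Animals per group in this arm.
#' @param samples_per_animal Samples per animal (2 for the destructive arm,
#'   3 for serial arms in the reference design).
#' @return A list of class `arm_design`.
#' @export
arm_design <- function(arm, dose, schedule,
                       mode = c("destructive", "serial"),
                       n_animals, samples_per_animal) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(schedule), !is.unsorted(schedule), all(schedule >= 0),
            !anyDuplicated(schedule), n_animals >= 1, samples_per_animal >= 1)
  n_slots <- n_animals * samples_per_animal
  if (n_slots < length(schedule)) {
    stop("arm '", arm, "': ", n_slots, " sample slots cannot cover ",
         length(schedule), " schedule times", call. = FALSE)
  }
  structure(
    list(arm = arm, dose = dose, schedule = schedule, mode = mode,
         n_animals = n_animals, samples_per_animal = samples_per_animal),
    class = "arm_design"
  )
}

#' Construct a study design
#'
#' A study design bundles the dosing arms (with their sampling schedules and
#' sampling modes), the group labels, the lower limits of quantification, and
#' the generator's true brain-to-plasma partition ratios. Brain is sampled at
#' each animal's terminal time only; plasma at every assigned time.
#'
#' @param arms Named list of [arm_design()] objects.
#' @param groups Character vector of group labels.
#' @param lloq Named numeric vector `c(plasma = ..., brain = ...)`: lower
#'   limits of quantification, ng/mL (plasma) and ng/g (brain).
#' @param kp_brain Generator truth for the brain:plasma concentration ratio,
#'   as a list with elements `parent` and `metabolite`, each a named numeric
#'   vector over groups. Brain is not a model compartment; simulated brain
#'   concentrations are plasma concentrations scaled by this ratio with
#'   independent residual error.
#' @return A list of class `study_design`.
#' @seealso [default_study_design()], [simulate_study()]
#' @export
study_design <- function(arms, groups, lloq = c(plasma = 0.2, brain = 0.2),
                         kp_brain = NULL) {
  stopifnot(is.list(arms), length(arms) >= 1, !is.null(names(arms)),
            is.character(groups), length(groups) >= 1,
            all(c("plasma", "brain") %in% names(lloq)))
  purrr::walk(arms, function(a) stopifnot(inherits(a, "arm_design")))
  if (is.null(kp_brain)) {
    kp_brain <- list(
      parent = stats::setNames(rep(5, length(groups)), groups),
      metabolite = stats::setNames(rep(0.05, length(groups)), groups)
    )
  }
  structure(list(arms = arms, groups = groups, lloq = lloq,
                 kp_brain = kp_brain),
            class = "study_design")
}

#' The reference two-group, three-arm endotoxemia design
#'
#' Reproduces the sparse sampling structure of the endotoxemia study this
#' package models: two groups (LPS-challenged, control); a 4 mg/kg oral
#' olanzapine arm with destructive sampling (18 animals per group, 3 animals
#' per time point at 12 time points: predose 0 and 0.25-24 h, two samples per
#' animal with the second terminal); and two IV arms (0.5 mg/kg olanzapine or
#' 0.5 mg/kg DMO, 10 animals per group) with serial sampling at 11 time
#' points from 3 min to 6 h, three samples per animal. Default LLOQ is
#' 0.2 ng/mL in plasma and 0.2 ng/g in brain (the brain detection limit);
#' default brain:plasma generator ratios are the fixture values discussed in
#' the methods vignette.
#'
#' @return A [study_design()] object.
#' @export
#' @examples
#' d <- default_study_design()
#' names(d$arms)
default_study_design <- function() {
  po_times <- c(0, 0.25, 0.5, 1, 2, 3, 4, 5, 6, 8, 10, 24)
  iv_times <- c(3 / 60, 5 / 60, 10 / 60, 20 / 60, 40 / 60, 1, 1.5, 2, 3, 4, 6)
  study_design(
    arms = list(
      PO_parent = arm_design("PO_parent", 4, po_times,
                             mode = "destructive", n_animals = 18,
                             samples_per_animal = 2),
      IV_parent = arm_design("IV_parent", 0.5, iv_times,
                             mode = "serial", n_animals = 10,
                             samples_per_animal = 3),
      IV_metabolite = arm_design("IV_metabolite", 0.5, iv_times,
                                 mode = "serial", n_animals = 10,
                                 samples_per_animal = 3)
    ),
    groups = c("control", "lps"),
    lloq = c(plasma = 0.2, brain = 0.2),
    kp_brain = list(
      parent = c(control = 6.3, lps = 8.5),
      metabolite = c(control = 0.077, lps = 0.039)
    )
  )
}

#' Between-animal and residual variability model
#'
#' @param bsv_cv Between-animal lognormal coefficient of variation, either a
#'   single value applied to every parameter or a named vector over parameter
#'   names. Fractions (`F_po_total`, `F_d`) are perturbed on the logit scale
#'   with this value as the logit-normal standard deviation, which preserves
#'   the median and keeps draws in (0, 1).
#' @param prop_cv Proportional residual error CV applied multiplicatively to
#'   every simulated concentration (mean-one lognormal, so observed
#'   concentrations are unbiased for the model prediction).
#' @param add_sd Optional additive error floor, ng/mL (default 0).
#' @return A list of class `variability_model`.
#' @export
variability_model <- function(bsv_cv = 0.25, prop_cv = 0.15, add_sd = 0) {
  stopifnot(all(bsv_cv >= 0), prop_cv >= 0, add_sd >= 0)
  structure(list(bsv_cv = bsv_cv, prop_cv = prop_cv, add_sd = add_sd),
            class = "variability_model")
}

# deterministic animal -> schedule assignment for one arm; returns a list of
# per-animal time vectors (the last entry is the terminal time)
assign_schedule <- function(arm) {
  times <- arm$schedule
  J <- length(times)
  n <- arm$n_animals
  k <- arm$samples_per_animal
  if (arm$mode == "destructive") {
    # pair early time j with late time j + J/2; terminal is the later time;
    # animals are filled 3-per-pair in schedule order
    if (k != 2 || J %% 2 != 0) {
      # general fallback: cycle times over animal slots
      return(assign_cycled(times, n, k))
    }
    half <- J / 2
    per_pair <- n / half
    if (per_pair != floor(per_pair)) return(assign_cycled(times, n, k))
    pairs <- lapply(seq_len(half), function(j) c(times[j], times[j + half]))
    rep(pairs, each = per_pair)
  } else {
    # serial: overlapping triplet patterns (1,2,3), (3,4,5), (5,6,7), ... so
    # consecutive patterns share a time and batches keep >= 2 animals
    if (k == 3 && J >= 5) {
      starts <- seq(1, by = 2, length.out = ceiling((J - 1) / 2))
      patterns <- lapply(starts, function(s) times[pmin(c(s, s + 1, s + 2), J)])
      patterns <- lapply(patterns, unique)
      patterns <- patterns[!duplicated(patterns)]
      idx <- rep(seq_along(patterns), length.out = n)
      lapply(idx, function(i) patterns[[i]])
    } else {
      assign_cycled(times, n, k)
    }
  }
}

assign_cycled <- function(times, n, k) {
  J <- length(times)
  lapply(seq_len(n), function(i) {
    sel <- sort(unique(((k * (i - 1)) + seq_len(k) - 1) %% J + 1))
    times[sel]
  })
}

#' Draw individual parameter sets around group medians
#'
#' Each positive parameter is drawn lognormally around the group median with
#' the model's between-animal CV (`meanlog = log(median)`, so the generating
#' median is preserved); the fractions `F_po_total` and `F_d` are drawn on the
#' logit scale. With all CVs zero every individual equals the median set.
#'
#' @param group_medians A [pk_parameters()] object of group-median values.
#' @param v A [variability_model()].
#' @param n Number of individuals.
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @return A tibble with one row per individual and one column per parameter,
#'   plus an `id` column.
#' @export
#' @examples
#' sample_individual_parameters(default_parameters("control"),
#'                              variability_model(bsv_cv = 0.3), n = 4,
#'                              seed = 1)
sample_individual_parameters <- function(group_medians, v, n, seed = NULL) {
  validate_pk_parameters(group_medians)
  stopifnot(inherits(v, "variability_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  nm <- pk_parameter_names()
  cv_for <- function(param) {
    if (length(v$bsv_cv) == 1 && is.null(names(v$bsv_cv))) return(v$bsv_cv)
    if (param %in% names(v$bsv_cv)) return(v$bsv_cv[[param]])
    0
  }
  draws <- purrr::map(nm, function(param) {
    med <- group_medians[[param]]
    cv <- cv_for(param)
    if (cv == 0) return(rep(med, n))
    if (param %in% c("F_po_total", "F_d")) {
      stats::plogis(stats::rnorm(n, stats::qlogis(med), cv))
    } else {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
    }
  })
  names(draws) <- nm
  out <- tibble::as_tibble(draws)
  # redraw any set violating the clearance-partition invariant (rare at
  # moderate CVs; keeps every returned individual a valid parameter set)
  bad <- which(out$CL / out$V1 < out$k_pm)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    for (param in c("CL", "k_pm")) {
      cv <- cv_for(param)
      if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        out[[param]][bad] <- stats::rlnorm(length(bad),
                                           log(group_medians[[param]]), sdlog)
      }
    }
    bad <- which(out$CL / out$V1 < out$k_pm)
    guard <- guard + 1
  }
  if (length(bad) > 0) {
    stop("could not draw parameter sets satisfying CL/V1 >= k_pm; ",
         "reduce the between-animal CV", call. = FALSE)
  }
  dplyr::bind_cols(tibble::tibble(id = seq_len(n)), out)
}

row_to_parameters <- function(row) {
  do.call(pk_parameters, as.list(row[pk_parameter_names()]))
}

#' Simulate a sparse-sampling study
#'
#' Generates a long-format concentration table with the structure of the
#' two-group, three-arm endotoxemia design: per animal, individual parameters
#' are drawn around the group medians, the compartmental model is solved, the
#' animal's assigned schedule is read off, multiplicative (mean-one lognormal)
#' proportional residual error is applied, and values below the LLOQ are
#' censored with a below-limit flag. Brain concentrations are generated at
#' each animal's terminal time as plasma concentration times the design's
#' true partition ratio, with independent residual error. Predose records
#' (time 0) are true zeros and are not flagged.
#'
#' Draw order is fixed and documented: groups in design order, arms in design
#' order within group, individual parameters before residual errors, plasma
#' errors before brain errors; the schedule assignment is deterministic. A
#' single seed therefore fixes the whole table.
#'
#' @param design A [study_design()].
#' @param group_medians Named list mapping each group label to a
#'   [pk_parameters()] object.
#' @param v A [variability_model()].
#' @param seed Integer seed governing all random draws.
#' @return A tibble of concentration records with columns `animal_id`,
#'   `group`, `arm`, `compound`, `matrix`, `time_h`, `conc`, `unit`,
#'   `blq_flag`. The per-animal generating parameters are attached as the
#'   `"params"` attribute (a tibble with `animal_id` and one column per
#'   parameter).
#' @export
#' @examples
#' des <- default_study_design()
#' med <- list(control = default_parameters("control"),
#'             lps = default_parameters("lps"))
#' sim <- simulate_study(des, med, variability_model(0.25, 0.15), seed = 7)
#' dplyr::count(sim, group, arm, compound, matrix)
simulate_study <- function(design, group_medians, v, seed) {
  stopifnot(inherits(design, "study_design"),
            inherits(v, "variability_model"),
            all(design$groups %in% names(group_medians)))
  set.seed(seed)
  sdlog_res <- sqrt(log(1 + v$prop_cv^2))

  all_records <- list()
  all_params <- list()
  for (grp in design$groups) {
    med <- group_medians[[grp]]
    for (arm_name in names(design$arms)) {
      arm <- design$arms[[arm_name]]
      pars <- sample_individual_parameters(med, v, arm$n_animals)
      schedules <- assign_schedule(arm)
      ids <- sprintf("%s_%s_%02d", grp, arm_name, seq_len(arm$n_animals))
      pars$animal_id <- ids
      all_params[[paste(grp, arm_name)]] <-
        dplyr::select(pars, "animal_id", dplyr::all_of(pk_parameter_names()))
      ev <- dose_event(arm$arm, arm$dose)
      for (i in seq_len(arm$n_animals)) {
        p_i <- row_to_parameters(pars[i, ])
        tms <- schedules[[i]]
        curve <- pk_solve(p_i, ev, tms)
        term_time <- max(tms)
        rec <- curve
        rec$animal_id <- ids[i]
        rec$group <- grp
        rec$arm <- arm_name
        rec$unit <- "ng/mL"
        # plasma residual error (skip structural zeros)
        pos <- rec$conc_ng_ml > 0
        err <- exp(stats::rnorm(nrow(rec), 0, sdlog_res) - sdlog_res^2 / 2)
        rec$conc <- rec$conc_ng_ml * ifelse(pos, err, 1)
        if (v$add_sd > 0) {
          rec$conc <- pmax(0, rec$conc + stats::rnorm(nrow(rec), 0, v$add_sd))
        }
        # terminal brain samples, one per compound
        brain_true <- curve[curve$time_h == term_time, ]
        kp <- vapply(brain_true$compound,
                     function(cmp) design$kp_brain[[cmp]][[grp]], numeric(1),
                     USE.NAMES = FALSE)
        berr <- exp(stats::rnorm(nrow(brain_true), 0, sdlog_res) -
                      sdlog_res^2 / 2)
        brec <- tibble::tibble(
          time_h = brain_true$time_h,
          compound = brain_true$compound,
          matrix = "brain",
          conc_ng_ml = brain_true$conc_ng_ml * kp,
          animal_id = ids[i], group = grp, arm = arm_name, unit = "ng/g",
          conc = brain_true$conc_ng_ml * kp *
            ifelse(brain_true$conc_ng_ml > 0, berr, 1)
        )
        all_records[[length(all_records) + 1]] <- dplyr::bind_rows(rec, brec)
      }
    }
  }
  out <- dplyr::bind_rows(all_records)
  lloq <- design$lloq[out$matrix]
  structural_zero <- out$time_h == 0 & out$conc_ng_ml == 0
  out$blq_flag <- !structural_zero & out$conc < lloq
  out$conc[out$blq_flag] <- NA_real_
  out$conc <- unname(out$conc)
  out$blq_flag <- unname(out$blq_flag)
  out <- dplyr::select(out, "animal_id", "group", "arm", "compound",
                       "matrix", "time_h", "conc", "unit", "blq_flag")
  attr(out, "params") <- dplyr::bind_rows(all_params)
  out
}
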