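# Pooled maximum-likelihood fitting of the joint model across dosing arms.
#
# The population machinery of nonlinear mixed-effects software is deliberately
# not reproduced: with <= 3 observations per animal the destructive design
# carries little individual-level information, so each group is fitted as a
# naive-pooled maximum-likelihood problem with lognormal residuals, which is
# reproducible and testable at desk scale. Uncertainty, when needed, comes
# from a nonparametric bootstrap over animals.

# internal parameterization: log scale for positive parameters, logit scale
# for the fractions; k_pm is carried as the metabolized fraction
# fm = k_pm * V1 / CL in (0, 1), which enforces CL / V1 >= k_pm by
# construction.
est_par_names <- function() {
  c("ka", "ka_dmo", "V1", "V2", "Q", "CL",
    "V1_dmo", "V2_dmo", "Q_dmo", "CL_dmo",
    "fm", "F_po_total", "F_d")
}

to_theta <- function(p) {
  fm <- p$k_pm * p$V1 / p$CL
  vals <- c(log(p$ka), log(p$ka_dmo), log(p$V1), log(p$V2), log(p$Q),
            log(p$CL), log(p$V1_dmo), log(p$V2_dmo), log(p$Q_dmo),
            log(p$CL_dmo),
            stats::qlogis(min(max(fm, 1e-8), 1 - 1e-8)),
            stats::qlogis(min(max(p$F_po_total, 1e-8), 1 - 1e-8)),
            stats::qlogis(min(max(p$F_d, 1e-8), 1 - 1e-8)))
  stats::setNames(vals, est_par_names())
}

from_theta <- function(theta) {
  g <- function(nm) unname(theta[nm])
  p <- list(
    ka = exp(g("ka")), ka_dmo = exp(g("ka_dmo")),
    V1 = exp(g("V1")), V2 = exp(g("V2")), Q = exp(g("Q")),
    CL = exp(g("CL")),
    V1_dmo = exp(g("V1_dmo")), V2_dmo = exp(g("V2_dmo")),
    Q_dmo = exp(g("Q_dmo")), CL_dmo = exp(g("CL_dmo")),
    F_po_total = stats::plogis(g("F_po_total")),
    F_d = stats::plogis(g("F_d"))
  )
  p$k_pm <- stats::plogis(g("fm")) * p$CL / p$V1
  p
}

# fast plasma-concentration predictor for the 6-state core system;
# arm_times: named list arm -> sorted unique times (> 0)
predict_arm_conc <- function(p, arm_times, arm_doses) {
  A <- pk_rate_matrix(p)[1:6, 1:6]
  out <- vector("list", length(arm_times))
  names(out) <- names(arm_times)
  for (arm in names(arm_times)) {
    s0 <- numeric(6)
    amt <- arm_doses[[arm]] * 1e6
    if (arm == "PO_parent") {
      s0[1] <- amt * p$F_po_total * p$F_d
      s0[4] <- amt * p$F_po_total * (1 - p$F_d)
    } else if (arm == "IV_parent") {
      s0[2] <- amt
    } else {
      s0[5] <- amt
    }
    st <- propagate_states(A, s0, arm_times[[arm]])
    out[[arm]] <- cbind(parent = st[, 2] / p$V1 / 1000,
                        metabolite = st[, 5] / p$V1_dmo / 1000)
  }
  out
}

#' Specify a pooled model fit
#'
#' @param init A [pk_parameters()] object of initial values (every free
#'   parameter needs one).
#' @param fixed Optional named list of parameters to hold at their initial
#'   value (natural scale); names from the parameter vector, plus `"fm"` for
#'   the metabolized fraction `k_pm * V1 / CL`.
#' @param n_starts Number of multistart optimizations (default 8): the first
#'   starts at `init`, the rest at lognormally/logit jittered copies.
#' @param jitter_sd Standard deviation of the jitter on the transformed scale
#'   (default 0.2).
#' @param seed Seed for the multistart jitter (default 1).
#' @param blq How below-limit records enter the likelihood: `"exclude"`
#'   (default) or `"half_lloq"` (requires `lloq`).
#' @param lloq LLOQ value(s) for `blq = "half_lloq"`.
#' @return A list of class `fit_spec`.
#' @export
fit_spec <- function(init, fixed = list(), n_starts = 8, jitter_sd = 0.2,
                     seed = 1, blq = c("exclude", "half_lloq"), lloq = NULL) {
  validate_pk_parameters(init)
  blq <- match.arg(blq)
  stopifnot(n_starts >= 1, jitter_sd >= 0,
            all(names(fixed) %in% est_par_names()))
  structure(list(init = init, fixed = fixed, n_starts = n_starts,
                 jitter_sd = jitter_sd, seed = seed, blq = blq, lloq = lloq),
            class = "fit_spec")
}

check_identifiability <- function(arms_present, free) {
  fail <- function(arm, pars) {
    pars <- intersect(pars, free)
    if (length(pars) > 0) {
      stop("under-identified fit: arm '", arm, "' is missing and parameters ",
           paste(pars, collapse = ", "),
           " cannot be separated from the remaining arms", call. = FALSE)
    }
  }
  if (!"IV_metabolite" %in% arms_present) {
    fail("IV_metabolite", c("CL_dmo", "V1_dmo", "V2_dmo", "Q_dmo"))
  }
  if (!"IV_parent" %in% arms_present) {
    fail("IV_parent", c("CL", "V1", "V2", "Q", "fm"))
  }
  if (!"PO_parent" %in% arms_present) {
    fail("PO_parent", c("ka", "ka_dmo", "F_po_total", "F_d"))
  }
}

#' Fit the joint model to one group by pooled maximum likelihood
#'
#' Maximizes the pooled lognormal likelihood of all quantifiable plasma
#' concentrations of one group across its dosing arms. With a shared residual
#' standard deviation the maximum-likelihood estimate minimizes the residual
#' sum of squares on the log scale, which is the objective reported.
#' Optimization runs `n_starts` times from jittered initials (L-BFGS-free
#' quasi-Newton via [stats::nlminb()] on log/logit-transformed parameters);
#' the best objective wins, with ties broken by distance to the initials.
#'
#' Identifiability requires the IV-metabolite arm (to pin the metabolite
#' disposition), the IV-parent arm (to separate clearance from
#' bioavailability) and the oral arm (for the absorption/split parameters);
#' a missing arm raises an error naming the confounded parameters unless they
#' are fixed.
#'
#' @param data Long-format concentration records of a single group (plasma
#'   rows are used; predose zeros and below-limit records are excluded from
#'   the log-scale likelihood, or imputed per the spec's `blq` rule).
#' @param spec A [fit_spec()].
#' @return An object of class `pk_fit` with elements `params`
#'   ([pk_parameters()]), `derived` (from [derived_parameters()]),
#'   `objective` (log-scale residual sum of squares), `sigma`, `logLik`,
#'   `n_obs`, `converged`, `message`, `residuals` (per arm x compound
#'   summaries), `starts`, `spec`. [tidy()] and [glance()] methods are
#'   provided.
#' @export
fit_group <- function(data, spec) {
  stopifnot(inherits(spec, "fit_spec"))
  need <- c("arm", "compound", "matrix", "time_h", "conc", "blq_flag")
  stopifnot(all(need %in% names(data)))
  if ("group" %in% names(data) && length(unique(data$group)) > 1) {
    stop("fit_group expects data from a single group; got: ",
         paste(unique(data$group), collapse = ", "), call. = FALSE)
  }

  df <- dplyr::filter(data, .data$matrix == "plasma", .data$time_h > 0)
  if (spec$blq == "half_lloq") {
    df <- resolve_blq(df, rule = "half_lloq", lloq = spec$lloq)
  } else {
    df <- dplyr::filter(df, !.data$blq_flag)
  }
  df <- dplyr::filter(df, is.finite(.data$conc), .data$conc > 0)
  if (nrow(df) < 10) {
    stop("too few quantifiable observations to fit (", nrow(df), ")",
         call. = FALSE)
  }

  free <- setdiff(est_par_names(), names(spec$fixed))
  check_identifiability(unique(df$arm), free)

  # dose per arm: taken from the reference design amounts unless supplied
  arm_doses <- list(PO_parent = 4, IV_parent = 0.5, IV_metabolite = 0.5)
  if (!is.null(attr(data, "arm_doses"))) {
    arm_doses <- utils::modifyList(arm_doses, attr(data, "arm_doses"))
  }

  arms <- unique(df$arm)
  arm_times <- lapply(stats::setNames(arms, arms),
                      function(a) sort(unique(df$time_h[df$arm == a])))
  # observation index into the prediction matrices
  df$row_idx <- vapply(seq_len(nrow(df)), function(i) {
    match(df$time_h[i], arm_times[[df$arm[i]]])
  }, integer(1))
  log_obs <- log(df$conc)

  theta_full <- to_theta(spec$init)
  for (nm in names(spec$fixed)) {
    theta_full[nm] <- if (nm %in% c("fm", "F_po_total", "F_d")) {
      stats::qlogis(min(max(spec$fixed[[nm]], 1e-8), 1 - 1e-8))
    } else {
      log(spec$fixed[[nm]])
    }
  }

  objective <- function(theta_free) {
    th <- theta_full
    th[free] <- theta_free
    p <- from_theta(th)
    pred <- tryCatch(predict_arm_conc(p, arm_times, arm_doses),
                     error = function(e) NULL)
    if (is.null(pred)) return(1e10)
    ph <- vapply(seq_len(nrow(df)), function(i) {
      pred[[df$arm[i]]][df$row_idx[i], df$compound[i]]
    }, numeric(1))
    if (any(!is.finite(ph)) || any(ph <= 0)) return(1e10)
    sum((log_obs - log(ph))^2)
  }

  if (length(free) == 0) {
    # fully fixed model: nothing to optimize, just evaluate
    spec$n_starts <- 1L
    runs <- list(list(par = numeric(0), objective = objective(numeric(0)),
                      converged = TRUE, message = "all parameters fixed",
                      dist = 0))
  } else {
    set.seed(spec$seed)
    starts <- matrix(rep(theta_full[free], spec$n_starts),
                     nrow = spec$n_starts, byrow = TRUE,
                     dimnames = list(NULL, free))
    if (spec$n_starts > 1) {
      jit <- matrix(stats::rnorm((spec$n_starts - 1) * length(free),
                                 0, spec$jitter_sd),
                    nrow = spec$n_starts - 1)
      starts[-1, ] <- starts[-1, , drop = FALSE] + jit
    }
    runs <- purrr::map(seq_len(spec$n_starts), function(i) {
      res <- tryCatch(
        stats::nlminb(starts[i, ], objective,
                      control = list(iter.max = 1000, eval.max = 2000)),
        error = function(e) list(objective = Inf, par = starts[i, ],
                                 convergence = 1L,
                                 message = conditionMessage(e))
      )
      list(par = res$par, objective = res$objective,
           converged = identical(res$convergence, 0L),
           message = res$message %||% "",
           dist = sqrt(sum((res$par - theta_full[free])^2)))
    })
  }

  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best_obj <- min(objs)
  cand <- which(objs <= best_obj + 1e-8 * max(1, abs(best_obj)))
  best <- runs[[cand[which.min(vapply(runs[cand], `[[`, numeric(1), "dist"))]]]

  th <- theta_full
  th[free] <- best$par
  p_hat <- do.call(pk_parameters, from_theta(th)[pk_parameter_names()])

  pred <- predict_arm_conc(unclass(p_hat), arm_times, arm_doses)
  df$pred <- vapply(seq_len(nrow(df)), function(i) {
    pred[[df$arm[i]]][df$row_idx[i], df$compound[i]]
  }, numeric(1))
  df$resid_log <- log(df$conc) - log(df$pred)
  resid_summary <- df |>
    dplyr::group_by(.data$arm, .data$compound) |>
    dplyr::summarise(n = dplyr::n(),
                     rmse_log = sqrt(mean(.data$resid_log^2)),
                     bias_log = mean(.data$resid_log), .groups = "drop")

  n <- nrow(df)
  rss <- best$objective
  sigma <- sqrt(rss / n)
  ll <- -n / 2 * (log(2 * pi) + log(max(rss / n, 1e-300)) + 1) - sum(log_obs)

  structure(
    list(params = p_hat, derived = derived_parameters(p_hat),
         objective = rss, sigma = sigma, logLik = ll, n_obs = n,
         converged = best$converged, message = best$message,
         residuals = resid_summary,
         starts = tibble::tibble(start = seq_len(spec$n_starts),
                                 objective = objs),
         fitted = tibble::as_tibble(df[c("arm", "compound", "time_h",
                                         "conc", "pred", "resid_log")]),
         spec = spec),
    class = "pk_fit"
  )
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> pooled lognormal fit,", x$n_obs, "observations\n")
  cat(sprintf("  log-RSS %.5g, sigma %.3g, converged: %s\n",
              x$objective, x$sigma, x$converged))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @method tidy pk_fit
#' @export
tidy.pk_fit <- function(x, ...) {
  est <- unlist(unclass(x$params)[pk_parameter_names()])
  der <- unlist(x$derived[1, ])
  tibble::tibble(
    term = c(names(est), names(der)),
    estimate = c(unname(est), unname(der)),
    kind = rep(c("structural", "derived"), c(length(est), length(der)))
  )
}

#' @method glance pk_fit
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, sigma = x$sigma,
                 logLik = x$logLik, n_obs = x$n_obs,
                 converged = x$converged, n_starts = nrow(x$starts))
}

fit_param_value <- function(fit, param) {
  if (inherits(fit, "pk_fit")) {
    if (!fit$converged) {
      stop("fit did not converge; refusing to contrast it", call. = FALSE)
    }
    vals <- c(unclass(fit$params), as.list(fit$derived[1, ]))
  } else if (inherits(fit, "pk_parameters")) {
    vals <- c(unclass(fit), as.list(derived_parameters(fit)[1, ]))
  } else {
    stop("expected a pk_fit or pk_parameters object", call. = FALSE)
  }
  if (!param %in% names(vals)) {
    stop("unknown parameter '", param, "'", call. = FALSE)
  }
  vals[[param]]
}

#' Contrast a parameter between two fitted groups
#'
#' Fold change and percent change of a structural or derived parameter
#' between two group fits, conventionally treatment over control (e.g. the
#' LPS-challenged group against saline controls).
#'
#' @param fit_a,fit_b [fit_group()] results (or [pk_parameters()] objects);
#'   `fit_a` is the numerator group.
#' @param param Parameter name: any structural name or a derived name
#'   (`F_po`, `F_po_dmo`, `CL_parent_to_dmo`, `fm`).
#' @return A one-row tibble with `param`, `value_a`, `value_b`, `fold`
#'   (`a / b`), `pct_change` (`100 * (a - b) / b`). Values are not rounded;
#'   round only for display.
#' @export
#' @examples
#' contrast_groups(default_parameters("lps"), default_parameters("control"),
#'                 "CL")  # pct_change about -35
contrast_groups <- function(fit_a, fit_b, param) {
  a <- fit_param_value(fit_a, param)
  b <- fit_param_value(fit_b, param)
  if (b == 0) stop("reference value is zero", call. = FALSE)
  tibble::tibble(param = param, value_a = a, value_b = b,
                 fold = a / b, pct_change = 100 * (a - b) / b)
}

#' Welch two-sample t-test on individual parameter values
#'
#' Compares per-animal parameter values between two groups with Welch's
#' unequal-variance t-test, optionally after log transformation (appropriate
#' for lognormally distributed clearances and volumes).
#'
#' @param x,y Numeric vectors of per-animal parameter values (length >= 2).
#' @param log Test on the log scale (default `FALSE`).
#' @return A one-row tibble with `statistic`, `df`, `p.value`, `mean_x`,
#'   `mean_y`.
#' @export
welch_t_on_params <- function(x, y, log = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2, length(y) >= 2)
  if (log) {
    stopifnot(all(x > 0), all(y > 0))
    tx <- base::log(x); ty <- base::log(y)
  } else {
    tx <- x; ty <- y
  }
  if (stats::var(tx) == 0 && stats::var(ty) == 0) {
    if (mean(tx) == mean(ty)) {
      return(tibble::tibble(statistic = 0, df = NA_real_, p.value = 1,
                            mean_x = mean(x), mean_y = mean(y)))
    }
    stop("degenerate (zero) variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(tx, ty, var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p.value = tt$p.value,
                 mean_x = mean(x), mean_y = mean(y))
}
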