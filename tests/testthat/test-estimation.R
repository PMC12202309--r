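make_perturbed_init <- function(truth) {
  init <- unclass(truth)
  init$CL <- init$CL * 1.4
  init$CL_dmo <- init$CL_dmo * 0.7
  init$V1 <- init$V1 * 0.8
  init$k_pm <- init$k_pm * 1.5
  init$F_d <- min(init$F_d * 1.1, 0.95)
  init$F_po_total <- init$F_po_total * 0.7
  do.call(pk_parameters, init)
}

test_that("noise-free data are recovered essentially exactly", {
  des <- default_study_design()
  med <- group_medians_fixture()
  sim <- simulate_study(des, med, variability_model(0, 0), seed = 1)
  d <- dplyr::filter(sim, group == "control")
  sp <- fit_spec(make_perturbed_init(med$control), n_starts = 2,
                 jitter_sd = 0.1, seed = 1)
  fit <- fit_group(d, sp)
  expect_true(fit$converged)
  truth <- unlist(unclass(med$control))
  est <- unlist(unclass(fit$params))
  expect_equal(est, truth[names(est)], tolerance = 0.01)
  # derived quantities are recomputed from the estimates
  expect_equal(fit$derived$CL_parent_to_dmo,
               fit$params$V1 * fit$params$k_pm, tolerance = 1e-12)
})

test_that("the likelihood is invariant to data row order", {
  des <- default_study_design()
  med <- group_medians_fixture()
  sim <- simulate_study(des, med, variability_model(0, 0.15), seed = 8)
  d <- dplyr::filter(sim, group == "lps")
  sp <- fit_spec(med$lps, n_starts = 1, seed = 2)
  f1 <- fit_group(d, sp)
  set.seed(99)
  f2 <- fit_group(d[sample(nrow(d)), ], sp)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-10)
  expect_equal(unclass(f1$params), unclass(f2$params), tolerance = 1e-6)
})

test_that("the converged optimum is a local minimum in every free parameter", {
  des <- default_study_design()
  med <- group_medians_fixture()
  sim <- simulate_study(des, med, variability_model(0, 0.15), seed = 4)
  d <- dplyr::filter(sim, group == "control")
  sp <- fit_spec(med$control, n_starts = 1, seed = 1)
  fit <- fit_group(d, sp)
  expect_true(fit$converged)

  refit_obj <- function(p_mod) {
    spf <- fit_spec(p_mod, n_starts = 1, jitter_sd = 0, seed = 1)
    # objective at fixed parameters: evaluate by fixing everything
    fixed <- unclass(p_mod)[c("ka", "ka_dmo", "V1", "V2", "Q", "CL",
                              "V1_dmo", "V2_dmo", "Q_dmo", "CL_dmo",
                              "F_po_total", "F_d")]
    fixed$fm <- p_mod$k_pm * p_mod$V1 / p_mod$CL
    spf <- fit_spec(p_mod, fixed = fixed, n_starts = 1, seed = 1)
    fit_group(d, spf)$objective
  }
  base_obj <- refit_obj(fit$params)
  expect_equal(base_obj, fit$objective, tolerance = 1e-8)
  for (nm in c("CL", "CL_dmo", "V1", "ka", "F_d")) {
    for (fac in c(0.8, 1.2)) {
      p_mod <- unclass(fit$params)
      p_mod[[nm]] <- p_mod[[nm]] * fac
      p_mod <- do.call(pk_parameters, p_mod)
      expect_gt(refit_obj(p_mod), base_obj)
    }
  }
})

test_that("a missing arm raises an under-identifiability error naming parameters", {
  des <- default_study_design()
  med <- group_medians_fixture()
  sim <- simulate_study(des, med, variability_model(0, 0.1), seed = 6)
  d <- dplyr::filter(sim, group == "control", arm != "IV_metabolite")
  sp <- fit_spec(med$control, n_starts = 1, seed = 1)
  expect_error(fit_group(d, sp), "under-identified.*CL_dmo")

  # but fixing the confounded parameters makes the reduced fit legal
  fixed <- list(CL_dmo = med$control$CL_dmo, V1_dmo = med$control$V1_dmo,
                V2_dmo = med$control$V2_dmo, Q_dmo = med$control$Q_dmo)
  sp2 <- fit_spec(med$control, fixed = fixed, n_starts = 1, seed = 1)
  expect_s3_class(fit_group(d, sp2), "pk_fit")
})

test_that("a one-compartment truth is recovered as the closed-form regression estimate", {
  # IV bolus, one-compartment: log C = log(dose/V1/1000) - (CL/V1) t
  p <- one_compartment_params(V1 = 2, CL = 1.5)
  times <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6)
  set.seed(31)
  n_animals <- 6
  d <- tidyr::expand_grid(animal_id = seq_len(n_animals), time_h = times)
  sol <- pk_solve(p, dose_event("IV_parent", 0.5), times)
  mu <- sol$conc_ng_ml[sol$compound == "parent"]
  d$conc <- rep(mu, n_animals) * exp(stats::rnorm(nrow(d), 0, 0.15))
  d$arm <- "IV_parent"
  d$compound <- "parent"
  d$matrix <- "plasma"
  d$blq_flag <- FALSE

  # closed-form oracle: least squares on the log scale
  lmfit <- stats::lm(log(conc) ~ time_h, data = d)
  V1_hat <- 0.5e6 / exp(stats::coef(lmfit)[[1]]) / 1000
  CL_hat <- -stats::coef(lmfit)[[2]] * V1_hat

  fixed <- list(ka = 1, ka_dmo = 1, V2 = 1, Q = 1e-9, V1_dmo = 1,
                V2_dmo = 1, Q_dmo = 1e-9, CL_dmo = 1, fm = 1e-8,
                F_po_total = 0.5, F_d = 1 - 1e-8)
  sp <- fit_spec(p, fixed = fixed, n_starts = 2, jitter_sd = 0.1, seed = 1)
  fit <- fit_group(d, sp)
  expect_equal(fit$params$CL, CL_hat, tolerance = 1e-3)
  expect_equal(fit$params$V1, V1_hat, tolerance = 1e-3)
})

test_that("group contrasts reproduce the fold and percent arithmetic", {
  ctrl <- default_parameters("control")
  lps <- default_parameters("lps")

  cl <- contrast_groups(lps, ctrl, "CL")
  expect_equal(round(cl$pct_change), -35)
  expect_equal(cl$fold, 1.85 / 2.84)

  fpo <- contrast_groups(lps, ctrl, "F_po")
  expect_equal(round(fpo$fold, 1), 3.1)

  same <- contrast_groups(ctrl, ctrl, "CL_parent_to_dmo")
  expect_equal(same$pct_change, 0)
  expect_equal(same$fold, 1)

  expect_error(contrast_groups(lps, ctrl, "nope"), "unknown parameter")
})

test_that("welch test behaves at its symmetry and degeneracy limits", {
  x <- c(1, 2, 3, 4)
  expect_equal(welch_t_on_params(x, x)$p.value, 1, tolerance = 1e-12)
  expect_equal(welch_t_on_params(x, x)$statistic, 0)

  y <- c(2, 4, 5, 7)
  a <- welch_t_on_params(x, y)
  b <- welch_t_on_params(y, x)
  expect_equal(abs(a$statistic), abs(b$statistic))
  expect_equal(a$p.value, b$p.value)

  expect_error(welch_t_on_params(c(1, 1), c(2, 2)), "degenerate")
  expect_equal(welch_t_on_params(c(1, 1), c(1, 1))$p.value, 1)
})

test_that("the t-test detects a 2-fold separation with the study's group sizes", {
  # power simulation: lognormal CV 0.2, n = 10 per group, medians 2x apart
  sdlog <- sqrt(log(1 + 0.2^2))
  reject <- vapply(1:500, function(s) {
    set.seed(s)
    x <- stats::rlnorm(10, log(1), sdlog)
    y <- stats::rlnorm(10, log(2), sdlog)
    welch_t_on_params(x, y, log = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.8)
})
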