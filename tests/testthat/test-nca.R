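test_that("trapezoid weights reproduce the composite trapezoid rule", {
  expect_equal(trapezoid_weights(c(0, 1, 2)), c(0.5, 1, 0.5))
  expect_equal(trapezoid_weights(c(0, 24)), c(12, 12))
  # conservation on an arbitrary grid
  g <- sort(stats::runif(17, 0, 24))
  expect_equal(sum(trapezoid_weights(g)), max(g) - min(g))
  expect_error(trapezoid_weights(c(1, 1, 2)), "strictly increasing")
  expect_error(trapezoid_weights(c(2, 1)), "strictly increasing")
})

test_that("the point estimate is the trapezoid-weighted sum of per-time means", {
  # per-time means 0, 10, 5 over times 0, 1, 2 -> AUC 12.5
  d <- tibble::tibble(
    animal_id = rep(1:3, each = 3),
    time_h = rep(c(0, 1, 2), 3),
    conc = c(0, 9, 4, 0, 10, 5, 0, 11, 6)
  )
  est <- batch_auc(d, B = 0, seed = 1)
  expect_equal(est$auc, 12.5)
})

test_that("on complete data the estimator equals the per-animal oracle exactly", {
  times <- c(0, 0.5, 1, 2, 4, 8)
  d <- complete_batch_data(8, times, function(t) 50 * exp(-0.4 * t),
                           cv = 0.25, seed = 7)
  est <- batch_auc(d, B = 0, seed = 1)

  # brute-force oracle: each animal's trapezoid AUC, averaged
  per_animal <- vapply(split(d, d$animal_id), function(a) {
    a <- a[order(a$time_h), ]
    sum(trapezoid_weights(a$time_h) * a$conc)
  }, numeric(1))
  expect_equal(est$auc, mean(per_animal), tolerance = 1e-12)
  expect_equal(est$se, stats::sd(per_animal) / sqrt(length(per_animal)),
               tolerance = 1e-12)
})

test_that("all-zero data give a degenerate zero interval", {
  d <- tibble::tibble(animal_id = rep(1:3, each = 2),
                      time_h = rep(c(0, 2), 3), conc = 0)
  est <- batch_auc(d, B = 100, seed = 1)
  expect_equal(est$auc, 0)
  expect_equal(est$se, 0)
  expect_equal(c(est$lower, est$upper), c(0, 0))
})

test_that("AUC is equivariant to concentration scale and time units", {
  times <- c(0, 0.5, 1, 2, 4, 8)
  d <- complete_batch_data(6, times, function(t) 40 * exp(-0.3 * t),
                           cv = 0.2, seed = 3)
  base <- batch_auc(d, B = 500, seed = 11)

  d_scaled <- dplyr::mutate(d, conc = conc * 3)
  sc <- batch_auc(d_scaled, B = 500, seed = 11)
  expect_equal(sc$auc, 3 * base$auc, tolerance = 1e-12)
  expect_equal(sc$se, 3 * base$se, tolerance = 1e-12)
  expect_equal(sc$lower, 3 * base$lower, tolerance = 1e-10)
  expect_equal(sc$upper, 3 * base$upper, tolerance = 1e-10)

  d_min <- dplyr::mutate(d, time_h = time_h * 60)
  mn <- batch_auc(d_min, B = 500, seed = 11)
  expect_equal(mn$auc, 60 * base$auc, tolerance = 1e-12)
})

test_that("the bootstrap is reproducible under its seed", {
  times <- c(0, 1, 2, 4, 8, 24)
  p <- default_parameters("control")
  sol <- pk_solve(p, dose_event("PO_parent", 4), times)
  mu <- sol$conc_ng_ml[sol$compound == "parent"]
  d <- destructive_study(times, mu, seed = 4)
  a <- batch_auc(d, B = 300, seed = 21)
  b <- batch_auc(d, B = 300, seed = 21)
  expect_identical(tidy(a), tidy(b))
  c2 <- batch_auc(d, B = 300, seed = 22)
  expect_false(identical(a$lower, c2$lower))
})

test_that("incomplete batch designs are handled with the documented covariance rule", {
  # two batches with disjoint time pairs plus a singleton animal
  d <- tibble::tibble(
    animal_id = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6),
    time_h    = c(0, 2, 0, 2, 1, 4, 1, 4, 2, 4, 4),
    conc      = c(0, 8, 0, 10, 6, 3, 7, 2, 9, 4, 3)
  )
  expect_warning(est <- batch_auc(d, B = 0, seed = 1), "size 1")
  # point estimate: means at t = 0,1,2,4 are 0, 6.5, 9, 3
  w <- trapezoid_weights(c(0, 1, 2, 4))
  expect_equal(est$auc, sum(w * c(0, 6.5, 9, 3)))
  expect_gt(est$se, 0)
})

test_that("serial per-animal AUCs match their closed forms and the model", {
  d <- tibble::tibble(animal_id = rep(c("a", "b"), each = 2),
                      time_h = c(0, 6, 0, 1),
                      conc = c(10, 10, 0, 10))
  res <- serial_auc(d)
  expect_equal(res$auc[res$animal_id == "a"], 60)
  expect_equal(res$auc[res$animal_id == "b"], 5)

  # fewer than 2 points -> skipped with warning
  d1 <- dplyr::bind_rows(d, tibble::tibble(animal_id = "c", time_h = 1,
                                           conc = 4))
  expect_warning(res1 <- serial_auc(d1), "fewer than 2")
  expect_false("c" %in% res1$animal_id)

  # noise-free simulated IV profile vs quadrature of the generating model
  p <- default_parameters("control")
  times <- c(0.05, 0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 6)
  sol <- pk_solve(p, dose_event("IV_parent", 0.5), times)
  dd <- tibble::tibble(animal_id = "m1", time_h = times,
                       conc = sol$conc_ng_ml[sol$compound == "parent"])
  trap <- serial_auc(dd)$auc
  quad <- pk_auc_quadrature(p, dose_event("IV_parent", 0.5), "parent",
                            0.05, 6)
  # trapezoid error bound: sum over intervals of (dt^3 / 12) * max |c''|,
  # with c'' estimated by central differences on a fine grid
  bound <- sum(vapply(seq_len(length(times) - 1), function(i) {
    tt <- seq(times[i], times[i + 1], length.out = 21)
    h <- tt[2] - tt[1]
    cc <- pk_solve(p, dose_event("IV_parent", 0.5), tt)
    cc <- cc$conc_ng_ml[cc$compound == "parent"]
    d2 <- abs(diff(diff(cc)) / h^2)
    (times[i + 1] - times[i])^3 / 12 * max(d2)
  }, numeric(1)))
  expect_lt(abs(trap - quad), bound)
})

test_that("AUC ratios reproduce the metabolic-ratio arithmetic", {
  expect_equal(round(auc_ratio(1070, 462), 2), 2.32)
  expect_equal(round(auc_ratio(462, 121), 2), 3.82)
  expect_equal(auc_ratio(57.6, 192), 0.3)
  x <- structure(list(auc = 77), class = "batch_auc")
  expect_equal(auc_ratio(x, x), 1)
  expect_error(auc_ratio(1, 0), "zero")
})

test_that("below-limit rules act only on flagged records", {
  d <- tibble::tibble(
    animal_id = rep(1:2, each = 4),
    time_h = rep(c(0, 1, 4, 8), 2),
    conc = c(0, 10, 2, NA, 0, 12, 3, NA),
    blq_flag = rep(c(FALSE, FALSE, FALSE, TRUE), 2),
    matrix = "plasma"
  )
  # default: BLQ after tmax dropped
  r <- resolve_blq(d)
  expect_equal(nrow(r), 6)
  expect_false(anyNA(r$conc))

  # BLQ before tmax becomes zero
  d2 <- d
  d2$blq_flag <- rep(c(TRUE, FALSE, FALSE, FALSE), 2)
  d2$conc[d2$blq_flag] <- NA
  r2 <- resolve_blq(d2)
  expect_equal(nrow(r2), 8)
  expect_equal(r2$conc[r2$time_h == 0], c(0, 0))

  # half-LLOQ imputation
  r3 <- resolve_blq(d, rule = "half_lloq", lloq = c(plasma = 0.5))
  expect_equal(r3$conc[r3$blq_flag], c(0.25, 0.25))

  # exclusion
  r4 <- resolve_blq(d, rule = "exclude")
  expect_equal(nrow(r4), 6)

  # unflagged records are never touched
  expect_equal(r$conc[!r$blq_flag], d$conc[!d$blq_flag])
})

test_that("the grouped nca wrapper returns one row per stratum", {
  des <- default_study_design()
  sim <- simulate_study(des, group_medians_fixture(),
                        variability_model(0.2, 0.15), seed = 3)
  suppressWarnings(
    res <- nca(sim, t_last = 24, B = 200, seed = 5)
  )
  plasma <- dplyr::filter(res, matrix == "plasma")
  # 2 groups x (PO: 2 compounds, IV parent: 2, IV metabolite: 2)
  expect_equal(nrow(plasma), 12)
  # parent after IV metabolite is structurally absent -> zero exposure
  zero_rows <- dplyr::filter(plasma, arm == "IV_metabolite",
                             compound == "parent")
  expect_true(all(zero_rows$auc == 0))
  real <- dplyr::filter(plasma, !(arm == "IV_metabolite" &
                                    compound == "parent"))
  expect_true(all(real$auc > 0))
  expect_true(all(real$se > 0))
  expect_true(all(real$lower <= real$auc & real$auc <= real$upper))
})
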