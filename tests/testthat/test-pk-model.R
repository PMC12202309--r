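test_that("derived parameters follow the bioavailability product and clearance split", {
  # no presystemic conversion: all availability goes to the parent
  p <- one_compartment_params()
  d <- derived_parameters(p)
  expect_equal(d$F_po, 0.5)
  expect_equal(d$F_po_dmo, 0)

  # partial metabolic clearance is V1 * k_pm
  p2 <- pk_parameters(ka = 1, ka_dmo = 1, V1 = 2, V2 = 4, Q = 2, CL = 2.84,
                      V1_dmo = 1.5, V2_dmo = 2, Q_dmo = 1, CL_dmo = 0.6,
                      k_pm = 0.13, F_po_total = 0.101, F_d = 0.74)
  d2 <- derived_parameters(p2)
  expect_equal(d2$CL_parent_to_dmo, 0.26)
  expect_equal(d2$fm, 0.26 / 2.84)
  # bioavailability product consistent with 0.101 * 0.74
  expect_equal(d2$F_po, 0.07474, tolerance = 1e-6)
})

test_that("invalid parameter sets are rejected", {
  expect_error(pk_parameters(ka = 1, ka_dmo = 1, V1 = 1, V2 = 1, Q = 1,
                             CL = 1, V1_dmo = 1, V2_dmo = 1, Q_dmo = 1,
                             CL_dmo = 1, k_pm = 2, F_po_total = 0.5,
                             F_d = 0.5),
               "CL / V1 < k_pm")
  expect_error(pk_parameters(ka = -1, ka_dmo = 1, V1 = 1, V2 = 1, Q = 1,
                             CL = 1, V1_dmo = 1, V2_dmo = 1, Q_dmo = 1,
                             CL_dmo = 1, k_pm = 0.1, F_po_total = 0.5,
                             F_d = 0.5),
               "strictly positive")
  expect_error(pk_parameters(ka = 1, ka_dmo = 1, V1 = 1, V2 = 1, Q = 1,
                             CL = 1, V1_dmo = 1, V2_dmo = 1, Q_dmo = 1,
                             CL_dmo = 1, k_pm = 0.1, F_po_total = 1.5,
                             F_d = 0.5),
               "F_po_total")
})

test_that("the right-hand side behaves at its structural limits", {
  p <- default_parameters("control")
  # empty system
  expect_equal(unname(pk_rhs(rep(0, 8), 0, p)), rep(0, 8))

  # one-compartment limit: central parent decays at CL/V1
  p1 <- one_compartment_params(V1 = 2, CL = 1)
  s <- c(0, 1000, 0, 0, 0, 0, 0, 0)
  ds <- unname(pk_rhs(s, 0, p1))
  expect_equal(ds[2], -1 / 2 * 1000, tolerance = 1e-6)

  # complete conversion: parent elimination ledger stays flat
  pc <- pk_parameters(ka = 1, ka_dmo = 1, V1 = 1, V2 = 1, Q = 1, CL = 0.5,
                      V1_dmo = 1, V2_dmo = 1, Q_dmo = 1, CL_dmo = 1,
                      k_pm = 0.5, F_po_total = 0.5, F_d = 0.5)
  ds <- unname(pk_rhs(c(0, 1000, 0, 0, 0, 0, 0, 0), 0, pc))
  expect_equal(ds[7], 0)
  expect_equal(ds[5], 0.5 * 1000)
})

test_that("dose events load the correct compartments with unit conversion", {
  p <- pk_parameters(ka = 1, ka_dmo = 1, V1 = 1, V2 = 1, Q = 1, CL = 1,
                     V1_dmo = 1, V2_dmo = 1, Q_dmo = 1, CL_dmo = 1,
                     k_pm = 0, F_po_total = 0.1, F_d = 0.75)
  s0 <- rep(0, 8)
  s <- apply_dose(s0, dose_event("PO_parent", 4), p)
  expect_equal(s[1], 3.0e5)
  expect_equal(s[4], 1.0e5)

  s <- apply_dose(s0, dose_event("IV_parent", 0.5), p)
  expect_equal(s[2], 5e5)

  p0 <- pk_parameters(ka = 1, ka_dmo = 1, V1 = 1, V2 = 1, Q = 1, CL = 1,
                      V1_dmo = 1, V2_dmo = 1, Q_dmo = 1, CL_dmo = 1,
                      k_pm = 0, F_po_total = 0, F_d = 0.75)
  expect_equal(apply_dose(s0, dose_event("PO_parent", 4), p0), s0)
  expect_error(dose_event("oral", 4))
})

test_that("the solver matches the one-compartment closed form", {
  p <- one_compartment_params(V1 = 1, CL = 1)
  sol <- pk_solve(p, dose_event("IV_parent", 0.5), c(0, 0.5, 1, 2, 4))
  parent <- sol$conc_ng_ml[sol$compound == "parent"]
  expect_equal(parent, 500 * exp(-c(0, 0.5, 1, 2, 4)), tolerance = 1e-6)
})

test_that("analytic and lsoda solutions agree", {
  p <- default_parameters("lps")
  times <- c(0.05, 0.25, 1, 2, 6, 12, 24)
  for (arm in c("PO_parent", "IV_parent", "IV_metabolite")) {
    a <- pk_solve(p, dose_event(arm, 2), times, method = "eigen")
    b <- pk_solve(p, dose_event(arm, 2), times, method = "lsoda")
    expect_equal(a$conc_ng_ml, b$conc_ng_ml, tolerance = 1e-6)
  }
})

test_that("mass balance holds at all times for all arms", {
  for (grp in c("control", "lps")) {
    p <- default_parameters(grp)
    for (arm in c("PO_parent", "IV_parent", "IV_metabolite")) {
      ev <- dose_event(arm, 4)
      am <- pk_solve_amounts(p, ev, c(0.1, 1, 6, 24, 72))
      bioavailable <- if (arm == "PO_parent") 4e6 * p$F_po_total else 4e6
      total <- rowSums(am[, -1])
      expect_equal(total, rep(bioavailable, nrow(am)), tolerance = 1e-6)
    }
  }
})

test_that("the solution is linear in dose (superposition)", {
  p <- default_parameters("control")
  times <- c(0.25, 1, 4, 10, 24)
  s1 <- pk_solve(p, dose_event("PO_parent", 2), times)
  s2 <- pk_solve(p, dose_event("PO_parent", 4), times)
  expect_equal(s2$conc_ng_ml, 2 * s1$conc_ng_ml, tolerance = 1e-8)
})

test_that("exposure identities AUC = F*dose/CL and fm*dose/CL_dmo hold", {
  for (grp in c("control", "lps")) {
    p <- default_parameters(grp)
    ev <- dose_event("IV_parent", 0.5)
    auc_p <- pk_auc_quadrature(p, ev, "parent", 0, Inf)
    expect_equal(auc_p, 0.5e6 / p$CL / 1000, tolerance = 5e-3)
    auc_m <- pk_auc_quadrature(p, ev, "metabolite", 0, Inf)
    fm <- p$V1 * p$k_pm / p$CL
    expect_equal(auc_m, fm * 0.5e6 / p$CL_dmo / 1000, tolerance = 5e-3)
  }
})

test_that("no parent appears after an IV dose of the metabolite", {
  p <- default_parameters("control")
  sol <- pk_solve(p, dose_event("IV_metabolite", 0.5),
                  c(0.05, 0.5, 1, 2, 4, 6))
  expect_true(all(sol$conc_ng_ml[sol$compound == "parent"] == 0))
  expect_true(all(sol$conc_ng_ml[sol$compound == "metabolite"] > 0))
})

test_that("multiple dose events superpose correctly", {
  p <- one_compartment_params(V1 = 1, CL = 1)
  two <- pk_solve(p, list(dose_event("IV_parent", 0.5, time = 0),
                          dose_event("IV_parent", 0.5, time = 2)),
                  c(1, 2, 3, 5))
  parent <- two$conc_ng_ml[two$compound == "parent"]
  expected <- 500 * exp(-c(1, 2, 3, 5)) +
    c(0, 500, 500 * exp(-1), 500 * exp(-3))
  expect_equal(parent, expected, tolerance = 1e-6)
})

test_that("the optional molar-mass correction scales the conversion transfer", {
  p <- default_parameters("control")
  ev <- dose_event("IV_parent", 0.5)
  times <- c(0.5, 2, 6, 24)
  off <- pk_solve(p, ev, times)
  on <- pk_solve(p, ev, times, molar_mass_ratio = 298.4 / 312.4)
  # parent kinetics untouched, metabolite scaled by the mass ratio
  expect_equal(on$conc_ng_ml[on$compound == "parent"],
               off$conc_ng_ml[off$compound == "parent"])
  expect_equal(on$conc_ng_ml[on$compound == "metabolite"],
               off$conc_ng_ml[off$compound == "metabolite"] * 298.4 / 312.4,
               tolerance = 1e-10)
  # the balance audit still closes: shed mass is booked as eliminated parent
  am <- pk_solve_amounts(p, ev, times, molar_mass_ratio = 298.4 / 312.4)
  expect_equal(rowSums(am[, -1]), rep(0.5e6, length(times)),
               tolerance = 1e-6)
})
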