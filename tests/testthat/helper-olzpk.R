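# shared fixtures, built in code

# effectively one-compartment parent (no distribution, no conversion)
one_compartment_params <- function(V1 = 1, CL = 1, ka = 1) {
  pk_parameters(
    ka = ka, ka_dmo = 1, V1 = V1, V2 = 1, Q = 1e-9, CL = CL,
    V1_dmo = 1, V2_dmo = 1, Q_dmo = 1e-9, CL_dmo = 1,
    k_pm = 0, F_po_total = 0.5, F_d = 1
  )
}

group_medians_fixture <- function() {
  list(control = default_parameters("control"),
       lps = default_parameters("lps"))
}

# complete single-batch dataset: every animal observed at every time
complete_batch_data <- function(n_animals, times, base_fun, cv = 0.2,
                                seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(animal_id = seq_len(n_animals), time_h = times) |>
    dplyr::mutate(conc = base_fun(time_h) *
                    exp(stats::rnorm(dplyr::n(), 0, cv)))
}

# destructive study generator used by the NCA simulation experiments:
# fixed true curve mu over `times`, time pairs (j, j + J/2), `per_pair`
# animals per pair, mean-one lognormal proportional error
destructive_study <- function(times, mu, per_pair = 3, prop_cv = 0.15,
                              seed = 1) {
  set.seed(seed)
  J <- length(times)
  half <- J / 2
  sdlog <- sqrt(log(1 + prop_cv^2))
  rows <- vector("list", half * per_pair)
  a <- 0
  for (b in seq_len(half)) {
    jj <- c(b, b + half)
    for (i in seq_len(per_pair)) {
      a <- a + 1
      m <- mu[jj]
      obs <- ifelse(m > 0, m * exp(stats::rnorm(2, 0, sdlog) - sdlog^2 / 2), 0)
      rows[[a]] <- data.frame(animal_id = a, time_h = times[jj], conc = obs)
    }
  }
  do.call(rbind, rows)
}

# minimal qPCR Ct table: one target, one reference gene, duplicates
ct_table_fixture <- function() {
  base <- tidyr::expand_grid(
    sample_id = sprintf("s%02d", 1:12),
    gene = c("Cyp1a2", "Gapdh"),
    replicate = 1:2
  )
  base$group <- rep(rep(c("control", "lps"), each = 4), 3)[1:nrow(base)]
  base <- tidyr::expand_grid(
    tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                   group = rep(c("control", "lps"), 6),
                   time_h = rep(c(24, 48), each = 6)),
    gene = c("Cyp1a2", "Gapdh"),
    replicate = 1:2
  )
  base$role <- ifelse(base$gene == "Gapdh", "reference", "target")
  set.seed(42)
  base$ct <- ifelse(base$role == "reference", 20, 25) +
    stats::rnorm(nrow(base), 0, 0.3) +
    ifelse(base$role == "target" & base$group == "lps", 2, 0)
  base
}
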