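# Non-compartmental AUC estimation for sparse designs.
#
# The point estimate is the Bailer-type weighted sum of per-time mean
# concentrations, generalized to batch designs: animals are grouped into
# batches by their sampling-time pattern, the variance pools within-batch
# covariances across times, and the confidence interval is a bootstrap-t
# interval from resampling animals with replacement within batches.

#' Linear trapezoid quadrature weights
#'
#' Weights `w` such that `sum(w * y)` is the linear trapezoid integral of `y`
#' observed at `times`: `w_1 = (t_2 - t_1)/2`, `w_j = (t_{j+1} - t_{j-1})/2`,
#' `w_J = (t_J - t_{J-1})/2`. The weights sum to the spanned interval.
#'
#' @param times Strictly increasing numeric vector, length >= 2.
#' @return Numeric vector of weights, same length as `times`.
#' @export
#' @examples
#' trapezoid_weights(c(0, 1, 2))  # 0.5, 1, 0.5
trapezoid_weights <- function(times) {
  stopifnot(is.numeric(times), length(times) >= 2)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing without duplicates", call. = FALSE)
  }
  J <- length(times)
  w <- numeric(J)
  w[1] <- (times[2] - times[1]) / 2
  if (J > 2) w[2:(J - 1)] <- (times[3:J] - times[1:(J - 2)]) / 2
  w[J] <- (times[J] - times[J - 1]) / 2
  w
}

# Build the internal batch representation from long data:
# list(times, X [animals x J, NA where unsampled], batch_id per animal)
as_batch_dataset <- function(data, animal = "animal_id", time = "time_h",
                             conc = "conc") {
  stopifnot(all(c(animal, time, conc) %in% names(data)))
  df <- tibble::tibble(animal = data[[animal]], time = data[[time]],
                       conc = data[[conc]])
  if (anyNA(df$conc)) {
    stop("concentrations must be resolved (no NA) before AUC estimation; ",
         "apply a BLQ rule first", call. = FALSE)
  }
  if (any(duplicated(df[c("animal", "time")]))) {
    stop("each (animal, time) pair may carry at most one concentration",
         call. = FALSE)
  }
  times <- sort(unique(df$time))
  if (length(times) < 2) stop("need at least 2 time points", call. = FALSE)
  animals <- unique(df$animal)
  X <- matrix(NA_real_, length(animals), length(times),
              dimnames = list(animals, NULL))
  X[cbind(match(df$animal, animals), match(df$time, times))] <- df$conc
  pattern <- apply(!is.na(X), 1, function(z) paste(which(z), collapse = ","))
  list(times = times, X = X, batch_id = match(pattern, unique(pattern)))
}

# Point estimate and design-aware variance from the batch representation.
# Returns list(auc, var, mean_j, pair_info) where pair_info caches the pair
# bookkeeping reused by the bootstrap.
batch_auc_core <- function(bd, w) {
  X <- bd$X
  J <- ncol(X)
  n_j <- colSums(!is.na(X))
  if (any(n_j == 0)) {
    stop("every schedule time must be covered by at least one animal",
         call. = FALSE)
  }
  mean_j <- colMeans(X, na.rm = TRUE)
  auc <- sum(w * mean_j)

  batches <- split(seq_len(nrow(X)), bd$batch_id)
  singletons <- vapply(batches, length, integer(1)) == 1
  if (any(singletons)) {
    warning(sum(singletons), " batch(es) of size 1 contribute no covariance ",
            "and were dropped from the variance", call. = FALSE)
  }
  # enumerate time pairs (j <= k) jointly covered by some batch of size >= 2
  pair_rows <- list()
  for (b in which(!singletons)) {
    rows <- batches[[b]]
    cols <- which(!is.na(X[rows[1], ]))
    prs <- expand.grid(j = cols, k = cols)
    prs <- prs[prs$j <= prs$k, , drop = FALSE]
    prs$batch <- b
    pair_rows[[length(pair_rows) + 1]] <- prs
  }
  v <- 0
  pairs <- NULL
  if (length(pair_rows) > 0) {
    pairs <- do.call(rbind, pair_rows)
    key <- paste(pairs$j, pairs$k)
    for (kk in unique(key)) {
      sub <- pairs[key == kk, , drop = FALSE]
      j <- sub$j[1]; k <- sub$k[1]
      ss <- 0; df <- 0; n_cov <- 0
      for (b in sub$batch) {
        rows <- batches[[b]]
        xj <- X[rows, j]; xk <- X[rows, k]
        ss <- ss + sum((xj - mean(xj)) * (xk - mean(xk)))
        df <- df + length(rows) - 1
        n_cov <- n_cov + length(rows)
      }
      # animals in singleton batches also contribute to n at (j, k)
      for (b in which(singletons)) {
        rows <- batches[[b]]
        if (!is.na(X[rows[1], j]) && !is.na(X[rows[1], k])) {
          n_cov <- n_cov + length(rows)
        }
      }
      if (df > 0) {
        cov_jk <- (ss / df) / n_cov
        mult <- if (j == k) 1 else 2
        v <- v + mult * w[j] * w[k] * cov_jk
      }
    }
  }
  list(auc = auc, var = max(v, 0), mean_j = mean_j, n_j = n_j,
       batches = batches, singletons = singletons)
}

#' Batch-design AUC with bootstrap-t confidence interval
#'
#' Estimates the area under the concentration-time curve up to the last
#' sampled time (`AUC_t`) from a sparse design in which no animal need have a
#' complete profile. Animals are grouped into batches by their sampling-time
#' pattern. The point estimate is `sum_j w_j * mean_j`, the trapezoid-weighted
#' sum of per-time mean concentrations; its variance is
#' `sum_jk w_j w_k cov_jk` where `cov_jk` is the within-batch-pooled sample
#' covariance of concentrations at times `j` and `k`, divided by the number of
#' animals observed at both times (zero when no batch covers the pair). On
#' complete data (a single batch, every animal at every time) this reduces
#' exactly to the mean and variance of the per-animal trapezoid AUCs.
#'
#' The 95% interval is a bootstrap-t interval: animals are resampled with
#' replacement within their batches `B` times; for each replicate the
#' studentized statistic `t* = (AUC* - AUC) / se*` is formed, and the interval
#' is `AUC - se * q*(1 - alpha/2)`, `AUC - se * q*(alpha/2)` from the
#' empirical quantiles of `t*`. Replicates with a degenerate (zero or
#' non-finite) `se*` are dropped.
#'
#' @param data A data frame with one row per measured concentration.
#' @param animal,time,conc Names of the animal-identifier, time and
#'   concentration columns (defaults `animal_id`, `time_h`, `conc`).
#' @param B Number of bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap resampling (required).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `batch_auc`: a list with `auc`, `se`, `lower`,
#'   `upper`, `conf_level`, `B`, `B_used`, `seed`, `times`, `n_animals`.
#'   [tidy()] and [glance()] methods return one-row tibbles.
#' @references Bailer, A. J. (1988) Testing for the equality of area under
#'   the curves when using destructive measurement techniques.
#'   J Pharmacokinet Biopharm 16, 303-309.
#' @export
#' @examples
#' df <- tidyr::expand_grid(animal_id = 1:6, time_h = c(0, 1, 2, 4))
#' df$conc <- 10 * exp(-0.5 * df$time_h) * (1 + 0.05 * (df$animal_id - 3.5))
#' batch_auc(df, B = 200, seed = 1)
batch_auc <- function(data, animal = "animal_id", time = "time_h",
                      conc = "conc", B = 2000, seed, conf_level = 0.95) {
  if (missing(seed)) stop("a bootstrap seed is required", call. = FALSE)
  bd <- as_batch_dataset(data, animal, time, conc)
  w <- trapezoid_weights(bd$times)
  core <- batch_auc_core(bd, w)
  se <- sqrt(core$var)

  lower <- upper <- NA_real_
  B_used <- 0L
  if (B > 0 && se > 0) {
    set.seed(seed)
    tstar <- boot_tstar(bd, w, core, B)
    tstar <- tstar[is.finite(tstar)]
    B_used <- length(tstar)
    if (B_used > 0) {
      alpha <- 1 - conf_level
      q <- stats::quantile(tstar, c(1 - alpha / 2, alpha / 2), names = FALSE)
      lower <- core$auc - se * q[1]
      upper <- core$auc - se * q[2]
    }
  } else if (se == 0) {
    lower <- upper <- core$auc
    B_used <- 0L
  }
  structure(
    list(auc = core$auc, se = se, lower = lower, upper = upper,
         conf_level = conf_level, B = B, B_used = B_used, seed = seed,
         times = bd$times, n_animals = nrow(bd$X)),
    class = "batch_auc"
  )
}

# Vectorized bootstrap of the studentized AUC statistic. For each batch the
# with-replacement resample is drawn as multinomial counts over its animals;
# per-replicate means and pooled covariances are then assembled from batch
# sums, so the B replicates are computed with matrix algebra rather than a
# loop over replicates.
boot_tstar <- function(bd, w, core, B) {
  X <- bd$X
  J <- ncol(X)
  batches <- core$batches
  nb <- length(batches)

  counts <- vector("list", nb)      # n_b x B multinomial counts
  for (b in seq_len(nb)) {
    n_b <- length(batches[[b]])
    counts[[b]] <- stats::rmultinom(B, n_b, rep(1 / n_b, n_b))
  }

  # per-time resampled sums and n (n is fixed: batch sizes are preserved)
  sum_tj <- matrix(0, B, J)
  n_j <- core$n_j
  # per-batch first and second moments
  S1 <- vector("list", nb)          # J_b x B sums per batch
  cols_of <- vector("list", nb)
  for (b in seq_len(nb)) {
    rows <- batches[[b]]
    cols <- which(!is.na(X[rows[1], ]))
    cols_of[[b]] <- cols
    M <- X[rows, cols, drop = FALSE]             # n_b x J_b
    S1[[b]] <- crossprod(M, counts[[b]])         # J_b x B
    sum_tj[, cols] <- sum_tj[, cols] + t(S1[[b]])
  }
  mean_tj <- sweep(sum_tj, 2, n_j, "/")
  auc_star <- drop(mean_tj %*% w)

  # variance per replicate: pooled within-batch covariances over covered pairs
  var_star <- numeric(B)
  # collect per-pair cross-product sums and per-pair df/n across batches
  pair_keys <- list()
  for (b in seq_len(nb)) {
    rows <- batches[[b]]
    if (length(rows) < 2) next
    cols <- cols_of[[b]]
    M <- X[rows, cols, drop = FALSE]
    n_b <- length(rows)
    for (a_i in seq_along(cols)) {
      for (a_k in a_i:length(cols)) {
        j <- cols[a_i]; k <- cols[a_k]
        key <- paste(j, k)
        cross <- crossprod(M[, a_i] * M[, a_k], counts[[b]])  # 1 x B
        ssb <- drop(cross) -
          drop(S1[[b]][a_i, ]) * drop(S1[[b]][a_k, ]) / n_b
        rec <- pair_keys[[key]]
        if (is.null(rec)) {
          rec <- list(j = j, k = k, ss = numeric(B), df = 0, n = 0)
        }
        rec$ss <- rec$ss + ssb
        rec$df <- rec$df + n_b - 1
        rec$n <- rec$n + n_b
        pair_keys[[key]] <- rec
      }
    }
  }
  # animals in singleton batches still count toward n at covered pairs
  for (b in seq_len(nb)) {
    rows <- batches[[b]]
    if (length(rows) != 1) next
    cols <- cols_of[[b]]
    for (a_i in seq_along(cols)) {
      for (a_k in a_i:length(cols)) {
        key <- paste(cols[a_i], cols[a_k])
        if (!is.null(pair_keys[[key]])) {
          pair_keys[[key]]$n <- pair_keys[[key]]$n + 1
        }
      }
    }
  }
  for (rec in pair_keys) {
    if (rec$df <= 0) next
    mult <- if (rec$j == rec$k) 1 else 2
    var_star <- var_star +
      mult * w[rec$j] * w[rec$k] * (rec$ss / rec$df) / rec$n
  }
  var_star[var_star < 0] <- 0
  se_star <- sqrt(var_star)
  out <- (auc_star - core$auc) / se_star
  out[se_star == 0] <- NA_real_
  out
}

#' @export
print.batch_auc <- function(x, ...) {
  cat("<batch_auc>\n")
  cat(sprintf("  AUC_t = %.4g (se %.3g), %d animals, t in [%g, %g] h\n",
              x$auc, x$se, x$n_animals, min(x$times), max(x$times)))
  cat(sprintf("  %g%% bootstrap-t CI: [%.4g, %.4g] (B = %d, used %d)\n",
              100 * x$conf_level, x$lower, x$upper, x$B, x$B_used))
  invisible(x)
}

#' @method tidy batch_auc
#' @export
tidy.batch_auc <- function(x, ...) {
  tibble::tibble(estimate = x$auc, std.error = x$se,
                 conf.low = x$lower, conf.high = x$upper,
                 conf.level = x$conf_level)
}

#' @method glance batch_auc
#' @export
glance.batch_auc <- function(x, ...) {
  tibble::tibble(n_animals = x$n_animals, n_times = length(x$times),
                 B = x$B, B_used = x$B_used, seed = x$seed)
}

#' Per-animal trapezoid AUCs for serial profiles
#'
#' Computes each animal's linear trapezoid AUC from its first to its last
#' sampled time. Animals with fewer than 2 points are skipped with a warning.
#'
#' @inheritParams batch_auc
#' @return A tibble with `animal_id`, `auc`, `t_first`, `t_last`, `n_points`.
#' @export
serial_auc <- function(data, animal = "animal_id", time = "time_h",
                       conc = "conc") {
  stopifnot(all(c(animal, time, conc) %in% names(data)))
  df <- tibble::tibble(animal_id = data[[animal]], time_h = data[[time]],
                       conc = data[[conc]])
  res <- df |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      t_first = min(.data$time_h), t_last = max(.data$time_h),
      auc = if (dplyr::n() >= 2) {
        sum(trapezoid_weights(.data$time_h) * .data$conc)
      } else NA_real_,
      .groups = "drop"
    )
  dropped <- res$animal_id[res$n_points < 2]
  if (length(dropped) > 0) {
    warning("skipping animals with fewer than 2 points: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    res <- res[res$n_points >= 2, ]
  }
  dplyr::select(res, "animal_id", "auc", "t_first", "t_last", "n_points")
}

#' Ratio of AUC point estimates
#'
#' Plain ratio of two exposure point estimates (metabolic ratios, brain-to-
#' plasma ratios). Accepts [batch_auc()] objects or scalars; no uncertainty is
#' propagated.
#'
#' @param numerator,denominator `batch_auc` objects or positive scalars.
#' @return The ratio (a bare number).
#' @export
#' @examples
#' auc_ratio(1070, 462)  # DMO-to-olanzapine metabolic ratio, displays 2.3
auc_ratio <- function(numerator, denominator) {
  val <- function(x) if (inherits(x, "batch_auc")) x$auc else x
  num <- val(numerator); den <- val(denominator)
  stopifnot(is.numeric(num), is.numeric(den))
  if (den == 0) stop("denominator AUC is zero", call. = FALSE)
  num / den
}

#' Resolve below-limit records for NCA
#'
#' Applies a censoring rule to flagged records: `"zero_before_tmax"` (default)
#' sets BLQ concentrations to 0 at or before the time of the maximum of the
#' per-time mean curve and drops BLQ records after it; `"half_lloq"` imputes
#' LLOQ/2; `"exclude"` drops all BLQ records.
#'
#' @param data Concentration records with `conc` and `blq_flag` columns.
#' @param rule One of `"zero_before_tmax"`, `"half_lloq"`, `"exclude"`.
#' @param lloq LLOQ value(s) for `"half_lloq"`: a single number or a named
#'   vector over the `matrix` column values.
#' @return The records with `conc` resolved (no NA) and BLQ rows possibly
#'   removed.
#' @export
resolve_blq <- function(data, rule = c("zero_before_tmax", "half_lloq",
                                       "exclude"), lloq = NULL) {
  rule <- match.arg(rule)
  stopifnot(all(c("conc", "blq_flag") %in% names(data)))
  if (!any(data$blq_flag)) return(data)
  if (rule == "exclude") return(dplyr::filter(data, !.data$blq_flag))
  if (rule == "half_lloq") {
    if (is.null(lloq)) stop("half_lloq rule needs an lloq value", call. = FALSE)
    lv <- if (length(lloq) == 1 && is.null(names(lloq))) {
      rep(lloq, nrow(data))
    } else {
      unname(lloq[data$matrix])
    }
    data$conc[data$blq_flag] <- lv[data$blq_flag] / 2
    return(data)
  }
  # zero_before_tmax: tmax of the mean curve with BLQ treated as zero
  tmp <- data
  tmp$conc[tmp$blq_flag] <- 0
  mean_curve <- tmp |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(m = mean(.data$conc), .groups = "drop")
  tmax <- mean_curve$time_h[which.max(mean_curve$m)]
  keep <- !(data$blq_flag & data$time_h > tmax)
  out <- data[keep, ]
  out$conc[out$blq_flag] <- 0
  out
}

#' Grouped non-compartmental AUC analysis
#'
#' Tidy front end over [batch_auc()]: resolves below-limit records, restricts
#' to `t <= t_last`, and estimates `AUC_t` with its bootstrap-t interval for
#' every combination of the grouping columns.
#'
#' @param data Long-format concentration records (as produced by
#'   [simulate_study()] or [read_concentrations()]).
#' @param by Character vector of grouping columns (default
#'   `c("group", "arm", "compound", "matrix")`).
#' @param t_last Optional last time, h; records after it are dropped.
#' @param blq_rule,lloq Passed to [resolve_blq()].
#' @inheritParams batch_auc
#' @return A tibble with the grouping columns plus `auc`, `se`, `lower`,
#'   `upper`, `n_animals`, `n_times`.
#' @export
nca <- function(data, by = c("group", "arm", "compound", "matrix"),
                t_last = NULL, B = 2000, seed,
                blq_rule = "zero_before_tmax", lloq = NULL) {
  if (missing(seed)) stop("a bootstrap seed is required", call. = FALSE)
  stopifnot(all(by %in% names(data)))
  if (!is.null(t_last)) data <- dplyr::filter(data, .data$time_h <= t_last)
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      d <- resolve_blq(d, rule = blq_rule, lloq = lloq)
      if (nrow(d) == 0 || length(unique(d$time_h)) < 2 || all(d$conc == 0)) {
        zero <- nrow(d) > 0
        return(tibble::tibble(auc = if (zero) 0 else NA_real_,
                              se = 0,
                              lower = if (zero) 0 else NA_real_,
                              upper = if (zero) 0 else NA_real_,
                              n_animals = length(unique(d$animal_id)),
                              n_times = length(unique(d$time_h))))
      }
      res <- batch_auc(d, B = B, seed = seed)
      tibble::tibble(auc = res$auc, se = res$se, lower = res$lower,
                     upper = res$upper, n_animals = res$n_animals,
                     n_times = length(res$times))
    }) |>
    dplyr::ungroup()
}
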