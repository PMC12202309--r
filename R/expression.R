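# Relative gene expression by the 2^-ddCt method.

#' Relative expression by the 2^-ddCt method
#'
#' Reduces a long qPCR cycle-threshold table to per-sample relative
#' expression. Technical replicates are averaged arithmetically on the Ct
#' scale; each sample's delta-Ct is `Ct_target - Ct_reference`; the
#' delta-delta-Ct subtracts the arithmetic mean delta-Ct of the calibrator
#' group (by default within the same time stratum, so each time point's
#' controls calibrate that time point); relative expression is `2^-ddCt`.
#' By construction the geometric mean of the calibrator group's relative
#' expression is 1 in every stratum.
#'
#' @param data A data frame with columns `sample_id`, `group`, `time_h`,
#'   `gene`, `role` (`"target"` or `"reference"`), `replicate`, `ct`.
#' @param calibrator Calibrator group label (e.g. the saline controls).
#' @param by_time If `TRUE` (default) the calibrator mean is taken within
#'   each time stratum; if `FALSE` a single global calibrator mean is used.
#' @return A tibble with `sample_id`, `group`, `time_h`, `gene`, `dct`,
#'   `ddct`, `rel_expr` (one row per sample x target gene).
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   group = rep(c("control", "lps"), each = 2),
#'   time_h = 24,
#'   gene = rep(c("Cyp1a2", "Gapdh"), 2),
#'   role = rep(c("target", "reference"), 2),
#'   replicate = 1, ct = c(25, 20, 28, 20)
#' )
#' ddct(ct, calibrator = "control")
ddct <- function(data, calibrator, by_time = TRUE) {
  need <- c("sample_id", "group", "time_h", "gene", "role", "replicate", "ct")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("ddct input is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(data$role %in% c("target", "reference")))
  if (any(data$ct <= 0 | data$ct > 45)) {
    stop("Ct values must lie in (0, 45]", call. = FALSE)
  }
  if (!calibrator %in% data$group) {
    stop("calibrator group '", calibrator, "' not present in the data",
         call. = FALSE)
  }

  averaged <- data |>
    dplyr::group_by(.data$sample_id, .data$group, .data$time_h,
                    .data$gene, .data$role) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  refs <- averaged |>
    dplyr::filter(.data$role == "reference") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ct_ref = mean(.data$ct), .groups = "drop")

  targets <- dplyr::filter(averaged, .data$role == "target")
  no_ref <- setdiff(unique(targets$sample_id), refs$sample_id)
  if (length(no_ref) > 0) {
    stop("samples without a reference-gene Ct: ",
         paste(no_ref, collapse = ", "), call. = FALSE)
  }

  dct_tbl <- targets |>
    dplyr::left_join(refs, by = "sample_id") |>
    dplyr::mutate(dct = .data$ct - .data$ct_ref)

  strata <- if (by_time) c("gene", "time_h") else "gene"
  calib <- dct_tbl |>
    dplyr::filter(.data$group == calibrator) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::summarise(calib_dct = mean(.data$dct), .groups = "drop")

  out <- dplyr::left_join(dct_tbl, calib, by = strata)
  if (anyNA(out$calib_dct)) {
    bad <- out[is.na(out$calib_dct), strata, drop = FALSE]
    stop("no calibrator samples for stratum: ",
         paste(utils::capture.output(print(unique(bad))), collapse = " "),
         call. = FALSE)
  }
  out |>
    dplyr::mutate(ddct = .data$dct - .data$calib_dct,
                  rel_expr = 2^(-.data$ddct)) |>
    dplyr::select("sample_id", "group", "time_h", "gene",
                  "dct", "ddct", "rel_expr")
}
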