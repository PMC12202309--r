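# Equilibrium-dialysis reduction and brain-penetration coefficients.

#' Unbound fraction in plasma from equilibrium dialysis
#'
#' The plasma unbound fraction is the ratio of the drug concentration in the
#' buffer chamber to that in the plasma chamber at dialysis equilibrium.
#' Values above 1 can arise from assay noise; they are reported as-is with a
#' warning (no silent clipping) so that QC surfaces them.
#'
#' @param c_buffer,c_plasma Buffer- and plasma-chamber concentrations, ng/mL.
#'   Vectorized.
#' @return Unbound fraction(s).
#' @export
#' @examples
#' fu_plasma(20.05, 50)  # 0.401
fu_plasma <- function(c_buffer, c_plasma) {
  stopifnot(is.numeric(c_buffer), is.numeric(c_plasma),
            all(c_buffer >= 0))
  if (any(c_plasma <= 0)) {
    stop("plasma-chamber concentration must be positive", call. = FALSE)
  }
  fu <- c_buffer / c_plasma
  if (any(fu > 1)) {
    warning("unbound fraction exceeds 1 for ", sum(fu > 1),
            " measurement(s); reported unclipped (assay noise)",
            call. = FALSE)
  }
  fu
}

#' Unbound fraction in diluted brain homogenate
#'
#' Ratio of buffer-chamber to diluted-homogenate-chamber concentration. This
#' is the apparent free fraction of the *diluted* tissue and must be corrected
#' for the homogenate dilution with [fu_brain()].
#'
#' @param c_buffer,c_homogenate Chamber concentrations, ng/mL. Vectorized.
#' @return Apparent unbound fraction(s) of the diluted homogenate.
#' @export
fu_diluted <- function(c_buffer, c_homogenate) {
  stopifnot(is.numeric(c_buffer), is.numeric(c_homogenate),
            all(c_buffer >= 0))
  if (any(c_homogenate <= 0)) {
    stop("homogenate-chamber concentration must be positive", call. = FALSE)
  }
  fu <- c_buffer / c_homogenate
  if (any(fu > 1)) {
    warning("unbound fraction exceeds 1 for ", sum(fu > 1),
            " measurement(s); reported unclipped (assay noise)",
            call. = FALSE)
  }
  fu
}

#' Dilution correction for tissue-homogenate unbound fractions
#'
#' Converts the apparent free fraction measured on a D-fold diluted tissue
#' homogenate back to the undiluted tissue:
#' `fu_brain = (1/D) / ((1/fu_diluted - 1) + 1/D)`.
#' At `D = 1` the correction is the identity; for `fu_diluted < 1` the result
#' decreases with `D` and increases with `fu_diluted`.
#'
#' @param fu_dil Apparent unbound fraction of the diluted homogenate, in
#'   (0, 1\]. Vectorized.
#' @param D Dilution factor, >= 1 (default 5, a typical brain-homogenate
#'   dialysis dilution).
#' @return Corrected unbound fraction(s) in undiluted tissue, in (0, 1\].
#' @export
#' @examples
#' fu_brain(0.2, D = 5)  # 0.2 / (4 + 0.2)
fu_brain <- function(fu_dil, D = 5) {
  stopifnot(is.numeric(fu_dil), is.numeric(D), all(D >= 1))
  if (any(fu_dil <= 0)) {
    stop("fu_diluted must be positive (the correction is undefined at 0)",
         call. = FALSE)
  }
  if (any(fu_dil > 1)) {
    warning("fu_diluted exceeds 1; corrected value will exceed 1",
            call. = FALSE)
  }
  (1 / D) / ((1 / fu_dil - 1) + 1 / D)
}

# inverse of fu_brain; used for round-trip checks
fu_diluted_from_brain <- function(fu_br, D = 5) {
  1 / ((1 / fu_br - 1) / D + 1)
}

#' Reduce a table of dialysis measurements to unbound fractions
#'
#' Tidy wrapper over [fu_plasma()], [fu_diluted()] and [fu_brain()] for a
#' table of paired chamber concentrations. Plasma rows use the direct ratio;
#' brain-homogenate rows apply the dilution correction with each row's
#' dilution factor.
#'
#' @param data A data frame with columns `c_buffer`, `c_matrix` (chamber
#'   concentrations, ng/mL), `kind` (`"plasma"` or `"brain_homogenate"`) and,
#'   for homogenate rows, `dilution_factor` (>= 1; taken as 1 when absent).
#' @return The input with columns `fu_diluted` (homogenate rows) and `fu`
#'   (the matrix-level unbound fraction) appended.
#' @export
dialysis_fu <- function(data) {
  stopifnot(all(c("c_buffer", "c_matrix", "kind") %in% names(data)),
            all(data$kind %in% c("plasma", "brain_homogenate")))
  if (!"dilution_factor" %in% names(data)) data$dilution_factor <- 1
  data$dilution_factor[is.na(data$dilution_factor)] <- 1
  stopifnot(all(data$dilution_factor >= 1))
  is_pl <- data$kind == "plasma"
  data$fu_diluted <- NA_real_
  data$fu <- NA_real_
  if (any(is_pl)) {
    data$fu[is_pl] <- fu_plasma(data$c_buffer[is_pl], data$c_matrix[is_pl])
  }
  if (any(!is_pl)) {
    fud <- fu_diluted(data$c_buffer[!is_pl], data$c_matrix[!is_pl])
    data$fu_diluted[!is_pl] <- fud
    data$fu[!is_pl] <- fu_brain(fud, data$dilution_factor[!is_pl])
  }
  tibble::as_tibble(data)
}

#' Brain-penetration partition coefficients
#'
#' Combines brain and plasma exposures with the matched unbound fractions
#' into the total and unbound brain-to-plasma partition coefficients:
#' `Kp_brain = AUC_brain / AUC_plasma` and
#' `Kp_uu_brain = (fu_brain * AUC_brain) / (fu_plasma * AUC_plasma)`.
#' A `Kp_uu_brain` above 1 indicates net uptake into the brain beyond passive
#' equilibration of unbound drug.
#'
#' @param auc_brain,auc_plasma Exposure point estimates over the same time
#'   span, h*ng/g and h*ng/mL (or [batch_auc()] objects).
#' @param fu_brain,fu_plasma Unbound fractions in brain tissue and plasma.
#' @return A one-row tibble with `kp_brain`, `kp_uu_brain` and the four
#'   inputs. By construction `kp_uu_brain == kp_brain * fu_brain / fu_plasma`.
#' @export
#' @examples
#' brain_penetration(3950, 462, fu_brain = 0.291, fu_plasma = 0.401)
brain_penetration <- function(auc_brain, auc_plasma, fu_brain, fu_plasma) {
  val <- function(x) if (inherits(x, "batch_auc")) x$auc else x
  auc_brain <- val(auc_brain); auc_plasma <- val(auc_plasma)
  stopifnot(is.numeric(auc_brain), is.numeric(auc_plasma),
            is.numeric(fu_brain), is.numeric(fu_plasma))
  if (any(auc_plasma <= 0)) stop("plasma AUC must be positive", call. = FALSE)
  if (any(fu_plasma <= 0)) {
    stop("plasma unbound fraction must be positive", call. = FALSE)
  }
  kp <- auc_brain / auc_plasma
  tibble::tibble(
    kp_brain = kp,
    kp_uu_brain = kp * fu_brain / fu_plasma,
    auc_brain = auc_brain, auc_plasma = auc_plasma,
    fu_brain = fu_brain, fu_plasma = fu_plasma
  )
}
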