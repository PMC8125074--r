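#' GC-density calibration and DNA molecular-weight labeling model
#'
#' Bundles the constants linking a genome's GC content to the buoyant
#' density of its unlabeled DNA and to the average molecular weight of a
#' nucleotide, used to convert a buoyant-density shift into the excess
#' atom fraction (EAF) of \eqn{^{13}}C in that taxon's DNA.
#'
#' The unlabeled buoyant density of DNA with GC fraction \eqn{G} is
#' \eqn{\rho = b_G + m_G G}; the average nucleotide molecular weight is
#' \eqn{M = 0.496 G + 307.691} g/mol; an average nucleotide carries
#' \eqn{N_C(G) = 10 - 0.5 G} carbon atoms (A, T and G have 10 carbons, C
#' has 9). Full \eqn{^{13}}C substitution adds \eqn{N_C(G)\,\Delta m}
#' g/mol, with \eqn{\Delta m = 1.003355} the \eqn{^{13}}C-\eqn{^{12}}C
#' mass difference.
#'
#' @param gc_slope Density increase per unit GC fraction (g/ml).
#' @param gc_intercept Buoyant density of GC = 0 DNA (g/ml).
#' @param mw_slope Molecular-weight increase per unit GC fraction (g/mol).
#' @param mw_intercept Molecular weight at GC = 0 (g/mol).
#' @param delta_mass_13C Mass difference between 13C and 12C (g/mol).
#' @param natural_13C Natural abundance of 13C (atom fraction).
#' @return An object of class `labeling_model`.
#' @examples
#' m <- labeling_model()
#' excess_atom_fraction(1.70, 0.005, m)  # ~0.092, i.e. ~9 APE
#' @export
labeling_model <- function(gc_slope = 0.083506,
                           gc_intercept = 1.646057,
                           mw_slope = 0.496,
                           mw_intercept = 307.691,
                           delta_mass_13C = 1.003355,
                           natural_13C = 0.011112) {
  stopifnot(gc_slope > 0, delta_mass_13C > 0,
            natural_13C >= 0, natural_13C < 1)
  structure(
    list(gc_slope = gc_slope, gc_intercept = gc_intercept,
         mw_slope = mw_slope, mw_intercept = mw_intercept,
         delta_mass_13C = delta_mass_13C, natural_13C = natural_13C),
    class = "labeling_model"
  )
}

#' @export
print.labeling_model <- function(x, ...) {
  cat("Labeling model (13C qSIP)\n")
  cat(sprintf("  density(GC):  %.6f + %.6f * GC  [g/ml]\n",
              x$gc_intercept, x$gc_slope))
  cat(sprintf("  MW(GC):       %.3f + %.3f * GC  [g/mol]\n",
              x$mw_intercept, x$mw_slope))
  cat(sprintf("  delta m 13C:  %.6f g/mol; natural 13C: %.6f\n",
              x$delta_mass_13C, x$natural_13C))
  invisible(x)
}

#' Carbon atoms per average nucleotide
#'
#' A, T and G contribute 10 carbon atoms per nucleotide, C contributes 9,
#' so the average over a genome of GC fraction `gc` is `10 - 0.5 * gc`.
#'
#' @param gc GC content as a fraction in \[0, 1\].
#' @return Carbon atoms per average nucleotide (between 9.5 and 10).
#' @export
carbon_atoms <- function(gc) {
  stopifnot(all(is.finite(gc)), all(gc >= 0 & gc <= 1))
  10 - 0.5 * gc
}

#' Infer GC content from unlabeled buoyant density
#'
#' Inverts the linear GC-density calibration. Values outside \[0, 1\] are
#' clipped with a warning (densities slightly outside the calibrated range
#' occur with measurement noise).
#'
#' @param w_light Unlabeled (light) buoyant density, g/ml.
#' @param model A [labeling_model()].
#' @return GC fraction in \[0, 1\].
#' @export
density_to_gc <- function(w_light, model = labeling_model()) {
  if (!all(is.finite(w_light))) stop("non-finite density in density_to_gc")
  g <- (w_light - model$gc_intercept) / model$gc_slope
  if (any(g < -1e-9 | g > 1 + 1e-9))
    warning("GC estimate outside [0, 1]; clipping")
  pmin(pmax(g, 0), 1)
}

#' Unlabeled buoyant density of DNA of a given GC content
#'
#' @param gc GC fraction in \[0, 1\].
#' @inheritParams density_to_gc
#' @return Buoyant density, g/ml. Exact inverse of [density_to_gc()].
#' @export
gc_to_density <- function(gc, model = labeling_model()) {
  stopifnot(all(is.finite(gc)), all(gc >= 0 & gc <= 1))
  model$gc_intercept + model$gc_slope * gc
}

#' Excess atom fraction of 13C implied by a buoyant-density shift
#'
#' Converts a labeled-minus-control weighted-mean density difference
#' `delta_w` for a taxon whose unlabeled density is `w_light` into the
#' excess atom fraction of \eqn{^{13}}C in its DNA carbon. The taxon's GC
#' is inferred from `w_light`, giving its light molecular weight
#' \eqn{M_{light}}; the labeled molecular weight is
#' \eqn{M_{lab} = M_{light}(1 + \delta w / w_{light})} and
#' \deqn{EAF = \frac{M_{lab} - M_{light}}{N_C(G)\,\Delta m}(1 - a_{nat}).}
#'
#' EAF is exactly linear in `delta_w` at fixed `w_light`. Negative shifts
#' return negative EAF (never clipped) so that control-control comparisons
#' stay symmetric around zero.
#'
#' @param w_light Unlabeled weighted-mean buoyant density, g/ml (> 0).
#' @param delta_w Labeled minus control weighted-mean density, g/ml.
#' @param model A [labeling_model()].
#' @return Excess atom fraction (atom percent excess is `100 *` this).
#' @export
excess_atom_fraction <- function(w_light, delta_w, model = labeling_model()) {
  if (!all(is.finite(w_light)) || !all(is.finite(delta_w)))
    stop("non-finite input to excess_atom_fraction")
  if (any(w_light <= 0)) stop("w_light must be positive")
  g <- density_to_gc(w_light, model)
  m_light <- model$mw_slope * g + model$mw_intercept
  m_lab <- m_light * (1 + delta_w / w_light)
  dm_max <- carbon_atoms(g) * model$delta_mass_13C
  ((m_lab - m_light) / dm_max) * (1 - model$natural_13C)
}

#' Buoyant-density shift produced by a given excess atom fraction
#'
#' Inverse of [excess_atom_fraction()]; used by the gradient simulator to
#' place labeled band centers.
#'
#' @inheritParams excess_atom_fraction
#' @param eaf Excess atom fraction in \[0, 1\].
#' @return Density shift, g/ml.
#' @export
density_shift_for_eaf <- function(w_light, eaf, model = labeling_model()) {
  if (!all(is.finite(eaf)) || any(eaf < 0 | eaf > 1))
    stop("eaf must be within [0, 1]")
  if (any(w_light <= 0)) stop("w_light must be positive")
  g <- density_to_gc(w_light, model)
  m_light <- model$mw_slope * g + model$mw_intercept
  dm_max <- carbon_atoms(g) * model$delta_mass_13C
  w_light * eaf * dm_max / ((1 - model$natural_13C) * m_light)
}
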