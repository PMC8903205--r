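#' Muscle activation state
#'
#' The simulator's control vector: activation fractions of the five
#' intrinsic laryngeal muscle pairs and the lung pressure. Activations are
#' stored as fractions in \[0, 1\]; the sweep-level constraint rules
#' ([lung_pressure_rule()], [adduction_rule()]) operate on the 0-100
#' percent scale and convert at this boundary.
#'
#' @param aCT,aTA,aLC,aIA,aPCA activation fractions in \[0, 1\].
#' @param PL lung pressure, kPa (>= 0).
#' @return an `activation_state` object.
#' @export
activation_state <- function(aCT = 0, aTA = 0, aLC = 0, aIA = 0, aPCA = 0,
                             PL = 0) {
  act <- list(aCT = aCT, aTA = aTA, aLC = aLC, aIA = aIA, aPCA = aPCA, PL = PL)
  for (nm in c("aCT", "aTA", "aLC", "aIA", "aPCA")) {
    v <- act[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("activation_state: ", nm, " must be a single number in [0, 1]")
  }
  if (!is.numeric(PL) || length(PL) != 1 || is.na(PL) || PL < 0)
    stop("activation_state: PL must be a single number >= 0 (kPa)")
  structure(act, class = "activation_state")
}

#' @export
print.activation_state <- function(x, ...) {
  cat(sprintf(
    "<activation_state> CT=%.2f TA=%.2f LC=%.2f IA=%.2f PCA=%.2f  PL=%.3f kPa\n",
    x$aCT, x$aTA, x$aLC, x$aIA, x$aPCA, x$PL))
  invisible(x)
}

#' Quasi-static vocal fold strain from muscle activations
#'
#' Solves the 1-DOF anterior-posterior force balance
#' \deqn{a_{CT} G_{CT} \sigma_m^{CT} A_{CT} - a_{TA} G_{TA} \sigma_m^{TA}
#'   A_{TA} - \sum_l A_l[\sigma_l(\epsilon) - \sigma_l(0)] = 0}
#' for the strain: CT active force elongates, TA active force shortens,
#' and the area-weighted passive fiber stresses of the three fold layers
#' resist departure from rest. The passive sum is strictly increasing in
#' strain, so the root is unique; it is found by bisection on the
#' configured bracket. The gains are calibrated so the full-CT and
#' full-TA corners reach the 1.9 cm and 1.0 cm fold lengths.
#'
#' @param act an [activation_state()].
#' @param cfg a [vp_config()].
#' @return strain (dimensionless scalar).
#' @export
compute_strain <- function(act, cfg = vp_config()) {
  stopifnot(inherits(act, "activation_state"))
  lay <- cfg$layers
  sm_CT <- lay$sigma_m[lay$layer == "CT"]
  sm_TA <- lay$sigma_m[lay$layer == "TA"]
  f_active <- act$aCT * cfg$gain_CT * sm_CT * cfg$A_CT -
    act$aTA * cfg$gain_TA * sm_TA * cfg$A_TA
  bal <- function(eps) f_active - passive_restoring_force(eps, cfg)
  lo <- cfg$eps_bracket[1]; hi <- cfg$eps_bracket[2]
  flo <- bal(lo); fhi <- bal(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (flo * fhi > 0)
    stop(sprintf(
      "compute_strain: no root in bracket [%g, %g] (F = %g, %g)",
      lo, hi, flo, fhi))
  # deterministic bisection; bal() is strictly decreasing in eps
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    fm <- bal(mid)
    if (abs(fm) < cfg$eps_tol * max(1, abs(f_active)) || (hi - lo) < 1e-12)
      return(mid)
    if (fm > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Empirical posturing rules
#'
#' Maps strain, TA activation and the vocal-process half-width to the
#' full prephonatory geometry: length \eqn{L = L_0(1+\epsilon)},
#' thickness \eqn{T = T_0/(1+\epsilon)} (isovolume), lower adduction
#' half-width \eqn{\xi_{01} = \xi_{02} + \max(0,\, 0.1T(1 - 1.5a_{TA}))}
#' and medial bulging \eqn{\xi_b = 0.05T(1 - a_{TA})}.
#'
#' @param epsilon vocal fold strain (> -1).
#' @param aTA TA activation fraction in \[0, 1\].
#' @param xi02 vocal-process half-width, cm (see [compute_adduction()]).
#' @param cfg a [vp_config()].
#' @return a `postural_geometry` object (named list with `epsilon`, `L`,
#'   `T`, `xi01`, `xi02`, `xib`, all lengths in cm).
#' @export
apply_posture_rules <- function(epsilon, aTA, xi02, cfg = vp_config()) {
  if (epsilon <= -1) stop("apply_posture_rules: strain must exceed -1")
  stopifnot(aTA >= 0, aTA <= 1)
  L <- cfg$L0_cm * (1 + epsilon)
  T <- cfg$T0_cm / (1 + epsilon)
  xi01 <- xi02 + max(0, 0.1 * T * (1 - 1.5 * aTA))
  xib <- 0.05 * T * (1 - aTA)
  structure(list(epsilon = epsilon, L = L, T = T,
                 xi01 = xi01, xi02 = xi02, xib = xib),
            class = "postural_geometry")
}

#' @export
print.postural_geometry <- function(x, ...) {
  cat(sprintf(
    "<postural_geometry> eps=%.4f L=%.3f T=%.3f xi01=%.3f xi02=%.3f xib=%.3f (cm)\n",
    x$epsilon, x$L, x$T, x$xi01, x$xi02, x$xib))
  invisible(x)
}

#' Vocal-process half-width from adductor activations
#'
#' Saturating adduction rule: the LCA/IA pair closes the cartilaginous
#' glottis and the TA contributes a slight medial compression,
#' \deqn{\xi_{02} = \xi_{02}^{rest}\,
#'   e^{-k_{LC}(a_{LC}+a_{IA})/2 - k_{TA} a_{TA}}}
#' which is strictly decreasing in the adductor activations, approaches
#' full closure asymptotically at maximal adduction, and keeps the
#' vocal processes from overlapping at any activation. With the default
#' constants the constraint-rule activation range (LCA/IA 20-60%) lands
#' in (0, 0.05] cm, where the phonation threshold is reachable.
#'
#' @param act an [activation_state()].
#' @param cfg a [vp_config()].
#' @return xi02 in cm.
#' @export
compute_adduction <- function(act, cfg = vp_config()) {
  stopifnot(inherits(act, "activation_state"))
  xi02 <- cfg$xi02_rest_cm *
    exp(-cfg$k_LC * (act$aLC + act$aIA) / 2 - cfg$k_TA * act$aTA)
  max(cfg$xi02_min_cm, xi02)
}

#' Prephonatory medial-surface half-width field
#'
#' Evaluates the glottal half-width at points (y, z) of the medial
#' surface,
#' \deqn{\xi_0(y,z) = (1 - y/L)\,[\xi_{02} + (\xi_{01} - \xi_{02} -
#'   4\xi_b z/T)(1 - z/T)]}
#' with y running along the fold from the vocal process (y = 0, where the
#' half-width interpolates xi01 at the bottom to xi02 at the top) to the
#' zero-width commissure end (y = L), and z from the inferior (z = 0) to
#' the superior (z = T) surface.
#'
#' @param geom a `postural_geometry`.
#' @param y_samples,z_samples numeric vectors of sample positions, cm,
#'   within \[0, L\] and \[0, T\].
#' @return a tibble with columns `y`, `z`, `xi0` (the full grid).
#' @export
medial_surface <- function(geom, y_samples, z_samples) {
  stopifnot(inherits(geom, "postural_geometry"))
  if (any(y_samples < 0 | y_samples > geom$L + 1e-12))
    stop("medial_surface: y samples outside [0, L]")
  if (any(z_samples < 0 | z_samples > geom$T + 1e-12))
    stop("medial_surface: z samples outside [0, T]")
  grid <- tidyr::expand_grid(y = y_samples, z = z_samples)
  grid$xi0 <- xi0_eval(grid$y, grid$z, geom)
  grid
}

# scalar/vector evaluation of the half-width surface
xi0_eval <- function(y, z, geom) {
  (1 - y / geom$L) *
    (geom$xi02 + (geom$xi01 - geom$xi02 - 4 * geom$xib * z / geom$T) *
       (1 - z / geom$T))
}

#' Full posture pipeline
#'
#' Convenience wrapper running adduction, strain balance and the
#' posturing rules for one activation state.
#'
#' @inheritParams compute_strain
#' @return a `postural_geometry`.
#' @export
compute_posture <- function(act, cfg = vp_config()) {
  xi02 <- compute_adduction(act, cfg)
  eps <- compute_strain(act, cfg)
  apply_posture_rules(eps, act$aTA, xi02, cfg)
}
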