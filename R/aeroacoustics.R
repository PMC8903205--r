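#' Vocal tract and subglottal area functions
#'
#' The supraglottal airway is a stylized male /a/ profile (narrow
#' epilarynx and pharynx opening into a wide oral cavity), 44 sections of
#' c/(2 fs) = 0.3968 cm, shipped as a plain-text table; it is a synthetic
#' stand-in for published area measurements, validated by its formant
#' behaviour rather than by table equality. The subglottal airway is 36
#' sections: a 2.5 cm^2 trachea flaring toward a wider lung termination.
#'
#' @param cfg a [vp_config()].
#' @return list with numeric vectors `sub` (lung end first, glottal end
#'   last) and `sup` (glottal end first, lips last), areas in cm^2, and
#'   the section length `dx_cm`.
#' @export
airway_areas <- function(cfg = vp_config()) {
  path <- system.file("extdata", "areas_aa_synthetic.tsv",
                      package = "larynxsim", mustWork = TRUE)
  sup <- utils::read.delim(path)$area_cm2
  stopifnot(length(sup) == cfg$n_sup)
  n_flare <- 8L
  sub <- c(seq(cfg$lung_area_cm2, cfg$trachea_area_cm2, length.out = n_flare),
           rep(cfg$trachea_area_cm2, cfg$n_sub - n_flare))
  list(sub = sub, sup = sup, dx_cm = cfg$c_air / (2 * cfg$fs))
}

#' Radiation reflection filter at the lips
#'
#' First-order digital reflection coefficient for the low-frequency
#' parallel resistance/inertance equivalent of the piston-in-baffle
#' radiation impedance (R = 128/(9 pi^2) rho c / A, L = 8 rho /
#' (3 pi^2 a)), discretized with the bilinear transform at the half-pass
#' rate 2 fs. The reflection tends to -1 at DC (an open end radiates no
#' static pressure).
#'
#' @param A_lip lip opening area, cm^2.
#' @param cfg a [vp_config()].
#' @return list with coefficients `b0`, `b1`, `a1` of
#'   `B[n] = b0 F[n] + b1 F[n-1] - a1 B[n-1]`.
#' @export
radiation_filter <- function(A_lip, cfg = vp_config()) {
  rho <- cfg$rho_air; cc <- cfg$c_air
  Zc <- rho * cc / A_lip
  R <- 128 / (9 * pi^2) * Zc
  a <- sqrt(A_lip / pi)
  L <- 8 * rho / (3 * pi^2 * a)
  K <- 2 * (2 * cfg$fs)            # bilinear constant at the half-pass rate
  alpha <- L * (R - Zc); bet <- -Zc * R
  gam <- L * (R + Zc);  del <- Zc * R
  den <- gam * K + del
  list(b0 = (alpha * K + bet) / den,
       b1 = (bet - alpha * K) / den,
       a1 = (del - gam * K) / den)
}

#' Flow through the glottal constriction
#'
#' Solves the quadratic glottal junction equation: the transglottal
#' driving pressure (twice the difference of the incident waves) is
#' spent on the kinetic pressure loss (rho/2)(ug/Ag)^2 of the glottal jet
#' plus the characteristic-impedance loading of the two tubes. The
#' positive root is taken and flow is rectified at zero; as the glottal
#' area closes the flow tends continuously to zero, and with no acoustic
#' loading it reduces to the Bernoulli orifice law
#' \eqn{u_g = A_g \sqrt{2 P / \rho}}.
#'
#' @param Ag minimum glottal area, cm^2.
#' @param F_sub forward pressure wave incident at the glottal end of the
#'   subglottal tube, dyn/cm^2.
#' @param B_sup backward pressure wave incident at the glottal end of the
#'   supraglottal tube, dyn/cm^2.
#' @param A_sub,A_sup adjacent tube section areas, cm^2.
#' @param cfg a [vp_config()].
#' @return list with `ug` (cm^3/s), the glottal-end pressures `p_sub`,
#'   `p_sup` (dyn/cm^2) and the driving pressure `dp`.
#' @export
glottal_flow <- function(Ag, F_sub, B_sup, A_sub, A_sup, cfg = vp_config()) {
  stopifnot(Ag >= 0)
  cpp_glottal_flow(Ag, F_sub, B_sup, A_sub, A_sup, cfg$rho_air, cfg$c_air)
}

#' Glottal surface pressure profile
#'
#' Bernoulli pressures (energy-conserving, referenced to the subglottal
#' pressure) below the minimum glottal diameter; jet flow at and above it,
#' where the medial surface sees the supraglottal pressure with no
#' recovery. Closed rows get the stagnation (subglottal) pressure on the
#' upstream side.
#'
#' @param a_rows glottal channel area per z-row, inferior first, cm^2.
#' @param ug glottal flow, cm^3/s.
#' @param p_sub,p_sup glottal-end pressures, dyn/cm^2.
#' @param cfg a [vp_config()].
#' @return pressure per row, dyn/cm^2.
#' @export
surface_pressures <- function(a_rows, ug, p_sub, p_sup, cfg = vp_config()) {
  stopifnot(all(is.finite(a_rows)), is.finite(ug))
  as.numeric(cpp_surface_pressures(a_rows, ug, p_sub, p_sup, cfg$rho_air))
}

#' Initialize a wave-reflection airway
#'
#' @param cfg a [vp_config()].
#' @param areas optional override of [airway_areas()].
#' @param PL lung pressure, kPa.
#' @param loss per-section amplitude attenuation factor.
#' @return a `waveguide` state object.
#' @export
waveguide_init <- function(cfg = vp_config(), areas = airway_areas(cfg),
                           PL = 0, loss = cfg$section_loss) {
  rad <- radiation_filter(areas$sup[length(areas$sup)], cfg)
  structure(list(areas = areas, PL_dyn = PL * 1e4, loss = loss, rad = rad,
                 cfg = cfg),
            class = "waveguide")
}

#' Run the airway for a prescribed glottal flow signal
#'
#' Feeds a glottal flow series through the wave-reflection airway (one
#' scattering update per junction per half-sample, two half-passes per
#' sample) and returns the oral pressure together with the pressures on
#' the glottal ends of the two tubes.
#'
#' @param wg a [waveguide_init()] object.
#' @param ug glottal flow series, cm^3/s.
#' @return tibble with columns `po`, `p_sub`, `p_sup` (dyn/cm^2), one row
#'   per sample at `cfg$fs`.
#' @export
waveguide_run <- function(wg, ug) {
  stopifnot(inherits(wg, "waveguide"))
  out <- cpp_wg_run(wg$areas$sub, wg$areas$sup, ug, wg$loss, wg$PL_dyn,
                    0, wg$cfg$rho_air, wg$cfg$c_air,
                    wg$rad$b0, wg$rad$b1, wg$rad$a1)
  tibble::tibble(po = out$po, p_sub = out$p_sub, p_sup = out$p_sup)
}
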