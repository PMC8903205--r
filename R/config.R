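#' Simulator configuration
#'
#' Builds the configuration object used by every stage of the simulator:
#' geometry constants, the layer constitutive table, gel viscoelastic
#' constants, the posturing rule constants, the anterior-posterior strain
#' balance (with its two calibration gains), mesh/integration settings,
#' airway settings, and feature-extraction settings. All internal units
#' are CGS (cm, g, s, dyn/cm^2); 1 kPa = 1e4 dyn/cm^2 at the boundary.
#'
#' The two strain-balance gains are calibrated so that full CT activation
#' alone stretches the fold to 1.9 cm and full TA activation alone
#' shortens it to 1.0 cm (strains +0.1875 and -0.375 from the 1.6 cm rest
#' length). Because the quasi-static balance is affine in each gain, the
#' calibration has a closed form and is evaluated here once.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `vp_config` (a named list).
#' @export
vp_config <- function(...) {
  cfg <- list(
    # rest geometry (cm)
    L0_cm = 1.6,
    T0_cm = 0.7,
    depth_cm = 1.0,          # medial-to-lateral fold depth at the lateral wall
    # adduction rule
    xi02_rest_cm = 0.15,
    k_LC = 3.7,
    k_TA = 0.4,
    xi02_min_cm = 0,         # lower clip for extreme overrides
    # gel constants ("0.5 kPa", "0.1 Pa s" in CGS)
    mu = 5e3,                # dyn/cm^2
    eta = 1.0,               # dyn s/cm^2 = 0.1 Pa s
    damp_ref_hz = 150,       # frequency where Rayleigh damping matches eta
    rho_tissue = 1.04,       # g/cm^3
    poisson_penalty = 50,    # bulk penalty as a multiple of mu
    # constitutive switches
    as_printed = FALSE,
    eps_peak = 0.4,
    fl_width = 1.4,
    fiber_fraction = 0.45,   # effective fiber volume fraction of the tissue
    # strain balance: layer cross-section areas (cm^2); fold section
    # T0 * depth = 0.7 cm^2 split 1:2:7 across SLLP/LIG/TA columns
    A_SLLP = 0.07,
    A_LIG = 0.14,
    A_TA = 0.49,
    A_CT = 0.5,              # CT muscle cross-section acting on the balance
    eps_bracket = c(-0.45, 0.45),
    eps_tol = 1e-9,
    cal_eps_CT = 0.1875,     # strain anchor at full CT, zero TA (L = 1.9 cm)
    cal_eps_TA = -0.375,     # strain anchor at full TA, zero CT (L = 1.0 cm)
    # mesh
    n_slices = 15L,
    n_cols = 10L,
    n_rows = 6L,
    layer_cols = c(SLLP = 1L, LIG = 2L, TA = 7L),
    # time stepping
    fs = 44100,
    collision_stiffness_factor = 3,
    collision_damping_zeta = 0.5,
    abort_disp_cm = 1.0,
    seed = 1L,
    v0_kick_cm_s = 1e-4,     # seeded symmetric-equilibrium-breaking velocity
    pl_ramp_s = 0.01,
    # airway
    rho_air = 1.14e-3,       # g/cm^3
    c_air = 35000,           # cm/s
    n_sub = 36L,
    n_sup = 44L,
    section_loss = 0.996,    # amplitude factor per section traversal
    trachea_area_cm2 = 2.5,
    lung_area_cm2 = 5.0,
    # features
    analysis_window_s = 0.2,
    steady_window_s = 0.1,
    f0_range_hz = c(50, 600),
    f0_conf_threshold = 0.3,
    spl_R_cm = 30,
    spl_Rm = 1,
    spl_offset_db = -7,
    apen_m = 2L,
    apen_tau = 1L,
    apen_r_factor = 0.2,
    apen_r_mode = "sd",      # "sd" (default) or "variance"
    apen_fs_hz = 4410,
    # sweep / oscillation detection
    duration_s = 0.4,
    osc_area_amp_cm2 = 5e-3,
    osc_sustain_ratio = 0.95,
    layer_overrides = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$layers <- layer_params(cfg$layer_overrides)
  cfg <- calibrate_strain_gains(cfg)
  structure(cfg, class = "vp_config")
}

# Sum over fold layers of area-weighted passive stress change from rest;
# the passive restoring force of the anterior-posterior balance (dyn).
passive_restoring_force <- function(epsilon, cfg) {
  lay <- cfg$layers
  areas <- c(SLLP = cfg$A_SLLP, LIG = cfg$A_LIG, TA = cfg$A_TA)
  out <- 0
  for (nm in names(areas)) {
    l <- lay[lay$layer == nm, ]
    out <- out + areas[[nm]] *
      (passive_stress(epsilon, l, cfg$as_printed) -
         passive_stress(0, l, cfg$as_printed))
  }
  out
}

# Closed-form calibration: the balance
#   F(eps) = aCT G_CT sigma_m_CT A_CT - aTA G_TA sigma_m_TA A_TA - P(eps)
# must have roots at the two length anchors, so each gain equals the
# passive restoring force at its anchor divided by the muscle's maximum
# force.
calibrate_strain_gains <- function(cfg) {
  lay <- cfg$layers
  sm_CT <- lay$sigma_m[lay$layer == "CT"]
  sm_TA <- lay$sigma_m[lay$layer == "TA"]
  cfg$gain_CT <- passive_restoring_force(cfg$cal_eps_CT, cfg) / (sm_CT * cfg$A_CT)
  cfg$gain_TA <- -passive_restoring_force(cfg$cal_eps_TA, cfg) / (sm_TA * cfg$A_TA)
  cfg
}

#' @export
print.vp_config <- function(x, ...) {
  cat("<vp_config>\n")
  cat("  rest geometry: L0 =", x$L0_cm, "cm, T0 =", x$T0_cm, "cm, depth =",
      x$depth_cm, "cm\n")
  cat("  gel: mu =", x$mu, "dyn/cm^2, eta =", x$eta, "dyn s/cm^2\n")
  cat("  strain gains: CT =", signif(x$gain_CT, 4), ", TA =",
      signif(x$gain_TA, 4), "\n")
  cat("  mesh:", x$n_slices, "slices x", x$n_cols, "x", x$n_rows, "cells\n")
  cat("  airway:", x$n_sub, "sub +", x$n_sup, "supra sections @", x$fs, "Hz\n")
  invisible(x)
}
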