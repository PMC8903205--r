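#' Build the mechanical system for one activation state
#'
#' Runs the posture pipeline, evaluates the tissue state at the postural
#' strain, builds the layered mesh and assembles the operators, together
#' with the index arrays (medial/inferior/superior surface nodes, areas,
#' collision parameters) the time-stepper needs.
#'
#' @param act an [activation_state()].
#' @param cfg a [vp_config()].
#' @return a `fold_system` list.
#' @export
fold_system <- function(act, cfg = vp_config()) {
  posture <- compute_posture(act, cfg)
  tis <- tissue_state(posture$epsilon, act$aTA, cfg)
  mesh <- build_mesh(posture, cfg)
  sys <- assemble_system(mesh, tis, cfg)

  nc <- mesh$n_cols; nr <- mesh$n_rows; M <- mesh$n_slices
  npsl <- mesh$nodes_per_slice
  dz <- mesh$geom$T / nr
  # medial column node ids, (slice x z-row)
  med_ids <- outer(seq_len(M) - 1L, 0:nr,
                   function(i, k) i * npsl + k * (nc + 1L) + 1L)
  fz <- ifelse(0:nr %in% c(0L, nr), 0.5, 1)
  med_area <- matrix(rep(mesh$dy * dz * fz, each = M), nrow = M)
  slice_wgt <- rep(1, M); slice_wgt[c(1, M)] <- 0.5

  # collision: penalty stiffness as a multiple of the local medial-column
  # elastic stiffness, plus contact damping at the configured ratio
  hx <- (mesh$depth - mean(mesh$xi0)) / nc
  k_col <- cfg$collision_stiffness_factor *
    (cfg$poisson_penalty + 2) * cfg$mu * (mesh$dy * dz * fz) / hx
  m_med <- cfg$rho_tissue * mesh$dy * dz * hx
  c_col <- cfg$collision_damping_zeta * 2 * sqrt(k_col * m_med)

  ninf <- mesh$nodes[mesh$nodes$k == 0L, ]
  nsup <- mesh$nodes[mesh$nodes$k == nr, ]
  fxj <- function(j) ifelse(j %in% c(0L, nc), 0.5, 1)
  inf_area <- (mesh$depth / nc) * mesh$dy * fxj(ninf$j)
  sup_area <- (mesh$depth / nc) * mesh$dy * fxj(nsup$j)

  structure(list(
    act = act, cfg = cfg, posture = posture, tissue = tis,
    mesh = mesh, sys = sys,
    med_ids = med_ids, xi0_med = mesh$xi0, med_area = med_area,
    slice_wgt = slice_wgt, contact_k = k_col, contact_c = c_col,
    inf_ids = ninf$id, inf_area = inf_area,
    sup_ids = nsup$id, sup_area = sup_area
  ), class = "fold_system")
}

#' Time-march a fold system
#'
#' Explicit central-difference integration of the assembled fold coupled
#' to the wave-reflection airways at the acoustic sampling rate. The
#' symmetric prephonatory equilibrium is broken by a tiny seeded random
#' nodal velocity so that flow-induced oscillation can start; the lung
#' pressure is ramped over `cfg$pl_ramp_s`. With `aero = FALSE` the
#' airways are bypassed and a constant per-row medial pressure can be
#' prescribed instead (used for static-deflection and energy checks).
#'
#' @param fsys a [fold_system()].
#' @param duration_s run length, s.
#' @param PL_kPa lung pressure override, kPa (default: the activation
#'   state's).
#' @param aero couple to the airways (default TRUE).
#' @param p_rows_const per-row constant medial pressure (dyn/cm^2) when
#'   `aero = FALSE`.
#' @param u0,v0 optional initial displacement/velocity (full dof vectors).
#' @param seed seed of the symmetry-breaking velocity kick (default
#'   `cfg$seed`); ignored when `v0` is given.
#' @param track_energy also record total mechanical energy per step.
#' @param loss per-section airway attenuation override.
#' @return a `fold_run` list: `series` tibble (t, po, ug, ag), `aborted`,
#'   `max_disp`, final state, and the generating system.
#' @export
simulate_fold <- function(fsys, duration_s = NULL, PL_kPa = NULL,
                          aero = TRUE, p_rows_const = NULL,
                          u0 = NULL, v0 = NULL, seed = NULL,
                          track_energy = FALSE, loss = NULL) {
  stopifnot(inherits(fsys, "fold_system"))
  cfg <- fsys$cfg
  if (is.null(duration_s)) duration_s <- cfg$duration_s
  if (is.null(PL_kPa)) PL_kPa <- fsys$act$PL
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(loss)) loss <- cfg$section_loss
  nsteps <- round(duration_s * cfg$fs)
  ndof <- length(fsys$sys$M)
  if (is.null(u0)) u0 <- numeric(ndof)
  if (is.null(v0)) {
    v0 <- numeric(ndof)
    kick <- local_runif(seed, sum(fsys$sys$free)) * 2 - 1
    v0[fsys$sys$free] <- cfg$v0_kick_cm_s * kick
  }
  nrow_n <- ncol(fsys$med_ids)
  if (is.null(p_rows_const)) p_rows_const <- numeric(nrow_n)
  stopifnot(length(p_rows_const) == nrow_n)

  areas <- airway_areas(cfg)
  rad <- radiation_filter(areas$sup[length(areas$sup)], cfg)
  K <- fsys$sys$K

  out <- cpp_fg_simulate(
    K@p, K@i, K@x, fsys$sys$M, fsys$sys$beta, fsys$sys$damp_a, fsys$sys$free,
    fsys$med_ids, fsys$xi0_med, fsys$med_area, fsys$slice_wgt,
    fsys$mesh$dy, fsys$contact_k, fsys$contact_c,
    fsys$inf_ids, fsys$inf_area, fsys$sup_ids, fsys$sup_area,
    areas$sub, areas$sup, loss, 0, cfg$rho_air, cfg$c_air,
    rad$b0, rad$b1, rad$a1,
    PL_kPa * 1e4, round(cfg$pl_ramp_s * cfg$fs),
    nsteps, 1 / cfg$fs, u0, v0, cfg$abort_disp_cm,
    aero, p_rows_const, track_energy)

  series <- tibble::tibble(
    t = (seq_len(nsteps) - 1) / cfg$fs,
    po = out$po, ug = out$ug, ag = out$ag)
  structure(list(series = series, energy = out$energy,
                 aborted = out$aborted, max_disp = out$max_disp,
                 n_done = out$n_done, u = out$u, v = out$v,
                 fsys = fsys, PL_kPa = PL_kPa, fs = cfg$fs),
            class = "fold_run")
}

#' @export
print.fold_run <- function(x, ...) {
  cat(sprintf("<fold_run> %.3f s @ %d Hz, PL=%.2f kPa%s, max disp %.3g cm\n",
              nrow(x$series) / x$fs, x$fs, x$PL_kPa,
              if (x$aborted) " [ABORTED]" else "", x$max_disp))
  invisible(x)
}

# deterministic uniform draws that do not disturb the caller's RNG
local_runif <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}

#' Self-sustained oscillation check
#'
#' A run counts as oscillating when the glottal-area oscillation in the
#' final analysis window has non-trivial amplitude and at least the
#' configured fraction of the amplitude in the preceding window (the
#' self-sustainment criterion: the oscillation is not decaying away).
#'
#' @param run a `fold_run`.
#' @param cfg a [vp_config()] (defaults to the run's).
#' @return logical scalar.
#' @export
is_oscillating <- function(run, cfg = run$fsys$cfg) {
  if (run$aborted) return(FALSE)
  ag <- run$series$ag
  n <- length(ag)
  nw <- round(cfg$steady_window_s * cfg$fs)
  if (n < 2 * nw) return(FALSE)
  last <- ag[(n - nw + 1):n]
  prev <- ag[(n - 2 * nw + 1):(n - nw)]
  amp_last <- (max(last) - min(last)) / 2
  amp_prev <- (max(prev) - min(prev)) / 2
  amp_last >= cfg$osc_area_amp_cm2 &&
    amp_last >= cfg$osc_sustain_ratio * amp_prev
}

#' Phonation threshold pressure by bisection
#'
#' Finds the lung pressure above which the fixed posture self-sustains
#' oscillation and below which it decays, to the requested resolution.
#'
#' @param fsys a [fold_system()].
#' @param lo,hi search bracket, kPa.
#' @param tol_kPa bisection resolution, kPa.
#' @param duration_s run length per probe, s.
#' @return threshold in kPa, or NA if the bracket does not straddle onset.
#' @export
phonation_threshold <- function(fsys, lo = 0.05, hi = 4.5, tol_kPa = 0.05,
                                duration_s = 0.25) {
  osc <- function(pl) is_oscillating(
    simulate_fold(fsys, duration_s = duration_s, PL_kPa = pl))
  if (osc(lo) || !osc(hi)) return(NA_real_)
  while (hi - lo > tol_kPa) {
    mid <- (lo + hi) / 2
    if (osc(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
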