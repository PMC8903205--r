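#' Lung pressure constraint rule
#'
#' Affine rule tying lung pressure to the CT and TA activation levels so
#' that every grid point stays above phonation threshold:
#' \deqn{P_L = 0.8 + 0.025\,a_{CT} + 0.01\,a_{TA}\ \mathrm{kPa}}
#' with activations on the 0-100 percent scale. The rule spans 0.8 kPa at
#' rest to 4.3 kPa at full co-activation.
#'
#' @param aCT_pct,aTA_pct activation levels in percent (0-100),
#'   vectorized.
#' @return lung pressure, kPa.
#' @export
lung_pressure_rule <- function(aCT_pct, aTA_pct) {
  check_pct(aCT_pct); check_pct(aTA_pct)
  0.8 + 0.025 * aCT_pct + 0.01 * aTA_pct
}

#' LCA/IA adduction constraint rule
#'
#' Affine rule for the balanced LCA/IA activation (percent):
#' \deqn{a_{LC} = a_{IA} = 30 + 0.3\,a_{CT} - 0.1\,a_{TA}}
#' clipped to \[0, 100\] (the clip never triggers on the activation
#' grid). More LCA/IA with CT compensates the abduction that accompanies
#' elongation; TA slightly adducts by itself.
#'
#' @param aCT_pct,aTA_pct activation levels in percent (0-100),
#'   vectorized.
#' @return LCA (= IA) activation, percent.
#' @export
adduction_rule <- function(aCT_pct, aTA_pct) {
  check_pct(aCT_pct); check_pct(aTA_pct)
  pmin(100, pmax(0, 30 + 0.3 * aCT_pct - 0.1 * aTA_pct))
}

check_pct <- function(x) {
  if (any(!is.finite(x) | x < 0 | x > 100))
    stop("activation percent out of [0, 100]")
  invisible(x)
}

#' Enumerate the TA-CT activation grid
#'
#' @param grid_step_pct grid step in percent; must divide 100.
#' @return tibble with one row per cell: `aTA_pct`, `aCT_pct`, `PL_kPa`,
#'   `aLC_pct` from the constraint rules (PCA fixed at 0).
#' @export
sweep_grid <- function(grid_step_pct = 5) {
  if (100 %% grid_step_pct != 0)
    stop("grid_step_pct must divide 100")
  lv <- seq(0, 100, by = grid_step_pct)
  g <- tidyr::expand_grid(aCT_pct = lv, aTA_pct = lv)
  dplyr::mutate(g,
    PL_kPa = lung_pressure_rule(.data$aCT_pct, .data$aTA_pct),
    aLC_pct = adduction_rule(.data$aCT_pct, .data$aTA_pct))
}

#' Activation state of a grid cell
#'
#' Applies the constraint rules to one (aCT, aTA) percent pair: LCA = IA
#' from the adduction rule, PCA at 0, lung pressure from the pressure
#' rule; converts to fractions at the posture boundary.
#'
#' @param aCT_pct,aTA_pct activation levels in percent.
#' @param PL_kPa optional lung pressure override, kPa.
#' @return an [activation_state()].
#' @export
grid_activation <- function(aCT_pct, aTA_pct, PL_kPa = NULL) {
  aLC <- adduction_rule(aCT_pct, aTA_pct) / 100
  if (is.null(PL_kPa)) PL_kPa <- lung_pressure_rule(aCT_pct, aTA_pct)
  activation_state(aCT = aCT_pct / 100, aTA = aTA_pct / 100,
                   aLC = aLC, aIA = aLC, aPCA = 0, PL = PL_kPa)
}

#' Simulate one activation grid point
#'
#' Runs the full pipeline for one (aCT, aTA) cell: posture, tissue state,
#' flow-induced oscillation coupled to the airways for the configured
#' duration, then acoustic features of the radiated pressure and
#' steady-state postural averages (final 100 ms). A numerically failed
#' run is reported with status `"failed"` and missing features, never as
#' an error.
#'
#' @param aCT_pct,aTA_pct activation levels in percent.
#' @param cfg a [vp_config()].
#' @param PL_kPa optional lung pressure override, kPa.
#' @param keep_run also return the `fold_run` object as an attribute.
#' @return one-row tibble: activations, PL, status (`oscillating`,
#'   `non-oscillating` or `failed`), `fo_Hz`, `SPL_dB`, `NSC`, `ApEn`,
#'   `L_cm`, `sigma_SLLP`, `sigma_lig`, `sigma_mus` (dyn/cm^2).
#' @export
run_point <- function(aCT_pct, aTA_pct, cfg = vp_config(), PL_kPa = NULL,
                      keep_run = FALSE) {
  act <- grid_activation(aCT_pct, aTA_pct, PL_kPa)
  fsys <- fold_system(act, cfg)
  run <- simulate_fold(fsys)

  sig <- setNames(fsys$tissue$sigma_y, fsys$tissue$layer)
  n <- nrow(run$series)
  post_series <- tibble::tibble(
    L_cm = rep(fsys$posture$L, n),
    sigma_SLLP = rep(sig[["SLLP"]], n),
    sigma_lig = rep(sig[["LIG"]], n),
    sigma_mus = rep(sig[["TA"]], n))
  post <- steady_state_postural(post_series, cfg$fs, cfg)

  status <- if (run$aborted) "failed"
    else if (is_oscillating(run, cfg)) "oscillating" else "non-oscillating"
  feats <- if (status == "oscillating") {
    acoustic_features(run$series$po, cfg$fs, cfg)
  } else {
    tibble::tibble(fo_Hz = NA_real_, SPL_dB = NA_real_,
                   NSC = NA_real_, ApEn = NA_real_)
  }
  out <- dplyr::bind_cols(
    tibble::tibble(aTA_pct = aTA_pct, aCT_pct = aCT_pct,
                   PL_kPa = act$PL, aLC_pct = act$aLC * 100,
                   status = status),
    feats, post)
  if (keep_run) attr(out, "run") <- run
  out
}

#' Run the TA-CT activation sweep
#'
#' Simulates every cell of the activation grid through [run_point()] and
#' assembles the feature map. Cells are cached by (aCT, aTA, config,
#' step) within the supplied cache environment, so an interrupted sweep
#' can be resumed by calling again with the same cache.
#'
#' @param grid_step_pct grid step in percent (5 gives the full 441-cell
#'   map; 25 the reduced 5x5 map).
#' @param cfg a [vp_config()].
#' @param cache an environment used as cell cache (optional).
#' @param progress print one line per cell.
#' @return a `feature_map` tibble (one row per cell) with the sweep
#'   metadata in attributes.
#' @export
run_sweep <- function(grid_step_pct = 5, cfg = vp_config(),
                      cache = NULL, progress = FALSE) {
  grid <- sweep_grid(grid_step_pct)
  key_cfg <- config_hash(cfg)
  rows <- purrr::pmap(list(grid$aCT_pct, grid$aTA_pct), function(ct, ta) {
    key <- sprintf("%s_%g_%g", key_cfg, ct, ta)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    row <- run_point(ct, ta, cfg)
    if (progress)
      message(sprintf("aCT=%3g aTA=%3g -> %s", ct, ta, row$status))
    if (!is.null(cache)) cache[[key]] <- row
    row
  })
  map <- dplyr::bind_rows(rows)
  attr(map, "grid_step_pct") <- grid_step_pct
  attr(map, "config_hash") <- key_cfg
  attr(map, "duration_s") <- cfg$duration_s
  attr(map, "seed") <- cfg$seed
  class(map) <- c("feature_map", class(map))
  map
}

# short stable digest of the configuration (no external digest dep)
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}
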