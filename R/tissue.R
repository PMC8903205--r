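#' Load the per-layer constitutive parameter table
#'
#' Returns the packaged table of passive stress-strain parameters for the
#' five intrinsic laryngeal muscles (CT, LCA, TA, IA, PCA), the vocal
#' ligament (LIG) and the superficial layer of the lamina propria (SLLP).
#' For each layer the passive fiber stress along the fiber direction is a
#' combined linear + exponential function of strain with scale factors
#' `sigma0` and `sigma2` (dyn/cm^2), exponential rate `B`, the strain
#' `eps1` where the linear part starts and the strain `eps2` where the
#' exponential part starts. Muscles additionally carry a maximum isometric
#' active stress `sigma_m` (dyn/cm^2).
#'
#' @param overrides optional named list of per-layer overrides, e.g.
#'   `list(LIG = list(B = 13))`.
#' @return a tibble with one row per layer.
#' @export
layer_params <- function(overrides = NULL) {
  path <- system.file("extdata", "layer_params.tsv", package = "larynxsim",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tibble::as_tibble(tab)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, tab$layer)
      if (is.na(i)) stop("unknown layer in overrides: ", nm)
      for (field in names(overrides[[nm]])) {
        tab[[field]][i] <- overrides[[nm]][[field]]
      }
    }
  }
  stopifnot(all(tab$eps1 < tab$eps2))
  tab
}

#' Passive fiber stress of a vocal fold tissue layer
#'
#' Combined linear + exponential stress-strain law along the fiber
#' direction,
#' \deqn{\sigma_y(\epsilon) = \sigma_{lin}(\epsilon) +
#'   \sigma_2 [e^{B(\epsilon-\epsilon_2)} - 1 - B(\epsilon-\epsilon_2)]}
#' where the exponential bracket is zeroed for strains at or below
#' `eps2` (this keeps the law C1-continuous there). The default linear
#' term is \eqn{-(\sigma_0/\epsilon_1)(\epsilon - \epsilon_1)}, i.e. a
#' positive slope through \eqn{\sigma_0} at zero strain since
#' \eqn{\epsilon_1 < 0}, consistent with sigma0's role as a scale factor;
#' `as_printed = TRUE` switches the linear term to the literal
#' \eqn{-\sigma_0(\epsilon - \epsilon_1)} form (negative slope).
#'
#' @param epsilon strain (dimensionless), vectorized.
#' @param layer a one-row data frame (a row of [layer_params()]) or a list
#'   with fields `sigma0`, `sigma2`, `B`, `eps1`, `eps2`.
#' @param as_printed logical; reproduce the literal negative-slope linear
#'   term instead of the corrected positive-slope form.
#' @return fiber stress in dyn/cm^2, same length as `epsilon`.
#' @export
passive_stress <- function(epsilon, layer, as_printed = FALSE) {
  stopifnot(all(epsilon > -1), all(epsilon < 1))
  lin <- if (as_printed) {
    -layer$sigma0 * (epsilon - layer$eps1)
  } else {
    -(layer$sigma0 / layer$eps1) * (epsilon - layer$eps1)
  }
  de <- epsilon - layer$eps2
  ex <- ifelse(de > 0, layer$sigma2 * (exp(layer$B * de) - 1 - layer$B * de), 0)
  as.numeric(lin + ex)
}

#' Active muscle fiber stress (quasi-static)
#'
#' Quasi-static reduction of the active stress of an intrinsic laryngeal
#' muscle: activation times maximum isometric stress times a Gaussian
#' force-length factor peaking at strain `eps_peak`,
#' \deqn{\sigma_{act} = a\,\sigma_m\,\exp[-((\epsilon -
#'   \epsilon_{peak})/w)^2]}.
#'
#' @param a activation level in \[0, 1\].
#' @param epsilon fiber strain.
#' @param layer a muscle row of [layer_params()] (must have finite `sigma_m`).
#' @param eps_peak strain of peak active force (default 0.4).
#' @param fl_width Gaussian width of the force-length factor (default 0.6).
#' @return active stress in dyn/cm^2.
#' @export
active_stress <- function(a, epsilon, layer, eps_peak = 0.4, fl_width = 0.6) {
  stopifnot(all(a >= 0), all(a <= 1))
  if (is.null(layer$sigma_m) || is.na(layer$sigma_m))
    stop("active_stress: layer '", layer$layer, "' is not a muscle (no sigma_m)")
  fl <- exp(-((epsilon - eps_peak) / fl_width)^2)
  as.numeric(a * layer$sigma_m * fl)
}

#' Fiber-equivalent transverse shear modulus
#'
#' A taut fiber resists transverse displacement with a restoring force per
#' unit length proportional to its tension, so the fiber contribution to
#' the transverse shear modulus equals the tensile fiber stress; a slack
#' (compressed) fiber contributes nothing.
#'
#' @param sigma_y fiber stress, dyn/cm^2 (vectorized).
#' @return mu_prime = max(0, sigma_y), dyn/cm^2.
#' @export
fiber_shear_modulus <- function(sigma_y) {
  stopifnot(all(is.finite(sigma_y)))
  pmax(0, sigma_y)
}

#' Per-layer tissue state at a given posture
#'
#' Evaluates the passive (and, for the TA muscle, active) fiber stress of
#' the three vocal fold layers at the postural strain and converts it to
#' the fiber-equivalent shear modulus used by the gel model.
#'
#' @param epsilon vocal fold strain.
#' @param aTA TA activation fraction in \[0, 1\] (adds active stress to the
#'   muscle layer).
#' @param cfg a [vp_config()] object.
#' @return a tibble with one row per fold layer (SLLP, LIG, TA) and columns
#'   `sigma_y` (dyn/cm^2), `mu_prime` (dyn/cm^2), plus the gel constants
#'   `mu` and `eta` as attributes-free columns.
#' @export
tissue_state <- function(epsilon, aTA, cfg = vp_config()) {
  lay <- cfg$layers
  rows <- c("SLLP", "LIG", "TA")
  sig <- vapply(rows, function(nm) {
    l <- lay[lay$layer == nm, ]
    s <- passive_stress(epsilon, l, as_printed = cfg$as_printed)
    if (nm == "TA" && aTA > 0)
      s <- s + active_stress(aTA, epsilon, l,
                             eps_peak = cfg$eps_peak, fl_width = cfg$fl_width)
    s
  }, numeric(1))
  tibble::tibble(
    layer = rows,
    sigma_y = as.numeric(sig),
    mu_prime = fiber_shear_modulus(as.numeric(sig)),
    mu = cfg$mu,
    eta = cfg$eta
  )
}
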