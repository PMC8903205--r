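#' Tidy a feature map
#'
#' Long format of a [run_sweep()] feature map: one row per cell and
#' feature, convenient for faceted plotting.
#'
#' @param x a `feature_map`.
#' @param ... unused.
#' @return tibble with `aTA_pct`, `aCT_pct`, `status`, `feature`,
#'   `value`.
#' @export
tidy.feature_map <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = -c("aTA_pct", "aCT_pct", "status"),
    names_to = "feature", values_to = "value")
}

#' One-line summary of a feature map
#'
#' @param x a `feature_map`.
#' @param ... unused.
#' @return one-row tibble: cell counts by status and the observed fo and
#'   SPL ranges over oscillating cells.
#' @export
glance.feature_map <- function(x, ...) {
  osc <- x[x$status == "oscillating", ]
  tibble::tibble(
    n_cells = nrow(x),
    n_oscillating = nrow(osc),
    n_failed = sum(x$status == "failed"),
    fo_min = suppressWarnings(min(osc$fo_Hz, na.rm = TRUE)),
    fo_max = suppressWarnings(max(osc$fo_Hz, na.rm = TRUE)),
    SPL_min = suppressWarnings(min(osc$SPL_dB, na.rm = TRUE)),
    SPL_max = suppressWarnings(max(osc$SPL_dB, na.rm = TRUE)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Muscle activation contour plot
#'
#' Filled-contour muscle activation plot of one feature over the TA-CT
#' grid (TA on the x axis, CT on the y axis, both percent).
#' Non-oscillating and failed cells are blank.
#'
#' @param object a `feature_map` from [run_sweep()].
#' @param feature column to plot (default `"fo_Hz"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.feature_map <- function(object, feature = "fo_Hz", ...) {
  df <- tibble::as_tibble(object)
  if (!feature %in% names(df)) stop("unknown feature: ", feature)
  df$value <- df[[feature]]
  df$value[df$status != "oscillating" &
             feature %in% c("fo_Hz", "SPL_dB", "NSC", "ApEn")] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$aTA_pct, .data$aCT_pct)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$value),
                          colour = "grey20", na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(name = feature, na.value = "white") +
    ggplot2::labs(x = "TA activation (%)", y = "CT activation (%)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Export contour maps and tidy CSVs of a feature map
#'
#' Writes, for each requested feature, a tidy CSV and (optionally) a
#' contour plot image into `dir`. The full map CSV (`feature_map.csv`) is
#' always written.
#'
#' @param map a `feature_map`.
#' @param dir output directory (created if needed).
#' @param which feature columns to export (default: all standard maps).
#' @param plots also write PNG contour plots.
#' @return invisibly, the paths written.
#' @export
export_maps <- function(map, dir,
                        which = c("PL_kPa", "aLC_pct", "fo_Hz", "SPL_dB",
                                  "NSC", "ApEn", "L_cm", "sigma_SLLP",
                                  "sigma_lig", "sigma_mus"),
                        plots = TRUE) {
  if (!nrow(map)) stop("export_maps: empty map")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "feature_map.csv")
  utils::write.csv(tibble::as_tibble(map), paths[1], row.names = FALSE)
  for (f in intersect(which, names(map))) {
    p <- file.path(dir, paste0("map_", f, ".csv"))
    utils::write.csv(map[, c("aTA_pct", "aCT_pct", "status", f)], p,
                     row.names = FALSE)
    paths <- c(paths, p)
    if (plots) {
      pp <- file.path(dir, paste0("map_", f, ".png"))
      ggplot2::ggsave(pp, autoplot(map, f), width = 5, height = 4, dpi = 120)
      paths <- c(paths, pp)
    }
  }
  invisible(paths)
}
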