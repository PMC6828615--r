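#' Biofilm volume per unit substratum area
#'
#' A mean thickness of `T` um over 1 cm2 = 1e8 um2 of substratum gives
#' `V = T * 1e8` um3/cm2.
#'
#' @param mean_thickness_um Mean biofilm thickness in um (>= 0).
#' @return Volume in um3 per cm2.
#' @examples
#' biofilm_volume_per_area(252)  # 2.52e10
#' @export
biofilm_volume_per_area <- function(mean_thickness_um) {
  if (any(mean_thickness_um < 0, na.rm = TRUE))
    stop("thickness must be non-negative")
  mean_thickness_um * 1e8
}

#' Bacterial cell volume per unit substratum area
#'
#' @param tcc Total cell concentration in cells/cm2 (>= 0).
#' @param mean_cell_volume Mean volume of a single cell in um3
#'   (default 0.3, an SEM-derived estimate).
#' @return Cell volume in um3 per cm2.
#' @examples
#' cell_volume_per_area(3.8e7)  # 1.14e7
#' @export
cell_volume_per_area <- function(tcc, mean_cell_volume = 0.3) {
  if (any(tcc < 0, na.rm = TRUE) || mean_cell_volume < 0)
    stop("inputs must be non-negative")
  tcc * mean_cell_volume
}

#' Volume fraction of bacterial cells in the biofilm
#'
#' The ratio of summed cell volume to total biofilm volume per unit area
#' (V_cells : V_biofilm), in percent.
#'
#' @param v_cells Cell volume per area (um3/cm2).
#' @param v_biofilm Biofilm volume per area (um3/cm2); must be > 0.
#' @return Percentage; `NA` (with a warning) where `v_biofilm` is 0.
#' @examples
#' volume_fraction(6.8e6, 2.5e10)  # ~0.027%
#' @export
volume_fraction <- function(v_cells, v_biofilm) {
  if (any(v_cells < 0, na.rm = TRUE) || any(v_biofilm < 0, na.rm = TRUE))
    stop("volumes must be non-negative")
  out <- ifelse(v_biofilm > 0, v_cells / v_biofilm * 100, NA_real_)
  if (any(!is.na(v_biofilm) & v_biofilm == 0))
    warning("v_biofilm is 0; volume fraction undefined there")
  out
}

#' Total bacteria over the hose
#'
#' Sums per-section TCC times a section area. The default `"unit"` area
#' model assigns 1 cm2 per section, which reproduces published hose totals
#' computed as average concentration times section count. The `"geometric"`
#' model uses the actual inner half-shell area of a section,
#' `section_length * pi * diameter / 2` (about 1.51 cm2 for a 1.2 cm
#' section of a 0.8 cm bore).
#'
#' @param section_tcc Per-section TCC in cells/cm2 (`NA` dropped).
#' @param area_model `"unit"` or `"geometric"`.
#' @param section_length Section length in cm (geometric model).
#' @param diameter Inner hose diameter in cm (geometric model).
#' @return Total cell count.
#' @examples
#' hose_totals(rep(3.8e7, 200))  # 7.6e9
#' @export
hose_totals <- function(section_tcc, area_model = c("unit", "geometric"),
                        section_length = 1.2, diameter = 0.8) {
  area_model <- match.arg(area_model)
  v <- section_tcc[!is.na(section_tcc)]
  if (any(v < 0)) stop("TCC must be non-negative")
  area <- switch(area_model,
                 unit = 1,
                 geometric = section_length * pi * diameter / 2)
  sum(v * area)
}

#' Volume summary of a section table
#'
#' Convenience wrapper combining the four volume operations for a
#' per-section measurement table.
#'
#' @param sections Data frame with columns `thickness_um` (or
#'   `true_thickness_um`) and `tcc_cells_per_cm2`.
#' @param mean_cell_volume Mean single-cell volume in um3.
#' @param area_model Passed to [hose_totals()].
#' @return Object of class `volume_summary`: list with `v_biofilm`,
#'   `v_cells` (means, um3/cm2), `fraction_pct`, `total_cells`,
#'   `mean_cell_volume`, `area_model`, `n`.
#' @export
volume_summary <- function(sections, mean_cell_volume = 0.3,
                           area_model = "unit") {
  th_col <- intersect(c("thickness_um", "true_thickness_um"),
                      names(sections))[1]
  if (is.na(th_col)) stop("sections must carry a thickness column")
  th <- sections[[th_col]]
  tcc <- sections$tcc_cells_per_cm2
  vb <- biofilm_volume_per_area(mean(th, na.rm = TRUE))
  vc <- cell_volume_per_area(mean(tcc, na.rm = TRUE), mean_cell_volume)
  structure(list(
    v_biofilm = vb, v_cells = vc,
    fraction_pct = volume_fraction(vc, vb),
    total_cells = hose_totals(tcc, area_model),
    mean_cell_volume = mean_cell_volume,
    area_model = area_model,
    n = sum(!is.na(th))
  ), class = "volume_summary")
}

#' @export
print.volume_summary <- function(x, ...) {
  cat(sprintf("Biofilm volume: %.2g um3/cm2; cell volume: %.2g um3/cm2\n",
              x$v_biofilm, x$v_cells))
  cat(sprintf("V_cells:V_biofilm = %.2g%%; total %.2g cells (%s area model)\n",
              x$fraction_pct, x$total_cells, x$area_model))
  invisible(x)
}
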