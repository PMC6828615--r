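#' Configuration for the synthetic hose-biofilm generator
#'
#' Bundles every parameter of the synthetic shower-hose biofilm: the
#' longitudinal thickness field per hose half, per-section total cell
#' concentrations (TCC), and the taxa count table. Defaults emulate a biofilm
#' grown for a year inside a 120 cm PVC-P hose under controlled twice-daily
#' flushing: thickness increasing along the flow direction (0.83 um/cm in the
#' top half, 2.13 um/cm in the bottom half, half means 252 and 386 um),
#' weakly thickness-correlated TCC around 2.4e7 cells/cm2, and a low-diversity
#' community in which three taxa carry ~58% of the reads over a
#' geometric-decay background tail.
#'
#' @param hose_length Sampled hose length in cm.
#' @param section_length Section length in cm; `hose_length / section_length`
#'   must be a whole number of sections per half.
#' @param halves Labels of the two longitudinal halves.
#' @param baseline_thickness Named numeric (one value per half): thickness in
#'   um at the upstream end of the linear trend.
#' @param trend_slope Named numeric per half: linear thickness increase in
#'   um/cm along the flow direction.
#' @param smallscale_cv Named numeric per half: coefficient of variation of
#'   the stationary small-scale thickness fluctuation, relative to the mean
#'   trend level (drives adjacent-section variation).
#' @param topo_wavelength Correlation length of the small-scale topography
#'   ("hills and dunes") in mm.
#' @param field_resolution Longitudinal resolution of the thickness field in
#'   cm (default 0.1 cm = 1 mm).
#' @param tcc_mean Mean TCC in cells/cm2.
#' @param tcc_cv Coefficient of variation of TCC across sections.
#' @param tcc_thickness_corr Target Pearson correlation between per-section
#'   TCC and thickness, in [-1, 1].
#' @param n_taxa Total number of taxa in the community table.
#' @param dominant_profile Named numeric: mean relative abundance of each
#'   dominant taxon; must sum to < 1.
#' @param dominant_anticorr_pair List with elements `taxa` (two taxon names
#'   from `dominant_profile`) and `strength` (log-scale sd of a shared
#'   smooth fluctuation applied as a multiplicative tilt, up for the first
#'   and down for the second taxon).
#' @param step_changes List of localized step changes, each a list with
#'   `taxon`, `half`, `sections` (integer vector of section indices within
#'   the half) and `delta` (additive change in relative abundance).
#' @param composition_noise Sd (log scale) of a smooth per-taxon lognormal
#'   fluctuation of expected proportions along the hose; sets the level of
#'   adjacent-section community dissimilarity.
#' @param background_decay Geometric rank-abundance decay ratio of the
#'   non-dominant background tail, in (0, 1).
#' @param reads_per_section Sequencing reads drawn per section.
#' @param missing_section_prob Probability that a section is missing from the
#'   community table (e.g. failed DNA amplification); missing sections are
#'   dropped, not imputed.
#' @param seed Master seed; fully determines all generator output. Separate
#'   RNG streams are derived for the field, TCC, community and images, so
#'   regenerating one artifact does not shift the others.
#' @return An object of class `sim_config`.
#' @seealso [simulate_hose()], [generate_thickness_field()],
#'   [generate_tcc()], [generate_community()]
#' @export
sim_config <- function(hose_length = 120,
                       section_length = 1.2,
                       halves = c("top", "bottom"),
                       baseline_thickness = c(top = 202.2, bottom = 258.2),
                       trend_slope = c(top = 0.83, bottom = 2.13),
                       smallscale_cv = c(top = 0.12, bottom = 0.24),
                       topo_wavelength = 6,
                       field_resolution = 0.1,
                       tcc_mean = 2.4e7,
                       tcc_cv = 0.2,
                       tcc_thickness_corr = 0.4,
                       n_taxa = 384,
                       dominant_profile = c(Cytophagaceae = 0.247,
                                            Bradyrhizobium = 0.234,
                                            TM6_Dependentiae = 0.096),
                       dominant_anticorr_pair = list(
                         taxa = c("Cytophagaceae", "Bradyrhizobium"),
                         strength = 0.25),
                       step_changes = list(
                         list(taxon = "TM6_Dependentiae", half = "top",
                              sections = 81:91, delta = 0.081)),
                       composition_noise = 0.45,
                       background_decay = 0.9,
                       reads_per_section = 50000,
                       missing_section_prob = 0.025,
                       seed = 1L) {
  n_per_half <- hose_length / section_length
  if (abs(n_per_half - round(n_per_half)) > 1e-8)
    stop("hose_length must be a whole multiple of section_length")
  stopifnot(length(halves) == 2, hose_length > 0, section_length > 0,
            field_resolution > 0, topo_wavelength > 0)
  for (nm in c("baseline_thickness", "trend_slope", "smallscale_cv")) {
    v <- get(nm)
    if (!all(halves %in% names(v)))
      stop(nm, " must be named with an entry per half")
  }
  if (tcc_mean <= 0) stop("tcc_mean must be positive")
  if (tcc_cv < 0) stop("tcc_cv must be non-negative")
  if (abs(tcc_thickness_corr) > 1)
    stop("tcc_thickness_corr must lie in [-1, 1]")
  if (length(dominant_profile) && is.null(names(dominant_profile)))
    stop("dominant_profile must be a named vector")
  if (sum(dominant_profile) >= 1)
    stop("dominant mean abundances must sum to < 1")
  if (any(dominant_profile < 0)) stop("dominant abundances must be >= 0")
  if (n_taxa < length(dominant_profile))
    stop("n_taxa is smaller than the number of configured dominant taxa")
  if (!is.null(dominant_anticorr_pair)) {
    if (!all(dominant_anticorr_pair$taxa %in% names(dominant_profile)))
      stop("anticorrelated pair must name dominant taxa")
    stopifnot(dominant_anticorr_pair$strength >= 0)
  }
  for (st in step_changes) {
    if (!st$taxon %in% names(dominant_profile))
      stop("step change refers to unknown taxon: ", st$taxon)
    if (!st$half %in% halves)
      stop("step change refers to unknown half: ", st$half)
    if (any(st$sections < 1 | st$sections > round(n_per_half)))
      stop("step change section range outside the hose")
  }
  if (missing_section_prob < 0 || missing_section_prob > 1)
    stop("missing_section_prob must be a probability in [0, 1]")
  if (background_decay <= 0 || background_decay >= 1)
    stop("background_decay must lie in (0, 1)")
  stopifnot(reads_per_section >= 1, composition_noise >= 0)

  structure(list(
    hose_length = hose_length, section_length = section_length,
    halves = as.character(halves),
    baseline_thickness = baseline_thickness[halves],
    trend_slope = trend_slope[halves],
    smallscale_cv = smallscale_cv[halves],
    topo_wavelength = topo_wavelength,
    field_resolution = field_resolution,
    tcc_mean = tcc_mean, tcc_cv = tcc_cv,
    tcc_thickness_corr = tcc_thickness_corr,
    n_taxa = as.integer(n_taxa),
    dominant_profile = dominant_profile,
    dominant_anticorr_pair = dominant_anticorr_pair,
    step_changes = step_changes,
    composition_noise = composition_noise,
    background_decay = background_decay,
    reads_per_section = as.integer(reads_per_section),
    missing_section_prob = missing_section_prob,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic hose configuration\n")
  cat("  hose:", x$hose_length, "cm,", x$hose_length / x$section_length,
      "sections of", x$section_length, "cm per half\n")
  cat("  thickness: baseline",
      paste(sprintf("%s=%g", names(x$baseline_thickness),
                    x$baseline_thickness), collapse = ", "),
      "um; slope",
      paste(sprintf("%s=%g", names(x$trend_slope), x$trend_slope),
            collapse = ", "), "um/cm\n")
  cat("  TCC: mean", format(x$tcc_mean, digits = 3), "cells/cm2, cv",
      x$tcc_cv, ", corr with thickness", x$tcc_thickness_corr, "\n")
  cat("  community:", x$n_taxa, "taxa,", length(x$dominant_profile),
      "dominants (", sprintf("%.1f%%", 100 * sum(x$dominant_profile)),
      "of reads ),", x$reads_per_section, "reads/section\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Configuration of the OCT-like imaging model
#'
#' @param image_length Lateral image extent in mm.
#' @param image_height Axial image extent in mm; `image_height * 1000 /
#'   axial_pixel` must be a whole number of rows.
#' @param axial_pixel Axial pixel size in um per pixel.
#' @param lateral_pixel Lateral pixel size in um per pixel.
#' @param noise_sd Sd of additive Gaussian intensity noise (8-bit units).
#' @param artifact_rate Expected number of floating detached-biofilm
#'   artifacts rendered per image (Poisson).
#' @param detection_limit Axial detection limit in um; extracted thickness
#'   below this limit is reported as censored.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(image_length = 2, image_height = 1,
                           axial_pixel = 2.0, lateral_pixel = 4.0,
                           noise_sd = 8, artifact_rate = 0,
                           detection_limit = 4.4) {
  stopifnot(image_length > 0, image_height > 0, axial_pixel > 0,
            lateral_pixel > 0, noise_sd >= 0, artifact_rate >= 0,
            detection_limit >= 0)
  n_rows <- image_height * 1000 / axial_pixel
  if (abs(n_rows - round(n_rows)) > 1e-8)
    stop("image_height * 1000 / axial_pixel must be a whole row count")
  n_cols <- image_length * 1000 / lateral_pixel
  if (abs(n_cols - round(n_cols)) > 1e-8)
    stop("image_length * 1000 / lateral_pixel must be a whole column count")
  structure(list(
    image_length = image_length, image_height = image_height,
    axial_pixel = axial_pixel, lateral_pixel = lateral_pixel,
    noise_sd = noise_sd, artifact_rate = artifact_rate,
    detection_limit = detection_limit,
    n_rows = as.integer(round(n_rows)), n_cols = as.integer(round(n_cols))
  ), class = "imaging_config")
}

# Independent RNG streams per generated artifact, split from the master seed.
derive_stream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  names(s) <- c("field", "tcc", "community", "missing", "images")
  s
}
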