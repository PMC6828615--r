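#' Generate the ground-truth longitudinal thickness field
#'
#' The field per half is `T(x) = baseline + slope * x + e(x)`, where `e` is a
#' stationary Gaussian fluctuation obtained by moving-average smoothing of
#' white noise to the correlation length `topo_wavelength` and scaled so its
#' sd equals `smallscale_cv` times the mean trend level. The field is clipped
#' at zero (thickness cannot be negative).
#'
#' @param cfg A [sim_config()].
#' @return An object of class `thickness_field`: a list with one data frame
#'   per half (`position_cm`, `thickness_um`) plus the grid resolution.
#' @export
generate_thickness_field <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_stream_seeds(cfg$seed)
  set.seed(seeds[["field"]])
  res <- cfg$field_resolution
  x <- seq(0, cfg$hose_length, by = res)
  # moving-average window spanning one topography wavelength
  w <- max(1L, as.integer(round(cfg$topo_wavelength / 10 / res)))
  halves <- lapply(cfg$halves, function(h) {
    trend <- cfg$baseline_thickness[[h]] + cfg$trend_slope[[h]] * x
    if (mean(trend <= 0) > 0.5)
      stop("invalid trend for half '", h,
           "': baseline/slope drive more than half the hose to zero ",
           "thickness")
    z <- stats::rnorm(length(x) + 2L * w)
    if (w > 1L) {
      z <- stats::filter(z, rep(1 / w, w), sides = 2)
    }
    z <- as.numeric(z[(w + 1L):(w + length(x))])
    z <- (z - mean(z)) / stats::sd(z)
    th <- pmax(trend + z * cfg$smallscale_cv[[h]] * mean(trend), 0)
    if (mean(th == 0) > 0.5)
      stop("more than half of the thickness field for half '", h,
           "' clipped to zero; check baseline/slope/cv settings")
    data.frame(position_cm = x, thickness_um = th)
  })
  names(halves) <- cfg$halves
  structure(list(halves = halves, resolution = res,
                 hose_length = cfg$hose_length,
                 section_length = cfg$section_length),
            class = "thickness_field")
}

#' @export
print.thickness_field <- function(x, ...) {
  cat("Thickness field:", x$hose_length, "cm at", x$resolution * 10,
      "mm resolution\n")
  for (h in names(x$halves)) {
    th <- x$halves[[h]]$thickness_um
    cat(sprintf("  %s: mean %.1f um, range %.1f-%.1f um\n", h, mean(th),
                min(th), max(th)))
  }
  invisible(x)
}

#' Per-section mean thickness of a ground-truth field
#'
#' The integral average of the (piecewise-linear) field over each section of
#' `section_length` cm, computed with trapezoidal weights; section `i`
#' covers `[(i-1), i] * section_length`. This is the quantity the imaging
#' pipeline estimates when it averages dense per-column thickness over a
#' section.
#'
#' @param field A `thickness_field`.
#' @return Data frame: `section_id`, `half`, `section_index`, `position_cm`
#'   (midpoint), `true_thickness_um`.
#' @export
field_section_means <- function(field) {
  stopifnot(inherits(field, "thickness_field"))
  sl <- field$section_length
  res <- field$resolution
  n_sec <- as.integer(round(field$hose_length / sl))
  npts <- sl / res
  if (abs(npts - round(npts)) > 1e-8)
    stop("field resolution must divide the section length")
  npts <- as.integer(round(npts))
  out <- do.call(rbind, lapply(names(field$halves), function(h) {
    f <- field$halves[[h]]$thickness_um
    m <- vapply(seq_len(n_sec), function(i) {
      a <- (i - 1L) * npts + 1L
      b <- a + npts
      (sum(f[a:b]) - (f[a] + f[b]) / 2) / npts
    }, numeric(1))
    data.frame(section_id = sprintf("%s_%03d", h, seq_len(n_sec)),
               half = h, section_index = seq_len(n_sec),
               position_cm = (seq_len(n_sec) - 0.5) * sl,
               true_thickness_um = m, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate per-section total cell concentrations
#'
#' TCC is coupled to section thickness through a Gaussian copula-style
#' construction: with `z_thick` the standardized section thickness and
#' `z_ind` independent standard normals,
#' `TCC_i = tcc_mean * (1 + tcc_cv * (rho * z_thick_i +
#' sqrt(1 - rho^2) * z_ind_i))`, clipped at zero. The sample Pearson
#' correlation between TCC and thickness approaches `rho =
#' tcc_thickness_corr` and the coefficient of variation approaches `tcc_cv`.
#'
#' @param field A `thickness_field`.
#' @param cfg The [sim_config()] used to generate the field.
#' @return Data frame: section identifiers plus `tcc_cells_per_cm2`.
#' @export
generate_tcc <- function(field, cfg) {
  stopifnot(inherits(field, "thickness_field"), inherits(cfg, "sim_config"))
  if (cfg$tcc_mean <= 0) stop("tcc_mean must be positive")
  sec <- field_section_means(field)
  if (abs(field$hose_length - cfg$hose_length) > 1e-8 ||
      abs(field$section_length - cfg$section_length) > 1e-8)
    stop("field and config disagree on the hose layout")
  seeds <- derive_stream_seeds(cfg$seed)
  set.seed(seeds[["tcc"]])
  th <- sec$true_thickness_um
  z_thick <- if (stats::sd(th) > 0) (th - mean(th)) / stats::sd(th) else
    rep(0, length(th))
  rho <- cfg$tcc_thickness_corr
  z_ind <- stats::rnorm(length(th))
  tcc <- cfg$tcc_mean *
    (1 + cfg$tcc_cv * (rho * z_thick + sqrt(1 - rho^2) * z_ind))
  sec$tcc_cells_per_cm2 <- pmax(tcc, 0)
  sec
}

#' Generate a synthetic taxa-by-section count table
#'
#' Expected per-section proportions are built from the configured dominant
#' profile plus (i) a smooth lognormal fluctuation of every taxon along the
#' hose (spatial autocorrelation, `composition_noise`), (ii) a shared smooth
#' fluctuation tilting one member of the anticorrelated dominant pair up and
#' the other down, (iii) localized additive step changes, and
#' (iv) a geometric-decay background tail over the non-dominant taxa. Read
#' counts are drawn multinomially per section; sections are dropped
#' (columns of `NA`) with probability `missing_section_prob`.
#'
#' @param cfg A [sim_config()].
#' @return An integer matrix (taxa x sections) of class `community_table`
#'   with taxon rownames and section-id colnames; missing sections are
#'   columns of `NA`.
#' @export
generate_community <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_per_half <- as.integer(round(cfg$hose_length / cfg$section_length))
  n_sec <- 2L * n_per_half
  k <- length(cfg$dominant_profile)
  if (cfg$n_taxa < k)
    stop("n_taxa is smaller than the number of dominant taxa")
  seeds <- derive_stream_seeds(cfg$seed)
  set.seed(seeds[["community"]])

  n_bg <- cfg$n_taxa - k
  taxa <- c(names(cfg$dominant_profile),
            if (n_bg > 0) sprintf("zotu_%04d", seq_len(n_bg)))
  # geometric rank-abundance tail carrying the non-dominant read mass
  bg_w <- if (n_bg > 0) {
    w <- cfg$background_decay^(seq_len(n_bg) - 1L)
    w / sum(w)
  } else numeric(0)
  remaining <- 1 - sum(cfg$dominant_profile)
  base <- c(cfg$dominant_profile, remaining * bg_w)
  names(base) <- taxa

  smooth_series <- function(n, corr_sections = 5L) {
    w <- max(1L, corr_sections)
    z <- stats::rnorm(n + 2L * w)
    if (w > 1L) z <- stats::filter(z, rep(1 / w, w), sides = 2)
    z <- as.numeric(z[(w + 1L):(w + n)])
    (z - mean(z)) / stats::sd(z)
  }

  # smooth per-taxon lognormal fluctuation (half-wise, sections correlated)
  props <- matrix(0, nrow = cfg$n_taxa, ncol = n_sec,
                  dimnames = list(taxa, NULL))
  for (j in seq_len(cfg$n_taxa)) {
    f <- c(smooth_series(n_per_half), smooth_series(n_per_half))
    props[j, ] <- base[j] * exp(cfg$composition_noise * f -
                                  cfg$composition_noise^2 / 2)
  }
  # shared anticorrelated fluctuation of the dominant pair: a multiplicative
  # tilt exp(+/- strength * g) keeps proportions strictly positive for any
  # strength, unlike an additive shift
  pair <- cfg$dominant_anticorr_pair
  if (!is.null(pair) && pair$strength > 0) {
    g <- c(smooth_series(n_per_half), smooth_series(n_per_half))
    props[pair$taxa[1], ] <- props[pair$taxa[1], ] * exp(pair$strength * g)
    props[pair$taxa[2], ] <- props[pair$taxa[2], ] * exp(-pair$strength * g)
  }
  props <- sweep(props, 2, colSums(props), "/")

  # localized step changes: additive in relative abundance
  half_of <- rep(cfg$halves, each = n_per_half)
  idx_in_half <- rep(seq_len(n_per_half), times = 2L)
  delta <- matrix(0, nrow = cfg$n_taxa, ncol = n_sec,
                  dimnames = list(taxa, NULL))
  for (st in cfg$step_changes) {
    cols <- which(half_of == st$half & idx_in_half %in% st$sections)
    delta[st$taxon, cols] <- delta[st$taxon, cols] + st$delta
  }
  adjusted <- props + delta
  if (any(adjusted < 0))
    stop("configured fluctuations/steps drive an expected proportion ",
         "below zero; reduce strength or delta")
  # rescale untouched taxa so every column still sums to one
  touched <- rowSums(delta != 0) > 0
  if (any(touched)) {
    mass_touched_new <- colSums(adjusted[touched, , drop = FALSE])
    mass_touched_old <- colSums(props[touched, , drop = FALSE])
    if (any(mass_touched_new >= 1))
      stop("configured fluctuations/steps exceed the available read mass")
    scale <- (1 - mass_touched_new) / (1 - mass_touched_old)
    props[!touched, ] <- sweep(props[!touched, , drop = FALSE], 2, scale, "*")
    props[touched, ] <- adjusted[touched, , drop = FALSE]
  }

  counts <- matrix(0L, nrow = cfg$n_taxa, ncol = n_sec,
                   dimnames = list(taxa, NULL))
  for (i in seq_len(n_sec))
    counts[, i] <- stats::rmultinom(1, cfg$reads_per_section, props[, i])

  set.seed(seeds[["missing"]])
  missing <- stats::runif(n_sec) < cfg$missing_section_prob
  counts[, missing] <- NA_integer_
  colnames(counts) <- sprintf("%s_%03d", half_of, idx_in_half)
  attr(counts, "true_proportions") <- props
  attr(counts, "missing") <- missing
  class(counts) <- c("community_table", class(counts))
  counts
}

#' Simulate a complete synthetic hose biofilm
#'
#' Runs the three generators off independent RNG streams derived from the
#' master seed and assembles the per-section measurement table.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `hose_simulation` with elements `config`, `field`
#'   (ground-truth thickness), `sections` (data frame: section_id, half,
#'   section_index, position_cm, true_thickness_um, tcc_cells_per_cm2,
#'   missing) and `community` (taxa x section count matrix).
#' @examples
#' sim <- simulate_hose(sim_config(seed = 42))
#' head(sim$sections)
#' @export
simulate_hose <- function(cfg = sim_config()) {
  field <- generate_thickness_field(cfg)
  sections <- generate_tcc(field, cfg)
  community <- generate_community(cfg)
  stopifnot(identical(sections$section_id, colnames(community)))
  sections$missing <- attr(community, "missing")
  structure(list(config = cfg, field = field, sections = sections,
                 community = community),
            class = "hose_simulation")
}

#' @export
print.hose_simulation <- function(x, ...) {
  cat("Synthetic hose biofilm (seed", x$config$seed, ")\n")
  cat(" ", nrow(x$sections), "sections;", sum(x$sections$missing),
      "missing from the community table\n")
  cat(sprintf("  thickness %.0f +/- %.0f um; TCC %.2g +/- %.2g cells/cm2\n",
              mean(x$sections$true_thickness_um),
              stats::sd(x$sections$true_thickness_um),
              mean(x$sections$tcc_cells_per_cm2),
              stats::sd(x$sections$tcc_cells_per_cm2)))
  invisible(x)
}
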