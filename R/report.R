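#' Full heterogeneity report for one hose
#'
#' Runs every analysis stage on a simulated (or measured) hose: per-half
#' longitudinal trends and adjacent-section variation for thickness and
#' TCC, fold ranges, top-versus-bottom comparison, community diversity,
#' dominance and adjacent-section Bray-Curtis, volume reconstruction, and a
#' sampling-representativeness curve. Regenerating with the same
#' configuration and seed yields an identical report.
#'
#' @param sim A `hose_simulation`, or a list with elements `sections` (data
#'   frame) and `community` (count matrix).
#' @param window_sizes Window sizes for the representativeness curve.
#' @param mean_cell_volume Mean single-cell volume in um3.
#' @return Object of class `hose_report` (a nested list; see element names).
#' @export
run_report <- function(sim, window_sizes = c(1, 2, 5, 10, 25, 50, 100),
                       mean_cell_volume = 0.3) {
  sections <- sim$sections
  community <- sim$community
  th_col <- intersect(c("thickness_um", "true_thickness_um"),
                      names(sections))[1]
  halves <- unique(sections$half)
  per_half <- function(col) {
    out <- lapply(halves, function(h) {
      d <- sections[sections$half == h, ]
      list(trend = longitudinal_trend(d[[col]], d$position_cm),
           adjacent = adjacent_variation(d[[col]]),
           mean = mean(d[[col]], na.rm = TRUE),
           sd = stats::sd(d[[col]], na.rm = TRUE),
           fold = fold_range(d[[col]]))
    })
    names(out) <- halves
    out
  }

  thickness <- per_half(th_col)
  tcc <- per_half("tcc_cells_per_cm2")
  halves_compare <- group_compare(
    sections[[th_col]][sections$half == halves[1]],
    sections[[th_col]][sections$half == halves[2]])

  # community: drop sections flagged missing
  comm_masked <- community
  if (!is.null(sections$missing))
    comm_masked[, sections$missing] <- NA_integer_
  div_sec <- diversity_summary(comm_masked, "section")
  div_pool <- diversity_summary(comm_masked, "pooled")
  dom <- dominant_taxa(comm_masked)
  bc <- adjacent_dissimilarity(comm_masked)

  rep_curve <- representativeness_curve(
    sections[[th_col]], window_sizes[window_sizes <= nrow(sections)])

  vol <- volume_summary(sections, mean_cell_volume)

  provenance <- list(
    seed = if (!is.null(sim$config)) sim$config$seed else NA_integer_,
    config_hash = if (!is.null(sim$config)) config_hash(sim$config) else NA,
    package_version = as.character(utils::packageVersion("biofilmscale"))
  )

  structure(list(
    thickness = thickness, tcc = tcc, halves_compare = halves_compare,
    diversity_per_section = div_sec, diversity_pooled = div_pool,
    dominance = dom, adjacent_bray_curtis = bc,
    representativeness = rep_curve, volumes = vol,
    provenance = provenance
  ), class = "hose_report")
}

#' @export
print.hose_report <- function(x, ...) {
  cat("== Hose heterogeneity report ==\n")
  for (h in names(x$thickness)) {
    t <- x$thickness[[h]]
    cat(sprintf(
      "thickness %-7s %.0f +/- %.0f um; slope %.2f um/cm (R2 %.2f); adj. var %.1f +/- %.1f%%\n",
      h, t$mean, t$sd, t$trend$slope, t$trend$r_squared,
      t$adjacent$mean, t$adjacent$sd))
  }
  for (h in names(x$tcc)) {
    t <- x$tcc[[h]]
    cat(sprintf(
      "TCC       %-7s %.2g +/- %.2g cells/cm2 (%.1f-fold); adj. var %.1f +/- %.1f%%\n",
      h, t$mean, t$sd, t$fold, t$adjacent$mean, t$adjacent$sd))
  }
  dp <- x$diversity_pooled
  cat(sprintf("community: pooled S = %d, J' = %.2f; adjacent BC %.2f +/- %.2f\n",
              dp$richness, dp$evenness, x$adjacent_bray_curtis$mean,
              x$adjacent_bray_curtis$sd))
  cat(sprintf("dominants: top-3 share %.1f%%; %d taxa >= %.0f%% of reads\n",
              top_share(x$dominance, 3), length(x$dominance$dominant),
              x$dominance$threshold * 100))
  print(x$volumes)
  invisible(x)
}

#' Write a report to JSON
#'
#' Deterministic serialization (fixed numeric precision) so identical runs
#' produce byte-identical files.
#'
#' @param report A `hose_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  simplify <- function(x) {
    if (inherits(x, "data.frame")) return(x)
    if (is.list(x)) return(lapply(unclass(x), simplify))
    x
  }
  jsonlite::write_json(simplify(unclass(report)), path, digits = 10,
                       auto_unbox = TRUE, force = TRUE, na = "null")
  invisible(path)
}
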