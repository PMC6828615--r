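#' Read and write per-section measurement tables
#'
#' Plain UTF-8 tab-separated files with a header row; "." decimal, no
#' thousands separators. Required columns: `section_id`, `half`,
#' `position_cm`, `true_thickness_um`, `tcc_cells_per_cm2`, `missing`;
#' unknown columns are preserved.
#'
#' @param path File path.
#' @return `read_section_table()`: a data frame; `write_section_table()`:
#'   the path, invisibly.
#' @export
read_section_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  required <- c("section_id", "half", "position_cm", "true_thickness_um",
                "tcc_cells_per_cm2", "missing")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("section table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("position_cm", "true_thickness_um", "tcc_cells_per_cm2")) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "NA")
      if (length(bad))
        stop("non-numeric value in column '", col, "', row ", bad[1],
             ": '", v[bad[1]], "'")
      d[[col]] <- conv
    }
  }
  d$missing <- as.logical(d$missing)
  d
}

#' @rdname read_section_table
#' @param table Data frame as returned by [simulate_hose()]'s `sections`
#'   element or [read_section_table()].
#' @export
write_section_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write taxa-by-section count tables
#'
#' Tab-separated; first column `taxon` holds the taxon label, remaining
#' columns are section ids with integer counts (`NA` for missing sections).
#' Duplicate taxon labels are rejected.
#'
#' @param path File path.
#' @return `read_taxa_table()`: an integer matrix with taxon rownames;
#'   `write_taxa_table()`: the path, invisibly.
#' @export
read_taxa_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "taxon")
    stop("taxa table ", path, " must have 'taxon' as its first column")
  if (anyDuplicated(d$taxon))
    stop("duplicate taxon label(s): ",
         paste(unique(d$taxon[duplicated(d$taxon)]), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("taxa table counts must be numeric")
  storage.mode(m) <- "integer"
  rownames(m) <- d$taxon
  m
}

#' @rdname read_taxa_table
#' @param table Taxa-by-section integer count matrix with rownames.
#' @export
write_taxa_table <- function(table, path) {
  d <- data.frame(taxon = rownames(table), table, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write B-scan images as grayscale TIFF
#'
#' Single-page 8-bit grayscale TIFF; intensity 0-255 maps to [0, 1] in the
#' file. Pixel sizes travel in the function arguments (TIFF tags are not
#' used), so supply the matching [imaging_config()] when reading.
#'
#' @param image A `bscan`.
#' @param path File path (conventionally `{half}_{piece:02d}_{image:02d}.tif`).
#' @return `write_bscan()`: the path, invisibly; `read_bscan()`: a `bscan`
#'   (without ground truth).
#' @export
write_bscan <- function(image, path) {
  stopifnot(inherits(image, "bscan"))
  tiff::writeTIFF(image$intensity / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_bscan
#' @param img_cfg An [imaging_config()] supplying pixel sizes.
#' @export
read_bscan <- function(path, img_cfg = imaging_config()) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure(list(intensity = round(m * 255),
                 axial_pixel = img_cfg$axial_pixel,
                 lateral_pixel = img_cfg$lateral_pixel,
                 truth = NULL),
            class = "bscan")
}

#' Write all rendered hose images to a directory
#'
#' Files are named `{half}_{piece:02d}_{image:02d}.tif`.
#'
#' @param images Output of [render_hose_images()].
#' @param dir Output directory (created if needed).
#' @param layout The [hose_layout()] used for rendering.
#' @return Character vector of written paths, invisibly.
#' @export
write_hose_images <- function(images, dir, layout = hose_layout()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (h in names(images)) {
    for (i in seq_along(images[[h]])) {
      piece <- ((i - 1L) %/% layout$images_per_piece) + 1L
      within <- ((i - 1L) %% layout$images_per_piece) + 1L
      p <- file.path(dir, sprintf("%s_%02d_%02d.tif", h, piece, within))
      write_bscan(images[[h]][[i]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read and write simulation configuration files
#'
#' Structured `key: value` text (YAML). Only scalar and simple list fields
#' are stored; the file round-trips through [sim_config()].
#'
#' @param cfg A [sim_config()].
#' @param path File path.
#' @return `write_sim_config()`: the path, invisibly; `read_sim_config()`:
#'   a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  raw <- unclass(cfg)
  # named numeric vectors serialize as YAML maps, not bare sequences
  for (nm in c("baseline_thickness", "trend_slope", "smallscale_cv",
               "dominant_profile"))
    raw[[nm]] <- as.list(raw[[nm]])
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$baseline_thickness <- unlist(raw$baseline_thickness)
  raw$trend_slope <- unlist(raw$trend_slope)
  raw$smallscale_cv <- unlist(raw$smallscale_cv)
  raw$dominant_profile <- unlist(raw$dominant_profile)
  if (!is.null(raw$dominant_anticorr_pair))
    raw$dominant_anticorr_pair$taxa <-
      unlist(raw$dominant_anticorr_pair$taxa)
  do.call(sim_config, raw)
}

#' Stable hash of a simulation configuration
#'
#' MD5 of the canonical YAML serialization; recorded in reports for
#' provenance.
#'
#' @param cfg A [sim_config()].
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_sim_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Read manual interface overrides from a sidecar file
#'
#' Tab-separated with columns `col_start`, `col_end`, `surface_row`,
#' `substratum_row` (empty/NA = leave unchanged).
#'
#' @param path File path.
#' @return Data frame suitable for [manual_overrides()].
#' @export
read_overrides <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("col_start", "col_end")
  if (!all(need %in% names(d)))
    stop("override file must have col_start and col_end columns")
  d
}
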