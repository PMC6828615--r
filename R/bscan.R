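#' Render an OCT-like B-scan image from a thickness profile
#'
#' Produces a 2D grayscale intensity grid (axial rows x lateral columns) in
#' 8-bit units. Row 1 is nearest the probe (water side); rows increase with
#' depth. Each column shows, from top to bottom: water (level 30), the
#' biofilm band (level 120), and the substratum (level 220), with additive
#' Gaussian noise of sd `noise_sd` everywhere. The substratum interface sits
#' at a fixed depth; the biofilm surface row follows the true thickness at
#' that lateral position. Optionally, floating detached-biofilm artifacts
#' (elliptical blobs at biofilm intensity) are placed in the water above the
#' surface; their bounding boxes are recorded so they can be masked.
#'
#' The true per-column interface rows are stored in the `truth` element as
#' ground truth for round-trip testing; they are not used by the detection
#' code.
#'
#' @param thickness Numeric vector of true thickness (um) per lateral
#'   column, length `img_cfg$n_cols`, or a single value recycled.
#' @param img_cfg An [imaging_config()].
#' @param seed Optional integer seed for noise and artifact placement.
#' @return An object of class `bscan`: list with `intensity` (matrix,
#'   `n_rows` x `n_cols`, values 0-255), `axial_pixel`, `lateral_pixel`,
#'   `truth` (list `surface_row`, `substratum_row`, `artifact_boxes`).
#' @export
render_bscan <- function(thickness, img_cfg = imaging_config(), seed = NULL) {
  stopifnot(inherits(img_cfg, "imaging_config"))
  nr <- img_cfg$n_rows
  nc <- img_cfg$n_cols
  if (length(thickness) == 1L) thickness <- rep(thickness, nc)
  if (length(thickness) != nc)
    stop("thickness must have one value per lateral column (",
         nc, "), got ", length(thickness))
  if (any(thickness < 0)) stop("thickness must be non-negative")
  if (any(thickness > img_cfg$image_height * 1000))
    stop("thickness exceeds the image height of ",
         img_cfg$image_height * 1000, " um")
  if (!is.null(seed)) set.seed(seed)

  # substratum interface at fixed depth, leaving ~100 um of visible substratum
  margin <- as.integer(round(100 / img_cfg$axial_pixel))
  sub_row <- nr - margin
  surf_row <- sub_row - as.integer(round(thickness / img_cfg$axial_pixel))
  if (any(surf_row < 4L))
    stop("thickness too large for the imaging window: biofilm surface ",
         "reaches the top rows of the image")

  row_idx <- matrix(seq_len(nr), nr, nc)
  surf_m <- matrix(surf_row, nr, nc, byrow = TRUE)
  img <- matrix(30, nr, nc)
  img[row_idx >= surf_m & row_idx < sub_row] <- 120
  img[row_idx >= sub_row] <- 220

  boxes <- list()
  if (img_cfg$artifact_rate > 0) {
    n_art <- stats::rpois(1, img_cfg$artifact_rate)
    for (a in seq_len(n_art)) {
      headroom <- min(surf_row) - 6L
      if (headroom < 12L) break
      h <- sample(6:14, 1)                       # axial extent, px
      wdt <- sample(10:40, 1)                    # lateral extent, px
      r0 <- sample(4:max(4L, headroom - h), 1)
      c0 <- sample(seq_len(max(1L, nc - wdt)), 1)
      rows <- r0:min(nr, r0 + h - 1L)
      cols <- c0:min(nc, c0 + wdt - 1L)
      rr <- (rows - mean(rows)) / (length(rows) / 2)
      cc <- (cols - mean(cols)) / (length(cols) / 2)
      blob <- outer(rr^2, cc^2, "+") <= 1
      img[rows, cols][blob] <- 120
      boxes[[length(boxes) + 1L]] <- list(rows = range(rows),
                                          cols = range(cols))
    }
  }
  if (img_cfg$noise_sd > 0)
    img <- img + stats::rnorm(length(img), sd = img_cfg$noise_sd)
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"        # 8-bit payload; halves memory

  structure(list(
    intensity = img,
    axial_pixel = img_cfg$axial_pixel,
    lateral_pixel = img_cfg$lateral_pixel,
    truth = list(surface_row = surf_row,
                 substratum_row = rep(sub_row, nc),
                 artifact_boxes = boxes)
  ), class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat("B-scan image:", nrow(x$intensity), "x", ncol(x$intensity),
      "px (axial", x$axial_pixel, "um/px, lateral", x$lateral_pixel,
      "um/px)\n")
  if (length(x$truth$artifact_boxes))
    cat(" ", length(x$truth$artifact_boxes), "floating artifact(s)\n")
  invisible(x)
}

#' True thickness per lateral image column from a ground-truth field
#'
#' Linearly interpolates the thickness field of one half onto the lateral
#' pixel grid of an image starting at `start_cm`.
#'
#' @param field A `thickness_field`.
#' @param half Half label.
#' @param start_cm Upstream edge of the image in cm.
#' @param img_cfg An [imaging_config()]; the image spans
#'   `img_cfg$image_length` mm from `start_cm`.
#' @return Numeric vector of length `img_cfg$n_cols` (um).
#' @export
field_columns <- function(field, half, start_cm, img_cfg) {
  stopifnot(inherits(field, "thickness_field"))
  d <- field$halves[[half]]
  if (is.null(d)) stop("unknown half: ", half)
  xs <- start_cm + (seq_len(img_cfg$n_cols) - 0.5) *
    img_cfg$lateral_pixel / 1e4          # um -> cm
  if (start_cm < 0 || max(xs) > field$hose_length + 1e-9)
    stop("image extends beyond the hose")
  stats::approx(d$position_cm, d$thickness_um, xout = xs, rule = 2)$y
}

#' Render every B-scan image of a simulated hose
#'
#' Images tile each half contiguously: `images_per_piece * n_pieces` images
#' of `image_length` mm, starting at the upstream end. One RNG substream
#' (derived from the simulation master seed) drives noise and artifacts.
#'
#' @param sim A `hose_simulation` (or a `thickness_field` plus `cfg`).
#' @param img_cfg An [imaging_config()].
#' @param layout A [hose_layout()] consistent with the simulation.
#' @return Nested list: `images[[half]][[i]]` is a `bscan`; attribute
#'   `start_cm` gives image start positions.
#' @export
render_hose_images <- function(sim, img_cfg = imaging_config(),
                               layout = hose_layout()) {
  stopifnot(inherits(sim, "hose_simulation"))
  field <- sim$field
  if (abs(hose_length(layout) - field$hose_length) > 1e-8)
    stop("layout and simulation disagree on hose length")
  seeds <- derive_stream_seeds(sim$config$seed)
  set.seed(seeds[["images"]])
  img_len_cm <- img_cfg$image_length / 10
  n_img <- layout$n_pieces * layout$images_per_piece
  starts <- (seq_len(n_img) - 1L) * img_len_cm
  out <- lapply(layout$halves, function(h) {
    lapply(starts, function(s)
      render_bscan(field_columns(field, h, s, img_cfg), img_cfg))
  })
  names(out) <- layout$halves
  attr(out, "start_cm") <- starts
  out
}
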