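#' Mask image regions with black boxes
#'
#' Reproduces the manual masking step used to remove detached biofilm
#' structures floating above the surface: every pixel inside a box is set to
#' the water background level so it cannot trigger interface detection. The
#' input image is not modified.
#'
#' @param image A `bscan`.
#' @param boxes List of boxes, each a list with `rows = c(first, last)` and
#'   `cols = c(first, last)` (1-based, inclusive). An empty list returns the
#'   image unchanged.
#' @param background Intensity written into masked pixels (default 30, the
#'   water level).
#' @return A new `bscan` with masked intensity.
#' @export
mask_regions <- function(image, boxes, background = 30) {
  stopifnot(inherits(image, "bscan"))
  img <- image$intensity
  for (b in boxes) {
    r <- as.integer(b$rows); cl <- as.integer(b$cols)
    if (length(r) != 2L || length(cl) != 2L ||
        r[1] < 1L || r[2] > nrow(img) || cl[1] < 1L || cl[2] > ncol(img) ||
        r[1] > r[2] || cl[1] > cl[2])
      stop("mask box out of image bounds: rows ", paste(r, collapse = "-"),
           ", cols ", paste(cl, collapse = "-"))
    img[r[1]:r[2], cl[1]:cl[2]] <- background
  }
  out <- image
  out$intensity <- img
  out
}

#' Detect biofilm interfaces by gray-scale gradient analysis
#'
#' Per column, the intensity profile is smoothed axially with a moving
#' average of `smooth_px` pixels and differentiated with a centred finite
#' difference. The substratum interface is the tie-broken location of the
#' maximum positive gradient; the biofilm surface is located in the first
#' contiguous run of rows (from the probe side, above the substratum
#' neighbourhood) whose gradient exceeds a threshold. The threshold is
#' `threshold_k` times the sd of the background gradient (estimated from the
#' top water rows), with an absolute floor `min_gradient` so that noise-free
#' images are handled. Columns whose maxima stay below threshold are
#' reported as undetected (`NA`) -- undetected is a value, not an error.
#' Columns where the region above the substratum is at water level are
#' reported with coinciding interfaces (zero thickness).
#'
#' @param image A `bscan` (optionally masked).
#' @param smooth_px Axial moving-average window in pixels.
#' @param threshold_k Multiplier on the background gradient sd.
#' @param min_gradient Absolute gradient floor (intensity units per pixel).
#' @return An object of class `interface_curves`: data frame with columns
#'   `column`, `surface_row`, `substratum_row` (`NA` = undetected).
#' @export
detect_interfaces <- function(image, smooth_px = 5, threshold_k = 4,
                              min_gradient = 2) {
  stopifnot(inherits(image, "bscan"))
  img <- image$intensity
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 8L) stop("image must have at least 8 rows")

  sm <- stats::filter(img, rep(1 / smooth_px, smooth_px), sides = 2)
  sm <- matrix(as.numeric(sm), nr, nc)
  g <- matrix(NA_real_, nr, nc)
  g[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  pad <- (smooth_px %/% 2) + 1L
  valid <- (pad + 1L):(nr - pad)
  gv <- g[valid, , drop = FALSE]

  # per-column threshold from the background gradient noise level; the MAD
  # over the whole column is robust to the (few) genuine interface rows
  mad_g <- apply(gv, 2, stats::mad)
  thr <- pmax(threshold_k * mad_g, min_gradient)

  tie_mid <- function(first, last) as.integer(ceiling((first + last) / 2))
  nrv <- nrow(gv)
  row_m <- matrix(seq_len(nrv), nrv, nc)

  # substratum: the deepest suprathreshold gradient run (>= 2 consecutive
  # rows); the biofilm-substratum edge is the deepest transition in a
  # column, below the surface and any floating artifacts
  above_all <- sweep(gv, 2, thr, ">=")
  cand_sub <- above_all & rbind(above_all[-1, , drop = FALSE],
                                matrix(FALSE, 1, nc))
  det_sub <- colSums(cand_sub) > 0
  sub_rel <- rep(NA_integer_, nc)
  if (any(det_sub)) {
    r0 <- max.col(t(cand_sub), ties.method = "last")
    r0_m <- matrix(r0, nrv, nc, byrow = TRUE)
    before <- (!above_all) & (row_m < r0_m)
    run_start <- ifelse(colSums(before) > 0,
                        max.col(t(before), ties.method = "last") + 1L, 1L)
    after <- (!above_all) & (row_m > r0_m)
    run_end <- ifelse(colSums(after) > 0,
                      max.col(t(after), ties.method = "first") - 1L, nrv)
    sub_rel[det_sub] <- tie_mid(run_start, run_end)[det_sub]
  }
  sub_row <- sub_rel + valid[1] - 1L

  # surface: first suprathreshold run (of >= 2 consecutive rows, to reject
  # isolated noise spikes) above the substratum neighbourhood
  surf_row <- rep(NA_integer_, nc)
  region_top <- row_m
  upper_lim <- ifelse(is.na(sub_rel), nrv, sub_rel - 4L)
  in_region <- region_top <= matrix(upper_lim, nrv, nc, byrow = TRUE)
  above <- sweep(gv, 2, thr, ">=") & in_region
  cand <- above & rbind(above[-1, , drop = FALSE],
                        matrix(FALSE, 1, nc))
  has_surf <- colSums(cand) > 0
  if (any(has_surf)) {
    r0 <- max.col(t(cand), ties.method = "first")
    r0_m <- matrix(r0, nrv, nc, byrow = TRUE)
    before <- (!above) & (region_top < r0_m)
    run_start <- ifelse(colSums(before) > 0,
                        max.col(t(before), ties.method = "last") + 1L, 1L)
    after <- (!above) & (region_top > r0_m)
    run_end <- ifelse(colSums(after) > 0,
                      max.col(t(after), ties.method = "first") - 1L, nrv)
    mid <- tie_mid(run_start, run_end)
    surf_row[has_surf] <- mid[has_surf] + valid[1] - 1L
  }

  # zero-thickness columns: substratum detected, nothing above it but water
  need_check <- det_sub & !has_surf
  if (any(need_check)) {
    for (j in which(need_check)) {
      pre <- sub_row[j] - (8:4)
      pre <- pre[pre >= 1]
      if (length(pre) && mean(sm[pre, j], na.rm = TRUE) < 75)
        surf_row[j] <- sub_row[j]
    }
  }
  surf_row[is.na(sub_row)] <- NA_integer_
  bad <- !is.na(surf_row) & !is.na(sub_row) & surf_row > sub_row
  surf_row[bad] <- sub_row[bad]

  structure(data.frame(column = seq_len(nc), surface_row = surf_row,
                       substratum_row = sub_row),
            class = c("interface_curves", "data.frame"),
            axial_pixel = image$axial_pixel,
            n_rows = nr)
}

#' Apply manual interface overrides
#'
#' Mirrors the manual repair step of drawing interface lines by hand:
#' explicit row assignments replace the detected rows over column ranges.
#'
#' @param curves An `interface_curves` object.
#' @param overrides Data frame with columns `col_start`, `col_end` (1-based,
#'   inclusive) and `surface_row` and/or `substratum_row` (`NA` = leave that
#'   interface unchanged). An empty override set returns `curves` unchanged.
#' @return The modified `interface_curves`.
#' @export
manual_overrides <- function(curves, overrides) {
  stopifnot(inherits(curves, "interface_curves"))
  if (is.null(overrides) || nrow(overrides) == 0L) return(curves)
  nr <- attr(curves, "n_rows")
  for (i in seq_len(nrow(overrides))) {
    o <- overrides[i, ]
    cols <- o$col_start:o$col_end
    if (o$col_start < 1L || o$col_end > nrow(curves))
      stop("override columns out of bounds")
    for (fld in c("surface_row", "substratum_row")) {
      if (!is.null(o[[fld]]) && !is.na(o[[fld]])) {
        if (o[[fld]] < 1L || o[[fld]] > nr)
          stop("override row out of image bounds")
        curves[[fld]][cols] <- as.integer(o[[fld]])
      }
    }
  }
  both <- !is.na(curves$surface_row) & !is.na(curves$substratum_row)
  if (any(curves$surface_row[both] > curves$substratum_row[both]))
    stop("override violates surface_row <= substratum_row")
  curves
}

#' Binary biofilm map from interface curves
#'
#' @param image The `bscan` the curves were detected on (supplies the
#'   dimensions).
#' @param curves Matching `interface_curves`.
#' @return Logical matrix: `TRUE` iff `surface_row <= row < substratum_row`
#'   for that column (biofilm); undetected columns are all-`FALSE`.
#' @export
binarize <- function(image, curves) {
  stopifnot(inherits(image, "bscan"), inherits(curves, "interface_curves"))
  nr <- nrow(image$intensity); nc <- ncol(image$intensity)
  if (nrow(curves) != nc) stop("curves do not match the image")
  row_idx <- matrix(seq_len(nr), nr, nc)
  surf <- matrix(curves$surface_row, nr, nc, byrow = TRUE)
  sub <- matrix(curves$substratum_row, nr, nc, byrow = TRUE)
  out <- row_idx >= surf & row_idx < sub
  out[is.na(out)] <- FALSE
  out
}

#' Per-column thickness profile and image mean
#'
#' Thickness per column is `(substratum_row - surface_row) * axial_pixel`
#' (um). Values below the axial detection limit are flagged censored; by the
#' default policy censored columns contribute `detection_limit / 2` to the
#' image mean (set `censor_policy = "exclude"` to drop them). Undetected
#' columns never contribute. An image with more than half of its columns
#' undetected is flagged (`flagged = TRUE`) so it can be excluded from its
#' section mean, mirroring the manual-repair path for unreadable images.
#'
#' @param curves An `interface_curves`.
#' @param img_cfg The [imaging_config()] (supplies axial pixel size and
#'   detection limit).
#' @param censor_policy `"half_limit"` (default) or `"exclude"`.
#' @return Object of class `thickness_profile`: list with `thickness_um`
#'   (per column, `NA` = undetected), `censored` (logical), `image_mean_um`,
#'   `fraction_censored`, `fraction_undetected`, `flagged`.
#' @export
thickness_profile <- function(curves, img_cfg,
                              censor_policy = c("half_limit", "exclude")) {
  stopifnot(inherits(curves, "interface_curves"),
            inherits(img_cfg, "imaging_config"))
  censor_policy <- match.arg(censor_policy)
  th <- (curves$substratum_row - curves$surface_row) * img_cfg$axial_pixel
  detected <- !is.na(th)
  censored <- detected & th < img_cfg$detection_limit
  vals <- th
  if (censor_policy == "half_limit") {
    vals[censored] <- img_cfg$detection_limit / 2
  } else {
    vals[censored] <- NA_real_
  }
  mean_um <- if (any(!is.na(vals))) mean(vals, na.rm = TRUE) else NA_real_
  structure(list(
    thickness_um = th,
    censored = censored,
    image_mean_um = mean_um,
    fraction_censored = mean(censored[detected]),
    fraction_undetected = mean(!detected),
    flagged = mean(!detected) > 0.5,
    censor_policy = censor_policy
  ), class = "thickness_profile")
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf(
    "Thickness profile: mean %.1f um (%.0f%% censored, %.0f%% undetected%s)\n",
    x$image_mean_um, 100 * x$fraction_censored, 100 * x$fraction_undetected,
    if (x$flagged) ", FLAGGED" else ""))
  invisible(x)
}

#' Aggregate image means to per-section thickness
#'
#' Images tile each half contiguously, `images_per_section(layout)` per
#' section; a section mean is the unweighted mean of its (non-flagged)
#' image means.
#'
#' @param image_means Named list (one numeric vector per half, in image
#'   order) or a single numeric vector for one half. `NA` entries (flagged
#'   images) are excluded from their section mean.
#' @param layout A [hose_layout()].
#' @return Data frame: `section_id`, `half`, `section_index`, `position_cm`,
#'   `thickness_um`, `n_images`.
#' @export
aggregate_sections <- function(image_means, layout = hose_layout()) {
  stopifnot(inherits(layout, "hose_layout"))
  if (!is.list(image_means)) image_means <- stats::setNames(
    list(image_means), layout$halves[1])
  per_sec <- images_per_section(layout)
  out <- do.call(rbind, lapply(names(image_means), function(h) {
    m <- image_means[[h]]
    if (length(m) %% per_sec != 0)
      stop("number of image means (", length(m), ") for half '", h,
           "' is not divisible by images per section (", per_sec, ")")
    n_sec <- length(m) %/% per_sec
    grp <- rep(seq_len(n_sec), each = per_sec)
    data.frame(
      section_id = sprintf("%s_%03d", h, seq_len(n_sec)),
      half = h,
      section_index = seq_len(n_sec),
      position_cm = (seq_len(n_sec) - 0.5) * layout$section_length,
      thickness_um = as.numeric(tapply(m, grp, mean, na.rm = TRUE)),
      n_images = as.integer(tapply(!is.na(m), grp, sum)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Extract per-section thickness from rendered hose images
#'
#' Convenience wrapper: runs [detect_interfaces()] and [thickness_profile()]
#' on every image and aggregates to section means.
#'
#' @param images Output of [render_hose_images()].
#' @param img_cfg The [imaging_config()] used for rendering.
#' @param layout A [hose_layout()].
#' @param ... Passed to [detect_interfaces()].
#' @return As [aggregate_sections()].
#' @export
extract_hose_thickness <- function(images, img_cfg = imaging_config(),
                                   layout = hose_layout(), ...) {
  means <- lapply(images, function(imgs) {
    vapply(imgs, function(im) {
      pr <- thickness_profile(detect_interfaces(im, ...), img_cfg)
      if (pr$flagged) NA_real_ else pr$image_mean_um
    }, numeric(1))
  })
  aggregate_sections(means, layout)
}

#' Streamed imaging round trip for a simulated hose
#'
#' Renders, detects, and summarises one B-scan at a time (the image is
#' discarded after its mean is taken), so a full 1200-image hose fits in a
#' few hundred MB of memory. Produces the same result as
#' [render_hose_images()] followed by [extract_hose_thickness()].
#'
#' @param sim A `hose_simulation`.
#' @param img_cfg An [imaging_config()].
#' @param layout A [hose_layout()] consistent with the simulation.
#' @param ... Passed to [detect_interfaces()].
#' @return As [aggregate_sections()].
#' @export
measure_hose_thickness <- function(sim, img_cfg = imaging_config(),
                                   layout = hose_layout(), ...) {
  stopifnot(inherits(sim, "hose_simulation"))
  seeds <- derive_stream_seeds(sim$config$seed)
  set.seed(seeds[["images"]])
  img_len_cm <- img_cfg$image_length / 10
  n_img <- layout$n_pieces * layout$images_per_piece
  starts <- (seq_len(n_img) - 1L) * img_len_cm
  means <- lapply(layout$halves, function(h) {
    vapply(starts, function(s) {
      b <- render_bscan(field_columns(sim$field, h, s, img_cfg), img_cfg)
      pr <- thickness_profile(detect_interfaces(b, ...), img_cfg)
      if (pr$flagged) NA_real_ else pr$image_mean_um
    }, numeric(1))
  })
  names(means) <- layout$halves
  aggregate_sections(means, layout)
}
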