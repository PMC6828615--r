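#' Hose sectioning and imaging layout
#'
#' Describes how a hose is dissected for analysis: the hose is cut into
#' `n_pieces` pieces of `piece_length` cm, each piece is bisected
#' longitudinally into two halves, imaged, and finally cut into
#' `sections_per_piece` sections of `section_length` cm. The default layout
#' (20 pieces x 6 cm, 5 x 1.2 cm sections, 30 images per piece) yields 100
#' sections and 600 images per half, i.e. 200 sections and 1200 images per
#' hose.
#'
#' @param n_pieces Number of pieces the sampled hose length is cut into.
#' @param piece_length Piece length in cm.
#' @param halves Labels of the two longitudinal halves.
#' @param sections_per_piece Number of sections cut from each piece.
#' @param section_length Section length in cm.
#' @param images_per_piece Number of B-scan images captured along one piece
#'   (per half).
#' @return An object of class `hose_layout`.
#' @examples
#' lay <- hose_layout()
#' n_sections(lay)  # 200
#' n_images(lay)    # 1200
#' @export
hose_layout <- function(n_pieces = 20, piece_length = 6,
                        halves = c("top", "bottom"),
                        sections_per_piece = 5, section_length = 1.2,
                        images_per_piece = 30) {
  stopifnot(n_pieces >= 1, piece_length > 0, length(halves) == 2,
            sections_per_piece >= 1, section_length > 0,
            images_per_piece >= 1)
  if (abs(sections_per_piece * section_length - piece_length) > 1e-8)
    stop("sections_per_piece * section_length must equal piece_length")
  if (images_per_piece %% sections_per_piece != 0)
    stop("images_per_piece must be divisible by sections_per_piece")
  structure(list(
    n_pieces = as.integer(n_pieces),
    piece_length = piece_length,
    halves = as.character(halves),
    sections_per_piece = as.integer(sections_per_piece),
    section_length = section_length,
    images_per_piece = as.integer(images_per_piece)
  ), class = "hose_layout")
}

#' @rdname hose_layout
#' @param layout A `hose_layout` object.
#' @export
hose_length <- function(layout) layout$n_pieces * layout$piece_length

#' @rdname hose_layout
#' @export
n_sections <- function(layout) {
  layout$n_pieces * layout$sections_per_piece * length(layout$halves)
}

#' @rdname hose_layout
#' @export
n_images <- function(layout) {
  layout$n_pieces * layout$images_per_piece * length(layout$halves)
}

#' @rdname hose_layout
#' @export
images_per_section <- function(layout) {
  layout$images_per_piece %/% layout$sections_per_piece
}

#' @export
print.hose_layout <- function(x, ...) {
  cat("Hose layout:", hose_length(x), "cm in", x$n_pieces, "pieces of",
      x$piece_length, "cm\n")
  cat("  halves:", paste(x$halves, collapse = ", "), "\n")
  cat("  sections:", n_sections(x), "of", x$section_length, "cm (",
      images_per_section(x), "images each,", n_images(x), "images total)\n")
  invisible(x)
}

#' Section identifiers and midpoint positions for a layout
#'
#' Section ids are 1-based per half (`top_001` ... `top_100`), positions are
#' section midpoints in cm measured from the upstream end.
#'
#' @param layout A `hose_layout`.
#' @return A data frame with columns `section_id`, `half`, `section_index`,
#'   `position_cm`.
#' @export
section_positions <- function(layout) {
  per_half <- layout$n_pieces * layout$sections_per_piece
  idx <- seq_len(per_half)
  out <- do.call(rbind, lapply(layout$halves, function(h) {
    data.frame(
      section_id = sprintf("%s_%03d", h, idx),
      half = h,
      section_index = idx,
      position_cm = (idx - 0.5) * layout$section_length,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
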