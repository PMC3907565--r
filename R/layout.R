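#' The 24-2 visual-field test layout (52 analysed points)
#'
#' Coordinates of the 24-2 perimetry test pattern in visual-field degrees,
#' right-eye convention: positive `x_deg` is the temporal field (where the
#' physiological blind spot sits, ~15 degrees temporal), negative `x_deg`
#' is nasal, positive `y_deg` is the superior hemifield.  The full pattern
#' has 54 locations (rows at |y| = 21 hold 4 points, |y| = 15 hold 6,
#' |y| = 9 hold 8, and |y| = 3 hold 9, the nasal row extending to
#' -27 degrees); the two locations adjacent to the blind spot, (15, 3) and
#' (15, -3), are excluded from analysis, leaving 52.
#'
#' Points are ordered in chart-reading order: `y_deg` descending, then
#' `x_deg` ascending; the order is fixed and identical on every call.
#'
#' @param eye `"right"` (canonical frame) or `"left"` (horizontally
#'   mirrored frame, as acquired from a left eye before remapping).
#' @return A data.frame with columns `index`, `x_deg`, `y_deg` and
#'   attribute `eye`; exactly 52 rows.
#' @examples
#' lay <- layout_242()
#' nrow(lay)            # 52
#' any(lay$x_deg == 15 & abs(lay$y_deg) == 3)  # FALSE: blind spot excluded
#' @export
layout_242 <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  rows <- list(
    list(y = 21, x = c(-9, -3, 3, 9)),
    list(y = 15, x = c(-15, -9, -3, 3, 9, 15)),
    list(y = 9,  x = c(-21, -15, -9, -3, 3, 9, 15, 21)),
    list(y = 3,  x = c(-27, -21, -15, -9, -3, 3, 9, 15, 21))
  )
  pts <- do.call(rbind, lapply(c(1, 2, 3, 4, -4, -3, -2, -1), function(i) {
    r <- rows[[abs(i)]]
    data.frame(x_deg = r$x, y_deg = sign(i) * r$y)
  }))
  ## drop the two points flanking the blind spot (15 deg temporal)
  pts <- pts[!(pts$x_deg == 15 & abs(pts$y_deg) == 3), , drop = FALSE]
  if (eye == "left") pts$x_deg <- -pts$x_deg
  ## chart-reading order: top row first, left to right
  pts <- pts[order(-pts$y_deg, pts$x_deg), , drop = FALSE]
  pts <- data.frame(index = seq_len(nrow(pts)), pts, row.names = NULL)
  attr(pts, "eye") <- eye
  pts
}

#' Number of analysed points in the 24-2 layout
#' @return 52L
#' @export
n_points_242 <- function() 52L

#' Permutation mapping a left-eye field onto the right-eye frame
#'
#' A left-eye 24-2 grid is the horizontal mirror image of the right-eye
#' grid, so mirroring a left-eye field is a pure reindexing: the value
#' recorded at left-eye point `(x, y)` belongs at right-eye point
#' `(-x, y)`.  Returns `perm` such that `v_right <- v_left[perm]`.
#'
#' @return Integer vector of length 52.
#' @keywords internal
mirror_permutation_242 <- function() {
  right <- layout_242("right")
  left  <- layout_242("left")
  perm <- match(
    paste(-right$x_deg, right$y_deg),
    paste(left$x_deg, left$y_deg)
  )
  stopifnot(!anyNA(perm), anyDuplicated(perm) == 0L)
  perm
}

#' Region masks on the 24-2 layout
#'
#' Logical masks used to define defect archetypes and to summarise
#' patterns by region.  Superior: `y_deg > 0`; inferior: `y_deg < 0`;
#' nasal: `x_deg < 0` in the right-eye frame (the blind spot at
#' +15 degrees marks the temporal side).
#'
#' @param layout A layout from [layout_242()].
#' @return Named list of logical vectors of length 52:
#'   `superior`, `inferior`, `nasal`, `temporal`,
#'   `superior_nasal`, `inferior_nasal`.
#' @export
region_masks_242 <- function(layout = layout_242()) {
  sup <- layout$y_deg > 0
  nas <- layout$x_deg < 0
  list(
    superior = sup,
    inferior = !sup,
    nasal = nas,
    temporal = !nas,
    superior_nasal = sup & nas,
    inferior_nasal = !sup & nas
  )
}
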