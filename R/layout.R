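#' Electrode array layout
#'
#' Construct the planar geometry of a regular grid electrode array, such as a
#' 16 x 16 micro-electrocorticography (uECoG) array with 1250 um pitch and
#' 850 um site diameter. Channels are ordered row-major from the top-left of
#' the grid and site coordinates are expressed in millimetres, centred on the
#' array centroid.
#'
#' @param n_rows,n_cols number of grid rows and columns (>= 1).
#' @param pitch_um centre-to-centre inter-electrode spacing in micrometres;
#'   must exceed the site diameter.
#' @param diameter_um recording-site diameter in micrometres (> 0).
#'
#' @return an object of class `ecog_layout` with fields `n_rows`, `n_cols`,
#'   `pitch_mm`, `diameter_mm`, `site_xy` (channels x 2 matrix, mm, centred at
#'   the origin; x increases with column, y decreases with row) and
#'   `channel_ids` (integer vector, row-major order).
#' @examples
#' lay <- ecog_layout(16, 16, 1250, 850)
#' nrow(lay$site_xy)       # 256 sites
#' layout_density(lay)     # 64 channels per cm^2
#' @export
ecog_layout <- function(n_rows, n_cols, pitch_um, diameter_um) {
  if (!is_count(n_rows) || !is_count(n_cols))
    stopf("n_rows and n_cols must be positive integers")
  if (!is_scalar_num(pitch_um) || !is_scalar_num(diameter_um) ||
      pitch_um <= 0 || diameter_um <= 0)
    stopf("pitch_um and diameter_um must be positive")
  if (pitch_um <= diameter_um)
    stopf("pitch (%g um) must exceed site diameter (%g um)", pitch_um, diameter_um)

  pitch_mm <- pitch_um / 1000
  rows <- rep(seq_len(n_rows), each = n_cols)
  cols <- rep(seq_len(n_cols), times = n_rows)
  x <- (cols - 1) * pitch_mm
  y <- -(rows - 1) * pitch_mm
  site_xy <- cbind(x = x - mean(x), y = y - mean(y))

  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      pitch_mm = pitch_mm, diameter_mm = diameter_um / 1000,
      site_xy = site_xy,
      channel_ids = seq_len(n_rows * n_cols),
      grid_row = rows, grid_col = cols
    ),
    class = "ecog_layout"
  )
}

#' Electrode density of a grid layout
#'
#' Channels per square centimetre of a pitch-aligned unit window: one site
#' per pitch^2, i.e. `(10 / pitch_mm)^2` channels/cm^2.
#'
#' @param layout an [ecog_layout()].
#' @return density in channels per cm^2.
#' @export
layout_density <- function(layout) {
  stopifnot(inherits(layout, "ecog_layout"))
  (10 / layout$pitch_mm)^2
}

#' @export
print.ecog_layout <- function(x, ...) {
  cat(sprintf(
    "ecog_layout: %d x %d grid (%d channels), pitch %.3g mm, diameter %.3g mm\n",
    x$n_rows, x$n_cols, length(x$channel_ids), x$pitch_mm, x$diameter_mm))
  cat(sprintf("  span %.4g x %.4g mm, density %.3g channels/cm^2\n",
              (x$n_cols - 1) * x$pitch_mm, (x$n_rows - 1) * x$pitch_mm,
              layout_density(x)))
  invisible(x)
}

# row-major channel index for (row, col)
grid_channel <- function(layout, row, col) {
  (row - 1L) * layout$n_cols + col
}
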