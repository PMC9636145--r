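#' Build a hexagonal monopolar pixel array
#'
#' Constructs the layout of a planar photovoltaic implant: a hexagonal lattice
#' of pixels clipped to a circular device, each pixel carrying a central disk
#' electrode, with a common return ring along the device rim. Rows run along
#' the x axis; adjacent rows are offset by half a pixel width, so the
#' row-to-row pitch is `pixel_width * cos(30 deg)` and the nearest-neighbour
#' centre distance equals `pixel_width`.
#'
#' Pixel indexing is deterministic: rows are ordered bottom to top, pixels
#' within a row left to right (row-major, then x), so cross-resistance
#' matrices and simulation traces are reproducible across runs.
#'
#' @param pixel_width Pixel width (flat-to-flat), um.
#' @param array_diameter Device diameter, um. Pixels whose centres fall within
#'   `array_diameter / 2` of the device centre are kept.
#' @param electrode_diameter Active-electrode diameter, um. Default scales
#'   linearly with pixel width (18 um for a 40 um pixel).
#' @param return_width Radial width of the peripheral return ring, um. The
#'   ring's outer radius is the device radius.
#' @param device_thickness Device thickness, um (metadata only; the electrode
#'   plane is z = 0 and z points into the tissue).
#' @return A `pv_layout` object: list with `pixel_width`, `row_pitch`,
#'   `centers` (n x 2 matrix, um), `row_index`, `electrode_radius`,
#'   `array_diameter`, `return_inner`, `return_outer`, `device_thickness`.
#' @examples
#' lay <- build_hex_array(40, 1500)
#' lay$row_pitch            # 34.64 um
#' nrow(lay$centers)        # about 1275 pixels on a 1.5 mm disc
#' @export
build_hex_array <- function(pixel_width, array_diameter, electrode_diameter = NULL,
                            return_width = 50, device_thickness = 30) {
  stopifnot(pixel_width > 0, array_diameter > 0)
  if (is.null(electrode_diameter)) electrode_diameter <- 18 * pixel_width / 40
  if (electrode_diameter <= 0 || electrode_diameter >= pixel_width)
    stop("invalid geometry: electrode_diameter must be positive and smaller than pixel_width")

  rp <- pixel_width * cos(pi / 6)
  R <- array_diameter / 2
  kmax <- ceiling(R / rp)
  rows <- seq(-kmax, kmax)
  centers <- do.call(rbind, lapply(rows, function(k) {
    y <- k * rp
    xoff <- if (k %% 2 == 0) 0 else pixel_width / 2
    imax <- ceiling(R / pixel_width) + 1
    x <- seq(-imax, imax) * pixel_width + xoff
    cbind(x = x, y = y, row = k)
  }))
  keep <- centers[, 1]^2 + centers[, 2]^2 <= R^2 + 1e-9
  centers <- centers[keep, , drop = FALSE]
  ord <- order(centers[, 3], centers[, 1])
  centers <- centers[ord, , drop = FALSE]

  structure(list(
    pixel_width = pixel_width,
    row_pitch = rp,
    centers = centers[, 1:2, drop = FALSE],
    row_index = as.integer(centers[, 3]),
    electrode_radius = electrode_diameter / 2,
    array_diameter = array_diameter,
    return_inner = max(R - return_width, 0),
    return_outer = R,
    device_thickness = device_thickness
  ), class = "pv_layout")
}

#' @export
print.pv_layout <- function(x, ...) {
  cat(sprintf("<pv_layout> %d pixels, %g um wide, on a %g um disc\n",
              nrow(x$centers), x$pixel_width, x$array_diameter))
  cat(sprintf("  row pitch %.4g um, electrode radius %g um, return ring %g-%g um\n",
              x$row_pitch, x$electrode_radius, x$return_inner, x$return_outer))
  invisible(x)
}

#' Number of pixels in a layout
#' @param layout A `pv_layout`.
#' @return Integer pixel count.
#' @export
n_pixels <- function(layout) nrow(layout$centers)

# interior pixels: at least `margin_rows` row pitches inside the rim
interior_pixels <- function(layout, margin_rows = 2) {
  r <- sqrt(rowSums(layout$centers^2))
  r <= layout$array_diameter / 2 - margin_rows * layout$row_pitch
}

#' Export / import a layout as CSV
#'
#' The CSV holds one row per pixel (`pixel`, `x_um`, `y_um`, `row`,
#' `electrode_radius_um`); scalar geometry travels in a JSON sidecar string in
#' the first comment line when writing, and is restored on reading.
#'
#' @param layout A `pv_layout`.
#' @param file Path to a CSV file.
#' @return `write_layout_csv` returns `file` invisibly; `read_layout_csv`
#'   returns a `pv_layout`.
#' @export
write_layout_csv <- function(layout, file) {
  meta <- jsonlite::toJSON(layout[c("pixel_width", "array_diameter",
                                    "return_inner", "return_outer",
                                    "device_thickness")], auto_unbox = TRUE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  df <- data.frame(pixel = seq_len(n_pixels(layout)),
                   x_um = layout$centers[, 1], y_um = layout$centers[, 2],
                   row = layout$row_index,
                   electrode_radius_um = layout$electrode_radius)
  write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(file) {
  first <- readLines(file, n = 1)
  if (!startsWith(first, "# ")) stop("not a pvpix layout CSV (missing metadata line)")
  meta <- jsonlite::fromJSON(sub("^# ", "", first))
  df <- read.csv(file, comment.char = "#")
  lay <- structure(list(
    pixel_width = meta$pixel_width,
    row_pitch = meta$pixel_width * cos(pi / 6),
    centers = cbind(x = df$x_um, y = df$y_um),
    row_index = as.integer(df$row),
    electrode_radius = df$electrode_radius_um[1],
    array_diameter = meta$array_diameter,
    return_inner = meta$return_inner,
    return_outer = meta$return_outer,
    device_thickness = meta$device_thickness
  ), class = "pv_layout")
  lay
}
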