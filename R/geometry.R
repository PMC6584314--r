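#' Radial chip geometry
#'
#' Describes the physical layout of a radial two-compartment microfluidic
#' barrier chip: a cylindrical central (basolateral, receiver) chamber
#' surrounded by an annular apical perfusion channel, the two separated by a
#' pillar barrier perforated by micron-scale pore slits. All primary
#' dimensions are given in micrometres; derived compartment constants are
#' reported in cm-based units because permeabilities are conventionally
#' quoted in cm/s.
#'
#' The derived fields are
#' \describe{
#'   \item{`receiver_volume_cm3`}{cylinder volume of the central chamber,
#'     \eqn{\pi r^2 h}.}
#'   \item{`exchange_area_cm2`}{full cylindrical side-wall area,
#'     \eqn{2 \pi r h}. The pore openings occupy only
#'     `pore_open_fraction` of the wall; that factor is deliberately *not*
#'     applied here, because a scaffold permeability measured through the
#'     same wall already absorbs it.}
#'   \item{`vs_ratio_cm`}{`receiver_volume / exchange_area`, which for a
#'     cylinder with full-perimeter exchange equals \eqn{r/2} exactly. This
#'     is the V/S factor that converts a normalized-intensity slope (1/s)
#'     into a permeability (cm/s).}
#' }
#'
#' @param apical_width width of the annular apical channel, um.
#' @param channel_height height of both compartments, um.
#' @param chamber_diameter diameter of the central chamber, um.
#' @param pore_width,pore_height,pore_depth dimensions of one pore slit, um.
#' @param pore_spacing centre-to-centre pitch of the pore slits, um.
#' @return An object of class `chip_geometry`: a list of the primary
#'   dimensions (um) plus the derived constants described above.
#' @examples
#' g <- chip_geometry()
#' g$vs_ratio_cm           # 0.045 for an 1800 um chamber
#' @export
chip_geometry <- function(apical_width = 200, channel_height = 100,
                          chamber_diameter = 1800,
                          pore_width = 3, pore_height = 3,
                          pore_depth = 50, pore_spacing = 50) {
  g <- list(apical_width = apical_width, channel_height = channel_height,
            chamber_diameter = chamber_diameter, pore_width = pore_width,
            pore_height = pore_height, pore_depth = pore_depth,
            pore_spacing = pore_spacing)
  dims <- unlist(g)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("invalid geometry: all dimensions must be finite and strictly positive")
  if (pore_height > channel_height)
    stop("invalid geometry: pore_height must not exceed channel_height")
  class(g) <- "chip_geometry"
  derive_compartment_constants(g)
}

#' Recompute derived compartment constants of a chip geometry
#'
#' Recomputes the receiver volume, exchange-wall area, V/S ratio and pore
#' open fraction from the primary dimensions, so the derived fields can
#' never be inconsistent with them. Called by [chip_geometry()]; call it
#' again after modifying any primary field in place.
#'
#' @param geometry a `chip_geometry` object.
#' @return The geometry with `receiver_volume_cm3`, `exchange_area_cm2`,
#'   `vs_ratio_cm` and `pore_open_fraction` refreshed.
#' @export
derive_compartment_constants <- function(geometry) {
  stopifnot(inherits(geometry, "chip_geometry"))
  r_cm <- um_to_cm(geometry$chamber_diameter) / 2
  h_cm <- um_to_cm(geometry$channel_height)
  geometry$receiver_volume_cm3 <- pi * r_cm^2 * h_cm
  geometry$exchange_area_cm2 <- 2 * pi * r_cm * h_cm
  geometry$vs_ratio_cm <- geometry$receiver_volume_cm3 / geometry$exchange_area_cm2
  geometry$pore_open_fraction <- geometry$pore_width / geometry$pore_spacing
  geometry
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat("Radial barrier chip geometry\n")
  cat(sprintf("  central chamber : %g um diameter x %g um high\n",
              x$chamber_diameter, x$channel_height))
  cat(sprintf("  apical channel  : %g um wide annulus\n", x$apical_width))
  cat(sprintf("  pore slits      : %g x %g um, %g um deep, %g um pitch (open fraction %.3f)\n",
              x$pore_width, x$pore_height, x$pore_depth, x$pore_spacing,
              x$pore_open_fraction))
  cat(sprintf("  receiver volume : %.4g cm^3\n", x$receiver_volume_cm3))
  cat(sprintf("  exchange area   : %.4g cm^2\n", x$exchange_area_cm2))
  cat(sprintf("  V/S ratio       : %.4g cm\n", x$vs_ratio_cm))
  invisible(x)
}

#' Rasterize a chip geometry into ROI masks
#'
#' Renders the radial layout into boolean pixel masks on a raster whose
#' origin is the top-left pixel (row-major, 1-based indices in R): a central
#' basolateral disk, an annular apical channel separated from it by the
#' pillar barrier (`pore_depth` wide, assigned to no ROI), and a background
#' region outside the device. The basolateral disk is additionally split
#' into `n_sectors` equal-angle wedges, numbered counterclockwise starting
#' from the +x axis (image columns increase with x, physical y points up).
#'
#' @param geometry a `chip_geometry` object.
#' @param pixel_size raster resolution, um per pixel.
#' @param frame_shape integer `c(rows, cols)`; defaults to the smallest
#'   square frame that contains the chamber, barrier and apical annulus
#'   plus a margin.
#' @param n_sectors number of azimuthal sectors of the basolateral disk.
#' @param margin background margin around the apical annulus, um.
#' @return An object of class `roi_masks`: logical matrices `apical`,
#'   `basolateral`, `background`, a list `sectors`, and the `pixel_size`.
#' @examples
#' masks <- rasterize_chip(chip_geometry(), pixel_size = 10)
#' sum(masks$basolateral) * 10^2 / (pi * 900^2)  # close to 1
#' @export
rasterize_chip <- function(geometry, pixel_size, frame_shape = NULL,
                           n_sectors = 12, margin = 100) {
  stopifnot(inherits(geometry, "chip_geometry"))
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive length in um")
  r_baso <- geometry$chamber_diameter / 2
  r_ap_in <- r_baso + geometry$pore_depth
  r_ap_out <- r_ap_in + geometry$apical_width
  if (is.null(frame_shape)) {
    n <- ceiling(2 * (r_ap_out + margin) / pixel_size)
    frame_shape <- c(n, n)
  }
  frame_shape <- as.integer(frame_shape)
  if (min(frame_shape) * pixel_size < 2 * r_ap_out)
    stop(sprintf(
      "chamber plus apical channel (diameter %g um) does not fit in a %d x %d frame at %g um/px",
      2 * r_ap_out, frame_shape[1], frame_shape[2], pixel_size))
  nr <- frame_shape[1]; nc <- frame_shape[2]
  # pixel-centre coordinates in um, chamber centred on the raster centroid
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  x <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx) * pixel_size
  y <- (cy - matrix(seq_len(nr), nr, nc)) * pixel_size  # physical y up
  rad <- sqrt(x^2 + y^2)
  baso <- rad <= r_baso
  apical <- rad > r_ap_in & rad <= r_ap_out
  background <- rad > r_ap_out + margin / 2
  theta <- atan2(y, x)               # (-pi, pi], counterclockwise from +x
  theta[theta < 0] <- theta[theta < 0] + 2 * pi
  sec_idx <- pmin(floor(theta / (2 * pi / n_sectors)) + 1L, n_sectors)
  sectors <- lapply(seq_len(n_sectors), function(s) baso & sec_idx == s)
  out <- list(apical = apical, basolateral = baso, background = background,
              sectors = sectors, pixel_size = pixel_size,
              frame_shape = frame_shape)
  class(out) <- "roi_masks"
  out
}

#' @export
print.roi_masks <- function(x, ...) {
  cat(sprintf("ROI masks: %d x %d frame at %g um/px\n",
              x$frame_shape[1], x$frame_shape[2], x$pixel_size))
  cat(sprintf("  apical %d px | basolateral %d px (%d sectors) | background %d px\n",
              sum(x$apical), sum(x$basolateral), length(x$sectors),
              sum(x$background)))
  invisible(x)
}

#' Write geometry and ROI masks to disk
#'
#' Serializes the geometry as JSON and each mask as a single-page 0/255
#' grayscale PNG, with a JSON index naming the files.
#'
#' @param geometry a `chip_geometry` object.
#' @param masks a `roi_masks` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the path of the JSON index.
#' @export
write_roi_masks <- function(geometry, masks, dir) {
  stopifnot(inherits(masks, "roi_masks"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(unclass(geometry)[sapply(geometry, is.numeric)],
                       file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  write1 <- function(m, name) {
    png::writePNG(m * 1.0, file.path(dir, paste0(name, ".png")))
    paste0(name, ".png")
  }
  idx <- list(pixel_size_um = masks$pixel_size,
              frame_shape = masks$frame_shape,
              apical = write1(masks$apical, "mask_apical"),
              basolateral = write1(masks$basolateral, "mask_basolateral"),
              background = write1(masks$background, "mask_background"),
              sectors = vapply(seq_along(masks$sectors), function(s)
                write1(masks$sectors[[s]], sprintf("mask_sector_%02d", s)),
                character(1)))
  path <- file.path(dir, "masks.json")
  jsonlite::write_json(idx, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
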