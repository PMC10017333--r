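# Georeferenced raster container and TIFF + world-file I/O.
#
# Grids are plain numeric matrices in row-major image orientation: row 1 is
# the northernmost line (top-left origin), 1-based indices, half-open pixel
# windows. World coordinates come from an affine transform
# (x0, y0, res): pixel (r, c) has centre x = x0 + (c - 0.5) res,
# y = y0 - (r - 0.5) res, in metres of a local projected frame.

#' Construct a raster stack
#'
#' @param grids Named list of numeric matrices sharing one dimension.
#' @param transform Numeric c(x0, y0, res): world coordinates of the grid's
#'   top-left corner and the square pixel size in metres.
#' @param nodata Sentinel for missing cells (default -9999).
#' @param crs Free-text tag for the coordinate frame.
#' @return A \code{raster_stack} object.
#' @export
raster_stack <- function(grids, transform, nodata = -9999, crs = "local-metres") {
  stopifnot(is.list(grids), length(grids) >= 1, !is.null(names(grids)))
  dims <- unique(lapply(grids, dim))
  if (length(dims) != 1L)
    stop_cfg("all grids in a raster_stack must share one shape")
  stopifnot(length(transform) == 3, transform[3] > 0)
  structure(list(grids = grids, transform = as.numeric(transform),
                 nodata = nodata, crs = crs),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$grids[[1]])
  cat(sprintf("raster_stack: %d layer(s) [%s], %d x %d px @ %.3g m/px\n",
              length(x$grids), paste(names(x$grids), collapse = ", "),
              d[1], d[2], x$transform[3]))
  invisible(x)
}

# world coords of all pixel centres
pixel_centres <- function(stack) {
  d <- dim(stack$grids[[1]]); tf <- stack$transform
  list(x = tf[1] + (seq_len(d[2]) - 0.5) * tf[3],
       y = tf[2] - (seq_len(d[1]) - 0.5) * tf[3])
}

# world -> (row, col), 1-based; points outside return NA
world_to_cell <- function(stack, x, y) {
  tf <- stack$transform; d <- dim(stack$grids[[1]])
  col <- floor((x - tf[1]) / tf[3]) + 1L
  row <- floor((tf[2] - y) / tf[3]) + 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Write a raster stack as TIFF layers with georeferencing sidecars
#'
#' Each layer goes to \code{<name>.tif} (32-bit float, values stored scaled
#' to [0, 1]) with an ESRI world file \code{<name>.tfw} and a JSON sidecar
#' \code{<name>.json} recording the value offset/scale, nodata and frame tag
#' needed to restore physical units (metres for elevation, reflectance for
#' bands).
#'
#' @param stack A \code{raster_stack}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of .tif paths written.
#' @export
write_raster_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "raster_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tf <- stack$transform
  paths <- character(0)
  for (nm in names(stack$grids)) {
    g <- stack$grids[[nm]]
    finite <- g[g != stack$nodata & is.finite(g)]
    off <- if (length(finite)) min(finite) else 0
    rng <- if (length(finite)) max(finite) - off else 0
    scale <- if (rng > 0) rng else 1
    gs <- (g - off) / scale
    gs[g == stack$nodata | !is.finite(g)] <- 0
    path <- file.path(dir, paste0(nm, ".tif"))
    suppressWarnings(tiff::writeTIFF(gs, path, bits.per.sample = 32L, reduce = FALSE))
    # world file: pixel size, rotations, centre of the upper-left pixel
    writeLines(formatC(c(tf[3], 0, 0, -tf[3],
                         tf[1] + tf[3] / 2, tf[2] - tf[3] / 2),
                       format = "g", digits = 17),
               file.path(dir, paste0(nm, ".tfw")))
    mask <- which(g == stack$nodata | !is.finite(g)) - 1L
    jsonlite::write_json(
      list(layer = nm, value_offset = off, value_scale = scale,
           nodata = stack$nodata, crs = stack$crs,
           nodata_cells = as.integer(mask)),
      file.path(dir, paste0(nm, ".json")), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a raster stack written by \code{write_raster_stack}
#'
#' @param dir Directory holding \code{<name>.tif/.tfw/.json} triplets.
#' @param layers Layer names to read; default all .tif files present.
#' @return A \code{raster_stack} in physical units.
#' @export
read_raster_stack <- function(dir, layers = NULL) {
  if (is.null(layers)) {
    layers <- sub("\\.tif$", "", basename(list.files(dir, pattern = "\\.tif$")))
  }
  if (!length(layers)) stop_cfg("no raster layers found in %s", dir)
  grids <- list(); tfm <- NULL; nodata <- -9999; crs <- "local-metres"
  for (nm in layers) {
    path <- file.path(dir, paste0(nm, ".tif"))
    if (!file.exists(path)) stop_cfg("missing raster file: %s", path)
    g <- tiff::readTIFF(path)
    if (length(dim(g)) == 3L) g <- g[, , 1]
    meta <- jsonlite::read_json(file.path(dir, paste0(nm, ".json")),
                                simplifyVector = TRUE)
    g <- g * meta$value_scale + meta$value_offset
    if (length(meta$nodata_cells)) g[meta$nodata_cells + 1L] <- meta$nodata
    w <- as.numeric(readLines(file.path(dir, paste0(nm, ".tfw"))))
    tfm_i <- c(w[5] - w[1] / 2, w[6] + w[1] / 2, w[1])
    if (is.null(tfm)) tfm <- tfm_i
    else if (max(abs(tfm - tfm_i)) > 1e-9)
      stop_cfg("raster layers in %s disagree on extent/transform", dir)
    nodata <- meta$nodata; crs <- meta$crs
    grids[[nm]] <- g
  }
  raster_stack(grids, tfm, nodata = nodata, crs = crs)
}

#' Terrain settings for scene rendering
#'
#' A smooth analytic ground surface: base elevation plus two low-frequency
#' sinusoids. Amplitudes default to a total relief under 10 m, matching a
#' near-flat plantation site.
#'
#' @param base_elevation Metres above datum.
#' @param amp_x,amp_y Sinusoid amplitudes (m); total relief is
#'   2(amp_x + amp_y).
#' @param wavelength_x,wavelength_y Sinusoid wavelengths (m).
#' @param soil Named soil background reflectances per band; defaults are
#'   darker in NIR than canopy so NDVI separates crown from ground.
#' @export
terrain_config <- function(base_elevation = 100, amp_x = 2.5, amp_y = 1.5,
                           wavelength_x = 120, wavelength_y = 90,
                           soil = c(blue = 0.06, green = 0.09, red = 0.13,
                                    rededge = 0.17, nir = 0.20)) {
  if (2 * (amp_x + amp_y) > 10)
    stop_cfg("terrain relief 2*(amp_x+amp_y) must be at most 10 m")
  structure(list(base_elevation = base_elevation, amp_x = amp_x, amp_y = amp_y,
                 wavelength_x = wavelength_x, wavelength_y = wavelength_y,
                 soil = soil),
            class = "terrain_config")
}

#' Render DSM, DTM and five band rasters for one month
#'
#' Builds the synthetic scene a photogrammetric pipeline would deliver: a
#' smooth terrain model (DTM), a surface model (DSM) compositing a right
#' circular cone per tree (apex at the tree's true height above ground, base
#' radius its crown radius) by cellwise maximum, and five reflectance bands
#' painting each crown disc with that tree's band value over a soil
#' background; overlapping crown pixels belong to the nearest apex. The grid
#' is aligned so planting positions fall on pixel centres.
#'
#' @param layout An \code{orchard_layout}.
#' @param reflectance Per-tree reflectance table from
#'   \code{\link{simulate_reflectance}}.
#' @param month Month label selecting reflectance rows.
#' @param resolution Pixel size in metres (default 0.05).
#' @param terrain A \code{terrain_config}.
#' @param margin Margin around the planted extent (m); kept a multiple of
#'   the resolution so grid alignment holds.
#' @return A \code{raster_stack} with layers dsm, dtm, blue, green, red,
#'   rededge, nir.
#' @export
render_rasters <- function(layout, reflectance, month,
                           resolution = 0.05, terrain = terrain_config(),
                           margin = 3) {
  stopifnot(inherits(layout, "orchard_layout"), inherits(terrain, "terrain_config"))
  if (resolution <= 0) stop_cfg("resolution must be positive")
  tr <- layout$trees
  refl <- reflectance[reflectance$month == month, ]
  bands <- c("blue", "green", "red", "rededge", "nir")
  empty <- nrow(tr) == 0L

  margin <- round(margin / resolution) * resolution
  if (empty) { xmin <- 0; xmax <- 10; ymin <- 0; ymax <- 10 } else {
    xmin <- min(tr$x) - margin; xmax <- max(tr$x) + margin
    ymin <- min(tr$y) - margin; ymax <- max(tr$y) + margin
  }
  # half-pixel shift puts planting positions (multiples of the spacing) on
  # pixel centres, so each cone apex is sampled exactly
  x0 <- xmin - resolution / 2
  y0 <- ymax + resolution / 2
  ncol <- ceiling((xmax - x0) / resolution) + 1L
  nrow <- ceiling((y0 - ymin) / resolution) + 1L
  if (ncol < 1 || nrow < 1) stop_cfg("zero-area raster extent")

  xs <- x0 + (seq_len(ncol) - 0.5) * resolution
  ys <- y0 - (seq_len(nrow) - 0.5) * resolution
  dtm <- outer(ys, xs, function(y, x) {
    terrain$base_elevation +
      terrain$amp_x * sin(2 * pi * x / terrain$wavelength_x) +
      terrain$amp_y * cos(2 * pi * y / terrain$wavelength_y)
  })
  dsm <- dtm
  grids <- c(list(dsm = NULL, dtm = dtm),
             stats::setNames(lapply(bands, function(b)
               matrix(terrain$soil[[b]], nrow, ncol)), bands))
  own <- matrix(Inf, nrow, ncol) # distance to owning apex, for band painting

  if (!empty) {
    idx <- match(tr$tree_id, refl$tree_id)
    if (anyNA(idx) && nrow(refl))
      stop_cfg("reflectance missing for tree(s): %s",
               paste(utils::head(tr$tree_id[is.na(idx)], 5), collapse = ", "))
    for (i in seq_len(nrow(tr))) {
      r <- tr$crown_radius[i]; h <- tr$height[i]
      ci <- which(abs(xs - tr$x[i]) <= r)
      ri <- which(abs(ys - tr$y[i]) <= r)
      if (!length(ci) || !length(ri)) next
      dx <- xs[ci] - tr$x[i]; dy <- ys[ri] - tr$y[i]
      dist <- sqrt(outer(dy^2, dx^2, `+`))
      inside <- dist < r
      cone <- h * (1 - dist / r)
      sub_dsm <- dsm[ri, ci, drop = FALSE]
      cand <- dtm[ri, ci, drop = FALSE] + cone
      upd <- inside & cand > sub_dsm
      sub_dsm[upd] <- cand[upd]
      dsm[ri, ci] <- sub_dsm
      if (nrow(refl)) {
        sub_own <- own[ri, ci, drop = FALSE]
        claim <- inside & dist < sub_own
        if (any(claim)) {
          sub_own[claim] <- dist[claim]
          own[ri, ci] <- sub_own
          for (b in bands) {
            sub <- grids[[b]][ri, ci, drop = FALSE]
            sub[claim] <- refl[[b]][idx[i]]
            grids[[b]][ri, ci] <- sub
          }
        }
      }
    }
  }
  grids$dsm <- dsm
  raster_stack(grids, c(x0, y0, resolution))
}
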