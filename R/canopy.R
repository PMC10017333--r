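#' Canopy height model from surface and terrain models
#'
#' CHM = DSM - DTM, cellwise. Nodata in either input propagates; negative
#' differences (terrain/surface reconstruction noise) are clamped to zero
#' and counted.
#'
#' @param dsm,dtm Numeric matrices sharing one shape, in metres.
#' @param nodata Sentinel value (default -9999).
#' @return The CHM matrix with attribute \code{n_clamped}, the number of
#'   negative cells clamped to 0.
#' @export
compute_chm <- function(dsm, dtm, nodata = -9999) {
  if (!all(dim(dsm) == dim(dtm)))
    stop_cfg("DSM and DTM shapes differ (%s vs %s)",
             paste(dim(dsm), collapse = "x"), paste(dim(dtm), collapse = "x"))
  chm <- dsm - dtm
  bad <- dsm == nodata | dtm == nodata
  neg <- !bad & chm < 0
  chm[neg] <- 0
  chm[bad] <- nodata
  n_clamped <- sum(neg)
  if (n_clamped > 0)
    message(sprintf("compute_chm: clamped %d negative cell(s) to 0", n_clamped))
  attr(chm, "n_clamped") <- n_clamped
  chm
}

#' Detect individual trees on a canopy height model
#'
#' Variable-window-filter detection: a cell is an apex iff its height is at
#' least \code{min_height} and it is the strict maximum within a circular
#' window of radius clamp(a + b * height, r_min, max_crown_diameter / 2).
#' Ties break to the first cell in row-major order; candidates closer than
#' \code{r_min} are merged keeping the taller.
#'
#' @param chm CHM matrix (metres) or a \code{raster_stack} with a
#'   \code{chm} layer.
#' @param transform Affine transform c(x0, y0, res); taken from the stack if
#'   \code{chm} is one.
#' @param min_height Detection floor in metres (default 2.6).
#' @param max_crown_diameter Maximum crown diameter in metres (default 2.5);
#'   half of it caps the search radius.
#' @param a,b Intercept and slope of the height-to-radius rule (defaults 0,
#'   0.3 m per m).
#' @param r_min Minimum window radius in metres (default 0.5).
#' @return data.frame (det_id, row, col, x, y, height), one row per apex.
#' @export
detect_trees <- function(chm, transform = NULL, min_height = 2.6,
                         max_crown_diameter = 2.5, a = 0, b = 0.3,
                         r_min = 0.5) {
  if (inherits(chm, "raster_stack")) {
    transform <- chm$transform
    chm <- chm$grids$chm %||% stop_cfg("raster_stack has no 'chm' layer")
  }
  stopifnot(!is.null(transform))
  res <- transform[3]
  if (r_min / res < 1)
    stop_cfg("window radius r_min = %.2f m spans under one pixel at %.3g m/px; use a finer resolution",
             r_min, res)
  cand <- detect_maxima_cpp(chm, res, min_height, a, b, r_min,
                            max_crown_diameter / 2)
  if (nrow(cand) == 0L) {
    return(data.frame(det_id = character(0), row = integer(0), col = integer(0),
                      x = numeric(0), y = numeric(0), height = numeric(0),
                      stringsAsFactors = FALSE))
  }
  # merge candidates closer than r_min, keeping the taller
  ord <- order(-cand[, 3], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  kx <- ky <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    x <- transform[1] + (cand[i, 2] - 0.5) * res
    y <- transform[2] - (cand[i, 1] - 0.5) * res
    if (!length(kx) || min((kx - x)^2 + (ky - y)^2) >= r_min^2) {
      keep[i] <- TRUE
      kx <- c(kx, x); ky <- c(ky, y)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  ord <- order(cand[, 1], cand[, 2]) # stable row-major output order
  cand <- cand[ord, , drop = FALSE]
  data.frame(det_id = sprintf("D%04d", seq_len(nrow(cand))),
             row = as.integer(cand[, 1]), col = as.integer(cand[, 2]),
             x = transform[1] + (cand[, 2] - 0.5) * res,
             y = transform[2] - (cand[, 1] - 0.5) * res,
             height = cand[, 3], stringsAsFactors = FALSE)
}

#' Delineate tree crowns by region growing from detected apexes
#'
#' Crowns grow from their apex over 4-connected neighbours whose CHM
#' exceeds both \code{seed_fraction} of the apex height and
#' \code{crown_fraction} of the current crown's mean height, never beyond
#' half the maximum crown diameter from the apex and never into another
#' crown (first claim wins; apexes are processed tallest-first). Each crown
#' is polygonised in world coordinates as the convex hull of its pixel
#' footprint.
#'
#' @param chm CHM matrix (metres).
#' @param apexes Apex table from \code{\link{detect_trees}}.
#' @param transform Affine transform c(x0, y0, res).
#' @param seed_fraction,crown_fraction Growing thresholds (defaults 0.45,
#'   0.55, the cited algorithm's conventional values).
#' @param max_crown_diameter Crown diameter cap in metres (default 2.5).
#' @return A list of class \code{crown_set}: per crown \code{det_id},
#'   apex (x, y), height, integer pixel indices (\code{cells}, column-major
#'   into the CHM), pixel count, area (m^2), equivalent diameter (m) and a
#'   polygon (two-column matrix of world coordinates). The claim matrix is
#'   attached as attribute \code{claim}.
#' @export
delineate_crowns <- function(chm, apexes, transform,
                             seed_fraction = 0.45, crown_fraction = 0.55,
                             max_crown_diameter = 2.5) {
  res <- transform[3]
  if (nrow(apexes) == 0L) {
    return(structure(list(), class = "crown_set",
                     claim = matrix(0L, nrow(chm), ncol(chm))))
  }
  ok <- logical(nrow(apexes))
  for (i in seq_len(nrow(apexes))) {
    r <- apexes$row[i]; c <- apexes$col[i]
    nb <- c(if (r > 1) chm[r - 1, c], if (r < nrow(chm)) chm[r + 1, c],
            if (c > 1) chm[r, c - 1], if (c < ncol(chm)) chm[r, c + 1])
    ok[i] <- all(chm[r, c] >= nb)
    if (!ok[i])
      warning(sprintf("apex %s is not a local maximum of the supplied CHM; skipped",
                      apexes$det_id[i]))
  }
  apexes <- apexes[ok, , drop = FALSE]
  ord <- order(-apexes$height, apexes$row, apexes$col)
  ap <- apexes[ord, , drop = FALSE]
  claim <- grow_crowns_cpp(chm, ap$row, ap$col, res, seed_fraction,
                           crown_fraction, max_crown_diameter / 2)
  crowns <- vector("list", nrow(ap))
  for (k in seq_len(nrow(ap))) {
    cells <- which(claim == k)
    rows <- (cells - 1L) %% nrow(chm) + 1L
    cols <- (cells - 1L) %/% nrow(chm) + 1L
    px <- transform[1] + (cols - 0.5) * res
    py <- transform[2] - (rows - 0.5) * res
    # polygon: convex hull over the four corners of every footprint pixel
    cx <- c(px - res / 2, px + res / 2, px + res / 2, px - res / 2)
    cy <- c(py - res / 2, py - res / 2, py + res / 2, py + res / 2)
    hull <- grDevices::chull(cx, cy)
    area <- length(cells) * res^2
    crowns[[k]] <- list(det_id = ap$det_id[k], x = ap$x[k], y = ap$y[k],
                        height = ap$height[k], cells = cells,
                        n_pixels = length(cells), area = area,
                        equiv_diameter = 2 * sqrt(area / pi),
                        polygon = cbind(x = cx[hull], y = cy[hull]))
  }
  structure(crowns, class = "crown_set", claim = claim)
}

#' Extract per-crown mean band reflectance
#'
#' For every crown and band layer: the mean over the crown's footprint
#' pixels, excluding nodata. Crowns with no valid pixel are flagged for
#' downstream exclusion.
#'
#' @param stack A \code{raster_stack} holding band layers.
#' @param crowns A \code{crown_set} delineated on the same grid.
#' @param bands Layer names to average (default the five spectral bands).
#' @return data.frame (det_id, x, y, height, n_pixels, one column per band,
#'   flag_empty).
#' @export
extract_spectra <- function(stack, crowns,
                            bands = c("blue", "green", "red", "rededge", "nir")) {
  stopifnot(inherits(stack, "raster_stack"))
  miss <- setdiff(bands, names(stack$grids))
  if (length(miss)) stop_cfg("missing band layer(s): %s", paste(miss, collapse = ", "))
  if (!length(crowns)) {
    out <- c(list(det_id = character(0), x = numeric(0), y = numeric(0),
                  height = numeric(0), n_pixels = integer(0)),
             stats::setNames(rep(list(numeric(0)), length(bands)), bands),
             list(flag_empty = logical(0)))
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  rows <- lapply(crowns, function(cr) {
    vals <- lapply(bands, function(b) {
      v <- stack$grids[[b]][cr$cells]
      v <- v[v != stack$nodata & is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    })
    nvalid <- length(stack$grids[[bands[1]]][cr$cells][
      stack$grids[[bands[1]]][cr$cells] != stack$nodata])
    c(list(det_id = cr$det_id, x = cr$x, y = cr$y, height = cr$height,
           n_pixels = nvalid), stats::setNames(vals, bands),
      list(flag_empty = nvalid == 0L))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Match detected trees to planted field records
#'
#' Greedy nearest-neighbour matching in the world frame: candidate pairs are
#' taken in increasing distance order, each detection and each field record
#' used at most once, pairs beyond the tolerance never matched. Unmatched
#' detections are retained without labels; unmatched field records are
#' reported on the result.
#'
#' @param detected data.frame with det_id, x, y (e.g. from
#'   \code{\link{extract_spectra}}).
#' @param field data.frame with tree_id, x, y and label columns
#'   (family, block, site).
#' @param tolerance Maximum match distance in metres (default 1).
#' @return \code{detected} with tree_id/family/block/site columns added
#'   (NA where unmatched) and attribute \code{unmatched_field}: the
#'   tree_ids of field records no detection claimed.
#' @export
match_trees <- function(detected, field, tolerance = 1.0) {
  labels <- intersect(c("tree_id", "family", "block", "site"), names(field))
  out <- detected
  for (lb in labels) out[[lb]] <- rep(NA_character_, nrow(detected))
  if (nrow(detected) && nrow(field)) {
    d2 <- outer(detected$x, field$x, `-`)^2 + outer(detected$y, field$y, `-`)^2
    cand <- which(d2 <= tolerance^2, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d2[cand]), , drop = FALSE]
      used_d <- logical(nrow(detected)); used_f <- logical(nrow(field))
      for (i in seq_len(nrow(cand))) {
        di <- cand[i, 1]; fi <- cand[i, 2]
        if (used_d[di] || used_f[fi]) next
        used_d[di] <- TRUE; used_f[fi] <- TRUE
        for (lb in labels) out[[lb]][di] <- as.character(field[[lb]][fi])
      }
      attr(out, "unmatched_field") <- field$tree_id[!used_f]
    } else {
      attr(out, "unmatched_field") <- field$tree_id
    }
  } else {
    attr(out, "unmatched_field") <- if (nrow(field)) field$tree_id else character(0)
  }
  out
}

#' Write crown polygons as GeoJSON
#'
#' @param crowns A \code{crown_set}.
#' @param path Output .geojson path.
#' @return Invisibly, \code{path}.
#' @export
write_crowns_geojson <- function(crowns, path) {
  feats <- lapply(crowns, function(cr) {
    ring <- rbind(cr$polygon, cr$polygon[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(det_id = cr$det_id, height = cr$height,
                           area = cr$area, n_pixels = cr$n_pixels),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
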