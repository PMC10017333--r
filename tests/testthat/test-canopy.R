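# CHM arithmetic, variable-window detection, crown growing, spectra
# extraction and field matching.

test_that("CHM is exact cellwise subtraction with clamping and nodata rules", {
  dsm <- matrix(c(12.4, 10, -9999, 9.5), 2, 2)
  dtm <- matrix(c(10, 10, 10, 10.5), 2, 2)
  chm <- suppressMessages(compute_chm(dsm, dtm))
  expect_equal(chm[1, 1], 2.4)
  expect_equal(chm[2, 1], 0)
  expect_equal(chm[1, 2], -9999) # nodata propagates
  expect_equal(chm[2, 2], 0)     # negative clamped
  expect_equal(attr(chm, "n_clamped"), 1)
  expect_error(compute_chm(dsm, matrix(0, 3, 2)), "differ")
  # reconstruction on non-clamped cells
  ok <- dsm != -9999 & (dsm - dtm) >= 0
  expect_equal((chm + dtm)[ok], dsm[ok])
  expect_true(all(suppressMessages(compute_chm(dtm, dtm)) == 0))
})

test_that("a single cone yields exactly one apex at the true position", {
  st <- cone_stack(height = 5, radius = 1, res = 0.05)
  chm <- compute_chm(st$grids$dsm, st$grids$dtm)
  det <- detect_trees(chm, st$transform)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x), st$transform[3] + 1e-12)
  expect_lt(abs(det$y), st$transform[3] + 1e-12)
  expect_equal(det$height, 5, tolerance = 1e-9)
})

test_that("cones below the 2.6 m floor are not detected", {
  st <- cone_stack(height = 2.0, radius = 1, res = 0.05)
  chm <- compute_chm(st$grids$dsm, st$grids$dtm)
  expect_equal(nrow(detect_trees(chm, st$transform)), 0)
  # just above the floor is detected (the exact boundary is not testable
  # through CHM subtraction: (base + 2.6) - base != 2.6 in floating point)
  st2 <- cone_stack(height = 2.65, radius = 1, res = 0.05)
  chm2 <- compute_chm(st2$grids$dsm, st2$grids$dtm)
  expect_equal(nrow(detect_trees(chm2, st2$transform)), 1)
})

test_that("detection refuses resolutions coarser than the minimum window", {
  st <- cone_stack(height = 5, radius = 1, res = 0.6)
  chm <- compute_chm(st$grids$dsm, st$grids$dtm)
  expect_error(detect_trees(chm, st$transform, r_min = 0.5), "resolution")
})

test_that("detection is invariant to a constant added to DSM and DTM", {
  st <- cone_stack(height = 5, radius = 1, res = 0.05)
  chm1 <- compute_chm(st$grids$dsm, st$grids$dtm)
  chm2 <- compute_chm(st$grids$dsm + 57.3, st$grids$dtm + 57.3)
  expect_equal(detect_trees(chm1, st$transform),
               detect_trees(chm2, st$transform))
})

test_that("two equal cones 3 m apart give two disjoint crowns", {
  res <- 0.05
  xs <- seq(-4, 4, by = res)
  d1 <- sqrt(outer(xs^2, (xs + 1.5)^2, `+`))
  d2 <- sqrt(outer(xs^2, (xs - 1.5)^2, `+`))
  chm <- pmax(3 * pmax(1 - d1 / 1, 0), 3 * pmax(1 - d2 / 1, 0))
  tf <- c(min(xs) - res / 2, max(xs) + res / 2, res)
  det <- detect_trees(chm, tf)
  expect_equal(nrow(det), 2)
  crowns <- delineate_crowns(chm, det, tf)
  cells <- lapply(crowns, `[[`, "cells")
  expect_length(intersect(cells[[1]], cells[[2]]), 0)
})

test_that("crown geometry follows the growing thresholds and the size cap", {
  st <- cone_stack(height = 5, radius = 1.25, res = 0.05)
  chm <- compute_chm(st$grids$dsm, st$grids$dtm)
  det <- detect_trees(chm, st$transform)
  cr <- delineate_crowns(chm, det, st$transform)
  expect_length(cr, 1)
  # on a cone the admissible region height > seed_fraction * apex ends at
  # (1 - seed_fraction) * radius
  expect_equal(cr[[1]]$equiv_diameter, 2 * (1 - 0.45) * 1.25, tolerance = 0.2)
  # no crown cell farther than max_crown_diameter / 2 from its apex
  rows <- (cr[[1]]$cells - 1) %% nrow(chm) + 1
  cols <- (cr[[1]]$cells - 1) %/% nrow(chm) + 1
  px <- st$transform[1] + (cols - 0.5) * st$transform[3]
  py <- st$transform[2] - (rows - 0.5) * st$transform[3]
  expect_true(all(sqrt((px - cr[[1]]$x)^2 + (py - cr[[1]]$y)^2) <= 1.25 + 1e-9))
  # polygon contains the apex
  expect_true(min(px) <= cr[[1]]$x && max(px) >= cr[[1]]$x)
})

test_that("an apex that is not a local maximum is skipped with a warning", {
  st <- cone_stack(height = 5, radius = 1, res = 0.05)
  chm <- compute_chm(st$grids$dsm, st$grids$dtm)
  det <- detect_trees(chm, st$transform)
  fake <- det
  fake$row <- fake$row + 8 # off-apex cell on the cone flank
  fake$col <- fake$col + 8
  expect_warning(cr <- delineate_crowns(chm, fake, st$transform), "skipped")
  expect_length(cr, 0)
})

test_that("spectra extraction averages crown pixels and flags empty crowns", {
  st <- cone_stack(height = 5, radius = 1, res = 0.05, band_value = 0.8)
  chm <- compute_chm(st$grids$dsm, st$grids$dtm)
  det <- detect_trees(chm, st$transform)
  cr <- delineate_crowns(chm, det, st$transform)
  sp <- extract_spectra(st, cr)
  expect_equal(sp$nir, 0.8) # constant paint -> exact mean

  # split crown: half the pixels at 0.2, half at 0.6 -> mean 0.4
  cells <- cr[[1]]$cells
  half <- cells[seq_len(floor(length(cells) / 2) * 2)]
  st$grids$nir[half[seq(1, length(half), 2)]] <- 0.2
  st$grids$nir[half[seq(2, length(half), 2)]] <- 0.6
  cr2 <- cr
  cr2[[1]]$cells <- half
  sp2 <- extract_spectra(st, cr2)
  expect_equal(sp2$nir, 0.4)

  # all-nodata crown flagged
  st$grids$nir[cells] <- st$nodata
  st$grids$blue[cells] <- st$nodata
  st$grids$green[cells] <- st$nodata
  st$grids$red[cells] <- st$nodata
  st$grids$rededge[cells] <- st$nodata
  sp3 <- extract_spectra(st, cr)
  expect_true(sp3$flag_empty)
  expect_equal(extract_spectra(st, structure(list(), class = "crown_set")) |> nrow(), 0)
})

test_that("field matching respects the tolerance and reports leftovers", {
  det <- data.frame(det_id = c("D1", "D2"), x = c(0, 10), y = c(0, 0))
  field <- data.frame(tree_id = c("T1", "T2", "T3"),
                      x = c(0, 11.5, 50), y = c(0, 0, 0),
                      family = c("F1", "F2", "F3"),
                      block = "B1", site = "S1")
  m <- match_trees(det, field, tolerance = 1.0)
  expect_equal(m$tree_id, c("T1", NA)) # 1.5 m away stays unmatched
  expect_setequal(attr(m, "unmatched_field"), c("T2", "T3"))
})

test_that("end-to-end on a noiseless orchard: extracted means track the truth", {
  lay <- small_layout(seed = 21, sites = 1, blocks = 3, families = 5)
  tr <- rbind(simulate_traits(lay, default_n_genetics(), "Jul", "N"),
              simulate_traits(lay, default_nsc_genetics(), "Jul", "NSC"))
  refl <- simulate_reflectance(tr, optics_config(noise_sd = 0))
  st <- render_rasters(lay, refl, "Jul", resolution = 0.05)
  chm <- suppressMessages(compute_chm(st$grids$dsm, st$grids$dtm))
  det <- detect_trees(chm, st$transform)
  cr <- delineate_crowns(chm, det, st$transform)
  sp <- extract_spectra(st, cr)
  m <- match_trees(sp, lay$trees, 1.0)
  expect_gte(mean(!is.na(m$tree_id)), 0.95) # nearly all detections labelled
  idx <- match(m$tree_id, refl$tree_id)
  ok <- !is.na(idx)
  for (b in c("red", "nir")) {
    expect_gte(cor(m[[b]][ok], refl[[b]][idx[ok]]), 0.99)
  }
})
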