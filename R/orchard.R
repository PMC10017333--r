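#' Build a progeny-trial orchard layout
#'
#' Lays out a slash-pine open-pollinated progeny trial as single-tree plots
#' in incomplete blocks: each block contains every family exactly once, with
#' the family-to-position assignment randomised per block (a seeded proxy for
#' the alpha-lattice randomisation used in such trials). Trees sit on a
#' regular planting grid (default 2 m within rows, 3 m between rows); blocks
#' tile each site, and sites are placed side by side with an alley.
#'
#' @param sites Number of sites (default 2) or character vector of site ids.
#' @param blocks_per_site Blocks per site (default 20).
#' @param families Number of families (default 20) or character ids. Must
#'   equal the number of trees per block (single-tree plots).
#' @param spacing_x,spacing_y Planting spacing in metres (default 2, 3).
#' @param height_mean,height_sd Mean and SD of true tree height (m).
#' @param crown_radius_range Range of true crown radii (m); the upper end is
#'   capped at 1.25 m, half the 2.5 m maximum crown diameter used downstream.
#' @param seed Integer seed; the layout is a pure function of config + seed.
#' @return An object of class \code{orchard_layout}: a list with the design
#'   parameters and a \code{trees} data.frame
#'   (tree_id, site, block, family, x, y, height, crown_radius).
#' @export
make_layout <- function(sites = 2, blocks_per_site = 20, families = 20,
                        spacing_x = 2, spacing_y = 3,
                        height_mean = 5, height_sd = 0.5,
                        crown_radius_range = c(0.9, 1.25),
                        seed = 1L) {
  if (is.numeric(sites)) sites <- sprintf("S%d", seq_len(sites))
  if (is.numeric(families)) families <- sprintf("F%02d", seq_len(families))
  nfam <- length(families)
  trees_per_block <- nfam # single-tree plots: one tree per family per block
  if (blocks_per_site < 1 || nfam < 1 || spacing_x <= 0 || spacing_y <= 0)
    stop_cfg("sites, blocks, families and spacings must all be positive")
  if (any(crown_radius_range <= 0) || crown_radius_range[2] > 1.25)
    stop_cfg("crown radii must be positive and at most 1.25 m")

  # trees within a block on a bc x br grid; blocks tile the site in a grid
  bc <- ceiling(sqrt(trees_per_block))
  br <- ceiling(trees_per_block / bc)
  block_w <- bc * spacing_x
  block_h <- br * spacing_y
  gcols <- ceiling(sqrt(blocks_per_site))
  grows <- ceiling(blocks_per_site / gcols)
  # alleys between blocks are multiples of the spacing so every position
  # stays on one global planting grid
  alley_x <- 2 * spacing_x
  alley_y <- 2 * spacing_y
  site_w <- gcols * block_w + (gcols - 1) * alley_x
  site_gap <- 5 * spacing_x

  with_seed(seed, {
    rows <- vector("list", length(sites) * blocks_per_site)
    i <- 0L
    for (si in seq_along(sites)) {
      x_site <- (si - 1) * (site_w + site_gap)
      for (bl in seq_len(blocks_per_site)) {
        gc <- (bl - 1) %% gcols
        gr <- (bl - 1) %/% gcols
        x0 <- x_site + gc * (block_w + alley_x)
        y0 <- gr * (block_h + alley_y)
        pos <- seq_len(trees_per_block) - 1L
        fam <- sample(families) # fresh permutation per block
        i <- i + 1L
        rows[[i]] <- data.frame(
          tree_id = sprintf("%s_B%02d_T%02d", sites[si], bl, seq_len(trees_per_block)),
          site = sites[si],
          block = sprintf("B%02d", bl),
          family = fam,
          x = x0 + (pos %% bc) * spacing_x,
          y = y0 + (pos %/% bc) * spacing_y,
          height = pmin(pmax(rnorm(trees_per_block, height_mean, height_sd),
                             height_mean - 3 * height_sd), height_mean + 3 * height_sd),
          crown_radius = runif(trees_per_block, crown_radius_range[1], crown_radius_range[2]),
          stringsAsFactors = FALSE
        )
      }
    }
    trees <- do.call(rbind, rows)
    rownames(trees) <- NULL
    structure(
      list(sites = sites, blocks_per_site = blocks_per_site,
           families = families, trees_per_block = trees_per_block,
           spacing_x = spacing_x, spacing_y = spacing_y, seed = seed,
           trees = trees),
      class = "orchard_layout")
  })
}

#' @export
print.orchard_layout <- function(x, ...) {
  cat(sprintf("orchard_layout: %d site(s) x %d block(s) x %d trees = %d trees, %d families\n",
              length(x$sites), x$blocks_per_site, x$trees_per_block,
              nrow(x$trees), length(x$families)))
  invisible(x)
}

#' Genetic simulation settings for one trait
#'
#' Variance components of the individual-tree model
#' \eqn{y = \mu_{month} + site + block + family + e} with
#' \eqn{block \sim N(0,\sigma^2_b)}, \eqn{family \sim N(0,\sigma^2_f)} and
#' \eqn{e \sim N(0,\sigma^2_e)}, all in squared trait-percent units. Under
#' the open-pollinated (half-sib) assumption the implied narrow-sense
#' heritability is \eqn{2.5\sigma^2_f/(\sigma^2_f+\sigma^2_b+\sigma^2_e)}.
#'
#' @param var_family,var_block,var_residual Variance components (>= 0).
#' @param site_effects Named numeric of per-site fixed offsets.
#' @param monthly_means Named numeric of length 11 (one per flight month).
#' @param bounds Soft plausibility bounds; simulated values are clipped here
#'   and the clip count recorded on the result.
#' @param redraw_monthly If TRUE, family effects are redrawn independently
#'   every month (month-varying heritability mode); default FALSE keeps one
#'   genetic value per family across the year.
#' @param seed Integer seed.
#' @return A \code{genetic_config} list.
#' @export
genetic_config <- function(var_family, var_block, var_residual,
                           site_effects, monthly_means,
                           bounds = c(-Inf, Inf),
                           redraw_monthly = FALSE, seed = 1L) {
  if (any(c(var_family, var_block, var_residual) < 0))
    stop_cfg("variance components must be nonnegative")
  if (length(monthly_means) != 11L)
    stop_cfg("monthly_means must have exactly 11 values (Feb absent)")
  if (is.null(names(monthly_means))) names(monthly_means) <- flight_months()
  structure(list(var_family = var_family, var_block = var_block,
                 var_residual = var_residual, site_effects = site_effects,
                 monthly_means = monthly_means, bounds = bounds,
                 redraw_monthly = redraw_monthly, seed = seed),
            class = "genetic_config")
}

#' Default genetic settings for needle nitrogen (percent dry mass)
#'
#' Seasonal means follow the observed phenology of conifer needle N (spring
#' flush high, late-autumn low); components give a true half-sib
#' heritability of 0.25.
#' @param seed Integer seed.
#' @export
default_n_genetics <- function(seed = 11L) {
  genetic_config(
    var_family = 0.010, var_block = 0.010, var_residual = 0.080,
    site_effects = c(S1 = 0, S2 = 0.10),
    monthly_means = c(Jan = 1.30, Mar = 1.35, Apr = 1.80, May = 1.85,
                      Jun = 1.80, Jul = 1.55, Aug = 1.70, Sep = 1.75,
                      Oct = 1.45, Nov = 1.35, Dec = 1.30),
    bounds = c(0.5, 4), seed = seed)
}

#' Default genetic settings for needle nonstructural carbohydrate (percent)
#'
#' Seasonal means decline through the growing season and recover after
#' growth cessation in autumn; components give a true half-sib heritability
#' of about 0.26.
#' @param seed Integer seed.
#' @export
default_nsc_genetics <- function(seed = 12L) {
  genetic_config(
    var_family = 0.15, var_block = 0.10, var_residual = 1.20,
    site_effects = c(S1 = 0, S2 = -0.30),
    monthly_means = c(Jan = 11.5, Mar = 11.0, Apr = 10.2, May = 9.6,
                      Jun = 9.0, Jul = 8.6, Aug = 8.2, Sep = 7.8,
                      Oct = 7.3, Nov = 9.0, Dec = 10.8),
    bounds = c(5, 15), seed = seed)
}

#' Simulate monthly trait values over an orchard
#'
#' Draws one trait realisation per tree and month under the mixed model in
#' \code{\link{genetic_config}}: value = monthly mean + site effect + block
#' effect + family effect + residual. Block and family effects are drawn
#' once (constant across months); residuals are redrawn every month. Set
#' \code{redraw_monthly} in the config to also redraw family effects per
#' month.
#'
#' @param layout An \code{orchard_layout}.
#' @param genetics A \code{genetic_config}.
#' @param months Character vector of month labels (subset of
#'   \code{flight_months()}).
#' @param trait Trait name, e.g. "N" or "NSC".
#' @param family_shift Optional named numeric added to the drawn family
#'   effects.
#' @param family_set Optional named numeric overriding the drawn effects of
#'   those families exactly (used to plant known superior families in
#'   recovery studies, where the planted signal must be controlled rather
#'   than left to the genetic draw).
#' @return A data.frame (tree_id, month, trait, value, family, block, site)
#'   with attribute \code{n_clipped}: the number of values clipped to the
#'   config's plausibility bounds.
#' @export
simulate_traits <- function(layout, genetics, months = flight_months(),
                            trait = "N", family_shift = NULL,
                            family_set = NULL) {
  stopifnot(inherits(layout, "orchard_layout"), inherits(genetics, "genetic_config"))
  bad <- setdiff(months, flight_months())
  if (length(bad))
    stop_cfg("unknown month label(s): %s (calendar has no February flight)",
             paste(bad, collapse = ", "))
  tr <- layout$trees
  fam_levels <- layout$families
  blk_levels <- unique(paste(tr$site, tr$block, sep = ":"))
  blk_of_tree <- paste(tr$site, tr$block, sep = ":")

  with_seed(genetics$seed, {
    blk_eff <- stats::setNames(rnorm(length(blk_levels), 0, sqrt(genetics$var_block)),
                               blk_levels)
    fam_base <- stats::setNames(rnorm(length(fam_levels), 0, sqrt(genetics$var_family)),
                                fam_levels)
    out <- vector("list", length(months))
    for (mi in seq_along(months)) {
      m <- months[mi]
      fam_eff <- if (isTRUE(genetics$redraw_monthly)) {
        stats::setNames(rnorm(length(fam_levels), 0, sqrt(genetics$var_family)),
                        fam_levels)
      } else fam_base
      if (!is.null(family_shift)) {
        fam_eff[names(family_shift)] <- fam_eff[names(family_shift)] + family_shift
      }
      if (!is.null(family_set)) {
        fam_eff[names(family_set)] <- family_set
      }
      e <- rnorm(nrow(tr), 0, sqrt(genetics$var_residual))
      val <- genetics$monthly_means[[m]] +
        unname(genetics$site_effects[tr$site]) +
        unname(blk_eff[blk_of_tree]) +
        unname(fam_eff[tr$family]) + e
      out[[mi]] <- data.frame(tree_id = tr$tree_id, month = m, trait = trait,
                              value = val, family = tr$family,
                              block = tr$block, site = tr$site,
                              stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    lo <- genetics$bounds[1]; hi <- genetics$bounds[2]
    n_clip <- sum(res$value < lo | res$value > hi)
    res$value <- pmin(pmax(res$value, lo), hi)
    rownames(res) <- NULL
    attr(res, "n_clipped") <- n_clip
    res
  })
}

#' Canopy optics settings: the trait-to-reflectance forward model
#'
#' A linear forward model giving the machine-learning stage learnable
#' signal: band reflectance = baseline + c_N * N + c_NSC * NSC + noise,
#' clipped to [0, 1]. It is an artifact convention, not a radiative-transfer
#' claim about pine optics. Default coefficients follow the qualitative
#' physiology: higher N (chlorophyll) depresses visible reflectance and
#' raises red-edge/NIR; NSC carries a weaker signature concentrated in the
#' green and red-edge bands, deliberately near-orthogonal to the N
#' direction. The coefficient matrix must have rank 2 so both traits are
#' identifiable, and nearly collinear directions draw a warning: they make
#' the two traits inseparable in practice even at full rank.
#'
#' @param baseline Named reflectances (blue, green, red, rededge, nir).
#' @param coef_n,coef_nsc Named per-band linear coefficients (per trait %).
#' @param noise_sd Per-band Gaussian noise SD (reflectance units).
#' @param seed Integer seed.
#' @export
optics_config <- function(baseline = c(blue = 0.05, green = 0.10, red = 0.08,
                                       rededge = 0.28, nir = 0.48),
                          coef_n = c(blue = -0.010, green = -0.012, red = -0.018,
                                     rededge = 0.020, nir = 0.030),
                          coef_nsc = c(blue = 0.0005, green = 0.0045, red = -0.0010,
                                       rededge = 0.0060, nir = -0.0030),
                          noise_sd = 0.01, seed = 21L) {
  bands <- c("blue", "green", "red", "rededge", "nir")
  stopifnot(all(bands %in% names(baseline)), all(bands %in% names(coef_n)),
            all(bands %in% names(coef_nsc)), noise_sd >= 0)
  if (any(baseline < 0 | baseline > 1))
    stop_cfg("baseline reflectances must lie in [0, 1]")
  cm <- cbind(coef_n[bands], coef_nsc[bands])
  if (any(cm != 0)) {
    if (qr(cm)$rank < 2)
      stop_cfg("coefficient matrix must have rank 2 so both traits are identifiable")
    cosang <- abs(sum(cm[, 1] * cm[, 2])) /
      (sqrt(sum(cm[, 1]^2)) * sqrt(sum(cm[, 2]^2)))
    if (is.finite(cosang) && cosang > 0.95)
      warning("N and NSC coefficient directions are nearly collinear; the traits will be hard to separate from reflectance")
  }
  structure(list(baseline = baseline[bands], coef_n = coef_n[bands],
                 coef_nsc = coef_nsc[bands], noise_sd = noise_sd, seed = seed),
            class = "optics_config")
}

#' Simulate per-tree canopy reflectance from trait values
#'
#' Applies the linear forward model of \code{\link{optics_config}} to a
#' trait table holding both N and NSC for every tree-month.
#'
#' @param traits Long trait table from \code{\link{simulate_traits}} with
#'   both traits present for every tree-month.
#' @param optics An \code{optics_config}.
#' @return A data.frame (tree_id, month, blue, green, red, rededge, nir),
#'   one row per tree-month, reflectances clipped to [0, 1].
#' @export
simulate_reflectance <- function(traits, optics) {
  stopifnot(inherits(optics, "optics_config"))
  key <- paste(traits$tree_id, traits$month)
  n_tab <- traits[traits$trait == "N", ]
  c_tab <- traits[traits$trait == "NSC", ]
  kn <- paste(n_tab$tree_id, n_tab$month)
  kc <- paste(c_tab$tree_id, c_tab$month)
  miss <- union(setdiff(kn, kc), setdiff(kc, kn))
  if (length(miss))
    stop_cfg("both N and NSC required per tree-month; missing for: %s",
             paste(utils::head(miss, 5), collapse = ", "))
  c_tab <- c_tab[match(kn, kc), ]
  bands <- names(optics$baseline)
  with_seed(optics$seed, {
    refl <- sapply(bands, function(b) {
      v <- optics$baseline[[b]] + optics$coef_n[[b]] * n_tab$value +
        optics$coef_nsc[[b]] * c_tab$value
      v + rnorm(length(v), 0, optics$noise_sd)
    })
    refl <- pmin(pmax(refl, 0), 1)
    out <- data.frame(tree_id = n_tab$tree_id, month = n_tab$month,
                      stringsAsFactors = FALSE)
    out[bands] <- as.data.frame(refl)
    rownames(out) <- NULL
    out
  })
}

#' Randomly sample trees for ground-truth needle collection
#'
#' Emulates the monthly destructive sampling: a uniform random subset of
#' trees (20-50 per month in the field protocol) whose needle chemistry is
#' "measured", retaining family/block/site labels for matching to imagery.
#'
#' @param traits Long trait table.
#' @param month Month label to sample within.
#' @param n Number of trees to sample (without replacement).
#' @param seed Integer seed.
#' @return The subset of trait rows (all traits) for the sampled trees.
#' @export
sample_ground_truth <- function(traits, month, n, seed = 1L) {
  sub <- traits[traits$month == month, ]
  ids <- unique(sub$tree_id)
  if (n < 1 || n > length(ids))
    stop_cfg("n = %d outside [1, %d] trees available in %s", n, length(ids), month)
  with_seed(seed, {
    keep <- sample(ids, n)
    out <- sub[sub$tree_id %in% keep, ]
    rownames(out) <- NULL
    out
  })
}

#' Kjeldahl needle nitrogen content from titration volumes
#'
#' Standard Kjeldahl arithmetic: N% = (Vs - Vb) x normality x 0.014 x
#' (Vd / Va) x 100 / W, where 0.014 g/meq is the milliequivalent weight of
#' nitrogen and Vd/Va scales the analysed aliquot back to the digested
#' volume.
#'
#' @param Vs Acid volume titrating the sample (ml).
#' @param Vb Acid volume titrating the blank (ml).
#' @param normality Acid concentration (normality, meq/ml).
#' @param Vd Digested sample solution volume (ml).
#' @param W Dry needle sample weight (g).
#' @param Va Aliquot of the digest taken for analysis (ml).
#' @return Nitrogen content in percent dry mass.
#' @examples
#' kjeldahl_n_content(Vs = 5.0, Vb = 0.2, normality = 0.05,
#'                    Vd = 50, W = 0.25, Va = 10) # 6.72
#' @export
kjeldahl_n_content <- function(Vs, Vb, normality, Vd, W, Va) {
  if (any(W <= 0) || any(Va <= 0) || any(Vd <= 0))
    stop_cfg("W, Va and Vd must be positive")
  if (any(Vs < Vb))
    stop_cfg("titration volume below blank (Vs < Vb)")
  (Vs - Vb) * normality * 0.014 * (Vd / Va) * 100 / W
}
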