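# Shared fixtures and independent oracles. Everything is built in code at
# test time; nothing is read from disk.

flat_months <- function(mu = 2) stats::setNames(rep(mu, 11), flight_months())

# A small but structured trial for fast end-to-end tests.
small_layout <- function(seed = 3, sites = 1, blocks = 4, families = 6) {
  make_layout(sites = sites, blocks_per_site = blocks, families = families,
              seed = seed)
}

# Raster stack holding one cone on flat terrain, built directly (not via
# render_rasters) so detection tests have construction-level ground truth.
cone_stack <- function(height = 5, radius = 1, res = 0.05, base = 100,
                       half_extent = 4, band_value = 0.5) {
  k <- round(half_extent / res)
  xs <- (-k:k) * res # exact at 0 so the apex samples the full cone height
  n <- length(xs)
  d <- sqrt(outer(xs^2, xs^2, `+`))
  cone <- pmax(height * (1 - d / radius), 0) * (d < radius)
  dtm <- matrix(base, n, n)
  bands <- c("blue", "green", "red", "rededge", "nir")
  grids <- c(list(dsm = dtm + cone, dtm = dtm),
             stats::setNames(lapply(bands, function(b) {
               g <- matrix(0.1, n, n)
               g[d < radius] <- band_value
               g
             }), bands))
  # centre the grid so the apex (0, 0) is a pixel centre
  raster_stack(grids, c(min(xs) - res / 2, max(xs) + res / 2, res))
}

# Independent dense-matrix restricted log-likelihood: builds V explicitly
# and uses generic determinants/solves. Used as the oracle for the
# cross-product implementation; shares no code with it.
dense_reml_ll <- function(vf, vb, ve, y, X, Zb, Zf) {
  n <- length(y)
  p <- ncol(X)
  V <- ve * diag(n) + vf * tcrossprod(Zf)
  if (!is.null(Zb)) V <- V + vb * tcrossprod(Zb)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  beta <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XVX, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}

# Grid + local-refine maximiser of the dense restricted likelihood over
# variance triples; the brute-force oracle for reml_fit on tiny instances.
dense_reml_grid_opt <- function(y, X, Zb, Zf, n_grid = 50) {
  vy <- stats::var(y)
  vals <- vy * exp(seq(log(1e-3), log(2), length.out = n_grid))
  best <- c(ll = -Inf, vf = NA, vb = NA, ve = NA)
  for (ve in vals) {
    for (vf in c(0, vals)) {
      vbs <- if (is.null(Zb)) 0 else c(0, vals)
      for (vb in vbs) {
        ll <- dense_reml_ll(vf, vb, ve, y, X, Zb, Zf)
        if (ll > best["ll"]) best <- c(ll = ll, vf = vf, vb = vb, ve = ve)
      }
    }
  }
  # local refinement from the lattice argmax, still on the dense oracle
  obj <- function(lv) -dense_reml_ll(exp(lv[1]), if (is.null(Zb)) 0 else exp(lv[2]),
                                     exp(lv[3]), y, X, Zb, Zf)
  start <- log(pmax(c(best["vf"], best["vb"], best["ve"]), 1e-8 * vy))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  max(best["ll"], -opt$value)
}

# Quick design-matrix builder matching the model's fixed/random structure,
# independent of pedigree_design's internals.
bare_design_mats <- function(site, block, family) {
  X <- if (length(unique(site)) > 1) stats::model.matrix(~factor(site))
       else matrix(1, length(family), 1)
  Zb <- if (is.null(block)) NULL
        else stats::model.matrix(~0 + interaction(factor(site), factor(block), drop = TRUE))
  Zf <- stats::model.matrix(~0 + factor(family))
  list(X = X, Zb = Zb, Zf = Zf)
}

# Feature table with a known linear trait, for model tests.
linear_feature_table <- function(n, noise_sd = 0, seed = 1, beta = 3) {
  with_seed <- get("with_seed", envir = asNamespace("pinephenomics"))
  with_seed(seed, {
    X <- as.data.frame(matrix(stats::runif(n * 5, 0.05, 0.6), n))
    names(X) <- c("blue", "green", "red", "rededge", "nir")
    fx <- compute_features(X)
    fx$N <- beta * fx$NDVI + stats::rnorm(n, 0, noise_sd)
    fx
  })
}
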