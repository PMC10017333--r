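# REML variance components, heritability, breeding values, family
# selection and the monthly series.

sim_trial <- function(vf, vb, ve, seed, months = "Jul", layout_seed = 2,
                      trait = "N", ...) {
  lay <- make_layout(seed = layout_seed)
  g <- genetic_config(vf, vb, ve, c(S1 = 0, S2 = 0.2), flat_months(2),
                      seed = seed)
  simulate_traits(lay, g, months, trait, ...)
}

test_that("design construction validates its inputs", {
  expect_error(pedigree_design(family = rep("F1", 10)), "2 families")
  expect_error(pedigree_design(site = "S1", block = rep("B1", 4),
                               family = c("F1", "F2", "F1", "F2")), "2 blocks")
  expect_error(pedigree_design(family = c("F1", NA, "F2")), "complete")
})

test_that("restricted likelihood matches an independent dense-matrix oracle", {
  set.seed(31)
  for (rep in 1:4) {
    nf <- sample(3:5, 1); nb <- sample(2:3, 1)
    site <- rep(c("S1", "S2"), each = nf * nb)[1:(nf * nb * 2)]
    block <- rep(rep(sprintf("B%d", 1:nb), each = nf), 2)
    family <- rep(sprintf("F%d", 1:nf), nb * 2)
    n <- length(family) # <= 50
    y <- rnorm(n, 10)
    des <- pedigree_design(site, block, family)
    mats <- bare_design_mats(site, block, family)
    for (vset in list(c(0.3, 0.2, 1), c(1e-4, 2, 0.5), c(2, 1e-4, 0.1))) {
      mine <- reml_loglik(list(var_family = vset[1], var_block = vset[2],
                               var_residual = vset[3]), y, des)
      oracle <- dense_reml_ll(vset[1], vset[2], vset[3], y,
                              mats$X, mats$Zb, mats$Zf)
      expect_equal(mine, oracle, tolerance = 1e-8)
    }
  }
})

test_that("restricted likelihood is invariant to location and equivariant to scale", {
  tr <- sim_trial(0.1, 0.1, 0.8, seed = 5)
  tr <- tr[1:60, ]
  des <- pedigree_design(tr$site, tr$block, tr$family)
  vc <- list(var_family = 0.1, var_block = 0.1, var_residual = 0.8)
  l0 <- reml_loglik(vc, tr$value, des)
  expect_equal(reml_loglik(vc, tr$value + 13.7, des), l0, tolerance = 1e-8)
  # scaling y by c and variances by c^2 shifts ll by -(n - p) log c
  cc <- 2.5
  vc2 <- lapply(vc, `*`, cc^2)
  np <- length(tr$value) - ncol(des$X)
  expect_equal(reml_loglik(vc2, cc * tr$value, des), l0 - np * log(cc),
               tolerance = 1e-8)
})

test_that("REML equals the balanced one-way ANOVA estimator", {
  set.seed(8)
  nf <- 12; n0 <- 10
  family <- rep(sprintf("F%02d", 1:nf), each = n0)
  y <- rnorm(nf * n0, 5) + rep(rnorm(nf, 0, sqrt(0.5)), each = n0)
  des <- pedigree_design(family = family)
  vc <- reml_fit(y, des)
  av <- anova(aov(y ~ factor(family)))
  msf <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
  expect_equal(vc$var_family, (msf - msw) / n0, tolerance = 1e-6)
  expect_equal(vc$var_residual, msw, tolerance = 1e-6)
})

test_that("optimiser attains the dense grid + refine maximum on a tiny instance", {
  set.seed(9)
  site <- rep("S1", 12)
  block <- rep(c("B1", "B2"), each = 6)
  family <- rep(c("F1", "F2", "F3"), 4)
  y <- rnorm(12, 3) + rep(c(0, 0.8), each = 6) + rep(c(-0.5, 0, 0.5), 4)
  des <- pedigree_design(site, block, family)
  vc <- reml_fit(y, des)
  mats <- bare_design_mats(site, block, family)
  oracle <- dense_reml_grid_opt(y, mats$X, mats$Zb, mats$Zf, n_grid = 30)
  expect_gte(vc$loglik, oracle - 1e-4)
})

test_that("variance estimates agree with an established REML implementation", {
  skip_if_not_installed("lme4")
  tr <- sim_trial(0.1, 0.1, 0.8, seed = 55)
  des <- pedigree_design(tr$site, tr$block, tr$family)
  vc <- reml_fit(tr$value, des)
  d <- data.frame(y = tr$value, site = tr$site,
                  blk = interaction(tr$site, tr$block), fam = tr$family)
  m <- lme4::lmer(y ~ site + (1 | blk) + (1 | fam), d, REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(m))
  expect_equal(vc$var_family, vcs$vcov[vcs$grp == "fam"], tolerance = 1e-4)
  expect_equal(vc$var_block, vcs$vcov[vcs$grp == "blk"], tolerance = 1e-4)
  expect_equal(vc$var_residual, vcs$vcov[vcs$grp == "Residual"], tolerance = 1e-4)
  expect_equal(unname(vc$fixed), unname(lme4::fixef(m)), tolerance = 1e-4)
})

test_that("zero family variance is recovered at the boundary", {
  hits <- 0
  for (s in 1:10) {
    tr <- sim_trial(0, 0.1, 0.8, seed = 600 + s)
    des <- pedigree_design(tr$site, tr$block, tr$family)
    vc <- reml_fit(tr$value, des)
    hits <- hits + (vc$var_family <= 0.01 * vc$var_residual)
  }
  expect_gte(hits, 9)
})

test_that("heritability and breeding values are exact arithmetic", {
  expect_equal(heritability(list(var_family = 0.2, var_block = 0.3,
                                 var_residual = 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(heritability(list(var_family = 0, var_block = 0.3,
                                 var_residual = 0.5)), 0)
  expect_warning(h <- heritability(list(var_family = 0.5, var_block = 0.1,
                                        var_residual = 0.2)), "exceeds 1")
  expect_equal(h, 2.5 * 0.5 / 0.8, tolerance = 1e-12)
  expect_error(heritability(list(var_family = 0, var_block = 0,
                                 var_residual = 0)), "undefined")
  # coefficient override
  expect_equal(heritability(list(var_family = 0.2, var_block = 0.3,
                                 var_residual = 0.5), coefficient = 4), 0.8)

  expect_equal(breeding_values(0.49, c(F1 = 2.1, F2 = 2.0), 2.0)[["F1"]],
               0.049, tolerance = 1e-12)
  expect_equal(breeding_values(0.49, c(F1 = 2.0, F2 = 2.2), 2.0)[["F1"]], 0)
  # size-weighted breeding values sum to zero about the weighted grand mean
  set.seed(4)
  sizes <- c(F1 = 10, F2 = 25, F3 = 5)
  means <- c(F1 = 2.2, F2 = 1.9, F3 = 2.5)
  mu <- sum(sizes * means) / sum(sizes)
  bv <- breeding_values(0.3, means, mu)
  expect_equal(sum(sizes * bv), 0, tolerance = 1e-12)
})

test_that("family selection follows the quadrant rule", {
  fams <- sprintf("F%02d", 1:6)
  mk <- function(vals_n, vals_c, month) {
    rbind(data.frame(family = fams, month = month, trait = "N", bv = vals_n),
          data.frame(family = fams, month = month, trait = "NSC", bv = vals_c))
  }
  bv <- mk(c(3, 1, -1, -1, -1, -1), c(2, -1, 1, -1, -1, 0), "Jul")
  sel <- select_families(bv, "Jul")
  expect_equal(sel$family[1], "F01") # dominant in both -> first
  expect_false("F02" %in% sel$family) # above mean in N only
  # identical families -> nobody strictly above the mean
  expect_equal(nrow(select_families(mk(rep(1, 6), rep(2, 6), "Jul"), "Jul")), 0)
  expect_error(select_families(bv, character(0)), "nonempty")
  # k truncation
  bv2 <- mk(c(3, 2, 1.5, -2, -2, -2.5), c(3, 2, 1.5, -2, -2, -2.5), "Jul")
  expect_equal(nrow(select_families(bv2, "Jul", k = 2)), 2)
})

test_that("monthly series emits one fit per trait-month, independently", {
  lay <- make_layout(seed = 41)
  months <- c("Jun", "Jul")
  gA <- genetic_config(0.1, 0.1, 0.8, c(S1 = 0, S2 = 0.2), flat_months(2),
                       seed = 42)
  g0 <- genetic_config(0, 0.1, 0.8, c(S1 = 0, S2 = 0.2), flat_months(2),
                       seed = 43)
  tr <- rbind(simulate_traits(lay, gA, "Jun", "N"),
              simulate_traits(lay, g0, "Jul", "N")) # family signal absent in Jul
  gen <- monthly_genetic_series(tr)
  expect_equal(nrow(gen$h2), 2)
  h_jun <- gen$h2$h2[gen$h2$month == "Jun"]
  h_jul <- gen$h2$h2[gen$h2$month == "Jul"]
  expect_lte(h_jul, 0.05)
  expect_gt(h_jun, h_jul)
  expect_equal(sort(unique(gen$breeding_values$family)), sort(lay$families))
  # per-month breeding values average to zero (balanced families)
  for (m in months) {
    bvm <- gen$breeding_values$bv[gen$breeding_values$month == m]
    expect_equal(mean(bvm), 0, tolerance = 1e-10)
  }
})

test_that("permuting family labels collapses heritability to zero", {
  tr <- sim_trial(0.1, 0.1, 0.8, seed = 77)
  des_template <- tr
  h2s <- sapply(1:30, function(s) {
    shuf <- des_template
    set.seed(7000 + s)
    shuf$family <- sample(shuf$family)
    des <- pedigree_design(shuf$site, shuf$block, shuf$family)
    heritability(reml_fit(shuf$value, des))
  })
  expect_lte(median(h2s), 0.05)
})
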