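# REML variance components, narrow-sense heritability and family breeding
# values for the open-pollinated progeny trial.
#
# Model: y = X m + Z1 b + Z2 f + e with fixed effects m = intercept + site,
# random block b ~ N(0, s2_b I), random family f ~ N(0, s2_f I) and residual
# e ~ N(0, s2_e I). The restricted likelihood is profiled over the residual
# variance and maximised over the two variance ratios g_b = s2_b/s2_e,
# g_f = s2_f/s2_e on the log scale. All linear algebra runs on q x q
# cross-products (q = blocks + families) via the Woodbury identity, so a fit
# at n = 800 costs milliseconds; boundary optima (a ratio driven to zero)
# are detected and refitted with that component fixed at zero.

#' Design labels for the genetic mixed model
#'
#' @param site,block,family Character/factor label vectors of one length,
#'   aligned with the trait vector. Blocks are treated as nested in sites.
#'   \code{block} (and \code{site}) may be NULL for a one-way family design.
#' @return A \code{pedigree_design}: incidence matrices X (fixed:
#'   intercept + site), Zb (site:block), Zf (family).
#' @export
pedigree_design <- function(site = NULL, block = NULL, family) {
  n <- length(family)
  if (n == 0) stop_cfg("empty design")
  if (anyNA(family) || (!is.null(site) && anyNA(site)) ||
      (!is.null(block) && anyNA(block)))
    stop_cfg("every tree needs complete site/block/family labels")
  fam <- factor(family)
  if (nlevels(fam) < 2) stop_cfg("need at least 2 families")
  if (!is.null(site)) {
    st <- factor(site)
    X <- if (nlevels(st) > 1) stats::model.matrix(~st) else matrix(1, n, 1)
  } else {
    st <- NULL
    X <- matrix(1, n, 1)
  }
  colnames(X)[1] <- "(Intercept)"
  Zb <- NULL
  if (!is.null(block)) {
    blk <- if (!is.null(st)) interaction(st, factor(block), drop = TRUE)
           else factor(block)
    if (nlevels(blk) < 2) stop_cfg("need at least 2 blocks")
    Zb <- stats::model.matrix(~0 + blk)
  }
  Zf <- stats::model.matrix(~0 + fam)
  if (qr(X)$rank < ncol(X)) stop_cfg("singular fixed-effects design")
  structure(list(X = X, Zb = Zb, Zf = Zf, n = n,
                 families = levels(fam)),
            class = "pedigree_design")
}

# cross-products shared by every likelihood evaluation
reml_xprod <- function(y, design) {
  X <- design$X
  Z <- cbind(design$Zb, design$Zf)
  qb <- if (is.null(design$Zb)) 0L else ncol(design$Zb)
  list(C = crossprod(Z), ZX = crossprod(Z, X), Zy = drop(crossprod(Z, y)),
       XX = crossprod(X), Xy = drop(crossprod(X, y)), yy = sum(y * y),
       n = design$n, p = ncol(X), qb = qb, qf = ncol(design$Zf))
}

# core restricted-likelihood pieces at variance ratios (gb, gf).
# Returns logdet terms, GLS fixed effects and the residual quadratic form
# of the scaled covariance V~ = I + gb Zb Zb' + gf Zf Zf'.
reml_core <- function(gb, gf, xp) {
  s <- sqrt(c(rep(gb, xp$qb), rep(gf, xp$qf)))
  A <- diag(xp$qb + xp$qf) + (s %o% s) * xp$C
  R <- chol(A)
  U <- backsolve(R, s * xp$ZX, transpose = TRUE)
  uy <- backsolve(R, s * xp$Zy, transpose = TRUE)
  XVX <- xp$XX - crossprod(U)
  XVy <- xp$Xy - drop(crossprod(U, uy))
  Rx <- chol(XVX)
  beta <- backsolve(Rx, backsolve(Rx, XVy, transpose = TRUE))
  rVr <- max(xp$yy - sum(uy^2) - sum(XVy * beta), 1e-300)
  list(logdetA = 2 * sum(log(diag(R))),
       logdetXVX = 2 * sum(log(diag(Rx))),
       beta = drop(beta), rVr = rVr)
}

# profiled restricted log-likelihood at log variance ratios
reml_ll_profiled <- function(lg, xp) {
  core <- reml_core(exp(lg[1]), exp(lg[2]), xp)
  ve <- core$rVr / (xp$n - xp$p)
  ll <- -0.5 * ((xp$n - xp$p) * (log(2 * pi) + 1) +
                  (xp$n - xp$p) * log(ve) + core$logdetA + core$logdetXVX)
  list(ll = ll, ve = ve, core = core)
}

#' Restricted log-likelihood of the genetic mixed model
#'
#' The exact Gaussian restricted likelihood at a supplied variance triple,
#' exposed as a deterministic function for validation:
#' \eqn{-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + r'V^{-1}r]}
#' with \eqn{V = \sigma^2_e I + \sigma^2_b Z_1 Z_1' + \sigma^2_f Z_2 Z_2'}
#' and r the GLS residual.
#'
#' @param components List or numeric with var_family, var_block,
#'   var_residual (all >= 0, var_residual > 0).
#' @param y Trait vector.
#' @param design A \code{pedigree_design}.
#' @return Scalar restricted log-likelihood.
#' @export
reml_loglik <- function(components, y, design) {
  vf <- components$var_family %||% components[["var_family"]]
  vb <- components$var_block %||% components[["var_block"]] %||% 0
  ve <- components$var_residual %||% components[["var_residual"]]
  if (is.null(design$Zb)) vb <- 0
  if (any(c(vf, vb, ve) < 0) || ve <= 0)
    stop_cfg("variances must be nonnegative with var_residual > 0")
  xp <- reml_xprod(y, design)
  core <- reml_core(vb / ve, vf / ve, xp)
  -0.5 * ((xp$n - xp$p) * log(2 * pi) + (xp$n - xp$p) * log(ve) +
            core$logdetA + core$logdetXVX + core$rVr / ve)
}

#' REML fit of the family/block variance-component model
#'
#' Maximises the profiled restricted likelihood over the nonnegative
#' variance orthant: bounded quasi-Newton search on log variance ratios from
#' three starts, plus explicit boundary profiles with either or both ratios
#' fixed at zero; ratios optimised below a small floor are snapped to the
#' boundary and refitted. Fixed effects are the GLS estimates at the
#' optimum.
#'
#' @param y Trait vector.
#' @param design A \code{pedigree_design} of the same length.
#' @return A \code{variance_components} object: var_family, var_block,
#'   var_residual, fixed (named GLS estimates), loglik (restricted),
#'   converged, boundary (named logical flags).
#' @export
reml_fit <- function(y, design) {
  stopifnot(inherits(design, "pedigree_design"))
  if (length(y) != design$n) stop_cfg("y and design lengths differ")
  xp <- reml_xprod(y, design)
  if (xp$n < xp$p + 2) stop_cfg("need n >= p + 2 observations")
  has_block <- xp$qb > 0
  lo <- -16; hi <- 8

  best <- list(ll = -Inf); conv <- FALSE
  obj2 <- function(lg) -reml_ll_profiled(lg, xp)$ll
  if (has_block) {
    for (start in list(c(log(0.1), log(0.1)), c(-5, 0), c(0, -5))) {
      opt <- tryCatch(
        optim(start, obj2, method = "L-BFGS-B", lower = lo, upper = hi),
        error = function(e) NULL)
      if (!is.null(opt) && -opt$value > best$ll) {
        best <- list(ll = -opt$value, lg = opt$par)
        conv <- opt$convergence == 0
      }
    }
  }
  # boundary profiles: one ratio (or both) pinned at zero
  prof1 <- function(which_free) {
    f <- function(lg1) {
      lg <- if (which_free == "f") c(-Inf, lg1) else c(lg1, -Inf)
      -reml_ll_profiled(pmax(lg, -744), xp)$ll # exp(-744) underflows to 0
    }
    optimize(f, c(lo, hi))
  }
  cands <- list()
  of <- prof1("f")
  cands$f_only <- list(ll = -of$objective, lg = c(-Inf, of$minimum))
  if (has_block) {
    ob <- prof1("b")
    cands$b_only <- list(ll = -ob$objective, lg = c(ob$minimum, -Inf))
  }
  cands$none <- list(ll = reml_ll_profiled(c(-744, -744), xp)$ll,
                     lg = c(-Inf, -Inf))
  for (cd in cands) if (cd$ll > best$ll + 1e-9) { best <- cd; conv <- TRUE }
  if (!is.finite(best$ll))
    stop_cfg("REML optimisation failed to find a finite optimum")

  lg <- best$lg
  # snap near-zero ratios to the boundary and refit the other
  floor_lg <- log(1e-7)
  snapped <- is.finite(lg) & lg < floor_lg
  if (any(snapped)) {
    lg[snapped] <- -Inf
    if (is.finite(lg[2]) && !is.finite(lg[1])) {
      of <- prof1("f"); lg[2] <- of$minimum
    } else if (is.finite(lg[1]) && !is.finite(lg[2])) {
      ob <- prof1("b"); lg[1] <- ob$minimum
    }
  }
  fin <- reml_ll_profiled(pmax(lg, -744), xp)
  gb <- if (is.finite(lg[1])) exp(lg[1]) else 0
  gf <- if (is.finite(lg[2])) exp(lg[2]) else 0
  ve <- fin$ve
  beta <- fin$core$beta
  names(beta) <- colnames(design$X)
  structure(list(var_family = gf * ve,
                 var_block = if (has_block) gb * ve else 0,
                 var_residual = ve, fixed = beta, loglik = fin$ll,
                 converged = conv,
                 boundary = c(family = gf == 0,
                              block = has_block && gb == 0)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components: s2_f=%.4g s2_b=%.4g s2_e=%.4g (REML ll=%.3f%s)\n",
              x$var_family, x$var_block, x$var_residual, x$loglik,
              if (any(x$boundary)) paste0("; boundary: ",
                paste(names(x$boundary)[x$boundary], collapse = ",")) else ""))
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' h^2 = 2.5 s2_f / (s2_f + s2_b + s2_e). The 2.5 numerator converts
#' open-pollinated family variance to additive variance (half-sib families
#' with a small inflation for relatedness); it permits h^2 > 1, which is
#' reported with a warning rather than truncated.
#'
#' @param components A \code{variance_components}, or a list/vector with
#'   var_family, var_block, var_residual.
#' @param coefficient Additive conversion coefficient (default 2.5).
#' @return Heritability estimate (>= 0).
#' @export
heritability <- function(components, coefficient = 2.5) {
  vf <- components$var_family %||% components[["var_family"]]
  vb <- components$var_block %||% components[["var_block"]] %||% 0
  ve <- components$var_residual %||% components[["var_residual"]]
  tot <- vf + vb + ve
  if (tot <= 0) stop_cfg("all variance components are zero; h^2 undefined")
  h2 <- coefficient * vf / tot
  if (h2 > 1)
    warning(sprintf("h^2 = %.3f exceeds 1 (the %.1f coefficient permits this)",
                    h2, coefficient))
  h2
}

#' Family breeding values
#'
#' a_i = h^2 (y_i - mu): predicted additive merit of each family from its
#' phenotypic mean deviation, shrunk by the heritability. Preserves the
#' rank order of the family means.
#'
#' @param h2 Heritability for the trait-month.
#' @param family_means Named numeric of family means y_i.
#' @param mu Population mean estimate (the grand mean of the trait).
#' @return Named numeric of breeding values.
#' @export
breeding_values <- function(h2, family_means, mu) {
  if (length(family_means) < 2) stop_cfg("need at least 2 families")
  h2 * (family_means - mu)
}

#' Bivariate family selection by the quadrant rule
#'
#' Selects families whose breeding values exceed the across-family mean for
#' both traits in every month of the supplied set (the first-quadrant rule
#' on the N x NSC breeding-value plane), ranked by the sum of standardised
#' breeding values over the selected months.
#'
#' @param bv data.frame (family, month, trait, bv) holding both traits for
#'   every family in every month used.
#' @param months Month labels to require (nonempty).
#' @param traits The two trait names (default c("N", "NSC")).
#' @param k Optional truncation to the k best.
#' @return data.frame (family, score) of selected families, best first;
#'   zero rows when no family clears the rule.
#' @export
select_families <- function(bv, months, traits = c("N", "NSC"), k = NULL) {
  if (length(months) == 0) stop_cfg("month set must be nonempty")
  fams <- sort(unique(bv$family))
  qualifies <- rep(TRUE, length(fams)); names(qualifies) <- fams
  score <- rep(0, length(fams)); names(score) <- fams
  for (m in months) {
    for (tr in traits) {
      sub <- bv[bv$month == m & bv$trait == tr, ]
      if (!all(fams %in% sub$family))
        stop_cfg("missing %s breeding values for month %s", tr, m)
      v <- stats::setNames(sub$bv, sub$family)[fams]
      qualifies <- qualifies & (v > mean(v))
      s <- stats::sd(v)
      score <- score + if (s > 0) (v - mean(v)) / s else 0
    }
  }
  sel <- fams[qualifies]
  out <- data.frame(family = sel, score = score[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  if (!is.null(k)) out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Monthly genetic evaluation series
#'
#' Runs the per trait-month univariate pipeline: REML variance components,
#' heritability and family breeding values, independently for every trait
#' and month present. A month whose fit fails is recorded as missing and the
#' series continues.
#'
#' @param traits Long trait table (tree_id, month, trait, value, family,
#'   block, site).
#' @param h2_coefficient Passed to \code{\link{heritability}}.
#' @return list of data.frames: \code{h2} (trait, month, h2, var_family,
#'   var_block, var_residual, converged), \code{breeding_values} (trait,
#'   month, family, family_mean, bv).
#' @export
monthly_genetic_series <- function(traits, h2_coefficient = 2.5) {
  months <- intersect(flight_months(), unique(traits$month))
  trait_names <- unique(traits$trait)
  h2_rows <- list(); bv_rows <- list()
  for (tr in trait_names) {
    for (m in months) {
      sub <- traits[traits$trait == tr & traits$month == m, ]
      res <- tryCatch({
        des <- pedigree_design(sub$site, sub$block, sub$family)
        vc <- reml_fit(sub$value, des)
        h2 <- suppressWarnings(heritability(vc, h2_coefficient))
        mu <- mean(sub$value)
        fm <- tapply(sub$value, sub$family, mean)
        bv <- breeding_values(h2, fm, mu)
        list(vc = vc, h2 = h2, fm = fm, bv = bv)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        h2_rows[[paste(tr, m)]] <- data.frame(
          trait = tr, month = m, h2 = NA_real_, var_family = NA_real_,
          var_block = NA_real_, var_residual = NA_real_, converged = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      h2_rows[[paste(tr, m)]] <- data.frame(
        trait = tr, month = m, h2 = res$h2,
        var_family = res$vc$var_family, var_block = res$vc$var_block,
        var_residual = res$vc$var_residual, converged = res$vc$converged,
        stringsAsFactors = FALSE)
      bv_rows[[paste(tr, m)]] <- data.frame(
        trait = tr, month = m, family = names(res$bv),
        family_mean = as.numeric(res$fm[names(res$bv)]),
        bv = as.numeric(res$bv), stringsAsFactors = FALSE)
    }
  }
  h2 <- do.call(rbind, h2_rows); rownames(h2) <- NULL
  bv <- do.call(rbind, bv_rows); rownames(bv) <- NULL
  list(h2 = h2, breeding_values = bv)
}
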