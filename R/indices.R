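# Vegetation indices computed from the five multispectral bands
# (Blue 450, Green 560, Red 650, Red-edge 730, NIR 840 nm).
#
# The sixteen formulas are implemented exactly as used by the workflow this
# package reproduces, including two forms that deviate from the common
# literature versions (see vi_catalog notes): EVI omits the usual 2.5 gain,
# and MNLI uses the green band where most formulations use red. NRI and
# GRVI share one formula and are kept as deliberate duplicates, since the
# feature set ranks them separately.

vi_defs <- list(
  NDVI  = list(full = "Normalized difference vegetation index",
               formula = "(NIR - R) / (NIR + R)", ref = "Rouse et al. 1974"),
  GNDVI = list(full = "Green normalized difference vegetation index",
               formula = "(NIR - G) / (NIR + G)", ref = "Gitelson et al. 1996"),
  NDRE  = list(full = "Normalized difference red-edge",
               formula = "(NIR - RE) / (NIR + RE)", ref = "Barnes et al. 2000"),
  SAVI  = list(full = "Soil-adjusted vegetation index",
               formula = "1.5 * (NIR - R) / (NIR + R + 0.5)", ref = "Huete 1988"),
  OSAVI = list(full = "Optimized soil-adjusted vegetation index",
               formula = "(NIR - R) / (NIR + R + 0.16)", ref = "Rondeaux et al. 1996"),
  RERVI = list(full = "Red-edge ratio vegetation index",
               formula = "NIR / RE", ref = "Jasper et al. 2009"),
  LCI   = list(full = "Leaf chlorophyll index",
               formula = "(NIR - RE) / (NIR + R)", ref = "Datt 1999"),
  SCCCI = list(full = "Simplified canopy chlorophyll content index",
               formula = "((NIR - RE) / (NIR + RE)) / ((NIR - R) / (NIR + R))",
               ref = "Fitzgerald et al. 2010",
               note = "NDRE / NDVI"),
  NRI   = list(full = "Nitrogen reflectance index",
               formula = "(G - R) / (G + R)", ref = "Schleicher et al. 2001",
               note = "identical formula to GRVI; both kept"),
  GRVI  = list(full = "Green-red vegetation index",
               formula = "(G - R) / (G + R)", ref = "Tucker 1979"),
  MNLI  = list(full = "Modified nonlinear index",
               formula = "(NIR^2 * 1.5 - G * 1.5) / (NIR^2 + R + 0.5)",
               ref = "Gong et al. 2003",
               note = "uses G where common forms use R; implemented as adopted"),
  DVI   = list(full = "Difference vegetation index",
               formula = "NIR - R", ref = "Jordan 1969"),
  EVI   = list(full = "Enhanced vegetation index",
               formula = "(NIR - R) / (1 + NIR + 6 * R - 7.5 * B)",
               ref = "Huete et al. 2002",
               note = "no 2.5 gain; implemented as adopted"),
  RVI   = list(full = "Ratio vegetation index",
               formula = "NIR / R", ref = "Pearson & Miller 1972"),
  NG    = list(full = "Norm green",
               formula = "G / (R + G + NIR)", ref = "Sripada et al. 2006"),
  NR    = list(full = "Norm red",
               formula = "R / (R + G + NIR)", ref = "Sripada et al. 2006")
)

# denominator expressions, for explicit undefined-value flagging
vi_denoms <- list(
  NDVI = "NIR + R", GNDVI = "NIR + G", NDRE = "NIR + RE",
  SAVI = "NIR + R + 0.5", OSAVI = "NIR + R + 0.16", RERVI = "RE",
  LCI = "NIR + R", SCCCI = "(NIR + RE) * (NIR + R) * ((NIR - R) / (NIR + R))",
  NRI = "G + R", GRVI = "G + R", MNLI = "NIR^2 + R + 0.5", DVI = "1",
  EVI = "1 + NIR + 6 * R - 7.5 * B", RVI = "R", NG = "R + G + NIR",
  NR = "R + G + NIR")

#' Catalogue of the sixteen vegetation indices
#'
#' @return data.frame (name, full_name, formula, reference, note) in the
#'   fixed feature order used throughout the package. Formula strings use
#'   band symbols NIR, RE, R, G, B and evaluate directly in R.
#' @export
vi_catalog <- function() {
  data.frame(name = names(vi_defs),
             full_name = vapply(vi_defs, `[[`, "", "full"),
             formula = vapply(vi_defs, `[[`, "", "formula"),
             reference = vapply(vi_defs, `[[`, "", "ref"),
             note = vapply(vi_defs, function(d) d$note %||% "", ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute one vegetation index
#'
#' Evaluates the catalogued formula on band reflectances. Zero denominators
#' are flagged explicitly: the value is NA and the affected positions are
#' returned in the \code{undefined} attribute (never a silent NaN).
#'
#' @param name Index name (one of \code{vi_catalog()$name}).
#' @param bands List or data.frame with numeric elements NIR, RE, R, G, B
#'   (vectorised).
#' @return Numeric vector of index values with attribute \code{undefined}:
#'   integer positions where the formula's denominator vanished.
#' @examples
#' compute_vi("NDVI", list(NIR = 0.8, RE = 0.5, R = 0.2, G = 0.1, B = 0.05))
#' @export
compute_vi <- function(name, bands) {
  if (!name %in% names(vi_defs))
    stop_cfg("unknown vegetation index '%s'", name)
  need <- c("NIR", "RE", "R", "G", "B")
  if (!all(need %in% names(bands)))
    stop_cfg("bands must contain %s", paste(need, collapse = ", "))
  env <- list2env(lapply(bands[need], as.numeric))
  den <- eval(parse(text = vi_denoms[[name]]), env)
  val <- suppressWarnings(eval(parse(text = vi_defs[[name]]$formula), env))
  undef <- which(den == 0 | !is.finite(val))
  val[undef] <- NA_real_
  attr(val, "undefined") <- undef
  val
}

#' Assemble the 21-variable predictor table (5 bands + 16 indices)
#'
#' Appends every catalogued index to a per-tree spectra table. Rows where
#' any index is undefined are flagged (\code{flag_undefined}) for downstream
#' exclusion rather than imputed.
#'
#' @param spectra data.frame with band columns blue, green, red, rededge,
#'   nir (as produced by \code{\link{extract_spectra}}).
#' @return \code{spectra} with 16 index columns appended in catalogue order,
#'   plus \code{flag_undefined}.
#' @export
compute_features <- function(spectra) {
  need <- c("blue", "green", "red", "rededge", "nir")
  miss <- setdiff(need, names(spectra))
  if (length(miss)) stop_cfg("missing band column(s): %s", paste(miss, collapse = ", "))
  bands <- list(NIR = spectra$nir, RE = spectra$rededge, R = spectra$red,
                G = spectra$green, B = spectra$blue)
  out <- spectra
  undef <- logical(nrow(spectra))
  for (nm in names(vi_defs)) {
    v <- compute_vi(nm, bands)
    undef[attr(v, "undefined")] <- TRUE
    out[[nm]] <- as.numeric(v)
  }
  out$flag_undefined <- undef
  out
}

#' Names of the 21 model predictors in canonical order
#'
#' @return Character vector: the five band columns then the sixteen index
#'   columns.
#' @export
predictor_names <- function() {
  c("blue", "green", "red", "rededge", "nir", names(vi_defs))
}
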