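#' Model parameters for the monolayer/substrate system
#'
#' Collects every constant of the equations of motion in one validated list:
#' the damping coefficient, the eight cell force laws, the substrate spring
#' calibration inputs, the focal-adhesion strength law and rupture threshold,
#' the structural remodeling thresholds, the division clock, and the
#' integrator controls. Units are micrometres (length), seconds (time) and
#' grams (mass); forces are reported in AU = g um/s^2, so spring constants
#' carry g/s^2 and Young's moduli entered in kPa are numerically equal to
#' g/(um s^2).
#'
#' The focal-adhesion strength per micrometre of membrane, `k_fa(E)`, is a
#' piecewise-linear interpolation through the calibrated anchor points
#' 0.5, 0.8 and 1.0 g/s^2/um at 1.1, 4.5 and 11 kPa, clamped outside that
#' range (the substrate model is only validated on 1.1-11 kPa).
#'
#' @param ... named overrides of any default listed below.
#'
#' @section Defaults:
#' \describe{
#'   \item{eta}{damping coefficient, g/s. One global scalar; it fixes only the
#'     timescale of the overdamped dynamics.}
#'   \item{k_cort_const}{constant cortical line tension, g um/s^2.}
#'   \item{k_cort_perim}{perimeter-elasticity coefficient, g/s^2 (tension per
#'     um of perimeter strain).}
#'   \item{p0_coef}{rest perimeter P0 = p0_coef * sqrt(A0), dimensionless.}
#'   \item{k_junc}{cell-cell junction spring constant, g/s^2.}
#'   \item{k_area}{pressure stiffness, g/(um s^2).}
#'   \item{k_mem}{membrane segment spring constant (strain-normalized), g um/s^2.}
#'   \item{k_cont}{contact repulsion constant, g/s^2.}
#'   \item{k_edge}{epithelium-edge anchor constant, g/s^2.}
#'   \item{k_div}{division-furrow constriction constant, g um/s^2.}
#'   \item{fa_E, fa_k}{anchor points of the k_fa(E) law (kPa; g/s^2/um).}
#'   \item{d_fa_rupture}{focal-adhesion rupture extension, um (a hard
#'     geometric detachment cap).}
#'   \item{tau_fa}{focal-adhesion turnover time, s: in remodeling-enabled
#'     (minutes-timescale) runs each anchor's spring extension relaxes
#'     toward zero with this Maxwell time constant, modelling adhesion
#'     turnover; frozen in short elastic (micromanipulation) runs.}
#'   \item{f_fa_rupture}{focal-adhesion rupture force, AU: an anchor whose
#'     spring force exceeds this breaks irreversibly. Because anchor
#'     strength grows with substrate stiffness through k_fa(E), the same
#'     threshold yields no detachment on 1.1 kPa and increasing detachment
#'     on stiffer gels.}
#'   \item{l_max, l_min}{vertex add/remove segment-length thresholds, um.}
#'   \item{d_junc_pair, d_junc_unpair}{junction (re)pairing distances, um.}
#'   \item{A0_mean, A0_cv}{target-area distribution (um^2; coefficient of
#'     variation).}
#'   \item{T_div_mean, T_div_sd}{division-interval distribution, s (a
#'     compressed division clock: only the ordering and normal spread matter
#'     for tissue geometry, not the wall-clock 18 h cycle).}
#'   \item{T_furrow}{duration of active furrow constriction before the
#'     topological split, s.}
#'   \item{nu}{substrate Poisson ratio (PAA is nearly incompressible).}
#'   \item{substrate_h}{substrate lattice spacing, um.}
#'   \item{substrate_thickness}{gel thickness bonded to glass, um.}
#'   \item{dt_init, dt_min, dt_max, err_tol}{integrator controls (s; err_tol
#'     in um of step-doubling position discrepancy).}
#' }
#'
#' @return an object of class `epi_params` (a named list).
#' @export
#' @examples
#' p <- epi_params(k_junc = 5)
#' p$k_junc
epi_params <- function(...) {
  p <- list(
    eta           = 0.1,
    k_cort_const  = 1.0,
    k_cort_perim  = 0.06,
    p0_coef       = 3.65,
    k_junc        = 4.0,
    k_area        = 5.0,
    k_mem         = 4.0,
    k_cont        = 8.0,
    k_edge        = 1.0,
    k_div         = 3.0,
    fa_E          = c(1.1, 4.5, 11),
    fa_k          = c(0.5, 0.8, 1.0),
    d_fa_rupture  = 25,
    tau_fa        = 300,
    f_fa_rupture  = 22,
    l_max         = 3.0,
    l_min         = 1.0,
    d_junc_pair   = 0.8,
    d_junc_unpair = 1.6,
    A0_mean       = 90,
    A0_cv         = 0.15,
    T_div_mean    = 10,
    T_div_sd      = 3,
    T_furrow      = 1.5,
    nu            = 0.5,
    substrate_h   = 2.0,
    substrate_thickness = 100,
    dt_init       = 1e-4,
    dt_min        = 1e-8,
    dt_max        = 0.02,
    err_tol       = 1e-1
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("epi_params(): all overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("epi_params(): unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_params(p)
  structure(p, class = "epi_params")
}

validate_params <- function(p) {
  nonneg <- c("k_cort_const", "k_cort_perim", "k_junc", "k_area", "k_mem",
              "k_cont", "k_edge", "k_div", "d_fa_rupture", "f_fa_rupture")
  for (nm in nonneg)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("epi_params(): '", nm, "' must be a single non-negative number")
  if (p$eta <= 0) stop("epi_params(): 'eta' must be positive")
  if (p$l_min >= p$l_max) stop("epi_params(): need l_min < l_max")
  if (p$d_junc_pair > p$d_junc_unpair)
    stop("epi_params(): need d_junc_pair <= d_junc_unpair")
  if (length(p$fa_E) != length(p$fa_k) || is.unsorted(p$fa_E))
    stop("epi_params(): fa_E must be increasing and match fa_k in length")
  if (any(diff(p$fa_k) < 0))
    stop("epi_params(): k_fa(E) must be non-decreasing in E")
  if (any(p$fa_k < 0)) stop("epi_params(): focal adhesion strengths must be >= 0")
  if (p$A0_mean <= 0 || p$A0_cv < 0) stop("epi_params(): invalid area distribution")
  if (p$T_div_mean <= 0 || p$T_div_sd < 0) stop("epi_params(): invalid division clock")
  if (p$tau_fa <= 0) stop("epi_params(): tau_fa must be positive")
  if (p$dt_min <= 0 || p$dt_max <= p$dt_min) stop("epi_params(): invalid dt bounds")
  if (p$err_tol <= 0) stop("epi_params(): err_tol must be positive")
  invisible(p)
}

#' Focal-adhesion strength per micrometre of membrane as a function of
#' local substrate Young's modulus
#'
#' Piecewise-linear through the calibrated anchors in `p$fa_E`/`p$fa_k`,
#' clamped to the end values outside the calibrated stiffness range.
#'
#' @param E Young's modulus, kPa (vectorized).
#' @param p an [epi_params()] object.
#' @return strength in g/s^2 per um of represented membrane.
#' @export
k_fa <- function(E, p) {
  stats::approx(p$fa_E, p$fa_k, xout = pmin(pmax(E, min(p$fa_E)), max(p$fa_E)),
                rule = 2)$y
}

#' @export
print.epi_params <- function(x, ...) {
  cat("<epi_params> (um-s-g units; force AU = g um/s^2)\n")
  flat <- vapply(x, function(v) paste(format(v, digits = 4), collapse = ", "), "")
  cat(paste0("  ", format(names(flat)), " : ", flat, collapse = "\n"), "\n")
  invisible(x)
}
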