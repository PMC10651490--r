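# Darcy permeability (Kozeny-Carman) and interstitial fluid shear stress.

#' Equivalent circular diameter of a cross-sectional area
#' @param area cross-sectional area (any squared length unit).
#' @return diameter in the matching length unit, \code{sqrt(4 * area / pi)}.
#' @export
areaToDiameter <- function(area) sqrt(4 * area / pi)

#' Kozeny-Carman permeability of a porous medium
#'
#' \deqn{K_p = \frac{\varepsilon^3 d^2}{36 K (1-\varepsilon)^2}}
#' with \eqn{\varepsilon} the interstitial (extracellular) volume fraction,
#' \eqn{K} the Kozeny constant (shape/tortuosity factor, 4.5--5.5 for
#' channel-like brain interstitial space) and \eqn{d} the equivalent circular
#' pore diameter.
#'
#' @param epsilon volume fraction in (0, 1).
#' @param kozenyK Kozeny constant (> 0).
#' @param diameter pore diameter in metres.
#' @return permeability in m^2. All arguments recycle elementwise.
#' @examples
#' kozenyCarmanPermeability(0.2, 5.5, areaToDiameter(0.0083e-12))  # ~6.7e-19
#' @export
kozenyCarmanPermeability <- function(epsilon, kozenyK, diameter) {
  if (any(epsilon <= 0) || any(epsilon >= 1))
    stop("epsilon must lie strictly between 0 and 1")
  stopifnot(all(kozenyK > 0), all(diameter > 0))
  epsilon^3 * diameter^2 / (36 * kozenyK * (1 - epsilon)^2)
}

#' Darcy shear stress at the interstitial cell surface
#'
#' \deqn{\tau = \mu u / \sqrt{K_p}}
#' the standard porous-media estimate of the wall shear stress produced by a
#' superficial flow speed \eqn{u} through a medium of permeability
#' \eqn{K_p}.
#'
#' @param mu dynamic viscosity (Pa s).
#' @param u flow speed (m/s).
#' @param kp Darcy permeability (m^2).
#' @return shear stress in Pa; arguments recycle elementwise.
#' @examples
#' darcyShearStress(1e-3, 1e-6, 1e-18)  # 1 Pa
#' @export
darcyShearStress <- function(mu, u, kp) {
  stopifnot(all(mu > 0), all(u > 0), all(kp > 0))
  mu * u / sqrt(kp)
}

#' Default biophysical configuration for the shear-stress envelope
#'
#' The working ranges: flow speed 0.4--0.6 um/s (head-motion-enhanced
#' interstitial flow), Kozeny constant 4.5--5.5, channel cross-section
#' 0.0083--0.18 um^2 (measured envelope), extracellular volume fraction 0.2,
#' and dynamic viscosity 0.8 mPa s. The viscosity default is a point value:
#' interstitial fluid at body temperature plausibly spans 0.7--1.0 mPa s, but
#' the reported stress envelope for this tissue is only consistent with a
#' fixed viscosity near 0.8 mPa s, so the range is left to the caller to
#' widen explicitly.
#'
#' @param uUmPerS flow speed range (um/s).
#' @param muMPaS viscosity value or range (mPa s).
#' @param epsilon extracellular volume fraction value or range.
#' @param kozenyK Kozeny constant value or range.
#' @param areaUm2 cross-sectional area range (um^2).
#' @return named list understood by \code{\link{shearStressRange}}.
#' @export
shearConfig <- function(uUmPerS = c(0.4, 0.6), muMPaS = 0.8, epsilon = 0.2,
                        kozenyK = c(4.5, 5.5), areaUm2 = c(0.0083, 0.18)) {
  list(uUmPerS = uUmPerS, muMPaS = muMPaS, epsilon = epsilon,
       kozenyK = kozenyK, areaUm2 = areaUm2)
}

#' Shear-stress envelope over biophysical input ranges
#'
#' Evaluates the permeability/shear chain on every corner combination of the
#' input ranges. The shear stress is monotone in each argument, so the corner
#' set attains the extremes; the function returns the envelope together with
#' the corner attaining each bound. The permeability and shear formulas are
#' pluggable so an alternative algebra can be swapped without touching
#' callers.
#'
#' @param config list as returned by \code{\link{shearConfig}}; each entry is
#'   a value or a \code{c(low, high)} range in the interface units (um/s,
#'   mPa s, dimensionless, dimensionless, um^2). Conversion to SI happens
#'   here, at the boundary.
#' @param permeabilityFun function(epsilon, kozenyK, diameter) -> m^2.
#' @param shearFun function(mu, u, kp) -> Pa.
#' @return A \linkS4class{ShearStressEstimate}.
#' @examples
#' tauRange(shearStressRange())  # ~[0.076, 0.59] Pa
#' @export
shearStressRange <- function(config = shearConfig(),
                             permeabilityFun = kozenyCarmanPermeability,
                             shearFun = darcyShearStress) {
  rng <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 1) x <- c(x, x)
    if (length(x) != 2 || x[1] > x[2]) stop("each input must be a value or c(low, high)")
    unique(x)
  }
  g <- expand.grid(u = rng(config$uUmPerS), mu = rng(config$muMPaS),
                   epsilon = rng(config$epsilon), kozenyK = rng(config$kozenyK),
                   area = rng(config$areaUm2))
  kp <- permeabilityFun(g$epsilon, g$kozenyK, areaToDiameter(g$area * 1e-12))
  tau <- shearFun(g$mu * 1e-3, g$u * 1e-6, kp)
  iMin <- which.min(tau)
  iMax <- which.max(tau)
  corner <- function(i) {
    v <- as.numeric(g[i, ])
    names(v) <- c("uUmPerS", "muMPaS", "epsilon", "kozenyK", "areaUm2")
    v
  }
  new("ShearStressEstimate", kpRange = range(kp), tauRange = c(tau[iMin], tau[iMax]),
      minCorner = corner(iMin), maxCorner = corner(iMax),
      config = config)
}
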