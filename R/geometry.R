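#' Reference left-ventricular geometry
#'
#' Constructs the undeformed LV wall: a thick truncated prolate-spheroidal
#' shell bounded by the inner surface \code{mu0 = mu_in0}, the outer surface
#' \code{mu0 = mu_out0}, and the basal truncation \code{nu0 = nu_up}, with
#' interfocal half-distance \code{a0}.  All lengths are in cm, angles in
#' radians.
#'
#' Three named presets reproduce the matched-volume shapes used in the
#' shape-dependence experiments (all with cavity volume 59.8714 cm^3 and
#' wall volume 158.112 cm^3): \code{"spherical"}, \code{"normal"},
#' \code{"ellipsoidal"}.
#'
#' @param a0 interfocal half-distance (cm), or one of the preset names.
#' @param mu_in0,mu_out0 inner/outer wall radial coordinates (dimensionless).
#' @param nu_up basal truncation angle (rad); the wall spans
#'   \code{nu_up <= nu0 <= pi}.
#' @return An object of class \code{"lv_geometry"}.
#' @examples
#' g <- lv_geometry("normal")
#' cavity_volume(g)
#' @export
lv_geometry <- function(a0, mu_in0, mu_out0, nu_up = 1.1112) {
  if (is.character(a0)) {
    p <- lv_shape_presets()[[match.arg(a0, names(lv_shape_presets()))]]
    return(do.call(lv_geometry, p))
  }
  stopifnot(is.numeric(a0), a0 > 0,
            mu_in0 > 0, mu_out0 > mu_in0,
            nu_up > 0, nu_up < pi)
  g <- structure(list(a0 = a0, mu_in0 = mu_in0, mu_out0 = mu_out0,
                      nu_up = nu_up),
                 class = "lv_geometry")
  if (!(.ref_cavity_volume(g) > 0)) stop("degenerate geometry: nonpositive cavity volume")
  g
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat("LV reference geometry (truncated prolate spheroid)\n")
  cat(sprintf("  a0 = %.5g cm, mu_in0 = %.8g, mu_out0 = %.8g, nu_up = %.5g rad\n",
              x$a0, x$mu_in0, x$mu_out0, x$nu_up))
  cat(sprintf("  cavity volume %.6g cm^3, wall volume %.6g cm^3\n",
              cavity_volume(x), wall_volume(x)))
  invisible(x)
}

#' Matched-volume shape presets
#'
#' Geometric parameters of the three reference shapes with identical cavity
#' (59.8714 cm^3) and wall (158.112 cm^3) volumes.
#' @return Named list of argument lists for [lv_geometry()].
#' @export
lv_shape_presets <- function() {
  list(
    normal      = list(a0 = 4.6307, mu_in0 = 0.39521852, mu_out0 = 0.6719001,  nu_up = 1.1112),
    spherical   = list(a0 = 2.7307, mu_in0 = 0.7470308,  mu_out0 = 1.1173771,  nu_up = 1.1112),
    ellipsoidal = list(a0 = 6.7307, mu_in0 = 0.235,      mu_out0 = 0.426,      nu_up = 1.1112)
  )
}

#' Prolate spheroidal to Cartesian coordinates
#'
#' Maps prolate spheroidal coordinates \code{(mu, nu, phi)} with interfocal
#' half-distance \code{a} to Cartesian \code{(x, y, z)}:
#' \deqn{x = a \sinh\mu \sin\nu \cos\phi,\quad
#'       y = a \sinh\mu \sin\nu \sin\phi,\quad
#'       z = a \cosh\mu \cos\nu.}
#' Surfaces of constant \code{mu} are confocal prolate spheroids.
#'
#' @param a interfocal half-distance (cm), \code{a > 0}.
#' @param mu,nu,phi coordinates (vectors recycled to common length);
#'   \code{mu >= 0}, \code{0 <= nu <= pi}.
#' @return A data.frame with columns \code{x}, \code{y}, \code{z} (cm).
#' @seealso [prolate_metric()] for scale factors and the Jacobian determinant.
#' @export
prolate_to_cartesian <- function(a, mu, nu, phi = 0) {
  stopifnot(a > 0, all(mu >= 0), all(nu >= -1e-12), all(nu <= pi + 1e-12))
  data.frame(x = a * sinh(mu) * sin(nu) * cos(phi),
             y = a * sinh(mu) * sin(nu) * sin(phi),
             z = a * cosh(mu) * cos(nu))
}

#' Scale factors and Jacobian determinant of prolate spheroidal coordinates
#'
#' @inheritParams prolate_to_cartesian
#' @return A data.frame with the scale factors \code{g_mu = g_nu =
#'   a*sqrt(sinh^2 mu + sin^2 nu)}, \code{g_phi = a*sinh(mu)*sin(nu)} and the
#'   Jacobian determinant \code{detJ = a^3 sinh(mu) sin(nu) (sinh^2 mu +
#'   sin^2 nu)}.
#' @export
prolate_metric <- function(a, mu, nu) {
  sh <- sinh(mu); sn <- sin(nu)
  h <- sh^2 + sn^2
  data.frame(g_mu = a * sqrt(h), g_nu = a * sqrt(h), g_phi = a * sh * sn,
             detJ = a^3 * sh * sn * h)
}

## Closed-form cavity volume of the *reference* truncated spheroid:
## solid of revolution of the surface mu = const from the apex (nu = pi)
## to nu_up, closed by a flat disk at the basal edge.
## V = pi a^3 sinh^2(mu) cosh(mu) * int_{nu_up}^{pi} sin^3 nu dnu
.truncated_spheroid_volume <- function(a, mu, nu_up) {
  cu <- cos(nu_up)
  pi * a^3 * sinh(mu)^2 * cosh(mu) * (2 / 3 + cu - cu^3 / 3)
}

.ref_cavity_volume <- function(geom) {
  .truncated_spheroid_volume(geom$a0, geom$mu_in0, geom$nu_up)
}

.ref_wall_volume <- function(geom) {
  .truncated_spheroid_volume(geom$a0, geom$mu_out0, geom$nu_up) -
    .ref_cavity_volume(geom)
}

#' Build a reference shape with prescribed cavity and wall volumes
#'
#' Solves for the inner and outer wall coordinates \code{mu_in0},
#' \code{mu_out0} such that the reference cavity volume (solid of revolution
#' of the endocardial surface, closed flat at the basal endocardial edge)
#' and the wall volume (epicardial solid of revolution minus cavity) match
#' the targets.  Both solves are monotone one-dimensional root finds on the
#' truncated-spheroid closed form.
#'
#' @param cavity target cavity volume (cm^3).
#' @param wall target wall volume (cm^3).
#' @param a0 interfocal half-distance (cm).
#' @param nu_up basal truncation angle (rad).
#' @param tol relative tolerance of the volume match.
#' @return An [lv_geometry()] object with the requested volumes.
#' @examples
#' g <- build_matched_shape(59.8714, 158.112, a0 = 2.7307)
#' c(g$mu_in0, g$mu_out0)   # spherical-shape wall coordinates
#' @export
build_matched_shape <- function(cavity, wall, a0, nu_up = 1.1112,
                                tol = 1e-10) {
  stopifnot(cavity > 0, wall > 0, a0 > 0)
  solve_mu <- function(target) {
    f <- function(mu) .truncated_spheroid_volume(a0, mu, nu_up) - target
    hi <- 1
    while (f(hi) < 0 && hi < 50) hi <- hi * 2
    if (f(hi) < 0) stop("infeasible volume target: no mu solves")
    stats::uniroot(f, c(1e-8, hi), tol = tol * max(1, target))$root
  }
  mu_in <- solve_mu(cavity)
  mu_out <- solve_mu(cavity + wall)
  lv_geometry(a0, mu_in, mu_out, nu_up)
}

#' Uniform-fiber-stress pressure ratio
#'
#' Ratio of cavity pressure to fiber stress predicted by the uniform-stress
#' model of Arts and co-workers for any rotationally symmetric ventricle:
#' \deqn{p/\sigma_{ff} = \frac{1}{3}\ln(1 + V_{wall}/V).}
#' Used to overlay the uniform-stress prediction on computed fiber-stress
#' time courses.
#'
#' @param v_wall wall volume (cm^3).
#' @param v cavity volume (cm^3); both may be vectors.
#' @return The dimensionless ratio \code{p / sigma_ff}.
#' @export
arts_ratio <- function(v_wall, v) {
  stopifnot(all(v_wall > 0), all(v > 0))
  log1p(v_wall / v) / 3
}
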