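#' Helical muscle fiber field
#'
#' Fibers lie in surfaces of constant \code{mu0} and wind helically with a
#' wrapping parameter \code{omega(mu0)} chosen so that the equatorial helix
#' angle varies linearly across the wall from \code{psi_in} (endocardium,
#' default +85 degrees) to \code{psi_out} (epicardium, default -65 degrees),
#' following the transmural profile measured by Streeter.  The local fiber
#' angle is measured from the circumferential direction either as
#' \code{psi} in (-pi/2, pi/2] or as the quadrant-adjusted
#' \code{psi* = psi + pi} for \code{psi < 0} (so \code{0 <= psi* < pi}).
#'
#' @param geometry an [lv_geometry()] object.
#' @param psi_in_deg endocardial equatorial helix angle (degrees).
#' @param psi_out_deg epicardial equatorial helix angle (degrees).
#' @param L_s0 reference (slack) sarcomere length (micrometers).
#' @return An object of class \code{"lv_fibers"}.
#' @export
lv_fibers <- function(geometry, psi_in_deg = 85, psi_out_deg = -65,
                      L_s0 = 1.82) {
  stopifnot(inherits(geometry, "lv_geometry"), L_s0 > 0)
  structure(list(geometry = geometry,
                 psi_in = psi_in_deg * pi / 180,
                 psi_out = psi_out_deg * pi / 180,
                 L_s0 = L_s0),
            class = "lv_fibers")
}

#' Equatorial helix angle profile
#'
#' Linear transmural interpolation of the fiber angle at the equator
#' (\code{nu0 = pi/2}) between the endocardial and epicardial values.
#'
#' @param mu0 transmural coordinate(s) in \code{[mu_in0, mu_out0]}.
#' @param fibers an [lv_fibers()] object.
#' @return \code{psi_eq} in radians (signed).
#' @export
equatorial_angle <- function(mu0, fibers) {
  g <- fibers$geometry
  w <- (mu0 - g$mu_in0) / (g$mu_out0 - g$mu_in0)
  fibers$psi_in * (1 - w) + fibers$psi_out * w
}

#' Wrapping parameter from the equatorial helix angle
#'
#' Inverts the equatorial relation \code{cos(psi*_eq) =
#' omega*sinh(mu0)/sqrt(cosh^2 mu0 + omega^2 sinh^2 mu0)} to
#' \code{omega = cot(psi*_eq) * coth(mu0)}.  A vanishing \code{psi*_eq}
#' means exactly circumferential fibers, for which the wrapping parameter
#' is undefined (signalled as infinite; the fiber curves degenerate to
#' circles of constant \code{nu0}).
#'
#' @param psi_eq_star quadrant-adjusted equatorial angle (rad) in \code{[0, pi)}.
#' @param mu0 transmural coordinate(s).
#' @return \code{omega} (dimensionless; \code{Inf} with the sign of
#'   \code{cos(psi*_eq)} for circumferential fibers).
#' @export
wrapping_parameter <- function(psi_eq_star, mu0) {
  out <- ifelse(sin(psi_eq_star) == 0,
                Inf * sign(cos(psi_eq_star)),
                cos(psi_eq_star) / sin(psi_eq_star) / tanh(mu0))
  out
}

.psi_star_adjust <- function(psi) ifelse(psi < 0, psi + pi, psi)

## omega at a transmural position from the equatorial profile
.omega_at <- function(mu0, fibers) {
  wrapping_parameter(.psi_star_adjust(equatorial_angle(mu0, fibers)), mu0)
}

#' Local fiber angle
#'
#' The quadrant-adjusted fiber angle \code{psi*} at reference position
#' \code{(mu0, nu0)}:
#' \deqn{\cos\psi^* = \frac{\omega \sinh\mu_0 \sin^2\nu_0}
#'  {\sqrt{\sinh^2\mu_0 + \sin^2\nu_0 + \omega^2\sinh^2\mu_0\sin^4\nu_0}}.}
#' At the apex (\code{nu0 -> pi}) fibers become meridional
#' (\code{psi* -> pi/2}); on the midwall surface where the equatorial
#' angle changes sign, fibers are circumferential (\code{psi* = 0}).
#'
#' @inheritParams equatorial_angle
#' @param nu0 polar coordinate(s) in \code{[nu_up, pi]}.
#' @return \code{psi*} in \code{[0, pi)} (radians).
#' @export
fiber_angle <- function(mu0, nu0, fibers) {
  n <- max(length(mu0), length(nu0))
  mu0 <- rep_len(mu0, n); nu0 <- rep_len(nu0, n)
  om <- .omega_at(mu0, fibers)
  acos(.cos_psi_star(om, mu0, nu0))
}

.cos_psi_star <- function(omega, mu0, nu0) {
  sh <- sinh(mu0); sn <- sin(nu0)
  num <- omega * sh * sn^2
  den <- sqrt(sh^2 + sn^2 + omega^2 * sh^2 * sn^4)
  cp <- ifelse(is.infinite(omega), sign(omega) * (sn > 0), num / den)
  pmin(pmax(cp, -1), 1)
}

## sin(psi*) >= 0 companion (psi* in [0, pi])
.sin_psi_star <- function(omega, mu0, nu0) {
  sqrt(pmax(1 - .cos_psi_star(omega, mu0, nu0)^2, 0))
}

#' Local fiber basis
#'
#' Orthonormal right-handed basis of the fiber frame \code{(s, n, f)} at a
#' reference point: \code{s} is the transmural (mu) direction, \code{f} is
#' the unit tangent of the fiber curve, and \code{n = f x s}.  The returned
#' rotation matrix has the \code{(s, n, f)} basis vectors as columns in
#' prolate-spheroidal \code{(mu, nu, phi)} components, so that fiber-frame
#' tensor components \code{T} transform to prolate components as
#' \code{Q \%*\% T \%*\% t(Q)}:
#' \deqn{Q = \begin{pmatrix} 1 & 0 & 0\\ 0 & -\cos\psi^* & \sin\psi^*\\
#'   0 & -\sin\psi^* & -\cos\psi^* \end{pmatrix}.}
#'
#' @inheritParams fiber_angle
#' @param mu0,nu0 scalar reference coordinates.
#' @return A 3x3 orthogonal matrix with determinant +1.
#' @export
fiber_basis <- function(mu0, nu0, fibers) {
  psi <- fiber_angle(mu0, nu0, fibers)
  .Q_matrix(cos(psi), sin(psi))
}

.Q_matrix <- function(cp, sp) {
  matrix(c(1, 0, 0,
           0, -cp, -sp,
           0, sp, -cp), 3, 3)
}

#' Fiber stretch ratio and sarcomere length
#'
#' Computes the fiber stretch \code{lambda_f = ds/ds0} at a reference point
#' by two independent routes that must agree: (i) the ratio of deformed to
#' reference arc-length increments of the helical fiber curve, and (ii) the
#' tensor contraction \code{lambda_f^2 = f0' C f0} with the unit reference
#' fiber direction.  Returns the sarcomere length \code{L_s = lambda_f *
#' L_s0} and fiber Green strain \code{eps_f = (lambda_f^2 - 1)/2}.
#'
#' @inheritParams solve_mapped_mu
#' @param fibers an [lv_fibers()] object.
#' @param mu0,nu0 reference coordinates (vectors recycled).
#' @return A data.frame with \code{lambda_f}, \code{lambda_f_arc},
#'   \code{L_s}, \code{eps_f}.
#' @export
fiber_stretch <- function(geometry, state, fibers, mu0, nu0) {
  s <- .state_vec(state)
  n <- max(length(mu0), length(nu0))
  mu0 <- rep_len(mu0, n); nu0 <- rep_len(nu0, n)
  k <- .kin_points(geometry, s[1], s[2], s[3], mu0, nu0)
  om <- .omega_at(mu0, fibers)
  cp <- .cos_psi_star(om, mu0, nu0)
  sp <- sqrt(pmax(1 - cp^2, 0))
  ## route (ii): contraction with f0 = (0, sin psi*, -cos psi*)
  lam2 <- sp^2 * k$C22 - 2 * sp * cp * k$C23 + cp^2 * k$C33
  ## route (i): arc-length ratio (finite omega only; circumferential fibers
  ## use the phi-circle parameterization instead)
  sn <- sin(nu0)
  sh <- k$sh
  ds <- (geometry$a0 + s[1]) *
    sqrt((1 + k$dmu_dnu0^2) * (sh^2 + sn^2) + (om + s[3])^2 * sh^2 * sn^4)
  ds0 <- geometry$a0 *
    sqrt(sinh(mu0)^2 + sn^2 + om^2 * sinh(mu0)^2 * sn^4)
  lam_arc <- ifelse(is.finite(om), ds / ds0,
                    ## circumferential: stretch of the phi circle
                    ((geometry$a0 + s[1]) * sh) / (geometry$a0 * sinh(mu0)))
  lam <- sqrt(lam2)
  data.frame(lambda_f = lam, lambda_f_arc = lam_arc,
             L_s = lam * fibers$L_s0, eps_f = (lam2 - 1) / 2)
}
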