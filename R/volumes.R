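## Simpson weights on n (odd) equally spaced nodes over [a, b]
.simpson_weights <- function(a, b, n) {
  if (n < 3L || n %% 2L == 0L) stop("Simpson rule needs an odd number of nodes >= 3")
  h <- (b - a) / (n - 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- w[n] <- 1
  w * h / 3
}

## Surface-of-revolution machinery.  The deformed endocardial (or
## epicardial) surface is the image of mu0 = const; its meridian curve
## (r(nu0), z(nu0)) and the sensitivities dr/da_i, dz/da_i come from the
## kinematics engine evaluated on a line of nu0 nodes.
.surface_line <- function(geom, s, mu0_surf, n_line, with_derivs = FALSE) {
  nu <- seq(geom$nu_up, pi, length.out = n_line)
  w <- .simpson_weights(geom$nu_up, pi, n_line)
  if (with_derivs) {
    kp <- .kin_with_perturbations(geom, s, rep(mu0_surf, n_line), nu)
    d <- .strain_derivs(kp)
    list(nu = nu, w = w, k = kp$base,
         dr = lapply(d, `[[`, "dr"), dz = lapply(d, `[[`, "dz"))
  } else {
    list(nu = nu, w = w,
         k = .kin_points(geom, s[1], s[2], s[3], rep(mu0_surf, n_line), nu))
  }
}

## volume of the solid of revolution below the flat basal cap:
## V = pi * int r^2 (-dz/dnu0) dnu0 over [nu_up, pi]
.solid_volume <- function(line) {
  sum(line$w * line$k$r^2 * (-line$k$dz_dnu0)) * pi
}

#' Cavity volume of the (possibly deformed) left ventricle
#'
#' Volume of the solid of revolution bounded by the deformed endocardial
#' surface from the apex to the basal truncation, closed by a flat disk at
#' the height of the basal endocardial edge.  Optionally returns the
#' sensitivities \code{dV/da_i}, computed from the boundary line integral
#' (lateral sweep plus basal-disk sweep); torsion does not change the
#' volume, so \code{dV/da3 = 0}.
#'
#' @inheritParams solve_mapped_mu
#' @param state kinematic state (default: reference configuration).
#' @param derivatives if \code{TRUE} also return \code{dV_da}.
#' @param n_line number of Simpson nodes along the meridian (odd).
#' @return Volume in cm^3, or a list \code{(V, dV_da)} when
#'   \code{derivatives = TRUE}.
#' @export
cavity_volume <- function(geometry, state = lv_state(), derivatives = FALSE,
                          n_line = 201) {
  s <- .state_vec(state)
  ln <- .surface_line(geometry, s, geometry$mu_in0, n_line,
                      with_derivs = derivatives)
  V <- .solid_volume(ln)
  if (!derivatives) return(V)
  list(V = V, dV_da = .volume_derivs_line(ln))
}

## dV/da_i = pi r_b^2 dz_b/da_i + 2 pi int r (r' dz/da_i - z' dr/da_i) dnu0
.volume_derivs_line <- function(ln) {
  k <- ln$k
  vapply(1:3, function(i) {
    pi * k$r[1]^2 * ln$dz[[i]][1] +
      2 * pi * sum(ln$w * k$r *
                     (k$dr_dnu0 * ln$dz[[i]] - k$dz_dnu0 * ln$dr[[i]]))
  }, numeric(1))
}

#' Wall volume of the (possibly deformed) left ventricle
#'
#' Volume of the epicardial solid of revolution (same flat-cap construction
#' as [cavity_volume()], at the epicardial basal edge) minus the cavity
#' volume.  For the reference configuration this reproduces the
#' truncated-spheroid closed form.
#'
#' @inheritParams cavity_volume
#' @return Wall volume in cm^3.
#' @export
wall_volume <- function(geometry, state = lv_state(), n_line = 201) {
  s <- .state_vec(state)
  .solid_volume(.surface_line(geometry, s, geometry$mu_out0, n_line)) -
    .solid_volume(.surface_line(geometry, s, geometry$mu_in0, n_line))
}

## Material volume of the wall (the (mu0, nu0) rectangle mapped forward);
## invariant under the mapping because det F = 1.  Computed in the deformed
## configuration as a quadrature of det(F) |J0| -- used as the
## volume-preservation oracle.
.material_wall_volume <- function(geom, s, n_mu = 33, n_nu = 33) {
  mu <- seq(geom$mu_in0, geom$mu_out0, length.out = n_mu)
  nu <- seq(geom$nu_up, pi, length.out = n_nu)
  wmu <- .simpson_weights(geom$mu_in0, geom$mu_out0, n_mu)
  wnu <- .simpson_weights(geom$nu_up, pi, n_nu)
  gr <- expand.grid(mu0 = mu, nu0 = nu)
  w <- as.vector(outer(wmu, wnu))
  k <- .kin_points(geom, s[1], s[2], s[3], gr$mu0, gr$nu0)
  m0 <- prolate_metric(geom$a0, gr$mu0, gr$nu0)
  2 * pi * sum(w * k$detF * m0$detJ)
}
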