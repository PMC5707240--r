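#' Kinematic state of the deformation family
#'
#' The three time-dependent parameters of the volume-preserving deformation
#' family: \code{a1} lengthens (\code{a1 > 0}) or shortens (\code{a1 < 0})
#' the ventricle through the interfocal distance \code{a = a0 + a1};
#' \code{a2} contracts (\code{a2 > 0}) or expands (\code{a2 < 0}) the wall;
#' \code{a3} twists the wall about its axis, increasing from base to apex.
#'
#' @param a1 elongation parameter (cm).
#' @param a2 contraction parameter (cm).
#' @param a3 torsion parameter (rad).
#' @return A named numeric vector of class \code{"lv_state"}.
#' @export
lv_state <- function(a1 = 0, a2 = 0, a3 = 0) {
  structure(c(a1 = a1, a2 = a2, a3 = a3), class = "lv_state")
}

.state_vec <- function(state) {
  s <- unname(as.numeric(state))
  if (length(s) != 3L || any(!is.finite(s))) stop("state must be 3 finite numbers (a1, a2, a3)")
  s
}

## ---------------------------------------------------------------------------
## Implicit radial mapping mu(mu0, nu0)
##
## Volume preservation (equality of |J| d mu d nu d phi element integrals,
## with nu and phi unchanged up to torsion) defines mu implicitly through a
## cubic in u = cosh(mu):
##    u^3/3 - cos^2(nu0) u - (1/3 - cos^2(nu0)) = R0(mu0, nu0) / a^3
## where a = a0 + a1 and R0 collects the reference-side terms including the
## a2 contraction of the inner surface.  The physical root is the branch
## continuous with u = cosh(mu0) at a1 = a2 = 0 and satisfies u > 1.
## ---------------------------------------------------------------------------

## Vectorized core: all arguments recycled to common length.
## Returns u = cosh(mu), mu, partials of mu, and the deformed interfocal a.
.map_mu <- function(geom, a1, a2, mu0, nu0, tol = 1e-14, maxit = 60L) {
  a0 <- geom$a0
  a <- a0 + a1
  if (any(a <= 0)) stop("inadmissible state: a0 + a1 <= 0")
  c2 <- cos(nu0)^2
  chin <- cosh(geom$mu_in0)
  ch0 <- cosh(mu0)
  R0 <- a0^3 * ch0 * (ch0^2 / 3 - c2) -
    a2 * a0^2 * chin * (chin^2 / 3 - c2) -
    a0^2 * (a0 - a2) * (1 / 3 - c2)
  rhs <- R0 / a^3
  if (any(rhs <= 0))
    stop("deformation too extreme: mapped mu would leave the physical domain (mu <= 0)")
  ## Newton on f(u) = u^3/3 - c2*u - (1/3 - c2) - rhs, f'(u) = u^2 - c2 > 0
  u <- pmax(ch0, 1 + 1e-12)
  third <- 1 / 3 - c2
  for (it in 1:3) {
    u <- u - (u^3 / 3 - c2 * u - third - rhs) / (u^2 - c2)
    if (any(u <= 1)) u <- pmax(u, 1 + 1e-15)
  }
  for (it in seq_len(maxit)) {
    du <- (u^3 / 3 - c2 * u - third - rhs) / (u^2 - c2)
    u <- u - du
    if (any(u <= 1)) u <- pmax(u, 1 + 1e-15)
    if (max(abs(du)) < tol) break
  }
  sh <- sqrt(u^2 - 1)
  if (any(sh <= 0))
    stop("deformation too extreme: mapped mu reached zero")
  dR0_dmu0 <- a0^3 * sinh(mu0) * (ch0^2 - c2)
  dc2 <- -sin(2 * nu0)
  df_dnu0 <- dc2 * (1 - u) -
    dc2 * (-a0^3 * ch0 + a2 * a0^2 * chin + a0^2 * (a0 - a2)) / a^3
  denom <- u^2 - c2
  du_dmu0 <- dR0_dmu0 / (a^3 * denom)
  du_dnu0 <- -df_dnu0 / denom
  list(a = a, u = u, sh = sh,
       dmu_dmu0 = du_dmu0 / sh, dmu_dnu0 = du_dnu0 / sh)
}

#' Solve the volume-preserving radial mapping
#'
#' Finds the deformed radial coordinate \code{mu} of the material point with
#' reference coordinates \code{(mu0, nu0)} under a kinematic state, together
#' with the partial derivatives of the implicit mapping.  The mapping keeps
#' \code{nu = nu0} and preserves the volume of every material shell; the
#' root of the cubic in \code{cosh(mu)} is found by safeguarded Newton
#' iteration started from the reference value.
#'
#' @param geometry an [lv_geometry()] object.
#' @param state an [lv_state()] (or numeric vector \code{c(a1, a2, a3)}).
#' @param mu0,nu0 reference coordinates (vectors, recycled).
#' @return A data.frame with \code{mu}, \code{dmu_dmu0}, \code{dmu_dnu0}.
#' @export
solve_mapped_mu <- function(geometry, state, mu0, nu0) {
  s <- .state_vec(state)
  n <- max(length(mu0), length(nu0))
  m <- .map_mu(geometry, s[1], s[2], rep_len(mu0, n), rep_len(nu0, n))
  data.frame(mu = asinh(m$sh), dmu_dmu0 = m$dmu_dmu0, dmu_dnu0 = m$dmu_dnu0)
}

#' Torsional component of the deformation
#'
#' \deqn{\phi = \phi_0 + a_3(\cos\nu_0 - \cos\nu_{up})}
#' Torsion vanishes at the base \code{nu0 = nu_up} and grows toward the
#' apex; the dependence on \code{cos(nu0)} avoids a singularity of the
#' deformation field at the apex.
#'
#' @param state an [lv_state()] or numeric \code{c(a1, a2, a3)}.
#' @param nu0 reference polar coordinate(s), \code{nu_up <= nu0 <= pi}.
#' @param phi0 reference azimuthal coordinate(s).
#' @param nu_up basal truncation angle (rad).
#' @return Deformed azimuthal coordinate(s) \code{phi}.
#' @export
torsion_phi <- function(state, nu0, phi0 = 0, nu_up = 1.1112) {
  s <- .state_vec(state)
  phi0 + s[3] * (cos(nu0) - cos(nu_up))
}

## ---------------------------------------------------------------------------
## Deformation tensors in orthonormal prolate-spheroidal components.
##
## With nu = nu0 and phi = phi0 + a3 (cos nu0 - cos nu_up), the physical
## deformation gradient has the sparsity
##      [ F11 F12  0  ]
##  F = [  0  F22  0  ],   F11 = (g_mu/g0_mu) dmu/dmu0, ...
##      [  0  F32 F33 ]
## so C = F^T F and E = (C - I)/2 have identically zero (1,3) components.
## Tensors are carried as five vectors (11, 12, 22, 23, 33).
## ---------------------------------------------------------------------------

## Vectorized kinematics at points (mu0, nu0) for per-point states
## (a1, a2, a3 may vary across points).  Returns a list of vectors; with
## minimal = TRUE only the strain components and meridian position needed
## for finite differencing are computed.
.kin_points <- function(geom, a1, a2, a3, mu0, nu0, minimal = FALSE) {
  n <- max(length(mu0), length(nu0), length(a1))
  mu0 <- rep_len(mu0, n); nu0 <- rep_len(nu0, n)
  a1 <- rep_len(a1, n); a2 <- rep_len(a2, n); a3 <- rep_len(a3, n)
  m <- .map_mu(geom, a1, a2, mu0, nu0)
  a0 <- geom$a0
  sn <- sin(nu0); cn <- cos(nu0)
  sh0 <- sinh(mu0)
  h0 <- sqrt(sh0^2 + sn^2)          # g0_mu / a0 = g0_nu / a0
  sh <- m$sh; ch <- m$u; a <- m$a
  h <- sqrt(sh^2 + sn^2)
  g_ratio_m <- (a * h) / (a0 * h0)           # g_mu/g0_mu = g_nu/g0_nu
  F11 <- g_ratio_m * m$dmu_dmu0
  F12 <- g_ratio_m * m$dmu_dnu0
  F22 <- g_ratio_m
  qsn <- (a * sh * sn^2) / (a0 * h0)
  F32 <- -qsn * a3
  F33 <- (a * sh) / (a0 * sh0)
  C12 <- F11 * F12
  C22 <- F12^2 + F22^2 + F32^2
  C23 <- F32 * F33
  out <- list(E11 = (F11^2 - 1) / 2, E12 = C12 / 2, E22 = (C22 - 1) / 2,
              E23 = C23 / 2, E33 = (F33^2 - 1) / 2,
              r = a * sh * sn, z = a * ch * cn)
  if (minimal) return(out)
  c(out,
    list(mu = asinh(sh), dmu_dmu0 = m$dmu_dmu0, dmu_dnu0 = m$dmu_dnu0,
         a = a, sh = sh, ch = ch,
         F11 = F11, F12 = F12, F22 = F22, F32 = F32, F33 = F33,
         dF32_da3 = -qsn,
         detF = F11 * F22 * F33,
         C11 = F11^2, C12 = C12, C22 = C22, C23 = C23, C33 = F33^2,
         ## meridian-curve derivatives along nu0 (for line integrals)
         dr_dnu0 = a * (ch * m$dmu_dnu0 * sn + sh * cn),
         dz_dnu0 = a * (sh * m$dmu_dnu0 * cn - ch * sn)))
}

## Finite-difference steps for the kinematic parameters.
.fd_steps <- function(s, h = 1e-5) h * pmax(1, abs(s))

## Kinematics at the base state together with the strain sensitivities
## dE/da_i: a1 and a2 by central differences of the mapping (one stacked
## vectorized evaluation of the four perturbed states), a3 analytically
## (only F32 depends on a3, linearly).  Each dE_i carries the five strain
## components plus dr/da_i, dz/da_i of the meridian position.
.kin_with_perturbations <- function(geom, s, mu0, nu0, h = 1e-5) {
  n <- max(length(mu0), length(nu0))
  mu0 <- rep_len(mu0, n); nu0 <- rep_len(nu0, n)
  base <- .kin_points(geom, s[1], s[2], s[3], mu0, nu0)
  hs <- .fd_steps(s, h)
  states <- rbind(s + c(hs[1], 0, 0), s - c(hs[1], 0, 0),
                  s + c(0, hs[2], 0), s - c(0, hs[2], 0))
  idx <- rep(1:4, each = n)
  kin <- .kin_points(geom,
                     a1 = states[idx, 1], a2 = states[idx, 2],
                     a3 = states[idx, 3],
                     mu0 = rep(mu0, 4L), nu0 = rep(nu0, 4L),
                     minimal = TRUE)
  comps <- c("E11", "E12", "E22", "E23", "E33", "r", "z")
  dd <- function(i) {
    ip <- ((2 * i - 2) * n + 1):((2 * i - 1) * n)
    im <- ((2 * i - 1) * n + 1):((2 * i) * n)
    d <- lapply(comps, function(cc) (kin[[cc]][ip] - kin[[cc]][im]) / (2 * hs[i]))
    names(d) <- c(comps[1:5], "dr", "dz")
    d
  }
  zero <- numeric(n)
  dE3 <- list(E11 = zero, E12 = zero,
              E22 = base$F32 * base$dF32_da3,
              E23 = base$dF32_da3 * base$F33 / 2,
              E33 = zero, dr = zero, dz = zero)
  list(base = base, dE = list(dd(1), dd(2), dE3), steps = hs)
}

## strain sensitivities accessor (kept for clarity at call sites)
.strain_derivs <- function(kp) kp$dE

#' Deformation tensors at a material point
#'
#' Computes the deformation gradient \code{F}, right Cauchy-Green tensor
#' \code{C = t(F) \%*\% F} and Green-Lagrange strain \code{E = (C - I)/2} in
#' orthonormal prolate-spheroidal components at reference point
#' \code{(mu0, nu0)}, together with the strain sensitivities
#' \code{dE/da_i} with respect to the three kinematic parameters
#' (by validated central differencing of the mapping).  \code{det(F) = 1}
#' expresses the incompressibility built into the mapping family.
#'
#' @inheritParams solve_mapped_mu
#' @param mu0,nu0 scalar reference coordinates inside the wall.
#' @return A list with 3x3 matrices \code{F}, \code{C}, \code{E}, the scalar
#'   \code{detF}, the mapped \code{mu} and its partials, and \code{dE_da}, a
#'   list of three 3x3 matrices.
#' @export
deformation_tensors <- function(geometry, state, mu0, nu0) {
  stopifnot(length(mu0) == 1L, length(nu0) == 1L)
  s <- .state_vec(state)
  kp <- .kin_with_perturbations(geometry, s, mu0, nu0)
  k <- kp$base
  Fm <- matrix(c(k$F11, 0, 0, k$F12, k$F22, k$F32, 0, 0, k$F33), 3, 3)
  Cm <- t(Fm) %*% Fm
  Em <- (Cm - diag(3)) / 2
  dE <- lapply(.strain_derivs(kp), function(d)
    matrix(c(d$E11, d$E12, 0, d$E12, d$E22, d$E23, 0, d$E23, d$E33), 3, 3))
  dimnames(Fm) <- dimnames(Cm) <- dimnames(Em) <-
    list(c("mu", "nu", "phi"), c("mu", "nu", "phi"))
  list(F = Fm, C = Cm, E = Em, detF = k$detF,
       mu = k$mu, dmu_dmu0 = k$dmu_dmu0, dmu_dnu0 = k$dmu_dnu0,
       dE_da = dE)
}
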