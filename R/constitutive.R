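#' Material, activation and fiber parameters
#'
#' Returns the default material parameter set, optionally overridden.
#' Units: stresses kPa, times s, sarcomere lengths micrometers.
#'
#' Active contraction: \code{F0} peak active stress scale (300 kPa),
#' \code{k_av} force-velocity coefficient (0.5 kPa s), \code{k}
#' Frank-Starling force sensitivity to end-diastolic fiber strain (0 =
#' disabled), \code{k_prime} activation-shape sensitivity (1), \code{L_smax}
#' optimal sarcomere length (2.23 um), \code{L_sw} length-tension width
#' (0.2 um), \code{T_a} activation period (0.4 s), \code{T_c} cycle period
#' (1 s).  Passive elasticity (Fung-type, transversely isotropic):
#' \code{c1} stress scale (1 kPa) and exponent coefficients \code{b_ff} (5),
#' \code{b_xx} (3), \code{b_fx} (7).  Kelvin-Voigt matrix viscosity
#' \code{k_vm} (0.025 kPa s).  Fiber architecture: \code{psi_in_deg} (85),
#' \code{psi_out_deg} (-65), \code{L_s0} (1.82 um).
#'
#' @param ... name = value overrides of any default.
#' @return A named list of class \code{"lv_material"}.
#' @export
lv_material <- function(...) {
  p <- list(
    F0 = 300, k_av = 0.5, k = 0, k_prime = 1,
    L_smax = 2.23, L_sw = 0.2, T_a = 0.4, T_c = 1.0,
    c1 = 1, b_ff = 5, b_xx = 3, b_fx = 7, k_vm = 0.025,
    psi_in_deg = 85, psi_out_deg = -65, L_s0 = 1.82,
    clamp_active = FALSE
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown material parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$F0 > 0, p$L_sw > 0, p$T_a > 0, p$T_a <= p$T_c,
            p$c1 >= 0, p$b_ff >= 0, p$b_xx >= 0, p$b_fx >= 0, p$k_vm >= 0)
  structure(p, class = "lv_material")
}

#' Fiber activation function
#'
#' Time course of active-stress activation within a cycle:
#' \deqn{A(t) = [\sin(\pi t/T_a)]^d,\qquad d = 1/(1 + k' \epsilon_{f,ed})}
#' for \code{0 <= t <= T_a}, and \code{A = 0} for \code{T_a <= t <= T_c}.
#' The exponent steepens (preload low) or broadens (preload high) the
#' activation according to the end-diastolic fiber strain at the material
#' point, so \code{A} is a field, not a single scalar.
#'
#' @param t_cycle time after the start of contraction within a cycle (s).
#' @param eps_f_ed end-diastolic fiber Green strain at the point(s).
#' @param params an [lv_material()] list.
#' @return Activation in \code{[0, 1]} (vectorized over \code{eps_f_ed}).
#' @export
activation <- function(t_cycle, eps_f_ed = 0, params = lv_material()) {
  stopifnot(t_cycle >= 0, t_cycle <= params$T_c + 1e-12)
  d <- 1 / (1 + params$k_prime * eps_f_ed)
  if (any(d <= 0))
    stop("pathological end-diastolic strain: activation exponent d <= 0")
  if (t_cycle >= params$T_a) return(rep(0, length(eps_f_ed)))
  sin(pi * t_cycle / params$T_a)^d
}

#' Length-tension relation
#'
#' Gaussian dependence of active stress on sarcomere length, peaked at
#' \code{L_smax} with width \code{L_sw}:
#' \deqn{G(L_s) = \exp(-(L_s - L_{smax})^2 / (2 L_{sw}^2)).}
#'
#' @param L_s sarcomere length(s), micrometers.
#' @param params an [lv_material()] list.
#' @return \code{G} in \code{(0, 1]}.
#' @export
length_tension <- function(L_s, params = lv_material()) {
  stopifnot(all(L_s > 0))
  exp(-(L_s - params$L_smax)^2 / (2 * params$L_sw^2))
}

#' Active fiber stress (second Piola-Kirchhoff)
#'
#' Uniaxial active Cauchy stress in the fiber direction,
#' \deqn{\sigma_{ff} = A\,G\,(F_0 + k_{av}\,d\epsilon_f/dt)\,(1 + k\,\epsilon_{f,ed}),}
#' returned in PK2 form \code{S_f = lambda_f^-2 sigma_ff f0 o f0} with
#' \code{f0} the unit reference fiber direction.  No clamp is applied by
#' default; a negative value (possible under extreme shortening velocity)
#' triggers a warning unless \code{params$clamp_active} is set, in which
#' case the stress is floored at zero.
#'
#' @param A activation value in \code{[0, 1]}.
#' @param G length-tension value in \code{(0, 1]}.
#' @param deps_f_dt fiber strain rate (1/s).
#' @param eps_f_ed end-diastolic fiber strain.
#' @param lambda_f fiber stretch ratio.
#' @param e_f unit reference fiber direction (length-3 vector).
#' @param params an [lv_material()] list.
#' @return A list with \code{sigma_ff} (kPa) and the 3x3 matrix \code{S_f}.
#' @export
active_stress <- function(A, G, deps_f_dt = 0, eps_f_ed = 0, lambda_f = 1,
                          e_f = c(0, 0, 1), params = lv_material()) {
  sig <- A * G * (params$F0 + params$k_av * deps_f_dt) *
    (1 + params$k * eps_f_ed)
  if (sig < 0) {
    if (params$clamp_active) sig <- 0
    else warning("negative active fiber stress (rapid shortening); not clamped")
  }
  list(sigma_ff = sig,
       S_f = (sig / lambda_f^2) * (e_f %o% e_f))
}

#' Passive elastic stress (fiber frame)
#'
#' Transversely isotropic Fung-type elasticity: strain energy
#' \deqn{\Psi = \tfrac{1}{2} c_1 (e^W - 1),\quad
#'  W = b_{ff}E_{ff}^2 + b_{xx}(E_{nn}^2+E_{ss}^2+2E_{sn}^2)
#'    + b_{fx}(2E_{fn}^2+2E_{fs}^2),}
#' with \code{E} in fiber coordinates \code{(s, n, f)}.  The PK2 stress is
#' the strain-energy gradient \code{S_e = dPsi/dE = c1 e^W [b-weighted E]}.
#'
#' @param E_fiber_frame symmetric 3x3 Green-Lagrange strain in \code{(s, n, f)}
#'   components.
#' @param params an [lv_material()] list.
#' @return A list with the 3x3 \code{S_e} (fiber frame, kPa), \code{W} and
#'   \code{Psi}.
#' @export
passive_elastic_stress <- function(E_fiber_frame, params = lv_material()) {
  E <- E_fiber_frame
  stopifnot(is.matrix(E), all(dim(E) == 3), max(abs(E - t(E))) < 1e-10)
  W <- params$b_ff * E[3, 3]^2 +
    params$b_xx * (E[1, 1]^2 + E[2, 2]^2 + 2 * E[1, 2]^2) +
    params$b_fx * (2 * E[1, 3]^2 + 2 * E[2, 3]^2)
  if (W > 250) stop("strain energy exponent overflow: strain far outside physiological range")
  cw <- params$c1 * exp(W)
  S <- cw * matrix(c(
    params$b_xx * E[1, 1], params$b_xx * E[1, 2], params$b_fx * E[1, 3],
    params$b_xx * E[1, 2], params$b_xx * E[2, 2], params$b_fx * E[2, 3],
    params$b_fx * E[1, 3], params$b_fx * E[2, 3], params$b_ff * E[3, 3]), 3, 3)
  list(S_e = S, W = W, Psi = params$c1 * (exp(W) - 1) / 2)
}

#' Viscous (Kelvin-Voigt) stress
#'
#' PK2 form of the matrix viscosity, the pull-back of the fluid-like Cauchy
#' stress \code{k_vm (grad v + grad v^T)}:
#' \deqn{S_v = k_{vm}\, C^{-1} \dot{C}\, C^{-1}.}
#'
#' @param C right Cauchy-Green tensor (3x3, symmetric positive definite).
#' @param Cdot material time derivative of \code{C} (3x3 symmetric).
#' @param k_vm viscosity coefficient (kPa s).
#' @return The 3x3 PK2 viscous stress (kPa).
#' @export
viscous_stress <- function(C, Cdot, k_vm = 0.025) {
  Ci <- tryCatch(solve(C), error = function(e) stop("singular C in viscous stress"))
  k_vm * Ci %*% Cdot %*% Ci
}

#' Total second Piola-Kirchhoff stress at a material point
#'
#' Assembles \code{S = S_f + S_e + S_v} in prolate-spheroidal components
#' (the incompressibility reaction term \code{-p_M C^-1} does no work under
#' the volume-preserving deformation family and is omitted), together with
#' the deviatoric Cauchy stress \code{dev(F S F')} and the active fiber
#' stress.  Fiber-frame quantities are rotated with the local basis
#' [fiber_basis()].
#'
#' @inheritParams fiber_stretch
#' @param rates time derivatives \code{c(da1, da2, da3)/dt}.
#' @param t_cycle time within the cycle (s).
#' @param eps_f_ed end-diastolic fiber strain at this point.
#' @param params an [lv_material()] list.
#' @param mu0,nu0 scalar reference coordinates.
#' @return A list with matrices \code{S}, \code{S_f}, \code{S_e}, \code{S_v}
#'   (prolate components, kPa), \code{sigma_dev} (deviatoric Cauchy),
#'   \code{sigma_ff_active} and \code{sigma_ff_dev} (kPa).
#' @export
total_pk2 <- function(geometry, state, rates = c(0, 0, 0), t_cycle = 0.5,
                      eps_f_ed = 0, params = lv_material(), mu0, nu0) {
  fib <- lv_fibers(geometry, params$psi_in_deg, params$psi_out_deg, params$L_s0)
  d <- deformation_tensors(geometry, state, mu0, nu0)
  Q <- fiber_basis(mu0, nu0, fib)
  f0 <- Q[, 3]
  lam2 <- drop(f0 %*% d$C %*% f0)
  eps_f <- (lam2 - 1) / 2
  Edot <- d$dE_da[[1]] * rates[1] + d$dE_da[[2]] * rates[2] +
    d$dE_da[[3]] * rates[3]
  deps <- drop(f0 %*% Edot %*% f0)
  A <- activation(t_cycle, eps_f_ed, params)
  G <- length_tension(sqrt(lam2) * params$L_s0, params)
  act <- active_stress(A, G, deps, eps_f_ed, sqrt(lam2), f0, params)
  Sf <- act$S_f
  Se_fib <- passive_elastic_stress(t(Q) %*% d$E %*% Q, params)$S_e
  Se <- Q %*% Se_fib %*% t(Q)
  Sv <- viscous_stress(d$C, 2 * Edot, params$k_vm)
  S <- Sf + Se + Sv
  sig <- d$F %*% S %*% t(d$F)
  sig_dev <- sig - diag(3) * sum(diag(sig)) / 3
  ef <- d$F %*% f0
  ef <- ef / sqrt(sum(ef^2))
  list(S = S, S_f = Sf, S_e = Se, S_v = Sv,
       sigma_dev = sig_dev,
       sigma_ff_active = act$sigma_ff,
       sigma_ff_dev = drop(t(ef) %*% sig_dev %*% ef))
}
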