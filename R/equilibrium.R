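#' Quadrature grid over the reference wall
#'
#' Regular Simpson-compatible mesh over the rectangle
#' \code{[mu_in0, mu_out0] x [nu_up, pi]} (default 9 x 11 nodes, both odd),
#' with cached reference metric, Simpson weights (including the analytic
#' \code{2*pi} azimuthal factor and reference Jacobian, so weights sum to
#' the material wall volume) and fiber-field quantities per node.
#'
#' @param geometry an [lv_geometry()] object.
#' @param fibers an [lv_fibers()] object (defaults to the standard field).
#' @param n_mu,n_nu node counts in the two directions (odd).
#' @param n_line Simpson node count of the endocardial boundary line
#'   integral (odd).
#' @return An object of class \code{"lv_grid"}.
#' @export
lv_grid <- function(geometry, fibers = lv_fibers(geometry),
                    n_mu = 9, n_nu = 11, n_line = 41) {
  mu <- seq(geometry$mu_in0, geometry$mu_out0, length.out = n_mu)
  nu <- seq(geometry$nu_up, pi, length.out = n_nu)
  gr <- expand.grid(mu0 = mu, nu0 = nu)
  w2 <- as.vector(outer(.simpson_weights(geometry$mu_in0, geometry$mu_out0, n_mu),
                        .simpson_weights(geometry$nu_up, pi, n_nu)))
  m0 <- prolate_metric(geometry$a0, gr$mu0, gr$nu0)
  om <- .omega_at(gr$mu0, fibers)
  cp <- .cos_psi_star(om, gr$mu0, gr$nu0)
  structure(list(
    geometry = geometry, fibers = fibers,
    n_mu = n_mu, n_nu = n_nu, n_line = n_line,
    mu0 = gr$mu0, nu0 = gr$nu0,
    wV = 2 * pi * w2 * m0$detJ,     # dV0 weights
    omega = om, cpsi = cp, spsi = sqrt(pmax(1 - cp^2, 0))
  ), class = "lv_grid")
}

## ---------------------------------------------------------------------------
## Generalized force balance.  The three weak-form equations are linear in
## the kinematic rates adot and in the cavity pressure p:
##     M(a, t) adot + g(a, t) = b(a) p
## with M from the rate-linear stresses (matrix viscosity + force-velocity
## part of the active stress), g from the rate-independent stresses
## (passive elastic + isometric active), and b from the boundary virtual
## work of the cavity pressure (endocardial lateral sweep + basal disk).
## ---------------------------------------------------------------------------

## Fiber-frame strain components from prolate components (13-sparse input):
## E_fib = Q^T E Q with Q = [[1,0,0],[0,-c,s],[0,-s,-c]] (columns s, n, f).
.to_fiber_frame <- function(E11, E12, E22, E23, E33, cp, sp) {
  list(ss = E11,
       sn = -cp * E12,
       sf = sp * E12,
       nn = cp^2 * E22 + 2 * cp * sp * E23 + sp^2 * E33,
       nf = -cp * sp * E22 + (cp^2 - sp^2) * E23 + cp * sp * E33,
       ff = sp^2 * E22 - 2 * cp * sp * E23 + cp^2 * E33)
}

## Prolate components of a symmetric fiber-frame tensor: A = Q T Q^T.
.to_prolate_frame <- function(T_, cp, sp) {
  list(m11 = T_$ss,
       m12 = -cp * T_$sn + sp * T_$sf,
       m13 = -sp * T_$sn - cp * T_$sf,
       m22 = cp^2 * T_$nn - 2 * cp * sp * T_$nf + sp^2 * T_$ff,
       m23 = cp * sp * T_$nn + (cp^2 - sp^2) * T_$nf - cp * sp * T_$ff,
       m33 = sp^2 * T_$nn + 2 * cp * sp * T_$nf + cp^2 * T_$ff)
}

## inverse of symmetric 3x3 with zero (1,3) component, vectorized
.inv_sym_13sparse <- function(c11, c12, c22, c23, c33) {
  det <- c11 * (c22 * c33 - c23^2) - c12^2 * c33
  if (any(!is.finite(det)) || any(abs(det) < 1e-300)) stop("singular C tensor")
  list(i11 = (c22 * c33 - c23^2) / det,
       i12 = -(c12 * c33) / det,
       i13 = (c12 * c23) / det,
       i22 = (c11 * c33) / det,
       i23 = -(c11 * c23) / det,
       i33 = (c11 * c22 - c12^2) / det)
}

## Y = Ci %*% D %*% Ci for symmetric Ci (full) and symmetric D with D13 = 0.
## Returns the five components of Y needed for contraction against a
## 13-sparse tensor.
.sandwich_ci <- function(ci, d11, d12, d22, d23, d33) {
  ## X = Ci D  (rows i of Ci dotted with columns of D)
  x11 <- ci$i11 * d11 + ci$i12 * d12
  x12 <- ci$i11 * d12 + ci$i12 * d22 + ci$i13 * d23
  x13 <- ci$i12 * d23 + ci$i13 * d33
  x21 <- ci$i12 * d11 + ci$i22 * d12
  x22 <- ci$i12 * d12 + ci$i22 * d22 + ci$i23 * d23
  x23 <- ci$i22 * d23 + ci$i23 * d33
  x31 <- ci$i13 * d11 + ci$i23 * d12
  x32 <- ci$i13 * d12 + ci$i23 * d22 + ci$i33 * d23
  x33 <- ci$i23 * d23 + ci$i33 * d33
  ## Y = X Ci
  list(m11 = x11 * ci$i11 + x12 * ci$i12 + x13 * ci$i13,
       m12 = x11 * ci$i12 + x12 * ci$i22 + x13 * ci$i23,
       m13 = x11 * ci$i13 + x12 * ci$i23 + x13 * ci$i33,
       m22 = x21 * ci$i12 + x22 * ci$i22 + x23 * ci$i23,
       m23 = x21 * ci$i13 + x22 * ci$i23 + x23 * ci$i33,
       m33 = x31 * ci$i13 + x32 * ci$i23 + x33 * ci$i33)
}

## double contraction of two symmetric tensors, both with zero 13 component
.ddot13 <- function(a11, a12, a22, a23, a33, b11, b12, b22, b23, b33) {
  a11 * b11 + a22 * b22 + a33 * b33 + 2 * (a12 * b12 + a23 * b23)
}

## Full assembly at kinematic state s, cycle time t_cycle, per-node
## end-diastolic strain eps_ed.  Returns the generalized system and the
## per-node caches needed for work accounting and field output.
.assemble <- function(grid, s, t_cycle, eps_ed, mat) {
  geom <- grid$geometry
  kp <- .kin_with_perturbations(geom, s, grid$mu0, grid$nu0)
  dE <- .strain_derivs(kp)
  k <- kp$base
  cp <- grid$cpsi; sp <- grid$spsi
  wV <- grid$wV

  ## fiber strain, stretch, activation, length-tension
  eps_f <- sp^2 * k$E22 - 2 * sp * cp * k$E23 + cp^2 * k$E33
  lam2 <- 1 + 2 * eps_f
  if (any(lam2 <= 0)) stop("nonpositive fiber stretch encountered")
  L_s <- sqrt(lam2) * mat$L_s0
  A <- activation(t_cycle %% mat$T_c, eps_ed, mat)
  G <- length_tension(L_s, mat)
  starling <- 1 + mat$k * eps_ed

  ## fiber-direction projections of dE/da_i
  phi_ <- lapply(dE, function(d)
    sp^2 * d$E22 - 2 * sp * cp * d$E23 + cp^2 * d$E33)

  ## active: isometric -> g, force-velocity -> M
  act_iso <- A * G * mat$F0 * starling / lam2
  act_fv <- A * G * mat$k_av * starling / lam2
  gf <- vapply(1:3, function(i) sum(wV * act_iso * phi_[[i]]), numeric(1))
  Mf <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3)
    Mf[i, j] <- Mf[j, i] <- sum(wV * act_fv * phi_[[i]] * phi_[[j]])

  ## passive elastic
  Ef <- .to_fiber_frame(k$E11, k$E12, k$E22, k$E23, k$E33, cp, sp)
  W <- mat$b_ff * Ef$ff^2 + mat$b_xx * (Ef$ss^2 + Ef$nn^2 + 2 * Ef$sn^2) +
    mat$b_fx * 2 * (Ef$sf^2 + Ef$nf^2)
  if (any(W > 250)) stop("strain energy exponent overflow at a quadrature node")
  cw <- mat$c1 * exp(W)
  Sfib <- list(ss = cw * mat$b_xx * Ef$ss, sn = cw * mat$b_xx * Ef$sn,
               sf = cw * mat$b_fx * Ef$sf, nn = cw * mat$b_xx * Ef$nn,
               nf = cw * mat$b_fx * Ef$nf, ff = cw * mat$b_ff * Ef$ff)
  Se <- .to_prolate_frame(Sfib, cp, sp)
  ge <- vapply(1:3, function(i) {
    d <- dE[[i]]
    sum(wV * .ddot13(d$E11, d$E12, d$E22, d$E23, d$E33,
                     Se$m11, Se$m12, Se$m22, Se$m23, Se$m33))
  }, numeric(1))

  ## viscous: M_v[i, j] = 2 k_vm  int dE_i : (C^-1 dE_j C^-1) dV0
  ci <- .inv_sym_13sparse(k$C11, k$C12, k$C22, k$C23, k$C33)
  Mv <- matrix(0, 3, 3)
  Bj <- lapply(1:3, function(j) {
    d <- dE[[j]]
    .sandwich_ci(ci, d$E11, d$E12, d$E22, d$E23, d$E33)
  })
  for (i in 1:3) for (j in 1:3) {
    d <- dE[[i]]; B <- Bj[[j]]
    Mv[i, j] <- 2 * mat$k_vm *
      sum(wV * .ddot13(d$E11, d$E12, d$E22, d$E23, d$E33,
                       B$m11, B$m12, B$m22, B$m23, B$m33))
  }
  Mv <- (Mv + t(Mv)) / 2

  ## external virtual work and cavity volume from the endocardial line
  ln <- .surface_line(geom, s, geom$mu_in0, grid$n_line, with_derivs = TRUE)
  b <- .volume_derivs_line(ln)
  V <- .solid_volume(ln)

  list(M = Mf + Mv, Mf = Mf, Mv = Mv, g = gf + ge, gf = gf, ge = ge,
       b = b, dVda = b, V = V,
       eps_f = eps_f, lam2 = lam2, A = A, G = G,
       kin = k, dE = dE, cw = cw, Ef = Ef, Se = Se, Sfib = Sfib, ci = ci,
       act_iso = act_iso, act_fv = act_fv, phi_ = phi_)
}

#' Internal virtual work operator
#'
#' Splits the internal virtual work integrand
#' \eqn{\int \partial E/\partial a_i : S \, dV_0} into its rate-independent
#' part (passive elastic + isometric active stresses), returned as the
#' generalized force \code{g}, and its rate-linear part (matrix viscosity +
#' force-velocity active stress), returned as the 3x3 coefficient matrix
#' \code{M} so that the internal term equals \code{M \%*\% adot + g}.
#'
#' @param grid an [lv_grid()] object.
#' @param state kinematic state.
#' @param t_cycle time within the cardiac cycle (s).
#' @param eps_f_ed end-diastolic fiber strain per quadrature node (scalar
#'   recycled, or a vector of length \code{n_mu * n_nu}).
#' @param params an [lv_material()] list.
#' @return A list with \code{M} (kPa cm^3 s), \code{g} (kPa cm^3) and the
#'   viscous/active splits \code{Mv}, \code{Mf}, \code{ge}, \code{gf}.
#' @export
internal_virtual_work <- function(grid, state, t_cycle = 0.5,
                                  eps_f_ed = 0, params = lv_material()) {
  s <- .state_vec(state)
  eps_ed <- rep_len(eps_f_ed, length(grid$mu0))
  a <- .assemble(grid, s, t_cycle, eps_ed, params)
  a[c("M", "g", "Mv", "Mf", "ge", "gf")]
}

#' External virtual work coefficients
#'
#' Virtual work done by the cavity pressure per unit pressure: the
#' endocardial lateral line integral of the pressure traction dotted with
#' the boundary displacement sensitivities, plus the basal term modelled as
#' the pressure acting on the flat basal disk of the cavity through the
#' axial motion of the basal endocardial edge.  The total coefficients
#' satisfy \code{b_i = dV/da_i}, so external power equals
#' \code{p * dV/dt}; torsion does no boundary work (\code{b_3 = 0}).
#'
#' @inheritParams internal_virtual_work
#' @param geometry an [lv_geometry()] object.
#' @param state kinematic state.
#' @param p cavity pressure (kPa).
#' @param n_line Simpson node count for the line integral (odd).
#' @return A list with \code{b} (cm^3, per-pressure coefficients) and the
#'   external virtual work \code{b * p} (kPa cm^3).
#' @export
external_virtual_work <- function(geometry, state, p = 1, n_line = 41) {
  s <- .state_vec(state)
  ln <- .surface_line(geometry, s, geometry$mu_in0, n_line, with_derivs = TRUE)
  b <- .volume_derivs_line(ln)
  list(b = b, work = b * p)
}

#' Assemble the generalized force balance
#'
#' Combines [internal_virtual_work()] and [external_virtual_work()] into
#' the three equilibrium equations \code{M \%*\% adot = b * p - g} at the
#' given state and cycle time.
#'
#' @inheritParams internal_virtual_work
#' @param p cavity pressure (kPa).
#' @return A list with \code{M}, \code{g}, \code{b}, \code{rhs = b*p - g}
#'   and the condition number of \code{M}.
#' @export
assemble_balance <- function(grid, state, t_cycle = 0.5, p = 0,
                             eps_f_ed = 0, params = lv_material()) {
  s <- .state_vec(state)
  eps_ed <- rep_len(eps_f_ed, length(grid$mu0))
  a <- .assemble(grid, s, t_cycle, eps_ed, params)
  kappa <- tryCatch(kappa(a$M, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa)) stop("singular generalized mass matrix M")
  list(M = a$M, g = a$g, b = a$b, rhs = a$b * p - a$g, condition = kappa,
       V = a$V, dVda = a$dVda)
}
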