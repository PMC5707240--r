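#' Solver settings
#'
#' Time-step policy and tolerances of the differential-algebraic
#' integrator.  \code{dt_base} is the baseline step; during valve
#' transitions (a sigmoid argument inside the band \code{5/beta} and
#' slewing faster than \code{slew_min}) the step is refined to
#' \code{dt_min}.  \code{newton_tol} is the accepted residual of the
#' per-stage algebraic solve (flow-balance constraint, cm^3/s).
#'
#' @param dt_base baseline time step (s).  The default sits inside the
#'   stability bound of the explicit two-stage scheme for the fast viscous
#'   relaxation modes of the wall (decay rates of a few 1000/s during
#'   systole).
#' @param dt_min refined step during valve transitions (s).
#' @param newton_tol residual tolerance of the per-stage solve.
#' @param n_cycles default number of cardiac cycles.
#' @param slew_min minimum sigmoid-argument slew rate (kPa/s) for
#'   triggering refinement.
#' @param step_tol relative embedded-error tolerance: a step whose
#'   stage-disagreement error estimate exceeds it is redone with half the
#'   step (not below \code{dt_min}).
#' @param n_mu,n_nu quadrature mesh (odd).
#' @param n_line boundary line-integral nodes (odd).
#' @return A named list of class \code{"lv_solver"}.
#' @export
lv_solver <- function(dt_base = 5e-4, dt_min = 5e-5, newton_tol = 1e-10,
                      n_cycles = 12, slew_min = 1.0, step_tol = 2e-3,
                      n_mu = 9, n_nu = 11, n_line = 41) {
  stopifnot(dt_min <= dt_base, n_cycles >= 1)
  structure(list(dt_base = dt_base, dt_min = dt_min, newton_tol = newton_tol,
                 n_cycles = n_cycles, slew_min = slew_min, step_tol = step_tol,
                 n_mu = n_mu, n_nu = n_nu, n_line = n_line),
            class = "lv_solver")
}

#' Left-ventricle dynamic model
#'
#' Constructs the coupled ventricle-circulation model: reference geometry,
#' fiber field, material and circulation parameters, and a cached
#' quadrature grid.  The returned object is simulated with [simulate()]
#' (or [run_cycles()]), statically inflated with [static_inflate()], and
#' inspected with \code{print}/\code{summary}.
#'
#' @param shape preset name (\code{"normal"}, \code{"spherical"},
#'   \code{"ellipsoidal"}) or an [lv_geometry()] object.
#' @param material an [lv_material()] parameter list.
#' @param circulation an [lv_circulation()] parameter list.
#' @param solver an [lv_solver()] settings list.
#' @return An object of class \code{"lv_model"}.
#' @examples
#' m <- lv_model("normal")
#' print(m)
#' @export
lv_model <- function(shape = "normal", material = lv_material(),
                     circulation = lv_circulation(), solver = lv_solver()) {
  geom <- if (inherits(shape, "lv_geometry")) shape else lv_geometry(shape)
  fib <- lv_fibers(geom, material$psi_in_deg, material$psi_out_deg,
                   material$L_s0)
  grid <- lv_grid(geom, fib, solver$n_mu, solver$n_nu, solver$n_line)
  structure(list(geometry = geom, fibers = fib, grid = grid,
                 material = material, circulation = circulation,
                 solver = solver),
            class = "lv_model")
}

#' @export
print.lv_model <- function(x, ...) {
  cat("Low-order dynamic LV model\n")
  print(x$geometry)
  cat(sprintf("  quadrature %d x %d, boundary line %d nodes\n",
              x$solver$n_mu, x$solver$n_nu, x$solver$n_line))
  cat(sprintf("  F0 = %g kPa, c1 = %g kPa, k_vm = %g kPa s, T_a/T_c = %g/%g s\n",
              x$material$F0, x$material$c1, x$material$k_vm,
              x$material$T_a, x$material$T_c))
  invisible(x)
}

## fiber strain field at the quadrature nodes for a given state (used for
## the end-diastolic snapshot)
.eps_field <- function(model, s) {
  g <- model$grid
  k <- .kin_points(model$geometry, s[1], s[2], s[3], g$mu0, g$nu0)
  g$spsi^2 * k$E22 - 2 * g$spsi * g$cpsi * k$E23 + g$cpsi^2 * k$E33
}

## Solve the algebraic stage problem: given differential state
## (s, P_A, P_AO) at time t, find cavity pressure p and rates.
.stage <- function(model, s, P_A, P_AO, t, eps_ed, p_guess) {
  mat <- model$material; cir <- model$circulation
  asm <- .assemble(model$grid, s, t %% mat$T_c, eps_ed, mat)
  Mi <- solve(asm$M, cbind(asm$b, asm$g))
  Mi_b <- Mi[, 1]
  Mi_g <- Mi[, 2]
  alpha <- sum(asm$dVda * Mi_b)
  gamma <- -sum(asm$dVda * Mi_g)
  res <- function(p) {
    R_AOV <- .solve_aortic_valve(p, P_AO, cir)
    P_aov <- proximal_aortic_pressure(p, P_AO, R_AOV, cir)
    R_MV <- .sigmoid_resistance(P_A - p, cir$R_cc, cir$R_op_mv, cir$beta)
    alpha * p + gamma - (P_A - p) / R_MV + (p - P_aov) / R_AOV
  }
  ## warm-started secant/Newton on the monotone scalar residual; fall back
  ## to bracketed bisection via uniroot if it wanders
  p <- p_guess
  r0 <- res(p)
  ok <- abs(r0) < model$solver$newton_tol
  if (!ok) {
    p1 <- p + ifelse(r0 > 0, -1e-6, 1e-6)
    r1 <- res(p1)
    for (it in 1:30) {
      if (abs(r1 - r0) < 1e-300) break
      p2 <- p1 - r1 * (p1 - p) / (r1 - r0)
      if (!is.finite(p2) || abs(p2 - p1) > 20) break
      p <- p1; r0 <- r1
      p1 <- p2; r1 <- res(p2)
      if (abs(r1) < model$solver$newton_tol) { ok <- TRUE; break }
    }
    p <- p1
  }
  if (!ok && abs(res(p)) >= model$solver$newton_tol) {
    lo <- p_guess - 1; hi <- p_guess + 1
    k <- 0
    while (res(lo) > 0 && k < 40) { k <- k + 1; lo <- lo - 2^k * 0.5 }
    k <- 0
    while (res(hi) < 0 && k < 40) { k <- k + 1; hi <- hi + 2^k * 0.5 }
    p <- stats::uniroot(res, c(lo, hi), tol = 1e-13)$root
    for (it in 1:6) {
      r0 <- res(p)
      if (abs(r0) < model$solver$newton_tol) break
      dr <- (res(p + 1e-9) - r0) / 1e-9
      p <- p - r0 / dr
    }
  }
  cr <- circuit_rates(P_A, P_AO, p, dV_dt = alpha * p + gamma, params = cir)
  adot <- Mi_b * p - Mi_g
  qV <- sum(asm$dVda * adot)
  list(adot = adot, dP_A = cr$dP_A, dP_AO = cr$dP_AO, p = p,
       P_aov = cr$P_aov, R_MV = cr$R_MV, R_AOV = cr$R_AOV,
       q_mv = cr$q_mv, q_ao = cr$q_ao, qV = qV, V = asm$V,
       residual = cr$residual,
       ## instantaneous powers, kPa cm^3/s (work done ON the tissue /
       ## blood); cycle works flip the sign so tissue output is positive
       P_fiber = sum((asm$gf + asm$Mf %*% adot) * adot),
       P_fiber_fv = sum((asm$Mf %*% adot) * adot),
       P_visc = sum((asm$Mv %*% adot) * adot),
       P_elast = sum(asm$ge * adot),
       P_stroke = p * qV,
       P_ext = p * sum(asm$b * adot),
       eps_f = asm$eps_f, asm = asm)
}

#' Run full cardiac cycles
#'
#' Integrates the coupled differential-algebraic system over \code{cycles}
#' cardiac cycles with the two-stage second-order Runge-Kutta (Heun)
#' scheme; at each stage the cavity pressure and kinematic rates are
#' resolved from the three equilibrium equations plus the flow-balance
#' constraint by a Newton-type scalar solve.  The end-diastolic fiber
#' strain field is snapshotted at the start of each cycle (activation
#' onset).  Steps land exactly on activation and cycle boundaries.
#'
#' @param model an [lv_model()] object.
#' @param cycles number of cardiac cycles (default from the solver
#'   settings).
#' @param keep_fields if \code{TRUE}, store stress/strain field snapshots
#'   at end diastole, peak activation and end systole of the final cycle.
#' @param stop_at optional absolute time (s) at which to halt integration
#'   mid-cycle (used for step-size convergence studies); the work ledger of
#'   the unfinished cycle is left \code{NA}.
#' @return An object of class \code{"lv_sim"}: list with \code{time} (one
#'   row per accepted step: t, a1..a3, p, P_A, P_AO, P_aov, R_MV, R_AOV,
#'   V, dV/dt, valve flows, mid-wall strain components), \code{work} (one
#'   row per cycle, J), \code{fields} (optional), and the model.
#' @export
run_cycles <- function(model, cycles = model$solver$n_cycles,
                       keep_fields = FALSE, stop_at = NULL) {
  mat <- model$material; cir <- model$circulation; sv <- model$solver
  T_c <- mat$T_c; T_a <- mat$T_a
  band <- 5 / cir$beta
  s <- c(0, 0, 0); P_A <- cir$P_A0; P_AO <- cir$P_AO0
  eps_ed <- rep(0, length(model$grid$mu0))
  t <- 0; p_guess <- P_A
  mu_mid <- (model$geometry$mu_in0 + model$geometry$mu_out0) / 2
  nu_mid <- 3 * pi / 4

  nmax <- ceiling(cycles * (T_c / sv$dt_base) * 1.2 +
                    cycles * 4 * (0.02 / sv$dt_min)) + 10
  rec <- matrix(NA_real_, nmax, 18)
  colnames(rec) <- c("t", "a1", "a2", "a3", "p", "P_A", "P_AO", "P_aov",
                     "R_MV", "R_AOV", "V", "dVdt", "q_mv", "q_ao",
                     "E_phiphi", "E_nunu", "E_nuphi", "A_mean")
  work <- matrix(NA_real_, cycles, 10)
  colnames(work) <- c("cycle", "fiber", "viscous", "elastic", "internal",
                      "external", "stroke", "fiber_fv", "V_start", "V_end")
  irow <- 0L
  cyc <- 0L
  acc <- NULL
  prev <- NULL      # previous accepted stage-1 solution (for trapezoids)
  prev_args <- NULL # previous sigmoid arguments, for the slew estimate
  prev_dt <- sv$dt_base
  dt_ctrl <- sv$dt_base  # step-size memory across the error controller
  last_redone <- FALSE
  fields <- if (keep_fields) list() else NULL

  midwall_strain <- function(s) {
    k <- .kin_points(model$geometry, s[1], s[2], s[3], mu_mid, nu_mid,
                     minimal = TRUE)
    c(k$E33, k$E22, k$E23)
  }

  close_ledger <- function(acc, V_end) {
    c(-acc$fiber, -acc$visc, -acc$elast,
      -(acc$fiber + acc$visc + acc$elast), -acc$ext, -acc$stroke,
      -acc$fv) * 1e-3
  }

  repeat {
    st1 <- .stage(model, s, P_A, P_AO, t, eps_ed, p_guess)
    ## record
    irow <- irow + 1L
    if (irow > nrow(rec)) rec <- rbind(rec, matrix(NA_real_, nmax, ncol(rec)))
    ms <- midwall_strain(s)
    tc_rec <- t %% T_c
    rec[irow, ] <- c(t, s, st1$p, P_A, P_AO, st1$P_aov, st1$R_MV, st1$R_AOV,
                     st1$V, st1$qV, st1$q_mv, st1$q_ao, ms,
                     mean(activation(tc_rec, eps_ed, mat)))
    ## trapezoid accumulation within the current cycle
    if (cyc > 0L && !is.null(prev)) {
      h2 <- (t - prev$t) / 2
      acc$fiber <- acc$fiber + h2 * (prev$P_fiber + st1$P_fiber)
      acc$fv <- acc$fv + h2 * (prev$P_fiber_fv + st1$P_fiber_fv)
      acc$visc <- acc$visc + h2 * (prev$P_visc + st1$P_visc)
      acc$elast <- acc$elast + h2 * (prev$P_elast + st1$P_elast)
      acc$stroke <- acc$stroke + h2 * (prev$P_stroke + st1$P_stroke)
      acc$ext <- acc$ext + h2 * (prev$P_ext + st1$P_ext)
    }
    at_boundary <- abs(t - cyc * T_c) < 1e-9
    if (at_boundary) {
      if (cyc > 0L) {
        work[cyc, ] <- c(cyc, close_ledger(acc), acc$V0, st1$V)
      }
      if (cyc >= cycles) {
        if (keep_fields && is.null(fields$end_cycle))
          fields$end_cycle <- lv_fields(model, s, st1$adot, 0, eps_ed)
        break
      }
      cyc <- cyc + 1L
      eps_ed <- .eps_field(model, s)
      acc <- list(fiber = 0, visc = 0, elast = 0, stroke = 0, ext = 0,
                  fv = 0, V0 = st1$V)
      if (keep_fields && cyc == cycles)
        fields$end_diastole <- lv_fields(model, s, st1$adot, 0, eps_ed)
    }
    if (!is.null(stop_at) && t >= stop_at - 1e-12) break
    if (keep_fields && cyc == cycles && !at_boundary) {
      tc <- t - (cyc - 1L) * T_c
      for (ph in list(list("peak_activation", T_a / 2),
                      list("end_systole", T_a))) {
        if (abs(tc - ph[[2]]) < 1e-9 && is.null(fields[[ph[[1]]]]))
          fields[[ph[[1]]]] <- lv_fields(model, s, st1$adot, tc, eps_ed)
      }
    }
    prev <- c(st1, list(t = t))
    ## time-step selection: refine inside a fast-moving valve-sigmoid band
    args <- c(P_A - st1$p, st1$p - st1$P_aov)
    slew <- if (is.null(prev_args)) c(0, 0) else abs(args - prev_args) / prev_dt
    refine <- any(abs(args) < band & slew > sv$slew_min)
    dt <- min(if (refine) sv$dt_min else sv$dt_base,
              if (last_redone) dt_ctrl else 2 * dt_ctrl)
    t_cycle <- t - (cyc - 1L) * T_c
    for (ev in c(T_a / 2, T_a, T_c)) {
      gap <- ev - t_cycle
      if (gap > 1e-9 && gap < dt + 1e-9) dt <- gap
    }
    prev_args <- args
    ## Heun step with embedded-error control: the stage disagreement
    ## dt/2 |f2 - f1| estimates the local error; redo with dt/2 if large
    escale <- c(1, 1, 1, 5, 5)   # cm, cm, rad, kPa, kPa
    n_redo <- 0L
    repeat {
      y1_s <- s + dt * st1$adot
      y1_PA <- P_A + dt * st1$dP_A
      y1_PAO <- P_AO + dt * st1$dP_AO
      st2 <- tryCatch(
        .stage(model, y1_s, y1_PA, y1_PAO, t + dt, eps_ed, st1$p),
        error = function(e) if (dt > sv$dt_min * 1.0001) NULL else stop(e))
      if (!is.null(st2)) {
        df <- c(st2$adot - st1$adot, st2$dP_A - st1$dP_A,
                st2$dP_AO - st1$dP_AO)
        err <- dt / 2 * max(abs(df) / escale)
        if (err <= sv$step_tol || dt <= sv$dt_min * 1.0001) break
      }
      dt <- max(dt / 2, sv$dt_min)
      n_redo <- n_redo + 1L
    }
    prev_dt <- dt
    last_redone <- n_redo > 0L
    dt_ctrl <- dt
    s <- s + dt / 2 * (st1$adot + st2$adot)
    P_A <- P_A + dt / 2 * (st1$dP_A + st2$dP_A)
    P_AO <- P_AO + dt / 2 * (st1$dP_AO + st2$dP_AO)
    t <- t + dt
    p_guess <- st2$p
  }

  time <- as.data.frame(rec[seq_len(irow), , drop = FALSE])
  work <- as.data.frame(work)
  work$closure <- abs(work$internal - work$stroke) / work$stroke
  structure(list(time = time, work = work, fields = fields,
                 final_state = list(s = s, P_A = P_A, P_AO = P_AO,
                                    eps_ed = eps_ed),
                 model = model),
            class = "lv_sim")
}

#' Simulate cardiac cycles of an LV model
#'
#' S3 [stats::simulate()] method; \code{nsim} is the number of cardiac
#' cycles.  The model is deterministic, so \code{seed} only feeds the
#' standard simulate contract and does not alter the output.
#'
#' @param object an [lv_model()].
#' @param nsim number of cardiac cycles.
#' @param seed ignored (deterministic model); kept for the generic.
#' @param ... passed to [run_cycles()].
#' @return An \code{lv_sim} object.
#' @export
simulate.lv_model <- function(object, nsim = object$solver$n_cycles,
                              seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  run_cycles(object, cycles = nsim, ...)
}

#' Per-cycle work ledger
#'
#' Per-cycle integrals of the internal virtual work split into fiber,
#' viscous and net elastic contributions, the external boundary work and
#' the stroke work (PV-loop area), all in J (1 kPa cm^3 = 1 mJ).  Signs:
#' fiber work done by the contracting fibers is positive, viscous
#' dissipation is negative, and over a closed periodic cycle the net
#' elastic term vanishes so internal = fiber + viscous.
#'
#' @param sim an \code{lv_sim} object from [run_cycles()].
#' @param cycles which cycles to keep (default all).
#' @return A data.frame, one row per cycle.
#' @export
work_accounting <- function(sim, cycles = NULL) {
  w <- sim$work
  if (!is.null(cycles)) w <- w[w$cycle %in% cycles, , drop = FALSE]
  w
}

#' Stress and strain fields on the quadrature grid
#'
#' Evaluates the total PK2 stress (active + passive elastic + viscous; the
#' workless incompressibility reaction omitted), pushes it forward to the
#' deviatoric Cauchy stress, and reports fiber quantities, at every
#' quadrature node for a given state and rates.
#'
#' @param model an [lv_model()].
#' @param state kinematic state \code{c(a1, a2, a3)}.
#' @param rates kinematic rates (default zero: static fields).
#' @param t_cycle time within the cycle (s), sets the activation.
#' @param eps_f_ed end-diastolic fiber strain (scalar or per-node vector).
#' @return A data.frame with one row per node: deviatoric Cauchy
#'   components \code{sigma_mumu}, \code{sigma_nunu}, \code{sigma_phiphi},
#'   \code{sigma_phinu}, \code{sigma_ff}, strains \code{E_phiphi},
#'   \code{E_nunu}, \code{E_nuphi}, \code{lambda_f}, \code{L_s} and the
#'   active fiber Cauchy stress.
#' @export
lv_fields <- function(model, state, rates = c(0, 0, 0), t_cycle = 0,
                      eps_f_ed = 0) {
  s <- .state_vec(state)
  grid <- model$grid; mat <- model$material
  eps_ed <- rep_len(eps_f_ed, length(grid$mu0))
  a <- .assemble(grid, s, t_cycle, eps_ed, mat)
  k <- a$kin; cp <- grid$cpsi; sp <- grid$spsi
  dE <- a$dE
  ## strain rate and viscous stress (full components incl. 13)
  Ed <- lapply(c("E11", "E12", "E22", "E23", "E33"), function(cc)
    dE[[1]][[cc]] * rates[1] + dE[[2]][[cc]] * rates[2] + dE[[3]][[cc]] * rates[3])
  names(Ed) <- c("e11", "e12", "e22", "e23", "e33")
  Sv <- .sandwich_ci(a$ci, 2 * mat$k_vm * Ed$e11, 2 * mat$k_vm * Ed$e12,
                     2 * mat$k_vm * Ed$e22, 2 * mat$k_vm * Ed$e23,
                     2 * mat$k_vm * Ed$e33)
  ## active stress with force-velocity term
  deps <- sp^2 * Ed$e22 - 2 * sp * cp * Ed$e23 + cp^2 * Ed$e33
  sig_act <- a$A * a$G * (mat$F0 + mat$k_av * deps) * (1 + mat$k * eps_ed)
  sfac <- sig_act / a$lam2
  ## S_f = lam^-2 sig f0 (x) f0, f0 = (0, sp, -cp)
  S11 <- a$Se$m11 + Sv$m11
  S12 <- a$Se$m12 + Sv$m12
  S13 <- a$Se$m13 + Sv$m13
  S22 <- a$Se$m22 + Sv$m22 + sfac * sp^2
  S23 <- a$Se$m23 + Sv$m23 - sfac * sp * cp
  S33 <- a$Se$m33 + Sv$m33 + sfac * cp^2
  F11 <- k$F11; F12 <- k$F12; F22 <- k$F22; F32 <- k$F32; F33 <- k$F33
  s11 <- F11^2 * S11 + 2 * F11 * F12 * S12 + F12^2 * S22
  s12 <- F22 * (F11 * S12 + F12 * S22)
  s13 <- F11 * (F32 * S12 + F33 * S13) + F12 * (F32 * S22 + F33 * S23)
  s22 <- F22^2 * S22
  s23 <- F22 * (F32 * S22 + F33 * S23)
  s33 <- F32^2 * S22 + 2 * F32 * F33 * S23 + F33^2 * S33
  tr3 <- (s11 + s22 + s33) / 3
  s11 <- s11 - tr3; s22 <- s22 - tr3; s33 <- s33 - tr3
  ## deformed fiber direction e_f = F f0 / |F f0|
  f1 <- F12 * sp; f2 <- F22 * sp; f3 <- F32 * sp - F33 * cp
  nf <- sqrt(f1^2 + f2^2 + f3^2)
  f1 <- f1 / nf; f2 <- f2 / nf; f3 <- f3 / nf
  sig_ff <- f1^2 * s11 + f2^2 * s22 + f3^2 * s33 +
    2 * (f1 * f2 * s12 + f1 * f3 * s13 + f2 * f3 * s23)
  data.frame(mu0 = grid$mu0, nu0 = grid$nu0,
             sigma_mumu = s11, sigma_nunu = s22, sigma_phiphi = s33,
             sigma_phinu = s23, sigma_ff = sig_ff,
             E_phiphi = k$E33, E_nunu = k$E22, E_nuphi = k$E23,
             lambda_f = sqrt(a$lam2), L_s = sqrt(a$lam2) * mat$L_s0,
             sigma_ff_active = sig_act)
}

#' Static passive inflation
#'
#' Solves the three equilibrium equations with zero activation and zero
#' rates for a fixed cavity pressure: \code{g(a) = b(a) p}.  Newton
#' iteration with a finite-difference Jacobian and step halving; falls
#' back to damped pseudo-time relaxation (integrating the viscous dynamics
#' to rest) if Newton stalls.
#'
#' @param model an [lv_model()].
#' @param pressure cavity pressure (kPa).
#' @param tol residual tolerance (kPa cm^3).
#' @param maxit Newton iteration cap.
#' @return An object of class \code{"lv_static"} with the equilibrium
#'   state, residual norm, cavity volume and stress fields.
#' @export
static_inflate <- function(model, pressure, tol = 1e-8, maxit = 60) {
  grid <- model$grid; mat <- model$material
  eps0 <- rep(0, length(grid$mu0))
  tq <- mat$T_a + (mat$T_c - mat$T_a) / 2   # quiescent phase: A = 0
  resid <- function(s) {
    a <- .assemble(grid, s, tq, eps0, mat)
    a$g - a$b * pressure
  }
  s <- c(0, 0, 0)
  r <- resid(s)
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    nr <- sqrt(sum(r^2))
    hist <- c(hist, nr)
    if (nr < tol) break
    J <- matrix(0, 3, 3)
    h <- 1e-6 * pmax(1, abs(s))
    for (j in 1:3) {
      sp <- s; sm <- s
      sp[j] <- sp[j] + h[j]; sm[j] <- sm[j] - h[j]
      J[, j] <- (resid(sp) - resid(sm)) / (2 * h[j])
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in static inflation")
    lam <- 1
    repeat {
      s_new <- s + lam * step
      r_new <- tryCatch(resid(s_new), error = function(e) NULL)
      if (!is.null(r_new) && sqrt(sum(r_new^2)) < nr) break
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) {
      ## pseudo-time relaxation fallback through the viscous dynamics
      for (k in 1:4000) {
        a <- .assemble(grid, s, tq, eps0, mat)
        adot <- solve(a$M, a$b * pressure - a$g)
        s <- s + 0.002 * adot
        if (sqrt(sum(adot^2)) < 1e-10) break
      }
      r <- resid(s)
      next
    }
    s <- s_new; r <- r_new
  }
  if (sqrt(sum(r^2)) >= tol)
    warning(sprintf("static inflation: residual %.3g above tolerance %.3g; history: %s",
                    sqrt(sum(r^2)), tol, paste(signif(hist, 3), collapse = " ")))
  structure(list(state = lv_state(s[1], s[2], s[3]), pressure = pressure,
                 residual = sqrt(sum(r^2)), iterations = length(hist),
                 V = cavity_volume(model$geometry, s),
                 V_ref = cavity_volume(model$geometry),
                 fields = lv_fields(model, s, t_cycle = tq),
                 model = model),
            class = "lv_static")
}

#' @export
print.lv_static <- function(x, ...) {
  cat(sprintf("Static passive inflation at p = %g kPa\n", x$pressure))
  cat(sprintf("  a1 = %.6g cm, a2 = %.6g cm, a3 = %.6g rad  (residual %.2g)\n",
              x$state[1], x$state[2], x$state[3], x$residual))
  cat(sprintf("  cavity volume %.4f -> %.4f cm^3\n", x$V_ref, x$V))
  invisible(x)
}

#' @export
coef.lv_static <- function(object, ...) unclass(object$state)
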