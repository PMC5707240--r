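test_that("quiescent reference with equalized sources is a fixed point", {
  # no active force, all node pressures equal and sources nulled
  cir <- lv_circulation(P_PA = 0, P_SV = 0, P_A0 = 0, P_AO0 = 0)
  m <- lv_model("normal", circulation = cir,
                material = lv_material(F0 = 1e-12),
                solver = lv_solver(dt_base = 1e-3, n_cycles = 1))
  sim <- run_cycles(m, 1)
  tm <- sim$time
  expect_lt(max(abs(tm$a1)), 1e-8)
  expect_lt(max(abs(tm$a2)), 1e-8)
  expect_lt(max(abs(tm$p)), 1e-8)
  expect_lt(max(abs(tm$P_A)), 1e-8)
})

test_that("algebraic constraint residuals satisfy the solver contract", {
  sim <- full_run("normal")
  r <- residuals(sim)
  expect_lt(max(abs(r)), 1e-8)
})

test_that("time stepping shows second-order convergence", {
  # fixed-step integration over a smooth early-systole window; Richardson
  # ratio of successive halvings gives the observed order
  run_short <- function(dt) {
    m <- lv_model("normal",
                  solver = lv_solver(dt_base = dt, dt_min = dt,
                                     step_tol = Inf, slew_min = Inf))
    sim <- run_cycles(m, 1, stop_at = 0.2)
    tm <- sim$time
    i <- which.min(abs(tm$t - 0.2))
    unlist(tm[i, c("a1", "a2", "a3", "P_A", "P_AO")])
  }
  y1 <- run_short(2e-4)
  y2 <- run_short(1e-4)
  y3 <- run_short(5e-5)
  e1 <- sqrt(sum((y1 - y2)^2))
  e2 <- sqrt(sum((y2 - y3)^2))
  order <- log2(e1 / e2)
  expect_gt(order, 1.8)
})

test_that("simulation is deterministic", {
  m <- lv_model("normal", solver = lv_solver(n_cycles = 1))
  s1 <- run_cycles(m, 1)
  s2 <- run_cycles(m, 1)
  expect_identical(s1$time, s2$time)
  expect_identical(s1$work, s2$work)
})

test_that("simulate() follows the cycles argument and returns methods-ready output", {
  m <- lv_model("normal", solver = lv_solver(n_cycles = 1))
  sim <- simulate(m, nsim = 1)
  expect_s3_class(sim, "lv_sim")
  expect_equal(nrow(sim$work), 1)
  expect_output(print(sim), "cardiac cycle")
  expect_output(print(summary(sim)), "stroke work")
  s <- summary(sim)
  expect_true(s$work["stroke"] > 0)
})

test_that("physiological ordering holds in the periodic state", {
  sim <- full_run("normal")
  tm <- sim$time
  lc <- tm[tm$t >= 11 - 1e-9, ]
  # ejection pressure reaches the systolic aortic pressure
  expect_gt(max(lc$p), max(lc$P_AO) * 0.98)
  # during filling LV pressure sits below atrial pressure
  fill <- lc[lc$q_mv > 10, ]
  expect_true(all(fill$p < fill$P_A))
  # valves never simultaneously wide open
  expect_gt(min(lc$R_MV + lc$R_AOV), 1)
  # diastolic filling commences slightly before the end of activation
  # (ignore filling carried over the cycle boundary from late diastole)
  Ta <- sim$model$material$T_a
  tt <- lc$t %% 1
  t_fill <- min(tt[lc$q_mv > 5 & tt > Ta / 2])
  expect_lt(t_fill, Ta)
  expect_gt(t_fill, Ta / 2)
})

test_that("periodic steady state is reached with a closed PV loop", {
  sim <- full_run("normal")
  w <- sim$work
  # cycle-to-cycle stroke-work drift < 0.1% by cycle 12
  drift <- abs(w$stroke[12] - w$stroke[11]) / w$stroke[12]
  expect_lt(drift, 1e-3)
  # volume returns to its cycle-start value
  expect_lt(abs(w$V_end[12] - w$V_start[12]) / w$V_start[12], 1e-3)
  # end-systolic volume returns near the (end-systolic) reference volume
  lc <- sim$time[sim$time$t >= 11 - 1e-9, ]
  expect_lt(abs(min(lc$V) - 59.8714) / 59.8714, 0.15)
})

test_that("work ledger is self-consistent and energy-balanced", {
  sim <- full_run("normal")
  w <- converged_work(sim)
  # internal = fiber + viscous + elastic by construction; elastic net ~ 0
  expect_equal(w$internal, w$fiber + w$viscous + w$elastic, tolerance = 1e-10)
  expect_true(all(abs(w$elastic) < 0.002 * w$stroke))
  # dissipation is nonnegative
  expect_true(all(w$viscous <= 0))
  expect_true(all(w$fiber_fv <= 0))
  # internal vs stroke (exact basal closure of the boundary work)
  expect_true(all(w$closure < 1e-6))
  # positive pumping
  expect_true(all(w$stroke > 0))
})

test_that("static inflation of the dynamic model matches quasi-static diastole", {
  # at the converged end-diastolic point the wall is nearly in static
  # equilibrium with the cavity pressure (rates are small in diastasis)
  sim <- full_run("normal")
  tm <- sim$time
  i <- which.min(abs(tm$t - 11.95))   # late diastole, slow filling
  st <- static_inflate(sim$model, tm$p[i])
  expect_equal(st$V, tm$V[i], tolerance = 0.05)
})

test_that("stress fields show the expected systolic pattern", {
  sim <- cached_run("fields_run", function() {
    run_cycles(lv_model("normal"), 2, keep_fields = TRUE)
  })
  f <- sim$fields$peak_activation
  expect_false(is.null(f))
  # fiber stress is maximal near the midwall at the equatorial end of the
  # wall (where fibers are nearly circumferential), not at the surfaces
  eq_band <- f[f$nu0 < quantile(f$nu0, 0.3), ]
  by_mu <- tapply(eq_band$sigma_ff, eq_band$mu0, mean)
  expect_gt(which.max(by_mu), 1)
  expect_lt(which.max(by_mu), length(by_mu))
  # deviatoric trace vanishes
  expect_lt(max(abs(f$sigma_mumu + f$sigma_nunu + f$sigma_phiphi)), 1e-8)
  # sarcomeres shorten below slack at peak contraction somewhere
  expect_lt(min(f$L_s), 1.82)
})

test_that("sensitivity sweep at zero fraction reproduces the baseline", {
  sv <- lv_solver(dt_base = 1e-3, n_cycles = 1)
  base <- shapes_experiment(shapes = "normal", cycles = 1, solver = sv)
  sw <- sensitivity_sweep(fraction = 0, groups = "active",
                          shapes = "normal", cycles = 1, solver = sv)
  expect_equal(sw$stroke_mean, base$table$stroke, tolerance = 1e-12)
  expect_true(all(is.na(sw$error)))
})

test_that("raising contractility raises stroke work", {
  sv <- lv_solver(dt_base = 1e-3, n_cycles = 3)
  lo <- shapes_experiment(shapes = "normal", cycles = 3, solver = sv,
                          material = lv_material(F0 = 240))
  hi <- shapes_experiment(shapes = "normal", cycles = 3, solver = sv,
                          material = lv_material(F0 = 360))
  expect_gt(hi$table$stroke, lo$table$stroke)
})
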