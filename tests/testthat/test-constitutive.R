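test_that("activation has the prescribed shape and preload sensitivity", {
  p <- lv_material()
  expect_equal(activation(0, 0, p), 0)
  expect_equal(activation(p$T_a / 2, 0, p), 1)
  expect_equal(activation(p$T_a / 4, 0, p), sin(pi / 4))
  expect_equal(activation(0.7, 0, p), 0)   # quiescent after T_a
  # increased end-diastolic strain broadens the activation (d < 1)
  expect_gt(activation(p$T_a / 4, 0.3, p), activation(p$T_a / 4, 0, p))
  expect_error(activation(0.1, -1.5, p), "d <= 0")
})

test_that("length-tension is a unit-peak Gaussian in sarcomere length", {
  p <- lv_material()
  expect_equal(length_tension(2.23, p), 1)
  expect_equal(length_tension(2.03, p), exp(-0.5))
  expect_equal(length_tension(2.23 + 0.13, p), length_tension(2.23 - 0.13, p))
})

test_that("active stress is uniaxial with the default peak scale", {
  p <- lv_material()
  off <- active_stress(0, 1, 0, 0, 1, c(0, 0, 1), p)
  expect_equal(off$sigma_ff, 0)
  expect_equal(max(abs(off$S_f)), 0)
  iso <- active_stress(1, 1, 0, 0, 1, c(0, 0, 1), p)
  expect_equal(iso$sigma_ff, 300)
  expect_equal(iso$S_f[3, 3], 300)
  expect_equal(sum(abs(iso$S_f)) - abs(iso$S_f[3, 3]), 0)  # rank one
  # linear force-velocity reduction
  fv <- active_stress(1, 1, -100, 0, 1, c(0, 0, 1), p)
  expect_equal(iso$sigma_ff - fv$sigma_ff, 50)
  # PK2 scaling with stretch
  st <- active_stress(1, 1, 0, 0, 1.2, c(0, 0, 1), p)
  expect_equal(st$S_f[3, 3], 300 / 1.2^2)
  expect_warning(active_stress(1, 1, -1000, 0, 1, c(0, 0, 1), p), "negative")
})

test_that("passive stress is the gradient of the strain energy", {
  p <- lv_material()
  expect_equal(max(abs(passive_elastic_stress(matrix(0, 3, 3), p)$S_e)), 0)
  # single-component case evaluates in closed form
  E <- diag(c(0, 0, 0.1))
  se <- passive_elastic_stress(E, p)
  expect_equal(se$W, 5 * 0.01)
  expect_equal(se$S_e[3, 3], exp(0.05) * 5 * 0.1)
  # full-tensor case against a numerical gradient of Psi
  E <- matrix(c(0.05, 0.02, -0.01, 0.02, -0.03, 0.04, -0.01, 0.04, 0.08), 3, 3)
  psi <- function(E) {
    W <- p$b_ff * E[3, 3]^2 +
      p$b_xx * (E[1, 1]^2 + E[2, 2]^2 + 2 * E[1, 2]^2) +
      p$b_fx * 2 * (E[1, 3]^2 + E[2, 3]^2)
    p$c1 * (exp(W) - 1) / 2
  }
  S <- passive_elastic_stress(E, p)$S_e
  h <- 1e-6
  for (i in 1:3) for (j in 1:3) {
    Ep <- E; Em <- E
    # symmetric perturbation, consistent with dPsi = S : dE
    Ep[i, j] <- Ep[i, j] + h / 2; Ep[j, i] <- Ep[j, i] + h / 2
    Em[i, j] <- Em[i, j] - h / 2; Em[j, i] <- Em[j, i] - h / 2
    fd <- (psi(Ep) - psi(Em)) / (2 * h)
    expect_equal(S[i, j], fd, tolerance = 1e-5)
  }
  expect_error(passive_elastic_stress(diag(c(10, 10, 10)), p), "overflow")
})

test_that("viscous stress has the Kelvin-Voigt limits and push-forward", {
  expect_equal(max(abs(viscous_stress(diag(3) * 1.4, matrix(0, 3, 3)))), 0)
  Cd <- matrix(c(0.1, 0.02, 0, 0.02, -0.1, 0.05, 0, 0.05, 0.2), 3, 3)
  expect_equal(viscous_stress(diag(3), Cd, 0.025), 0.025 * Cd)
  # push-forward reproduces the fluid form k_vm (grad v + grad v^T):
  # simple shear x1 += gamma x2 at unit rate
  gam <- 0.3
  Fm <- matrix(c(1, 0, 0, gam, 1, 0, 0, 0, 1), 3, 3)
  L <- matrix(c(0, 0, 0, 1, 0, 0, 0, 0, 0), 3, 3)  # grad v, dgamma/dt = 1
  C <- t(Fm) %*% Fm
  Cdot <- t(Fm) %*% (t(L) + L) %*% Fm
  Sv <- viscous_stress(C, Cdot, 0.025)
  sigma <- Fm %*% Sv %*% t(Fm)
  expect_equal(sigma, 0.025 * (L + t(L)), tolerance = 1e-10)
  expect_error(viscous_stress(matrix(0, 3, 3), Cd), "singular")
})

test_that("total PK2 stress assembles consistently", {
  g <- normal_geometry()
  p <- lv_material()
  # reference state without activation is stress free
  st <- total_pk2(g, lv_state(), t_cycle = 0.7, params = p,
                  mu0 = 0.5, nu0 = 2)
  expect_equal(max(abs(st$S)), 0, tolerance = 1e-12)
  # deviatoric part is trace free
  st2 <- total_pk2(g, c(-0.3, 0.2, 0.1), rates = c(0.5, -0.4, 0.2),
                   t_cycle = 0.2, eps_f_ed = 0.1, params = p,
                   mu0 = 0.5, nu0 = 2)
  expect_equal(sum(diag(st2$sigma_dev)), 0, tolerance = 1e-10)
  # rotating a fiber-frame tensor to prolate and back is the identity
  f <- default_fibers(g)
  Q <- fiber_basis(0.5, 2, f)
  A <- matrix(c(2, 1, 0, 1, 3, 1, 0, 1, 4), 3, 3)
  expect_equal(t(Q) %*% (Q %*% A %*% t(Q)) %*% Q, A, tolerance = 1e-12)
  # S13-sparse active + symmetric components recombine: S is symmetric
  expect_equal(st2$S, t(st2$S), tolerance = 1e-12)
})

test_that("vectorized assembly stresses match the pointwise constitutive path", {
  # the weak-form assembly uses fused component formulas; cross-check the
  # elastic part against the matrix-algebra path at a quadrature node
  g <- normal_geometry()
  p <- lv_material()
  m <- lv_model("normal")
  s <- c(-0.3, 0.22, 0.08)
  fld <- lv_fields(m, s, rates = c(0.3, -0.2, 0.1), t_cycle = 0.2,
                   eps_f_ed = 0.05)
  i <- 40  # an interior node
  pt <- total_pk2(g, s, rates = c(0.3, -0.2, 0.1), t_cycle = 0.2,
                  eps_f_ed = 0.05, params = p,
                  mu0 = fld$mu0[i], nu0 = fld$nu0[i])
  expect_equal(fld$sigma_phinu[i], pt$sigma_dev[3, 2], tolerance = 1e-6)
  expect_equal(fld$sigma_mumu[i], pt$sigma_dev[1, 1], tolerance = 1e-6)
  expect_equal(fld$sigma_ff[i], pt$sigma_ff_dev, tolerance = 1e-6)
})
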