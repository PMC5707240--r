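test_that("prolate coordinates map to Cartesian with the right metric", {
  # apex of the unit spheroid family
  expect_equal(unlist(prolate_to_cartesian(1, 0, 0, 0)),
               c(x = 0, y = 0, z = 1))
  # equatorial plane has z = 0 for any mu
  expect_equal(prolate_to_cartesian(2, 0.7, pi / 2, 0)$z, 0)
  # Jacobian determinant at (a=1, mu=1, nu=pi/2)
  expect_equal(prolate_metric(1, 1, pi / 2)$detJ, sinh(1) * cosh(1)^2)
  # metric consistency with finite differences of the map
  h <- 1e-6
  num <- (prolate_to_cartesian(1.3, 0.5 + h, 1.1) -
            prolate_to_cartesian(1.3, 0.5 - h, 1.1)) / (2 * h)
  expect_equal(sqrt(sum(num^2)), prolate_metric(1.3, 0.5, 1.1)$g_mu,
               tolerance = 1e-8)
})

test_that("reference cavity and wall volumes reproduce the matched-shape values", {
  presets <- lv_shape_presets()
  for (nm in names(presets)) {
    g <- do.call(lv_geometry, presets[[nm]])
    expect_equal(cavity_volume(g), 59.8714, tolerance = 1e-5)
    expect_equal(wall_volume(g), 158.112, tolerance = 1e-5)
  }
})

test_that("cavity volume agrees with the truncated-spheroid closed form", {
  g <- normal_geometry()
  cu <- cos(g$nu_up)
  closed <- pi * g$a0^3 * sinh(g$mu_in0)^2 * cosh(g$mu_in0) *
    (2 / 3 + cu - cu^3 / 3)
  expect_equal(cavity_volume(g), closed, tolerance = 1e-10)
  # half-spheroid at nu_up = pi/2
  gh <- lv_geometry(3, 0.5, 0.8, nu_up = pi / 2)
  expect_equal(cavity_volume(gh),
               2 * pi / 3 * 27 * sinh(0.5)^2 * cosh(0.5), tolerance = 1e-8)
})

test_that("build_matched_shape inverts the volume targets", {
  sph <- build_matched_shape(59.8714, 158.112, a0 = 2.7307, nu_up = 1.1112)
  expect_equal(sph$mu_in0, 0.7470308, tolerance = 1e-5)
  expect_equal(sph$mu_out0, 1.1173771, tolerance = 1e-5)
  ell <- build_matched_shape(59.8714, 158.112, a0 = 6.7307, nu_up = 1.1112)
  expect_equal(ell$mu_in0, 0.235, tolerance = 1e-3)
  expect_equal(ell$mu_out0, 0.426, tolerance = 1e-3)
  # round trip at arbitrary targets
  g <- build_matched_shape(80, 120, a0 = 4, nu_up = 1.3)
  expect_equal(cavity_volume(g), 80, tolerance = 1e-7)
  expect_equal(wall_volume(g), 120, tolerance = 1e-7)
  expect_error(build_matched_shape(-5, 1, a0 = 1))
})

test_that("identity state maps every point to itself", {
  g <- normal_geometry()
  mu0 <- seq(g$mu_in0, g$mu_out0, length.out = 5)
  nu0 <- seq(g$nu_up, pi - 1e-9, length.out = 5)
  mp <- solve_mapped_mu(g, lv_state(), rep(mu0, each = 5), rep(nu0, 5))
  expect_equal(mp$mu, rep(mu0, each = 5), tolerance = 1e-12)
  d <- deformation_tensors(g, lv_state(), 0.5, 2)
  expect_equal(d$F, diag(3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(max(abs(d$E)), 0, tolerance = 1e-12)
})

test_that("mapped mu is strictly increasing in mu0 and volume-preserving", {
  g <- normal_geometry()
  s <- lv_state(-0.3, 0.2, 0)
  nu0 <- seq(g$nu_up, pi - 1e-6, length.out = 11)
  for (nu in nu0) {
    mu <- solve_mapped_mu(g, s, seq(g$mu_in0, g$mu_out0, length.out = 9), nu)$mu
    expect_true(all(diff(mu) > 0))
  }
  # material wall volume is invariant under the mapping
  v0 <- lvdyn:::.material_wall_volume(g, c(0, 0, 0))
  for (svec in list(c(-0.3, 0.2, 0.1), c(0.5, -0.6, -0.2), c(0, 0.4, 0))) {
    expect_equal(lvdyn:::.material_wall_volume(g, svec), v0,
                 tolerance = 1e-9)
  }
})

test_that("deformation gradient is volume preserving and matches a position oracle", {
  g <- normal_geometry()
  s <- c(-0.4, 0.3, -0.2)
  mu0 <- seq(g$mu_in0, g$mu_out0, length.out = 9)
  nu0 <- seq(g$nu_up, pi, length.out = 11)
  k <- lvdyn:::.kin_points(g, s[1], s[2], s[3],
                           rep(mu0, 11), rep(nu0, each = 9))
  expect_lt(max(abs(k$detF - 1)), 1e-8)

  # independent oracle: central differences of the mapped Cartesian
  # position, rotated into the deformed orthonormal prolate frame
  fdF <- function(mu0p, nu0p) {
    h <- 1e-6
    pos <- function(m0, n0) {
      mp <- solve_mapped_mu(g, s, m0, n0)
      phi <- torsion_phi(s, n0, 0, g$nu_up)
      unlist(prolate_to_cartesian(g$a0 + s[1], mp$mu, n0, phi))
    }
    J <- cbind((pos(mu0p + h, nu0p) - pos(mu0p - h, nu0p)) / (2 * h),
               (pos(mu0p, nu0p + h) - pos(mu0p, nu0p - h)) / (2 * h), 0)
    mp <- solve_mapped_mu(g, s, mu0p, nu0p)
    phi <- torsion_phi(s, nu0p, 0, g$nu_up)
    a <- g$a0 + s[1]
    J[, 3] <- a * sinh(mp$mu) * sin(nu0p) * c(-sin(phi), cos(phi), 0)
    mu <- mp$mu
    emu <- c(cosh(mu) * sin(nu0p) * cos(phi), cosh(mu) * sin(nu0p) * sin(phi),
             sinh(mu) * cos(nu0p))
    enu <- c(sinh(mu) * cos(nu0p) * cos(phi), sinh(mu) * cos(nu0p) * sin(phi),
             -cosh(mu) * sin(nu0p))
    eph <- c(-sin(phi), cos(phi), 0)
    g0 <- prolate_metric(g$a0, mu0p, nu0p)
    rbind(emu / sqrt(sum(emu^2)), enu / sqrt(sum(enu^2)), eph) %*%
      (J %*% diag(1 / c(g0$g_mu, g0$g_nu, g0$g_phi)))
  }
  for (pt in list(c(0.45, 1.5), c(0.6, 2.2), c(0.5, 2.9))) {
    d <- deformation_tensors(g, s, pt[1], pt[2])
    expect_equal(unclass(d$F), unclass(fdF(pt[1], pt[2])),
                 ignore_attr = TRUE, tolerance = 1e-5)
    expect_equal(d$detF, 1, tolerance = 1e-10)
    # C consistency and symmetry
    expect_equal(d$C, t(d$F) %*% d$F, ignore_attr = TRUE, tolerance = 1e-12)
    expect_true(all(eigen(d$C, symmetric = TRUE)$values > 0))
  }
})

test_that("strain sensitivities match a higher-order finite-difference oracle", {
  g <- normal_geometry()
  s <- c(-0.25, 0.18, 0.12)
  d <- deformation_tensors(g, s, 0.52, 2.1)
  for (i in 1:3) {
    h <- 2e-4
    Ef <- function(sv) deformation_tensors(g, sv, 0.52, 2.1)$E
    sp <- s; sm <- s; sp2 <- s; sm2 <- s
    sp[i] <- s[i] + h; sm[i] <- s[i] - h
    sp2[i] <- s[i] + 2 * h; sm2[i] <- s[i] - 2 * h
    # fourth-order central difference
    dE_fd <- (8 * (Ef(sp) - Ef(sm)) - (Ef(sp2) - Ef(sm2))) / (12 * h)
    expect_equal(unclass(d$dE_da[[i]]), unclass(dE_fd),
                 ignore_attr = TRUE, tolerance = 1e-6)
  }
})

test_that("torsion is zero at the base and volume-neutral", {
  g <- normal_geometry()
  expect_equal(torsion_phi(lv_state(0, 0, 0.3), g$nu_up, 1.2, g$nu_up), 1.2)
  expect_equal(torsion_phi(lv_state(0, 0, 0.1), pi, 0, 1.1112),
               0.1 * (-1 - cos(1.1112)))
  V1 <- cavity_volume(g, c(-0.2, 0.15, 0))
  V2 <- cavity_volume(g, c(-0.2, 0.15, 0.8))
  expect_equal(V1, V2, tolerance = 1e-12)
})

test_that("volume sensitivities agree with differencing the volume", {
  g <- normal_geometry()
  s <- c(-0.2, 0.12, 0.1)
  cv <- cavity_volume(g, s, derivatives = TRUE, n_line = 201)
  h <- 1e-5
  for (i in 1:2) {
    sp <- s; sm <- s
    sp[i] <- s[i] + h; sm[i] <- s[i] - h
    fd <- (cavity_volume(g, sp, n_line = 201) -
             cavity_volume(g, sm, n_line = 201)) / (2 * h)
    expect_equal(cv$dV_da[i], fd, tolerance = 1e-6)
  }
  expect_identical(cv$dV_da[3], 0)
})

test_that("arts ratio follows the uniform-stress law", {
  expect_equal(arts_ratio(158.112, 59.8714), log(1 + 158.112 / 59.8714) / 3)
  expect_equal(arts_ratio(1e-9, 50), 0, tolerance = 1e-9)
  r <- arts_ratio(seq(10, 300, by = 10), 60)
  expect_true(all(diff(r) > 0))
})
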