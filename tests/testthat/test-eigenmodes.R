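art <- whisker_preset("artificial")
real <- whisker_preset("real")

test_that("cylinder characteristic roots match the classical values", {
  cf <- cylinder_char_roots("clamped_free", 6)
  expect_equal(cf[1], 1.87510, tolerance = 1e-5)
  expect_equal(cf[2], 4.69409, tolerance = 1e-5)
  cp <- cylinder_char_roots("clamped_pinned", 6)
  expect_equal(cp[1], 3.92660, tolerance = 1e-5)
  # residuals of the characteristic equations
  expect_true(all(abs(1 + cos(cf) * cosh(cf)) / cosh(cf) < 1e-10))
  expect_true(all(abs(sin(cp) - cos(cp) * tanh(cp)) < 1e-10))
  # spacing approaches pi from either family
  expect_equal(diff(cf)[5], pi, tolerance = 1e-4)
  expect_equal(diff(cp)[5], pi, tolerance = 1e-4)
})

test_that("pinned modes: ordered eigenvalues, boundary residuals, orthonormality", {
  for (eps in c(0.2, 0.44, 0.6)) {
    ms <- solve_modes_pinned(art, eps, n_modes = 3)
    expect_true(all(diff(ms$lambda) > 0))
    expect_true(all(ms$lambda > 0))
    expect_equal(ms$omega, ms$lambda / timescale_k(art))
    n <- length(ms$s)
    for (i in 1:3) {
      v <- ms$V[, i]
      scale <- max(abs(v))
      expect_lt(abs(v[1]) / scale, 1e-6)                     # V(1) = 0
      expect_lt(abs((ms$D1 %*% v)[1]) / scale, 1e-6)         # V'(1) = 0
      expect_lt(abs(v[n]) / scale, 1e-6)                     # V(eps) = 0
      expect_lt(abs(ms$Vpp[n, i]) / scale, 1e-6)             # V''(eps) = 0
      expect_gt((ms$D1 %*% v)[n], 0)                         # sign convention
    }
    G <- crossprod(ms$V, (ms$weights * ms$s^2) * ms$V)
    expect_lt(max(abs(G - diag(3))), 1e-6)
  }
})

test_that("free-tip modes: five finite modes, natural-end residuals, orthonormality", {
  ms <- solve_modes_free(real, n_modes = 5)
  expect_length(ms$lambda, 5)
  expect_true(all(is.finite(ms$omega)))
  n <- length(ms$s)
  for (i in 1:5) {
    v <- ms$V[, i]
    scale <- max(abs(v))
    expect_lt(abs(v[1]) / scale, 1e-6)
    expect_lt(abs((ms$D1 %*% v)[1]) / scale, 1e-6)
    expect_lt(abs(ms$Vpp[n, i]) / scale, 1e-4)               # V''(s_tip) = 0
    expect_lt(abs(ms$d3V_end[i]) / scale, 1e-4)              # V'''(s_tip) = 0
  }
  G <- crossprod(ms$V, (ms$weights * ms$s^2) * ms$V)
  expect_lt(max(abs(G - diag(5))), 1e-6)
})

test_that("modes satisfy the conical beam ODE in the interior", {
  # residual of (s^4 V'')'' - lambda^2 s^2 V, differentiating the smooth
  # bending moment s^4 V'' once with the spectral operator
  for (ms in list(solve_modes_pinned(art, 0.3, 3), solve_modes_free(real, 5))) {
    interior <- 15:(length(ms$s) - 15)
    for (i in seq_along(ms$lambda)) {
      lhs <- ms$D2 %*% (ms$s^4 * ms$Vpp[, i])
      rhs <- ms$lambda[i]^2 * ms$s^2 * ms$V[, i]
      expect_lt(max(abs(lhs - rhs)[interior]) / max(abs(rhs)), 1e-4)
    }
  }
})

test_that("first pinned frequency stiffens as the contact approaches the base", {
  for (w in list(art, real)) {
    o3 <- solve_modes_pinned(w, 0.3, 1)$omega[1]
    o6 <- solve_modes_pinned(w, 0.6, 1)$omega[1]
    expect_gt(o6, o3)
  }
})

test_that("eigenfrequencies scale as 1/k: quadrupling E doubles every omega", {
  ms1 <- solve_modes_free(real, n_modes = 3)
  real4 <- whisker_spec(real$base_radius, real$conicity,
                        4 * real$young_modulus, real$density)
  ms4 <- solve_modes_free(real4, n_modes = 3)
  expect_equal(ms4$lambda, ms1$lambda, tolerance = 1e-10)  # geometry only
  expect_equal(ms4$omega, 2 * ms1$omega, tolerance = 1e-10)
})

test_that("removing the contact constraint lowers the first frequency", {
  pin <- solve_modes_pinned(real, 0.5, 1)
  free <- solve_modes_free(real, 1)
  expect_lt(free$omega[1], pin$omega[1])
})

test_that("cylinder-basis Galerkin agrees with direct collocation across boundary kinds", {
  for (eps in c(0.2, 0.3, 0.35)) {
    d <- solve_modes_pinned(art, eps, n_modes = 2)
    g <- cylinder_basis_modes(art, eps, "contact_pinned", n_modes = 2)
    expect_equal(g$omega[1], d$omega[1], tolerance = 0.01)
    expect_equal(g$omega[2], d$omega[2], tolerance = 0.01)
  }
  df <- solve_modes_free(real, n_modes = 2)
  gf <- cylinder_basis_modes(real, boundary_kind = "free_tip", n_modes = 2)
  expect_equal(gf$omega[1:2], df$omega[1:2], tolerance = 0.01)
  # base curvatures agree across methods up to the 1e-2 eigensolve tolerance
  d6 <- solve_modes_pinned(art, 0.3, n_modes = 2)
  g6 <- cylinder_basis_modes(art, 0.3, "contact_pinned", n_modes = 2)
  expect_equal(abs(g6$d2V_base), abs(d6$d2V_base), tolerance = 0.01)
})

test_that("Rayleigh-Ritz eigenvalues decrease monotonically with basis size", {
  lam <- sapply(c(8, 16, 24), function(nb)
    cylinder_basis_modes(art, 0.44, "contact_pinned",
                         n_basis = nb, n_modes = 3)$lambda)
  for (i in 1:3) {
    expect_lte(lam[i, 2], lam[i, 1] + 1e-10)
    expect_lte(lam[i, 3], lam[i, 2] + 1e-10)
  }
})

test_that("Galerkin route works where direct solution was reported unstable", {
  g <- cylinder_basis_modes(art, 0.6, "contact_pinned", n_modes = 3)
  expect_true(all(is.finite(g$lambda)))
  expect_true(all(diff(g$lambda) > 0))
  # and still matches our collocation there
  d <- solve_modes_pinned(art, 0.6, n_modes = 3)
  expect_equal(g$omega, d$omega, tolerance = 0.01)
})

test_that("guards: basis size, conditioning, mode counts", {
  expect_error(cylinder_basis_modes(art, 0.3, "contact_pinned",
                                    n_basis = 5, n_modes = 3), "n_basis")
  expect_error(solve_modes_pinned(art, 0.99), "0.97")
  expect_error(whisker_modes(art, boundary_kind = "free_tip",
                             n_modes = 200), "eigenvalues")
})

test_that("mode sets survive a CSV round trip", {
  ms <- solve_modes_pinned(art, 0.3, n_modes = 2)
  f <- tempfile(fileext = ".csv")
  write_mode_set(ms, f)
  back <- read_mode_set(f)
  expect_equal(back$lambda, ms$lambda)
  expect_equal(back$s, ms$s)
  expect_equal(unname(back$V), unname(ms$V), tolerance = 1e-12)
})
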