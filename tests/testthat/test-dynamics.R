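art <- whisker_preset("artificial")
real <- whisker_preset("real")

test_that("Green's function has the right limits, start and first zero", {
  expect_equal(greens_function(500, 0.041, 0), 0)
  # G'(0) = 1 from a forward difference at tiny dt
  dt <- 1e-9
  expect_equal(greens_function(500, 0.041, dt) / dt, 1, tolerance = 1e-5)
  # vanishing damping limit: sin(omega t) / omega
  t <- seq(0, 0.01, length.out = 50)
  expect_equal(greens_function(300, 1e-9, t), sin(300 * t) / 300,
               tolerance = 1e-6)
  # first zero crossing at pi / (sqrt(1 - zeta^2) omega)
  om <- 700; z <- 0.2
  tz <- pi / (sqrt(1 - z^2) * om)
  expect_equal(greens_function(om, z, tz), 0, tolerance = 1e-12)
  expect_gt(min(greens_function(om, z, seq(tz / 50, tz * 0.98,
                                           length.out = 50))), 0)
  # bounded by the damped envelope
  tt <- seq(0, 0.05, length.out = 200)
  expect_true(all(abs(greens_function(om, z, tt)) <=
                  exp(-z * om * tt) / (sqrt(1 - z^2) * om) + 1e-15))
  expect_error(greens_function(-1, 0.1, 0), "omega")
  expect_error(greens_function(1, 1.1, 0), "zeta")
})

test_that("shock shapes carry the quasi-static boundary values", {
  for (eps in c(0.3, 0.5, 0.7)) {
    expect_equal(shock_shape_ubar(eps, "fixed", eps), 1, tolerance = 1e-12)
    expect_equal(shock_shape_ubar(eps, "fixed", 1), 0, tolerance = 1e-12)
    expect_equal(shock_shape_ubar(eps, "rotating", eps), 0, tolerance = 1e-12)
    expect_equal(shock_shape_ubar(eps, "rotating", 1), 0, tolerance = 1e-12)
  }
  # pointwise equality with the quasi-static profile per unit drive
  eps <- 0.44; s <- seq(eps, 1, length.out = 17)
  ind <- 3e-3
  expect_equal(shock_shape_ubar(eps, "fixed", s) * ind,
               qs_profile_fixed(art, eps, ind, s)$U, tolerance = 1e-12)
  phi <- 0.03; L <- art$untruncated_length
  expect_equal(shock_shape_ubar(eps, "rotating", s) * L * phi,
               qs_profile_rotating(art, eps, phi, s)$U, tolerance = 1e-12)
})

test_that("modal amplitudes scale with A, start at zero, and match a quadrature oracle", {
  modes <- solve_modes_pinned(art, 0.44, n_modes = 3)
  t <- seq(0, 0.005, by = 2e-5)
  ub <- function(s) shock_shape_ubar(0.44, "fixed", s)
  q1 <- modal_amplitudes(modes, ub, 1, t)
  q2 <- modal_amplitudes(modes, ub, 2, t)
  expect_equal(unname(q2), unname(2 * q1), tolerance = 1e-12)
  expect_equal(unname(q1[1, ]), rep(0, 3))
  expect_true(all(modal_amplitudes(modes, ub, 0, t) == 0))
  # projection integrals against adaptive quadrature on the interpolant
  P <- attr(q1, "projections")
  for (i in 1:3) {
    oracle <- stats::integrate(function(x)
      x^2 * ub(x) * pracma::barylag(modes$s, modes$V[, i], x),
      0.44, 1, rel.tol = 1e-12)$value
    expect_lt(abs(-P[i] - (-oracle)), 1e-8)
  }
  expect_error(modal_amplitudes(modes, rep(1, 3), 1, t), "mode grid")
})

test_that("shock response: zero drive, opposing initial transient, damped tail", {
  cc0 <- contact_config(0.44, speed = 0, mode = "fixed", spec = art)
  t <- seq(0, 0.01, by = 1 / 25000)
  r0 <- shock_response(art, cc0, t)
  expect_equal(r0$M_total, rep(0, length(t)))

  cc <- contact_config(0.44, speed = 0.689, mode = "fixed", spec = art)
  r <- shock_response(art, cc, t)
  # quasi-static torque grows positive; the incoming wave front first drives
  # the dynamic torque negative
  expect_gt(r$qs_rate_per_time, 0)
  early <- r$t > 0 & r$t < 0.3e-3
  expect_lt(min(r$M_dyn[early]), 0)
  expect_lt(mean(r$M_dyn[early]), 0)
  # late-time envelope decays like the first mode: fit log |peaks| of M_dyn
  tl <- seq(0, 0.2, by = 1 / 25000)
  rl <- shock_response(art, cc, tl, n_modes = 1)
  pk <- which(diff(sign(diff(abs(rl$M_dyn)))) == -2) + 1
  pk <- pk[tl[pk] > 0.02 & tl[pk] < 0.15]
  fit <- stats::lm(log(abs(rl$M_dyn[pk])) ~ tl[pk])
  z_om1 <- art$damping * rl$modes$omega[1]
  expect_equal(unname(stats::coef(fit)[2]), -z_om1, tolerance = 0.05)
  expect_error(shock_response(art, cc, t, n_modes = 40), "exceeds")
})

test_that("shock metrics: delta_Mdot proportional to V, tau invariant in V", {
  t <- seq(0, 0.01, by = 1 / 25000)
  Vs <- c(0.2, 0.5, 1.0)
  res <- lapply(Vs, function(V)
    shock_metrics(shock_response(
      art, contact_config(0.44, speed = V, mode = "fixed", spec = art), t)))
  taus <- vapply(res, `[[`, numeric(1), "tau")
  dMs <- vapply(res, `[[`, numeric(1), "delta_Mdot")
  expect_lt(diff(range(taus)) / mean(taus), 0.05)
  expect_equal(dMs / Vs, rep(dMs[1] / Vs[1], 3), tolerance = 1e-10)
  expect_true(all(vapply(res, `[[`, numeric(1), "delta_Mdot") >= 0))
  expect_true(all(taus > 0))
})

test_that("delta_Mdot rises and tau falls as the contact nears the base", {
  # 50 kHz keeps the sampling precondition satisfied up to eps = 0.7
  t <- seq(0, 0.01, by = 1 / 50000)
  eps_grid <- seq(0.2, 0.7, by = 0.1)
  m <- lapply(eps_grid, function(eps)
    shock_metrics(shock_response(
      art, contact_config(eps, speed = 0.99, mode = "fixed", spec = art), t)))
  dM <- vapply(m, `[[`, numeric(1), "delta_Mdot")
  tau <- vapply(m, `[[`, numeric(1), "tau")
  # monotone trends across the sweep (individual neighbours may jitter as the
  # dominant dM/dt peak hops between modes)
  expect_gt(stats::cor(eps_grid, dM, method = "kendall"), 0.5)
  expect_lt(stats::cor(eps_grid, tau, method = "kendall"), -0.3)
  expect_gt(dM[length(dM)], dM[1])
  expect_lt(tau[length(tau)], tau[1])
})

test_that("metrics guard their sampling preconditions", {
  cc <- contact_config(0.44, speed = 0.5, mode = "fixed", spec = art)
  slow <- shock_response(art, cc, seq(0, 0.01, by = 1 / 2000), n_modes = 2)
  expect_error(shock_metrics(slow), "sampling rate")
  ok <- shock_response(art, cc, seq(0, 0.01, by = 1 / 25000))
  expect_error(shock_metrics(ok, window = 1e-4), "window")
})

test_that("free whisking: zero amplitude, linearity, closed-form convolution", {
  t <- seq(0, 0.4, by = 1 / 20000)
  f0 <- free_whisking_response(real, 15, 0, t)
  expect_equal(f0$M, rep(0, length(t)))
  f1 <- free_whisking_response(real, 15, 10 * pi / 180, t)
  f2 <- free_whisking_response(real, 15, 20 * pi / 180, t)
  expect_equal(f2$M, 2 * f1$M, tolerance = 1e-12)
  # closed-form damped convolution against a Simpson oracle
  zeta <- real$damping
  om <- f1$modes$omega[1:2]
  for (i in 1:2) {
    a <- zeta * om[i]; b <- sqrt(1 - zeta^2) * om[i]; w <- 2 * pi * 15
    for (tt in c(0.013, 0.11)) {
      exact <- conewhisk:::conv_damped_sin(a, b, w, tt)
      expect_equal(exact, simpson_conv(a, b, w, tt), tolerance = 1e-6)
    }
  }
})

test_that("steady-state whisking torque is periodic at f_w with omega^2 phi0 scaling", {
  fs <- 20000
  t <- seq(0, 4 / 15, by = 1 / fs)
  fw <- free_whisking_response(real, 15, 10 * pi / 180, t, steady_state = TRUE)
  per <- round(fs / 15)
  expect_equal(fw$M[1:per], fw$M[per + (1:per)], tolerance = 1e-6)
  # doubling the whisking frequency scales the drive by 4 (amplitude not
  # exactly 4x because the modal transfer function moves, but close below
  # resonance)
  amp1 <- max(abs(fw$M))
  fw2 <- free_whisking_response(real, 30, 10 * pi / 180, t, steady_state = TRUE)
  expect_gt(max(abs(fw2$M)) / amp1, 3)
})

test_that("modal energy decays between forcing events", {
  modes <- solve_modes_pinned(art, 0.44, n_modes = 3)
  t <- seq(0, 0.05, by = 1e-5)
  q <- modal_amplitudes(modes, function(s) shock_shape_ubar(0.44, "fixed", s),
                        0.7, t)
  qd <- apply(q, 2, function(x) c(diff(x) / 1e-5, 0))
  E <- rowSums(qd^2) + rowSums(sweep(q^2, 2, modes$omega^2, "*"))
  E <- E[t > 0.002 & t < 0.045]
  # allow tiny numerical ripple from the finite-difference velocity
  expect_true(all(diff(E) < 1e-3 * max(E)))
  expect_lt(E[length(E)], 0.2 * E[1])
})

test_that("whisking against an unreachable object reduces to free whisking", {
  tr <- whisking_contact_sim(real, 15, 10 * pi / 180,
                             object = list(epsilon = 0.5, phi_c = 0.5),
                             n_cycles = 2)
  expect_equal(nrow(tr$events), 0)
  expect_equal(tr$M, attr(tr, "air"))
  fw <- free_whisking_response(real, 15, 10 * pi / 180, tr$t,
                               steady_state = TRUE)
  expect_equal(tr$M, fw$M, tolerance = 1e-12)
})

test_that("contacts at the end of protraction launch vanishing shocks", {
  sims <- lapply(c(0.5, 0.9, 0.99), function(r)
    whisking_contact_sim(real, 15, 10 * pi / 180,
                         object = list(epsilon = 0.5, phi_c = r * 10 * pi / 180),
                         n_cycles = 2))
  As <- vapply(sims, function(s) attr(s, "contacts")$A[1], numeric(1))
  expect_true(all(diff(As) < 0))
  # A = L phi0 omega cos(asin(r)) at the upward crossing of r * phi0
  # onset quantised to the sampling grid, so allow a few percent
  expect_equal(As[3] / As[1], sqrt(1 - 0.99^2) / sqrt(1 - 0.5^2),
               tolerance = 0.05)
})

test_that("per-cycle torque maximum grows as the contact angle drops", {
  phis <- c(0.7, 0.4, 0.0, -0.4) * 10 * pi / 180
  mx <- vapply(phis, function(pc) {
    tr <- whisking_contact_sim(real, 15, 10 * pi / 180,
                               object = list(epsilon = 0.5, phi_c = pc),
                               n_cycles = 2)
    max(abs(tr$M))
  }, numeric(1))
  expect_true(all(diff(mx) > 0))
})

test_that("wave-speed scale reproduces the printed values and their ratio", {
  expect_equal(wave_speed_scale(art), 8.3, tolerance = 0.01)
  expect_equal(wave_speed_scale(real), 3.1, tolerance = 0.01)
  expect_equal(round(wave_speed_scale(art) / wave_speed_scale(real), 1), 2.7)
})
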