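# Damped modal time-domain responses: shock-induced vibrations, free-whisking
# inertial deflections, and the composite whisking-against-object simulation.
# All convolutions are evaluated in closed form (damped sinusoid x sinusoid
# via complex exponentials), so results carry no time-step quadrature error.

#' Green's function of one damped mode
#'
#' `G(t) = exp(-zeta omega t) sin(sqrt(1 - zeta^2) omega t) /
#' (sqrt(1 - zeta^2) omega)`: the unit-impulse velocity response of a damped
#' oscillator, with `G(0) = 0` and `G'(0) = 1`.
#'
#' @param omega Angular eigenfrequency in rad/s.
#' @param zeta Damping ratio in (0, 1).
#' @param t Times in seconds, `t >= 0` (vectorised).
#' @return `G(t)` in seconds.
#' @export
greens_function <- function(omega, zeta, t) {
  if (omega <= 0) stop("omega must be positive", call. = FALSE)
  if (zeta <= 0 || zeta >= 1) stop("zeta must lie in (0, 1)", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  wd <- sqrt(1 - zeta^2) * omega
  exp(-zeta * omega * t) * sin(wd * t) / wd
}

greens_function_deriv <- function(omega, zeta, t) {
  wd <- sqrt(1 - zeta^2) * omega
  exp(-zeta * omega * t) * (cos(wd * t) - zeta * omega / wd * sin(wd * t))
}

# closed-form I(t) = int_0^t exp(-a (t - u)) sin(b (t - u)) sin(w u) du.
# steady = TRUE drops the decaying homogeneous terms (harmonic steady state).
conv_damped_sin <- function(a, b, w, t, steady = FALSE) {
  p <- complex(real = -a, imaginary = b)
  ept <- if (steady) 0 else exp(p * t)
  f1 <- (exp(1i * w * t) - ept) / (1i * w - p)
  f2 <- (exp(-1i * w * t) - ept) / (-1i * w - p)
  Im((f1 - f2) / 2i)
}

#' Normalised shock shape
#'
#' The quasi-static profile grows as `U_qs(s, t) = A t Ubar(s)` after the
#' shock, so its second time derivative is the impulse `delta(t) A Ubar(s)`
#' that excites the modes. `Ubar` is the dimensionless Table-geometry shape:
#' for the fixed-whisker shock it equals 1 at the contact point; for the
#' rotating one it vanishes there and has unit base slope (per `L gamma`).
#'
#' @param epsilon Contact coordinate in (0, 1).
#' @param mode `"fixed"` or `"rotating"`.
#' @param s Evaluation points in `[epsilon, 1]`.
#' @return Dimensionless profile values.
#' @export
shock_shape_ubar <- function(epsilon, mode = c("fixed", "rotating"), s) {
  mode <- match.arg(mode)
  check_epsilon(epsilon)
  switch(mode,
         fixed = qs_shape_fixed(s, epsilon),
         rotating = qs_shape_rotating(s, epsilon))
}

#' Modal amplitudes of a shock response
#'
#' `q_i(t) = -A (int_eps^1 s^2 Ubar(s) V_i(s) ds) G_i(t)`: each mode is
#' kicked by the mass-weighted projection of the shock shape and rings down
#' with its own damped Green's function. Strictly proportional to `A`.
#'
#' @param modes A `mode_set` (mass-normalised).
#' @param ubar Shock shape: function of `s`, or values on `modes$s`.
#' @param A Shock amplitude: `V` (m/s, fixed) or `L gamma` (m/s, rotating).
#' @param t_grid Times from the shock (s).
#' @param zeta Damping ratio; defaults to the whisker's.
#' @return Matrix `length(t_grid) x n_modes` of amplitudes in metres, with
#'   the projection integrals attached as attribute `"projections"`.
#' @export
modal_amplitudes <- function(modes, ubar, A, t_grid, zeta = NULL) {
  stopifnot(inherits(modes, "mode_set"))
  if (is.null(zeta)) zeta <- modes$spec$damping
  if (!is.function(ubar) && length(ubar) != length(modes$s))
    stop("ubar values do not match the mode grid", call. = FALSE)
  P <- modeset_project(modes, ubar)
  G <- vapply(modes$omega,
              function(om) greens_function(om, zeta, t_grid),
              numeric(length(t_grid)))
  q <- -A * sweep(matrix(G, ncol = length(P)), 2, P, "*")
  attr(q, "projections") <- P
  q
}

# default mode count: all modes resolvable by the time grid with at least
# three samples per period (a discrete derivative at fewer is meaningless)
bandwidth_mode_count <- function(omega, fs, n_max = length(omega)) {
  min(max(1L, sum(omega / (2 * pi) <= fs / 3)), n_max)
}

modes_subset <- function(modes, idx) {
  modes$lambda <- modes$lambda[idx]
  modes$omega <- modes$omega[idx]
  modes$V <- modes$V[, idx, drop = FALSE]
  modes$d2V_base <- modes$d2V_base[idx]
  modes
}

#' Shock-induced base-torque response
#'
#' Assembles the total base torque after a quasi point-like shock as the sum
#' of the linearly growing quasi-static torque and the damped modal dynamic
#' torque `M_dyn(t) = (E pi b^4 / 4) (1/L^2) sum_i q_i(t) V_i''(1)`. The
#' incoming deflection wave makes the initial dynamic transient oppose the
#' quasi-static growth (negative base-torque excursion), followed by damped
#' oscillations.
#'
#' Mode count: when `n_modes` is `NULL`, all modes with eigenfrequency below
#' a third of the sampling rate of `t_grid` are kept (the delta-impulse drive
#' has unbounded bandwidth, so the response must be truncated at what the
#' sampling can represent; three samples per period is the least that gives a
#' meaningful discrete derivative). Modes come from direct collocation for
#' `epsilon <= 0.35` and from the cylinder-basis projection closer to the
#' base.
#'
#' @param spec A [whisker_spec()].
#' @param contact A [contact_config()].
#' @param t_grid Uniform time grid starting at the shock (`t[1] = 0`).
#' @param n_modes Number of modes, or `NULL` for the bandwidth default.
#' @param n_solve Modes solved before truncation (default 12).
#' @return A `shock_response`: `t`, `M_qs`, `M_dyn`, `M_total`, modal
#'   amplitudes `q`, the `mode_set`, drive amplitude `A`.
#' @export
shock_response <- function(spec, contact, t_grid, n_modes = NULL, n_solve = 12) {
  stop_if_not_spec(spec)
  stopifnot(inherits(contact, "contact_config"))
  if (abs(t_grid[1]) > 1e-12) stop("t_grid must start at the shock (t = 0)",
                                   call. = FALSE)
  fs <- 1 / (t_grid[2] - t_grid[1])
  eps <- contact$epsilon
  L <- spec$untruncated_length
  A <- if (contact$mode == "fixed") contact$speed else L * contact$angular_rate
  modes_all <- whisker_modes(spec, eps, "contact_pinned", n_modes = n_solve)
  if (is.null(n_modes)) {
    n_modes <- bandwidth_mode_count(modes_all$omega, fs)
  } else if (n_modes > n_solve) {
    stop(sprintf("n_modes = %d exceeds the %d solved modes", n_modes, n_solve),
         call. = FALSE)
  }
  modes <- modes_subset(modes_all, seq_len(n_modes))
  ubar <- shock_shape_ubar(eps, contact$mode, modes$s)
  q <- modal_amplitudes(modes, ubar, A, t_grid)
  EIL2 <- base_stiffness(spec) / L^2
  M_dyn <- EIL2 * as.numeric(q %*% modes$d2V_base)
  d <- contact_distance_unchecked(spec, eps)
  rate <- switch(contact$mode,
                 fixed = qs_torque_rate_fixed(spec, d) * contact$speed,
                 rotating = qs_torque_rate_rotating(spec, d) * contact$angular_rate)
  M_qs <- rate * t_grid
  structure(list(t = t_grid, M_qs = M_qs, M_dyn = M_dyn,
                 M_total = M_qs + M_dyn, q = q, modes = modes,
                 contact = contact, A = A, spec = spec,
                 qs_rate_per_time = rate),
            class = "shock_response")
}

#' Dynamic displacement field of a shock response
#'
#' `u(s, t) + U_qs(s, t)` sampled on `s_out` (within `[epsilon, 1]`), in
#' metres; rows follow the response time grid.
#'
#' @param resp A [shock_response()].
#' @param s_out Dimensionless positions in `[epsilon, 1]`.
#' @param total Include the quasi-static part (default `TRUE`).
#' @export
displacement_field <- function(resp, s_out, total = TRUE) {
  stopifnot(inherits(resp, "shock_response"))
  V <- modeset_eval(resp$modes, s_out)
  u <- resp$q %*% t(V)
  if (total) {
    g <- shock_shape_ubar(resp$contact$epsilon, resp$contact$mode, s_out)
    u <- u + outer(resp$A * resp$t, g)
  }
  u
}

#' Shock metrics: maximal torque-derivative swing and its delay
#'
#' The discrete time derivative of the total base torque oscillates strongly
#' just after the shock; `dM_plus` and `dM_minus` are its extrema within the
#' post-shock window, `delta_Mdot = dM_plus - dM_minus` their swing, and
#' `tau` the time (from the shock) at which the swing is completed, i.e. the
#' time of the later of the two extremes. `delta_Mdot` is proportional to the
#' shock amplitude while `tau` is amplitude-independent.
#'
#' @param resp A [shock_response()].
#' @param window Post-shock analysis window in seconds (default 10 ms).
#' @return A `shock_metrics` list: `dM_plus`, `dM_minus` (N m / s),
#'   `delta_Mdot`, `tau` (s).
#' @export
shock_metrics <- function(resp, window = 0.01) {
  stopifnot(inherits(resp, "shock_response"))
  dt <- resp$t[2] - resp$t[1]
  f1 <- resp$modes$omega[1] / (2 * pi)
  if (1 / dt < 20 * f1)
    stop(sprintf("sampling rate %.3g Hz below 20x first mode frequency %.3g Hz",
                 1 / dt, f1), call. = FALSE)
  if (window < 1 / f1)
    stop("analysis window shorter than one period of the first mode",
         call. = FALSE)
  keep <- resp$t <= window + dt / 2
  M <- resp$M_total[keep]
  tm <- (resp$t[keep][-1] + resp$t[keep][-sum(keep)]) / 2
  Md <- diff(M) / dt
  imax <- which.max(Md); imin <- which.min(Md)
  structure(list(dM_plus = Md[imax], dM_minus = Md[imin],
                 delta_Mdot = Md[imax] - Md[imin],
                 tau = max(tm[imax], tm[imin]),
                 t_plus = tm[imax], t_minus = tm[imin]),
            class = "shock_metrics")
}

#' @export
print.shock_metrics <- function(x, ...) {
  cat(sprintf("<shock_metrics> dMdot+ = %.4g, dMdot- = %.4g N m/s; delta = %.4g; tau = %.4g s\n",
              x$dM_plus, x$dM_minus, x$delta_Mdot, x$tau))
  invisible(x)
}

#' Inertial base torque during free whisking
#'
#' With the base angle driven as `phi(t) = phi0 sin(2 pi f_w t)` and no
#' contact, the rigid rotation `U_qs = L phi(t) (1 - s)` carries no base
#' curvature, but the whisker's inertia excites the free-tip modes:
#' `u(s,t) = -(L omega_w^2 phi0 / sqrt(1 - zeta^2)) sum_i (V_i(s)/omega_i)
#' J_i I_i(t)` with `J_i = int s^2 (1 - s) V_i ds` and `I_i` the damped
#' convolution with the sinusoidal drive (evaluated in closed form). The
#' resulting base torque oscillates at the whisking frequency with amplitude
#' proportional to `phi0 omega_w^2` — the mechanical noise floor of whisking
#' in air.
#'
#' @param spec A [whisker_spec()].
#' @param f_w Whisking frequency in Hz.
#' @param phi0 Whisking amplitude in radians.
#' @param t_grid Time grid in seconds.
#' @param n_modes Number of free-tip modes (default 5).
#' @param steady_state If `TRUE`, return the periodic steady state (the
#'   particular harmonic solution) instead of the from-rest transient.
#' @param modes Optional precomputed free-tip `mode_set`.
#' @return A `free_whisking` list: `t`, `M` (N m), modal displacement
#'   coefficients `q` (m), `phi`, the `mode_set`.
#' @export
free_whisking_response <- function(spec, f_w, phi0, t_grid, n_modes = 5,
                                   steady_state = FALSE, modes = NULL) {
  stop_if_not_spec(spec)
  if (is.null(modes)) modes <- solve_modes_free(spec, n_modes = n_modes)
  zeta <- spec$damping
  L <- spec$untruncated_length
  ww <- 2 * pi * f_w
  wd <- sqrt(1 - zeta^2) * modes$omega
  J <- modeset_project(modes, function(s) 1 - s)
  I <- vapply(seq_along(modes$omega), function(i)
    conv_damped_sin(zeta * modes$omega[i], wd[i], ww, t_grid,
                    steady = steady_state),
    numeric(length(t_grid)))
  coef <- -L * ww^2 * phi0 / sqrt(1 - zeta^2)
  q <- coef * sweep(matrix(I, ncol = length(J)), 2, J / modes$omega, "*")
  M <- base_stiffness(spec) / L^2 * as.numeric(q %*% modes$d2V_base)
  structure(list(t = t_grid, M = M, q = q, phi = phi0 * sin(ww * t_grid),
                 f_w = f_w, phi0 = phi0, modes = modes,
                 steady_state = steady_state),
            class = "free_whisking")
}

#' Characteristic deflection-wave speed
#'
#' Dimensional scaling of the contact-triggered transverse wave speed,
#' `alpha sqrt(E / rho)`: the bulk sound speed scaled by the conicity.
#'
#' @param spec A [whisker_spec()].
#' @return Speed in m/s.
#' @export
wave_speed_scale <- function(spec) {
  stop_if_not_spec(spec)
  spec$conicity * sqrt(spec$young_modulus / spec$density)
}

# --- whisking against an object -------------------------------------------

# ring-down of free modes from initial modal displacement/velocity
ringdown <- function(Q0, Qd0, omega, zeta, tau) {
  wd <- sqrt(1 - zeta^2) * omega
  e <- exp(-zeta * omega * tau)
  e * (Q0 * cos(wd * tau) + (Qd0 + zeta * omega * Q0) / wd * sin(wd * tau))
}

#' Whisking against an approaching or fixed object
#'
#' Simulates the total base torque of a sinusoidally whisking whisker that
#' repeatedly contacts an object. The torque is assembled by linear
#' superposition of: (i) the steady-state inertial free-whisking torque;
#' (ii) during each contact interval (`phi(t) >= phi_c`), the rotating-mode
#' quasi-static torque at the excess angle `phi(t) - phi_c`; (iii) a pinned
#' shock transient launched at each contact onset with amplitude
#' `A = L phid(t_on)`; and (iv) after each release, a free-tip ring-down
#' started from the instantaneous modal state (pinned state projected onto
#' the free modes). Contact onsets are upward crossings of the contact angle.
#'
#' @param spec A [whisker_spec()].
#' @param f_w Whisking frequency (Hz).
#' @param phi0 Whisking amplitude (rad).
#' @param object Either `list(epsilon =, phi_c =)` — an object fixed at
#'   contact coordinate `epsilon`, touched when the protraction angle exceeds
#'   `phi_c` — or `list(H =, approach_speed =, y_stop =, y_start =)` — an
#'   object translating parallel to the whisker's rest axis at distance `H`,
#'   from `y_start` (default: just out of reach) towards `y_stop`.
#' @param n_cycles Number of whisking cycles simulated.
#' @param fs Sampling rate (Hz).
#' @param n_modes_free Free-tip modes (default 5).
#' @param n_modes_contact Pinned modes per contact, or `NULL` for the
#'   bandwidth default.
#' @param cache Optional environment reusing mode solutions across calls.
#' @return A [torque_trace()] with one `"contact"` and `"release"` event per
#'   contact; attributes `"air"` (the free-whisking component) and
#'   `"contacts"` (onset/release/epsilon/amplitude table).
#' @export
whisking_contact_sim <- function(spec, f_w, phi0, object, n_cycles = 3,
                                 fs = 20000, n_modes_free = 5,
                                 n_modes_contact = NULL, cache = NULL) {
  stop_if_not_spec(spec)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  n <- ceiling(n_cycles / f_w * fs) + 1
  t <- (seq_len(n) - 1) / fs
  ww <- 2 * pi * f_w
  phi <- phi0 * sin(ww * t)
  phid <- phi0 * ww * cos(ww * t)
  L <- spec$untruncated_length
  zeta <- spec$damping
  EIL2 <- base_stiffness(spec) / L^2

  if (is.null(cache$modes_free))
    cache$modes_free <- solve_modes_free(spec, n_modes = n_modes_free)
  modes_free <- cache$modes_free
  air <- free_whisking_response(spec, f_w, phi0, t, steady_state = TRUE,
                                modes = modes_free)
  M <- air$M

  # contact condition over time
  if (!is.null(object$epsilon)) {
    eps_of_onset <- function(i) object$epsilon
    phc <- rep(object$phi_c, n)
    reachable <- abs(object$phi_c) < phi0
  } else {
    H <- object$H
    y_start <- if (!is.null(object$y_start)) object$y_start
               else H * tan(phi0) * 1.0001
    y_obj <- pmax(y_start - object$approach_speed * t, object$y_stop)
    phc <- atan2(y_obj, H)
    d_t <- H / cos(phc)
    reachable <- any(phc < phi0 & d_t < L * (1 - spec$tip_coord))
    eps_of_onset <- function(i) 1 - (H / cos(phc[i])) / L
  }

  events <- data.frame(label = character(), time = numeric())
  contacts <- data.frame(t_on = numeric(), t_off = numeric(),
                         epsilon = numeric(), A = numeric())
  if (reachable) {
    inc <- phi >= phc
    trans <- diff(inc)
    onsets <- which(trans == 1) + 1
    onsets <- onsets[phid[onsets] > 0 & onsets < n]
    for (i_on in onsets) {
      i_off <- i_on + which(!inc[(i_on + 1):n])[1]
      if (is.na(i_off)) i_off <- n
      eps <- eps_of_onset(i_on)
      if (eps <= spec$tip_coord || eps >= 1) next
      key <- sprintf("pinned_%.6f", eps)
      if (is.null(cache[[key]])) {
        mp <- whisker_modes(spec, eps, "contact_pinned",
                            n_modes = if (is.null(n_modes_contact)) 10
                                      else n_modes_contact)
        nm <- if (is.null(n_modes_contact))
          bandwidth_mode_count(mp$omega, fs) else n_modes_contact
        mp <- modes_subset(mp, seq_len(nm))
        # cross-projection of pinned modes onto free modes over [eps, 1]
        Vf_on_p <- modeset_eval(modes_free, mp$s)
        X <- crossprod(Vf_on_p, (mp$weights * mp$s^2) * mp$V)
        cache[[key]] <- list(modes = mp, X = X,
                             P = modeset_project(mp, function(s)
                               qs_shape_rotating(s, eps)))
      }
      ck <- cache[[key]]
      mp <- ck$modes
      A <- L * phid[i_on]
      d <- contact_distance_unchecked(spec, eps)
      idx_c <- i_on:i_off
      tau_c <- t[idx_c] - t[i_on]
      # quasi-static push while in contact
      M[idx_c] <- M[idx_c] +
        qs_torque_rate_rotating(spec, d) * pmax(phi[idx_c] - phc[i_on], 0)
      # pinned shock transient
      G <- vapply(mp$omega, function(om) greens_function(om, zeta, tau_c),
                  numeric(length(tau_c)))
      q <- -A * sweep(matrix(G, ncol = length(ck$P)), 2, ck$P, "*")
      M[idx_c] <- M[idx_c] + EIL2 * as.numeric(q %*% mp$d2V_base)
      # release: project instantaneous pinned state onto free modes
      if (i_off < n) {
        tau_off <- t[i_off] - t[i_on]
        q_off <- -A * ck$P *
          vapply(mp$omega, function(om) greens_function(om, zeta, tau_off),
                 numeric(1))
        qd_off <- -A * ck$P * greens_function_deriv(mp$omega, zeta, tau_off)
        Q0 <- as.numeric(ck$X %*% q_off)
        Qd0 <- as.numeric(ck$X %*% qd_off)
        idx_r <- (i_off + 1):n
        tau_r <- t[idx_r] - t[i_off]
        Qr <- vapply(seq_along(Q0), function(j)
          ringdown(Q0[j], Qd0[j], modes_free$omega[j], zeta, tau_r),
          numeric(length(tau_r)))
        M[idx_r] <- M[idx_r] +
          EIL2 * as.numeric(matrix(Qr, ncol = length(Q0)) %*% modes_free$d2V_base)
      }
      events <- rbind(events,
                      data.frame(label = c("contact", "release"),
                                 time = c(t[i_on], t[min(i_off, n)])))
      contacts <- rbind(contacts,
                        data.frame(t_on = t[i_on], t_off = t[min(i_off, n)],
                                   epsilon = eps, A = A))
    }
  }
  tr <- torque_trace(t, M, events = events[order(events$time), , drop = FALSE])
  attr(tr, "air") <- air$M
  attr(tr, "contacts") <- contacts
  attr(tr, "phi") <- phi
  tr
}
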