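# Video-profile analysis chain: sub-pixel centerline extraction from bright-
# on-dark frames, displacement and base-curvature estimation, torque-curvature
# calibration, and deflection-wave-front tracking.

#' Profile stack
#'
#' Time-ordered whisker profiles on a fixed column grid. `y` holds one row
#' per frame, in metres; `x` are the column positions (metres from the base
#' column).
#'
#' @param t Frame times (s), uniform.
#' @param y Matrix `n_frames x n_columns` of whisker ordinates (m); `NA`
#'   marks missing columns.
#' @param pixel_size Pixel size (m).
#' @param frame_rate Frame rate (Hz).
#' @export
profile_stack <- function(t, y, pixel_size, frame_rate) {
  stopifnot(is.matrix(y), length(t) == nrow(y), pixel_size > 0)
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("frame times must be uniform", call. = FALSE)
  }
  structure(list(t = t, y = y, x = (seq_len(ncol(y)) - 1) * pixel_size,
                 pixel_size = pixel_size, frame_rate = frame_rate),
            class = "profile_stack")
}

#' @export
print.profile_stack <- function(x, ...) {
  cat(sprintf("<profile_stack> %d frames x %d columns, %.0f fps, pixel %.3g m\n",
              nrow(x$y), ncol(x$y), x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Sub-pixel whisker profile from one frame
#'
#' Per-column intensity barycentre of a single bright curvilinear object on a
#' darker background. Each column is background-subtracted (median) and
#' thresholded at 20% of its contrast before the centroid, which suppresses
#' the noise bias of a full-column barycentre. Columns whose contrast falls
#' below `contrast_floor` (default: 6 times a robust noise estimate of the
#' frame) are returned as `NA`; frames containing more than one bright object
#' per column are flagged.
#'
#' @param frame Intensity matrix (rows x columns).
#' @param pixel_size Pixel size (m).
#' @param contrast_floor Minimum column contrast; `NULL` for the default.
#' @return Numeric vector of ordinates (m), `NA` where missing, with
#'   attribute `"ambiguous"` (logical per column).
#' @export
extract_profile <- function(frame, pixel_size, contrast_floor = NULL) {
  stopifnot(is.matrix(frame), pixel_size > 0)
  if (is.null(contrast_floor)) {
    noise <- stats::mad(frame)
    contrast_floor <- 6 * max(noise, 1e-12)
  }
  nc <- ncol(frame)
  y <- rep(NA_real_, nc)
  amb <- rep(FALSE, nc)
  rows <- seq_len(nrow(frame))
  for (j in seq_len(nc)) {
    col <- frame[, j]
    bg <- stats::median(col)
    sig <- col - bg
    contrast <- max(sig)
    if (!is.finite(contrast) || contrast < contrast_floor) next
    mask <- sig > 0.2 * contrast
    runs <- rle(mask)
    if (sum(runs$values & runs$lengths >= 2) > 1) amb[j] <- TRUE
    # soft threshold: a hard cut-off biases the centroid of off-centre ridges
    wgt <- pmax(sig - 0.2 * contrast, 0)
    y[j] <- (sum(wgt * rows) / sum(wgt) - 1) * pixel_size
  }
  if (all(is.na(y)))
    warning("empty frame: no column exceeded the contrast floor")
  if (any(amb))
    warning("ambiguous frame: multiple bright objects in some columns")
  attr(y, "ambiguous") <- amb
  y
}

#' Extract a profile stack from a sequence of frames
#'
#' @param frames 3-d array (frame x row x column) or list of matrices.
#' @param pixel_size Pixel size (m).
#' @param frame_rate Frame rate (Hz).
#' @param t0 Time of the first frame (s).
#' @inheritParams extract_profile
#' @return A [profile_stack()].
#' @export
extract_stack <- function(frames, pixel_size, frame_rate, t0 = 0,
                          contrast_floor = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
  y <- t(vapply(frames, function(f)
    suppressWarnings(as.numeric(extract_profile(f, pixel_size, contrast_floor))),
    numeric(ncol(frames[[1]]))))
  t <- t0 + (seq_along(frames) - 1) / frame_rate
  profile_stack(t, y, pixel_size, frame_rate)
}

# sliding-window mean smoothing with NA interpolation; width in samples
smooth_profile <- function(y, width) {
  n <- length(y)
  miss <- !is.finite(y)
  if (all(miss)) return(y)
  if (any(miss))
    y <- stats::approx(which(!miss), y[!miss], xout = seq_len(n), rule = 2)$y
  if (width <= 1) return(y)
  kern <- rep(1 / width, width)
  pad <- floor(width / 2)
  yp <- c(rep(y[1], pad), y, rep(y[n], width - 1 - pad))
  as.numeric(stats::filter(yp, kern, sides = 1))[(width - 1 + 1):(width - 1 + n)]
}

# constrained cubic fit U(x) = c0 + c2 (x - xb)^2 + c3 (x - xb)^3 (zero slope
# at the base column); returns base curvature 2 c2 and residual RMS
fit_constrained_cubic <- function(x, U, x_base) {
  dx <- x - x_base
  X <- cbind(1, dx^2, dx^3)
  ok <- is.finite(U)
  if (sum(ok) < 4) return(list(C = NA_real_, rms = NA_real_))
  fit <- stats::lm.fit(X[ok, , drop = FALSE], U[ok])
  list(C = 2 * fit$coefficients[2],
       rms = sqrt(mean(fit$residuals^2)))
}

#' Displacement and base curvature, fixed-whisker experiment
#'
#' Per frame: subtract the reference profile, smooth on a sliding window
#' (default 10 pixels), and fit a third-order polynomial constrained to zero
#' slope at the base (rigid anchoring); the base curvature is twice the
#' quadratic coefficient.
#'
#' @param stack A [profile_stack()].
#' @param reference_profile Reference ordinates (m), one per column.
#' @param smooth_px Smoothing window width in pixels (default 10).
#' @param base_col Column index of the base (default 1).
#' @param fit_cols Columns used in the cubic fit. Defaults to the basal half
#'   of the profile: base curvature is a local quantity, and restricting the
#'   fit keeps it unbiased by the propagating deflection wave distal of
#'   mid-span (the quasi-static shapes are near-cubic there, so the
#'   restriction costs little).
#' @return A `displacement_result`: displacement matrix `U` (m) and a
#'   `curvature` data frame `t, C, residual` (class `curvature_trace`).
#' @export
displacement_fixed <- function(stack, reference_profile, smooth_px = 10,
                               base_col = 1, fit_cols = NULL) {
  stopifnot(inherits(stack, "profile_stack"))
  if (length(reference_profile) != ncol(stack$y))
    stop("reference profile does not match the column grid", call. = FALSE)
  if (is.null(fit_cols)) fit_cols <- seq_len(ceiling(ncol(stack$y) / 2))
  nt <- nrow(stack$y)
  U <- matrix(NA_real_, nt, ncol(stack$y))
  C <- numeric(nt); rms <- numeric(nt)
  for (i in seq_len(nt)) {
    u <- smooth_profile(stack$y[i, ] - reference_profile, smooth_px)
    U[i, ] <- u
    f <- fit_constrained_cubic(stack$x[fit_cols], u[fit_cols],
                               stack$x[base_col])
    C[i] <- f$C; rms[i] <- f$rms
  }
  curv <- data.frame(t = stack$t, C = C, residual = rms)
  class(curv) <- c("curvature_trace", "data.frame")
  structure(list(U = U, curvature = curv, x = stack$x),
            class = "displacement_result")
}

# sine fit y(t) = a sin(w t + ph) + c at one position; linear in (sin, cos)
# at fixed w, refined over w by nonlinear least squares
fit_sine <- function(t, y, f_init) {
  w0 <- 2 * pi * f_init
  lin <- function(w) {
    X <- cbind(sin(w * t), cos(w * t), 1)
    co <- stats::lm.fit(X, y)$coefficients
    list(a = sqrt(co[1]^2 + co[2]^2), ph = atan2(co[2], co[1]), c = co[3],
         rss = sum((y - X %*% co)^2))
  }
  l0 <- lin(w0)
  st <- list(a = unname(max(l0$a, 1e-12)), w = w0,
             ph = unname(l0$ph), c = unname(l0$c))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * sin(w * t + ph) + c, start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    c(a = unname(l0$a), w = w0, ph = unname(l0$ph), c = unname(l0$c))
  } else {
    co <- stats::coef(fit)
    if (co[["a"]] < 0) {  # canonical form: positive amplitude
      co[["a"]] <- -co[["a"]]; co[["ph"]] <- co[["ph"]] + pi
    }
    co[["ph"]] <- atan2(sin(co[["ph"]]), cos(co[["ph"]]))
    co
  }
}

#' Displacement and base curvature, whisking experiment
#'
#' Inertia-induced displacements during whisking are too small for simple
#' profile differencing, so each column's time series is referenced against
#' sinusoidal motion: a slow "twin" experiment (quasi-static rotation at e.g.
#' 0.5 Hz) gives the solid-rotation amplitude `a_slow(s)`; the air phase of
#' the fast experiment gives pulsation and phase `omega_fast(s), phi_fast(s)`.
#' The displacement is
#' `U(s, t) = y(s, t) - offset(s) - a_slow(s) sin(omega_fast(s) t + phi_fast(s))`,
#' then smoothed and fitted by the constrained cubic as in
#' [displacement_fixed()]. Columns whose sine fit fails are interpolated from
#' their neighbours and flagged.
#'
#' @param stack Fast-whisking [profile_stack()].
#' @param slow_stack Slow-reference [profile_stack()] on the same column grid.
#' @param air_window Time window `c(t0, t1)` of the fast stack free of
#'   contacts.
#' @param f_w Whisking frequency of the fast experiment (Hz).
#' @param f_slow Frequency of the slow reference (Hz).
#' @inheritParams displacement_fixed
#' @return A `displacement_result` (as in [displacement_fixed()]) with the
#'   per-column sine parameters attached as `"sine_fits"`.
#' @export
displacement_whisking <- function(stack, slow_stack, air_window, f_w = 15,
                                  f_slow = 0.5, smooth_px = 10, base_col = 1,
                                  fit_cols = NULL) {
  stopifnot(inherits(stack, "profile_stack"),
            inherits(slow_stack, "profile_stack"))
  if (ncol(stack$y) != ncol(slow_stack$y))
    stop("stacks must share the column grid", call. = FALSE)
  nc <- ncol(stack$y)
  in_air <- stack$t >= air_window[1] & stack$t <= air_window[2]
  if (sum(in_air) < 8) stop("air window too short", call. = FALSE)
  a_slow <- rep(NA_real_, nc); w_fast <- rep(NA_real_, nc)
  ph_fast <- rep(NA_real_, nc); off <- rep(NA_real_, nc)
  failed <- rep(FALSE, nc)
  for (j in seq_len(nc)) {
    ys <- slow_stack$y[, j]; yf <- stack$y[in_air, j]
    if (any(!is.finite(ys)) || any(!is.finite(yf))) { failed[j] <- TRUE; next }
    cs <- fit_sine(slow_stack$t, ys, f_slow)
    cf <- fit_sine(stack$t[in_air], yf, f_w)
    a_slow[j] <- cs[["a"]]; w_fast[j] <- cf[["w"]]
    ph_fast[j] <- cf[["ph"]]; off[j] <- cf[["c"]]
  }
  if (any(failed) && !all(failed)) {
    okc <- which(!failed)
    for (v in c("a_slow", "w_fast", "ph_fast", "off")) {
      val <- get(v)
      val[failed] <- stats::approx(okc, val[okc], xout = which(failed),
                                   rule = 2)$y
      assign(v, val)
    }
  }
  if (is.null(fit_cols)) fit_cols <- seq_len(ceiling(nc / 2))
  nt <- nrow(stack$y)
  U <- matrix(NA_real_, nt, nc)
  C <- numeric(nt); rms <- numeric(nt)
  for (i in seq_len(nt)) {
    model <- off + a_slow * sin(w_fast * stack$t[i] + ph_fast)
    u <- smooth_profile(stack$y[i, ] - model, smooth_px)
    U[i, ] <- u
    f <- fit_constrained_cubic(stack$x[fit_cols], u[fit_cols],
                               stack$x[base_col])
    C[i] <- f$C; rms[i] <- f$rms
  }
  curv <- data.frame(t = stack$t, C = C, residual = rms)
  class(curv) <- c("curvature_trace", "data.frame")
  structure(list(U = U, curvature = curv, x = stack$x,
                 sine_fits = data.frame(a_slow = a_slow, omega_fast = w_fast,
                                        phi_fast = ph_fast, offset = off,
                                        failed = failed)),
            class = "displacement_result")
}

#' Torque-curvature calibration
#'
#' Through-origin least-squares slope `K` of simultaneous base-torque and
#' base-curvature measurements over a quasi-static segment; the model
#' predicts `K = E pi b^4 / 4`.
#'
#' @param M_sensor A [torque_trace()] from the sensor.
#' @param C A `curvature_trace` (data frame with `t`, `C`), time-aligned.
#' @param spec Optional [whisker_spec()]; when given, the ratio
#'   `K / (E pi b^4 / 4)` is reported.
#' @return A `calibration` list: `K` (N m^2), `ratio` (or `NA`), `n`.
#' @export
calibrate_K <- function(M_sensor, C, spec = NULL) {
  stopifnot(inherits(M_sensor, "torque_trace"))
  Cv <- C$C
  if (length(Cv) != length(M_sensor$M))
    stop("torque and curvature traces must be time-aligned", call. = FALSE)
  ok <- is.finite(Cv) & is.finite(M_sensor$M)
  ssc <- sum(Cv[ok]^2)
  if (ssc <= 1e-12 * max(Cv[ok]^2, 1e-300) * sum(ok) || max(abs(Cv[ok])) == 0)
    stop("degenerate regression: curvature has no variation", call. = FALSE)
  K <- sum(M_sensor$M[ok] * Cv[ok]) / ssc
  structure(list(K = K,
                 ratio = if (is.null(spec)) NA_real_ else K / base_stiffness(spec),
                 n = sum(ok)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> K = %.4g N m^2 (ratio to E pi b^4/4: %.3g, n = %d)\n",
              x$K, x$ratio, x$n))
  invisible(x)
}

#' Track the contact-triggered deflection wave front
#'
#' The deflection at time `t` is the profile minus the profile at the shock
#' instant; the front is the position of the minimal deflection between the
#' contact point and the base, refined to sub-column precision by a parabolic
#' fit around the discrete minimum. The front's distance to the base
#' decreases linearly in time; the fitted speed is the wave velocity `V_w`.
#'
#' @param stack A [profile_stack()].
#' @param shock_time Time of the shock (s).
#' @param contact_col Column index of the contact point.
#' @param base_col Column index of the base (default 1).
#' @param min_depth_frac Frames whose minimal deflection is shallower than
#'   this fraction of the deepest observed deflection are dropped (front not
#'   yet formed or already absorbed).
#' @return A `wavefront_fit`: per-frame front positions and distances, the
#'   speed `V_w` (m/s), its standard error, and the `lm` fit.
#' @export
track_wavefront <- function(stack, shock_time, contact_col, base_col = 1,
                            min_depth_frac = 0.1) {
  stopifnot(inherits(stack, "profile_stack"))
  i0 <- which.min(abs(stack$t - shock_time))
  ref <- stack$y[i0, ]
  cols <- if (contact_col > base_col) base_col:contact_col
          else contact_col:base_col
  n <- nrow(stack$y)
  front_x <- rep(NA_real_, n); depth <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i <= i0) next
    defl <- stack$y[i, cols] - ref[cols]
    if (all(!is.finite(defl))) next
    jm <- which.min(defl)
    depth[i] <- defl[jm]
    # parabolic sub-column refinement
    xj <- stack$x[cols]
    if (jm > 1 && jm < length(cols) && all(is.finite(defl[(jm - 1):(jm + 1)]))) {
      y1 <- defl[jm - 1]; y2 <- defl[jm]; y3 <- defl[jm + 1]
      den <- y1 - 2 * y2 + y3
      sh <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
      sh <- max(min(sh, 0.5), -0.5)
      front_x[i] <- xj[jm] + sh * stack$pixel_size
    } else {
      front_x[i] <- xj[jm]
    }
  }
  deepest <- min(depth, na.rm = TRUE)
  use <- is.finite(front_x) & is.finite(depth) &
    depth <= min_depth_frac * deepest
  if (sum(use) < 3)
    stop("fewer than three usable frames to fit the wave front", call. = FALSE)
  dist <- abs(front_x - stack$x[base_col])
  tt <- stack$t[use]; dd <- dist[use]
  if (any(diff(dd) > 0.05 * max(dd)))
    warning("wave-front trajectory not monotone towards the base")
  fit <- stats::lm(dd ~ tt)
  # noiseless synthetic stacks give perfect fits; silence summary.lm's note
  se <- suppressWarnings(unname(summary(fit)$coefficients[2, 2]))
  structure(list(t = tt, front_x = front_x[use], distance = dd,
                 V_w = abs(unname(stats::coef(fit)[2])),
                 se = se,
                 fit = fit),
            class = "wavefront_fit")
}

#' @export
print.wavefront_fit <- function(x, ...) {
  cat(sprintf("<wavefront_fit> V_w = %.3g +/- %.2g m/s over %d frames\n",
              x$V_w, x$se, length(x$t)))
  invisible(x)
}

#' Write a curvature trace as CSV
#'
#' Columns `t_s, C_per_m, residual`.
#'
#' @param curv A `curvature_trace`.
#' @param path CSV path.
#' @export
write_curvature_trace <- function(curv, path) {
  utils::write.csv(data.frame(t_s = curv$t, C_per_m = curv$C,
                              residual = curv$residual),
                   path, row.names = FALSE)
  invisible(path)
}
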