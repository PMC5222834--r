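# Closed-form quasi-static solutions of (s^4 U'')'' = 0 for the two shock
# geometries. Dimensionless profile shapes g(s) are defined so that
# U_qs(s, t) = A t g(s) with A = V (fixed) or L gamma (rotating).

qs_shape_fixed <- function(s, epsilon) {
  epsilon * (1 - s)^2 * (epsilon - 3 * s + 2 * s * epsilon) /
    (2 * (epsilon - 1)^3 * s^2)
}

qs_shape_rotating <- function(s, epsilon) {
  (s - 1) * (2 * s^2 + epsilon^2 * (1 + s) - epsilon * s * (3 + s)) /
    (2 * (1 - epsilon)^2 * s^2)
}

check_epsilon <- function(epsilon) {
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("epsilon must lie strictly in (0, 1)", call. = FALSE)
}

#' Quasi-static deflection profile, fixed-whisker shock
#'
#' Equilibrium small-deflection shape of the cone clamped at the base
#' (`U(1) = 0`, `U'(1) = 0`) and indented by `indentation` at the contact
#' point (`U(eps) = indentation`, `U''(eps) = 0`). The profile solves
#' `(s^4 U'')'' = 0` exactly.
#'
#' @param spec A [whisker_spec()].
#' @param epsilon Contact coordinate in (0, 1).
#' @param indentation Object displacement `V t` in metres.
#' @param s_grid Dimensionless sample points in `[epsilon, 1]`; defaults to a
#'   uniform 201-point grid.
#' @return A `qs_solution`: list with `s`, `U` (metres), `epsilon`, `mode` and
#'   `base_torque_rate` (N m per metre of indentation).
#' @export
qs_profile_fixed <- function(spec, epsilon, indentation, s_grid = NULL) {
  stop_if_not_spec(spec); check_epsilon(epsilon)
  if (is.null(s_grid)) s_grid <- seq(epsilon, 1, length.out = 201)
  if (any(s_grid < epsilon - 1e-12) || any(s_grid > 1 + 1e-12))
    stop("s_grid must lie within [epsilon, 1]", call. = FALSE)
  structure(list(s = s_grid,
                 U = indentation * qs_shape_fixed(s_grid, epsilon),
                 epsilon = epsilon, mode = "fixed",
                 base_torque_rate = qs_torque_rate_fixed(
                   spec, contact_distance_unchecked(spec, epsilon))),
            class = "qs_solution")
}

#' Quasi-static deflection profile, rotating-whisker shock
#'
#' Equilibrium shape when the base is rotated by `angle` against an object
#' held fixed at `s = epsilon`: `U(1) = 0`, `U'(1) = L * angle` (base slope in
#' `s`), `U(eps) = 0`, `U''(eps) = 0`.
#'
#' @inheritParams qs_profile_fixed
#' @param angle Base rotation `gamma t` in radians.
#' @return A `qs_solution` with `base_torque_rate` in N m per radian.
#' @export
qs_profile_rotating <- function(spec, epsilon, angle, s_grid = NULL) {
  stop_if_not_spec(spec); check_epsilon(epsilon)
  if (is.null(s_grid)) s_grid <- seq(epsilon, 1, length.out = 201)
  if (any(s_grid < epsilon - 1e-12) || any(s_grid > 1 + 1e-12))
    stop("s_grid must lie within [epsilon, 1]", call. = FALSE)
  L <- spec$untruncated_length
  structure(list(s = s_grid,
                 U = L * angle * qs_shape_rotating(s_grid, epsilon),
                 epsilon = epsilon, mode = "rotating",
                 base_torque_rate = qs_torque_rate_rotating(
                   spec, contact_distance_unchecked(spec, epsilon))),
            class = "qs_solution")
}

# d for a given epsilon without the tip_coord guard (profiles are defined for
# any epsilon in (0,1), including inside the truncated part)
contact_distance_unchecked <- function(spec, epsilon) {
  spec$untruncated_length * (1 - epsilon)
}

check_d <- function(spec, d) {
  L <- spec$untruncated_length
  if (any(!is.finite(d)) || any(d <= 0))
    stop("d must be positive", call. = FALSE)
  if (any(d > L * (1 + 1e-12)))
    stop("contact beyond the virtual tip: require d <= L", call. = FALSE)
}

#' Quasi-static base-torque rates
#'
#' Rate of change of the quasi-static base torque with the drive:
#' `dM_qs/d(Vt) = (3 E pi b^4 / 4) (1/d^2 - alpha/(d b))` for the
#' fixed-whisker shock (N m per metre of indentation) and
#' `dM_qs/dphi = (3 E pi b^4 / 4) (1/d - alpha/b)` for the rotating one
#' (N m per radian). Both are positive, strictly decreasing in `d`, and vanish
#' at `d = L` where the contact reaches the virtual tip.
#'
#' @inheritParams qs_profile_fixed
#' @param d Radial contact distance in metres, `0 < d <= L` (vectorised).
#' @return Torque rate (see units above).
#' @export
qs_torque_rate_fixed <- function(spec, d) {
  stop_if_not_spec(spec); check_d(spec, d)
  3 * base_stiffness(spec) * (1 / d^2 - spec$conicity / (d * spec$base_radius))
}

#' @rdname qs_torque_rate_fixed
#' @export
qs_torque_rate_rotating <- function(spec, d) {
  stop_if_not_spec(spec); check_d(spec, d)
  3 * base_stiffness(spec) * (1 / d - spec$conicity / spec$base_radius)
}

#' Dimensionless master curve of the quasi-static rate
#'
#' All whiskers collapse onto `f(x) = 1/x^2 - 1/x` when the fixed-mode torque
#' rate is rescaled by `4 / (3 E pi (alpha b)^2)` and `d` by `L`: the
#' identity `(b/alpha)^2 (1/d^2 - alpha/(d b)) = 1/x^2 - 1/x` with `x = d/L`
#' is exact when `L = b/alpha`.
#'
#' @param x Dimensionless distance `d / L` in `(0, 1]` (vectorised).
#' @return `1/x^2 - 1/x`, non-negative, zero only at `x = 1`.
#' @export
master_curve <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 1))
    stop("x = d/L must lie in (0, 1]", call. = FALSE)
  1 / x^2 - 1 / x
}

#' Base curvature per unit protraction angle
#'
#' For a rotating whisker pressed against a fixed object at distance `d`, the
#' base curvature grows linearly with the protraction angle `phi` with slope
#' `C / phi = 3 (1/d - alpha/b)`, i.e. the rotating torque rate divided by
#' `E pi b^4 / 4`.
#'
#' @inheritParams qs_torque_rate_fixed
#' @return Slope in m^-1 rad^-1.
#' @export
curvature_angle_slope <- function(spec, d) {
  stop_if_not_spec(spec); check_d(spec, d)
  3 * (1 / d - spec$conicity / spec$base_radius)
}

#' Radial localisation from a measured quasi-static torque rate
#'
#' Inverts the monotone maps of [qs_torque_rate_fixed()] /
#' [qs_torque_rate_rotating()] by bracketed bisection on
#' `(1e-6 L, L (1 - 1e-9))`: a measured rate maps to a unique radial
#' distance `d`.
#'
#' @inheritParams qs_profile_fixed
#' @param measured_rate Observed torque rate (units of the chosen mode).
#' @param mode `"fixed"` or `"rotating"`.
#' @return Radial distance `d` in metres.
#' @export
locate_radial <- function(spec, measured_rate, mode = c("fixed", "rotating")) {
  stop_if_not_spec(spec)
  mode <- match.arg(mode)
  ratef <- switch(mode, fixed = qs_torque_rate_fixed,
                  rotating = qs_torque_rate_rotating)
  L <- spec$untruncated_length
  lo <- 1e-6 * L; hi <- L * (1 - 1e-9)
  if (!is.finite(measured_rate) || measured_rate <= 0 ||
      measured_rate >= ratef(spec, lo) || measured_rate <= ratef(spec, hi))
    stop("measured rate outside the attainable open range for this mode",
         call. = FALSE)
  f <- function(d) ratef(spec, d) - measured_rate
  stats::uniroot(f, c(lo, hi), tol = 1e-14 * L)$root
}
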