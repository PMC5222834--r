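#' Whisker specification
#'
#' A whisker is modelled as a truncated elastic cone with no intrinsic
#' curvature, characterised by its base radius `b`, conicity (half opening
#' angle) `alpha`, Young's modulus `E`, mass density `rho` and modal damping
#' ratio `zeta`. The untruncated length is `L = b / alpha`; the dimensionless
#' curvilinear coordinate `s` runs from 0 at the virtual (untruncated) tip to
#' 1 at the base, and the physical tip sits at `s = tip_coord`.
#'
#' @param base_radius Base radius `b` in metres.
#' @param conicity Cone half-angle `alpha` in radians.
#' @param young_modulus Young's modulus `E` in pascals.
#' @param density Mass density `rho` in kg m^-3.
#' @param damping Dimensionless damping ratio `zeta` in (0, 1).
#' @param untruncated_length Optional untruncated length `L` in metres. When
#'   omitted it is recomputed as `b / alpha`; when supplied it must agree with
#'   `b / alpha` to within 5%.
#' @param tip_coord Dimensionless coordinate of the physical tip, in `[0, 1)`.
#'   The free-whisking results are weakly sensitive to this truncation because
#'   the `s^2` mass weighting suppresses the tip; 0.05 is the default.
#' @param name Optional label.
#' @return An object of class `whisker_spec`.
#' @seealso [whisker_preset()] for the two laboratory whiskers.
#' @export
whisker_spec <- function(base_radius, conicity, young_modulus, density,
                         damping = 0.041, untruncated_length = NULL,
                         tip_coord = 0.05, name = NULL) {
  vals <- c(base_radius, conicity, young_modulus, density, damping, tip_coord)
  if (any(!is.finite(vals)))
    stop("whisker parameters must be finite numbers", call. = FALSE)
  if (base_radius <= 0 || conicity <= 0 || young_modulus <= 0 || density <= 0)
    stop("b, alpha, E and rho must all be positive", call. = FALSE)
  if (damping <= 0 || damping >= 1)
    stop("damping ratio zeta must lie strictly in (0, 1)", call. = FALSE)
  if (tip_coord < 0 || tip_coord >= 1)
    stop("tip_coord must lie in [0, 1)", call. = FALSE)
  L0 <- base_radius / conicity
  if (is.null(untruncated_length)) {
    untruncated_length <- L0
  } else if (abs(untruncated_length - L0) > 0.05 * L0) {
    stop(sprintf("untruncated_length %.4g inconsistent with b/alpha = %.4g (>5%%)",
                 untruncated_length, L0), call. = FALSE)
  }
  structure(
    list(base_radius = base_radius, conicity = conicity,
         untruncated_length = untruncated_length,
         young_modulus = young_modulus, density = density,
         damping = damping, tip_coord = tip_coord, name = name),
    class = "whisker_spec")
}

#' Laboratory whisker presets
#'
#' Geometrical and mechanical properties of the polyurethane artificial
#' whisker and the rat C1 whisker used throughout: base radius, conicity,
#' Young's modulus and density, with damping ratio 0.041 for both.
#'
#' @param name `"artificial"` or `"real"`.
#' @param ... Overrides passed on to [whisker_spec()] (e.g. `tip_coord`).
#' @return A `whisker_spec`.
#' @export
whisker_preset <- function(name = c("artificial", "real"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    artificial = list(base_radius = 600e-6, conicity = 8.1e-3,
                      young_modulus = 1.19e9, density = 1140),
    real = list(base_radius = 88e-6, conicity = 1.8e-3,
                young_modulus = 3.3e9, density = 1100))
  do.call(whisker_spec, c(args, list(damping = 0.041, name = name), list(...)))
}

#' @export
print.whisker_spec <- function(x, ...) {
  cat(sprintf("<whisker_spec%s>\n", if (is.null(x$name)) "" else paste0(": ", x$name)))
  cat(sprintf("  b = %.3g m, alpha = %.3g rad, L = %.3g m\n",
              x$base_radius, x$conicity, x$untruncated_length))
  cat(sprintf("  E = %.3g Pa, rho = %.3g kg/m^3, zeta = %.3g, s_tip = %.3g\n",
              x$young_modulus, x$density, x$damping, x$tip_coord))
  invisible(x)
}

stop_if_not_spec <- function(spec) {
  if (!inherits(spec, "whisker_spec"))
    stop("expected a 'whisker_spec' object", call. = FALSE)
  invisible(spec)
}

#' Resonance timescale of the isolated whisker
#'
#' `k = 2 (L / alpha) sqrt(rho / E)`, the timescale that sets the mechanical
#' resonances of the cone: all dimensionless eigenvalues `lambda_i` convert to
#' angular frequencies as `omega_i = lambda_i / k`.
#'
#' @param spec A [whisker_spec()].
#' @return Timescale in seconds.
#' @export
timescale_k <- function(spec) {
  stop_if_not_spec(spec)
  2 * (spec$untruncated_length / spec$conicity) *
    sqrt(spec$density / spec$young_modulus)
}

#' Base bending stiffness E I(1)
#'
#' Flexural rigidity at the base, `E * pi * b^4 / 4`, the proportionality
#' constant between base torque and base curvature.
#'
#' @inheritParams timescale_k
#' @return Stiffness in N m^2.
#' @export
base_stiffness <- function(spec) {
  stop_if_not_spec(spec)
  spec$young_modulus * pi * spec$base_radius^4 / 4
}

#' Base torque from base curvature
#'
#' The planar base torque is `M = E I(1) C` with `I(1) = pi b^4 / 4` and `C`
#' the base curvature (in m^-1) in the small-deflection limit. Exactly linear
#' in `C`.
#'
#' @inheritParams timescale_k
#' @param curvature Base curvature in m^-1 (vectorised).
#' @return Torque in N m.
#' @export
torque_from_base_curvature <- function(spec, curvature) {
  stop_if_not_spec(spec)
  if (any(!is.finite(curvature)))
    stop("curvature must be finite", call. = FALSE)
  base_stiffness(spec) * curvature
}

#' Contact coordinate from radial distance (and back)
#'
#' An object contacting the whisker at radial distance `d` from the base sits
#' at dimensionless coordinate `epsilon = 1 - d / L`. `contact_distance()` is
#' the exact inverse.
#'
#' @inheritParams timescale_k
#' @param d Radial distance from the base in metres, in `(0, L (1 - s_tip))`.
#' @return Dimensionless `epsilon` in `(s_tip, 1)`.
#' @export
contact_coordinate <- function(spec, d) {
  stop_if_not_spec(spec)
  L <- spec$untruncated_length
  if (any(d <= 0) || any(d >= L * (1 - spec$tip_coord)))
    stop("contact distance d must lie within the whisker: 0 < d < L(1 - s_tip)",
         call. = FALSE)
  1 - d / L
}

#' @rdname contact_coordinate
#' @param epsilon Dimensionless contact coordinate in `(s_tip, 1)`.
#' @export
contact_distance <- function(spec, epsilon) {
  stop_if_not_spec(spec)
  if (any(epsilon <= spec$tip_coord) || any(epsilon >= 1))
    stop("epsilon must lie strictly in (s_tip, 1)", call. = FALSE)
  spec$untruncated_length * (1 - epsilon)
}

#' Shock contact configuration
#'
#' Describes one quasi point-like contact: its dimensionless location
#' `epsilon` and the drive, either a translation speed `V` of the object
#' against a fixed whisker, or a constant angular rate `gamma` of a rotating
#' whisker against a fixed object. Exactly one of `speed` / `angular_rate`
#' must be given and must match `mode`.
#'
#' @param epsilon Contact coordinate in `(s_tip, 1)`.
#' @param speed Object speed `V` in m/s (fixed-whisker mode).
#' @param angular_rate Whisker angular velocity `gamma` in rad/s (rotating mode).
#' @param mode `"fixed"` or `"rotating"`.
#' @param spec Optional [whisker_spec()] used to validate `epsilon` against
#'   `tip_coord`.
#' @return An object of class `contact_config`.
#' @export
contact_config <- function(epsilon, speed = NULL, angular_rate = NULL,
                           mode = c("fixed", "rotating"), spec = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (is.null(speed) || !is.null(angular_rate)))
    stop("fixed mode takes 'speed' only", call. = FALSE)
  if (mode == "rotating" && (is.null(angular_rate) || !is.null(speed)))
    stop("rotating mode takes 'angular_rate' only", call. = FALSE)
  lo <- if (is.null(spec)) 0 else spec$tip_coord
  if (epsilon <= lo || epsilon >= 1)
    stop("epsilon must lie strictly inside (s_tip, 1)", call. = FALSE)
  structure(list(epsilon = epsilon, speed = speed,
                 angular_rate = angular_rate, mode = mode),
            class = "contact_config")
}

#' Read and write whisker specifications as flat JSON
#'
#' Serialises a whisker as a flat key-value JSON object with keys
#' `base_radius_m`, `conicity_rad`, `young_modulus_pa`, `density_kg_m3`,
#' `damping` and `tip_coord`.
#'
#' @inheritParams timescale_k
#' @param path File path.
#' @return `read_whisker_spec()` returns a `whisker_spec`;
#'   `write_whisker_spec()` returns `path` invisibly.
#' @export
write_whisker_spec <- function(spec, path) {
  stop_if_not_spec(spec)
  jsonlite::write_json(
    list(base_radius_m = spec$base_radius, conicity_rad = spec$conicity,
         young_modulus_pa = spec$young_modulus, density_kg_m3 = spec$density,
         damping = spec$damping, tip_coord = spec$tip_coord),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_whisker_spec
#' @export
read_whisker_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  whisker_spec(base_radius = x$base_radius_m, conicity = x$conicity_rad,
               young_modulus = x$young_modulus_pa, density = x$density_kg_m3,
               damping = x$damping, tip_coord = x$tip_coord)
}

#' Base-torque time series
#'
#' A uniformly sampled base-torque trace with optional event annotations
#' (e.g. contact onsets). Events must fall within the time span.
#'
#' @param t Time grid in seconds, strictly increasing and uniform.
#' @param M Base torque samples in N m, same length as `t`.
#' @param events Optional `data.frame` with columns `label` and `time`.
#' @return An object of class `torque_trace` with fields `t`, `M`, `events`
#'   and the sampling rate `fs`.
#' @export
torque_trace <- function(t, M, events = NULL) {
  if (length(t) != length(M)) stop("t and M must have equal length", call. = FALSE)
  if (length(t) < 2) stop("need at least two samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("t must be strictly increasing and uniform", call. = FALSE)
  if (is.null(events)) {
    events <- data.frame(label = character(), time = numeric())
  } else {
    events <- as.data.frame(events)
    stopifnot(all(c("label", "time") %in% names(events)))
    if (nrow(events) && (any(events$time < t[1]) || any(events$time > t[length(t)])))
      stop("event times must lie within the trace", call. = FALSE)
  }
  structure(list(t = t, M = M, events = events, fs = 1 / dt[1]),
            class = "torque_trace")
}

#' @export
print.torque_trace <- function(x, ...) {
  cat(sprintf("<torque_trace> %d samples at %.6g Hz, t in [%.4g, %.4g] s, %d event(s)\n",
              length(x$t), x$fs, x$t[1], x$t[length(x$t)], nrow(x$events)))
  invisible(x)
}

#' Read and write torque traces as CSV
#'
#' The trace itself is written with header `t_s,M_Nm`; events go to a sidecar
#' CSV with header `label,time_s` (default: same path with an `_events.csv`
#' suffix).
#'
#' @param trace A [torque_trace()].
#' @param path CSV path for the trace.
#' @param events_path CSV path for the events sidecar.
#' @return `read_torque_trace()` returns a `torque_trace`.
#' @export
write_torque_trace <- function(trace, path,
                               events_path = sub("\\.csv$", "_events.csv", path)) {
  stopifnot(inherits(trace, "torque_trace"))
  df <- data.frame(t_s = trace$t, M_Nm = trace$M)
  utils::write.csv(df, path, row.names = FALSE)
  ev <- data.frame(label = trace$events$label, time_s = trace$events$time)
  utils::write.csv(ev, events_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_torque_trace
#' @export
read_torque_trace <- function(path,
                              events_path = sub("\\.csv$", "_events.csv", path)) {
  df <- utils::read.csv(path)
  ev <- NULL
  if (file.exists(events_path)) {
    e <- utils::read.csv(events_path, colClasses = c("character", "numeric"))
    ev <- data.frame(label = e$label, time = e$time_s)
  }
  torque_trace(df$t_s, df$M_Nm, events = ev)
}
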