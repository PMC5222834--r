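# Seeded generators for the three experiment types: noisy base-torque traces
# and rendered high-speed frames of a bright whisker on a dark background,
# always shipped with their noiseless ground truth.

#' Experiment recipe
#'
#' Bundles a whisker, a protocol and the sensor/camera constants into a
#' reproducible generator input. Torque noise defaults to the 1 uN m sensor
#' resolution; the camera pixel defaults to 60 um.
#'
#' @param kind `"fixed_shock"`, `"rotating_shock"` or `"whisking_approach"`.
#' @param whisker A [whisker_spec()] or preset name.
#' @param seed Mandatory integer seed.
#' @param epsilon Contact coordinate (shock kinds).
#' @param speed Shock speed `V` in m/s (`fixed_shock`) or object approach
#'   speed (`whisking_approach`).
#' @param angular_rate `gamma` in rad/s (`rotating_shock`).
#' @param f_w,phi0 Whisking frequency (Hz) and amplitude (rad).
#' @param H Base-to-trajectory distance (m), whisking kind.
#' @param y_stop Object stop position (m), whisking kind.
#' @param duration Simulated duration (s).
#' @param sample_rate Torque sampling rate (Hz).
#' @param sigma_n Torque noise s.d. (N m).
#' @param pixel_size Camera pixel (m).
#' @param frame_rate Camera frame rate (Hz).
#' @param image_height Frame height in pixels.
#' @param camera_snr Ridge peak over pixel-noise s.d.
#' @param n_cycles Whisking cycles (whisking kind).
#' @return An `experiment_recipe`.
#' @export
experiment_recipe <- function(kind = c("fixed_shock", "rotating_shock",
                                       "whisking_approach"),
                              whisker = "artificial", seed,
                              epsilon = NULL, speed = NULL, angular_rate = NULL,
                              f_w = 15, phi0 = 10 * pi / 180, H = NULL,
                              y_stop = NULL, duration = 0.01,
                              sample_rate = 25000, sigma_n = 1e-6,
                              pixel_size = 60e-6, frame_rate = 10000,
                              image_height = 160, camera_snr = 20,
                              n_cycles = 3) {
  kind <- match.arg(kind)
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory", call. = FALSE)
  spec <- if (inherits(whisker, "whisker_spec")) whisker else whisker_preset(whisker)
  if (kind %in% c("fixed_shock", "rotating_shock")) {
    if (is.null(epsilon)) stop("shock recipes need epsilon", call. = FALSE)
    if (kind == "fixed_shock" && is.null(speed))
      stop("fixed_shock needs speed", call. = FALSE)
    if (kind == "rotating_shock" && is.null(angular_rate))
      stop("rotating_shock needs angular_rate", call. = FALSE)
  } else {
    if (is.null(H)) stop("whisking_approach needs H", call. = FALSE)
    if (is.null(speed)) speed <- 0.05
    if (is.null(y_stop)) y_stop <- H * tan(phi0 / 2)
  }
  structure(list(kind = kind, spec = spec, seed = as.integer(seed),
                 epsilon = epsilon, speed = speed, angular_rate = angular_rate,
                 f_w = f_w, phi0 = phi0, H = H, y_stop = y_stop,
                 duration = duration, sample_rate = sample_rate,
                 sigma_n = sigma_n, pixel_size = pixel_size,
                 frame_rate = frame_rate, image_height = image_height,
                 camera_snr = camera_snr, n_cycles = n_cycles),
            class = "experiment_recipe")
}

#' Named default recipes
#'
#' `"fig6_shock"`: artificial whisker, fixed shock at `epsilon = 0.44`,
#' `V = 0.689` m/s, sampled at 25 kHz. `"fig8_whisking"`: real whisker
#' whisking at 15 Hz / 10 deg while the object approaches at the mid
#' separation `H = 2.60` cm (override with `H`).
#'
#' @param name Recipe name.
#' @param seed Mandatory seed.
#' @param ... Overrides passed to [experiment_recipe()].
#' @export
recipe_preset <- function(name = c("fig6_shock", "fig8_whisking"), seed, ...) {
  name <- match.arg(name)
  args <- switch(name,
    fig6_shock = list(kind = "fixed_shock", whisker = "artificial",
                      epsilon = 0.44, speed = 0.689, duration = 0.01,
                      sample_rate = 25000, frame_rate = 25000),
    fig8_whisking = list(kind = "whisking_approach", whisker = "real",
                         H = 0.026, f_w = 15, phi0 = 10 * pi / 180,
                         sample_rate = 20000, n_cycles = 4))
  over <- list(...)
  args[names(over)] <- over
  do.call(experiment_recipe, c(args, list(seed = seed)))
}

#' Contact geometry of the whisking experiment
#'
#' An object at horizontal distance `H` from the whisker base, met at
#' protraction angle `phi`, sits at radial distance `d = H / cos(phi)` along
#' the whisker, i.e. at `epsilon = 1 - H / (L cos(phi))`. The contact is
#' reachable when `d` lies within the truncated cone.
#'
#' @param spec A [whisker_spec()].
#' @param H Base-to-trajectory distance (m).
#' @param phi Protraction angle at contact (rad), `|phi| < pi/2`.
#' @return `list(d =, epsilon =, reachable =)`.
#' @export
whisking_geometry <- function(spec, H, phi) {
  stop_if_not_spec(spec)
  if (any(abs(phi) >= pi / 2)) stop("|phi| must be below pi/2", call. = FALSE)
  d <- H / cos(phi)
  L <- spec$untruncated_length
  reachable <- d < L * (1 - spec$tip_coord)
  list(d = d, epsilon = 1 - d / L, reachable = reachable)
}

#' Generate a noisy base-torque trace with ground truth
#'
#' Runs the deterministic mechanical simulation for the recipe's experiment
#' kind and adds i.i.d. Gaussian sensor noise of s.d. `sigma_n`. The
#' noiseless trace, the event list and the underlying response object are
#' returned as ground truth; with `sigma_n = 0` the trace is bit-identical
#' to the simulation.
#'
#' @param recipe An [experiment_recipe()].
#' @return `list(trace =, truth = list(trace_clean =, events =, response =))`.
#' @export
gen_torque_trace <- function(recipe) {
  stopifnot(inherits(recipe, "experiment_recipe"))
  spec <- recipe$spec
  if (recipe$kind == "whisking_approach") {
    tr <- whisking_contact_sim(spec, recipe$f_w, recipe$phi0,
                               object = list(H = recipe$H,
                                             approach_speed = recipe$speed,
                                             y_stop = recipe$y_stop),
                               n_cycles = recipe$n_cycles,
                               fs = recipe$sample_rate)
    resp <- NULL
  } else {
    t_grid <- seq(0, recipe$duration, by = 1 / recipe$sample_rate)
    contact <- if (recipe$kind == "fixed_shock")
      contact_config(recipe$epsilon, speed = recipe$speed, mode = "fixed",
                     spec = spec)
    else
      contact_config(recipe$epsilon, angular_rate = recipe$angular_rate,
                     mode = "rotating", spec = spec)
    resp <- shock_response(spec, contact, t_grid)
    tr <- torque_trace(t_grid, resp$M_total,
                       events = data.frame(label = "contact", time = 0))
  }
  set.seed(recipe$seed)
  noisy <- torque_trace(tr$t, tr$M + stats::rnorm(length(tr$M),
                                                  sd = recipe$sigma_n),
                        events = tr$events)
  list(trace = noisy,
       truth = list(trace_clean = tr, events = tr$events, response = resp))
}

#' Render whisker centerlines as bright-ridge frames
#'
#' Low-level renderer shared by [render_stack()] and the recovery tests: each
#' frame draws the centerline `y[i, ]` as an anti-aliased bright ridge with a
#' Gaussian cross-section (~2 px) on a dark background, plus Gaussian pixel
#' noise of s.d. `peak / snr`.
#'
#' @param y Matrix `n_frames x n_columns` of centerline ordinates (m).
#' @param pixel_size Pixel size (m).
#' @param image_height Rows per frame.
#' @param peak Ridge peak intensity.
#' @param snr Peak over noise s.d.; `Inf` for noiseless frames.
#' @param ridge_sigma_px Ridge cross-section s.d. in pixels.
#' @param seed Seed for the pixel noise.
#' @return 3-d array `frame x row x column`.
#' @export
render_frames <- function(y, pixel_size, image_height = 160, peak = 1,
                          snr = 20, ridge_sigma_px = 2, seed = 1) {
  stopifnot(is.matrix(y))
  nt <- nrow(y); nc <- ncol(y)
  rows <- seq_len(image_height)
  frames <- array(0, dim = c(nt, image_height, nc))
  set.seed(seed)
  for (i in seq_len(nt)) {
    rowpos <- y[i, ] / pixel_size + 1
    img <- peak * exp(-0.5 * outer(rows, rowpos, "-")^2 / ridge_sigma_px^2)
    if (is.finite(snr)) img <- img + stats::rnorm(length(img), sd = peak / snr)
    frames[i, , ] <- img
  }
  frames
}

#' Render a synthetic high-speed recording with ground truth
#'
#' Simulates the recipe's displacement field, converts it to centerline
#' ordinates on the camera's column grid, optionally box-averages over the
#' exposure time (the exposure equals the frame interval), and renders
#' frames with [render_frames()]. Frame count is exactly
#' `duration x frame_rate`.
#'
#' @param recipe An [experiment_recipe()] of a shock kind.
#' @param y_offset Rest position of the whisker in the frame (m); defaults to
#'   mid-height.
#' @param exposure_subsamples Sub-instants box-averaged per frame (default 2;
#'   1 disables exposure blur).
#' @return `list(frames =, t =, truth = list(y =, response =, M =))`.
#' @export
render_stack <- function(recipe, y_offset = NULL, exposure_subsamples = 2) {
  stopifnot(inherits(recipe, "experiment_recipe"))
  if (!recipe$kind %in% c("fixed_shock", "rotating_shock"))
    stop("render_stack supports the shock kinds", call. = FALSE)
  spec <- recipe$spec
  if (is.null(y_offset))
    y_offset <- (recipe$image_height / 2) * recipe$pixel_size
  nframes <- round(recipe$duration * recipe$frame_rate)
  t_frames <- (seq_len(nframes) - 1) / recipe$frame_rate
  d <- contact_distance(spec, recipe$epsilon)
  x <- seq(0, d, by = recipe$pixel_size)           # base at column 1
  s_out <- 1 - x / spec$untruncated_length
  s_out[1] <- 1
  contact <- if (recipe$kind == "fixed_shock")
    contact_config(recipe$epsilon, speed = recipe$speed, mode = "fixed",
                   spec = spec)
  else
    contact_config(recipe$epsilon, angular_rate = recipe$angular_rate,
                   mode = "rotating", spec = spec)
  nsub <- max(1, exposure_subsamples)
  t_fine <- as.vector(outer((seq_len(nsub) - 1) / (nsub * recipe$frame_rate),
                            t_frames, "+"))
  resp <- shock_response(spec, contact, t_fine[order(t_fine)])
  Uf <- displacement_field(resp, s_out)
  idx <- matrix(seq_along(t_fine), nrow = nsub)
  y_true <- t(apply(idx, 2, function(ii) colMeans(Uf[ii, , drop = FALSE])))
  y <- y_true + y_offset
  frames <- render_frames(y, recipe$pixel_size, recipe$image_height,
                          snr = recipe$camera_snr, seed = recipe$seed + 1L)
  # torque ground truth at the frame instants, same modal content as the
  # rendered field
  resp_frames <- shock_response(spec, contact, t_frames,
                                n_modes = ncol(resp$q))
  list(frames = frames, t = t_frames,
       truth = list(y = y, x = x, response = resp_frames,
                    M = resp_frames$M_total))
}

#' Read and write image stacks as numbered PNG frames
#'
#' Frames are written as `frame_0001.png, ...` (intensities clipped to
#' `[0, 1]`) with a JSON metadata file `{pixel_size_m, frame_rate_hz,
#' shock_frame}`.
#'
#' @param frames 3-d array `frame x row x column`.
#' @param dir Output directory.
#' @param pixel_size,frame_rate Camera constants.
#' @param shock_frame Index of the shock frame.
#' @export
write_image_stack <- function(frames, dir, pixel_size, frame_rate,
                              shock_frame = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(dim(frames)[1])) {
    img <- pmin(pmax(frames[i, , ], 0), 1)
    png::writePNG(img, file.path(dir, sprintf("frame_%04d.png", i)))
  }
  jsonlite::write_json(list(pixel_size_m = pixel_size,
                            frame_rate_hz = frame_rate,
                            shock_frame = shock_frame),
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  imgs <- lapply(files, png::readPNG)
  frames <- array(0, dim = c(length(imgs), nrow(imgs[[1]]), ncol(imgs[[1]])))
  for (i in seq_along(imgs)) frames[i, , ] <- imgs[[i]]
  list(frames = frames, pixel_size = meta$pixel_size_m,
       frame_rate = meta$frame_rate_hz, shock_frame = meta$shock_frame)
}
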