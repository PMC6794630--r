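# Synthetic dextran influx assay and fluorescence rendering.
#
# The assay: medium carrying 10 uM fluorescent dextran (3 or 40 kDa) fills
# the bEC barrier MC at t = 0; tracer crosses the endothelial monolayer
# (membrane conductance set from the ground-truth permeability) into the
# collagen scaffold and is imaged every 5 min. Rendering maps concentration
# to pixel intensity linearly (gain, background) with optional Poisson shot
# noise and additive Gaussian read noise.

#' Ground truth for one synthetic dextran assay
#'
#' @param P_true_cm_s True monolayer permeability, cm/s (>= 0).
#' @param solute Solute name or [solute()]; default `"dextran_40kda"`.
#' @param luminal_concentration_mol_m3 Initial luminal tracer concentration;
#'   default 1e-2 mol m^-3 (= 10 uM).
#' @param layout Device layout; default [build_default_layout()].
#' @param frame_interval_s Frame clock, s; default 300 (every 5 min).
#' @param n_frames Number of frames; default 25 (covers 2 h).
#' @param seed Integer seed recorded with the device.
#' @return An object of class `bbb_assay_truth`.
#' @export
assay_ground_truth <- function(P_true_cm_s,
                               solute = "dextran_40kda",
                               luminal_concentration_mol_m3 = 1e-2,
                               layout = build_default_layout(),
                               frame_interval_s = 300,
                               n_frames = 25,
                               seed = 1L) {
  if (P_true_cm_s < 0) stop("P_true_cm_s must be >= 0", call. = FALSE)
  if (luminal_concentration_mol_m3 <= 0)
    stop("luminal concentration must be > 0", call. = FALSE)
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0",
                                  call. = FALSE)
  if (n_frames < 2) stop("need at least 2 frames", call. = FALSE)
  solute_name <- if (inherits(solute, "bbb_solute")) solute$name else solute
  structure(list(P_true_cm_s = P_true_cm_s, solute_name = solute_name,
                 luminal_concentration_mol_m3 = luminal_concentration_mol_m3,
                 layout = layout, frame_interval_s = frame_interval_s,
                 n_frames = n_frames, seed = as.integer(seed)),
            class = "bbb_assay_truth")
}

#' Simulate a dextran influx assay with known permeability
#'
#' Initial condition: the luminal concentration uniformly in
#' `bec_barrier_mc`, zero elsewhere; the monolayer conductance is set to
#' `P_true_cm_s / 100` m/s; snapshots are stored on the frame clock.
#' Deterministic.
#'
#' @param truth A [assay_ground_truth()].
#' @param dx_um Grid spacing, default 50.
#' @param method Integrator, default `"explicit"`.
#' @param dt Optional time step override, s.
#' @return A `bbb_history` with snapshots at the frame times.
#' @export
simulate_dextran_assay <- function(truth, dx_um = 50,
                                   method = c("explicit", "implicit"),
                                   dt = NULL) {
  method <- match.arg(method)
  cfg <- simulation_config(
    layout = truth$layout, solute = truth$solute_name,
    t_end = (truth$n_frames - 1L) * truth$frame_interval_s,
    dx_um = dx_um, dt = dt,
    initial_values = list(
      bec_barrier_mc = truth$luminal_concentration_mol_m3),
    snapshot_interval = truth$frame_interval_s,
    method = method,
    membrane_conductance = truth$P_true_cm_s / 100)
  run_simulation(cfg)
}

#' Define an imaging model
#'
#' @param gain Intensity units per mol m^-3 (> 0). Default 5e4, so a 10 uM
#'   lumen reads ~500 counts.
#' @param background Constant background intensity (>= 0), default 100.
#' @param gaussian_sigma Additive Gaussian read-noise SD (>= 0), default 2.
#' @param poisson Logical: apply Poisson shot noise to the expected counts.
#' @param bit_depth Detector bit depth (pixels clipped to
#'   `[0, 2^bit_depth - 1]`), default 16.
#' @param pixel_size_um Pixel size; `NULL` (default) inherits the grid
#'   spacing at render time.
#' @return An object of class `bbb_imaging_model`.
#' @export
imaging_model <- function(gain = 5e4, background = 100, gaussian_sigma = 2,
                          poisson = TRUE, bit_depth = 16,
                          pixel_size_um = NULL) {
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0", call. = FALSE)
  structure(list(gain = gain, background = background,
                 gaussian_sigma = gaussian_sigma, poisson = isTRUE(poisson),
                 bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um),
            class = "bbb_imaging_model")
}

#' Noise-free imaging model
#'
#' Convenience wrapper: [imaging_model()] with Poisson and Gaussian noise
#' disabled.
#'
#' @param ... Passed to [imaging_model()].
#' @return A `bbb_imaging_model`.
#' @export
noiseless_imaging_model <- function(...) {
  imaging_model(gaussian_sigma = 0, poisson = FALSE, ...)
}

# Run fn with a private RNG stream; the caller's RNG state is untouched.
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Render a fluorescence time-lapse from a concentration history
#'
#' `pixel = gain * C + background`, then optional Poisson shot noise and
#' additive Gaussian noise, clipped to `[0, 2^bit_depth - 1]`. A pure
#' function of `(history, model, seed)`: identical inputs give bit-identical
#' stacks, and the caller's RNG state is left untouched.
#'
#' @param history A `bbb_history` (snapshots become frames).
#' @param model A [imaging_model()].
#' @param seed Integer seed for the noise.
#' @param times Optional subset of frame times (default: all snapshots);
#'   times absent from the history are an error.
#' @return An object of class `bbb_timelapse`: `frames` (list of ny x nx
#'   intensity matrices), `timestamps_s`, `pixel_size_um`, `metadata`.
#' @export
render_timelapse <- function(history, model, seed = 1L, times = NULL) {
  times <- times %||% history$times
  idx <- vapply(times, function(t) {
    k <- which(abs(history$times - t) < 1e-6)
    if (length(k) != 1L)
      stop(sprintf("no snapshot at frame time t = %g s", t), call. = FALSE)
    k
  }, integer(1))
  ceiling_val <- 2^model$bit_depth - 1
  frames <- .with_seed(seed, function() {
    lapply(idx, function(k) {
      f <- model$gain * history$snapshots[[k]] + model$background
      if (model$poisson)
        f[] <- stats::rpois(length(f), lambda = as.vector(f))
      if (model$gaussian_sigma > 0)
        f <- f + stats::rnorm(length(f), sd = model$gaussian_sigma)
      pmin(pmax(f, 0), ceiling_val)
    })
  })
  structure(list(
    frames = frames, timestamps_s = history$times[idx] - history$times[idx[1]],
    pixel_size_um = model$pixel_size_um %||% history$grid$dx_um,
    metadata = list(solute = history$config$solute_name,
                    bit_depth = model$bit_depth, gain = model$gain,
                    background = model$background,
                    gaussian_sigma = model$gaussian_sigma,
                    poisson = model$poisson, seed = seed,
                    membrane_face = history$grid$membrane_face,
                    region_map_cols = history$grid$region_map[1, ])
  ), class = "bbb_timelapse")
}

#' @export
print.bbb_timelapse <- function(x, ...) {
  cat(sprintf(
    "bbb_timelapse: %d frames of %d x %d px (%.3g um/px), t = 0..%g s\n",
    length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
    x$pixel_size_um, max(x$timestamps_s)))
  invisible(x)
}

#' Draw per-device ground-truth permeabilities for a two-group cohort
#'
#' Device permeabilities are log-normal with the requested arithmetic group
#' mean and coefficient of variation (`dispersion`); default group sizes and
#' 40-kDa day-3 means follow the study cohort (13 wild-type, 25 AD devices).
#'
#' @param n_wt,n_ad Group sizes (> 0).
#' @param P_means Named vector `c(wt=, ad=)`, cm/s; default
#'   `c(wt = 1.96e-6, ad = 6.45e-6)`.
#' @param dispersion Coefficient of variation of the log-normal inter-device
#'   variability (>= 0), default 0.25.
#' @param seed Master seed. Per-device sub-seeds are drawn from the master
#'   RNG stream after the permeability draws and recorded in the table.
#' @return Data frame: `device_id`, `group` (`"wt"`/`"ad"`),
#'   `P_true_cm_s`, `seed`.
#' @export
draw_cohort_permeabilities <- function(n_wt = 13, n_ad = 25,
                                       P_means = c(wt = 1.96e-6,
                                                   ad = 6.45e-6),
                                       dispersion = 0.25, seed = 1L) {
  if (n_wt < 1 || n_ad < 1) stop("group sizes must be >= 1", call. = FALSE)
  if (any(P_means <= 0)) stop("group means must be > 0", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  sdlog <- sqrt(log(1 + dispersion^2))
  .with_seed(seed, function() {
    draw <- function(n, m)
      stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    p <- c(draw(n_wt, P_means[["wt"]]), draw(n_ad, P_means[["ad"]]))
    data.frame(
      device_id = sprintf("dev%03d", seq_len(n_wt + n_ad)),
      group = rep(c("wt", "ad"), c(n_wt, n_ad)),
      P_true_cm_s = p,
      seed = sample.int(.Machine$integer.max - 1L, n_wt + n_ad))
  })
}

#' Generate a full synthetic cohort of rendered assays
#'
#' Draws per-device permeabilities with [draw_cohort_permeabilities()],
#' then simulates and renders every device with its recorded sub-seed.
#'
#' @inheritParams draw_cohort_permeabilities
#' @param model Imaging model, default [imaging_model()].
#' @param solute Tracer, default `"dextran_40kda"`.
#' @param layout Device layout shared by all devices.
#' @param dx_um Grid spacing for the device simulations.
#' @param frame_interval_s,n_frames Frame clock per device.
#' @return List with `truth` (ground-truth data frame) and `devices`
#'   (list of `list(truth=, timelapse=)` per device).
#' @export
generate_cohort <- function(n_wt = 13, n_ad = 25,
                            P_means = c(wt = 1.96e-6, ad = 6.45e-6),
                            dispersion = 0.25, model = imaging_model(),
                            seed = 1L, solute = "dextran_40kda",
                            layout = build_default_layout(),
                            dx_um = 50, frame_interval_s = 300,
                            n_frames = 3) {
  tab <- draw_cohort_permeabilities(n_wt, n_ad, P_means, dispersion, seed)
  devices <- lapply(seq_len(nrow(tab)), function(i) {
    truth <- assay_ground_truth(
      tab$P_true_cm_s[i], solute = solute, layout = layout,
      frame_interval_s = frame_interval_s, n_frames = n_frames,
      seed = tab$seed[i])
    hist <- simulate_dextran_assay(truth, dx_um = dx_um)
    list(truth = truth,
         timelapse = render_timelapse(hist, model, seed = tab$seed[i]))
  })
  names(devices) <- tab$device_id
  list(truth = tab, devices = devices)
}

# ---- TIFF + JSON sidecar persistence ---------------------------------------

#' Write / read a time-lapse as multi-plane TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float planes scaled by the bit-depth ceiling;
#' timestamps, pixel size and metadata go to `<path>.json`.
#'
#' @param tl A `bbb_timelapse`.
#' @param path TIFF file path.
#' @return `write_timelapse` the path invisibly; `read_timelapse` a
#'   `bbb_timelapse`.
#' @export
write_timelapse <- function(tl, path) {
  ceiling_val <- 2^(tl$metadata$bit_depth %||% 16) - 1
  tiff::writeTIFF(lapply(tl$frames, function(f) f / ceiling_val), path,
                  bits.per.sample = 32L)
  sidecar <- list(timestamps_s = tl$timestamps_s,
                  pixel_size_um = tl$pixel_size_um,
                  intensity_scale = ceiling_val, metadata = tl$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timelapse
#' @export
read_timelapse <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  planes <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(planes, function(p) p * side$intensity_scale)
  structure(list(frames = frames, timestamps_s = side$timestamps_s,
                 pixel_size_um = side$pixel_size_um,
                 metadata = side$metadata),
            class = "bbb_timelapse")
}
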