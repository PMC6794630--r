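# Control-volume permeability estimation from a fluorescence time-lapse.
#
# The estimator implements the standard microfluidic permeability relation
#
#   P = (Vg / Av) * (1 / dIm) * d/dt Ig_bar
#
# where Vg is the gel volume inside the control volume (CV), Av the
# monolayer surface area bounding it, Ig_bar(t) the mean gel fluorescence in
# the CV, and dIm = I_lumen(0) - I_gel(0) the t = 0 lumen/gel intensity
# difference that proxies the transmural concentration difference. For the
# plan-view geometry with uniform channel height, Vg/Av reduces to
# (CV in-plane area) / (interface length): the CV depth when the CV spans
# the full interface. P is reported in cm/s.

#' Define a control volume and lumen ROI
#'
#' Rectangles are given in image pixel coordinates as half-open intervals
#' `[first, last)` counted from 0: `rows = c(r0, r1)`, `cols = c(c0, c1)`.
#' Rows run along the channel (interface) direction; columns across it.
#'
#' @param gel_rows,gel_cols CV rectangle in the gel, adjacent to the
#'   monolayer.
#' @param lumen_rows,lumen_cols Lumen ROI rectangle; must be disjoint from
#'   the CV.
#' @param pixel_size_um Pixel size in micrometres.
#' @param height_um Channel height (cancels in Vg/Av for full-width CVs but
#'   kept for the volume/area bookkeeping), default 150.
#' @param vg_over_av_um Optional explicit override of Vg/Av in micrometres;
#'   by default `(CV area) / (CV row extent)`, i.e. the CV depth.
#' @return An object of class `bbb_control_volume` with `Vg_m3`, `Av_m2`
#'   and `vg_over_av_m`.
#' @export
control_volume <- function(gel_rows, gel_cols, lumen_rows, lumen_cols,
                           pixel_size_um, height_um = 150,
                           vg_over_av_um = NULL) {
  chk <- function(r, what) {
    if (length(r) != 2L || r[2] <= r[1] || any(r < 0))
      stop(sprintf("%s must be a half-open interval c(first, last)", what),
           call. = FALSE)
    as.integer(r)
  }
  gel_rows <- chk(gel_rows, "gel_rows"); gel_cols <- chk(gel_cols, "gel_cols")
  lumen_rows <- chk(lumen_rows, "lumen_rows")
  lumen_cols <- chk(lumen_cols, "lumen_cols")
  overlap <- function(a, b) max(a[1], b[1]) < min(a[2], b[2])
  if (overlap(gel_rows, lumen_rows) && overlap(gel_cols, lumen_cols))
    stop("CV and lumen ROI must be disjoint", call. = FALSE)
  px_m <- pixel_size_um * 1e-6
  h_m <- height_um * 1e-6
  area_m2 <- diff(gel_rows) * diff(gel_cols) * px_m^2
  iface_m <- diff(gel_rows) * px_m
  vg_over_av_m <- if (!is.null(vg_over_av_um)) vg_over_av_um * 1e-6 else
    area_m2 / iface_m
  structure(list(gel_rows = gel_rows, gel_cols = gel_cols,
                 lumen_rows = lumen_rows, lumen_cols = lumen_cols,
                 pixel_size_um = pixel_size_um, height_um = height_um,
                 Vg_m3 = area_m2 * h_m, Av_m2 = iface_m * h_m,
                 vg_over_av_m = vg_over_av_m),
            class = "bbb_control_volume")
}

#' Default control volume for a rendered device
#'
#' Places the CV in the collagen scaffold touching the monolayer, spanning
#' the full interface length, and the lumen ROI symmetrically on the
#' luminal side. The default CV depth is the full scaffold width so that
#' the diffusion front stays inside the CV over the fit window; pass
#' `depth_um` for a shallower CV.
#'
#' @param tl A `bbb_timelapse` rendered by [render_timelapse()] (its
#'   metadata carries the interface position), or a `bbb_grid`.
#' @param depth_um CV depth into the gel, um; `NULL` = full scaffold width.
#' @param lumen_depth_um Lumen ROI depth, um; `NULL` = full lumen width.
#' @param height_um Channel height, default 150.
#' @return A `bbb_control_volume`.
#' @export
default_control_volume <- function(tl, depth_um = NULL,
                                   lumen_depth_um = NULL, height_um = 150) {
  if (inherits(tl, "bbb_grid")) {
    px <- tl$dx_um
    face <- tl$membrane_face
    region_cols <- tl$region_map[1, ]
    nrows <- tl$ny
  } else {
    px <- tl$pixel_size_um
    face <- tl$metadata$membrane_face
    region_cols <- unlist(tl$metadata$region_map_cols)
    nrows <- nrow(tl$frames[[1]])
  }
  if (is.null(face) || is.na(face))
    stop("interface position unknown; build the CV explicitly", call. = FALSE)
  scaffold_cols <- which(region_cols == 4L)  # collagen_scaffold_mc
  lumen_cols <- which(region_cols == 5L)     # bec_barrier_mc
  depth_px <- if (is.null(depth_um)) length(scaffold_cols) else
    max(1L, min(length(scaffold_cols), round(depth_um / px)))
  ldepth_px <- if (is.null(lumen_depth_um)) length(lumen_cols) else
    max(1L, min(length(lumen_cols), round(lumen_depth_um / px)))
  control_volume(
    gel_rows = c(0L, nrows), gel_cols = c(face - depth_px, face),
    lumen_rows = c(0L, nrows), lumen_cols = c(face, face + ldepth_px),
    pixel_size_um = px, height_um = height_um)
}

#' Extract mean-intensity time series from a time-lapse
#'
#' Per frame, the mean pixel value inside the CV; saturated pixels (at the
#' bit-depth ceiling, when the bit depth is known) are excluded from means
#' and counted in the diagnostics.
#'
#' @param tl A `bbb_timelapse`.
#' @param cv A [control_volume()].
#' @return An object of class `bbb_intensity_series`: `times_s`,
#'   `gel_mean`, `I_lumen_0`, `I_gel_0`, `saturated_fraction`.
#' @export
extract_intensity_series <- function(tl, cv) {
  fr1 <- tl$frames[[1]]
  sel <- function(rect_rows, rect_cols) {
    if (rect_rows[2] > nrow(fr1) || rect_cols[2] > ncol(fr1))
      stop("ROI out of frame bounds", call. = FALSE)
    list(rows = (rect_rows[1] + 1L):rect_rows[2],
         cols = (rect_cols[1] + 1L):rect_cols[2])
  }
  g <- sel(cv$gel_rows, cv$gel_cols)
  l <- sel(cv$lumen_rows, cv$lumen_cols)
  bit <- tl$metadata$bit_depth
  ceiling_val <- if (is.null(bit)) Inf else 2^bit - 1
  masked_mean <- function(px) {
    ok <- px < ceiling_val
    if (!any(ok)) stop("all ROI pixels saturated", call. = FALSE)
    c(mean(px[ok]), mean(!ok))
  }
  gel <- vapply(tl$frames, function(f)
    masked_mean(f[g$rows, g$cols, drop = FALSE]), numeric(2))
  lum0 <- masked_mean(fr1[l$rows, l$cols, drop = FALSE])
  structure(list(times_s = tl$timestamps_s, gel_mean = gel[1, ],
                 I_lumen_0 = lum0[1], I_gel_0 = gel[1, 1],
                 saturated_fraction = max(gel[2, ], lum0[2])),
            class = "bbb_intensity_series")
}

#' Fit the gel-intensity rise
#'
#' `two_point` (default) takes the secant slope between t = 0 and the end
#' of the window (600 s by default, the published read-out); `regression`
#' fits ordinary least squares over all frames in the window.
#'
#' @param series A `bbb_intensity_series`.
#' @param mode `"two_point"` or `"regression"`.
#' @param window_s Fit window, s (default 600). Two-point mode requires a
#'   frame at the window end.
#' @return List: `slope` (intensity/s), `mode`, `window_s`, `n_frames`,
#'   `residual_sd`.
#' @export
fit_intensity_slope <- function(series, mode = c("two_point", "regression"),
                                window_s = 600) {
  mode <- match.arg(mode)
  t <- series$times_s
  if (window_s > max(t) + 1e-6)
    stop(sprintf("window %g s exceeds the series span %g s", window_s,
                 max(t)), call. = FALSE)
  if (mode == "two_point") {
    k <- which(abs(t - window_s) < 1e-6)
    if (length(k) != 1L)
      stop(sprintf("two-point mode needs a frame at t = %g s", window_s),
           call. = FALSE)
    slope <- (series$gel_mean[k] - series$gel_mean[1]) / (t[k] - t[1])
    list(slope = slope, mode = mode, window_s = window_s, n_frames = 2L,
         residual_sd = NA_real_)
  } else {
    inw <- t <= window_s + 1e-6
    if (sum(inw) < 2L)
      stop("regression mode needs at least 2 frames in the window",
           call. = FALSE)
    fit <- stats::lm(y ~ x, data = data.frame(x = t[inw],
                                              y = series$gel_mean[inw]))
    list(slope = unname(stats::coef(fit)[2]), mode = mode,
         window_s = window_s, n_frames = sum(inw),
         residual_sd = stats::sd(stats::residuals(fit)))
  }
}

#' Estimate the permeability coefficient from an intensity series
#'
#' Applies `P = (Vg/Av) * slope / dIm` with `dIm = I_lumen(0) - I_gel(0)`,
#' reported in cm/s.
#'
#' @param series A `bbb_intensity_series`.
#' @param cv The [control_volume()] the series was extracted with.
#' @param mode,window_s Passed to [fit_intensity_slope()].
#' @return An object of class `bbb_perm_estimate`: `P_cm_s`, `slope`,
#'   `delta_Im`, `fit_mode`, `window_s`, `diagnostics` (saturated fraction,
#'   flag, residual sd).
#' @export
estimate_permeability <- function(series, cv,
                                  mode = c("two_point", "regression"),
                                  window_s = 600) {
  delta_Im <- series$I_lumen_0 - series$I_gel_0
  if (!is.finite(delta_Im) || delta_Im <= 0)
    stop(structure(class = c("bbb_assay_error", "error", "condition"),
                   list(message = paste(
                     "invalid assay: lumen not brighter than gel at t = 0",
                     sprintf("(delta_Im = %g)", delta_Im)), call = NULL)))
  fit <- fit_intensity_slope(series, mode, window_s)
  P_m_s <- cv$vg_over_av_m * fit$slope / delta_Im
  flag <- if (series$saturated_fraction > 0.05) "saturated" else "ok"
  structure(list(P_cm_s = 100 * P_m_s, slope = fit$slope,
                 delta_Im = delta_Im, fit_mode = fit$mode,
                 window_s = fit$window_s,
                 diagnostics = list(
                   saturated_fraction = series$saturated_fraction,
                   residual_sd = fit$residual_sd, n_frames = fit$n_frames,
                   flag = flag)),
            class = "bbb_perm_estimate")
}

#' @export
print.bbb_perm_estimate <- function(x, ...) {
  cat(sprintf(
    "Permeability estimate: P = %.4g cm/s (%s over %g s, dIm = %.4g, flag %s)\n",
    x$P_cm_s, x$fit_mode, x$window_s, x$delta_Im, x$diagnostics$flag))
  invisible(x)
}

#' One-call estimation from a time-lapse
#'
#' @param tl A `bbb_timelapse`.
#' @param cv Control volume; default [default_control_volume()] on `tl`.
#' @param ... Passed to [estimate_permeability()].
#' @return A `bbb_perm_estimate`.
#' @export
estimate_from_timelapse <- function(tl, cv = default_control_volume(tl),
                                    ...) {
  estimate_permeability(extract_intensity_series(tl, cv), cv, ...)
}
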