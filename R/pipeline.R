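# End-to-end experiments: the 7-day amyloid-beta accumulation scenario,
# permeability-recovery validation on synthetic cohorts, and the two-sample
# group comparison (Student's t, as in the study; Welch behind a flag).

#' Run the amyloid-beta accumulation experiment
#'
#' Simulates 7 days (by default) of constant distributed Abeta secretion in
#' the 3D neural culture MC (1.4e-12 mol m^-3 s^-1), starting from
#' 1.65e-7 mol m^-3 there, with the endothelial barrier membrane
#' (D_b = 2e-15 m^2/s over h_b) and daily replacement of the bEC barrier MC
#' with fresh medium (reset to 0). Emits daily cross-channel profiles and
#' the time course of the barrier-adjacent gel concentration.
#'
#' @param layout Device layout; default [build_default_layout()].
#' @param days Simulated duration in days, default 7.
#' @param source_rate_mol_m3_s Secretion rate, default 1.4e-12.
#' @param initial_mol_m3 Initial concentration of the 3D culture MC,
#'   default 1.65e-7.
#' @param replacement_period_s Medium replacement period, default 86400.
#' @param dx_um Grid spacing, default 50.
#' @param dt Time step, default 600 s (implicit scheme).
#' @param method Integrator, default `"implicit"`.
#' @param snapshot_interval_s Snapshot interval, default 3600.
#' @param out_dir Optional directory for CSV/PNG artifacts.
#' @return List of class `bbb_abeta_report`: `history`, `daily_profiles`
#'   (list of day -> profile data frame), `barrier_series` (time course of
#'   the scaffold cells touching the monolayer), `lumen_series`
#'   (bEC barrier MC mean), `params` echo.
#' @export
run_abeta_profile_experiment <- function(layout = build_default_layout(),
                                         days = 7,
                                         source_rate_mol_m3_s = 1.4e-12,
                                         initial_mol_m3 = 1.65e-7,
                                         replacement_period_s = 86400,
                                         dx_um = 50, dt = 600,
                                         method = "implicit",
                                         snapshot_interval_s = 3600,
                                         out_dir = NULL) {
  cfg <- simulation_config(
    layout = layout, solute = "abeta", t_end = days * 86400,
    dx_um = dx_um, dt = dt,
    initial_values = list(ren_3d_mc = initial_mol_m3),
    sources = if (source_rate_mol_m3_s > 0)
      list(list(region_role = "ren_3d_mc", rate = source_rate_mol_m3_s))
    else list(),
    schedule = list(list(region_role = "bec_barrier_mc",
                         period_s = replacement_period_s, reset_value = 0)),
    snapshot_interval = snapshot_interval_s, method = method)
  history <- run_simulation(cfg)
  daily <- lapply(seq_len(days), function(d)
    profile_along_axis(history, d * 86400))
  names(daily) <- sprintf("day%d", seq_len(days))
  report <- structure(list(
    history = history,
    daily_profiles = daily,
    barrier_series = barrier_adjacent_series(history),
    lumen_series = region_mean_series(history, "bec_barrier_mc"),
    params = list(source_rate_mol_m3_s = source_rate_mol_m3_s,
                  initial_mol_m3 = initial_mol_m3,
                  replacement_period_s = replacement_period_s,
                  dx_um = dx_um, dt = dt, method = method,
                  days = days)), class = "bbb_abeta_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (d in seq_len(days))
      write_profile_csv(daily[[d]],
                        file.path(out_dir, sprintf("profile_day%d.csv", d)))
    utils::write.csv(report$barrier_series,
                     file.path(out_dir, "barrier_adjacent_series.csv"),
                     row.names = FALSE)
    utils::write.csv(history$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report$params, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
    grDevices::png(file.path(out_dir, "profiles.png"), 900, 600)
    plot_abeta_profiles(report)
    grDevices::dev.off()
  }
  report
}

#' Barrier-adjacent gel concentration time course
#'
#' Mean concentration of the scaffold grid column touching the monolayer,
#' per snapshot.
#'
#' @param history A `bbb_history` (interface mode).
#' @return Data frame `time_s`, `mean_mol_m3`.
#' @export
barrier_adjacent_series <- function(history) {
  j <- history$grid$membrane_face
  data.frame(time_s = history$times,
             mean_mol_m3 = vapply(history$snapshots, function(v)
               mean(v[, j]), numeric(1)))
}

#' Plot the daily cross-channel concentration profiles
#'
#' @param report A `bbb_abeta_report`.
#' @return Invisibly, the report.
#' @export
plot_abeta_profiles <- function(report) {
  pr <- report$daily_profiles
  ymax <- max(vapply(pr, function(p) max(p$concentration_mol_m3),
                     numeric(1)))
  graphics::plot(NULL, xlim = range(pr[[1]]$position_um), ylim = c(0, ymax),
                 xlab = "position across channels (um)",
                 ylab = "concentration (mol m^-3)",
                 main = "Amyloid-beta accumulation, daily profiles")
  cols <- grDevices::hcl.colors(length(pr), "viridis")
  for (i in seq_along(pr))
    graphics::lines(pr[[i]]$position_um, pr[[i]]$concentration_mol_m3,
                    col = cols[i], lwd = 2)
  graphics::abline(v = attr(pr[[1]], "boundaries_um"), lty = 3,
                   col = "grey40")
  graphics::legend("topright", legend = names(pr), col = cols, lwd = 2,
                   bty = "n")
  invisible(report)
}

#' Two-sample comparison of permeability groups
#'
#' Student's two-sample t test with pooled variance (the study's analysis),
#' two-sided; Welch's unequal-variance form behind `welch = TRUE`.
#'
#' @param a,b Numeric vectors of per-device permeabilities (each >= 2
#'   finite values with positive variance).
#' @param welch Use Welch's t instead of the pooled form.
#' @return List: `statistic`, `df`, `p_value`, `method`.
#' @export
compare_groups_ttest <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 finite values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate groups: zero variance in both samples", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, method = if (welch) "welch" else "student")
}

#' Permeability-recovery experiment on a synthetic cohort
#'
#' Generates a cohort ([generate_cohort()]), renders every device, runs the
#' control-volume estimator, joins estimates to ground truth, and compares
#' the groups. A failed device is recorded with its error message and the
#' run continues.
#'
#' @inheritParams generate_cohort
#' @param mode,window_s Estimator settings (default two-point over 600 s).
#' @param cv_depth_um CV depth (default `NULL`: full scaffold width).
#' @return Object of class `bbb_run_report`: `devices` (per-device table
#'   with `P_true_cm_s`, `P_hat_cm_s`, `rel_error`, `flag`), `groups`
#'   (mean, sd, sem, n, bias, rmse per group), `ttest`, `params`,
#'   `master_seed`, `version`.
#' @export
run_recovery_experiment <- function(n_wt = 13, n_ad = 25,
                                    P_means = c(wt = 1.96e-6, ad = 6.45e-6),
                                    dispersion = 0.25,
                                    model = imaging_model(), seed = 1L,
                                    solute = "dextran_40kda",
                                    layout = build_default_layout(),
                                    dx_um = 50, frame_interval_s = 300,
                                    n_frames = 3,
                                    mode = "two_point", window_s = 600,
                                    cv_depth_um = NULL) {
  cohort <- generate_cohort(n_wt, n_ad, P_means, dispersion, model, seed,
                            solute, layout, dx_um, frame_interval_s,
                            n_frames)
  tab <- cohort$truth
  est <- lapply(cohort$devices, function(dev) {
    tryCatch({
      cv <- default_control_volume(dev$timelapse, depth_um = cv_depth_um,
                                   height_um = layout$height_um)
      e <- estimate_from_timelapse(dev$timelapse, cv, mode = mode,
                                   window_s = window_s)
      list(P_hat = e$P_cm_s, slope = e$slope, delta_Im = e$delta_Im,
           flag = e$diagnostics$flag)
    }, error = function(err)
      list(P_hat = NA_real_, slope = NA_real_, delta_Im = NA_real_,
           flag = paste("failed:", conditionMessage(err))))
  })
  tab$P_hat_cm_s <- vapply(est, `[[`, numeric(1), "P_hat")
  tab$slope <- vapply(est, `[[`, numeric(1), "slope")
  tab$delta_Im <- vapply(est, `[[`, numeric(1), "delta_Im")
  tab$flag <- vapply(est, `[[`, character(1), "flag")
  tab$rel_error <- tab$P_hat_cm_s / tab$P_true_cm_s - 1

  summarise_group <- function(g) {
    x <- tab$P_hat_cm_s[tab$group == g]
    x <- x[is.finite(x)]
    err <- tab$rel_error[tab$group == g]
    err <- err[is.finite(err)]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = stats::sd(x), sem = stats::sd(x) / sqrt(length(x)),
               bias = mean(err), rmse = sqrt(mean(err^2)))
  }
  groups <- rbind(summarise_group("wt"), summarise_group("ad"))
  tt <- compare_groups_ttest(tab$P_hat_cm_s[tab$group == "wt"],
                             tab$P_hat_cm_s[tab$group == "ad"])
  structure(list(devices = tab, groups = groups, ttest = tt,
                 params = list(P_means = P_means, dispersion = dispersion,
                               solute = solute, dx_um = dx_um,
                               frame_interval_s = frame_interval_s,
                               n_frames = n_frames, mode = mode,
                               window_s = window_s,
                               cv_depth_um = cv_depth_um),
                 master_seed = seed,
                 version = as.character(utils::packageVersion("bbbperm"))),
            class = "bbb_run_report")
}

#' @export
print.bbb_run_report <- function(x, ...) {
  cat(sprintf("Permeability recovery report (seed %d, bbbperm %s)\n",
              x$master_seed, x$version))
  print(x$groups, row.names = FALSE)
  cat(sprintf("Student's t = %.3f, df = %g, p = %.3g\n",
              x$ttest$statistic, x$ttest$df, x$ttest$p_value))
  invisible(x)
}

#' Write a run report to CSV/JSON files
#'
#' @param report A `bbb_run_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$devices, file.path(dir, "devices.csv"),
                   row.names = FALSE)
  utils::write.csv(report$groups, file.path(dir, "groups.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(ttest = report$ttest, params = report$params,
         master_seed = report$master_seed, version = report$version),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Cohort-separation power of the two-group design
#'
#' For each of `n_seeds` master seeds, draws a cohort of per-device
#' permeabilities (log-normal, the given group means and CV) and applies the
#' pooled two-sample t test; returns the fraction of seeds with
#' `p < alpha`. This measures the statistical power of the cohort design
#' itself; estimator noise is negligible at this dispersion.
#'
#' @inheritParams draw_cohort_permeabilities
#' @param n_seeds Number of master seeds, default 200.
#' @param alpha Significance threshold, default 1e-4.
#' @return List: `rejection_rate`, `n_seeds`, `alpha`, `p_values`.
#' @export
cohort_separation_power <- function(n_seeds = 200, n_wt = 13, n_ad = 25,
                                    P_means = c(wt = 1.96e-6,
                                                ad = 6.45e-6),
                                    dispersion = 0.25, alpha = 1e-4,
                                    seed = 1L) {
  seeds <- .with_seed(seed, function()
    sample.int(.Machine$integer.max - 1L, n_seeds))
  p_values <- vapply(seeds, function(s) {
    tab <- draw_cohort_permeabilities(n_wt, n_ad, P_means, dispersion, s)
    compare_groups_ttest(tab$P_true_cm_s[tab$group == "wt"],
                         tab$P_true_cm_s[tab$group == "ad"])$p_value
  }, numeric(1))
  list(rejection_rate = mean(p_values < alpha), n_seeds = n_seeds,
       alpha = alpha, p_values = p_values)
}
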