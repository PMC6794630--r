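test_that("discretization maps cells to regions and respects preconditions", {
  g <- homogeneous_grid(side_um = 100, dx_um = 10)
  expect_equal(c(g$ny, g$nx), c(10, 10))
  expect_equal(length(unique(as.vector(g$material_map))), 1L)

  lay <- short_layout()
  g1 <- discretize(lay, 50)
  g2 <- discretize(lay, 25)
  expect_equal(g2$nx, 2 * g1$nx)
  expect_equal(g2$ny, 2 * g1$ny)
  # interface face sits at the scaffold/bEC shared edge
  expect_equal(g1$membrane_face * g1$dx_um, lay$barrier_interface)

  expect_error(discretize(lay, 5, barrier_mode = "thin_region"),
               class = "bbb_config_error")
  expect_error(discretize(lay, 600), class = "bbb_config_error")
  expect_error(discretize(lay, -1), class = "bbb_config_error")
})

test_that("uniform fields are equilibria of both schemes", {
  lay <- short_layout(200)
  for (method in c("explicit", "implicit")) {
    cfg <- simulation_config(layout = lay, solute = "abeta", t_end = 900,
                             dx_um = 50, initial_values = 0.5,
                             snapshot_interval = 900, method = method)
    h <- run_simulation(cfg)
    expect_equal(max(abs(h$snapshots[[length(h$snapshots)]] - 0.5)), 0,
                 tolerance = 1e-10)
  }
})

test_that("a Gaussian pulse spreads with variance sigma0^2 + 2Dt", {
  g <- homogeneous_grid(side_um = 4000, dx_um = 25)
  s0 <- 100e-6
  V0 <- gaussian_field_matrix(g, sigma_um = 100)
  cfg <- simulation_config(grid = g, solute = "abeta", t_end = 800,
                           initial_values = V0, snapshot_interval = 800,
                           method = "explicit")
  h <- run_simulation(cfg)
  v <- h$snapshots[[length(h$snapshots)]]
  D <- lookup_diffusivity("medium", "abeta")
  expected <- s0^2 + 2 * D * 800
  expect_equal(field_x_variance(v, g$dx_um) / expected, 1, tolerance = 0.01)
  expect_equal(field_x_variance(t(v), g$dx_um) / expected, 1,
               tolerance = 0.01)
})

test_that("two-material slab steady state matches the series-resistance closed form", {
  lay <- build_default_layout(list(length_um = 200,
    materials_by_region = c(ren_media_mc = "matrigel",
                            ren_3d_mc = "matrigel", barrier_mc = "matrigel",
                            collagen_scaffold_mc = "collagen_scaffold",
                            bec_barrier_mc = "collagen_scaffold")))
  dx <- 50
  g <- discretize(lay, dx, membrane_conductance = Inf)
  cfg <- simulation_config(grid = g, solute = "abeta", t_end = 2e6, dt = 2e4,
                           pinned = list(ren_media_mc = 1,
                                         bec_barrier_mc = 0),
                           snapshot_interval = 2e6, method = "implicit")
  h <- run_simulation(cfg)
  v <- h$snapshots[[length(h$snapshots)]][1, ]
  # independent closed form: flux through two resistors in series between
  # the Dirichlet nodes (outermost reservoir cell centres)
  D1 <- lookup_diffusivity("matrigel", "abeta")
  D2 <- lookup_diffusivity("collagen_scaffold", "abeta")
  xa <- 1000 - dx / 2; xb <- 3500 + dx / 2; xi <- 2500
  R1 <- (xi - xa) / D1; R2 <- (xb - xi) / D2
  q <- 1 / (R1 + R2)
  xc <- (seq_len(g$nx) - 0.5) * dx
  cont <- ifelse(xc <= xa, 1, ifelse(xc >= xb, 0,
            ifelse(xc <= xi, 1 - q * (xc - xa) / D1, q * (xb - xc) / D2)))
  expect_lt(max(abs(v - cont)), 0.01 * max(cont))
  # interface value itself
  expect_equal(1 - q * R1, 0.5734266, tolerance = 1e-6)
})

test_that("mass is conserved in a sealed domain with a distributed source", {
  lay <- short_layout(300)
  cfg <- simulation_config(layout = lay, solute = "abeta", t_end = 3600,
                           dx_um = 50,
                           initial_values = list(ren_3d_mc = 1.65e-7),
                           sources = list(list(region_role = "ren_3d_mc",
                                               rate = 1.4e-12)),
                           snapshot_interval = 3600, method = "explicit")
  h <- run_simulation(cfg)
  dxm <- 50e-6; hm <- lay$height_um * 1e-6
  M0 <- sum(h$snapshots[[1]]) * dxm^2 * hm
  M1 <- sum(h$snapshots[[length(h$snapshots)]]) * dxm^2 * hm
  A_src <- sum(h$grid$region_map == 2L) * dxm^2
  expect_equal(M1, M0 + 1.4e-12 * A_src * hm * 3600, tolerance = 1e-3)
})

test_that("without sources the extrema obey the maximum principle", {
  g <- homogeneous_grid(side_um = 1000, dx_um = 50)
  set.seed(11)
  V0 <- gaussian_field_matrix(g, sigma_um = 200) +
    0.05 * matrix(runif(g$ny * g$nx), g$ny, g$nx)
  f <- concentration_field(g, V0)
  rates <- bbbperm:::.face_rates(g, "abeta")
  dt <- 0.9 * bbbperm:::.stability_dt(g, rates)
  mx <- max(f$values); mn <- min(f$values)
  for (i in 1:25) {
    f <- step_field(f, dt, solute_name = "abeta", rates = rates)
    expect_lte(max(f$values), mx + 1e-12)
    expect_gte(min(f$values), mn - 1e-12)
    mx <- max(f$values); mn <- min(f$values)
  }
})

test_that("medium replacement resets one region and books the removed mass", {
  lay <- short_layout(300)
  g <- discretize(lay, 50)
  f <- concentration_field(g, list(bec_barrier_mc = 2e-3, ren_3d_mc = 1e-3))
  pre <- sum(f$values[g$region_map == 5L]) * (50e-6)^2 * 150e-6
  f2 <- apply_replacement(f, "bec_barrier_mc", 0)
  expect_equal(sum(f2$values[g$region_map == 5L]), 0)
  expect_equal(f2$values[g$region_map == 2L], f$values[g$region_map == 2L])
  expect_equal(attr(f2, "mass_removed_mol"), pre)
  expect_equal(f2$time, f$time)
  expect_error(apply_replacement(f, "no_such_region"), "unknown region")
})

test_that("zero input gives an identically zero history with scheduled events logged", {
  cfg <- simulation_config(layout = short_layout(200), solute = "abeta",
                           t_end = 7200, dx_um = 50, dt = 1800,
                           schedule = list(list(region_role = "bec_barrier_mc",
                                                period_s = 3600,
                                                reset_value = 0)),
                           snapshot_interval = 3600, method = "implicit")
  h <- run_simulation(cfg)
  expect_true(all(vapply(h$snapshots, function(v) all(v == 0), logical(1))))
  expect_equal(h$events$time_s, c(3600, 7200))
  expect_true(all(diff(h$times) > 0))
  expect_equal(h$events$mass_removed_mol, c(0, 0))
})

test_that("profiles are flat for uniform fields and span the domain", {
  cfg <- simulation_config(layout = short_layout(200), solute = "abeta",
                           t_end = 600, dx_um = 50, initial_values = 0.25,
                           snapshot_interval = 600)
  h <- run_simulation(cfg)
  p <- profile_along_axis(h, 600)
  expect_equal(nrow(p), h$grid$nx)
  expect_equal(unique(p$concentration_mol_m3), 0.25, tolerance = 1e-12)
  expect_equal(attr(p, "boundaries_um"), c(1000, 2000, 2500, 3500, 4500))
  expect_error(profile_along_axis(h, 1e9), "outside")
})

test_that("total mass integrates concentration over the device volume", {
  g <- discretize(short_layout(300), 50)
  f <- concentration_field(g, 1)   # 1 mol/m^3 everywhere
  vol <- g$nx * g$ny * (50e-6)^2 * 150e-6
  expect_equal(total_mass(f), vol)
  f0 <- concentration_field(g, 0)
  expect_equal(total_mass(f0), 0)
  fa <- concentration_field(g, list(ren_3d_mc = 1))
  fb <- concentration_field(g, list(bec_barrier_mc = 1))
  fab <- concentration_field(g, list(ren_3d_mc = 1, bec_barrier_mc = 1))
  expect_equal(total_mass(fa) + total_mass(fb), total_mass(fab))
})

test_that("explicit and implicit schemes agree on the accumulation scenario", {
  lay <- short_layout(300)
  run1 <- function(method, dt) {
    cfg <- simulation_config(layout = lay, solute = "abeta", t_end = 86400,
                             dx_um = 50, dt = dt,
                             initial_values = list(ren_3d_mc = 1.65e-7),
                             sources = list(list(region_role = "ren_3d_mc",
                                                 rate = 1.4e-12)),
                             snapshot_interval = 86400, method = method)
    run_simulation(cfg)
  }
  he <- run1("explicit", NULL)
  hi <- run1("implicit", 600)
  j <- he$grid$membrane_face
  a <- mean(he$snapshots[[length(he$snapshots)]][, j])
  b <- mean(hi$snapshots[[length(hi$snapshots)]][, j])
  expect_equal(b / a, 1, tolerance = 0.01)
})

test_that("a leakier barrier passes strictly more mass into the luminal channel", {
  flux_into_lumen <- function(K) {
    cfg <- simulation_config(layout = short_layout(300), solute = "abeta",
                             t_end = 43200, dx_um = 50, dt = 600,
                             initial_values = list(ren_3d_mc = 1.65e-7),
                             snapshot_interval = 43200, method = "implicit",
                             membrane_conductance = K)
    h <- run_simulation(cfg)
    mean(h$snapshots[[length(h$snapshots)]][, h$grid$region_map[1, ] == 5L])
  }
  m <- vapply(c(1e-9, 1e-8, 1e-7), flux_into_lumen, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("halving the grid spacing changes the day-3 barrier concentration by < 2%", {
  day3 <- function(dx) {
    cfg <- simulation_config(layout = short_layout(300), solute = "abeta",
                             t_end = 3 * 86400, dx_um = dx, dt = 600,
                             initial_values = list(ren_3d_mc = 1.65e-7),
                             sources = list(list(region_role = "ren_3d_mc",
                                                 rate = 1.4e-12)),
                             schedule = list(list(
                               region_role = "bec_barrier_mc",
                               period_s = 86400, reset_value = 0)),
                             snapshot_interval = 3 * 86400,
                             method = "implicit")
    h <- run_simulation(cfg)
    mean(h$snapshots[[length(h$snapshots)]][, h$grid$membrane_face])
  }
  expect_equal(day3(50) / day3(25), 1, tolerance = 0.02)
})

test_that("histories export to plain-text files that round-trip the snapshots", {
  cfg <- simulation_config(layout = short_layout(200), solute = "abeta",
                           t_end = 1200, dx_um = 100,
                           initial_values = list(ren_3d_mc = 1e-6),
                           snapshot_interval = 600, method = "implicit",
                           dt = 600)
  h <- run_simulation(cfg)
  dir <- withr::local_tempdir()
  export_history(h, dir)
  expect_true(all(c("times.csv", "events.csv", "config.json",
                    "material_map.csv") %in% list.files(dir)))
  snap <- as.matrix(utils::read.csv(file.path(dir, "snapshot_0002.csv"),
                                    header = FALSE))
  expect_equal(unname(snap), unname(h$snapshots[[3]]), tolerance = 1e-12)
  meta <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(meta$dx_um, 100)
})
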