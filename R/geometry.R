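# Device geometry, material/solute tables and unit conversions.
#
# The device is a plan-view rectangle tiled by five parallel microchannels
# (MCs), ordered across x:
#   ren_media_mc -> ren_3d_mc -> barrier_mc -> collagen_scaffold_mc ->
#   bec_barrier_mc
# The brain-endothelial (bEC) monolayer sits on the shared edge of the
# collagen scaffold MC and the bEC barrier MC and is represented as a thin
# membrane with diffusivity D_b and thickness h_b, or equivalently a
# conductance K = D_b / h_b (m/s). All in-plane lengths are in micrometres.

REGION_ROLES <- c("ren_media_mc", "ren_3d_mc", "barrier_mc",
                  "collagen_scaffold_mc", "bec_barrier_mc")

#' Define a solute
#'
#' @param name Label, e.g. `"abeta"` or `"dextran_40kda"`.
#' @param molecular_weight_kda Molecular weight in kDa (> 0).
#' @return An object of class `bbb_solute`.
#' @examples
#' solute("abeta", 4)
#' @export
solute <- function(name, molecular_weight_kda) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molecular_weight_kda) || length(molecular_weight_kda) != 1L ||
      !is.finite(molecular_weight_kda) || molecular_weight_kda <= 0)
    stop("molecular_weight_kda must be a single positive number", call. = FALSE)
  structure(list(name = name, molecular_weight_kda = molecular_weight_kda),
            class = "bbb_solute")
}

#' Built-in solutes
#'
#' Soluble amyloid-beta (~4 kDa) and the two fluorescent dextran tracers
#' (3 and 40 kDa) used in the influx assay.
#'
#' @return Named list of [solute()] objects.
#' @export
default_solutes <- function() {
  list(
    abeta         = solute("abeta", 4),
    dextran_3kda  = solute("dextran_3kda", 3),
    dextran_40kda = solute("dextran_40kda", 40)
  )
}

#' Define a material with per-solute diffusivities
#'
#' @param name One of `medium`, `matrigel`, `collagen_2mgml`,
#'   `collagen_scaffold`, `barrier` (other labels are allowed).
#' @param diffusivity Named numeric vector, solute name -> D in m^2/s
#'   (all > 0).
#' @return An object of class `bbb_material`.
#' @export
material <- function(name, diffusivity) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(diffusivity) || is.null(names(diffusivity)) ||
      any(!nzchar(names(diffusivity))))
    stop("diffusivity must be a named numeric vector (solute -> m^2/s)",
         call. = FALSE)
  if (any(!is.finite(diffusivity)) || any(diffusivity <= 0))
    stop("all diffusivities must be positive and finite", call. = FALSE)
  structure(list(name = name, diffusivity = diffusivity),
            class = "bbb_material")
}

# Diffusivities (m^2/s). Abeta values are the study's stated coefficients;
# dextran values follow Stokes-Einstein Mw^(-1/3) scaling anchored at the
# 4-kDa abeta coefficient of the same material (factor 1.1006 for 3 kDa,
# 0.4642 for 40 kDa).
.default_diffusivity_table <- function() {
  abeta <- c(medium = 1.8e-10, matrigel = 1.24e-10,
             collagen_2mgml = 0.7e-10, collagen_scaffold = 0.62e-10)
  scale3  <- (4 / 3)^(1 / 3)
  scale40 <- (4 / 40)^(1 / 3)
  list(abeta = abeta, dextran_3kda = abeta * scale3,
       dextran_40kda = abeta * scale40)
}

#' Built-in materials
#'
#' Culture medium, Matrigel, 2 mg/mL collagen (barrier MC fill), the collagen
#' scaffold, and the endothelial barrier material (D_b = 2e-15 m^2/s for every
#' solute by default; the monolayer restricts all tracers used here).
#'
#' @param barrier_diffusivity Barrier diffusivity in m^2/s, applied to all
#'   solutes. Default 2e-15.
#' @return Named list of [material()] objects.
#' @export
default_materials <- function(barrier_diffusivity = 2e-15) {
  tab <- .default_diffusivity_table()
  solute_names <- names(tab)
  mk <- function(mat) {
    d <- vapply(tab, function(v) unname(v[[mat]]), numeric(1))
    names(d) <- solute_names
    material(mat, d)
  }
  mats <- lapply(c("medium", "matrigel", "collagen_2mgml",
                   "collagen_scaffold"), mk)
  names(mats) <- c("medium", "matrigel", "collagen_2mgml",
                   "collagen_scaffold")
  db <- rep(barrier_diffusivity, length(solute_names))
  names(db) <- solute_names
  mats$barrier <- material("barrier", db)
  mats
}

#' Look up a diffusion coefficient
#'
#' @param material_name Material label.
#' @param solute A [solute()] object or a solute name.
#' @param materials Material table, default [default_materials()].
#' @return Diffusivity in m^2/s.
#' @examples
#' lookup_diffusivity("medium", solute("abeta", 4))  # 1.8e-10
#' @export
lookup_diffusivity <- function(material_name, solute,
                               materials = default_materials()) {
  sname <- if (inherits(solute, "bbb_solute")) solute$name else solute
  mat <- materials[[material_name]]
  if (is.null(mat))
    stop(sprintf("no diffusivity known for material '%s' (solute '%s')",
                 material_name, sname), call. = FALSE)
  d <- mat$diffusivity[sname]
  if (is.na(d))
    stop(sprintf("no diffusivity known for material '%s' and solute '%s'",
                 material_name, sname), call. = FALSE)
  unname(d)
}

#' Convert a volumetric production rate from M/h to SI
#'
#' Converts mol L^-1 h^-1 (molar per hour) to mol m^-3 s^-1:
#' `rate * 1000 / 3600`. The stated neural secretion rate 5e-12 M/h
#' corresponds to 1.39e-12 (printed 1.4e-12) mol m^-3 s^-1.
#'
#' @param rate Rate in mol L^-1 h^-1; finite numeric (vectorised).
#' @return Rate in mol m^-3 s^-1.
#' @export
convert_rate_molar_per_hour_to_si <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)))
    stop("rate must be finite numeric", call. = FALSE)
  rate * 1000 / 3600
}

#' Define one device region
#'
#' @param role Region role, one of
#'   `ren_media_mc, ren_3d_mc, barrier_mc, collagen_scaffold_mc,
#'   bec_barrier_mc`.
#' @param x_range,y_range Half-open intervals `[min, max)` in micrometres.
#' @param material Material name filling the region.
#' @return An object of class `bbb_region`.
#' @export
device_region <- function(role, x_range, y_range, material) {
  role <- match.arg(role, REGION_ROLES)
  stopifnot(length(x_range) == 2L, length(y_range) == 2L)
  if (diff(x_range) <= 0 || diff(y_range) <= 0)
    stop(sprintf("region '%s' must have positive extents", role),
         call. = FALSE)
  structure(list(role = role, x_range = as.numeric(x_range),
                 y_range = as.numeric(y_range), material = material),
            class = "bbb_region")
}

#' Assemble a device layout
#'
#' @param regions List of [device_region()] in channel order across x.
#' @param height_um Uniform out-of-plane channel height (default 150).
#' @param barrier_thickness_um Nominal monolayer thickness h_b (default 2).
#' @param barrier_diffusivity Barrier diffusivity D_b in m^2/s (default
#'   2e-15); membrane conductance is `K = D_b / h_b`.
#' @param materials Material table used for validation and simulation.
#' @return An object of class `bbb_layout` with a `barrier_interface`
#'   element (the x position, in um, of the scaffold/bEC shared edge).
#' @export
device_layout <- function(regions, height_um = 150,
                          barrier_thickness_um = 2,
                          barrier_diffusivity = 2e-15,
                          materials = default_materials()) {
  lay <- structure(list(regions = regions, height_um = height_um,
                        barrier_thickness_um = barrier_thickness_um,
                        barrier_diffusivity = barrier_diffusivity,
                        materials = materials),
                   class = "bbb_layout")
  lay$barrier_interface <- .barrier_interface_x(lay)
  validate_layout(lay)
  lay
}

.barrier_interface_x <- function(layout) {
  roles <- vapply(layout$regions, `[[`, character(1), "role")
  sc <- layout$regions[[match("collagen_scaffold_mc", roles)]]
  sc$x_range[2]
}

#' Validate a device layout
#'
#' Checks that the regions tile the rectangular domain without overlap in
#' the canonical channel order, that extents and height are positive, and
#' that the barrier interface lies on the scaffold/bEC shared edge.
#'
#' @param layout A `bbb_layout`.
#' @return The layout, invisibly; signals an error of class
#'   `bbb_layout_error` otherwise.
#' @export
validate_layout <- function(layout) {
  fail <- function(msg) stop(structure(class = c("bbb_layout_error", "error",
                                                 "condition"),
                                       list(message = msg, call = NULL)))
  if (!inherits(layout, "bbb_layout")) fail("not a bbb_layout")
  roles <- vapply(layout$regions, `[[`, character(1), "role")
  if (!identical(roles, REGION_ROLES))
    fail(paste("regions must be exactly", paste(REGION_ROLES, collapse = ", "),
               "in order"))
  if (!is.finite(layout$height_um) || layout$height_um <= 0)
    fail("height_um must be positive")
  if (layout$barrier_thickness_um <= 0) fail("barrier thickness must be > 0")
  if (layout$barrier_diffusivity <= 0) fail("barrier diffusivity must be > 0")
  yr <- layout$regions[[1]]$y_range
  x_edge <- layout$regions[[1]]$x_range[1]
  for (rg in layout$regions) {
    if (diff(rg$x_range) <= 0 || diff(rg$y_range) <= 0)
      fail(sprintf("region '%s' has non-positive extent", rg$role))
    if (!isTRUE(all.equal(rg$y_range, yr)))
      fail("all regions must share the same y range")
    if (abs(rg$x_range[1] - x_edge) > 1e-9)
      fail(sprintf("regions overlap or leave a gap at x = %g um", x_edge))
    x_edge <- rg$x_range[2]
    if (is.null(layout$materials[[rg$material]]))
      fail(sprintf("unknown material '%s' in region '%s'", rg$material,
                   rg$role))
  }
  sc <- layout$regions[[match("collagen_scaffold_mc", roles)]]
  if (abs(layout$barrier_interface - sc$x_range[2]) > 1e-9)
    fail("barrier_interface must lie on the scaffold/bEC shared edge")
  invisible(layout)
}

#' Build the default five-channel layout
#'
#' Default in-plane dimensions (configurable; exact device dimensions are
#' printed only on the device drawing): media / 3D culture / scaffold / bEC
#' MCs 1000 um wide, central barrier MC 500 um wide, channels 7500 um long,
#' height 150 um. Default fills: medium in `ren_media_mc` and
#' `bec_barrier_mc`, Matrigel in `ren_3d_mc`, 2 mg/mL collagen in
#' `barrier_mc`, collagen scaffold (D of the 5 mg/mL literature value) in
#' `collagen_scaffold_mc`.
#'
#' @param overrides Named list; recognised keys: `widths_um` (named vector
#'   per region role), `length_um`, `height_um`, `barrier_thickness_um`,
#'   `barrier_diffusivity`, `materials_by_region` (named character),
#'   `materials` (material table).
#' @return A validated `bbb_layout`.
#' @examples
#' lay <- build_default_layout()
#' lay$height_um  # 150
#' @export
build_default_layout <- function(overrides = list()) {
  ov <- function(key) overrides[[key, exact = TRUE]]
  widths <- c(ren_media_mc = 1000, ren_3d_mc = 1000, barrier_mc = 500,
              collagen_scaffold_mc = 1000, bec_barrier_mc = 1000)
  if (!is.null(ov("widths_um"))) {
    w <- ov("widths_um")
    widths[names(w)] <- w
  }
  length_um <- ov("length_um") %||% 7500
  height_um <- ov("height_um") %||% 150
  mats_by_region <- c(ren_media_mc = "medium", ren_3d_mc = "matrigel",
                      barrier_mc = "collagen_2mgml",
                      collagen_scaffold_mc = "collagen_scaffold",
                      bec_barrier_mc = "medium")
  if (!is.null(ov("materials_by_region"))) {
    m <- ov("materials_by_region")
    mats_by_region[names(m)] <- m
  }
  materials <- ov("materials") %||%
    default_materials(ov("barrier_diffusivity") %||% 2e-15)
  edges <- cumsum(c(0, widths[REGION_ROLES]))
  regions <- lapply(seq_along(REGION_ROLES), function(i) {
    role <- REGION_ROLES[i]
    if (widths[[role]] <= 0)
      stop(structure(class = c("bbb_layout_error", "error", "condition"),
                     list(message = sprintf(
                       "region '%s' has non-positive width", role),
                       call = NULL)))
    device_region(role, c(edges[i], edges[i + 1]), c(0, length_um),
                  mats_by_region[[role]])
  })
  device_layout(regions, height_um = height_um,
                barrier_thickness_um = ov("barrier_thickness_um") %||% 2,
                barrier_diffusivity = ov("barrier_diffusivity") %||% 2e-15,
                materials = materials)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bbb_layout <- function(x, ...) {
  cat("Microfluidic BBB device layout (plan view)\n")
  for (rg in x$regions)
    cat(sprintf("  %-22s x [%6g, %6g) um  material: %s\n", rg$role,
                rg$x_range[1], rg$x_range[2], rg$material))
  cat(sprintf("  height %g um; barrier interface at x = %g um (K = %.3g m/s)\n",
              x$height_um, x$barrier_interface,
              barrier_conductance(x)))
  invisible(x)
}

#' Membrane conductance of the endothelial barrier
#'
#' `K = D_b / h_b` in m/s. Multiply by 100 for cm/s.
#'
#' @param layout A `bbb_layout`.
#' @return Conductance in m/s.
#' @export
barrier_conductance <- function(layout) {
  layout$barrier_diffusivity / (layout$barrier_thickness_um * 1e-6)
}

# ---- configuration (YAML/JSON) serialization -------------------------------

#' Serialize a layout to a plain configuration list
#'
#' The schema uses unit-suffixed keys: `regions[]` (role, x_um, y_um,
#' material), `height_um`, `barrier{thickness_um, diffusivity}`,
#' `materials{name: {solute: D}}`.
#'
#' @param layout A `bbb_layout`.
#' @return A plain list serializable with [yaml::as.yaml()] or
#'   [jsonlite::toJSON()].
#' @export
layout_to_config <- function(layout) {
  list(
    regions = lapply(layout$regions, function(rg)
      list(role = rg$role, x_um = rg$x_range, y_um = rg$y_range,
           material = rg$material)),
    height_um = layout$height_um,
    barrier = list(thickness_um = layout$barrier_thickness_um,
                   diffusivity = layout$barrier_diffusivity),
    materials = lapply(layout$materials, function(m) as.list(m$diffusivity))
  )
}

#' Rebuild a layout from a configuration list
#'
#' Inverse of [layout_to_config()].
#'
#' @param config Plain list as produced by [layout_to_config()] or read
#'   from YAML/JSON.
#' @return A validated `bbb_layout`.
#' @export
layout_from_config <- function(config) {
  materials <- lapply(names(config$materials), function(nm)
    material(nm, unlist(config$materials[[nm]])))
  names(materials) <- names(config$materials)
  regions <- lapply(config$regions, function(rg)
    device_region(rg$role, unlist(rg$x_um), unlist(rg$y_um), rg$material))
  device_layout(regions, height_um = config$height_um,
                barrier_thickness_um = config$barrier$thickness_um,
                barrier_diffusivity = config$barrier$diffusivity,
                materials = materials)
}

#' Write / read a layout configuration as YAML
#'
#' @param layout A `bbb_layout`.
#' @param path File path.
#' @return `write_layout_yaml` the path invisibly; `read_layout_yaml` a
#'   `bbb_layout`.
#' @export
write_layout_yaml <- function(layout, path) {
  yaml::write_yaml(layout_to_config(layout), path)
  invisible(path)
}

#' @rdname write_layout_yaml
#' @export
read_layout_yaml <- function(path) {
  layout_from_config(yaml::read_yaml(path))
}
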