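# Synaptic environment geometry: truncated pre/postsynaptic hemispheres,
# apposition zone with cleft, and a lattice of neighbouring obstacles whose
# inner faces carry the astroglial (PAP) membrane sectors.

#' Geometry configuration for the synaptic environment
#'
#' All lengths in nanometres. The defaults reproduce the canonical CA3-CA1
#' geometry: two truncated hemispheres separated by a 300 nm wide, 20 nm high
#' apposition zone that includes a 200 nm wide synaptic cleft, surrounded by
#' 20-30 nm extracellular gaps between neighbouring cellular obstacles.
#'
#' @param hemisphere_radius Radius of the pre/postsynaptic hemispherical caps.
#' @param apposition_width Width (diameter) of the apposition zone.
#' @param apposition_height Height of the apposition zone (pre-post membrane
#'   separation).
#' @param cleft_width Width of the synaptic cleft (must not exceed
#'   `apposition_width`).
#' @param gap_width Width of the extracellular gaps between obstacles
#'   (20-30 nm).
#' @param nmdar_cluster_band Radial band (min, max) for the extrasynaptic
#'   NMDAR cluster distance from the synaptic centroid.
#' @param sector_count Number of azimuthal astroglial sectors (fixed at 4).
#' @param voxel_pitch Voxel pitch for extracellular-fraction integration.
#' @param obstacle_pitch Lattice pitch of the obstacle packing. The default
#'   (600 nm) is the frozen calibration for which the default gaps yield an
#'   extracellular volume fraction of about 0.15.
#' @return A list of class `papsim_geometry_config`.
#' @export
geometry_config <- function(hemisphere_radius = 250,
                            apposition_width = 300,
                            apposition_height = 20,
                            cleft_width = 200,
                            gap_width = 25,
                            nmdar_cluster_band = c(200, 250),
                            sector_count = 4,
                            voxel_pitch = 5,
                            obstacle_pitch = 600) {
  cfg <- list(hemisphere_radius = hemisphere_radius,
              apposition_width = apposition_width,
              apposition_height = apposition_height,
              cleft_width = cleft_width,
              gap_width = gap_width,
              nmdar_cluster_band = nmdar_cluster_band,
              sector_count = sector_count,
              voxel_pitch = voxel_pitch,
              obstacle_pitch = obstacle_pitch)
  class(cfg) <- "papsim_geometry_config"
  validate_geometry_config(cfg)
  cfg
}

validate_geometry_config <- function(cfg) {
  lens <- c(cfg$hemisphere_radius, cfg$apposition_width,
            cfg$apposition_height, cfg$cleft_width, cfg$obstacle_pitch,
            cfg$voxel_pitch)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("geometry configuration error: all lengths must be positive")
  if (cfg$gap_width < 0)
    stop("geometry configuration error: gap_width must be non-negative")
  if (cfg$cleft_width > cfg$apposition_width)
    stop("geometry configuration error: cleft wider than apposition zone")
  if (cfg$hemisphere_radius <= cfg$apposition_width / 2)
    stop("geometry configuration error: hemisphere radius must exceed half the apposition width")
  if (cfg$sector_count != 4L)
    stop("geometry configuration error: only 4 astroglial sectors are supported")
  if (any(cfg$nmdar_cluster_band <= cfg$apposition_width / 2))
    stop("geometry configuration error: NMDAR cluster band must lie outside the apposition zone")
  if (cfg$gap_width >= cfg$obstacle_pitch)
    stop("geometry configuration error: gap wider than obstacle pitch")
  invisible(cfg)
}

# Parameter vector consumed by the C++ engine.
geom_vector <- function(model) {
  c(pitch = model$obstacle_pitch,
    side = model$obstacle_side,
    hc = model$apposition_height / 2,
    radius = model$hemisphere_radius,
    zc = model$zc,
    domxy = 1.5 * model$obstacle_pitch,
    domz = 2 * model$obstacle_pitch)
}

#' Build the 3D synaptic-environment model
#'
#' Constructs the solid/extracellular partition: the two truncated hemispheres
#' (base disc of radius `apposition_width/2`, separated by
#' `apposition_height`), embedded in a 3 x 3 x 4 lattice of cuboid obstacles
#' of side `obstacle_pitch - gap_width` whose central 1 x 1 x 2 block is
#' vacated for the synapse. The four inner faces of the lateral obstacles
#' form the astroglial membrane, one azimuthal sector each. The extracellular
#' volume fraction is computed by voxel integration at `voxel_pitch`.
#'
#' @param config A [geometry_config()].
#' @param voxel_pitch Optional override of the integration pitch (nm).
#' @return An object of class `papsim_geometry` with, among others,
#'   `ecs_fraction`, per-sector astroglial membrane patch definitions and
#'   areas (um^2), and the frozen obstacle-packing record.
#' @export
build_geometry <- function(config = geometry_config(), voxel_pitch = NULL) {
  validate_geometry_config(config)
  pitch <- if (is.null(voxel_pitch)) config$voxel_pitch else voxel_pitch

  R <- config$hemisphere_radius
  hw <- config$apposition_width / 2
  hc <- config$apposition_height / 2
  model <- list(
    hemisphere_radius = R,
    apposition_width = config$apposition_width,
    apposition_height = config$apposition_height,
    cleft_width = config$cleft_width,
    gap_width = config$gap_width,
    nmdar_cluster_band = config$nmdar_cluster_band,
    sector_count = 4L,
    obstacle_pitch = config$obstacle_pitch,
    obstacle_side = config$obstacle_pitch - config$gap_width,
    zc = hc + sqrt(R^2 - hw^2)
  )
  gv <- geom_vector(model)
  model$domain_halfwidth <- unname(gv["domxy"])
  model$domain_halfheight <- unname(gv["domz"])
  # inner wall plane of the perisynaptic cavity
  model$wall_distance <- model$obstacle_pitch - model$obstacle_side / 2

  # astroglial membrane band on each wall: |z| in [gap/2, pitch/2], transverse
  # extent two thirds of the obstacle side (leaves room for the lateral-shift
  # scenario while staying on the wall)
  model$band_v <- c(config$gap_width / 2, config$obstacle_pitch / 2)
  model$band_u_half <- model$obstacle_side / 3
  band_area_nm2 <- 2 * (2 * model$band_u_half) * diff(model$band_v)
  model$membrane_area_um2 <- rep(band_area_nm2 * 1e-6, 4L)

  model$voxel_pitch <- pitch
  model$ecs_fraction <- cpp_ecs_fraction(gv, pitch)
  model$packing <- sprintf(
    "cubic obstacle lattice, pitch %g nm, side %g nm, 3x3x4 cells, central 1x1x2 vacated",
    model$obstacle_pitch, model$obstacle_side)
  class(model) <- "papsim_geometry"
  stopifnot(model$ecs_fraction > 0, model$ecs_fraction < 1)
  model
}

#' @export
print.papsim_geometry <- function(x, ...) {
  cat("Synaptic environment geometry\n")
  cat(sprintf("  apposition %g x %g nm, cleft %g nm, gaps %g nm\n",
              x$apposition_width, x$apposition_height, x$cleft_width,
              x$gap_width))
  cat(sprintf("  packing: %s\n", x$packing))
  cat(sprintf("  extracellular volume fraction: %.4f (voxel pitch %g nm)\n",
              x$ecs_fraction, x$voxel_pitch))
  cat(sprintf("  astroglial membrane per sector: %.3f um^2\n",
              x$membrane_area_um2[1]))
  invisible(x)
}

#' Point-in-solid predicate
#'
#' Returns `TRUE` for points inside a cellular (solid) region of the model,
#' `FALSE` for extracellular points. Vectorised over rows of `xyz`.
#'
#' @param model A `papsim_geometry`.
#' @param xyz Numeric matrix (n x 3) of coordinates in nm.
#' @export
in_solid_region <- function(model, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  hc <- model$apposition_height / 2
  zc <- model$zc
  R2 <- model$hemisphere_radius^2
  solid <- (z >= hc & x^2 + y^2 + (z - zc)^2 <= R2) |
    (z <= -hc & x^2 + y^2 + (z + zc)^2 <= R2)
  P <- model$obstacle_pitch
  a2 <- model$obstacle_side / 2
  ix <- pmax(-1, pmin(1, round(x / P)))
  iy <- pmax(-1, pmin(1, round(y / P)))
  kz <- pmax(-2, pmin(1, floor(z / P)))
  in_cube <- abs(x - ix * P) <= a2 & abs(y - iy * P) <= a2 &
    abs(z - (kz + 0.5) * P) <= a2
  synapse_cell <- ix == 0 & iy == 0 & (kz == 0 | kz == -1)
  solid | (in_cube & !synapse_cell)
}

#' Azimuthal sector of extracellular points
#'
#' Sectors are quadrants about the synaptic centroid: 1 faces +x, 2 faces +y,
#' 3 faces -x, 4 faces -y.
#'
#' @param model A `papsim_geometry`.
#' @param xyz Numeric matrix (n x 3), nm.
#' @export
sector_of <- function(model, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  phi <- atan2(xyz[, 2], xyz[, 1])
  s <- floor((phi + pi / 4) / (pi / 2)) %% 4
  as.integer(s) + 1L
}

#' Monte Carlo estimate of the extracellular volume fraction
#'
#' Uniform random point sampling over the simulation domain; used as a
#' cross-check of the voxel integration.
#'
#' @param model A `papsim_geometry`.
#' @param n Number of sample points.
#' @param seed RNG seed.
#' @export
ecs_fraction_mc <- function(model, n = 1e6, seed = 1) {
  cpp_ecs_mc(geom_vector(model), as.integer(n), as.double(seed))
}
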