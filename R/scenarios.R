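# Astroglial coverage scenarios and the placement of transporters and
# extrasynaptic NMDAR clusters.

#' Astroglial coverage scenario specification
#'
#' Four patterns of glial glutamate transporter (EAAT1-2 type) coverage:
#' \describe{
#'   \item{baseline}{full perisynaptic band, unit density.}
#'   \item{i}{PAP withdrawal with conserved transporter number: the membrane
#'     sheet retracts away from the synapse carrying all its transporters, so
#'     coverage concentrates on the distal half of the band at doubled
#'     density and the perisynaptic (receptor-level) zone is vacated.}
#'   \item{ii}{PAP withdrawal with transporter loss: the retracting (distal)
#'     membrane is lost together with its transporters, leaving the proximal
#'     half of the band covered at unit density; the total number halves.}
#'   \item{iii}{lateral rearrangement: same area and number, but the occupied
#'     patch is shifted azimuthally toward one side of the nearby NMDAR
#'     cluster, partly exposing it.}
#'   \item{none}{no transporters (control).}
#' }
#' The within-band placement for the withdrawal scenarios is a model choice
#' (the density/area/number contracts are fixed); see the methods vignette.
#'
#' @param id One of `"baseline"`, `"i"`, `"ii"`, `"iii"`, `"none"`.
#' @return A list of class `papsim_scenario` with `density_multiplier`,
#'   `area_multiplier` and `lateral_shift` fields.
#' @export
scenario_spec <- function(id = c("baseline", "i", "ii", "iii", "none")) {
  id <- match.arg(id)
  spec <- switch(id,
    baseline = list(density_multiplier = 1, area_multiplier = 1,
                    lateral_shift = FALSE, retained = "full"),
    i = list(density_multiplier = 2, area_multiplier = 0.5,
             lateral_shift = FALSE, retained = "distal"),
    ii = list(density_multiplier = 1, area_multiplier = 0.5,
              lateral_shift = FALSE, retained = "proximal"),
    iii = list(density_multiplier = 1, area_multiplier = 1,
               lateral_shift = TRUE, retained = "full"),
    none = list(density_multiplier = 0, area_multiplier = 0,
                lateral_shift = FALSE, retained = "none"))
  spec$id <- id
  class(spec) <- "papsim_scenario"
  spec
}

# Occupied rectangles (u = transverse wall coordinate, v = z) for one sector.
# Returns a data.frame with umin, umax, vmin, vmax and the local density
# multiplier. u increases counter-clockwise; the NMDAR cluster sits at u = 0.
scenario_patches <- function(model, scenario, nmdar_side = NULL) {
  uh <- model$band_u_half
  v1 <- model$band_v[1]
  v2 <- model$band_v[2]
  if (scenario$id == "none") {
    return(data.frame(umin = numeric(0), umax = numeric(0),
                      vmin = numeric(0), vmax = numeric(0),
                      dens_mult = numeric(0)))
  }
  if (scenario$lateral_shift) {
    if (is.null(nmdar_side))
      stop("configuration error: scenario iii requires a defined NMDAR-cluster side")
    shift <- uh / 2 * if (identical(nmdar_side, "-u")) -1 else 1
    u <- c(-uh, uh) + shift
    v <- c(v1, v2)
  } else if (scenario$area_multiplier < 1) {
    # withdrawal: which half of the band stays covered depends on whether the
    # retracting membrane keeps its transporters (distal) or sheds them
    # (proximal remains)
    u <- c(-uh, uh)
    vm <- (v1 + v2) / 2
    v <- if (identical(scenario$retained, "proximal")) c(v1, vm) else c(vm, v2)
  } else {
    u <- c(-uh, uh)
    v <- c(v1, v2)
  }
  data.frame(umin = u[1], umax = u[2],
             vmin = c(v[1], -v[2]), vmax = c(v[2], -v[1]),
             dens_mult = scenario$density_multiplier)
}

# map wall-local (u, v) in sector s to xyz on the wall plane
wall_to_xyz <- function(model, s, u, v) {
  cb <- model$wall_distance
  switch(s,
         cbind(cb, u, v),
         cbind(-u, cb, v),
         cbind(-cb, -u, v),
         cbind(u, -cb, v))
}

#' Place glial glutamate transporters under a coverage scenario
#'
#' Transporters are distributed uniformly over the occupied astroglial
#' membrane patches of each sector at the local surface density implied by
#' the scenario. The baseline count per sector is
#' `N0 = surface_density x membrane area`; scenarios i and iii conserve N0,
#' scenario ii yields N0/2 (up to rounding).
#'
#' @param model A `papsim_geometry`.
#' @param scenario A single [scenario_spec()] (applied to all sectors) or a
#'   list of 4 specs, one per sector.
#' @param surface_density Transporter surface density, um^-2 (default 7500,
#'   in the reported 5-10 x 10^3 um^-2 range).
#' @param seed RNG seed for position sampling.
#' @param nmdar_side Which transverse side of the cluster scenario iii shifts
#'   toward (`"+u"` or `"-u"`); required when scenario iii is requested.
#' @param capture_area Per-transporter capture cross-section (nm^2) used to
#'   convert local density into a per-collision capture probability
#'   `1 - exp(-density x capture_area)`.
#' @return A `papsim_transporters` object: `positions` (data.frame x, y, z,
#'   sector), per-sector `counts`, capture `patches` for the engine, and the
#'   scenario ids.
#' @export
place_transporters <- function(model, scenario = scenario_spec("baseline"),
                               surface_density = 7500, seed = 1,
                               nmdar_side = NULL, capture_area = 30) {
  if (surface_density < 0)
    stop("configuration error: surface density must be >= 0")
  scenarios <- if (inherits(scenario, "papsim_scenario")) {
    rep(list(scenario), 4L)
  } else {
    stopifnot(length(scenario) == 4L)
    lapply(scenario, function(s) if (is.character(s)) scenario_spec(s) else s)
  }
  dens_nm2 <- surface_density * 1e-6  # um^-2 -> nm^-2

  set.seed(seed)
  all_patches <- NULL
  pos <- vector("list", 4L)
  counts <- integer(4L)
  for (s in 1:4) {
    pp <- scenario_patches(model, scenarios[[s]], nmdar_side = nmdar_side)
    if (nrow(pp) == 0 || dens_nm2 == 0) {
      pos[[s]] <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                             sector = integer(0))
      next
    }
    area <- (pp$umax - pp$umin) * (pp$vmax - pp$vmin)
    n_tot <- round(dens_nm2 * pp$dens_mult[1] * sum(area))
    n_per <- floor(n_tot * area / sum(area))
    rem <- n_tot - sum(n_per)
    if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
    xyz <- do.call(rbind, lapply(seq_len(nrow(pp)), function(r) {
      if (n_per[r] == 0) return(NULL)
      u <- runif(n_per[r], pp$umin[r], pp$umax[r])
      v <- runif(n_per[r], pp$vmin[r], pp$vmax[r])
      wall_to_xyz(model, s, u, v)
    }))
    if (is.null(xyz)) xyz <- matrix(numeric(0), ncol = 3)
    pos[[s]] <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           sector = rep(s, nrow(xyz)))
    counts[s] <- n_tot
    pcap <- -expm1(-dens_nm2 * pp$dens_mult * capture_area)
    all_patches <- rbind(all_patches,
                         cbind(sector = s, as.matrix(pp[, 1:4]), pcap = pcap))
  }
  if (is.null(all_patches))
    all_patches <- matrix(numeric(0), ncol = 6,
                          dimnames = list(NULL, c("sector", "umin", "umax",
                                                  "vmin", "vmax", "pcap")))
  out <- list(positions = do.call(rbind, pos),
              counts = counts,
              patches = all_patches,
              scenario = vapply(scenarios, `[[`, "", "id"),
              surface_density = surface_density,
              capture_area = capture_area,
              seed = seed)
  class(out) <- "papsim_transporters"
  out
}

#' Place an extrasynaptic NMDAR cluster in each sector
#'
#' Receptors are placed on the postsynaptic-side membrane (the lower
#' hemisphere surface) within a radial band from the synaptic centroid,
#' clustered around each sector's azimuth centre. The default 200-250 nm band
#' is approximately equidistant to the nearest-neighbouring synapses.
#'
#' @param model A `papsim_geometry`.
#' @param cluster_band Radial distance band (min, max) in nm.
#' @param n_receptors Receptors per sector cluster.
#' @param seed RNG seed.
#' @param half_angle Azimuthal half-width of each cluster (radians).
#' @return A `papsim_receptors` object with `positions` (x, y, z, sector) and
#'   the radial distances.
#' @export
place_nmdars <- function(model, cluster_band = model$nmdar_cluster_band,
                         n_receptors = 20, seed = 1, half_angle = pi / 12) {
  stopifnot(length(cluster_band) == 2, cluster_band[1] <= cluster_band[2])
  zc <- model$zc
  R <- model$hemisphere_radius
  hc <- model$apposition_height / 2
  # on the postsynaptic sphere, |p|^2 = R^2 - zc^2 - 2 zc z
  z_of_r <- function(r) (R^2 - zc^2 - r^2) / (2 * zc)
  zr <- z_of_r(cluster_band)
  if (any(zr > -hc) || any(cluster_band^2 - zr^2 < 0) || any(zr < -(zc + R)))
    stop("configuration error: NMDAR cluster band outside the postsynaptic membrane")

  set.seed(seed)
  centres <- c(0, pi / 2, pi, -pi / 2)
  pos <- do.call(rbind, lapply(1:4, function(s) {
    if (n_receptors == 0)
      return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        sector = integer(0)))
    r <- runif(n_receptors, cluster_band[1], cluster_band[2])
    phi <- centres[s] + runif(n_receptors, -half_angle, half_angle)
    z <- z_of_r(r)
    rho <- sqrt(r^2 - z^2)
    data.frame(x = rho * cos(phi), y = rho * sin(phi), z = z,
               sector = rep(s, n_receptors))
  }))
  out <- list(positions = pos,
              radial_distance = sqrt(pos$x^2 + pos$y^2 + pos$z^2),
              cluster_band = cluster_band,
              n_per_sector = n_receptors,
              seed = seed)
  class(out) <- "papsim_receptors"
  out
}
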