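# Cylindrical phantom scenarios: voxel grids, ROI masks, oxygen-tension
# maps and water-equivalent depth along arbitrary gantry angles.
#
# Geometry convention: isocenter at the origin; the cylinder axis is z;
# gantry angles rotate clockwise from +y in the axial (x,y) plane. Grids
# are stored as (in-plane point) x (axial slice) matrices: only voxel
# centers inside the phantom circle are kept, which makes the pencil-beam
# accumulation dense and compact.

.PHANTOM_R <- 100   # mm
.PHANTOM_H <- 200   # mm
.TARGET_R <- 30     # mm
.TARGET_H <- 60     # mm
.CORE_R <- 5        # mm

#' Build a phantom scenario
#'
#' Case A is the simple study: a water cylinder (H = 200 mm, r = 100 mm)
#' with a cylindrical target at isocenter (H = 60 mm, r = 30 mm) and an
#' r = 5 mm core. Case B adds a cylindrical organ at risk (default r = 10 mm,
#' H = 60 mm) on the +x side with a 5 mm radial surface gap to the target.
#'
#' @param case_id `"A"` or `"B"`.
#' @param voxel_size voxel edge, mm; one of 1, 2, 4.
#' @param oar_gap target-to-OAR surface gap, mm (case B; default 5).
#' @param oar_radius OAR cylinder radius, mm (default 10).
#' @param slab_half_height if not `NULL`, restrict the grid axially to
#'   `|z| <= slab_half_height` (mm) — a reduced evaluation domain for fast
#'   runs; masks and metrics are otherwise identical in the slab interior.
#' @return a `scenario` object with in-plane coordinates `xy`, slice centers
#'   `zc`, logical mask matrices (`phantom`, `target`, `core`, `oar`,
#'   `shell`, `normal`) and bookkeeping fields.
#' @export
build_scenario <- function(case_id = c("A", "B"), voxel_size = 2,
                           oar_gap = 5, oar_radius = 10,
                           slab_half_height = NULL) {
  case_id <- match.arg(case_id)
  if (!voxel_size %in% c(1, 2, 4))
    stop("voxel_size must be 1, 2 or 4 mm")
  if (voxel_size > oar_gap)
    stop("voxel size cannot resolve the target-OAR gap")
  half_h <- if (is.null(slab_half_height)) .PHANTOM_H / 2 else slab_half_height

  n1 <- ceiling(.PHANTOM_R / voxel_size)
  ax <- (seq(-n1, n1 - 1) + 0.5) * voxel_size
  g <- expand.grid(x = ax, y = ax)
  r2 <- g$x^2 + g$y^2
  keep <- r2 <= .PHANTOM_R^2
  xy <- as.matrix(g[keep, ])
  r <- sqrt(r2[keep])

  nzh <- ceiling(half_h / voxel_size)
  zc <- (seq(-nzh, nzh - 1) + 0.5) * voxel_size

  in_h <- function(h) matrix(rep(abs(zc) <= h / 2, each = nrow(xy)),
                             nrow(xy), length(zc))
  radial <- function(rmax) matrix(r <= rmax, nrow(xy), length(zc))
  phantom <- radial(.PHANTOM_R)
  target <- radial(.TARGET_R) & in_h(.TARGET_H)
  core <- radial(.CORE_R) & in_h(.TARGET_H)

  # lateral fall-off shell: within 5 mm of the target surface
  dist_surf <- pmax(r - .TARGET_R, 0)
  shell_rad <- matrix(r > .TARGET_R & r <= .TARGET_R + 5, nrow(xy), length(zc))
  zdist <- pmax(abs(rep(zc, each = nrow(xy))) - .TARGET_H / 2, 0)
  ldist <- sqrt(matrix(dist_surf, nrow(xy), length(zc))^2 +
                matrix(zdist, nrow(xy), length(zc))^2)
  shell <- !target & ldist <= 5 & phantom

  oar <- NULL
  if (case_id == "B") {
    x0 <- .TARGET_R + oar_gap + oar_radius
    roar <- sqrt((xy[, 1] - x0)^2 + xy[, 2]^2)
    oar <- matrix(roar <= oar_radius, nrow(xy), length(zc)) & in_h(.TARGET_H)
  } else {
    oar <- matrix(FALSE, nrow(xy), length(zc))
  }
  normal <- phantom & !target & !oar

  structure(list(case_id = case_id, voxel_size = voxel_size,
                 xy = xy, r = r, zc = zc,
                 phantom = phantom, target = target, core = core,
                 oar = oar, shell = shell, normal = normal,
                 shell_dist = ldist,
                 oar_gap = oar_gap, oar_radius = oar_radius,
                 slab_half_height = slab_half_height,
                 po2 = NULL), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> case %s, %g mm voxels, %d in-plane points x %d slices\n",
              x$case_id, x$voxel_size, nrow(x$xy), length(x$zc)))
  cat(sprintf("  target %d voxels, core %d, OAR %d\n",
              sum(x$target), sum(x$core), sum(x$oar)))
  invisible(x)
}

#' Oxygen-tension map with a radial hypoxia gradient
#'
#' Assigns 9 logarithmically spaced pO2 levels from 5% (outer target ring)
#' to 0.25% (inner core) over 9 equal-width radial shells between r = 30 mm
#' and r = 5 mm; the r <= 5 mm core shares the innermost 0.25% level and
#' everything outside the target is normoxic at 21%.
#'
#' @param scenario a [build_scenario()] object.
#' @return the scenario with a `po2` matrix (% O2 per voxel) and
#'   `po2_levels` attached.
#' @export
build_po2_map <- function(scenario) {
  levels <- 5 * (0.25 / 5)^((0:8) / 8)
  edges <- seq(.TARGET_R, .CORE_R, length.out = 10)   # outer -> inner shells
  rmat <- matrix(scenario$r, nrow(scenario$xy), length(scenario$zc))
  po2 <- matrix(21, nrow(scenario$xy), length(scenario$zc))
  idx <- pmin(findInterval(-rmat, -edges), 9)          # shell number, 1 = outer
  inside <- scenario$target
  po2[inside] <- levels[idx[inside]]
  scenario$po2 <- po2
  scenario$po2_levels <- levels
  scenario
}

#' Water-equivalent depth of a point along a gantry angle
#'
#' For the homogeneous water cylinder the radiological depth equals the
#' geometric distance from the beam entry point on the cylinder surface,
#' measured along the beam direction.
#'
#' @param scenario a [build_scenario()] object.
#' @param point numeric length-3 (x, y, z) in mm; must lie inside the phantom.
#' @param gantry_angle degrees, clockwise from +y.
#' @return depth in mm.
#' @export
radiological_depth <- function(scenario, point, gantry_angle) {
  stopifnot(length(point) == 3)
  if (point[1]^2 + point[2]^2 > .PHANTOM_R^2 ||
      abs(point[3]) > .PHANTOM_H / 2)
    stop("point outside phantom")
  th <- gantry_angle * pi / 180
  u <- point[1] * cos(th) - point[2] * sin(th)
  t <- -point[1] * sin(th) - point[2] * cos(th)
  t + sqrt(.PHANTOM_R^2 - u^2)
}

# beam-frame coordinates of all in-plane points for one angle:
# lateral offset u and water depth d (NA where the ray misses the phantom)
scenario_beam_frame <- function(scenario, gantry_angle) {
  th <- gantry_angle * pi / 180
  x <- scenario$xy[, 1]; y <- scenario$xy[, 2]
  u <- x * cos(th) - y * sin(th)
  t <- -x * sin(th) - y * cos(th)
  inside <- u^2 < .PHANTOM_R^2
  d <- rep(NA_real_, length(u))
  d[inside] <- t[inside] + sqrt(.PHANTOM_R^2 - u[inside]^2)
  list(u = u, depth = d)
}
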