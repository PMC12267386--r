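# Body-relative calibration and the nine-location stimulus grid.
#
# Frame convention: meters, +y up, +z participant-forward, +x participant's
# right (right-handed). All grid geometry is expressed relative to location b,
# the sternum anchor recorded during calibration.

vec3 <- function(x, y, z) {
  v <- c(x, y, z)
  if (length(v) != 3L || !is.numeric(v) || !all(is.finite(v)))
    stop("a 3D point needs three finite numeric coordinates", call. = FALSE)
  unname(v)
}

as_vec3 <- function(p) {
  if (is.list(p)) p <- unlist(p[c("x", "y", "z")])
  vec3(p[[1]], p[[2]], p[[3]])
}

vnorm <- function(v) sqrt(sum(v * v))

#' Calibrate the body-relative reach geometry
#'
#' Records the two calibration anchors of the reach instrument: `location_b`,
#' the controller position held against the sternum, and `location_r`, the
#' position with the dominant arm extended forward at shoulder level. The reach
#' distance `d` is their straight-line (Euclidean) separation and scales all
#' stimulus placement for the participant.
#'
#' @param location_b Numeric length-3, sternum anchor in meters.
#' @param location_r Numeric length-3, extended-arm anchor in meters.
#' @return An object of class `rt_calibration`: a list with elements
#'   `location_b`, `location_r` and `distance_d`.
#' @examples
#' cal <- calibrate(c(0, 1.2, 0), c(0, 1.2, 0.5))
#' cal$distance_d  # 0.5
#' @export
calibrate <- function(location_b, location_r) {
  b <- as_vec3(location_b)
  r <- as_vec3(location_r)
  d <- vnorm(r - b)
  if (d <= 0)
    stop("invalid calibration: location_r coincides with location_b", call. = FALSE)
  structure(list(location_b = b, location_r = r, distance_d = d),
            class = "rt_calibration")
}

#' @export
print.rt_calibration <- function(x, ...) {
  cat(sprintf("Reach calibration: d = %.4f m\n  b = (%.3f, %.3f, %.3f)\n  r = (%.3f, %.3f, %.3f)\n",
              x$distance_d, x$location_b[1], x$location_b[2], x$location_b[3],
              x$location_r[1], x$location_r[2], x$location_r[3]))
  invisible(x)
}

# Unit direction at elevation e and azimuth a (degrees) in the frame whose
# basis is (right, up, forward). Positive a is the participant's right.
grid_direction <- function(elevation_deg, azimuth_deg) {
  e <- elevation_deg * pi / 180
  a <- azimuth_deg * pi / 180
  c(cos(e) * sin(a), sin(e), cos(e) * cos(a))
}

# row-major numbering, 1 = upper-left ... 9 = lower-right, 5 central
GRID_ELEVATIONS <- c(30, 30, 30, 0, 0, 0, -30, -30, -30)
GRID_AZIMUTHS   <- c(-35, 0, 35, -35, 0, 35, -35, 0, 35)

#' Build the nine-location stimulus grid
#'
#' Places nine stimulus locations on a sphere of radius `distance_d` centered
#' on `location_b`. Location 5, the central location, lies straight ahead of
#' the sternum anchor (aligned with it on the vertical and horizontal axes);
#' the others are offset by `elevation_deg` above/below and `azimuth_deg` to
#' the participant's left/right. Locations are numbered row-major from the
#' upper-left (1) to the lower-right (9).
#'
#' Each location is `b + d * dir(e, a)` with
#' `dir(e, a) = cos(e) sin(a) * right + sin(e) * up + cos(e) cos(a) * forward`,
#' which keeps every location exactly at distance `d` from `b`, including the
#' corner locations that combine both angular offsets.
#'
#' @param cal An `rt_calibration`.
#' @param forward Length-3 horizontal direction the participant faces
#'   (default +z). Its vertical component must be zero-dominant; the vector is
#'   projected to the horizontal plane and normalized.
#' @param elevation_deg Vertical offset of the upper/lower rows, degrees
#'   (default 30).
#' @param azimuth_deg Lateral offset of the left/right columns, degrees
#'   (default 35).
#' @return An `rt_grid`: list with `locations` (9 x 3 matrix, meters, rows
#'   `loc1`..`loc9`), `elevation_deg`, `azimuth_deg`, and the calibration.
#' @examples
#' cal <- calibrate(c(0, 1.2, 0), c(0, 1.2, 0.5))
#' g <- build_grid(cal)
#' g$locations["loc5", ]  # (0, 1.2, 0.5)
#' @export
build_grid <- function(cal, forward = c(0, 0, 1), elevation_deg = 30,
                       azimuth_deg = 35) {
  stopifnot(inherits(cal, "rt_calibration"))
  if (elevation_deg <= 0 || elevation_deg >= 90 || azimuth_deg <= 0 || azimuth_deg >= 90)
    stop("grid angles must lie in (0, 90) degrees", call. = FALSE)
  f <- as_vec3(forward)
  f[2] <- 0                       # horizontal-plane direction
  nf <- vnorm(f)
  if (nf < 1e-12)
    stop("forward must be a nonzero horizontal direction", call. = FALSE)
  f <- f / nf
  up <- c(0, 1, 0)
  right <- c(up[2] * f[3] - up[3] * f[2],
             up[3] * f[1] - up[1] * f[3],
             up[1] * f[2] - up[2] * f[1])  # up x forward
  basis <- cbind(right, up, f)
  locs <- t(vapply(seq_len(9), function(i) {
    dir_local <- grid_direction(GRID_ELEVATIONS[i], GRID_AZIMUTHS[i])
    cal$location_b + cal$distance_d * as.numeric(basis %*% dir_local)
  }, numeric(3)))
  dimnames(locs) <- list(paste0("loc", 1:9), c("x", "y", "z"))
  structure(list(locations = locs, elevation_deg = elevation_deg,
                 azimuth_deg = azimuth_deg, calibration = cal),
            class = "rt_grid")
}

#' @export
print.rt_grid <- function(x, ...) {
  cat(sprintf("Stimulus grid: 9 locations at d = %.4f m (elevation %g deg, azimuth %g deg)\n",
              x$calibration$distance_d, x$elevation_deg, x$azimuth_deg))
  print(round(x$locations, 4))
  invisible(x)
}

#' Test whether the controller is inside the base sphere
#'
#' The base position is a small sphere centered on `location_b`; participants
#' hold the controller there between reach trials. Membership is inclusive at
#' the boundary.
#'
#' @param p Length-3 controller position, meters.
#' @param cal An `rt_calibration`.
#' @param radius Base-sphere radius in meters (default 0.028).
#' @return Logical.
#' @export
in_base <- function(p, cal, radius = 0.028) {
  stopifnot(inherits(cal, "rt_calibration"), radius > 0)
  vnorm(as_vec3(p) - cal$location_b) <= radius
}

#' Construct a cube stimulus
#'
#' @param face_center Length-3 front-face center, meters (placed on a grid
#'   location).
#' @param edge Cube edge length in meters (default 0.10).
#' @param color One of `"yellow"`, `"green"`, `"blue"`, `"red"`.
#' @return An object of class `rt_cube`.
#' @export
cube_stimulus <- function(face_center, edge = 0.10,
                          color = c("yellow", "green", "blue", "red")) {
  color <- match.arg(color)
  if (edge <= 0) stop("cube edge must be positive", call. = FALSE)
  structure(list(face_center = as_vec3(face_center), edge = edge, color = color),
            class = "rt_cube")
}

#' Test whether a point lies inside a cube's touch volume
#'
#' The cube's front face is centered on its grid location and faces the
#' participant; its body extends away from the participant behind the face.
#' The touch volume is the full solid: within `edge/2` of the face center
#' laterally and vertically, and within `[0, edge]` beyond the face plane along
#' the inward direction. All boundaries are inclusive.
#'
#' @param p Length-3 point, meters.
#' @param cube An `rt_cube`.
#' @param inward Length-3 direction from the participant toward the cube
#'   (the b-to-face-center direction); need not be unit length.
#' @return Logical.
#' @export
cube_contains <- function(p, cube, inward) {
  stopifnot(inherits(cube, "rt_cube"))
  w <- as_vec3(inward)
  nw <- vnorm(w)
  if (nw < 1e-12) stop("inward direction must be nonzero", call. = FALSE)
  w <- w / nw
  up <- c(0, 1, 0)
  lat <- c(up[2] * w[3] - up[3] * w[2],
           up[3] * w[1] - up[1] * w[3],
           up[1] * w[2] - up[2] * w[1])  # up x inward
  nl <- vnorm(lat)
  if (nl < 1e-9) lat <- c(1, 0, 0) else lat <- lat / nl
  vert <- c(w[2] * lat[3] - w[3] * lat[2],
            w[3] * lat[1] - w[1] * lat[3],
            w[1] * lat[2] - w[2] * lat[1])  # inward x lat
  rel <- as_vec3(p) - cube$face_center
  h <- cube$edge / 2
  depth <- sum(rel * w)
  abs(sum(rel * lat)) <= h + 1e-12 &&
    abs(sum(rel * vert)) <= h + 1e-12 &&
    depth >= -1e-12 && depth <= cube$edge + 1e-12
}

#' Specify the motion of a dynamic-task cube
#'
#' @param origin_index,target_index Grid indices 1..9; the cube appears at the
#'   origin location moving toward the target location. Must differ.
#' @param speed Constant speed in m/s.
#' @return An object of class `rt_motion`.
#' @export
motion_spec <- function(origin_index, target_index, speed) {
  stopifnot(origin_index %in% 1:9, target_index %in% 1:9, speed > 0)
  if (origin_index == target_index)
    stop("motion target must differ from origin", call. = FALSE)
  structure(list(origin_index = as.integer(origin_index),
                 target_index = as.integer(target_index),
                 speed = speed), class = "rt_motion")
}

#' Position of a moving cube at a given time since onset
#'
#' Dynamic-task cubes appear at the origin location and translate at constant
#' speed along the straight line toward the target location. Motion continues
#' along that line past the target until stimulus offset.
#'
#' @param grid An `rt_grid`.
#' @param motion An `rt_motion`.
#' @param t Time since stimulus onset, seconds (non-negative).
#' @return Length-3 face-center position at time `t`, meters.
#' @export
cube_position_at <- function(grid, motion, t) {
  stopifnot(inherits(grid, "rt_grid"), inherits(motion, "rt_motion"))
  if (any(t < 0)) stop("time since onset must be non-negative", call. = FALSE)
  o <- grid$locations[motion$origin_index, ]
  tg <- grid$locations[motion$target_index, ]
  u <- (tg - o) / vnorm(tg - o)
  if (length(t) == 1L) return(unname(o + motion$speed * t * u))
  t(vapply(t, function(ti) unname(o + motion$speed * ti * u), numeric(3)))
}
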