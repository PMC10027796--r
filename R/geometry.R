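# 3D math: vectors, quaternions, poses, rays, primitive intersections.
#
# Coordinate frame convention (fixed package-wide): X right, Y up, Z forward
# (away from the participant), units meters, right-handed. Lateral target
# offsets are +/- X. Orientations are stored as unit quaternions and exported
# as yaw(Y)-pitch(X)-roll(Z) Euler angles in degrees.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Create a 3D vector
#'
#' A plain numeric vector of length 3 (x, y, z) in meters (unitless for
#' directions). All positions and directions in the package use this
#' representation.
#'
#' @param x,y,z Finite numeric components.
#' @return Numeric vector \code{c(x, y, z)}.
#' @export
vec3 <- function(x = 0, y = 0, z = 0) {
  v <- c(as.numeric(x), as.numeric(y), as.numeric(z))
  if (!all(is.finite(v))) stop("vec3 components must be finite")
  v
}

vec3_norm <- function(v) sqrt(sum(v * v))

vec3_normalize <- function(v) {
  n <- vec3_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

vec3_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# --- quaternions (w, x, y, z), always unit norm -----------------------------

#' Identity quaternion
#' @return Numeric vector \code{c(w, x, y, z) = c(1, 0, 0, 0)}.
#' @export
quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < 1e-12) stop("degenerate quaternion")
  q / n
}

#' Quaternion from an axis-angle rotation
#' @param axis Rotation axis (normalized internally).
#' @param angle_deg Rotation angle in degrees (right-handed about \code{axis}).
#' @return Unit quaternion \code{c(w, x, y, z)}.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- vec3_normalize(axis)
  h <- angle_deg * DEG2RAD / 2
  c(cos(h), sin(h) * axis)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conjugate <- function(q) c(q[1], -q[2:4])

# Rotate vector v by unit quaternion q: v' = v + 2 u x (u x v + w v)
quat_rotate <- function(q, v) {
  u <- q[2:4]
  t <- 2 * vec3_cross(u, v)
  v + q[1] * t + vec3_cross(u, t)
}

#' Quaternion from yaw-pitch-roll Euler angles
#'
#' Composition order is yaw about +Y, then pitch about +X, then roll about +Z
#' (intrinsic), i.e. \code{R = Ry(yaw) Rx(pitch) Rz(roll)}.
#'
#' @param yaw,pitch,roll Angles in degrees.
#' @return Unit quaternion.
#' @export
quat_from_euler <- function(yaw = 0, pitch = 0, roll = 0) {
  qy <- quat_from_axis_angle(c(0, 1, 0), yaw)
  qx <- quat_from_axis_angle(c(1, 0, 0), pitch)
  qz <- quat_from_axis_angle(c(0, 0, 1), roll)
  quat_normalize(quat_multiply(quat_multiply(qy, qx), qz))
}

#' Yaw-pitch-roll Euler angles from a quaternion
#' @param q Unit quaternion.
#' @return Named numeric vector \code{c(yaw, pitch, roll)} in degrees.
#' @export
quat_to_euler <- function(q) {
  # From R = Ry(yaw) Rx(pitch) Rz(roll): m23 = -sin(pitch),
  # yaw = atan2(m13, m33), roll = atan2(m21, m22).
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  m23 <- 2 * (y * z - w * x)
  pitch <- asin(max(-1, min(1, -m23)))
  if (abs(abs(m23) - 1) < 1e-9) {
    # gimbal lock: put all remaining rotation into yaw
    yaw <- atan2(2 * (x * z + w * y), 1 - 2 * (y * y + z * z))
    roll <- 0
  } else {
    m13 <- 2 * (x * z + w * y)
    m33 <- 1 - 2 * (x * x + y * y)
    yaw <- atan2(m13, m33)
    m21 <- 2 * (x * y + w * z)
    m22 <- 1 - 2 * (x * x + z * z)
    roll <- atan2(m21, m22)
  }
  c(yaw = yaw * RAD2DEG, pitch = pitch * RAD2DEG, roll = roll * RAD2DEG)
}

# --- poses ------------------------------------------------------------------

#' Create a rigid pose (position + orientation)
#'
#' @param position \code{\link{vec3}} position in meters.
#' @param orientation Unit quaternion (default identity). Alternatively pass
#'   Euler angles via \code{yaw}, \code{pitch}, \code{roll} in degrees.
#' @param yaw,pitch,roll Euler angles in degrees, used when
#'   \code{orientation} is \code{NULL}.
#' @return An object of class \code{"vr_pose"}.
#' @export
pose <- function(position = vec3(), orientation = NULL,
                 yaw = 0, pitch = 0, roll = 0) {
  q <- if (is.null(orientation)) quat_from_euler(yaw, pitch, roll)
       else quat_normalize(orientation)
  structure(list(position = position, orientation = q), class = "vr_pose")
}

#' @export
print.vr_pose <- function(x, ...) {
  e <- quat_to_euler(x$orientation)
  cat(sprintf("<pose> pos (%.3f, %.3f, %.3f) m, ypr (%.1f, %.1f, %.1f) deg\n",
              x$position[1], x$position[2], x$position[3],
              e[1], e[2], e[3]))
  invisible(x)
}

#' Transform a local point or direction into world space
#'
#' Points are rotated then translated by the pose; directions are rotated
#' only and renormalized to unit length.
#'
#' @param pose A \code{\link{pose}}.
#' @param local A \code{\link{vec3}} in the pose's local frame.
#' @return The world-space \code{vec3}.
#' @export
transform_point <- function(pose, local) {
  quat_rotate(pose$orientation, local) + pose$position
}

#' @rdname transform_point
#' @export
transform_direction <- function(pose, local) {
  if (vec3_norm(local) < 1e-12)
    stop("cannot transform a zero-length direction", call. = FALSE)
  vec3_normalize(quat_rotate(pose$orientation, local))
}

#' Inverse-transform a world point or direction into a pose's local frame
#' @inheritParams transform_point
#' @param world A world-space \code{vec3}.
#' @export
inverse_transform_point <- function(pose, world) {
  quat_rotate(quat_conjugate(pose$orientation), world - pose$position)
}

#' @rdname inverse_transform_point
#' @export
inverse_transform_direction <- function(pose, world) {
  if (vec3_norm(world) < 1e-12)
    stop("cannot transform a zero-length direction", call. = FALSE)
  vec3_normalize(quat_rotate(quat_conjugate(pose$orientation), world))
}

# --- rays and primitives ----------------------------------------------------

#' Create a ray
#' @param origin World-space \code{\link{vec3}} origin.
#' @param direction Direction vector (normalized internally).
#' @return An object of class \code{"vr_ray"}.
#' @export
ray <- function(origin, direction) {
  structure(list(origin = origin, direction = vec3_normalize(direction)),
            class = "vr_ray")
}

#' Scene primitives
#'
#' Geometric primitives used as visual stimuli and raycast targets. Each has
#' an \code{id}, a \code{visible} flag (whether the object is rendered) and a
#' \code{pickable} flag (whether it participates in gaze raycasts); the two
#' flags are independent, so an invisible object can still intercept gaze
#' rays (used for the invisible gaze-recording plane).
#'
#' @param id Unique object identifier string.
#' @param center World-space center \code{\link{vec3}}.
#' @param radius Sphere radius in meters (> 0).
#' @param half_extents Box half side lengths \code{vec3} (> 0).
#' @param orientation Box orientation quaternion.
#' @param normal Plane normal vector.
#' @param width,height Plane extents in meters (> 0).
#' @param visible,pickable Logical flags.
#' @return An object of class \code{"vr_primitive"}.
#' @name scene_primitives
NULL

#' @rdname scene_primitives
#' @export
sphere <- function(id, center, radius, visible = TRUE, pickable = TRUE) {
  stopifnot(radius > 0)
  structure(list(id = id, shape = "sphere", center = center, radius = radius,
                 visible = visible, pickable = pickable),
            class = "vr_primitive")
}

#' @rdname scene_primitives
#' @export
box <- function(id, center, half_extents, orientation = quat_identity(),
                visible = TRUE, pickable = TRUE) {
  stopifnot(all(half_extents > 0))
  structure(list(id = id, shape = "box", center = center,
                 half_extents = half_extents,
                 orientation = quat_normalize(orientation),
                 visible = visible, pickable = pickable),
            class = "vr_primitive")
}

#' @rdname scene_primitives
#' @export
rect_plane <- function(id, center, normal, width, height,
                       visible = TRUE, pickable = TRUE) {
  stopifnot(width > 0, height > 0)
  n <- vec3_normalize(normal)
  up <- if (abs(n[2]) > 1 - 1e-9) c(0, 0, 1) else c(0, 1, 0)
  u <- vec3_normalize(vec3_cross(up, n))   # in-plane "width" axis
  v <- vec3_cross(n, u)                    # in-plane "height" axis
  structure(list(id = id, shape = "rect_plane", center = center, normal = n,
                 width = width, height = height, u = u, v = v,
                 visible = visible, pickable = pickable),
            class = "vr_primitive")
}

#' Intersect a ray with a scene primitive
#'
#' Returns the closest intersection at parameter \code{t >= 0}. Grazing hits
#' (tangent rays) count as hits. A ray starting inside a sphere or box hits
#' the surface on the way out.
#'
#' @param ray A \code{\link{ray}}.
#' @param prim A \code{\link{scene_primitives}} object.
#' @return \code{NULL} on a miss, else \code{list(t = <meters>,
#'   point = <vec3>)}.
#' @export
intersect_ray <- function(ray, prim) {
  hit_t <- switch(prim$shape,
    sphere = {
      oc <- ray$origin - prim$center
      b <- sum(oc * ray$direction)
      cc <- sum(oc * oc) - prim$radius^2
      disc <- b * b - cc
      if (disc < -1e-12) NULL else {
        s <- sqrt(max(disc, 0))
        t1 <- -b - s
        t2 <- -b + s
        if (t1 >= 0) t1 else if (t2 >= 0) t2 else NULL
      }
    },
    box = {
      # slab test in the box's local frame
      inv <- quat_conjugate(prim$orientation)
      o <- quat_rotate(inv, ray$origin - prim$center)
      d <- quat_rotate(inv, ray$direction)
      tmin <- -Inf; tmax <- Inf
      ok <- TRUE
      for (ax in 1:3) {
        if (abs(d[ax]) < 1e-12) {
          if (abs(o[ax]) > prim$half_extents[ax]) { ok <- FALSE; break }
        } else {
          ta <- (-prim$half_extents[ax] - o[ax]) / d[ax]
          tb <- (prim$half_extents[ax] - o[ax]) / d[ax]
          tmin <- max(tmin, min(ta, tb))
          tmax <- min(tmax, max(ta, tb))
        }
      }
      if (!ok || tmin > tmax + 1e-12 || tmax < 0) NULL
      else if (tmin >= 0) tmin else tmax
    },
    rect_plane = {
      denom <- sum(ray$direction * prim$normal)
      if (abs(denom) < 1e-12) NULL else {
        t <- sum((prim$center - ray$origin) * prim$normal) / denom
        if (t < 0) NULL else {
          p <- ray$origin + t * ray$direction
          rel <- p - prim$center
          if (abs(sum(rel * prim$u)) <= prim$width / 2 + 1e-12 &&
              abs(sum(rel * prim$v)) <= prim$height / 2 + 1e-12) t else NULL
        }
      }
    },
    stop("unknown primitive shape: ", prim$shape)
  )
  if (is.null(hit_t)) return(NULL)
  list(t = hit_t, point = ray$origin + hit_t * ray$direction)
}

#' Closest intersection of a ray with a set of primitives
#'
#' Only \code{pickable} primitives participate. Ties (equal \code{t}) are
#' broken by registration order.
#'
#' @param ray A \code{\link{ray}}.
#' @param prims A list of primitives.
#' @return \code{NULL} if nothing is hit, else
#'   \code{list(id, t, point)} for the nearest hit.
#' @export
closest_intersection <- function(ray, prims) {
  best <- NULL
  for (prim in prims) {
    if (!isTRUE(prim$pickable)) next
    hit <- intersect_ray(ray, prim)
    if (!is.null(hit) && (is.null(best) || hit$t < best$t)) {
      best <- list(id = prim$id, t = hit$t, point = hit$point)
    }
  }
  best
}

#' Angular distance between two directions
#'
#' The scalar angle between two (not necessarily unit) vectors, computed as
#' the arccosine of the clamped normalized dot product.
#'
#' @param a,b Nonzero \code{\link{vec3}} directions.
#' @return Angle in degrees, in \code{[0, 180]}.
#' @export
angular_distance <- function(a, b) {
  na <- vec3_norm(a); nb <- vec3_norm(b)
  if (na < 1e-12 || nb < 1e-12)
    stop("angular_distance is undefined for zero vectors", call. = FALSE)
  d <- sum(a * b) / (na * nb)
  acos(max(-1, min(1, d))) * RAD2DEG
}
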