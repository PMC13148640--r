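#' Muscle wrapping surface
#'
#' An analytic obstacle (cylinder or sphere) attached to a bone frame that
#' deflects a muscle path when the straight chord between two consecutive
#' path points penetrates it. `active_side` selects which tangent family
#' the path may take around a cylinder (+1 or -1, the sign of the 2D
#' cross product of the chord direction with the detour direction in the
#' cylinder cross-section plane); it is never flipped automatically.
#'
#' @param kind "cylinder" or "sphere".
#' @param bone name of the bone the surface is attached to.
#' @param transform 4 x 4 local transform of the surface frame in
#'   bone-local coordinates (cylinder axis = local z).
#' @param radius surface radius (m).
#' @param half_length cylinder half-length (m; informational).
#' @param active_side +1 or -1 (cylinders only).
#' @return object of class `wrap_surface`.
#' @export
wrap_surface <- function(kind = c("cylinder", "sphere"), bone,
                         transform = diag(4), radius,
                         half_length = Inf, active_side = 1) {
  kind <- match.arg(kind)
  if (radius <= 0) stop("wrap radius must be positive")
  if (!active_side %in% c(-1, 1)) stop("active_side must be +1 or -1")
  structure(list(kind = kind, bone = bone, transform = transform,
                 radius = radius, half_length = half_length,
                 active_side = active_side),
            class = "wrap_surface")
}

#' Muscle path
#'
#' An ordered polyline of attachment points (origin, optional via points,
#' insertion), each fixed in a bone's local frame, plus wrapping surfaces
#' assigned to particular spans of the path.
#'
#' @param name muscle acronym.
#' @param points list of path points, each `list(bone =, xyz =)` with
#'   bone-local coordinates (m); first = origin, last = insertion.
#' @param wraps list of `wrap_surface`; each may carry a `span` attribute
#'   (index i: surface acts between points i and i+1), default 1.
#' @return object of class `muscle_path`.
#' @export
muscle_path <- function(name, points, wraps = list()) {
  if (length(points) < 2L) stop("a muscle path needs at least 2 points")
  for (p in points) {
    if (is.null(p$bone) || length(p$xyz) != 3)
      stop("each path point needs a bone and xyz")
  }
  for (w in wraps) stopifnot(inherits(w, "wrap_surface"))
  structure(list(name = name, points = points, wraps = wraps),
            class = "muscle_path")
}

apply_mat4 <- function(m, xyz) as.numeric(m[1:3, 1:3] %*% xyz + m[1:3, 4])

# 2D circle wrap: both endpoints outside a circle of radius r at the
# origin; returns in-plane tangent points and arc length for the detour
# on the requested side, or NULL when the chord clears the circle.
circle_wrap_2d <- function(p, s, r, side = 1) {
  # does the segment pass within r of the origin?
  d <- s - p
  len2 <- sum(d^2)
  t0 <- if (len2 > 0) -sum(p * d) / len2 else 0
  t0 <- min(max(t0, 0), 1)
  closest <- p + t0 * d
  if (sqrt(sum(closest^2)) >= r) return(NULL)
  rp <- sqrt(sum(p^2)); rs <- sqrt(sum(s^2))
  if (rp < r || rs < r) stop("path point lies inside wrap surface")
  # tangent points seen from p and s, on the chosen side: rotating the
  # point direction by +/- the tangent half-angle
  tangent_pt <- function(q, sgn) {
    rq <- sqrt(sum(q^2))
    alpha <- acos(min(max(r / rq, -1), 1))
    phi <- atan2(q[2], q[1]) + sgn * alpha
    r * c(cos(phi), sin(phi))
  }
  # side = +1: detour keeps the obstacle on the right of travel
  # (counter-clockwise tangents); side = -1 mirrors
  t1 <- tangent_pt(p, side)
  t2 <- tangent_pt(s, -side)
  a1 <- atan2(t1[2], t1[1]); a2 <- atan2(t2[2], t2[1])
  sweep_ang <- (a2 - a1) * side
  sweep_ang <- sweep_ang %% (2 * pi)
  arc <- r * sweep_ang
  list(t1 = t1, t2 = t2, arc = arc, sweep = sweep_ang)
}

wrap_span_length <- function(p_world, s_world, wrap, bone_world) {
  # frame of the wrap surface in world coordinates
  W <- bone_world %*% wrap$transform
  Winv <- solve(W)
  p <- apply_mat4(Winv, p_world)
  s <- apply_mat4(Winv, s_world)
  r <- wrap$radius
  if (wrap$kind == "cylinder") {
    w2 <- circle_wrap_2d(p[1:2], s[1:2], r, wrap$active_side)
    if (is.null(w2)) return(sqrt(sum((s_world - p_world)^2)))
    # distribute the axial (z) travel proportionally to the unrolled
    # in-plane arclength: exact for the planar case, standard
    # obstacle-set treatment otherwise
    l1 <- sqrt(sum((w2$t1 - p[1:2])^2))
    l2 <- sqrt(sum((w2$t2 - s[1:2])^2))
    ltot <- l1 + w2$arc + l2
    dz <- s[3] - p[3]
    z1 <- p[3] + dz * l1 / ltot
    z2 <- p[3] + dz * (l1 + w2$arc) / ltot
    sqrt(l1^2 + (z1 - p[3])^2) +
      sqrt(w2$arc^2 + (z2 - z1)^2) +
      sqrt(l2^2 + (s[3] - z2)^2)
  } else {
    # sphere: single geodesic in the plane through both points and the
    # centre
    n <- c(p[2] * s[3] - p[3] * s[2], p[3] * s[1] - p[1] * s[3],
           p[1] * s[2] - p[2] * s[1])
    nn <- sqrt(sum(n^2))
    if (nn < 1e-15) {
      # endpoints collinear with centre: chord passes through the centre;
      # any great-circle plane gives the same length
      u <- p / sqrt(sum(p^2))
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      n <- c(u[2] * ref[3] - u[3] * ref[2], u[3] * ref[1] - u[1] * ref[3],
             u[1] * ref[2] - u[2] * ref[1])
      nn <- sqrt(sum(n^2))
    }
    n <- n / nn
    ref <- p - sum(p * n) * n
    u <- ref / sqrt(sum(ref^2))
    v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
           n[1] * u[2] - n[2] * u[1])
    p2 <- c(sum(p * u), sum(p * v))
    s2 <- c(sum(s * u), sum(s * v))
    w2 <- circle_wrap_2d(p2, s2, r, 1)
    if (is.null(w2)) return(sqrt(sum((s_world - p_world)^2)))
    # geodesic: the shorter of the two tangent-arc solutions
    w2b <- circle_wrap_2d(p2, s2, r, -1)
    len_of <- function(w) {
      sqrt(sum((w$t1 - p2)^2)) + w$arc + sqrt(sum((w$t2 - s2)^2))
    }
    min(len_of(w2), len_of(w2b))
  }
}

#' Route a muscle path through a posed chain
#'
#' Resolves all path points to world coordinates for the given pose,
#' applies each wrapping surface to its assigned span (replacing the
#' straight chord by the shortest tangent-arc-tangent detour when the
#' chord penetrates the surface), and returns the total musculotendon
#' length. The length is continuous across wrap engagement: a chord that
#' just grazes the surface has detour length equal to the chord.
#'
#' @param muscle a `muscle_path`.
#' @param chain a `kinematic_chain`.
#' @param joint_angles pose as in [pose()] (radians).
#' @param world optional precomputed bone transforms from [pose()].
#' @return list with `points` (world polyline anchor points, n x 3),
#'   `length` (m), `wrapped` (logical per wrap surface).
#' @export
route_path <- function(muscle, chain, joint_angles = list(), world = NULL) {
  stopifnot(inherits(muscle, "muscle_path"))
  if (is.null(world)) world <- pose(chain, joint_angles, check_rom = FALSE)
  pts <- t(vapply(muscle$points, function(p) {
    W <- world[[p$bone]]
    if (is.null(W)) stop(sprintf("muscle '%s': unknown bone '%s'",
                                 muscle$name, p$bone))
    apply_mat4(W, p$xyz)
  }, numeric(3)))
  spans <- vapply(muscle$wraps, function(w) attr(w, "span") %||% 1L,
                  integer(1))
  total <- 0
  wrapped <- logical(length(muscle$wraps))
  for (i in seq_len(nrow(pts) - 1L)) {
    widx <- which(spans == i)
    p0 <- pts[i, ]; p1 <- pts[i + 1L, ]
    chord <- sqrt(sum((p1 - p0)^2))
    if (length(widx) == 0) {
      total <- total + chord
    } else {
      w <- muscle$wraps[[widx[1]]]
      seg <- tryCatch(
        wrap_span_length(p0, p1, w, world[[w$bone]]),
        error = function(e) stop(sprintf(
          "muscle '%s', wrap on '%s': %s", muscle$name, w$bone,
          conditionMessage(e))))
      wrapped[widx[1]] <- seg > chord + 1e-12
      total <- total + seg
    }
  }
  list(points = pts, length = total, wrapped = wrapped)
}

#' Muscle moment arm by tendon excursion
#'
#' The moment arm of a muscle about one joint DOF at a given angle,
#' computed as minus the derivative of musculotendon length with respect
#' to the joint angle (tendon-excursion method), by central finite
#' difference with half-width `h`. The sign follows the joint's angle
#' convention: a muscle whose length shortens as the angle increases has
#' a positive moment arm about that DOF.
#'
#' @param muscle a `muscle_path`.
#' @param chain a `kinematic_chain`.
#' @param joint joint name.
#' @param dof "x", "y" or "z".
#' @param angle evaluation angle (radians unless `degrees = TRUE`).
#' @param h finite-difference half-width in degrees (default 0.25).
#' @param joint_angles base pose for the remaining joints.
#' @param degrees interpret `angle` in degrees.
#' @return moment arm in metres (signed).
#' @export
moment_arm <- function(muscle, chain, joint, dof, angle = 0, h = 0.25,
                       joint_angles = list(), degrees = FALSE) {
  if (degrees) angle <- angle * pi / 180
  h_rad <- h * pi / 180
  len_at <- function(a) {
    ja <- joint_angles
    cur <- ja[[joint]] %||% c(x = 0, y = 0, z = 0)
    full <- c(x = 0, y = 0, z = 0)
    full[names(cur)] <- cur
    full[dof] <- a
    ja[[joint]] <- full
    route_path(muscle, chain, ja)$length
  }
  lp <- len_at(angle + h_rad)
  lm <- len_at(angle - h_rad)
  -(lp - lm) / (2 * h_rad)
}

#' Moment-arm curve over a joint's range of motion
#'
#' Evaluates the tendon-excursion moment arm on an inclusive grid from
#' the DOF's ROM minimum to maximum. Grid steps where a wrap surface
#' engages or releases are recorded.
#'
#' @param muscle a `muscle_path`.
#' @param chain a `kinematic_chain` whose joint carries `rom_limits` for
#'   the DOF.
#' @param joint,dof joint name and DOF.
#' @param grid_step grid spacing in degrees (default 5).
#' @param ... passed to [moment_arm()].
#' @return list of class `mma_curve` with `joint`, `dof`, `angles_deg`,
#'   `moment_arms` (m), `wrap_events` (angles where wrap state changed).
#' @export
mma_curve <- function(muscle, chain, joint, dof, grid_step = 5, ...) {
  j <- chain$joints[[joint]]
  if (is.null(j)) stop(sprintf("unknown joint '%s'", joint))
  lim <- j$rom_limits[[dof]]
  if (is.null(lim)) stop(sprintf("joint '%s' has no ROM limits for '%s'",
                                 joint, dof))
  grid <- seq(lim[1], lim[2], by = grid_step)
  if (grid[length(grid)] < lim[2]) grid <- c(grid, lim[2])
  ma <- vapply(grid, function(a) {
    tryCatch(moment_arm(muscle, chain, joint, dof, a, degrees = TRUE, ...),
             error = function(e) stop(sprintf(
               "moment arm failed for '%s' at %s/%s = %g deg: %s",
               muscle$name, joint, dof, a, conditionMessage(e))))
  }, numeric(1))
  wrap_state <- vapply(grid, function(a) {
    ja <- stats::setNames(list(stats::setNames(a * pi / 180, dof)), joint)
    any(route_path(muscle, chain, ja)$wrapped)
  }, logical(1))
  events <- grid[which(diff(wrap_state) != 0) + 1L]
  structure(list(muscle = muscle$name, joint = joint, dof = dof,
                 angles_deg = grid, moment_arms = ma,
                 wrap_events = events),
            class = "mma_curve")
}

#' Mean dimensionless moment arm over the ROM
#'
#' The unweighted arithmetic mean of a moment-arm curve over its grid,
#' divided by a normalising bone length (femur for the hip, tibia for
#' the knee, metatarsal III for the ankle), giving a dimensionless
#' leverage measure comparable across taxa of different size.
#'
#' @param curve an `mma_curve`.
#' @param bone_length normalising length (m).
#' @return dimensionless scalar.
#' @export
mean_dimensionless_mma <- function(curve, bone_length) {
  stopifnot(inherits(curve, "mma_curve"))
  if (!is.finite(bone_length) || bone_length <= 0)
    stop("bone_length must be positive")
  if (length(curve$moment_arms) == 0) stop("empty moment-arm curve")
  mean(curve$moment_arms) / bone_length
}

#' Dimensionless mean moment-arm report
#'
#' One row per muscle per analysed DOF (hip flexion/extension, hip
#' ab/adduction, knee flexion/extension, ankle flexion/extension),
#' normalised by the stated bone lengths, optionally grouped
#' uniarticular/biarticular.
#'
#' @param muscles list of `muscle_path`.
#' @param chain a `kinematic_chain` with ROM limits set.
#' @param dof_table data.frame with columns `joint`, `dof`,
#'   `normalizing_length` (m) and optionally `label`.
#' @param groups optional named character vector mapping muscle name to a
#'   grouping label (e.g. "uniarticular hip").
#' @param assignments optional data.frame with columns `muscle`, `joint`,
#'   `dof` restricting which muscle x DOF combinations are evaluated
#'   (muscles only act at joints they cross); default: every muscle at
#'   every DOF in `dof_table`.
#' @param grid_step grid spacing in degrees.
#' @return data.frame with `muscle`, `group`, `joint`, `dof`,
#'   `mean_dimensionless_mma`.
#' @export
mma_report <- function(muscles, chain, dof_table, groups = NULL,
                       assignments = NULL, grid_step = 5) {
  if (inherits(muscles, "muscle_path")) muscles <- list(muscles)
  rows <- list()
  for (m in muscles) {
    for (k in seq_len(nrow(dof_table))) {
      jt <- dof_table$joint[k]; df <- dof_table$dof[k]
      if (!is.null(assignments) &&
          !any(assignments$muscle == m$name & assignments$joint == jt &
               assignments$dof == df)) next
      L <- dof_table$normalizing_length[k]
      if (!is.finite(L) || L <= 0)
        stop(sprintf("missing normalizing length for %s/%s", jt, df))
      cur <- mma_curve(m, chain, jt, df, grid_step = grid_step)
      rows[[length(rows) + 1L]] <- data.frame(
        muscle = m$name,
        group = if (!is.null(groups)) groups[[m$name]] %||% NA_character_
                else NA_character_,
        joint = jt, dof = df,
        mean_dimensionless_mma = mean_dimensionless_mma(cur, L))
    }
  }
  do.call(rbind, rows)
}
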