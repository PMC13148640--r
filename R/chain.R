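#' Anatomical/joint coordinate frame
#'
#' A right-handed orthonormal frame: an origin plus x, y, z axis columns.
#' Orthonormality and positive determinant are enforced at construction
#' (axes are re-orthonormalised by SVD if within tolerance, rejected
#' otherwise).
#'
#' @param origin length-3 point (m).
#' @param axes 3 x 3 matrix, columns are x, y, z axes.
#' @return object of class `frame_acs`.
#' @export
frame_acs <- function(origin = c(0, 0, 0), axes = diag(3)) {
  axes <- as.matrix(axes)
  stopifnot(all(dim(axes) == c(3, 3)))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6)
    stop("axes are not orthonormal")
  sv <- svd(axes)
  axes <- sv$u %*% t(sv$v)
  if (det(axes) < 0)
    stop("left-handed frame rejected (det = -1); supply right-handed axes")
  structure(list(origin = as.numeric(origin), axes = axes),
            class = "frame_acs")
}

frame_to_mat4 <- function(frame) {
  m <- diag(4)
  m[1:3, 1:3] <- frame$axes
  m[1:3, 4] <- frame$origin
  m
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Compose a z-y-x Euler rotation
#'
#' Rotation matrix R = Rz(z) Ry(y) Rx(x), the fixed joint rotation order
#' of the pipeline: flexion/extension about z first, then
#' abduction/adduction about y, then long-axis rotation about x.
#'
#' @param angles length-3 vector `c(x, y, z)` in radians (named by the
#'   axis each angle rotates about).
#' @return 3 x 3 rotation matrix.
#' @export
euler_zyx_matrix <- function(angles) {
  rot_z(angles[3]) %*% rot_y(angles[2]) %*% rot_x(angles[1])
}

#' Decompose a rotation matrix into z-y-x Euler angles
#'
#' Inverse of [euler_zyx_matrix()]. Near gimbal lock (|y| -> 90 deg) the
#' y angle is clamped to +/- 89.999 deg with a warning; the x/z split is
#' then conventional.
#'
#' @param R 3 x 3 rotation matrix.
#' @return length-3 vector `c(x, y, z)` in radians.
#' @export
euler_zyx_angles <- function(R) {
  sy <- -R[3, 1]
  if (abs(sy) >= sin(89.999 * pi / 180)) {
    warning("gimbal proximity: |y| clamped to 89.999 deg")
    sy <- sign(sy) * sin(89.999 * pi / 180)
  }
  y <- asin(sy)
  x <- atan2(R[3, 2], R[3, 3])
  z <- atan2(R[2, 1], R[1, 1])
  c(x = x, y = y, z = z)
}

#' Round-trip z-y-x Euler angles through a rotation matrix
#'
#' Composes the angles to a matrix and decomposes again; away from gimbal
#' lock the input is recovered to ~1e-10 rad. Used to pin the rotation
#' order convention.
#'
#' @param angles length-3 `c(x, y, z)` in radians.
#' @return recovered angles.
#' @export
euler_zyx_roundtrip <- function(angles) {
  euler_zyx_angles(euler_zyx_matrix(angles))
}

#' Build a joint coordinate system from fitted primitives
#'
#' Pairs the primitives fitted to the parent (socket/proximal) and child
#' (distal) articular surfaces into a right-handed JCS:
#' * cylinder hinge: z along the cylinder axis (flexion/extension),
#'   origin at the cylinder centre;
#' * sphere-in-socket: origin at the socket sphere centre; z is chosen so
#'   flexion/extension sweeps the sagittal plane defined by the
#'   convention's `sagittal_normal` (z is the sagittal-plane normal,
#'   canonicalised to point along it).
#' Axis signs are canonicalised (flipping a fitted primitive's axis does
#' not change the JCS); x completes the right-handed triad.
#'
#' @param parent_primitive `geometric_primitive` for the parent surface.
#' @param child_primitive `geometric_primitive` for the child surface
#'   (may be NULL for a pure hinge).
#' @param conventions list: `sagittal_normal` (default c(0,0,1)) the
#'   mediolateral direction that flexion/extension rotates about;
#'   `long_axis` (default c(0,-1,0)) the reference proximodistal
#'   direction used to orient x.
#' @return `frame_acs`.
#' @export
build_jcs <- function(parent_primitive, child_primitive = NULL,
                      conventions = list()) {
  sagittal_normal <- conventions$sagittal_normal %||% c(0, 0, 1)
  long_axis <- conventions$long_axis %||% c(0, -1, 0)
  sagittal_normal <- sagittal_normal / sqrt(sum(sagittal_normal^2))
  prim <- parent_primitive
  if (prim$kind == "cylinder") {
    z <- prim$axis
    # canonical sign: along the convention's mediolateral direction
    if (sum(z * sagittal_normal) < 0) z <- -z
    origin <- prim$centre
  } else if (prim$kind == "sphere") {
    origin <- prim$centre
    z <- sagittal_normal
  } else {
    stop(sprintf("unsupported parent primitive kind '%s' for a JCS",
                 prim$kind))
  }
  if (abs(sum(z * long_axis)) > 0.999) {
    warning("near-parallel axis ambiguity; tie-broken by convention long_axis")
    long_axis <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  # x orthogonal to z, as close as possible to the convention long axis
  x <- long_axis - sum(long_axis * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  frame_acs(origin, cbind(x, y, z))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Joint specification
#'
#' A named joint between two bones carrying its JCS (in world coordinates
#' at the reference pose), active degrees of freedom, per-axis sign
#' conventions (what a positive angle means anatomically), and per-DOF
#' range-of-motion limits in degrees. Rotation order is fixed z, y, x.
#'
#' @param name joint name.
#' @param parent_bone,child_bone bone names.
#' @param jcs a `frame_acs` in world coordinates at the reference pose.
#' @param dof_mask character subset of c("x","y","z"): x = long-axis
#'   rotation, y = ab/adduction, z = flexion/extension.
#' @param sign_convention named list mapping each axis to a string naming
#'   the anatomical direction of positive rotation.
#' @param rom_limits named list of c(min, max) degrees per active axis.
#' @return object of class `joint_spec`.
#' @export
joint_spec <- function(name, parent_bone, child_bone, jcs,
                       dof_mask = "z",
                       sign_convention = list(z = "positive = extension"),
                       rom_limits = list()) {
  dof_mask <- match.arg(dof_mask, c("x", "y", "z"), several.ok = TRUE)
  if (length(dof_mask) == 0) stop("dof_mask must be non-empty")
  if (is.null(sign_convention) || length(sign_convention) == 0)
    stop("every joint needs an explicit sign_convention")
  for (d in names(rom_limits)) {
    lim <- rom_limits[[d]]
    if (length(lim) != 2 || lim[1] >= lim[2])
      stop(sprintf("joint '%s' dof '%s': limits must satisfy min < max",
                   name, d))
  }
  structure(list(name = name, parent_bone = parent_bone,
                 child_bone = child_bone, jcs = jcs, dof_mask = dof_mask,
                 sign_convention = sign_convention,
                 rom_limits = rom_limits, rotation_order = c("z", "y", "x")),
            class = "joint_spec")
}

#' Kinematic chain of bones and joints
#'
#' A tree of bones connected by joints; the reference pose (all angles 0)
#' is the parasagittally straight articulated pose in which bone rest
#' transforms and JCS frames were defined.
#'
#' @param bones named list; each element a list with `mesh` (`paleo_mesh`
#'   or NULL), `rest` (4x4 world transform, default identity), and
#'   optionally `points` (n x 3 articular surface points in bone-local
#'   coordinates, for disarticulation checks) and `length` (bone length
#'   m).
#' @param joints list of `joint_spec` (tree topology: every bone except
#'   the root has exactly one parent joint).
#' @return object of class `kinematic_chain`.
#' @export
kinematic_chain <- function(bones, joints) {
  if (inherits(joints, "joint_spec")) joints <- list(joints)
  names(joints) <- vapply(joints, `[[`, character(1), "name")
  for (b in names(bones)) {
    if (is.null(bones[[b]]$rest)) bones[[b]]$rest <- diag(4)
  }
  child_of <- vapply(joints, `[[`, character(1), "child_bone")
  if (anyDuplicated(child_of))
    stop("a bone has more than one parent joint")
  for (j in joints) {
    if (!j$parent_bone %in% names(bones))
      stop(sprintf("unknown parent bone '%s'", j$parent_bone))
    if (!j$child_bone %in% names(bones))
      stop(sprintf("unknown child bone '%s'", j$child_bone))
  }
  # check acyclicity by walking to root from each bone
  parent_bone_of <- stats::setNames(
    vapply(joints, `[[`, character(1), "parent_bone"), child_of)
  for (b in names(bones)) {
    seen <- character(0); cur <- b
    while (cur %in% names(parent_bone_of)) {
      if (cur %in% seen) stop("joint topology contains a cycle")
      seen <- c(seen, cur)
      cur <- parent_bone_of[[cur]]
    }
  }
  structure(list(bones = bones, joints = joints),
            class = "kinematic_chain")
}

topo_order_joints <- function(chain) {
  child_of <- vapply(chain$joints, `[[`, character(1), "child_bone")
  parent_of <- vapply(chain$joints, `[[`, character(1), "parent_bone")
  ordered <- character(0)
  placed <- setdiff(names(chain$bones), child_of)  # roots
  remaining <- names(chain$joints)
  while (length(remaining) > 0) {
    ready <- remaining[parent_of[remaining] %in% placed]
    if (length(ready) == 0) stop("joint topology is not a rooted tree")
    ordered <- c(ordered, ready)
    placed <- c(placed, child_of[ready])
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

#' Pose a kinematic chain
#'
#' Applies joint rotations in the fixed z-y-x order about each joint's
#' JCS: the child bone's world transform is
#' parent %*% J %*% Rz Ry Rx %*% J^-1 %*% rest_offset, composed down the
#' tree. All angles zero returns the rest transforms exactly.
#'
#' @param chain a `kinematic_chain`.
#' @param joint_angles named list; per joint a named numeric vector with
#'   any of elements x, y, z (radians unless `degrees = TRUE`). Omitted
#'   joints stay at 0.
#' @param degrees logical; interpret angles in degrees (default FALSE).
#' @param check_rom logical; error if an angle lies outside the joint's
#'   declared ROM limits (default TRUE when limits are set).
#' @return named list of 4 x 4 world transforms, one per bone.
#' @export
pose <- function(chain, joint_angles = list(), degrees = FALSE,
                 check_rom = TRUE) {
  stopifnot(inherits(chain, "kinematic_chain"))
  conv <- if (degrees) pi / 180 else 1
  offenders <- character(0)
  if (check_rom) {
    for (jn in names(joint_angles)) {
      j <- chain$joints[[jn]]
      if (is.null(j)) stop(sprintf("unknown joint '%s'", jn))
      ang <- joint_angles[[jn]]
      for (d in names(ang)) {
        lim <- j$rom_limits[[d]]
        deg <- ang[[d]] * conv * 180 / pi
        if (!is.null(lim) && (deg < lim[1] - 1e-9 || deg > lim[2] + 1e-9))
          offenders <- c(offenders, sprintf("%s/%s = %.4g deg", jn, d, deg))
      }
    }
    if (length(offenders) > 0)
      stop("angles outside declared ROM (use check_rom = FALSE to override): ",
           paste(offenders, collapse = "; "))
  }
  world <- lapply(chain$bones, `[[`, "rest")
  for (jn in topo_order_joints(chain)) {
    j <- chain$joints[[jn]]
    ang <- c(x = 0, y = 0, z = 0)
    if (!is.null(joint_angles[[jn]])) {
      a <- joint_angles[[jn]]
      ang[names(a)] <- unlist(a) * conv
    }
    if (all(ang == 0)) {
      # child subtree keeps whatever transform it has accumulated
      delta <- diag(4)
    } else {
      J <- frame_to_mat4(j$jcs)
      Rm <- diag(4)
      Rm[1:3, 1:3] <- euler_zyx_matrix(ang)
      delta <- J %*% Rm %*% solve(J)
    }
    # apply delta to the child bone and all its descendants, composed
    # with any transform already applied to the parent
    parent_delta <- world[[j$parent_bone]] %*% solve(chain$bones[[j$parent_bone]]$rest)
    total <- parent_delta %*% delta
    for (b in bones_in_subtree(chain, j$child_bone)) {
      world[[b]] <- total %*% chain$bones[[b]]$rest
    }
  }
  world
}

bones_in_subtree <- function(chain, bone) {
  child_of <- vapply(chain$joints, `[[`, character(1), "child_bone")
  parent_of <- vapply(chain$joints, `[[`, character(1), "parent_bone")
  out <- bone
  frontier <- bone
  while (length(frontier) > 0) {
    nxt <- child_of[parent_of %in% frontier]
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Translate a segment distally to account for missing cartilage
#'
#' Fossil long bones lack their articular cartilage, so the model inserts
#' joint space by translating a segment (and all its distal descendants,
#' with their JCS origins) along the parent bone's long axis by a stated
#' fraction of a reference bone length (conventionally 5% of humerus
#' length for the forearm, 10% of femur length for the crus).
#'
#' @param chain a `kinematic_chain`.
#' @param segment_name bone to translate (with its subtree).
#' @param fraction offset as a fraction of `reference_bone_length`
#'   (0 <= fraction < 1).
#' @param reference_bone_length reference length (m).
#' @param direction world unit vector of the distal direction; default
#'   uses the parent bone's stored `long_axis` or -y.
#' @return modified `kinematic_chain`.
#' @export
apply_cartilage_offset <- function(chain, segment_name, fraction,
                                   reference_bone_length,
                                   direction = NULL) {
  stopifnot(inherits(chain, "kinematic_chain"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  if (!segment_name %in% names(chain$bones))
    stop(sprintf("unknown segment '%s'", segment_name))
  if (fraction == 0) return(chain)
  if (is.null(direction)) {
    parent_joint <- Filter(function(j) j$child_bone == segment_name,
                           chain$joints)
    direction <- if (length(parent_joint) > 0)
      chain$bones[[parent_joint[[1]]$parent_bone]]$long_axis %||% c(0, -1, 0)
    else c(0, -1, 0)
  }
  direction <- direction / sqrt(sum(direction^2))
  shift <- fraction * reference_bone_length * direction
  moved <- bones_in_subtree(chain, segment_name)
  for (b in moved) {
    chain$bones[[b]]$rest[1:3, 4] <- chain$bones[[b]]$rest[1:3, 4] + shift
    if (!is.null(chain$bones[[b]]$points_world))
      chain$bones[[b]]$points_world <-
        sweep(chain$bones[[b]]$points_world, 2, shift, `+`)
  }
  for (jn in names(chain$joints)) {
    j <- chain$joints[[jn]]
    if (j$child_bone %in% moved) {
      chain$joints[[jn]]$jcs$origin <- j$jcs$origin + shift
    }
  }
  chain
}
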