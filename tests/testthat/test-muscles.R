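simple_hinge_chain <- function() {
  kinematic_chain(
    bones = list(base = list(rest = diag(4)),
                 seg = list(rest = diag(4))),
    joints = list(joint_spec(
      "hinge", "base", "seg", frame_acs(), dof_mask = c("x", "y", "z"),
      sign_convention = list(z = "positive = extension"),
      rom_limits = list(z = c(-90, 90)))))
}

test_that("an unobstructed path is the straight chord", {
  ch <- simple_hinge_chain()
  m <- muscle_path("straight", list(
    list(bone = "base", xyz = c(0, 0, 0)),
    list(bone = "seg", xyz = c(0.1, 0, 0))))
  r <- route_path(m, ch)
  expect_equal(r$length, 0.1, tolerance = 1e-12)
  # via point detour is never shorter than the chord
  m2 <- muscle_path("via", list(
    list(bone = "base", xyz = c(0, 0, 0)),
    list(bone = "base", xyz = c(0.05, 0.03, 0)),
    list(bone = "seg", xyz = c(0.1, 0, 0))))
  expect_gt(route_path(m2, ch)$length, 0.1)
})

test_that("cylinder wrap matches closed form and the numeric geodesic oracle", {
  ch <- simple_hinge_chain()
  w <- wrap_surface("cylinder", "base", diag(4), 0.01, active_side = -1)
  attr(w, "span") <- 1L
  d <- 0.05
  m <- muscle_path("wrapped", list(
    list(bone = "base", xyz = c(-d, 0, 0)),
    list(bone = "seg", xyz = c(d, 0, 0))), list(w))
  r <- route_path(m, ch)
  # symmetric chord through the axis plane: 2 sqrt(d^2 - r^2) + r * phi
  phi <- pi - 2 * acos(0.01 / d)
  expect_equal(r$length, 2 * sqrt(d^2 - 0.01^2) + 0.01 * phi,
               tolerance = 1e-9)
  expect_true(any(r$wrapped))
  # independent boundary-graph geodesic oracle
  oracle <- circle_detour_oracle(c(-d, 0), c(d, 0), 0.01)
  expect_equal(r$length, oracle, tolerance = 1e-6)
  # off-centre chord, both sides checked against the oracle's minimum
  m2 <- muscle_path("off", list(
    list(bone = "base", xyz = c(-0.05, 0.005, 0)),
    list(bone = "seg", xyz = c(0.05, 0.005, 0))), list(w))
  r2 <- route_path(m2, ch)
  expect_equal(r2$length,
               circle_detour_oracle(c(-0.05, 0.005), c(0.05, 0.005), 0.01),
               tolerance = 1e-6)
})

test_that("wrap engagement is continuous at tangency", {
  ch <- simple_hinge_chain()
  w <- wrap_surface("cylinder", "base", diag(4), 0.01, active_side = -1)
  attr(w, "span") <- 1L
  len_at_y <- function(y) {
    m <- muscle_path("m", list(
      list(bone = "base", xyz = c(-0.05, y, 0)),
      list(bone = "seg", xyz = c(0.05, y, 0))), list(w))
    route_path(m, ch)$length
  }
  expect_equal(len_at_y(0.0100001), 0.1, tolerance = 1e-9)
  expect_equal(len_at_y(0.0099999), 0.1, tolerance = 1e-6)
  expect_lt(abs(len_at_y(0.0099) - 0.1), 1e-4)
})

test_that("sphere wrap matches the planar closed form", {
  ch <- simple_hinge_chain()
  w <- wrap_surface("sphere", "base", diag(4), 0.01)
  attr(w, "span") <- 1L
  d <- 0.04
  m <- muscle_path("sph", list(
    list(bone = "base", xyz = c(-d, 0.002, 0)),
    list(bone = "seg", xyz = c(d, 0.002, 0))), list(w))
  r <- route_path(m, ch)
  oracle <- circle_detour_oracle(c(-d, 0.002), c(d, 0.002), 0.01)
  expect_equal(r$length, oracle, tolerance = 1e-6)
  expect_gt(r$length, 2 * d)
})

test_that("a path point inside a wrap surface errors with the muscle named", {
  ch <- simple_hinge_chain()
  w <- wrap_surface("cylinder", "base", diag(4), 0.05, active_side = 1)
  attr(w, "span") <- 1L
  m <- muscle_path("inside", list(
    list(bone = "base", xyz = c(0.01, 0, 0)),
    list(bone = "seg", xyz = c(0.2, 0, 0))), list(w))
  expect_error(route_path(m, ch), "inside")
  expect_error(route_path(m, ch), "inside.*wrap|wrap.*inside")
})

test_that("hinge moment arm equals the perpendicular distance and virtual work", {
  ch <- simple_hinge_chain()
  off <- 0.02
  m <- muscle_path("m", list(
    list(bone = "base", xyz = c(-0.1, off, 0)),
    list(bone = "seg", xyz = c(0.1, off, 0))))
  ma <- moment_arm(m, ch, "hinge", "z", 0)
  expect_equal(abs(ma), off, tolerance = 1e-6)
  # virtual-work oracle: unit tension force at the insertion, torque
  # about the hinge axis from the cross product
  A <- c(-0.1, off, 0); B <- c(0.1, off, 0)
  Fv <- (A - B) / sqrt(sum((A - B)^2))
  tau_z <- B[1] * Fv[2] - B[2] * Fv[1]
  expect_equal(ma, tau_z, tolerance = 1e-6)
  # muscle parallel to the hinge axis has zero moment arm
  mp <- muscle_path("par", list(
    list(bone = "base", xyz = c(0.05, 0.02, -0.1)),
    list(bone = "seg", xyz = c(0.05, 0.02, 0.1))))
  expect_equal(moment_arm(mp, ch, "hinge", "z", 0), 0, tolerance = 1e-9)
})

test_that("virtual-work consistency holds across poses and muscles", {
  sk <- make_toy_skeleton()
  tm <- make_toy_muscles()
  # numeric virtual work: project insertion-point velocity onto the line
  # of action, independently of the tendon-excursion routine
  m <- tm$muscles$knee_ext
  for (ang in c(-0.3, 0, 0.4)) {
    ma <- moment_arm(m, sk$chain, "knee", "z", ang)
    h <- 1e-6
    wp <- pose(sk$chain, list(knee = c(z = ang + h)), check_rom = FALSE)
    wm <- pose(sk$chain, list(knee = c(z = ang - h)), check_rom = FALSE)
    w0 <- pose(sk$chain, list(knee = c(z = ang)), check_rom = FALSE)
    B_loc <- c(m$points[[2]]$xyz, 1)
    vB <- ((wp$tibia %*% B_loc)[1:3] - (wm$tibia %*% B_loc)[1:3]) / (2 * h)
    A <- (w0$femur %*% c(m$points[[1]]$xyz, 1))[1:3]
    B <- (w0$tibia %*% B_loc)[1:3]
    Fv <- (A - B) / sqrt(sum((A - B)^2))
    expect_equal(ma, sum(Fv * vB), tolerance = 1e-6)
  }
})

test_that("a path fully wrapped on a coaxial cylinder has |MMA| = radius", {
  sk <- make_toy_skeleton()
  tm <- make_toy_muscles()
  for (ang in c(-0.4, -0.2, 0)) {
    ma <- moment_arm(tm$muscles$cfl, sk$chain, "hip", "z", ang)
    expect_equal(abs(ma), 0.012, tolerance = 1e-9)
  }
})

test_that("finite-difference moment arms converge with h", {
  ch <- simple_hinge_chain()
  m <- muscle_path("m", list(
    list(bone = "base", xyz = c(-0.1, 0.02, 0)),
    list(bone = "seg", xyz = c(0.1, 0.02, 0))))
  ma1 <- moment_arm(m, ch, "hinge", "z", 0.3, h = 0.125)
  ma2 <- moment_arm(m, ch, "hinge", "z", 0.3, h = 0.0625)
  expect_lt(abs(ma1 - ma2), 1e-8)
  # second-order convergence: quartering h shrinks the change ~16x
  ma0 <- moment_arm(m, ch, "hinge", "z", 0.3, h = 0.5)
  expect_gt(abs(ma0 - ma1), abs(ma1 - ma2))
})

test_that("moment-arm curves respect the grid and flag wrap events", {
  sk <- make_toy_skeleton()
  tm <- make_toy_muscles()
  cur <- mma_curve(tm$muscles$knee_ext, sk$chain, "knee", "z")
  expect_equal(cur$angles_deg[1], -130)
  expect_equal(cur$angles_deg[length(cur$angles_deg)], 0)
  expect_true(all(diff(cur$angles_deg) > 0))
  expect_true(all(is.finite(cur$moment_arms)))
  # constant-offset muscle (coaxial wrap engaged across the whole grid):
  # flat curve at the wrap radius
  ch <- kinematic_chain(
    bones = list(base = list(rest = diag(4)), seg = list(rest = diag(4))),
    joints = list(joint_spec(
      "hinge", "base", "seg", frame_acs(), dof_mask = "z",
      sign_convention = list(z = "positive = extension"),
      rom_limits = list(z = c(-30, 0)))))
  w <- wrap_surface("cylinder", "base", diag(4), 0.012, active_side = 1)
  attr(w, "span") <- 1L
  m <- muscle_path("coax", list(
    list(bone = "base", xyz = c(-0.05, 0.004, 0)),
    list(bone = "seg", xyz = c(0.05, 0.004, 0))), list(w))
  flat <- mma_curve(m, ch, "hinge", "z")
  expect_lt(diff(range(flat$moment_arms)), 1e-9)
  expect_equal(abs(flat$moment_arms[1]), 0.012, tolerance = 1e-9)
})

test_that("mean dimensionless MMA is the grid mean over bone length", {
  sk <- make_toy_skeleton()
  tm <- make_toy_muscles()
  flat <- mma_curve(tm$muscles$gast, sk$chain, "ankle", "z")
  expect_equal(mean_dimensionless_mma(flat, 0.080),
               mean(flat$moment_arms) / 0.080)
  # worked arithmetic: flat 0.004 m curve over an 0.080 m femur = 0.05
  fake <- structure(list(angles_deg = seq(-65, 65, 5),
                         moment_arms = rep(0.004, 27)),
                    class = "mma_curve")
  expect_equal(mean_dimensionless_mma(fake, 0.080), 0.05)
  expect_error(mean_dimensionless_mma(fake, 0), "positive")
})

test_that("mean dimensionless MMA is invariant under uniform scaling", {
  k <- 2
  sk <- make_toy_skeleton()
  tm <- make_toy_muscles()
  scale_chain <- function(chain, k) {
    for (b in names(chain$bones))
      chain$bones[[b]]$rest[1:3, 4] <- chain$bones[[b]]$rest[1:3, 4] * k
    for (j in names(chain$joints))
      chain$joints[[j]]$jcs$origin <- chain$joints[[j]]$jcs$origin * k
    chain
  }
  scale_muscle <- function(m, k) {
    m$points <- lapply(m$points, function(p) { p$xyz <- p$xyz * k; p })
    m$wraps <- lapply(m$wraps, function(w) {
      sp <- attr(w, "span")
      w$radius <- w$radius * k
      w$transform[1:3, 4] <- w$transform[1:3, 4] * k
      attr(w, "span") <- sp
      w
    })
    m
  }
  ch2 <- scale_chain(sk$chain, k)
  for (nm in c("cfl", "knee_ext", "gast")) {
    m <- tm$muscles[[nm]]
    jt <- tm$registry$joint[tm$registry$muscle == m$name]
    cur1 <- mma_curve(m, sk$chain, jt, "z")
    cur2 <- mma_curve(scale_muscle(m, k), ch2, jt, "z")
    expect_equal(mean_dimensionless_mma(cur2, k * 0.080),
                 mean_dimensionless_mma(cur1, 0.080), tolerance = 1e-9)
  }
})

test_that("the dimensionless report has one row per assigned muscle-DOF", {
  sk <- make_toy_skeleton()
  tm <- make_toy_muscles()
  dof_table <- data.frame(joint = c("hip", "knee", "ankle"), dof = "z",
                          normalizing_length = c(0.080, 0.15, 0.031))
  rep1 <- mma_report(tm$muscles, sk$chain, dof_table,
                     assignments = tm$registry)
  expect_equal(nrow(rep1), 4)
  rep2 <- mma_report(tm$muscles, sk$chain, dof_table,
                     assignments = tm$registry)
  expect_identical(rep1, rep2)  # deterministic across runs
  bad <- dof_table; bad$normalizing_length[1] <- NA
  expect_error(mma_report(tm$muscles, sk$chain, bad,
                          assignments = tm$registry), "normalizing")
})
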