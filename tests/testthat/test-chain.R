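test_that("JCS construction from a cylinder hinge is canonical", {
  set.seed(6)
  t_ <- runif(80, -0.1, 0.1); a <- runif(80, 0, 2 * pi)
  # cylinder along +y through the origin
  p <- cbind(0.01 * cos(a), t_, 0.01 * sin(a))
  cyl <- fit_primitive(p, "cylinder")
  jcs <- build_jcs(cyl, conventions = list(sagittal_normal = c(0, 1, 0),
                                           long_axis = c(0, 0, -1)))
  expect_equal(abs(jcs$axes[, 3]), c(0, 1, 0), tolerance = 1e-6)
  expect_equal(det(jcs$axes), 1, tolerance = 1e-9)
  # flipping the fitted axis sign yields the identical frame
  cyl2 <- cyl; cyl2$axis <- -cyl2$axis
  jcs2 <- build_jcs(cyl2, conventions = list(sagittal_normal = c(0, 1, 0),
                                             long_axis = c(0, 0, -1)))
  expect_equal(jcs$axes, jcs2$axes, tolerance = 1e-9)
})

test_that("ball-and-socket JCS sits at the socket sphere centre", {
  set.seed(7)
  th <- runif(60, 0, pi); ph <- runif(60, 0, 2 * pi)
  ctr <- c(0.01, 0.02, 0.03)
  p <- cbind(ctr[1] + 0.004 * sin(th) * cos(ph),
             ctr[2] + 0.004 * sin(th) * sin(ph),
             ctr[3] + 0.004 * cos(th))
  socket <- fit_primitive(p, "sphere")
  jcs <- build_jcs(socket, conventions = list(sagittal_normal = c(0, 0, 1)))
  expect_equal(jcs$origin, ctr, tolerance = 1e-8)
  expect_equal(jcs$axes[, 3], c(0, 0, 1), tolerance = 1e-9)
  expect_equal(det(jcs$axes), 1, tolerance = 1e-9)
})

test_that("z-y-x Euler angles round-trip", {
  a <- c(10, 20, 30) * pi / 180
  expect_equal(unname(euler_zyx_roundtrip(a)), a, tolerance = 1e-10)
  set.seed(8)
  for (k in 1:25) {
    a <- runif(3, -80, 80) * pi / 180
    expect_equal(unname(euler_zyx_roundtrip(a)), a, tolerance = 1e-10)
  }
  expect_warning(euler_zyx_angles(euler_zyx_matrix(c(0, pi / 2, 0))),
                 "gimbal")
})

test_that("rotation order is z, then y, then x", {
  a <- c(x = 0, y = 30, z = 30) * pi / 180
  R_zyx <- euler_zyx_matrix(a)
  # independent composition oracle
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0,
                 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                 sin(a[2]), 0, cos(a[2])), 3, 3)
  expect_equal(R_zyx, Rz %*% Ry, tolerance = 1e-12)
  # the reversed application order gives a different rotation
  expect_gt(max(abs(R_zyx - Ry %*% Rz)), 1e-3)
})

test_that("posing at zero returns rest transforms exactly", {
  sk <- make_toy_skeleton()
  world <- pose(sk$chain, list())
  for (b in names(sk$chain$bones))
    expect_identical(world[[b]], sk$chain$bones[[b]]$rest)
})

test_that("hip flexion/extension sweeps the femur symmetrically", {
  sk <- make_toy_skeleton()
  tip <- c(0, -0.08, 0, 1)  # distal femur in bone-local coordinates
  w_flex <- pose(sk$chain, list(hip = c(z = -65 * pi / 180)))
  w_ext <- pose(sk$chain, list(hip = c(z = 65 * pi / 180)))
  p_flex <- (w_flex$femur %*% tip)[1:3]
  p_ext <- (w_ext$femur %*% tip)[1:3]
  # mirror symmetry about the rest (sagittal x-y) configuration
  expect_equal(p_flex[2], p_ext[2], tolerance = 1e-12)
  expect_equal(p_flex[1], -p_ext[1], tolerance = 1e-12)
  # continuity: displacement bounded by chain length times angle step
  w1 <- pose(sk$chain, list(hip = c(z = 0.10)))
  w2 <- pose(sk$chain, list(hip = c(z = 0.11)))
  d <- sqrt(sum(((w1$toe - w2$toe) %*% c(0.1, -0.3, 0, 1))^2))
  expect_lt(d, 0.5 * 0.01)
})

test_that("out-of-ROM poses error with the offending joint named", {
  sk <- make_toy_skeleton()
  expect_error(pose(sk$chain, list(knee = c(z = 20 * pi / 180))),
               "knee/z")
  expect_silent(pose(sk$chain, list(knee = c(z = 20 * pi / 180)),
                     check_rom = FALSE))
})

test_that("cartilage offsets translate subtrees and compose additively", {
  sk <- make_toy_skeleton()
  ch1 <- apply_cartilage_offset(sk$chain, "tibia", 0.10, 0.080,
                                direction = c(0, -1, 0))
  shift <- ch1$bones$tibia$rest[1:3, 4] - sk$chain$bones$tibia$rest[1:3, 4]
  expect_equal(shift, c(0, -0.008, 0))
  # distal descendants move too, and their JCS origins move with them
  expect_equal(ch1$bones$pes$rest[1:3, 4] - sk$chain$bones$pes$rest[1:3, 4],
               c(0, -0.008, 0))
  expect_equal(ch1$joints$ankle$jcs$origin - sk$chain$joints$ankle$jcs$origin,
               c(0, -0.008, 0))
  # parent of the moved segment does not move
  expect_equal(ch1$bones$femur$rest, sk$chain$bones$femur$rest)
  expect_identical(apply_cartilage_offset(sk$chain, "tibia", 0, 0.08),
                   sk$chain)
  ch2 <- apply_cartilage_offset(ch1, "tibia", 0.10, 0.080,
                                direction = c(0, -1, 0))
  expect_equal(ch2$bones$tibia$rest[1:3, 4] -
                 sk$chain$bones$tibia$rest[1:3, 4], c(0, -0.016, 0))
  expect_error(apply_cartilage_offset(sk$chain, "nope", 0.1, 0.08),
               "unknown segment")
})
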