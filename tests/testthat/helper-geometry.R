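# Geometry helpers and independent numeric oracles used across tests.

# icosphere: subdivided icosahedron projected to radius r
make_icosphere <- function(radius = 1, subdivisions = 3, centre = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env()
    nv <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(midcache[[key]])) return(midcache[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- rbind(nv, m)
      midcache[[key]] <- nrow(nv)
      nrow(nv)
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                  c(ab, bc, ca))
    }
    v <- nv; f <- nf
  }
  paleo_mesh(sweep(v * radius, 2, centre, `+`), f)
}

random_rigid_transform <- function() {
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  m <- diag(4)
  m[1:3, 1:3] <- Q
  m[1:3, 4] <- rnorm(3, sd = 0.5)
  m
}

# independent geodesic oracle for a 2D circular obstacle: discretise the
# circle boundary, connect the endpoints to every visible boundary node,
# travel along the boundary between nodes; no tangent-line formulas
circle_detour_oracle <- function(p, s, r, n = 1440) {
  seg_clears <- function(a, b) {
    d <- b - a
    t0 <- -sum(a * d) / sum(d^2)
    t0 <- min(max(t0, 0), 1)
    sqrt(sum((a + t0 * d)^2)) >= r * (1 - 1e-9)
  }
  if (seg_clears(p, s)) return(sqrt(sum((s - p)^2)))
  ang <- (0:(n - 1)) * 2 * pi / n
  bpts <- cbind(cos(ang), sin(ang)) * r
  dp <- sqrt((bpts[, 1] - p[1])^2 + (bpts[, 2] - p[2])^2)
  ds <- sqrt((bpts[, 1] - s[1])^2 + (bpts[, 2] - s[2])^2)
  vis_p <- vapply(seq_len(n), function(i) seg_clears(p, bpts[i, ]), TRUE)
  vis_s <- vapply(seq_len(n), function(i) seg_clears(s, bpts[i, ]), TRUE)
  dp[!vis_p] <- Inf; ds[!vis_s] <- Inf
  ai <- matrix(ang, n, n); aj <- t(ai)
  dang <- abs(ai - aj)
  arc <- r * pmin(dang, 2 * pi - dang)
  min(outer(dp, ds, `+`) + arc)
}

# two-wall hinge fixture: a rod on a z hinge between two angular stop
# sectors at +/- stop_deg (contact occurs just past the last free angle)
make_hinge_stop_chain <- function(stop_deg_pos = 66.6,
                                  stop_deg_neg = -66.6) {
  rotz4 <- function(a) {
    m <- diag(4)
    m[1:3, 1:3] <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                            0, 0, 1), 3, 3)
    m
  }
  rod <- box_mesh(c(0.05, -0.002, -0.002), c(0.9, 0.002, 0.002))
  wp <- transform_mesh(box_mesh(c(0.5, 0, -0.05), c(0.8, 0.25, 0.05)),
                       rotz4(stop_deg_pos * pi / 180))
  wm <- transform_mesh(box_mesh(c(0.5, -0.25, -0.05), c(0.8, 0, 0.05)),
                       rotz4(stop_deg_neg * pi / 180))
  walls <- merge_meshes(wp, wm)
  kinematic_chain(
    bones = list(base = list(mesh = walls, rest = diag(4)),
                 rod = list(mesh = rod, rest = diag(4))),
    joints = list(joint_spec(
      "hinge", "base", "rod", frame_acs(), dof_mask = "z",
      sign_convention = list(z = "positive = extension"))))
}
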