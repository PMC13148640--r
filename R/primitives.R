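#' Fit a geometric primitive to an articular surface
#'
#' Least-squares fits of the primitive shapes used to define anatomical
#' coordinate systems from isolated joint articular surfaces: planes
#' (total least squares), spheres (algebraic solve then geometric
#' refinement), cylinders (nonlinear refinement of axis, axis point and
#' radius, seeded from the point covariance), and ellipsoids (algebraic
#' 9-parameter fit). Typical usage: cylinders for vertebral centra and
#' distal limb-bone ends, spheres for glenoid and acetabulum, planes for
#' most proximal limb-bone ends, ellipsoids for proximal humerus/femur.
#'
#' @param points n x 3 matrix of surface points (m).
#' @param kind one of "plane", "sphere", "cylinder", "ellipsoid".
#' @return list of class `geometric_primitive` with `kind`, fitted
#'   parameters (`centre`, `normal`, `axis`, `radius`, `radii`, `axes` as
#'   appropriate) and `rms_residual` (m; orthogonal distance).
#' @export
fit_primitive <- function(points, kind = c("plane", "sphere", "cylinder",
                                           "ellipsoid")) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  need <- c(plane = 3L, sphere = 4L, cylinder = 6L, ellipsoid = 9L)
  if (nrow(points) < need[[kind]])
    stop(sprintf("%s fit needs at least %d points", kind, need[[kind]]))
  fit <- switch(kind,
                plane = fit_plane(points),
                sphere = fit_sphere(points),
                cylinder = fit_cylinder(points),
                ellipsoid = fit_ellipsoid(points))
  structure(c(list(kind = kind), fit), class = "geometric_primitive")
}

fit_plane <- function(p) {
  ctr <- colMeans(p)
  d <- sweep(p, 2, ctr)
  sv <- svd(d)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate plane fit: points are (nearly) collinear")
  normal <- sv$v[, 3]
  res <- d %*% normal
  list(centre = ctr, normal = as.numeric(normal),
       rms_residual = sqrt(mean(res^2)))
}

fit_sphere <- function(p) {
  # algebraic: |x|^2 = 2 c.x + (r^2 - |c|^2), linear in (c, k)
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop("degenerate sphere fit: points are coplanar or coincident")
  sol <- qr.coef(qrA, b)
  ctr <- sol[1:3]
  r <- sqrt(sol[4] + sum(ctr^2))
  # geometric refinement: minimise sum (|x - c| - r)^2
  obj <- function(th) {
    d <- sqrt(rowSums(sweep(p, 2, th[1:3])^2))
    sum((d - th[4])^2)
  }
  opt <- stats::optim(c(ctr, r), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  ctr <- opt$par[1:3]; r <- opt$par[4]
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  list(centre = ctr, radius = r, rms_residual = sqrt(mean((d - r)^2)))
}

cyl_residuals <- function(p, origin, axis, radius) {
  d <- sweep(p, 2, origin)
  along <- d %*% axis
  radial <- sqrt(pmax(rowSums(d^2) - along^2, 0))
  radial - radius
}

fit_cylinder <- function(p) {
  ctr <- colMeans(p)
  d <- sweep(p, 2, ctr)
  ev <- eigen(crossprod(d) / nrow(p), symmetric = TRUE)
  # candidate axes: all three covariance eigenvectors (the cylinder axis
  # of a partial articular patch is not reliably any single one)
  ortho_basis <- function(ax) {
    ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * ax) * ax; u <- u / sqrt(sum(u^2))
    v <- c(ax[2] * u[3] - ax[3] * u[2], ax[3] * u[1] - ax[1] * u[3],
           ax[1] * u[2] - ax[2] * u[1])
    cbind(u, v)
  }
  # axis parametrised as normalize(a0 + alpha u0 + beta v0): smooth in a
  # neighbourhood of the seed direction a0 (no polar singularity);
  # Levenberg-Marquardt on the orthogonal distance residuals
  refine <- function(a0) {
    B0 <- ortho_basis(a0)
    start_r <- sqrt(mean(cyl_residuals(p, ctr, a0, 0)^2))
    resid <- function(th) {
      ax <- a0 + B0 %*% th[1:2]
      ax <- as.numeric(ax / sqrt(sum(ax^2)))
      B <- ortho_basis(ax)
      o <- ctr + as.numeric(B %*% th[3:4])
      cyl_residuals(p, o, ax, th[5])
    }
    fit <- minpack.lm::nls.lm(c(0, 0, 0, 0, start_r), fn = resid,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-15, ptol = 1e-15, maxiter = 500))
    list(par = fit$par, value = sum(resid(fit$par)^2))
  }
  # candidate seeds: all three covariance eigenvectors; two refinement
  # rounds (re-seeding from the first solution) tighten convergence
  best <- NULL; best_a0 <- NULL
  for (k in 1:3) {
    a0 <- ev$vectors[, k]
    opt <- refine(a0)
    if (is.null(best) || opt$value < best$value) { best <- opt; best_a0 <- a0 }
  }
  axis_from <- function(a0, th) {
    ax <- a0 + ortho_basis(a0) %*% th[1:2]
    as.numeric(ax / sqrt(sum(ax^2)))
  }
  ax <- axis_from(best_a0, best$par)
  opt2 <- refine(ax)
  if (opt2$value <= best$value) { best <- opt2; best_a0 <- ax }
  th <- best$par
  ax <- axis_from(best_a0, th)
  o <- ctr + as.numeric(ortho_basis(ax) %*% th[3:4])
  r <- abs(th[5])
  if (r <= 0) stop("degenerate cylinder fit: zero radius")
  # canonical axis sign: first nonzero component positive
  nz <- which(abs(ax) > 1e-8)[1]
  if (ax[nz] < 0) ax <- -ax
  res <- cyl_residuals(p, o, ax, r)
  list(centre = as.numeric(o), axis = as.numeric(ax), radius = r,
       rms_residual = sqrt(mean(res^2)))
}

fit_ellipsoid <- function(p) {
  # algebraic 9-parameter fit: x'Ax + b'x = 1
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  D <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z)
  qrD <- qr(D)
  if (qrD$rank < 9L)
    stop("degenerate ellipsoid fit: points do not span a quadric")
  v <- qr.coef(qrD, rep(1, nrow(p)))
  A <- matrix(c(v[1], v[4] / 2, v[5] / 2,
                v[4] / 2, v[2], v[6] / 2,
                v[5] / 2, v[6] / 2, v[3]), 3, 3)
  b <- v[7:9]
  ctr <- as.numeric(solve(-2 * A, b))
  scale <- 1 - as.numeric(ctr %*% A %*% ctr) - sum(b * ctr)
  ev <- eigen(A / scale, symmetric = TRUE)
  if (any(ev$values <= 0))
    stop("degenerate ellipsoid fit: quadric is not an ellipsoid")
  radii <- 1 / sqrt(ev$values)
  ord <- order(radii, decreasing = TRUE)
  # rms orthogonal residual approximated by normalised algebraic distance
  dd <- sweep(p, 2, ctr)
  q <- rowSums((dd %*% ev$vectors)^2 %*% diag(1 / radii^2))
  res <- (sqrt(q) - 1) * min(radii)
  list(centre = ctr, radii = radii[ord], axes = ev$vectors[, ord],
       rms_residual = sqrt(mean(res^2)))
}
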