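#' Octagonal hoop stack
#'
#' An ordered series of octagonal cross-sections along a body segment's
#' long axis, the raw material for lofting watertight segment shapes.
#' Hoops are 8 x 3 matrices of ordered vertices; hoop planes must proceed
#' monotonically along the segment axis.
#'
#' @param hoops list of 8 x 3 numeric matrices, ordered along the axis.
#' @param segment_name character segment label.
#' @param inflation_multipliers per-hoop scale factors (recycled from
#'   length 1); defaults to 1 (no inflation).
#' @return object of class `hoop_stack`.
#' @export
hoop_stack <- function(hoops, segment_name = "segment",
                       inflation_multipliers = 1) {
  if (length(hoops) < 2L) stop("a hoop stack needs at least 2 hoops")
  for (h in hoops) {
    if (!is.matrix(h) || nrow(h) != 8L || ncol(h) != 3L)
      stop("each hoop must be an 8 x 3 matrix of ordered vertices")
  }
  mult <- rep_len(inflation_multipliers, length(hoops))
  if (any(mult <= 0)) stop("inflation multipliers must be positive")
  structure(list(hoops = hoops, segment_name = segment_name,
                 inflation_multipliers = mult),
            class = "hoop_stack")
}

#' Regular octagon hoop
#'
#' Convenience constructor for a regular octagon of given circumradius in
#' a plane perpendicular to `axis`, centred at `centre`.
#'
#' @param centre length-3 centre point (m).
#' @param circumradius distance from centre to each vertex (m).
#' @param axis plane normal (segment long axis); default +z.
#' @return 8 x 3 matrix of vertices.
#' @export
regular_octagon <- function(centre, circumradius, axis = c(0, 0, 1)) {
  if (circumradius <= 0) stop("circumradius must be positive")
  axis <- axis / sqrt(sum(axis^2))
  # build an orthonormal basis {u, v, axis}
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  ang <- (0:7) * pi / 4
  pts <- outer(cos(ang) * circumradius, u) + outer(sin(ang) * circumradius, v)
  sweep(pts, 2, centre, `+`)
}

#' Inflate hoops about their own centroids
#'
#' Scales each octagon in its own plane about its own centroid by the
#' given multiplier(s), leaving hoop centroids unchanged. This mirrors the
#' standard correction for "shrink-wrapped" initial hoops, whose
#' multipliers are calibrated on extant animals and supplied as data.
#'
#' @param stack a `hoop_stack`.
#' @param multipliers scalar or per-hoop positive factors; defaults to the
#'   stack's own `inflation_multipliers`.
#' @return inflated `hoop_stack` (with multipliers reset to 1).
#' @export
inflate_hoops <- function(stack, multipliers = stack$inflation_multipliers) {
  stopifnot(inherits(stack, "hoop_stack"))
  mult <- rep_len(multipliers, length(stack$hoops))
  if (any(!is.finite(mult)) || any(mult <= 0))
    stop("inflation multipliers must be positive and finite")
  stack$hoops <- Map(function(h, k) {
    ctr <- colMeans(h)
    sweep(sweep(h, 2, ctr, `-`) * k, 2, ctr, `+`)
  }, stack$hoops, mult)
  stack$inflation_multipliers <- rep(1, length(stack$hoops))
  stack
}

#' Loft a hoop stack into a watertight mesh
#'
#' Joins consecutive octagons with triangulated side strips (vertex i of
#' one hoop joins vertex i of the next; no twist minimisation) and closes
#' the ends with triangle fans about the end-hoop centroids, producing a
#' watertight segment shape. Emits a warning naming the hoop indices if an
#' adjacent pair of hoops crosses (self-intersecting loft).
#'
#' @param stack a `hoop_stack`.
#' @param cap_ends logical; close the two ends (default TRUE). Open lofts
#'   are returned unvalidated.
#' @return a `paleo_mesh`.
#' @export
loft_hoops <- function(stack, cap_ends = TRUE) {
  stopifnot(inherits(stack, "hoop_stack"))
  n <- length(stack$hoops)
  if (n < 2L) stop("a hoop stack needs at least 2 hoops")
  verts <- do.call(rbind, stack$hoops)
  # detect crossing adjacent hoops: the axial direction from hoop centroid
  # j to j+1 should carry every vertex pair forward
  ctrs <- t(vapply(stack$hoops, colMeans, numeric(3)))
  for (j in seq_len(n - 1L)) {
    d <- ctrs[j + 1L, ] - ctrs[j, ]
    proj <- (stack$hoops[[j + 1L]] - stack$hoops[[j]]) %*% d
    if (any(proj < 0))
      warning(sprintf("loft may self-intersect between hoops %d and %d",
                      j, j + 1L))
  }
  faces <- vector("list", n - 1L)
  for (j in seq_len(n - 1L)) {
    a <- (j - 1L) * 8L + (1:8)           # hoop j vertex ids
    b <- j * 8L + (1:8)                  # hoop j+1 vertex ids
    nxt <- c(2:8, 1)
    # two triangles per quad; winding chosen so normals point outward for
    # hoops ordered counter-clockwise about the advancing axis (global
    # orientation is repaired by signed volume anyway)
    faces[[j]] <- rbind(cbind(a, b, b[nxt]), cbind(a, b[nxt], a[nxt]))
  }
  faces <- do.call(rbind, faces)
  if (cap_ends) {
    c1 <- nrow(verts) + 1L
    c2 <- nrow(verts) + 2L
    verts <- rbind(verts, colMeans(stack$hoops[[1L]]),
                   colMeans(stack$hoops[[n]]))
    nxt <- c(2:8, 1)
    id1 <- 1:8
    idn <- (n - 1L) * 8L + (1:8)
    faces <- rbind(faces,
                   cbind(id1, id1[nxt], c1),     # start cap
                   cbind(idn[nxt], idn, c2))     # end cap, reversed fan
  } else {
    return(structure(list(vertices = verts, faces = faces),
                     class = "paleo_mesh"))
  }
  paleo_mesh(verts, faces)
}

#' Reconstruct a caudal vertebral series by linear regression
#'
#' Fits ordinary least squares of centrum length and height against
#' vertebra number for the measured caudal vertebrae and predicts the
#' dimensions of the missing distal vertebrae, representing each vertebral
#' segment as a cylinder (height taken as the dorsoventral extent, hence
#' used as cylinder diameter). Axial gaps of `gap_fraction` times the
#' local segment length are inserted between successive cylinders to
#' represent missing intervertebral soft tissue.
#'
#' @param measured data.frame with columns `vertebra`, `length`, `height`
#'   (numbers; metres).
#' @param n_total total number of caudal vertebrae assumed in the series
#'   (default 30).
#' @param gap_fraction fraction of each vertebral length added as a gap
#'   after it (default 0.10).
#' @return list of class `caudal_series` with a `segments` data.frame
#'   (`vertebra`, `length`, `height`, `radius`, `start`, `end`,
#'   `measured`), regression fits `fit_length`, `fit_height`, their
#'   `r_squared` (named vector), and `total_extent` (m).
#' @export
reconstruct_caudal_series <- function(measured, n_total = 30,
                                      gap_fraction = 0.10) {
  measured <- as.data.frame(measured)
  need <- c("vertebra", "length", "height")
  if (!all(need %in% names(measured)))
    stop("measured needs columns vertebra, length, height")
  if (nrow(measured) < 3L)
    stop("need at least 3 measured vertebrae for regression")
  if (anyDuplicated(measured$vertebra))
    stop("measured vertebra numbers must be unique")
  if (n_total < max(measured$vertebra))
    stop("n_total must be >= the largest measured vertebra number")
  fit_l <- stats::lm(length ~ vertebra, data = measured)
  fit_h <- stats::lm(height ~ vertebra, data = measured)
  r2 <- suppressWarnings(  # summary.lm warns on perfect fits
    c(length = summary(fit_l)$r.squared,
      height = summary(fit_h)$r.squared))
  all_n <- seq_len(n_total)
  pred_l <- stats::predict(fit_l, data.frame(vertebra = all_n))
  pred_h <- stats::predict(fit_h, data.frame(vertebra = all_n))
  is_meas <- all_n %in% measured$vertebra
  len <- ifelse(is_meas,
                measured$length[match(all_n, measured$vertebra)], pred_l)
  hei <- ifelse(is_meas,
                measured$height[match(all_n, measured$vertebra)], pred_h)
  # negative extrapolations are clamped to the smallest measured value
  if (any(len <= 0) || any(hei <= 0)) {
    warning("negative predicted dimension clamped to smallest measured value")
    len[len <= 0] <- min(measured$length)
    hei[hei <= 0] <- min(measured$height)
  }
  gap <- gap_fraction * len
  end <- cumsum(len + gap)
  start <- end - len - gap
  segments <- data.frame(vertebra = all_n, length = len, height = hei,
                         radius = hei / 2, start = start,
                         end = start + len, measured = is_meas)
  structure(list(segments = segments, fit_length = fit_l,
                 fit_height = fit_h, r_squared = r2,
                 # total axial extent: lengths plus inter-cylinder gaps
                 # (no trailing gap after the last vertebra)
                 total_extent = sum(len) + sum(gap) - gap[n_total]),
            class = "caudal_series")
}
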