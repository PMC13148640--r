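## Synthetic fixture generator: parametric skeletons, muscles, character
## matrices and morphometric datasets, each shipped with its own
## closed-form or exhaustively enumerated reference answer so the whole
## pipeline can run and be tested offline.

#' Axis-aligned box mesh
#'
#' Watertight triangulated box between two corners; a convenience solid
#' for collision fixtures and tests.
#'
#' @param lo,hi length-3 opposite corners (m).
#' @return a `paleo_mesh`.
#' @export
box_mesh <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(v) <- NULL
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  paleo_mesh(v, f)
}

#' Combine meshes into one (possibly multi-component) surface
#'
#' @param ... `paleo_mesh` objects.
#' @return a `paleo_mesh` (validation skipped: components are
#'   individually closed).
#' @export
merge_meshes <- function(...) {
  ms <- list(...)
  verts <- NULL; faces <- NULL; off <- 0L
  for (m in ms) {
    verts <- rbind(verts, m$vertices)
    faces <- rbind(faces, m$faces + off)
    off <- off + nrow(m$vertices)
  }
  structure(list(vertices = verts, faces = faces), class = "paleo_mesh")
}

#' Default toy taxon specification
#'
#' A small quadrupedal archosauriform-scale animal (~1 kg, segment
#' lengths 0.05-0.3 m) whose body segments are octagonal-prism lofts with
#' closed-form volumes. Cavity fractions emulate the air spaces of the
#' head/neck and trunk; joint limits follow the packaged focal-taxon
#' configuration.
#'
#' @param seed integer seed recorded in the spec (generation itself is
#'   deterministic).
#' @return list of class `toy_taxon_spec`.
#' @export
toy_taxon_spec <- function(seed = 1) {
  segments <- data.frame(
    name   = c("head_neck", "trunk", "body", "proximal_tail",
               "distal_tail", "thigh", "crus", "pes"),
    length = c(0.12, 0.12, 0.10, 0.15, 0.20, 0.08, 0.07, 0.05),
    radius = c(0.025, 0.035, 0.035, 0.020, 0.010, 0.015, 0.010, 0.008),
    cavity_fraction = c(0.05, 0.08, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  structure(list(seed = seed, segments = segments, density = 1060,
                 femur_length = 0.080,
                 hip_midpoint = c(0, 0, 0),
                 craniocaudal_axis = c(1, 0, 0)),
            class = "toy_taxon_spec")
}

octagon_prism_volume <- function(circumradius, length) {
  2 * sqrt(2) * circumradius^2 * length
}

#' Generate a toy skeleton: body model plus kinematic chain
#'
#' Builds every body segment as an octagonal-prism hoop loft laid along
#' the craniocaudal (x) axis - head/neck and torso cranial to the hips,
#' tail caudal - with analytically known volume (2 sqrt(2) r^2 L per
#' prism) and centroid, plus a right-hindlimb kinematic chain (hip 3 DOF,
#' knee 1, ankle 3, third metatarsophalangeal 1) with the packaged sign
#' conventions and ROM limits. Cavity segments carry a coaxial internal
#' prism sized to the spec's cavity fraction.
#'
#' @param spec a `toy_taxon_spec`.
#' @return list with `model` (a `body_model`), `chain`
#'   (a `kinematic_chain`), `expected` (closed-form per-segment volumes,
#'   masses, coms and totals).
#' @export
make_toy_skeleton <- function(spec = toy_taxon_spec()) {
  stopifnot(inherits(spec, "toy_taxon_spec"))
  seg <- spec$segments
  # axial layout: body ends at the hips (x = 0), more cranial segments
  # stack toward +x, tail toward -x
  cranial <- c("head_neck", "trunk", "body")
  caudal <- c("proximal_tail", "distal_tail")
  x_hi <- sum(seg$length[match(cranial, seg$name)])
  starts <- stats::setNames(numeric(nrow(seg)), seg$name)
  x <- x_hi
  for (nm in cranial) { starts[nm] <- x; x <- x - seg$length[seg$name == nm] }
  x <- 0
  for (nm in caudal) { starts[nm] <- x; x <- x - seg$length[seg$name == nm] }
  # limb segments hang below the hip, along -y; they are stored as
  # prisms along their own long axis
  segments <- list()
  expected <- list()
  for (i in seq_len(nrow(seg))) {
    nm <- seg$name[i]; L <- seg$length[i]; r <- seg$radius[i]
    axial <- nm %in% c(cranial, caudal)
    if (axial) {
      c0 <- c(starts[nm] - L, 0.02, 0)  # slight dorsal offset of axis
      axis <- c(1, 0, 0)
      h1 <- regular_octagon(c0, r, axis)
      h2 <- regular_octagon(c0 + axis * L, r, axis)
    } else {
      y0 <- -0.02 - sum(seg$length[match(c("thigh", "crus", "pes"),
                                         seg$name)][
        seq_len(match(nm, c("thigh", "crus", "pes")) - 1)])
      c0 <- c(0, y0, 0.03)
      axis <- c(0, -1, 0)
      h1 <- regular_octagon(c0, r, axis)
      h2 <- regular_octagon(c0 + axis * L, r, axis)
    }
    solid <- loft_hoops(hoop_stack(list(h1, h2), nm))
    cavities <- list()
    vol <- octagon_prism_volume(r, L)
    cav_vol <- 0
    cf <- seg$cavity_fraction[i]
    if (cf > 0) {
      # coaxial internal prism with the same length fraction 0.8 and
      # radius chosen to give exactly the requested volume fraction
      rc <- r * sqrt(cf / 0.8)
      cc0 <- c0 + axis * (0.1 * L)
      cav <- loft_hoops(hoop_stack(list(
        regular_octagon(cc0, rc, axis),
        regular_octagon(cc0 + axis * (0.8 * L), rc, axis))))
      cavities <- list(cav)
      cav_vol <- octagon_prism_volume(rc, 0.8 * L)
    }
    segments[[nm]] <- body_segment(nm, solid, cavities, spec$density)
    centroid <- c0 + axis * (L / 2)
    expected[[nm]] <- list(volume = vol, cavity_volume = cav_vol,
                           mass = spec$density * (vol - cav_vol),
                           com = centroid)
  }
  exp_masses <- vapply(expected, `[[`, numeric(1), "mass")
  exp_com <- colSums(t(vapply(expected, `[[`, numeric(3), "com")) *
                       exp_masses) / sum(exp_masses)
  model <- body_model(unname(segments), hip_midpoint = spec$hip_midpoint,
                      femur_length = spec$femur_length,
                      craniocaudal_axis = spec$craniocaudal_axis)
  chain <- make_toy_chain(spec)
  list(model = model, chain = chain,
       expected = list(segments = expected, total_mass = sum(exp_masses),
                       com = exp_com))
}

make_toy_chain <- function(spec = toy_taxon_spec()) {
  fl <- spec$femur_length
  hip_o <- c(0, 0, 0)
  knee_o <- c(0, -fl, 0)
  ankle_o <- c(0, -fl - 0.15, 0)
  mtp_o <- c(0.05, -fl - 0.15, 0)
  cfg <- gracilisuchus_joint_config()
  lim <- function(joint) {
    sub <- cfg[cfg$joint == joint, ]
    stats::setNames(lapply(seq_len(nrow(sub)),
                           function(i) c(sub$min[i], sub$max[i])), sub$dof)
  }
  sgn <- function(joint) {
    sub <- cfg[cfg$joint == joint, ]
    as.list(stats::setNames(sub$motion, sub$dof))
  }
  bones <- list(
    pelvis = list(rest = diag(4), long_axis = c(0, -1, 0)),
    femur = list(rest = diag(4), length = fl, long_axis = c(0, -1, 0)),
    tibia = list(rest = diag(4), length = 0.15, long_axis = c(0, -1, 0)),
    pes = list(rest = diag(4), length = 0.05, long_axis = c(1, 0, 0)),
    toe = list(rest = diag(4), length = 0.03, long_axis = c(1, 0, 0)))
  joints <- list(
    joint_spec("hip", "pelvis", "femur", frame_acs(hip_o),
               dof_mask = c("x", "y", "z"), sign_convention = sgn("hip"),
               rom_limits = lim("hip")),
    joint_spec("knee", "femur", "tibia", frame_acs(knee_o),
               dof_mask = "z", sign_convention = sgn("knee"),
               rom_limits = lim("knee")),
    joint_spec("ankle", "tibia", "pes", frame_acs(ankle_o),
               dof_mask = c("x", "y", "z"), sign_convention = sgn("ankle"),
               rom_limits = lim("ankle")),
    joint_spec("mtp3", "pes", "toe", frame_acs(mtp_o),
               dof_mask = "z", sign_convention = sgn("mtp3"),
               rom_limits = lim("mtp3")))
  kinematic_chain(bones, joints)
}

#' Generate toy muscles with analytically known moment arms
#'
#' Builds a small muscle set on the toy hindlimb chain, each with a
#' closed-form moment arm recorded in a registry for oracle testing:
#' a caudofemoralis-like hip muscle fully wrapped on a cylinder coaxial
#' with the hip flexion/extension axis (|MMA| = wrap radius while
#' wrapped), a knee muscle crossing the hinge as a straight line at a
#' known perpendicular distance, a gastrocnemius-like ankle extensor
#' acting through a calcaneal-tuber-like lever (straight line at the
#' tuber offset), and an axis-parallel muscle with zero moment arm.
#'
#' @param spec a `toy_taxon_spec`.
#' @return list with `muscles` (list of `muscle_path`) and `registry`
#'   (data.frame: muscle, joint, dof, angle_deg, analytic_mma).
#' @export
make_toy_muscles <- function(spec = toy_taxon_spec()) {
  fl <- spec$femur_length
  wrap_r <- 0.012
  cfl_wrap <- wrap_surface("cylinder", "pelvis", diag(4), wrap_r,
                           active_side = 1)
  attr(cfl_wrap, "span") <- 1L
  muscles <- list(
    cfl = muscle_path("CFL_like", list(
      list(bone = "pelvis", xyz = c(-0.05, 0.004, 0)),
      list(bone = "femur", xyz = c(0.05, 0.004, 0))), list(cfl_wrap)),
    knee_ext = muscle_path("KE_like", list(
      list(bone = "femur", xyz = c(0.02, -fl + 0.05, 0)),
      list(bone = "tibia", xyz = c(0.02, -fl - 0.05, 0)))),
    gast = muscle_path("GAST_like", list(
      list(bone = "tibia", xyz = c(-0.008, -fl - 0.10, 0)),
      list(bone = "pes", xyz = c(-0.008, -fl - 0.155, 0)))),
    parallel = muscle_path("PAR_like", list(
      list(bone = "femur", xyz = c(0.02, -fl - 0.005, -0.05)),
      list(bone = "tibia", xyz = c(0.02, -fl - 0.005, 0.05)))))
  registry <- data.frame(
    muscle = c("CFL_like", "KE_like", "GAST_like", "PAR_like"),
    joint = c("hip", "knee", "ankle", "knee"),
    dof = "z",
    angle_deg = 0,
    analytic_mma = c(-wrap_r, 0.02, -0.008, 0),
    note = c("fully wrapped: |MMA| = wrap radius",
             "straight line at 0.02 m from hinge",
             "tuber lever at 0.008 m from hinge",
             "axis-parallel: zero moment arm"))
  list(muscles = muscles, registry = registry)
}

#' Generate a toy tree and character matrix with a brute-force solution
#'
#' Random rooted tree plus random multistate character matrix at desk
#' scale, accompanied by the exhaustively enumerated minimum change
#' count and most-parsimonious-reconstruction state sets for every
#' internal node - the independent oracle against which the dynamic
#' programming optimiser is tested.
#'
#' @param seed integer seed (all randomness flows from it).
#' @param n_tips number of tips (<= 8; enumeration is exponential).
#' @param n_chars number of characters.
#' @param n_states states per character (<= 3).
#' @param missing_frac fraction of cells set to "?" (default 0).
#' @return list with `tree`, `matrix` (`character_matrix`), `oracle`
#'   (list per character: `changes`, `node_sets`).
#' @export
make_toy_characters <- function(seed = 1, n_tips = 6, n_chars = 10,
                                n_states = 2, missing_frac = 0) {
  stopifnot(n_tips <= 8, n_states <= 3)
  set.seed(seed)
  tree <- ape::rtree(n_tips, rooted = TRUE)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  m <- matrix(sample(0:(n_states - 1), n_tips * n_chars, replace = TRUE),
              n_tips, n_chars, dimnames = list(tree$tip.label, NULL))
  storage.mode(m) <- "integer"
  if (missing_frac > 0) {
    idx <- which(stats::runif(length(m)) < missing_frac)
    m[idx] <- NA_integer_
  }
  oracle <- lapply(seq_len(n_chars), function(ch)
    enumerate_parsimony(tree, m[, ch], n_states))
  list(tree = tree,
       matrix = structure(m, class = "character_matrix"),
       oracle = oracle)
}

#' Exhaustive-enumeration parsimony oracle
#'
#' Brute-force minimum change count and MPR state sets for one character
#' on a small rooted tree, by enumerating every assignment of states to
#' internal nodes. Independent of the dynamic-programming optimiser;
#' exponential in the number of internal nodes, so desk scale only.
#'
#' @param tree rooted `phylo` (<= ~8 tips).
#' @param tip_states integer vector named/ordered by `tree$tip.label`
#'   (NA = missing, any state allowed).
#' @param n_states number of states (codes 0..n_states-1).
#' @return list with `changes` (minimum) and `node_sets` (list per
#'   internal node, ape numbering, of states attaining the minimum).
#' @export
enumerate_parsimony <- function(tree, tip_states, n_states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  edges <- tree$edge
  combos <- as.matrix(expand.grid(rep(list(0:(n_states - 1)), n_int)))
  cost <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    assign_ <- combos[r, ]
    cc <- 0
    for (e in seq_len(nrow(edges))) {
      a <- assign_[edges[e, 1] - n_tip]
      b <- edges[e, 2]
      if (b <= n_tip) {
        s <- tip_states[b]
        if (!is.na(s) && s != a) cc <- cc + 1
      } else if (assign_[b - n_tip] != a) cc <- cc + 1
    }
    cost[r] <- cc
  }
  best <- min(cost)
  node_sets <- lapply(seq_len(n_int), function(i)
    sort(unique(combos[cost == best, i])))
  list(changes = best, node_sets = node_sets)
}

#' Generate a toy two-class morphometric dataset
#'
#' Draws labelled biped and quadruped classes from multivariate normal
#' distributions with stated means and shared covariance, plus one
#' "unknown" focal row at a stated displacement from the quadruped
#' centroid - the recovery target for the repeated-LDA battery.
#'
#' @param seed integer seed.
#' @param biped_mean,quadruped_mean length-4 class means for
#'   (body_mass, dimensionless_com, forelimb_length, hindlimb_length).
#' @param covariance 4 x 4 shared covariance (default identity * sigma^2
#'   with sigma = 1).
#' @param n per-class sample size (default 40).
#' @param focal_offset displacement of the focal taxon from the
#'   quadruped mean (default 0).
#' @return `data.frame` (a stance dataset); the focal row is last,
#'   labelled "unknown".
#' @export
make_toy_morphometrics <- function(seed = 1,
                                   biped_mean = rep(0, 4),
                                   quadruped_mean = rep(3, 4),
                                   covariance = diag(4),
                                   n = 40,
                                   focal_offset = rep(0, 4)) {
  set.seed(seed)
  cols <- c("body_mass", "dimensionless_com", "forelimb_length",
            "hindlimb_length")
  draw <- function(mu, label) {
    x <- MASS::mvrnorm(n, mu, covariance)
    colnames(x) <- cols
    cbind(as.data.frame(x), stance = label)
  }
  d <- rbind(draw(biped_mean, "biped"), draw(quadruped_mean, "quadruped"))
  focal <- as.data.frame(as.list(stats::setNames(
    quadruped_mean + focal_offset, cols)))
  focal$stance <- "unknown"
  rbind(d, focal)
}
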