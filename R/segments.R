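#' Body segment with optional zero-density cavities
#'
#' A fleshed-out body segment: a watertight outer solid plus zero or more
#' watertight internal air cavities (pharynx, trachea, lungs) that are
#' subtracted at zero density, lowering the segment's net density below
#' the base tissue density.
#'
#' @param name segment label.
#' @param solid outer `paleo_mesh`.
#' @param cavities list of `paleo_mesh` cavities (may be empty).
#' @param density base tissue density, kg m^-3 (default 1060).
#' @return object of class `body_segment`.
#' @export
body_segment <- function(name, solid, cavities = list(), density = 1060) {
  stopifnot(inherits(solid, "paleo_mesh"))
  if (inherits(cavities, "paleo_mesh")) cavities <- list(cavities)
  structure(list(name = name, solid = solid, cavities = cavities,
                 density = density),
            class = "body_segment")
}

#' Mass properties of a segment with air cavities
#'
#' Subtracts zero-density cavity volumes from the solid: mass is
#' density x (V_solid - sum V_cavity) and the centre of mass is the
#' signed combination of solid and cavity first moments. The net density
#' (mass over solid volume) is reported so that cavity bookkeeping can be
#' compared with published segment densities.
#'
#' @param segment a `body_segment`.
#' @return `mass_properties` with an extra `net_density` field.
#' @export
composite_segment_properties <- function(segment) {
  stopifnot(inherits(segment, "body_segment"))
  mp_solid <- mesh_mass_properties(segment$solid, segment$density)
  v_cav <- 0
  moment_cav <- c(0, 0, 0)
  inertia_cav <- matrix(0, 3, 3)
  for (cav in segment$cavities) {
    mp <- mesh_mass_properties(cav, segment$density)
    v_cav <- v_cav + mp$volume
    moment_cav <- moment_cav + mp$mass * mp$com
    inertia_cav <- inertia_cav + mp$inertia_origin
  }
  if (v_cav >= mp_solid$volume)
    stop(sprintf("segment '%s': cavity volume (%.4g) >= solid volume (%.4g)",
                 segment$name, v_cav, mp_solid$volume))
  net_vol <- mp_solid$volume - v_cav
  mass <- segment$density * net_vol
  com <- (mp_solid$mass * mp_solid$com - moment_cav) / mass
  J0 <- mp_solid$inertia_origin - inertia_cav
  c2 <- sum(com^2)
  Jc <- J0 - mass * (diag(c2, 3) - outer(com, com))
  structure(list(mass = mass, com = com, inertia = Jc, inertia_origin = J0,
                 volume = net_vol, density = segment$density,
                 net_density = mass / mp_solid$volume),
            class = "mass_properties")
}

#' Whole-body model
#'
#' Collects body segments together with the anatomical landmarks needed
#' for the bipedalism bookkeeping: the hip midpoint, the femur length and
#' the craniocaudal unit axis (conventionally defined by the sacral
#' vertebrae, pointing cranially).
#'
#' @param segments list of `body_segment`.
#' @param hip_midpoint length-3 point (m).
#' @param femur_length femur length (m).
#' @param craniocaudal_axis length-3 vector, normalised internally.
#' @return object of class `body_model`.
#' @export
body_model <- function(segments, hip_midpoint = c(0, 0, 0),
                       femur_length = NA_real_,
                       craniocaudal_axis = c(1, 0, 0)) {
  if (inherits(segments, "body_segment")) segments <- list(segments)
  stopifnot(all(vapply(segments, inherits, TRUE, "body_segment")))
  axis <- craniocaudal_axis / sqrt(sum(craniocaudal_axis^2))
  structure(list(segments = segments, hip_midpoint = hip_midpoint,
                 femur_length = femur_length, craniocaudal_axis = axis),
            class = "body_model")
}

#' Whole-body mass, centre of mass and bipedality summary
#'
#' Totals segment masses, computes the mass-weighted whole-body centre of
#' mass, per-segment mass fractions, the cranial offset of the COM from
#' the hip midpoint (projection onto the craniocaudal axis) and the
#' bipedality ratio (COM offset divided by femur length), reported as a
#' percentage. A COM much less than one femur length cranial to the hips
#' is a necessary condition for static bipedal standing.
#'
#' @param model a `body_model`.
#' @return list of class `body_summary`: `total_mass` (kg), `com` (m),
#'   `fractions` (named, sums to 1), `segment_masses`,
#'   `com_cranial_offset` (m), `bipedality_ratio_pct` (percent of femur
#'   length; NA when femur length unset).
#' @export
whole_body_summary <- function(model) {
  stopifnot(inherits(model, "body_model"))
  if (length(model$segments) < 1L) stop("model has no segments")
  props <- lapply(model$segments, composite_segment_properties)
  masses <- vapply(props, `[[`, numeric(1), "mass")
  names(masses) <- vapply(model$segments, `[[`, character(1), "name")
  total <- sum(masses)
  if (total <= 0) stop("zero total mass")
  com <- colSums(do.call(rbind, lapply(props, `[[`, "com")) * masses) / total
  offset <- sum((com - model$hip_midpoint) * model$craniocaudal_axis)
  ratio <- if (is.finite(model$femur_length) && model$femur_length > 0)
    100 * offset / model$femur_length else NA_real_
  structure(list(total_mass = total, com = com,
                 fractions = masses / total, segment_masses = masses,
                 com_cranial_offset = offset,
                 bipedality_ratio_pct = ratio),
            class = "body_summary")
}

#' @export
print.body_summary <- function(x, ...) {
  cat(sprintf("total mass: %.4f kg\n", x$total_mass))
  cat(sprintf("whole-body COM: (%.4g, %.4g, %.4g) m\n",
              x$com[1], x$com[2], x$com[3]))
  cat(sprintf("COM cranial offset from hips: %.4g m\n", x$com_cranial_offset))
  if (is.finite(x$bipedality_ratio_pct))
    cat(sprintf("COM offset / femur length: %.0f%%\n", x$bipedality_ratio_pct))
  cat("segment mass fractions:\n")
  print(round(x$fractions, 4))
  invisible(x)
}
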