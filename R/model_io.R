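## Readers/writers for the standard formats the pipeline touches
## (Wavefront OBJ meshes, a small OpenSim-style XML model subset, CSV
## tables, YAML configs) and the end-to-end pipeline driver.

#' Read a Wavefront OBJ mesh
#'
#' Parses `v` and `f` lines; polygon faces are fan-triangulated on read.
#' Texture/normal indices in face tokens (`v/vt/vn`) are ignored.
#'
#' @param path OBJ file path.
#' @param validate check watertightness (default TRUE).
#' @return a `paleo_mesh`.
#' @export
read_obj <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  vidx <- grepl("^v ", lines)
  fidx <- grepl("^f ", lines)
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", lines[vidx])),
                                          "\\s+"), function(x) {
    as.numeric(x[1:3])
  }))
  faces <- list()
  for (ln in which(fidx)) {
    toks <- strsplit(trimws(sub("^f", "", lines[ln])), "\\s+")[[1]]
    ids <- suppressWarnings(as.integer(sub("/.*", "", toks)))
    if (any(is.na(ids)) || length(ids) < 3)
      stop(sprintf("malformed face at line %d of %s", ln, path))
    for (k in seq_len(length(ids) - 2L))  # fan triangulation
      faces[[length(faces) + 1L]] <- c(ids[1], ids[k + 1L], ids[k + 2L])
  }
  paleo_mesh(verts, do.call(rbind, faces), validate = validate)
}

#' Write a Wavefront OBJ mesh
#'
#' @param mesh a `paleo_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a musculoskeletal model from an OpenSim-style XML subset
#'
#' Parses the subset of the `.osim` XML format this package writes and
#' reads: `Body` elements (bones), `CustomJoint` elements with a
#' parent/child body, a joint-frame translation and orientation
#' (body-fixed z-y-x), and per-axis coordinate names; muscle
#' `GeometryPath`/`PathPoint` sets; and `WrapCylinder`/`WrapSphere`
#' elements. Every other element is recorded in the returned manifest of
#' skipped elements, never silently dropped.
#'
#' @param path `.osim` XML file.
#' @return list with `chain` (a `kinematic_chain`), `muscles` (list of
#'   `muscle_path`) and `manifest` (character vector of skipped element
#'   names).
#' @export
read_osim_subset <- function(path) {
  doc <- xml2::read_xml(path)
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing")) stop("no <Model> element found")
  manifest <- character(0)
  known_top <- c("BodySet", "JointSet", "ForceSet", "WrapObjectSet")
  for (child in xml2::xml_children(model)) {
    nm <- xml2::xml_name(child)
    if (!nm %in% known_top)
      manifest <- c(manifest, sprintf("Model/%s", nm))
  }
  num3 <- function(node, tag, default = c(0, 0, 0)) {
    x <- xml2::xml_find_first(node, sprintf("./%s", tag))
    if (inherits(x, "xml_missing")) return(default)
    as.numeric(strsplit(trimws(xml2::xml_text(x)), "\\s+")[[1]])
  }
  bones <- list()
  for (b in xml2::xml_find_all(model, ".//BodySet//Body")) {
    bones[[xml2::xml_attr(b, "name")]] <- list(rest = diag(4))
    for (child in xml2::xml_children(b)) {
      nm <- xml2::xml_name(child)
      if (!nm %in% c("mass", "mass_center", "inertia"))
        manifest <- c(manifest, sprintf("Body/%s", nm))
    }
  }
  joints <- list()
  for (j in xml2::xml_find_all(model, ".//JointSet//CustomJoint")) {
    name <- xml2::xml_attr(j, "name")
    parent <- xml2::xml_text(xml2::xml_find_first(j, "./parent_body"))
    child <- xml2::xml_text(xml2::xml_find_first(j, "./child_body"))
    loc <- num3(j, "location_in_parent")
    ori <- num3(j, "orientation_in_parent")
    dofs <- xml2::xml_find_all(j, ".//TransformAxis")
    dof_mask <- character(0)
    for (ax in dofs) {
      v <- as.numeric(strsplit(trimws(xml2::xml_text(
        xml2::xml_find_first(ax, "./axis"))), "\\s+")[[1]])
      dof_mask <- c(dof_mask, c("x", "y", "z")[which.max(abs(v))])
    }
    if (length(dof_mask) == 0)
      stop(sprintf("joint '%s': unsupported parameterization (no rotation axes)",
                   name))
    lims <- list(); sgn <- list()
    for (ax in dofs) {
      d <- c("x", "y", "z")[which.max(abs(as.numeric(strsplit(trimws(
        xml2::xml_text(xml2::xml_find_first(ax, "./axis"))), "\\s+")[[1]])))]
      rng <- xml2::xml_find_first(ax, "./range")
      lims[[d]] <- if (!inherits(rng, "xml_missing"))
        as.numeric(strsplit(trimws(xml2::xml_text(rng)), "\\s+")[[1]])
      else NULL
      conv <- xml2::xml_find_first(ax, "./convention")
      sgn[[d]] <- if (!inherits(conv, "xml_missing")) xml2::xml_text(conv)
                  else "unspecified"
    }
    axes <- euler_zyx_matrix(ori)
    joints[[name]] <- joint_spec(name, parent, child,
                                 frame_acs(loc, axes),
                                 dof_mask = unique(dof_mask),
                                 sign_convention = sgn,
                                 rom_limits = Filter(Negate(is.null), lims))
  }
  muscles <- list()
  for (mu in xml2::xml_find_all(model, ".//ForceSet//*[GeometryPath]")) {
    name <- xml2::xml_attr(mu, "name")
    pts <- list()
    for (pp in xml2::xml_find_all(mu, ".//PathPoint")) {
      pts[[length(pts) + 1L]] <- list(
        bone = xml2::xml_text(xml2::xml_find_first(pp, "./body")),
        xyz = num3(pp, "location"))
    }
    wraps <- list()
    for (kind in c("WrapCylinder", "WrapSphere")) {
      for (w in xml2::xml_find_all(mu, sprintf(".//%s", kind))) {
        tr <- diag(4)
        tr[1:3, 4] <- num3(w, "translation")
        tr[1:3, 1:3] <- euler_zyx_matrix(num3(w, "xyz_body_rotation"))
        ws <- wrap_surface(
          if (kind == "WrapCylinder") "cylinder" else "sphere",
          bone = xml2::xml_text(xml2::xml_find_first(w, "./body")),
          transform = tr,
          radius = as.numeric(xml2::xml_text(
            xml2::xml_find_first(w, "./radius"))),
          active_side = {
            a <- xml2::xml_find_first(w, "./active_side")
            if (inherits(a, "xml_missing")) 1 else as.numeric(xml2::xml_text(a))
          })
        attr(ws, "span") <- {
          sp <- xml2::xml_find_first(w, "./span")
          if (inherits(sp, "xml_missing")) 1L
          else as.integer(xml2::xml_text(sp))
        }
        wraps[[length(wraps) + 1L]] <- ws
      }
    }
    muscles[[name]] <- muscle_path(name, pts, wraps)
  }
  chain <- if (length(joints) > 0) kinematic_chain(bones, joints) else NULL
  list(chain = chain, muscles = muscles, manifest = unique(manifest))
}

#' Write a kinematic chain and muscles as the OpenSim-style XML subset
#'
#' Emits the same element subset that [read_osim_subset()] parses, so a
#' model round-trips through the pair.
#'
#' @param chain a `kinematic_chain`.
#' @param muscles list of `muscle_path` (optional).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_osim_subset <- function(chain, muscles = list(), path) {
  doc <- xml2::xml_new_root("OpenSimDocument", Version = "40500")
  model <- xml2::xml_add_child(doc, "Model", name = "paleolimb_model")
  bodyset <- xml2::xml_add_child(model, "BodySet")
  objs <- xml2::xml_add_child(bodyset, "objects")
  for (b in names(chain$bones))
    xml2::xml_add_child(objs, "Body", name = b)
  jointset <- xml2::xml_add_child(model, "JointSet")
  jobjs <- xml2::xml_add_child(jointset, "objects")
  fmt3 <- function(x) paste(sprintf("%.12g", x), collapse = " ")
  for (j in chain$joints) {
    jn <- xml2::xml_add_child(jobjs, "CustomJoint", name = j$name)
    xml2::xml_add_child(jn, "parent_body", j$parent_bone)
    xml2::xml_add_child(jn, "child_body", j$child_bone)
    xml2::xml_add_child(jn, "location_in_parent", fmt3(j$jcs$origin))
    xml2::xml_add_child(jn, "orientation_in_parent",
                        fmt3(euler_zyx_angles(j$jcs$axes)))
    st <- xml2::xml_add_child(jn, "SpatialTransform")
    unit <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
    for (d in j$dof_mask) {
      ta <- xml2::xml_add_child(st, "TransformAxis",
                                name = paste0(j$name, "_", d))
      xml2::xml_add_child(ta, "axis", fmt3(unit[[d]]))
      if (!is.null(j$rom_limits[[d]]))
        xml2::xml_add_child(ta, "range", fmt3(j$rom_limits[[d]]))
      xml2::xml_add_child(ta, "convention",
                          j$sign_convention[[d]] %||% "unspecified")
    }
  }
  if (length(muscles) > 0) {
    fs <- xml2::xml_add_child(model, "ForceSet")
    fobjs <- xml2::xml_add_child(fs, "objects")
    for (m in muscles) {
      mn <- xml2::xml_add_child(fobjs, "Thelen2003Muscle", name = m$name)
      gp <- xml2::xml_add_child(mn, "GeometryPath")
      pps <- xml2::xml_add_child(gp, "PathPointSet")
      for (p in m$points) {
        pp <- xml2::xml_add_child(pps, "PathPoint")
        xml2::xml_add_child(pp, "body", p$bone)
        xml2::xml_add_child(pp, "location", fmt3(p$xyz))
      }
      if (length(m$wraps) > 0) {
        ws <- xml2::xml_add_child(gp, "PathWrapSet")
        for (w in m$wraps) {
          wn <- xml2::xml_add_child(ws, if (w$kind == "cylinder")
            "WrapCylinder" else "WrapSphere")
          xml2::xml_add_child(wn, "body", w$bone)
          xml2::xml_add_child(wn, "translation", fmt3(w$transform[1:3, 4]))
          xml2::xml_add_child(wn, "xyz_body_rotation",
                              fmt3(euler_zyx_angles(w$transform[1:3, 1:3])))
          xml2::xml_add_child(wn, "radius", sprintf("%.12g", w$radius))
          xml2::xml_add_child(wn, "active_side",
                              sprintf("%d", w$active_side))
          xml2::xml_add_child(wn, "span",
                              sprintf("%d", attr(w, "span") %||% 1L))
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Run the full analysis pipeline on a configuration
#'
#' Drives every stage in dependency order on synthetic fixtures (or
#' user-supplied inputs): body segment parameters and whole-body COM,
#' the ROM table, the dimensionless moment-arm report, the
#' parsimony-based muscle map, and the stance analyses; writes CSV/JSON
#' reports plus a log to `out_dir` and returns the results. Rerunning
#' with the same config and seed reproduces identical outputs.
#'
#' @param config list (or path to a YAML file) with optional elements:
#'   `seed` (default 1), `out_dir` (default tempdir()), `toy_spec`
#'   (a `toy_taxon_spec`), `mma_grid_step` (deg, default 5),
#'   `stylopodial` (list with `humeral`, `femoral` circumference mm).
#' @return list of class `pipeline_result` with `bsp`, `summary`, `rom`,
#'   `mma`, `muscle_map`, `stance`, `paths`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% file.path(tempdir(), "paleolimb_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    say("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("stage %s: done", name)
    res
  }
  spec <- config$toy_spec %||% toy_taxon_spec(seed)
  sk <- stage("skeleton", make_toy_skeleton(spec))
  summ <- stage("bsp", whole_body_summary(sk$model))
  bsp <- data.frame(
    segment = names(summ$segment_masses),
    mass_kg = as.numeric(summ$segment_masses),
    fraction = as.numeric(summ$fractions))
  utils::write.csv(bsp, file.path(out_dir, "bsp.csv"), row.names = FALSE)
  rom <- stage("rom", rom_table(sk$chain))
  utils::write.csv(rom, file.path(out_dir, "rom.csv"), row.names = FALSE)
  tm <- make_toy_muscles(spec)
  dof_table <- data.frame(
    joint = c("hip", "hip", "knee", "ankle"),
    dof = c("z", "y", "z", "z"),
    normalizing_length = c(spec$femur_length, spec$femur_length,
                           0.15, 0.031))
  mma <- stage("mma", mma_report(tm$muscles, sk$chain, dof_table,
                                 assignments = tm$registry,
                                 grid_step = config$mma_grid_step %||% 5))
  utils::write.csv(mma, file.path(out_dir, "mma.csv"), row.names = FALSE)
  mm <- stage("muscle_map",
              build_muscle_map(gracilisuchus_muscle_dictionary()))
  utils::write.csv(mm, file.path(out_dir, "muscle_map.csv"),
                   row.names = FALSE)
  sty <- config$stylopodial %||% list(humeral = 14, femoral = 13)
  morpho <- make_toy_morphometrics(seed)
  verdict <- stage("stance", lda_stance_tests(morpho, nrow(morpho),
                                              seed = seed))
  stance <- list(
    allometric_mass_kg = campione_evans_mass(sty$humeral, sty$femoral),
    model_mass_kg = summ$total_mass,
    com_cranial_offset_m = summ$com_cranial_offset,
    bipedality = static_bipedalism_check(
      summ$com_cranial_offset, spec$femur_length)[c("ratio_pct", "verdict")],
    lda = list(tally = verdict$tally, n_tests = verdict$n_tests,
               majority = verdict$majority))
  jsonlite::write_json(stance, file.path(out_dir, "stance.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(out_dir, "pipeline.log"))
  structure(list(bsp = bsp, summary = summ, rom = rom, mma = mma,
                 muscle_map = mm, stance = stance,
                 paths = list(out_dir = out_dir)),
            class = "pipeline_result")
}
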