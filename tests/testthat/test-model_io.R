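test_that("OBJ files round-trip with vertex order preserved", {
  m <- box_mesh(c(0, 0, 0), c(0.1, 0.2, 0.3))
  f <- tempfile(fileext = ".obj")
  write_obj(m, f)
  m2 <- read_obj(f)
  expect_equal(m2$vertices, m$vertices)
  expect_equal(mesh_mass_properties(m2, 1)$volume,
               mesh_mass_properties(m, 1)$volume)
  expect_error(read_obj(tempfile()), "no such file")
})

test_that("quad faces are triangulated on read, preserving volume", {
  f <- tempfile(fileext = ".obj")
  writeLines(c(
    "v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
    "v 0 0 1", "v 1 0 1", "v 1 1 1", "v 0 1 1",
    "f 1 4 3 2", "f 5 6 7 8", "f 1 2 6 5",
    "f 2 3 7 6", "f 3 4 8 7", "f 4 1 5 8"), f)
  m <- read_obj(f)
  expect_equal(nrow(m$faces), 12)
  expect_equal(mesh_mass_properties(m, 1)$volume, 1, tolerance = 1e-12)
  # malformed face reports its line number
  f2 <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 x"), f2)
  expect_error(read_obj(f2), "line 4")
})

test_that("the osim-style subset round-trips chain, muscles and wraps", {
  sk <- make_toy_skeleton()
  tm <- make_toy_muscles()
  f <- tempfile(fileext = ".osim")
  write_osim_subset(sk$chain, tm$muscles, f)
  r <- read_osim_subset(f)
  expect_equal(sort(names(r$chain$bones)), sort(names(sk$chain$bones)))
  expect_equal(sort(names(r$chain$joints)), sort(names(sk$chain$joints)))
  expect_length(r$muscles, 4)
  expect_length(r$manifest, 0)
  # geometry survives: identical moment arms on the re-read model
  for (i in seq_len(nrow(tm$registry))) {
    reg <- tm$registry[i, ]
    ma <- moment_arm(r$muscles[[reg$muscle]], r$chain, reg$joint, reg$dof,
                     reg$angle_deg * pi / 180)
    expect_lt(abs(ma - reg$analytic_mma), 1e-6)
  }
  # and ROM limits survive
  expect_equal(r$chain$joints$knee$rom_limits$z, c(-130, 0))
})

test_that("a minimal hand-written two-body model parses", {
  f <- tempfile(fileext = ".osim")
  writeLines(c(
    '<OpenSimDocument Version="40500">',
    '<Model name="mini">',
    '<BodySet><objects>',
    '<Body name="pelvis"/><Body name="femur"/>',
    '</objects></BodySet>',
    '<JointSet><objects>',
    '<CustomJoint name="hip">',
    '<parent_body>pelvis</parent_body><child_body>femur</child_body>',
    '<location_in_parent>0 0 0</location_in_parent>',
    '<orientation_in_parent>0 0 0</orientation_in_parent>',
    '<SpatialTransform><TransformAxis name="hip_z">',
    '<axis>0 0 1</axis><range>-1.13 1.13</range>',
    '</TransformAxis></SpatialTransform>',
    '</CustomJoint>',
    '</objects></JointSet>',
    '<ForceSet><objects>',
    '<Thelen2003Muscle name="IF"><GeometryPath><PathPointSet>',
    '<PathPoint><body>pelvis</body><location>0 0.02 0</location></PathPoint>',
    '<PathPoint><body>femur</body><location>0 -0.03 0</location></PathPoint>',
    '</PathPointSet></GeometryPath></Thelen2003Muscle>',
    '</objects></ForceSet>',
    '<UnknownBlock>ignored</UnknownBlock>',
    '</Model></OpenSimDocument>'), f)
  r <- read_osim_subset(f)
  expect_length(r$chain$joints, 1)
  expect_length(r$muscles, 1)
  expect_equal(r$muscles$IF$points[[1]]$bone, "pelvis")
  # skipped elements surface in the manifest, never silently dropped
  expect_true("Model/UnknownBlock" %in% r$manifest)
})

test_that("the pipeline runs end to end and is reproducible", {
  out1 <- file.path(tempdir(), "plrun1")
  out2 <- file.path(tempdir(), "plrun2")
  r1 <- run_pipeline(list(seed = 3, out_dir = out1))
  r2 <- run_pipeline(list(seed = 3, out_dir = out2))
  expect_s3_class(r1, "pipeline_result")
  for (f in c("bsp.csv", "rom.csv", "mma.csv", "muscle_map.csv",
              "stance.json", "pipeline.log"))
    expect_true(file.exists(file.path(out1, f)))
  expect_identical(readLines(file.path(out1, "stance.json")),
                   readLines(file.path(out2, "stance.json")))
  expect_identical(readLines(file.path(out1, "mma.csv")),
                   readLines(file.path(out2, "mma.csv")))
  expect_equal(nrow(r1$muscle_map), 37)
})

test_that("a failing stage is reported by name", {
  bad_spec <- toy_taxon_spec()
  bad_spec$segments$radius[1] <- -1
  expect_error(run_pipeline(list(toy_spec = bad_spec)),
               "stage 'skeleton'")
})
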