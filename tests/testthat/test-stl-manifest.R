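test_that("minimal ASCII STL with one facet parses", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid one",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0",
    "      vertex 0 1 0",
    "    endloop",
    "  endfacet",
    "endsolid one"
  ), path)
  s <- read_stl(path)
  expect_equal(s$n_triangles, 1)
  expect_equal(s$format, "ascii")
  expect_false(s$watertight)
  expect_equal(unname(s$bbox["x", ]), c(0, 1))
})

test_that("binary and ASCII dialects round-trip to identical summaries", {
  tri <- tetra_triangles()
  pa <- withr::local_tempfile(fileext = ".stl")
  pb <- withr::local_tempfile(fileext = ".stl")
  write_stl(tri, pa, format = "ascii")
  write_stl(tri, pb, format = "binary")
  sa <- read_stl(pa)
  sb <- read_stl(pb)
  expect_equal(sa$n_triangles, sb$n_triangles)
  expect_equal(sa$bbox, sb$bbox, tolerance = 1e-6)
  expect_true(sa$watertight)
  expect_true(sb$watertight)
  expect_equal(sa$format, "ascii")
  expect_equal(sb$format, "binary")
})

test_that("degenerate and truncated STL files raise format errors", {
  empty <- withr::local_tempfile(fileext = ".stl")
  file.create(empty)
  expect_error(read_stl(empty), "empty file")

  trunc <- withr::local_tempfile(fileext = ".stl")
  full <- withr::local_tempfile(fileext = ".stl")
  write_stl(tetra_triangles(), full, format = "binary")
  bytes <- readBin(full, "raw", n = file.info(full)$size)
  writeBin(bytes[1:(length(bytes) - 25)], trunc)  # cut into the last record
  expect_error(read_stl(trunc), "byte")
  expect_error(read_stl(tempfile()), "not found")
})

test_that("manifest build fits one recipe per tissue and matches the table", {
  stl1 <- write_ascii_stl_fixture(withr::local_tempfile(fileext = ".stl"))
  stl2 <- write_ascii_stl_fixture(withr::local_tempfile(fileext = ".stl"))
  cfg <- phantom_config(
    phantom = "two-cavity head",
    cavities = data.frame(
      cavity = c("brain", "csf_shell"),
      stl = c(stl1, stl2),
      tissue = c("brain", "csf")
    )
  )
  m <- build_manifest(cfg)
  expect_equal(m$schema_version, "1.0")
  expect_length(m$entries, 2)
  comp <- setNames(lapply(m$entries, `[[`, "composition"),
                   vapply(m$entries, `[[`, character(1), "tissue"))
  expect_equal(comp$brain$tx100_vol_pct, 34, tolerance = 2 / 34)
  expect_equal(comp$csf$tx100_vol_pct, 5.5, tolerance = 2 / 5.5)
  expect_equal(comp$csf$nacl_g_l, 13.95, tolerance = 1 / 13.95)

  # three-cavity variant adds a muscle recipe near the published 21-22 vol%
  stl3 <- write_ascii_stl_fixture(withr::local_tempfile(fileext = ".stl"))
  cfg3 <- phantom_config(
    phantom = "three-cavity head",
    cavities = data.frame(
      cavity = c("brain", "csf_shell", "lower"),
      stl = c(stl1, stl2, stl3),
      tissue = c("brain", "csf", "muscle")
    )
  )
  m3 <- build_manifest(cfg3)
  muscle <- m3$entries[[3]]$composition
  expect_equal(muscle$tx100_vol_pct, 21.5, tolerance = 2 / 21.5)
})

test_that("manifest validation: unknown tissue, missing STL, atomic write, determinism", {
  stl1 <- write_ascii_stl_fixture(withr::local_tempfile(fileext = ".stl"))
  bad <- phantom_config("x", data.frame(cavity = "a", stl = stl1,
                                        tissue = "kryptonite"))
  expect_error(build_manifest(bad), "fixture library")
  expect_error(
    phantom_config("x", data.frame(cavity = c("a", "a"), stl = stl1,
                                   tissue = "csf")),
    "duplicate")

  out <- withr::local_tempfile(fileext = ".json")
  missing <- phantom_config("x", data.frame(
    cavity = c("a", "b"), stl = c(stl1, tempfile()), tissue = "csf"))
  expect_error(build_manifest(missing, out = out), "missing STL")
  expect_false(file.exists(out))  # nothing partially written

  cfg <- phantom_config("det", data.frame(cavity = "a", stl = stl1,
                                          tissue = "csf"))
  o1 <- withr::local_tempfile(fileext = ".json")
  o2 <- withr::local_tempfile(fileext = ".json")
  build_manifest(cfg, out = o1)
  build_manifest(cfg, out = o2)
  expect_identical(readLines(o1), readLines(o2))

  # JSON config round-trip drives the same build
  cfg_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    phantom = "det",
    cavities = list(list(cavity = "a", stl = stl1, tissue = "csf"))
  ), cfg_path, auto_unbox = TRUE)
  m <- build_manifest(cfg_path)
  expect_equal(m$entries[[1]]$tissue, "csf")
})
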