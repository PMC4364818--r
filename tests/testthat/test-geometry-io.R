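test_that("areas follow the planar m2/10,000 convention", {
  g <- land_grid(matrix(1L, 10, 10), "a", cellsize = 10)
  expect_equal(cell_area_ha(g), 0.01)
  expect_equal(unname(class_areas(g)["a"]), 1)  # 100 m x 100 m = 1 ha
})

test_that("rasterization assigns by cell centre and clips exactly on the lattice", {
  tpl <- grid_template(10, 10, 10, codes = "a")
  g <- rasterize_features(list(rect_feature(20, 20, 60, 70)), tpl)
  expect_equal(unname(class_areas(g)["a"]), (40 * 50) / 1e4)
  # feature fully outside the template contributes nothing
  g2 <- rasterize_features(list(rect_feature(500, 500, 600, 600)), tpl)
  expect_equal(sum(g2$cells), 0)
  # later feature wins where features overlap
  g3 <- rasterize_features(list(rect_feature(0, 0, 100, 100),
                                rect_feature(0, 0, 50, 100,
                                             props = list(class = "b"))),
                           tpl)
  a <- class_areas(g3)
  expect_equal(unname(a["a"]), 0.5)
  expect_equal(unname(a["b"]), 0.5)
})

test_that("clipping a feature to a unit matches the geometric intersection", {
  tpl <- grid_template(20, 10, 10, codes = "a")
  map <- rasterize_features(list(rect_feature(30, 20, 160, 80)), tpl)
  zones <- rasterize_features(list(rect_feature(0, 0, 100, 100,
                                                props = list(class = "U1"))),
                              grid_template(20, 10, 10, codes = "U1"))
  clipped <- clip_to_unit(map, zones, "U1")
  # analytic intersection of [30,160]x[20,80] with [0,100]x[0,100]
  expect_equal(unname(class_areas(clipped)["a"]), (70 * 60) / 1e4)
  # fully inside is unchanged; fully outside vanishes
  inside <- rasterize_features(list(rect_feature(10, 10, 60, 60)), tpl)
  expect_equal(class_areas(clip_to_unit(inside, zones, "U1")),
               class_areas(inside))
  outside <- rasterize_features(list(rect_feature(120, 10, 190, 60)), tpl)
  expect_equal(sum(clip_to_unit(outside, zones, "U1")$cells), 0)
})

test_that("polygonize/rasterize round-trips random mosaics exactly, holes included", {
  set.seed(42)
  for (i in 1:10) {
    g <- random_mosaic(15, 18, k = 3)
    feats <- grid_to_features(g)
    tpl <- g; tpl$cells[] <- 0L
    back <- rasterize_features(feats, tpl)
    expect_identical(back$cells, g$cells)
  }
  # explicit donut: an 8x8 block of class a with a 4x4 hole of class b
  cells <- matrix(0L, 12, 12)
  cells[3:10, 3:10] <- 1L
  cells[5:8, 5:8] <- 2L
  g <- land_grid(cells, c("a", "b"), 10)
  feats <- grid_to_features(g)
  rings_a <- feats[[which(vapply(feats, function(f) f$props$class,
                                 "") == "a")]]$rings
  expect_length(rings_a, 2)  # exterior plus hole
  tpl <- g; tpl$cells[] <- 0L
  expect_identical(rasterize_features(feats, tpl)$cells, g$cells)
})

test_that("GeoJSON write/read round-trips features and areas", {
  set.seed(7)
  g <- random_mosaic(12, 12, k = 4)
  p <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(grid_to_features(g), p, crs = "local-metric")
  gj <- read_geojson(p)
  tpl <- g; tpl$cells[] <- 0L
  back <- rasterize_features(gj$features, tpl)
  expect_identical(back$cells, g$cells)
  expect_equal(class_areas(back), class_areas(g), tolerance = 1e-9)
})

test_that("loaders enforce registry closure and projected CRS", {
  reg <- default_registry()
  p <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(list(rect_feature(0, 0, 50, 50, props = list(class = "X9"))),
                p)
  expect_error(load_landcover(p, reg), "X9")
  write_geojson(list(rect_feature(0, 0, 50, 50,
                                  props = list(class = "meadow"))), p)
  expect_error(load_landcover(p, reg, crs = "EPSG:4326"), "projected")
  g <- load_landcover(p, reg, cellsize = 10)
  expect_equal(unname(class_areas(g)["meadow"]), 0.25)
  expect_equal(sum(class_areas(g)) , 0.25)
})
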