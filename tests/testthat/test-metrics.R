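test_that("Shannon diversity and evenness match closed forms", {
  expect_equal(shannon_diversity(1), 0)
  expect_equal(shannon_diversity(rep(0.25, 4)), log(4), tolerance = 1e-12)
  p <- c(0.7, 0.2, 0.1)
  expect_equal(shannon_diversity(p),
               -(0.7 * log(0.7) + 0.2 * log(0.2) + 0.1 * log(0.1)),
               tolerance = 1e-12)
  expect_equal(shannon_evenness(shannon_diversity(p), 3),
               -(0.7 * log(0.7) + 0.2 * log(0.2) + 0.1 * log(0.1)) / log(3),
               tolerance = 1e-12)
  expect_equal(shannon_evenness(log(4), 4), 1)
  expect_equal(shannon_evenness(0, 1), 0)  # single class: no evenness info
  expect_error(shannon_diversity(numeric(0)), "no classes")
  expect_error(shannon_diversity(c(0.5, 0.6)), "sum to 1")
  expect_error(shannon_evenness(1, 0), "at least 1")
})

test_that("diversity matches direct summation on random share vectors", {
  set.seed(11)
  for (i in 1:25) {
    p <- runif(12); p <- p / sum(p)
    expect_equal(shannon_diversity(p), oracle_sdi(p), tolerance = 1e-9)
  }
})

test_that("patch delineation follows the edge-adjacency rule", {
  # two disjoint squares of one class -> 2 patches
  cells <- matrix(0L, 10, 10)
  cells[2:3, 2:3] <- 1L
  cells[6:7, 6:7] <- 1L
  g <- land_grid(cells, "a", 10)
  expect_equal(nrow(delineate_patches(g)$patches), 2)

  # sharing an edge -> merged, area is the sum, shared edge interior
  cells <- matrix(0L, 10, 10)
  cells[2:3, 2:3] <- 1L
  cells[2:3, 4:5] <- 1L
  g <- land_grid(cells, "a", 10)
  del <- delineate_patches(g)
  expect_equal(nrow(del$patches), 1)
  expect_equal(del$patches$area_ha, 8 * 0.01)
  expect_equal(del$patches$perimeter_m, 12 * 10)  # 4x2 block perimeter

  # corner contact only -> distinct patches
  cells <- matrix(0L, 10, 10)
  cells[2, 2] <- 1L
  cells[3, 3] <- 1L
  g <- land_grid(cells, "a", 10)
  expect_equal(nrow(delineate_patches(g)$patches), 2)
})

test_that("patch metrics of a 100 m square match closed forms", {
  cells <- matrix(1L, 10, 10)  # one square patch filling a 1-ha unit
  g <- land_grid(cells, "a", 10)
  del <- delineate_patches(g)
  pm <- patch_metrics(del$patches, t_area_ha = 1)
  expect_equal(pm$np_p, 1)
  expect_equal(pm$msi_p, 400 / (2 * sqrt(pi * 1e4)), tolerance = 1e-9)
  expect_equal(pm$msi_p, 1.128379, tolerance = 1e-6)
  expect_equal(pm$ed_p, 400)
  # raster-normalized variant scores a square as 1
  expect_equal(patch_metrics(del$patches, 1, shape_index = "raster")$msi_p, 1)
  expect_warning(pm0 <- patch_metrics(del$patches[0, ], 1), "empty")
  expect_equal(pm0$np_p, 0)
})

test_that("NP/ED/MSI agree with brute-force raster counting on random mosaics", {
  set.seed(23)
  for (i in 1:30) {
    g <- random_mosaic(ny = sample(8:16, 1), nx = sample(8:16, 1),
                       k = sample(2:4, 1))
    del <- delineate_patches(g)
    lab_o <- oracle_label(g$cells)
    expect_equal(nrow(del$patches), max(lab_o))
    per_o <- oracle_perimeter_edges(lab_o) * g$cellsize
    # patch labellings may differ in order; compare as multisets
    expect_equal(sort(del$patches$perimeter_m), sort(per_o))
    expect_equal(sum(del$patches$perimeter_m), sum(per_o))
    # SEI bounds hold on every mosaic
    a <- class_areas(g); a <- a[a > 0]
    sei <- shannon_evenness(shannon_diversity(a / sum(a)), length(a))
    expect_gte(sei, 0); expect_lte(sei, 1)
  }
})

test_that("metrics are invariant to splitting a patch into adjacent parts", {
  tpl <- grid_template(12, 12, 10, codes = "a")
  zones <- whole_unit_zones(tpl)
  one <- rasterize_features(list(rect_feature(10, 10, 90, 70)), tpl)
  two <- rasterize_features(list(rect_feature(10, 10, 50, 70),
                                 rect_feature(50, 10, 90, 70)), tpl)
  reg <- hnvf_registry(data.frame(code = "a", label = "a", role = "farmland",
                                  hnvf_likelihood = "minimum"))
  m1 <- landscape_elements(one, zones, "U1", reg)
  m2 <- landscape_elements(two, zones, "U1", reg)
  expect_equal(m1[, -(1:2)], m2[, -(1:2)], tolerance = 1e-6)
})

test_that("landscape_elements handles degenerate and uniform landscapes", {
  reg <- default_registry()
  tpl <- grid_template(10, 10, 10, codes = reg$code)
  zones <- whole_unit_zones(tpl)
  # single class covering the unit
  g <- tpl; g$cells[] <- match("meadow", reg$code)
  le <- landscape_elements(g, zones, "U1", reg)
  expect_equal(le$sdi_p, 0); expect_equal(le$sei_p, 0)
  expect_equal(le$np_p, 1)
  # checkerboard of two classes, equal area -> maximal evenness
  g2 <- tpl
  idx <- outer(1:10, 1:10, function(r, c) (r + c) %% 2)
  g2$cells <- matrix(match("meadow", reg$code), 10, 10)
  g2$cells[idx == 1] <- match("arable", reg$code)
  le2 <- landscape_elements(g2, zones, "U1", reg)
  expect_equal(le2$sei_p, 1, tolerance = 1e-12)
})

test_that("farmland-only scope is a subset of the all-classes scope", {
  set.seed(5)
  gen <- generate_municipality(small_scenario(seed = 5))
  for (uid in c("P01", "P05", "P08")) {
    clipped <- clip_to_unit(gen$landcover, gen$zones, uid)
    all_p <- delineate_patches(clipped, gen$registry, "all_classes")$patches
    farm_p <- delineate_patches(clipped, gen$registry, "farmland_only")$patches
    expect_lte(nrow(farm_p), nrow(all_p))
    expect_lte(sum(farm_p$area_ha), sum(all_p$area_ha))
  }
})

test_that("edge density can exclude the unit boundary", {
  tpl <- grid_template(10, 10, 10, codes = "a")
  zones <- whole_unit_zones(tpl)
  g <- tpl; g$cells[] <- 1L  # one patch filling the unit
  le_in <- landscape_elements(g, zones, "U1",
                              hnvf_registry(data.frame(
                                code = "a", label = "a", role = "farmland",
                                hnvf_likelihood = "minimum")),
                              exclude_unit_boundary = FALSE)
  le_ex <- landscape_elements(g, zones, "U1",
                              hnvf_registry(data.frame(
                                code = "a", label = "a", role = "farmland",
                                hnvf_likelihood = "minimum")),
                              exclude_unit_boundary = TRUE)
  expect_equal(le_in$ed_p, 400)  # 400 m of boundary over 1 ha
  expect_equal(le_ex$ed_p, 0)    # all of it lies on the unit boundary
})
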