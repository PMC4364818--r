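test_that("generation is deterministic under a fixed seed and varies across seeds", {
  g1 <- generate_municipality(small_scenario(seed = 5))
  g2 <- generate_municipality(small_scenario(seed = 5))
  expect_identical(g1$landcover$cells, g2$landcover$cells)
  expect_identical(g1$agrarian, g2$agrarian)
  expect_identical(vapply(g1$species, function(f) f$rings[[1]][1, 1],
                          numeric(1)),
                   vapply(g2$species, function(f) f$rings[[1]][1, 1],
                          numeric(1)))
  g3 <- generate_municipality(small_scenario(seed = 6))
  expect_false(identical(g1$landcover$cells, g3$landcover$cells))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_municipality(small_scenario(seed = 7)))
  expect_identical(runif(3), before)
})

test_that("generated mosaics tile each parish exactly", {
  gen <- generate_municipality(small_scenario(seed = 10))
  for (uid in gen$units$unit_id) {
    clipped <- clip_to_unit(gen$landcover, gen$zones, uid)
    unit_ha <- sum(grid_mask(gen$zones, uid)) * cell_area_ha(gen$zones)
    expect_equal(sum(class_areas(clipped)), unit_ha, tolerance = 1e-6)
  }
  # every cell carries a class and a parish
  expect_true(all(gen$landcover$cells > 0L))
  expect_true(all(gen$zones$cells > 0L))
})

test_that("an all-extensive scenario plants type-1 everywhere and is recovered", {
  sc <- hnvf_scenario(rows = 2, cols = 2, unit_size_m = 400,
                      profiles = rep("extensive_seminatural", 4), seed = 2)
  gen <- generate_municipality(sc)
  expect_true(all(gen$truth$label == "hnvf1"))
  # crop richness is constant across four identical profiles, so the
  # redundancy screen warns; that is expected here
  run <- suppressWarnings(
    run_pipeline(gen$landcover, gen$zones, gen$registry, gen$agrarian,
                 constraints = gen$constraints))
  expect_true(all(predict_labels(run)$predicted == "hnvf1"))
})

test_that("degenerate scenario parameters are rejected", {
  expect_error(hnvf_scenario(rows = 1, cols = 1, unit_size_m = 100,
                             profiles = "intensive"),
               "patch size exceeds")
  expect_error(hnvf_scenario(profiles = rep("swampy", 18)), "unknown profile")
  expect_error(hnvf_scenario(rows = 2, cols = 2,
                             profiles = rep("intensive", 3)),
               "length")
})

test_that("the worked-example fixture carries the reference values", {
  fx <- melgaco_table_fixture()
  expect_equal(nrow(fx$units), 18)
  expect_equal(sum(!fx$units$eligible), 6)
  i <- fx$indicators
  expect_equal(i$lsi_p[i$unit_id == "lamas_de_mouro"], 0.03)
  expect_equal(fx$areas$phnvf_min_ha[fx$areas$unit_id == "castro_laboreiro"],
               4730.33)
  # minimum candidate never exceeds maximum candidate
  expect_true(all(fx$areas$phnvf_min_ha <= fx$areas$phnvf_max_ha))
})
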