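test_that("agrarian CSV reading validates and fills blanks", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,livestock_dairy_cows,livestock_sheep,irrigated_ha,crop_maize",
               "u1,10,100,5.5,12",
               "u2,3,4,0,"), p)
  expect_warning(tab <- load_agrarian(p), "read as 0")
  expect_equal(nrow(tab), 2)
  expect_equal(agrarian_record(tab, "u1", "livestock"),
               c(dairy_cows = 10, sheep = 100))
  expect_equal(agrarian_record(tab, "u2", "crops"), c(maize = 0))
  expect_equal(tab$irrigated_ha, c(5.5, 0))

  writeLines(c("unit_id,livestock_sheep", "u1,5", "u1,7"), p)
  expect_error(load_agrarian(p), "duplicated")
  writeLines(c("unit_id,livestock_sheep", "u1,-5"), p)
  expect_error(load_agrarian(p), "negative")
})

test_that("a generated municipality round-trips through disk", {
  sc <- small_scenario(seed = 3)
  gen <- generate_municipality(sc)
  dir <- withr::local_tempdir()
  write_scenario(gen, dir)
  back <- load_scenario(dir)
  # identical class areas (and in fact identical lattices)
  expect_equal(class_areas(back$landcover), class_areas(gen$landcover),
               tolerance = 1e-6)
  expect_identical(back$landcover$cells, gen$landcover$cells)
  expect_identical(back$zones$cells, gen$zones$cells)
  expect_identical(back$constraints$cells, gen$constraints$cells)
  # agrarian table equals the in-memory values
  expect_equal(as.data.frame(back$agrarian), as.data.frame(gen$agrarian),
               tolerance = 1e-9)
  expect_equal(length(back$species), length(gen$species))
})

test_that("write_result emits tables whose totals row sums the unit rows", {
  gen <- generate_municipality(small_scenario(seed = 4))
  run <- run_pipeline(gen$landcover, gen$zones, gen$registry, gen$agrarian,
                      constraints = gen$constraints, species = gen$species)
  dir <- withr::local_tempdir()
  files <- write_result(run, dir)
  acct <- utils::read.csv(file.path(dir, "hnvf_areas.csv"))
  units <- acct[acct$unit_id != "TOTAL", ]
  tot <- acct[acct$unit_id == "TOTAL", ]
  for (col in c("hnvf1_ha", "hnvf2_ha", "hnvf3_ha"))
    expect_equal(tot[[col]], sum(units[[col]]), tolerance = 0.01)
  ind <- utils::read.csv(file.path(dir, "indicators.csv"))
  expect_true(all(c("SDI_p", "SEI_p", "NP_p", "MSI_p", "ED_p", "LSI_p",
                    "Irrig_p", "SDI_c", "SEI_c", "SCrop_p") %in% names(ind)))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$thresholds$uaa_dominance_pct, 40)
  # non-empty HNVf layers re-read to the same extent
  if (any(run$masks$hnvf1)) {
    gj <- read_geojson(file.path(dir, "hnvf1.geojson"))
    tpl <- run$grid; tpl$cells[] <- 0L; tpl$codes <- "hnvf1"
    m <- rasterize_features(gj$features, tpl, class_field = "hnvf_type")
    expect_equal(sum(m$cells == 1L), sum(run$masks$hnvf1))
  }
})
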