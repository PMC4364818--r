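occ_square <- function(id, x0, y0, size = 40, kind = "plant_grid") {
  list(props = list(species_id = id, kind = kind),
       rings = list(matrix(c(x0, y0, x0 + size, y0, x0 + size, y0 + size,
                             x0, y0 + size, x0, y0), ncol = 2, byrow = TRUE)))
}

test_that("coincidence separates partial from complete containment", {
  tpl <- grid_template(20, 20, 10, codes = "x")
  hnvf1 <- matrix(FALSE, 20, 20); hnvf1[, 1:10] <- TRUE  # west half
  occs <- list(occ_square("sp1", 20, 20),    # fully inside type 1
               occ_square("sp2", 80, 20),    # straddles the border
               occ_square("sp3", 150, 20))   # fully outside
  masks <- occurrence_masks(occs, tpl)
  co <- species_coincidence(occs, masks, list(hnvf1 = hnvf1))
  expect_equal(co$n_partial_hnvf1[match(c("sp1", "sp2", "sp3"),
                                        co$species_id)], c(1L, 1L, 0L))
  expect_equal(co$n_complete_hnvf1[match(c("sp1", "sp2", "sp3"),
                                         co$species_id)], c(1L, 0L, 0L))
})

test_that("coincidence counts match brute-force pairwise intersection", {
  set.seed(31)
  tpl <- grid_template(30, 30, 10, codes = "x")
  hnvf <- matrix(runif(900) < 0.4, 30, 30)
  occs <- lapply(1:12, function(i)
    occ_square(sprintf("sp%02d", i %% 4 + 1),
               sample(0:25, 1) * 10, sample(0:25, 1) * 10,
               size = sample(2:5, 1) * 10))
  masks <- occurrence_masks(occs, tpl)
  co <- species_coincidence(occs, masks, list(t = hnvf))
  # oracle: per-occurrence explicit cell comparisons, aggregated by species
  part <- vapply(masks, function(m) {
    hit <- FALSE
    for (i in which(m)) if (hnvf[i]) hit <- TRUE
    hit
  }, logical(1))
  comp <- vapply(seq_along(masks), function(k) {
    m <- masks[[k]]
    all(hnvf[which(m)]) && any(m)
  }, logical(1))
  sp <- vapply(occs, function(f) f$props$species_id, "")
  for (s in unique(sp)) {
    i <- match(s, co$species_id)
    expect_equal(co$n_partial_t[i], sum(part[sp == s]))
    expect_equal(co$n_complete_t[i], sum(comp[sp == s]))
    # count consistency
    expect_lte(co$n_complete_t[i], co$n_partial_t[i])
    expect_lte(co$n_partial_t[i], co$n_total[i])
  }
})

test_that("type-3 designation is species-supported UAA outside mapped HNVf", {
  tpl <- grid_template(20, 20, 10, codes = "x")
  uaa <- matrix(TRUE, 20, 20); uaa[, 16:20] <- FALSE  # east strip not UAA
  hnvf12 <- matrix(FALSE, 20, 20); hnvf12[, 1:5] <- TRUE
  inside <- occurrence_masks(list(occ_square("a", 10, 10)), tpl)
  out3 <- designate_hnvf3(inside, hnvf12, uaa)
  expect_false(any(out3))  # already inside mapped HNVf -> empty
  mid <- occurrence_masks(list(occ_square("b", 80, 80)), tpl)
  out3 <- designate_hnvf3(mid, hnvf12, uaa)
  expect_equal(sum(out3) * 0.01, 0.16)  # full 40 m square, in UAA
  east <- occurrence_masks(list(occ_square("c", 160, 80)), tpl)
  expect_false(any(designate_hnvf3(east, hnvf12, uaa)))  # outside UAA
  # disjointness invariant
  both <- designate_hnvf3(c(inside, mid, east), hnvf12, uaa)
  expect_false(any(both & hnvf12))
})

test_that("after designation every occurrence touching UAA meets some HNVf type", {
  gen <- generate_municipality(small_scenario(seed = 12))
  run <- run_pipeline(gen$landcover, gen$zones, gen$registry, gen$agrarian,
                      constraints = gen$constraints, species = gen$species)
  occ <- occurrence_masks(gen$species, gen$zones)
  all_hnvf <- run$masks$hnvf1 | run$masks$hnvf2 | run$masks$hnvf3
  for (m in occ) {
    if (any(m & run$masks$uaa))
      expect_true(any(m & all_hnvf))
  }
})
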