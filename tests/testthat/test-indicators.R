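test_that("livestock density computes LSU per hectare of UAA", {
  expect_equal(livestock_density(c(dairy_cows = 50), uaa_ha = 500), 0.1)
  expect_equal(livestock_density(numeric(0), uaa_ha = 100), 0)
  # mixed herd, hand-computed: 30 x 1.0 + 200 x 0.1 = 50 LSU over 250 ha
  expect_equal(livestock_density(c(dairy_cows = 30, sheep = 200),
                                 uaa_ha = 250), 0.2)
  expect_error(livestock_density(c(dairy_cows = 1), uaa_ha = 0),
               "no utilized agricultural area")
  expect_error(livestock_density(c(llamas = 5), uaa_ha = 10), "llamas")
  # linearity: doubling every head count doubles the index exactly
  herd <- c(dairy_cows = 13, sheep = 170, goats = 22)
  expect_equal(livestock_density(2 * herd, uaa_ha = 321),
               2 * livestock_density(herd, uaa_ha = 321))
})

test_that("irrigation share is a percentage of UAA with boundary behaviour", {
  expect_equal(irrigation_share(0, 500), 0)
  expect_equal(irrigation_share(75, 500), 15)
  expect_error(irrigation_share(10, 0), "no utilized agricultural area")
  expect_warning(capped <- irrigation_share(600, 500), "capped")
  expect_equal(capped, 100)
  expect_error(irrigation_share(600, 500, cap = FALSE), "exceeds")
})

test_that("crop diversity matches closed forms and is label-invariant", {
  one <- crop_diversity(c(wheat = 12))
  expect_equal(one, list(sdi_c = 0, sei_c = 0, scrop_p = 1L))
  five <- crop_diversity(setNames(rep(3, 5), letters[1:5]))
  expect_equal(five$sdi_c, log(5), tolerance = 1e-12)
  expect_equal(five$sei_c, 1)
  expect_equal(five$scrop_p, 5L)
  mix <- crop_diversity(c(a = 10, b = 30, c = 60))
  expect_equal(mix$sdi_c,
               -(0.1 * log(0.1) + 0.3 * log(0.3) + 0.6 * log(0.6)),
               tolerance = 1e-12)
  # permutation of crop labels leaves all indicators unchanged
  perm <- crop_diversity(c(c = 60, a = 10, b = 30))
  expect_equal(perm, mix)
  expect_warning(zero <- crop_diversity(c(a = 0, b = 0)), "all-zero")
  expect_equal(zero$scrop_p, 0L)
})

test_that("Kendall screening drops redundant indicators by priority", {
  set.seed(3)
  base <- runif(8)
  tab <- data.frame(unit_id = paste0("u", 1:8),
                    lsi_p = base,
                    irrig_p = base,             # identical -> tau = 1
                    sei_p = -base,              # negation -> tau = -1
                    ed_p = runif(8))
  res <- kendall_screen(tab, tau_max = 0.7,
                        priority = c("lsi_p", "irrig_p", "sei_p", "ed_p"))
  expect_equal(res$retained, c("lsi_p", "ed_p"))
  expect_setequal(res$dropped, c("irrig_p", "sei_p"))
  expect_equal(res$tau["lsi_p", "irrig_p"], 1)
  expect_equal(res$tau["lsi_p", "sei_p"], -1)
  # screening the retained set again drops nothing (idempotence)
  res2 <- kendall_screen(tab[, c("unit_id", res$retained)], tau_max = 0.7,
                         priority = res$retained)
  expect_equal(res2$retained, res$retained)
})

test_that("tau matrix matches exhaustive pair enumeration and is symmetric", {
  set.seed(9)
  # a hand-built pattern with ties in both columns
  x <- c(1, 2, 2, 3, 5, 5, 6, 7)
  y <- c(2, 1, 4, 4, 5, 7, 6, 8)
  tab <- data.frame(unit_id = paste0("u", 1:8), lsi_p = x, irrig_p = y)
  res <- kendall_screen(tab, tau_max = 0.99,
                        priority = c("lsi_p", "irrig_p"))
  expect_equal(res$tau["lsi_p", "irrig_p"], oracle_tau_b(x, y),
               tolerance = 1e-12)
  expect_equal(res$tau, t(res$tau))
  expect_true(all(diag(res$tau) == 1))
  expect_true(all(abs(res$tau) <= 1 + 1e-12))
  for (i in 1:10) {
    a <- sample(1:5, 9, replace = TRUE)
    b <- sample(1:5, 9, replace = TRUE)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    tb <- data.frame(unit_id = paste0("u", 1:9), lsi_p = a, irrig_p = b)
    r <- kendall_screen(tb, 0.999999, priority = c("lsi_p", "irrig_p"))
    expect_equal(r$tau["lsi_p", "irrig_p"], oracle_tau_b(a, b),
                 tolerance = 1e-12)
  }
})

test_that("constant indicator columns are reported NA and retained", {
  tab <- data.frame(unit_id = paste0("u", 1:6), lsi_p = 1:6,
                    irrig_p = rep(2, 6))
  expect_warning(res <- kendall_screen(tab, 0.7,
                                       priority = c("lsi_p", "irrig_p")),
                 "constant")
  expect_true("irrig_p" %in% res$retained)
  expect_true(is.na(res$tau["lsi_p", "irrig_p"]))
})
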