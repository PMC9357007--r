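test_that("fibre phantoms are deterministic and honour degenerate limits", {
  a <- make_fibre_phantom(c(64, 64), n_fibres = 20, seed = 11)
  b <- make_fibre_phantom(c(64, 64), n_fibres = 20, seed = 11)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$fibres, b$fibres)

  ## kappa -> infinity: all angles collapse onto the mean
  par <- make_fibre_phantom(c(64, 64), n_fibres = 50, mean_angle = 25,
                            kappa = 1e7, seed = 1)
  expect_equal(stats::sd(par$fibres$angle_deg), 0)
  expect_true(all(par$fibres$angle_deg == 25))

  ## no fibres, no noise: constant background
  flat <- make_fibre_phantom(c(32, 32), n_fibres = 0, noise_sd = 0,
                             background = 7, seed = 1)
  expect_true(all(flat$image$pixels == 7))

  expect_error(make_fibre_phantom(c(0, 10)), "positive")
  expect_error(make_fibre_phantom(fibre_fwhm_px = 0), "fwhm")
  expect_error(make_fibre_phantom(kappa = -1), "kappa")
})

test_that("isotropic phantom angles are uniform on the half-circle", {
  ph <- make_fibre_phantom(c(16, 16), n_fibres = 1e4, kappa = 0, seed = 42)
  th2 <- 2 * ph$fibres$angle_deg * pi / 180
  resultant <- sqrt(mean(cos(th2))^2 + mean(sin(th2))^2)
  expect_lt(resultant, 0.02)
})

test_that("phantom ground-truth angles match the requested von Mises law", {
  ## chi-square GOF of the doubled-angle construction against the axial
  ## density, at n = 1e4
  breaks <- seq(-90, 90, by = 10)
  for (kappa in c(0.5, 3)) {
    ph <- make_fibre_phantom(c(16, 16), n_fibres = 1e4, mean_angle = 10,
                             kappa = kappa, seed = 7)
    obs <- table(cut(ph$fibres$angle_deg, breaks, include.lowest = TRUE))
    pr <- axial_vm_bin_probs(breaks, 10, kappa)
    gof <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pr / sum(pr)))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("stain phantoms plant exact class fractions", {
  ph <- make_stain_phantom(list(red = 0.37), image_size = c(100, 100),
                           boxes = stain_boxes("picrosirius"), seed = 3)
  hsb <- rgb_to_hsb(ph$image)
  in_red <- hsb$h >= 200 & hsb$h <= 240 & hsb$s >= 150 & hsb$s <= 255
  expect_equal(sum(in_red), 3700)

  full <- make_stain_phantom(list(red = 1), image_size = c(20, 20),
                             boxes = stain_boxes("picrosirius"), seed = 1)
  hsb2 <- rgb_to_hsb(full$image)
  expect_true(all(hsb2$h >= 200 & hsb2$h <= 240 & hsb2$s >= 150))

  empty <- make_stain_phantom(list(), image_size = c(10, 10), seed = 1)
  expect_equal(sum(unlist(empty$true_fractions)), 0)

  expect_error(make_stain_phantom(list(red = 0.7, yellow = 0.4),
                                  image_size = c(10, 10)), "sum")
})

test_that("abundance simulation is reproducible with controllable effects", {
  s1 <- simulate_abundance(n_per_cluster = 5, n_null = 10, seed = 5)
  s2 <- simulate_abundance(n_per_cluster = 5, n_null = 10, seed = 5)
  expect_identical(s1$matrix, s2$matrix)
  expect_equal(nrow(s1$design), 30)
  expect_setequal(unique(paste(s1$design$tissue, s1$design$stage)),
                  c("healthy early", "healthy mid", "healthy late",
                    "tumour early", "tumour mid", "tumour late"))

  ## no missingness: presence filter keeps everything
  full <- simulate_abundance(n_per_cluster = 5, n_null = 5,
                             missing_rate = 0, seed = 2)
  kept <- filter_presence(full$matrix)
  expect_equal(nrow(kept), nrow(full$matrix))
  expect_equal(attr(kept, "n_removed"), 0L)

  expect_error(simulate_abundance(missing_rate = 1), "missing_rate")
})

test_that("null abundance simulations carry no planted group signal", {
  ## with effect_size 0 the ANOVA flag rate sits at (or below) the FDR
  rates <- vapply(1:20, function(s) {
    sim <- simulate_abundance(n_per_cluster = 10, n_null = 100,
                              effect_size = 0, missing_rate = 0, seed = s)
    a <- multi_sample_anova(normalise_abundance(sim$matrix), sim$design)
    mean(a$significant)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("stress-strain curves have the stated toe and linear slope", {
  sc <- simulate_stress_strain(2, toe_strain = 0, noise_sd = 0,
                               n_points = 50, seed = 1)
  expect_equal(sc$stress, 2 * sc$strain, tolerance = 1e-12)

  sc2 <- simulate_stress_strain(14.5, toe_strain = 0.05, noise_sd = 0,
                                n_points = 200, seed = 1)
  lin <- sc2$strain >= 0.05
  slopes <- diff(sc2$stress[lin]) / diff(sc2$strain[lin])
  expect_equal(unname(slopes), rep(14.5, sum(lin) - 1), tolerance = 1e-9)
  ## toe is concave up and continuous at the knot
  toe <- sc2$strain < 0.05
  expect_true(all(diff(diff(sc2$stress[toe])) > -1e-12))

  expect_error(simulate_stress_strain(-1), "modulus")
  expect_error(bulk_modulus(c(0, 0.1, 0.2), c(0, 1, 2)), "insufficient")
})
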