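test_that("RGB to HSB conversion follows the 0-255 integer convention", {
  arr <- array(0, c(1, 3, 3))
  arr[1, 1, ] <- c(255, 0, 0)     # pure red
  arr[1, 2, ] <- c(128, 128, 128) # grey
  arr[1, 3, ] <- c(0, 0, 255)     # pure blue
  hsb <- rgb_to_hsb(arr)
  expect_equal(hsb$h[1, 1], 0L)
  expect_equal(hsb$s[1, 1], 255L)
  expect_equal(hsb$b[1, 1], 255L)
  expect_equal(hsb$s[1, 2], 0L)   # grey: no saturation, hue 0 by convention
  expect_equal(hsb$h[1, 2], 0L)
  expect_equal(hsb$b[1, 2], 128L)
  expect_equal(hsb$h[1, 3], as.integer(round(2 / 3 * 255)))
})

test_that("HSB round-trips RGB within one integer step", {
  set.seed(6)
  h <- sample(0:255, 300, TRUE); s <- sample(60:255, 300, TRUE)
  b <- sample(80:255, 300, TRUE)
  rgb <- fibrarch:::hsb_to_rgb(h, s, b)
  arr <- array(0, c(1, 300, 3))
  for (k in 1:3) arr[1, , k] <- rgb[k, ]
  back <- rgb_to_hsb(arr)
  ## the integer RGB grid quantises S and H more coarsely at lower
  ## brightness (steps of ~255/B), so allow two integer steps
  expect_lte(max(abs(back$s[1, ] - s)), 2)
  expect_lte(max(abs(back$b[1, ] - b)), 1)
  dh <- pmin(abs(back$h[1, ] - h), 256 - abs(back$h[1, ] - h))
  expect_lte(max(dh), 2)
})

test_that("stain area recovers planted fractions on phantoms", {
  ph <- make_stain_phantom(list(red = 0.37), image_size = c(100, 100),
                           boxes = stain_boxes("picrosirius"), seed = 21)
  res <- stain_area(ph$image, stain_boxes("picrosirius"))
  expect_equal(unname(res$class_fractions["red"]), 0.37,
               tolerance = 1 / (100 * 100))

  ## three birefringence classes at once
  ph3 <- make_stain_phantom(list(red = 0.2, yellow = 0.3, green = 0.1),
                            image_size = c(80, 90), seed = 5)
  res3 <- stain_area(ph3$image, stain_boxes("birefringence"))
  for (cls in names(ph3$true_fractions))
    expect_equal(unname(res3$class_fractions[cls]),
                 unname(ph3$true_fractions[[cls]]),
                 tolerance = 1 / (80 * 90))
  expect_lte(sum(res3$class_fractions), 1)
})

test_that("stain fractions are invariant under rotation and flips", {
  ph <- make_stain_phantom(list(red = 0.25, green = 0.15),
                           image_size = c(40, 60), seed = 8)
  base <- stain_area(ph$image, stain_boxes("birefringence"))$class_fractions
  rot <- ph$image$pixels
  rot <- aperm(rot, c(2, 1, 3))[dim(rot)[2]:1, , , drop = FALSE]
  rres <- stain_area(rgb_image(rot),
                     stain_boxes("birefringence"))$class_fractions
  expect_equal(base, rres)
  flip <- rgb_image(ph$image$pixels[dim(ph$image$pixels)[1]:1, , ,
                                    drop = FALSE])
  expect_equal(base,
               stain_area(flip, stain_boxes("birefringence"))$class_fractions)
})

test_that("edge cases: all-white errors, full-space box saturates", {
  white <- rgb_image(array(255, c(10, 10, 3)))
  expect_error(stain_area(white, stain_boxes("picrosirius")), "tissue")

  ph <- make_stain_phantom(list(red = 0.5), image_size = c(20, 20), seed = 2)
  allbox <- list(everything = hsb_box(0, 255, 0, 255, 0, 255))
  expect_equal(unname(stain_area(ph$image,
                                 allbox)$class_fractions["everything"]), 1)

  expect_error(stain_area(ph$image,
                          list(a = hsb_box(0, 100, 0, 255, 0, 255),
                               b = hsb_box(50, 150, 0, 255, 0, 255))),
               "overlap")
})

test_that("DAB positive area works via HSB box and colour deconvolution", {
  ph <- make_stain_phantom(list(dab = 0.2), image_size = c(50, 50),
                           boxes = stain_boxes("dab"), seed = 4)
  res <- dab_positive_area(ph$image)
  expect_equal(unname(res$class_fractions["dab"]), 0.2,
               tolerance = 1 / (50 * 50))

  none <- make_stain_phantom(list(), image_size = c(30, 30), seed = 1)
  expect_equal(unname(dab_positive_area(none$image)$class_fractions["dab"]), 0)

  ## a saturated brown field is positive under deconvolution too
  brown <- rgb_image(array(rep(c(120, 70, 30), each = 400), c(20, 20, 3)))
  dec <- dab_positive_area(brown, method = "deconvolution")
  expect_gt(unname(dec$class_fractions["dab"]), 0.95)
  ## and an unstained (grey) field is negative
  grey <- rgb_image(array(180, c(20, 20, 3)))
  expect_lt(unname(dab_positive_area(grey,
                                     method = "deconvolution")$class_fractions["dab"]),
            0.05)
})
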