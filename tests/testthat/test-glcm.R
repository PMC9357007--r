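test_that("co-occurrence counts match pair enumeration on worked examples", {
  m <- matrix(c(0, 0, 255, 255), 2, 2, byrow = TRUE) / 255 * 255
  ## 2x2 image [[0,0],[255,255]] at 2 levels -> values bin to {0,1}
  counts <- glcm_counts(m, offset = c(0, 1), levels = 2)
  expect_equal(counts, matrix(c(1, 0, 0, 1), 2), ignore_attr = TRUE)
  expect_equal(attr(counts, "n_pairs"), 2)

  ## opposite offsets give transposed matrices
  set.seed(1)
  r <- matrix(sample(0:255, 64, replace = TRUE), 8)
  expect_equal(t(glcm_counts(r, c(0, 1), 8)),
               glcm_counts(r, c(0, -1), 8), ignore_attr = TRUE)

  ## constant image: all mass on one diagonal cell
  const <- glcm_counts(matrix(100, 4, 4), c(1, 0), levels = 4)
  expect_equal(sum(const), 12)
  expect_equal(sum(diag(const) > 0), 1)

  expect_error(glcm_counts(matrix(0, 3, 3), c(0, 5), 4), "offset")
})

test_that("haralick correlation agrees with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:16, 1)
    levels <- sample(2:8, 1)
    img <- matrix(sample(0:255, n * n, replace = TRUE), n)
    dy <- sample(-2:2, 1); dx <- sample(-2:2, 1)
    if (dy == 0 && dx == 0) dx <- 1
    q <- pmin(floor(img * levels / 256), levels - 1)
    got <- haralick_correlation(glcm_counts(img, c(dy, dx), levels))
    want <- oracle_haralick_correlation(oracle_glcm_counts(q, dy, dx, levels))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("correlation hits its analytic values on structured images", {
  ## constant image: undefined (zero marginal variance)
  expect_true(is.na(haralick_correlation(glcm_counts(matrix(7, 5, 5),
                                                     c(0, 1), 4))))
  ## alternating vertical stripes at horizontal offset 1: always opposite
  stripes <- matrix(rep(c(0, 255), 8), 4, 4, byrow = TRUE)
  expect_equal(haralick_correlation(glcm_counts(stripes, c(0, 1), 2)), -1)

  ## sinusoid of period 16: anti-correlated at half period, correlated at
  ## full period
  x <- matrix(rep(0:63, each = 64), 64)  # value = column index: varies in x
  sim <- calibrated_image(127.5 + 127.5 * sin(2 * pi * x / 16), 1)
  cur <- glcm_correlation_curve(sim, max_distance_px = 16)
  tab <- cur$table
  expect_lt(tab$correlation[tab$distance == 8 & tab$direction == 0], -0.99)
  expect_gt(tab$correlation[tab$distance == 16 & tab$direction == 0], 0.99)
})

test_that("0/180-degree curves are equal and rotation swaps axes", {
  set.seed(3)
  img <- calibrated_image(matrix(sample(0:255, 40 * 40, replace = TRUE), 40), 1)
  cur <- glcm_correlation_curve(img, max_distance_px = 6)
  tab <- cur$table
  for (d in 1:6)
    expect_equal(tab$correlation[tab$distance == d & tab$direction == 0],
                 tab$correlation[tab$distance == d & tab$direction == 180],
                 tolerance = 1e-14)

  ## rotating the image by 90 degrees exchanges horizontal and vertical
  rot <- calibrated_image(t(img$pixels)[ncol(img$pixels):1, ], 1)
  cr <- glcm_correlation_curve(rot, max_distance_px = 6)$table
  for (d in 1:6)
    expect_equal(cr$correlation[cr$distance == d & cr$direction == 90],
                 tab$correlation[tab$distance == d & tab$direction == 0],
                 tolerance = 1e-12)
})

test_that("curve summary flags undefined entries and rejects degenerates", {
  flat <- calibrated_image(matrix(3, 30, 30), 1)
  expect_error(suppressWarnings(glcm_correlation_curve(flat, 3)),
               "degenerate")

  set.seed(8)
  wn <- calibrated_image(matrix(runif(128 * 128) * 255, 128), 1)
  cur <- glcm_correlation_curve(wn, max_distance_px = 10)
  expect_equal(cur$n_undefined, 0)
  expect_lt(max(abs(cur$mean_correlation)), 0.1)
  expect_equal(length(cur$normalised), 10)
  expect_equal(cur$normalised[1], 1)
})

test_that("aligned fibre networks correlate farther than isotropic ones", {
  ## the organised-matrix effect: same fibre density, different kappa
  wins <- vapply(1:5, function(s) {
    al <- make_fibre_phantom(c(160, 160), n_fibres = 80, kappa = 5,
                             noise_sd = 5, seed = s)
    iso <- make_fibre_phantom(c(160, 160), n_fibres = 80, kappa = 0,
                              noise_sd = 5, seed = s + 50)
    a <- glcm_correlation_curve(al$image, 30)$summary_mean_correlation
    b <- glcm_correlation_curve(iso$image, 30)$summary_mean_correlation
    a > b
  }, TRUE)
  expect_true(all(wins))
})
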