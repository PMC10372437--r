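test_that("contrast and mean gradient match analytic cases", {
  expect_equal(image_contrast(matrix(5, 4, 4)), 0)
  expect_equal(mean_gradient(matrix(5, 4, 4)), 0)
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  expect_equal(image_contrast(cb, normalize = FALSE), 1, tolerance = 1e-15)
  ramp <- outer(rep(1, 5), 1:7, function(i, j) 0.3 * j)
  expect_equal(mean_gradient(ramp, normalize = FALSE), 0.3 / sqrt(2),
               tolerance = 1e-15)
  expect_error(image_contrast(matrix(1, 1, 5)), class = "pit_validation_error")
})

test_that("metrics match exhaustive pair enumeration on explicit matrices", {
  cross <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(image_contrast(cross, normalize = FALSE), oracle_contrast(cross),
               tolerance = 1e-15)
  asym <- matrix(c(0.1, 0.7, 0.4, 0.2), 2, 2)
  expect_equal(image_contrast(asym, normalize = FALSE), oracle_contrast(asym),
               tolerance = 1e-15)
  expect_equal(mean_gradient(asym, normalize = FALSE), oracle_mean_gradient(asym),
               tolerance = 1e-15)
  set.seed(51)
  r4 <- matrix(runif(16), 4, 4)
  expect_equal(mean_gradient(r4, normalize = FALSE), oracle_mean_gradient(r4),
               tolerance = 1e-14)
})

test_that("the two contrast formulations agree on random images", {
  set.seed(52)
  for (rep in 1:30) {
    img <- matrix(rnorm(15 * 11), 15, 11)
    # distribution form: sum over the empirical adjacent-difference FDH
    d <- adjacent_differences(pitenhance:::norm01(img))
    p <- table(d) / length(d)
    c_dist <- sum(as.numeric(names(p))^2 * as.numeric(p))
    expect_equal(image_contrast(img), c_dist, tolerance = 1e-12)
  }
})

test_that("metrics are translation invariant and scale correctly", {
  set.seed(53)
  img <- matrix(rnorm(100), 10, 10)
  c0 <- image_contrast(img, normalize = FALSE)
  g0 <- mean_gradient(img, normalize = FALSE)
  expect_equal(image_contrast(img + 3, normalize = FALSE), c0, tolerance = 1e-12)
  expect_equal(mean_gradient(img + 3, normalize = FALSE), g0, tolerance = 1e-12)
  expect_equal(image_contrast(-2.5 * img, normalize = FALSE), 2.5^2 * c0,
               tolerance = 1e-12)
  expect_equal(mean_gradient(-2.5 * img, normalize = FALSE), 2.5 * g0,
               tolerance = 1e-12)
  # normalized metrics are invariant to any affine display transform
  expect_equal(image_contrast(5 * img - 2), image_contrast(img), tolerance = 1e-12)
})

test_that("normalized coefficients follow the definition, including printed-table arithmetic", {
  nc <- normalized_coefficients(0.5, 0.5, 1, 1)
  expect_equal(c(nc$Cp, nc$MGp), c(0, 0))
  nc2 <- normalized_coefficients(1, 0.5, 3, 1)
  expect_equal(c(nc2$Cp, nc2$MGp), c(1, 2))
  # original-vs-enhanced contrast pair from a published measurement table
  nc3 <- normalized_coefficients(0.0101, 0.0012, 1, 1)
  expect_equal(nc3$Cp, (0.0101 - 0.0012) / 0.0012, tolerance = 1e-12)
  expect_equal(nc3$Cp, 7.4167, tolerance = 1e-4)
  expect_error(normalized_coefficients(1, 0, 1, 1), class = "pit_validation_error")
})

test_that("significance tests match the textbook formula and handle edge cases", {
  set.seed(54)
  mk <- function(values, el = "m12") tibble::tibble(
    sample_id = seq_along(values), element = el, C = values, MG = values
  )
  x <- rnorm(12, mean = 1, sd = 0.2)
  y <- rnorm(12, mean = 0.8, sd = 0.2)
  tab <- significance_table(mk(y), mk(x), "C")
  o <- oracle_paired_t(x, y)
  expect_equal(tab$t, o$t, tolerance = 1e-12)
  expect_equal(tab$p, o$p, tolerance = 1e-12)

  # forced significance: constant shift with tiny jitter
  shift <- y + 0.5 + rnorm(12, sd = 1e-4)
  expect_lt(significance_table(mk(y), mk(shift), "C")$p, 1e-10)

  # degenerate: identical records
  deg <- significance_table(mk(y), mk(y), "C")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))

  expect_error(significance_table(mk(y[1:2]), mk(x[1:2]), "C"), ">= 3 samples")
  expect_error(
    significance_table(mk(y), mk(x)[1:5, ], "C"),
    class = "pit_validation_error"
  )
})

test_that("sweep fast path equals the direct overlay computation", {
  ph <- generate_phantom(phantom_config(shape = c(60L, 30L), texture = 2, seed = 61))
  sw <- sweep_assessment(ph, elements = "m23", alphas = c(0.3, 0.7), Ns = c(3L, 6L))
  for (i in which(sw$coefficient != "none")) {
    ref <- pitenhance:::assess_one(
      element_image(ph$mueller, sw$element[i]), ph$mask, sw$region_label[i],
      sw$coefficient[i], sw$alpha[i], sw$N[i]
    )
    expect_equal(sw$C[i], ref$C, tolerance = 1e-12)
    expect_equal(sw$MG[i], ref$MG, tolerance = 1e-12)
  }
})

test_that("identity sweep cells give zero improvement and order does not matter", {
  ph <- generate_phantom(phantom_config(shape = c(40L, 20L), texture = 2, seed = 62))
  sw <- sweep_assessment(ph, elements = c("m12", "m31"), alphas = 1, Ns = 4L)
  enh <- dplyr::filter(sw, coefficient != "none")
  expect_true(all(abs(enh$Cp) < 1e-12))
  expect_true(all(abs(enh$MGp) < 1e-12))

  sw_rev <- sweep_assessment(ph, elements = c("m31", "m12"), alphas = 1, Ns = 4L)
  expect_equal(
    dplyr::arrange(as.data.frame(sw), element, region_label, coefficient),
    dplyr::arrange(as.data.frame(sw_rev), element, region_label, coefficient)
  )
})

test_that("enhancement improves C and MG on a default-texture phantom", {
  sw <- sweep_phantom_replicates(
    phantom_config(shape = c(240L, 120L), seed = 70), n_reps = 3L,
    elements = c("m12", "m23"), alphas = c(0.5, 0.9), Ns = c(4L, 10L)
  )
  cells <- dplyr::filter(tidy(sw), coefficient != "none")
  expect_true(all(cells$Cp > 0))
  expect_true(all(cells$MGp > 0))
  g <- glance(sw)
  expect_equal(g$n_samples, 3L)
  expect_gt(g$mean_Cp, 0)
})

test_that("sweep and significance tidiers return well-formed tables", {
  ph <- generate_phantom(phantom_config(shape = c(40L, 20L), texture = 2, seed = 63))
  sw <- sweep_assessment(ph, elements = "m12", alphas = c(0.5, 0.9), Ns = 4L)
  td <- tidy(sw)
  expect_true(all(c("element", "region", "coefficient", "alpha", "N", "Cp") %in% names(td)))
  expect_s3_class(autoplot(sw, "C"), "ggplot")
  expect_s3_class(autoplot(sw, "MG"), "ggplot")
})
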