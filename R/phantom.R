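# Seeded synthetic two-region phantoms. Regional marginal distributions are
# matched to prescribed (P3, P4) targets through the Johnson translation
# system (SU above the log-normal line in the (skewness^2, kurtosis) plane,
# SB below it, SL on it); spatial texture comes from a Gaussian-copula random
# field, so the marginal is exact at any smoothness.

# ---- Gauss-Hermite quadrature (probabilists'), via Golub-Welsch ------------
gauss_hermite_normal <- function(n = 131L) {
  k <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- sqrt(k / 2)
  J[cbind(k + 1L, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  list(z = e$values * sqrt(2), w = e$vectors[1, ]^2) # E f(Z) = sum w f(z)
}
.gh_cache <- new.env(parent = emptyenv())
gh_nodes <- function(n = 131L) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- gauss_hermite_normal(n)
  .gh_cache[[key]]
}

std_moments_from_raw <- function(m1, m2, m3, m4) {
  if (!all(is.finite(c(m1, m2, m3, m4)))) {
    return(c(mu = NA_real_, sigma = 0, P3 = 0, P4 = 0)) # overflow guard
  }
  s2 <- m2 - m1^2
  s <- sqrt(max(s2, 0))
  if (s <= 0) return(c(mu = m1, sigma = 0, P3 = 0, P4 = 0))
  c(
    mu = m1, sigma = s,
    P3 = (m3 - 3 * m1 * m2 + 2 * m1^3) / s^3,
    P4 = (m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4) / s^4
  )
}

# moments of sinh((Z - gamma)/delta): closed form through the normal mgf
su_moments <- function(gamma, delta) {
  E <- function(a) exp(-a * gamma / delta + a^2 / (2 * delta^2))
  m1 <- (E(1) - E(-1)) / 2
  m2 <- (E(2) - 2 + E(-2)) / 4
  m3 <- (E(3) - 3 * E(1) + 3 * E(-1) - E(-3)) / 8
  m4 <- (E(4) - 4 * E(2) + 6 - 4 * E(-2) + E(-4)) / 16
  std_moments_from_raw(m1, m2, m3, m4)
}

# moments of plogis((Z - gamma)/delta): Gauss-Hermite (bounded transform)
sb_moments <- function(gamma, delta, gh = gh_nodes()) {
  x <- stats::plogis((gh$z - gamma) / delta)
  std_moments_from_raw(
    sum(gh$w * x), sum(gh$w * x^2), sum(gh$w * x^3), sum(gh$w * x^4)
  )
}

# kurtosis on the log-normal line for squared skewness b1
lognormal_line <- function(b1) {
  if (b1 == 0) return(list(w = 1, P4 = 3))
  w <- uniroot(
    function(w) (w - 1) * (w + 2)^2 - b1,
    lower = 1, upper = 2 + sqrt(b1) + b1, tol = 1e-14
  )$root
  list(w = w, P4 = w^4 + 2 * w^3 + 3 * w^2 - 3)
}

#' Fit a Johnson-system distribution to target skewness and kurtosis
#'
#' Selects the Johnson family covering the target point of the
#' (skewness^2, kurtosis) plane -- `SU` above the log-normal line, `SB`
#' between that line and the boundary `P4 = P3^2 + 1`, `SL` on the line,
#' Gaussian at (0, 3) -- and matches its shape parameters by moment matching.
#'
#' @param P3,P4 Target skewness and kurtosis (population convention).
#' @param tol Acceptance tolerance on the matched moments.
#' @return A list of class `johnson_fit` with fields `family`, `gamma`,
#'   `delta`, achieved `P3`/`P4`, and the standardization constants of the
#'   unit transform.
#' @export
johnson_fit <- function(P3, P4, tol = 1e-4) {
  if (!is.finite(P3) || !is.finite(P4)) abort_validation("P3/P4 must be finite")
  if (P4 < P3^2 + 1 - 1e-9) {
    abort_validation(sprintf(
      "unattainable moment pair: P4 = %.4g < P3^2 + 1 = %.4g (no distribution exists)",
      P4, P3^2 + 1
    ))
  }
  if (abs(P3) < 1e-8 && abs(P4 - 3) < 1e-8) {
    return(structure(
      list(family = "normal", gamma = NA, delta = NA, P3 = 0, P4 = 3, mu = 0, sigma = 1),
      class = "johnson_fit"
    ))
  }
  line <- lognormal_line(P3^2)
  if (abs(P4 - line$P4) < 1e-8) {
    s2 <- log(line$w)
    m <- std_moments_from_raw(
      exp(s2 / 2), exp(2 * s2), exp(4.5 * s2), exp(8 * s2)
    )
    return(structure(
      list(
        family = "SL", gamma = NA, delta = 1 / sqrt(s2), sign = sign(P3),
        P3 = sign(P3) * m[["P3"]], P4 = m[["P4"]], mu = sign(P3) * m[["mu"]],
        sigma = m[["sigma"]]
      ),
      class = "johnson_fit"
    ))
  }
  family <- if (P4 > line$P4) "SU" else "SB"
  fmom <- if (family == "SU") su_moments else sb_moments
  obj <- function(par) {
    par <- unname(as.numeric(par))
    m <- fmom(par[1], exp(par[2]))
    if (m[["sigma"]] <= 0) return(1e6)
    (m[["P3"]] - P3)^2 + ((m[["P4"]] - P4) / 4)^2
  }
  starts <- expand.grid(
    gamma = c(0, -0.5, 0.5, -1.5, 1.5, -3, 3, -6, 6),
    logdelta = log(c(0.25, 0.5, 1, 2, 4, 8))
  )
  vals <- apply(starts, 1, obj)
  best <- NULL
  for (i in order(vals)[1:6]) {
    fit <- optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 4000))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-18) break
  }
  gamma <- best$par[1]; delta <- exp(best$par[2])
  m <- fmom(gamma, delta)
  if (abs(m[["P3"]] - P3) > tol || abs(m[["P4"]] - P4) > 10 * tol) {
    stop(sprintf(
      "johnson_fit(): moment matching failed for (P3 = %.4g, P4 = %.4g); achieved (%.4g, %.4g)",
      P3, P4, m[["P3"]], m[["P4"]]
    ))
  }
  structure(
    list(
      family = family, gamma = gamma, delta = delta,
      P3 = m[["P3"]], P4 = m[["P4"]], mu = m[["mu"]], sigma = m[["sigma"]]
    ),
    class = "johnson_fit"
  )
}

# transform standard-normal draws to the fitted distribution,
# standardized to mean 0 / sd 1 (population convention)
johnson_transform <- function(fit, z) {
  g <- switch(fit$family,
    normal = z,
    SU = sinh((z - fit$gamma) / fit$delta),
    SB = stats::plogis((z - fit$gamma) / fit$delta),
    SL = fit$sign * exp(z / fit$delta)
  )
  (g - fit$mu) / fit$sigma
}

#' Specification of one region's marginal distribution
#'
#' @param label Region label (1 glioma, 2 non-glioma).
#' @param mean,sigma Target mean and standard deviation of the element values.
#' @param P3,P4 Target skewness and kurtosis. Must satisfy `P4 >= P3^2 + 1`
#'   (no distribution exists below that boundary).
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(label, mean, sigma, P3, P4) {
  if (!is.finite(sigma) || sigma <= 0) abort_validation("`sigma` must be > 0")
  if (P4 < P3^2 + 1 - 1e-9) {
    abort_validation(sprintf(
      "unattainable (P3, P4) = (%.4g, %.4g): kurtosis must be >= P3^2 + 1 = %.4g",
      P3, P4, P3^2 + 1
    ))
  }
  structure(
    list(label = label, mean = mean, sigma = sigma, P3 = P3, P4 = P4),
    class = "region_spec"
  )
}

#' Draw a sample with prescribed moments
#'
#' Draws `n` i.i.d. values from the Johnson-system distribution matched to
#' the spec's `(mean, sigma, P3, P4)`. Empirical population-convention
#' moments converge to the targets; at `n = 65536` skewness is typically
#' within 0.05 and kurtosis within 0.15 of the target.
#'
#' @param spec A [region_spec()].
#' @param n Sample size.
#' @param seed RNG seed (the caller's RNG state is restored).
#' @return Numeric vector of length `n`.
#' @export
sample_with_moments <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "region_spec"))
  fit <- johnson_fit(spec$P3, spec$P4)
  z <- with_seed(seed, rnorm(n))
  spec$mean + spec$sigma * johnson_transform(fit, z)
}

# ---- spatial texture -------------------------------------------------------

# Unit-variance Gaussian random field with separable Gaussian autocorrelation
# of scale `ell` pixels (circular convolution; kernel has unit l2 norm, so
# the N(0,1) marginal is exact, which the copula transform relies on).
smooth_gaussian_field <- function(h, w, ell) {
  z <- matrix(rnorm(h * w), h, w)
  if (ell <= 0) return(z)
  half <- ceiling(3 * ell)
  if (2 * half + 1 > min(h, w)) {
    abort_validation(sprintf(
      "texture scale %g too large for a %d x %d image", ell, h, w
    ))
  }
  k <- dnorm(seq(-half, half), sd = ell)
  k <- k / sqrt(sum(k^2))
  z <- apply(z, 2, function(col) as.numeric(stats::filter(col, k, sides = 2, circular = TRUE)))
  t(apply(z, 1, function(row) as.numeric(stats::filter(row, k, sides = 2, circular = TRUE))))
}

#' Generate a two-region mask
#'
#' @param shape `c(height, width)` in pixels (at least 4 x 4).
#' @param geometry `"half"` (top half glioma, bottom half non-glioma; the
#'   default, mirroring per-region processing of separate tissue areas) or
#'   `"disc"` (glioma disc centered in a non-glioma background, for
#'   boundary-straddling block experiments).
#' @param radius Disc radius in pixels (default `min(shape) / 4`).
#' @param seed Unused for the deterministic geometries; kept so every
#'   generator entry point shares the `(config, seed)` determinism contract.
#' @return A [region_mask()].
#' @export
generate_mask <- function(shape, geometry = c("half", "disc"), radius = NULL,
                          seed = NULL) {
  geometry <- match.arg(geometry)
  h <- shape[1]; w <- shape[2]
  if (h < 4 || w < 4) abort_validation("mask shape must be at least 4 x 4")
  if (geometry == "half") {
    labels <- matrix(2L, h, w)
    labels[seq_len(h %/% 2), ] <- 1L
  } else {
    if (is.null(radius)) radius <- min(h, w) / 4
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
    labels <- matrix(2L, h, w)
    labels[d2 <= radius^2] <- 1L
  }
  if (!any(labels == 1L) || !any(labels == 2L)) {
    abort_validation("geometry leaves an empty region")
  }
  region_mask(labels)
}

#' Default per-element regional moment targets
#'
#' Regional skewness/kurtosis targets for all eight informative elements
#' (m11 is identically 1 after normalization) in both regions, together with
#' plausible element means and spreads: diagonal elements are larger in the
#' glioma region (weaker depolarization), off-diagonal elements are small
#' with slight regional mean offsets. Two kurtosis targets (m22 and m33,
#' non-glioma) are raised to `P3^2 + 1.5` because the nominal pairs fall
#' below the attainability boundary `P4 >= P3^2 + 1` that every real
#' distribution obeys; see the methods vignette.
#'
#' @return A tibble with columns `element`, `region`, `label`, `mean`,
#'   `sigma`, `P3`, `P4`.
#' @export
default_phantom_specs <- function() {
  tab <- tibble::tribble(
    ~element, ~g_mean, ~ng_mean, ~g_sd, ~ng_sd, ~g_P3, ~ng_P3, ~g_P4, ~ng_P4,
    "m12", 0.020, 0.035, 0.020, 0.020, -0.114, -0.967, 3.976, 5.317,
    "m13", 0.010, 0.020, 0.020, 0.020, 0.008, -1.684, 4.531, 8.024,
    "m21", 0.020, 0.030, 0.020, 0.020, -0.199, -0.081, 3.787, 5.929,
    "m22", 0.450, 0.280, 0.040, 0.040, -0.469, 1.964, 2.038, 1.964^2 + 1.5,
    "m23", -0.010, -0.018, 0.020, 0.020, -0.041, -0.098, 4.090, 8.455,
    "m31", 0.012, 0.020, 0.020, 0.020, 0.879, 0.129, 6.176, 8.508,
    "m32", -0.008, -0.015, 0.020, 0.020, 0.004, 0.151, 4.513, 7.958,
    "m33", 0.430, 0.260, 0.040, 0.040, -0.263, -1.923, 2.492, 1.923^2 + 1.5
  )
  dplyr::bind_rows(
    dplyr::transmute(tab, element = .data$element, region = "glioma", label = 1L,
                     mean = .data$g_mean, sigma = .data$g_sd,
                     P3 = .data$g_P3, P4 = .data$g_P4),
    dplyr::transmute(tab, element = .data$element, region = "non_glioma", label = 2L,
                     mean = .data$ng_mean, sigma = .data$ng_sd,
                     P3 = .data$ng_P3, P4 = .data$ng_P4)
  ) |> dplyr::arrange(.data$element, .data$label)
}

#' Phantom configuration
#'
#' @param shape `c(height, width)` of the full phantom (default 400 x 200:
#'   two 200 x 200 regions under the half-split geometry).
#' @param geometry Mask geometry, see [generate_mask()].
#' @param specs Tibble of per-(element, region) targets as produced by
#'   [default_phantom_specs()].
#' @param texture Correlation length (pixels) of the Gaussian-copula texture
#'   field; 0 gives i.i.d. pixels. The default 12 px reproduces the
#'   smoothness scale of measured element images (original-image contrast
#'   ~1e-4..1e-3 and mean gradient ~0.01 on the display-normalized scale).
#' @param noise_sigma Element-domain noise scale used when `add_noise = TRUE`
#'   (default 0.04/3, a third of the instrument calibration-error budget).
#' @param add_noise Add i.i.d. element-domain noise? Default `FALSE`: the
#'   regional moment targets are defined on the noise-free elements, and the
#'   acquisition error budget is exercised in the intensity domain by
#'   [generate_phantom_stack()] instead.
#' @param intensity_noise Additive intensity noise s.d. (relative to `gain`)
#'   for [generate_phantom_stack()]. The default 0.02 keeps reconstructed,
#'   m11-normalized element errors within the instrument's stated 0.04 bound
#'   for over 99% of pixels (worst-element noise gain is 0.559).
#' @param gain Detector gain of the forward model.
#' @param seed Integer seed; all generator outputs are pure functions of
#'   `(config, seed)`.
#' @param radius Disc radius, for `geometry = "disc"`.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(400L, 200L), geometry = "half",
                           specs = default_phantom_specs(), texture = 12,
                           noise_sigma = 0.04 / 3, add_noise = FALSE,
                           intensity_noise = 0.02, gain = 1, seed = 1L,
                           radius = NULL) {
  needed <- setdiff(MUELLER_ELEMENTS, "m11")
  if (!all(needed %in% specs$element)) {
    abort_validation("`specs` must configure every element m12..m33")
  }
  if (!all(c(1L, 2L) %in% specs$label)) {
    abort_validation("`specs` must configure both region labels 1 and 2")
  }
  for (i in seq_len(nrow(specs))) {
    region_spec(specs$label[i], specs$mean[i], specs$sigma[i],
                specs$P3[i], specs$P4[i]) # validates attainability
  }
  structure(
    list(
      shape = as.integer(shape), geometry = geometry, specs = specs,
      texture = texture, noise_sigma = noise_sigma, add_noise = add_noise,
      intensity_noise = intensity_noise, gain = gain, seed = as.integer(seed),
      radius = radius
    ),
    class = "phantom_config"
  )
}

#' Generate a synthetic two-region Mueller element phantom
#'
#' For each element and region, pixel values are drawn from the
#' Johnson-system distribution matched to the configured
#' `(mean, sigma, P3, P4)` through a Gaussian-copula texture field:
#' a unit-variance smoothed Gaussian field is transformed through the exact
#' quantile map, so the regional marginal hits the targets in distribution
#' at any texture scale. m11 is identically 1 (the phantom is
#' pre-normalized). Values are clipped to the physical range [-1, 1]; the
#' clip rate is recorded in the `clip_rate` attribute.
#'
#' @param config A [phantom_config()].
#' @return A list of class `pit_phantom` with fields `mueller`
#'   (a [mueller_image()]), `mask` (a [region_mask()]) and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$shape[1]; w <- config$shape[2]
  mask <- generate_mask(config$shape, config$geometry, radius = config$radius)
  fits <- lapply(seq_len(nrow(config$specs)), function(i) {
    johnson_fit(config$specs$P3[i], config$specs$P4[i])
  })
  clipped <- 0; total <- 0
  elements <- with_seed(config$seed, {
    out <- list(m11 = matrix(1, h, w))
    for (el in setdiff(MUELLER_ELEMENTS, "m11")) {
      z <- smooth_gaussian_field(h, w, config$texture)
      img <- matrix(NA_real_, h, w)
      for (lab in c(1L, 2L)) {
        i <- which(config$specs$element == el & config$specs$label == lab)
        sel <- unclass(mask) == lab
        x <- config$specs$mean[i] +
          config$specs$sigma[i] * johnson_transform(fits[[i]], z[sel])
        img[sel] <- x
      }
      if (config$add_noise) {
        img <- img + rnorm(h * w, sd = config$noise_sigma)
      }
      clipped <- clipped + sum(img < -1 | img > 1, na.rm = TRUE)
      total <- total + sum(!is.na(img))
      out[[el]] <- pmin(pmax(img, -1), 1)
    }
    out
  })
  M <- mueller_image(elements[MUELLER_ELEMENTS], normalized = TRUE)
  out <- structure(
    list(mueller = M, mask = mask, config = config),
    class = "pit_phantom"
  )
  attr(out, "clip_rate") <- clipped / max(total, 1)
  out
}

#' @export
print.pit_phantom <- function(x, ...) {
  cat(sprintf(
    "<pit_phantom> %d x %d px, geometry '%s', texture %g px, seed %d, clip rate %.2g\n",
    x$config$shape[1], x$config$shape[2], x$config$geometry,
    x$config$texture, x$config$seed, attr(x, "clip_rate")
  ))
  invisible(x)
}

#' Forward-simulate the acquisition stack of a phantom
#'
#' Generates the phantom's Mueller image, pushes it through
#' [simulate_intensities()] and adds the configured acquisition noise
#' (additive Gaussian of s.d. `intensity_noise * gain`, or scaled by
#' `sqrt(I / mean(I))` for `model = "shot"`). Under the default noise level,
#' reconstructing and normalizing the stack recovers the element images with
#' errors below 0.04 at over 99% of pixels.
#'
#' @param config A [phantom_config()].
#' @param model Noise model: `"gaussian"` (default), `"shot"`, or `"none"`.
#' @return A list of class `pit_phantom_stack`: `stack`, `phantom`.
#' @export
generate_phantom_stack <- function(config, model = c("gaussian", "shot", "none")) {
  model <- match.arg(model)
  phantom <- generate_phantom(config)
  stack <- simulate_intensities(phantom$mueller, gain = config$gain)
  if (model != "none" && config$intensity_noise > 0) {
    frames <- with_seed(config$seed + 1000003L, {
      meanI <- mean(unlist(lapply(stack$frames, mean)))
      lapply(stack$frames, function(f) {
        sdmap <- if (model == "shot") {
          config$intensity_noise * config$gain * sqrt(pmax(f, 0) / meanI)
        } else {
          config$intensity_noise * config$gain
        }
        pmax(f + rnorm(length(f), sd = sdmap), 0)
      })
    })
    stack <- polarization_stack(frames)
  }
  structure(list(stack = stack, phantom = phantom), class = "pit_phantom_stack")
}
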