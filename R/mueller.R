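#' Mueller element names in row-major order
#' @export
MUELLER_ELEMENTS <- c("m11", "m12", "m13", "m21", "m22", "m23", "m31", "m32", "m33")

#' Canonical polarizer angles (degrees) of the rotating generator/analyzer
#' @export
POLARIZER_ANGLES <- c(0, 45, 90, 135)

# Stokes-style reduced vector of a linear polarizer at `theta` degrees.
# Angles are degrees in all interfaces; 2*theta enters the trigonometry.
# cospi/sinpi give exact 0/+-1 at the four canonical angles.
linear_state <- function(theta) {
  c(1, cospi(theta / 90), sinpi(theta / 90))
}

angle_pairs <- function() {
  # row-major over generator then analyzer: (0,0),(0,45),...,(135,135)
  g <- rep(POLARIZER_ANGLES, each = 4L)
  a <- rep(POLARIZER_ANGLES, times = 4L)
  data.frame(theta_g = g, theta_a = a)
}

pair_key <- function(theta_g, theta_a) sprintf("g%03d_a%03d", theta_g, theta_a)

# 16 x 9 design matrix of the bilinear form a' M s, elements in row-major
# order m11..m33. Full rank for the four canonical angles.
mueller_design_matrix <- function() {
  pairs <- angle_pairs()
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    s <- linear_state(pairs$theta_g[k])
    a <- linear_state(pairs$theta_a[k])
    as.vector(t(outer(a, s))) # coefficient of M[r,c] is a_r * s_c
  })
  A <- do.call(rbind, rows)
  dimnames(A) <- list(pair_key(pairs$theta_g, pairs$theta_a), MUELLER_ELEMENTS)
  A
}

#' Construct a polarization intensity stack
#'
#' A stack holds the 16 intensity frames measured with the polarization state
#' generator and analyzer at all pairs of angles in \{0, 45, 90, 135\} degrees.
#'
#' @param frames Named list of 16 numeric matrices. Names must be
#'   `"g<GGG>_a<AAA>"` (zero-padded degrees, e.g. `"g045_a135"`); all frames
#'   must share one shape and contain finite, non-negative intensities.
#' @return An object of class `polarization_stack`.
#' @export
polarization_stack <- function(frames) {
  pairs <- angle_pairs()
  expected <- pair_key(pairs$theta_g, pairs$theta_a)
  if (!is.list(frames) || is.null(names(frames))) {
    abort_validation("`frames` must be a named list of 16 matrices")
  }
  if (!setequal(names(frames), expected) || length(frames) != 16L) {
    missing <- setdiff(expected, names(frames))
    extra <- setdiff(names(frames), expected)
    abort_validation(paste0(
      "stack must contain exactly one frame per angle pair; ",
      if (length(missing)) paste0("missing: ", paste(missing, collapse = ", "), "; ") else "",
      if (length(extra)) paste0("unexpected: ", paste(extra, collapse = ", ")) else ""
    ))
  }
  frames <- frames[expected]
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort_validation("all frames must share an identical height x width")
  }
  bad <- vapply(frames, function(f) any(!is.finite(f)) || any(f < 0), logical(1))
  if (any(bad)) {
    abort_validation(paste0(
      "frames contain non-finite or negative intensities: ",
      paste(names(frames)[bad], collapse = ", ")
    ))
  }
  structure(
    list(frames = frames, height = dims[1, 1], width = dims[2, 1]),
    class = "polarization_stack"
  )
}

#' @export
print.polarization_stack <- function(x, ...) {
  cat(sprintf(
    "<polarization_stack> 16 frames, %d x %d px, intensity range [%.4g, %.4g]\n",
    x$height, x$width, min(unlist(lapply(x$frames, min))),
    max(unlist(lapply(x$frames, max)))
  ))
  invisible(x)
}

#' Construct a Mueller-matrix element image set
#'
#' @param elements Named list of nine matrices `m11` .. `m33`, identical shape.
#' @param normalized Logical; `TRUE` once elements have been divided by m11.
#' @param valid Optional logical matrix flagging pixels with meaningful values
#'   (defaults to all `TRUE`). Invalid pixels carry `NA` in every element.
#' @return An object of class `mueller_image`.
#' @export
mueller_image <- function(elements, normalized = FALSE, valid = NULL) {
  if (!setequal(names(elements), MUELLER_ELEMENTS)) {
    abort_validation("`elements` must be a named list m11..m33")
  }
  elements <- elements[MUELLER_ELEMENTS]
  dims <- vapply(elements, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort_validation("all element images must share an identical shape")
  }
  if (is.null(valid)) valid <- matrix(TRUE, dims[1, 1], dims[2, 1])
  structure(
    list(
      elements = elements, normalized = isTRUE(normalized), valid = valid,
      height = dims[1, 1], width = dims[2, 1]
    ),
    class = "mueller_image"
  )
}

#' @export
print.mueller_image <- function(x, ...) {
  cat(sprintf(
    "<mueller_image> %d x %d px, %s, %d invalid pixel(s)\n",
    x$height, x$width,
    if (x$normalized) "m11-normalized" else "un-normalized",
    sum(!x$valid)
  ))
  invisible(x)
}

#' Construct a region mask
#'
#' Labels: 0 background/excluded, 1 glioma, 2 non-glioma.
#'
#' @param labels Integer matrix with values in \{0, 1, 2\}.
#' @return Integer matrix of class `region_mask`.
#' @export
region_mask <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (any(!labels %in% 0:2)) {
    abort_validation("mask labels must be 0 (background), 1 (glioma) or 2 (non-glioma)")
  }
  structure(labels, class = c("region_mask", "matrix", "array"))
}

#' Simulate the 16-frame acquisition of a Mueller image
#'
#' Forward model of the rotating-polarizer acquisition: for generator and
#' analyzer angles `theta_g`, `theta_a`, the detected intensity at each pixel
#' is `gain * a' M s` with reduced polarization vectors
#' `s = (1, cos 2*theta_g, sin 2*theta_g)` and `a = (1, cos 2*theta_a, sin 2*theta_a)`.
#' The radiometric 1/2 prefactors of the polarizer matrices are absorbed into
#' `gain`; only ratios survive m11 normalization downstream.
#'
#' @param M A [mueller_image()] (un-normalized scale permitted).
#' @param gain Positive scalar detector gain.
#' @return A [polarization_stack()].
#' @examples
#' M <- mueller_image(setNames(lapply(MUELLER_ELEMENTS, function(e) {
#'   diag(3)[match(substr(e, 2, 2), 1:3), match(substr(e, 3, 3), 1:3)] + matrix(0, 2, 2)
#' }), MUELLER_ELEMENTS))
#' stack <- simulate_intensities(M, gain = 1)
#' stack$frames[["g000_a000"]][1, 1] # 2: aligned polarizers on identity
#' @export
simulate_intensities <- function(M, gain = 1) {
  stopifnot(inherits(M, "mueller_image"))
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0) {
    abort_validation("`gain` must be a positive finite scalar")
  }
  A <- mueller_design_matrix()
  elem <- do.call(rbind, lapply(M$elements, as.vector)) # 9 x npix
  I <- gain * (A %*% elem)                              # 16 x npix
  tol <- 1e-9 * max(abs(I), 1)
  if (any(I < -tol, na.rm = TRUE)) {
    idx <- which(I < -tol, arr.ind = TRUE)[1, ]
    px <- arrayInd(idx[2], c(M$height, M$width))
    stop(sprintf(
      "unphysical Mueller matrix: negative intensity %.4g at pixel (%d, %d), angle pair %s",
      I[idx[1], idx[2]], px[1], px[2], rownames(A)[idx[1]]
    ))
  }
  I[I < 0] <- 0
  frames <- lapply(seq_len(nrow(A)), function(k) matrix(I[k, ], M$height, M$width))
  names(frames) <- rownames(A)
  polarization_stack(frames)
}

#' Reconstruct a Mueller image from a 16-frame stack
#'
#' Per-pixel linear least squares of the 16 intensity equations
#' `I(theta_g, theta_a) = gain * a' M s` for the nine elements; the detector
#' gain is absorbed into the scale of m11. The 16 x 9 design matrix for the
#' four canonical angles is full rank, so on noiseless stacks produced by
#' [simulate_intensities()] the solution recovers the input exactly up to
#' floating tolerance.
#'
#' @param stack A [polarization_stack()].
#' @return An un-normalized [mueller_image()].
#' @export
reconstruct_mueller <- function(stack) {
  stopifnot(inherits(stack, "polarization_stack"))
  A <- mueller_design_matrix()
  I <- do.call(rbind, lapply(stack$frames[rownames(A)], as.vector)) # 16 x npix
  qrA <- qr(A)
  coef <- qr.coef(qrA, I) # 9 x npix
  elements <- lapply(seq_len(9L), function(j) {
    matrix(coef[j, ], stack$height, stack$width)
  })
  names(elements) <- MUELLER_ELEMENTS
  mueller_image(elements, normalized = FALSE)
}

#' Normalize a Mueller image by its m11 element
#'
#' Divides every element pixel-wise by m11, so m11 becomes exactly 1 at valid
#' pixels. Pixels whose m11 does not exceed `eps` are flagged invalid (set to
#' `NA`), never silently zeroed: dark background would otherwise blow up the
#' division.
#'
#' @param M A [mueller_image()].
#' @param eps Validity threshold for m11; default `1e-6 * max(m11)`.
#' @return An m11-normalized [mueller_image()]. Idempotent.
#' @export
normalize_by_m11 <- function(M, eps = NULL) {
  stopifnot(inherits(M, "mueller_image"))
  if (M$normalized) return(M)
  m11 <- M$elements$m11
  if (is.null(eps)) eps <- 1e-6 * max(m11, na.rm = TRUE)
  ok <- is.finite(m11) & m11 > eps & M$valid
  if (!any(ok)) stop("normalize_by_m11(): no valid pixels (all m11 <= eps)")
  elements <- lapply(M$elements, function(e) {
    out <- e / m11
    out[!ok] <- NA_real_
    out
  })
  elements$m11[ok] <- 1
  out <- mueller_image(elements, normalized = TRUE, valid = ok)
  attr(out, "eps") <- eps
  out
}

#' Extract one element image as a plain matrix
#'
#' @param M A [mueller_image()].
#' @param element Element name, one of `"m11"` .. `"m33"`.
#' @return Numeric matrix.
#' @export
element_image <- function(M, element) {
  stopifnot(inherits(M, "mueller_image"))
  if (!element %in% MUELLER_ELEMENTS) {
    abort_validation(sprintf(
      "unknown element '%s' (must be one of %s)",
      element, paste(MUELLER_ELEMENTS, collapse = ", ")
    ))
  }
  M$elements[[element]]
}

#' Off-diagonal element names
#'
#' The six off-diagonal Mueller elements (m12, m13, m21, m23, m31, m32): the
#' low-contrast images the enhancement targets.
#' @return Character vector.
#' @export
off_diagonal_elements <- function() {
  c("m12", "m13", "m21", "m23", "m31", "m32")
}
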