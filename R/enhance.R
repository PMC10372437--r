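#' Rescale an enhancement matrix onto a display/overlay range
#'
#' Affine min-max map of the valid raw block values onto
#' `[target_lo, target_hi]`; a constant raw map goes to the midpoint.
#' Invalid blocks keep their flag, but for display their rescaled pixels
#' inherit the nearest valid block's value (nearest block center); the flag,
#' not the filled value, is what downstream statistics respect.
#'
#' Overlaying raw P3/P4 values (magnitudes of order 1-10) on element images
#' whose range is a fraction of that would let a small `beta` dominate the
#' blend, so [overlay_enhance()] rescales onto the original image's observed
#' range by default; pass an explicit range here (or
#' `rescale = FALSE` there) for raw-overlay experiments.
#'
#' @param E An enhancement matrix from [blockwise_cmc()].
#' @param target_lo,target_hi Target range, `target_lo < target_hi`.
#' @return The enhancement matrix with its `rescaled` field filled.
#' @export
rescale_enhancement_matrix <- function(E, target_lo, target_hi) {
  stopifnot(inherits(E, "enhancement_matrix"))
  if (!is.finite(target_lo) || !is.finite(target_hi) || target_lo >= target_hi) {
    abort_validation("`target_lo` must be smaller than `target_hi`")
  }
  vals <- E$blocks
  if (!any(vals$valid)) stop("rescale_enhancement_matrix(): no valid blocks")
  coefv <- vals[[E$coefficient]]
  lo <- min(coefv[vals$valid]); hi <- max(coefv[vals$valid])
  resc_block <- if (hi > lo) {
    (coefv - lo) / (hi - lo) * (target_hi - target_lo) + target_lo
  } else {
    rep((target_lo + target_hi) / 2, length(coefv))
  }
  # display fill: invalid blocks borrow the nearest valid block's value
  if (any(!vals$valid)) {
    vi <- which(vals$valid)
    for (bi in which(!vals$valid)) {
      d2 <- (vals$block_row[vi] - vals$block_row[bi])^2 +
        (vals$block_col[vi] - vals$block_col[bi])^2
      resc_block[bi] <- resc_block[vi[which.min(d2)]]
    }
  }
  grid <- E$grid
  resc <- matrix(NA_real_, nrow(E$raw), ncol(E$raw))
  inreg <- !is.na(E$raw) | E$valid
  idx <- grid$index[inreg]
  resc[inreg] <- resc_block[idx]
  E$rescaled <- resc
  attr(E, "target_range") <- c(target_lo, target_hi)
  E
}

#' Overlay an enhancement matrix on the original element image
#'
#' The enhanced image is the convex blend
#' `values(i, j) = alpha * I(i, j) + beta * E(i, j)` with `alpha + beta = 1`,
#' computed wherever the enhancement matrix is valid; where it is not
#' (blocks outside the region or with too few pixels), the original image
#' shows through unchanged.
#'
#' @param I Numeric matrix: the original element image.
#' @param E An enhancement matrix from [blockwise_cmc()]; rescaled onto
#'   `range(I)` automatically if `rescale = TRUE` and not yet rescaled.
#' @param alpha Overlay weight of the original image, in `[0, 1]`.
#' @param beta Overlay weight of the enhancement matrix; must satisfy
#'   `alpha + beta = 1`.
#' @param rescale If the matrix is not yet rescaled, map it onto the
#'   observed range of `I` first (default). `FALSE` overlays raw coefficient
#'   values.
#' @return An object of class `enhanced_image` with fields `values`,
#'   `alpha`, `beta`, `N`, `coefficient`, `region_label`.
#' @export
overlay_enhance <- function(I, E, alpha, beta = 1 - alpha, rescale = TRUE) {
  stopifnot(inherits(E, "enhancement_matrix"))
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      abs(alpha + beta - 1) > 1e-12 || alpha < 0 || alpha > 1 ||
      beta < 0 || beta > 1) {
    abort_validation("overlay weights must satisfy alpha + beta = 1 with both in [0, 1]")
  }
  if (!all(dim(I) == dim(E$raw))) abort_validation("image and enhancement matrix shapes differ")
  if (is.null(E$rescaled)) {
    if (rescale) {
      rng <- range(I[is.finite(I)])
      if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
      E <- rescale_enhancement_matrix(E, rng[1], rng[2])
    } else {
      E$rescaled <- E$raw
    }
  }
  vals <- alpha * I + beta * E$rescaled
  fallback <- !E$valid | is.na(E$rescaled)
  vals[fallback] <- I[fallback]
  structure(
    list(
      values = vals, alpha = alpha, beta = beta, N = E$N,
      coefficient = E$coefficient, region_label = E$region_label
    ),
    class = "enhanced_image"
  )
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf(
    "<enhanced_image> %s overlay, alpha = %.2f, beta = %.2f, N = %d, %d x %d px\n",
    x$coefficient, x$alpha, x$beta, x$N, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Pseudocolor plot of an enhanced image
#' @param object An [overlay_enhance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enhanced_image <- function(object, ...) {
  df <- raster_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf(
      "I-S-%s (alpha = %.1f, N = %d)", object$coefficient, object$alpha, object$N
    ), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Render a scalar image in pseudocolors
#'
#' Linear map of `value_range` onto an R color palette, quantized to 8 bits.
#' Non-finite pixels get a reserved color. Quality metrics are always
#' computed on scalar images, never on this RGB rendering.
#'
#' @param image Numeric matrix.
#' @param colormap A palette name accepted by [grDevices::hcl.colors()]
#'   (e.g. `"viridis"`, `"Blue-Red"`) or `"gray"`.
#' @param value_range Values mapped to the palette ends; defaults to the
#'   finite range of `image`.
#' @param invalid_color RGB triplet in `[0, 1]` for non-finite pixels.
#' @return `h x w x 3` array in `[0, 1]` (8-bit quantized levels).
#' @export
render_pseudocolor <- function(image, colormap = "viridis", value_range = NULL,
                               invalid_color = c(0, 0, 0)) {
  pal <- if (identical(colormap, "gray")) {
    gray(0:255 / 255)
  } else {
    hit <- match(tolower(colormap), tolower(grDevices::hcl.pals()))
    if (is.na(hit)) {
      abort_validation(sprintf("unknown colormap '%s'", colormap))
    }
    grDevices::hcl.colors(256, grDevices::hcl.pals()[hit])
  }
  if (is.null(value_range)) {
    fin <- image[is.finite(image)]
    if (length(fin) == 0L) stop("render_pseudocolor(): no finite pixels")
    value_range <- range(fin)
  }
  span <- diff(value_range)
  u <- if (span > 0) (image - value_range[1]) / span else image * 0 + 0.5
  idx <- pmin(pmax(floor(u * 256) + 1L, 1L), 256L)
  rgb <- grDevices::col2rgb(pal) / 255
  out <- array(0, c(nrow(image), ncol(image), 3L))
  bad <- !is.finite(image)
  for (ch in 1:3) {
    plane <- matrix(rgb[ch, idx], nrow(image), ncol(image))
    plane[bad] <- invalid_color[ch]
    out[, , ch] <- plane
  }
  out
}

#' Write an enhanced image to disk
#'
#' Writes the scalar values as a 32-bit float TIFF (affine storage mapping
#' recorded in a JSON sidecar) and, optionally, a pseudocolor PNG.
#'
#' @param enh An [overlay_enhance()] result (or a plain matrix).
#' @param path Output TIFF path; the PNG, if any, replaces the extension.
#' @param png_too Also write the pseudocolor rendering?
#' @param colormap Palette for the PNG.
#' @return `path`, invisibly.
#' @export
write_enhanced <- function(enh, path, png_too = TRUE, colormap = "viridis") {
  vals <- if (inherits(enh, "enhanced_image")) enh$values else enh
  fin <- vals[is.finite(vals)]
  rng <- range(fin)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  tiff::writeTIFF(encode01(vals, rng[1], rng[2]), path,
                  bits.per.sample = 32L, reduce = FALSE)
  meta <- list(kind = "enhanced_image", value_range = rng)
  if (inherits(enh, "enhanced_image")) {
    meta <- c(meta, enh[c("alpha", "beta", "N", "coefficient", "region_label")])
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  if (png_too) {
    png::writePNG(
      render_pseudocolor(vals, colormap),
      paste0(tools::file_path_sans_ext(path), ".png")
    )
  }
  invisible(path)
}
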