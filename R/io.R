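# File interfaces. Element and intensity images are stored as 32-bit float
# TIFF pages affinely mapped into [0, 1] (the TIFF writer's storage range);
# the affine (offset, scale) is recorded in a JSON sidecar so readers recover
# the original values exactly up to float-32 rounding.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

encode01 <- function(x, lo, hi) {
  y <- (x - lo) / (hi - lo)
  y[!is.finite(y)] <- 0
  pmin(pmax(y, 0), 1)
}

#' Write a Mueller image as a multi-page TIFF with JSON metadata
#'
#' Pages are the nine elements in row-major order m11..m33, stored as 32-bit
#' float, followed by a tenth 0/1 page encoding the valid-pixel mask. Values
#' are mapped from `value_range` into the TIFF storage range; the mapping and
#' the normalization state are recorded in `<path>.json`.
#'
#' @param M A [mueller_image()].
#' @param path Output TIFF path.
#' @param value_range Affine storage range; default `c(-1, 1)` for normalized
#'   images, observed range otherwise.
#' @return `path`, invisibly.
#' @export
write_mueller_tiff <- function(M, path, value_range = NULL) {
  stopifnot(inherits(M, "mueller_image"))
  if (is.null(value_range)) {
    value_range <- if (M$normalized) c(-1, 1) else
      range(unlist(M$elements), na.rm = TRUE)
  }
  pages <- lapply(M$elements, encode01, lo = value_range[1], hi = value_range[2])
  pages <- c(pages, list(valid = M$valid * 1))
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    kind = "mueller_elements",
    elements = MUELLER_ELEMENTS,
    normalized = M$normalized,
    value_range = value_range,
    eps = attr(M, "eps"),
    pages = c(MUELLER_ELEMENTS, "valid")
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Mueller image written by [write_mueller_tiff()]
#'
#' @param path TIFF path (JSON sidecar expected alongside).
#' @return A [mueller_image()].
#' @export
read_mueller_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  lo <- meta$value_range[1]; hi <- meta$value_range[2]
  elements <- lapply(pages[1:9], function(p) p * (hi - lo) + lo)
  names(elements) <- MUELLER_ELEMENTS
  valid <- pages[[10]] > 0.5
  for (e in MUELLER_ELEMENTS) elements[[e]][!valid] <- NA_real_
  M <- mueller_image(elements, normalized = isTRUE(meta$normalized), valid = valid)
  if (!is.null(meta$eps)) attr(M, "eps") <- meta$eps
  M
}

#' Write a polarization stack as a 16-page TIFF with JSON metadata
#'
#' Page order is row-major over generator then analyzer angle:
#' (0,0), (0,45), ..., (135,135). Intensities are stored scaled by their
#' maximum, recorded in the sidecar.
#'
#' @param stack A [polarization_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "polarization_stack"))
  top <- max(unlist(lapply(stack$frames, max)), 1e-300)
  pages <- lapply(stack$frames, function(f) f / top)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    kind = "polarization_stack", pages = names(stack$frames),
    intensity_scale = top
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a polarization stack
#'
#' Accepts either a 16-page TIFF written by [write_stack_tiff()] (a JSON
#' sidecar may override page ordering) or a directory of single-frame files
#' named `I_<thetaG>_<thetaA>.tif`.
#'
#' @param path TIFF file or directory.
#' @return A [polarization_stack()].
#' @export
read_polarization_stack <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "^I_\\d+_\\d+\\.tiff?$", full.names = TRUE)
    if (length(files) != 16L) {
      abort_validation(sprintf(
        "expected 16 files I_<thetaG>_<thetaA>.tif in %s, found %d", path, length(files)
      ))
    }
    ang <- regmatches(basename(files), regexec("^I_(\\d+)_(\\d+)\\.", basename(files)))
    frames <- lapply(files, tiff::readTIFF)
    names(frames) <- vapply(ang, function(m) {
      pair_key(as.integer(m[2]), as.integer(m[3]))
    }, character(1))
    return(polarization_stack(frames))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  keys <- pair_key(angle_pairs()$theta_g, angle_pairs()$theta_a)
  scale <- 1
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$pages)) keys <- meta$pages
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (length(pages) != 16L) {
    abort_validation(sprintf("expected a 16-page TIFF, found %d pages", length(pages)))
  }
  frames <- lapply(pages, function(p) p * scale)
  names(frames) <- keys
  polarization_stack(frames)
}

#' Write a region mask as an 8-bit PNG
#'
#' Labels 0/1/2 are stored as gray levels 0, 128, 255.
#' @param mask A [region_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  png::writePNG(unclass(mask) / 2, path)
  invisible(path)
}

#' Read a region mask written by [write_mask_png()]
#' @param path PNG path.
#' @return A [region_mask()].
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  region_mask(round(img * 2))
}
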