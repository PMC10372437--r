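#' Relative frequency-distribution histogram (FDH) of a pixel population
#'
#' @param values Numeric vector (at least one finite value).
#' @param bin_count Number of bins (default 128, a smooth curve for typical
#'   element images).
#' @param value_range Histogram support; default `c(-1, 1)`, the theoretical
#'   range of m11-normalized elements.
#' @param oob How to treat values outside `value_range`: `"clip"` (counted in
#'   the end bins, default) or `"drop"`.
#' @return A tibble of class `fdh` with columns `lo`, `hi`, `mid`,
#'   `frequency`; frequencies are non-negative and sum to 1.
#' @export
compute_fdh <- function(values, bin_count = 128L, value_range = c(-1, 1),
                        oob = c("clip", "drop")) {
  oob <- match.arg(oob)
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("compute_fdh(): no finite values")
  if (bin_count < 1L) abort_validation("`bin_count` must be >= 1")
  if (diff(value_range) <= 0) abort_validation("`value_range` must be increasing")
  edges <- seq(value_range[1], value_range[2], length.out = bin_count + 1L)
  if (oob == "drop") {
    values <- values[values >= value_range[1] & values <= value_range[2]]
    if (length(values) == 0L) stop("compute_fdh(): all values outside `value_range`")
  } else {
    values <- pmin(pmax(values, value_range[1]), value_range[2])
  }
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bin_count)
  out <- tibble::tibble(
    lo = edges[-length(edges)],
    hi = edges[-1],
    mid = (edges[-length(edges)] + edges[-1]) / 2,
    frequency = counts / sum(counts)
  )
  class(out) <- c("fdh", class(out))
  attr(out, "bin_edges") <- edges
  out
}

#' Central-moment coefficients of a pixel population
#'
#' Population-convention moments of the values `X`: mean `mu`, standard
#' deviation `sigma` with `sigma^2 = mean((X - mu)^2)` (divide by n, no
#' small-sample correction), skewness `P3 = mean((X - mu)^3) / sigma^3` and
#' kurtosis `P4 = mean((X - mu)^4) / sigma^4`. `P3` measures the asymmetry of
#' the FDH curve (positive: right tail longer), `P4` the sharpness of its
#' peak (3 for a Gaussian). A constant sample is degenerate: `sigma = 0` and
#' `P3 = P4 = 0` are reported with `degenerate = TRUE`.
#'
#' @param values Numeric vector with at least one finite value.
#' @return One-row tibble with columns `n`, `mu`, `sigma`, `P3`, `P4`,
#'   `degenerate`.
#' @examples
#' cmc_moments(c(0, 0, 1, 1)) # P3 = 0, P4 = 1
#' @export
cmc_moments <- function(values) {
  if (length(values) == 0L) stop("cmc_moments(): empty input")
  if (any(!is.finite(values))) stop("cmc_moments(): non-finite values")
  n <- length(values)
  mu <- mean(values)
  d <- values - mu
  s2 <- mean(d^2)
  sigma <- sqrt(s2)
  if (sigma == 0) {
    return(tibble::tibble(
      n = n, mu = mu, sigma = 0, P3 = 0, P4 = 0, degenerate = TRUE
    ))
  }
  tibble::tibble(
    n = n, mu = mu, sigma = sigma,
    P3 = mean(d^3) / sigma^3,
    P4 = mean(d^4) / sigma^4,
    degenerate = FALSE
  )
}

#' Block grid for segmentation mode N
#'
#' Partitions an `h x w` image into non-overlapping blocks of side `N`
#' pixels (`i * j / N^2` sub-regions when `N` divides both sides). When `N`
#' does not divide a side, the last block in that direction absorbs the
#' remainder, so no pixel is discarded.
#'
#' @param h,w Image height and width in pixels.
#' @param N Block side length in pixels (segmentation mode).
#' @return A list of class `block_grid`: `N`, `nrow_blocks`, `ncol_blocks`,
#'   `row_id`/`col_id` (per-pixel block coordinates) and `index` (per-pixel
#'   block id, row-major).
#' @export
block_grid <- function(h, w, N) {
  N <- as.integer(N)
  if (N < 1L) abort_validation("`N` must be >= 1")
  if (N > h || N > w) {
    abort_validation(sprintf("segmentation mode N = %d larger than image (%d x %d)", N, h, w))
  }
  nr <- h %/% N
  nc <- w %/% N
  row_id <- pmin((seq_len(h) - 1L) %/% N + 1L, nr)
  col_id <- pmin((seq_len(w) - 1L) %/% N + 1L, nc)
  index <- matrix(0L, h, w)
  index[] <- (rep(row_id, times = w) - 1L) * nc + rep(col_id, each = h)
  structure(
    list(
      N = N, nrow_blocks = nr, ncol_blocks = nc,
      row_id = row_id, col_id = col_id, index = index
    ),
    class = "block_grid"
  )
}

block_stat <- function(values, ids, nblocks) {
  out <- numeric(nblocks)
  s <- rowsum(values, ids)
  out[as.integer(rownames(s))] <- s
  out
}

#' Blockwise central-moment coefficient maps (enhancement matrices)
#'
#' Builds the segmentation-mode-N block grid over an element image and
#' computes the moment summary of each block's pixel population, restricted
#' to pixels carrying `region_label` in the mask. Returns the blockwise
#' skewness map (the P3 enhancement matrix) and kurtosis map (the P4
#' enhancement matrix) as blockwise-constant images over the member pixels.
#'
#' Blocks with fewer than `min_pixels` in-region pixels, and degenerate
#' (zero-variance) blocks, are flagged invalid; degenerate blocks report
#' flagged zeros rather than failing so whole-image maps stay computable.
#'
#' @param image Numeric matrix (one element image, or any scalar image).
#' @param mask Optional [region_mask()] (or `NULL` for the whole image).
#' @param region_label Label of the region to analyze (1 or 2) when `mask`
#'   is given.
#' @param N Segmentation mode: block side length in pixels.
#' @param min_pixels Minimum in-region pixels for a valid block (default 4).
#' @return Named list with `P3` and `P4` [enhancement matrices][rescale_enhancement_matrix]
#'   and `blocks`, a tibble with one row per block
#'   (`block_row`, `block_col`, `n`, `mu`, `sigma`, `P3`, `P4`, `valid`).
#' @export
blockwise_cmc <- function(image, mask = NULL, region_label = NULL, N = 10L,
                          min_pixels = 4L) {
  h <- nrow(image); w <- ncol(image)
  grid <- block_grid(h, w, N)
  sel <- is.finite(image)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(image))) {
      abort_validation("mask and image shapes differ")
    }
    if (is.null(region_label)) abort_validation("`region_label` required with a mask")
    sel <- sel & (unclass(mask) == region_label)
  }
  if (!any(sel)) stop("blockwise_cmc(): empty region")
  ids <- grid$index[sel]
  v <- image[sel]
  nb <- grid$nrow_blocks * grid$ncol_blocks
  n_b <- tabulate(ids, nbins = nb)
  mu_b <- ifelse(n_b > 0, block_stat(v, ids, nb) / pmax(n_b, 1L), NA_real_)
  d <- v - mu_b[ids]
  m2 <- block_stat(d^2, ids, nb) / pmax(n_b, 1L)
  m3 <- block_stat(d^3, ids, nb) / pmax(n_b, 1L)
  m4 <- block_stat(d^4, ids, nb) / pmax(n_b, 1L)
  sigma <- sqrt(m2)
  degen <- n_b > 0 & sigma == 0
  P3 <- ifelse(n_b > 0 & !degen, m3 / sigma^3, 0)
  P4 <- ifelse(n_b > 0 & !degen, m4 / sigma^4, 0)
  valid_b <- n_b >= min_pixels & !degen
  if (!any(n_b >= min_pixels)) {
    stop("blockwise_cmc(): no block with enough valid pixels")
  }

  blocks <- tibble::tibble(
    block_row = rep(seq_len(grid$nrow_blocks), each = grid$ncol_blocks),
    block_col = rep(seq_len(grid$ncol_blocks), times = grid$nrow_blocks),
    n = n_b, mu = mu_b, sigma = sigma, P3 = P3, P4 = P4, valid = valid_b
  )

  broadcast <- function(vals) {
    out <- matrix(NA_real_, h, w)
    out[sel] <- vals[ids]
    out
  }
  valid_px <- matrix(FALSE, h, w)
  valid_px[sel] <- valid_b[ids]
  mk <- function(coef, vals) {
    structure(
      list(
        coefficient = coef, N = grid$N, raw = broadcast(vals),
        rescaled = NULL, valid = valid_px, grid = grid, blocks = blocks,
        region_label = region_label
      ),
      class = "enhancement_matrix"
    )
  }
  list(P3 = mk("P3", P3), P4 = mk("P4", P4), blocks = blocks)
}

#' @export
print.enhancement_matrix <- function(x, ...) {
  rng <- range(x$raw[x$valid], na.rm = TRUE)
  cat(sprintf(
    "<enhancement_matrix> %s map, N = %d (%d x %d blocks), raw range [%.3f, %.3f]%s\n",
    x$coefficient, x$N, x$grid$nrow_blocks, x$grid$ncol_blocks, rng[1], rng[2],
    if (is.null(x$rescaled)) "" else ", rescaled"
  ))
  invisible(x)
}

#' @export
as_tibble.enhancement_matrix <- function(x, ...) x$blocks

#' Tidy method for enhancement matrices: the per-block coefficient table
#' @param x An enhancement matrix from [blockwise_cmc()].
#' @param ... Unused.
#' @export
tidy.enhancement_matrix <- function(x, ...) x$blocks

#' Pseudocolor plot of an enhancement matrix
#' @param object An enhancement matrix from [blockwise_cmc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enhancement_matrix <- function(object, ...) {
  df <- raster_df(object$raw)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = object$coefficient) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s enhancement matrix (N = %d)", object$coefficient, object$N),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

raster_df <- function(m) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Export a per-block coefficient table to CSV
#' @param x An enhancement matrix or the result of [blockwise_cmc()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(x, path) {
  blocks <- if (inherits(x, "enhancement_matrix")) x$blocks else x$blocks
  utils::write.csv(blocks, path, row.names = FALSE)
  invisible(path)
}
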