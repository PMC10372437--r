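# Image-quality assessment: contrast C (expected squared adjacent-pixel gray
# difference), mean gradient MG, normalized improvements Cp/MGp, factorial
# parameter sweeps over (element x region x coefficient x alpha x N), and
# paired significance tests across samples.

norm01 <- function(image) {
  fin <- image[is.finite(image)]
  r <- range(fin)
  if (r[2] > r[1]) (image - r[1]) / (r[2] - r[1]) else image * 0
}

check_image2x2 <- function(image) {
  if (is.null(dim(image)) || nrow(image) < 2L || ncol(image) < 2L) {
    abort_validation("image must be at least 2 x 2 pixels")
  }
  if (any(!is.finite(image))) abort_validation("image must be finite")
}

#' Gray differences between 4-connected adjacent pixel pairs
#'
#' Each unordered right/down neighbor pair is counted once. The empirical
#' distribution of these differences is the adjacent-difference distribution
#' whose second moment is the contrast C.
#'
#' @param image Numeric matrix.
#' @return Numeric vector of differences.
#' @export
adjacent_differences <- function(image) {
  check_image2x2(image)
  c(
    image[-1, ] - image[-nrow(image), ],
    image[, -1] - image[, -ncol(image)]
  )
}

#' Image contrast C
#'
#' `C = sum_delta delta^2 p(delta)` over the empirical distribution of
#' 4-connected adjacent-pixel gray differences -- algebraically the mean
#' squared adjacent difference. Computed on the scalar image as-is (no gray
#' quantization); by default the image's display range is first mapped to
#' `[0, 1]`, the same convention applied to original and enhanced images so
#' their C values are comparable.
#'
#' @param image Numeric matrix, at least 2 x 2.
#' @param normalize Map the image's range to `[0, 1]` first (default TRUE).
#' @return Non-negative scalar; 0 iff the image is constant.
#' @examples
#' image_contrast(matrix(c(0, 1, 1, 0), 2, 2)) # checkerboard: 1
#' @export
image_contrast <- function(image, normalize = TRUE) {
  check_image2x2(image)
  if (normalize) image <- norm01(image)
  mean(adjacent_differences(image)^2)
}

#' Image mean gradient MG
#'
#' `MG = 1/((m-1)(n-1)) * sum sqrt(((DN(i,j)-DN(i+1,j))^2 +
#' (DN(i,j)-DN(i,j+1))^2) / 2)`: the average root-mean-square of the two
#' forward differences at each interior-corner pixel. Larger MG means more
#' fine texture detail.
#'
#' @inheritParams image_contrast
#' @return Non-negative scalar; 0 iff the image is constant.
#' @export
mean_gradient <- function(image, normalize = TRUE) {
  check_image2x2(image)
  if (normalize) image <- norm01(image)
  m <- nrow(image); n <- ncol(image)
  dv <- image[seq_len(m - 1), seq_len(n - 1)] - image[2:m, seq_len(n - 1)]
  dh <- image[seq_len(m - 1), seq_len(n - 1)] - image[seq_len(m - 1), 2:n]
  mean(sqrt((dv^2 + dh^2) / 2))
}

#' Normalized assessment coefficients Cp and MGp
#'
#' Relative improvement of the enhanced image over the original:
#' `Cp = (C_e - C_o) / C_o`, `MGp = (MG_e - MG_o) / MG_o`.
#'
#' @param C_e,C_o Contrast of the enhanced and original image.
#' @param MG_e,MG_o Mean gradient of the enhanced and original image.
#' @return A tibble with columns `Cp` and `MGp` (vectorized).
#' @examples
#' normalized_coefficients(0.0101, 0.0012, 0.03, 0.015) # Cp ~ 7.417
#' @export
normalized_coefficients <- function(C_e, C_o, MG_e, MG_o) {
  if (any(C_o <= 0) || any(MG_o <= 0)) {
    abort_validation("original C and MG must be > 0 (normalization undefined)")
  }
  tibble::tibble(Cp = (C_e - C_o) / C_o, MGp = (MG_e - MG_o) / MG_o)
}

region_crop <- function(image, mask, label) {
  sel <- unclass(mask) == label
  if (!any(sel)) stop(sprintf("region label %d is empty", label))
  rows <- range(which(rowSums(sel) > 0))
  cols <- range(which(colSums(sel) > 0))
  list(
    image = image[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
    mask = region_mask(unclass(mask)[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE])
  )
}

#' Assess one enhancement setting of one region crop
#' @keywords internal
assess_one <- function(image, mask, label, coefficient, alpha, N,
                       normalize = TRUE, min_pixels = 4L) {
  crop <- region_crop(image, mask, label)
  maps <- blockwise_cmc(crop$image, crop$mask, label, N, min_pixels)
  enh <- overlay_enhance(crop$image, maps[[coefficient]], alpha)
  list(C = image_contrast(enh$values, normalize),
       MG = mean_gradient(enh$values, normalize))
}

#' Factorial assessment sweep over elements, regions, overlay scales and modes
#'
#' Runs the full enhancement pipeline for every combination of element,
#' region, coefficient (P3/P4), overlay scale alpha and segmentation mode N,
#' and records contrast and mean gradient of the original region image and
#' each enhanced image together with the normalized improvements. Each
#' region is assessed on the bounding-box crop of its labeled pixels
#' (regions are processed as separate images).
#'
#' @param M A normalized [mueller_image()] (or `pit_phantom`).
#' @param mask A [region_mask()] (taken from the phantom if `M` is one).
#' @param elements Elements to process; default the six off-diagonal
#'   elements, where the enhancement is most useful.
#' @param coefficients `"P3"`, `"P4"` or both (default).
#' @param alphas Overlay scales; default 0.1 .. 0.9.
#' @param Ns Segmentation modes; default `c(2, 4, 10, 20, 25)`.
#' @param regions Region labels; default `c(1, 2)`.
#' @param normalize Display-normalize images before metric computation.
#' @param sample_id Identifier recorded in the output rows.
#' @return A tibble of class `pit_sweep`: one row per assessed cell
#'   (original rows carry `coefficient = "none"` and `NA` alpha/N), with
#'   columns `sample_id`, `element`, `region_label`, `region`, `coefficient`,
#'   `alpha`, `N`, `C`, `MG`, `Cp`, `MGp`.
#' @export
sweep_assessment <- function(M, mask = NULL, elements = off_diagonal_elements(),
                             coefficients = c("P3", "P4"),
                             alphas = seq(0.1, 0.9, by = 0.1),
                             Ns = c(2L, 4L, 10L, 20L, 25L),
                             regions = c(1L, 2L), normalize = TRUE,
                             sample_id = 1L) {
  if (inherits(M, "pit_phantom")) {
    if (is.null(mask)) mask <- M$mask
    M <- M$mueller
  }
  stopifnot(inherits(M, "mueller_image"))
  if (is.null(mask)) abort_validation("a region mask is required")
  if (length(alphas) == 0L || length(Ns) == 0L) abort_validation("empty sweep grid")
  bad <- setdiff(elements, MUELLER_ELEMENTS)
  if (length(bad)) abort_validation(paste("unknown element(s):", paste(bad, collapse = ", ")))

  region_names <- c("1" = "glioma", "2" = "non_glioma")
  acc <- list()
  add_row <- function(el, lab, coef, a, N, C, MG, Cp, MGp) {
    acc[[length(acc) + 1L]] <<- list(
      element = el, region_label = lab, coefficient = coef,
      alpha = a, N = N, C = C, MG = MG, Cp = Cp, MGp = MGp
    )
  }
  for (el in sort(elements)) {
    img <- element_image(M, el)
    for (lab in regions) {
      crop <- region_crop(img, mask, lab)
      I <- crop$image
      C_o <- image_contrast(I, normalize)
      MG_o <- mean_gradient(I, normalize)
      add_row(el, lab, "none", NA_real_, NA_integer_, C_o, MG_o, NA_real_, NA_real_)
      m <- nrow(I); n <- ncol(I)
      # adjacent differences of the overlay are the same convex blend of the
      # operands' differences, so precompute them once per (element, region)
      dIv <- I[-1, ] - I[-m, ]; dIh <- I[, -1] - I[, -n]
      gIv <- I[seq_len(m - 1), seq_len(n - 1)] - I[2:m, seq_len(n - 1)]
      gIh <- I[seq_len(m - 1), seq_len(n - 1)] - I[seq_len(m - 1), 2:n]
      for (N in Ns) {
        maps <- blockwise_cmc(I, crop$mask, lab, N)
        for (coef in coefficients) {
          E <- maps[[coef]]
          rng <- range(I[is.finite(I)])
          if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
          E <- rescale_enhancement_matrix(E, rng[1], rng[2])
          fast <- all(E$valid) && !anyNA(E$rescaled)
          if (fast) {
            R <- E$rescaled
            dEv <- R[-1, ] - R[-m, ]; dEh <- R[, -1] - R[, -n]
            gEv <- R[seq_len(m - 1), seq_len(n - 1)] - R[2:m, seq_len(n - 1)]
            gEh <- R[seq_len(m - 1), seq_len(n - 1)] - R[seq_len(m - 1), 2:n]
          }
          for (a in alphas) {
            b <- 1 - a
            if (fast) {
              vals <- a * I + b * E$rescaled
              span <- if (normalize) diff(range(vals)) else 1
              if (span == 0) span <- 1
              C_e <- mean(c((a * dIv + b * dEv)^2, (a * dIh + b * dEh)^2)) / span^2
              MG_e <- mean(sqrt(
                ((a * gIv + b * gEv)^2 + (a * gIh + b * gEh)^2) / 2
              )) / span
            } else {
              enh <- overlay_enhance(I, E, a)
              C_e <- image_contrast(enh$values, normalize)
              MG_e <- mean_gradient(enh$values, normalize)
            }
            nc <- normalized_coefficients(C_e, C_o, MG_e, MG_o)
            add_row(el, lab, coef, a, as.integer(N), C_e, MG_e, nc$Cp, nc$MGp)
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(acc)
  out <- dplyr::mutate(
    out, sample_id = sample_id,
    region = region_names[as.character(.data$region_label)], .before = 1
  )
  out <- dplyr::relocate(out, "sample_id", "element", "region_label", "region")
  class(out) <- c("pit_sweep", class(out))
  out
}

#' Run the assessment sweep on seeded phantom replicates
#'
#' Generates `n_reps` phantoms from `config` (seeds `config$seed + 1 ..
#' config$seed + n_reps`) and binds their [sweep_assessment()] tables; the
#' replicate index is the `sample_id`. This is the multi-sample protocol
#' behind the significance tests.
#'
#' @param config A [phantom_config()].
#' @param n_reps Number of replicates (samples).
#' @param ... Passed to [sweep_assessment()].
#' @return A `pit_sweep` tibble.
#' @export
sweep_phantom_replicates <- function(config, n_reps = 20L, ...) {
  res <- purrr::map(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    ph <- generate_phantom(cfg)
    sweep_assessment(ph, sample_id = r, ...)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("pit_sweep", class(out))
  out
}

#' Paired significance tests of enhancement across samples
#'
#' For every element, tests whether the chosen metric differs between
#' enhanced and original images across samples: a two-sided paired t-test on
#' the per-sample differences (enhanced - original), or Welch's unpaired
#' variant. All-zero differences are a degenerate case reported with `NA`
#' p-value and `degenerate = TRUE` rather than an error.
#'
#' @param records_original Tibble with columns `sample_id`, `element`, and
#'   the metric (rows with `coefficient = "none"` of a sweep work directly).
#' @param records_enhanced Same columns for the enhanced condition (one row
#'   per sample and element).
#' @param metric `"C"` or `"MG"`.
#' @param paired Paired t-test (default) or Welch's two-sample test.
#' @return Tibble with one row per element: `element`, `n`, `mean_diff`,
#'   `t`, `p`, `degenerate`.
#' @export
significance_table <- function(records_original, records_enhanced,
                               metric = c("C", "MG"), paired = TRUE) {
  metric <- match.arg(metric)
  orig <- dplyr::select(
    tibble::as_tibble(records_original),
    "sample_id", "element", original = dplyr::all_of(metric)
  )
  enh <- dplyr::select(
    tibble::as_tibble(records_enhanced),
    "sample_id", "element", enhanced = dplyr::all_of(metric)
  )
  if (anyDuplicated(orig[c("sample_id", "element")]) ||
      anyDuplicated(enh[c("sample_id", "element")])) {
    abort_validation("records must contain one row per (sample_id, element)")
  }
  joined <- dplyr::inner_join(orig, enh, by = c("sample_id", "element"))
  if (paired && (nrow(joined) < nrow(orig) || nrow(joined) < nrow(enh))) {
    abort_validation("original and enhanced records are not fully paired")
  }
  joined |>
    dplyr::group_by(.data$element) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 3L) abort_validation("need >= 3 samples per element")
      d <- df$enhanced - df$original
      if (all(d == 0) || (paired && sd(d) == 0) ||
          (!paired && sd(df$enhanced) == 0 && sd(df$original) == 0)) {
        return(tibble::tibble(
          n = n, mean_diff = mean(d), t = NA_real_, p = NA_real_, degenerate = TRUE
        ))
      }
      ht <- if (paired) {
        t.test(df$enhanced, df$original, paired = TRUE)
      } else {
        t.test(df$enhanced, df$original, var.equal = FALSE)
      }
      tibble::tibble(
        n = n, mean_diff = mean(d), t = unname(ht$statistic),
        p = ht$p.value, degenerate = FALSE
      )
    }) |>
    dplyr::ungroup()
}

#' Glance method for assessment sweeps
#'
#' One-row summary: number of enhanced cells, fraction with improved C and
#' MG relative to their matched originals, and mean Cp/MGp.
#'
#' @param x A `pit_sweep` tibble.
#' @param ... Unused.
#' @export
glance.pit_sweep <- function(x, ...) {
  enh <- dplyr::filter(x, .data$coefficient != "none")
  tibble::tibble(
    n_samples = dplyr::n_distinct(x$sample_id),
    n_cells = nrow(enh),
    frac_improved_C = mean(enh$Cp > 0),
    frac_improved_MG = mean(enh$MGp > 0),
    mean_Cp = mean(enh$Cp),
    mean_MGp = mean(enh$MGp)
  )
}

#' Tidy method for assessment sweeps: per-cell means across samples
#' @param x A `pit_sweep` tibble.
#' @param ... Unused.
#' @export
tidy.pit_sweep <- function(x, ...) {
  x |>
    dplyr::group_by(
      .data$element, .data$region, .data$coefficient, .data$alpha, .data$N
    ) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(c("C", "MG", "Cp", "MGp")), mean),
      .groups = "drop"
    )
}

#' Bar-chart of mean C or MG by overlay-scale group
#'
#' Mirrors the multi-sample evaluation figures: group A is the original
#' image, groups B..J the enhanced images with alpha = 0.1 .. 0.9, split by
#' coefficient.
#'
#' @param object A `pit_sweep` tibble.
#' @param metric `"C"` or `"MG"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pit_sweep <- function(object, metric = c("C", "MG"), ...) {
  metric <- match.arg(metric)
  df <- object |>
    dplyr::mutate(group = ifelse(
      .data$coefficient == "none", "A",
      LETTERS[1L + as.integer(round(.data$alpha * 10))]
    )) |>
    dplyr::group_by(.data$element, .data$region, .data$coefficient, .data$group) |>
    dplyr::summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$group, y = .data$value, fill = .data$coefficient
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(region ~ element) +
    ggplot2::labs(x = "overlay-scale group (A = original)", y = metric) +
    ggplot2::theme_minimal()
}
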