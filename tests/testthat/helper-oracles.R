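# Independent brute-force oracles. These deliberately avoid the package's
# code paths: literal sums and loops, base trig in degrees, exhaustive pair
# enumeration.

oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  s2 <- sum((x - mu)^2) / n
  s <- sqrt(s2)
  list(
    mu = mu, sigma = s,
    P3 = sum((x - mu)^3) / n / s^3,
    P4 = sum((x - mu)^4) / n / s^4
  )
}

# a' M s for one angle pair, base trig in radians
oracle_intensity <- function(M3, theta_g, theta_a, gain = 1) {
  s <- c(1, cos(2 * theta_g * pi / 180), sin(2 * theta_g * pi / 180))
  a <- c(1, cos(2 * theta_a * pi / 180), sin(2 * theta_a * pi / 180))
  gain * as.numeric(t(a) %*% M3 %*% s)
}

# exhaustive enumeration of unordered 4-neighbor pairs
oracle_contrast <- function(img) {
  deltas <- c()
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      if (i < nrow(img)) deltas <- c(deltas, img[i + 1, j] - img[i, j])
      if (j < ncol(img)) deltas <- c(deltas, img[i, j + 1] - img[i, j])
    }
  }
  mean(deltas^2)
}

oracle_mean_gradient <- function(img) {
  m <- nrow(img); n <- ncol(img)
  total <- 0
  for (i in seq_len(m - 1)) {
    for (j in seq_len(n - 1)) {
      total <- total + sqrt(
        ((img[i, j] - img[i + 1, j])^2 + (img[i, j] - img[i, j + 1])^2) / 2
      )
    }
  }
  total / ((m - 1) * (n - 1))
}

# textbook paired t statistic
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1))
}

# random pixel-wise physical Mueller field: m11 = 1 and the other entries
# bounded so every a' M s stays positive (|entries| <= u with 3u < 1)
random_physical_mueller <- function(h, w, u = 0.3) {
  els <- list(m11 = matrix(1, h, w))
  for (e in setdiff(MUELLER_ELEMENTS, "m11")) {
    els[[e]] <- matrix(runif(h * w, -u, u), h, w)
  }
  mueller_image(els[MUELLER_ELEMENTS])
}

max_element_error <- function(M1, M2, elements = MUELLER_ELEMENTS) {
  max(vapply(elements, function(e) {
    max(abs(element_image(M1, e) - element_image(M2, e)), na.rm = TRUE)
  }, numeric(1)))
}
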