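test_that("moment coefficients match closed-form and brute-force cases", {
  # two-point symmetric sample: skew 0, kurtosis 1 exactly
  m <- cmc_moments(c(0, 0, 1, 1))
  expect_equal(m$P3, 0)
  expect_equal(m$P4, 1)
  expect_false(m$degenerate)

  m2 <- cmc_moments(c(1, 2, 3, 4, 10))
  o <- oracle_moments(c(1, 2, 3, 4, 10))
  expect_equal(m2$P3, o$P3, tolerance = 1e-14)
  expect_equal(m2$P4, o$P4, tolerance = 1e-14)

  set.seed(1)
  g <- rnorm(2e5)
  mg <- cmc_moments(g)
  expect_lt(abs(mg$P3), 0.02)
  expect_lt(abs(mg$P4 - 3), 0.05)

  expect_error(cmc_moments(numeric(0)), "empty")
  expect_error(cmc_moments(c(1, NA)), "non-finite")
  d <- cmc_moments(rep(2, 7))
  expect_true(d$degenerate)
  expect_equal(c(d$P3, d$P4), c(0, 0))
})

test_that("moments satisfy affine invariance and the Pearson bound", {
  set.seed(2)
  for (rep in 1:200) {
    n <- sample(2:500, 1)
    x <- switch(sample(3, 1),
      rnorm(n), rexp(n), sample(0:3, n, replace = TRUE) + runif(n) * 0.01
    )
    m <- cmc_moments(x)
    if (!m$degenerate) {
      expect_gte(m$P4, m$P3^2 + 1 - 1e-9)
      a <- runif(1, -3, 3); b <- runif(1, -5, 5)
      if (abs(a) > 1e-3) {
        ma <- cmc_moments(a * x + b)
        expect_equal(ma$P3, sign(a)^3 * m$P3, tolerance = 1e-8)
        expect_equal(ma$P4, m$P4, tolerance = 1e-8)
      }
    }
  }
})

test_that("FDH is a relative-frequency histogram matching an independent binning", {
  # point mass: single bin holds everything
  f <- compute_fdh(rep(0.25, 10), bin_count = 8, value_range = c(0, 1))
  expect_equal(sum(f$frequency), 1)
  expect_equal(max(f$frequency), 1)

  f2 <- compute_fdh(c(0, 1), bin_count = 2, value_range = c(0, 1))
  expect_equal(f2$frequency, c(0.5, 0.5))

  set.seed(3)
  x <- rnorm(1e5)
  f3 <- compute_fdh(x, bin_count = 64, value_range = c(-4, 4))
  edges <- attr(f3, "bin_edges")
  h <- hist(pmin(pmax(x, -4), 4), breaks = edges, right = FALSE,
            include.lowest = TRUE, plot = FALSE)
  expect_equal(f3$frequency, h$counts / length(x), tolerance = 1e-12)

  # out-of-range handling (bins are left-closed: 0.5 lands in [0.5, 1])
  fc <- compute_fdh(c(-5, 0.5, 5), bin_count = 2, value_range = c(0, 1))
  expect_equal(fc$frequency, c(1 / 3, 2 / 3))
  fd <- compute_fdh(c(-5, 0.5, 5), bin_count = 2, value_range = c(0, 1), oob = "drop")
  expect_equal(fd$frequency, c(0, 1))
  expect_error(compute_fdh(numeric(0)), "no finite")
})

test_that("block grid covers the image with remainder-absorbing border blocks", {
  g <- block_grid(100, 100, 10)
  expect_equal(g$nrow_blocks * g$ncol_blocks, 100) # i*j/N^2
  expect_equal(sort(unique(as.vector(g$index))), 1:100)
  expect_equal(tabulate(g$index), rep(100L, 100))

  g2 <- block_grid(23, 10, 10)
  expect_equal(g2$nrow_blocks, 2L) # last row block absorbs 3 extra rows
  expect_equal(sum(g2$index == g2$index[23, 1]), 13 * 10)
  expect_error(block_grid(5, 5, 10), "larger than image")
})

test_that("blockwise maps agree with per-block brute force and recover skew sign", {
  set.seed(4)
  img <- matrix(0, 40, 40)
  img[, 1:20] <- rexp(40 * 20)          # right-skewed left half
  img[, 21:40] <- -rexp(40 * 20)        # left-skewed right half
  maps <- blockwise_cmc(img, N = 10)
  blocks <- maps$blocks
  expect_true(all(blocks$P3[blocks$block_col <= 2] > 0))
  expect_true(all(blocks$P3[blocks$block_col >= 3] < 0))
  # brute-force check of one interior block
  b <- img[11:20, 31:40]
  o <- oracle_moments(as.vector(b))
  row <- blocks[blocks$block_row == 2 & blocks$block_col == 4, ]
  expect_equal(row$P3, o$P3, tolerance = 1e-12)
  expect_equal(row$P4, o$P4, tolerance = 1e-12)
  expect_equal(row$sigma, o$sigma, tolerance = 1e-12)
  # raw map is blockwise constant
  expect_equal(length(unique(as.vector(maps$P3$raw[11:20, 31:40]))), 1L)
})

test_that("single-block mode equals whole-region moments exactly", {
  set.seed(5)
  img <- matrix(rnorm(30 * 30), 30, 30)
  maps <- blockwise_cmc(img, N = 30)
  whole <- cmc_moments(as.vector(img))
  expect_equal(maps$blocks$P3, whole$P3, tolerance = 1e-14)
  expect_equal(maps$blocks$P4, whole$P4, tolerance = 1e-14)
  expect_equal(dim(maps$blocks)[1], 1L)
})

test_that("degenerate and under-filled blocks are flagged, masked pixels excluded", {
  img <- matrix(1, 20, 20)
  maps <- blockwise_cmc(img, N = 5)
  expect_error(rescale_enhancement_matrix(maps$P3, 0, 1), "no valid blocks")
  expect_true(all(!maps$blocks$valid))
  expect_true(all(maps$blocks$P3 == 0)) # flagged zeros, not NaN

  set.seed(6)
  img2 <- matrix(rnorm(400), 20, 20)
  mask <- matrix(0L, 20, 20)
  mask[1:20, 1:7] <- 1L # region covers block column 2 only partially
  mask[3, 14] <- 1L     # lone 1-pixel membership in block (1,3)
  maps2 <- blockwise_cmc(img2, region_mask(mask), 1L, N = 5)
  blocks <- maps2$blocks
  expect_false(blocks$valid[blocks$block_row == 1 & blocks$block_col == 3]) # n = 1 < 4
  inreg <- blocks[blocks$block_col == 1, ]
  expect_true(all(inreg$valid))
  # in-region pixels only: block (1,3) stats use the single pixel,
  # block (1,2) uses just its 10 in-region pixels
  expect_equal(blocks$n[blocks$block_row == 1 & blocks$block_col == 3], 1L)
  expect_equal(blocks$n[blocks$block_row == 1 & blocks$block_col == 2], 10L)
  b12 <- oracle_moments(img2[1:5, 6:7])
  expect_equal(blocks$P3[blocks$block_row == 1 & blocks$block_col == 2], b12$P3,
               tolerance = 1e-12)
  expect_true(all(is.na(maps2$P3$raw[unclass(mask) == 0])))
  expect_error(blockwise_cmc(img2, region_mask(matrix(0L, 20, 20)), 1L, N = 5), "empty region")
})

test_that("Pearson bound holds for every valid block of random images", {
  set.seed(7)
  img <- matrix(rt(64 * 64, df = 5), 64, 64)
  for (N in c(4, 8, 16)) {
    blocks <- blockwise_cmc(img, N = N)$blocks
    v <- blocks[blocks$valid, ]
    expect_true(all(v$P4 >= v$P3^2 + 1 - 1e-9))
  }
})
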