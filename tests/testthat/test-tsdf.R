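test_that("boundary pixels follow the inner 4-neighbor rule", {
  m <- matrix(c(0, 0, 1, 1, 1), 1, 5)
  expect_equal(unname(boundary_pixels(m, 1)), matrix(c(1, 3), 1, 2))
  expect_equal(unname(boundary_pixels(m, 0)), matrix(c(1, 2), 1, 2))
  # uniform mask: image borders alone create no boundary
  expect_equal(nrow(boundary_pixels(matrix(2L, 4, 4), 2)), 0)
  # single interior pixel is its own boundary
  m3 <- matrix(0L, 3, 3); m3[2, 2] <- 1L
  expect_equal(unname(boundary_pixels(m3, 1)), matrix(c(2, 2), 1, 2))
  # absent class: empty set, not an error
  expect_equal(nrow(boundary_pixels(m3, 2)), 0)
})

test_that("signed distance matches hand-derived values and conventions", {
  m <- matrix(c(0, 0, 1, 1, 1), 1, 5)
  expect_equal(as.vector(signed_distance(m, 1, 5)), c(2, 1, 0, -1, -2))
  # absent class: constant +tau; full class: constant -tau
  expect_equal(signed_distance(m, 2, 5), matrix(5, 1, 5))
  expect_equal(signed_distance(matrix(0L, 3, 3), 0, 4), matrix(-4, 3, 3))
  expect_error(signed_distance(m, 1, 0), "tau")
  # 3x3 square centered in 9x9 with tau = 1
  sq <- matrix(0L, 9, 9); sq[4:6, 4:6] <- 1L
  d <- signed_distance(sq, 1, 1)
  expect_true(all(d %in% c(-1, 0, 1)))
  zeros <- which(d == 0, arr.ind = TRUE)
  expect_equal(nrow(zeros), 8)  # square boundary minus the center
  expect_true(all(d[5, 5] == -1))
})

test_that("normalization divides by the global max abs and handles zeros", {
  expect_equal(normalize_sd(matrix(c(2, 1, 0, -1, -2), 1)),
               matrix(c(1, 0.5, 0, -0.5, -1), 1))
  expect_equal(normalize_sd(matrix(0, 2, 2)), matrix(0, 2, 2))
  for (s in 1:5) {
    x <- matrix(stats::rnorm(20), 4, 5)
    expect_true(max(abs(normalize_sd(x))) %in% c(0, 1))
  }
})

test_that("tsdf stack reproduces the per-class worked example", {
  m <- matrix(c(0, 0, 1, 1, 1), 1, 5)
  st <- tsdf_stack(m, 2, 5)
  expect_equal(dim(st), c(1, 5, 2))
  # class 0: boundary at column 2, distances (-1,0,1,2,3)/3
  expect_equal(as.vector(st[1, , 1]), c(-1, 0, 1, 2, 3) / 3)
  # class 1: boundary at column 3, distances (2,1,0,-1,-2)/2
  expect_equal(as.vector(st[1, , 2]), c(1, 0.5, 0, -0.5, -1))
  # single-class image: constant -1 after normalization
  expect_equal(tsdf_stack(matrix(0L, 4, 4), 1, 5),
               array(-1, c(4, 4, 1)))
  expect_error(tsdf_stack(m, 1, 5), ">= K")
})

test_that("signed distance matches the brute-force oracle on random masks", {
  set.seed(42)
  for (i in 1:50) {
    H <- sample(4:16, 1); W <- sample(4:16, 1); K <- sample(2:4, 1)
    m <- random_mask(H, W, K)
    k <- sample(0:(K - 1), 1)
    tau <- sample(c(2, 5, 10), 1)
    expect_lt(max(abs(signed_distance(m, k, tau) -
                        brute_signed_distance(m, k, tau))), 1e-9)
  }
})

test_that("tsdf structure: sign, boundary zeros, truncation, normalization", {
  set.seed(7)
  for (i in 1:12) {
    K <- sample(2:4, 1)
    m <- if (i %% 2) random_mask(12, 12, K) else layered_mask(12, 12, K, i)
    for (k in 0:(K - 1)) {
      if (!any(m == k)) next
      d <- signed_distance(m, k, 5)
      expect_true(all(d[m == k] <= 0))
      expect_true(all(d[m != k] >= 0))
      bp <- boundary_pixels(m, k)
      if (nrow(bp) > 0) expect_true(all(d[bp] == 0))
      expect_lte(max(abs(d)), 5)  # truncation
      expect_true(all(abs(normalize_sd(d)) <= 1))
    }
  }
})

test_that("top2 returns the two largest channels with first-index ties", {
  x <- array(c(0.3, -0.2, 0.9), c(1, 1, 3))
  t2 <- top2(x)
  expect_equal(as.vector(t2$dmax1), 0.9)
  expect_equal(as.vector(t2$dmax2), 0.3)
  xc <- array(0.4, c(2, 2, 3))
  t2c <- top2(xc)
  expect_equal(t2c$dmax1, t2c$dmax2)
  expect_error(top2(array(1, c(2, 2, 1))), "K >= 2")
  # sort-based oracle
  set.seed(1)
  s <- array(stats::rnorm(4 * 5 * 5), c(5, 5, 4))
  t2s <- top2(s)
  for (r in 1:5) for (cc in 1:5) {
    v <- sort(s[r, cc, ], decreasing = TRUE)
    expect_equal(t2s$dmax1[r, cc], v[1])
    expect_equal(t2s$dmax2[r, cc], v[2])
  }
})

test_that("entropy weight matches scalar closed forms", {
  expect_equal(entropy_weight(matrix(0.3), matrix(0.3)), matrix(1))
  expect_equal(entropy_weight(matrix(1), matrix(-1)), matrix(0.527),
               tolerance = 1e-3)
  expect_equal(entropy_weight(matrix(0.6), matrix(0.4)), matrix(0.9928),
               tolerance = 1e-4)
})

test_that("entropy weight decreases in the gap and depends only on it", {
  gaps <- seq(0, 2, by = 0.1)
  w <- sapply(gaps, function(g) entropy_weight(matrix(0.5 + g / 2),
                                               matrix(0.5 - g / 2))[1])
  expect_true(all(diff(w) < 0))
  # same gap, different means
  expect_equal(entropy_weight(matrix(0.9), matrix(0.7)),
               entropy_weight(matrix(-0.1), matrix(-0.3)))
  expect_true(all(w > 0 & w <= 1))
})
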