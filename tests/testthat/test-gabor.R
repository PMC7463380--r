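test_that("the Gabor kernel matches its closed form at reference points", {
  # at the origin with zero phase every exponent vanishes
  for (theta in c(0, pi / 5, pi / 2)) {
    p <- gabor_params(lambda = 4, theta = theta)
    expect_equal(gabor_kernel_value(0, 0, p), 1 + 0i)
  }
  # one pixel along the wave axis: envelope e^(-1/2), phase pi/2
  p <- gabor_params(lambda = 4, theta = 0, gamma = 1, sigma = 1)
  v <- gabor_kernel_value(1, 0, p)
  expect_equal(Re(v), exp(-1 / 2) * cos(pi / 2))
  expect_equal(Im(v), exp(-1 / 2) * sin(pi / 2))
  expect_equal(Re(v), 0)
  expect_equal(Im(v), exp(-1 / 2))
})

test_that("kernels are rotation-equivariant", {
  # kernel at angle theta equals the theta = 0 kernel evaluated at
  # rotated coordinates, checked over a 9x9 offset grid
  theta <- pi / 4
  p_rot <- gabor_params(lambda = 3, theta = theta, gamma = 0.7, sigma = 2)
  p_axis <- gabor_params(lambda = 3, theta = 0, gamma = 0.7, sigma = 2)
  for (x in -4:4) {
    for (y in -4:4) {
      xr <- x * cos(theta) + y * sin(theta)
      yr <- -x * sin(theta) + y * cos(theta)
      expect_equal(gabor_kernel_value(x, y, p_rot),
                   gabor_kernel_value(xr, yr, p_axis), tolerance = 1e-12)
    }
  }
})

test_that("the default filter bank has 4 x 8 octave-spaced filters", {
  bank <- gabor_filter_bank()
  expect_length(bank$filters, 32L)
  # scale-major ordering with theta = (o-1) * pi / 8
  f1 <- bank$filters[[1L]]
  expect_equal(f1$scale, 1L)
  expect_equal(f1$params$theta, 0)
  f10 <- bank$filters[[10L]]
  expect_equal(f10$scale, 2L)
  expect_equal(f10$params$lambda, 8)
  expect_equal(f10$params$sigma, 0.56 * 8)
  expect_equal(f10$params$theta, pi / 8)
  # kernels are odd squares of side 2 * ceil(3 sigma) + 1
  for (f in bank$filters[c(1, 17, 32)]) {
    expect_equal(dim(f$kernel),
                 rep(2L * ceiling(3 * f$params$sigma) + 1L, 2L))
  }
  single <- gabor_filter_bank(n_scales = 1L, n_orientations = 1L)
  expect_length(single$filters, 1L)
  expect_equal(single$filters[[1L]]$params$theta, 0)
})

test_that("orthogonal orientations are grid rotations of each other", {
  bank <- gabor_filter_bank(n_scales = 1L, n_orientations = 4L, lambda0 = 6)
  k0 <- bank$filters[[1L]]$kernel   # theta = 0
  k90 <- bank$filters[[3L]]$kernel  # theta = pi/2
  # rotating the theta = 0 kernel array by 90 degrees gives theta = pi/2
  rot90 <- t(k0)[rev(seq_len(ncol(k0))), ]
  expect_equal(Mod(k90), Mod(rot90), tolerance = 1e-9)
})

test_that("filter responses obey convolution identities", {
  bank <- gabor_filter_bank(n_scales = 2L, n_orientations = 2L, lambda0 = 3)
  zero <- matrix(0, 10L, 20L)
  for (map in filter_response(zero, bank)) {
    expect_true(all(map == 0))
  }
  # homogeneity: scaling the profile scales every response linearly
  set.seed(3)
  x <- matrix(runif(10L * 20L), 10L, 20L)
  r1 <- filter_response(x, bank)
  r3 <- filter_response(3 * x, bank)
  for (i in seq_along(r1)) {
    expect_equal(r3[[i]], 3 * r1[[i]], tolerance = 1e-12)
  }
  expect_error(filter_response(matrix(1, 3L, 20L), bank), "at least 4")
})

test_that("responses match a brute-force direct-sum correlation oracle", {
  bank <- gabor_filter_bank(n_scales = 2L, n_orientations = 3L, lambda0 = 3)
  set.seed(11)
  x <- matrix(runif(9L * 12L), 9L, 12L)
  maps <- filter_response(x, bank)
  for (i in seq_along(bank$filters)) {
    oracle <- brute_xcorr(x, bank$filters[[i]]$kernel)
    expect_equal(maps[[i]], Mod(oracle), tolerance = 1e-9)
  }
})

test_that("an impulse reproduces the kernel magnitude around its location", {
  bank <- gabor_filter_bank(n_scales = 1L, n_orientations = 1L, lambda0 = 2)
  kern <- bank$filters[[1L]]$kernel
  h <- (nrow(kern) - 1L) / 2L
  x <- matrix(0, 31L, 31L)
  x[16L, 16L] <- 1
  map <- filter_response(x, bank)[[1L]]
  patch <- map[16L + (-h:h), 16L + (-h:h)]
  # correlation flips the kernel relative to convolution, but the Gabor
  # magnitude is symmetric under (x, y) -> (-x, -y)
  expect_equal(patch, Mod(kern), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("GIST pooling yields the advertised geometry", {
  bank <- gabor_filter_bank()
  p <- synthesize_pssm("g1", 23L, seed = 8L)
  g <- extract_gist(normalize_pssm(p), bank)
  expect_length(g$values, 512L)
  expect_true(all(g$values >= 0))

  zero <- extract_gist(matrix(0, 8L, 20L), bank)
  expect_true(all(zero$values == 0))

  # non-default configurations keep length = n_blocks x n_filters
  small_bank <- gabor_filter_bank(n_scales = 3L, n_orientations = 5L)
  g2 <- extract_gist(matrix(runif(40L * 20L), 40L, 20L), small_bank,
                     grid = c(2L, 5L))
  expect_length(g2$values, 2L * 5L * 15L)
})

test_that("block pooling partitions the response exactly", {
  bank <- gabor_filter_bank(n_scales = 1L, n_orientations = 2L, lambda0 = 3)
  set.seed(5)
  x <- matrix(runif(16L * 20L), 16L, 20L)
  maps <- filter_response(x, bank)
  g <- extract_gist(x, bank)
  # sum over blocks of block_size * block_mean recovers the map total
  n_blocks <- 16L
  for (i in seq_along(maps)) {
    block_means <- g$values[(i - 1L) * n_blocks + seq_len(n_blocks)]
    block_size <- 4L * 5L  # 16 rows and 20 cols split evenly
    expect_equal(sum(block_means) * block_size, sum(maps[[i]]),
                 tolerance = 1e-9)
  }
})

test_that("descriptors are stateless across batch order", {
  bank <- gabor_filter_bank(n_scales = 2L, n_orientations = 2L)
  p1 <- synthesize_pssm("s1", 15L, seed = 1L)
  p2 <- synthesize_pssm("s2", 18L, seed = 2L)
  ab <- extract_gist_batch(list(p1, p2), bank)
  ba <- extract_gist_batch(list(p2, p1), bank)
  expect_equal(ab["s1", ], ba["s1", ])
  expect_equal(ab["s2", ], ba["s2", ])
})

test_that("descriptor TSVs round-trip", {
  bank <- gabor_filter_bank(n_scales = 1L, n_orientations = 2L)
  d <- extract_gist_batch(list(synthesize_pssm("r1", 12L, seed = 3L)), bank)
  path <- tempfile()
  write_gist(d, path)
  back <- read_gist(path)
  expect_equal(back, d, tolerance = 1e-9)
})
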