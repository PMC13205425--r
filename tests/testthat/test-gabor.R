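test_that("kernel synthesis matches the filter formula and its symmetries", {
  # odd window, zero phase: sine is odd, envelope even -> centre weight 0,
  # point-reflection antisymmetry, zero sum
  k <- gabor_kernel(gabor_params(9, 2.5, 1.1, 4, 0.6, 0))$weights
  expect_identical(k[5, 5], 0)
  expect_equal(k, -k[9:1, 9:1])
  expect_equal(sum(k), 0)

  # 1x1 window at quarter phase is the identity weight
  k1 <- gabor_kernel(gabor_params(1, 2, 0.3, 5, 0.5, pi / 2))$weights
  expect_equal(k1, matrix(1, 1, 1))

  # isotropic envelope: rotating the filter by 90 degrees swaps coordinates
  k0 <- gabor_kernel(gabor_params(7, 2, 0, 3, 1, 1))$weights
  k90 <- gabor_kernel(gabor_params(7, 2, pi / 2, 3, 1, 1))$weights
  expect_equal(k90, t(k0))

  # pointwise agreement with a scalar evaluation of the formula,
  # on an optimized fixture filter and on an even-size window
  p <- bank_fixture("median")$filters[[1]]
  kw <- gabor_kernel(p)$weights
  offs <- seq_len(p$m) - (p$m + 1) / 2
  for (i in seq_len(p$m)) for (j in seq_len(p$m)) {
    expect_equal(kw[i, j],
                 gabor_point(offs[i], offs[j], p$sigma, p$theta, p$lambda,
                             p$gamma, p$psi),
                 tolerance = 1e-12)
  }
  pe <- gabor_params(6, 2, 0.8, 3.5, 0.4, 1.2)
  kwe <- gabor_kernel(pe)$weights
  offs <- seq_len(6) - 3.5  # symmetric half-integer offsets for even windows
  expect_equal(kwe[2, 5],
               gabor_point(offs[2], offs[5], 2, 0.8, 3.5, 0.4, 1.2),
               tolerance = 1e-12)
})

test_that("parameter domains are enforced", {
  expect_error(gabor_params(0, 2, 1, 4, 0.5, 1), "out of domain")
  expect_error(gabor_params(21, 2, 1, 4, 0.5, 1), "out of domain")
  expect_error(gabor_params(9, 2, 4, 4, 0.5, 1), "out of domain")
  expect_error(gabor_params(9, 2, 1, 4, 1.5, 1), "out of domain")
  expect_silent(gabor_params(20, 5, pi, 10, 1, 2 * pi))
})

test_that("convolution matches the nested-loop oracle and its identities", {
  # zero-sum kernel on a constant image: exactly zero under replicate padding
  kz <- gabor_kernel(gabor_params(9, 2.5, 0.7, 4, 0.6, 0))
  expect_equal(gabor_convolve(matrix(42, 12, 15), kz),
               matrix(0, 12, 15), tolerance = 1e-10)

  # 1x1 quarter-phase kernel is the identity operator
  ki <- gabor_kernel(gabor_params(1, 2, 0.3, 5, 0.5, pi / 2))
  img <- matrix(runif(63), 7, 9)
  expect_equal(gabor_convolve(img, ki), img)

  # random kernels against the brute-force double loop, odd and even sizes
  set.seed(41)
  for (m in c(3, 4, 5)) {
    img <- matrix(runif(49, 0, 255), 7, 7)
    ker <- matrix(rnorm(m * m), m, m)
    expect_equal(gabor_convolve(img, ker), conv2_oracle(img, ker),
                 tolerance = 1e-12)
  }

  # linearity: response(a*I1 + b*I2) = a*response(I1) + b*response(I2)
  set.seed(42)
  ker <- gabor_kernel(gabor_params(5, 2, 1.2, 3, 0.5, 0.8))
  for (rep in 1:5) {
    i1 <- matrix(runif(60), 6, 10); i2 <- matrix(runif(60), 6, 10)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(gabor_convolve(a * i1 + b * i2, ker),
                 a * gabor_convolve(i1, ker) + b * gabor_convolve(i2, ker),
                 tolerance = 1e-9)
  }
})

test_that("response statistics are the population mean and sd", {
  expect_equal(response_stats(matrix(0, 3, 4)), c(mu = 0, sigma = 0))
  r <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]]
  st <- response_stats(r)
  expect_equal(st[["mu"]], 2.5)
  expect_equal(st[["sigma"]], sqrt(1.25))
  # population (divisor MN) form, not the n-1 sample form
  expect_false(isTRUE(all.equal(st[["sigma"]], sd(r))))
  set.seed(5)
  for (rep in 1:10) {
    x <- matrix(rnorm(24), 4, 6)
    expect_gte(response_stats(x)[["sigma"]], 0)
  }
  expect_equal(response_stats(matrix(7.7, 5, 5))[["sigma"]], 0)
})

test_that("feature vectors compose kernel, convolution and statistics", {
  bank <- bank_fixture("median")
  zero <- matrix(0, 8, 8)
  expect_equal(unname(extract_features(zero, bank)), rep(0, 8))

  # identity filter: mu = image mean, sigma = population sd
  idb <- gabor_bank(gabor_params(1, 2, 0, 5, 0.5, pi / 2))
  img <- matrix(runif(96, 0, 255), 8, 12)
  f <- extract_features(img, idb)
  expect_equal(f[["mu1"]], mean(img))
  expect_equal(f[["sigma1"]], sqrt(mean((img - mean(img))^2)))

  # checkerboard + fixture bank equals composing the oracle-tested steps
  cb <- 255 * outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  f <- extract_features(cb, bank)
  expect_length(f, 8)
  for (j in seq_along(bank$filters)) {
    resp <- conv2_oracle(cb, gabor_kernel(bank$filters[[j]])$weights)
    expect_equal(f[[2 * j - 1]], mean(resp), tolerance = 1e-9)
    expect_equal(f[[2 * j]], sqrt(mean((resp - mean(resp))^2)),
                 tolerance = 1e-9)
  }
})

test_that("response energy peaks at the grating orientation", {
  theta0 <- pi / 3; lam <- 5
  img <- grating_image(48, 48, theta0, lam)
  grid <- seq(0, pi, by = pi / 36)
  energy <- vapply(grid, function(th) {
    k <- gabor_kernel(gabor_params(11, 3, th, lam, 0.5, 0))
    response_stats(gabor_convolve(img, k))[["sigma"]]
  }, numeric(1))
  expect_lte(abs(grid[which.max(energy)] - theta0), pi / 36 + 1e-9)
})

test_that("bank JSON serialization round-trips with domain revalidation", {
  path <- withr::local_tempfile(fileext = ".json")
  bank <- gabor_bank(gabor_params(9, 2.5, 1.1, 4, 0.6, 0),
                     gabor_params(15, 4, 3, 8, 0.9, 5))
  write_bank(bank, path, metadata = list(seed = 7))
  back <- read_bank(path)
  expect_equal(back$filters, bank$filters)
  expect_equal(attr(back, "metadata")$seed, 7)

  # invalid stored parameters are rejected on load
  jsonlite::write_json(list(filters = list(list(m = 30, sigma = 2, theta = 1,
                                                lambda = 4, gamma = 0.5,
                                                psi = 1))),
                       path, auto_unbox = TRUE)
  expect_error(read_bank(path), "out of domain")
})
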