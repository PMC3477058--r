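test_that("conduction function has the closed form and monotonicity", {
  expect_equal(conduction(0, 1), 1)
  expect_equal(conduction(0.5, 0.5), exp(-1))
  expect_equal(conduction(90, 90), exp(-1))
  g <- conduction(seq(0, 2, by = 0.1), 0.7)
  expect_true(all(diff(g) < 0))
  expect_true(all(g > 0 & g <= 1))
  expect_equal(conduction(-0.3, 0.3), conduction(0.3, 0.3))
  expect_error(conduction(0.1, 0), class = "retinodiag_bad_param")
  expect_error(conduction(0.1, -1), class = "retinodiag_bad_param")
})

test_that("parameter validation enforces the stability ranges", {
  expect_error(diffusion_params(lam = 0), class = "retinodiag_bad_param")
  expect_error(diffusion_params(lam = 0.3), class = "retinodiag_bad_param")
  expect_error(diffusion_params(K = -1), class = "retinodiag_bad_param")
  expect_error(diffusion_params(n_iter = 0), class = "retinodiag_bad_param")
  expect_error(diffusion_params(neighbors = 6), class = "retinodiag_bad_param")
  expect_warning(diffusion_params(lam = 0.2), "maximum principle")
  expect_silent(diffusion_params(lam = 0.125))
  expect_silent(diffusion_params(lam = 0.25, neighbors = 4L))
})

test_that("constant images are exact fixed points", {
  img <- matrix(0.37, 30, 40)
  for (nb in c(4L, 8L)) {
    out <- anisotropic_diffuse(img, diffusion_params(K = 0.1, n_iter = 5,
                                                     neighbors = nb))
    expect_identical(out, img)
  }
  # statistical K path on a flat image is also a fixed point
  expect_identical(anisotropic_diffuse(img, diffusion_params(n_iter = 3)),
                   img)
})

test_that("with g == 1 the scheme is the linear 8-neighbor stencil", {
  set.seed(31)
  img <- matrix(runif(20 * 24), 20)
  lam <- 0.1
  stencil <- matrix(lam, 3, 3); stencil[2, 2] <- 1 - 8 * lam
  # replicate-border convolution oracle
  oracle <- img
  n <- 4
  pad_conv <- function(m) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, H, W)
    for (a in -1:1) for (b in -1:1) {
      ri <- pmin(pmax(seq_len(H) + a, 1), H)
      ci <- pmin(pmax(seq_len(W) + b, 1), W)
      out <- out + stencil[a + 2, b + 2] * m[ri, ci]
    }
    out
  }
  for (i in seq_len(n)) oracle <- pad_conv(oracle)
  got <- anisotropic_diffuse(img, diffusion_params(lam = lam, K = 1,
                                                   n_iter = n),
                             force_linear = TRUE)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("single-step update on a step edge matches the hand computation", {
  # two flat columns of height h apart; compute one explicit step by hand
  K <- 0.2; h <- 0.6; lam <- 0.125
  img <- cbind(matrix(0.1, 4, 2), matrix(0.1 + h, 4, 2))
  out <- anisotropic_diffuse(img, diffusion_params(lam = lam, K = K,
                                                   n_iter = 1))
  # interior pixel on the dark side of the edge: E and the two diagonal
  # east neighbors cross the edge, everything else is flat
  flux <- (conduction(h, K) * h) * 3 * lam
  expect_equal(out[2, 2], 0.1 + flux, tolerance = 1e-12)
  expect_equal(out[2, 3], 0.1 + h - flux, tolerance = 1e-12)
  expect_equal(out[2, 1], 0.1, tolerance = 1e-12)  # far column untouched
})

test_that("maximum principle holds at lam = 1/8 with 8 neighbors", {
  set.seed(32)
  for (i in 1:10) {
    img <- matrix(runif(32 * 32), 32)
    out <- anisotropic_diffuse(img, diffusion_params(lam = 1 / 8, K = 0.2,
                                                     n_iter = 10))
    expect_gte(min(out), min(img) - 1e-12)
    expect_lte(max(out), max(img) + 1e-12)
  }
})

test_that("edges are preserved while flat regions smooth", {
  set.seed(33)
  K <- 0.1; h <- 5 * K
  img <- cbind(matrix(0.2, 32, 16), matrix(0.2 + h, 32, 16)) +
    matrix(rnorm(32 * 32, 0, 0.01), 32)
  img <- pmin(pmax(img, 0), 1)
  edge_grad <- function(m) mean(abs(m[, 17] - m[, 16]))
  g0 <- edge_grad(img)
  p1 <- diffusion_params(K = K, n_iter = 1)
  cur <- img
  vars <- var(as.vector(cur[, 1:14]))
  for (i in 1:20) {
    cur <- anisotropic_diffuse(cur, p1)
    v <- var(as.vector(cur[, 1:14]))
    expect_lt(v, vars[length(vars)])   # within-region variance decreases
    vars <- c(vars, v)
  }
  expect_gt(edge_grad(cur), 0.9 * g0)  # edge survives 20 iterations
})
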