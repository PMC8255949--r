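# Independent oracles used below:
#  - numeric differentiation for gradient checks
#  - a plain (non-accelerated) projected-gradient dual solver, run very long,
#    for the TV proximal mapping
#  - direct normal-equation algebra for least squares

num_grad <- function(fun, x, h = 1e-6) {
  v <- as_vec(x)
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    vp <- v; vm <- v
    vp[i] <- vp[i] + h; vm[i] <- vm[i] - h
    g[i] <- (fun(td_from_vec(vp, x$geometry)) -
               fun(td_from_vec(vm, x$geometry))) / (2 * h)
  }
  g
}


test_that("least squares matches explicit normal-equation arithmetic", {
  oracle <- rand_dense_op(3, 2, 101)
  M <- oracle$M; A <- oracle$A
  b <- td_from_vec(c(1, -2, 0.5), vec_geom(3L))
  u <- td_from_vec(c(0.3, -0.7), vec_geom(2L))
  res <- least_squares_value_gradient(u, A, b)
  r <- M %*% as_vec(u) - as_vec(b)
  expect_equal(res$value, sum(r^2))
  expect_equal(as_vec(res$gradient), as.numeric(2 * crossprod(M, r)))
  # minimizer: value/gradient vanish residual-wise
  ustar <- solve(crossprod(M), crossprod(M, as_vec(b)))
  res2 <- least_squares_value_gradient(td_from_vec(ustar, vec_geom(2L)), A, b)
  expect_lt(l2norm(res2$gradient), 1e-10)
  # A = I: gradient 2(u - b)
  ig <- vec_geom(3L)
  f <- least_squares(identity_operator(ig), b)
  expect_equal(as_vec(fn_gradient(f, td_from_vec(c(1, 1, 1), ig))),
               2 * (c(1, 1, 1) - as_vec(b)))
  # L = 2 ||A||^2
  expect_equal(fn_L(f), 2, tolerance = 1e-6)
})

test_that("closed-form proximal mappings are exact", {
  ig <- vec_geom(4L)
  x <- td_from_vec(c(2, 0.4, -0.2, -3), ig)
  # soft thresholding, alpha*tau = 0.5
  expect_equal(as_vec(prox_l1(x, 0.5, alpha = 1)), c(1.5, 0, 0, -2.5))
  expect_equal(as_vec(prox_l1(-1 * x, 0.5)), -as_vec(prox_l1(x, 0.5)))
  # l2 squared: b = 0, alpha*tau = 0.5 -> x/2
  expect_equal(as_vec(prox_l2sq(x, 0.5)), as_vec(x) / 2)
  expect_equal(as_vec(prox_l2sq(x, 1e-12)), as_vec(x), tolerance = 1e-9)
  b <- td_from_vec(c(1, 1, 1, 1), ig)
  expect_equal(as_vec(prox_l2sq(b, 0.7, b = b)), as_vec(b))
  # mixed l21: voxel vector (3,4), alpha*tau = 1 -> shrink by 1 - 1/5
  X <- block_data(td_from_vec(c(3, 0, 0.1, 0), ig),
                  td_from_vec(c(4, 0, 0.1, 0), ig))
  P <- prox_mixed_l21(X, 1, alpha = 1)
  expect_equal(as_vec(get_block(P, 1))[1], 2.4)
  expect_equal(as_vec(get_block(P, 2))[1], 3.2)
  expect_equal(as_vec(get_block(P, 1))[3], 0)  # ||v|| <= alpha tau -> 0
  # direction preserved
  expect_equal(as_vec(get_block(P, 1))[1] / as_vec(get_block(P, 2))[1], 3 / 4)
  # box projection
  y <- td_from_vec(c(0.12, 0.05, -0.3, 0.09), ig)
  pb <- project_box(y, 0, 0.09)
  expect_equal(as_vec(pb), c(0.09, 0.05, 0, 0.09))
  expect_equal(as_vec(project_box(pb, 0, 0.09)), as_vec(pb))  # idempotent
  expect_error(project_box(y, 1, 0), "lower")
})

test_that("smoothed L2,1 value/gradient and its limit", {
  ig <- vec_geom(5L)
  Z <- block_data(allocate(ig, 0), allocate(ig, 0))
  beta <- 0.01
  res <- smooth_l21_value_gradient(Z, beta)
  expect_equal(res$value, 5 * beta)
  expect_equal(l2norm(res$gradient), 0)
  X <- block_data(rand_td(ig, 110), rand_td(ig, 111))
  f <- smooth_l21_norm(1e-6)
  g <- mixed_l21_norm(1)
  expect_equal(fn_value(f, X), fn_value(g, X), tolerance = 1e-4)
  expect_error(smooth_l21_norm(0), "beta")
})

test_that("Kullback-Leibler divergence obeys its identities", {
  ig <- vec_geom(4L)
  b <- td_from_vec(c(2, 0, 1.5, 4), ig)
  v <- b  # v + eta = b with eta = 0
  res <- kl_value_gradient(v, b)
  expect_equal(res$value, 0)
  expect_equal(as_vec(res$gradient)[c(1, 3, 4)], c(0, 0, 0))
  # b = 0 voxel contributes v + eta
  v2 <- td_from_vec(c(2, 0.7, 1.5, 4), ig)
  expect_equal(kl_value_gradient(v2, b)$value, 0.7)
  # Gibbs: non-negative on random feasible inputs
  for (i in 1:25) {
    vv <- rand_td(ig, 120 + i) * 3 + 0.05
    expect_gte(kl_value_gradient(vv, b)$value, 0)
  }
  expect_error(kl_value_gradient(td_from_vec(c(-1, 1, 1, 1), ig), b),
               "undefined")
})

test_that("tv_value computes the mixed L2,1 norm of the gradient", {
  ig <- image_geometry(2, 2)
  u <- as_tomo_data(matrix(c(0, 0, 1, 1), 2, 2), ig)  # columns 0 and 1
  expect_equal(tv_value(u, 1), 2)
  expect_equal(tv_value(allocate(small_ig(), 5)), 0)
  u2 <- rand_td(small_ig(), 130)
  expect_equal(tv_value(-3 * u2), 3 * tv_value(u2))
})

test_that("tv_proximal matches a long-run dual oracle on 4x4 images", {
  ig <- image_geometry(4, 4)
  for (i in 1:3) {
    u <- rand_td(ig, 140 + i)
    lam <- c(0.1, 0.3, 1)[i]
    ours <- tv_proximal(u, 1, alpha = lam, inner_iters = 5000, tol = 1e-12)
    oracle <- tv_prox_oracle(u, lam, iters = 1e5)
    expect_lt(sqrt(mean((as_array(ours) - oracle)^2)), 1e-4)
  }
  # constant image is the TV minimizer
  uc <- allocate(ig, 2)
  expect_equal(as_array(tv_proximal(uc, 1, alpha = 1)), as_array(uc))
  # huge alpha*tau flattens to the mean
  u <- rand_td(ig, 150)
  flat <- tv_proximal(u, 1, alpha = 500, inner_iters = 5000, tol = 1e-12)
  expect_lt(max(abs(as_array(flat) - mean(u))), 1e-3)
})

test_that("smooth functions pass finite-difference gradient checks", {
  ig <- vec_geom(4L)
  b <- td_from_vec(c(0.5, 1, 0.2, 2), ig)
  oracle <- rand_dense_op(5, 4, 160)
  cases <- list(
    l2sq = l2sq_norm(b = b, alpha = 0.8),
    weighted = weighted_l2sq_norm(td_from_vec(c(1, 2, 3, 4), ig), b = b),
    ls = least_squares(oracle$A, td_from_vec(seq_len(5) / 5, vec_geom(5L))),
    kl = kullback_leibler(b, eta = 0.1)
  )
  for (nm in names(cases)) {
    f <- cases[[nm]]
    x <- rand_td(ig, 170) + 0.3
    g <- fn_gradient(f, x)
    gn <- num_grad(function(z) fn_value(f, z), x)
    expect_equal(as_vec(g), gn, tolerance = 1e-5, label = nm)
  }
  # Lipschitz bound on random pairs
  f <- cases$l2sq
  for (i in 1:10) {
    x <- rand_td(ig, 180 + i); y <- rand_td(ig, 190 + i)
    expect_lte(l2norm(fn_gradient(f, x) - fn_gradient(f, y)),
               fn_L(f) * l2norm(x - y) + 1e-12)
  }
})

test_that("prox characterization inequality holds for proximable g", {
  ig <- vec_geom(6L)
  tau <- 0.37
  gs <- list(l1 = l1_norm(0.5),
             l2 = l2sq_norm(b = rand_td(ig, 200), alpha = 2),
             box = indicator_box(0, 1),
             kl = kullback_leibler(rand_td(ig, 201) * 2 + 0.2, eta = 0.3))
  for (nm in names(gs)) {
    g <- gs[[nm]]
    x <- rand_td(ig, 210) + 0.2
    xp <- fn_prox(g, x, tau)
    lhs <- fn_value(g, xp) + dot(xp - x, xp - x) / (2 * tau)
    for (i in 1:100) {
      v <- rand_td(ig, 300 + i) * 0.8 + 0.1
      rhs <- fn_value(g, v) + dot(v - x, v - x) / (2 * tau)
      expect_lte(lhs, rhs + 1e-9, label = nm)
    }
  }
})

test_that("Moreau identity ties prox and conjugate prox", {
  ig <- vec_geom(5L)
  tau <- 0.8
  fs <- list(l1_norm(0.7), l2sq_norm(b = rand_td(ig, 220)),
             indicator_box(-0.5, 0.5))
  for (f in fs) {
    x <- rand_td(ig, 221) * 2 - 1
    lhs <- fn_prox(f, x, tau) + tau * fn_prox_conjugate(f, x * (1 / tau),
                                                        1 / tau)
    expect_equal(as_vec(lhs), as_vec(x), tolerance = 1e-6)
  }
  # block/mixed-l21 version
  X <- block_data(rand_td(ig, 222), rand_td(ig, 223))
  f <- mixed_l21_norm(0.6)
  lhs <- fn_prox(f, X, tau) + tau * fn_prox_conjugate(f, X * (1 / tau),
                                                      1 / tau)
  expect_equal(as_vec(get_block(lhs, 1)), as_vec(get_block(X, 1)),
               tolerance = 1e-6)
})

test_that("proximal mappings are firmly nonexpansive", {
  ig <- vec_geom(6L)
  gs <- list(l1_norm(0.3), l2sq_norm(alpha = 1.5), indicator_box(0, 0.5))
  for (g in gs) for (i in 1:10) {
    x <- rand_td(ig, 400 + i) * 4 - 2
    y <- rand_td(ig, 500 + i) * 4 - 2
    expect_lte(l2norm(fn_prox(g, x, 0.9) - fn_prox(g, y, 0.9)),
               l2norm(x - y) + 1e-12)
  }
})

test_that("function algebra: scaling, sums, composition, blocks", {
  ig <- vec_geom(4L)
  b <- rand_td(ig, 230)
  f <- l2sq_norm(b = b)
  x <- rand_td(ig, 231)
  sf <- 3 * f
  expect_equal(fn_value(sf, x), 3 * fn_value(f, x))
  expect_equal(as_vec(fn_gradient(sf, x)), 3 * as_vec(fn_gradient(f, x)))
  expect_equal(fn_L(sf), 3 * fn_L(f))
  # prox of scaled = prox with scaled parameter
  expect_equal(as_vec(fn_prox(sf, x, 0.2)), as_vec(fn_prox(f, x, 0.6)))
  # sum: value/gradient add, prox refused
  s <- f + l2sq_norm(alpha = 0.5)
  expect_equal(fn_value(s, x), fn_value(f, x) + 0.5 * dot(x, x))
  expect_error(fn_prox(s, x, 0.1), "no proximal")
  # composition with identity leaves the gradient alone
  cf <- operator_composition(f, identity_operator(ig))
  expect_equal(as_vec(fn_gradient(cf, x)), as_vec(fn_gradient(f, x)))
  # composition gradient matches central differences
  oracle <- rand_dense_op(5, 4, 232)
  cf2 <- operator_composition(l2sq_norm(b = td_from_vec(seq_len(5) / 3,
                                                        vec_geom(5L))),
                              oracle$A)
  g <- fn_gradient(cf2, x)
  gn <- num_grad(function(z) fn_value(cf2, z), x)
  expect_equal(as_vec(g), gn, tolerance = 1e-5)
  # block function: value sums, prox applies blockwise
  bf <- block_function(l1_norm(0.5), l2sq_norm())
  X <- block_data(rand_td(ig, 233), rand_td(ig, 234))
  expect_equal(fn_value(bf, X),
               0.5 * sum(abs(as_vec(get_block(X, 1)))) +
                 dot(get_block(X, 2), get_block(X, 2)))
  P <- fn_prox(bf, X, 0.4)
  expect_equal(as_vec(get_block(P, 1)),
               as_vec(prox_l1(get_block(X, 1), 0.4, 0.5)))
  expect_equal(as_vec(get_block(P, 2)),
               as_vec(prox_l2sq(get_block(X, 2), 0.4)))
})
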