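# Independent oracles: dense normal equations, weighted normal equations,
# coordinate descent for the LASSO.



test_that("CGLS solves identity in one step and matches dense oracles", {
  ig <- vec_geom(5L)
  b <- rand_td(ig, 600)
  st <- run_cgls(identity_operator(ig), b, max_iters = 1)
  expect_equal(as_vec(st$x), as_vec(b), tolerance = 1e-12)

  oracle <- rand_dense_op(6, 4, 601)
  bb <- rand_td(vec_geom(6L), 602)
  st2 <- run_cgls(oracle$A, bb, max_iters = 40, tol = 1e-15)
  xo <- solve(crossprod(oracle$M), crossprod(oracle$M, as_vec(bb)))
  expect_lt(max(abs(as_vec(st2$x) - xo)), 1e-8)
  # residual norm non-increasing
  expect_true(all(diff(st2$objective_history$objective) <= 1e-10))
})

test_that("Tikhonov block CGLS matches the closed form", {
  # 16-pixel image, few-view projector, gradient regularizer
  ig <- image_geometry(4, 4)
  ag <- acquisition_geometry("parallel2D", angles = c(0, 45, 90, 135),
                             pixel_num_h = 4)
  A <- projection_operator(ig, ag)
  D <- gradient_operator(ig)
  alpha <- 0.9
  # dense representations built by probing with basis vectors
  probe <- function(op, nin, nout) {
    M <- matrix(0, nout, nin)
    for (j in seq_len(nin)) {
      e <- numeric(nin); e[j] <- 1
      M[, j] <- td_values(op$direct(td_from_vec(array(e, c(4, 4)), ig)))
    }
    M
  }
  Ma <- probe(A, 16L, 16L)    # 4 angles x 4 detectors
  Md <- probe(D, 16L, 32L)    # 2 blocks x 16
  u_true <- rand_td(ig, 610)
  b <- op_direct(A, u_true)
  Atilde <- block_operator(list(A, alpha * D), nrow = 2L)
  btilde <- block_data(b, block_data(allocate(ig, 0), allocate(ig, 0)))
  st <- run_cgls(Atilde, btilde, max_iters = 200, tol = 1e-14)
  xo <- solve(crossprod(Ma) + alpha^2 * crossprod(Md),
              crossprod(Ma, td_values(b)))
  expect_lt(max(abs(td_values(st$x) - xo)), 1e-6)
  # alpha = 0 degenerates to plain least squares on the same data
  At0 <- block_operator(list(A, 0 * D), nrow = 2L)
  st0 <- run_cgls(At0, btilde, max_iters = 200, tol = 1e-14)
  stp <- run_cgls(A, b, max_iters = 200, tol = 1e-14)
  expect_equal(td_values(st0$x), td_values(stp$x), tolerance = 1e-6)
})

test_that("SIRT respects bounds and approaches the weighted LS solution", {
  # consistent identity system converges to b under the bounds
  ig <- vec_geom(4L)
  b <- td_from_vec(c(0.02, 0.05, 0.07, 0.04), ig)
  st <- run_sirt(identity_operator(ig), b, max_iters = 60,
                 lower = 0, upper = 0.09)
  expect_equal(as_vec(st$x), as_vec(b), tolerance = 1e-8)

  # bounds hold at every iterate
  ag <- acquisition_geometry("parallel2D", angles = seq(0, 160, by = 20),
                             pixel_num_h = 8)
  ig2 <- small_ig()
  A <- projection_operator(ig2, ag)
  sino <- simulate_acquisition(make_phantom(phantom_spec("disc", 8,
                                                         value = 0.2)), ag)
  state <- run_sirt(A, sino, max_iters = 1, lower = 0, upper = 0.09)
  for (k in 1:15) {
    state <- run_more(state, 1)
    expect_gte(min(as_array(state$x)), 0)
    expect_lte(max(as_array(state$x)), 0.09)
  }

  # unconstrained SIRT -> row-weighted least-squares minimizer
  set.seed(620)
  M <- matrix(runif(24, 0.1, 1), 6, 4)
  Aop <- dense_operator(M, vec_geom(4L), vec_geom(6L))
  bb <- rand_td(vec_geom(6L), 621)
  stw <- run_sirt(Aop, bb, max_iters = 1e4)
  W <- diag(1 / rowSums(M))
  xo <- solve(t(M) %*% W %*% M, t(M) %*% W %*% as_vec(bb))
  expect_lt(max(abs(as_vec(stw$x) - xo)), 1e-4)
})

test_that("gradient descent: quadratic convergence and Armijo monotonicity", {
  ig <- vec_geom(5L)
  b <- rand_td(ig, 630)
  f <- l2sq_norm(b = b)           # L = 2
  st <- run_gd(f, allocate(ig, 0), step = 0.5 * (1 / 2) * 2, max_iters = 60)
  expect_lt(l2norm(st$x - b), 1e-8)
  # backtracking on a composed Tikhonov objective is monotone
  oracle <- rand_dense_op(6, 4, 631)
  D <- finite_difference_operator(vec_geom(4L), "horizontal_x")
  fT <- least_squares(oracle$A, rand_td(vec_geom(6L), 632)) +
    operator_composition(l2sq_norm(alpha = 0.5), D)
  stb <- run_gd(fT, allocate(vec_geom(4L), 0), step = "backtracking",
                max_iters = 80)
  expect_true(all(diff(stb$objective_history$objective) <= 1e-12))
})

test_that("GD on smooth Tikhonov agrees with block CGLS", {
  ig <- image_geometry(4, 4)
  ag <- acquisition_geometry("parallel2D", angles = c(0, 60, 120),
                             pixel_num_h = 4)
  A <- projection_operator(ig, ag)
  D <- gradient_operator(ig)
  alpha <- 0.5
  b <- op_direct(A, rand_td(ig, 640))
  f <- least_squares(A, b) +
    operator_composition(l2sq_norm(alpha = alpha^2), D)
  st <- run_gd(f, allocate(ig, 0), step = "backtracking", max_iters = 4000)
  Atilde <- block_operator(list(A, alpha * D), nrow = 2L)
  btilde <- block_data(b, block_data(allocate(ig, 0), allocate(ig, 0)))
  stc <- run_cgls(Atilde, btilde, max_iters = 300, tol = 1e-14)
  expect_lt(l2norm(st$x - stc$x) / l2norm(stc$x), 1e-4)
})

test_that("FISTA solves the LASSO to coordinate-descent accuracy", {
  oracle <- rand_dense_op(6, 4, 650)
  bb <- rand_td(vec_geom(6L), 651)
  alpha <- 0.1
  f <- least_squares(oracle$A, bb)
  g <- l1_norm(alpha)
  st <- run_fista(f, g, allocate(vec_geom(4L), 0), max_iters = 2000)
  uo <- lasso_cd_oracle(oracle$M, as_vec(bb), alpha)
  expect_lt(abs(lasso_obj(oracle$M, as_vec(bb), alpha, as_vec(st$x)) -
                  lasso_obj(oracle$M, as_vec(bb), alpha, uo)), 1e-6)
})

test_that("FISTA with a nonnegativity box keeps iterates feasible", {
  oracle <- rand_dense_op(6, 4, 660)
  bb <- rand_td(vec_geom(6L), 661) - 0.8
  f <- least_squares(oracle$A, bb)
  g <- indicator_box(0, Inf)
  state <- run_fista(f, g, allocate(vec_geom(4L), 0.1), max_iters = 1)
  for (k in 1:20) {
    state <- run_more(state, 1)
    expect_gte(min(as_vec(state$x)), 0)
  }
})

test_that("FISTA beats plain GD on an ill-conditioned quadratic", {
  n <- 8L
  ig <- vec_geom(n)
  w <- td_from_vec(10^seq(0, 3, length.out = n), ig)  # condition number 1e3
  b <- rand_td(ig, 670)
  f <- weighted_l2sq_norm(w, b = b)
  x0 <- allocate(ig, 0)
  stg <- run_gd(f, x0, max_iters = 50)
  stf <- run_fista(f, constant_function(0), x0, max_iters = 50)
  expect_lt(utils::tail(stf$objective_history$objective, 1),
            utils::tail(stg$objective_history$objective, 1))
})

test_that("PDHG solves the trivial saddle point and closes the gap", {
  ig <- vec_geom(6L)
  b <- rand_td(ig, 680)
  st <- run_pdhg(l2sq_norm(b = b), identity_operator(ig), max_iters = 400)
  expect_lt(l2norm(st$x - b), 1e-6)
  gaps <- abs(st$gap_history$gap)
  expect_lt(utils::tail(gaps, 1), 1e-6)
})

test_that("PDHG rejects step sizes violating the bound", {
  ig <- vec_geom(4L)
  b <- rand_td(ig, 690)
  expect_error(run_pdhg(l2sq_norm(b = b), identity_operator(ig),
                        sigma = 2, tau = 2, max_iters = 5),
               "step-size bound")
})

test_that("deterministic solvers resume bit-exactly", {
  oracle <- rand_dense_op(6, 4, 700)
  bb <- rand_td(vec_geom(6L), 701)
  # CGLS
  a1 <- run_cgls(oracle$A, bb, max_iters = 10)
  a1 <- run_more(a1, 10)
  a2 <- run_cgls(oracle$A, bb, max_iters = 20)
  expect_identical(as_vec(a1$x), as_vec(a2$x))
  expect_identical(a1$objective_history, a2$objective_history)
  # SIRT
  M2 <- abs(oracle$M)
  Ao <- dense_operator(M2, vec_geom(4L), vec_geom(6L))
  s1 <- run_more(run_sirt(Ao, bb, max_iters = 7, lower = 0), 8)
  s2 <- run_sirt(Ao, bb, max_iters = 15, lower = 0)
  expect_identical(as_vec(s1$x), as_vec(s2$x))
  # GD
  f <- least_squares(oracle$A, bb)
  g1 <- run_more(run_gd(f, allocate(vec_geom(4L), 0), max_iters = 9), 6)
  g2 <- run_gd(f, allocate(vec_geom(4L), 0), max_iters = 15)
  expect_identical(as_vec(g1$x), as_vec(g2$x))
  # FISTA
  fi1 <- run_more(run_fista(f, l1_norm(0.05), allocate(vec_geom(4L), 0),
                            max_iters = 11), 9)
  fi2 <- run_fista(f, l1_norm(0.05), allocate(vec_geom(4L), 0),
                   max_iters = 20)
  expect_identical(as_vec(fi1$x), as_vec(fi2$x))
  # PDHG with fixed steps
  p1 <- run_more(run_pdhg(l2sq_norm(b = bb), identity_operator(vec_geom(6L)),
                          sigma = 0.5, tau = 0.5, max_iters = 6), 6)
  p2 <- run_pdhg(l2sq_norm(b = bb), identity_operator(vec_geom(6L)),
                 sigma = 0.5, tau = 0.5, max_iters = 12)
  expect_identical(as_vec(p1$x), as_vec(p2$x))
})

test_that("CGLS semi-convergence appears on noisy data", {
  n <- 32
  ig <- image_geometry(n, n)
  ag <- acquisition_geometry("parallel2D",
                             angles = seq(0, 176, by = 4), pixel_num_h = n)
  ph <- make_phantom(phantom_spec("steel_wire_like", n, seed = 4))
  clean <- simulate_acquisition(ph, ag)
  sigma <- 0.05 * max(abs(as_array(clean)))
  sino <- simulate_acquisition(ph, ag,
                               noise = list(type = "gaussian", sigma = sigma,
                                            seed = 41))
  A <- projection_operator(ig, ag)
  state <- NULL
  errs <- numeric(100)
  state <- run_cgls(A, sino, max_iters = 1)
  errs[1] <- l2norm(state$x - ph)
  for (k in 2:100) {
    state <- run_more(state, 1)
    errs[k] <- l2norm(state$x - ph)
  }
  kmin <- which.min(errs)
  expect_gt(kmin, 1)
  expect_lt(kmin, 100)
})
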