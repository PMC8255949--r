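test_that("every operator kind passes the adjoint identity", {
  ig <- small_ig(6L)
  ag <- acquisition_geometry("parallel2D",
                             angles = seq(0, 170, length.out = 9),
                             pixel_num_h = 6)
  d <- rand_td(ig, 31) + 0.5
  kernel <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
  mask <- as_array(rand_td(ig, 32)) > 0.3
  ops <- list(
    identity = identity_operator(ig),
    zero = zero_operator(ig, ig),
    diagonal = diagonal_operator(d),
    mask = mask_operator(mask, ig),
    finite_difference = finite_difference_operator(ig, "horizontal_x"),
    gradient = gradient_operator(ig),
    blurring = blurring_operator(ig, kernel),
    dense = rand_dense_op(7, 5, 33)$A,
    projector = projection_operator(ig, ag),
    scaled = 2.5 * projection_operator(ig, ag),
    sum = identity_operator(ig) + diagonal_operator(d),
    composition = op_compose(diagonal_operator(d),
                             finite_difference_operator(ig, "horizontal_y")),
    block = block_operator(list(projection_operator(ig, ag),
                                0.7 * gradient_operator(ig)), nrow = 2L)
  )
  for (nm in names(ops))
    expect_lt(adjoint_rel_err(ops[[nm]], npairs = 10L, seed = 40L), 1e-6,
              label = paste0("adjoint identity for '", nm, "'"))
})

test_that("elementary operators map as documented", {
  ig <- vec_geom(2L)
  v <- td_from_vec(c(5, -2), ig)
  expect_equal(as_vec(op_direct(identity_operator(ig), v)), c(5, -2))
  dg <- diagonal_operator(td_from_vec(c(1, 3), ig))
  expect_equal(as_vec(op_direct(dg, v)), c(5, -6))
  z <- zero_operator(ig, ig)
  expect_equal(as_vec(op_direct(z, v)), c(0, 0))
  expect_error(op_direct(dg, allocate(vec_geom(3L), 1)), "geometry mismatch")
})

test_that("finite differences use the stated stencil and exact transpose", {
  ig <- vec_geom(3L)
  D <- finite_difference_operator(ig, "horizontal_x")
  expect_equal(as_vec(op_direct(D, td_from_vec(c(1, 2, 4), ig))), c(1, 2, 0))
  expect_equal(as_vec(op_adjoint(D, td_from_vec(c(1, 1, 0), ig))),
               c(-1, 0, 1))
  expect_equal(as_vec(op_direct(D, td_from_vec(c(3, 3, 3), ig))), c(0, 0, 0))
  expect_error(finite_difference_operator(vec_geom(1L), "horizontal_x"),
               "extent")
})

test_that("gradient operator stacks one block per axis", {
  ig2 <- small_ig(5L)
  G2 <- gradient_operator(ig2)
  g2 <- op_direct(G2, rand_td(ig2, 50))
  expect_identical(n_blocks(g2), 2L)
  ig3 <- image_geometry(4, 4, 3)
  g3 <- op_direct(gradient_operator(ig3), allocate(ig3, "random", 51))
  expect_identical(n_blocks(g3), 3L)
  const <- op_direct(G2, allocate(ig2, 7))
  expect_equal(l2norm(const), 0)
})

test_that("block operators implement the Tikhonov stack", {
  oracle <- rand_dense_op(6, 4, 60)
  A <- oracle$A; M <- oracle$M
  ig <- vec_geom(4L); rg <- vec_geom(6L)
  D <- finite_difference_operator(ig, "horizontal_x")
  alpha <- 0.7
  Atilde <- block_operator(list(A, alpha * D), nrow = 2L)
  u <- rand_td(ig, 61)
  out <- op_direct(Atilde, u)
  expect_equal(as_vec(get_block(out, 1)), as.numeric(M %*% as_vec(u)))
  expect_equal(as_vec(get_block(out, 2)),
               alpha * as_vec(op_direct(D, u)))
  # adjoint on (b; 0) reduces to A* b
  b <- rand_td(rg, 62)
  bt <- block_data(b, allocate(ig, 0))
  expect_equal(as_vec(op_adjoint(Atilde, bt)),
               as.numeric(crossprod(M, as_vec(b))))
  # 4-row anisotropic stack evaluates as the concatenated residuals
  ig2 <- small_ig(4L)
  ag2 <- acquisition_geometry("parallel2D", angles = c(0, 45, 90, 135),
                              pixel_num_h = 4)
  P <- projection_operator(ig2, ag2)
  Dx <- finite_difference_operator(ig2, "horizontal_x")
  Dy <- finite_difference_operator(ig2, "horizontal_y")
  S <- block_operator(list(P, 30 * Dx, 0.1 * Dy), nrow = 3L)
  u2 <- rand_td(ig2, 63)
  res <- op_direct(S, u2)
  expect_equal(as_array(get_block(res, 1)), as_array(op_direct(P, u2)))
  expect_equal(as_array(get_block(res, 2)),
               30 * as_array(op_direct(Dx, u2)))
  expect_equal(as_array(get_block(res, 3)),
               0.1 * as_array(op_direct(Dy, u2)))
})

test_that("the projector integrates chords of a disc", {
  n <- 64
  ig <- image_geometry(n, n)
  r <- 0.25 * n
  ph <- make_phantom(phantom_spec("disc", n, radius = 0.25, value = 1))
  ag <- acquisition_geometry("parallel2D",
                             angles = seq(0, 165, by = 15), pixel_num_h = n)
  sino <- as_array(op_direct(projection_operator(ig, ag), ph))
  s <- (seq_len(n) - (n + 1) / 2)  # detector coordinates
  chord <- ifelse(abs(s) < r, 2 * sqrt(pmax(r^2 - s^2, 0)), 0)
  # central ray within 1%
  mid <- chord[n / 2]
  expect_lt(abs(sino[1, n / 2] - mid) / mid, 0.01)
  # RMS over the full profile within 2% of the chord scale, every angle
  for (a in seq_len(nrow(sino))) {
    rmse <- sqrt(mean((sino[a, ] - chord)^2))
    expect_lt(rmse / max(chord), 0.02)
  }
  # rotational symmetry: profiles agree across angles within 1% RMS
  for (a in 2:nrow(sino)) {
    expect_lt(sqrt(mean((sino[a, ] - sino[1, ])^2)) / max(chord), 0.01)
  }
  # zero image -> zero sinogram
  expect_equal(l2norm(op_direct(projection_operator(ig, ag),
                                allocate(ig, 0))), 0)
  # cone geometry refused
  cg <- acquisition_geometry("cone2D", angles = 0, pixel_num_h = n,
                             source_position = c(0, -10, 0),
                             detector_position = c(0, 10, 0))
  expect_error(projection_operator(ig, cg), "parallel")
})

test_that("back-projection of a single angle smears along rays", {
  n <- 16
  ig <- image_geometry(n, n)
  ag <- acquisition_geometry("parallel2D", angles = 0, pixel_num_h = n)
  bp <- as_array(op_adjoint(projection_operator(ig, ag), allocate(ag, 1)))
  # at theta = 0 rays run along y: columns are constant in the interior
  interior <- bp[4:(n - 3), 4:(n - 3)]
  expect_lt(max(apply(interior, 2, function(col) diff(range(col)))), 1e-9)
  expect_equal(l2norm(op_adjoint(projection_operator(ig, ag),
                                 allocate(ag, 0))), 0)
})

test_that("3D projection equals slice-wise 2D projection", {
  ag3 <- acquisition_geometry("parallel3D", angles = c(0, 30, 60),
                              pixel_num_h = 8, pixel_num_v = 3)
  ig3 <- default_image_geometry(ag3)
  x <- allocate(ig3, "random", 70)
  sino3 <- as_array(op_direct(projection_operator(ig3, ag3), x))
  ag2 <- acquisition_geometry("parallel2D", angles = c(0, 30, 60),
                              pixel_num_h = 8)
  ig2 <- image_geometry(8, 8)
  for (v in 1:3) {
    slice <- as_tomo_data(array(as_array(x)[v, , ], dim = c(8, 8)), ig2)
    sino2 <- as_array(op_direct(projection_operator(ig2, ag2), slice))
    expect_equal(sino3[, v, ], sino2)
  }
})

test_that("operator norm matches known singular values", {
  ig <- vec_geom(2L)
  expect_equal(operator_norm(identity_operator(ig), iters = 50), 1,
               tolerance = 1e-6)
  Dg <- diagonal_operator(td_from_vec(c(1, 3), ig))
  expect_equal(operator_norm(Dg, iters = 100), 3, tolerance = 1e-4)
  expect_equal(operator_norm(zero_operator(ig, ig)), 0)
  oracle <- rand_dense_op(6, 4, 80)
  nsvd <- max(svd(oracle$M)$d)
  expect_equal(operator_norm(oracle$A, iters = 200), nsvd, tolerance = 1e-6)
  expect_equal(operator_norm(2 * oracle$A, iters = 200), 2 * nsvd,
               tolerance = 1e-6)
  # Rayleigh lower bound on random vectors
  for (i in 1:5) {
    v <- allocate(vec_geom(4L), "random", 90 + i)
    expect_gte(nsvd + 1e-9,
               l2norm(op_direct(oracle$A, v)) / l2norm(v))
  }
})

test_that("operator algebra composes with correct adjoints", {
  ig <- small_ig(5L)
  v <- rand_td(ig, 95)
  expect_equal(as_array(op_direct(2 * identity_operator(ig), v)),
               2 * as_array(v))
  D <- finite_difference_operator(ig, "horizontal_x")
  CI <- op_compose(D, identity_operator(ig))
  expect_equal(as_array(op_direct(CI, v)), as_array(op_direct(D, v)))
  expect_error(op_compose(D, rand_dense_op(3, 2, 96)$A), "incompatible")
  S <- D + 0.5 * identity_operator(ig)
  expect_equal(as_array(op_direct(S, v)),
               as_array(op_direct(D, v)) + 0.5 * as_array(v))
})
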