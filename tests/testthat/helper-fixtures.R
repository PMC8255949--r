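# Shared fixtures: tiny geometries, random containers, dense oracles.

steel_wire_ag <- function() {
  # 91 projections over 180 degrees (last mirrors the first), 160x135 panel
  acquisition_geometry("parallel3D", angles = seq(0, 180, length.out = 91),
                       pixel_num_h = 160, pixel_num_v = 135)
}

small_ig <- function(n = 8L) image_geometry(n, n)

vec_geom <- function(n) image_geometry(n, 0L)   # 1D grid for dense oracles

rand_td <- function(geometry, seed) allocate(geometry, "random", seed)

as_vec <- function(x) as.numeric(as_array(x))

td_from_vec <- function(v, geometry)
  as_tomo_data(array(v, dim = unname(geom_shape(geometry))), geometry)

# random dense matrix operator between 1D grids
rand_dense_op <- function(nrow, ncol, seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  list(M = M, A = dense_operator(M, vec_geom(ncol), vec_geom(nrow)))
}

# adjoint-identity check on n random pairs, returns max relative error
adjoint_rel_err <- function(A, npairs = 10L, seed = 1L) {
  errs <- vapply(seq_len(npairs), function(i) {
    v <- allocate(A$domain, "random", seed + 2L * i)
    z <- allocate(A$range, "random", seed + 2L * i + 1L)
    lhs <- dot(op_direct(A, v), z)
    rhs <- dot(v, op_adjoint(A, z))
    den <- l2norm(op_direct(A, v)) * l2norm(z)
    if (den == 0) abs(lhs - rhs) else abs(lhs - rhs) / den
  }, numeric(1L))
  max(errs)
}
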