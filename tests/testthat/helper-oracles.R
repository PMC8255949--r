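# Independent oracles shared by the unit and acceptance suites.  Each is a
# deliberately different algorithm/code path from the implementation it
# checks.

# cyclic coordinate descent for  min ||Mu - b||^2 + alpha ||u||_1
lasso_cd_oracle <- function(M, b, alpha, iters = 5000) {
  u <- numeric(ncol(M))
  c2 <- 2 * colSums(M^2)
  for (k in seq_len(iters)) {
    for (j in seq_len(ncol(M))) {
      r <- b - M[, -j, drop = FALSE] %*% u[-j]
      rho <- 2 * sum(M[, j] * r)
      u[j] <- sign(rho) * max(abs(rho) - alpha, 0) / c2[j]
    }
  }
  u
}

lasso_obj <- function(M, b, alpha, u) sum((M %*% u - b)^2) + alpha * sum(abs(u))

# plain (non-accelerated) projected gradient on the ROF dual, long run
tv_prox_oracle <- function(u, lam, iters = 1e5) {
  uv <- as_array(u)
  axes <- which(dim(uv) >= 2L)
  d <- length(axes)
  p <- replicate(d, array(0, dim = dim(uv)), simplify = FALSE)
  fd <- function(a, ax) tomopt:::fd_forward_arr(a, ax)
  fdT <- function(a, ax) tomopt:::fd_adjoint_arr(a, ax)
  step <- 1 / (4 * d * lam)
  for (k in seq_len(iters)) {
    v <- uv - lam * Reduce(`+`, Map(fdT, p, as.list(axes)))
    p <- Map(function(pp, ax) pp + step * fd(v, ax), p, as.list(axes))
    nrm <- sqrt(Reduce(`+`, lapply(p, function(x) x^2)))
    fac <- ifelse(nrm > 1, 1 / nrm, 1)
    p <- lapply(p, function(x) x * fac)
  }
  uv - lam * Reduce(`+`, Map(fdT, p, as.list(axes)))
}
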