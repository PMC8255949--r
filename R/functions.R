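#' Convex function objects
#'
#' A `tomo_function` bundles whatever calculus a convex function exposes:
#' `value`, `gradient` (with Lipschitz constant `L` when the gradient is
#' Lipschitz), the proximal mapping
#' \deqn{\mathrm{prox}_{\tau g}(u) = \arg\min_v \{\tau g(v) +
#'   \tfrac12\|v-u\|_2^2\},}
#' the convex conjugate value and the proximal mapping of the conjugate
#' (used by PDHG).  When a closed-form conjugate prox is not supplied it is
#' derived from the Moreau identity
#' \eqn{\mathrm{prox}_{\sigma f^*}(y) = y - \sigma\,
#' \mathrm{prox}_{f/\sigma}(y/\sigma)}.
#'
#' @param kind tag string.
#' @param value function of one container.
#' @param gradient,prox,conjugate_value,prox_conjugate optional functions
#'   (`prox`/`prox_conjugate` take `(x, tau)`).
#' @param L optional Lipschitz constant of the gradient (may be a
#'   zero-argument function for lazy evaluation).
#' @return an object of class `tomo_function`.
#' @keywords internal
#' @export
tomo_function <- function(kind, value, gradient = NULL, prox = NULL,
                          conjugate_value = NULL, prox_conjugate = NULL,
                          L = NULL) {
  f <- structure(list(kind = kind, value = value, gradient = gradient,
                      prox = prox, conjugate_value = conjugate_value,
                      prox_conjugate = prox_conjugate, L = L),
                 class = "tomo_function")
  f
}

#' @export
print.tomo_function <- function(x, ...) {
  caps <- c(if (!is.null(x$gradient)) "gradient",
            if (!is.null(x$prox)) "prox",
            if (!is.null(x$prox_conjugate)) "prox*")
  cat("<tomo_function:", x$kind, "> [", paste(caps, collapse = ", "), "]\n")
  invisible(x)
}

#' Evaluate a function / its calculus
#'
#' @param f a `tomo_function`.
#' @param x,tau container argument and (positive) prox parameter.
#' @return `fn_value`: scalar; `fn_gradient`: container; `fn_prox` /
#'   `fn_prox_conjugate`: container; `fn_L`: scalar Lipschitz constant.
#' @export
fn_value <- function(f, x) f$value(x)

#' @rdname fn_value
#' @export
fn_gradient <- function(f, x) {
  if (is.null(f$gradient)) stop("function '", f$kind, "' is not smooth")
  f$gradient(x)
}

#' @rdname fn_value
#' @export
fn_prox <- function(f, x, tau) {
  if (is.null(f$prox)) stop("function '", f$kind, "' has no proximal mapping")
  stopifnot(tau > 0)
  f$prox(x, tau)
}

#' @rdname fn_value
#' @export
fn_prox_conjugate <- function(f, x, tau) {
  stopifnot(tau > 0)
  if (!is.null(f$prox_conjugate)) return(f$prox_conjugate(x, tau))
  if (is.null(f$prox)) stop("function '", f$kind,
                            "' has neither prox nor conjugate prox")
  x - tau * f$prox(x * (1 / tau), 1 / tau)   # Moreau identity
}

#' @rdname fn_value
#' @export
fn_L <- function(f) {
  if (is.null(f$L)) stop("function '", f$kind, "' has no Lipschitz constant")
  if (is.function(f$L)) f$L() else f$L
}

# ---- elementwise helpers on containers ------------------------------------

vox_norm <- function(X) {  # per-voxel l2 norm across blocks -> array
  sq <- lapply(X$blocks, function(b) b$values^2)
  sqrt(Reduce(`+`, sq))
}

#' Closed-form proximal mappings
#'
#' Stand-alone versions of the classic proximal operators, also wired into
#' the corresponding `tomo_function` constructors: soft-thresholding for the
#' L1 norm, the linear shrink for the squared L2 norm, per-voxel vector
#' shrinkage for the mixed L2,1 norm, and the box projection.
#'
#' @param x container (or `block_data` for the L2,1 case).
#' @param tau prox parameter (> 0).
#' @param alpha regularization weight (>= 0).
#' @param b shift (data) term for the squared L2 norm.
#' @return container of the same structure.
#' @name prox_ops
NULL

#' @rdname prox_ops
#' @export
prox_l1 <- function(x, tau, alpha = 1) {
  stopifnot(tau > 0, alpha >= 0)
  t <- alpha * tau
  td_map_any(x, function(v) sign(v) * pmax(abs(v) - t, 0))
}

#' @rdname prox_ops
#' @export
prox_l2sq <- function(x, tau, b = NULL, alpha = 1) {
  stopifnot(tau > 0)
  a <- 2 * alpha * tau
  if (is.null(b)) x * (1 / (1 + a)) else (x + a * b) * (1 / (1 + a))
}

#' @rdname prox_ops
#' @export
prox_mixed_l21 <- function(x, tau, alpha = 1) {
  stopifnot(inherits(x, "block_data"), tau > 0, alpha >= 0)
  nrm <- vox_norm(x)
  shrink <- ifelse(nrm > 0, pmax(1 - alpha * tau / nrm, 0), 0)
  out <- x
  out$blocks <- lapply(x$blocks, function(b) td_map(b, function(v) v * shrink))
  out
}

#' @rdname prox_ops
#' @param lower,upper box bounds (scalars or arrays).
#' @export
project_box <- function(x, lower = -Inf, upper = Inf) {
  if (any(lower > upper)) stop("'lower' must be <= 'upper'")
  td_map_any(x, function(v) pmin(pmax(v, lower), upper))
}

td_map_any <- function(x, fun) {
  if (inherits(x, "block_data")) {
    x$blocks <- lapply(x$blocks, td_map_any, fun = fun)
    x
  } else td_map(x, fun)
}

# ---- function constructors -------------------------------------------------

#' @rdname function_constructors
#' @export
constant_function <- function(c = 0) {
  tomo_function("constant",
    value = function(x) c,
    gradient = function(x) 0 * x,
    prox = function(x, tau) x,
    conjugate_value = function(y) if (l2norm(y) <= 1e-12) -c else Inf,
    L = 0)
}

#' Function constructors
#'
#' The convex functions of the framework.  `alpha` always scales the whole
#' function (the regularization parameter of penalty terms).
#'
#' * `constant_function(c)`: the constant `c`.
#' * `l2sq_norm(b, alpha)`: \eqn{\alpha\|x - b\|_2^2}.
#' * `weighted_l2sq_norm(w, b, alpha)`: \eqn{\alpha\sum_i w_i (x_i-b_i)^2}.
#' * `least_squares(A, b, c)`: \eqn{c\,\|Ax - b\|_2^2} with gradient
#'   \eqn{2c\,A^*(Ax-b)} and \eqn{L = 2c\,\|A\|^2} (power iteration, lazy).
#' * `l1_norm(alpha)`: \eqn{\alpha\|x\|_1}, prox = soft-thresholding.
#' * `mixed_l21_norm(alpha)`: \eqn{\alpha\|X\|_{2,1}} on block containers
#'   (per-voxel l2 across blocks, l1 over voxels); prox = vector shrinkage;
#'   conjugate = indicator of the per-voxel l2 ball of radius alpha.
#' * `smooth_l21_norm(beta, alpha)`: smoothed variant
#'   \eqn{\alpha\sum_v \sqrt{\sum_k X_{k,v}^2 + \beta^2}} with
#'   \eqn{L = \alpha/\beta}.
#' * `kullback_leibler(b, eta)`: count-data divergence
#'   \eqn{\sum_i (v_i+\eta_i) - b_i + b_i \log(b_i/(v_i+\eta_i))}
#'   (convention \eqn{0\log 0 = 0}); prox in closed form (quadratic root).
#' * `indicator_box(lower, upper)`: \eqn{\iota_{[l,u]}}, prox = projection.
#' * `total_variation(alpha, ...)`: \eqn{\alpha\|Du\|_{2,1}} with prox via
#'   fast gradient projection (FGP), see [tv_proximal()].
#' * `block_function(...)`: separable sum over a block container.
#' * `operator_composition(f, A)`: \eqn{f(Ax)}, gradient
#'   \eqn{A^*\nabla f(Ax)}, \eqn{L = L_f\|A\|^2}.
#'
#' @param b data container (defaults to zero where optional).
#' @param alpha non-negative scale.
#' @param w weight container.
#' @param A a `linear_operator`.
#' @param c scalar factor (least squares) or constant value.
#' @param beta smoothing parameter (> 0).
#' @param eta non-negative background term.
#' @param lower,upper box bounds.
#' @return a `tomo_function`.
#' @name function_constructors
NULL

#' @rdname function_constructors
#' @export
l2sq_norm <- function(b = NULL, alpha = 1) {
  stopifnot(alpha >= 0)
  tomo_function("l2sq",
    value = function(x) {
      r <- if (is.null(b)) x else x - b
      alpha * dot(r, r)
    },
    gradient = function(x) {
      r <- if (is.null(b)) x else x - b
      (2 * alpha) * r
    },
    prox = function(x, tau) prox_l2sq(x, tau, b = b, alpha = alpha),
    conjugate_value = function(y) {
      v <- dot(y, y) / (4 * alpha)
      if (!is.null(b)) v <- v + dot(b, y)
      v
    },
    prox_conjugate = function(y, sigma) {
      num <- if (is.null(b)) y else y - sigma * b
      num * (1 / (1 + sigma / (2 * alpha)))
    },
    L = 2 * alpha)
}

#' @rdname function_constructors
#' @export
weighted_l2sq_norm <- function(w, b = NULL, alpha = 1) {
  wv <- if (inherits(w, "tomo_data")) w$values else as.array(w)
  stopifnot(all(wv >= 0), alpha >= 0)
  tomo_function("weighted_l2sq",
    value = function(x) {
      r <- if (is.null(b)) x else x - b
      alpha * sum(wv * r$values^2)
    },
    gradient = function(x) {
      r <- if (is.null(b)) x else x - b
      td_map(r, function(v) 2 * alpha * wv * v)
    },
    prox = function(x, tau) {
      a <- 2 * alpha * tau * wv
      bb <- if (is.null(b)) 0 else b$values
      td_map(x, function(v) (v + a * bb) / (1 + a))
    },
    L = 2 * alpha * max(wv))
}

#' @rdname function_constructors
#' @export
least_squares <- function(A, b, c = 1) {
  stopifnot(inherits(A, "linear_operator"), c > 0)
  env <- new.env(parent = emptyenv())
  getL <- function() {
    if (is.null(env$L)) {
      nA <- if (!is.null(A$norm_hint)) A$norm_hint else operator_norm(A)
      env$L <- 2 * c * nA^2
    }
    env$L
  }
  tomo_function("least_squares",
    value = function(u) {
      r <- op_direct(A, u) - b
      c * dot(r, r)
    },
    gradient = function(u) {
      r <- op_direct(A, u) - b
      (2 * c) * op_adjoint(A, r)
    },
    L = getL)
}

#' @rdname function_constructors
#' @export
l1_norm <- function(alpha = 1) {
  stopifnot(alpha >= 0)
  tomo_function("l1",
    value = function(x) alpha * sum(abs(td_values(x))),
    prox = function(x, tau) prox_l1(x, tau, alpha),
    conjugate_value = function(y)
      if (max(abs(td_values(y))) <= alpha * (1 + 1e-9)) 0 else Inf,
    prox_conjugate = function(y, sigma)
      td_map_any(y, function(v) pmin(pmax(v, -alpha), alpha)))
}

td_values <- function(x) {
  if (inherits(x, "block_data"))
    unlist(lapply(x$blocks, td_values))
  else as.numeric(x$values)
}

#' @rdname function_constructors
#' @export
mixed_l21_norm <- function(alpha = 1) {
  stopifnot(alpha >= 0)
  tomo_function("mixed_l21",
    value = function(X) alpha * sum(vox_norm(X)),
    prox = function(X, tau) prox_mixed_l21(X, tau, alpha),
    conjugate_value = function(Y)
      if (max(vox_norm(Y)) <= alpha * (1 + 1e-9)) 0 else Inf,
    prox_conjugate = function(Y, sigma) {
      nrm <- vox_norm(Y)
      fac <- ifelse(nrm > alpha, alpha / nrm, 1)
      Y$blocks <- lapply(Y$blocks, function(b) td_map(b, function(v) v * fac))
      Y
    })
}

#' @rdname function_constructors
#' @export
smooth_l21_norm <- function(beta, alpha = 1) {
  if (beta <= 0) stop("'beta' must be > 0")
  tomo_function("smooth_l21",
    value = function(X) alpha * sum(sqrt(vox_norm(X)^2 + beta^2)),
    gradient = function(X) {
      den <- sqrt(vox_norm(X)^2 + beta^2)
      X$blocks <- lapply(X$blocks, function(b)
        td_map(b, function(v) alpha * v / den))
      X
    },
    L = alpha / beta)
}

#' Smoothed L2,1 value and gradient
#' @param X a `block_data`.
#' @param beta smoothing parameter (> 0).
#' @param alpha scale.
#' @return list with `value` and `gradient`.
#' @export
smooth_l21_value_gradient <- function(X, beta, alpha = 1) {
  f <- smooth_l21_norm(beta, alpha)
  list(value = fn_value(f, X), gradient = fn_gradient(f, X))
}

#' @rdname function_constructors
#' @export
kullback_leibler <- function(b, eta = 0) {
  bv <- td_values(b)
  stopifnot(all(bv >= 0))
  ev <- if (inherits(eta, "tomo_data")) eta$values else eta
  tomo_function("kullback_leibler",
    value = function(x) {
      w <- td_values(x) + as.numeric(ev)
      if (any(w <= 0 & bv > 0))
        stop("KL divergence undefined: v + eta <= 0 where b > 0")
      term <- w - bv
      pos <- bv > 0
      term[pos] <- term[pos] + bv[pos] * log(bv[pos] / w[pos])
      sum(term)
    },
    gradient = function(x) {
      td_map(x, function(v) {
        w <- v + ev
        bb <- array(bv, dim = dim(v))
        if (any(w <= 0 & bb > 0))
          stop("KL gradient undefined: v + eta <= 0 where b > 0")
        1 - bb / w
      })
    },
    prox = function(x, tau) {
      td_map(x, function(v) {
        bb <- array(bv, dim = dim(v))
        q <- tau - ev - v
        w <- 0.5 * (-q + sqrt(q^2 + 4 * tau * bb))
        w - ev
      })
    })
}

#' Kullback-Leibler value and gradient
#' @param v container of expected counts (before background).
#' @param b observed counts (same shape, non-negative).
#' @param eta background term (scalar or array, >= 0).
#' @return list with `value` and `gradient`.
#' @export
kl_value_gradient <- function(v, b, eta = 0) {
  f <- kullback_leibler(b, eta)
  list(value = fn_value(f, v), gradient = fn_gradient(f, v))
}

#' @rdname function_constructors
#' @export
indicator_box <- function(lower = -Inf, upper = Inf) {
  if (any(lower > upper)) stop("'lower' must be <= 'upper'")
  tomo_function("indicator_box",
    value = function(x) {
      v <- td_values(x)
      if (all(v >= lower - 1e-12) && all(v <= upper + 1e-12)) 0 else Inf
    },
    prox = function(x, tau) project_box(x, lower, upper),
    conjugate_value = function(y) {   # support function of the box
      v <- td_values(y)
      if ((any(v > 0) && !all(is.finite(upper))) ||
          (any(v < 0) && !all(is.finite(lower)))) return(Inf)
      sum(pmax(v, 0) * upper) + sum(pmin(v, 0) * lower)
    })
}

#' @rdname function_constructors
#' @param inner_iters,tol,nonneg FGP controls, see [tv_proximal()].
#' @export
total_variation <- function(alpha = 1, inner_iters = 100L, tol = 1e-5,
                            nonneg = FALSE) {
  stopifnot(alpha >= 0)
  env <- new.env(parent = emptyenv())  # warm-started dual variables
  tomo_function("total_variation",
    value = function(u) tv_value(u, alpha),
    prox = function(u, tau) {
      out <- tv_proximal(u, tau, alpha = alpha, inner_iters = inner_iters,
                         tol = tol, nonneg = nonneg, dual_init = env$p)
      env$p <- attr(out, "dual")
      attr(out, "dual") <- NULL
      out
    })
}

#' Total-variation value
#'
#' Isotropic TV: the mixed L2,1 norm of the Neumann finite-difference
#' gradient, scaled by `alpha`.
#'
#' @param u an `image_data`.
#' @param alpha scale.
#' @return scalar.
#' @export
tv_value <- function(u, alpha = 1) {
  stopifnot(inherits(u, "tomo_data"))
  u <- to_canonical(u)
  axes <- which(dim(u$values) >= 2L)
  if (length(axes) == 0L) return(0)
  sq <- lapply(axes, function(ax) fd_forward_arr(u$values, ax)^2)
  alpha * sum(sqrt(Reduce(`+`, sq)))
}

#' Total-variation proximal mapping by fast gradient projection
#'
#' Approximately solves the denoising problem
#' \deqn{\arg\min_v \{\alpha\tau\,TV(v) + \tfrac12\|v-u\|_2^2\}}
#' by accelerated projected gradient (FGP) on the dual, with dual step
#' \eqn{1/(4d\lambda)} for `d` differenced axes and
#' \eqn{\lambda = \alpha\tau}, FISTA momentum, and optional nonnegativity
#' projection of the primal at every step.  Stops after `inner_iters`
#' iterations or when the relative dual change drops below `tol`.
#'
#' @param u an `image_data`.
#' @param tau prox parameter (> 0).
#' @param alpha TV weight (> 0).
#' @param inner_iters iteration budget (default 100).
#' @param tol relative dual-change tolerance (default `1e-5`).
#' @param nonneg clip the primal to `[0, Inf)` (default `FALSE`).
#' @param dual_init optional warm-start dual variables (as returned in the
#'   `"dual"` attribute).
#' @return the denoised image; the final dual variables are attached as
#'   attribute `"dual"` (used for warm starts across FISTA iterations).
#' @export
tv_proximal <- function(u, tau, alpha = 1, inner_iters = 100L, tol = 1e-5,
                        nonneg = FALSE, dual_init = NULL) {
  stopifnot(inherits(u, "tomo_data"), tau > 0, alpha >= 0)
  u <- to_canonical(u)
  if (alpha == 0) return(u)
  uv <- u$values
  axes <- which(dim(uv) >= 2L)
  d <- length(axes)
  if (d == 0L) return(u)
  lam <- alpha * tau
  step <- 1 / (4 * d * lam)
  clipC <- function(v) if (nonneg) pmax(v, 0) else v
  p <- q <- if (!is.null(dual_init) && length(dual_init) == d &&
                identical(dim(dual_init[[1L]]), dim(uv)))
    dual_init else replicate(d, array(0, dim = dim(uv)), simplify = FALSE)
  q <- p
  t_k <- 1
  for (k in seq_len(inner_iters)) {
    divq <- Reduce(`+`, Map(function(pp, ax) fd_adjoint_arr(pp, ax),
                            q, as.list(axes)))
    v <- clipC(uv - lam * divq)
    pn <- Map(function(qq, ax) qq + step * fd_forward_arr(v, ax),
              q, as.list(axes))
    nrm <- sqrt(Reduce(`+`, lapply(pn, function(x) x^2)))
    fac <- ifelse(nrm > 1, 1 / nrm, 1)
    pn <- lapply(pn, function(x) x * fac)
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    q <- Map(function(new, old) new + ((t_k - 1) / t_next) * (new - old),
             pn, p)
    dp <- sqrt(sum(unlist(Map(function(a, b) sum((a - b)^2), pn, p))))
    np <- sqrt(sum(unlist(lapply(pn, function(x) sum(x^2)))))
    p <- pn
    t_k <- t_next
    if (np > 0 && dp / np < tol) break
  }
  divp <- Reduce(`+`, Map(function(pp, ax) fd_adjoint_arr(pp, ax),
                          p, as.list(axes)))
  out <- td_map(u, function(vv) clipC(vv - lam * divp))
  attr(out, "dual") <- p
  out
}

#' Least-squares value and gradient
#' @param u point of evaluation.
#' @param A a `linear_operator`.
#' @param b data in the range of `A`.
#' @return list with `value` and `gradient`.
#' @export
least_squares_value_gradient <- function(u, A, b) {
  f <- least_squares(A, b)
  list(value = fn_value(f, u), gradient = fn_gradient(f, u))
}

#' @rdname function_constructors
#' @param ... `tomo_function`s, one per block (or a single list).
#' @export
block_function <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && is.list(fs[[1L]]) &&
      !inherits(fs[[1L]], "tomo_function"))
    fs <- fs[[1L]]
  stopifnot(all(vapply(fs, inherits, logical(1L), "tomo_function")))
  bf <- tomo_function("block",
    value = function(X) sum(unlist(Map(function(f, x) f$value(x),
                                       fs, X$blocks))),
    gradient = if (all(vapply(fs, function(f) !is.null(f$gradient),
                              logical(1L))))
      function(X) {
        X$blocks <- Map(function(f, x) f$gradient(x), fs, X$blocks)
        X
      },
    prox = if (all(vapply(fs, function(f) !is.null(f$prox), logical(1L))))
      function(X, tau) {
        X$blocks <- Map(function(f, x) f$prox(x, tau), fs, X$blocks)
        X
      },
    conjugate_value = if (all(vapply(fs, function(f)
      !is.null(f$conjugate_value), logical(1L))))
      function(Y) sum(unlist(Map(function(f, y) f$conjugate_value(y),
                                 fs, Y$blocks))),
    prox_conjugate = function(Y, sigma) {
      Y$blocks <- Map(function(f, y) fn_prox_conjugate(f, y, sigma),
                      fs, Y$blocks)
      Y
    },
    L = if (all(vapply(fs, function(f) !is.null(f$L), logical(1L))))
      function() max(vapply(fs, fn_L, numeric(1L))))
  bf$functions <- fs
  bf
}

#' @rdname function_constructors
#' @export
operator_composition <- function(f, A) {
  stopifnot(inherits(f, "tomo_function"), inherits(A, "linear_operator"))
  env <- new.env(parent = emptyenv())
  getL <- function() {
    if (is.null(env$L)) {
      nA <- if (!is.null(A$norm_hint)) A$norm_hint else operator_norm(A)
      env$L <- fn_L(f) * nA^2
    }
    env$L
  }
  tomo_function("operator_composition",
    value = function(u) f$value(op_direct(A, u)),
    gradient = if (!is.null(f$gradient))
      function(u) op_adjoint(A, f$gradient(op_direct(A, u))),
    L = if (!is.null(f$L)) getL)
}

#' @export
Ops.tomo_function <- function(e1, e2) {
  if (.Generic == "*") {
    if (inherits(e1, "tomo_function") && is.numeric(e2)) {
      f <- e1; a <- e2
    } else if (inherits(e2, "tomo_function") && is.numeric(e1)) {
      f <- e2; a <- e1
    } else stop("function '*' requires one function and one scalar")
    stopifnot(length(a) == 1L, a >= 0)
    return(tomo_function(paste0("scaled(", f$kind, ")"),
      value = function(x) a * f$value(x),
      gradient = if (!is.null(f$gradient)) function(x) a * f$gradient(x),
      prox = if (!is.null(f$prox)) function(x, tau)
        if (a == 0) x else f$prox(x, a * tau),
      conjugate_value = if (!is.null(f$conjugate_value) && a > 0)
        function(y) a * f$conjugate_value(y * (1 / a)),
      L = if (!is.null(f$L)) function() a * fn_L(f)))
  }
  if (.Generic == "+") {
    stopifnot(inherits(e1, "tomo_function"), inherits(e2, "tomo_function"))
    return(tomo_function(paste0(e1$kind, "+", e2$kind),
      value = function(x) e1$value(x) + e2$value(x),
      gradient = if (!is.null(e1$gradient) && !is.null(e2$gradient))
        function(x) e1$gradient(x) + e2$gradient(x),
      prox = NULL,  # sums are not separable
      L = if (!is.null(e1$L) && !is.null(e2$L))
        function() fn_L(e1) + fn_L(e2)))
  }
  stop("unsupported function generic: ", .Generic)
}
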