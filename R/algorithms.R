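#' Iterative solvers with resumable state
#'
#' Every solver returns a `tomo_algorithm` state holding the current
#' iterate (`$x`), the iteration counter, objective (and, for PDHG, dual
#' and gap) histories, and everything needed to continue: running
#' `run_more(state, m)` after `run_*(..., max_iters = n)` reproduces
#' `run_*(..., max_iters = n + m)` bit-exactly for the deterministic
#' solvers.
#'
#' @name tomo_algorithm
NULL

new_algo_state <- function(kind, x, env) {
  structure(list(kind = kind, iteration = 0L, x = x, env = env,
                 objective_history = data.frame(iteration = integer(),
                                                objective = numeric()),
                 dual_history = data.frame(iteration = integer(),
                                           dual = numeric()),
                 gap_history = data.frame(iteration = integer(),
                                          gap = numeric())),
            class = "tomo_algorithm")
}

#' @export
print.tomo_algorithm <- function(x, ...) {
  cat("<tomo_algorithm:", x$kind, "> iteration", x$iteration, "\n")
  if (nrow(x$objective_history) > 0L)
    cat("  objective:",
        format(utils::tail(x$objective_history$objective, 1L)), "\n")
  invisible(x)
}

record <- function(state, objective, dual = NULL, gap = NULL) {
  state$objective_history <- rbind(
    state$objective_history,
    data.frame(iteration = state$iteration, objective = objective))
  if (!is.null(dual))
    state$dual_history <- rbind(
      state$dual_history,
      data.frame(iteration = state$iteration, dual = dual))
  if (!is.null(gap))
    state$gap_history <- rbind(
      state$gap_history,
      data.frame(iteration = state$iteration, gap = gap))
  state
}

#' Continue an algorithm from its current state
#' @param state a `tomo_algorithm`.
#' @param n number of additional iterations.
#' @return the advanced state.
#' @export
run_more <- function(state, n) {
  stopifnot(inherits(state, "tomo_algorithm"))
  stepper <- switch(state$kind,
    cgls = step_cgls, sirt = step_sirt, gd = step_gd,
    fista = step_fista, pdhg = step_pdhg,
    stop("unknown algorithm kind: ", state$kind))
  for (i in seq_len(n)) {
    state <- stepper(state)
    if (isTRUE(state$env$converged)) break
  }
  state
}

#' Conjugate gradient least squares (CGLS)
#'
#' Minimizes \eqn{\|Au - b\|_2^2} by conjugate gradients on the normal
#' equations without forming \eqn{A^*A}.  Exhibits semi-convergence on
#' noisy data: iterate count acts as the regularization parameter.
#'
#' @param A a `linear_operator` (plain or block).
#' @param b data in the range of `A` (container or block container).
#' @param x0 initial iterate (default: zeros).
#' @param max_iters iteration budget.
#' @param tol optional stop when
#'   \eqn{\|A^*(Au-b)\| / \|A^*b\| < } `tol` (0 disables).
#' @param state resume from a previous state (other arguments ignored).
#' @return a `tomo_algorithm`; `$x` is the solution,
#'   `$objective_history` records \eqn{\|Au-b\|_2^2}.
#' @export
run_cgls <- function(A, b, x0 = NULL, max_iters = 10L, tol = 0,
                     state = NULL) {
  if (is.null(state)) {
    x <- if (is.null(x0)) allocate_any(A$domain, 0) else x0
    env <- new.env(parent = emptyenv())
    env$A <- A; env$b <- b; env$tol <- tol
    env$r <- b - A$direct(x)
    env$s <- A$adjoint(env$r)
    env$p <- env$s
    env$gamma <- dot(env$s, env$s)
    env$denom <- l2norm(A$adjoint(b))
    env$converged <- FALSE
    state <- new_algo_state("cgls", x, env)
  }
  run_more(state, max_iters)
}

step_cgls <- function(state) {
  e <- state$env
  if (e$gamma == 0) { e$converged <- TRUE; return(state) }
  q <- e$A$direct(e$p)
  qn <- dot(q, q)
  if (qn == 0) { e$converged <- TRUE; return(state) }
  alpha <- e$gamma / qn
  state$x <- state$x + alpha * e$p
  e$r <- e$r - alpha * q
  e$s <- e$A$adjoint(e$r)
  gnew <- dot(e$s, e$s)
  beta <- gnew / e$gamma
  e$gamma <- gnew
  e$p <- e$s + beta * e$p
  state$iteration <- state$iteration + 1L
  state <- record(state, dot(e$r, e$r))
  if (e$tol > 0 && e$denom > 0 && sqrt(gnew) / e$denom < e$tol)
    e$converged <- TRUE
  state
}

#' Simultaneous iterative reconstruction technique (SIRT)
#'
#' Solves the row-weighted least-squares problem by the relaxation
#' \deqn{x \leftarrow P_{[l,u]}\big(x + D A^*(M (b - Ax))\big)}
#' with \eqn{M = \mathrm{diag}(1/\text{row sums})} and
#' \eqn{D = \mathrm{diag}(1/\text{column sums})}, the sums obtained by
#' applying \eqn{A} and \eqn{A^*} to all-ones containers (valid for
#' operators with non-negative entries, e.g. projectors).  Box constraints
#' are enforced exactly at every iterate.
#'
#' @inheritParams run_cgls
#' @param lower,upper optional box bounds (default unbounded).
#' @return a `tomo_algorithm`; `$objective_history` records the weighted
#'   residual norm \eqn{(b-Ax)^T M (b-Ax)}.
#' @export
run_sirt <- function(A, b, x0 = NULL, max_iters = 10L,
                     lower = -Inf, upper = Inf, state = NULL) {
  if (is.null(state)) {
    x <- if (is.null(x0)) allocate_any(A$domain, 0) else x0
    x <- project_box(x, lower, upper)
    env <- new.env(parent = emptyenv())
    env$A <- A; env$b <- b; env$lower <- lower; env$upper <- upper
    rows <- A$direct(allocate_any(A$domain, 1))
    cols <- A$adjoint(allocate_any(A$range, 1))
    inv0 <- function(v) {
      bad <- v <= 0
      out <- ifelse(bad, 0, 1 / pmax(v, .Machine$double.xmin))
      if (any(bad))
        warning(sum(bad), " zero row/column sum(s); weights set to 0")
      out
    }
    env$M <- td_map_any(rows, inv0)
    env$D <- td_map_any(cols, inv0)
    env$converged <- FALSE
    state <- new_algo_state("sirt", x, env)
  }
  run_more(state, max_iters)
}

step_sirt <- function(state) {
  e <- state$env
  res <- e$b - e$A$direct(state$x)
  upd <- e$D * e$A$adjoint(e$M * res)
  state$x <- project_box(state$x + upd, e$lower, e$upper)
  state$iteration <- state$iteration + 1L
  record(state, dot(res, e$M * res))
}

#' Gradient descent (constant step or Armijo backtracking)
#'
#' @param f a smooth `tomo_function` (gradient available; constant step
#'   additionally needs `L`).
#' @param x0 initial iterate.
#' @param step positive scalar step, or `"backtracking"` (Armijo with
#'   shrink 0.5, slope factor `1e-4`, trial step 1); default `1/L`.
#' @param max_iters iteration budget.
#' @param state resume from a previous state.
#' @return a `tomo_algorithm` with objective history `f(x)`.
#' @export
run_gd <- function(f, x0, step = NULL, max_iters = 100L, state = NULL) {
  if (is.null(state)) {
    if (is.null(f$gradient)) stop("gradient descent requires a smooth 'f'")
    env <- new.env(parent = emptyenv())
    env$f <- f
    if (identical(step, "backtracking")) {
      env$backtrack <- TRUE
    } else {
      env$backtrack <- FALSE
      env$step <- if (is.null(step)) 1 / fn_L(f) else step
      stopifnot(env$step > 0)
    }
    env$converged <- FALSE
    state <- new_algo_state("gd", x0, env)
  }
  run_more(state, max_iters)
}

step_gd <- function(state) {
  e <- state$env
  g <- fn_gradient(e$f, state$x)
  if (e$backtrack) {
    fx <- fn_value(e$f, state$x)
    gg <- dot(g, g)
    s <- 1
    repeat {
      xn <- state$x - s * g
      if (fn_value(e$f, xn) <= fx - 1e-4 * s * gg || s < 1e-12) break
      s <- s / 2
    }
    state$x <- xn
  } else {
    state$x <- state$x - e$step * g
  }
  state$iteration <- state$iteration + 1L
  record(state, fn_value(e$f, state$x))
}

#' FISTA (fast iterative shrinkage-thresholding)
#'
#' Solves \eqn{\min_u f(u) + g(u)} with `f` L-smooth and `g` proximable:
#' \deqn{x_k = \mathrm{prox}_{g/L}(y_k - \nabla f(y_k)/L)}
#' with momentum \eqn{t_{k+1} = (1+\sqrt{1+4t_k^2})/2},
#' \eqn{y_{k+1} = x_k + \frac{t_k - 1}{t_{k+1}}(x_k - x_{k-1})}.
#'
#' @param f smooth `tomo_function` with Lipschitz constant.
#' @param g proximable `tomo_function` (e.g. [l1_norm()],
#'   [indicator_box()], [total_variation()]).
#' @param x0 initial iterate.
#' @param max_iters iteration budget.
#' @param state resume from a previous state.
#' @return a `tomo_algorithm`; objective history records `f(x) + g(x)`.
#' @export
run_fista <- function(f, g, x0, max_iters = 100L, state = NULL) {
  if (is.null(state)) {
    if (is.null(f$gradient) || is.null(f$L))
      stop("FISTA requires a smooth 'f' with known Lipschitz constant")
    if (is.null(g$prox)) stop("FISTA requires a proximable 'g'")
    env <- new.env(parent = emptyenv())
    env$f <- f; env$g <- g
    env$L <- fn_L(f)
    env$y <- x0
    env$t <- 1
    env$converged <- FALSE
    state <- new_algo_state("fista", x0, env)
  }
  run_more(state, max_iters)
}

step_fista <- function(state) {
  e <- state$env
  grad <- fn_gradient(e$f, e$y)
  xn <- fn_prox(e$g, e$y - (1 / e$L) * grad, 1 / e$L)
  tn <- (1 + sqrt(1 + 4 * e$t^2)) / 2
  e$y <- xn + ((e$t - 1) / tn) * (xn - state$x)
  e$t <- tn
  state$x <- xn
  state$iteration <- state$iteration + 1L
  record(state, fn_value(e$f, xn) + fn_value(e$g, xn))
}

#' Primal-dual hybrid gradient (PDHG / Chambolle-Pock)
#'
#' Solves \eqn{\min_u f(Ku) + g(u)} where the proximal mapping of the
#' conjugate of each block of `f` and the proximal mapping of `g` are
#' available:
#' \deqn{y \leftarrow \mathrm{prox}_{\sigma f^*}(y + \sigma K \bar x),\quad
#'       x^+ \leftarrow \mathrm{prox}_{\tau g}(x - \tau K^* y),\quad
#'       \bar x \leftarrow x^+ + \theta(x^+ - x).}
#' Default steps \eqn{\sigma = \tau = 1/\|K\|} (power iteration) and
#' \eqn{\theta = 1}; the convergence requirement
#' \eqn{\sigma\tau\|K\|^2 \le 1} is checked.  The primal objective
#' \eqn{f(Kx)+g(x)}, a dual objective and the primal-dual gap are recorded
#' every `eval_interval` iterations; when `g` is the zero function the dual
#' reported is the unconstrained surrogate \eqn{-\sum_i f_i^*(y_i)}.
#'
#' @param f a `tomo_function` (typically a [block_function()]) with
#'   conjugate prox available.
#' @param K a `linear_operator` (typically a [block_operator()]).
#' @param g proximable `tomo_function`; default: zero.
#' @param x0 initial iterate (default zeros).
#' @param sigma,tau positive step sizes (defaults `1/||K||`).
#' @param theta over-relaxation (default 1).
#' @param max_iters iteration budget.
#' @param eval_interval history recording cadence (default 1).
#' @param state resume from a previous state.
#' @return a `tomo_algorithm` with `$objective_history`, `$dual_history`
#'   and `$gap_history`.
#' @export
run_pdhg <- function(f, K, g = NULL, x0 = NULL, sigma = NULL, tau = NULL,
                     theta = 1, max_iters = 100L, eval_interval = 1L,
                     state = NULL) {
  if (is.null(state)) {
    if (is.null(g)) g <- constant_function(0)
    if (is.null(g$prox)) stop("PDHG requires a proximable 'g'")
    normK <- operator_norm(K)
    if (is.null(sigma) && is.null(tau)) {
      sigma <- tau <- 1 / normK
    } else if (is.null(sigma)) sigma <- 1 / (tau * normK^2)
    else if (is.null(tau)) tau <- 1 / (sigma * normK^2)
    if (sigma * tau * normK^2 > 1 + 1e-6)
      stop("sigma * tau * ||K||^2 = ", format(sigma * tau * normK^2),
           " > 1 violates the PDHG step-size bound; try sigma = tau = 1/||K||",
           " = ", format(1 / normK))
    env <- new.env(parent = emptyenv())
    env$f <- f; env$K <- K; env$g <- g
    env$sigma <- sigma; env$tau <- tau; env$theta <- theta
    env$eval_interval <- as.integer(eval_interval)
    x <- if (is.null(x0)) allocate_any(K$domain, 0) else x0
    env$xbar <- x
    env$y <- 0 * K$direct(x)
    env$converged <- FALSE
    state <- new_algo_state("pdhg", x, env)
  }
  run_more(state, max_iters)
}

step_pdhg <- function(state) {
  e <- state$env
  e$y <- fn_prox_conjugate(e$f, e$y + e$sigma * e$K$direct(e$xbar), e$sigma)
  xn <- fn_prox(e$g, state$x - e$tau * e$K$adjoint(e$y), e$tau)
  e$xbar <- xn + e$theta * (xn - state$x)
  state$x <- xn
  state$iteration <- state$iteration + 1L
  if (state$iteration %% e$eval_interval == 0L) {
    primal <- fn_value(e$f, e$K$direct(xn)) + fn_value(e$g, xn)
    dual <- pdhg_dual_value(e)
    state <- record(state, primal, dual = dual,
                    gap = if (is.finite(dual)) primal - dual else NA_real_)
  }
  state
}

pdhg_dual_value <- function(e) {
  fstar <- if (!is.null(e$f$conjugate_value)) e$f$conjugate_value(e$y)
           else return(NA_real_)
  gstar <- if (e$g$kind == "constant") 0
           else if (!is.null(e$g$conjugate_value))
             e$g$conjugate_value((-1) * e$K$adjoint(e$y))
           else return(NA_real_)
  -(fstar + gstar)
}

#' Export objective histories as CSV
#'
#' Writes `(iteration, objective[, dual, gap])` rows for convergence
#' plotting.
#'
#' @param state a `tomo_algorithm`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_history_csv <- function(state, path) {
  stopifnot(inherits(state, "tomo_algorithm"))
  h <- state$objective_history
  if (nrow(state$dual_history) > 0L)
    h <- merge(h, state$dual_history, by = "iteration", all.x = TRUE)
  if (nrow(state$gap_history) > 0L)
    h <- merge(h, state$gap_history, by = "iteration", all.x = TRUE)
  utils::write.csv(h, path, row.names = FALSE)
  invisible(path)
}
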