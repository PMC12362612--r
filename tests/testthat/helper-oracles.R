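# Independent oracles used to cross-check the package's root finding,
# reaction mapping and filter realization. These deliberately avoid the
# implementation paths they validate.

# repressing / activating Hill functions
h_rep <- function(y, K, m) K^m / (K^m + y^m)
h_act <- function(y, K, m) y^m / (K^m + y^m)

# All equilibria of the ISOLATED (possibly unbalanced) toggle by explicit
# 1-D elimination: y2 = a2*h(y1)/delta, then dense sign-change bracketing
# of g(y1) = a1*h(y2(y1))/delta - y1 plus uniroot refinement.
toggle_roots_1d <- function(a1, a2, K = 1, m = 3, delta = 1, n = 20000) {
  g <- function(y1) {
    y2 <- a2 * h_rep(y1, K, m) / delta
    a1 * h_rep(y2, K, m) / delta - y1
  }
  hi <- 1.5 * max(a1, a2) / delta
  xs <- seq(0, hi, length.out = n)
  gv <- g(xs)
  idx <- which(sign(gv[-n]) * sign(gv[-1]) < 0)
  y1 <- vapply(idx, function(i)
    uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-13)$root, numeric(1))
  cbind(y1 = y1, y2 = a2 * h_rep(y1, K, m) / delta)
}

# Brute-force equilibrium count: cells of an n x n lattice over the search
# box where BOTH components of the reduced map change sign among the four
# corners. No Newton iteration, no seeding heuristics.
brute_equilibrium_count <- function(spec, n = 400) {
  f <- fatecontrol:::reduced_rhs_fn(spec)
  box <- fatecontrol:::search_box(spec)
  g <- seq(box[1], box[2], length.out = n)
  G <- expand.grid(y1 = g, y2 = g)
  Fv <- f(G$y1, G$y2)
  F1 <- matrix(Fv[, 1], n, n)
  F2 <- matrix(Fv[, 2], n, n)
  change <- function(M) {
    lo <- pmin(M[-n, -n], M[-1, -n], M[-n, -1], M[-1, -1])
    hi <- pmax(M[-n, -n], M[-1, -n], M[-n, -1], M[-1, -1])
    lo <= 0 & hi >= 0
  }
  flag <- change(F1) & change(F2)
  # a transversal crossing can light up a small patch of adjacent cells;
  # count connected components (8-connectivity) rather than raw cells
  comp <- 0L
  visited <- matrix(FALSE, n - 1, n - 1)
  idx <- which(flag, arr.ind = TRUE)
  flagged <- flag
  for (k in seq_len(nrow(idx))) {
    i0 <- idx[k, 1]; j0 <- idx[k, 2]
    if (visited[i0, j0]) next
    comp <- comp + 1L
    queue <- list(c(i0, j0))
    visited[i0, j0] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii >= 1 && ii <= n - 1 && jj >= 1 && jj <= n - 1 &&
            flagged[ii, jj] && !visited[ii, jj]) {
          visited[ii, jj] <- TRUE
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  comp
}

# Simpson-rule convolution of the input with the impulse response
# k*theta * t * exp(-delta t) - xi * exp(-delta t): the direct inverse
# Laplace evaluation of the (unclipped) fast-sequestration transfer
# function, independent of the ODE filter-cascade realization.
convolution_linear_output <- function(params, input_fn, t_star, dt = 0.0015) {
  kth <- params$k * params$theta
  xi <- params$xi
  del <- params$delta
  vapply(t_star, function(tt) {
    if (tt == 0) return(0)
    ns <- ceiling(tt / dt / 2) * 2  # even number of intervals
    s <- seq(0, tt, length.out = ns + 1)
    integrand <- (kth * s * exp(-del * s) - xi * exp(-del * s)) *
      vapply(tt - s, input_fn, numeric(1))
    w <- c(1, rep(c(4, 2), length.out = ns - 1), 1)
    sum(w * integrand) * (tt / ns) / 3
  }, numeric(1))
}

nominal <- function(...) kinetic_params(...)

expect_close <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max|%s - %s| < %g",
                              paste(signif(object, 6), collapse = ","),
                              paste(signif(expected, 6), collapse = ","),
                              tol))
}
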