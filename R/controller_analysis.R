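# Fast-sequestration approximation of the controller output: a two-state
# low-pass filter cascade followed by a clipped linear combination, and the
# convergence of the full nonlinear controller to it as gamma grows.

#' Approximate controller output in the fast-sequestration limit
#'
#' Realizes the limiting input-output map of the controller as a time-domain
#' filter cascade: z1' = -delta*z1 + y(t), z2' = -delta*z2 + z1, with output
#' u1 ~ max{0, k*theta*z2 - xi*z1}. This is the state-space realization of
#' the transfer function [k*theta - xi*(s+delta)] / (s+delta)^2, i.e. a
#' low-pass filter minus a filtered derivative; at adaptive metric r = 1 the
#' DC gain is zero, so the output vanishes for any input that settles to a
#' constant (perfect adaptation). The clip to zero is applied pointwise to
#' the output signal.
#'
#' @param params a [kinetic_params()] object (only xi, theta, k, delta used).
#' @param input_fn nonnegative function of time (uM).
#' @param t_grid strictly increasing time grid starting at 0 (h).
#' @return Numeric vector of the approximate u1 on \code{t_grid}; the
#'   unclipped linear response is in \code{attr(,"linear")}.
#' @export
approx_output <- function(params, input_fn, t_grid) {
  stopifnot(inherits(params, "kinetic_params"), is.function(input_fn))
  yv <- vapply(t_grid, input_fn, numeric(1))
  if (any(yv < 0))
    stop("input_fn must be nonnegative on t_grid", call. = FALSE)
  del <- params$delta
  sol <- deSolve::ode(y = c(z1 = 0, z2 = 0), times = t_grid,
                      func = function(t, z, p)
                        list(c(-del * z[1] + input_fn(t),
                               -del * z[2] + z[1])),
                      rtol = 1e-10, atol = 1e-12)
  lin <- params$k * params$theta * sol[, "z2"] - params$xi * sol[, "z1"]
  out <- pmax(0, lin)
  attr(out, "linear") <- unname(lin)
  out
}

#' Distance of the full controller to its fast-sequestration approximation
#'
#' For each sequestration rate, simulates the full isolated controller
#' driven by the input and reports the sup-norm distance between its u1 and
#' [approx_output()] on the grid. The distance shrinks as gamma grows.
#'
#' @param params a [kinetic_params()] object (gamma is overridden per run).
#' @param input_fn nonnegative input function of time.
#' @param gammas positive, increasing sequestration rates.
#' @param t_grid time grid (h).
#' @return Named numeric vector of sup-norm errors, one per gamma.
#' @export
error_vs_gamma <- function(params, input_fn, gammas, t_grid) {
  if (any(gammas <= 0) || is.unsorted(gammas, strictly = TRUE))
    stop("gammas must be positive and increasing", call. = FALSE)
  u_approx <- approx_output(params, input_fn, t_grid)
  errs <- vapply(gammas, function(gam) {
    p <- params
    p$gamma <- gam
    spec <- make_isolated_controller(p, input_fn)
    sol <- deSolve::ode(y = c(0, 0, 0), times = t_grid,
                        func = function(t, y, q)
                          list(rhs_eval(spec, y, t)),
                        rtol = 1e-9, atol = 1e-11)
    u1 <- sol[, 1 + match("U1", spec$species)]
    max(abs(u1 - u_approx))
  }, numeric(1))
  names(errs) <- paste0("gamma=", gammas)
  errs
}
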