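# Deterministic and stochastic integration of model specs.

new_trajectory <- function(times, states, kind, species,
                           omega = NA_real_, seed = NA_integer_,
                           absorbed = FALSE) {
  colnames(states) <- species
  structure(list(times = times, states = states, kind = kind,
                 omega = omega, seed = seed, absorbed = absorbed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d points over [0, %g] h, species %s\n",
              toupper(x$kind), length(x$times), max(x$times),
              paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Integrate a model deterministically
#'
#' Stiff-capable integration (lsoda) of the ODE right-hand side encoded in
#' the spec, sampled on a uniform output grid. Concentrations are clipped at
#' zero in the returned states (the integrator may probe values a rounding
#' error below zero).
#'
#' @param spec a [model_spec()].
#' @param x0 initial concentrations (uM), in species order.
#' @param t_end final time (h).
#' @param rtol,atol relative / absolute integration tolerances. The defaults
#'   are tight because basin boundaries of the bistable systems are
#'   sensitive to integration error.
#' @param n_out number of output grid points.
#' @return A \code{"trajectory"} object (states in uM).
#' @export
simulate_ode <- function(spec, x0, t_end, rtol = 1e-8, atol = 1e-10,
                         n_out = 2000) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(x0) != length(spec$species))
    stop("x0 length does not match species count", call. = FALSE)
  if (any(x0 < 0)) stop("x0 must be nonnegative", call. = FALSE)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = as.numeric(x0), times = times,
                      func = function(t, y, p) list(rhs_eval(spec, y, t)),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed at t = ", max(sol[, 1]), call. = FALSE)
  states <- unname(sol[, -1, drop = FALSE])
  if (min(states) < -1e-9)
    stop("integration produced negative states beyond numerical slack",
         call. = FALSE)
  states[states < 0] <- 0
  new_trajectory(sol[, 1], states, "ode", spec$species)
}

#' Simulate a model with the exact stochastic simulation algorithm
#'
#' Gillespie's direct method over [reactions()]\code{(spec)}. Concentrations
#' are converted to molecule counts at system size \code{omega} (molecules
#' per uM): zeroth-order propensities scale by omega and second-order ones
#' by 1/omega. An identical seed yields an identical trajectory. If the
#' total propensity reaches zero before \code{t_end} the state is absorbing
#' and is held to the end of the horizon (no error).
#'
#' @param spec a [model_spec()].
#' @param x0 initial concentrations (uM); \code{round(x0 * omega)} gives the
#'   initial counts.
#' @param t_end final time (h).
#' @param omega system size (molecules per uM), >= 1.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param n_out number of recording grid points.
#' @return A \code{"trajectory"} object; states are molecule counts.
#' @export
simulate_ssa <- function(spec, x0, t_end, omega = 1, seed = NULL,
                         n_out = 400) {
  stopifnot(inherits(spec, "model_spec"))
  if (omega < 1) stop("omega must be >= 1", call. = FALSE)
  if (length(x0) != length(spec$species))
    stop("x0 length does not match species count", call. = FALSE)
  if (any(x0 < 0)) stop("x0 must be nonnegative", call. = FALSE)
  counts <- round(x0 * omega)
  if (max(abs(counts - x0 * omega)) > 1e-8)
    warning("x0 * omega is not integer; counts were rounded")
  enc <- encode_reactions(reactions(spec))
  if (!is.null(seed)) set.seed(seed)
  out_times <- seq(0, t_end, length.out = n_out)
  res <- ssa_direct_cpp(enc$stoich, enc$type, enc$rate, enc$s1, enc$s2,
                        enc$K, enc$m, enc$act, as.numeric(counts),
                        out_times, omega)
  new_trajectory(out_times, res$states, "ssa", spec$species,
                 omega = omega,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 absorbed = res$absorbed)
}

# per-run seed derived from the master seed so that any subset of runs is
# reproducible independently of the others
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 65011) * 33013 + i * 7919) %% 2147483629L + 1L
}

#' Run an ensemble of independent simulations
#'
#' Repeats a simulation \code{n} times with per-run seeds derived
#' deterministically from the master seed, and returns the terminal states
#' only (rows = runs). This is the protocol behind the cell-fate ensembles:
#' many stochastic trajectories from a common start, classified at a fixed
#' horizon.
#'
#' @param spec a [model_spec()].
#' @param x0 initial concentrations (uM).
#' @param n number of runs (>= 1).
#' @param t_end final time (h).
#' @param mode "ssa" (default) or "ode" (deterministic; all runs identical).
#' @param omega system size for SSA.
#' @param seed master seed.
#' @return Matrix \code{n x n_species} of terminal states (counts for SSA,
#'   uM for ODE), with the per-run seeds in \code{attr(,"seeds")}.
#' @export
run_ensemble <- function(spec, x0, n, t_end, mode = c("ssa", "ode"),
                         omega = 1, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  finals <- matrix(NA_real_, n, length(spec$species),
                   dimnames = list(NULL, spec$species))
  for (i in seq_len(n)) {
    tr <- if (mode == "ssa") {
      simulate_ssa(spec, x0, t_end, omega = omega, seed = seeds[i],
                   n_out = 2L)
    } else {
      simulate_ode(spec, x0, t_end, n_out = 200L)
    }
    finals[i, ] <- tr$states[nrow(tr$states), ]
  }
  attr(finals, "seeds") <- seeds
  attr(finals, "omega") <- if (mode == "ssa") omega else NA_real_
  attr(finals, "t_end") <- t_end
  attr(finals, "mode") <- mode
  finals
}
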